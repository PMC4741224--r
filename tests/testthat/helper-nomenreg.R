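# Shared helpers: handcrafted minimal manuscripts and store constructors.

ACCEPT_DAY <- as.Date("2015-11-20")
PUB_DAY <- as.Date("2016-01-07")

make_store <- function(registry = "zoobank", clock = ACCEPT_DAY) {
  registry_store(registry, clock = clock)
}

# Handcrafted prefix-free manuscript (exercises the non-namespaced dialect).
tiny_manuscript <- function(treatments = "", title = "A tiny revision",
                            code = "ICZN", issn = "2000-1234",
                            archive = "CLOCKSS",
                            contribs = '<contrib contrib-type="author"><name><surname>Smith</surname><given-names>Jane</given-names></name></contrib>') {
  issn_xml <- if (nzchar(issn)) sprintf("<issn>%s</issn>", issn) else ""
  archive_xml <- if (nzchar(archive)) {
    sprintf("<custom-meta><meta-name>archive</meta-name><meta-value>%s</meta-value></custom-meta>",
            archive)
  } else ""
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<article dtd-version="1.1">
  <front>
    <journal-meta><journal-title>Tiny Journal</journal-title>%s</journal-meta>
    <article-meta>
      <article-id pub-id-type="doi">10.9999/tiny.1</article-id>
      <title-group><article-title>%s</article-title></title-group>
      <contrib-group>%s</contrib-group>
      <history><date date-type="accepted" iso-8601-date="2015-11-20"/></history>
      <custom-meta-group>%s<custom-meta><meta-name>nomenclatural-code</meta-name><meta-value>%s</meta-value></custom-meta></custom-meta-group>
    </article-meta>
  </front>
  <body>%s</body>
</article>
', issn_xml, title, contribs, archive_xml, code, treatments)
}

treatment_block <- function(genus = "Aus", species = NULL, status = "sp. nov.",
                            authority = "Smith", hybrid = FALSE,
                            uninomial = NULL) {
  parts <- c(
    if (!is.null(uninomial))
      sprintf('<taxon-name-part taxon-name-part-type="uninomial">%s</taxon-name-part>', uninomial),
    if (is.null(uninomial))
      sprintf('<taxon-name-part taxon-name-part-type="genus">%s</taxon-name-part>', genus),
    if (!is.null(species))
      sprintf('<taxon-name-part taxon-name-part-type="species">%s</taxon-name-part>', species))
  sprintf('<taxon-treatment><nomenclature><taxon-name%s>%s</taxon-name><taxon-authority>%s</taxon-authority><taxon-status>%s</taxon-status></nomenclature></taxon-treatment>',
          if (hybrid) ' is-hybrid="true"' else "",
          paste(parts, collapse = ""), authority, status)
}

# Convenience generator wrapper returning both fixture and parsed form.
gen_ms <- function(n_acts, seed, ...) {
  fx <- generate_manuscript(fixture_spec(n_acts = n_acts, seed = seed, ...))
  list(fx = fx, ms = parse_manuscript(fx$xml))
}

# A pipeline report's identifier coverage: injected ids recovered by reparse.
reparse_injected_ids <- function(xml_text) {
  ms <- parse_manuscript(xml_text)
  unlist(lapply(ms$treatments, `[[`, "injected_ids"))
}
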