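# The botanical/fungal registration channel: acts go out as a batch of
# name records in a conservative subset of the Taxon Concept Transfer
# Schema (TaxonName with canonical name, authorship, rank, status phrase,
# basionym authorship, publication citation), and the registry answers the
# same batch with a RegistryId inserted per record.  Transport is modelled
# as a function call against a registry store; documents can be written to
# disk for audit.

tcs_rank_of <- function(act) {
  if (!is.null(act$rank)) return(act$rank)
  n <- act$name
  if (!is.null(n$infraspecific)) "infraspecific"
  else if (!is.null(n$species)) "specific"
  else if (!is.null(n$uninomial)) "generic"
  else "unranked"
}

#' Export acts as a TCS name-record batch
#'
#' One `<TaxonName>` record per act, in act order.  Every act must pass
#' [validate_act()] for the target registry; a rejected act refuses the
#' whole batch with the validation reason, since the registry would bounce
#' it.  New combinations carry their basionym authorship; other records do
#' not.
#'
#' @param acts list of [nomenclatural_act()]s.
#' @param meta article metadata list (as in a parsed manuscript).
#' @param registry target registry (defaults to `"ipni"`).
#' @return TCS-subset XML as a string.
#' @export
to_tcs <- function(acts, meta, registry = "ipni") {
  matrix <- scope_matrix()
  for (i in seq_along(acts)) {
    verdict <- validate_act(acts[[i]], registry, matrix)
    if (verdict$status == "reject") {
      stop(sprintf("act %d refused for %s: %s", i, registry, verdict$reason),
           call. = FALSE)
    }
  }
  doc <- xml2::xml_new_root("DataSet", schema = "tcs-subset-1.0")
  names_node <- xml2::xml_add_child(doc, "TaxonNames")
  for (i in seq_along(acts)) {
    act <- acts[[i]]
    canonical <- canonical_name_string(act$name)
    tn <- xml2::xml_add_child(
      names_node, "TaxonName", id = sprintf("n%d", i),
      nomenclaturalCode = if (act$code == "ICZN") "Zoological" else "Botanical")
    xml2::xml_add_child(tn, "Simple",
                        trimws(paste(canonical, act$name$authorship)))
    xml2::xml_add_child(tn, "Rank", tcs_rank_of(act))
    cn <- xml2::xml_add_child(tn, "CanonicalName")
    xml2::xml_add_child(cn, "Simple", canonical)
    xml2::xml_add_child(tn, "CanonicalAuthorship", act$name$authorship)
    xml2::xml_add_child(tn, "PublicationStatus", act$status_phrase %||%
                          paste(act_descriptor(act), collapse = " "))
    if (act$is_hybrid) xml2::xml_add_child(tn, "Hybrid", "true")
    if (act$kind == "new_combination") {
      if (is.null(act$name$basionym_authorship)) {
        stop(sprintf("act %d: new combination without basionym authorship", i),
             call. = FALSE)
      }
      xml2::xml_add_child(tn, "Basionym", act$name$basionym_authorship)
    }
    xml2::xml_add_child(tn, "PublishedIn", paste0(
      meta$title %||% "", ". ", meta$journal %||% "",
      if (!is.null(meta$doi)) paste0(". doi:", meta$doi) else ""))
  }
  as.character(doc)
}

#' Parse a TCS registry response into an identifier map
#'
#' @param xml_text response XML (the submitted batch with `<RegistryId>`
#'   elements inserted).
#' @param n_submitted size of the submitted batch.
#' @return character vector of length `n_submitted`: the identifier per
#'   act index, or `NA` where the registry failed to supply one.
#' @export
parse_tcs_response <- function(xml_text, n_submitted) {
  doc <- xml2::read_xml(xml_text)
  records <- xml2::xml_find_all(doc, ".//TaxonNames/TaxonName")
  if (length(records) != n_submitted) {
    stop(sprintf("protocol error: response has %d records for a batch of %d",
                 length(records), n_submitted), call. = FALSE)
  }
  vapply(records, function(r) {
    id <- xml_text1(r, "./RegistryId")
    if (is.null(id) || !nzchar(id)) NA_character_ else id
  }, character(1L))
}

# Rebuild an act from a TCS record (registry side of the loopback).
act_from_tcs_record <- function(tn, code) {
  canonical <- xml_text1(tn, "./CanonicalName/Simple") %||% ""
  tokens <- strsplit(trimws(canonical), "\\s+")[[1L]]
  rank <- xml_text1(tn, "./Rank")
  name <- if (length(tokens) >= 3L) {
    scientific_name(genus = tokens[1L], species = tokens[2L],
                    infraspecific = tokens[3L])
  } else if (length(tokens) == 2L) {
    scientific_name(genus = tokens[1L], species = tokens[2L])
  } else {
    scientific_name(uninomial = tokens[1L])
  }
  name$authorship <- xml_text1(tn, "./CanonicalAuthorship") %||% ""
  basionym <- xml_text1(tn, "./Basionym")
  if (!is.null(basionym)) name$basionym_authorship <- basionym
  classify_act(xml_text1(tn, "./PublicationStatus"), name,
               is_hybrid = identical(xml_text1(tn, "./Hybrid"), "true"),
               code = code)
}

#' Simulated registry endpoint for a TCS batch
#'
#' Plays the registry's side of the TCS channel: parses the submitted
#' batch, upserts every record into the store (embargoed, under the
#' article), and returns the batch with a `<RegistryId>` inserted per
#' record -- the response [parse_tcs_response()] consumes.
#'
#' @param tcs_xml the submitted batch from [to_tcs()].
#' @param store the receiving [registry_store()].
#' @param article_id optional owning article record identifier.
#' @return response XML as a string.
#' @export
tcs_respond <- function(tcs_xml, store, article_id = NULL) {
  doc <- xml2::read_xml(tcs_xml)
  code <- store$code
  for (tn in xml2::xml_find_all(doc, ".//TaxonNames/TaxonName")) {
    act <- act_from_tcs_record(tn, code)
    res <- upsert_record(store, act, article_id = article_id)
    xml2::xml_add_child(tn, "RegistryId", res$record$id)
  }
  as.character(doc)
}
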