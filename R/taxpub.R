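# The supported manuscript dialect is a small TaxPub-conformant subset of
# JATS: an <article> whose <front> carries the bibliographic metadata and
# whose <body> holds <tp:taxon-treatment> elements, each with one or more
# <tp:nomenclature> blocks (taxon name parts, authority, status phrase).
# Both the tp:-prefixed and prefix-free spellings of the treatment elements
# are accepted.  The dialect is documented in
# inst/extdata/schema/taxpub-subset.xsd.

NOMEN_OPEN_RE <- "<(tp:)?nomenclature(\\s[^>]*)?>"
INJECT_TEMPLATE <- '<object-id content-type="registry-id">%s</object-id>'

# Normalize the dialect for DOM queries: drop the tp: namespace prefix and
# its declaration so namespaced and prefix-free manuscripts parse alike.
# Used only for the DOM; byte anchors are computed on the original text.
strip_tp_prefix <- function(xml_text) {
  xml_text <- gsub(' xmlns:tp="[^"]*"', "", xml_text)
  gsub("(</?)tp:", "\\1", xml_text)
}

parse_iso_date <- function(x, what) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(NULL)
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) {
    stop(sprintf("structural error: %s '%s' is not an ISO-8601 calendar date",
                 what, x), call. = FALSE)
  }
  d <- as.Date(x)
  if (is.na(d)) {
    stop(sprintf("structural error: %s '%s' is not a real calendar date",
                 what, x), call. = FALSE)
  }
  d
}

xml_text1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NULL else xml2::xml_text(hit)
}

custom_meta_value <- function(meta, name) {
  xml_text1(meta, sprintf(
    ".//custom-meta[meta-name='%s']/meta-value", name))
}

# Byte anchors: position right after the ">" of every nomenclature open tag,
# in document order.  Injection splices at these offsets, so everything
# outside them is preserved verbatim.
nomenclature_anchors <- function(xml_text) {
  m <- gregexpr(NOMEN_OPEN_RE, xml_text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) + attr(m, "match.length") - 1L
}

parse_name_node <- function(nom) {
  part <- function(type) {
    xml_text1(nom, sprintf(
      ".//taxon-name/taxon-name-part[@taxon-name-part-type='%s']", type))
  }
  authorship <- xml_text1(nom, ".//taxon-authority") %||% ""
  basionym <- NULL
  paren <- regmatches(authorship, regexec("^\\(([^)]+)\\)", authorship))[[1L]]
  if (length(paren) == 2L) basionym <- paren[2L]
  scientific_name(uninomial = part("uninomial"), genus = part("genus"),
                  species = part("species"),
                  infraspecific = part("infraspecific"),
                  authorship = authorship, basionym_authorship = basionym)
}

#' Parse a TaxPub manuscript
#'
#' Reads a manuscript in the supported TaxPub/JATS dialect and extracts the
#' article metadata, the contributor list, and every taxonomic treatment
#' with its nomenclatural acts, in document order.  Byte anchors into the
#' source text are kept so that identifier injection can splice the source
#' rather than re-serialize it.
#'
#' @param xml_text the manuscript XML as a single UTF-8 string.
#' @return an object of class `manuscript` with fields `article_meta`,
#'   `contributors`, `treatments` (each with `acts` and `injected_ids`),
#'   `anchors` and `xml_text`.
#' @export
parse_manuscript <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(strip_tp_prefix(xml_text)),
                  error = function(e) {
                    stop(sprintf("XML parse error: %s", conditionMessage(e)),
                         call. = FALSE)
                  })
  xml2::xml_ns_strip(doc)

  title <- xml_text1(doc, ".//article-meta//article-title")
  contrib_nodes <- xml2::xml_find_all(
    doc, ".//article-meta//contrib-group/contrib")
  missing <- c(
    if (is.null(title) || !nzchar(title)) "article-title",
    if (length(contrib_nodes) == 0L) "contrib-group/contrib")
  if (length(missing) > 0L) {
    stop(sprintf("structural error: missing required element(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  meta_node <- xml2::xml_find_first(doc, ".//article-meta")
  acceptance_date <- parse_iso_date(
    xml2::xml_attr(xml2::xml_find_first(
      doc, ".//article-meta//date[@date-type='accepted']"), "iso-8601-date"),
    "acceptance date")
  publication_date <- parse_iso_date(
    xml2::xml_attr(xml2::xml_find_first(
      doc, ".//article-meta/pub-date"), "iso-8601-date"),
    "publication date")
  if (!is.null(publication_date) && !is.null(acceptance_date) &&
      publication_date < acceptance_date) {
    stop("structural error: publication date precedes acceptance date",
         call. = FALSE)
  }

  article_meta <- list(
    title = title,
    journal = xml_text1(doc, ".//journal-meta/journal-title"),
    issn_or_isbn = xml_text1(doc, ".//journal-meta/issn"),
    doi = xml_text1(doc, ".//article-meta/article-id[@pub-id-type='doi']"),
    archive_name = custom_meta_value(meta_node, "archive"),
    code = custom_meta_value(meta_node, "nomenclatural-code") %||% "ICNafp",
    acceptance_date = acceptance_date,
    publication_date = publication_date
  )
  if (!article_meta$code %in% CODES) {
    stop(sprintf("structural error: unknown nomenclatural code '%s'",
                 article_meta$code), call. = FALSE)
  }

  contributors <- lapply(contrib_nodes, function(n) {
    surname <- xml_text1(n, ".//surname")
    if (is.null(surname) || !nzchar(surname)) {
      stop("structural error: contributor without surname", call. = FALSE)
    }
    author_name(surname, xml_text1(n, ".//given-names") %||% "")
  })

  treatments <- lapply(
    xml2::xml_find_all(doc, ".//body//taxon-treatment"),
    function(tr) {
      noms <- xml2::xml_find_all(tr, ".//nomenclature")
      acts <- lapply(noms, function(nom) {
        phrase <- xml_text1(nom, ".//taxon-status")
        if (is.null(phrase)) {
          stop("structural error: nomenclature block without taxon-status",
               call. = FALSE)
        }
        hybrid <- identical(
          xml2::xml_attr(xml2::xml_find_first(nom, ".//taxon-name"),
                         "is-hybrid"), "true")
        classify_act(phrase, parse_name_node(nom), is_hybrid = hybrid,
                     code = article_meta$code)
      })
      injected <- xml2::xml_text(xml2::xml_find_all(
        tr, ".//nomenclature/object-id[@content-type='registry-id']"))
      if (length(injected) > 0L && length(injected) != length(acts)) {
        stop("structural error: injected identifiers do not match acts one-to-one",
             call. = FALSE)
      }
      list(acts = acts, injected_ids = injected)
    })

  anchors <- nomenclature_anchors(xml_text)
  n_acts <- sum(vapply(treatments, function(t) length(t$acts), integer(1L)))
  if (length(anchors) != n_acts) {
    stop("structural error: nomenclature anchors do not match parsed acts",
         call. = FALSE)
  }

  structure(
    list(article_meta = article_meta, contributors = contributors,
         treatments = treatments, anchors = anchors, xml_text = xml_text),
    class = "manuscript"
  )
}

#' Flatten a manuscript's acts in document order
#'
#' @param manuscript a parsed [parse_manuscript()] object.
#' @return list of `nomenclatural_act` objects, document order.
#' @export
manuscript_acts <- function(manuscript) {
  do.call(c, c(lapply(manuscript$treatments, `[[`, "acts"), list()))
}

#' @export
print.manuscript <- function(x, ...) {
  cat(sprintf("<manuscript> \"%s\" (%d contributors, %d treatments, %d acts)\n",
              x$article_meta$title, length(x$contributors),
              length(x$treatments), length(manuscript_acts(x))))
  invisible(x)
}

#' Inject registry identifiers into a manuscript
#'
#' Splices one `<object-id content-type="registry-id">` element as the first
#' child of each act's nomenclature block.  The input text is modified only
#' at those injection points: everything else -- whitespace, attribute
#' order, entities -- is preserved byte for byte, so diffs against the
#' source show exactly one insertion per act.
#'
#' @param manuscript the parsed manuscript (for its act list).
#' @param assignments character vector of identifiers, one per act in
#'   document order (may be named by act index).
#' @param xml_text manuscript XML to splice; defaults to the text
#'   `manuscript` was parsed from.
#' @return the manuscript XML with identifiers injected.
#' @export
inject_identifiers <- function(manuscript, assignments,
                               xml_text = manuscript$xml_text) {
  acts <- manuscript_acts(manuscript)
  assignments <- unlist(assignments, use.names = TRUE)
  if (!is.null(names(assignments)) && any(nzchar(names(assignments)))) {
    idx <- as.integer(names(assignments))
    ordered <- rep(NA_character_, length(acts))
    ordered[idx] <- assignments
    assignments <- ordered
  }
  uncovered <- which(is.na(assignments) | !nzchar(assignments))
  if (length(assignments) != length(acts) || length(uncovered) > 0L) {
    if (length(assignments) < length(acts)) {
      uncovered <- union(uncovered, seq(length(assignments) + 1L, length(acts)))
    }
    stop(sprintf("incomplete assignment: no identifier for act(s) %s",
                 paste(sort(uncovered), collapse = ", ")), call. = FALSE)
  }
  anchors <- nomenclature_anchors(xml_text)
  if (length(anchors) != length(acts)) {
    stop("xml_text does not contain one nomenclature block per act",
         call. = FALSE)
  }
  out <- xml_text
  for (i in rev(seq_along(anchors))) {
    insert <- sprintf(INJECT_TEMPLATE, assignments[i])
    out <- paste0(substr(out, 1L, anchors[i]), insert,
                  substr(out, anchors[i] + 1L, nchar(out)))
  }
  out
}
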