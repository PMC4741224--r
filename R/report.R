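# Registration reports mirror the registry's acceptance-stage response: one
# outcome per act (and per author), each carrying exactly one of a minted
# identifier, an error message, or a pending-disambiguation reference.

empty_outcomes <- function() {
  data.frame(index = integer(0), status = character(0), id = character(0),
             message = character(0), pending_ref = character(0),
             stringsAsFactors = FALSE)
}

outcome_row <- function(index, status, id = "", message = "",
                        pending_ref = "") {
  data.frame(index = as.integer(index), status = status, id = id,
             message = message, pending_ref = pending_ref,
             stringsAsFactors = FALSE)
}

#' Construct a registration report
#'
#' @param article_id identifier of the article record in the registry.
#' @param registry target registry name.
#' @param acts,authors outcome data.frames with columns `index`, `status`
#'   (`"registered"`, `"error"` or `"pending"`), `id`, `message`,
#'   `pending_ref`.
#' @return an object of class `registration_report`.
#' @export
registration_report <- function(article_id, registry,
                                acts = empty_outcomes(),
                                authors = empty_outcomes()) {
  for (df in list(acts, authors)) {
    stopifnot(all(df$status %in% c("registered", "error", "pending")),
              !is.unsorted(df$index))
  }
  rownames(acts) <- NULL
  rownames(authors) <- NULL
  structure(list(article_id = article_id, registry = registry,
                 acts = acts, authors = authors),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  tab <- table(factor(x$acts$status,
                      levels = c("registered", "error", "pending")))
  cat(sprintf("<registration report> article %s @ %s: %d registered, %d error, %d pending\n",
              x$article_id, x$registry, tab[["registered"]], tab[["error"]],
              tab[["pending"]]))
  invisible(x)
}

#' Does a report block the downstream pipeline?
#'
#' Identifier injection and release require every act outcome to be
#' `registered`; a pending author disambiguation also blocks.
#'
#' @param report a [registration_report()].
#' @return `TRUE` when any outcome is `error` or `pending`.
#' @export
report_blocked <- function(report) {
  any(report$acts$status != "registered") ||
    any(report$authors$status == "pending")
}

serialize_outcomes <- function(parent, rows, element) {
  force(parent)  # the container element must exist even with zero outcomes
  for (i in seq_len(nrow(rows))) {
    node <- xml2::xml_add_child(parent, element, index = rows$index[i],
                                status = rows$status[i])
    if (rows$status[i] == "registered") {
      xml2::xml_add_child(node, "id", rows$id[i])
    } else if (rows$status[i] == "error") {
      xml2::xml_add_child(node, "message", rows$message[i])
    } else {
      xml2::xml_add_child(node, "pending-ref", rows$pending_ref[i])
    }
    if (rows$status[i] == "registered" && nzchar(rows$message[i])) {
      xml2::xml_add_child(node, "message", rows$message[i])
    }
  }
}

#' Serialize a registration report to response XML
#'
#' The response document carries one `<act>` (and one `<author>`) element
#' per outcome, each holding exactly one of `<id>`, `<message>` or
#' `<pending-ref>` according to its status (a registered outcome may carry
#' an additional advisory `<message>`).  [parse_report()] is its inverse.
#'
#' @param report a [registration_report()].
#' @return response XML as a string.
#' @export
serialize_report <- function(report) {
  doc <- xml2::xml_new_root("registration-report",
                            "article-id" = report$article_id,
                            registry = report$registry)
  serialize_outcomes(xml2::xml_add_child(doc, "acts"), report$acts, "act")
  serialize_outcomes(xml2::xml_add_child(doc, "authors"), report$authors,
                     "author")
  as.character(doc)
}

parse_outcomes <- function(doc, xpath) {
  nodes <- xml2::xml_find_all(doc, xpath)
  if (length(nodes) == 0L) return(empty_outcomes())
  do.call(rbind, lapply(nodes, function(n) {
    status <- xml2::xml_attr(n, "status")
    outcome_row(
      index = as.integer(xml2::xml_attr(n, "index")),
      status = status,
      id = if (status == "registered") xml_text1(n, "./id") %||% "" else "",
      message = xml_text1(n, "./message") %||% "",
      pending_ref = xml_text1(n, "./pending-ref") %||% "")
  }))
}

#' Parse a response-report XML document
#'
#' @param xml_text response XML produced by [serialize_report()].
#' @return the [registration_report()] it encodes.
#' @export
parse_report <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  registration_report(
    article_id = xml2::xml_attr(doc, "article-id"),
    registry = xml2::xml_attr(doc, "registry"),
    acts = parse_outcomes(doc, "./acts/act"),
    authors = parse_outcomes(doc, "./authors/author"))
}
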