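# Schema validation against the in-repo XSDs.  Instance documents may use
# the tp: prefix; the schemas describe the namespace-stripped form, so
# documents are stripped before validation.

load_schema <- function(name) {
  xml2::read_xml(system.file("extdata", "schema", name, package = "nomenreg",
                             mustWork = TRUE))
}

validate_against <- function(xml_text, schema_file) {
  doc <- xml2::read_xml(strip_tp_prefix(xml_text))
  xml2::xml_ns_strip(doc)
  ok <- xml2::xml_validate(doc, load_schema(schema_file))
  structure(as.logical(ok), errors = attr(ok, "errors"))
}

#' Validate a document against an in-repo schema
#'
#' @param xml_text document text.
#' @return `TRUE`/`FALSE` with validator messages in the `errors`
#'   attribute.
#' @export
#' @rdname schema-validation
validate_taxpub <- function(xml_text) {
  validate_against(xml_text, "taxpub-subset.xsd")
}

#' @export
#' @rdname schema-validation
validate_tcs <- function(xml_text) {
  validate_against(xml_text, "tcs-subset.xsd")
}

#' @export
#' @rdname schema-validation
validate_report_xml <- function(xml_text) {
  validate_against(xml_text, "registration-report.xsd")
}
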