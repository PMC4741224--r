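# Store files are JSON-lines: a schema-versioned header line followed by
# one record per line, in insertion order, so the registration trail stays
# human-auditable with line-oriented tools.

payload_to_json_list <- function(payload, type) {
  switch(type,
    act = list(kind = payload$kind, rank = payload$rank,
               type_kind = payload$type_kind, is_hybrid = payload$is_hybrid,
               code = payload$code, status_phrase = payload$status_phrase,
               name = payload$name[!vapply(payload$name, is.null, TRUE)]),
    author = list(surname = payload$surname,
                  given_names = payload$given_names,
                  registry_id = payload$registry_id),
    article = lapply(payload, function(v) {
      if (inherits(v, "Date")) format(v) else v
    }))
}

payload_from_json_list <- function(x, type) {
  switch(type,
    act = nomenclatural_act(
      kind = x$kind, rank = x$rank, type_kind = x$type_kind,
      is_hybrid = isTRUE(x$is_hybrid), code = x$code,
      status_phrase = x$status_phrase,
      name = scientific_name(uninomial = x$name$uninomial,
                             genus = x$name$genus, species = x$name$species,
                             infraspecific = x$name$infraspecific,
                             authorship = x$name$authorship %||% "",
                             basionym_authorship = x$name$basionym_authorship)),
    author = author_name(x$surname, x$given_names %||% "",
                         registry_id = x$registry_id),
    article = {
      for (f in c("acceptance_date", "publication_date")) {
        if (!is.null(x[[f]])) x[[f]] <- as.Date(x[[f]])
      }
      x
    })
}

#' Write a registry store to a JSON-lines file
#'
#' @param store a [registry_store()].
#' @param path file to write (UTF-8, one JSON object per line).
#' @export
save_store <- function(store, path) {
  header <- jsonlite::toJSON(
    list(schema_version = STORE_SCHEMA_VERSION, registry = store$registry,
         clock = format(store$clock)),
    auto_unbox = TRUE, null = "null")
  lines <- vapply(all_records(store), function(rec) {
    rec$payload <- payload_to_json_list(rec$payload, rec$payload_type)
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
  }, character(1L))
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read a registry store back from a JSON-lines file
#'
#' @param path file written by [save_store()].
#' @return a reconstructed [registry_store()].
#' @export
load_store <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- jsonlite::fromJSON(lines[1L])
  if (!identical(as.integer(header$schema_version), STORE_SCHEMA_VERSION)) {
    stop(sprintf("unsupported store schema version: %s",
                 header$schema_version), call. = FALSE)
  }
  store <- registry_store(header$registry, clock = as.Date(header$clock))
  for (line in lines[-1L]) {
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    rec$payload <- payload_from_json_list(rec$payload, rec$payload_type)
    rec$article_id <- rec$article_id %||% NULL
    rec$article_link <- rec$article_link %||% NULL
    if (is.null(rec$xref)) rec$xref <- list()
    store$records[[rec$id]] <- rec
    store$dedup[[rec$dedup_key]] <- rec$id
    store$n_inserted <- max(store$n_inserted, rec$seq)
  }
  store
}
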