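# The embedded registry engine.  A store is an environment holding records
# keyed by identifier, with a secondary index on deduplication key.  The
# clock is injected (a Date, not wall time) so the embargo lifecycle is
# deterministic and replayable; all timestamps come from it.

REGISTRY_CODES <- c(ipni = "ICNafp", index_fungorum = "ICNafp",
                    mycobank = "ICNafp", fungal_names = "ICNafp",
                    zoobank = "ICZN")
STORE_SCHEMA_VERSION <- 1L

#' Create an embedded registry store
#'
#' @param registry which registry this store plays: `"ipni"`,
#'   `"index_fungorum"`, `"mycobank"`, `"fungal_names"` or `"zoobank"`.
#' @param clock the registry's current date (injectable for deterministic
#'   embargo behaviour).
#' @return an environment of class `registry_store`.
#' @export
#' @examples
#' store <- registry_store("zoobank", clock = as.Date("2016-01-01"))
registry_store <- function(registry, clock = Sys.Date()) {
  registry <- match.arg(registry, REGISTRIES)
  store <- new.env(parent = emptyenv())
  store$registry <- registry
  store$code <- REGISTRY_CODES[[registry]]
  store$clock <- as.Date(clock)
  store$records <- new.env(parent = emptyenv())
  store$dedup <- new.env(parent = emptyenv())
  store$pending <- new.env(parent = emptyenv())
  store$n_inserted <- 0L
  class(store) <- "registry_store"
  store
}

#' @export
print.registry_store <- function(x, ...) {
  recs <- all_records(x)
  states <- table(factor(vapply(recs, `[[`, "", "state"),
                         levels = c("embargoed", "public", "superseded")))
  cat(sprintf("<registry store> %s @ %s: %d records (%d embargoed, %d public, %d superseded)\n",
              x$registry, format(x$clock), length(recs), states[["embargoed"]],
              states[["public"]], states[["superseded"]]))
  invisible(x)
}

#' Advance (or set) a store's clock
#'
#' @param store a [registry_store()].
#' @param date new current date; must not move backwards.
#' @export
set_clock <- function(store, date) {
  date <- as.Date(date)
  if (date < store$clock) stop("registry clock cannot move backwards", call. = FALSE)
  store$clock <- date
  invisible(store)
}

all_records <- function(store) {
  ids <- ls(store$records, sorted = TRUE)
  recs <- mget(ids, envir = store$records)
  unname(recs[order(vapply(recs, `[[`, 0L, "seq"))])
}

payload_type_of <- function(payload) {
  if (inherits(payload, "nomenclatural_act")) "act"
  else if (inherits(payload, "author_name")) "author"
  else if (is.list(payload) && !is.null(payload$title)) "article"
  else stop("unsupported payload type", call. = FALSE)
}

# Field extraction used by search filters; payload-level fields resolve
# against the payload the record carries.
record_field <- function(record, field) {
  switch(field,
    id = record$id,
    state = record$state,
    article_id = record$article_id %||% "",
    dedup_key = record$dedup_key,
    payload_type = record$payload_type,
    kind = if (record$payload_type == "act") record$payload$kind else "",
    name = switch(record$payload_type,
                  act = canonical_name_string(record$payload$name),
                  author = paste(record$payload$surname,
                                 record$payload$given_names),
                  article = record$payload$title),
    surname = if (record$payload_type == "author") record$payload$surname else "",
    normalized_key = if (record$payload_type == "author")
      record$payload$normalized_key else "",
    stop(sprintf("unknown filter field: '%s'", field), call. = FALSE))
}

#' Search registry records
#'
#' Returns all and only the records matching every filter.  In the
#' `"public"` context -- what the outside world sees -- embargoed and
#' superseded records are invisible; the `"publisher"` context (the owning
#' editorial office) sees everything.
#'
#' @param store a [registry_store()].
#' @param filters named list, field to required value.  Known fields:
#'   `id`, `state`, `article_id`, `dedup_key`, `payload_type`, `kind`,
#'   `name`, `surname`, `normalized_key`.
#' @param context `"publisher"` or `"public"`.
#' @return list of matching records, insertion order.
#' @export
search_records <- function(store, filters = list(),
                           context = c("publisher", "public")) {
  context <- match.arg(context)
  fields <- names(filters)
  if (length(filters) > 0L && (is.null(fields) || any(!nzchar(fields)))) {
    stop("filters must be a named list", call. = FALSE)
  }
  known <- c("id", "state", "article_id", "dedup_key", "payload_type",
             "kind", "name", "surname", "normalized_key")
  unknown <- setdiff(fields, known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown filter field: '%s'", unknown[1L]), call. = FALSE)
  }
  recs <- all_records(store)
  if (context == "public") {
    recs <- Filter(function(r) r$state == "public", recs)
  }
  for (f in fields) {
    want <- filters[[f]]
    recs <- Filter(function(r) identical(record_field(r, f), want), recs)
  }
  recs
}

#' Insert-or-update a record (upsert)
#'
#' Update-if-exists, insert-otherwise, keyed on the deduplication key.  An
#' update keeps the record's identifier -- re-uploading corrected data never
#' re-mints -- and refreshes the payload and `updated_at`.  A record that is
#' already public cannot be silently rewritten with different data: that is
#' a conflict, and published records are corrected by explicit
#' supersession instead.
#'
#' @param store a [registry_store()].
#' @param payload a [nomenclatural_act()], [author_name()] or article
#'   metadata list.
#' @param dedup_key deduplication key; defaults to the canonical key for
#'   acts and authors.
#' @param article_id identifier of the owning article record, if any.
#' @return list with `record` and `action` (`"inserted"` or `"updated"`).
#' @export
upsert_record <- function(store, payload, dedup_key = NULL,
                          article_id = NULL) {
  type <- payload_type_of(payload)
  if (is.null(dedup_key)) {
    dedup_key <- switch(type,
      act = act_dedup_key(payload),
      author = payload$normalized_key,
      article = stop("article payloads need an explicit dedup_key", call. = FALSE))
  }
  now <- format(store$clock)
  existing_id <- store$dedup[[dedup_key]]
  if (!is.null(existing_id)) {
    rec <- store$records[[existing_id]]
    if (rec$state == "public" && !identical(rec$payload, payload)) {
      stop(sprintf("conflict: record %s is public; use supersede_record()",
                   existing_id), call. = FALSE)
    }
    rec$payload <- payload
    rec$updated_at <- now
    if (rec$state == "superseded") rec$state <- "embargoed"  # reinstated pre-release
    if (!is.null(article_id)) rec$article_id <- article_id
    store$records[[existing_id]] <- rec
    return(list(record = rec, action = "updated"))
  }
  id <- mint_identifier(store)
  store$n_inserted <- store$n_inserted + 1L
  rec <- list(id = id, seq = store$n_inserted, payload = payload,
              payload_type = type, dedup_key = dedup_key,
              state = "embargoed", article_id = article_id,
              article_link = NULL, xref = list(),
              created_at = now, updated_at = now)
  store$records[[id]] <- rec
  store$dedup[[dedup_key]] <- id
  list(record = rec, action = "inserted")
}

#' Mark a record as superseded
#'
#' The explicit correction path for records that may no longer be silently
#' updated (e.g. an act dropped from a re-uploaded manuscript, or a public
#' record being replaced).
#'
#' @param store a [registry_store()].
#' @param id identifier of the record to supersede.
#' @export
supersede_record <- function(store, id) {
  rec <- store$records[[id]]
  if (is.null(rec)) stop(sprintf("not found: %s", id), call. = FALSE)
  rec$state <- "superseded"
  rec$updated_at <- format(store$clock)
  store$records[[id]] <- rec
  invisible(rec)
}

#' Match an author against the registry
#'
#' Looks for previously registered authors with the same written name under
#' the normalization rules (diacritics stripped, casefolded, punctuation
#' removed), with initials matching full given names as prefixes
#' ("Smith, J." matches "Smith, John").  No match, a unique match, or --
#' when the registry holds several distinct people under that name --
#' a pending homonym disambiguation for the editorial-office operator.
#'
#' @param store a [registry_store()].
#' @param author an [author_name()]; must have a non-empty surname.
#' @return list with `status` (`"no_match"`, `"unique_match"`,
#'   `"homonyms"`), plus `record` or `pending`.
#' @export
match_authors <- function(store, author) {
  stopifnot(inherits(author, "author_name"))
  candidates <- Filter(
    function(r) r$payload_type == "author" && r$state != "superseded" &&
      authors_match(r$payload, author),
    all_records(store))
  if (length(candidates) == 0L) return(list(status = "no_match"))
  if (length(candidates) == 1L) {
    return(list(status = "unique_match", record = candidates[[1L]]))
  }
  pending <- structure(
    list(submitted = author, candidates = candidates,
         ref = paste0("pending:", author$normalized_key)),
    class = "pending_disambiguation")
  store$pending[[pending$ref]] <- pending
  list(status = "homonyms", pending = pending)
}

#' Resolve a pending author-homonym disambiguation
#'
#' The operator either selects one of the candidate records or declares the
#' submitted author a new person (`choice = "NEW"`), which mints a fresh
#' author record.
#'
#' @param store a [registry_store()].
#' @param pending a `pending_disambiguation` from [match_authors()].
#' @param choice a candidate's identifier, or `"NEW"`.
#' @return the chosen (or freshly minted) author record.
#' @export
resolve_disambiguation <- function(store, pending, choice) {
  stopifnot(inherits(pending, "pending_disambiguation"))
  if (identical(choice, "NEW")) {
    res <- upsert_record(store, pending$submitted,
                         dedup_key = paste(pending$submitted$normalized_key,
                                           mint_identifier(store)))
    rec <- res$record
  } else {
    ids <- vapply(pending$candidates, `[[`, "", "id")
    if (!choice %in% ids) {
      stop(sprintf("invalid choice: %s is not among the candidates", choice),
           call. = FALSE)
    }
    rec <- pending$candidates[[match(choice, ids)]]
  }
  rm(list = pending$ref, envir = store$pending)
  rec
}

#' Release an article's records on publication day
#'
#' Ends the embargo: every embargoed record belonging to the article
#' becomes public, with the article link attached.  Releasing before the
#' publication date is an embargo violation and changes nothing.  The
#' operation is idempotent: a second call releases zero records.
#'
#' @param store a [registry_store()].
#' @param article_id identifier of the article record.
#' @param publication_date the article's publication date.
#' @param article_link URI of the published article.
#' @return number of act records released (the article and author records
#'   are released alongside but not counted).
#' @export
release_records <- function(store, article_id, publication_date,
                            article_link) {
  publication_date <- as.Date(publication_date)
  recs <- Filter(
    function(r) identical(r$article_id, article_id) || identical(r$id, article_id),
    all_records(store))
  if (length(recs) == 0L) {
    stop(sprintf("not found: no records for article %s", article_id),
         call. = FALSE)
  }
  if (store$clock < publication_date) {
    stop(sprintf("embargo violation: publication date %s is after the registry clock %s",
                 format(publication_date), format(store$clock)),
         call. = FALSE)
  }
  released <- 0L
  for (rec in recs) {
    if (rec$state != "embargoed") next
    rec$state <- "public"
    rec$article_link <- article_link
    rec$updated_at <- format(store$clock)
    store$records[[rec$id]] <- rec
    if (rec$payload_type == "act") released <- released + 1L
  }
  released
}

#' Propagate a record to sibling registries
#'
#' The fungal registries (Index Fungorum, MycoBank, Fungal Names) are
#' interchangeable for registration: an act registered with one is
#' synchronized to the others.  Each target receives an equivalent record
#' under the same deduplication key, cross-referenced to the source
#' identifier; repeating the propagation updates rather than duplicates.  A
#' target whose scope matrix does not record the act rejects it without
#' affecting the other targets.
#'
#' @param source_store store holding the record.
#' @param record the record to propagate (an act record).
#' @param targets character vector of target registry names.
#' @param target_stores named list of [registry_store()]s, one per target.
#' @return named character vector of per-target actions (`"inserted"`,
#'   `"updated"` or `"rejected: <reason>"`).
#' @export
propagate <- function(source_store, record, targets, target_stores) {
  stopifnot(record$payload_type == "act",
            all(targets %in% names(target_stores)))
  if (!all(targets %in% FUNGAL_REGISTRIES)) {
    stop("propagation targets must be fungal registries", call. = FALSE)
  }
  matrix <- scope_matrix()
  out <- character(0)
  for (tg in targets) {
    ts <- target_stores[[tg]]
    verdict <- validate_act(record$payload, tg, matrix)
    if (verdict$status == "reject") {
      out[[tg]] <- paste0("rejected: ", verdict$reason)
      next
    }
    res <- upsert_record(ts, record$payload, dedup_key = record$dedup_key,
                         article_id = record$article_id)
    rec <- res$record
    rec$xref[[source_store$registry]] <- record$id
    if (record$state == "public" && rec$state == "embargoed") {
      rec$state <- "public"
      rec$article_link <- record$article_link
    }
    ts$records[[rec$id]] <- rec
    out[[tg]] <- res$action
  }
  out
}
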