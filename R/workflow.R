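# The acceptance-to-publication pipeline: register on acceptance (records
# embargoed), report identifiers/errors/pendings back, re-upload replaces,
# inject identifiers into the published treatments, release on publication
# day with the article link, and diff the final metadata against what was
# registered.

article_dedup_key <- function(meta) {
  normalize_name_key(meta$doi %||% paste(meta$title, meta$journal))
}

wf_log <- function(verbose, step, what) {
  if (verbose) message(sprintf("[%s] %s", step, what))
}

register_acts <- function(manuscript, store, article_id, verbose = FALSE) {
  matrix <- scope_matrix()
  acts <- manuscript_acts(manuscript)
  rows <- empty_outcomes()
  actions <- character(0)
  keys <- character(0)
  for (i in seq_along(acts)) {
    act <- acts[[i]]
    verdict <- validate_act(act, store$registry, matrix)
    if (verdict$status == "reject") {
      rows <- rbind(rows, outcome_row(i, "error", message = verdict$reason))
      actions[i] <- "rejected"
      wf_log(verbose, "register", sprintf("act %d: error (%s)", i, verdict$reason))
      next
    }
    res <- upsert_record(store, act, article_id = article_id)
    keys <- c(keys, res$record$dedup_key)
    rows <- rbind(rows, outcome_row(i, "registered", id = res$record$id,
                                    message = verdict$reason %||% ""))
    actions[i] <- res$action
    wf_log(verbose, "register", sprintf("act %d: %s -> %s", i, res$action,
                                        res$record$id))
  }
  list(rows = rows, actions = actions, keys = unique(keys))
}

register_authors <- function(manuscript, store, article_id,
                             verbose = FALSE) {
  rows <- empty_outcomes()
  for (i in seq_along(manuscript$contributors)) {
    a <- manuscript$contributors[[i]]
    m <- match_authors(store, a)
    if (m$status == "homonyms") {
      rows <- rbind(rows, outcome_row(i, "pending",
                                      pending_ref = m$pending$ref))
      wf_log(verbose, "register", sprintf("author %d: pending (%s)", i,
                                          m$pending$ref))
      next
    }
    rec <- if (m$status == "unique_match") m$record else {
      # a new author record belongs to the article that introduced it, so
      # it leaves embargo when that article is released
      upsert_record(store, a,
                    dedup_key = paste(a$normalized_key,
                                      mint_identifier(store)),
                    article_id = article_id)$record
    }
    rows <- rbind(rows, outcome_row(i, "registered", id = rec$id))
    wf_log(verbose, "register", sprintf("author %d: %s -> %s", i, m$status,
                                        rec$id))
  }
  rows
}

#' Register a manuscript's acts with a registry on acceptance
#'
#' The acceptance-stage upload: the article, its contributors and every
#' validated act are stored embargoed, and a registration report is
#' returned with one outcome per act.  An act the registry does not record
#' yields an error outcome (its valid siblings proceed); a contributor whose
#' name matches several registered people yields a pending outcome that
#' blocks injection until an operator resolves it.  A manuscript without
#' acceptance-stage metadata is rejected whole, storing nothing.
#'
#' @param manuscript a parsed [parse_manuscript()] object.
#' @param store the target [registry_store()].
#' @param verbose log one line per act and author.
#' @return a [registration_report()]; the per-act upsert actions
#'   (`"inserted"`, `"updated"`, `"rejected"`) are attached as attribute
#'   `"act_actions"`.
#' @export
register_manuscript <- function(manuscript, store, verbose = FALSE) {
  meta <- manuscript$article_meta
  if (is.null(meta$title) || !nzchar(meta$title) ||
      length(manuscript$contributors) == 0L) {
    stop("registration rejected: manuscript lacks acceptance-stage metadata (title, contributors)",
         call. = FALSE)
  }
  art <- upsert_record(store, meta, dedup_key = article_dedup_key(meta))
  article_id <- art$record$id
  wf_log(verbose, "register", sprintf("article: %s -> %s", art$action,
                                      article_id))
  author_rows <- register_authors(manuscript, store, article_id, verbose)
  acts <- register_acts(manuscript, store, article_id, verbose)
  report <- registration_report(article_id, store$registry,
                                acts = acts$rows, authors = author_rows)
  attr(report, "act_actions") <- acts$actions
  report
}

#' Re-upload a changed manuscript before publication
#'
#' Replaces the previously registered data: unchanged and corrected acts
#' keep their identifiers (matched by deduplication key), new acts are
#' inserted, and acts no longer present in the upload are marked
#' superseded.  Re-uploading after release is a conflict.
#'
#' @inheritParams register_manuscript
#' @return a [registration_report()] reflecting the final state; the
#'   attribute `"superseded"` carries the identifiers superseded by this
#'   upload.
#' @export
reupload <- function(manuscript, store, verbose = FALSE) {
  meta <- manuscript$article_meta
  prior_id <- store$dedup[[article_dedup_key(meta)]]
  if (is.null(prior_id)) {
    stop("reupload: article was never registered here", call. = FALSE)
  }
  if (store$records[[prior_id]]$state == "public") {
    stop("conflict: article already released; corrections require supersession",
         call. = FALSE)
  }
  report <- register_manuscript(manuscript, store, verbose = verbose)
  live_keys <- vapply(
    Filter(function(r) r$payload_type == "act" && r$state == "embargoed" &&
             identical(r$article_id, report$article_id),
           all_records(store)),
    `[[`, "", "dedup_key")
  current <- vapply(manuscript_acts(manuscript), act_dedup_key, character(1L))
  gone <- setdiff(live_keys, current)
  superseded <- character(0)
  for (k in gone) {
    id <- store$dedup[[k]]
    supersede_record(store, id)
    superseded <- c(superseded, id)
    wf_log(verbose, "reupload", sprintf("superseded %s", id))
  }
  attr(report, "superseded") <- superseded
  report
}

#' Finalize on publication day: inject identifiers, release, validate
#'
#' The publication-day leg of the workflow: the registry identifiers from
#' the report are injected into the final manuscript XML, the article's
#' records are released (made public, with the article link), and the final
#' published metadata is diffed against what was stored at acceptance;
#' discrepancies are reported, not auto-corrected.  A report with any error
#' or pending outcome refuses to proceed.  On the ZooBank electronic-only
#' route, the registration must state the preserving archive and the
#' ISSN/ISBN of the work; finalization refuses without them.
#'
#' @param xml_text the final manuscript XML.
#' @param report the [registration_report()] for this article.
#' @param store the [registry_store()] holding the records.
#' @param publication_date publication date (must not be after the store
#'   clock; advance the clock with [set_clock()] first).
#' @param article_link URI of the published article.
#' @param verbose log one line per step.
#' @return list with `xml` (identifier-injected manuscript), `released`
#'   (record count) and `metadata_diff` (character vector of field names
#'   that differ between registration and publication).
#' @export
finalize_publication <- function(xml_text, report, store, publication_date,
                                 article_link, verbose = FALSE) {
  if (report_blocked(report)) {
    stop("cannot finalize: report has error or pending outcomes", call. = FALSE)
  }
  ms <- parse_manuscript(xml_text)
  if (store$registry == "zoobank") {
    meta <- ms$article_meta
    missing <- c(
      if (is.null(meta$archive_name)) "archive name",
      if (is.null(meta$issn_or_isbn)) "ISSN/ISBN")
    if (length(missing) > 0L) {
      stop(sprintf(
        "ZooBank e-only registration must state the preserving electronic archive and the ISSN or ISBN of the work; missing: %s",
        paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  final_xml <- inject_identifiers(ms, setNames(report$acts$id,
                                               report$acts$index))
  wf_log(verbose, "inject", sprintf("%d identifiers injected",
                                    nrow(report$acts)))
  released <- release_records(store, report$article_id, publication_date,
                              article_link)
  wf_log(verbose, "release", sprintf("%d records released", released))

  stored <- store$records[[report$article_id]]$payload
  final_meta <- ms$article_meta
  fields <- c("title", "journal", "issn_or_isbn", "doi", "archive_name")
  diff <- fields[vapply(fields, function(f) {
    !identical(stored[[f]] %||% "", final_meta[[f]] %||% "")
  }, logical(1L))]
  wf_log(verbose, "validate", sprintf("metadata diff: %s",
                                      if (length(diff)) paste(diff, collapse = ", ")
                                      else "clean"))
  list(xml = final_xml, released = released, metadata_diff = diff)
}
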