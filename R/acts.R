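# Act kinds, ranks and type kinds recognised by the model.
ACT_KINDS  <- c("new_taxon", "new_replacement_name", "new_combination",
                "tautonym", "typification")
ACT_RANKS  <- c("suprafamilial", "familial", "infrafamilial", "generic",
                "infrageneric", "specific", "infraspecific")
TYPE_KINDS <- c("holotype", "lectotype", "neotype", "epitype")
REGISTRIES <- c("ipni", "index_fungorum", "mycobank", "fungal_names",
                "zoobank")
FUNGAL_REGISTRIES <- c("index_fungorum", "mycobank", "fungal_names")
CODES <- c("ICNafp", "ICZN")

#' Construct a nomenclatural act
#'
#' A nomenclatural act is one code-governed event: the description of a new
#' taxon at some rank, a new combination, a replacement name, a tautonym, or
#' a typification.  `rank` is required exactly when `kind = "new_taxon"`,
#' `type_kind` exactly when `kind = "typification"`.  Hybrids are not a
#' separate kind: any rank can be flagged as a hybrid under the botanical
#' code (`is_hybrid = TRUE` is invalid under the ICZN).
#'
#' @param kind one of `"new_taxon"`, `"new_replacement_name"`,
#'   `"new_combination"`, `"tautonym"`, `"typification"`.
#' @param name a [scientific_name()].
#' @param rank rank of a new taxon (see `ACT_RANKS`).
#' @param type_kind kind of type designated by a typification.
#' @param is_hybrid flag a botanical name as a hybrid.
#' @param code governing code, `"ICNafp"` or `"ICZN"`.
#' @param status_phrase the status phrase as printed (kept for round trips).
#' @return an object of class `nomenclatural_act`.
#' @export
nomenclatural_act <- function(kind, name, rank = NULL, type_kind = NULL,
                              is_hybrid = FALSE, code = "ICNafp",
                              status_phrase = NULL) {
  kind <- match.arg(kind, ACT_KINDS)
  code <- match.arg(code, CODES)
  if (kind == "new_taxon") {
    if (is.null(rank)) stop("new_taxon acts require a rank", call. = FALSE)
    rank <- match.arg(rank, ACT_RANKS)
  } else if (!is.null(rank)) {
    stop(sprintf("rank given for kind '%s'", kind), call. = FALSE)
  }
  if (kind == "typification") {
    if (is.null(type_kind)) stop("typifications require a type_kind", call. = FALSE)
    type_kind <- match.arg(type_kind, TYPE_KINDS)
  } else if (!is.null(type_kind)) {
    stop(sprintf("type_kind given for kind '%s'", kind), call. = FALSE)
  }
  if (isTRUE(is_hybrid) && code != "ICNafp") {
    stop("hybrid flag is only meaningful under the ICNafp", call. = FALSE)
  }
  if (!inherits(name, "scientific_name")) {
    stop("'name' must be a scientific_name", call. = FALSE)
  }
  structure(
    list(kind = kind, rank = rank, type_kind = type_kind, name = name,
         is_hybrid = isTRUE(is_hybrid), code = code,
         status_phrase = status_phrase),
    class = "nomenclatural_act"
  )
}

#' @export
print.nomenclatural_act <- function(x, ...) {
  extra <- x$rank %||% x$type_kind %||% ""
  cat(sprintf("<act> %s%s: %s %s [%s]%s\n", x$kind,
              if (nzchar(extra)) paste0("/", extra) else "",
              canonical_name_string(x$name), x$name$authorship, x$code,
              if (x$is_hybrid) " (hybrid)" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row label of the scope matrix an act falls under.  The hybrid flag routes
# a new taxon to the dedicated hybrid row.
act_descriptor <- function(act) {
  switch(act$kind,
    new_taxon = c("new_taxon", if (act$is_hybrid) "hybrid" else act$rank),
    typification = c("typification", act$type_kind),
    c(act$kind, "-"))
}

# Deduplication key: governing code + kind + canonical name with the rank /
# status marker + type kind, all under the author-name normalization.  Two
# uploads of the same act collapse to the same key; the identifier minted at
# first upload therefore survives re-uploads.
act_dedup_key <- function(act) {
  marker <- act$status_phrase %||% paste(act_descriptor(act), collapse = " ")
  normalize_name_key(paste(act$code, act$kind,
                           canonical_name_string(act$name), marker,
                           act$type_kind %||% ""))
}

read_config_tsv <- function(name) {
  path <- system.file("extdata", name, package = "nomenreg", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          fill = TRUE, na.strings = NULL)
  df[is.na(df)] <- ""
  df
}

status_vocabulary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_config_tsv("status_phrases.tsv")
    cache
  }
})

#' The registrability matrix of nomenclatural acts by registry
#'
#' Which acts each registry records.  IPNI covers vascular plants and does
#' not record suprafamilial new taxa nor lecto-/neo-/epitypifications; the
#' fungal registries (Index Fungorum, MycoBank, Fungal Names) record all
#' listed acts; ZooBank operates under the ICZN, so hybrid-flagged names,
#' tautonym-as-act rows and epitypes are not applicable to it.  Cells that
#' standard act-by-registry tabulations leave unattested for ZooBank are
#' filled as recorded and carry `table_blank = TRUE`, so audits can exclude
#' them.
#'
#' The matrix ships as a human-auditable config file
#' (`inst/extdata/scope_matrix.tsv`); this function loads and checks it.
#'
#' @return a data.frame with columns `kind`, `descriptor`, `registry`,
#'   `status` (one of `"recorded"`, `"not_recorded"`, `"not_applicable"`)
#'   and `table_blank`.
#' @export
#' @examples
#' m <- scope_matrix()
#' subset(m, registry == "ipni" & kind == "typification")
scope_matrix <- function() {
  raw <- read_config_tsv("scope_matrix.tsv")
  regs <- setdiff(names(raw), c("kind", "descriptor"))
  out <- do.call(rbind, lapply(regs, function(r) {
    data.frame(kind = raw$kind, descriptor = raw$descriptor, registry = r,
               cell = raw[[r]], stringsAsFactors = FALSE)
  }))
  out$table_blank <- out$cell == "(+)"
  out$status <- c("+" = "recorded", "(+)" = "recorded", "-" = "not_recorded",
                  "n/a" = "not_applicable")[out$cell]
  if (anyNA(out$status)) {
    stop("scope_matrix.tsv contains an undefined cell", call. = FALSE)
  }
  out$cell <- NULL
  rownames(out) <- NULL
  out
}

# One cell of the scope matrix.
scope_cell <- function(matrix, kind, descriptor, registry) {
  hit <- matrix[matrix$kind == kind & matrix$descriptor == descriptor &
                  matrix$registry == registry, ]
  if (nrow(hit) != 1L) {
    stop(sprintf("no scope-matrix cell for (%s/%s, %s)", kind, descriptor,
                 registry), call. = FALSE)
  }
  hit
}

#' Classify a nomenclature block into a nomenclatural act
#'
#' Reads the status phrase printed in a treatment's nomenclature block and
#' maps it through the status-phrase vocabulary
#' (`inst/extdata/status_phrases.tsv`).  A new species whose epithet repeats
#' its genus name is classified as a tautonym regardless of the phrase
#' printed, since tautonymy is a property of the name, not of the phrase.
#' An unrecognized phrase is an error, never a guess.
#'
#' @param status_phrase the printed status phrase, e.g. `"sp. nov."`.
#' @param name a [scientific_name()].
#' @param is_hybrid hybrid flag from the treatment.
#' @param code governing code.
#' @return a [nomenclatural_act()].
#' @export
#' @examples
#' classify_act("gen. nov.", scientific_name(uninomial = "Lettowia",
#'                                           authorship = "H. Rob."))
classify_act <- function(status_phrase, name, is_hybrid = FALSE,
                         code = "ICNafp") {
  vocab <- status_vocabulary()
  phrase <- trimws(status_phrase)
  hit <- vocab[vocab$phrase == phrase, ]
  if (nrow(hit) != 1L) {
    stop(sprintf("unrecognized status phrase: '%s'", phrase), call. = FALSE)
  }
  kind <- hit$kind
  rank <- if (nzchar(hit$rank)) hit$rank else NULL
  type_kind <- if (nzchar(hit$type_kind)) hit$type_kind else NULL
  if (kind == "new_taxon" && identical(rank, "specific") &&
      !is.null(name$genus) && !is.null(name$species) &&
      tolower(name$species) == tolower(name$genus)) {
    kind <- "tautonym"
    rank <- NULL
  }
  nomenclatural_act(kind = kind, name = name, rank = rank,
                    type_kind = type_kind, is_hybrid = is_hybrid,
                    code = code, status_phrase = phrase)
}

#' Validate an act against one registry's scope
#'
#' An act is accepted exactly when its scope-matrix cell is `recorded` and
#' no code rule fires.  Three rules accompany the matrix: (1) hybrid-flagged
#' names are not applicable to ZooBank; (2) tautonyms are not validly
#' published under the ICNafp, so a botanical registry records them only
#' with a warning, for pick-up at the indexing stage; (3) IPNI does not
#' record new lecto-, neo- or epitypifications (holotypes of new taxa only).
#'
#' @param act a [nomenclatural_act()].
#' @param registry one of `"ipni"`, `"index_fungorum"`, `"mycobank"`,
#'   `"fungal_names"`, `"zoobank"`.
#' @param matrix the scope matrix, by default [scope_matrix()].
#' @return a list with `status` (`"accept"`, `"warn"` or `"reject"`) and
#'   `reason` (`NULL` on a clean accept).
#' @export
#' @examples
#' act <- classify_act("epitype designated",
#'                     scientific_name(genus = "Aus", species = "bus"))
#' validate_act(act, "zoobank")$status  # "reject"
validate_act <- function(act, registry, matrix = scope_matrix()) {
  registry <- match.arg(registry, REGISTRIES)
  desc <- act_descriptor(act)
  cell <- scope_cell(matrix, desc[1L], desc[2L], registry)
  if (cell$status == "not_applicable") {
    return(list(status = "reject",
                reason = sprintf("not_applicable: %s/%s is not an act under %s's code",
                                 desc[1L], desc[2L], registry)))
  }
  if (cell$status == "not_recorded") {
    return(list(status = "reject",
                reason = sprintf("not_recorded: %s does not record %s/%s",
                                 registry, desc[1L], desc[2L])))
  }
  if (act$is_hybrid && registry == "zoobank") {
    return(list(status = "reject",
                reason = "not_applicable: hybrid-flagged names are outside the ICZN"))
  }
  if (act$kind == "tautonym" && act$code == "ICNafp") {
    return(list(status = "warn",
                reason = "tautonym is not validly published under the ICNafp; recorded but flagged for the indexing stage"))
  }
  list(status = "accept", reason = NULL)
}
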