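#' Normalize a person-name string for matching
#'
#' Unicode-decomposes, strips diacritics, casefolds, strips punctuation and
#' collapses whitespace.  This is the pure normalization used for author
#' deduplication and homonym detection: two spellings with the same
#' normalized key are treated as the same written name (e.g. "Müller" and
#' "Muller", "J." and "J").
#'
#' @param x character vector of raw name strings.
#' @return character vector of normalized keys.
#' @export
#' @examples
#' normalize_name_key("Müller, J.-P.")  # "muller j p"
normalize_name_key <- function(x) {
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Construct an author name
#'
#' @param surname family name (non-empty).
#' @param given_names given names or initials (may be "").
#' @param registry_id optional registry identifier already linked to this
#'   author.
#' @return an object of class `author_name`.
#' @export
author_name <- function(surname, given_names = "", registry_id = NULL) {
  if (!is.character(surname) || length(surname) != 1L || !nzchar(trimws(surname))) {
    stop("author_name: 'surname' must be a non-empty string", call. = FALSE)
  }
  structure(
    list(
      surname = surname,
      given_names = given_names,
      normalized_key = normalize_name_key(paste(surname, given_names)),
      registry_id = registry_id
    ),
    class = "author_name"
  )
}

#' @export
print.author_name <- function(x, ...) {
  cat(sprintf("<author> %s, %s [key: %s]\n", x$surname, x$given_names,
              x$normalized_key))
  invisible(x)
}

# Given-name compatibility with initials-as-prefix semantics: every token of
# the shorter side must be a prefix of the corresponding token of the longer
# side ("j" matches "john"; "j p" matches "john paul").  Tokens are compared
# in order.
given_names_compatible <- function(a, b) {
  ta <- strsplit(normalize_name_key(a), " ", fixed = TRUE)[[1L]]
  tb <- strsplit(normalize_name_key(b), " ", fixed = TRUE)[[1L]]
  ta <- ta[nzchar(ta)]; tb <- tb[nzchar(tb)]
  if (length(ta) == 0L || length(tb) == 0L) return(TRUE)
  n <- min(length(ta), length(tb))
  for (i in seq_len(n)) {
    if (!startsWith(ta[i], tb[i]) && !startsWith(tb[i], ta[i])) return(FALSE)
  }
  TRUE
}

# TRUE when two author names denote the same written name under the
# normalization + initials-prefix rules.
authors_match <- function(a, b) {
  normalize_name_key(a$surname) == normalize_name_key(b$surname) &&
    given_names_compatible(a$given_names, b$given_names)
}

#' Construct a scientific name
#'
#' Epithets are stored separately so canonical strings and dedup keys can be
#' derived; a new combination carries the basionym authorship in
#' parenthesised form inside `authorship` (e.g. `"(Oliv.) H. Rob."`).
#'
#' @param genus,species,infraspecific,uninomial name parts; use `uninomial`
#'   for names at genus rank and above.
#' @param authorship authorship string as printed.
#' @param basionym_authorship authorship of the basionym, without
#'   parentheses, for new combinations.
#' @return an object of class `scientific_name`.
#' @export
scientific_name <- function(uninomial = NULL, genus = NULL, species = NULL,
                            infraspecific = NULL, authorship = "",
                            basionym_authorship = NULL) {
  structure(
    list(
      uninomial = uninomial, genus = genus, species = species,
      infraspecific = infraspecific, authorship = authorship,
      basionym_authorship = basionym_authorship
    ),
    class = "scientific_name"
  )
}

# Canonical (authorship-free) name string, e.g. "Aus bus subsp. cus".
canonical_name_string <- function(name) {
  parts <- c(name$uninomial, name$genus, name$species, name$infraspecific)
  paste(parts[!vapply(parts, is.null, logical(1L))], collapse = " ")
}

#' @export
print.scientific_name <- function(x, ...) {
  cat(sprintf("<name> %s %s\n", canonical_name_string(x), x$authorship))
  invisible(x)
}

#' Mint a fresh registry identifier
#'
#' Identifiers are RFC 4122 version-4 UUIDs in URN form
#' (`urn:uuid:xxxxxxxx-xxxx-4xxx-yxxx-xxxxxxxxxxxx`), drawn from R's RNG so
#' a seeded pipeline run is bit-reproducible.  When a store is supplied the
#' identifier is guaranteed never to have been issued by that store.
#'
#' @param store optional [registry_store()] used to check uniqueness.
#' @return a length-1 character identifier.
#' @export
#' @examples
#' set.seed(1); mint_identifier()
mint_identifier <- function(store = NULL) {
  repeat {
    bytes <- as.integer(floor(runif(16L, 0, 256)))
    bytes[7L] <- bitwOr(bitwAnd(bytes[7L], 0x0FL), 0x40L)  # version 4
    bytes[9L] <- bitwOr(bitwAnd(bytes[9L], 0x3FL), 0x80L)  # RFC variant
    hex <- paste(sprintf("%02x", bytes), collapse = "")
    id <- sprintf("urn:uuid:%s-%s-%s-%s-%s",
                  substr(hex, 1, 8), substr(hex, 9, 12), substr(hex, 13, 16),
                  substr(hex, 17, 20), substr(hex, 21, 32))
    if (is.null(store) || is.null(store$records[[id]])) return(id)
  }
}
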