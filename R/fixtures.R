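# Seeded synthetic-manuscript generator.  Everything is a pure function of
# the fixture spec (including its seed): names are drawn from a closed
# syllable alphabet so they are pronounceable and collide only when a
# collision is planted, and the manifest enumerates every planted feature
# (expected classification per act, duplicates, homonyms, invalid acts) so
# tests can diff pipeline output against it.

SYLLABLES <- c("ba", "be", "bi", "ca", "co", "cu", "da", "do", "ka", "la",
               "le", "li", "lu", "ma", "mi", "mo", "na", "ne", "no", "pa",
               "pe", "ra", "re", "ri", "ro", "sa", "si", "ta", "ti", "tu",
               "va", "ve", "vi", "za", "zo")
GIVEN_POOL <- c("Anna", "Boris", "Carla", "Dimitar", "Elena", "Felix",
                "Greta", "Hugo", "Ivan", "Jana", "Johann", "Klara", "Lars",
                "Maria", "Nils", "Olga", "Peter", "Rosa", "Stefan", "Teodora")

RANK_PHRASES <- c(suprafamilial = "ordo nov.", familial = "fam. nov.",
                  infrafamilial = "subfam. nov.", generic = "gen. nov.",
                  infrageneric = "subgen. nov.", specific = "sp. nov.",
                  infraspecific = "subsp. nov.")

DEFAULT_KIND_MIX <- c("new_taxon:specific" = 0.70,
                      "new_taxon:generic" = 0.10,
                      "new_combination" = 0.10,
                      "new_replacement_name" = 0.05,
                      "typification:lectotype" = 0.05)

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Specify a synthetic manuscript
#'
#' @param n_acts number of nomenclatural acts.
#' @param kind_mix named probability vector over act descriptors
#'   (`"new_taxon:<rank>"`, `"new_combination"`, `"new_replacement_name"`,
#'   `"tautonym"`, `"hybrid"`, `"typification:<type>"`).
#' @param code governing code of the manuscript, `"ICNafp"` or `"ICZN"`.
#' @param n_authors number of contributors.
#' @param n_author_homonyms contributors planted so that the registry,
#'   once seeded from the manifest, holds two distinct people under the
#'   contributor's written name.
#' @param n_duplicate_acts act slots that repeat an earlier act of the same
#'   manuscript (same name and status, hence the same deduplication key).
#' @param planted_invalid character vector of act descriptors appended as
#'   acts expected to fail validation at some registry (e.g.
#'   `"typification:epitype"` for a ZooBank-bound manuscript).
#' @param seed integer RNG seed; generation is a pure function of the spec.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_acts, kind_mix = DEFAULT_KIND_MIX,
                         code = "ICNafp", n_authors = 3L,
                         n_author_homonyms = 0L, n_duplicate_acts = 0L,
                         planted_invalid = character(0), seed = 1L) {
  code <- match.arg(code, CODES)
  if (n_acts < 0L || n_authors < 1L) {
    stop("fixture spec error: need n_acts >= 0 and n_authors >= 1",
         call. = FALSE)
  }
  if (n_author_homonyms > n_authors) {
    stop("fixture spec error: more homonyms than authors", call. = FALSE)
  }
  if (n_duplicate_acts > 0L && n_duplicate_acts >= n_acts) {
    stop("fixture spec error: duplicates must leave at least one original act",
         call. = FALSE)
  }
  if (abs(sum(kind_mix) - 1) > 1e-8 || is.null(names(kind_mix))) {
    stop("fixture spec error: kind_mix must be a named probability vector",
         call. = FALSE)
  }
  if (code == "ICZN" &&
      any(grepl("^(hybrid|typification:epitype)$",
                c(names(kind_mix)[kind_mix > 0])))) {
    stop("fixture spec error: hybrids and epitypes cannot be drawn under the ICZN mix",
         call. = FALSE)
  }
  structure(list(n_acts = as.integer(n_acts), kind_mix = kind_mix,
                 code = code, n_authors = as.integer(n_authors),
                 n_author_homonyms = as.integer(n_author_homonyms),
                 n_duplicate_acts = as.integer(n_duplicate_acts),
                 planted_invalid = planted_invalid,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

syllable_word <- function(n_syl) {
  paste(sample(SYLLABLES, n_syl, replace = TRUE), collapse = "")
}

capitalize <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

fresh_word <- function(n_syl, used) {
  for (i in 1:100) {
    w <- syllable_word(n_syl)
    if (!w %in% used) return(w)
  }
  stop("could not draw a fresh name; syllable space exhausted", call. = FALSE)
}

# One act blueprint: everything the XML emitter and the manifest need.
draw_act <- function(descriptor, code, used_env) {
  used <- used_env$words
  part <- function(n) {
    w <- fresh_word(n, used_env$words)
    used_env$words <- c(used_env$words, w)
    w
  }
  genus <- capitalize(part(3L))
  authorship <- paste0(capitalize(substr(part(2L), 1, 4)), ".")
  bp <- list(descriptor = descriptor, is_hybrid = FALSE,
             name = list(), authorship = authorship, code = code)
  if (grepl("^new_taxon:", descriptor)) {
    rank <- sub("^new_taxon:", "", descriptor)
    bp$status_phrase <- RANK_PHRASES[[rank]]
    bp$expected <- list(kind = "new_taxon", rank = rank)
    if (rank %in% c("specific", "infraspecific")) {
      bp$name <- list(genus = genus, species = part(3L))
      if (rank == "infraspecific") bp$name$infraspecific <- part(3L)
    } else {
      bp$name <- list(uninomial = genus)
    }
  } else if (descriptor == "tautonym") {
    bp$status_phrase <- "sp. nov."
    bp$expected <- list(kind = "tautonym")
    bp$name <- list(genus = genus, species = tolower(genus))
  } else if (descriptor == "hybrid") {
    bp$status_phrase <- "sp. nov."
    bp$is_hybrid <- TRUE
    bp$expected <- list(kind = "new_taxon", rank = "specific")
    bp$name <- list(genus = genus, species = part(3L))
  } else if (descriptor == "new_combination") {
    bp$status_phrase <- "comb. nov."
    bp$expected <- list(kind = "new_combination")
    bp$name <- list(genus = genus, species = part(3L))
    bp$authorship <- paste0("(", capitalize(substr(part(2L), 1, 4)), ".) ",
                            authorship)
  } else if (descriptor == "new_replacement_name") {
    bp$status_phrase <- "nom. nov."
    bp$expected <- list(kind = "new_replacement_name")
    bp$name <- list(genus = genus, species = part(3L))
  } else if (grepl("^typification:", descriptor)) {
    tk <- sub("^typification:", "", descriptor)
    bp$status_phrase <- paste(tk, "designated")
    bp$expected <- list(kind = "typification", type_kind = tk)
    bp$name <- list(genus = genus, species = part(3L))
  } else {
    stop(sprintf("fixture spec error: unknown act descriptor '%s'",
                 descriptor), call. = FALSE)
  }
  bp
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

act_xml <- function(bp) {
  parts <- vapply(names(bp$name), function(ty) {
    sprintf('          <tp:taxon-name-part taxon-name-part-type="%s">%s</tp:taxon-name-part>',
            ty, xml_escape(bp$name[[ty]]))
  }, character(1L))
  hybrid_attr <- if (bp$is_hybrid) ' is-hybrid="true"' else ""
  paste0(
    "      <tp:nomenclature>\n",
    sprintf("        <tp:taxon-name%s>\n", hybrid_attr),
    paste(parts, collapse = "\n"), "\n",
    "        </tp:taxon-name>\n",
    sprintf("        <tp:taxon-authority>%s</tp:taxon-authority>\n",
            xml_escape(bp$authorship)),
    sprintf("        <tp:taxon-status>%s</tp:taxon-status>\n",
            xml_escape(bp$status_phrase)),
    "      </tp:nomenclature>")
}

#' Generate a synthetic TaxPub manuscript with a manifest
#'
#' Emits a manuscript in the supported TaxPub/JATS dialect, one treatment
#' per act, plus a manifest recording the expected classification of every
#' act and every planted feature (duplicates, author homonyms, invalid
#' acts).  Given the same spec, the output is byte-identical across calls.
#'
#' @param spec a [fixture_spec()].
#' @return list with `xml` (manuscript text) and `manifest` (list; JSON
#'   serializable).
#' @export
#' @examples
#' fx <- generate_manuscript(fixture_spec(n_acts = 3, seed = 42))
#' ms <- parse_manuscript(fx$xml)
generate_manuscript <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    used_env <- new.env(); used_env$words <- character(0)

    n_base <- spec$n_acts - spec$n_duplicate_acts - length(spec$planted_invalid)
    if (n_base < 0L) {
      stop("fixture spec error: duplicates + invalid acts exceed n_acts",
           call. = FALSE)
    }
    # descriptor and name are drawn per act, so a longer run of the same
    # seed reproduces a shorter run's acts as its prefix (what a revised
    # manuscript with added treatments looks like)
    blueprints <- lapply(seq_len(n_base), function(i) {
      d <- sample(names(spec$kind_mix), 1L, prob = spec$kind_mix)
      draw_act(d, code = spec$code, used_env = used_env)
    })
    for (desc in spec$planted_invalid) {
      bp <- draw_act(desc, spec$code, used_env)
      bp$planted_invalid <- TRUE
      blueprints <- c(blueprints, list(bp))
    }
    if (spec$n_duplicate_acts > 0L) {
      origins <- sample(seq_len(n_base), spec$n_duplicate_acts,
                        replace = spec$n_duplicate_acts > n_base)
      for (o in origins) {
        bp <- blueprints[[o]]
        bp$duplicate_of <- o
        blueprints <- c(blueprints, list(bp))
      }
    }

    # Contributors: the first n_author_homonyms are planted with an
    # initials-only given name plus two registry-side namesakes whose full
    # given names share that initial and whose surnames differ only in
    # diacritics -- exercising both normalization rules.
    authors <- list()
    homonyms <- list()
    for (i in seq_len(spec$n_authors)) {
      surname <- capitalize(fresh_word(2L, used_env$words))
      used_env$words <- c(used_env$words, tolower(surname))
      if (i <= spec$n_author_homonyms) {
        pool <- sample(GIVEN_POOL, 2L)
        initial <- substr(pool[1L], 1L, 1L)
        pool2 <- GIVEN_POOL[startsWith(GIVEN_POOL, initial)]
        seeds_given <- if (length(pool2) >= 2L) pool2[1:2] else
          c(pool[1L], paste0(initial, "ohannes"))
        accented <- chartr("aeiou", "áéíóú", surname)
        authors[[i]] <- list(surname = surname,
                             given_names = paste0(initial, "."))
        homonyms[[length(homonyms) + 1L]] <- list(
          contributor_index = i,
          seeds = list(
            list(surname = surname, given_names = seeds_given[1L]),
            list(surname = accented, given_names = seeds_given[2L])))
      } else {
        authors[[i]] <- list(surname = surname,
                             given_names = sample(GIVEN_POOL, 1L))
      }
    }

    genus_word <- capitalize(fresh_word(3L, used_env$words))
    meta <- list(
      title = sprintf("Revision of %s with %d nomenclatural novelties",
                      genus_word, spec$n_acts),
      journal = if (spec$code == "ICZN") "Journal of Synthetic Zoology"
                else "Journal of Synthetic Botany",
      issn = "2000-1234",
      doi = sprintf("10.5281/synth.%d", spec$seed),
      archive = "CLOCKSS",
      code = spec$code,
      acceptance_date = "2015-11-20")

    contrib_xml <- vapply(authors, function(a) {
      paste0("        <contrib contrib-type=\"author\"><name>",
             sprintf("<surname>%s</surname>", xml_escape(a$surname)),
             sprintf("<given-names>%s</given-names>",
                     xml_escape(a$given_names)),
             "</name></contrib>")
    }, character(1L))

    treatment_xml <- vapply(blueprints, function(bp) {
      paste0("    <tp:taxon-treatment>\n", act_xml(bp), "\n",
             "      <tp:treatment-sec sec-type=\"description\"><p>",
             "Diagnosis and description.",
             "</p></tp:treatment-sec>\n",
             "    </tp:taxon-treatment>")
    }, character(1L))

    xml <- paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      '<article xmlns:tp="http://www.plazi.org/taxpub" dtd-version="1.1">\n',
      "  <front>\n",
      "    <journal-meta>\n",
      sprintf("      <journal-title>%s</journal-title>\n",
              xml_escape(meta$journal)),
      sprintf("      <issn>%s</issn>\n", meta$issn),
      "    </journal-meta>\n",
      "    <article-meta>\n",
      sprintf('      <article-id pub-id-type="doi">%s</article-id>\n',
              meta$doi),
      "      <title-group><article-title>",
      xml_escape(meta$title),
      "</article-title></title-group>\n",
      "      <contrib-group>\n",
      paste(contrib_xml, collapse = "\n"), "\n",
      "      </contrib-group>\n",
      "      <history>\n",
      sprintf('        <date date-type="accepted" iso-8601-date="%s"/>\n',
              meta$acceptance_date),
      "      </history>\n",
      "      <custom-meta-group>\n",
      sprintf("        <custom-meta><meta-name>archive</meta-name><meta-value>%s</meta-value></custom-meta>\n",
              meta$archive),
      sprintf("        <custom-meta><meta-name>nomenclatural-code</meta-name><meta-value>%s</meta-value></custom-meta>\n",
              meta$code),
      "      </custom-meta-group>\n",
      "    </article-meta>\n",
      "  </front>\n",
      "  <body>\n",
      if (length(treatment_xml) > 0L)
        paste0(paste(treatment_xml, collapse = "\n"), "\n") else "",
      "  </body>\n",
      "</article>\n")

    manifest_acts <- lapply(seq_along(blueprints), function(i) {
      bp <- blueprints[[i]]
      list(index = i, status_phrase = bp$status_phrase,
           expected = bp$expected, name = bp$name,
           authorship = bp$authorship, is_hybrid = bp$is_hybrid,
           duplicate_of = bp$duplicate_of %||% NULL,
           planted_invalid = isTRUE(bp$planted_invalid))
    })

    list(xml = xml,
         manifest = list(
           spec = unclass(spec), article = meta, authors = authors,
           acts = manifest_acts, homonyms = homonyms,
           n_acts = length(blueprints)))
  })
}

#' Seed a registry with the manifest's planted author homonyms
#'
#' For every planted homonym the manifest lists two distinct people whose
#' written names normalize to the manuscript contributor's name; inserting
#' both makes a subsequent [match_authors()] call return a pending
#' disambiguation, as it would at a registry that already knows two authors
#' by that name.
#'
#' @param store a [registry_store()].
#' @param manifest the manifest from [generate_manuscript()].
#' @return number of seed author records inserted.
#' @export
plant_homonyms <- function(store, manifest) {
  n <- 0L
  for (h in manifest$homonyms) {
    for (s in h$seeds) {
      a <- author_name(s$surname, s$given_names)
      upsert_record(store, a,
                    dedup_key = paste(a$normalized_key, mint_identifier(store)))
      n <- n + 1L
    }
  }
  n
}
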