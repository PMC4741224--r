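register_fixture <- function(n_acts = 2, seed = 1, registry = "zoobank",
                             code = "ICZN", ...) {
  g <- gen_ms(n_acts = n_acts, seed = seed, code = code,
              kind_mix = c("new_taxon:specific" = 1), ...)
  store <- make_store(registry)
  set.seed(seed)
  list(g = g, store = store,
       report = register_manuscript(g$ms, store))
}

test_that("a clean manuscript registers every act embargoed, with distinct ids", {
  r <- register_fixture(n_acts = 2, seed = 21)
  expect_identical(r$report$acts$status, c("registered", "registered"))
  expect_length(unique(r$report$acts$id), 2L)
  states <- vapply(search_records(r$store, list(payload_type = "act")),
                   `[[`, "", "state")
  expect_true(all(states == "embargoed"))
  # no public leak before release
  expect_length(search_records(r$store, list(payload_type = "act"),
                               context = "public"), 0L)
})

test_that("an act outside the registry's scope errors; its siblings register", {
  r <- register_fixture(n_acts = 4, seed = 33,
                        planted_invalid = "typification:epitype")
  expect_identical(sum(r$report$acts$status == "registered"), 3L)
  bad <- r$report$acts[r$report$acts$status == "error", ]
  expect_identical(nrow(bad), 1L)
  expect_match(bad$message, "not_applicable")
  expect_true(r$g$fx$manifest$acts[[bad$index]]$planted_invalid)
})

test_that("a manuscript without acceptance-stage metadata is rejected whole", {
  g <- gen_ms(n_acts = 1, seed = 2, code = "ICZN",
              kind_mix = c("new_taxon:specific" = 1))
  broken <- g$ms
  broken$article_meta$title <- ""
  store <- make_store()
  expect_error(register_manuscript(broken, store), "acceptance-stage")
  expect_length(nomenreg:::all_records(store), 0L)
})

test_that("planted author homonyms yield a pending outcome that blocks finalize", {
  g <- gen_ms(n_acts = 2, seed = 77, code = "ICZN",
              kind_mix = c("new_taxon:specific" = 1), n_author_homonyms = 1)
  store <- make_store()
  set.seed(77)
  plant_homonyms(store, g$fx$manifest)
  report <- register_manuscript(g$ms, store)
  expect_identical(sum(report$authors$status == "pending"), 1L)
  expect_true(all(report$acts$status == "registered"))
  expect_true(report_blocked(report))
  set_clock(store, PUB_DAY)
  expect_error(finalize_publication(g$fx$xml, report, store, PUB_DAY, "uri"),
               "pending")
  # operator resolves; the pipeline unblocks
  ref <- report$authors$pending_ref[report$authors$status == "pending"]
  pend <- store$pending[[ref]]
  resolve_disambiguation(store, pend, "NEW")
  report$authors$status[report$authors$status == "pending"] <- "registered"
  fin <- finalize_publication(g$fx$xml, report, store, PUB_DAY, "uri")
  expect_identical(fin$released, 2L)
})

test_that("an identical reupload updates every act and keeps identifiers", {
  r <- register_fixture(n_acts = 3, seed = 41)
  rep2 <- reupload(r$g$ms, r$store)
  expect_true(all(attr(rep2, "act_actions") == "updated"))
  expect_identical(rep2$acts$id, r$report$acts$id)
  expect_length(attr(rep2, "superseded"), 0L)
})

test_that("a reupload with one extra act inserts exactly one record", {
  r <- register_fixture(n_acts = 3, seed = 55)
  bigger <- generate_manuscript(fixture_spec(
    n_acts = 4, seed = 55, code = "ICZN",
    kind_mix = c("new_taxon:specific" = 1)))
  # same seed: the first three acts are identical, the fourth is new
  rep2 <- reupload(parse_manuscript(bigger$xml), r$store)
  expect_identical(sum(attr(rep2, "act_actions") == "inserted"), 1L)
  expect_identical(rep2$acts$id[1:3], r$report$acts$id)
})

test_that("acts missing from a reupload are superseded, not deleted", {
  r <- register_fixture(n_acts = 3, seed = 62)
  smaller <- generate_manuscript(fixture_spec(
    n_acts = 2, seed = 62, code = "ICZN",
    kind_mix = c("new_taxon:specific" = 1)))
  rep2 <- reupload(parse_manuscript(smaller$xml), r$store)
  gone <- attr(rep2, "superseded")
  expect_length(gone, 1L)
  expect_identical(gone, r$report$acts$id[3L])
  expect_identical(r$store$records[[gone]]$state, "superseded")
})

test_that("reupload after release is a conflict", {
  r <- register_fixture(n_acts = 1, seed = 70)
  set_clock(r$store, PUB_DAY)
  finalize_publication(r$g$fx$xml, r$report, r$store, PUB_DAY, "uri")
  expect_error(reupload(r$g$ms, r$store), "conflict")
})

test_that("a clean run injects, releases and reports an empty metadata diff", {
  r <- register_fixture(n_acts = 3, seed = 83)
  set_clock(r$store, PUB_DAY)
  fin <- finalize_publication(r$g$fx$xml, r$report, r$store, PUB_DAY,
                              "https://doi.org/10.9999/x")
  expect_identical(fin$released, 3L)
  expect_length(fin$metadata_diff, 0L)
  expect_identical(reparse_injected_ids(fin$xml), r$report$acts$id)
  recs <- search_records(r$store, list(payload_type = "act"),
                         context = "public")
  expect_length(recs, 3L)
  expect_identical(sort(vapply(recs, `[[`, "", "id")),
                   sort(r$report$acts$id))
})

test_that("the zoological e-only route demands an archive and an ISSN/ISBN", {
  treat <- treatment_block(genus = "Aus", species = "bus")
  no_issn <- tiny_manuscript(treat, issn = "", archive = "CLOCKSS")
  store <- make_store()
  set.seed(91)
  report <- register_manuscript(parse_manuscript(no_issn), store)
  set_clock(store, PUB_DAY)
  expect_error(finalize_publication(no_issn, report, store, PUB_DAY, "uri"),
               "ISSN")
  # same manuscript at a botanical registry finalizes without them
  no_issn_bot <- tiny_manuscript(treat, issn = "", archive = "",
                                 code = "ICNafp")
  ipni <- make_store("ipni")
  rep_b <- register_manuscript(parse_manuscript(no_issn_bot), ipni)
  set_clock(ipni, PUB_DAY)
  fin <- finalize_publication(no_issn_bot, rep_b, ipni, PUB_DAY, "uri")
  expect_identical(fin$released, 1L)
})

test_that("a title changed between acceptance and publication shows up in the diff", {
  r <- register_fixture(n_acts = 2, seed = 95)
  final_xml <- sub("Revision of", "Monograph of", r$g$fx$xml)
  set_clock(r$store, PUB_DAY)
  fin <- finalize_publication(final_xml, r$report, r$store, PUB_DAY, "uri")
  expect_identical(fin$metadata_diff, "title")
})

test_that("acts parsed, outcomes, injected ids and released records all agree", {
  for (seed in c(7L, 29L)) {
    r <- register_fixture(n_acts = 5, seed = seed)
    n <- length(manuscript_acts(r$g$ms))
    expect_identical(nrow(r$report$acts), n)
    set_clock(r$store, PUB_DAY)
    fin <- finalize_publication(r$g$fx$xml, r$report, r$store, PUB_DAY, "uri")
    expect_identical(length(reparse_injected_ids(fin$xml)), n)
    expect_identical(fin$released, n)
  }
})

test_that("the pipeline is bit-reproducible for a given seed and clock", {
  run <- function() {
    g <- gen_ms(n_acts = 4, seed = 11, code = "ICZN",
                kind_mix = c("new_taxon:specific" = 1))
    store <- make_store()
    set.seed(11)
    report <- register_manuscript(g$ms, store)
    set_clock(store, PUB_DAY)
    fin <- finalize_publication(g$fx$xml, report, store, PUB_DAY, "uri")
    path <- withr::local_tempfile(fileext = ".jsonl")
    save_store(store, path)
    list(report = report, xml = fin$xml,
         store_lines = readLines(path))
  }
  a <- run(); b <- run()
  expect_identical(a$report, b$report)
  expect_identical(a$xml, b$xml)
  expect_identical(a$store_lines, b$store_lines)
})
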