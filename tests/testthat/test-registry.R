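sp_act <- function(genus = "Aus", species = "bus", code = "ICZN") {
  nomenclatural_act("new_taxon", scientific_name(genus = genus,
                                                 species = species,
                                                 authorship = "Smith"),
                    rank = "specific", code = code)
}

test_that("search matches all filters; embargoed records hide from the public", {
  store <- make_store()
  expect_length(search_records(store, list(kind = "new_taxon")), 0L)
  set.seed(1)
  res <- upsert_record(store, sp_act(), article_id = "urn:uuid:art")
  found <- search_records(store, list(name = "Aus bus"))
  expect_length(found, 1L)
  expect_identical(found[[1L]]$id, res$record$id)
  # embargo: invisible publicly, visible to the owning publisher
  expect_length(search_records(store, list(name = "Aus bus"),
                               context = "public"), 0L)
  expect_error(search_records(store, list(colour = "red")), "unknown filter")
})

test_that("upsert inserts once, then updates in place with a stable identifier", {
  store <- make_store()
  set.seed(2)
  first <- upsert_record(store, sp_act())
  expect_identical(first$action, "inserted")
  again <- upsert_record(store, sp_act())
  expect_identical(again$action, "updated")
  expect_identical(again$record$id, first$record$id)
  # changed payload, same dedup key: read-back shows the new authorship
  changed <- sp_act()
  changed$name$authorship <- "Jones"
  res <- upsert_record(store, changed, dedup_key = first$record$dedup_key)
  expect_identical(res$action, "updated")
  expect_identical(store$records[[first$record$id]]$payload$name$authorship,
                   "Jones")
  expect_length(nomenreg:::all_records(store), 1L)
})

test_that("upsert is idempotent with respect to store state", {
  set.seed(3)
  s1 <- make_store(); s2 <- make_store()
  upsert_record(s1, sp_act())
  set.seed(3)
  upsert_record(s2, sp_act()); upsert_record(s2, sp_act())
  ids1 <- ls(s1$records); ids2 <- ls(s2$records)
  expect_identical(ids1, ids2)
  expect_identical(s1$records[[ids1]]$payload, s2$records[[ids2]]$payload)
  expect_identical(s1$records[[ids1]]$state, s2$records[[ids2]]$state)
})

test_that("a public record cannot be silently rewritten", {
  store <- make_store()
  set.seed(4)
  res <- upsert_record(store, sp_act(), article_id = "urn:uuid:art")
  set_clock(store, PUB_DAY)
  release_records(store, "urn:uuid:art", PUB_DAY, "https://doi.org/x")
  changed <- sp_act(); changed$name$authorship <- "Other"
  expect_error(upsert_record(store, changed), "conflict")
  # identical payload is still a harmless update
  expect_identical(upsert_record(store, sp_act())$action, "updated")
  # the sanctioned path: supersession
  rec <- supersede_record(store, res$record$id)
  expect_identical(rec$state, "superseded")
})

test_that("author matching distinguishes none, one, and homonyms", {
  store <- make_store()
  set.seed(5)
  expect_identical(match_authors(store, author_name("Smith", "J."))$status,
                   "no_match")
  upsert_record(store, author_name("Smith", "J."), dedup_key = "smith j 1")
  expect_identical(match_authors(store, author_name("Smith", "J."))$status,
                   "unique_match")
  # two distinct people under the same written name
  upsert_record(store, author_name("Smíth", "Jana"), dedup_key = "smith j 2")
  hom <- match_authors(store, author_name("Smith", "J."))
  expect_identical(hom$status, "homonyms")
  expect_length(hom$pending$candidates, 2L)
  # all candidates carry the submitted normalized surname
  keys <- vapply(hom$pending$candidates,
                 function(r) normalize_name_key(r$payload$surname), "")
  expect_true(all(keys == normalize_name_key("Smith")))
})

test_that("disambiguation accepts a candidate or NEW, rejects anything else", {
  store <- make_store()
  set.seed(6)
  upsert_record(store, author_name("Lee", "Kim"), dedup_key = "lee k 1")
  upsert_record(store, author_name("Lee", "Karl"), dedup_key = "lee k 2")
  hom <- match_authors(store, author_name("Lee", "K."))
  chosen <- resolve_disambiguation(store, hom$pending,
                                   hom$pending$candidates[[1L]]$id)
  expect_identical(chosen$id, hom$pending$candidates[[1L]]$id)

  hom <- match_authors(store, author_name("Lee", "K."))
  fresh <- resolve_disambiguation(store, hom$pending, "NEW")
  expect_false(fresh$id %in% vapply(hom$pending$candidates, `[[`, "", "id"))
  expect_identical(fresh$payload$normalized_key,
                   author_name("Lee", "K.")$normalized_key)

  hom <- match_authors(store, author_name("Lee", "K."))
  expect_error(resolve_disambiguation(store, hom$pending, "urn:uuid:none"),
               "invalid choice")
})

test_that("release flips every embargoed record of the article, idempotently", {
  store <- make_store()
  set.seed(7)
  art <- upsert_record(store, list(title = "T", journal = "J"),
                       dedup_key = "t j")
  for (sp in c("a", "b", "c")) {
    upsert_record(store, sp_act(species = sp), article_id = art$record$id)
  }
  expect_error(release_records(store, art$record$id, PUB_DAY, "uri"),
               "embargo violation")
  # failed release leaves every state untouched
  states <- vapply(nomenreg:::all_records(store), `[[`, "", "state")
  expect_true(all(states == "embargoed"))

  set_clock(store, PUB_DAY)
  expect_identical(release_records(store, art$record$id, PUB_DAY, "uri"), 3L)
  recs <- nomenreg:::all_records(store)
  expect_true(all(vapply(recs, `[[`, "", "state") == "public"))
  expect_true(all(vapply(recs, function(r) identical(r$article_link, "uri"),
                         TRUE)))
  expect_identical(release_records(store, art$record$id, PUB_DAY, "uri"), 0L)
  expect_error(release_records(store, "urn:uuid:ghost", PUB_DAY, "uri"),
               "not found")
})

test_that("propagation converges across the fungal registries", {
  set.seed(8)
  mb <- make_store("mycobank")
  targets <- list(index_fungorum = make_store("index_fungorum"),
                  fungal_names = make_store("fungal_names"))
  lect <- nomenclatural_act("typification",
                            scientific_name(genus = "Fungus", species = "albus"),
                            type_kind = "lectotype")
  rec <- upsert_record(mb, lect)$record
  acts1 <- propagate(mb, rec, names(targets), targets)
  expect_identical(unname(acts1), c("inserted", "inserted"))
  acts2 <- propagate(mb, rec, names(targets), targets)
  expect_identical(unname(acts2), c("updated", "updated"))
  # exactly one record per dedup key everywhere, cross-referenced
  for (tg in targets) {
    hits <- search_records(tg, list(dedup_key = rec$dedup_key))
    expect_length(hits, 1L)
    expect_identical(hits[[1L]]$xref$mycobank, rec$id)
  }
  expect_error(propagate(mb, rec, "zoobank", list(zoobank = make_store())),
               "fungal")
})

test_that("a store round-trips through its JSON-lines file", {
  store <- make_store("mycobank")
  set.seed(9)
  art <- upsert_record(store, list(title = "T", journal = "J"),
                       dedup_key = "t j")
  upsert_record(store, sp_act(code = "ICNafp"), article_id = art$record$id)
  upsert_record(store, author_name("Müller", "J."), dedup_key = "muller j 1")
  path <- withr::local_tempfile(fileext = ".jsonl")
  save_store(store, path)
  # one header line plus one line per record
  expect_length(readLines(path), 4L)
  back <- load_store(path)
  expect_identical(back$registry, "mycobank")
  expect_identical(back$clock, store$clock)
  orig <- nomenreg:::all_records(store)
  copy <- nomenreg:::all_records(back)
  expect_identical(length(orig), length(copy))
  for (i in seq_along(orig)) {
    expect_identical(copy[[i]]$id, orig[[i]]$id)
    expect_identical(copy[[i]]$payload, orig[[i]]$payload)
    expect_identical(copy[[i]]$state, orig[[i]]$state)
    expect_identical(copy[[i]]$dedup_key, orig[[i]]$dedup_key)
  }
  # a reloaded store keeps upserting against the same keys
  expect_identical(upsert_record(back, sp_act(code = "ICNafp"))$action,
                   "updated")
})
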