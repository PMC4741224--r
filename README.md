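# nomenreg

Automated, pre-publication registration of nomenclatural acts, as an R
package with an embedded registry engine.

## The problem

Biological nomenclature requires new names and related acts — new taxa,
new combinations, replacement names, typifications — to be recorded in
the community's name registries: IPNI for vascular plants, Index
Fungorum / MycoBank / Fungal Names for fungi (registration mandatory
since 2013), ZooBank for animals (mandatory for electronic-only works
since 2012). For modern journals this must happen *between acceptance
and publication*: the registry mints an identifier for every act, the
identifier is printed in the published treatment, and the registry
record stays **embargoed** — stored but invisible — until publication
day, when it goes public with a link to the article. With
"turbo-taxonomic" papers describing hundreds of species at once, doing
this by hand is not an option.

`nomenreg` implements the whole publisher-side workflow, offline and
deterministically:

1. **Submit on acceptance** — parse the manuscript (TaxPub-flavoured
   JATS XML), classify each act, validate it against the per-registry
   registrability matrix, and upsert article, authors and acts into the
   registry store (embargoed).
2. **Report** — one outcome per act: a minted `urn:uuid:` identifier,
   an error, or a pending author-homonym disambiguation for an
   editorial operator to resolve.
3. **Inject** — splice the identifiers back into each treatment's
   nomenclature block, byte-stably (the XML changes only at the
   injection points).
4. **Release** — on publication day, end the embargo, attach the
   article link, and diff the final published metadata against what was
   registered at acceptance.

Re-uploading a corrected manuscript before release *replaces* the
previous data: unchanged acts keep their identifiers (matched by a
deduplication key), dropped acts are superseded, new acts are inserted.
A parallel TCS channel (`to_tcs()` / `parse_tcs_response()`) serves the
botanical/fungal registries, which exchange name records rather than
whole manuscripts, and `propagate()` synchronizes a record across the
three fungal registries.

The registrability matrix (which of the four registries records which
act, with the three code-specific footnote rules: hybrid flagging,
tautonyms not validly published under the botanical code, IPNI
recording holotypifications only) ships as a human-auditable config
file in `inst/extdata/scope_matrix.tsv`.

A seeded synthetic-manuscript generator (`generate_manuscript()`)
produces TaxPub fixtures with a manifest of every planted feature —
duplicate acts, author homonyms varying only in diacritics or initials,
out-of-scope acts — so the entire pipeline is testable with no network
access.

## Worked example

```r
library(nomenreg)

fx <- generate_manuscript(fixture_spec(
  n_acts = 3, code = "ICZN", kind_mix = c("new_taxon:specific" = 1),
  seed = 42))
ms <- parse_manuscript(fx$xml)
print(ms)
#> <manuscript> "Revision of Sacucu with 3 nomenclatural novelties" (3 contributors, 3 treatments, 3 acts)

store <- registry_store("zoobank", clock = as.Date("2015-11-20"))
set.seed(42)
report <- register_manuscript(ms, store)
report$acts[, c("index", "status", "id")]
#>   index     status                                            id
#> 1     1 registered urn:uuid:c0738989-005b-4cd4-9b69-9296b865ebf6
#> 2     2 registered urn:uuid:3bb9e79a-a1ef-4994-921d-c39f261476c7
#> 3     3 registered urn:uuid:bbd12bf1-4b26-4852-8764-adc6300722ae

# embargo: nothing is publicly visible before publication day
length(search_records(store, list(payload_type = "act"), context = "public"))
#> [1] 0

set_clock(store, "2016-01-07")
fin <- finalize_publication(fx$xml, report, store, "2016-01-07",
                            "https://doi.org/10.3897/example.1")
fin$released
#> [1] 3
length(search_records(store, list(payload_type = "act"), context = "public"))
#> [1] 3
```

Each act's outcome is a freshly minted RFC 4122 UUID in URN form; after
`finalize_publication()` those same identifiers are present inside the
published XML (`fin$xml`) and the records are public with the article
link attached. All timestamps come from the injected registry clock and
all identifiers from the seeded RNG, so a run is bit-reproducible.

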