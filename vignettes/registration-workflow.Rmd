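---
title: "The registration workflow: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The registration workflow: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomenreg)
```

## The procedure being modelled

Registration of nomenclatural acts is a contract between a publisher
and a name registry with a strict temporal shape:

1. on *acceptance*, the publisher sends the acts and preliminary
   bibliographic metadata; the registry stores them but keeps them
   invisible to the public (the **embargo**);
2. the registry answers with one identifier per act, or an error, or —
   for author names that collide with several known people — a pending
   disambiguation for a human operator;
3. the publisher prints the identifiers inside the published
   treatments;
4. on *publication day* the records become public, each linked to the
   article, and the final published metadata is checked against what
   was registered.

`nomenreg` implements both sides of this contract: the publisher-side
parsing/injection and the registry engine itself, so the whole loop is
executable and testable in one process. The key assumptions are:

* **The act is the unit of registration.** A manuscript is an ordered
  list of treatments, each holding one or more nomenclature blocks, and
  each block is exactly one act. Order is preserved everywhere —
  report outcomes, injected identifiers and TCS records all follow
  document order.
* **Identity is the deduplication key, not the identifier.** An act's
  key is the normalized combination of governing code, act kind,
  canonical name string (with its status marker) and type kind. Upsert
  semantics — update if the key exists, insert otherwise — make
  re-uploads replace earlier data while the minted identifier stays
  stable. This is the property the whole workflow leans on: the
  identifier printed in the article at step 3 is the identifier the
  public sees after step 4.
* **Time is injected.** A registry store carries a clock (a calendar
  date) set by the caller; all timestamps derive from it and the
  embargo check (`release` before the publication date is an error) is
  evaluated against it. Together with RNG-seeded identifier minting
  this makes any pipeline run bit-reproducible, which the test suite
  exploits heavily.

## The registrability matrix and its three rules

Not every act is registrable everywhere. The package ships a
human-auditable grid (`inst/extdata/scope_matrix.tsv`): fifteen act
descriptors (seven new-taxon ranks, the hybrid flag row, replacement
names, combinations, tautonyms, four typification kinds) against five
registries. A cell is `recorded`, `not_recorded` or `not_applicable`;
`validate_act()` accepts exactly when the cell is `recorded` and no
code rule fires:

```{r}
act <- classify_act("sp. nov.", scientific_name(genus = "Aus", species = "aus"),
                    code = "ICNafp")
act$kind                      # epithet repeats the genus: a tautonym
validate_act(act, "ipni")     # recorded if published, but flagged
```

The three rules that accompany the grid: hybrid-flagged names are a
flag on any botanical rank, not a separate kind, and are not applicable
under the zoological code; tautonyms are not validly published under
the botanical code, so botanical registries record them with a warning
for the indexing stage; and IPNI records holotypifications of new taxa
but not new lecto-, neo- or epitypifications.

Two transcription choices were genuinely open. First, standard
tabulations of this grid leave six zoological cells unattested
(suprafamilial new taxa, replacement names, combinations, holo-,
lecto- and neotypifications). Since the zoological code governs these
acts and ZooBank registers them, the matrix fills them as `recorded`,
but every such cell carries `table_blank = TRUE` and the conformance
check in `tests/testthat/test-acceptance.R` diffs only the 54
unattested-free cells — the package does not silently claim the grid
printed a `+`. Second, Fungal Names is one of the three official fungal
registries but absent from the published grid; its column mirrors Index
Fungorum so that `propagate()` has a scope to validate against.

The status-phrase vocabulary (`inst/extdata/status_phrases.tsv`) is
configuration, not code, because journals vary. An unrecognized phrase
is a classification *error*, never a guess — "stat. nov." and
orthographic corrections are deliberately absent because no registry's
scope row lists them.

## Author matching and homonyms

Author identity matching uses a two-part rule: surnames must match
under the normalization (Unicode-decompose, strip diacritics, casefold,
strip punctuation, collapse whitespace) and given names must be
prefix-compatible token by token, so "J." matches "John" and "J. B."
matches "Jane B.". No fuzzy scoring is attempted: the goal is to
reproduce the operator-in-the-loop behaviour — zero matches mint a new
author record, one match links it, two or more put a
`pending_disambiguation` in the queue and block identifier injection
until an operator chooses a candidate or declares a new person.
The pending queue blocks *injection*, not registration: valid sibling
acts still receive identifiers, mirroring how an editorial office
would proceed.

## Lifecycle and its one deliberate extension

Records move `embargoed → public` (at release) and `anything →
superseded` (explicit correction, or an act dropped by a re-upload).
One extension proved necessary: when a pre-release re-upload re-adds an
act that an earlier re-upload had superseded, the record is reinstated
to `embargoed` rather than duplicated, because identifier stability
must hold in both directions. Published records are never silently
rewritten — an upsert with changed payload against a `public` record is
a conflict, and the sanctioned path is explicit supersession.

The publication-day metadata check only *reports* discrepancies
(`finalize_publication()$metadata_diff`); it never auto-corrects the
registry. The registry holds the acceptance-time truth and the
publisher holds the published truth; reconciling them is editorial
work, not something a pipeline should guess at.

## What the synthetic generator does and does not emulate

`generate_manuscript()` is a pure function of its `fixture_spec()`:
names come from a closed syllable alphabet (collisions occur only when
planted), each act's descriptor and name are drawn per act so a longer
run of the same seed extends a shorter one as a prefix (exactly what a
revised manuscript with added or dropped treatments looks like), and
the manifest enumerates every act's expected classification plus every
planted duplicate, homonym and out-of-scope act. Homonym planting
varies raw spelling while preserving the normalized key — one namesake
differs by diacritics, the other by initials versus full given name —
so both normalization rules are exercised.

Defaults encode a realistic mid-size revision: a kind mix dominated by
new species (70%), with new genera, combinations, replacement names and
lectotypifications making up the rest; three contributors; acceptance
on 2015-11-20 and publication on 2016-01-07 in the tests. Bulk runs use
a pure new-species mix at 277, 178 and 101 acts — the sizes of the
record-setting bulk-description papers — because that is what such
manuscripts contain.

What the generator does **not** emulate, and what passing tests
therefore cannot show: real TaxPub markup diversity (publisher-specific
tagging, nested subsections, non-treatment body text), messy authority
strings ("ex" authors, "in" citations), infrageneric name formatting
quirks, non-Latin-script author names beyond what diacritic stripping
covers, and any registry-side behaviour of the real IPNI/MycoBank/
ZooBank endpoints — transport, authentication and their server-side
validation are explicitly out of scope, with the "POST request"
modelled as a function call against the embedded store.

## Numerical and formatting choices

* Identifiers are RFC 4122 v4 UUIDs drawn from R's RNG; uniqueness is
  enforced per store by re-drawing on collision (astronomically rare,
  but the check makes the post-condition unconditional).
* Injection is anchor-based string splicing, not DOM re-serialization:
  the identifier element is inserted as the first child of each
  nomenclature block, and everything outside the insertion points is
  preserved byte for byte. This is what makes the round-trip invariant
  ("remove the injected elements and you recover the input exactly")
  testable at all.
* Dates are ISO-8601 calendar dates only; anything else is a
  structural error, as is a publication date preceding acceptance.
* Degenerate inputs are first-class: a manuscript with zero treatments
  parses cleanly to zero acts, an empty report serializes to a
  schema-valid document, an empty assignment on an act-free manuscript
  is the identity.
* Store files are JSON-lines with a schema-versioned header — one
  record per line, insertion-ordered, so the registration trail is
  auditable with line-oriented tools.

## Problem sizes

The test suite registers manuscripts end-to-end at 277, 178 and 101
acts (each completes in about a second), runs 1,000 randomized
register/query/release schedules for the embargo property, 100
generator seeds for the three round-trip suites, and 15–20 seeds for
the re-upload/supersession oracles. These sizes were chosen to cover
the documented bulk-description scales and to give the property suites
enough randomized schedules to be convincing while keeping the whole
suite in the tens of seconds.

## Known limitations

Only the registrability matrix and its three footnote rules are
checked — no Latin diagnosis, gender agreement or priority analysis.
The TCS subset is conservative (names, status, basionym authorship,
citation) and emitted without namespace machinery; real TCS 1.01
instance fidelity was not attempted since the pilot's exact field list
is not public. Author matching is deliberately literal: "Zhang, W."
against two registered W. Zhangs is a pending queue entry, not a
probabilistic guess. And the embedded registry is single-process by
design — distributed operation, authentication and live endpoint
dialects are out of scope.
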