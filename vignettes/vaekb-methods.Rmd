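---
title: "vaekb: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vaekb: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaekb)
```

## The knowledge model

`vaekb` treats vaccine adverse-event curation as an ontology-engineering
problem. The unit of curation is one row of a ten-column template (vaccine
name and VO-style id, VAE location, insert and ontology AE names, OAE-style
id, age category, age range in years, occurrence, citation). Rows sharing a
(vaccine, AE) pair are merged into one *association* carrying a list of age
groups, and every association compiles into one leaf class through a fixed
design pattern:

* the leaf is asserted under **two** parents — the adverse-event class from
  the AE vocabulary and a per-vaccine grouping class
  `"<vaccine> vaccine adverse event"`. Dual parentage reconciles the
  vaccine-grouped browsing hierarchy with the AE-anchored axioms; the
  single-inheritance discipline of the upstream AE vocabulary applies to that
  vocabulary, not to these compiled leaves.
* the defining axiom says the event *is preceded by* a vaccination with the
  vaccine and *occurs in* a human vaccinee population restricted by
  `'has age in year'` (a closed decimal interval, open-ended upper bounds
  allowed) and `'has VAE occurrence'` (a decimal fraction). Age groups
  combine with an OR-clause inside the population filler; with a single
  group the disjunction node degenerates away.
* the axiom is emitted as **SubClassOf**, not EquivalentClasses. The
  equivalence reading is not needed by any analysis here and subclass is the
  weaker, safer commitment; defined *grouping* classes (e.g.
  `'injection-site adverse event'`) do use definition-style equivalence,
  which is exactly what the reasoner needs to reclassify leaves under them.
* occurrence is stored internally as a fraction in [0, 1] and rendered as a
  percent only in reports, so no value is ever converted twice.
* `'has VAE occurrence'` is a **datatype** property over decimals; its axiom
  usage forces this even though shortcut relations of this kind are
  sometimes described as object properties.
* all five pattern properties are minted in the package's own id space
  (`OVAE_0000001`–`OVAE_0000005`) rather than borrowing upstream relation
  ids; this keeps the "every KB carries the pattern properties" invariant
  self-contained and makes the per-source statistics table deterministic.

Identifier minting is `OVAE_` plus seven auto-incrementing digits, skipping
reserved ids. Associations are compiled in (vaccine label, AE label) order,
so recompiling identical input reproduces identical ids and a byte-identical
Turtle file.

## Age semantics

Age expressions follow a small grammar: `18-40`, `65+`, `6mo-35mo`
(months / 12), and a bare `2`, which is widened to the closed interval
[2, 3] — sources rarely state how single ages were widened, and [n, n + 1]
is the smallest interval consistent with "age two". Categories are derived
from the interval: *child* when entirely ≤ 18, *senior* when entirely ≥ 65,
*adult* when starting at ≥ 18, *child-adult* when the interval straddles 18.
A declared category that disagrees with the computed one raises a warning,
not an error: "typically under 18" implies curator discretion, and senior
intervals sit inside the adult range, so senior/adult disagreements are
accepted silently. For the three-way child/adult/child-adult comparison,
senior entries fold into adult; the interval-grouped summary keeps them
distinct. Overlap between age groups of one association is an error, but
sharing an endpoint ([0.5, 3] next to [3, 8]) is allowed — closed intervals
with matching clinical-trial strata almost always touch.

## The EL reasoner

Classification uses the polynomial EL fragment: atomic subsumptions,
conjunctions, existential restrictions, and definition-style equivalences.
Defining expressions are normalized into the four EL normal forms with fresh
auxiliary atoms; **datatype restrictions and the OR-clause are opaque
atoms** keyed by a canonical rendering, so identical restrictions align but
no interval subsumption is ever inferred. This keeps the fragment small and
sound: the only inference the analyses rely on is object-existential (an AE
that `'occurs in' some 'injection site'` classifies under the defined
injection-site grouping). Completion runs a worklist to the least fixpoint;
rule application order is deterministic, classification is idempotent and
monotone, and the test suite checks soundness and completeness against a
brute-force saturation oracle on hundreds of random ontologies of up to 30
classes. `inferred_only_edges()` reports the direct edges of the inferred
hierarchy that are not derivable from the asserted transitive closure,
skipping mutually subsumed pairs.

## Serialization and querying

The triple view uses OBO-style PURLs
(`http://purl.obolibrary.org/obo/<PREFIX>_<digits>`). Pattern expressions
serialize as standard OWL structures (`owl:Restriction`,
`owl:intersectionOf`/`owl:unionOf` lists, `owl:hasValue`, and
`rdfs:Datatype` facet restrictions with `xsd:minInclusive` /
`xsd:maxInclusive` on `xsd:decimal`). The facet vocabulary is a documented
choice, not a claim about any released ontology. The writer is canonical —
fixed prefix block, sorted subjects/predicates/objects, inlined blank
structures — so identical KBs give identical bytes; the reader accepts that
subset plus the common standard forms, and round-trip isomorphism (up to
blank renaming) is property-tested. No R RDF library was available in the
target environment, so both ends are implemented here.

`sparql_lite()` is an internal matcher over the named-node projection of the
triple view, not a SPARQL 1.1 engine: basic graph patterns over
`rdfs:subClassOf` (direct), `rdfs:subClassOf*` (reflexive-transitive
closure) and `rdfs:label`, `FILTER regex` (case-sensitive), `COUNT`/`GROUP
BY`, `ORDER BY`, `LIMIT`. Regex label matching is substring-based and relies
on the label convention (leaves: "associated" + "AE"; grouping classes:
"adverse event"); the structural and label-convention counting modes are
required to agree on every compiled KB, and that agreement is
property-tested. Ranking ties break alphabetically by label; AE-frequency
percents are `100 × count / total` rounded half-up to one decimal (half-up
is what reproduces printed values like 54.0 for 34/63).

## The synthetic generator

`generate()` emulates a curated package-insert corpus: by default 63
vaccines drawing 3–20 AEs from an 87-term vocabulary, age groups drawn from
the 0/18/65 breakpoint schemes, and occurrences from per-category Beta
distributions — child Beta(2.4, 3.6) (mean 0.40), adult and senior
Beta(1.8, 4.2) (mean 0.30), child-adult Beta(2.1, 3.9) (mean 0.35). The
sources give no distributional model, only the qualitative observation that
child occurrences run higher than adult ones; the defaults plant that shift
at δ = 0.1, a magnitude a pharmacoepidemiologist would call a visible but
not extreme difference. Ground truth is recomputed from the emitted record
strings, so truth and records agree exactly by construction, and the test
suite closes the loop generate → compile → classify → query for many seeds.

What the generator does **not** emulate: correlated AE profiles across
related vaccines, severity grading, reporting heterogeneity between
manufacturers, and realistic occurrence text precision. A green pipeline
test therefore establishes bookkeeping correctness of the engine, not
epidemiological realism of any particular dataset.

Bundled fixtures transcribe published structure (AE lists, ids, printed
count tables) and flag every value that is not legible from published text
as synthetic; `inst/extdata/README.md` is the provenance ledger. The printed
statistics table the `"table1"` fixture reproduces is internally
inconsistent in its property columns (they do not sum to their printed
totals); only the self-consistent class column (total 1189) is treated as
checkable. Likewise one printed frequency percent (40.7 for 25/63) is
arithmetically impossible and is excluded from the checked set.

## Numerical and degenerate-input choices

* decimals serialize via a fixed non-scientific 15-significant-digit
  rendering; literals keep their lexical form through read/write cycles.
* empty KBs: frequency and maximum-occurrence queries raise a typed
  `empty_kb` error; the per-vaccine ranking returns an empty table.
* an empty record list compiles to seed terms plus pattern infrastructure.
* all errors are classed conditions (`vaekb_schema`, `vaekb_cycle`,
  `vaekb_overlap`, …) so callers can branch without message matching.

## Known limitations

* The reasoner supports no negation, universal restrictions, cardinality,
  role hierarchies, or datatype reasoning; disjunction is legal only inside
  the population filler.
* The Turtle reader targets the package's own canonical subset plus common
  forms; it is not a conformance-grade parser.
* KB reconstruction from Turtle re-derives associations only for leaves
  whose axioms have the exact pattern shape, and re-derives the VAE location
  from the AE label ("injection-site" substring) since location is not
  axiomatized separately.
* Corpus-wide published counts (e.g. total distinct AE types across all
  licensed vaccines, or the 240/160/177 age-category tallies) depend on the
  full proprietary-curation corpus and are out of scope; the package checks
  them only in the form of planted-ground-truth properties.
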