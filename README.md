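# vaekb — a vaccine adverse-event knowledge-base engine

`vaekb` builds, reasons over, and queries an ontology-based knowledge base of
**vaccine adverse events (VAEs)** — the adverse reactions recorded in the
"Adverse Reactions" sections of licensed-vaccine package inserts. It is aimed
at pharmacovigilance and biomedical-ontology researchers who want
package-insert-style curation rows turned into a formally classified,
queryable OWL-EL knowledge base without any external tooling (no Protégé, no
external reasoner, no triple store).

## The model

Each curated row records one vaccine × adverse event × age group observation.
Rows are merged into associations and compiled through a single **design
pattern**: the vaccine-specific adverse-event class

```
<V>-associated <AE> AE  ⊑  <AE class from the AE ontology>
                        ⊓  'is preceded by'        some ('vaccination with' V)
                        ⊓  'occurs in population'  some ('human vaccinee population'
                               ⊓  ( ('has age in year' ∈ [a₁, b₁]) ⊓ ('has VAE occurrence' value p₁)
                                  ⊔ ('has age in year' ∈ [a₂, b₂]) ⊓ ('has VAE occurrence' value p₂)
                                  ⊔ … ))
```

Occurrence rates attach to a *human vaccinee population* (never to an
individual), age is a plain decimal in years via the shortcut datatype
property `'has age in year'`, and the OR-clause collects the age groups
reported for the same vaccine–AE pair. Every generated class follows the
label convention *leaf labels contain "associated" and end in "AE"; grouping
labels contain "adverse event"*, which is what the regex-based counting
queries rely on.

On top of the compiled KB, the package provides:

- a small **EL reasoner** (conjunction + existential restriction +
  definition-style equivalence) that computes the inferred subsumption
  hierarchy — e.g. a pain AE that `'occurs in' some 'injection site'` is
  inferred under a defined `'injection-site adverse event'` class;
- canonical **Turtle (RDF)** serialization with round-trip reading and
  KB reconstruction;
- a **SPARQL-like query subset** (basic graph patterns over
  `rdfs:subClassOf`, `rdfs:subClassOf*`, `rdfs:label`, `FILTER regex`,
  `COUNT`/`GROUP BY`/`ORDER BY`/`LIMIT`);
- the standard analyses: AE-variety ranking per vaccine, AE frequency across
  vaccines (percent, half-up to one decimal), age-stratified occurrence
  summaries with a child-vs-adult comparison, and the global maximum
  occurrence;
- a **synthetic record generator** with exact ground-truth bookkeeping, plus
  bundled mini fixtures (see `inst/extdata/README.md` for provenance).

## Worked example

```r
library(vaekb)

records <- load_fixture("afluria")          # 11 curation rows, 9 AE types
kb <- compile_kb(records, vaekb_seed_terms())
kb
#> <vae_kb> 44 classes, 5 properties, 9 associations, unclassified

count_vae_per_vaccine(kb)
#>             id                         label n_vae
#> 1 OVAE_0000008 Afluria vaccine adverse event     9

max_occurrence(kb)
#>      vaccine vaccine_label          ae               ae_label min max occurrence
#> 1 VO_0004001       Afluria OAE_0000369 injection-site pain AE   5  17        0.6
```

Afluria's nine adverse-event types compile to nine leaf classes under
`Afluria vaccine adverse event`; the highest reported rate in this fixture is
injection-site pain at 60% in the 5–17-year group (occurrences are stored as
fractions, printed tables use percent).

Reasoning over the bundled top-10 AE hierarchy:

```r
kb4 <- load_fixture("figure4")
classify_kb(kb4)
inferred_only_edges(kb4)[, c("child_label", "parent_label")]
#>                 child_label                 parent_label
#> 1    injection-site pain AE injection-site adverse event
#> 2 injection-site redness AE injection-site adverse event
```

Two classes are newly classified under the *defined* class
`'injection-site adverse event'` — they stay asserted under their phenotype
parents (`pain AE`, `redness AE`) because the AE ontology disallows multiple
inheritance, and the reasoner recovers the site-based grouping from their
`'occurs in' some 'injection site'` axioms.

A command-line interface is installed at `inst/scripts/vaekb`
(`validate`, `build`, `classify`, `query`, `sparql`, `simulate`).

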