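Package: vaekb
Title: Vaccine Adverse-Event Knowledge Base Construction, Reasoning and Query
Version: 0.1.0
Authors@R:
    person("VAEKB", "Maintainers", email = "vaekb@example.org", role = c("aut", "cre"))
Description: Compiles curated package-insert-style vaccine adverse-event (VAE)
    records into an OWL-EL ontology knowledge base built around a fixed design
    pattern linking a vaccine, an adverse-event class, a human vaccinee
    population, age intervals in years, and occurrence rates. Provides a small
    EL subsumption reasoner to compute the inferred class hierarchy, canonical
    Turtle (RDF) serialization with round-trip reading, a SPARQL-like query
    subset, and ranking, frequency, and age-stratified occurrence analyses over
    the knowledge base. Ships transcribed mini term tables and a synthetic
    record generator with known ground truth so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
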