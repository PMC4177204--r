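# Bundled fixtures — provenance

All files are small plain-text CSVs. "Transcribed" below means copied from the
published summary tables of the vaccine-adverse-event knowledge base these
fixtures emulate; "synthetic" means invented here because the underlying value
is not legible from published text (figure screenshots, unpublished curation
rows) — synthetic values are stable but carry no real-world meaning.

- `seed_terms.csv` — mini adverse-event / vaccine class hierarchy.
  Transcribed: the ten top-reported AE labels and their OAE ids
  (OAE_0000369, OAE_0000377, OAE_0000361, OAE_0001139, OAE_0001546,
  OAE_0001105, OAE_0000390, OAE_0000644, OAE_0000375, OAE_0000034).
  Synthetic: the intermediate grouping ids (pain AE, skin AE, ...), the
  `OAE_0002xxx` / `OAE_09xxxxx` ids, the `injection site` UBERON-style id, and
  the exact parent placement of fever / local swelling.
- `afluria.csv` — the nine Afluria AE types with injection-site pain split
  over three age groups. AE list and ids transcribed; the vaccine VO id, the
  age-group bounds and every occurrence percentage are synthetic.
- `typhim_vi.csv` — the 97.5% injection-site tenderness occurrence at ages
  18–40 is transcribed; everything else (ids, other rows) is synthetic.
- `table2_counts.csv` — top-10 vaccines by VAE variety: names, VO ids and
  counts transcribed verbatim.
- `table3_counts.csv` — top-10 most frequently reported VAEs: labels, OAE
  ids, vaccine counts and printed percents transcribed verbatim (the 40.7%
  redness row is a known typo in the source: 25/63 = 39.7%).

`load_fixture("table2")` / `load_fixture("table3")` expand the printed count
tables into deterministic synthetic record rows whose aggregates equal the
printed numbers; `load_fixture("figure4")` builds the asserted top-10 AE
hierarchy in code and adds the definitional axiom for
'injection-site adverse event'.
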