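# dkbuild

Medical knowledge about a single disease is scattered across health web
portals: each portal describes diseases, symptoms, medicines, examinations,
departments and body structures on template-generated pages, under its own
labels and with its own mistakes. `dkbuild` implements the full pipeline for
turning several such portal dumps into one disease-centric knowledge base
(KB), with diabetes as the worked domain:

1. **Extraction.** Per-portal records (navigation rows plus list / table /
   infobox entries) are assigned to KB properties by matching their topic
   sentences against per-relation heuristic word sets, rewritten into
   vertically-partitioned two-column property tables, and materialised as a
   typed RDF-style data graph (class tables become `rdf:type` statements by
   namespace prefixing; relation rows become instance–instance edges when
   the object label resolves, attribute values otherwise).
2. **Fusion.** The per-portal graphs are integrated: conflicting class
   assignments for a shared label (overwhelmingly disease-vs-symptom) are
   cleansed by first consulting a reference disease code list and then a
   majority vote over sources, `argmax_c (1/n) Σ_i 1(c, c_i)`; equivalent
   instances are matched by the standard five-step procedure (features,
   same-class candidate blocking, syntactic + structural similarity,
   weighted aggregation, greedy one-to-one derivation) and matched clusters
   are fused into a unified graph `G_d`.
3. **Topic extraction.** A distance-based EM procedure carves the
   disease-centric subgraph `G_k` out of `G_d`: from seed instances, the
   E-step takes the closed relational neighbourhood of the current centers
   as an induced subgraph, the M-step scores it with eigenvector centrality
   `c(v)` and keeps `c(v) > φ_c` as the next centers; at convergence the
   vertices with `c(v) ≥ φ_d` (defaults `φ_c = φ_d = 0.01`) form the
   topic KB.

It is aimed at researchers in medical knowledge-graph construction who need
the whole chain — typed schema with domain/range/subclass/disjointness
axioms, validation, fusion diagnostics, topic extraction — runnable and
testable offline: a synthetic-corpus generator plants a ground-truth master
KB, noisy multi-portal views (coverage gaps, duplicates, aliases, class
flips) and a reference code list, so every stage can be scored against a
known truth.

## Worked example

```r
library(dkbuild)

corpus <- generate_corpus(corpus_config(seed = 1))  # 8 portals, 1000 instances
res <- run_pipeline(corpus)
res$stats
#>        source instances edges
#> 1    portal01       314  2147
#> 2    portal02       229  2033
#> ...
#> 8    portal08       301  2300
#> 9  Overall KB      1572 12029
#> 10   Topic KB       409  4489

res$trace
#>   t   stage n_centers n_vertices n_edges
#> 1 1 iterate         6        120     383
#> 2 2 iterate       117        475    1580
#> 3 3 iterate       328        741    2320
#> 4 4 iterate       408        837    2602
#> 5 5 iterate       409        838    2606
#> 6 6   final       409       1611    4489

score_recovery(res$topic_kb, corpus$truth, "topic")
#> $precision 0.504  $recall 0.953  $f1 0.659 ...
```

Reading the output: eight noisy portal views re-emit ~1750 instance
descriptions; fusion collapses them to 1572 (duplicate labels merged where
the matcher is confident), and the EM extractor grows from 6 seed labels to
a stable center set in 4 iterations — its size plateaus exactly as more
iterations stop adding vertices. The extracted subgraph recovers 95% of the
planted topic community; precision is lower because, at `φ_d = 0.01`,
background instances with several links into the dense community are
genuinely close to its core. `run_pipeline(corpus, out_dir = "out/")`
additionally writes the fused KB and topic KB as Turtle/N-Triples, the
mapping and cleansing reports as TSV, the iteration trace, and a manifest.

A shell front end with the same functionality lives in `inst/cli/dkb.R`:

```sh
Rscript inst/cli/dkb.R simulate --out corpus/ --seed 1
Rscript inst/cli/dkb.R run --corpus corpus/ --out out/
Rscript inst/cli/dkb.R stats --out out/
```

## Package layout

- `R/schema-graph.R`, `R/data-graph.R` — typed schema/data graph model,
  axiom validation, the default diabetes schema.
- `R/extraction.R` — portal dumps, heuristic lexicon, property tables, D2R
  materialisation.
- `R/fusion.R` — reference code list, voting, class cleansing, instance
  matching, fusing.
- `R/em.R` — eigenvector centrality, E/M steps, topic extraction, traces.
- `R/synthetic.R` — master-KB and portal-view generators, planted-partition
  benchmark, recovery scoring.
- `R/io.R`, `R/pipeline.R` — Turtle/N-Triples/TSV/JSONL readers and
  writers, corpus directories, the end-to-end pipeline.

The methods vignette (`vignettes/dkb-methods.Rmd`) documents the model,
parameter choices and known limitations in detail.
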