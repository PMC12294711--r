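# priorank

Seeded candidate-gene prioritization with functional and network
evidence.

## The problem

Genes downregulated in the aging human heart that are also responsive
to endurance training are natural candidates for mediating the
protective effect of exercise on cardiac aging. Given two such gene
sets — an aging-downregulated set and an exercise-responsive set —
the genes they share are the *candidates* (test set), and the genes
unique to the aging set are the *seeds* (training set). The question
is which candidate is the most plausible effector. `priorank` answers
it by combining two independent lines of evidence and ranking the
candidates by a single integrated score.

The package is generic: any pair of gene sets, any annotation
libraries, any protein–protein interaction (PPI) network in the
supported plain-text formats can be used. A synthetic-data generator
produces complete, fully reproducible benchmark inputs with planted
signal, so the whole pipeline is testable without any downloads.

## The method

1. **Overlap and partition.** Candidates = aging ∩ exercise; seeds =
   aging \ candidates. Jaccard similarities and membership-pattern
   (UpSet) counts summarize the overlap structure.
2. **Over-representation.** For each library term, the hypergeometric
   upper tail *p* = P(X ≥ k) with X ~ Hypergeom(N, K, n), where N is
   the universe size, K the term size, n the query size and k the
   overlap; Benjamini–Hochberg and Bonferroni corrections, ranking by
   −log₁₀ *p*.
3. **Regulator aggregation.** Per evidence source, a one-sided Fisher
   exact test of each regulator's targets against the query, BH
   correction, dense integer ranks; across sources, the MeanRank
   (average rank where testable) and the best scaled rank.
4. **Functional similarity.** A training profile is built per
   annotation category (term frequencies for categorical categories,
   mean vectors for quantitative ones). Candidate similarities (fuzzy
   cosine / Pearson) are converted to empirical p-values by random
   sampling from the universe and combined with Fisher's inverse
   chi-square method:
   S_combined = 1 − P_fisher, with X = −2 Σᵢ ln pᵢ ~ χ²(2n).
5. **Network proximity.** PageRank with priors on the PPI graph,
   PR = (1−d)·prior + d·W·PR with the teleport concentrated on the
   seeds (d = 0.85), plus K-step Markov diffusion and
   degree/betweenness centralities as diagnostics.
6. **Linear integration.**
   FinalScore = α·Gene_scaled + (1−α)·Net_scaled + β·IsTopNet with
   α = β = 0.5, where Gene_scaled and Net_scaled are the min–max
   scaled functional and network scores over the candidates and
   IsTopNet flags the top 5% of network scores. Candidates are ranked
   by descending FinalScore.

## Worked example

```r
library(priorank)

bundle <- generateBundle(syntheticConfig(rngSeed = 42))
dir <- file.path(tempdir(), "bundle42"); writeBundle(bundle, dir)
out <- file.path(tempdir(), "run42")
runPipeline(file.path(dir, "run_config.json"), out)

ranking <- read.delim(file.path(out, "06_integrated.tsv"))
head(ranking, 5)
#>      gene gene_scaled net_scaled is_top_net final_score rank
#> 1 G001098   1.0000000 1.00000000          1   1.5000000    1
#> 2 G000259   1.0000000 0.75575761          1   1.3778788    2
#> 3 G000410   1.0000000 0.66852570          0   0.8342628    3
#> 4 G001177   0.9276972 0.05469986          0   0.4911985    4
#> 5 G001954   0.8601894 0.08992002          0   0.4750547    5

bundle$truth$effectors
#> [1] "G000259" "G001098" "G000410"
```

The default bundle plants three effector genes inside the 37-gene
candidate set (annotated with the training profile's terms and wired
to training genes in the network). Here they occupy the top three
ranks: the winner maximizes both evidence channels and carries the
top-network bonus (0.5·1 + 0.5·1 + 0.5 = 1.5); the third planted gene
matches the training profile perfectly (`gene_scaled` = 1) but misses
the two `is_top_net` slots. Non-planted candidates trail with low
network proximity. Stage tables `01_*`–`06_*` and a JSON run manifest
are written to `out`; re-running with the same config and seed
reproduces them byte-identically.

## Layout

- `R/` — implementation (S4 classes for gene sets, libraries,
  annotation categories and PPI networks; one file per pipeline
  stage).
- `tests/testthat/` — unit, property and end-to-end acceptance tests
  with independent oracles in `helper-oracles.R`.
- `vignettes/prioritizing-effector-genes.Rmd` — the methods vignette:
  model, parameters, design choices, limitations.
- `inst/scripts/run-pipeline.R` — thin command-line wrapper over
  `runPipeline()`.
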