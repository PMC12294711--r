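---
title: "Prioritizing effector genes with functional and network evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing effector genes with functional and network evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(priorank)
```

# Motivation and model

`priorank` ranks candidate genes by how strongly two independent
evidence channels tie them to a phenotype defined through a seed gene
set. The motivating design is exercise-modulated cardiac aging: one
input set holds genes downregulated in older hearts, the other genes
responsive to endurance training. Their intersection — genes the two
conditions move in opposite directions — forms the *candidate* (test)
set; the genes unique to the aging set form the *training* (seed)
set. The hypothesis behind the scoring is that a true effector
resembles the seeds functionally (it participates in the same
biological programs) and sits close to them in the interactome.

The pipeline has six stages, each exposed as an ordinary function and
orchestrated by `runPipeline()`:

1. overlap and training/test partition;
2. hypergeometric over-representation of each input set against
   annotation libraries;
3. regulator (kinase/transcription-factor) enrichment with rank
   aggregation across evidence sources;
4. annotation-based functional scoring of candidates against the
   training profile;
5. seeded network scoring on a protein–protein interaction graph;
6. linear integration into a final ranking.

Stages 2–3 characterize the biology of the inputs; stages 4–6 produce
the ranking. Each stage writes a TSV before the next starts, so any
prefix of the pipeline can be re-run or inspected in isolation.

# The statistical pieces

## Over-representation (stage 2)

For a query of $n$ genes and a term of $K$ genes in a universe of $N$,
the enrichment p-value is the hypergeometric upper tail including the
observed overlap $k$:

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n).$$

It is computed through the survival function (`lower.tail = FALSE`),
not as $1 - \mathrm{CDF}$, so p-values near machine precision keep
their relative accuracy. Benjamini–Hochberg is the correction used
for reporting; Bonferroni is kept as a side column. The universe size
$N$ follows the precedence *explicit argument > library field >
20,000*; the last is a conventional order of magnitude for
protein-coding genomes, used only when nothing better is known (the
synthetic generator always sets $N$ to its universe size instead).
Ties in $p$ are ordered by descending $k$, then term identifier, so
output tables are deterministic.

## Regulator rank aggregation (stage 3)

Each evidence source maps regulators to target sets. Per source, a
one-sided Fisher exact test of the 2×2 table (in query vs not) ×
(target vs not) is computed via its hypergeometric-tail identity, BH
corrected, and regulators get dense integer ranks (ascending p, ties
by symbol). Across sources the *MeanRank* is the average rank over
the sources where the regulator is testable — a regulator absent from
a source contributes nothing to its mean, since an absence reflects
library coverage rather than evidence against the regulator; a fixed
penalty rank is available via `missingPenalty` for the stricter
reading. The *best scaled rank* is the minimum of rank divided by the
number tested in that source. The default Fisher-table universe is
the union of the source's targets and the query: the smallest
universe in which every table is well defined.

## Functional similarity (stage 4)

The training profile stores, per categorical category, the fraction
of training genes annotated with each term, and per quantitative
category the coordinate-wise mean vector. "Fuzzy" similarity of a
candidate to a categorical profile is implemented as the cosine
between the candidate's binary term vector and the frequency-weight
vector; an alternative soft-Jaccard (`method = "jaccard"`) treats the
weights as graded memberships and forms
$\sum \min / \sum \max$. Both are standard parameter-free readings of
fuzzy set similarity; cosine is the default because it discounts
high-frequency terms less aggressively. Quantitative categories use
the Pearson correlation with the profile mean; zero-variance vectors
score 0 with a warning.

Raw similarities are not comparable across categories, so each is
converted to an empirical p-value by sampling $M = 999$ genes from
the universe (training genes excluded — they define the profile) and
applying the add-one estimator

$$p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{M + 1},$$

which is never zero and, for continuous similarity distributions,
uniform on $\{1/(M{+}1), \dots, 1\}$ under the null. Sampling is per
candidate and per category from the session RNG, so a single
`set.seed()` (or the pipeline's `rng_seed`) fixes every p-value.
Categorical similarities are discrete with an atom at zero, so their
empirical p-values are conservative rather than exactly uniform; the
calibration property should be (and in the tests is) checked on a
quantitative category. A candidate unannotated in a category gets
similarity 0 and $p = 1$: keeping the category count constant across
candidates keeps the combined scores comparable. The correction is
applied per category and then combined (rather than correcting the
combined score), which keeps each $p_i$ interpretable and the
combination exact.

Per-category p-values are merged with Fisher's inverse chi-square
method:

$$X = -2 \sum_{i=1}^{n} \ln p_i \sim \chi^2(2n), \qquad
  S_{\text{combined}} = 1 - P_{\text{fisher}},$$

with $P_{\text{fisher}}$ the upper tail at $X$. For $n = 1$,
$S_{\text{combined}} = 1 - p$ exactly, which is a useful sanity
anchor. Fisher's method assumes independent categories; real
annotation sources overlap, so $S_{\text{combined}}$ is a score, not
a calibrated probability — only its ranking is consumed downstream.

## Seeded network scoring (stage 5)

The network score is PageRank with priors: the stationary point of

$$x = (1-d)\,\pi + d\,(W x + m(x)\,\pi)$$

where $W$ is the column-stochastic walk matrix of the undirected
graph (transition probability proportional to edge confidence,
$L(v)$ = weighted degree), $\pi$ the teleport distribution — uniform
over the seed genes by default — and $m(x)$ the probability mass on
dangling (isolated) nodes, which teleport with probability 1. With a
uniform $\pi$ over all nodes this reduces to classical PageRank with
teleport $(1-d)/N$; concentrating $\pi$ on the seeds is what makes
the score measure seed proximity. Defaults: $d = 0.85$ (the
conventional damping), L1 tolerance $10^{-10}$, at most 1,000 power
iterations (non-convergence warns and returns the last iterate;
scores are renormalized to sum to 1 before return).

K-step Markov diffusion applies $W$ for $k = 3$ steps from the
uniform seed distribution and averages the visit mass over steps
$1..k$ — the cumulative variant, chosen over final-step mass because
the average is less sensitive to the parity oscillations of short
walks on near-bipartite subgraphs. Degree and betweenness (igraph,
unweighted, fractional over tied shortest paths) are reported as
diagnostics. The score fed to integration is the PageRank value;
`netScore = "rank_average"` switches to the rank-average of all four
statistics for sensitivity analysis.

## Integration (stage 6)

$$\mathrm{FinalScore} = \alpha\,\mathrm{Gene}_{scaled}
  + (1-\alpha)\,\mathrm{Net}_{scaled} + \beta\,\mathrm{IsTopNet}$$

with $\alpha = 0.5$ (equal channel weighting), $\beta = 0.5$, and
IsTopNet indicating the $\lceil 0.05\,m \rceil$ candidates with the
highest raw network scores among $m$ candidates — the ceiling keeps
the tier non-empty for small panels (for $m = 37$, exactly 2
candidates). Min–max scaling is over the candidate set only: the
formula compares candidates to each other, not to the genome. The
indicator is *added*: the formula is authoritative even though a
hub-gene *penalty* is the other natural reading; `betaSign =
"penalty"` exposes that alternative. With defaults the score lies in
$[0, 1.5]$. All tie-breaks (top-net tier, final ordering) fall back
to descending score then gene symbol, so rankings are deterministic.

# The synthetic benchmark generator

`generateBundle()` produces a complete input bundle under a single
RNG stream seeded by `rngSeed` (no module reseeds mid-stream), so
bundles are bit-reproducible. Defaults encode the study conditions
the pipeline targets: sets of 243 and 634 genes with a forced 37-gene
intersection, 5 annotation categories, 3 planted effectors, 2
regulator sources, and a 1,500-node network. The universe is 2,000
abstract symbols (`G000001`…): large enough that background overlap
is realistic, small enough that a bundle generates in milliseconds;
synthetic symbols avoid any accidental biological claims, and
enrichment uses the synthetic universe size as $N$.

The planted structure, per channel:

* **Annotations.** Each categorical category has 8 profile terms
  (each annotating ~70% of training genes) and 12 decoy terms.
  Planted effectors carry each profile term with probability
  `enrichmentStrength` (0.9); every other gene carries any term with
  probability `backgroundAnnotationRate` (0.1). The quantitative
  category draws a latent profile vector; training genes track it
  with noise, planted effectors track it with probability
  `enrichmentStrength`, background genes with probability
  `backgroundAnnotationRate`, everyone else is independent noise.
  Setting `enrichmentStrength` equal to the background rate therefore
  makes planted and background genes exchangeable — the null
  configuration used in the calibration tests.
* **Regulators.** Each source holds one planted regulator targeting
  60% of the aging set (plus padding) and nine size-matched decoys
  with random targets.
* **Network.** Preferential-attachment growth (3 edges per node)
  gives the heavy-tailed degree distribution of real interactomes.
  The candidate genes are assigned to the newest nodes of the growth
  process, so all candidates enter degree-matched at roughly the
  attachment degree; each planted effector is then wired to 4
  distinct training genes. Seed proximity is thereby the only
  systematic network difference among candidates — a controlled
  experiment for the seeded scoring. This also reflects biology:
  small tissue-specific differential-expression sets essentially
  never contain the interactome's universal hubs, so letting a
  candidate land on a mega-hub would confound hubness with the
  planted signal.

What the generator does **not** emulate: correlated annotation
categories (real GO terms are strongly nested), incomplete and biased
annotation coverage, false-positive interaction edges, study-batch
structure, or any expression-level signal. Passing the recovery tests
therefore shows the pipeline correctly extracts the kind of signal it
assumes, not that real cardiac datasets contain such signal.

# Numerical and design choices

* **Training rule.** With inputs of 243 and 634 genes overlapping in
  37, `training = aging \ intersection` gives the 206-gene seed set;
  `trainingRule = "symmetric_difference"` pools both unique parts
  (803 genes) for the broader reading of "unique to either".
* **Hypergeometric domain.** $k > \min(K, n)$, $K > N$ or $n > N$
  raise errors rather than returning 0/NaN.
* **Empty intersections** stop the pipeline after the overlap stage
  with a diagnostic (there is nothing to rank); identical inputs warn
  (empty training set).
* **Constant score vectors** min–max scale to all zeros with a
  warning — a candidate panel with no score variation carries no
  evidence, and zeros keep FinalScore well defined.
* **Zero p-values** entering Fisher's method are clamped to the
  smallest positive double with a warning (cannot occur via the
  add-one estimator; can occur for user-supplied p-values).
* **Determinism.** Tables are written with fixed formatting and Unix
  newlines; the run manifest records stage order, row counts and
  warnings but no wall-clock times, so re-running a configuration
  reproduces every output file byte-identically.
* **Problem sizes in the test suite.** Module-level property tests
  run on reduced bundles (universe 300, 10 candidates, 150-node
  networks); the end-to-end recovery and calibration checks use the
  full default bundle at 50 (signal) and 200 (null) replicates, and
  the oracle comparisons cover the complete $N \le 20$ hypergeometric
  grid and 100 random graphs of up to 10 nodes. These sizes give the
  binomial/chi-square checks enough resolution while keeping a full
  run of the suite in the minutes range.

# A small end-to-end run

```{r example, eval = FALSE}
bundle <- generateBundle(syntheticConfig(rngSeed = 42))
dir <- file.path(tempdir(), "bundle"); writeBundle(bundle, dir)
out <- file.path(tempdir(), "run")
runPipeline(file.path(dir, "run_config.json"), out)
ranking <- read.delim(file.path(out, "06_integrated.tsv"))
head(ranking)          # planted effectors populate the top ranks
bundle$truth$effectors # the ground truth to compare against
```

# Limitations

* Fisher's combination treats annotation categories as independent;
  with correlated real-world categories $S_{\text{combined}}$ is
  anti-conservative as a probability and must be read as a ranking
  score.
* The empirical p-value resolution is $1/(M+1)$; with the default
  $M = 999$, differences beyond the third decimal are noise.
* PageRank with priors rewards absolute proximity mass, so in real
  interactomes high-degree candidates attract score regardless of
  seed wiring; the `betaSign = "penalty"` switch and the
  rank-average network score are the built-in sensitivity checks.
* Symbol handling is uppercase-and-trim only; identifier mapping and
  cross-species orthology must happen upstream.
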