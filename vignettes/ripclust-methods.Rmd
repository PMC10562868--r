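---
title: "Methods: integrative RIP-seq enrichment, clustering and cohort characterization"
author: "ripclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative RIP-seq enrichment, clustering and cohort characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripclust)
```

# The problem

RNA immunoprecipitation sequencing (RIP-seq) measures which transcripts
co-purify with a tagged RNA-binding factor. A single experiment compares IP
samples against matched total-extract samples from the same cultures; the
quantity of interest per gene is the log2(IP/total) enrichment (LFC). When
many factors — translation initiation factors, decay factors, helicases,
eIF4E-binding proteins — are assayed on the same transcriptome, the
gene × factor matrix of LFCs becomes an *interaction profile* for every
mRNA, and mRNAs can be partitioned into cohorts with shared binding
behavior. `ripclust` implements that integration end to end, together with
the downstream characterization of the cohorts (physical properties, 5'UTR
adenosine composition, codon optimality, gene-set overlaps), and a
synthetic-data generator that plants known cohort structure so every stage
can be validated against ground truth.

# Enrichment model

Counts are modelled as negative binomial with variance
$\mu + \phi\mu^2$. For one factor with $r$ replicate IP/total pairs, the
design is paired: replicate block effects plus a single IP-role
coefficient,
$$\log \mu_{gs} = \log N_s + \beta_{g,\mathrm{rep}(s)} +
\beta_{g,\mathrm{IP}}\,[s \in \mathrm{IP}],$$
where $N_s$ is the effective library size. $\beta_{g,\mathrm{IP}}$ (in
log2 units) is the reported LFC and is tested with a likelihood-ratio test
against the reduced model. The fitting stack is edgeR's GLM machinery
(`glmFit`/`glmLRT`), which is also the lineage of tools used in practice
for this design; the package's own contract is at the calibration level
(null p-values uniform, planted LFCs recovered), not at
coefficient-identity level with any particular release.

Choices that the design leaves open, fixed here:

* **Normalization** — TMM (trimmed mean of M-values, 30% M-trim, 5%
  A-trim) against the column closest to the mean log library size. The
  tests verify the factors against an independent reimplementation of the
  trimmed-mean formula.
* **Dispersion** — common dispersion by adjusted profile likelihood, then
  tagwise moderation toward the common value with `priorDf = 10` (a
  standard moderation strength for triplicate designs); tagwise values are
  clipped to $[0, 10]$. `priorDf = Inf` collapses every gene to the
  common value.
* **Expression floor** — genes with average count below 1 are not tested
  (degenerate fits); they are reported `tested = FALSE` and count as
  non-significant downstream.
* **Test statistic** — likelihood-ratio rather than quasi-likelihood
  F-test; with three replicate pairs the LRT's null calibration is
  verified directly by simulation in the test suite.

One caveat worth stating: a *global* enrichment shared by every gene is
absorbed by library-size normalization — only relative enrichment between
genes is identifiable. The simulation defaults therefore plant centered
profiles, and the LFC-recovery checks use balanced strata.

# Filtering to the analysis universe

A gene enters the universe iff

1. its FDR (Benjamini-Hochberg within factor) is below `fdrMax = 0.01`
   in at least one factor (enriched or depleted), and
2. its raw count is **strictly greater than** `minTotalReads = 20` in
   every total-extract sample of every factor under analysis.

"Greater than 20" is strict: a count of exactly 20 fails. Genes untested
in a factor count as non-significant for clause 1 but remain subject to
clause 2. The output preserves input gene order.

# Integration and clustering

The LFC matrix over the universe takes each factor's estimated
coefficient; genes untestable in one factor receive LFC 0 there (the
neutral "no enrichment" imputation — the integration keeps the complete
gene set rather than dropping rows).

* **Experiment similarity** — Pearson correlation $R$ across universe
  genes; the reported pairwise statistic is $R^2$ and the experiment
  dendrogram uses the dissimilarity $D = 1 - R$ under UPGMA.
* **UPGMA** — implemented directly so that tie-breaks and leaf order are
  deterministic: ties merge the pair with the smallest original indices,
  and each merge places the subtree holding the smaller original index on
  the left. Heights agree with average-linkage `hclust` (verified in the
  tests); cophenetic distances reproduce ultrametric inputs exactly.
* **Gene clustering** — Lloyd's k-means on the raw LFC rows
  (squared-Euclidean), k-means++ initialization, best of `nStarts = 50`
  restarts by within-cluster sum of squares, empty clusters reseeded from
  the farthest point. `k = 7` is the default cohort count; since the
  choice of k is ultimately a judgment call on the heatmap,
  `chooseKDiagnostics()` reports inertia and mean silhouette across a k
  range instead of selecting automatically. Whether rows should be scaled
  is exposed as `scaleRows` (default `FALSE`, raw LFCs).
* **Cluster numbering** — cluster IDs 1..k are relabeled to follow the
  UPGMA leaf order of the centers under correlation distance, so
  "cluster 3" means the same thing across reruns.

k-means and the center dendrogram deliberately use different metrics
(Euclidean on rows; correlation between centers): the partition should
respect magnitude, while the tree relates cluster *shapes*.

# Cohort characterization

Each per-gene property (half-life, ribosome occupancy, SSU positional
ratio, protein fraction, structure score, tAI, UTR adenosine fraction) is
compared per cluster against the **all-gene** distribution — the cluster's
own members included, matching the "vs all mRNA" convention of the
figures this analysis style produces — with a two-sided Mann-Whitney U
test (midranks for ties; exact enumeration when $n_1 n_2 \le 400$ and no
ties, otherwise normal approximation with continuity and tie correction).
Overlap between the cluster and its reference makes the test
conservative, never anticonservative, which the null-calibration tests
confirm. BH correction is applied jointly across all (cluster × property)
tests of a run; significance stars at adjusted 0.05 / 0.01 / 0.001.
Box summaries use linearly interpolated quartiles (position
$1 + (n-1)q$) and the notch $\mathrm{median} \pm 1.58\,\mathrm{IQR}/\sqrt{n}$,
the 95% confidence interval of the median. Protein fractions are
additionally aggregated as a plain per-cluster sum.

Positional adenosine profiles anchor at the start codon: position $-1$ is
the base immediately 5' of the AUG. Only UTRs spanning a position
contribute; the enrichment at a position is the cluster frequency divided
by the all-gene frequency, reported as missing below `minCoverage = 25`
UTRs. The ratio-of-frequencies form and the start-codon anchoring are a
reconstruction (the alternative — cap-anchored or difference-based — is
not used); note that because the reference includes the cluster itself, a
planted composition boost of $p$ against background $b$ in a cluster
holding fraction $f$ of genes appears as enrichment
$p / (f\,p + (1-f)\,b)$, not $p/b$.

# Codon metrics

tAI weights come from tRNA gene copy numbers: for each sense codon,
$W_c = \sum_{\mathrm{pairings}} (1 - s)\,\mathrm{tGCN}(\mathrm{anticodon})$
over the Watson-Crick anticodon and the single wobble anticodon of the
codon's third base (U: I/G, C: G/I, A: U/I, G: C/U; inosine encoded as
genomic A). Relative weights $w_c = W_c / \max W$; codons with no pairing
receive the geometric mean of the nonzero weights. Default penalties
$s$ are the canonical constraint values
(I:U 0, G:U 0.41, G:C 0, I:C 0.28, U:A 0, I:A 0.9999, C:G 0, U:G 0.68),
all configurable. The general four-pairing rule is applied uniformly to
all 61 sense codons; organism-specific anticodon modifications beyond the
inosine convention are out of scope.

The per-gene score — exposed as `tai` and as `classicalTe` — is the
geometric mean of $w$ over the CDS codons excluding the start and stop
codon. Codon usage enters through each gene's own codon composition; no
additional usage weighting is layered on, and the identification of the
"classical TE" with gene tAI is documented here rather than asserted as
an external fact. The score is scale-invariant in tGCN and order-invariant
in the codons, both verified in the tests.

# Set overlaps

Pairwise overlaps use the exact hypergeometric upper tail
$P(X \ge x)$ (via `phyper`; the tests verify it against exhaustive
enumeration of all draws for every universe up to size 12). Three-way
overlaps use Monte-Carlo simulation: every set is redrawn uniformly
without replacement at its observed size (1,000,000 draws by default),
the statistic is the size of the full intersection, and the p-value uses
the add-one estimator $(k+1)/(n+1)$ so it is never zero; the binomial
standard error is reported. Randomizing *all* sets (rather than
conditioning on one observed set) is the implemented null; under
exchangeability the two agree, which the enumerable four-element example
in the tests confirms. Term over-representation applies the same
hypergeometric machinery per (query, term) pair with BH adjustment within
each query set, skipping terms outside [3, 2000] universe genes, and
exports the enrichment ratio $(x/n)/(K/N)$ for dot-plot rendering.

# The synthetic-data generator

The generator emulates the structure of a 12-factor triplicate RIP-seq
compendium at desk scale — the package default is 2000 genes, 12 factors,
3 replicate pairs, 7 planted clusters:

* cluster centers with entries in $\{-2, 0, +2\}$ log2 units (the
  separation parameter), redrawn until rows are distinct and every
  cluster is enriched/depleted with at least a quarter of the factors, so
  each planted cluster is in principle detectable after FDR filtering;
* gene-level Gaussian profile noise (SD 0.3 log2 units) around the
  center — the simplest exchangeable perturbation;
* lognormal baseline abundances (median 200 counts) and NB counts with
  $\phi = 0.1$; $\phi = 0$ degenerates to Poisson, which the moment
  tests exploit;
* annotation with lognormal region lengths (5'UTR median 60 nt, CDS 450,
  3'UTR 120), optional per-cluster adenosine boosts over the whole 5'UTR
  or a window upstream of the start codon, and CDSs sampled from sense
  codons;
* property tables drawn per gene from location-shifted lognormal/normal
  bases, shifts expressed in units of the base scale.

What it does **not** emulate: correlated replicate effects and batch
structure, length- or GC-dependent count biases, shared membership
ambiguity between overlapping complexes, UTR isoform heterogeneity, and
any sequence grammar beyond i.i.d. composition. Passing the recovery
tests therefore demonstrates the pipeline's correctness under its own
model assumptions, not performance on any particular real compendium;
replicate variance components in real data are unknown to the generator
and its defaults are chosen for testability.

# Numerical and reproducibility choices

* All randomness is seeded; `stageSeed()` hashes (global seed, stage
  name) into a 32-bit seed so stages rerun independently yet
  reproducibly, and identical config + seed reproduce identical output
  checksums (recorded in the run manifest).
* k-means determinism comes from running all restarts under one seeded
  stream; restart count trades runtime against the chance of a poor local
  optimum (inertia is non-increasing in restarts).
* Mann-Whitney on fully tied data returns p = 1 (no evidence), and the
  minimum group size for a test is 2 (smaller groups report NA).
* Degenerate inputs are first-class: k = 1 clustering skips the center
  dendrogram but the downstream stages still run; zero-length UTRs are
  excluded from composition; empty universes halt the pipeline with the
  failing stage named.

# Problem sizes

The validation suite runs entirely on synthetic data sized for a desk:
the end-to-end recovery checks use 2000 genes × 12 factors × 3 pairs
(five seeds), calibration and recovery checks 1500–2000 genes with a
single factor, Monte-Carlo checks 10^5 draws on enumerable universes,
and the orchestration checks 150-gene runs. These sizes are the package's
own validation choices; the stages themselves have no built-in scale
limits and the full-scale analysis (thousands of genes, 10^6 draws) uses
the same code paths.

# Known limitations

* Equivalence with any specific GLM implementation is at the
  calibration/recovery level by design; coefficient-level agreement
  across library versions is not a goal.
* A global enrichment common to all genes is unidentifiable (normalization
  absorbs it) — inherent to relative count data.
* The positional-enrichment normalization and the identification of
  classical TE with gene tAI are documented reconstructions, exposed as
  flags/columns rather than hard-coded interpretations.
* The Monte-Carlo overlap loop is plain R; at 10^6 draws over a
  5000-gene universe it takes on the order of a minute, which is accepted
  for the sake of transparency.
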