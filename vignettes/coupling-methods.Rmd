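---
title: "Methods: dissecting gene co-expression coupling with functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting gene co-expression coupling with functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

The package relates two region-pair ("connection") profiles over a brain
parcellation with $R$ regions and $S = R(R-1)/2$ connections:

* **Functional connectivity** $FC_s$: per subject, the (normalized)
  connectivity strength of connection $s$.
* **Correlated gene expression**
  $CGE_{ij} = \frac{1}{N}\sum_a E_{ia} E_{ja}$, the mean product of
  normalized expression values of the $N$ genes in the two end regions.

Their per-connection product, the connectivity–expression coupling
$CEC_s = FC_s \times CGE_s$, averages over connections to the Pearson
correlation between the two profiles; and the contribution of a single gene
$a$ to the coupling at connection $s$ is
$C_{sa} = (FC_s \times CGE_s)\,(E_{ia} E_{ja})$. Stacking $C_{sa}$ over
genes, connections and subjects gives the 3-way coupling tensor on which
all downstream selection operates.

## Normalization conventions

`normalize_expression()` z-scores each gene across regions with the
*population* SD (divisor $R$) and, by default, additionally standardizes
each region's profile across genes, alternating the two constraints until
both hold to $10^{-12}$. Under this convention the mean product form of
$CGE$ *equals* the Pearson correlation of the two regions' expression
profiles, so the two common definitions of regional co-expression
coincide; `method = "zscore"` keeps the literal gene-wise-only z-scoring
for users who prefer it. `normalize_connectivity()` applies an optional
Fisher r-to-z transform followed by a per-subject z-score across
connections (population SD), which likewise turns the mean product in the
global coupling statistic into a correlation coefficient. Whether raw
connectivity was Fisher-transformed before normalization is not an
established convention; it is exposed as the `fisher` flag (synthetic data
is generated directly on a z-like scale, so the flag is off there).
Population-SD scaling is used wherever a mean of products must equal a
correlation; the mean + SD selection thresholds use the sample SD.

# The four-stage procedure

1. **Individual-level screening.** Per subject, each gene's co-expression
   contribution vector $(E_{ia}E_{ja})_s$ is correlated with the subject's
   connectivity profile across all $S$ connections; two-sided p-values come
   from the t distribution with $S-2$ df, thresholded at the
   Bonferroni-corrected level $\alpha/N$. Genes significant in strictly
   more than 80% of subjects form the connectivity-related pool. "More
   than" is read as a strict inequality; both threshold and prevalence are
   configurable.
2. **Coupling tensor and CP decomposition.** The tensor is built over the
   pooled genes (the pool also defines the $CGE$ used in the coupling
   term). Subjects are split into four groups (within acquisition site
   when site labels exist) and each group's tensor is decomposed by a
   semi-nonnegative canonical polyadic model: alternating least squares
   with exact LS updates for the gene and connection modes and
   hierarchical nonnegative least-squares updates for the individual mode.
   Every block update is an exact minimizer, so the relative
   reconstruction error is non-increasing — an invariant the test suite
   asserts on every run. Rank 10, tolerance $10^{-8}$ on the fit change,
   at most 500 iterations and 5 random restarts are the defaults; which
   mode carries the nonnegativity constraint is configurable
   (`constraint_modes`), the individual mode being the natural choice when
   subject loadings act as mixture weights.
3. **Gene and connection selection.** Genes: per group, the leading
   component's gene weights are thresholded at mean + SD of the absolute
   weights; genes selected in all four groups (after sign alignment —
   CP components are sign- and order-indeterminate) form the tensor route.
   Independently, a permutation test shuffles all entries of the
   population-averaged $C_{sa}$ matrix 1000 times and declares a gene
   significant when its observed connection-averaged mean exceeds every
   permuted value ($P < 0.001$); the full entry shuffle is the only
   reading of a joint gene-and-connection relabeling that perturbs row
   means, and a column-preserving variant is available. The reliable set
   is the intersection of the two routes. Connections: the absolute
   population-averaged $CEC_s$ is thresholded at mean + SD, intersected
   with the analogous threshold on the (group-averaged, sign-aligned)
   leading-component connection weights.
4. **Network dissection.** Connections are classified intra-/inter-network
   and homologous from the atlas. Network-shared genes are those whose
   population-averaged $C_{sa}$ shows no difference across the networks'
   intra-network connection groups (one-way ANOVA, $P \ge 0.05$).
   Network-specific genes must pass four criteria in order: (1) mean + SD
   candidacy on the leading component of the tensor restricted to the
   network's intra-network connections; (2) a specificity index —
   target-network mean minus pooled other-network mean of the gene's
   population-averaged $C_{sa}$ — exceeding all 1000 size-preserving
   label permutations; (3) one-way ANOVA across network groups at the
   Bonferroni level $0.05/(\text{number of criterion-2 survivors})$,
   computed dynamically; (4) a first-vs-second network comparison
   requiring a fold ratio of at least 2 between the top two
   connection-averaged means, a positive top mean, a Welch two-sample
   t-test at $P<0.05$, and agreement between the top network and the
   candidate network.

Networks with fewer than two intra-network connections cannot support any
of these within-network statistics, so one usability rule excludes them
uniformly from the ANOVA grouping, the SI pools and the post hoc ranking;
they are still classified and counted. The specificity index adapts the
cell-type specificity idea with the simplest target-vs-rest statistic
consistent with its purpose; a fold-ratio variant of the mean + SD
selection on signed values is available through configuration switches.

# The synthetic benchmark

`generate_dataset()` emulates the study design: one expression matrix
shared by all subjects (expression comes from donor brains, not the imaged
cohort), per-subject connectivity equal to a structural template plus iid
noise, and an atlas with interleaved left/right homolog pairs grouped into
networks. The template is `base_fc` everywhere, plus an intra-network
boost and an additional homologous-pair boost, on a Fisher-z-like scale.

Planted signal is introduced through rank-1 expression factors. The
template matrix is symmetrized and **double-centered**, and the leading
eigenvector of the centered matrix is the global coupling factor: because
every gene column is z-scored across regions, only the centered component
of a factor survives normalization, and the centered leading eigenvector
is precisely the rank-1 pattern whose outer product best tracks the
template after that normalization (the uncentered eigenvector is
near-uniform and vanishes under centering). Each planted coupling gene is
$v\sqrt{w} + e\sqrt{1-w}$ with $w$ = `coupling_effect` and $e$
standardized noise orthogonalized against $v$, making $w$ an exact
variance share. Network-specific genes use the eigenvector of the
centered template restricted to their network's regions, zero-padded.
Background genes are noise plus a weak (`network_coexpression`, default
8% variance) loading on a randomly assigned network's factor: real
transcriptomes show elevated within-network co-expression brain-wide, and
without this floor the coupling term $FC_s \times CGE_s$ has a random sign
on any network not hosting planted genes, leaving the network-level
statistics nothing to measure. The share is far too small for background
genes to reach screening significance.

Two stock configurations are provided, chosen once as the package's
benchmark conditions:

* `synthetic_config()` — 30 regions in networks of sizes (10, 10, 4, 4, 2),
  300 genes (20 coupling genes at effect 0.5, 10 network-specific genes),
  40 subjects, subject noise SD 0.2, intra/homolog boosts 1.2/0.4 over a
  0.2 baseline. Two *equal* dominant networks concentrate the template's
  rank-1 share (the planted factor spans both as a contrast), which is
  what makes a 0.5-variance-share gene detectable per subject at the
  Bonferroni threshold with 435 connections.
* `network_dissection_config()` — 48 regions: one 8-region network
  carrying the global factor, four 6-region host networks (15
  intra-network connections each, enough to power the post hoc t-test)
  for the 10 network-specific genes, and eight 2-region networks. The
  larger atlas is an identifiability requirement: a zero-padded network
  factor concentrates as the region count grows, and only then does the
  planted per-network mass rise above the noise floor of the per-network
  CP decomposition, making criterion-1 candidacy reliable rather than a
  lottery.

The truth record stores the planted gene sets, the template, the
noise-free coupling profile implied by the planted factors, the
connections the mean + SD rule would select on that noise-free profile
(`coupled_connections`), and their homologous subset
(`strong_connections`) as the clearest planted positives.

## What passing the benchmark does and does not show

The generator reproduces the statistical skeleton the method assumes —
planted coupling with an exact variance share, within- vs between-network
connectivity contrast, strong homologous connections, and a brain-wide
co-expression floor. It does not emulate spatial autocorrelation of
expression maps, donor-to-donor expression variability, distance effects
on connectivity, or preprocessing artifacts; recovery results here
therefore speak to the correctness and calibration of the statistics, not
to their robustness against those confounds (the screening explicitly
performs no spatial-autocorrelation correction, mirroring the analysis it
implements).

Three properties of the benchmark are worth knowing when reading test
results:

* With sharp screening and 300 genes the prevalence-filtered pool is
  almost entirely truly-coupled genes. A mean + SD rule applied to a
  homogeneous pool selects few or no items, and the full-shuffle
  permutation null is as extreme as the observations — so the within-pool
  tensor and permutation refinements legitimately return small or empty
  sets at this scale. Their mechanics are validated on constructed
  heterogeneous inputs instead.
* A rank-1 expression factor cannot make a gene's contributions uniform
  across networks, so planted *global* genes are recovered as
  network-shared only partially (roughly 55–75% across seeds); planted
  network-specific genes are essentially never classified shared. This is
  a structural property of rank-1 planting, not a defect of the ANOVA.
* The per-connection $CGE$ noise floor at 300 genes blurs the mean + SD
  cut inside the intra-network plateau, so the full noise-free-selected
  connection set is recovered at about 0.8 sensitivity while its
  homologous core and the complement are recovered nearly perfectly;
  recovery assertions therefore use the graded truth sets.

# Numerical choices and degenerate inputs

* Alternating row/column standardization converges linearly and is capped
  at 200 sweeps; already-normalized input is a fixed point.
* The Fisher transform rejects $|r| \ge 1$; constant gene columns and
  constant weight vectors raise errors or warnings naming the offender;
  constant co-expression product vectors are recorded as non-significant
  with a warning rather than failing a whole screening run.
* ALS linear solves add a ridge of machine-epsilon scale for rank-deficient
  Gram matrices; all-zero tensors are rejected; ties in the leading
  component score warn and resolve to the first in stable order.
* Empirical permutation p-values use the $(k+1)/(n+1)$ convention and can
  never be zero; requesting fewer than 1000 permutations warns that the
  $P < 0.001$ criterion is unattainable.
* Seeds: every stochastic step (group splitting, ALS restarts, both
  permutation nulls, the generator) takes an explicit seed and restores
  the caller's RNG state, so identical seeds give bit-identical results
  end to end.

# Problem sizes

The stock benchmarks run the full pipeline in roughly a minute and the
complete validation suite in a few minutes on a single core: 30–48
regions (435–1128 connections), 300 genes, 40 subjects, rank-10
decompositions with 5 restarts, and 1000-permutation nulls. These sizes
were chosen so that every recovery property is measurable with comfortable
statistical margins while keeping iteration fast; the statistics
themselves are dimension-agnostic and have been exercised up to the
4005-connection atlas used in the structural accounting checks.

# Known limitations

* The coupling statistics inherit the field's assumption that one
  expression matrix represents all subjects; inter-individual expression
  variability is not modeled.
* The permutation null for per-gene means treats the population-averaged
  matrix as exchangeable entries; spatially structured alternatives
  (row/column-preserving shuffles) are provided but not default.
* The specificity index's published antecedent is defined for cell types;
  the adaptation here (target-vs-rest mean difference with a
  size-preserving label permutation) is deliberately the simplest
  consistent statistic, and other variants would give different candidate
  counts.
* Mean + SD thresholds are scale-free but distribution-sensitive; on
  homogeneous inputs they select nothing, which callers should treat as
  information, not error.
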