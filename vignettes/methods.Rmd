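---
title: "Models and methods behind mgstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mgstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgstates)
```

`mgstates` re-implements, as reusable and testable components, the
computational procedures used to characterize the cell states of human
microglia xenografted into mouse models of amyloid pathology: droplet
quality control and hashtag demultiplexing, Wilcoxon marker detection,
gene-set module scoring, cross-dataset cell-state mapping by correlation of
differential-expression log fold changes (with mouse–human ortholog
resolution), per-mouse composition statistics, and a modified Sholl
analysis of marker fluorescence around amyloid plaques. Every stage can be
exercised on synthetic data with planted ground truth, so the package's
claims about its own correctness are backed by recovery experiments rather
than by comparison to an inaccessible cohort. This vignette explains the
models, the defaults, and the choices made where the underlying procedures
were underdetermined.

## The synthetic cohort generator

`simulate_cohort()` emulates a hashed droplet experiment over several mice
and host genotypes:

* **Counts.** Each droplet's UMI counts are negative-binomial with
  per-gene means and a common dispersion, parameterized as mean $\mu$ and
  size $\theta$ with variance $\mu + \mu^2/\theta$ (the standard
  single-cell overdispersion form; default $\theta = 2$). Baseline per-gene
  means are drawn log-uniformly over `baseline_mean_range`
  (default 0.05–5), which reproduces the dynamic range of a shallowly
  sequenced droplet library without fitting any real dataset.
* **Cell states.** Each state owns a disjoint *program* of marker genes
  whose means are multiplied by $2^{\text{effect}}$ in cells of that state
  (default effect 1, i.e. a doubling). Program genes draw their baselines
  from `program_baseline_range` (default 1–5): bona fide cell-state
  markers — CD9, GPNMB, HLA-DRA, CCL3 and the like — are reliably detected
  genes, and a power analysis of the default condition (200 cells per
  state, $\theta = 2$, Bonferroni over 1,000 genes) shows the rank-sum
  test loses essentially all power once a marker's baseline mean falls
  below ~0.5 counts per cell, so planting programs at the detection floor
  would emulate a situation no annotated marker panel is in.
* **Mice.** Per-mouse state proportions are Dirichlet draws around the
  group means with concentration 200, i.e. a ~30% coefficient of variation
  for a 5% state — comparable to the spread of per-mouse points in
  published xenograft composition figures. The default two-group design
  plants a doubling of the DAM, HLA and CRM-1 proportions in the
  amyloid-pathology group.
* **Doublets and hashes.** A configurable fraction of droplets contains
  two independently drawn parent cells (their counts are summed); the
  second parent's mouse is drawn uniformly, so $1/n_\text{mice}$ of
  doublets are same-sample and intrinsically invisible to hash-based
  calling — the achievable hash doublet recall is capped at
  $1 - 1/n_\text{mice}$ (about 83% for six mice), which the recovery
  checks respect. Hash counts are Poisson: `hash_signal_mean` (default
  200) on each parent's own hash, `hash_background_mean` (default 5)
  elsewhere. A small `negative_rate` of droplets receives background on
  every hash, emulating failed staining. Neither rate is an estimate of
  any particular experiment; both are free parameters.
* **Mitochondrial reads.** Each droplet is assigned a Beta-distributed
  target share (default shape (2, 38), mean 5%) which is realized by
  adding a multinomial block of mitochondrial counts; the ground-truth
  table records the share recomputed from the emitted matrix, so count
  conservation is exact.

What the generator deliberately does **not** emulate: ambient RNA, batch
effects between libraries, gene–gene correlation beyond the state
programs, and library-size confounding between states. Passing recovery
tests on this generator therefore demonstrates the correctness of the
implementations under their stated models, not robustness to every
artifact of real droplet data.

## Quality control and demultiplexing

`filter_cells()` applies the hard filters first — fewer than 1,000 reads,
fewer than 100 detected genes, or more than 15% mitochondrial reads, all
with strict boundary semantics (a cell at exactly 1,000 reads or exactly
15.0% survives) — and only then the per-library outlier rule, so dead and
empty droplets cannot distort the library means. The outlier rule removes
cells whose total counts or gene counts lie more than 3 standard
deviations from their library's mean. It is applied **two-sided** by
default: the high tail is the doublet proxy, but a literal reading of the
rule does not restrict it to one side, so an `"upper"` mode is provided
for users who want the one-sided variant. The rule is not idempotent
(removing outliers changes the mean and standard deviation); the hard
filters are.

`demultiplex_hashes()` is a minimal re-specification of pooled-hash
demultiplexing, not a clone of any published implementation: per hash, the
log1p counts are split by 2-means clustering and the positivity threshold
is the midpoint of the two centers (99th percentile of the lower half as a
degenerate-clustering fallback; an all-zero hash is never positive). Cells
positive for exactly one hash are singlets assigned to that sample, for
two or more are doublets, for none are negatives. The algorithm is
validated against planted truth — across 100 default cohorts, singlet
sample assignment is ≥95% accurate and doublet recall approaches its
same-sample ceiling — rather than against the external tool the original
pipeline called.

## Normalization and differential expression

The package normalizes with log1p counts-per-10k. The original pipeline
used a variance-stabilizing regression transform; that choice matters for
re-analysis of the deposited cohort but not for this package's purpose,
where all quantitative claims are made against synthetic data generated
under known effects, and a deterministic, dependency-light transform keeps
every downstream result exactly reproducible. The transform is recorded in
the matrix's `transform` attribute.

`find_markers()` mirrors the original testing protocol: a gene is tested
only if detected in at least 1% of either population and if its fold
change is at least 0.1 on the **natural-log** scale (the convention the
0.1 threshold comes from); fold changes are stored in log2, so the
equivalent cut is $0.1/\ln 2 \approx 0.144$. Group means are computed on
the de-logged scale with a pseudocount of 1, which bounds fold changes for
zero-mean groups. P-values come from the two-sided Wilcoxon rank-sum test
and are Bonferroni-corrected; the default multiplier is the total number
of genes in the matrix (the convention of the tooling the protocol came
from), with the tested-genes variant available as a flag.

`wilcoxon_test()` uses midranks for ties and, in approximate mode, the
normal approximation with tie-corrected variance and continuity
correction. An exact mode enumerates all $\binom{n_a+n_b}{n_a}$ group
assignments and is the automatic choice when $n_a + n_b \le 12$. The two
modes were compared exhaustively on all tie-free arrangements with
$n_a = n_b \le 6$: the maximum absolute p-value gap is 0.088 at $n = 2$,
0.037 at $n = 3$, 0.031 at $n = 4$, and first drops below 0.02 at
$n = 5$. The coarseness at tiny $n$ is intrinsic to the normal
approximation — which is exactly why exact mode is the default there.

## Module scores and state panels

`module_score()` is a binned-control score: genes are ranked by average
expression and cut into 25 equal-frequency bins; each set gene draws 100
control genes (with replacement) from its own bin; the per-cell score is
the mean over set genes minus the mean over pooled controls. Rank-based
binning makes the score invariant to adding a constant to the matrix, and
equal-frequency cuts are robust to the heavy right skew of expression
averages. Control sampling is seeded and the parameters are recorded on
the result. `score_state_panel()` derives one seed per panel from the
*sorted* panel names, so reordering panels permutes columns without
changing any panel's control draw; the optional hard label is the argmax,
with ties broken by panel order.

## Cross-dataset state mapping

Signatures are per-cluster logFC vectors filtered as in the original
figure legend: the reference side keeps genes with $|logFC| \ge 0.25$ and
$P < 0.05$, the query side $P < 0.05$ only. Mouse signatures are converted
to human identifiers with the conservative rules: a mouse gene with
several human orthologs maps to the one with the highest logFC in the
human reference (absent genes rank lowest, residual ties break
alphabetically so the conversion is order-independent); several mouse
genes converging on one human gene are resolved to the highest mouse
logFC. Every decision is recorded in a conversion ledger.

`correlate_signatures()` intersects gene names per (reference, query)
pair — genes present in only one signature are dropped, since zero-filling
manufactures correlation — and requires at least 10 shared genes, below
which a Pearson p-value is too unstable to report; such cells are reported
as missing, not zero. P-values come from the t transform of $r$ on
$n - 2$ degrees of freedom and are Benjamini–Hochberg adjusted across the
whole map (the original legend reports "P-adjusted" without naming the
method; BH matches the per-map star annotations, and Bonferroni is exposed
as a flag). Masking non-positive correlations, as the published heatmaps
do, affects presentation only: $r$, $p$ and the adjusted $p$ are always
retained. `signature_overlap_pct()` reports the directed overlap
percentage together with the Jaccard index, and both directions can be
computed, since the published "20–25%" overlap statement does not fix the
denominator.

## Composition statistics

All between-group tests operate on per-mouse **proportions** (each mouse
is one point, as in the published box plots), never on pooled cell
counts. Two groups are compared with Welch's unequal-variance t-test
(Satterthwaite degrees of freedom, two-sided); three or more with one-way
ANOVA plus Tukey's HSD. Proportions are not transformed by default — the
original methods mention normalizing "if needed" without specifying — and
an arcsine-square-root flag is provided. `embedding_density()` weights
every cell by $1/(n_\text{samples} \times n_\text{cells in its sample})$
so each mouse contributes equal mass to its group's kernel density
(Scott's rule bandwidth per group, a grid extended 3 bandwidths beyond the
data so each group integrates to 1). `bin_pseudotime()` cuts pseudotime
(consumed, not inferred) into 20 equal-width bins, normalizes per sample,
and averages sample curves within groups.

## Radial (modified Sholl) profiling

Plaques are segmented from the plaque channel by Otsu (or absolute)
thresholding and 8-connected component labeling, with sub-pixel centroids
and a minimum-area filter. Around each center, pixel-center distances are
cut into 24 contiguous annuli of width 10/3 µm: the geometry is inferred
from the published near window (0–10 µm, the inner three annuli) and
distant window (70–80 µm, the outer three), which only a 24 × 10/3 µm
layout satisfies; both numbers are configurable. The printed "mm" units in
the legend are treated as a typo for µm, since the distances are
plaque-scale. Pixels are assigned to their **nearest** plaque center only,
so overlapping annuli of neighboring plaques never count a pixel twice,
and image area outside the frame is simply absent. Per channel, annulus
means are z-scored across the whole table (sample standard deviation,
$n-1$); z-scoring within image is available via subsetting before the
call. The near/far comparison pools each replicate's inner three and outer
three annuli and applies an unpaired one-tailed t-test in a
**user-declared** direction, mirroring the marker-specific expectations
(disease-associated markers rise toward plaques, homeostatic markers
fall); replicates are plaques by default in the synthetic checks and mice
(pooling plaques first) when a `mouse` column is present.

`loess_curve()` is the package's own local regression: tricube weights
over the `ceiling(span * n)` nearest points, local polynomial of degree 1,
fit expressed as a linear smoother so pointwise standard errors follow
from the hat values with residual variance on $n - \mathrm{tr}(L)$
degrees of freedom. Local linear fits reproduce exactly linear data to
machine precision, and every fitted value matches an independent per-point
weighted-least-squares computation — that equivalence is asserted in the
tests.

## Numerical conventions and degenerate inputs

* Empty droplets have mitochondrial fraction 0 by convention; empty
  matrices yield empty results, not errors.
* Fully tied Wilcoxon samples give $p = 1$; constant-by-constant Welch
  comparisons give $t = 0, p = 1$ when means agree and $p = 0$ otherwise;
  a constant-response ANOVA gives $F = 0, p = 1$.
* A zero-variance channel z-scores to 0 with a warning; annuli with no
  pixels report a missing mean and zero pixels, and replicates missing a
  near/far window are dropped with a warning.
* All generators are seeded and byte-reproducible; every control draw or
  subsample records its seed.

## Problem sizes used by the checks

The recovery checks run at sizes chosen to make their statistical targets
meaningful on a single CPU: 100 simulated cohorts for demultiplexing
(six mice, 100 droplets each), five cohorts of ~220 cells per state for
marker recovery plus 100 null cohorts of 1,000 genes for the family-wise
error, 100 seeds for state-mapping recovery (300-gene signatures through a
70/10/10/10 ortholog mix), 100 paper-scale composition cohorts
(6 vs 6 mice, ~1,300 cells per mouse), 100 noisy plaque images
(420 × 420 px, 8 plaques) for the near/far test, and 2,000 null draws for
the Welch type-I rate. The same measurements, at the same sizes, are what
`scripts/acceptance.R` recomputes and reports.

## Known limitations

* The log1p CP10K stand-in is not a variance-stabilizing transform; logFC
  magnitudes on deeply sequenced real data will differ from the original
  pipeline's SCT-based values.
* The demultiplexer assumes each hash's log counts are bimodal across the
  pool; a hash whose signal leaks into most droplets (as happened for one
  library in the original study) needs manual thresholds.
* Module-score argmax labeling is a convenience, not a substitute for
  expert curation of cluster identities.
* The image model is 2D with isotropic Gaussian blur and exponential
  radial gradients measured from plaque centers (not edges); plaque
  morphology, z-stacks and deconvolution are out of scope.
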