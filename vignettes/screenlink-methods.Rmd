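---
title: "Models and methods behind screenlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind screenlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(screenlink)
```

# The problem

A single-cell CRISPR screen (CROP-seq, Perturb-seq and relatives) reads out
a pooled perturbation experiment with single-cell RNA-seq: every cell
carries one or more sgRNAs, and its transcriptome is the phenotype. Because
any gene's (or gene signature's) expression can serve as an in-silico
sorting axis — "virtual FACS" — one screen supports an unlimited number of
phenotype read-outs. screenlink implements two complementary statistical
engines that link each perturbation target to such read-outs, together with
the preprocessing, baseline, network and simulation machinery needed to
exercise them end to end.

# The rank-aggregation engine

`rra_test()` ranks all $M$ analyzed cells by the marker's expression and
asks whether the $n$ cells carrying a perturbation concentrate at one end
of the ranking. Rank percentiles $u_i = r_i / M$ of the target cells are
i.i.d. Uniform(0,1) under the null, so the $k$-th smallest of $n$
percentiles follows a Beta($k$, $n+1-k$) distribution;
`order_statistic_pvalues()` evaluates its CDF (equivalently the binomial
tail $P(\mathrm{Binom}(n, u_{(k)}) \ge k)$).

Dropout — a zero count for a gene that is actually expressed — is the
defining nuisance of this data. The two selection directions handle it
asymmetrically:

* **Positive selection** (perturbation raises the marker): the ranking is
  descending, and $\rho = \min(p_1, \dots, p_j)$ where $j$ of the $n$
  target cells have a nonzero raw marker count. A dropout cell cannot carry
  evidence of *high* expression, so only the first $j$ order statistics are
  eligible; $j = 0$ yields $\rho = 1$.
* **Negative selection** (perturbation lowers the marker): the ranking is
  ascending, which places the whole dropout block at the front of the
  list, where it is indistinguishable from true low expression. The $j$
  zero-count target cells are excluded and
  $\rho = \min(p_{j+1}, \dots, p_n)$; $j = n$ yields $\rho = 1$.

The one-ranking-per-direction design is the only reading under which the
two truncation rules are simultaneously coherent: dropouts sit at the
*bottom* of a descending list (hence eligible positions $1..j$) and at the
*front* of an ascending list (hence excluded positions $1..j$).

The fraction $\alpha$ of cells with a nonzero marker count is computed and
reported on every ranking (`cell_ranking$alpha`), but no additional
$\alpha$-based truncation is applied beyond the per-target $j$ rule: the
per-target rule is what the $\rho$ formulas state, and an extra global
threshold would double-count the same exclusion. Ties in expression —
including the zero block — are broken deterministically by barcode
(radix/C-locale order), which matters only for reproducibility: tied zero
cells are excluded from the direction their ties could distort.

Significance is assessed by permutation: whole sgRNA bundles are reassigned
to cells (`permute_identity()`), preserving each cell's multiplicity of
infection (MOI) and each target's cell count, and the observed $\rho$ is
compared with its permutation distribution using the add-one estimator
$p = (1 + \#\{\rho_{perm} \le \rho_{obs}\})/(1 + B)$, whose floor
$1/(B+1)$ avoids zero p-values. The comparison is `<=`, the conservative
choice. Benjamini–Hochberg adjustment runs across targets within one
marker and one direction. The signed **selection score** combines the two
directions: $s = \log p_{neg}$ if $p_{neg} < p_{pos}$, $s = -\log p_{pos}$
if $p_{pos} < p_{neg}$, and $0$ at a tie (natural log; p-values clamped to
the floor).

Cells carrying several targets contribute to every carried target's cell
set; the rank test cannot attribute an effect within a co-occurring group,
so `rra_test()` warns on high-MOI screens and the regression engine is the
recommended tool there (demonstrated by `evaluate_deconvolution()`).

# The regression engine

`lr_test()` models the scaled expression matrix $Y$ ($M$ cells × $N$
genes) as $Y = D S + \epsilon$ with $D$ the binary $M \times K$ cell
identity matrix ($d_{jX} = 1$ iff cell $j$ carries an sgRNA targeting $X$)
and solves the ridge problem in closed form,

$$S = (D^\top D + \lambda I)^{-1} D^\top Y,$$

via a Cholesky factorization of the $K \times K$ system (never an explicit
inverse; a $10^{-10}$ jitter is added only if the factorization fails, and
$\lambda = 0$ demands a full-rank design, with collinear columns reported
by name). The default $\lambda = 0.01$ is a small positive stabilizer, not
a tuning parameter; `ridge_solve()` exposes the solver directly. A row of
$S$ is a perturbation's effect profile across all genes; a column is a
phenotype scan across all perturbations. High-MOI cells put several ones
in a row of $D$, and the regression attributes shared expression variance
among co-occurring targets — this is what makes the engine suitable for
high-MOI screens.

Non-targeting controls enter as an explicit NTC pseudo-target column by
default (`ntc_mode = "column"`), which leaves the closed form untouched; an
alternative mode centers every gene of $Y$ at its mean over NTC-only cells
(`ntc_mode = "center"`). The column default was chosen because it keeps the
estimator a single linear solve and makes the control's own coefficient an
observable null check.

The permutation null shuffles the correspondence between expression rows
and identity rows with one global permutation per round — preserving
within-cell MOI correlation, and incidentally leaving $D^\top D$ (hence the
factorization) unchanged, so each round costs one cross-product and one
triangular solve. Empirical p-values are two-sided on $|s|$ by default
(one-sided tails are available); the published description reports signed
scores without stating sidedness, so two-sided is the conservative
default. Benjamini–Hochberg families are emitted both per target row
across genes (`fdr_gene`, a perturbation's transcriptome scan) and per
gene column across targets (`fdr_target`, a phenotype scan, the family
`query_marker()` reports); which family is appropriate depends on which
question is being asked, so both are kept.

# Preprocessing

Cells with fewer than 500 expressed genes or more than 10% mitochondrial
counts are removed (`qc_filter()`); both inequalities are strict, so
boundary cells are retained. Scaling follows the conventional single-cell
chain — per-cell depth normalization to $10^4$, $\log(1+x)$, per-gene
z-score (`normalize_and_scale()`, each step toggleable) — and the raw
count layer is kept alongside, because the rank engine's dropout flags
must come from true zeros, not from scaled values. Covariate regression
(depth, mitochondrial load) is deliberately approximated by the z-score
step rather than fit as a separate model: the rank engine is invariant to
any per-cell monotone normalization applied uniformly, so the choice only
affects the regression engine, where the z-score already removes the
dominant per-gene location/scale structure. Signature scores
(`signature_score()`) average member-gene z-scores by default — the mean
of standardized expression — with a raw-flavoured normalized-layer mode
available, since published figure legends do not settle which layer
"average expression" used.

# The cluster-enrichment baseline

The conventional alternative to direct association testing clusters cells
first and then tests whether a target's cells are over-represented in a
cluster. `cluster_enrichment()` implements it as stated: per (target,
cluster) pair a 2×2 chi-squared test without continuity correction (Yates
correction available by flag), Benjamini–Hochberg across all pairs, and an
enrichment call requiring both adjusted $p < 0.25$ and the target's cells
exceeding 20% of the cluster. The fraction is read as (target cells in
cluster)/(cluster size); the alternative reading — share of the target's
own cells — is noted but not used. `evaluate_baseline_contrast()` shows
why this baseline is weak: a perturbation that downregulates only its own
gene barely perturbs global expression structure, so clustering never
isolates it, while the rank test finds it directly.

# The simulator

`simulate_screen()` generates screens with known ground truth so every
statistical claim above is testable without external data. Per cell: MOI
is zero-truncated Poisson(`moi_mean`); targets are drawn without
replacement; an efficiency Bernoulli per (cell, target) decides whether
that target's effects apply — modelling incomplete editing; gene means are
baseline × Gamma-distributed per-cell depth factor × applicable
multipliers; counts are negative binomial (`nb_dispersion` = size), and an
extra dropout layer zeroes entries with probability
$\mathrm{logit}^{-1}(c_0 - c_1 \log \mu)$ so dropout is exercised
independently of NB sampling zeros. Knockout efficacy acts on the *mean*
(a generative reading of reduced expression), not by post-hoc count
editing. The `truth` table records exactly which effects were applied in
which cells.

Defaults were fixed once as realistic study conditions: baseline mean 2
UMI/gene, dispersion 10, knockout efficiency 0.8, NTC fraction 0.1, depth
factor Gamma(10, 10) (CV ≈ 0.32; `depth_shape = Inf` disables it for
distributional checks), dropout intercept −1 and slope 1 (≈27% extra
dropout at mean 1, ≈7% at mean 5). What the simulator deliberately does
not emulate: transcriptome-wide correlation structure, cell-cycle or batch
effects, and guide-level (as opposed to target-level) variability beyond
the efficiency Bernoulli. Passing tests therefore demonstrate correctness
of the statistics under a faithful dropout/MOI/efficacy model, not
robustness to every artefact of real data.

# Evaluation studies and their problem sizes

The `evaluate_*()` family packages the recurring experimental designs:

* `evaluate_false_positives()` — effects-null screens with shuffled labels
  and a 50-gene random marker panel (200 cells, 20 targets, 100 genes, 10
  seeds); the reported quantity is significant pairs per marker run.
  Permutations default to 500 here, enough that the smallest attainable
  BH-adjusted value (20/501 ≈ 0.04) stays below the 0.05 call threshold,
  so the null check has teeth.
* `evaluate_recovery()` — own-gene multiplier 0.3 at 100 cells/target, 20
  seeds, 1000 permutations (the BH floor across 50 genes must clear 0.05).
* `power_sweep()` — detection fraction across baseline target expression
  {0.5, 2, 8, 32} mean UMI (10 reps): power rises with expression because
  both dropout and NB noise shrink relative to the implanted fold change.
* `evaluate_moi_power()` — 150 total cells, 10 targets, own-gene
  multiplier 0.5, MOI 1 vs 4: at fixed cell budget, high MOI multiplies
  carrier cells per target, reproducing the top-rank-fraction gap between
  low- and high-MOI screens (the low-MOI regime sits near 60%, the
  high-MOI regime above 90%).
* `evaluate_deconvolution()` — two targets sharing 160 cells with 20
  unique cells each, strong opposite own-gene effects (×0.1 vs ×6) at
  efficiency 1 (a designed experiment, not a sampled one): the regression
  engine separates them; the rank engine blames both for the
  downregulation. This study runs the regression in NTC-centering mode for
  a structural reason worth recording: with z-scored expression and no
  intercept column, a bimodal gene's nonzero baseline has nowhere to go
  but the design columns, so in column mode the confounded target picks up
  a spurious baseline coefficient on the affected gene. Centering the
  response at the negative-control means absorbs that baseline and the
  confounder's coefficient collapses to zero — the negative controls are
  doing real statistical work here, not just occupying a column. The study
  uses 2000 permutations because the Benjamini–Hochberg family over 30
  genes needs p-value resolution finer than 1/1001 for its second-smallest
  attainable adjusted value to clear 0.05.
* `evaluate_baseline_contrast()` — 20 own-gene targets at 50 cells/target
  against k-means labels (k = 8).

These sizes are the package's chosen desk-scale study conditions; all of
them run in minutes on one CPU, and `scripts/acceptance.R` re-derives
every reported number from them at run time.

# Numerical and design notes

* Permutation streams derive one sub-seed per (analysis seed, round), so a
  fixed seed reproduces results byte-for-byte and engines can share a
  plan; all RNG use is wrapped so the caller's RNG state is untouched.
* Duplicate-cell homogeneity of the ridge solution ($D$ and $Y$ duplicated
  row-wise) is exact only at $\lambda = 0$ — at $\lambda > 0$ doubling
  $D^\top D$ against a fixed $\lambda$ shifts the shrinkage — so the
  package asserts the identity in the least-squares limit.
* Degenerate inputs are errors, not silent repairs: zero-total cells at
  scaling (they should have been removed by QC), empty target cell sets,
  unsorted percentile vectors, markers absent from the gene axis (with
  near-match suggestions), sgRNAs mapping to two targets, all-cells-removed
  QC.
* Zero-variance genes scale to all-zero columns rather than NaN.
* BH adjustment delegates to `stats::p.adjust`; the chi-squared test to
  `stats::chisq.test`; MatrixMarket IO to the Matrix package — the
  package's own code is reserved for the statistics it contributes.

# Known limitations

The rank engine tests one marker at a time and pools all sgRNAs of a
target; guide-level heterogeneity and off-target effects are out of scope.
The regression engine is linear — a perturbation affecting only a small
subpopulation of its cells can be invisible to it while remaining
detectable by rank aggregation. Covariate columns (batch, cell cycle) are
intentionally absent from the design matrix, and no elastic-net or lasso
variants are provided.
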