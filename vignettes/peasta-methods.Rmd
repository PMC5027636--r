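---
title: "Models and methods behind peasta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peasta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peasta)
```

# The measurement problem

Combined PEA/STA experiments quantify protein (by proximity extension
assay, PEA) and RNA (by specific target amplification, STA) in the same
single cell, both read out as qPCR cycle-threshold (Ct) values on a
microfluidic array. Two features dominate the statistics of such data:

* **Bimodality.** A target is either undetected in a cell (no
  amplification, or signal indistinguishable from background) or expressed
  at a level that is roughly log-normal. We describe each target at each
  time point by a *fraction expressing* $\pi$ plus a normal component
  $\mathcal{N}(\mu, \sigma^2)$ on the $\Delta C_t$ scale — the
  "three-parameter model".
* **Background-referenced scale.** Raw Ct is meaningless without a
  reference. RNA is referenced against a fixed ceiling of 24 cycles
  ($\Delta C_t = 24 - C_t$, negatives and non-amplifications set to 0);
  protein is referenced against the per-assay mean background estimated
  from wells in which no cell was captured (Ct first clipped at 24, then
  $\Delta C_t = \overline{C_t}^{bg} - C_t$, clipped at 0). One
  $\Delta C_t$ unit is one qPCR doubling, i.e. a factor of 2 in abundance.

Everything downstream — detection calls, correlations, gating screens,
networks, classification, trajectories — consumes the resulting
nonnegative cells × targets `DeltaCtTable`, in which 0 encodes
"undetected". For protein targets 0 can also mean "at or below
background"; the two cannot be distinguished after clipping, which is why
detection for protein is judged against a positive threshold rather than
against 0.

# Backgrounds, detection and limits of detection

Zero-cell wells give, per protein assay, a background mean and standard
deviation (`estimate_protein_background()`). Pooling those wells across
time points is justified by all-pairwise Welch t-tests
(`check_background_homogeneity()`, verdict `"pool"` at $\alpha = 0.05$);
when any pair fails, per-time-point backgrounds should be used instead.
Degenerate zero-variance groups are handled explicitly (identical means
give $p = 1$, separated means $p = 0$).

After normalization the background sits at $\Delta C_t = 0$, so under a
one-sided normal background model a value is a *detection* at confidence
$\alpha$ when

$$\Delta C_t > z_{1-\alpha} \cdot \widehat{\sigma}_{bg},$$

the default $\alpha = 0.01$ ( `detection_threshold()` /
`call_detection()` ). The comparison is strict: a value exactly at the
threshold is not detected, which makes the zero-threshold RNA case
("detected $\iff \Delta C_t > 0$") a special case of the same rule.

The limit of detection of a dilution series is the smallest quantity at
which at least 7 of 8 replicates are detected; with a different replicate
count $n$ the rule scales to $\lceil 7n/8 \rceil$.

# Calibration on dilution standard curves

Dilution plates (lysate or recombinant-protein ladders, referenced to
lysis-buffer wells) calibrate each assay. Replicate-mean $\Delta C_t$ is
regressed on $\log_2(\text{quantity})$ over **every contiguous window of
at least three levels**, and the selected window maximizes

$$R^2 - 0.03 \times (\text{levels removed}),$$

ties broken toward the longer window, then the earlier start
(`select_linear_range()`). Windows of fewer than three levels are
disallowed because $R^2$ is degenerate at two points; a window with
zero response variance is assigned $R^2 = 0$. The search is exhaustive by
construction, and the test suite checks it against an independently coded
brute-force oracle on random series. We deliberately do **not** automate
the manual extending/shortening of ranges that a human operator might
perform; instead `select_linear_range(..., override = c(lo, hi))` accepts
an explicit, auditable per-target window override.

A probe is **reliable** (`classify_probe_reliability()`) when

1. its selected window spans the single-cell quantity (default 1.3 cell
   equivalents),
2. the mean signal at the level nearest that quantity is detected,
3. the window fit is a genuine positive linear response: slope at least
   `min_slope` (default 0.2 cycles per doubling) **and** window
   $R^2 \geq$ `min_r2` (default 0.8).

The two floors in (3) matter: a constantly saturated assay is flat, and
the sign of a slope fitted to flat noise is a coin flip, while a lucky
three-level window of noise can even reach a high $R^2$ with a
near-zero slope. A slope below 0.2 cycles per doubling means the assay
changes by less than $2^{0.2} \approx 15\%$ per doubling of input — not
usable for quantification. Failure modes are reported as `NO_SIGNAL` (no
level detected), `SATURATED` (at least half the levels above threshold
but no usable positive linear response), or
`RANGE_EXCLUDES_SINGLE_CELL`.

# Correlation statistics

Paired RNA–protein association uses Spearman's $\rho$ per gene per time
point, **including zeros**: undetected cells are data, and dropping them
would silently change $n$ per gene. A `detected_only` flag exists for
sensitivity analysis. Changes in correlation between time points are
tested by mixing the time-point labels of the pooled cells (10,000
permutations by default, group sizes preserved), summarizing the null
$\Delta\rho$ by its mean and SD, and taking the two-sided normal tail of
the observed $\Delta\rho$. Two-sided is the conservative choice where
sidedness is not inherent to the question. Degenerate nulls (SD 0) return
$p = 1$ at the null mean and 0 elsewhere, flagged. Distribution-level
comparisons of the per-gene $\rho$ sets use a Lilliefors normality check
plus pairwise t (means) and F (variances) tests.

Q–Q comparison curves pair empirical quantiles at probabilities
$(i - 0.5)/n$; some convention had to be fixed and this one is symmetric
in the tails.

# Differential expression and in-silico gating

Because only a minority of target distributions pass a $\chi^2$
goodness-of-fit against either the two-parameter normal or the
three-parameter model, differential analysis uses two nonparametric
tests per target:

* **Fisher's exact test** on detected/undetected counts, run only when
  the total number of undetected cells across both groups exceeds 10;
* **Mann–Whitney U** on the detected values only, run only when the
  total number of detected cells across both groups exceeds 10.

"Exceeds ten for the two populations" is read as the *sum* across both
groups (the more inclusive reading); a per-group variant would only
shrink the eligible set. The in-silico gating screen
(`in_silico_gate_all()`) makes every target a gate in turn, splits the
retained cells by its detection, applies both tests to every other
target, and runs one Benjamini–Hochberg correction per gate's experiment
(Fisher and MWU p-values pooled, since they are one experiment's
hypothesis family). Directions come from the detected-proportion
difference (Fisher) and the median difference (MWU).

The $\chi^2$ goodness-of-fit uses equal-probability bins with expected
counts of at least 5 and $k - 1 - 2$ degrees of freedom; with fewer than
20 observations no valid binning exists and the statistic is reported as
`NA`. The three-parameter fit estimates $\pi$ as the detected fraction
and fits $\mu, \sigma$ by maximum likelihood on the detected values
conditional on that cut — "fraction expressing" is a threshold concept,
not a latent mixture, so EM would answer a different question.

# Correlation networks

The edge threshold is calibrated from permutation nulls: per target pair,
one margin's cell labels are mixed (10,000 times by default) and the
Spearman null's mean and variance recorded. The threshold at tail
probability $\alpha$ is $\text{mean} + z_{1-\alpha}\sqrt{\text{var}}$;
with null mean 0.005, variance 0.015 and $\alpha = 0.01$ this gives 0.29,
and correlations **strictly greater than** 0.3 are edges. Networks grow
from a seed set: edges run from non-seed targets to seed members only (no
transitive growth), matching a seed-circuit reading of the analysis;
edge degree is the number of such edges per target. Correlations are
recomputed on the time-point-restricted cells.

Circuit-level cell clustering scales each circuit target to a maximum of
1, correlates cells against cells (Spearman, for consistency with the
rest of the package; Pearson by flag), clusters with average linkage on
$1 - \rho$, cuts at $k = 2$, and tests cluster membership against gate
detection and against time point with Fisher's exact test.

# Classification and trajectories

PCA standardizes every target (z-score) first, so high-variance assays do
not dominate, and fixes component signs by making the largest-magnitude
loading positive. The random-forest evaluation draws the training set
*with replacement* to four-fifths of the cells and tests on the cells
never drawn — taking the resampling wording literally, which makes the
test-set size random; realized sizes are recorded, and a deterministic
stratified split is available by flag. Per-class one-vs-rest ROC curves
and trapezoidal AUCs (via pROC) summarize performance. Forest size
defaults to 500 trees.

Trajectory analysis bins each cell, per gene, into four joint-detection
quadrants (P−R−, P−R+, P+R+, P+R−) at the $\alpha = 0.01$ detection
cutoff. RNA has no zero-cell background, so RNA detection defaults to
$\Delta C_t > 0$ unless a threshold is supplied. Gene profiles are the
quadrant fractions per time point, concatenated time-ascending in the
fixed quadrant order; genes are clustered by average linkage on
$1 - \rho_{\text{Spearman}}$ between profile vectors and partitioned at
cut height 0.75. A constant profile has no rank ordering to correlate and
becomes a singleton cluster, with a warning.

# The synthetic-data generator

`generate_single_cell_study()` emulates the measurement structure with
known ground truth. Per cell and gene a latent bivariate standard normal
with correlation `pair_rho` couples the RNA and protein margins (a
Gaussian copula). Each margin is detected when its latent value lies in
the upper $\pi$ tail; the detected quantile maps through the
truncated-normal inverse CDF to a $\Delta C_t$ in $(0, 24]$, so margins
are exactly $\pi$-thinned truncated normals while detection and level
co-vary the way bimodal single-cell data do. $\Delta C_t$ is generated
first and Ct back-derived (RNA: $24 - \Delta C_t$; protein:
$\mu_{bg} - \Delta C_t$) because the analysis operates on $\Delta C_t$
and truth should live on the analysis scale; truncation, rather than
resampling, matches the clipping the normalization applies anyway.
Zero-cell wells draw protein Ct from
$\mathcal{N}(\mu_{bg}, \sigma_{bg})$.

`generate_dilution_series()` produces replicate ladders that are linear
in $\log_2(\text{quantity})$ inside a stated window, flat at background
below the window's smallest quantity, and — with `hook = TRUE` —
declining above its largest (the PEA hook effect, where excess antigen
splits probe pairs onto separate molecules).

What the generator does **not** emulate: plate spatial effects,
PCR-efficiency kinetics, melt curves, splice isoforms, or heavy-tailed
background contamination. Tests passing on this generator therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to every artifact of real plates.

Default study conditions used by the test suite and the acceptance
script: three time points with tens of cells each (87/71/70-scale where
the full design matters), 5/17/13 zero-cell wells, protein background
$\mathcal{N}(20, 0.4^2)$ Ct, expressing components around
$\Delta C_t \approx 4$–8 with SD 1.5–2, latent coupling 0.3–0.5, and
dilution ladders spanning 0.08–10.63 cell equivalents at 8 replicates.
Simulation sizes in tests (e.g. 2000 cells for recovery properties, 200
seeds for window recovery, 50 seeds for permuted-label AUC) were chosen
so Monte-Carlo error sits well inside the asserted bounds.

# Numerical and degenerate-input conventions

* Undetected raw Ct is `NA` internally — never the 999 sentinel — so a
  sentinel can never leak into a mean; 999/"Undetermined"/empty cells are
  mapped on read and 999 is written on export.
* Strict inequalities at thresholds throughout (detection, network
  edges).
* Constant vectors: Spearman returns `NA` with a `degenerate` attribute;
  PCA excludes zero-variance targets with a warning; all-zero circuit
  targets are dropped; exact-test p-values of $1 + 2\epsilon$ from
  floating point are clamped before BH.
* All stochastic steps (generator, permutations, bootstrap, forest) take
  explicit seeds and record them in their outputs; the pipeline manifest
  snapshots the full configuration and input digests.

# Known limitations

* The protein $\Delta C_t = 0$ ambiguity (undetected vs at-background) is
  inherited from the normalization and is why culling counts RNA only.
* The cell-culling rule counts $\Delta C_t > 0$ over reliable RNA
  targets, the literal "expressed" reading; a probabilistic-call variant
  would need RNA backgrounds that the assay design does not provide.
* BH-adjusted values are reported per gate experiment; no across-gate
  correction is attempted.
* Goodness-of-fit pass rates depend on the binning convention; they are
  reported but should not be compared across packages using different
  bin rules.
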