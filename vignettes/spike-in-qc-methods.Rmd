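---
title: "Methods: composite QC of ERCC spike-in pools under a modified Latin square design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite QC of ERCC spike-in pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeqc)
```

# The design and what it buys

External RNA controls (the ERCC catalog, ERCC-00001..00176) are synthetic
transcripts spiked into a sample at known concentrations so that an
expression platform can be audited against ground truth. `spikeqc`
implements a composite testing scheme built on a *modified Latin square*
mixture design: the controls are split into five subpools A–E, each
subpool internally spanning a $2^{20}$ ladder of relative abundance, and
the subpools are mixed by volume into four pools (12–15). Subpools B–E
rotate through mixing proportions 10/15/25/40 % in a Latin square; subpool
A is pinned at 10 % in every pool (the "modification"), providing a 1-to-1
component. Three performance characteristics fall out of one experiment of
four samples:

* **dose response** of each control across its four abundances;
* **signal response across the dynamic range**, pooled over controls;
* **ratio detection** between pool pairs, whose titrated fold changes are
  known exactly: 40/10 = 4, 40/15 = 2.7, 40/25 = 1.6, 25/10 = 2.5,
  25/15 = 1.7, 15/10 = 1.5 (and reciprocals), plus 1 from subpool A.

Ratios are stored exact and rounded only for reporting (one decimal), so
40/15 prints as 2.7 without accumulating rounding into the analysis.

The packaged design table pairs each control with its subpool and ladder
abundance. The published rendering of that table is typographically
ambiguous about the ladders; the reconstruction shipped here places each
subpool's 19 SRM-2374 controls on the ladder $\{2^0..2^{16}, 2^{18},
2^{20}\}$ and the one non-SRM control (ERCC-00114) at $2^{17}$ in subpool
A — the unique pairing consistent with the per-control log2 target
abundances printed alongside the outlier census. `inst/extdata/PROVENANCE.txt`
records the reasoning. Validation of all structural invariants (Latin
square closure, ladder span, one omitted control, seven antisense
controls) runs at load time, before any analysis.

# Platform models

**Hybridization arrays.** Probe signal saturates with analyte
concentration following a Langmuir isotherm,

$$ I \;=\; \frac{I_{max}\, C}{K_d + C} \;+\; bg, $$

with $I_{max}$ the saturation intensity, $K_d$ the dissociation constant
(the concentration at half-saturation, in relative-abundance units), and
$bg$ an additive background. $I_{max}$ and $bg$ are not free parameters:
they are anchored experimentally — $I_{max}$ from the mean linear-scale
signal of the most abundant control in each of the four pools, $bg$ from
ERCC-00073, which is deliberately omitted from every pool so its probe
reports pure background. Only $K_d$ is fit, by minimizing squared
residuals of log2 signal against the log2 of the model prediction over
per-control *centroids* (the average log2 abundance and average log2
signal over the four pools). Fitting in log2 space weights the $2^{20}$
range evenly; fitting centroids rather than all points follows the
mid-point convention of the design. Anchor averaging is done in linear
intensity space because the model is linear-scale.

Two consequences of centroid fitting are worth knowing. First, the
centroid ordinate is a mean of log2 signals over four different
abundances, which is not the log2 signal at the mean abundance wherever
the curve bends (Jensen's inequality); even noise-free simulated data
therefore leave a small residual at the ends of the range (about 0.03 log2
units under the default geometry), which is part of the model's honest
misfit, not an optimizer failure. Second, the $I_{max}$ anchor estimates
$I_{max}+bg$ at finite abundance; at the default geometry the top rung
sits at $420\,K_d$, so the bias is a fraction of a percent and is absorbed
by the $K_d$ fit.

**RNA-Seq.** Counting is linear in concentration — no saturation — so the
model is a line of slope 1 in log2–log2 space with a fitted intercept.
The least-squares intercept has the closed form
$\widehat{b} = \overline{(\log_2 S - \log_2 C)}$; no iterative optimizer
is involved.

**Outliers.** For either model, a control is a response-curve outlier if
its centroid falls outside the 99 % interval. The interval construction is
not specified beyond its level in the source design, so both are offered:
the default is a prediction-style band, $|r| > t_{0.995,\,n-1}\,
\hat\sigma$, with $\hat\sigma$ the root-mean-square residual at $n-1$
degrees of freedom; a confidence band on the mean curve (narrower by
$\sqrt n$) is available via `band = "confidence"`. With Gaussian
residuals, the prediction band flags about 1 % of null controls, which the
acceptance suite verifies on $n = 10{,}000$.

# Monotonicity, slopes, and the linear region

A titrated control's signal should increase strictly with its mixing
proportion (10 < 15 < 25 < 40 %). Monotonicity is certified by Spearman's
$\rho$ over the four pools: $\rho = 1$ and nothing less. Ties are
conservatively non-monotonic (midranks give $\rho < 1$). With $n = 4$
there is no useful null distribution, so $\rho$ is a screen, not a test,
and no multiplicity correction is applied. The implementation delegates to
`stats::cor(method = "spearman")`; the test suite checks it exhaustively
against the $1 - 6\sum d_i^2 / (n(n^2-1))$ formula over all 24 orderings.
Subpool A is excluded — a constant proportion has no rank order.

The per-control least-squares slope of log2 signal on log2 abundance
(ideal: 1) is compared to the model's *expected slope*, the analytic
derivative

$$ m(C) \;=\; \frac{d\,\log_2 I}{d\,\log_2 C}
   \;=\; \frac{C}{I}\cdot\frac{I_{max} K_d}{(K_d + C)^2}, $$

which rises from 0 (background-dominated), peaks below 1, and falls back
to 0 (saturation). The two inflection points of $m(\log_2 C)$ demarcate
the **linear region**. They are located as sign changes of the second
difference on a 0.01-step grid over the design ladder extended one decade
each side, refined to 0.001 near each change — cheap, reproducible, and
directly checkable against a brute-force dense grid (the tests do
exactly that). With $bg = 0$ the low side has no inflection and the
region is reported undefined rather than invented.

Flagging combines the two screens by platform: on arrays, a non-monotonic
control is an outlier only if it lies inside the linear region; below the
lower bound it merely marks the detection floor and is listed separately
(`sub_range`). On RNA-Seq every non-monotonic control is flagged. A
control's position is judged by its centroid by default
(`region_rule = "centroid"`); judging by any of its four abundances is a
configuration away, since the source convention is not stated.

**Mis-assignment diagnosis.** A control whose signal contradicts its
subpool label — the canonical fingerprint being the lowest-proportion pool
giving the highest signal with the rest increasing, $\rho = -0.2$ — may
have been prepared into the wrong subpool. `best_fit_subpool()` re-scores
the control under each candidate subpool's proportions (its $\rho$, and
its summed squared residuals against the platform fit) and suggests the
assignment maximizing $\rho$, ties broken by residual sum; an all-tie
(e.g. flat signal) returns the original label with a tie flag. The
packaged design records the one known case (ERCC-00113, labeled E,
consistent with C) in a `reassigned_subpool` column; analyses honor it by
default, and `honor_reassignment = FALSE` re-opens the diagnosis. Note
that under the packaged square, a control truly prepared in C but labeled
E scores $\rho = -0.6$; the $-0.2$ fingerprint is the worked example the
screen is calibrated on, and real data decide the value.

# Ratio analysis

For any pool pair, each control contributes a Bland–Altman point:
$M = \log_2 S_i - \log_2 S_j$, $A = (\log_2 S_i + \log_2 S_j)/2$. The MA
convention (mean of logs) is the default; the literal Bland–Altman
abscissa (log of the linear mean) is available with `ma = FALSE`. From the
fitted Langmuir model, the *expected* ratio curve for a nominal fold $f$
is traced parametrically, $M(C) = \log_2 I(fC) - \log_2 I(C)$: it
approaches 0 at both extremes — additive background enters both signals at
the bottom, saturation equalizes them at the top — and reaches $\log_2 f$
only in the interior. This is ratio compression, and the curve never
exceeds $\log_2 f$. For RNA-Seq the expected curve is the constant
$\log_2 f$; the low-count scatter is Poisson shot noise, whose SD of $M$
shrinks as $1/\sqrt{\lambda}$ (about $\sqrt 2 / (\ln 2\,\sqrt\lambda)$ by
the delta method), verified empirically in the tests.
`ratio_recovery_summary()` reports median $M$ and median $|M - \log_2 f|$
per fold, split inside/outside the linear region.

# Dynamic-range coverage

Per sample, the minimum and maximum log2 signal over detected controls;
reported as mean ± SD over the four samples, with range = max − min and
the range SD combined in quadrature,
$\sqrt{sd_{min}^2 + sd_{max}^2}$. The quadrature rule is adopted because
it reproduces the published coverage arithmetic (13.88 ± 0.11 over
5.72 ± 0.07 gives 8.16 ± 0.13 exactly; the companion background row lands
within a rounding step of its printed value, consistent with the inputs
themselves being printed at two decimals). Whether per-sample minima
exclude partially detected controls is not stated at the source;
per-sample detected-only is used. An endogenous-background subset can be
summarized by passing its own signal table.

# The synthetic-data generator

The generator exists so every stage is testable without platform data; it
is first-class, tested code with fixed defaults that define the study
conditions:

* **Arrays** (`array_sim_config()`): $K_d = 10^4$, $I_{max} = 2^{14}$,
  $bg = 2^5$, Gaussian noise of 0.1 on log2 signal (multiplicative ~7 %
  intensity noise — the visible spread of single-channel dose-response
  panels), spike fraction 0.3 % wt/wt as metadata. These place the ladder
  across background, linear, and saturated regimes the way a real bead
  array sees it: roughly the top quarter of the $2^{20}$ range in
  compression. ERCC-00073 and the seven antisense controls (which cannot
  hybridize sense-strand probes) report background-level signal, so the
  exclusion logic is exercised.
* **RNA-Seq** (`rnaseq_sim_config()`): expected counts proportional to
  depth × abundance × transcript length, Poisson-sampled, reported as
  RPKM with the 0.01 reporting floor treated as missing on read. The
  normalizer is pool-independent (the mean total over pools): pools are
  spiked at a constant mass fraction, so per-pool renormalization would
  distort the very ratios the design fixes. Transcript lengths default to
  a deterministic synthetic assignment (250–2000 nt, a hash of the
  control number); they are synthetic, not the catalog lengths. Default
  depth $10^7$; at $10^5$ the ladder bottom drops out, exercising the
  partial/undetected flags.
* **Anomalies** (`anomaly_spec()`): subpool mis-assignments (the default
  injects the ERCC-00113 pattern: labeled E, truly C), forced dropouts,
  and per-control log2 offsets mimicking mixing errors. Simulated truth
  uses the *original* labels — a recorded reassignment is a diagnosis
  made by the analysis, not part of the truth — so the default dataset
  tells the complete story: flagged under nominal labels, clean after
  reassignment.

What the generator does **not** emulate: probe-sequence-specific
affinities, array spatial artifacts, GC or positional coverage bias,
non-uniform read distributions along transcripts, library-preparation
biases such as poly-A enrichment, and competition with an endogenous
background transcriptome. Passing tests therefore demonstrate that the
*pipeline* is correct under its stated statistical assumptions, not that
any real platform meets them.

# Numerical choices and problem sizes

* $K_d$ search: golden-section over $\log_{10} K_d \in [-2, 8]$ at
  tolerance $10^{-7}$; a solution within $10^{-3}$ of the bracket edge is
  treated as non-convergence and reported with diagnostics. The tests
  compare every fit against a 0.001-step grid search.
* Inflection search: 0.01-step grid, 0.001 refinement, as above.
* Degenerate inputs: $bg = 0$ yields a defined error (no linear region);
  flat signals yield $\rho =$ NA and a tie-flagged diagnosis; subpool-A
  controls have undefined slope by construction; a pool with no detected
  controls is an anchoring error.
* Determinism: simulators restore the caller's RNG state and are fully
  determined by their seed; assessment reruns are byte-identical.
* Test problem sizes: the full 97-control design everywhere; 100 seeds
  for $K_d$ recovery and swap diagnosis; $10^4$ null controls for flag
  calibration; depth $10^7$ (and $10^5$ for dropout behavior) in
  sequencing simulations. These sizes give the stochastic checks
  comfortable margins at a few minutes of total runtime.

# Worked run

```{r, eval = FALSE}
design <- load_design()
tab <- simulate_microarray(design, array_sim_config(seed = 7))
res <- run_assessment(assessment_config("array", tab,
                                        honor_reassignment = FALSE))
print(res)
res$diagnoses[["ERCC-00113"]]$evidence
```

The `analysis/` directory holds the same workflow as numbered scripts
(design export, simulation, array and RNA-Seq assessments, cross-platform
summaries), writing their tables under `results/`.

# Known limitations

* The linear-region rule implements the inflection-point demarcation
  directly; alternative demarcations from the dose-response literature
  (e.g. relative-error bands) are out of scope.
* With only four abundance points per control, $\rho$ and the per-control
  slope are coarse instruments; they are screens for cross-platform
  comparison, not estimators with uncertainty.
* The Langmuir fit assumes one shared $K_d$; probe-specific affinity
  differences show up as residual spread, not as model structure.
* Dynamic-range summaries depend on detection flags at the ladder bottom,
  which in turn depend on the reporting floor chosen upstream.
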