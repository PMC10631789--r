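---
title: "Methods: network segregation and top-down threat bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network segregation and top-down threat bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threatseg)
```

## The scientific question

When a painful stimulus is preceded by a threat cue, some people's pain
reports track the cue more than the stimulus.  That *top-down threat bias*
can be quantified behaviorally: on runs where every stimulus is delivered at
the same maximal temperature, the difference between mean ratings after
low-threat cues and after high-threat cues is attributable to the cue alone.
On the brain side, resting-state functional networks differ between people
in how *segregated* they are — how much stronger within-network coupling is
than between-network coupling.  This package implements the full analysis
chain linking the two: more segregated resting connectomes are hypothesized
to go with stronger (more negative) threat bias, i.e. a reduced capacity to
integrate contradicting sensory evidence with prior expectation.

## The core statistic

For a subject's ROI time-series matrix, functional connectivity is the
zero-lag Pearson correlation between all ROI pairs.  Negative entries and
the diagonal are removed, entries are Fisher z-transformed
(`atanh`), and a proportional threshold retains the fraction `p` of the
strongest edges (grid 0.20–0.50 in steps of 0.05, seven thresholds; there is
no consensus optimal threshold, so consistency across the grid is the
criterion).  Given a parcellation of ROIs into networks, **system
segregation** is

$$SS = \frac{\bar z_w - \bar z_b}{\bar z_w}$$

where $\bar z_w$ is the mean z-weight over all *possible* within-network
pairs and $\bar z_b$ over all possible between-network pairs; edges removed
by thresholding contribute zero.  Dividing by possible-pair counts rather
than surviving counts means that on a binarized matrix the same formula
becomes a connection-count density contrast — this reconciles the two ways
the measure is usually described (mean connectivity vs. connection counts).
$SS \le 1$, with 1 attained exactly when no between-network edge survives;
uniform connectivity gives 0.  Whole-brain SS pools all pairs globally
(well-defined when networks differ in size); per-network SS restricts to
pairs touching one network.  Both are emitted; pooled is primary.

Subject-specific parcellations come from modularity maximization on the
subject's own thresholded matrix:
$$Q = \frac{1}{2m} \sum_{ij} \left(A_{ij} - \frac{k_i k_j}{2m}\right)
\delta(c_i, c_j),$$
optimized by Louvain (local moves + aggregation, resolution 1, best of 20
seeded runs) or Girvan–Newman (iterative removal of the highest-betweenness
edge, weights as inverse distances, returning the dendrogram partition with
maximal $Q$ — the algorithm itself has no stopping rule, so maximum
modularity is the standard selection).  Both the configuration-null and a
general-null $Q$ are available; the configuration null is the default.

## The task model and bias score

The cued pain task has four runs.  In the *matched* run each 10-point rise
in cued threat maps to a 0.4 °C rise over 43.8–47.0 °C
(`matched_temperature()`; the printed range spans eight 0.4° steps while ten
cue deciles exist, so the top deciles clamp at 47.0 — note a span-10 cue
with lower bound ≥ 91 cannot fit in 1–100, so in practice deciles 0–8 are
presented).  The *level-1 mismatched* run pairs cues 1–40 with 45 °C and
cues 60–100 with 47 °C.  The two *level-2 mismatched* runs hold temperature
constant at the 47 °C maximum.  The **threat-bias score** is
mean(ratings | cue 8–32) − mean(ratings | cue 70–98) over level-2 rows at
47 °C; "unknown"-cue trials are excluded.  More negative = more biased.
Cues are stored as range midpoints and bands matched inclusively on the
midpoint.

Bias groups come from 1-D 2-means.  The reported partition is the global
within-cluster sum-of-squares optimum (exhaustive scan over sorted split
points — 1-D clusters are intervals, so this is exact and deterministic);
the more negative centroid is the high-bias group.  Stability is the
fraction of seeded Lloyd restarts (random initialization, equidistant
points re-assigned by coin flip) agreeing with that partition; subjects
below the cutoff (default 0.9) are excluded — the analogue of a cutoff band
around the cluster boundary.  The iteration scheme behind the original
"reclassified after each iteration" exclusion is not a defined quantity for
standard K-means, so no attempt is made to reproduce its exclusion count.

## Quality control

From the six rigid-body parameters, framewise displacement is the sum of
absolute backward differences with rotations converted to arc length on a
50 mm sphere (the common convention; none is prescribed by the source
analyses).  DVARS is the RMS across ROIs of the frame-to-frame difference.
A scan is excluded when max FD > 3 mm or when more than 10% of frames are
DVARS outliers; the outlier rule (above median + 1.5·IQR of the series) is
this package's choice since none is stated.  Note that for very integrated
subjects the DVARS distribution is dominated by one global factor and is
right-skewed, so the 10% rule occasionally trips on clean synthetic data —
visible in the worked README example, and intended behavior of the rule.

## The synthetic cohort: what it emulates

No raw data accompany the empirical analysis, so a generator provides
ground truth:

* **Connectome**: a factor model.  ROI signal = $\sqrt{a}\,F_{net} +
  \sqrt{b}\,G + \sqrt{1-a-b}\,\varepsilon$ with i.i.d. standard-normal
  factors, so population correlations are exactly $a+b$ within and $b$
  between networks; a subject's segregation latent $s \in [0,1]$
  interpolates $r_w$ upward over `within_coupling_range` (default
  0.35–0.70) and $r_b$ downward over `between_coupling_range` (default
  0.05–0.30).  The closed-form covariance is the oracle for the
  connectivity tests.
* **Behavior**: rating $= 100\,[w\,\mathrm{cue}/100 + (1-w)\,g(T)]$ + noise
  clamped to 0–100, with $w$ the bias weight and $g$ linear in temperature
  over 43.8–47 °C.  Noiselessly, the bias score is exactly
  $w\,(\overline{\mathrm{cue}}_{low} - \overline{\mathrm{cue}}_{high})$:
  strictly decreasing in $w$.
* **Coupling**: latents are uniforms from a Gaussian copula.  Planted
  correlations are specified on the latent (uniform) scale and mapped to
  the normal scale by $\rho_N = 2\sin(\pi\rho/6)$.  `brain_behavior_rho`
  is defined against the *bias score*; since the score decreases in $w$,
  the $(s, w)$ pair is generated with correlation $-\rho$.  The
  bias–psychological coupling is induced only through the shared
  segregation latent, keeping the correlation matrix positive definite for
  any inputs.
* **Scans**: task runs shift the effective segregation latent downward by
  `task_integration_shift[scan] * bias_weight` — high-bias subjects
  integrate progressively from rest through Task 2b, planting the
  group-by-scan interaction the rest-to-task analysis looks for.
* **Motion**: small Gaussian jitter (0.02 mm translations, 2·10⁻⁴ rad
  rotations, giving mean FD near 0.1 mm, typical of a compliant adult
  cohort) plus an optional injected spike to exercise the exclusion rule.
* **Defaults**: 39 subjects (the analyzed cohort size), 500 volumes (the
  resting protocol), rating noise 5 NRS points (small relative to the
  ~19-point bias-score spread the generator produces, matching the
  empirical SD of 15.9), planted `brain_behavior_rho` −0.4 (the magnitude
  of the strongest reported threshold).

What the generator does *not* emulate: autocorrelated BOLD spectra,
physiological noise, spatial structure within ROIs, heavy-tailed rating
distributions, or any joint effect-size decomposition between segregation
and the psychological covariates (the knobs are independent, since no such
decomposition is reported).  A green parameter-recovery test therefore
establishes that the estimators are consistent for this stated world — not
that the empirical effect replicates.

## Numerical choices

* Proportional thresholding keeps `round(p·N(N−1)/2)` edges with
  round-half-away-from-zero (banker's rounding would make counts depend on
  IEEE parity), capped by the number of positive edges; ties break by
  ascending node-pair index, so results are deterministic.
* Negative-weight removal precedes thresholding: proportions refer to
  positive edges.
* Weighted analysis is the default; binarization is a flag (the headline
  measure is weighted, but both readings of the thresholding description
  are cheap to expose).
* Fisher z of entries at exactly 1 (duplicated signals) requires explicit
  clipping (`clip = TRUE`, r_max 0.999999) — silent clipping would mask
  data errors.
* Louvain accepts a move only if it improves Q by more than 10⁻¹²;
  the returned q is recomputed exactly from the final partition.
* A partial correlation whose residual is numerically null (variable fully
  explained by covariates) is defined as 0 with p = 1.
* RM-ANOVA uses the classical univariate Error-strata decomposition;
  Greenhouse–Geisser epsilon is computed per within-effect from orthonormal
  effect contrasts (averaging vectors for main effects, Kronecker products
  for the interaction) and reported alongside uncorrected p.  The printed
  degrees of freedom of the source analysis cannot be mapped onto a
  standard design and are not reproduced.
* All randomness flows from one root seed through named substreams
  (stage × subject × scan), so any stage can be re-run independently and
  reruns are byte-identical.

## Known limitations

* Statistical power at the empirical cohort size (n ≈ 39, as the README
  example shows) is modest; the acceptance-grade recovery runs at n = 500.
* The DVARS outlier rule is distribution-dependent (see above).
* Girvan–Newman recomputes betweenness after every removal and is
  O(E²·N log N)-ish; it is intended for ROI-scale graphs, not voxel scale.
* Multiple testing across thresholds and parcellations is reported
  uncorrected, as in the source analysis; an FDR adjustment is left to the
  caller.
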