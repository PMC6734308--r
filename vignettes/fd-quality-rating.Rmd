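---
title: "Quality rating of AFM force-distance curves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality rating of AFM force-distance curves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdrate)
```

## The problem

Atomic force microscopy (AFM) nano-indentation records a force-distance
(FD) curve per measurement: the cantilever force as the probe approaches
and indents a sample. Fitting a contact model to the approach part yields
the apparent Young's modulus *E*, the standard readout of cell and tissue
stiffness. Biological tissue routinely disturbs these curves — partial
tip-sample contact puts a force step at the contact point, slippage causes
sudden spikes during indentation, and poorly attached samples tilt the
approach baseline. Goodness-of-fit statistics do not separate usable from
unusable curves, so experimenters sort them by eye, which does not scale
to FD maps with thousands of pixels. `fdrate` automates that sorting: it
fits every curve, extracts quality-dependent features from the fit
residuals, and uses supervised regression against subjective 0 (poor) to
10 (good) ratings to predict the quality of unseen curves.

## Contact models

For a rigid sphere of radius $R$ indenting an elastic half-space to depth
$\delta$, the exact force is parametric in the contact radius $a$:

$$F = \frac{E}{1-\nu^2}\left(\frac{R^2+a^2}{2}
      \ln\frac{R+a}{R-a} - aR\right),
  \qquad
  \delta = \frac{a}{2}\ln\frac{R+a}{R-a}.$$

`sneddon_exact()` inverts the depth relation by bisection on
$a/R \in [0,1)$ (relative tolerance $10^{-12}$; $\delta(a)$ is strictly
increasing and spans $[0,\infty)$, so the bracket always exists). Because
the exact law has no closed form in $\delta$, fitting uses the parabolic
Hertz force $F_p = \tfrac{4}{3}\tfrac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}$
times a truncated power-series correction:

$$\frac{F}{F_p} = 1 - \frac{1}{10}\frac{\delta}{R}
  - \frac{1}{840}\left(\frac{\delta}{R}\right)^2
  + \frac{11}{15120}\left(\frac{\delta}{R}\right)^3
  + \frac{1357}{6652800}\left(\frac{\delta}{R}\right)^4.$$

`series_coefficients()` derives these coefficients from first principles
rather than tabulating them: with $u = a/R$ and $s = u^2$, the depth
relation reads $\delta/R = s\,A(s)$ with $A(s)=\sum_k s^k/(2k+1)$, and the
force ratio is $B(s)/(\tfrac43 A(s)^{3/2})$ with
$B(s)=\sum_{k\ge1}s^{k-1}\bigl(\tfrac{1}{2k+1}+\tfrac{1}{2k-1}\bigr)$.
Reverting $x = sA(s)$ and composing gives the expansion in
$x=\delta/R$. All of this runs in exact reduced-fraction arithmetic (a
small rational power-series toolbox; numerators and denominators stay far
below the $2^{53}$ exact-integer limit of doubles through order 8), so
the four coefficients above come out as exact fractions:

```{r}
series_coefficients(4)
```

A numeric mode estimates the same coefficients independently by a
least-squares polynomial fit to the evaluated ratio
`sneddon_exact()/force_parabolic()` at small $\delta/R$; it is a
cross-check accurate to roughly $10^{-6}$, not a reference. Over the
working range $\delta \le R/2$ the truncated series tracks the exact
force to better than $10^{-6}$ of the maximum force — comfortably inside
the $10^{-4}$ accuracy the approximation is specified to deliver.

Defaults mirror the standard soft-tissue experiment: $R = 18.64$ µm
(polystyrene bead), $\nu = 0.5$ (incompressible), indentation up to
about 2 µm, i.e. $\delta/R \approx 0.1$.

## Preprocessing and fitting

Sign convention: the piezo height decreases toward the sample, and the
tip position $\delta_t = h - F/k$ corrects it for cantilever bending
(spring constant $k$). Post-contact formulas are written in the
indentation depth $d = \delta_c - \delta_t \ge 0$.

Preprocessing has three steps. (1) `compute_tip_position()` applies the
deflection correction exactly. (2) `estimate_baseline()` takes the first
half of the approach part (far from contact by construction) and computes
the mean, standard deviation, and least-squares slope of the force there;
`correct_offset()` subtracts the baseline mean. (3)
`estimate_contact_point()` smooths the force with a centered moving
average (window 15, clipped at the edges) and reports the tip position of
the first point from which the smoothed force stays above
$\text{mean} + 3\,\text{sd}$ for at least 10 consecutive points. A small
relative floor ($10^{-3}$ of the smoothed force range) is added to the
threshold: with exactly zero baseline noise the bare crossing fires half
a smoothing window early, and the floor restores convergence to the true
contact point as noise vanishes. This estimate is deliberately rough —
the fit below treats the contact point as a free parameter — and all of
its constants are exposed as arguments.

`fit_curve()` minimizes the weighted squared residual
$\sum_i w_i (F_i - F_\text{model}(d_i))^2$ over $E$ and $\delta_c$, with
the model force clamped to zero before contact. Because large residuals
concentrate near the contact point without carrying quality information,
the weights follow a linear ramp across the interval
$(\delta_c - 2\,\mu\text{m},\ \delta_c + 2\,\mu\text{m})$ (about
$\pm 10\%$ of $R$): weight 0 at the baseline-side edge, rising linearly
to 1 at the indentation-side edge, and 1 everywhere outside. The force
law is linear in $E$, so $E$ has a closed-form weighted least-squares
solution at fixed $\delta_c$ and is profiled out; $\delta_c$ is then
located on a deterministic 61-point grid spanning $\pm 3$ µm around the
initial estimate (clipped to the data range $\pm 10\%$) and refined by
golden-section search. The optimizer is therefore derivative-free,
deterministic, and cannot end above the initialization objective. Fits
with fewer than ten post-contact points, or all-zero force, report
`converged = FALSE` with a reason instead of raising.

## Quality features

Each fitted curve yields three binary usability flags — contact point
inside the data range, at least 600 combined approach + indentation
points, at most five distinct spikes ("less than 600" excludes 599 and
keeps 600; "more than five" keeps 5 and excludes 6) — and twelve
continuous features. With $r$ the unweighted residuals, IDT the
post-contact points, APR the pre-contact points, BLN the first half of
APR, and $F_{max}$, $d_{max}$ the maximum indentation force and depth:

| feature | definition |
|---|---|
| `spike_area` | $\sum_{\text{spikes}} \lvert r_i\rvert\,\Delta d_i / (F_{max} d_{max})$ |
| `curvature_cp` | $2qR^2/F_{max}$, $q$ the parabola coefficient of $F(d)$ on $\lvert d\rvert \le 1$ µm |
| `flatness_apr` | fraction of positive gradients of smoothed residuals on APR |
| `maxima_idt` | sum of $\max\lvert r\rvert$ over three equal bins of $[0.25\,d_{max}, d_{max}]$, $/F_{max}$ |
| `monotony_idt` | fraction of negative smoothed force gradients on IDT |
| `overall_idt` | mean $\lvert r\rvert$ on IDT $/F_{max}$ |
| `relative_apr` | $N_{APR}/N_{IDT}$ |
| `residuals_cp` | mean $\lvert r\rvert$ on $\lvert d\rvert \le 2$ µm $/F_{max}$ |
| `residuals_75idt` | mean $\lvert r\rvert$ on $d \in [0.25\,d_{max}, d_{max}]$ $/F_{max}$ |
| `residuals_apr` | mean $\lvert r\rvert$ on APR $/F_{max}$ |
| `slope_bln` | least-squares slope on BLN $\times\, d\text{-range(BLN)}/F_{max}$ |
| `variation_bln` | $\lvert$mean force, first 10% of BLN $-$ last 10%$\rvert/F_{max}$ |

Every feature is normalized to be dimensionless, so rescaling force and
model by a common factor changes nothing. A spike is a maximal run of at
least 3 consecutive indentation points deviating from a running median by
more than 5 MADs (plus an absolute floor of $10^{-4} F_{max}$ so that
numerically flat residual series report none). The running-median window
is 25 points: a pulse only registers as deviation while it fills less
than half the window, so the window must exceed twice the widest spike
the detector should resolve (about 12 points here). Before training, a
logarithmic filter compresses the unbounded features
($x \mapsto \ln(1+100x)$, signed features via
$\mathrm{sign}(x)\ln(1+100\lvert x\rvert)$, the size ratio via $\ln x$;
bounded fractions pass through); the constants live in `fd_config()`.

## Rating, classification, evaluation

`assemble_training_set()` drops samples failing any flag or with any
non-computable feature (reporting counts per rule) and attaches
occurrence weights $n/(k\,\cdot\,\text{count(class)})$ over the $k$
rating classes present, so each class carries equal total weight (mean
weight 1). `train_rater()` supports extra trees (the primary scheme),
random forest, gradient boosting, AdaBoost.R2, a single decision tree,
and linear/RBF SVR; the SVR kinds first scale the features and project
them onto linear-discriminant axes of the rating classes, fitted on the
training set only (the SVR backend takes no per-sample weights, so those
two kinds ignore the occurrence weights). Hyper-parameters are fixed
defaults (100 trees, unconstrained depth for the ensembles), exposed
through the `hyper` argument rather than searched. Training rows are
sorted into a canonical order internally, making the fitted rater
invariant to row order at a fixed seed. Predictions are clipped to
$[0, 10]$; curves with non-computable features rate as the sentinel $-1$
so that maps can render them as missing rather than aborting.

`classify_rating()` calls a curve good when its rating exceeds 4.5 — the
midpoint below "just usable" (5); raising the threshold (e.g. to 6)
trades kept curves for a lower false-positive rate. The evaluation
protocols mirror the standard study design: `mse_vs_fraction()` (mean
squared rating error over repeated random train/test splits per training
fraction, default 100 repetitions), `averaged_roc()` (true- vs
false-positive rate, averaged threshold-wise over repeated equal-half
splits — averaging at fixed threshold was chosen over fp-rate-wise
averaging because every repetition evaluates the same grid),
`threshold_scan()` (accuracy and fp rate per candidate threshold), and
`prediction_table()` (rounded prediction-vs-manual tables at nested
training subfractions of a pool, with a fixed 200-sample test split;
rounding is half-away-from-zero). All randomness derives from one seed
through a per-repeat counter, so every figure is reproducible and every
regressor kind sees identical splits.

## The synthetic test bed

Real training data are instrument-bound, so the generator produces the
study conditions in silico. `generate_curve()` ramps the tip position
linearly from 6 µm above to 2 µm below the contact point (1000 points by
default — a 600-point usability filter demands headroom, and real maps
record at comparable depth), evaluates the series-corrected force law,
reconstructs the piezo height as $\delta_t + F/k$ so the deflection
correction round-trips exactly, and injects artifacts: a baseline tilt
proportional to travel, a force step at contact, rectangular spikes of
random sign placed stratified across the indentation (one per equal bin,
so a requested count yields that many distinct spikes), and Gaussian
noise. The default spring constant is 0.5 N/m, chosen so the
reconstructed piezo ramp stays monotone up to the stiffest simulated
tissue (10 kPa) under the package's sign convention.

`ground_truth_rating()` stands in for the human rater: each artifact
contributes a penalty proportional to its magnitude
(`penalty = 16 · spikes·amplitude + 5 · |tilt|/10⁻⁴ + 25 · offset +
5 · noise/0.1`), and the rating is `round(10 − penalty)` clipped to
$[0,10]$. The constants anchor one moderate artifact — 10% noise, a 20%
contact step, a $10^{-4}$ N/m tilt — at the "just usable" rating of 5,
and the rating is monotone non-increasing in every magnitude.
`generate_training_set()` draws artifact inclusion per class (probability
0.65) with log-uniform severities between 0.05 and 8 penalty units plus
an ever-present 0.5% noise floor, and moduli log-uniform between 200 and
5000 Pa: a heterogeneous population that fills all eleven rating classes
from about 500 curves on with no dominant class. `generate_map()` lays
such curves on a grid with per-region stiffness and artifact severity,
emulating stiff and soft tissue regions next to artifact-prone borders.

What passing tests on this test bed do and do not show: the synthetic
ratings are a deterministic function of the injected artifact magnitudes,
and the features were designed to see exactly those artifacts — so
end-to-end results (held-out MSE far below the constant-mean baseline,
binary accuracy above 0.85, maximum-accuracy threshold at 4.5) demonstrate
that the pipeline is wired correctly and that the features carry the
artifact information through fitting, filtering, and regression. They do
not certify performance on real tissue, where rater subjectivity,
viscoelastic drift, adhesion, and setup-specific noise enter; a rater for
real data must be trained on curves from the same protocol and setup.

## Numerical choices and problem sizes

Bisection tolerance $10^{-12}$ on $a/R$; golden-section tolerance 0.1 nm
on the contact point; series truncation order 4 (matching the force law
used for fitting); degenerate inputs (all-zero force, missing
indentation, empty feature regions) flow out as flags, sentinels, or
per-feature computability, never as exceptions from the fit path. The
packaged tests run the study at 1200 generated curves with 20 protocol
repetitions and 100-seed recovery checks, and the unit tests use 300-700
point curves — sizes at which the whole suite completes in a few minutes
on one core while keeping every statistical check comfortably powered.

## Known limitations

Only the approach segment is analyzed; retract-side physics (adhesion,
hysteresis) is out of scope, as are conical/pyramidal tips and
viscoelastic kernels. The TSV dialect and the directory-per-map layout
are the only on-disk formats. The per-feature operational definitions
(region boundaries, normalizations, spike-detector and log-filter
constants) are this package's conventions, exposed in `fd_config()`;
other implementations of the same study design differ in these details,
so trained raters are not interchangeable across implementations.
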