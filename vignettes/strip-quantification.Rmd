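---
title: "Methods: strip densitometry, 4PL calibration and diagnostic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strip densitometry, 4PL calibration and diagnostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfaquant)
```

`lfaquant` turns a photograph of a lateral-flow immunoassay (LFA) strip
into an analyte concentration and a clinical call. This vignette is the
package's account of the science: the signal model, the algorithmic and
numerical choices, what the synthetic data do and do not emulate, and
the known limitations.

## The measurement problem

A competitive-format LFA for a small analyte (here vitamin B12) prints
two transverse reagent lines on a nitrocellulose membrane: a **test
line** of analyte–protein conjugate and, 3 mm downstream, a **control
line** of secondary antibody. Labelled antibody that has *not* been
blocked by analyte from the sample binds the test line, so the
test-line darkness falls monotonically as the sample concentration
rises, while the control line captures label regardless and validates
the run. After silver enhancement the lines photograph as dark bands on
a light membrane. The quantitative readout is the ratio of test- to
control-line signal, **T/C**, which normalises out flow, label load and
exposure.

## Image-to-T/C pipeline

`analyze_strip()` composes six stages; each is exposed as a function so
the chain can be inspected or ablated.

**Smoothing.** A 3×3 Gaussian filter — the binomial kernel
$(1,2,1)^T(1,2,1)/16$, the standard discrete 3×3 Gaussian — is applied
per channel with replicated borders, so constant regions are preserved
exactly. The kernel's variance (0.5 px² per axis) is negligible against
a line's ~8.5 px Gaussian half-width, so line depths are attenuated by
well under 1%.

**Grayscale.** ITU-R BT.601 luma weights (0.299, 0.587, 0.114), rounded
to whole gray levels; single-channel input passes through untouched.
Intensity, not hue, is the working quantity: the hue of a gray
membrane background is undefined, whereas the dark lines are darker
than the background in plain intensity.

**Row-median collapse.** Each image row (perpendicular to flow) is
replaced by its median, yielding one intensity per position along the
flow axis. The median rejects dust specks, strip-edge shadows and other
outliers that a mean would smear into the profile; even-width rows use
the mean-of-middle-two convention. This reduces line detection to 1D
signal processing and suppresses pixel noise by roughly $1/\sqrt{w}$
for strip width $w$.

**Minima detection with hysteresis prominence.** Lines are local minima
of the profile. A minimum counts only if it lies at least `min_depth`
(default **10 gray levels**) below the enclosing baseline on *both*
sides — a one-sided dip on a slope is not a line. The implementation
steps through the profile with a hysteresis band: a turning point
becomes a baseline only once the profile has moved `min_depth` away
from it. We chose this over the naive "nearest enclosing turning
point" reading after observing that the latter is unstable on noisy
data: a noise wiggle of a fraction of a gray level at the flat bottom
of a deep line dip creates micro turning points that formally cap the
prominence at that wiggle's height, masking a 100-gray-level line. With
hysteresis, sub-threshold wiggles neither mask a line nor split it into
duplicate detections, and an exhaustive reach-based enumeration (used
as the test oracle) provably selects the same minima. Plateau minima
report their centre index; equal minima within one valley report the
first.

**Line assignment.** The two deepest detections are kept (ties broken
toward the upstream line; more than two triggers a warning), and the
one nearer the sample-inlet end (row 1) is the test line — the test
reagent is always printed upstream of the control. Fewer than two
detections raises an `lfa_invalid_test` condition, the software
equivalent of "control line absent, test void".

**T/C.** The default is the ratio of **baseline-subtracted depths**.
The raw-minimum ratio (`tc_mode = "raw_min_ratio"`) is retained for
ablation, but it *increases* with concentration and inherits the
background level; depth ratios fall from ~1 toward the bottom
asymptote as concentration rises, matching the calibration convention,
and are exactly invariant to a constant illumination offset (the
offset cancels in both depths).

ROI cropping (`quant_config(roi = )`) optionally restricts the search
window, for photographs that include cassette edges. No automatic strip
localisation, perspective or colour-constancy correction is attempted.

## Calibration

T/C is linked to concentration $x$ by the four-parameter logistic
$$\mathrm{T/C}(x) = d + \frac{a - d}{1 + (x/c)^b},$$
the standard immunoassay form: $a$ is the zero-analyte (top) asymptote,
$d$ the saturation (bottom) asymptote, $c$ the inflection concentration
in pmol/L and $b$ the slope. For a competitive assay $a > d$, $b > 0$
and the curve is strictly decreasing, so it inverts in closed form:
$$x = c\left(\frac{a-d}{t-d} - 1\right)^{1/b}.$$

`fit_4pl()` fits by Levenberg–Marquardt least squares over all
replicates, unweighted (nothing in the assay suggests a variance
model). Initialisation is data-driven — $a_0$/$d_0$ from the extreme
per-level means, $c_0$ the level whose mean is nearest the midpoint,
$b_0 = 1$ — with bounds $a, d \in [0, 2]$, $b \in (0, 20]$,
$c \in (0, 10^5]$, wide enough never to bind for realistic strips.
$R^2$ is computed against the per-level replicate means, the convention
when one $R^2$ is quoted for a replicated dilution series. Calibration
is per strip batch; curves serialise to JSON at 17 significant digits
so a round trip is bit-exact.

The package carries the published reference curve
(`b12_reference_curve()`: $a=0.99$, $b=3$, $c=303.7$, $d=0.3$, fitted
over 0–1107 pmol/L) as the generating truth for all simulations.

**Out-of-range policy.** Readings are clamped and flagged rather than
rejected: $t \ge a$ maps to 0 pmol/L (`below_range`); $t \le d$ maps to
`Inf` (`above_range`); and a finite inversion *above the top
calibrator* is also flagged `above_range`, because beyond the
calibrated span the inverse curve is an extrapolation on the flattening
tail where a small T/C error translates into an unbounded concentration
error. This mirrors clinical practice of reporting such results only
as "greater than" the top calibrator. Flagged rows participate in
classification through their flag (`below_range` → deficient,
`above_range` → not deficient) but are excluded from bias and
correlation, where their magnitude would be meaningless. Without the
top-calibrator rule, a handful of tail subjects dominates the error
variance of a simulated cohort and the Pearson correlation collapses
even though every in-range prediction is accurate.

## Diagnostics

`diagnostic_summary()` reports the method-comparison and classification
statistics conventional for a point-of-care test against a laboratory
reference:

* **median relative bias**, $\mathrm{med}_i\,100\,(p_i - r_i)/r_i$ —
  median, not mean, because inversion noise is heavy-tailed;
* **Pearson correlation** with its t-transform p-value (a signed $r$
  with p-value is the conventional report; Spearman is available);
* **sensitivity/specificity** at the clinical vitamin-B12 cut-offs
  150, 221, 258 and 332 pmol/L, with *deficient = strictly below* the
  cut-off (equality is not deficient);
* the **ROC staircase** over every distinct predicted value, with
  deficiency as the positive class and "predicted < threshold" as the
  decision rule; the trapezoidal AUC equals the Mann–Whitney
  concordance (asserted against both a brute-force oracle and `pROC`
  in the tests).

## What the synthetic data emulate

`render_strip()` draws a light background (default gray level 200),
two dark transverse lines and additive zero-mean Gaussian pixel noise,
clipped to [0, 255]. Geometry follows the physical strip: 1 mm nominal
line width, 3 mm centre-to-centre separation, a 25 mm membrane at the
default 20 px/mm (a phone-camera macro scale), strip width 4 mm
(80 px). Line cross-sections are *Gaussian* dips with FWHM equal to
the nominal width — dispensed reagent diffuses, so real profiles have
one smooth minimum, not a rectangular trough — truncated at 2.5 FWHM
where the tail is below $10^{-7}$ of the depth. Default depths are 120
gray levels (control) and 60 (test, i.e. T/C 0.5): silver-enhanced
lines are high-contrast, and a control of 120 keeps even a T/C of 0.1
test line (12 gray levels) above the 10-level detection threshold.
Default pixel noise is 5 gray levels; an optional linear illumination
ramp along the flow axis and an RGB mode with reddish-brown line tint
exercise baseline robustness and the grayscale path. All renders are
seeded and bit-reproducible.

`generate_cohort()` draws reference concentrations log-uniformly over
100–1100 pmol/L — spanning the deficient and sufficient ranges around
the clinical cut-offs — and simulates each subject's measured T/C from
the reference curve with multiplicative Gaussian noise of the stated
analytic CV (default 10%, consistent with the published per-level CVs
of ~6–17%).

Deliberately **not** modelled: optics (lens blur, vignetting, LED
geometry), binding kinetics and silver-amplification chemistry (both
enter only implicitly through the calibration curve), strip
localisation in a larger photograph, membrane texture, and inter-batch
drift. Passing tests on synthetic strips therefore validate the signal
processing and statistics, not the chemistry: on real photographs the
dominant unmodelled errors are geometric (strip not axis-aligned) and
photometric (colour casts), both out of scope.

## Problem sizes and numerical conventions

The test suite and the reproduction script use sizes chosen to make
Monte-Carlo checks stable at interactive runtimes: 200 simulated
calibration batches (7 levels × 3 replicates, T/C noise sd 0.01) for
parameter-recovery medians; 1000 random profiles for the
detector/oracle equivalence property; 100 seeded renders at pixel-noise
sd 5 for measurement-error bounds; cohorts of n = 200 at 10% CV for the
end-to-end bands. Fixed conventions: even-count medians average the
middle two; the 3×3 filter replicates borders; plateau minima report
their centre index, ties in depth resolve to the upstream line; all
seeds are explicit function arguments and generators restore the
caller's RNG state.

## Known limitations

* Single-analyte, two-line strips only; no multiplexed panels.
* The hysteresis detector reports one minimum per significant valley;
  two lines closer than the hysteresis band at their shared saddle
  would merge (physically, lines 3 mm apart with 1 mm widths are far
  from this regime).
* 4PL only — no 5PL asymmetry, no spline calibration, no inter-batch
  harmonisation.
* Above-range results carry no magnitude; cohorts dominated by
  saturating concentrations yield few usable pairs for bias and
  correlation.
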