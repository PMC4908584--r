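# lfaquant

Quantitative read-out for lateral-flow immunoassay (LFA) strips, built
around the smartphone-based vitamin-B12 test workflow: strip image in,
analyte concentration and clinical call out.

Rapid LFA strips are usually read by eye as present/absent lines. For a
*competitive* assay of a small analyte such as vitamin B12, the test-line
signal **decreases** continuously as analyte concentration rises, so the
strip carries quantitative information — if the line darkness can be
measured reliably and mapped through a calibration curve. `lfaquant`
implements that chain:

1. **Densitometry** (`analyze_strip()`). The strip photograph (flow axis
   vertical, row 1 = sample inlet) is smoothed with the 3×3 discrete
   Gaussian (binomial 1-2-1 kernel), converted to grayscale, and
   collapsed to a 1D intensity profile by taking the **median across
   each row**. The test and control lines appear as local minima of the
   profile; a minimum is accepted when it lies at least 10 gray levels
   below the last significant turning point on both sides (hysteresis
   prominence). The two deepest detections are assigned by flow order
   (test line upstream, control downstream) and the readout is the
   baseline-subtracted depth ratio `T/C`.
2. **Calibration** (`fit_4pl()`, `invert_4pl()`). T/C is linked to
   concentration by the four-parameter logistic

   ```
   T/C = d + (a − d) / (1 + ([B12]/c)^b)
   ```

   with top asymptote `a`, slope `b`, inflection `c` (pmol/L) and
   bottom asymptote `d`, fitted per strip batch by Levenberg–Marquardt
   least squares and inverted analytically for prediction. The
   published reference curve (`b12_reference_curve()`: a = 0.99, b = 3,
   c = 303.7, d = 0.3) is built in as a simulation ground truth.
   Readings outside `(d, a)` or beyond the top calibrator are clamped
   and range-flagged rather than rejected.
3. **Diagnostics** (`diagnostic_summary()`). Median relative bias,
   Pearson correlation, sensitivity/specificity at the clinical
   deficiency cut-offs (150, 221, 258, 332 pmol/L; deficient = strictly
   below), and the ROC staircase with trapezoidal AUC.
4. **Synthetic data** (`render_strip()`, `generate_calibration_set()`,
   `generate_cohort()`). Seeded generators of silver-enhanced-style
   strip images (light background, two dark 1 mm lines 3 mm apart,
   Gaussian cross-sections, pixel noise, optional illumination ramp)
   and of subject cohorts with known ground truth, so the whole
   pipeline is testable without photographs.

## Worked example

```r
library(lfaquant)

# a noiseless synthetic strip with line depths 60 (test) and 120 (control)
r <- render_strip(strip_spec(noise_sd = 0))
a <- analyze_strip(r$image)
a
#> <strip_analysis> T/C = 0.4986 (test row 220 depth 59.4; control row 280 depth 119.2)

invert_4pl(b12_reference_curve(), a$tc)
#> [1] 410.8058
#> attr(,"flag")
#> [1] "ok"
```

The measured T/C of 0.4986 recovers the rendered truth of 0.5 to 0.3%,
and maps through the reference curve to 411 pmol/L — on the curve, a
T/C of 0.5 corresponds to ~410 pmol/L, i.e. a vitamin-B12-sufficient
sample at every standard cut-off.

The one-command demonstration runs the full chain (render a 7-level ×
3-replicate calibration series as images, quantify every strip, fit the
batch curve, simulate a 200-subject cohort at 10% analytic CV, predict
and evaluate):

```r
run_pipeline_demo(seed = 1)
#> fitted 4PL: a=0.9874 b=3.0287 c=303.32 d=0.3031 (R^2 = 1.0000)
#> median bias: -1.77%
#> Pearson r: 0.9245 (p = 8.66e-75)
#> ROC AUC (deficiency < 332 pmol/L): 0.9925
#>   258 pmol/L: sens 0.892 spec 0.983 (tp 74 fp 2 tn 115 fn 9)
#>   332 pmol/L: sens 0.959 spec 0.941 (tp 94 fp 6 tn 96 fn 4)
```

The batch curve fitted from rendered images lands within ~1% of the
generating parameters, and the simulated cohort shows the small median
bias, high correlation and near-perfect deficiency discrimination
expected when the only error source is a 10% T/C measurement CV.

## Command-line use

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lfaquant.R", package = "lfaquant"))')
Rscript $CLI simulate strip --seed 1 --out-dir out/
Rscript $CLI analyze out/strip.png --calib calib.json --json-out result.json
Rscript $CLI calibrate series.csv --batch B1 --out calib.json
Rscript $CLI evaluate cohort.csv --calib calib.json --cutoff 258 --cutoff 332
Rscript $CLI demo --seed 1 --out-dir demo/
```

Exit status 2 flags an invalid test (control line absent); batch
analysis records per-strip failures without aborting.

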