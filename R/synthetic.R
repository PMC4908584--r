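#' Synthetic strip specification
#'
#' Parameters of the synthetic strip renderer. The geometry emulates a
#' silver-enhanced competitive LFA strip: a light background crossed by
#' two dark transverse lines of 1 mm nominal width separated by 3 mm,
#' the upstream line being the test line. Defaults describe a 25 mm
#' nitrocellulose window imaged at 20 px/mm (500 x 80 px for a 4 mm
#' wide strip).
#'
#' Line cross-sections are rendered as Gaussian dips along the flow
#' axis whose full width at half maximum equals the nominal printed
#' line width: dispensed reagent lines diffuse, so a real profile has a
#' single smooth local minimum rather than a rectangular trough.
#'
#' @param height_px image height in pixels (flow axis; row 1 = sample
#'   inlet).
#' @param width_px image width in pixels.
#' @param px_per_mm pixels per millimetre.
#' @param background_level background gray level (0--255; silver-stained
#'   membranes photograph light gray).
#' @param test_line_depth,control_line_depth line darkness in gray
#'   levels below background. The ground-truth T/C ratio is
#'   `test_line_depth / control_line_depth`.
#' @param line_width_mm nominal dispensed line width (FWHM of the
#'   rendered dip), mm.
#' @param line_separation_mm centre-to-centre test/control separation,
#'   mm.
#' @param test_line_position_mm test-line centre, mm from the
#'   sample-inlet (row 1) end.
#' @param noise_sd additive zero-mean Gaussian pixel noise, gray levels.
#' @param illumination_slope linear illumination ramp along the flow
#'   axis, gray levels per row (0 = flat illumination).
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   image.
#' @param color if `TRUE`, render a 3-channel image with reddish-brown
#'   lines (darkening strongest in green/blue) to exercise the
#'   grayscale-conversion path; channel weights are normalised so the
#'   luma-equivalent depth equals the nominal depth.
#' @return A validated `synthetic_strip_spec` (a list).
#' @export
strip_spec <- function(height_px = 500L, width_px = 80L, px_per_mm = 20,
                       background_level = 200, test_line_depth = 60,
                       control_line_depth = 120, line_width_mm = 1,
                       line_separation_mm = 3, test_line_position_mm = 11,
                       noise_sd = 5, illumination_slope = 0,
                       seed = 1L, color = FALSE) {
  spec <- list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    px_per_mm = px_per_mm, background_level = background_level,
    test_line_depth = test_line_depth,
    control_line_depth = control_line_depth,
    line_width_mm = line_width_mm,
    line_separation_mm = line_separation_mm,
    test_line_position_mm = test_line_position_mm,
    noise_sd = noise_sd, illumination_slope = illumination_slope,
    seed = as.integer(seed), color = isTRUE(color)
  )
  validate_strip_spec(spec)
  structure(spec, class = "synthetic_strip_spec")
}

validate_strip_spec <- function(spec) {
  with(spec, {
    if (height_px < 3L || width_px < 3L)
      abort_config("image must be at least 3 x 3 px")
    if (test_line_depth < 0 || control_line_depth < 0)
      abort_config("line depths must be non-negative")
    if (max(test_line_depth, control_line_depth) >= background_level)
      abort_config("line depth must be smaller than the background level")
    if (line_separation_mm * px_per_mm < 2)
      abort_config("lines closer than 2 px cannot be resolved")
    if (noise_sd < 0) abort_config("`noise_sd` must be non-negative")
    centers <- line_centers_px(spec)
    margin <- ceiling(2 * line_width_mm * px_per_mm)  # ~2 FWHM of tail
    if (centers[1] - margin < 1L || centers[2] + margin > height_px)
      abort_config("line geometry places a line outside the image bounds")
  })
  invisible(spec)
}

line_centers_px <- function(spec) {
  test <- as.integer(round(spec$test_line_position_mm * spec$px_per_mm))
  ctrl <- test + as.integer(round(spec$line_separation_mm * spec$px_per_mm))
  c(test = test, control = ctrl)
}

# Reddish-brown line tint: per-channel depth multipliers, normalised so
# the luma-weighted depth equals the nominal (grayscale) depth.
line_tint <- function(weights = c(0.299, 0.587, 0.114)) {
  m <- c(0.60, 1.20, 1.00)
  m / sum(weights * m)
}

#' Render a synthetic strip image
#'
#' Deterministically renders the strip described by a [strip_spec()]:
#' a flat (optionally linearly ramped) background minus one Gaussian dip
#' per line, plus additive Gaussian pixel noise, clipped to \[0, 255\].
#' The same spec and seed always produce a bit-identical image; the
#' caller's RNG state is left untouched.
#'
#' @param spec a [strip_spec()].
#' @return A list with elements `image` (a [strip_image()]) and `truth`
#'   (ground truth: `true_tc_ratio`, `true_test_depth`,
#'   `true_control_depth`, `true_concentration` (`NA` unless set by a
#'   calibration-set generator) and `line_centers_px`).
#' @examples
#' r <- render_strip(strip_spec(noise_sd = 0))
#' r$truth$true_tc_ratio
#' @export
render_strip <- function(spec) {
  validate_strip_spec(spec)
  centers <- line_centers_px(spec)
  fwhm <- spec$line_width_mm * spec$px_per_mm
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  rows <- seq_len(spec$height_px)
  # Gaussian cross-section, truncated at 2.5 FWHM where it is < 1e-7 of
  # the depth: keeps each line's support finite so line centres hit
  # background - depth exactly and the two lines never overlap.
  dip <- function(center, depth) {
    g <- depth * exp(-(rows - center)^2 / (2 * sigma^2))
    g[abs(rows - center) > 2.5 * fwhm] <- 0
    g
  }
  profile <- spec$background_level +
    spec$illumination_slope * (rows - 1) -
    dip(centers["test"], spec$test_line_depth) -
    dip(centers["control"], spec$control_line_depth)

  base <- matrix(profile, nrow = spec$height_px, ncol = spec$width_px)
  px <- withr::with_seed(spec$seed, {
    if (spec$color) {
      tint <- line_tint()
      arr <- array(0, dim = c(spec$height_px, spec$width_px, 3L))
      bg <- spec$background_level +
        spec$illumination_slope * (rows - 1)
      dip <- bg - profile                      # combined line dip, >= 0
      for (ch in 1:3)
        arr[, , ch] <- matrix(bg - tint[ch] * dip,
                              spec$height_px, spec$width_px) +
          matrix(rnorm(spec$height_px * spec$width_px, 0, spec$noise_sd),
                 spec$height_px, spec$width_px)
      arr
    } else {
      base + matrix(rnorm(length(base), 0, spec$noise_sd),
                    nrow = nrow(base))
    }
  })
  px <- pmin(pmax(px, 0), 255)

  truth <- list(
    true_tc_ratio = if (spec$control_line_depth > 0)
      spec$test_line_depth / spec$control_line_depth else NA_real_,
    true_test_depth = spec$test_line_depth,
    true_control_depth = spec$control_line_depth,
    true_concentration = NA_real_,
    line_centers_px = centers
  )
  list(image = strip_image(px, spec$px_per_mm), truth = truth)
}

#' Simulate a calibration dilution series
#'
#' `simulate_tc_series()` draws replicate T/C readings directly from a
#' calibration curve with additive Gaussian noise -- the fast path used
#' for calibration fitting studies. `generate_calibration_set()` goes
#' through the image domain: for each concentration it sets the
#' test-line darkness to `control_depth * eval_4pl(curve, conc)` and
#' renders full strip images with independent noise.
#'
#' @param curve a [calibration_curve()].
#' @param concentrations calibrator concentrations, pmol/L.
#' @param replicates strips per concentration level.
#' @param noise_sd additive Gaussian noise on the T/C scale
#'   (`simulate_tc_series`).
#' @param seed integer seed.
#' @return `simulate_tc_series()`: a data.frame with columns
#'   `concentration`, `replicate`, `tc`.
#' @export
simulate_tc_series <- function(curve, concentrations, replicates = 3L,
                               noise_sd = 0.01, seed = 1L) {
  if (any(concentrations < 0)) abort_input("concentrations must be >= 0")
  out <- data.frame(
    concentration = rep(concentrations, each = replicates),
    replicate = rep(seq_len(replicates), length(concentrations))
  )
  tc_true <- eval_4pl(curve, out$concentration)
  out$tc <- withr::with_seed(seed,
    tc_true + rnorm(nrow(out), 0, noise_sd))
  out
}

#' @rdname simulate_tc_series
#' @param control_depth control-line darkness in gray levels; the
#'   test-line darkness at each concentration is
#'   `control_depth * eval_4pl(curve, conc)`.
#' @param base_spec a [strip_spec()] providing geometry, background and
#'   noise settings; its depths and seed are overridden per render.
#' @return `generate_calibration_set()`: a list of records, each with
#'   `concentration`, `replicate`, `image` and `truth` (with
#'   `true_concentration` filled in).
#' @export
generate_calibration_set <- function(curve, concentrations,
                                     control_depth = 120,
                                     base_spec = strip_spec(),
                                     replicates = 3L, seed = 1L) {
  if (any(concentrations < 0)) abort_input("concentrations must be >= 0")
  tc <- eval_4pl(curve, concentrations)
  if (any(control_depth * tc >= base_spec$background_level))
    abort_config("control_depth * T/C exceeds the background level")
  out <- vector("list", length(concentrations) * replicates)
  k <- 0L
  for (i in seq_along(concentrations)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      spec <- base_spec
      spec$test_line_depth <- control_depth * tc[i]
      spec$control_line_depth <- control_depth
      spec$seed <- as.integer(seed + 1000L * (k - 1L))
      rendered <- render_strip(spec)
      rendered$truth$true_concentration <- concentrations[i]
      out[[k]] <- list(concentration = concentrations[i], replicate = r,
                       image = rendered$image, truth = rendered$truth)
    }
  }
  out
}

#' Simulate a subject cohort
#'
#' Draws reference concentrations from a log-uniform distribution and a
#' measured T/C per subject from the calibration curve with
#' multiplicative Gaussian noise of the stated coefficient of variation
#' (so replicate T/C at a fixed concentration has empirical CV
#' `analytic_cv`). Use [predict_cohort()] to add back-calculated
#' concentrations.
#'
#' @param n number of subjects.
#' @param curve a [calibration_curve()] acting as the true dose-response.
#' @param conc_range reference concentrations are drawn log-uniformly
#'   over this range (pmol/L). The default 100--1100 spans the deficient
#'   and sufficient vitamin-B12 ranges.
#' @param analytic_cv coefficient of variation of the T/C measurement
#'   (fraction, e.g. `0.10`).
#' @param seed integer seed.
#' @return A data.frame (a cohort table) with columns `subject_id`,
#'   `reference_pmol_L`, `tc_true`, `tc_measured`.
#' @export
generate_cohort <- function(n, curve = b12_reference_curve(),
                            conc_range = c(100, 1100),
                            analytic_cv = 0.10, seed = 1L) {
  if (n < 1L) abort_input("`n` must be >= 1")
  if (analytic_cv < 0) abort_input("`analytic_cv` must be >= 0")
  withr::with_seed(seed, {
    ref <- exp(runif(n, log(conc_range[1]), log(conc_range[2])))
    tc_true <- eval_4pl(curve, ref)
    tc_meas <- tc_true * (1 + rnorm(n, 0, analytic_cv))
  })
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    reference_pmol_L = ref,
    tc_true = tc_true,
    tc_measured = tc_meas
  )
}

#' @rdname generate_cohort
#' @param cohort a cohort table from `generate_cohort()` (or any
#'   data.frame with `tc_measured`).
#' @return `predict_cohort()`: the cohort with `predicted_pmol_L` and
#'   `flag` columns appended (see [invert_4pl()] for the range flags).
#' @export
predict_cohort <- function(cohort, curve) {
  pred <- invert_4pl(curve, cohort$tc_measured)
  cohort$predicted_pmol_L <- as.numeric(pred)
  cohort$flag <- attr(pred, "flag")
  cohort
}
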