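#' Four-parameter logistic calibration curve
#'
#' The standard immunoassay dose-response form
#' \deqn{T/C = d + \frac{a - d}{1 + (x/c)^b}}
#' with top asymptote `a` (the T/C ratio at zero analyte), slope
#' exponent `b`, inflection concentration `c` (pmol/L) and bottom
#' asymptote `d`. On a competitive strip `a > d` and `b > 0`, so the
#' curve is strictly decreasing: more analyte means a fainter test
#' line.
#'
#' @param a,b,c,d curve parameters (see Description).
#' @param batch_id strip-batch identifier; calibration is performed per
#'   batch to absorb batch-to-batch variation.
#' @param r_squared coefficient of determination of the fit, computed
#'   against per-level replicate means.
#' @param conc_range concentrations spanned by the calibrators
#'   (pmol/L). Predictions above the top calibrator are flagged
#'   `above_range`: outside the calibrated span the inverse curve is an
#'   extrapolation and results are reported as "greater than" the top
#'   calibrator, as clinical assays do.
#' @return A validated `calibration_curve` object.
#' @export
calibration_curve <- function(a, b, c, d, batch_id = "", r_squared = NA_real_,
                              conc_range = NULL) {
  if (!(a > d)) abort_input("top asymptote `a` must exceed bottom `d`")
  if (!(b > 0)) abort_input("slope exponent `b` must be positive")
  if (!(c > 0)) abort_input("inflection concentration `c` must be positive")
  structure(
    list(a = a, b = b, c = c, d = d, batch_id = as.character(batch_id),
         r_squared = r_squared, conc_range = conc_range),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> batch '%s': a=%.4g b=%.4g c=%.4g d=%.4g (R^2 = %.4g)\n",
    x$batch_id, x$a, x$b, x$c, x$d, x$r_squared))
  invisible(x)
}

#' Published vitamin-B12 reference curve
#'
#' The four-parameter logistic calibration reported for silver-enhanced
#' competitive vitamin-B12 strips: a = 0.99, b = 3, c = 303.7 pmol/L,
#' d = 0.3, fitted over a 0--1107 pmol/L dilution series. Used
#' throughout the package as the generating truth for simulations.
#'
#' @return A [calibration_curve()].
#' @export
b12_reference_curve <- function() {
  calibration_curve(a = 0.99, b = 3, c = 303.7, d = 0.3,
                    batch_id = "b12-reference", r_squared = 0.8776,
                    conc_range = c(0, 1107))
}

#' Evaluate a 4PL curve
#'
#' @param curve a [calibration_curve()].
#' @param concentration concentration(s), pmol/L, `>= 0`. At zero the
#'   curve returns the top asymptote `a` exactly.
#' @return T/C ratio(s).
#' @export
eval_4pl <- function(curve, concentration) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(concentration < 0)) abort_input("concentration must be >= 0")
  curve$d + (curve$a - curve$d) / (1 + (concentration / curve$c)^curve$b)
}

#' Invert a 4PL curve (concentration from T/C)
#'
#' Analytic inverse \eqn{x = c ((a-d)/(t-d) - 1)^{1/b}} for T/C values
#' strictly inside `(d, a)`. Out-of-range readings are clamped and
#' flagged rather than rejected, so cohort evaluation can proceed:
#'
#' * `tc >= a`: concentration 0, flag `below_range` (signal at or above
#'   the zero-analyte asymptote).
#' * `tc <= d`: concentration `Inf`, flag `above_range` (signal at or
#'   below the saturation asymptote; reportable only as greater than
#'   the top calibrator).
#' * finite inversions above the top calibrator in `conc_range` keep
#'   their value but are flagged `above_range` (extrapolation beyond
#'   the calibrated span).
#'
#' Flagged predictions should enter classification via their flag and
#' be excluded from bias/correlation statistics (see
#' [diagnostic_summary()]).
#'
#' @param curve a [calibration_curve()].
#' @param tc T/C ratio(s).
#' @return Numeric concentration(s) in pmol/L with a character
#'   attribute `"flag"` (`"ok"`, `"below_range"`, `"above_range"`).
#' @examples
#' crv <- b12_reference_curve()
#' invert_4pl(crv, eval_4pl(crv, 300))  # ~ 300, flag "ok"
#' @export
invert_4pl <- function(curve, tc) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- numeric(length(tc))
  flag <- character(length(tc))
  below <- tc >= curve$a
  above <- tc <= curve$d
  mid <- !below & !above
  conc[below] <- 0
  flag[below] <- "below_range"
  conc[above] <- Inf
  flag[above] <- "above_range"
  conc[mid] <- curve$c *
    ((curve$a - curve$d) / (tc[mid] - curve$d) - 1)^(1 / curve$b)
  flag[mid] <- "ok"
  if (!is.null(curve$conc_range)) {
    over <- mid & conc > max(curve$conc_range)
    flag[over] <- "above_range"
  }
  attr(conc, "flag") <- flag
  conc
}

#' Fit a 4PL calibration curve
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) over all replicates of a dilution series.
#' Initialisation: `a0` = largest per-level mean T/C, `d0` = smallest,
#' `c0` = the calibrator concentration whose mean T/C is nearest
#' `(a0 + d0)/2`, `b0` = 1. Parameter bounds: `a, d` in \[0, 2\], `b`
#' in (0, 20\], `c` in (0, 1e5\]. `r_squared` is computed against the
#' per-level replicate means, matching the convention of reporting one
#' R^2 for a replicated calibration.
#'
#' @param points either a data.frame with columns `concentration` and
#'   `tc` (one row per replicate) or a list of
#'   `list(concentration=, tc_values=)` calibration points.
#' @param batch_id batch label stored on the fitted curve.
#' @return A [calibration_curve()] with `r_squared` and `conc_range`
#'   filled in.
#' @examples
#' dat <- simulate_tc_series(b12_reference_curve(),
#'                           c(0, 46, 92, 184, 369, 738, 1107))
#' fit_4pl(dat, batch_id = "demo")
#' @export
fit_4pl <- function(points, batch_id = "") {
  if (is.data.frame(points)) {
    dat <- data.frame(x = points$concentration, y = points$tc)
  } else {
    dat <- do.call(rbind, lapply(points, function(p)
      data.frame(x = p$concentration, y = p$tc_values)))
  }
  dat <- dat[is.finite(dat$x) & is.finite(dat$y), , drop = FALSE]
  if (length(unique(dat$x)) < 4L)
    abort_input("4PL fitting needs at least 4 distinct concentrations")

  means <- tapply(dat$y, dat$x, mean)
  levels <- as.numeric(names(means))
  a0 <- max(means); d0 <- min(means)
  c0 <- levels[which.min(abs(means - (a0 + d0) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ d + (a - d) / (1 + (x / c)^b), data = dat,
      start = list(a = a0, b = 1, c = max(c0, 1e-6), d = d0),
      lower = c(a = 0, b = 1e-8, c = 1e-8, d = 0),
      upper = c(a = 2, b = 20, c = 1e5, d = 2),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort_fit(sprintf(
      "4PL fit did not converge: %s", conditionMessage(e)))
  )
  cf <- coef(fit)
  pred_means <- cf[["d"]] + (cf[["a"]] - cf[["d"]]) /
    (1 + (levels / cf[["c"]])^cf[["b"]])
  ss_res <- sum((means - pred_means)^2)
  ss_tot <- sum((means - mean(means))^2)
  r2 <- if (ss_tot == 0) ifelse(ss_res == 0, 1, NA_real_) else 1 - ss_res / ss_tot
  calibration_curve(cf[["a"]], cf[["b"]], cf[["c"]], cf[["d"]],
                    batch_id = batch_id, r_squared = r2,
                    conc_range = range(dat$x))
}

#' Coefficient of variation at one calibrator level
#'
#' `100 * sd / mean` of replicate T/C readings (sample SD), the
#' standard precision report for an immunoassay level.
#'
#' @param tc_values numeric vector of replicate T/C values (>= 2, with
#'   positive mean).
#' @return CV in percent.
#' @export
cv_at_level <- function(tc_values) {
  if (length(tc_values) < 2L)
    abort_input("CV needs at least 2 replicates")
  m <- mean(tc_values)
  if (m <= 0) abort_input("CV undefined for non-positive mean")
  100 * sd(tc_values) / m
}

#' Save or load a calibration curve as JSON
#'
#' Serialises all curve fields at full double precision (17 significant
#' digits), so `load_calibration(save_calibration(curve, path))`
#' reproduces the curve bit-exactly. Loading re-validates the 4PL
#' invariants (`a > d`, `b > 0`, `c > 0`).
#'
#' @param curve a [calibration_curve()].
#' @param path JSON file path.
#' @return `save_calibration()` returns `path` invisibly;
#'   `load_calibration()` returns the [calibration_curve()].
#' @export
save_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  payload <- list(
    batch_id = curve$batch_id, a = curve$a, b = curve$b, c = curve$c,
    d = curve$d, r_squared = curve$r_squared,
    conc_range = curve$conc_range,
    fitted_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) abort_input(sprintf(
                        "malformed calibration file: %s", conditionMessage(e))))
  needed <- c("batch_id", "a", "b", "c", "d")
  missing <- setdiff(needed, names(payload))
  if (length(missing))
    abort_input(sprintf("calibration file lacks field(s): %s",
                        paste(missing, collapse = ", ")))
  calibration_curve(
    as.numeric(payload$a), as.numeric(payload$b), as.numeric(payload$c),
    as.numeric(payload$d),
    batch_id = payload$batch_id,
    r_squared = if (is.null(payload$r_squared)) NA_real_
                else as.numeric(payload$r_squared),
    conc_range = if (is.null(payload$conc_range)) NULL
                 else as.numeric(payload$conc_range)
  )
}
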