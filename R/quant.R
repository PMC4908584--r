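#' Quantification configuration
#'
#' Settings for the strip-analysis pipeline.
#'
#' @param min_depth detection threshold, gray levels: a local minimum
#'   counts as a line only if it lies at least this far below its
#'   nearest enclosing baseline on *both* sides (bilateral prominence).
#'   The default of 10 gray levels rejects noise dips while keeping
#'   faint test lines.
#' @param expected_lines number of lines a valid strip must show
#'   (test + control = 2).
#' @param grayscale_weights RGB luma weights used by [to_gray()]; must
#'   sum to 1. Default ITU-R BT.601 (0.299, 0.587, 0.114).
#' @param tc_mode how the T/C ratio is formed. `"depth_ratio"`
#'   (default): ratio of baseline-subtracted line depths, which cancels
#'   the background level and falls as analyte concentration rises on a
#'   competitive strip. `"raw_min_ratio"`: ratio of the raw minimum
#'   intensities, kept for ablation only.
#' @param roi optional crop along the flow axis, as fractions
#'   `c(top, bottom)` of image height (e.g. `c(0.1, 0.9)` trims
#'   cassette edges in photographs). `NULL` analyses the full image.
#' @return A `quant_config` list.
#' @export
quant_config <- function(min_depth = 10, expected_lines = 2L,
                         grayscale_weights = c(0.299, 0.587, 0.114),
                         tc_mode = c("depth_ratio", "raw_min_ratio"),
                         roi = NULL) {
  tc_mode <- match.arg(tc_mode)
  if (min_depth <= 0) abort_config("`min_depth` must be positive")
  if (length(grayscale_weights) != 3L ||
      abs(sum(grayscale_weights) - 1) > 1e-8)
    abort_config("`grayscale_weights` must be 3 values summing to 1")
  if (!is.null(roi) &&
      (length(roi) != 2L || roi[1] < 0 || roi[2] > 1 || roi[1] >= roi[2]))
    abort_config("`roi` must be fractions c(top, bottom) with top < bottom")
  structure(
    list(min_depth = min_depth, expected_lines = as.integer(expected_lines),
         grayscale_weights = grayscale_weights, tc_mode = tc_mode,
         roi = roi),
    class = "quant_config"
  )
}

# Separable 1-2-1 pass along one dimension with replicated borders.
smooth_pass <- function(m, along_rows) {
  if (along_rows) {
    p <- m[c(1L, seq_len(nrow(m)), nrow(m)), , drop = FALSE]
    (p[seq_len(nrow(m)), , drop = FALSE] +
       2 * p[seq_len(nrow(m)) + 1L, , drop = FALSE] +
       p[seq_len(nrow(m)) + 2L, , drop = FALSE]) / 4
  } else {
    p <- m[, c(1L, seq_len(ncol(m)), ncol(m)), drop = FALSE]
    (p[, seq_len(ncol(m)), drop = FALSE] +
       2 * p[, seq_len(ncol(m)) + 1L, drop = FALSE] +
       p[, seq_len(ncol(m)) + 2L, drop = FALSE]) / 4
  }
}

#' Smooth a strip image with the 3x3 Gaussian kernel
#'
#' Convolves each channel with the discrete 3x3 Gaussian (the binomial
#' 1-2-1 outer product, normalised by 16), the first step of the
#' analysis pipeline. Borders are handled by edge replication, so a
#' constant image is preserved exactly.
#'
#' @param image a [strip_image()], at least 3x3 px.
#' @return The smoothed [strip_image()] (same size, scale and channel
#'   count; values remain on the 0--255 scale but are no longer
#'   integral).
#' @export
smooth_image <- function(image) {
  stopifnot(inherits(image, "strip_image"))
  if (image_height(image) < 3L || image_width(image) < 3L)
    abort_input("image must be at least 3 x 3 px for 3 x 3 filtering")
  px <- image$pixels
  if (n_channels(image) == 1L) {
    out <- smooth_pass(smooth_pass(px, TRUE), FALSE)
  } else {
    out <- px
    for (ch in 1:3)
      out[, , ch] <- smooth_pass(smooth_pass(px[, , ch], TRUE), FALSE)
  }
  strip_image(out, image$px_per_mm)
}

#' Convert a strip image to grayscale
#'
#' Maps a 3-channel image to single-channel intensity using the
#' configured luma weights, rounding to whole gray levels; a
#' single-channel image passes through unchanged.
#'
#' @param image a [strip_image()].
#' @param weights RGB weights summing to 1.
#' @return A single-channel [strip_image()].
#' @export
to_gray <- function(image, weights = c(0.299, 0.587, 0.114)) {
  stopifnot(inherits(image, "strip_image"))
  if (n_channels(image) == 1L) return(image)
  px <- image$pixels
  gray <- round(weights[1] * px[, , 1] + weights[2] * px[, , 2] +
                  weights[3] * px[, , 3])
  strip_image(pmin(pmax(gray, 0), 255), image$px_per_mm)
}

#' Collapse a strip image to a 1D flow-axis profile
#'
#' Reduces the 2D image to one intensity value per row by taking the
#' median across each row (perpendicular to flow). The median rejects
#' dust specks and edge artefacts that a mean would smear into the
#' profile. Even-width rows use the usual mean-of-middle-two
#' convention.
#'
#' @param image a single-channel [strip_image()].
#' @return A `gray_profile`: list with `values` (length = image height)
#'   and `px_per_mm`.
#' @export
collapse_profile <- function(image) {
  stopifnot(inherits(image, "strip_image"))
  if (n_channels(image) != 1L)
    abort_input("collapse_profile() needs a single-channel image")
  if (image_width(image) < 1L) abort_input("zero-width image")
  structure(
    list(values = apply(image$pixels, 1L, median),
         px_per_mm = image$px_per_mm),
    class = "gray_profile"
  )
}

#' Detect line candidates as prominent local minima
#'
#' Steps through the 1D profile with a hysteresis band of `min_depth`
#' gray levels, keeping every minimum that lies at least `min_depth`
#' below the last significant turning point on **both** sides. A
#' turning point only counts once the profile has moved `min_depth`
#' away from it, so sub-threshold wiggles -- pixel noise riding on the
#' floor of a line dip -- neither split a line into spurious
#' detections nor mask it. Each detected minimum carries the enclosing
#' baselines (the highest profile value between it and the neighbouring
#' detection, or the profile end) and its depth below the lower of the
#' two. Plateau minima report their centre index; equal minima within
#' one valley report the first.
#'
#' @param profile a `gray_profile` from [collapse_profile()] (or a bare
#'   numeric vector).
#' @param config a [quant_config()]; only `min_depth` is used.
#' @return A data.frame with one row per detection, sorted by `index`:
#'   `index`, `min_value`, `left_baseline`, `right_baseline`, `depth`
#'   (= min(baselines) - min_value, always >= `min_depth`). Zero rows
#'   when nothing qualifies.
#' @export
find_minima <- function(profile, config = quant_config()) {
  v <- if (inherits(profile, "gray_profile")) profile$values else profile
  n <- length(v)
  if (n < 3L) abort_input("profile must have at least 3 points")
  thr <- config$min_depth

  # pass 1: hysteresis scan committing one minimum per significant valley
  commit_s <- commit_e <- integer()
  left_max <- v[1]          # running max since the last committed minimum
  cm_val <- Inf             # candidate minimum of the current valley
  cm_s <- cm_e <- 0L
  for (i in seq_len(n)) {
    x <- v[i]
    if (x < cm_val) {
      cm_val <- x; cm_s <- i; cm_e <- i
    } else if (x == cm_val && i == cm_e + 1L) {
      cm_e <- i               # contiguous plateau extends the candidate
    }
    if (is.finite(cm_val) && x - cm_val >= thr) {
      # significant rise on the right; the valley ends here. left_max does
      # not yet include x, which belongs to the right side of the valley.
      if (left_max - cm_val >= thr) {
        commit_s <- c(commit_s, cm_s)
        commit_e <- c(commit_e, cm_e)
        left_max <- x         # x tops everything since the committed minimum
      }
      cm_val <- Inf           # seek the next valley either way
    }
    if (x > left_max) left_max <- x
  }
  if (!length(commit_s))
    return(data.frame(index = integer(), min_value = numeric(),
                      left_baseline = numeric(), right_baseline = numeric(),
                      depth = numeric()))

  # pass 2: baselines are the segment maxima between neighbouring minima
  k <- length(commit_s)
  left_edge <- c(1L, commit_e[-k])
  right_edge <- c(commit_s[-1L], n)
  out <- data.frame(
    index = as.integer(floor((commit_s + commit_e) / 2)),
    min_value = v[commit_s],
    left_baseline = vapply(seq_len(k), function(j)
      max(v[left_edge[j]:commit_s[j]]), 0),
    right_baseline = vapply(seq_len(k), function(j)
      max(v[commit_e[j]:right_edge[j]]), 0)
  )
  out$depth <- pmin(out$left_baseline, out$right_baseline) - out$min_value
  out
}

#' Assign detections to the test and control lines
#'
#' Keeps the two deepest detections (ties broken toward the upstream,
#' lower-index line) and labels the one nearer the sample-inlet end
#' (row 1) as the test line and the other as the control line,
#' following the strip architecture in which the analyte-conjugate test
#' line precedes the secondary-antibody control line along the flow
#' path. Extra detections beyond the expected two trigger a warning;
#' fewer than two is an invalid test (in a real assay: control line
#' absent).
#'
#' @param detections data.frame from [find_minima()].
#' @param expected_lines number of expected lines (2).
#' @return list with elements `test` and `control`, each a one-row
#'   data.frame.
#' @export
assign_lines <- function(detections, expected_lines = 2L) {
  if (nrow(detections) < 2L)
    abort_invalid_test(sprintf(
      "%d line(s) detected; a valid strip shows a test and a control line",
      nrow(detections)), stage = "assign_lines")
  if (nrow(detections) > expected_lines)
    warning(sprintf("%d detections for %d expected lines; keeping the %d deepest",
                    nrow(detections), expected_lines, expected_lines),
            call. = FALSE)
  keep <- detections[order(-detections$depth, detections$index), , drop = FALSE]
  keep <- keep[1:2, , drop = FALSE]
  keep <- keep[order(keep$index), , drop = FALSE]
  list(test = keep[1, , drop = FALSE], control = keep[2, , drop = FALSE])
}

#' Test/control signal ratio
#'
#' In the default `depth_ratio` mode the ratio of baseline-subtracted
#' line depths, `test$depth / control$depth`. Depths are measured from
#' the local baseline, so a global illumination offset cancels exactly.
#' `raw_min_ratio` divides the raw minimum intensities instead
#' (ablation mode; note raw minima *rise* with analyte concentration on
#' a competitive strip).
#'
#' @param test,control one-row detection data.frames from
#'   [assign_lines()].
#' @param config a [quant_config()].
#' @return The T/C ratio (scalar).
#' @export
tc_ratio <- function(test, control, config = quant_config()) {
  if (config$tc_mode == "depth_ratio") {
    if (control$depth <= 0)
      abort_invalid_test("control line has zero depth", stage = "tc_ratio")
    test$depth / control$depth
  } else {
    if (control$min_value <= 0)
      abort_invalid_test("control minimum is zero", stage = "tc_ratio")
    test$min_value / control$min_value
  }
}

#' Analyse a strip image
#'
#' Full quantification pipeline: 3x3 Gaussian smoothing, grayscale
#' conversion, row-median collapse to a 1D profile, prominence-gated
#' local-minima detection, test/control assignment, T/C ratio. Invalid
#' strips (fewer than two detected lines, zero-depth control) raise a
#' condition of class `lfa_invalid_test` carrying the failing stage.
#'
#' @param image a [strip_image()].
#' @param config a [quant_config()].
#' @return A `strip_analysis` list: `tc`, `test`, `control`,
#'   `detections`, `profile`, and `log` (per-stage diagnostics).
#' @examples
#' r <- render_strip(strip_spec(noise_sd = 0))
#' analyze_strip(r$image)$tc   # ~ 0.5 for the default 60/120 depths
#' @export
analyze_strip <- function(image, config = quant_config()) {
  stopifnot(inherits(image, "strip_image"))
  if (!is.null(config$roi)) {
    h <- image_height(image)
    rows <- max(1L, round(config$roi[1] * h) + 1L):min(h, round(config$roi[2] * h))
    px <- if (n_channels(image) == 1L) image$pixels[rows, , drop = FALSE]
          else image$pixels[rows, , , drop = FALSE]
    image <- strip_image(px, image$px_per_mm)
  }
  smoothed <- smooth_image(image)
  gray <- to_gray(smoothed, config$grayscale_weights)
  profile <- collapse_profile(gray)
  detections <- find_minima(profile, config)
  lines <- assign_lines(detections, config$expected_lines)
  tc <- tc_ratio(lines$test, lines$control, config)
  structure(
    list(
      tc = tc, test = lines$test, control = lines$control,
      detections = detections, profile = profile,
      log = list(
        image_px = c(image_height(image), image_width(image)),
        channels = n_channels(image),
        n_detections = nrow(detections),
        test_index = lines$test$index, control_index = lines$control$index,
        test_depth = lines$test$depth, control_depth = lines$control$depth,
        tc_mode = config$tc_mode
      )
    ),
    class = "strip_analysis"
  )
}

#' @export
print.strip_analysis <- function(x, ...) {
  cat(sprintf(
    "<strip_analysis> T/C = %.4f (test row %d depth %.1f; control row %d depth %.1f)\n",
    x$tc, x$test$index, x$test$depth, x$control$index, x$control$depth))
  invisible(x)
}
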