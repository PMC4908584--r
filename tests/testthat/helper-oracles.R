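# Independent brute-force oracle for prominent-minima detection.
#
# Deliberately different strategy from find_minima()'s single-pass
# hysteresis scan: enumerate every plateau of the profile, test each by
# explicit outward reach (scan each side until a strictly lower value or
# the profile end; the side's baseline is the maximum over that stretch and
# must clear value + min_depth), then merge candidates that share a valley
# (equal value, no intervening rise of min_depth), keeping the first.
# Baselines are recomputed as segment maxima between surviving minima.
brute_minima <- function(v, min_depth = 10) {
  n <- length(v)
  run_start <- which(c(TRUE, v[-1] != v[-n]))
  run_end <- c(run_start[-1] - 1L, n)
  keep <- list()
  for (r in seq_along(run_start)) {
    s <- run_start[r]; e <- run_end[r]; val <- v[s]
    a <- s
    while (a > 1L && v[a - 1L] >= val) a <- a - 1L
    b <- e
    while (b < n && v[b + 1L] >= val) b <- b + 1L
    if (max(v[a:s]) >= val + min_depth && max(v[e:b]) >= val + min_depth)
      keep[[length(keep) + 1L]] <- c(s = s, e = e)
  }
  if (!length(keep))
    return(data.frame(index = integer(), min_value = numeric(),
                      left_baseline = numeric(), right_baseline = numeric(),
                      depth = numeric()))
  keep <- do.call(rbind, keep)
  # merge equal minima in one valley: no rise of min_depth between them
  merged <- keep[1, , drop = FALSE]
  for (r in seq_len(nrow(keep))[-1]) {
    prev <- merged[nrow(merged), ]
    same_valley <- v[keep[r, "s"]] == v[prev["s"]] &&
      max(v[prev["e"]:keep[r, "s"]]) < v[prev["s"]] + min_depth
    if (!same_valley) merged <- rbind(merged, keep[r, , drop = FALSE])
  }
  k <- nrow(merged)
  left_edge <- c(1L, merged[-k, "e"])
  right_edge <- c(merged[-1L, "s"], n)
  out <- data.frame(
    index = as.integer(floor((merged[, "s"] + merged[, "e"]) / 2)),
    min_value = v[merged[, "s"]],
    left_baseline = vapply(seq_len(k), function(j)
      max(v[left_edge[j]:merged[j, "s"]]), 0),
    right_baseline = vapply(seq_len(k), function(j)
      max(v[merged[j, "e"]:right_edge[j]]), 0)
  )
  out$depth <- pmin(out$left_baseline, out$right_baseline) - out$min_value
  rownames(out) <- NULL
  out
}

# Random profile generators exercising plateaus, noise and smooth dips.
random_profile <- function(n = NULL) {
  if (is.null(n)) n <- sample(20:150, 1)
  kind <- sample(3, 1)
  if (kind == 1) {
    sample(0:60, n, replace = TRUE)               # small alphabet: plateaus
  } else if (kind == 2) {
    round(200 + 30 * sin(seq(0, 6 * pi, length.out = n)) +
            rnorm(n, 0, 8))
  } else {
    base <- rep(200, n)
    for (k in seq_len(sample(1:3, 1))) {
      ctr <- sample(5:(n - 4), 1)
      base <- base - sample(5:60, 1) *
        exp(-(seq_len(n) - ctr)^2 / (2 * sample(2:6, 1)^2))
    }
    round(base + rnorm(n, 0, 3))
  }
}

# Mann-Whitney AUC oracle: concordance probability that a positive
# (deficient) subject has the lower predicted concentration.
mann_whitney_auc <- function(pred, positive) {
  p <- pred[positive]; q <- pred[!positive]
  mean(outer(p, q, function(a, b) (a < b) + 0.5 * (a == b)))
}
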