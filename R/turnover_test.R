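# The non-selective turnover classification.
#
# A clade's post-extinction fauna is compared with a bootstrap null in which
# species turnover is unbiased with respect to body size: the null ("test")
# distribution is built by resampling N_m species with replacement from the
# pre-extinction pool of species-level log sizes and taking the mean, B
# times. If the center of the modern resampled distribution falls inside the
# central 50% window of that null, the turnover is classified as having left
# the size distribution unchanged; above the window, the modern fauna is
# larger than expected by chance; below, smaller. The rule is a descriptor
# (its null flag rate is ~50% by construction), not a significance test.

#' Resampling plan for the turnover classification
#'
#' @param n_boot Number of bootstrap draws B per distribution (default 1000).
#' @param coverage Central coverage of the confidence window on the null
#'   distribution, in (0, 1). Default 0.5: the window spans the 25th to 75th
#'   percentiles ("central quartiles").
#' @param seed Integer root seed. The three bootstrap distributions use
#'   independent sub-seeds derived deterministically from it.
#' @param log_base Base of the size log-transform. The classification is
#'   provably invariant to this choice; natural log is the fixed default.
#' @return Object of class `resample_plan`.
#' @export
resample_plan <- function(n_boot = 1000, coverage = 0.5, seed = 1L,
                          log_base = exp(1)) {
  if (!is.numeric(n_boot) || length(n_boot) != 1 || n_boot < 1) {
    stop_ps("`n_boot` must be a positive integer")
  }
  if (!is.numeric(coverage) || length(coverage) != 1 ||
      coverage <= 0 || coverage >= 1) {
    stop_ps("`coverage` must lie strictly between 0 and 1")
  }
  if (!is.numeric(log_base) || length(log_base) != 1 || log_base <= 0 ||
      log_base == 1) {
    stop_ps("`log_base` must be a positive number different from 1")
  }
  structure(list(n_boot = as.integer(n_boot), coverage = coverage,
                 seed = as.integer(seed), log_base = log_base),
            class = "resample_plan")
}

#' Log-transform positive sizes
#'
#' @param sizes Vector of positive sizes (mm).
#' @param base Log base (default natural log).
#' @return Vector of log sizes, same length.
#' @export
log_sizes <- function(sizes, base = exp(1)) {
  bad <- which(!is.finite(sizes) | sizes <= 0)
  if (length(bad) > 0) {
    stop_ps("non-positive size at index ", bad[1])
  }
  log(sizes, base = base)
}

#' Bootstrap distribution of sample means
#'
#' Draws `n_boot` resamples of size `n_draw`, uniformly with replacement
#' from `values`, and returns the `n_boot` resample means.
#'
#' @param values Non-empty numeric vector.
#' @param n_draw Resample size (>= 1).
#' @param n_boot Number of resamples.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched. When `NULL`, the current
#'   RNG stream is used.
#' @return Numeric vector of length `n_boot`; every element lies in
#'   `[min(values), max(values)]`.
#' @export
bootstrap_means <- function(values, n_draw, n_boot, seed = NULL) {
  if (length(values) == 0) stop_ps("`values` must be non-empty")
  if (any(!is.finite(values))) stop_ps("`values` must be finite")
  if (n_draw < 1 || n_boot < 1) stop_ps("`n_draw` and `n_boot` must be >= 1")
  n_draw <- as.integer(n_draw)
  n_boot <- as.integer(n_boot)
  draw <- function() {
    idx <- sample.int(length(values), n_draw * n_boot, replace = TRUE)
    .colMeans(values[idx], n_draw, n_boot)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Central confidence window of a distribution
#'
#' Returns the bounds of the central `coverage` interval of `dist` using the
#' linear-interpolation quantile convention (type 7): the quantiles at
#' `(1 - coverage)/2` and `1 - (1 - coverage)/2`.
#'
#' @param dist Non-empty numeric vector.
#' @param coverage Central coverage in (0, 1).
#' @return Numeric vector `c(lo, hi)` with `lo <= hi`.
#' @export
central_window <- function(dist, coverage) {
  if (length(dist) == 0) stop_ps("`dist` must be non-empty")
  if (coverage <= 0 || coverage >= 1) {
    stop_ps("`coverage` must lie strictly between 0 and 1")
  }
  tail_p <- (1 - coverage) / 2
  unname(quantile(dist, probs = c(tail_p, 1 - tail_p), names = FALSE, type = 7))
}

#' Classify a clade's size turnover against the non-selective null
#'
#' Builds three bootstrap distributions on species-level log sizes, with
#' N_f = number of pre-extinction species and N_m = number of modern
#' species:
#' \describe{
#'   \item{fossil_resampled}{B means of N_f draws from the pre-extinction
#'     log sizes (the fossil fauna resampled at its own richness).}
#'   \item{test_dist}{B means of N_m draws from the pre-extinction log
#'     sizes — the non-selective turnover null: what the modern fauna would
#'     look like if turnover were unbiased with respect to size.}
#'   \item{modern_resampled}{B means of N_m draws from the modern log
#'     sizes.}
#' }
#' The comparison statistic is the mean of `modern_resampled`. It is
#' compared with the central `coverage` window of `test_dist`: inside
#' (bounds inclusive) classifies as `"no_change"`, above as `"larger"`,
#' below as `"smaller"`.
#'
#' @param fauna A [fauna_table()] with non-empty bins.
#' @param plan A [resample_plan()].
#' @return Object of class `turnover_result`: the three distributions,
#'   `window` (lo, hi), `modern_center`, `decision`, `n_f`, `n_m`, plus the
#'   clade, metric and plan.
#' @export
classify_turnover <- function(fauna, plan = resample_plan()) {
  stopifnot(inherits(fauna, "fauna_table"), inherits(plan, "resample_plan"))
  if (length(fauna$pre_sizes) == 0) {
    stop_ps("pre-extinction bin is empty for clade '", fauna$clade, "'")
  }
  if (length(fauna$modern_sizes) == 0) {
    stop_ps("modern bin is empty for clade '", fauna$clade, "'")
  }
  log_pre <- log_sizes(fauna$pre_sizes, base = plan$log_base)
  log_mod <- log_sizes(fauna$modern_sizes, base = plan$log_base)
  n_f <- length(log_pre)
  n_m <- length(log_mod)
  seeds <- derive_seeds(plan$seed, 3)
  fossil_resampled <- bootstrap_means(log_pre, n_f, plan$n_boot, seeds[1])
  test_dist <- bootstrap_means(log_pre, n_m, plan$n_boot, seeds[2])
  modern_resampled <- bootstrap_means(log_mod, n_m, plan$n_boot, seeds[3])
  window <- central_window(test_dist, plan$coverage)
  modern_center <- mean(modern_resampled)
  decision <- if (modern_center > window[2]) {
    "larger"
  } else if (modern_center < window[1]) {
    "smaller"
  } else {
    "no_change" # bounds inclusive: a tie means the center fell within
  }
  structure(
    list(clade = fauna$clade, metric = fauna$metric,
         n_f = n_f, n_m = n_m, plan = plan,
         fossil_resampled = fossil_resampled,
         test_dist = test_dist,
         modern_resampled = modern_resampled,
         window = window, modern_center = modern_center,
         decision = decision),
    class = "turnover_result"
  )
}

#' @export
print.turnover_result <- function(x, ...) {
  b <- x$plan$log_base
  cat("Non-selective turnover classification:", x$clade,
      paste0("(metric: ", x$metric, " size)\n"))
  cat(sprintf("  N_f = %d pre-extinction species, N_m = %d modern species, B = %d\n",
              x$n_f, x$n_m, x$plan$n_boot))
  cat(sprintf("  null %d%% window: [%.4f, %.4f] log units  (%.1f to %.1f mm)\n",
              round(100 * x$plan$coverage), x$window[1], x$window[2],
              b^x$window[1], b^x$window[2]))
  cat(sprintf("  modern resampled center: %.4f log units  (%.1f mm)\n",
              x$modern_center, b^x$modern_center))
  cat("  decision:", x$decision, "\n")
  invisible(x)
}

#' One-row summary of a turnover result
#'
#' Flattens a [classify_turnover()] result into a single-row tibble for CSV
#' output, with window bounds and the modern center in both log units and
#' back-transformed mm.
#'
#' @param result A `turnover_result`.
#' @param variant Optional label distinguishing exclusion variants of the
#'   same clade/metric run.
#' @return One-row tibble.
#' @export
turnover_row <- function(result, variant = "all species") {
  stopifnot(inherits(result, "turnover_result"))
  b <- result$plan$log_base
  tibble(
    clade = result$clade,
    metric = result$metric,
    variant = variant,
    n_f = result$n_f,
    n_m = result$n_m,
    n_boot = result$plan$n_boot,
    coverage = result$plan$coverage,
    window_lo = result$window[1],
    window_hi = result$window[2],
    modern_center = result$modern_center,
    window_lo_mm = b^result$window[1],
    window_hi_mm = b^result$window[2],
    modern_center_mm = b^result$modern_center,
    decision = result$decision,
    seed = result$plan$seed
  )
}

#' Full bootstrap distributions of a turnover result
#'
#' Long-to-wide dump of the three bootstrap distributions (one row per
#' bootstrap draw), for plotting violin/histogram panels.
#'
#' @param result A `turnover_result`.
#' @return Tibble with columns `fossil_resampled`, `test_dist`,
#'   `modern_resampled`, `n_boot` rows.
#' @export
turnover_distributions <- function(result) {
  stopifnot(inherits(result, "turnover_result"))
  tibble(
    fossil_resampled = result$fossil_resampled,
    test_dist = result$test_dist,
    modern_resampled = result$modern_resampled
  )
}
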