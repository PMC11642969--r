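# Ancestor-descendant lineage comparisons.
#
# Survivor lineages (a species present both before the extinction interval
# and today, or an anagenetic ancestor-descendant pair) are compared
# population against population on raw specimen lengths in mm: pooled and
# Welch two-sample t-tests, a permutation t-test, and Bonferroni-corrected
# significance across the battery of lineages tested.

#' Two-sample t-test (pooled or Welch)
#'
#' Standard two-sided two-sample t-test with the sign convention that t is
#' positive when `mean(x) > mean(y)`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` (equal-variance) or `"welch"`
#'   (Welch-Satterthwaite degrees of freedom).
#' @return List with elements `t`, `p`, `df`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) {
    stop_ps("both samples must contain at least 2 observations")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_ps("samples must be finite")
  }
  if (var(x) + var(y) == 0) {
    stop_ps("zero variance in both samples: t statistic undefined")
  }
  fit <- t.test(x, y, var.equal = (variant == "pooled"))
  list(t = unname(fit$statistic), p = fit$p.value, df = unname(fit$parameter))
}

# Pooled-t (or mean-difference fallback) statistics for a set of group-x
# index assignments, vectorized over the columns of `idx`.
perm_statistics <- function(z, nx, idx) {
  idx <- as.matrix(idx)
  n <- length(z)
  ny <- n - nx
  S <- sum(z)
  Q <- sum(z^2)
  zx <- matrix(z[idx], nrow = nx)
  sx <- .colSums(zx, nx, ncol(idx))
  mx <- sx / nx
  my <- (S - sx) / ny
  if (nx < 2 || ny < 2) {
    return(mx - my) # t undefined: mean-difference statistic
  }
  sxx <- .colSums(zx^2, nx, ncol(idx))
  vx <- pmax(sxx - nx * mx^2, 0) / (nx - 1)
  vy <- pmax((Q - sxx) - ny * my^2, 0) / (ny - 1)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (n - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  stat <- (mx - my) / se
  degen <- se == 0
  if (any(degen)) {
    # a permutation with zero pooled variance: all values in each group
    # equal; the statistic degenerates to the sign of the mean difference
    stat[degen] <- sign(mx[degen] - my[degen]) * Inf
    stat[degen & (mx == my)] <- 0
  }
  stat
}

#' Permutation two-sample t-test
#'
#' Tests the difference in means by permuting group labels. The statistic is
#' the pooled two-sample t (falling back to the raw mean difference when
#' group sizes make t undefined, and to a signed infinite value for
#' permutations with zero pooled variance). The two-sided p-value is the
#' proportion of labelings whose absolute statistic is at least the observed
#' one.
#'
#' When the number of distinct group assignments `choose(n, nx)` is at most
#' `max_exhaustive`, all labelings are enumerated and the p-value is exact.
#' Otherwise `n_perm` Monte-Carlo labelings are drawn and the observed
#' labeling is included, giving `p = (1 + k) / (n_perm + 1)`; p is always in
#' (0, 1].
#'
#' @param x,y Numeric vectors (each length >= 1).
#' @param n_perm Number of Monte-Carlo permutations (default 9999).
#' @param seed Optional integer seed for the Monte-Carlo draw.
#' @param exhaustive Force (`TRUE`) or forbid (`FALSE`) full enumeration;
#'   `NULL` (default) auto-selects by feasibility.
#' @param max_exhaustive Enumeration cutoff on `choose(n, nx)` (default
#'   2e5).
#' @return List with `t_obs`, `p`, `exhaustive` (logical), `n_used`
#'   (labelings evaluated).
#' @export
permutation_t <- function(x, y, n_perm = 9999, seed = NULL,
                          exhaustive = NULL, max_exhaustive = 2e5) {
  if (length(x) < 1 || length(y) < 1) {
    stop_ps("both samples must be non-empty")
  }
  if (any(!is.finite(c(x, y)))) stop_ps("samples must be finite")
  z <- c(x, y)
  nx <- length(x)
  n <- length(z)
  n_labelings <- choose(n, nx)
  feasible <- n_labelings <= max_exhaustive
  if (is.null(exhaustive)) exhaustive <- feasible
  if (exhaustive && !feasible) {
    stop_ps("exhaustive enumeration infeasible: choose(", n, ", ", nx, ") = ",
            format(n_labelings), " labelings exceed max_exhaustive")
  }
  t_obs <- perm_statistics(z, nx, matrix(seq_len(nx), ncol = 1))
  tol <- 1e-12
  if (exhaustive) {
    stats_all <- perm_statistics(z, nx, combn(n, nx))
    p <- mean(abs(stats_all) >= abs(t_obs) - tol)
    n_used <- length(stats_all)
  } else {
    draw <- function() {
      vapply(seq_len(n_perm), function(i) sample.int(n, nx), integer(nx))
    }
    idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    stats_mc <- perm_statistics(z, nx, idx)
    p <- (1 + sum(abs(stats_mc) >= abs(t_obs) - tol)) / (n_perm + 1)
    n_used <- n_perm + 1L
  }
  list(t_obs = t_obs, p = p, exhaustive = exhaustive, n_used = n_used)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of comparisons (positive integer).
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_ps("`alpha` must lie strictly between 0 and 1")
  }
  if (!is.numeric(m) || length(m) != 1 || m < 1) {
    stop_ps("`m` must be a positive integer")
  }
  alpha / m
}

#' Define an ancestor-descendant lineage pair
#'
#' The fossil and modern species names may coincide (a species that
#' persisted across the boundary) or differ (an anagenetic
#' ancestor-descendant pair). Lengths are raw specimen lengths in mm.
#'
#' @param lineage_name Label for the lineage.
#' @param fossil_lengths,modern_lengths Positive numeric vectors (mm).
#' @param fossil_species,modern_species Species names; default the lineage
#'   name.
#' @return Object of class `lineage_pair`.
#' @export
lineage_pair <- function(lineage_name, fossil_lengths, modern_lengths,
                         fossil_species = lineage_name,
                         modern_species = lineage_name) {
  for (v in list(fossil_lengths, modern_lengths)) {
    if (length(v) == 0) stop_ps("lineage '", lineage_name,
                                "': both length vectors must be non-empty")
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop_ps("lineage '", lineage_name, "': lengths must be positive")
    }
  }
  structure(
    list(lineage_name = lineage_name,
         fossil_species = fossil_species, modern_species = modern_species,
         fossil_lengths = as.numeric(fossil_lengths),
         modern_lengths = as.numeric(modern_lengths)),
    class = "lineage_pair"
  )
}

#' Build lineage pairs from specimen records
#'
#' For each row of `pairs`, collects the fossil species' lengths from the
#' pre-extinction bin and the modern species' lengths from the modern bin.
#' Lineage pairings are user input (e.g. following a published phylogeny);
#' no ancestor-descendant inference is performed.
#'
#' @param records Specimen records (see [read_measurements()]).
#' @param pairs Data frame with columns `lineage`, `fossil_species`,
#'   `modern_species` (missing species columns default to `lineage`).
#' @param include_figure_derived Keep figure-derived measurements (default
#'   `TRUE`).
#' @return List of [lineage_pair()] objects.
#' @export
lineage_pairs_from_records <- function(records, pairs,
                                       include_figure_derived = TRUE) {
  validate_records(records)
  pairs <- as_tibble(pairs)
  if (!"lineage" %in% names(pairs)) stop_ps("`pairs` needs a `lineage` column")
  if (!"fossil_species" %in% names(pairs)) pairs$fossil_species <- pairs$lineage
  if (!"modern_species" %in% names(pairs)) pairs$modern_species <- pairs$lineage
  if (!include_figure_derived && "from_figure" %in% names(records)) {
    records <- records[!records$from_figure, , drop = FALSE]
  }
  lapply(seq_len(nrow(pairs)), function(i) {
    fl <- records$length_mm[records$species == pairs$fossil_species[i] &
                              records$time_bin == "pre_extinction"]
    ml <- records$length_mm[records$species == pairs$modern_species[i] &
                              records$time_bin == "modern"]
    if (length(fl) == 0 || length(ml) == 0) {
      stop_ps("lineage '", pairs$lineage[i], "': no ",
              if (length(fl) == 0) "pre-extinction" else "modern",
              " specimens found")
    }
    lineage_pair(pairs$lineage[i], fl, ml,
                 fossil_species = pairs$fossil_species[i],
                 modern_species = pairs$modern_species[i])
  })
}

#' Run a battery of lineage comparisons
#'
#' Applies the pooled t-test, Welch t-test, and permutation t-test to every
#' lineage pair and flags raw and Bonferroni-corrected significance (on the
#' pooled p-value). Comparisons operate on raw lengths in mm by default;
#' `log_scale = TRUE` tests natural-log lengths instead (reported means stay
#' in mm either way).
#'
#' @param pairs List of [lineage_pair()] objects (a single pair is
#'   accepted).
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Number of comparisons for the Bonferroni correction; default
#'   the number of pairs tested.
#' @param n_perm Monte-Carlo permutation count (default 9999); exhaustive
#'   enumeration is auto-selected when feasible.
#' @param seed Integer root seed for the permutation draws.
#' @param log_scale Test log-transformed lengths.
#' @return Tibble, one row per pair, in input order.
#' @export
run_lineage_battery <- function(pairs, alpha = 0.05, m = NULL,
                                n_perm = 9999, seed = 1L, log_scale = FALSE) {
  if (inherits(pairs, "lineage_pair")) pairs <- list(pairs)
  if (length(pairs) == 0) {
    return(tibble(lineage = character(), fossil_species = character(),
                  modern_species = character(), n_fossil = integer(),
                  n_modern = integer(), mean_fossil_mm = double(),
                  mean_modern_mm = double(), t_pooled = double(),
                  p_pooled = double(), df_pooled = double(),
                  t_welch = double(), p_welch = double(), df_welch = double(),
                  t_perm = double(), p_perm = double(), alpha = double(),
                  m = integer(), alpha_bonferroni = double(),
                  significant_raw = logical(),
                  significant_bonferroni = logical()))
  }
  stopifnot(all(vapply(pairs, inherits, logical(1), "lineage_pair")))
  if (is.null(m)) m <- length(pairs)
  alpha_corr <- bonferroni_alpha(alpha, m)
  seeds <- derive_seeds(seed, length(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    fx <- pr$fossil_lengths
    mx <- pr$modern_lengths
    x <- if (log_scale) log(fx) else fx
    y <- if (log_scale) log(mx) else mx
    res <- tryCatch({
      pooled <- two_sample_t(x, y, "pooled")
      welch <- two_sample_t(x, y, "welch")
      perm <- permutation_t(x, y, n_perm = n_perm, seed = seeds[i])
      tibble(
        lineage = pr$lineage_name,
        fossil_species = pr$fossil_species,
        modern_species = pr$modern_species,
        n_fossil = length(fx), n_modern = length(mx),
        mean_fossil_mm = mean(fx), mean_modern_mm = mean(mx),
        t_pooled = pooled$t, p_pooled = pooled$p, df_pooled = pooled$df,
        t_welch = welch$t, p_welch = welch$p, df_welch = welch$df,
        t_perm = perm$t_obs, p_perm = perm$p,
        alpha = alpha, m = as.integer(m), alpha_bonferroni = alpha_corr,
        significant_raw = pooled$p < alpha,
        significant_bonferroni = pooled$p < alpha_corr
      )
    }, error = function(e) {
      stop_ps("lineage '", pr$lineage_name, "': ", conditionMessage(e))
    })
    res
  })
  bind_rows(rows)
}

#' Long-format specimen lengths for a set of lineage pairs
#'
#' Plot-ready table (box-plot data): one row per specimen with `lineage`,
#' `species`, `bin`, `length_mm`.
#'
#' @param pairs List of [lineage_pair()] objects.
#' @return Tibble.
#' @export
lineage_specimens_long <- function(pairs) {
  if (inherits(pairs, "lineage_pair")) pairs <- list(pairs)
  if (length(pairs) == 0) {
    return(tibble(lineage = character(), species = character(),
                  bin = character(), length_mm = double()))
  }
  bind_rows(lapply(pairs, function(pr) {
    tibble(
      lineage = pr$lineage_name,
      species = c(rep(pr$fossil_species, length(pr$fossil_lengths)),
                  rep(pr$modern_species, length(pr$modern_lengths))),
      bin = c(rep("pre_extinction", length(pr$fossil_lengths)),
              rep("modern", length(pr$modern_lengths))),
      length_mm = c(pr$fossil_lengths, pr$modern_lengths)
    )
  }))
}
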