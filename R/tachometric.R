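# Tachometric curves: choice accuracy as a function of processing time,
# estimated in wide bins slid in small steps along the PT axis.

#' Agresti-Coull binomial confidence interval
#'
#' For `k` successes in `n` trials and confidence level `conf`, with `z` the
#' corresponding standard-normal quantile: `n~ = n + z^2`,
#' `p~ = (k + z^2/2) / n~`, half-width `z * sqrt(p~ (1 - p~) / n~)`. The
#' interval is clipped to `[0, 1]`.
#'
#' @param k Number of successes, `0 <= k <= n` (vectorized).
#' @param n Number of trials, `>= 1`.
#' @param conf Confidence level (default 0.95).
#' @return A list with numeric vectors `low` and `high`.
#' @examples
#' agresti_coull_ci(50, 100)  # approx (0.404, 0.596)
#' @export
agresti_coull_ci <- function(k, n, conf = 0.95) {
  if (any(n < 1)) abort("agresti_coull_ci requires n >= 1")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n")
  z <- qnorm(1 - (1 - conf) / 2)
  n_t <- n + z^2
  p_t <- (k + z^2 / 2) / n_t
  hw <- z * sqrt(p_t * (1 - p_t) / n_t)
  list(low = pmax(0, p_t - hw), high = pmin(1, p_t + hw))
}

#' Compute a tachometric curve
#'
#' Accuracy as a function of processing time, estimated by counting trials
#' in bins of width `bin_width_ms` whose centers advance every `step_ms`
#' along the PT axis. A bin centered at `c` covers the half-open interval
#' `[c - w/2, c + w/2)`, so every trial is counted in the same number of
#' sliding bins. Bins containing no trials are carried as undefined (`NA`
#' fraction), never as zero accuracy.
#'
#' @param trials Trial table with `pt_ms` and `correct`.
#' @param bin_width_ms Bin width in ms (default 50).
#' @param step_ms Grid step in ms (default 1).
#' @param pt_range Optional `c(min, max)` for the grid of bin centers;
#'   defaults to the span of the observed PTs.
#' @param conf Confidence level for the per-bin Agresti-Coull band.
#' @return A tibble of class `tachometric_curve` with columns `pt` (bin
#'   center, ms), `n_trials`, `n_correct`, `fraction_correct`, `ci_low`,
#'   `ci_high`, and attributes `bin_width_ms`, `step_ms`.
#' @export
compute_tachometric <- function(trials, bin_width_ms = 50, step_ms = 1,
                                pt_range = NULL, conf = 0.95) {
  if (bin_width_ms <= 0) abort("bin_width_ms must be > 0")
  if (step_ms <= 0) abort("step_ms must be > 0")
  pt <- trials$pt_ms
  corr <- trials$correct
  if (is.null(pt_range)) {
    if (length(pt) == 0) {
      pt_range <- c(0, 0)
    } else {
      pt_range <- c(floor(min(pt)), ceiling(max(pt)))
    }
  }
  centers <- seq(pt_range[1], pt_range[2], by = step_ms)
  half <- bin_width_ms / 2

  # counts in [c - w/2, c + w/2) via sorted PTs:
  # #{x : x < t} = findInterval(t, sorted, left.open = TRUE)
  all_sorted <- sort(pt)
  cor_sorted <- sort(pt[corr])
  n_lt <- function(v, t) findInterval(t, v, left.open = TRUE)
  n_trials  <- n_lt(all_sorted, centers + half) - n_lt(all_sorted, centers - half)
  n_correct <- n_lt(cor_sorted, centers + half) - n_lt(cor_sorted, centers - half)

  frac <- ifelse(n_trials > 0, n_correct / n_trials, NA_real_)
  ci_low <- ci_high <- rep(NA_real_, length(centers))
  pos <- n_trials > 0
  if (any(pos)) {
    ci <- agresti_coull_ci(n_correct[pos], n_trials[pos], conf)
    ci_low[pos] <- ci$low
    ci_high[pos] <- ci$high
  }
  out <- tibble::tibble(pt = centers, n_trials = as.integer(n_trials),
                        n_correct = as.integer(n_correct),
                        fraction_correct = frac,
                        ci_low = ci_low, ci_high = ci_high)
  attr(out, "bin_width_ms") <- bin_width_ms
  attr(out, "step_ms") <- step_ms
  class(out) <- c("tachometric_curve", class(out))
  out
}

#' @export
print.tachometric_curve <- function(x, ...) {
  defined <- sum(x$n_trials > 0)
  cat(sprintf(
    "Tachometric curve: %d bin centers (%g ms wide, step %g ms), %d defined\n",
    nrow(x), attr(x, "bin_width_ms"), attr(x, "step_ms"), defined))
  NextMethod()
}

# Scalar summaries ---------------------------------------------------------

.accuracy_estimate <- function(k, n, region, conf = 0.95) {
  if (n == 0) {
    est <- list(k = 0L, n = 0L, proportion = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, region = region, defined = FALSE)
  } else {
    ci <- agresti_coull_ci(k, n, conf)
    est <- list(k = as.integer(k), n = as.integer(n), proportion = k / n,
                ci_low = ci$low, ci_high = ci$high, region = region,
                defined = TRUE)
  }
  structure(est, class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("Accuracy (%s): undefined (0 trials)\n", x$region))
  } else {
    cat(sprintf("Accuracy (%s): %d/%d = %.3f [%.3f, %.3f]\n",
                x$region, x$k, x$n, x$proportion, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Floor and ceiling accuracy
#'
#' Floor accuracy is the proportion correct over trials with processing time
#' strictly below 100 ms (uninformed guesses); ceiling accuracy is the
#' proportion correct over trials with PT strictly above 150 ms (informed
#' choices). The 100-150 ms transition band belongs to neither summary, and
#' both are independent of any binning. With no qualifying trials the
#' estimate is flagged undefined.
#'
#' @param trials Trial table with `pt_ms` and `correct`.
#' @param cutoff_ms Region boundary (defaults: 100 floor, 150 ceiling).
#' @param conf Confidence level for the Agresti-Coull interval.
#' @return An `accuracy_estimate`: a list with `k`, `n`, `proportion`,
#'   `ci_low`, `ci_high`, `region`, `defined`.
#' @export
floor_accuracy <- function(trials, cutoff_ms = 100, conf = 0.95) {
  sel <- trials$pt_ms < cutoff_ms
  .accuracy_estimate(sum(trials$correct[sel]), sum(sel), "floor", conf)
}

#' @rdname floor_accuracy
#' @export
ceiling_accuracy <- function(trials, cutoff_ms = 150, conf = 0.95) {
  sel <- trials$pt_ms > cutoff_ms
  .accuracy_estimate(sum(trials$correct[sel]), sum(sel), "ceiling", conf)
}

#' Mean reaction time with its standard error
#'
#' Computed over all supplied trials, correct and incorrect, at all
#' processing times.
#'
#' @param trials Trial table.
#' @return A list with `mean`, `sem` (`NA` when fewer than 2 trials), `n`.
#' @export
mean_rt <- function(trials) {
  rt <- trials$rt_ms
  n <- length(rt)
  list(mean = if (n > 0) mean(rt) else NA_real_,
       sem = if (n > 1) sd(rt) / sqrt(n) else NA_real_,
       n = n)
}

# Difference curves --------------------------------------------------------

#' Difference between two tachometric curves
#'
#' Per-bin difference `fraction_s - fraction_d` between a curve conditioned
#' on same (S) histories and one conditioned on different (D) histories,
#' with a standard-error band `sqrt(SE_s^2 + SE_d^2)` from the per-bin
#' binomial standard errors. Undefined wherever either input bin is
#' undefined.
#'
#' @param curve_s,curve_d Tachometric curves on identical grids and bin
#'   parameters.
#' @return A tibble with columns `pt`, `difference`, `se`.
#' @export
difference_curve <- function(curve_s, curve_d) {
  if (!isTRUE(all.equal(curve_s$pt, curve_d$pt)) ||
      attr(curve_s, "bin_width_ms") != attr(curve_d, "bin_width_ms")) {
    abort("difference_curve requires identical grids and bin parameters")
  }
  binom_se <- function(cv) {
    ifelse(cv$n_trials > 0,
           sqrt(cv$fraction_correct * (1 - cv$fraction_correct) / cv$n_trials),
           NA_real_)
  }
  tibble::tibble(
    pt = curve_s$pt,
    difference = curve_s$fraction_correct - curve_d$fraction_correct,
    se = sqrt(binom_se(curve_s)^2 + binom_se(curve_d)^2))
}

# Resampling comparisons ---------------------------------------------------

#' Bootstrap comparison of floor or ceiling accuracy between two trial sets
#'
#' Two-sided significance for the difference in the chosen summary
#' statistic, by resampling trials with replacement within each group
#' (percentile bootstrap). Deterministic given `seed`.
#'
#' @param trials_a,trials_b Trial tables.
#' @param statistic `"floor"` or `"ceiling"`.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed (required).
#' @return A list with `observed` (difference a - b), `p_value`, and
#'   `boot` (the bootstrap distribution of the difference).
#' @export
resample_compare <- function(trials_a, trials_b,
                             statistic = c("floor", "ceiling"),
                             n_boot = 10000, seed) {
  statistic <- match.arg(statistic)
  if (missing(seed)) abort("resample_compare requires an explicit seed")
  cutoff <- if (statistic == "floor") 100 else 150
  pick <- function(tr) {
    sel <- if (statistic == "floor") tr$pt_ms < cutoff else tr$pt_ms > cutoff
    tr$correct[sel]
  }
  xa <- pick(trials_a); xb <- pick(trials_b)
  if (length(xa) == 0 || length(xb) == 0) {
    abort("both groups must contain trials in the requested PT region")
  }
  observed <- mean(xa) - mean(xb)
  boot <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    na <- length(xa); nb <- length(xb)
    vapply(seq_len(n_boot), function(i) {
      mean(xa[sample.int(na, na, replace = TRUE)]) -
        mean(xb[sample.int(nb, nb, replace = TRUE)])
    }, numeric(1))
  })
  # two-sided percentile p: how often the resampled difference crosses zero
  p_lo <- (sum(boot <= 0) + 1) / (n_boot + 1)
  p_hi <- (sum(boot >= 0) + 1) / (n_boot + 1)
  list(observed = observed, p_value = min(1, 2 * min(p_lo, p_hi)), boot = boot)
}
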