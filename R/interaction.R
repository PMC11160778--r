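# Conditional-independence interaction analysis. For each joint history
# sequence, the accuracy of informed choices (PT > 150 ms) is measured
# directly and also predicted from the two marginal histories under the
# assumption that they influence the outcome conditionally independently.
# Points off the measured = predicted diagonal indicate an interaction.

#' Accuracy of informed choices under a history condition
#'
#' Proportion correct among trials matching `labels == label` and lying in
#' the informed (ceiling) region, PT strictly above `informed_cutoff_ms`,
#' with an Agresti-Coull interval. With `label = NULL` all trials qualify
#' and the result equals [ceiling_accuracy()].
#'
#' @param trials History-labeled trial table (pooled across subjects).
#' @param labels Character vector of per-trial history labels aligned with
#'   `trials` (e.g. from [classify_sequence()]), or `NULL`.
#' @param label The label defining the condition.
#' @param informed_cutoff_ms PT bound for informed trials (default 150).
#' @param conf Confidence level.
#' @return An `accuracy_estimate` (undefined and flagged when no trials match).
#' @export
conditional_accuracy <- function(trials, labels = NULL, label = NULL,
                                 informed_cutoff_ms = 150, conf = 0.95) {
  sel <- trials$pt_ms > informed_cutoff_ms
  if (!is.null(labels)) {
    if (length(labels) != nrow(trials)) {
      abort("labels must align with the rows of trials")
    }
    sel <- sel & !is.na(labels) & labels == label
  }
  .accuracy_estimate(sum(trials$correct[sel]), sum(sel), "ceiling", conf)
}

#' Predicted joint accuracy under conditional independence
#'
#' Given the accuracies conditioned on two history events separately,
#' `p_a = P(C=1|A)` and `p_b = P(C=1|B)`, and the overall prior
#' `P(C=1)`, the conditional-independence prediction for the joint
#' condition is
#' \deqn{P(C=1|A,B) = \frac{p_a p_b}{p_a p_b + (1-p_a)(1-p_b)\,
#'   \pi/(1-\pi)}}{p_a p_b / (p_a p_b + (1-p_a)(1-p_b) prior/(1-prior))}
#' with \eqn{\pi} the prior. The prediction is symmetric in `p_a`, `p_b`,
#' nondecreasing in each, and collapses to `p_a` when `p_b` equals the
#' prior (an uninformative second condition).
#'
#' @param p_a,p_b Conditional accuracies in `[0, 1]` (vectorized).
#' @param prior Overall probability correct, strictly inside `(0, 1)`.
#' @return Predicted joint accuracy in `[0, 1]`.
#' @examples
#' predict_joint(0.80, 0.75, 0.70)  # 0.84
#' predict_joint(0.59, 0.71, 0.66)  # 0.64
#' @export
predict_joint <- function(p_a, p_b, prior) {
  if (any(!is.finite(p_a)) || any(!is.finite(p_b)) || any(!is.finite(prior)) ||
      any(p_a < 0 | p_a > 1) || any(p_b < 0 | p_b > 1) ||
      any(prior < 0 | prior > 1)) {
    abort("p_a, p_b, prior must lie in [0, 1]")
  }
  if (any(prior == 0 | prior == 1)) {
    abort("prior must be strictly inside (0, 1)")
  }
  num <- p_a * p_b
  num / (num + (1 - p_a) * (1 - p_b) * prior / (1 - prior))
}

#' Measured versus predicted accuracy for all joint history sequences
#'
#' For every sequence-mode label of depth `h` over the requested history
#' dimensions, measures the informed-choice accuracy directly and predicts
#' it from the two marginal conditions via [predict_joint()], using the
#' overall informed-trial proportion correct as the prior. With
#' `dims = c("color", "location")` the marginals are the color sequence and
#' the location sequence; with the triple
#' `c("color", "location", "outcome")` the marginals are color-with-outcome
#' and location-with-outcome (outcome enters both sides). A point is
#' flagged reliable when the span of its measured 95% CI is below
#' `ci_span_threshold` percentage points.
#'
#' @param trials Pooled, validity-filtered trial table, ordered by trial
#'   index within each session.
#' @param dims Two of `c("color", "location", "outcome")`, or all three.
#' @param h History depth, 1 to 4.
#' @param ci_span_threshold Reliability threshold on the measured CI span,
#'   percentage points (default 15).
#' @param informed_cutoff_ms PT bound for informed trials (default 150).
#' @param prior `"ceiling"` (default) uses the informed-region proportion
#'   correct of all trials as the prior; `"all"` uses the all-PT proportion.
#' @return A tibble of class `interaction_points`: one row per sequence with
#'   `label`, `label_a`, `label_b`, `n`, `k`, `measured_p`, `ci_low`,
#'   `ci_high`, `p_a`, `p_b`, `predicted_p`, `reliable`, `h`; the prior is
#'   stored in `attr(x, "prior")`.
#' @export
interaction_analysis <- function(trials, dims = c("color", "location"),
                                 h = 1, ci_span_threshold = 15,
                                 informed_cutoff_ms = 150,
                                 prior = c("ceiling", "all")) {
  prior_mode <- match.arg(prior)
  if (!h %in% 1:4) abort("h must be in 1..4")
  dims <- .order_dims(dims)
  if (length(dims) < 2) abort("dims must name at least two history dimensions")
  if (length(dims) == 2) {
    dims_a <- dims[1]; dims_b <- dims[2]
  } else {
    dims_a <- c(dims[1], "outcome"); dims_b <- c(dims[2], "outcome")
  }

  joint <- classify_sequence(trials, dims, h)
  lab_a <- sequence_marginal(joint, dims, dims_a)
  lab_b <- sequence_marginal(joint, dims, dims_b)

  informed <- trials$pt_ms > informed_cutoff_ms
  prior_sel <- if (prior_mode == "ceiling") informed else rep(TRUE, nrow(trials))
  prior_p <- mean(trials$correct[prior_sel])

  acc <- function(lab, value) {
    sel <- informed & !is.na(lab) & lab == value
    c(k = sum(trials$correct[sel]), n = sum(sel))
  }

  labels <- enumerate_sequences(dims, h)
  rows <- lapply(labels, function(L) {
    m <- acc(joint, L)
    la <- sequence_marginal(L, dims, dims_a)
    lb <- sequence_marginal(L, dims, dims_b)
    a <- acc(lab_a, la)
    b <- acc(lab_b, lb)
    measured <- if (m["n"] > 0) m["k"] / m["n"] else NA_real_
    ci <- if (m["n"] > 0) agresti_coull_ci(m["k"], m["n"]) else
      list(low = NA_real_, high = NA_real_)
    p_a <- if (a["n"] > 0) a["k"] / a["n"] else NA_real_
    p_b <- if (b["n"] > 0) b["k"] / b["n"] else NA_real_
    predicted <- if (!is.na(p_a) && !is.na(p_b)) {
      predict_joint(p_a, p_b, prior_p)
    } else NA_real_
    span_pp <- (ci$high - ci$low) * 100
    tibble::tibble(label = L, label_a = la, label_b = lb,
                   n = as.integer(m["n"]), k = as.integer(m["k"]),
                   measured_p = unname(measured),
                   ci_low = unname(ci$low), ci_high = unname(ci$high),
                   p_a = unname(p_a), p_b = unname(p_b),
                   predicted_p = unname(predicted),
                   reliable = isTRUE(span_pp < ci_span_threshold) &&
                     !is.na(predicted), h = as.integer(h))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "prior") <- prior_p
  attr(out, "ci_span_threshold") <- ci_span_threshold
  class(out) <- c("interaction_points", class(out))
  out
}

#' @export
print.interaction_points <- function(x, ...) {
  if (all(c("h", "reliable") %in% names(x))) {
    cat(sprintf(
      "Interaction analysis: %d sequences (h = %d), %d reliable, prior = %.3f\n",
      nrow(x), x$h[1], sum(x$reliable), attr(x, "prior") %||% NA_real_))
  }
  NextMethod()
}

#' Slope of predicted versus measured accuracy
#'
#' Least-squares regression of the predicted accuracy on the measured
#' accuracy, restricted to reliable points. A slope near 1 indicates that
#' the joint effect of the two histories is predictable from their separate
#' effects (no interaction); a shallower slope indicates that the
#' prediction under-covers the extremes. The 95% CI is a percentile
#' bootstrap over points (seeded); the closed-form OLS CI is also returned.
#'
#' @param points An `interaction_points` tibble.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @return A list with `beta2`, `ci_low`, `ci_high` (bootstrap),
#'   `ols_ci_low`, `ols_ci_high`, `n_points`.
#' @export
interaction_slope <- function(points, n_boot = 10000, seed = 1) {
  pts <- points[points$reliable & !is.na(points$measured_p) &
                  !is.na(points$predicted_p), ]
  if (nrow(pts) < 3) abort("interaction_slope needs at least 3 reliable points")
  fit <- lm(predicted_p ~ measured_p, data = pts)
  beta2 <- unname(coef(fit)[2])
  ols_ci <- suppressWarnings(confint(fit, "measured_p", level = 0.95))
  slope_of <- function(idx) {
    x <- pts$measured_p[idx]; y <- pts$predicted_p[idx]
    if (length(unique(x)) < 2) return(NA_real_)
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  boot <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    vapply(seq_len(n_boot), function(i) {
      slope_of(sample.int(nrow(pts), nrow(pts), replace = TRUE))
    }, numeric(1))
  })
  qs <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(beta2 = beta2, ci_low = qs[1], ci_high = qs[2],
       ols_ci_low = unname(ols_ci[1]), ols_ci_high = unname(ols_ci[2]),
       n_points = nrow(pts))
}
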