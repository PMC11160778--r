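# Cross-subject alignment of tachometric curves. One curve is rescaled and
# shifted, z(j) = g * y2(j + delta) + b, and (g, b, delta) are chosen to
# minimize the mean absolute deviation from the reference curve over the
# bins where both are defined. Only delta is propagated to the trial data
# (as an RT shift); g and b are alignment diagnostics.

#' Gain/baseline/shift transform of a tachometric curve
#'
#' Returns the curve whose value at bin center `j` is
#' `g * y(j + delta) + b`, where `y` is the input curve's fraction correct.
#' Bins shifted outside the input grid become undefined. `delta` must be a
#' multiple of the curve's grid step.
#'
#' @param curve A `tachometric_curve`.
#' @param g Gain applied to the fraction correct.
#' @param b Baseline shift added after the gain.
#' @param delta Shift along the PT axis, ms (positive moves features
#'   leftward on the transformed grid).
#' @return A tibble with `pt` and transformed `fraction_correct` (plus the
#'   source bin counts, `NA` where undefined).
#' @export
transform_curve <- function(curve, g = 1, b = 0, delta = 0) {
  step <- attr(curve, "step_ms") %||% diff(curve$pt[1:2])
  shift_bins <- delta / step
  if (abs(shift_bins - round(shift_bins)) > 1e-9) {
    abort("delta must be a multiple of the curve's step_ms")
  }
  shift_bins <- as.integer(round(shift_bins))
  n <- nrow(curve)
  src <- seq_len(n) + shift_bins
  ok <- src >= 1L & src <= n
  frac <- n_tr <- rep(NA_real_, n)
  frac[ok] <- g * curve$fraction_correct[src[ok]] + b
  n_tr[ok] <- curve$n_trials[src[ok]]
  out <- tibble::tibble(pt = curve$pt, fraction_correct = frac,
                        n_trials = n_tr)
  attr(out, "bin_width_ms") <- attr(curve, "bin_width_ms")
  attr(out, "step_ms") <- step
  out
}

#' Optimal alignment of two tachometric curves
#'
#' Finds the gain `g`, baseline `b`, and PT shift `delta` minimizing the
#' mean absolute deviation between `curve1` and the transformed `curve2`
#' over their overlapping defined bins. `delta` is searched exhaustively on
#' the curve's grid step; for each `(delta, g)` the L1-optimal baseline is
#' the median residual (clamped to `b_range`), so no grid in `b` is needed.
#' Ties (objectives equal to within 1e-12) are broken by smallest
#' `|delta|`, then smallest `|b|`, then `g` closest to 1.
#'
#' @param curve1 Reference `tachometric_curve`.
#' @param curve2 Curve to be transformed onto `curve1`.
#' @param delta_range Search range for `delta` in ms (default `c(-60, 60)`),
#'   stepped at the curves' grid step.
#' @param g_range,g_step Gain search grid (default 0.5-1.5 by 0.01).
#' @param b_range Admissible baseline range (default `c(-0.25, 0.25)`).
#' @param min_overlap Minimum number of overlapping defined bins for a
#'   candidate `delta` to be admissible (default 10).
#' @return A list of class `alignment_params`: `g`, `b`, `delta`,
#'   `objective` (mean absolute deviation per overlapping bin), `n_overlap`.
#' @export
align_curves <- function(curve1, curve2, delta_range = c(-60, 60),
                         g_range = c(0.5, 1.5), g_step = 0.01,
                         b_range = c(-0.25, 0.25), min_overlap = 10) {
  if (!isTRUE(all.equal(curve1$pt, curve2$pt))) {
    abort("curves must share bin centers and parameters")
  }
  step <- attr(curve1, "step_ms") %||% diff(curve1$pt[1:2])
  deltas <- seq(ceiling(delta_range[1] / step) * step,
                floor(delta_range[2] / step) * step, by = step)
  gs <- seq(g_range[1], g_range[2], by = g_step)
  y1 <- curve1$fraction_correct
  y2 <- curve2$fraction_correct
  n <- length(y1)

  best <- NULL
  cand <- list()
  for (delta in deltas) {
    sb <- as.integer(round(delta / step))
    src <- seq_len(n) + sb
    ok <- src >= 1L & src <= n
    idx <- which(ok)
    y2s <- y2[src[idx]]
    keep <- !is.na(y1[idx]) & !is.na(y2s)
    if (sum(keep) < min_overlap) next
    a <- y1[idx][keep]
    z <- y2s[keep]
    for (g in gs) {
      r <- a - g * z
      b <- min(max(median(r), b_range[1]), b_range[2])
      obj <- mean(abs(r - b))
      cand[[length(cand) + 1L]] <- c(delta = delta, g = g, b = b, obj = obj,
                                     n_overlap = sum(keep))
    }
  }
  if (length(cand) == 0) {
    abort("no admissible overlap at any candidate delta")
  }
  m <- do.call(rbind, cand)
  tied <- which(m[, "obj"] <= min(m[, "obj"]) + 1e-12)
  pick <- tied[order(abs(m[tied, "delta"]), abs(m[tied, "b"]),
                     abs(m[tied, "g"] - 1))][1]
  structure(list(g = unname(m[pick, "g"]), b = unname(m[pick, "b"]),
                 delta = unname(m[pick, "delta"]),
                 objective = unname(m[pick, "obj"]),
                 n_overlap = unname(m[pick, "n_overlap"])),
            class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat(sprintf(
    "Curve alignment: g = %.3f, b = %.3f, delta = %g ms (objective %.4g over %d bins)\n",
    x$g, x$b, x$delta, x$objective, x$n_overlap))
  invisible(x)
}

#' Pool trial sets across subjects after per-subject RT shifts
#'
#' Applies [shift_rts()] to each subject's trials with that subject's shift
#' (the `delta` from [align_curves()]) and concatenates the results into one
#' trial stream for pooled analyses. Subjects without an entry in `shifts`
#' are shifted by 0.
#'
#' @param trials_by_subject Named list of trial tables, one per subject, or
#'   a single trial table (split internally on `subject_id`).
#' @param shifts Named numeric vector of per-subject RT shifts in ms.
#' @return A single trial table containing all (shifted) trials.
#' @export
pool_subjects <- function(trials_by_subject, shifts = numeric()) {
  if (is.data.frame(trials_by_subject)) {
    trials_by_subject <- split(trials_by_subject,
                               trials_by_subject$subject_id)
  }
  shifted <- lapply(names(trials_by_subject), function(s) {
    d <- if (s %in% names(shifts)) shifts[[s]] else 0
    shift_rts(trials_by_subject[[s]], d)
  })
  dplyr::bind_rows(shifted)
}
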