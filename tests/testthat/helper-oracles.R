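# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive every quantity from first principles (explicit
# loops, materialized predecessor windows) so they share no code with the
# package implementations they check.

# minimal trial table from parallel vectors; fills plausible timing fields
# when only the sequence structure matters
make_trials <- function(colors = NULL, quadrants = NULL, correct = NULL,
                        pt = NULL, rt = NULL, gap = NULL,
                        subject = "s", session = "a") {
  n <- max(length(colors), length(quadrants), length(correct),
           length(pt), length(rt), length(gap))
  if (is.null(quadrants)) quadrants <- rep("right", n)
  if (is.null(colors)) colors <- rep("red", n)
  if (is.null(correct)) correct <- rep(TRUE, n)
  if (is.null(gap)) gap <- rep(100, n)
  if (is.null(rt) && is.null(pt)) pt <- rep(200, n)
  if (is.null(rt)) rt <- pt + gap
  pt <- rt - gap  # enforce the exact identity against float round-off
  choice <- ifelse(correct, quadrants,
                   vapply(quadrants, function(q) {
                     setdiff(c("right", "up", "left", "down"), q)[1]
                   }, character(1)))
  tibble::tibble(subject_id = subject, session_id = session,
                 trial_index = seq_len(n) - 1L, gap_ms = gap, rt_ms = rt,
                 pt_ms = pt, target_color = colors,
                 target_quadrant = quadrants, choice_quadrant = choice,
                 correct = correct)
}

# a random multi-session trial table for property tests (independent of the
# package's generator)
random_sessions <- function(n_sessions, max_trials, seed) {
  set.seed(seed)
  quads <- c("right", "up", "left", "down")
  dplyr::bind_rows(lapply(seq_len(n_sessions), function(s) {
    n <- sample.int(max_trials, 1)
    make_trials(colors = sample(c("red", "green"), n, TRUE),
                quadrants = sample(quads, n, TRUE),
                correct = sample(c(TRUE, FALSE), n, TRUE),
                pt = runif(n, -50, 350),
                session = sprintf("sess%02d", s))
  }))
}

# brute-force run-mode label: materialize the N predecessors and test the
# definition directly
oracle_run_label <- function(values, i, n, same_fun, diff_fun) {
  if (i - n < 1) return(NA_character_)
  window <- values[(i - n):(i - 1)]
  if (all(same_fun(window, values[i]))) return("S")
  if (all(diff_fun(window, values[i]))) return("D")
  NA_character_
}

oracle_color_history <- function(trials, n) {
  out <- rep(NA_character_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    ses <- trials$session_id == trials$session_id[i] &
      trials$subject_id == trials$subject_id[i]
    v <- trials$target_color[ses]
    j <- sum(ses[seq_len(i)])
    out[i] <- oracle_run_label(v, j, n,
                               function(w, c) w == c, function(w, c) w != c)
  }
  out
}

oracle_location_history <- function(trials, n) {
  out <- rep(NA_character_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    ses <- trials$session_id == trials$session_id[i] &
      trials$subject_id == trials$subject_id[i]
    v <- trials$target_quadrant[ses]
    j <- sum(ses[seq_len(i)])
    out[i] <- oracle_run_label(v, j, n,
                               function(w, c) w == c, function(w, c) w != c)
  }
  out
}

oracle_outcome_history <- function(trials, n) {
  out <- rep(NA_character_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    ses <- trials$session_id == trials$session_id[i] &
      trials$subject_id == trials$subject_id[i]
    v <- trials$correct[ses]
    j <- sum(ses[seq_len(i)])
    if (j - n < 1) next
    w <- v[(j - n):(j - 1)]
    out[i] <- if (all(w)) "C" else if (all(!w)) "E" else NA_character_
  }
  out
}

# brute-force sequence-mode label (letters oldest -> newest)
oracle_sequence <- function(trials, dims, h) {
  out <- rep(NA_character_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    ses <- which(trials$session_id == trials$session_id[i] &
                   trials$subject_id == trials$subject_id[i])
    j <- match(i, ses)
    if (j - h < 1) next
    groups <- character(0)
    for (k in seq(h, 1)) {
      prev <- ses[j - k]
      letters_k <- ""
      if ("color" %in% dims) {
        letters_k <- paste0(letters_k,
          if (trials$target_color[prev] == trials$target_color[i]) "S" else "D")
      }
      if ("location" %in% dims) {
        letters_k <- paste0(letters_k,
          if (trials$target_quadrant[prev] == trials$target_quadrant[i]) "S" else "D")
      }
      if ("outcome" %in% dims) {
        letters_k <- paste0(letters_k, if (trials$correct[prev]) "C" else "E")
      }
      groups <- c(groups, letters_k)
    }
    out[i] <- paste(groups, collapse = if (h > 1) "-" else "")
  }
  out
}

# brute-force single-event membership
oracle_single_event <- function(trials, dimension, relation, lag) {
  out <- rep(NA, nrow(trials))
  v <- if (dimension == "color") trials$target_color else trials$target_quadrant
  for (i in seq_len(nrow(trials))) {
    ses <- which(trials$session_id == trials$session_id[i] &
                   trials$subject_id == trials$subject_id[i])
    j <- match(i, ses)
    if (j - lag < 1) next
    same <- v[ses[j - lag]] == v[i]
    out[i] <- if (relation == "S") same else !same
  }
  out
}

# naive double-loop tachometric counter
oracle_tachometric <- function(pt, correct, centers, width) {
  n <- k <- integer(length(centers))
  for (ci in seq_along(centers)) {
    lo <- centers[ci] - width / 2
    hi <- centers[ci] + width / 2
    for (t in seq_along(pt)) {
      if (pt[t] >= lo && pt[t] < hi) {
        n[ci] <- n[ci] + 1L
        if (correct[t]) k[ci] <- k[ci] + 1L
      }
    }
  }
  list(n = n, k = k)
}

# smooth tachometric-shaped curve object on a 1-ms grid, optionally with
# binomial sampling noise
smooth_curve <- function(frac, pt_grid = seq(-50, 400, 1), n_per_bin = 200,
                         noisy = FALSE) {
  k <- if (noisy) rbinom(length(frac), n_per_bin, frac) else
    round(n_per_bin * frac)
  f <- if (noisy) k / n_per_bin else frac
  out <- tibble::tibble(pt = pt_grid, n_trials = n_per_bin, n_correct = k,
                        fraction_correct = f, ci_low = NA_real_,
                        ci_high = NA_real_)
  attr(out, "bin_width_ms") <- 50
  attr(out, "step_ms") <- 1
  class(out) <- c("tachometric_curve", class(out))
  out
}

longest_true_run <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}
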