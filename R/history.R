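# Selection-history classification.
#
# Two schemes coexist in the analyses:
#  * run mode ("at least N"): the N immediately preceding trials form a
#    homogeneous run (all same color -> NS, all different -> ND, all
#    correct -> NC, ...). Used for the 1S..4S / 1D..4D conditioning.
#  * sequence mode: each of the H preceding trials carries its own relation
#    letter(s), giving (alphabet size)^H distinct labels per depth. Used for
#    the interaction analysis (e.g. 16 color-location sequences at H = 2).
#
# Histories never cross session boundaries: a trial with fewer than the
# required within-session predecessors belongs to no condition (NA).

.history_dims <- c("color", "location", "outcome")

# lag within contiguous session blocks: value k rows back, NA if that row
# belongs to a different (subject, session) or falls off the front.
session_lag <- function(x, key, k) {
  n <- length(x)
  out <- rep(x[NA_integer_], length.out = n)  # NA of x's type
  if (n == 0 || k >= n) return(out)
  idx <- seq_len(n) - k
  ok <- idx >= 1L
  ok[ok] <- key[idx[ok]] == key[seq_len(n)][ok]
  out[ok] <- x[idx[ok]]
  out
}

.session_key <- function(trials) {
  paste(trials$subject_id, trials$session_id, sep = "\r")
}

# per-trial relation letter of the trial `k` back, or NA
.relation_letters <- function(trials, dimension, k, key = .session_key(trials)) {
  switch(dimension,
    color = {
      prev <- session_lag(trials$target_color, key, k)
      ifelse(is.na(prev), NA_character_,
             ifelse(prev == trials$target_color, "S", "D"))
    },
    location = {
      prev <- session_lag(trials$target_quadrant, key, k)
      ifelse(is.na(prev), NA_character_,
             ifelse(prev == trials$target_quadrant, "S", "D"))
    },
    outcome = {
      prev <- session_lag(trials$correct, key, k)
      ifelse(is.na(prev), NA_character_, ifelse(prev, "C", "E"))
    },
    abort(sprintf("unknown history dimension '%s'", dimension))
  )
}

.check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("history depth N must be an integer >= 1")
  }
  as.integer(n)
}

# Run-mode classifiers ----------------------------------------------------

#' Classify trials by target-color history (run mode)
#'
#' A trial is `"S"` if its `n` immediately preceding same-session trials all
#' had the same target color as the current trial, `"D"` if they all had the
#' opposing color, and `NA` otherwise (mixed run, or fewer than `n`
#' within-session predecessors). "At least N" semantics hold: every
#' `(N+1)`-deep member is also an `N`-deep member.
#'
#' @param trials Trial table, ordered by trial index within each session.
#' @param n Run depth (number of constrained preceding trials), `>= 1`.
#' @return Character vector (`"S"`, `"D"`, or `NA`) aligned with the rows of
#'   `trials`.
#' @export
classify_color_history <- function(trials, n = 1) {
  classify_joint_history(trials, "color", n)
}

#' Classify trials by target-location history (run mode)
#'
#' `"S"` requires all `n` preceding target quadrants to equal the current
#' trial's target quadrant; `"D"` requires each of them to differ from it
#' (the predecessors need not match one another).
#'
#' @inheritParams classify_color_history
#' @return Character vector (`"S"`, `"D"`, or `NA`).
#' @export
classify_location_history <- function(trials, n = 1) {
  classify_joint_history(trials, "location", n)
}

#' Classify trials by outcome history (run mode)
#'
#' `"C"` if the `n` immediately preceding same-session trials were all
#' correct, `"E"` if all were errors, `NA` otherwise. The current trial's
#' own outcome plays no role.
#'
#' @inheritParams classify_color_history
#' @return Character vector (`"C"`, `"E"`, or `NA`).
#' @export
classify_outcome_history <- function(trials, n = 1) {
  classify_joint_history(trials, "outcome", n)
}

#' Classify trials by a joint history run
#'
#' Conjunction of per-dimension run conditions over the same `n` preceding
#' trials. For example, with `dims = c("color", "outcome")` and `n = 1`, a
#' trial whose predecessor had the same color and was correct is labeled
#' `"SC"`; with `dims = c("color", "location", "outcome")` a trial preceded
#' by a same-color, same-location, correct trial is `"SSC"`. A trial whose
#' window is mixed along any requested dimension is `NA`.
#'
#' @param trials Trial table, ordered by trial index within each session.
#' @param dims Subset of `c("color", "location", "outcome")`.
#' @param n Run depth, `>= 1`.
#' @return Character vector of joint labels (letters in the order color,
#'   location, outcome) or `NA`.
#' @export
classify_joint_history <- function(trials, dims, n = 1) {
  n <- .check_n(n)
  dims <- .order_dims(dims)
  key <- .session_key(trials)
  label <- rep("", nrow(trials))
  defined <- rep(TRUE, nrow(trials))
  for (d in dims) {
    first <- .relation_letters(trials, d, 1L, key)
    ok <- !is.na(first)
    if (n > 1) {
      for (k in 2:n) {
        rk <- .relation_letters(trials, d, k, key)
        ok <- ok & !is.na(rk) & rk == first
      }
    }
    defined <- defined & ok
    label <- paste0(label, first)
  }
  label[!defined] <- NA_character_
  label
}

.order_dims <- function(dims) {
  dims <- unique(dims)
  if (length(dims) == 0 || !all(dims %in% .history_dims)) {
    abort("dims must be a non-empty subset of c('color', 'location', 'outcome')")
  }
  .history_dims[.history_dims %in% dims]
}

# Lagged single events ----------------------------------------------------

#' Classify trials by a single lagged history event
#'
#' Membership in the `1S(lag-1)x` / `1D(lag-1)x` conditions used to track
#' how quickly the influence of a single past target fades: a trial is a
#' member iff the trial exactly `lag` positions earlier in the same session
#' bears the stated relation (same/different color or quadrant) to the
#' current trial; the `lag - 1` intervening trials are unconstrained. With
#' `lag = 1` this reduces exactly to the run-mode classification at depth 1.
#'
#' @param trials Trial table, ordered by trial index within each session.
#' @param dimension `"color"` or `"location"`.
#' @param relation `"S"` (repeat) or `"D"` (switch).
#' @param lag Positions back to the constrained trial, `>= 1`.
#' @return Logical vector: `TRUE` member, `FALSE` non-member, `NA` if the
#'   trial has fewer than `lag` within-session predecessors.
#' @export
classify_single_event <- function(trials, dimension = c("color", "location"),
                                  relation = c("S", "D"), lag = 1) {
  dimension <- match.arg(dimension)
  relation <- match.arg(relation)
  lag <- .check_n(lag)
  rel <- .relation_letters(trials, dimension, lag)
  ifelse(is.na(rel), NA, rel == relation)
}

# Sequence mode -----------------------------------------------------------

.dim_alphabet <- function(d) {
  if (d == "outcome") c("E", "C") else c("D", "S")
}

#' Enumerate all joint history sequences of a given depth
#'
#' In sequence mode each of the `h` preceding trials carries its own
#' relation letter per dimension, so the label space is the Cartesian
#' product of per-trial letter groups. Labels list the past trials oldest to
#' newest; within a trial, letters follow the order color, location,
#' outcome. Past trials are separated by `"-"` when `h > 1`.
#'
#' @param dims Subset of `c("color", "location", "outcome")`.
#' @param h History depth (number of preceding trials), `>= 1`.
#' @return Character vector of `prod(alphabet sizes)^h` labels.
#' @examples
#' enumerate_sequences(c("color", "location"), 1)  # "DD" "SD" "DS" "SS"
#' length(enumerate_sequences(c("color", "location"), 2))  # 16
#' @export
enumerate_sequences <- function(dims, h = 1) {
  h <- .check_n(h)
  dims <- .order_dims(dims)
  group_alphabet <- do.call(paste0, expand.grid(lapply(dims, .dim_alphabet),
                                                stringsAsFactors = FALSE))
  grids <- rep(list(group_alphabet), h)
  # oldest trial's letters vary fastest; join oldest -> newest
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  apply(as.matrix(combos), 1L, paste, collapse = if (h > 1) "-" else "")
}

#' Classify trials by their full history sequence
#'
#' Assigns each trial its sequence-mode label: one relation letter per
#' requested dimension for each of the `h` preceding same-session trials
#' (oldest to newest, `"-"`-separated when `h > 1`), matching the labels of
#' [enumerate_sequences()]. Trials with fewer than `h` within-session
#' predecessors are `NA`.
#'
#' @inheritParams enumerate_sequences
#' @param trials Trial table, ordered by trial index within each session.
#' @return Character vector of labels or `NA`, aligned with `trials`.
#' @export
classify_sequence <- function(trials, dims, h = 1) {
  h <- .check_n(h)
  dims <- .order_dims(dims)
  key <- .session_key(trials)
  groups <- vector("list", h)
  defined <- rep(TRUE, nrow(trials))
  for (k in seq_len(h)) {
    letters_k <- rep("", nrow(trials))
    for (d in dims) {
      rel <- .relation_letters(trials, d, k, key)
      defined <- defined & !is.na(rel)
      letters_k <- paste0(letters_k, rel)
    }
    groups[[k]] <- letters_k
  }
  # groups[[k]] is k trials back; oldest (k = h) comes first in the label
  label <- do.call(paste, c(rev(groups), sep = if (h > 1) "-" else ""))
  label[!defined] <- NA_character_
  label
}

# drop letter positions to obtain a marginal sequence label
sequence_marginal <- function(labels, dims, keep) {
  dims <- .order_dims(dims)
  keep <- .order_dims(keep)
  pos <- match(keep, dims)
  if (any(is.na(pos))) abort("keep must be a subset of dims")
  groups <- strsplit(labels, "-", fixed = TRUE)
  vapply(groups, function(g) {
    if (anyNA(g)) return(NA_character_)
    paste(vapply(g, function(s) {
      paste(strsplit(s, "")[[1]][pos], collapse = "")
    }, character(1)), collapse = if (length(g) > 1) "-" else "")
  }, character(1))
}
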