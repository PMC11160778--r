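#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats median qnorm pnorm plogis qlogis quantile sd optim lm coef confint setNames runif
NULL

# Canonical trial-table schema -------------------------------------------

#' Canonical column names of a trial table
#'
#' A trial table holds one row per behavioral trial of an urgent oddball
#' search task: the subject and session identifiers, the within-session
#' trial index (temporal order), the Gap duration (go signal to cue onset,
#' ms), the reaction time (go signal to saccade onset, ms), the derived
#' processing time `pt_ms = rt_ms - gap_ms` (cue viewing time, may be
#' negative), the target color (`"red"`/`"green"`), the target and chosen
#' quadrants (`"right"`, `"up"`, `"left"`, `"down"`), and the outcome flag
#' `correct`. Optional columns `target_x_deg`/`target_y_deg` give the target
#' position in degrees of visual angle, from which the quadrant can be
#' derived via [assign_quadrant()].
#'
#' @return Character vector of required column names.
#' @export
trial_columns <- function() {
  c("subject_id", "session_id", "trial_index", "gap_ms", "rt_ms", "pt_ms",
    "target_color", "target_quadrant", "choice_quadrant", "correct")
}

.colors    <- c("red", "green")
.quadrants <- c("right", "up", "left", "down")

#' Colors and quadrants of the task
#'
#' The task uses two target colors and four stimulus quadrants; these
#' helpers expose the canonical level sets.
#'
#' @return Character vector of levels.
#' @export
task_colors <- function() .colors

#' @rdname task_colors
#' @export
task_quadrants <- function() .quadrants

#' Validate a trial table
#'
#' Checks the canonical schema and its invariants: `pt_ms == rt_ms - gap_ms`
#' exactly, `correct == (choice_quadrant == target_quadrant)`, and legal
#' factor levels. Used internally by every analysis entry point.
#'
#' @param trials A data frame with the columns of [trial_columns()].
#' @param check_pt If `TRUE` (default) enforce the processing-time identity.
#' @return The input, invisibly, as a tibble.
#' @export
validate_trials <- function(trials, check_pt = TRUE) {
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(trial_columns(), names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("trial table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(trials) == 0) return(invisible(trials))
  if (!all(trials$target_color %in% .colors)) {
    abort("target_color must be one of: red, green")
  }
  bad_quad <- !(trials$target_quadrant %in% .quadrants) |
    !(trials$choice_quadrant %in% .quadrants)
  if (any(bad_quad)) {
    abort("quadrants must be one of: right, up, left, down")
  }
  if (check_pt) {
    dev <- trials$pt_ms - (trials$rt_ms - trials$gap_ms)
    if (any(dev != 0, na.rm = TRUE)) {
      abort("pt_ms must equal rt_ms - gap_ms exactly")
    }
  }
  mismatch <- trials$correct != (trials$choice_quadrant == trials$target_quadrant)
  if (any(mismatch, na.rm = TRUE)) {
    abort(sprintf(
      "`correct` disagrees with choice_quadrant == target_quadrant in %d row(s)",
      sum(mismatch, na.rm = TRUE)))
  }
  invisible(trials)
}

# Derived quantities -----------------------------------------------------

#' Processing time of a trial
#'
#' The processing time (PT) is the nominal cue viewing time: the reaction
#' time minus the Gap between the go signal and cue onset. Negative values
#' are legitimate (the saccade was launched before the cue appeared).
#'
#' @param rt_ms Reaction time(s) in ms, finite.
#' @param gap_ms Gap duration(s) in ms, finite.
#' @return `rt_ms - gap_ms`, in ms.
#' @examples
#' compute_pt(250, 100)  # 150
#' compute_pt(200, 225)  # -25, saccade launched before the cue
#' @export
compute_pt <- function(rt_ms, gap_ms) {
  if (!is.numeric(rt_ms) || !is.numeric(gap_ms) ||
      any(!is.finite(rt_ms)) || any(!is.finite(gap_ms))) {
    abort("rt_ms and gap_ms must be finite numeric")
  }
  rt_ms - gap_ms
}

#' Assign a stimulus position to a task quadrant
#'
#' Positions are mapped to the four quadrant labels counter-clockwise with
#' half-open 90-degree sectors anchored on the axes: the positive x axis and
#' the interior of the upper-right quadrant are `right`; the positive y axis
#' and the upper-left quadrant are `up`; the negative x axis and the
#' lower-left quadrant are `left`; the negative y axis and the lower-right
#' quadrant are `down`. Equivalently, with `theta = atan2(y, x)` in
#' `[0, 360)`: right = `[0, 90)`, up = `[90, 180)`, left = `[180, 270)`,
#' down = `[270, 360)`.
#'
#' @param x_deg,y_deg Position in degrees of visual angle; vectors recycle.
#' @return Character vector of quadrant labels.
#' @examples
#' assign_quadrant(5, 0)    # "right"
#' assign_quadrant(0, 7)    # "up"
#' assign_quadrant(-3, -4)  # "left"
#' @export
assign_quadrant <- function(x_deg, y_deg) {
  if (any(x_deg == 0 & y_deg == 0)) {
    abort("quadrant undefined at the origin (0, 0)")
  }
  theta <- atan2(y_deg, x_deg)            # (-pi, pi]
  theta <- ifelse(theta < 0, theta + 2 * pi, theta)
  sector <- floor(theta / (pi / 2)) %% 4  # 0..3 counter-clockwise from +x
  .quadrants[sector + 1L]
}

# I/O --------------------------------------------------------------------

#' Load a trial table from a delimited text file
#'
#' Reads a comma-separated trial table with a header naming the canonical
#' fields (see [trial_columns()]). `pt_ms` and `target_quadrant` may be
#' absent and are then derived (from `rt_ms - gap_ms` and from
#' `target_x_deg`/`target_y_deg` respectively). Rows with unparseable or
#' missing required values, and duplicate `(session_id, trial_index)` rows,
#' are skipped with a warning and collected in the load report. If the file
#' carries a `correct` column it is cross-checked against the quadrants; a
#' mismatch is a hard error, catching mis-coded inputs early.
#'
#' @param path Path to a delimited text file.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(rt_ms = "RT")`, or the path to a
#'   YAML/JSON file holding such a mapping.
#' @return A tibble of trials sorted by `(subject_id, session_id,
#'   trial_index)`, with a `"load_report"` attribute: a list with `n_parsed`,
#'   `n_derived_pt`, `n_derived_quadrant`, `n_rejected`, and `rejected` (a
#'   tibble of row numbers and reasons).
#' @export
load_trials <- function(path, column_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.character(column_map) && is.null(names(column_map)) &&
      length(column_map) == 1 && file.exists(column_map)) {
    column_map <- if (grepl("\\.ya?ml$", column_map)) {
      unlist(yaml::read_yaml(column_map))
    } else {
      unlist(jsonlite::read_json(column_map))
    }
  }
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        abort(sprintf("column_map names '%s' but the file has no column '%s'",
                      canon, src))
      }
      names(raw)[names(raw) == src] <- canon
    }
  }

  required <- c("subject_id", "session_id", "trial_index", "gap_ms", "rt_ms",
                "target_color", "choice_quadrant")
  missing_cols <- setdiff(required, names(raw))
  has_xy <- all(c("target_x_deg", "target_y_deg") %in% names(raw))
  if (!"target_quadrant" %in% names(raw) && !has_xy) {
    missing_cols <- c(missing_cols, "target_quadrant (or target_x_deg/target_y_deg)")
  }
  if (length(missing_cols) > 0) {
    abort(paste0("required columns missing from ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }

  rejected <- tibble::tibble(row = integer(), reason = character())
  reject <- function(rows, reason) {
    if (length(rows) > 0) {
      rejected <<- dplyr::bind_rows(rejected,
                                    tibble::tibble(row = rows, reason = reason))
    }
  }

  raw$.row <- seq_len(nrow(raw))
  num_cols <- intersect(c("trial_index", "gap_ms", "rt_ms", "pt_ms",
                          "target_x_deg", "target_y_deg"), names(raw))
  for (cc in num_cols) raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))

  bad <- !is.finite(raw$rt_ms) | !is.finite(raw$gap_ms) |
    !is.finite(raw$trial_index) |
    is.na(raw$target_color) | !(raw$target_color %in% .colors) |
    is.na(raw$choice_quadrant) | !(raw$choice_quadrant %in% .quadrants)
  reject(raw$.row[bad], "unparseable or missing required value")
  raw <- raw[!bad, , drop = FALSE]

  dup <- duplicated(raw[, c("session_id", "trial_index")])
  reject(raw$.row[dup], "duplicate (session_id, trial_index)")
  raw <- raw[!dup, , drop = FALSE]

  n_derived_pt <- 0L
  if (!"pt_ms" %in% names(raw)) {
    raw$pt_ms <- raw$rt_ms - raw$gap_ms
    n_derived_pt <- nrow(raw)
  } else {
    fill <- !is.finite(raw$pt_ms)
    n_derived_pt <- sum(fill)
    # beyond printed precision the stated PT contradicts RT - Gap: reject
    off <- !fill & abs(raw$pt_ms - (raw$rt_ms - raw$gap_ms)) > 1e-6
    reject(raw$.row[off], "pt_ms inconsistent with rt_ms - gap_ms")
    raw <- raw[!off, , drop = FALSE]
    # re-derive so the identity holds exactly for every loaded record
    raw$pt_ms <- raw$rt_ms - raw$gap_ms
  }

  n_derived_quadrant <- 0L
  if (!"target_quadrant" %in% names(raw)) {
    raw$target_quadrant <- assign_quadrant(raw$target_x_deg, raw$target_y_deg)
    n_derived_quadrant <- nrow(raw)
  }
  bad_q <- !(raw$target_quadrant %in% .quadrants)
  reject(raw$.row[bad_q], "invalid target_quadrant")
  raw <- raw[!bad_q, , drop = FALSE]

  derived_correct <- raw$choice_quadrant == raw$target_quadrant
  if ("correct" %in% names(raw)) {
    prov <- as.logical(raw$correct)
    if (any(prov != derived_correct, na.rm = TRUE)) {
      abort("provided `correct` column disagrees with the quadrant columns")
    }
  }
  raw$correct <- derived_correct

  keep <- intersect(c(trial_columns(), "target_x_deg", "target_y_deg"),
                    names(raw))
  out <- tibble::as_tibble(raw[, keep, drop = FALSE])
  out <- dplyr::arrange(out, .data$subject_id, .data$session_id,
                        .data$trial_index)
  validate_trials(out)

  report <- list(n_parsed = nrow(out),
                 n_derived_pt = n_derived_pt,
                 n_derived_quadrant = n_derived_quadrant,
                 n_rejected = nrow(rejected),
                 rejected = rejected)
  if (nrow(rejected) > 0) {
    warn(sprintf("load_trials: skipped %d row(s); see attr(x, 'load_report')",
                 nrow(rejected)))
  }
  attr(out, "load_report") <- report
  out
}

#' Write a trial table to CSV
#'
#' @param trials A validated trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

# Filters and transforms -------------------------------------------------

#' Keep only valid task trials
#'
#' A valid trial has a finite reaction time within the allowed response
#' window (`rt_ms <= 450` by default). Order is preserved; the number of
#' removed trials is reported via `message()` when `quiet = FALSE`.
#'
#' @param trials Trial table.
#' @param max_rt_ms Response deadline in ms (default 450).
#' @param quiet Suppress the removal message.
#' @return Filtered trial table.
#' @export
filter_valid <- function(trials, max_rt_ms = 450, quiet = TRUE) {
  keep <- is.finite(trials$rt_ms) & trials$rt_ms <= max_rt_ms
  removed <- sum(!keep)
  if (!quiet && removed > 0) {
    inform(sprintf("filter_valid: removed %d of %d trials (RT > %g ms or non-finite)",
                   removed, length(keep), max_rt_ms))
  }
  trials[keep, , drop = FALSE]
}

#' Shift all reaction times of a trial set
#'
#' Subtracts `delta_ms` from every `rt_ms` and recomputes `pt_ms`; all other
#' fields are unchanged. Used to align one subject's trials to another's
#' before pooling (see [align_curves()] and [pool_subjects()]).
#'
#' @param trials Trial table.
#' @param delta_ms Amount subtracted from every RT, ms.
#' @return Shifted trial table.
#' @export
shift_rts <- function(trials, delta_ms) {
  stopifnot(is.numeric(delta_ms), length(delta_ms) == 1, is.finite(delta_ms))
  trials$rt_ms <- trials$rt_ms - delta_ms
  trials$pt_ms <- trials$rt_ms - trials$gap_ms
  trials
}
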