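test_that("color run classification matches the printed example sequences", {
  # red-red-red: the last trial is 2S (and therefore 1S)
  tr <- make_trials(colors = c("red", "red", "red"))
  expect_equal(classify_color_history(tr, 2)[3], "S")
  expect_equal(classify_color_history(tr, 1)[3], "S")
  # green-red: 1D
  tr2 <- make_trials(colors = c("green", "red"))
  expect_equal(classify_color_history(tr2, 1)[2], "D")
  # first trial of a session has no label at any depth
  expect_true(is.na(classify_color_history(tr, 1)[1]))
  expect_true(is.na(classify_color_history(tr, 3)[3]))
  # red-green-red: mixed window at N = 2
  tr3 <- make_trials(colors = c("red", "green", "red"))
  expect_true(is.na(classify_color_history(tr3, 2)[3]))
})

test_that("location runs: D needs all predecessors off-target, not matching each other", {
  expect_equal(classify_location_history(
    make_trials(quadrants = c("up", "right")), 1)[2], "D")
  expect_equal(classify_location_history(
    make_trials(quadrants = c("left", "down", "right")), 2)[3], "D")
  expect_equal(classify_location_history(
    make_trials(quadrants = c("down", "down", "down")), 2)[3], "S")
  # up-up-left is still 2D: predecessors may repeat among themselves
  expect_equal(classify_location_history(
    make_trials(quadrants = c("up", "up", "left")), 2)[3], "D")
  # at N = 1 every trial with a predecessor is S or D
  tr <- random_sessions(2, 30, seed = 3)
  lab <- classify_location_history(tr, 1)
  has_pred <- ave(seq_len(nrow(tr)), tr$session_id, FUN = seq_along) > 1
  expect_true(all(!is.na(lab[has_pred])))
  expect_true(all(is.na(lab[!has_pred])))
})

test_that("outcome runs follow correct/error windows, ignoring the current trial", {
  tr <- make_trials(correct = c(TRUE, FALSE))
  expect_equal(classify_outcome_history(tr, 1)[2], "C")
  tr2 <- make_trials(correct = c(FALSE, FALSE, TRUE))
  expect_equal(classify_outcome_history(tr2, 2)[3], "E")
  tr3 <- make_trials(correct = c(TRUE, FALSE, TRUE))
  expect_true(is.na(classify_outcome_history(tr3, 2)[3]))
})

test_that("joint run labels conjoin dimensions over the same window", {
  tr <- make_trials(colors = c("red", "red"), quadrants = c("up", "up"),
                    correct = c(TRUE, TRUE))
  expect_equal(classify_joint_history(tr, c("color", "outcome"), 1)[2], "SC")
  expect_equal(classify_joint_history(tr, c("color", "location", "outcome"),
                                      1)[2], "SSC")
  tr2 <- make_trials(colors = c("green", "red"), correct = c(FALSE, TRUE))
  expect_equal(classify_joint_history(tr2, c("color", "outcome"), 1)[2], "DE")
  # any mixed dimension voids the joint label
  tr3 <- make_trials(colors = c("red", "green", "red"),
                     correct = c(TRUE, TRUE, TRUE))
  expect_true(is.na(classify_joint_history(tr3, c("color", "outcome"), 2)[3]))
  expect_equal(classify_joint_history(tr3, "outcome", 2)[3], "C")
})

test_that("single lagged events: intervening trials are unconstrained", {
  tr <- make_trials(colors = c("red", "green", "green", "green", "green", "red"))
  expect_true(classify_single_event(tr, "color", "S", lag = 5)[6])   # 1S4x
  tr2 <- make_trials(quadrants = c("up", "left", "right", "down"))
  expect_true(classify_single_event(tr2, "location", "D", lag = 3)[4])  # 1D2x
  # lag 1 reduces exactly to the run classification at N = 1
  tr3 <- random_sessions(3, 25, seed = 9)
  ev <- classify_single_event(tr3, "color", "S", lag = 1)
  run <- classify_color_history(tr3, 1)
  expect_equal(ev, ifelse(is.na(run), NA, run == "S"))
  expect_error(classify_single_event(tr3, "color", "S", lag = 0), "integer")
})

test_that("sequence enumeration produces the full Cartesian label space", {
  expect_equal(enumerate_sequences(c("color", "location"), 1),
               c("DD", "SD", "DS", "SS"))
  e2 <- enumerate_sequences(c("color", "location"), 2)
  expect_length(e2, 16)
  expect_length(unique(e2), 16)
  expect_length(enumerate_sequences(c("color", "location", "outcome"), 1), 8)
  expect_length(enumerate_sequences(c("color", "outcome"), 3), 64)
  # every classified label belongs to the enumerated space
  tr <- random_sessions(2, 40, seed = 21)
  lab <- classify_sequence(tr, c("color", "location"), 2)
  expect_true(all(na.omit(lab) %in% e2))
})

test_that("run-mode nesting, disjointness, and session isolation hold", {
  tr <- random_sessions(4, 50, seed = 13)
  for (dim_fun in list(classify_color_history, classify_location_history)) {
    l1 <- dim_fun(tr, 1); l2 <- dim_fun(tr, 2); l3 <- dim_fun(tr, 3)
    # nesting: (N+1)-membership implies N-membership with the same relation
    expect_true(all(is.na(l2) | l2 == l1))
    expect_true(all(is.na(l3) | l3 == l2))
  }
  # session isolation: permuting session blocks never changes a label
  sessions <- unique(tr$session_id)
  perm <- dplyr::bind_rows(split(tr, tr$session_id)[rev(sessions)])
  for (n in 1:3) {
    orig <- classify_color_history(tr, n)
    shuf <- classify_color_history(perm, n)
    key_o <- paste(tr$session_id, tr$trial_index)
    key_p <- paste(perm$session_id, perm$trial_index)
    expect_equal(shuf[match(key_o, key_p)], orig)
  }
})

test_that("all classifiers match brute-force re-derivation on random sessions", {
  n_batches <- 10
  sessions_per_batch <- 10
  for (b in seq_len(n_batches)) {
    tr <- random_sessions(sessions_per_batch, 50, seed = 5000 + b)
    for (n in c(1, 2, 4)) {
      expect_equal(classify_color_history(tr, n), oracle_color_history(tr, n))
      expect_equal(classify_location_history(tr, n),
                   oracle_location_history(tr, n))
      expect_equal(classify_outcome_history(tr, n),
                   oracle_outcome_history(tr, n))
    }
    for (h in 1:2) {
      expect_equal(classify_sequence(tr, c("color", "location"), h),
                   oracle_sequence(tr, c("color", "location"), h))
      expect_equal(classify_sequence(tr, c("color", "location", "outcome"), h),
                   oracle_sequence(tr, c("color", "location", "outcome"), h))
    }
    for (lag in c(1, 3, 5)) {
      expect_equal(classify_single_event(tr, "color", "S", lag),
                   oracle_single_event(tr, "color", "S", lag))
      expect_equal(classify_single_event(tr, "location", "D", lag),
                   oracle_single_event(tr, "location", "D", lag))
    }
  }
})

test_that("joint runs equal the intersection of their marginal runs", {
  tr <- random_sessions(3, 40, seed = 77)
  for (n in 1:2) {
    joint <- classify_joint_history(tr, c("color", "outcome"), n)
    col <- classify_color_history(tr, n)
    out <- classify_outcome_history(tr, n)
    both <- !is.na(col) & !is.na(out)
    expect_equal(joint[both], paste0(col[both], out[both]))
    expect_true(all(is.na(joint[!both])))
  }
})
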