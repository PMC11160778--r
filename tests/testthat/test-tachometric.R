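test_that("Agresti-Coull intervals match the closed form and clip at 0/1", {
  ci <- agresti_coull_ci(50, 100)
  expect_equal(ci$low, 0.4038, tolerance = 1e-3)
  expect_equal(ci$high, 0.5962, tolerance = 1e-3)
  # frozen closed-form values: z = qnorm(0.975), nt = n + z^2,
  # pt = (k + z^2/2)/nt, hw = z sqrt(pt(1-pt)/nt)
  z <- qnorm(0.975)
  nt <- 100 + z^2; pt <- (50 + z^2 / 2) / nt
  expect_equal(ci$low, pt - z * sqrt(pt * (1 - pt) / nt), tolerance = 1e-12)
  expect_equal(agresti_coull_ci(0, 20)$low, 0)
  expect_equal(agresti_coull_ci(20, 20)$high, 1)
  expect_error(agresti_coull_ci(5, 0), "n >= 1")
  expect_error(agresti_coull_ci(-1, 10), "0 <= k <= n")
})

test_that("Agresti-Coull width shrinks like 1/sqrt(n)", {
  w <- function(k, n) diff(unlist(agresti_coull_ci(k, n)))
  ratio <- unname(w(2000, 4000) / w(4000, 8000))
  expect_equal(ratio, sqrt(2), tolerance = 0.05)
})

test_that("sliding bins are half-open and counted exactly", {
  # 10 trials at PT 91..100, alternating correct/error starting correct:
  # the bin centered at 100 covers [75, 125) and holds all 10
  tr <- make_trials(pt = 91:100, correct = rep(c(TRUE, FALSE), 5))
  cv <- compute_tachometric(tr, pt_range = c(60, 130))
  at100 <- cv[cv$pt == 100, ]
  expect_equal(at100$n_trials, 10L)
  expect_equal(at100$fraction_correct, 0.5)
  # half-open edges: bin at 116 covers [91, 141) and takes all 10 trials;
  # bin at 66 covers [41, 91) and excludes the PT = 91 trial entirely
  expect_equal(cv$n_trials[cv$pt == 116], 10L)
  expect_equal(cv$n_trials[cv$pt == 66], 0L)
  expect_equal(cv$n_trials[cv$pt == 125], 1L)  # [100, 150): only PT = 100

  # all-correct input gives fraction 1 wherever defined
  trc <- make_trials(pt = runif(50, 0, 300), correct = rep(TRUE, 50))
  cvc <- compute_tachometric(trc)
  expect_true(all(cvc$fraction_correct[cvc$n_trials > 0] == 1))
  # empty input: all bins undefined, not zero
  cve <- compute_tachometric(tr[0, ], pt_range = c(0, 100))
  expect_true(all(is.na(cve$fraction_correct)))
  expect_error(compute_tachometric(tr, bin_width_ms = 0), "bin_width")
})

test_that("tachometric counts match a naive double-loop oracle", {
  set.seed(17)
  tr <- make_trials(pt = runif(800, -60, 380),
                    correct = sample(c(TRUE, FALSE), 800, TRUE))
  cv <- compute_tachometric(tr, pt_range = c(-50, 350))
  orc <- oracle_tachometric(tr$pt_ms, tr$correct, cv$pt, 50)
  expect_equal(cv$n_trials, orc$n)
  expect_equal(cv$n_correct, orc$k)
})

test_that("bin counts aggregate additively over disjoint trial sets", {
  set.seed(23)
  a <- make_trials(pt = runif(300, 0, 300),
                   correct = sample(c(TRUE, FALSE), 300, TRUE))
  b <- make_trials(pt = runif(200, 0, 300),
                   correct = sample(c(TRUE, FALSE), 200, TRUE))
  rng <- c(0, 300)
  ca <- compute_tachometric(a, pt_range = rng)
  cb <- compute_tachometric(b, pt_range = rng)
  cab <- compute_tachometric(dplyr::bind_rows(a, b), pt_range = rng)
  expect_equal(cab$n_trials, ca$n_trials + cb$n_trials)
  expect_equal(cab$n_correct, ca$n_correct + cb$n_correct)
})

test_that("floor and ceiling summaries use strict PT cutoffs", {
  tr <- make_trials(pt = c(99.9, 100, 120, 150, 150.1),
                    correct = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  fl <- floor_accuracy(tr)
  ce <- ceiling_accuracy(tr)
  expect_equal(fl$n, 1L)            # only 99.9
  expect_equal(ce$n, 1L)            # only 150.1
  # 3 correct of 12 below 100
  tr2 <- make_trials(pt = rep(50, 12), correct = rep(c(TRUE, FALSE, FALSE,
                                                       FALSE), 3))
  expect_equal(floor_accuracy(tr2)$proportion, 0.25)
  # 66 of 100 above 150
  tr3 <- make_trials(pt = rep(200, 100), correct = c(rep(TRUE, 66),
                                                     rep(FALSE, 34)))
  expect_equal(ceiling_accuracy(tr3)$proportion, 0.66)
  # empty regions are flagged undefined
  expect_false(floor_accuracy(tr3)$defined)
  expect_false(ceiling_accuracy(tr2)$defined)
})

test_that("mean RT and SEM follow their definitions and ignore order", {
  tr <- make_trials(rt = c(200, 300), gap = c(0, 0))
  m <- mean_rt(tr)
  expect_equal(m$mean, 250)
  expect_equal(m$sem, 50)
  expect_true(is.na(mean_rt(tr[1, ])$sem))
  tr2 <- random_sessions(1, 30, seed = 2)
  expect_equal(mean_rt(tr2)$mean, mean_rt(tr2[rev(seq_len(nrow(tr2))), ])$mean)
})

test_that("difference curves subtract fractions and pool binomial errors", {
  f1 <- rep(0.7, 451); f2 <- rep(0.4, 451)
  c1 <- smooth_curve(f1); c2 <- smooth_curve(f2)
  d <- difference_curve(c1, c2)
  expect_true(all(abs(d$difference - 0.3) < 1e-12))
  se_expected <- sqrt(0.7 * 0.3 / 200 + 0.4 * 0.6 / 200)
  expect_true(all(abs(d$se - se_expected) < 1e-12))
  d0 <- difference_curve(c1, c1)
  expect_true(all(d0$difference == 0))
  expect_true(all(is.finite(d0$se)))
  c3 <- smooth_curve(rep(0.7, 101), pt_grid = seq(0, 100, 1))
  expect_error(difference_curve(c1, c3), "identical grids")
})

test_that("bootstrap comparison is seeded, null-calibrated, and sensitive", {
  set.seed(31)
  a <- make_trials(pt = rep(200, 400), correct = runif(400) < 0.7)
  b <- make_trials(pt = rep(200, 400), correct = runif(400) < 0.7)
  r1 <- resample_compare(a, b, "ceiling", n_boot = 2000, seed = 5)
  r2 <- resample_compare(a, b, "ceiling", n_boot = 2000, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(resample_compare(a, a, "ceiling", n_boot = 2000, seed = 6)$p_value,
            0.01)
  strong <- make_trials(pt = rep(200, 2000), correct = runif(2000) < 0.9)
  weak <- make_trials(pt = rep(200, 2000), correct = runif(2000) < 0.5)
  expect_lt(resample_compare(strong, weak, "ceiling", n_boot = 2000,
                             seed = 7)$p_value, 0.001)
  expect_error(resample_compare(a, b[0, ], "ceiling", seed = 1), "both groups")
  expect_error(resample_compare(a, b, "ceiling"), "seed")
})
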