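# Generative model of urgent oddball-search sessions.
#
# Each trial draws a target color (2 equiprobable), a target quadrant
# (4 equiprobable), a Gap from a discrete grid, and an RT from a truncated
# normal; PT = RT - Gap. The choice arbitrates between an informed read-out
# and a guess: with probability q(PT) = logistic((PT - center)/width) the
# choice is informed (target with probability p_ceil, else a uniform
# distracter); otherwise it is a guess drawn from a softmax over four
# location weights. Selection history enters through leaky-integrator
# latents: after every trial the four location weights decay by
# exp(-1/location_decay_trials) and the target's weight receives an
# outcome-signed increment (reward +kappa, error -kappa); the two color
# gains decay by exp(-1/color_decay_trials) and the target color's gain is
# incremented the same way. The ceiling is squashed through a logistic
# link, p_ceil = plogis(qlogis(ceiling_base) + color gain + interaction),
# so likelihoods stay smooth. With all kappas at 0 the agent is
# history-free: floor accuracy 0.25, ceiling ceiling_base, repetition
# priors 0.5 (color) and 0.25 (location).

#' Parameters of the synthetic session generator
#'
#' @param n_trials Trials per session.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @param gap_values Discrete Gap grid in ms (default 0 to 225 by 25).
#' @param rt_mean_ms,rt_sd_ms Truncated-normal RT parameters (defaults 275
#'   and 60 ms).
#' @param rt_min_ms,rt_max_ms RT truncation bounds (defaults 0 and 450 ms,
#'   the response deadline).
#' @param floor_base Chance accuracy implied by the 4-alternative geometry
#'   (0.25; informational, not tunable).
#' @param ceiling_base Asymptotic accuracy of informed choices with no
#'   history modulation (default 0.70).
#' @param sigmoid_center_ms,sigmoid_width_ms Center and width of the
#'   logistic guess-to-informed transition along PT (defaults 125 and 5 ms).
#'   The default width keeps the 1%-99% span of the transition (about 9.2
#'   widths) inside the 100-150 ms band, so the floor region (PT < 100) is
#'   pure guessing and the ceiling region (PT > 150) pure informed choice.
#' @param color_gain_kappa Outcome-signed increment to the target color's
#'   ceiling gain per trial (default 0).
#' @param color_decay_trials Decay constant of the color gains, in trials
#'   (default 5).
#' @param location_bias_kappa Outcome-signed increment to the target
#'   quadrant's guess weight per trial (default 0).
#' @param location_decay_trials Decay constant of the location weights, in
#'   trials (default 9).
#' @param interaction_strength Coefficient of the color-gain x
#'   location-weight product added to the ceiling latent; 0 (default) makes
#'   color and location histories act conditionally independently.
#' @return A list of class `generative_params`.
#' @export
generative_params <- function(n_trials = 1000, seed = 1,
                              gap_values = seq(0, 225, by = 25),
                              rt_mean_ms = 275, rt_sd_ms = 60,
                              rt_min_ms = 0, rt_max_ms = 450,
                              floor_base = 0.25, ceiling_base = 0.70,
                              sigmoid_center_ms = 125, sigmoid_width_ms = 5,
                              color_gain_kappa = 0, color_decay_trials = 5,
                              location_bias_kappa = 0,
                              location_decay_trials = 9,
                              interaction_strength = 0) {
  stopifnot(n_trials >= 1, rt_sd_ms > 0, sigmoid_width_ms > 0,
            ceiling_base > 0, ceiling_base < 1,
            all(is.finite(gap_values)), rt_min_ms < rt_max_ms,
            color_decay_trials > 0, location_decay_trials > 0)
  structure(as.list(environment()), class = "generative_params")
}

#' @export
print.generative_params <- function(x, ...) {
  cat(sprintf(
    paste0("Generative params: %d trials, ceiling %.2f, sigmoid %g/%g ms,\n",
           "  color kappa %.3g (decay %g tr), location kappa %.3g (decay %g tr),",
           " interaction %.3g\n"),
    x$n_trials, x$ceiling_base, x$sigmoid_center_ms, x$sigmoid_width_ms,
    x$color_gain_kappa, x$color_decay_trials, x$location_bias_kappa,
    x$location_decay_trials, x$interaction_strength))
  invisible(x)
}

# core engine; does NOT touch the seed (callers own the RNG stream)
.generate_engine <- function(params, subject_id, session_id) {
  p <- params
  n <- p$n_trials
  u <- matrix(runif(n * 6L), nrow = n)  # color, quad, gap, rt, mode, choice

  color_idx <- ifelse(u[, 1] < 0.5, 1L, 2L)
  quad_idx <- as.integer(floor(u[, 2] * 4) + 1)
  gap <- p$gap_values[as.integer(floor(u[, 3] * length(p$gap_values)) + 1)]
  plo <- pnorm(p$rt_min_ms, p$rt_mean_ms, p$rt_sd_ms)
  phi <- pnorm(p$rt_max_ms, p$rt_mean_ms, p$rt_sd_ms)
  rt <- qnorm(plo + u[, 4] * (phi - plo), p$rt_mean_ms, p$rt_sd_ms)
  pt <- rt - gap
  p_informed <- plogis((pt - p$sigmoid_center_ms) / p$sigmoid_width_ms)
  informed <- u[, 5] < p_informed
  eta0 <- qlogis(p$ceiling_base)
  decay_w <- exp(-1 / p$location_decay_trials)
  decay_g <- exp(-1 / p$color_decay_trials)

  history_free <- p$color_gain_kappa == 0 && p$location_bias_kappa == 0 &&
    p$interaction_strength == 0

  choice_idx <- integer(n)
  w_log <- matrix(0, n, 4)
  g_log <- matrix(0, n, 2)
  p_ceil_log <- numeric(n)

  if (history_free) {
    p_ceil <- rep(plogis(eta0), n)
    # informed: target if u6 < p_ceil, else one of the 3 distracters
    di <- pmin(2L, as.integer(floor((u[, 6] - p_ceil) / (1 - p_ceil) * 3)))
    # the (di+1)-th smallest non-target quadrant index
    distracter <- di + 1L + as.integer(di + 1L >= quad_idx)
    # guess: uniform over 4 (softmax of zero weights, cum = .25/.5/.75/1)
    guess_choice <- 1L + (u[, 6] > 0.25) + (u[, 6] > 0.5) + (u[, 6] > 0.75)
    choice_idx <- ifelse(informed,
                         ifelse(u[, 6] < p_ceil, quad_idx, distracter),
                         guess_choice)
    p_ceil_log <- p_ceil
  } else {
    w <- numeric(4)
    g <- numeric(2)
    for (i in seq_len(n)) {
      w_log[i, ] <- w
      g_log[i, ] <- g
      qd <- quad_idx[i]; cl <- color_idx[i]
      p_ceil <- plogis(eta0 + g[cl] + p$interaction_strength * g[cl] * w[qd])
      p_ceil_log[i] <- p_ceil
      u6 <- u[i, 6]
      if (informed[i]) {
        if (u6 < p_ceil) {
          choice_idx[i] <- qd
        } else {
          di <- min(2L, as.integer(floor((u6 - p_ceil) / (1 - p_ceil) * 3)))
          choice_idx[i] <- setdiff(1:4, qd)[di + 1L]
        }
      } else {
        ew <- exp(w - max(w))
        cum <- cumsum(ew) / sum(ew)
        choice_idx[i] <- findInterval(u6, cum, left.open = TRUE) + 1L
      }
      correct_i <- choice_idx[i] == qd
      sgn <- if (correct_i) 1 else -1
      w <- w * decay_w
      w[qd] <- w[qd] + sgn * p$location_bias_kappa
      g <- g * decay_g
      g[cl] <- g[cl] + sgn * p$color_gain_kappa
    }
  }

  correct <- choice_idx == quad_idx
  trials <- tibble::tibble(
    subject_id = subject_id, session_id = session_id,
    trial_index = seq_len(n) - 1L,
    gap_ms = gap, rt_ms = rt, pt_ms = pt,
    target_color = .colors[color_idx],
    target_quadrant = .quadrants[quad_idx],
    choice_quadrant = .quadrants[choice_idx],
    correct = correct)
  latents <- tibble::tibble(
    trial_index = seq_len(n) - 1L,
    w_right = w_log[, 1], w_up = w_log[, 2], w_left = w_log[, 3],
    w_down = w_log[, 4], g_red = g_log[, 1], g_green = g_log[, 2],
    p_informed = p_informed, p_ceil = p_ceil_log, informed = informed,
    u_mode = u[, 5], u_choice = u[, 6])
  list(trials = trials, latents = latents)
}

#' Generate one synthetic session
#'
#' Draws an ordered session of trials from the generative model described
#' in [generative_params()], together with the ground-truth latent log
#' (location weights, color gains, ceiling, arbitration probability, and
#' the uniform draws behind each choice). Output is bit-reproducible given
#' `params$seed`.
#'
#' @param params A `generative_params` list.
#' @param subject_id,session_id Identifiers stamped on the trials.
#' @return A list with `trials` (canonical trial table), `latents`
#'   (per-trial latent log), and `params`.
#' @export
generate_session <- function(params, subject_id = "sim", session_id = "s1") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)
  out <- .generate_engine(params, subject_id, session_id)
  out$params <- params
  out
}

#' Generate several synthetic sessions from one seed
#'
#' Sessions are generated sequentially from a single RNG stream seeded with
#' `params$seed`; latent states reset at each session boundary (histories
#' never cross sessions).
#'
#' @param params A `generative_params` list (`n_trials` applies per session).
#' @param n_sessions Number of sessions.
#' @param subject_id Identifier stamped on all trials.
#' @return A list with `trials` (all sessions bound), `latents` (with a
#'   `session_id` column), and `params`.
#' @export
generate_sessions <- function(params, n_sessions = 1, subject_id = "sim") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)
  sessions <- lapply(seq_len(n_sessions), function(s) {
    sid <- sprintf("s%03d", s)
    out <- .generate_engine(params, subject_id, sid)
    out$latents$session_id <- sid
    out
  })
  list(trials = dplyr::bind_rows(lapply(sessions, `[[`, "trials")),
       latents = dplyr::bind_rows(lapply(sessions, `[[`, "latents")),
       params = params)
}

#' Replay logged latents through the choice rule
#'
#' Recomputes every choice deterministically from the latent log (location
#' weights, ceiling, arbitration flag and the logged uniform draws) and the
#' trial's target. Used to verify that the emitted choices are exactly the
#' ones the latent trajectories imply.
#'
#' @param session Output of [generate_session()].
#' @return Character vector of replayed choice quadrants.
#' @export
replay_choices <- function(session) {
  tr <- session$trials
  la <- session$latents
  n <- nrow(tr)
  quad_idx <- match(tr$target_quadrant, .quadrants)
  w <- as.matrix(la[, c("w_right", "w_up", "w_left", "w_down")])
  choice <- integer(n)
  for (i in seq_len(n)) {
    u6 <- la$u_choice[i]
    if (la$informed[i]) {
      if (u6 < la$p_ceil[i]) {
        choice[i] <- quad_idx[i]
      } else {
        di <- min(2L, as.integer(floor((u6 - la$p_ceil[i]) /
                                         (1 - la$p_ceil[i]) * 3)))
        choice[i] <- setdiff(1:4, quad_idx[i])[di + 1L]
      }
    } else {
      wi <- w[i, ]
      ew <- exp(wi - max(wi))
      cum <- cumsum(ew) / sum(ew)
      choice[i] <- findInterval(u6, cum, left.open = TRUE) + 1L
    }
  }
  .quadrants[choice]
}

# Parameter recovery -------------------------------------------------------

#' Fit the history-free accuracy model to trial data
#'
#' Maximum-likelihood fit of
#' `p(correct | pt) = floor + (ceiling - floor) * plogis((pt - center) / width)`
#' by a coarse grid scan followed by bounded quasi-Newton refinement.
#' Deterministic given the data. Wald 95% CIs come from the numerical
#' Hessian at the optimum; estimates within tolerance of a box bound are
#' flagged as boundary solutions (their CIs are unreliable).
#'
#' @param trials Trial table with `pt_ms` and `correct` (intended for
#'   5000+ trials; fewer triggers a warning).
#' @param conf Confidence level for the Wald intervals.
#' @return A list with `estimates` (named: floor, ceiling, center, width),
#'   `se`, `ci_low`, `ci_high`, `loglik`, `boundary` (named logical), and
#'   `converged`.
#' @export
recover_parameters <- function(trials, conf = 0.95) {
  pt <- trials$pt_ms
  y <- as.numeric(trials$correct)
  if (length(pt) < 5000) {
    warn("recover_parameters: fewer than 5000 trials; estimates may be unstable")
  }
  if (diff(range(pt)) < 50) abort("degenerate PT range")

  nll <- function(th) {
    p <- th[1] + (th[2] - th[1]) * plogis((pt - th[3]) / th[4])
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  nll_grad <- function(th) {
    s <- plogis((pt - th[3]) / th[4])
    p <- th[1] + (th[2] - th[1]) * s
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    dldp <- -(y / p - (1 - y) / (1 - p))
    sg <- s * (1 - s) * (th[2] - th[1])
    c(sum(dldp * (1 - s)),
      sum(dldp * s),
      sum(dldp * (-sg / th[4])),
      sum(dldp * (-sg * (pt - th[3]) / th[4]^2)))
  }
  lower <- c(0.01, 0.05, min(pt), 1)
  upper <- c(0.95, 0.999, max(pt), 500)
  grid <- expand.grid(fl = c(0.2, 0.25, 0.3),
                      ce = c(0.5, 0.7, 0.9),
                      ct = quantile(pt, c(0.3, 0.5, 0.7), names = FALSE),
                      wd = c(5, 15, 40))
  grid_nll <- apply(grid, 1L, nll)
  start <- as.numeric(grid[which.min(grid_nll), ])
  start <- pmin(pmax(start, lower + 1e-6), upper - 1e-6)
  fit <- optim(start, nll, gr = nll_grad, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 1000, factr = 1e4))
  est <- setNames(fit$par, c("floor", "ceiling", "center", "width"))
  boundary <- setNames(fit$par <= lower + 1e-6 | fit$par >= upper - 1e-6,
                       names(est))

  se <- ci_low <- ci_high <- setNames(rep(NA_real_, 4), names(est))
  hess_ok <- FALSE
  if (!any(boundary)) {
    # expected Fisher information: I = sum_i J_i J_i' / (p_i (1 - p_i)),
    # with J the gradient of p(pt; theta) in theta
    th <- fit$par
    s <- plogis((pt - th[3]) / th[4])
    p <- pmin(pmax(th[1] + (th[2] - th[1]) * s, 1e-10), 1 - 1e-10)
    sg <- s * (1 - s) * (th[2] - th[1])
    J <- cbind(1 - s, s, -sg / th[4], -sg * (pt - th[3]) / th[4]^2)
    Iexp <- crossprod(J / sqrt(p * (1 - p)))
    V <- try(solve(Iexp), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) {
      z <- qnorm(1 - (1 - conf) / 2)
      se <- setNames(sqrt(diag(V)), names(est))
      ci_low <- est - z * se
      ci_high <- est + z * se
      hess_ok <- TRUE
    }
  }
  list(estimates = est, se = se, ci_low = ci_low, ci_high = ci_high,
       loglik = -fit$value, boundary = boundary,
       converged = fit$convergence == 0 && (hess_ok || any(boundary)))
}
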