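#' Score trials from first-lick times
#'
#' The response period spans the first 1 s after onset. Go trials with a lick
#' in [150 ms, 1 s) are hits; licks before 150 ms are likely random and mark
#' the trial "too_soon" (excluded from downstream analysis); no lick is a
#' miss. Catch trials with a lick in the response period are false positives,
#' otherwise correct rejections. Reward-only trials are left unscored.
#'
#' @param trials trial table with `first_lick_ms` relative to onset.
#' @param response_window_ms response period end (default 1000).
#' @param too_soon_ms minimum plausible perceptual latency (default 150).
#' @return trial table with the `outcome` column filled in.
#' @export
score_trials <- function(trials, response_window_ms = 1000, too_soon_ms = 150) {
  lick <- trials$first_lick_ms
  in_win <- !is.na(lick) & lick < response_window_ms
  go <- trials$trial_type == "go"
  catch <- trials$trial_type == "catch"
  trials$outcome[go] <- "miss"
  trials$outcome[go & in_win] <- "hit"
  trials$outcome[go & in_win & lick < too_soon_ms] <- "too_soon"
  trials$outcome[catch] <- "correct_rejection"
  trials$outcome[catch & in_win] <- "false_positive"
  trials$outcome[trials$trial_type == "reward_only"] <- "unscored"
  trials
}

#' Detection sensitivity d'
#'
#' `d' = z(hit rate) - z(false alarm rate)`. Rates of exactly 0 or 1 are
#' undefined under the probit transform and are corrected to `1/(2n)` and
#' `1 - 1/(2n)` using the trial counts (standard log-linear correction);
#' without counts, extreme rates are an error.
#'
#' @param hit_rate,fa_rate rates in `[0, 1]`.
#' @param n_go,n_catch trial counts behind each rate (needed only when a rate
#'   is exactly 0 or 1).
#' @return d' (numeric scalar).
#' @export
compute_dprime <- function(hit_rate, fa_rate, n_go = NULL, n_catch = NULL) {
  fix <- function(r, n) {
    if (r > 0 && r < 1) return(r)
    if (is.null(n)) stop("rate of ", r, " needs a trial count for correction")
    max(1 / (2 * n), min(1 - 1 / (2 * n), r))
  }
  stats::qnorm(fix(hit_rate, n_go)) - stats::qnorm(fix(fa_rate, n_catch))
}

#' Per-condition behavioural summary for one session
#'
#' Hit rate and d' per number of targeted cells (each compared against the
#' session-wide catch-trial false-alarm rate) plus the session false-alarm
#' rate. Too-soon trials are excluded.
#'
#' @param trials scored trial table.
#' @return list with `by_n_targets` data.frame (n_targets, n_go, hit_rate,
#'   dprime), `fa_rate`, `n_catch`.
#' @export
behavior_summary <- function(trials) {
  tr <- trials[trials$outcome != "too_soon", , drop = FALSE]
  catch <- tr$trial_type == "catch"
  n_catch <- sum(catch)
  fa_rate <- if (n_catch > 0) mean(tr$outcome[catch] == "false_positive") else NA
  go <- tr[tr$trial_type == "go", , drop = FALSE]
  by_n <- do.call(rbind, lapply(split(go, go$n_targets), function(g) {
    hr <- mean(g$outcome == "hit")
    data.frame(n_targets = g$n_targets[1], n_go = nrow(g), hit_rate = hr,
               dprime = compute_dprime(hr, fa_rate, nrow(g), n_catch))
  }))
  rownames(by_n) <- NULL
  list(by_n_targets = by_n[order(by_n$n_targets), ], fa_rate = fa_rate,
       n_catch = n_catch)
}

#' Session inclusion criterion
#'
#' A session is kept when d' for 150-target trials is at least 0.95 and d'
#' for pooled 40- and 50-target trials is at least 0.5.
#'
#' @param trials scored trial table.
#' @return list with `include` (logical, `NA` if a condition is missing),
#'   `dprime_150`, `dprime_40_50`.
#' @export
session_qc <- function(trials) {
  tr <- trials[trials$outcome != "too_soon", , drop = FALSE]
  catch <- tr$trial_type == "catch"
  n_catch <- sum(catch)
  fa <- if (n_catch > 0) mean(tr$outcome[catch] == "false_positive") else NA
  d_for <- function(ns) {
    g <- tr[tr$trial_type == "go" & tr$n_targets %in% ns, , drop = FALSE]
    if (nrow(g) == 0 || n_catch == 0) return(NA_real_)
    compute_dprime(mean(g$outcome == "hit"), fa, nrow(g), n_catch)
  }
  d150 <- d_for(150)
  d4050 <- d_for(c(40, 50))
  inc <- if (is.na(d150) || is.na(d4050)) {
    warning("session_qc: missing condition, decision deferred")
    NA
  } else d150 >= 0.95 && d4050 >= 0.5
  list(include = inc, dprime_150 = d150, dprime_40_50 = d4050)
}

#' Fit a psychometric curve to d' versus number of targeted cells
#'
#' Least-squares fit of `d'(n) = dmax / (1 + exp(-k (n - x50)))`, a logistic
#' with its lower bound fixed at d' = 0. `x50` is the half-maximum point in
#' targeted cells.
#'
#' @param points data.frame with columns `n_targets` and `dprime` (points from
#'   one session, or pooled across sessions with equal weight).
#' @return An object of class `optoprop_psychfit`: list with `dmax`, `k`,
#'   `x50`, `converged`, `degenerate` and the fitted function `predict`.
#' @export
fit_psychometric <- function(points) {
  stopifnot(all(c("n_targets", "dprime") %in% names(points)))
  pts <- points[is.finite(points$dprime), , drop = FALSE]
  if (length(unique(pts$n_targets)) < 3)
    stop("need at least 3 distinct n_targets")
  if (all(abs(pts$dprime) < 1e-12)) {
    return(structure(list(dmax = 0, k = NA_real_, x50 = NA_real_,
                          converged = FALSE, degenerate = TRUE),
                     class = "optoprop_psychfit"))
  }
  resid_fn <- function(par) {
    pts$dprime - par[1] / (1 + exp(-par[2] * (pts$n_targets - par[3])))
  }
  fit <- try(minpack.lm::nls.lm(
    par = c(dmax = max(pts$dprime), k = 0.1,
            x50 = stats::median(pts$n_targets)),
    lower = c(0, 1e-4, 0),
    upper = c(20, 10, max(pts$n_targets) * 2),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error") || fit$info < 1 || fit$info > 4) {
    return(structure(list(dmax = NA_real_, k = NA_real_, x50 = NA_real_,
                          converged = FALSE, degenerate = FALSE),
                     class = "optoprop_psychfit"))
  }
  cf <- fit$par
  structure(list(dmax = unname(cf["dmax"]), k = unname(cf["k"]),
                 x50 = unname(cf["x50"]), converged = TRUE,
                 degenerate = FALSE,
                 predict = function(n) cf["dmax"] /
                   (1 + exp(-cf["k"] * (n - cf["x50"])))),
            class = "optoprop_psychfit")
}

#' @export
print.optoprop_psychfit <- function(x, ...) {
  cat(sprintf("<psychometric fit> dmax=%.3g  k=%.3g  x50=%.3g  (converged: %s)\n",
              x$dmax, x$k, x$x50, x$converged))
  invisible(x)
}

#' Expected psychometric half-point of an outcome model
#'
#' Computes the psychometric curve a given behavioural design would produce
#' in expectation under an [outcome_model()] — marginal hit rate per target
#' count (Gaussian quadrature over the latent z-scored log variance), the
#' same extreme-rate correction as [compute_dprime()] at the design's trial
#' counts, d' against the model's false-alarm rate — and returns the fitted
#' half-maximum point. This is the estimand the psychometric fit recovers on
#' generated sessions.
#'
#' @param model an [outcome_model()].
#' @param n_targets_set stimulus strengths of the design.
#' @param n_go_per_cond expected go trials per strength.
#' @param n_catch expected catch trials.
#' @return list with `x50`, `dmax`, `points` (the expected d' curve).
#' @export
psychometric_half_point <- function(model,
                                    n_targets_set = c(5, 10, 20, 30, 40, 50,
                                                      150),
                                    n_go_per_cond = 50, n_catch = 100) {
  v <- seq(-4, 4, length.out = 201)
  wv <- stats::dnorm(v); wv <- wv / sum(wv)
  fa <- min(max(model$fa_rate, 1 / (2 * n_catch)), 1 - 1 / (2 * n_catch))
  pts <- data.frame(n_targets = n_targets_set, dprime = vapply(
    n_targets_set, function(n) {
      p <- sum(wv * stats::plogis(model$beta0 + model$beta_ntargets * n +
                                    model$beta_logvar * v))
      # expected rates are clamped to the design's resolution, mirroring the
      # extreme-rate correction finite sessions are subject to
      p <- min(max(p, 1 / (2 * n_go_per_cond)), 1 - 1 / (2 * n_go_per_cond))
      compute_dprime(p, fa, n_go = n_go_per_cond, n_catch = n_catch)
    }, numeric(1)))
  fit <- fit_psychometric(pts)
  list(x50 = fit$x50, dmax = fit$dmax, points = pts)
}
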