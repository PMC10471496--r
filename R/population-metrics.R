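#' Pre-stimulus population mean and variance per trial
#'
#' Each cell's dF/F is averaged over the 500-ms window immediately before
#' trial onset (15 frames at 30 Hz); the population mean and the across-cell
#' sample variance (n - 1 convention) of the resulting vector give one scalar
#' pair per trial. The variance is passed through the selected transform
#' (natural log by default, matching its log-normal across-trial
#' distribution; `"auto"` chooses by KL divergence via [select_transform()]).
#'
#' @param tensor an `optoprop_tensor` (baselining does not touch the
#'   pre-window).
#' @param window_s pre-stimulus window length in seconds (default 0.5).
#' @param transform `"log"`, `"identity"` or `"auto"`.
#' @return data.frame of class `optoprop_popstate` with one row per trial:
#'   `trial_id`, `trial_type`, `outcome`, `n_targets`, `pop_mean`, `pop_var`,
#'   `pop_var_t` (transformed variance); the chosen transform is attached as
#'   attribute `"transform"`.
#' @export
prestim_population_metrics <- function(tensor, window_s = 0.5,
                                       transform = c("log", "identity", "auto")) {
  stopifnot(inherits(tensor, "optoprop_tensor"))
  transform <- match.arg(transform)
  if (dim(tensor$data)[2] < 2) stop("population variance needs >= 2 cells")
  sel <- tensor$time_axis_s >= -window_s & tensor$time_axis_s < 0
  cellmean <- apply(tensor$data[, , sel, drop = FALSE], c(1, 2), mean,
                    na.rm = TRUE)
  pop_mean <- rowMeans(cellmean)
  pop_var <- apply(cellmean, 1, stats::var)
  if (transform == "auto") transform <- select_transform(pop_var)
  pop_var_t <- if (transform == "log") log(pop_var) else pop_var
  out <- data.frame(trial_id = tensor$trials$trial_id,
                    trial_type = tensor$trials$trial_type,
                    outcome = tensor$trials$outcome,
                    n_targets = tensor$trials$n_targets,
                    pop_mean = pop_mean, pop_var = pop_var,
                    pop_var_t = pop_var_t)
  attr(out, "transform") <- transform
  class(out) <- c("optoprop_popstate", "data.frame")
  out
}

#' Choose between identity and log transform by KL divergence
#'
#' Fits a normal and a log-normal by maximum likelihood and compares each
#' family's KL divergence from the empirical distribution (histogram over 50
#' equal-width bins spanning the pooled range, with Laplace smoothing). The
#' family with the smaller divergence wins; the log branch is only eligible
#' for strictly positive data.
#'
#' @param values numeric vector.
#' @param n_bins histogram bins (default 50).
#' @return `"log"` or `"identity"`.
#' @export
select_transform <- function(values, n_bins = 50) {
  values <- values[is.finite(values)]
  if (stats::sd(values) == 0) {
    warning("degenerate (constant) distribution: identity transform forced")
    return("identity")
  }
  if (any(values <= 0)) {
    warning("non-positive values: identity transform forced")
    return("identity")
  }
  br <- seq(min(values), max(values), length.out = n_bins + 1)
  counts <- graphics::hist(values, breaks = br, plot = FALSE)$counts
  p <- (counts + 1) / (length(values) + n_bins)
  kl <- function(cdf_fun) {
    q <- pmax(diff(cdf_fun(br)), 1e-12)
    q <- q / sum(q)
    sum(p * log(p / q))
  }
  kl_norm <- kl(function(x) stats::pnorm(x, mean(values), stats::sd(values)))
  kl_lnorm <- kl(function(x) stats::plnorm(x, mean(log(values)),
                                           stats::sd(log(values))))
  if (kl_lnorm < kl_norm) "log" else "identity"
}

#' z-score population metrics across trials within a session
#'
#' Centres and scales `pop_mean` and `pop_var_t` across all trials possessing
#' the metric (sd with n - 1), before any split by outcome, adding columns
#' `z_pop_mean` and `z_pop_var`.
#'
#' @param state an `optoprop_popstate`.
#' @return the state with z-scored columns added.
#' @export
zscore_metrics <- function(state) {
  if (nrow(state) < 2) stop("z-scoring needs >= 2 trials")
  z <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero spread: z-score undefined")
    (x - mean(x, na.rm = TRUE)) / s
  }
  state$z_pop_mean <- z(state$pop_mean)
  state$z_pop_var <- z(state$pop_var_t)
  state
}

#' Hit-versus-miss contrast of a population metric across sessions
#'
#' For each session, the mean z-scored metric is computed separately over hit
#' and miss trials; the paired session means are compared with a two-sided
#' Wilcoxon signed-rank test.
#'
#' @param states list of `optoprop_popstate` (z-scored), one per session.
#' @param metric `"z_pop_var"` or `"z_pop_mean"`.
#' @return list with `per_session` (session, mean_hit, mean_miss),
#'   `p_value`, `statistic`, `median_paired_diff` (miss - hit).
#' @export
outcome_contrast <- function(states, metric = "z_pop_var") {
  per <- do.call(rbind, lapply(seq_along(states), function(i) {
    s <- states[[i]]
    hit <- s$outcome == "hit"; miss <- s$outcome == "miss"
    if (!any(hit) || !any(miss)) return(NULL)
    data.frame(session = i, mean_hit = mean(s[[metric]][hit]),
               mean_miss = mean(s[[metric]][miss]))
  }))
  if (is.null(per) || nrow(per) < 2)
    stop("need >= 2 sessions with both hits and misses")
  if (nrow(per) < 6)
    warning("fewer than 6 sessions: signed-rank test has little power")
  wt <- stats::wilcox.test(per$mean_miss, per$mean_hit, paired = TRUE,
                           exact = FALSE)
  list(per_session = per, p_value = wt$p.value, statistic = unname(wt$statistic),
       median_paired_diff = stats::median(per$mean_miss - per$mean_hit))
}

#' Hit probability across variance bins, with a slope test
#'
#' Go trials of a session are split into equal-count bins of z-scored
#' population variance (bins with fewer than `min_per_bin` trials are merged
#' with their neighbour); the per-bin hit probability is regressed on the bin
#' centre and a one-sided t-test for a negative slope is reported. With
#' several sessions, p-values are Bonferroni corrected.
#'
#' @param states list of z-scored `optoprop_popstate`, one per session.
#' @param n_bins number of bins (default 5).
#' @param min_per_bin minimum trials per bin (default 5).
#' @return data.frame: session, slope, p_one_sided, p_bonferroni, n_trials.
#' @export
hit_rate_by_variance <- function(states, n_bins = 5, min_per_bin = 5) {
  res <- do.call(rbind, lapply(seq_along(states), function(i) {
    s <- states[[i]]
    go <- s[s$outcome %in% c("hit", "miss"), , drop = FALSE]
    if (nrow(go) < 2 * min_per_bin) return(NULL)
    q <- stats::quantile(go$z_pop_var, probs = seq(0, 1, length.out = n_bins + 1))
    q[1] <- -Inf; q[length(q)] <- Inf
    bin <- cut(go$z_pop_var, breaks = unique(q), labels = FALSE)
    # merge undersized bins into their left neighbour
    repeat {
      tab <- table(bin)
      small <- names(tab)[tab < min_per_bin]
      if (length(small) == 0 || length(tab) <= 2) break
      b <- as.integer(small[1])
      bin[bin == b] <- if (b > min(bin)) b - 1L else b + 1L
      bin <- as.integer(factor(bin))
    }
    agg <- do.call(rbind, lapply(split(go, bin), function(g) {
      data.frame(center = mean(g$z_pop_var), p_hit = mean(g$outcome == "hit"))
    }))
    if (nrow(agg) < 3) return(NULL)
    fit <- stats::lm(p_hit ~ center, data = agg)
    sm <- summary(fit)$coefficients
    tval <- sm["center", "t value"]
    data.frame(session = i, slope = sm["center", "Estimate"],
               p_one_sided = stats::pt(tval, df = fit$df.residual),
               n_trials = nrow(go))
  }))
  if (is.null(res)) stop("no session had enough go trials")
  res$p_bonferroni <- pmin(1, res$p_one_sided * nrow(res))
  res
}

#' Hit-probability surface over variance and stimulus strength, and its SNR axis
#'
#' Pooled go trials are binned by z-scored population variance (bin width 0.5)
#' crossed with the discrete target-count categories; each occupied bin's hit
#' probability forms a 2-D grid. Bin centres, rescaled to the unit square, are
#' projected onto the normalised anti-diagonal (low variance and high count =
#' high SNR) and bin values are averaged per projection coordinate to give the
#' 1-D SNR curve. Empty bins are missing and excluded from the averages.
#'
#' @param pooled data.frame of go trials across sessions with columns
#'   `z_pop_var`, `n_targets`, `outcome`.
#' @param var_bin_width z-variance bin width (default 0.5).
#' @param n_axis_bins resolution of the projected SNR axis (default 10).
#' @return list with `grid` (data.frame: n_targets, var_bin_center, p_hit,
#'   n), and `projection` (data.frame: snr_coord, p_hit, n_bins).
#' @export
snr_surface <- function(pooled, var_bin_width = 0.5, n_axis_bins = 10) {
  go <- pooled[pooled$outcome %in% c("hit", "miss"), , drop = FALSE]
  stopifnot(nrow(go) > 0)
  lo <- floor(min(go$z_pop_var) / var_bin_width) * var_bin_width
  hi <- ceiling(max(go$z_pop_var) / var_bin_width) * var_bin_width
  br <- seq(lo, hi, by = var_bin_width)
  vb <- cut(go$z_pop_var, breaks = br, include.lowest = TRUE, labels = FALSE)
  counts <- sort(unique(go$n_targets))
  grid <- do.call(rbind, lapply(split(seq_len(nrow(go)),
                                      list(go$n_targets, vb), drop = TRUE),
    function(ix) {
      data.frame(n_targets = go$n_targets[ix[1]],
                 var_bin_center = br[vb[ix[1]]] + var_bin_width / 2,
                 p_hit = mean(go$outcome[ix] == "hit"), n = length(ix))
    }))
  rownames(grid) <- NULL
  # unit-square coordinates: count rank up, variance up
  cx <- (match(grid$n_targets, counts) - 1) / max(1, length(counts) - 1)
  cy <- (grid$var_bin_center - min(grid$var_bin_center)) /
    max(1e-12, diff(range(grid$var_bin_center)))
  proj <- (cx - cy + 1) / 2         # in [0, 1]; 1 = high count, low variance
  pb <- cut(proj, breaks = seq(0, 1, length.out = n_axis_bins + 1),
            include.lowest = TRUE, labels = FALSE)
  projection <- do.call(rbind, lapply(split(seq_along(pb), pb), function(ix) {
    data.frame(snr_coord = mean(proj[ix]), p_hit = mean(grid$p_hit[ix]),
               n_bins = length(ix))
  }))
  rownames(projection) <- NULL
  list(grid = grid, projection = projection[order(projection$snr_coord), ])
}

#' Logistic model of trial outcome on stimulus strength and population variance
#'
#' Maximum-likelihood logistic regression of hit/miss on the number of
#' targeted cells and the z-scored log population variance (plus intercept),
#' with per-coefficient two-sided Wald tests and McFadden's pseudo-R-squared
#' for the full model and for each single-regressor model.
#'
#' @param pooled data.frame of pooled hit/miss trials with columns `outcome`,
#'   `n_targets`, `z_pop_var`.
#' @return An object of class `optoprop_snrmodel`: list with `coefficients`,
#'   `p_values`, `mcfadden_r2`, `mcfadden_r2_ntargets`, `mcfadden_r2_popvar`,
#'   `ll_model`, `ll_null`, `separation` flag and the `glm` fit.
#' @export
snr_logistic_model <- function(pooled) {
  go <- pooled[pooled$outcome %in% c("hit", "miss"), , drop = FALSE]
  y <- as.integer(go$outcome == "hit")
  X <- cbind(n_targets = go$n_targets, z_pop_var = go$z_pop_var)
  if (qr(cbind(1, X))$rank < 3)
    stop("rank-deficient design (duplicated or constant regressor)")
  dat <- data.frame(y = y, X)
  fit <- suppressWarnings(stats::glm(y ~ n_targets + z_pop_var, data = dat,
                                     family = stats::binomial()))
  separation <- any(abs(stats::coef(fit)) > 50) || !fit$converged
  ll <- function(f) as.numeric(stats::logLik(f))
  null <- stats::glm(y ~ 1, data = dat, family = stats::binomial())
  f_n <- stats::glm(y ~ n_targets, data = dat, family = stats::binomial())
  f_v <- stats::glm(y ~ z_pop_var, data = dat, family = stats::binomial())
  mcf <- function(f) 1 - ll(f) / ll(null)
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = stats::coef(fit),
    p_values = sm[, "Pr(>|z|)"],
    mcfadden_r2 = mcf(fit),
    mcfadden_r2_ntargets = mcf(f_n),
    mcfadden_r2_popvar = mcf(f_v),
    ll_model = ll(fit), ll_null = ll(null),
    separation = separation, fit = fit
  ), class = "optoprop_snrmodel")
}

#' @export
print.optoprop_snrmodel <- function(x, ...) {
  cat("<SNR logistic model>\n")
  print(round(x$coefficients, 4))
  cat(sprintf("McFadden R2: full %.4f | n_targets %.4f | pop_var %.4f\n",
              x$mcfadden_r2, x$mcfadden_r2_ntargets, x$mcfadden_r2_popvar))
  invisible(x)
}

#' Correlations of population variance with task covariates
#'
#' Pearson correlations (with p-values) of the z-scored population variance
#' with the trial index, the recent reward count, and optionally the paired
#' metric of the other region.
#'
#' @param state a z-scored `optoprop_popstate`.
#' @param trial_index integer covariate (defaults to row order).
#' @param recent_rewards optional numeric covariate.
#' @param other_region_var optional paired z-variance from the other region.
#' @return data.frame: covariate, r, p (constant covariates give `NA` with a
#'   warning).
#' @export
variance_covariates <- function(state, trial_index = seq_len(nrow(state)),
                                recent_rewards = NULL,
                                other_region_var = NULL) {
  covs <- list(trial_index = trial_index)
  if (!is.null(recent_rewards)) covs$recent_rewards <- recent_rewards
  if (!is.null(other_region_var)) covs$other_region <- other_region_var
  do.call(rbind, lapply(names(covs), function(nm) {
    x <- covs[[nm]]
    if (stats::sd(x, na.rm = TRUE) == 0) {
      warning("constant covariate '", nm, "': correlation undefined")
      return(data.frame(covariate = nm, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(state$z_pop_var, x)
    data.frame(covariate = nm, r = unname(ct$estimate), p = ct$p.value)
  }))
}
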