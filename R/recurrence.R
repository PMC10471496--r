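#' Subsampled pre-trial activity segments
#'
#' Draws `n_subsamples` sets of `trials_per_subsample` trials of the requested
#' condition (without replacement within a set, with replacement across sets)
#' and records, for each trial, the frames of the 6.5-s window immediately
#' preceding its onset. Frames blanked by a previous trial's photostimulation
#' are excluded from the windows (and the overlap fraction reported); trials
#' whose window would start before the recording are unusable.
#'
#' @param dff an `optoprop_dff` (session-level dF/F).
#' @param trials trial table (scored).
#' @param frame_rate_hz imaging frame rate.
#' @param condition `"hit"`, `"miss"` or `"all"` (go trials).
#' @param segment_length_s pre-trial window length (default 6.5).
#' @param trials_per_subsample trials concatenated per draw (default 15).
#' @param n_subsamples number of draws (default 1000).
#' @param seed integer seed; draws are deterministic given it.
#' @return list of class `optoprop_segments` with `frames` (list of frame
#'   index vectors per usable trial), `draws` (n_subsamples x
#'   trials_per_subsample index matrix), `condition`, `blank_overlap`.
#' @export
extract_pretrial_segments <- function(dff, trials, frame_rate_hz,
                                      condition = c("all", "hit", "miss"),
                                      segment_length_s = 6.5,
                                      trials_per_subsample = 15,
                                      n_subsamples = 1000, seed = 1L) {
  stopifnot(inherits(dff, "optoprop_dff"))
  condition <- match.arg(condition)
  sel <- switch(condition,
                all = trials$trial_type == "go" & trials$outcome != "too_soon",
                hit = trials$outcome == "hit",
                miss = trials$outcome == "miss")
  tr <- trials[sel, , drop = FALSE]
  n_seg <- round(segment_length_s * frame_rate_hz)
  blank <- blanked_frames(trials, frame_rate_hz, ncol(dff$dff))
  frames <- lapply(tr$onset_frame, function(on) {
    w <- (on - n_seg + 1):on          # 1-based frames of [-6.5 s, 0)
    if (min(w) < 1) return(NULL)
    w[!w %in% blank]
  })
  usable <- !vapply(frames, is.null, logical(1))
  frames <- frames[usable]
  if (length(frames) < trials_per_subsample)
    stop(sprintf("only %d usable '%s' trials (< %d): session skipped",
                 length(frames), condition, trials_per_subsample))
  total <- sum(lengths(frames))
  overlap <- 1 - total / (length(frames) * n_seg)
  set.seed(seed)
  draws <- t(replicate(n_subsamples,
                       sample(length(frames), trials_per_subsample)))
  structure(list(frames = frames, draws = draws, condition = condition,
                 blank_overlap = overlap, dff = dff),
            class = "optoprop_segments")
}

#' Split activity into shared and non-shared components
#'
#' Maximum-likelihood factor analysis (EM, principal-axis ordered loadings)
#' on the cells x cells covariance of the input; the shared component is the
#' reconstruction from the posterior factor scores and the residual is the
#' non-shared activity. Variance explained per factor is reported for the
#' first `report_factors` factors (fit separately when larger than
#' `n_factors`); set `report_factors = 0` to skip the report in tight loops.
#'
#' @param X cells x frames activity matrix (>= 10 cells, more frames than
#'   factors).
#' @param n_factors factors removed (default 5: recurrent filtering spreads a
#'   low-dimensional shared input over several observed dimensions, so a
#'   single factor under-removes it).
#' @param report_factors factors in the variance-explained report (default 5).
#' @return list of class `optoprop_shared_decomp`: `n_factors`,
#'   `factor_variance_explained`, `shared_component`, `residuals`, `loadings`,
#'   `scores`.
#' @export
remove_shared_activity <- function(X, n_factors = 5, report_factors = 5) {
  p <- nrow(X); T_ <- ncol(X)
  if (p < 10) stop("need >= 10 cells for factor analysis")
  if (T_ <= n_factors) stop("need more frames than factors")
  Xc <- X - rowMeans(X)
  S <- tcrossprod(Xc) / (T_ - 1)
  fit <- fa_em(S, n_factors)
  L <- fit$loadings; psi <- fit$uniquenesses
  Lp <- L / psi
  G <- solve(diag(n_factors) + crossprod(L, Lp))
  scores <- G %*% crossprod(Lp, Xc)               # k x T posterior means
  shared <- L %*% scores
  ve <- NULL
  if (report_factors > 0) {
    frep <- if (report_factors > n_factors) fa_em(S, report_factors) else fit
    ve <- colSums(frep$loadings^2)[seq_len(report_factors)] / sum(diag(S))
  }
  structure(list(n_factors = n_factors,
                 factor_variance_explained = ve,
                 shared_component = shared,
                 residuals = Xc - shared,
                 loadings = L, scores = scores),
            class = "optoprop_shared_decomp")
}

#' Pairwise statistics of non-shared activity
#'
#' Cross-neuron correlation and covariance matrices over time, with the mean
#' of the strictly off-diagonal correlations. Zero-variance cells are
#' excluded with a warning.
#'
#' @param residuals cells x frames matrix of non-shared activity.
#' @return list with `cor_matrix`, `cov_matrix`, `mean_offdiag_cor`,
#'   `kept` (row indices retained).
#' @export
nonshared_pairwise_stats <- function(residuals) {
  if (nrow(residuals) < 2) stop("need >= 2 cells")
  v <- apply(residuals, 1, stats::var)
  keep <- v > 0
  if (!all(keep)) warning(sum(!keep), " zero-variance cell(s) excluded")
  X <- residuals[keep, , drop = FALSE]
  C <- fast_row_cov(X)
  R <- stats::cov2cor(C)
  list(cor_matrix = R, cov_matrix = C,
       mean_offdiag_cor = mean(R[upper.tri(R)]),
       kept = which(keep))
}

#' Bias-corrected width of the cross-covariance distribution
#'
#' The sample covariance of `n_frames` observations adds estimation noise of
#' variance approximately `(c_ii c_jj + c_ij^2) / (n_frames - 1)` to each
#' off-diagonal entry; the corrected squared width subtracts the mean of this
#' contribution from the raw across-pair variance and is floored at zero
#' (flagged when the correction exceeds the raw width). `abar` is the mean
#' diagonal (variance).
#'
#' @param cov_matrix covariance matrix from [nonshared_pairwise_stats()].
#' @param n_frames number of time samples behind the estimate.
#' @return list with `sigma_cc`, `abar`, `floored`.
#' @export
covariance_width <- function(cov_matrix, n_frames) {
  d <- diag(cov_matrix)
  abar <- mean(d)
  off <- cov_matrix[upper.tri(cov_matrix)]
  raw <- stats::var(off)
  noise <- (tcrossprod(d)[upper.tri(cov_matrix)] + off^2) / (n_frames - 1)
  s2 <- raw - mean(noise)
  list(sigma_cc = sqrt(max(s2, 0)), abar = abar, floored = s2 < 0)
}

#' Split-half estimate of the cross-covariance width
#'
#' Covariance matrices computed on two disjoint temporal halves carry
#' independent estimation noise, so the across-pair covariance between their
#' off-diagonal entries isolates the true squared width without a
#' distributional noise model. Floored at zero.
#'
#' @param X cells x frames matrix of non-shared activity.
#' @return list with `sigma_cc`, `abar` (mean variance over the full data),
#'   `floored`.
#' @export
covariance_width_splithalf <- function(X) {
  T_ <- ncol(X)
  h <- floor(T_ / 2)
  C1 <- fast_row_cov(X[, 1:h, drop = FALSE])
  C2 <- fast_row_cov(X[, (h + 1):(2 * h), drop = FALSE])
  ut <- upper.tri(C1)
  s2 <- stats::cov(C1[ut], C2[ut])
  abar <- mean(diag(fast_row_cov(X)))
  list(sigma_cc = sqrt(max(s2, 0)), abar = abar, floored = s2 < 0)
}

# sample covariance across columns (rows = variables), BLAS-backed
fast_row_cov <- function(X) {
  Xc <- X - rowMeans(X)
  tcrossprod(Xc) / (ncol(X) - 1)
}

# calibration table G(R) = N * Var_offdiag(C) / abar^2, loaded once
the_inversion <- new.env(parent = emptyenv())
inversion_table <- function() {
  if (is.null(the_inversion$tab)) {
    f <- system.file("extdata", "recurrence_inversion.csv",
                     package = "optoprop", mustWork = TRUE)
    tab <- utils::read.csv(f)
    tab <- tab[order(tab$R), ]
    tab$G <- cummax(tab$G)         # enforce monotonicity against seed noise
    the_inversion$tab <- tab
  }
  the_inversion$tab
}

#' Effective recurrence from the covariance width
#'
#' Inverts the monotone relation between the relative width of the
#' off-diagonal cross-covariance distribution and the spectral bound R of a
#' linear recurrent network of `N_assumed` neurons. The relation
#' `G(R) = N (sigma_cc / abar)^2` is calibrated from exact stationary
#' covariances of the discrete-time network model (see
#' `scripts/calibrate_recurrence.R`); `G` collapses across network size, so a
#' width measured on a recorded subpopulation is inverted at the size of the
#' full local network (50,000 by convention for cortical data). Ratios above
#' the calibrated range clamp to the grid maximum with a flag.
#'
#' @param sigma_cc bias-corrected width (>= 0).
#' @param abar mean variance (> 0).
#' @param N_assumed assumed network size (default 50000).
#' @return list of class `optoprop_recurrence`: `R`, `sigma_cc`, `abar`,
#'   `N_assumed`, `clamped`.
#' @export
estimate_recurrence <- function(sigma_cc, abar, N_assumed = 50000) {
  stopifnot(abar > 0, sigma_cc >= 0)
  tab <- inversion_table()
  G <- N_assumed * (sigma_cc / abar)^2
  clamped <- FALSE
  if (G <= 0) {
    R <- 0
  } else if (G >= max(tab$G)) {
    R <- max(tab$R); clamped <- TRUE
  } else {
    R <- stats::approx(tab$G, tab$R, xout = G, ties = "ordered")$y
  }
  structure(list(R = R, sigma_cc = sigma_cc, abar = abar,
                 N_assumed = N_assumed, clamped = clamped),
            class = "optoprop_recurrence")
}

#' Effective recurrence of an activity matrix
#'
#' The full inference chain on one cells x frames matrix: remove shared
#' activity by factor analysis, estimate the bias-corrected cross-covariance
#' width of the residuals (split-half estimator), and invert to R.
#'
#' @param X cells x frames activity (rates or dF/F).
#' @param n_factors shared factors to remove (default 1).
#' @param N_assumed network size for the inversion (defaults to `nrow(X)` —
#'   appropriate when the matrix covers the whole simulated network; use
#'   50000 for recorded cortical subpopulations).
#' @param width method: `"splithalf"` (default) or `"analytic"`.
#' @return an `optoprop_recurrence` (with the decomposition attached as
#'   attribute `"decomposition"`).
#' @export
recurrence_from_activity <- function(X, n_factors = 5, N_assumed = nrow(X),
                                     width = c("splithalf", "analytic")) {
  width <- match.arg(width)
  dec <- remove_shared_activity(X, n_factors, report_factors = 0)
  w <- if (width == "splithalf") {
    covariance_width_splithalf(dec$residuals)
  } else {
    covariance_width(stats::cov(t(dec$residuals)), ncol(X))
  }
  out <- estimate_recurrence(w$sigma_cc, w$abar, N_assumed)
  attr(out, "decomposition") <- dec
  out
}

#' Session-level effective recurrence by trial subsampling
#'
#' Applies [recurrence_from_activity()] to each concatenated pre-trial
#' segment draw of an [extract_pretrial_segments()] set and averages R across
#' subsamples.
#'
#' @param segments an `optoprop_segments`.
#' @param n_factors shared factors to remove.
#' @param N_assumed network size for the inversion (default 50000).
#' @return list with `R_mean`, `R_per_subsample`, `condition`, `n_clamped`.
#' @export
session_recurrence <- function(segments, n_factors = 5, N_assumed = 50000) {
  stopifnot(inherits(segments, "optoprop_segments"))
  dff <- segments$dff$dff
  Rs <- apply(segments$draws, 1, function(ix) {
    cols <- unlist(segments$frames[ix])
    est <- recurrence_from_activity(dff[, cols, drop = FALSE], n_factors,
                                    N_assumed)
    c(est$R, est$clamped)
  })
  list(R_mean = mean(Rs[1, ]), R_per_subsample = Rs[1, ],
       condition = segments$condition, n_clamped = sum(Rs[2, ]))
}

#' Paired hit-versus-miss comparison of per-session recurrence
#'
#' Two-sided Wilcoxon signed-rank test across sessions on paired R values.
#'
#' @param R_hit,R_miss numeric vectors, one value per session.
#' @return list with `p_value`, `statistic`, `median_diff` (miss - hit).
#' @export
recurrence_condition_contrast <- function(R_hit, R_miss) {
  stopifnot(length(R_hit) == length(R_miss))
  if (length(R_hit) < 2) stop("need >= 2 sessions for a paired test")
  if (length(R_hit) < 6)
    warning("fewer than 6 sessions: signed-rank test has little power")
  wt <- stats::wilcox.test(R_miss, R_hit, paired = TRUE, exact = FALSE)
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       median_diff = stats::median(R_miss - R_hit))
}

#' Network response timescale from targeted-cell decay
#'
#' Restricted to 250-ms-stimulation trials (5-50 targets) of the requested
#' condition. Per trial, the targeted cells' dF/F is averaged over cells up
#' to 5.5 s post-onset, corrected for their mean fluorescence in the 6.5-s
#' pre-trial window. Trial-averaged responses of `trials_per_subsample`
#' randomly drawn trials (default 10, drawn `n_subsamples` times) are each
#' fit with `A * exp(-t / tau)` by nonlinear least squares on unblanked
#' frames; the mean decay time across successful fits is reported. Fits that
#' diverge are dropped and counted; sessions with > 50% failures are flagged.
#'
#' @param dff an `optoprop_dff`.
#' @param trials scored trial table.
#' @param cells cell metadata (for id -> row lookup).
#' @param frame_rate_hz frame rate.
#' @param condition `"hit"`, `"miss"` or `"all"`.
#' @param trials_per_subsample,n_subsamples subsampling controls.
#' @param seed integer seed.
#' @param post_s,pre_s response and baseline window lengths (5.5 / 6.5 s).
#' @return list of class `optoprop_timescale`: `tau_post`, `A`,
#'   `tau_per_subsample`, `n_failed`, `flagged`, `fit_r2`.
#' @export
fit_response_timescale <- function(dff, trials, cells, frame_rate_hz,
                                   condition = c("all", "hit", "miss"),
                                   trials_per_subsample = 10,
                                   n_subsamples = 1000, seed = 1L,
                                   post_s = 5.5, pre_s = 6.5) {
  condition <- match.arg(condition)
  sel <- trials$trial_type == "go" & trials$n_targets >= 5 &
    trials$n_targets <= 50
  if (condition != "all") sel <- sel & trials$outcome == condition
  tr <- trials[sel, , drop = FALSE]
  if (nrow(tr) < trials_per_subsample)
    stop(sprintf("only %d usable trials (< %d)", nrow(tr),
                 trials_per_subsample))
  n_post <- round(post_s * frame_rate_hz)
  n_pre <- round(pre_s * frame_rate_hz)
  blank <- blanked_frames(trials, frame_rate_hz, ncol(dff$dff))
  id2row <- match(seq_len(max(cells$cell_id)), dff$kept_cell_ids)
  # per-trial mean targeted-cell response, baseline-corrected
  resp <- matrix(NA_real_, nrow(tr), n_post)
  for (i in seq_len(nrow(tr))) {
    ids <- parse_target_ids(tr$targeted_cell_ids[i])[[1]]
    rows <- id2row[ids]; rows <- rows[!is.na(rows)]
    on <- tr$onset_frame[i]
    if (length(rows) == 0 || on - n_pre + 1 < 1 ||
        on + n_post > ncol(dff$dff)) next
    base <- rowMeans(dff$dff[rows, (on - n_pre + 1):on, drop = FALSE])
    post_cols <- (on + 1):(on + n_post)
    m <- colMeans(dff$dff[rows, post_cols, drop = FALSE] - base)
    m[post_cols %in% blank] <- NA
    resp[i, ] <- m
  }
  ok_tr <- which(rowSums(is.finite(resp)) > 0)
  if (length(ok_tr) < trials_per_subsample)
    stop("too few trials with usable responses")
  t_s <- (seq_len(n_post) - 0.5) / frame_rate_hz
  set.seed(seed)
  fits <- t(vapply(seq_len(n_subsamples), function(k) {
    ix <- sample(ok_tr, trials_per_subsample)
    y <- colMeans(resp[ix, , drop = FALSE], na.rm = TRUE)
    use <- is.finite(y)
    df <- data.frame(t = t_s[use], y = y[use])
    best <- NULL
    for (tau0 in c(0.3, 1, 3)) {
      f <- try(minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                                 start = list(A = max(df$y[1], 0.01),
                                              tau = tau0),
                                 lower = c(A = -10, tau = 1e-3),
                                 upper = c(A = 100, tau = 60),
                                 control = minpack.lm::nls.lm.control(maxiter = 100)),
               silent = TRUE)
      if (inherits(f, "try-error")) next
      if (is.null(best) || sum(stats::resid(f)^2) < sum(stats::resid(best)^2))
        best <- f
    }
    if (is.null(best)) return(c(NA_real_, NA_real_, NA_real_))
    f <- best
    cf <- stats::coef(f)
    # degenerate: unbounded decay or vanishing amplitude
    if (cf["tau"] > 30 || cf["A"] <= 1e-4) return(c(NA_real_, NA_real_, NA_real_))
    r2 <- 1 - sum(stats::resid(f)^2) / sum((df$y - mean(df$y))^2)
    c(cf["A"], cf["tau"], r2)
  }, numeric(3)))
  good <- is.finite(fits[, 2])
  n_failed <- sum(!good)
  structure(list(tau_post = mean(fits[good, 2]), A = mean(fits[good, 1]),
                 tau_per_subsample = fits[good, 2], n_failed = n_failed,
                 flagged = n_failed > 0.5 * n_subsamples,
                 fit_r2 = mean(fits[good, 3])),
            class = "optoprop_timescale")
}

#' Compare the recurrence-theory timescale law against a linear trend
#'
#' Fits `tau = c / (1 - R)` (single scale, the linear-network prediction that
#' the decay time along the leading eigenvector diverges as R -> 1) and an
#' ordinary linear regression `tau = a + b R`, reporting r-squared for both.
#'
#' @param R,tau_post numeric vectors (>= 3 sessions / conditions).
#' @return list with `c_theory`, `r2_theory`, `r2_linear`, `theory_wins`.
#' @export
relate_timescale_recurrence <- function(R, tau_post) {
  stopifnot(length(R) == length(tau_post), length(R) >= 3)
  if (any(R >= 1)) stop("R >= 1 is rejected upstream")
  x <- 1 / (1 - R)
  cc <- sum(tau_post * x) / sum(x^2)
  sst <- sum((tau_post - mean(tau_post))^2)
  r2_theory <- if (sst > 0) 1 - sum((tau_post - cc * x)^2) / sst else 0
  lin <- stats::lm(tau_post ~ R)
  r2_linear <- if (sst > 0) summary(lin)$r.squared else 0
  list(c_theory = cc, r2_theory = r2_theory, r2_linear = r2_linear,
       theory_wins = r2_theory > r2_linear)
}
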