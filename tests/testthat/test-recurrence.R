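test_that("EM factor analysis agrees with the reference ML implementation", {
  set.seed(21)
  n <- 2000; p <- 12
  L_true <- matrix(rnorm(p * 2), p, 2)
  X <- L_true %*% matrix(rnorm(2 * n), 2, n) +
    matrix(rnorm(p * n, sd = 0.7), p, n)
  S <- tcrossprod(X - rowMeans(X)) / (n - 1)
  em <- optoprop:::fa_em(S, 2)
  fa <- stats::factanal(covmat = stats::cov2cor(S), factors = 2,
                        n.obs = n, rotation = "none")
  # compare uniquenesses on the correlation scale (rotation-invariant)
  psi_em <- em$uniquenesses / diag(S)
  expect_equal(unname(psi_em), unname(fa$uniquenesses), tolerance = 0.02)
  # and the communal subspace: column spaces of the loadings coincide
  L_em <- em$loadings / sqrt(diag(S))
  P_em <- L_em %*% solve(crossprod(L_em), t(L_em))
  L_fa <- matrix(fa$loadings, p)
  P_fa <- L_fa %*% solve(crossprod(L_fa), t(L_fa))
  expect_lt(max(abs(P_em - P_fa)), 0.05)
})

test_that("shared-activity removal isolates a planted global factor", {
  set.seed(22)
  p <- 30; n <- 4000
  load <- runif(p, 0.8, 1.2)
  f <- rnorm(n)
  X <- outer(load, f) + matrix(rnorm(p * n, sd = 0.1), p, n)
  dec <- remove_shared_activity(X, n_factors = 1, report_factors = 5)
  expect_gt(dec$factor_variance_explained[1], 0.9)
  expect_true(all(diff(dec$factor_variance_explained) < 1e-8))
  expect_equal(dec$residuals, X - rowMeans(X) - dec$shared_component,
               tolerance = 1e-12)
  # residuals are uncorrelated with the extracted factor scores
  rho <- cor(t(dec$residuals), dec$scores[1, ])
  expect_lt(max(abs(rho)), 0.02)

  # independent cells: each factor explains about 1/p of the variance
  Xw <- matrix(rnorm(p * n), p, n)
  dw <- remove_shared_activity(Xw, n_factors = 1, report_factors = 5)
  expect_lt(dw$factor_variance_explained[1], 3 / p)
})

test_that("pairwise statistics behave on degenerate and duplicated cells", {
  set.seed(23)
  x <- rnorm(5000)
  X <- rbind(x, x, rnorm(5000))
  st <- nonshared_pairwise_stats(X)
  expect_equal(st$cor_matrix[1, 2], 1)
  expect_true(isSymmetric(st$cov_matrix))
  expect_equal(diag(st$cov_matrix), apply(X, 1, var), tolerance = 1e-12,
               ignore_attr = TRUE)

  Xn <- matrix(rnorm(50 * 20000), 50)
  expect_lt(abs(nonshared_pairwise_stats(Xn)$mean_offdiag_cor), 0.005)

  Xz <- rbind(rep(1, 100), matrix(rnorm(300), 3))
  expect_warning(st2 <- nonshared_pairwise_stats(Xz), "zero-variance")
  expect_equal(nrow(st2$cov_matrix), 3)
})

test_that("bias-corrected width is null on white noise and scales correctly", {
  set.seed(24)
  X <- matrix(rnorm(50 * 20000), 50)
  w <- covariance_width_splithalf(X)
  expect_lt(w$sigma_cc / w$abar, 0.02)
  wa <- covariance_width(optoprop:::fast_row_cov(X), ncol(X))
  expect_lt(wa$sigma_cc / wa$abar, 0.02)

  # doubling activity: abar x4, sigma_cc x4, ratio unchanged
  set.seed(25)
  net <- network_config(N_cells = 60, R_true = 0.8, shared_gain = 0, seed = 25)
  r <- simulate_rates(net, 20000, seed = 26)$rates
  w1 <- covariance_width_splithalf(r)
  w2 <- covariance_width_splithalf(2 * r)
  expect_equal(w2$abar, 4 * w1$abar, tolerance = 1e-10)
  expect_equal(w2$sigma_cc, 4 * w1$sigma_cc, tolerance = 1e-8)

  # recurrent network: width well above the white-noise null
  expect_gt(w1$sigma_cc / w1$abar, 5 * (w$sigma_cc / max(w$abar, 1e-12) + 1e-3))

  # split-half and analytic corrections agree on simulated data
  wsa <- covariance_width(optoprop:::fast_row_cov(r), ncol(r))
  expect_equal(wsa$sigma_cc, w1$sigma_cc, tolerance = 0.15 * w1$sigma_cc)
})

test_that("the inversion is monotone, zero at zero width, and clamps", {
  expect_equal(estimate_recurrence(0, 1, 500)$R, 0)
  s <- seq(0.001, 0.1, length.out = 20)
  Rs <- vapply(s, function(x) estimate_recurrence(x, 1, 500)$R, numeric(1))
  expect_true(all(diff(Rs) > 0))
  big <- estimate_recurrence(10, 1, 50000)
  expect_true(big$clamped)
  expect_equal(big$R, 0.995)
})

test_that("segment extraction has the documented arithmetic and guards", {
  s <- small_session()
  d <- attr(small_tensor(), "dff")
  seg <- extract_pretrial_segments(d, s$trials, 30, "all",
                                   n_subsamples = 10, seed = 2)
  # a clean 6.5-s window at 30 Hz has 195 frames; 15 trials -> 2925
  lens <- lengths(seg$frames)
  expect_true(all(lens <= 195))
  expect_gte(max(lens), 190)
  expect_equal(ncol(seg$draws), 15)
  expect_equal(nrow(seg$draws), 10)
  seg2 <- extract_pretrial_segments(d, s$trials, 30, "all",
                                    n_subsamples = 10, seed = 2)
  expect_identical(seg$draws, seg2$draws)

  few <- s$trials[s$trials$trial_type == "go", ][1:14, ]
  expect_error(extract_pretrial_segments(d, few, 30, "all", seed = 1),
               "session skipped")
})

test_that("timescale fitting recovers known exponentials", {
  # exact model class: noiseless decay tau = 1.5 s
  fr <- 30
  n_frames <- 8000L
  dffm <- matrix(0, 12, n_frames)
  tr <- trial_record(1:12, seq(400L, by = 600L, length.out = 12), "go", 10L,
                     targeted_cell_ids = paste(1:10, collapse = ";"),
                     outcome = "hit")
  t_s <- (seq_len(round(5.5 * fr)) - 0.5) / fr
  for (i in seq_len(12)) {
    cols <- tr$onset_frame[i] + seq_len(round(5.5 * fr))
    dffm[1:10, cols] <- matrix(rep(0.5 * exp(-t_s / 1.5), each = 10), 10)
  }
  d <- structure(list(dff = dffm, kept_cell_ids = 1:12,
                      session_mean_F = rep(1, 12), dropped = integer(0)),
                 class = "optoprop_dff")
  cells <- cell_meta(1:12, "S1")
  ts <- fit_response_timescale(d, tr, cells, fr, "all",
                               n_subsamples = 20, seed = 1)
  expect_equal(ts$tau_post, 1.5, tolerance = 0.02)
  expect_equal(ts$A, 0.5, tolerance = 0.05)

  # 20% amplitude noise: within 15%
  set.seed(31)
  dffn <- dffm + matrix(rnorm(length(dffm), sd = 0.1), nrow(dffm))
  dn <- d; dn$dff <- dffn
  tsn <- fit_response_timescale(dn, tr, cells, fr, "all",
                                n_subsamples = 50, seed = 2)
  expect_lt(abs(tsn$tau_post - 1.5) / 1.5, 0.15)

  # flat response: degenerate fits are dropped / flagged
  df_ <- d; df_$dff[,] <- 0.2
  tsf <- fit_response_timescale(df_, tr, cells, fr, "all",
                                n_subsamples = 10, seed = 3)
  expect_true(tsf$flagged || tsf$n_failed > 0 || is.nan(tsf$tau_post))
})

test_that("the timescale law comparison prefers the generating model", {
  R <- c(0.5, 0.65, 0.8, 0.9, 0.95)
  tau <- 2 / (1 - R)
  cmp <- relate_timescale_recurrence(R, tau)
  expect_equal(cmp$r2_theory, 1, tolerance = 1e-10)
  expect_equal(cmp$c_theory, 2, tolerance = 1e-10)
  expect_true(cmp$theory_wins)

  cmp0 <- relate_timescale_recurrence(R, rep(3, 5))
  expect_lt(cmp0$r2_theory, 0.1)
  expect_error(relate_timescale_recurrence(c(0.5, 1.0, 0.7), c(1, 2, 3)),
               "R >= 1")
})

test_that("condition contrast is paired and refuses single sessions", {
  suppressWarnings({
    same <- recurrence_condition_contrast(c(0.9, 0.92, 0.88),
                                          c(0.9, 0.92, 0.88))
    expect_equal(same$median_diff, 0)
  })
  expect_error(recurrence_condition_contrast(0.9, 0.95), ">= 2 sessions")

  # condition-dependent ground truth: direction detected in most seeds
  detect <- 0
  for (s in 1:5) {
    Rh <- Rm <- numeric(6)
    for (i in 1:6) {
      net_h <- network_config(N_cells = 60, R_true = 0.80, seed = 100 * s + i)
      net_m <- network_config(N_cells = 60, R_true = 0.90, seed = 100 * s + i)
      Rh[i] <- recurrence_from_activity(
        simulate_rates(net_h, 4000, seed = 200 * s + i)$rates,
        N_assumed = 60)$R
      Rm[i] <- recurrence_from_activity(
        simulate_rates(net_m, 4000, seed = 300 * s + i)$rates,
        N_assumed = 60)$R
    }
    if (recurrence_condition_contrast(Rh, Rm)$median_diff > 0)
      detect <- detect + 1
  }
  expect_gte(detect, 4)
})

test_that("subsampled session recurrence is stable under trial-order shuffles", {
  s <- small_session()
  d <- attr(small_tensor(), "dff")
  seg <- extract_pretrial_segments(d, s$trials, 30, "all",
                                   n_subsamples = 15, seed = 4)
  r1 <- session_recurrence(seg, N_assumed = 5000)
  # shuffle the usable-trial order; the subsample distribution is unchanged
  seg2 <- seg
  perm <- sample(length(seg$frames))
  seg2$frames <- seg$frames[perm]
  r2 <- session_recurrence(seg2, N_assumed = 5000)
  expect_lt(abs(r1$R_mean - r2$R_mean), 0.05)
  expect_true(all(r1$R_per_subsample >= 0 & r1$R_per_subsample <= 0.995))
})
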