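test_that("make_connectivity hits the requested spectral radius exactly", {
  W <- make_connectivity(200, 0.9, seed = 7)
  expect_equal(max(Mod(eigen(W, only.values = TRUE)$values)), 0.9,
               tolerance = 1e-6)
  expect_identical(W, make_connectivity(200, 0.9, seed = 7))
  expect_true(all(make_connectivity(50, 0, seed = 1) == 0))
  expect_error(make_connectivity(50, 1.0, seed = 1), "unstable")
})

test_that("uncoupled noise-driven rates are white; recurrence adds memory", {
  lag1 <- function(r) {
    x <- colMeans(r)  # population mean trace
    cor(x[-1], x[-length(x)])
  }
  net0 <- network_config(N_cells = 50, R_true = 0, shared_gain = 0, seed = 2)
  r0 <- simulate_rates(net0, 20000, seed = 3)$rates
  ac0 <- mean(apply(r0[1:20, ], 1, function(x) cor(x[-1], x[-20000])))
  expect_lt(abs(ac0), 0.05)
  expect_lt(abs(lag1(r0)), 0.05)

  net9 <- network_config(N_cells = 50, R_true = 0.95, shared_gain = 0,
                         seed = 2)
  r9 <- simulate_rates(net9, 20000, seed = 3)$rates
  expect_gt(lag1(r9), lag1(r0) + 0.3)
})

test_that("the leading-mode timescale grows monotonically with recurrence", {
  # the intrinsic timescale lives on the leading eigenmode; project onto its
  # left eigenvector, whose lag-1 autocorrelation modulus equals |lambda_1|
  taus <- vapply(c(0.3, 0.5, 0.9, 0.99), function(R) {
    net <- network_config(N_cells = 40, R_true = R, shared_gain = 0, seed = 4)
    r <- simulate_rates(net, 10000, seed = 5)$rates
    e <- eigen(t(net$W))
    u <- e$vectors[, which.max(Mod(e$values))]
    z <- as.vector(t(Conj(u)) %*% r)
    ac <- Mod(sum(Conj(z[-1]) * z[-length(z)]) / sum(Mod(z)^2))
    -1 / log(min(max(ac, 1e-4), 0.9999))  # implied timescale, frames
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("shared input concentrates variance in the first factor", {
  net_s <- network_config(N_cells = 40, R_true = 0.3, shared_gain = 2,
                          n_latent = 1, seed = 6)
  net_n <- network_config(N_cells = 40, R_true = 0.3, shared_gain = 0,
                          seed = 6)
  ve1 <- function(net) {
    r <- simulate_rates(net, 5000, seed = 7)$rates
    remove_shared_activity(r, n_factors = 1,
                           report_factors = 1)$factor_variance_explained[1]
  }
  expect_gt(ve1(net_s), ve1(net_n) + 0.1)
})

test_that("trial schedule obeys the task's pseudorandom constraints", {
  for (seed in 1:5) {
    tr <- make_trial_schedule(300, 30, seed)
    main <- tr[tr$trial_type != "reward_only", ]
    # no more than three consecutive trials of the same type
    key <- ifelse(main$trial_type == "catch", "catch",
                  ifelse(main$n_targets == 150, "go150", "go_var"))
    expect_lte(max(rle(key)$lengths), 3)
    # variable-count go trials draw only from the allowed set
    counts <- main$n_targets[key == "go_var"]
    expect_true(all(counts %in% c(5, 10, 20, 30, 40, 50)))
    # equal thirds within binomial error (3 sd)
    p <- table(key) / nrow(main)
    expect_true(all(abs(p - 1 / 3) < 3 * sqrt(1 / 9 * 2 / 3 / nrow(main)) +
                      0.02))
  }
  # pre-session block: 10 reward-only trials spaced 10 s
  tr <- make_trial_schedule(50, 30, 1)
  ro <- tr[tr$trial_type == "reward_only", ]
  expect_equal(nrow(ro), 10)
  expect_true(all(diff(ro$onset_frame) == 300))
})

test_that("photostimulation injects only into targeted rows and windows", {
  m <- matrix(0, 10, 600)
  tr <- trial_record(1:2, c(100L, 400L), "go", c(5L, 5L),
                     targeted_cell_ids = "1;2;3;4;5")
  tg <- list(1:5, 1:5)
  expect_identical(apply_photostim(m, tr, tg, 0, 30), m)
  out <- apply_photostim(m, tr, tg, 2, 30)
  expect_equal(sort(unique(which(rowSums(out) > 0))), 1:5)
  # 250 ms at 30 Hz -> ceiling(7.5) = 8 frames
  expect_equal(sum(out[1, ] > 0), 16)
  expect_true(all(out[1, 101:108] == 2) && all(out[1, c(100, 109)] == 0))

  tr150 <- trial_record(1L, 100L, "go", 150L)
  out150 <- apply_photostim(m, tr150, list(1:5), 2, 30)
  # 760 ms -> 23 frames, ~0.77 s
  expect_equal(sum(out150[1, ] > 0), 23)

  tro <- trial_record(1:2, c(100L, 104L), "go", c(5L, 5L),
                      targeted_cell_ids = "1;2;3;4;5")
  expect_error(apply_photostim(m, tro, tg, 2, 30), "overlaps")
})

test_that("fluorescence rendering follows the closed-form kernel", {
  cal <- calcium_config(shot_noise_sd = 0, neuropil_mix = 0,
                        spike_gain_hz = 1e-9)
  # negligible spike intensity: soma sits at baseline
  r0 <- matrix(-50, 2, 300)
  fl <- render_fluorescence(r0, cal, seed = 1)
  expect_equal(fl$F_soma, matrix(cal$baseline_F, 2, 300), tolerance = 1e-6)

  # a single spike produces the kernel: peak near the rise time, and the
  # post-peak decay halves in decay * ln 2
  spikes <- matrix(0, 1, 600); spikes[1, 100] <- 1
  k <- optoprop:::conv_doe(spikes, 0.18, 1.4, 1 / 30)
  pk <- which.max(k[1, ])
  t_pk <- (pk - 100) / 30
  expect_lt(abs(t_pk - log(1.4 / 0.18) * 0.18 * 1.4 / (1.4 - 0.18)), 0.1)
  expect_equal(max(k), 1, tolerance = 1e-3)  # sampled between true peak frames
  # closed-form oracle: post-peak half-time of the continuous kernel
  doe <- function(t) exp(-t / 1.4) - exp(-t / 0.18)
  tpk_c <- log(1.4 / 0.18) * 0.18 * 1.4 / (1.4 - 0.18)
  t_half <- uniroot(function(t) doe(t) - doe(tpk_c) / 2, c(tpk_c, 10))$root -
    tpk_c
  half <- which(k[1, pk:600] <= max(k) / 2)[1] / 30
  expect_equal(half, t_half, tolerance = 0.1)
})

test_that("outcome draws follow the logistic model", {
  tr <- make_trial_schedule(1000, 30, 1)
  v <- rnorm(nrow(tr))
  m0 <- outcome_model(beta0 = 0, beta_ntargets = 0, beta_logvar = 0)
  out <- simulate_outcomes(tr, v, m0, seed = 2)
  go <- out$trial_type == "go"
  hr <- mean(out$outcome[go] == "hit")
  expect_lt(abs(hr - 0.5), 3 * sqrt(0.25 / sum(go)))

  msat <- outcome_model(beta0 = 0, beta_ntargets = 50, beta_logvar = 0)
  osat <- simulate_outcomes(tr, v, msat, seed = 3)
  expect_true(all(osat$outcome[osat$n_targets == 150] == "hit"))

  mv <- outcome_model(beta0 = 0.5, beta_ntargets = 0, beta_logvar = -1.5)
  ov <- simulate_outcomes(tr, v, mv, seed = 4)
  gv <- ov[ov$trial_type == "go", ]
  terc <- cut(rank(v[ov$trial_type == "go"]), 3, labels = FALSE)
  hr_t <- tapply(gv$outcome == "hit", terc, mean)
  expect_true(hr_t[1] > hr_t[2] && hr_t[2] > hr_t[3])
})

test_that("synthesize_session is deterministic and valid end to end", {
  s <- small_session()
  expect_length(validate_session(s), 0)
  net <- network_config(N_cells = 80, R_true = 0.8, seed = 5)
  s2 <- suppressWarnings(
    synthesize_session(net, n_trials = 60, seed = 5, n_candidates = 40))
  expect_identical(s$trials, s2$trials)
  expect_equal(s$F_soma, s2$F_soma)
  # the full pipeline runs without error on generator output
  tens <- small_tensor(baselined = TRUE)
  expect_s3_class(tens, "optoprop_tensor")
  st <- zscore_metrics(prestim_population_metrics(small_tensor()))
  expect_true(all(is.finite(st$z_pop_var)))
})
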