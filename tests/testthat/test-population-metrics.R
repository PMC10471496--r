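make_popstate <- function(pop_mean, pop_var, outcome,
                          n_targets = rep(10L, length(pop_mean))) {
  out <- data.frame(trial_id = seq_along(pop_mean),
                    trial_type = ifelse(outcome %in% c("hit", "miss"),
                                        "go", "catch"),
                    outcome = outcome, n_targets = n_targets,
                    pop_mean = pop_mean, pop_var = pop_var,
                    pop_var_t = log(pop_var))
  attr(out, "transform") <- "log"
  class(out) <- c("optoprop_popstate", "data.frame")
  out
}

test_that("pre-stimulus metrics use the 500-ms window and the n-1 variance", {
  # constant activity 0.2: mean 0.2, variance 0
  d <- structure(list(dff = matrix(0.2, 3, 600), kept_cell_ids = 1:3,
                      session_mean_F = rep(1, 3), dropped = integer(0)),
                 class = "optoprop_dff")
  tr <- trial_record(1L, 100L, "catch", 0L)
  tens <- segment_trials(d, tr, 30)
  st <- prestim_population_metrics(tens, transform = "identity")
  expect_equal(st$pop_mean, 0.2)
  expect_equal(st$pop_var, 0)

  # two cells at 0 and 1: sample variance 0.5
  d2 <- structure(list(dff = rbind(rep(0, 600), rep(1, 600)),
                       kept_cell_ids = 1:2, session_mean_F = c(1, 1),
                       dropped = integer(0)), class = "optoprop_dff")
  t2 <- segment_trials(d2, tr, 30)
  expect_equal(prestim_population_metrics(t2, transform = "identity")$pop_var,
               0.5)

  # exactly 15 frames enter at 30 Hz: only frames in [-0.5, 0) matter
  d3 <- d
  win_cols <- 101 - (15:1)        # 0-based frames 85..99 -> 1-based 86..100
  d3$dff[, win_cols] <- 1
  t3 <- segment_trials(d3, tr, 30)
  expect_equal(prestim_population_metrics(t3, transform = "identity")$pop_mean,
               1)
})

test_that("population variance is shift-invariant; the mean shifts exactly", {
  tens <- small_tensor()
  s1 <- prestim_population_metrics(tens, transform = "identity")
  tens2 <- tens
  tens2$data <- tens$data + 0.37
  s2 <- prestim_population_metrics(tens2, transform = "identity")
  expect_equal(s2$pop_var, s1$pop_var, tolerance = 1e-10)
  expect_equal(s2$pop_mean, s1$pop_mean + 0.37, tolerance = 1e-10)
})

test_that("the transform chooser identifies log-normal and normal samples", {
  set.seed(11)
  expect_identical(select_transform(rlnorm(5000, 0, 1)), "log")
  expect_identical(select_transform(rnorm(5000, 10, 1)), "identity")
  expect_warning(tf <- select_transform(rep(2, 100)), "degenerate")
  expect_identical(tf, "identity")
  expect_warning(tf2 <- select_transform(c(-1, rnorm(99))), "non-positive")
  expect_identical(tf2, "identity")
})

test_that("z-scoring is exact on two points, idempotent, and guards edge cases", {
  st <- make_popstate(c(1, 3), c(1, 2), c("hit", "miss"))
  z <- zscore_metrics(st)
  expect_equal(z$z_pop_mean, c(-1, 1) / sqrt(2))  # n-1 sd convention
  z2 <- zscore_metrics(z[, setdiff(names(z), c("z_pop_mean", "z_pop_var"))])
  expect_equal(z2$z_pop_mean, z$z_pop_mean, tolerance = 1e-12)
  expect_error(zscore_metrics(st[1, ]), ">= 2 trials")
  stc <- make_popstate(c(1, 1), c(1, 1), c("hit", "miss"))
  expect_error(zscore_metrics(stc), "zero spread")
})

test_that("outcome contrast finds variance differences only when generated", {
  gen_states <- function(beta_logvar, n_sessions, seed) {
    lapply(seq_len(n_sessions), function(i) {
      m <- outcome_model(beta0 = 0.6, beta_ntargets = 0,
                         beta_logvar = beta_logvar)
      tr <- make_trial_schedule(150, 30, seed + i)
      set.seed(seed + 100 + i)
      v <- rnorm(nrow(tr))
      tr <- simulate_outcomes(tr, v, m, seed + 200 + i)
      zscore_metrics(make_popstate(rnorm(nrow(tr)), exp(v), tr$outcome,
                                   tr$n_targets))
    })
  }
  st_null <- gen_states(0, 8, seed = 30)
  res_null <- outcome_contrast(st_null, "z_pop_var")
  expect_lt(abs(res_null$median_paired_diff), 0.25)

  hits <- 0
  for (s in 1:5) {
    st_eff <- gen_states(-1.5, 8, seed = 40 + 10 * s)
    if (outcome_contrast(st_eff, "z_pop_var")$median_paired_diff > 0)
      hits <- hits + 1
  }
  expect_gte(hits, 4)  # variance higher before misses in most seeds

  # the mean metric shows no systematic difference under the same generator
  st_eff <- gen_states(-1.5, 8, seed = 99)
  expect_lt(abs(outcome_contrast(st_eff, "z_pop_mean")$median_paired_diff),
            0.4)
})

test_that("hit rate declines across variance bins only under a negative beta", {
  gen_state <- function(beta_logvar, seed) {
    m <- outcome_model(beta0 = 0.5, beta_ntargets = 0,
                       beta_logvar = beta_logvar)
    tr <- make_trial_schedule(400, 30, seed)
    set.seed(seed + 1)
    v <- rnorm(nrow(tr))
    tr <- simulate_outcomes(tr, v, m, seed + 2)
    zscore_metrics(make_popstate(rnorm(nrow(tr)), exp(v), tr$outcome,
                                 tr$n_targets))
  }
  res0 <- hit_rate_by_variance(list(gen_state(0, 50)))
  expect_gt(res0$p_one_sided, 0.05)

  res_neg <- hit_rate_by_variance(lapply(1:4, function(i) gen_state(-2, 60 + i)))
  expect_true(mean(res_neg$p_bonferroni < 0.05) >= 0.5)
  expect_true(all(res_neg$slope < 0))

  # all-hit session: probability 1 in every bin, slope 0
  st1 <- make_popstate(rnorm(60), exp(rnorm(60)), rep("hit", 60))
  st1 <- zscore_metrics(st1)
  r1 <- hit_rate_by_variance(list(st1))
  expect_equal(r1$slope, 0)
})

test_that("the SNR surface projection is monotone when both factors act", {
  m <- outcome_model(beta0 = -1.3, beta_ntargets = 0.06, beta_logvar = -0.8)
  pooled <- do.call(rbind, lapply(1:8, function(i) {
    tr <- make_trial_schedule(300, 30, 70 + i)
    set.seed(80 + i)
    v <- rnorm(nrow(tr))
    tr <- simulate_outcomes(tr, v, m, 90 + i)
    go <- tr$trial_type == "go"
    data.frame(z_pop_var = scale(v[go])[, 1], n_targets = tr$n_targets[go],
               outcome = tr$outcome[go])
  }))
  srf <- snr_surface(pooled)
  expect_true(all(srf$grid$p_hit >= 0 & srf$grid$p_hit <= 1))
  rho <- cor(srf$projection$snr_coord, srf$projection$p_hit,
             method = "spearman")
  expect_gt(rho, 0.5)

  # outcome depending only on count still yields a count-monotone projection
  pooled2 <- pooled
  pooled2$outcome <- ifelse(pooled2$n_targets >= 30, "hit", "miss")
  srf2 <- snr_surface(pooled2)
  expect_gt(cor(srf2$projection$snr_coord, srf2$projection$p_hit,
                method = "spearman"), 0)
})

test_that("SNR logistic model: null data, recovery, nesting, rank check", {
  set.seed(7)
  null_df <- data.frame(outcome = sample(c("hit", "miss"), 2000, TRUE),
                        n_targets = sample(c(5, 10, 20, 30, 40, 50, 150),
                                           2000, TRUE),
                        z_pop_var = rnorm(2000))
  m0 <- snr_logistic_model(null_df)
  expect_lt(m0$mcfadden_r2, 0.005)

  m <- outcome_model()
  tr <- make_trial_schedule(3000, 30, 8)
  set.seed(9)
  v <- rnorm(nrow(tr))
  tr <- simulate_outcomes(tr, v, m, seed = 10)
  go <- tr$outcome %in% c("hit", "miss")
  df <- data.frame(outcome = tr$outcome[go], n_targets = tr$n_targets[go],
                   z_pop_var = scale(v[go])[, 1])
  fit <- snr_logistic_model(df)
  expect_gt(fit$coefficients["n_targets"], 0)
  expect_lt(fit$coefficients["z_pop_var"], 0)
  expect_true(all(fit$p_values[c("n_targets", "z_pop_var")] < 0.01))
  expect_gte(fit$mcfadden_r2, fit$mcfadden_r2_ntargets)
  expect_gte(fit$mcfadden_r2, fit$mcfadden_r2_popvar)
  expect_equal(fit$mcfadden_r2, 1 - fit$ll_model / fit$ll_null)

  dup <- null_df
  dup$z_pop_var <- dup$n_targets
  expect_error(snr_logistic_model(dup), "rank-deficient")
})

test_that("variance covariates report correlations and flag constants", {
  set.seed(12)
  st <- make_popstate(rnorm(100), exp(rnorm(100)),
                      sample(c("hit", "miss"), 100, TRUE))
  st <- zscore_metrics(st)
  shuffled <- variance_covariates(st, trial_index = sample(100))
  expect_lt(abs(shuffled$r[1]), 0.25)

  other <- st$z_pop_var + rnorm(100, sd = 0.5)
  res <- variance_covariates(st, other_region_var = other)
  expect_gt(res$r[res$covariate == "other_region"], 0.5)
  expect_warning(vc <- variance_covariates(st, trial_index = rep(1, 100)),
                 "constant covariate")
  expect_true(is.na(vc$r[1]))
})
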