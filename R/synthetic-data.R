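#' Draw a random recurrent weight matrix with a prescribed spectral bound
#'
#' The matrix is a random bulk of iid Gaussian entries (sd \eqn{1/\sqrt{N}})
#' plus, when `mean_coupling > 0`, a uniform rank-one component
#' \eqn{c\,\mathbf{1}\mathbf{1}^T/N} representing net positive mean recurrent
#' excitation. The whole matrix is rescaled so its spectral radius equals
#' `R_true` exactly (to numerical precision). With the default
#' `mean_coupling = 1` the leading eigenmode is the (near-uniform) mean mode
#' at eigenvalue `R_true`, so injected activity decays along it at rate
#' `R_true` per step and propagates across the population — the regime the
#' network-response-timescale analysis assumes; the random bulk sits just
#' inside. `mean_coupling = 0` gives the pure zero-mean (Ginibre) ensemble
#' used to calibrate the covariance-width inversion; the width pipeline
#' removes the uniform mode as shared activity, so both ensembles present the
#' same bulk to the recurrence estimator. `R_true = 0` returns the zero
#' matrix. Deterministic given `seed`.
#'
#' @param N_cells network size (>= 2).
#' @param R_true target spectral radius in `[0, 1)`.
#' @param seed integer seed.
#' @param mean_coupling uniform-mode eigenvalue as a fraction of `R_true`
#'   before the final rescale (default 1; 0 = pure random bulk).
#' @param bulk_scale relative weight of the random bulk against the uniform
#'   mode (default 1: bulk spectral edge just inside `R_true`). Smaller
#'   values give a cleaner leading-mode response — used when validating the
#'   response-timescale estimator against the known decay law.
#' @return `N_cells` x `N_cells` weight matrix.
#' @export
make_connectivity <- function(N_cells, R_true, seed, mean_coupling = 1,
                              bulk_scale = 1) {
  stopifnot(N_cells >= 2, mean_coupling >= 0, bulk_scale >= 0)
  if (R_true < 0 || R_true >= 1)
    stop("R_true must be in [0, 1): networks with spectral radius >= 1 are unstable")
  set.seed(seed)
  W <- bulk_scale *
    matrix(stats::rnorm(N_cells * N_cells, sd = 1 / sqrt(N_cells)),
           N_cells, N_cells)
  if (R_true == 0) return(W * 0)
  if (mean_coupling > 0) {
    # uniform mean-excitation mode at the bulk's spectral edge; with a small
    # bulk_scale it clearly leads (clean stimulated-response decay), while at
    # bulk_scale 1 the bulk edge stays at ~R_true (the width estimator's
    # estimand is not displaced)
    W <- W + (mean_coupling * max(bulk_scale, 0.98)) *
      matrix(1 / N_cells, N_cells, N_cells)
  }
  sr <- max(Mod(eigen(W, only.values = TRUE)$values))
  W * (R_true / sr)
}

#' Simulate linear recurrent rate dynamics
#'
#' Iterates \eqn{r_{t+1} = W r_t + g B f_t + u_t + \xi_t} from rest, where `f`
#' is an AR(1) latent with unit stationary variance and loadings `B` (drawn
#' once from `N(1, 0.5^2)/sqrt(n_latent)`, deterministically from `seed`), and
#' \eqn{\xi} is iid Gaussian private noise. Rates are in arbitrary units
#' centred on zero; stationarity is guaranteed by `R_true < 1`.
#'
#' @param net an [network_config()].
#' @param n_frames number of time steps (>= 1).
#' @param seed integer seed for noise, latent and loadings.
#' @param external_input optional cells x frames matrix added to the drive
#'   (used for photostimulation); `NULL` for none.
#' @param diverge_bound abort with a diagnostic if any |rate| exceeds this.
#' @return list with `rates` (cells x frames) and `latent`
#'   (n_latent x frames).
#' @export
simulate_rates <- function(net, n_frames, seed, external_input = NULL,
                           diverge_bound = 1e6) {
  stopifnot(inherits(net, "optoprop_network_config"), n_frames >= 1)
  N <- net$N_cells
  if (!is.null(external_input))
    stopifnot(nrow(external_input) == N, ncol(external_input) == n_frames)
  set.seed(seed)
  B <- matrix(stats::rnorm(N * net$n_latent, mean = 1, sd = 0.5), N,
              net$n_latent) / sqrt(net$n_latent)
  a <- net$latent_ar_coeff
  eps <- matrix(stats::rnorm(net$n_latent * n_frames), net$n_latent, n_frames)
  f <- matrix(0, net$n_latent, n_frames)
  f[, 1] <- eps[, 1]
  if (n_frames > 1) {
    sc <- sqrt(1 - a^2)
    for (t in 2:n_frames) f[, t] <- a * f[, t - 1] + sc * eps[, t]
  }
  drive <- (net$shared_gain * B) %*% f +
    matrix(stats::rnorm(N * n_frames, sd = net$private_noise_sd), N, n_frames)
  if (!is.null(external_input)) drive <- drive + external_input
  r <- linear_recursion(net$W, drive, diverge_bound)
  list(rates = r, latent = f)
}

#' Generate the behavioural trial schedule
#'
#' Emulates the task structure: a pre-session block of 10 reward-only trials
#' at 10-s spacing, followed by `n_trials` pseudorandom main trials with equal
#' 1/3 proportions of 150-target go, variable-count go (counts drawn with
#' replacement from {5, 10, 20, 30, 40, 50}) and catch trials, with no more
#' than three consecutive trials of the same type. Consecutive onsets are
#' separated by the 5-s inter-trial interval, a lick-withhold drawn uniformly
#' from 4-6 s, and the 1-s response period. Outcomes are left `"unscored"` and
#' targeted cells unassigned (see [synthesize_session()]).
#'
#' @param n_trials number of main trials (>= 1).
#' @param frame_rate_hz imaging frame rate.
#' @param seed integer seed.
#' @return trial table (see [trial_record()]).
#' @export
make_trial_schedule <- function(n_trials, frame_rate_hz = 30, seed = 1L) {
  stopifnot(n_trials >= 1, frame_rate_hz > 0)
  set.seed(seed)
  types <- c("go150", "go_var", "catch")
  seq_types <- character(n_trials)
  for (i in seq_len(n_trials)) {
    avail <- types
    if (i > 3 && length(unique(seq_types[(i - 3):(i - 1)])) == 1)
      avail <- setdiff(types, seq_types[i - 1])
    seq_types[i] <- sample(avail, 1)
  }
  n_targets <- integer(n_trials)
  n_targets[seq_types == "go150"] <- 150L
  n_var <- sum(seq_types == "go_var")
  n_targets[seq_types == "go_var"] <-
    sample(c(5L, 10L, 20L, 30L, 40L, 50L), n_var, replace = TRUE)
  trial_type <- ifelse(seq_types == "catch", "catch", "go")

  reward_onsets_s <- seq(0, by = 10, length.out = 10)
  # main block starts 30 s after the last pre-session reward
  t0 <- reward_onsets_s[10] + 30
  gaps_s <- 5 + stats::runif(n_trials, 4, 6) + 1
  main_onsets_s <- t0 + cumsum(gaps_s)
  onsets_s <- c(reward_onsets_s, main_onsets_s)
  rbind(
    trial_record(seq_len(10), round(reward_onsets_s * frame_rate_hz),
                 "reward_only", 0L, reward_time_ms = 0),
    trial_record(10L + seq_len(n_trials),
                 round(main_onsets_s * frame_rate_hz),
                 trial_type, n_targets)
  )
}

#' Inject photostimulation into a rate or input matrix
#'
#' Adds `stim_amplitude` to the rows of the targeted cells for the duration of
#' each go trial's stimulation window (250 ms for 5-50 targets, 760 ms for 150
#' targets; frame count = `ceiling(duration * rate)`). All other entries are
#' untouched. When applied to the external-input matrix of [simulate_rates()],
#' the injected activity propagates through the recurrent weights.
#'
#' @param rates cells x frames matrix (rates or external input).
#' @param trials trial table with onset frames and stim durations.
#' @param targets_per_trial list (one element per trial row) of row indices
#'   into `rates` to perturb; empty for unstimulated trials.
#' @param stim_amplitude additive amplitude (rate units).
#' @param frame_rate_hz frame rate used to convert durations to frames.
#' @return perturbed copy of `rates`.
#' @export
apply_photostim <- function(rates, trials, targets_per_trial, stim_amplitude,
                            frame_rate_hz = 30) {
  stopifnot(length(targets_per_trial) == nrow(trials))
  if (stim_amplitude == 0) return(rates)
  n_frames <- ncol(rates)
  prev_end <- -1L
  for (i in seq_len(nrow(trials))) {
    rows <- targets_per_trial[[i]]
    if (length(rows) == 0 || trials$stim_duration_ms[i] <= 0) next
    if (any(rows < 1 | rows > nrow(rates)))
      stop("targeted cell index out of range on trial ", trials$trial_id[i])
    start <- trials$onset_frame[i] + 1L  # onset_frame is 0-based
    len <- ceiling(trials$stim_duration_ms[i] / 1000 * frame_rate_hz)
    end <- min(start + len - 1L, n_frames)
    if (start <= prev_end)
      stop("stimulation on trial ", trials$trial_id[i],
           " overlaps the previous trial's window")
    rates[rows, start:end] <- rates[rows, start:end] + stim_amplitude
    prev_end <- end
  }
  rates
}

# peak-normalised difference-of-exponentials kernel applied by two recursive
# exponential filters (exact discrete convolution, O(N T))
conv_doe <- function(x, rise_s, decay_s, dt_s) {
  ad <- exp(-dt_s / decay_s)
  ar <- exp(-dt_s / rise_s)
  tpk <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  peak <- exp(-tpk / decay_s) - exp(-tpk / rise_s)
  filt <- function(v, a) as.numeric(stats::filter(v, a, method = "recursive"))
  out <- t(apply(x, 1, function(v) (filt(v, ad) - filt(v, ar)) / peak))
  out
}

#' Render rates into raw fluorescence traces
#'
#' Spikes are Poisson with intensity `spike_gain_hz * softplus(rate +
#' spike_offset)`, convolved with the peak-normalised difference-of-
#' exponentials kernel. The soma channel is `baseline_F + gain * signal +
#' 0.7 * neuropil + shot noise`, so that the standard neuropil subtraction
#' with coefficient 0.7 recovers the cell's own signal; the neuropil channel
#' is `neuropil_mix` times the population-average signal (plus baseline and
#' independent noise).
#'
#' @param rates cells x frames rate matrix.
#' @param cal an [calcium_config()].
#' @param seed integer seed.
#' @param dt_s frame interval in seconds.
#' @return list with matrices `F_soma`, `F_neuropil` and the spike count
#'   matrix `spikes`.
#' @export
render_fluorescence <- function(rates, cal, seed, dt_s = 1 / 30) {
  stopifnot(inherits(cal, "optoprop_calcium_config"), all(is.finite(rates)))
  set.seed(seed)
  lam <- cal$spike_gain_hz * log1p(exp(pmin(rates + cal$spike_offset, 30)))
  spikes <- matrix(stats::rpois(length(lam), lam * dt_s), nrow(rates))
  sig <- cal$gain * conv_doe(spikes, cal$kernel_rise_s, cal$kernel_decay_s,
                             dt_s)
  pop_sig <- colMeans(sig)
  F_np <- cal$neuropil_mix *
    (cal$baseline_F + matrix(pop_sig, nrow(rates), ncol(rates),
                             byrow = TRUE)) +
    matrix(stats::rnorm(length(rates), sd = cal$shot_noise_sd), nrow(rates))
  F_soma <- cal$baseline_F + sig + 0.7 * F_np +
    matrix(stats::rnorm(length(rates), sd = cal$shot_noise_sd), nrow(rates))
  list(F_soma = F_soma, F_neuropil = F_np, spikes = spikes)
}

#' Draw behavioural outcomes from the SNR model
#'
#' Go trials become hits with probability
#' `plogis(beta0 + beta_ntargets * n + beta_logvar * v)` where `v` is the
#' supplied pre-stimulus log population variance (z-scored across go trials
#' within the session before use); catch trials are false positives at the
#' model's base rate; reward-only trials stay unscored. Responders receive a
#' first-lick latency drawn uniformly from 150-1000 ms.
#'
#' @param trials trial table.
#' @param prestim_logvar numeric vector, one value per trial row (only go
#'   trials need finite values).
#' @param model an [outcome_model()].
#' @param seed integer seed.
#' @return scored trial table.
#' @export
simulate_outcomes <- function(trials, prestim_logvar, model, seed) {
  stopifnot(inherits(model, "optoprop_outcome_model"),
            length(prestim_logvar) == nrow(trials))
  set.seed(seed)
  go <- which(trials$trial_type == "go")
  if (any(!is.finite(prestim_logvar[go])))
    stop("every go trial needs a finite prestim_logvar")
  v <- prestim_logvar
  if (length(go) > 1 && stats::sd(v[go]) > 0)
    v[go] <- (v[go] - mean(v[go])) / stats::sd(v[go])
  p_hit <- stats::plogis(model$beta0 + model$beta_ntargets * trials$n_targets[go] +
                           model$beta_logvar * v[go])
  hit <- stats::runif(length(go)) < p_hit
  trials$outcome[go] <- ifelse(hit, "hit", "miss")
  trials$first_lick_ms[go][hit] <- stats::runif(sum(hit), 150, 1000)
  trials$reward_time_ms[go][hit] <- trials$first_lick_ms[go][hit]
  ca <- which(trials$trial_type == "catch")
  fp <- stats::runif(length(ca)) < model$fa_rate
  trials$outcome[ca] <- ifelse(fp, "false_positive", "correct_rejection")
  trials$first_lick_ms[ca][fp] <- stats::runif(sum(fp), 150, 1000)
  trials
}

#' Generate a complete synthetic session
#'
#' Composes the generator: connectivity, trial schedule, target assignment
#' among photoresponsive S1 cells, photostimulation injected as external input
#' (so it propagates through the network), linear rate dynamics with shared
#' latent input, behavioural outcomes from the SNR model, and GCaMP6s-like
#' fluorescence rendering. Fully deterministic given `seed`; the result passes
#' [validate_session()].
#'
#' Cells are split `frac_s1` / `1 - frac_s1` between S1 and S2;
#' `n_candidates` photoresponsive S1 cells (default 150, the size of the
#' responsive pool identified before each experimental session) form the
#' target pool. 150-target trials stimulate the whole pool.
#'
#' @param net an [network_config()] (or `NULL` for defaults).
#' @param cal an [calcium_config()] (or `NULL` for defaults).
#' @param model an [outcome_model()] (or `NULL` for defaults).
#' @param n_trials number of main trials.
#' @param seed integer seed.
#' @param stim_amplitude photostimulation drive per targeted cell (rate units).
#' @param frac_s1 fraction of cells labelled S1.
#' @param n_candidates size of the photoresponsive S1 target pool.
#' @param session_id character label.
#' @param render logical; if `FALSE`, skip calcium rendering and store rates
#'   directly (faster; used for rate-level analyses).
#' @return An `optoprop_session` with the simulated ground truth attached as
#'   attribute `"ground_truth"` (rates, latent, configs).
#' @export
synthesize_session <- function(net = NULL, cal = NULL, model = NULL,
                               n_trials = 150L, seed = 1L,
                               stim_amplitude = 3, frac_s1 = 0.6,
                               n_candidates = 150L, session_id = NULL,
                               render = TRUE) {
  net <- net %||% network_config(seed = seed)
  cal <- cal %||% calcium_config()
  model <- model %||% outcome_model()
  if (is.null(session_id)) session_id <- sprintf("synthetic-%d", seed)
  fr <- 1 / net$dt_s
  N <- net$N_cells
  n_s1 <- as.integer(round(frac_s1 * N))
  n_candidates <- as.integer(min(n_candidates, n_s1))

  trials <- make_trial_schedule(n_trials, fr, seed)
  n_frames <- max(trials$onset_frame) + round(10 * fr)

  set.seed(seed + 1L)
  cells <- cell_meta(
    cell_id = seq_len(N),
    region = rep(c("S1", "S2"), c(n_s1, N - n_s1)),
    x_um = c(stats::runif(n_s1, 0, 700), stats::runif(N - n_s1, 700, 1400)),
    y_um = stats::runif(N, 0, 700),
    is_target_candidate = rep(FALSE, N)
  )
  cand <- sample(seq_len(n_s1), n_candidates)
  cells$is_target_candidate[cand] <- TRUE
  cells$min_target_distance_um <- ifelse(cells$is_target_candidate,
                                         stats::runif(N, 0, 15),
                                         stats::runif(N, 20, 300))

  # assign target identities per go trial
  targets <- vector("list", nrow(trials))
  for (i in which(trials$trial_type == "go")) {
    k <- as.integer(min(trials$n_targets[i], n_candidates))
    trials$n_targets[i] <- k
    trials$stim_duration_ms[i] <- if (k >= 150) 760 else 250
    targets[[i]] <- sort(sample(cand, k))
  }
  trials$targeted_cell_ids <- join_target_ids(lapply(targets, function(v) {
    if (is.null(v)) integer(0) else cells$cell_id[v]
  }))

  u <- apply_photostim(matrix(0, N, n_frames), trials, targets,
                       stim_amplitude, fr)
  sim <- simulate_rates(net, n_frames, seed + 2L, external_input = u)

  # pre-stimulus population variance of the latent rates drives the outcome
  pre_frames <- round(0.5 * fr)
  logvar <- vapply(seq_len(nrow(trials)), function(i) {
    w <- (trials$onset_frame[i] - pre_frames + 1):trials$onset_frame[i]
    if (min(w) < 1) return(NA_real_)
    log(stats::var(rowMeans(sim$rates[, w, drop = FALSE])))
  }, numeric(1))
  trials <- simulate_outcomes(trials, logvar, model, seed + 3L)

  if (render) {
    fl <- render_fluorescence(sim$rates, cal, seed + 4L, net$dt_s)
    F_soma <- fl$F_soma
    F_np <- fl$F_neuropil
  } else {
    F_soma <- sim$rates + 10  # positive offset so dF/F is well defined
    F_np <- matrix(0, N, n_frames)
  }
  s <- session_data(F_soma, F_np, cells, trials, fr, session_id)
  attr(s, "ground_truth") <- list(net = net, cal = cal, model = model,
                                  latent = sim$latent,
                                  prestim_logvar = logvar)
  s
}
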