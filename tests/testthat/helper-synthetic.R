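# Shared fixtures, built in code. The small session is generated once per
# test run and reused read-only by several files.

the_fixtures <- new.env()

small_session <- function() {
  if (is.null(the_fixtures$session)) {
    net <- network_config(N_cells = 80, R_true = 0.8, seed = 5)
    the_fixtures$session <- suppressWarnings(
      synthesize_session(net, n_trials = 60, seed = 5, n_candidates = 40))
  }
  the_fixtures$session
}

small_tensor <- function(baselined = FALSE) {
  key <- if (baselined) "tensor_b" else "tensor"
  if (is.null(the_fixtures[[key]])) {
    tens <- suppressWarnings(preprocess_session(small_session()))
    the_fixtures$tensor <- tens
    the_fixtures$tensor_b <- baseline_post_stimulus(tens)
  }
  the_fixtures[[key]]
}

# minimal hand-built session: 2 cells, deterministic traces
tiny_session <- function(n_trials = 1) {
  n_frames <- 400L
  F_soma <- matrix(rep(c(10, 20), each = n_frames), nrow = 2, byrow = TRUE)
  F_np <- matrix(1, 2, n_frames)
  cells <- cell_meta(1:2, c("S1", "S2"), x_um = c(0, 1000), y_um = c(0, 0),
                     min_target_distance_um = c(5, 100),
                     is_target_candidate = c(TRUE, FALSE))
  trials <- trial_record(seq_len(n_trials),
                         onset_frame = 100L + 150L * (seq_len(n_trials) - 1L),
                         trial_type = "go", n_targets = 1L,
                         targeted_cell_ids = "1")
  session_data(F_soma, F_np, cells, trials[seq_len(n_trials), , drop = FALSE],
               30, "tiny")
}

# hand-built trial tensor with a known injected class signal, for decoding
# tests: `signal` is added to the first `n_sig_cells` cells of positive-class
# trials on post-stimulus frames
make_decoding_tensor <- function(n_per_class = 30, n_cells = 20, n_frames = 30,
                                 n_pre = 10, signal = 1, n_sig_cells = 5,
                                 noise_sd = 1, seed = 1,
                                 labels = c("correct_rejection", "hit"),
                                 extra_label = NULL, n_extra = 0) {
  set.seed(seed)
  n_sig_cells <- min(n_sig_cells, n_cells)
  n_tr <- 2 * n_per_class + n_extra
  data <- array(rnorm(n_tr * n_cells * n_frames, sd = noise_sd),
                c(n_tr, n_cells, n_frames))
  post <- (n_pre + 1):n_frames
  pos <- (n_per_class + 1):(2 * n_per_class)
  data[pos, seq_len(n_sig_cells), post] <-
    data[pos, seq_len(n_sig_cells), post] + signal
  outcome <- c(rep(labels[1], n_per_class), rep(labels[2], n_per_class),
               rep(if (is.null(extra_label)) character(0) else extra_label,
                   n_extra))
  trial_type <- ifelse(outcome == "reward_only", "reward_only",
                       ifelse(outcome %in% c("hit", "miss"), "go", "catch"))
  trials <- trial_record(seq_len(n_tr), seq_len(n_tr) * 1000L, trial_type,
                         n_targets = ifelse(trial_type == "go", 10L, 0L),
                         targeted_cell_ids = ifelse(trial_type == "go",
                                                    paste(1:10, collapse = ";"),
                                                    ""),
                         outcome = outcome)
  structure(list(
    data = data,
    time_axis_s = (seq_len(n_frames) - n_pre - 1) / 30,
    blank_mask = matrix(FALSE, n_tr, n_frames),
    baselined = TRUE,
    trials = trials,
    kept_cell_ids = seq_len(n_cells),
    frame_rate_hz = 30
  ), class = "optoprop_tensor")
}

# trial-level behavioural generation (no imaging): schedule + outcomes from a
# known model, with latent log-variance draws
simulate_behavior_only <- function(n_trials, model, seed) {
  tr <- make_trial_schedule(n_trials, 30, seed)
  set.seed(seed + 1000)
  logvar <- rnorm(nrow(tr))
  simulate_outcomes(tr, logvar, model, seed + 2000)
}
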