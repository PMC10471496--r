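#' Network configuration for the synthetic session generator
#'
#' The generator simulates a discrete-time linear recurrent rate network at the
#' imaging frame rate: \eqn{r_{t+1} = W r_t + g B f_t + u_t + \xi_t}, with iid
#' Gaussian recurrent weights `W` rescaled so that the spectral radius equals
#' `R_true`, a low-dimensional AR(1) latent input `f` (the "shared" activity),
#' optional external input `u` (photostimulation), and Gaussian private noise
#' \eqn{\xi}.
#'
#' @param N_cells number of neurons (>= 2).
#' @param R_true spectral bound of `W`, in `[0, 1)`. Default 0.9: a strongly
#'   recurrent but comfortably stable operating point.
#' @param n_latent dimension of the shared latent input.
#' @param latent_ar_coeff AR(1) coefficient of the latent, in `[0, 1)`;
#'   0.9 at 30 Hz gives a slow (~0.3 s) state fluctuation.
#' @param private_noise_sd standard deviation of per-cell private noise (> 0).
#' @param shared_gain gain `g` applied to the shared input (>= 0).
#' @param dt_s simulation step in seconds (default 1/30, the frame interval).
#' @param seed integer seed used to draw `W` (and latent loadings).
#' @param mean_coupling uniform mean-excitation component of `W`, see
#'   [make_connectivity()] (default 1).
#' @param bulk_scale relative weight of the random bulk, see
#'   [make_connectivity()] (default 1).
#' @return A list of class `optoprop_network_config` with the realised weight
#'   matrix `W` attached.
#' @export
network_config <- function(N_cells = 300L, R_true = 0.9, n_latent = 1L,
                           latent_ar_coeff = 0.9, private_noise_sd = 1,
                           shared_gain = 1, dt_s = 1 / 30, seed = 1L,
                           mean_coupling = 1, bulk_scale = 1) {
  stopifnot(N_cells >= 2, R_true >= 0, R_true < 1,
            latent_ar_coeff >= 0, latent_ar_coeff < 1,
            private_noise_sd > 0, shared_gain >= 0, dt_s > 0)
  W <- make_connectivity(N_cells, R_true, seed, mean_coupling, bulk_scale)
  structure(list(
    N_cells = as.integer(N_cells), R_true = R_true, W = W,
    n_latent = as.integer(n_latent), latent_ar_coeff = latent_ar_coeff,
    private_noise_sd = private_noise_sd, shared_gain = shared_gain,
    dt_s = dt_s, seed = as.integer(seed)
  ), class = "optoprop_network_config")
}

#' Calcium rendering configuration
#'
#' Parameters of the spike-to-fluorescence forward model: Poisson spikes with
#' intensity given by a softplus-rectified affine map of the rate, convolved
#' with a difference-of-exponentials kernel (peak-normalised), scaled and
#' offset into raw fluorescence with additive shot noise. Kernel defaults
#' emulate GCaMP6s (rise 0.18 s, decay 1.4 s); they are configuration, not
#' constants of the method.
#'
#' @param kernel_rise_s,kernel_decay_s kernel time constants in seconds
#'   (decay > rise > 0).
#' @param baseline_F baseline fluorescence (arbitrary units, > 0).
#' @param gain fluorescence units per convolved spike (> 0).
#' @param shot_noise_sd additive Gaussian noise sd (>= 0).
#' @param neuropil_mix fraction of the population-average signal entering the
#'   neuropil channel, in `[0, 1]`.
#' @param spike_gain_hz scale of the softplus rate-to-intensity map (Hz).
#' @param spike_offset offset of the affine map (rate units).
#' @return A list of class `optoprop_calcium_config`.
#' @export
calcium_config <- function(kernel_rise_s = 0.18, kernel_decay_s = 1.4,
                           baseline_F = 100, gain = 20, shot_noise_sd = 2,
                           neuropil_mix = 0.4, spike_gain_hz = 5,
                           spike_offset = 0) {
  stopifnot(kernel_rise_s > 0, kernel_decay_s > kernel_rise_s,
            baseline_F > 0, gain > 0, shot_noise_sd >= 0,
            neuropil_mix >= 0, neuropil_mix <= 1, spike_gain_hz > 0)
  structure(list(
    kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
    baseline_F = baseline_F, gain = gain, shot_noise_sd = shot_noise_sd,
    neuropil_mix = neuropil_mix, spike_gain_hz = spike_gain_hz,
    spike_offset = spike_offset
  ), class = "optoprop_calcium_config")
}

#' Behavioural outcome model
#'
#' Generative counterpart of the SNR analysis: on go trials,
#' \eqn{P(hit) = logistic(\beta_0 + \beta_n n + \beta_v v)} where `n` is the
#' number of targeted cells and `v` the within-session z-scored log population
#' variance in the 0.5 s before stimulation. Catch trials lick (false
#' positive) at a fixed base rate. Defaults are calibrated by simulation
#' (`scripts/calibrate_outcome_model.R`) so the psychometric 50% point lands
#' near 22 targeted cells.
#'
#' @param beta0 intercept.
#' @param beta_ntargets coefficient on the number of targeted cells.
#' @param beta_logvar coefficient on the z-scored log population variance
#'   (negative: high variance suppresses detection).
#' @param fa_rate catch-trial false-positive (lick) base rate.
#' @return A list of class `optoprop_outcome_model`.
#' @export
outcome_model <- function(beta0 = -1.68, beta_ntargets = 0.12,
                          beta_logvar = -0.5, fa_rate = 0.1) {
  stopifnot(is.finite(beta0), is.finite(beta_ntargets), is.finite(beta_logvar),
            fa_rate >= 0, fa_rate <= 1)
  structure(list(beta0 = beta0, beta_ntargets = beta_ntargets,
                 beta_logvar = beta_logvar, fa_rate = fa_rate),
            class = "optoprop_outcome_model")
}

#' Read generator configuration from YAML
#'
#' Accepts a file with optional top-level sections `network`, `calcium`,
#' `outcome` and `session`; entries override the corresponding constructor
#' defaults.
#'
#' @param path YAML file.
#' @return list with elements `network`, `calcium`, `outcome`, `session`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    network = do.call(network_config, cfg$network %||% list()),
    calcium = do.call(calcium_config, cfg$calcium %||% list()),
    outcome = do.call(outcome_model, cfg$outcome %||% list()),
    session = cfg$session %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
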