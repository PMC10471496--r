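#' Neuropil subtraction
#'
#' `F = F_soma - coeff * F_neuropil`, elementwise, with the standard
#' coefficient 0.7.
#'
#' @param F_soma,F_neuropil equal-shape numeric matrices (cells x frames).
#' @param coeff neuropil coefficient (default 0.7).
#' @return corrected fluorescence matrix.
#' @export
neuropil_subtract <- function(F_soma, F_neuropil, coeff = 0.7) {
  if (!identical(dim(F_soma), dim(F_neuropil)))
    stop("F_soma and F_neuropil must have identical shape")
  F_soma - coeff * F_neuropil
}

#' Compute dF/F with the whole-session mean as baseline
#'
#' \eqn{\Delta F/F = (F - \bar F)/\bar F} per cell, where \eqn{\bar F} is the
#' mean of the (neuropil-corrected) trace across the entire session. Cells
#' whose session mean fails the positivity guard (below `1e-6` times the 95th
#' percentile of all session means) would produce meaningless ratios and are
#' dropped and reported; neuropil subtraction can drive means to or below
#' zero.
#'
#' @param F corrected fluorescence matrix (cells x frames).
#' @param cell_ids optional ids for the rows (default `1:ncells`).
#' @return An object of class `optoprop_dff`: list with `dff` matrix,
#'   `kept_cell_ids`, `session_mean_F`, and `dropped` (ids that failed the
#'   positivity guard).
#' @export
compute_dff <- function(F, cell_ids = seq_len(nrow(F))) {
  mF <- rowMeans(F)
  thresh <- 1e-6 * stats::quantile(mF, 0.95, names = FALSE)
  keep <- mF > max(thresh, 0)
  if (!any(keep))
    stop("all cells dropped: no positive session-mean fluorescence")
  dff <- sweep(F[keep, , drop = FALSE], 1, mF[keep], "-") / mF[keep]
  structure(list(dff = dff, kept_cell_ids = cell_ids[keep],
                 session_mean_F = mF[keep], dropped = cell_ids[!keep]),
            class = "optoprop_dff")
}

#' Discard cells with implausibly large dF/F transients
#'
#' Cells with `max(dF/F) > max_dff` (default 10) are unlikely to reflect
#' spiking and are removed.
#'
#' @param dff an `optoprop_dff`.
#' @param max_dff threshold (default 10).
#' @return filtered `optoprop_dff`.
#' @export
qc_filter_cells <- function(dff, max_dff = 10) {
  stopifnot(inherits(dff, "optoprop_dff"))
  keep <- apply(dff$dff, 1, max) <= max_dff
  structure(list(dff = dff$dff[keep, , drop = FALSE],
                 kept_cell_ids = dff$kept_cell_ids[keep],
                 session_mean_F = dff$session_mean_F[keep],
                 dropped = c(dff$dropped, dff$kept_cell_ids[!keep])),
            class = "optoprop_dff")
}

#' Frames blanked by the photostimulation laser, session-wide
#'
#' For each go trial: `ceiling(duration * rate)` stimulation frames starting
#' at the onset frame, plus two frames on each side. Returns 1-based column
#' indices into the session's trace matrices.
#' @keywords internal
blanked_frames <- function(trials, frame_rate_hz, n_frames) {
  idx <- integer(0)
  for (i in which(trials$trial_type == "go" & trials$stim_duration_ms > 0)) {
    start <- trials$onset_frame[i] + 1L
    len <- ceiling(trials$stim_duration_ms[i] / 1000 * frame_rate_hz)
    idx <- c(idx, (start - 2L):(start + len + 1L))
  }
  idx <- idx[idx >= 1L & idx <= n_frames]
  sort(unique(idx))
}

#' Cut trial-aligned dF/F tensors with photostimulation blanking
#'
#' Windows span 2 s before to 8 s after trial onset (onset = photostimulation
#' for go, sham-spiral onset for catch, reward for reward-only). Frames while
#' the stimulation laser was on, plus two frames on each side, are blanked:
#' they are `NA` in the tensor and `TRUE` in `blank_mask`, and must never
#' enter downstream statistics. Trials whose window does not fit inside the
#' recording are dropped with a warning.
#'
#' @param dff an `optoprop_dff`.
#' @param trials trial table.
#' @param frame_rate_hz imaging frame rate (> 0).
#' @return An object of class `optoprop_tensor`: list with `data`
#'   (trials x cells x frames), `time_axis_s`, `blank_mask` (trials x frames),
#'   `baselined` flag, the retained `trials` table, `kept_cell_ids` and
#'   `frame_rate_hz`.
#' @export
segment_trials <- function(dff, trials, frame_rate_hz) {
  stopifnot(inherits(dff, "optoprop_dff"))
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  n_pre <- round(2 * frame_rate_hz)
  n_post <- round(8 * frame_rate_hz)
  n_frames <- ncol(dff$dff)
  win_len <- n_pre + n_post
  start0 <- trials$onset_frame - n_pre          # 0-based window start
  ok <- start0 >= 0 & (trials$onset_frame + n_post - 1) < n_frames
  if (any(!ok))
    warning(sprintf("dropping %d trial(s) whose window exceeds the recording",
                    sum(!ok)))
  tr <- trials[ok, , drop = FALSE]
  n_tr <- nrow(tr)
  n_cells <- nrow(dff$dff)
  data <- array(NA_real_, c(n_tr, n_cells, win_len))
  mask <- matrix(FALSE, n_tr, win_len)
  stim_frames <- blanked_frames(tr, frame_rate_hz, n_frames)
  for (i in seq_len(n_tr)) {
    cols <- (tr$onset_frame[i] - n_pre + 1):(tr$onset_frame[i] + n_post)
    data[i, , ] <- dff$dff[, cols]
    if (tr$trial_type[i] == "go") {
      b <- cols %in% stim_frames
      mask[i, b] <- TRUE
      data[i, , b] <- NA_real_
    }
  }
  structure(list(
    data = data,
    time_axis_s = ((-n_pre):(n_post - 1)) / frame_rate_hz,
    blank_mask = mask,
    baselined = FALSE,
    trials = tr,
    kept_cell_ids = dff$kept_cell_ids,
    frame_rate_hz = frame_rate_hz
  ), class = "optoprop_tensor")
}

#' Subtract the pre-stimulus baseline from post-stimulus activity
#'
#' Per trial and per cell, the mean dF/F over the 2-s pre-onset window is
#' subtracted from the post-onset trace; pre-onset frames are left unmodified.
#' Applying twice is an error.
#'
#' @param tensor an `optoprop_tensor`.
#' @return baselined tensor.
#' @export
baseline_post_stimulus <- function(tensor) {
  stopifnot(inherits(tensor, "optoprop_tensor"))
  if (isTRUE(tensor$baselined)) stop("tensor is already baselined")
  pre <- tensor$time_axis_s < 0
  post <- !pre
  base <- apply(tensor$data[, , pre, drop = FALSE], c(1, 2), mean,
                na.rm = TRUE)
  tensor$data[, , post] <- tensor$data[, , post, drop = FALSE] -
    array(base, c(dim(base), sum(post)))
  tensor$baselined <- TRUE
  tensor
}

#' Display ordering of cells for trial-type rasters
#'
#' Orders cells from strongly inhibited to strongly excited by the sum of
#' their trial-averaged post-stimulus responses across hit, miss and
#' reward-only trials. Ties are broken by cell id. Display-only.
#'
#' @param tensor a baselined `optoprop_tensor`.
#' @param trial_types trial types/outcomes to sum over; defaults to hit,
#'   miss and reward-only trials.
#' @return integer vector of `kept_cell_ids` in display order.
#' @export
sort_cells_for_raster <- function(tensor,
                                  trial_types = c("hit", "miss", "reward_only")) {
  stopifnot(inherits(tensor, "optoprop_tensor"), isTRUE(tensor$baselined))
  post <- tensor$time_axis_s >= 0
  lab <- ifelse(tensor$trials$trial_type == "reward_only", "reward_only",
                tensor$trials$outcome)
  score <- rep(0, dim(tensor$data)[2])
  for (tt in trial_types) {
    sel <- lab == tt
    if (!any(sel)) next
    m <- apply(tensor$data[sel, , post, drop = FALSE], 2, mean, na.rm = TRUE)
    score <- score + m
  }
  ord <- order(score, tensor$kept_cell_ids)
  tensor$kept_cell_ids[ord]
}

#' Full preprocessing chain for one session
#'
#' Neuropil subtraction (0.7), dF/F with session-mean baseline, max-dF/F cell
#' QC, and trial segmentation with blanking.
#'
#' @param session an `optoprop_session`.
#' @param max_dff QC threshold.
#' @return an `optoprop_tensor` (not baselined), with the session-level
#'   `optoprop_dff` attached as attribute `"dff"`.
#' @export
preprocess_session <- function(session, max_dff = 10) {
  F <- neuropil_subtract(session$F_soma, session$F_neuropil)
  d <- qc_filter_cells(compute_dff(F, session$cells$cell_id), max_dff)
  tens <- segment_trials(d, session$trials, session$frame_rate_hz)
  attr(tens, "dff") <- d
  tens
}
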