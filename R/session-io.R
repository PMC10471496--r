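#' Write a session to an HDF5 container
#'
#' Layout: one file per session with datasets `/traces/soma` and
#' `/traces/neuropil` (cells x frames, float64), compound tables `/cells` and
#' `/trials`, and scalar datasets `/session_id` and `/frame_rate_hz`. Optional
#' times (`first_lick_ms`, `reward_time_ms`) are stored as NaN when absent and
#' restored to `NA` on read. The write -> read round trip is lossless for
#' integers and strings and exact to float64 precision for traces.
#'
#' @param session a valid `optoprop_session` (see [validate_session()]).
#' @param path output file path (`.h5`).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  viol <- validate_session(session)
  if (length(viol) > 0)
    stop("invalid session:\n  ", paste(viol, collapse = "\n  "))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "traces")
  for (nm in c("soma", "neuropil")) {
    m <- if (nm == "soma") session$F_soma else session$F_neuropil
    rhdf5::h5createDataset(path, paste0("traces/", nm), dims = dim(m),
                           storage.mode = "double",
                           chunk = c(nrow(m), min(ncol(m), 4096L)),
                           level = 4)
    rhdf5::h5write(m, path, paste0("traces/", nm))
  }
  cells <- session$cells
  # HDF5 compounds have no logical type; stored as 0/1 integer
  cells$is_target_candidate <- as.integer(cells$is_target_candidate)
  rhdf5::h5write(cells, path, "cells")
  tr <- session$trials
  if (nrow(tr) == 0) {
    # rhdf5 cannot write 0-row compounds; store an empty marker instead
    rhdf5::h5write(0L, path, "trials_empty")
  } else {
    tr$first_lick_ms[is.na(tr$first_lick_ms)] <- NaN
    tr$reward_time_ms[is.na(tr$reward_time_ms)] <- NaN
    rhdf5::h5write(tr, path, "trials")
  }
  rhdf5::h5write(session$session_id, path, "session_id")
  rhdf5::h5write(session$frame_rate_hz, path, "frame_rate_hz")
  invisible(path)
}

#' Read a session from an HDF5 container
#'
#' Inverse of [write_session()]. Raises a format error naming any missing
#' group/dataset and a validation error if the stored session violates the
#' data-model invariants (e.g. mismatched trace shapes or trial tables that
#' reference unknown cells).
#'
#' @param path HDF5 file written by [write_session()] or conforming to the
#'   documented layout.
#' @return An `optoprop_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  present <- rhdf5::h5ls(path)$name
  needed <- c("soma", "neuropil", "cells", "session_id", "frame_rate_hz")
  missing <- setdiff(needed, present)
  if (length(missing) > 0)
    stop("session container is missing field(s): ",
         paste(missing, collapse = ", "))
  soma <- rhdf5::h5read(path, "traces/soma")
  neuropil <- rhdf5::h5read(path, "traces/neuropil")
  # h5read returns 1-d arrays; strip dims so columns are plain vectors
  undim <- function(df) { df[] <- lapply(df, as.vector); df }
  cells <- undim(as.data.frame(rhdf5::h5read(path, "cells"),
                               stringsAsFactors = FALSE))
  cells$cell_id <- as.integer(cells$cell_id)
  cells$is_target_candidate <- as.logical(cells$is_target_candidate)
  if ("trials" %in% present) {
    tr <- undim(as.data.frame(rhdf5::h5read(path, "trials"),
                              stringsAsFactors = FALSE))
    tr$first_lick_ms[is.nan(tr$first_lick_ms)] <- NA_real_
    tr$reward_time_ms[is.nan(tr$reward_time_ms)] <- NA_real_
    for (cn in c("trial_id", "onset_frame", "n_targets"))
      tr[[cn]] <- as.integer(tr[[cn]])
    tr$stim_duration_ms <- as.numeric(tr$stim_duration_ms)
    tr <- tr[, trial_columns()]
  } else {
    tr <- trial_record(integer(0), integer(0), character(0))
  }
  s <- session_data(soma, neuropil,
                    cells[, c("cell_id", "region", "x_um", "y_um",
                              "min_target_distance_um", "is_target_candidate")],
                    tr,
                    frame_rate_hz = rhdf5::h5read(path, "frame_rate_hz"),
                    session_id = rhdf5::h5read(path, "session_id"))
  viol <- validate_session(s)
  if (length(viol) > 0)
    stop("stored session is invalid:\n  ", paste(viol, collapse = "\n  "))
  s
}

#' Export / import the trial table as CSV
#'
#' Column order is fixed: trial_id, onset_frame, trial_type, n_targets,
#' targeted_cell_ids (semicolon-joined), first_lick_ms, reward_time_ms,
#' outcome, stim_duration_ms.
#'
#' @param trials a trial table.
#' @param path CSV file path.
#' @return `path` (write) or the trial table (read).
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials[, trial_columns()], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(targeted_cell_ids = "character"))
  missing <- setdiff(trial_columns(), names(tr))
  if (length(missing) > 0)
    stop("trial CSV is missing column(s): ", paste(missing, collapse = ", "))
  tr$trial_id <- as.integer(tr$trial_id)
  tr$onset_frame <- as.integer(tr$onset_frame)
  tr$n_targets <- as.integer(tr$n_targets)
  tr$targeted_cell_ids[is.na(tr$targeted_cell_ids)] <- ""
  tr[, trial_columns()]
}
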