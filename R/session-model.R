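#' Construct a cell metadata table
#'
#' One row per imaged cell. `min_target_distance_um` is the distance from the
#' cell's soma to the nearest photostimulation beam centre across the session's
#' stimulation groups; cells within 15 um of a beam centre count as targets.
#'
#' @param cell_id integer vector, unique within a session.
#' @param region character, one of `"S1"` or `"S2"` per cell.
#' @param x_um,y_um soma position in micrometres.
#' @param min_target_distance_um non-negative distance to the nearest beam
#'   centre, in micrometres.
#' @param is_target_candidate logical; whether the cell is photoresponsive and
#'   eligible to be targeted.
#' @return A `data.frame` with one row per cell.
#' @export
cell_meta <- function(cell_id, region, x_um = NA_real_, y_um = NA_real_,
                      min_target_distance_um = NA_real_,
                      is_target_candidate = FALSE) {
  data.frame(
    cell_id = as.integer(cell_id),
    region = as.character(region),
    x_um = as.numeric(x_um),
    y_um = as.numeric(y_um),
    min_target_distance_um = as.numeric(min_target_distance_um),
    is_target_candidate = as.logical(is_target_candidate),
    stringsAsFactors = FALSE
  )
}

#' Column order of the trial table
#' @keywords internal
trial_columns <- function() {
  c("trial_id", "onset_frame", "trial_type", "n_targets", "targeted_cell_ids",
    "first_lick_ms", "reward_time_ms", "outcome", "stim_duration_ms")
}

trial_types <- c("go", "catch", "reward_only")
trial_outcomes <- c("hit", "miss", "false_positive", "correct_rejection",
                    "too_soon", "unscored")

#' Construct a trial table
#'
#' Times are milliseconds relative to trial onset; `onset_frame` is a 0-based
#' frame index into the session's fluorescence matrices. Targeted cell ids are
#' stored as a semicolon-joined string (the same encoding used by the CSV
#' export). Missing licks/rewards are `NA`, never sentinel values.
#'
#' @param trial_id integer vector.
#' @param onset_frame 0-based frame index of stimulation (go), sham-spiral
#'   onset (catch) or reward delivery (reward_only).
#' @param trial_type one of `"go"`, `"catch"`, `"reward_only"`.
#' @param n_targets number of cells targeted (0 for catch/reward_only).
#' @param targeted_cell_ids semicolon-joined cell ids (`""` if none).
#' @param first_lick_ms,reward_time_ms optional times in ms relative to onset.
#' @param outcome one of `"hit"`, `"miss"`, `"false_positive"`,
#'   `"correct_rejection"`, `"too_soon"`, `"unscored"`.
#' @param stim_duration_ms photostimulation duration: 250 for 5-50 targets,
#'   760 for 150 targets, 0 otherwise.
#' @return A `data.frame` with one row per trial.
#' @export
trial_record <- function(trial_id, onset_frame, trial_type, n_targets = 0L,
                         targeted_cell_ids = "", first_lick_ms = NA_real_,
                         reward_time_ms = NA_real_, outcome = "unscored",
                         stim_duration_ms = NULL) {
  n <- length(trial_id)
  n_targets <- rep_len(as.integer(n_targets), n)
  if (is.null(stim_duration_ms)) {
    stim_duration_ms <- ifelse(n_targets >= 150, 760,
                               ifelse(n_targets > 0, 250, 0))
  }
  if (n == 0) {
    return(data.frame(trial_id = integer(0), onset_frame = integer(0),
                      trial_type = character(0), n_targets = integer(0),
                      targeted_cell_ids = character(0),
                      first_lick_ms = numeric(0), reward_time_ms = numeric(0),
                      outcome = character(0), stim_duration_ms = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    trial_id = as.integer(trial_id),
    onset_frame = as.integer(onset_frame),
    trial_type = as.character(trial_type),
    n_targets = n_targets,
    targeted_cell_ids = as.character(targeted_cell_ids),
    first_lick_ms = as.numeric(first_lick_ms),
    reward_time_ms = as.numeric(reward_time_ms),
    outcome = as.character(outcome),
    stim_duration_ms = as.numeric(stim_duration_ms),
    stringsAsFactors = FALSE
  )
}

#' Parse semicolon-joined targeted cell ids
#' @param x character vector of semicolon-joined ids.
#' @return list of integer vectors (length 0 for empty strings).
#' @export
parse_target_ids <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) as.integer(v[nzchar(v)]))
}

#' Join targeted cell ids into the semicolon encoding
#' @param ids list of integer vectors.
#' @return character vector.
#' @export
join_target_ids <- function(ids) {
  vapply(ids, function(v) paste(v, collapse = ";"), character(1))
}

#' Assemble a session object
#'
#' Ties raw soma and neuropil fluorescence (cells x frames, typically 30 Hz),
#' cell metadata and the behavioural trial table for one recording session.
#'
#' @param F_soma,F_neuropil numeric matrices (cells x frames), identical shape;
#'   rows follow `cells$cell_id` order.
#' @param cells cell metadata table, see [cell_meta()].
#' @param trials trial table, see [trial_record()].
#' @param frame_rate_hz imaging frame rate in Hz (default 30).
#' @param session_id character label.
#' @return An object of class `optoprop_session`.
#' @export
session_data <- function(F_soma, F_neuropil, cells, trials,
                         frame_rate_hz = 30, session_id = "session") {
  s <- structure(list(
    session_id = as.character(session_id),
    frame_rate_hz = as.numeric(frame_rate_hz),
    F_soma = as.matrix(F_soma),
    F_neuropil = as.matrix(F_neuropil),
    cells = cells,
    trials = trials
  ), class = "optoprop_session")
  s
}

#' @export
print.optoprop_session <- function(x, ...) {
  cat(sprintf("<optoprop_session '%s'>  %d cells x %d frames @ %g Hz, %d trials\n",
              x$session_id, nrow(x$F_soma), ncol(x$F_soma), x$frame_rate_hz,
              nrow(x$trials)))
  invisible(x)
}

#' Validate a session object
#'
#' Checks every structural invariant of the session data model and returns a
#' character vector of human-readable violations (empty when the session is
#' valid). Violations are reported, never thrown; `validate_session` is a pure
#' function of its input.
#'
#' @param session an `optoprop_session`.
#' @return character vector of violations (length 0 if valid).
#' @export
validate_session <- function(session) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!is.matrix(session$F_soma) || !is.matrix(session$F_neuropil)) {
    add("F_soma and F_neuropil must be matrices")
    return(v)
  }
  if (!identical(dim(session$F_soma), dim(session$F_neuropil)))
    add(sprintf("shape mismatch: F_soma %s vs F_neuropil %s",
                paste(dim(session$F_soma), collapse = "x"),
                paste(dim(session$F_neuropil), collapse = "x")))
  if (!isTRUE(session$frame_rate_hz > 0))
    add("frame_rate_hz must be positive")
  cells <- session$cells
  if (nrow(cells) != nrow(session$F_soma))
    add(sprintf("cells table has %d rows but F_soma has %d rows",
                nrow(cells), nrow(session$F_soma)))
  if (anyDuplicated(cells$cell_id))
    add("cell_id values are not unique")
  bad_region <- !cells$region %in% c("S1", "S2")
  if (any(bad_region))
    add(sprintf("invalid region label(s) for cell_id %s",
                paste(cells$cell_id[bad_region], collapse = ",")))
  if (any(!is.na(cells$min_target_distance_um) &
          cells$min_target_distance_um < 0))
    add("min_target_distance_um must be non-negative")
  tr <- session$trials
  if (nrow(tr) > 0) {
    if (is.unsorted(tr$onset_frame, strictly = TRUE))
      add("trial onset frames must be strictly increasing")
    go_zero <- tr$trial_type == "go" & tr$n_targets <= 0
    for (i in which(go_zero))
      add(sprintf("trial %d: go trial with n_targets = %d",
                  tr$trial_id[i], tr$n_targets[i]))
    nz <- tr$trial_type != "go" & tr$n_targets != 0
    for (i in which(nz))
      add(sprintf("trial %d: %s trial with n_targets = %d",
                  tr$trial_id[i], tr$trial_type[i], tr$n_targets[i]))
    bad_type <- !tr$trial_type %in% trial_types
    for (i in which(bad_type))
      add(sprintf("trial %d: unknown trial_type '%s'",
                  tr$trial_id[i], tr$trial_type[i]))
    bad_out <- !tr$outcome %in% trial_outcomes
    for (i in which(bad_out))
      add(sprintf("trial %d: unknown outcome '%s'",
                  tr$trial_id[i], tr$outcome[i]))
    ids <- parse_target_ids(tr$targeted_cell_ids)
    n_ids <- lengths(ids)
    mismatch <- n_ids != tr$n_targets
    for (i in which(mismatch))
      add(sprintf("trial %d: %d targeted_cell_ids but n_targets = %d",
                  tr$trial_id[i], n_ids[i], tr$n_targets[i]))
    unknown <- !unlist(ids) %in% cells$cell_id
    if (any(unknown))
      add(sprintf("targeted_cell_ids not present in cells: %s",
                  paste(unique(unlist(ids)[unknown]), collapse = ",")))
    if (any(!is.na(tr$first_lick_ms) & tr$first_lick_ms < 0))
      add("first_lick_ms must be non-negative")
  }
  v
}
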