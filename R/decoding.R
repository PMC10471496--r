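#' Time-resolved decoding of trial type from population activity
#'
#' For every timeframe, an L2-penalised logistic regression (regularisation
#' strength 0.001, the value selected by a factor-10 parameter sweep over
#' 1e-7..1e3) is trained to separate two trial classes from the vector of one
#' scalar dF/F value per cell, under 4-fold cross-validation: classes are
#' balanced once per fold by randomly subsampling the majority class, each
#' retained trial appears in the held-out set exactly once per timepoint, and
#' accuracy is the fold-averaged held-out fraction correct. Timepoints at
#' which any trial is blanked are skipped (`NA`).
#'
#' @param tensor a baselined `optoprop_tensor`.
#' @param labels length-2 character vector naming the negative and positive
#'   class; matched against outcomes, with `"reward_only"` matched against
#'   trial type. E.g. `c("correct_rejection", "hit")`.
#' @param n_folds folds (default 4, a 3:1 train:test split).
#' @param lambda ridge penalty (default 0.001).
#' @param seed integer seed (balancing + fold assignment).
#' @param region optional `"S1"`/`"S2"` cell filter (needs `cells` metadata).
#' @param cells optional cell metadata for region filtering.
#' @return object of class `optoprop_decoding`: `accuracy` (per timepoint),
#'   `time_axis_s`, `models` (per timepoint list of per-fold coefficient
#'   vectors), `folds`, `trial_rows`, `labels`, `cell_cols`.
#' @export
train_timepoint_decoders <- function(tensor, labels, n_folds = 4,
                                     lambda = 0.001, seed = 1L,
                                     region = NULL, cells = NULL) {
  stopifnot(inherits(tensor, "optoprop_tensor"), length(labels) == 2)
  lab_of <- function(tr) ifelse(tr$trial_type == "reward_only", "reward_only",
                                tr$outcome)
  y_all <- lab_of(tensor$trials)
  rows <- which(y_all %in% labels)
  y <- as.integer(y_all[rows] == labels[2])
  cols <- seq_len(dim(tensor$data)[2])
  if (!is.null(region)) {
    stopifnot(!is.null(cells))
    cols <- which(cells$region[match(tensor$kept_cell_ids, cells$cell_id)] ==
                    region)
  }
  if (min(table(y)) < n_folds)
    stop("a class has fewer trials than folds: pair skipped")
  set.seed(seed)
  # balance classes by subsampling the majority
  n_min <- min(table(y))
  keep <- c(sample(which(y == 0), n_min), sample(which(y == 1), n_min))
  rows <- rows[keep]; y <- y[keep]
  if (length(y) < 2 * n_folds) stop("need >= 8 balanced trials")
  # stratified fold assignment
  folds <- integer(length(y))
  folds[y == 0] <- sample(rep_len(seq_len(n_folds), n_min))
  folds[y == 1] <- sample(rep_len(seq_len(n_folds), n_min))
  n_t <- dim(tensor$data)[3]
  acc <- rep(NA_real_, n_t)
  models <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    X <- tensor$data[rows, cols, t, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = length(cols))
    if (anyNA(X)) next                      # blanked timepoint
    correct <- logical(length(y))
    fmods <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      te <- folds == f
      fit <- glmnet::glmnet(X[!te, , drop = FALSE], y[!te],
                            family = "binomial", alpha = 0, lambda = lambda,
                            standardize = FALSE)
      pred <- stats::predict(fit, X[te, , drop = FALSE], type = "response")
      correct[te] <- (pred > 0.5) == (y[te] == 1)
      fmods[[f]] <- as.numeric(stats::coef(fit))
    }
    acc[t] <- mean(correct)
    models[[t]] <- fmods
  }
  structure(list(accuracy = acc, time_axis_s = tensor$time_axis_s,
                 models = models, folds = folds, trial_rows = rows,
                 labels = labels, cell_cols = cols, n_folds = n_folds,
                 lambda = lambda),
            class = "optoprop_decoding")
}

#' Evaluate trained decoders on a third trial type
#'
#' Applies the per-timepoint, per-fold models of a trained decoder to trials
#' of a different type (e.g. reward-only or miss trials, which never appear
#' in training) and reports the fold-averaged fraction classified as the
#' positive class at each timepoint.
#'
#' @param decoder an `optoprop_decoding` from [train_timepoint_decoders()].
#' @param tensor the tensor the decoder was trained on.
#' @param eval_label trial label to evaluate (`"reward_only"`, `"miss"`, ...).
#' @return numeric vector (per timepoint) of classified-as-positive
#'   fractions; `NA` at skipped timepoints or if the label is absent.
#' @export
cross_condition_evaluate <- function(decoder, tensor, eval_label) {
  stopifnot(inherits(decoder, "optoprop_decoding"))
  lab <- ifelse(tensor$trials$trial_type == "reward_only", "reward_only",
                tensor$trials$outcome)
  rows <- which(lab == eval_label)
  n_t <- length(decoder$accuracy)
  out <- rep(NA_real_, n_t)
  if (length(rows) == 0) return(out)
  for (t in seq_len(n_t)) {
    fmods <- decoder$models[[t]]
    if (is.null(fmods)) next
    X <- tensor$data[rows, decoder$cell_cols, t, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = length(decoder$cell_cols))
    if (anyNA(X)) next
    fr <- vapply(fmods, function(cf) {
      eta <- cf[1] + X %*% cf[-1]
      mean(stats::plogis(eta) > 0.5)
    }, numeric(1))
    out[t] <- mean(fr)
  }
  out
}

#' Per-timepoint significance of decoding across sessions
#'
#' Two-sided Wilcoxon signed-rank test of session accuracies against chance
#' (0.5) at every timepoint, Bonferroni corrected over the number of tested
#' timepoints. Timepoints with undefined tests (all accuracies identical to
#' chance, or missing) are masked `NA`.
#'
#' @param accuracy_matrix sessions x timepoints accuracy matrix (>= 6
#'   sessions recommended; < 2 refused).
#' @param chance chance level (0.5 for balanced classes).
#' @param alpha significance level before correction (default 0.05).
#' @return list with `significant` (logical per timepoint, `NA` where
#'   untestable), `p_raw`, `p_bonferroni`, `n_tested`.
#' @export
significance_profile <- function(accuracy_matrix, chance = 0.5, alpha = 0.05) {
  if (is.null(dim(accuracy_matrix)) || nrow(accuracy_matrix) < 2)
    stop("need accuracies from >= 2 sessions")
  if (nrow(accuracy_matrix) < 6)
    warning("fewer than 6 sessions: signed-rank test has little power")
  n_t <- ncol(accuracy_matrix)
  p <- rep(NA_real_, n_t)
  for (t in seq_len(n_t)) {
    a <- accuracy_matrix[, t]
    a <- a[is.finite(a)]
    if (length(a) < 2 || all(a == chance)) next
    p[t] <- suppressWarnings(
      stats::wilcox.test(a, mu = chance)$p.value)
  }
  n_tested <- sum(is.finite(p))
  p_adj <- pmin(1, p * n_tested)
  list(significant = p_adj < alpha, p_raw = p, p_bonferroni = p_adj,
       n_tested = n_tested)
}
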