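#' Classify a cell's response sign on a trial set
#'
#' Default criterion: two-sided Wilcoxon signed-rank test of the trial-wise
#' mean baselined post-stimulus response (0-1.5 s, unblanked frames) against
#' zero at `alpha`; the sign of the median labels significant cells excited
#' or inhibited, everything else is neutral. Sets with fewer than `min_trials`
#' trials are neutral with a flag. Window, test level and window bounds are
#' configuration, not constants.
#'
#' @param tensor a baselined `optoprop_tensor`.
#' @param trial_rows integer rows of `tensor$trials` forming the trial set.
#' @param window_s response window in seconds (default `c(0, 1.5)`).
#' @param alpha test level (default 0.05).
#' @param min_trials minimum trials (default 5).
#' @return data.frame: cell_id, class (`"excited"`/`"inhibited"`/`"neutral"`),
#'   statistic, p, median_response, flagged.
#' @export
classify_response_sign <- function(tensor, trial_rows, window_s = c(0, 1.5),
                                   alpha = 0.05, min_trials = 5) {
  stopifnot(inherits(tensor, "optoprop_tensor"), isTRUE(tensor$baselined))
  sel <- tensor$time_axis_s >= window_s[1] & tensor$time_axis_s < window_s[2]
  n_cells <- dim(tensor$data)[2]
  flagged <- length(trial_rows) < min_trials
  out <- data.frame(cell_id = tensor$kept_cell_ids,
                    class = "neutral", statistic = NA_real_, p = NA_real_,
                    median_response = NA_real_, flagged = flagged,
                    stringsAsFactors = FALSE)
  if (flagged) return(out)
  for (c_ in seq_len(n_cells)) {
    v <- apply(tensor$data[trial_rows, c_, sel, drop = FALSE], 1, mean,
               na.rm = TRUE)
    v <- v[is.finite(v)]
    if (length(v) < min_trials) { out$flagged[c_] <- TRUE; next }
    wt <- suppressWarnings(stats::wilcox.test(v, mu = 0, exact = FALSE))
    out$statistic[c_] <- unname(wt$statistic)
    out$p[c_] <- wt$p.value
    out$median_response[c_] <- stats::median(v)
    if (is.finite(wt$p.value) && wt$p.value < alpha)
      out$class[c_] <- if (stats::median(v) > 0) "excited" else "inhibited"
  }
  out
}

#' Excited / inhibited fractions versus stimulation strength
#'
#' Weighted least-squares line through the per-strength fractions, with
#' inverse-variance weights clipped to their 25th-75th percentile range to
#' prevent extreme weights; slope p-value by two-sided t-test. With equal
#' variances the fit reduces exactly to ordinary least squares.
#'
#' @param fractions data.frame with columns `n_targets`, `fraction` and
#'   optionally `var` (across-trial variance behind each point; equal
#'   weights when absent).
#' @return list with `slope`, `intercept`, `p_value`, `weights`, `fit`.
#' @export
fractions_vs_strength <- function(fractions) {
  stopifnot(all(c("n_targets", "fraction") %in% names(fractions)))
  if (length(unique(fractions$n_targets)) < 3)
    stop("need >= 3 strength levels")
  w <- if (!is.null(fractions$var) && any(fractions$var > 0)) {
    wi <- 1 / pmax(fractions$var, 1e-12)
    q <- stats::quantile(wi, c(0.25, 0.75))
    pmin(pmax(wi, q[1]), q[2])
  } else rep(1, nrow(fractions))
  fit <- stats::lm(fraction ~ n_targets, data = fractions, weights = w)
  sm <- summary(fit)$coefficients
  list(slope = sm["n_targets", "Estimate"],
       intercept = sm["(Intercept)", "Estimate"],
       p_value = sm["n_targets", "Pr(>|t|)"],
       weights = w, fit = fit)
}

#' Steiger's Z for two dependent, non-overlapping correlations
#'
#' Compares `cor(x1, y1)` with `cor(x2, y2)` measured on the same sample
#' (shared sessions, different variable pairs), using the Pearson-Filon
#' covariance of the two correlations and Fisher's z.
#'
#' @param x1,y1,x2,y2 numeric vectors of equal length (>= 4).
#' @return list with `r1`, `r2`, `z`, `p` (two-tailed).
#' @export
steiger_test <- function(x1, y1, x2, y2) {
  n <- length(x1)
  stopifnot(length(y1) == n, length(x2) == n, length(y2) == n)
  if (n < 4) stop("need >= 4 paired observations")
  r12 <- stats::cor(x1, y1); r34 <- stats::cor(x2, y2)
  r13 <- stats::cor(x1, x2); r14 <- stats::cor(x1, y2)
  r23 <- stats::cor(y1, x2); r24 <- stats::cor(y1, y2)
  if (abs(r12 - r34) < .Machine$double.eps^0.5)
    return(list(r1 = r12, r2 = r34, z = 0, p = 1))
  psi <- ((r13 - r23 * r12) * (r24 - r23 * r34) +
          (r14 - r13 * r34) * (r23 - r13 * r12) +
          (r13 - r14 * r34) * (r24 - r14 * r12) +
          (r14 - r12 * r24) * (r23 - r24 * r34)) / 2
  cv <- psi / ((1 - r12^2) * (1 - r34^2))
  z1 <- atanh(r12); z2 <- atanh(r34)
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cv))
  list(r1 = r12, r2 = r34, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Correlation between excitation and inhibition, with a regional comparison
#'
#' Pearson correlation (t-test) between the fraction of excited and the
#' fraction of inhibited cells across session x strength points, and -- when
#' a second region's fractions are supplied -- Steiger's test comparing the
#' two dependent correlations.
#'
#' @param frac_excited,frac_inhibited paired fraction vectors (>= 4 points).
#' @param frac_excited2,frac_inhibited2 optional second region's fractions on
#'   the same points.
#' @return list with `r`, `p` and, when comparing, `r2`, `steiger_z`,
#'   `steiger_p`.
#' @export
ei_correlation <- function(frac_excited, frac_inhibited,
                           frac_excited2 = NULL, frac_inhibited2 = NULL) {
  if (length(frac_excited) < 4) stop("need >= 4 paired points")
  ct <- stats::cor.test(frac_excited, frac_inhibited)
  out <- list(r = unname(ct$estimate), p = ct$p.value)
  if (!is.null(frac_excited2)) {
    st <- steiger_test(frac_excited, frac_inhibited,
                       frac_excited2, frac_inhibited2)
    out$r2 <- st$r2; out$steiger_z <- st$z; out$steiger_p <- st$p
  }
  out
}

#' Post-stimulus response of targets, S1 non-targets and S2 cells
#'
#' Groups cells into S1 targets (within 15 um of a beam centre, inclusive),
#' S1 non-targets and S2 cells, and reports each group's area under the
#' trial-averaged post-stimulus dF/F curve (unblanked frames, trapezoid-free
#' discrete sum x frame interval). Targeted cells are excluded from the
#' non-target pool on the trials in which they were targeted by using the
#' session-level distance threshold.
#'
#' @param tensor a baselined `optoprop_tensor`.
#' @param cells cell metadata with `min_target_distance_um` and `region`.
#' @param trial_rows trial set (e.g. go trials with photostimulation).
#' @param target_radius_um target definition radius (default 15, inclusive).
#' @return data.frame: group, auc, n_cells (empty groups skipped).
#' @export
target_response_auc <- function(tensor, cells, trial_rows,
                                target_radius_um = 15) {
  stopifnot(inherits(tensor, "optoprop_tensor"), isTRUE(tensor$baselined))
  meta <- cells[match(tensor$kept_cell_ids, cells$cell_id), ]
  grp <- ifelse(meta$region == "S2", "S2",
                ifelse(meta$min_target_distance_um <= target_radius_um,
                       "S1_target", "S1_nontarget"))
  post <- tensor$time_axis_s >= 0
  dt <- 1 / tensor$frame_rate_hz
  out <- do.call(rbind, lapply(c("S1_target", "S1_nontarget", "S2"),
    function(g) {
      ix <- which(grp == g)
      if (length(ix) == 0) return(NULL)
      tr <- apply(tensor$data[trial_rows, ix, post, drop = FALSE], 3, mean,
                  na.rm = TRUE)
      data.frame(group = g, auc = sum(tr, na.rm = TRUE) * dt,
                 n_cells = length(ix))
    }))
  rownames(out) <- NULL
  out
}

#' Cross-session tests of group responses against zero
#'
#' Two-sided Wilcoxon signed-rank test of per-session AUCs against zero for
#' each cell group, Bonferroni corrected over groups.
#'
#' @param auc_table row-bound [target_response_auc()] results across sessions
#'   (columns `group`, `auc`).
#' @return data.frame: group, mean_auc, p_raw, p_bonferroni, n_sessions.
#' @export
target_response_summary <- function(auc_table) {
  groups <- unique(auc_table$group)
  res <- do.call(rbind, lapply(groups, function(g) {
    a <- auc_table$auc[auc_table$group == g]
    p <- if (length(a) >= 2 && stats::sd(a) > 0)
      suppressWarnings(stats::wilcox.test(a, mu = 0, exact = FALSE)$p.value)
    else NA_real_
    data.frame(group = g, mean_auc = mean(a), p_raw = p,
               n_sessions = length(a))
  }))
  res$p_bonferroni <- pmin(1, res$p_raw * length(groups))
  res
}
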