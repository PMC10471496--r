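# Maximum-likelihood factor analysis by EM on the sample covariance.
# Written for speed on wide populations (hundreds of cells x long recordings):
# each iteration is O(p^2 k), so it scales to the subsampled-segment loop of
# the recurrence estimator where stats::factanal (which it is cross-checked
# against in the tests) would dominate the runtime.

#' Fit a factor model S ~ Lambda Lambda' + Psi by EM
#'
#' @param S p x p sample covariance matrix.
#' @param n_factors number of factors (>= 1).
#' @param max_iter,tol EM iteration controls (convergence on relative
#'   log-likelihood change).
#' @param n_restart random restarts on non-convergence before failing.
#' @param seed seed for initialisation jitter on restarts.
#' @return list with `loadings` (p x k, columns ordered by explained
#'   variance), `uniquenesses` (psi vector), `converged`, `loglik_path`.
#' @keywords internal
fa_em <- function(S, n_factors, max_iter = 500, tol = 1e-7, n_restart = 2,
                  seed = 1L) {
  p <- nrow(S)
  stopifnot(n_factors >= 1, n_factors < p)
  ev <- eigen(S, symmetric = TRUE)
  run <- function(jitter) {
    k <- n_factors
    L <- ev$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[seq_len(k)], 1e-10)), k)
    if (jitter > 0) L <- L * (1 + jitter * stats::rnorm(length(L)))
    psi <- pmax(diag(S) - rowSums(L^2), 1e-6)
    ll_old <- -Inf; path <- numeric(0)
    for (it in seq_len(max_iter)) {
      Lp <- L / psi                                   # Psi^-1 Lambda
      G <- solve(diag(k) + crossprod(L, Lp))          # (I + L'P^-1 L)^-1
      beta <- G %*% t(Lp)                             # k x p
      bS <- beta %*% S                                # k x p
      Ezz <- G + bS %*% t(beta)                       # k x k
      L <- t(solve(Ezz, bS))                          # p x k
      psi <- pmax(diag(S) - rowSums(L * t(bS)), 1e-8)
      # log-likelihood up to constants: -0.5(log det Sigma + tr(Sigma^-1 S))
      # via Woodbury using the same G
      Lp <- L / psi
      G2 <- solve(diag(k) + crossprod(L, Lp))
      logdet <- sum(log(psi)) - determinant(G2, logarithm = TRUE)$modulus
      SiS <- sum(diag(S) / psi) -
        sum((crossprod(Lp, S) %*% Lp) * G2)
      ll <- -0.5 * (as.numeric(logdet) + SiS)
      path <- c(path, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1))
        return(list(L = L, psi = psi, converged = TRUE, path = path))
      ll_old <- ll
    }
    # weakly identified (e.g. near-null) models drift slowly near the
    # optimum; accept when the likelihood is effectively flat
    near_flat <- length(path) > 2 &&
      abs(diff(utils::tail(path, 2))) < 1e-4 * (abs(utils::tail(path, 1)) + 1)
    list(L = L, psi = psi, converged = near_flat, path = path)
  }
  set.seed(seed)
  res <- run(0)
  tries <- 0
  while (!res$converged && tries < n_restart) {
    tries <- tries + 1
    res <- run(0.05 * tries)
  }
  if (!res$converged)
    stop("factor analysis failed to converge after ", n_restart, " restarts")
  # rotate loadings to principal orthogonal form so factors are ordered
  sv <- svd(res$L)
  L <- sv$u %*% diag(sv$d, length(sv$d))
  ord <- order(colSums(L^2), decreasing = TRUE)
  list(loadings = L[, ord, drop = FALSE], uniquenesses = res$psi,
       converged = TRUE, loglik_path = res$path)
}
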