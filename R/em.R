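#' Construct a parameter vector for the multivariate mixed model
#'
#' Bundles the fixed-effect vectors, the joint random-effects covariance and
#' the residual variances into a single object. The random-effects covariance
#' is `q x q` with `q = sum(q_k)`, ordered dimension-major (all random effects
#' of outcome 1, then outcome 2, ...).
#'
#' @param betas List of numeric fixed-effect vectors, one per dimension.
#' @param gamma_bar Symmetric positive semi-definite `q x q` matrix.
#' @param sigma2 Numeric vector of strictly positive residual variances.
#' @return An object of class `"mvlmm_theta"`.
#' @export
mvlmm_theta <- function(betas, gamma_bar, sigma2) {
  stopifnot(is.list(betas), is.matrix(gamma_bar),
            nrow(gamma_bar) == ncol(gamma_bar),
            length(sigma2) == length(betas), all(sigma2 > 0))
  if (max(abs(gamma_bar - t(gamma_bar))) > 1e-8 * (1 + max(abs(gamma_bar))))
    stop("gamma_bar must be symmetric")
  gamma_bar <- (gamma_bar + t(gamma_bar)) / 2
  structure(list(betas = lapply(betas, as.numeric), gamma_bar = gamma_bar,
                 sigma2 = as.numeric(sigma2)),
            class = "mvlmm_theta")
}

# index ranges of each dimension's random effects within the stacked vector
q_ranges <- function(q) {
  ends <- cumsum(q)
  starts <- ends - q + 1L
  lapply(seq_along(q), function(k) seq.int(starts[k], ends[k]))
}

# stacked block-diagonal Z_i for one group (N_i x q)
group_blockdiag_z <- function(group, q) {
  m <- length(group$Z)
  Ntot <- sum(group$N)
  Z <- matrix(0, Ntot, sum(q))
  rng <- q_ranges(q)
  row0 <- 0L
  for (k in seq_len(m)) {
    if (group$N[k] > 0L)
      Z[row0 + seq_len(group$N[k]), rng[[k]]] <- group$Z[[k]]
    row0 <- row0 + group$N[k]
  }
  Z
}

#' Marginal mean and covariance of one group's stacked responses
#'
#' For a group `i`, the stacked response `y_i = (y_1i', ..., y_mi')'` is
#' Gaussian with mean `stack(X_ki beta_k)` and covariance
#' `Z_i Gamma_bar Z_i' + blockdiag(sigma_k^2 I)`, where `Z_i` is the
#' block-diagonal (by dimension) random-effect design mapped onto the shared
#' random-effect vector of the group.
#'
#' @param theta An [mvlmm_theta()].
#' @param group One element of `designs$groups` from [build_designs()].
#' @return A list with components `mean` and `cov`.
#' @export
marginal_moments_group <- function(theta, group) {
  m <- length(group$y)
  stopifnot(length(theta$betas) == m)
  q <- vapply(group$Z, ncol, integer(1))
  if (sum(q) != nrow(theta$gamma_bar))
    stop("dimension mismatch between theta and group design")
  mu <- unlist(lapply(seq_len(m), function(k)
    if (group$N[k] > 0L) drop(group$X[[k]] %*% theta$betas[[k]]) else numeric(0)))
  Z <- group_blockdiag_z(group, q)
  Sig <- diag(rep(theta$sigma2, group$N), nrow = sum(group$N))
  V <- Z %*% theta$gamma_bar %*% t(Z) + Sig
  list(mean = as.numeric(mu), cov = V)
}

#' E-step: posterior moments of the random effects given the data
#'
#' Computes, per group, the conditional mean `m_i` and covariance `V_i` of the
#' stacked random-effect vector given the observed responses, by joint
#' Gaussian conditioning with `Cov(gamma_i, y_i) = Gamma_bar Z_i'`. The
#' computation is blocked per group; the full stacked `N x N` covariance is
#' never formed.
#'
#' @param theta An [mvlmm_theta()].
#' @param designs An `"mvlmm_designs"` object.
#' @return An object of class `"mvlmm_posterior"`: lists `mean` and `cov`
#'   over groups, plus the group ids.
#' @export
e_step <- function(theta, designs) {
  G <- theta$gamma_bar
  means <- covs <- vector("list", designs$n)
  for (i in seq_len(designs$n)) {
    g <- designs$groups[[i]]
    if (sum(g$N) == 0L) {
      means[[i]] <- numeric(nrow(G))
      covs[[i]] <- G
      next
    }
    mm <- marginal_moments_group(theta, g)
    Z <- group_blockdiag_z(g, designs$q)
    Cgy <- G %*% t(Z)
    sol <- tryCatch(solve(mm$cov, cbind(t(Cgy), unlist(g$y) - mm$mean)),
                    error = function(e)
                      stop("singular marginal covariance in group '", g$id, "'"))
    means[[i]] <- drop(Cgy %*% sol[, ncol(sol)])
    Vi <- G - Cgy %*% sol[, -ncol(sol), drop = FALSE]
    covs[[i]] <- (Vi + t(Vi)) / 2
  }
  structure(list(mean = means, cov = covs,
                 ids = vapply(designs$groups, function(g) as.character(g$id),
                              character(1))),
            class = "mvlmm_posterior")
}

#' M-step update of the fixed effects
#'
#' Under homoscedastic within-dimension residuals the generalized
#' least-squares weighting cancels, giving
#' `beta_k = (sum_i X_ki' X_ki)^{-1} sum_i X_ki' (y_ki - Z_ki m_ki)` with
#' `m_ki` the dimension-`k` block of the posterior mean.
#'
#' @param posterior An `"mvlmm_posterior"` from [e_step()].
#' @param designs An `"mvlmm_designs"` object.
#' @param theta_old The parameter value at which the posterior was computed
#'   (kept in the signature to make the EM data flow explicit; the update
#'   itself only needs the posterior means).
#' @return List of updated fixed-effect vectors.
#' @export
update_beta <- function(posterior, designs, theta_old = NULL) {
  rng <- q_ranges(designs$q)
  betas <- vector("list", designs$m)
  for (k in seq_len(designs$m)) {
    XtX <- matrix(0, designs$p[k], designs$p[k])
    Xtr <- numeric(designs$p[k])
    for (i in seq_len(designs$n)) {
      g <- designs$groups[[i]]
      if (g$N[k] == 0L) next
      mk <- posterior$mean[[i]][rng[[k]]]
      XtX <- XtX + crossprod(g$X[[k]])
      Xtr <- Xtr + drop(crossprod(g$X[[k]], g$y[[k]] - g$Z[[k]] %*% mk))
    }
    betas[[k]] <- tryCatch(unname(drop(solve(XtX, Xtr))),
                           error = function(e)
                             stop("singular fixed-effect design in dimension ", k))
  }
  betas
}

#' M-step update of the random-effects covariance
#'
#' Averages the posterior second moments over groups:
#' `Gamma_bar = (1/n) sum_i (V_i + m_i m_i')`, which is symmetric positive
#' semi-definite by construction.
#'
#' @param posterior An `"mvlmm_posterior"`.
#' @param n Number of groups.
#' @return The updated `q x q` covariance matrix.
#' @export
update_gamma_bar <- function(posterior, n) {
  stopifnot(n >= 2, length(posterior$mean) == n)
  q <- length(posterior$mean[[1]])
  G <- matrix(0, q, q)
  for (i in seq_len(n))
    G <- G + posterior$cov[[i]] + tcrossprod(posterior$mean[[i]])
  G <- G / n
  (G + t(G)) / 2
}

#' M-step update of the residual variances
#'
#' `sigma_k^2 = (1/N_k) sum_i [ trace(Z_ki V_kki Z_ki') +
#' || y_ki - X_ki beta_k - Z_ki m_ki ||^2 ]`, the scalar reduction of the
#' matrix residual-covariance update under homoscedastic residuals.
#'
#' @param posterior An `"mvlmm_posterior"`.
#' @param designs An `"mvlmm_designs"` object.
#' @param betas Current (already updated) fixed-effect vectors.
#' @return Numeric vector of residual variances.
#' @export
update_sigma2 <- function(posterior, designs, betas) {
  rng <- q_ranges(designs$q)
  sig2 <- numeric(designs$m)
  for (k in seq_len(designs$m)) {
    if (designs$N[k] == 0L) stop("dimension ", k, " has no observations")
    acc <- 0
    for (i in seq_len(designs$n)) {
      g <- designs$groups[[i]]
      if (g$N[k] == 0L) next
      mk <- posterior$mean[[i]][rng[[k]]]
      Vk <- posterior$cov[[i]][rng[[k]], rng[[k]], drop = FALSE]
      r <- g$y[[k]] - drop(g$X[[k]] %*% betas[[k]]) - drop(g$Z[[k]] %*% mk)
      acc <- acc + sum(crossprod(g$Z[[k]]) * Vk) + sum(r^2)
    }
    sig2[k] <- acc / designs$N[k]
  }
  sig2
}

#' Observed-data log-likelihood
#'
#' Sum over groups of the Gaussian log-density of the stacked responses under
#' the marginal moments of [marginal_moments_group()].
#'
#' @param theta An [mvlmm_theta()].
#' @param designs An `"mvlmm_designs"` object.
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(theta, designs) {
  ll <- 0
  for (i in seq_len(designs$n)) {
    g <- designs$groups[[i]]
    if (sum(g$N) == 0L) next
    mm <- marginal_moments_group(theta, g)
    ch <- tryCatch(chol(mm$cov),
                   error = function(e)
                     stop("marginal covariance not positive definite in group '",
                          g$id, "'"))
    yc <- unlist(g$y) - mm$mean
    z <- backsolve(ch, yc, transpose = TRUE)
    ll <- ll - 0.5 * (length(yc) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  ll
}
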