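#' Fit the independence (null) model of the correlation test
#'
#' Under the null hypothesis that the cross-dimension random-effect
#' covariance block is zero, the joint likelihood factorizes into the product
#' of the per-dimension univariate mixed-model likelihoods (residuals are
#' independent across dimensions by model assumption). Each dimension is
#' therefore fitted by the univariate EM with its within-dimension
#' random-effect correlations left free, and the log-likelihoods are summed.
#'
#' @param designs An `"mvlmm_designs"` object.
#' @param options An [em_options()].
#' @return A list with `loglik` (sum over dimensions) and `fits` (the
#'   per-dimension `"mvlmm_fit"` objects).
#' @export
fit_null <- function(designs, options = em_options()) {
  fits <- lapply(seq_len(designs$m), function(k)
    fit_em(subset_designs(designs, k), options = options))
  list(loglik = sum(vapply(fits, `[[`, numeric(1), "loglik")), fits = fits)
}

#' Likelihood-ratio statistic
#'
#' `S = 2 (loglik_H1 - loglik_H0)`. Small negative values (within `1e-4`,
#' possible through finite stopping tolerances on nested fits) are clipped to
#' zero; anything more negative indicates the alternative-model optimizer
#' failed and raises an error.
#'
#' @param loglik_H1,loglik_H0 Log-likelihoods of the nested fits.
#' @return The nonnegative LR statistic.
#' @export
lr_statistic <- function(loglik_H1, loglik_H0) {
  stopifnot(is.finite(loglik_H1), is.finite(loglik_H0))
  S <- 2 * (loglik_H1 - loglik_H0)
  if (S < -1e-4)
    stop(sprintf(paste0("negative LR statistic (%.6g): the alternative-model ",
                        "fit did not reach its optimum"), S))
  max(S, 0)
}

#' Degrees of freedom of the cross-correlation test
#'
#' The null constrains every entry of the `q1 x q2` cross-dimension
#' covariance block to zero, so the nominal degrees of freedom are
#' `q1 * q2`.
#'
#' @param q1,q2 Number of random effects in each dimension.
#' @return `q1 * q2`.
#' @export
df_cross <- function(q1, q2) {
  stopifnot(q1 >= 1, q2 >= 1)
  as.integer(q1) * as.integer(q2)
}

#' Empirical Bartlett correction of the LR statistic
#'
#' Rescales the statistic so its null mean matches the reference chi-square:
#' `S_B = df * S / E[S | H0]`, with the null mean estimated empirically
#' (across simulation replicates, or by parametric bootstrap for a single
#' dataset). This mitigates the finite-sample distortion of the chi-square
#' approximation.
#'
#' @param S LR statistic.
#' @param df Degrees of freedom.
#' @param E_S_H0 Estimated null mean of `S` (must be positive).
#' @return A list with `S_bartlett` and `p_bartlett`.
#' @export
bartlett_correct <- function(S, df, E_S_H0) {
  if (!is.finite(E_S_H0) || E_S_H0 <= 0)
    stop("estimated null mean of S must be positive")
  S_B <- df * S / E_S_H0
  list(S_bartlett = S_B,
       p_bartlett = stats::pchisq(S_B, df = df, lower.tail = FALSE))
}

# simulate responses from a fitted null (independence) model on the observed
# designs: same X, Z and group sizes, new random effects and residuals
simulate_from_null <- function(null_fit, designs) {
  m <- designs$m
  sim <- designs
  for (i in seq_len(designs$n)) {
    for (k in seq_len(m)) {
      g <- designs$groups[[i]]
      if (g$N[k] == 0L) next
      th <- null_fit$fits[[k]]$theta
      gam <- drop(MASS::mvrnorm(1, mu = rep(0, ncol(g$Z[[k]])),
                                Sigma = th$gamma_bar))
      sim$groups[[i]]$y[[k]] <- drop(g$X[[k]] %*% th$betas[[1]]) +
        drop(g$Z[[k]] %*% gam) +
        stats::rnorm(g$N[k], sd = sqrt(th$sigma2[1]))
    }
  }
  sim
}

# S computed on a design set: null fit, then joint fit warm-started from the
# null parameters with the empirical cross-moment of the per-dimension
# posterior means seeding the cross-block
lr_stat_designs <- function(designs, options = em_options(),
                            null_fit = NULL) {
  if (is.null(null_fit)) null_fit <- fit_null(designs, options)
  init <- joint_init_from_null(null_fit, designs)
  h1 <- fit_em(designs, options = options, init_theta = init)
  list(S = lr_statistic(h1$loglik, null_fit$loglik),
       null = null_fit, h1 = h1)
}

joint_init_from_null <- function(null_fit, designs) {
  rng <- q_ranges(designs$q)
  G <- matrix(0, designs$qtot, designs$qtot)
  for (k in seq_len(designs$m))
    G[rng[[k]], rng[[k]]] <- null_fit$fits[[k]]$theta$gamma_bar
  gt <- do.call(rbind, lapply(seq_len(designs$n), function(i)
    unlist(lapply(null_fit$fits, function(f) f$posterior$mean[[i]]))))
  M <- crossprod(gt) / (designs$n - 1)
  for (k in seq_len(designs$m)) for (l in seq_len(designs$m)) {
    if (k != l) G[rng[[k]], rng[[l]]] <- M[rng[[k]], rng[[l]]]
  }
  mvlmm_theta(lapply(null_fit$fits, function(f) f$theta$betas[[1]]),
              repair_psd(G, 1e-6),
              vapply(null_fit$fits, function(f) f$theta$sigma2[1], numeric(1)))
}

#' Parametric-bootstrap estimate of the null mean of the LR statistic
#'
#' Simulates `B` datasets from the fitted independence model on the observed
#' design (same covariates, random-effect designs and group sizes), computes
#' the LR statistic on each, and returns the average. Used to Bartlett-correct
#' the test on a single observed dataset. Bootstrap replicates whose fits fail
#' are skipped with a warning; at least `B/2` successes are required.
#'
#' @param null_fit Result of [fit_null()].
#' @param designs The observed `"mvlmm_designs"`.
#' @param B Number of bootstrap replicates (at least 2).
#' @param seed Integer seed making the bootstrap deterministic.
#' @param options An [em_options()] for the replicate fits.
#' @return The estimated null mean, with the replicate statistics in
#'   attribute `"S"`.
#' @export
estimate_null_mean <- function(null_fit, designs, B = 200L, seed = NULL,
                               options = em_options()) {
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  S <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    S[b] <- tryCatch(lr_stat_designs(simulate_from_null(null_fit, designs),
                                     options)$S,
                     error = function(e) {
                       warning("bootstrap replicate ", b, " failed: ",
                               conditionMessage(e))
                       NA_real_
                     })
  }
  ok <- sum(!is.na(S))
  if (ok < B / 2)
    stop("fewer than half of the bootstrap replicates succeeded (", ok,
         " of ", B, ")")
  structure(mean(S, na.rm = TRUE), S = S)
}

#' Likelihood-ratio test of the cross-outcome random-effect correlation
#'
#' Tests whether the random effects of two outcome dimensions are correlated
#' (`H0`: cross-covariance block zero, i.e. the two outcomes can be modelled
#' independently) by comparing the joint bivariate fit against the product of
#' the two univariate fits. The statistic is referred to a chi-square with
#' `q1 * q2` degrees of freedom; optionally an empirical Bartlett correction
#' is applied, with the null mean estimated by parametric bootstrap.
#'
#' @param data A long-format data.frame, or an `"mvlmm_designs"` object.
#' @param spec An [mvlmm_spec()] with exactly two outcomes (ignored when
#'   `data` is already a design set).
#' @param options An [em_options()].
#' @param bartlett `"none"` (default) or `"bootstrap"`.
#' @param B Bootstrap replicates for the Bartlett correction.
#' @param seed Seed for the bootstrap.
#' @return An object of class `"mvlmm_lrt"`: the statistic `S`, `df`,
#'   asymptotic p-value, the two fits' log-likelihoods, and (when requested)
#'   `E_S_H0`, `S_bartlett`, `p_bartlett`, `B`.
#' @examples
#' d <- simulate_bivariate(sim_config(n = 50, N = 250, seed = 7))
#' tst <- bivariate_correlation_test(d, bivariate_sim_spec())
#' tst$p_asymptotic
#' @export
bivariate_correlation_test <- function(data, spec = NULL,
                                       options = em_options(),
                                       bartlett = c("none", "bootstrap"),
                                       B = 200L, seed = NULL) {
  bartlett <- match.arg(bartlett)
  designs <- if (inherits(data, "mvlmm_designs")) data else {
    stopifnot(inherits(spec, "mvlmm_spec"))
    if (length(spec$outcomes) != 2L)
      stop("the bivariate correlation test needs exactly two outcomes")
    build_designs(data, spec)
  }
  if (designs$m != 2L)
    stop("the bivariate correlation test needs exactly two outcomes")
  res <- lr_stat_designs(designs, options)
  df <- df_cross(designs$q[1], designs$q[2])
  out <- list(S = res$S, df = df,
              p_asymptotic = stats::pchisq(res$S, df, lower.tail = FALSE),
              loglik_H0 = res$null$loglik, loglik_H1 = res$h1$loglik,
              fit_H1 = res$h1, fits_H0 = res$null$fits,
              E_S_H0 = NA_real_, S_bartlett = NA_real_,
              p_bartlett = NA_real_, B = 0L,
              outcomes = designs$outcome_names)
  if (bartlett == "bootstrap") {
    E_S <- estimate_null_mean(res$null, designs, B = B, seed = seed,
                              options = options)
    bc <- bartlett_correct(res$S, df, as.numeric(E_S))
    out$E_S_H0 <- as.numeric(E_S)
    out$S_bartlett <- bc$S_bartlett
    out$p_bartlett <- bc$p_bartlett
    out$B <- as.integer(B)
  }
  structure(out, class = "mvlmm_lrt")
}

#' @export
print.mvlmm_lrt <- function(x, ...) {
  cat("Likelihood-ratio test of the cross-outcome random-effect correlation\n")
  cat(sprintf("  outcomes: %s\n", paste(x$outcomes, collapse = " ~ ")))
  cat(sprintf("  S = %.4f on %d df, asymptotic p = %.4g\n",
              x$S, x$df, x$p_asymptotic))
  cat(sprintf("  loglik H1 = %.4f, loglik H0 = %.4f\n",
              x$loglik_H1, x$loglik_H0))
  if (!is.na(x$S_bartlett))
    cat(sprintf("  Bartlett-corrected: S = %.4f, p = %.4g (E[S|H0] = %.3f, B = %d)\n",
                x$S_bartlett, x$p_bartlett, x$E_S_H0, x$B))
  invisible(x)
}
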