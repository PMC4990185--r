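#' Options controlling the EM fit
#'
#' @param tol Relative-change stopping tolerance on all free parameters
#'   (fixed effects, lower triangle of the random-effects covariance,
#'   residual variances). Default `1e-5`.
#' @param max_iter Maximum number of EM iterations; non-convergence is
#'   reported via the `converged` flag, not as an error. EM for variance
#'   components is slow near the boundary, hence the generous default.
#' @param init Initialization strategy: `"univariate"` fits each dimension
#'   separately by the univariate special case of the same EM and seeds the
#'   joint covariance from the empirical second moment of the stacked
#'   per-dimension posterior means; `"ols"` starts from pooled least squares
#'   with a scaled-identity covariance.
#' @param denom_floor Small constant added to the denominator of the relative
#'   stopping rule so parameters with a true value of zero cannot stall it.
#' @param engine `"cpp"` (fast compiled loop, the default) or `"r"` (pure-R
#'   loop built from the exported step functions; used on small problems and
#'   in cross-checks).
#' @return A list of class `"em_options"`.
#' @export
em_options <- function(tol = 1e-5, max_iter = 5000L,
                       init = c("univariate", "ols"),
                       denom_floor = 1e-8, engine = c("cpp", "r")) {
  stopifnot(tol > 0, max_iter >= 1, denom_floor > 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 init = match.arg(init), denom_floor = denom_floor,
                 engine = match.arg(engine)),
            class = "em_options")
}

# eigenvalue floor keeping a covariance matrix usable as an EM iterate
repair_psd <- function(G, rel_floor = 1e-8) {
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE)
  floor_val <- max(rel_floor * max(ev$values, 0), 1e-12)
  if (min(ev$values) >= floor_val) return(G)
  vals <- pmax(ev$values, floor_val)
  ev$vectors %*% (vals * t(ev$vectors))
}

# pooled OLS start: beta by least squares per dimension, sigma2 the residual
# mean square, gamma_bar a scaled identity per dimension
init_ols <- function(designs) {
  m <- designs$m
  betas <- vector("list", m)
  sigma2 <- numeric(m)
  for (k in seq_len(m)) {
    X <- do.call(rbind, lapply(designs$groups, function(g) g$X[[k]]))
    y <- unlist(lapply(designs$groups, function(g) g$y[[k]]))
    fit <- stats::lm.fit(X, y)
    betas[[k]] <- unname(stats::coef(fit))
    sigma2[k] <- max(mean(fit$residuals^2), 1e-8)
  }
  G <- diag(rep(sigma2, designs$q), nrow = designs$qtot)
  mvlmm_theta(betas, G, sigma2)
}

#' Initialize the EM from separate univariate fits
#'
#' Each dimension is fitted on its own by the univariate special case of the
#' same EM (itself started from pooled least squares with a scaled-identity
#' random-effects covariance). The per-dimension fixed effects and residual
#' variances seed the joint model directly; the joint random-effects
#' covariance is seeded by the empirical second-moment matrix
#' `(1/(n-1)) sum_i gtilde_i gtilde_i'` of the stacked per-dimension
#' posterior means, so the cross-dimension blocks start at their empirical
#' values. If a univariate fit fails, the pooled least-squares start is used
#' instead (with a warning). The moment matrix is floored spectrally when it
#' is rank deficient (it always is when `n - 1 < q`).
#'
#' @param designs An `"mvlmm_designs"` object.
#' @param strategy `"univariate"` or `"ols"`.
#' @param options An [em_options()] used for the inner univariate fits.
#' @return An [mvlmm_theta()] starting value.
#' @export
initialize_theta <- function(designs, strategy = c("univariate", "ols"),
                             options = em_options()) {
  strategy <- match.arg(strategy)
  # univariate models use the OLS start directly: fitting a univariate model
  # to initialize itself would not terminate
  if (strategy == "ols" || designs$m == 1L) return(init_ols(designs))
  fits <- vector("list", designs$m)
  ok <- TRUE
  for (k in seq_len(designs$m)) {
    fits[[k]] <- tryCatch(
      fit_em(subset_designs(designs, k),
             options = em_options(tol = options$tol,
                                  max_iter = options$max_iter,
                                  init = "ols",
                                  denom_floor = options$denom_floor,
                                  engine = options$engine)),
      error = function(e) {
        warning("univariate initialization failed in dimension ", k, " (",
                conditionMessage(e), "); falling back to least-squares start")
        NULL
      })
    if (is.null(fits[[k]])) { ok <- FALSE; break }
  }
  if (!ok) return(init_ols(designs))
  betas <- lapply(fits, function(f) f$theta$betas[[1]])
  sigma2 <- vapply(fits, function(f) f$theta$sigma2[1], numeric(1))
  gt <- do.call(rbind, lapply(seq_len(designs$n), function(i)
    unlist(lapply(fits, function(f) f$posterior$mean[[i]]))))
  G <- crossprod(gt) / (designs$n - 1)
  mvlmm_theta(betas, repair_psd(G, 1e-6), sigma2)
}

# free-parameter vector entering the stopping rule: all fixed effects, the
# lower triangle of gamma_bar (cross-blocks included only when they exist),
# and the residual variances
theta_vec <- function(theta) {
  G <- theta$gamma_bar
  c(unlist(theta$betas), G[lower.tri(G, diag = TRUE)], theta$sigma2)
}

# per-group sufficient statistics consumed by the iteration engines
precompute_stats <- function(designs) {
  m <- designs$m
  per_dim <- vector("list", m)
  for (k in seq_len(m)) {
    p <- designs$p[k]; q <- designs$q[k]; n <- designs$n
    XtX <- array(0, c(p, p, n)); ZtX <- array(0, c(q, p, n))
    ZtZ <- array(0, c(q, q, n)); Xty <- matrix(0, p, n); Zty <- matrix(0, q, n)
    yty <- numeric(n); Ni <- integer(n)
    for (i in seq_len(n)) {
      g <- designs$groups[[i]]
      Ni[i] <- g$N[k]
      if (g$N[k] == 0L) next
      XtX[, , i] <- crossprod(g$X[[k]])
      ZtX[, , i] <- crossprod(g$Z[[k]], g$X[[k]])
      ZtZ[, , i] <- crossprod(g$Z[[k]])
      Xty[, i] <- crossprod(g$X[[k]], g$y[[k]])
      Zty[, i] <- crossprod(g$Z[[k]], g$y[[k]])
      yty[i] <- sum(g$y[[k]]^2)
    }
    per_dim[[k]] <- list(XtX = XtX, ZtX = ZtX, ZtZ = ZtZ, Xty = Xty,
                         Zty = Zty, yty = yty, Ni = Ni)
  }
  list(per_dim = per_dim, m = m, n = designs$n, p = designs$p, q = designs$q,
       N = designs$N)
}

#' Fit the multivariate linear mixed model by EM
#'
#' Iterates the E-step (posterior moments of the stacked random effects per
#' group) and the closed-form M-step updates for the fixed effects, the joint
#' random-effects covariance and the residual variances until the maximum
#' relative parameter change drops below `tol` or `max_iter` is reached.
#' The observed-data log-likelihood is recorded at every iteration and is
#' nondecreasing (up to numerical slack); a decrease beyond `1e-8` relative
#' triggers a diagnostic warning naming the iteration.
#'
#' @param designs An `"mvlmm_designs"` object from [build_designs()], with
#'   any number of dimensions `m >= 1` (the univariate case is used
#'   internally for initialization and the null model of the correlation
#'   test).
#' @param options An [em_options()].
#' @param init_theta Optional [mvlmm_theta()] overriding the initialization
#'   strategy.
#' @return An object of class `"mvlmm_fit"` with elements `theta`, `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, `posterior` and bookkeeping
#'   (`designs` dimensions, parameter names).
#' @examples
#' cfg <- sim_config(n = 40, N = 200, seed = 1)
#' d <- simulate_bivariate(cfg)
#' ds <- build_designs(d, bivariate_sim_spec())
#' fit <- fit_em(ds)
#' fit$theta$sigma2
#' @export
fit_em <- function(designs, options = em_options(), init_theta = NULL) {
  stopifnot(inherits(designs, "mvlmm_designs"))
  theta0 <- if (is.null(init_theta))
    initialize_theta(designs, options$init, options) else init_theta
  stats_pre <- precompute_stats(designs)
  res <- if (options$engine == "cpp")
    run_em_cpp(stats_pre, theta0, options) else run_em_r(designs, theta0, options)
  if (!is.na(res$decrease_iter) && res$decrease_iter > 0)
    warning(sprintf(paste0("observed-data log-likelihood decreased beyond ",
                           "numerical slack at iteration %d"),
                    res$decrease_iter))
  theta <- mvlmm_theta(res$betas, res$gamma_bar, pmax(res$sigma2, 1e-300))
  post <- structure(list(mean = res$post_mean, cov = res$post_cov,
                         ids = vapply(designs$groups,
                                      function(g) as.character(g$id),
                                      character(1))),
                    class = "mvlmm_posterior")
  structure(list(theta = theta, loglik = res$loglik,
                 loglik_trace = res$trace, iterations = res$iterations,
                 converged = res$converged, posterior = post,
                 m = designs$m, n = designs$n, N = designs$N,
                 p = designs$p, q = designs$q,
                 outcome_names = designs$outcome_names,
                 xnames = designs$xnames, znames = designs$znames,
                 options = options),
            class = "mvlmm_fit")
}

run_em_cpp <- function(stats_pre, theta0, options) {
  out <- em_loop_cpp(stats_pre$per_dim, as.integer(stats_pre$p),
                     as.integer(stats_pre$q), as.numeric(stats_pre$N),
                     theta0$betas, theta0$gamma_bar, theta0$sigma2,
                     options$tol, options$max_iter, options$denom_floor)
  out$post_mean <- lapply(seq_len(ncol(out$post_mean_mat)),
                          function(i) out$post_mean_mat[, i])
  q <- nrow(out$gamma_bar)
  out$post_cov <- lapply(seq_len(stats_pre$n), function(i)
    matrix(out$post_cov_mat[, i], q, q))
  out
}

run_em_r <- function(designs, theta0, options) {
  theta <- theta0
  trace <- numeric(0)
  vec_old <- theta_vec(theta)
  converged <- FALSE
  decrease_iter <- NA_integer_
  iter <- 0L
  post <- NULL
  for (iter in seq_len(options$max_iter)) {
    trace <- c(trace, log_likelihood(theta, designs))
    if (length(trace) > 1L) {
      drop_rel <- (trace[length(trace) - 1L] - trace[length(trace)]) /
        (abs(trace[length(trace) - 1L]) + 1)
      if (drop_rel > 1e-8 && is.na(decrease_iter)) decrease_iter <- iter - 1L
    }
    post <- e_step(theta, designs)
    betas <- update_beta(post, designs, theta)
    sigma2 <- pmax(update_sigma2(post, designs, betas), 1e-12)
    G <- update_gamma_bar(post, designs$n)
    theta <- mvlmm_theta(betas, G, sigma2)
    vec_new <- theta_vec(theta)
    rel <- max(abs(vec_new - vec_old) / (abs(vec_new) + options$denom_floor))
    vec_old <- vec_new
    if (rel < options$tol) { converged <- TRUE; break }
  }
  ll <- log_likelihood(theta, designs)
  trace <- c(trace, ll)
  post <- e_step(theta, designs)
  list(betas = theta$betas, gamma_bar = theta$gamma_bar,
       sigma2 = theta$sigma2, loglik = ll, trace = trace,
       iterations = iter, converged = converged,
       post_mean = post$mean, post_cov = post$cov,
       decrease_iter = decrease_iter)
}

#' @export
print.mvlmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Multivariate linear mixed model fit by EM (%d dimension%s)\n",
              x$m, if (x$m > 1) "s" else ""))
  cat(sprintf("  groups: %d   observations per dimension: %s\n", x$n,
              paste(x$N, collapse = ", ")))
  cat(sprintf("  log-likelihood: %.*f   iterations: %d   converged: %s\n",
              digits, x$loglik, x$iterations, x$converged))
  for (k in seq_len(x$m)) {
    cat("\nFixed effects (", x$outcome_names[k], "):\n", sep = "")
    b <- x$theta$betas[[k]]
    names(b) <- x$xnames[[k]]
    print(round(b, digits))
    cat("Residual SD: ", round(sqrt(x$theta$sigma2[k]), digits), "\n", sep = "")
  }
  cat("\nRandom-effects covariance:\n")
  print(round(x$theta$gamma_bar, digits))
  cat("\nRandom-effects correlation:\n")
  print(round(cov_to_corr(x$theta$gamma_bar), digits))
  invisible(x)
}

#' Serialize a fit to structured JSON
#'
#' Writes the parameter estimates, correlation matrix, log-likelihood and
#' convergence diagnostics (including options and the log-likelihood trace so
#' the EM ascent is auditable) to a JSON file.
#'
#' @param fit An `"mvlmm_fit"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    outcomes = fit$outcome_names,
    betas = stats::setNames(lapply(seq_len(fit$m), function(k)
      stats::setNames(as.list(fit$theta$betas[[k]]), fit$xnames[[k]])),
      fit$outcome_names),
    gamma_bar = fit$theta$gamma_bar,
    correlation = cov_to_corr(fit$theta$gamma_bar),
    sigma = sqrt(fit$theta$sigma2),
    loglik = fit$loglik,
    loglik_trace = fit$loglik_trace,
    iterations = fit$iterations,
    converged = fit$converged,
    options = unclass(fit$options))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export per-group posterior random-effect means as a data frame
#'
#' @param fit An `"mvlmm_fit"`.
#' @return A data.frame with one row per group: the group id followed by the
#'   posterior mean of each random effect (columns named by dimension and
#'   random covariate).
#' @export
ranef_table <- function(fit) {
  rng <- q_ranges(fit$q)
  cols <- unlist(lapply(seq_len(fit$m), function(k)
    paste(fit$outcome_names[k], fit$znames[[k]], sep = ".")))
  mat <- do.call(rbind, fit$posterior$mean)
  colnames(mat) <- cols
  data.frame(group = fit$posterior$ids, mat, check.names = FALSE,
             row.names = NULL)
}
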