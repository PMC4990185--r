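#' Configuration of the bivariate longitudinal simulator
#'
#' Describes the synthetic study design used throughout the replication
#' harnesses: `n` subjects contributing `N` observation occasions in total
#' (split as evenly as possible, every subject at least 2), two continuous
#' responses ("weight" and "height") driven by an intercept, a subject-level
#' sex indicator, a per-occasion nutrition score and age, with a random
#' intercept and a random nutrition-score slope per subject and dimension.
#' The default parameter values are the ones used in the replication
#' studies: `beta1 = (50.67, -4.80, 14.00, 2.70)`,
#' `beta2 = (13.20, -2.80, 27.00, 1.70)`, residual SDs 5.80 and 7.60, and
#' the structured random-effects covariance of [gamma_params()].
#'
#' @param n Number of subjects.
#' @param N Total number of observation occasions (needs `N/n >= 2`).
#' @param beta1,beta2 Length-4 fixed-effect vectors (intercept, sex,
#'   Nscore, age) for the two responses.
#' @param gamma A [gamma_params()] object.
#' @param sigma1,sigma2 Residual standard deviations (positive).
#' @param seed Optional integer seed consumed by [simulate_bivariate()].
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n = 300L, N = 5000L,
                       beta1 = c(50.67, -4.80, 14.00, 2.70),
                       beta2 = c(13.20, -2.80, 27.00, 1.70),
                       gamma = gamma_params(),
                       sigma1 = 5.80, sigma2 = 7.60, seed = NULL) {
  stopifnot(length(beta1) == 4L, length(beta2) == 4L,
            sigma1 > 0, sigma2 > 0, inherits(gamma, "gamma_params"))
  if (N / n < 2) stop("N/n must be at least 2 (two observations per subject)")
  structure(list(n = as.integer(n), N = as.integer(N), beta1 = beta1,
                 beta2 = beta2, gamma = gamma, sigma1 = sigma1,
                 sigma2 = sigma2, seed = seed),
            class = "sim_config")
}

#' Model specification matching the simulated bivariate design
#'
#' @return An [mvlmm_spec()] for the columns produced by
#'   [simulate_bivariate()]: both responses on fixed covariates
#'   (sex, Nscore, age) with random (intercept, Nscore) per subject.
#' @export
bivariate_sim_spec <- function() {
  mvlmm_spec(list(
    outcome_spec("weight", fixed = c("sex", "Nscore", "age"), random = "Nscore"),
    outcome_spec("height", fixed = c("sex", "Nscore", "age"), random = "Nscore")),
    group = "subject")
}

#' Simulate a bivariate longitudinal dataset
#'
#' Draws covariates per occasion (`Nscore ~ U(20, 50)`, `age ~ U(18, 37)`)
#' and per subject (`sex ~ Bernoulli(0.5)`, constant within subject), then a
#' joint random-effect vector per subject from the structured 4x4 covariance
#' of [build_gamma_bar()] and independent Gaussian residuals per dimension.
#' Both responses are observed at every occasion (the design is balanced by
#' construction; unbalancedness enters the model layer through missing
#' values, not the generator). The realized random effects are attached as
#' attribute `"gamma"`.
#'
#' @param config A [sim_config()]. Its `seed` element, when non-NULL, seeds
#'   the generator, making the dataset reproducible.
#' @return A long-format data.frame with columns `subject`, `sex`, `Nscore`,
#'   `age`, `weight`, `height`.
#' @export
simulate_bivariate <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n; N <- config$N
  base <- N %/% n; rem <- N %% n
  sizes <- rep(base, n) + (seq_len(n) <= rem)
  G <- build_gamma_bar(config$gamma)
  gam <- matrix(stats::rnorm(n * 4L), n, 4L) %*% chol(G)
  sex_subj <- stats::rbinom(n, 1L, 0.5)
  subject <- rep(seq_len(n), sizes)
  Nscore <- stats::runif(N, 20, 50)
  age <- stats::runif(N, 18, 37)
  sex <- sex_subj[subject]
  Xb1 <- config$beta1[1] + config$beta1[2] * sex +
    config$beta1[3] * Nscore + config$beta1[4] * age
  Xb2 <- config$beta2[1] + config$beta2[2] * sex +
    config$beta2[3] * Nscore + config$beta2[4] * age
  weight <- Xb1 + gam[subject, 1L] + gam[subject, 2L] * Nscore +
    stats::rnorm(N, sd = config$sigma1)
  height <- Xb2 + gam[subject, 3L] + gam[subject, 4L] * Nscore +
    stats::rnorm(N, sd = config$sigma2)
  out <- data.frame(subject = subject, sex = sex, Nscore = Nscore, age = age,
                    weight = weight, height = height)
  attr(out, "gamma") <- gam
  attr(out, "config") <- config
  out
}

# truth vector in reporting order: beta1, beta2, sigma1, sigma2 (as SDs)
sim_truth <- function(config) {
  c(stats::setNames(config$beta1,
                    paste0("beta1.", c("(Intercept)", "sex", "Nscore", "age"))),
    stats::setNames(config$beta2,
                    paste0("beta2.", c("(Intercept)", "sex", "Nscore", "age"))),
    sigma1 = config$sigma1, sigma2 = config$sigma2)
}

# one simulate -> fit cycle; returns the flat estimate vector and gamma matrix
fit_one_replicate <- function(config, seed, options) {
  cfg <- config; cfg$seed <- seed
  d <- simulate_bivariate(cfg)
  fit <- fit_em(build_designs(d, bivariate_sim_spec()), options = options)
  list(est = c(fit$theta$betas[[1]], fit$theta$betas[[2]],
               sqrt(fit$theta$sigma2)),
       gamma = fit$theta$gamma_bar,
       converged = fit$converged)
}

derive_seeds <- function(seed, R) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, R)
}

#' Replicated bias study of the EM estimators
#'
#' Runs `R` independent simulate-and-fit cycles under `config` and reports,
#' per parameter, the empirical mean, empirical SD and absolute bias
#' (|empirical mean - truth|), plus the entrywise mean, SD, bias and
#' coefficient of variation (SD divided by |true value|) of the
#' random-effects covariance estimate. Each replicate uses a seed derived
#' from `seed`, so the study is reproducible; replicate seeds can also be
#' supplied directly.
#'
#' @param config A [sim_config()].
#' @param R Number of replications.
#' @param seed Master seed from which per-replicate seeds are derived.
#' @param options An [em_options()] for the fits.
#' @param seeds Optional explicit vector of `R` replicate seeds (overrides
#'   `seed`).
#' @return An object of class `"mvlmm_bias_study"`.
#' @export
bias_study <- function(config, R = 200L, seed = NULL,
                       options = em_options(), seeds = NULL) {
  stopifnot(R >= 2)
  if (is.null(seeds)) seeds <- derive_seeds(seed, R)
  stopifnot(length(seeds) == R)
  truth <- sim_truth(config)
  G_true <- build_gamma_bar(config$gamma)
  est <- matrix(NA_real_, R, length(truth),
                dimnames = list(NULL, names(truth)))
  gammas <- array(NA_real_, c(4L, 4L, R))
  failed <- integer(0)
  for (r in seq_len(R)) {
    res <- tryCatch(fit_one_replicate(config, seeds[r], options),
                    error = function(e) {
                      warning("replicate ", r, " failed: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) { failed <- c(failed, r); next }
    est[r, ] <- res$est
    gammas[, , r] <- res$gamma
  }
  keep <- setdiff(seq_len(R), failed)
  est <- est[keep, , drop = FALSE]
  gammas <- gammas[, , keep, drop = FALSE]
  gm <- apply(gammas, c(1, 2), mean)
  gs <- apply(gammas, c(1, 2), stats::sd)
  structure(list(
    truth = truth, mean = colMeans(est), sd = apply(est, 2, stats::sd),
    bias = abs(colMeans(est) - truth),
    gamma_true = G_true, gamma_mean = gm, gamma_sd = gs,
    gamma_bias = abs(gm - G_true), gamma_cv = gs / abs(G_true),
    estimates = est, R = length(keep), failed = failed,
    config = config, seeds = seeds),
    class = "mvlmm_bias_study")
}

#' @export
print.mvlmm_bias_study <- function(x, digits = 3, ...) {
  cat(sprintf("Replicated bias study (%d effective replications, n = %d, N = %d)\n",
              x$R, x$config$n, x$config$N))
  tab <- data.frame(truth = x$truth, emp.mean = x$mean, emp.sd = x$sd,
                    bias = x$bias)
  print(round(tab, digits))
  cat("\nRandom-effects covariance: entrywise bias\n")
  print(round(x$gamma_bias, digits))
  cat("\nRandom-effects covariance: entrywise CV (SD / |truth|)\n")
  print(round(x$gamma_cv, digits))
  invisible(x)
}

#' Mean-squared-error study over a grid of study sizes
#'
#' For each `(n, N)` cell, replicates simulate-and-fit cycles and pools the
#' squared estimation errors within each parameter group (fixed effects per
#' dimension, residual SDs, random-effects covariance entries), reporting the
#' group MSE with 2.5/97.5 percentile bounds of the pooled squared errors.
#'
#' @param config Base [sim_config()] (its `n`, `N` are overridden per cell).
#' @param n_values,N_values Grid of subject counts and total observation
#'   counts; cells with `N/n < 2` are skipped.
#' @param R Replications per cell.
#' @param seed Master seed.
#' @param options An [em_options()].
#' @return A data.frame with one row per (parameter group, cell).
#' @export
mse_study <- function(config = sim_config(), n_values = c(50L, 100L),
                      N_values = c(600L, 1000L), R = 50L, seed = NULL,
                      options = em_options()) {
  if (!is.null(seed)) set.seed(seed)
  truth <- sim_truth(config)
  G_true <- build_gamma_bar(config$gamma)
  groups <- list(beta1 = 1:4, beta2 = 5:8, sigma1 = 9L, sigma2 = 10L)
  rows <- list()
  for (n in n_values) for (N in N_values) {
    if (N / n < 2) next
    cfg <- config; cfg$n <- as.integer(n); cfg$N <- as.integer(N)
    seeds <- sample.int(.Machine$integer.max, R)
    sq <- matrix(NA_real_, R, length(truth))
    sqg <- matrix(NA_real_, R, 16L)
    for (r in seq_len(R)) {
      res <- tryCatch(fit_one_replicate(cfg, seeds[r], options),
                      error = function(e) NULL)
      if (is.null(res)) next
      sq[r, ] <- (res$est - truth)^2
      sqg[r, ] <- (as.numeric(res$gamma) - as.numeric(G_true))^2
    }
    ok <- stats::complete.cases(sq)
    for (gname in names(groups)) {
      pool <- as.numeric(sq[ok, groups[[gname]]])
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = gname, n = n, N = N, mse = mean(pool),
        lo = stats::quantile(pool, 0.025), hi = stats::quantile(pool, 0.975),
        R = sum(ok))
    }
    pool <- as.numeric(sqg[ok, ])
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "gamma_bar", n = n, N = N, mse = mean(pool),
      lo = stats::quantile(pool, 0.025), hi = stats::quantile(pool, 0.975),
      R = sum(ok))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# S statistics over `reps` datasets simulated at a given cross-correlation
# scale rho (rho = 0 is the null arm)
simulate_lr_stats <- function(n, N, rho, reps, seeds, config, options) {
  S <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$n <- as.integer(n); cfg$N <- as.integer(N); cfg$seed <- seeds[r]
    cfg$gamma$rho <- rho
    d <- simulate_bivariate(cfg)
    S[r] <- tryCatch(
      lr_stat_designs(build_designs(d, bivariate_sim_spec()), options)$S,
      error = function(e) {
        warning("replicate ", r, " (rho = ", rho, ") failed: ",
                conditionMessage(e))
        NA_real_
      })
  }
  S[!is.na(S)]
}

#' Null-distribution study of the LR statistic
#'
#' For each total size `N` (with `n = N/5` subjects), simulates `reps`
#' datasets under the independence null (cross-covariance block zero),
#' computes the LR statistic on each, and reports the Kolmogorov-Smirnov
#' p-value against chi-square(4) and the type-I error rates at the 5% and
#' 10% chi-square critical values, both for the raw statistic and for the
#' Bartlett-corrected statistic (correction factor `4 / mean(S)` from the
#' same replicates).
#'
#' @param N_values Total observation counts (each needs `N/5 >= 2` subjects).
#' @param reps Replications per size.
#' @param seed Master seed.
#' @param config Base [sim_config()] supplying the non-null parameters.
#' @param options An [em_options()].
#' @return A data.frame (one row per `N`) with the LR statistics attached as
#'   attribute `"S"`.
#' @export
null_distribution_study <- function(N_values = c(500L, 2000L), reps = 200L,
                                    seed = NULL, config = sim_config(),
                                    options = em_options()) {
  if (!is.null(seed)) set.seed(seed)
  crit5 <- stats::qchisq(0.95, 4); crit10 <- stats::qchisq(0.90, 4)
  rows <- list(); Slist <- list()
  for (N in N_values) {
    n <- max(as.integer(N / 5), 2L)
    seeds <- sample.int(.Machine$integer.max, reps)
    S <- simulate_lr_stats(n, N, rho = 0, reps, seeds, config, options)
    SB <- 4 * S / mean(S)
    ks_raw <- stats::ks.test(S, stats::pchisq, df = 4)$p.value
    ks_bart <- stats::ks.test(SB, stats::pchisq, df = 4)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      N = N, n = n, reps = length(S), mean_S = mean(S),
      ks_p_raw = ks_raw, ks_p_bartlett = ks_bart,
      typeI_5_raw = mean(S > crit5), typeI_10_raw = mean(S > crit10),
      typeI_5_bartlett = mean(SB > crit5),
      typeI_10_bartlett = mean(SB > crit10))
    Slist[[as.character(N)]] <- S
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "S") <- Slist
  out
}

#' Rank (Mann-Whitney) AUC of the LR statistic
#'
#' Estimates `P(S_H1 > S_H0)` (ties counted half) from the two vectors of LR
#' statistics: the power summary of the correlation test viewed as a
#' classifier separating correlated-truth datasets from null datasets.
#'
#' @param S0 LR statistics from null simulations.
#' @param S1 LR statistics from alternative simulations.
#' @return The AUC in `[0, 1]`.
#' @export
lr_auc <- function(S0, S1) {
  stopifnot(length(S0) >= 1, length(S1) >= 1)
  if (length(unique(c(S0, S1))) == 1L)
    stop("all statistics identical: AUC undefined")
  r <- rank(c(S1, S0))
  n1 <- length(S1); n0 <- length(S0)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified bootstrap percentile interval for the AUC
lr_auc_ci <- function(S0, S1, boot = 2000L, level = 0.95) {
  vals <- vapply(seq_len(boot), function(b)
    lr_auc(sample(S0, replace = TRUE), sample(S1, replace = TRUE)),
    numeric(1))
  stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}

#' Power study of the correlation test via ROC/AUC
#'
#' For each cross-correlation scale `rho`, simulates `reps` datasets under
#' the alternative and compares their LR statistics against `reps` null
#' (`rho = 0`) statistics simulated once per call at the same `(n, N)`.
#' The AUC is the rank estimator of `P(S_H1 > S_H0)` with a stratified
#' bootstrap percentile confidence interval.
#'
#' @param rho_values Cross-correlation scales in (0, 1].
#' @param n,N Study size.
#' @param reps Replications per arm.
#' @param seed Master seed.
#' @param config Base [sim_config()] supplying the remaining parameters.
#' @param options An [em_options()].
#' @param boot Bootstrap resamples for the AUC interval.
#' @return A data.frame with one row per `rho` (`auc`, `auc_lo`, `auc_hi`,
#'   arm sizes); the statistic vectors are attached as attribute `"S"`.
#' @export
power_study <- function(rho_values = c(0.2, 0.3), n = 300L, N = 3000L,
                        reps = 200L, seed = NULL, config = sim_config(),
                        options = em_options(), boot = 2000L) {
  if (!is.null(seed)) set.seed(seed)
  seeds0 <- sample.int(.Machine$integer.max, reps)
  S0 <- simulate_lr_stats(n, N, rho = 0, reps, seeds0, config, options)
  rows <- list(); Slist <- list(S0 = S0)
  for (rho in rho_values) {
    seeds1 <- sample.int(.Machine$integer.max, reps)
    S1 <- simulate_lr_stats(n, N, rho, reps, seeds1, config, options)
    auc <- lr_auc(S0, S1)
    ci <- lr_auc_ci(S0, S1, boot = boot)
    rows[[length(rows) + 1L]] <- data.frame(
      rho = rho, n = n, N = N, reps0 = length(S0), reps1 = length(S1),
      auc = auc, auc_lo = ci[1], auc_hi = ci[2])
    Slist[[paste0("S1_rho", rho)]] <- S1
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "S") <- Slist
  out
}
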