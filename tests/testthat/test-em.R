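test_that("marginal moments reduce to known closed forms", {
  r <- random_bivariate_dataset(n_groups = 2, obs = 3, seed = 3)
  ds <- r$designs
  # no random-effect variability: covariance is the diagonal residual block
  th0 <- mvlmm_theta(lapply(ds$p, function(p) rep(0, p)),
                     matrix(0, ds$qtot, ds$qtot), c(1.5, 0.7))
  mm <- marginal_moments_group(th0, ds$groups[[1]])
  expect_equal(mm$cov, diag(rep(c(1.5, 0.7), ds$groups[[1]]$N)))

  # single dimension, random intercept only: compound symmetry g*J + s*I
  d <- data.frame(g = rep(1:2, each = 4), y1 = rnorm(8), y2 = rnorm(8))
  sp <- mvlmm_spec(list(outcome_spec("y1"), outcome_spec("y2")), group = "g")
  ds1 <- subset_designs(build_designs(d, sp), 1L)
  th <- mvlmm_theta(list(0), matrix(2.5, 1, 1), 0.8)
  mm <- marginal_moments_group(th, ds1$groups[[1]])
  expect_equal(mm$cov, 2.5 * matrix(1, 4, 4) + 0.8 * diag(4))
})

test_that("E-step handles the degenerate no-information cases", {
  r <- random_bivariate_dataset(n_groups = 2, obs = 3, seed = 4)
  ds <- r$designs
  th0 <- mvlmm_theta(lapply(ds$p, function(p) rep(0, p)),
                     matrix(0, ds$qtot, ds$qtot), c(1, 1))
  post <- e_step(th0, ds)
  for (i in 1:2) {
    expect_equal(post$mean[[i]], rep(0, ds$qtot))
    expect_equal(post$cov[[i]], matrix(0, ds$qtot, ds$qtot))
  }

  # zero random-effect design: data carry no information about gamma
  ds0 <- ds
  for (i in 1:2) for (k in 1:2) ds0$groups[[i]]$Z[[k]][] <- 0
  th <- random_theta(ds, seed = 5)
  post0 <- e_step(th, ds0)
  for (i in 1:2) {
    expect_equal(post0$mean[[i]], rep(0, ds$qtot))
    expect_equal(post0$cov[[i]], th$gamma_bar, tolerance = 1e-12)
  }
})

test_that("E-step agrees with brute-force joint-Gaussian conditioning", {
  for (seed in 1:3) {
    r <- random_bivariate_dataset(n_groups = 2, obs = 3, seed = seed,
                                  miss = if (seed == 3) 1 else 0)
    th <- random_theta(r$designs, seed = seed + 10)
    post <- e_step(th, r$designs)
    for (i in seq_len(r$designs$n)) {
      orc <- oracle_posterior_group(th, r$designs$groups[[i]])
      expect_equal(post$mean[[i]], orc$mean, tolerance = 1e-10)
      expect_equal(post$cov[[i]], orc$cov, tolerance = 1e-10)
      # posterior never exceeds the prior in the Loewner order
      expect_gt(min(eigen(th$gamma_bar - post$cov[[i]],
                          symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    }
  }
})

test_that("fixed-effect update collapses to OLS without random effects", {
  r <- random_bivariate_dataset(n_groups = 3, obs = 4, seed = 6)
  ds <- r$designs
  th0 <- mvlmm_theta(lapply(ds$p, function(p) rep(0, p)),
                     matrix(0, ds$qtot, ds$qtot), c(1, 1))
  post <- e_step(th0, ds)
  betas <- update_beta(post, ds, th0)
  for (k in 1:2) {
    X <- do.call(rbind, lapply(ds$groups, function(g) g$X[[k]]))
    y <- unlist(lapply(ds$groups, function(g) g$y[[k]]))
    expect_equal(betas[[k]], unname(stats::lm.fit(X, y)$coefficients),
                 tolerance = 1e-10)
  }
})

test_that("fixed-effect update agrees with the pseudo-inverse oracle", {
  for (seed in 4:6) {
    r <- random_bivariate_dataset(n_groups = 3, obs = 4, seed = seed)
    th <- random_theta(r$designs, seed = seed)
    post <- e_step(th, r$designs)
    betas <- update_beta(post, r$designs, th)
    orc <- oracle_beta(post, r$designs)
    for (k in 1:2) expect_equal(betas[[k]], orc[[k]], tolerance = 1e-10)
  }
})

test_that("covariance update is the posterior second-moment average", {
  q <- 4L
  set.seed(7)
  ms <- lapply(1:3, function(i) rnorm(q))
  # pure-mean posterior: update is the empirical second moment
  post <- structure(list(mean = ms,
                         cov = replicate(3, matrix(0, q, q), simplify = FALSE)),
                    class = "mvlmm_posterior")
  G <- update_gamma_bar(post, 3L)
  expect_equal(G, Reduce(`+`, lapply(ms, tcrossprod)) / 3, tolerance = 1e-12)
  # pure-covariance posterior: update returns the common covariance
  C <- crossprod(matrix(rnorm(q * q), q)) / q
  post2 <- structure(list(mean = replicate(3, rep(0, q), simplify = FALSE),
                          cov = replicate(3, C, simplify = FALSE)),
                     class = "mvlmm_posterior")
  expect_equal(update_gamma_bar(post2, 3L), C, tolerance = 1e-12)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
})

test_that("residual-variance update matches the dense trace oracle", {
  for (seed in 7:8) {
    r <- random_bivariate_dataset(n_groups = 3, obs = 4, seed = seed)
    th <- random_theta(r$designs, seed = seed)
    post <- e_step(th, r$designs)
    betas <- update_beta(post, r$designs, th)
    expect_equal(update_sigma2(post, r$designs, betas),
                 oracle_sigma2(post, r$designs, betas), tolerance = 1e-12)
  }
  # degenerate posterior and a perfect fit give zero residual variance
  r <- random_bivariate_dataset(n_groups = 2, obs = 3, seed = 9)
  ds <- r$designs
  th <- random_theta(ds, seed = 9)
  for (i in seq_len(ds$n)) for (k in 1:2)
    ds$groups[[i]]$y[[k]] <- drop(ds$groups[[i]]$X[[k]] %*% th$betas[[k]])
  post0 <- structure(list(
    mean = replicate(ds$n, rep(0, ds$qtot), simplify = FALSE),
    cov = replicate(ds$n, matrix(0, ds$qtot, ds$qtot), simplify = FALSE)),
    class = "mvlmm_posterior")
  expect_equal(update_sigma2(post0, ds, th$betas), c(0, 0), tolerance = 1e-12)
})

test_that("log-likelihood matches closed form and the dense stacked oracle", {
  # one group, one observation, unit variance, centred response
  g <- list(id = "a", y = list(0), X = list(matrix(1, 1, 1)),
            Z = list(matrix(0, 1, 1)), N = 1L)
  ds1 <- structure(list(groups = list(g), m = 1L, n = 1L, p = 1L, q = 1L,
                        qtot = 1L, N = 1L, outcome_names = "y",
                        group_name = "g", xnames = list("i"),
                        znames = list("i")),
                   class = "mvlmm_designs")
  th1 <- mvlmm_theta(list(0), matrix(1, 1, 1), 1)
  expect_equal(log_likelihood(th1, ds1), -0.5 * log(2 * pi), tolerance = 1e-12)

  for (seed in 11:13) {
    r <- random_bivariate_dataset(n_groups = 3, obs = 3, seed = seed,
                                  miss = if (seed == 13) 1 else 0)
    th <- random_theta(r$designs, seed = seed)
    expect_equal(log_likelihood(th, r$designs),
                 oracle_loglik_stacked(th, r$designs), tolerance = 1e-10)
  }
})

test_that("compiled and pure-R engines produce the same fit", {
  r <- random_bivariate_dataset(n_groups = 4, obs = 5, seed = 21)
  opts_r <- em_options(max_iter = 40, engine = "r", init = "ols")
  opts_c <- em_options(max_iter = 40, engine = "cpp", init = "ols")
  f_r <- fit_em(r$designs, opts_r)
  f_c <- fit_em(r$designs, opts_c)
  expect_equal(f_r$theta$gamma_bar, f_c$theta$gamma_bar, tolerance = 1e-8)
  expect_equal(unlist(f_r$theta$betas), unlist(f_c$theta$betas),
               tolerance = 1e-8)
  expect_equal(f_r$theta$sigma2, f_c$theta$sigma2, tolerance = 1e-8)
  expect_equal(f_r$loglik, f_c$loglik, tolerance = 1e-8)
  expect_equal(f_r$loglik_trace, f_c$loglik_trace, tolerance = 1e-8)
})

test_that("EM ascends and reaches a fixed point", {
  d <- simulate_bivariate(sim_config(n = 40, N = 240, seed = 31))
  ds <- build_designs(d, bivariate_sim_spec())
  opts <- em_options(max_iter = 20000)
  fit <- fit_em(ds, opts)
  expect_true(fit$converged)
  # monotone log-likelihood up to numerical slack
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
  # initialization never beats the converged fit
  th0 <- initialize_theta(ds, "univariate", opts)
  expect_lte(log_likelihood(th0, ds), fit$loglik + 1e-6)
  # one more EM iteration moves no parameter by more than tol (relative)
  one_more <- fit_em(ds, em_options(max_iter = 1, init = "ols"),
                     init_theta = fit$theta)
  v0 <- c(unlist(fit$theta$betas),
          fit$theta$gamma_bar[lower.tri(fit$theta$gamma_bar, diag = TRUE)],
          fit$theta$sigma2)
  v1 <- c(unlist(one_more$theta$betas),
          one_more$theta$gamma_bar[lower.tri(one_more$theta$gamma_bar,
                                             diag = TRUE)],
          one_more$theta$sigma2)
  expect_lt(max(abs(v1 - v0) / (abs(v1) + opts$denom_floor)), opts$tol)
})

test_that("negligible random-effect variability is recovered as such", {
  cfg <- sim_config(n = 100, N = 1000, sigma1 = 1, sigma2 = 1,
                    gamma = gamma_params(eta1 = 1e-3, eta2 = 1e-4,
                                         tau1 = 1e-3, tau2 = 1e-4,
                                         rho_eta = 0, rho_tau = 0, rho = 0),
                    seed = 41)
  d <- simulate_bivariate(cfg)
  ds <- build_designs(d, bivariate_sim_spec())
  fit <- fit_em(ds)
  expect_lt(max(abs(fit$theta$gamma_bar)), 0.2)
  for (k in 1:2) {
    X <- do.call(rbind, lapply(ds$groups, function(g) g$X[[k]]))
    y <- unlist(lapply(ds$groups, function(g) g$y[[k]]))
    ols <- unname(stats::lm.fit(X, y)$coefficients)
    expect_equal(fit$theta$betas[[k]], ols, tolerance = 0.05)
  }
})

test_that("least-squares initialization seeds the expected starting point", {
  r <- random_bivariate_dataset(n_groups = 3, obs = 4, seed = 51)
  th0 <- initialize_theta(r$designs, "ols")
  for (k in 1:2) {
    X <- do.call(rbind, lapply(r$designs$groups, function(g) g$X[[k]]))
    y <- unlist(lapply(r$designs$groups, function(g) g$y[[k]]))
    fitk <- stats::lm.fit(X, y)
    expect_equal(th0$betas[[k]], unname(fitk$coefficients), tolerance = 1e-10)
    expect_equal(th0$sigma2[k], mean(fitk$residuals^2), tolerance = 1e-10)
  }
  # scaled-identity covariance start, blocked per dimension
  expect_equal(th0$gamma_bar,
               diag(rep(th0$sigma2, r$designs$q)), tolerance = 1e-12)
})
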