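test_that("the generator is deterministic given a seed", {
  d1 <- simulate_bivariate(sim_config(n = 20, N = 100, seed = 5))
  d2 <- simulate_bivariate(sim_config(n = 20, N = 100, seed = 5))
  expect_identical(d1, d2)
  d3 <- simulate_bivariate(sim_config(n = 20, N = 100, seed = 6))
  expect_false(identical(d1$weight, d3$weight))
})

test_that("observations are split as evenly as possible with minimum two", {
  d <- simulate_bivariate(sim_config(n = 7, N = 23, seed = 1))
  sizes <- as.integer(table(d$subject))
  expect_equal(sum(sizes), 23L)
  expect_lte(diff(range(sizes)), 1L)
  expect_gte(min(sizes), 2L)
  expect_error(sim_config(n = 10, N = 15), "at least 2")
})

test_that("vanishing noise recovers the fixed-effect surface exactly", {
  cfg <- sim_config(n = 10, N = 40, sigma1 = 1e-9, sigma2 = 1e-9,
                    gamma = gamma_params(eta1 = 1e-9, eta2 = 1e-9,
                                         tau1 = 1e-9, tau2 = 1e-9,
                                         rho_eta = 0, rho_tau = 0, rho = 0),
                    seed = 2)
  d <- simulate_bivariate(cfg)
  pred1 <- cfg$beta1[1] + cfg$beta1[2] * d$sex + cfg$beta1[3] * d$Nscore +
    cfg$beta1[4] * d$age
  pred2 <- cfg$beta2[1] + cfg$beta2[2] * d$sex + cfg$beta2[3] * d$Nscore +
    cfg$beta2[4] * d$age
  expect_equal(d$weight, pred1, tolerance = 1e-6)
  expect_equal(d$height, pred2, tolerance = 1e-6)
})

test_that("sex is a subject-level trait and covariates stay in range", {
  d <- simulate_bivariate(sim_config(n = 30, N = 150, seed = 3))
  per_subj <- tapply(d$sex, d$subject, function(x) length(unique(x)))
  expect_true(all(per_subj == 1L))
  expect_true(all(d$Nscore >= 20 & d$Nscore <= 50))
  expect_true(all(d$age >= 18 & d$age <= 37))
})

test_that("realized random effects match the target covariance at large n", {
  cfg <- sim_config(n = 5000, N = 10000, seed = 4)
  d <- simulate_bivariate(cfg)
  gam <- attr(d, "gamma")
  G <- build_gamma_bar(cfg$gamma)
  emp <- crossprod(gam) / nrow(gam)
  # entrywise three-standard-error band for a Wishart sample covariance
  se <- sqrt((diag(G) %o% diag(G) + G^2) / nrow(gam))
  expect_true(all(abs(emp - G) <= 3 * se))
  # independent blocks when the cross-scale is zero
  cfg0 <- sim_config(n = 5000, N = 10000,
                     gamma = gamma_params(rho = 0), seed = 4)
  gam0 <- attr(simulate_bivariate(cfg0), "gamma")
  emp0 <- crossprod(gam0) / nrow(gam0)
  expect_true(max(abs(emp0[1:2, 3:4])) < 3 * max(se[1:2, 3:4]))
})

test_that("replicated bias study reports coherent summaries", {
  cfg <- sim_config(n = 30, N = 150, seed = NULL)
  st <- bias_study(cfg, R = 3, seed = 11, options = em_options(max_iter = 300))
  expect_s3_class(st, "mvlmm_bias_study")
  expect_equal(st$R, 3L)
  expect_equal(st$bias, abs(st$mean - st$truth))
  expect_equal(st$gamma_cv, st$gamma_sd / abs(st$gamma_true))
  # identical replicate seeds leave nothing to vary
  st0 <- bias_study(cfg, R = 2, seeds = c(77L, 77L),
                    options = em_options(max_iter = 300))
  expect_equal(unname(st0$sd), rep(0, length(st0$sd)))
  expect_equal(max(st0$gamma_sd), 0)
  # squared error decomposes into squared bias plus variance
  mse <- colMeans((st$estimates - rep(st$truth, each = st$R))^2)
  decomp <- st$bias^2 + apply(st$estimates, 2, stats::var) * (st$R - 1) / st$R
  expect_equal(unname(mse), unname(decomp), tolerance = 1e-10)
})

test_that("MSE study output improves with more data", {
  st <- mse_study(sim_config(n = 30, N = 150, seed = NULL),
                  n_values = 30, N_values = c(150, 1200), R = 10, seed = 12)
  expect_true(all(c("parameter", "n", "N", "mse", "lo", "hi") %in% names(st)))
  # residual-SD information grows with the number of observations
  s1 <- st[st$parameter == "sigma1", ]
  expect_lt(s1$mse[s1$N == 1200], s1$mse[s1$N == 150])
  expect_true(all(st$lo <= st$hi))
  expect_true(all(st$mse >= 0))
})

test_that("rank AUC matches the Mann-Whitney statistic and its edge cases", {
  set.seed(13)
  S0 <- rchisq(40, 4); S1 <- rchisq(35, 4) + 2
  w <- stats::wilcox.test(S1, S0)$statistic
  expect_equal(lr_auc(S0, S1), unname(w) / (40 * 35), tolerance = 1e-12)
  # identical distributions give chance-level separation
  big0 <- rchisq(4000, 4); big1 <- rchisq(4000, 4)
  expect_equal(lr_auc(big0, big1), 0.5, tolerance = 0.05)
  expect_equal(lr_auc(c(1, 2), c(5, 6)), 1)
  expect_error(lr_auc(c(2, 2), c(2, 2)), "identical")
})

test_that("null-distribution study wires the calibration pieces together", {
  st <- null_distribution_study(N_values = 300, reps = 25, seed = 14)
  expect_equal(st$n, 60L)
  expect_true(st$reps <= 25 && st$reps >= 20)
  S <- attr(st, "S")[["300"]]
  expect_length(S, st$reps)
  # Bartlett correction recentres the statistics on the chi-square mean
  expect_equal(mean(4 * S / mean(S)), 4, tolerance = 1e-10)
  rates <- unlist(st[grepl("typeI", names(st))])
  expect_true(all(rates >= 0 & rates <= 1))
})

test_that("power study reproducibility and monotonicity in the signal", {
  st1 <- power_study(rho_values = 0.8, n = 40, N = 240, reps = 20, seed = 15,
                     boot = 200)
  st2 <- power_study(rho_values = 0.8, n = 40, N = 240, reps = 20, seed = 15,
                     boot = 200)
  expect_equal(st1$auc, st2$auc)
  expect_true(st1$auc_lo <= st1$auc & st1$auc <= st1$auc_hi)
  st <- power_study(rho_values = c(0.3, 0.8), n = 40, N = 240, reps = 25,
                    seed = 16, boot = 200)
  expect_gte(st$auc[st$rho == 0.8], st$auc[st$rho == 0.3] - 0.05)
})
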