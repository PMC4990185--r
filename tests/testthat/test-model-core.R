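test_that("design construction matches hand-built matrices on the toy data", {
  ds <- build_designs(toy_growth_data(), toy_growth_spec())

  expect_equal(ds$n, 3L)
  expect_equal(ds$N, c(7L, 8L))
  expect_equal(ds$p, c(3L, 3L))
  expect_equal(ds$q, c(2L, 2L))

  X1 <- do.call(rbind, lapply(ds$groups, function(g) g$X[[1]]))
  X2 <- do.call(rbind, lapply(ds$groups, function(g) g$X[[2]]))
  expect_equal(dim(X1), c(7L, 3L))
  expect_equal(dim(X2), c(8L, 3L))
  # subject 1 appears first; its age-16 row has a missing V1, so it is
  # present in dimension 2 but absent from dimension 1
  expect_equal(ds$groups[[1]]$N, c(2L, 3L))
  expect_equal(unname(ds$groups[[1]]$X[[1]]),
               matrix(c(1, 63.76, 0, 1, 60.98, 0), 2, byrow = TRUE))
  # per-subject random-effect blocks: (intercept, age) at the observed ages
  expect_equal(unname(ds$groups[[1]]$Z[[1]]),
               matrix(c(1, 0, 1, 6), 2, byrow = TRUE))
  expect_equal(unname(ds$groups[[1]]$Z[[2]]),
               matrix(c(1, 0, 1, 6, 1, 16), 3, byrow = TRUE))
  expect_equal(unname(ds$groups[[2]]$Z[[1]]),
               matrix(c(1, 4, 1, 7, 1, 10), 3, byrow = TRUE))
  expect_equal(unname(ds$groups[[3]]$Z[[2]]),
               matrix(c(1, 0, 1, 9), 2, byrow = TRUE))
  # dummy coding: first observed sex level (F) is the reference
  expect_equal(colnames(ds$groups[[1]]$X[[1]]), c("(Intercept)", "V1", "sexM"))
})

test_that("a complete dataset yields equal totals in all dimensions", {
  r <- random_bivariate_dataset(n_groups = 4, obs = 3, seed = 2)
  expect_equal(r$designs$N, c(12L, 12L))
})

test_that("missingness in one dimension never leaks into the other", {
  d <- toy_growth_data()
  base <- build_designs(d, toy_growth_spec())
  d2 <- d
  d2$V2[2] <- NA  # knock a row out of dimension 2 only
  mut <- build_designs(d2, toy_growth_spec())
  for (i in seq_len(base$n)) {
    expect_identical(mut$groups[[i]]$y[[1]], base$groups[[i]]$y[[1]])
    expect_identical(mut$groups[[i]]$X[[1]], base$groups[[i]]$X[[1]])
    expect_identical(mut$groups[[i]]$Z[[1]], base$groups[[i]]$Z[[1]])
  }
  expect_equal(mut$N, c(7L, 7L))
})

test_that("configuration and data errors are reported", {
  d <- toy_growth_data()
  bad <- mvlmm_spec(list(outcome_spec("y1", fixed = "nope"),
                         outcome_spec("y2")), group = "subject")
  expect_error(build_designs(d, bad), "not found")

  d_allna <- d
  d_allna$y1 <- NA_real_
  expect_error(build_designs(d_allna, toy_growth_spec()), "no usable rows")

  d_onesex <- d
  d_onesex$sex <- "F"
  expect_warning(build_designs(d_onesex, toy_growth_spec()),
                 "single observed level")

  # one observation per group on average: unidentifiable variance components
  d1 <- data.frame(g = 1:6, a = rnorm(6), y1 = rnorm(6), y2 = rnorm(6))
  sp <- mvlmm_spec(list(outcome_spec("y1", fixed = "a"),
                        outcome_spec("y2", fixed = "a")), group = "g")
  expect_warning(build_designs(d1, sp), "unidentifiable")
})

test_that("structured covariance assembly reproduces the reference matrix", {
  G <- build_gamma_bar(gamma_params())
  expect_equal(diag(G), c(5.27^2, 6.00^2, 9.89^2, 1.17^2), tolerance = 1e-12)
  ref <- matrix(c(27.77, 18.80, 41.70, 4.93,
                  18.80, 36.00, 47.47, 5.62,
                  41.70, 47.47, 97.81, 8.91,
                  4.93, 5.62, 8.91, 1.37), 4, byrow = TRUE)
  expect_true(max(abs(G - ref)) < 0.005)
  expect_equal(G, t(G))
})

test_that("zero cross-scale gives a block-diagonal covariance", {
  G <- build_gamma_bar(gamma_params(rho = 0))
  expect_true(all(G[1:2, 3:4] == 0))
  expect_true(all(G[3:4, 1:2] == 0))
})

test_that("assembled covariances are symmetric positive definite or error", {
  set.seed(42)
  for (j in 1:40) {
    pars <- gamma_params(eta1 = runif(1, 0.5, 10), eta2 = runif(1, 0.5, 10),
                         tau1 = runif(1, 0.5, 10), tau2 = runif(1, 0.5, 10),
                         rho_eta = runif(1, -0.6, 0.6),
                         rho_tau = runif(1, -0.6, 0.6),
                         rho = runif(1, -0.5, 0.5))
    G <- tryCatch(build_gamma_bar(pars), error = identity)
    if (inherits(G, "error")) {
      # a rejected assembly must really be indefinite, and say so
      expect_match(conditionMessage(G), "eigenvalue")
    } else {
      expect_equal(G, t(G))
      expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
  # uncorrelated within dimensions but strong cross-coupling is not PD
  expect_error(build_gamma_bar(gamma_params(eta1 = 1, eta2 = 1, tau1 = 1,
                                            tau2 = 1, rho_eta = 0,
                                            rho_tau = 0, rho = 0.9)),
               "eigenvalue")
})

test_that("covariance-to-correlation conversion matches reference values", {
  R <- cov_to_corr(build_gamma_bar(gamma_params()))
  expect_equal(diag(R), rep(1, 4))
  expect_lt(abs(R[1, 2] - 0.59), 0.005)
  expect_lt(abs(R[3, 4] - 0.77), 0.005)
  expect_true(max(abs(R[1:2, 3:4] - 0.80)) < 0.005)

  expect_equal(cov_to_corr(diag(3)), diag(3))

  V <- matrix(c(5.15, 5.41, 5.41, 7.07), 2)
  expect_lt(abs(cov_to_corr(V)[1, 2] - 0.895), 0.01)

  expect_error(cov_to_corr(matrix(c(0, 0, 0, 1), 2)), "diagonal")
})

test_that("design subsetting preserves the selected dimension untouched", {
  ds <- build_designs(toy_growth_data(), toy_growth_spec())
  d1 <- subset_designs(ds, 1L)
  expect_equal(d1$m, 1L)
  expect_equal(d1$N, 7L)
  expect_identical(d1$groups[[2]]$X[[1]], ds$groups[[2]]$X[[1]])
})
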