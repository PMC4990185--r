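# Fixtures and independent dense oracles used across the suite.
#
# The oracles deliberately take the brute-force route (explicit joint
# Gaussian assembly, pseudo-inverse normal equations, fully stacked
# covariance) so they share no code path with the blocked implementations
# they check. They are only ever used on toy-sized instances.

toy_growth_path <- function() {
  system.file("extdata", "toy_growth.csv", package = "mvlmmcor")
}

toy_growth_data <- function() read_long_csv(toy_growth_path())

toy_growth_spec <- function() {
  mvlmm_spec(list(outcome_spec("y1", fixed = c("V1", "sex"), random = "age"),
                  outcome_spec("y2", fixed = c("V2", "sex"), random = "age")),
             group = "subject")
}

# small random bivariate dataset with a shared numeric covariate pair;
# optional missingness knocked into outcomes and covariates independently
random_bivariate_dataset <- function(n_groups = 3, obs = 4, seed = 1,
                                     miss = 0) {
  set.seed(seed)
  n <- n_groups * obs
  d <- data.frame(g = rep(seq_len(n_groups), each = obs),
                  a = rnorm(n), w = runif(n, -1, 1),
                  y1 = rnorm(n, sd = 2), y2 = rnorm(n, sd = 2))
  if (miss > 0) {
    for (cl in c("y1", "y2", "a")) {
      idx <- sample.int(n, miss)
      d[[cl]][idx] <- NA
    }
  }
  spec <- mvlmm_spec(list(outcome_spec("y1", fixed = "a", random = "w"),
                          outcome_spec("y2", fixed = "a", random = "w")),
                     group = "g")
  list(data = d, spec = spec, designs = build_designs(d, spec))
}

# random valid parameter value matching a design set
random_theta <- function(designs, seed = 1) {
  set.seed(seed)
  q <- designs$qtot
  A <- matrix(rnorm(q * q), q)
  G <- crossprod(A) / q + 0.5 * diag(q)
  betas <- lapply(designs$p, function(p) rnorm(p))
  mvlmm_theta(betas, G, runif(designs$m, 0.5, 2))
}

# dense block-diagonal Z_i of one group (rows stacked dimension-major)
dense_group_z <- function(group) {
  q <- vapply(group$Z, ncol, integer(1))
  Z <- matrix(0, sum(group$N), sum(q))
  ends <- cumsum(q); starts <- ends - q + 1
  row0 <- 0
  for (k in seq_along(q)) {
    if (group$N[k] > 0) {
      Z[row0 + seq_len(group$N[k]), starts[k]:ends[k]] <- group$Z[[k]]
      row0 <- row0 + group$N[k]
    }
  }
  Z
}

# brute-force posterior of (gamma_i | y_i): assemble the joint Gaussian of
# (gamma_i, y_i) explicitly and condition through the joint precision matrix
oracle_posterior_group <- function(theta, group) {
  G <- theta$gamma_bar
  q <- nrow(G)
  Z <- dense_group_z(group)
  Sig <- diag(rep(theta$sigma2, group$N), nrow = sum(group$N))
  J <- rbind(cbind(G, G %*% t(Z)),
             cbind(Z %*% G, Z %*% G %*% t(Z) + Sig))
  Om <- solve(J)
  Vc <- solve(Om[1:q, 1:q, drop = FALSE])
  mu <- unlist(lapply(seq_along(group$y), function(k)
    if (group$N[k] > 0) drop(group$X[[k]] %*% theta$betas[[k]]) else numeric(0)))
  yc <- unlist(group$y) - mu
  m <- -drop(Vc %*% Om[1:q, -(1:q), drop = FALSE] %*% yc)
  list(mean = m, cov = Vc)
}

# fully stacked dense log-likelihood: assemble the N x N covariance of the
# complete response vector in dimension-major order (all groups of outcome 1,
# then outcome 2, ...) with block (k, l) = Z_k diag_i(Gbar_kl) Z_l' +
# delta_kl sigma_k^2 I, and evaluate the Gaussian log-density directly
oracle_loglik_stacked <- function(theta, designs) {
  m <- designs$m
  n <- designs$n
  q <- designs$q
  ends <- cumsum(q); starts <- ends - q + 1
  # dense per-dimension Z_k: N_k x (n * q_k), subject-blocked
  Zk <- lapply(seq_len(m), function(k) {
    Z <- matrix(0, designs$N[k], n * q[k])
    row0 <- 0
    for (i in seq_len(n)) {
      g <- designs$groups[[i]]
      if (g$N[k] > 0) {
        Z[row0 + seq_len(g$N[k]), (i - 1) * q[k] + seq_len(q[k])] <- g$Z[[k]]
        row0 <- row0 + g$N[k]
      }
    }
    Z
  })
  gam_block <- function(k, l) {
    Gkl <- theta$gamma_bar[starts[k]:ends[k], starts[l]:ends[l], drop = FALSE]
    kronecker(diag(n), Gkl)
  }
  V <- matrix(0, sum(designs$N), sum(designs$N))
  mu <- numeric(sum(designs$N))
  offs <- c(0, cumsum(designs$N))
  for (k in seq_len(m)) {
    rows <- offs[k] + seq_len(designs$N[k])
    mu[rows] <- unlist(lapply(designs$groups, function(g)
      if (g$N[k] > 0) drop(g$X[[k]] %*% theta$betas[[k]]) else numeric(0)))
    for (l in seq_len(m)) {
      cols <- offs[l] + seq_len(designs$N[l])
      V[rows, cols] <- Zk[[k]] %*% gam_block(k, l) %*% t(Zk[[l]])
      if (k == l) V[rows, cols] <- V[rows, cols] +
          theta$sigma2[k] * diag(designs$N[k])
    }
  }
  y <- unlist(lapply(seq_len(m), function(k)
    unlist(lapply(designs$groups, function(g) g$y[[k]]))))
  r <- y - mu
  -0.5 * (length(y) * log(2 * pi) + determinant(V)$modulus[1] +
            drop(crossprod(r, solve(V, r))))
}

# pseudo-inverse normal-equations oracle for the fixed-effect update
oracle_beta <- function(posterior, designs) {
  ends <- cumsum(designs$q); starts <- ends - designs$q + 1
  lapply(seq_len(designs$m), function(k) {
    X <- do.call(rbind, lapply(designs$groups, function(g) g$X[[k]]))
    resp <- unlist(lapply(seq_len(designs$n), function(i) {
      g <- designs$groups[[i]]
      if (g$N[k] == 0) return(numeric(0))
      g$y[[k]] - drop(g$Z[[k]] %*% posterior$mean[[i]][starts[k]:ends[k]])
    }))
    drop(MASS::ginv(crossprod(X)) %*% crossprod(X, resp))
  })
}

# dense oracle for the residual-variance update: builds the full per-group
# residual moment matrix and reduces by trace
oracle_sigma2 <- function(posterior, designs, betas) {
  ends <- cumsum(designs$q); starts <- ends - designs$q + 1
  vapply(seq_len(designs$m), function(k) {
    acc <- 0
    for (i in seq_len(designs$n)) {
      g <- designs$groups[[i]]
      if (g$N[k] == 0) next
      mk <- posterior$mean[[i]][starts[k]:ends[k]]
      Vk <- posterior$cov[[i]][starts[k]:ends[k], starts[k]:ends[k]]
      r <- g$y[[k]] - drop(g$X[[k]] %*% betas[[k]]) - drop(g$Z[[k]] %*% mk)
      M <- g$Z[[k]] %*% Vk %*% t(g$Z[[k]]) + tcrossprod(r)
      acc <- acc + sum(diag(M))
    }
    acc / designs$N[k]
  }, numeric(1))
}

# four-outcome dataset with two independent bivariate blocks sharing the
# same subjects and covariates: block A from the packaged generator, block B
# drawn independently over the same design rows
planted_partition_data <- function(n = 150, N = 1200, rho = 0.8, seed = 99) {
  cfg <- sim_config(n = n, N = N, gamma = gamma_params(rho = rho), seed = seed)
  d <- simulate_bivariate(cfg)
  names(d)[names(d) == "weight"] <- "A1"
  names(d)[names(d) == "height"] <- "A2"
  G <- build_gamma_bar(cfg$gamma)
  gamB <- MASS::mvrnorm(n, rep(0, 4), G)
  s <- d$subject
  d$B1 <- cfg$beta1[1] + cfg$beta1[2] * d$sex + cfg$beta1[3] * d$Nscore +
    cfg$beta1[4] * d$age + gamB[s, 1] + gamB[s, 2] * d$Nscore +
    rnorm(nrow(d), sd = cfg$sigma1)
  d$B2 <- cfg$beta2[1] + cfg$beta2[2] * d$sex + cfg$beta2[3] * d$Nscore +
    cfg$beta2[4] * d$age + gamB[s, 3] + gamB[s, 4] * d$Nscore +
    rnorm(nrow(d), sd = cfg$sigma2)
  spec <- mvlmm_spec(lapply(c("A1", "A2", "B1", "B2"), function(nm)
    outcome_spec(nm, fixed = c("sex", "Nscore", "age"), random = "Nscore")),
    group = "subject")
  list(data = d, spec = spec)
}
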