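# Conjugate updates, transition machinery and sampler behaviour.

matched_prior <- function(st, traj, n0 = 4, nu0 = 4) {
  d <- length(st$mu)
  dynamics_prior(M0 = cbind(st$F, st$mu),
                 V0 = diag(c(rep(1, d), 1)),
                 S0 = (n0 - d - 1) * st$Sigma, n0 = n0,
                 Psi0 = (nu0 - d - 1) * st$R, nu0 = nu0)
}

test_that("degenerate transition matrix forces a constant state sequence", {
  set.seed(1)
  K <- 4
  theta <- lapply(1:K, function(k) random_stable_state(with_R = FALSE))
  path <- matrix(rnorm(60, sd = 0.1), 30, 2)
  pi <- matrix(0, K, K); pi[, 1] <- 1
  beta <- c(1, 0, 0, 0)
  z <- sample_state_sequence(path, theta, pi, beta)
  expect_true(all(z == 1))
})

test_that("symmetric states give uniform marginal state frequencies", {
  set.seed(2)
  K <- 3
  st <- free_diffusion_state(0.02, 0.02)
  st$R <- NULL
  theta <- rep(list(st), K)
  sim <- simulate_slds(simulation_spec(list(free_diffusion_state(0.02, 0.02)),
                                       schedule = rep(1, 50), dt = DT22,
                                       seed = 3))
  path <- sim$true_path
  pi <- matrix(1 / K, K, K)
  beta <- rep(1 / K, K)
  counts <- numeric(K)
  ndraw <- 2000
  for (i in seq_len(ndraw)) {
    z <- sample_state_sequence(path, theta, pi, beta)
    counts <- counts + tabulate(z, K)
  }
  freq <- counts / (ndraw * 50)
  se <- sqrt((1 / K) * (1 - 1 / K) / ndraw)  # conservative: draws correlated within a path
  expect_true(all(abs(freq - 1 / K) < 5 * se))
})

test_that("given true parameters, contrasting states are recovered near-perfectly", {
  set.seed(4)
  s1 <- free_diffusion_state(0.002, 0.02); s1$R <- NULL
  s2 <- free_diffusion_state(0.2, 0.02); s2$R <- NULL
  z_true <- rep(rep(1:2, 2), each = 250)
  sim <- simulate_slds(simulation_spec(
    list(free_diffusion_state(0.002, 0.001), free_diffusion_state(0.2, 0.001)),
    schedule = z_true, dt = DT22, seed = 5))
  pi <- matrix(c(0.996, 0.004, 0.004, 0.996), 2, 2)
  z <- sample_state_sequence(sim$true_path, list(s1, s2), pi, c(0.5, 0.5))
  expect_lte(hamming_distance(z_true, z), 0.02)
})

test_that("states without data fall back to the prior (mean of [F mu] near M0)", {
  set.seed(6)
  d <- 2
  prior <- dynamics_prior(M0 = cbind(diag(d), c(0.1, -0.1)),
                          V0 = diag(0.2, d + 1),
                          S0 = diag(0.01, d) * 5, n0 = d + 6,
                          Psi0 = diag(1e-4, d), nu0 = d + 6)
  path <- matrix(rnorm(20, sd = 0.1), 10, 2)
  nrep <- 5000
  acc <- matrix(0, d, d + 1); acc2 <- matrix(0, d, d + 1)
  for (i in seq_len(nrep)) {
    # state 2 never appears in the labels -> prior draw
    th <- sample_emission_params(path, rep(1, 10), prior, K = 2)[[2]]
    A <- cbind(th$F, th$mu)
    acc <- acc + A; acc2 <- acc2 + A^2
  }
  m <- acc / nrep
  se <- sqrt(pmax(acc2 / nrep - m^2, 0) / nrep)
  expect_true(all(abs(m - prior$M0) < 4 * se + 1e-12))
})

test_that("large-n MNIW posterior mean matches the OLS estimate", {
  set.seed(7)
  st <- random_stable_state(with_R = FALSE)
  sim <- simulate_slds(simulation_spec(
    list(state_params(st$mu, st$F, st$Sigma, R = diag(1e-12, 2))),
    schedule = rep(1, 5001), dt = DT22, seed = 8))
  path <- sim$true_path
  X <- cbind(path[-5001, ], 1)
  Y <- path[-1, ]
  A_ols <- t(solve(crossprod(X), crossprod(X, Y)))
  prior <- matched_prior(state_params(c(0, 0), diag(2) * 0.5,
                                      diag(0.01, 2), diag(1e-4, 2)),
                         sim$trajectory)
  nrep <- 200
  acc <- matrix(0, 2, 3)
  for (i in seq_len(nrep)) {
    th <- sample_emission_params(path, rep(1, 5001), prior, K = 1)[[1]]
    acc <- acc + cbind(th$F, th$mu)
  }
  expect_lt(max(abs(acc / nrep - A_ols)), 1e-2)
})

test_that("tiny-case posterior matches the brute-force Bayes-rule ratio", {
  # d = 1, n = 3 transitions: the MNIW posterior density ratio at two
  # parameter points must equal the prior x likelihood ratio.
  set.seed(9)
  r <- c(0.1, 0.25, 0.2, 0.4)
  prior <- dynamics_prior(M0 = matrix(c(0.8, 0.05), 1, 2),
                          V0 = diag(c(0.5, 0.3)),
                          S0 = matrix(0.02), n0 = 3.5,
                          Psi0 = matrix(1e-4), nu0 = 3.5)
  X <- cbind(r[-4], 1); Y <- matrix(r[-1])
  pp <- hdpslds:::mniw_posterior_params(crossprod(X), crossprod(X, Y),
                                        crossprod(Y), 3, prior)
  log_mniw <- function(A, Sig, M, V, S, n) {
    # unnormalized in (A, Sig): MN(A; M, Sig, V) x IW(Sig; S, n), p = 1
    q <- ncol(M)
    -0.5 * q * log(Sig) - 0.5 * sum((A - M) %*% solve(V) %*% t(A - M)) / Sig -
      (n + 2) / 2 * log(Sig) - 0.5 * S[1, 1] / Sig
  }
  loglik <- function(A, Sig) {
    mu_hat <- X %*% t(A)
    sum(dnorm(r[-1], mu_hat, sqrt(Sig), log = TRUE))
  }
  th1 <- list(A = matrix(c(0.7, 0.1), 1, 2), Sig = 0.015)
  th2 <- list(A = matrix(c(0.95, -0.05), 1, 2), Sig = 0.04)
  lhs <- log_mniw(th1$A, th1$Sig, pp$Mn, pp$Vn, pp$Sn, pp$nn) -
         log_mniw(th2$A, th2$Sig, pp$Mn, pp$Vn, pp$Sn, pp$nn)
  rhs <- (log_mniw(th1$A, th1$Sig, prior$M0, prior$V0, prior$S0, prior$n0) +
            loglik(th1$A, th1$Sig)) -
         (log_mniw(th2$A, th2$Sig, prior$M0, prior$V0, prior$S0, prior$n0) +
            loglik(th2$A, th2$Sig))
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("measurement-noise draws: prior mean, data dominance, PSD", {
  set.seed(10)
  d <- 2
  prior <- dynamics_prior(M0 = cbind(diag(d), c(0, 0)), V0 = diag(1, d + 1),
                          S0 = diag(0.01, d), n0 = 4,
                          Psi0 = diag(0.0016, d) * 7, nu0 = d + 8)
  # no residuals: mean over draws ~ Psi0 / (nu0 - d - 1)
  nrep <- 4000
  acc <- matrix(0, d, d); acc2 <- matrix(0, d, d)
  worst_asym <- 0; worst_eig <- Inf
  for (i in seq_len(nrep)) {
    Rd <- sample_measurement_noise(matrix(0, 0, d), matrix(0, 0, d), prior)
    worst_asym <- max(worst_asym, abs(Rd - t(Rd)))
    worst_eig <- min(worst_eig,
                     eigen(Rd, symmetric = TRUE, only.values = TRUE)$values)
    acc <- acc + Rd; acc2 <- acc2 + Rd^2
  }
  expect_lt(worst_asym, 1e-12)
  expect_gte(worst_eig, 0)
  m <- acc / nrep
  se <- sqrt(pmax(acc2 / nrep - m^2, 0) / nrep)
  target <- prior$Psi0 / (prior$nu0 - d - 1)
  expect_true(all(abs(m - target) < 4 * se + 1e-9))
  # data dominance: T = 1e4 residuals with known covariance
  C <- matrix(c(4e-4, 1e-4, 1e-4, 9e-4), 2, 2)
  E <- matrix(rnorm(2e4), 1e4, 2) %*% chol(C)
  draws <- replicate(50, sample_measurement_noise(E, E * 0, prior))
  expect_lt(max(abs(apply(draws, c(1, 2), mean) - crossprod(E) / 1e4) /
                  max(abs(C))), 0.05)
})

test_that("transition draws obey the Dirichlet means and sticky limit", {
  set.seed(11)
  K <- 3; alpha <- 1; gamma <- 2
  beta0 <- c(0.5, 0.3, 0.2)
  nrep <- 1e4
  acc_pi <- matrix(0, K, K); acc_beta <- numeric(K)
  worst_sum <- 0
  for (i in seq_len(nrep)) {
    tw <- sample_transitions(NULL, beta0, alpha, 0, gamma, K)
    acc_pi <- acc_pi + tw$pi
    acc_beta <- acc_beta + tw$beta
    worst_sum <- max(worst_sum, abs(rowSums(tw$pi) - 1), abs(sum(tw$beta) - 1))
  }
  expect_lt(worst_sum, 1e-10)
  # with no data each row mean equals E[beta_k] = 1/K (rows are
  # Dirichlet(alpha beta) around the freshly resampled global weights)
  se <- sqrt(0.25 / nrep)
  expect_true(all(abs(acc_pi / nrep - 1 / K) < 5 * se))
  expect_true(all(abs(acc_beta / nrep - 1 / K) < 4 * se))
  # conditional on fixed beta: E[pi_jk | beta] = beta_k
  acc_fix <- matrix(0, K, K)
  for (i in seq_len(nrep)) {
    tw <- sample_transitions(NULL, beta0, alpha, 0, gamma, K,
                             resample_beta = FALSE)
    acc_fix <- acc_fix + tw$pi
  }
  expect_true(all(abs(sweep(acc_fix / nrep, 2, beta0)) < 5 * se))
  # strong stickiness: E[pi_jj] = (alpha beta_j + kappa)/(alpha + kappa) -> 1
  kappa <- 100 * alpha
  acc_diag <- numeric(K)
  for (i in 1:2000) {
    tw <- sample_transitions(NULL, beta0, alpha, kappa, gamma, K)
    acc_diag <- acc_diag + diag(tw$pi)
  }
  expect_true(all(acc_diag / 2000 >= 0.95))
})

test_that("run_gibbs is deterministic under a fixed seed", {
  sim <- two_state_switch_sim(seed = 21, T = 120, t_switch = 60)
  prior <- default_dynamics_prior(sim$trajectory, sigma = 0.03)
  cfg <- sticky_hdp_config(K = 5, n_iter = 40, seed = 33)
  a <- run_gibbs(sim$trajectory, prior, cfg)
  b <- run_gibbs(sim$trajectory, prior, cfg)
  expect_identical(a$z, b$z)
  expect_identical(a$R, b$R)
  expect_identical(a$beta, b$beta)
})

test_that("a single-state trajectory is dominated by one state", {
  set.seed(12)
  st <- ou_state(b = 2, D = 0.05, sigma = 0.03)
  sim <- simulate_slds(simulation_spec(list(st), schedule = rep(1, 500),
                                       dt = DT22, seed = 13))
  prior <- matched_prior(st, sim$trajectory)
  post <- run_gibbs(sim$trajectory, prior,
                    sticky_hdp_config(n_iter = 400, seed = 14))
  frac_single <- mean(apply(post$z, 1, function(z) max(tabulate(z, 10)) > 0.95 * 500))
  expect_gte(frac_single, 0.9)
})

test_that("change points follow the strict 25% rule and permutation invariance", {
  # synthetic sample set: 20 draws over 6 frames
  z <- matrix(1L, 20, 6)
  z[1:6, 3:6] <- 2L    # change at frame 2 in 30% of draws
  z[1:4, 5:6] <- 3L    # change at frame 4 in 20% of draws
  z[1:5, 6] <- 4L      # change at frame 5 in exactly 25% of draws
  fake <- structure(list(z = z, cfg = list(K = 5)),
                    class = "posterior_sample_set")
  seg <- extract_changepoints(fake, threshold = 0.25, min_dwell = 2)
  expect_equal(seg$change_freq[2], 0.30)
  expect_equal(seg$change_freq[4], 0.20)
  expect_equal(seg$change_freq[5], 0.25)
  expect_equal(seg$changepoints, 2L)  # 0.20 and the exact 0.25 tie excluded
  # relabeling leaves the segmentation untouched
  perm <- c(3L, 5L, 1L, 4L, 2L)
  fake2 <- fake; fake2$z <- matrix(perm[z], nrow(z), ncol(z))
  seg2 <- extract_changepoints(fake2, threshold = 0.25, min_dwell = 2)
  expect_equal(seg2$changepoints, seg$changepoints)
  expect_equal(seg2$change_freq, seg$change_freq)
  expect_equal(seg2$segment_id, seg$segment_id)
  # constant draws: no change points
  fake3 <- structure(list(z = matrix(2L, 10, 6), cfg = list(K = 5)),
                     class = "posterior_sample_set")
  expect_length(extract_changepoints(fake3)$changepoints, 0)
})
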