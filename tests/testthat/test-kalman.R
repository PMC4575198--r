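# Filter/smoother/path-sampler checks against explicit joint-Gaussian
# oracles on short trajectories, plus reductions and invariances.

make_short_traj <- function(T = 6, d = 1, seed = 1) {
  set.seed(seed)
  mu <- rnorm(d, sd = 0.05)
  F <- diag(0.8, d)
  Sigma <- diag(0.02, d)
  R <- diag(0.01, d)
  m0 <- rnorm(d, sd = 0.1); P0 <- diag(0.05, d)
  psi <- matrix(rnorm(T * d, sd = 0.5), T, d)
  list(traj = trajectory(cbind(psi, psi * 0 + seq_len(T) * 0)[, seq_len(d), drop = FALSE],
                         dt = 0.1),
       mu = mu, F = F, Sigma = Sigma, R = R, m0 = m0, P0 = P0, psi = psi)
}

test_that("filter log-likelihood equals the joint-Gaussian oracle (T <= 8)", {
  for (case in 1:4) {
    T <- c(4, 6, 8, 6)[case]
    set.seed(case)
    d <- 2
    st <- random_stable_state()
    m0 <- rnorm(d, sd = 0.2); P0 <- crossprod(matrix(rnorm(4, sd = 0.3), 2)) + diag(0.02, 2)
    psi <- matrix(rnorm(T * d, sd = 0.3), T, d)
    traj <- trajectory(psi, dt = DT22)
    flt <- kalman_filter(traj, st, init_mean = m0, init_cov = P0)
    jg <- joint_gaussian_model(T, st$mu, st$F, st$Sigma, st$R, m0, P0)
    x <- as.numeric(t(psi))
    idx1 <- 1:d; rest <- (d + 1):(T * d)
    cond <- gaussian_conditional(jg$mean, jg$cov_psi, rest, idx1, x[idx1])
    oracle <- log_dmvnorm(x[rest], cond$mean, cond$cov)
    expect_equal(flt$loglik, oracle, tolerance = 1e-8)
  }
})

test_that("smoothed means equal the conditional mean of the joint Gaussian", {
  set.seed(11)
  T <- 6; d <- 2
  st <- random_stable_state()
  m0 <- c(0.1, -0.2); P0 <- diag(0.04, 2)
  psi <- matrix(rnorm(T * d, sd = 0.3), T, d)
  traj <- trajectory(psi, dt = DT22)
  flt <- kalman_filter(traj, st, init_mean = m0, init_cov = P0)
  sm <- kalman_smoother(traj, filter = flt)
  jg <- joint_gaussian_model(T, st$mu, st$F, st$Sigma, st$R, m0, P0)
  x <- as.numeric(t(psi))
  # r | psi: joint of (r, psi) has cross-cov cov_r (measurement noise indep)
  big_mean <- c(jg$mean, jg$mean)
  big_cov <- rbind(cbind(jg$cov_r, jg$cov_r), cbind(jg$cov_r, jg$cov_psi))
  cond <- gaussian_conditional(big_mean, big_cov, 1:(T * d),
                               T * d + 1:(T * d), x)
  expect_equal(as.numeric(t(sm$path)), cond$mean, tolerance = 1e-8)
  # last frame: smoothed = filtered
  expect_equal(sm$path[T, ], flt$filt_mean[T, ], tolerance = 1e-12)
  # smoothed covariance is no larger than filtered (matrix sense)
  for (i in 1:T) {
    dcov <- flt$filt_cov[, , i] - sm$cov[, , i]
    expect_gt(min(eigen(dcov, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("R = 0 reduces the filter to a vector autoregression", {
  set.seed(2)
  st <- random_stable_state(with_R = FALSE)
  st$R <- diag(0, 2)
  sim <- simulate_slds(simulation_spec(list(st), schedule = rep(1, 50),
                                       dt = DT22, seed = 30))
  psi <- sim$trajectory$positions
  flt <- kalman_filter(sim$trajectory, st, init_mean = psi[1, ],
                       init_cov = diag(0, 2))
  L <- chol(st$Sigma)
  var_ll <- 0
  for (i in 2:nrow(psi)) {
    var_ll <- var_ll + log_dmvnorm(psi[i, ], st$mu + st$F %*% psi[i - 1, ],
                                   st$Sigma)
  }
  expect_equal(flt$loglik, var_ll, tolerance = 1e-6)
  # smoother and sampled paths collapse onto the observations
  sm <- kalman_smoother(sim$trajectory, st, init_mean = psi[1, ],
                        init_cov = diag(0, 2))
  expect_equal(sm$path, psi, tolerance = 1e-4)
  set.seed(1)
  p <- ffbs_sample_path(sim$trajectory, st, init_mean = psi[1, ],
                        init_cov = diag(0, 2))
  expect_equal(p, psi, tolerance = 1e-4)
})

test_that("scalar Brownian+noise filtered variance follows the hand recursion", {
  D <- 0.05; sigma <- 0.02; dt <- 0.1
  st <- state_params(mu = 0, F = matrix(1), Sigma = matrix(2 * D * dt),
                     R = matrix(sigma^2))
  psi <- matrix(cumsum(rnorm(21, sd = 0.1)), 21, 1)
  traj <- trajectory(psi, dt = dt)
  P0 <- 0.5
  flt <- kalman_filter(traj, st, init_mean = psi[1, ], init_cov = matrix(P0))
  # hand iteration of predict/update on the variance
  P <- P0
  hand <- numeric(21)
  for (i in 1:21) {
    S <- P + sigma^2 + 1e-12
    K <- P / S
    P <- (1 - K)^2 * P + K^2 * sigma^2
    hand[i] <- P
    P <- P + 2 * D * dt
  }
  expect_equal(as.numeric(flt$filt_cov[1, 1, ]), hand, tolerance = 1e-10)
})

test_that("log-likelihood is invariant under rigid translation when F = I", {
  set.seed(4)
  st <- free_diffusion_state(0.05, 0.03)
  sim <- simulate_slds(simulation_spec(list(st), schedule = rep(1, 100),
                                       dt = DT22, seed = 12))
  traj <- sim$trajectory
  flt1 <- kalman_filter(traj, st)
  shift <- c(3.7, -1.2)
  traj2 <- trajectory(sweep(traj$positions, 2, shift, "+"), dt = traj$dt)
  flt2 <- kalman_filter(traj2, st,
                        init_mean = traj$positions[1, ] + shift,
                        init_cov = st$R + diag(1, 2))
  expect_equal(flt1$loglik, flt2$loglik, tolerance = 1e-9)
})

test_that("reported covariances stay PSD after symmetrization", {
  set.seed(8)
  st <- random_stable_state()
  sim <- simulate_slds(simulation_spec(list(st), schedule = rep(1, 200),
                                       dt = DT22, seed = 2))
  flt <- kalman_filter(sim$trajectory, st)
  mins <- sapply(seq_len(200), function(i)
    min(eigen(flt$filt_cov[, , i], symmetric = TRUE, only.values = TRUE)$values))
  expect_gt(min(mins), -1e-10)
})

test_that("FFBS paths are reproducible and average to the smoother mean", {
  set.seed(10)
  st <- free_diffusion_state(0.03, 0.03)
  sim <- simulate_slds(simulation_spec(list(st), schedule = rep(1, 40),
                                       dt = DT22, seed = 17))
  flt <- kalman_filter(sim$trajectory, st)
  set.seed(55); p1 <- ffbs_sample_path(sim$trajectory, filter = flt)
  set.seed(55); p2 <- ffbs_sample_path(sim$trajectory, filter = flt)
  expect_identical(p1, p2)
  sm <- kalman_smoother(sim$trajectory, filter = flt)
  set.seed(77)
  nrep <- 2000
  acc <- matrix(0, 40, 2); acc2 <- matrix(0, 40, 2)
  for (i in seq_len(nrep)) {
    p <- ffbs_sample_path(sim$trajectory, filter = flt)
    acc <- acc + p; acc2 <- acc2 + p^2
  }
  mean_p <- acc / nrep
  se_p <- sqrt((acc2 / nrep - mean_p^2) / nrep)
  expect_true(all(abs(mean_p - sm$path) < 4 * se_p + 1e-12))
})

test_that("time-varying parameters are honoured per transition", {
  # two regimes with very different Sigma: likelihood must beat the
  # mismatched constant-parameter filter on regime-switching data
  s1 <- free_diffusion_state(0.002, 0.02)
  s2 <- free_diffusion_state(0.2, 0.02)
  z <- rep(1:2, each = 100)
  sim <- simulate_slds(simulation_spec(list(s1, s2), schedule = z, dt = DT22,
                                       seed = 44))
  params_seq <- lapply(z[-200], function(k) list(s1, s2)[[k]])
  ll_true <- kalman_filter(sim$trajectory, params_seq)$loglik
  ll_wrong <- kalman_filter(sim$trajectory, s1)$loglik
  expect_gt(ll_true, ll_wrong + 100)
})
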