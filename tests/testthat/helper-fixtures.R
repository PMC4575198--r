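# Shared fixtures: random stable parameter sets and standard simulation
# designs, all built in code at test time.

DT22 <- 1 / 22  # video-rate frame interval, seconds

# random stable continuous parameters (eigenvalues of B with negative real
# part, SPD D)
random_stable_cont <- function(d = 2, kBT = KBT_DEFAULT) {
  repeat {
    B <- matrix(rnorm(d * d, sd = 1.5), d, d) - diag(2 + runif(d), d)
    if (max(Re(eigen(B, only.values = TRUE)$values)) < -0.05) break
  }
  A <- rnorm(d, sd = 0.2)
  G <- matrix(rnorm(d * d, sd = 0.2), d, d)
  D <- crossprod(G) + diag(0.02 + runif(d, 0, 0.05), d)
  continuous_params(A = A, B = B, D = D, kBT = kBT)
}

# random stable discrete state (spectral radius of F < 1)
random_stable_state <- function(d = 2, with_R = TRUE) {
  disc <- discrete_from_continuous(random_stable_cont(d), DT22)
  R <- if (with_R) diag(runif(d, 0.0005^2, 0.04^2), d) else NULL
  state_params(disc$mu, disc$F, disc$Sigma, R = R)
}

# free diffusion state: F = I, Sigma = 2 D dt I, isotropic measurement noise
free_diffusion_state <- function(D, sigma, dt = DT22, d = 2) {
  state_params(mu = rep(0, d), F = diag(d), Sigma = diag(2 * D * dt, d),
               R = diag(sigma^2, d))
}

# confined (Ornstein-Uhlenbeck) state around a centre
ou_state <- function(b, D, sigma, centre = c(0, 0), dt = DT22) {
  cont <- continuous_params(A = b * centre, B = -b * diag(2), D = diag(D, 2))
  disc <- discrete_from_continuous(cont, dt)
  state_params(disc$mu, disc$F, disc$Sigma, R = diag(sigma^2, 2))
}

# the two-state 10x diffusion-contrast design with a single switch
two_state_switch_sim <- function(seed, T = 1000, t_switch = 500,
                                 D = c(0.01, 0.1), sigma = 0.03) {
  s1 <- free_diffusion_state(D[1], sigma)
  s2 <- free_diffusion_state(D[2], sigma)
  z <- rep(1:2, c(t_switch, T - t_switch))
  simulate_slds(simulation_spec(list(s1, s2), schedule = z, dt = DT22,
                                seed = seed))
}

# dense joint-Gaussian construction of the state-space model on a short
# trajectory: r_1 ~ N(m0, P0), r_{i+1} = mu + F r_i + eta, psi_i = r_i + eps.
# Returns the mean/covariance of the stacked (r, psi) vector.
joint_gaussian_model <- function(T, mu, F, Sigma, R, m0, P0) {
  d <- length(mu)
  # moments of r
  means <- matrix(0, T, d)
  means[1, ] <- m0
  for (i in 2:T) means[i, ] <- mu + F %*% means[i - 1, ]
  # cov blocks of r: C[i,j] built recursively
  C <- array(0, c(T, T, d, d))
  C[1, 1, , ] <- P0
  for (i in 2:T) {
    C[i, i, , ] <- F %*% C[i - 1, i - 1, , ] %*% t(F) + Sigma
    for (j in 1:(i - 1)) {
      C[i, j, , ] <- F %*% C[i - 1, j, , ]
      C[j, i, , ] <- t(C[i, j, , ])
    }
  }
  big <- function(arr) {
    M <- matrix(0, T * d, T * d)
    for (i in 1:T) for (j in 1:T)
      M[(i - 1) * d + 1:d, (j - 1) * d + 1:d] <- arr[i, j, , ]
    M
  }
  Sr <- big(C)
  Spsi <- Sr + kronecker(diag(T), R)
  list(mean = as.numeric(t(means)), cov_r = Sr, cov_psi = Spsi)
}

log_dmvnorm <- function(x, mean, cov) {
  d <- length(x)
  L <- chol(cov)
  w <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(w^2)
}

# conditional distribution of a Gaussian subvector given another
gaussian_conditional <- function(mean, cov, idx_keep, idx_given, x_given) {
  S11 <- cov[idx_keep, idx_keep, drop = FALSE]
  S12 <- cov[idx_keep, idx_given, drop = FALSE]
  S22 <- cov[idx_given, idx_given, drop = FALSE]
  W <- S12 %*% solve(S22)
  list(mean = mean[idx_keep] + as.numeric(W %*% (x_given - mean[idx_given])),
       cov = S11 - W %*% t(S12))
}
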