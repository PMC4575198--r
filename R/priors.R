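# Conjugate priors for the per-state dynamics and the measurement noise.

#' Matrix-normal inverse-Wishart prior for SLDS dynamics
#'
#' Prior over one state's transition regression `r_{i+1} = [F mu] [r_i; 1] +
#' eta`: `Sigma ~ IW(S0, n0)` and `[F mu] | Sigma ~ MN(M0, Sigma, V0)`
#' (row covariance `Sigma`, column covariance `V0`).  The global measurement
#' noise carries an independent inverse-Wishart prior `R ~ IW(Psi0, nu0)`.
#'
#' @param M0 d x (d+1) prior mean of `[F mu]`.
#' @param V0 (d+1) x (d+1) SPD column covariance.
#' @param S0 d x d SPD inverse-Wishart scale for Sigma.
#' @param n0 inverse-Wishart degrees of freedom for Sigma (> d + 1).
#' @param Psi0 d x d SPD inverse-Wishart scale for R.
#' @param nu0 degrees of freedom for R (> d + 1).
#' @return An object of class `dynamics_prior`.
#' @export
dynamics_prior <- function(M0, V0, S0, n0, Psi0, nu0) {
  M0 <- as.matrix(M0); V0 <- as.matrix(V0); S0 <- as.matrix(S0)
  Psi0 <- as.matrix(Psi0)
  d <- nrow(M0)
  stopifnot(ncol(M0) == d + 1, all(dim(V0) == d + 1), all(dim(S0) == d),
            all(dim(Psi0) == d))
  for (nm in c("V0", "S0", "Psi0")) {
    m <- get(nm)
    ev <- eigen(0.5 * (m + t(m)), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(nm, " must be symmetric positive definite")
  }
  if (n0 <= d + 1) stop("n0 must exceed d + 1")
  if (nu0 <= d + 1) stop("nu0 must exceed d + 1")
  structure(list(M0 = M0, V0 = V0, S0 = S0, n0 = n0, Psi0 = Psi0, nu0 = nu0),
            class = "dynamics_prior")
}

#' @export
print.dynamics_prior <- function(x, ...) {
  d <- nrow(x$M0)
  cat("MNIW dynamics prior (d =", d, ")\n")
  cat("  E[Sigma] diag (um^2):",
      format(diag(x$S0) / (x$n0 - d - 1), digits = 4), " (n0 =", x$n0, ")\n")
  cat("  E[R] diag (um^2)    :",
      format(diag(x$Psi0) / (x$nu0 - d - 1), digits = 4), " (nu0 =", x$nu0, ")\n")
  invisible(x)
}

#' Default data-scaled dynamics prior
#'
#' Random-walk-centered prior: `M0 = [I 0]`, `V0 = diag(1, ..., 1, L^2)`
#' with `L` the trajectory's spatial extent (so the drift offset's prior
#' scale tracks the explored region), `S0` set so the prior mean of Sigma is
#' `2 D_pilot dt I`, and `Psi0` set so the prior mean of R is `sigma^2 I`.
#' `sigma` defaults to 40 nm, a typical effective localization error for
#' fluorophore-tagged SPT at video rate.  When `D_pilot` is not supplied, a
#' crude moment pilot is used: per-coordinate increment variance minus twice
#' the measurement variance, divided by `2 dt`.
#'
#' @param traj an `spt_trajectory` used to scale `V0` and the pilot `D`.
#' @param sigma prior measurement-noise standard deviation, micrometres.
#' @param D_pilot pilot diffusion coefficient, micrometres^2/second.
#' @param n0,nu0 inverse-Wishart degrees of freedom.  The defaults (`d + 2`)
#'   are weakly informative; pass a large `nu0` to pin the measurement noise
#'   near its prior mean, mimicking a nominally known localization error.
#' @return A `dynamics_prior`.
#' @export
default_dynamics_prior <- function(traj, sigma = 0.040, D_pilot = NULL,
                                   n0 = NULL, nu0 = NULL) {
  traj <- as_trajectory(traj)
  d <- n_dims(traj)
  if (is.null(n0)) n0 <- d + 2
  if (is.null(nu0)) nu0 <- d + 2
  L <- max(apply(traj$positions, 2, function(x) diff(range(x))), 1e-3)
  if (is.null(D_pilot)) {
    v <- mean(apply(diff(traj$positions), 2, var))
    D_pilot <- max((v - 2 * sigma^2) / (2 * traj$dt), 1e-4)
  }
  dynamics_prior(M0 = cbind(diag(d), rep(0, d)),
                 V0 = diag(c(rep(1, d), L^2)),
                 S0 = (n0 - d - 1) * 2 * D_pilot * traj$dt * diag(d),
                 n0 = n0,
                 Psi0 = (nu0 - d - 1) * sigma^2 * diag(d),
                 nu0 = nu0)
}

# ---- internal conjugate draws --------------------------------------------

# Inverse-Wishart draw via rWishart on the inverted scale.
riwish <- function(S, nu) {
  d <- nrow(S)
  Sinv <- tryCatch(solve(S), error = function(e) solve(S + 1e-10 * diag(d)))
  W <- rWishart(1, nu, 0.5 * (Sinv + t(Sinv)))[, , 1]
  V <- solve(W)
  0.5 * (V + t(V))
}

# One draw of ([F mu], Sigma) from an MNIW distribution.
rmniw <- function(M, V, S, n) {
  d <- nrow(M)
  Sigma <- riwish(S, n)
  Z <- matrix(rnorm(d * (d + 1)), d, d + 1)
  A <- M + t(chol(Sigma)) %*% Z %*% chol(0.5 * (V + t(V)))
  list(A = A, Sigma = Sigma)
}

draw_state_from_prior <- function(prior) {
  dr <- rmniw(prior$M0, prior$V0, prior$S0, prior$n0)
  d <- nrow(prior$M0)
  state_params(mu = dr$A[, d + 1], F = dr$A[, seq_len(d), drop = FALSE],
               Sigma = dr$Sigma)
}
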