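#' Default thermal energy
#'
#' k_B x 297.15 K (24 degrees C, the growth temperature of the yeast
#' experiments this pipeline targets) in piconewton-micrometres.
#' @export
KBT_DEFAULT <- 4.10e-3

#' Per-state discrete SLDS dynamics
#'
#' Parameters of one latent state's discrete-time model
#' \deqn{r_{i+1} = \mu + F r_i + \eta_i, \quad \eta_i \sim N(0, \Sigma)}
#' \deqn{\psi_i = r_i + \epsilon_i, \quad \epsilon_i \sim N(0, R)}
#' with positions in micrometres.
#'
#' @param mu drift offset per frame (micrometres), length-d vector.
#' @param F d x d dimensionless autoregression matrix.
#' @param Sigma d x d symmetric positive-definite process-noise covariance
#'   (micrometres^2 per frame).
#' @param R d x d symmetric positive-semidefinite effective measurement-noise
#'   covariance (micrometres^2); may be NULL when the state is used only for
#'   latent dynamics (a shared global R is common during Gibbs sampling).
#' @return An object of class `slds_state`.
#' @export
state_params <- function(mu, F, Sigma, R = NULL) {
  mu <- as.numeric(mu)
  F <- as.matrix(F); Sigma <- as.matrix(Sigma)
  d <- length(mu)
  stopifnot(all(dim(F) == d), all(dim(Sigma) == d))
  if (!all(is.finite(mu), is.finite(F), is.finite(Sigma)))
    stop("non-finite state parameters")
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma))))
    stop("Sigma must be symmetric")
  ev <- eigen(0.5 * (Sigma + t(Sigma)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite (min eigenvalue ",
                         format(min(ev)), ")")
  if (!is.null(R)) {
    R <- as.matrix(R)
    stopifnot(all(dim(R) == d))
    evR <- eigen(0.5 * (R + t(R)), symmetric = TRUE, only.values = TRUE)$values
    if (min(evR) < -1e-12) stop("R must be positive semidefinite")
  }
  structure(list(mu = mu, F = F, Sigma = 0.5 * (Sigma + t(Sigma)), R = R),
            class = "slds_state")
}

#' @export
print.slds_state <- function(x, ...) {
  cat("SLDS state parameters (d =", length(x$mu), ")\n")
  cat("  mu    :", format(x$mu, digits = 4), "\n")
  cat("  F     :", paste(format(t(x$F), digits = 4), collapse = " "), "\n")
  cat("  Sigma :", paste(format(t(x$Sigma), digits = 4), collapse = " "), "\n")
  if (!is.null(x$R))
    cat("  R     :", paste(format(t(x$R), digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Continuous-time overdamped Langevin parameters
#'
#' Parameters of the linear stochastic differential equation
#' \deqn{dr_t = (A + B r_t)\,dt + \sqrt{2D}\,dB_t}
#' interpreted through the overdamped Langevin model: the drift equals
#' mobility times force, with mobility given by the Einstein relation
#' \eqn{\gamma^{-1} = D / k_B T}.
#'
#' @param A constant drift, micrometres/second (length-d).
#' @param B d x d linear drift ("restoring force") matrix, 1/second.
#' @param D d x d symmetric positive-semidefinite diffusion matrix,
#'   micrometres^2/second (positive definite for any state with thermal
#'   motion; a numerically zero D encodes the photobleached/static regime,
#'   in which [force_at()] refuses to evaluate).
#' @param kBT thermal energy in piconewton-micrometres.
#' @return An object of class `langevin_params`.
#' @export
continuous_params <- function(A, B, D, kBT = KBT_DEFAULT) {
  A <- as.numeric(A); B <- as.matrix(B); D <- as.matrix(D)
  d <- length(A)
  stopifnot(all(dim(B) == d), all(dim(D) == d))
  if (!all(is.finite(A), is.finite(B), is.finite(D), is.finite(kBT)))
    stop("non-finite continuous parameters")
  if (kBT <= 0) stop("kBT must be positive")
  D <- 0.5 * (D + t(D))
  e <- eigen(D, symmetric = TRUE)
  scale <- max(abs(e$values), 1e-300)
  # negatives below the zero-diffusion resolution (1e-6 um^2/s) are
  # numerical noise from the ill-conditioned embedding solve near Sigma = 0
  if (min(e$values) < -max(1e-8 * scale, 1e-6))
    stop("D must be positive semidefinite (min eigenvalue ",
         format(min(e$values)), ")")
  if (min(e$values) < 0)  # clamp numerically negative eigenvalues to zero
    D <- e$vectors %*% diag(pmax(e$values, 0), d) %*% t(e$vectors)
  structure(list(A = A, B = B, D = D, kBT = kBT),
            class = "langevin_params")
}

#' @export
print.langevin_params <- function(x, ...) {
  cat("Overdamped Langevin parameters (d =", length(x$A), ")\n")
  cat("  A (um/s)  :", format(x$A, digits = 4), "\n")
  cat("  B (1/s)   :", paste(format(t(x$B), digits = 4), collapse = " "), "\n")
  cat("  D (um2/s) :", paste(format(t(x$D), digits = 4), collapse = " "), "\n")
  cat("  kBT (pN um):", format(x$kBT, digits = 4), "\n")
  invisible(x)
}

#' Exact discretization of the linear SDE
#'
#' Maps continuous parameters (A, B, D) to the per-frame discrete dynamics
#' over an interval `dt`:
#' \deqn{F = e^{B\,dt},\qquad \mu = \Big(\int_0^{dt} e^{Bs} ds\Big) A,
#'   \qquad \Sigma = \int_0^{dt} e^{Bs} (2D) e^{B^T s} ds.}
#' The drift integral and covariance integral are evaluated with augmented
#' (Van Loan) matrix exponentials, so no invertibility of B is required.
#'
#' @param cont a `langevin_params` object.
#' @param dt frame interval in seconds.
#' @return An `slds_state` with `R = NULL` (measurement noise is not part of
#'   the latent dynamics).
#' @export
discrete_from_continuous <- function(cont, dt) {
  stopifnot(inherits(cont, "langevin_params"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number of seconds")
  B <- cont$B; d <- nrow(B)
  F <- cpp_expmat(B * dt)
  # drift integral J = int_0^dt e^{Bs} ds via [[B, I], [0, 0]]
  Mdrift <- rbind(cbind(B, diag(d)), matrix(0, d, 2 * d))
  Ed <- cpp_expmat(Mdrift * dt)
  J <- Ed[seq_len(d), d + seq_len(d), drop = FALSE]
  mu <- as.numeric(J %*% cont$A)
  # Van Loan block for Sigma = int_0^dt e^{Bs} (2D) e^{B's} ds
  Q <- 2 * cont$D
  Mcov <- rbind(cbind(-B, Q), cbind(matrix(0, d, d), t(B)))
  Ec <- cpp_expmat(Mcov * dt)
  E12 <- Ec[seq_len(d), d + seq_len(d), drop = FALSE]
  E22 <- Ec[d + seq_len(d), d + seq_len(d), drop = FALSE]
  Sigma <- t(E22) %*% E12
  Sigma <- 0.5 * (Sigma + t(Sigma))
  state_params(mu = mu, F = F, Sigma = Sigma, R = NULL)
}

#' Embed discrete SLDS dynamics in a continuous linear SDE
#'
#' Inverts [discrete_from_continuous()]: B is the principal matrix logarithm
#' of F divided by `dt`; A inverts the drift integral; D solves the linear
#' (vectorized) Lyapunov-type system implied by the covariance integral.
#' Near the identity (`norm(F - I) < tol`) the small-`dt` limits
#' `B = (F - I)/dt`, `A = mu/dt`, `D = Sigma/(2 dt)` are used.
#'
#' @param disc an `slds_state`.
#' @param dt frame interval in seconds.
#' @param kBT thermal energy attached to the result.
#' @param tol near-identity threshold on the Frobenius norm of `F - I`.
#' @return A `langevin_params` object.
#' @export
continuous_from_discrete <- function(disc, dt, kBT = KBT_DEFAULT, tol = 1e-6) {
  stopifnot(inherits(disc, "slds_state"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number of seconds")
  F <- disc$F; d <- nrow(F)
  ev <- eigen(F, only.values = TRUE)$values
  bad <- which(Re(ev) <= 0 & abs(Im(ev)) < 1e-12)
  if (length(bad))
    stop("F is not embeddable: eigenvalue ", format(ev[bad[1]]),
         " lies on the closed negative real axis (principal logarithm undefined)")
  if (norm(F - diag(d), "F") < tol) {
    B <- (F - diag(d)) / dt
    A <- disc$mu / dt
    D <- disc$Sigma / (2 * dt)
    return(continuous_params(A = A, B = B, D = D, kBT = kBT))
  }
  lg <- cpp_logmat(F)
  if (lg$imnorm > 1e-8 * max(1, norm(F, "F")))
    stop("principal matrix logarithm of F is not real (imaginary norm ",
         format(lg$imnorm), ")")
  B <- lg$real / dt
  Mdrift <- rbind(cbind(B, diag(d)), matrix(0, d, 2 * d))
  J <- cpp_expmat(Mdrift * dt)[seq_len(d), d + seq_len(d), drop = FALSE]
  A <- as.numeric(solve(J, disc$mu))
  # d(Sigma)/d(dt) identity: B Sigma + Sigma B' = F (2D) F' - 2D,
  # rearranged as a linear system for vec(2D).
  rhs <- B %*% disc$Sigma + disc$Sigma %*% t(B)
  Kmat <- kronecker(F, F) - diag(d * d)
  twoD <- matrix(solve(Kmat, as.numeric(rhs)), d, d)
  D <- 0.25 * (twoD + t(twoD))
  continuous_params(A = A, B = B, D = D, kBT = kBT)
}

#' Instantaneous effective force at a position
#'
#' Under the overdamped Langevin model with Einstein mobility
#' \eqn{\gamma^{-1} = D/k_BT}, the drift `A + B r` equals
#' \eqn{\gamma^{-1} f(r)}, so
#' \deqn{f(r) = k_B T\, D^{-1} (A + B r).}
#' Units: piconewtons when kBT is in pN um, D in um^2/s, A in um/s and B in
#' 1/s.
#'
#' @param cont a `langevin_params` object.
#' @param r position vector (micrometres).
#' @return Force vector in piconewtons.
#' @export
force_at <- function(cont, r) {
  stopifnot(inherits(cont, "langevin_params"))
  r <- as.numeric(r)
  rc <- rcond(cont$D)
  if (!is.finite(rc) || rc < 1e-12)
    stop("singular diffusion matrix: force is undefined in the zero-diffusion ",
         "(e.g. photobleached) regime")
  as.numeric(cont$kBT * solve(cont$D, cont$A + cont$B %*% r))
}

#' Stationary mean and covariance of a stable discrete state
#'
#' For spectral radius of F below 1: mean = (I - F)^{-1} mu and the
#' covariance solves the discrete Lyapunov equation P = F P F' + Sigma.
#'
#' @param disc an `slds_state`.
#' @return List with `mean` and `cov`.
#' @export
stationary_moments <- function(disc) {
  stopifnot(inherits(disc, "slds_state"))
  F <- disc$F; d <- nrow(F)
  rho <- max(Mod(eigen(F, only.values = TRUE)$values))
  if (rho >= 1)
    stop("state is non-stationary (spectral radius of F = ", format(rho), " >= 1)")
  m <- as.numeric(solve(diag(d) - F, disc$mu))
  P <- matrix(solve(diag(d * d) - kronecker(F, F), as.numeric(disc$Sigma)), d, d)
  list(mean = m, cov = 0.5 * (P + t(P)))
}
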