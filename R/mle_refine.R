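# Prior-free maximum-likelihood refinement of per-segment dynamics, and
# windowed pilot estimation used for data-driven prior tuning.
#
# The likelihood is the exact Kalman-filter likelihood of the linear
# state-space model; Sigma is parameterized by its Cholesky factor (log
# diagonal) and R is restricted to a diagonal with log-parameterized
# entries, so the optimizer works on an unconstrained scale.

LOGD_MIN <- -20  # lower bound on log Cholesky/R diagonals (allows D ~ 0)
LOGD_MAX <- 5

subset_trajectory <- function(traj, idx) {
  trajectory(traj$positions[idx, , drop = FALSE], dt = traj$dt,
             label = traj$label)
}

# F is parameterized through its matrix logarithm, F = expm(G dt) with G
# free: every candidate stays embeddable in a continuous linear SDE (the
# model family the estimates are interpreted in), and the noise-chasing
# optima with negative/complex F eigenvalues that plague degenerate
# (zero-diffusion) data are excluded by construction.
pack_theta <- function(state, dt) {
  d <- length(state$mu)
  lg <- cpp_logmat(state$F)
  if (lg$imnorm > 1e-8)
    stop("MLE initialization requires an embeddable F (principal log real)")
  L <- t(chol(state$Sigma))
  ltri <- which(lower.tri(L))
  c(state$mu, as.numeric(lg$real / dt),
    log(pmax(diag(L), exp(LOGD_MIN))), L[ltri],
    log(pmax(diag(state$R), exp(LOGD_MIN))))
}

unpack_theta <- function(par, d, dt) {
  mu <- par[seq_len(d)]
  G <- matrix(par[d + seq_len(d * d)], d, d)
  F <- cpp_expmat(G * dt)
  off <- d + d * d
  L <- diag(exp(par[off + seq_len(d)]), d)
  nlow <- d * (d - 1) / 2
  if (nlow > 0) L[lower.tri(L)] <- par[off + d + seq_len(nlow)]
  Sigma <- L %*% t(L)
  Rdiag <- exp(par[off + d + nlow + seq_len(d)])
  list(mu = mu, F = F, Sigma = Sigma, R = diag(Rdiag, d))
}

theta_par_bounds <- function(d, dt) {
  nlow <- d * (d - 1) / 2
  gmax <- 2 / dt  # |G| cap keeps expm well-scaled; generous vs. frame rate
  lower <- c(rep(-Inf, d), rep(-gmax, d * d), rep(LOGD_MIN, d),
             rep(-Inf, nlow), rep(LOGD_MIN, d))
  upper <- c(rep(Inf, d), rep(gmax, d * d), rep(LOGD_MAX, d),
             rep(Inf, nlow), rep(LOGD_MAX, d))
  list(lower = lower, upper = upper)
}

neg_loglik_par <- function(par, psi, d, dt) {
  th <- unpack_theta(par, d, dt)
  init_cov <- th$R + KAPPA0_INIT * diag(d)
  ll <- tryCatch(cpp_kalman_loglik_const(psi, th$mu, th$F, th$Sigma, th$R,
                                         psi[1, ], init_cov),
                 error = function(e) -Inf)
  if (!is.finite(ll)) return(1e12)
  -ll
}

# moment initialization: for diffusion + white localization noise the
# increment variance is Sigma + 2R and the lag-1 increment autocovariance
# is -R (per coordinate)
default_mle_init <- function(psi, d) {
  inc <- diff(psi)
  v <- pmax(apply(inc, 2, var), 1e-8)
  n <- nrow(inc)
  lag1 <- sapply(seq_len(d), function(j) mean(inc[-1, j] * inc[-n, j]))
  R0 <- pmin(pmax(-lag1, 1e-8), 0.9 * v / 2)
  S0 <- pmax(v - 2 * R0, 1e-8)
  state_params(mu = rep(0, d), F = diag(d), Sigma = diag(S0, d),
               R = diag(R0, d))
}

#' Fit one segment by maximum likelihood
#'
#' Maximizes the exact Kalman-filter log-likelihood over
#' `(mu, F, Sigma, R)` with multiple starting points (the supplied or
#' default moment-based initialization, a frozen-spot start covering the
#' zero-diffusion regime, plus random perturbations), returning the best
#' local optimum.  R is diagonal; Sigma is a full SPD matrix; F is
#' parameterized as `expm(G dt)` with G free, so every candidate embeds in
#' a continuous linear SDE and D, B, A are always recoverable via
#' [continuous_from_discrete()].
#'
#' @param traj_segment an `spt_trajectory` (a segment of a longer
#'   trajectory); at least `min_frames` frames.
#' @param init optional `slds_state` (with R) used as the first start.
#' @param n_starts number of optimizer starts (first is `init`).
#' @param min_frames minimum segment length.
#' @param control passed to [stats::optim()] (`L-BFGS-B`).
#' @return An `mle_fit`: `theta` (`slds_state` including its fitted
#'   diagonal R), `loglik`, `convergence` (TRUE when any start converged),
#'   `n_starts`, and `identifiability_warning` (TRUE when `F` is within
#'   0.02 of the identity, where diffusion and measurement noise are weakly
#'   separable).
#' @export
fit_segment_mle <- function(traj_segment, init = NULL, n_starts = 5,
                            min_frames = 20, control = list()) {
  traj_segment <- as_trajectory(traj_segment)
  psi <- traj_segment$positions
  d <- ncol(psi)
  if (nrow(psi) < min_frames)
    stop("segment has ", nrow(psi), " frames; at least ", min_frames, " required")
  dt <- traj_segment$dt
  if (is.null(init)) init <- default_mle_init(psi, d)
  if (is.null(init$R)) stop("init must carry a measurement-noise matrix R")
  par0 <- pack_theta(init, dt)
  # a "frozen spot" start (negligible process noise, all variance in R)
  # keeps the zero-diffusion / photobleached regime reachable
  par_frozen <- pack_theta(state_params(
    mu = rep(0, d), F = diag(d), Sigma = diag(exp(2 * LOGD_MIN), d),
    R = diag(pmax(apply(psi, 2, var), 1e-8), d)), dt)
  bounds <- theta_par_bounds(d, dt)
  # factr 4.5e7 ~ 1e-8 relative tolerance on the log-likelihood
  control <- modifyList(list(maxit = 400, factr = 4.5e7), control)
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    par <- par0
    if (s == 2) par <- par_frozen
    if (s > 2) {
      # perturb: small for mu, ~frame-rate scale for G, larger on the logs
      np <- length(par)
      dmu <- seq_len(d)
      dG <- d + seq_len(d * d)
      par[dmu] <- par[dmu] + rnorm(d, sd = 0.05)
      par[dG] <- par[dG] + rnorm(d * d, sd = 1)
      par[(d + d * d + 1):np] <- par[(d + d * d + 1):np] +
        rnorm(np - d - d * d, sd = 0.5)
      par <- pmin(pmax(par, bounds$lower), bounds$upper)
    }
    fit <- tryCatch(
      optim(par, neg_loglik_par, psi = psi, d = d, dt = dt,
            method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper, control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  th <- unpack_theta(best$par, d, dt)
  theta <- state_params(mu = th$mu, F = th$F, Sigma = th$Sigma, R = th$R)
  structure(list(theta = theta, loglik = -best$value,
                 convergence = any_conv, n_starts = n_starts,
                 identifiability_warning = norm(th$F - diag(d), "F") < 0.02,
                 dt = traj_segment$dt, n = nrow(psi)),
            class = "mle_fit")
}

#' @export
print.mle_fit <- function(x, ...) {
  d <- length(x$theta$mu)
  cont <- tryCatch(continuous_from_discrete(x$theta, x$dt),
                   error = function(e) NULL)
  cat(sprintf("Segment MLE (%d frames): log-likelihood %.3f%s\n", x$n,
              x$loglik, if (x$convergence) "" else " [not converged]"))
  cat("  R^ diag (nm):",
      format(1e3 * sqrt(diag(x$theta$R)), digits = 4), "\n")
  if (!is.null(cont))
    cat("  D^ diag (um^2/s):", format(diag(cont$D), digits = 4), "\n")
  if (x$identifiability_warning)
    cat("  note: F is near identity; D and R are weakly identified\n")
  invisible(x)
}

#' Windowed local maximum-likelihood estimation
#'
#' Independent [fit_segment_mle()] fits on sliding windows; used as a pilot
#' pass to expose slow trends in measurement noise and diffusion, and to
#' supply data-driven prior hyperparameters ([tune_priors_from_pilot()]).
#'
#' @param traj an `spt_trajectory`.
#' @param window window length in frames.
#' @param stride window offset in frames.
#' @param ... passed to [fit_segment_mle()].
#' @return List of class `windowed_mle`: `fits` (list of `mle_fit`),
#'   `centers` (window center frames), `starts`.
#' @export
windowed_mle <- function(traj, window = 100, stride = 50, ...) {
  traj <- as_trajectory(traj)
  T_ <- n_frames(traj)
  if (window > T_) stop("window (", window, ") exceeds trajectory length (", T_, ")")
  starts <- seq(1, T_ - window + 1, by = stride)
  fits <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window - 1)
    fits[[i]] <- fit_segment_mle(subset_trajectory(traj, idx), ...)
  }
  structure(list(fits = fits, centers = starts + (window - 1) / 2,
                 starts = starts, window = window),
            class = "windowed_mle")
}

#' Tune prior hyperparameters from pilot fits
#'
#' Sets the inverse-Wishart prior mean of R to the elementwise median of the
#' pilot estimates of R, and the prior mean of Sigma to the elementwise
#' median of the pilot estimates of Sigma.  The regression prior (`M0`,
#' `V0`) keeps the random-walk-centered defaults.  The median (rather than
#' the mean) is used for robustness against occasional degenerate windows.
#'
#' @param pilot a `windowed_mle` result or list of `mle_fit` objects.
#' @param traj the trajectory the prior will be applied to (scales `V0`).
#' @param n0,nu0 degrees of freedom of the returned prior (defaults `d+2`).
#' @return A [dynamics_prior()].
#' @export
tune_priors_from_pilot <- function(pilot, traj, n0 = NULL, nu0 = NULL) {
  fits <- if (inherits(pilot, "windowed_mle")) pilot$fits else pilot
  stopifnot(length(fits) >= 1)
  traj <- as_trajectory(traj)
  d <- length(fits[[1]]$theta$mu)
  if (is.null(n0)) n0 <- d + 2
  if (is.null(nu0)) nu0 <- d + 2
  Rmed <- apply(vapply(fits, function(f) f$theta$R, matrix(0, d, d)),
                c(1, 2), median)
  Smed <- apply(vapply(fits, function(f) f$theta$Sigma, matrix(0, d, d)),
                c(1, 2), median)
  # keep the scales strictly positive definite
  Rmed <- Rmed + 1e-12 * diag(d)
  Smed <- Smed + 1e-12 * diag(d)
  L <- max(apply(traj$positions, 2, function(x) diff(range(x))), 1e-3)
  dynamics_prior(M0 = cbind(diag(d), rep(0, d)),
                 V0 = diag(c(rep(1, d), L^2)),
                 S0 = (n0 - d - 1) * Smed, n0 = n0,
                 Psi0 = (nu0 - d - 1) * Rmed, nu0 = nu0)
}
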