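# Switching-SLDS trajectory simulator and segmentation scoring metrics.

#' Specify a switching-SLDS simulation
#'
#' Collects everything needed to generate a labeled trajectory: per-state
#' dynamics, a state schedule, frame count/interval, and optional measurement
#' artifacts mimicking common SPT defects (a linear localization-noise ramp,
#' and large periodic outlier frames such as fluorescent background flashes).
#'
#' @param states list of [state_params()] objects (R required per state
#'   unless a noise ramp overrides it).
#' @param schedule either an integer vector of per-frame state labels
#'   (length T) or a list `list(P = transition matrix, init = initial
#'   distribution)` describing a Markov chain over states.
#' @param T number of frames (required for Markov schedules; inferred from
#'   explicit label schedules).
#' @param dt frame interval, seconds.
#' @param noise_ramp optional `c(sigma_start, sigma_end)` in micrometres: the
#'   per-frame measurement noise is isotropic with standard deviation ramping
#'   linearly across frames, replacing the per-state R.
#' @param outliers optional `list(period =, displacement =)`: every
#'   `period`-th frame the observation (not the latent path) is displaced by
#'   `displacement` micrometres along +x.  Defaults inside the list: period
#'   50 frames, displacement 0.2 um.
#' @param seed integer seed making the simulation reproducible.
#' @return A validated list of class `sim_spec`.
#' @export
simulation_spec <- function(states, schedule, T = NULL, dt = 1 / 22,
                            noise_ramp = NULL, outliers = NULL, seed = 1L) {
  stopifnot(is.list(states), length(states) >= 1)
  for (s in states) stopifnot(inherits(s, "slds_state"))
  if (is.numeric(schedule) && !is.list(schedule)) {
    schedule <- as.integer(schedule)
    if (is.null(T)) T <- length(schedule)
    if (length(schedule) != T) stop("explicit schedule must have length T")
    if (any(schedule < 1L | schedule > length(states)))
      stop("schedule references undefined states")
  } else if (is.list(schedule)) {
    P <- as.matrix(schedule$P)
    K <- length(states)
    stopifnot(all(dim(P) == K), all(P >= 0), max(abs(rowSums(P) - 1)) < 1e-8)
    if (is.null(schedule$init)) schedule$init <- rep(1 / K, K)
    if (is.null(T)) stop("T is required for a Markov schedule")
  } else stop("schedule must be a label vector or list(P =, init =)")
  if (T < 2) stop("T must be at least 2")
  if (!is.null(noise_ramp)) {
    stopifnot(length(noise_ramp) == 2, all(noise_ramp >= 0))
  }
  if (!is.null(outliers)) {
    outliers <- modifyList(list(period = 50L, displacement = 0.2), outliers)
    stopifnot(outliers$period >= 2, is.finite(outliers$displacement))
  }
  structure(list(states = states, schedule = schedule, T = as.integer(T),
                 dt = dt, noise_ramp = noise_ramp, outliers = outliers,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a labeled switching-SLDS trajectory
#'
#' The latent path starts from the first state's stationary distribution
#' (or the origin if that state is non-stationary) and evolves as
#' `r_{i+1} = mu_z + F_z r_i + eta_i` with the state labels of the schedule
#' (label of the source frame governs each transition).  Observations add
#' per-frame Gaussian measurement noise from the state's R, or from the
#' linear noise ramp when one is specified; outlier frames displace the
#' observation only.
#'
#' @param spec a [simulation_spec()].
#' @return A `labeled_trajectory`: list with `trajectory`
#'   (`spt_trajectory`), `true_states` (length-T labels) and `true_path`
#'   (T x d latent positions).
#' @export
simulate_slds <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  T_ <- spec$T
  d <- length(spec$states[[1]]$mu)
  # state sequence
  if (is.list(spec$schedule)) {
    K <- length(spec$states)
    z <- integer(T_)
    z[1] <- sample.int(K, 1, prob = spec$schedule$init)
    for (i in 2:T_) z[i] <- sample.int(K, 1, prob = spec$schedule$P[z[i - 1], ])
  } else z <- spec$schedule
  # latent path
  r <- matrix(0, T_, d)
  s1 <- spec$states[[z[1]]]
  rho <- max(Mod(eigen(s1$F, only.values = TRUE)$values))
  if (rho < 1) {
    sm <- stationary_moments(s1)
    r[1, ] <- sm$mean + drop(crossprod(chol(sm$cov), rnorm(d)))
  }
  chols <- lapply(spec$states, function(s) chol(s$Sigma))
  for (i in seq_len(T_ - 1)) {
    s <- spec$states[[z[i]]]
    r[i + 1, ] <- s$mu + s$F %*% r[i, ] + drop(crossprod(chols[[z[i]]], rnorm(d)))
  }
  # measurement noise
  psi <- r
  if (!is.null(spec$noise_ramp)) {
    sig <- seq(spec$noise_ramp[1], spec$noise_ramp[2], length.out = T_)
    psi <- psi + matrix(rnorm(T_ * d), T_, d) * sig
  } else {
    for (i in seq_len(T_)) {
      Rk <- spec$states[[z[i]]]$R
      if (is.null(Rk)) stop("state ", z[i], " has no R and no noise ramp is set")
      if (max(abs(Rk)) > 0)
        psi[i, ] <- psi[i, ] + drop(crossprod(chol(Rk + 1e-300 * diag(d)), rnorm(d)))
    }
  }
  if (!is.null(spec$outliers)) {
    idx <- seq(spec$outliers$period, T_, by = spec$outliers$period)
    psi[idx, 1] <- psi[idx, 1] + spec$outliers$displacement
  }
  structure(list(trajectory = trajectory(psi, dt = spec$dt, label = "simulated"),
                 true_states = z, true_path = r),
            class = "labeled_trajectory")
}

#' @export
print.labeled_trajectory <- function(x, ...) {
  cat(sprintf("Labeled SLDS trajectory: %d frames, %d distinct true states\n",
              length(x$true_states), length(unique(x$true_states))))
  invisible(x)
}

# ---- label matching -------------------------------------------------------

# Hungarian algorithm (shortest augmenting paths with potentials) for a
# square cost matrix; returns the column assigned to each row.  Small inputs
# only (state counts), so an R implementation is ample.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Hamming distance between state sequences under optimal relabeling
#'
#' MCMC state labels are arbitrary, so the mismatch fraction is minimized
#' over injective relabelings of the estimated sequence: an optimal
#' assignment is computed on the label confusion matrix (unmatched estimated
#' labels count all their frames as errors).
#'
#' @param z_true,z_est equal-length label vectors (any integer coding).
#' @return Mismatch fraction in [0, 1].
#' @export
hamming_distance <- function(z_true, z_est) {
  if (length(z_true) != length(z_est))
    stop("state sequences have different lengths")
  T_ <- length(z_true)
  lt <- sort(unique(z_true)); le <- sort(unique(z_est))
  C <- table(factor(z_true, levels = lt), factor(z_est, levels = le))
  C <- matrix(as.numeric(C), length(lt), length(le))
  n <- max(dim(C))
  Cp <- matrix(0, n, n)
  Cp[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  assign <- solve_assignment(max(Cp) - Cp)   # maximize matches
  matched <- sum(Cp[cbind(seq_len(n), assign)])
  1 - matched / T_
}

#' Score estimated change points against truth
#'
#' Greedy nearest-neighbour matching of estimated to true change points
#' within a tolerance window.
#'
#' @param true_cp,est_cp sorted integer frame indices.
#' @param tol matching window in frames.
#' @return List with `matched`, `misses`, `false_alarms` counts and the
#'   matched pairs.
#' @export
changepoint_error <- function(true_cp, est_cp, tol = 10) {
  true_cp <- sort(as.numeric(true_cp)); est_cp <- sort(as.numeric(est_cp))
  used <- rep(FALSE, length(est_cp))
  pairs <- NULL
  for (cp in true_cp) {
    if (!length(est_cp)) break
    dists <- abs(est_cp - cp)
    dists[used] <- Inf
    j <- which.min(dists)
    if (length(j) && is.finite(dists[j]) && dists[j] <= tol) {
      used[j] <- TRUE
      pairs <- rbind(pairs, c(true = cp, est = est_cp[j]))
    }
  }
  matched <- sum(used)
  list(matched = matched,
       misses = length(true_cp) - matched,
       false_alarms = length(est_cp) - matched,
       pairs = pairs)
}
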