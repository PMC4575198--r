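# Truncated ("weak limit") sticky-HDP blocked Gibbs sampler for the SLDS.
#
# The hierarchical Dirichlet process couples the K rows of the transition
# matrix through global weights beta; the sticky mass kappa adds prior
# weight to self-transitions, encouraging temporally persistent states.
# Label z_i governs the transition from frame i to i+1 (source-frame
# convention); z_1 is drawn against the global weights.

#' Sampler configuration for the sticky-HDP SLDS
#'
#' @param K truncation level of the weak-limit approximation (number of
#'   candidate states made available to the sampler).
#' @param gamma_conc top-level Dirichlet process concentration.
#' @param alpha_conc per-row concentration.
#' @param kappa sticky self-transition mass (0 disables stickiness).
#' @param n_iter number of Gibbs sweeps.
#' @param burn_in fraction of sweeps discarded before summaries.
#' @param seed integer seed.
#' @param store_paths store the sampled latent paths (off by default to
#'   bound memory).
#' @param verbose print progress every 500 sweeps.
#' @return List of class `sticky_hdp_config`.
#' @export
sticky_hdp_config <- function(K = 10, gamma_conc = 1, alpha_conc = 1,
                              kappa = 50, n_iter = 10000, burn_in = 0.1,
                              seed = 1L, store_paths = FALSE, verbose = FALSE) {
  stopifnot(K >= 2, gamma_conc > 0, alpha_conc > 0, kappa >= 0,
            n_iter >= 1, burn_in >= 0, burn_in < 1)
  structure(list(K = as.integer(K), gamma_conc = gamma_conc,
                 alpha_conc = alpha_conc, kappa = kappa,
                 n_iter = as.integer(n_iter), burn_in = burn_in,
                 seed = as.integer(seed), store_paths = isTRUE(store_paths),
                 verbose = isTRUE(verbose)),
            class = "sticky_hdp_config")
}

#' Sample the state sequence given a latent path
#'
#' Exact joint draw of `z_{1:T}` by backward message passing with transition
#' likelihoods `N(r_{i+1}; mu_k + F_k r_i, Sigma_k)` and forward sampling.
#' The first label is weighted by the global HDP weights `beta`; the last
#' label carries no emission term.  Computations are in the log domain.
#'
#' @param path T x d latent path (micrometres).
#' @param theta_list list of K `slds_state` objects (inactive states carry
#'   prior draws).
#' @param pi K x K row-stochastic transition matrix.
#' @param beta global weight vector (K-simplex).
#' @return Integer labels in 1..K.
#' @export
sample_state_sequence <- function(path, theta_list, pi, beta) {
  path <- as.matrix(path)
  K <- length(theta_list); d <- ncol(path)
  mu_k <- t(vapply(theta_list, function(s) s$mu, numeric(d)))
  F_k <- array(0, c(d, d, K)); Sig_k <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    F_k[, , k] <- theta_list[[k]]$F
    Sig_k[, , k] <- theta_list[[k]]$Sigma
  }
  as.integer(cpp_sample_z(path, mu_k, F_k, Sig_k,
                          log(pmax(pi, 1e-300)), log(pmax(beta, 1e-300))))
}

#' Sample per-state dynamics from the conjugate MNIW posterior
#'
#' For each state k the transition pairs `{(r_i, r_{i+1}) : z_i = k}` update
#' the matrix-normal inverse-Wishart prior on `([F mu], Sigma)`; states with
#' no assigned transitions draw from the prior.
#'
#' @param path T x d latent path.
#' @param labels integer state labels in 1..K (length T).
#' @param prior a [dynamics_prior()].
#' @param K number of states (defaults to `max(labels)`).
#' @return List of K `slds_state` objects (R = NULL).
#' @export
sample_emission_params <- function(path, labels, prior, K = max(labels)) {
  path <- as.matrix(path)
  d <- ncol(path)
  ss <- cpp_state_suffstats(path, as.integer(labels), as.integer(K))
  out <- vector("list", K)
  for (k in seq_len(K)) {
    if (ss$n[k] == 0) {
      out[[k]] <- draw_state_from_prior(prior)
      next
    }
    pp <- mniw_posterior_params(ss$Sxx[, , k], ss$Sxy[, , k], ss$Syy[, , k],
                                ss$n[k], prior)
    dr <- rmniw(pp$Mn, pp$Vn, pp$Sn, pp$nn)
    out[[k]] <- state_params(mu = dr$A[, d + 1],
                             F = dr$A[, seq_len(d), drop = FALSE],
                             Sigma = dr$Sigma)
  }
  out
}

# Conjugate MNIW posterior parameters from regression sufficient statistics
# (design rows x = [r_i; 1], responses y = r_{i+1}).
mniw_posterior_params <- function(Sxx, Sxy, Syy, n, prior) {
  d <- nrow(prior$M0)
  V0inv <- solve(prior$V0)
  M0V0inv <- prior$M0 %*% V0inv
  Vninv <- V0inv + Sxx
  Vn <- tryCatch(solve(Vninv), error = function(e)
    solve(Vninv + 1e-10 * diag(d + 1)))
  Vn <- 0.5 * (Vn + t(Vn))
  Mn <- (M0V0inv + t(Sxy)) %*% Vn
  Sn <- prior$S0 + M0V0inv %*% t(prior$M0) + Syy - Mn %*% Vninv %*% t(Mn)
  Sn <- 0.5 * (Sn + t(Sn))
  if (min(eigen(Sn, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    warning("jittering near-singular posterior scale")
    Sn <- Sn + 1e-10 * diag(d)
  }
  list(Mn = Mn, Vn = Vn, Sn = Sn, nn = prior$n0 + n)
}

#' Sample the global measurement-noise covariance
#'
#' Conjugate inverse-Wishart update from the measurement residuals
#' `e_i = psi_i - r_i`: one draw from `IW(Psi0 + sum e e', nu0 + T)`.  A
#' single global R is sampled per sweep; per-segment measurement noise is
#' recovered downstream by maximum likelihood.
#'
#' @param traj an `spt_trajectory` (or T x d observation matrix).
#' @param path T x d latent path (may have zero rows for a pure prior draw).
#' @param prior a [dynamics_prior()] (its `Psi0`, `nu0` fields are used).
#' @return d x d symmetric PSD draw.
#' @export
sample_measurement_noise <- function(traj, path, prior) {
  psi <- if (inherits(traj, "spt_trajectory")) traj$positions else as.matrix(traj)
  path <- as.matrix(path)
  if (nrow(path) == 0) return(riwish(prior$Psi0, prior$nu0))
  E <- psi - path
  riwish(prior$Psi0 + crossprod(E), prior$nu0 + nrow(E))
}

# Chinese-restaurant table counts for the weak-limit HDP update, with the
# sticky override correction of the self-transition tables.
sample_table_counts <- function(n_counts, beta, alpha_conc, kappa) {
  K <- length(beta)
  m <- matrix(0L, K, K)
  for (j in seq_len(K)) for (k in seq_len(K)) {
    n_jk <- n_counts[j, k]
    if (n_jk == 0) next
    a <- alpha_conc * beta[k] + if (j == k) kappa else 0
    i <- seq_len(n_jk)
    m[j, k] <- sum(runif(n_jk) < a / (i - 1 + a))
  }
  mbar <- m
  if (kappa > 0) {
    rho <- kappa / (alpha_conc + kappa)
    for (j in seq_len(K)) {
      if (m[j, j] > 0) {
        p_override <- rho / (rho + beta[j] * (1 - rho))
        mbar[j, j] <- m[j, j] - rbinom(1, m[j, j], p_override)
      }
    }
  }
  list(m = m, mbar = mbar)
}

#' Sample transition rows and global weights
#'
#' Each transition row is drawn from
#' `Dirichlet(alpha beta + kappa e_j + n_j.)` with `n_j.` the observed
#' transition counts out of state j.  The global weights `beta` are
#' resampled from `Dirichlet(gamma/K + mbar.1, ..., gamma/K + mbar.K)` where
#' the table counts `mbar` come from the standard Chinese-restaurant
#' auxiliary scheme with the sticky override correction (and the first label
#' contributes one count to its component, since `z_1 ~ beta`).
#'
#' @param labels integer state sequence in 1..K (may be `NULL` for a pure
#'   prior draw).
#' @param beta current global weights.
#' @param alpha_conc,kappa,gamma_conc HDP concentration parameters.
#' @param K truncation level.
#' @param resample_beta set `FALSE` to hold the global weights fixed and
#'   draw only the transition rows conditional on them.
#' @return List with `pi` (K x K), `beta`, and table counts `mbar`.
#' @export
sample_transitions <- function(labels, beta, alpha_conc, kappa, gamma_conc, K,
                               resample_beta = TRUE) {
  n_counts <- matrix(0, K, K)
  z1 <- integer(0)
  if (!is.null(labels) && length(labels) >= 1) {
    labels <- as.integer(labels)
    if (length(labels) >= 2) {
      tr <- cbind(labels[-length(labels)], labels[-1])
      for (i in seq_len(nrow(tr))) n_counts[tr[i, 1], tr[i, 2]] <-
          n_counts[tr[i, 1], tr[i, 2]] + 1
    }
    z1 <- labels[1]
  }
  tc <- sample_table_counts(n_counts, beta, alpha_conc, kappa)
  if (resample_beta) {
    beta_par <- rep(gamma_conc / K, K) + colSums(tc$mbar)
    if (length(z1)) beta_par[z1] <- beta_par[z1] + 1
    beta_new <- rgamma(K, shape = beta_par, rate = 1)
    beta_new <- beta_new / sum(beta_new)
  } else beta_new <- beta
  pi <- matrix(0, K, K)
  for (j in seq_len(K)) {
    par <- alpha_conc * beta_new + n_counts[j, ]
    par[j] <- par[j] + kappa
    g <- rgamma(K, shape = par, rate = 1)
    pi[j, ] <- g / sum(g)
  }
  list(pi = pi, beta = beta_new, mbar = tc$mbar)
}

#' Run the blocked Gibbs sampler
#'
#' Iterates (1) latent path `r | z, theta, R` by forward-filter
#' backward-sampling, (2) state sequence `z | r, theta, pi, beta`, (3)
#' per-state dynamics `theta | r, z`, (4) global measurement noise
#' `R | psi, r`, and (5) transition weights `(pi, beta) | z`.
#' Initialization is over-dispersed and oracle-free: `z` uniform over
#' `ceiling(K/2)` labels, `theta` from the prior, and `r` from the smoother
#' under a single prior-mean dynamics.
#'
#' @param traj an `spt_trajectory`.
#' @param prior a [dynamics_prior()].
#' @param cfg a [sticky_hdp_config()].
#' @return A `posterior_sample_set`: post-burn-in draws with elements `z`
#'   (draws x T integer matrix), `theta` (list of per-draw state lists),
#'   `beta`, `pi`, `R` (d x d x draws), `loglik` and `n_active` traces, and
#'   optionally `paths`.
#' @export
run_gibbs <- function(traj, prior, cfg = sticky_hdp_config()) {
  traj <- as_trajectory(traj)
  stopifnot(inherits(prior, "dynamics_prior"), inherits(cfg, "sticky_hdp_config"))
  psi <- traj$positions
  T_ <- nrow(psi); d <- ncol(psi); K <- cfg$K
  set.seed(cfg$seed)

  # over-dispersed initialization
  z <- sample.int(ceiling(K / 2), T_, replace = TRUE)
  theta <- lapply(seq_len(K), function(k) draw_state_from_prior(prior))
  R <- prior$Psi0 / (prior$nu0 - d - 1)
  mean_state <- state_params(mu = prior$M0[, d + 1],
                             F = prior$M0[, seq_len(d), drop = FALSE],
                             Sigma = prior$S0 / (prior$n0 - d - 1))
  r <- kalman_smoother(traj, mean_state, R = R)$path
  tw <- sample_transitions(z, rep(1 / K, K), cfg$alpha_conc, cfg$kappa,
                           cfg$gamma_conc, K)
  pi <- tw$pi; beta <- tw$beta

  n_keep <- cfg$n_iter - floor(cfg$burn_in * cfg$n_iter)
  keep_from <- cfg$n_iter - n_keep + 1
  z_draws <- matrix(NA_integer_, n_keep, T_)
  R_draws <- array(NA_real_, c(d, d, n_keep))
  beta_draws <- matrix(NA_real_, n_keep, K)
  pi_draws <- array(NA_real_, c(K, K, n_keep))
  theta_draws <- vector("list", n_keep)
  path_draws <- if (cfg$store_paths) array(NA_real_, c(T_, d, n_keep)) else NULL
  loglik_trace <- numeric(cfg$n_iter)
  n_active_trace <- integer(cfg$n_iter)

  R_seq <- array(0, c(d, d, T_))
  mu_k <- matrix(0, K, d)
  F_arr <- array(0, c(d, d, K)); S_arr <- array(0, c(d, d, K))

  for (it in seq_len(cfg$n_iter)) {
    for (k in seq_len(K)) {
      mu_k[k, ] <- theta[[k]]$mu
      F_arr[, , k] <- theta[[k]]$F
      S_arr[, , k] <- theta[[k]]$Sigma
    }
    src <- z[seq_len(T_ - 1)]
    F_src <- F_arr[, , src, drop = FALSE]
    R_seq <- array(R, c(d, d, T_))
    init_mean <- psi[1, ]; init_cov <- R + KAPPA0_INIT * diag(d)
    flt <- cpp_kalman_filter(psi, mu_k[src, , drop = FALSE], F_src,
                             S_arr[, , src, drop = FALSE],
                             R_seq, init_mean, init_cov)
    if (!is.finite(flt$loglik))
      stop("numerical failure in Gibbs sweep ", it, ": non-finite filter likelihood")
    loglik_trace[it] <- flt$loglik
    r <- cpp_ffbs_path(flt$filt_mean, flt$filt_cov, flt$pred_state_mean,
                       flt$pred_state_cov, F_src)
    z <- as.integer(cpp_sample_z(r, mu_k, F_arr, S_arr,
                                 log(pmax(pi, 1e-300)), log(pmax(beta, 1e-300))))
    theta <- sample_emission_params(r, z, prior, K = K)
    R <- sample_measurement_noise(psi, r, prior)
    tw <- sample_transitions(z, beta, cfg$alpha_conc, cfg$kappa,
                             cfg$gamma_conc, K)
    pi <- tw$pi; beta <- tw$beta
    n_active_trace[it] <- length(unique(z))
    if (cfg$verbose && it %% 500 == 0)
      message(sprintf("sweep %d/%d: %d active states, loglik %.2f",
                      it, cfg$n_iter, n_active_trace[it], loglik_trace[it]))
    if (it >= keep_from) {
      j <- it - keep_from + 1
      z_draws[j, ] <- z
      R_draws[, , j] <- R
      beta_draws[j, ] <- beta
      pi_draws[, , j] <- pi
      theta_draws[[j]] <- theta
      if (cfg$store_paths) path_draws[, , j] <- r
    }
  }
  structure(list(z = z_draws, R = R_draws, beta = beta_draws, pi = pi_draws,
                 theta = theta_draws, paths = path_draws,
                 loglik = loglik_trace, n_active = n_active_trace,
                 cfg = cfg, prior = prior, T = T_, d = d),
            class = "posterior_sample_set")
}

#' @export
print.posterior_sample_set <- function(x, ...) {
  cat(sprintf("Sticky-HDP posterior sample set: %d retained draws, T = %d, K = %d\n",
              nrow(x$z), x$T, x$cfg$K))
  cat("  active-state counts (last sweep trace):",
      paste(range(x$n_active), collapse = "-"), "\n")
  invisible(x)
}

count_longlived <- function(labels, min_dwell) {
  rl <- rle(as.integer(labels))
  length(unique(rl$values[rl$lengths >= min_dwell]))
}

#' Summarize change points and modal segmentation
#'
#' Frame i is declared a change point when the fraction of retained draws
#' with `z_i != z_{i+1}` strictly exceeds `threshold` (ties at the threshold
#' are not reported).  The modal label sequence is the per-frame majority
#' vote; long-lived states are labels covering at least `min_dwell`
#' consecutive frames of the modal sequence.
#'
#' @param samples a `posterior_sample_set` from [run_gibbs()].
#' @param threshold posterior change frequency required to report a change
#'   point (default 0.25).
#' @param min_dwell minimum run length (frames) for a state to count as
#'   long-lived.
#' @return A `slds_segmentation`: `change_freq` (length T-1), `changepoints`
#'   (frame indices i, change between i and i+1), `modal_states`,
#'   `segment_id` per frame, `n_longlived` (modal count), and
#'   `n_longlived_posterior` (distribution over draws).
#' @export
extract_changepoints <- function(samples, threshold = 0.25, min_dwell = 10) {
  stopifnot(inherits(samples, "posterior_sample_set"))
  if (nrow(samples$z) == 0) stop("empty posterior sample set")
  zd <- samples$z
  T_ <- ncol(zd)
  change_freq <- colMeans(zd[, -T_, drop = FALSE] != zd[, -1, drop = FALSE])
  cps <- which(change_freq > threshold)
  modal <- apply(zd, 2, function(col) {
    tb <- tabulate(col, nbins = samples$cfg$K)
    which.max(tb)
  })
  seg_id <- cumsum(c(1L, as.integer(seq_len(T_ - 1) %in% cps)))
  nl_draws <- apply(zd, 1, count_longlived, min_dwell = min_dwell)
  structure(list(change_freq = change_freq,
                 changepoints = as.integer(cps),
                 modal_states = as.integer(modal),
                 segment_id = as.integer(seg_id),
                 n_longlived = count_longlived(modal, min_dwell),
                 n_longlived_posterior = table(nl_draws) / length(nl_draws),
                 threshold = threshold, min_dwell = min_dwell),
            class = "slds_segmentation")
}

#' @export
print.slds_segmentation <- function(x, ...) {
  cat(sprintf("SLDS segmentation: %d change point(s) at the %.0f%% rule",
              length(x$changepoints), 100 * x$threshold))
  if (length(x$changepoints))
    cat(" (frames ", paste(x$changepoints, collapse = ", "), ")", sep = "")
  cat(sprintf("\n  %d long-lived state(s) in the modal sequence (min dwell %d frames)\n",
              x$n_longlived, x$min_dwell))
  invisible(x)
}
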