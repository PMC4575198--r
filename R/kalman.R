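# Exact linear-Gaussian inference for the SLDS emission model.
#
# Parameter sequences follow source-frame indexing: the parameters of
# transition i (frame i -> i+1) are entry i of the per-transition sequence,
# i = 1..T-1.  Measurement noise R is per frame and may vary (needed for
# localization-noise ramps and per-segment refits).

KAPPA0_INIT <- 1  # diffuse prior variance (um^2) added to R for r_1

# Expand user-facing parameter specifications into the dense arrays the C++
# recursions consume.  `params` is a single slds_state or a length T-1 list
# of slds_state; `R` optionally overrides measurement noise (d x d matrix, or
# T-list / d x d x T array of per-frame covariances).
expand_params <- function(traj, params, R = NULL) {
  T_ <- n_frames(traj); d <- n_dims(traj)
  if (inherits(params, "slds_state")) params <- rep(list(params), T_ - 1)
  if (length(params) != T_ - 1)
    stop("params must be a single state or a list of length T - 1 (transitions)")
  mu_seq <- matrix(unlist(lapply(params, `[[`, "mu")), ncol = d, byrow = TRUE)
  F_seq <- array(0, c(d, d, T_ - 1))
  Q_seq <- array(0, c(d, d, T_ - 1))
  for (i in seq_len(T_ - 1)) {
    F_seq[, , i] <- params[[i]]$F
    Q_seq[, , i] <- params[[i]]$Sigma
  }
  R_seq <- array(0, c(d, d, T_))
  if (is.null(R)) {
    for (i in seq_len(T_)) {
      p <- params[[min(i, T_ - 1)]]
      if (is.null(p$R)) stop("no measurement noise R available: set R in the ",
                             "state parameters or pass R explicitly")
      R_seq[, , i] <- p$R
    }
  } else if (is.matrix(R)) {
    for (i in seq_len(T_)) R_seq[, , i] <- R
  } else if (is.array(R) && length(dim(R)) == 3) {
    stopifnot(dim(R)[3] == T_)
    R_seq <- R
  } else if (is.list(R)) {
    stopifnot(length(R) == T_)
    for (i in seq_len(T_)) R_seq[, , i] <- R[[i]]
  } else stop("unsupported R specification")
  list(mu_seq = mu_seq, F_seq = F_seq, Q_seq = Q_seq, R_seq = R_seq)
}

default_init <- function(traj, R_seq) {
  d <- n_dims(traj)
  list(mean = as.numeric(traj$positions[1, ]),
       cov = R_seq[, , 1] + KAPPA0_INIT * diag(d))
}

#' Kalman filter for an SPT trajectory
#'
#' Runs the standard predict/update recursions for the model
#' `r_{i+1} = mu_i + F_i r_i + eta_i`, `psi_i = r_i + eps_i`, with
#' Joseph-form (symmetric) covariance updates.  `init_mean`/`init_cov`
#' parameterize the Gaussian prior of the first latent position; the filter
#' updates it with the first observation, and the log-likelihood sums the
#' one-step predictive log-densities of frames 2..T (frame 1 is treated as
#' initialization).  The default initial prior is diffuse: mean at the first
#' observation with covariance `R + 1 um^2 * I`.
#'
#' @param traj an `spt_trajectory`.
#' @param params a single `slds_state` shared by all transitions, or a list
#'   of T-1 states indexed by the transition's source frame.
#' @param R optional measurement-noise override: d x d matrix, list of T
#'   matrices, or d x d x T array (per frame).
#' @param init_mean,init_cov prior mean/covariance of the first latent
#'   position (micrometres, micrometres^2).
#' @return A list of class `kalman_result`: `filt_mean` (T x d), `filt_cov`
#'   (d x d x T), `pred_obs_mean`/`pred_obs_cov` (one-step predictive
#'   distribution of each observation), `loglik` (nats), and the predicted
#'   state moments used by the smoother and path sampler.
#' @export
kalman_filter <- function(traj, params, R = NULL,
                          init_mean = NULL, init_cov = NULL) {
  traj <- as_trajectory(traj)
  ex <- expand_params(traj, params, R)
  if (is.null(init_mean) || is.null(init_cov)) {
    ini <- default_init(traj, ex$R_seq)
    if (is.null(init_mean)) init_mean <- ini$mean
    if (is.null(init_cov)) init_cov <- ini$cov
  }
  out <- cpp_kalman_filter(traj$positions, ex$mu_seq, ex$F_seq, ex$Q_seq,
                           ex$R_seq, as.numeric(init_mean), as.matrix(init_cov))
  if (!is.finite(out$loglik))
    stop("numerical failure in Kalman filter: non-finite log-likelihood")
  out$F_seq <- ex$F_seq
  class(out) <- "kalman_result"
  out
}

#' @export
print.kalman_result <- function(x, ...) {
  cat(sprintf("Kalman filter: %d frames, log-likelihood %.4f nats\n",
              nrow(x$filt_mean), x$loglik))
  invisible(x)
}

#' Rauch-Tung-Striebel smoother
#'
#' Backward pass over a completed forward filter, returning the smoothed
#' latent path (conditional means given the whole trajectory) and per-frame
#' smoothed covariances.
#'
#' @inheritParams kalman_filter
#' @param filter optionally, a precomputed [kalman_filter()] result.
#' @return List with `path` (T x d smoothed means) and `cov` (d x d x T).
#' @export
kalman_smoother <- function(traj, params = NULL, R = NULL,
                            init_mean = NULL, init_cov = NULL, filter = NULL) {
  if (is.null(filter))
    filter <- kalman_filter(traj, params, R, init_mean, init_cov)
  sm <- cpp_rts_smoother(filter$filt_mean, filter$filt_cov,
                         filter$pred_state_mean, filter$pred_state_cov,
                         filter$F_seq)
  list(path = sm$mean, cov = sm$cov)
}

#' Sample a latent path by forward filtering, backward sampling
#'
#' Exact joint draw of `r_{1:T}` given the observations, dynamics and
#' measurement noise.  Uses R's random number generator, so results are
#' reproducible under `set.seed()`.
#'
#' @inheritParams kalman_smoother
#' @return T x d matrix: one sampled latent path.
#' @export
ffbs_sample_path <- function(traj, params = NULL, R = NULL,
                             init_mean = NULL, init_cov = NULL, filter = NULL) {
  if (is.null(filter))
    filter <- kalman_filter(traj, params, R, init_mean, init_cov)
  cpp_ffbs_path(filter$filt_mean, filter$filt_cov,
                filter$pred_state_mean, filter$pred_state_cov, filter$F_seq)
}
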