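# Conversion of segmentation + fitted dynamics into instantaneous effective
# force vectors (overdamped Langevin + Einstein relation) and the
# eigen-structure of the restoring-force matrix B.

D_SINGULAR_TOL <- 1e-6  # um^2/s; below this a segment is treated as
                        # zero-diffusion (photobleached) and force is undefined

#' Instantaneous effective forces along a segmented trajectory
#'
#' For each segment, runs the Kalman filter under that segment's fitted
#' parameters to obtain latent position estimates, converts the fit to
#' continuous Langevin parameters, and evaluates
#' `f_i = kBT D^-1 (A + B r_i)` at every frame.  Segments whose fitted
#' diffusion matrix has an eigenvalue below `1e-6 um^2/s` are excluded
#' (force is undefined in the zero-diffusion regime) and flagged.
#'
#' @param traj the full `spt_trajectory`.
#' @param segmentation an `slds_segmentation` (from
#'   [extract_changepoints()]) whose `segment_id` covers the trajectory.
#' @param fits list of `mle_fit` objects, one per segment (in segment
#'   order).
#' @param kBT thermal energy, pN um.
#' @param smoothed use smoothed rather than filtered position estimates.
#' @return A `force_series`: data frame with `frame`, `t`, force components
#'   (pN), `magnitude`, `segment`; excluded segment ids in
#'   `attr(, "excluded_segments")`.
#' @export
infer_forces <- function(traj, segmentation, fits, kBT = KBT_DEFAULT,
                         smoothed = FALSE) {
  traj <- as_trajectory(traj)
  seg_id <- segmentation$segment_id
  stopifnot(length(seg_id) == n_frames(traj))
  n_seg <- max(seg_id)
  if (length(fits) != n_seg)
    stop("need one fit per segment (", n_seg, " segments, ", length(fits),
         " fits)")
  rows <- NULL
  excluded <- integer(0)
  for (s in seq_len(n_seg)) {
    idx <- which(seg_id == s)
    fit <- fits[[s]]
    cont <- tryCatch(continuous_from_discrete(fit$theta, traj$dt, kBT = kBT),
                     error = function(e) NULL)
    if (is.null(cont) ||
        min(eigen(cont$D, symmetric = TRUE, only.values = TRUE)$values) <
          D_SINGULAR_TOL) {
      excluded <- c(excluded, s)
      next
    }
    sub <- subset_trajectory(traj, idx)
    est <- if (smoothed) kalman_smoother(sub, fit$theta)$path
           else kalman_filter(sub, fit$theta)$filt_mean
    drift <- sweep(est %*% t(cont$B), 2, cont$A, "+")
    f <- kBT * t(solve(cont$D, t(drift)))
    rows <- rbind(rows, data.frame(frame = idx, t = traj$times[idx],
                                   fx = f[, 1], fy = f[, 2],
                                   magnitude = sqrt(rowSums(f^2)),
                                   segment = s))
  }
  if (is.null(rows))
    rows <- data.frame(frame = integer(0), t = numeric(0), fx = numeric(0),
                       fy = numeric(0), magnitude = numeric(0),
                       segment = integer(0))
  structure(rows, excluded_segments = excluded, kBT = kBT,
            class = c("force_series", "data.frame"))
}

#' Eigen-structure of the restoring-force matrices
#'
#' Converts each segment fit to its continuous restoring-force matrix B and
#' reports eigenvalues (sorted by descending magnitude), unit eigenvectors
#' (sign fixed so the largest-magnitude component is positive), the drift
#' fixed point `-B^-1 A`, and flags for complex-conjugate pairs and
#' (near-)degenerate multiplicities.
#'
#' @param fits list of `mle_fit` objects.
#' @param dt frame interval, seconds.
#' @param kBT thermal energy attached to the conversions.
#' @return List of class `eigen_report`, one entry per fit with elements
#'   `values`, `vectors`, `fixed_point`, `complex_pair`, `degenerate`, `B`.
#' @export
eigen_report <- function(fits, dt, kBT = KBT_DEFAULT) {
  out <- lapply(seq_along(fits), function(s) {
    cont <- continuous_from_discrete(fits[[s]]$theta, dt, kBT = kBT)
    B <- cont$B
    e <- eigen(B)
    ord <- order(Mod(e$values), decreasing = TRUE)
    vals <- e$values[ord]
    vecs <- e$vectors[, ord, drop = FALSE]
    for (j in seq_len(ncol(vecs))) {
      vecs[, j] <- vecs[, j] / sqrt(sum(Mod(vecs[, j])^2))
      piv <- which.max(Mod(vecs[, j]))
      if (Re(vecs[piv, j]) < 0) vecs[, j] <- -vecs[, j]
    }
    complex_pair <- any(abs(Im(vals)) > 1e-10 * max(Mod(vals), 1e-300))
    degenerate <- length(vals) > 1 &&
      min(abs(diff(Mod(vals)))) < 1e-8 * max(Mod(vals), 1e-300)
    fixed_point <- tryCatch(as.numeric(-solve(B, cont$A)),
                            error = function(e) rep(NA_real_, nrow(B)))
    if (!complex_pair) { vals <- Re(vals); vecs <- Re(vecs) }
    list(segment = s, values = vals, vectors = vecs,
         fixed_point = fixed_point, complex_pair = complex_pair,
         degenerate = degenerate, B = B, A = cont$A)
  })
  class(out) <- "eigen_report"
  out
}

#' @export
print.eigen_report <- function(x, ...) {
  cat("Restoring-force eigen-analysis (B, 1/s)\n")
  for (e in x) {
    cat(sprintf("  segment %d: eigenvalues %s%s%s\n", e$segment,
                paste(format(e$values, digits = 4), collapse = ", "),
                if (e$complex_pair) " [complex pair]" else "",
                if (e$degenerate) " [degenerate]" else ""))
  }
  invisible(x)
}

#' @export
plot.force_series <- function(x, bin_width = 0.01, ...) {
  h <- force_histogram(x, bin_width = bin_width)
  graphics::barplot(h$counts, names.arg = signif(h$mids, 2), space = 0,
                    xlab = "force magnitude (pN)", ylab = "frames",
                    main = "Inferred force magnitudes", ...)
  invisible(h)
}

#' Histogram of force magnitudes
#'
#' @param forces a `force_series` from [infer_forces()].
#' @param bin_width bin width in piconewtons.
#' @return List with `edges`, `counts`, `mids`; counts sum to the number of
#'   included frames.
#' @export
force_histogram <- function(forces, bin_width = 0.01) {
  mags <- forces$magnitude
  if (!length(mags)) stop("no forces to histogram (all segments excluded?)")
  top <- max(mags, bin_width)
  edges <- seq(0, (floor(top / bin_width) + 1) * bin_width, by = bin_width)
  counts <- as.integer(table(cut(mags, breaks = edges, include.lowest = TRUE,
                                 right = FALSE)))
  list(edges = edges, counts = counts,
       mids = (edges[-1] + edges[-length(edges)]) / 2)
}
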