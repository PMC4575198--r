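#' Construct a trajectory object
#'
#' A trajectory is a uniformly sampled sequence of measured particle
#' positions.  Positions are stored in micrometres and times in seconds;
#' [read_trajectory_csv()] performs unit conversion on input.
#'
#' @param positions numeric matrix, T x d (d = 2 for standard SPT data),
#'   measured positions in micrometres.
#' @param dt frame interval in seconds (supply either `dt` or `times`).
#' @param times optional numeric vector of frame times in seconds; must be
#'   uniformly spaced.
#' @param label free-text label carried through outputs.
#' @return An object of class `spt_trajectory` with elements `positions`,
#'   `times`, `dt`, `label`.
#' @examples
#' tr <- trajectory(matrix(rnorm(20), 10, 2), dt = 1/22)
#' tr
#' @export
trajectory <- function(positions, dt = NULL, times = NULL, label = "") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  T_ <- nrow(positions)
  if (T_ < 2) stop("trajectory needs at least 2 frames")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (is.null(times)) {
    if (is.null(dt) || !is.finite(dt) || dt <= 0)
      stop("supply a positive frame interval dt (seconds) or a times vector")
    times <- (seq_len(T_) - 1) * dt
  } else {
    if (length(times) != T_) stop("times length must match number of frames")
    gaps <- diff(times)
    dt <- gaps[1]
    if (dt <= 0 || any(abs(gaps - dt) > 1e-9 * max(dt, 1)))
      stop("frame times must be uniformly spaced (offending gaps at frames ",
           paste(which(abs(gaps - dt) > 1e-9 * max(dt, 1)) + 1, collapse = ", "), ")")
  }
  structure(list(positions = positions, times = as.numeric(times),
                 dt = as.numeric(dt), label = as.character(label)),
            class = "spt_trajectory")
}

#' @export
print.spt_trajectory <- function(x, ...) {
  cat(sprintf("SPT trajectory: %d frames x %d dims, dt = %.5g s%s\n",
              nrow(x$positions), ncol(x$positions), x$dt,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$positions)
n_dims <- function(traj) ncol(traj$positions)

as_trajectory <- function(x) {
  if (inherits(x, "spt_trajectory")) return(x)
  stop("expected an spt_trajectory; see trajectory() or read_trajectory_csv()")
}

#' Read a trajectory from CSV
#'
#' Expects header columns `frame`, `t`, `x`, `y` (extra columns are kept as
#' attributes when recognized: `true_state`, `true_x`, `true_y`).  Positions
#' are converted to micrometres; times must be in seconds (or supply a frame
#' rate via `dt` when `t` is absent).
#'
#' @param path CSV file path.
#' @param units position unit of the file, `"um"` or `"nm"`.
#' @param label optional label; defaults to the file name.
#' @return An `spt_trajectory`.  If the file carries a `true_state` column it
#'   is attached as `attr(, "true_states")` (and `true_x`/`true_y` as
#'   `attr(, "true_path")`).
#' @export
read_trajectory_csv <- function(path, units = c("um", "nm"), label = NULL) {
  units <- match.arg(units)
  df <- read.csv(path, check.names = FALSE)
  need <- c("frame", "t", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trajectory CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  fr <- as.numeric(df$frame)
  gaps <- diff(fr)
  if (length(unique(gaps)) > 1 && any(abs(gaps - gaps[1]) > 1e-9))
    stop("non-uniform frame spacing at frame(s) ",
         paste(fr[which(abs(gaps - gaps[1]) > 1e-9) + 1], collapse = ", "))
  scale <- if (units == "nm") 1e-3 else 1
  pos <- cbind(x = as.numeric(df$x), y = as.numeric(df$y)) * scale
  tr <- trajectory(pos, times = as.numeric(df$t),
                   label = if (is.null(label)) basename(path) else label)
  if ("true_state" %in% names(df))
    attr(tr, "true_states") <- as.integer(df$true_state)
  if (all(c("true_x", "true_y") %in% names(df)))
    attr(tr, "true_path") <- cbind(as.numeric(df$true_x), as.numeric(df$true_y)) * scale
  tr
}

#' Write a trajectory to CSV
#'
#' Columns `frame` (0-based), `t` (seconds), `x`, `y` (micrometres), plus
#' `true_state`, `true_x`, `true_y` when available (labeled simulator
#' output).
#'
#' @param traj an `spt_trajectory` or `labeled_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  true_states <- NULL; true_path <- NULL
  if (inherits(traj, "labeled_trajectory")) {
    true_states <- traj$true_states
    true_path <- traj$true_path
    traj <- traj$trajectory
  } else {
    true_states <- attr(traj, "true_states")
    true_path <- attr(traj, "true_path")
  }
  df <- data.frame(frame = seq_len(n_frames(traj)) - 1L,
                   t = traj$times,
                   x = traj$positions[, 1],
                   y = traj$positions[, 2])
  if (!is.null(true_states)) df$true_state <- true_states
  if (!is.null(true_path)) {
    df$true_x <- true_path[, 1]
    df$true_y <- true_path[, 2]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
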