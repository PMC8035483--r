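#' Expand six rigid-body motion parameters to the Friston-24 set
#'
#' Column order is fixed: the 6 parameters, their one-volume lags (first row
#' zero-padded), the squares of the parameters, and the squares of the lags.
#'
#' @param motion T x 6 matrix (3 translations in mm, 3 rotations in
#'   degrees).
#' @return T x 24 matrix with descriptive column names.
#' @export
friston24_expand <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have exactly 6 columns")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
                     paste0(base, "_lag_sq"))
  out
}

#' Framewise displacement from motion parameters
#'
#' FD(t) is the sum of absolute inter-volume translation differences plus
#' the rotation differences converted to arc length on a sphere of
#' `head_radius` mm (rotations are stored in degrees and converted to
#' radians internally). FD of the first volume is 0.
#'
#' @param motion T x 6 matrix (translations mm, rotations degrees).
#' @param head_radius assumed head radius in mm.
#' @return numeric vector of length T.
#' @examples
#' m <- matrix(0, 5, 6); m[3, 1] <- 0.3
#' framewise_displacement(m)  # 0 0 0.3 0.3 0
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have exactly 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 volumes")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE] * pi / 180)
  c(0, fd)
}

#' Volume-retention mask from framewise displacement
#'
#' @param fd numeric FD vector.
#' @param threshold FD cutoff in mm; volumes with FD strictly above it are
#'   flagged for removal.
#' @return logical vector, FALSE where the volume is scrubbed.
#' @export
scrub_mask <- function(fd, threshold = 0.5) {
  if (threshold <= 0) stop("threshold must be positive")
  !(fd > threshold)
}

#' Head-motion quality control
#'
#' A subject fails if any translation exceeds `max_trans` mm or any rotation
#' exceeds `max_rot` degrees (strict inequalities; a value exactly at the
#' bound passes).
#'
#' @param motion T x 6 matrix (translations mm, rotations degrees).
#' @param max_trans translation bound in mm.
#' @param max_rot rotation bound in degrees.
#' @return list with `pass` (logical) and `offending` (character vector of
#'   parameter names exceeding their bound, empty when passing).
#' @export
qc_motion <- function(motion, max_trans = 1.0, max_rot = 1.0) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have exactly 6 columns")
  nm <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  peak <- apply(abs(motion), 2, max)
  bad <- c(peak[1:3] > max_trans, peak[4:6] > max_rot)
  list(pass = !any(bad), offending = nm[bad])
}

detrend_columns <- function(x) {
  t_idx <- seq_len(nrow(x))
  design <- cbind(1, t_idx - mean(t_idx))
  x - design %*% qr.solve(design, x)
}

#' Clean a ROI time-series matrix
#'
#' Fixed processing order: discard the first `discard` volumes, remove
#' linear trends per region, regress out nuisance signals (ordinary least
#' squares with an intercept; residuals kept), band-pass filter, then scrub
#' high-motion volumes. Filtering is a zero-phase (forward-backward)
#' Butterworth band-pass of order `filter_order` per pass. Scrubbed rows are
#' recorded in the `volume_mask` (rows are retained in `values` so that
#' surviving rows stay bit-identical; downstream covariance estimation drops
#' masked rows).
#'
#' @param ts a `conn_ts` object (or T x N matrix).
#' @param motion optional T x 6 motion matrix, aligned with `ts` before
#'   discarding; used for Friston-24 regressors (when `nuisance` is NULL)
#'   and for FD scrubbing.
#' @param nuisance optional T x K matrix of additional nuisance regressors
#'   (e.g. cerebrospinal-fluid and white-matter signals), aligned with `ts`
#'   before discarding. Constant columns are dropped (the regression has its
#'   own intercept); a rank-deficient regressor matrix is an error naming
#'   the collinear columns.
#' @param discard number of initial volumes to drop.
#' @param band band-pass edges in Hz.
#' @param fd_threshold FD scrubbing cutoff in mm.
#' @param head_radius head radius in mm for FD.
#' @param filter_order Butterworth order per pass.
#' @return a `conn_ts` with `nrow(ts) - discard` rows and an updated
#'   `volume_mask`, plus attributes `qc` (motion QC result) and `n_scrubbed`.
#' @export
clean_timeseries <- function(ts, motion = NULL, nuisance = NULL,
                             discard = 10, band = c(0.01, 0.08),
                             fd_threshold = 0.5, head_radius = 50,
                             filter_order = 2) {
  if (!inherits(ts, "conn_ts")) ts <- timeseries_matrix(ts, tr = 2)
  x <- ts$values
  t_in <- nrow(x)
  if (t_in <= discard + 20) stop("too few volumes to filter after discard")
  keep <- (discard + 1):t_in
  x <- x[keep, , drop = FALSE]

  reg <- NULL
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != t_in) stop("nuisance rows must match input volumes")
    reg <- nuisance[keep, , drop = FALSE]
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != t_in) stop("motion rows must match input volumes")
    if (is.null(reg)) reg <- friston24_expand(motion)[keep, , drop = FALSE]
  }

  # detrend
  x <- detrend_columns(x)

  # nuisance regression (OLS residuals)
  if (!is.null(reg)) {
    const <- apply(reg, 2, function(v) max(v) - min(v)) < 1e-12
    reg <- reg[, !const, drop = FALSE]
    if (ncol(reg) > 0) {
      design <- cbind(intercept = 1, reg)
      qrd <- qr(design)
      if (qrd$rank < ncol(design)) {
        dropped <- colnames(design)[-seq_len(qrd$rank)]
        stop("nuisance regressors are collinear: ",
             paste(dropped, collapse = ", "))
      }
      x <- qr.resid(qrd, x)
    }
  }

  # zero-phase band-pass
  fs <- 1 / ts$tr
  wn <- band / (fs / 2)
  if (any(wn <= 0) || any(wn >= 1)) stop("band edges must lie inside (0, Nyquist)")
  bf <- signal::butter(filter_order, wn, type = "pass")
  for (j in seq_len(ncol(x))) {
    x[, j] <- signal::filtfilt(bf, x[, j])
  }

  # scrubbing mask from FD (computed on the retained volumes)
  mask <- rep(TRUE, nrow(x))
  n_scrub <- 0L
  if (!is.null(motion)) {
    fd <- framewise_displacement(motion[keep, , drop = FALSE], head_radius)
    mask <- scrub_mask(fd, fd_threshold)
    n_scrub <- sum(!mask)
  }

  out <- timeseries_matrix(x, tr = ts$tr, region_labels = ts$region_labels,
                           volume_mask = mask)
  attr(out, "qc") <- if (is.null(motion)) NULL else qc_motion(motion)
  attr(out, "n_scrubbed") <- n_scrub
  attr(out, "n_discarded") <- discard
  out
}
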