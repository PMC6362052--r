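#' Convert a 4D series to a time-by-voxel matrix
#' @noRd
vol_to_matrix <- function(vol) {
  d <- dim(vol$data)
  t(matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4]))
}

#' Rebuild a 4D series from a time-by-voxel matrix
#' @noRd
matrix_to_vol <- function(m, template) {
  d <- dim(template$data)
  out <- template
  out$data <- array(t(m), dim = d)
  out
}

#' Synthetic 12-column motion confound table
#'
#' Builds a per-volume table of 3 translations, 3 rotations and their first
#' backward differences: slow drifts plus white jitter, with abrupt jumps at
#' the given spike volumes. Used to exercise the confound-regression stage on
#' synthetic data, and as the format real realignment parameters slot into.
#'
#' @param n_rep number of volumes.
#' @param spike_times volumes with an abrupt displacement.
#' @param seed integer seed.
#' @param drift_mm,jitter_mm scale of the slow drift / white jitter (mm and
#'   degrees for rotations).
#' @param spike_mm displacement amplitude at spike volumes.
#' @return numeric matrix \code{n_rep x 12} with named columns.
#' @export
make_motion_confounds <- function(n_rep, spike_times = integer(), seed = 1,
                                  drift_mm = 0.05, jitter_mm = 0.005,
                                  spike_mm = 0.5) {
  set.seed(seed)
  base <- sapply(1:6, function(i) {
    drift_mm * sin(2 * pi * seq_len(n_rep) / n_rep * stats::runif(1, 0.5, 2) +
                     stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(n_rep, 0, jitter_mm)
  })
  if (length(spike_times))
    base[spike_times, ] <- base[spike_times, ] +
      spike_mm * matrix(stats::rnorm(length(spike_times) * 6), ncol = 6)
  derivs <- rbind(0, diff(base))
  out <- cbind(base, derivs)
  colnames(out) <- c(paste0("trans_", c("x", "y", "z")),
                     paste0("rot_", c("x", "y", "z")),
                     paste0("trans_", c("x", "y", "z"), "_d"),
                     paste0("rot_", c("x", "y", "z"), "_d"))
  out
}

#' Regress motion confounds out of a 4D series
#'
#' Ordinary least squares per voxel against \code{[intercept | confounds]};
#' returns the residual series, orthogonal to every confound column (and
#' demeaned, because of the intercept). Collinear confound columns are
#' dropped with a warning.
#'
#' @param vol an \code{epi_volume4d}.
#' @param confounds numeric matrix, one row per volume.
#' @return the residual \code{epi_volume4d}.
#' @export
regress_confounds <- function(vol, confounds) {
  stopifnot(inherits(vol, "epi_volume4d"))
  confounds <- as.matrix(confounds)
  n_t <- dim(vol$data)[4]
  if (nrow(confounds) != n_t)
    stop("confound table has ", nrow(confounds), " rows but series has ",
         n_t, " volumes")
  if (!all(is.finite(confounds))) stop("confound table contains non-finite values")
  x <- cbind(intercept = 1, confounds)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop_cols <- qx$pivot[(qx$rank + 1):ncol(x)]
    warning("dropping ", length(drop_cols),
            " collinear confound column(s): ",
            paste(colnames(x)[drop_cols], collapse = ", "))
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  y <- vol_to_matrix(vol)
  res <- qr.resid(qx, y)
  matrix_to_vol(res, vol)
}

#' Temporal band-pass filter (0.01-0.1 Hz default)
#'
#' Linear detrend followed by an FFT-domain filter: hard high-pass at
#' \code{lo_hz}, flat pass band up to \code{hi_hz}, then a Gaussian roll-off
#' whose half-amplitude point sits half a bandwidth above \code{hi_hz}
#' (width configurable via \code{lp_width_hz}). The transfer function is
#' exactly characterizable, unlike recursive filters.
#'
#' @param vol an \code{epi_volume4d}.
#' @param lo_hz,hi_hz band edges in Hz; \code{hi_hz} must lie below Nyquist.
#' @param lp_width_hz Gaussian roll-off scale above \code{hi_hz}
#'   (half-amplitude at \code{hi_hz + lp_width_hz}); default \code{hi_hz/2}.
#' @return filtered \code{epi_volume4d} (zero mean per voxel).
#' @export
bandpass <- function(vol, lo_hz = 0.01, hi_hz = 0.1, lp_width_hz = NULL) {
  stopifnot(inherits(vol, "epi_volume4d"), lo_hz >= 0, hi_hz > lo_hz)
  nyq <- 1 / (2 * vol$tr_vol_s)
  if (hi_hz >= nyq)
    stop(sprintf("hi_hz = %.3g Hz is not below Nyquist %.3g Hz", hi_hz, nyq))
  if (is.null(lp_width_hz)) lp_width_hz <- hi_hz / 2
  y <- vol_to_matrix(vol)
  n <- nrow(y)
  # linear detrend
  tt <- cbind(1, seq_len(n))
  y <- qr.resid(qr(tt), y)
  f <- (seq_len(n) - 1) / (n * vol$tr_vol_s)
  f <- pmin(f, 1 / vol$tr_vol_s - f)
  h <- as.numeric(f >= lo_hz)
  above <- f > hi_hz
  h[above] <- h[above] * exp(-log(2) * ((f[above] - hi_hz) / lp_width_hz)^2)
  filt <- Re(stats::mvfft(stats::mvfft(y) * h, inverse = TRUE)) / n
  matrix_to_vol(filt, vol)
}

#' DVARS: volume-to-volume RMS signal change
#'
#' \code{DVARS_t} is the root-mean-square over brain voxels of the backward
#' temporal difference, scaled by the median brain intensity of the whole
#' series; the first element is 0 by convention.
#'
#' @param vol an \code{epi_volume4d}.
#' @param brain_mask logical 3D array.
#' @return numeric vector of length n_rep.
#' @export
dvars <- function(vol, brain_mask) {
  stopifnot(inherits(vol, "epi_volume4d"))
  if (!any(brain_mask)) stop("empty brain mask")
  y <- vol_to_matrix(vol)[, as.vector(brain_mask), drop = FALSE]
  dif <- diff(y)
  rms <- sqrt(rowMeans(dif^2))
  scale <- stats::median(y)
  if (scale == 0) scale <- 1
  c(0, rms / scale)
}

#' Censor motion-corrupted volumes from a DVARS trace
#'
#' Default rule: a volume is an outlier iff its DVARS exceeds the 75th
#' percentile plus \code{k_iqr} times the inter-quartile range (strict
#' inequality, so a constant trace yields no outliers). An absolute
#' \code{threshold} can be supplied instead.
#'
#' @param dvars_series numeric DVARS vector.
#' @param k_iqr IQR multiplier of the default rule.
#' @param threshold optional absolute threshold overriding the IQR rule
#'   (\code{Inf} keeps everything).
#' @return list with \code{keep} (logical, TRUE = retain), \code{fraction}
#'   (censored fraction), and \code{threshold} used.
#' @export
censor <- function(dvars_series, k_iqr = 1.5, threshold = NULL) {
  stopifnot(is.numeric(dvars_series))
  if (is.null(threshold)) {
    q <- stats::quantile(dvars_series, c(0.25, 0.75), names = FALSE)
    threshold <- q[2] + k_iqr * (q[2] - q[1])
  }
  keep <- dvars_series <= threshold
  list(keep = keep, fraction = mean(!keep), threshold = threshold)
}

#' Optional isotropic Gaussian spatial smoothing
#'
#' Volume-wise separable Gaussian smoothing at the given FWHM (mm). Off by
#' default in the pipeline; stands in for edge-preserving image-noise
#' filtering, which is out of scope.
#'
#' @param vol an \code{epi_volume4d}.
#' @param fwhm_mm full width at half maximum in mm.
#' @return smoothed \code{epi_volume4d}.
#' @export
smooth_spatial <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "epi_volume4d"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_size
  out <- vol
  for (t in seq_len(dim(vol$data)[4]))
    out$data[, , , t] <- gauss_smooth3d(vol$data[, , , t], sigma_vox)
  out
}
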