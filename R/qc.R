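#' ROI signal-to-noise ratio
#'
#' Mean time-averaged signal over an ROI divided by the standard deviation
#' of a background (noise-only) region, the SD being pooled over background
#' voxels and time points.
#'
#' @param vol an \code{epi_volume4d}.
#' @param roi,background logical 3D masks; both must be nonempty.
#' @return scalar SNR.
#' @export
roi_snr <- function(vol, roi, background) {
  stopifnot(inherits(vol, "epi_volume4d"))
  if (!any(roi)) stop("empty ROI mask")
  if (!any(background)) stop("empty background mask")
  y <- vol_to_matrix(vol)
  tmean <- colMeans(y)
  noise <- stats::sd(y[, as.vector(background)])
  if (noise == 0) stop("background SD is zero (noiseless input)")
  mean(tmean[as.vector(roi)]) / noise
}

#' Voxelwise temporal SNR map
#'
#' tSNR is the temporal mean divided by the temporal standard deviation of
#' each voxel's time course (population SD, over uncensored volumes only).
#' Voxels with zero temporal SD are flagged invalid and set to 0.
#'
#' @param vol an \code{epi_volume4d}.
#' @param mask optional logical 3D array; voxels outside it are invalid.
#' @param keep optional logical vector of volumes to retain (censor mask);
#'   at least 8 volumes must remain.
#' @return object of class \code{tsnr_map}: list with \code{tsnr} (3D),
#'   \code{valid} (logical 3D), \code{n_volumes}.
#' @export
tsnr_map <- function(vol, mask = NULL, keep = NULL) {
  stopifnot(inherits(vol, "epi_volume4d"))
  d <- dim(vol$data)
  if (is.null(keep)) keep <- rep(TRUE, d[4])
  stopifnot(length(keep) == d[4])
  n <- sum(keep)
  if (n < 8) stop("tsnr_map needs at least 8 uncensored volumes")
  y <- vol_to_matrix(vol)[keep, , drop = FALSE]
  mu <- colMeans(y)
  s <- sqrt(pmax(colMeans(y^2) - mu^2, 0))   # population SD
  valid <- s > 0
  tsnr <- numeric(length(mu))
  tsnr[valid] <- mu[valid] / s[valid]
  tsnr[tsnr < 0] <- 0
  if (!is.null(mask)) valid <- valid & as.vector(mask)
  tsnr[!valid] <- 0
  structure(list(tsnr = array(tsnr, dim = d[1:3]),
                 valid = array(valid, dim = d[1:3]),
                 n_volumes = n),
            class = "tsnr_map")
}

#' Summarize tSNR over named ROIs
#'
#' @param tm a \code{tsnr_map}.
#' @param rois named list of logical 3D masks.
#' @return data.frame with columns roi, mean, sd, n.
#' @export
tsnr_roi_stats <- function(tm, rois) {
  stopifnot(inherits(tm, "tsnr_map"), is.list(rois))
  rows <- lapply(names(rois), function(nm) {
    sel <- rois[[nm]] & tm$valid
    v <- tm$tsnr[sel]
    data.frame(roi = nm, mean = mean(v), sd = stats::sd(v), n = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group comparison of tSNR maps
#'
#' Voxelwise two-sample t between two groups of tSNR maps, TFCE-enhanced,
#' with FWE correction by max-statistic permutation (group-label shuffles).
#' Both directions are returned.
#'
#' @param group_a,group_b lists of \code{tsnr_map} objects (>= 3 each).
#' @param n_perm,seed permutation settings.
#' @param mask optional logical 3D analysis mask.
#' @param ... further TFCE parameters passed to
#'   \code{\link{permutation_fwe}}.
#' @return a \code{stat_map}; \code{fwe_one_minus_p} tests a > b and
#'   \code{fwe_one_minus_p_neg} tests b > a.
#' @export
compare_tsnr <- function(group_a, group_b, n_perm = 499, seed = 1,
                         mask = NULL, ...) {
  stopifnot(length(group_a) >= 3, length(group_b) >= 3)
  maps <- c(lapply(group_a, `[[`, "tsnr"), lapply(group_b, `[[`, "tsnr"))
  dims <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) all(dim(m) == dims), TRUE)))
    stop("tSNR maps have mismatched shapes")
  grp <- rep(c(TRUE, FALSE), c(length(group_a), length(group_b)))
  permutation_fwe(maps, design = "two_sample", group = grp,
                  n_perm = n_perm, seed = seed, mask = mask, ...)
}
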