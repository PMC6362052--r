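#' Dice similarity index of two binary masks
#'
#' \code{2|A∩B| / (|A| + |B|)}. Calling it with two empty masks is an
#' error rather than a conventional 0.
#'
#' @param mask_a,mask_b logical arrays of identical shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  if (!any(a) && !any(b)) stop("both masks are empty; Dice undefined")
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Brain mask from a 4D series
#'
#' Binarizes the temporal mean image at a fraction of its typical
#' foreground intensity (median of voxels above 5\% of the maximum).
#'
#' @param vol an \code{epi_volume4d}.
#' @param frac threshold fraction; default 0.5.
#' @return logical 3D array.
#' @export
brain_mask_from_volume <- function(vol, frac = 0.5) {
  stopifnot(inherits(vol, "epi_volume4d"), frac > 0)
  m <- apply(vol$data, 1:3, mean)
  fg <- m[m > 0.05 * max(m)]
  m > frac * stats::median(fg)
}

#' Build a warp field from a phase-encode displacement
#'
#' @param disp a \code{pe_displacement} (or 3D array of shifts).
#' @param pe_axis phase-encode axis if \code{disp} is a bare array.
#' @return 4D array (x, y, z, component) of voxel displacements.
#' @export
as_warp_field <- function(disp, pe_axis = NULL) {
  if (inherits(disp, "pe_displacement")) {
    shift <- disp$shift_vox
    pe_axis <- disp$pe_axis
  } else {
    shift <- disp
    stopifnot(!is.null(pe_axis))
  }
  d <- dim(shift)
  wf <- array(0, dim = c(d, 3))
  wf[, , , pe_axis] <- shift
  wf
}

#' Jacobian determinant map of a warp field
#'
#' For a displacement field u (voxels), returns \code{det(I + du/dx)} with
#' central differences in the interior and one-sided stencils at the
#' boundary. Values above 1 mark local expansion, below 1 compression.
#'
#' @param warp 4D array (x, y, z, 3) of voxel displacements.
#' @return 3D array of Jacobian determinants.
#' @export
jacobian_map <- function(warp) {
  d <- dim(warp)
  stopifnot(length(d) == 4, d[4] == 3, all(d[1:3] >= 3), all(is.finite(warp)))
  g <- array(0, dim = c(d[1:3], 3, 3))   # g[,,,i,j] = d u_i / d x_j
  for (i in 1:3)
    for (j in 1:3)
      g[, , , i, j] <- axis_gradient(warp[, , , i], j)
  a11 <- 1 + g[, , , 1, 1]; a12 <- g[, , , 1, 2]; a13 <- g[, , , 1, 3]
  a21 <- g[, , , 2, 1]; a22 <- 1 + g[, , , 2, 2]; a23 <- g[, , , 2, 3]
  a31 <- g[, , , 3, 1]; a32 <- g[, , , 3, 2]; a33 <- 1 + g[, , , 3, 3]
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Pooled histogram and tail mass of Jacobian maps
#'
#' Pools per-subject Jacobian determinants over a brain mask and reports a
#' fixed-bin histogram plus the fraction of voxels above \code{1 + delta}
#' and below \code{1 - delta} (the "heavy tail" summary of distortion
#' severity).
#'
#' @param jmaps list of 3D Jacobian maps (or a single map).
#' @param brain_mask logical 3D array.
#' @param breaks histogram break points.
#' @param delta tail offset; default 0.05.
#' @return list with \code{histogram} (data.frame mid/count/density),
#'   \code{tail_above}, \code{tail_below}, \code{n_voxels}.
#' @export
jacobian_summary <- function(jmaps, brain_mask,
                             breaks = seq(0, 2, by = 0.02), delta = 0.05) {
  if (!is.list(jmaps)) jmaps <- list(jmaps)
  stopifnot(length(jmaps) >= 1)
  vals <- unlist(lapply(jmaps, function(j) j[brain_mask]))
  vals_b <- pmin(pmax(vals, min(breaks)), max(breaks))
  h <- graphics::hist(vals_b, breaks = breaks, plot = FALSE)
  list(histogram = data.frame(mid = h$mids, count = h$counts,
                              density = h$density),
       tail_above = mean(vals > 1 + delta),
       tail_below = mean(vals < 1 - delta),
       n_voxels = length(vals))
}

#' Correct geometric distortion with a known field map
#'
#' Resamples every volume at positions displaced by the off-resonance
#' phase-encode shift (the inverse of the distortion applied at
#' acquisition), using linear interpolation. Also returns the correction
#' warp field so its Jacobian can be analyzed. A zero field map is an exact
#' pass-through.
#'
#' @param vol an \code{epi_volume4d}.
#' @param fmap the \code{epi_fieldmap} describing the distortion.
#' @param seq the \code{epi_seq} the data were acquired with.
#' @return list with \code{volume} (dewarped \code{epi_volume4d}) and
#'   \code{warp} (4D correction field, voxel displacements).
#' @export
dewarp <- function(vol, fmap, seq) {
  stopifnot(inherits(vol, "epi_volume4d"), inherits(fmap, "epi_fieldmap"),
            inherits(seq, "epi_seq"))
  d <- dim(vol$data)
  if (!all(dim(fmap$delta_f) == d[1:3]))
    stop("field map shape does not match volume")
  disp <- pe_displacement(fmap, seq)
  out <- vol
  if (any(disp$shift_vox != 0)) {
    ww <- warp_weights(-disp$shift_vox, fmap$pe_axis)
    # undo the Jacobian intensity modulation of the distortion, then
    # resample back on the regular grid
    jac_mod <- pmax(1 - axis_gradient(disp$shift_vox, fmap$pe_axis), 0.1)
    for (t in seq_len(d[4]))
      out$data[, , , t] <- apply_warp(vol$data[, , , t] / jac_mod, ww)
  }
  warp <- as_warp_field(-disp$shift_vox, pe_axis = fmap$pe_axis)
  list(volume = out, warp = warp)
}
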