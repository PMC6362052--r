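#' Digital rodent-head phantom
#'
#' Builds a 3D label volume and baseline signal map standing in for a rat
#' head: an ellipsoidal brain with cortical parcels on the dorsal shell,
#' subcortical parcels in the ventral interior, and two air cavities placed
#' ventro-laterally outside the brain (mimicking the aural/nasal cavities
#' that drive susceptibility artifacts). Every parcel is created in left and
#' right hemisphere copies.
#'
#' @param shape integer length-3: volume dimensions (x = left-right,
#'   y = anterior-posterior, z = ventral-dorsal). In-plane dimensions must be
#'   at least 16 and the slice dimension at least 8.
#' @param n_cortical,n_subcortical number of cortical / subcortical parcels
#'   per hemisphere.
#' @param seed integer seed; the phantom is a pure function of its arguments.
#' @param voxel_size_mm voxel size per axis in mm. Default emulates a
#'   35 x 35 x 16 mm field of view at the requested matrix size.
#' @param pe_axis phase-encode axis (1-based). Default 2 (anterior-posterior).
#' @param baseline_mean mean baseline signal intensity in brain tissue
#'   (arbitrary units).
#' @param texture_sd relative SD of the smooth intensity texture added to the
#'   baseline so that tissue is not perfectly uniform.
#'
#' @return An object of class \code{epi_phantom}: list with \code{labels}
#'   (3D integer array, 0 = background), \code{baseline} (3D array, zero in
#'   background and air), \code{voxel_size} (mm), \code{pe_axis}, and
#'   \code{parcels} (data.frame: id, name, hemisphere, class).
#' @export
make_phantom <- function(shape, n_cortical, n_subcortical, seed,
                         voxel_size_mm = NULL, pe_axis = 2L,
                         baseline_mean = 100, texture_sd = 0.08) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, n_cortical >= 1L, n_subcortical >= 1L,
            pe_axis %in% 1:3)
  if (shape[1] < 16L || shape[2] < 16L || shape[3] < 8L)
    stop("phantom shape too small: need at least 16 x 16 in-plane and 8 slices")
  if (is.null(voxel_size_mm))
    voxel_size_mm <- c(35 / shape[1], 35 / shape[2], 16 / shape[3])

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  # brain centre sits dorsally, leaving ventral room for air cavities
  cz <- 0.58 * nz
  ax <- 0.38 * nx; ay <- 0.42 * ny; az <- 0.40 * nz

  xs <- array(rep(seq_len(nx), times = ny * nz), dim = shape)
  ys <- array(rep(rep(seq_len(ny), each = nx), times = nz), dim = shape)
  zs <- array(rep(seq_len(nz), each = nx * ny), dim = shape)

  r2 <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 + ((zs - cz) / az)^2
  brain <- r2 <= 1

  labels <- array(0L, dim = shape)
  parcels <- list()
  next_id <- 1L

  place_band <- function(sel, n_bins, class, hemi_sign, name_offset = 0L) {
    # split a voxel set into n_bins along the anterior-posterior axis using
    # equal-count quantile bins, so every parcel is nonempty when possible
    idx <- which(sel)
    if (length(idx) < 2L * n_bins)
      stop("phantom shape too small to place all requested parcels")
    yv <- ys[idx]
    qs <- stats::quantile(yv, probs = seq(0, 1, length.out = n_bins + 1),
                          type = 1)
    bins <- findInterval(yv, qs[-c(1, n_bins + 1)]) + 1L
    for (b in seq_len(n_bins)) {
      vox <- idx[bins == b]
      if (length(vox) == 0L)
        stop("phantom shape too small to place all requested parcels")
      labels[vox] <<- next_id
      parcels[[length(parcels) + 1L]] <<- data.frame(
        id = next_id,
        name = sprintf("%s_%02d_%s", class, b + name_offset,
                       if (hemi_sign < 0) "L" else "R"),
        hemisphere = if (hemi_sign < 0) "L" else "R",
        class = class, stringsAsFactors = FALSE)
      next_id <<- next_id + 1L
    }
  }

  # cortex: dorsal shell, excluding the extreme anterior/posterior caps
  # (olfactory bulb / cerebellum, not neocortex); subcortex: the ventral
  # half of the brain, which (as for the real ventral nuclei) reaches the
  # ventral brain surface just above the air cavities
  shell <- brain & r2 >= 0.72^2 & zs >= cz & abs(ys - cy) <= 0.55 * ay
  core  <- brain & zs < cz
  for (hs in c(-1, 1)) {
    hemi <- if (hs < 0) xs < cx else xs >= cx
    place_band(shell & hemi, n_cortical, "cortical", hs)
  }
  # an even subcortical count is split into a ventral and a dorsal layer of
  # anterior-posterior bands, giving compact nuclei; the ventral layer sits
  # directly above the air cavities like the real ventral nuclei
  for (hs in c(-1, 1)) {
    hemi <- if (hs < 0) xs < cx else xs >= cx
    sel <- core & hemi & labels == 0L
    if (n_subcortical %% 2L == 0L) {
      zmed <- stats::median(zs[sel])
      place_band(sel & zs < zmed, n_subcortical %/% 2L, "subcortical", hs)
      place_band(sel & zs >= zmed & labels == 0L, n_subcortical %/% 2L,
                 "subcortical", hs, name_offset = n_subcortical %/% 2L)
    } else {
      place_band(sel, n_subcortical, "subcortical", hs)
    }
  }

  # air cavities hugging the ventral brain surface: one aural pair
  # postero-laterally (ear canals) and one nasal pair antero-medially
  r_cav <- max(2, round(0.10 * min(shape[1:2])))
  cav_spots <- list(aural = c(dx = 0.50, dy = -0.10),
                    nasal = c(dx = 0.28, dy = -0.62))
  for (spot in names(cav_spots)) {
    for (hs in c(-1, 1)) {
      ccx <- cx + hs * cav_spots[[spot]]["dx"] * ax
      ccy <- cy + cav_spots[[spot]]["dy"] * ay
      zb <- cz - az * sqrt(max(0, 1 - cav_spots[[spot]]["dx"]^2 -
                                 cav_spots[[spot]]["dy"]^2))
      ccz <- max(1.5, zb - 0.6 * r_cav)
      cav <- ((xs - ccx)^2 + (ys - ccy)^2 + (zs - ccz)^2) <= r_cav^2 & !brain
      if (!any(cav))
        stop("phantom shape too small to place air cavities")
      labels[cav] <- next_id
      parcels[[length(parcels) + 1L]] <- data.frame(
        id = next_id,
        name = sprintf("air_cavity_%s_%s", spot, if (hs < 0) "L" else "R"),
        hemisphere = if (hs < 0) "L" else "R", class = "air",
        stringsAsFactors = FALSE)
      next_id <- next_id + 1L
    }
  }

  parcels <- do.call(rbind, parcels)

  # smooth multiplicative texture so tissue intensity is not flat
  set.seed(seed)
  noise <- array(stats::rnorm(prod(shape)), dim = shape)
  noise <- gauss_smooth3d(noise, sigma_vox = c(2, 2, 1))
  noise <- noise / max(stats::sd(noise), .Machine$double.eps)

  baseline <- array(0, dim = shape)
  in_brain <- labels > 0L & !(labels %in% parcels$id[parcels$class == "air"])
  baseline[brain] <- baseline_mean * pmax(0.5, 1 + texture_sd * noise[brain])
  baseline[!brain] <- 0
  baseline[labels %in% parcels$id[parcels$class == "air"]] <- 0

  structure(list(labels = labels, baseline = baseline,
                 voxel_size = voxel_size_mm, pe_axis = as.integer(pe_axis),
                 parcels = parcels, brain = brain, seed = seed),
            class = "epi_phantom")
}

#' @export
print.epi_phantom <- function(x, ...) {
  cat("EPI digital phantom\n")
  cat("  dimensions :", paste(dim(x$labels), collapse = " x "), "voxels\n")
  cat("  voxel size :", paste(signif(x$voxel_size, 3), collapse = " x "), "mm\n")
  cat("  parcels    :", sum(x$parcels$class == "cortical"), "cortical,",
      sum(x$parcels$class == "subcortical"), "subcortical,",
      sum(x$parcels$class == "air"), "air\n")
  invisible(x)
}

#' Brain mask of a phantom
#'
#' @param phantom an \code{epi_phantom}.
#' @return logical 3D array, TRUE inside the brain ellipsoid.
#' @export
phantom_brain_mask <- function(phantom) {
  phantom$brain
}

#' Parcel centroid in voxel coordinates
#' @noRd
parcel_centroid <- function(phantom, id) {
  idx <- which(phantom$labels == id, arr.ind = TRUE)
  colMeans(idx)
}

#' B0 off-resonance field map
#'
#' Constructs an off-resonance map (Hz) as a sum of Gaussian bumps centred on
#' the phantom's air-cavity centroids, the standard picture of susceptibility
#' mismatch at air-tissue interfaces. An optional smooth low-order background
#' field can be added on top.
#'
#' @param phantom an \code{epi_phantom} with at least one air-cavity parcel.
#' @param peak_hz peak off-resonance at each cavity centroid (Hz, >= 0).
#' @param width_mm Gaussian SD of each bump in mm.
#' @param seed seed for the background field coefficients (unused when
#'   \code{background_hz = 0}).
#' @param background_hz amplitude of a smooth first-order background field
#'   (Hz); default 0, making the map exactly linear in \code{peak_hz}.
#'
#' @return Object of class \code{epi_fieldmap}: list with \code{delta_f}
#'   (3D array, Hz), \code{voxel_size}, \code{pe_axis}.
#' @export
make_fieldmap <- function(phantom, peak_hz, width_mm = 3, seed = 1,
                          background_hz = 0) {
  stopifnot(inherits(phantom, "epi_phantom"), peak_hz >= 0, width_mm > 0)
  air_ids <- phantom$parcels$id[phantom$parcels$class == "air"]
  if (length(air_ids) == 0L)
    stop("phantom has no air-cavity parcels; cannot build a field map")

  shape <- dim(phantom$labels)
  vs <- phantom$voxel_size
  xs <- array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape) * vs[1]
  ys <- array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
              dim = shape) * vs[2]
  zs <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape) * vs[3]

  delta_f <- array(0, dim = shape)
  for (id in air_ids) {
    ctr <- parcel_centroid(phantom, id) * vs
    d2 <- (xs - ctr[1])^2 + (ys - ctr[2])^2 + (zs - ctr[3])^2
    delta_f <- delta_f + peak_hz * exp(-d2 / (2 * width_mm^2))
  }

  if (background_hz > 0) {
    set.seed(seed)
    co <- stats::rnorm(3)
    bg <- co[1] * (xs - mean(xs)) / max(xs) + co[2] * (ys - mean(ys)) / max(ys) +
      co[3] * (zs - mean(zs)) / max(zs)
    delta_f <- delta_f + background_hz * bg / max(abs(bg))
  }

  structure(list(delta_f = delta_f, voxel_size = vs,
                 pe_axis = phantom$pe_axis),
            class = "epi_fieldmap")
}

#' Separable Gaussian smoothing of a 3D array (FFT-free, reflective edges)
#' @noRd
gauss_smooth3d <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  out <- arr
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

#' 1D convolution along one axis with edge replication
#' @noRd
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  half <- (length(kernel) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- nrow(m)
  pad_top <- m[rep(1L, half), , drop = FALSE]
  pad_bot <- m[rep(n, half), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  res <- matrix(0, nrow = n, ncol = ncol(m))
  for (i in seq_along(kernel))
    res <- res + kernel[i] * mp[i:(i + n - 1L), , drop = FALSE]
  b <- array(res, dim = d[perm])
  aperm(b, order(perm))
}
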