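#' Resting-state network specification
#'
#' Ground-truth networks planted in the phantom: each network is a named set
#' of parcel ids that share a band-limited BOLD-like fluctuation.
#'
#' @param networks list of lists with elements \code{name}, \code{parcels}
#'   (parcel ids), \code{amplitude} (fractional signal change relative to
#'   baseline, e.g. 0.02 for 2\%).
#' @param band_hz pass band of the simulated fluctuations (Hz).
#' @param cross_network_correlation target pairwise correlation between the
#'   time courses of different networks, in [0, 1).
#' @param unique_amplitude fractional amplitude of the region-specific
#'   fluctuation each member parcel carries on top of its network signal
#'   (0 disables it). Spontaneous activity is never purely network-shared,
#'   and these independent regional components keep edge statistics from
#'   collapsing onto a handful of shared time courses.
#' @return object of class \code{network_spec}.
#' @export
network_spec <- function(networks, band_hz = c(0.01, 0.1),
                         cross_network_correlation = 0,
                         unique_amplitude = 0) {
  stopifnot(is.list(networks), length(band_hz) == 2, band_hz[1] > 0,
            band_hz[2] > band_hz[1],
            cross_network_correlation >= 0, cross_network_correlation < 1,
            unique_amplitude >= 0)
  for (nw in networks) {
    stopifnot(!is.null(nw$name), length(nw$parcels) >= 1,
              is.numeric(nw$amplitude), nw$amplitude >= 0)
  }
  structure(list(networks = networks, band_hz = band_hz,
                 cross_network_correlation = cross_network_correlation,
                 unique_amplitude = unique_amplitude),
            class = "network_spec")
}

#' Simulate band-limited network time courses
#'
#' Each network receives a zero-mean, unit-variance time course obtained by
#' band-pass filtering white noise to \code{spec$band_hz}. A shared
#' band-limited factor induces the requested pairwise correlation between
#' different networks.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param n_t number of time points (>= 16).
#' @param tr_vol_s sampling interval (volume TR) in seconds.
#' @param seed integer seed.
#' @return numeric matrix \code{n_t x K} with one column per network.
#' @export
simulate_network_timecourses <- function(spec, n_t, tr_vol_s, seed) {
  stopifnot(inherits(spec, "network_spec"), n_t >= 16, tr_vol_s > 0)
  nyq <- 1 / (2 * tr_vol_s)
  if (spec$band_hz[2] >= nyq)
    stop(sprintf("pass band upper edge %.3g Hz is not below Nyquist %.3g Hz",
                 spec$band_hz[2], nyq))
  k <- length(spec$networks)
  set.seed(seed)
  rho <- spec$cross_network_correlation
  white <- matrix(stats::rnorm(n_t * (k + 1)), nrow = n_t)
  filt <- bandlimit_columns(white, tr_vol_s, spec$band_hz)
  shared <- filt[, 1]
  uniq <- filt[, -1, drop = FALSE]
  tc <- sqrt(rho) * shared + sqrt(1 - rho) * uniq
  tc <- scale(tc)          # zero mean, unit variance per column
  attr(tc, "scaled:center") <- NULL
  attr(tc, "scaled:scale") <- NULL
  colnames(tc) <- vapply(spec$networks, `[[`, "", "name")
  tc
}

#' Hard band-pass of matrix columns in the frequency domain
#' @noRd
bandlimit_columns <- function(m, dt, band) {
  n <- nrow(m)
  f <- (seq_len(n) - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)   # two-sided frequency axis
  h <- as.numeric(f >= band[1] & f <= band[2])
  sp <- stats::mvfft(m) * h
  Re(stats::mvfft(sp, inverse = TRUE)) / n
}

#' Off-resonance displacement along the phase-encode axis
#'
#' Pixel displacement \code{shift = delta_f / pe_bandwidth_per_pixel(seq)}:
#' off-resonance in Hz divided by the per-pixel phase-encode bandwidth.
#' Segmentation enters only through the echo train length, so a 4-shot
#' protocol shows exactly one quarter of the single-shot displacement.
#'
#' @param fmap an \code{epi_fieldmap}.
#' @param seq an \code{epi_seq}.
#' @return object of class \code{pe_displacement}: list with
#'   \code{shift_vox} (signed voxel displacement, 3D) and \code{pe_axis}.
#' @export
pe_displacement <- function(fmap, seq) {
  stopifnot(inherits(fmap, "epi_fieldmap"), inherits(seq, "epi_seq"))
  shift <- fmap$delta_f / pe_bandwidth_per_pixel(seq)
  structure(list(shift_vox = shift, pe_axis = fmap$pe_axis,
                 voxel_size = fmap$voxel_size),
            class = "pe_displacement")
}

#' Susceptibility signal-dropout attenuation map
#'
#' Mesoscopic dropout model: attenuation \code{exp(-TE * dR2s)} with
#' \code{dR2s = kappa * |grad(delta_f)|}, the spatial gradient of the
#' off-resonance field in Hz/mm (central differences, one-sided at the
#' boundary). Attenuation is 1 wherever the field is locally constant.
#'
#' @param fmap an \code{epi_fieldmap}.
#' @param seq an \code{epi_seq} (supplies TE).
#' @param kappa gradient-to-relaxation coupling (s mm); 0 disables dropout.
#' @return 3D attenuation array with values in (0, 1].
#' @export
dropout_map <- function(fmap, seq, kappa) {
  stopifnot(inherits(fmap, "epi_fieldmap"), inherits(seq, "epi_seq"),
            kappa >= 0)
  if (kappa == 0) return(array(1, dim = dim(fmap$delta_f)))
  exp(-(seq$te_ms / 1000) * kappa * fieldmap_gradient_mag(fmap))
}

#' |grad(delta_f)| in Hz/mm
#' @noRd
fieldmap_gradient_mag <- function(fmap) {
  g2 <- array(0, dim = dim(fmap$delta_f))
  for (ax in 1:3) {
    g <- axis_gradient(fmap$delta_f, ax) / fmap$voxel_size[ax]
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

#' Through-readout dephasing attenuation
#'
#' Signal loss accumulating over the EPI echo train: attenuation
#' \code{exp(-T_readout/2 * kappa_readout * |grad(delta_f)|)} with
#' \code{T_readout = ETL * echo_spacing}. Unlike the TE-governed dropout,
#' this term depends on the readout duration, so segmentation (shorter echo
#' train) reduces it directly.
#'
#' @param fmap an \code{epi_fieldmap}.
#' @param seq an \code{epi_seq} (supplies ETL and echo spacing).
#' @param kappa_readout coupling constant (s mm); 0 disables the term.
#' @return 3D attenuation array in (0, 1].
#' @export
readout_dropout_map <- function(fmap, seq, kappa_readout) {
  stopifnot(inherits(fmap, "epi_fieldmap"), inherits(seq, "epi_seq"),
            kappa_readout >= 0)
  if (kappa_readout == 0) return(array(1, dim = dim(fmap$delta_f)))
  t_ro <- seq$etl * seq$echo_spacing_ms / 1000
  exp(-(t_ro / 2) * kappa_readout * fieldmap_gradient_mag(fmap))
}

#' Per-axis gradient, central differences with one-sided stencils at edges
#' @noRd
axis_gradient <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 2) return(array(0, dim = d))
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  denom <- idx_p - idx_m
  slicer <- function(i) {
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- i
    do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  }
  g <- (slicer(idx_p) - slicer(idx_m))
  sweep_dims <- array(rep(denom, each = prod(d[seq_len(axis - 1)])),
                      dim = d)
  g / sweep_dims
}

#' Precompute linear-interpolation weights for a static 1-axis warp
#' @noRd
warp_weights <- function(shift_vox, pe_axis) {
  d <- dim(shift_vox)
  n <- d[pe_axis]
  stride <- c(1, cumprod(d))[pe_axis]
  # phase-encode coordinate of every voxel (1-based)
  pe_idx <- array(rep(rep(seq_len(n),
                          each = prod(d[seq_len(pe_axis - 1)])),
                      length.out = prod(d)), dim = d)
  src <- pe_idx - shift_vox
  i0 <- floor(src)
  w1 <- as.vector(src - i0)
  i0 <- as.vector(i0)
  lin <- seq_len(prod(d))
  base <- lin + (i0 - as.vector(pe_idx)) * stride
  ok0 <- i0 >= 1 & i0 <= n
  ok1 <- (i0 + 1) >= 1 & (i0 + 1) <= n
  list(idx0 = ifelse(ok0, base, 1L), w0 = (1 - w1) * ok0,
       idx1 = ifelse(ok1, base + stride, 1L), w1 = w1 * ok1)
}

#' Apply a precomputed 1-axis warp to a 3D array
#' @noRd
apply_warp <- function(arr, ww) {
  out <- ww$w0 * arr[ww$idx0] + ww$w1 * arr[ww$idx1]
  array(out, dim = dim(arr))
}

#' Simulate an EPI acquisition of the phantom
#'
#' Forward signal model, per volume: baseline x Ernst steady-state factor x
#' dropout attenuation x (1 + sum of network amplitude x membership x
#' network time course), then geometric distortion (warp along the
#' phase-encode axis by the off-resonance displacement, linear
#' interpolation), then volume-level multiplicative inter-shot instability
#' noise, motion-spike corruption (global intensity jump plus a one-voxel
#' translation), and finally additive Gaussian thermal noise. When the
#' displacement is identically zero the warp is an exact pass-through.
#'
#' @param phantom an \code{epi_phantom}.
#' @param fmap an \code{epi_fieldmap} (or NULL for a homogeneous field).
#' @param seq an \code{epi_seq}; supplies geometry, noise levels and n_rep.
#' @param netspec optional \code{\link{network_spec}} of planted networks.
#' @param motion_spike_times integer volume indices (1-based) corrupted by
#'   abrupt motion.
#' @param seed integer seed; the acquisition is a pure function of
#'   (inputs, seed).
#' @param kappa dropout coupling passed to \code{\link{dropout_map}}.
#' @param kappa_readout through-readout dephasing coupling passed to
#'   \code{\link{readout_dropout_map}}; this is the dropout term that
#'   segmentation mitigates.
#' @param spike_scale intensity jump of spike volumes, as a fraction of mean
#'   brain signal.
#' @return object of class \code{epi_volume4d}: list with \code{data}
#'   (4D array x,y,z,t), \code{voxel_size}, \code{tr_vol_s}, \code{meta}.
#' @export
acquire_series <- function(phantom, fmap, seq, netspec = NULL,
                           motion_spike_times = integer(), seed = 1,
                           kappa = 0.02, kappa_readout = 0.7,
                           spike_scale = 0.05) {
  stopifnot(inherits(phantom, "epi_phantom"), inherits(seq, "epi_seq"))
  shape <- dim(phantom$labels)
  if (!is.null(fmap) && !all(dim(fmap$delta_f) == shape))
    stop("field map shape does not match phantom")
  if (!all(seq$matrix == shape))
    stop("sequence matrix does not match phantom shape")
  n_rep <- seq$n_rep
  if (length(motion_spike_times) &&
      (any(motion_spike_times < 1) || any(motion_spike_times > n_rep)))
    stop("motion spike time outside 1..n_rep")

  static <- phantom$baseline *
    ernst_signal(seq$flip_deg, seq$tr_shot_ms, seq$t1_ms)
  if (!is.null(fmap) && kappa > 0)
    static <- static * dropout_map(fmap, seq, kappa)
  if (!is.null(fmap) && kappa_readout > 0)
    static <- static * readout_dropout_map(fmap, seq, kappa_readout)

  # network machinery
  k <- 0L; tc <- NULL; members <- list(); amps <- numeric()
  if (!is.null(netspec) && length(netspec$networks)) {
    ids_all <- phantom$parcels$id
    for (nw in netspec$networks)
      if (!all(nw$parcels %in% ids_all))
        stop("network references parcels absent from the phantom")
    k <- length(netspec$networks)
    tc <- simulate_network_timecourses(netspec, n_t = n_rep,
                                       tr_vol_s = seq$tr_vol_s,
                                       seed = seed + 1L)
    members <- lapply(netspec$networks, function(nw)
      array(phantom$labels %in% nw$parcels, dim = shape))
    amps <- vapply(netspec$networks, `[[`, 0, "amplitude")
  }
  # region-specific fluctuations: one independent band-limited time course
  # per member parcel, on top of the shared network signal
  uniq_tc <- NULL; uniq_members <- list()
  ua <- netspec$unique_amplitude %||% 0
  if (k > 0 && ua > 0) {
    uniq_ids <- sort(unique(unlist(lapply(netspec$networks, `[[`, "parcels"))))
    uspec <- network_spec(lapply(uniq_ids, function(id)
      list(name = paste0("parcel_", id), parcels = id, amplitude = ua)),
      band_hz = netspec$band_hz, cross_network_correlation = 0)
    uniq_tc <- simulate_network_timecourses(uspec, n_t = n_rep,
                                            tr_vol_s = seq$tr_vol_s,
                                            seed = seed + 3L)
    uniq_members <- lapply(uniq_ids, function(id)
      array(phantom$labels == id, dim = shape))
  }

  ww <- NULL; jac_mod <- NULL
  if (!is.null(fmap)) {
    disp <- pe_displacement(fmap, seq)
    if (any(disp$shift_vox != 0)) {
      ww <- warp_weights(disp$shift_vox, phantom$pe_axis)
      # EPI distortion redistributes signal: local stretching dilutes
      # intensity and compression piles it up (Jacobian modulation)
      jac_mod <- pmax(1 - axis_gradient(disp$shift_vox, phantom$pe_axis), 0)
    }
  }

  set.seed(seed + 2L)
  eta <- if (seq$shot_instability > 0)
    stats::rnorm(n_rep, 0, seq$shot_instability) else numeric(n_rep)
  mean_brain <- mean(static[phantom$brain])
  # physiological/system noise floor: spatially smooth fields, band-limited
  # in time to the slow-fluctuation band, so neither parcel averaging nor
  # temporal resampling averages it away
  physio <- NULL
  if (seq$sigma_physio > 0) {
    sig_vox <- seq$physio_fwhm_mm / (2 * sqrt(2 * log(2))) /
      phantom$voxel_size
    nvox <- prod(shape)
    physio <- matrix(0, n_rep, nvox)
    for (t in seq_len(n_rep))
      physio[t, ] <- gauss_smooth3d(array(stats::rnorm(nvox), dim = shape),
                                    sig_vox)
    nyq <- 1 / (2 * seq$tr_vol_s)
    physio <- bandlimit_columns(physio, seq$tr_vol_s,
                                c(0.005, min(0.12, 0.9 * nyq)))
    physio <- physio * (seq$sigma_physio / stats::sd(physio))
  }

  data <- array(0, dim = c(shape, n_rep))
  nvox <- prod(shape)
  for (t in seq_len(n_rep)) {
    vol <- static
    if (k > 0) {
      mod <- 1
      for (j in seq_len(k))
        mod <- mod + amps[j] * members[[j]] * tc[t, j]
      if (!is.null(uniq_tc))
        for (j in seq_along(uniq_members))
          mod <- mod + ua * uniq_members[[j]] * uniq_tc[t, j]
      vol <- vol * mod
    }
    if (!is.null(ww)) vol <- apply_warp(vol, ww) * jac_mod
    vol <- vol * (1 + eta[t])
    if (t %in% motion_spike_times) {
      vol <- shift_axis(vol, phantom$pe_axis, 1L) + spike_scale * mean_brain
    }
    if (!is.null(physio))
      vol <- vol + array(physio[t, ], dim = shape)
    if (seq$sigma_thermal > 0)
      vol <- vol + stats::rnorm(nvox, 0, seq$sigma_thermal)
    data[, , , t] <- vol
  }

  structure(list(data = data, voxel_size = phantom$voxel_size,
                 tr_vol_s = seq$tr_vol_s,
                 meta = list(seq = seq, seed = seed, kappa = kappa,
                             spikes = motion_spike_times,
                             pe_axis = phantom$pe_axis)),
            class = "epi_volume4d")
}

#' @export
print.epi_volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EPI 4D series: %d x %d x %d voxels, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_vol_s))
  invisible(x)
}

#' Integer shift of a 3D array along one axis, zero fill
#' @noRd
shift_axis <- function(arr, axis, by) {
  d <- dim(arr)
  out <- array(0, dim = d)
  n <- d[axis]
  src <- seq_len(n) - by
  keep <- src >= 1 & src <= n
  idx_out <- rep(list(quote(expr = )), 3)
  idx_in <- idx_out
  idx_out[[axis]] <- which(keep)
  idx_in[[axis]] <- src[keep]
  do.call(`[<-`, c(list(out), idx_out,
                   list(do.call(`[`, c(list(arr), idx_in, list(drop = FALSE))))))
}

#' Construct a 4D series object from an array
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxel_size voxel size in mm.
#' @param tr_vol_s volume repetition time (s).
#' @param meta optional provenance list.
#' @return an \code{epi_volume4d}.
#' @export
as_volume4d <- function(data, voxel_size = c(1, 1, 1), tr_vol_s = 1,
                        meta = list()) {
  stopifnot(length(dim(data)) == 4, tr_vol_s > 0, all(is.finite(data)))
  structure(list(data = data, voxel_size = voxel_size, tr_vol_s = tr_vol_s,
                 meta = meta), class = "epi_volume4d")
}
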