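#' EPI sequence parameters
#'
#' Complete description of a gradient-echo EPI protocol, single-shot or
#' segmented (multishot). The phase-encode dimension is split into
#' \code{n_shots * ppi} interleaves, so the echo train length per excitation
#' is \code{ETL = n_pe / (n_shots * ppi)}.
#'
#' @param tr_shot_ms repetition time per excitation (ms). For a segmented
#'   sequence the effective volume TR is \code{tr_shot_ms * n_shots}.
#' @param n_shots number of k-space segments (1 = single-shot).
#' @param n_rep number of repetitions (volumes).
#' @param te_ms echo time (ms).
#' @param flip_deg excitation flip angle (degrees).
#' @param matrix acquisition matrix \code{c(n_ro, n_pe, n_slices)}.
#' @param fov_mm field of view per axis (mm).
#' @param bw_hz readout bandwidth (Hz).
#' @param ppi parallel acceleration factor.
#' @param echo_spacing_ms inter-echo spacing in the EPI train (ms).
#' @param t1_ms,t2s_ms tissue relaxation constants used by the signal model.
#' @param sigma_thermal additive white Gaussian noise SD (signal units).
#' @param sigma_physio SD of the spatially smooth additive noise floor
#'   (physiological/ghosting/system noise, temporally white but correlated
#'   in space, so it does not average out over parcels).
#' @param physio_fwhm_mm spatial FWHM of the smooth noise floor (mm).
#' @param shot_instability SD of volume-level multiplicative inter-shot
#'   instability noise (0 for single-shot).
#'
#' @return Object of class \code{epi_seq} (a validated list).
#' @export
seq_params <- function(tr_shot_ms, n_shots, n_rep, te_ms = 17, flip_deg = 60,
                       matrix = c(96, 96, 16), fov_mm = c(35, 35, 16),
                       bw_hz = 250e3, ppi = 2, echo_spacing_ms = 0.5,
                       t1_ms = 1800, t2s_ms = 40,
                       sigma_thermal = 0, sigma_physio = 0,
                       physio_fwhm_mm = 4.5, shot_instability = 0) {
  stopifnot(n_shots >= 1, ppi >= 1, tr_shot_ms > 0, te_ms > 0,
            echo_spacing_ms > 0, t1_ms > 0, t2s_ms > 0, n_rep >= 0,
            length(matrix) == 3, length(fov_mm) == 3,
            sigma_thermal >= 0, sigma_physio >= 0, physio_fwhm_mm > 0,
            shot_instability >= 0)
  n_pe <- matrix[2]
  if (n_pe %% (n_shots * ppi) != 0)
    stop("n_pe must be divisible by n_shots * ppi")
  etl <- n_pe / (n_shots * ppi)
  structure(list(tr_shot_ms = tr_shot_ms, n_shots = as.integer(n_shots),
                 n_rep = as.integer(n_rep), te_ms = te_ms,
                 flip_deg = flip_deg, matrix = as.integer(matrix),
                 fov_mm = fov_mm, bw_hz = bw_hz, ppi = as.integer(ppi),
                 echo_spacing_ms = echo_spacing_ms, t1_ms = t1_ms,
                 t2s_ms = t2s_ms, sigma_thermal = sigma_thermal,
                 sigma_physio = sigma_physio,
                 physio_fwhm_mm = physio_fwhm_mm,
                 shot_instability = shot_instability,
                 etl = as.integer(etl),
                 tr_vol_s = tr_shot_ms * n_shots / 1000),
            class = "epi_seq")
}

#' @export
print.epi_seq <- function(x, ...) {
  cat(sprintf("EPI protocol: TR %g ms x %d shot(s), TE %g ms, flip %g deg\n",
              x$tr_shot_ms, x$n_shots, x$te_ms, x$flip_deg))
  cat(sprintf("  matrix %s, FOV %s mm, PPI %d, ETL %d, NREP %d\n",
              paste(x$matrix, collapse = "x"),
              paste(x$fov_mm, collapse = "x"), x$ppi, x$etl, x$n_rep))
  cat(sprintf("  volume TR %.3g s, acquisition %.1f min\n",
              x$tr_vol_s, acquisition_time_min(x)))
  invisible(x)
}

#' Segmented (multishot) protocol preset
#'
#' The 4-shot protocol: per-shot TR 500 ms, TE 17 ms, 4 segments,
#' 900 repetitions at full size (2 s volume TR, 30 min).
#'
#' @param matrix,n_rep override matrix size / repetitions, e.g. for reduced
#'   desk-scale simulations.
#' @param ... further overrides passed to \code{\link{seq_params}}.
#' @export
seq_params_ms <- function(matrix = c(96, 96, 16), n_rep = 900, ...) {
  args <- list(tr_shot_ms = 500, n_shots = 4, n_rep = n_rep, matrix = matrix,
               sigma_thermal = 1, sigma_physio = 2,
               shot_instability = 0.002)
  args <- utils::modifyList(args, list(...))
  do.call(seq_params, args)
}

#' Single-shot protocol preset
#'
#' The conventional protocol: TR 1000 ms, TE 17 ms, one shot,
#' 1800 repetitions at full size (1 s volume TR, 30 min).
#'
#' @inheritParams seq_params_ms
#' @export
seq_params_ss <- function(matrix = c(96, 96, 16), n_rep = 1800, ...) {
  # thermal noise is hardware-determined and equal across arms; the
  # physiological noise floor scales with this arm's higher steady-state
  # signal (signal-proportional physiological noise)
  args <- list(tr_shot_ms = 1000, n_shots = 1, n_rep = n_rep, matrix = matrix,
               sigma_thermal = 1, sigma_physio = 2.9,
               shot_instability = 0)
  args <- utils::modifyList(args, list(...))
  do.call(seq_params, args)
}

#' Per-pixel bandwidth along the phase-encode direction
#'
#' The phase-encode bandwidth per pixel is \code{1 / (ETL * echo_spacing)}:
#' segmentation shortens the echo train and so widens the per-pixel
#' bandwidth, reducing off-resonance displacement proportionally.
#'
#' @param seq an \code{epi_seq}.
#' @return bandwidth in Hz per pixel.
#' @export
pe_bandwidth_per_pixel <- function(seq) {
  stopifnot(inherits(seq, "epi_seq"))
  1 / (seq$etl * seq$echo_spacing_ms / 1000)
}

#' Steady-state spoiled gradient-echo signal (Ernst equation)
#'
#' Relative steady-state signal \eqn{S = \sin\alpha (1-E_1)/(1-E_1\cos\alpha)}
#' with \eqn{E_1 = \exp(-TR_{shot}/T_1)}. The maximum over flip angle is at
#' the Ernst angle \eqn{\alpha_E = \arccos E_1}.
#'
#' @param flip_deg flip angle in degrees (0..180).
#' @param tr_shot_ms per-excitation repetition time (ms).
#' @param t1_ms longitudinal relaxation time (ms).
#' @return relative signal in [0, 1].
#' @export
ernst_signal <- function(flip_deg, tr_shot_ms, t1_ms) {
  stopifnot(all(flip_deg >= 0), all(flip_deg <= 180), tr_shot_ms > 0, t1_ms > 0)
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_shot_ms / t1_ms)
  sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Total acquisition time of a protocol
#'
#' @param seq an \code{epi_seq}.
#' @return acquisition time in minutes:
#'   \code{tr_shot_ms * n_shots * n_rep / 60000}.
#' @export
acquisition_time_min <- function(seq) {
  stopifnot(inherits(seq, "epi_seq"))
  seq$tr_shot_ms * seq$n_shots * seq$n_rep / 60000
}
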