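#' Default desk-scale experiment configuration
#'
#' A complete two-arm experiment specification at reduced size: 48 x 48 x 12
#' matrix, 120 multishot volumes (240 single-shot, resampled 2:1), 8
#' subjects per arm, 6 cortical and 6 subcortical parcels per hemisphere,
#' and four planted networks (two cortical, two subcortical) at 2\% BOLD
#' amplitude. The full-size protocol (96 x 96 x 16, 900/1800 volumes,
#' subject ICA order 70, group order 30) is obtained with
#' \code{full_scale = TRUE}.
#'
#' @param full_scale use the full acquisition geometry instead of the
#'   desk-scale default.
#' @return a config list consumed by \code{\link{run_experiment}}.
#' @export
default_experiment_config <- function(full_scale = FALSE) {
  if (full_scale) {
    shape <- c(96, 96, 16); n_rep_ms <- 900; n_rep_ss <- 1800
    ica <- list(enabled = TRUE, n_subject = 70, d_group = 30)
  } else {
    shape <- c(48, 48, 12); n_rep_ms <- 120; n_rep_ss <- 240
    ica <- list(enabled = TRUE, n_subject = 16, d_group = 6)
  }
  list(shape = shape,
       n_cortical = 6, n_subcortical = 6,
       phantom_seed = 11,
       fieldmap = list(peak_hz = 450, width_mm = 3.5),
       network_amplitude = 0.015,
       unique_amplitude = 0.015,
       cross_network_correlation = 0,
       band_hz = c(0.01, 0.1),
       n_rep_ms = n_rep_ms, n_rep_ss = n_rep_ss,
       n_subjects = 8,
       kappa = 0.02,
       kappa_readout = 0.7,
       spike_prob = c(ms = 0.03, ss = 0.01),
       n_perm = 199,
       tfce = list(E = 0.5, H = 2, connectivity = 26),
       power = list(z0 = 2.3, alpha = 0.05, power = 0.8),
       ica = ica,
       master_seed = 1)
}

#' Derive a per-subject seed from the master seed (stated counter scheme)
#' @noRd
subject_seed <- function(master, arm_idx, subj) {
  (abs(master) %% 10000L) * 100000L + arm_idx * 10000L + subj * 7L
}

#' Default planted networks for a phantom
#'
#' Splits each parcel class into an anterior and a posterior bilateral
#' network (four networks total).
#' @param phantom an \code{epi_phantom}.
#' @param amplitude fractional BOLD amplitude.
#' @param band_hz pass band.
#' @param rho cross-network correlation.
#' @param unique_amplitude region-specific fluctuation amplitude.
#' @return a \code{\link{network_spec}}.
#' @export
default_networks <- function(phantom, amplitude = 0.015,
                             band_hz = c(0.01, 0.1), rho = 0,
                             unique_amplitude = 0.015) {
  p <- phantom$parcels
  nets <- list()
  for (cls in c("cortical", "subcortical")) {
    ids_l <- p$id[p$class == cls & p$hemisphere == "L"]
    ids_r <- p$id[p$class == cls & p$hemisphere == "R"]
    half <- ceiling(length(ids_l) / 2)
    nets[[length(nets) + 1]] <- list(
      name = paste0(cls, "_anterior"),
      parcels = c(ids_l[seq_len(half)], ids_r[seq_len(half)]),
      amplitude = amplitude)
    nets[[length(nets) + 1]] <- list(
      name = paste0(cls, "_posterior"),
      parcels = c(ids_l[-seq_len(half)], ids_r[-seq_len(half)]),
      amplitude = amplitude)
  }
  network_spec(nets, band_hz = band_hz, cross_network_correlation = rho,
               unique_amplitude = unique_amplitude)
}

#' Simulate and analyze one subject of one arm
#' @noRd
run_subject <- function(phantom, fmap, seqp, netspec, config, arm_idx,
                        subj) {
  seed <- subject_seed(config$master_seed, arm_idx, subj)
  set.seed(seed)
  arm <- if (arm_idx == 1) "ms" else "ss"
  n_rep <- seqp$n_rep
  spikes <- which(stats::runif(n_rep) < config$spike_prob[[arm]])
  vol <- acquire_series(phantom, fmap, seqp, netspec,
                        motion_spike_times = spikes, seed = seed + 1L,
                        kappa = config$kappa,
                        kappa_readout = config$kappa_readout)
  brain <- phantom_brain_mask(phantom)
  dv <- dvars(vol, brain)
  cen <- censor(dv)
  tsnr <- tsnr_map(vol, mask = brain, keep = cen$keep)
  conf <- make_motion_confounds(n_rep, spikes, seed = seed + 2L)
  clean <- bandpass(regress_confounds(vol, conf),
                    lo_hz = config$band_hz[1], hi_hz = config$band_hz[2])
  pts <- parcellate(clean, phantom)
  list(vol = vol, clean = clean, dvars = dv, censor = cen, tsnr = tsnr,
       pts = pts, spikes = spikes, seed = seed)
}

#' Restrict a parcel time series to kept samples after boxcar resampling
#' @noRd
resample_and_censor <- function(pts, target_dt_s, keep_src) {
  k <- round(target_dt_s / pts$dt_s)
  out <- resample_to_rate(pts, target_dt_s)
  n_out <- ncol(out$ts)
  bin_keep <- vapply(seq_len(n_out), function(b)
    all(keep_src[((b - 1) * k + 1):(b * k)]), TRUE)
  out$ts <- out$ts[, bin_keep, drop = FALSE]
  out
}

#' Run the full two-arm experiment
#'
#' Simulates every subject of both acquisition arms from one phantom and
#' field map, runs the complete analysis chain (censoring, tSNR and its
#' TFCE/permutation comparison, Dice and Jacobian distortion metrics,
#' optional ICA + dual regression with arm comparison, adjacency-matrix
#' consistency with paired arm tests and power analysis), and returns a
#' machine-readable report. Fully reproducible from (config, master seed):
#' per-subject seeds are derived from the master seed by a fixed counter
#' scheme, and the report carries the config hash.
#'
#' @param config list from \code{\link{default_experiment_config}} (fields
#'   may be overridden).
#' @param out_dir optional directory; when given, \code{report.json} and
#'   \code{config.json} are written there.
#' @param stages subset of \code{c("qc", "spatial", "connectome",
#'   "networks")} to run (the simulation always runs).
#' @return the report list, invisibly when writing to disk.
#' @export
run_experiment <- function(config = default_experiment_config(),
                           out_dir = NULL,
                           stages = c("qc", "spatial", "connectome",
                                      "networks")) {
  if (config$n_subjects < 2)
    stop("group statistics require at least 2 subjects per arm ",
         "(and the permutation tests at least 3)")
  phantom <- make_phantom(config$shape, config$n_cortical,
                          config$n_subcortical, seed = config$phantom_seed)
  fmap <- make_fieldmap(phantom, peak_hz = config$fieldmap$peak_hz,
                        width_mm = config$fieldmap$width_mm)
  netspec <- default_networks(phantom,
                              amplitude = config$network_amplitude,
                              band_hz = config$band_hz,
                              rho = config$cross_network_correlation,
                              unique_amplitude = config$unique_amplitude)
  seq_ms <- seq_params_ms(matrix = config$shape, n_rep = config$n_rep_ms)
  seq_ss <- seq_params_ss(matrix = config$shape, n_rep = config$n_rep_ss)
  brain <- phantom_brain_mask(phantom)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)

  subjects <- list(ms = list(), ss = list())
  for (arm_idx in 1:2) {
    arm <- c("ms", "ss")[arm_idx]
    seqp <- if (arm == "ms") seq_ms else seq_ss
    for (s in seq_len(config$n_subjects))
      subjects[[arm]][[s]] <- run_subject(phantom, fmap, seqp, netspec,
                                          config, arm_idx, s)
  }

  report <- list(config_hash = cfg_hash,
                 master_seed = config$master_seed,
                 protocol = list(
                   acq_time_ms_min = acquisition_time_min(seq_ms),
                   acq_time_ss_min = acquisition_time_min(seq_ss),
                   pe_bw_ms_hz = pe_bandwidth_per_pixel(seq_ms),
                   pe_bw_ss_hz = pe_bandwidth_per_pixel(seq_ss)),
                 censoring = list(
                   frac_ms = mean(vapply(subjects$ms,
                                         function(x) x$censor$fraction, 0)),
                   frac_ss = mean(vapply(subjects$ss,
                                         function(x) x$censor$fraction, 0))))

  cort_mask <- array(phantom$labels %in%
                       phantom$parcels$id[phantom$parcels$class == "cortical"],
                     dim = dim(phantom$labels))
  sub_mask <- array(phantom$labels %in%
                      phantom$parcels$id[phantom$parcels$class ==
                                           "subcortical"],
                    dim = dim(phantom$labels))

  if ("qc" %in% stages) {
    tsnr_ms <- lapply(subjects$ms, `[[`, "tsnr")
    tsnr_ss <- lapply(subjects$ss, `[[`, "tsnr")
    mean_roi <- function(maps, roi) mean(vapply(maps, function(m)
      mean(m$tsnr[roi & m$valid]), 0))
    cmp <- compare_tsnr(tsnr_ms, tsnr_ss, n_perm = config$n_perm,
                        seed = config$master_seed + 101L, mask = brain,
                        E = config$tfce$E, H = config$tfce$H,
                        connectivity = config$tfce$connectivity)
    sig_ms <- cmp$fwe_one_minus_p > 0.95
    report$qc <- list(
      tsnr_cortical_ms = mean_roi(tsnr_ms, cort_mask),
      tsnr_cortical_ss = mean_roi(tsnr_ss, cort_mask),
      tsnr_subcortical_ms = mean_roi(tsnr_ms, sub_mask),
      tsnr_subcortical_ss = mean_roi(tsnr_ss, sub_mask),
      n_sig_ms_gt_ss_subcortical = sum(sig_ms & sub_mask),
      n_sig_ms_gt_ss_cortical = sum(sig_ms & cort_mask),
      n_sig_ss_gt_ms = sum(cmp$fwe_one_minus_p_neg > 0.95 & brain))
    sub_parcels <- phantom$parcels[phantom$parcels$class == "subcortical", ]
    per_parcel <- function(maps, id) {
      roi <- phantom$labels == id
      mean(vapply(maps, function(m) mean(m$tsnr[roi & m$valid]), 0))
    }
    report$qc$tsnr_subcortical_parcels <- data.frame(
      name = sub_parcels$name,
      ms = vapply(sub_parcels$id, function(i) per_parcel(tsnr_ms, i), 0),
      ss = vapply(sub_parcels$id, function(i) per_parcel(tsnr_ss, i), 0),
      stringsAsFactors = FALSE)
    report$qc_statmap <- cmp
  }

  if ("spatial" %in% stages) {
    dice_arm <- function(arm) vapply(subjects[[arm]], function(x)
      dice(brain_mask_from_volume(x$vol), brain), 0)
    d_ms <- dice_arm("ms"); d_ss <- dice_arm("ss")
    jm <- list()
    for (arm in c("ms", "ss")) {
      seqp <- if (arm == "ms") seq_ms else seq_ss
      dw <- dewarp(as_volume4d(array(phantom$baseline,
                                     dim = c(dim(phantom$baseline), 1)),
                               voxel_size = phantom$voxel_size),
                   fmap, seqp)
      jm[[arm]] <- jacobian_summary(jacobian_map(dw$warp), brain)
    }
    report$spatial <- list(
      dice_ms_mean = mean(d_ms), dice_ms_sd = stats::sd(d_ms),
      dice_ss_mean = mean(d_ss), dice_ss_sd = stats::sd(d_ss),
      dice_p = tryCatch(stats::t.test(d_ms, d_ss)$p.value,
                        error = function(e) NA_real_),
      jac_tail_above_ms = jm$ms$tail_above,
      jac_tail_above_ss = jm$ss$tail_above,
      jac_tail_below_ms = jm$ms$tail_below,
      jac_tail_below_ss = jm$ss$tail_below)
  }

  if ("connectome" %in% stages) {
    adj <- list()
    for (arm in c("ms", "ss")) {
      adj[[arm]] <- lapply(subjects[[arm]], function(x) {
        pts <- if (arm == "ss")
          resample_and_censor(x$pts, seq_ms$tr_vol_s, x$censor$keep)
        else {
          p <- x$pts
          p$ts <- p$ts[, x$censor$keep, drop = FALSE]
          p
        }
        adjacency(pts)
      })
    }
    cons_ms <- group_consistency(adj$ms)
    cons_ss <- group_consistency(adj$ss)
    arm_cmp <- compare_arms(cons_ms, cons_ss)
    pw <- config$power
    ss_ms <- sample_size_analysis(cons_ms, z0 = pw$z0, alpha = pw$alpha,
                                  power = pw$power, stratum = "subcortical")
    ss_ss <- sample_size_analysis(cons_ss, z0 = pw$z0, alpha = pw$alpha,
                                  power = pw$power, stratum = "subcortical")
    report$connectome <- list(
      summary_ms = cons_ms$summary, summary_ss = cons_ss$summary,
      tests = arm_cmp$tests,
      sample_size_ms = ss_ms, sample_size_ss = ss_ss)
    report$consistency <- list(ms = cons_ms, ss = cons_ss,
                               comparison = arm_cmp)
  }

  if ("networks" %in% stages && isTRUE(config$ica$enabled)) {
    denoised <- list()
    arms_vec <- character()
    for (arm in c("ms", "ss")) {
      for (s in seq_along(subjects[[arm]])) {
        x <- subjects[[arm]][[s]]
        cs <- subject_ica(x$clean, brain,
                          n_components = config$ica$n_subject,
                          seed = x$seed + 4L)
        cs <- classify_components(cs, brain)
        denoised[[length(denoised) + 1]] <- denoise_nonaggressive(x$clean, cs)
        arms_vec <- c(arms_vec, arm)
      }
    }
    gica <- group_ica(denoised, brain, d = config$ica$d_group,
                      seed = config$master_seed + 301L, arms = arms_vec)
    sub_frac <- apply(abs(gica$maps), 1, function(m) {
      v <- as.vector(sub_mask)[as.vector(brain)]
      sum(m[v]) / sum(m)
    })
    sub_comps <- which(sub_frac >= 0.5)
    dr <- lapply(denoised, function(v) dual_regression(gica, v))
    n_a <- sum(arms_vec == "ms")
    report$networks <- list(
      n_components = config$ica$d_group,
      subcortical_components = as.integer(sub_comps),
      subcortical_mass = sub_frac)
    if (length(sub_comps) >= 1) {
      cmp_nw <- compare_component_maps(
        lapply(dr[arms_vec == "ms"], `[[`, "maps"),
        lapply(dr[arms_vec == "ss"], `[[`, "maps"),
        mask = brain, component_ids = sub_comps,
        n_perm = config$n_perm, seed = config$master_seed + 401L)
      report$networks$max_one_minus_p <- vapply(cmp_nw, function(sm)
        max(sm$fwe_one_minus_p), 0)
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(cfg_json, file.path(out_dir, "config.json"))
    serializable <- report[!(names(report) %in%
                               c("qc_statmap", "consistency"))]
    jsonlite::write_json(serializable, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}
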