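#' Atlas-based parcellation of a 4D series
#'
#' Spatial mean of every brain parcel at each retained time point. Parcels
#' smaller than 2 voxels are flagged and their rows filled with NA.
#'
#' @param vol an \code{epi_volume4d}.
#' @param atlas either an \code{epi_phantom} or a 3D integer label array.
#' @param parcels data.frame with columns id, name, hemisphere, class
#'   (taken from the phantom when one is given). Air and background labels
#'   are never parcellated.
#' @param keep optional logical censor mask over volumes (TRUE = retain).
#' @return object of class \code{parcel_timeseries}: list with \code{ts}
#'   (n_roi x n_t matrix), \code{roi} (data.frame), \code{dt_s},
#'   \code{flagged} (too-small parcel ids).
#' @export
parcellate <- function(vol, atlas, parcels = NULL, keep = NULL) {
  stopifnot(inherits(vol, "epi_volume4d"))
  if (inherits(atlas, "epi_phantom")) {
    parcels <- atlas$parcels
    labels <- atlas$labels
  } else labels <- atlas
  if (is.null(parcels)) stop("parcel table required")
  if (!all(dim(labels) == dim(vol$data)[1:3]))
    stop("atlas shape does not match volume")
  roi <- parcels[parcels$class %in% c("cortical", "subcortical"), ,
                 drop = FALSE]
  d <- dim(vol$data)
  if (is.null(keep)) keep <- rep(TRUE, d[4])
  y <- vol_to_matrix(vol)[keep, , drop = FALSE]
  lab_v <- as.vector(labels)
  ts <- matrix(NA_real_, nrow = nrow(roi), ncol = nrow(y))
  flagged <- integer()
  for (i in seq_len(nrow(roi))) {
    sel <- lab_v == roi$id[i]
    nvox <- sum(sel)
    if (nvox < 2) {
      flagged <- c(flagged, roi$id[i])
      warning("parcel ", roi$id[i], " has fewer than 2 voxels; flagged")
      next
    }
    ts[i, ] <- rowMeans(y[, sel, drop = FALSE])
  }
  rownames(ts) <- roi$name
  structure(list(ts = ts, roi = roi, dt_s = vol$tr_vol_s,
                 flagged = flagged),
            class = "parcel_timeseries")
}

#' Downsample parcel time series by boxcar averaging
#'
#' Averages k consecutive samples (k = target_dt / source_dt, which must be
#' an integer), matching the sampling rate of a slower acquisition while
#' anti-aliasing the band-limited fluctuations.
#'
#' @param pts a \code{parcel_timeseries}.
#' @param target_dt_s target sampling interval (s).
#' @return resampled \code{parcel_timeseries} of length
#'   \code{floor(n_t / k)}.
#' @export
resample_to_rate <- function(pts, target_dt_s) {
  stopifnot(inherits(pts, "parcel_timeseries"), target_dt_s > 0)
  ratio <- target_dt_s / pts$dt_s
  k <- round(ratio)
  if (abs(ratio - k) > 1e-8 || k < 1)
    stop("target_dt_s must be an integer multiple of the source interval")
  if (k == 1) return(pts)
  n_t <- ncol(pts$ts)
  n_out <- floor(n_t / k)
  idx <- matrix(seq_len(n_out * k), nrow = k)
  out <- pts
  out$ts <- t(apply(pts$ts, 1, function(x) colMeans(matrix(x[seq_len(n_out * k)],
                                                           nrow = k))))
  out$dt_s <- target_dt_s
  out
}

#' Fisher-z adjacency matrix of parcel time series
#'
#' Pairwise Pearson correlation over the retained time points, clipped in
#' magnitude to \code{1 - 1e-7} and Fisher-transformed. The diagonal is
#' masked (NA). Zero-variance parcels get NA edges and are reported in
#' \code{flagged}; edges at the clipping bound are reported in
#' \code{clipped}.
#'
#' @param pts a \code{parcel_timeseries} with at least 8 time points.
#' @return object of class \code{adjacency_matrix}: list with \code{z}
#'   (symmetric n_roi x n_roi), \code{roi}, \code{n_t}, \code{flagged},
#'   \code{clipped} (logical matrix).
#' @export
adjacency <- function(pts) {
  stopifnot(inherits(pts, "parcel_timeseries"))
  n_t <- ncol(pts$ts)
  if (n_t < 8) stop("adjacency needs at least 8 time points")
  x <- t(pts$ts)
  sds <- apply(x, 2, stats::sd)
  flagged <- which(is.na(sds) | sds == 0)
  r <- suppressWarnings(stats::cor(x))
  clip <- 1 - 1e-7
  clipped <- !is.na(r) & abs(r) >= clip
  z <- fisher_z(ifelse(is.na(r), 0, r))
  z[is.na(r)] <- NA_real_
  diag(z) <- NA_real_
  diag(clipped) <- FALSE
  z[flagged, ] <- NA_real_
  z[, flagged] <- NA_real_
  structure(list(z = z, roi = pts$roi, n_t = n_t,
                 flagged = pts$roi$id[flagged], clipped = clipped),
            class = "adjacency_matrix")
}

#' Edge strata from an ROI table
#'
#' "cortical" edges join two cortical parcels; "subcortical" edges have at
#' least one subcortical endpoint; "all" is every off-diagonal edge.
#' @noRd
edge_strata <- function(roi) {
  n <- nrow(roi)
  cort <- roi$class == "cortical"
  ut <- upper.tri(matrix(0, n, n))
  both_cort <- outer(cort, cort, `&`) & ut
  any_sub <- outer(!cort, !cort, `|`) & ut
  list(all = ut, cortical = both_cort, subcortical = any_sub)
}

#' Group-level consistency of pairwise correlations
#'
#' For every edge, a one-sample t test across subjects on the Fisher-z
#' values, expressed as a z-statistic ("robustness", clamped at |z| = 8).
#' Summaries (mean z across subjects, between-subject SD, and the
#' mean-to-SD ratio) are reported over all edges, cortico-cortical edges,
#' and edges with at least one subcortical endpoint.
#'
#' @param mats list of \code{adjacency_matrix} from >= 3 subjects of one
#'   arm, identical parcellation.
#' @return object of class \code{consistency_result}: list with
#'   \code{zstat} (edge-wise group z matrix), \code{edge_mean},
#'   \code{edge_sd} (across subjects), \code{summary} (data.frame per
#'   stratum), \code{roi}, \code{n_subjects}, \code{subject_z}
#'   (subjects x edges, upper triangle), \code{strata}.
#' @export
group_consistency <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 3)
  n_roi <- nrow(mats[[1]]$z)
  for (m in mats)
    if (nrow(m$z) != n_roi) stop("subject adjacency matrices differ in size")
  roi <- mats[[1]]$roi
  n_sub <- length(mats)
  ut <- upper.tri(mats[[1]]$z)
  subject_z <- t(vapply(mats, function(m) m$z[ut], numeric(sum(ut))))

  mu <- colMeans(subject_z)
  sdv <- apply(subject_z, 2, stats::sd)
  tstat <- ifelse(sdv > 0, mu / (sdv / sqrt(n_sub)),
                  sign(mu) * Inf)
  zstat_v <- t_to_z(tstat, n_sub - 1)

  to_mat <- function(v) {
    m <- matrix(NA_real_, n_roi, n_roi)
    m[ut] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  strata <- edge_strata(roi)
  summ <- do.call(rbind, lapply(names(strata), function(nm) {
    sel <- strata[[nm]][ut]
    data.frame(stratum = nm,
               n_edges = sum(sel),
               mean_z = mean(mu[sel], na.rm = TRUE),
               sd_z = mean(sdv[sel], na.rm = TRUE),
               ratio = mean(mu[sel], na.rm = TRUE) /
                 mean(sdv[sel], na.rm = TRUE),
               mean_zstat = mean(zstat_v[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(zstat = to_mat(zstat_v), edge_mean = to_mat(mu),
                 edge_sd = to_mat(sdv), summary = summ, roi = roi,
                 n_subjects = n_sub, subject_z = subject_z,
                 strata = strata),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("consistency_result: %d subjects, %d ROIs\n",
              x$n_subjects, nrow(x$roi)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare edge-wise consistency between two acquisition arms
#'
#' Paired Wilcoxon signed-rank tests across matched edges on the group
#' z-statistics, per stratum (whole brain, cortico-cortical, subcortical),
#' plus the mean/SD consistency ratios and edge-histogram summaries.
#'
#' @param res_a,res_b \code{consistency_result} objects with identical
#'   parcellations (arm a vs arm b).
#' @param breaks histogram breaks for the z-stat distributions.
#' @return list with \code{tests} (data.frame: stratum, p_two_sided,
#'   p_a_greater, median_diff, ratio_a, ratio_b) and \code{histograms}.
#' @export
compare_arms <- function(res_a, res_b, breaks = seq(-8.5, 8.5, by = 0.5)) {
  stopifnot(inherits(res_a, "consistency_result"),
            inherits(res_b, "consistency_result"))
  if (!identical(dim(res_a$zstat), dim(res_b$zstat)))
    stop("edge sets do not match between arms")
  ut <- upper.tri(res_a$zstat)
  za <- res_a$zstat[ut]
  zb <- res_b$zstat[ut]
  strata <- res_a$strata
  tests <- do.call(rbind, lapply(names(strata), function(nm) {
    sel <- strata[[nm]][ut]
    a <- za[sel]; b <- zb[sel]
    if (all(a == b)) {
      p2 <- 1; pg <- 1
    } else {
      p2 <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
      pg <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                               alternative = "greater")$p.value
    }
    ra <- res_a$summary$ratio[res_a$summary$stratum == nm]
    rb <- res_b$summary$ratio[res_b$summary$stratum == nm]
    data.frame(stratum = nm, n_edges = sum(sel),
               p_two_sided = p2, p_a_greater = pg,
               median_diff = stats::median(a - b),
               ratio_a = ra, ratio_b = rb, stringsAsFactors = FALSE)
  }))
  hists <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]][ut]
    list(stratum = nm,
         a = graphics::hist(pmin(pmax(za[sel], min(breaks)), max(breaks)),
                            breaks = breaks, plot = FALSE)$counts,
         b = graphics::hist(pmin(pmax(zb[sel], min(breaks)), max(breaks)),
                            breaks = breaks, plot = FALSE)$counts,
         mids = graphics::hist(0, breaks = breaks, plot = FALSE)$mids)
  })
  names(hists) <- names(strata)
  list(tests = tests, histograms = hists)
}

#' Sample size required for group-level edge detection
#'
#' Power analysis of the one-sample t test on stratum-average Fisher-z
#' values. Two effect-size modes are reported: \code{plain}, d = mean /
#' between-subject SD of the per-subject stratum-average z; and
#' \code{offset}, d = (mean - z0) / SD, testing exceedance of a
#' cluster-forming threshold z0 (default 2.3).
#'
#' @param res a \code{consistency_result}.
#' @param z0 offset threshold for the \code{offset} mode.
#' @param alpha,power test level and target power.
#' @param stratum one of "all", "cortical", "subcortical".
#' @return data.frame with mode, effect size d, and required n (NA with
#'   reason "not achievable" when d <= 0).
#' @export
sample_size_analysis <- function(res, z0 = 2.3, alpha = 0.05, power = 0.8,
                                 stratum = "subcortical") {
  stopifnot(inherits(res, "consistency_result"),
            stratum %in% names(res$strata))
  ut <- upper.tri(res$zstat)
  sel <- res$strata[[stratum]][ut]
  if (!any(sel)) stop("empty stratum")
  per_subject <- rowMeans(res$subject_z[, sel, drop = FALSE], na.rm = TRUE)
  mu <- mean(per_subject)
  sdv <- stats::sd(per_subject)
  modes <- data.frame(mode = c("plain", "offset"),
                      d = c(mu / sdv, (mu - z0) / sdv),
                      stringsAsFactors = FALSE)
  modes$n <- NA_integer_
  modes$note <- ""
  for (i in 1:2) {
    if (is.finite(modes$d[i]) && modes$d[i] > 0) {
      modes$n[i] <- required_sample_size(modes$d[i], alpha = alpha,
                                         power = power)
    } else modes$note[i] <- "not achievable"
  }
  modes
}
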