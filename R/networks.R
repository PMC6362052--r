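#' Fixed-point symmetric ICA on whitened data
#'
#' Negentropy-maximising fixed-point iteration with tanh contrast and
#' symmetric decorrelation; z is k x N whitened (unit-variance,
#' uncorrelated rows).
#' @return unmixing matrix W (k x k) with attribute "converged".
#' @noRd
fastica_symmetric <- function(z, tol = 1e-6, max_iter = 500) {
  k <- nrow(z); N <- ncol(z)
  w <- matrix(stats::rnorm(k * k), k, k)
  w <- sym_decorrelate(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    w_new <- g %*% t(z) / N - diag(gp, k) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(1 - abs(rowSums(w_new * w))))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  attr(w, "converged") <- converged
  w
}

#' Symmetric decorrelation W <- (W W^T)^{-1/2} W
#' @noRd
sym_decorrelate <- function(w) {
  e <- eigen(w %*% t(w), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), nrow = length(vals)) %*%
    t(e$vectors) %*% w
}

#' Core spatial ICA on a time-by-voxel matrix
#' @noRd
spatial_ica_core <- function(y, n_components, seed, max_attempts = 3) {
  n_t <- nrow(y); n_v <- ncol(y)
  if (n_components >= n_t)
    stop("n_components must be smaller than the number of time points")
  y <- sweep(y, 2, colMeans(y))        # demean each voxel over time
  sv <- svd(y, nu = n_components, nv = n_components)
  if (sv$d[n_components] < 1e-10 * sv$d[1])
    warning("data rank below requested number of components")
  # principal-component spatial scores, centred and whitened over voxels
  p <- diag(sv$d[seq_len(n_components)], n_components) %*% t(sv$v)
  p <- p - rowMeans(p)
  cv <- p %*% t(p) / n_v
  ec <- eigen(cv, symmetric = TRUE)
  z <- diag(1 / sqrt(pmax(ec$values, .Machine$double.eps)),
            n_components) %*% t(ec$vectors) %*% p

  w <- NULL
  for (attempt in seq_len(max_attempts)) {
    set.seed(seed + 1000L * (attempt - 1L))
    w_try <- fastica_symmetric(z)
    if (attr(w_try, "converged")) { w <- w_try; break }
  }
  if (is.null(w))
    stop("ICA failed to converge after ", max_attempts, " seeded restarts")

  maps <- w %*% z                       # k x V independent spatial maps
  # time courses by least squares of the maps against the data
  mm <- maps %*% t(maps)
  tc <- y %*% t(maps) %*% solve(mm)
  # explained variance per component (maps are near-orthogonal)
  ev <- colSums(tc^2) * rowSums(maps^2) / (n_t * n_v)
  ord <- order(ev, decreasing = TRUE)
  maps <- maps[ord, , drop = FALSE]
  tc <- tc[, ord, drop = FALSE]
  ev <- ev[ord]
  # sign convention: positive skew of the spatial map
  for (i in seq_len(n_components)) {
    sk <- mean((maps[i, ] - mean(maps[i, ]))^3)
    if (sk < 0) { maps[i, ] <- -maps[i, ]; tc[, i] <- -tc[, i] }
  }
  # z-score maps over analysis voxels
  maps <- (maps - rowMeans(maps)) /
    apply(maps, 1, stats::sd)
  list(maps = maps, tc = tc, ev = ev)
}

#' Subject-level spatial ICA
#'
#' PCA reduction of the voxel-by-time data to \code{n_components}
#' dimensions followed by fixed-point negentropy-maximising ICA (symmetric
#' decorrelation, tanh contrast, tolerance 1e-6, at most 500 iterations;
#' non-convergence triggers up to 3 seeded restarts). Components are
#' ordered by explained variance, spatial maps z-scored over the analysis
#' mask with a positive-skew sign convention.
#'
#' @param vol an \code{epi_volume4d} with more time points than components.
#' @param mask logical 3D analysis mask.
#' @param n_components model order (the subject-level default in this
#'   pipeline is 70 at full scale).
#' @param seed integer seed (deterministic given the seed).
#' @return object of class \code{component_set}: list with \code{maps}
#'   (k x V over mask voxels), \code{tc} (t x k), \code{mask},
#'   \code{labels}, \code{ev}, \code{tr_vol_s}, \code{meta}.
#' @export
subject_ica <- function(vol, mask, n_components = 70, seed = 1) {
  stopifnot(inherits(vol, "epi_volume4d"))
  y <- vol_to_matrix(vol)[, as.vector(mask), drop = FALSE]
  res <- spatial_ica_core(y, n_components, seed)
  structure(list(maps = res$maps, tc = res$tc, mask = mask,
                 labels = rep("unlabeled", n_components),
                 ev = res$ev, tr_vol_s = vol$tr_vol_s,
                 meta = list(level = "subject", seed = seed,
                             algorithm = "fixed-point tanh ICA")),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set: %d components over %d voxels (%s level)\n",
              nrow(x$maps), ncol(x$maps), x$meta$level))
  if (any(x$labels != "unlabeled"))
    cat("  labels:", sum(x$labels == "signal"), "signal,",
        sum(x$labels == "noise"), "noise\n")
  invisible(x)
}

#' Rule-based component classification
#'
#' Deterministic replacement for hand labeling: a component is noise iff
#' any rule fires: (i) more than half its time-course spectral power lies
#' above \code{hf_cut_hz}; (ii) more than a third of its absolute spatial
#' mass lies outside the brain mask; (iii) its time course has excess
#' kurtosis above 10 (spike trains). Thresholds are configurable.
#'
#' @param cs a \code{component_set}.
#' @param brain_mask logical 3D array of true brain voxels.
#' @param tr_vol_s sampling interval of the time courses (defaults to the
#'   value stored in \code{cs}).
#' @param rules list overriding \code{hf_cut_hz} (0.1), \code{hf_frac}
#'   (0.5), \code{out_frac} (0.33), \code{kurtosis} (10).
#' @return the \code{component_set} with labels filled in.
#' @export
classify_components <- function(cs, brain_mask, tr_vol_s = NULL,
                                rules = list()) {
  stopifnot(inherits(cs, "component_set"))
  r <- utils::modifyList(list(hf_cut_hz = 0.1, hf_frac = 0.5,
                              out_frac = 0.33, kurtosis = 10), rules)
  if (is.null(tr_vol_s)) tr_vol_s <- cs$tr_vol_s
  in_brain <- as.vector(brain_mask)[as.vector(cs$mask)]
  k <- nrow(cs$maps)
  n_t <- nrow(cs$tc)
  f <- (seq_len(n_t) - 1) / (n_t * tr_vol_s)
  f <- pmin(f, 1 / tr_vol_s - f)
  labels <- character(k)
  for (i in seq_len(k)) {
    tc <- cs$tc[, i] - mean(cs$tc[, i])
    pw <- Mod(stats::fft(tc))^2
    hf <- sum(pw[f > r$hf_cut_hz]) / max(sum(pw), .Machine$double.eps)
    mass <- abs(cs$maps[i, ])
    outside <- sum(mass[!in_brain]) / max(sum(mass), .Machine$double.eps)
    kurt <- mean(tc^4) / max(mean(tc^2)^2, .Machine$double.eps) - 3
    labels[i] <- if (hf > r$hf_frac || outside > r$out_frac ||
                     kurt > r$kurtosis) "noise" else "signal"
  }
  cs$labels <- labels
  cs
}

#' Non-aggressive removal of noise components
#'
#' Fits all component time courses jointly to every voxel by least squares
#' and subtracts only the partial fit attributable to noise-labeled
#' components, i.e. only the variance uniquely explained by them. With no
#' noise labels the data pass through unchanged.
#'
#' @param vol an \code{epi_volume4d}.
#' @param cs a labeled \code{component_set} whose time courses match the
#'   series length.
#' @return denoised \code{epi_volume4d}.
#' @export
denoise_nonaggressive <- function(vol, cs) {
  stopifnot(inherits(vol, "epi_volume4d"), inherits(cs, "component_set"))
  noise <- cs$labels == "noise"
  if (!any(noise)) return(vol)
  a <- cs$tc
  if (nrow(a) != dim(vol$data)[4])
    stop("component time courses do not match series length")
  y <- vol_to_matrix(vol)
  beta <- solve(crossprod(a), crossprod(a, y))
  clean <- y - a[, noise, drop = FALSE] %*% beta[noise, , drop = FALSE]
  matrix_to_vol(clean, vol)
}

#' Group-level spatial ICA by temporal concatenation
#'
#' Each subject's series is voxelwise-demeaned and scaled to unit global
#' SD, the series are concatenated in time, and the same fixed-point ICA is
#' run at reduced order \code{d}. Pooling both acquisition arms in one call
#' keeps the group components unbiased with respect to arm; a single-arm
#' input triggers a warning.
#'
#' @param subjects list of \code{epi_volume4d} (>= 2), identical grids.
#' @param mask logical 3D analysis mask.
#' @param d group model order (the group-level default in this pipeline is
#'   30 at full scale).
#' @param seed integer seed.
#' @param arms optional vector naming each subject's acquisition arm, used
#'   only for the pooling check and metadata.
#' @return a \code{component_set} (group level).
#' @export
group_ica <- function(subjects, mask, d = 30, seed = 1, arms = NULL) {
  stopifnot(is.list(subjects), length(subjects) >= 2)
  dims <- dim(subjects[[1]]$data)[1:3]
  for (s in subjects)
    if (!all(dim(s$data)[1:3] == dims)) stop("subject grids do not match")
  if (!is.null(arms) && length(unique(arms)) < 2)
    warning("group ICA on a single arm: components are not arm-unbiased")
  ys <- lapply(subjects, function(s) {
    y <- vol_to_matrix(s)[, as.vector(mask), drop = FALSE]
    y <- sweep(y, 2, colMeans(y))
    y / max(stats::sd(y), .Machine$double.eps)
  })
  y <- do.call(rbind, ys)
  res <- spatial_ica_core(y, d, seed)
  structure(list(maps = res$maps, tc = res$tc, mask = mask,
                 labels = rep("unlabeled", d), ev = res$ev,
                 tr_vol_s = subjects[[1]]$tr_vol_s,
                 meta = list(level = "group", seed = seed, arms = arms,
                             pooled = is.null(arms) ||
                               length(unique(arms)) > 1)),
            class = "component_set")
}

#' Dual regression of group components into a subject
#'
#' Stage 1 regresses the (demeaned) group spatial maps against each time
#' point of the subject's series, yielding subject-specific component time
#' courses. Stage 2 regresses those time courses (variance-normalized,
#' with intercept) against each voxel's series, yielding subject-specific
#' spatial maps.
#'
#' @param group_maps a group-level \code{component_set}, or a k x V matrix
#'   with an accompanying \code{mask}.
#' @param vol the subject's \code{epi_volume4d} on the same grid.
#' @param mask logical 3D mask (taken from the component set when given).
#' @return list with \code{tc} (t x k) and \code{maps} (k x V over mask).
#' @export
dual_regression <- function(group_maps, vol, mask = NULL) {
  stopifnot(inherits(vol, "epi_volume4d"))
  if (inherits(group_maps, "component_set")) {
    mask <- group_maps$mask
    gm <- group_maps$maps
  } else {
    gm <- group_maps
    stopifnot(!is.null(mask))
  }
  k <- nrow(gm)
  y <- vol_to_matrix(vol)[, as.vector(mask), drop = FALSE]
  x1 <- t(gm)                          # V x k design
  x1 <- sweep(x1, 2, colMeans(x1))
  q1 <- qr(x1)
  if (q1$rank < k) {
    bad <- q1$pivot[(q1$rank + 1):k]
    stop("collinear group components in stage 1: ",
         paste(bad, collapse = ", "))
  }
  tc <- t(qr.coef(q1, t(sweep(y, 1, rowMeans(y)))))   # t x k
  tcs <- apply(tc, 2, stats::sd)
  if (any(tcs == 0)) stop("degenerate stage-1 time course")
  z <- cbind(1, sweep(tc, 2, tcs, "/"))
  q2 <- qr(z)
  if (q2$rank < ncol(z))
    stop("collinear stage-2 design: components ",
         paste(q2$pivot[(q2$rank + 1):ncol(z)] - 1, collapse = ", "))
  beta <- qr.coef(q2, y)
  list(tc = tc, maps = beta[-1, , drop = FALSE])
}

#' Match components to reference maps by absolute spatial correlation
#'
#' Greedy assignment: repeatedly pairs the remaining component and
#' reference with the largest |correlation|.
#'
#' @param maps k x V component maps.
#' @param ref_maps r x V reference maps.
#' @return data.frame with reference index, matched component, and the
#'   (absolute) spatial correlation.
#' @export
match_components <- function(maps, ref_maps) {
  cc <- abs(stats::cor(t(ref_maps), t(maps)))
  n_ref <- nrow(ref_maps)
  out <- data.frame(ref = integer(n_ref), component = integer(n_ref),
                    correlation = numeric(n_ref))
  used_r <- rep(FALSE, nrow(cc)); used_c <- rep(FALSE, ncol(cc))
  for (i in seq_len(n_ref)) {
    cc_work <- cc
    cc_work[used_r, ] <- -1; cc_work[, used_c] <- -1
    best <- arrayInd(which.max(cc_work), dim(cc))
    out$ref[i] <- best[1]; out$component[i] <- best[2]
    out$correlation[i] <- cc[best[1], best[2]]
    used_r[best[1]] <- TRUE; used_c[best[2]] <- TRUE
  }
  out[order(out$ref), ]
}

#' Arm comparison of dual-regression component maps
#'
#' For each selected component, runs a two-sample TFCE/FWE permutation test
#' on the subject-specific stage-2 maps of the two arms.
#'
#' @param maps_a,maps_b lists (one element per subject, >= 3 each) of
#'   k x V stage-2 map matrices.
#' @param mask logical 3D mask the map columns refer to.
#' @param component_ids which component rows to test.
#' @param n_perm,seed permutation settings.
#' @param ... further arguments to \code{\link{permutation_fwe}}.
#' @return named list of \code{stat_map}, one per component id.
#' @export
compare_component_maps <- function(maps_a, maps_b, mask, component_ids,
                                   n_perm = 499, seed = 1, ...) {
  stopifnot(length(maps_a) >= 3, length(maps_b) >= 3)
  k <- nrow(maps_a[[1]])
  if (any(component_ids < 1 | component_ids > k))
    stop("component id out of range 1..", k)
  d3 <- dim(mask)
  vox <- which(as.vector(mask))
  res <- list()
  for (ci in component_ids) {
    to_arr <- function(m) {
      full <- numeric(prod(d3)); full[vox] <- m[ci, ]
      array(full, dim = d3)
    }
    arrs <- c(lapply(maps_a, to_arr), lapply(maps_b, to_arr))
    grp <- rep(c(TRUE, FALSE), c(length(maps_a), length(maps_b)))
    res[[as.character(ci)]] <- permutation_fwe(
      arrs, design = "two_sample", group = grp, n_perm = n_perm,
      seed = seed + ci, mask = mask, ...)
  }
  res
}
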