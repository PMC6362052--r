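#' Fisher z transform of correlation coefficients
#'
#' \code{z = atanh(r)} with the magnitude of r clipped to \code{1 - clip}
#' so the transform stays finite on degenerate (perfectly correlated)
#' inputs.
#'
#' @param r correlations in [-1, 1] (vector, matrix or array).
#' @param clip clipping margin; default \code{1e-7}.
#' @return Fisher z values, same shape as \code{r}.
#' @export
fisher_z <- function(r, clip = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must satisfy |r| <= 1")
  atanh(pmin(pmax(r, -(1 - clip)), 1 - clip))
}

#' One-sample t statistic with z-equivalent
#'
#' \code{t = mean / (sd / sqrt(n))} with the sample (n-1) SD. The
#' z-equivalent maps t through the t distribution function to a standard
#' normal quantile, clamped at |z| = 8. A zero-SD sample is flagged and
#' its t clamped to +-Inf by convention (z to +-8).
#'
#' @param x numeric vector (n >= 2) of per-subject values.
#' @return list with \code{t}, \code{z}, \code{df}, \code{flagged}
#'   (TRUE when the SD was zero).
#' @export
one_sample_t <- function(x) {
  n <- length(x)
  if (n < 2) stop("one_sample_t needs at least 2 observations")
  m <- mean(x)
  s <- stats::sd(x)
  flagged <- s == 0
  t <- if (flagged) sign(m) * Inf else m / (s / sqrt(n))
  list(t = t, z = t_to_z(t, n - 1), df = n - 1, flagged = flagged)
}

#' t-to-z conversion through the distribution function, clamped at |z| = 8
#' @noRd
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  neg <- !is.na(t) & t < 0
  # work in the lower tail on log scale for precision in both directions
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], df, log.p = TRUE), log.p = TRUE)
  z[is.na(t)] <- NA_real_
  pmin(pmax(z, -8), 8)
}

#' Column-wise one-sample t over a subjects-by-voxels matrix
#' @noRd
colwise_one_sample_t <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  v <- (colSums(m^2) - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- ifelse(se > 0, mu / se, sign(mu) * 1e10)
  t[se == 0 & mu == 0] <- 0
  t
}

#' Column-wise two-sample pooled t (group a minus group b)
#' @noRd
colwise_two_sample_t <- function(m, is_a) {
  na <- sum(is_a); nb <- sum(!is_a)
  ma <- colMeans(m[is_a, , drop = FALSE])
  mb <- colMeans(m[!is_a, , drop = FALSE])
  va <- (colSums(m[is_a, , drop = FALSE]^2) - na * ma^2) / (na - 1)
  vb <- (colSums(m[!is_a, , drop = FALSE]^2) - nb * mb^2) / (nb - 1)
  sp2 <- ((na - 1) * pmax(va, 0) + (nb - 1) * pmax(vb, 0)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- ifelse(se > 0, (ma - mb) / se, sign(ma - mb) * 1e10)
  t[se == 0 & ma == mb] <- 0
  t
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster support over all thresholds:
#' \code{TFCE(v) = sum_h extent(v, h)^E * h^H * dh} over
#' \code{h = dh, 2 dh, ... <= max}, where \code{extent(v, h)} is the size of
#' the connected component containing v at threshold h. Negative values are
#' enhanced separately on the negated map and returned with negative sign,
#' so the output is signed like the input.
#'
#' @param stat_map 3D numeric array (a 2D map is treated as one slice).
#' @param E,H extent and height exponents; defaults 0.5 and 2, the standard
#'   choice of the TFCE literature.
#' @param dh threshold step; \code{NULL} uses \code{max(|map|)/100}.
#' @param connectivity 6 or 26 (3D face or full neighbourhood).
#' @return enhanced map, same shape, sign matching the input.
#' @export
tfce <- function(stat_map, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(stat_map)
  if (is.null(d)) d <- c(length(stat_map), 1L, 1L)
  if (length(d) == 2) d <- c(d, 1L)
  stopifnot(length(d) == 3)
  mx <- max(abs(stat_map))
  if (mx == 0) return(array(0, dim = d))
  if (is.null(dh)) dh <- mx / 100
  stopifnot(dh > 0)
  pos <- pmax(as.numeric(stat_map), 0)
  neg <- pmax(-as.numeric(stat_map), 0)
  out <- .tfce_cpp(pos, as.integer(d), E, H, dh, as.integer(connectivity))
  if (any(neg > 0))
    out <- out - .tfce_cpp(neg, as.integer(d), E, H, dh,
                           as.integer(connectivity))
  array(out, dim = dim(stat_map) %||% d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation test with TFCE and max-statistic FWE correction
#'
#' Voxelwise statistic (one-sample t under sign flipping, or two-sample
#' pooled t under group-label shuffling), TFCE enhancement, and family-wise
#' error correction through the permutation distribution of the image-wide
#' maximum enhanced statistic. The identity permutation is always included;
#' with Monte-Carlo sampling of \code{n_perm} permutations the smallest
#' attainable p is \code{1/(n_perm + 1)}. When the full permutation group is
#' no larger than \code{n_perm} it is enumerated exhaustively instead.
#'
#' @param data 4D array with subjects in the last dimension, or a list of
#'   3D arrays (one per subject).
#' @param design \code{"one_sample"} (sign flips) or \code{"two_sample"}
#'   (label shuffles; requires \code{group}).
#' @param group logical or two-level vector marking group membership for the
#'   two-sample design (TRUE / first level = group a).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation draws.
#' @param E,H,dh,connectivity TFCE parameters; \code{dh} is fixed from the
#'   observed map and reused for every permutation.
#' @param mask optional logical 3D array restricting the analysis.
#' @return object of class \code{stat_map}: list with 3D arrays \code{stat}
#'   (t), \code{z}, \code{tfce} (signed), \code{fwe_one_minus_p} (positive
#'   direction: a > b or mean > 0) and \code{fwe_one_minus_p_neg} (opposite
#'   direction), plus \code{meta}.
#' @export
permutation_fwe <- function(data, design = c("one_sample", "two_sample"),
                            group = NULL, n_perm = 999, seed = 1,
                            E = 0.5, H = 2, dh = NULL, connectivity = 26,
                            mask = NULL) {
  design <- match.arg(design)
  if (is.list(data)) {
    d3 <- dim(data[[1]])
    data <- array(unlist(data), dim = c(d3, length(data)))
  }
  d <- dim(data)
  stopifnot(length(d) == 4)
  n <- d[4]
  if (design == "one_sample" && n < 2)
    stop("one-sample design needs at least 2 subjects")
  if (design == "two_sample") {
    if (is.null(group) || length(group) != n)
      stop("two-sample design needs a group vector of length n")
    is_a <- if (is.logical(group)) group else group == unique(group)[1]
    if (sum(is_a) < 2 || sum(!is_a) < 2)
      stop("two-sample design needs at least 2 subjects per group")
  }
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  vox <- which(as.vector(mask))
  m <- t(matrix(data, nrow = prod(d[1:3]), ncol = n))[, vox, drop = FALSE]

  stat_fn <- if (design == "one_sample") {
    function(mm) colwise_one_sample_t(mm)
  } else {
    function(mm, ia = is_a) colwise_two_sample_t(mm, ia)
  }

  to_map <- function(v) {
    full <- numeric(prod(d[1:3]))
    full[vox] <- v
    array(full, dim = d[1:3])
  }

  t_obs <- stat_fn(m)
  t_map <- to_map(t_obs)
  if (is.null(dh)) {
    mx <- max(abs(t_map))
    dh <- if (mx > 0) mx / 100 else 1
  }
  enh_obs <- tfce(t_map, E = E, H = H, dh = dh, connectivity = connectivity)
  obs_pos <- pmax(as.vector(enh_obs)[vox], 0)
  obs_neg <- pmax(-as.vector(enh_obs)[vox], 0)

  # permutation set: identity first, then exhaustive or Monte-Carlo draws
  set.seed(seed)
  if (design == "one_sample") {
    n_total <- 2^n
    exhaustive <- is.finite(n_total) && n_total <= n_perm
    if (exhaustive) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      # put the identity (all +1) first
      idn <- which(rowSums(signs == 1) == n)[1]
      signs <- rbind(signs[idn, ], signs[-idn, , drop = FALSE])
    } else {
      signs <- rbind(rep(1, n),
                     matrix(sample(c(1, -1), n * n_perm, replace = TRUE),
                            ncol = n))
    }
    perm_stat <- function(i) colwise_one_sample_t(m * signs[i, ])
    n_used <- nrow(signs)
  } else {
    n_total <- choose(n, sum(is_a))
    exhaustive <- n_total <= n_perm
    if (exhaustive) {
      combos <- utils::combn(n, sum(is_a))
      perms <- lapply(seq_len(ncol(combos)), function(j) {
        g <- rep(FALSE, n); g[combos[, j]] <- TRUE; g
      })
      idn <- which(vapply(perms, function(g) all(g == is_a), TRUE))[1]
      perms <- c(perms[idn], perms[-idn])
    } else {
      perms <- c(list(is_a),
                 lapply(seq_len(n_perm), function(i) {
                   g <- rep(FALSE, n); g[sample(n, sum(is_a))] <- TRUE; g
                 }))
    }
    perm_stat <- function(i) colwise_two_sample_t(m, perms[[i]])
    n_used <- length(perms)
  }

  cnt_pos <- numeric(length(vox))
  cnt_neg <- numeric(length(vox))
  for (i in seq_len(n_used)) {
    tv <- if (i == 1) t_obs else perm_stat(i)
    enh <- tfce(to_map(tv), E = E, H = H, dh = dh,
                connectivity = connectivity)
    mxp <- max(c(as.vector(enh), 0))
    mxn <- max(c(-as.vector(enh), 0))
    cnt_pos <- cnt_pos + (mxp >= obs_pos)
    cnt_neg <- cnt_neg + (mxn >= obs_neg)
  }
  p_pos <- cnt_pos / n_used
  p_neg <- cnt_neg / n_used

  structure(list(stat = t_map,
                 z = to_map(t_to_z(pmin(pmax(t_obs, -1e10), 1e10),
                                   if (design == "one_sample") n - 1
                                   else n - 2)),
                 tfce = enh_obs,
                 fwe_one_minus_p = to_map(1 - p_pos),
                 fwe_one_minus_p_neg = to_map(1 - p_neg),
                 meta = list(design = design, n = n, n_perm = n_used,
                             exhaustive = exhaustive, seed = seed,
                             E = E, H = H, dh = dh,
                             connectivity = connectivity)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map: %s design, n = %d, %d permutations%s\n",
              x$meta$design, x$meta$n, x$meta$n_perm,
              if (isTRUE(x$meta$exhaustive)) " (exhaustive)" else ""))
  cat(sprintf("  max |t| = %.3g, max FWE 1-p = %.4g (pos) / %.4g (neg)\n",
              max(abs(x$stat)), max(x$fwe_one_minus_p),
              max(x$fwe_one_minus_p_neg)))
  invisible(x)
}

#' Power of a two-sided one-sample t test
#'
#' Exact power from the noncentral t distribution: with effect size
#' \code{d = mean/SD}, noncentrality \code{d * sqrt(n)}, and critical value
#' from the central t at level alpha.
#'
#' @param n sample size (>= 2).
#' @param d standardized effect size, > 0.
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
power_one_sample_t <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(-tc, df, ncp = ncp) + stats::pt(tc, df, ncp = ncp,
                                            lower.tail = FALSE)
}

#' Smallest sample size reaching a target power
#'
#' Minimal integer \code{n >= 2} whose two-sided one-sample t test at level
#' \code{alpha} has power at least \code{power} for effect size \code{d}.
#'
#' @param d standardized effect size (mean/SD), must be > 0.
#' @param alpha two-sided significance level.
#' @param power target power in (0, 1).
#' @param max_n search cap.
#' @return integer sample size.
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.8,
                                 max_n = 100000L) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  if (!is.finite(d) || d <= 0)
    stop("effect size d must be positive; requested power is unreachable")
  for (n in 2:max_n) {
    if (power_one_sample_t(n, d, alpha) >= power) return(as.integer(n))
  }
  stop("no n <= max_n reaches the requested power")
}
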