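test_that("parcellation averages voxels within each parcel", {
  ph <- tiny_phantom()
  d <- dim(ph$labels)
  n_t <- 10
  roi_id <- ph$parcels$id[ph$parcels$class == "cortical"][1]
  m <- matrix(0, n_t, prod(d))
  m[, as.vector(ph$labels == roi_id)] <- 4.2
  pts <- parcellate(vol_from_matrix(m, d), ph)
  row <- which(pts$roi$id == roi_id)
  expect_equal(unname(pts$ts[row, ]), rep(4.2, n_t))
  # air parcels never appear
  expect_false(any(pts$roi$class == "air"))
  # hand mean on a two-voxel parcel
  lab <- array(0L, dim = c(2, 1, 1)); lab[] <- 1L
  ptab <- data.frame(id = 1L, name = "p", hemisphere = "L",
                     class = "cortical")
  v2 <- vol_from_matrix(rbind(c(1, 3), c(3, 5)), c(2, 1, 1))
  pts2 <- parcellate(v2, lab, parcels = ptab)
  expect_equal(unname(pts2$ts[1, ]), c(2, 4))
})

test_that("boxcar resampling matches the slower acquisition grid", {
  ptab <- data.frame(id = 1L, name = "p", hemisphere = "L",
                     class = "cortical")
  pts <- structure(list(ts = matrix(seq_len(1800), 1), roi = ptab,
                        dt_s = 1, flagged = integer()),
                   class = "parcel_timeseries")
  out <- resample_to_rate(pts, 2)
  expect_equal(ncol(out$ts), 900L)
  expect_equal(out$dt_s, 2)
  pts2 <- pts; pts2$ts <- matrix(c(1, 3, 5, 7), 1)
  expect_equal(unname(resample_to_rate(pts2, 2)$ts[1, ]), c(2, 6))
  expect_identical(resample_to_rate(pts2, 1), pts2)
  expect_error(resample_to_rate(pts2, 1.5), "integer multiple")
})

test_that("adjacency is a clipped Fisher-z correlation matrix", {
  ptab <- data.frame(id = 1:3, name = c("a", "b", "c"),
                     hemisphere = c("L", "R", "L"),
                     class = c("cortical", "cortical", "subcortical"))
  set.seed(9)
  x <- rnorm(900)
  ts <- rbind(x, x, rnorm(900))
  pts <- structure(list(ts = ts, roi = ptab, dt_s = 1,
                        flagged = integer()), class = "parcel_timeseries")
  am <- adjacency(pts)
  expect_true(all(is.na(diag(am$z))))
  expect_equal(am$z[1, 2], atanh(1 - 1e-7))   # identical series, clipped
  expect_true(am$clipped[1, 2])
  expect_lt(abs(am$z[1, 3]), 0.2)             # independent white noise
  expect_equal(am$z, t(am$z))
  # zero-variance parcel masked
  pts$ts[3, ] <- 5
  am2 <- adjacency(pts)
  expect_true(all(is.na(am2$z[3, ])))
  expect_equal(am2$flagged, 3L)
  pts$ts <- pts$ts[, 1:4]
  expect_error(adjacency(pts), "at least 8")
})

fake_adjacency <- function(z, ptab) {
  structure(list(z = z, roi = ptab, n_t = 100, flagged = integer(),
                 clipped = z > 100), class = "adjacency_matrix")
}

grid_roi_table <- function(n_cort = 4, n_sub = 4) {
  data.frame(id = seq_len(n_cort + n_sub),
             name = paste0("r", seq_len(n_cort + n_sub)),
             hemisphere = rep(c("L", "R"), length.out = n_cort + n_sub),
             class = rep(c("cortical", "subcortical"), c(n_cort, n_sub)))
}

test_that("group consistency computes edge z-statistics and strata", {
  ptab <- grid_roi_table()
  n <- 8
  mkmat <- function(fill) {
    z <- matrix(fill, 8, 8); diag(z) <- NA; z
  }
  # identical positive matrices: zero variance, clamped at +8
  same <- lapply(1:5, function(i) fake_adjacency(mkmat(0.5), ptab))
  res <- group_consistency(same)
  ut <- upper.tri(res$zstat)
  expect_true(all(res$zstat[ut] == 8))
  # null N(0,1) values: mean edge z-stat near zero
  set.seed(11)
  big_tab <- grid_roi_table(23, 24)   # 47 rois -> 1081 edges
  null_mats <- lapply(1:20, function(i) {
    z <- matrix(0, 47, 47)
    z[upper.tri(z)] <- rnorm(47 * 46 / 2)
    z <- z + t(z); diag(z) <- NA
    fake_adjacency(z, big_tab)
  })
  res0 <- group_consistency(null_mats)
  expect_lt(abs(mean(res0$zstat[upper.tri(res0$zstat)])), 0.1)
  # sqrt(n) monotonicity: doubling subjects with identical values raises |z|
  set.seed(12)
  base <- lapply(1:4, function(i) {
    z <- matrix(0, 8, 8)
    z[upper.tri(z)] <- rnorm(28, 0.8, 0.3)
    z <- z + t(z); diag(z) <- NA
    fake_adjacency(z, ptab)
  })
  res1 <- group_consistency(base)
  res2 <- group_consistency(c(base, base))
  ut8 <- upper.tri(res1$zstat)
  unclamped <- abs(res1$zstat[ut8]) < 8 & abs(res2$zstat[ut8]) < 8
  expect_true(all(abs(res2$zstat[ut8])[unclamped] >
                    abs(res1$zstat[ut8])[unclamped]))
  expect_error(group_consistency(base[1:2]), "3")
})

test_that("arm comparison detects shifts and degenerates correctly", {
  ptab <- grid_roi_table()
  set.seed(13)
  mats_a <- lapply(1:6, function(i) {
    z <- matrix(0, 8, 8)
    z[upper.tri(z)] <- rnorm(28, 1, 0.4)
    z <- z + t(z); diag(z) <- NA
    fake_adjacency(z, ptab)
  })
  res_a <- group_consistency(mats_a)
  cmp_same <- compare_arms(res_a, res_a)
  expect_true(all(cmp_same$tests$p_two_sided == 1))
  expect_equal(cmp_same$tests$ratio_a, cmp_same$tests$ratio_b)
  # a uniform +0.5 shift in arm a is detected in its favor
  mats_b <- lapply(mats_a, function(m) {
    m$z <- m$z - 0.5
    m
  })
  res_b <- group_consistency(mats_b)
  cmp <- compare_arms(res_a, res_b)
  # the 6-edge cortical stratum cannot go below p ~ 0.016 under a rank test
  expect_true(all(cmp$tests$p_a_greater[cmp$tests$n_edges >= 10] < 0.01))
  expect_true(all(cmp$tests$p_a_greater < 0.05))
  bad <- group_consistency(lapply(1:4, function(i)
    fake_adjacency(matrix(0.2, 6, 6) + diag(NA, 6), grid_roi_table(3, 3))))
  expect_error(compare_arms(res_a, bad), "match")
})

test_that("sample-size analysis feeds the noncentral-t solver correctly", {
  ptab <- grid_roi_table()
  # per-subject stratum means engineered to give d = 1 exactly
  set.seed(14)
  vals <- c(0.9, 1.1, 1.2, 0.8, 1.1, 0.9)
  vals <- 1 + (vals - mean(vals)) / sd(vals) * 1   # mean 1, sd 1 -> d = 1
  mats <- lapply(vals, function(v)
    fake_adjacency(matrix(v, 8, 8) + diag(NA, 8), ptab))
  res <- group_consistency(mats)
  out <- sample_size_analysis(res, stratum = "subcortical")
  plain <- out[out$mode == "plain", ]
  expect_equal(plain$d, 1, tolerance = 1e-10)
  expect_equal(plain$n, 10L)
  # offset mode with z0 above the mean is not achievable
  off <- out[out$mode == "offset", ]
  expect_true(is.na(off$n))
  expect_match(off$note, "not achievable")
  # larger z0 never decreases required n (when achievable)
  res2 <- res
  res2$subject_z <- res2$subject_z + 4
  a <- sample_size_analysis(res2, z0 = 2.3, stratum = "subcortical")
  b <- sample_size_analysis(res2, z0 = 3.0, stratum = "subcortical")
  expect_gte(b$n[b$mode == "offset"], a$n[a$mode == "offset"])
})
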