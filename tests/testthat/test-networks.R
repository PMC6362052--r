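sparse_netspec <- function(ph, amplitude = 0.02, rho = 0) {
  p <- ph$parcels
  pick <- function(cls, k) c(p$id[p$class == cls & p$hemisphere == "L"][k],
                             p$id[p$class == cls & p$hemisphere == "R"][k])
  network_spec(list(
    list(name = "cort_a", parcels = pick("cortical", 1), amplitude = amplitude),
    list(name = "cort_b", parcels = pick("cortical", 2), amplitude = amplitude),
    list(name = "sub_a", parcels = pick("subcortical", 1), amplitude = amplitude),
    list(name = "sub_b", parcels = pick("subcortical", 2), amplitude = amplitude)),
    cross_network_correlation = rho)
}

test_that("subject ICA recovers orthogonal spatial sources from a mixture", {
  set.seed(1)
  dims <- c(12, 12, 4)
  V <- prod(dims)
  maps <- matrix(0, 3, V)
  maps[1, 1:40] <- 1
  maps[2, 201:260] <- 1
  maps[3, 401:450] <- 1
  tc <- matrix(rnorm(60 * 3), 60, 3)
  y <- tc %*% maps
  vol <- vol_from_matrix(y + 100, dims)
  mask <- array(TRUE, dim = dims)
  cs <- subject_ica(vol, mask, n_components = 3, seed = 4)
  cc <- abs(cor(t(cs$maps), t(maps)))
  expect_true(all(apply(cc, 2, max) > 0.99))
  # determinism
  cs2 <- subject_ica(vol, mask, n_components = 3, seed = 4)
  expect_equal(cs$maps, cs2$maps, tolerance = 1e-10)
  expect_error(subject_ica(vol, mask, n_components = 60, seed = 1),
               "smaller")
})

test_that("rule-based classification separates signal from noise components", {
  n_t <- 120; tr <- 2
  t_s <- (seq_len(n_t) - 1) * tr
  mask <- array(TRUE, dim = c(10, 10, 2))
  brain <- array(FALSE, dim = c(10, 10, 2)); brain[3:8, 3:8, ] <- TRUE
  inside <- as.numeric(as.vector(brain))
  rim <- 1 - inside
  spike_tc <- rep(0, n_t); spike_tc[c(20, 60, 100)] <- 10
  cs <- structure(list(
    maps = rbind(inside, rim, inside),
    tc = cbind(sin(2 * pi * 0.05 * t_s),        # in-band, in-brain: signal
               sin(2 * pi * 0.3 * t_s * 0.8),   # high-frequency rim: noise
               spike_tc),                       # spike train: noise
    mask = mask, labels = rep("unlabeled", 3), ev = c(3, 2, 1),
    tr_vol_s = tr, meta = list(level = "subject")),
    class = "component_set")
  got <- classify_components(cs, brain)$labels
  expect_identical(got, c("signal", "noise", "noise"))
  # kurtosis arithmetic: the spike train fires rule (iii) on its own
  k <- mean((spike_tc - mean(spike_tc))^4) /
    mean((spike_tc - mean(spike_tc))^2)^2 - 3
  expect_gt(k, 10)
})

test_that("non-aggressive denoising removes only noise-unique variance", {
  set.seed(2)
  n_t <- 100
  sig_tc <- sin(2 * pi * seq_len(n_t) / 25)
  noise_tc <- rnorm(n_t)
  noise_tc <- residuals(lm(noise_tc ~ sig_tc))  # orthogonalize
  dims <- c(4, 4, 1)
  m <- outer(sig_tc, rep(1, prod(dims))) + outer(noise_tc, rep(0.7, prod(dims)))
  vol <- vol_from_matrix(m, dims)
  cs <- structure(list(
    maps = matrix(1, 2, prod(dims)), tc = cbind(sig_tc, noise_tc),
    mask = array(TRUE, dim = dims), labels = c("signal", "noise"),
    ev = c(2, 1), tr_vol_s = 1, meta = list()), class = "component_set")
  out <- segepi:::vol_to_matrix(denoise_nonaggressive(vol, cs))
  expect_gt(cor(out[, 1], sig_tc), 0.99)
  # with no noise labels the data pass through unchanged
  cs_clean <- cs; cs_clean$labels <- c("signal", "signal")
  expect_identical(denoise_nonaggressive(vol, cs_clean)$data, vol$data)
  # non-aggressive removal leaves at least as much variance as aggressive
  agg <- m - cbind(noise_tc) %*% solve(crossprod(cbind(noise_tc)),
                                       crossprod(cbind(noise_tc), m))
  expect_gte(sum(out^2), sum(agg^2) - 1e-8)
})

test_that("group ICA recovers planted networks across subjects", {
  # enough parcels per class that each planted network stays sparse
  ph <- make_phantom(c(24, 24, 8), 6, 6, seed = 11)
  ns <- sparse_netspec(ph)
  sq <- seq_params_ms(matrix = dim(ph$labels), n_rep = 80, sigma_thermal = 0,
                      sigma_physio = 0, shot_instability = 0)
  subs <- lapply(1:6, function(s) acquire_series(ph, NULL, sq, ns,
                                                 seed = 500 + s))
  brain <- phantom_brain_mask(ph)
  g <- group_ica(subs, brain, d = 4, seed = 2)
  refs <- t(sapply(ns$networks, function(nw)
    as.numeric(ph$labels %in% nw$parcels)[as.vector(brain)]))
  m <- match_components(g$maps, refs)
  expect_true(all(m$correlation > 0.9))
  expect_warning(group_ica(subs[1:2], brain, d = 2, seed = 1,
                           arms = c("ms", "ms")), "single arm")
  g2 <- group_ica(subs, brain, d = 4, seed = 2)
  expect_equal(g$maps, g2$maps, tolerance = 1e-10)
})

test_that("dual regression is an exact two-stage least-squares oracle", {
  set.seed(3)
  dims <- c(8, 8, 2)
  mask <- array(TRUE, dim = dims)
  V <- prod(dims); k <- 3; n_t <- 50
  gm <- matrix(rnorm(k * V), k, V)
  tc <- matrix(rnorm(n_t * k), n_t, k)
  vol <- vol_from_matrix(tc %*% gm + 10, dims)
  dr <- dual_regression(gm, vol, mask = mask)
  cc <- abs(cor(dr$tc, tc))
  expect_true(all(diag(cc) > 0.999))
  # a component absent from the subject yields a near-zero stage-2 map
  vol0 <- vol_from_matrix(tc[, 1:2] %*% gm[1:2, ] + 10, dims)
  dr0 <- dual_regression(gm, vol0, mask = mask)
  expect_lt(sqrt(mean(dr0$maps[3, ]^2)),
            0.01 * sqrt(mean(dr0$maps[1, ]^2)))
  # permutation equivariance
  drp <- dual_regression(gm[c(2, 3, 1), ], vol, mask = mask)
  expect_equal(drp$maps[c(3, 1, 2), ], dr$maps, tolerance = 1e-8)
  # collinear maps are refused with the culprits named
  expect_error(dual_regression(rbind(gm[1, ], gm[1, ]), vol, mask = mask),
               "collinear")
})

test_that("component-map comparison is valid on identical arms", {
  set.seed(5)
  dims <- c(6, 6, 2)
  mask <- array(TRUE, dim = dims)
  mk <- function(seed) {
    set.seed(seed)
    matrix(rnorm(2 * prod(dims)), 2)
  }
  shared <- lapply(1:3, function(i) mk(i))
  res <- compare_component_maps(shared, shared, mask, component_ids = 1,
                                n_perm = 99, seed = 1)
  expect_lt(max(res[["1"]]$fwe_one_minus_p), 0.95)
  expect_error(compare_component_maps(shared, shared, mask,
                                      component_ids = 5), "out of range")
})
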