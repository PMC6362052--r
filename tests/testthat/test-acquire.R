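make_netspec <- function(ph, amplitude = 0.02, rho = 0, ...) {
  p <- ph$parcels
  pick <- function(cls, k) c(p$id[p$class == cls & p$hemisphere == "L"][k],
                             p$id[p$class == cls & p$hemisphere == "R"][k])
  network_spec(list(
    list(name = "cort", parcels = pick("cortical", 1), amplitude = amplitude),
    list(name = "sub", parcels = pick("subcortical", 1), amplitude = amplitude)),
    cross_network_correlation = rho, ...)
}

test_that("network time courses are band-limited, standardized and seeded", {
  ph <- tiny_phantom()
  ns <- make_netspec(ph, rho = 0)
  tc <- simulate_network_timecourses(ns, n_t = 900, tr_vol_s = 2, seed = 3)
  expect_equal(dim(tc), c(900L, 2L))
  expect_equal(colMeans(tc), c(cort = 0, sub = 0), tolerance = 1e-10)
  expect_equal(apply(tc, 2, sd), c(cort = 1, sub = 1), tolerance = 1e-10)
  # uncorrelated networks stay near zero correlation at n_t = 900
  expect_lt(abs(cor(tc[, 1], tc[, 2])), 0.1)
  # spectral content: almost no power above the pass band
  pw <- Mod(fft(tc[, 1]))^2
  f <- (seq_len(900) - 1) / (900 * 2)
  f <- pmin(f, 0.5 - f)
  expect_lt(sum(pw[f > 0.12]) / sum(pw), 0.05)
  expect_identical(tc, simulate_network_timecourses(ns, 900, 2, seed = 3))
  expect_error(simulate_network_timecourses(ns, 900, tr_vol_s = 6, seed = 1),
               "Nyquist")
})

test_that("requested cross-network correlation is realized", {
  ph <- tiny_phantom()
  ns <- make_netspec(ph, rho = 0.4)
  r <- replicate(20, {
    tc <- simulate_network_timecourses(ns, 600, 2,
                                       seed = sample.int(1e6, 1))
    cor(tc[, 1], tc[, 2])
  })
  expect_lt(abs(mean(r) - 0.4), 0.1)
})

test_that("off-resonance displacement scales inversely with shots", {
  ph <- tiny_phantom()
  fm <- make_fieldmap(ph, peak_hz = 120, width_mm = 3)
  ms <- seq_params_ms(matrix = dim(ph$labels), n_rep = 8)
  ss <- seq_params_ss(matrix = dim(ph$labels), n_rep = 16)
  d_ms <- pe_displacement(fm, ms)$shift_vox
  d_ss <- pe_displacement(fm, ss)$shift_vox
  expect_equal(d_ss, 4 * d_ms, tolerance = 1e-12)
  # zero field, unit case
  fm0 <- fm; fm0$delta_f[] <- 0
  expect_true(all(pe_displacement(fm0, ss)$shift_vox == 0))
  fm1 <- fm; fm1$delta_f[] <- pe_bandwidth_per_pixel(ss)
  expect_equal(unique(as.vector(pe_displacement(fm1, ss)$shift_vox)), 1)
})

test_that("dropout attenuation follows exp(-TE * kappa * |grad|)", {
  ph <- tiny_phantom()
  sq <- seq_params_ss(matrix = dim(ph$labels), n_rep = 8)
  fm <- make_fieldmap(ph, peak_hz = 100, width_mm = 3)
  fm_unif <- fm; fm_unif$delta_f[] <- 42
  expect_equal(unique(as.vector(dropout_map(fm_unif, sq, kappa = 1))), 1)
  expect_true(all(dropout_map(fm, sq, kappa = 0) == 1))
  att <- dropout_map(fm, sq, kappa = 0.05)
  expect_true(all(att > 0 & att <= 1))
  # linear ramp along y: |grad| = g Hz/mm at interior voxels
  fm_ramp <- fm
  d <- dim(ph$labels)
  ys <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  g_per_vox <- 5
  fm_ramp$delta_f <- g_per_vox * ys
  g_hz_mm <- g_per_vox / ph$voxel_size[2]
  att <- dropout_map(fm_ramp, sq, kappa = 0.05)
  interior <- att[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  expect_equal(unique(round(as.vector(interior), 12)),
               round(exp(-0.017 * 0.05 * g_hz_mm), 12))
})

test_that("noiseless static acquisition repeats one volume exactly", {
  ph <- tiny_phantom()
  sq <- seq_params_ms(matrix = dim(ph$labels), n_rep = 5, sigma_thermal = 0,
                      sigma_physio = 0, shot_instability = 0)
  v <- acquire_series(ph, NULL, sq, NULL, seed = 1)
  expect_equal(dim(v$data)[4], 5L)
  for (t in 2:5) expect_identical(v$data[, , , t], v$data[, , , 1])
  # zero-shift warp is an exact pass-through
  fm0 <- make_fieldmap(ph, peak_hz = 0)
  v0 <- acquire_series(ph, fm0, sq, NULL, seed = 1, kappa = 0)
  expect_identical(v0$data, v$data)
})

test_that("acquisition geometry and volume TR follow the protocol", {
  ph <- tiny_phantom()
  sq <- seq_params_ms(matrix = dim(ph$labels), n_rep = 12)
  v <- acquire_series(ph, NULL, sq, NULL, seed = 1)
  expect_equal(dim(v$data), c(dim(ph$labels), 12L))
  expect_equal(v$tr_vol_s, 2)
  expect_equal(seq_params_ms()$n_rep, 900L)
  expect_equal(seq_params_ss()$n_rep, 1800L)
})

test_that("a planted network modulates its parcels with the right time course", {
  ph <- tiny_phantom()
  ns <- make_netspec(ph, amplitude = 0.02)
  sq <- seq_params_ms(matrix = dim(ph$labels), n_rep = 60, sigma_thermal = 0,
                      sigma_physio = 0, shot_instability = 0)
  v <- acquire_series(ph, NULL, sq, ns, seed = 9)
  tc <- simulate_network_timecourses(ns, 60, sq$tr_vol_s, seed = 9 + 1)
  roi <- ph$labels %in% ns$networks[[1]]$parcels
  series <- apply(v$data, 4, function(vol) mean(vol[roi]))
  expect_gt(cor(series, tc[, 1]), 0.99)
})

test_that("acquisition rejects out-of-range spikes and is seed-deterministic", {
  ph <- tiny_phantom()
  sq <- seq_params_ms(matrix = dim(ph$labels), n_rep = 10)
  expect_error(acquire_series(ph, NULL, sq, NULL, motion_spike_times = 11,
                              seed = 1), "spike")
  a <- acquire_series(ph, NULL, sq, NULL, motion_spike_times = 4, seed = 7)
  b <- acquire_series(ph, NULL, sq, NULL, motion_spike_times = 4, seed = 7)
  expect_identical(a$data, b$data)
})
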