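test_that("Fisher z transform is exact, odd, and safely clipped", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(1.9 / 0.1), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-10)
  expect_error(fisher_z(1.5), "<= 1")
})

test_that("one-sample t and its z-equivalent behave", {
  r <- one_sample_t(c(2, 4))
  expect_equal(r$t, 3)
  expect_equal(r$df, 1)
  expect_false(r$flagged)
  expect_true(one_sample_t(c(1, 1, 1, 1))$flagged)
  x <- c(-1.2, 0.3, 2.5, -0.7)
  expect_equal(one_sample_t(-x)$t, -one_sample_t(x)$t)
  expect_equal(one_sample_t(-x)$z, -one_sample_t(x)$z)
  # zero-SD samples clamp their z-equivalent at the +-8 bound
  expect_equal(one_sample_t(c(5, 5, 5))$z, 8)
  expect_equal(segepi:::t_to_z(100, 200), 8)
  expect_equal(segepi:::t_to_z(-100, 200), -8)
})

test_that("TFCE matches the brute-force threshold-sweep oracle", {
  # single voxel of height h: Riemann sum of h'^2 dh ~ h^3/3
  m <- array(0, dim = c(4, 4, 4)); m[2, 2, 2] <- 2
  enh <- tfce(m, dh = 0.02)
  expect_equal(max(enh), 2^3 / 3, tolerance = 0.05)
  expect_equal(enh, tfce_oracle(m, dh = 0.02), tolerance = 1e-12)
  # uniform plateau of N voxels: extent factor N^0.5
  p <- array(0, dim = c(4, 4, 1)); p[1:3, 1:2, 1] <- 1.5
  enh_p <- tfce(p, dh = 0.015)
  expect_equal(max(enh_p), sqrt(6) * max(tfce(array(c(1.5, rep(0, 63)),
                                                    c(4, 4, 4)), dh = 0.015)),
               tolerance = 1e-10)
  expect_equal(enh_p, tfce_oracle(p, dh = 0.015), tolerance = 1e-12)
  # all-zero map
  expect_true(all(tfce(array(0, dim = c(3, 3, 3))) == 0))
})

test_that("TFCE agrees with the oracle on random maps at both connectivities", {
  set.seed(42)
  for (i in 1:6) {
    m <- array(rnorm(64), dim = c(4, 4, 4))
    for (conn in c(6, 26)) {
      a <- tfce(m, dh = max(abs(m)) / 50, connectivity = conn)
      pos <- tfce_oracle(pmax(m, 0), dh = max(abs(m)) / 50,
                         connectivity = conn)
      neg <- tfce_oracle(pmax(-m, 0), dh = max(abs(m)) / 50,
                         connectivity = conn)
      expect_equal(a, pos - neg, tolerance = 1e-9)
    }
  }
})

test_that("TFCE is monotone and scales as c^3 on single-voxel maps", {
  set.seed(7)
  base <- array(abs(rnorm(27)), dim = c(3, 3, 3))
  bigger <- base + 0.5
  dh <- max(bigger) / 100
  expect_true(all(tfce(bigger, dh = dh) >= tfce(base, dh = dh) - 1e-10))
  m <- array(0, dim = c(3, 3, 3)); m[2, 2, 2] <- 1
  f1 <- max(tfce(m, dh = 0.01))
  m[2, 2, 2] <- 3
  f3 <- max(tfce(m, dh = 0.03))   # same relative discretization
  expect_equal(f3 / f1, 27, tolerance = 1e-6)
})

test_that("permutation FWE enumerates small designs exhaustively", {
  set.seed(1)
  maps <- lapply(1:4, function(i) array(rnorm(27, 1), dim = c(3, 3, 3)))
  sm <- permutation_fwe(maps, design = "one_sample", n_perm = 999, seed = 5)
  expect_true(sm$meta$exhaustive)
  expect_equal(sm$meta$n_perm, 16L)
  p <- 1 - sm$fwe_one_minus_p
  expect_true(all(p >= 1 / 16 - 1e-12))
  expect_true(all(p <= 1))
  # determinism under the seed
  sm2 <- permutation_fwe(maps, design = "one_sample", n_perm = 999, seed = 5)
  expect_identical(sm$fwe_one_minus_p, sm2$fwe_one_minus_p)
})

test_that("two-sample permutation finds nothing between identical groups", {
  set.seed(2)
  shared <- lapply(1:4, function(i) array(rnorm(27), dim = c(3, 3, 3)))
  maps <- c(shared, shared)
  grp <- rep(c(TRUE, FALSE), each = 4)
  sm <- permutation_fwe(maps, design = "two_sample", group = grp,
                        n_perm = 200, seed = 3)
  expect_true(all(sm$stat == 0))
  expect_true(all(sm$fwe_one_minus_p <= 1 - 1 / sm$meta$n_perm + 1e-12))
  expect_lt(max(sm$fwe_one_minus_p), 0.5)
  # n_perm = 1: attainable p-values are 1/2 and 1 only
  set.seed(4)
  maps2 <- lapply(1:6, function(i) array(rnorm(27, i / 10), dim = c(3, 3, 3)))
  sm1 <- permutation_fwe(maps2, design = "two_sample",
                         group = rep(c(TRUE, FALSE), 3), n_perm = 1, seed = 1)
  expect_true(all((1 - sm1$fwe_one_minus_p) %in% c(0.5, 1)))
})

test_that("required sample size reproduces the noncentral-t oracle", {
  # independent oracle: base R's power.t.test on the same one-sample design
  oracle_n <- function(d) ceiling(stats::power.t.test(
    delta = d, sd = 1, sig.level = 0.05, power = 0.8,
    type = "one.sample", strict = TRUE)$n)
  expect_equal(required_sample_size(0.5), 34L)
  expect_equal(oracle_n(0.5), 34)
  expect_equal(required_sample_size(1.0), 10L)
  expect_equal(oracle_n(1.0), 10)
  expect_gt(required_sample_size(0.25), required_sample_size(0.5))
  expect_error(required_sample_size(0), "positive")
  # power curve agrees with power.t.test across n
  for (n in c(5, 10, 34, 60))
    expect_equal(power_one_sample_t(n, 0.5),
                 stats::power.t.test(n = n, delta = 0.5, sd = 1,
                                     sig.level = 0.05, strict = TRUE,
                                     type = "one.sample")$power,
                 tolerance = 1e-6)
})
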