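ext <- hb_extinction()
Emat <- cbind(ext$eps_hbo, ext$eps_hbd)

test_that("extinction table validation enforces the oximetry model", {
  expect_s3_class(ext, "extinction_table")
  expect_true(ext$eps_hbd[1] > ext$eps_hbo[1])  # HbD dominates at 750
  expect_true(ext$eps_hbo[2] > ext$eps_hbd[2])  # HbO dominates at 850

  expect_error(extinction_table(750, 500, 1400), "two wavelengths")
  expect_error(extinction_table(c(750, 850), c(0, 1058), c(1405, 691)),
               "positive")
  expect_error(extinction_table(c(750, 850), c(1405, 1058), c(518, 691)),
               "750 nm")

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = 750, eps_hbo = 518,
                       eps_hbd = 1405.24), csv, row.names = FALSE)
  expect_error(read_extinction_table(csv), "missing required wavelength")
})

test_that("unmix_pixel solves the constrained 2x2 system exactly", {
  # pure oxyhemoglobin signal reconstructs itself at any positive scale
  for (k in c(0.3, 1, 7)) {
    out <- unmix_pixel(k * ext$eps_hbo, ext)
    expect_equal(unname(out), c(k, 0), tolerance = 1e-10)
  }
  expect_equal(unname(unmix_pixel(c(0, 0), ext)), c(0, 0))
  # noiseless round trip
  out <- unmix_pixel(as.numeric(Emat %*% c(2, 3)), ext)
  expect_equal(unname(out), c(2, 3), tolerance = 1e-10)
  expect_error(unmix_pixel(c(1, NA), ext), "finite")
})

test_that("clamped solutions match a dense non-negative grid search", {
  set.seed(41)
  # targeted adversarial case: unconstrained solution has negative HbD
  m_adv <- as.numeric(Emat %*% c(1, -0.5))
  out <- unmix_pixel(m_adv, ext)
  expect_identical(unname(out[2]), 0)
  g <- oracle_grid_nnls(m_adv, ext)
  expect_lte(abs(out[1] - g$c[1]), 2 * g$resolution)
  expect_lte(nnls_objective(out, m_adv, ext), g$objective + 1e-6)

  # random sample mixing feasible, noisy and sign-flipped measurements
  for (i in 1:60) {
    m <- switch(1L + i %% 3L,
                as.numeric(Emat %*% runif(2, 0, 4)),
                as.numeric(Emat %*% runif(2, 0, 4)) + rnorm(2, 0, 500),
                rnorm(2, 0, 2000))
    out <- unmix_pixel(m, ext)
    expect_true(all(out >= 0))
    g <- oracle_grid_nnls(m, ext, n_grid = 401L)
    expect_lte(nnls_objective(out, m, ext), g$objective + 1e-6 * (1 + g$objective))
    expect_lte(max(abs(out - g$c)), 2 * g$resolution + 1e-9)
  }
})

test_that("unmixing is scale-equivariant and saturation gain-independent", {
  set.seed(7)
  for (i in 1:25) {
    m <- rnorm(2, 500, 800)
    base <- unmix_pixel(m, ext)
    for (k in c(0.1, 2, 13)) {
      scaled <- unmix_pixel(k * m, ext)
      expect_equal(unname(scaled), unname(k * base), tolerance = 1e-9)
    }
  }
  # doubling both channels leaves StO2 unchanged, doubles HbT
  pair1 <- frame_pair(matrix(Emat[1, ] %*% c(2, 3), 4, 4),
                      matrix(Emat[2, ] %*% c(2, 3), 4, 4), 0)
  pair2 <- frame_pair(2 * pair1$img_750, 2 * pair1$img_850, 0)
  o1 <- compute_oximetry(pair1, ext)
  o2 <- compute_oximetry(pair2, ext)
  expect_equal(o2$sto2, o1$sto2, tolerance = 1e-9)
  expect_equal(o2$hbt, 2 * o1$hbt, tolerance = 1e-9)
})

test_that("compute_oximetry handles pure, mixed and empty frames", {
  # uniform pure HbO: saturation 100 everywhere, uniform HbT
  k <- 1.5
  pair <- frame_pair(matrix(k * ext$eps_hbo[1], 5, 6),
                     matrix(k * ext$eps_hbo[2], 5, 6), 0)
  o <- compute_oximetry(pair, ext)
  expect_true(all(o$mask))
  expect_equal(o$sto2, matrix(100, 5, 6), tolerance = 1e-9)
  expect_equal(o$hbt, matrix(k, 5, 6), tolerance = 1e-9)

  # all-zero frames: everything undefined
  o0 <- compute_oximetry(frame_pair(matrix(0, 5, 6), matrix(0, 5, 6), 0),
                         ext)
  expect_false(any(o0$mask))
  expect_true(all(o0$sto2 == 0) && all(o0$hbt == 0))

  expect_error(frame_pair(matrix(0, 5, 6), matrix(0, 6, 5), 0),
               "dimensions")
})

test_that("noiseless phantom frames round-trip through the unmixer", {
  fx <- small_fixture("HFR", seed = 3, noise_sd = 0)
  idx <- c(1L, 40L, length(fx$stack$frames))
  for (i in idx) {
    o <- compute_oximetry(fx$stack$frames[[i]], ext)
    truth_s <- fx$truth$sto2[, , i]
    truth_h <- fx$truth$hbt[, , i]
    valid <- truth_h > 0
    expect_lt(max(abs(o$sto2[valid] - truth_s[valid])), 1e-6)
    expect_equal(o$hbt[valid], truth_h[valid], tolerance = 1e-9)
    expect_true(all(o$hbt[!valid] < 1e-9))
  }
})

test_that("stack unmixing equals per-frame unmixing", {
  fx <- small_fixture("LFR", seed = 5)
  sub <- frame_stack(fx$stack$frames[1:10], fx$stack$pixel_spacing)
  os <- unmix_stack(sub, ext)
  for (i in c(1L, 6L, 10L)) {
    o <- compute_oximetry(sub$frames[[i]], ext)
    expect_equal(os$sto2[, , i], o$sto2)
    expect_equal(os$hbt[, , i], o$hbt)
    expect_equal(os$mask[, , i], o$mask)
  }
})

test_that("noise floor pools both top corner patches over all frames", {
  mk <- function(corner_val, interior_val, h = 48, w = 48) {
    m <- matrix(interior_val, h, w)
    m[1:20, c(1:20, (w - 19):w)] <- corner_val
    oximetry_maps(m * 0 + 50, m, m > 0, 0)
  }
  expect_equal(estimate_noise_floor(mk(5, 5)), 5)
  expect_equal(estimate_noise_floor(mk(2, 50)), 2)
  expect_equal(estimate_noise_floor(list(mk(1, 50), mk(3, 50))), 2)
  expect_error(estimate_noise_floor(mk(1, 1, h = 30, w = 30)),
               "too small")
})

test_that("thresholding zeroes sub-floor pixels and is idempotent", {
  set.seed(11)
  h <- matrix(runif(48 * 48, 0, 50), 48, 48)
  h[1:20, c(1:20, 29:48)] <- 2
  s <- matrix(runif(48 * 48, 0, 100), 48, 48)
  maps <- oximetry_maps(s, h, h > 0, 0)

  m0 <- apply_threshold(maps, 0)
  expect_equal(m0$mask, maps$hbt > 0)
  expect_equal(m0$sto2, maps$sto2)

  mall <- apply_threshold(maps, max(h) + 1)
  expect_false(any(mall$mask))

  thr <- 2
  mt <- apply_threshold(maps, thr)
  expect_equal(sum(mt$mask), sum(h >= thr & h > 0))  # brute-force count
  expect_true(all(mt$hbt[!mt$mask] == 0) && all(mt$sto2[!mt$mask] == 0))
  expect_identical(apply_threshold(mt, thr), mt)
})

test_that("unmixing generalizes to more than two wavelengths", {
  ext3 <- extinction_table(c(750, 800, 850),
                           c(518, 816, 1058), c(1405.24, 761.72, 691.32))
  E3 <- cbind(ext3$eps_hbo, ext3$eps_hbd)
  out <- unmix_pixel(as.numeric(E3 %*% c(1.2, 0.4)), ext3)
  expect_equal(unname(out), c(1.2, 0.4), tolerance = 1e-9)
  out2 <- unmix_pixel(as.numeric(E3 %*% c(1, -0.4)), ext3)
  expect_true(all(out2 >= 0))
  expect_identical(unname(out2[2]), 0)
})
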