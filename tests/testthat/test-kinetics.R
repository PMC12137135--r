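mk_maps <- function(sto2, hbt, t = 0) {
  oximetry_maps(sto2, hbt, hbt > 0, t)
}

test_that("ROI averaging excludes masked (zero) pixels", {
  s <- matrix(60, 10, 10)
  h <- matrix(1, 10, 10)
  h[1:3, ] <- 0; s[1:3, ] <- 0              # masked band
  roi <- roi_mask(matrix(TRUE, 10, 10))
  tl <- pdt_timeline(0, 10, 20, 30)
  tr <- roi_mean_trace(list(mk_maps(s, h, 0), mk_maps(s, h, 5)), roi, tl)
  expect_equal(tr$raw, c(60, 60))           # not diluted by zeros

  s2 <- matrix(0, 10, 10); h2 <- matrix(0, 10, 10)
  s2[, 1:5] <- 80; h2[, 1:5] <- 1           # half valid at 80, half masked
  tr2 <- roi_mean_trace(list(mk_maps(s2, h2, 0)), roi, tl)
  expect_equal(tr2$raw, 80)                 # 80, not 40

  # all-masked frame propagates as missing
  tr3 <- roi_mean_trace(list(mk_maps(s2 * 0, h2 * 0, 0)), roi, tl)
  expect_true(is.na(tr3$raw))
  expect_error(roi_mask(matrix(FALSE, 3, 3)), "no TRUE pixel")
})

test_that("ROI trace matches brute-force per-pixel averaging on a phantom", {
  fx <- small_fixture("HFR", seed = 2)
  os <- unmix_stack(fx$stack, hb_extinction())
  thr <- estimate_noise_floor(os)
  os <- apply_threshold(os, thr)
  tl <- fx$spec$timeline
  tr <- roi_mean_trace(os, fx$roi, tl)
  for (i in c(1L, 30L, 75L)) {
    m <- oximetry_frame(os, i)
    ok <- fx$roi$mask & m$mask
    expect_equal(tr$raw[i], mean(m$sto2[ok]))
    expect_equal(tr$hbt_raw[i], mean(m$hbt[ok]))
  }
})

test_that("sliding median filters as specified at edges and interior", {
  expect_equal(median_filter_trace(rep(4, 30), 15), rep(4, 30))
  x <- rep(10, 40); x[20] <- 500
  expect_equal(median_filter_trace(x, 15), rep(10, 40))  # spike removed

  set.seed(9)
  y <- cumsum(rnorm(80))
  for (ord in c(1L, 5L, 15L)) {
    expect_equal(median_filter_trace(y, ord), oracle_sliding_median(y, ord))
  }
  # never escapes the local window range
  f <- median_filter_trace(y, 15)
  for (i in seq_along(y)) {
    w <- y[max(1, i - 7):min(80, i + 7)]
    expect_gte(f[i], min(w)); expect_lte(f[i], max(w))
  }
  # NA samples are skipped, not imputed
  yna <- y; yna[10] <- NA
  fna <- median_filter_trace(yna, 5)
  expect_false(anyNA(fna))
  expect_error(median_filter_trace(y, 4), "odd")
  expect_error(median_filter_trace(y, 81), "length")
})

test_that("baseline normalization scales the pre-light mean to 100", {
  tl <- pdt_timeline(0, 300, 1200, 1500)
  t <- seq(0, 1496, by = 4)
  vals <- rep(50, length(t))
  out <- normalize_trace(vals, t, tl)
  expect_equal(out, rep(100, length(t)))    # scale by 2
  vals2 <- rep(100, length(t)); vals2[t >= 300] <- 25
  out2 <- normalize_trace(vals2, t, tl)
  expect_equal(out2[t >= 300], rep(25, sum(t >= 300)))  # identity scale

  expect_error(normalize_trace(rep(0, length(t)), t, tl), "positive")
  expect_error(normalize_trace(vals, t + 5000, tl), "baseline")
})

test_that("moving slope is exact on affine series and matches lm windows", {
  t <- seq(0, 400, by = 4)
  y <- 80 - 5 * t / 60                      # -5 %/min
  expect_equal(moving_slope(y, t, 15), rep(-5, length(t)), tolerance = 1e-9)
  expect_equal(moving_slope(rep(3, 50), seq_len(50) * 4, 15), rep(0, 50))

  set.seed(12)
  yn <- y + rnorm(length(y), 0, 2)
  for (w in c(2L, 7L, 15L)) {
    expect_equal(moving_slope(yn, t, w), oracle_moving_slope(yn, t, w),
                 tolerance = 1e-8)
  }
  expect_error(moving_slope(y, t, 1), ">= 2")
})

test_that("mean depletion rate averages slopes over the first light window", {
  tl <- pdt_timeline(0, 60, 360, 420)
  t <- seq(0, 416, by = 4)
  raw <- ifelse(t < 60, 100, 100 - 5 * (t - 60) / 60)
  tr <- structure(list(t = t, raw = raw, filtered = raw, normalized = raw,
                       hbt_raw = raw, timeline = tl),
                  class = "sto2_trace")
  expect_equal(mean_depletion_rate(tr, duration = 240, window = 5), -5,
               tolerance = 0.15)            # edge windows straddle the kink
  expect_warning(mean_depletion_rate(tr, duration = 1000), "available")
  expect_error(mean_depletion_rate(structure(list(normalized = NULL),
                                             class = "sto2_trace")),
               "normalized")
})

test_that("active-PDT end detection finds troughs and light-off declines", {
  tl <- pdt_timeline(0, 300, 1200, 1500)
  t <- seq(0, 1496, by = 4)
  mk_tr <- function(v) {
    structure(list(t = t, raw = v, filtered = v, normalized = v,
                   timeline = tl), class = "sto2_trace")
  }
  # V-shaped trace, unique trough at 12 min
  v <- 100 + abs(t - 720) / 60 * 3
  expect_equal(detect_active_pdt_end(mk_tr(v)), 720)
  # monotone decline through light-off
  v2 <- 100 - t / 60
  expect_equal(detect_active_pdt_end(mk_tr(v2)), 1200)
  # tied plateau: center returned; plateau touching light-off => light-off
  v3 <- pmax(40, 100 - t / 60)              # floor from t = 3600 (absent)
  v3[t >= 700 & t <= 760] <- 30
  expect_equal(detect_active_pdt_end(mk_tr(v3)), 728)
  v4 <- v2; v4[t >= 1100 & t <= 1200] <- 50
  expect_equal(detect_active_pdt_end(mk_tr(v4)), 1200)
  # invariance to positive affine rescaling
  set.seed(3)
  vr <- 100 - 20 * sin(t / 500) + rnorm(length(t), 0, 0.5)
  t1 <- detect_active_pdt_end(mk_tr(vr))
  t2 <- detect_active_pdt_end(mk_tr(7 + 3.2 * vr))
  expect_equal(t1, t2)
  # plateau (sustained non-decrease) rule on the V-trace
  expect_lt(abs(detect_active_pdt_end(mk_tr(v), rule = "plateau") - 720),
            61)
})

test_that("Severinghaus curve matches its landmarks and inverts", {
  s10 <- severinghaus_so2(10)
  expect_equal(round(s10), 10)              # ~10% StO2 at 10 mmHg
  expect_equal(s10, 100 / (23400 / (10^3 + 150 * 10) + 1))
  expect_gt(severinghaus_so2(1e6), 99.99)   # saturates toward 100

  p <- seq(1, 150, by = 0.5)
  expect_true(all(diff(severinghaus_so2(p)) > 0))
  for (p0 in c(5, 26.8, 100)) {
    expect_equal(severinghaus_po2(severinghaus_so2(p0)), p0,
                 tolerance = 1e-6)
  }
  expect_error(severinghaus_so2(0), "> 0")
  expect_error(severinghaus_po2(100), "between")
})

test_that("group comparison reproduces the fluence-rate significance pattern", {
  set.seed(21)
  df <- data.frame(
    group = rep(c("HFR", "LFR", "light_only"), each = 5),
    rate = c(rnorm(5, -20, 2), rnorm(5, -2, 2), rnorm(5, 0, 2)))
  out <- compare_group_rates(df)
  sig <- setNames(out$significant, out$pair)
  expect_true(sig[["LFR-HFR"]])
  expect_true(sig[["light_only-HFR"]])
  expect_false(sig[["light_only-LFR"]])
  expect_lt(attr(out, "p_value"), 0.01)

  # identical groups: no effect, F ~ 0, p ~ 1
  df0 <- data.frame(group = rep(c("a", "b"), each = 3),
                    rate = rep(c(-1, -2, -3), 2))
  out0 <- compare_group_rates(df0)
  expect_equal(attr(out0, "F"), 0, tolerance = 1e-12)
  expect_equal(out0$p_adj, 1, tolerance = 1e-9)

  expect_error(compare_group_rates(data.frame(group = c("a", "a", "b"),
                                              rate = 1:3)), "at least two")
})

test_that("Tukey comparisons hold the family-wise error near nominal", {
  set.seed(99)
  reps <- 1000L
  fam <- logical(reps)
  grp <- rep(c("a", "b", "c"), each = 5L)
  for (r in seq_len(reps)) {
    out <- compare_group_rates(rnorm(15), grp)
    fam[r] <- any(out$significant)
  }
  expect_gt(mean(fam), 0.025)
  expect_lt(mean(fam), 0.075)
})
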