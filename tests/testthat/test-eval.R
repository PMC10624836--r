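test_that("SSIM accuracy is 100 for identical and globally shifted images", {
  set.seed(4)
  x <- matrix(rnorm(64 * 64, sd = 0.2), 64, 64)
  expect_equal(ssim_accuracy(x, x)$ssim_pct, 100, tolerance = 1e-9)
  r <- ssim_accuracy(x + 0.3, x, align_global_phase = TRUE)
  expect_equal(r$ssim_pct, 100, tolerance = 1e-9)
  expect_equal(r$offset_rad, 0.3, tolerance = 1e-12)
  # without alignment the offset costs luminance similarity
  expect_lt(ssim_accuracy(x + 0.3, x, align_global_phase = FALSE)$ssim_pct,
            99.9)
})

test_that("constant images reduce to the closed-form luminance term", {
  c1 <- matrix(0.2, 32, 32); c2 <- matrix(0.4, 32, 32)
  # zero variance: the contrast-structure factor is exactly C2/C2 = 1 and
  # SSIM collapses to the luminance term. With a flat reference the
  # dynamic range falls back to the absolute data scale (0.4).
  L <- 0.4; C1 <- (0.01 * L)^2
  expected <- (2 * 0.2 * 0.4 + C1) / (0.2^2 + 0.4^2 + C1)
  r <- ssim_accuracy(c1, c2, align_global_phase = FALSE)
  expect_equal(r$ssim_pct / 100, expected, tolerance = 1e-9)
})

test_that("SSIM is symmetric without alignment and masks are honored", {
  set.seed(5)
  a <- matrix(rnorm(48 * 48), 48, 48)
  b <- a + matrix(rnorm(48 * 48, sd = 0.3), 48, 48)
  expect_equal(ssim_accuracy(a, b, align_global_phase = FALSE)$ssim_pct,
               ssim_accuracy(b, a, align_global_phase = FALSE)$ssim_pct,
               tolerance = 0.2)
  m <- matrix(TRUE, 48, 48); m[1:10, ] <- FALSE
  r <- ssim_accuracy(a, b, mask = m)
  expect_equal(r$coverage, mean(m))
  expect_error(ssim_accuracy(a, b, mask = matrix(FALSE, 48, 48)), "mask")
  expect_error(ssim_accuracy(a, b[1:10, 1:10]), "congruent")
})

test_that("FRC of identical images reports the Nyquist limit", {
  set.seed(6)
  x <- matrix(rnorm(96 * 96), 96, 96)
  f <- frc_resolution(x, x, pixel_size_nm = 8)
  expect_equal(f$resolution_nm, 16)
  expect_true(all(abs(f$curve$frc - 1) < 1e-9))
})

test_that("FRC of independent noise decorrelates beyond DC", {
  set.seed(7)
  a <- matrix(rnorm(96 * 96), 96, 96)
  b <- matrix(rnorm(96 * 96), 96, 96)
  f <- frc_resolution(a, b, pixel_size_nm = 8)
  # rings decorrelate on average to ~1/sqrt(n_ring) sampling noise (the
  # innermost rings hold only a handful of Fourier pixels)
  expect_lt(mean(abs(f$curve$frc[f$curve$n_ring >= 16])), 0.12)
  expect_true(all(abs(f$curve$frc) <= 1 + 1e-9))
  expect_error(frc_resolution(a[1:32, 1:32], b[1:32, 1:32], 8), "small")
})

test_that("FRC is invariant to a global phase offset on both inputs", {
  set.seed(8)
  # band-limited common signal + independent white noise: correlation
  # persists at low frequency and dies where the signal is gone
  base <- ptychostream:::gaussian_blur(matrix(rnorm(96 * 96), 96, 96), 2) * 6
  noisy1 <- base + matrix(rnorm(96 * 96, sd = 0.6), 96, 96)
  noisy2 <- base + matrix(rnorm(96 * 96, sd = 0.6), 96, 96)
  f1 <- frc_resolution(noisy1, noisy2, 8)
  f2 <- frc_resolution(noisy1 + 0.4, noisy2 + 0.4, 8)
  expect_equal(f1$resolution_nm, f2$resolution_nm, tolerance = 1e-6)
  # band-limited correlated content yields a finite resolution above Nyquist
  expect_gt(f1$resolution_nm, 16)
  expect_lt(f1$resolution_nm, 96 * 8)
})

test_that("two seeds' reconstructions of one region give a sane resolution", {
  sc <- fx_scan64()
  recs <- lapply(c(3, 17), function(sd) {
    rpie_reconstruct(sc$stack, sc$plan, fx_probe64(),
                     rpie_options(iterations = 40, beta = 0, n_modes = 1,
                                  random_object_init = TRUE, seed = sd))
  })
  # common centred 64-px window of the two phase maps
  win <- function(r) {
    cx <- round((191 * 4 - r$origin_nm[1]) / 8)
    r$phase[cx - 31 + 1:64, cx - 31 + 1:64]
  }
  f <- frc_resolution(win(recs[[1]]), win(recs[[2]]), 8)
  expect_gte(f$resolution_nm, 16)          # at least 2 pixels
  expect_lte(f$resolution_nm, 300)         # no worse than the probe size
})

test_that("the overlap sweep reproduces the sparse-sampling ordering", {
  cam <- fx_campaign()
  sw <- overlap_sweep(cam$stack, cam$plan, cam$phantom, cam$model,
                      rpie_options(iterations = 60, alpha = 0.25, beta = 0,
                                   n_modes = 1, random_object_init = TRUE,
                                   seed = 13),
                      target_ratios = c(0.9, 0.6, 0), probe = cam$probe)
  expect_equal(sw$overlap_ratio, c(0.9, 0.6, 0))
  expect_true(all(diff(sw$step_nm) > 0))
  # dose falls with the squared effective step
  expect_true(all(diff(sw$mean_dose) < 0))
  # ratio 0.9 keeps the full scan
  expect_equal(sw$n_points[1], cam$plan$n_points)
  # iterative retrieval collapses without overlap; the single-shot
  # surrogate does not care and wins clearly at zero overlap
  expect_lt(sw$ssim_iterative_pct[3], min(sw$ssim_iterative_pct[1:2]) - 20)
  expect_gt(sw$ssim_ai_pct[3], sw$ssim_iterative_pct[3])
  expect_gte(sw$ssim_ai_pct[3], 90)
})

test_that("line profiles sample phase images along a segment", {
  img <- outer(1:20, 1:20, function(i, j) j * 1.0)  # ramp in x
  lp <- line_profile(list(a = img, b = img * 2), from_nm = c(0, 40),
                     to_nm = c(80, 40), pixel_size_nm = 8, n = 11)
  expect_equal(nrow(lp), 11)
  expect_equal(lp$distance_nm, seq(0, 80, length.out = 11))
  # ramp: value = x/8 + 1
  expect_equal(lp$a, seq(0, 80, length.out = 11) / 8 + 1, tolerance = 1e-12)
  expect_equal(lp$b, 2 * lp$a, tolerance = 1e-12)
})
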