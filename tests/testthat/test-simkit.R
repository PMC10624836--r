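test_that("overlap ratio follows the spiral-step geometry", {
  expect_equal(round(as.numeric(overlap_ratio(50, 800)), 1), 0.9)
  expect_equal(round(as.numeric(overlap_ratio(180, 800)), 1), 0.6)
  expect_equal(as.numeric(overlap_ratio(0, 800)), 1.0)
  expect_equal(as.numeric(overlap_ratio(800 / sqrt(3), 800)), 0,
               tolerance = 1e-12)
  expect_true(attr(overlap_ratio(800, 800), "no_overlap"))
  expect_false(attr(overlap_ratio(50, 800), "no_overlap"))
  expect_error(overlap_ratio(50, 0), "beamsize")
  # strictly decreasing in S
  steps <- seq(0, 400, by = 25)
  r <- vapply(steps, overlap_ratio, numeric(1), beamsize_nm = 800)
  expect_true(all(diff(r) < 0))
  # inverse relation
  expect_equal(as.numeric(overlap_ratio(step_for_overlap(0.37, 512), 512)),
               0.37, tolerance = 1e-12)
})

test_that("object pixel size follows the far-field sampling relation", {
  g <- detector_geometry(10, 1.55, 512, 55)
  expect_equal(round(pixel_size_from_geometry(g), 2), 6.82)
  # linear in z, inverse in N and p
  expect_equal(pixel_size_from_geometry(detector_geometry(10, 3.10, 512, 55)),
               2 * pixel_size_from_geometry(g))
  expect_equal(pixel_size_from_geometry(detector_geometry(10, 1.55, 1024, 55)),
               pixel_size_from_geometry(g) / 2)
  expect_equal(pixel_size_from_geometry(detector_geometry(10, 1.55, 512, 110)),
               pixel_size_from_geometry(g) / 2)
  # independently derived value: lambda*z/(N*p) at 10 keV, 0.9 m, 128, 75 um
  lambda_nm <- 1.23984 / 10
  expect_equal(pixel_size_from_geometry(detector_geometry(10, 0.9, 128, 75)),
               lambda_nm * 0.9e9 / (128 * 75e3), tolerance = 1e-12)
  expect_error(detector_geometry(-1, 1, 128, 55), "positive")
})

test_that("raw data volume arithmetic matches acquisition bookkeeping", {
  expect_equal(data_volume(1, 100, 1e6, 16), 200e12)
  expect_equal(data_volume(1e-6, 1000, 1e6, 16), 2e6)  # one frame, 2 MB
  # 963 frames of 128x128 at 16 bit
  expect_equal(963 * 128 * 128 * 16 / 8, 31555584)
  expect_equal(data_volume(963 * 0.1^2 * 1e-6, 100, 128 * 128, 16),
               31555584, tolerance = 1e-9)
})

test_that("spiral scans step at constant chord length with uniform density", {
  plan <- make_spiral_scan(963, 50, 800)
  expect_s3_class(plan, "scan_plan")
  expect_equal(plan$n_points, 963L)
  expect_equal(nrow(plan$positions_nm), 963L)
  consec <- sqrt(rowSums(diff(plan$positions_nm)^2))
  expect_lt(max(abs(consec - 50)) / 50, 0.02)
  expect_lt(abs(median(nearest_neighbor_spacing(plan)) - 50) / 50, 0.05)
  # deterministic, centred single point
  expect_identical(plan, make_spiral_scan(963, 50, 800))
  p1 <- make_spiral_scan(1, 50, 800, center_nm = c(10, -4))
  expect_equal(as.numeric(p1$positions_nm), c(10, -4))
  expect_error(make_spiral_scan(0, 50), "n_points")
})

test_that("plan subsampling matches the density of the target step", {
  plan <- make_spiral_scan(963, 50, 800)
  sub <- subsample_plan(plan, 150)
  expect_equal(sub$k, 9L)
  expect_equal(sub$plan$n_points, length(sub$keep))
  expect_equal(sub$plan$step_nm, 150)
  expect_true(is.finite(sub$achieved_nn_nm))
  # dose bookkeeping: point count (hence dose at fixed per-shot flux)
  # drops by the squared step ratio, the scaling of the sparse analysis
  expect_lt(abs(sub$plan$n_points / plan$n_points - 1 / 9), 0.02)
  expect_error(subsample_plan(plan, 10), "target step")
})

test_that("annulus probes hit the target spot size with a central dip", {
  p <- fx_probe64()
  expect_gte(p$fwhm_nm, 0.95 * 300)
  expect_lte(p$fwhm_nm, 1.05 * 300)
  expect_equal(sum(Mod(p$field)^2), 1, tolerance = 1e-12)
  expect_lt(ptychostream:::probe_center_dip(p), 0.5)
  # the paper-scale configuration: 128 px at 6.82 nm, 800 nm spot
  g <- detector_geometry(10, 1.55, 128, 55 * 4)
  p800 <- make_probe(g, 6.82, fwhm_nm = 800)
  expect_gte(p800$fwhm_nm, 760)
  expect_lte(p800$fwhm_nm, 840)
  expect_lt(ptychostream:::probe_center_dip(p800), 0.5)
  # gaussian style is filled, not a donut
  pg <- make_probe(fx_geometry64(), 8, style = "gaussian", fwhm_nm = 300)
  expect_gt(ptychostream:::probe_center_dip(pg), 0.9)
  expect_error(make_probe(fx_geometry64(), 8, fwhm_nm = 5000), "fit")
})

test_that("phantoms respect the declared phase range and seed determinism", {
  ph <- make_phantom(c(128, 128), 8, c(-0.4, 0), seed = 3)
  expect_true(all(ph$phase >= -0.4 - 1e-12 & ph$phase <= 1e-12))
  expect_true(all(ph$amplitude > 0 & ph$amplitude <= 1))
  expect_identical(ph, make_phantom(c(128, 128), 8, c(-0.4, 0), seed = 3))
  ph2 <- make_phantom(c(128, 128), 8, c(-0.4, 0), seed = 4)
  s <- ssim_accuracy(ph$phase, ph2$phase, align_global_phase = FALSE)
  expect_lt(s$ssim_pct / 100, 0.9)
  lt <- make_phantom(c(128, 128), 8, c(-0.4, 0), style = "letters", seed = 3)
  expect_true(all(lt$phase >= -0.4 - 1e-12 & lt$phase <= 1e-12))
  expect_gt(sd(lt$phase), 0.01)  # glyphs actually drawn
  expect_error(make_phantom(c(64, 64), 8, c(-4, 0)), "inside")
})

test_that("forward model conserves photons (Parseval) and vacuum is trivial", {
  sc <- fx_scan64()
  stack <- sc$stack
  obj <- fx_phantom()$amplitude * exp(1i * fx_phantom()$phase)
  probe <- fx_probe64()
  n <- 64
  for (j in c(1, 50, 200)) {
    c0 <- ptychostream:::window_start0(sc$plan$positions_nm[j, 1], 8, n)
    r0 <- ptychostream:::window_start0(sc$plan$positions_nm[j, 2], 8, n)
    psi <- probe$field * obj[r0 + seq_len(n), c0 + seq_len(n)]
    expect_equal(sum(stack$frames[, , j]),
                 1e6 * 1 * sum(Mod(psi)^2), tolerance = 1e-6)
  }
  # vacuum object: every frame identical to the probe's own far field
  vac <- make_phantom(c(96, 96), 8, c(-0.1, 0), seed = 1)
  vac$phase[] <- 0; vac$amplitude[] <- 1
  vplan <- make_spiral_scan(5, 20, 300, center_nm = c(95 * 8 / 2, 95 * 8 / 2))
  vstack <- simulate_scan(vac, probe, vplan, fx_geometry64(),
                          flux_scale = 1e6, poisson = FALSE)
  expect_equal(vstack$frames[, , 3], vstack$frames[, , 1], tolerance = 1e-12)
  expect_equal(vstack$frames[, , 1],
               Mod(ptychostream:::fft2c(probe$field))^2 * 1e6,
               tolerance = 1e-9)
  # out-of-bounds positions are named
  bad <- make_spiral_scan(3, 50, 300, center_nm = c(0, 0))
  expect_error(simulate_scan(vac, probe, bad, fx_geometry64()),
               "position 1")
})

test_that("Poisson sampling reproduces mean and variance", {
  probe <- fx_probe64()
  vac <- make_phantom(c(96, 96), 8, c(-0.1, 0), seed = 1)
  plan1 <- make_spiral_scan(1, 20, 300, center_nm = c(95 * 8 / 2, 95 * 8 / 2))
  lam <- simulate_scan(vac, probe, plan1, fx_geometry64(), flux_scale = 1e5,
                       poisson = FALSE)$frames[, , 1]
  reps <- sapply(1:100, function(k) {
    simulate_scan(vac, probe, plan1, fx_geometry64(), flux_scale = 1e5,
                  poisson = TRUE, seed = k)$frames[, , 1]
  })
  dim(reps) <- c(64 * 64, 100)
  sel <- which(as.vector(lam) > 50)   # pixels with enough photons to test
  mns <- rowMeans(reps)[sel]
  vrs <- apply(reps, 1, var)[sel]
  expect_lt(median(abs(vrs / mns - 1)), 0.2)
  expect_lt(abs(mean(mns / as.vector(lam)[sel]) - 1), 0.05)
  expect_true(all(reps == round(reps)))
  # bit-reproducible given the seed
  a <- simulate_scan(vac, probe, plan1, fx_geometry64(), poisson = TRUE,
                     seed = 5)
  b <- simulate_scan(vac, probe, plan1, fx_geometry64(), poisson = TRUE,
                     seed = 5)
  expect_identical(a$frames, b$frames)
})

test_that("dose maps conserve photons and scale with step density", {
  probe <- fx_probe64()
  plan <- make_spiral_scan(120, 80, 300)
  dm <- dose_map(plan, probe, flux_scale = 1e6, exposure_ms = 1)
  expect_equal(dm$total_photons, 120 * 1e6, tolerance = 1e-9)
  expect_true(all(dm$grid >= 0))
  # halving the step (4x positions per area) quadruples the average dose
  plan2 <- make_spiral_scan(480, 40, 300)
  dm2 <- dose_map(plan2, probe, flux_scale = 1e6, exposure_ms = 1)
  expect_lt(abs(dm2$average_dose / dm$average_dose - 4) / 4, 0.1)
  # calibrated default flux: the reference dense scenario (963 points,
  # 50 nm step, 800 nm probe) deposits ~2e4 ph/nm^2; subsampling the same
  # scan to effective steps of 180 and 460 nm over the same field drops
  # the average dose to ~1.6e3 and ~2.5e2 -- the (step ratio)^-2 ladder of
  # the sparse-sampling analysis
  p800 <- make_probe(detector_geometry(10, 1.55, 128, 220), 6.82,
                     fwhm_nm = 800)
  plan800 <- make_spiral_scan(963, 50, 800)
  d9 <- dose_map(plan800, p800)
  expect_lt(abs(d9$average_dose / 2e4 - 1), 0.2)
  gs <- list(origin_nm = d9$origin_nm, shape = dim(d9$grid))
  lit <- d9$grid > 0.01 * max(d9$grid)
  for (cfg in list(c(180, 1600), c(460, 250))) {
    sub <- subsample_plan(plan800, cfg[1])
    ds <- dose_map(sub$plan, p800, grid_spec = gs)
    expect_lt(abs(mean(ds$grid[lit]) / cfg[2] - 1), 0.25)
  }
  # single position: dose image is the scaled probe footprint
  p1 <- make_spiral_scan(1, 80, 300)
  d1 <- dose_map(p1, probe, flux_scale = 1e3, exposure_ms = 2)
  core <- d1$grid[d1$grid > 0]
  expect_equal(sum(d1$grid) * d1$pixel_size_nm^2, 2e3, tolerance = 1e-9)
  expect_error(dose_map(structure(list(n_points = 0), class = "scan_plan"),
                        probe), "empty")
})
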