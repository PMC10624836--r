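test_that("one labeled pair per in-bounds position, campaign arithmetic", {
  cam <- fx_campaign()
  expect_equal(n_pairs(cam$pairs), cam$plan$n_points)
  expect_equal(dim(cam$pairs$diffraction)[1:2], c(32L, 32L))
  expect_equal(dim(cam$pairs$phase)[1:2], c(32L, 32L))
  # the full experiment's corpus arithmetic
  expect_equal(campaign_pair_count(make_spiral_scan(963, 50, 800), 113),
               108819L)
  expect_equal(campaign_pair_count(963L, 113L), 113L * 963L)
})

test_that("a position on a grid node interpolates to the direct crop", {
  ph <- fx_phantom()
  rec <- list(phase = ph$phase, origin_nm = c(0, 0), pixel_size_nm = 8)
  class(rec) <- "recon_result"
  n <- 32L; c0 <- n %/% 2L
  # position exactly at pixel (81, 75) (0-based), i.e. on a grid node
  pos <- matrix(c(75 * 8, 81 * 8), 1)
  plan <- structure(list(positions_nm = pos, step_nm = 10, beamsize_nm = 240,
                         n_points = 1L), class = "scan_plan")
  stack <- list(frames = array(0, c(n, n, 1)))
  pairs <- prepare_training_pairs(rec, plan, stack, fov_side = n)
  direct <- ph$phase[81 - c0 + seq_len(n), 75 - c0 + seq_len(n)]
  expect_lt(max(abs(pairs$phase[, , 1] - direct)), 1e-12)
})

test_that("windows leaving the reconstruction are skipped with a warning", {
  ph <- fx_phantom()
  rec <- list(phase = ph$phase[1:48, 1:48], origin_nm = c(0, 0),
              pixel_size_nm = 8)
  class(rec) <- "recon_result"
  pos <- rbind(c(24 * 8, 24 * 8), c(500 * 8, 24 * 8))
  plan <- structure(list(positions_nm = pos, step_nm = 10, beamsize_nm = 240,
                         n_points = 2L), class = "scan_plan")
  stack <- list(frames = array(0, c(32, 32, 2)))
  expect_warning(pairs <- prepare_training_pairs(rec, plan, stack, 32),
                 "skipped")
  expect_equal(n_pairs(pairs), 1L)
})

test_that("corpus append is exact and order-preserving", {
  cam <- fx_campaign()
  half1 <- half2 <- cam$pairs
  idx <- seq_len(600)
  half1$diffraction <- cam$pairs$diffraction[, , idx]
  half1$phase <- cam$pairs$phase[, , idx]
  half1$positions_nm <- cam$pairs$positions_nm[idx, ]
  half1$scan_id <- cam$pairs$scan_id[idx]
  rest <- seq(601, n_pairs(cam$pairs))
  half2$diffraction <- cam$pairs$diffraction[, , rest]
  half2$phase <- cam$pairs$phase[, , rest]
  half2$positions_nm <- cam$pairs$positions_nm[rest, ]
  half2$scan_id <- cam$pairs$scan_id[rest]
  joined <- append_pairs(half1, half2)
  expect_equal(n_pairs(joined), n_pairs(cam$pairs))
  expect_identical(joined$diffraction, cam$pairs$diffraction)
  expect_identical(joined$positions_nm, cam$pairs$positions_nm)
})

test_that("intensity downscaling divides counts and resamples Poisson", {
  cam <- fx_campaign()
  pairs <- cam$pairs
  idn <- downscale_training_intensities(pairs, 1, poisson_resample = FALSE)
  expect_identical(idn$diffraction, pairs$diffraction)
  expect_identical(idn$phase, pairs$phase)
  d10 <- downscale_training_intensities(pairs, 10, poisson_resample = FALSE)
  expect_equal(d10$diffraction, pairs$diffraction / 10)
  # Poisson resampling preserves the scaled mean over a large ensemble
  dp <- downscale_training_intensities(pairs, 10, poisson_resample = TRUE,
                                       seed = 4)
  expect_true(all(dp$diffraction == round(dp$diffraction)))
  sel <- pairs$diffraction / 10 > 20
  expect_lt(abs(sum(dp$diffraction[sel]) / sum(pairs$diffraction[sel] / 10) - 1),
            0.05)
  expect_identical(dp$phase, pairs$phase)
  expect_error(downscale_training_intensities(pairs, 0.5), "k must be")
})

test_that("training memorizes a tiny corpus (overfit oracle)", {
  cam <- fx_campaign()
  sub <- cam$pairs
  # five well-separated scan positions (nearby spiral points are nearly
  # identical frames, which makes distinct noisy labels unlearnable)
  keep <- round(seq(1, n_pairs(cam$pairs), length.out = 5))
  sub$diffraction <- cam$pairs$diffraction[, , keep]
  sub$phase <- cam$pairs$phase[, , keep]
  sub$positions_nm <- cam$pairs$positions_nm[keep, ]
  sub$scan_id <- cam$pairs$scan_id[keep]
  model <- build_network(network_spec(32L, c(8L, 16L, 32L)), seed = 3)
  cfg <- train_config(epochs_per_increment = 1000, batch_size = 5,
                      lr_min = 1e-6, lr_max = 5e-3, val_fraction = 0.2,
                      seed = 2)
  fit <- train_incremental(model, NULL, sub, cfg)
  expect_lt(tail(fit$history$train_mae, 1), 0.01)
})

test_that("best-validation selection and version bookkeeping hold", {
  cam <- fx_campaign()
  hist <- cam$history
  model <- cam$model
  expect_equal(model$training_meta$best_val_loss, min(hist$val_mae))
  expect_lte(model$training_meta$best_val_loss, tail(hist$val_mae, 1))
  # one version per accepted increment; corpus = scan 1 + its dimmed arm
  expect_equal(model$version, 5L)
  expect_equal(model$training_meta$corpus_size,
               n_pairs(cam$pairs) + n_pairs(cam$pairs) %/% 2)
  expect_error(train_incremental(build_network(network_spec(32L, c(4L, 8L))),
                                 NULL, NULL), "pairs")
})

test_that("retraining policy triggers on mismatch and suspends when aligned", {
  cam <- fx_campaign()
  pol <- policy_state(tolerance_ssim_pct = 10)
  # model inference on its own training scan agrees well: suspend expected
  step1 <- retrain_policy_step(pol, cam$model, cam$pairs, cam$recon)
  expect_lt(step1$mismatch_pct, 50)  # sanity: inference is meaningful
  # decision rule is a pure threshold on the measured mismatch
  if (step1$mismatch_pct < 10) {
    expect_equal(step1$decision, "suspend")
    expect_equal(step1$policy$mode, "suspended")
  } else {
    expect_equal(step1$decision, "retrain")
    expect_equal(step1$policy$mode, "active")
  }
  expect_equal(nrow(step1$policy$history), 1L)
  # an untrained (garbage) model must trigger retraining
  fresh <- build_network(cam$spec, seed = 99)
  fresh$norm_const <- cam$model$norm_const
  step2 <- retrain_policy_step(pol, fresh, cam$pairs, cam$recon)
  expect_gte(step2$mismatch_pct, 10)
  expect_equal(step2$decision, "retrain")
  # resume when suspended and mismatch reappears
  pol_s <- step1$policy; pol_s$mode <- "suspended"
  step3 <- retrain_policy_step(pol_s, fresh, cam$pairs, cam$recon)
  expect_equal(step3$decision, "resume")
  expect_equal(step3$policy$mode, "active")
  expect_error(policy_state(0), "tolerance")
})
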