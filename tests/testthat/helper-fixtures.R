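# Shared small fixtures, built in code. Heavyweight artifacts (trained
# models, campaigns) are memoized in this environment so several test files
# can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 64-px probe window at 8 nm pixels: the workhorse for solver tests.
fx_geometry64 <- function() detector_geometry(10, 0.9, 64, 75)

fx_probe64 <- function() {
  fixture("probe64", function() {
    make_probe(fx_geometry64(), object_pixel_nm = 8, fwhm_nm = 300)
  })
}

fx_phantom <- function() {
  fixture("phantom192", function() {
    make_phantom(c(192, 192), 8, c(-0.4, 0), seed = 7, feature_nm = 60)
  })
}

# Noiseless overlap-0.9 scan over the phantom centre (64-px window).
fx_scan64 <- function() {
  fixture("scan64", function() {
    plan <- make_spiral_scan(200, step_for_overlap(0.9, 300), 300,
                             center_nm = c(191 * 8 / 2, 191 * 8 / 2))
    stack <- simulate_scan(fx_phantom(), fx_probe64(), plan, fx_geometry64(),
                           exposure_ms = 1, flux_scale = 1e6, poisson = FALSE)
    list(plan = plan, stack = stack)
  })
}

# rPIE solver oracle: random start on the noiseless 64-px scan.
fx_rpie64 <- function() {
  fixture("rpie64", function() {
    sc <- fx_scan64()
    rpie_reconstruct(sc$stack, sc$plan, fx_probe64(),
                     rpie_options(iterations = 100, alpha = 0.25, beta = 0,
                                  n_modes = 1, random_object_init = TRUE,
                                  seed = 3))
  })
}

# The reduced-scale training campaign shared by the end-to-end tests: one
# dense overlap-0.9 scan (32-px window, training-dose exposure of 400 ms),
# its rPIE reconstruction as ground truth, and a surrogate trained over
# five 60-epoch increments of the continual loop. The second increment
# appends a quarter-exposure (Poisson re-sampled) rendition of half the
# pairs, emulating the exposure diversity of a real campaign, whose scans
# span a wide range of count rates. The stitched accuracy of the
# zero-overlap subset is recorded after every increment.
fx_campaign <- function() {
  fixture("campaign", function() {
    g <- detector_geometry(10, 0.9, 32, 75)
    px <- 8; B <- 240
    probe <- make_probe(g, px, fwhm_nm = B)
    phantom <- make_phantom(c(192, 192), px, c(-0.4, 0), seed = 42,
                            feature_nm = 60)
    plan <- make_spiral_scan(800, step_for_overlap(0.9, B), B,
                             center_nm = c(768, 768))
    stack <- simulate_scan(phantom, probe, plan, g, exposure_ms = 400,
                           flux_scale = 1e6, poisson = TRUE, seed = 101)
    rec <- rpie_reconstruct(stack, plan, probe,
                            rpie_options(iterations = 100, alpha = 0.25,
                                         beta = 0, n_modes = 1,
                                         random_object_init = TRUE, seed = 5))
    pairs <- prepare_training_pairs(rec, plan, stack, fov_side = 32,
                                    scan_id = 1)
    # the low-exposure arm of the corpus (scans taken at 1/4 the dose)
    idx <- seq(1, n_pairs(pairs), by = 2)
    dim4 <- pairs
    dim4$diffraction <- pairs$diffraction[, , idx]
    dim4$phase <- pairs$phase[, , idx]
    dim4$positions_nm <- pairs$positions_nm[idx, ]
    dim4$scan_id <- rep(2L, length(idx))
    dim4 <- downscale_training_intensities(dim4, 4, poisson_resample = TRUE,
                                           seed = 41)
    sub <- subsample_plan(plan, step_for_overlap(0, B))
    spec <- network_spec(32L, c(8L, 16L, 32L), 2L)
    cfg <- train_config(epochs_per_increment = 60, batch_size = 32,
                        lr_min = 1e-5, lr_max = 2e-3, seed = 7)
    model <- build_network(spec, seed = 11)
    corpus <- NULL
    ssim_by_increment <- numeric(0)
    for (inc in 1:5) {
      newp <- if (inc == 1) pairs else if (inc == 2) dim4 else NULL
      fit <- train_incremental(model, corpus, newp, cfg)
      model <- fit$model; corpus <- fit$corpus
      hist <- fit$history
      ssim_by_increment[inc] <- campaign_zero_overlap_ssim(
        model, stack, sub, phantom, px)
    }
    list(geometry = g, probe = probe, phantom = phantom, plan = plan,
         stack = stack, recon = rec, pairs = pairs, sub = sub,
         model = model, history = hist, spec = spec, cfg = cfg,
         ssim_by_increment = ssim_by_increment)
  })
}

# Poisson thinning: emulate a k-fold lower count rate on recorded frames.
thin_counts <- function(frames, k, seed) {
  if (k == 1) return(frames)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  array(stats::rpois(length(frames), as.vector(frames) / k),
        dim = dim(frames))
}

# The x10,000 low-count arm: Poisson-resampled dimmed corpus, fresh network,
# four increments, scored on matched low-count zero-overlap frames.
fx_lowcount <- function() {
  fixture("lowcount", function() {
    cam <- fx_campaign()
    pairs_lo <- downscale_training_intensities(cam$pairs, 1e4,
                                               poisson_resample = TRUE,
                                               seed = 31)
    model <- build_network(cam$spec, seed = 12)
    cfg <- train_config(epochs_per_increment = 60, batch_size = 32,
                        lr_min = 1e-5, lr_max = 2e-3, seed = 8)
    corpus <- NULL
    for (inc in 1:4) {
      fit <- train_incremental(model, corpus,
                               if (inc == 1) pairs_lo else NULL, cfg)
      model <- fit$model; corpus <- fit$corpus
    }
    frames_lo <- thin_counts(cam$stack$frames[, , cam$sub$keep], 1e4,
                             seed = 77)
    ssim <- campaign_zero_overlap_ssim(model, cam$stack, cam$sub,
                                       cam$phantom, 8, frames = frames_lo)
    list(model = model, pairs = pairs_lo, ssim = ssim)
  })
}

# Stitched accuracy of single-shot inferences on the zero-overlap subset,
# scored against the true phantom phase.
campaign_zero_overlap_ssim <- function(model, stack, sub, phantom, px,
                                       frames = stack$frames[, , sub$keep]) {
  pred <- infer(model, preprocess_frames(frames, 1, model))
  st <- stitch(patch_set(pred, sub$plan$positions_nm, px))
  ref <- resample_to_stitched(phantom$phase, c(0, 0), px, st)
  msk <- is.finite(st$phase) & is.finite(ref)
  ssim_accuracy(st$phase, ref, mask = msk)$ssim_pct
}
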