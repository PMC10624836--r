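#' Campaign configuration for the streaming demonstration
#'
#' Collects every knob of a simulated measure--train--infer campaign:
#' geometry, probe, phantom, per-scan plans, photon budget, solver options,
#' training schedule and retraining policy. Configurations round-trip
#' through YAML via [write_config()] / [read_config()].
#'
#' @param energy_keV,distance_m,n_pixels,pixel_pitch_um Detector geometry
#'   (the frame and probe-window side is `n_pixels`).
#' @param object_pixel_nm Object-plane pixel size; `NULL` derives it from
#'   the geometry.
#' @param probe_style,probe_fwhm_nm Probe construction (see [make_probe()]).
#' @param phantom_shape,phantom_phase_range,phantom_style,phantom_seed,
#'   phantom_feature_nm Phantom construction (see [make_phantom()]).
#' @param scans List of per-scan lists with `n_points`, `step_nm`,
#'   `center_nm` (and optional `exposure_ms`, `seed`).
#' @param beamsize_nm Beam size used for overlap bookkeeping.
#' @param exposure_ms,flux_scale Photon budget per frame.
#' @param rpie [rpie_options()] (plain lists are upgraded).
#' @param train [train_config()] (plain lists are upgraded).
#' @param network [network_spec()] (plain lists are upgraded).
#' @param tolerance_ssim_pct Retraining-policy tolerance.
#' @param holdout Optional list (`n_points`, `step_nm`, `center_nm`) of a
#'   held-out scan scored against the phantom after every increment.
#' @param seed Campaign master seed.
#' @return A `campaign_config` list.
#' @export
campaign_config <- function(energy_keV = 10, distance_m = 0.9, n_pixels = 32,
                            pixel_pitch_um = 75, object_pixel_nm = 8,
                            probe_style = "annulus", probe_fwhm_nm = 150,
                            phantom_shape = c(256, 256),
                            phantom_phase_range = c(-0.4, 0),
                            phantom_style = "random_etch", phantom_seed = 42,
                            phantom_feature_nm = NULL,
                            scans = list(), beamsize_nm = probe_fwhm_nm,
                            exposure_ms = 1, flux_scale = 1e6,
                            rpie = rpie_options(iterations = 60, n_modes = 1,
                                                beta = 0),
                            train = train_config(),
                            network = network_spec(input_side = n_pixels),
                            tolerance_ssim_pct = 10,
                            holdout = NULL, seed = 1L) {
  as_opts <- function(x, ctor, cls) {
    if (inherits(x, cls)) x else do.call(ctor, x)
  }
  structure(list(
    energy_keV = energy_keV, distance_m = distance_m, n_pixels = n_pixels,
    pixel_pitch_um = pixel_pitch_um, object_pixel_nm = object_pixel_nm,
    probe_style = probe_style, probe_fwhm_nm = probe_fwhm_nm,
    phantom_shape = phantom_shape,
    phantom_phase_range = phantom_phase_range,
    phantom_style = phantom_style, phantom_seed = phantom_seed,
    phantom_feature_nm = phantom_feature_nm,
    scans = scans, beamsize_nm = beamsize_nm,
    exposure_ms = exposure_ms, flux_scale = flux_scale,
    rpie = as_opts(rpie, rpie_options, "rpie_options"),
    train = as_opts(train, train_config, "train_config"),
    network = as_opts(network, network_spec, "network_spec"),
    tolerance_ssim_pct = tolerance_ssim_pct,
    holdout = holdout, seed = as.integer(seed)),
    class = "campaign_config")
}

## Materialize the static pieces of a campaign.
campaign_setup <- function(config) {
  geometry <- detector_geometry(config$energy_keV, config$distance_m,
                                config$n_pixels, config$pixel_pitch_um)
  probe <- make_probe(geometry, config$object_pixel_nm,
                      style = config$probe_style,
                      fwhm_nm = config$probe_fwhm_nm)
  feature <- config$phantom_feature_nm
  phantom <- make_phantom(config$phantom_shape, config$object_pixel_nm,
                          config$phantom_phase_range,
                          style = config$phantom_style,
                          seed = config$phantom_seed,
                          feature_nm = if (is.null(feature))
                            12 * config$object_pixel_nm else feature)
  list(geometry = geometry, probe = probe, phantom = phantom)
}

scan_plan_from_cfg <- function(sc, config) {
  make_spiral_scan(sc$n_points, sc$step_nm, config$beamsize_nm,
                   center_nm = sc$center_nm)
}

#' Run the in-process streaming demonstration
#'
#' Emulates the live workflow on one machine: scans are measured (simulated)
#' sequentially; frames of each scan are inferred on arrival with the
#' latest published model and stitched into a live image; after each scan
#' the iterative reconstruction is run, cropped into labeled pairs, the
#' mismatch policy decides whether to (re)train, and an accepted training
#' publishes a new model version. Every step is recorded in an ordered
#' event log (kinds `frame`, `inference`, `scan_end`, `model_update`), each
#' inference event carrying the model version that produced it.
#'
#' @param config A [campaign_config()] with at least one scan.
#' @return A campaign report: `events` (data.frame with `seq`, `kind`,
#'   `scan`, `frame`, `model_version`, `info`), `model`, `per_scan` (list of
#'   per-scan results: `stitched_ai`, `recon`, `decision`, `mismatch_pct`,
#'   `n_pairs`), `holdout` (data.frame of held-out SSIM per increment),
#'   `corpus_size`, `setup`.
#' @export
run_stream_demo <- function(config) {
  if (!length(config$scans)) stop_invalid("campaign has no scans")
  setup <- campaign_setup(config)
  model <- build_network(config$network, seed = config$seed)
  policy <- policy_state(config$tolerance_ssim_pct)
  corpus <- NULL
  events <- list(); seqno <- 0L
  emit <- function(kind, scan = NA_integer_, frame = NA_integer_, info = "") {
    seqno <<- seqno + 1L
    events[[seqno]] <<- data.frame(seq = seqno, kind = kind, scan = scan,
                                   frame = frame,
                                   model_version = model$version, info = info)
  }
  holdout_rows <- list()
  eval_holdout <- function(after_scan) {
    if (is.null(config$holdout) || model$version < 1L) return()
    hplan <- scan_plan_from_cfg(config$holdout, config)
    hstack <- simulate_scan(setup$phantom, setup$probe, hplan, setup$geometry,
                            config$exposure_ms, config$flux_scale,
                            poisson = TRUE, seed = child_seed(config$seed, 999))
    pred <- infer_with_norm(model, preprocess_frames(hstack, 1, model))
    st <- stitch(patch_set(pred, hplan$positions_nm,
                           setup$probe$pixel_size_nm))
    ref <- resample_to_stitched(setup$phantom$phase, c(0, 0),
                                setup$phantom$pixel_size_nm, st)
    m <- is.finite(st$phase) & is.finite(ref)
    holdout_rows[[length(holdout_rows) + 1L]] <<- data.frame(
      after_scan = after_scan, model_version = model$version,
      ssim_pct = ssim_accuracy(st$phase, ref, mask = m)$ssim_pct)
  }

  per_scan <- vector("list", length(config$scans))
  for (s in seq_along(config$scans)) {
    sc <- config$scans[[s]]
    plan <- scan_plan_from_cfg(sc, config)
    exposure <- if (is.null(sc$exposure_ms)) config$exposure_ms else sc$exposure_ms
    stack <- simulate_scan(setup$phantom, setup$probe, plan, setup$geometry,
                           exposure, config$flux_scale, poisson = TRUE,
                           seed = child_seed(config$seed, s))
    # live inference with the latest published model
    stitched_ai <- NULL
    for (j in seq_len(plan$n_points)) emit("frame", s, j)
    if (model$version >= 1L) {
      pred <- infer_with_norm(model, preprocess_frames(stack, 1, model))
      for (j in seq_len(plan$n_points)) emit("inference", s, j)
      stitched_ai <- stitch(patch_set(pred, plan$positions_nm,
                                      setup$probe$pixel_size_nm))
    }
    emit("scan_end", s)

    recon <- rpie_reconstruct(stack, plan, setup$probe, config$rpie)
    pairs <- prepare_training_pairs(recon, plan, stack,
                                    fov_side = config$network$input_side,
                                    scan_id = s)
    decision <- "retrain"; mismatch <- NA_real_
    if (model$version >= 1L) {
      step <- retrain_policy_step(policy, model, pairs, recon)
      decision <- step$decision; mismatch <- step$mismatch_pct
      policy <- step$policy
    }
    corpus_after <- if (is.null(corpus)) pairs else append_pairs(corpus, pairs)
    if (decision %in% c("retrain", "resume")) {
      fit <- train_incremental(model, corpus, pairs, config$train)
      model <- fit$model
      corpus <- fit$corpus
      emit("model_update", s,
           info = sprintf("val_mae=%.4g", model$training_meta$best_val_loss))
    } else {
      corpus <- corpus_after
    }
    per_scan[[s]] <- list(stitched_ai = stitched_ai, recon = recon,
                          decision = decision, mismatch_pct = mismatch,
                          n_pairs = n_pairs(pairs))
    eval_holdout(s)
  }

  list(events = do.call(rbind, events), model = model, per_scan = per_scan,
       holdout = if (length(holdout_rows)) do.call(rbind, holdout_rows)
                 else NULL,
       corpus_size = n_pairs(corpus), setup = setup)
}
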