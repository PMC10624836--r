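#' Training configuration for incremental (online) learning
#'
#' @param epochs_per_increment Epochs run each time a new scan is appended
#'   (default 50).
#' @param val_fraction Fraction of the corpus held out for validation,
#'   re-drawn at random every epoch (default 0.10).
#' @param lr_min,lr_max Bounds of the triangular cyclic learning-rate
#'   schedule; one full cycle spans an increment.
#' @param batch_size Mini-batch size.
#' @param seed Seed controlling validation splits and batch shuffling.
#' @return A `train_config` list. The optimizer is adaptive moment
#'   estimation (Adam) minimizing mean absolute error.
#' @export
train_config <- function(epochs_per_increment = 50L, val_fraction = 0.10,
                         lr_min = 1e-4, lr_max = 5e-4, batch_size = 64L,
                         seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop_invalid("val_fraction must be in (0, 1)")
  if (lr_min >= lr_max) stop_invalid("lr_min must be below lr_max")
  structure(list(epochs_per_increment = as.integer(epochs_per_increment),
                 val_fraction = val_fraction, lr_min = lr_min,
                 lr_max = lr_max, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Labeled diffraction/phase pairs from an iterative reconstruction
#'
#' For each scan position, the reconstructed phase is interpolated
#' (bilinearly) onto a `fov_side` x `fov_side` regular grid centred at the
#' beam position with the reconstruction pixel size -- the label for the
#' diffraction frame recorded there. Interpolation (rather than a direct
#' crop) handles the irregular spiral grid; when a position falls exactly on
#' a grid node the label reduces to the direct crop. Positions whose window
#' leaves the reconstructed area are skipped with a warning.
#'
#' @param recon A `recon_result`.
#' @param plan The scan plan of the stack.
#' @param stack The diffraction stack providing the input frames.
#' @param fov_side Label/frame side in pixels (matches the network spec).
#' @param scan_id Identifier stored with the pairs.
#' @return A `labeled_pairs` object: `diffraction` (array), `phase` (array),
#'   `positions_nm`, `scan_id`, `pixel_size_nm`.
#' @export
prepare_training_pairs <- function(recon, plan, stack, fov_side = 128L,
                                   scan_id = 1L) {
  n <- as.integer(fov_side)
  if (dim(stack$frames)[1] != n)
    stop_invalid("frame side %d does not match fov_side %d",
                 dim(stack$frames)[1], n)
  px <- recon$pixel_size_nm
  c0 <- n %/% 2L
  offs <- (0:(n - 1)) - c0
  keep <- logical(plan$n_points)
  labels <- array(0, dim = c(n, n, plan$n_points))
  for (j in seq_len(plan$n_points)) {
    u0 <- (plan$positions_nm[j, 1] - recon$origin_nm[1]) / px
    v0 <- (plan$positions_nm[j, 2] - recon$origin_nm[2]) / px
    u <- u0 + offs; v <- v0 + offs
    if (min(u) < 0 || min(v) < 0 ||
        max(u) > ncol(recon$phase) - 1 || max(v) > nrow(recon$phase) - 1) {
      warning(sprintf("position %d window exits the reconstruction; skipped", j))
      next
    }
    uu <- matrix(rep(u, each = n), n, n)   # columns vary along x
    vv <- matrix(rep(v, times = n), n, n)  # rows vary along y
    labels[, , j] <- matrix(bilinear_sample(recon$phase, uu, vv), n, n)
    keep[j] <- TRUE
  }
  structure(list(diffraction = stack$frames[, , keep, drop = FALSE],
                 phase = labels[, , keep, drop = FALSE],
                 positions_nm = plan$positions_nm[keep, , drop = FALSE],
                 scan_id = rep(as.integer(scan_id), sum(keep)),
                 pixel_size_nm = px),
            class = "labeled_pairs")
}

#' Number of pairs contributed by a campaign
#'
#' One labeled pair per scan position: `n_scans * plan$n_points`.
#'
#' @param plan A `scan_plan` (or an integer number of points per scan).
#' @param n_scans Number of scans acquired.
#' @return Integer pair count.
#' @examples
#' campaign_pair_count(make_spiral_scan(963, 50), 113)  # 108819
#' @export
campaign_pair_count <- function(plan, n_scans) {
  npts <- if (inherits(plan, "scan_plan")) plan$n_points else as.integer(plan)
  as.integer(n_scans) * npts
}

#' Concatenate labeled-pair sets (corpus append)
#'
#' @param ... `labeled_pairs` objects.
#' @return A single `labeled_pairs` object.
#' @export
append_pairs <- function(...) {
  sets <- Filter(Negate(is.null), list(...))
  sets <- Filter(function(p) n_pairs(p) > 0, sets)
  if (!length(sets)) stop_invalid("no pairs to append")
  ntot <- sum(vapply(sets, n_pairs, integer(1)))
  structure(list(
    diffraction = array(unlist(lapply(sets, `[[`, "diffraction")),
                        dim = c(dim(sets[[1]]$diffraction)[1:2], ntot)),
    phase = array(unlist(lapply(sets, `[[`, "phase")),
                  dim = c(dim(sets[[1]]$phase)[1:2], ntot)),
    positions_nm = do.call(rbind, lapply(sets, `[[`, "positions_nm")),
    scan_id = unlist(lapply(sets, `[[`, "scan_id")),
    pixel_size_nm = sets[[1]]$pixel_size_nm),
    class = "labeled_pairs")
}

#' @rdname append_pairs
#' @param pairs A `labeled_pairs` object.
#' @export
n_pairs <- function(pairs) if (is.null(pairs)) 0L else dim(pairs$diffraction)[3]

#' Rescale training intensities (low-count emulation)
#'
#' Divides the diffraction counts by `k`; with `poisson_resample = TRUE` the
#' scaled expectations are re-drawn as Poisson counts, emulating genuinely
#' shorter exposures. Labels are unchanged.
#'
#' @param pairs A `labeled_pairs` object.
#' @param k Scaling factor >= 1.
#' @param poisson_resample Redraw counts as Poisson(counts / k)?
#' @param seed Seed for the redraw.
#' @return The rescaled `labeled_pairs`.
#' @export
downscale_training_intensities <- function(pairs, k, poisson_resample = FALSE,
                                           seed = 1L) {
  if (k < 1) stop_invalid("k must be >= 1")
  if (k == 1 && !poisson_resample) return(pairs)
  out <- pairs
  out$diffraction <- pairs$diffraction / k
  if (poisson_resample) {
    out$diffraction <- with_seed(seed, {
      array(stats::rpois(length(out$diffraction),
                         lambda = as.vector(out$diffraction)),
            dim = dim(out$diffraction))
    })
  }
  out
}

#' Incremental training step
#'
#' Appends `new_pairs` to `corpus` and trains for
#' `config$epochs_per_increment` epochs of Adam on the mean absolute error,
#' with a triangular cyclic learning rate spanning the increment. A random
#' `val_fraction` of the corpus is re-drawn as validation data every epoch
#' (seeded); the epoch snapshot with the lowest validation loss becomes the
#' returned model, and the model version is incremented. The input
#' normalization constant (99.9th percentile of corpus counts) is recorded
#' on the model so inference matches training.
#'
#' @param model A `ptycho_model` (fresh or previously trained).
#' @param corpus Existing `labeled_pairs` corpus or `NULL`.
#' @param new_pairs Newly acquired `labeled_pairs` (may be `NULL` if
#'   `corpus` is non-empty).
#' @param config A [train_config()].
#' @param epochs Optional override of `epochs_per_increment`.
#' @return A list: `model` (best-validation snapshot, version incremented),
#'   `history` (data.frame epoch/train_mae/val_mae/lr), `corpus` (appended).
#' @export
train_incremental <- function(model, corpus, new_pairs, config = train_config(),
                              epochs = config$epochs_per_increment) {
  corpus <- if (is.null(corpus)) new_pairs
            else if (is.null(new_pairs)) corpus
            else append_pairs(corpus, new_pairs)
  ntot <- n_pairs(corpus)
  if (ntot < 2) stop_invalid("training requires at least 2 labeled pairs")

  Xt <- corpus$diffraction
  if (model$spec$input_transform == "sqrt") Xt <- sqrt(Xt)
  norm_const <- stats::quantile(Xt, 0.999, names = FALSE)
  if (norm_const <= 0) norm_const <- 1
  X <- Xt / norm_const
  Y <- corpus$phase

  nval <- max(1L, round(config$val_fraction * ntot))
  steps_per_epoch <- max(1L, ceiling((ntot - nval) / config$batch_size))
  total_steps <- epochs * steps_per_epoch

  m <- numeric(length(model$params)); v <- numeric(length(model$params))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0
  lr_at <- function(t) {  # one triangular cycle over the increment
    frac <- t / max(1, total_steps)
    config$lr_min + (config$lr_max - config$lr_min) * (1 - abs(2 * frac - 1))
  }

  best_val <- Inf; best_params <- model$params
  hist <- vector("list", epochs)
  side <- dim(X)[1]
  increment_seed <- child_seed(config$seed, model$version + 1L)

  for (ep in seq_len(epochs)) {
    ep_seed <- child_seed(increment_seed, ep)
    split <- with_seed(ep_seed, sample.int(ntot))
    val_idx <- split[seq_len(nval)]
    tr_idx <- split[-seq_len(nval)]
    tr_idx <- with_seed(child_seed(ep_seed, 2), sample(tr_idx))
    tr_loss <- 0; nb <- 0L; lr_sum <- 0
    for (b0 in seq(1L, length(tr_idx), by = config$batch_size)) {
      idx <- tr_idx[b0:min(b0 + config$batch_size - 1L, length(tr_idx))]
      lg <- nn_loss_grad(model, X[, , idx, drop = FALSE],
                         Y[, , idx, drop = FALSE])
      tstep <- tstep + 1
      lr <- lr_at(tstep); lr_sum <- lr_sum + lr
      g <- lg$grad
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^tstep); vhat <- v / (1 - b2^tstep)
      model$params <- model$params - lr * mhat / (sqrt(vhat) + eps)
      tr_loss <- tr_loss + lg$loss; nb <- nb + 1L
    }
    pred <- infer_with_norm(model, X[, , val_idx, drop = FALSE])
    val_loss <- mean(abs(pred - Y[, , val_idx, drop = FALSE]))
    if (val_loss < best_val) { best_val <- val_loss; best_params <- model$params }
    hist[[ep]] <- data.frame(epoch = ep, train_mae = tr_loss / nb,
                             val_mae = val_loss, lr = lr_sum / nb)
  }

  model$params <- best_params
  model$version <- model$version + 1L
  model$norm_const <- norm_const
  model$training_meta <- list(
    epochs_seen = model$training_meta$epochs_seen + epochs,
    corpus_size = ntot, best_val_loss = best_val)
  list(model = model, history = do.call(rbind, hist), corpus = corpus)
}

## infer() on already-normalized input (skips the side check duplication)
infer_with_norm <- function(model, batch) {
  d <- dim(batch)
  x <- array(batch, dim = c(d[1], d[2], 1L, d[3]))
  array(nn_forward_cpp(x, model$layers, model$params), dim = d)
}

#' Mismatch-triggered retraining policy state
#'
#' @param tolerance_ssim_pct Mismatch tolerance in SSIM percentage points
#'   (default 10): services stay active only while the AI-inferred and
#'   iteratively retrieved phases disagree by at least this much.
#' @param check_period Scans between periodic checks while suspended.
#' @return A `policy_state` list (`mode` starts `"active"`, empty history).
#' @export
policy_state <- function(tolerance_ssim_pct = 10, check_period = 1L) {
  if (tolerance_ssim_pct <= 0 || tolerance_ssim_pct >= 100)
    stop_invalid("tolerance must be in (0, 100)")
  structure(list(tolerance_ssim_pct = tolerance_ssim_pct,
                 check_period = as.integer(check_period),
                 mode = "active",
                 history = data.frame(mismatch_pct = numeric(0),
                                      decision = character(0))),
            class = "policy_state")
}

#' One step of the retraining policy
#'
#' Stitches the model's inferences on the new scan's frames, compares the
#' result to the iteratively retrieved phase for the same scan by structural
#' similarity, and decides: mismatch (100 - SSIM%) at or above tolerance
#' triggers retraining (resuming services if they were suspended); below
#' tolerance the automatic reconstruction/retraining services are suspended
#' pending periodic checks.
#'
#' @param policy A [policy_state()].
#' @param model The current `ptycho_model` (version >= 1).
#' @param new_pairs `labeled_pairs` of the new scan (frames + positions).
#' @param recon The `recon_result` for the same scan.
#' @return A list: `decision` (`"retrain"`, `"resume"` or `"suspend"`),
#'   `mismatch_pct`, `policy` (updated state).
#' @export
retrain_policy_step <- function(policy, model, new_pairs, recon) {
  batch <- preprocess_frames(new_pairs$diffraction, 1, model)
  pred <- infer_with_norm(model, batch)
  ps <- patch_set(pred, new_pairs$positions_nm, recon$pixel_size_nm)
  st <- stitch(ps)
  ref <- resample_to_stitched(recon$phase, recon$origin_nm,
                              recon$pixel_size_nm, st)
  mask <- is.finite(st$phase) & is.finite(ref)
  rep_ <- ssim_accuracy(st$phase, ref, align_global_phase = TRUE, mask = mask)
  mismatch <- 100 - rep_$ssim_pct
  was_suspended <- policy$mode == "suspended"
  if (mismatch >= policy$tolerance_ssim_pct) {
    decision <- if (was_suspended) "resume" else "retrain"
    policy$mode <- "active"
  } else {
    decision <- "suspend"
    policy$mode <- "suspended"
  }
  policy$history <- rbind(policy$history,
                          data.frame(mismatch_pct = mismatch,
                                     decision = decision))
  list(decision = decision, mismatch_pct = mismatch, policy = policy)
}
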