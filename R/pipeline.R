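# Training, prediction and evaluation orchestration.

#' Training configuration
#'
#' Defaults follow the full-scale recipe (Adam, initial learning rate
#' 0.001, weight decay 1e-8, cosine annealing with warm restarts with
#' eta_min 1e-4, 600 epochs, 3-fold cross-validation). The `"desk"`
#' preset scales the run to CPU desk size: 50 epochs, 32-cube crops.
#'
#' @param preset `"full"` (600 epochs, 128 crop) or `"desk"` (50 epochs,
#'   32 crop).
#' @param lr Initial learning rate.
#' @param weight_decay L2 weight decay added to the gradient.
#' @param eta_min Scheduler floor.
#' @param t0 Scheduler restart period in epochs.
#' @param epochs Training epochs.
#' @param batch_size Cases per gradient step.
#' @param crop Cubic crop size.
#' @param folds Cross-validation folds (used by [penet_cv()]).
#' @param seed RNG seed for initialization and batch shuffling.
#' @param val_every Validation cadence in epochs.
#' @param deterministic Kept for config echo; all computation here is
#'   single-threaded and deterministic given the seed.
#' @export
train_config <- function(preset = c("desk", "full"), lr = 0.001,
                         weight_decay = 1e-8, eta_min = 1e-4, t0 = 100L,
                         epochs = NULL, batch_size = 2L, crop = NULL,
                         folds = 3L, seed = 1L, val_every = 5L,
                         deterministic = TRUE) {
  preset <- match.arg(preset)
  if (is.null(epochs)) epochs <- if (preset == "desk") 50L else 600L
  if (is.null(crop)) crop <- if (preset == "desk") 32L else 128L
  stopifnot(lr > eta_min, eta_min >= 0, epochs >= 1)
  structure(list(preset = preset, optimizer = "adam", lr = lr,
                 weight_decay = weight_decay, eta_min = eta_min,
                 t0 = as.integer(t0), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), crop = as.integer(crop),
                 folds = as.integer(folds), seed = as.integer(seed),
                 val_every = as.integer(val_every),
                 deterministic = isTRUE(deterministic)),
            class = "train_config")
}

#' Cosine annealing with warm restarts
#'
#' `lr(t) = eta_min + (lr0 - eta_min) * (1 + cos(pi * t_cur / T0)) / 2`
#' with `t_cur = epoch mod T0`; the rate returns to `lr0` at every restart
#' boundary and never drops below `eta_min`.
#'
#' @param epoch Zero-based epoch index.
#' @param cfg A [train_config()] (or list with `lr`, `eta_min`, `t0`).
#' @export
cosine_annealing_lr <- function(epoch, cfg) {
  tcur <- epoch %% cfg$t0
  cfg$eta_min + (cfg$lr - cfg$eta_min) * (1 + cos(pi * tcur / cfg$t0)) / 2
}

adam_init <- function(leaves) {
  list(m = lapply(leaves, function(l) l$value * 0),
       v = lapply(leaves, function(l) l$value * 0),
       t = 0L)
}

adam_step <- function(leaves, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(leaves)) {
    l <- leaves[[i]]
    g <- l$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * l$value
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    l$value <- l$value - lr * (state$m[[i]] / bc1) /
      (sqrt(state$v[[i]] / bc2) + eps)
  }
  state
}

stack_batch <- function(cases, idx) {
  d <- dim(cases[[idx[1]]]$image)
  x <- array(0, c(length(idx), 1L, d))
  t <- array(0L, c(length(idx), d))
  for (j in seq_along(idx)) {
    x[j, 1, , , ] <- cases[[idx[j]]]$image
    t[j, , , ] <- cases[[idx[j]]]$label
  }
  list(x = x, t = t)
}

val_dice <- function(model, cases) {
  if (length(cases) == 0) return(NA_real_)
  plain <- list(cfg = model$cfg, params = pn_unwrap_params(model$params))
  class(plain) <- "penet_model"
  vapply(cases, function(cs) {
    pr <- predict_mask(plain, cs$image)
    dsc(confusion_counts(pr, cs$label))
  }, numeric(1)) |> mean()
}

#' Train a segmentation model
#'
#' Single training run over the given cases with Adam and cosine
#' annealing with warm restarts; validation Dice is tracked every
#' `val_every` epochs and the best-by-validation-DSC parameters are
#' retained. A non-finite loss aborts training and keeps the last good
#' parameters.
#'
#' @param cases List of cases, each a list with `image` (3D array) and
#'   `label` (3D 0/1 array), e.g. from [make_dataset()].
#' @param net_cfg A [net_config()].
#' @param cfg A [train_config()].
#' @param val_cases Held-out cases for validation (same structure).
#' @param log_path Optional JSONL path; one line per epoch.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best parameters), `log` (data.frame:
#'   epoch, lr, loss, val_dsc), `final_loss`, `best_val_dsc`.
#' @export
penet_train <- function(cases, net_cfg, cfg = train_config(),
                        val_cases = list(), log_path = NULL, verbose = FALSE) {
  stopifnot(length(cases) >= 1)
  set.seed(cfg$seed)
  model <- penet_build(net_cfg)
  wrapped <- pn_wrap_params(model$params)
  model$params <- wrapped
  leaves <- pn_param_leaves(wrapped)
  state <- adam_init(leaves)
  lw <- loss_weights()
  best <- list(dsc = -Inf, params = NULL)
  log <- data.frame()
  aborted <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_annealing_lr(epoch - 1L, cfg)
    idx <- sample.int(length(cases))
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    losses <- numeric(0)
    for (b in batches) {
      bt <- stack_batch(cases, b)
      pn_zero_grad(wrapped)
      pred <- penet_forward(model, bt$x)
      loss <- composite_loss(pred, bt$t, lw)
      lv <- pn_val(loss)
      if (!is.finite(lv)) {
        warning(sprintf("penet_train: non-finite loss at epoch %d; aborting with last good parameters", epoch))
        aborted <- TRUE
        break
      }
      pn_backward(loss)
      state <- adam_step(leaves, state, lr, cfg$weight_decay)
      losses <- c(losses, lv)
    }
    if (aborted) break
    vd <- if (length(val_cases) > 0 &&
              (epoch %% cfg$val_every == 0L || epoch == cfg$epochs)) {
      val_dice(model, val_cases)
    } else NA_real_
    if (!is.na(vd) && vd > best$dsc)
      best <- list(dsc = vd, params = pn_unwrap_params(wrapped))
    row <- data.frame(epoch = epoch, lr = lr, loss = mean(losses), val_dsc = vd)
    log <- rbind(log, row)
    if (!is.null(log_path))
      cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE, digits = NA), "\n",
          file = log_path, append = epoch > 1)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  val_dsc %s",
                      epoch, lr, mean(losses),
                      ifelse(is.na(vd), "-", sprintf("%.3f", vd))))
  }
  final_params <- if (!is.null(best$params)) best$params else pn_unwrap_params(wrapped)
  out_model <- structure(list(cfg = net_cfg, params = final_params,
                              n_params = model$n_params),
                         class = "penet_model")
  list(model = out_model, log = log, final_loss = utils::tail(log$loss, 1),
       best_val_dsc = if (is.finite(best$dsc)) best$dsc else NA_real_)
}

#' K-fold cross-validated training
#'
#' Runs the fold loop: for each fold, trains on the other folds and
#' validates on the held-out fold.
#'
#' @param cases List of cases (see [penet_train()]).
#' @param fold Integer fold assignment per case (see [assign_folds()]).
#' @param net_cfg,cfg As in [penet_train()].
#' @return List of per-fold [penet_train()] results.
#' @export
penet_cv <- function(cases, fold, net_cfg, cfg = train_config()) {
  stopifnot(length(fold) == length(cases))
  lapply(sort(unique(fold)), function(f) {
    penet_train(cases[fold != f], net_cfg, cfg, val_cases = cases[fold == f])
  })
}

# pad a 3D array up to extents divisible by `f` (zero padding at the high
# end), run the model, crop back
predict_mask <- function(model, image) {
  d <- dim(image)
  f <- 2L^(model$cfg$levels - 1L)
  dp <- as.integer(ceiling(d / f) * f)
  dp <- rep(max(dp), 3L)  # positional tables are cubic; pad to a cube
  padded <- array(0, dp)
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- image
  x <- array(padded, c(1L, 1L, dp))
  mdl <- model
  if (!is.null(mdl$cfg$crop) && mdl$cfg$crop != dp[1])
    mdl <- penet_resize_tables(mdl, dp[1])
  pr <- penet_forward(mdl, x)
  p1 <- pr[1, 2, , , ]
  mask <- array(as.integer(p1 > pr[1, 1, , , ]), dp)
  mask[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
}

#' Predict a segmentation mask
#'
#' Runs tape-free inference, takes the per-voxel argmax, and (for file
#' input) writes the mask with the input's NIfTI header.
#'
#' @param model A `penet_model` with plain-array parameters.
#' @param input 3D image array or NIfTI path.
#' @param out Optional output NIfTI path for the mask.
#' @return Integer mask array (invisibly when `out` is given); the number
#'   of foreground voxels is attached as attribute `"n_foreground"`.
#' @export
penet_predict <- function(model, input, out = NULL) {
  template <- NULL
  if (is.character(input)) {
    image <- read_volume(input)
    template <- attr(image, "template")
  } else image <- input
  mask <- predict_mask(model, image)
  attr(mask, "n_foreground") <- sum(mask)
  if (!is.null(out)) {
    write_volume(mask, out, template = template)
    return(invisible(mask))
  }
  mask
}

#' Evaluate predictions against reference labels
#'
#' @param preds,labels Named lists of binary 3D masks, or directories of
#'   NIfTI files paired by file name.
#' @param ahd_variant Passed to [ahd()].
#' @return List with `per_case` (data.frame: case_id, SEN, DSC, AHD,
#'   variant), `aggregate` (mean/std/median/min/max per metric), and
#'   `unpaired` (character vector of unmatched case ids).
#' @export
penet_evaluate <- function(preds, labels, ahd_variant = "standard") {
  load_dir <- function(d) {
    fs <- list.files(d, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    out <- lapply(fs, read_volume)
    names(out) <- sub("\\.nii(\\.gz)?$", "", basename(fs))
    out
  }
  if (is.character(preds)) preds <- load_dir(preds)
  if (is.character(labels)) labels <- load_dir(labels)
  ids <- intersect(names(preds), names(labels))
  unpaired <- setdiff(union(names(preds), names(labels)), ids)
  if (length(unpaired) > 0)
    warning("penet_evaluate: unpaired cases skipped: ",
            paste(unpaired, collapse = ", "))
  per <- do.call(rbind, lapply(ids, function(id) {
    cbind(case_id = id,
          case_metrics(preds[[id]] != 0, labels[[id]] != 0,
                       ahd_variant = ahd_variant))
  }))
  list(per_case = per, aggregate = aggregate_metrics(per), unpaired = unpaired)
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report Result of [penet_evaluate()].
#' @param csv_path,json_path Output paths (either may be NULL).
#' @export
write_metrics <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_case, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$aggregate, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(report)
}

#' Desk-scale presets
#'
#' Architecture and phantom settings sized so a full train/evaluate cycle
#' runs on one CPU in minutes: 2 levels with widths 4-8, 2 heads of
#' dimension 4, 32-cube volumes; phantoms with two branches and one
#' distractor tube.
#'
#' @param seed Phantom seed.
#' @return `desk_net_config()`: a [net_config()]; `desk_phantom_spec()`: a
#'   [phantom_spec()].
#' @export
desk_net_config <- function() {
  net_config(levels = 2L, base_channels = 4L, heads = 2L, head_dim = 4L,
             crop = 32L)
}

#' @rdname desk_net_config
#' @export
desk_phantom_spec <- function(seed = 1L) {
  phantom_spec(extent = 32L, n_branches = 2L, radius_range = c(1.5, 2.5),
               curvature = 0.15, distractor_count = 1L, seed = seed)
}
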