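# Full network assembly: per encoder level a double-convolution CNN
# branch runs in parallel with a TAGT branch; the two are fused by FFM.
# Skip paths pass through EFC (using the adjacent deeper level) and FFB;
# the decoder upsamples with transposed convolutions and ends in a 1x1x1
# convolution plus channel softmax.

#' Network configuration
#'
#' @param levels Number of encoder levels (downsampling happens
#'   `levels - 1` times).
#' @param base_channels Width of the first level; widths double per level.
#' @param heads,head_dim TAGT head layout.
#' @param crop Cubic crop size the positional tables are built for; must
#'   be divisible by `2^(levels - 1)`.
#' @param num_classes Output classes (background/vessel).
#' @param gate_init Initial value of the attention gates.
#' @param tagt_weight_map Passed to [tagt_config()].
#' @param ffb_gate_mode Passed to [ffb_params()].
#' @return A `net_config` list.
#' @export
net_config <- function(levels = 4L, base_channels = 8L, heads = 8L,
                       head_dim = 16L, crop = 128L, num_classes = 2L,
                       gate_init = 1, tagt_weight_map = "sigmoid",
                       ffb_gate_mode = "spatial") {
  levels <- as.integer(levels); crop <- as.integer(crop)
  if (base_channels < 1) stop("net_config: base_channels must be >= 1")
  if (crop %% 2L^(levels - 1L) != 0L)
    stop(sprintf("net_config: crop %d is not divisible by 2^(levels-1) = %d",
                 crop, 2L^(levels - 1L)))
  structure(list(levels = levels, base_channels = as.integer(base_channels),
                 heads = as.integer(heads), head_dim = as.integer(head_dim),
                 crop = crop, num_classes = as.integer(num_classes),
                 gate_init = gate_init, tagt_weight_map = tagt_weight_map,
                 ffb_gate_mode = ffb_gate_mode),
            class = "net_config")
}

net_widths <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$levels) - 1L)

double_conv_params <- function(ci, co) {
  mk <- function(ci, co) list(
    w = array(stats::rnorm(co * ci * 27, sd = sqrt(2 / (ci * 27))), c(co, ci, 3, 3, 3)),
    b = rep(0, co), gamma = rep(1, co), beta = rep(0, co))
  list(c1 = mk(ci, co), c2 = mk(co, co))
}

double_conv <- function(x, p) {
  y <- op_conv3d(x, p$c1$w, p$c1$b, stride = 1L, pad = 1L)
  y <- op_relu(op_groupnorm(y, p$c1$gamma, p$c1$beta))
  y <- op_conv3d(y, p$c2$w, p$c2$b, stride = 1L, pad = 1L)
  op_relu(op_groupnorm(y, p$c2$gamma, p$c2$beta))
}

#' Build a segmentation model
#'
#' Initializes all parameters for the configured architecture. Initial
#' weights are drawn from the current RNG state; seed beforehand for
#' reproducible builds.
#'
#' @param cfg A [net_config()].
#' @return A `penet_model` list with `cfg`, the parameter tree `params`
#'   (plain arrays) and `n_params`.
#' @export
penet_build <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  w <- net_widths(cfg)
  Lv <- cfg$levels
  tcfg <- tagt_config(cfg$heads, cfg$head_dim, weight_map = cfg$tagt_weight_map)
  ext <- function(i) rep(cfg$crop %/% 2L^(i - 1L), 3L)
  enc <- list()
  for (i in seq_len(Lv)) {
    ci <- if (i == 1L) 1L else w[i - 1L]
    enc[[i]] <- list(
      down = if (i == 1L) NULL else list(
        w = array(stats::rnorm(ci * ci * 8, sd = sqrt(2 / (ci * 8))),
                  c(ci, ci, 2, 2, 2)),
        b = rep(0, ci)),
      conv = double_conv_params(ci, w[i]),
      tagt = tagt_params(1L, ext(i), tcfg, gate_init = cfg$gate_init),
      ffm = ffm_params(w[i])
    )
  }
  bottleneck <- double_conv_params(w[Lv], 2L * w[Lv])
  dec <- list()
  for (i in seq_len(Lv - 1L)) {
    cu <- if (i == Lv - 1L) 2L * w[Lv] else w[i + 1L]
    dec[[i]] <- list(
      up = list(w = array(stats::rnorm(cu * w[i] * 8, sd = sqrt(2 / (cu * 8))),
                          c(cu, w[i], 2, 2, 2)),
                b = rep(0, w[i])),
      efc = efc_params(w[i + 1L], w[i]),
      ffb = ffb_params(2L * w[i], w[i], gate_mode = cfg$ffb_gate_mode),
      conv = double_conv_params(w[i], w[i])
    )
  }
  head <- list(w = matrix(stats::rnorm(cfg$num_classes * w[1L], sd = 1 / sqrt(w[1L])),
                          cfg$num_classes, w[1L]),
               b = rep(0, cfg$num_classes))
  params <- list(enc = enc, bottleneck = bottleneck, dec = dec, head = head)
  model <- structure(list(cfg = cfg, params = params,
                          n_params = count_params(params)),
                     class = "penet_model")
  model
}

#' Total learnable parameter count of a parameter tree
#' @param params Nested list of numeric arrays (or a `penet_model`).
#' @export
count_params <- function(params) {
  if (inherits(params, "penet_model")) params <- params$params
  n <- 0L
  walk <- function(p) {
    if (is_pn(p)) p <- p$value
    if (is.numeric(p)) n <<- n + length(p)
    else if (is.list(p)) for (q in p) walk(q)
  }
  walk(params)
  n
}

check_divisible <- function(d, cfg) {
  f <- 2L^(cfg$levels - 1L)
  if (any(d[3:5] %% f != 0L))
    stop(sprintf("input extents %s are not divisible by the downsampling factor %d",
                 paste(d[3:5], collapse = "x"), f))
}

#' Forward pass of the full network
#'
#' @param model A `penet_model` (from [penet_build()] or [penet_load()]);
#'   its parameter tree may hold plain arrays (tape-free inference) or
#'   `pn_tensor` leaves (training).
#' @param x Input volume `(N, 1, D, H, W)` with extents divisible by
#'   `2^(levels - 1)`. Positional tables must match the per-level extents
#'   (inputs of the configured crop size, or any size after
#'   [penet_resize_tables()]).
#' @return Class-probability volume `(N, num_classes, D, H, W)`; per-voxel
#'   probabilities sum to one.
#' @export
penet_forward <- function(model, x) {
  cfg <- model$cfg
  p <- model$params
  d <- dim(pn_val(x))
  if (length(d) != 5L) stop("penet_forward: input must be rank-5 (N, C, D, H, W)")
  check_divisible(d, cfg)
  tcfg <- tagt_config(cfg$heads, cfg$head_dim, weight_map = cfg$tagt_weight_map)
  Lv <- cfg$levels
  feats <- vector("list", Lv)
  cnn_in <- x
  tagt_in <- x
  for (i in seq_len(Lv)) {
    if (i > 1L) {
      cnn_in <- op_conv3d(feats[[i - 1L]], p$enc[[i]]$down$w, p$enc[[i]]$down$b,
                          stride = 2L, pad = 0L)
      tagt_in <- op_avgpool2(tagt_in)
    }
    fc <- double_conv(cnn_in, p$enc[[i]]$conv)
    tm <- tagt_layer(tagt_in, tcfg, p$enc[[i]]$tagt)
    feats[[i]] <- ffm(fc, tm, p$enc[[i]]$ffm)
    tagt_in <- tm
  }
  dec <- double_conv(feats[[Lv]], p$bottleneck)
  for (i in rev(seq_len(Lv - 1L))) {
    up <- op_convt3d(dec, p$dec[[i]]$up$w, p$dec[[i]]$up$b)
    skip <- efc(feats[[i + 1L]], feats[[i]], p$dec[[i]]$efc)
    fused <- ffb(skip, up, p$dec[[i]]$ffb, project = TRUE)
    dec <- double_conv(fused, p$dec[[i]]$conv)
  }
  logits <- op_conv1x1(dec, p$head$w, p$head$b)
  op_softmax_ch(logits)
}

#' Resize a model's positional tables to new input extents
#'
#' Positional tables are sized to the configured crop. For a different
#' (divisible) input size, tables are remapped by nearest-offset lookup.
#'
#' @param model A `penet_model`.
#' @param crop New cubic crop size.
#' @return The model with resized tables and updated `cfg$crop`.
#' @export
penet_resize_tables <- function(model, crop) {
  cfg <- model$cfg
  crop <- as.integer(crop)
  if (crop %% 2L^(cfg$levels - 1L) != 0L)
    stop("penet_resize_tables: crop not divisible by the downsampling factor")
  for (i in seq_len(cfg$levels)) {
    Lnew <- crop %/% 2L^(i - 1L)
    for (ax in names(AXES)) {
      tb <- model$params$enc[[i]]$tagt$axes[[ax]]
      Lold <- dim(tb$rq)[1]
      idx <- pmin(pmax(round(seq_len(Lnew) * Lold / Lnew), 1L), Lold)
      for (nm in c("rq", "rk", "rv"))
        tb[[nm]] <- tb[[nm]][idx, idx, , drop = FALSE]
      model$params$enc[[i]]$tagt$axes[[ax]] <- tb
    }
  }
  model$cfg$crop <- crop
  model
}

#' Per-layer architecture summary
#'
#' Arithmetic walk over the configured architecture at the configured crop
#' size: layer names, input/output dimensions `(N, C, D, H, W)` and
#' kernel/stride notes, in the style of a layer table.
#'
#' @param cfg A [net_config()].
#' @param batch Batch size used in the printed dimensions.
#' @return A data.frame with columns `layer`, `input`, `output`,
#'   `supplement`.
#' @export
penet_summary <- function(cfg, batch = 1L) {
  w <- net_widths(cfg)
  Lv <- cfg$levels
  dims <- function(C, s) paste(c(batch, C, s, s, s), collapse = ", ")
  rows <- list()
  addr <- function(layer, inp, out, sup = "")
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, input = inp,
                                             output = out, supplement = sup)
  s <- cfg$crop
  for (i in seq_len(Lv)) {
    ci <- if (i == 1L) 1L else w[i - 1L]
    if (i > 1L) {
      addr(sprintf("Down%d", i), dims(ci, s * 2L), dims(ci, s), "K = 2, S = 2")
    }
    addr(sprintf("Double Conv%d", i), dims(ci, s), dims(w[i], s), "K = 3, S = 1")
    np <- count_axial_problems(cfg, rep(s, 3L), "depth", batch = batch)
    addr(sprintf("TAGT%d head = %d head_dim = %d", i, cfg$heads, cfg$head_dim),
         dims(1L, s), dims(1L, s),
         sprintf("q, k, v = (%d, 1, 1, %d) / (%d, %d, %d)",
                 np$problems, cfg$head_dim, np$folded_leading, s, s))
    addr(sprintf("FFM%d", i), dims(w[i], s), dims(w[i], s), "channel attention")
    s <- s %/% 2L
  }
  s <- cfg$crop %/% 2L^(Lv - 1L)
  addr("Bottleneck", dims(w[Lv], s), dims(2L * w[Lv], s), "K = 3, S = 1")
  for (i in rev(seq_len(Lv - 1L))) {
    s2 <- cfg$crop %/% 2L^(i - 1L)
    cu <- if (i == Lv - 1L) 2L * w[Lv] else w[i + 1L]
    addr(sprintf("Up%d", i), dims(cu, s2 %/% 2L), dims(w[i], s2), "K = 2, S = 2")
    addr(sprintf("EFC%d", i), dims(w[i + 1L], s2 %/% 2L), dims(w[i], s2), "K = 2, S = 2")
    addr(sprintf("FFB%d", i), dims(2L * w[i], s2), dims(w[i], s2), "K = 3/3/1")
    addr(sprintf("Double Conv dec%d", i), dims(w[i], s2), dims(w[i], s2), "K = 3, S = 1")
  }
  addr("Head", dims(w[1L], cfg$crop), dims(cfg$num_classes, cfg$crop),
       "K = 1, softmax")
  do.call(rbind, rows)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized checkpoint holding the plain-array parameter
#' tree, the configuration, and the package version.
#'
#' @param model A `penet_model`.
#' @param path File path.
#' @export
penet_save <- function(model, path) {
  obj <- list(cfg = model$cfg, params = pn_unwrap_params(model$params),
              n_params = model$n_params,
              version = as.character(utils::packageVersion("penet")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname penet_save
#' @export
penet_load <- function(path) {
  obj <- readRDS(path)
  structure(list(cfg = obj$cfg, params = obj$params,
                 n_params = obj$n_params, version = obj$version),
            class = "penet_model")
}

#' @export
print.penet_model <- function(x, ...) {
  cat(sprintf("<penet_model: %d levels, base width %d, heads %d x %d, crop %d, %s parameters>\n",
              x$cfg$levels, x$cfg$base_channels, x$cfg$heads, x$cfg$head_dim,
              x$cfg$crop, format(x$n_params, big.mark = ",")))
  invisible(x)
}
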