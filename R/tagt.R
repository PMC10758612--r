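# Triple-axial gated transformer (TAGT) layer: gated axial attention run
# along depth, height and width, summed, squashed to a position weight
# map, applied to the input, then projected and residually connected.

#' TAGT layer configuration
#'
#' @param heads Number of attention heads.
#' @param head_dim Per-head embedding dimension.
#' @param axis_order Order in which the three axes are evaluated (the sum
#'   is order-invariant up to floating-point rounding).
#' @param weight_map `"sigmoid"` (default): the summed axial outputs pass
#'   through a logistic to give a weight map in (0,1); `"raw"` exposes the
#'   un-squashed sum.
#' @param norm Normalization applied to the layer input and after the
#'   output projection; `"group"` is group normalization with one group.
#' @return A `tagt_config` list.
#' @export
tagt_config <- function(heads = 8L, head_dim = 16L,
                        axis_order = c("depth", "height", "width"),
                        weight_map = c("sigmoid", "raw"),
                        norm = "group") {
  stopifnot(heads >= 1, head_dim >= 1)
  if (length(axis_order) != 3L || !setequal(axis_order, names(AXES)))
    stop("axis_order must be a permutation of depth, height, width")
  structure(list(heads = as.integer(heads), head_dim = as.integer(head_dim),
                 axis_order = axis_order,
                 weight_map = match.arg(weight_map), norm = norm),
            class = "tagt_config")
}

#' Initialize TAGT layer parameters
#'
#' One shared q/k/v projection plus per-axis relative-position tables and
#' gates, an output 1x1x1 projection to a single channel, and the affine
#' parameters of the two normalizations.
#'
#' @param in_channels Channels of the layer input (the position-weight-map
#'   branch carries a single channel).
#' @param extents Spatial extents `c(D, H, W)` the tables are sized to.
#' @param cfg A [tagt_config()].
#' @param gate_init Initial gate value.
#' @return Nested parameter list (plain arrays).
#' @export
tagt_params <- function(in_channels, extents, cfg, gate_init = 1) {
  Z <- cfg$heads * cfg$head_dim
  axes <- list()
  for (ax in names(AXES)) {
    axes[[ax]] <- axial_tables(extents[[AXES[[ax]] - 2L]], cfg$head_dim,
                               gate_init = gate_init)
  }
  list(
    norm_in = list(gamma = rep(1, in_channels), beta = rep(0, in_channels)),
    proj = qkv_projections(in_channels, cfg$heads, cfg$head_dim),
    axes = axes,
    out = list(w = matrix(stats::rnorm(Z, sd = 1 / sqrt(Z)), 1, Z), b = 0),
    norm_out = list(gamma = 1, beta = 0)
  )
}

#' TAGT layer forward pass
#'
#' Pipeline: group-normalize the input, embed q/k/v, run gated axial
#' attention along depth, height and width, sum the three outputs,
#' logistic-squash into a position weight map, multiply the map with the
#' original input, project with a 1x1x1 convolution plus normalization,
#' and add the input back (residual). The layer is evaluated one head at a
#' time so large volumes never materialize the full multi-head q/k/v.
#'
#' @param x Volume `(N, C, D, H, W)`; the position-weight-map branch uses
#'   `C = 1`.
#' @param cfg A [tagt_config()].
#' @param params Parameters from [tagt_params()].
#' @return Single-channel volume `(N, 1, D, H, W)`.
#' @export
tagt_layer <- function(x, cfg, params) {
  xv <- pn_val(x)
  d <- dim(xv)
  if (length(d) != 5L) stop("tagt_layer: input must be rank-5 (N, C, D, H, W)")
  if (d[2] != 1L) stop("tagt_layer: the position-weight-map branch expects a single-channel input")
  for (ax in names(AXES)) {
    L <- dim(pn_val(params$axes[[ax]]$rq))[1]
    if (L != d[AXES[[ax]]])
      stop(sprintf("tagt_layer: %s positional table length %d does not match extent %d",
                   ax, L, d[AXES[[ax]]]))
  }
  dm <- cfg$head_dim
  xn <- op_groupnorm(x, params$norm_in$gamma, params$norm_in$beta)
  # Heads are processed in blocks sized so q/k/v never exceed a memory
  # budget (large volumes go head by head, small ones in one block); the
  # 1x1x1 output projection is linear in channels, so block contributions
  # of conv1x1(weight_map * x) just add.
  nvox <- prod(d[c(1, 3:5)])
  block <- max(1L, min(cfg$heads, floor(2^25 / (dm * nvox))))
  acc <- NULL
  h0 <- 1L
  while (h0 <= cfg$heads) {
    nb <- min(block, cfg$heads - h0 + 1L)
    rows <- (h0 - 1L) * dm + seq_len(nb * dm)
    ph <- list(Wq = op_slice_rows(params$proj$Wq, rows),
               Wk = op_slice_rows(params$proj$Wk, rows),
               Wv = op_slice_rows(params$proj$Wv, rows))
    qkv <- embed_qkv(xn, ph)
    att <- NULL
    for (ax in cfg$axis_order) {
      ya <- gated_axial_attention(qkv, ax, params$axes[[ax]], nb, dm)
      att <- if (is.null(att)) ya else op_add(att, ya)
    }
    wmap <- if (cfg$weight_map == "sigmoid") op_sigmoid(att) else att
    gated <- op_mul_bcast(wmap, x)
    ch <- op_conv1x1(gated, op_slice_cols(params$out$w, rows))
    acc <- if (is.null(acc)) ch else op_add(acc, ch)
    h0 <- h0 + nb
  }
  out <- pn_make(pn_val(acc) + pn_val(params$out$b),
                 list(acc, params$out$b),
                 function(g) list(g, sum(g)))
  out <- op_groupnorm(out, params$norm_out$gamma, params$norm_out$beta)
  op_add(out, x)
}
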