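# Feature fusion blocks. FFB gates the concatenation of skip features and
# upsampled decoder features with an attention map computed by three
# convolution blocks. FFM fuses the two parallel encoder branches (CNN
# features and the single-channel TAGT position map) with
# squeeze-excitation style channel attention.

#' Initialize FFB parameters
#'
#' Three convolution blocks (kernels 3, 3, 1, each followed by group
#' normalization and ReLU) compute the selection map; a final 1x1x1
#' projection maps the gated concatenation to the decoder width.
#'
#' @param in_channels Channels of the concatenated feature
#'   (skip + decoder).
#' @param out_channels Decoder width after fusion.
#' @param gate_mode `"spatial"` (default): the third block emits a single
#'   channel so the attention map is a spatial saliency map broadcast over
#'   channels; `"channel"`: the third block emits `in_channels` so gating
#'   is per channel.
#' @export
ffb_params <- function(in_channels, out_channels, gate_mode = c("spatial", "channel")) {
  gate_mode <- match.arg(gate_mode)
  c3 <- function(ci, co) list(
    w = array(stats::rnorm(co * ci * 27, sd = sqrt(2 / (ci * 27))), c(co, ci, 3, 3, 3)),
    b = rep(0, co), gamma = rep(1, co), beta = rep(0, co))
  cg <- if (gate_mode == "spatial") 1L else in_channels
  list(
    block1 = c3(in_channels, in_channels),
    block2 = c3(in_channels, in_channels),
    block3 = list(w = matrix(stats::rnorm(cg * in_channels, sd = 1 / sqrt(in_channels)),
                             cg, in_channels),
                  b = rep(0, cg), gamma = rep(1, cg), beta = rep(0, cg)),
    proj = list(w = matrix(stats::rnorm(out_channels * in_channels,
                                        sd = 1 / sqrt(in_channels)),
                           out_channels, in_channels),
                b = rep(0, out_channels)),
    gate_mode = gate_mode
  )
}

conv_block3 <- function(x, bp) {
  y <- op_conv3d(x, bp$w, bp$b, stride = 1L, pad = 1L)
  op_relu(op_groupnorm(y, bp$gamma, bp$beta))
}

#' Feature fusion block (skip path / decoder fusion)
#'
#' Concatenates skip and decoder features along channels, computes a
#' selection map through the three convolution blocks, squashes it with
#' the logistic into attention weights `A`, and gates the concatenation
#' with `A`. With `project = TRUE` (as used inside the network) the gated
#' feature is additionally projected to the decoder width with a 1x1x1
#' convolution.
#'
#' @param skip Skip-path volume `(N, C1, D, H, W)`.
#' @param decoded Upsampled decoder volume `(N, C2, D, H, W)` (same
#'   spatial extents).
#' @param params [ffb_params()] built for `C1 + C2` input channels.
#' @param project Apply the output projection (default `FALSE`: the raw
#'   gated concatenation is returned).
#' @return Volume `(N, C1 + C2, D, H, W)`, or `(N, out_channels, D, H, W)`
#'   when `project = TRUE`.
#' @export
ffb <- function(skip, decoded, params, project = FALSE) {
  ds <- dim(pn_val(skip)); dd <- dim(pn_val(decoded))
  if (!all(ds[3:5] == dd[3:5]))
    stop(sprintf("FFB: skip extents %s do not match decoder extents %s",
                 paste(ds[3:5], collapse = "x"), paste(dd[3:5], collapse = "x")))
  f <- op_concat_ch(skip, decoded)
  w <- conv_block3(f, params$block1)
  w <- conv_block3(w, params$block2)
  w <- op_conv1x1(w, params$block3$w, params$block3$b)
  w <- op_relu(op_groupnorm(w, params$block3$gamma, params$block3$beta))
  a <- op_sigmoid(w)
  gated <- if (params$gate_mode == "spatial") op_mul_bcast(f, a) else op_mul(f, a)
  if (!project) return(gated)
  op_conv1x1(gated, params$proj$w, params$proj$b)
}

#' Initialize FFM parameters
#'
#' Squeeze-excitation channel attention over the concatenation of the
#' convolutional features and the broadcast TAGT map.
#'
#' @param channels Channel count of the convolutional branch.
#' @param reduction Bottleneck reduction ratio.
#' @export
ffm_params <- function(channels, reduction = 2L) {
  tc <- 2L * channels
  hid <- max(1L, tc %/% reduction)
  list(
    # small positive bias keeps the narrow bottleneck's ReLU units active
    # at initialization so the descriptor trains from the first step
    fc1 = list(w = matrix(stats::rnorm(hid * tc, sd = 1 / sqrt(tc)), hid, tc),
               b = rep(0.1, hid)),
    fc2 = list(w = matrix(stats::rnorm(tc * hid, sd = 1 / sqrt(hid)), tc, hid),
               b = rep(0, tc))
  )
}

#' Feature fusion module (parallel-branch fusion)
#'
#' Broadcasts the single-channel TAGT position map to the convolutional
#' branch's channel count, concatenates, weights every channel with a
#' squeeze-excitation descriptor (global average pool, bottleneck,
#' logistic), and combines the two gated halves by elementwise sum so the
#' output keeps the convolutional branch's channel count.
#'
#' @param conv_feat Convolutional-branch volume `(N, C, D, H, W)`.
#' @param tagt_map Single-channel TAGT volume `(N, 1, D, H, W)`.
#' @param params [ffm_params()].
#' @return Volume `(N, C, D, H, W)`.
#' @export
ffm <- function(conv_feat, tagt_map, params) {
  dc <- dim(pn_val(conv_feat)); dt <- dim(pn_val(tagt_map))
  if (dt[2] != 1L) stop("FFM: the TAGT map must be single-channel")
  if (!all(dc[3:5] == dt[3:5]))
    stop(sprintf("FFM: conv extents %s do not match TAGT extents %s",
                 paste(dc[3:5], collapse = "x"), paste(dt[3:5], collapse = "x")))
  C <- dc[2]
  xb <- op_broadcast_ch(tagt_map, C)
  cat2 <- op_concat_ch(conv_feat, xb)
  s <- op_gap(cat2)
  s <- op_relu(op_dense(s, params$fc1$w, params$fc1$b))
  s <- op_sigmoid(op_dense(s, params$fc2$w, params$fc2$b))
  scaled <- op_scale_channels(cat2, s)
  op_add(op_slice_ch(scaled, seq_len(C)), op_slice_ch(scaled, C + seq_len(C)))
}
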