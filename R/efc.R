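# Edge feature capture (EFC): a dual-path block on the skip connections
# that up-weights vessel-boundary voxels. Path 1 derives an edge weight
# map from the adjacent deeper encoder layer (upsampled 2x); path 2 from
# the skip layer itself. Both weight maps are single-channel and broadcast
# across the skip feature's channels.

#' Initialize EFC block parameters
#'
#' @param deep_channels Channels of the deeper layer `F_i` (half
#'   resolution).
#' @param skip_channels Channels of the skip layer `F_(i-1)`.
#' @param share_conv1 If `TRUE`, the 1x1x1 channel-reduction convolution is
#'   shared between the two paths.
#' @return Nested parameter list: `up` (transposed convolution, kernel 2,
#'   stride 2), `conv1_p1`, `conv1_p2` (1x1x1 reductions to one channel).
#' @export
efc_params <- function(deep_channels, skip_channels, share_conv1 = FALSE) {
  p <- list(
    up = list(w = array(stats::rnorm(deep_channels * skip_channels * 8,
                                     sd = 1 / sqrt(deep_channels * 8)),
                        c(deep_channels, skip_channels, 2, 2, 2)),
              b = rep(0, skip_channels)),
    conv1_p1 = list(w = matrix(stats::rnorm(skip_channels, sd = 1 / sqrt(skip_channels)),
                               1, skip_channels), b = 0),
    share_conv1 = share_conv1
  )
  p$conv1_p2 <- if (share_conv1) p$conv1_p1 else
    list(w = matrix(stats::rnorm(skip_channels, sd = 1 / sqrt(skip_channels)),
                    1, skip_channels), b = 0)
  p
}

conv1_map <- function(x, cp) {
  z <- op_conv1x1(x, cp$w, cp$b)
  op_sigmoid(op_relu(z))
}

#' Path-1 edge weights from the deeper layer
#'
#' Upsamples `F_i` 2x (transposed convolution, kernel 2, stride 2),
#' reduces to one channel, applies ReLU then the logistic, and returns
#' `A = 1 - sigma_1`. Since ReLU output is nonnegative, `sigma_1 >= 0.5`
#' and every entry of `A` lies in `[0, 0.5]`.
#'
#' @param f_deep Deeper-layer volume `(N, C_i, D/2, H/2, W/2)`.
#' @param params [efc_params()].
#' @param target_extents Spatial extents of the skip layer (for the shape
#'   check).
#' @return Single-channel weight volume at the skip layer's resolution.
#' @export
edge_weight_path1 <- function(f_deep, params, target_extents = NULL) {
  up <- op_convt3d(f_deep, params$up$w, params$up$b)
  de <- dim(pn_val(up))[3:5]
  if (!is.null(target_extents) && !all(de == target_extents))
    stop(sprintf("EFC path 1: upsampled extents %s do not match skip extents %s",
                 paste(de, collapse = "x"), paste(target_extents, collapse = "x")))
  s1 <- conv1_map(up, params$conv1_p1)
  op_sub(array(1, dim(pn_val(s1))), s1)
}

#' Path-1 edge enhancement
#'
#' `E = F * A` (elementwise, `A` broadcast over channels) and
#' `F_sum1 = F + E`.
#'
#' @param f_skip Skip-layer volume.
#' @param a Edge weight map from [edge_weight_path1()].
#' @export
edge_enhance_path1 <- function(f_skip, a) {
  op_add(f_skip, op_mul_bcast(f_skip, a))
}

#' Path-2 edge enhancement from the skip layer itself
#'
#' `sigma_2 = logistic(ReLU(conv1(F)))`, `F_sum2 = F * sigma_2 + F` (no
#' upsampling on this path). `sigma_2` always lies in `[0.5, 1)`.
#'
#' @param f_skip Skip-layer volume.
#' @param params [efc_params()].
#' @export
edge_enhance_path2 <- function(f_skip, params) {
  s2 <- conv1_map(f_skip, params$conv1_p2)
  op_add(op_mul_bcast(f_skip, s2), f_skip)
}

#' Edge feature capture block
#'
#' `F_sum = F_sum1 + F_sum2`; with all convolution weights zero this
#' reduces to `3 * F_skip` exactly (both logistic maps sit at 0.5).
#'
#' @param f_deep Deeper-layer volume at half the skip resolution.
#' @param f_skip Skip-layer volume.
#' @param params [efc_params()].
#' @return Volume with the skip layer's shape.
#' @export
efc <- function(f_deep, f_skip, params) {
  dd <- dim(pn_val(f_deep))[3:5]
  ds <- dim(pn_val(f_skip))[3:5]
  if (!all(2L * dd == ds))
    stop(sprintf("EFC: deeper extents %s must be exactly half of skip extents %s",
                 paste(dd, collapse = "x"), paste(ds, collapse = "x")))
  a <- edge_weight_path1(f_deep, params, target_extents = ds)
  f1 <- edge_enhance_path1(f_skip, a)
  f2 <- edge_enhance_path2(f_skip, params)
  op_add(f1, f2)
}
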