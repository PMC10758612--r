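# Convolution ops backed by the compiled kernels. Volumes are R arrays
# with dim = c(batch, channel, depth, height, width).

#' 3D convolution
#'
#' Direct (cross-correlation) 3D convolution with cubic kernel, symmetric
#' zero padding and integer stride. Works on plain arrays or autodiff
#' tensors.
#'
#' @param x Input volume `(N, Cin, D, H, W)` (array or `pn_tensor`).
#' @param w Kernel `(Cout, Cin, k, k, k)`.
#' @param b Optional bias of length `Cout`.
#' @param stride Integer stride (1 or 2 are used in this package).
#' @param pad Zero padding on every spatial side.
#' @return Volume `(N, Cout, D', H', W')`.
#' @export
op_conv3d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- pn_val(x); wv <- pn_val(w)
  dx <- dim(xv); dw <- dim(wv)
  if (length(dx) != 5L) stop("conv3d: input must be rank-5 (N, C, D, H, W)")
  if (dx[2] != dw[2])
    stop(sprintf("conv3d: weight expects %d input channels, input has %d",
                 dw[2], dx[2]))
  bv <- if (is.null(b)) numeric(0) else pn_val(b)
  need_dx <- is_pn(x)
  if (stride == 1L) {
    y <- .cpp_conv3d_s1_fwd(xv, wv, bv, as.integer(pad))
    return(pn_make(y, list(x, w, b), function(g) {
      gr <- .cpp_conv3d_s1_bwd(xv, wv, g, as.integer(pad), need_dx)
      list(if (need_dx) gr$dx else NULL, gr$dw,
           if (is.null(b)) NULL else gr$db)
    }))
  }
  y <- .cpp_conv3d_fwd(xv, wv, bv, as.integer(stride), as.integer(pad))
  pn_make(y, list(x, w, b), function(g) {
    gr <- .cpp_conv3d_bwd(xv, wv, g, as.integer(stride), as.integer(pad),
                          need_dx)
    list(if (need_dx) gr$dx else NULL, gr$dw,
         if (is.null(b)) NULL else gr$db)
  })
}

#' Transposed 3D convolution (kernel 2, stride 2)
#'
#' Exact 2x spatial upsampler used by the decoder and the edge-capture
#' block.
#'
#' @param x Input volume `(N, Cin, D, H, W)`.
#' @param w Kernel `(Cin, Cout, 2, 2, 2)`.
#' @param b Optional bias of length `Cout`.
#' @return Volume `(N, Cout, 2D, 2H, 2W)`.
#' @export
op_convt3d <- function(x, w, b = NULL) {
  xv <- pn_val(x); wv <- pn_val(w)
  bv <- if (is.null(b)) numeric(0) else pn_val(b)
  if (dim(xv)[2] != dim(wv)[1])
    stop(sprintf("conv_transpose3d: weight expects %d input channels, input has %d",
                 dim(wv)[1], dim(xv)[2]))
  y <- .cpp_convt3d_fwd(xv, wv, bv)
  pn_make(y, list(x, w, b), function(g) {
    gr <- .cpp_convt3d_bwd(xv, wv, g)
    list(gr$dx, gr$dw, if (is.null(b)) NULL else gr$db)
  })
}

#' Pointwise (1x1x1) convolution
#'
#' A per-voxel linear map across channels, computed as a single BLAS
#' matrix product.
#'
#' @param x Input volume `(N, Cin, D, H, W)`.
#' @param w Matrix `(Cout, Cin)`.
#' @param b Optional bias of length `Cout`.
#' @return Volume `(N, Cout, D, H, W)`.
#' @export
op_conv1x1 <- function(x, w, b = NULL) {
  xv <- pn_val(x); wv <- pn_val(w)
  d <- dim(xv)
  if (is.null(dim(wv))) dim(wv) <- c(1L, length(wv))
  if (d[2] != ncol(wv))
    stop(sprintf("conv1x1: weight expects %d input channels, input has %d",
                 ncol(wv), d[2]))
  Co <- nrow(wv)
  # (N, C, S) with S = D*H*W; contract over C
  x3 <- xv
  dim(x3) <- c(d[1], d[2], prod(d[3:5]))
  y <- array(0, c(d[1], Co, prod(d[3:5])))
  for (n in seq_len(d[1])) {
    xm <- array(x3[n, , ], c(d[2], prod(d[3:5])))
    y[n, , ] <- wv %*% xm
  }
  if (!is.null(b)) {
    bv <- pn_val(b)
    for (co in seq_len(Co)) y[, co, ] <- y[, co, ] + bv[co]
  }
  dim(y) <- c(d[1], Co, d[3], d[4], d[5])
  pn_make(y, list(x, w, b), function(g) {
    g3 <- g
    dim(g3) <- c(d[1], Co, prod(d[3:5]))
    gx <- array(0, c(d[1], d[2], prod(d[3:5])))
    gw <- matrix(0, Co, d[2])
    for (n in seq_len(d[1])) {
      gm <- array(g3[n, , ], c(Co, prod(d[3:5])))
      xm <- array(x3[n, , ], c(d[2], prod(d[3:5])))
      gx[n, , ] <- crossprod(wv, gm)
      gw <- gw + tcrossprod(gm, xm)
    }
    dim(gx) <- d
    gb <- if (is.null(b)) NULL else apply(g3, 2, sum)
    list(gx, gw, gb)
  })
}
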