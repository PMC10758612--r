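# Minimal reverse-mode automatic differentiation over plain R numeric
# arrays. Every op is dual-mode: given plain arrays it just computes the
# value (tape-free inference); given at least one `pn_tensor` it records a
# node whose `backward` maps the output gradient to per-parent gradients.

pn_env <- new.env(parent = emptyenv())
pn_env$id <- 0L

pn_next_id <- function() {
  pn_env$id <- pn_env$id + 1L
  pn_env$id
}

#' Create an autodiff leaf tensor
#'
#' Wraps a numeric array as a leaf node of the computation graph. After a
#' call to [pn_backward()] on a downstream scalar, the accumulated gradient
#' is available in `$grad`.
#'
#' @param value Numeric array (any shape) or scalar.
#' @return An object of class `pn_tensor`.
#' @export
pn_tensor <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- list()
  e$backward <- NULL
  e$grad <- NULL
  e$id <- pn_next_id()
  class(e) <- "pn_tensor"
  e
}

is_pn <- function(x) inherits(x, "pn_tensor")

#' Value of a tensor or plain array
#'
#' Returns the numeric value held by a `pn_tensor`, or the input unchanged.
#' @param x A `pn_tensor` or numeric array.
#' @export
pn_val <- function(x) if (is_pn(x)) x$value else x

# internal node constructor; `backward` returns a list of gradients
# aligned with `parents` (NULL entries allowed for constants)
pn_node <- function(value, parents, backward) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$id <- pn_next_id()
  class(e) <- "pn_tensor"
  e
}

# Build a node if any input is a tensor, else return the plain value.
pn_make <- function(value, inputs, backward) {
  if (!any(vapply(inputs, is_pn, logical(1)))) return(value)
  pn_node(value, inputs, backward)
}

#' @export
print.pn_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<pn_tensor", if (is.null(d)) paste0("scalar(", length(x$value), ")") else
    paste(d, collapse = "x"), ">\n")
  invisible(x)
}

pn_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Reverse-mode backward pass
#'
#' Accumulates gradients of a scalar-valued tensor with respect to every
#' tensor in its graph (gradients land in each node's `$grad`).
#'
#' @param root A `pn_tensor` holding a scalar value.
#' @param grad Seed gradient; defaults to 1.
#' @export
pn_backward <- function(root, grad = 1) {
  stopifnot(is_pn(root))
  # iterative topological sort (graphs can be deep)
  order <- vector("list", 64L)
  norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is_pn(p) && is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
    }
  }
  root$grad <- grad
  for (i in seq(norder, 1L)) {
    node <- order[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      if (is_pn(ps[[j]]) && !is.null(gs[[j]])) pn_accum(ps[[j]], gs[[j]])
    }
  }
  invisible(root)
}

#' Clear gradients in a nested parameter structure
#' @param params Nested list of `pn_tensor` leaves.
#' @export
pn_zero_grad <- function(params) {
  rapply(params, function(p) { if (is_pn(p)) p$grad <- NULL; NULL },
         classes = "ANY", how = "unlist")
  invisible(params)
}

# --- elementwise ops ---------------------------------------------------------

#' Elementwise and reduction ops on tensors or arrays
#'
#' Dual-mode autodiff operations: on plain arrays they simply compute the
#' value; if any argument is a [pn_tensor()] they record a graph node for
#' [pn_backward()]. `op_add`/`op_sub`/`op_mul` are elementwise on
#' equal-shaped arguments, `op_scale` multiplies by a plain scalar,
#' `op_sum`/`op_mean` reduce to a scalar, `op_relu`/`op_sigmoid` apply the
#' pointwise nonlinearity.
#'
#' @param a,b Tensors or numeric arrays.
#' @param s Plain numeric scalar.
#' @name engine-ops
NULL

#' @rdname engine-ops
#' @export
op_add <- function(a, b) {
  av <- pn_val(a); bv <- pn_val(b)
  pn_make(av + bv, list(a, b), function(g) list(g, g))
}

#' @rdname engine-ops
#' @export
op_sub <- function(a, b) {
  av <- pn_val(a); bv <- pn_val(b)
  pn_make(av - bv, list(a, b), function(g) list(g, -g))
}

#' @rdname engine-ops
#' @export
op_mul <- function(a, b) {
  av <- pn_val(a); bv <- pn_val(b)
  pn_make(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# multiply by a plain scalar constant
#' @rdname engine-ops
#' @export
op_scale <- function(a, s) {
  av <- pn_val(a)
  pn_make(av * s, list(a), function(g) list(g * s))
}

op_neg <- function(a) op_scale(a, -1)

#' @rdname engine-ops
#' @export
op_relu <- function(a) {
  av <- pn_val(a)
  y <- av * (av > 0)
  pn_make(y, list(a), function(g) list(g * (av > 0)))
}

#' @rdname engine-ops
#' @export
op_sigmoid <- function(a) {
  av <- pn_val(a)
  y <- 1 / (1 + exp(-av))
  pn_make(y, list(a), function(g) list(g * y * (1 - y)))
}

#' @rdname engine-ops
#' @export
op_sum <- function(a) {
  av <- pn_val(a)
  d <- dim(av)
  pn_make(sum(av), list(a), function(g) list(array(g, if (is.null(d)) length(av) else d)))
}

#' @rdname engine-ops
#' @export
op_mean <- function(a) {
  av <- pn_val(a)
  n <- length(av)
  d <- dim(av)
  pn_make(mean(av), list(a),
          function(g) list(array(g / n, if (is.null(d)) n else d)))
}

# sum a list of same-shaped tensors
op_addn <- function(xs) {
  v <- Reduce(`+`, lapply(xs, pn_val))
  pn_make(v, xs, function(g) rep(list(g), length(xs)))
}

# --- shape ops ---------------------------------------------------------------

# channel concatenation of (N, C, D, H, W) volumes
op_concat_ch <- function(a, b) {
  av <- pn_val(a); bv <- pn_val(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 5L, all(da[-2] == db[-2]))
  y <- array(0, c(da[1], da[2] + db[2], da[3], da[4], da[5]))
  ia <- seq_len(da[2])
  ib <- da[2] + seq_len(db[2])
  y[, ia, , , ] <- av
  y[, ib, , , ] <- bv
  pn_make(y, list(a, b), function(g) {
    list(array(g[, ia, , , , drop = FALSE], da),
         array(g[, ib, , , , drop = FALSE], db))
  })
}

# select a channel range (contiguous) of a (N, C, D, H, W) volume
op_slice_ch <- function(a, idx) {
  av <- pn_val(a)
  d <- dim(av)
  y <- array(av[, idx, , , , drop = FALSE], c(d[1], length(idx), d[3], d[4], d[5]))
  pn_make(y, list(a), function(g) {
    gx <- array(0, d)
    gx[, idx, , , ] <- g
    list(gx)
  })
}

# sum a (N, C, D, H, W) array over channels -> (N, 1, D, H, W)
ch_sum <- function(g, d) {
  dim(g) <- c(d[1], d[2], prod(d[3:5]))
  out <- g[, 1L, ]
  if (d[2] > 1L) for (c0 in 2:d[2]) out <- out + g[, c0, ]
  array(out, c(d[1], 1L, d[3], d[4], d[5]))
}

# broadcast a single-channel volume to C channels
op_broadcast_ch <- function(a, C) {
  av <- pn_val(a)
  d <- dim(av)
  stopifnot(d[2] == 1L)
  y <- array(av[, rep(1L, C), , , , drop = FALSE], c(d[1], C, d[3], d[4], d[5]))
  pn_make(y, list(a), function(g) {
    list(ch_sum(g, dim(y)))
  })
}

# multiply a (N, C, D, H, W) volume by a single-channel (N, 1, D, H, W) map
op_mul_bcast <- function(a, m) {
  av <- pn_val(a); mv <- pn_val(m)
  da <- dim(av); dm <- dim(mv)
  stopifnot(dm[2] == 1L, all(da[-2] == dm[-2]))
  C <- da[2]
  mb <- array(mv[, rep(1L, C), , , , drop = FALSE], da)
  pn_make(av * mb, list(a, m), function(g) {
    list(g * mb, ch_sum(g * av, da))
  })
}

op_aperm <- function(a, perm) {
  av <- pn_val(a)
  inv <- order(perm)
  pn_make(aperm(av, perm), list(a), function(g) list(aperm(g, inv)))
}

op_reshape <- function(a, newdim) {
  av <- pn_val(a)
  d <- dim(av)
  y <- av
  dim(y) <- newdim
  pn_make(y, list(a), function(g) { dim(g) <- d; list(g) })
}

# --- pooling / reductions over space ----------------------------------------

# 2x average pooling over the three spatial axes of (N, C, D, H, W)
op_avgpool2 <- function(a) {
  av <- pn_val(a)
  d <- dim(av)
  stopifnot(all(d[3:5] %% 2L == 0L))
  od <- c(d[1], d[2], d[3] %/% 2L, d[4] %/% 2L, d[5] %/% 2L)
  x6 <- av
  dim(x6) <- c(d[1] * d[2], 2L, od[3], 2L, od[4], 2L, od[5])
  y <- 0
  for (i in 1:2) for (j in 1:2) for (l in 1:2)
    y <- y + x6[, i, , j, , l, ]
  y <- y / 8
  dim(y) <- od
  pn_make(y, list(a), function(g) {
    gb <- array(g / 8, c(d[1] * d[2], 1L, od[3], 1L, od[4], 1L, od[5]))
    gx <- gb[, c(1L, 1L), , c(1L, 1L), , c(1L, 1L), , drop = FALSE]
    dim(gx) <- d
    list(gx)
  })
}

# global average pool -> (N, C)
op_gap <- function(a) {
  av <- pn_val(a)
  d <- dim(av)
  nv <- prod(d[3:5])
  y2 <- av
  dim(y2) <- c(d[1] * d[2], nv)
  y <- rowMeans(y2)
  dim(y) <- d[1:2]
  pn_make(y, list(a), function(g) {
    gx <- array(rep(as.vector(g), times = nv), d)
    list(gx / nv)
  })
}

# dense layer on (N, F) matrices: y = x %*% t(W) + b, W is (out, in)
op_dense <- function(x, W, b = NULL) {
  xv <- pn_val(x); Wv <- pn_val(W)
  y <- xv %*% t(Wv)
  if (!is.null(b)) y <- sweep(y, 2, pn_val(b), `+`)
  pn_make(y, list(x, W, b), function(g) {
    list(g %*% Wv, t(g) %*% xv, if (is.null(b)) NULL else colSums(g))
  })
}

# scale channels of (N, C, D, H, W) by per-sample per-channel weights (N, C)
op_scale_channels <- function(a, s) {
  av <- pn_val(a); sv <- pn_val(s)
  d <- dim(av)
  sb <- array(rep(as.vector(sv), times = prod(d[3:5])), d)
  pn_make(av * sb, list(a, s), function(g) {
    gs <- apply(g * av, c(1, 2), sum)
    dim(gs) <- d[1:2]
    list(g * sb, gs)
  })
}

# --- normalization -----------------------------------------------------------

#' Group normalization (single group)
#'
#' Normalizes each sample over all channels and voxels, then applies a
#' per-channel affine transform.
#' @param a Volume `(N, C, D, H, W)` (array or tensor).
#' @param gamma,beta Per-channel affine parameters (length `C`).
#' @param eps Variance floor.
#' @export
op_groupnorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- pn_val(a)
  gv <- pn_val(gamma); bv <- pn_val(beta)
  d <- dim(av)
  N <- d[1]; C <- d[2]; m <- prod(d[2:5])
  x2 <- av
  dim(x2) <- c(N, m)
  mu <- rowMeans(x2)
  xc <- x2 - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xh <- xc * istd
  dim(xh) <- d
  gb <- array(rep(rep(gv, each = N), times = prod(d[3:5])), d)
  bb <- array(rep(rep(bv, each = N), times = prod(d[3:5])), d)
  y <- xh * gb + bb
  pn_make(y, list(a, gamma, beta), function(g) {
    gxh_c <- g * xh
    dim(gxh_c) <- c(N, C, prod(d[3:5]))
    dgamma <- vapply(seq_len(C), function(c0) sum(gxh_c[, c0, ]), numeric(1))
    gc <- g
    dim(gc) <- c(N, C, prod(d[3:5]))
    dbeta <- vapply(seq_len(C), function(c0) sum(gc[, c0, ]), numeric(1))
    gxh <- g * gb
    dim(gxh) <- c(N, m)
    xh2 <- xh
    dim(xh2) <- c(N, m)
    # layer-norm style backward per sample
    t1 <- rowMeans(gxh)
    t2 <- rowMeans(gxh * xh2)
    gx <- istd * (gxh - t1 - xh2 * t2)
    dim(gx) <- d
    list(gx, dgamma, dbeta)
  })
}

#' Softmax over the channel dimension
#' @param a Volume `(N, C, D, H, W)` (array or tensor).
#' @export
op_softmax_ch <- function(a) {
  av <- pn_val(a)
  d <- dim(av)
  a3 <- av
  dim(a3) <- c(d[1], d[2], prod(d[3:5]))
  mx <- a3[, 1L, ]
  if (d[2] > 1L) for (c0 in 2:d[2]) mx <- pmax(mx, a3[, c0, ])
  ex <- a3
  s <- 0
  for (c0 in seq_len(d[2])) {
    ex[, c0, ] <- exp(a3[, c0, ] - mx)
    s <- s + ex[, c0, ]
  }
  y <- ex
  for (c0 in seq_len(d[2])) y[, c0, ] <- ex[, c0, ] / s
  dim(y) <- d
  pn_make(y, list(a), function(g) {
    g3 <- g
    dim(g3) <- c(d[1], d[2], prod(d[3:5]))
    y3 <- y
    dim(y3) <- c(d[1], d[2], prod(d[3:5]))
    dot <- 0
    for (c0 in seq_len(d[2])) dot <- dot + g3[, c0, ] * y3[, c0, ]
    gx <- g3
    for (c0 in seq_len(d[2])) gx[, c0, ] <- y3[, c0, ] * (g3[, c0, ] - dot)
    dim(gx) <- d
    list(gx)
  })
}

# --- indexing / scalar helpers ----------------------------------------------

op_slice_rows <- function(W, idx) {
  Wv <- pn_val(W)
  y <- Wv[idx, , drop = FALSE]
  pn_make(y, list(W), function(g) {
    gx <- matrix(0, nrow(Wv), ncol(Wv))
    gx[idx, ] <- g
    list(gx)
  })
}

op_slice_cols <- function(W, idx) {
  Wv <- pn_val(W)
  y <- Wv[, idx, drop = FALSE]
  pn_make(y, list(W), function(g) {
    gx <- matrix(0, nrow(Wv), ncol(Wv))
    gx[, idx] <- g
    list(gx)
  })
}

op_index <- function(a, i) {
  av <- pn_val(a)
  pn_make(av[i], list(a), function(g) {
    gx <- av * 0
    gx[i] <- g
    list(gx)
  })
}

op_log <- function(a) {
  av <- pn_val(a)
  pn_make(log(av), list(a), function(g) list(g / av))
}

op_clamp <- function(a, lo, hi) {
  av <- pn_val(a)
  y <- pmin(pmax(av, lo), hi)
  pn_make(y, list(a), function(g) list(g * (av >= lo & av <= hi)))
}

op_div <- function(a, b) {
  av <- pn_val(a); bv <- pn_val(b)
  pn_make(av / bv, list(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

# gather the probability of the target class per voxel:
# pred (N, C, D, H, W), target (N, D, H, W) in 0..C-1 -> (N, D, H, W)
op_gather_class <- function(pred, target) {
  pv <- pn_val(pred)
  d <- dim(pv)
  tv <- as.integer(target)
  n_sp <- d[1]
  # linear indices: (n, c = target+1, spatial...)
  sp <- prod(d[3:5])
  nidx <- rep(seq_len(d[1]), times = sp)
  spidx <- rep(seq_len(sp) - 1L, each = d[1])
  lin <- nidx + d[1] * (tv + d[1] * 0L) + d[1] * d[2] * spidx
  # careful: index of (n, c, s) = n + N*(c-1) + N*C*(s-1); c-1 = tv
  lin <- nidx + d[1] * tv + d[1] * d[2] * spidx
  y <- pv[lin]
  dim(y) <- c(d[1], d[3], d[4], d[5])
  pn_make(y, list(pred), function(g) {
    gx <- array(0, d)
    gx[lin] <- g
    list(gx)
  })
}

# --- parameter tree helpers --------------------------------------------------

#' Wrap every numeric leaf of a parameter tree as an autodiff tensor
#' @param params Nested list of numeric arrays.
#' @return Nested list of the same shape with `pn_tensor` leaves.
#' @export
pn_wrap_params <- function(params) {
  if (is.numeric(params)) return(pn_tensor(params))
  if (is.list(params)) return(lapply(params, pn_wrap_params))
  params
}

#' Extract plain values from a wrapped parameter tree
#' @param params Nested list with `pn_tensor` leaves.
#' @export
pn_unwrap_params <- function(params) {
  if (is_pn(params)) return(params$value)
  if (is.list(params)) return(lapply(params, pn_unwrap_params))
  params
}

# flat list of all pn_tensor leaves (for the optimizer)
pn_param_leaves <- function(params, path = "") {
  if (is_pn(params)) {
    out <- list(params)
    names(out) <- path
    return(out)
  }
  if (is.list(params)) {
    nms <- names(params)
    if (is.null(nms)) nms <- as.character(seq_along(params))
    out <- list()
    for (i in seq_along(params)) {
      out <- c(out, pn_param_leaves(params[[i]], paste0(path, "/", nms[i])))
    }
    return(out)
  }
  list()
}
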