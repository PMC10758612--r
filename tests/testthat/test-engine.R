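# Reverse-mode engine: gradients of composite graphs against central
# finite differences.

test_that("gradients of a conv/norm/pool graph match finite differences", {
  set.seed(71)
  x0 <- array(rnorm(1 * 2 * 4 * 4 * 4), c(1, 2, 4, 4, 4))
  w0 <- array(rnorm(3 * 2 * 27, sd = 0.3), c(3, 2, 3, 3, 3))
  b0 <- rnorm(3)
  g0 <- runif(3, 0.5, 1.5); be0 <- rnorm(3)
  wts <- array(rnorm(3 * 8), c(1, 3, 2, 2, 2))
  fval <- function(xv, wv, bv, gv, bev) {
    y <- op_conv3d(xv, wv, bv, stride = 1L, pad = 1L)
    y <- op_relu(op_groupnorm(y, gv, bev))
    y <- penet:::op_avgpool2(y)
    sum(pn_val(y) * wts)
  }
  x <- pn_tensor(x0); w <- pn_tensor(w0); b <- pn_tensor(b0)
  ga <- pn_tensor(g0); be <- pn_tensor(be0)
  y <- op_conv3d(x, w, b, stride = 1L, pad = 1L)
  y <- op_relu(op_groupnorm(y, ga, be))
  y <- penet:::op_avgpool2(y)
  pn_backward(op_sum(op_mul(y, wts)))
  expect_equal(x$grad, fd_grad(function(v) fval(v, w0, b0, g0, be0), x0),
               tolerance = 1e-5)
  expect_equal(w$grad, fd_grad(function(v) fval(x0, v, b0, g0, be0), w0),
               tolerance = 1e-5)
  expect_equal(b$grad, fd_grad(function(v) fval(x0, w0, v, g0, be0), b0),
               tolerance = 1e-5)
  expect_equal(ga$grad, fd_grad(function(v) fval(x0, w0, b0, v, be0), g0),
               tolerance = 1e-5)
  expect_equal(be$grad, fd_grad(function(v) fval(x0, w0, b0, g0, v), be0),
               tolerance = 1e-5)
})

test_that("gradients of the fusion-style ops match finite differences", {
  set.seed(72)
  x0 <- array(rnorm(2 * 2 * 2 * 2 * 2), c(2, 2, 2, 2, 2))
  m0 <- array(rnorm(2 * 1 * 2 * 2 * 2), c(2, 1, 2, 2, 2))
  wt0 <- array(rnorm(2 * 2 * 8), c(2, 2, 2, 2, 2))
  f <- function(xv, mv) {
    cat2 <- penet:::op_concat_ch(penet:::op_mul_bcast(xv, penet:::op_sigmoid(mv)),
                                 penet:::op_broadcast_ch(mv, 2L))
    s <- penet:::op_gap(cat2)
    sc <- penet:::op_scale_channels(cat2, penet:::op_sigmoid(s))
    up <- op_convt3d(penet:::op_slice_ch(sc, 1:2), wt0, NULL)
    pn_val(penet:::op_mean(up))
  }
  x <- pn_tensor(x0); m <- pn_tensor(m0)
  cat2 <- penet:::op_concat_ch(penet:::op_mul_bcast(x, penet:::op_sigmoid(m)),
                               penet:::op_broadcast_ch(m, 2L))
  s <- penet:::op_gap(cat2)
  sc <- penet:::op_scale_channels(cat2, penet:::op_sigmoid(s))
  up <- op_convt3d(penet:::op_slice_ch(sc, 1:2), wt0, NULL)
  pn_backward(penet:::op_mean(up))
  expect_equal(x$grad, fd_grad(function(v) f(v, m0), x0), tolerance = 1e-5)
  expect_equal(m$grad, fd_grad(function(v) f(x0, v), m0), tolerance = 1e-5)
})

test_that("softmax over channels normalizes and backpropagates correctly", {
  set.seed(73)
  x0 <- array(rnorm(2 * 3 * 2 * 2 * 2), c(2, 3, 2, 2, 2))
  wts <- array(rnorm(length(x0)), dim(x0))
  x <- pn_tensor(x0)
  y <- penet:::op_softmax_ch(x)
  sums <- pn_val(y)[, 1, , , ] + pn_val(y)[, 2, , , ] + pn_val(y)[, 3, , , ]
  expect_lt(max(abs(sums - 1)), 1e-12)
  pn_backward(op_sum(op_mul(y, wts)))
  f <- function(v) sum(pn_val(penet:::op_softmax_ch(v)) * wts)
  expect_equal(x$grad, fd_grad(f, x0), tolerance = 1e-5)
})

test_that("gradients accumulate across reused leaves", {
  a <- pn_tensor(2)
  y <- op_add(op_mul(a, a), op_scale(a, 3))  # a^2 + 3a
  pn_backward(y)
  expect_equal(a$grad, 2 * 2 + 3)
})

test_that("dense and strided-conv gradients match finite differences", {
  set.seed(74)
  x0 <- array(rnorm(1 * 2 * 4 * 4 * 4), c(1, 2, 4, 4, 4))
  w0 <- array(rnorm(3 * 2 * 8, sd = 0.4), c(3, 2, 2, 2, 2))
  f <- function(xv, wv) {
    y <- op_conv3d(xv, wv, NULL, stride = 2L, pad = 0L)
    sum(pn_val(y)^2) / 2
  }
  x <- pn_tensor(x0); w <- pn_tensor(w0)
  y <- op_conv3d(x, w, NULL, stride = 2L, pad = 0L)
  pn_backward(op_scale(op_sum(op_mul(y, y)), 0.5))
  expect_equal(x$grad, fd_grad(function(v) f(v, w0), x0), tolerance = 1e-5)
  expect_equal(w$grad, fd_grad(function(v) f(x0, v), w0), tolerance = 1e-5)
})
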