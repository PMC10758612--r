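# Triple-axial gated transformer: embedding, single-axis attention, and
# the full layer.

test_that("q/k/v embedding is a pure per-voxel linear map", {
  set.seed(11)
  x <- array(rnorm(2 * 4 * 3 * 4 * 5), c(2, 4, 3, 4, 5))
  p <- qkv_projections(4, 2, 2, init = "identity")
  qkv <- embed_qkv(x, p)
  expect_equal(qkv$q, x)
  expect_equal(qkv$k, x)
  expect_equal(qkv$v, x)

  p2 <- qkv_projections(4, 2, 3)
  q1 <- embed_qkv(x, p2)$q
  q2 <- embed_qkv(2.5 * x, p2)$q
  expect_equal(q2, 2.5 * q1, tolerance = 1e-12)
  expect_equal(dim(q1), c(2L, 6L, 3L, 4L, 5L))

  expect_error(embed_qkv(x, qkv_projections(5, 2, 3)), "Wq")
})

test_that("single-axis attention matches the exhaustive double-loop oracle", {
  set.seed(12)
  heads <- 2L; dm <- 3L
  d <- c(2, heads * dm, 4, 5, 6)
  q <- array(rnorm(prod(d)), d); k <- array(rnorm(prod(d)), d)
  v <- array(rnorm(prod(d)), d)
  for (axis in c("depth", "height", "width")) {
    L <- switch(axis, depth = d[3], height = d[4], width = d[5])
    tb <- axial_tables(L, dm)
    tb$gates <- c(0.7, -0.4, 1.1, 0.6)
    y <- gated_axial_attention(list(q = q, k = k, v = v), axis, tb, heads, dm)
    expect_equal(dim(y), as.integer(d))
    yo <- attention_oracle(q, k, v, axis, tb, heads, dm)
    expect_lt(max(abs(y - yo)), 1e-6)
  }
})

test_that("gate degeneracies: zero gates annihilate, Gv1 alone is plain attention", {
  set.seed(13)
  d <- c(1, 4, 3, 4, 5)
  q <- array(rnorm(prod(d)), d); k <- array(rnorm(prod(d)), d)
  v <- array(rnorm(prod(d)), d)
  tb <- axial_tables(4L, 4L)
  tb$gates <- c(0, 0, 0, 0)
  y0 <- gated_axial_attention(list(q = q, k = k, v = v), "height", tb, 1L, 4L)
  expect_equal(max(abs(y0)), 0)

  tb$gates <- c(0, 0, 1, 0)
  y1 <- gated_axial_attention(list(q = q, k = k, v = v), "height", tb, 1L, 4L)
  # plain non-positional axial attention oracle
  yo <- array(0, d)
  for (z in 1:3) for (x in 1:5) for (i in 1:4) {
    s <- sapply(1:4, function(j) sum(q[1, , z, i, x] * k[1, , z, j, x]))
    a <- exp(s - max(s)); a <- a / sum(a)
    yo[1, , z, i, x] <- sapply(1:4, function(dd) sum(a * v[1, dd, z, , x]))
  }
  expect_lt(max(abs(y1 - yo)), 1e-6)
})

test_that("softmax weights along the attended axis sum to one", {
  # with Gv2 = 0 and v identically 1, the output equals the row sums of
  # the attention weights
  set.seed(14)
  d <- c(2, 2, 5, 3, 4)
  q <- array(rnorm(prod(d)), d); k <- array(rnorm(prod(d)), d)
  v <- array(1, d)
  tb <- axial_tables(5L, 2L)
  tb$gates <- c(0.9, 0.3, 1, 0)
  y <- gated_axial_attention(list(q = q, k = k, v = v), "depth", tb, 1L, 2L)
  expect_lt(max(abs(y - 1)), 1e-6)
})

test_that("attention along one axis is equivariant to permutations of another", {
  set.seed(15)
  d <- c(1, 3, 4, 5, 3)
  q <- array(rnorm(prod(d)), d); k <- array(rnorm(prod(d)), d)
  v <- array(rnorm(prod(d)), d)
  tb <- axial_tables(4L, 3L)
  tb$gates <- c(0.5, 0.5, 1, 0.5)
  y <- gated_axial_attention(list(q = q, k = k, v = v), "depth", tb, 1L, 3L)
  perm <- c(3, 1, 5, 2, 4)  # permute the height axis
  yp <- gated_axial_attention(list(q = q[, , , perm, , drop = FALSE],
                                   k = k[, , , perm, , drop = FALSE],
                                   v = v[, , , perm, , drop = FALSE]),
                              "depth", tb, 1L, 3L)
  expect_equal(yp, y[, , , perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("axis of extent one reduces to the value term", {
  set.seed(16)
  d <- c(2, 3, 1, 4, 5)
  q <- array(rnorm(prod(d)), d); k <- array(rnorm(prod(d)), d)
  v <- array(rnorm(prod(d)), d)
  tb <- axial_tables(1L, 3L)
  tb$gates <- c(0.3, -0.7, 1.4, 0.8)
  y <- gated_axial_attention(list(q = q, k = k, v = v), "depth", tb, 1L, 3L)
  expected <- 1.4 * v
  for (dd in 1:3) expected[, dd, 1, , ] <- expected[, dd, 1, , ] + 0.8 * tb$rv[1, 1, dd]
  expect_equal(y, expected, tolerance = 1e-10)
})

test_that("mismatched positional tables raise a shape error", {
  d <- c(1, 2, 4, 4, 4)
  q <- array(0, d)
  tb <- axial_tables(5L, 2L)
  expect_error(gated_axial_attention(list(q = q, k = q, v = q), "depth", tb, 1L, 2L),
               "does not match axis extent")
})

test_that("gate gradients from autodiff match finite differences", {
  set.seed(17)
  d <- c(1, 2, 3, 4, 2)
  q <- array(rnorm(prod(d)), d); k <- array(rnorm(prod(d)), d)
  v <- array(rnorm(prod(d)), d)
  tb <- axial_tables(4L, 2L)
  wts <- array(rnorm(prod(d)), d)
  f <- function(g) {
    tb2 <- tb; tb2$gates <- g
    sum(gated_axial_attention(list(q = q, k = k, v = v), "height", tb2, 1L, 2L) * wts)
  }
  gates0 <- c(0.6, -0.2, 0.8, 0.4)
  tbw <- tb
  tbw$gates <- pn_tensor(gates0)
  loss <- op_sum(op_mul(gated_axial_attention(list(q = q, k = k, v = v),
                                              "height", tbw, 1L, 2L), wts))
  pn_backward(loss)
  gfd <- fd_grad(f, gates0, eps = 1e-5)
  expect_lt(max(abs(gfd - tbw$gates$grad) / pmax(abs(gfd), 1e-6)), 1e-3)
})

test_that("TAGT layer with all gates zero reduces to conv-norm of half the input", {
  set.seed(18)
  cfg <- tagt_config(heads = 2L, head_dim = 3L)
  x <- array(rnorm(1 * 1 * 4 * 4 * 4), c(1, 1, 4, 4, 4))
  p <- tagt_params(1L, c(4, 4, 4), cfg, gate_init = 0)
  y <- tagt_layer(x, cfg, p)
  z <- 0.5 * sum(p$out$w) * x + p$out$b
  expected <- gn_oracle(z, p$norm_out$gamma, p$norm_out$beta) + x
  expect_equal(y, expected, tolerance = 1e-10)
})

test_that("TAGT layer output is a single-channel map of the input size", {
  set.seed(19)
  cfg <- tagt_config(heads = 2L, head_dim = 2L)
  x <- array(rnorm(2 * 1 * 6 * 4 * 8), c(2, 1, 6, 4, 8))
  p <- tagt_params(1L, c(6, 4, 8), cfg)
  y1 <- tagt_layer(x, cfg, p)
  expect_equal(dim(y1), c(2L, 1L, 6L, 4L, 8L))
  y2 <- tagt_layer(x, cfg, p)
  expect_identical(y1, y2)  # deterministic forward
  expect_error(tagt_layer(x[, , 1:4, , , drop = FALSE], cfg, p),
               "does not match extent")
})

test_that("the raw weight-map flag bypasses the sigmoid squash", {
  set.seed(20)
  x <- array(rnorm(1 * 1 * 4 * 4 * 4), c(1, 1, 4, 4, 4))
  cfg_raw <- tagt_config(heads = 1L, head_dim = 2L, weight_map = "raw")
  p <- tagt_params(1L, c(4, 4, 4), cfg_raw, gate_init = 0)
  # raw map of an all-gates-zero layer is 0, so output = gn(b) + x
  y <- tagt_layer(x, cfg_raw, p)
  z <- array(p$out$b, dim(x)) * 1
  expected <- gn_oracle(z * 0 + p$out$b, p$norm_out$gamma, p$norm_out$beta) + x
  expect_equal(y, expected, tolerance = 1e-10)
})
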