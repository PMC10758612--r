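# FFB (skip/decoder fusion) and FFM (parallel-branch fusion).

test_that("FFB with zero convolution weights gates the concatenation at 0.5", {
  set.seed(31)
  skip <- array(rnorm(1 * 2 * 4 * 4 * 4), c(1, 2, 4, 4, 4))
  dec <- array(rnorm(1 * 3 * 4 * 4 * 4), c(1, 3, 4, 4, 4))
  p <- ffb_params(5L, 2L)
  for (blk in c("block1", "block2")) { p[[blk]]$w[] <- 0; p[[blk]]$b[] <- 0 }
  p$block3$w[] <- 0; p$block3$b[] <- 0
  out <- ffb(skip, dec, p)
  cat0 <- array(0, c(1, 5, 4, 4, 4))
  cat0[, 1:2, , , ] <- skip; cat0[, 3:5, , , ] <- dec
  expect_equal(out, 0.5 * cat0)
})

test_that("FFB concatenation arithmetic and shape preservation", {
  set.seed(32)
  skip <- array(rnorm(2 * 3 * 4 * 6 * 8), c(2, 3, 4, 6, 8))
  dec <- array(rnorm(2 * 5 * 4 * 6 * 8), c(2, 5, 4, 6, 8))
  p <- ffb_params(8L, 4L)
  out <- ffb(skip, dec, p)
  expect_equal(dim(out), c(2L, 8L, 4L, 6L, 8L))
  outp <- ffb(skip, dec, p, project = TRUE)
  expect_equal(dim(outp), c(2L, 4L, 4L, 6L, 8L))
  expect_error(ffb(skip, dec[, , 1:2, , , drop = FALSE], p), "extents")
})

test_that("FFB on a single voxel matches a hand-evaluated conv chain", {
  set.seed(33)
  skip <- array(rnorm(2), c(1, 2, 1, 1, 1))
  dec <- array(rnorm(2), c(1, 2, 1, 1, 1))
  p <- ffb_params(4L, 2L)
  out <- ffb(skip, dec, p)
  f <- c(skip[1, , 1, 1, 1], dec[1, , 1, 1, 1])
  gn1 <- function(v, gamma, beta) {
    (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5) * gamma + beta
  }
  w1 <- pmax(gn1(p$block1$w[, , 2, 2, 2] %*% f + p$block1$b, p$block1$gamma, p$block1$beta), 0)
  w2 <- pmax(gn1(p$block2$w[, , 2, 2, 2] %*% w1 + p$block2$b, p$block2$gamma, p$block2$beta), 0)
  w3 <- pmax(gn1(p$block3$w %*% w2 + p$block3$b, p$block3$gamma, p$block3$beta), 0)
  a <- 1 / (1 + exp(-w3))
  expect_equal(as.vector(out), as.vector(f * as.vector(a)), tolerance = 1e-10)
})

test_that("FFB attention weights stay in (0,1) and pass gradient to both inputs", {
  set.seed(34)
  skip <- pn_tensor(array(rnorm(1 * 2 * 4 * 4 * 4), c(1, 2, 4, 4, 4)))
  dec <- pn_tensor(array(rnorm(1 * 2 * 4 * 4 * 4), c(1, 2, 4, 4, 4)))
  p <- ffb_params(4L, 2L)
  out <- ffb(skip, dec, p, project = TRUE)
  pn_backward(op_sum(out))
  expect_gt(sqrt(sum(skip$grad^2)), 0)
  expect_gt(sqrt(sum(dec$grad^2)), 0)
})

test_that("FFM degenerate channel gates select one branch", {
  set.seed(35)
  conv_feat <- array(rnorm(1 * 3 * 4 * 4 * 4), c(1, 3, 4, 4, 4))
  tmap <- array(rnorm(1 * 1 * 4 * 4 * 4), c(1, 1, 4, 4, 4))
  p <- ffm_params(3L)
  # drive the logistic to 1 for conv channels, 0 for the map channels
  p$fc1$w[] <- 0; p$fc1$b[] <- 0
  p$fc2$w[] <- 0
  p$fc2$b <- c(rep(40, 3), rep(-40, 3))
  expect_equal(ffm(conv_feat, tmap, p), conv_feat, tolerance = 1e-12)
  # equal half-gates give the elementwise mean of the two branches
  p$fc2$b <- rep(0, 6)
  out <- ffm(conv_feat, tmap, p)
  tb <- array(tmap[, rep(1, 3), , , ], dim(conv_feat))
  expect_equal(out, 0.5 * conv_feat + 0.5 * tb, tolerance = 1e-12)
})

test_that("FFM matches a hand-coded pool/bottleneck/logistic/scale oracle", {
  set.seed(36)
  conv_feat <- array(rnorm(2 * 2 * 3 * 3 * 3), c(2, 2, 3, 3, 3))
  tmap <- array(rnorm(2 * 1 * 3 * 3 * 3), c(2, 1, 3, 3, 3))
  p <- ffm_params(2L)
  out <- ffm(conv_feat, tmap, p)
  for (n in 1:2) {
    cat4 <- array(0, c(4, 27))
    cat4[1:2, ] <- matrix(conv_feat[n, , , , ], 2, 27)
    cat4[3:4, ] <- matrix(tmap[n, rep(1, 2), , , ], 2, 27)
    z <- rowMeans(cat4)
    h <- pmax(p$fc1$w %*% z + p$fc1$b, 0)
    sgate <- 1 / (1 + exp(-(p$fc2$w %*% h + p$fc2$b)))
    scaled <- cat4 * as.vector(sgate)
    expected <- scaled[1:2, ] + scaled[3:4, ]
    expect_equal(matrix(out[n, , , , ], 2, 27), expected, tolerance = 1e-10)
  }
  expect_error(ffm(conv_feat, conv_feat, p), "single-channel")
})
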