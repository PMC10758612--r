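# Full-network assembly: shapes, probability normalization, gradients,
# parameter accounting.

tiny_cfg <- function(crop) net_config(levels = 2L, base_channels = 2L,
                                      heads = 1L, head_dim = 2L, crop = crop)

test_that("configuration validation rejects indivisible crops", {
  expect_error(net_config(levels = 4L, crop = 100L), "divisible")
  expect_silent(net_config(levels = 4L, crop = 128L))
})

test_that("end-to-end shape contract holds across crop sizes", {
  for (crop in c(16L, 32L)) {
    set.seed(40 + crop)
    m <- penet_build(tiny_cfg(crop))
    x <- array(rnorm(crop^3), c(1, 1, crop, crop, crop))
    pr <- penet_forward(m, x)
    expect_equal(dim(pr), c(1L, 2L, crop, crop, crop))
    sums <- pr[1, 1, , , ] + pr[1, 2, , , ]
    expect_lt(max(abs(sums - 1)), 1e-6)
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("indivisible inputs fail before any compute", {
  set.seed(43)
  m <- penet_build(tiny_cfg(16L))
  x <- array(0, c(1, 1, 15, 16, 16))
  expect_error(penet_forward(m, x), "divisible")
})

test_that("repeated forward passes are bit-identical", {
  set.seed(44)
  m <- penet_build(tiny_cfg(16L))
  x <- array(rnorm(16^3), c(1, 1, 16, 16, 16))
  expect_identical(penet_forward(m, x), penet_forward(m, x))
})

test_that("every learnable tensor receives gradient after one backward pass", {
  set.seed(45)
  m <- penet_build(tiny_cfg(16L))
  m$params <- pn_wrap_params(m$params)
  x <- array(rnorm(16^3), c(1, 1, 16, 16, 16))
  tgt <- array(as.integer(runif(16^3) < 0.05), c(1, 16, 16, 16))
  loss <- composite_loss(penet_forward(m, x), tgt)
  pn_backward(loss)
  leaves <- penet:::pn_param_leaves(m$params)
  norms <- vapply(leaves, function(l)
    if (is.null(l$grad)) 0 else sqrt(sum(l$grad^2)), numeric(1))
  expect_true(all(norms > 0))
  gate_leaves <- grep("gates", names(leaves))
  expect_true(length(gate_leaves) == 3L * 2L)  # 3 axes x 2 levels
  expect_true(all(norms[gate_leaves] > 0))
})

test_that("parameter count of a one-level toy matches the hand-counted formula", {
  set.seed(46)
  w <- 2L; heads <- 1L; dm <- 2L; L <- 8L
  cfg <- net_config(levels = 1L, base_channels = w, heads = heads,
                    head_dim = dm, crop = L)
  m <- penet_build(cfg)
  Z <- heads * dm
  dc <- function(ci, co) (co * ci * 27 + co + 2 * co) + (co * co * 27 + co + 2 * co)
  tagt <- 2 + 3 * Z * 1 + 3 * (3 * L * L * dm + 4) + (Z + 1) + 2
  ffm <- (w * 2 * w + w) + (2 * w * w + 2 * w)
  expected <- dc(1L, w) + tagt + ffm + dc(w, 2L * w) + (2L * w + 2L)
  expect_identical(m$n_params, as.integer(expected))
  expect_identical(count_params(m), m$n_params)
})

test_that("axial problem counting enumerates (batch, head, off-axis) tuples", {
  cfg <- net_config()
  r <- count_axial_problems(cfg, c(128, 128, 128), "depth")
  expect_identical(r$problems, 131072L)
  expect_identical(r$folded_leading, 1024L)
  r1 <- count_axial_problems(list(heads = 1L), c(1, 1, 1), "width")
  expect_identical(r1$problems, 1L)
  r2 <- count_axial_problems(list(heads = 3L), c(4, 6, 8), "height", batch = 2L)
  expect_identical(r2$problems, 192L)  # 2 * 3 * (4 * 8)
  expect_error(count_axial_problems(cfg, c(4, 4, 4), "diag"))
})

test_that("checkpoints round-trip bit-exactly through disk", {
  set.seed(47)
  m <- penet_build(tiny_cfg(16L))
  x <- array(rnorm(16^3), c(1, 1, 16, 16, 16))
  pr1 <- penet_forward(m, x)
  path <- tempfile(fileext = ".rds")
  penet_save(m, path)
  m2 <- penet_load(path)
  expect_identical(penet_forward(m2, x), pr1)
  unlink(path)
})

test_that("translation of the input shifts interior CNN-branch responses", {
  # equivariance of the stacked convolutions themselves (normalization
  # statistics are volume-wide, so the property is stated on raw convs)
  set.seed(48)
  w1 <- array(rnorm(2 * 1 * 27), c(2, 1, 3, 3, 3))
  w2 <- array(rnorm(2 * 2 * 27), c(2, 2, 3, 3, 3))
  chain <- function(v) op_conv3d(penet:::op_relu(op_conv3d(v, w1, pad = 1L)), w2, pad = 1L)
  x <- array(rnorm(12^3), c(1, 1, 12, 12, 12))
  xs <- array(0, dim(x))
  xs[, , 2:12, , ] <- x[, , 1:11, , ]  # shift one voxel along depth
  y <- chain(x)
  ys <- chain(xs)
  expect_equal(ys[, , 5:10, 4:9, 4:9], y[, , 4:9, 4:9, 4:9], tolerance = 1e-10)
})

test_that("the layer summary reproduces the printed layer-1 dimensions", {
  cfg <- net_config()
  tb <- penet_summary(cfg)
  r <- tb[tb$layer == "Double Conv1", ]
  expect_equal(r$input, "1, 1, 128, 128, 128")
  expect_equal(r$output, "1, 8, 128, 128, 128")
  expect_equal(r$supplement, "K = 3, S = 1")
  expect_true(any(grepl("131072, 1, 1, 16", tb$supplement)))
  expect_true(any(grepl("1024, 128, 128", tb$supplement)))
})
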