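# Composite loss and evaluation metrics.

test_that("loss weights echo the configured coefficients", {
  w <- loss_weights()
  expect_identical(w$w_ce, 0.6)
  expect_identical(w$w_wce, 0.4)
  expect_identical(w$w_dice, 1.0)
  expect_error(loss_weights(w_ce = -1), "w_ce")
})

test_that("a clamped perfect prediction has near-zero loss", {
  set.seed(51)
  tgt <- array(as.integer(runif(2 * 4 * 4 * 4) < 0.3), c(2, 4, 4, 4))
  pred <- array(0, c(2, 2, 4, 4, 4))
  eps <- 1e-7
  pred[, 1, , , ] <- ifelse(tgt == 0L, 1 - eps, eps)
  pred[, 2, , , ] <- ifelse(tgt == 1L, 1 - eps, eps)
  expect_lt(composite_loss(pred, tgt), 1e-5)
})

test_that("the two-voxel composite matches hand arithmetic", {
  pred <- array(0, c(1, 2, 2, 1, 1))
  pred[1, , 1, 1, 1] <- c(0.8, 0.2)
  pred[1, , 2, 1, 1] <- c(0.4, 0.6)
  tgt <- array(c(0L, 1L), c(1, 2, 1, 1))
  w <- loss_weights(class_weights = c(1, 1))
  # hand arithmetic: CE = -(log .8 + log .6)/2; uniform WCE equals CE;
  # soft Dice on foreground probs (0.2, 0.6) against (0, 1)
  ce <- -(log(0.8) + log(0.6)) / 2
  sm <- 1e-5
  dice <- (2 * 0.6 + sm) / (0.2 + 0.6 + 1 + sm)
  expected <- 0.6 * ce + 0.4 * ce + (1 - dice)
  expect_equal(composite_loss(pred, tgt, w), expected, tolerance = 1e-9)
})

test_that("NaN probabilities raise instead of propagating", {
  pred <- array(NaN, c(1, 2, 1, 1, 1))
  expect_error(composite_loss(pred, array(0L, c(1, 1, 1, 1))), "NaN")
})

test_that("inverse-frequency class weights are clipped", {
  tgt <- c(rep(0L, 999), 1L)
  w <- penet:::wce_class_weights(tgt, 2L)
  expect_equal(w[2], 100)
  expect_equal(w[1], 1000 / 999)
  tgt0 <- rep(0L, 10)
  expect_equal(penet:::wce_class_weights(tgt0, 2L)[2], 100)
})

test_that("SEN and DSC match brute-force voxel counting", {
  pred <- array(c(1, 1, 1, 1, 1, 0), c(1, 2, 3))
  lab <- array(c(1, 1, 1, 0, 0, 1), c(1, 2, 3))
  cc <- confusion_counts(pred, lab)
  expect_identical(cc, list(TP = 3L, FN = 1L, FP = 2L))
  expect_equal(sen(cc), 0.75)
  expect_equal(dsc(cc), 6 / 9)

  same <- array(runif(27) < 0.5, c(3, 3, 3))
  ccs <- confusion_counts(same, same)
  expect_equal(sen(ccs), 1)
  expect_equal(dsc(ccs), 1)

  a <- array(c(1, 0, 0, 0), c(2, 2, 1))
  b <- array(c(0, 1, 0, 0), c(2, 2, 1))
  ccd <- confusion_counts(a, b)
  expect_equal(sen(ccd), 0)
  expect_equal(dsc(ccd), 0)

  empty <- array(0, c(2, 2, 1))
  expect_equal(dsc(confusion_counts(empty, empty)), 1)
  expect_true(is.na(sen(confusion_counts(empty, empty))))
})

test_that("AHD equals the exhaustive all-pairs oracle on random voxel sets", {
  set.seed(52)
  for (rep in 1:5) {
    P <- matrix(sample(0:19, 60, replace = TRUE), 20, 3)
    L <- matrix(sample(0:19, 60, replace = TRUE), 20, 3)
    dpl <- min_dists_oracle(P, L)
    dlp <- min_dists_oracle(L, P)
    expect_equal(ahd(P, L), (mean(dpl) + mean(dlp)) / 2)
    expect_equal(ahd(P, L, variant = "as-printed"),
                 (max(dpl) / 20 + max(dlp) / 20) / 2)
  }
})

test_that("AHD identities: zero at equality, exact single-pair distance", {
  P <- matrix(c(0, 0, 0), 1, 3)
  L <- matrix(c(3, 4, 0), 1, 3)
  expect_equal(ahd(P, L), 5)
  expect_equal(ahd(P, L, variant = "as-printed"), 5)
  S <- matrix(sample(0:9, 30, replace = TRUE), 10, 3)
  expect_equal(ahd(S, S), 0)
  expect_error(ahd(matrix(numeric(0), 0, 3), L), "empty")
})

test_that("standard AHD is symmetric and non-increasing as P absorbs L", {
  set.seed(53)
  for (rep in 1:5) {
    P <- unique(matrix(sample(0:14, 45, replace = TRUE), 15, 3))
    L <- unique(matrix(sample(0:14, 45, replace = TRUE), 15, 3))
    expect_equal(ahd(P, L), ahd(L, P))
    prev <- ahd(P, L)
    add <- L[!duplicated(rbind(P, L))[-seq_len(nrow(P))], , drop = FALSE]
    for (take in seq_len(min(4, nrow(add)))) {
      P <- rbind(P, add[take, ])
      cur <- ahd(P, L)
      expect_lte(cur, prev + 1e-12)
      prev <- cur
    }
  }
})

test_that("AHD respects physical voxel spacing", {
  P <- matrix(c(0, 0, 0), 1, 3)
  L <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(ahd(P, L, spacing = c(2, 1, 1)), 2)
})

test_that("loss is non-negative and decreases along a gradient step", {
  set.seed(54)
  logits <- pn_tensor(array(rnorm(2 * 2 * 4 * 4 * 4, sd = 0.1), c(2, 2, 4, 4, 4)))
  tgt <- array(as.integer(runif(2 * 4 * 4 * 4) < 0.2), c(2, 4, 4, 4))
  loss1 <- composite_loss(penet:::op_softmax_ch(logits), tgt)
  expect_gte(pn_val(loss1), 0)
  pn_backward(loss1)
  logits2 <- pn_tensor(logits$value - 0.5 * logits$grad)
  loss2 <- composite_loss(penet:::op_softmax_ch(logits2), tgt)
  expect_lt(pn_val(loss2), pn_val(loss1))
})

test_that("case metrics assemble SEN/DSC/AHD with the variant label", {
  set.seed(55)
  lab <- array(0L, c(6, 6, 6)); lab[2:4, 3, 3] <- 1L
  pred <- lab; pred[5, 3, 3] <- 1L
  cm <- case_metrics(pred, lab, ahd_variant = "standard")
  expect_equal(cm$SEN, 1)
  expect_equal(cm$DSC, 2 * 3 / (2 * 3 + 0 + 1))
  expect_equal(cm$variant, "standard")
  expect_gt(cm$AHD, 0)
})
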