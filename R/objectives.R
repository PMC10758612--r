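# Composite training loss (cross-entropy + weighted cross-entropy +
# soft-Dice) and voxel-based evaluation metrics: sensitivity, Dice
# similarity coefficient and average Hausdorff distance.

#' Loss weights for the composite segmentation loss
#'
#' The total loss is `w_ce * CE + w_wce * WCE + w_dice * DiceLoss` with
#' defaults 0.6 / 0.4 / 1.0.
#'
#' @param w_ce,w_wce,w_dice Nonnegative term weights.
#' @param class_weights Optional fixed per-class weights for the WCE term;
#'   the default `NULL` uses inverse class frequency per batch, clipped to
#'   `[0.01, 100]`.
#' @export
loss_weights <- function(w_ce = 0.6, w_wce = 0.4, w_dice = 1.0,
                         class_weights = NULL) {
  stopifnot(w_ce >= 0, w_wce >= 0, w_dice >= 0)
  structure(list(w_ce = w_ce, w_wce = w_wce, w_dice = w_dice,
                 class_weights = class_weights),
            class = "loss_weights")
}

wce_class_weights <- function(target, num_classes, fixed = NULL) {
  if (!is.null(fixed)) return(fixed)
  f <- tabulate(as.integer(target) + 1L, nbins = num_classes) / length(target)
  w <- ifelse(f > 0, 1 / f, Inf)
  pmin(pmax(w, 0.01), 100)
}

#' Composite segmentation loss
#'
#' `w_ce * CE + w_wce * WCE + w_dice * (1 - softDice)` on
#' softmax-normalized class probabilities. The soft Dice is computed on
#' the foreground class with epsilon smoothing (1e-5) in numerator and
#' denominator; probabilities are clamped to `[1e-7, 1 - 1e-7]` inside the
#' logs.
#'
#' @param pred Probability volume `(N, C, D, H, W)` (array or
#'   `pn_tensor`).
#' @param target Integer label array `(N, D, H, W)` with values in
#'   `0..C-1`.
#' @param w A [loss_weights()].
#' @return Scalar loss (a `pn_tensor` when `pred` is one).
#' @export
composite_loss <- function(pred, target, w = loss_weights()) {
  pv <- pn_val(pred)
  if (anyNA(pv) || any(is.nan(pv)))
    stop("composite_loss: NaN in predicted probabilities")
  d <- dim(pv)
  target <- as.integer(round(pn_val(target)))
  if (length(target) != prod(d[-2]))
    stop("composite_loss: target size does not match prediction")
  eps <- 1e-7
  py <- op_clamp(op_gather_class(pred, target), eps, 1 - eps)
  nll <- op_neg(op_log(py))
  ce <- op_mean(nll)
  cw <- wce_class_weights(target, d[2], w$class_weights)
  wv <- cw[target + 1L]
  wce <- op_scale(op_sum(op_mul(nll, array(wv, dim(pn_val(nll))))), 1 / sum(wv))
  # soft Dice on the foreground class
  p1 <- op_slice_ch(pred, 2L)
  t1 <- array(as.numeric(target == 1L), c(d[1], 1L, d[3], d[4], d[5]))
  sm <- 1e-5
  inter <- op_sum(op_mul(p1, t1))
  denom <- op_add(op_sum(p1), sum(t1))
  dice <- op_div(op_add(op_scale(inter, 2), sm), op_add(denom, sm))
  dice_loss <- op_sub(1, dice)
  op_add(op_add(op_scale(ce, w$w_ce), op_scale(wce, w$w_wce)),
         op_scale(dice_loss, w$w_dice))
}

#' Confusion counts between binary masks
#'
#' @param pred,label Binary arrays (0/1) of identical shape.
#' @return List with `TP`, `FN`, `FP`.
#' @export
confusion_counts <- function(pred, label) {
  pred <- as.logical(pred); label <- as.logical(label)
  stopifnot(length(pred) == length(label))
  list(TP = sum(pred & label), FN = sum(!pred & label), FP = sum(pred & !label))
}

#' Sensitivity (true-positive rate)
#'
#' `SEN = TP / (TP + FN)`; `NA` when the label set is empty.
#'
#' @param counts A [confusion_counts()] list.
#' @export
sen <- function(counts) {
  if (counts$TP + counts$FN == 0) return(NA_real_)
  counts$TP / (counts$TP + counts$FN)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 TP / (2 TP + FN + FP)`. When both prediction and label are
#' empty the DSC is defined as 1 (perfect agreement on the empty set).
#'
#' @param counts A [confusion_counts()] list.
#' @export
dsc <- function(counts) {
  den <- 2 * counts$TP + counts$FN + counts$FP
  if (den == 0) return(1)
  2 * counts$TP / den
}

as_voxel_set <- function(x, nm) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) stop(sprintf("ahd: %s must be an n x 3 coordinate matrix", nm))
    return(x)
  }
  w <- which(x != 0, arr.ind = TRUE)
  if (length(dim(x)) != 3) stop(sprintf("ahd: %s must be a 3D mask or n x 3 matrix", nm))
  matrix(as.numeric(w), ncol = 3)
}

#' Average Hausdorff distance between voxel sets
#'
#' Variant `"standard"` is the conventional average Hausdorff distance
#' \deqn{\tfrac12\big[\mathrm{mean}_{p \in P} \min_l d(p,l) +
#'   \mathrm{mean}_{l \in L} \min_p d(p,l)\big];}
#' variant `"as-printed"` divides the directed *maximum* of minima by the
#' set size on each side (a literal reading of one printed form of the
#' metric), i.e. `0.5 * (max_p min_l d / |P| + max_l min_p d / |L|)`.
#'
#' @param P,L Predicted and reference voxel sets: `n x 3` coordinate
#'   matrices or 3D binary arrays.
#' @param variant `"standard"` (default) or `"as-printed"`.
#' @param spacing Physical voxel spacing multiplier, length 3.
#' @return Distance in voxel units (times `spacing`).
#' @export
ahd <- function(P, L, variant = c("standard", "as-printed"), spacing = c(1, 1, 1)) {
  variant <- match.arg(variant)
  P <- as_voxel_set(P, "P"); L <- as_voxel_set(L, "L")
  if (nrow(P) == 0) stop("ahd: the predicted set is empty; the distance is undefined")
  if (nrow(L) == 0) stop("ahd: the label set is empty; the distance is undefined")
  Ps <- sweep(P, 2, spacing, `*`)
  Ls <- sweep(L, 2, spacing, `*`)
  dpl <- .cpp_min_dists(Ps, Ls)
  dlp <- .cpp_min_dists(Ls, Ps)
  if (variant == "standard") (mean(dpl) + mean(dlp)) / 2
  else (max(dpl) / nrow(P) + max(dlp) / nrow(L)) / 2
}

#' Per-case segmentation metrics
#'
#' @param pred,label Binary 3D masks.
#' @param ahd_variant Passed to [ahd()].
#' @param spacing Voxel spacing.
#' @return One-row data.frame with `SEN`, `DSC`, `AHD`, `variant`.
#' @export
case_metrics <- function(pred, label, ahd_variant = "standard", spacing = c(1, 1, 1)) {
  cc <- confusion_counts(pred, label)
  a <- if (sum(pred != 0) == 0 || sum(label != 0) == 0) NA_real_
       else ahd(pred != 0, label != 0, variant = ahd_variant, spacing = spacing)
  data.frame(SEN = sen(cc), DSC = dsc(cc), AHD = a, variant = ahd_variant,
             stringsAsFactors = FALSE)
}

#' Aggregate a per-case metric table
#'
#' @param df Data.frame with numeric columns `SEN`, `DSC`, `AHD`.
#' @return Named list of per-metric mean, sd, median, min, max.
#' @export
aggregate_metrics <- function(df) {
  ag <- function(v) {
    v <- v[!is.na(v)]
    list(mean = mean(v), std = stats::sd(v), median = stats::median(v),
         min = min(v), max = max(v))
  }
  list(SEN = ag(df$SEN), DSC = ag(df$DSC), AHD = ag(df$AHD))
}
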