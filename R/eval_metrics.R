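#' Pixel-wise confusion counts
#'
#' Compares a predicted binary mask against a ground-truth mask, with
#' foreground coded as 1.
#'
#' @param pred,gt binary (0/1 or logical) matrices of identical shape.
#' @return A list of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, gt) {
  pred <- as_binary_matrix(pred, "pred")
  gt <- as_binary_matrix(gt, "gt")
  if (!identical(dim(pred), dim(gt)))
    stop("`pred` and `gt` must have identical dimensions")
  structure(
    list(TP = sum(pred == 1L & gt == 1L),
         FP = sum(pred == 1L & gt == 0L),
         FN = sum(pred == 0L & gt == 1L),
         TN = sum(pred == 0L & gt == 0L)),
    class = "confusion_counts"
  )
}

as_binary_matrix <- function(x, name) {
  if (is.logical(x)) x <- x + 0L
  if (!is.matrix(x) || !all(x %in% c(0L, 1L)))
    stop("`", name, "` must be a binary 0/1 matrix")
  storage.mode(x) <- "integer"
  x
}

#' Region-overlap metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, Dice `2TP/(2TP+FP+FN)`, Jaccard/IoU
#' `TP/(TP+FP+FN)`, precision `TP/(TP+FP)` and recall `TP/(TP+FN)`. A metric
#' whose denominator is zero is reported as `NA` (undefined), never silently
#' as 0 or 1; the single exception is accuracy, which is always defined for a
#' non-empty image.
#'
#' @param cc a `confusion_counts` object from [confusion()].
#' @return Named list with `accuracy`, `dsc`, `iou`, `precision`, `recall`.
#' @export
region_metrics <- function(cc) {
  if (!inherits(cc, "confusion_counts")) stop("expected `confusion_counts`")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  with(cc, list(
    accuracy  = sdiv(TP + TN, TP + TN + FP + FN),
    dsc       = sdiv(2 * TP, 2 * TP + FP + FN),
    iou       = sdiv(TP, TP + FP + FN),
    precision = sdiv(TP, TP + FP),
    recall    = sdiv(TP, TP + FN)
  ))
}

# boundary pixels: foreground with at least one background 8-neighbour;
# the image border counts as background
boundary_pixels <- function(mask) {
  M <- nrow(mask); N <- ncol(mask)
  padded <- matrix(0L, M + 2L, N + 2L)
  padded[2:(M + 1L), 2:(N + 1L)] <- mask
  bg_neigh <- matrix(FALSE, M, N)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    bg_neigh <- bg_neigh |
      (padded[(2:(M + 1L)) + dr, (2:(N + 1L)) + dc] == 0L)
  }
  which(mask == 1L & bg_neigh, arr.ind = TRUE)
}

# for each row of `a` (n x 2 coords), the minimum Euclidean distance to any
# row of `b`; memory-bounded by chunking over `a`
min_cross_dist <- function(a, b, chunk = 512L) {
  out <- numeric(nrow(a))
  for (s in seq(1L, nrow(a), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(a))
    d2 <- outer(a[idx, 1L], b[, 1L], "-")^2 + outer(a[idx, 2L], b[, 2L], "-")^2
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Boundary F1 score
#'
#' Extracts boundary pixels from both masks (a foreground pixel with at least
#' one background 8-neighbour; the image border counts as background), then
#' computes boundary precision (fraction of predicted boundary pixels within
#' `tolerance` Euclidean distance of some ground-truth boundary pixel),
#' boundary recall (the symmetric quantity) and their harmonic mean
#' `2PR/(P+R)`. If both boundaries are empty the score is 1; if exactly one is
#' empty it is 0.
#'
#' @param pred,gt binary masks of identical shape.
#' @param tolerance match distance in pixels, default 2.
#' @return Scalar in `[0, 1]`.
#' @export
bf_score <- function(pred, gt, tolerance = 2) {
  pred <- as_binary_matrix(pred, "pred")
  gt <- as_binary_matrix(gt, "gt")
  if (!identical(dim(pred), dim(gt)))
    stop("`pred` and `gt` must have identical dimensions")
  if (tolerance < 0) stop("`tolerance` must be nonnegative")
  bp <- boundary_pixels(pred)
  bg <- boundary_pixels(gt)
  if (nrow(bp) == 0L && nrow(bg) == 0L) return(1)
  if (nrow(bp) == 0L || nrow(bg) == 0L) return(0)
  P <- mean(min_cross_dist(bp, bg) <= tolerance)
  R <- mean(min_cross_dist(bg, bp) <= tolerance)
  if (P + R == 0) return(0)
  2 * P * R / (P + R)
}

#' Combined region-and-boundary score
#'
#' `CS = wm * DSC + (1 - wm) * BF`, a convex combination of the Dice overlap
#' and the boundary F1 score.
#'
#' @param dsc Dice similarity coefficient in `[0, 1]`.
#' @param bf boundary F1 score in `[0, 1]`.
#' @param wm weight on the Dice term, in `[0, 1]`; default 0.5.
#' @return Scalar in `[0, 1]`.
#' @export
combined_score <- function(dsc, bf, wm = 0.5) {
  if (wm < 0 || wm > 1) stop("`wm` must lie in [0, 1]")
  wm * dsc + (1 - wm) * bf
}

#' Full evaluation of a predicted mask
#'
#' Convenience wrapper producing all region metrics, the boundary F1 score and
#' the combined score in one report.
#'
#' @param pred,gt binary masks of identical shape.
#' @param bf_tolerance boundary match tolerance in pixels, default 2.
#' @param wm combined-score weight on Dice, default 0.5.
#' @return Named list with `accuracy`, `dsc`, `iou`, `precision`, `recall`,
#'   `bf`, `cs`, plus the settings `bf_tolerance` and `wm`.
#' @export
evaluate_mask <- function(pred, gt, bf_tolerance = 2, wm = 0.5) {
  cc <- confusion(pred, gt)
  rm <- region_metrics(cc)
  bf <- bf_score(pred, gt, bf_tolerance)
  cs <- if (is.na(rm$dsc)) NA_real_ else combined_score(rm$dsc, bf, wm)
  c(rm, list(bf = bf, cs = cs, bf_tolerance = bf_tolerance, wm = wm))
}
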