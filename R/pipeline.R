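#' Partition an image at thresholds and posterize by segment means
#'
#' Pixels are assigned to segments `S1 = {p <= t1}`,
#' `Sk = {t_{k-1} < p <= t_k}`, `S_{n+1} = {p > t_n}`; each pixel is replaced
#' by the rounded mean intensity of its segment. Segments containing no pixels
#' contribute no value to the posterized image.
#'
#' @param img a [gray_image].
#' @param thresholds strictly increasing thresholds in `(0, L-1)`.
#' @return List with `labels` (integer matrix of segment indices), `means`
#'   (named numeric vector of segment means, `NA` for empty segments) and `G`
#'   (the posterized [gray_image]).
#' @export
partition_posterize <- function(img, thresholds) {
  assert_gray_image(img)
  thresholds <- as.integer(thresholds)
  if (length(thresholds) && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  labels <- matrix(
    findInterval(img$pixels, thresholds, left.open = TRUE) + 1L,
    img$M, img$N
  )
  nseg <- length(thresholds) + 1L
  means <- vapply(seq_len(nseg), function(k) {
    v <- img$pixels[labels == k]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  gvals <- round_half_up(means)
  G <- gray_image(matrix(gvals[labels], img$M, img$N), L = img$L)
  list(labels = labels, means = means, G = G)
}

#' Binarize a posterized image at a threshold
#'
#' Strict greater-than rule: mask is 1 where `G > T`, 0 otherwise.
#'
#' @param G a [gray_image] (typically the posterized image).
#' @param T threshold in `[0, L-1]`.
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(G, T) {
  assert_gray_image(G)
  if (T < 0 || T > G$L - 1L) stop("`T` must lie in [0, L-1]")
  m <- (G$pixels > T) + 0L
  dim(m) <- dim(G$pixels)
  m
}

#' Iterative multilevel thresholding segmentation
#'
#' The full segmentation pipeline for a thermal image:
#' 1. bilevel threshold search on the input image;
#' 2. foreground mean above that pre-threshold, adaptive gamma, logit mapping,
#'    rescale and pixel-wise application, giving the enhanced image `Y`;
#' 3. `n`-level threshold search on `Y`;
#' 4. partition of `Y` into `n+1` segments, each replaced by its mean
#'    intensity (the posterized image `G`);
#' 5. bilevel threshold search on `G` and strict-greater binarization, giving
#'    the region-of-interest mask `B`.
#'
#' Every intermediate is returned for inspection. All three searches use the
#' same entropy configuration (the adaptive tan-log objective by default).
#'
#' The threshold search definition includes a max-normalisation of its input.
#' The pipeline applies [normalize_quantize()] once, to the input image, and
#' lets the later stages use their images directly: the enhancement rescale
#' already places the enhanced image on the full `[0, rho*(L-1)]` range, and
#' the final threshold must be applied to the posterized image on its own
#' scale for the binarisation rule to be meaningful. This keeps every reported
#' threshold on the scale of the image it partitions.
#'
#' @param img a [gray_image].
#' @param n number of thresholds for the multilevel pass (default 1).
#' @param cfg an [entropy_config()].
#' @param rho `"adaptive"` or a fixed positive scale for the logit mapping.
#' @param gamma_mode `"foreground"` (default) or `"global"` reference mean.
#' @param search `"exhaustive"` (default, for `n <= 3`) or `"dp"`.
#' @return An object of class `segmentation_result` with fields
#'   `thresholds_pre`, `params`, `enhanced`, `thresholds_multi`, `labels`,
#'   `means`, `G`, `thresholds_final`, `mask`.
#' @export
run_pipeline <- function(img, n = 1L, cfg = entropy_config(),
                         rho = "adaptive",
                         gamma_mode = c("foreground", "global"),
                         search = c("exhaustive", "dp")) {
  assert_gray_image(img)
  gamma_mode <- match.arg(gamma_mode)
  search <- match.arg(search)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1")
  do_search <- function(dist, k, stage) {
    tryCatch(
      if (search == "dp" || k > 3L) search_thresholds_dp(dist, k, cfg)
      else search_thresholds(dist, k, cfg),
      error = function(e) stop("pipeline stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  I0 <- normalize_quantize(img)
  thr_pre <- do_search(intensity_histogram(I0), 1L, "pre-threshold")
  enh <- tryCatch(
    enhance(I0, rho = rho, gamma_mode = gamma_mode,
            threshold = thr_pre$values, cfg = cfg),
    error = function(e) stop("pipeline stage 'enhance' failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  Y <- enh$image
  thr_multi <- do_search(intensity_histogram(Y), n, "multilevel")
  post <- partition_posterize(Y, thr_multi$values)
  G <- post$G
  thr_final <- do_search(intensity_histogram(G), 1L, "final-bilevel")
  mask <- binarize(G, thr_final$values)
  structure(
    list(thresholds_pre = thr_pre, params = enh$params, enhanced = Y,
         thresholds_multi = thr_multi, labels = post$labels,
         means = post$means, G = G,
         thresholds_final = thr_final, mask = mask),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_result %dx%d>\n",
                     "  pre-threshold  t = %s\n",
                     "  multilevel     t = %s (k = %d)\n",
                     "  final          t = %s\n",
                     "  gamma_phi = %.4f, rho = %.4f, mu = %.2f\n",
                     "  mask foreground: %d px\n"),
              nrow(x$mask), ncol(x$mask),
              paste(x$thresholds_pre$values, collapse = ", "),
              paste(x$thresholds_multi$values, collapse = ", "),
              x$thresholds_multi$k,
              paste(x$thresholds_final$values, collapse = ", "),
              x$params$gamma_phi, x$params$rho, x$params$mu,
              sum(x$mask)))
  invisible(x)
}
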