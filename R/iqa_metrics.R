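#' Block tiling of an image
#'
#' Non-overlapping rectangular blocks covering every pixel exactly once; edge
#' remainders are kept as partial blocks. 8x8 is the customary block size in
#' the block-contrast-measure literature and is the default.
#'
#' @param img a [gray_image].
#' @param block_height,block_width block dimensions in pixels.
#' @return A `block_grid`: list of blocks, each a list with `rows` and `cols`
#'   index vectors.
#' @export
block_grid <- function(img, block_height = 8L, block_width = 8L) {
  assert_gray_image(img)
  if (block_height < 1L || block_width < 1L) stop("block dimensions must be positive")
  rs <- seq(1L, img$M, by = block_height)
  cs <- seq(1L, img$N, by = block_width)
  blocks <- list()
  for (r0 in rs) for (c0 in cs) {
    blocks[[length(blocks) + 1L]] <- list(
      rows = r0:min(r0 + block_height - 1L, img$M),
      cols = c0:min(c0 + block_width - 1L, img$N)
    )
  }
  structure(list(blocks = blocks, block_height = block_height,
                 block_width = block_width), class = "block_grid")
}

block_apply <- function(img, grid, f) {
  vapply(grid$blocks, function(b) f(img$pixels[b$rows, b$cols, drop = FALSE]),
         numeric(1))
}

#' Block-based adaptive entropy metric
#'
#' Evaluates the adaptive tan-log entropy kernel on each block's local
#' intensity distribution and averages over blocks. Unlike global entropies,
#' which depend only on the image-wide histogram, this metric changes when
#' pixels are rearranged across blocks, making it sensitive to spatial
#' structure.
#'
#' For each block the local PDF is `p_i = h_block(i) / |block|` and the
#' kernel's normalising weight is the block's total probability mass (1 for a
#' complete block), mirroring the segment weight in the thresholding
#' objective.
#'
#' @param img a [gray_image].
#' @param grid a [block_grid()]; default 8x8 blocks.
#' @param gamma sensitivity exponent, default 1.
#' @param eps stabiliser, default 1.
#' @return Scalar metric (mean over blocks).
#' @export
block_a_entropy <- function(img, grid = block_grid(img), gamma = 1, eps = 1) {
  assert_gray_image(img)
  L <- img$L
  vals <- block_apply(img, grid, function(blk) {
    p <- tabulate(as.vector(blk) + 1L, nbins = L) / length(blk)
    d <- dist_from_p(p)
    a_entropy_segment(d, make_segment(d, 0L, L - 1L), gamma = gamma, eps = eps)
  })
  mean(vals)
}

block_minmax_metric <- function(img, grid, guard, f) {
  vals <- block_apply(img, grid, function(blk) {
    f(max(blk), min(blk))
  })
  mean(vals)
}

#' Block contrast measures (EME family)
#'
#' No-reference block-based contrast measures, averaged over the blocks of a
#' [block_grid()]. All four are oriented so that larger values indicate more
#' within-block contrast, and a constant image scores exactly 0:
#'
#' * `eme`:  `20 * log10(r)` with the guarded max/min ratio
#'   `r = (Imax + guard) / (Imin + guard)`;
#' * `emee`: `alpha * r^alpha * ln(r)` (entropy-weighted ratio measure);
#' * `ame`:  the guarded Michelson contrast
#'   `Mc = (Imax - Imin) / (Imax + Imin + guard)`;
#' * `amee`: `alpha * (1 + Mc)^alpha * ln(1 + Mc)` (entropy-weighted Michelson
#'   measure).
#'
#' The guard keeps ratios finite when a block minimum is 0; adding it to both
#' numerator and denominator makes constant blocks score identically 0.
#'
#' @param img a [gray_image].
#' @param grid a [block_grid()]; default 8x8 blocks.
#' @param guard small positive constant, default `1e-4`.
#' @param alpha exponent of the entropy-weighted variants, default 0.5.
#' @return Scalar metric (mean over blocks).
#' @export
eme <- function(img, grid = block_grid(img), guard = 1e-4) {
  assert_gray_image(img)
  if (guard <= 0) stop("`guard` must be positive")
  block_minmax_metric(img, grid, guard, function(mx, mn)
    20 * log10((mx + guard) / (mn + guard)))
}

#' @rdname eme
#' @export
emee <- function(img, grid = block_grid(img), guard = 1e-4, alpha = 0.5) {
  assert_gray_image(img)
  if (guard <= 0) stop("`guard` must be positive")
  block_minmax_metric(img, grid, guard, function(mx, mn) {
    r <- (mx + guard) / (mn + guard)
    alpha * r^alpha * log(r)
  })
}

#' @rdname eme
#' @export
ame <- function(img, grid = block_grid(img), guard = 1e-4) {
  assert_gray_image(img)
  if (guard <= 0) stop("`guard` must be positive")
  block_minmax_metric(img, grid, guard, function(mx, mn)
    (mx - mn) / (mx + mn + guard))
}

#' @rdname eme
#' @export
amee <- function(img, grid = block_grid(img), guard = 1e-4, alpha = 0.5) {
  assert_gray_image(img)
  if (guard <= 0) stop("`guard` must be positive")
  block_minmax_metric(img, grid, guard, function(mx, mn) {
    mc <- (mx - mn) / (mx + mn + guard)
    alpha * (1 + mc)^alpha * log(1 + mc)
  })
}

#' All block metrics at once
#'
#' Convenience wrapper returning the proposed block entropy metric and the
#' four contrast comparators as a named vector.
#'
#' @inheritParams eme
#' @param gamma,eps parameters of the block entropy kernel.
#' @param alpha exponent of the entropy-weighted contrast variants.
#' @return Named numeric vector with entries `a_entropy`, `eme`, `emee`,
#'   `ame`, `amee`.
#' @export
iqa_metrics <- function(img, grid = block_grid(img), guard = 1e-4,
                        gamma = 1, eps = 1, alpha = 0.5) {
  c(a_entropy = block_a_entropy(img, grid, gamma, eps),
    eme  = eme(img, grid, guard),
    emee = emee(img, grid, guard, alpha),
    ame  = ame(img, grid, guard),
    amee = amee(img, grid, guard, alpha))
}
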