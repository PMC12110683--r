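#' Synthetic thermal scene specification
#'
#' Parameters of the deterministic scene generator used throughout the test
#' surfaces: an aerial-thermal-like image with a spatially smooth noisy
#' background and a small number of brighter blob-shaped objects (warm bodies)
#' with feathered edges, plus additive pixel noise.
#'
#' @param height,width scene size in pixels.
#' @param n_blobs number of foreground blobs.
#' @param blob_radius_range min/max blob radius in pixels.
#' @param contrast_ratio foreground-mean over background-mean (must exceed 1).
#' @param background_mean mean background intensity.
#' @param noise_sigma standard deviation of the additive pixel noise.
#' @param smoothing_sigma Gaussian smoothing scale of the background field, in
#'   pixels.
#' @param feather_sigma width in pixels of the Gaussian edge feather centred
#'   on the blob boundary.
#' @param seed integer seed; the same spec always produces the same scene.
#' @param L number of intensity levels.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(height = 128L, width = 128L, n_blobs = 3L,
                       blob_radius_range = c(5, 10), contrast_ratio = 2,
                       background_mean = 60, noise_sigma = 5,
                       smoothing_sigma = 3, feather_sigma = 1,
                       seed = 1L, L = 256L) {
  if (height < 1L || width < 1L) stop("scene dimensions must be positive")
  if (contrast_ratio <= 1) stop("`contrast_ratio` must exceed 1")
  if (n_blobs < 0L) stop("`n_blobs` must be nonnegative")
  if (any(blob_radius_range <= 0) || blob_radius_range[1] > blob_radius_range[2])
    stop("invalid `blob_radius_range`")
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_blobs = as.integer(n_blobs), blob_radius_range = blob_radius_range,
         contrast_ratio = contrast_ratio, background_mean = background_mean,
         noise_sigma = noise_sigma, smoothing_sigma = smoothing_sigma,
         feather_sigma = feather_sigma, seed = as.integer(seed),
         L = as.integer(L)),
    class = "scene_spec"
  )
}

# run `expr` under a locally seeded Mersenne-Twister stream, restoring any
# pre-existing global RNG state afterwards
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# separable Gaussian smoothing with circular boundary handling
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  sm_cols <- apply(m, 2L, function(v) stats::filter(v, k, circular = TRUE))
  t(apply(t(sm_cols), 2L, function(v) stats::filter(v, k, circular = TRUE)))
}

#' Generate a synthetic thermal scene with ground truth
#'
#' Builds the background as a smoothed Gaussian noise field around
#' `background_mean`, places `n_blobs` elliptical blobs at non-overlapping
#' random positions with plateau intensity
#' `contrast_ratio * background_mean` and a Gaussian feather across the blob
#' boundary, adds independent pixel noise, and clips/rounds to `[0, L-1]`.
#' The ground-truth mask marks the elliptical blob support (the region inside
#' the boundary, before feathering).
#'
#' @param spec a [scene_spec()].
#' @return List with `image` (a [gray_image]) and `mask` (0/1 integer matrix).
#' @export
make_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("expected a `scene_spec`")
  with_local_seed(spec$seed, {
    M <- spec$height; N <- spec$width
    bg <- matrix(stats::rnorm(M * N, spec$background_mean,
                              max(spec$noise_sigma, 1)), M, N)
    bg <- gaussian_smooth(bg, spec$smoothing_sigma)
    img <- bg
    mask <- matrix(0L, M, N)
    fg_level <- spec$contrast_ratio * spec$background_mean
    placed <- list()
    for (b in seq_len(spec$n_blobs)) {
      r <- stats::runif(1, spec$blob_radius_range[1], spec$blob_radius_range[2])
      ok <- FALSE
      for (try in 1:200) {
        cy <- stats::runif(1, r + 2, M - r - 1)
        cx <- stats::runif(1, r + 2, N - r - 1)
        clear <- all(vapply(placed, function(q)
          sqrt((q$cy - cy)^2 + (q$cx - cx)^2) > (q$r + r + 2), logical(1)))
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place ", spec$n_blobs,
                    " non-overlapping blobs after bounded retries")
      placed[[length(placed) + 1L]] <- list(cy = cy, cx = cx, r = r)
      # elliptical normalised distance (randomly squashed and rotated)
      ar <- stats::runif(1, 0.7, 1)
      th <- stats::runif(1, 0, pi)
      dy <- outer(seq_len(M) - cy, rep(1, N))
      dx <- outer(rep(1, M), seq_len(N) - cx)
      u <- (cos(th) * dx + sin(th) * dy) / r
      v <- (-sin(th) * dx + cos(th) * dy) / (r * ar)
      e <- sqrt(u^2 + v^2)
      w <- stats::pnorm((1 - e) * r / spec$feather_sigma)
      img <- img + (fg_level - bg) * w
      mask[e <= 1] <- 1L
    }
    img <- img + stats::rnorm(M * N, 0, spec$noise_sigma)
    img <- pmin(pmax(round_half_up(img), 0), spec$L - 1L)
    list(image = gray_image(matrix(img, M, N), L = spec$L), mask = mask)
  })
}

#' Shuffle pixels within rows, columns, or globally
#'
#' Spatial permutations that exactly preserve the intensity histogram:
#' `row_wise` permutes pixels independently within each row, `column_wise`
#' within each column, `full` across the whole image.
#'
#' @param img a [gray_image].
#' @param mode `"row_wise"`, `"column_wise"` or `"full"`.
#' @param seed integer seed for the permutation stream.
#' @return A [gray_image] with identical histogram.
#' @export
shuffle_pixels <- function(img, mode = c("row_wise", "column_wise", "full"),
                           seed = 1L) {
  assert_gray_image(img)
  mode <- match.arg(mode)
  with_local_seed(seed, {
    px <- img$pixels
    out <- switch(mode,
      row_wise = t(apply(px, 1L, function(v) v[sample.int(length(v))])),
      column_wise = apply(px, 2L, function(v) v[sample.int(length(v))]),
      full = matrix(px[sample.int(length(px))], nrow(px), ncol(px))
    )
    gray_image(matrix(out, img$M, img$N), L = img$L)
  })
}

#' Degree-of-Enhancement series
#'
#' A family of progressively contrast-stretched versions of an image: at
#' enhancement degree `d` percent, each pixel `v` maps to
#' `mean + (1 + d/100 * kappa) * (v - mean)`, rounded and clipped to
#' `[0, L-1]`. Degree 0 returns the original image unchanged. The gain is
#' affine about the global mean, so the intensity spread is nondecreasing in
#' `d` until clipping saturates.
#'
#' @param img a [gray_image].
#' @param levels enhancement degrees in percent, default `c(0, 25, 50, 75, 100)`.
#' @param kappa gain constant, default 0.5 (degree 100 stretches contrast by
#'   a factor 1.5).
#' @return Named list of [gray_image]s, one per degree.
#' @export
doe_series <- function(img, levels = c(0, 25, 50, 75, 100), kappa = 0.5) {
  assert_gray_image(img)
  if (any(levels < 0 | levels > 100)) stop("`levels` must lie in [0, 100]")
  m <- mean(img$pixels)
  out <- lapply(levels, function(d) {
    if (d == 0) return(img)
    v <- m + (1 + d / 100 * kappa) * (img$pixels - m)
    gray_image(matrix(pmin(pmax(round_half_up(v), 0), img$L - 1L),
                      img$M, img$N), L = img$L)
  })
  names(out) <- paste0("doe_", levels)
  out
}
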