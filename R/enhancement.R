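#' Adaptive gamma from image statistics
#'
#' `gamma_phi = exp((mu - Imax/2) / (Imax/2))`. A mean at half the maximum
#' gives gamma 1 (no bias); a dark image (`mu -> 0`) gives `exp(-1)` and a
#' bright one (`mu -> Imax`) gives `e`, so the parameter always lies in
#' `[1/e, e]`.
#'
#' @param mu reference mean intensity (global or foreground mean).
#' @param imax maximum intensity of the image (must be positive).
#' @return The adaptive gamma, a positive scalar.
#' @export
adaptive_gamma <- function(mu, imax) {
  if (imax <= 0) stop("`imax` must be positive")
  if (mu < 0 || mu > imax) stop("`mu` must lie in [0, imax]")
  exp((mu - imax / 2) / (imax / 2))
}

#' Mean intensity of pixels above a threshold
#'
#' The foreground reference mean used by the segmentation pipeline: the
#' arithmetic mean of all pixels strictly greater than `T`.
#'
#' @param img a [gray_image].
#' @param T threshold; pixels `> T` count as foreground.
#' @return Scalar mean intensity.
#' @export
foreground_mean <- function(img, T) {
  assert_gray_image(img)
  v <- img$pixels[img$pixels > T]
  if (length(v) == 0L)
    stop("no pixel exceeds T = ", T, "; cannot form a foreground mean")
  mean(v)
}

#' Logit-based intensity mapping
#'
#' Builds the lookup table of the monotone contrast mapping
#' `f(i) = log((i/(L-1)) / (1 - i/(L-1) + gamma_phi))` for levels
#' `i = 1, ..., L-1`, affinely rescaled to `[0, rho*(L-1)]`. `f(0)` (a log of
#' zero) is filled by linear extrapolation from `f(1)` and `f(2)` before
#' rescaling so the affine map stays finite. The returned table is
#' real-valued; [enhance()] performs the requantization onto `[0, L-1]`.
#'
#' @param gamma_phi adaptive gamma (positive), see [adaptive_gamma()].
#' @param rho output scale constant (positive).
#' @param L number of intensity levels.
#' @param domain optional length-2 integer vector of levels: the rescale's
#'   min/max are taken over `f` restricted to `[domain[1], domain[2]]` (the
#'   image's occupied range in the pipeline, mirroring a min/max rescale
#'   computed on the mapped image itself); levels outside are clamped to the
#'   ends. `NULL` (default) uses the full level range.
#' @return Numeric vector of length `L`, nondecreasing from 0 to
#'   `rho * (L-1)` (strictly increasing inside `domain`); entry `i+1` is the
#'   mapped value of level `i`.
#' @export
logit_map <- function(gamma_phi, rho, L = 256L, domain = NULL) {
  if (gamma_phi <= 0) stop("`gamma_phi` must be positive")
  if (rho <= 0) stop("`rho` must be positive")
  if (L < 3L) stop("`L` must be at least 3")
  i <- 1:(L - 1L)
  x <- i / (L - 1L)
  f <- log(x / (1 - x + gamma_phi))
  f <- c(f[1] - (f[2] - f[1]), f)  # extrapolated f(0)
  if (is.null(domain)) domain <- c(0L, L - 1L)
  if (length(domain) != 2L || domain[1] < 0L || domain[2] > L - 1L ||
      domain[1] >= domain[2])
    stop("`domain` must be two increasing levels inside [0, L-1]")
  fd <- f[(domain[1] + 1L):(domain[2] + 1L)]
  if (max(fd) == min(fd)) stop("degenerate logit map (constant f on domain)")
  fp <- (f - min(fd)) / (max(fd) - min(fd)) * rho * (L - 1L)
  pmin(pmax(fp, 0), rho * (L - 1L))
}

#' Adaptive contrast enhancement
#'
#' Applies the logit mapping with an image-adapted gamma. The reference mean
#' is either the global mean (`gamma_mode = "global"`) or, as in the full
#' segmentation pipeline, the mean of pixels above a bilevel pre-threshold
#' (`gamma_mode = "foreground"`). When no pre-threshold is supplied in
#' foreground mode, one is found with a bilevel adaptive-entropy search. If no
#' pixel exceeds the pre-threshold the global mean is used instead and the
#' fallback is recorded in the returned parameters.
#'
#' The mapped values span `[0, rho*(L-1)]` and must be brought back to the
#' representable range. The default (`requantize = "normalize"`) rounds at the
#' scaled resolution and divides by the realized maximum, exactly as the
#' threshold search's own max-normalization would; the scale `rho` then acts
#' through rounding granularity (small `rho` merges intensity levels). The
#' alternative `"clip"` truncates values above `L-1` instead; note that for
#' `rho` appreciably above 1 truncation saturates most of the level range.
#'
#' @param img a [gray_image].
#' @param rho `"adaptive"` (default, `rho = mu / (10 * gamma_phi)`) or a fixed
#'   positive number.
#' @param gamma_mode `"foreground"` (default) or `"global"`.
#' @param threshold optional pre-threshold for foreground mode.
#' @param requantize `"normalize"` (default) or `"clip"`, see Details.
#' @param cfg [entropy_config()] used when the pre-threshold must be searched.
#' @return A list of class `enhancement_result`: `image` (the enhanced
#'   [gray_image]) and `params` (list with `mu`, `gamma_phi`, `rho`, `mode`,
#'   `threshold`, `fallback_global`, `lut`).
#' @export
enhance <- function(img, rho = "adaptive",
                    gamma_mode = c("foreground", "global"),
                    threshold = NULL, requantize = c("normalize", "clip"),
                    cfg = entropy_config()) {
  assert_gray_image(img)
  gamma_mode <- match.arg(gamma_mode)
  requantize <- match.arg(requantize)
  imax <- max(img$pixels)
  if (imax == 0L) stop("cannot enhance an all-zero image")
  if (imax == min(img$pixels))
    stop("cannot enhance a constant image (degenerate mapping domain)")
  fallback <- FALSE
  if (gamma_mode == "global") {
    mu <- mean(img$pixels)
    threshold <- NA_integer_
  } else {
    if (is.null(threshold)) {
      threshold <- search_thresholds(intensity_histogram(img), 1L, cfg)$values
    }
    mu <- tryCatch(foreground_mean(img, threshold), error = function(e) {
      fallback <<- TRUE
      mean(img$pixels)
    })
  }
  g <- adaptive_gamma(mu, imax)
  rho_val <- if (identical(rho, "adaptive")) mu / (10 * g) else {
    if (!is.numeric(rho) || rho <= 0) stop("`rho` must be 'adaptive' or a positive number")
    rho
  }
  lut_real <- logit_map(g, rho_val, img$L,
                        domain = range(img$pixels))
  lut_scaled <- round_half_up(lut_real)
  lut <- if (requantize == "clip") {
    as.integer(pmin(pmax(lut_scaled, 0), img$L - 1L))
  } else {
    as.integer(round_half_up(lut_scaled / max(lut_scaled) * (img$L - 1L)))
  }
  out <- gray_image(matrix(lut[img$pixels + 1L], img$M, img$N), L = img$L)
  structure(
    list(image = out,
         params = list(mu = mu, gamma_phi = g, rho = rho_val,
                       mode = gamma_mode, threshold = threshold,
                       fallback_global = fallback, lut = lut)),
    class = "enhancement_result"
  )
}
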