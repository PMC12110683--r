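#' Grayscale image container
#'
#' A `gray_image` is a 2-D grid of integer intensities in `[0, L-1]` together
#' with the number of representable levels `L` (256 for 8-bit data). It is the
#' common currency of every operation in the package: histogramming, entropy
#' objectives, enhancement and segmentation all consume and produce
#' `gray_image` objects.
#'
#' @param pixels numeric or integer matrix of nonnegative intensities.
#' @param L number of intensity levels (default 256). All pixels must lie in
#'   `[0, L-1]`.
#' @return An object of class `gray_image`: a list with elements `pixels`
#'   (integer matrix), `M` (height), `N` (width) and `L`.
#' @examples
#' img <- gray_image(matrix(0:3, 2, 2))
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, L = 256L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1")
  L <- as.integer(L)
  if (L < 2L) stop("`L` must be at least 2")
  if (anyNA(pixels)) stop("image contains missing values")
  px <- round(pixels)
  if (any(px < 0) || any(px > L - 1L))
    stop("pixel values must lie in [0, L-1] = [0, ", L - 1L, "]")
  storage.mode(px) <- "integer"
  structure(
    list(pixels = px, M = nrow(px), N = ncol(px), L = L),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, L=%d, range [%d, %d]>\n",
              x$M, x$N, x$L, min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

assert_gray_image <- function(x) {
  if (!is_gray_image(x)) stop("expected a `gray_image` object")
  invisible(x)
}

#' Read a grayscale raster from disk
#'
#' Reads a PNG or TIFF raster as a single-channel [gray_image]. Multi-channel
#' input is reduced by averaging the channels (thermal exports are frequently
#' saved as replicated RGB). Sample values are mapped linearly onto the
#' `[0, L-1]` integer range, so 16-bit input is rescaled to 8-bit by default.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param L number of levels for the returned image (default 256).
#' @return A [gray_image].
#' @export
read_gray <- function(path, L = 256L) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path")
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported raster format '.", ext, "' for: ", path)
    ),
    error = function(e) stop("failed to read raster ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(arr) == 0L) stop("zero-sized image: ", path)
  if (length(dim(arr)) == 3L) {
    # average channels; ignore a 2nd (gray+alpha) or 4th (RGBA) alpha plane
    nc <- dim(arr)[3]
    keep <- if (nc %in% c(2L, 4L)) seq_len(nc - 1L) else seq_len(nc)
    arr <- apply(arr[, , keep, drop = FALSE], c(1, 2), mean)
  }
  # readers return values in [0,1]; quantize onto L levels
  gray_image(round_half_up(arr * (L - 1)), L = L)
}

#' Write a grayscale image or binary mask as PNG
#'
#' Masks (0/1 matrices or logical matrices) are written with foreground mapped
#' to 255 so they are viewable in any image viewer.
#'
#' @param img a [gray_image], or a binary 0/1 (or logical) matrix for masks.
#' @param path output path; format is always 8-bit grayscale PNG.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  if (is_gray_image(img)) {
    m <- img$pixels / (img$L - 1)
  } else if (is.matrix(img)) {
    v <- unique(as.vector(img))
    if (!all(v %in% c(0, 1)))
      stop("matrix input to write_gray must be binary (0/1)")
    m <- matrix(as.numeric(img), nrow(img), ncol(img))
  } else {
    stop("`img` must be a gray_image or a binary matrix")
  }
  png::writePNG(m, target = path)
  invisible(path)
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Normalize and requantize an image
#'
#' Divides by the image maximum and requantizes onto `L` uniformly spaced
#' levels, so the output maximum is always `L-1`. This is the normalization
#' step applied before histogram computation in the threshold search.
#'
#' @param img a [gray_image].
#' @return A [gray_image] with `max(pixels) == L - 1`.
#' @export
normalize_quantize <- function(img) {
  assert_gray_image(img)
  mx <- max(img$pixels)
  if (mx == 0L)
    stop("cannot normalize an all-zero image (division by max = 0)")
  gray_image(round_half_up(img$pixels / mx * (img$L - 1)), L = img$L)
}

#' Intensity histogram and probability distribution
#'
#' Counts pixels at every level `i` in `[0, L-1]` and normalizes the counts to
#' a probability mass function. All entropy objectives in the package are
#' functions of this distribution alone, so any spatial rearrangement of the
#' pixels leaves them unchanged.
#'
#' @param img a [gray_image].
#' @return An object of class `intensity_dist`: a list with `counts` (integer
#'   vector of length `L`, bin `i+1` holds the count of level `i`), `p`
#'   (probabilities summing to 1) and `L`.
#' @export
intensity_histogram <- function(img) {
  assert_gray_image(img)
  counts <- tabulate(as.vector(img$pixels) + 1L, nbins = img$L)
  structure(
    list(counts = counts, p = counts / sum(counts), L = img$L),
    class = "intensity_dist"
  )
}

#' Build an intensity distribution directly from probabilities
#'
#' Mainly useful for testing threshold search on arbitrary probability
#' vectors without materialising an image.
#'
#' @param p nonnegative numeric vector; normalised to sum to 1.
#' @return An `intensity_dist` (with `counts = NA`).
#' @export
dist_from_p <- function(p) {
  if (any(p < 0) || sum(p) <= 0) stop("`p` must be nonnegative with positive sum")
  structure(
    list(counts = rep(NA_integer_, length(p)), p = p / sum(p), L = length(p)),
    class = "intensity_dist"
  )
}

is_intensity_dist <- function(x) inherits(x, "intensity_dist")

assert_intensity_dist <- function(x) {
  if (!is_intensity_dist(x)) stop("expected an `intensity_dist` object")
  invisible(x)
}

#' @export
print.intensity_dist <- function(x, ...) {
  nz <- sum(x$p > 0)
  cat(sprintf("<intensity_dist L=%d, %d nonzero bins>\n", x$L, nz))
  invisible(x)
}
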