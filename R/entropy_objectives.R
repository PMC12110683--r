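#' Entropy objective configuration
#'
#' Bundles the objective choice and its parameters. Six objectives are
#' available for multilevel thresholding:
#'
#' * `a_entropy` — the adaptive tan-log entropy kernel
#'   `E_s = -sum_i (p_i/w_s + eps)^gamma * tan(log(p_i/w_s + eps))^gamma`
#'   evaluated per segment with natural logarithms (the package default);
#' * `shannon` — the Shannon entropy of the class-mass distribution: each
#'   segment contributes `-w_s log w_s` where `w_s` is its cumulative
#'   probability, so the total is maximal for mass-balanced partitions.
#'   (Summing the unnormalised within-segment entropies instead would be
#'   partition-invariant — the same value for every threshold tuple — and
#'   thus not an objective at all.);
#' * `tsallis` — within-segment Tsallis entropy of order `q`;
#' * `renyi` — within-segment Renyi entropy of order `alpha`;
#' * `kapur` — Shannon entropy of the segment-normalised distribution;
#' * `masi` — Masi entropy with flexibility parameter `r` (recovers Kapur as
#'   `r -> 1`).
#'
#' @param method one of `"a_entropy"`, `"shannon"`, `"tsallis"`, `"renyi"`,
#'   `"kapur"`, `"masi"`.
#' @param q Tsallis order (must differ from 1). Default 0.5.
#' @param alpha Renyi order (positive, different from 1). Default 2.
#' @param r Masi flexibility parameter (different from 1). Default 0.5.
#' @param gamma sensitivity exponent of the adaptive kernel. Default 1, the
#'   form executed by the segmentation pipeline.
#' @param eps shift constant added to the normalised probability ratio in the
#'   adaptive kernel; default 1, which confines the tangent argument to
#'   `(0, log 2]` (no poles) and makes zero-probability terms vanish exactly.
#' @param log_base base of the logarithm for the Shannon/Renyi/Kapur/Masi
#'   objectives, `2` (bits, default) or `exp(1)`. The adaptive kernel always
#'   uses natural logarithms.
#' @param ratio_floor optional lower floor applied to the probability ratio in
#'   the adaptive kernel before the tan-log evaluation; `NULL` (default)
#'   disables it. Intended only for robustness experiments.
#' @return A list of class `entropy_config`.
#' @export
entropy_config <- function(method = c("a_entropy", "shannon", "tsallis",
                                      "renyi", "kapur", "masi"),
                           q = 0.5, alpha = 2, r = 0.5,
                           gamma = 1, eps = 1, log_base = 2,
                           ratio_floor = NULL) {
  method <- match.arg(method)
  if (method == "tsallis" && q == 1)
    stop("Tsallis order q = 1 is the Shannon limit; use method = 'shannon'")
  if (method == "renyi" && (alpha == 1 || alpha <= 0))
    stop("Renyi order must be positive and different from 1; use 'shannon' for alpha = 1")
  if (method == "masi" && r == 1)
    stop("Masi parameter r = 1 is the Kapur limit; use method = 'kapur'")
  if (eps <= 0) stop("`eps` must be positive")
  if (gamma <= 0) stop("`gamma` must be positive")
  if (!log_base %in% c(2, exp(1))) stop("`log_base` must be 2 or exp(1)")
  structure(
    list(method = method, q = q, alpha = alpha, r = r, gamma = gamma,
         eps = eps, log_base = log_base, ratio_floor = ratio_floor),
    class = "entropy_config"
  )
}

#' Shannon entropy of a probability vector
#'
#' `-sum p_i log p_i`, with zero-probability terms contributing 0.
#'
#' @param p nonnegative probability vector (sum at most 1 + 1e-12).
#' @param log_base logarithm base, default 2 (bits).
#' @return Scalar entropy.
#' @export
shannon_entropy <- function(p, log_base = 2) {
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (sum(p) > 1 + 1e-12) stop("probabilities sum to more than 1")
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log(p, base = log_base))
}

#' Tsallis entropy of order q
#'
#' `(1/(q-1)) * (1 - sum p_i^q)`. Recovers natural-log Shannon entropy as
#' `q -> 1`.
#'
#' @param p nonnegative probability vector.
#' @param q entropic order, `q != 1`.
#' @return Scalar entropy.
#' @export
tsallis_entropy <- function(p, q) {
  if (q == 1) stop("q = 1 is the Shannon limit; call shannon_entropy()")
  if (any(p < 0)) stop("probabilities must be nonnegative")
  (1 - sum(p[p > 0]^q)) / (q - 1)
}

#' Renyi entropy of order alpha
#'
#' `(1/(1-alpha)) * log sum p_i^alpha`. Recovers Shannon entropy as
#' `alpha -> 1`.
#'
#' @param p nonnegative probability vector.
#' @param alpha entropic order, positive and different from 1.
#' @param log_base logarithm base, default 2.
#' @return Scalar entropy.
#' @export
renyi_entropy <- function(p, alpha, log_base = 2) {
  if (alpha == 1) stop("alpha = 1 is the Shannon limit; call shannon_entropy()")
  if (alpha <= 0) stop("`alpha` must be positive")
  if (any(p < 0)) stop("probabilities must be nonnegative")
  log(sum(p[p > 0]^alpha), base = log_base) / (1 - alpha)
}

#' Construct a histogram segment
#'
#' A segment is a contiguous level range `[lo, hi]` (inclusive, 0-based level
#' indices) with its cumulative probability weight.
#'
#' @param dist an `intensity_dist`.
#' @param lo,hi inclusive level bounds, `0 <= lo <= hi <= L-1`.
#' @return List with `lo`, `hi` and `omega` (the segment's probability mass).
#' @export
make_segment <- function(dist, lo, hi) {
  assert_intensity_dist(dist)
  if (lo < 0 || hi > dist$L - 1L || lo > hi)
    stop("invalid segment bounds [", lo, ", ", hi, "] for L = ", dist$L)
  list(lo = as.integer(lo), hi = as.integer(hi),
       omega = sum(dist$p[(lo + 1L):(hi + 1L)]))
}

seg_p <- function(dist, seg) dist$p[(seg$lo + 1L):(seg$hi + 1L)]

#' Kapur within-segment entropy
#'
#' Shannon entropy of the segment-normalised distribution:
#' `-sum (p_i/w) log(p_i/w)` over levels in the segment, where `w` is the
#' segment's cumulative probability. An empty segment (`w = 0`) scores 0.
#'
#' @param dist an `intensity_dist`.
#' @param seg a segment from [make_segment()].
#' @param log_base logarithm base, default 2.
#' @return Scalar entropy.
#' @export
kapur_segment_entropy <- function(dist, seg, log_base = 2) {
  if (seg$omega <= 0) return(0)
  pn <- seg_p(dist, seg) / seg$omega
  pn <- pn[pn > 0]
  -sum(pn * log(pn, base = log_base))
}

#' Masi within-segment entropy
#'
#' `(1/(1-r)) * log(1 - (1-r) * sum (p_i/w) log(p_i/w))`. The inner sum is the
#' negative of the Kapur entropy, so the `r -> 1` limit recovers
#' [kapur_segment_entropy()]. The expression is evaluated with natural
#' logarithms and the result expressed in `log_base` units (divided by
#' `log(log_base)`): this is the convention under which the Kapur recovery
#' holds in any base. For some distributions and `r` the outer log argument
#' can become nonpositive; this is reported as an error rather than silently
#' producing `NaN`.
#'
#' @inheritParams kapur_segment_entropy
#' @param r flexibility parameter, `r != 1`.
#' @return Scalar entropy.
#' @export
masi_segment_entropy <- function(dist, seg, r, log_base = 2) {
  if (r == 1) stop("r = 1 is the Kapur limit; call kapur_segment_entropy()")
  if (seg$omega <= 0) return(0)
  pn <- seg_p(dist, seg) / seg$omega
  pn <- pn[pn > 0]
  inner <- sum(pn * log(pn))  # natural log; = -Kapur entropy in nats
  arg <- 1 - (1 - r) * inner
  if (arg <= 0)
    stop("Masi entropy undefined (log argument ", format(arg),
         " <= 0) on segment [", seg$lo, ", ", seg$hi, "] with r = ", r)
  log(arg) / (1 - r) / log(log_base)
}

# distance from each value of x to the nearest pole of tan (odd multiples of pi/2)
tan_pole_distance <- function(x) {
  k <- round((x - pi / 2) / pi)
  abs(x - (pi / 2 + k * pi))
}

#' Adaptive tan-log segment entropy
#'
#' The package's central objective. For a segment with cumulative weight
#' `w > 0`, every nonzero level contributes
#' `-(p_i/w + eps)^gamma * tan(log(p_i/w + eps))^gamma` (natural log, radians);
#' `p_i/w` is the within-segment normalised probability, as in the Kapur
#' objective. Zero-probability levels are skipped (with `eps = 1` their terms
#' are exactly `-tan(log 1) = 0` anyway), and an empty segment scores 0.
#'
#' With the default `eps = 1` the shifted ratio lies in `[1, 2]`, so the
#' tangent argument stays inside `(0, log 2]`, far from any pole: the kernel
#' is bounded and smooth, and `tan^gamma` is well defined for fractional
#' `gamma` because the tangent is nonnegative. For small `eps`
#' (`eps < exp(-pi/2) ~ 0.208`) the argument can cross a tangent pole; ratios
#' whose log falls within `1e-12` of a pole raise an error naming the level
#' rather than returning an astronomically large value.
#'
#' @param dist an `intensity_dist`.
#' @param seg a segment from [make_segment()].
#' @param gamma sensitivity exponent, default 1.
#' @param eps shift constant, default 1.
#' @param ratio_floor optional floor on the normalised probability ratio
#'   before the shift (default `NULL`, disabled).
#' @return Scalar segment score (nonpositive for `eps >= 1`).
#' @export
a_entropy_segment <- function(dist, seg, gamma = 1, eps = 1,
                              ratio_floor = NULL) {
  if (eps <= 0) stop("`eps` must be positive")
  if (seg$omega <= 0) return(0)
  p <- seg_p(dist, seg)
  keep <- p > 0
  if (!any(keep)) return(0)
  ratio <- p[keep] / seg$omega
  if (!is.null(ratio_floor)) ratio <- pmax(ratio, ratio_floor)
  x <- ratio + eps
  lg <- log(x)
  near <- tan_pole_distance(lg) < 1e-12
  if (any(near)) {
    lev <- ((seg$lo):(seg$hi))[keep][which(near)[1]]
    stop("tan-log kernel hits a tangent pole at level ", lev,
         " (log argument = ", format(lg[which(near)[1]]), ")")
  }
  -sum(x^gamma * tan(lg)^gamma)
}

# vectorised single-segment score dispatch used by the search tables
segment_score <- function(dist, lo, hi, cfg) {
  seg <- make_segment(dist, lo, hi)
  switch(cfg$method,
    a_entropy = a_entropy_segment(dist, seg, cfg$gamma, cfg$eps, cfg$ratio_floor),
    shannon   = if (seg$omega <= 0) 0 else
                  -seg$omega * log(seg$omega, base = cfg$log_base),
    kapur     = kapur_segment_entropy(dist, seg, cfg$log_base),
    masi      = masi_segment_entropy(dist, seg, cfg$r, cfg$log_base),
    tsallis   = if (seg$omega <= 0) 0 else
                  tsallis_entropy(seg_p(dist, seg) / seg$omega, cfg$q),
    renyi     = if (seg$omega <= 0) 0 else
                  renyi_entropy(seg_p(dist, seg) / seg$omega, cfg$alpha, cfg$log_base)
  )
}

#' Total multilevel thresholding objective
#'
#' Partitions the level range `[0, L-1]` at the given thresholds into
#' contiguous segments `[0, t1], (t1, t2], ..., (tn, L-1]` and sums the
#' per-segment scores of the configured objective. This is the quantity the
#' threshold search maximises.
#'
#' @param dist an `intensity_dist`.
#' @param thresholds strictly increasing integer thresholds in `(0, L-1)`
#'   (i.e. between 1 and `L-2`); may be empty, in which case the whole range
#'   is a single segment.
#' @param cfg an [entropy_config()].
#' @return Scalar objective value.
#' @export
total_objective <- function(dist, thresholds, cfg = entropy_config()) {
  assert_intensity_dist(dist)
  thresholds <- as.integer(thresholds)
  if (length(thresholds)) {
    if (any(diff(thresholds) <= 0))
      stop("thresholds must be strictly increasing")
    if (thresholds[1] < 1L || thresholds[length(thresholds)] > dist$L - 2L)
      stop("thresholds must lie strictly inside (0, L-1)")
  }
  bounds <- c(-1L, thresholds, dist$L - 1L)
  total <- 0
  for (j in seq_len(length(bounds) - 1L)) {
    total <- total + segment_score(dist, bounds[j] + 1L, bounds[j + 1L], cfg)
  }
  total
}
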