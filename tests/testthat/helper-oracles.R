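# shared helpers: independent oracles and small fixtures built in code

# independent per-segment score using only the exported single-segment
# operations (unit-tested against hand values elsewhere)
oracle_segment_score <- function(dist, lo, hi, cfg) {
  seg <- make_segment(dist, lo, hi)
  if (seg$omega <= 0) return(0)
  pn <- dist$p[(lo + 1):(hi + 1)]
  switch(cfg$method,
    a_entropy = a_entropy_segment(dist, seg, cfg$gamma, cfg$eps),
    shannon   = -seg$omega * log(seg$omega, base = cfg$log_base),
    kapur     = kapur_segment_entropy(dist, seg, cfg$log_base),
    masi      = masi_segment_entropy(dist, seg, cfg$r, cfg$log_base),
    tsallis   = tsallis_entropy(pn / seg$omega, cfg$q),
    renyi     = renyi_entropy(pn / seg$omega, cfg$alpha, cfg$log_base)
  )
}

# brute-force threshold search: enumerate every strictly increasing tuple,
# skip tuples carving out an empty class, keep the first strict maximiser
oracle_search <- function(dist, k, cfg) {
  L <- dist$L
  tab <- matrix(NA_real_, L, L)
  for (lo in 0:(L - 1)) for (hi in lo:(L - 1))
    tab[lo + 1, hi + 1] <- oracle_segment_score(dist, lo, hi, cfg)
  cw <- c(0, cumsum(dist$p))
  best <- -Inf; best_thr <- NULL
  for (tup in asplit(t(utils::combn(1:(L - 2), k)), 1)) {
    lo <- c(0L, tup + 1L); hi <- c(tup, L - 1L)
    if (any(cw[hi + 2L] - cw[lo + 1L] <= 0)) next
    sc <- 0
    for (j in seq_along(lo)) sc <- sc + tab[lo[j] + 1L, hi[j] + 1L]
    if (sc > best) { best <- sc; best_thr <- as.integer(tup) }
  }
  list(values = best_thr, score = best)
}

# random PDF over L levels with a few empty bins, reproducible
random_pdf <- function(L, seed, n_empty = max(1L, L %/% 6L)) {
  set.seed(seed)
  p <- stats::runif(L)
  p[sample.int(L, n_empty)] <- 0
  dist_from_p(p)
}

# small deterministic test scene
tiny_scene <- function(seed = 1, ...) {
  make_scene(scene_spec(height = 64L, width = 64L, n_blobs = 2L,
                        blob_radius_range = c(4, 7), seed = seed, ...))
}

# image from an explicit pixel matrix
img_of <- function(m, L = 256L) gray_image(m, L = L)
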