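#' @title Threshold search over the entropy objective
#' @description Exact maximisation of a multilevel entropy objective over
#'   strictly increasing threshold tuples. Two equivalent search modes are
#'   provided: the literal nested-loop exhaustive search (feasible for up to
#'   three thresholds at 256 levels) and a dynamic program over precomputed
#'   per-segment scores with identical optimum and tie-breaking.
#' @name threshold_search
NULL

new_threshold_set <- function(values, score, cfg) {
  structure(
    list(values = as.integer(values), k = length(values),
         score = score, method = cfg$method),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set k=%d [%s], %s objective = %.6g>\n",
              x$k, paste(x$values, collapse = ", "), x$method, x$score))
  invisible(x)
}

# per-level plog and power prefix sums with zero bins contributing 0
.safe_plog <- function(p, base) ifelse(p > 0, p * log(p, base = base), 0)

# score all segments sharing a left endpoint under the adaptive kernel:
# given the probability slice p[lo..L-1] and its running weights, return the
# segment score for every right endpoint. Entry j corresponds to the segment
# of width j; empty segments (weight 0) score 0.
.a_entropy_running <- function(pseg, wv, gamma, eps, ratio_floor, where) {
  m <- length(pseg)
  pos <- pseg > 0
  wsafe <- ifelse(wv > 0, wv, 1)      # empty columns masked to 0 below
  x <- outer(pseg, 1 / wsafe)
  if (!is.null(ratio_floor)) x <- pmax(x, ratio_floor)
  x <- x + eps
  lg <- matrix(0, m, m)
  lg[pos, ] <- log(x[pos, , drop = FALSE])
  relevant <- pos & (row(lg) <= col(lg)) & rep(wv > 0, each = m)
  if (any(relevant & (tan_pole_distance(lg) < 1e-12)))
    stop("tan-log kernel hits a tangent pole while scoring segments (", where, ")")
  term <- -(x^gamma) * tan(lg)^gamma
  term[!pos, ] <- 0
  # running column sums: entry [j, j] is the full segment score for width j
  cs <- apply(term, 2L, cumsum)
  if (m == 1L) cs <- matrix(cs, 1L, 1L)
  out <- diag(cs)
  out[wv <= 0] <- 0
  out
}

#' Precompute all contiguous segment scores
#'
#' Builds the `L x L` upper-triangular table `S[lo+1, hi+1]` of per-segment
#' objective scores over every contiguous level range `[lo, hi]`, the
#' workhorse behind both search modes. Entries below the diagonal are `NA`.
#'
#' @param dist an `intensity_dist`.
#' @param cfg an [entropy_config()].
#' @return An `L x L` numeric matrix of segment scores.
#' @export
precompute_segment_scores <- function(dist, cfg = entropy_config()) {
  assert_intensity_dist(dist)
  L <- dist$L
  p <- dist$p
  S <- matrix(NA_real_, L, L)
  if (cfg$method == "a_entropy") {
    for (lo1 in seq_len(L)) {
      pseg <- p[lo1:L]
      wv <- cumsum(pseg)
      S[lo1, lo1:L] <- .a_entropy_running(pseg, wv, cfg$gamma, cfg$eps,
                                          cfg$ratio_floor,
                                          paste0("lo=", lo1 - 1L))
    }
    return(S)
  }
  # the remaining objectives decompose into prefix sums
  cw  <- c(0, cumsum(p))                              # cumulative mass
  cpl <- c(0, cumsum(.safe_plog(p, cfg$log_base)))    # cumulative p log p
  lo <- rep(seq_len(L), times = L)
  hi <- rep(seq_len(L), each = L)
  ok <- lo <= hi
  lo <- lo[ok]; hi <- hi[ok]
  w <- cw[hi + 1L] - cw[lo]
  B <- cpl[hi + 1L] - cpl[lo]
  val <- switch(cfg$method,
    shannon = ifelse(w > 0, -w * log(w, base = cfg$log_base), 0),
    kapur   = ifelse(w > 0, -B / w + log(w, base = cfg$log_base), 0),
    masi    = {
      cpln <- c(0, cumsum(.safe_plog(p, exp(1))))  # natural-log inner sum
      Bn <- cpln[hi + 1L] - cpln[lo]
      inner <- ifelse(w > 0, Bn / w - log(w), 0)
      arg <- 1 - (1 - cfg$r) * inner
      if (any(w > 0 & arg <= 0)) {
        bad <- which(w > 0 & arg <= 0)[1]
        stop("Masi entropy undefined on segment [", lo[bad] - 1L, ", ",
             hi[bad] - 1L, "] (log argument <= 0)")
      }
      ifelse(w > 0, log(arg) / (1 - cfg$r) / log(cfg$log_base), 0)
    },
    tsallis = {
      cq <- c(0, cumsum(p^cfg$q))
      Pq <- cq[hi + 1L] - cq[lo]
      ifelse(w > 0, (1 - Pq / w^cfg$q) / (cfg$q - 1), 0)
    },
    renyi   = {
      ca <- c(0, cumsum(p^cfg$alpha))
      Pa <- ca[hi + 1L] - ca[lo]
      ifelse(w > 0, log(Pa / w^cfg$alpha, base = cfg$log_base) / (1 - cfg$alpha), 0)
    }
  )
  S[cbind(lo, hi)] <- val
  S
}

# search table: per-segment scores plus -Inf on empty segments, so that
# threshold tuples carving out a class with no probability mass are
# infeasible (the within-class normalisation is undefined there). The
# plain score table keeps the empty-class-scores-0 reporting convention.
.search_table <- function(dist, cfg) {
  S <- precompute_segment_scores(dist, cfg)
  L <- dist$L
  cw <- c(0, cumsum(dist$p))
  W <- outer(-cw[1:L], cw[2:(L + 1L)], "+")  # mass of segment [lo, hi]
  Sx <- S
  Sx[!is.na(S) & W <= 0] <- -Inf
  list(S = S, Sx = Sx)
}

# left-to-right sum of segment scores for a threshold tuple, from the table
.tuple_score <- function(S, thr, L) {
  b <- c(0L, thr + 1L, L)  # 1-based segment starts plus sentinel
  tot <- 0
  for (j in seq_len(length(b) - 1L)) tot <- tot + S[b[j] + 1L, b[j + 1L]]
  tot
}

.check_search_pre <- function(dist, k, degenerate) {
  L <- dist$L
  if (k < 1L) stop("`k` must be at least 1")
  if (k > L - 2L) stop("`k` = ", k, " infeasible for L = ", L)
  if (sum(dist$p > 0) <= 1L) {
    if (degenerate == "error")
      stop("histogram has a single nonzero bin; no meaningful threshold exists ",
           "(set degenerate = 'lowest' for the lowest feasible tuple)")
    return(FALSE)
  }
  TRUE
}

#' Exhaustive threshold search
#'
#' Enumerates every strictly increasing tuple of `k` thresholds in
#' `(0, L-1)`, scores each by the summed per-segment objective and returns the
#' maximiser. Tuples that carve out a class with no probability mass are
#' infeasible (the within-class normalisation is undefined for an empty
#' class), so every class of the returned partition is guaranteed non-empty.
#' Enumeration is in ascending lexicographic order with a strict improvement
#' test, so on plateaus the lexicographically smallest maximising tuple is
#' returned. The running maximum is initialised at `-Inf`.
#'
#' @param dist an `intensity_dist`.
#' @param k number of thresholds (1 to 3 by default; larger `k` should use
#'   [search_thresholds_dp()]).
#' @param cfg an [entropy_config()].
#' @param max_k guard on the exhaustive enumeration size, default 3.
#' @param degenerate behaviour on single-bin histograms: `"error"` (default)
#'   or `"lowest"` (return thresholds `1..k`).
#' @return A `threshold_set` with elements `values`, `k`, `score`, `method`.
#' @export
search_thresholds <- function(dist, k, cfg = entropy_config(), max_k = 3L,
                              degenerate = c("error", "lowest")) {
  assert_intensity_dist(dist)
  degenerate <- match.arg(degenerate)
  k <- as.integer(k)
  if (k > max_k)
    stop("exhaustive search limited to k <= ", max_k,
         "; use search_thresholds_dp() for larger k")
  if (!.check_search_pre(dist, k, degenerate))
    return(new_threshold_set(seq_len(k), NA_real_, cfg))
  L <- dist$L
  tb <- .search_table(dist, cfg)
  S <- tb$S; Sx <- tb$Sx
  cand <- seq_len(L - 2L)  # threshold values 1 .. L-2
  best <- -Inf
  best_thr <- NULL
  if (k == 1L) {
    tot <- Sx[1L, cand + 1L] + Sx[cand + 2L, L]
    j <- which.max(tot)   # which.max keeps the first (smallest) maximiser
    if (is.finite(tot[j])) { best_thr <- cand[j]; best <- tot[j] }
  } else if (k == 2L) {
    for (a in cand[-length(cand)]) {
      b <- (a + 1L):(L - 2L)
      tot <- Sx[1L, a + 1L] + Sx[a + 2L, b + 1L] + Sx[b + 2L, L]
      j <- which.max(tot)
      if (tot[j] > best) { best <- tot[j]; best_thr <- c(a, b[j]) }
    }
  } else {
    for (a in 1:(L - 4L)) {
      pre <- Sx[1L, a + 1L]
      if (!is.finite(pre)) next
      for (b in (a + 1L):(L - 3L)) {
        mid <- Sx[a + 2L, b + 1L]
        if (!is.finite(mid)) next
        cc <- (b + 1L):(L - 2L)
        tot <- pre + mid + Sx[b + 2L, cc + 1L] + Sx[cc + 2L, L]
        j <- which.max(tot)
        if (tot[j] > best) { best <- tot[j]; best_thr <- c(a, b, cc[j]) }
      }
    }
  }
  if (is.null(best_thr) || !is.finite(best))
    stop("no feasible threshold tuple: fewer than k+1 = ", k + 1L,
         " occupied intensity levels")
  new_threshold_set(best_thr, .tuple_score(S, best_thr, L), cfg)
}

#' Dynamic-programming threshold search
#'
#' Computes the same optimum as [search_thresholds()] (including the
#' empty-class infeasibility rule) in `O(k L^2)` by a suffix dynamic program
#' over the precomputed segment-score table, then reconstructs the
#' lexicographically smallest maximising tuple. The returned score is
#' recomputed as the left-to-right sum of segment scores so the two modes
#' agree bit for bit on the same tuple.
#'
#' @inheritParams search_thresholds
#' @return A `threshold_set`.
#' @export
search_thresholds_dp <- function(dist, k, cfg = entropy_config(),
                                 degenerate = c("error", "lowest")) {
  assert_intensity_dist(dist)
  degenerate <- match.arg(degenerate)
  k <- as.integer(k)
  if (!.check_search_pre(dist, k, degenerate))
    return(new_threshold_set(seq_len(k), NA_real_, cfg))
  L <- dist$L
  tb <- .search_table(dist, cfg)
  S <- tb$S; Sx <- tb$Sx
  # B[j+1, s+1] = best score of j thresholds placed in (s, L-2], covering
  # levels s+1 .. L-1; s ranges over 0 .. L-2 (value of the previous threshold)
  ns <- L - 1L
  B <- matrix(-Inf, k + 1L, ns)
  s_idx <- 0:(L - 2L)
  B[1L, ] <- Sx[cbind(s_idx + 2L, L)]
  for (j in seq_len(k)) {
    # highest admissible threshold after s leaves room for j-1 more
    for (s in s_idx) {
      ts <- if (s + 1L <= L - 1L - j) (s + 1L):(L - 1L - j) else integer(0)
      if (!length(ts)) next
      v <- Sx[cbind(s + 2L, ts + 1L)] + B[j, ts + 1L]
      B[j + 1L, s + 1L] <- max(v)
    }
  }
  target <- {
    ts <- 1:(L - 1L - k)
    v <- Sx[cbind(1L, ts + 1L)] + B[k, ts + 1L]
    max(v)
  }
  if (!is.finite(target))
    stop("no feasible threshold tuple: fewer than k+1 = ", k + 1L,
         " occupied intensity levels")
  # greedy lexicographic reconstruction: stage by stage pick the smallest
  # threshold achieving the (exactly equal) optimal continuation
  thr <- integer(k)
  s <- -1L
  remaining <- target
  for (j in k:1) {
    ts <- max(s + 1L, 1L):(L - 1L - j)
    v <- Sx[cbind(s + 2L, ts + 1L)] + B[j, ts + 1L]
    pick <- ts[which(v == remaining)[1]]
    thr[k - j + 1L] <- pick
    remaining <- B[j, pick + 1L]
    s <- pick
  }
  new_threshold_set(thr, .tuple_score(S, thr, L), cfg)
}
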