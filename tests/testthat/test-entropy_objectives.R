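test_that("shannon entropy matches closed forms", {
  expect_equal(shannon_entropy(rep(1 / 256, 256)), 8)
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0)), 1)  # zero terms vanish
  expect_error(shannon_entropy(c(-0.1, 1.1)), "nonnegative")
})

test_that("tsallis and renyi entropies match closed forms and limits", {
  expect_equal(tsallis_entropy(c(0.5, 0.5), q = 2), 0.5)
  expect_equal(tsallis_entropy(1, q = 3), 0)
  expect_error(tsallis_entropy(c(0.5, 0.5), q = 1), "Shannon")
  expect_equal(renyi_entropy(c(0.5, 0.5), alpha = 2), 1)
  expect_equal(renyi_entropy(1, alpha = 2), 0)
  expect_error(renyi_entropy(c(0.5, 0.5), alpha = 1), "Shannon")

  # q, alpha -> 1 recovers Shannon on randomized PDFs
  set.seed(42)
  for (i in 1:10) {
    p <- stats::runif(20); p <- p / sum(p)
    hs_nat <- shannon_entropy(p, log_base = exp(1))
    expect_equal(tsallis_entropy(p, q = 1 + 1e-4), hs_nat, tolerance = 1e-3)
    expect_equal(renyi_entropy(p, alpha = 1 + 1e-4, log_base = 2),
                 shannon_entropy(p, log_base = 2), tolerance = 1e-3)
  }
})

test_that("kapur segment entropy behaves like within-class Shannon", {
  d <- dist_from_p(rep(0.25, 4))
  expect_equal(kapur_segment_entropy(d, make_segment(d, 0, 1)), 1)
  # degenerate class scores 0, empty class scores 0 by convention
  d2 <- dist_from_p(c(0.3, 0, 0, 0.7))
  expect_equal(kapur_segment_entropy(d2, make_segment(d2, 0, 2)), 0)
  expect_equal(kapur_segment_entropy(d2, make_segment(d2, 1, 2)), 0)
  # maximal for the uniform within-class distribution (enumeration, 3 levels)
  dun <- dist_from_p(c(1, 1, 1, 3) / 6)
  h_uni <- kapur_segment_entropy(dun, make_segment(dun, 0, 2))
  for (p1 in seq(0.05, 0.9, by = 0.05))
    for (p2 in seq(0.05, 0.95 - p1 + 1e-9, by = 0.05)) {
      dd <- dist_from_p(c(p1, p2, max(1 - p1 - p2, 1e-9), 1e-9))
      h <- kapur_segment_entropy(dd, make_segment(dd, 0, 2))
      expect_lte(h, h_uni + 1e-9)
    }
})

test_that("masi entropy recovers kapur as r -> 1 and flags bad arguments", {
  d <- dist_from_p(c(0.25, 0.25, 0.2, 0.3))
  seg <- make_segment(d, 0, 1)
  expect_equal(masi_segment_entropy(d, seg, r = 1 + 1e-6),
               kapur_segment_entropy(d, seg), tolerance = 1e-4)
  expect_equal(masi_segment_entropy(d, seg, r = 1 - 1e-6),
               kapur_segment_entropy(d, seg), tolerance = 1e-4)
  # degenerate segment scores 0 for any valid r
  dd <- dist_from_p(c(1, 0, 0, 0))
  expect_equal(masi_segment_entropy(dd, make_segment(dd, 0, 0), r = 0.5), 0)
  expect_equal(masi_segment_entropy(dd, make_segment(dd, 1, 3), r = 0.5), 0)
  # large r can push the outer log argument nonpositive -> explicit error
  du <- dist_from_p(rep(1 / 16, 16))
  expect_error(
    masi_segment_entropy(du, make_segment(du, 0, 15), r = 3),
    "undefined"
  )
})

test_that("adaptive tan-log kernel matches its closed form", {
  # constant image: single level with p = 1, within-class ratio 1
  d <- dist_from_p(c(0, 1, 0, 0))
  seg <- make_segment(d, 0, 3)
  expect_equal(a_entropy_segment(d, seg), -2 * tan(log(2)))
  # empty segment scores 0
  expect_equal(a_entropy_segment(d, make_segment(d, 2, 3)), 0)
  # two equal levels: each ratio 0.5, shifted to 1.5
  d2 <- dist_from_p(c(0.5, 0.5))
  expect_equal(a_entropy_segment(d2, make_segment(d2, 0, 1)),
               -2 * 1.5 * tan(log(1.5)))
  # gamma exponent applies to both factors
  expect_equal(a_entropy_segment(d2, make_segment(d2, 0, 1), gamma = 2),
               -2 * (1.5 * tan(log(1.5)))^2)
  # zero-probability levels are skipped / contribute nothing
  d3 <- dist_from_p(c(0.5, 0, 0.5, 0))
  expect_equal(a_entropy_segment(d3, make_segment(d3, 0, 3)),
               a_entropy_segment(d2, make_segment(d2, 0, 1)))
})

test_that("adaptive kernel is bounded for eps = 1 and flags pole crossings", {
  # with eps = 1 the tangent argument lives in (0, log 2]: always finite
  set.seed(7)
  for (i in 1:20) {
    p <- stats::runif(64); p[sample(64, 20)] <- 0
    d <- dist_from_p(p)
    v <- a_entropy_segment(d, make_segment(d, 0, 63))
    expect_true(is.finite(v))
    expect_lte(v, 0)
  }
  # a small eps puts log(ratio + eps) onto a tangent pole: ratio + eps = e^{-pi/2}
  pole_x <- exp(-pi / 2)
  eps <- 1e-3
  r1 <- pole_x - eps          # single-level ratio is 1 -> use two levels
  d <- dist_from_p(c(r1, 1 - r1))
  expect_error(a_entropy_segment(d, make_segment(d, 0, 1), eps = eps),
               "tangent pole")
})

test_that("total objective partitions correctly and validates thresholds", {
  d <- dist_from_p(rep(0.25, 4))
  cfg <- entropy_config(method = "kapur")
  # zero thresholds: score of the whole-range segment
  expect_equal(total_objective(d, integer(0), cfg),
               kapur_segment_entropy(d, make_segment(d, 0, 3)))
  # uniform over 4 levels: the mid split maximises Kapur
  scores <- sapply(1:2, function(t) total_objective(d, t, cfg))
  expect_equal(which.max(scores), 1L)  # t = 1 -> {0,1} vs {2,3}, 1 bit each
  expect_equal(scores[1], 2)
  expect_error(total_objective(d, c(2, 2), cfg), "strictly increasing")
  expect_error(total_objective(d, c(0), cfg), "strictly inside")
})

test_that("all objectives depend on the PDF only (shuffle invariance)", {
  sc <- tiny_scene(5)
  d0 <- intensity_histogram(sc$image)
  for (mode in c("row_wise", "column_wise", "full")) {
    dS <- intensity_histogram(shuffle_pixels(sc$image, mode, seed = 2))
    for (m in c("a_entropy", "shannon", "tsallis", "renyi", "kapur", "masi")) {
      cfg <- entropy_config(method = m)
      expect_identical(total_objective(d0, c(80, 160), cfg),
                       total_objective(dS, c(80, 160), cfg))
    }
  }
})
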