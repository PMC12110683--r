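test_that("adaptive gamma hits its analytic anchor points", {
  expect_equal(adaptive_gamma(127.5, 255), 1)
  expect_equal(adaptive_gamma(255, 255), exp(1))
  expect_equal(adaptive_gamma(0, 255), exp(-1))
  expect_error(adaptive_gamma(10, 0), "positive")
  expect_error(adaptive_gamma(-1, 255), "0, imax")
  # bounds hold over randomized means
  set.seed(3)
  for (mu in stats::runif(50, 0, 255)) {
    g <- adaptive_gamma(mu, 255)
    expect_gte(g, exp(-1)); expect_lte(g, exp(1))
  }
})

test_that("foreground mean averages pixels strictly above the threshold", {
  img <- img_of(matrix(c(10L, 20L, 200L, 240L), 2, 2))
  expect_equal(foreground_mean(img, 100), 220)
  expect_equal(foreground_mean(img, 5), mean(c(10, 20, 200, 240)))
  expect_error(foreground_mean(img, 250), "no pixel exceeds")
})

test_that("logit map is monotone with the documented range and anchor", {
  L <- 256L
  for (g in c(exp(-1), 0.7, 1, 1.8, exp(1))) {
    lut <- logit_map(g, rho = 1, L = L)
    expect_length(lut, L)
    expect_true(all(diff(lut) > 0))
    expect_equal(min(lut), 0)
    expect_equal(max(lut), 255)
  }
  # independently recompute the mapped mid level for gamma = 1:
  # f(x) = log(x / (1 - x + 1)), affinely rescaled over [0, 255]
  i <- 1:(L - 1); x <- i / (L - 1)
  f <- log(x / (1 - x + 1))
  f <- c(f[1] - (f[2] - f[1]), f)
  expect_equal(f[128], log((127 / 255) / (1 - 127 / 255 + 1)))
  expected <- (f - min(f)) / (max(f) - min(f)) * 255
  expect_equal(logit_map(1, 1, L), expected)
  # rho scales the pre-requantization range
  expect_equal(max(logit_map(1, 2, L)), 510)
})

test_that("enhancement preserves pixel ordering and records parameters", {
  sc <- tiny_scene(2)
  res <- enhance(normalize_quantize(sc$image))
  Y <- res$image
  I <- normalize_quantize(sc$image)
  ord <- order(as.vector(I$pixels))
  expect_true(all(diff(as.vector(Y$pixels)[ord]) >= 0))
  expect_true(all(c("mu", "gamma_phi", "rho", "mode", "lut") %in%
                  names(res$params)))
  expect_equal(res$params$mode, "foreground")
  expect_gte(res$params$gamma_phi, exp(-1))
  expect_lte(res$params$gamma_phi, exp(1))
})

test_that("distinct rho values yield distinct histogram supports", {
  sc <- tiny_scene(4)
  I <- normalize_quantize(sc$image)
  e_adapt <- enhance(I, rho = "adaptive")
  e_fixed <- enhance(I, rho = 2)
  s1 <- sort(unique(as.vector(e_adapt$image$pixels)))
  s2 <- sort(unique(as.vector(e_fixed$image$pixels)))
  expect_false(identical(s1, s2))
})

test_that("degenerate inputs error; global mode uses the global mean", {
  expect_error(enhance(img_of(matrix(0L, 4, 4))), "all-zero")
  expect_error(enhance(img_of(matrix(9L, 4, 4))), "constant image")
  expect_error(enhance(img_of(matrix(9L, 4, 4)), gamma_mode = "global"),
               "constant image")
  img <- img_of(matrix(c(40L, 80L, 120L, 255L), 2, 2))
  res <- enhance(img, gamma_mode = "global")
  expect_equal(res$params$mu, mean(img$pixels))
  # foreground mode falls back to the global mean when nothing exceeds T
  res2 <- enhance(img, gamma_mode = "foreground", threshold = 254L)
  expect_false(res2$params$fallback_global)
  res3 <- enhance(img_of(matrix(c(40L, 80L, 120L, 250L), 2, 2)),
                  gamma_mode = "foreground", threshold = 250L)
  expect_true(res3$params$fallback_global)
  expect_equal(res3$params$mu, mean(c(40, 80, 120, 250)))
})

test_that("clip requantization truncates while normalize rescales", {
  img <- img_of(matrix(seq(0L, 255L, length.out = 64), 8, 8))
  nrm <- enhance(img, rho = 2, requantize = "normalize")$image
  clp <- enhance(img, rho = 2, requantize = "clip")$image
  expect_equal(max(nrm$pixels), 255L)
  expect_equal(max(clp$pixels), 255L)
  # with rho = 2 clipping saturates far more pixels at the top
  expect_gt(sum(clp$pixels == 255L), sum(nrm$pixels == 255L))
})
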