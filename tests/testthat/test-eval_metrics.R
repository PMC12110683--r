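test_that("confusion counts match hand-enumerated masks", {
  gt <- matrix(c(1, 1, 0,
                 1, 0, 0,
                 0, 0, 0), 3, 3, byrow = TRUE)
  pred <- matrix(c(1, 0, 1,
                   1, 0, 0,
                   0, 0, 0), 3, 3, byrow = TRUE)
  cc <- confusion(pred, gt)
  expect_identical(unclass(cc)[c("TP", "FP", "FN", "TN")],
                   list(TP = 2L, FP = 1L, FN = 1L, TN = 5L))
  expect_identical(cc$TP + cc$FP + cc$FN + cc$TN, 9L)
  # identical and complementary masks
  expect_identical(confusion(gt, gt)$FP + confusion(gt, gt)$FN, 0L)
  inv <- confusion(1 - gt, gt)
  expect_identical(inv$TP + inv$TN, 0L)
  expect_error(confusion(pred[1:2, ], gt), "identical dimensions")
  expect_error(confusion(matrix(2, 3, 3), gt), "binary")
})

test_that("region metrics follow their printed formulas", {
  cc <- structure(list(TP = 2L, FP = 1L, FN = 1L, TN = 5L),
                  class = "confusion_counts")
  m <- region_metrics(cc)
  expect_equal(m$accuracy, 7 / 9)
  expect_equal(m$dsc, 2 / 3)
  expect_equal(m$iou, 1 / 2)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  # perfect prediction
  p <- region_metrics(structure(list(TP = 4L, FP = 0L, FN = 0L, TN = 5L),
                                class = "confusion_counts"))
  expect_true(all(unlist(p) == 1))
  # empty gt and empty pred: overlap metrics undefined, accuracy 1
  e <- region_metrics(structure(list(TP = 0L, FP = 0L, FN = 0L, TN = 9L),
                                class = "confusion_counts"))
  expect_equal(e$accuracy, 1)
  expect_true(is.na(e$dsc) && is.na(e$iou) && is.na(e$precision) &&
              is.na(e$recall))
})

test_that("dice and jaccard obey their algebraic identity", {
  set.seed(5)
  for (i in 1:1000) {
    cc <- structure(as.list(c(TP = sample(0:50, 1), FP = sample(0:50, 1),
                              FN = sample(0:50, 1), TN = sample(0:50, 1))),
                    class = "confusion_counts")
    m <- region_metrics(cc)
    if (!is.na(m$iou)) {
      expect_equal(m$dsc, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
      expect_gte(m$dsc, m$iou)
    }
    if (cc$FN == 0L && cc$TP > 0L) expect_equal(m$recall, 1)
  }
})

test_that("boundary F1 matches geometry on explicit masks", {
  sq <- function(r0, c0, side, M = 20, N = 20) {
    m <- matrix(0L, M, N)
    m[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- 1L
    m
  }
  a <- sq(5, 5, 8)
  expect_equal(bf_score(a, a, 2), 1)
  # 1-pixel shift is within a 2-pixel tolerance everywhere
  expect_equal(bf_score(sq(6, 5, 8), a, 2), 1)
  # far-apart boundaries score 0
  expect_equal(bf_score(sq(1, 1, 3), sq(15, 15, 3), 2), 0)
  # symmetry under swapping prediction and truth
  b <- sq(7, 6, 9)
  expect_equal(bf_score(a, b, 2), bf_score(b, a, 2))
  # both empty -> 1; one empty -> 0
  z <- matrix(0L, 20, 20)
  expect_equal(bf_score(z, z, 2), 1)
  expect_equal(bf_score(a, z, 2), 0)
})

test_that("boundary extraction counts the image border as background", {
  full <- matrix(1L, 5, 5)
  # every pixel of a full-frame mask touching the border is boundary;
  # a mask shifted fully inside has only its ring as boundary
  inner <- matrix(0L, 5, 5); inner[2:4, 2:4] <- 1L
  expect_equal(bf_score(full, full, 0), 1)
  # the full mask's boundary is its 16-pixel border ring, at distance 1
  # from the inner mask's ring -> all matched at tolerance 1
  expect_equal(bf_score(full, inner, 1.5), 1)
  expect_lt(bf_score(full, inner, 0.5), 1)
})

test_that("combined score is the stated convex combination", {
  expect_equal(combined_score(0.8, 0.6, 0.5), 0.7)
  expect_equal(combined_score(0.8, 0.6, 1), 0.8)
  expect_equal(combined_score(0.8, 0.6, 0), 0.6)
  expect_error(combined_score(0.5, 0.5, 1.2), "0, 1")
  rep <- evaluate_mask(matrix(c(1L, 0L, 0L, 1L), 2, 2),
                       matrix(c(1L, 0L, 1L, 1L), 2, 2))
  expect_equal(rep$cs, rep$wm * rep$dsc + (1 - rep$wm) * rep$bf)
})
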