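maskFrom <- function(cells, nr = 2L, nc = 2L) {
  m <- matrix(0L, nr, nc)
  for (p in cells) m[p[1], p[2]] <- 255L
  m
}

test_that("confusion counts enumerate pixels correctly", {
  pred <- maskFrom(list(c(1, 1), c(1, 2)))
  truth <- maskFrom(list(c(1, 1), c(2, 1)))
  cc <- confusionCounts(pred, truth)
  expect_identical(cc, list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  expect_identical(sum(unlist(cc)), 4L)
  samePix <- maskFrom(list(c(1, 1), c(2, 2)))
  cc2 <- confusionCounts(samePix, samePix)
  expect_identical(cc2$TP, 2L)
  expect_identical(cc2$FP + cc2$FN, 0L)
  empty <- matrix(0L, 2, 2)
  cc3 <- confusionCounts(empty, samePix)
  expect_identical(cc3$FN, 2L)
  expect_identical(cc3$TP + cc3$FP, 0L)
  expect_error(confusionCounts(empty, matrix(0L, 3, 3)), "differ")
})

test_that("jaccard and dice evaluate their defining ratios", {
  cc <- list(TP = 3L, FP = 1L, FN = 1L, TN = 10L)
  expect_equal(jaccardIndex(cc), 0.6)
  expect_equal(diceIndex(cc), 0.75)
  perfect <- list(TP = 5L, FP = 0L, FN = 0L, TN = 5L)
  expect_equal(jaccardIndex(perfect), 1)
  expect_equal(diceIndex(perfect), 1)
  disjoint <- list(TP = 0L, FP = 4L, FN = 4L, TN = 2L)
  expect_equal(jaccardIndex(disjoint), 0)
  expect_equal(diceIndex(disjoint), 0)
})

test_that("both-empty masks report 1 with a warning, or NaN on request", {
  cc <- list(TP = 0L, FP = 0L, FN = 0L, TN = 9L)
  expect_warning(j <- jaccardIndex(cc), "empty")
  expect_equal(j, 1)
  expect_true(is.nan(jaccardIndex(cc, emptyAs = "nan")))
  expect_true(is.nan(diceIndex(cc, emptyAs = "nan")))
})

test_that("the J = D/(2-D) identity and symmetry hold across random masks", {
  set.seed(31)
  for (trial in 1:20) {
    pred <- matrix(ifelse(runif(100) > 0.5, 255L, 0L), 10, 10)
    truth <- matrix(ifelse(runif(100) > 0.5, 255L, 0L), 10, 10)
    cc <- confusionCounts(pred, truth)
    j <- jaccardIndex(cc); d <- diceIndex(cc)
    expect_equal(j, d / (2 - d))
    ccSwap <- confusionCounts(truth, pred)
    expect_equal(jaccardIndex(ccSwap), j)
    expect_equal(diceIndex(ccSwap), d)
  }
})

test_that("converting a false negative to a true positive never hurts", {
  set.seed(32)
  truth <- matrix(ifelse(runif(64) > 0.4, 255L, 0L), 8, 8)
  pred <- truth
  miss <- which(truth == 255L)
  pred[miss[1:5]] <- 0L
  for (k in 1:5) {
    before <- confusionCounts(pred, truth)
    pred[miss[k]] <- 255L
    after <- confusionCounts(pred, truth)
    expect_gte(jaccardIndex(after), jaccardIndex(before))
    expect_gte(diceIndex(after), diceIndex(before))
  }
})

test_that("batch evaluation reports per-image rows plus means", {
  td <- withr::local_tempdir()
  truth <- maskFrom(list(c(1, 1), c(2, 1)), 4, 4)
  exact <- truth
  half <- maskFrom(list(c(1, 1)), 4, 4)    # TP=1 FN=1 -> J=0.5
  writeMaskImage(truth, file.path(td, "t1.png"))
  writeMaskImage(truth, file.path(td, "t2.png"))
  writeMaskImage(exact, file.path(td, "p1.png"))
  writeMaskImage(half, file.path(td, "p2.png"))
  rep <- evaluateBatch(file.path(td, c("p1.png", "p2.png")),
                       file.path(td, c("t1.png", "t2.png")),
                       ids = c("a", "b"),
                       reportPath = file.path(td, "report.csv"))
  expect_identical(rep$image_id, c("a", "b", "mean_jaccard", "mean_dice"))
  expect_equal(rep$jaccard[1:2], c(1, 0.5))
  expect_equal(rep$jaccard[3], 0.75)
  expect_equal(rep$dice[4], mean(c(1, 2 / 3)))
  csv <- utils::read.csv(file.path(td, "report.csv"))
  expect_equal(csv$jaccard[1:2], c(1, 0.5))
  # unreadable file lands in the error column and is excluded from means
  rep2 <- evaluateBatch(file.path(td, c("p1.png", "missing.png")),
                        file.path(td, c("t1.png", "t2.png")),
                        ids = c("a", "b"))
  expect_match(rep2$error[rep2$image_id == "b"], "no such file")
  expect_equal(rep2$jaccard[rep2$image_id == "mean_jaccard"], 1)
  # empty input produces an empty report without means
  expect_identical(nrow(evaluateBatch(character(0), character(0))), 0L)
})
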