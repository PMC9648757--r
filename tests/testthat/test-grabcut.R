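test_that("the automatic rectangle follows the truncating percentage rule", {
  r <- autoRect(430, 430)
  expect_identical(r$start, c(21L, 21L))
  expect_identical(r$end, c(400L, 400L))
  r2 <- autoRect(100, 100)
  expect_identical(r2$start, c(5L, 5L))
  expect_identical(r2$end, c(93L, 93L))
  r3 <- autoRect(20, 20)
  expect_identical(r3$start, c(1L, 1L))
  expect_identical(r3$end, c(19L, 19L))
  expect_error(autoRect(10, 10), "at least 20")
})

test_that("trimap initialization is background outside, unknown inside", {
  tm <- initTrimap(list(start = c(2L, 2L), end = c(8L, 8L)), 10L, 10L)
  expect_identical(sum(tm == 1L), 36L)
  expect_identical(sum(tm == 0L), 64L)
  expect_identical(sum(tm == 2L), 0L)   # hard foreground empty at init
  # unknown is exactly the complement of background
  expect_identical(sum(tm == 0L) + sum(tm == 1L), 100L)
})

test_that("min-cut solver agrees with an independent max-flow implementation", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (trial in 1:8) {
    src <- 11L; snk <- 12L
    edges <- t(utils::combn(10, 2))
    edges <- edges[sample(nrow(edges), 20), ]
    edges <- rbind(edges, cbind(src, 1:10), cbind(1:10, snk))
    caps <- runif(nrow(edges), 0.1, 5)
    g <- igraph::make_graph(t(edges), n = 12, directed = FALSE)
    mf <- igraph::max_flow(g, src, snk, capacity = caps)
    ref <- if (src %in% mf$partition1) mf$partition1 else mf$partition2
    side <- dermseg:::.dinicMinCut(edges[, 1], edges[, 2], caps, 12L,
                                   src, snk)
    expect_identical(sort(which(side)), sort(as.integer(ref)))
  }
})

test_that("a dark disk inside the rectangle is extracted almost exactly", {
  dd <- diskImage(80L)
  res <- segmentLesion(dd$image, details = TRUE)
  cc <- confusionCounts(res$mask, dd$truth)
  expect_gte(jaccardIndex(cc), 0.95)
  # energy after each cut never exceeds the energy before it
  expect_true(all(res$result@energyAfter <=
                  res$result@energyBefore + 1e-6))
})

test_that("segmentation is deterministic under a fixed seed", {
  dd <- diskImage(60L, radius = 14L, seed = 8L)
  m1 <- segmentLesion(dd$image)
  m2 <- segmentLesion(dd$image)
  expect_identical(m1, m2)
})

test_that("foreground never escapes the initialization rectangle", {
  dd <- diskImage(70L, radius = 30L)  # disk pokes past the rectangle
  res <- segmentLesion(dd$image, details = TRUE)
  outside <- matrix(TRUE, 70, 70)
  r <- res$rect
  outside[(r$start[1] + 1L):r$end[1], (r$start[2] + 1L):r$end[2]] <- FALSE
  expect_true(all(res$mask[outside] == 0L))
})

test_that("uniform images resolve to an empty mask", {
  img <- array(100L, c(40, 40, 3))
  expect_message(m <- segmentLesion(img), "degenerate")
  expect_true(all(m == 0L))
})

test_that("empty unknown regions are rejected", {
  img <- array(100L, c(30, 30, 3))
  expect_error(grabCutIterate(img, matrix(0L, 30, 30)), "unknown")
})
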