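test_that("outer contour stores the image corners for edge-touching borders", {
  g <- frameImage(435L, 12L)
  pts <- detectOuterContour(g)
  expect_equal(pts, rbind(c(0, 0), c(0, 434), c(434, 434), c(434, 0)))
})

test_that("outer contour is empty without sub-threshold corner components", {
  expect_identical(nrow(detectOuterContour(matrix(200L, 50, 50))), 0L)
  # dark blob in the middle does not touch a corner
  g <- matrix(200L, 50, 50)
  g[20:30, 20:30] <- 0L
  expect_identical(nrow(detectOuterContour(g)), 0L)
})

test_that("corner wedges report the four image corners", {
  g <- matrix(200L, 100, 100)
  r0 <- matrix(0:99, 100, 100)
  c0 <- t(r0)
  wedge <- (r0 + c0 < 20) | (r0 + (99 - c0) < 20) |
    ((99 - r0) + c0 < 20) | ((99 - r0) + (99 - c0) < 20)
  g[wedge] <- 0L
  pts <- detectOuterContour(g)
  expect_equal(pts, rbind(c(0, 0), c(0, 99), c(99, 99), c(99, 0)))
})

test_that("inner-corner walk matches the three-predecessor rule", {
  # diagonal gray levels 0,0,0,3,124,144 from the corner: the test at (5,5)
  # fails (144 and 124 are not below 4) and the walk advances until (3,3)
  g <- matrix(200L, 30, 30)
  diag(g)[1:4] <- c(0L, 0L, 0L, 3L)
  g[5, 5] <- 124L
  g[6, 6] <- 144L
  p <- findInnerCorner(g, borderConfig(), "TL")
  expect_true(p$found)
  expect_identical(c(p$row, p$col), c(3L, 3L))
  # walk test evaluated at (5,5) must reject: predecessors not sub-threshold
  expect_false(all(c(g[6, 6], g[5, 5], g[4, 4]) < 4L))
})

test_that("clean images report no inner corner", {
  p <- findInnerCorner(matrix(200L, 40, 40), borderConfig(), "TL")
  expect_false(p$found)
  expect_error(findInnerCorner(matrix(200L, 10, 10), borderConfig(), "TL"),
               "smaller")
})

test_that("synthetic TL border rows/cols 0-7 resolves to (7,7)", {
  g <- matrix(200L, 60, 60)
  g[1:8, 1:8] <- 0L
  p <- findInnerCorner(g, borderConfig(), "TL")
  expect_identical(c(p$row, p$col), c(7L, 7L))
})

test_that("frame thickness recovery matches the exhaustive diagonal oracle", {
  for (t in c(4L, 8L, 12L, 16L, 20L)) {
    g <- frameImage(120L, t)
    p <- findInnerCorner(g, borderConfig(), "TL")
    expect_true(p$found)
    expect_identical(c(p$row, p$col), c(t - 1L, t - 1L))
    expect_identical(oracleInnerTL(g), c(t - 1L, t - 1L))
    # all four orientations agree by symmetry of the frame
    for (ori in c("TR", "BL", "BR")) {
      q <- findInnerCorner(g, borderConfig(), ori)
      expect_true(q$found)
      expect_true(all(c(q$row, q$col) %in% c(t - 1L, 120L - t)))
    }
  }
})

test_that("detector exits after one search on borderless images", {
  rects <- detectInnerRectangle(matrix(200L, 80, 80))
  expect_false(rects@bordersPresent)
  expect_identical(rects@searches, 1L)
})

test_that("uniform 12-px frame yields the documented inner rectangle", {
  g <- frameImage(300L, 12L)
  rects <- detectInnerRectangle(g)
  expect_true(rects@bordersPresent)
  expect_identical(rects@searches, 4L)
  expect_equal(unname(rects@inner),
               rbind(c(11L, 11L), c(11L, 288L), c(288L, 11L), c(288L, 288L)))
})

test_that("missing corners default their sides to the image edge", {
  g <- matrix(200L, 100, 100)
  g[1:10, 1:10] <- 0L  # only the TL corner is dark
  rects <- detectInnerRectangle(g)
  expect_true(rects@bordersPresent)
  expect_identical(rects@found, c(TRUE, FALSE, FALSE, FALSE))
  img <- grayToRgb(g)
  res <- removeBorders(img, rects)
  # TL corner found at (9,9): crop keeps rows/cols 10..99
  expect_identical(res$offset, c(10L, 10L))
  expect_identical(dim(res$image)[1:2], c(90L, 90L))
})

test_that("border detachment crops bit-identically and re-embeds", {
  g <- frameImage(200L, 10L)
  img <- grayToRgb(g)
  rects <- detectInnerRectangle(g)
  res <- removeBorders(img, rects)
  expect_identical(dim(res$image)[1:2], c(180L, 180L))
  expect_identical(res$offset, c(10L, 10L))
  expect_identical(res$image, img[11:190, 11:190, , drop = FALSE])
  # full-coverage mask re-embeds with zeros exactly on the detached ring
  full <- matrix(255L, 180, 180)
  emb <- embedMask(full, res$offset, 200L, 200L)
  ring <- matrix(TRUE, 200, 200)
  ring[11:190, 11:190] <- FALSE
  expect_true(all(emb[ring] == 0L))
  expect_true(all(emb[!ring] == 255L))
})

test_that("borderless images pass through unchanged", {
  img <- grayToRgb(matrix(150L, 64, 64))
  rects <- detectInnerRectangle(rgbToGray(img))
  res <- removeBorders(img, rects)
  expect_identical(res$image, img)
  expect_identical(res$offset, c(0L, 0L))
})

test_that("border detection and removal is idempotent on clean frames", {
  g <- frameImage(150L, 8L)
  img <- grayToRgb(g)
  res1 <- removeBorders(img, detectInnerRectangle(g))
  rects2 <- detectInnerRectangle(rgbToGray(res1$image))
  expect_false(rects2@bordersPresent)
  res2 <- removeBorders(res1$image, rects2)
  expect_identical(res2$image, res1$image)
})

test_that("degenerate inner rectangles abort border removal", {
  g <- frameImage(41L, 20L)  # interior 1x1 after the strict crop
  img <- grayToRgb(g)
  expect_error(removeBorders(img, detectInnerRectangle(g)), "degenerate")
})
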