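test_that("closing difference responds on thin dark strokes only", {
  expect_true(all(hairContour(matrix(137L, 40, 40)) == 0L))
  # 2-px dark stroke on a bright field: response ~ bright - dark on the
  # stroke, zero far away
  g <- matrix(200L, 40, 40)
  g[, 20:21] <- 20L
  ct <- hairContour(g)
  expect_true(all(ct[, 20:21] == 180L))
  expect_true(all(ct[, c(1:8, 32:40)] == 0L))
  # structures wider than the element are untouched by closing
  gw <- matrix(200L, 60, 60)
  gw[, 20:45] <- 20L
  ctw <- hairContour(gw)
  expect_true(all(ctw[, 25:40] == 0L))
  expect_error(hairContour(matrix(1L, 5, 5)), "larger")
})

test_that("gray-level slicing maps 9 to 0 and 10 to 255", {
  m9 <- makeHairMask(matrix(9L, 3, 3))
  m10 <- makeHairMask(matrix(10L, 3, 3))
  expect_true(all(m9$mask == 0L))
  expect_false(m9$hairsPresent)
  expect_true(all(m10$mask == 255L))
  expect_true(m10$hairsPresent)
  m0 <- makeHairMask(matrix(0L, 4, 4))
  expect_true(all(m0$mask == 0L))
  expect_false(m0$hairsPresent)
})

test_that("inpainting weight terms follow the dir/dst/lev product", {
  # unit distance makes the geometric term exactly one
  expect_equal(inpaintWeight(c(5, 5), c(5, 4), 1, 1, c(0, 1)), 1)
  # equal arrival times make the level-set term exactly one
  w <- inpaintWeight(c(5, 5), c(3, 5), 2, 2, c(1, 0))
  expect_equal(w, 1 * (1 / 4) * 1)
  # q exactly along the normal at unit distance: directional term one
  expect_equal(inpaintWeight(c(5, 5), c(4, 5), 3, 2, c(1, 0)), 1 * 1 * 0.5)
  # opposite to the normal: clamped to zero
  expect_equal(inpaintWeight(c(5, 5), c(6, 5), 3, 2, c(1, 0)), 0)
  expect_error(inpaintWeight(c(5, 5), c(5, 5), 1, 1, c(1, 0)), "differ")
})

test_that("single holes are restored exactly on constant and linear images", {
  mask <- matrix(0L, 15, 15)
  mask[8, 8] <- 255L
  const <- array(120L, c(15, 15, 3))
  const[8, 8, ] <- 0L
  out <- inpaintTelea(const, mask)
  expect_identical(out[8, 8, ], c(120L, 120L, 120L))
  ramp <- array(0L, c(15, 15, 3))
  for (ch in 1:3) ramp[, , ch] <- matrix(rep(10L * (0:14) + 30L, each = 15),
                                         15, 15)
  expected <- ramp[8, 8, 1]
  ramp[8, 8, ] <- 0L
  out2 <- inpaintTelea(ramp, mask)
  expect_lte(max(abs(out2[8, 8, ] - expected)), 1)
})

test_that("inpainting modifies only masked pixels and stays in range", {
  set.seed(3)
  img <- array(sample(0:255, 30 * 30 * 3, TRUE), c(30, 30, 3))
  mask <- matrix(0L, 30, 30)
  mask[10:20, 14:16] <- 255L
  out <- inpaintTelea(img, mask)
  keep <- mask == 0L
  for (ch in 1:3) {
    expect_identical(out[, , ch][keep], img[, , ch][keep])
  }
  expect_true(all(out >= 0L & out <= 255L))
})

test_that("strokes over constant skin are filled to the skin level", {
  img <- array(180L, c(60, 60, 3))
  img[, 30:31, ] <- 30L
  hr <- removeHairs(img)
  expect_true(hr$hairsPresent)
  stroke <- hr$mask == 255L
  for (ch in 1:3) {
    expect_lte(max(abs(hr$image[, , ch][stroke] - 180L)), 2)
    expect_identical(hr$image[, , ch][!stroke], img[, , ch][!stroke])
  }
})

test_that("hair-free images skip inpainting bit-identically", {
  img <- array(150L, c(40, 40, 3))
  hr <- removeHairs(img)
  expect_false(hr$hairsPresent)
  expect_identical(hr$image, img)
})

test_that("re-running the contour on the inpainted image lowers the response", {
  fx <- generateFixture(fixtureSpec(seed = 5, height = 120, width = 120,
                                    hairs = TRUE))
  img <- fixtureImage(fx)
  before <- sum(hairContour(rgbToGray(img)))
  hr <- removeHairs(img)
  after <- sum(hairContour(rgbToGray(hr$image)))
  expect_lt(after, before)
})
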