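test_that("fixture generation is seed-deterministic and leaves the RNG alone", {
  spec <- fixtureSpec(seed = 4L, height = 96L, width = 96L,
                      borders = TRUE, hairs = TRUE)
  set.seed(777)
  before <- .Random.seed
  f1 <- generateFixture(spec)
  expect_identical(.Random.seed, before)
  f2 <- generateFixture(spec)
  expect_identical(fixtureImage(f1), fixtureImage(f2))
  expect_identical(lesionTruth(f1), lesionTruth(f2))
  # different seeds move the lesion
  f3 <- generateFixture(fixtureSpec(seed = 5L, height = 96L, width = 96L))
  expect_false(identical(lesionTruth(f1), lesionTruth(f3)))
})

test_that("fixtures honor their artifact contracts", {
  # borders off: nothing below the detection threshold on the corner diagonals
  clean <- generateFixture(fixtureSpec(seed = 1L, height = 96L, width = 96L))
  g <- rgbToGray(fixtureImage(clean))
  expect_true(all(diag(g)[1:21] >= 4L))
  expect_true(all(borderTruth(clean) == 0L))
  # borders on: every border-truth pixel below the threshold
  bordered <- generateFixture(fixtureSpec(seed = 1L, height = 96L, width = 96L,
                                          borders = TRUE,
                                          borderThickness = 10L))
  gb <- rgbToGray(fixtureImage(bordered))
  expect_true(all(gb[borderTruth(bordered) == 255L] < 4L))
  expect_true(all(lesionTruth(bordered)[borderTruth(bordered) == 255L] == 0L))
  # hairs darker than the local skin
  hairy <- generateFixture(fixtureSpec(seed = 1L, height = 96L, width = 96L,
                                       hairs = TRUE))
  gh <- rgbToGray(fixtureImage(hairy))
  hairPx <- hairTruth(hairy) == 255L
  expect_gt(sum(hairPx), 0)
  expect_lt(mean(gh[hairPx]), mean(gh[!hairPx]) - 50)
})

test_that("thickness-10 borders are recovered by the corner detector", {
  fx <- generateFixture(fixtureSpec(seed = 6L, height = 120L, width = 120L,
                                    borders = TRUE, borderThickness = 10L))
  rects <- detectInnerRectangle(rgbToGray(fixtureImage(fx)))
  expect_true(rects@bordersPresent)
  expect_lte(max(abs(rects@inner[1, ] - c(9L, 9L))), 1L)
})

test_that("suites round-trip through their manifest", {
  td <- withr::local_tempdir()
  base <- fixtureSpec(seed = 10L, height = 64L, width = 64L, hairs = TRUE)
  man <- generateSuite(3, base, td)
  expect_identical(nrow(man), 3L)
  expect_identical(man$seed, 10:12)
  expect_true(all(file.exists(file.path(td, man$image))))
  expect_identical(length(list.files(td)), 13L)  # 3 x 4 rasters + manifest
  specs <- readManifest(file.path(td, "manifest.txt"))
  expect_identical(length(specs), 3L)
  rebuilt <- generateFixture(specs[["fixture_011"]])
  expect_identical(fixtureImage(rebuilt),
                   readImageRGB(file.path(td, "fixture_011_image.png")))
})

test_that("distinct seeds give distinct lesion centroids", {
  cents <- sapply(0:7, function(s) {
    tr <- lesionTruth(generateFixture(fixtureSpec(seed = s, height = 72L,
                                                  width = 72L)))
    idx <- which(tr == 255L, arr.ind = TRUE)
    colMeans(idx)
  })
  expect_identical(nrow(unique(t(cents))), 8L)
})

test_that("invalid specs are rejected", {
  expect_error(fixtureSpec(height = 8L), "32")
  expect_error(fixtureSpec(borders = TRUE, borderIntensity = 9L), "threshold")
  expect_error(fixtureSpec(borders = TRUE, borderThickness = 30L), "4, 20")
  expect_error(fixtureSpec(hairs = TRUE, hairWidth = 7L), "1, 3")
})
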