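test_that("blank and sub-resolution images give empty tables, not errors", {
  blank <- surfaceImage(matrix(0, 64, 64))
  expect_identical(nrow(patchData(segmentPatches(blank))), 0L)

  ## a 3-pixel speck at 0.032 um/pixel is ~0.003 um^2, below the 0.02 um^2
  ## structured-illumination resolution filter
  m <- matrix(0, 64, 64)
  m[30, 30:32] <- 1
  expect_identical(nrow(patchData(segmentPatches(surfaceImage(m)))), 0L)

  expect_error(segmentPatches(surfaceImage(matrix(2, 8, 8))), "constant")
})

test_that("a planted blurred band is recovered with pixel-level length and degree-level pitch accuracy", {
  g <- genSurfaceImage(data.frame(length = 0.3, pitch = 80, intensity = 1),
                       imageSize = 128L, seed = 5)
  tab <- patchData(segmentPatches(g$image))
  expect_identical(nrow(tab), 1L)
  expect_lt(abs(tab$length - 0.3), 0.032)
  expect_lt(abs(tab$pitch - 80), 3)
})

test_that("segmentation is invariant to global intensity scaling and deterministic", {
  g <- genSurfaceImage(data.frame(length = c(0.25, 0.4), pitch = c(70, 85),
                                  intensity = 1), imageSize = 128L, seed = 9)
  a <- segmentPatches(g$image)
  scaled <- surfaceImage(g$image@intensity * 7.3,
                         pixelSize = g$image@pixelSize,
                         cellID = g$image@cellID)
  b <- segmentPatches(scaled)
  expect_equal(patchData(a), patchData(b), tolerance = 1e-12)
  expect_identical(patchData(a), patchData(segmentPatches(g$image)))
})

test_that("lengths are preserved and pitches complemented under axis transposition", {
  g <- genSurfaceImage(data.frame(length = 0.35, pitch = 25, intensity = 1),
                       imageSize = 128L, seed = 13)
  a <- patchData(segmentPatches(g$image))
  flipped <- surfaceImage(t(g$image@intensity),
                          pixelSize = g$image@pixelSize)
  b <- patchData(segmentPatches(flipped))
  expect_equal(b$length, a$length, tolerance = 1e-9)
  expect_equal(b$pitch, 90 - a$pitch, tolerance = 1e-9)
})

test_that("region moments agree with an independent image-analysis implementation", {
  g <- genSurfaceImage(data.frame(length = c(0.3, 0.2), pitch = c(40, 75),
                                  intensity = 1), imageSize = 128L, seed = 17)
  tab <- patchData(segmentPatches(g$image))
  ## independent route: EBImage labelling + moment features on the same mask
  In <- g$image@intensity
  In <- (In - min(In)) / diff(range(In))
  lab <- EBImage::bwlabel(In > 0.5)
  f <- EBImage::computeFeatures.moment(lab)
  f <- f[order(f[, "m.cx"]), , drop = FALSE]
  tabO <- tab[order(tab$cx), ]
  ## the only systematic difference is the +1/12 single-pixel variance
  ## correction (regionprops convention) that the EBImage route omits
  expect_equal(tabO$length, unname(f[, "m.majoraxis"]) * g$image@pixelSize,
               tolerance = 0.02)
  ebPitch <- abs(unname(f[, "m.theta"])) * 180 / pi
  expect_equal(tabO$pitch, ebPitch, tolerance = 0.02)
})

test_that("Otsu thresholding is available as an alternative", {
  g <- genSurfaceImage(data.frame(length = 0.3, pitch = 60, intensity = 1),
                       imageSize = 128L, seed = 21)
  tab <- patchData(segmentPatches(g$image, method = "otsu"))
  expect_gte(nrow(tab), 1L)
})

test_that("pooled length distribution: percentile, small-n refusal, monotonicity", {
  mk <- function(lens) new("PatchTable",
                           patches = data.frame(area = 0.05, length = lens,
                                                pitch = 45, cx = 0, cy = 0,
                                                cellID = "c"),
                           minArea = 0.02)
  d <- lengthDistribution(mk(1:100 / 100))
  expect_identical(d$n, 100L)
  expect_equal(d$percentile, 0.9901, tolerance = 1e-3)

  expect_warning(small <- lengthDistribution(mk(1:50 / 50)), "refusing")
  expect_true(is.na(small$percentile))

  set.seed(31)
  lens <- rlnorm(2000, meanlog = log(0.2), sdlog = 0.4)
  d2 <- lengthDistribution(mk(lens))
  expect_equal(d2$percentile, qlnorm(0.99, log(0.2), 0.4), tolerance = 0.05)

  d3 <- lengthDistribution(list(mk(lens), mk(rep(5, 120))))
  expect_gte(d3$percentile, d2$percentile)
})

test_that("pooled pitch distribution reports mean and SEM with correct folding", {
  mk <- function(p) new("PatchTable",
                        patches = data.frame(area = 0.05, length = 0.2,
                                             pitch = p, cx = 0, cy = 0,
                                             cellID = "c"),
                        minArea = 0.02)
  all90 <- pitchDistribution(mk(rep(90, 40)))
  expect_equal(all90$mean, 90)
  expect_equal(all90$sem, 0)

  set.seed(41)
  d <- pitchDistribution(mk(pmin(90, pmax(0, rnorm(1500, 75, 5)))))
  expect_lt(abs(d$mean - 75), 3 * d$sem + 0.1)

  ## a band drawn at 100 degrees in image coordinates reports 80
  g <- genSurfaceImage(data.frame(length = 0.3, pitch = 100, intensity = 1),
                       imageSize = 128L, seed = 43)
  tab <- patchData(segmentPatches(g$image))
  expect_lt(abs(tab$pitch - 80), 3)
})

test_that("panel correlation machinery rejects degenerate summaries", {
  expect_error(mutantPanelCorrelation(c(2, 4, 6, 8, 10), rep(1, 5)), "constant")
  res <- mutantPanelCorrelation(c(2, 4, 6, 8, 10), c(5, 4, 3.2, 2, 1))
  expect_lt(res[["r"]], -0.9)
})
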