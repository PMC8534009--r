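flatStack <- function(value, n = 16, nz = 3, pixelSize = 0.5) {
  imageStack(array(value, dim = c(nz, n, n)), pixelSize = pixelSize)
}

test_that("stack projection takes per-column maxima", {
  one <- imageStack(matrix(1:12, 3, 4), pixelSize = 1)
  expect_equal(projectStack(one), matrix(1:12, 3, 4))

  set.seed(1)
  vox <- array(stats::runif(5 * 6 * 7), dim = c(5, 6, 7))
  expect_equal(projectStack(imageStack(vox, pixelSize = 1)),
               apply(vox, c(2, 3), max))
  expect_equal(projectStack(imageStack(vox, pixelSize = 1), "sum"),
               apply(vox, c(2, 3), sum))
  expect_error(projectStack(array(0, c(0, 2, 2))), "empty")
})

test_that("junction mosaic renders ridges at the ground-truth peak", {
  f <- simulateJunctionField(cellCount = 8, junctionAmplitude = 100,
                             backgroundLevel = 10, deficitFactor = 1,
                             noiseSd = 0, fieldPx = 96, seed = 2)
  img <- projectStack(f$stack)
  expect_equal(max(img), 110, tolerance = 1e-3)
  expect_equal(min(img), 10, tolerance = 0.05)

  fd <- simulateJunctionField(cellCount = 8, junctionAmplitude = 100,
                              backgroundLevel = 10, deficitFactor = 0.6,
                              noiseSd = 0, fieldPx = 96, seed = 2)
  expect_equal(max(projectStack(fd$stack)), 70, tolerance = 1e-3)

  # same seed -> byte-identical output
  f2 <- simulateJunctionField(cellCount = 8, junctionAmplitude = 100,
                              backgroundLevel = 10, deficitFactor = 1,
                              noiseSd = 0, fieldPx = 96, seed = 2)
  expect_identical(voxels(f$stack), voxels(f2$stack))
  expect_identical(f$segments, f2$segments)

  expect_error(simulateJunctionField(cellCount = 1), ">= 2")
})

test_that("profiles of a flat image are constant and peak at the value", {
  img <- matrix(7, 32, 32)
  segs <- data.frame(x0 = 8, y0 = 8, x1 = 24, y1 = 20)
  pr <- sampleJunctionProfiles(img, segs, pixelSize = 0.5)
  expect_true(all(abs(pr$profiles - 7) < 1e-12))
  expect_equal(pr$peaks, 7)
  expect_equal(subtractBackground(pr, img)$peaks, 0)
})

test_that("profile sampling is rotation invariant", {
  f <- simulateJunctionField(cellCount = 6, noiseSd = 0, fieldPx = 64,
                             seed = 4)
  img <- projectStack(f$stack)
  segs <- f$segments
  pr <- sampleJunctionProfiles(img, segs, pixelSize = 0.5)

  # rotate image and segments by 90 degrees: (x, y) -> (y, n + 1 - x),
  # i.e. imgR[n + 1 - x, y] = img[y, x]
  n <- nrow(img)
  imgR <- t(img)[n:1, , drop = FALSE]
  segsR <- data.frame(x0 = segs$y0, y0 = n + 1 - segs$x0,
                      x1 = segs$y1, y1 = n + 1 - segs$x1)
  prR <- sampleJunctionProfiles(imgR, segsR, pixelSize = 0.5)
  expect_equal(prR$peaks, pr$peaks, tolerance = 1e-10)
})

test_that("profile peaks agree with a dense resampling oracle", {
  f <- simulateJunctionField(cellCount = 8, noiseSd = 0, fieldPx = 96,
                             seed = 5)
  img <- projectStack(f$stack)
  segs <- f$segments[sqrt((f$segments$x1 - f$segments$x0)^2 +
                          (f$segments$y1 - f$segments$y0)^2) >= 2, ]
  pr <- sampleJunctionProfiles(img, segs, pixelSize = 0.5)
  for (i in seq_len(min(10, nrow(segs)))) {
    dense <- denseProfilePeak(img, segs[i, ], pixelSize = 0.5)
    expect_equal(pr$peaks[i], dense, tolerance = 0.01)
  }
})

test_that("background subtraction is shift invariant and uses the margin", {
  f <- simulateJunctionField(cellCount = 6, junctionAmplitude = 100,
                             backgroundLevel = 20, noiseSd = 0, fieldPx = 96,
                             seed = 6)
  img <- projectStack(f$stack)
  pr <- sampleJunctionProfiles(img, f$segments, pixelSize = 0.5)
  bg1 <- subtractBackground(pr, img)
  expect_equal(bg1$background, 20, tolerance = 0.2)

  prShift <- sampleJunctionProfiles(img + 50, f$segments, pixelSize = 0.5)
  bg2 <- subtractBackground(prShift, img + 50)
  expect_equal(bg2$peaks, bg1$peaks, tolerance = 1e-9)

  tiny <- matrix(1, 8, 8)
  prT <- sampleJunctionProfiles(tiny, data.frame(x0 = 1, y0 = 4, x1 = 8,
                                                 y1 = 4), pixelSize = 1)
  expect_error(subtractBackground(prT, tiny, marginUm = 50), "non-border")
})

test_that("normalization sets the control mean to one", {
  r <- normalizeToControl(c(0.6, 0.6, 0.6), c(1, 1, 1))
  expect_equal(r$meanDel, 0.6)
  expect_equal(r$meanWt, 1)
  set.seed(9)
  r2 <- normalizeToControl(stats::rlnorm(20), stats::rlnorm(20))
  expect_equal(mean(r2$normalizedWt), 1, tolerance = 1e-12)
  expect_error(normalizeToControl(numeric(0), 1), "non-empty")
})

test_that("excess kurtosis matches closed forms", {
  expect_equal(kurtosisExcess(c(-1, -1, 1, 1)), -2)
  set.seed(10)
  expect_lt(abs(kurtosisExcess(stats::rnorm(1e5))), 0.1)
  expect_equal(kurtosisExcess(stats::runif(2e5)), -1.2, tolerance = 0.05)
  expect_error(kurtosisExcess(c(1, 1, 1, 1)), "constant")
  expect_error(kurtosisExcess(1:3), "at least 4")
})

test_that("glycocalyx generator hits its ground-truth mean exactly", {
  st <- simulateEsgField(amplitude = 80, backgroundLevel = 5,
                         deficitFactor = 0.42, noiseSd = 0, seed = 3)
  expect_equal(mean(projectStack(st)), 5 + 80 * 0.42, tolerance = 1e-9)

  # no texture: uniform field, mean equals the value everywhere
  u <- simulateEsgField(amplitude = 60, deficitFactor = 1, noiseSd = 0,
                        textureAmp = 0, seed = 1)
  expect_true(all(abs(projectStack(u) - 60) < 1e-12))

  # noise-free field means identical across fields (different textures, same mean)
  m <- vapply(1:4, function(s)
    mean(projectStack(simulateEsgField(noiseSd = 0, seed = s))), numeric(1))
  expect_equal(max(m) - min(m), 0, tolerance = 1e-9)
})

test_that("glycocalyx quantification recovers group ratios", {
  wt <- lapply(1:3, function(i) lapply(1:2, function(f)
    simulateEsgField(deficitFactor = 1, noiseSd = 0, seed = 10 * i + f)))
  del42 <- lapply(1:3, function(i) lapply(1:2, function(f)
    simulateEsgField(deficitFactor = 0.42, noiseSd = 0, seed = 100 + 10 * i + f)))
  r <- esgFieldIntensity(wt, del42)
  expect_equal(100 * r$meanDel, 42, tolerance = 1e-6)

  same <- esgFieldIntensity(wt, wt)
  expect_equal(100 * same$meanDel, 100, tolerance = 1e-9)

  zero <- lapply(1:3, function(i)
    list(imageStack(array(0, c(2, 8, 8)), pixelSize = 5)))
  expect_equal(esgFieldIntensity(wt, zero)$meanDel, 0)
})

test_that("junction deficit is recovered end to end across deficits", {
  recoverDeficit <- function(d, seeds) {
    vals <- vapply(seeds, function(sd) {
      quantify <- function(deficit, s) {
        f <- simulateJunctionField(cellCount = 10, junctionAmplitude = 100,
                                   backgroundLevel = 10, deficitFactor = deficit,
                                   noiseSd = 5, fieldPx = 96, seed = s)
        img <- projectStack(f$stack)
        pr <- sampleJunctionProfiles(img, f$segments, pixelSize = 0.5)
        mean(subtractBackground(pr, img)$peaks)
      }
      quantify(d, sd) / quantify(1, sd + 5000)
    }, numeric(1))
    mean(vals)
  }
  seeds <- 1:20
  for (d in c(0.3, 0.5, 0.7, 1.0))
    expect_equal(recoverDeficit(d, seeds), d, tolerance = 0.05)
})

test_that("normalized outputs are invariant to global intensity scaling", {
  quantify <- function(img, segs) {
    pr <- sampleJunctionProfiles(img, segs, pixelSize = 0.5)
    mean(subtractBackground(pr, img)$peaks)
  }
  f1 <- simulateJunctionField(cellCount = 8, noiseSd = 3, fieldPx = 64, seed = 21)
  f2 <- simulateJunctionField(cellCount = 8, deficitFactor = 0.5, noiseSd = 3,
                              fieldPx = 64, seed = 22)
  i1 <- projectStack(f1$stack); i2 <- projectStack(f2$stack)
  base <- quantify(i2, f2$segments) / quantify(i1, f1$segments)
  scaled <- quantify(3.7 * i2, f2$segments) / quantify(3.7 * i1, f1$segments)
  expect_equal(scaled, base, tolerance = 1e-12)
})
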