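test_that("scale schedules follow the geometric rule and its guards", {
  expect_equal(defaultScales(BinaryMask(matrix(TRUE, 64, 64)), 2),
               c(1L, 2L, 4L, 8L, 16L, 32L))
  expect_equal(defaultScales(BinaryMask(matrix(TRUE, 81, 81)), 3),
               c(1L, 3L, 9L, 27L))
  expect_error(defaultScales(BinaryMask(matrix(TRUE, 3, 3)), 2), "too small")
  # a tight structure inside a large canvas is scheduled by its own extent
  z <- matrix(FALSE, 256, 256)
  z[100:131, 100:131] <- TRUE
  expect_equal(defaultScales(BinaryMask(z), 2), c(1L, 2L, 4L, 8L, 16L))
})

test_that("box counts obey the exact laws on analytic shapes", {
  sq <- genReferenceFractal("filled_square", 64)
  cv <- boxCount(sq)
  expect_equal(counts(cv), (64 / scales(cv))^2)

  one <- matrix(FALSE, 32, 32)
  one[7, 19] <- TRUE
  cv1 <- boxCount(BinaryMask(one), scales = c(1L, 2L, 4L, 8L))
  expect_equal(counts(cv1), rep(1, 4))
  expect_error(boxCount(BinaryMask(matrix(FALSE, 8, 8))), "empty")
})

test_that("box counting matches the brute-force tiling oracle", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(8:32, 1)
    z <- matrix(runif(n * n) < runif(1, 0.05, 0.6), n, n)
    if (!any(z)) z[sample(n, 1), sample(n, 1)] <- TRUE
    m <- BinaryMask(z)
    # nested chain: each scale divides the next (counts then nonincreasing)
    s1 <- sample(1:3, 1)
    ss <- unique(c(s1, s1 * sample(2:3, 1), s1 * 4))
    cv <- boxCount(m, scales = sort(ss))
    for (k in seq_along(cv@scales)) {
      expect_identical(as.integer(cv@counts[k]),
                       bruteBoxCount(z, cv@scales[k]))
    }
  }
})

test_that("box counting works volumetrically", {
  a <- array(TRUE, c(16, 16, 16))
  cv <- boxCount(BinaryMask(a), scales = c(1L, 2L, 4L, 8L))
  expect_equal(counts(cv), (16 / c(1, 2, 4, 8))^3)
  expect_equal(fdValue(fitFD(cv)), 3)
})

test_that("log-log regression recovers analytic dimensions exactly", {
  r <- fitFD(new("BoxCountCurve", scales = c(1L, 2L, 4L, 8L, 16L, 32L),
                 counts = c(4096, 1024, 256, 64, 16, 4)))
  expect_equal(fdValue(r), 2, tolerance = 1e-12)
  expect_equal(fdRSquared(r), 1)

  flat <- fitFD(new("BoxCountCurve", scales = c(1L, 2L, 4L),
                    counts = c(1, 1, 1)))
  expect_equal(fdValue(flat), 0)
  expect_equal(fdRSquared(flat), 1)

  carp <- genReferenceFractal("sierpinski_carpet", 5)
  rc <- fitFD(boxCount(carp, defaultScales(carp, 3)))
  expect_equal(fdValue(rc), log10(8) / log10(3), tolerance = 1e-7)
  expect_equal(fdRSquared(rc), 1)

  expect_error(fitFD(new("BoxCountCurve", scales = c(1L, 2L),
                         counts = c(4, 2))), "3 scales")
})

test_that("intercept is reported on the base-10 scale", {
  # N = 1000 * S^-1.5 exactly
  s <- c(1L, 4L, 16L)
  r <- fitFD(new("BoxCountCurve", scales = s, counts = 1000 * s^-1.5))
  expect_equal(fdValue(r), 1.5, tolerance = 1e-12)
  expect_equal(r@intercept, 3, tolerance = 1e-12)
})

test_that("aspect FD of one region propagates labels and handles emptiness", {
  asp <- extractAllAspects(genTumorMask(baseRadius = 30, seed = 2))
  res <- fdOfAspects(asp, region = "whole_tumor")
  expect_named(res, c("general", "boundary", "skeleton"))
  expect_equal(res$general@region, "whole_tumor")
  r2 <- vapply(res, fdRSquared, numeric(1))
  expect_true(all(r2 >= 0 & r2 <= 1))
  # the filled structure and its closed boundary scale cleanly; the skeleton
  # of a smooth disc is near-degenerate and its fit quality is not asserted
  expect_gt(r2[["general"]], 0.95)
  expect_gt(r2[["boundary"]], 0.95)
  df <- as.data.frame(res$boundary)
  expect_equal(df$aspect, "boundary")

  miss <- regionFD(BinaryMask(matrix(FALSE, 16, 16)), region = "enhanced_tumor")
  expect_true(all(is.na(vapply(miss, fdValue, numeric(1)))))
})

test_that("general and boundary FD of a space-filling region behave as a
           surface and a curve", {
  sq <- BinaryMask(matrix(TRUE, 256, 256))
  expect_equal(fdValue(boxCountFD(sq)), 2, tolerance = 1e-12)
  bfd <- fdValue(boxCountFD(extractBoundary(sq)))
  expect_gt(bfd, 0.85)
  expect_lt(bfd, 1.15)
})
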