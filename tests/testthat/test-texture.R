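test_that("8-bit quantization rescales min-max with half-up rounding", {
  img <- GrayImage(matrix(c(10, 20, 30, 99), 2, 2))
  msk <- BinaryMask(matrix(c(1, 1, 1, 0), 2, 2))
  q <- imageData(quantize8bit(img, msk))
  expect_equal(sort(q[maskData(msk)]), c(0, 128, 255))
  expect_equal(q[2, 2], 0)  # outside mask

  const <- quantize8bit(GrayImage(matrix(7, 4, 4)), BinaryMask(matrix(1, 4, 4)))
  expect_true(all(imageData(const) == 0))

  full <- matrix(rep(c(0, 100, 255), length.out = 16), 4, 4)
  qf <- quantize8bit(GrayImage(full), BinaryMask(matrix(1, 4, 4)))
  expect_identical(imageData(qf), full)
})

test_that("GLCM pair counting matches hand-enumerated examples", {
  # 2x2 image [[0,1],[0,1]] (row-major), offset one step right
  img <- GrayImage(matrix(c(0, 0, 1, 1), 2, 2))
  msk <- BinaryMask(matrix(TRUE, 2, 2))
  g <- computeGLCM(img, msk, offset = c(0, 1), symmetric = FALSE, levels = 2)
  expect_equal(g@matrix, matrix(c(0, 0, 1, 0), 2, 2))
  gs <- computeGLCM(img, msk, offset = c(0, 1), symmetric = TRUE, levels = 2)
  expect_equal(gs@matrix, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  const <- computeGLCM(GrayImage(matrix(0, 4, 4)), BinaryMask(matrix(1, 4, 4)),
                       levels = 4)
  expect_equal(const@matrix[1, 1], 1)
  expect_error(
    computeGLCM(GrayImage(matrix(0, 1, 1)), BinaryMask(matrix(1, 1, 1))),
    "offset|pairs")
})

test_that("GLCM equals brute-force pair enumeration on random images", {
  set.seed(31)
  for (i in 1:100) {
    L <- sample(c(4L, 8L), 1)
    vals <- matrix(sample(0:(L - 1), 64, replace = TRUE), 8, 8)
    msk <- matrix(runif(64) < 0.8, 8, 8)
    off <- list(c(0, 1), c(1, 0), c(1, 1), c(0, 2))[[sample(4, 1)]]
    sym <- sample(c(TRUE, FALSE), 1)
    if (sum(msk) < 4) next
    ref <- bruteGLCM(vals, msk, off, sym, L)
    if (any(is.nan(ref))) next
    g <- computeGLCM(GrayImage(vals), BinaryMask(msk), offset = off,
                     symmetric = sym, levels = L)
    expect_equal(g@matrix, ref)
  }
})

test_that("Haralick features match hand-evaluated sums", {
  degen <- new("GLCM", matrix = diag(c(1, 0)), levels = 2L,
               offset = c(0L, 1L), symmetric = FALSE)
  fd <- glcmFeatures(degen)
  expect_equal(unname(fd[c("asm", "contrast", "idm", "entropy")]),
               c(1, 0, 1, 0))
  expect_true(is.na(fd["correlation"]))

  anti <- new("GLCM", matrix = matrix(c(0, 0.5, 0.5, 0), 2, 2), levels = 2L,
              offset = c(0L, 1L), symmetric = TRUE)
  fa <- glcmFeatures(anti)
  expect_equal(unname(fa["asm"]), 0.5)
  expect_equal(unname(fa["contrast"]), 1)
  expect_equal(unname(fa["idm"]), 0.5)
  expect_equal(unname(fa["correlation"]), -1)
  expect_equal(unname(fa["entropy"]), log(2))

  unif <- new("GLCM", matrix = matrix(1 / 16, 4, 4), levels = 4L,
              offset = c(0L, 1L), symmetric = FALSE)
  fu <- glcmFeatures(unif)
  expect_equal(unname(fu["asm"]), 1 / 16)
  expect_equal(unname(fu["entropy"]), log(16))
})

test_that("feature ranges hold on random GLCMs and entropy peaks at uniform", {
  set.seed(32)
  for (i in 1:50) {
    L <- sample(3:6, 1)
    p <- matrix(rexp(L * L), L, L)
    p <- p / sum(p)
    f <- glcmFeatures(new("GLCM", matrix = p, levels = as.integer(L),
                          offset = c(0L, 1L), symmetric = FALSE))
    expect_gt(f[["asm"]], 0); expect_lte(f[["asm"]], 1)
    expect_gt(f[["idm"]], 0); expect_lte(f[["idm"]], 1)
    expect_gte(f[["contrast"]], 0)
    expect_gte(f[["entropy"]], 0)
    expect_lte(f[["entropy"]], log(L^2) + 1e-12)
    if (!is.na(f[["correlation"]])) {
      expect_gte(f[["correlation"]], -1)
      expect_lte(f[["correlation"]], 1)
    }
  }
})

test_that("region texture composes the full path and tolerates empty regions", {
  mk <- genTumorMask(baseRadius = 25, size = 128, seed = 8)
  img <- genTexturedRegion(mk, contrastLevel = 2, noiseSd = 1, seed = 9)
  tx <- regionTexture(img, mk)
  expect_named(tx, c("asm", "contrast", "idm", "correlation", "entropy"))
  expect_true(all(is.finite(tx)))

  empty <- regionTexture(img, BinaryMask(matrix(FALSE, 128, 128)))
  expect_true(all(is.na(empty)))
  # 1-pixel region: no valid pairs, missing record rather than an error
  one <- matrix(FALSE, 128, 128)
  one[5, 5] <- TRUE
  expect_true(all(is.na(regionTexture(img, BinaryMask(one)))))
})
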