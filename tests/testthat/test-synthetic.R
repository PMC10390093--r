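test_that("reference fractals have the analytic self-similar counts", {
  sq <- genReferenceFractal("filled_square", 64)
  expect_equal(nVoxels(sq), 4096L)
  cv <- boxCount(sq, scales = c(1L, 2L, 4L, 8L, 16L, 32L, 64L))
  expect_equal(counts(cv), (64 / scales(cv))^2)

  carp <- genReferenceFractal("sierpinski_carpet", 4)
  expect_identical(dim(carp), c(81L, 81L))
  expect_equal(nVoxels(carp), 8^4)
  cv3 <- boxCount(carp, scales = 3L^(0:3))
  expect_equal(cv3@counts, 8^(4:1))

  tri <- genReferenceFractal("sierpinski_triangle", 5)
  expect_identical(dim(tri), c(32L, 32L))
  expect_equal(nVoxels(tri), 3^5)
  cv2 <- boxCount(tri, scales = 2L^(0:4))
  expect_equal(cv2@counts, 3^(5:1))
})

test_that("reference fractal generation is guarded", {
  expect_error(genReferenceFractal("sierpinski_carpet", 9), "maximum")
  expect_error(genReferenceFractal("filled_square", 0), "depthOrSize")
  expect_error(genReferenceFractal("blob", 4))
})

test_that("tumor masks are deterministic, connected, and smooth at zero roughness", {
  m1 <- genTumorMask(baseRadius = 40, seed = 42)
  m2 <- genTumorMask(baseRadius = 40, seed = 42)
  expect_identical(maskData(m1), maskData(m2))
  expect_equal(countComponents(m1), 1L)

  mb <- genTumorMask(baseRadius = 40, roughnessAmplitude = 0.5,
                     nBranches = 5, branchLength = 25, seed = 3)
  expect_equal(countComponents(mb), 1L)
  expect_false(identical(maskData(m1), maskData(mb)))

  # smooth-curve limit: boundary of an amplitude-0 mask is close to a circle
  fdSmooth <- fdValue(boxCountFD(extractBoundary(m1)))
  expect_gt(fdSmooth, 0.8)
  expect_lt(fdSmooth, 1.15)
})

test_that("boundary roughness raises boundary FD", {
  fdAt <- function(amp, seed)
    fdValue(boxCountFD(extractBoundary(
      genTumorMask(baseRadius = 40, roughnessAmplitude = amp,
                   roughnessFrequency = 16, seed = seed))))
  f0 <- fdAt(0, 1)
  f6 <- fdAt(0.6, 1)
  expect_gt(f6, f0)
})

test_that("tumor mask parameter validation rejects bad shapes", {
  expect_error(genTumorMask(baseRadius = -2), "positive")
  expect_error(genTumorMask(roughnessAmplitude = 1.4), "roughnessAmplitude")
  expect_error(genTumorMask(roughnessFrequency = 0), "roughnessFrequency")
})

test_that("textured regions are deterministic and respond to contrast level", {
  mk <- genTumorMask(baseRadius = 30, size = 128, seed = 5)
  flat <- genTexturedRegion(mk, contrastLevel = 0, noiseSd = 0, seed = 1)
  inside <- imageData(flat)[maskData(mk)]
  expect_true(all(inside == inside[1]))
  expect_true(all(imageData(flat)[!maskData(mk)] == 0))
  tf <- regionTexture(flat, mk)
  expect_equal(unname(tf["contrast"]), 0)
  expect_equal(unname(tf["asm"]), 1)

  lo <- genTexturedRegion(mk, contrastLevel = 0.5, noiseSd = 0, seed = 7)
  hi <- genTexturedRegion(mk, contrastLevel = 5, noiseSd = 0, seed = 7)
  expect_identical(imageData(lo),
                   imageData(genTexturedRegion(mk, 0.5, 0, seed = 7)))
  expect_gt(regionTexture(hi, mk)["contrast"], regionTexture(lo, mk)["contrast"])
})

test_that("cohorts satisfy the region containment and disjointness invariants", {
  co <- genCohort(3, 3, seed = 21, size = 128)
  expect_equal(nSubjects(co), 6L)
  for (s in cohortSubjects(co)) {
    expect_setequal(names(s$masks),
                    c("whole_tumor", "enhanced_tumor", "edema", "gm", "wm"))
    wt <- maskData(s$masks$whole_tumor)
    expect_false(any(maskData(s$masks$enhanced_tumor) & !wt))
    expect_false(any(maskData(s$masks$edema) & !wt))
    expect_false(any(maskData(s$masks$gm) & wt))
    expect_false(any(maskData(s$masks$wm) & wt))
    expect_length(s$images, 5L)
  }
})

test_that("default cohort sizes follow the study design and are reproducible", {
  co <- genCohort(seed = 7, textures = FALSE)
  labs <- vapply(cohortSubjects(co), function(s) s$label, character(1))
  expect_equal(sum(labs == "LGG"), 27L)
  expect_equal(sum(labs == "HGG"), 15L)
  # any subject is reproducible in isolation from its recorded sub-seed
  s5 <- cohortSubjects(co)[[5]]
  again <- fracmorph:::simulateSubject(s5$id, s5$label,
                                       cohortEffect()$lgg, cohortEffect()$shared,
                                       256L, s5$seed, textures = FALSE)
  expect_identical(maskData(s5$masks$whole_tumor),
                   maskData(again$masks$whole_tumor))
})

test_that("minimal and degenerate cohort requests are handled", {
  co <- genCohort(2, 2, seed = 1, size = 96, textures = FALSE)
  expect_equal(nSubjects(co), 4L)
  expect_error(genCohort(1, 5), "at least 2")
  bad <- cohortEffect()
  bad$hgg$radiusSd <- -1
  expect_error(genCohort(3, 3, effect = bad), "degenerate")
})
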