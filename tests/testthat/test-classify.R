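test_that("AUC equals the all-pairs probability with tie credit", {
  expect_equal(rocAUC(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(rocAUC(c(9, 8, 1, 2), c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_equal(rocAUC(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)),
               bruteAUC(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)))
  expect_error(rocAUC(1:4, rep(TRUE, 4)), "both classes")

  set.seed(51)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    sc <- sample(1:8, n, replace = TRUE)  # heavy ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(rocAUC(sc, pos), bruteAUC(sc, pos))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(52)
  sc <- rnorm(40)
  pos <- runif(40) < 0.4
  expect_equal(rocAUC(sc, pos),
               as.numeric(pROC::auc(pROC::roc(pos, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("widely separated clusters are classified perfectly", {
  set.seed(53)
  x <- matrix(c(rnorm(27), rnorm(15) + 10))
  lab <- rep(c("LGG", "HGG"), c(27, 15))
  r <- crossValidatedSVM(x, lab, kernel = "linear", seed = 2)
  expect_equal(r@accuracy, 100)
  expect_equal(r@auc, 100)
  expect_equal(r@sensitivity, 100)
  expect_equal(r@specificity, 100)
  expect_s4_class(r, "ClassificationReport")
})

test_that("label permutation yields chance-level AUC", {
  set.seed(54)
  aucs <- vapply(1:40, function(s) {
    x <- matrix(rnorm(42))
    lab <- sample(rep(c("LGG", "HGG"), c(27, 15)))
    crossValidatedSVM(x, lab, kernel = "linear", seed = s)@auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 50), 5)
})

test_that("standardization uses training-fold statistics only", {
  set.seed(55)
  x <- matrix(rnorm(42))
  lab <- rep(c("LGG", "HGG"), c(27, 15))
  splits <- fracmorph:::makeSplits(lab == "HGG", "repeated_split", 5L, 0.7, 9L)
  base <- fracmorph:::evalFold(x, lab == "HGG", splits[[1]], "linear", 1)
  # corrupt one test-fold subject with an extreme outlier: the fitted model
  # (trained and standardized without it) must classify the others the same
  x2 <- x
  victim <- splits[[1]]$test[1]
  x2[victim, 1] <- 1e6
  mod <- fracmorph:::evalFold(x2, lab == "HGG", splits[[1]], "linear", 1)
  # remove the victim entirely and compare per-subject agreement instead
  keepTest <- setdiff(splits[[1]]$test, victim)
  sp3 <- list(train = splits[[1]]$train, test = keepTest)
  a <- fracmorph:::evalFold(x, lab == "HGG", sp3, "linear", 1)
  b <- fracmorph:::evalFold(x2, lab == "HGG", sp3, "linear", 1)
  expect_equal(a, b)
  expect_false(is.null(base))
  expect_false(is.null(mod))
})

test_that("a duplicated feature column leaves the rbf report unchanged", {
  set.seed(56)
  x <- matrix(rnorm(42))
  lab <- rep(c("LGG", "HGG"), c(27, 15))
  a <- crossValidatedSVM(x, lab, kernel = "rbf", seed = 4)
  b <- crossValidatedSVM(cbind(x, x), lab, kernel = "rbf", seed = 4)
  expect_equal(a@foldMetrics, b@foldMetrics)
})

test_that("kernel selection shares folds and prefers the right kernel", {
  set.seed(57)
  x <- matrix(c(rnorm(27), rnorm(15) + 8))
  lab <- rep(c("LGG", "HGG"), c(27, 15))
  best <- selectBestKernel(x, lab, seed = 5)
  expect_equal(best@kernel, "linear")  # simplicity tie-break on a tie at 100

  xor <- matrix(runif(120, -1, 1), ncol = 2)
  xlab <- ifelse(xor[, 1] * xor[, 2] > 0, "HGG", "LGG")
  bx <- selectBestKernel(xor, xlab, seed = 6)
  expect_equal(bx@kernel, "rbf")

  expect_error(crossValidatedSVM(matrix(rnorm(2)), c("LGG", "HGG")),
               "at least 2")
})

test_that("stratified k-fold mode is available and deterministic", {
  set.seed(58)
  x <- matrix(c(rnorm(27), rnorm(15) + 6))
  lab <- rep(c("LGG", "HGG"), c(27, 15))
  r1 <- crossValidatedSVM(x, lab, seed = 3, mode = "kfold")
  r2 <- crossValidatedSVM(x, lab, seed = 3, mode = "kfold")
  expect_equal(r1@foldMetrics, r2@foldMetrics)
  expect_equal(r1@mode, "kfold")
  expect_equal(sum(vapply(
    fracmorph:::makeSplits(lab == "HGG", "kfold", 5L, 0.7, 3L),
    function(s) length(s$test), integer(1))), 42L)
})

test_that("rows with missing features are dropped with a message", {
  set.seed(59)
  x <- matrix(c(rnorm(27), rnorm(15) + 10))
  x[3, 1] <- NA
  lab <- rep(c("LGG", "HGG"), c(27, 15))
  expect_message(r <- crossValidatedSVM(x, lab, seed = 2), "dropped")
  expect_equal(r@accuracy, 100)
})
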