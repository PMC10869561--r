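test_that("ROC/AUC handles separation, ties, and the worked example", {
  expect_equal(rocAuc(c(2, 3), c(0, 1))$auc, 1)
  expect_equal(rocAuc(c(0, 1), c(2, 3))$auc, 0)
  expect_equal(rocAuc(c(1, 1, 1), c(1, 1))$auc, 0.5)   # all tied
  expect_equal(rocAuc(c(3, 1), c(2, 0))$auc, 0.75)
  expect_error(rocAuc(numeric(0), 1), "nonempty")
})

test_that("threshold-sweep AUC equals the Mann-Whitney statistic exactly", {
  for (s in 1:20) {
    set.seed(s)
    # coarse grid forces plenty of ties
    pos <- sample(0:5, 12, replace = TRUE) + rnorm(12, sd = ifelse(s %% 2, 0, 0.3))
    cand <- sample(0:5, 30, replace = TRUE)
    r <- rocAuc(pos, cand)
    expect_equal(r$auc, aucOracle(pos, cand), tolerance = 1e-12)
    # curve is a valid monotone ROC from (0,0) to (1,1)
    expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
    expect_equal(r$roc$fpr[nrow(r$roc)], 1)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  }
})

test_that("AUC agrees with pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(9)
  pos <- rnorm(15, mean = 1); cand <- rnorm(40)
  a <- rocAuc(pos, cand)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 15), rep(0, 40)), predictor = c(pos, cand),
    quiet = TRUE, direction = "<")))
  expect_equal(a, ref, tolerance = 1e-12)
  expect_equal(rocAuc(exp(pos), exp(cand))$auc, a, tolerance = 1e-12)
})

test_that("LOOCV with reference scorers hits the AUC extremes", {
  A <- randomBinaryA(8, 5, 0.25, seed = 2)
  # reference scorers: held-out positions always outrank (or never outrank)
  # the candidate pairs, regardless of the masked matrix they are handed
  expect_equal(auc(globalLoocv(A, scorer = function(Am) A@.Data)), 1)
  expect_equal(auc(globalLoocv(A, scorer = function(Am) -A@.Data)), 0)
})

test_that("a random scorer yields chance-level pooled AUC", {
  A <- randomBinaryA(25, 10, 0.8, seed = 3)   # 200 positives
  set.seed(4)
  res <- globalLoocv(A, scorer = function(Am)
    matrix(runif(length(Am)), nrow(Am)))
  expect_lt(abs(auc(res) - 0.5), 0.05)
})

test_that("LOOCV is leakage-safe: each round scores from the masked matrix", {
  A <- randomBinaryA(6, 4, 0.3, seed = 5)
  pos <- which(A@.Data == 1)
  seen <- list()
  res <- globalLoocv(A, scorer = function(Am) {
    seen[[length(seen) + 1]] <<- Am@.Data
    matrix(1, nrow(Am), ncol(Am))
  })
  expect_length(seen, length(pos))
  for (t in seq_along(pos)) {
    expect_equal(seen[[t]][pos[t]], 0)            # held-out pair masked
    expect_equal(sum(A@.Data - seen[[t]]), 1)     # and nothing else
  }
  expect_error(globalLoocv(associationMatrix(
    matrix(c(1, 0), 1, 2, dimnames = list("m1", c("d1", "d2"))))),
    "at least 2")
})

test_that("k-fold CV is deterministic with balanced folds", {
  A <- randomBinaryA(12, 6, 0.3, seed = 6)
  sc <- function(Am) degreeBaseline(Am)
  r1 <- kfoldCv(A, k = 5, repeats = 3, foldSeed = 2, scorer = sc)
  r2 <- kfoldCv(A, k = 5, repeats = 3, foldSeed = 2, scorer = sc)
  expect_identical(r1@foldAssignments, r2@foldAssignments)
  expect_identical(r1@perRepeatAUC, r2@perRepeatAUC)
  for (fa in r1@foldAssignments) {
    sizes <- tabulate(fa, 5)
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  # a different fold seed changes the partition
  r3 <- kfoldCv(A, k = 5, repeats = 3, foldSeed = 99, scorer = sc)
  expect_false(identical(r1@foldAssignments, r3@foldAssignments))
  expect_error(kfoldCv(A, k = 1000, scorer = sc), "exceeds")
})

test_that("k-fold with a perfect scorer gives AUC 1; repeats stabilize", {
  A <- randomBinaryA(10, 5, 0.3, seed = 7)
  expect_equal(auc(kfoldCv(A, repeats = 1, scorer = function(Am) A@.Data)), 1)

  # sampling stability on a stochastic scorer: small-repeat mean within
  # 2 SD of a larger-repeat mean
  set.seed(8)
  noisy <- function(Am) degreeBaseline(Am) +
    matrix(rnorm(length(Am)), nrow(Am))
  r5 <- kfoldCv(A, repeats = 5, foldSeed = 1, scorer = noisy)
  r25 <- kfoldCv(A, repeats = 25, foldSeed = 50, scorer = noisy)
  expect_lt(abs(auc(r5) - auc(r25)), 2 * (r5@aucSD + r25@aucSD))
})

test_that("LOOCV with the real pipeline runs end-to-end on a small instance", {
  sim <- simulateAssociations(m = 15, n = 6, rank = 2, density = 0.15,
                              seed = 12)
  res <- globalLoocv(sim$A, mdaParams(maxIter = 150), seed = 1)
  expect_s4_class(res, "CVResult")
  expect_gte(auc(res), 0)
  expect_lte(auc(res), 1)
  expect_true(all(res@ranks >= 1 & res@ranks <= res@nCandidates + 1))
})
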