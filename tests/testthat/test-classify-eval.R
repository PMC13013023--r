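# small labeled feature tables built directly (no arbors needed)
fakeTable <- function(label, nCells, rowsPerCell, betaCenter, seed,
                      relLevels = 0:3) {
  set.seed(seed)
  rows <- lapply(seq_len(nCells), function(i) {
    data.frame(
      cellID = sprintf("%s%02d", label, i),
      label = label,
      betaMean = rnorm(rowsPerCell, betaCenter, 0.05),
      betaDiff = rnorm(rowsPerCell, 0.1, 0.05),
      relLeafNumber = sample(relLevels, rowsPerCell, replace = TRUE)
    )
  })
  do.call(rbind, rows)
}

test_that("balancing subsamples the larger class to equal image counts", {
  tabs <- list(
    A = fakeTable("A", 12, 5, 0.5, 1),
    B = fakeTable("B", 5, 5, 0.6, 2)
  )
  bal <- balanceCohort(tabs, seed = 3)
  expect_equal(length(unique(bal$A$cellID)), 5L)
  expect_equal(length(unique(bal$B$cellID)), 5L)
  # already balanced -> identity
  bal2 <- balanceCohort(bal, seed = 4)
  expect_identical(bal2, bal)
  # seeded: same seed, same retained subset
  expect_identical(balanceCohort(tabs, seed = 3)$A, bal$A)
  expect_error(balanceCohort(list(A = tabs$A[0, ], B = tabs$B), 1), "zero")
})

test_that("image-wise splits are stratified, leak-free and clamped", {
  tabs <- list(
    A = fakeTable("A", 4, 6, 0.5, 1),
    B = fakeTable("B", 4, 6, 0.6, 2)
  )
  plan <- splitByImage(tabs, trainFraction = 0.75, seed = 1)
  trA <- sum(startsWith(plan@trainCells, "A"))
  expect_equal(trA, 3L)
  expect_equal(sum(startsWith(plan@testCells, "A")), 1L)
  # no cell on both sides, across many seeds; rows follow their cell
  for (seed in 1:100) {
    p <- splitByImage(tabs, seed = seed)
    expect_length(intersect(p@trainCells, p@testCells), 0L)
  }
  parts <- applySplit(tabs, plan)
  expect_length(intersect(parts$train$cellID, parts$test$cellID), 0L)
  expect_equal(nrow(parts$train) + nrow(parts$test), nrow(tabs$A) + nrow(tabs$B))
  # every class keeps at least one test cell even at extreme fractions
  p <- splitByImage(tabs, trainFraction = 0.99, seed = 5)
  expect_true(all(c("A", "B") %in% substr(p@testCells, 1, 1)))
  expect_error(splitByImage(tabs, trainFraction = 1.2), "trainFraction")
})

test_that("AUC equals exhaustive pair counting and handles degeneracies", {
  r <- rocAucCI(c(0.9, 0.1), c(1, 0))
  expect_equal(r$auc, 1.0)
  r <- rocAucCI(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(r$auc, 0.5)
  expect_true(r$ciLow <= 0.5 && r$ciHigh >= 0.5)
  # pair-counting oracle on random vectors, including ties
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(c(1, 2, 6), 1)) # coarse rounding forces ties
    r <- rocAucCI(s, y)
    expect_equal(r$auc, oracleAucPairCount(s, y), tolerance = 1e-12)
    expect_gte(r$ciHigh + 1e-12, r$auc)
    expect_lte(r$ciLow - 1e-12, r$auc)
  }
  expect_error(rocAucCI(c(0.1, 0.2), c(1, 1)), "two classes")
})

test_that("DeLong interval width shrinks roughly as n^(-1/2)", {
  width <- function(n, seed) {
    set.seed(seed)
    s <- c(rnorm(n / 2, 0.4, 0.2), rnorm(n / 2, 0.6, 0.2))
    y <- rep(0:1, each = n / 2)
    r <- rocAucCI(s, y)
    r$ciHigh - r$ciLow
  }
  w50 <- mean(vapply(1:5, function(s) width(50, s), numeric(1)))
  w800 <- mean(vapply(1:5, function(s) width(800, s), numeric(1)))
  expect_lt(w800, w50 / 2) # expect ~1/4 at 16x the n
})

test_that("image accuracy majority-votes rows per cell with ties to
           class 0", {
  test <- data.frame(
    cellID = c("a", "a", "a", "b", "b"),
    label = c("pos", "pos", "pos", "neg", "neg"),
    betaMean = 0, betaDiff = 0, relLeafNumber = 0
  )
  # cell a (true 1): rows (1,1,0) -> mean 2/3 -> predicted 1, correct;
  # cell b (true 0): rows (0,0) -> predicted 0, correct
  acc <- imageAccuracy(c(0.9, 0.8, 0.2, 0.1, 0.3), test)
  expect_equal(acc$nCorrect, 2L)
  expect_equal(acc$nImages, 2L)
  # tie at exactly 0.5 resolves to class 0: cell of true class 1 with
  # rows (1,0) counts as incorrect
  test2 <- data.frame(
    cellID = c("a", "a", "b"), label = c("pos", "pos", "neg"),
    betaMean = 0, betaDiff = 0, relLeafNumber = 0
  )
  acc2 <- imageAccuracy(c(0.9, 0.1, 0.2), test2)
  expect_equal(acc2$perCell$predLabel[acc2$perCell$cellID == "a"], 0L)
  expect_equal(acc2$nCorrect, 1L)
})

test_that("perfectly separated classes give AUC 1 for every method", {
  tabs <- list(
    A = fakeTable("A", 4, 20, 0.3, 1),
    B = fakeTable("B", 4, 20, 0.8, 2)
  )
  plan <- splitByImage(tabs, seed = 2)
  parts <- applySplit(tabs, plan)
  for (m in c("LR", "SVM", "KNN", "RF", "DT", "Bayes", "NN")) {
    res <- suppressWarnings(
      fitPredict(parts$train, parts$test,
        method = m, featureMode = "2D",
        seed = 5
      )
    )
    expect_equal(res@auc, 1.0, info = m)
  }
})

test_that("fitPredict validates its inputs", {
  tabs <- list(
    A = fakeTable("A", 3, 10, 0.3, 1),
    B = fakeTable("B", 3, 10, 0.8, 2)
  )
  parts <- applySplit(tabs, splitByImage(tabs, seed = 1))
  oneClass <- parts$train[parts$train$label == "A", ]
  expect_error(
    fitPredict(oneClass, parts$test, method = "LR"),
    "two classes"
  )
  bad <- parts$train
  bad$betaMean[1] <- NA
  expect_error(
    fitPredict(bad, parts$test, method = "LR"),
    "NaN/NA"
  )
  # 2D tables cannot serve a 3D fit
  expect_error(
    fitPredict(
      parts$train[, c("cellID", "label", "betaMean", "betaDiff")],
      parts$test,
      method = "LR", featureMode = "3D"
    ),
    "relLeafNumber"
  )
})

test_that("the comparison report is complete, deterministic and leak-free", {
  specs <- gliaLikeSpecs(depth = 5)
  recs <- generateCohort(cohortSpec(specs, nCellsPerClass = 8, seed = 41))
  tabs <- cohortFeatureTables(recs)
  rep1 <- suppressWarnings(runComparison(tabs, seed = 13))
  expect_length(rep1@results, 14L) # 7 methods x 2 modes
  expect_equal(nrow(aucTable(rep1)), 14L)
  expect_equal(nrow(accuracyTable(rep1)), 14L)
  expect_length(
    intersect(rep1@split@trainCells, rep1@split@testCells), 0L
  )
  expect_true(all(aucTable(rep1)$ciLow <= aucTable(rep1)$auc + 1e-12))
  rep2 <- suppressWarnings(runComparison(tabs, seed = 13))
  expect_identical(aucTable(rep2), aucTable(rep1))
  # the level-localized class difference: adding the relative leaf number
  # lifts the mean AUC across methods by a wide margin
  a <- aucTable(rep1)
  gain <- mean(a$auc[a$featureMode == "3D"]) -
    mean(a$auc[a$featureMode == "2D"])
  expect_gt(gain, 0.1)
})
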