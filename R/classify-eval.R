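.CLASSIFIERS <- c("LR", "SVM", "KNN", "RF", "DT", "Bayes", "NN")

# midrank (Mann-Whitney, ties = 1/2) AUC; used internally for the KNN
# k-scan. The reported pipeline AUC and its CI come from rocAucCI().
.aucFast <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.featureCols <- function(featureMode, absDiff = FALSE) {
  cols <- c("betaMean", "betaDiff")
  if (featureMode == "3D") cols <- c(cols, "relLeafNumber")
  cols
}

.designMatrix <- function(table, featureMode, absDiff = FALSE) {
  cols <- .featureCols(featureMode)
  if (!all(cols %in% names(table))) {
    stop(sprintf(
      "feature table lacks column(s) %s required for %s mode",
      paste(setdiff(cols, names(table)), collapse = ", "), featureMode
    ), call. = FALSE)
  }
  X <- table[, cols, drop = FALSE]
  if (absDiff) X$betaDiff <- abs(X$betaDiff)
  if (anyNA(X) || any(!vapply(X, function(c) all(is.finite(c)), logical(1)))) {
    stop("NaN/NA feature values", call. = FALSE)
  }
  X
}

#' Balance a two-class cohort by image count
#'
#' The label with more cells is randomly subsampled (seeded) so both labels
#' contribute the same number of cells; per-junction row counts stay
#' unequal, since the number of junctions per image cannot be controlled.
#'
#' @param tables named list of exactly two feature tables (label ->
#'   table).
#' @param seed RNG seed for the subsample.
#' @return the balanced named list.
#' @export
balanceCohort <- function(tables, seed = 1) {
  if (length(tables) != 2L) {
    stop("balanceCohort expects exactly two labeled tables", call. = FALSE)
  }
  cells <- lapply(tables, function(t) unique(t$cellID))
  if (any(lengths(cells) == 0L)) {
    stop("a label has zero cells", call. = FALSE)
  }
  nMin <- min(lengths(cells))
  set.seed(as.integer(seed))
  out <- tables
  for (i in seq_along(tables)) {
    if (length(cells[[i]]) > nMin) {
      keep <- sample(cells[[i]], nMin)
      t <- tables[[i]]
      t <- t[t$cellID %in% keep, , drop = FALSE]
      rownames(t) <- NULL
      out[[i]] <- t
    }
  }
  out
}

#' Image-wise train/test split
#'
#' Assigns whole cells (never individual junction rows) to the training or
#' test set, stratified by class: per class, `round(trainFraction * n)`
#' cells go to training, clamped so at least one test cell and one training
#' cell remain. All of a cell's rows follow its assignment, so no cell
#' leaks across the split.
#'
#' @param tables named list of two feature tables.
#' @param trainFraction fraction of cells per class used for training, in
#'   (0, 1); default 0.75 (the middle of the customary 70-80 percent
#'   range).
#' @param seed RNG seed.
#' @return a [SplitPlan-class].
#' @export
splitByImage <- function(tables, trainFraction = 0.75, seed = 1) {
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must be in (0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  trainCells <- character()
  testCells <- character()
  for (t in tables) {
    cells <- unique(t$cellID)
    n <- length(cells)
    if (n < 2L) {
      stop("need >= 2 cells per class to split", call. = FALSE)
    }
    nTrain <- min(max(round(trainFraction * n), 1L), n - 1L)
    tr <- sample(cells, nTrain)
    trainCells <- c(trainCells, tr)
    testCells <- c(testCells, setdiff(cells, tr))
  }
  new("SplitPlan",
    trainCells = trainCells, testCells = testCells,
    trainFraction = trainFraction, seed = as.integer(seed)
  )
}

#' Apply a split plan to feature tables
#'
#' @param tables named list of feature tables.
#' @param plan a [SplitPlan-class].
#' @return list(train = data.frame, test = data.frame) of stacked rows.
#' @export
applySplit <- function(tables, plan) {
  stopifnot(is(plan, "SplitPlan"))
  all <- do.call(rbind, c(tables, make.row.names = FALSE))
  list(
    train = all[all$cellID %in% plan@trainCells, , drop = FALSE],
    test = all[all$cellID %in% plan@testCells, , drop = FALSE]
  )
}

# choose k for KNN by scanning odd k on a seeded hold-out of ~25% of the
# training cells (row-level fallback when a class has too few cells)
.chooseKnnK <- function(Xtr, y, cells, kGrid, seed) {
  set.seed(seed)
  byClass <- split(unique(cells), y[match(unique(cells), cells)])
  valCells <- character()
  if (all(lengths(byClass) >= 2L)) {
    for (cc in byClass) {
      nv <- max(1L, round(0.25 * length(cc)))
      nv <- min(nv, length(cc) - 1L)
      valCells <- c(valCells, sample(cc, nv))
    }
    valIdx <- which(cells %in% valCells)
  } else {
    valIdx <- sample(seq_len(nrow(Xtr)), max(2L, round(0.25 * nrow(Xtr))))
  }
  if (length(unique(y[valIdx])) < 2L || length(unique(y[-valIdx])) < 2L) {
    return(min(kGrid))
  }
  pos <- levels(y)[2L]
  best <- kGrid[1L]
  bestAuc <- -Inf
  for (k in kGrid) {
    if (k >= length(y) - length(valIdx)) break
    pred <- class::knn(
      train = Xtr[-valIdx, , drop = FALSE],
      test = Xtr[valIdx, , drop = FALSE],
      cl = y[-valIdx], k = k, prob = TRUE
    )
    p <- attr(pred, "prob")
    p1 <- ifelse(pred == pos, p, 1 - p)
    a <- .aucFast(p1, as.integer(y[valIdx] == pos))
    if (!is.na(a) && a > bestAuc + 1e-12) {
      bestAuc <- a
      best <- k
    }
  }
  best
}

#' Train one classifier and score the test rows
#'
#' Trains the named method on the chosen feature mode and returns per-row
#' predicted probabilities of the positive class (the second label in sort
#' order) together with the DeLong AUC interval. Features are standardized
#' with training-set mean/SD for LR, SVM, KNN and NN; the tree methods (RF,
#' DT) and Bayes consume raw features. The SVM uses a radial (Gaussian)
#' kernel with cost 1 and the median heuristic for the kernel width; KNN
#' scans odd k in 1..51 maximizing hold-out AUC; the NN is a single hidden
#' layer of 8 logistic units (weight decay 1e-4, up to 1e4 iterations).
#' Every stochastic method is seeded.
#'
#' @param train,test feature tables sharing columns; `train` must contain
#'   both classes.
#' @param method one of "LR", "SVM", "KNN", "RF", "DT", "Bayes", "NN".
#' @param featureMode "2D" (betaMean, betaDiff) or "3D" (adds
#'   relLeafNumber).
#' @param seed RNG seed.
#' @param absDiff use |betaDiff| instead of the signed difference.
#' @return a [ClassifierResult-class] (image-accuracy slots filled by
#'   [imageAccuracy()] / [runComparison()]).
#' @export
fitPredict <- function(train, test, method = .CLASSIFIERS,
                       featureMode = c("3D", "2D"), seed = 1,
                       absDiff = FALSE) {
  method <- match.arg(method)
  featureMode <- match.arg(featureMode)
  seed <- as.integer(seed)
  y <- factor(train$label)
  if (nlevels(y) != 2L) {
    stop("training set must contain exactly two classes", call. = FALSE)
  }
  pos <- levels(y)[2L]
  Xtr <- .designMatrix(train, featureMode, absDiff)
  Xte <- .designMatrix(test, featureMode, absDiff)

  if (method %in% c("LR", "SVM", "KNN", "NN")) {
    mu <- vapply(Xtr, mean, numeric(1))
    sg <- vapply(Xtr, stats::sd, numeric(1))
    sg[sg == 0 | is.na(sg)] <- 1
    Xtr <- as.data.frame(scale(Xtr, center = mu, scale = sg))
    Xte <- as.data.frame(scale(Xte, center = mu, scale = sg))
  }
  dtr <- cbind(Xtr, label = y)
  knnK <- NA_integer_

  set.seed(seed)
  scores <- switch(method,
    LR = {
      fit <- stats::glm(label ~ ., family = stats::binomial(), data = dtr)
      as.numeric(stats::predict(fit, newdata = Xte, type = "response"))
    },
    SVM = {
      sub <- if (nrow(Xtr) > 500L) {
        Xtr[sample(nrow(Xtr), 500L), , drop = FALSE]
      } else {
        Xtr
      }
      med <- stats::median(stats::dist(as.matrix(sub)))
      gamma <- if (is.finite(med) && med > 0) 1 / (2 * med^2) else 1 / ncol(Xtr)
      fit <- e1071::svm(
        x = as.matrix(Xtr), y = y, kernel = "radial",
        gamma = gamma, cost = 1, probability = TRUE
      )
      pr <- stats::predict(fit, as.matrix(Xte), probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, pos])
    },
    KNN = {
      knnK <- as.integer(.chooseKnnK(
        Xtr, y, train$cellID,
        kGrid = seq(1L, 51L, by = 2L), seed = seed
      ))
      pred <- class::knn(
        train = Xtr, test = Xte, cl = y, k = knnK, prob = TRUE
      )
      p <- attr(pred, "prob")
      as.numeric(ifelse(pred == pos, p, 1 - p))
    },
    RF = {
      fit <- randomForest::randomForest(x = Xtr, y = y)
      as.numeric(stats::predict(fit, Xte, type = "prob")[, pos])
    },
    DT = {
      fit <- rpart::rpart(label ~ ., data = dtr, method = "class")
      as.numeric(stats::predict(fit, newdata = Xte, type = "prob")[, pos])
    },
    Bayes = {
      fit <- e1071::naiveBayes(x = Xtr, y = y)
      as.numeric(stats::predict(fit, Xte, type = "raw")[, pos])
    },
    NN = {
      fit <- nnet::nnet(label ~ .,
        data = dtr, size = 8, decay = 1e-4,
        maxit = 10000, trace = FALSE
      )
      as.numeric(stats::predict(fit, newdata = Xte, type = "raw"))
    }
  )
  r <- rocAucCI(scores, test$label)
  new("ClassifierResult",
    method = method, featureMode = featureMode,
    scores = scores, auc = r$auc,
    aucCiLow = r$ciLow, aucCiHigh = r$ciHigh,
    rocPoints = r$rocPoints, knnK = knnK, seed = seed
  )
}

#' ROC AUC with DeLong 95% confidence interval
#'
#' The AUC is the normalized Mann-Whitney U statistic (ties count 1/2) and
#' the 95% confidence interval uses the DeLong variance estimate, both via
#' pROC. The positive class is the second label in sort order; higher
#' scores indicate the positive class. Degenerate vectors (zero DeLong
#' variance, e.g. all scores tied) return a zero-width interval at the AUC.
#'
#' @param scores numeric predicted scores/probabilities.
#' @param labels two-class label vector aligned with `scores`.
#' @return list(auc, ciLow, ciHigh, rocPoints = data.frame(fpr, tpr)).
#' @export
rocAucCI <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  if (length(scores) != length(labels) || length(scores) < 2L) {
    stop("need >= 2 aligned score/label pairs", call. = FALSE)
  }
  r <- pROC::roc(
    response = labels, predictor = scores,
    levels = levels(labels), direction = "<", quiet = TRUE
  )
  auc <- as.numeric(pROC::auc(r))
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))),
    error = function(e) c(auc, auc, auc)
  )
  if (anyNA(ci) || any(!is.finite(ci))) ci <- c(auc, auc, auc)
  list(
    auc = auc,
    ciLow = max(0, min(ci[1L], auc)),
    ciHigh = min(1, max(ci[3L], auc)),
    rocPoints = data.frame(
      fpr = 1 - r$specificities, tpr = r$sensitivities
    )
  )
}

#' Image-level accuracy
#'
#' Each test row is hard-labeled by thresholding its score at 0.5 (strict);
#' each cell's predicted label is 1 when the mean of its rows' labels
#' exceeds 0.5 and 0 otherwise (an exact 0.5 tie resolves to class 0).
#' Cell predictions are compared with true labels and reported as
#' "k of n images".
#'
#' @param result a [ClassifierResult-class], or a numeric score vector.
#' @param test the test feature table the scores align with.
#' @return list(nCorrect, nImages, perCell = data.frame).
#' @export
imageAccuracy <- function(result, test) {
  scores <- if (is(result, "ClassifierResult")) result@scores else result
  stopifnot(length(scores) == nrow(test))
  pos <- sort(unique(test$label))[min(2L, length(unique(test$label)))]
  rowPred <- as.integer(scores > 0.5)
  cells <- unique(test$cellID)
  perCell <- data.frame(
    cellID = cells,
    trueLabel = vapply(
      cells, function(cc) {
        as.integer(test$label[test$cellID == cc][1L] == pos)
      },
      integer(1)
    ),
    meanPred = vapply(
      cells, function(cc) mean(rowPred[test$cellID == cc]), numeric(1)
    )
  )
  perCell$predLabel <- as.integer(perCell$meanPred > 0.5)
  rownames(perCell) <- NULL
  list(
    nCorrect = sum(perCell$predLabel == perCell$trueLabel),
    nImages = nrow(perCell),
    perCell = perCell
  )
}

#' Run the full seven-classifier, two-mode comparison
#'
#' Executes the evaluation protocol on a two-class cohort of feature
#' tables: balance image counts, split image-wise into train/test, then fit
#' every requested method in every feature mode, collecting the DeLong AUC
#' interval and the image-level accuracy of each combination.
#'
#' @param tables named list of two labeled (3D) feature tables.
#' @param trainFraction train fraction of cells per class (default 0.75).
#' @param seed master seed; balancing, splitting and all fits derive from
#'   it.
#' @param methods classifier subset (default all seven).
#' @param modes feature modes (default both "2D" and "3D").
#' @param absDiff use |betaDiff| instead of signed.
#' @return a [ComparisonReport-class].
#' @export
runComparison <- function(tables, trainFraction = 0.75, seed = 1,
                          methods = .CLASSIFIERS,
                          modes = c("2D", "3D"), absDiff = FALSE) {
  seed <- as.integer(seed)
  methods <- match.arg(methods, .CLASSIFIERS, several.ok = TRUE)
  balanced <- balanceCohort(tables, seed = seed)
  plan <- splitByImage(balanced, trainFraction = trainFraction, seed = seed)
  parts <- applySplit(balanced, plan)
  results <- list()
  aucRows <- list()
  accRows <- list()
  for (mode in modes) {
    for (m in methods) {
      res <- fitPredict(parts$train, parts$test,
        method = m,
        featureMode = mode, seed = seed, absDiff = absDiff
      )
      acc <- imageAccuracy(res, parts$test)
      res@nCorrectImages <- as.integer(acc$nCorrect)
      res@nImages <- as.integer(acc$nImages)
      key <- paste(m, mode, sep = ".")
      results[[key]] <- res
      aucRows[[key]] <- data.frame(
        method = m, featureMode = mode, auc = res@auc,
        ciLow = res@aucCiLow, ciHigh = res@aucCiHigh
      )
      accRows[[key]] <- data.frame(
        method = m, featureMode = mode,
        nCorrect = acc$nCorrect, nImages = acc$nImages
      )
    }
  }
  aucTab <- do.call(rbind, aucRows)
  accTab <- do.call(rbind, accRows)
  rownames(aucTab) <- rownames(accTab) <- NULL
  new("ComparisonReport",
    results = results, aucTable = aucTab, accuracyTable = accTab,
    split = plan,
    config = list(
      trainFraction = trainFraction, seed = seed, methods = methods,
      modes = modes, absDiff = absDiff,
      svm = list(kernel = "radial", cost = 1, gamma = "median heuristic"),
      knn = list(kGrid = "odd 1..51", validation = "25% of training cells"),
      nn = list(size = 8, decay = 1e-4, maxit = 10000),
      knnK = vapply(results, function(r) r@knnK, integer(1))
    )
  )
}

#' @rdname ComparisonReport-class
#' @export
setMethod("aucTable", "ComparisonReport", function(x) x@aucTable)

#' @rdname ComparisonReport-class
#' @export
setMethod("accuracyTable", "ComparisonReport", function(x) x@accuracyTable)

setMethod("show", "ClassifierResult", function(object) {
  cat(sprintf(
    "ClassifierResult %s/%s: AUC %.3f [%.3f, %.3f]%s%s\n",
    object@method, object@featureMode, object@auc,
    object@aucCiLow, object@aucCiHigh,
    if (is.na(object@nImages)) {
      ""
    } else {
      sprintf(", %d/%d images", object@nCorrectImages, object@nImages)
    },
    if (is.na(object@knnK)) "" else sprintf(", k=%d", object@knnK)
  ))
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf(
    "ComparisonReport: %d results (%s x %s), %d train / %d test cells\n",
    length(object@results),
    paste(object@config$methods, collapse = ","),
    paste(object@config$modes, collapse = ","),
    length(object@split@trainCells), length(object@split@testCells)
  ))
  print(object@aucTable, digits = 3)
})
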