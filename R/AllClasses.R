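#' @import methods
NULL

.SWC_COLUMNS <- c("sampleID", "typeCode", "x", "y", "z", "radius", "parentID")

#' Reconstruction: one cell's SWC sample table
#'
#' Container for a single morphology reconstruction in the SWC sample model:
#' ordered rows of (sampleID, typeCode, x, y, z, radius, parentID), with
#' coordinates and radii in micrometres. `parentID` is -1 for a root sample;
#' multiple roots (disconnected trees) are permitted. Type code 1 marks soma
#' samples, which are never assigned to branches downstream.
#'
#' @slot samples data.frame with columns sampleID, typeCode, x, y, z, radius,
#'   parentID.
#' @slot cellID single string identifying the cell (one reconstruction per
#'   image/cell).
#' @slot label optional class label (NA when unlabeled).
#' @slot source optional free-text provenance.
#'
#' @seealso [readSWC()], [writeSWC()], [extractBranches()]
#' @export
setClass("Reconstruction",
  representation(
    samples = "data.frame",
    cellID = "character",
    label = "character",
    source = "character"
  ),
  prototype(
    samples = data.frame(
      sampleID = integer(), typeCode = integer(),
      x = numeric(), y = numeric(), z = numeric(),
      radius = numeric(), parentID = integer()
    ),
    cellID = NA_character_, label = NA_character_, source = NA_character_
  )
)

setValidity("Reconstruction", function(object) {
  s <- object@samples
  if (!all(.SWC_COLUMNS %in% names(s))) {
    return(paste(
      "samples must have columns:",
      paste(.SWC_COLUMNS, collapse = ", ")
    ))
  }
  if (length(object@cellID) != 1L) return("cellID must be a single string")
  if (nrow(s) == 0L) return(TRUE)
  if (anyDuplicated(s$sampleID)) return("sample IDs must be unique")
  if (any(s$sampleID <= 0)) return("sample IDs must be positive")
  if (any(!is.finite(s$radius)) || any(s$radius <= 0)) {
    return("all radii must be finite and > 0")
  }
  if (any(s$parentID == s$sampleID)) {
    return("a sample cannot be its own parent")
  }
  nonroot <- s$parentID != -1L
  if (!all(s$parentID[nonroot] %in% s$sampleID)) {
    bad <- s$parentID[nonroot][!(s$parentID[nonroot] %in% s$sampleID)]
    return(sprintf(
      "dangling parent ID(s): %s",
      paste(unique(bad), collapse = ", ")
    ))
  }
  # acyclicity: follow parents with a visited/finished mark
  idx <- match(s$parentID, s$sampleID) # NA at roots
  state <- integer(nrow(s)) # 0 unseen, 1 in progress, 2 done
  for (i in seq_len(nrow(s))) {
    if (state[i] != 0L) next
    path <- integer(0)
    j <- i
    while (!is.na(j) && state[j] == 0L) {
      state[j] <- 1L
      path <- c(path, j)
      j <- idx[j]
    }
    if (!is.na(j) && state[j] == 1L) return("parent relation contains a cycle")
    state[path] <- 2L
  }
  TRUE
})

#' BranchTree: branch-level view of a reconstruction
#'
#' A reconstruction partitioned into branches (maximal unbranched chains of
#' non-soma samples between branch points and tips), with per-branch metrics
#' and leaf-number statistics. Built incrementally: [extractBranches()] fills
#' topology, [branchMetrics()] the mean radius and path length,
#' [computeLeafNumbers()] and [relativeLeafNumbers()] the tree statistics;
#' [buildBranchTree()] chains all four.
#'
#' @slot branches data.frame with one row per branch: branchID,
#'   parentBranchID (NA at roots), typeCode, nSamples, meanRadius,
#'   pathLength, leafNumber, relLeafNumber (metric columns NA until
#'   computed).
#' @slot sampleIDs list of integer vectors, the ordered (proximal-to-distal)
#'   sample IDs of each branch.
#' @slot cellID the originating cell.
#'
#' @export
setClass("BranchTree",
  representation(
    branches = "data.frame",
    sampleIDs = "list",
    cellID = "character"
  )
)

setValidity("BranchTree", function(object) {
  b <- object@branches
  need <- c(
    "branchID", "parentBranchID", "typeCode", "nSamples",
    "meanRadius", "pathLength", "leafNumber", "relLeafNumber"
  )
  if (!all(need %in% names(b))) {
    return(paste("branches must have columns:", paste(need, collapse = ", ")))
  }
  if (length(object@sampleIDs) != nrow(b)) {
    return("sampleIDs must have one element per branch")
  }
  if (nrow(b) > 0L) {
    if (anyDuplicated(b$branchID)) return("branch IDs must be unique")
    nonroot <- !is.na(b$parentBranchID)
    if (!all(b$parentBranchID[nonroot] %in% b$branchID)) {
      return("parentBranchID must reference an existing branch or be NA")
    }
    if (any(lengths(object@sampleIDs) < 1L)) {
      return("every branch must contain at least one sample")
    }
    mr <- b$meanRadius
    if (any(!is.na(mr) & mr <= 0)) return("meanRadius must be > 0")
    pl <- b$pathLength
    if (any(!is.na(pl) & pl < 0)) return("pathLength must be >= 0")
  }
  TRUE
})

#' ScaleSchedule: per-level scale factors for the power-loss recursion
#'
#' An ordered list of branching levels j = 0..N-1, each carrying the mean and
#' absolute-difference radius scale factors and their length analogues, plus
#' the total terminal-level resistance. Input to [powerLoss()].
#'
#' @slot levels data.frame with columns betaMean, betaDiffAbs, gammaMean,
#'   gammaDiffAbs; one row per branching level.
#' @slot terminalResistance total resistance at the terminal level (units of
#'   rho/pi; all resistances relative).
#'
#' @export
setClass("ScaleSchedule",
  representation(levels = "data.frame", terminalResistance = "numeric")
)

setValidity("ScaleSchedule", function(object) {
  lv <- object@levels
  need <- c("betaMean", "betaDiffAbs", "gammaMean", "gammaDiffAbs")
  if (!all(need %in% names(lv))) {
    return(paste("levels must have columns:", paste(need, collapse = ", ")))
  }
  if (length(object@terminalResistance) != 1L ||
    !is.finite(object@terminalResistance) ||
    object@terminalResistance <= 0) {
    return("terminalResistance must be a single positive number")
  }
  if (nrow(lv) > 0L) {
    if (any(lv$betaDiffAbs < 0) || any(lv$gammaDiffAbs < 0)) {
      return("betaDiffAbs and gammaDiffAbs must be >= 0")
    }
    if (any(lv$betaMean - lv$betaDiffAbs <= 0)) {
      return("betaMean - betaDiffAbs must be > 0 at every level")
    }
    if (any(lv$gammaMean - lv$gammaDiffAbs <= 0)) {
      return("gammaMean - gammaDiffAbs must be > 0 at every level")
    }
  }
  TRUE
})

#' ArborSpec: parameters of one synthetic arbor
#'
#' Specification for a deterministic (seeded) synthetic binary arbor: a
#' complete binary tree of `depth` branch generations (2^depth tips) whose
#' junctions draw mean/difference radius scale factors around level-dependent
#' profile values. The complete-tree topology makes the relative leaf number
#' of a generation-g junction exactly g, so expected features are closed
#' form.
#'
#' @slot depth branch generations below the root branch (2^depth tips).
#' @slot rootRadius,rootLength root-branch radius and length, micrometres.
#' @slot betaMeanProfile,betaDiffProfile functions mapping junction
#'   generation (0-based; equals the parent branch's relative leaf number)
#'   to the target mean / signed difference scale factor.
#' @slot gammaMean,gammaDiff daughter/parent length-ratio mean and
#'   half-difference (gammaDiff >= 0; the longer daughter is daughter 1).
#' @slot noiseSD standard deviation of additive truncated-normal noise on
#'   the per-junction scale-factor draws (0 = deterministic ratios).
#' @slot samplesPerBranch SWC samples per branch (>= 2).
#' @slot pixelSize radius quantization floor in micrometres (0 = off); see
#'   [quantizeRadii()].
#' @slot typeCode SWC type code written for non-soma samples.
#' @slot seed integer RNG seed.
#'
#' @seealso [arborSpec()], [generateArbor()]
#' @export
setClass("ArborSpec",
  representation(
    depth = "integer",
    rootRadius = "numeric",
    rootLength = "numeric",
    betaMeanProfile = "function",
    betaDiffProfile = "function",
    gammaMean = "numeric",
    gammaDiff = "numeric",
    noiseSD = "numeric",
    samplesPerBranch = "integer",
    pixelSize = "numeric",
    typeCode = "integer",
    seed = "integer"
  )
)

setValidity("ArborSpec", function(object) {
  if (object@depth < 1L) return("depth must be >= 1")
  if (object@rootRadius <= 0 || object@rootLength <= 0) {
    return("rootRadius and rootLength must be > 0")
  }
  if (object@gammaDiff < 0) return("gammaDiff must be >= 0")
  if (object@gammaMean - object@gammaDiff <= 0) {
    return("gammaMean - gammaDiff must be > 0")
  }
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@samplesPerBranch < 2L) return("samplesPerBranch must be >= 2")
  if (object@pixelSize < 0) return("pixelSize must be >= 0")
  g <- seq_len(object@depth) - 1L
  bm <- vapply(g, object@betaMeanProfile, numeric(1))
  bd <- vapply(g, object@betaDiffProfile, numeric(1))
  if (any(!is.finite(bm)) || any(!is.finite(bd))) {
    return("profiles must be finite over generations 0..depth-1")
  }
  if (any(bm - abs(bd) <= 0)) {
    return("betaMeanProfile - |betaDiffProfile| must be > 0 at every generation")
  }
  TRUE
})

#' CohortSpec: a labeled collection of arbor specifications
#'
#' @slot classSpecs named list (class label -> ArborSpec).
#' @slot nCellsPerClass cells generated per class (>= 2).
#' @slot seed cohort master seed; per-cell seeds are derived from it
#'   deterministically (counter-based), so the cohort is reproducible
#'   regardless of generation order.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    classSpecs = "list",
    nCellsPerClass = "integer",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  labs <- names(object@classSpecs)
  if (is.null(labs) || any(!nzchar(labs))) {
    return("classSpecs must be a named list (class label -> ArborSpec)")
  }
  if (anyDuplicated(labs)) return("duplicate class labels")
  if (!all(vapply(object@classSpecs, is, logical(1), class2 = "ArborSpec"))) {
    return("every element of classSpecs must be an ArborSpec")
  }
  if (object@nCellsPerClass < 2L) return("need >= 2 cells per class")
  TRUE
})

#' SplitPlan: an image-wise train/test assignment
#'
#' Cells (never individual junction rows) are assigned to the training or the
#' test set, stratified by class, so that no cell contributes rows to both
#' sides of the split.
#'
#' @slot trainCells,testCells disjoint character vectors of cell IDs.
#' @slot trainFraction fraction of cells per class assigned to training.
#' @slot seed RNG seed used for the assignment.
#'
#' @export
setClass("SplitPlan",
  representation(
    trainCells = "character",
    testCells = "character",
    trainFraction = "numeric",
    seed = "integer"
  )
)

setValidity("SplitPlan", function(object) {
  if (length(intersect(object@trainCells, object@testCells)) > 0L) {
    return("trainCells and testCells must be disjoint")
  }
  if (object@trainFraction <= 0 || object@trainFraction >= 1) {
    return("trainFraction must be in (0, 1)")
  }
  TRUE
})

#' ClassifierResult: one method x feature-mode evaluation
#'
#' @slot method one of "LR", "SVM", "KNN", "RF", "DT", "Bayes", "NN".
#' @slot featureMode "2D" (betaMean, betaDiff) or "3D" (adds relLeafNumber).
#' @slot scores per-test-row predicted probability of the positive class.
#' @slot auc,aucCiLow,aucCiHigh AUC with DeLong 95% confidence interval.
#' @slot rocPoints data.frame(fpr, tpr) of the ROC curve.
#' @slot nCorrectImages,nImages image-level accuracy (majority vote of row
#'   scores per cell, tie at 0.5 resolved to class 0).
#' @slot knnK chosen number of neighbours (NA for other methods).
#' @slot seed the seed the fit used.
#'
#' @export
setClass("ClassifierResult",
  representation(
    method = "character",
    featureMode = "character",
    scores = "numeric",
    auc = "numeric",
    aucCiLow = "numeric",
    aucCiHigh = "numeric",
    rocPoints = "data.frame",
    nCorrectImages = "integer",
    nImages = "integer",
    knnK = "integer",
    seed = "integer"
  ),
  prototype(
    nCorrectImages = NA_integer_, nImages = NA_integer_,
    knnK = NA_integer_
  )
)

setValidity("ClassifierResult", function(object) {
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1)) {
    return("auc must lie in [0, 1]")
  }
  if (!is.na(object@aucCiLow) && !is.na(object@aucCiHigh) &&
    !is.na(object@auc)) {
    if (object@aucCiLow > object@auc + 1e-12 ||
      object@aucCiHigh < object@auc - 1e-12) {
      return("confidence interval must bracket the AUC")
    }
  }
  TRUE
})

#' ComparisonReport: the full seven-classifier, two-mode comparison
#'
#' @slot results list of [ClassifierResult-class] objects (method x mode).
#' @slot aucTable data.frame: method, featureMode, auc, ciLow, ciHigh.
#' @slot accuracyTable data.frame: method, featureMode, nCorrect, nImages.
#' @slot split the [SplitPlan-class] used.
#' @slot config list of all settings and seeds (serialized for audit).
#'
#' @export
setClass("ComparisonReport",
  representation(
    results = "list",
    aucTable = "data.frame",
    accuracyTable = "data.frame",
    split = "SplitPlan",
    config = "list"
  )
)
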