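#' Compute per-junction asymmetric scale factors
#'
#' For every branch with exactly two children, computes the daughter/parent
#' radius scale factors beta_i = r_daughter / r_parent and the length
#' analogues gamma_i = l_daughter / l_parent, then the mean and signed
#' half-difference
#' \deqn{\bar\beta = (\beta_1+\beta_2)/2, \qquad
#'       \Delta\beta = (\beta_1-\beta_2)/2.}
#' Daughter 1 is the longer daughter (gamma_1 >= gamma_2), which fixes
#' Delta-gamma >= 0 and makes Delta-beta signed: positive when the longer
#' daughter is also the wider one. When the daughters' path lengths tie
#' exactly, the wider daughter is taken as daughter 1 (Delta-beta >= 0).
#'
#' Each junction also carries the parent branch's leaf number and relative
#' leaf number. Branches with three or more children (multifurcations) are
#' not junctions of the binary theory: they are skipped and counted in the
#' `"nSkippedMultifurcation"` attribute. A parent with path length 0 yields
#' NA gammas; the junction is retained for the radius features and counted
#' in `"nUndefinedGamma"`.
#'
#' @param tree a fully annotated [BranchTree-class] (see
#'   [buildBranchTree()]).
#' @param cellID cell identifier attached to every row (defaults to the
#'   tree's).
#' @return data.frame with one row per bifurcation: cellID,
#'   parentBranchID, beta1, beta2, gamma1, gamma2, betaMean, betaDiff,
#'   gammaMean, gammaDiff, leafNumberParent, relLeafNumber; attributes
#'   `nSkippedMultifurcation`, `nUndefinedGamma`.
#' @export
computeJunctions <- function(tree, cellID = NULL) {
  stopifnot(is(tree, "BranchTree"))
  if (is.null(cellID)) cellID <- tree@cellID
  b <- tree@branches
  if (anyNA(b$meanRadius) || anyNA(b$leafNumber) || anyNA(b$relLeafNumber)) {
    stop("branch metrics and leaf numbers must be computed first",
      call. = FALSE
    )
  }
  kidList <- branchChildren(tree)
  nKids <- lengths(kidList)
  nSkipped <- sum(nKids >= 3L)
  parents <- which(nKids == 2L)
  nGammaNA <- 0L
  rows <- vector("list", length(parents))
  for (k in seq_along(parents)) {
    p <- parents[k]
    ci <- match(kidList[[p]], b$branchID)
    rp <- b$meanRadius[p]
    lp <- b$pathLength[p]
    betas <- b$meanRadius[ci] / rp
    if (lp > 0) {
      gammas <- b$pathLength[ci] / lp
    } else {
      gammas <- c(NA_real_, NA_real_)
      nGammaNA <- nGammaNA + 1L
    }
    # daughter 1 = longer daughter; length tie (or undefined gamma) ->
    # wider daughter first, so betaDiff >= 0. Ties are detected at
    # relative tolerance 1e-9: reconstructed path lengths are sums of
    # coordinate distances and identical-length daughters differ only in
    # the last floating-point bits.
    tied <- anyNA(gammas) ||
      abs(gammas[1L] - gammas[2L]) <= 1e-9 * max(abs(gammas))
    if (!tied) {
      ord <- order(gammas, decreasing = TRUE)
    } else {
      ord <- order(betas, decreasing = TRUE)
    }
    betas <- betas[ord]
    gammas <- gammas[ord]
    rows[[k]] <- data.frame(
      cellID = cellID,
      parentBranchID = b$branchID[p],
      beta1 = betas[1L], beta2 = betas[2L],
      gamma1 = gammas[1L], gamma2 = gammas[2L],
      betaMean = (betas[1L] + betas[2L]) / 2,
      betaDiff = (betas[1L] - betas[2L]) / 2,
      gammaMean = (gammas[1L] + gammas[2L]) / 2,
      gammaDiff = (gammas[1L] - gammas[2L]) / 2,
      leafNumberParent = b$leafNumber[p],
      relLeafNumber = b$relLeafNumber[p]
    )
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      cellID = character(), parentBranchID = integer(),
      beta1 = numeric(), beta2 = numeric(),
      gamma1 = numeric(), gamma2 = numeric(),
      betaMean = numeric(), betaDiff = numeric(),
      gammaMean = numeric(), gammaDiff = numeric(),
      leafNumberParent = integer(), relLeafNumber = numeric()
    )
  }
  rownames(out) <- NULL
  attr(out, "nSkippedMultifurcation") <- nSkipped
  attr(out, "nUndefinedGamma") <- nGammaNA
  out
}

#' Remove resolution-artifact junctions
#'
#' Removes every junction for which either daughter's radius scale factor is
#' at or above the threshold (default 0.999). Ratios that close to 1 arise
#' when radii saturate at the image pixel size deep in the arbor, producing
#' spurious beta ~ 1; filtering them removes the artifactual symmetric peak.
#' The operation is idempotent; the counts before/after and the threshold
#' are recorded in attributes.
#'
#' @param junctions junction table from [computeJunctions()].
#' @param threshold positive finite filter threshold (default 0.999).
#' @return the filtered junction table with attributes `filterThreshold`,
#'   `nBeforeFilter`, `nRemovedByFilter` (existing attributes preserved).
#' @export
filterJunctions <- function(junctions, threshold = 0.999) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
    !is.finite(threshold) || threshold <= 0) {
    stop("threshold must be a single positive finite number", call. = FALSE)
  }
  drop <- junctions$beta1 >= threshold | junctions$beta2 >= threshold
  out <- junctions[!drop, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("nSkippedMultifurcation", "nUndefinedGamma")) {
    attr(out, a) <- attr(junctions, a)
  }
  attr(out, "filterThreshold") <- threshold
  attr(out, "nBeforeFilter") <- nrow(junctions)
  attr(out, "nRemovedByFilter") <- sum(drop)
  out
}

#' Assemble a labeled classifier feature table
#'
#' One row per (filtered) junction. In 2D mode the features are betaMean and
#' betaDiff; 3D mode adds relLeafNumber. Gamma columns are carried through
#' for export but are never used as classifier features.
#'
#' @param junctions filtered junction table.
#' @param classLabel class label attached to every row.
#' @param features "3D" (default) or "2D".
#' @param keepGamma also keep gammaMean/gammaDiff columns (default FALSE).
#' @return data.frame with columns cellID, label, betaMean, betaDiff
#'   (+ relLeafNumber in 3D mode); filter provenance attributes preserved.
#' @export
assembleFeatureTable <- function(junctions, classLabel,
                                 features = c("3D", "2D"),
                                 keepGamma = FALSE) {
  features <- match.arg(features)
  if (nrow(junctions) == 0L) {
    stop("empty junction set: no rows to assemble", call. = FALSE)
  }
  cols <- c("betaMean", "betaDiff")
  if (features == "3D") cols <- c(cols, "relLeafNumber")
  if (keepGamma) cols <- c(cols, "gammaMean", "gammaDiff")
  out <- cbind(
    data.frame(
      cellID = junctions$cellID,
      label = as.character(classLabel),
      stringsAsFactors = FALSE
    ),
    junctions[, cols, drop = FALSE]
  )
  rownames(out) <- NULL
  for (a in c(
    "filterThreshold", "nBeforeFilter", "nRemovedByFilter",
    "nSkippedMultifurcation"
  )) {
    attr(out, a) <- attr(junctions, a)
  }
  out
}

#' Per-level feature profile (visualization aid)
#'
#' Averages betaMean and betaDiff at each distinct relLeafNumber value
#' within each cell (or each class). Used only for plotting level profiles;
#' classification always consumes the raw per-junction rows.
#'
#' @param table a 3D feature table (must contain relLeafNumber).
#' @param groupBy "cell" or "class".
#' @return data.frame: group, relLeafNumber, meanBetaMean, meanBetaDiff, n.
#' @export
levelProfile <- function(table, groupBy = c("cell", "class")) {
  groupBy <- match.arg(groupBy)
  if (nrow(table) == 0L) stop("empty feature table", call. = FALSE)
  if (!"relLeafNumber" %in% names(table)) {
    stop("level profiles require a 3D feature table (relLeafNumber column)",
      call. = FALSE
    )
  }
  g <- if (groupBy == "cell") table$cellID else table$label
  key <- interaction(g, table$relLeafNumber, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(table)), key), function(i) {
    data.frame(
      group = g[i[1L]],
      relLeafNumber = table$relLeafNumber[i[1L]],
      meanBetaMean = mean(table$betaMean[i]),
      meanBetaDiff = mean(table$betaDiff[i]),
      n = length(i)
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$group, out$relLeafNumber), , drop = FALSE]
  rownames(out) <- NULL
  out
}
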