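#' Convert a sample-level reconstruction to a branch-level tree
#'
#' Partitions the non-soma samples of a reconstruction into branches:
#' maximal unbranched chains of samples. A new branch starts at each root
#' sample (parent -1 or a soma sample) and at each child of a branch point
#' (a sample with two or more children). Soma samples (type code 1) are
#' never assigned to a branch; the first branch of each neurite starts at
#' the first non-soma sample whose parent is a soma sample or -1.
#'
#' Branch points are detected topologically (>= 2 children) rather than by
#' gaps in parent-ID numbering: the two rules agree on contiguously numbered
#' files, and the topological rule is robust to renumbering.
#'
#' @param rec a validated [Reconstruction-class].
#' @return a [BranchTree-class] with topology and sample membership filled;
#'   metric and leaf-number columns are NA until [branchMetrics()] /
#'   [computeLeafNumbers()] are applied.
#' @examples
#' spec <- arborSpec(depth = 2, seed = 1)
#' tree <- extractBranches(generateArbor(spec))
#' nBranches(tree) # 7 = 1 + 2 + 4
#' @export
extractBranches <- function(rec) {
  stopifnot(is(rec, "Reconstruction"))
  s <- rec@samples
  soma <- s$typeCode == 1L
  parentIdx <- match(s$parentID, s$sampleID) # NA for parent -1
  # children (non-soma) of every sample
  childOf <- which(!soma)
  childOf <- childOf[!is.na(parentIdx[childOf]) | TRUE] # all non-soma
  kids <- split(childOf, factor(parentIdx[childOf], levels = seq_len(nrow(s))))
  nKids <- lengths(kids)

  isStart <- !soma & (
    is.na(parentIdx) | # parent -1
      soma[ifelse(is.na(parentIdx), 1L, parentIdx)] | # parent is soma
      nKids[ifelse(is.na(parentIdx), 1L, parentIdx)] >= 2L # branch point
  )
  starts <- which(isStart)

  sampleIDs <- vector("list", 0L)
  branchOfStart <- integer(nrow(s)) # branch id by start sample index
  rows <- list()
  bid <- 0L
  for (st in starts) {
    bid <- bid + 1L
    chain <- st
    cur <- st
    repeat {
      ch <- kids[[cur]]
      if (length(ch) != 1L) break
      if (isStart[ch]) break # defensive; a single child is never a start
      chain <- c(chain, ch)
      cur <- ch
    }
    branchOfStart[st] <- bid
    sampleIDs[[bid]] <- s$sampleID[chain]
    rows[[bid]] <- data.frame(
      branchID = bid,
      parentBranchID = NA_integer_, # filled below
      typeCode = s$typeCode[st],
      nSamples = length(chain),
      startIdx = st
    )
  }
  b <- do.call(rbind, rows)
  # branch parent: branch containing the start sample's parent (if non-soma)
  lastIdxOfBranch <- vapply(
    sampleIDs, function(ids) match(ids[length(ids)], s$sampleID), integer(1)
  )
  branchOfSample <- integer(nrow(s))
  for (i in seq_len(bid)) {
    branchOfSample[match(sampleIDs[[i]], s$sampleID)] <- i
  }
  pidx <- parentIdx[b$startIdx]
  hasParent <- !is.na(pidx) & !soma[ifelse(is.na(pidx), 1L, pidx)]
  b$parentBranchID[hasParent] <- branchOfSample[pidx[hasParent]]
  b$startIdx <- NULL
  b$meanRadius <- NA_real_
  b$pathLength <- NA_real_
  b$leafNumber <- NA_integer_
  b$relLeafNumber <- NA_real_
  new("BranchTree", branches = b, sampleIDs = sampleIDs, cellID = rec@cellID)
}

#' Compute per-branch mean radius and path length
#'
#' `meanRadius` is the arithmetic mean of the branch's sample radii (the
#' per-branch radius used for the scale factors). `pathLength` is the sum of
#' Euclidean distances between consecutive samples along the branch,
#' including the segment connecting the parent branch's last sample to this
#' branch's first sample. A root branch has no connecting segment; a
#' single-sample root branch therefore has path length 0.
#'
#' @param tree a [BranchTree-class] from [extractBranches()].
#' @param rec the originating [Reconstruction-class].
#' @return the tree with `meanRadius` and `pathLength` filled.
#' @export
branchMetrics <- function(tree, rec) {
  stopifnot(is(tree, "BranchTree"), is(rec, "Reconstruction"))
  s <- rec@samples
  b <- tree@branches
  coords <- as.matrix(s[, c("x", "y", "z")])
  lastSampleID <- vapply(
    tree@sampleIDs, function(ids) ids[length(ids)], numeric(1)
  )
  for (i in seq_len(nrow(b))) {
    idx <- match(tree@sampleIDs[[i]], s$sampleID)
    b$meanRadius[i] <- mean(s$radius[idx])
    pts <- coords[idx, , drop = FALSE]
    pid <- b$parentBranchID[i]
    if (!is.na(pid)) {
      pLast <- match(lastSampleID[[match(pid, b$branchID)]], s$sampleID)
      pts <- rbind(coords[pLast, , drop = FALSE], pts)
    }
    if (nrow(pts) >= 2L) {
      d <- diff(pts)
      b$pathLength[i] <- sum(sqrt(rowSums(d * d)))
    } else {
      b$pathLength[i] <- 0
    }
  }
  initialize(tree, branches = b)
}

#' Compute leaf numbers
#'
#' The leaf number of a branch is the number of terminal tips distal to it.
#' Tips contribute 1 (a tip branch has leaf number 1), and every other
#' branch's leaf number is the sum over its children; the root branch of a
#' tree therefore carries that tree's tip count, and the cell-wide maximum
#' is recorded for normalization.
#'
#' @param tree a [BranchTree-class].
#' @return the tree with `leafNumber` filled.
#' @export
computeLeafNumbers <- function(tree) {
  stopifnot(is(tree, "BranchTree"))
  b <- tree@branches
  n <- nrow(b)
  parent <- match(b$parentBranchID, b$branchID) # NA at roots
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L
    j <- parent[i]
    while (!is.na(j)) {
      d <- d + 1L
      j <- parent[j]
    }
    depth[i] <- d
  }
  ln <- integer(n)
  hasChild <- tabulate(parent[!is.na(parent)], nbins = n) > 0L
  for (i in order(depth, decreasing = TRUE)) {
    if (!hasChild[i]) {
      ln[i] <- 1L
    }
    j <- parent[i]
    if (!is.na(j)) ln[j] <- ln[j] + ln[i]
  }
  b$leafNumber <- ln
  initialize(tree, branches = b)
}

#' Compute relative leaf numbers
#'
#' The relative leaf number of branch i is log2(Lmax / L_i), where Lmax is
#' the cell's maximum leaf number. It is 0 exactly at the branch attaining
#' Lmax (the branch closest to the soma) and grows toward the tips; tips
#' have leaf number 1, so the logarithm is always finite.
#'
#' @param tree a [BranchTree-class] with leaf numbers computed.
#' @return the tree with `relLeafNumber` filled.
#' @export
relativeLeafNumbers <- function(tree) {
  stopifnot(is(tree, "BranchTree"))
  ln <- tree@branches$leafNumber
  if (anyNA(ln)) {
    stop("leaf numbers must be computed first (computeLeafNumbers)",
      call. = FALSE
    )
  }
  b <- tree@branches
  b$relLeafNumber <- log2(max(ln) / ln)
  initialize(tree, branches = b)
}

#' Build a fully annotated branch tree in one call
#'
#' Chains [extractBranches()], [branchMetrics()], [computeLeafNumbers()] and
#' [relativeLeafNumbers()].
#'
#' @param rec a validated [Reconstruction-class].
#' @return a fully annotated [BranchTree-class].
#' @export
buildBranchTree <- function(rec) {
  tree <- extractBranches(rec)
  tree <- branchMetrics(tree, rec)
  tree <- computeLeafNumbers(tree)
  relativeLeafNumbers(tree)
}

#' Export the branch table as a plain data frame
#'
#' @param tree a [BranchTree-class].
#' @param path optional CSV path; when given the table is also written.
#' @return the branch table (invisibly when `path` is given).
#' @export
exportBranchTable <- function(tree, path = NULL) {
  stopifnot(is(tree, "BranchTree"))
  tab <- tree@branches
  tab <- cbind(cellID = tree@cellID, tab)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @rdname BranchTree-class
#' @export
setMethod("branchTable", "BranchTree", function(x) x@branches)

#' @rdname BranchTree-class
#' @export
setMethod("nBranches", "BranchTree", function(x) nrow(x@branches))

#' @rdname BranchTree-class
#' @export
setMethod("branchChildren", "BranchTree", function(x) {
  b <- x@branches
  lapply(b$branchID, function(id) {
    b$branchID[!is.na(b$parentBranchID) & b$parentBranchID == id]
  })
})

#' @rdname BranchTree-class
#' @export
setMethod("tips", "BranchTree", function(x) {
  b <- x@branches
  withKids <- unique(b$parentBranchID[!is.na(b$parentBranchID)])
  b$branchID[!(b$branchID %in% withKids)]
})

#' @rdname BranchTree-class
#' @export
setMethod("leafNumbers", "BranchTree", function(x) {
  stats::setNames(x@branches$leafNumber, x@branches$branchID)
})

#' @rdname BranchTree-class
#' @export
setMethod("maxLeafNumber", "BranchTree", function(x) {
  max(x@branches$leafNumber)
})

#' @rdname BranchTree-class
#' @export
setMethod("relLeafNumbers", "BranchTree", function(x) {
  stats::setNames(x@branches$relLeafNumber, x@branches$branchID)
})

setMethod("show", "BranchTree", function(object) {
  b <- object@branches
  cat(sprintf(
    "BranchTree '%s': %d branches, %d tip(s), %d root(s)%s\n",
    object@cellID, nrow(b), length(tips(object)),
    sum(is.na(b$parentBranchID)),
    if (all(is.na(b$leafNumber))) {
      ""
    } else {
      sprintf(", max leaf number %d", max(b$leafNumber))
    }
  ))
})
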