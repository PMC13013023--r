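.asProfile <- function(p, depth) {
  if (is.function(p)) {
    return(p)
  }
  if (is.numeric(p)) {
    v <- rep_len(p, depth)
    return(function(g) v[g + 1L])
  }
  stop("profile must be a function or numeric", call. = FALSE)
}

#' Construct an arbor specification
#'
#' Builds a validated [ArborSpec-class]. Profiles may be given as a single
#' number (constant across levels), a numeric vector over generations
#' 0..depth-1 (recycled), or a function of the 0-based junction generation.
#' For the complete binary tree the generation of a junction equals the
#' relative leaf number of its parent branch, so level-dependent profiles
#' directly encode a feature-vs-level relationship.
#'
#' Defaults emulate a mid-size dendritic arbor: 6 branch generations (64
#' tips), root radius 1 um, root length 40 um, beta-bar 0.7, |Delta-beta|
#' 0.1, symmetric lengths with gamma-bar 0.8, ratio noise SD 0.02, 5 samples
#' per branch, no pixel quantization.
#'
#' @param depth branch generations below the root branch.
#' @param rootRadius,rootLength root branch radius/length, micrometres.
#' @param betaMeanProfile,betaDiffProfile scale-factor profiles (see
#'   Details).
#' @param gammaMean,gammaDiff length-ratio mean and half-difference.
#' @param noiseSD SD of additive per-junction ratio noise.
#' @param samplesPerBranch SWC samples per branch.
#' @param pixelSize radius quantization floor (0 = off).
#' @param typeCode SWC type code for non-soma samples (3 = dendrite).
#' @param seed RNG seed.
#' @return an [ArborSpec-class].
#' @export
arborSpec <- function(depth = 6, rootRadius = 1, rootLength = 40,
                      betaMeanProfile = 0.7, betaDiffProfile = 0.1,
                      gammaMean = 0.8, gammaDiff = 0,
                      noiseSD = 0.02, samplesPerBranch = 5,
                      pixelSize = 0, typeCode = 3, seed = 1) {
  new("ArborSpec",
    depth = as.integer(depth),
    rootRadius = rootRadius, rootLength = rootLength,
    betaMeanProfile = .asProfile(betaMeanProfile, as.integer(depth)),
    betaDiffProfile = .asProfile(betaDiffProfile, as.integer(depth)),
    gammaMean = gammaMean, gammaDiff = gammaDiff,
    noiseSD = noiseSD,
    samplesPerBranch = as.integer(samplesPerBranch),
    pixelSize = pixelSize,
    typeCode = as.integer(typeCode),
    seed = as.integer(seed)
  )
}

# clip daughter ratios so radii stay positive and strictly below the
# resolution-filter threshold; returns c(b1, b2, nClipped)
.clipPair <- function(b1, b2, lo = 0.01, hi = 0.999 * 0.999) {
  n <- 0L
  if (b1 < lo || b1 > hi) {
    b1 <- min(max(b1, lo), hi)
    n <- n + 1L
  }
  if (b2 < lo || b2 > hi) {
    b2 <- min(max(b2, lo), hi)
    n <- n + 1L
  }
  c(b1, b2, n)
}

# unit vectors orthogonal to d
.orthobasis <- function(d) {
  a <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * d) * d
  u <- u / sqrt(sum(u * u))
  v <- c(
    d[2L] * u[3L] - d[3L] * u[2L],
    d[3L] * u[1L] - d[1L] * u[3L],
    d[1L] * u[2L] - d[2L] * u[1L]
  )
  list(u = u, v = v)
}

#' Generate a synthetic arbor
#'
#' Builds a complete binary tree of `depth` branch generations as a valid
#' SWC reconstruction. Each junction at generation g draws a mean and a
#' (signed) difference scale factor around the profile values with
#' truncated-normal noise of SD `noiseSD` (clipped so daughter ratios stay
#' in (0.01, 0.998), clip events counted in the `"nClipped"` attribute),
#' and sets daughter radii r(beta-bar +/- Delta-beta) and lengths
#' l(gamma-bar +/- Delta-gamma), the "+" going to the longer daughter.
#' Branches are discretized into `samplesPerBranch` collinear samples of
#' constant radius; when `noiseSD > 0` interior samples get a small
#' perpendicular jitter. A single soma sample (type 1) roots the arbor.
#' Output is deterministic given the seed (the caller's RNG state is left
#' untouched), and radii are pixel-quantized when `pixelSize > 0`.
#'
#' @param spec an [ArborSpec-class].
#' @param cellID cell identifier (default "synthetic").
#' @param label optional class label.
#' @return a [Reconstruction-class] with attribute `nClipped`.
#' @examples
#' rec <- generateArbor(arborSpec(depth = 3, noiseSD = 0, seed = 7))
#' tree <- buildBranchTree(rec)
#' maxLeafNumber(tree) # 8 tips
#' @export
generateArbor <- function(spec, cellID = "synthetic", label = NA_character_) {
  stopifnot(is(spec, "ArborSpec"))
  validObject(spec)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(spec@seed)
  nsb <- spec@samplesPerBranch
  branchAngle <- 35 * pi / 180
  nClipped <- 0L

  samples <- list()
  nextID <- 1L
  addSample <- function(type, p, r, parent) {
    samples[[nextID]] <<- c(nextID, type, p[1L], p[2L], p[3L], r, parent)
    id <- nextID
    nextID <<- nextID + 1L
    id
  }
  somaID <- addSample(1L, c(0, 0, 0), spec@rootRadius, -1L)

  # queue of branches to realize: generation, radius, length, start point,
  # direction, parent sample id, isRoot
  emitBranch <- function(gen, r, len, start, dir, parentSample, isRoot) {
    if (isRoot) {
      offs <- seq(0, len, length.out = nsb)
    } else {
      offs <- seq(len / nsb, len, length.out = nsb)
    }
    jitterSD <- if (spec@noiseSD > 0) 0.02 * len else 0
    ob <- .orthobasis(dir)
    prev <- parentSample
    lastPoint <- start
    for (i in seq_len(nsb)) {
      p <- start + offs[i] * dir
      if (jitterSD > 0 && i > 1L && i < nsb) {
        p <- p + stats::rnorm(1, 0, jitterSD) * ob$u +
          stats::rnorm(1, 0, jitterSD) * ob$v
      }
      prev <- addSample(spec@typeCode, p, r, prev)
      if (i == nsb) lastPoint <- p
    }
    list(lastSample = prev, end = lastPoint)
  }

  queue <- list(list(
    gen = 0L, r = spec@rootRadius, len = spec@rootLength,
    start = c(0, 0, 0), dir = c(0, 0, 1),
    parentSample = somaID, isRoot = TRUE
  ))
  while (length(queue) > 0L) {
    br <- queue[[1L]]
    queue <- queue[-1L]
    got <- emitBranch(
      br$gen, br$r, br$len, br$start, br$dir, br$parentSample, br$isRoot
    )
    if (br$gen < spec@depth) {
      g <- br$gen
      bm <- spec@betaMeanProfile(g) + stats::rnorm(1, 0, spec@noiseSD)
      bd <- spec@betaDiffProfile(g) + stats::rnorm(1, 0, spec@noiseSD)
      cl <- .clipPair(bm + bd, bm - bd)
      nClipped <- nClipped + cl[3L]
      radii <- cl[1:2] * br$r # daughter 1 (longer) first
      lens <- c(
        spec@gammaMean + spec@gammaDiff,
        spec@gammaMean - spec@gammaDiff
      ) * br$len
      phi <- stats::runif(1, 0, 2 * pi)
      ob <- .orthobasis(br$dir)
      for (d in 1:2) {
        ang <- phi + (d - 1) * pi
        dirD <- cos(branchAngle) * br$dir +
          sin(branchAngle) * (cos(ang) * ob$u + sin(ang) * ob$v)
        dirD <- dirD / sqrt(sum(dirD^2))
        queue[[length(queue) + 1L]] <- list(
          gen = br$gen + 1L, r = radii[d], len = lens[d],
          start = got$end, dir = dirD,
          parentSample = got$lastSample, isRoot = FALSE
        )
      }
    }
  }
  m <- do.call(rbind, samples)
  rec <- new("Reconstruction",
    samples = data.frame(
      sampleID = as.integer(m[, 1L]), typeCode = as.integer(m[, 2L]),
      x = m[, 3L], y = m[, 4L], z = m[, 5L],
      radius = m[, 6L], parentID = as.integer(m[, 7L])
    ),
    cellID = cellID, label = as.character(label),
    source = sprintf("branchflow generator, seed %d", spec@seed)
  )
  if (spec@pixelSize > 0) rec <- quantizeRadii(rec, spec@pixelSize)
  attr(rec, "nClipped") <- nClipped
  rec
}

#' Quantize radii to a pixel grid
#'
#' Emulates the resolution limit of traced images: every radius is replaced
#' by `max(pixelSize, pixelSize * round(r / pixelSize))`, so radii below the
#' pixel size saturate at the pixel size. Deep branches whose true radii
#' fall below the floor become equal-radius, producing junction scale
#' factors of exactly 1 — the artifact that [filterJunctions()] removes at
#' the 0.999 threshold. `pixelSize = 0` is the identity.
#'
#' @param rec a [Reconstruction-class].
#' @param pixelSize pixel size in micrometres (>= 0).
#' @return the quantized [Reconstruction-class].
#' @export
quantizeRadii <- function(rec, pixelSize) {
  stopifnot(is(rec, "Reconstruction"))
  if (length(pixelSize) != 1L || !is.finite(pixelSize) || pixelSize < 0) {
    stop("pixelSize must be a single number >= 0", call. = FALSE)
  }
  if (pixelSize == 0) {
    return(rec)
  }
  s <- rec@samples
  s$radius <- pmax(pixelSize, pixelSize * round(s$radius / pixelSize))
  initialize(rec, samples = s)
}

#' Construct a cohort specification
#'
#' @param classSpecs named list mapping class label to [ArborSpec-class].
#' @param nCellsPerClass cells per class (>= 2).
#' @param seed cohort master seed.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(classSpecs, nCellsPerClass = 10, seed = 1) {
  new("CohortSpec",
    classSpecs = classSpecs,
    nCellsPerClass = as.integer(nCellsPerClass),
    seed = as.integer(seed)
  )
}

#' Generate a labeled cohort of synthetic arbors
#'
#' Generates `nCellsPerClass` reconstructions per class. Per-cell seeds are
#' derived from the cohort seed by a counter-based rule (class index and
#' cell index), so any cell can be regenerated independently and the cohort
#' is reproducible regardless of generation order.
#'
#' @param cohort a [CohortSpec-class].
#' @return named list of [Reconstruction-class] objects (names = cell IDs),
#'   with a `manifest` attribute: data.frame(cellID, label, seed).
#' @export
generateCohort <- function(cohort) {
  stopifnot(is(cohort, "CohortSpec"))
  validObject(cohort)
  labs <- names(cohort@classSpecs)
  recs <- list()
  manifest <- list()
  for (ci in seq_along(labs)) {
    lab <- labs[ci]
    spec <- cohort@classSpecs[[ci]]
    for (i in seq_len(cohort@nCellsPerClass)) {
      cellSeed <- as.integer(
        (as.numeric(cohort@seed) + 1299709 * (ci - 1) + 104729 * i) %%
          2147483647
      )
      spec@seed <- cellSeed
      cid <- sprintf("%s_%03d", lab, i)
      recs[[cid]] <- generateArbor(spec, cellID = cid, label = lab)
      manifest[[cid]] <- data.frame(
        cellID = cid, label = lab, seed = cellSeed
      )
    }
  }
  man <- do.call(rbind, manifest)
  rownames(man) <- NULL
  attr(recs, "manifest") <- man
  recs
}

#' Feature tables for a whole cohort
#'
#' Convenience pipeline: for every reconstruction of a generated cohort,
#' build the branch tree, compute and filter junctions, and stack the
#' labeled feature rows per class.
#'
#' @param recs output of [generateCohort()].
#' @param threshold resolution-filter threshold (default 0.999).
#' @param features "3D" (default) or "2D".
#' @return named list (class label -> feature table).
#' @export
cohortFeatureTables <- function(recs, threshold = 0.999, features = "3D") {
  man <- attr(recs, "manifest")
  stopifnot(!is.null(man))
  tabs <- list()
  for (cid in man$cellID) {
    rec <- recs[[cid]]
    j <- filterJunctions(
      computeJunctions(buildBranchTree(rec)),
      threshold = threshold
    )
    lab <- man$label[man$cellID == cid]
    tabs[[cid]] <- assembleFeatureTable(j, lab, features = features)
  }
  byLab <- split(tabs, man$label)
  lapply(byLab, function(ts) {
    out <- do.call(rbind, ts)
    rownames(out) <- NULL
    out
  })
}
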