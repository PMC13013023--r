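#' Read an SWC morphology file
#'
#' Parses a standard SWC file (whitespace-separated 7-column records:
#' sample ID, type code, x, y, z, radius, parent ID; '#' comment lines and
#' blank lines skipped) into a validated [Reconstruction-class]. Sample
#' order is preserved and IDs are not renumbered. Coordinates and radii are
#' taken to be micrometres, IDs 1-based as in standard SWC.
#'
#' Samples with radius <= 0 cause the file to be rejected rather than
#' silently repaired: repaired radii would bias the daughter/parent scale
#' factors, and genuine resolution artifacts are handled downstream by the
#' beta >= 0.999 junction filter. Multiple roots (parent -1) are allowed;
#' each starts its own tree.
#'
#' @param path path to the SWC file.
#' @param cellID cell identifier; defaults to the file name without
#'   extension.
#' @param label optional class label attached to the reconstruction.
#' @param quiet suppress the parsed-sample-count message.
#' @return a [Reconstruction-class].
#' @examples
#' tf <- tempfile(fileext = ".swc")
#' writeLines(c(
#'   "# toy cell",
#'   "1 1 0 0 0 1.0 -1",
#'   "2 3 0 0 1 0.5 1",
#'   "3 3 0 0 2 0.5 2"
#' ), tf)
#' rec <- readSWC(tf, cellID = "toy")
#' nrow(swcSamples(rec))
#' @export
readSWC <- function(path, cellID = NULL, label = NA_character_,
                    quiet = FALSE) {
  if (!file.exists(path)) {
    stop("SWC file not found: ", path, call. = FALSE)
  }
  if (is.null(cellID)) {
    cellID <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, "#")
  lineNo <- which(keep)
  if (length(lineNo) == 0L) {
    stop("no data lines in SWC file: ", path, call. = FALSE)
  }
  fields <- strsplit(trimmed[keep], "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- lineNo[which(nf != 7L)[1L]]
    stop(sprintf(
      "malformed SWC record at line %d of %s: expected 7 fields, found %d",
      bad, path, nf[which(nf != 7L)[1L]]
    ), call. = FALSE)
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  )
  if (anyNA(m)) {
    bad <- lineNo[which(rowSums(is.na(m)) > 0)[1L]]
    stop(sprintf(
      "non-numeric field at line %d of %s", bad, path
    ), call. = FALSE)
  }
  samples <- data.frame(
    sampleID = as.integer(m[, 1L]),
    typeCode = as.integer(m[, 2L]),
    x = m[, 3L], y = m[, 4L], z = m[, 5L],
    radius = m[, 6L],
    parentID = as.integer(m[, 7L])
  )
  rec <- new("Reconstruction",
    samples = samples, cellID = cellID,
    label = as.character(label), source = path
  )
  if (!quiet) {
    message(sprintf(
      "readSWC: parsed %d samples from %s (cell '%s')",
      nrow(samples), basename(path), cellID
    ))
  }
  rec
}

#' Write a reconstruction to an SWC file
#'
#' Writes the standard 7-column SWC format, with a comment header recording
#' the cell ID, label and writer. Radii and coordinates are printed with 17
#' significant digits, so `readSWC(writeSWC(rec))` reproduces the sample
#' table exactly (bit-for-bit at double precision).
#'
#' @param rec a [Reconstruction-class] with at least one sample.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSWC <- function(rec, path) {
  stopifnot(is(rec, "Reconstruction"))
  s <- rec@samples
  if (nrow(s) == 0L) {
    stop("cannot write an empty reconstruction", call. = FALSE)
  }
  header <- c(
    "# SWC written by branchflow",
    sprintf("# cell_id: %s", rec@cellID),
    sprintf("# label: %s", rec@label),
    sprintf("# source: %s", rec@source)
  )
  body <- sprintf(
    "%d %d %.17g %.17g %.17g %.17g %d",
    s$sampleID, s$typeCode, s$x, s$y, s$z, s$radius, s$parentID
  )
  ok <- tryCatch(
    {
      writeLines(c(header, body), path)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stop("cannot write SWC file: ", path, call. = FALSE)
  invisible(path)
}

#' Restrict a reconstruction to selected structure types
#'
#' Keeps samples whose SWC type code is in `structureTypes`, plus all soma
#' samples (type 1), which may be needed as roots and are never assigned to
#' branches anyway. Non-soma samples whose parent was removed are re-rooted
#' (parent set to -1), so each orphaned subtree starts its own tree. The
#' counts of removed samples are recorded in the `"nRemoved"` attribute.
#'
#' By default all non-soma types present in the file are analyzed; restrict
#' to e.g. `structureTypes = 3:4` to analyze dendrites only.
#'
#' @param rec a [Reconstruction-class].
#' @param structureTypes integer vector of SWC type codes to retain
#'   (default: all non-soma types present).
#' @return a validated, restricted [Reconstruction-class] with attribute
#'   `nRemoved`.
#' @export
validateReconstruction <- function(rec, structureTypes = NULL) {
  stopifnot(is(rec, "Reconstruction"))
  s <- rec@samples
  if (is.null(structureTypes)) {
    structureTypes <- setdiff(unique(s$typeCode), 1L)
  }
  keep <- s$typeCode %in% structureTypes | s$typeCode == 1L
  out <- s[keep, , drop = FALSE]
  if (sum(out$typeCode != 1L) == 0L) {
    stop(sprintf(
      "empty selection: no samples of type(s) %s in cell '%s'",
      paste(structureTypes, collapse = ", "), rec@cellID
    ), call. = FALSE)
  }
  # re-root subtrees whose parent was removed
  orphan <- out$parentID != -1L & !(out$parentID %in% out$sampleID)
  out$parentID[orphan] <- -1L
  res <- new("Reconstruction",
    samples = out, cellID = rec@cellID,
    label = rec@label, source = rec@source
  )
  attr(res, "nRemoved") <- nrow(s) - nrow(out)
  res
}

#' @rdname Reconstruction-class
#' @export
setMethod("swcSamples", "Reconstruction", function(x) x@samples)

#' @rdname Reconstruction-class
#' @export
setMethod("cellID", "Reconstruction", function(x) x@cellID)

#' @rdname Reconstruction-class
#' @export
setMethod("cellLabel", "Reconstruction", function(x) x@label)

setMethod("show", "Reconstruction", function(object) {
  s <- object@samples
  nroot <- sum(s$parentID == -1L)
  cat(sprintf(
    "Reconstruction '%s': %d samples, %d root(s), types {%s}%s\n",
    object@cellID, nrow(s), nroot,
    paste(sort(unique(s$typeCode)), collapse = ","),
    if (is.na(object@label)) "" else sprintf(", label '%s'", object@label)
  ))
})
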