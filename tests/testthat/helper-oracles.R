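# Independent oracles and tiny fixture builders used across the suite.

# write SWC lines to a temp file and parse them
swcFromLines <- function(lines, cellID = "fixture", label = NA_character_) {
  tf <- tempfile(fileext = ".swc")
  writeLines(lines, tf)
  readSWC(tf, cellID = cellID, label = label, quiet = TRUE)
}

# Y-shape: 3-sample root chain whose last sample has two 2-sample children
ySwcLines <- c(
  "1 3 0 0 0 1.0 -1",
  "2 3 0 0 1 1.0 1",
  "3 3 0 0 2 1.0 2",
  "4 3 1 0 3 0.8 3",
  "5 3 2 0 4 0.8 4",
  "6 3 -1 0 3 0.6 3",
  "7 3 -2 0 4 0.6 6"
)

# brute-force leaf counts: count tips reachable from every branch
oracleLeafCounts <- function(tree) {
  b <- branchTable(tree)
  kids <- branchChildren(tree)
  countTips <- function(pos) {
    ch <- kids[[pos]]
    if (length(ch) == 0L) {
      return(1L)
    }
    sum(vapply(match(ch, b$branchID), countTips, integer(1)))
  }
  vapply(seq_len(nrow(b)), countTips, integer(1))
}

# exhaustive pair-counting AUC (ties count 1/2)
oracleAucPairCount <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) {
    s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  }
  s / (length(pos) * length(neg))
}

# loop-free closed form for a uniform schedule with per-level bracket f
oraclePowerUniform <- function(f, N, R = 1) {
  if (abs(f - 1) < 1e-14) {
    return(R * (N + 1))
  }
  R * (f^(N + 1) - 1) / (f - 1)
}

# a small two-class cohort whose classes differ only in where (by
# generation) the mean scale factor is high vs low; pooled 2D marginals are
# matched up to one junction per cell
gliaLikeSpecs <- function(depth = 6, lowBeta = 0.55, highBeta = 0.75,
                          noiseSD = 0.05) {
  pa <- function(g) ifelse(g < depth - 1, lowBeta, highBeta)
  pb <- function(g) ifelse(g < depth - 1, highBeta, lowBeta)
  list(
    A = arborSpec(
      depth = depth, betaMeanProfile = pa, betaDiffProfile = 0.1,
      noiseSD = noiseSD, seed = 1
    ),
    B = arborSpec(
      depth = depth, betaMeanProfile = pb, betaDiffProfile = 0.1,
      noiseSD = noiseSD, seed = 2
    )
  )
}
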