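test_that("branch extraction handles chains, Y-shapes and complete trees", {
  # unbranched 10-sample chain -> one branch, one tip
  chain <- swcFromLines(sprintf(
    "%d 3 0 0 %d 1.0 %d", 1:10, 0:9, c(-1L, 1:9)
  ))
  tr <- extractBranches(chain)
  expect_equal(nBranches(tr), 1L)
  expect_equal(length(tips(tr)), 1L)

  # Y-shape: 7 samples -> 3 branches, 2 tips, root is parent of both
  tr <- extractBranches(swcFromLines(ySwcLines))
  b <- branchTable(tr)
  expect_equal(nBranches(tr), 3L)
  expect_equal(length(tips(tr)), 2L)
  root <- b$branchID[is.na(b$parentBranchID)]
  expect_length(root, 1L)
  expect_equal(sum(b$parentBranchID == root, na.rm = TRUE), 2L)
  expect_equal(sort(lengths(tr@sampleIDs)), c(2L, 2L, 3L))

  # complete binary tree, branch depth 3 below the root branch
  rec <- generateArbor(arborSpec(depth = 3, seed = 2))
  tr <- extractBranches(rec)
  expect_equal(nBranches(tr), 15L)
  expect_equal(length(tips(tr)), 8L)
})

test_that("soma samples are never assigned to branches", {
  rec <- generateArbor(arborSpec(depth = 2, seed = 3))
  tr <- extractBranches(rec)
  s <- swcSamples(rec)
  somaIDs <- s$sampleID[s$typeCode == 1L]
  expect_false(any(somaIDs %in% unlist(tr@sampleIDs)))
  # sample partition: every non-soma sample in exactly one branch
  nonSoma <- s$sampleID[s$typeCode != 1L]
  expect_setequal(unlist(tr@sampleIDs), nonSoma)
  expect_equal(sum(lengths(tr@sampleIDs)), length(nonSoma))
})

test_that("branch metrics average radii and accumulate path length", {
  # root sample at z = -1 with two daughters: one straight 3-sample branch
  # at z = 0,1,2, one 2-sample branch with radii 0.5 and 0.7
  rec <- swcFromLines(c(
    "1 3 0 0 -1 1.0 -1",
    "2 3 0 0 0 0.5 1",
    "3 3 0 0 1 0.7 2",
    "4 3 0 0 2 0.9 3",
    "5 3 1 0 -1 0.5 1",
    "6 3 2 0 -1 0.7 5"
  ))
  tr <- branchMetrics(extractBranches(rec), rec)
  b <- branchTable(tr)
  straight <- which(vapply(tr@sampleIDs, function(i) 2L %in% i, logical(1)))
  expect_equal(b$pathLength[straight], 3.0)
  pair <- which(vapply(tr@sampleIDs, function(i) 5L %in% i, logical(1)))
  expect_equal(b$meanRadius[pair], 0.6)
  # single-sample root branch has path length 0
  lone <- swcFromLines("1 3 0 0 0 1.0 -1")
  expect_equal(branchTable(branchMetrics(extractBranches(lone), lone))$pathLength, 0)
  # constant per-branch generator radius is recovered exactly
  rec <- generateArbor(arborSpec(depth = 2, noiseSD = 0, seed = 1))
  tr <- branchMetrics(extractBranches(rec), rec)
  s <- swcSamples(rec)
  for (i in seq_len(nBranches(tr))) {
    r <- unique(s$radius[match(tr@sampleIDs[[i]], s$sampleID)])
    expect_length(r, 1L)
    expect_identical(branchTable(tr)$meanRadius[i], r)
  }
})

test_that("leaf numbers: tips count one, parents sum children, roots carry
           tip totals", {
  rec <- generateArbor(arborSpec(depth = 3, seed = 5))
  tr <- computeLeafNumbers(extractBranches(rec))
  b <- branchTable(tr)
  # parent of two terminal tips has leaf number 2
  kids <- branchChildren(tr)
  tipIDs <- tips(tr)
  bothTips <- vapply(
    kids, function(k) length(k) == 2L && all(k %in% tipIDs), logical(1)
  )
  expect_true(any(bothTips))
  expect_true(all(b$leafNumber[bothTips] == 2L))
  # root of the complete 8-tip tree has leaf number 8
  expect_equal(maxLeafNumber(tr), 8L)
  expect_equal(b$leafNumber[is.na(b$parentBranchID)], 8L)
  # unbranched chain: single branch with leaf number 1
  chain <- swcFromLines(sprintf("%d 3 0 0 %d 1 %d", 1:4, 0:3, c(-1L, 1:3)))
  expect_equal(maxLeafNumber(computeLeafNumbers(extractBranches(chain))), 1L)
})

test_that("leaf-number conservation, root totals, monotonicity and the
           brute-force oracle hold on generated arbors", {
  for (seed in 1:4) {
    set.seed(seed)
    rec <- generateArbor(
      arborSpec(depth = sample(2:4, 1), noiseSD = 0.05, seed = seed)
    )
    tr <- computeLeafNumbers(extractBranches(rec))
    tr <- relativeLeafNumbers(tr)
    b <- branchTable(tr)
    kids <- branchChildren(tr)
    idx <- function(ids) match(ids, b$branchID)
    for (i in seq_len(nrow(b))) {
      if (length(kids[[i]]) > 0L) {
        # conservation at every internal branch
        expect_equal(
          b$leafNumber[i], sum(b$leafNumber[idx(kids[[i]])])
        )
        # monotone non-increasing toward children
        expect_true(all(b$leafNumber[idx(kids[[i]])] <= b$leafNumber[i]))
        # relative leaf number non-decreasing root -> tip
        expect_true(
          all(b$relLeafNumber[idx(kids[[i]])] >= b$relLeafNumber[i])
        )
      }
    }
    # sum of root leaf numbers equals the number of tips
    expect_equal(
      sum(b$leafNumber[is.na(b$parentBranchID)]), length(tips(tr))
    )
    # independent reachable-tip count from every branch
    expect_equal(b$leafNumber, oracleLeafCounts(tr))
  }
})

test_that("relative leaf numbers normalize by the cell maximum", {
  rec <- generateArbor(arborSpec(depth = 3, seed = 9))
  tr <- relativeLeafNumbers(computeLeafNumbers(extractBranches(rec)))
  b <- branchTable(tr)
  expect_equal(b$relLeafNumber[which.max(b$leafNumber)], 0)
  expect_equal(b$relLeafNumber[b$leafNumber == 2L], rep(2, 4))
  expect_equal(b$relLeafNumber[b$leafNumber == 4L], rep(1, 2))
  expect_true(all(b$relLeafNumber >= 0))
  # requires leaf numbers first
  expect_error(
    relativeLeafNumbers(extractBranches(rec)), "leaf numbers"
  )
})

test_that("multifurcations create one daughter branch per child", {
  tri <- swcFromLines(c(
    "1 3 0 0 0 1.0 -1",
    "2 3 0 0 1 1.0 1",
    "3 3 1 0 2 0.5 2",
    "4 3 -1 0 2 0.5 2",
    "5 3 0 1 2 0.5 2"
  ))
  tr <- computeLeafNumbers(extractBranches(tri))
  expect_equal(nBranches(tr), 4L)
  expect_equal(length(tips(tr)), 3L)
  expect_equal(maxLeafNumber(tr), 3L)
})
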