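# The detection regime emulates chimeras that switch between a nearly
# identical within-clade relative and a distant-clade donor (the situation in
# which recombinant recognition genes are recognisable at all).

test_that("window profiles identify the nearest relative per window", {
  set.seed(1)
  tr <- twoCladeTree()
  m <- simulateAlignment(tr, 600, 0.8)
  prof <- windowProfiles(m, focal = "a1", window = 100, step = 50)
  # a1's closest row must be an a-clade member in essentially every window
  best <- do.call(rbind, lapply(split(prof, prof$start), function(d)
    d[which.min(d$dist), ]))
  expect_gte(mean(startsWith(best$other, "a")), 0.95)
  expect_error(windowProfiles(m, focal = "zz"), "not in the alignment")
  expect_error(windowProfiles(m, focal = "a1", window = 10), "window")
})

test_that("window profiles localize a chimeric switch", {
  set.seed(2)
  tr <- twoCladeTree()
  m <- simulateAlignment(tr, 600, 0.8)
  m["a1", 301:600] <- m["b1", 301:600]
  prof <- windowProfiles(m, focal = "a1", window = 100, step = 100)
  best <- do.call(rbind, lapply(split(prof, prof$start), function(d)
    d[which.min(d$dist), ]))
  best <- best[order(best$start), ]
  left <- best$other[best$end <= 300]
  right <- best$other[best$start >= 300]
  expect_true(all(startsWith(left, "a")))
  expect_true(all(startsWith(right, "b")))
})

test_that("segmentation recovers a planted recombination block", {
  set.seed(7)
  tr <- twoCladeTree()
  hits <- 0L; errs <- c()
  for (i in 1:12) {
    m <- simulateAlignment(tr, 900, 0.8)
    m["a1", 301:600] <- m["b1", 301:600]
    bp <- segmentAlignment(m, maxBreakpoints = 4)
    if (length(bp$breakpoints) >= 2) {
      e1 <- min(abs(bp$breakpoints - 300))
      e2 <- min(abs(bp$breakpoints - 600))
      errs <- c(errs, e1, e2)
      if (e1 <= 10 && e2 <= 10) hits <- hits + 1L
    }
    # the recombinant's nearest relative switches between flanking segments
    if (length(bp$breakpoints)) {
      asg <- bp$assignments["a1", ]
      expect_gte(length(unique(asg)), 2L)
    }
  }
  expect_gte(hits / 12, 0.7)
  expect_lte(stats::median(errs), 10)
})

test_that("segmentation is clean on recombination-free alignments", {
  set.seed(8)
  tr <- twoCladeTree()
  fp <- replicate(10, {
    m <- simulateAlignment(tr, 900, 0.8)
    length(segmentAlignment(m, maxBreakpoints = 4)$breakpoints) > 0
  })
  expect_lte(mean(fp), 0.2)
})

test_that("an infinite penalty forbids breakpoints", {
  set.seed(9)
  m <- simulateAlignment(twoCladeTree(), 600, 0.8)
  m["a1", 201:400] <- m["b1", 201:400]
  bp <- segmentAlignment(m, maxBreakpoints = 4, penalty = Inf)
  expect_length(bp$breakpoints, 0L)
  expect_error(segmentAlignment(m, maxBreakpoints = -1), "maxBreakpoints")
})

test_that("segments partition the alignment and cost is monotone in the cap", {
  set.seed(10)
  m <- simulateAlignment(twoCladeTree(), 900, 0.8)
  m["a1", 301:600] <- m["b1", 301:600]
  prev <- Inf
  for (k in 0:3) {
    bp <- segmentAlignment(m, maxBreakpoints = k)
    expect_equal(bp$segments$start[1], 0)
    expect_equal(bp$segments$end[nrow(bp$segments)], ncol(m))
    if (nrow(bp$segments) > 1)
      expect_identical(bp$segments$start[-1],
                       bp$segments$end[-nrow(bp$segments)])
    expect_lte(bp$cost, prev + 1e-9)
    prev <- bp$cost
  }
})

test_that("the permutation filter keeps true breakpoints and is reproducible", {
  set.seed(11)
  m <- simulateAlignment(twoCladeTree(), 900, 0.8)
  m["a1", 301:600] <- m["b1", 301:600]
  bp <- segmentAlignment(m, maxBreakpoints = 4)
  expect_gte(length(bp$breakpoints), 2L)
  r1 <- testBreakpointSignificance(m, bp, nPerm = 29, seed = 5)
  r2 <- testBreakpointSignificance(m, bp, nPerm = 29, seed = 5)
  expect_identical(r1$pvalues, r2$pvalues)
  expect_true(all(r1$pvalues <= 0.05))
  expect_setequal(r1$significant, r1$breakpoints)
  expect_error(testBreakpointSignificance(m, bp, nPerm = 5), "at least 20")
})

test_that("permutation p-values are roughly uniform on linkage-free data", {
  set.seed(12)
  ps <- sapply(1:12, function(i) {
    m <- simulateAlignment(twoCladeTree(), 600, 0.8)
    m <- m[, sample.int(ncol(m))]     # destroy any residual linkage
    b1 <- segmentAlignment(m, maxBreakpoints = 1, penalty = 0,
                           minSegment = 100)
    if (!length(b1$breakpoints)) return(NA)
    testBreakpointSignificance(m, b1, nPerm = 29, seed = 100 + i)$pvalues[1]
  })
  ps <- ps[!is.na(ps)]
  expect_gte(length(ps), 8)
  expect_gt(mean(ps), 0.2)   # not systematically significant
  expect_lte(mean(ps <= 0.05), 0.25)
})
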