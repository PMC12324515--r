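randomLocus <- function(n, gc = 0.23, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

test_that("a locus aligned to itself gives one full-length forward block", {
  s <- randomLocus(8000)
  bl <- anchorAlign(s, s)
  top <- bl[which.max(bl$columns), ]
  expect_equal(top$orientation, "forward")
  expect_equal(top$aStart, 0)
  expect_equal(top$aEnd, 8000)
  expect_equal(top$identity, 1.0)
})

test_that("a locus aligned to its reverse complement gives one inverted block", {
  s <- randomLocus(6000, seed = 2)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  bl <- anchorAlign(s, rc)
  top <- bl[which.max(bl$columns), ]
  expect_equal(top$orientation, "inverted")
  expect_equal(top$columns, 6000L)
  expect_equal(top$identity, 1.0)
  expect_equal(top$bStart, 0)
  expect_equal(top$bEnd, 6000)
})

test_that("a shared 95%-identity island is found within +-50 bp", {
  set.seed(3)
  a <- randomLocus(9000, seed = 31)
  b <- randomLocus(9000, seed = 32)
  island <- substr(a, 4001, 5000)
  b <- paste0(substr(b, 1, 2000), mutateSequence(island, 0.05),
              substr(b, 3001, 9000))
  bl <- anchorAlign(a, b)
  expect_equal(nrow(bl), 1L)
  expect_lte(abs(bl$aStart - 4000), 50)
  expect_lte(abs(bl$aEnd - 5000), 50)
  expect_lte(abs(bl$bStart - 2000), 50)
  expect_gte(bl$identity, 0.85)
})

test_that("random unrelated loci produce no blocks", {
  a <- randomLocus(8000, seed = 41)
  b <- randomLocus(8000, seed = 42)
  expect_equal(nrow(anchorAlign(a, b)), 0L)
})

test_that("identical loci yield zero unalignable regions", {
  s <- randomLocus(9000, seed = 5)
  cc <- callUnalignableRegions(anchorAlign(s, s), 9000, 9000)
  expect_equal(nrow(cc$regions), 0L)
})

test_that("a 10-kb novel insertion is called as one unalignable region", {
  set.seed(6)
  a <- randomLocus(12000, seed = 61)
  ins <- randomLocus(10000, seed = 62)
  b <- paste0(substr(a, 1, 6000), ins, substr(a, 6001, 12000))
  cc <- callUnalignableRegions(anchorAlign(a, b), nchar(a), nchar(b))
  regB <- cc$regions[cc$regions$locus == "B", ]
  expect_equal(nrow(regB), 1L)
  expect_equal(regB$length, 10000, tolerance = 300 / 10000)
  expect_lte(abs(regB$start - 6000), 300)
  # the A side stays fully covered
  expect_equal(nrow(cc$regions[cc$regions$locus == "A", ]), 0L)
})

test_that("coverage partition: blocks + unalignable + sub-threshold gaps = locus", {
  p <- smallParams(seed = 51L)
  g <- simulateRootGenome(p)
  sim <- evolveAlongTree(g, fourTipTree(0.25), p)
  locs <- lapply(sim$tips, extractLocus, markers = p@markerIds[1:2])
  sa <- locusSequence(sim$tips$A, locs$A)
  sb <- locusSequence(sim$tips$C, locs$C)
  cc <- callUnalignableRegions(anchorAlign(sa, sb), nchar(sa), nchar(sb),
                               minRegion = 1000L)
  for (side in c("A", "B")) {
    len <- if (side == "A") nchar(sa) else nchar(sb)
    iv <- if (side == "A")
      data.frame(start = cc$blocks$aStart, end = cc$blocks$aEnd)
    else data.frame(start = cc$blocks$bStart, end = cc$blocks$bEnd)
    blockCov <- hyperlocus:::.totalCovered(iv)
    gaps <- hyperlocus:::.complementIntervals(iv, len)
    regs <- cc$regions[cc$regions$locus == side, ]
    big <- gaps[gaps$end - gaps$start >= 1000, ]
    small <- gaps[gaps$end - gaps$start < 1000, ]
    expect_equal(blockCov + sum(big$end - big$start) +
                   sum(small$end - small$start), len)
    expect_equal(sum(regs$length), sum(big$end - big$start))
  }
})

test_that("lowering the identity threshold never decreases block coverage", {
  set.seed(7)
  a <- randomLocus(8000, seed = 71)
  b <- mutateSequence(a, 0.15)
  cov <- function(minId) {
    bl <- anchorAlign(a, b, minIdentity = minId)
    hyperlocus:::.totalCovered(data.frame(start = bl$aStart, end = bl$aEnd))
  }
  c30 <- cov(0.30); c60 <- cov(0.60); c90 <- cov(0.90)
  expect_gte(c30, c60)
  expect_gte(c60, c90)
})

test_that("comparisons are symmetric in total unalignable length", {
  p <- smallParams(seed = 77L)
  g <- simulateRootGenome(p)
  sim <- evolveAlongTree(g, fourTipTree(0.25), p)
  locs <- lapply(sim$tips, extractLocus, markers = p@markerIds[1:2])
  sa <- locusSequence(sim$tips$A, locs$A)
  sb <- locusSequence(sim$tips$D, locs$D)
  ab <- callUnalignableRegions(anchorAlign(sa, sb), nchar(sa), nchar(sb))
  ba <- callUnalignableRegions(anchorAlign(sb, sa), nchar(sb), nchar(sa))
  lenIn <- function(cc, side) sum(cc$regions$length[cc$regions$locus == side])
  expect_equal(lenIn(ab, "A"), lenIn(ba, "B"), tolerance = 0.25)
  expect_equal(lenIn(ab, "B"), lenIn(ba, "A"), tolerance = 0.25)
})

test_that("the origin test separates local, imported, and random regions", {
  p <- EvolParams(nBackgroundGenes = 40L, nLocusGenes = 8L, seed = 9L)
  g <- simulateRootGenome(p)
  loc <- extractLocus(g, p@markerIds[1:2])
  locSeq <- locusSequence(g, loc)
  set.seed(10)
  # built by intralocus duplication + divergence: masked with the locus
  local <- mutateSequence(substr(locSeq, 1001, 4000), 0.05)
  expect_equal(testRegionOrigin(local, g, loc)$origin, "local")
  # copied verbatim from another contig: transposition-like, hence imported
  bg <- as.character(contigSeqs(g)[["bg1"]])
  imported <- mutateSequence(substr(bg, 10001, 13000), 0.03)
  r <- testRegionOrigin(imported, g, loc)
  expect_equal(r$origin, "imported")
  expect_gte(r$longestHit, 0.8 * 3000)
  # random sequence: longest hit around seed-word size
  rand <- randomLocus(3000, seed = 91)
  rr <- testRegionOrigin(rand, g, loc)
  expect_equal(rr$origin, "local")
  expect_lte(rr$longestHit, medianGeneLength(g))
  # degenerate input stays in-band
  tiny <- testRegionOrigin("ACGT", g, loc)
  expect_equal(tiny$origin, "unresolved")
})
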