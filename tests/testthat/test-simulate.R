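test_that("root genome honours the construction contract", {
  p <- EvolParams(nBackgroundGenes = 20L, nLocusGenes = 10L, seed = 3L)
  g <- simulateRootGenome(p)
  gm <- geneModels(g)
  expect_gte(nrow(gm), 30L)  # 20 background + 10 locus + markers + seeds
  expect_true(all(p@markerIds %in% gm$gene_id))
  # markers flank exactly the locus genes
  loc <- extractLocus(g, p@markerIds[1:2])
  expect_equal(nrow(geneModels(loc)), 10L)
  hs <- gm[gm$contig == "hs1", ]
  hs <- hs[order(hs$start), ]
  expect_equal(hs$gene_id[1], p@markerIds[1])
  expect_equal(utils::tail(hs$gene_id, 2), p@markerIds[2:3])
  # intact genes are translatable without internal stops
  prots <- geneProteins(g)
  expect_false(any(grepl("X", prots[gm$gene_id[gm$intact]], fixed = TRUE)))
  expect_error(simulateRootGenome(EvolParams(meanGeneLen = 0)), "meanGeneLen")
})

test_that("root base composition hits the GC target", {
  p <- EvolParams(nBackgroundGenes = 30L, nLocusGenes = 8L, seed = 5L)
  g <- simulateRootGenome(p)
  gc <- sum(Biostrings::letterFrequency(contigSeqs(g), "GC")) /
    sum(Biostrings::width(contigSeqs(g)))
  expect_equal(gc, 0.23, tolerance = 0.02 / 0.23)
})

test_that("the simulator is byte-identical under a fixed seed", {
  p <- smallParams(seed = 9L)
  g1 <- simulateRootGenome(p)
  g2 <- simulateRootGenome(p)
  expect_identical(as.character(contigSeqs(g1)), as.character(contigSeqs(g2)))
  expect_identical(geneModels(g1), geneModels(g2))
  tr <- fourTipTree()
  s1 <- evolveAlongTree(g1, tr, p)
  s2 <- evolveAlongTree(g2, tr, p)
  for (nm in names(s1$tips)) {
    expect_identical(as.character(contigSeqs(s1$tips[[nm]])),
                     as.character(contigSeqs(s2$tips[[nm]])))
    expect_identical(s1$logs[[nm]], s2$logs[[nm]])
  }
  d <- tempfile(); writeFixtures(s1, d)
  d2 <- tempfile(); writeFixtures(s2, d2)
  expect_identical(readLines(file.path(d, "A.fasta")),
                   readLines(file.path(d2, "A.fasta")))
})

test_that("replaying the event log reproduces every tip exactly", {
  p <- smallParams(seed = 21L)
  g <- simulateRootGenome(p)
  sim <- evolveAlongTree(g, fourTipTree(), p)
  for (nm in names(sim$tips)) {
    rebuilt <- replayEvents(sim$root, sim$logs[[nm]])
    expect_identical(unname(rebuilt),
                     unname(as.character(contigSeqs(sim$tips[[nm]]))))
  }
})

test_that("zero structural rates leave tips collinear with the root", {
  p <- EvolParams(nBackgroundGenes = 12L, nLocusGenes = 6L, meanGeneLen = 450,
                  dupRate = 0, recRate = 0, invRate = 0, lossRate = 0,
                  truncRate = 0, transRate = 0, seed = 2L)
  g <- simulateRootGenome(p)
  sim <- evolveAlongTree(g, fourTipTree(), p)
  for (nm in names(sim$tips)) {
    expect_true(all(sim$logs[[nm]]$kind %in% c("substitution", "indel")))
    gm <- geneModels(sim$tips[[nm]])
    rootOrder <- geneModels(g)[order(geneModels(g)$contig,
                                     geneModels(g)$start), "gene_id"]
    tipOrder <- gm[order(gm$contig, gm$start), "gene_id"]
    expect_identical(tipOrder, rootOrder)
    expect_identical(gm$strand[order(gm$gene_id)],
                     geneModels(g)$strand[order(geneModels(g)$gene_id)])
  }
})

test_that("every tip gene traces to a root gene or a logged duplication", {
  p <- smallParams(seed = 33L)
  g <- simulateRootGenome(p)
  sim <- evolveAlongTree(g, fourTipTree(), p)
  rootIds <- geneModels(g)$gene_id
  for (nm in names(sim$tips)) {
    lg <- sim$logs[[nm]]
    dupNew <- sub(",.*$", "",
                  lg$gene_ids[lg$kind %in% c("duplication", "transposition")])
    for (gid in geneModels(sim$tips[[nm]])$gene_id)
      expect_true(gid %in% rootIds || gid %in% dupNew)
  }
})

test_that("expected event counts scale linearly with branch length", {
  p <- EvolParams(nBackgroundGenes = 12L, nLocusGenes = 6L, meanGeneLen = 450,
                  subRate = 0, indelRate = 0, hotspotMultiplier = 1,
                  dupRate = 0.3, lossRate = 0, invRate = 0, truncRate = 0,
                  recRate = 0, transRate = 0, seed = 4L)
  g <- simulateRootGenome(p)
  counts <- function(bl, reps) {
    tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", bl, bl))
    mean(replicate(reps, {
      p2 <- EvolParams(nBackgroundGenes = 12L, nLocusGenes = 6L,
                       meanGeneLen = 450, subRate = 0, indelRate = 0,
                       hotspotMultiplier = 1, dupRate = 0.3, lossRate = 0,
                       invRate = 0, truncRate = 0, recRate = 0, transRate = 0,
                       seed = sample.int(1e6, 1))
      sim <- evolveAlongTree(g, tr, p2)
      nrow(sim$logs$A)
    }))
  }
  set.seed(8)
  m1 <- counts(0.5, 60)
  m2 <- counts(1.0, 60)
  expect_equal(m2 / m1, 2, tolerance = 0.2)
})

test_that("hotspot multiplier concentrates structural events as mf/(mf+1-f)", {
  # genome-wide event kinds only (duplication/loss/truncation/inversion);
  # all mutable genes on the hotspot contig are locus genes (markers are
  # structurally immune), so events classify by contig: f = 6 locus genes of
  # 20 eligible genes (12 background + 2 expanding seeds + 6 locus)
  mkP <- function(seed, m) EvolParams(
    nBackgroundGenes = 12L, nLocusGenes = 6L, meanGeneLen = 450,
    subRate = 0, indelRate = 0, recRate = 0, transRate = 0,
    hotspotMultiplier = m, seed = seed)
  fracInLocus <- function(m, reps, seed0, bl) {
    tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", bl, bl))
    tot <- 0; inloc <- 0
    for (i in seq_len(reps)) {
      p <- mkP(seed0 + i, m)
      g <- simulateRootGenome(p)
      sim <- evolveAlongTree(g, tr, p)
      for (lg in sim$logs) {
        ev <- lg[lg$kind %in% c("duplication", "loss", "truncation",
                                "inversion"), ]
        if (!nrow(ev)) next
        tot <- tot + nrow(ev)
        inloc <- inloc + sum(ev$src_contig == "hs1")
      }
    }
    c(frac = inloc / tot, n = tot)
  }
  f <- 6 / 20
  r1 <- fracInLocus(1, 25, 1000, bl = 0.8)
  expect_gt(stats::binom.test(round(r1["frac"] * r1["n"]), r1["n"],
                              p = f)$p.value, 0.01)
  r50 <- fracInLocus(50, 25, 5000, bl = 0.2)
  expected <- 50 * f / (50 * f + 1 - f)   # ~0.955
  expect_equal(unname(r50["frac"]), expected, tolerance = 0.05)
  expect_gt(r50["frac"], 0.5)
})

test_that("every tip keeps at least one intact diverging pair", {
  for (seed in c(3L, 14L)) {
    p <- EvolParams(nBackgroundGenes = 12L, nLocusGenes = 6L,
                    meanGeneLen = 450, lossRate = 0.1, truncRate = 0.1,
                    seed = seed)
    g <- simulateRootGenome(p)
    sim <- evolveAlongTree(g, fourTipTree(0.3), p)
    for (nm in names(sim$tips)) {
      loc <- extractLocus(sim$tips[[nm]], p@markerIds[1:2])
      prs <- findDivergingPairs(loc, p@familyB, p@familyC)
      expect_gte(sum(prs$pairIntact), 1L)
    }
  }
})

test_that("unrooted trees and missing branch lengths are rejected", {
  p <- smallParams()
  g <- simulateRootGenome(p)
  tr <- fourTipTree()
  noBl <- tr; noBl$edge.length <- NULL
  expect_error(evolveAlongTree(g, noBl, p), "branch lengths")
  unrooted <- ape::unroot(ape::read.tree(text = "(A:1,B:1,C:1);"))
  expect_error(evolveAlongTree(g, unrooted, p), "rooted")
})

test_that("the ancestry map tracks copies, losses and novel insertions", {
  p <- smallParams(seed = 17L)
  g <- simulateRootGenome(p)
  sim <- evolveAlongTree(g, fourTipTree(0.3), p)
  for (nm in names(sim$tips)[1:2]) {
    am <- ancestryMap(sim$root, sim$logs[[nm]])
    tip <- sim$tips[[nm]]
    expect_identical(vapply(am, length, 0L),
                     stats::setNames(Biostrings::width(contigSeqs(tip)),
                                     names(contigSeqs(tip))))
    # a duplicated gene's tags equal its parent's root tags somewhere
    lg <- sim$logs[[nm]]
    dup <- lg[lg$kind == "duplication", ][1, ]
    if (!is.na(dup$branch)) {
      rootLen <- sum(Biostrings::width(contigSeqs(sim$root)))
      expect_true(any(unlist(am) > rootLen) ||
                    any(duplicated(unlist(am))))
    }
  }
})
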