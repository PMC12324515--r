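toyGenome <- function() {
  # markers at [0,1000) and [50000,51000); two locus genes; one outside
  seq <- paste(rep("A", 60000), collapse = "")
  genes <- data.frame(
    gene_id = c("mkA", "geneB", "geneC", "mkB", "outside"),
    family = c("mkA", "tgrB", "tgrC", "mkB", "bg1"),
    contig = "c1",
    start = c(0, 2000, 3800, 50000, 52000),
    end = c(1002, 3500, 5300, 51002, 53002),
    strand = c("+", "-", "+", "+", "+"),
    intact = TRUE, parent_id = NA_character_, stringsAsFactors = FALSE)
  AnnotatedGenome("toy", c(c1 = seq), genes)
}

test_that("locus extraction returns the interval strictly between markers", {
  g <- toyGenome()
  loc <- extractLocus(g, c("mkA", "mkB"))
  expect_equal(loc@start, 1002)
  expect_equal(loc@end, 50000)
  expect_equal(locusSpan(loc), 48998)
  expect_setequal(geneModels(loc)$gene_id, c("geneB", "geneC"))
})

test_that("locus extraction errors name the offending marker", {
  g <- toyGenome()
  expect_error(extractLocus(g, c("mkA", "missing")),
               "marker not resolvable.*missing")
  gm <- geneModels(g)
  dup <- rbind(gm, within(gm[1, ], {gene_id <- "mkA2"; family <- "mkA"
                                    start <- 55000; end <- 56002}))
  g2 <- AnnotatedGenome("toy2", contigSeqs(g), dup)
  expect_error(extractLocus(g2, c("mkA", "mkB")), "marker not resolvable")
  gm3 <- gm
  gm3$contig[gm3$gene_id == "mkB"] <- "c2"
  g3 <- AnnotatedGenome("toy3", c(contigSeqs(g),
                                  Biostrings::DNAStringSet(c(c2 = strrep("A", 60000)))),
                        gm3)
  expect_error(extractLocus(g3, c("mkA", "mkB")), "locus split")
})

test_that("locus span grows by the truth-log net insertion length", {
  p <- smallParams(seed = 25L)
  g <- simulateRootGenome(p)
  sim <- evolveAlongTree(g, fourTipTree(), p)
  rootLoc <- extractLocus(g, p@markerIds[1:2])
  for (nm in names(sim$tips)[1:2]) {
    tipLoc <- extractLocus(sim$tips[[nm]], p@markerIds[1:2])
    lg <- sim$logs[[nm]]
    # net bp change inside the locus contig between the markers: insertions
    # minus deletions whose application interval fell inside the locus; use
    # the ancestry map for an exact account instead of coordinate bookkeeping
    am <- ancestryMap(sim$root, sim$logs[[nm]])
    expect_equal(locusSpan(tipLoc),
                 length(am[[tipLoc@contig]][(tipLoc@start + 1):tipLoc@end]))
  }
})

test_that("diverging pairs require head-to-head orientation and adjacency", {
  g <- toyGenome()
  loc <- extractLocus(g, c("mkA", "mkB"))
  pr <- findDivergingPairs(loc, "tgrB", "tgrC")
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$gap, 300)
  expect_equal(pr$bGene, "geneB")

  # tail-to-tail is not a pair
  gm <- geneModels(g)
  gm$strand[gm$gene_id == "geneB"] <- "+"
  gm$strand[gm$gene_id == "geneC"] <- "-"
  g2 <- AnnotatedGenome("t", contigSeqs(g), gm)
  pr2 <- findDivergingPairs(extractLocus(g2, c("mkA", "mkB")), "tgrB", "tgrC")
  expect_equal(nrow(pr2), 0L)
  expect_gte(attr(pr2, "nearMisses"), 1L)

  # an intervening gene breaks the pair
  gm3 <- rbind(geneModels(g), data.frame(
    gene_id = "wedge", family = "w", contig = "c1", start = 3550, end = 3700,
    strand = "+", intact = TRUE, parent_id = NA_character_))
  g3 <- AnnotatedGenome("t3", contigSeqs(g), gm3)
  pr3 <- findDivergingPairs(extractLocus(g3, c("mkA", "mkB")), "tgrB", "tgrC")
  expect_equal(nrow(pr3), 0L)

  # a gap beyond maxGap is rejected
  pr4 <- findDivergingPairs(loc, "tgrB", "tgrC", maxGap = 200)
  expect_equal(nrow(pr4), 0L)
})

test_that("planted pairs in simulated loci are recovered exactly", {
  p <- smallParams(seed = 31L)
  g <- simulateRootGenome(p)
  sim <- evolveAlongTree(g, fourTipTree(), p)
  for (nm in names(sim$tips)) {
    loc <- extractLocus(sim$tips[[nm]], p@markerIds[1:2])
    pr <- findDivergingPairs(loc, p@familyB, p@familyC)
    gm <- geneModels(loc)
    gm <- gm[order(gm$start), ]
    # exhaustively verify against a direct scan of the annotation
    expected <- 0L
    for (i in seq_len(nrow(gm) - 1)) {
      a <- gm[i, ]; b <- gm[i + 1, ]
      if (setequal(c(a$family, b$family), c("tgrB", "tgrC")) &&
          a$strand == "-" && b$strand == "+" && b$start - a$end <= 3000)
        expected <- expected + 1L
    }
    expect_equal(nrow(pr), expected)
  }
})

test_that("the intactness filter applies the strict >50 aa deletion rule", {
  ref <- paste(rep("MKLVNPQRST", 40), collapse = "")  # 400 aa
  mk <- function(protein) protein
  delAA <- function(p, at, n) paste0(substr(p, 1, at), substr(p, at + n + 1,
                                                              nchar(p)))
  pairs <- data.frame(genome = "g", bGene = c("b0", "b50", "b51", "bshort"),
                      cGene = "c0", gap = 100, bIntact = TRUE, cIntact = TRUE,
                      pairIntact = TRUE, stringsAsFactors = FALSE)
  proteins <- c(b0 = ref, b50 = delAA(ref, 100, 50), b51 = delAA(ref, 100, 51),
                bshort = substr(ref, 1, 150), c0 = ref)
  refs <- list(tgrB = ref, tgrC = ref)
  f <- filterIntactPairs(pairs, proteins, refs)
  status <- stats::setNames(pairs$bGene %in% f$intact$bGene, pairs$bGene)
  expect_true(status[["b0"]])
  expect_true(status[["b50"]])    # exactly 50 aa: tolerated
  expect_false(status[["b51"]])   # strictly more than 50 aa: rejected
  expect_false(status[["bshort"]])
  expect_match(f$rejected$reason[f$rejected$bGene == "b51"], "deletion")
  expect_match(f$rejected$reason[f$rejected$bGene == "bshort"], "length")
})

test_that("simulated truncations are rejected by the intactness filter", {
  p <- EvolParams(nBackgroundGenes = 12L, nLocusGenes = 8L, meanGeneLen = 600,
                  truncRate = 0.25, lossRate = 0, seed = 41L)
  g <- simulateRootGenome(p)
  sim <- evolveAlongTree(g, fourTipTree(0.3), p)
  trunc <- 0L; caught <- 0L; intactOK <- 0L; intactAll <- 0L
  refs <- list(tgrB = geneProteins(g)[["tgrB.1"]],
               tgrC = geneProteins(g)[["tgrC.1"]])
  for (nm in names(sim$tips)) {
    tip <- sim$tips[[nm]]
    loc <- extractLocus(tip, p@markerIds[1:2])
    pr <- findDivergingPairs(loc, p@familyB, p@familyC)
    if (!nrow(pr)) next
    prot <- geneProteins(tip)
    gm <- geneModels(tip)
    f <- filterIntactPairs(pr, prot, refs)
    for (i in seq_len(nrow(pr))) {
      for (side in c("bGene", "cGene")) {
        gid <- pr[[side]][i]
        # truncation truth: inherited intactness flag (duplicates of a
        # truncated gene carry the damage without their own event row)
        isTrunc <- !gm$intact[gm$gene_id == gid]
        called <- !(gid %in% c(f$intact$bGene, f$intact$cGene))
        if (isTrunc) { trunc <- trunc + 1L; caught <- caught + called }
        else { intactAll <- intactAll + 1L; intactOK <- intactOK + !called }
      }
    }
  }
  expect_gte(trunc, 1L)
  expect_equal(caught / trunc, 1.0, tolerance = 0.05)
  expect_gte(intactOK / intactAll, 0.95)
})
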