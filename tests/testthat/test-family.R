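simFamilyFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    p <- EvolParams(nBackgroundGenes = 15L, nLocusGenes = 6L,
                    meanGeneLen = 450, seed = 7L)
    g <- simulateRootGenome(p)
    sim <- evolveAlongTree(g, fourTipTree(), p)
    queries <- stats::setNames(
      geneProteins(g)[c("tgrB.1", "tgrC.1", "tgrA.1", "bg001")],
      c("tgrB", "tgrC", "tgrA", "bg001"))
    cache <<- list(p = p, root = g, sim = sim, queries = queries,
                   hits = findHomologs(sim$tips, queries))
    cache
  }
})

test_that("a query finds itself with full aligned fraction and own label", {
  fx <- simFamilyFixture()
  root <- fx$root
  hits <- findHomologs(list(root), fx$queries)
  self <- hits[hits$gene_id == "tgrB.1", ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$family, "tgrB")
  expect_equal(self$fraction, 1.0)
})

test_that("scrambled decoys yield no hits at the default threshold", {
  fx <- simFamilyFixture()
  set.seed(1)
  scramble <- function(s) paste(sample(strsplit(s, "")[[1]]), collapse = "")
  root <- fx$root
  gm <- geneModels(root)[1:8, ]
  seqs <- contigSeqs(root)
  # decoy genome: scrambled CDS content in place
  decoySeq <- vapply(as.character(seqs), identity, "")
  for (i in seq_len(nrow(gm))) {
    s <- gm[i, ]
    sub <- substr(decoySeq[[s$contig]], s$start + 1, s$end)
    substr(decoySeq[[s$contig]], s$start + 1, s$end) <- scramble(sub)
  }
  decoy <- AnnotatedGenome("decoy", decoySeq, gm)
  hits <- findHomologs(list(decoy), fx$queries)
  expect_equal(nrow(hits[hits$gene_id %in% gm$gene_id[1:8], ]), 0L)
})

test_that("simulated homologs are recovered with near-full query coverage", {
  fx <- simFamilyFixture()
  hits <- fx$hits
  # every tip carries recoverable tgrB/tgrC descendants
  for (nm in names(fx$sim$tips)) {
    hB <- hits[hits$genome == nm & hits$family == "tgrB" & hits$intact, ]
    expect_gte(nrow(hB), 1L)
    expect_gte(max(hB$fraction), 0.9)
  }
  # labels agree with the simulator's family annotation for intact genes
  ann <- do.call(rbind, lapply(fx$sim$tips, function(g)
    cbind(genome = genomeId(g), geneModels(g))))
  merged <- merge(hits, ann, by.x = c("genome", "gene_id"),
                  by.y = c("genome", "gene_id"))
  core <- merged[merged$family.y %in% c("tgrB", "tgrC", "tgrA"), ]
  expect_gte(mean(core$family.x == core$family.y), 0.95)
})

test_that("length filter applies the strict below-half rule per family", {
  hits <- data.frame(genome = "g", gene_id = paste0("x", 1:3),
                     family = "fam", score = 500, fraction = 1,
                     length = c(100L, 80L, 49L), intact = TRUE,
                     protein = "M", stringsAsFactors = FALSE)
  f <- filterByLength(hits, 0.5)
  expect_setequal(f$retained$gene_id, c("x1", "x2"))
  expect_equal(f$removed$gene_id, "x3")

  # exactly at the threshold is retained (removal is strictly below)
  hits$length <- c(100L, 50L, 49L)
  f2 <- filterByLength(hits, 0.5)
  expect_true("x2" %in% f2$retained$gene_id)
  expect_false("x3" %in% f2$retained$gene_id)

  # idempotence
  f3 <- filterByLength(f2$retained, 0.5)
  expect_identical(f3$retained, f2$retained)
  expect_equal(nrow(f3$removed), 0L)
})

test_that("simulated truncations beyond half the gene are filtered out", {
  fx <- simFamilyFixture()
  # plant hard truncations: halve a set of tgrC descendants
  hits <- fx$hits[fx$hits$family == "tgrC", ]
  full <- max(hits$length)
  planted <- hits[rep(1, 4), ]
  planted$gene_id <- paste0("trunc", 1:4)
  planted$length <- as.integer(round(full * c(0.2, 0.3, 0.4, 0.45)))
  f <- filterByLength(rbind(hits, planted))
  expect_true(all(planted$gene_id %in% f$removed$gene_id))
  expect_gte(mean(hits$gene_id %in% f$retained$gene_id), 0.5)
})

test_that("family trees collapse for identical sequences and need 3+ members", {
  prots <- stats::setNames(rep(paste(rep("MKLV", 25), collapse = ""), 4),
                           paste0("s", 1:4))
  tr <- buildFamilyTree(prots)
  expect_s3_class(tr, "phylo")
  expect_equal(sum(tr$edge.length), 0)
  expect_error(buildFamilyTree(prots[1:2], "tiny"), "tiny")
})

test_that("families simulated without duplication mirror the species tree", {
  fx <- simFamilyFixture()
  hits <- fx$hits[fx$hits$family == "bg001", ]
  expect_equal(nrow(hits), 4L)   # single copy in each tip
  prots <- stats::setNames(hits$protein, hits$genome)
  tr <- buildFamilyTree(prots, "bg001")
  rf <- phangorn::RF.dist(ape::unroot(tr), ape::unroot(fourTipTree()))
  expect_equal(rf, 0)
})

test_that("classification separates static, expanding and ambiguous families", {
  fx <- simFamilyFixture()
  filt <- filterByLength(fx$hits)
  trees <- list()
  bg <- filt$retained[filt$retained$family == "bg001", ]
  trees$bg001 <- buildFamilyTree(stats::setNames(bg$protein, bg$gene_id),
                                 "bg001")
  # rename by genome for concordance (single copy per genome)
  trees$bg001$tip.label <- bg$genome[match(trees$bg001$tip.label, bg$gene_id)]
  cls <- classifyFamilies(filt$retained, trees, fourTipTree(),
                          genomes = fx$sim$tips)
  expect_equal(cls$class[cls$family == "bg001"], "static_single_copy")
  expect_equal(cls$class[cls$family == "tgrA"], "expanding")

  # rule coverage: copy numbers {1,1,2} with a concordant tree -> ambiguous
  toy <- data.frame(genome = c("A", "B", "C", "C"),
                    gene_id = c("f.A", "f.B", "f.C1", "f.C2"),
                    family = "toy", score = 500, fraction = 1, length = 100L,
                    intact = TRUE, protein = "M", stringsAsFactors = FALSE)
  cls2 <- classifyFamilies(toy, genomeIds = c("A", "B", "C"))
  expect_equal(cls2$class, "ambiguous")

  # absence from a genome records copy number 0 without an exception
  cls3 <- classifyFamilies(toy, genomeIds = c("A", "B", "C", "D"))
  expect_match(cls3$copyNumbers, "D=0")
})

test_that("zero-structural-rate simulations classify every family as static", {
  p <- EvolParams(nBackgroundGenes = 6L, nLocusGenes = 6L, meanGeneLen = 450,
                  dupRate = 0, recRate = 0, invRate = 0, lossRate = 0,
                  truncRate = 0, transRate = 0, nExpandingSeeds = 0L,
                  seed = 13L)
  g <- simulateRootGenome(p)
  sim <- evolveAlongTree(g, fourTipTree(), p)
  fams <- paste0("bg00", 1:3)
  queries <- stats::setNames(geneProteins(g)[fams], fams)
  hits <- findHomologs(sim$tips, queries)
  filt <- filterByLength(hits)
  trees <- lapply(stats::setNames(fams, fams), function(f) {
    h <- filt$retained[filt$retained$family == f, ]
    tr <- buildFamilyTree(stats::setNames(h$protein, h$gene_id), f)
    tr$tip.label <- h$genome[match(tr$tip.label, h$gene_id)]
    tr
  })
  cls <- classifyFamilies(filt$retained, trees, fourTipTree(),
                          genomes = sim$tips)
  expect_true(all(cls$class == "static_single_copy"))
})

test_that("family consensus reflects the longest members", {
  prots <- c(a = "MKKKKKKKKKK", b = "MKKKKKKKKKK", c = "MKK")
  expect_equal(familyConsensus(prots), "MKKKKKKKKKK")
})
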