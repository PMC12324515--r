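# Self-contained evaluation harness: each benchmark simulates data with known
# truth, runs the corresponding detector, and returns the measured rates.
# These functions back both the test suite and the acceptance script, so the
# quantities they report are always recomputed from scratch.

#' Structural-event enrichment of the hotspot locus
#'
#' Simulates two-branch clades with only genome-wide-targeted structural
#' events (duplication, inversion, loss, truncation) and measures the
#' fraction of events whose target lies on the hotspot contig. Since the
#' marker genes are structurally immune, every mutable gene on that contig is
#' a locus gene and events classify by contig. The root carries 6 locus genes
#' among 20 eligible genes, so the expected fraction is `m*f/(m*f + 1 - f)`
#' with `f = 0.3`.
#'
#' @param multiplier hotspot rate multiplier.
#' @param nSims number of independent two-branch simulations.
#' @param branchLength branch length of each branch.
#' @param seed base seed.
#' @return List: `fraction` observed, `expected`, `nEvents`, `f`.
#' @export
benchmarkEnrichment <- function(multiplier, nSims = 25L, branchLength = 0.5,
                                seed = 1L) {
  tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", branchLength,
                                      branchLength))
  tot <- 0L; inloc <- 0L
  for (i in seq_len(nSims)) {
    p <- EvolParams(nBackgroundGenes = 12L, nLocusGenes = 6L,
                    meanGeneLen = 450, subRate = 0, indelRate = 0,
                    recRate = 0, transRate = 0,
                    hotspotMultiplier = multiplier, seed = seed + i)
    g <- simulateRootGenome(p)
    sim <- evolveAlongTree(g, tr, p)
    for (lg in sim$logs) {
      ev <- lg[lg$kind %in% c("duplication", "loss", "truncation",
                              "inversion"), ]
      tot <- tot + nrow(ev)
      inloc <- inloc + sum(ev$src_contig == "hs1")
    }
  }
  f <- 6 / 20
  list(fraction = inloc / tot, nEvents = tot, f = f,
       expected = multiplier * f / (multiplier * f + 1 - f))
}

# ancestry-mask edges of locus A vs locus B (for boundary evaluation)
.maskEdges <- function(tagsA, tagsB, minRun = 150L, slop = 250L) {
  cntA <- table(tagsA); cntB <- table(tagsB)
  haveB <- as.numeric(cntB[as.character(tagsA)]); haveB[is.na(haveB)] <- 0
  mark <- as.vector(as.numeric(cntA[as.character(tagsA)]) > haveB)
  r <- rle(mark)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  iv <- iv[iv$end - iv$start >= minRun, , drop = FALSE]
  if (nrow(iv)) iv <- .mergeIntervals(iv, slop = slop)
  c(iv$start, iv$end)
}

#' End-to-end detection benchmark on a default-scale simulation
#'
#' Runs one default simulation (six tips, ~300 kb genomes) and measures:
#' diverging-pair detection recall/precision against the annotation-level
#' geometric truth (detection goes through the homolog search, so family
#' labelling is exercised); truncation-filter recall over all locus genes of
#' the two pair families; gene-content-swap recovery (a [plantSwap()] edit
#' into one member of each sister pair, compared against its sister) with
#' boundary error against ancestry-mask edges; and origin-test accuracy on
#' planted local-duplication versus transposition regions.
#'
#' @param seed simulation seed.
#' @param swapSeeds additional seeds whose simulations contribute three more
#'   sister-pair swaps each.
#' @param nOrigin planted regions per origin class.
#' @return List of measured quantities (see details).
#' @export
benchmarkDetection <- function(seed = 1L, swapSeeds = seed + 1L,
                               nOrigin = 6L) {
  p <- EvolParams(seed = seed)
  tree <- defaultSpeciesTree()
  root <- simulateRootGenome(p)
  sim <- evolveAlongTree(root, tree, p)
  markers <- p@markerIds[1:2]

  queries <- stats::setNames(
    geneProteins(root)[c("tgrB.1", "tgrC.1", "tgrA.1")],
    c(p@familyB, p@familyC, p@expandingFamily))
  hits <- findHomologs(sim$tips, queries)
  filt <- filterByLength(hits)

  relabel <- function(genome) {
    h <- filt$retained[filt$retained$genome == genomeId(genome), ]
    g <- geneModels(genome)
    idx <- match(g$gene_id, h$gene_id)
    g$family[!is.na(idx)] <- h$family[idx[!is.na(idx)]]
    AnnotatedGenome(genomeId(genome), contigSeqs(genome), g)
  }

  # --- diverging pairs: called via homolog labels, truth via annotation
  key <- function(df) if (nrow(df)) paste(df$genome, df$bGene, df$cGene)
    else character()
  called <- do.call(rbind, lapply(sim$tips, function(tp)
    findDivergingPairs(extractLocus(relabel(tp), markers),
                       p@familyB, p@familyC)))
  truthP <- do.call(rbind, lapply(sim$tips, function(tp)
    findDivergingPairs(extractLocus(tp, markers), p@familyB, p@familyC)))
  tp <- length(intersect(key(called), key(truthP)))
  pairRecall <- if (nrow(truthP)) tp / nrow(truthP) else 1
  pairPrecision <- if (nrow(called)) tp / nrow(called) else 1

  # --- truncation filter over all locus genes of the pair families
  refs <- list()
  for (fam in c(p@familyB, p@familyC)) {
    fh <- filt$retained[filt$retained$family == fam, ]
    refs[[fam]] <- familyConsensus(stats::setNames(
      fh$protein, paste(fh$genome, fh$gene_id)))
  }
  truncTP <- 0L; truncN <- 0L; falseRej <- 0L; intactN <- 0L
  for (nm in names(sim$tips)) {
    tip <- sim$tips[[nm]]
    loc <- extractLocus(tip, markers)
    g <- geneModels(loc)
    g <- g[g$family %in% c(p@familyB, p@familyC), , drop = FALSE]
    if (!nrow(g)) next
    prots <- geneProteins(tip)
    # truncation truth is the inherited intactness flag: duplicates of a
    # truncated gene carry the damage without an event row of their own
    for (i in seq_len(nrow(g))) {
      rejected <- !checkGeneIntactness(prots[[g$gene_id[i]]],
                                       refs[[g$family[i]]])$ok
      if (!g$intact[i]) {
        truncN <- truncN + 1L
        truncTP <- truncTP + rejected
      } else {
        intactN <- intactN + 1L
        falseRej <- falseRej + rejected
      }
    }
  }

  # --- planted gene-content swaps between sister tips
  sisters <- list(c("t1", "t2"), c("t3", "t4"), c("t5", "t6"))
  swapHits <- c(); swapBerr <- c()
  evalSwaps <- function(sim0, p0, rngSeed) {
    set.seed(rngSeed)
    for (pr in sisters) {
      ga <- pr[1]; gb <- pr[2]
      sw <- plantSwap(sim0$tips[[ga]], markers)
      la <- extractLocus(sw$genome, markers)
      lb <- extractLocus(sim0$tips[[gb]], markers)
      sa <- locusSequence(sw$genome, la)
      sb <- locusSequence(sim0$tips[[gb]], lb)
      cc <- callUnalignableRegions(anchorAlign(sa, sb), nchar(sa), nchar(sb))
      ca <- cc$regions[cc$regions$locus == "A", , drop = FALSE]
      amA <- applySwapToAncestry(ancestryMap(sim0$root, sim0$logs[[ga]]), sw)
      amB <- ancestryMap(sim0$root, sim0$logs[[gb]])
      edges <- .maskEdges(amA[[la@contig]][(la@start + 1):la@end],
                          amB[[lb@contig]][(lb@start + 1):lb@end])
      hit <- FALSE
      for (j in seq_len(nrow(ca))) {
        ro <- .reciprocalOverlap(sw$insertStart, sw$insertEnd,
                                 ca$start[j], ca$end[j])
        cov <- max(0, min(sw$insertEnd, ca$end[j]) -
                     max(sw$insertStart, ca$start[j]))
        if (ro >= 0.5 || cov >= 0.8 * (sw$insertEnd - sw$insertStart)) {
          hit <- TRUE
          if (length(edges))
            swapBerr <<- c(swapBerr, (min(abs(ca$start[j] - edges)) +
                                        min(abs(ca$end[j] - edges))) / 2)
        }
      }
      swapHits <<- c(swapHits, hit)
    }
  }
  evalSwaps(sim, p, seed + 1000L)
  for (s2 in swapSeeds) {
    p2 <- EvolParams(seed = s2)
    sim2 <- evolveAlongTree(simulateRootGenome(p2), tree, p2)
    evalSwaps(sim2, p2, s2 + 1000L)
  }

  # --- origin test on planted local-duplication vs transposition regions
  set.seed(seed + 2000L)
  tip <- sim$tips$t1
  loc <- extractLocus(tip, markers)
  locSeq <- locusSequence(tip, loc)
  bg <- as.character(contigSeqs(tip)[["bg1"]])
  ok <- 0L; nO <- 0L
  for (i in seq_len(nOrigin)) {
    a0 <- sample.int(nchar(locSeq) - 3000L, 1L)
    localSeq <- mutateSequence(substr(locSeq, a0, a0 + 2999L), 0.05)
    nO <- nO + 1L
    ok <- ok + (testRegionOrigin(localSeq, tip, loc)$origin == "local")
    b0 <- sample.int(nchar(bg) - 3000L, 1L)
    impSeq <- mutateSequence(substr(bg, b0, b0 + 2999L), 0.05)
    nO <- nO + 1L
    ok <- ok + (testRegionOrigin(impSeq, tip, loc)$origin == "imported")
  }

  list(pairRecall = pairRecall, pairPrecision = pairPrecision,
       nPairs = nrow(truthP),
       truncationRecall = if (truncN) truncTP / truncN else NA_real_,
       truncationN = truncN,
       intactFalseRejectRate = if (intactN) falseRej / intactN else NA_real_,
       swapRecall = mean(swapHits), nSwaps = length(swapHits),
       swapBoundaryError = if (length(swapBerr)) mean(swapBerr) else NA_real_,
       originAccuracy = ok / nO, nOriginRegions = nO)
}

#' Breakpoint recovery and false-positive benchmark
#'
#' Chimeric alignments emulate a recombinant gene switching between a nearly
#' identical within-clade relative and a distant-clade donor (deep two-clade
#' tree, strong divergence). Recovery requires both junctions of a planted
#' 300-column block to be located within one grid step.
#'
#' @param nRecovery,nNull replicate counts for the two arms.
#' @param sites alignment length.
#' @param rate substitution rate.
#' @param seed base seed.
#' @return List: `recoveryRate`, `fpr`, `medianError`.
#' @export
benchmarkBreakpoints <- function(nRecovery = 25L, nNull = 25L, sites = 900L,
                                 rate = 0.8, seed = 1L) {
  tr <- ape::read.tree(text = paste0(
    "((a1:0.02,(a2:0.015,a3:0.015):0.005):0.25,",
    "(b1:0.02,(b2:0.015,b3:0.015):0.005):0.25);"))
  set.seed(seed)
  lo <- round(sites / 3); hi <- round(2 * sites / 3)
  errs <- c(); hits <- logical(nRecovery)
  for (i in seq_len(nRecovery)) {
    m <- simulateAlignment(tr, sites, rate)
    m["a1", (lo + 1):hi] <- m["b1", (lo + 1):hi]
    bp <- segmentAlignment(m, maxBreakpoints = 4)
    if (length(bp$breakpoints) >= 2) {
      e1 <- min(abs(bp$breakpoints - lo))
      e2 <- min(abs(bp$breakpoints - hi))
      errs <- c(errs, e1, e2)
      hits[i] <- e1 <= bp$step && e2 <= bp$step
    }
  }
  fp <- logical(nNull)
  for (i in seq_len(nNull)) {
    m <- simulateAlignment(tr, sites, rate)
    fp[i] <- length(segmentAlignment(m, maxBreakpoints = 4)$breakpoints) > 0
  }
  list(recoveryRate = mean(hits), fpr = mean(fp),
       medianError = if (length(errs)) stats::median(errs) else NA_real_)
}

#' Permutation-null calibration benchmark
#'
#' Feeds column-permuted (linkage-free) alignments to the segmentation with a
#' forced single split and records the permutation p-values, which should be
#' uniform: the retention rate at the threshold estimates the nominal level.
#'
#' @param nRep replicates.
#' @param nPerm permutations per test.
#' @param threshold significance threshold.
#' @param seed base seed.
#' @return List: `retention`, `meanP`, `n`.
#' @export
benchmarkNullCalibration <- function(nRep = 15L, nPerm = 29L,
                                     threshold = 0.05, seed = 1L) {
  tr <- ape::read.tree(text = paste0(
    "((a1:0.02,(a2:0.015,a3:0.015):0.005):0.25,",
    "(b1:0.02,(b2:0.015,b3:0.015):0.005):0.25);"))
  set.seed(seed)
  ps <- rep(NA_real_, nRep)
  for (i in seq_len(nRep)) {
    m <- simulateAlignment(tr, 600L, 0.8)
    m <- m[, sample.int(ncol(m))]
    b1 <- segmentAlignment(m, maxBreakpoints = 1, penalty = 0)
    if (!length(b1$breakpoints)) next
    ps[i] <- testBreakpointSignificance(m, b1, nPerm = nPerm,
                                        seed = seed + i)$pvalues[1]
  }
  ps <- ps[!is.na(ps)]
  list(retention = mean(ps <= threshold), meanP = mean(ps), n = length(ps))
}

#' Neutral-simulation sanity benchmark for the statistics module
#'
#' Tajima's D is averaged over alignments evolved along coalescent trees
#' (`ape::rcoal`), under which the neutral expectation is approximately zero;
#' dN/dS is averaged over codon pairs evolved with equal acceptance of
#' synonymous and nonsynonymous changes, under which the estimator should be
#' close to one.
#'
#' @param nTajima,nDnds replicate counts.
#' @param n sample size per alignment.
#' @param sites alignment length.
#' @param seed base seed.
#' @return List: `meanTajimaD`, `nDefined`, `meanDnDs`, `nRatios`.
#' @export
benchmarkNeutralStats <- function(nTajima = 150L, nDnds = 80L, n = 8L,
                                  sites = 500L, seed = 1L) {
  set.seed(seed)
  ds <- rep(NA_real_, nTajima)
  for (i in seq_len(nTajima)) {
    tr <- ape::rcoal(n)
    m <- simulateAlignment(tr, sites, 0.02)
    r <- tajimasD(m)
    if (r$defined) ds[i] <- r$D
  }
  ratios <- rep(NA_real_, nDnds)
  for (i in seq_len(nDnds)) {
    pp <- simulateCodonPair(300L, divergence = 0.05)
    ratios[i] <- tryCatch(ng86dnds(pp$a, pp$b)$ratio,
                          error = function(e) NA_real_)
  }
  list(meanTajimaD = mean(ds, na.rm = TRUE), nDefined = sum(!is.na(ds)),
       meanDnDs = mean(ratios, na.rm = TRUE), nRatios = sum(!is.na(ratios)))
}
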