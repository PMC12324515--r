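# End-to-end orchestration: simulate (or load) genomes, curate homologs,
# extract loci and diverging pairs, compare locus pairs, compute gene
# statistics, scan for breakpoints, and (when simulation truth is available)
# score the calls against the event log.

#' Default pipeline configuration
#'
#' Returns the full list of recognised configuration keys with their
#' defaults. `runPipeline()` rejects unknown keys, so this doubles as the
#' configuration schema.
#'
#' @return Named list.
#' @export
defaultRunConfig <- function() {
  list(
    mode = "simulate",          # simulate | provided
    seed = 1L,
    tree = NULL,                # phylo, newick string, or NULL (default tree)
    params = list(),            # EvolParams overrides (simulate mode)
    genomesDir = NULL,          # provided mode: dir of <id>.fasta/<id>.gff3
    queries = NULL,             # provided mode: named protein vector/FASTA
    markers = NULL,             # locus-bounding marker ids (2+), ordered
    familyB = "tgrB", familyC = "tgrC",
    minScore = 250, maxGap = 3000,
    word = 12L, minBlock = 300L, minIdentity = 0.30, minRegion = 2000L,
    maxBreakpoints = 8L, penalty = .DEFAULT_PENALTY, recombStep = 10L,
    minSegment = 100L, nPerm = 0L,   # 0 = skip permutation filtering
    comparisons = "all",        # all | first (each genome vs the first)
    outDir = NULL
  )
}

.mergeConfig <- function(config) {
  def <- defaultRunConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    .stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  def[names(config)] <- config
  if (!def$mode %in% c("simulate", "provided"))
    .stopf("mode must be 'simulate' or 'provided'")
  def
}

.resolveTree <- function(tree) {
  if (is.null(tree)) return(defaultSpeciesTree())
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && file.exists(tree)) return(ape::read.tree(tree))
  if (is.character(tree)) return(ape::read.tree(text = tree))
  .stopf("cannot interpret 'tree' configuration value")
}

.stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    .stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

# nucleotide CDS (coding strand) of a set of genes
.geneCds <- function(genome, ids) {
  g <- geneModels(genome)
  seqs <- lapply(as.character(contigSeqs(genome)),
                 function(s) strsplit(s, "")[[1]])
  out <- vapply(ids, function(id) {
    row <- g[g$gene_id == id, ]
    .collapse(.geneSeq(seqs, row))
  }, "")
  stats::setNames(out, ids)
}

# codon-aware nucleotide alignment: align translations, thread codons back
.codonAlign <- function(cds) {
  prots <- vapply(cds, function(s)
    gsub("*", "X", .translateCds(strsplit(s, "")[[1]]), fixed = TRUE), "")
  m <- .alignProteins(prots)
  m <- m[names(cds), , drop = FALSE]
  out <- vapply(names(cds), function(id) {
    codons <- substring(cds[[id]], seq(1, nchar(cds[[id]]), 3),
                        pmin(seq(3, nchar(cds[[id]]) + 2, 3),
                             nchar(cds[[id]])))
    row <- m[id, ]
    res <- character(length(row))
    ci <- 0L
    for (k in seq_along(row)) {
      if (row[k] %in% .GAP) res[k] <- "---"
      else { ci <- ci + 1L; res[k] <- codons[ci] }
    }
    .collapse(res)
  }, "")
  stats::setNames(out, names(cds))
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: input (simulate along the tree, or load
#' FASTA+GFF3), homolog search and length filtering, locus extraction,
#' diverging-pair detection and intactness filtering, pairwise locus
#' comparison (syntenic blocks, unalignable regions, origin tests),
#' per-family diversity / selection statistics, breakpoint scanning, and --
#' in simulate mode -- truth comparison. Any stage failure aborts with a
#' stage-named error. With a fixed seed two runs are identical.
#'
#' @param config named list; see [defaultRunConfig()] for keys. Unknown keys
#'   are rejected before any computation.
#' @return A [RunReport-class].
#' @export
runPipeline <- function(config = list()) {
  cfg <- .mergeConfig(config)
  set.seed(cfg$seed)

  # ---- input stage
  truth <- NULL
  if (cfg$mode == "simulate") {
    params <- .stageError("input", do.call(EvolParams, c(
      cfg$params, if (!("seed" %in% names(cfg$params)))
        list(seed = cfg$seed))))
    tree <- .resolveTree(cfg$tree)
    root <- .stageError("input", simulateRootGenome(params))
    truth <- .stageError("input", evolveAlongTree(root, tree, params))
    genomes <- truth$tips
    if (is.null(cfg$markers)) cfg$markers <- params@markerIds[1:2]
    queries <- stats::setNames(
      geneProteins(root)[c(paste0(params@familyB, ".1"),
                           paste0(params@familyC, ".1"),
                           paste0(params@expandingFamily, ".1"))],
      c(params@familyB, params@familyC, params@expandingFamily))
    cfg$familyB <- params@familyB
    cfg$familyC <- params@familyC
  } else {
    if (is.null(cfg$genomesDir))
      .stopf("stage 'input' failed: provided mode requires genomesDir")
    fa <- setdiff(list.files(cfg$genomesDir, pattern = "\\.fasta$"),
                  "root.fasta")
    ids <- sub("\\.fasta$", "", fa)
    genomes <- .stageError("input", stats::setNames(lapply(ids, function(id)
      readAnnotatedGenome(file.path(cfg$genomesDir, paste0(id, ".fasta")),
                          file.path(cfg$genomesDir, paste0(id, ".gff3")),
                          genomeId = id)), ids))
    if (is.null(cfg$markers)) .stopf("provided mode requires markers")
    queries <- cfg$queries
    if (is.character(queries) && length(queries) == 1L &&
        file.exists(queries)) {
      q <- Biostrings::readAAStringSet(queries)
      queries <- stats::setNames(as.character(q), sub("\\s.*", "", names(q)))
    }
    if (is.null(queries)) .stopf("provided mode requires queries")
  }

  # ---- homolog curation
  hits <- .stageError("families", findHomologs(genomes, queries,
                                               minScore = cfg$minScore))
  filt <- if (nrow(hits)) filterByLength(hits) else
    list(retained = hits, removed = hits)

  # relabel locus genes from retained homolog hits
  relabel <- function(genome) {
    h <- filt$retained[filt$retained$genome == genomeId(genome), ]
    g <- geneModels(genome)
    idx <- match(g$gene_id, h$gene_id)
    g$family[!is.na(idx)] <- h$family[idx[!is.na(idx)]]
    AnnotatedGenome(genomeId(genome), contigSeqs(genome), g)
  }
  genomes <- lapply(genomes, relabel)

  # ---- loci and pairs
  loci <- .stageError("locus", lapply(genomes, extractLocus,
                                      markers = cfg$markers))
  lociTbl <- do.call(rbind, lapply(loci, function(l) data.frame(
    genome = l@genomeId, contig = l@contig, start = l@start, end = l@end,
    span = locusSpan(l), nGenes = nrow(l@genes), stringsAsFactors = FALSE)))
  rownames(lociTbl) <- NULL

  pairs <- do.call(rbind, lapply(loci, findDivergingPairs,
                                 familyB = cfg$familyB, familyC = cfg$familyC,
                                 maxGap = cfg$maxGap))
  if (is.null(pairs))
    pairs <- findDivergingPairs(loci[[1]], cfg$familyB, cfg$familyC)
  rownames(pairs) <- NULL

  # genome-qualified protein table: inherited gene ids recur across tips
  proteins <- do.call(c, unname(lapply(genomes, function(g) {
    p <- geneProteins(g)
    stats::setNames(p, paste(genomeId(g), names(p), sep = "|"))
  })))

  refs <- list()
  for (fam in c(cfg$familyB, cfg$familyC)) {
    fh <- filt$retained[filt$retained$family == fam, ]
    refs[[fam]] <- if (nrow(fh))
      familyConsensus(stats::setNames(fh$protein, fh$gene_id))
    else ""
  }
  pairFilt <- if (nrow(pairs)) .stageError("pairs",
    filterIntactPairs(pairs, proteins, refs, familyB = cfg$familyB,
                      familyC = cfg$familyC))
    else list(intact = pairs, rejected = cbind(pairs, reason = character()))
  pairsTbl <- rbind(
    if (nrow(pairFilt$intact))
      cbind(pairFilt$intact, reason = "", status = "intact"),
    if (nrow(pairFilt$rejected))
      cbind(pairFilt$rejected, status = "rejected"))
  if (is.null(pairsTbl))
    pairsTbl <- cbind(pairs, reason = character(), status = character())
  rownames(pairsTbl) <- NULL

  # ---- locus comparisons
  ids <- names(genomes)
  cmb <- if (cfg$comparisons == "first" && length(ids) > 1L)
    cbind(ids[1], ids[-1]) else t(utils::combn(ids, 2L))
  compRows <- list()
  regionRows <- list()
  for (r in seq_len(nrow(cmb))) {
    ga <- cmb[r, 1]; gb <- cmb[r, 2]
    sa <- locusSequence(genomes[[ga]], loci[[ga]])
    sb <- locusSequence(genomes[[gb]], loci[[gb]])
    blocks <- .stageError("synteny", anchorAlign(
      sa, sb, word = cfg$word, minBlock = cfg$minBlock,
      minIdentity = cfg$minIdentity))
    cc <- callUnalignableRegions(blocks, nchar(sa), nchar(sb),
                                 minRegion = cfg$minRegion)
    regs <- cc$regions
    if (nrow(regs)) for (i in seq_len(nrow(regs))) {
      side <- regs$locus[i]
      gname <- if (side == "A") ga else gb
      seq <- substr(if (side == "A") sa else sb,
                    regs$start[i] + 1L, regs$end[i])
      ot <- .stageError("origin", testRegionOrigin(
        seq, genomes[[gname]], loci[[gname]]))
      regs$origin[i] <- ot$origin
      regs$longestHit[i] <- ot$longestHit
    }
    if (nrow(regs)) {
      regs$genomeA <- ga; regs$genomeB <- gb
      regs$genome <- ifelse(regs$locus == "A", ga, gb)
      regionRows[[length(regionRows) + 1L]] <- regs
    }
    compRows[[length(compRows) + 1L]] <- data.frame(
      genomeA = ga, genomeB = gb, nBlocks = nrow(cc$blocks),
      blockCoverageA = .totalCovered(data.frame(start = cc$blocks$aStart,
                                                end = cc$blocks$aEnd)),
      nUnalignable = nrow(regs),
      unalignableLength = if (nrow(regs)) sum(regs$length) else 0,
      stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, compRows)
  regions <- if (length(regionRows)) do.call(rbind, regionRows) else
    data.frame(locus = character(), start = numeric(), end = numeric(),
               length = numeric(), origin = character(),
               longestHit = numeric(), genomeA = character(),
               genomeB = character(), genome = character(),
               stringsAsFactors = FALSE)
  rownames(regions) <- NULL

  # ---- per-family statistics and breakpoint scans on curated genes
  geneStats <- list()
  breakpoints <- list()
  for (fam in c(cfg$familyB, cfg$familyC)) {
    members <- if (fam == cfg$familyB) pairFilt$intact$bGene else
      pairFilt$intact$cGene
    memGenomes <- pairFilt$intact$genome
    if (length(members) >= 4L) {
      cds <- stats::setNames(unlist(lapply(seq_along(members), function(i)
        .geneCds(genomes[[memGenomes[i]]], members[i]))),
        paste(memGenomes, members, sep = "|"))
      caln <- .stageError("stats", .codonAlign(cds))
      ntAln <- caln
      td <- tajimasD(ntAln)
      # median pairwise dN/dS
      ratios <- c()
      nd <- utils::combn(length(caln), 2)
      for (p in seq_len(ncol(nd))) {
        r <- tryCatch(ng86dnds(caln[[nd[1, p]]], caln[[nd[2, p]]])$ratio,
                      error = function(e) NA_real_)
        ratios <- c(ratios, r)
      }
      aaIds <- c()
      prots <- vapply(cds, function(s)
        gsub("*", "X", .translateCds(strsplit(s, "")[[1]]), fixed = TRUE), "")
      pm <- .alignProteins(prots)
      for (p in seq_len(ncol(nd)))
        aaIds <- c(aaIds, pairwiseIdentity(.collapse(pm[nd[1, p], ]),
                                           .collapse(pm[nd[2, p], ]),
                                           mode = "aa"))
      geneStats[[fam]] <- data.frame(
        family = fam, n = td$n, sites = td$L, S = td$S, pi = td$pi,
        thetaW = td$thetaW, tajimasD = td$D, defined = td$defined,
        medianDnDs = stats::median(ratios, na.rm = TRUE),
        meanAaIdentity = mean(aaIds, na.rm = TRUE),
        stringsAsFactors = FALSE)
      bp <- .stageError("recomb", segmentAlignment(
        ntAln, maxBreakpoints = cfg$maxBreakpoints, penalty = cfg$penalty,
        step = cfg$recombStep, minSegment = cfg$minSegment))
      if (cfg$nPerm > 0L)
        bp <- testBreakpointSignificance(ntAln, bp, nPerm = cfg$nPerm,
                                         seed = cfg$seed)
      breakpoints[[fam]] <- bp
    }
  }
  geneStats <- if (length(geneStats)) do.call(rbind, geneStats) else
    data.frame(family = character(), n = integer(), sites = integer(),
               S = integer(), pi = numeric(), thetaW = numeric(),
               tajimasD = numeric(), defined = logical(),
               medianDnDs = numeric(), meanAaIdentity = numeric(),
               stringsAsFactors = FALSE)
  rownames(geneStats) <- NULL

  report <- new("RunReport", loci = lociTbl, pairs = pairsTbl,
                comparisons = comparisons, regions = regions,
                geneStats = geneStats, breakpoints = breakpoints,
                truthMetrics = data.frame(), manifest = cfg)

  if (!is.null(truth))
    report@truthMetrics <- compareToTruth(report, truth)

  if (!is.null(cfg$outDir)) .writeReport(report, cfg$outDir)
  report
}

.writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report@loci, "loci.tsv")
  wt(report@pairs, "pairs.tsv")
  wt(report@comparisons, "comparisons.tsv")
  wt(report@regions, "unalignable_regions.tsv")
  wt(report@geneStats, "gene_stats.tsv")
  if (nrow(report@truthMetrics)) wt(report@truthMetrics, "truth_metrics.tsv")
  if (nrow(report@regions)) {
    bed <- data.frame(chrom = report@regions$genome,
                      start = report@regions$start,
                      end = report@regions$end,
                      name = paste0("unalignable_", report@regions$origin))
    utils::write.table(bed, file.path(dir, "unalignable_regions.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  bp <- do.call(rbind, lapply(names(report@breakpoints), function(f) {
    b <- report@breakpoints[[f]]
    if (!length(b$breakpoints)) return(NULL)
    data.frame(family = f, column = b$breakpoints, pvalue = b$pvalues)
  }))
  if (!is.null(bp)) wt(bp, "breakpoints.tsv")
  manifest <- report@manifest
  manifest$tree <- if (inherits(manifest$tree, "phylo"))
    ape::write.tree(manifest$tree) else manifest$tree
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

# geometric truth scan for diverging pairs in a tip genome, from annotation
.truthPairs <- function(genome, params, markers, maxGap = 3000) {
  loc <- extractLocus(genome, markers)
  findDivergingPairs(loc, params@familyB, params@familyC, maxGap = maxGap)
}

#' Score a pipeline report against simulation truth
#'
#' Diverging pairs are matched by gene ids; truncations by gene id against
#' truncation events still present in each tip. Unalignable regions are
#' scored against per-base ancestry truth ([ancestryMap()]): recall is the
#' fraction of novel-core truth regions (locus material with no ancestral
#' counterpart in the partner locus) at least half covered by calls;
#' precision is the fraction of calls lying at least half inside the
#' permissive surplus mask (novel material plus every copy of
#' over-represented material, since a 1-1 collinear map necessarily leaves
#' one copy unplaced but which copy is the aligner's free choice); boundary
#' error is the mean distance from call boundaries to the nearest mask
#' transition. A comparison with no truth and no calls scores recall and
#' precision 1 by convention.
#'
#' @param report a [RunReport-class] from [runPipeline()].
#' @param truth the `hotspotSim` object of the same run (seed is checked).
#' @return data frame: `category`, `recall`, `precision`, `boundaryError`,
#'   `n`.
#' @export
compareToTruth <- function(report, truth) {
  stopifnot(inherits(truth, "hotspotSim"))
  cfgSeed <- report@manifest$seed
  if (!is.null(cfgSeed) && cfgSeed != truth$params@seed)
    .stopf("seed mismatch between report manifest (%s) and truth (%s)",
           cfgSeed, truth$params@seed)
  params <- truth$params
  markers <- report@manifest$markers
  if (is.null(markers)) markers <- params@markerIds[1:2]

  # --- diverging pairs (geometric detection, any intactness)
  key <- function(df) if (nrow(df)) paste(df$genome, df$bGene, df$cGene)
    else character()
  truthPairs <- do.call(rbind, lapply(truth$tips, .truthPairs,
                                      params = params, markers = markers,
                                      maxGap = report@manifest$maxGap))
  called <- report@pairs
  tp <- length(intersect(key(truthPairs), key(called)))
  pairRec <- if (nrow(truthPairs)) tp / nrow(truthPairs) else 1
  pairPrec <- if (nrow(called)) tp / nrow(called) else 1

  # --- truncations: truth-truncated pair-family genes still present
  truncTruth <- character()
  for (nm in names(truth$logs)) {
    lg <- truth$logs[[nm]]
    ids <- lg$gene_ids[lg$kind == "truncation"]
    g <- geneModels(truth$tips[[nm]])
    fams <- c(params@familyB, params@familyC)
    present <- ids[ids %in% g$gene_id[g$family %in% fams]]
    truncTruth <- c(truncTruth, paste(nm, present))
  }
  calledTrunc <- character()
  if (nrow(report@pairs)) {
    rej <- report@pairs[report@pairs$status == "rejected", , drop = FALSE]
    for (i in seq_len(nrow(rej))) {
      if (!rej$bIntact[i]) calledTrunc <- c(calledTrunc,
                                            paste(rej$genome[i], rej$bGene[i]))
      if (!rej$cIntact[i]) calledTrunc <- c(calledTrunc,
                                            paste(rej$genome[i], rej$cGene[i]))
    }
  }
  # restrict truth to genes that sit in called pairs (the filter only ever
  # sees pair members)
  pairGenes <- c(paste(report@pairs$genome, report@pairs$bGene),
                 paste(report@pairs$genome, report@pairs$cGene))
  truncTruthSeen <- intersect(truncTruth, pairGenes)
  ttp <- length(intersect(truncTruthSeen, calledTrunc))
  truncRec <- if (length(truncTruthSeen)) ttp / length(truncTruthSeen) else 1
  truncPrec <- if (length(calledTrunc))
    length(intersect(calledTrunc, truncTruth)) / length(calledTrunc) else 1

  # --- unalignable regions: truth from per-base ancestry -- runs of locus
  # bases whose root-ancestry tags have no counterpart in the partner locus
  locusOf <- function(nm) extractLocus(truth$tips[[nm]], markers)
  ids <- names(truth$tips)
  locs <- stats::setNames(lapply(ids, locusOf), ids)
  amaps <- stats::setNames(lapply(ids, function(nm)
    ancestryMap(truth$root, truth$logs[[nm]])), ids)
  locusTags <- function(nm) {
    l <- locs[[nm]]
    amaps[[nm]][[l@contig]][(l@start + 1L):l@end]
  }
  minRegion <- report@manifest$minRegion
  markedRuns <- function(mark, slop = 600L, minLen = minRegion) {
    r <- rle(mark)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    iv <- data.frame(start = starts[r$values], end = ends[r$values])
    iv <- iv[iv$end - iv$start >= 200L, , drop = FALSE]  # ignore slivers
    if (!nrow(iv)) return(iv)
    iv <- .mergeIntervals(iv, slop = slop)
    iv[iv$end - iv$start >= minLen, , drop = FALSE]
  }
  # novel core: bases with no ancestry counterpart anywhere in the partner
  # locus (assignment-unambiguous truth; recall is scored against it).
  # permissive mask: additionally every copy of over-represented material --
  # a 1-1 collinear map must leave one copy of such material unplaced, but
  # which copy is the aligner's free choice, so precision and boundaries are
  # scored against the mask.
  surplusMask <- function(tX, tY) {
    cntX <- table(tX); cntY <- table(tY)
    haveY <- as.numeric(cntY[as.character(tX)]); haveY[is.na(haveY)] <- 0
    haveX <- as.numeric(cntX[as.character(tX)])
    as.vector(haveX > haveY)
  }
  nTruth <- 0L; nTruthCov <- 0L; nCalled <- 0L; nCalledTP <- 0L
  bErr <- c()
  ovl <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  for (r in seq_len(nrow(report@comparisons))) {
    ga <- report@comparisons$genomeA[r]; gb <- report@comparisons$genomeB[r]
    tA <- locusTags(ga); tB <- locusTags(gb)
    for (side in c("A", "B")) {
      x <- if (side == "A") tA else tB
      y <- if (side == "A") tB else tA
      core <- markedRuns(!(x %in% y))
      mask <- markedRuns(surplusMask(x, y), minLen = 500L)
      called <- report@regions[report@regions$genomeA == ga &
                                 report@regions$genomeB == gb &
                                 report@regions$locus == side, , drop = FALSE]
      for (i in seq_len(nrow(core))) {
        nTruth <- nTruth + 1L
        cov <- sum(vapply(seq_len(nrow(called)), function(j)
          ovl(core$start[i], core$end[i], called$start[j], called$end[j]), 0))
        if (cov >= 0.5 * (core$end[i] - core$start[i]))
          nTruthCov <- nTruthCov + 1L
      }
      for (j in seq_len(nrow(called))) {
        nCalled <- nCalled + 1L
        inMask <- sum(vapply(seq_len(nrow(mask)), function(i)
          ovl(mask$start[i], mask$end[i], called$start[j], called$end[j]), 0))
        if (nrow(mask) && inMask >= 0.5 * (called$end[j] - called$start[j])) {
          nCalledTP <- nCalledTP + 1L
          bErr <- c(bErr,
                    (min(abs(called$start[j] - mask$start),
                         abs(called$start[j] - mask$end)) +
                       min(abs(called$end[j] - mask$start),
                           abs(called$end[j] - mask$end))) / 2)
        }
      }
    }
  }
  regRec <- if (nTruth) nTruthCov / nTruth else 1
  regPrec <- if (nCalled) nCalledTP / nCalled else 1

  data.frame(
    category = c("diverging_pairs", "truncations", "unalignable_regions"),
    recall = c(pairRec, truncRec, regRec),
    precision = c(pairPrec, truncPrec, regPrec),
    boundaryError = c(NA, NA, if (length(bErr)) mean(bErr) else NA),
    n = c(nrow(truthPairs), length(truncTruthSeen), nTruth),
    stringsAsFactors = FALSE)
}
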