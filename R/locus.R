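# Marker-bounded locus extraction, head-to-head diverging-pair detection,
# and the pair intactness filter (a gene is rejected when it is shortened or
# carries a deletion of more than 50 amino acids relative to the family
# reference; a deletion of exactly 50 residues is tolerated, the removal rule
# being strictly "greater than").

#' Extract the marker-bounded locus of a genome
#'
#' Returns the interval strictly between the outermost marker genes, with
#' every gene model fully contained in it. All markers must be present
#' exactly once, on one contig, in consistent order.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param markers ordered marker gene identifiers (matched against gene id,
#'   falling back to family label).
#' @return A [LocusRegion-class]; `locusSpan()` gives `end - start`.
#' @export
extractLocus <- function(genome, markers) {
  g <- geneModels(genome)
  rows <- lapply(markers, function(mk) {
    r <- g[g$gene_id == mk | g$family == mk, , drop = FALSE]
    if (nrow(r) != 1L)
      .stopf("marker not resolvable: '%s' found %d time(s) in genome %s",
             mk, nrow(r), genomeId(genome))
    r
  })
  mk <- do.call(rbind, rows)
  if (length(unique(mk$contig)) != 1L)
    .stopf("locus split: markers of genome %s lie on different contigs (%s)",
           genomeId(genome), paste(unique(mk$contig), collapse = ", "))
  ord <- order(mk$start)
  if (!(identical(ord, seq_along(markers)) ||
        identical(ord, rev(seq_along(markers)))))
    .stopf("markers of genome %s are not in consistent order",
           genomeId(genome))
  start <- min(mk$end)
  end <- max(mk$start)
  lo <- mk[which.min(mk$start), ]
  hi <- mk[which.max(mk$start), ]
  start <- lo$end
  end <- hi$start
  if (start >= end)
    .stopf("markers of genome %s enclose an empty interval", genomeId(genome))
  contained <- g[g$contig == mk$contig[1] & g$start >= start & g$end <= end &
                   !(g$gene_id %in% mk$gene_id), , drop = FALSE]
  contained <- contained[order(contained$start), , drop = FALSE]
  rownames(contained) <- NULL
  new("LocusRegion", genomeId = genomeId(genome), contig = mk$contig[1],
      start = start, end = end, genes = contained, markers = mk$gene_id)
}

#' Extract the locus nucleotide sequence
#' @param genome an [AnnotatedGenome-class].
#' @param locus a [LocusRegion-class] of that genome.
#' @return A character string.
#' @export
locusSequence <- function(genome, locus) {
  as.character(Biostrings::subseq(contigSeqs(genome)[[locus@contig]],
                                  start = locus@start + 1L, end = locus@end))
}

#' Find head-to-head diverging gene pairs in a locus
#'
#' A pair is two adjacent genes (no intervening gene model), one of family
#' `familyB` and one of `familyC`, transcribed divergently with their 5'
#' ends facing the shared intergenic gap (upstream gene on the minus strand,
#' downstream gene on the plus strand), with gap at most `maxGap`. Pairs are
#' reported 5' to 3' by locus coordinate. Adjacent same-family arrangements
#' in other orientations are counted as near misses.
#'
#' @param locus a [LocusRegion-class] whose genes carry family labels.
#' @param familyB,familyC family labels of the two pair members.
#' @param maxGap maximum intergenic gap in bp.
#' @return data frame: `genome`, `bGene`, `cGene`, `gap`, `bIntact`,
#'   `cIntact`, `pairIntact`, plus a `nearMisses` attribute.
#' @export
findDivergingPairs <- function(locus, familyB, familyC, maxGap = 3000) {
  g <- geneModels(locus)
  g <- g[order(g$start), , drop = FALSE]
  out <- list()
  nearMisses <- 0L
  if (nrow(g) >= 2L) for (i in seq_len(nrow(g) - 1L)) {
    a <- g[i, ]; b <- g[i + 1L, ]
    fams <- c(a$family, b$family)
    if (!setequal(fams, c(familyB, familyC))) next
    gap <- b$start - a$end
    if (a$strand == "-" && b$strand == "+" && gap >= 0 && gap <= maxGap) {
      bg <- if (a$family == familyB) a else b
      cg <- if (a$family == familyC) a else b
      out[[length(out) + 1L]] <- data.frame(
        genome = locus@genomeId, bGene = bg$gene_id, cGene = cg$gene_id,
        gap = gap, bIntact = bg$intact, cIntact = cg$intact,
        pairIntact = bg$intact && cg$intact, stringsAsFactors = FALSE)
    } else nearMisses <- nearMisses + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(genome = character(), bGene = character(),
               cGene = character(), gap = numeric(), bIntact = logical(),
               cIntact = logical(), pairIntact = logical(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "nearMisses") <- nearMisses
  res
}

# Longest gap run in the pattern row (deletions relative to the reference)
# and aligned length fraction, from a global alignment.
.deletionProfile <- function(protein, reference) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = .blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  pat <- as.character(Biostrings::alignedPattern(aln))
  runs <- rle(strsplit(pat, "")[[1]] == "-")
  maxGap <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(maxGapRun = maxGap,
       lengthFraction = nchar(protein) / nchar(reference))
}

#' Check a single gene's intactness against a family reference
#'
#' The per-gene rule behind [filterIntactPairs()]: a gene is intact iff its
#' translation aligns to the family reference without any single deletion
#' (gap run in reference coordinates) longer than `maxDeletionAA` residues
#' (a run of exactly `maxDeletionAA` is tolerated) and its length is at least
#' `minFraction` of the reference length.
#'
#' @param protein the gene's translation (string); empty or stop-containing
#'   translations are non-intact.
#' @param reference the family reference protein (e.g. [familyConsensus()]).
#' @param maxDeletionAA largest tolerated deletion, in residues.
#' @param minFraction minimum length relative to the reference.
#' @return List with `ok` (logical) and `reason` (string, empty when intact).
#' @export
checkGeneIntactness <- function(protein, reference, maxDeletionAA = 50,
                                minFraction = 0.5) {
  if (is.null(protein) || !nzchar(protein))
    return(list(ok = FALSE, reason = "untranslatable"))
  if (grepl("[X*]", protein))
    return(list(ok = FALSE, reason = "internal stop"))
  prof <- .deletionProfile(protein, reference)
  if (prof$lengthFraction < minFraction)
    return(list(ok = FALSE, reason = sprintf(
      "length %.0f%% of reference", 100 * prof$lengthFraction)))
  if (prof$maxGapRun > maxDeletionAA)
    return(list(ok = FALSE,
                reason = sprintf("deletion of %d aa", prof$maxGapRun)))
  list(ok = TRUE, reason = "")
}

#' Filter diverging pairs by gene intactness against family references
#'
#' A gene is intact iff its translation aligns to the family reference
#' without any single deletion (gap run in reference coordinates) longer than
#' `maxDeletionAA` residues and its length is at least `minFraction` of the
#' reference length. A deletion of exactly `maxDeletionAA` residues is
#' tolerated. A pair is intact iff both genes are; untranslatable genes are
#' non-intact with the reason recorded.
#'
#' @param pairs data frame from [findDivergingPairs()] (possibly several loci
#'   concatenated).
#' @param proteins named character vector of gene translations covering all
#'   pair members (e.g. from [geneProteins()]); names are gene ids, or
#'   `genome|gene_id` keys when the same gene id occurs in several genomes.
#' @param references named list/vector with one reference protein for
#'   `familyB` and `familyC` (names are the family labels); see
#'   [familyConsensus()].
#' @param familyB,familyC family labels.
#' @param maxDeletionAA largest tolerated deletion, in residues.
#' @param minFraction minimum length relative to the reference.
#' @return List with `intact` and `rejected` pair data frames; `rejected`
#'   carries a `reason` column.
#' @export
filterIntactPairs <- function(pairs, proteins, references,
                              familyB = "tgrB", familyC = "tgrC",
                              maxDeletionAA = 50, minFraction = 0.5) {
  if (!all(c(familyB, familyC) %in% names(references)))
    .stopf("references must be provided for both pair families")
  lookup <- function(key) {
    i <- match(key, names(proteins))
    if (is.na(i)) NULL else proteins[[i]]
  }
  checkGene <- function(genome, gid, fam) {
    p <- lookup(paste(genome, gid, sep = "|"))
    if (is.null(p)) p <- lookup(gid)
    checkGeneIntactness(p, references[[fam]], maxDeletionAA, minFraction)
  }
  reasons <- character(nrow(pairs))
  ok <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rb <- checkGene(pairs$genome[i], pairs$bGene[i], familyB)
    rc <- checkGene(pairs$genome[i], pairs$cGene[i], familyC)
    pairs$bIntact[i] <- rb$ok
    pairs$cIntact[i] <- rc$ok
    pairs$pairIntact[i] <- rb$ok && rc$ok
    ok[i] <- rb$ok && rc$ok
    reasons[i] <- paste(c(
      if (!rb$ok) paste0(pairs$bGene[i], ": ", rb$reason),
      if (!rc$ok) paste0(pairs$cGene[i], ": ", rc$reason)), collapse = "; ")
  }
  rejected <- pairs[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reasons[!ok]
  else rejected$reason <- character()
  list(intact = pairs[ok, , drop = FALSE], rejected = rejected)
}
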