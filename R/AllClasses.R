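#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

#' Parameters of the forward locus-evolution model
#'
#' `EvolParams` collects every tunable of the simulator: the point-mutation
#' and indel processes, the per-gene rates of the six structural event kinds
#' (segmental duplication, intralocus gene conversion, inversion, gene loss,
#' gene truncation, and transposition of the expanding family), the hotspot
#' rate multiplier applied to structural events whose target lies inside the
#' marker-bounded locus, and the geometry of the root genome.
#'
#' Rates are expressed per gene (structural events) or per site
#' (substitutions, indels) per unit of branch length, so that expected event
#' counts on a branch scale linearly with its length.
#'
#' @slot subRate per-site substitution rate per unit branch length.
#' @slot hotspotMultiplier factor (>= 1) by which structural event rates are
#'   elevated for targets inside the locus.
#' @slot dupRate per-gene segmental duplication rate.
#' @slot recRate per-locus-gene intralocus gene-conversion rate. These events
#'   are by definition confined to the locus.
#' @slot invRate per-gene inversion rate.
#' @slot lossRate per-gene loss rate.
#' @slot truncRate per-gene truncation rate (internal in-frame deletion of
#'   more than 50 codons, flagging the gene non-intact).
#' @slot transRate per-copy transposition rate of the expanding family.
#' @slot indelRate per-site intergenic indel rate.
#' @slot indelMeanLen mean indel length (geometric length distribution).
#' @slot meanGeneLen mean gene length in bp (rounded to whole codons).
#' @slot nBackgroundGenes number of single-copy background genes at the root.
#' @slot nLocusGenes number of genes inside the root locus, including the
#'   diverging pair and one extra copy of each pair family.
#' @slot nExpandingSeeds number of root copies of the expanding family.
#' @slot gcContent target GC fraction of the root genome.
#' @slot markerIds identifiers of the three structurally immune marker genes;
#'   the locus is the interval between the first two, the third sits just
#'   downstream as an outer anchor.
#' @slot familyB,familyC family labels of the diverging receptor pair.
#' @slot expandingFamily family label of the transposing family.
#' @slot seed integer random seed.
#' @export
setClass("EvolParams", representation(
  subRate = "numeric", hotspotMultiplier = "numeric",
  dupRate = "numeric", recRate = "numeric", invRate = "numeric",
  lossRate = "numeric", truncRate = "numeric", transRate = "numeric",
  indelRate = "numeric", indelMeanLen = "numeric",
  meanGeneLen = "numeric",
  nBackgroundGenes = "integer", nLocusGenes = "integer",
  nExpandingSeeds = "integer",
  gcContent = "numeric", markerIds = "character",
  familyB = "character", familyC = "character",
  expandingFamily = "character", seed = "integer"
))

setValidity("EvolParams", function(object) {
  msg <- character()
  rates <- c(object@subRate, object@dupRate, object@recRate, object@invRate,
             object@lossRate, object@truncRate, object@transRate,
             object@indelRate)
  if (any(!is.finite(rates)) || any(rates < 0))
    msg <- c(msg, "all rates must be finite and >= 0")
  if (object@hotspotMultiplier < 1)
    msg <- c(msg, "hotspotMultiplier must be >= 1")
  if (!is.finite(object@meanGeneLen) || object@meanGeneLen <= 0)
    msg <- c(msg, "meanGeneLen must be > 0")
  if (object@gcContent <= 0 || object@gcContent >= 1)
    msg <- c(msg, "gcContent must be in (0, 1)")
  if (length(object@markerIds) != 3L)
    msg <- c(msg, "exactly three markerIds are required")
  if (object@nLocusGenes < 4L)
    msg <- c(msg, "nLocusGenes must be >= 4 (diverging pair plus one extra copy of each family)")
  if (length(msg)) msg else TRUE
})

#' Construct simulator parameters
#'
#' Defaults emulate, at roughly one-tenth scale, a compact AT-rich genome in
#' which a bounded recognition locus experiences strongly elevated structural
#' turnover while the genomic background evolves mostly by point mutation.
#' See the package vignette for the rationale behind each default.
#'
#' @param subRate,hotspotMultiplier,dupRate,recRate,invRate,lossRate,truncRate,transRate,indelRate,indelMeanLen,meanGeneLen,nBackgroundGenes,nLocusGenes,nExpandingSeeds,gcContent,markerIds,familyB,familyC,expandingFamily,seed see the class documentation.
#' @return An [EvolParams-class] object.
#' @examples
#' p <- EvolParams(nBackgroundGenes = 20, nLocusGenes = 6, seed = 1)
#' @export
EvolParams <- function(subRate = 0.02, hotspotMultiplier = 25,
                       dupRate = 0.06, recRate = 0.08, invRate = 0.02,
                       lossRate = 0.025, truncRate = 0.03, transRate = 1.0,
                       indelRate = 5e-4, indelMeanLen = 5,
                       meanGeneLen = 900,
                       nBackgroundGenes = 240L, nLocusGenes = 12L,
                       nExpandingSeeds = 2L,
                       gcContent = 0.23,
                       markerIds = c("wacA", "chdB", "anchorC"),
                       familyB = "tgrB", familyC = "tgrC",
                       expandingFamily = "tgrA",
                       seed = 1L) {
  new("EvolParams", subRate = subRate, hotspotMultiplier = hotspotMultiplier,
      dupRate = dupRate, recRate = recRate, invRate = invRate,
      lossRate = lossRate, truncRate = truncRate, transRate = transRate,
      indelRate = indelRate, indelMeanLen = indelMeanLen,
      meanGeneLen = meanGeneLen,
      nBackgroundGenes = as.integer(nBackgroundGenes),
      nLocusGenes = as.integer(nLocusGenes),
      nExpandingSeeds = as.integer(nExpandingSeeds),
      gcContent = gcContent, markerIds = markerIds,
      familyB = familyB, familyC = familyC,
      expandingFamily = expandingFamily, seed = as.integer(seed))
}

#' An annotated genome: contig sequences plus ordered gene models
#'
#' Gene models are stored as a data frame with columns `gene_id`, `family`,
#' `contig`, `start`, `end`, `strand`, `intact`, `parent_id`. Coordinates are
#' 0-based half-open throughout the package; GFF3 emission converts to
#' 1-based inclusive.
#'
#' @slot genomeId single identifying string.
#' @slot seqs a [Biostrings::DNAStringSet] of contig sequences.
#' @slot genes the gene-model data frame described above.
#' @export
setClass("AnnotatedGenome", representation(
  genomeId = "character", seqs = "ANY", genes = "data.frame"
))

.GENE_COLS <- c("gene_id", "family", "contig", "start", "end",
                "strand", "intact", "parent_id")

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  g <- object@genes
  if (!all(.GENE_COLS %in% names(g)))
    return(paste("gene table must have columns:",
                 paste(.GENE_COLS, collapse = ", ")))
  if (anyDuplicated(g$gene_id))
    msg <- c(msg, "gene identifiers must be unique within a genome")
  if (nrow(g)) {
    if (any(g$start >= g$end))
      msg <- c(msg, "gene intervals must satisfy start < end")
    if (!all(g$contig %in% names(object@seqs)))
      msg <- c(msg, "every gene must lie on a named contig")
    w <- Biostrings::width(object@seqs)[match(g$contig, names(object@seqs))]
    if (any(g$start < 0 | g$end > w))
      msg <- c(msg, "gene intervals must lie within their contig")
    if (any(g$intact & ((g$end - g$start) %% 3L != 0L)))
      msg <- c(msg, "intact genes must have CDS length divisible by 3")
    if (!all(g$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedGenome
#' @param genomeId single string.
#' @param seqs named `DNAStringSet` (or named character vector) of contigs.
#' @param genes gene-model data frame (see [AnnotatedGenome-class]).
#' @return An [AnnotatedGenome-class] object.
#' @export
AnnotatedGenome <- function(genomeId, seqs, genes) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  genes <- as.data.frame(genes)[, .GENE_COLS]
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  rownames(genes) <- NULL
  new("AnnotatedGenome", genomeId = genomeId, seqs = seqs, genes = genes)
}

#' A marker-bounded locus region
#'
#' The interval strictly between the outermost resolved marker genes of a
#' genome, with the gene models it contains. Markers flank the interval but
#' are excluded from it; `end - start` is the reported locus span.
#'
#' @slot genomeId,contig identifying strings.
#' @slot start,end 0-based half-open interval on `contig`.
#' @slot genes gene models fully contained in the interval.
#' @slot markers the bounding marker gene identifiers.
#' @export
setClass("LocusRegion", representation(
  genomeId = "character", contig = "character",
  start = "numeric", end = "numeric",
  genes = "data.frame", markers = "character"
))

setValidity("LocusRegion", function(object) {
  msg <- character()
  if (object@start >= object@end)
    msg <- c(msg, "locus must satisfy start < end")
  g <- object@genes
  if (nrow(g) && any(g$start < object@start | g$end > object@end))
    msg <- c(msg, "contained genes must lie within the locus interval")
  if (nrow(g) && any(g$gene_id %in% object@markers))
    msg <- c(msg, "markers flank the locus and are excluded from it")
  if (length(msg)) msg else TRUE
})

#' Consolidated result of a full pipeline run
#'
#' @slot loci per-genome locus table (genome, contig, span, gene count).
#' @slot pairs diverging-pair table with intactness calls.
#' @slot comparisons per-locus-pair synteny summary (blocks, unalignable
#'   regions, origin calls).
#' @slot regions all called unalignable regions with origin calls.
#' @slot geneStats per-family molecular-evolution statistics.
#' @slot breakpoints list of breakpoint sets per curated family alignment.
#' @slot truthMetrics recall/precision table when simulation truth is known.
#' @slot manifest list echoing every parameter of the run.
#' @export
setClass("RunReport", representation(
  loci = "data.frame", pairs = "data.frame", comparisons = "data.frame",
  regions = "data.frame", geneStats = "data.frame",
  breakpoints = "list", truthMetrics = "data.frame", manifest = "list"
))

#' @describeIn AnnotatedGenome-class genome identifier
#' @param x an object.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
setMethod("genomeId", "AnnotatedGenome", function(x) x@genomeId)
setMethod("genomeId", "LocusRegion", function(x) x@genomeId)

#' @describeIn AnnotatedGenome-class contig sequences as a DNAStringSet
#' @export
setGeneric("contigSeqs", function(x) standardGeneric("contigSeqs"))
setMethod("contigSeqs", "AnnotatedGenome", function(x) x@seqs)

#' @describeIn AnnotatedGenome-class gene-model data frame
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
setMethod("geneModels", "AnnotatedGenome", function(x) x@genes)
setMethod("geneModels", "LocusRegion", function(x) x@genes)

#' @describeIn LocusRegion-class locus span in bp
#' @param x an object.
#' @export
setGeneric("locusSpan", function(x) standardGeneric("locusSpan"))
setMethod("locusSpan", "LocusRegion", function(x) x@end - x@start)

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome '", object@genomeId, "': ",
      length(object@seqs), " contig(s), ",
      sum(Biostrings::width(object@seqs)), " bp, ",
      nrow(object@genes), " gene model(s) (",
      sum(object@genes$intact), " intact)\n", sep = "")
})

setMethod("show", "LocusRegion", function(object) {
  cat("LocusRegion ", object@genomeId, ":", object@contig,
      " [", object@start, ",", object@end, ") span ",
      object@end - object@start, " bp, ", nrow(object@genes),
      " gene(s), markers: ", paste(object@markers, collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport:", nrow(object@loci), "loci,",
      nrow(object@pairs), "diverging pairs,",
      nrow(object@comparisons), "locus comparisons,",
      nrow(object@regions), "unalignable regions\n")
  if (nrow(object@truthMetrics)) {
    cat("Truth comparison:\n")
    print(object@truthMetrics)
  }
})

setMethod("show", "EvolParams", function(object) {
  cat("EvolParams: subRate=", object@subRate,
      ", hotspot x", object@hotspotMultiplier,
      ", structural rates (dup/rec/inv/loss/trunc/trans) = ",
      paste(c(object@dupRate, object@recRate, object@invRate,
              object@lossRate, object@truncRate, object@transRate),
            collapse = "/"),
      ", seed=", object@seed, "\n", sep = "")
})
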