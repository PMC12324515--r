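# Gene-family curation: translated homolog search against query proteins
# (local alignment under BLOSUM62 with a shared-k-mer prefilter), the
# pseudogene length filter (members shorter than half the longest family
# member are removed; the boundary is retained because the removal rule is
# strictly "shorter than"), family tree construction, and classification of
# families as static single-copy versus expanding.

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Translate every annotated gene of a genome
#'
#' CDS intervals are extracted on their coding strand and translated with the
#' standard code; internal stops become `X` so that pseudogene fragments stay
#' searchable. The terminal stop is dropped.
#'
#' @param genome an [AnnotatedGenome-class].
#' @return Named character vector of protein sequences (names = gene ids).
#' @export
geneProteins <- function(genome) {
  g <- geneModels(genome)
  seqs <- lapply(as.character(contigSeqs(genome)),
                 function(s) strsplit(s, "")[[1]])
  out <- vapply(seq_len(nrow(g)), function(i) {
    aa <- .translateCds(.geneSeq(seqs, g[i, ]))
    gsub("*", "X", aa, fixed = TRUE)
  }, "")
  stats::setNames(out, g$gene_id)
}

.aaKmers <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Find homologs of query protein families across genomes
#'
#' Every annotated CDS is translated and locally aligned (affine gaps,
#' BLOSUM62) against all queries, after a shared 4-mer prefilter. A gene is
#' reported as a hit when its best alignment score reaches `minScore`, and it
#' carries the best-scoring query's family label. Non-intact genes are
#' translated through their internal stops and remain searchable.
#'
#' @param genomes list of [AnnotatedGenome-class] objects.
#' @param queries named character vector or `AAStringSet` of query proteins;
#'   names are family labels.
#' @param minScore minimum local alignment score.
#' @param minSharedKmers prefilter: minimum number of shared 4-mers.
#' @return data frame: `genome`, `gene_id`, `family`, `score`, `fraction`
#'   (aligned fraction of the best query), `length` (protein length),
#'   `intact`, `protein`.
#' @export
findHomologs <- function(genomes, queries, minScore = 250,
                         minSharedKmers = 2L) {
  if (methods::is(queries, "XStringSet")) queries <- as.character(queries)
  if (!length(queries) || is.null(names(queries)))
    .stopf("queries must be a non-empty named set of proteins")
  qk <- lapply(queries, .aaKmers)
  out <- list()
  for (genome in genomes) {
    prots <- geneProteins(genome)
    if (!length(prots)) next
    gm <- geneModels(genome)
    pk <- lapply(prots, .aaKmers)
    best <- data.frame(gene = names(prots), score = -Inf,
                       family = NA_character_, fraction = NA_real_,
                       stringsAsFactors = FALSE)
    for (q in seq_along(queries)) {
      cand <- which(vapply(pk, function(x)
        sum(x %in% qk[[q]]) >= minSharedKmers, TRUE))
      if (!length(cand)) next
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(prots[cand]),
        Biostrings::AAString(queries[[q]]),
        type = "local", substitutionMatrix = .blosum62(),
        gapOpening = 10, gapExtension = 0.5, scoreOnly = FALSE)
      sc <- Biostrings::score(aln)
      fr <- Biostrings::width(Biostrings::subject(aln)) /
        nchar(queries[[q]])
      upd <- sc > best$score[cand]
      best$score[cand][upd] <- sc[upd]
      best$family[cand][upd] <- names(queries)[q]
      best$fraction[cand][upd] <- fr[upd]
    }
    keep <- is.finite(best$score) & best$score >= minScore
    if (any(keep)) {
      idx <- match(best$gene[keep], gm$gene_id)
      out[[length(out) + 1L]] <- data.frame(
        genome = genomeId(genome), gene_id = best$gene[keep],
        family = best$family[keep], score = best$score[keep],
        fraction = pmin(best$fraction[keep], 1),
        length = nchar(prots[best$gene[keep]]),
        intact = gm$intact[idx], protein = unname(prots[best$gene[keep]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(genome = character(), gene_id = character(),
                      family = character(), score = numeric(),
                      fraction = numeric(), length = integer(),
                      intact = logical(), protein = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove likely pseudogenes by relative protein length
#'
#' Within each family, the longest hit defines the reference length; hits
#' strictly shorter than `fractionThreshold` times that length are removed.
#' A hit exactly at the threshold is retained. Applying the filter twice
#' equals applying it once.
#'
#' @param hits data frame from [findHomologs()].
#' @param fractionThreshold length fraction below which hits are removed.
#' @return List with `retained` and `removed` data frames.
#' @export
filterByLength <- function(hits, fractionThreshold = 0.5) {
  if (!nrow(hits)) .stopf("hits must be non-empty")
  keep <- logical(nrow(hits))
  for (fam in unique(hits$family)) {
    sel <- hits$family == fam
    lmax <- max(hits$length[sel])
    keep[sel] <- hits$length[sel] >= fractionThreshold * lmax
    if (!any(keep[sel]))
      warning(sprintf("family '%s' has no members after length filtering",
                      fam))
  }
  list(retained = hits[keep, , drop = FALSE],
       removed = hits[!keep, , drop = FALSE])
}

# Multiple protein alignment via the MAFFT executable (deterministic default
# progressive mode). Returns a character matrix.
.alignProteins <- function(proteins) {
  if (Sys.which("mafft") == "")
    .stopf("the 'mafft' executable is required for multiple alignment")
  if (is.null(names(proteins)))
    names(proteins) <- paste0("s", seq_along(proteins))
  inf <- tempfile(fileext = ".fa"); outf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(inf, outf)))
  writeLines(paste0(">", names(proteins), "\n", unlist(proteins)), inf)
  status <- system2("mafft", c("--quiet", "--retree", "2", "--maxiterate",
                               "0", "--anysymbol", shQuote(inf)),
                    stdout = outf, stderr = FALSE)
  if (status != 0L) .stopf("mafft failed with status %d", status)
  aln <- Biostrings::readAAStringSet(outf)
  m <- .alnMatrix(aln)
  rownames(m) <- sub("\\s.*$", "", names(aln))
  m
}

.dropGappyColumns <- function(m, maxGapFrac = 0.5) {
  gapFrac <- colMeans(matrix(m %in% .GAP, nrow = nrow(m)))
  m[, gapFrac <= maxGapFrac, drop = FALSE]
}

.pDistMatrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !(m[i, ] %in% .GAP) & !(m[j, ] %in% .GAP)
    d[i, j] <- d[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
  }
  d
}

#' Build a family tree from protein sequences
#'
#' Sequences are multiply aligned, columns with more than 50% gaps are
#' removed, and neighbor-joining is applied to the p-distance matrix.
#' Negative NJ branch lengths are clamped to zero.
#'
#' @param proteins named character vector (>= 3 sequences).
#' @param familyLabel used in error messages.
#' @return Unrooted `phylo` tree.
#' @export
buildFamilyTree <- function(proteins, familyLabel = "family") {
  if (length(proteins) < 3L)
    .stopf("family '%s' has fewer than 3 sequences; no tree built",
           familyLabel)
  m <- .dropGappyColumns(.alignProteins(proteins))
  d <- .pDistMatrix(m)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

.rfDistance <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) return(0)
  t1 <- ape::unroot(ape::keep.tip(t1, shared))
  t2 <- ape::unroot(ape::keep.tip(t2, shared))
  phangorn::RF.dist(t1, t2)
}

# number of distinct genomic sites occupied by a family in one genome:
# maximal runs of consecutive family members in contig gene order
.familySites <- function(genome, fam) {
  g <- geneModels(genome)
  g <- g[order(g$contig, g$start), , drop = FALSE]
  isFam <- g$family == fam
  sum(isFam & (!c(FALSE, isFam[-length(isFam)]) |
                 c("", g$contig[-nrow(g)]) != g$contig))
}

#' Classify families as static single-copy, expanding, or ambiguous
#'
#' A family is `static_single_copy` iff it has exactly one copy in every
#' genome and its tree is topologically concordant with the species tree
#' (Robinson-Foulds distance 0 over shared leaves). It is `expanding` iff
#' any genome carries three or more copies, or the family occupies two or
#' more distinct genomic insertion sites in a genome (requires `genomes`).
#' Everything else is `ambiguous`. Absence from a genome is recorded as copy
#' number 0, never an error.
#'
#' @param hits retained hits from [filterByLength()].
#' @param familyTrees named list of `phylo` trees (tips = gene ids or genome
#'   ids); families without a tree get concordance `NA`.
#' @param speciesTree `phylo` with genome ids as tips.
#' @param genomes optional list of [AnnotatedGenome-class] for insertion-site
#'   counting.
#' @param genomeIds universe of genomes (defaults to those in `hits`).
#' @return data frame: `family`, `class`, `concordant`, `maxCopies`,
#'   `copyNumbers` (semicolon-separated `genome=count`).
#' @export
classifyFamilies <- function(hits, familyTrees = list(), speciesTree = NULL,
                             genomes = NULL,
                             genomeIds = sort(unique(hits$genome))) {
  fams <- sort(unique(hits$family))
  rows <- lapply(fams, function(fam) {
    sel <- hits[hits$family == fam, , drop = FALSE]
    cn <- table(factor(sel$genome, levels = genomeIds))
    concordant <- NA
    tr <- familyTrees[[fam]]
    if (!is.null(tr) && !is.null(speciesTree) && all(cn <= 1)) {
      tipGenome <- sel$genome[match(tr$tip.label, sel$gene_id)]
      t1 <- tr
      if (!all(is.na(tipGenome))) t1$tip.label <-
          ifelse(is.na(tipGenome), tr$tip.label, tipGenome)
      concordant <- .rfDistance(t1, speciesTree) == 0
    }
    sites <- if (!is.null(genomes)) {
      max(vapply(genomes, .familySites, 0, fam = fam))
    } else 1L
    cls <- if (all(cn == 1) && isTRUE(concordant)) "static_single_copy"
      else if (any(cn >= 3) || sites >= 2L) "expanding"
      else "ambiguous"
    data.frame(family = fam, class = cls, concordant = concordant,
               maxCopies = max(cn),
               copyNumbers = paste(sprintf("%s=%d", names(cn), as.integer(cn)),
                                   collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Majority-rule consensus protein of a family's longest members
#'
#' The reference used by the pair-intactness filter: the longest 25% of
#' family members (at least two when available) are aligned and each column's
#' most frequent non-gap residue is taken; columns that are gaps in the
#' majority of rows are dropped.
#'
#' @param proteins named character vector of the family's member proteins.
#' @return A single consensus protein string.
#' @export
familyConsensus <- function(proteins) {
  if (!length(proteins)) .stopf("no proteins supplied")
  if (length(proteins) == 1L) return(unname(proteins))
  len <- nchar(proteins)
  k <- max(2L, ceiling(length(proteins) * 0.25))
  top <- proteins[order(len, decreasing = TRUE)[seq_len(min(k, length(proteins)))]]
  if (length(top) == 1L) return(unname(top))
  m <- .alignProteins(top)
  cons <- apply(m, 2, function(col) {
    if (mean(col %in% .GAP) > 0.5) return(NA_character_)
    tb <- sort(table(col[!(col %in% .GAP)]), decreasing = TRUE)
    names(tb)[1]
  })
  paste(cons[!is.na(cons)], collapse = "")
}
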