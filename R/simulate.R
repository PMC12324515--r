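# Forward simulator of annotated genomes along a species tree, with a
# marker-bounded locus in which structural events (segmental duplication,
# intralocus gene conversion, inversion, gene loss, gene truncation) occur at
# an elevated rate. Point substitutions and intergenic indels act genome-wide
# at uniform rates; the hotspot multiplier applies to structural events only,
# so that the locus becomes structurally scrambled while remaining
# recognisable at the sequence level, as observed in real recognition loci.
#
# Internally a genome is a list(id, seqs, genes) where seqs is a named list
# of single-base character vectors (cheap splicing) and genes the standard
# gene-model data frame. Events are logged with the coordinates valid at the
# moment of application, so that replaying the log from the root genome
# reproduces each tip exactly.

.EVENT_COLS <- c("branch", "kind", "src_contig", "src_start", "src_end",
                 "dst_contig", "dst_start", "dst_end", "gene_ids", "detail")

.STRUCTURAL_KINDS <- c("duplication", "recombination", "inversion", "loss",
                       "truncation", "transposition")

.emptyLog <- function() {
  data.frame(branch = character(), kind = character(),
             src_contig = character(), src_start = numeric(),
             src_end = numeric(), dst_contig = character(),
             dst_start = numeric(), dst_end = numeric(),
             gene_ids = character(), detail = character(),
             stringsAsFactors = FALSE)
}

.logRow <- function(branch, kind, src = c(NA, NA, NA), dst = c(NA, NA, NA),
                    gene_ids = "", detail = "") {
  data.frame(branch = branch, kind = kind,
             src_contig = as.character(src[[1]]),
             src_start = as.numeric(src[[2]]), src_end = as.numeric(src[[3]]),
             dst_contig = as.character(dst[[1]]),
             dst_start = as.numeric(dst[[2]]), dst_end = as.numeric(dst[[3]]),
             gene_ids = gene_ids, detail = detail, stringsAsFactors = FALSE)
}

.asInternal <- function(g) {
  list(id = g@genomeId,
       seqs = lapply(as.character(g@seqs), function(s) strsplit(s, "")[[1]]),
       genes = g@genes)
}

.asGenome <- function(int) {
  AnnotatedGenome(int$id,
                  vapply(int$seqs, .collapse, "", USE.NAMES = TRUE),
                  int$genes)
}

# ---- root genome ---------------------------------------------------------

.sampleGeneCodons <- function(meanLen, minCodons = 95L) {
  mu <- meanLen / 3
  max(minCodons, round(stats::rgamma(1, shape = 8, rate = 8 / mu)))
}

#' Simulate the root genome
#'
#' Builds an ancestral genome with one background contig of single-copy
#' genes (interspersed with seed copies of the expanding family) and one
#' hotspot contig laid out as
#' `[markerA][locus: diverging pair + extra pair copies + filler genes][markerB][markerC]`.
#' The diverging pair is head-to-head: the B-family gene on the minus strand
#' immediately upstream of the C-family gene on the plus strand, sharing an
#' intergenic promoter region.
#'
#' @param params an [EvolParams-class] object; `params@seed` seeds the
#'   construction, so equal parameters give byte-identical genomes.
#' @return An [AnnotatedGenome-class].
#' @examples
#' g <- simulateRootGenome(EvolParams(nBackgroundGenes = 20, nLocusGenes = 6,
#'                                    seed = 7))
#' @export
simulateRootGenome <- function(params) {
  stopifnot(is(params, "EvolParams"))
  methods::validObject(params)
  set.seed(params@seed)
  gc <- params@gcContent

  genes <- list()
  addGene <- function(chars, id, family, contig, pos, strand, intact = TRUE,
                      parent = NA_character_) {
    if (strand == "-") chars <- .revcompChars(chars)
    genes[[length(genes) + 1L]] <<- list(
      chars = chars, gene_id = id, family = family, contig = contig,
      start = pos, end = pos + length(chars), strand = strand,
      intact = intact, parent_id = parent)
    invisible(NULL)
  }

  buildContig <- function(parts) {
    # parts: list of either list(gene spec) or integer spacer length
    chunks <- list()
    for (p in parts) chunks[[length(chunks) + 1L]] <- p
    chunks
  }

  spacer <- function() sample(150:400, 1L)

  # background contig
  pos <- 0L
  bgChunks <- list()
  push <- function(chars) {
    bgChunks[[length(bgChunks) + 1L]] <<- chars
    pos <<- pos + length(chars)
  }
  push(.randBases(spacer(), gc))
  expandingSeed <- .randCodingBases(.sampleGeneCodons(params@meanGeneLen), gc)
  expandSlots <- if (params@nExpandingSeeds > 0)
    sort(sample(params@nBackgroundGenes, params@nExpandingSeeds)) else integer()
  nExp <- 0L
  for (i in seq_len(params@nBackgroundGenes)) {
    fam <- sprintf("bg%03d", i)
    chars <- .randCodingBases(.sampleGeneCodons(params@meanGeneLen), gc)
    addGene(chars, fam, fam, "bg1", pos, sample(c("+", "-"), 1L))
    push(genes[[length(genes)]]$chars)
    push(.randBases(spacer(), gc))
    if (i %in% expandSlots) {
      nExp <- nExp + 1L
      id <- paste0(params@expandingFamily, ".", nExp)
      addGene(expandingSeed, id, params@expandingFamily, "bg1", pos, "+")
      push(genes[[length(genes)]]$chars)
      push(.randBases(spacer(), gc))
    }
  }
  bgSeq <- unlist(bgChunks, use.names = FALSE)

  # hotspot contig: markerA [locus] markerB markerC
  pos <- 0L
  hsChunks <- list()
  push2 <- function(chars) {
    hsChunks[[length(hsChunks) + 1L]] <<- chars
    pos <<- pos + length(chars)
  }
  push2(.randBases(spacer(), gc))
  mk <- function(id) {
    chars <- .randCodingBases(.sampleGeneCodons(params@meanGeneLen), gc)
    addGene(chars, id, id, "hs1", pos, "+")
    push2(genes[[length(genes)]]$chars)
    push2(.randBases(spacer(), gc))
  }
  mk(params@markerIds[1])

  # diverging pair: B on '-', then promoter gap, then C on '+'
  bChars <- .randCodingBases(round(1.2 * params@meanGeneLen / 3), gc)
  cChars <- .randCodingBases(round(1.5 * params@meanGeneLen / 3), gc)
  addGene(bChars, paste0(params@familyB, ".1"), params@familyB,
                 "hs1", pos, "-")
  push2(genes[[length(genes)]]$chars)
  push2(.randBases(sample(300:800, 1L), gc))
  addGene(cChars, paste0(params@familyC, ".1"), params@familyC,
                 "hs1", pos, "+")
  push2(genes[[length(genes)]]$chars)
  push2(.randBases(spacer(), gc))

  # extra pair-family copies (recombination partners), then fillers
  addGene(bChars, paste0(params@familyB, ".2"), params@familyB,
                 "hs1", pos, sample(c("+", "-"), 1L))
  push2(genes[[length(genes)]]$chars)
  push2(.randBases(spacer(), gc))
  addGene(cChars, paste0(params@familyC, ".2"), params@familyC,
                 "hs1", pos, sample(c("+", "-"), 1L))
  push2(genes[[length(genes)]]$chars)
  push2(.randBases(spacer(), gc))
  nFill <- params@nLocusGenes - 4L
  for (i in seq_len(max(0L, nFill))) {
    fam <- sprintf("locF%02d", i)
    chars <- .randCodingBases(.sampleGeneCodons(params@meanGeneLen), gc)
    addGene(chars, fam, fam, "hs1", pos, sample(c("+", "-"), 1L))
    push2(genes[[length(genes)]]$chars)
    push2(.randBases(spacer(), gc))
  }
  mk(params@markerIds[2])
  mk(params@markerIds[3])
  hsSeq <- unlist(hsChunks, use.names = FALSE)

  gdf <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, family = g$family, contig = g$contig,
               start = g$start, end = g$end, strand = g$strand,
               intact = g$intact, parent_id = g$parent_id,
               stringsAsFactors = FALSE)))
  AnnotatedGenome("root",
                  Biostrings::DNAStringSet(c(bg1 = .collapse(bgSeq),
                                             hs1 = .collapse(hsSeq))),
                  gdf)
}

# ---- coordinate-updating primitives --------------------------------------

.applyInsertion <- function(int, contig, pos, bases, newGene = NULL) {
  v <- int$seqs[[contig]]
  n <- length(v)
  stopifnot(pos >= 0, pos <= n)
  int$seqs[[contig]] <- c(v[seq_len(pos)], bases,
                          if (pos < n) v[(pos + 1L):n] else character())
  L <- length(bases)
  sel <- int$genes$contig == contig & int$genes$start >= pos
  int$genes$start[sel] <- int$genes$start[sel] + L
  int$genes$end[sel] <- int$genes$end[sel] + L
  if (!is.null(newGene)) int$genes <- rbind(int$genes, newGene)
  int
}

.applyDeletion <- function(int, contig, s, e, dropIds = character()) {
  v <- int$seqs[[contig]]
  L <- e - s
  int$seqs[[contig]] <- v[-((s + 1L):e)]
  g <- int$genes
  on <- g$contig == contig
  if (length(dropIds)) {
    keep <- !(g$gene_id %in% dropIds)
    g <- g[keep, , drop = FALSE]
    on <- on[keep]
  }
  after <- on & g$start >= e
  g$start[after] <- g$start[after] - L
  g$end[after] <- g$end[after] - L
  inside <- on & g$start <= s & g$end >= e & !after
  g$end[inside] <- g$end[inside] - L
  bad <- on & !after & !inside & !(g$end <= s)
  if (any(bad)) .stopf("deletion [%d,%d) on %s partially overlaps gene %s",
                       s, e, contig, g$gene_id[which(bad)[1]])
  int$genes <- g
  int
}

.applyInversion <- function(int, contig, s, e) {
  v <- int$seqs[[contig]]
  idx <- (s + 1L):e
  int$seqs[[contig]][idx] <- .revcompChars(v[idx])
  g <- int$genes
  sel <- g$contig == contig & g$start >= s & g$end <= e
  if (any(sel)) {
    os <- g$start[sel]; oe <- g$end[sel]
    g$start[sel] <- s + (e - oe)
    g$end[sel] <- s + (e - os)
    g$strand[sel] <- ifelse(g$strand[sel] == "+", "-", "+")
  }
  int$genes <- g
  int
}

.applyReplacement <- function(int, contig, s, e, bases) {
  stopifnot(length(bases) == e - s)
  int$seqs[[contig]][(s + 1L):e] <- bases
  int
}

# ---- state queries -------------------------------------------------------

.locusBounds <- function(int, params) {
  g <- int$genes
  a <- g[g$gene_id == params@markerIds[1], ]
  b <- g[g$gene_id == params@markerIds[2], ]
  if (nrow(a) != 1L || nrow(b) != 1L)
    .stopf("marker genes not resolvable in genome %s", int$id)
  list(contig = a$contig, start = a$end, end = b$start)
}

.inLocusFlag <- function(genes, lb) {
  genes$contig == lb$contig & genes$start >= lb$start & genes$end <= lb$end
}

# head-to-head intact diverging pairs currently present in the locus
.intactPairs <- function(int, params, lb = .locusBounds(int, params),
                         maxGap = 3000) {
  g <- int$genes[.inLocusFlag(int$genes, lb), , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  out <- list()
  if (nrow(g) >= 2L) for (i in seq_len(nrow(g) - 1L)) {
    a <- g[i, ]; b <- g[i + 1L, ]
    fams <- c(a$family, b$family)
    if (setequal(fams, c(params@familyB, params@familyC)) &&
        a$strand == "-" && b$strand == "+" &&
        (b$start - a$end) <= maxGap && a$intact && b$intact) {
      out[[length(out) + 1L]] <- list(ids = c(a$gene_id, b$gene_id),
                                      gapStart = a$end, gapEnd = b$start)
    }
  }
  out
}

# candidate intergenic insertion points on a contig (integer positions)
.insertionPoints <- function(int, contig, within = NULL, margin = 3L) {
  g <- int$genes[int$genes$contig == contig, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  len <- length(int$seqs[[contig]])
  lo <- c(50L, g$end + margin)
  hi <- c(g$start - margin, len - 50L)
  gaps <- data.frame(lo = lo, hi = hi)
  if (!is.null(within)) {
    gaps$lo <- pmax(gaps$lo, within$start + margin)
    gaps$hi <- pmin(gaps$hi, within$end - margin)
  }
  gaps[gaps$lo < gaps$hi, , drop = FALSE]
}

.samplePoint <- function(gaps) {
  if (nrow(gaps) == 0L) return(NULL)
  w <- gaps$hi - gaps$lo
  i <- sample.int(nrow(gaps), 1L, prob = w)
  gaps$lo[i] + sample.int(gaps$hi[i] - gaps$lo[i], 1L) - 1L
}

# ---- substitution machinery ----------------------------------------------

# Would substituting `base` at 0-based `pos` create an internal stop codon in
# an intact gene? Point mutations that would nonsense an intact gene are
# resampled, modelling purifying selection against nonsense mutations.
.subCreatesStop <- function(int, contig, pos, base) {
  g <- int$genes
  sel <- which(g$contig == contig & g$start <= pos & g$end > pos & g$intact)
  if (!length(sel)) return(FALSE)
  gn <- g[sel[1], ]
  if (gn$strand == "+") {
    off <- pos - gn$start
    ci <- off %/% 3L
    cs <- gn$start + 3L * ci
    codon <- int$seqs[[contig]][(cs + 1L):(cs + 3L)]
    codon[off %% 3L + 1L] <- base
  } else {
    off <- gn$end - 1L - pos
    ci <- off %/% 3L
    ce <- gn$end - 3L * ci          # codon covers genome (ce-3, ce]
    codon <- .revcompChars(int$seqs[[contig]][(ce - 2L):ce])
    codon[off %% 3L + 1L] <- .COMP[[base]]
  }
  nc <- (gn$end - gn$start) %/% 3L
  paste(codon, collapse = "") %in% .STOP_CODONS && ci < nc - 1L
}

.applySubBatch <- function(int, k, branch) {
  lens <- vapply(int$seqs, length, 0L)
  rows <- vector("list", k)
  contig <- sample(names(lens), k, replace = TRUE, prob = lens)
  pos <- floor(stats::runif(k) * lens[contig])
  todo <- seq_len(k)
  newBase <- character(k)
  for (iter in 1:25) {
    if (!length(todo)) break
    ok <- logical(length(todo))
    for (j in seq_along(todo)) {
      i <- todo[j]
      old <- int$seqs[[contig[i]]][pos[i] + 1L]
      nb <- sample(setdiff(.BASES, old), 1L)
      if (!.subCreatesStop(int, contig[i], pos[i], nb)) {
        newBase[i] <- nb
        ok[j] <- TRUE
      }
    }
    bad <- todo[!ok]
    if (length(bad)) {   # redraw position and base for rejected draws
      contig[bad] <- sample(names(lens), length(bad), replace = TRUE,
                            prob = lens)
      pos[bad] <- floor(stats::runif(length(bad)) * lens[contig[bad]])
    }
    todo <- bad
  }
  keep <- newBase != ""
  contig <- contig[keep]; pos <- pos[keep]; newBase <- newBase[keep]
  old <- vapply(seq_along(pos),
                function(i) int$seqs[[contig[i]]][pos[i] + 1L], "")
  for (i in seq_along(pos)) int$seqs[[contig[i]]][pos[i] + 1L] <- newBase[i]
  log <- if (length(pos)) data.frame(
    branch = branch, kind = "substitution",
    src_contig = NA_character_, src_start = NA_real_, src_end = NA_real_,
    dst_contig = contig, dst_start = pos, dst_end = pos + 1,
    gene_ids = "", detail = paste0(old, ">", newBase),
    stringsAsFactors = FALSE) else .emptyLog()
  list(int = int, log = log)
}

# ---- structural events ---------------------------------------------------

.pickTargetGene <- function(int, params, lb, eligible) {
  g <- int$genes
  w <- ifelse(.inLocusFlag(g, lb), params@hotspotMultiplier, 1)
  w[g$gene_id %in% params@markerIds] <- 0
  w[!eligible] <- 0
  if (all(w == 0)) return(NULL)
  sample.int(nrow(g), 1L, prob = w)
}

.protectedIds <- function(int, params, lb) {
  pr <- .intactPairs(int, params, lb)
  if (length(pr) == 1L) pr[[1]]$ids else character()
}

.eventDuplication <- function(int, params, lb, branch, counter, kind = "duplication") {
  g <- int$genes
  if (kind == "transposition") {
    eligible <- g$family == params@expandingFamily
    idx <- if (any(eligible)) sample(which(eligible), 1L) else NULL
  } else {
    idx <- .pickTargetGene(int, params, lb, rep(TRUE, nrow(g)))
  }
  if (is.null(idx)) return(NULL)
  src <- g[idx, ]
  protected <- .protectedIds(int, params, lb)
  prGap <- .intactPairs(int, params, lb)
  srcInLocus <- .inLocusFlag(src, lb)
  for (try in 1:8) {
    if (kind == "transposition") {
      ctg <- sample(names(int$seqs), 1L,
                    prob = vapply(int$seqs, length, 0L))
      pt <- .samplePoint(.insertionPoints(int, ctg))
    } else if (srcInLocus) {
      ctg <- lb$contig
      pt <- .samplePoint(.insertionPoints(int, ctg, within = lb))
    } else {
      ctg <- src$contig
      pt <- .samplePoint(.insertionPoints(int, ctg))
    }
    if (is.null(pt)) return(NULL)
    # do not break the promoter gap of the last intact diverging pair
    if (length(protected) && ctg == lb$contig &&
        pt > prGap[[1]]$gapStart && pt < prGap[[1]]$gapEnd) {
      counter$resamples <- counter$resamples + 1L
      next
    }
    counter$ndup <- counter$ndup + 1L
    newId <- paste0(src$gene_id, ".d", counter$ndup)
    bases <- int$seqs[[src$contig]][(src$start + 1L):src$end]
    newGene <- data.frame(gene_id = newId, family = src$family,
                          contig = ctg, start = pt, end = pt + length(bases),
                          strand = src$strand, intact = src$intact,
                          parent_id = src$gene_id, stringsAsFactors = FALSE)
    # coordinates of the new gene must be post-insertion: insertion at pt
    # shifts nothing below pt, and the gene itself begins exactly at pt
    int2 <- .applyInsertion(int, ctg, pt, bases, newGene)
    row <- .logRow(branch, kind,
                   src = list(src$contig, src$start, src$end),
                   dst = list(ctg, pt, pt + length(bases)),
                   gene_ids = paste(newId, src$gene_id, sep = ","))
    return(list(int = int2, log = row))
  }
  NULL
}

.eventLoss <- function(int, params, lb, branch, counter) {
  g <- int$genes
  protected <- .protectedIds(int, params, lb)
  eligible <- !(g$gene_id %in% protected)
  idx <- .pickTargetGene(int, params, lb, eligible)
  if (is.null(idx)) return(NULL)
  tg <- g[idx, ]
  int2 <- .applyDeletion(int, tg$contig, tg$start, tg$end,
                         dropIds = tg$gene_id)
  row <- .logRow(branch, "loss", src = list(tg$contig, tg$start, tg$end),
                 gene_ids = tg$gene_id)
  list(int = int2, log = row)
}

.eventTruncation <- function(int, params, lb, branch, counter) {
  g <- int$genes
  protected <- .protectedIds(int, params, lb)
  nc <- (g$end - g$start) %/% 3L
  eligible <- g$intact & nc >= 90L & !(g$gene_id %in% protected)
  idx <- .pickTargetGene(int, params, lb, eligible)
  if (is.null(idx)) return(NULL)
  tg <- g[idx, ]
  L3 <- (tg$end - tg$start) %/% 3L
  k <- sample(55:min(200L, L3 - 30L), 1L)      # >50-codon internal deletion
  a <- sample(10:(L3 - k - 10L), 1L)           # codon offset of the block
  if (tg$strand == "+") { s <- tg$start + 3L * a } else
    { s <- tg$end - 3L * a - 3L * k }
  e <- s + 3L * k
  int2 <- .applyDeletion(int, tg$contig, s, e)
  int2$genes$intact[int2$genes$gene_id == tg$gene_id] <- FALSE
  row <- .logRow(branch, "truncation", src = list(tg$contig, s, e),
                 gene_ids = tg$gene_id)
  list(int = int2, log = row)
}

.eventInversion <- function(int, params, lb, branch, counter) {
  g <- int$genes
  idx <- .pickTargetGene(int, params, lb, rep(TRUE, nrow(g)))
  if (is.null(idx)) return(NULL)
  tg <- g[idx, ]
  inLoc <- .inLocusFlag(g, lb)
  onCtg <- which(g$contig == tg$contig &
                   !(g$gene_id %in% params@markerIds) &
                   (inLoc == inLoc[idx]))
  ord <- onCtg[order(g$start[onCtg])]
  pos <- match(idx, ord)
  nRun <- sample(1:3, 1L)
  run <- ord[pos:min(pos + nRun - 1L, length(ord))]
  # the run must be contiguous in overall gene order (no marker in between)
  gg <- g[g$contig == tg$contig, , drop = FALSE]
  gg <- gg[order(gg$start), ]
  ids <- g$gene_id[run]
  sel <- match(ids, gg$gene_id)
  if (max(sel) - min(sel) != length(sel) - 1L)
    run <- run[1]                               # fall back to single gene
  ids <- g$gene_id[run]
  protected <- .protectedIds(int, params, lb)
  if (length(protected) && length(intersect(ids, protected)) == 1L) {
    counter$resamples <- counter$resamples + 1L
    return(NULL)  # would break the head-to-head geometry of the last pair
  }
  s <- min(g$start[run]) - 1L
  e <- max(g$end[run]) + 1L
  s <- max(s, 0L); e <- min(e, length(int$seqs[[tg$contig]]))
  # boundaries must not clip neighbouring genes
  others <- g$contig == tg$contig & !(g$gene_id %in% ids)
  if (any(others & g$end > s & g$start < e)) return(NULL)
  int2 <- .applyInversion(int, tg$contig, s, e)
  row <- .logRow(branch, "inversion", src = list(tg$contig, s, e),
                 gene_ids = paste(ids, collapse = ","))
  list(int = int2, log = row)
}

.eventRecombination <- function(int, params, lb, branch, counter) {
  g <- int$genes
  inLoc <- .inLocusFlag(g, lb) & !(g$gene_id %in% params@markerIds)
  cand <- g[inLoc, , drop = FALSE]
  cand$len <- cand$end - cand$start
  key <- paste(cand$family, cand$len)
  grp <- split(seq_len(nrow(cand)), key)
  grp <- grp[vapply(grp, function(i) length(i) >= 2L &&
                      sum(cand$intact[i]) >= 1L, TRUE)]
  if (!length(grp)) return(NULL)
  gi <- grp[[sample.int(length(grp), 1L,
                        prob = vapply(grp, length, 0L))]]
  donors <- gi[cand$intact[gi]]
  donor <- cand[sample(rep(donors, 2L), 1L), ]  # rep() guards length-1 sample
  recips <- setdiff(gi, which(cand$gene_id == donor$gene_id))
  recip <- cand[sample(rep(recips, 2L), 1L), ]
  L3 <- donor$len %/% 3L
  if (L3 < 35L) return(NULL)
  k <- sample(20:min(200L, L3 - 10L), 1L)       # conversion tract in codons
  a <- sample(0:(L3 - k), 1L)
  cdsInterval <- function(gn, a, k) {
    if (gn$strand == "+") c(gn$start + 3L * a, gn$start + 3L * (a + k))
    else c(gn$end - 3L * (a + k), gn$end - 3L * a)
  }
  si <- cdsInterval(donor, a, k)
  di <- cdsInterval(recip, a, k)
  block <- int$seqs[[donor$contig]][(si[1] + 1L):si[2]]
  if (donor$strand != recip$strand) block <- .revcompChars(block)
  int2 <- .applyReplacement(int, recip$contig, di[1], di[2], block)
  row <- .logRow(branch, "recombination",
                 src = list(donor$contig, si[1], si[2]),
                 dst = list(recip$contig, di[1], di[2]),
                 gene_ids = paste(donor$gene_id, recip$gene_id, sep = ","),
                 detail = paste0("seq:", .collapse(block)))
  list(int = int2, log = row)
}

.eventIndel <- function(int, params, lb, branch, counter) {
  lens <- vapply(int$seqs, length, 0L)
  ctg <- sample(names(lens), 1L, prob = lens)
  gaps <- .insertionPoints(int, ctg, margin = 6L)
  if (nrow(gaps) == 0L) return(NULL)
  k <- stats::rgeom(1L, 1 / params@indelMeanLen) + 1L
  if (stats::runif(1) < 0.5) {
    pt <- .samplePoint(gaps)
    if (is.null(pt)) return(NULL)
    bases <- .randBases(k, params@gcContent)
    int2 <- .applyInsertion(int, ctg, pt, bases)
    row <- .logRow(branch, "indel", dst = list(ctg, pt, pt),
                   detail = paste0("ins:", .collapse(bases)))
  } else {
    i <- sample.int(nrow(gaps), 1L, prob = gaps$hi - gaps$lo)
    room <- gaps$hi[i] - gaps$lo[i]
    k <- min(k, room)
    s <- gaps$lo[i] + sample.int(room - k + 1L, 1L) - 1L
    int2 <- .applyDeletion(int, ctg, s, s + k)
    row <- .logRow(branch, "indel", dst = list(ctg, s, s + k),
                   detail = "del")
  }
  list(int = int2, log = row)
}

# ---- branch evolution ----------------------------------------------------

.evolveBranch <- function(int, bl, params, branch, counter) {
  lb <- .locusBounds(int, params)
  g <- int$genes
  m <- params@hotspotMultiplier
  inLoc <- .inLocusFlag(g, lb) & !(g$gene_id %in% params@markerIds)
  nIn <- sum(inLoc)
  nOut <- sum(!inLoc & !(g$gene_id %in% params@markerIds))
  W <- nOut + m * nIn
  totLen <- sum(vapply(int$seqs, length, 0L))
  nExpand <- sum(g$family == params@expandingFamily)

  counts <- c(
    substitution = stats::rpois(1, params@subRate * bl * totLen),
    indel = stats::rpois(1, params@indelRate * bl * totLen),
    duplication = stats::rpois(1, params@dupRate * bl * W),
    inversion = stats::rpois(1, params@invRate * bl * W),
    loss = stats::rpois(1, params@lossRate * bl * W),
    truncation = stats::rpois(1, params@truncRate * bl * W),
    recombination = stats::rpois(1, params@recRate * bl * m * nIn),
    transposition = stats::rpois(1, params@transRate * bl * nExpand)
  )
  kinds <- rep(names(counts), counts)
  if (!length(kinds)) return(list(int = int, log = .emptyLog()))
  kinds <- kinds[order(stats::runif(length(kinds)))]

  logs <- list()
  i <- 1L
  while (i <= length(kinds)) {
    if (kinds[i] == "substitution") {
      j <- i
      while (j < length(kinds) && kinds[j + 1L] == "substitution") j <- j + 1L
      res <- .applySubBatch(int, j - i + 1L, branch)
      i <- j + 1L
    } else {
      lb <- .locusBounds(int, params)
      res <- switch(kinds[i],
        indel = .eventIndel(int, params, lb, branch, counter),
        duplication = .eventDuplication(int, params, lb, branch, counter),
        transposition = .eventDuplication(int, params, lb, branch, counter,
                                          kind = "transposition"),
        inversion = .eventInversion(int, params, lb, branch, counter),
        loss = .eventLoss(int, params, lb, branch, counter),
        truncation = .eventTruncation(int, params, lb, branch, counter),
        recombination = .eventRecombination(int, params, lb, branch, counter))
      i <- i + 1L
    }
    if (!is.null(res)) {
      int <- res$int
      logs[[length(logs) + 1L]] <- res$log
    }
  }
  list(int = int, log = if (length(logs)) do.call(rbind, logs) else .emptyLog())
}

#' Evolve a root genome along a species tree
#'
#' Events are drawn per branch from independent Poisson processes with rates
#' multiplied by branch length; structural events targeting genes inside the
#' marker-bounded locus occur at `hotspotMultiplier` times the background
#' rate. Marker genes are immune to structural events. Structural events that
#' would destroy or split the last intact head-to-head diverging pair of a
#' genome are resampled (the resample count is returned), so every tip keeps
#' at least one intact pair.
#'
#' @param root an [AnnotatedGenome-class], typically from
#'   [simulateRootGenome()].
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param params an [EvolParams-class]; `params@seed + 1` seeds the branch
#'   processes.
#' @return A list of class `hotspotSim` with elements `tips` (named list of
#'   [AnnotatedGenome-class]), `logs` (named list of event-log data frames,
#'   one per tip, containing all events on the root-to-tip path in
#'   application order), `tree`, `root`, `params`, and `resamples`.
#' @export
evolveAlongTree <- function(root, tree, params) {
  stopifnot(is(root, "AnnotatedGenome"), is(params, "EvolParams"))
  if (!inherits(tree, "phylo")) .stopf("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) .stopf("tree must have branch lengths")
  if (!ape::is.rooted(tree)) .stopf("tree must be rooted")
  methods::validObject(root)
  set.seed(params@seed + 1L)

  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")   # parents precede children
  genomes <- vector("list", ntip + tree$Nnode)
  logsAt <- vector("list", ntip + tree$Nnode)
  rootNode <- ntip + 1L
  genomes[[rootNode]] <- .asInternal(root)
  logsAt[[rootNode]] <- .emptyLog()
  counter <- new.env()
  counter$ndup <- 0L
  counter$resamples <- 0L

  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    branch <- if (child <= ntip) tree$tip.label[child]
              else paste0("node", child)
    res <- .evolveBranch(genomes[[par]], tree$edge.length[k], params,
                         branch, counter)
    genomes[[child]] <- res$int
    logsAt[[child]] <- rbind(logsAt[[par]], res$log)
  }

  tips <- stats::setNames(vector("list", ntip), tree$tip.label)
  logs <- tips
  for (t in seq_len(ntip)) {
    gi <- genomes[[t]]
    gi$id <- tree$tip.label[t]
    tips[[t]] <- .asGenome(gi)
    logs[[t]] <- logsAt[[t]]
  }
  structure(list(tips = tips, logs = logs, tree = tree, root = root,
                 params = params, resamples = counter$resamples),
            class = "hotspotSim")
}

#' @export
print.hotspotSim <- function(x, ...) {
  cat("hotspotSim:", length(x$tips), "tip genome(s); events per tip:",
      paste(vapply(x$logs, nrow, 0L), collapse = ", "),
      "; pair-protection resamples:", x$resamples, "\n")
  invisible(x)
}

#' Replay an event log from the root genome
#'
#' Applies every logged event, in order, to the root contig sequences. Each
#' event carries the coordinates that were valid at its application time, so
#' the result reproduces the corresponding tip sequence exactly. This is the
#' ground-truth check for the simulator.
#'
#' @param root the root [AnnotatedGenome-class].
#' @param log an event-log data frame as produced by [evolveAlongTree()].
#' @return A named character vector of contig sequences.
#' @export
replayEvents <- function(root, log) {
  seqs <- lapply(as.character(root@seqs), function(s) strsplit(s, "")[[1]])
  for (i in seq_len(nrow(log))) {
    ev <- log[i, ]
    seqs <- switch(ev$kind,
      substitution = {
        seqs[[ev$dst_contig]][ev$dst_start + 1L] <-
          sub(".*>", "", ev$detail)
        seqs
      },
      indel = {
        if (startsWith(ev$detail, "ins:")) {
          v <- seqs[[ev$dst_contig]]
          ins <- strsplit(sub("^ins:", "", ev$detail), "")[[1]]
          p <- ev$dst_start
          seqs[[ev$dst_contig]] <- c(v[seq_len(p)], ins,
                                     if (p < length(v)) v[(p + 1L):length(v)]
                                     else character())
        } else {
          seqs[[ev$dst_contig]] <-
            seqs[[ev$dst_contig]][-((ev$dst_start + 1L):ev$dst_end)]
        }
        seqs
      },
      duplication = ,
      transposition = {
        bl <- seqs[[ev$src_contig]][(ev$src_start + 1L):ev$src_end]
        v <- seqs[[ev$dst_contig]]
        p <- ev$dst_start
        seqs[[ev$dst_contig]] <- c(v[seq_len(p)], bl,
                                   if (p < length(v)) v[(p + 1L):length(v)]
                                   else character())
        seqs
      },
      loss = ,
      truncation = {
        seqs[[ev$src_contig]] <-
          seqs[[ev$src_contig]][-((ev$src_start + 1L):ev$src_end)]
        seqs
      },
      inversion = {
        idx <- (ev$src_start + 1L):ev$src_end
        seqs[[ev$src_contig]][idx] <- .revcompChars(seqs[[ev$src_contig]][idx])
        seqs
      },
      recombination = {
        seqs[[ev$dst_contig]][(ev$dst_start + 1L):ev$dst_end] <-
          strsplit(sub("^seq:", "", ev$detail), "")[[1]]
        seqs
      },
      .stopf("unknown event kind '%s'", ev$kind))
  }
  vapply(seqs, .collapse, "")
}

#' Per-base ancestry map of a tip genome
#'
#' Replays an event log over integer ancestry tags instead of bases: every
#' root position carries a unique tag, inserted material gets fresh tags, and
#' copy events (duplication, transposition, gene conversion) propagate the
#' source tags. The result tells, for every base of the tip genome, which
#' root base (if any) it descends from -- the ground truth behind
#' "unalignable" calls: tip-A material whose tags are absent from the
#' homologous interval of tip B has no alignable counterpart there.
#'
#' @param root the root [AnnotatedGenome-class].
#' @param log an event-log data frame from [evolveAlongTree()].
#' @return Named list of integer vectors, one per contig, parallel to the
#'   tip sequence.
#' @export
ancestryMap <- function(root, log) {
  w <- Biostrings::width(root@seqs)
  offs <- c(0, cumsum(as.numeric(w)))[seq_along(w)]
  tags <- stats::setNames(lapply(seq_along(w), function(i)
    offs[i] + seq_len(w[i])), names(root@seqs))
  fresh <- sum(w)
  ins <- function(v, p, x) c(v[seq_len(p)], x,
                             if (p < length(v)) v[(p + 1L):length(v)]
                             else integer())
  for (i in seq_len(nrow(log))) {
    ev <- log[i, ]
    if (ev$kind == "substitution") next
    if (ev$kind == "indel") {
      if (startsWith(ev$detail, "ins:")) {
        k <- nchar(sub("^ins:", "", ev$detail))
        tags[[ev$dst_contig]] <- ins(tags[[ev$dst_contig]], ev$dst_start,
                                     fresh + seq_len(k))
        fresh <- fresh + k
      } else {
        tags[[ev$dst_contig]] <-
          tags[[ev$dst_contig]][-((ev$dst_start + 1L):ev$dst_end)]
      }
    } else if (ev$kind %in% c("duplication", "transposition")) {
      bl <- tags[[ev$src_contig]][(ev$src_start + 1L):ev$src_end]
      tags[[ev$dst_contig]] <- ins(tags[[ev$dst_contig]], ev$dst_start, bl)
    } else if (ev$kind %in% c("loss", "truncation")) {
      tags[[ev$src_contig]] <-
        tags[[ev$src_contig]][-((ev$src_start + 1L):ev$src_end)]
    } else if (ev$kind == "inversion") {
      idx <- (ev$src_start + 1L):ev$src_end
      tags[[ev$src_contig]][idx] <- rev(tags[[ev$src_contig]][idx])
    } else if (ev$kind == "recombination") {
      tags[[ev$dst_contig]][(ev$dst_start + 1L):ev$dst_end] <-
        tags[[ev$src_contig]][(ev$src_start + 1L):ev$src_end]
    }
  }
  tags
}

#' Plant a gene-content swap into a genome's locus
#'
#' Replaces a run of `nRemove` adjacent locus genes with `nInsert` novel
#' genes (random coding sequences at the genome's base composition), the
#' situation observed when two genomes carry entirely different gene
#' complements inside their recognition locus. The exact replaced and
#' inserted intervals are returned as ground truth for unalignable-region
#' calling.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param markers locus-bounding marker ids.
#' @param nRemove number of adjacent locus genes to remove.
#' @param nInsert number of novel genes to insert in their place.
#' @param meanGeneLen mean novel gene length (bp).
#' @param gc base composition of inserted material.
#' @return List: `genome` (modified), `removedGeneIds`, and the inserted
#'   interval in locus-relative coordinates (`insertStart`, `insertEnd`).
#' @export
plantSwap <- function(genome, markers, nRemove = 3L, nInsert = 6L,
                      meanGeneLen = 900, gc = 0.23) {
  loc <- extractLocus(genome, markers)
  g <- geneModels(loc)
  g <- g[order(g$start), , drop = FALSE]
  if (nrow(g) < nRemove + 2L)
    .stopf("locus has too few genes (%d) for a %d-gene swap", nrow(g),
           nRemove)
  i0 <- max(2L, (nrow(g) - nRemove) %/% 2L)
  sel <- g[i0:(i0 + nRemove - 1L), ]
  s <- min(sel$start) - 20L
  e <- max(sel$end) + 20L
  others <- geneModels(genome)
  others <- others[others$contig == loc@contig &
                     !(others$gene_id %in% sel$gene_id), ]
  s <- max(s, max(others$end[others$end <= min(sel$start)]) + 3L, loc@start)
  e <- min(e, min(others$start[others$start >= max(sel$end)]) - 3L, loc@end)

  chunks <- list()
  newGenes <- list()
  pos <- 0L
  for (j in seq_len(nInsert)) {
    sp <- .randBases(sample(180:320, 1L), gc)
    chunks[[length(chunks) + 1L]] <- sp
    pos <- pos + length(sp)
    nc <- .sampleGeneCodons(meanGeneLen)
    chars <- .randCodingBases(nc, gc)
    strand <- sample(c("+", "-"), 1L)
    gchars <- if (strand == "-") .revcompChars(chars) else chars
    newGenes[[j]] <- data.frame(
      gene_id = sprintf("novel%02d", j), family = sprintf("novel%02d", j),
      contig = loc@contig, start = pos, end = pos + length(gchars),
      strand = strand, intact = TRUE, parent_id = NA_character_,
      stringsAsFactors = FALSE)
    chunks[[length(chunks) + 1L]] <- gchars
    pos <- pos + length(gchars)
  }
  chunks[[length(chunks) + 1L]] <- .randBases(200L, gc)
  insert <- unlist(chunks, use.names = FALSE)

  int <- .asInternal(genome)
  int <- .applyDeletion(int, loc@contig, s, e, dropIds = sel$gene_id)
  ng <- do.call(rbind, newGenes)
  ng$start <- ng$start + s
  ng$end <- ng$end + s
  int <- .applyInsertion(int, loc@contig, s, insert, ng)
  list(genome = .asGenome(int), removedGeneIds = sel$gene_id,
       insertStart = s - loc@start,
       insertEnd = s + length(insert) - loc@start,
       contig = loc@contig, editStart = s, editEnd = e,
       insertLen = length(insert))
}

#' Apply a [plantSwap()] edit to a per-contig ancestry map
#'
#' Keeps simulation ancestry tags consistent with a planted swap: the removed
#' interval's tags are dropped and the inserted material receives fresh tags.
#'
#' @param am ancestry map (named list of integer vectors).
#' @param swap the return value of [plantSwap()].
#' @return The edited ancestry map.
#' @export
applySwapToAncestry <- function(am, swap) {
  v <- am[[swap$contig]]
  fresh <- max(unlist(am)) + seq_len(swap$insertLen)
  am[[swap$contig]] <- c(v[seq_len(swap$editStart)], fresh,
                         if (swap$editEnd < length(v))
                           v[(swap$editEnd + 1L):length(v)] else integer())
  am
}

#' A six-tip species tree used as the default simulation scenario
#'
#' A rooted, ultrametric-ish tree of six tips whose depth, combined with the
#' default substitution rate, yields pairwise nucleotide divergences of a few
#' percent -- diverged enough for detection problems to be non-trivial
#' without approaching saturation.
#'
#' @return An ape `phylo` object.
#' @export
defaultSpeciesTree <- function() {
  ape::read.tree(text = paste0(
    "(((t1:0.10,t2:0.10):0.10,(t3:0.10,t4:0.10):0.10):0.05,",
    "(t5:0.15,t6:0.15):0.10);"))
}

#' Simulate a gap-free nucleotide alignment along a tree
#'
#' Substitution-only sequence evolution (Jukes-Cantor): each site on each
#' branch receives a Poisson number of substitution events with mean
#' `rate * branch length`, each replacing the base by one of the other three.
#' Useful as a recombination-free null for breakpoint scanning and as a
#' neutral generator for diversity statistics.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param sites alignment length.
#' @param rate per-site substitution rate per unit branch length.
#' @return Character matrix (tips x sites) of bases.
#' @export
simulateAlignment <- function(tree, sites, rate) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")
  seqAt <- vector("list", ntip + tree$Nnode)
  seqAt[[ntip + 1L]] <- sample(.BASES, sites, replace = TRUE)
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    v <- seqAt[[par]]
    nmut <- stats::rpois(sites, rate * tree$edge.length[k])
    while (any(nmut > 0)) {
      hit <- which(nmut > 0)
      v[hit] <- vapply(v[hit], function(b) sample(setdiff(.BASES, b), 1L), "")
      nmut <- nmut - 1L
    }
    seqAt[[child]] <- v
  }
  m <- do.call(rbind, seqAt[seq_len(ntip)])
  rownames(m) <- tree$tip.label
  m
}

#' Simulate a neutrally diverged codon-sequence pair
#'
#' Generates an ancestral stop-free codon sequence and evolves two copies by
#' uniform point mutation in which synonymous and nonsynonymous changes are
#' accepted equally; only mutations creating a stop codon are rejected.
#' Under this process the Nei-Gojobori dN/dS estimator is expected to be
#' close to 1.
#'
#' @param nCodons number of codons.
#' @param divergence expected substitutions per site on each of the two
#'   lineages.
#' @return List with elements `a` and `b`, each a codon character string.
#' @export
simulateCodonPair <- function(nCodons, divergence = 0.05) {
  anc <- unlist(strsplit(sample(.SENSE_CODONS, nCodons, replace = TRUE), ""))
  evolve <- function(v) {
    n <- stats::rpois(1, divergence * length(v))
    for (i in seq_len(n)) {
      for (try in 1:50) {
        p <- sample.int(length(v), 1L)
        nb <- sample(setdiff(.BASES, v[p]), 1L)
        ci <- (p - 1L) %/% 3L
        codon <- v[(3L * ci + 1L):(3L * ci + 3L)]
        codon[(p - 1L) %% 3L + 1L] <- nb
        if (!(paste(codon, collapse = "") %in% .STOP_CODONS)) {
          v[p] <- nb
          break
        }
      }
    }
    v
  }
  list(a = .collapse(evolve(anc)), b = .collapse(evolve(anc)))
}
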