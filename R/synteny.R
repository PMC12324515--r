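# Pairwise locus alignment by seeded anchor chaining. Shared words on both
# strands are grouped into exact-diagonal segments, segments are clustered
# into candidate blocks, and block identity is computed piecewise: direct
# base comparison along each diagonal segment, gapped alignment of the short
# inter-segment gaps, and X-drop ungapped extension at the ends. Identity is
# matches over alignment columns, gaps counting as mismatches. Retained
# blocks are chained collinearly per orientation; intervals of either locus
# covered by no retained block are emitted as unalignable regions.

#' @import data.table
NULL

.seedSegments <- function(a, b, word, maxSeedOcc = 32L, chainGap = 500L) {
  posA <- posB <- kmer <- diag <- run <- NULL  # data.table NSE
  nA <- nchar(a); nB <- nchar(b)
  if (nA < word || nB < word) return(NULL)
  dtA <- data.table(kmer = substring(a, 1:(nA - word + 1L), word:nA),
                    posA = 1:(nA - word + 1L))
  dtB <- data.table(kmer = substring(b, 1:(nB - word + 1L), word:nB),
                    posB = 1:(nB - word + 1L))
  dtA <- dtA[!grepl("N", kmer, fixed = TRUE)]
  dtB <- dtB[!grepl("N", kmer, fixed = TRUE)]
  occA <- dtA[, .N, by = kmer]; occB <- dtB[, .N, by = kmer]
  bad <- union(occA[occA$N > maxSeedOcc]$kmer, occB[occB$N > maxSeedOcc]$kmer)
  if (length(bad)) {
    dtA <- dtA[!kmer %in% bad]
    dtB <- dtB[!kmer %in% bad]
  }
  seeds <- dtA[dtB, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(seeds) == 0L) return(NULL)
  seeds[, diag := posA - posB]
  setorder(seeds, diag, posA)
  seeds[, run := cumsum(c(1L, (diff(diag) != 0L) |
                            (diff(posA) > chainGap)))]
  seg <- seeds[, .(aStart = min(posA), aEnd = max(posA) + word - 1L,
                   bStart = min(posB), bEnd = max(posB) + word - 1L,
                   diag = diag[1]), by = run]
  setorder(seg, aStart, bStart)
  seg
}

.clusterSegments <- function(seg, maxGap = 600L, maxDiagDrift = 250L) {
  clusters <- list()
  lastA <- numeric(); lastB <- numeric(); lastD <- numeric()
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    attached <- FALSE
    for (ci in rev(seq_along(clusters))) {
      if (s$aStart > lastA[ci] + maxGap) next
      if (s$aStart >= lastA[ci] - 150L && s$bStart >= lastB[ci] - 150L &&
          s$bStart <= lastB[ci] + maxGap &&
          abs(s$diag - lastD[ci]) <= maxDiagDrift) {
        clusters[[ci]] <- rbind(clusters[[ci]], s)
        lastA[ci] <- max(lastA[ci], s$aEnd)
        lastB[ci] <- max(lastB[ci], s$bEnd)
        lastD[ci] <- s$diag
        attached <- TRUE
        break
      }
    }
    if (!attached) {
      clusters[[length(clusters) + 1L]] <- s
      lastA <- c(lastA, s$aEnd); lastB <- c(lastB, s$bEnd)
      lastD <- c(lastD, s$diag)
    }
  }
  clusters
}

.countMatches <- function(x, y) {
  vx <- strsplit(x, "")[[1]]; vy <- strsplit(y, "")[[1]]
  sum(vx == vy)
}

.ntSubMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1,
                                                     baseOnly = FALSE)
    m
  }
})

# gapped comparison of two (possibly empty / unequal) gap substrings;
# returns c(matches, columns)
.gapStats <- function(x, y) {
  nx <- nchar(x); ny <- nchar(y)
  if (nx == 0L && ny == 0L) return(c(0L, 0L))
  if (nx == 0L || ny == 0L) return(c(0L, max(nx, ny)))
  if (nx == ny && nx <= 8L) return(c(.countMatches(x, y), nx))
  if (max(nx, ny) > 3000L) return(c(0L, max(nx, ny)))
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(x),
                                       Biostrings::DNAString(y),
                                       type = "global",
                                       substitutionMatrix = .ntSubMatrix(),
                                       gapOpening = 4, gapExtension = 1)
  c(Biostrings::nmatch(aln),
    nchar(as.character(Biostrings::alignedPattern(aln))))
}

# X-drop ungapped extension: returns number of extra columns and matches
.xdropExtend <- function(va, vb, xDrop = 10L, matchScore = 1L, mismatch = -2L) {
  n <- min(length(va), length(vb))
  if (n == 0L) return(c(cols = 0L, matches = 0L))
  eq <- va[seq_len(n)] == vb[seq_len(n)]
  sc <- cumsum(ifelse(eq, matchScore, mismatch))
  best <- cummax(sc)
  stopAt <- which(best - sc >= xDrop)
  lim <- if (length(stopAt)) stopAt[1] - 1L else n
  if (lim == 0L) return(c(cols = 0L, matches = 0L))
  k <- which.max(sc[seq_len(lim)])
  c(cols = k, matches = sum(eq[seq_len(k)]))
}

.scoreCluster <- function(cl, a, b, extendFlank = 400L, minUnitId = 0.60) {
  cl <- cl[order(cl$aStart), ]
  # enforce increasing b, dropping conflicting segments (shorter first)
  keep <- rep(TRUE, nrow(cl))
  lastB <- -Inf
  for (i in seq_len(nrow(cl))) {
    if (cl$bEnd[i] <= lastB) { keep[i] <- FALSE; next }
    lastB <- cl$bEnd[i]
  }
  cl <- cl[keep, ]
  prevA <- prevB <- NA
  segs <- list()
  gapM <- c(0); gapC <- c(0)          # gap piece before segment i
  segM <- c(); segC <- c()            # exact-diagonal piece of segment i
  for (i in seq_len(nrow(cl))) {
    s <- as.list(cl[i, ])
    if (!is.na(prevA)) {
      delta <- max(prevA + 1L - s$aStart, prevB + 1L - s$bStart, 0L)
      s$aStart <- s$aStart + delta
      s$bStart <- s$bStart + delta
      if (s$aStart > s$aEnd || s$bStart > s$bEnd) next
      gx <- if (s$aStart > prevA + 1L)
        substr(a, prevA + 1L, s$aStart - 1L) else ""
      gy <- if (s$bStart > prevB + 1L)
        substr(b, prevB + 1L, s$bStart - 1L) else ""
      gs <- .gapStats(gx, gy)
      gapM <- c(gapM, gs[1]); gapC <- c(gapC, gs[2])
    }
    sm <- .countMatches(substr(a, s$aStart, s$aEnd),
                        substr(b, s$bStart, s$bEnd))
    segM <- c(segM, sm)
    segC <- c(segC, s$aEnd - s$aStart + 1L)
    prevA <- s$aEnd; prevB <- s$bEnd
    segs[[length(segs) + 1L]] <- s
  }
  if (!length(segs)) return(NULL)
  # trim low-quality terminal units (chance seeds glued onto the cluster):
  # a terminal unit is the edge segment together with its inward gap piece
  n <- length(segs)
  lo <- 1L; hi <- n
  unitId <- function(i, side) {
    if (side == "L") {
      m <- segM[i] + if (i < n) gapM[i + 1L] else 0
      cc <- segC[i] + if (i < n) gapC[i + 1L] else 0
    } else {
      m <- segM[i] + gapM[i]
      cc <- segC[i] + gapC[i]
    }
    if (cc == 0) 1 else m / cc
  }
  while (lo < hi && unitId(lo, "L") < minUnitId) lo <- lo + 1L
  while (hi > lo && unitId(hi, "R") < minUnitId) hi <- hi - 1L
  idx <- lo:hi
  matches <- sum(segM[idx]) + if (length(idx) > 1L)
    sum(gapM[idx[-1]]) else 0
  cols <- sum(segC[idx]) + if (length(idx) > 1L)
    sum(gapC[idx[-1]]) else 0
  aS <- segs[[lo]]$aStart; bS <- segs[[lo]]$bStart
  aE <- segs[[hi]]$aEnd; bE <- segs[[hi]]$bEnd
  # extend left
  nl <- min(aS - 1L, bS - 1L, extendFlank)
  if (nl > 0L) {
    va <- rev(strsplit(substr(a, aS - nl, aS - 1L), "")[[1]])
    vb <- rev(strsplit(substr(b, bS - nl, bS - 1L), "")[[1]])
    ex <- .xdropExtend(va, vb)
    aS <- aS - ex["cols"]; bS <- bS - ex["cols"]
    matches <- matches + ex["matches"]; cols <- cols + ex["cols"]
  }
  # extend right
  nr <- min(nchar(a) - aE, nchar(b) - bE, extendFlank)
  if (nr > 0L) {
    va <- strsplit(substr(a, aE + 1L, aE + nr), "")[[1]]
    vb <- strsplit(substr(b, bE + 1L, bE + nr), "")[[1]]
    ex <- .xdropExtend(va, vb)
    aE <- aE + ex["cols"]; bE <- bE + ex["cols"]
    matches <- matches + ex["matches"]; cols <- cols + ex["cols"]
  }
  data.frame(aStart = aS, aEnd = aE, bStart = bS, bEnd = bE,
             matches = as.integer(matches), columns = as.integer(cols))
}

#' Align two locus sequences into syntenic blocks
#'
#' Seed-and-extend alignment on both strands (see the file header for the
#' algorithm). Blocks shorter than `minBlock` alignment columns or below
#' `minIdentity` are dropped; blocks overlapping a higher-scoring block by
#' more than half their extent on either sequence are removed. Inverted
#' blocks carry `orientation = "inverted"` with `bStart`/`bEnd` in original
#' B coordinates.
#'
#' @param a,b nucleotide sequences (strings or `DNAString`).
#' @param word seed word size.
#' @param minBlock minimum block length in alignment columns.
#' @param minIdentity minimum identity (matches / columns, gaps counting as
#'   mismatch); the default mirrors the conventional 30% nucleotide identity
#'   threshold for syntenic blocks.
#' @param maxSeedOcc seeds occurring more often than this in either sequence
#'   are ignored (repeat masking).
#' @param minZ composition-aware significance filter: a block's match count
#'   must exceed the random expectation (given the two sequences' base
#'   compositions) by at least this many standard deviations. In AT-rich
#'   genomes random gapped alignments reach 40-50% identity, so an identity
#'   floor alone does not separate homology from chance.
#' @return data frame with 0-based half-open `aStart`, `aEnd`, `bStart`,
#'   `bEnd`, `orientation`, `identity`, `columns`, `score`.
#' @export
anchorAlign <- function(a, b, word = 12L, minBlock = 300L,
                        minIdentity = 0.30, maxSeedOcc = 32L, minZ = 10) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) .stopf("both sequences must be non-empty")
  nB <- nchar(b)
  bRC <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  out <- list()
  for (orient in c("forward", "inverted")) {
    bb <- if (orient == "forward") b else bRC
    seg <- .seedSegments(a, bb, word, maxSeedOcc)
    if (is.null(seg) || nrow(seg) == 0L) next
    clusters <- .clusterSegments(as.data.frame(seg))
    for (cl in clusters) {
      blk <- .scoreCluster(cl, a, bb)
      if (is.null(blk)) next
      blk$orientation <- orient
      out[[length(out) + 1L]] <- blk
    }
  }
  if (!length(out))
    return(data.frame(aStart = numeric(), aEnd = numeric(),
                      bStart = numeric(), bEnd = numeric(),
                      orientation = character(), identity = numeric(),
                      columns = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  blocks <- do.call(rbind, out)
  blocks$identity <- blocks$matches / blocks$columns
  blocks$score <- 2 * blocks$matches - (blocks$columns - blocks$matches)
  freq <- function(s) {
    v <- strsplit(s, "")[[1]]
    tab <- table(factor(v, levels = .BASES))
    as.numeric(tab) / max(1, sum(tab))
  }
  rBase <- sum(freq(a) * freq(b))
  z <- (blocks$matches - rBase * blocks$columns) /
    sqrt(pmax(blocks$columns * rBase * (1 - rBase), 1e-9))
  blocks <- blocks[blocks$columns >= minBlock &
                     blocks$identity >= minIdentity &
                     z >= minZ, , drop = FALSE]
  if (!nrow(blocks))
    return(data.frame(aStart = numeric(), aEnd = numeric(),
                      bStart = numeric(), bEnd = numeric(),
                      orientation = character(), identity = numeric(),
                      columns = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  # map inverted blocks back to original B coordinates (1-based inclusive)
  inv <- blocks$orientation == "inverted"
  if (any(inv)) {
    s <- blocks$bStart[inv]; e <- blocks$bEnd[inv]
    blocks$bStart[inv] <- nB - e + 1L
    blocks$bEnd[inv] <- nB - s + 1L
  }
  # overlap resolution by score
  blocks <- blocks[order(-blocks$score), , drop = FALSE]
  kept <- list()
  ovl <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)
  for (i in seq_len(nrow(blocks))) {
    bi <- blocks[i, ]
    reject <- FALSE
    for (kb in kept) {
      oa <- ovl(bi$aStart, bi$aEnd, kb$aStart, kb$aEnd) /
        (bi$aEnd - bi$aStart + 1)
      ob <- ovl(bi$bStart, bi$bEnd, kb$bStart, kb$bEnd) /
        (bi$bEnd - bi$bStart + 1)
      if (oa > 0.5 || ob > 0.5) { reject <- TRUE; break }
    }
    if (!reject) kept[[length(kept) + 1L]] <- bi
  }
  blocks <- do.call(rbind, kept)
  # convert to 0-based half-open
  blocks$aStart <- blocks$aStart - 1L
  blocks$bStart <- blocks$bStart - 1L
  blocks <- blocks[order(blocks$aStart), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks[, c("aStart", "aEnd", "bStart", "bEnd", "orientation",
             "identity", "columns", "score")]
}

.bestChain <- function(blocks, orientation, slop = 150L) {
  bl <- blocks[blocks$orientation == orientation, , drop = FALSE]
  if (!nrow(bl)) return(bl)
  bl <- bl[order(bl$aStart), , drop = FALSE]
  n <- nrow(bl)
  best <- bl$score
  prev <- rep(0L, n)
  for (j in seq_len(n)) for (i in seq_len(j - 1L)) {
    okA <- bl$aStart[j] >= bl$aEnd[i] - slop
    okB <- if (orientation == "forward")
      bl$bStart[j] >= bl$bEnd[i] - slop
    else bl$bEnd[j] <= bl$bStart[i] + slop
    if (okA && okB && best[i] + bl$score[j] > best[j]) {
      best[j] <- best[i] + bl$score[j]
      prev[j] <- i
    }
  }
  j <- which.max(best)
  sel <- integer()
  while (j > 0L) { sel <- c(j, sel); j <- prev[j] }
  bl[sel, , drop = FALSE]
}

#' Chain syntenic blocks and call unalignable regions
#'
#' The highest-scoring collinear chain is selected per orientation by dynamic
#' programming (one orientation switch is thereby permitted: the retained set
#' is the union of the best forward and best inverted chains, overlaps
#' trimmed at the midpoint). Intervals of either locus covered by no retained
#' block and at least `minRegion` long are emitted as unalignable regions
#' with origin call `unresolved`.
#'
#' @param blocks data frame from [anchorAlign()].
#' @param lenA,lenB locus lengths in bp.
#' @param minRegion minimum unalignable region length.
#' @return List with `blocks` (the retained chain) and `regions` (data frame
#'   `locus` ("A"/"B"), `start`, `end`, `length`, `origin`, `longestHit`).
#' @export
callUnalignableRegions <- function(blocks, lenA, lenB, minRegion = 2000L) {
  chainF <- .bestChain(blocks, "forward")
  chainI <- .bestChain(blocks, "inverted")
  chain <- rbind(chainF, chainI)
  if (nrow(chain) > 1L) {
    # enforce a 1-1 map: a partner interval may back only one block, so a
    # surplus copy on either side stays uncovered and is called unalignable
    chain <- chain[order(-chain$score), , drop = FALSE]
    keep <- logical(nrow(chain))
    ovl <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
    for (i in seq_len(nrow(chain))) {
      ok <- TRUE
      for (j in which(keep)) {
        fa <- ovl(chain$aStart[i], chain$aEnd[i],
                  chain$aStart[j], chain$aEnd[j]) /
          (chain$aEnd[i] - chain$aStart[i])
        fb <- ovl(chain$bStart[i], chain$bEnd[i],
                  chain$bStart[j], chain$bEnd[j]) /
          (chain$bEnd[i] - chain$bStart[i])
        if (fa > 0.25 || fb > 0.25) { ok <- FALSE; break }
      }
      keep[i] <- ok
    }
    chain <- chain[keep, , drop = FALSE]
    chain <- chain[order(chain$aStart), , drop = FALSE]
    for (i in seq_len(nrow(chain) - 1L)) {
      ov <- chain$aEnd[i] - chain$aStart[i + 1L]
      if (ov > 0) {   # trim at midpoint of the overlap
        cut <- chain$aStart[i + 1L] + ov / 2
        chain$aEnd[i] <- floor(cut)
        chain$aStart[i + 1L] <- ceiling(cut)
      }
    }
  }
  uncov <- function(iv, len) {
    gaps <- .complementIntervals(iv, len)
    gaps[gaps$end - gaps$start >= minRegion, , drop = FALSE]
  }
  gA <- uncov(data.frame(start = chain$aStart, end = chain$aEnd), lenA)
  gB <- uncov(data.frame(start = chain$bStart, end = chain$bEnd), lenB)
  mk <- function(g, which) if (nrow(g))
    data.frame(locus = which, start = g$start, end = g$end,
               length = g$end - g$start, origin = "unresolved",
               longestHit = NA_real_, stringsAsFactors = FALSE)
  else NULL
  regions <- rbind(mk(gA, "A"), mk(gB, "B"))
  if (is.null(regions))
    regions <- data.frame(locus = character(), start = numeric(),
                          end = numeric(), length = numeric(),
                          origin = character(), longestHit = numeric(),
                          stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  rownames(chain) <- NULL
  list(blocks = chain, regions = regions)
}

#' Median annotated gene length of a genome
#' @param genome an [AnnotatedGenome-class].
#' @return Median of `end - start` over all gene models.
#' @export
medianGeneLength <- function(genome) {
  g <- geneModels(genome)
  stats::median(g$end - g$start)
}

#' Test whether an unalignable region originated inside or outside the locus
#'
#' The region sequence is locally aligned against the whole genome with the
#' locus interval masked. The call is `imported` when some hit covers at
#' least 80% of the region (the sequence exists elsewhere in the genome,
#' e.g. a transposed copy), `local` when the longest hit is shorter than a
#' single typical gene (the conventional reading: nothing larger than one
#' gene matches outside the locus), and `unresolved` otherwise. Regions
#' shorter than the seed word are returned `unresolved` with a reason.
#'
#' @param regionSeq the region's nucleotide sequence.
#' @param genome the [AnnotatedGenome-class] the region came from.
#' @param excluded the [LocusRegion-class] to mask (the locus itself).
#' @param geneLengthRef reference "single gene" length in bp; defaults to the
#'   genome's median gene length.
#' @param word seed word size for the search.
#' @return List with `origin` and `longestHit` (bp).
#' @export
testRegionOrigin <- function(regionSeq, genome, excluded,
                             geneLengthRef = medianGeneLength(genome),
                             word = 12L) {
  regionSeq <- toupper(as.character(regionSeq))
  if (nchar(regionSeq) < word)
    return(list(origin = "unresolved", longestHit = NA_real_,
                reason = "region shorter than seed word"))
  seqs <- as.character(contigSeqs(genome))
  if (!is.null(excluded)) {
    ctg <- seqs[[excluded@contig]]
    substr(ctg, excluded@start + 1L, excluded@end) <-
      strrep("N", excluded@end - excluded@start)
    seqs[[excluded@contig]] <- ctg
  }
  longest <- 0
  for (s in seqs) {
    hits <- anchorAlign(regionSeq, s, word = word, minBlock = 3L * word,
                        minIdentity = 0.6)
    if (nrow(hits))
      longest <- max(longest, max(hits$aEnd - hits$aStart))
  }
  origin <- if (longest >= 0.8 * nchar(regionSeq)) "imported"
    else if (longest < geneLengthRef) "local"
    else "unresolved"
  list(origin = origin, longestHit = longest)
}
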