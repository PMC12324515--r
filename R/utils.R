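# Internal sequence and interval helpers. Sequences are handled as character
# vectors of single bases inside the simulator (cheap splicing and vectorized
# substitution) and as Biostrings objects at module boundaries.

.BASES <- c("A", "C", "G", "T")

.baseProbs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                             T = (1 - gc) / 2)

.randBases <- function(n, gc) {
  sample(.BASES, n, replace = TRUE, prob = .baseProbs(gc))
}

.GENETIC_CODE <- Biostrings::GENETIC_CODE
.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]
.SENSE_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]

# Random coding sequence: ATG + sense codons + stop, approximating a target
# base composition by weighting codons by their base probabilities.
.randCodingBases <- function(nCodons, gc) {
  stopifnot(nCodons >= 3)
  p <- .baseProbs(gc)
  cw <- vapply(strsplit(.SENSE_CODONS, ""), function(b) prod(p[b]), 0)
  body <- sample(.SENSE_CODONS, nCodons - 2L, replace = TRUE, prob = cw)
  stop <- sample(.STOP_CODONS, 1L, prob = c(TAA = .6, TAG = .1, TGA = .3)[.STOP_CODONS])
  unlist(strsplit(c("ATG", body, stop), ""), use.names = FALSE)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcompChars <- function(v) unname(.COMP[rev(v)])

.collapse <- function(v) paste(v, collapse = "")

# Translate a CDS given as a character vector of bases (plus strand already
# applied). Returns the AA string including '*' for internal stops; the
# terminal stop is dropped. Length not divisible by 3 translates the whole
# codons only.
.translateCds <- function(bases) {
  n <- length(bases) %/% 3L
  if (n == 0L) return("")
  codons <- paste0(bases[3 * seq_len(n) - 2], bases[3 * seq_len(n) - 1],
                   bases[3 * seq_len(n)])
  aa <- .GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  if (n > 1L && aa[n] == "*") aa <- aa[-n]
  paste(aa, collapse = "")
}

.geneSeq <- function(seqChars, gene) {
  v <- seqChars[[gene$contig]][(gene$start + 1L):gene$end]
  if (gene$strand == "-") v <- .revcompChars(v)
  v
}

# Does this CDS (already stranded) contain an internal stop codon?
.hasInternalStop <- function(bases) {
  aa <- .translateCds(bases)
  grepl("*", aa, fixed = TRUE)
}

#' Copy a sequence with random substitutions
#'
#' Utility for planting diverged copies of a sequence (for example when
#' constructing test regions of known origin). Each position is substituted
#' independently with probability `rate`, drawing uniformly from the three
#' alternative bases.
#'
#' @param x a character string, `DNAString`, or character vector of bases.
#' @param rate per-site substitution probability.
#' @return An object of the same form as `x` (string in, string out).
#' @export
mutateSequence <- function(x, rate) {
  asString <- is.character(x) && length(x) == 1L && nchar(x) > 1L
  v <- if (asString) strsplit(x, "")[[1]] else if (is.character(x)) x
       else strsplit(as.character(x), "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(.BASES, b), 1L), "")
  }
  if (is.character(x) && !asString && length(x) > 1L) v else .collapse(v)
}

# ---- interval helpers (0-based half-open, data.frame with start/end) ----

.mergeIntervals <- function(df, slop = 0L) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$start, df$end), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    j <- nrow(out)
    if (df$start[i] <= out$end[j] + slop) {
      out$end[j] <- max(out$end[j], df$end[i])
    } else out <- rbind(out, df[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

# Complement of a set of intervals within [0, len)
.complementIntervals <- function(df, len) {
  if (nrow(df) == 0L) return(data.frame(start = 0, end = len)[len > 0, ])
  m <- .mergeIntervals(df)
  starts <- c(0, m$end)
  ends <- c(m$start, len)
  keep <- starts < ends
  data.frame(start = starts[keep], end = ends[keep])
}

.totalCovered <- function(df) {
  if (nrow(df) == 0L) return(0)
  m <- .mergeIntervals(df)
  sum(m$end - m$start)
}

# Fraction of [s1,e1) covered by [s2,e2), reciprocal-overlap style
.reciprocalOverlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
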