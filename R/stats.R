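# Molecular-evolution statistics on gene alignments: pairwise identity,
# nucleotide diversity (pi, Watterson's theta), Tajima's D, and the
# Nei-Gojobori (1986) dN/dS estimator with Jukes-Cantor correction and
# equal-weight averaging over shortest substitution pathways.

# Coerce an alignment to an uppercase character matrix (rows = sequences).
.alnMatrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else if (methods::is(x, "XStringSet") ||
             methods::is(x, "MultipleAlignment")) {
    s <- as.character(x)
    if (length(unique(nchar(s))) != 1L)
      .stopf("alignment rows must have equal length")
    m <- do.call(rbind, strsplit(s, ""))
    rownames(m) <- names(s)
  } else if (is.character(x)) {
    if (length(unique(nchar(x))) != 1L)
      .stopf("alignment rows must have equal length")
    m <- do.call(rbind, strsplit(x, ""))
    rownames(m) <- names(x)
  } else .stopf("unsupported alignment representation")
  toupper(m)
}

.GAP <- c("-", ".")

#' Pairwise identity of two aligned rows
#'
#' Identity is matches divided by the number of columns where neither row is
#' a gap; columns where both rows are gaps are skipped. Returns `NA` (with a
#' warning) when no comparable columns exist.
#'
#' @param a,b aligned sequences of equal length (strings or character
#'   vectors).
#' @param mode `"nt"` or `"aa"`; case-insensitive comparison either way.
#' @return Fraction in \[0, 1\], or `NA` if undefined.
#' @examples
#' pairwiseIdentity("ACGT", "AC-T")  # 1.0 over 3 comparable columns
#' @export
pairwiseIdentity <- function(a, b, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  m <- .alnMatrix(c(paste(a, collapse = ""), paste(b, collapse = "")))
  ok <- !(m[1, ] %in% .GAP) & !(m[2, ] %in% .GAP)
  if (!any(ok)) {
    warning("no comparable columns; identity undefined")
    return(NA_real_)
  }
  sum(m[1, ok] == m[2, ok]) / sum(ok)
}

# columns without any gap (listwise deletion)
.ungappedColumns <- function(m) {
  which(colSums(matrix(m %in% .GAP, nrow = nrow(m))) == 0L)
}

.tajimaConstants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Nucleotide diversity and Watterson's theta
#'
#' Gap-containing columns are excluded listwise; over the remaining `L`
#' sites, `pi` is the mean pairwise difference per site across all
#' `n(n-1)/2` sequence pairs and `thetaW = S / (a1 * L)` with
#' `a1 = sum(1/i), i = 1..n-1`.
#'
#' @param aln an alignment (character vector/matrix or `XStringSet`) with
#'   `n >= 2` rows.
#' @return A list with `n`, `L`, `S`, `pi`, `thetaW`, `piTotal` (mean
#'   pairwise differences, not per site), `D` (`NA` here) and `defined`.
#' @export
nucleotideDiversity <- function(aln) {
  m <- .alnMatrix(aln)
  n <- nrow(m)
  if (n < 2L) .stopf("at least 2 sequences are required")
  cols <- .ungappedColumns(m)
  m <- m[, cols, drop = FALSE]
  L <- ncol(m)
  if (L == 0L) .stopf("no gap-free columns")
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1L))
  pairsDiff <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    pairsDiff <- pairsDiff + sum(m[i, ] != m[j, ])
  nPairs <- n * (n - 1) / 2
  piTotal <- pairsDiff / nPairs
  k <- .tajimaConstants(max(n, 2L))
  list(n = n, L = L, S = S, pi = piTotal / L,
       thetaW = S / (k$a1 * L), piTotal = piTotal,
       D = NA_real_, defined = FALSE)
}

#' Tajima's D
#'
#' Standard formulation: `D = (piTotal - S/a1) / sqrt(e1*S + e2*S*(S-1))`
#' with the constants of the original derivation. The result carries
#' `defined = FALSE` (never an exception) when `S = 0` or `n < 4`.
#'
#' @inheritParams nucleotideDiversity
#' @return As [nucleotideDiversity()], with `D` and `defined` filled in.
#' @export
tajimasD <- function(aln) {
  res <- nucleotideDiversity(aln)
  if (res$S == 0L || res$n < 4L) return(res)
  k <- .tajimaConstants(res$n)
  S <- res$S
  res$D <- (res$piTotal - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  res$defined <- TRUE
  res
}

# ---- Nei-Gojobori 1986 ----------------------------------------------------

# Fraction of synonymous one-step changes at each position of a codon.
# All nine alternative bases are counted; changes to stop codons count as
# nonsynonymous so that N + S = 3 per codon.
.codonSynFractions <- local({
  cache <- new.env()
  function(codon) {
    if (!is.null(cache[[codon]])) return(cache[[codon]])
    b <- strsplit(codon, "")[[1]]
    aa <- .GENETIC_CODE[[codon]]
    s <- numeric(3)
    for (p in 1:3) {
      for (alt in setdiff(.BASES, b[p])) {
        b2 <- b; b2[p] <- alt
        aa2 <- .GENETIC_CODE[[paste(b2, collapse = "")]]
        if (!is.na(aa2) && aa2 != "*" && aa2 == aa) s[p] <- s[p] + 1
      }
    }
    cache[[codon]] <- s / 3
    s / 3
  }
})

# Average (syn, nonsyn) difference counts between two codons over all
# shortest substitution pathways, weighting pathways equally. Pathways that
# pass through a stop codon are excluded unless all do.
.codonPairDiffs <- local({
  cache <- new.env()
  function(c1, c2) {
    key <- paste0(c1, c2)
    if (!is.null(cache[[key]])) return(cache[[key]])
    b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
    pos <- which(b1 != b2)
    nd <- length(pos)
    if (nd == 0L) {
      res <- c(syn = 0, nonsyn = 0)
    } else {
      perms <- if (nd == 1L) list(pos)
        else if (nd == 2L) list(pos, rev(pos))
        else {
          idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                      c(3,2,1))
          lapply(idx, function(o) pos[o])
        }
      walk <- function(order) {
        cur <- b1
        syn <- 0; nonsyn <- 0; throughStop <- FALSE
        for (p in order) {
          aaFrom <- .GENETIC_CODE[[paste(cur, collapse = "")]]
          cur[p] <- b2[p]
          codonTo <- paste(cur, collapse = "")
          aaTo <- .GENETIC_CODE[[codonTo]]
          if (aaTo == "*" && codonTo != c2) throughStop <- TRUE
          if (aaFrom == aaTo && aaTo != "*") syn <- syn + 1
          else nonsyn <- nonsyn + 1
        }
        c(syn = syn, nonsyn = nonsyn, stop = as.numeric(throughStop))
      }
      w <- vapply(perms, walk, numeric(3))
      ok <- w["stop", ] == 0
      if (!any(ok)) ok <- rep(TRUE, ncol(w))
      res <- c(syn = mean(w["syn", ok]), nonsyn = mean(w["nonsyn", ok]))
    }
    cache[[key]] <- res
    res
  }
})

.jcCorrect <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) dN/dS for a pair of aligned codon sequences
#'
#' Synonymous/nonsynonymous site counts are averaged over the two sequences
#' (every codon contributes 3 sites, changes to stop codons counting as
#' nonsynonymous). Codons differing at several positions are averaged over
#' all shortest substitution pathways with equal weight, excluding pathways
#' through stop codons when possible. Proportions are Jukes-Cantor corrected:
#' `d = -3/4 log(1 - 4p/3)`, undefined (`NA`, flagged) when `p >= 0.75`.
#'
#' @param a,b aligned codon sequences of equal length (strings); gaps must
#'   come in whole-codon units and such codons are excluded pairwise.
#' @return List with `N`, `S` (site counts), `Nd`, `Sd` (differences), `pN`,
#'   `pS`, `dN`, `dS`, `ratio` (NA when `dS` is 0 or undefined), `codons`
#'   (codons compared) and `flags`.
#' @export
ng86dnds <- function(a, b) {
  av <- .alnMatrix(c(paste(a, collapse = ""), paste(b, collapse = "")))
  if (ncol(av) %% 3L != 0L) .stopf("codon alignment length must be divisible by 3")
  nC <- ncol(av) %/% 3L
  c1 <- apply(matrix(av[1, ], nrow = 3), 2, paste, collapse = "")
  c2 <- apply(matrix(av[2, ], nrow = 3), 2, paste, collapse = "")
  gap1 <- grepl("[-.]", c1); gap2 <- grepl("[-.]", c2)
  partial <- (gap1 & c1 != "---") | (gap2 & c2 != "---")
  if (any(grepl("[-.]", c1) & nchar(gsub("[-.]", "", c1)) %in% 1:2) ||
      any(grepl("[-.]", c2) & nchar(gsub("[-.]", "", c2)) %in% 1:2))
    .stopf("gaps must come in whole-codon units")
  keep <- !gap1 & !gap2
  c1 <- c1[keep]; c2 <- c2[keep]
  stop1 <- which(.GENETIC_CODE[c1] == "*")
  stop2 <- which(.GENETIC_CODE[c2] == "*")
  # a terminal stop codon pair is tolerated and dropped
  if (length(c1) && !is.na(.GENETIC_CODE[c1[length(c1)]]) &&
      .GENETIC_CODE[[c1[length(c1)]]] == "*" &&
      .GENETIC_CODE[[c2[length(c2)]]] == "*") {
    c1 <- c1[-length(c1)]; c2 <- c2[-length(c2)]
    stop1 <- which(.GENETIC_CODE[c1] == "*")
    stop2 <- which(.GENETIC_CODE[c2] == "*")
  }
  if (length(stop1)) .stopf("internal stop codon at codon %d", stop1[1])
  if (length(stop2)) .stopf("internal stop codon at codon %d", stop2[1])

  sSites <- 0
  for (cd in c(c1, c2)) sSites <- sSites + sum(.codonSynFractions(cd))
  Ssites <- sSites / 2
  Nsites <- 3 * length(c1) - Ssites

  Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    d <- .codonPairDiffs(c1[i], c2[i])
    Sd <- Sd + d["syn"]; Nd <- Nd + d["nonsyn"]
  }
  pS <- if (Ssites > 0) Sd / Ssites else NA_real_
  pN <- if (Nsites > 0) Nd / Nsites else NA_real_
  dS <- .jcCorrect(pS); dN <- .jcCorrect(pN)
  flags <- character()
  if (!is.na(pS) && pS >= 0.75) flags <- c(flags, "pS saturated")
  if (!is.na(pN) && pN >= 0.75) flags <- c(flags, "pN saturated")
  ratio <- if (is.na(dS) || is.na(dN) || dS == 0) {
    flags <- c(flags, "ratio undefined")
    NA_real_
  } else dN / dS
  list(N = Nsites, S = Ssites, Nd = unname(Nd), Sd = unname(Sd),
       pN = unname(pN), pS = unname(pS), dN = unname(dN), dS = unname(dS),
       ratio = ratio, codons = length(c1), flags = flags)
}

#' Evaluate a statistic in sliding windows
#'
#' Windows are half-open `[start, start + window)` on alignment columns
#' (0-based); a trailing partial window is included iff it spans at least
#' half a window.
#'
#' @param aln an alignment.
#' @param stat function taking the windowed alignment matrix, returning a
#'   single number.
#' @param window,step window size and step in alignment columns.
#' @return data frame with `start`, `end`, `value`.
#' @export
slidingWindow <- function(aln, stat, window, step) {
  if (step <= 0) .stopf("step must be positive")
  m <- .alnMatrix(aln)
  L <- ncol(m)
  if (window > L) .stopf("window exceeds alignment length")
  starts <- seq(0L, max(0L, L - window), by = step)
  last <- starts[length(starts)] + window
  if (L - last >= window / 2) starts <- c(starts, last)
  out <- lapply(starts, function(s) {
    e <- min(s + window, L)
    data.frame(start = s, end = e,
               value = stat(m[, (s + 1L):e, drop = FALSE]))
  })
  do.call(rbind, out)
}
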