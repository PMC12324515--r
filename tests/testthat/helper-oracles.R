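# Independent brute-force oracles, coded directly from the published
# formulas and definitions. They deliberately share no code with the package
# implementations they check.

# Tajima's D: literal transcription of the 1989 constants.
oracleTajimaD <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  keep <- apply(m, 2, function(col) !any(col == "-"))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- 0
  for (j in seq_len(ncol(m))) if (length(unique(m[, j])) > 1) S <- S + 1
  k <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- k + sum(m[i, ] != m[j, ])
    np <- np + 1
  }
  khat <- k / np
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  if (S == 0 || n < 4) return(NA_real_)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Nei-Gojobori 1986 by exhaustive enumeration. Sites: per codon and position,
# the number of the three possible changes that preserve the amino acid
# (changes to stops count as nonsynonymous). Differences: recursive
# enumeration of all orderings of the differing positions; orderings passing
# through a stop codon are discarded unless all do.
oracleNG86 <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  translate1 <- function(cd) code[[cd]]
  splitCodons <- function(s) substring(s, seq(1, nchar(s), 3),
                                       seq(3, nchar(s), 3))
  ca <- splitCodons(a); cb <- splitCodons(b)
  synSites <- function(cd) {
    bs <- strsplit(cd, "")[[1]]
    aa <- translate1(cd)
    syn <- 0
    for (pos in 1:3) for (nt in c("A", "C", "G", "T")) {
      if (nt == bs[pos]) next
      alt <- bs; alt[pos] <- nt
      aa2 <- translate1(paste(alt, collapse = ""))
      if (aa2 == aa && aa2 != "*") syn <- syn + 1 / 3
    }
    syn
  }
  pathways <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(list())
    perms <- if (length(pos) == 1) list(pos) else {
      out <- list()
      rec <- function(prefix, rest) {
        if (!length(rest)) { out[[length(out) + 1]] <<- prefix; return() }
        for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
      }
      rec(integer(), pos)
      out
    }
    res <- list()
    for (pm in perms) {
      cur <- strsplit(c1, "")[[1]]
      tgt <- strsplit(c2, "")[[1]]
      syn <- 0; nonsyn <- 0; bad <- FALSE
      for (p in pm) {
        before <- translate1(paste(cur, collapse = ""))
        cur[p] <- tgt[p]
        after <- translate1(paste(cur, collapse = ""))
        if (after == "*" && paste(cur, collapse = "") != c2) bad <- TRUE
        if (before == after && after != "*") syn <- syn + 1
        else nonsyn <- nonsyn + 1
      }
      res[[length(res) + 1]] <- list(syn = syn, nonsyn = nonsyn, bad = bad)
    }
    good <- Filter(function(x) !x$bad, res)
    if (!length(good)) good <- res
    good
  }
  Stot <- 0
  for (cd in c(ca, cb)) Stot <- Stot + synSites(cd)
  Ssites <- Stot / 2
  Nsites <- 3 * length(ca) - Ssites
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    pw <- pathways(ca[i], cb[i])
    if (!length(pw)) next
    Sd <- Sd + mean(vapply(pw, function(x) x$syn, 0))
    Nd <- Nd + mean(vapply(pw, function(x) x$nonsyn, 0))
  }
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -3 / 4 * log(1 - 4 * p / 3)
  list(N = Nsites, S = Ssites, Nd = Nd, Sd = Sd,
       dN = jc(Nd / Nsites), dS = jc(Sd / Ssites))
}

# random stop-free codon string
randomCodons <- function(n) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

smallParams <- function(seed = 1L, ...) {
  EvolParams(nBackgroundGenes = 12L, nLocusGenes = 6L, meanGeneLen = 450,
             seed = seed, ...)
}

fourTipTree <- function(bl = 0.15) {
  ape::read.tree(text = sprintf(
    "((A:%1$f,B:%1$f):0.08,(C:%1$f,D:%1$f):0.08);", bl))
}

# deep two-clade tree: near-identical sequences within clades, strong
# divergence between them (the regime in which chimeras are detectable)
twoCladeTree <- function() {
  ape::read.tree(text = paste0(
    "((a1:0.02,(a2:0.015,a3:0.015):0.005):0.25,",
    "(b1:0.02,(b2:0.015,b3:0.015):0.005):0.25);"))
}
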