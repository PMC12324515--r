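# Recombination breakpoint detection on curated gene alignments. The
# alignment is segmented by dynamic programming: candidate breakpoints lie on
# a column grid, the cost of a segment is the negative log-likelihood of its
# columns under a Jukes-Cantor model on the segment's own NJ tree (built from
# JC-corrected p-distances), and each breakpoint pays a fixed penalty. A pure
# distance-residual cost was tried first and discarded: a chimeric sequence
# merely shifts its average position in the distance matrix, which stays
# near-additive, so the residual barely responds to recombination, whereas
# the per-column likelihood is strongly bimodal around the junction. A
# column-permutation test (destroying linkage, preserving site frequencies)
# assigns each breakpoint a p-value.

# Per-site log-likelihood of alignment columns under a JC model on a given
# tree (Felsenstein pruning). Used to refine breakpoint positions: the
# log-likelihood ratio between the trees of the two flanking segments is a
# per-column signal whose cumulative sum peaks at the junction.
.siteLogLik <- function(m, tree) {
  L <- ncol(m)
  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  lv <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) {
    prof <- matrix(1, 4, L)
    row <- m[tree$tip.label[t], ]
    known <- row %in% .BASES
    prof[, known] <- 0
    prof[cbind(match(row[known], .BASES), which(known))] <- 1
    lv[[t]] <- prof
  }
  scale <- numeric(L)
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    t <- max(tree$edge.length[k], 1e-8)
    e <- exp(-4 * t / 3)
    a <- 0.25 + 0.75 * e; b <- 0.25 - 0.25 * e
    P <- matrix(b, 4, 4); diag(P) <- a
    msg <- P %*% lv[[child]]
    if (is.null(lv[[par]])) lv[[par]] <- msg
    else lv[[par]] <- lv[[par]] * msg
  }
  root <- tree$edge[nrow(tree$edge), 1]
  log(colSums(lv[[root]] * 0.25)) + scale
}

# NJ tree on JC-corrected distances of a segment's p-distance matrix
.segmentTree <- function(D) {
  p <- pmin(D, 0.70)
  d <- -0.75 * log(1 - 4 * p / 3)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 1e-8
  tr
}

# Precompute per-pair cumulative mismatch / comparable-column counts so that
# any segment's p-distance matrix is O(pairs) to obtain.
.alnScanner <- function(m) {
  n <- nrow(m)
  if (n < 4L) .stopf("at least 4 rows are required")
  L <- ncol(m)
  gaps <- m %in% .GAP
  dim(gaps) <- dim(m)
  pairs <- utils::combn(n, 2L)
  nP <- ncol(pairs)
  compC <- matrix(0, L + 1L, nP)
  mismC <- matrix(0, L + 1L, nP)
  for (p in seq_len(nP)) {
    r1 <- pairs[1, p]; r2 <- pairs[2, p]
    ok <- !gaps[r1, ] & !gaps[r2, ]
    compC[, p] <- c(0, cumsum(ok))
    mismC[, p] <- c(0, cumsum(ok & m[r1, ] != m[r2, ]))
  }
  cache <- new.env(parent = emptyenv())
  pdist <- function(i, j) {
    cnt <- compC[j + 1L, ] - compC[i + 1L, ]
    mm <- mismC[j + 1L, ] - mismC[i + 1L, ]
    d <- ifelse(cnt > 0, mm / cnt, 0)
    D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    D[t(pairs)] <- d
    D[t(pairs[2:1, , drop = FALSE])] <- d
    D
  }
  cost <- function(i, j) {
    key <- paste0(i, "_", j)
    v <- cache[[key]]
    if (!is.null(v)) return(v)
    tr <- .segmentTree(pdist(i, j))
    v <- -sum(.siteLogLik(m[, (i + 1L):j, drop = FALSE], tr))
    cache[[key]] <- v
    v
  }
  list(n = n, L = L, cost = cost, pdist = pdist)
}

#' Per-window distances from a focal sequence to every other row
#'
#' The profile behind breakpoint visualisation: in each window, the
#' p-distance from the focal row to every other row over comparable columns.
#' Windows with fewer than 10 comparable columns for a row are flagged.
#'
#' @param aln an alignment.
#' @param focal row name of the focal sequence.
#' @param window,step window size and step in columns (window >= 30).
#' @return data frame: `start`, `end`, `other`, `dist`, `comparable`,
#'   `flagged`.
#' @export
windowProfiles <- function(aln, focal, window = 100L, step = 25L) {
  m <- .alnMatrix(aln)
  if (window < 30L) .stopf("window must be at least 30 sites")
  if (!(focal %in% rownames(m)))
    .stopf("focal sequence '%s' is not in the alignment", focal)
  others <- setdiff(rownames(m), focal)
  fv <- m[focal, ]
  starts <- seq(0L, max(0L, ncol(m) - window), by = step)
  out <- list()
  for (s in starts) {
    e <- min(s + window, ncol(m))
    idx <- (s + 1L):e
    for (o in others) {
      ok <- !(fv[idx] %in% .GAP) & !(m[o, idx] %in% .GAP)
      cmp <- sum(ok)
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e, other = o,
        dist = if (cmp > 0) sum(fv[idx][ok] != m[o, idx][ok]) / cmp
               else NA_real_,
        comparable = cmp, flagged = cmp < 10L, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.DEFAULT_PENALTY <- 16  # calibrated by scripts/calibrate_penalty.R

#' Segment an alignment at recombination breakpoints
#'
#' Dynamic-programming segmentation minimizing total cost
#' `sum(segment fit deviance) + penalty * breakpoints`, where a segment's fit
#' deviance is the negative log-likelihood of its columns under a JC model on
#' the segment's own NJ tree. Candidate breakpoints are restricted
#' to every `step`-th column; segments must span at least `minSegment`
#' columns. The default penalty is calibrated so that substitution-only
#' (recombination-free) simulations yield at most ~10% false positives
#' (`scripts/calibrate_penalty.R` in the source repository reproduces the
#' calibration).
#'
#' @param aln an alignment with >= 4 rows.
#' @param maxBreakpoints largest admissible number of breakpoints.
#' @param penalty per-breakpoint cost penalty.
#' @param step candidate-breakpoint grid spacing in columns.
#' @param minSegment minimum segment length in columns.
#' @return An object of class `breakpointSet`: list with `breakpoints`
#'   (column positions, strictly increasing), `segments` (data frame
#'   `start`, `end`), `assignments` (rows x segments matrix of each row's
#'   nearest relative), `cost` (penalized total), `penalty`, `step`,
#'   `pvalues` (filled by [testBreakpointSignificance()]).
#' @export
segmentAlignment <- function(aln, maxBreakpoints = 8L,
                             penalty = .DEFAULT_PENALTY, step = 10L,
                             minSegment = 100L) {
  if (maxBreakpoints < 0L) .stopf("maxBreakpoints must be >= 0")
  m <- .alnMatrix(aln)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  sc <- .alnScanner(m)
  L <- sc$L
  grid <- unique(c(seq(0L, L, by = step), L))
  nG <- length(grid)
  K <- min(maxBreakpoints + 1L, max(1L, L %/% minSegment))
  INF <- Inf
  best <- matrix(INF, K, nG)   # best[k, gi]: cost of [0, grid[gi]) in k parts
  back <- matrix(0L, K, nG)
  for (gi in seq_len(nG)) {
    if (grid[gi] >= minSegment || grid[gi] == L)
      best[1, gi] <- if (grid[gi] > 0) sc$cost(0L, grid[gi]) else INF
  }
  if (K >= 2L) for (k in 2:K) {
    for (gi in seq_len(nG)) {
      if (grid[gi] < k * minSegment && grid[gi] < L) next
      for (pi in seq_len(gi - 1L)) {
        if (!is.finite(best[k - 1L, pi])) next
        seg <- grid[gi] - grid[pi]
        if (seg < minSegment) next
        v <- best[k - 1L, pi] + sc$cost(grid[pi], grid[gi])
        if (v < best[k, gi]) { best[k, gi] <- v; back[k, gi] <- pi }
      }
    }
  }
  endI <- nG
  pen <- penalty * (seq_len(K) - 1L)
  pen[1] <- 0                       # no penalty for zero breakpoints
  total <- best[, endI] + pen
  kBest <- which.min(total)
  bps <- integer()
  gi <- endI
  k <- kBest
  while (k > 1L) {
    gi <- back[k, gi]
    bps <- c(grid[gi], bps)
    k <- k - 1L
  }
  # refine each breakpoint at column resolution: per-column log-likelihood
  # ratio between the NJ trees of the two flanking segments, centred, with
  # the CUSUM argmax as the change-point estimate
  if (length(bps)) for (pass in 1:2) {
    bounds0 <- c(0L, bps, L)
    for (i in seq_along(bps)) {
      l <- bounds0[i]; b <- bps[i]; r <- bounds0[i + 2L]
      sub <- m[, (l + 1L):r, drop = FALSE]
      trL <- .segmentTree(sc$pdist(l, b))
      trR <- .segmentTree(sc$pdist(b, r))
      x <- .siteLogLik(sub, trL) - .siteLogLik(sub, trR)
      centre <- (mean(x[seq_len(b - l)]) + mean(x[(b - l + 1L):(r - l)])) / 2
      cs <- cumsum(x - centre)
      win <- if (pass == 1L) 5L * step else 2L * step
      lo <- max(b - win, l + 10L); hi <- min(b + win, r - 10L)
      if (lo >= hi) next
      cand <- lo:hi
      bps[i] <- cand[which.max(cs[cand - l])]
    }
    bps <- sort(unique(pmax(pmin(bps, L - 1L), 1L)))
  }
  bounds <- c(0L, bps, L)
  segments <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  assignments <- matrix(NA_character_, nrow(m), nrow(segments),
                        dimnames = list(rownames(m),
                                        paste0("seg", seq_len(nrow(segments)))))
  for (si in seq_len(nrow(segments))) {
    D <- sc$pdist(segments$start[si], segments$end[si])
    diag(D) <- Inf
    assignments[, si] <- rownames(m)[apply(D, 1, which.min)]
  }
  structure(list(breakpoints = bps, segments = segments,
                 assignments = assignments, cost = total[kBest],
                 rawCost = best[kBest, endI], penalty = penalty,
                 step = step, minSegment = minSegment,
                 pvalues = rep(NA_real_, length(bps)),
                 threshold = NA_real_),
            class = "breakpointSet")
}

#' @export
print.breakpointSet <- function(x, ...) {
  cat("breakpointSet:", length(x$breakpoints), "breakpoint(s)",
      if (length(x$breakpoints))
        paste0("at column(s) ", paste(x$breakpoints, collapse = ", ")),
      "| cost", format(x$cost, digits = 4), "\n")
  if (!all(is.na(x$pvalues)) && length(x$breakpoints))
    cat("p-values:", paste(format(x$pvalues, digits = 3), collapse = ", "),
        "(threshold", x$threshold, ")\n")
  invisible(x)
}

# best single-split improvement of segment [0, W) of matrix mm over the grid
.bestSplitImprovement <- function(mm, step, minSegment) {
  sc <- .alnScanner(mm)
  W <- sc$L
  whole <- sc$cost(0L, W)
  cand <- seq(minSegment, W - minSegment, by = step)
  if (!length(cand)) return(0)
  imp <- vapply(cand, function(b) whole - sc$cost(0L, b) - sc$cost(b, W), 0)
  max(imp)
}

#' Permutation significance test for breakpoints
#'
#' For each breakpoint, the observed improvement is the cost of merging its
#' two flanking segments minus the cost of keeping them split. The null
#' distribution is obtained by permuting the column order within the flanking
#' window (destroying spatial signal while preserving per-site frequencies)
#' and recording the best achievable single-split improvement. Breakpoints
#' with `p > threshold` are dropped from the significant set.
#'
#' @param aln the alignment passed to [segmentAlignment()].
#' @param bp the resulting `breakpointSet`.
#' @param nPerm number of permutations (>= 20).
#' @param seed integer seed; equal seeds give identical p-values.
#' @param threshold significance level.
#' @return `bp` with `pvalues`, `threshold` and `significant` (breakpoint
#'   columns with `p <= threshold`) filled in.
#' @export
testBreakpointSignificance <- function(aln, bp, nPerm = 99L, seed = 1L,
                                       threshold = 0.05) {
  if (nPerm < 20L) .stopf("nPerm must be at least 20 for any resolution")
  stopifnot(inherits(bp, "breakpointSet"))
  m <- .alnMatrix(aln)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  set.seed(seed)
  sc <- .alnScanner(m)
  bounds <- c(0L, bp$breakpoints, ncol(m))
  pv <- numeric(length(bp$breakpoints))
  for (i in seq_along(bp$breakpoints)) {
    l <- bounds[i]; b <- bp$breakpoints[i]; r <- bounds[i + 2L]
    # observed improvement: best single split of [l, r) over the same
    # candidate grid the null optimizes over (plus the reported breakpoint),
    # so that observed and null statistics undergo the same selection
    whole <- sc$cost(l, r)
    cand <- unique(c(seq(l + bp$minSegment, r - bp$minSegment,
                         by = bp$step), b))
    cand <- cand[cand > l & cand < r]
    obs <- max(vapply(cand, function(cc)
      whole - sc$cost(l, cc) - sc$cost(cc, r), 0))
    sub <- m[, (l + 1L):r, drop = FALSE]
    null <- vapply(seq_len(nPerm), function(x) {
      .bestSplitImprovement(sub[, sample.int(ncol(sub)), drop = FALSE],
                            bp$step, bp$minSegment)
    }, 0)
    pv[i] <- (1 + sum(null >= obs)) / (nPerm + 1)
  }
  bp$pvalues <- pv
  bp$threshold <- threshold
  bp$significant <- bp$breakpoints[pv <= threshold]
  bp
}
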