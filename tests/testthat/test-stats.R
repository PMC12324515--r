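test_that("pairwise identity skips gaps and counts matches over comparable columns", {
  expect_equal(pairwiseIdentity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwiseIdentity("ACGT", "AC-T"), 1.0)   # 3 comparable, 3 match
  expect_equal(pairwiseIdentity("ACGT", "ACTT"), 0.75)
  expect_warning(res <- pairwiseIdentity("--", "AA"), "no comparable")
  expect_true(is.na(res))
})

test_that("pairwise identity tracks simulated divergence", {
  set.seed(4)
  a <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  b <- mutateSequence(a, 0.40)
  # 40% substitution draws, each to one of the other three bases
  expect_equal(pairwiseIdentity(a, b), 0.60, tolerance = 0.05)
})

test_that("nucleotide diversity matches hand computations", {
  rows <- c(paste(rep("A", 100), collapse = ""),
            paste(c(rep("A", 99), "C"), collapse = ""))
  r <- nucleotideDiversity(rows)
  expect_equal(r$pi, 0.01)
  expect_equal(r$S, 1L)

  # 4 rows, hand-built with S = 3: theta = S / (a1 * L)
  rows4 <- c("AAAAAAAAAA", "CAAAAAAAAA", "ACAAAAAAAA", "AACAAAAAAA")
  r4 <- nucleotideDiversity(rows4)
  a1 <- 1 + 1 / 2 + 1 / 3
  expect_equal(r4$S, 3L)
  expect_equal(r4$thetaW, 3 / (a1 * 10))

  same <- rep("ACGTACGT", 3)
  r0 <- nucleotideDiversity(same)
  expect_equal(r0$pi, 0)
  expect_equal(r0$thetaW, 0)
  expect_error(nucleotideDiversity("ACGT"), "at least 2")
})

test_that("pi equals the mean pairwise-identity complement on gap-free alignments", {
  set.seed(9)
  for (rep in 1:5) {
    rows <- replicate(5, paste(sample(c("A", "C", "G", "T"), 60,
                                      replace = TRUE), collapse = ""))
    r <- nucleotideDiversity(rows)
    ids <- c()
    for (i in 1:4) for (j in (i + 1):5)
      ids <- c(ids, pairwiseIdentity(rows[i], rows[j]))
    expect_equal(r$pi, mean(1 - ids), tolerance = 1e-12)
  }
})

test_that("Tajima's D matches the brute-force oracle on random alignments", {
  set.seed(11)
  checked <- 0
  while (checked < 50) {
    n <- sample(4:8, 1)
    L <- sample(30:80, 1)
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    rows <- vapply(seq_len(n), function(i) {
      v <- base
      hit <- runif(L) < 0.08
      v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      paste(v, collapse = "")
    }, "")
    r <- tajimasD(rows)
    o <- oracleTajimaD(rows)
    if (is.na(o)) {
      expect_false(r$defined)
    } else {
      expect_true(r$defined)
      expect_equal(r$D, o, tolerance = 1e-10)
      checked <- checked + 1
    }
  }
})

test_that("Tajima's D is undefined in-band for S = 0 or n < 4", {
  expect_false(tajimasD(rep("ACGTACGTAC", 5))$defined)
  expect_false(tajimasD(c("AAAA", "AAAT", "AATA"))$defined)
})

test_that("NG86 handles the trivial code-table cases", {
  r0 <- ng86dnds("GGAGGG", "GGAGGG")
  expect_equal(r0$Nd, 0)
  expect_equal(r0$Sd, 0)
  expect_true(is.na(r0$ratio))

  r1 <- ng86dnds("GGAGGG", "GGGGGG")   # GGA->GGG is synonymous (Gly)
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$dN, 0)
  expect_equal(r1$N + r1$S, 3 * r1$codons)
})

test_that("NG86 matches the pathway-enumeration oracle on random codon pairs", {
  set.seed(5)
  nAmbiguous <- 0
  for (rep in 1:50) {
    a <- randomCodons(20)
    b <- mutateSequence(a, 0.08)
    cds <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    stops <- Biostrings::GENETIC_CODE[cds] == "*"
    if (any(stops)) {   # repair drawn stops so preconditions hold
      asp <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
      cds[stops] <- asp[stops]
      b <- paste(cds, collapse = "")
    }
    diffs <- mapply(function(x, y)
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
      substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3)), cds)
    if (any(diffs >= 2)) nAmbiguous <- nAmbiguous + 1
    r <- ng86dnds(a, b)
    o <- oracleNG86(a, b)
    expect_equal(r$N, o$N, tolerance = 1e-10)
    expect_equal(r$S, o$S, tolerance = 1e-10)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-10)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-10)
    if (!is.na(o$dN)) expect_equal(r$dN, o$dN, tolerance = 1e-10)
    if (!is.na(o$dS)) expect_equal(r$dS, o$dS, tolerance = 1e-10)
  }
  expect_gt(nAmbiguous, 5)  # the sample must exercise pathway averaging
})

test_that("NG86 is symmetric and rejects malformed input", {
  set.seed(6)
  a <- randomCodons(30)
  b <- mutateSequence(a, 0.05)
  while (any(Biostrings::GENETIC_CODE[substring(b, seq(1, nchar(b), 3),
                                                seq(3, nchar(b), 3))] == "*"))
    b <- mutateSequence(a, 0.05)
  r1 <- ng86dnds(a, b); r2 <- ng86dnds(b, a)
  expect_equal(r1$Nd, r2$Nd)
  expect_equal(r1$Sd, r2$Sd)
  expect_equal(r1$dN, r2$dN)
  expect_error(ng86dnds("ACGTA", "ACGTA"), "divisible by 3")
  expect_error(ng86dnds("ATGTAAATG", "ATGTAAATG"), "internal stop")
})

test_that("dN and dS respond monotonically to added substitutions of their class", {
  # one synonymous and one nonsynonymous ladder on a fixed backbone
  a <- paste(rep("GGATTA", 15), collapse = "")   # Gly-Leu repeats
  syn1 <- sub("GGA", "GGG", a)                    # one synonymous change
  syn2 <- sub("GGATTAGGA", "GGGTTAGGG", a)        # two
  r0 <- ng86dnds(a, a); r1 <- ng86dnds(a, syn1); r2 <- ng86dnds(a, syn2)
  expect_true(r0$dS <= r1$dS && r1$dS <= r2$dS)
  non1 <- sub("TTA", "TCA", a)                    # Leu -> Ser
  non2 <- sub("TTAGGATTA", "TCAGGATCA", a)
  n1 <- ng86dnds(a, non1); n2 <- ng86dnds(a, non2)
  expect_true(r0$dN <= n1$dN && n1$dN <= n2$dN)
})

test_that("sliding windows partition as specified and recover global values", {
  rows <- c(a = strrep("ACGT", 30), b = strrep("ACGA", 30))
  idStat <- function(m) pairwiseIdentity(paste(m[1, ], collapse = ""),
                                         paste(m[2, ], collapse = ""))
  # window = alignment length: single value equal to the global statistic
  all1 <- slidingWindow(rows, idStat, window = 120, step = 10)
  expect_equal(nrow(all1), 1L)
  expect_equal(all1$value, pairwiseIdentity(rows[1], rows[2]))
  # constant-divergence profile is flat
  prof <- slidingWindow(rows, idStat, window = 40, step = 20)
  expect_lt(stats::var(prof$value), 1e-20)
  expect_error(slidingWindow(rows, idStat, window = 40, step = 0), "step")

  # chimeric pair: identity profile steps at the junction
  set.seed(2)
  x <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  near <- mutateSequence(x, 0.02)
  far <- mutateSequence(x, 0.35)
  chim <- paste0(substr(near, 1, 300), substr(far, 301, 600))
  prof2 <- slidingWindow(c(x, chim), idStat, window = 50, step = 50)
  left <- prof2$value[prof2$end <= 300]
  right <- prof2$value[prof2$start >= 300]
  expect_gt(min(left), 0.9)
  expect_lt(max(right), 0.85)
})
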