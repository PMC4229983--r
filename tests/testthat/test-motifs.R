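test_that("direct repeats: planted pair, homopolymer masking, oracle", {
  set.seed(21)
  x <- rdna(12)
  s <- paste0(rdna(30), x, "TGA", x, rdna(30))
  h <- find_direct_repeats(s)
  # the planted pair sits at copy offset 15; chance flank matches may
  # lengthen the arm (shrinking the spacer) but never move the offset
  expect_true(any(h$start2 - h$start1 == 15L & h$arm_len >= 12L))
  # polyA floods are masked away
  expect_equal(nrow(find_direct_repeats(strrep("A", 120))), 0L)
  for (i in 1:12) {
    s <- rdna(300, gc = runif(1, 0.3, 0.6))
    got <- find_direct_repeats(s)
    exp <- oracle_direct(s)
    o1 <- got[order(got$start1, got$start2), c("start1", "start2",
                                               "arm_len", "spacer")]
    o2 <- exp[order(exp$start1, exp$start2), ]
    expect_equal(as.matrix(o1), as.matrix(o2), ignore_attr = TRUE)
  }
})

test_that("inverted repeats: planted arm, empty case, oracle", {
  h <- find_inverted_repeats("ACGTACAGGCGTACGT")
  expect_equal(nrow(h), 1L)
  expect_equal(h$arm_len, 6L)
  expect_equal(h$spacer, 4L)
  expect_equal(h$strand_relation, "revcomp")
  # no C/G and no complement pairing window
  expect_equal(nrow(find_inverted_repeats("ACACACAC",
                                          max_spacer = 0L)), 0L)
  set.seed(22)
  for (i in 1:10) {
    s <- rdna(250, gc = runif(1, 0.3, 0.6))
    got <- find_inverted_repeats(s)
    exp <- oracle_inverted(s)
    o1 <- got[order(got$start1, got$start2, got$arm_len),
              c("start1", "start2", "arm_len", "spacer")]
    o2 <- exp[order(exp$start1, exp$start2, exp$arm_len), ]
    expect_equal(as.matrix(o1), as.matrix(o2), ignore_attr = TRUE)
  }
})

test_that("raising thresholds never adds repeat hits", {
  set.seed(23)
  s <- paste0(rdna(80), substr(s0 <- rdna(20), 1, 20), "ACG", s0, rdna(80))
  lo <- find_direct_repeats(s, min_arm = 8L)
  hi <- find_direct_repeats(s, min_arm = 14L)
  expect_lte(nrow(hi), nrow(lo))
  expect_true(all(hi$arm_len >= 14L))
})

test_that("self-alignment finds large planted repeats at stated identity", {
  set.seed(24)
  base <- rdna(6000, 0.45)
  arm <- rdna(244)
  a2 <- strsplit(arm, "")[[1]]
  for (i in sample(244, 12)) {
    a2[i] <- sample(setdiff(c("A", "C", "G", "T"), a2[i]), 1)
  }
  w <- paste0(substr(base, 1, 1000), arm, substr(base, 1245, 3000),
              paste(a2, collapse = ""), substr(base, 3245, 6000))
  h <- self_align_repeats(w, min_len = 151L, min_identity = 87)
  expect_true(nrow(h) >= 1L)
  expect_true(any(abs(h$identity - 95.1) < 2 & h$arm_len >= 230L &
                    h$strand_relation == "same"))
  # windows without large duplications are empty
  expect_equal(nrow(self_align_repeats(rdna(5000, 0.45),
                                       min_len = 151L)), 0L)
  # 1 kb inverted pair at 99% identity in a 20 kb window
  base <- rdna(20000, 0.45)
  arm <- rdna(1000)
  a2 <- strsplit(arm, "")[[1]]
  for (i in sample(1000, 10)) {
    a2[i] <- sample(setdiff(c("A", "C", "G", "T"), a2[i]), 1)
  }
  w <- paste0(substr(base, 1, 5000), arm, substr(base, 6001, 12000),
              revcomp(paste(a2, collapse = "")), substr(base, 13001, 20000))
  h <- self_align_repeats(w, min_len = 800L, min_identity = 87)
  inv <- h[h$strand_relation == "revcomp", ]
  expect_true(nrow(inv) >= 1L)
  expect_true(any(inv$arm_len >= 950L & inv$identity >= 98))
})

test_that("L1 endonuclease site scan matches the naive 5-mer scan", {
  h <- scan_l1_en_sites("GGCTTTAGG")
  expect_equal(nrow(h), 1L)
  expect_equal(h$motif, "CTTT/A")
  expect_equal(h$strand, "+")
  # cut between the 4th and 5th motif base: between positions 6 and 7
  expect_equal(h$cleavage_pos, 6L)
  expect_equal(nrow(scan_l1_en_sites("GGGGGG")), 0L)
  set.seed(25)
  s <- rdna(10000, 0.35)
  got <- scan_l1_en_sites(s)
  # naive: test every 5-mer on both strands
  exp_plus <- exp_minus <- 0L
  for (p in 1:(nchar(s) - 4L)) {
    w <- substr(s, p, p + 4L)
    if (w %in% c("TTTTA", "CTTTA")) exp_plus <- exp_plus + 1L
    if (w %in% c("TAAAA", "TAAAG")) exp_minus <- exp_minus + 1L
  }
  expect_equal(sum(got$strand == "+"), exp_plus)
  expect_equal(sum(got$strand == "-"), exp_minus)
  # strand symmetry: scanning the revcomp mirrors the hit set
  expect_equal(nrow(scan_l1_en_sites(revcomp(s))), nrow(got))
})

test_that("homopolymer tracts are maximal runs above the threshold", {
  s <- paste0("ACG", strrep("T", 40), "GAC", strrep("T", 9), "GG")
  h <- find_homopolymer_tracts(s, "T", 10L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$length, 40L)
  expect_equal(h$start, 4L)
  expect_equal(nrow(find_homopolymer_tracts(strrep("T", 9), "T", 10L)), 0L)
  set.seed(26)
  s <- rdna(5000, 0.3)
  got <- find_homopolymer_tracts(s, "A", 5L)
  m <- gregexpr("A{5,}", s)[[1]]
  if (m[1] == -1) {
    expect_equal(nrow(got), 0L)
  } else {
    expect_equal(got$start, as.integer(m))
    expect_equal(got$length, attr(m, "match.length"))
  }
})

test_that("gc content matches direct counting, N excluded", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_true(is.nan(gc_content("NNNN")))
  set.seed(27)
  s <- rdna(2000, 0.6)
  x <- strsplit(s, "")[[1]]
  expect_equal(gc_content(s), sum(x %in% c("G", "C")) / length(x))
  w <- gc_content(s, window = 500L)
  expect_length(w, 4L)
  expect_equal(w[1], gc_content(substr(s, 1, 500)))
})

test_that("pairwise identity agrees with the affine DP oracle", {
  p <- pairwise_identity(strrep("ACGT", 25), strrep("ACGT", 25))
  expect_equal(p$identity, 100)
  expect_equal(p$alignment_len, 100L)
  a <- rdna(30)
  p <- pairwise_identity(a, revcomp(a), orientation = "both")
  expect_equal(p$identity, 100)
  expect_equal(p$strand, "-")
  set.seed(28)
  for (i in 1:20) {
    a <- rdna(sample(10:50, 1)); b <- rdna(sample(10:50, 1))
    got <- pairwise_identity(a, b)
    expect_equal(got$score, oracle_nw_affine(a, b), tolerance = 1e-9)
  }
})
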