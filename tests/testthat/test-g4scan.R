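test_that("base_scores applies the run-length scoring table", {
  expect_equal(base_scores("AATT"), c(0, 0, 0, 0))
  expect_equal(base_scores("GGGT"), c(3, 3, 3, 0))
  expect_equal(base_scores("CCCCC"), rep(-4, 5))   # run of 5 capped at 4
  expect_equal(base_scores("GNTC"), c(1, 0, 0, -1))
  expect_equal(base_scores(""), integer(0))
})

test_that("detect_motifs finds, merges and scores windowed hits", {
  # zero case
  expect_equal(nrow(detect_motifs(GenomeRecord("a", strrep("A", 25)))), 0L)
  # hand-computed: 25-nt G-tract pattern, mean = (6*9 + 1)/25 = 2.2
  m <- detect_motifs(GenomeRecord("g", "GGGTGGGTGGGTGGGTGGGTGGGTG"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$score, 2.2)
  expect_equal(c(m$start, m$end), c(0L, 25L))
  expect_equal(m$strand, "+")
  # forced by the scoring table: poly-C scores -4
  mc <- detect_motifs(GenomeRecord("c", strrep("C", 25)))
  expect_equal(mc$score, -4)
  expect_equal(mc$strand, "-")
  # shorter than the window: warning and empty result
  expect_warning(m0 <- detect_motifs(GenomeRecord("s", "ACGT")), "shorter")
  expect_equal(nrow(m0), 0L)
})

test_that("motifs embedded in neutral background are localized correctly", {
  set.seed(7)
  pad <- strrep("AT", 200)
  seq <- paste0(pad, strrep("GGGT", 7), pad, strrep("CCCT", 7), pad)
  m <- detect_motifs(GenomeRecord("g", seq))
  expect_equal(nrow(m), 2L)
  expect_equal(m$strand, c("+", "-"))
  # regions must contain the planted templates
  expect_true(m$start[1] <= 400 && m$end[1] >= 428)
  expect_true(m$start[2] <= 828 && m$end[2] >= 856)
})

test_that("a sign change terminates a merged region", {
  seq <- paste0(strrep("G", 30), strrep("C", 30))
  m <- detect_motifs(GenomeRecord("g", seq))
  expect_equal(nrow(m), 2L)
  expect_true(m$score[1] > 0 && m$score[2] < 0)
})

test_that("circular scanning wraps motifs across the origin", {
  set.seed(8)
  # split a planted template across the origin: 14 nt at the end, 14 at the start
  tmpl <- strrep("GGGT", 7)
  body <- strrep("AT", 300)
  seq <- paste0(substr(tmpl, 15, 28), body, substr(tmpl, 1, 14))
  g <- GenomeRecord("c", seq, circular = TRUE)
  expect_equal(nrow(detect_motifs(g, scan_params(circular = FALSE))), 0L)
  mw <- detect_motifs(g, scan_params(circular = TRUE))
  expect_equal(nrow(mw), 1L)
  expect_true(mw$end > g$length)  # wrapped region
  expect_equal(mw$score, 2.28)
})

test_that("strand antisymmetry: revcomp mirrors scores and motifs", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_seq(500, gc = 0.5)
    expect_equal(base_scores(revcomp(s)), -rev(base_scores(s)))
    m <- detect_motifs(GenomeRecord("f", s), scan_params(s = 1.2))
    mr <- detect_motifs(GenomeRecord("r", revcomp(s)), scan_params(s = 1.2))
    expect_equal(nrow(m), nrow(mr))
    if (nrow(m)) {
      expect_equal(sort(500 - m$end), sort(mr$start))
      expect_equal(sort(-m$score), sort(mr$score))
    }
  }
})

test_that("lowering the threshold never removes a motif region", {
  set.seed(12)
  for (i in 1:10) {
    s <- random_seq(2000, gc = 0.6)
    strict <- detect_motifs(GenomeRecord("g", s), scan_params(s = 1.7))
    relaxed <- detect_motifs(GenomeRecord("g", s), scan_params(s = 1.2))
    # every strict region is contained in some relaxed region
    for (j in seq_len(nrow(strict))) {
      expect_true(any(relaxed$start <= strict$start[j] &
                      relaxed$end >= strict$end[j]))
    }
  }
})

test_that("deduplication implements the strict >50% overlap rule", {
  m <- data.frame(start = c(0L, 40L), end = c(100L, 140L),
                  score = c(2, 2), peak_abs = c(2, 2),
                  length = c(100L, 100L), strand = "+")
  kept <- deduplicate_motifs(m)
  expect_equal(nrow(kept), 1L)       # overlap 60 > 50: eliminated
  expect_equal(kept$start, 0L)       # tie broken by smaller start
  m$start[2] <- 50L; m$end[2] <- 150L
  expect_equal(nrow(deduplicate_motifs(m)), 2L)  # overlap exactly 50: kept
  expect_equal(nrow(deduplicate_motifs(m[0, ])), 0L)
  # higher |score| wins regardless of position
  m2 <- data.frame(start = c(0L, 40L), end = c(100L, 140L),
                   score = c(1.8, -3), peak_abs = c(1.8, 3),
                   length = c(100L, 100L), strand = c("+", "-"))
  expect_equal(deduplicate_motifs(m2)$start, 40L)
  # position priority is available
  expect_equal(deduplicate_motifs(m2, order = "position")$start, 0L)
})

test_that("deduplication is idempotent on random motif sets", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    st <- sort(sample(0:2000, n))
    m <- data.frame(start = st, end = st + sample(25:120, n, replace = TRUE),
                    score = round(runif(n, 1.2, 4), 3))
    m$peak_abs <- abs(m$score); m$length <- m$end - m$start; m$strand <- "+"
    d1 <- deduplicate_motifs(m)
    d2 <- deduplicate_motifs(d1)
    expect_equal(d1, d2)
  }
})

test_that("region calls match the brute-force window scanner", {
  set.seed(14)
  for (i in 1:15) {
    s <- random_seq(2000, gc = 0.55)
    fast <- detect_motifs(GenomeRecord("g", s))
    slow <- brute_g4_regions(s)
    expect_equal(nrow(fast), nrow(slow))
    expect_equal(fast$start, slow$start)
    expect_equal(fast$end, slow$end)
  }
})

test_that("motif density is count-per-kb", {
  none <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  expect_equal(motif_density(none, 10000), 0)
  expect_equal(motif_density(5L, 10000), 0.5)
  expect_equal(motif_density(8L, 85779), 8 * 1000 / 85779, tolerance = 1e-12)
  expect_error(motif_density(1L, 0), "positive")
})
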