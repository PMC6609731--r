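make_genome <- function(n, seed = 1, gc = 0.3) {
  set.seed(seed)
  GenomeRecord("g", random_seq(n, gc), circular = TRUE)
}

feat_row <- function(kind, name, gene, start, end) {
  data.frame(kind = kind, name = name, gene = gene, start = start, end = end,
             strand = "+", group = NA_character_)
}

# random probability vector (uniform Dirichlet)
rand_prob_vec <- function(k) {
  x <- rgamma(k, shape = 1)
  x / sum(x)
}

test_that("compartment partition tiles the genome with exon priority", {
  g <- make_genome(1000)
  fs <- FeatureSet("g", feat_row("exon", "cox1.e1", "cox1", 100L, 400L), 1000L)
  p <- partition_compartments(g, fs)
  expect_equal(unname(p$lengths), c(300, 0, 700))
  expect_equal(sum(p$lengths), 1000)
  # overlapping exons are unioned
  fs2 <- FeatureSet("g", rbind(feat_row("exon", "cox1.e1", "cox1", 0L, 100L),
                               feat_row("exon", "cox2.e1", "cox2", 50L, 150L)), 1000L)
  expect_equal(unname(partition_compartments(g, fs2)$lengths[1]), 150)
  # no conserved genes: all intergenic
  fs3 <- FeatureSet("g", feat_row("gene", "orf1", NA_character_, 0L, 500L), 1000L)
  expect_equal(unname(partition_compartments(g, fs3)$lengths), c(0, 0, 1000))
  # a base in an exon of one gene and an intron of another is an exon
  fs4 <- FeatureSet("g", rbind(feat_row("exon", "cox1.e1", "cox1", 0L, 100L),
                               feat_row("intron", "cob.i1", "cob", 50L, 200L),
                               feat_row("exon", "cob.e1", "cob", 200L, 300L)), 1000L)
  p4 <- partition_compartments(g, fs4)
  expect_equal(unname(p4$lengths), c(200, 100, 700))
})

test_that("motifs are assigned by midpoint base", {
  g <- make_genome(1000)
  fs <- FeatureSet("g", feat_row("exon", "cox1.e1", "cox1", 100L, 400L), 1000L)
  p <- partition_compartments(g, fs)
  m <- data.frame(start = c(150L, 390L, 600L), end = c(175L, 420L, 625L),
                  score = 2)
  obs <- assign_motifs(m, p)
  # motif 2 straddles the boundary; midpoint 405 is intergenic
  expect_equal(unname(obs), c(1L, 0L, 2L))
  expect_equal(unname(assign_motifs(m[0, ], p)), c(0L, 0L, 0L))
})

test_that("expected counts are proportional to compartment lengths", {
  g <- make_genome(1000)
  fs <- FeatureSet("g", rbind(feat_row("exon", "cox1.e1", "cox1", 0L, 500L),
                              feat_row("intron", "cox1.i1", "cox1", 500L, 800L)), 1000L)
  p <- partition_compartments(g, fs)
  e <- expected_counts(10L, p)
  expect_equal(unname(e), c(5, 3, 2))
  expect_equal(sum(e), 10)
  expect_equal(unname(expected_counts(0L, p)), c(0, 0, 0))
})

test_that("chisq_enrichment computes the goodness-of-fit statistic", {
  r <- chisq_enrichment(c(10, 10, 10), c(10, 10, 10))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  r2 <- chisq_enrichment(c(30, 0, 0), c(10, 10, 10))
  expect_equal(r2$chi2, 60)
  expect_equal(r2$df, 2L)
  # small-count regime warns instead of switching tests
  expect_warning(chisq_enrichment(c(4, 0), c(2, 2)), "approximation")
  expect_error(chisq_enrichment(c(0, 0), c(0, 0)), "nothing to test")
  expect_error(chisq_enrichment(c(5, 5), c(10, 10)), "must equal")
  expect_error(chisq_enrichment(c(5, 5, 0), c(10, 0, 0)), "expected count 0")
  # compartments with expected == observed == 0 are dropped from df
  r3 <- suppressWarnings(chisq_enrichment(c(6, 4, 0), c(5, 5, 0)))
  expect_equal(r3$df, 1L)
})

test_that("chisq_enrichment matches independent computations on random tables", {
  set.seed(99)
  for (i in 1:300) {
    k <- sample(2:5, 1)
    pvec <- rand_prob_vec(k)
    n <- sample(20:200, 1)
    obs <- as.vector(rmultinom(1, n, pvec))
    exp <- n * pvec
    if (any(exp == 0)) next
    mine <- suppressWarnings(chisq_enrichment(obs, exp))
    slow <- textbook_chisq(obs, exp)
    expect_equal(mine$chi2, slow$chi2, tolerance = 1e-12)
    expect_equal(mine$p, slow$p, tolerance = 1e-12)
    ref <- suppressWarnings(stats::chisq.test(obs, p = pvec))
    expect_lt(abs(mine$chi2 - unname(ref$statistic)), 1e-9)
    expect_lt(abs(mine$p - ref$p.value), 1e-9)
  }
})

test_that("exon fractions inside IR and SC follow planted coverage", {
  # trivial: IR fully exonic, SC fully intergenic
  g <- make_genome(1000)
  ir <- ir_annotation(0L, 200L, 500L, 700L, 1, 1000L)
  fs <- FeatureSet("g", rbind(feat_row("exon", "cox1.e1", "cox1", 0L, 200L),
                              feat_row("exon", "cox1.e2", "cox1", 500L, 700L)), 1000L)
  p <- partition_compartments(g, fs)
  ef <- exon_fraction(p, ir)
  expect_equal(unname(ef), c(0, 100))
  # generator truth: compare against per-base label arithmetic
  sp <- synthetic_spec(genome_length = 60000, ir_arm_length = 12000,
                       g4_rate_per_kb = list(IR = 0.3, SC = 0.1))
  tr <- generate_genome(sp, seed = 105)
  p2 <- partition_compartments(tr$genome, tr$features)
  ef2 <- exon_fraction(p2, tr$ir)
  reg <- ir_region_labels(tr$ir)
  exonic <- p2$labels == "exon"
  expect_equal(unname(ef2["IR"]),
               100 * sum(exonic & reg == "IR_copy1") / sum(reg == "IR_copy1"))
  expect_gt(ef2["IR"], 0)
  expect_gt(ef2["SC"], 0)
})

test_that("IR/SC density counts arm-1 motifs over one arm length", {
  ir <- ir_annotation(0L, 20000L, 30000L, 50000L, 1, 80000L)
  m <- data.frame(start = c(seq(100, 19000, length.out = 10), 60000, 61000,
                            62000, 63000, 64000),
                  end = c(seq(100, 19000, length.out = 10), 60000, 61000,
                          62000, 63000, 64000) + 28, score = 2.2)
  d <- ir_sc_density(m, ir)
  expect_equal(unname(d["density_IR"]), 10 * 1000 / 20000)
  expect_equal(unname(d["density_SC"]), 5 * 1000 / 40000)
  expect_equal(unname(ir_sc_density(m[0, ], ir)), c(0, 0))
})

test_that("density is invariant to arm labeling for IR-symmetric motif sets", {
  sp <- synthetic_spec(genome_length = 60000, ir_arm_length = 12000,
                       g4_rate_per_kb = list(IR = 1.0, SC = 0.4))
  tr <- generate_genome(sp, seed = 115)
  m <- scan_g4(tr$genome)
  ir <- tr$ir
  swapped <- ir_annotation(ir$arm2_start, ir$arm2_end,
                           ir$arm1_start + ir$genome_length,
                           ir$arm1_end + ir$genome_length,
                           ir$identity, ir$genome_length)
  d1 <- ir_sc_density(m, ir)
  d2 <- ir_sc_density(m, swapped)
  expect_equal(d1[["density_IR"]], d2[["density_IR"]])
  expect_equal(d1[["density_SC"]], d2[["density_SC"]])
  # both-copies counting is the same density for symmetric motifs
  d3 <- ir_sc_density(m, ir, ir_copies = 2)
  expect_equal(d1[["density_IR"]], d3[["density_IR"]])
})
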