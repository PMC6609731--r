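test_that("GenomeRecord normalizes sequences and validates the alphabet", {
  g <- GenomeRecord("x", "acgt")
  expect_equal(g$sequence, "ACGT")
  expect_equal(g$length, 4L)
  expect_warning(g2 <- GenomeRecord("x", "acgR"), "mapped to N")
  expect_equal(g2$sequence, "ACGN")
  expect_error(GenomeRecord("x", ""), "empty")
  expect_error(GenomeRecord("x", "ACGJ"), "non-IUPAC")
})

test_that("read_genome reads FASTA, rejects multi-record files", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">x some description", "ACGT"), fa)
  g <- read_genome(fa, "fasta")
  expect_equal(g$id, "x")
  expect_equal(g$length, 4L)
  expect_false(g$circular)
  writeLines(c(">a", "ACGT", ">b", "GGCC"), fa)
  expect_error(read_genome(fa, "fasta"), "exactly one")
})

test_that("GenBank flat files parse: LOCUS topology, sequence, length", {
  set.seed(42)
  seq <- random_seq(523)
  gb <- tempfile(fileext = ".gb")
  write_mini_genbank(gb, seq, id = "SYN77", circular = TRUE)
  g <- read_genome(gb, "genbank")
  expect_equal(g$id, "SYN77")
  expect_equal(g$length, 523L)
  expect_true(g$circular)
  expect_equal(g$sequence, seq)
})

test_that("GenBank join() CDS yields exons and introns with shared parent", {
  set.seed(1)
  seq <- random_seq(200)
  gb <- tempfile(fileext = ".gb")
  write_mini_genbank(gb, seq, features = c(
    "     gene            1..90",
    '                     /gene="cox1"',
    "     CDS             join(1..30,61..90)",
    '                     /gene="cox1"'))
  fs <- read_features(gb, "genbank")
  exons <- fs$features[fs$features$kind == "exon", ]
  introns <- fs$features[fs$features$kind == "intron", ]
  expect_equal(nrow(exons), 2L)
  expect_equal(nrow(introns), 1L)
  expect_equal(c(introns$start, introns$end), c(30L, 60L))
  expect_equal(exons$start, c(0L, 60L))
  expect_equal(exons$end, c(30L, 90L))
  expect_true(all(c(exons$gene, introns$gene) == "cox1"))
  # exon + intron lengths tile the CDS span
  expect_equal(sum(exons$end - exons$start) + sum(introns$end - introns$start),
               max(exons$end) - min(exons$start))
})

test_that("GenBank complement(join()) flips strand", {
  set.seed(2)
  gb <- tempfile(fileext = ".gb")
  write_mini_genbank(gb, random_seq(200), features = c(
    "     CDS             complement(join(11..40,71..100))",
    '                     /gene="cob"'))
  fs <- read_features(gb, "genbank")
  expect_true(all(fs$features$strand == "-"))
  expect_equal(sum(fs$features$kind == "exon"), 2L)
})

test_that("GFF3 coordinates convert to 0-based half-open and round-trip", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "g1\ttest\texon\t1\t10\t.\t+\t.\tID=e1;Name=cox1.e1;gene=cox1"),
             gff)
  fs <- read_features(gff, "gff3")
  expect_equal(fs$features$start, 0L)
  expect_equal(fs$features$end, 10L)
  # empty GFF3
  writeLines("##gff-version 3", gff)
  expect_equal(nrow(read_features(gff, "gff3")$features), 0L)
  # round trip through the package writer
  feats <- data.frame(
    kind = c("gene", "exon", "intron", "rRNA"),
    name = c("cox1", "cox1.e1", "cox1.i1", "rns"),
    gene = c(NA, "cox1", "cox1", NA),
    start = c(10L, 10L, 40L, 200L), end = c(100L, 40L, 60L, 320L),
    strand = c("+", "+", "+", "-"), group = NA_character_)
  fs0 <- FeatureSet("g1", feats, genome_length = 1000L)
  out <- tempfile(fileext = ".gff3")
  write_gff3(fs0, out)
  fs1 <- read_features(out, "gff3")
  got <- fs1$features[order(fs1$features$start, fs1$features$kind), ]
  want <- fs0$features[order(fs0$features$start, fs0$features$kind), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[, c("kind", "name", "gene", "start", "end", "strand")],
               want[, c("kind", "name", "gene", "start", "end", "strand")])
})

test_that("wrap-around features split into grouped halves on circular genomes", {
  set.seed(3)
  g <- GenomeRecord("c", random_seq(100), circular = TRUE)
  gb <- tempfile(fileext = ".gb")
  write_mini_genbank(gb, g$sequence, features = c(
    "     gene            91..110",
    '                     /gene="orfX"'))
  fs <- read_features(gb, "genbank", genome = g)
  orf <- fs$features[!is.na(fs$features$group), ]
  expect_equal(nrow(orf), 2L)
  expect_setequal(orf$start, c(90L, 0L))
  expect_setequal(orf$end, c(100L, 10L))
  expect_equal(length(unique(orf$group)), 1L)
  # same annotation on a linear genome is an error
  glin <- GenomeRecord("l", g$sequence, circular = FALSE)
  expect_error(read_features(gb, "genbank", genome = glin), "linear")
})

test_that("conserved_exon_set filters by gene list with aliases", {
  feats <- data.frame(
    kind = c("exon", "exon", "exon", "gene", "rRNA", "gene"),
    name = c("cox1.e1", "orf255.e1", "CytB.e1", "CytB", "rnl", "nad4L"),
    gene = c("cox1", "orf255", "CytB", NA, NA, NA),
    start = c(0L, 100L, 200L, 200L, 300L, 500L),
    end = c(50L, 150L, 260L, 260L, 400L, 600L),
    strand = "+", group = NA_character_)
  fs <- FeatureSet("g", feats, 1000L)
  ces <- conserved_exon_set(fs)
  expect_setequal(ces$features$gene, c("cox1", "cob", "rnl", "nad4l"))
  expect_false("orf255" %in% ces$features$gene)
  comp <- attr(ces, "completeness")
  expect_true(all(c("cox1", "cob", "rnl", "nad4l") %in% comp$found))
  expect_true("rps3" %in% comp$missing)
  # nad4L exclusion is configurable
  ces2 <- conserved_exon_set(fs, include_nad4L = FALSE)
  expect_false("nad4l" %in% ces2$features$gene)
  # empty input -> empty output
  expect_equal(nrow(conserved_exon_set(FeatureSet("g"))$features), 0L)
})

test_that("write_bed emits BED6 with x1000 truncated scores and a sidecar TSV", {
  motifs <- data.frame(start = 10L, end = 35L, score = 2.2, peak_abs = 2.2,
                       length = 25L, strand = "+")
  bed <- tempfile(fileext = ".bed")
  write_bed(motifs, bed, chrom = "g1")
  lines <- readLines(bed)
  expect_match(lines[1], "^track")
  expect_equal(lines[2], "g1\t10\t35\tG4_1\t2200\t+")
  tsv <- read.delim(paste0(sub("\\.bed$", "", bed), ".tsv"))
  expect_equal(tsv$score, 2.2)
  # empty input: header only
  write_bed(motifs[0, ], bed, chrom = "g1")
  expect_equal(length(readLines(bed)), 1L)
  expect_match(readLines(bed), "^track")
  # minus-strand motif
  m2 <- data.frame(start = 0L, end = 25L, score = -4, peak_abs = 4,
                   length = 25L, strand = "-")
  write_bed(m2, bed, chrom = "g1")
  expect_equal(strsplit(readLines(bed)[2], "\t")[[1]][6], "-")
})
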