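#' Feature sets
#'
#' A `FeatureSet` holds typed, stranded genomic intervals on one genome.
#' Coordinates are 0-based half-open everywhere inside the package;
#' conversion to/from the 1-based inclusive convention of GFF3 and GenBank
#' happens only at the I/O boundary.
#'
#' @param genome_id Identifier of the genome the features live on.
#' @param features A data.frame with columns `kind` (one of gene, exon,
#'   intron, rRNA, other), `name`, `gene` (parent gene name, NA where not
#'   applicable), `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`)
#'   and `group` (shared id linking the two halves of a split wrap-around
#'   feature, NA otherwise).
#' @param genome_length Optional genome length (bp) for bounds checking.
#' @return An object of class `FeatureSet`.
#' @export
FeatureSet <- function(genome_id, features = empty_features(),
                       genome_length = NA_integer_) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  miss <- setdiff(c("kind", "name", "gene", "start", "end", "strand", "group"),
                  names(features))
  for (m in miss) features[[m]] <- if (m %in% c("start", "end")) integer(0) else NA
  features <- features[, c("kind", "name", "gene", "start", "end", "strand", "group")]
  if (nrow(features)) {
    stopifnot(all(features$start >= 0), all(features$end > features$start))
    if (!is.na(genome_length) && any(features$end > genome_length))
      stop("feature extends beyond genome length")
  }
  structure(list(genome_id = genome_id, features = features,
                 genome_length = genome_length),
            class = "FeatureSet")
}

empty_features <- function() {
  data.frame(kind = character(0), name = character(0), gene = character(0),
              start = integer(0), end = integer(0), strand = character(0),
              group = character(0), stringsAsFactors = FALSE)
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat(sprintf("FeatureSet on '%s': %d features\n", x$genome_id, nrow(x$features)))
  if (nrow(x$features)) print(table(x$features$kind))
  invisible(x)
}

#' Read features from GFF3 or a GenBank flat file
#'
#' GFF3 parsing goes through [rtracklayer::import()]. GenBank feature tables
#' are parsed directly; a CDS with a multi-segment `join()` location yields
#' one exon per segment and one intron per inter-segment gap, all carrying
#' the parent gene name. Features running past the end of a circular genome
#' are split into two features sharing a `group` id; on a linear genome this
#' is an error.
#'
#' @param path File path.
#' @param format `"gff3"` or `"genbank"`.
#' @param genome Optional [GenomeRecord] for bounds checking / wrap splitting.
#' @return A [FeatureSet].
#' @export
read_features <- function(path, format = c("gff3", "genbank"), genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gff3") fs <- read_features_gff3(path) else fs <- read_features_genbank(path)
  if (!is.null(genome)) {
    fs$genome_length <- genome$length
    fs <- split_wraparound(fs, genome)
  }
  fs
}

read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L)
    return(FeatureSet(genome_id = NA_character_))
  md <- S4Vectors::mcols(gr)
  kind <- as.character(md$type)
  kind[!kind %in% c("gene", "exon", "intron", "rRNA")] <- "other"
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else rep(NA_character_, length(gr))
  if ("ID" %in% names(md)) nm <- ifelse(is.na(nm), as.character(md$ID), nm)
  gene <- if ("gene" %in% names(md)) as.character(md$gene) else rep(NA_character_, length(gr))
  grp <- if ("group" %in% names(md)) as.character(md$group) else rep(NA_character_, length(gr))
  feats <- data.frame(
    kind = kind, name = nm, gene = gene,
    start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
    group = grp, stringsAsFactors = FALSE)
  FeatureSet(genome_id = as.character(GenomeInfoDb::seqnames(gr))[1], features = feats)
}

read_features_genbank <- function(path) {
  gb <- parse_genbank(path)
  rows <- list()
  gid <- gb$id
  for (f in gb$features %||% list()) {
    if (f$key %in% c("source")) next
    loc <- parse_gb_location(f$location)
    segs <- loc$segments
    nm <- if (!is.na(f$gene)) f$gene else f$product
    if (f$key == "CDS") {
      segs <- segs[order(segs[, 1]), , drop = FALSE]
      for (i in seq_len(nrow(segs)))
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "exon", name = paste0(nm, ".e", i), gene = nm,
          start = segs[i, 1] - 1L, end = segs[i, 2], strand = loc$strand,
          group = NA_character_, stringsAsFactors = FALSE)
      if (nrow(segs) > 1L)
        for (i in seq_len(nrow(segs) - 1L))
          rows[[length(rows) + 1L]] <- data.frame(
            kind = "intron", name = paste0(nm, ".i", i), gene = nm,
            start = segs[i, 2], end = segs[i + 1L, 1] - 1L, strand = loc$strand,
            group = NA_character_, stringsAsFactors = FALSE)
    } else {
      kind <- switch(f$key, gene = "gene", rRNA = "rRNA", exon = "exon",
                     intron = "intron", "other")
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, name = nm, gene = if (kind %in% c("exon", "intron")) nm else NA_character_,
        start = min(segs[, 1]) - 1L, end = max(segs[, 2]), strand = loc$strand,
        group = NA_character_, stringsAsFactors = FALSE)
    }
  }
  feats <- if (length(rows)) do.call(rbind, rows) else empty_features()
  FeatureSet(genome_id = gid, features = feats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split features running past the origin of a circular genome.
split_wraparound <- function(fs, genome) {
  f <- fs$features
  over <- which(f$end > genome$length)
  if (!length(over)) return(fs)
  if (!genome$circular)
    stop("feature extends beyond the end of a linear genome")
  extra <- f[over, , drop = FALSE]
  for (i in seq_along(over)) {
    gid <- paste0("wrap_", f$name[over[i]], "_", i)
    extra$start[i] <- 0L
    extra$end[i] <- f$end[over[i]] - genome$length
    extra$group[i] <- gid
    f$end[over[i]] <- genome$length
    f$group[over[i]] <- gid
  }
  fs$features <- rbind(f, extra)
  fs
}

#' Conserved gene set and aliases
#'
#' The conserved mitochondrial gene set used throughout the compartment
#' analysis: the core protein-coding genes (cox1-3, cob, nad1-6, atp6, atp8,
#' atp9, rps3, optionally nad4L) plus the two ribosomal RNA subunits (rns,
#' rnl), whose full spans are treated as exonic because they produce large
#' functional transcripts.
#'
#' @param include_nad4L Keep nad4L in the set (default TRUE).
#' @return Character vector of canonical protein-coding gene names.
#' @export
conserved_gene_names <- function(include_nad4L = TRUE) {
  g <- c("cox1", "cox2", "cox3", paste0("nad", 1:6), "atp6", "atp8", "atp9",
         "cob", "rps3")
  if (include_nad4L) g <- c(g, "nad4l")
  g
}

#' @rdname conserved_gene_names
#' @return `default_gene_aliases()`: named character vector mapping common
#'   alternative spellings (case-insensitive, punctuation-stripped) to
#'   canonical names.
#' @export
default_gene_aliases <- function() {
  c(cytb = "cob", cytochromeb = "cob", cob1 = "cob",
    coi = "cox1", coii = "cox2", coiii = "cox3",
    co1 = "cox1", co2 = "cox2", co3 = "cox3",
    cytochromeoxidase1 = "cox1", cytochromeoxidase2 = "cox2",
    cytochromeoxidase3 = "cox3",
    nd1 = "nad1", nd2 = "nad2", nd3 = "nad3", nd4 = "nad4", nd5 = "nad5",
    nd6 = "nad6", nd4l = "nad4l",
    rrnl = "rnl", rrns = "rns", lsu = "rnl", ssu = "rns",
    rrnL = "rnl", rrnS = "rns")
}

canonical_gene <- function(x, aliases = default_gene_aliases()) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  names(aliases) <- gsub("[^a-z0-9]", "", tolower(names(aliases)))
  out <- unname(aliases[key])
  ifelse(is.na(out), key, out)
}

#' Extract the conserved exonic spans from an annotation
#'
#' Keeps the exon features of the conserved protein-coding genes and the full
#' spans of the two rRNA subunits (`rns`, `rnl`); these spans define the
#' "exon" compartment of the enrichment analysis. A conserved gene annotated
#' only as a `gene` feature (no exon children) contributes its full span as a
#' single exon. A completeness report listing which conserved genes were
#' found is attached as attribute `"completeness"`.
#'
#' @param features A [FeatureSet].
#' @param include_nad4L Include nad4L in the conserved set (default TRUE).
#' @param aliases Alias table, as from [default_gene_aliases()].
#' @return A [FeatureSet] of exonic spans (kind `"exon"`).
#' @export
conserved_exon_set <- function(features, include_nad4L = TRUE,
                               aliases = default_gene_aliases()) {
  f <- features$features
  prot <- conserved_gene_names(include_nad4L)
  rrna <- c("rns", "rnl")
  out <- empty_features()
  if (nrow(f)) {
    cg <- canonical_gene(ifelse(is.na(f$gene), f$name, f$gene), aliases)
    keep_exon <- f$kind == "exon" & cg %in% prot
    # conserved genes annotated without exon children: full span is the exon
    exon_genes <- unique(cg[keep_exon])
    keep_gene <- f$kind == "gene" & cg %in% prot & !(cg %in% exon_genes)
    keep_rrna <- f$kind %in% c("rRNA", "gene") & cg %in% rrna
    out <- f[keep_exon | keep_gene | keep_rrna, , drop = FALSE]
    if (nrow(out)) {
      out$gene <- canonical_gene(ifelse(is.na(out$gene), out$name, out$gene), aliases)
      out$kind <- "exon"
    }
    found <- unique(cg[keep_exon | keep_gene | keep_rrna])
  } else found <- character(0)
  res <- FeatureSet(features$genome_id, out, features$genome_length)
  attr(res, "completeness") <- list(
    found = intersect(c(prot, rrna), found),
    missing = setdiff(c(prot, rrna), found))
  res
}

#' Write a FeatureSet as GFF3
#'
#' Writes the fixed GFF3 dialect the package itself reads back (attributes
#' `ID`, `Name`, `gene`, `group`); coordinates are converted to 1-based
#' inclusive.
#'
#' @param features A [FeatureSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  f <- features$features
  gr <- GenomicRanges::GRanges(
    seqnames = rep(features$genome_id %||% "genome", nrow(f)),
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$kind
  S4Vectors::mcols(gr)$ID <- paste0("feat", seq_len(nrow(f)))
  S4Vectors::mcols(gr)$Name <- f$name
  S4Vectors::mcols(gr)$gene <- f$gene
  S4Vectors::mcols(gr)$group <- f$group
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write scored motif intervals as BED6 (+ full-precision sidecar TSV)
#'
#' The BED score column carries the motif score scaled by 1000 and truncated
#' to integer; full precision is preserved in a sidecar TSV next to `path`.
#' An empty input produces a file holding only the track header.
#'
#' @param motifs A data.frame with columns `start`, `end`, `score` (signed)
#'   and optionally `strand` (derived from the score sign if absent), e.g.
#'   from [detect_motifs()].
#' @param path Output BED path.
#' @param chrom Chromosome/genome name for column 1.
#' @param tsv_path Sidecar TSV path (default: `path` with extension `.tsv`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(motifs, path, chrom = "genome",
                      tsv_path = paste0(sub("\\.bed$", "", path), ".tsv")) {
  header <- sprintf('track name="g4_motifs" description="G4 motif scan of %s"', chrom)
  n <- nrow(motifs)
  strand <- if (n && "strand" %in% names(motifs)) motifs$strand
            else if (n) ifelse(motifs$score >= 0, "+", "-") else character(0)
  lines <- header
  if (n) {
    lines <- c(lines, sprintf("%s\t%d\t%d\tG4_%d\t%d\t%s",
                              chrom, motifs$start, motifs$end, seq_len(n),
                              trunc(motifs$score * 1000), strand))
    tsv <- data.frame(chrom = chrom, start = motifs$start, end = motifs$end,
                      name = paste0("G4_", seq_len(n)), score = motifs$score,
                      length = motifs$end - motifs$start, strand = strand)
  } else {
    tsv <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0),
                      length = integer(0), strand = character(0))
  }
  writeLines(lines, path)
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
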