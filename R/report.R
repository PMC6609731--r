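#' Summary report for one genome
#'
#' Runs the core pipeline on a single genome: length and GC content, strict
#' G4 motif scan (detect + overlap elimination), inverted-repeat detection,
#' and — when an annotation is available and an IR was found — the exonic
#' percentages of the IR and single-copy regions and the IR/SC motif
#' densities.
#'
#' @param genome A [GenomeRecord].
#' @param features Optional [FeatureSet].
#' @param params [scan_params()] for the motif scan.
#' @param min_arm Minimum IR arm length passed to [find_inverted_repeat()].
#' @return List: `id`, `length_bp`, `gc_percent`, `n_motifs`,
#'   `motif_density_per_kb`, `ir_arm_length` (NA if none), `identity`,
#'   `exon_pct` (named SC/IR, if computable), `density` (named IR/SC per
#'   kb, if an IR was found).
#' @export
genome_report <- function(genome, features = NULL, params = scan_params(),
                          min_arm = 1000L) {
  b <- strsplit(genome$sequence, "")[[1]]
  gc <- 100 * sum(b %in% c("G", "C")) / genome$length
  motifs <- scan_g4(genome, params)
  ir <- find_inverted_repeat(genome, min_arm = min_arm)
  out <- list(id = genome$id, length_bp = genome$length,
              gc_percent = gc, n_motifs = nrow(motifs),
              motif_density_per_kb = motif_density(motifs, genome$length),
              ir_arm_length = if (is.null(ir)) NA_integer_ else ir$arm_length,
              identity = if (is.null(ir)) NA_real_ else ir$identity)
  if (!is.null(ir)) {
    out$density <- ir_sc_density(motifs, ir)
    if (!is.null(features)) {
      part <- partition_compartments(genome, features)
      out$exon_pct <- exon_fraction(part, ir)
    }
  }
  out
}

#' Recompute the reported statistics of the deposited records
#'
#' Recomputes, from locally supplied copies of the deposited GenBank
#' records, the published per-genome statistics: sequence length and GC
#' content of MH725791, the IR arm length of MG783568, the exonic
#' percentage inside the IR of MH725794, and the strict-setting G4 motif
#' count of the yeast (S. cerevisiae) mitochondrial reference. The records
#' are not bundled with the package; `dir` must contain files named
#' `<accession>.gb` (GenBank flat file, with features for MH725794) or
#' `<accession>.fasta`.
#'
#' @param dir Directory holding the downloaded records.
#' @return Named list of computed values (quantities for records that are
#'   missing are omitted with a warning).
#' @export
reproduce_reported_values <- function(dir) {
  if (!dir.exists(dir)) stop("record directory not found: ", dir)
  find_rec <- function(acc) {
    hits <- list.files(dir, pattern = paste0("^", acc, "\\.(gb|gbk|genbank|fasta|fa)$"),
                       full.names = TRUE)
    if (length(hits)) hits[1] else NULL
  }
  read_any <- function(path) {
    fmt <- if (grepl("\\.(gb|gbk|genbank)$", path)) "genbank" else "fasta"
    read_genome(path, fmt, circular = TRUE)
  }
  out <- list()
  p <- find_rec("MH725791")
  if (!is.null(p)) {
    g <- read_any(p)
    out$MH725791_length_bp <- g$length
    b <- strsplit(g$sequence, "")[[1]]
    out$MH725791_gc_percent <- 100 * sum(b %in% c("G", "C")) / g$length
  } else warning("MH725791 record not found in ", dir)
  p <- find_rec("MG783568")
  if (!is.null(p)) {
    ir <- find_inverted_repeat(read_any(p))
    out$MG783568_ir_arm_bp <- if (is.null(ir)) NA_integer_ else ir$arm_length
  } else warning("MG783568 record not found in ", dir)
  p <- find_rec("MH725794")
  if (!is.null(p) && grepl("\\.(gb|gbk|genbank)$", p)) {
    g <- read_any(p)
    fs <- read_features(p, "genbank", genome = g)
    ir <- find_inverted_repeat(g)
    if (!is.null(ir)) {
      part <- partition_compartments(g, fs)
      out$MH725794_ir_exon_pct <- unname(exon_fraction(part, ir)["IR"])
    }
  } else warning("MH725794 GenBank record (with features) not found in ", dir)
  p <- find_rec("NC_001224")
  if (!is.null(p)) {
    out$yeast_mt_n_motifs_strict <- nrow(scan_g4(read_any(p)))
  } else warning("yeast mitochondrial reference (NC_001224) not found in ", dir)
  out
}
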