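#' Partition a genome into exon / intron / intergenic compartments
#'
#' The exon compartment is the union of the conserved exonic spans
#' ([conserved_exon_set()]: exons of the conserved protein-coding genes plus
#' the full rns/rnl spans); the intron compartment is the introns of those
#' genes; everything else is intergenic. A base covered by both an exon and
#' an intron (of different genes) is classed exon (priority exon > intron >
#' intergenic). Compartment lengths always tile the genome exactly.
#'
#' @param genome A [GenomeRecord].
#' @param features A [FeatureSet] with the annotation.
#' @param include_nad4L,aliases Passed to [conserved_exon_set()].
#' @return List of class `CompartmentPartition`: `lengths` (named numeric),
#'   `intervals` (list of IRanges per compartment), `labels` (per-base
#'   factor), `genome_length`.
#' @export
partition_compartments <- function(genome, features, include_nad4L = TRUE,
                                   aliases = default_gene_aliases()) {
  L <- genome$length
  ces <- conserved_exon_set(features, include_nad4L, aliases)
  exon_genes <- unique(ces$features$gene)
  f <- features$features
  lab <- rep("intergenic", L)
  if (nrow(f)) {
    cg <- canonical_gene(ifelse(is.na(f$gene), f$name, f$gene), aliases)
    introns <- f[f$kind == "intron" & cg %in% exon_genes, , drop = FALSE]
    for (i in seq_len(nrow(introns))) {
      pos <- (introns$start[i]:(introns$end[i] - 1L)) %% L + 1L
      lab[pos] <- "intron"
    }
  }
  fe <- ces$features
  for (i in seq_len(nrow(fe))) {
    pos <- (fe$start[i]:(fe$end[i] - 1L)) %% L + 1L
    lab[pos] <- "exon"
  }
  lab <- factor(lab, levels = c("exon", "intron", "intergenic"))
  lens <- as.numeric(table(lab))
  names(lens) <- levels(lab)
  stopifnot(sum(lens) == L)  # compartments must tile the genome
  ivs <- lapply(levels(lab), function(k) {
    r <- rle(lab == k)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    IRanges::IRanges(start = s[r$values], end = e[r$values])
  })
  names(ivs) <- levels(lab)
  structure(list(lengths = lens, intervals = ivs, labels = lab,
                 genome_length = L),
            class = "CompartmentPartition")
}

#' Assign motifs to compartments by their midpoint base
#'
#' Each motif is counted in exactly one compartment: that of its midpoint
#' base, `floor((start + end) / 2)` (taken modulo the genome length for
#' wrapped motifs).
#'
#' @param motifs Motif data.frame ([detect_motifs()]).
#' @param partition A [partition_compartments()] result.
#' @return Named integer vector of observed counts per compartment.
#' @export
assign_motifs <- function(motifs, partition) {
  lv <- levels(partition$labels)
  if (!nrow(motifs)) return(stats::setNames(rep(0L, length(lv)), lv))
  mid <- ((motifs$start + motifs$end) %/% 2L) %% partition$genome_length
  tab <- table(partition$labels[mid + 1L])
  stats::setNames(as.integer(tab[lv]), lv)
}

#' Expected motif counts under an unbiased genome-wide distribution
#'
#' @param total_motifs Total motif count (>= 0).
#' @param partition A [partition_compartments()] result.
#' @return Named numeric vector `total_motifs * length_i / genome_length`;
#'   sums to `total_motifs` exactly.
#' @export
expected_counts <- function(total_motifs, partition) {
  stopifnot(total_motifs >= 0)
  total_motifs * partition$lengths / partition$genome_length
}

#' Chi-square goodness-of-fit test of motif counts
#'
#' Computes `chi2 = sum (O - E)^2 / E` over compartments, dropping those with
#' `expected == 0 && observed == 0`; `expected == 0` with `observed > 0` is
#' an error. No continuity correction. A warning is attached (field
#' `small_expected`) when any retained expected count is below 5.
#'
#' @param observed Integer counts per compartment.
#' @param expected Expected counts (same order; sums must agree).
#' @return List of class `EnrichmentResult`: `observed`, `expected`, `chi2`,
#'   `df`, `p`, `small_expected`.
#' @export
chisq_enrichment <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (abs(sum(observed) - sum(expected)) > 1e-9)
    stop("sum(expected) must equal sum(observed)")
  drop <- expected == 0 & observed == 0
  observed <- observed[!drop]; expected <- expected[!drop]
  if (!length(observed)) stop("nothing to test: all counts zero")
  if (any(expected == 0 & observed > 0))
    stop("expected count 0 with observed > 0")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- if (df >= 1L) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  small <- any(expected < 5)
  if (small) warning("expected count < 5 in at least one compartment; ",
                     "chi-square approximation may be poor")
  structure(list(observed = observed, expected = expected, chi2 = chi2,
                 df = df, p = p, small_expected = small),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit: X2 = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  print(rbind(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}

#' Exonic-DNA percentage inside the IR and in the single-copy regions
#'
#' Percentage of bases within one IR arm (copy 1) that belong to conserved
#' exonic spans, and the same percentage over SC1 and SC2 combined.
#'
#' @param partition A [partition_compartments()] result.
#' @param ir An [ir_annotation].
#' @return Named numeric vector `c(SC = %, IR = %)`.
#' @export
exon_fraction <- function(partition, ir) {
  L <- partition$genome_length
  reg <- ir_region_labels(ir, L)
  exonic <- partition$labels == "exon"
  in_ir <- reg == "IR_copy1"
  in_sc <- reg %in% c("SC1", "SC2")
  c(SC = 100 * sum(exonic & in_sc) / sum(in_sc),
    IR = 100 * sum(exonic & in_ir) / sum(in_ir))
}

#' G4 motif density inside the IR versus the single-copy regions
#'
#' Motifs are assigned by midpoint base. By default only motifs in IR copy 1
#' are counted and divided by one arm length (single-copy counting, so the
#' homogenized duplicate copies are not double-counted); `ir_copies = 2`
#' counts both copies over both arm lengths, which rescales nothing when
#' motifs are symmetric under the repeat.
#'
#' @param motifs Motif data.frame.
#' @param ir An [ir_annotation].
#' @param ir_copies Count motifs in 1 (default) or 2 IR copies.
#' @return Named numeric vector `c(density_IR = /kb, density_SC = /kb)`.
#' @export
ir_sc_density <- function(motifs, ir, ir_copies = 1L) {
  L <- ir$genome_length
  reg <- ir_region_labels(ir, L)
  sc_len <- sum(reg %in% c("SC1", "SC2"))
  if (nrow(motifs)) {
    mid <- ((motifs$start + motifs$end) %/% 2L) %% L
    mreg <- reg[mid + 1L]
  } else mreg <- factor(character(0), levels = levels(reg))
  if (ir_copies == 1L) {
    n_ir <- sum(mreg == "IR_copy1"); ir_len <- ir$arm_length
  } else {
    n_ir <- sum(mreg %in% c("IR_copy1", "IR_copy2")); ir_len <- 2L * ir$arm_length
  }
  n_sc <- sum(mreg %in% c("SC1", "SC2"))
  c(density_IR = n_ir * 1000 / ir_len, density_SC = n_sc * 1000 / sc_len)
}

#' Per-compartment G4 enrichment analysis of one genome
#'
#' Convenience wrapper: scan, partition, assign, and test. Mirrors the
#' observed-vs-expected compartment analysis and, when an IR annotation is
#' supplied, adds the exonic percentages and IR/SC densities.
#'
#' @param genome A [GenomeRecord].
#' @param features A [FeatureSet].
#' @param params [scan_params()].
#' @param ir Optional [ir_annotation].
#' @return List with `motifs`, `partition`, `observed`, `expected`,
#'   `enrichment`, and (with `ir`) `exon_pct`, `density`.
#' @export
compartment_enrichment <- function(genome, features, params = scan_params(),
                                   ir = NULL) {
  motifs <- scan_g4(genome, params)
  part <- partition_compartments(genome, features)
  obs <- assign_motifs(motifs, part)
  exp <- expected_counts(sum(obs), part)
  enr <- if (sum(obs) > 0) chisq_enrichment(obs, exp) else NULL
  out <- list(motifs = motifs, partition = part, observed = obs,
              expected = exp, enrichment = enr)
  if (!is.null(ir)) {
    out$exon_pct <- exon_fraction(part, ir)
    out$density <- ir_sc_density(motifs, ir)
  }
  out
}
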