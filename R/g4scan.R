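#' G4 scan parameters
#'
#' Parameters of the run-based sliding-window G4DNA scan. The defaults are
#' the strict setting (window 25 nt, absolute mean-score threshold 1.7); the
#' relaxed setting lowers the threshold to 1.2.
#'
#' @param w Window size in nt (>= 2). Default 25.
#' @param s Absolute window-mean score threshold (> 0). Default 1.7.
#' @param circular Scan across the origin of a circular genome (default
#'   FALSE, matching a scan of the linearized record).
#' @param max_overlap_frac Overlap fraction above which a motif is eliminated
#'   by [deduplicate_motifs()]. Default 0.5.
#' @return A list of class `ScanParams`.
#' @export
scan_params <- function(w = 25L, s = 1.7, circular = FALSE,
                        max_overlap_frac = 0.5) {
  stopifnot(w >= 2, s > 0, max_overlap_frac >= 0, max_overlap_frac <= 1)
  structure(list(w = as.integer(w), s = s, circular = isTRUE(circular),
                 max_overlap_frac = max_overlap_frac), class = "ScanParams")
}

#' Per-base G4 propensity scores
#'
#' Each G in a run of k consecutive Gs scores `+min(k, 4)`; each C in a run
#' of k Cs scores `-min(k, 4)`; A, T and N score 0. Positive scores mark
#' G-richness on the given strand, negative scores G4 potential on the
#' complement.
#'
#' @param sequence Normalized nucleotide string.
#' @return Integer vector, one score in -4..4 per base.
#' @export
base_scores <- function(sequence) {
  b <- strsplit(sequence, "")[[1]]
  if (!length(b)) return(integer(0))
  r <- rle(b)
  v <- integer(length(r$values))
  isg <- r$values == "G"
  isc <- r$values == "C"
  v[isg] <- pmin(r$lengths[isg], 4L)
  v[isc] <- -pmin(r$lengths[isc], 4L)
  rep(v, r$lengths)
}

#' Detect putative G4DNA motifs
#'
#' Slides a window of width `w` with step 1 over the genome; a window is a
#' hit when the absolute mean of the per-base scores ([base_scores()]) meets
#' the threshold `s`. Overlapping or adjacent hit windows of the same sign
#' are merged into maximal regions (a sign change terminates a region, since
#' a G-rich and a C-rich tract are distinct candidate quadruplexes). The
#' region score is the signed mean of its peak window. With
#' `params$circular` and a circular genome the scan wraps `w - 1` bases past
#' the origin and reported regions may have `end > genome length`, meaning
#' they wrap.
#'
#' @param genome A [GenomeRecord] (or plain character sequence).
#' @param params A [scan_params()] list.
#' @return A data.frame of motifs sorted by `start`: columns `start`, `end`
#'   (0-based half-open), `score` (signed peak-window mean), `peak_abs`,
#'   `length`, `strand` (`"+"` for G-rich, `"-"` for C-rich).
#' @export
detect_motifs <- function(genome, params = scan_params()) {
  seq <- if (inherits(genome, "GenomeRecord")) genome$sequence else normalize_sequence(genome)
  circ <- if (inherits(genome, "GenomeRecord")) genome$circular else TRUE
  L <- nchar(seq)
  w <- params$w
  if (L < w) {
    warning("genome shorter than scan window; no motifs reported")
    return(empty_motifs())
  }
  wrap <- params$circular && circ
  if (wrap) {
    # score on a tripled sequence so runs crossing the origin are scored in
    # full circular context, then keep one period plus the window overhang
    sc3 <- base_scores(paste0(seq, seq, seq))
    sc <- sc3[(L + 1L):(2L * L + w - 1L)]
    nwin <- L
  } else {
    sc <- base_scores(seq)
    nwin <- L - w + 1L
  }
  cs <- c(0, cumsum(sc))
  m <- (cs[(w + 1L):(w + nwin)] - cs[1:nwin]) / w
  hit <- which(abs(m) >= params$s)
  if (!length(hit)) return(empty_motifs())
  sgn <- sign(m[hit])
  # merge hit windows that overlap or touch and share a sign
  brk <- c(TRUE, diff(hit) > w | sgn[-1] != sgn[-length(sgn)])
  grp <- cumsum(brk)
  out <- do.call(rbind, lapply(split(seq_along(hit), grp), function(ix) {
    starts <- hit[ix] - 1L            # 0-based window starts
    means <- m[hit[ix]]
    peak <- means[which.max(abs(means))]
    data.frame(start = starts[1], end = starts[length(starts)] + w,
               score = peak, peak_abs = abs(peak),
               length = starts[length(starts)] + w - starts[1],
               strand = if (peak >= 0) "+" else "-")
  }))
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

empty_motifs <- function() {
  data.frame(start = integer(0), end = integer(0), score = numeric(0),
             peak_abs = numeric(0), length = integer(0), strand = character(0))
}

#' Eliminate overlapping motif calls
#'
#' Greedy pass in priority order; a motif is eliminated when its overlap with
#' any already-retained motif exceeds `max_overlap_frac` of its own length
#' (strictly greater than, so an exact 50% overlap is kept at the default).
#'
#' @param motifs Motif data.frame from [detect_motifs()].
#' @param max_overlap_frac Elimination threshold (default 0.5).
#' @param order Priority order: `"score"` (descending `|score|`, ties by
#'   smaller start; keeps the strongest representative) or `"position"`
#'   (ascending start).
#' @return The retained motifs, sorted by `start`.
#' @export
deduplicate_motifs <- function(motifs, max_overlap_frac = 0.5,
                               order = c("score", "position")) {
  order <- match.arg(order)
  n <- nrow(motifs)
  if (n <= 1L) return(motifs)
  prio <- if (order == "score") base::order(-abs(motifs$score), motifs$start)
          else base::order(motifs$start, -abs(motifs$score))
  keep <- logical(n)
  ks <- kE <- integer(0)
  for (i in prio) {
    s <- motifs$start[i]; e <- motifs$end[i]
    ov <- pmax(0L, pmin(kE, e) - pmax(ks, s))
    if (!length(ov) || max(ov) <= max_overlap_frac * (e - s)) {
      keep[i] <- TRUE
      ks <- c(ks, s); kE <- c(kE, e)
    }
  }
  out <- motifs[keep, , drop = FALSE]
  out[base::order(out$start), , drop = FALSE]
}

#' Motif density per kilobase
#'
#' @param motifs Motif data.frame (or an integer count).
#' @param region_length_bp Region length in bp (> 0).
#' @return Motifs per kb.
#' @export
motif_density <- function(motifs, region_length_bp) {
  if (region_length_bp <= 0) stop("region length must be positive")
  n <- if (is.data.frame(motifs)) nrow(motifs) else as.integer(motifs)
  n * 1000 / region_length_bp
}

#' Full G4 scan: detect then deduplicate
#'
#' Convenience wrapper running [detect_motifs()] followed by
#' [deduplicate_motifs()] with the parameters' overlap threshold.
#'
#' @inheritParams detect_motifs
#' @param dedup_order Priority order passed to [deduplicate_motifs()].
#' @return Motif data.frame.
#' @export
scan_g4 <- function(genome, params = scan_params(), dedup_order = "score") {
  deduplicate_motifs(detect_motifs(genome, params),
                     max_overlap_frac = params$max_overlap_frac,
                     order = dedup_order)
}
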