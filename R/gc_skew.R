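#' Windowed and cumulative GC-skew profile
#'
#' Per-window skew is `(G - C) / (G + C)` on the forward strand (the sign
#' convention matters: tools differ), defined as 0 with a warning for
#' windows containing no G or C. The cumulative curve is the running sum of
#' window skews; its extrema are the classical candidates for replication
#' origin and terminus.
#'
#' @param genome A [GenomeRecord] or nucleotide string.
#' @param window Window size in bp (default 1000).
#' @param step Step size in bp (default `window`: non-overlapping windows).
#' @return List of class `SkewProfile`: `window`, `step`, `start` (0-based
#'   window starts), `skew`, `cumulative`.
#' @export
gc_skew_profile <- function(genome, window = 1000L, step = window) {
  seq <- if (inherits(genome, "GenomeRecord")) genome$sequence else normalize_sequence(genome)
  L <- nchar(seq)
  if (window > L) stop("window larger than genome")
  b <- strsplit(seq, "")[[1]]
  cg <- c(0, cumsum(b == "G"))
  cc <- c(0, cumsum(b == "C"))
  starts <- seq.int(1L, L - window + 1L, by = step)
  nG <- cg[starts + window] - cg[starts]
  nC <- cc[starts + window] - cc[starts]
  tot <- nG + nC
  if (any(tot == 0)) warning(sum(tot == 0), " window(s) with no G or C; skew set to 0")
  skew <- ifelse(tot == 0, 0, (nG - nC) / tot)
  structure(list(window = window, step = step, start = starts - 1L,
                 skew = skew, cumulative = cumsum(skew)),
            class = "SkewProfile")
}

#' @export
print.SkewProfile <- function(x, ...) {
  cat(sprintf("SkewProfile: %d windows of %d bp (step %d)\n",
              length(x$skew), x$window, x$step))
  invisible(x)
}

#' Extrema of the cumulative GC-skew curve
#'
#' Global minimum and maximum of the cumulative curve; ties resolved to the
#' first occurrence. The extrema are candidate replication origin/terminus
#' positions under strand-asymmetric mutation models (a search this method
#' does not always resolve for rearranged genomes).
#'
#' @param profile A [gc_skew_profile()] result.
#' @return data.frame with rows `min` and `max`: window index (1-based),
#'   window start (0-based bp), window midpoint (bp), cumulative value.
#' @export
skew_extrema <- function(profile) {
  if (!length(profile$cumulative)) stop("empty profile")
  i_min <- which.min(profile$cumulative)
  i_max <- which.max(profile$cumulative)
  data.frame(
    extremum = c("min", "max"),
    window = c(i_min, i_max),
    start = profile$start[c(i_min, i_max)],
    midpoint_bp = profile$start[c(i_min, i_max)] + profile$window / 2,
    cumulative = profile$cumulative[c(i_min, i_max)])
}
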