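#' Inverted-repeat annotation
#'
#' Coordinates of the two arms of a large inverted repeat and the two derived
#' single-copy regions. All intervals are 0-based half-open; an interval with
#' `end > genome length` wraps past the origin of a circular genome (its
#' occupied bases are taken modulo the genome length).
#'
#' @param arm1_start,arm1_end,arm2_start,arm2_end Arm intervals; arm2 is the
#'   reverse complement of arm1.
#' @param identity Fraction of matching bases between arm1 and
#'   revcomp(arm2).
#' @param genome_length Genome length in bp.
#' @return An object of class `IRAnnotation` with fields `arm_length`, `sc1`
#'   and `sc2` (each a list `start`/`end`, possibly wrapping) derived from
#'   the arm coordinates. SC naming here is positional (sc1 follows arm1);
#'   [partition_ir()] applies the cox1 rule.
#' @export
ir_annotation <- function(arm1_start, arm1_end, arm2_start, arm2_end,
                          identity, genome_length) {
  stopifnot(arm1_end - arm1_start == arm2_end - arm2_start,
            arm1_end > arm1_start)
  if (arm1_start > arm2_start) {  # canonical order: arm1 first
    tmp <- c(arm1_start, arm1_end)
    arm1_start <- arm2_start; arm1_end <- arm2_end
    arm2_start <- tmp[1]; arm2_end <- tmp[2]
  }
  sc1 <- list(start = arm1_end, end = arm2_start)
  sc2 <- list(start = arm2_end, end = arm1_start + genome_length)
  structure(list(
    arm1_start = arm1_start, arm1_end = arm1_end,
    arm2_start = arm2_start, arm2_end = arm2_end,
    arm_length = arm1_end - arm1_start, identity = identity,
    sc1 = sc1, sc2 = sc2, genome_length = genome_length),
    class = "IRAnnotation")
}

#' @export
print.IRAnnotation <- function(x, ...) {
  cat(sprintf("IRAnnotation: arms %d bp (identity %.4f)\n", x$arm_length, x$identity))
  cat(sprintf("  arm1 [%d,%d)  arm2 [%d,%d)  genome %d bp\n",
              x$arm1_start, x$arm1_end, x$arm2_start, x$arm2_end, x$genome_length))
  invisible(x)
}

# Per-base region labels for a genome with an IR: factor of
# {IR_copy1, IR_copy2, SC1, SC2} of length L, wrap-aware. SC labels are
# positional (SC1 = the single-copy region following arm1).
ir_region_labels <- function(ir, L = ir$genome_length) {
  lab <- character(L)
  fill <- function(start, end, what) {
    if (end <= start) return()
    pos <- (start:(end - 1L)) %% L + 1L
    lab[pos] <<- what
  }
  fill(ir$arm1_start, ir$arm1_end, "IR_copy1")
  fill(ir$arm2_start, ir$arm2_end, "IR_copy2")
  fill(ir$sc1$start, ir$sc1$end, "SC1")
  fill(ir$sc2$start, ir$sc2$end, "SC2")
  factor(lab, levels = c("IR_copy1", "SC1", "IR_copy2", "SC2"))
}

#' Find the large inverted repeat in a finished genome
#'
#' Exact-match seeding with a k-mer index of the sequence against its reverse
#' complement, collinear seed chaining, then ungapped X-drop extension
#' (match +1, mismatch -3, drop 30) trimmed to the maximal-scoring endpoint;
#' the final arm pair must reach `min_identity`. Circular genomes are
#' searched over all rotations by doubling the sequence. Among candidates the
#' longest arm pair wins, ties broken by higher identity, then smaller
#' arm1_start.
#'
#' @param genome A [GenomeRecord].
#' @param min_arm Minimum arm length in bp (default 1000).
#' @param min_identity Minimum arm identity (default 0.99).
#' @param k Seed k-mer size (default 21).
#' @return An [ir_annotation], or `NULL` when no arm of at least `min_arm`
#'   is found. A palindrome spanning the whole genome (empty single-copy
#'   regions) is an error.
#' @export
find_inverted_repeat <- function(genome, min_arm = 1000L, min_identity = 0.99,
                                 k = 21L) {
  L <- genome$length
  if (L < 2L * min_arm) return(NULL)
  S <- genome$sequence
  if (identical(S, revcomp(S)))
    stop("genome is a perfect palindrome: single-copy regions would be empty")
  T <- if (genome$circular) paste0(S, S) else S
  n <- nchar(T)
  tb <- strsplit(T, "")[[1]]
  rcb <- rev(chartr("ACGTN", "TGCAN", tb))

  # seed matches between T and revcomp(T)
  a <- substring(T, 1:(n - k + 1L), k:n)
  R <- paste(rcb, collapse = "")
  b <- substring(R, 1:(n - k + 1L), k:n)
  q <- match(b, a)                      # for RC position p: position q in T
  p <- which(!is.na(q))
  if (!length(p)) return(NULL)
  q <- q[p]
  dg <- q - p

  cand <- list()
  max_gap <- 8L * k
  for (d in unique(dg)) {
    ps <- sort(p[dg == d])
    grp <- cumsum(c(TRUE, diff(ps) > max_gap))
    for (g in unique(grp)) {
      pp <- ps[grp == g]
      p0 <- pp[1]; p1 <- pp[length(pp)]
      if ((p1 - p0 + k) < max(min_arm, 2L * k)) next
      cand[[length(cand) + 1L]] <- c(p0 = p0, p1 = p1, d = d)
    }
  }
  if (!length(cand)) return(NULL)

  results <- list()
  for (cd in cand) {
    p0 <- cd["p0"]; p1 <- cd["p1"]; d <- cd["d"]
    # block in T: q in [p0+d, p1+d+k-1]; paired block: [n-p1-k+2, n-p0+1]
    q0 <- p0 + d; q1 <- p1 + d + k - 1L
    j0 <- n - (p1 + k - 1L) + 1L; j1 <- n - p0 + 1L
    # canonicalize: left block before right block (the pairing is symmetric)
    if (j1 < q0) { tmp <- c(q0, q1); q0 <- j0; q1 <- j1; j0 <- tmp[1]; j1 <- tmp[2] }
    ext <- xdrop_extend(tb, l0 = q0, l1 = q1, r0 = j0, r1 = j1, n = n)
    q0 <- ext$l0; q1 <- ext$l1; j0 <- ext$r0; j1 <- ext$r1
    alen <- q1 - q0 + 1L
    if (alen < min_arm || alen != (j1 - j0 + 1L)) next
    if (j0 <= q1 && q0 <= j1) next      # self-overlapping palindrome block
    armA <- tb[q0:q1]
    armB <- tb[j0:j1]
    ident <- mean(armA == rev(chartr("ACGTN", "TGCAN", armB)))
    if (ident < min_identity) next
    results[[length(results) + 1L]] <-
      list(s1 = min(q0, j0) - 1L, e1 = min(q1, j1),
           s2 = max(q0, j0) - 1L, e2 = max(q1, j1), len = alen, id = ident)
  }
  if (!length(results)) return(NULL)

  if (genome$circular) {
    # normalize doubled-sequence coordinates to [0, L) starts and drop
    # duplicates / pairs overlapping on the circle
    norm <- list()
    for (r in results) {
      sh <- L * (r$s1 %/% L)
      r$s1 <- r$s1 - sh; r$e1 <- r$e1 - sh
      r$s2 <- r$s2 - sh; r$e2 <- r$e2 - sh
      if (r$len > L %/% 2 + 1L) next
      if (r$s2 >= L + r$s1) next        # same copy seen across the junction
      occ1 <- (r$s1:(r$e1 - 1L)) %% L
      occ2 <- (r$s2:(r$e2 - 1L)) %% L
      if (length(intersect(occ1, occ2))) next
      key <- paste(r$s1, r$s2 %% L, r$len)
      norm[[key]] <- r
    }
    results <- unname(norm)
    if (!length(results)) return(NULL)
  }

  ord <- order(-vapply(results, `[[`, 0, "len"),
               -vapply(results, `[[`, 0, "id"),
               vapply(results, `[[`, 0, "s1"))
  best <- results[[ord[1]]]
  ir <- ir_annotation(best$s1, best$e1, best$s2, best$e2, best$id, L)
  if (sc_length(ir$sc1, L) == 0L && sc_length(ir$sc2, L) == 0L)
    stop("genome is a perfect palindrome: single-copy regions would be empty")
  ir
}

sc_length <- function(sc, L) (sc$end - sc$start)

# Ungapped X-drop extension of an inverted block pair, trimmed to the
# maximal-scoring endpoint (match +1, mismatch -3, drop 30). Left block
# [l0,l1] pairs with right block [r0,r1] as T[l0+t] == comp(T[r1-t]).
xdrop_extend <- function(tb, l0, l1, r0, r1, n,
                         match = 1, mismatch = -3, xdrop = 30) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "x")
  # inner extension: l1+i pairs with r0-i, blocks must not collide
  sc <- 0; best <- 0; bi <- 0L; i <- 0L
  while (sc > best - xdrop) {
    i <- i + 1L
    if (l1 + i >= r0 - i) break
    sc <- sc + if (identical(unname(comp[tb[l1 + i]]), tb[r0 - i])) match else mismatch
    if (sc > best) { best <- sc; bi <- i }
  }
  l1 <- l1 + bi; r0 <- r0 - bi
  # outer extension: l0-i pairs with r1+i
  sc <- 0; best <- 0; bi <- 0L; i <- 0L
  while (sc > best - xdrop) {
    i <- i + 1L
    if (l0 - i < 1L || r1 + i > n) break
    sc <- sc + if (identical(unname(comp[tb[l0 - i]]), tb[r1 + i])) match else mismatch
    if (sc > best) { best <- sc; bi <- i }
  }
  list(l0 = l0 - bi, l1 = l1, r0 = r0, r1 = r1 + bi)
}

#' Detect duplicated segments from a read-depth track
#'
#' A collapsed assembly represents a two-copy repeat once, at twice the
#' baseline coverage. Depth is normalized by its median, smoothed with a
#' 201-bp sliding median, and maximal runs with normalized depth in
#' `[fold_min, fold_max]` of at least `min_len` bp are reported.
#'
#' @param depth Numeric vector of per-base depth.
#' @param fold_min,fold_max Normalized-depth band (defaults 1.75, 2.5).
#' @param min_len Minimum run length in bp (default 2000).
#' @param smooth_window Sliding-median window (odd, default 201).
#' @return data.frame of intervals (`start`, `end`, 0-based half-open,
#'   `mean_fold`).
#' @export
detect_duplication_from_depth <- function(depth, fold_min = 1.75,
                                          fold_max = 2.5, min_len = 2000L,
                                          smooth_window = 201L) {
  if (all(depth == 0)) stop("all-zero depth track")
  med <- stats::median(depth)
  if (med <= 0) stop("median depth is zero; baseline not estimable")
  norm <- stats::runmed(depth / med, k = smooth_window, endrule = "median")
  inband <- norm >= fold_min & norm <= fold_max
  r <- rle(inband)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= min_len)
  if (!length(sel)) return(data.frame(start = integer(0), end = integer(0),
                                      mean_fold = numeric(0)))
  data.frame(start = starts[sel] - 1L, end = ends[sel],
             mean_fold = vapply(sel, function(i)
               mean(depth[starts[i]:ends[i]]) / med, 0))
}

#' Partition a genome into IR and single-copy regions
#'
#' Labels the four regions (IR copy 1 and 2, SC1, SC2). With an annotation,
#' SC1 is the single-copy region containing cox1 (midpoint rule); without
#' one, SC1 is the longer region (logged via message). The border report
#' gives, for each of the four IR/SC junctions, the nearest gene on either
#' side, and flags genes partially overlapping an arm.
#'
#' @param genome A [GenomeRecord].
#' @param ir An [ir_annotation].
#' @param features Optional [FeatureSet].
#' @return List with `regions` (data.frame name/start/end/length; wrapped
#'   regions keep `end > genome length`), `labels` (per-base factor),
#'   `borders` (data.frame), and `partially_overlapping` (gene names).
#' @export
partition_ir <- function(genome, ir, features = NULL) {
  L <- genome$length
  lab <- ir_region_labels(ir, L)
  sc1_len <- sc_length(ir$sc1, L)
  sc2_len <- sc_length(ir$sc2, L)
  sc1_name <- "SC1"; sc2_name <- "SC2"
  swap <- FALSE
  f <- if (!is.null(features)) features$features else NULL
  genes <- if (!is.null(f))
    f[f$kind == "gene" | (f$kind == "exon" & !is.na(f$gene)), , drop = FALSE]
  else NULL
  cox1_mid <- NULL
  if (!is.null(f)) {
    nm <- canonical_gene(ifelse(is.na(f$gene), f$name, f$gene))
    ci <- which(nm == "cox1")
    if (length(ci)) cox1_mid <- ((f$start[ci[1]] + f$end[ci[1]]) %/% 2L) %% L
  }
  if (!is.null(cox1_mid)) {
    swap <- lab[cox1_mid + 1L] == "SC2"
  } else {
    message("no cox1 annotation; labeling the longer single-copy region SC1")
    swap <- sc2_len > sc1_len
  }
  if (swap) levels(lab)[levels(lab) == "SC1"] <- "tmp_" else NULL
  if (swap) {
    levels(lab)[levels(lab) == "SC2"] <- "SC1"
    levels(lab)[levels(lab) == "tmp_"] <- "SC2"
  }
  regions <- data.frame(
    name = c("IR_copy1", if (swap) "SC2" else "SC1", "IR_copy2",
             if (swap) "SC1" else "SC2"),
    start = c(ir$arm1_start, ir$sc1$start, ir$arm2_start, ir$sc2$start),
    end = c(ir$arm1_end, ir$sc1$end, ir$arm2_end, ir$sc2$end))
  regions$length <- regions$end - regions$start
  borders <- NULL; partial <- character(0)
  if (!is.null(genes) && nrow(genes)) {
    gs <- genes$start %% L; ge <- (genes$end - 1L) %% L + 1L
    gname <- ifelse(is.na(genes$gene), genes$name, genes$gene)
    bpos <- c(arm1_start = ir$arm1_start %% L, arm1_end = ir$arm1_end %% L,
              arm2_start = ir$arm2_start %% L, arm2_end = ir$arm2_end %% L)
    borders <- do.call(rbind, lapply(names(bpos), function(bn) {
      pos <- bpos[[bn]]
      dl <- (pos - ge) %% L      # circular distance to genes ending before
      dr <- (gs - pos) %% L      # distance to genes starting after
      data.frame(border = bn, position = pos,
                 gene_before = gname[which.min(dl)],
                 gene_after = gname[which.min(dr)])
    }))
    # genes partially overlapping an arm: span crosses an arm boundary
    for (i in seq_len(nrow(genes))) {
      span <- (genes$start[i]:(genes$end[i] - 1L)) %% L + 1L
      inarm <- lab[span] %in% c("IR_copy1", "IR_copy2")
      if (any(inarm) && any(!inarm)) partial <- c(partial, gname[i])
    }
    partial <- unique(partial)
  }
  list(regions = regions, labels = lab, borders = borders,
       partially_overlapping = partial, sc_swapped = swap)
}
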