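#' Specification for a synthetic mitochondrial genome
#'
#' Describes a circular genome with an optional planted two-arm inverted
#' repeat, annotated conserved genes with exons/introns and the two rRNA
#' subunits, and planted G4 motifs at controlled densities. The defaults
#' emulate the assembled Lyophyllaceae-like genomes the pipeline targets:
#' 150 kb circular molecules at 35% GC with a 35-kb IR arm, and motif
#' densities of 1 per kb inside the repeat versus 0.4 per kb in the
#' single-copy regions.
#'
#' Layout: `arm1 | SC1 | arm2 | SC2` on the circle, with SC1 the longer
#' single-copy region. By default rns, rnl, atp6, nad2, nad3, nad4 and cox2
#' are placed inside the repeat (mirrored into the second copy), cox1 and
#' other genes in SC1, and cox3/rps3 at the edges of SC2.
#'
#' @param genome_length Total length in bp.
#' @param gc_content Background GC fraction (G/C runs are capped at 2 so the
#'   background produces essentially no G4 hits and planted counts are
#'   exact).
#' @param ir_arm_length Arm length in bp; 0 plants no repeat.
#' @param ir_mismatch_rate Substitution rate between the two arms (planted
#'   outside motif footprints, substituting G/C with A/T so the run cap is
#'   preserved).
#' @param g4_rate_per_kb Named list of planted motif densities: either per
#'   region (`IR`, `SC`) or per compartment (`exon`, `intron`,
#'   `intergenic`).
#' @param motif_template Planted motif sequence; must score at least the
#'   strict threshold (validated at construction).
#' @param genes Data.frame (name, n_exons, exon_len, intron_len, region)
#'   or NULL for the default conserved-gene layout.
#' @param depth_mean Mean read depth for [generate_depth()].
#' @param boundary_gene Plant one gene straddling the arm1/SC1 border (for
#'   border-report tests).
#' @return List of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(genome_length = 150000L, gc_content = 0.35,
                           ir_arm_length = 35000L, ir_mismatch_rate = 0,
                           g4_rate_per_kb = list(IR = 1.0, SC = 0.4),
                           motif_template = strrep("GGGT", 7),
                           genes = NULL, depth_mean = 100,
                           boundary_gene = FALSE) {
  stopifnot(genome_length > 0, gc_content > 0, gc_content < 1,
            ir_arm_length >= 0, ir_arm_length <= genome_length / 2,
            ir_mismatch_rate >= 0, ir_mismatch_rate < 1)
  tmpl_score <- mean(base_scores(motif_template))
  if (abs(tmpl_score) < 1.7)
    stop("motif template mean score ", round(tmpl_score, 2),
         " is below the strict threshold 1.7")
  if (is.null(genes)) genes <- default_gene_layout(ir_arm_length)
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content,
                 ir_arm_length = as.integer(ir_arm_length),
                 ir_mismatch_rate = ir_mismatch_rate,
                 g4_rate_per_kb = g4_rate_per_kb,
                 motif_template = motif_template, genes = genes,
                 depth_mean = depth_mean, boundary_gene = boundary_gene),
            class = "SyntheticSpec")
}

default_gene_layout <- function(ir_arm_length = 35000L) {
  g <- rbind(
    data.frame(name = "rns",  n_exons = 1, exon_len = 1500, intron_len = 0,   region = "IR"),
    data.frame(name = "rnl",  n_exons = 1, exon_len = 3000, intron_len = 0,   region = "IR"),
    data.frame(name = "atp6", n_exons = 1, exon_len = 700,  intron_len = 0,   region = "IR"),
    data.frame(name = "nad2", n_exons = 1, exon_len = 1600, intron_len = 0,   region = "IR"),
    data.frame(name = "nad3", n_exons = 1, exon_len = 400,  intron_len = 0,   region = "IR"),
    data.frame(name = "nad4", n_exons = 1, exon_len = 1400, intron_len = 0,   region = "IR"),
    data.frame(name = "cox2", n_exons = 2, exon_len = 400,  intron_len = 900, region = "IR"),
    data.frame(name = "cox1", n_exons = 4, exon_len = 400,  intron_len = 1200, region = "SC1"),
    data.frame(name = "nad1", n_exons = 1, exon_len = 1000, intron_len = 0,   region = "SC1"),
    data.frame(name = "nad5", n_exons = 1, exon_len = 2000, intron_len = 0,   region = "SC1"),
    data.frame(name = "nad6", n_exons = 1, exon_len = 700,  intron_len = 0,   region = "SC1"),
    data.frame(name = "nad4L", n_exons = 1, exon_len = 300, intron_len = 0,   region = "SC1"),
    data.frame(name = "atp8", n_exons = 1, exon_len = 200,  intron_len = 0,   region = "SC1"),
    data.frame(name = "atp9", n_exons = 1, exon_len = 250,  intron_len = 0,   region = "SC1"),
    data.frame(name = "cox3", n_exons = 1, exon_len = 800,  intron_len = 0,   region = "SC2"),
    data.frame(name = "cob",  n_exons = 2, exon_len = 600,  intron_len = 1000, region = "SC2"),
    data.frame(name = "rps3", n_exons = 1, exon_len = 1200, intron_len = 0,   region = "SC2"))
  # genes that do not fit inside a short (or absent) arm fall back to SC1
  glen <- g$n_exons * g$exon_len + pmax(0, g$n_exons - 1) * g$intron_len
  capacity <- max(0, ir_arm_length - 1000L)
  in_ir <- g$region == "IR"
  overflow <- in_ir & cumsum(ifelse(in_ir, glen, 0)) > capacity
  g$region[overflow] <- "SC1"
  g
}

COMP_BASES <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Generate a synthetic genome with full ground truth
#'
#' Builds a circular genome per the spec: i.i.d. background at the given GC
#' with G/C runs capped at 2, planted genes (annotated, with exons and
#' introns), a planted inverted repeat (arm2 = revcomp(arm1), with optional
#' mismatches), and planted G4 motifs at the requested densities. Motifs and
#' gene annotations inside arm1 are mirrored into arm2 automatically. Two
#' bases flanking each arm end are forced to mismatch in inverted
#' orientation so the planted repeat is also the maximal one.
#'
#' Randomness uses R's Mersenne-Twister; one seed governs the whole genome.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List with `genome` ([GenomeRecord]), `features` ([FeatureSet]),
#'   `ir` (truth [ir_annotation] or NULL) and `motifs` (truth data.frame of
#'   planted motifs: start, end, strand, region, compartment).
#' @export
generate_genome <- function(spec, seed = 1L) {
  set.seed(seed, kind = "Mersenne-Twister")
  L <- spec$genome_length
  armL <- spec$ir_arm_length
  p <- c(A = (1 - spec$gc_content) / 2, C = spec$gc_content / 2,
         G = spec$gc_content / 2, T = (1 - spec$gc_content) / 2)
  g <- sample(names(p), L, replace = TRUE, prob = p)
  g <- cap_gc_runs(g)

  # region layout: arm1 | SC1 | arm2 | SC2, SC1 the longer SC
  if (armL > 0) {
    sc_total <- L - 2L * armL
    sc1_len <- as.integer(ceiling(sc_total * 0.55))
    a1 <- c(0L, armL)
    s1 <- c(armL, armL + sc1_len)
    a2 <- c(s1[2], s1[2] + armL)
    s2 <- c(a2[2], L)
    ir <- ir_annotation(a1[1], a1[2], a2[1], a2[2],
                        identity = NA_real_, genome_length = L)
  } else {
    ir <- NULL
    s1 <- c(0L, as.integer(0.6 * L))
    s2 <- c(as.integer(0.6 * L), L)
  }

  feats <- place_genes(spec, L, armL, if (armL > 0) list(a1 = a1, s1 = s1, a2 = a2, s2 = s2)
                       else list(s1 = s1, s2 = s2))
  if (spec$boundary_gene && armL > 0) {
    bg <- data.frame(kind = "gene", name = "orf_border", gene = NA_character_,
                     start = a1[2] - 500L, end = a1[2] + 500L, strand = "+",
                     group = NA_character_)
    feats <- rbind(feats, bg)
  }

  motifs <- plant_motifs(spec, g, L, armL, feats,
                         if (armL > 0) list(a1 = a1, s1 = s1, a2 = a2, s2 = s2)
                         else list(s1 = s1))
  g <- motifs$g
  truth_motifs <- motifs$truth

  if (armL > 0) {
    # copy arm2 = revcomp(arm1), then planted mismatches outside motif
    # footprints (A<->T swaps or G/C -> A/T, preserving the run cap)
    arm1 <- g[(a1[1] + 1L):a1[2]]
    arm2 <- rev(unname(COMP_BASES[arm1]))
    if (spec$ir_mismatch_rate > 0) {
      n_mm <- round(spec$ir_mismatch_rate * armL)
      protected <- rep(FALSE, armL)
      in_arm2 <- truth_motifs[truth_motifs$region == "IR_copy2", , drop = FALSE]
      for (i in seq_len(nrow(in_arm2))) {
        off <- (in_arm2$start[i] - a2[1] + 1L):(in_arm2$end[i] - a2[1])
        protected[off] <- TRUE
      }
      pool <- which(!protected)
      mm <- sample(pool, min(n_mm, length(pool)))
      arm2[mm] <- ifelse(arm2[mm] == "A", "T",
                   ifelse(arm2[mm] == "T", "A",
                          sample(c("A", "T"), length(mm), replace = TRUE)))
    }
    g[(a2[1] + 1L):a2[2]] <- arm2
    # mirror arm1 gene annotations into arm2
    g_feats <- mirror_arm_features(feats, a1, a2)
    feats <- rbind(feats, g_feats)
    g <- enforce_arm_maximality(g, L, a1, a2)
    arm1 <- g[(a1[1] + 1L):a1[2]]
    arm2 <- g[(a2[1] + 1L):a2[2]]
    ir$identity <- mean(arm1 == rev(unname(COMP_BASES[arm2])))
  }

  genome <- GenomeRecord("synthetic", paste(g, collapse = ""), circular = TRUE)
  fs <- FeatureSet("synthetic", feats, genome_length = L)
  list(genome = genome, features = fs, ir = ir, motifs = truth_motifs,
       seed = seed, spec = spec)
}

# Replace the 3rd+ base of any G or C run with A/T so background windows
# cannot reach the strict threshold.
cap_gc_runs <- function(g) {
  r <- rle(g)
  long <- which(r$values %in% c("G", "C") & r$lengths > 2L)
  if (!length(long)) return(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fix <- unlist(lapply(long, function(i) (starts[i] + 2L):ends[i]))
  g[fix] <- sample(c("A", "T"), length(fix), replace = TRUE)
  g
}

# Lay the genes of the spec into their regions, serially with even gaps.
# Genes overflowing a region spill into the next one (IR -> SC1 -> SC2);
# only SC2 overflow is an error.
place_genes <- function(spec, L, armL, regions) {
  rows <- list()
  margin <- 300L
  genes <- spec$genes
  span_of <- function(rg) switch(rg, IR = regions$a1, SC1 = regions$s1,
                                 SC2 = regions$s2, stop("unknown region ", rg))
  if (is.null(regions$a1) && any(genes$region == "IR"))
    genes$region[genes$region == "IR"] <- "SC1"
  all_glen <- genes$n_exons * genes$exon_len +
    pmax(0, genes$n_exons - 1) * genes$intron_len
  for (ri in 1:2) {
    rg <- c("IR", "SC1", "SC2")[ri]
    sel_idx <- which(genes$region == rg)
    if (!length(sel_idx)) next
    span <- span_of(rg)
    avail <- (span[2] - span[1]) - 2L * margin
    over <- sel_idx[cumsum(all_glen[sel_idx]) > avail]
    if (length(over)) genes$region[over] <- c("IR", "SC1", "SC2")[ri + 1L]
  }
  for (rg in unique(genes$region)) {
    sel <- genes[genes$region == rg, , drop = FALSE]
    span <- span_of(rg)
    glen <- sel$n_exons * sel$exon_len + pmax(0, sel$n_exons - 1) * sel$intron_len
    avail <- (span[2] - span[1]) - 2L * margin
    if (sum(glen) > avail)
      stop("genes do not fit in region ", rg, " (need ", sum(glen),
           ", have ", avail, ")")
    gap <- (avail - sum(glen)) %/% (nrow(sel) + 1L)
    pos <- span[1] + margin + gap
    for (i in seq_len(nrow(sel))) {
      nm <- sel$name[i]
      kind_full <- if (nm %in% c("rns", "rnl")) "rRNA" else "gene"
      gstart <- pos
      for (e in seq_len(sel$n_exons[i])) {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "exon", name = paste0(nm, ".e", e), gene = nm,
          start = pos, end = pos + sel$exon_len[i], strand = "+",
          group = NA_character_)
        pos <- pos + sel$exon_len[i]
        if (e < sel$n_exons[i]) {
          rows[[length(rows) + 1L]] <- data.frame(
            kind = "intron", name = paste0(nm, ".i", e), gene = nm,
            start = pos, end = pos + sel$intron_len[i], strand = "+",
            group = NA_character_)
          pos <- pos + sel$intron_len[i]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind_full, name = nm, gene = NA_character_,
        start = gstart, end = pos, strand = "+", group = NA_character_)
      pos <- pos + gap
    }
  }
  do.call(rbind, rows)
}

# Mirror features lying in arm1 into arm2 (coordinates reflected, strand
# flipped), tagging the copies.
mirror_arm_features <- function(feats, a1, a2) {
  inarm <- feats$start >= a1[1] & feats$end <= a1[2]
  f <- feats[inarm, , drop = FALSE]
  if (!nrow(f)) return(f)
  armL <- a1[2] - a1[1]
  new_start <- a2[1] + (armL - (f$end - a1[1]))
  new_end <- a2[1] + (armL - (f$start - a1[1]))
  f$start <- new_start; f$end <- new_end
  f$strand <- ifelse(f$strand == "+", "-", "+")
  # keep the canonical gene identity on the copy; only the label is tagged
  f$gene <- ifelse(is.na(f$gene), f$name, f$gene)
  f$name <- paste0(f$name, "_ir2")
  f
}

# Force a mismatch (in inverted orientation) at the 2 bases flanking each
# arm end, so extension beyond the planted arms stops immediately.
enforce_arm_maximality <- function(g, L, a1, a2) {
  fix <- function(pos_out, pos_in) {
    # pos_out (modified, SC side) must not equal comp(pos_in)
    io <- pos_out %% L + 1L; ii <- pos_in %% L + 1L
    forbidden <- unname(COMP_BASES[g[ii]])
    pick <- setdiff(c("A", "T"), forbidden)
    if (g[io] == forbidden || g[io] %in% c("G", "C"))
      g[io] <<- pick[sample.int(length(pick), 1L)]
  }
  for (i in 1:2) {
    fix(a1[2] - 1L + i, a2[1] - i)      # inner: right of arm1 vs left of arm2
    fix(a2[2] - 1L + i, a1[1] - i)      # inner-equivalent on other junction
    fix(a1[1] - i, a2[2] - 1L + i)      # outer: left of arm1 vs right of arm2
  }
  g
}

# Plant motif copies at the requested densities; returns modified sequence
# and the truth table (arm1 motifs mirrored into arm2).
plant_motifs <- function(spec, g, L, armL, feats, regions) {
  tmpl <- strsplit(spec$motif_template, "")[[1]]
  tl <- length(tmpl)
  rates <- spec$g4_rate_per_kb
  region_mode <- all(names(rates) %in% c("IR", "SC"))
  occupied <- rep(FALSE, L)   # motif footprints + spacing
  margin <- 120L              # keep off region borders
  pad <- 80L                  # min gap between planted motifs

  # candidate mask per target
  mask_for <- function(what) {
    m <- rep(FALSE, L)
    if (region_mode) {
      if (what == "IR") m[(regions$a1[1] + 1L):regions$a1[2]] <- TRUE
      else {
        m[(regions$s1[1] + 1L):regions$s1[2]] <- TRUE
        if (!is.null(regions$s2)) m[(regions$s2[1] + 1L):regions$s2[2]] <- TRUE
      }
    } else {
      lab <- rep("intergenic", L)
      for (i in seq_len(nrow(feats))) {
        if (!feats$kind[i] %in% c("exon", "intron", "rRNA")) next
        k <- if (feats$kind[i] == "intron") "intron" else "exon"
        lab[(feats$start[i] + 1L):feats$end[i]] <- k
      }
      m[lab == what] <- TRUE
      if (!is.null(regions$a2))  # avoid the mirrored copy: plant outside arm2
        m[(regions$a2[1] + 1L):regions$a2[2]] <- FALSE
    }
    # keep clear of all region borders
    borders <- c(regions$a1, regions$s1, regions$a2, regions$s2, 0L, L)
    for (b in borders[!is.na(borders)]) {
      lo <- max(1L, b - margin); hi <- min(L, b + margin)
      m[lo:hi] <- FALSE
    }
    m
  }

  truth <- list()
  for (what in names(rates)) {
    m <- mask_for(what)
    target_len <- sum(m)
    if (region_mode && what == "IR") target_len <- armL
    n_plant <- round(rates[[what]] * target_len / 1000)
    placed <- 0L
    tries <- 0L
    while (placed < n_plant && tries < 50L * n_plant) {
      tries <- tries + 1L
      s <- sample.int(L - tl, 1L)     # 0-based start
      idx <- (s + 1L):(s + tl)
      if (!all(m[idx])) next
      lo <- max(1L, s + 1L - pad); hi <- min(L, s + tl + pad)
      if (any(occupied[lo:hi])) next
      gstrand <- sample(c("+", "-"), 1L)
      seq_t <- if (gstrand == "+") tmpl else rev(unname(COMP_BASES[tmpl]))
      g[idx] <- seq_t
      occupied[lo:hi] <- TRUE
      reg <- if (region_mode && what == "IR") "IR_copy1"
             else if (region_mode) "SC" else what
      truth[[length(truth) + 1L]] <- data.frame(
        start = s, end = s + tl, strand = gstrand, region = reg,
        compartment = if (region_mode) NA_character_ else what)
      placed <- placed + 1L
    }
    if (placed < n_plant)
      warning("placed ", placed, "/", n_plant, " motifs in ", what)
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(start = integer(0), end = integer(0),
                           strand = character(0), region = character(0),
                           compartment = character(0))
  # mirror arm1 motifs into arm2 (copying of the arm itself happens later,
  # so only the truth records are added here)
  if (!is.null(regions$a2) && nrow(truth)) {
    a1 <- regions$a1; a2 <- regions$a2
    inarm <- truth$start >= a1[1] & truth$end <= a1[2]
    mir <- truth[inarm, , drop = FALSE]
    if (nrow(mir)) {
      ns <- a2[1] + (armL - (mir$end - a1[1]))
      ne <- a2[1] + (armL - (mir$start - a1[1]))
      mir$start <- ns; mir$end <- ne
      mir$strand <- ifelse(mir$strand == "+", "-", "+")
      mir$region <- "IR_copy2"
      truth <- rbind(truth, mir)
    }
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(g = g, truth = truth)
}

#' Simulate a collapsed-assembly depth track
#'
#' Emulates the read-depth signal of an assembly in which the two identical
#' IR copies collapse onto one: the track covers the genome with arm2
#' dropped, Poisson(`depth_mean`) outside the repeat and
#' Poisson(`2 * depth_mean`) over arm1.
#'
#' @param truth A [generate_genome()] result (or any list with `genome` and
#'   `ir`).
#' @param depth_mean Mean single-copy depth (> 0).
#' @param seed Integer seed.
#' @return List: `depth` (per-base vector over the collapsed genome),
#'   `arm1` (0-based half-open interval of the doubled segment in collapsed
#'   coordinates, NULL without an IR).
#' @export
generate_depth <- function(truth, depth_mean = 100, seed = 1L) {
  if (depth_mean <= 0) stop("depth_mean must be positive")
  set.seed(seed, kind = "Mersenne-Twister")
  L <- truth$genome$length
  ir <- truth$ir
  if (is.null(ir)) {
    return(list(depth = stats::rpois(L, depth_mean), arm1 = NULL))
  }
  keep <- rep(TRUE, L)
  keep[(ir$arm2_start + 1L):ir$arm2_end] <- FALSE
  lambda <- rep(depth_mean, L)
  lambda[(ir$arm1_start + 1L):ir$arm1_end] <- 2 * depth_mean
  list(depth = stats::rpois(sum(keep), lambda[keep]),
       arm1 = c(ir$arm1_start, ir$arm1_end))
}

#' Simulate paired tip traits on a phylogeny
#'
#' `y` evolves by Brownian motion on the tree; the paired difference
#' `d = x - y` is multivariate normal with mean `mu` and covariance
#' `sigma^2 * V(lambda)` (Pagel's lambda transform of the Brownian
#' covariance). Returns the pair `(x, y)` for feeding
#' [phyl_paired_ttest()].
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param mu True mean paired difference.
#' @param sigma Scale of the difference process (>= 0).
#' @param lambda Pagel's lambda of the difference process.
#' @param seed Integer seed.
#' @param sigma_bm Scale of the baseline Brownian process (default 1).
#' @return List with named vectors `x`, `y` and `d`.
#' @export
simulate_paired_traits <- function(tree, mu = 0, sigma = 0.1, lambda = 1,
                                   seed = 1L, sigma_bm = 1) {
  set.seed(seed, kind = "Mersenne-Twister")
  n <- length(tree$tip.label)
  C <- ape::vcv.phylo(tree)
  y <- drop(t(chol(sigma_bm^2 * C)) %*% stats::rnorm(n))
  d <- rep(mu, n)
  if (sigma > 0) {
    Vl <- lambda * (C - diag(diag(C))) + diag(diag(C))
    d <- d + drop(t(chol(sigma^2 * Vl + diag(1e-12, n))) %*% stats::rnorm(n))
  }
  names(y) <- names(d) <- tree$tip.label
  list(x = y + d, y = y, d = d)
}
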