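# Independent oracles and fixture builders used across the suite.

random_seq <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Brute-force per-base G4 scores: for every position walk outward to find
# its run length (no rle; independent of the package implementation).
brute_base_scores <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (!b[i] %in% c("G", "C")) next
    k <- 1L
    j <- i - 1L
    while (j >= 1 && b[j] == b[i]) { k <- k + 1L; j <- j - 1L }
    j <- i + 1L
    while (j <= n && b[j] == b[i]) { k <- k + 1L; j <- j + 1L }
    out[i] <- if (b[i] == "G") min(k, 4) else -min(k, 4)
  }
  out
}

# Brute-force window scanner: enumerate every window with mean(), collect
# hits, merge naively by a linear sweep.
brute_g4_regions <- function(seq, w = 25, s = 1.7) {
  sc <- brute_base_scores(seq)
  n <- length(sc)
  if (n < w) return(data.frame(start = integer(0), end = integer(0)))
  hits <- list()
  for (i in 1:(n - w + 1)) {
    m <- mean(sc[i:(i + w - 1)])
    if (abs(m) >= s) hits[[length(hits) + 1L]] <- c(i, sign(m))
  }
  if (!length(hits)) return(data.frame(start = integer(0), end = integer(0)))
  h <- do.call(rbind, hits)
  regions <- list()
  cur_s <- h[1, 1]; cur_e <- h[1, 1] + w; cur_sign <- h[1, 2]
  for (r in seq_len(nrow(h))[-1]) {
    if (h[r, 1] <= cur_e && h[r, 2] == cur_sign) {
      cur_e <- h[r, 1] + w
    } else {
      regions[[length(regions) + 1L]] <- c(cur_s - 1L, cur_e - 1L)
      cur_s <- h[r, 1]; cur_e <- h[r, 1] + w; cur_sign <- h[r, 2]
    }
  }
  regions[[length(regions) + 1L]] <- c(cur_s - 1L, cur_e - 1L)
  m <- do.call(rbind, regions)
  data.frame(start = m[, 1], end = m[, 2])
}

# Textbook chi-square goodness of fit, written out longhand.
textbook_chisq <- function(obs, exp) {
  stat <- 0
  for (i in seq_along(obs)) stat <- stat + (obs[i] - exp[i])^2 / exp[i]
  df <- length(obs) - 1
  list(chi2 = stat, df = df, p = 1 - pchisq(stat, df))
}

# A small GenBank flat file written in code (keeps fixtures text-only and
# versioned with the tests).
write_mini_genbank <- function(path, seq, id = "TEST01", circular = TRUE,
                               features = character(0)) {
  n <- nchar(seq)
  lines <- c(
    sprintf("LOCUS       %s             %d bp    DNA     %s   PLN 01-JAN-2020",
            id, n, if (circular) "circular" else "linear"),
    sprintf("DEFINITION  synthetic test record %s.", id),
    "FEATURES             Location/Qualifiers",
    features,
    "ORIGIN")
  for (i in seq(1, n, by = 60)) {
    chunk <- substr(seq, i, min(i + 59, n))
    grp <- gsub("(.{10})", "\\1 ", chunk)
    lines <- c(lines, sprintf("%9d %s", i, tolower(grp)))
  }
  writeLines(c(lines, "//"), path)
  path
}
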