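#' Genome records
#'
#' A `GenomeRecord` is a named nucleotide sequence with a circular/linear
#' topology flag. Sequences are normalized on ingest: uppercased, and any
#' IUPAC ambiguity code other than `N` mapped to `N` (with a warning). `N`
#' bases score 0 in every downstream scan.
#'
#' @param id Character identifier.
#' @param sequence Nucleotide string; normalized to the `{A,C,G,T,N}` alphabet.
#' @param circular Logical topology flag.
#' @return An object of class `GenomeRecord`: a list with elements `id`,
#'   `sequence`, `circular` and `length` (bp).
#' @examples
#' g <- GenomeRecord("x", "acgn")
#' g$length
#' @export
GenomeRecord <- function(id, sequence, circular = FALSE) {
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence for genome '", id, "'")
  structure(
    list(id = as.character(id), sequence = sequence,
         circular = isTRUE(circular), length = nchar(sequence)),
    class = "GenomeRecord"
  )
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s': %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

# Uppercase and collapse ambiguity codes (other than N) to N.
normalize_sequence <- function(sequence) {
  s <- toupper(gsub("[ \t\r\n0-9]", "", sequence))
  bad <- gsub("[ACGTN]", "", s)
  if (nchar(bad) > 0L) {
    if (grepl("[^ACGTNRYSWKMBDHVU-]", bad))
      stop("sequence contains non-IUPAC characters: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
    warning(nchar(bad), " ambiguity/gap character(s) mapped to N")
    s <- gsub("[^ACGTN]", "N", s)
  }
  s
}

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character strings; `N` maps to `N`.
#'
#' @param sequence Nucleotide string over `{A,C,G,T,N}`.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Read a genome from FASTA or GenBank flat file
#'
#' Exactly one record per file is accepted. For GenBank input the LOCUS
#' topology word sets `circular`; FASTA defaults to linear unless `circular`
#' is supplied.
#'
#' @param path File path.
#' @param format `"fasta"` or `"genbank"`.
#' @param circular Optional logical overriding the topology flag.
#' @return A [GenomeRecord].
#' @export
read_genome <- function(path, format = c("fasta", "genbank"), circular = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) != 1L)
      stop("expected exactly one FASTA record, found ", length(set))
    id <- sub("\\s.*$", "", names(set)[1])
    rec <- GenomeRecord(id, as.character(set[[1]]),
                        circular = isTRUE(circular))
  } else {
    gb <- parse_genbank(path)
    rec <- GenomeRecord(gb$id, gb$sequence,
                        circular = if (is.null(circular)) gb$circular else circular)
    if (!is.null(gb$length) && gb$length != rec$length)
      warning("LOCUS length (", gb$length, ") differs from sequence length (",
              rec$length, ")")
  }
  rec
}

# Minimal GenBank flat-file parser: LOCUS, FEATURES and ORIGIN sections.
# Supports join()/complement() (possibly nested) feature locations.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  if (length(locus) > 1L) stop("expected exactly one GenBank record, found ", length(locus))
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  len <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1][1]))
  circ <- any(tolower(toks) == "circular")

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("GenBank record has no ORIGIN sequence block")
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1]][1] else length(lines) + 1L
  seqlines <- lines[(ori[1] + 1L):(endrec - 1L)]
  sequence <- gsub("[^A-Za-z]", "", paste(seqlines, collapse = ""))

  feat_start <- grep("^FEATURES", lines)
  features <- NULL
  if (length(feat_start)) {
    feat_lines <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]
    features <- parse_genbank_features(feat_lines)
  }
  list(id = id, length = len, circular = circ, sequence = sequence,
       features = features)
}

# Parse the FEATURES table into key / location / qualifier records.
parse_genbank_features <- function(feat_lines) {
  keep <- grepl("^ {4,}\\S", feat_lines)
  feat_lines <- feat_lines[keep]
  is_key <- grepl("^ {4,5}\\S", feat_lines) & !grepl("^ {6,}", feat_lines)
  idx <- cumsum(is_key)
  out <- list()
  for (i in seq_len(max(idx, 0))) {
    block <- feat_lines[idx == i]
    key <- sub("^\\s+", "", sub("^\\s+(\\S+).*$", "\\1", block[1]))
    rest <- sub("^\\s+\\S+\\s*", "", block[1])
    cont <- block[-1]
    qual_start <- grep("^\\s+/", cont)
    loc_extra <- if (length(qual_start)) cont[seq_len(min(qual_start) - 1)] else cont
    location <- gsub("\\s", "", paste(c(rest, trimws(loc_extra)), collapse = ""))
    quals <- character(0)
    if (length(qual_start)) {
      qlines <- trimws(cont[min(qual_start):length(cont)])
      # re-join continuation lines of quoted qualifier values
      joined <- character(0)
      for (q in qlines) {
        if (startsWith(q, "/")) joined <- c(joined, q)
        else if (length(joined)) joined[length(joined)] <- paste(joined[length(joined)], q)
      }
      quals <- joined
    }
    get_qual <- function(name) {
      hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
      if (!length(hit)) return(NA_character_)
      gsub('^"|"$', "", sub(paste0("^/", name, "="), "", hit[1]))
    }
    out[[i]] <- list(key = key, location = location,
                     gene = get_qual("gene"), product = get_qual("product"))
  }
  out
}

# Parse a GenBank location string into a strand and a matrix of 1-based
# inclusive segments (in biological order).
parse_gb_location <- function(loc) {
  strand <- "+"
  x <- loc
  while (grepl("^complement\\(", x)) {
    strand <- if (strand == "+") "-" else "+"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x) || grepl("^order\\(", x))
    x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
  parts <- strsplit(x, ",")[[1]]
  segs <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("complement", p)) p <- sub("^complement\\((.*)\\)$", "\\1", p)
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  }, integer(2)))
  dimnames(segs) <- NULL
  list(strand = strand, segments = segs)
}
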