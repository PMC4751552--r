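# Shared builders and independent brute-force oracles.

# -- observation-table builder ----------------------------------------------
# bases: character vector, one observation per element
mk_obs <- function(bases, pos = 100L, chrom = "c1", sample = "s1",
                   source = "RNA", strand = NULL, read_offset = NULL,
                   read_length = 101L, read_id = NULL) {
  n <- length(bases)
  data.table::data.table(
    sample = sample, source = source, chrom = chrom, pos = as.integer(pos),
    base = bases,
    strand = if (is.null(strand)) rep(c("+", "-"), length.out = n)
             else rep(strand, length.out = n),
    read_offset = if (is.null(read_offset)) rep(50L, n)
                  else as.integer(read_offset),
    read_length = as.integer(read_length),
    read_id = if (is.null(read_id)) sprintf("r%03d", seq_len(n)) else read_id)
}

mk_column <- function(bases, pos = 100L, source = "DNA", ...) {
  build_pileup(mk_obs(bases, pos = pos, source = source, ...),
               chrom = "c1", pos = pos)
}

mk_genome <- function(seq, name = "c1") {
  structure(stats::setNames(toupper(seq), name), class = "genome")
}

write_tmp <- function(lines, ext) {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# -- independent naive CIGAR walker -----------------------------------------
# Walks one base at a time; returns (pos, read_offset, base) for M/=/X ops.
oracle_cigar_walk <- function(pos, cigar, seq) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^\\d+", "", toks)
  ref <- pos
  off <- 0L
  g <- integer(0); o <- integer(0)
  for (k in seq_along(ops)) {
    for (u in seq_len(lens[k])) {
      if (ops[k] %in% c("M", "=", "X")) {
        g <- c(g, ref); o <- c(o, off)
        ref <- ref + 1L; off <- off + 1L
      } else if (ops[k] %in% c("I", "S")) {
        off <- off + 1L
      } else if (ops[k] %in% c("D", "N")) {
        ref <- ref + 1L
      }
    }
  }
  data.frame(pos = g, read_offset = o,
             base = substring(seq, o + 1L, o + 1L))
}

# random valid CIGAR + sequence; soft clips only at the ends
random_cigar_record <- function() {
  n_mid <- sample(1:5, 1)
  ops <- character(0)
  last <- ""
  for (i in seq_len(n_mid)) {
    op <- sample(setdiff(c("M", "I", "D", "N"), last), 1)
    # I/D/N must not be adjacent to each other at the boundaries of the walk
    if (i == 1 || i == n_mid) op <- "M"
    ops <- c(ops, op)
    last <- op
  }
  if (!any(ops == "M")) ops[1] <- "M"
  lens <- sample(1:12, length(ops), replace = TRUE)
  if (stats::runif(1) < 0.3) { ops <- c("S", ops); lens <- c(sample(1:5, 1), lens) }
  if (stats::runif(1) < 0.3) { ops <- c(ops, "S"); lens <- c(lens, sample(1:5, 1)) }
  cigar <- paste0(lens, ops, collapse = "")
  read_len <- sum(lens[ops %in% c("M", "I", "S")])
  seq <- paste(sample(c("A", "C", "G", "T"), read_len, replace = TRUE),
               collapse = "")
  list(pos = sample(1:5000, 1), cigar = cigar, seq = seq)
}

# -- quadratic brute-force tandem-repeat enumerator -------------------------
oracle_ssrs <- function(s, motif_min = 1L, motif_max = 6L, min_copies = 3L,
                        min_len = 9L) {
  n <- nchar(s)
  hits <- list()
  for (m in seq(motif_min, motif_max)) {
    for (i in seq_len(max(0L, n - 2L * m + 1L))) {
      motif <- substr(s, i, i + m - 1L)
      if (grepl("[^ACGT]", motif)) next
      # the period-m array must hold at i itself ...
      if (substr(s, i + m, i + m) != substr(s, i, i)) next
      # ... and be left-maximal at the character level
      if (i > 1L && substr(s, i - 1L, i - 1L) == substr(s, i - 1L + m,
                                                        i - 1L + m) &&
          !grepl("[^ACGT]", substr(s, i - 1L, i - 1L))) next
      # extend the perfect period-m array one character at a time
      arr_len <- m
      while (i + arr_len <= n &&
             substr(s, i + arr_len, i + arr_len) ==
               substr(s, i + arr_len - m, i + arr_len - m))
        arr_len <- arr_len + 1L
      copies <- arr_len %/% m
      if (copies < min_copies) next
      if (copies * m < min_len) next
      primitive <- TRUE
      if (m > 1L) for (d in seq_len(m - 1L)) {
        if (m %% d == 0L && strrep(substr(motif, 1L, d), m / d) == motif) {
          primitive <- FALSE; break
        }
      }
      if (!primitive) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = i, end = i + copies * m - 1L, motif = motif, copies = copies)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), copies = integer()))
  out <- unique(do.call(rbind, hits))
  out[order(out$start, out$end), , drop = FALSE]
}

random_repeat_string <- function(len = sample(10:50, 1)) {
  # biased toward repetitive content so SSRs actually occur
  alphabet <- if (stats::runif(1) < 0.5) c("A", "C") else c("A", "C", "G", "T")
  s <- sample(alphabet, len, replace = TRUE)
  if (stats::runif(1) < 0.5) {
    m <- sample(1:3, 1)
    copies <- sample(3:6, 1)
    ins <- rep(sample(alphabet, m, replace = TRUE), copies)
    at <- sample(seq_len(max(1, len - length(ins))), 1)
    s[at:(at + length(ins) - 1)] <- ins
  }
  paste(s, collapse = "")
}

# -- small two-exon gene with CDS, plus matching genome ---------------------
mk_coding_fixture <- function() {
  # genome: 1..400; gene 51..350, exons (51,150) and (201,350),
  # CDS (61,150,phase 0) and (201,310, phase computed): first segment 90 bp
  # (30 codons), so second starts in frame 0
  set.seed(99)
  g <- mk_genome(paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                       collapse = ""))
  gm <- gene_model("gX", "c1", "+", 51, 350,
                   exons = rbind(c(51, 150), c(201, 350)),
                   cds = rbind(c(61, 150, 0), c(201, 310, 0)))
  list(genome = g, model = gm)
}
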