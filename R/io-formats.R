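# Readers/writers for the plain-text formats the pipeline touches (FASTA,
# GFF3, SAM, FASTQ, TSV site tables) and conversion of alignments into
# per-base observations.

#' Read a reference genome from a FASTA file
#'
#' Sequences are uppercased and multi-line bodies concatenated. The result is
#' a named character vector of class \code{"genome"}, one element per record.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class \code{"genome"}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no records in FASTA file ", path)
  if (any(Biostrings::width(set) == 0L)) {
    bad <- names(set)[Biostrings::width(set) == 0L][1L]
    stop("empty sequence for FASTA record '", bad, "' in ", path)
  }
  seqs <- toupper(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(set))
  structure(seqs, class = "genome")
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", nm),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Retrieve reference bases by 1-based coordinates
#'
#' @param genome A \code{"genome"} object from \code{\link{read_fasta}}.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates; querying beyond the
#'   sequence length is an error.
#' @return Character scalar with the requested subsequence.
#' @export
genome_slice <- function(genome, chrom, start, end = start) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  n <- nchar(genome[[chrom]])
  if (start < 1L || end > n || start > end)
    stop("coordinates ", start, "-", end, " out of range for ", chrom,
         " (length ", n, ")")
  substr(genome[[chrom]], start, end)
}

#' @rdname genome_slice
#' @param pos 1-based position.
#' @export
genome_base <- function(genome, chrom, pos) genome_slice(genome, chrom, pos, pos)

seq_length <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  nchar(genome[[chrom]])
}

rc_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# ---- gene models -----------------------------------------------------------

#' Construct a gene model
#'
#' Exons and CDS are stored in genomic coordinates (1-based inclusive)
#' regardless of strand; \code{strand} carries the orientation.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param start,end Gene span, 1-based inclusive.
#' @param exons Two-column matrix (start, end), one row per exon.
#' @param cds Optional three-column matrix (start, end, frame); frame is the
#'   number of bases to skip before the first complete codon of the segment
#'   that starts translation.
#' @return An object of class \code{"gene_model"}.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, exons,
                       cds = matrix(numeric(0), ncol = 3)) {
  exons <- matrix(as.integer(exons), ncol = 2)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) == 0L) stop("gene ", gene_id, " has no exons")
  if (any(exons[, 1L] > exons[, 2L])) stop("exon with start > end in ", gene_id)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("overlapping exons in gene ", gene_id)
  if (any(exons[, 1L] < start) || any(exons[, 2L] > end))
    stop("exon outside gene span in gene ", gene_id)
  cds <- matrix(as.numeric(cds), ncol = 3)
  if (nrow(cds)) {
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    in_exon <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1L] <= cds[i, 1L] & exons[, 2L] >= cds[i, 2L])
    }, logical(1))
    if (!all(in_exon)) stop("CDS outside exon span in gene ", gene_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 gene_start = as.integer(start), gene_end = as.integer(end),
                 exons = exons, cds = cds),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Assembles one \code{\link{gene_model}} per \code{gene} feature, following
#' \code{Parent} links through mRNA/transcript features to exons and CDS.
#' Exons from multiple transcripts of one gene are merged into a
#' non-overlapping set.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of \code{"gene_model"} objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("no features in GFF3 file ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L))
    stop("malformed GFF3 line (expected 9 columns) in ", path)
  m <- do.call(rbind, fields)
  attr_field <- function(attrs, key) {
    m <- regexpr(paste0("(^|;)", key, "=[^;]*"), attrs)
    out <- rep(NA_character_, length(attrs))
    out[m > 0] <- sub(paste0("^;?", key, "="), "", regmatches(attrs, m))
    out
  }
  feat <- data.table::data.table(
    chrom = m[, 1L], type = m[, 3L],
    start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
    strand = m[, 7L], frame = m[, 8L],
    id = attr_field(m[, 9L], "ID"), parent = attr_field(m[, 9L], "Parent"))
  genes <- feat[feat$type == "gene", ]
  if (!nrow(genes)) stop("no gene features in GFF3 file ", path)
  # map every transcript-level feature to its gene
  tx <- feat[feat$type %in% c("mRNA", "transcript"), ]
  tx2gene <- stats::setNames(tx$parent, tx$id)
  resolve_gene <- function(parent) {
    ifelse(parent %in% genes$id, parent,
           unname(tx2gene[parent]))
  }
  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    kids_ex <- feat[feat$type == "exon" & resolve_gene(feat$parent) %in% g$id, ]
    kids_cds <- feat[feat$type == "CDS" & resolve_gene(feat$parent) %in% g$id, ]
    exons <- if (nrow(kids_ex)) {
      merge_intervals(cbind(kids_ex$start, kids_ex$end))
    } else cbind(g$start, g$end)
    if (any(exons[, 1L] < g$start) || any(exons[, 2L] > g$end))
      stop("exon outside gene span for gene ", g$id, " in ", path)
    cds <- if (nrow(kids_cds)) {
      cbind(kids_cds$start, kids_cds$end,
            suppressWarnings(as.numeric(kids_cds$frame)))
    } else matrix(numeric(0), ncol = 3)
    gene_model(g$id, g$chrom, g$strand, g$start, g$end, exons, cds)
  })
  stats::setNames(models, genes$id)
}

merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] <= out[nrow(out), 2L] + 0L) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[i, 2L])
    } else out <- rbind(out, iv[i, ])
  }
  out
}

#' Write gene models to a GFF3 file
#'
#' @param models List of \code{"gene_model"} objects.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (gm in models) {
    gid <- gm$gene_id
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
      paste(gm$chrom, "editscreen", "gene", gm$gene_start, gm$gene_end, ".",
            gm$strand, ".", paste0("ID=", gid), sep = "\t"),
      paste(gm$chrom, "editscreen", "mRNA", gm$gene_start, gm$gene_end, ".",
            gm$strand, ".", paste0("ID=", tid, ";Parent=", gid), sep = "\t"))
    for (i in seq_len(nrow(gm$exons)))
      lines <- c(lines, paste(gm$chrom, "editscreen", "exon",
                              gm$exons[i, 1L], gm$exons[i, 2L], ".",
                              gm$strand, ".", paste0("Parent=", tid),
                              sep = "\t"))
    for (i in seq_len(nrow(gm$cds)))
      lines <- c(lines, paste(gm$chrom, "editscreen", "CDS",
                              gm$cds[i, 1L], gm$cds[i, 2L], ".", gm$strand,
                              gm$cds[i, 3L], paste0("Parent=", tid),
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- SAM -------------------------------------------------------------------

#' Read aligned records from a SAM file
#'
#' Only the fields the pipeline uses are kept. Unmapped records (FLAG bit
#' 0x4, or missing RNAME/CIGAR) are dropped.
#'
#' @param path Path to a coordinate-sorted SAM file.
#' @return \code{data.table} with columns qname, flag, chrom, pos, cigar, seq,
#'   strand.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.table::data.table(qname = character(), flag = integer(),
                                  chrom = character(), pos = integer(),
                                  cigar = character(), seq = character(),
                                  strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 11L
  if (any(bad)) stop("malformed SAM record at data line ", which(bad)[1L],
                     " in ", path)
  m <- vapply(fields, function(x) x[1:10], character(10))
  dt <- data.table::data.table(
    qname = m[1L, ], flag = as.integer(m[2L, ]), chrom = m[3L, ],
    pos = as.integer(m[4L, ]), cigar = m[6L, ], seq = m[10L, ])
  dt <- dt[!bitwAnd(dt$flag, 4L) & dt$chrom != "*" & dt$cigar != "*", ]
  dt$strand <- ifelse(bitwAnd(dt$flag, 16L) > 0L, "-", "+")
  dt
}

parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(toks) || paste(toks, collapse = "") != cigar)
    stop("invalid CIGAR: ", cigar)
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

#' Convert SAM alignments to per-base observations
#'
#' Walks each record's CIGAR and emits one row per aligned M/=/X base:
#' S and I consume read only, D and N consume reference only, H and P
#' consume nothing. \code{read_offset} is the 0-based index of the base in
#' the stored read sequence. Records whose CIGAR read-length disagrees with
#' the stored sequence are skipped with a warning.
#'
#' @param sam Path to a SAM file, or a \code{data.table} from
#'   \code{\link{read_sam}}.
#' @param sample Sample identifier attached to every observation.
#' @param source \code{"DNA"} or \code{"RNA"}.
#' @return \code{data.table} with columns sample, source, chrom, pos, base,
#'   strand, read_offset, read_length, read_id.
#' @export
extract_observations <- function(sam, sample, source = c("DNA", "RNA")) {
  source <- match.arg(source)
  recs <- if (is.character(sam)) read_sam(sam) else sam
  pos_out <- vector("list", nrow(recs))
  off_out <- vector("list", nrow(recs))
  n_emitted <- integer(nrow(recs))
  n_skipped <- 0L
  for (i in seq_len(nrow(recs))) {
    cig <- tryCatch(parse_cigar(recs$cigar[i]), error = function(e) NULL)
    if (is.null(cig)) { n_skipped <- n_skipped + 1L; next }
    read_consumed <- sum(cig$len[cig$op %in% c("M", "I", "S", "=", "X")])
    if (read_consumed != nchar(recs$seq[i])) { n_skipped <- n_skipped + 1L; next }
    pos_list <- vector("list", length(cig$op))
    off_list <- vector("list", length(cig$op))
    ref_pos <- recs$pos[i]
    off <- 0L
    for (j in seq_along(cig$op)) {
      op <- cig$op[j]; l <- cig$len[j]
      if (op %in% c("M", "=", "X")) {
        pos_list[[j]] <- ref_pos + 0:(l - 1L)
        off_list[[j]] <- off + 0:(l - 1L)
        ref_pos <- ref_pos + l
        off <- off + l
      } else if (op %in% c("I", "S")) {
        off <- off + l
      } else if (op %in% c("D", "N")) {
        ref_pos <- ref_pos + l
      }
    }
    pos_out[[i]] <- unlist(pos_list)
    off_out[[i]] <- unlist(off_list)
    n_emitted[i] <- length(pos_out[[i]])
  }
  if (n_skipped > 0L)
    warning(n_skipped, " SAM record(s) skipped (CIGAR/sequence mismatch)")
  gp <- as.integer(unlist(pos_out))
  ro <- as.integer(unlist(off_out))
  rep_i <- rep(seq_len(nrow(recs)), n_emitted)
  obs <- data.table::data.table(
    chrom = recs$chrom[rep_i], pos = gp,
    base = substring(recs$seq[rep_i], ro + 1L, ro + 1L),
    strand = recs$strand[rep_i],
    read_offset = ro,
    read_length = nchar(recs$seq)[rep_i],
    read_id = recs$qname[rep_i])
  obs[, `:=`(sample = sample, source = source)]
  data.table::setcolorder(obs, c("sample", "source", "chrom", "pos", "base",
                                 "strand", "read_offset", "read_length",
                                 "read_id"))
  obs[]
}

# ---- FASTQ -----------------------------------------------------------------

#' Read raw reads from a FASTQ file
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return \code{data.table} with columns read_id, seq, mate. The mate number
#'   is taken from a trailing \code{/1} or \code{/2} on the read name
#'   (default 1).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record in ", path, " (", length(lines), " lines)")
  if (!length(lines))
    return(data.table::data.table(read_id = character(), seq = character(),
                                  mate = integer()))
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  if (!all(startsWith(ids, "@")))
    stop("malformed FASTQ header in ", path)
  if (any(!nzchar(seqs))) stop("empty read sequence in ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", ids))
  mate <- ifelse(grepl("/2$", ids), 2L, 1L)
  data.table::data.table(read_id = sub("/[12]$", "", ids), seq = seqs,
                         mate = mate)
}

#' Write raw reads to a FASTQ file
#'
#' @param reads \code{data.table} with columns read_id, seq and optionally
#'   mate.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  mate <- if ("mate" %in% names(reads)) paste0("/", reads$mate) else ""
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", reads$read_id, mate),
                             reads$seq, "+", qual)), path)
  invisible(path)
}

# ---- site tables -----------------------------------------------------------

site_table_cols <- c("tissue", "chrom", "pos", "dna_allele", "rna_allele",
                     "canonical", "replicates", "gene_names", "localization")

#' Read a TSV site table
#'
#' The format mirrors the published per-tissue site listing: one row per
#' editing event with tissue, position, alleles, canonical status, replicate
#' support, gene names and localization.
#'
#' @param path Path to a tab-separated site table with a header line.
#' @return \code{data.table} with character chrom and integer pos/replicates.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("tissue", "chrom",
                                                          "dna_allele",
                                                          "rna_allele",
                                                          "canonical",
                                                          "gene_names",
                                                          "localization"),
                                            integer = c("pos", "replicates")),
                          na.strings = NULL)
  missing <- setdiff(site_table_cols, names(dt))
  if (length(missing))
    stop("site table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  dt
}

#' Write a TSV site table
#'
#' Serialization round-trips: \code{read_site_table(write_site_table(x, p))}
#' reproduces \code{x} field for field.
#'
#' @param records \code{data.table} of site records.
#' @param path Output path.
#' @export
write_site_table <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Load the packaged published site-table fixture
#'
#' A transcription of the study's per-tissue list of replicated editing
#' events (19 adipose + 11 liver rows) used by the desk-scale checks.
#'
#' @return \code{data.table} of 30 site records.
#' @export
table2_sites <- function() {
  read_site_table(system.file("extdata", "table2_sites.tsv",
                              package = "editscreen", mustWork = TRUE))
}
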