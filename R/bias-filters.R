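# The five artifact filters applied to every candidate editing site:
# read-extremity bias, strand bias, splice-junction proximity, homopolymer /
# simple-sequence-repeat context, and multimapping control via an exact
# search of the edited-allele consensus in raw DNA reads.

#' Flag read-extremity bias
#'
#' A candidate is biased when the edited allele is mostly supported by bases
#' lying in the first or last \code{end_window} positions of their reads.
#' Only the distribution of the edited base is considered; distance to the
#' nearer read end is \code{min(read_offset, read_length - 1 - read_offset)}.
#'
#' @param candidate \code{"candidate_site"} or list with chrom, pos,
#'   rna_allele.
#' @param rna_obs RNA observations of the sample (any superset of the site's
#'   column; restricted internally to edited-allele observations at the
#'   site).
#' @param end_window Window size in bp at each read end (default 10).
#' @param max_end_frac Fraction above which the site is flagged (default 0.5,
#'   i.e. a strict majority).
#' @return Logical flag; attribute \code{"end_frac"} carries the fraction.
#' @export
flag_extremity_bias <- function(candidate, rna_obs, end_window = 10L,
                                max_end_frac = 0.5) {
  ed <- rna_obs[rna_obs$chrom == candidate$chrom &
                  rna_obs$pos == candidate$pos &
                  rna_obs$base == candidate$rna_allele, ]
  if (!nrow(ed))
    stop("no observations of the edited allele at ",
         candidate$chrom, ":", candidate$pos)
  dist_end <- pmin(ed$read_offset, ed$read_length - 1L - ed$read_offset)
  frac <- mean(dist_end < end_window)
  structure(frac > max_end_frac, end_frac = frac)
}

#' Flag strand bias
#'
#' With p_f the fraction of forward-strand reads at the site that carry the
#' edited allele and p_r the same for the reverse strand, the site is biased
#' when |p_f - p_r| exceeds \code{delta_max}. A strand with zero coverage is
#' treated as maximally imbalanced and flagged.
#'
#' @inheritParams flag_extremity_bias
#' @param delta_max Imbalance threshold (default 0.5).
#' @return Logical flag; attribute \code{"delta"} carries the imbalance.
#' @export
flag_strand_bias <- function(candidate, rna_obs, delta_max = 0.5) {
  col <- rna_obs[rna_obs$chrom == candidate$chrom &
                   rna_obs$pos == candidate$pos &
                   rna_obs$base %in% BASES, ]
  n_f <- sum(col$strand == "+")
  n_r <- sum(col$strand == "-")
  if (n_f == 0L || n_r == 0L) return(structure(TRUE, delta = NA_real_))
  p_f <- sum(col$strand == "+" & col$base == candidate$rna_allele) / n_f
  p_r <- sum(col$strand == "-" & col$base == candidate$rna_allele) / n_r
  delta <- abs(p_f - p_r)
  structure(delta > delta_max, delta = delta)
}

#' Flag splice-junction proximity
#'
#' A site is biased when it lies within 1-3 bases of the exon side or 3-8
#' bases of the intron side of any annotated exon-intron junction, counting
#' distance 1 as the base immediately adjacent to the junction on each side.
#'
#' @inheritParams flag_extremity_bias
#' @param gene_models List of \code{"gene_model"} objects.
#' @param exon_range,intron_range Inclusive distance windows on each side.
#' @return Logical flag; attribute \code{"junction_dist"} carries the
#'   smallest triggering distance (NA when unflagged).
#' @export
flag_splice_bias <- function(candidate, gene_models,
                             exon_range = c(1L, 3L),
                             intron_range = c(3L, 8L)) {
  pos <- candidate$pos
  for (gm in gene_models) {
    if (gm$chrom != candidate$chrom) next
    ex <- gm$exons
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      # junction after exon i: intron is (ex[i,2]+1) .. (ex[i+1,1]-1)
      # exon side of the donor (end of exon i)
      d_exon <- ex[i, 2L] - pos + 1L
      if (pos <= ex[i, 2L] && pos >= ex[i, 1L] &&
          d_exon >= exon_range[1L] && d_exon <= exon_range[2L])
        return(structure(TRUE, junction_dist = d_exon))
      d_intron <- pos - ex[i, 2L]
      if (pos > ex[i, 2L] && pos < ex[i + 1L, 1L] &&
          d_intron >= intron_range[1L] && d_intron <= intron_range[2L])
        return(structure(TRUE, junction_dist = d_intron))
      # acceptor (start of exon i+1)
      d_exon2 <- pos - ex[i + 1L, 1L] + 1L
      if (pos >= ex[i + 1L, 1L] && pos <= ex[i + 1L, 2L] &&
          d_exon2 >= exon_range[1L] && d_exon2 <= exon_range[2L])
        return(structure(TRUE, junction_dist = d_exon2))
      d_intron2 <- ex[i + 1L, 1L] - pos
      if (pos < ex[i + 1L, 1L] && pos > ex[i, 2L] &&
          d_intron2 >= intron_range[1L] && d_intron2 <= intron_range[2L])
        return(structure(TRUE, junction_dist = d_intron2))
    }
  }
  structure(FALSE, junction_dist = NA_integer_)
}

#' Flag homopolymer context
#'
#' Biased when the \code{run_len} reference bases immediately 5' of the site
#' are all identical, or the \code{run_len} bases immediately 3' are. Near a
#' contig end only the available side(s) are evaluated.
#'
#' @inheritParams flag_extremity_bias
#' @param genome Reference \code{"genome"}.
#' @param run_len Number of neighboring positions required (default 4).
#' @return Logical flag.
#' @export
flag_homopolymer <- function(candidate, genome, run_len = 4L) {
  n <- seq_length(genome, candidate$chrom)
  pos <- candidate$pos
  one_base_run <- function(s) {
    nchar(s) == run_len && length(unique(strsplit(s, "")[[1L]])) == 1L
  }
  left <- if (pos - run_len >= 1L)
    genome_slice(genome, candidate$chrom, pos - run_len, pos - 1L) else ""
  right <- if (pos + run_len <= n)
    genome_slice(genome, candidate$chrom, pos + 1L, pos + run_len) else ""
  one_base_run(left) || one_base_run(right)
}

#' Find perfect simple sequence repeats (SSRs)
#'
#' Enumerates maximal perfect tandem repeats of primitive motifs of length
#' \code{motif_min}..\code{motif_max} with at least \code{min_copies} full
#' copies and total length at least \code{min_len}. Partial trailing copies
#' are not counted, so every reported interval length equals
#' \code{nchar(motif) * copies}.
#'
#' @param seq Nucleotide string over A/C/G/T (N breaks all repeats).
#' @param motif_min,motif_max Motif length bounds (default 1-6).
#' @param min_copies Minimum full copies (default 3).
#' @param min_len Minimum total repeat length in bp (default 9).
#' @return \code{data.table} with columns start, end (1-based inclusive,
#'   relative to \code{seq}), motif, copies.
#' @export
find_ssrs <- function(seq, motif_min = 1L, motif_max = 6L, min_copies = 3L,
                      min_len = 9L) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  hits <- list()
  for (m in seq(motif_min, motif_max)) {
    if (n < 2L * m) next
    eq <- chars[seq_len(n - m)] == chars[seq_len(n - m) + m] &
      chars[seq_len(n - m)] %in% BASES
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- r$lengths[k]             # matched comparisons
      total <- run + m                # bp of perfect tandem (incl. partial)
      copies <- total %/% m
      if (copies < min_copies) next
      start <- starts[k]
      end <- start + copies * m - 1L
      if (end - start + 1L < min_len) next
      motif <- paste(chars[start:(start + m - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next
      hits[[length(hits) + 1L]] <-
        list(start = start, end = end, motif = motif, copies = copies)
    }
  }
  if (!length(hits))
    return(data.table::data.table(start = integer(), end = integer(),
                                  motif = character(), copies = integer()))
  out <- data.table::rbindlist(hits)
  out <- unique(out)
  data.table::setorder(out, start, end)
  out[]
}

is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L && strrep(substr(motif, 1L, d), m / d) == motif)
      return(FALSE)
  }
  TRUE
}

#' Find SSRs in a genomic window
#'
#' Convenience wrapper around \code{\link{find_ssrs}} that reports genomic
#' coordinates.
#'
#' @param genome Reference \code{"genome"}.
#' @param chrom Chromosome.
#' @param start,end Window, clipped to the contig.
#' @param ... Passed to \code{\link{find_ssrs}}.
#' @export
find_ssrs_genome <- function(genome, chrom, start, end, ...) {
  start <- max(1L, start)
  end <- min(seq_length(genome, chrom), end)
  ssrs <- find_ssrs(genome_slice(genome, chrom, start, end), ...)
  ssrs$start <- ssrs$start + start - 1L
  ssrs$end <- ssrs$end + start - 1L
  ssrs
}

#' Flag SSR context
#'
#' Biased when any SSR interval, expanded by \code{offset} bases on both
#' sides, contains the candidate position.
#'
#' @inheritParams flag_extremity_bias
#' @param ssrs SSR table in genomic coordinates
#'   (\code{\link{find_ssrs_genome}}).
#' @param offset Expansion in bp (default 3).
#' @return Logical flag.
#' @export
flag_ssr <- function(candidate, ssrs, offset = 3L) {
  if (!nrow(ssrs)) return(FALSE)
  any(ssrs$start - offset <= candidate$pos &
        ssrs$end + offset >= candidate$pos)
}

#' Build the edited-allele consensus sequence
#'
#' A \code{length}-bp consensus centered on the edited allele, built from the
#' pileup of RNA reads that carry the edited allele at the site. Each flank
#' position takes the majority base among those reads' observations; ties
#' break toward the reference, and positions covered by no edited read take
#' the reference base. The center (0-based index
#' \code{ceiling(length/2) - 1}, i.e. 19 for the default 40-mer) carries the
#' edited allele. Windows clipped at contig ends are shorter and flagged.
#'
#' @inheritParams flag_extremity_bias
#' @param genome Reference \code{"genome"}.
#' @param length Consensus length in bp (default 40).
#' @return List of class \code{"consensus_sequence"} with \code{seq},
#'   \code{center_index} (0-based) and \code{truncated}.
#' @export
build_edited_consensus <- function(candidate, rna_obs, genome, length = 40L) {
  chrom <- candidate$chrom; pos <- candidate$pos
  left <- ceiling(length / 2) - 1L
  right <- length - left - 1L
  lo <- pos - left
  hi <- pos + right
  n <- seq_length(genome, chrom)
  truncated <- lo < 1L || hi > n
  lo <- max(1L, lo); hi <- min(n, hi)
  carriers <- unique(rna_obs$read_id[rna_obs$chrom == chrom &
                                       rna_obs$pos == pos &
                                       rna_obs$base == candidate$rna_allele])
  if (!length(carriers))
    stop("no RNA read supports the edited allele at ", chrom, ":", pos)
  in_win <- rna_obs[["chrom"]] == chrom & rna_obs[["pos"]] >= lo &
    rna_obs[["pos"]] <= hi & rna_obs[["read_id"]] %in% carriers &
    rna_obs[["base"]] %in% BASES
  win <- rna_obs[which(in_win), ]
  ref <- strsplit(genome_slice(genome, chrom, lo, hi), "")[[1L]]
  cons <- ref
  if (nrow(win)) {
    for (p in unique(win$pos)) {
      cnt <- table(factor(win$base[win$pos == p], levels = BASES))
      best <- max(cnt)
      i <- p - lo + 1L
      if (best == 0L) next
      top <- BASES[cnt == best]
      cons[i] <- if (ref[i] %in% top) ref[i] else top[1L]
    }
  }
  cons[pos - lo + 1L] <- candidate$rna_allele
  structure(list(seq = paste(cons, collapse = ""),
                 center_index = pos - lo,
                 truncated = truncated),
            class = "consensus_sequence")
}

#' Flag multimapping via raw-read consensus search
#'
#' Biased when the consensus occurs as an exact substring of any raw genomic
#' DNA read of the same sample, or of its reverse complement. With
#' \code{max_mismatch > 0} a Hamming-tolerant search is used instead.
#'
#' @param consensus \code{"consensus_sequence"} or a plain string.
#' @param dna_reads Character vector of raw DNA read sequences (including
#'   unaligned reads), or a \code{data.table} from \code{\link{read_fastq}}.
#' @param max_mismatch Allowed mismatches (default 0, exact).
#' @return Logical flag.
#' @export
flag_multimapping <- function(consensus, dna_reads, max_mismatch = 0L) {
  pat <- if (inherits(consensus, "consensus_sequence")) consensus$seq
         else consensus
  reads <- if (is.data.frame(dna_reads)) dna_reads$seq else dna_reads
  if (!length(reads)) {
    warning("empty DNA read set; multimapping flag defaults to FALSE")
    return(FALSE)
  }
  pats <- c(pat, rc_string(pat))
  if (max_mismatch == 0L) {
    return(any(grepl(pats[1L], reads, fixed = TRUE)) ||
             any(grepl(pats[2L], reads, fixed = TRUE)))
  }
  subj <- Biostrings::DNAStringSet(reads)
  any(vapply(pats, function(p) {
    sum(Biostrings::vcountPattern(p, subj, max.mismatch = max_mismatch)) > 0L
  }, logical(1)))
}

#' Evaluate all six artifact flags for a candidate
#'
#' All flags are computed independently (no short-circuiting) so that
#' per-filter attrition can be reported. The SSR scan covers the window
#' \code{pos +/- ssr_window} around the site.
#'
#' @param candidate \code{"candidate_site"} or compatible list.
#' @param context List with elements \code{genome}, \code{gene_models},
#'   \code{rna_obs} (the sample's RNA observations, at least covering the
#'   consensus window) and \code{dna_reads} (raw DNA read sequences of the
#'   same sample).
#' @param end_window,max_end_frac,delta_max,run_len,ssr_offset,consensus_len,
#'   max_mismatch,ssr_window Filter tuning knobs; defaults follow the
#'   screening protocol.
#' @return List of class \code{"bias_flags"} with the six logical verdicts
#'   (extremity, strand, splice, homopolymer, ssr, multimapping) and a
#'   \code{diagnostics} list.
#' @export
apply_filters <- function(candidate, context, end_window = 10L,
                          max_end_frac = 0.5, delta_max = 0.5, run_len = 4L,
                          ssr_offset = 3L, consensus_len = 40L,
                          max_mismatch = 0L, ssr_window = 25L) {
  ext <- flag_extremity_bias(candidate, context$rna_obs, end_window,
                             max_end_frac)
  std <- flag_strand_bias(candidate, context$rna_obs, delta_max)
  spl <- flag_splice_bias(candidate, context$gene_models)
  hp <- flag_homopolymer(candidate, context$genome, run_len)
  ssrs <- find_ssrs_genome(context$genome, candidate$chrom,
                           candidate$pos - ssr_window,
                           candidate$pos + ssr_window)
  ssr <- flag_ssr(candidate, ssrs, ssr_offset)
  cons <- build_edited_consensus(candidate, context$rna_obs, context$genome,
                                 consensus_len)
  mm <- flag_multimapping(cons, context$dna_reads, max_mismatch)
  structure(list(extremity = as.logical(ext), strand = as.logical(std),
                 splice = as.logical(spl), homopolymer = hp, ssr = ssr,
                 multimapping = mm,
                 diagnostics = list(end_frac = attr(ext, "end_frac"),
                                    delta = attr(std, "delta"),
                                    junction_dist = attr(spl, "junction_dist"),
                                    n_ssrs = nrow(ssrs),
                                    consensus = cons$seq,
                                    consensus_truncated = cons$truncated)),
            class = "bias_flags")
}

#' Is a candidate free of all six artifact flags?
#'
#' @param flags \code{"bias_flags"} object.
#' @return Logical.
#' @export
is_unbiased <- function(flags) {
  !any(unlist(flags[c("extremity", "strand", "splice", "homopolymer",
                      "ssr", "multimapping")]))
}
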