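# Per-position pileups for matched DNA/RNA of one sample and the
# candidate-detection criteria: DNA strictly homozygous by counts (MAF = 1),
# RNA carrying exactly one alternative allele, both depths >= 15.

BASES <- c("A", "C", "G", "T")

#' Build a pileup column at one position
#'
#' @param observations \code{data.table} of per-base observations
#'   (\code{\link{extract_observations}}).
#' @param chrom,pos Position to pile up (1-based).
#' @param max_depth Depth cap; observations beyond it (in input order) are
#'   discarded, mirroring a pileup engine's coverage ceiling.
#' @return Object of class \code{"pileup_column"} with fields chrom, pos,
#'   sample, source and obs (the restricted observation table). Deletions and
#'   reference skips contribute nothing because they emit no observation.
#' @export
build_pileup <- function(observations, chrom, pos, max_depth = 10000L) {
  sel <- observations[["chrom"]] == chrom & observations[["pos"]] == pos
  obs <- observations[which(sel), ]
  if (nrow(obs) > max_depth) obs <- obs[seq_len(max_depth), ]
  structure(list(chrom = chrom, pos = as.integer(pos),
                 sample = if (nrow(obs)) obs$sample[1L] else NA_character_,
                 source = if (nrow(obs)) obs$source[1L] else NA_character_,
                 obs = obs),
            class = "pileup_column")
}

#' @export
print.pileup_column <- function(x, ...) {
  cat("<pileup_column> ", x$chrom, ":", x$pos, " ", x$source,
      " depth=", nrow(x$obs), "\n", sep = "")
  invisible(x)
}

#' Count alleles in a pileup column
#'
#' N bases never count as allele support; depth is the sum of A/C/G/T counts.
#'
#' @param column A \code{"pileup_column"} (or its \code{obs} table).
#' @return List with \code{counts} (named integer over A,C,G,T), per-strand
#'   splits \code{fwd}/\code{rev}, and \code{depth}.
#' @export
allele_counts <- function(column) {
  obs <- if (inherits(column, "pileup_column")) column$obs else column
  obs <- obs[obs$base %in% BASES, ]
  cnt <- function(sub) {
    v <- table(factor(sub$base, levels = BASES))
    stats::setNames(as.integer(v), BASES)
  }
  counts <- cnt(obs)
  structure(list(counts = counts,
                 fwd = cnt(obs[obs$strand == "+", ]),
                 rev = cnt(obs[obs$strand == "-", ]),
                 depth = sum(counts)),
            class = "allele_counts")
}

#' Call the genomic-DNA genotype at one position
#'
#' The site is homozygous iff the majority allele's frequency is at least
#' \code{1 - max_discordant_frac}; with the strict default every read must
#' support a single allele (counting MAF = 1), whether that allele matches
#' the reference or not.
#'
#' @param column DNA \code{"pileup_column"}.
#' @param max_discordant_frac Tolerated fraction of discordant reads
#'   (default 0, strictly homozygous).
#' @return List with \code{allele}, \code{maf} (majority allele frequency),
#'   \code{is_homozygous} and \code{depth}; an empty column yields a no-call
#'   (\code{allele = NA}).
#' @export
call_dna_genotype <- function(column, max_discordant_frac = 0) {
  ac <- allele_counts(column)
  if (ac$depth == 0L)
    return(list(allele = NA_character_, maf = NA_real_,
                is_homozygous = FALSE, depth = 0L))
  allele <- BASES[which.max(ac$counts)]
  maf <- ac$counts[[allele]] / ac$depth
  list(allele = allele, maf = maf,
       is_homozygous = maf >= 1 - max_discordant_frac,
       depth = ac$depth)
}

#' Determine which alleles the RNA pileup supports
#'
#' @param column RNA \code{"pileup_column"}.
#' @param min_alt_reads Minimum read count for an allele to be supported.
#' @param min_alt_frac Minimum fraction of depth for support.
#' @return Character vector of supported bases (possibly empty).
#' @export
call_rna_alleles <- function(column, min_alt_reads = 2L, min_alt_frac = 0) {
  ac <- allele_counts(column)
  if (ac$depth == 0L) return(character(0))
  BASES[ac$counts >= min_alt_reads & ac$counts / ac$depth >= min_alt_frac &
          ac$counts > 0L]
}

#' Detect a candidate editing site from matched DNA/RNA columns
#'
#' A candidate requires: strictly homozygous DNA (allele A), RNA supporting
#' exactly the alleles \{A,B\} or \{B\} with a single alternative B != A
#' (positions with two or more alternative alleles are triallelic and
#' excluded), and depth of at least \code{min_cov} in both DNA and RNA.
#' Indels never reach this function because deletions and skips emit no
#' observation.
#'
#' @param dna_column,rna_column Matched pileup columns at the same position.
#' @param min_cov Minimum depth in both sources (default 15).
#' @param min_alt_reads,min_alt_frac RNA allele-support thresholds.
#' @param max_discordant_frac DNA homozygosity tolerance.
#' @return A list of class \code{"candidate_site"} or \code{NULL}.
#' @export
detect_candidates <- function(dna_column, rna_column, min_cov = 15L,
                              min_alt_reads = 2L, min_alt_frac = 0,
                              max_discordant_frac = 0) {
  if (dna_column$chrom != rna_column$chrom ||
      dna_column$pos != rna_column$pos)
    stop("DNA and RNA columns are at different positions")
  gt <- call_dna_genotype(dna_column, max_discordant_frac)
  if (!gt$is_homozygous || gt$depth < min_cov) return(NULL)
  rna_ac <- allele_counts(rna_column)
  if (rna_ac$depth < min_cov) return(NULL)
  supported <- call_rna_alleles(rna_column, min_alt_reads, min_alt_frac)
  alt <- setdiff(supported, gt$allele)
  if (length(alt) != 1L) return(NULL)  # none, or triallelic
  structure(list(sample = rna_column$sample,
                 chrom = dna_column$chrom, pos = dna_column$pos,
                 dna_allele = gt$allele, rna_allele = alt,
                 dna_counts = allele_counts(dna_column),
                 rna_counts = rna_ac),
            class = "candidate_site")
}

#' Genome-wide candidate detection for one sample
#'
#' Vectorized equivalent of applying \code{\link{detect_candidates}} at every
#' covered position, used by the pipeline driver.
#'
#' @param dna_obs,rna_obs Observation tables for the sample's DNA and RNA
#'   alignments.
#' @inheritParams detect_candidates
#' @param max_depth Per-position depth cap applied in input order.
#' @return \code{data.table} with one row per candidate: chrom, pos,
#'   dna_allele, rna_allele, dna_depth, rna_depth, rna_alt_count.
#' @export
detect_sample_candidates <- function(dna_obs, rna_obs, min_cov = 15L,
                                     min_alt_reads = 2L, min_alt_frac = 0,
                                     max_discordant_frac = 0,
                                     max_depth = 10000L) {
  base <- chrom <- pos <- NULL  # NSE bindings
  cap <- function(obs) {
    obs <- obs[obs$base %in% BASES, ]
    obs[, idx__ := seq_len(.N), by = c("chrom", "pos")]
    obs <- obs[obs$idx__ <= max_depth, ]
    obs[, idx__ := NULL]
    obs
  }
  dna <- cap(dna_obs)
  rna <- cap(rna_obs)
  dna_cnt <- dna[, .N, by = c("chrom", "pos", "base")]
  dna_sum <- dna_cnt[, list(dna_depth = sum(N), dna_max = max(N),
                            dna_allele = base[which.max(N)]),
                     by = c("chrom", "pos")]
  hom <- dna_sum[dna_sum$dna_depth >= min_cov &
                   dna_sum$dna_max / dna_sum$dna_depth >=
                     1 - max_discordant_frac, ]
  rna_cnt <- rna[, .N, by = c("chrom", "pos", "base")]
  rna_depth <- rna_cnt[, list(rna_depth = sum(N)), by = c("chrom", "pos")]
  rna_cnt <- merge(rna_cnt, rna_depth, by = c("chrom", "pos"))
  rna_sup <- rna_cnt[rna_cnt$N >= min_alt_reads &
                       rna_cnt$N / rna_cnt$rna_depth >= min_alt_frac, ]
  j <- merge(rna_sup, hom, by = c("chrom", "pos"))
  j <- j[j$rna_depth >= min_cov, ]
  alt <- j[j$base != j$dna_allele, ]
  n_alt <- alt[, list(n_alt_alleles = .N), by = c("chrom", "pos")]
  alt <- merge(alt, n_alt, by = c("chrom", "pos"))
  alt <- alt[alt$n_alt_alleles == 1L, ]  # triallelic RNA excluded
  out <- alt[, list(chrom = chrom, pos = pos, dna_allele = dna_allele,
                    rna_allele = base, dna_depth = dna_depth,
                    rna_depth = rna_depth, rna_alt_count = N)]
  data.table::setorder(out, chrom, pos)
  out[]
}
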