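# Seeded simulator for matched DNA/RNA read sets with planted edits, genomic
# SNPs, paralog duplications and one site per sequencing/mapping artifact
# class, so every pipeline stage can be tested against a known truth table.

ARTIFACT_FLAG_MAP <- c(true_edit = "none", genomic_SNP = "none",
                       paralog_duplication = "multimapping",
                       strand_artifact = "strand",
                       extremity_artifact = "extremity",
                       splice_adjacent_error = "splice",
                       homopolymer_context = "homopolymer",
                       ssr_context = "ssr")

#' Default gene layout for the simulated 10 kb genome
#'
#' Two genes (one per strand), each with two exons and a CDS, giving the
#' splice filter and the coding-consequence caller something to work
#' against.
#'
#' @return List of gene specifications consumed by
#'   \code{\link{simulate_genome}}.
#' @export
default_gene_plan <- function() {
  list(
    list(gene_id = "geneA", strand = "+", start = 1001L, end = 3000L,
         exons = rbind(c(1001L, 1800L), c(2201L, 3000L)),
         cds = rbind(c(1101, 1800, 0), c(2201, 2600, 2))),
    list(gene_id = "geneB", strand = "-", start = 4001L, end = 6000L,
         exons = rbind(c(4001L, 4900L), c(5401L, 6000L)),
         cds = rbind(c(4101, 4900, 1), c(5401, 5900, 0))))
}

#' Default site plan: two true edits, one genomic SNP, and one site per
#' artifact class
#'
#' Positions sit inside the default gene layout's exons, at least 9 bp from
#' every exon boundary except the deliberately splice-adjacent site. Editing
#' rates and per-site sample support mirror a cohort of eight biological
#' replicates in which a real edit is expressed at a moderate rate in most
#' animals.
#'
#' @param n_samples Number of samples in the cohort.
#' @return \code{data.table} with one row per planted site.
#' @export
default_site_plan <- function(n_samples = 8L) {
  all_s <- list(seq_len(n_samples))
  most_s <- list(seq_len(min(5L, n_samples)))
  data.table::data.table(
    name = c("edit_AG", "edit_TC", "snp", "paralog", "strandb", "extremity",
             "splice", "homopoly", "ssr"),
    class = c("true_edit", "true_edit", "genomic_SNP", "paralog_duplication",
              "strand_artifact", "extremity_artifact",
              "splice_adjacent_error", "homopolymer_context", "ssr_context"),
    gene = c("geneA", "geneA", "geneB", "geneA", "geneA", "geneB", "geneA",
             "geneA", "geneB"),
    pos = c(1300L, 2400L, 4500L, 1500L, 2600L, 5600L, 1799L, 2800L, 5500L),
    dna_ref = c("A", "T", "A", "A", "C", "A", "G", "C", "T"),
    rna_allele = c("G", "C", "G", "G", "T", "G", "A", "G", "G"),
    rate = c(0.4, 0.5, 1.0, 0.4, 0.5, 0.5, 0.4, 0.4, 0.4),
    samples = c(most_s, all_s, all_s, most_s, all_s, all_s, all_s, all_s,
                all_s))
}

#' Build a simulation configuration
#'
#' Defaults mirror the study design: eight biological replicates, 101 bp
#' reads, ~30x depth in both sources, zero sequencing error for truth
#' testing.
#'
#' @param genome_length Genome size in bp (one chromosome; >= 7000).
#' @param n_samples Number of matched DNA/RNA samples.
#' @param read_length Read length in bp.
#' @param dna_depth,rna_depth Target depths.
#' @param error_rate Per-base substitution error rate.
#' @param tissue Tissue label for the cohort.
#' @param seed Master RNG seed; every derived stream is seeded from it.
#' @param site_plan,gene_plan Overrides for the planted sites / gene layout.
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(genome_length = 10000L, n_samples = 8L,
                       read_length = 101L, dna_depth = 30L, rna_depth = 30L,
                       error_rate = 0, tissue = "WAT", seed = 1L,
                       site_plan = default_site_plan(n_samples),
                       gene_plan = default_gene_plan()) {
  stopifnot(genome_length >= 7000L, n_samples >= 1L, dna_depth >= 1L,
            rna_depth >= 1L, error_rate >= 0, error_rate <= 1)
  if (anyDuplicated(site_plan$pos)) stop("planted positions must be unique")
  stopifnot(all(site_plan$rate >= 0 & site_plan$rate <= 1))
  structure(list(genome_length = as.integer(genome_length),
                 chrom = "chr1", n_samples = as.integer(n_samples),
                 read_length = as.integer(read_length),
                 dna_depth = as.integer(dna_depth),
                 rna_depth = as.integer(rna_depth),
                 error_rate = error_rate, tissue = tissue,
                 seed = as.integer(seed),
                 site_plan = site_plan, gene_plan = gene_plan),
            class = "sim_config")
}

sample_ids <- function(config) sprintf("s%d", seq_len(config$n_samples))

#' Simulate the reference genome and gene models
#'
#' Bases are i.i.d. uniform except around planted sites: the homopolymer
#' site gets an AAAA 5' flank, the SSR site gets (AC)6 ending 2 bp 5' of the
#' site, and the neighborhood of every other site is regenerated until it is
#' free of homopolymer and SSR context, so that each planted site can
#' trigger only its intended filter.
#'
#' @param config \code{"sim_config"}.
#' @return List with \code{genome} (a \code{"genome"}), \code{gene_models}
#'   and the site plan.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  chars <- sample(BASES, L, replace = TRUE)
  plan <- config$site_plan
  # force reference bases at planted sites
  chars[plan$pos] <- plan$dna_ref
  # install intended contexts
  for (i in seq_len(nrow(plan))) {
    p <- plan$pos[i]
    if (plan$class[i] == "homopolymer_context") {
      chars[(p - 4L):(p - 1L)] <- "A"
      if (chars[p - 5L] == "A") chars[p - 5L] <- "C"
      if (chars[p + 1L] == "A") chars[p + 1L] <- "C"
    } else if (plan$class[i] == "ssr_context") {
      chars[(p - 13L):(p - 2L)] <- rep(c("A", "C"), 6L)
    }
  }
  genome <- structure(stats::setNames(paste(chars, collapse = ""),
                                      config$chrom), class = "genome")
  # repair neighborhoods so no site carries an unintended context
  protected <- c(plan$pos,
                 unlist(lapply(seq_len(nrow(plan)), function(i) {
                   p <- plan$pos[i]
                   switch(plan$class[i],
                          homopolymer_context = (p - 5L):(p + 1L),
                          ssr_context = (p - 13L):(p - 2L),
                          integer(0))
                 })))
  for (i in seq_len(nrow(plan))) {
    p <- plan$pos[i]
    cand <- list(chrom = config$chrom, pos = p,
                 rna_allele = plan$rna_allele[i])
    for (try in 1:200) {
      hp_bad <- plan$class[i] != "homopolymer_context" &&
        flag_homopolymer(cand, genome)
      ssr_bad <- plan$class[i] != "ssr_context" &&
        flag_ssr(cand, find_ssrs_genome(genome, config$chrom, p - 25L,
                                        p + 25L))
      if (!hp_bad && !ssr_bad) break
      win <- setdiff((p - 12L):(p + 12L), protected)
      win <- win[win >= 1L & win <= L]
      chars[win] <- sample(BASES, length(win), replace = TRUE)
      genome <- structure(stats::setNames(paste(chars, collapse = ""),
                                          config$chrom), class = "genome")
    }
  }
  gene_models <- lapply(config$gene_plan, function(g) {
    gene_model(g$gene_id, config$chrom, g$strand, g$start, g$end, g$exons,
               g$cds)
  })
  names(gene_models) <- vapply(gene_models, `[[`, character(1), "gene_id")
  list(genome = genome, gene_models = gene_models, site_plan = plan)
}

# transcript <-> genome helpers (transcript = exon chain in genomic order;
# the libraries are unstranded so reads are generated in genomic orientation)
transcript_seq <- function(genome, gm) {
  paste(vapply(seq_len(nrow(gm$exons)), function(i)
    genome_slice(genome, gm$chrom, gm$exons[i, 1L], gm$exons[i, 2L]),
    character(1)), collapse = "")
}

genomic_to_transcript <- function(gm, gpos) {
  off <- 0L
  for (i in seq_len(nrow(gm$exons))) {
    s <- gm$exons[i, 1L]; e <- gm$exons[i, 2L]
    if (gpos >= s && gpos <= e) return(off + gpos - s + 1L)
    off <- off + e - s + 1L
  }
  stop("position ", gpos, " not exonic in ", gm$gene_id)
}

# genomic alignment blocks of transcript interval [t1, t2]
transcript_blocks <- function(gm, t1, t2) {
  blocks <- list()
  off <- 0L
  for (i in seq_len(nrow(gm$exons))) {
    s <- gm$exons[i, 1L]; e <- gm$exons[i, 2L]
    len <- e - s + 1L
    lo <- max(t1, off + 1L); hi <- min(t2, off + len)
    if (lo <= hi)
      blocks[[length(blocks) + 1L]] <- c(s + lo - off - 1L, s + hi - off - 1L)
    off <- off + len
  }
  blocks
}

blocks_to_cigar <- function(blocks) {
  parts <- character(0)
  for (i in seq_along(blocks)) {
    if (i > 1L) {
      gap <- blocks[[i]][1L] - blocks[[i - 1L]][2L] - 1L
      parts <- c(parts, paste0(gap, "N"))
    }
    parts <- c(parts, paste0(blocks[[i]][2L] - blocks[[i]][1L] + 1L, "M"))
  }
  paste(parts, collapse = "")
}

apply_seq_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1L]]
    hit <- which(stats::runif(length(ch)) < error_rate)
    for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate genomic DNA reads for every sample
#'
#' Reads tile the genome uniformly at ~\code{dna_depth}. Genomic-SNP sites
#' are homozygous for the alternative allele in their chosen samples.
#' Paralog-duplication sites contribute extra reads drawn from a duplicated
#' 200 bp segment carrying the RNA allele; these appear ONLY in the FASTQ
#' (they are "unaligned"), never in the SAM.
#'
#' @param config \code{"sim_config"}.
#' @param sim Output of \code{\link{simulate_genome}}.
#' @return Named list (per sample) of lists with \code{sam} (alignment
#'   table) and \code{fastq} (raw reads including the unaligned paralog
#'   reads).
#' @export
simulate_dna_reads <- function(config, sim) {
  set.seed(config$seed + 1L)
  L <- config$genome_length; rl <- config$read_length
  genome <- sim$genome; plan <- sim$site_plan
  n_reads <- ceiling(L * config$dna_depth / rl)
  out <- list()
  for (s_i in seq_len(config$n_samples)) {
    s_id <- sample_ids(config)[s_i]
    starts <- floor(seq(1L, L - rl + 1L, length.out = n_reads))
    seqs <- substring(genome[[config$chrom]], starts, starts + rl - 1L)
    # homozygous alternative alleles at genomic SNP sites
    snps <- plan[plan$class == "genomic_SNP", ]
    for (k in seq_len(nrow(snps))) {
      if (!s_i %in% snps$samples[[k]]) next
      p <- snps$pos[k]
      cov <- which(starts <= p & starts + rl - 1L >= p)
      tmp <- seqs[cov]
      substr(tmp, p - starts[cov] + 1L, p - starts[cov] + 1L) <-
        snps$rna_allele[k]
      seqs[cov] <- tmp
    }
    seqs <- apply_seq_errors(seqs, config$error_rate)
    strand <- rep(c("+", "-"), length.out = n_reads)
    qname <- sprintf("dna_%s_%05d", s_id, seq_len(n_reads))
    sam <- data.table::data.table(
      qname = qname, flag = ifelse(strand == "-", 16L, 0L),
      chrom = config$chrom, pos = starts, cigar = paste0(rl, "M"),
      seq = seqs, strand = strand)
    fq_seq <- ifelse(strand == "-", rc_string(seqs), seqs)
    fastq <- data.table::data.table(read_id = qname, seq = fq_seq, mate = 1L)
    # unaligned paralog reads (FASTQ only)
    pars <- plan[plan$class == "paralog_duplication", ]
    for (k in seq_len(nrow(pars))) {
      if (!s_i %in% pars$samples[[k]]) next
      p <- pars$pos[k]
      segment <- genome_slice(genome, config$chrom, p - 100L, p + 99L)
      substr(segment, 101L, 101L) <- pars$rna_allele[k]
      rel <- sample(21:(200L - rl + 1L), 10L, replace = TRUE)
      rel <- pmin(rel, 101L - 19L)  # keep the 40-mer window inside the read
      pseq <- substring(segment, rel, rel + rl - 1L)
      fastq <- rbind(fastq, data.table::data.table(
        read_id = sprintf("par_%s_%s_%02d", s_id, pars$name[k],
                          seq_along(rel)),
        seq = pseq, mate = 1L))
    }
    out[[s_id]] <- list(sam = sam, fastq = fastq)
  }
  out
}

#' Simulate spliced mRNA reads for every sample
#'
#' Exonic coverage only: ~\code{rna_depth} reads per planted site, placed
#' along the transcript so that spliced CIGARs appear whenever a read spans
#' an intron. True edits and artifact-context sites express the alternative
#' base in Binomial(depth, rate) reads, split evenly between alignment
#' strands; strand-artifact sites put the alternative base on one strand
#' only, and extremity-artifact sites only within 10 bp of read ends.
#'
#' @param config \code{"sim_config"}.
#' @param sim Output of \code{\link{simulate_genome}}.
#' @return List with \code{reads} (named per-sample list of alignment
#'   tables) and \code{alt_counts} (realized per site x sample alternative
#'   read counts, used by \code{\link{write_truth}}).
#' @export
simulate_rna_reads <- function(config, sim) {
  set.seed(config$seed + 2L)
  rl <- config$read_length; depth <- config$rna_depth
  genome <- sim$genome; plan <- sim$site_plan
  tx_cache <- lapply(sim$gene_models, function(gm)
    list(gm = gm, seq = transcript_seq(genome, gm)))
  reads <- list()
  alt_counts <- data.table::data.table()
  for (s_i in seq_len(config$n_samples)) {
    s_id <- sample_ids(config)[s_i]
    recs <- list()
    for (k in seq_len(nrow(plan))) {
      gm <- tx_cache[[plan$gene[k]]]$gm
      tseq <- tx_cache[[plan$gene[k]]]$seq
      tlen <- nchar(tseq)
      tpos <- genomic_to_transcript(gm, plan$pos[k])
      active <- s_i %in% plan$samples[[k]]
      cls <- plan$class[k]
      strand <- rep(c("+", "-"), length.out = depth)
      is_alt <- rep(FALSE, depth)
      if (active) {
        if (cls == "genomic_SNP") {
          is_alt[] <- TRUE
        } else if (cls == "strand_artifact") {
          is_alt[strand == "+"] <- TRUE
        } else {
          n_alt <- stats::rbinom(1L, depth, plan$rate[k])
          plus <- which(strand == "+"); minus <- which(strand == "-")
          n_plus <- min(ceiling(n_alt / 2), length(plus))
          n_minus <- min(n_alt - n_plus, length(minus))
          is_alt[c(plus[seq_len(n_plus)], minus[seq_len(n_minus)])] <- TRUE
        }
      }
      offsets <- integer(depth)
      mid <- 11:(rl - 12L)
      ends <- c(2:9, (rl - 10L):(rl - 3L))
      for (r in seq_len(depth)) {
        offsets[r] <- if (is_alt[r] && cls == "extremity_artifact")
          sample(ends, 1L) else sample(mid, 1L)
      }
      tstart <- pmax(1L, pmin(tpos - offsets, tlen - rl + 1L))
      offs <- tpos - tstart  # realized 0-based site offset in the read
      for (r in seq_len(depth)) {
        rseq <- substr(tseq, tstart[r], tstart[r] + rl - 1L)
        if (is_alt[r])
          substr(rseq, offs[r] + 1L, offs[r] + 1L) <- plan$rna_allele[k]
        blocks <- transcript_blocks(gm, tstart[r], tstart[r] + rl - 1L)
        recs[[length(recs) + 1L]] <- data.table::data.table(
          qname = sprintf("rna_%s_%s_%03d", s_id, plan$name[k], r),
          flag = if (strand[r] == "-") 16L else 0L,
          chrom = config$chrom, pos = blocks[[1L]][1L],
          cigar = blocks_to_cigar(blocks), seq = rseq, strand = strand[r])
      }
      alt_counts <- rbind(alt_counts, data.table::data.table(
        name = plan$name[k], sample = s_id, depth = depth,
        n_alt = sum(is_alt)))
    }
    tab <- data.table::rbindlist(recs)
    tab$seq <- apply_seq_errors(tab$seq, config$error_rate)
    reads[[s_id]] <- tab
  }
  list(reads = reads, alt_counts = alt_counts)
}

#' Derive the truth table from a realized simulation
#'
#' Expected detection requires, per sample, at least \code{min_alt_reads}
#' realized alternative reads and \code{min_cov} depth, in at least
#' \code{min_reps} samples; genomic SNPs are never expected (DNA and RNA
#' agree) and artifact sites carry the filter expected to flag them.
#'
#' @param config \code{"sim_config"}.
#' @param sim Output of \code{\link{simulate_genome}}.
#' @param rna Output of \code{\link{simulate_rna_reads}}.
#' @param min_cov,min_alt_reads,min_reps Detection thresholds the truth is
#'   evaluated against.
#' @return \code{data.table}, one row per planted site.
#' @export
write_truth <- function(config, sim, rna, min_cov = 15L, min_alt_reads = 2L,
                        min_reps = 3L) {
  plan <- sim$site_plan
  ac <- rna$alt_counts
  rows <- lapply(seq_len(nrow(plan)), function(k) {
    sub <- ac[ac$name == plan$name[k], ]
    detectable <- sum(sub$n_alt >= min_alt_reads & sub$depth >= min_cov)
    is_snp <- plan$class[k] == "genomic_SNP"
    dna_allele <- if (is_snp) plan$rna_allele[k] else plan$dna_ref[k]
    data.table::data.table(
      name = plan$name[k], class = plan$class[k], chrom = config$chrom,
      pos = plan$pos[k], dna_allele = dna_allele,
      rna_allele = plan$rna_allele[k], tissue = config$tissue,
      n_samples_detectable = if (is_snp) 0L else detectable,
      expected_candidate = !is_snp && detectable > 0L,
      expected_flag = unname(ARTIFACT_FLAG_MAP[plan$class[k]]),
      expected_in_final = plan$class[k] == "true_edit" &&
        detectable >= min_reps)
  })
  data.table::rbindlist(rows)
}

write_sam_file <- function(records, path, genome) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(genome), "\tLN:", nchar(genome)))
  records <- records[order(records$chrom, records$pos), ]
  body <- paste(records$qname, records$flag, records$chrom, records$pos,
                60L, records$cigar, "*", 0L, 0L, records$seq,
                vapply(nchar(records$seq), function(n) strrep("I", n),
                       character(1)),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a full matched DNA/RNA cohort and write it to disk
#'
#' Writes genome.fa, genes.gff3, truth.tsv, a samples.tsv manifest, and per
#' sample a DNA SAM, an RNA SAM and a DNA FASTQ (which includes the
#' unaligned paralog reads). Byte-identical across reruns with the same
#' config.
#'
#' @param config \code{"sim_config"}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the manifest, truth table and config.
#' @export
simulate_cohort <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  dna <- simulate_dna_reads(config, sim)
  rna <- simulate_rna_reads(config, sim)
  truth <- write_truth(config, sim, rna)
  write_fasta(sim$genome, file.path(out_dir, "genome.fa"))
  write_gff3(sim$gene_models, file.path(out_dir, "genes.gff3"))
  data.table::fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")
  manifest <- data.table::data.table(
    sample = sample_ids(config), tissue = config$tissue,
    dna_sam = paste0(sample_ids(config), ".dna.sam"),
    rna_sam = paste0(sample_ids(config), ".rna.sam"),
    dna_fastq = paste0(sample_ids(config), ".dna.fastq"))
  for (s_id in sample_ids(config)) {
    write_sam_file(dna[[s_id]]$sam, file.path(out_dir,
                                              paste0(s_id, ".dna.sam")),
                   sim$genome)
    write_sam_file(rna$reads[[s_id]], file.path(out_dir,
                                                paste0(s_id, ".rna.sam")),
                   sim$genome)
    write_fastq(dna[[s_id]]$fastq, file.path(out_dir,
                                             paste0(s_id, ".dna.fastq")))
  }
  data.table::fwrite(manifest, file.path(out_dir, "samples.tsv"), sep = "\t")
  invisible(list(manifest = manifest, truth = truth, config = config,
                 dir = out_dir))
}
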