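# End-to-end orchestration: per-sample candidate detection, artifact
# filtering with per-filter attrition accounting, per-tissue merging,
# replication filtering, spectrum, annotation, and the desk-scale checks
# against the packaged published site table.

FILTER_NAMES <- c("extremity", "strand", "splice", "homopolymer", "ssr",
                  "multimapping")

#' Run the full screening pipeline on a simulated or real dataset
#'
#' @param input_dir Directory holding genome.fa, genes.gff3 and a
#'   samples.tsv manifest with columns sample, tissue, dna_sam, rna_sam,
#'   dna_fastq (paths relative to the directory), as written by
#'   \code{\link{simulate_cohort}}.
#' @param out_dir Optional directory for the serialized intermediate tables.
#' @param min_cov Minimum depth in both sources (default 15).
#' @param min_reps Replication threshold for the final event set (default
#'   3).
#' @param min_alt_reads RNA allele-support floor (default 2).
#' @param end_window,delta_max,consensus_len,flank_bp Filter / annotation
#'   knobs passed through.
#' @param verbose Log one line per dropped candidate.
#' @return List with candidates, flags, attrition, events_by_tissue (final,
#'   annotated), spectra (per tissue and replication threshold 1..min_reps),
#'   and the unique/common site summary.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL, min_cov = 15L,
                         min_reps = 3L, min_alt_reads = 2L,
                         end_window = 10L, delta_max = 0.5,
                         consensus_len = 40L, flank_bp = 5000L,
                         verbose = FALSE) {
  need <- function(p) {
    fp <- file.path(input_dir, p)
    if (!file.exists(fp)) stop("missing input file: ", fp)
    fp
  }
  genome <- read_fasta(need("genome.fa"))
  gene_models <- read_gff3(need("genes.gff3"))
  manifest <- data.table::fread(need("samples.tsv"),
                                colClasses = list(character = "sample"))
  cand_list <- list(); flag_list <- list()
  for (i in seq_len(nrow(manifest))) {
    s <- manifest$sample[i]
    dna_obs <- extract_observations(need(manifest$dna_sam[i]), s, "DNA")
    rna_obs <- extract_observations(need(manifest$rna_sam[i]), s, "RNA")
    dna_reads <- read_fastq(need(manifest$dna_fastq[i]))$seq
    cands <- detect_sample_candidates(dna_obs, rna_obs, min_cov = min_cov,
                                      min_alt_reads = min_alt_reads)
    if (!nrow(cands)) next
    cands[, `:=`(sample = s, tissue = manifest$tissue[i])]
    ctx <- list(genome = genome, gene_models = gene_models,
                rna_obs = rna_obs, dna_reads = dna_reads)
    fl <- lapply(seq_len(nrow(cands)), function(j) {
      apply_filters(as.list(cands[j, ]), ctx, end_window = end_window,
                    delta_max = delta_max, consensus_len = consensus_len)
    })
    flags <- data.table::as.data.table(
      lapply(stats::setNames(FILTER_NAMES, FILTER_NAMES),
             function(f) vapply(fl, `[[`, logical(1), f)))
    flags <- cbind(cands[, c("sample", "tissue", "chrom", "pos",
                             "dna_allele", "rna_allele")], flags)
    flags$unbiased <- rowSums(flags[, FILTER_NAMES, with = FALSE]) == 0L
    if (verbose) {
      for (j in which(!flags$unbiased)) {
        hit <- FILTER_NAMES[unlist(flags[j, FILTER_NAMES, with = FALSE])]
        message("drop ", s, " ", flags$chrom[j], ":", flags$pos[j], " ",
                flags$dna_allele[j], ">", flags$rna_allele[j], " [",
                paste(hit, collapse = ","), "]")
      }
    }
    cand_list[[s]] <- cands
    flag_list[[s]] <- flags
  }
  candidates <- data.table::rbindlist(cand_list)
  flags <- data.table::rbindlist(flag_list)
  tissues <- unique(manifest$tissue)
  events_by_tissue <- list(); spectra <- list(); attr_list <- list()
  for (tis in tissues) {
    fsub <- flags[flags$tissue == tis, ]
    unb <- fsub[fsub$unbiased == TRUE, ]
    merged <- merge_candidates(unb, tis)
    n_by_rep <- vapply(seq_len(max(1L, min_reps)), function(k)
      nrow(filter_by_min_replicates(merged, k)), integer(1))
    attr_list[[tis]] <- data.table::data.table(
      tissue = tis,
      n_initial = nrow(fsub),
      n_initial_events = nrow(merge_candidates(fsub, tis)),
      t(vapply(FILTER_NAMES, function(f)
        if (nrow(fsub)) mean(fsub[[f]]) else NA_real_, numeric(1))),
      n_unbiased = nrow(unb),
      n_unbiased_events = nrow(merged),
      t(stats::setNames(n_by_rep,
                        paste0("n_events_min_reps_",
                               seq_len(max(1L, min_reps))))))
    final <- filter_by_min_replicates(merged, min_reps)
    if (nrow(final))
      final <- annotate_events(final, gene_models, genome,
                               flank_bp = flank_bp)
    events_by_tissue[[tis]] <- final
    spectra[[tis]] <- lapply(stats::setNames(seq_len(max(1L, min_reps)),
                                             paste0("N", seq_len(max(1L,
                                                                     min_reps)))),
                             function(k) substitution_spectrum(
                               filter_by_min_replicates(merged, k)))
  }
  attrition <- data.table::rbindlist(attr_list)
  dedup <- if (length(events_by_tissue) &&
                 any(vapply(events_by_tissue, nrow, integer(1)) > 0))
    deduplicate_union(data.table::rbindlist(events_by_tissue, fill = TRUE))
  else list(unique = NULL, common = NULL)
  res <- list(candidates = candidates, flags = flags, attrition = attrition,
              events_by_tissue = events_by_tissue, spectra = spectra,
              unique_events = dedup$unique, common_events = dedup$common,
              params = list(min_cov = min_cov, min_reps = min_reps,
                            min_alt_reads = min_alt_reads))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(candidates, file.path(out_dir, "candidates.tsv"),
                       sep = "\t")
    data.table::fwrite(flags, file.path(out_dir, "flags.tsv"), sep = "\t")
    data.table::fwrite(attrition, file.path(out_dir, "attrition.tsv"),
                       sep = "\t")
    for (tis in names(events_by_tissue))
      data.table::fwrite(events_by_tissue[[tis]],
                         file.path(out_dir, paste0("events_", tis, ".tsv")),
                         sep = "\t")
    if (!is.null(dedup$unique))
      data.table::fwrite(dedup$unique,
                         file.path(out_dir, "unique_events.tsv"), sep = "\t")
  }
  res
}

#' Find positional clusters of events
#'
#' Groups events on the same chromosome (within tissue when a tissue column
#' is present) whose successive positions are at most \code{max_gap} bp
#' apart, and reports every cluster of two or more sites with its span.
#'
#' @param events Event or site table with chrom and pos columns.
#' @param max_gap Maximum gap between successive cluster members (default
#'   2000 bp).
#' @return \code{data.table} with tissue, chrom, n_sites, start, end, span.
#' @export
find_clusters <- function(events, max_gap = 2000L) {
  ev <- data.table::as.data.table(events)
  if (!"tissue" %in% names(ev)) ev$tissue <- "all"
  out <- list()
  for (tis in unique(ev$tissue)) {
    for (chr in unique(ev$chrom[ev$tissue == tis])) {
      pos <- sort(unique(ev$pos[ev$tissue == tis & ev$chrom == chr]))
      if (length(pos) < 2L) next
      grp <- cumsum(c(1L, diff(pos) > max_gap))
      for (g in unique(grp)) {
        p <- pos[grp == g]
        if (length(p) < 2L) next
        out[[length(out) + 1L]] <- data.table::data.table(
          tissue = tis, chrom = chr, n_sites = length(p),
          start = min(p), end = max(p), span = cluster_span(p))
      }
    }
  }
  if (!length(out))
    return(data.table::data.table(tissue = character(), chrom = character(),
                                  n_sites = integer(), start = integer(),
                                  end = integer(), span = integer()))
  data.table::rbindlist(out)
}

#' Recompute the published per-tissue tallies from the packaged site table
#'
#' Loads the transcription of the published replicated-event list, reruns
#' the package's merge/dedup/cluster/spectrum operations on it and compares
#' every derived tally with the value printed in the original report.
#'
#' @param fixture_path Path to a site table; defaults to the packaged
#'   fixture.
#' @return \code{data.table} with columns target, value, expected, pass.
#' @export
table2_check <- function(fixture_path = NULL) {
  canonical <- NULL
  sites <- if (is.null(fixture_path)) table2_sites()
           else read_site_table(fixture_path)
  sites$canonical_lgl <- sites$canonical == "yes"
  ev <- data.table::data.table(tissue = sites$tissue, chrom = sites$chrom,
                               pos = sites$pos,
                               dna_allele = sites$dna_allele,
                               rna_allele = sites$rna_allele,
                               canonical = sites$canonical_lgl,
                               n_replicates = sites$replicates)
  dd <- deduplicate_union(ev)
  uni <- dd$unique
  clus <- find_clusters(ev)
  span_of <- function(tis, chr, lo, hi) {
    hit <- clus[clus$tissue == tis & clus$chrom == chr & clus$start >= lo &
                  clus$end <= hi, ]
    if (nrow(hit) != 1L) NA_integer_ else hit$span
  }
  checks <- data.table::data.table(
    target = c("wat_events", "liver_events", "unique_events",
               "common_events", "unique_canonical",
               "canonical_chromosomes", "min_replicates",
               "noncanonical_wat", "noncanonical_liver",
               "nox4_cluster_span", "mpzl1_cluster_span",
               "flnb_cluster_span"),
    value = c(sum(ev$tissue == "WAT"),
              sum(ev$tissue == "liver"),
              nrow(uni),
              nrow(dd$common),
              sum(uni$canonical),
              length(unique(uni$chrom[uni$canonical])),
              min(ev$n_replicates),
              sum(ev$tissue == "WAT" & !ev$canonical),
              sum(ev$tissue == "liver" & !ev$canonical),
              span_of("WAT", "1", 187000000L, 188000000L),
              span_of("liver", "1", 90000000L, 91000000L),
              span_of("WAT", "12", 8000000L, 9000000L)),
    expected = c(19, 11, 27, 3, 25, 13, 3, 1, 1, 1391, 26, 951))
  checks$pass <- checks$value == checks$expected
  # noncoding fractions under both plausible denominators (the published
  # percentages do not state theirs)
  noncoding <- !grepl("missense|synonymous|Exon", sites$localization,
                      ignore.case = TRUE)
  attr(checks, "noncoding_fraction_canonical") <- vapply(
    c(WAT = "WAT", liver = "liver"), function(t)
      mean(noncoding[sites$tissue == t & sites$canonical_lgl]), numeric(1))
  attr(checks, "noncoding_fraction_all") <- vapply(
    c(WAT = "WAT", liver = "liver"), function(t)
      mean(noncoding[sites$tissue == t]), numeric(1))
  checks
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate --out-dir DIR [--seed N]},
#' \code{run --in-dir DIR [--out-dir DIR] [--min-cov N] [--min-reps N]}, and
#' \code{check-table2 [--fixture PATH]}.
#'
#' @param args Character vector of arguments (defaults to the command line).
#' @return Invisibly, the subcommand's result.
#' @export
editscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: editscreen <simulate|run|check-table2> [options]",
                 "  simulate     --out-dir DIR [--seed N]",
                 "  run          --in-dir DIR [--out-dir DIR] [--min-cov N]",
                 "               [--min-reps N]",
                 "  check-table2 [--fixture PATH]", sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(NULL)) }
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  switch(args[1L],
    simulate = {
      out <- opt("out-dir")
      if (is.null(out)) stop("simulate requires --out-dir")
      seed <- as.integer(opt("seed", "1"))
      res <- simulate_cohort(sim_config(seed = seed), out)
      message("wrote simulated cohort to ", out)
      invisible(res)
    },
    run = {
      ind <- opt("in-dir")
      if (is.null(ind)) stop("run requires --in-dir")
      res <- run_pipeline(ind, out_dir = opt("out-dir"),
                          min_cov = as.integer(opt("min-cov", "15")),
                          min_reps = as.integer(opt("min-reps", "3")))
      print(res$attrition)
      invisible(res)
    },
    `check-table2` = {
      res <- table2_check(opt("fixture"))
      print(res)
      if (!all(res$pass)) stop("table2 check failed")
      invisible(res)
    },
    stop("unknown subcommand: ", args[1L], "\n", usage))
}
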