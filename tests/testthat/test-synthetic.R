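# Most simulator checks run on a reduced cohort (2 samples) for speed; the
# full 8-sample default is exercised by the acceptance suite.

small_cfg <- function(seed = 5L) sim_config(n_samples = 2L, seed = seed)

test_that("same seed gives byte-identical simulated output", {
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_cohort(small_cfg(), d1)
  simulate_cohort(small_cfg(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # a different seed changes at least the genome
  d3 <- file.path(tempdir(), "sim_c")
  simulate_cohort(small_cfg(seed = 6L), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("planted contexts are present in the genome", {
  sim <- simulate_genome(small_cfg())
  plan <- sim$site_plan
  hp <- plan[plan$class == "homopolymer_context", ]
  expect_equal(genome_slice(sim$genome, "chr1", hp$pos - 4L, hp$pos - 1L),
               "AAAA")
  ssr <- plan[plan$class == "ssr_context", ]
  expect_equal(genome_slice(sim$genome, "chr1", ssr$pos - 13L, ssr$pos - 2L),
               strrep("AC", 6))
  # reference bases at planted sites were forced and differ from RNA allele
  for (i in seq_len(nrow(plan))) {
    expect_equal(genome_base(sim$genome, "chr1", plan$pos[i]),
                 plan$dna_ref[i])
  }
  # non-context sites carry neither homopolymer nor SSR neighborhoods
  for (i in which(!plan$class %in% c("homopolymer_context", "ssr_context"))) {
    cand <- list(chrom = "chr1", pos = plan$pos[i])
    expect_false(flag_homopolymer(cand, sim$genome), info = plan$name[i])
    expect_false(flag_ssr(cand, find_ssrs_genome(sim$genome, "chr1",
                                                 plan$pos[i] - 25L,
                                                 plan$pos[i] + 25L)),
                 info = plan$name[i])
  }
})

test_that("paralog reads are in the FASTQ but never in the SAM", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  dna <- simulate_dna_reads(cfg, sim)
  s1 <- dna[["s1"]]
  par_ids <- grep("^par_", s1$fastq$read_id, value = TRUE)
  expect_gt(length(par_ids), 0)
  expect_false(any(par_ids %in% s1$sam$qname))
  # the paralog reads carry the RNA allele in the duplicated segment
  plan <- sim$site_plan
  par <- plan[plan$class == "paralog_duplication", ]
  cons <- genome_slice(sim$genome, "chr1", par$pos - 19L, par$pos + 20L)
  substr(cons, 20, 20) <- par$rna_allele
  expect_true(any(grepl(cons, s1$fastq$seq[grepl("^par_", s1$fastq$read_id)],
                        fixed = TRUE)))
})

test_that("zero-error DNA reads match the reference except at planted SNPs", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  dna <- simulate_dna_reads(cfg, sim)
  sam <- dna[["s1"]]$sam
  snp <- sim$site_plan[sim$site_plan$class == "genomic_SNP", ]
  idx <- sample(nrow(sam), 50)
  for (i in idx) {
    ref <- genome_slice(sim$genome, "chr1", sam$pos[i],
                        sam$pos[i] + nchar(sam$seq[i]) - 1L)
    covers_snp <- any(snp$pos >= sam$pos[i] &
                        snp$pos <= sam$pos[i] + nchar(sam$seq[i]) - 1L)
    if (!covers_snp) expect_equal(sam$seq[i], ref)
  }
  # SNP position is homozygous-alternative in the DNA reads
  obs <- extract_observations(sam, "s1", "DNA")
  at_snp <- obs[obs$pos == snp$pos[1], ]
  expect_true(all(at_snp$base == snp$rna_allele[1]))
  expect_gte(nrow(at_snp), 15L)
})

test_that("DNA coverage is uniform near the target depth", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  dna <- simulate_dna_reads(cfg, sim)
  obs <- extract_observations(dna[["s1"]]$sam, "s1", "DNA")
  depth <- obs[, .N, by = "pos"]
  # interior of the contig (edges taper by construction)
  interior <- depth[depth$pos > 200 & depth$pos < 9800, ]
  expect_lt(abs(mean(interior$N) - cfg$dna_depth) / cfg$dna_depth, 0.1)
})

test_that("edited-read counts follow Binomial(depth, rate)", {
  cfg <- sim_config(n_samples = 8L, seed = 13L)
  sim <- simulate_genome(cfg)
  rna <- simulate_rna_reads(cfg, sim)
  plan <- sim$site_plan
  edit <- plan[plan$name == "edit_AG", ]   # rate 0.4, samples 1..5
  ac <- rna$alt_counts[rna$alt_counts$name == "edit_AG", ]
  active <- ac[ac$sample %in% sprintf("s%d", edit$samples[[1]]), ]
  expect_equal(nrow(active), 5L)
  # each realized count within 3 sigma of the binomial mean
  mu <- cfg$rna_depth * edit$rate
  sigma <- sqrt(cfg$rna_depth * edit$rate * (1 - edit$rate))
  expect_true(all(abs(active$n_alt - mu) <= 3 * sigma))
  # inactive samples express no alternative reads at zero error
  inactive <- ac[!ac$sample %in% sprintf("s%d", edit$samples[[1]]), ]
  expect_true(all(inactive$n_alt == 0L))
  # strand-artifact site: alternative observations share one strand
  reads <- rna$reads[["s1"]]
  strandb <- plan[plan$name == "strandb", ]
  obs <- extract_observations(reads, "s1", "RNA")
  at <- obs[obs$pos == strandb$pos & obs$base == strandb$rna_allele, ]
  expect_gt(nrow(at), 0)
  expect_equal(unique(at$strand), "+")
  # extremity-artifact site: alternative bases only near read ends
  ext <- plan[plan$name == "extremity", ]
  at_e <- obs[obs$pos == ext$pos & obs$base == ext$rna_allele, ]
  expect_true(all(pmin(at_e$read_offset,
                       at_e$read_length - 1L - at_e$read_offset) < 10L))
})

test_that("RNA reads include spliced CIGARs and exon-only coverage", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  rna <- simulate_rna_reads(cfg, sim)
  reads <- rna$reads[["s1"]]
  expect_true(any(grepl("N", reads$cigar)))
  obs <- extract_observations(reads, "s1", "RNA")
  exonic <- unlist(lapply(sim$gene_models, function(gm)
    unlist(lapply(seq_len(nrow(gm$exons)),
                  function(i) gm$exons[i, 1]:gm$exons[i, 2]))))
  expect_true(all(obs$pos %in% exonic))
})

test_that("truth table is consistent with the plan", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  rna <- simulate_rna_reads(cfg, sim)
  truth <- write_truth(cfg, sim, rna)
  expect_equal(nrow(truth), nrow(sim$site_plan))   # every site exactly once
  expect_false(truth[truth$class == "genomic_SNP", ]$expected_candidate)
  expect_equal(truth[truth$class == "paralog_duplication", ]$expected_flag,
               "multimapping")
  expect_true(all(truth$expected_in_final ==
                    (truth$class == "true_edit" &
                       truth$n_samples_detectable >= 3L) |
                    !truth$expected_in_final))
  # with 2 samples no event can reach 3 replicates
  expect_false(any(truth$expected_in_final))
})
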