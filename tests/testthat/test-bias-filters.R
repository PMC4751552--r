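cand <- list(chrom = "c1", pos = 100L, rna_allele = "G", dna_allele = "A",
             sample = "s1")

test_that("extremity bias requires a strict majority of near-end support", {
  mid <- mk_obs(rep("G", 10), pos = 100, read_offset = rep(50, 10))
  expect_false(as.logical(flag_extremity_bias(cand, mid)))
  endy <- mk_obs(rep("G", 10), pos = 100,
                 read_offset = c(rep(3, 4), rep(97, 4), 50, 60))
  f <- flag_extremity_bias(cand, endy)
  expect_true(as.logical(f))
  expect_equal(attr(f, "end_frac"), 0.8)
  # exactly half is not a majority
  half <- mk_obs(rep("G", 10), pos = 100,
                 read_offset = c(rep(5, 5), rep(50, 5)))
  expect_false(as.logical(flag_extremity_bias(cand, half)))
  expect_error(flag_extremity_bias(cand, mk_obs("A", pos = 100)),
               "no observations")
})

test_that("extremity verdicts match a brute-force recount on random offsets", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    off <- sample(0:100, n, replace = TRUE)
    obs <- mk_obs(rep("G", n), pos = 100, read_offset = off)
    frac <- mean(pmin(off, 101 - 1 - off) < 10)
    expect_equal(as.logical(flag_extremity_bias(cand, obs)), frac > 0.5)
  }
})

test_that("strand bias compares per-strand edited-allele proportions", {
  bal <- rbind(mk_obs(c(rep("G", 4), rep("A", 6)), pos = 100, strand = "+"),
               mk_obs(c(rep("G", 4), rep("A", 6)), pos = 100, strand = "-"))
  expect_false(as.logical(flag_strand_bias(cand, bal)))   # delta = 0
  skew <- rbind(mk_obs(c(rep("G", 9), "A"), pos = 100, strand = "+"),
                mk_obs(c("G", rep("A", 9)), pos = 100, strand = "-"))
  f <- flag_strand_bias(cand, skew)
  expect_true(as.logical(f))
  expect_equal(attr(f, "delta"), 0.8)
  # a strand with zero coverage is flagged outright
  oneside <- mk_obs(rep("G", 20), pos = 100, strand = "+")
  expect_true(as.logical(flag_strand_bias(cand, oneside)))
})

test_that("splice proximity uses 1-3 bases of exon, 3-8 of intron", {
  gm <- gene_model("g1", "c1", "+", 1000, 2000,
                   exons = rbind(c(1000, 1200), c(1500, 2000)))
  at <- function(p) flag_splice_bias(list(chrom = "c1", pos = p), list(gm))
  expect_true(as.logical(at(1200)))   # last exon base, distance 1
  expect_true(as.logical(at(1198)))   # distance 3
  expect_false(as.logical(at(1197)))  # distance 4
  expect_false(as.logical(at(1201)))  # intron distance 1 not in [3,8]
  expect_false(as.logical(at(1202)))
  expect_true(as.logical(at(1203)))   # intron distance 3
  expect_true(as.logical(at(1205)))   # intron distance 5
  expect_true(as.logical(at(1208)))   # intron distance 8
  expect_false(as.logical(at(1210)))  # intron distance 10
  # acceptor side mirrors
  expect_true(as.logical(at(1500)))   # first base of next exon
  expect_true(as.logical(at(1502)))
  expect_false(as.logical(at(1503)))
  expect_true(as.logical(at(1497)))   # intron distance 3 before acceptor
  expect_false(as.logical(at(1499)))  # intron distance 1
  # no overlapping gene: never flagged
  expect_false(as.logical(flag_splice_bias(list(chrom = "c9", pos = 1200),
                                           list(gm))))
})

test_that("homopolymer flag checks the four adjacent bases on either side", {
  g <- mk_genome("TTGCAAAAGTCGA")        # positions 5-8 are AAAA
  expect_true(flag_homopolymer(list(chrom = "c1", pos = 9), g))   # AAAA[site]
  expect_false(flag_homopolymer(list(chrom = "c1", pos = 13), g))
  g2 <- mk_genome("CGTACGTTTTAGC")       # [site at 6]TTTT
  expect_true(flag_homopolymer(list(chrom = "c1", pos = 6), g2))
  g3 <- mk_genome("ACGTCTGCA")           # mixed context ACGT[site]TGCA
  expect_false(flag_homopolymer(list(chrom = "c1", pos = 5), g3))
  # near a contig end only the available side is evaluated
  expect_false(flag_homopolymer(list(chrom = "c1", pos = 1), g3))
  expect_true(flag_homopolymer(list(chrom = "c1", pos = 1),
                               mk_genome("GTTTTA")))
})

test_that("find_ssrs reports maximal primitive perfect repeats", {
  hits <- find_ssrs("ACACACACAC")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "AC")
  expect_equal(hits$copies, 5L)
  expect_equal(c(hits$start, hits$end), c(1L, 10L))
  expect_equal(nrow(find_ssrs("ACGTACGA")), 0L)
  # non-primitive motifs are suppressed in favor of the primitive period
  a9 <- find_ssrs("AAAAAAAAA")
  expect_equal(a9$motif, "A")
  expect_equal(a9$copies, 9L)
})

test_that("find_ssrs equals the quadratic brute-force enumerator", {
  set.seed(41)
  for (rep in 1:300) {
    s <- random_repeat_string()
    got <- as.data.frame(find_ssrs(s))
    exp <- oracle_ssrs(s)
    rownames(exp) <- NULL
    expect_equal(got, exp, info = s)
  }
})

test_that("flag_ssr applies the +/-3 bp offset", {
  ssrs <- data.table::data.table(start = 90L, end = 97L, motif = "AC",
                                 copies = 4L)
  expect_true(flag_ssr(list(pos = 100L), ssrs))    # 3 bp away
  expect_false(flag_ssr(list(pos = 101L), ssrs))   # 4 bp away
  expect_true(flag_ssr(list(pos = 95L), ssrs))     # inside
  expect_false(flag_ssr(list(pos = 100L), ssrs[0]))
})

test_that("edited consensus takes the majority of edited reads, ties to reference", {
  set.seed(51)
  g <- mk_genome(paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                       collapse = ""))
  # 5 edited reads covering 81..140 agreeing with the reference flanks
  mk_read_obs <- function(id, bases, start) {
    data.table::data.table(sample = "s1", source = "RNA", chrom = "c1",
                           pos = start:(start + length(bases) - 1L),
                           base = bases, strand = "+",
                           read_offset = 0:(length(bases) - 1L),
                           read_length = length(bases), read_id = id)
  }
  flank <- strsplit(genome_slice(g, "c1", 81, 140), "")[[1]]
  obs <- data.table::rbindlist(lapply(1:5, function(i) {
    b <- flank
    b[100 - 81 + 1] <- "G"          # the edited allele at pos 100
    mk_read_obs(paste0("e", i), b, 81)
  }))
  cons <- build_edited_consensus(cand, obs, g)
  expect_equal(nchar(cons$seq), 40L)
  expect_equal(cons$center_index, 19L)
  ref40 <- genome_slice(g, "c1", 81, 120)
  expected <- ref40
  substr(expected, 20, 20) <- "G"
  expect_equal(cons$seq, expected)

  # a flank SNP carried by all edited reads enters the consensus
  obs_snp <- data.table::copy(obs)
  obs_snp[pos == 90, base := "T"]
  cons2 <- build_edited_consensus(cand, obs_snp, g)
  expect_equal(substr(cons2$seq, 10, 10), "T")

  # tie (1 vs 1) resolves toward the reference
  two <- obs[read_id %in% c("e1", "e2"), ]
  two[read_id == "e1" & pos == 95, base := "T"]
  cons3 <- build_edited_consensus(cand, two, g)
  expect_equal(substr(cons3$seq, 15, 15), substr(ref40, 15, 15))
})

test_that("consensus matches a brute-force per-column majority on random reads", {
  set.seed(61)
  g <- mk_genome(paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                       collapse = ""))
  for (rep in 1:20) {
    n_reads <- sample(3:8, 1)
    obs <- data.table::rbindlist(lapply(seq_len(n_reads), function(i) {
      start <- sample(70:95, 1)
      len <- sample(30:60, 1)
      bases <- vapply(start:(start + len - 1L), function(p)
        if (stats::runif(1) < 0.15) sample(c("A", "C", "G", "T"), 1)
        else genome_base(g, "c1", p), character(1))
      data.table::data.table(sample = "s1", source = "RNA", chrom = "c1",
                             pos = start:(start + len - 1L), base = bases,
                             strand = "+", read_offset = 0:(len - 1L),
                             read_length = len,
                             read_id = paste0("r", i))
    }))
    obs[pos == 100L, base := "G"]   # all covering reads carry the edit
    if (!any(obs$pos == 100L)) next
    cons <- build_edited_consensus(cand, obs, g)
    carriers <- unique(obs$read_id[obs$pos == 100L & obs$base == "G"])
    for (p in 81:120) {
      sub <- obs[obs$pos == p & obs$read_id %in% carriers, ]
      expected <- if (p == 100L) "G" else if (nrow(sub) == 0L) {
        genome_base(g, "c1", p)
      } else {
        tab <- table(factor(sub$base, levels = c("A", "C", "G", "T")))
        top <- names(tab)[tab == max(tab)]
        if (genome_base(g, "c1", p) %in% top) genome_base(g, "c1", p)
        else top[1]
      }
      expect_equal(substr(cons$seq, p - 81 + 1, p - 81 + 1), expected,
                   info = paste("pos", p))
    }
  }
})

test_that("consensus windows are clipped and flagged at contig ends", {
  g <- mk_genome(strrep("ACGT", 10))   # 40 bp contig
  obs <- mk_obs(rep("G", 3), pos = 5)
  cons <- build_edited_consensus(list(chrom = "c1", pos = 5L,
                                      rna_allele = "G"), obs, g)
  expect_true(cons$truncated)
  expect_equal(nchar(cons$seq), 25L)   # 1..25 instead of -14..25
  expect_equal(cons$center_index, 4L)
})

test_that("multimapping search is exact substring plus reverse complement", {
  cons <- "ACGTACGTTTACGCGATATA"
  reads <- c(strrep("T", 50), paste0("CCC", cons, "GGG"))
  expect_true(flag_multimapping(cons, reads))
  expect_false(flag_multimapping(cons, strrep("T", 50)))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  expect_true(flag_multimapping(cons, paste0("AA", rc, "TT")))
  expect_warning(res <- flag_multimapping(cons, character(0)), "empty")
  expect_false(res)
  # Hamming-tolerant option
  near <- paste0("CC", sub("^A", "T", cons), "GG")
  expect_false(flag_multimapping(cons, near))
  expect_true(flag_multimapping(cons, near, max_mismatch = 1))
})

test_that("apply_filters evaluates all six flags independently and idempotently", {
  set.seed(71)
  g <- mk_genome(paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                       collapse = ""))
  gm <- gene_model("g1", "c1", "+", 50, 450,
                   exons = rbind(c(50, 200), c(300, 450)))
  rna <- rbind(
    mk_obs(c(rep("G", 6), rep("A", 8)), pos = 100, strand = "+",
           read_offset = 40:53),
    mk_obs(c(rep("G", 6), rep("A", 8)), pos = 100, strand = "-",
           read_offset = 40:53))
  ctx <- list(genome = g, gene_models = list(gm), rna_obs = rna,
              dna_reads = strrep("T", 60))
  f1 <- apply_filters(cand, ctx)
  f2 <- apply_filters(cand, ctx)
  expect_s3_class(f1, "bias_flags")
  expect_identical(f1[FILTER_SET <- c("extremity", "strand", "splice",
                                      "homopolymer", "ssr", "multimapping")],
                   f2[FILTER_SET])
  # verdicts equal the individual filter calls (order independence)
  expect_equal(f1$extremity, as.logical(flag_extremity_bias(cand, rna)))
  expect_equal(f1$strand, as.logical(flag_strand_bias(cand, rna)))
  expect_equal(f1$splice, as.logical(flag_splice_bias(cand, list(gm))))
  expect_equal(f1$homopolymer, flag_homopolymer(cand, g))
  expect_equal(f1$multimapping,
               flag_multimapping(build_edited_consensus(cand, rna, g),
                                 strrep("T", 60)))
  expect_true(is_unbiased(f1) == !any(unlist(f1[c("extremity", "strand",
                                                  "splice", "homopolymer",
                                                  "ssr", "multimapping")])))
})
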