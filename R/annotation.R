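# Minimal genomic localization and coding-consequence calls: the categories
# a variant-effect annotator would assign, restricted to those the screening
# report actually uses.

LOCALIZATION_SEVERITY <- c("exon_cds_missense", "exon_cds_synonymous",
                           "exon_noncoding", "intron", "upstream",
                           "downstream", "intergenic")

#' Localize a site against gene models
#'
#' Overlap precedence is exon > intron > flank > intergenic; when the site
#' overlaps several genes, every gene name is reported and the most severe
#' category wins. The flank side (upstream/downstream) is resolved by gene
#' strand. Intergenic sites within \code{naming_radius} of a gene report the
#' nearest gene's name(s).
#'
#' @param site List with chrom, pos and (for CDS sites) rna_allele.
#' @param gene_models List of \code{"gene_model"} objects.
#' @param genome Reference \code{"genome"}; needed to call the coding
#'   consequence when the site falls in a CDS.
#' @param flank_bp Flanking-region width in bp (default 5000).
#' @param naming_radius Distance within which intergenic sites are named
#'   after the closest gene (default 10000).
#' @return List of class \code{"feature_localization"} with \code{category},
#'   \code{gene_names} and \code{distance_bp} (0 when overlapping a gene).
#' @export
localize_site <- function(site, gene_models, genome = NULL,
                          flank_bp = 5000L, naming_radius = 10000L) {
  pos <- site$pos
  hits <- list()  # (category, gene, distance)
  for (gm in gene_models) {
    if (gm$chrom != site$chrom) next
    if (pos >= gm$gene_start && pos <= gm$gene_end) {
      in_exon <- any(gm$exons[, 1L] <= pos & gm$exons[, 2L] >= pos)
      cat <- if (in_exon) {
        in_cds <- nrow(gm$cds) > 0L &&
          any(gm$cds[, 1L] <= pos & gm$cds[, 2L] >= pos)
        if (in_cds) {
          if (is.null(genome) || is.null(site$rna_allele))
            stop("genome and rna_allele are required to resolve the coding ",
                 "consequence at ", site$chrom, ":", pos)
          paste0("exon_cds_",
                 coding_consequence(site, gm, genome, site$rna_allele))
        } else "exon_noncoding"
      } else "intron"
      hits[[length(hits) + 1L]] <- list(cat = cat, gene = gm$gene_id, d = 0L)
    } else {
      d <- if (pos < gm$gene_start) gm$gene_start - pos else pos - gm$gene_end
      if (d <= flank_bp) {
        before <- pos < gm$gene_start
        cat <- if ((before && gm$strand == "+") ||
                   (!before && gm$strand == "-")) "upstream" else "downstream"
        hits[[length(hits) + 1L]] <- list(cat = cat, gene = gm$gene_id, d = d)
      } else if (d <= naming_radius) {
        hits[[length(hits) + 1L]] <-
          list(cat = "intergenic", gene = gm$gene_id, d = d)
      }
    }
  }
  if (!length(hits)) {
    return(structure(list(category = "intergenic", gene_names = character(0),
                          distance_bp = NA_integer_),
                     class = "feature_localization"))
  }
  cats <- vapply(hits, `[[`, character(1), "cat")
  sev <- match(cats, LOCALIZATION_SEVERITY)
  best <- min(sev)
  if (LOCALIZATION_SEVERITY[best] == "intergenic") {
    # no overlap or flank: name only the closest gene(s)
    ds <- vapply(hits, `[[`, numeric(1), "d")
    genes <- unique(vapply(hits[ds == min(ds)], `[[`, character(1), "gene"))
    return(structure(list(category = "intergenic", gene_names = genes,
                          distance_bp = as.integer(min(ds))),
                     class = "feature_localization"))
  }
  keep <- cats != "intergenic"
  genes <- unique(vapply(hits[keep], `[[`, character(1), "gene"))
  structure(list(category = LOCALIZATION_SEVERITY[best], gene_names = genes,
                 distance_bp = as.integer(
                   min(vapply(hits[keep], `[[`, numeric(1), "d")))),
            class = "feature_localization")
}

# Genomic positions of the coding sequence in translation order, with the
# leading frame offset of the first translated segment removed.
cds_position_map <- function(gene_model) {
  cds <- gene_model$cds
  if (!nrow(cds)) stop("gene ", gene_model$gene_id, " has no CDS")
  if (gene_model$strand == "+") {
    segs <- cds[order(cds[, 1L]), , drop = FALSE]
    map <- unlist(lapply(seq_len(nrow(segs)),
                         function(i) segs[i, 1L]:segs[i, 2L]))
    frame <- segs[1L, 3L]
  } else {
    segs <- cds[order(cds[, 1L], decreasing = TRUE), , drop = FALSE]
    map <- unlist(lapply(seq_len(nrow(segs)),
                         function(i) segs[i, 2L]:segs[i, 1L]))
    frame <- segs[1L, 3L]
  }
  if (is.na(frame)) frame <- 0
  if (frame > 0) map <- map[-seq_len(frame)]
  map
}

#' Coding consequence of an edited base inside a CDS
#'
#' Builds the affected codon from the CDS segments (honoring phase and
#' strand, reverse-complementing for minus-strand genes), translates the
#' reference and edited codons with the standard genetic code, and reports
#' \code{"synonymous"} when the amino acid is unchanged, otherwise
#' \code{"missense"}.
#'
#' @param site List with chrom and pos; pos must fall inside a CDS interval.
#' @param gene_model A \code{"gene_model"} with CDS annotation.
#' @param genome Reference \code{"genome"}.
#' @param rna_allele Edited base observed in the mRNA (genomic strand).
#' @return \code{"missense"} or \code{"synonymous"}; attributes
#'   \code{"ref_aa"} and \code{"alt_aa"} carry the amino acids.
#' @export
coding_consequence <- function(site, gene_model, genome, rna_allele) {
  map <- cds_position_map(gene_model)
  idx <- match(site$pos, map)
  if (is.na(idx))
    stop("position ", site$chrom, ":", site$pos, " is not inside the CDS of ",
         gene_model$gene_id)
  codon_i <- (idx - 1L) %/% 3L
  cpos <- map[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  if (anyNA(cpos))
    stop("inconsistent frame annotation: incomplete codon at end of CDS of ",
         gene_model$gene_id)
  fetch <- function(allele_at_site) {
    b <- vapply(cpos, function(p) {
      if (p == site$pos) allele_at_site
      else genome_base(genome, gene_model$chrom, p)
    }, character(1))
    if (gene_model$strand == "-") b <- chartr("ACGT", "TGCA", b)
    paste(b, collapse = "")
  }
  ref_codon <- fetch(genome_base(genome, gene_model$chrom, site$pos))
  alt_codon <- fetch(rna_allele)
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  structure(if (identical(ref_aa, alt_aa)) "synonymous" else "missense",
            ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Annotate an event table with localization columns
#'
#' @param events Event table with chrom, pos, rna_allele columns.
#' @param gene_models List of \code{"gene_model"} objects.
#' @param genome Reference \code{"genome"}.
#' @param ... Passed to \code{\link{localize_site}}.
#' @return The event table with \code{category} and \code{gene_names}
#'   columns appended.
#' @export
annotate_events <- function(events, gene_models, genome, ...) {
  loc <- lapply(seq_len(nrow(events)), function(i) {
    localize_site(list(chrom = events$chrom[i], pos = events$pos[i],
                       rna_allele = events$rna_allele[i]),
                  gene_models, genome, ...)
  })
  events$category <- vapply(loc, `[[`, character(1), "category")
  events$gene_names <- vapply(loc, function(l)
    paste(l$gene_names, collapse = ","), character(1))
  events
}
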