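# Cross-sample merging of unbiased candidates into per-tissue editing
# events, the biological-replication filter, and the 12-class substitution
# spectrum with canonical (ADAR/APOBEC) complement collapsing.

SUBSTITUTION_CLASSES <- {
  p <- expand.grid(from = BASES, to = BASES, stringsAsFactors = FALSE)
  p <- p[p$from != p$to, ]
  paste0(p$from, ">", p$to)
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")
CANONICAL_CLASSES <- c("A>G", "T>C", "C>T", "G>A")

#' Classify a DNA-to-RNA base substitution
#'
#' Canonical classes are the ADAR (A>G) and APOBEC (C>T) signatures plus
#' their complements (T>C, G>A), which count as canonical because the
#' sequencing libraries are not strand-specific.
#'
#' @param dna_allele,rna_allele Single bases with
#'   \code{dna_allele != rna_allele}.
#' @return List with \code{label} (e.g. \code{"A>G"}), \code{is_transition}
#'   and \code{is_canonical}.
#' @export
classify_substitution <- function(dna_allele, rna_allele) {
  if (!dna_allele %in% BASES || !rna_allele %in% BASES)
    stop("alleles must be one of A, C, G, T")
  if (dna_allele == rna_allele)
    stop("DNA and RNA alleles are identical; not a substitution")
  label <- paste0(dna_allele, ">", rna_allele)
  list(label = label,
       is_transition = label %in% TRANSITIONS,
       is_canonical = label %in% CANONICAL_CLASSES)
}

#' Map a substitution class to its complement class
#'
#' X>Y maps to complement(X)>complement(Y); applying the map twice is the
#' identity, and transition/transversion status is preserved.
#'
#' @param label Class label such as \code{"T>C"}.
#' @return Complement class label (\code{"T>C"} returns \code{"A>G"}).
#' @export
collapse_complement <- function(label) {
  if (!all(label %in% SUBSTITUTION_CLASSES))
    stop("not a substitution class label: ", paste(label, collapse = ", "))
  chartr("ACGT", "TGCA", label)
}

#' Merge per-sample candidates into per-tissue editing events
#'
#' Groups candidates by (chrom, pos, dna_allele, rna_allele); the replicate
#' count of an event is the number of distinct samples it was detected in.
#' No candidate is lost or duplicated: the replicate counts sum to the
#' number of distinct (sample, site) input rows.
#'
#' @param candidates \code{data.table} with columns sample, chrom, pos,
#'   dna_allele, rna_allele (one row per sample x site).
#' @param tissue Tissue label attached to every event.
#' @return \code{data.table} of events with samples_detected
#'   (comma-separated), n_replicates, class, canonical.
#' @export
merge_candidates <- function(candidates, tissue) {
  dna_allele <- rna_allele <- NULL
  if (!nrow(candidates))
    return(data.table::data.table(tissue = character(), chrom = character(),
                                  pos = integer(), dna_allele = character(),
                                  rna_allele = character(),
                                  samples_detected = character(),
                                  n_replicates = integer(),
                                  class = character(), canonical = logical()))
  ev <- candidates[, list(
    samples_detected = paste(sort(unique(sample)), collapse = ","),
    n_replicates = length(unique(sample))),
    by = c("chrom", "pos", "dna_allele", "rna_allele")]
  ev[, `:=`(tissue = tissue,
            class = paste0(dna_allele, ">", rna_allele))]
  ev[, canonical := class %in% CANONICAL_CLASSES]
  data.table::setcolorder(ev, c("tissue", "chrom", "pos", "dna_allele",
                                "rna_allele", "samples_detected",
                                "n_replicates", "class", "canonical"))
  data.table::setorder(ev, chrom, pos)
  ev[]
}

#' Apply the biological-replication filter
#'
#' @param events Event table from \code{\link{merge_candidates}}.
#' @param min_reps Minimum number of biological replicates an event must be
#'   detected in (default 3).
#' @return Filtered event table; monotone in \code{min_reps}.
#' @export
filter_by_min_replicates <- function(events, min_reps = 3L) {
  events[events$n_replicates >= min_reps, ]
}

#' Substitution spectrum over the 12 classes
#'
#' @param events Event table with a \code{class} column.
#' @return \code{data.table} with one row per class (count, fraction;
#'   fractions sum to 1 over non-empty input) and attributes
#'   \code{"transversion_fraction"} and \code{"canonical_fraction"}.
#' @export
substitution_spectrum <- function(events) {
  tab <- table(factor(events$class, levels = SUBSTITUTION_CLASSES))
  n <- sum(tab)
  out <- data.table::data.table(class = SUBSTITUTION_CLASSES,
                                count = as.integer(tab),
                                fraction = if (n > 0) as.numeric(tab) / n
                                           else rep(NA_real_, 12L))
  out[, `:=`(is_transition = class %in% TRANSITIONS,
             is_canonical = class %in% CANONICAL_CLASSES)]
  attr(out, "transversion_fraction") <-
    if (n > 0) sum(tab[!SUBSTITUTION_CLASSES %in% TRANSITIONS]) / n
    else NA_real_
  attr(out, "canonical_fraction") <-
    if (n > 0) sum(tab[SUBSTITUTION_CLASSES %in% CANONICAL_CLASSES]) / n
    else NA_real_
  out[]
}

#' Unique-site union and common sites across tissues
#'
#' @param events_by_tissue Named list of per-tissue event tables (or one
#'   combined table with a \code{tissue} column).
#' @return List with \code{unique} (one row per distinct (chrom, pos,
#'   dna_allele, rna_allele) key, with the tissues it appears in) and
#'   \code{common} (keys present in every tissue).
#' @export
deduplicate_union <- function(events_by_tissue) {
  tissue <- NULL
  ev <- if (is.data.frame(events_by_tissue)) events_by_tissue
        else data.table::rbindlist(events_by_tissue, use.names = TRUE,
                                   fill = TRUE)
  key <- c("chrom", "pos", "dna_allele", "rna_allele")
  if (!"canonical" %in% names(ev))
    ev$canonical <- paste0(ev$dna_allele, ">", ev$rna_allele) %in%
      CANONICAL_CLASSES
  total_tissues <- length(unique(ev$tissue))
  uni <- ev[, list(tissues = paste(sort(unique(tissue)), collapse = ","),
                   n_tissues = length(unique(tissue)),
                   canonical = canonical[1L]),
            by = key]
  data.table::setorder(uni, chrom, pos)
  list(unique = uni[], common = uni[uni$n_tissues == total_tissues, ])
}

#' Genomic span of a cluster of events
#'
#' @param positions Numeric vector of positions on one chromosome, or an
#'   event table (its \code{pos} column is used).
#' @return Span in bp: \code{max(pos) - min(pos)}; 0 for a single site.
#' @export
cluster_span <- function(positions) {
  if (is.data.frame(positions)) {
    if (length(unique(positions$chrom)) > 1L)
      stop("cluster_span expects events on a single chromosome")
    positions <- positions$pos
  }
  if (!length(positions)) stop("no positions supplied")
  max(positions) - min(positions)
}
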