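# Editing-level computation (read-count or pyrosequencing-signal based) and
# factor-effect testing with the classical pooled-variance two-sample t-test.

#' Edited-allele fraction from read counts
#'
#' @param rna_counts Named numeric vector of per-base counts (A/C/G/T) or an
#'   \code{"allele_counts"} object.
#' @param edited_allele The edited base.
#' @return Fraction of reads carrying the edited allele; 0 at zero count.
#' @export
editing_fraction <- function(rna_counts, edited_allele) {
  if (inherits(rna_counts, "allele_counts")) rna_counts <- rna_counts$counts
  total <- sum(rna_counts)
  if (total <= 0) stop("zero total RNA signal")
  unname(rna_counts[edited_allele] / total)
}

#' Standardized editing level
#'
#' The raw mRNA edited-allele fraction is divided by the measured
#' genomic-DNA allele fraction of the same assay, so that amplification and
#' sequencing biases common to both templates cancel; with a perfectly
#' homozygous DNA signal the correction factor is 1. The result is clamped
#' to [0, 1] (a warning is issued when clamping occurs).
#'
#' @param rna_edited_signal,rna_total_signal mRNA signal for the edited
#'   allele and total mRNA signal (read counts or pyrosequencing peak
#'   heights).
#' @param dna_allele_signal,dna_total_signal Matching genomic-DNA signals for
#'   the (homozygous) DNA allele.
#' @return Editing level in [0, 1].
#' @export
standardize_level <- function(rna_edited_signal, rna_total_signal,
                              dna_allele_signal, dna_total_signal) {
  if (rna_total_signal <= 0 || dna_total_signal <= 0)
    stop("total signals must be positive")
  if (dna_allele_signal <= 0)
    stop("DNA allele signal must be positive")
  level <- (rna_edited_signal / rna_total_signal) /
    (dna_allele_signal / dna_total_signal)
  if (level > 1) {
    warning("editing level ", signif(level, 4), " clamped to 1")
    level <- 1
  }
  max(0, level)
}

#' Two-sided unpaired homoscedastic (pooled-variance) Student t-test
#'
#' Classical pooled t with df = n_a + n_b - 2 and a two-sided p-value from
#' the t distribution. When the pooled variance is zero: equal means give
#' t = 0, p = 1; unequal means give an infinite statistic and the smallest
#' representable p-value.
#'
#' @param group_a,group_b Numeric vectors of editing levels, each of length
#'   at least 2.
#' @return List of class \code{"group_comparison"} with group_a, group_b,
#'   t_statistic, df, p_value.
#' @export
pooled_t_test <- function(group_a, group_b) {
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a < 2L || n_b < 2L) stop("each group needs at least 2 values")
  df <- n_a + n_b - 2L
  sp2 <- ((n_a - 1) * stats::var(group_a) + (n_b - 1) * stats::var(group_b)) /
    df
  delta <- mean(group_a) - mean(group_b)
  if (sp2 == 0) {
    if (delta == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(delta) * Inf; p <- .Machine$double.xmin
    }
  } else {
    t_stat <- delta / sqrt(sp2 * (1 / n_a + 1 / n_b))
    p <- 2 * stats::pt(-abs(t_stat), df)
    p <- max(p, .Machine$double.xmin)
  }
  structure(list(group_a = group_a, group_b = group_b, t_statistic = t_stat,
                 df = df, p_value = p),
            class = "group_comparison")
}

#' Welch's unequal-variance t-test (optional alternative)
#'
#' Offered for heteroscedastic data; the screening protocol's default is the
#' pooled test.
#'
#' @inheritParams pooled_t_test
#' @return List of class \code{"group_comparison"}.
#' @export
welch_t_test <- function(group_a, group_b) {
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  structure(list(group_a = group_a, group_b = group_b,
                 t_statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "group_comparison")
}

#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#'
#' @param p P-value(s).
#' @return Character vector: \code{"***"}, \code{"**"}, \code{"*"} or
#'   \code{""}.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare editing levels between two factor groups, per site and tissue
#'
#' @param level_table \code{data.table} with columns site, tissue, group and
#'   level; \code{group} must take exactly two values within each (site,
#'   tissue).
#' @param welch Use Welch's test instead of the pooled test.
#' @return \code{data.table} with one row per (site, tissue): group sizes,
#'   means, t statistic, df, p-value and significance stars.
#' @export
compare_factor_groups <- function(level_table, welch = FALSE) {
  lt <- data.table::as.data.table(level_table)
  out <- lt[, {
    gs <- sort(unique(group))
    if (length(gs) != 2L)
      stop("expected exactly 2 groups, got: ", paste(gs, collapse = ", "))
    a <- level[group == gs[1L]]
    b <- level[group == gs[2L]]
    cmp <- if (welch) welch_t_test(a, b) else pooled_t_test(a, b)
    list(group_a = gs[1L], group_b = gs[2L],
         n_a = length(a), n_b = length(b),
         mean_a = mean(a), mean_b = mean(b),
         t_statistic = cmp$t_statistic, df = cmp$df, p_value = cmp$p_value,
         stars = significance_stars(cmp$p_value))
  }, by = c("site", "tissue")]
  out[]
}
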