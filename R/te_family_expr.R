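# TE-family expression: per-copy counts are aggregated to families and
# tested with the same negative-binomial machinery as genes, but filtered on
# the raw p-value (no multiple-testing adjustment) and a fold-change of 3,
# the conventional thresholds for repeat-family differential expression.

#' Aggregate per-copy TE counts to families
#'
#' @param per_copy_counts integer matrix, TE copies x samples, with copy ids
#'   as rownames.
#' @param family_map data.frame with `copy_id` and `family`.
#' @return integer matrix, families x samples; copies without a mapped
#'   family are collected under `"<unassigned>"`.
#' @export
aggregate_family_counts <- function(per_copy_counts, family_map) {
  m <- as.matrix(per_copy_counts)
  if (anyDuplicated(rownames(m))) stop_("duplicate copy ids in count matrix")
  fam <- family_map$family[match(rownames(m), family_map$copy_id)]
  fam[is.na(fam)] <- "<unassigned>"
  agg <- rowsum(m, group = fam)
  storage.mode(agg) <- "integer"
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Differentially expressed TE families for one strain
#'
#' @param family_counts matrix from [aggregate_family_counts()].
#' @param sample_meta sample sheet as in [nb_test()].
#' @param strain strain to test.
#' @param alpha raw p-value cutoff.
#' @param min_fold_change fold-change cutoff (|FC| >= value).
#' @param adjust use BH-adjusted instead of raw p-values.
#' @return data.frame of all families with `is_de` flagging those passing
#'   both cutoffs.
#' @export
family_de <- function(family_counts, sample_meta, strain, alpha = 0.05,
                      min_fold_change = 3, adjust = FALSE) {
  res <- nb_test(family_counts, sample_meta, strain,
                 alpha = 1, min_fold_change = 1, sf_fallback = TRUE)
  p_use <- if (adjust) res$padj else res$p_value
  res$is_de <- p_use <= alpha &
    abs(res$log2_fold_change) >= log2(min_fold_change)
  res$is_deg <- NULL
  res
}

#' Overlap of DE family sets between two datasets
#'
#' @param families_a,families_b character vectors of DE family names (subsets
#'   of `universe`); optionally named lists with `ids` and `direction`.
#' @param universe all family names testable in both datasets.
#' @param direction_a,direction_b optional named sign vectors (+1/-1 per
#'   family) for concordance counting among the overlap.
#' @return list with `n_overlap`, `statistic`, `p_value` (Pearson
#'   chi-square on the 2x2 over the universe), and when directions are given
#'   `n_same_direction` / `n_opposite`.
#' @export
cross_dataset_overlap <- function(families_a, families_b, universe,
                                  direction_a = NULL, direction_b = NULL) {
  if (!all(c(families_a, families_b) %in% universe)) {
    stop_("universe must contain every DE family of both datasets")
  }
  in_a <- universe %in% families_a
  in_b <- universe %in% families_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  out <- list(n_overlap = sum(in_a & in_b),
              statistic = unname(ct$statistic), p_value = ct$p.value)
  if (!is.null(direction_a) && !is.null(direction_b)) {
    shared <- intersect(families_a, families_b)
    sa <- sign(direction_a[shared]); sb <- sign(direction_b[shared])
    out$n_same_direction <- sum(sa == sb)
    out$n_opposite <- sum(sa != sb)
  }
  out
}

#' Correlation of DE-family burden with insecticide sensitivity
#'
#' @param mortality_pct per-strain mortality percentages.
#' @param n_de_families per-strain numbers of DE TE families (same order).
#' @return Pearson r, or `NA` when either vector is constant.
#' @export
tolerance_correlation <- function(mortality_pct, n_de_families) {
  if (length(mortality_pct) != length(n_de_families)) {
    stop_("vectors must have equal length")
  }
  if (length(mortality_pct) < 3) stop_("need at least 3 strains")
  if (sd(mortality_pct) == 0 || sd(n_de_families) == 0) return(NA_real_)
  cor(mortality_pct, n_de_families, method = "pearson")
}
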