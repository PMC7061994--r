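# TE insertions: proximity to genes, DEG-near-TE enrichment, genotype-class
# summaries and family/order enrichment.

#' Link TE insertions to nearby genes
#'
#' A TE is linked to a gene if it overlaps the gene span (relation
#' `inside_gene`, distance 0) or if the gap between the nearest feature edges
#' is strictly below `max_dist` base pairs. For non-overlapping links the
#' relation is `five_prime` or `three_prime` relative to the gene's strand.
#'
#' @param tes `GRanges` with a `te_id` column.
#' @param genes `GRanges` with a `gene_id` column and explicit +/- strands.
#' @param max_dist proximity cutoff in bp (strict `<`).
#' @return data.frame with `te_id`, `gene_id`, `relation`, `distance`.
#' @export
link_tes_to_genes <- function(tes, genes, max_dist = 1000) {
  gstrand <- as.character(GenomicRanges::strand(genes))
  if (any(!gstrand %in% c("+", "-"))) {
    stop_("all genes must have strand + or - (relation is strand-defined)")
  }
  fo <- findOverlaps(tes, genes, maxgap = max_dist - 1L, ignore.strand = TRUE)
  if (length(fo) == 0) {
    return(data.frame(te_id = character(0), gene_id = character(0),
                      relation = character(0), distance = integer(0),
                      stringsAsFactors = FALSE))
  }
  q <- queryHits(fo); s <- subjectHits(fo)
  d <- GenomicRanges::distance(tes[q], genes[s], ignore.strand = TRUE)
  te_end <- GenomicRanges::end(tes)[q]
  g_start <- GenomicRanges::start(genes)[s]
  overlaps <- d == 0 &
    GenomicRanges::start(tes)[q] <= GenomicRanges::end(genes)[s] &
    te_end >= g_start
  upstream_plus <- te_end < g_start            # TE entirely left of the gene
  on_plus <- gstrand[s] == "+"
  relation <- ifelse(overlaps, "inside_gene",
              ifelse(xor(upstream_plus, !on_plus), "five_prime", "three_prime"))
  data.frame(te_id = mcols(tes)$te_id[q],
             gene_id = mcols(genes)$gene_id[s],
             relation = relation,
             distance = ifelse(overlaps, 0L, d),
             stringsAsFactors = FALSE)
}

#' Enrichment of DEGs near TE insertions
#'
#' Pearson chi-square (1 df) on the 2x2 table of DEG status against having at
#' least one TE link, over a configurable gene universe.
#'
#' @param deg_ids DEG identifiers (must be a subset of `all_gene_ids`).
#' @param all_gene_ids the gene universe.
#' @param links proximity links from [link_tes_to_genes()].
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `table` (2x2), `statistic`, `p_value`.
#' @export
deg_te_enrichment <- function(deg_ids, all_gene_ids, links, correct = FALSE) {
  if (!all(deg_ids %in% all_gene_ids)) stop_("deg_ids must be a subset of all_gene_ids")
  is_deg <- factor(all_gene_ids %in% deg_ids, levels = c(TRUE, FALSE),
                   labels = c("DEG", "non-DEG"))
  has_te <- factor(all_gene_ids %in% links$gene_id, levels = c(TRUE, FALSE),
                   labels = c("TE nearby", "no TE"))
  tab <- table(is_deg, has_te)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn_("a margin of the 2x2 table is zero; p-value undefined")
    return(list(table = tab, statistic = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(table = tab, statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Genotype-class summary of TE insertions
#'
#' Partitions genotyped TEs into three classes: present in all strains,
#' present only in the reference strain, and polymorphic (everything else).
#' Strains genotyped as `NA` (failed genotyping) are ignored TE by TE; TEs
#' with no called non-reference genotype are dropped from the summary.
#'
#' @param presence matrix of 1/0/`NA`, TEs x strains.
#' @param ref_strain column name of the reference strain.
#' @return list with `summary` (class, count, pct to one decimal) and
#'   `n_genotyped`.
#' @export
genotype_summary <- function(presence, ref_strain) {
  if (is.null(colnames(presence)) || !ref_strain %in% colnames(presence)) {
    stop_("presence must have strain columns including ref_strain")
  }
  if (ncol(presence) < 2) stop_("need at least one non-reference strain")
  nonref <- presence[, setdiff(colnames(presence), ref_strain), drop = FALSE]
  known <- !is.na(nonref)
  genotyped <- rowSums(known) > 0
  nonref <- nonref[genotyped, , drop = FALSE]
  ref <- presence[genotyped, ref_strain]
  known <- known[genotyped, , drop = FALSE]

  all_present <- ref == 1 &
    rowSums(nonref == 1, na.rm = TRUE) == rowSums(known)
  ref_only <- ref == 1 & rowSums(nonref == 0, na.rm = TRUE) == rowSums(known)
  class <- ifelse(all_present, "present_in_all",
                  ifelse(ref_only, "reference_only", "polymorphic"))
  n <- length(class)
  counts <- c(present_in_all = sum(class == "present_in_all"),
              reference_only = sum(class == "reference_only"),
              polymorphic = sum(class == "polymorphic"))
  list(summary = data.frame(class = names(counts),
                            count = as.integer(counts),
                            pct = round_half_up(100 * counts / n, 1),
                            row.names = NULL, stringsAsFactors = FALSE),
       n_genotyped = n,
       class_by_te = setNames(class, rownames(presence)[genotyped]))
}

#' TE family or order enrichment in a subset
#'
#' For each family (or order), a Pearson chi-square on the 2x2 table of
#' subset membership against class membership over the TE universe, with
#' Benjamini-Hochberg adjustment across classes.
#'
#' @param subset_ids TE ids of the subset of interest.
#' @param te_families data.frame with `te_id`, `family`, `order`.
#' @param level `"family"` or `"order"`.
#' @param correct Yates correction flag passed to `chisq.test`.
#' @return data.frame per class: counts, `statistic`, `p_value`, `padj`,
#'   `enriched` (subset proportion above universe proportion).
#' @export
family_enrichment <- function(subset_ids, te_families,
                              level = c("family", "order"), correct = FALSE) {
  level <- match.arg(level)
  if (!all(subset_ids %in% te_families$te_id)) {
    stop_("subset contains TE ids absent from the universe")
  }
  cls <- te_families[[level]]
  in_sub <- te_families$te_id %in% subset_ids
  out <- lapply(unique(cls), function(cl) {
    in_cl <- cls == cl
    tab <- matrix(c(sum(in_sub & in_cl), sum(in_sub & !in_cl),
                    sum(!in_sub & in_cl), sum(!in_sub & !in_cl)),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(data.frame(class = cl, n_subset = tab[1, 1],
                        n_universe = sum(in_cl), statistic = NA_real_,
                        p_value = NA_real_, enriched = NA,
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    data.frame(class = cl, n_subset = tab[1, 1], n_universe = sum(in_cl),
               statistic = unname(ct$statistic), p_value = ct$p.value,
               enriched = tab[1, 1] / sum(in_sub) > sum(in_cl) / length(cls),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$padj <- NA_real_
  ok <- !is.na(res$p_value)
  res$padj[ok] <- bh_adjust(res$p_value[ok])
  res[order(res$p_value), ]
}
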