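# Evidence integration: the final candidate ledger joins hub DEGs, TE
# proximity, selection flags, cnc-binding-site counts and open-chromatin
# overlap. A TE is a candidate when it is the single TE near a hub DEG and
# carries at least one line of evidence (selection, cnc site, or an
# ATAC peak); cnc sites only count as evidence for TEs near upregulated
# hub genes, where a stress-response binding site is interpretable.

#' Apply the candidate retention rule to an evidence table
#'
#' @param evidence data.frame with columns `te_id`, `family`,
#'   `nearby_gene`, `te_location`, `gene_is_hub`, `gene_direction`,
#'   `single_te`, `selection_evidence` (`"none"` for no evidence),
#'   `cnc_bs` (integer), `atac_peak` (logical).
#' @param single_te_only require the hub gene to have a single TE nearby
#'   (default, the conservative rule); `FALSE` admits multi-TE hubs.
#' @return the retained rows with an `evidence_count` column, sorted by
#'   evidence count (descending) then `te_id`.
#' @export
apply_candidate_rule <- function(evidence, single_te_only = TRUE) {
  need <- c("te_id", "family", "nearby_gene", "te_location", "gene_is_hub",
            "gene_direction", "single_te", "selection_evidence", "cnc_bs",
            "atac_peak")
  miss <- setdiff(need, names(evidence))
  if (length(miss)) stop_("evidence lacks columns: %s", paste(miss, collapse = ", "))
  cnc_ok <- evidence$cnc_bs >= 1 &
    (is.na(evidence$gene_direction) | evidence$gene_direction != "down")
  evidence$evidence_count <-
    (evidence$selection_evidence != "none") + cnc_ok +
    (evidence$atac_peak %in% TRUE)
  keep <- evidence$gene_is_hub & evidence$evidence_count >= 1
  if (single_te_only) keep <- keep & evidence$single_te
  out <- evidence[keep, , drop = FALSE]
  out <- out[order(-out$evidence_count, out$te_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the candidate ledger from upstream stage outputs
#'
#' Joins the hub report, proximity links, selection flags, cnc-site counts
#' and TE-peak condition classes into one evidence row per (TE, hub gene)
#' pair, then applies the retention rule.
#'
#' @param hub_report from [hub_te_report()] (hub genes with nearby TEs).
#' @param links proximity links from [link_tes_to_genes()].
#' @param te_families data.frame with `te_id`, `family`.
#' @param selection_flags data.frame with `te_id`, `source`.
#' @param cnc_counts named integer vector of binding-site counts per TE.
#' @param te_peak_classes data.frame from [te_peak_overlap()].
#' @param single_te_only passed to [apply_candidate_rule()].
#' @return candidate data.frame (see [apply_candidate_rule()]).
#' @export
build_candidates <- function(hub_report, links, te_families, selection_flags,
                             cnc_counts, te_peak_classes,
                             single_te_only = TRUE) {
  if (nrow(hub_report) == 0) {
    return(apply_candidate_rule(data.frame(
      te_id = character(0), family = character(0), nearby_gene = character(0),
      te_location = character(0), gene_is_hub = logical(0),
      gene_direction = character(0), single_te = logical(0),
      selection_evidence = character(0), cnc_bs = integer(0),
      atac_peak = logical(0))))
  }
  sub <- links[links$gene_id %in% hub_report$gene_id, , drop = FALSE]
  orphans <- setdiff(sub$te_id, te_families$te_id)
  if (length(orphans)) {
    stop_("TE ids missing from te_families: %s", paste(orphans, collapse = ", "))
  }
  hr <- hub_report[match(sub$gene_id, hub_report$gene_id), ]
  sel <- selection_flags$source[match(sub$te_id, selection_flags$te_id)]
  cnc <- cnc_counts[sub$te_id]
  if (any(is.na(cnc))) {
    stop_("TE ids missing from cnc_counts: %s",
          paste(sub$te_id[is.na(cnc)], collapse = ", "))
  }
  peak_cls <- te_peak_classes$class[match(sub$te_id, te_peak_classes$te_id)]
  evidence <- data.frame(
    te_id = sub$te_id,
    family = te_families$family[match(sub$te_id, te_families$te_id)],
    nearby_gene = sub$gene_id,
    te_location = sub$relation,
    gene_is_hub = TRUE,
    gene_direction = hr$direction,
    single_te = hr$single_te,
    selection_evidence = ifelse(is.na(sel), "none", sel),
    cnc_bs = as.integer(cnc),
    atac_peak = !is.na(peak_cls) & peak_cls != "none",
    stringsAsFactors = FALSE)
  apply_candidate_rule(evidence, single_te_only = single_te_only)
}
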