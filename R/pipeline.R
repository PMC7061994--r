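# End-to-end run on a synthetic dataset: generate inputs, call DEGs per
# strain, link TEs to genes, rank hubs, process ATAC, scan motifs, test TE
# families, and integrate everything into the candidate ledger plus a run
# summary. Every stage seed is derived from the config seed, so two runs
# with the same configuration produce byte-identical outputs.

#' Thresholds of a pipeline run
#'
#' One document holding every tunable cutoff; defaults are the standard
#' values used throughout the package.
#'
#' @param alpha adjusted-p cutoff for gene DE.
#' @param min_fc gene fold-change cutoff.
#' @param family_alpha raw-p cutoff for TE-family DE.
#' @param family_min_fc family fold-change cutoff.
#' @param proximity_bp TE-gene proximity rule (strict `<`).
#' @param hub_fraction top fraction of MCC scores called hubs.
#' @param ppi_cutoff PPI confidence-score cutoff.
#' @param max_insert ATAC insert-size cutoff (inclusive).
#' @param min_overlap reciprocal peak-overlap fraction (strict `>`).
#' @param idr IDR cutoff (strict `<`).
#' @param flank summit flank for peak rescaling.
#' @param promoter_bp promoter window for peak assignment.
#' @param min_enrichment,min_width simple peak-caller parameters.
#' @param bg_windows,bg_window_size background-noise model parameters.
#' @return a `RunConfig` list.
#' @export
run_config <- function(alpha = 0.05, min_fc = 1.5, family_alpha = 0.05,
                       family_min_fc = 3, proximity_bp = 1000,
                       hub_fraction = 0.15, ppi_cutoff = 0.5,
                       max_insert = 100, min_overlap = 0.5, idr = 0.05,
                       flank = 100, promoter_bp = 1000, min_enrichment = 4,
                       min_width = 100, bg_windows = 10000,
                       bg_window_size = 1000) {
  as.list(environment())
}

#' Run the full synthetic pipeline
#'
#' @param config a [sim_config()]; its `rng_seed` drives every stage.
#' @param run_cfg a [run_config()] of analysis thresholds.
#' @param outdir optional directory; when given, the candidate ledger,
#'   per-stage tables and the run summary (JSON + TSV) are written there.
#' @return list with all stage outputs and `summary`.
#' @export
run_pipeline <- function(config = sim_config(), run_cfg = run_config(),
                         outdir = NULL) {
  sim <- simulate_genome(config)
  counts_sim <- simulate_counts(config, sim)
  copy_sim <- simulate_te_copy_counts(config, sim, counts_sim$sample_meta)
  atac_sim <- simulate_atac(config, sim)
  strains <- config$strains

  ## differential expression per strain
  de <- lapply(strains, function(s)
    nb_test(counts_sim$counts, counts_sim$sample_meta, s,
            alpha = run_cfg$alpha, min_fold_change = run_cfg$min_fc,
            sf_fallback = TRUE))
  names(de) <- strains
  deg_sets <- lapply(de, function(r) r$feature_id[r$is_deg])
  deg_overlap <- overlap_table(deg_sets)
  concordance <- list()
  for (i in seq_along(strains)) {
    for (j in seq_along(strains)) {
      if (i < j) {
        concordance[[paste(strains[i], strains[j], sep = "_vs_")]] <-
          direction_concordance(de[[i]], de[[j]])
      }
    }
  }

  ## TE-gene proximity and enrichment
  links <- link_tes_to_genes(sim$tes, sim$genes, max_dist = run_cfg$proximity_bp)
  gene_ids <- mcols(sim$genes)$gene_id
  te_enrich <- lapply(deg_sets, function(d)
    deg_te_enrichment(d, gene_ids, links))
  pct_deg_near_te <- vapply(deg_sets, function(d) {
    if (length(d) == 0) return(NA_real_)
    round_half_up(100 * mean(d %in% links$gene_id), 1)
  }, numeric(1))
  geno <- genotype_summary(sim$genotypes, config$ref_strain)

  ## PPI hubs per strain
  hubs <- list(); hub_reports <- list(); overlaps <- list()
  for (s in strains) {
    degs <- deg_sets[[s]]
    sizes <- config$planted_clique_sizes
    sizes <- sizes[cumsum(sizes) <= length(degs)]
    if (length(degs) < 4 || length(sizes) == 0) {
      hubs[[s]] <- character(0)
      hub_reports[[s]] <- hub_te_report(character(0), de[[s]], links)
      next
    }
    cfg_s <- config
    cfg_s$planted_clique_sizes <- sizes
    ppi <- simulate_ppi(degs, cfg_s, derive_seed(config$rng_seed, 100 + match(s, strains)),
                        clique_seed_genes = intersect(degs, links$gene_id))
    g <- load_ppi(ppi$edges, score_cutoff = run_cfg$ppi_cutoff)
    mcc <- mcc_scores(g)
    deg_sc <- degree_scores(g)
    hubs[[s]] <- top_hubs(mcc, fraction = run_cfg$hub_fraction)
    overlaps[[s]] <- method_overlap(top_hubs(deg_sc, run_cfg$hub_fraction),
                                    hubs[[s]])
    hub_reports[[s]] <- hub_te_report(hubs[[s]], de[[s]], links)
  }
  hub_report_all <- unique(do.call(rbind, hub_reports))

  ## ATAC chain per strain x condition
  atac <- list(); peak_sets <- list(); cov_tracks <- list()
  for (s in strains) {
    for (cond in c("control", "stress")) {
      key <- paste(s, cond, sep = "_")
      res <- atac_chain(atac_sim$fragments[[s]][[cond]], sim$seqlengths,
                        seed = derive_seed(config$rng_seed, 200 + length(atac)),
                        max_insert = run_cfg$max_insert,
                        min_enrichment = run_cfg$min_enrichment,
                        min_width = run_cfg$min_width,
                        min_overlap_frac = run_cfg$min_overlap,
                        idr_threshold = run_cfg$idr, flank = run_cfg$flank)
      atac[[key]] <- res
      peak_sets[[key]] <- res$peaks
      cov_tracks[[key]] <- res$coverage
    }
  }
  universal <- merge_universal(peak_sets)

  ## open/closed per strain x condition against the universal set
  open_by_cond <- list(control = GRanges(), stress = GRanges())
  open_calls <- list()
  for (key in names(cov_tracks)) {
    bg <- background_noise(cov_tracks[[key]], n_windows = run_cfg$bg_windows,
                           window_size = run_cfg$bg_window_size,
                           seed = derive_seed(config$rng_seed, 300 + match(key, names(cov_tracks))))
    oc <- call_open(universal, cov_tracks[[key]], bg)
    open_calls[[key]] <- oc
    cond <- sub("^.*_", "", key)
    open_by_cond[[cond]] <- c(open_by_cond[[cond]],
                              granges(oc[mcols(oc)$is_open %in% TRUE]))
  }
  open_by_cond <- lapply(open_by_cond, function(g) reduce(sort(g)))
  te_peak_cls <- te_peak_overlap(sim$tes, open_by_cond$control,
                                 open_by_cond$stress)
  peak_classes <- assign_peaks_to_genes(universal, sim$genes,
                                        promoter_bp = run_cfg$promoter_bp)

  ## cnc motif scanning
  motif <- default_cnc_motif()
  cnc_counts <- count_bs_per_feature(sim$te_seqs, motif)
  names(cnc_counts) <- names(sim$te_seqs)
  genome_seq <- atac_sim$genome_seq
  peak_motif_frac <- vapply(strains, function(s) {
    up <- de[[s]]$feature_id[de[[s]]$is_deg & de[[s]]$direction == "up"]
    idx <- peak_classes$peak_idx[!is.na(peak_classes$gene_id) &
                                   peak_classes$gene_id %in% up]
    if (length(idx) == 0) return(NA_real_)
    peaks_with_motif_fraction(universal[idx], genome_seq, motif)
  }, numeric(1))

  ## TE family expression
  fam_counts <- aggregate_family_counts(copy_sim$copy_counts, copy_sim$family_map)
  fam_de <- lapply(strains, function(s)
    family_de(fam_counts, counts_sim$sample_meta, s,
              alpha = run_cfg$family_alpha,
              min_fold_change = run_cfg$family_min_fc))
  names(fam_de) <- strains
  n_de_fam <- vapply(fam_de, function(r) sum(r$is_de), integer(1))
  tol_r <- if (config$n_strains >= 3)
    tolerance_correlation(config$mortality_pct, n_de_fam) else NA_real_
  fam_universe <- rownames(fam_counts)
  lfc_by_fam <- vapply(strains, function(s)
    setNames(fam_de[[s]]$log2_fold_change, fam_de[[s]]$feature_id)[fam_universe],
    numeric(length(fam_universe)))

  ## integration
  candidates <- build_candidates(hub_report_all, links, sim$te_families,
                                 sim$selection, cnc_counts, te_peak_cls)

  summary <- list(
    seed = config$rng_seed,
    n_genes = length(gene_ids), n_tes = length(sim$tes),
    n_degs = lapply(deg_sets, length),
    pct_degs_near_te = as.list(pct_deg_near_te),
    te_enrichment_p = lapply(te_enrich, function(x) x$p_value),
    genotype_pct = as.list(setNames(geno$summary$pct, geno$summary$class)),
    n_hubs = lapply(hubs, length),
    n_hub_genes_with_te = nrow(hub_report_all),
    n_hub_genes_single_te = sum(hub_report_all$single_te),
    hub_method_overlap_pct = lapply(overlaps, function(x) x$pct_of_b),
    n_reproducible_peaks = lapply(atac, function(x) x$n_after_idr),
    n_universal_peaks = length(universal),
    n_tes_with_open_peak = sum(te_peak_cls$class != "none"),
    te_peak_classes = as.list(table(te_peak_cls$class)),
    peak_motif_fraction = as.list(round(peak_motif_frac, 4)),
    n_de_families = as.list(n_de_fam),
    tolerance_correlation_r = round(tol_r, 4),
    n_candidates = nrow(candidates))

  out <- list(sim = sim, counts_sim = counts_sim, copy_sim = copy_sim,
              atac_sim = atac_sim, de = de, deg_sets = deg_sets,
              deg_overlap = deg_overlap, concordance = concordance,
              links = links, te_enrich = te_enrich, genotype = geno,
              hubs = hubs, hub_report = hub_report_all,
              method_overlaps = overlaps, atac = atac,
              universal_peaks = universal, open_calls = open_calls,
              open_by_cond = open_by_cond, te_peak_classes = te_peak_cls,
              peak_classes = peak_classes, cnc_counts = cnc_counts,
              peak_motif_frac = peak_motif_frac, family_counts = fam_counts,
              family_de = fam_de, lfc_by_family = lfc_by_fam,
              tolerance_r = tol_r, candidates = candidates,
              summary = summary, run_cfg = run_cfg)
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

#' Write pipeline outputs
#'
#' @param run a [run_pipeline()] result.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(run$de)) {
    write_tsv(run$de[[s]], file.path(outdir, sprintf("de_%s.tsv", s)))
  }
  write_tsv(run$links, file.path(outdir, "te_gene_links.tsv"))
  write_tsv(run$genotype$summary, file.path(outdir, "genotype_summary.tsv"))
  write_tsv(run$hub_report, file.path(outdir, "hub_te_report.tsv"))
  write_tsv(run$te_peak_classes, file.path(outdir, "te_peak_classes.tsv"))
  write_tsv(run$candidates, file.path(outdir, "candidates.tsv"))
  ov <- run$deg_overlap
  write_tsv(data.frame(strain = rownames(ov$counts), ov$counts,
                       check.names = FALSE),
            file.path(outdir, "deg_overlap_counts.tsv"))
  jsonlite::write_json(run$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Summarize a pipeline run
#'
#' @param run a [run_pipeline()] result.
#' @return the run's summary list.
#' @export
summarize_run <- function(run) run$summary
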