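small_cfg <- function(...) {
  sim_config(genome_size = 120000, n_chromosomes = 1, n_genes = 20,
             n_tes = 16, rng_seed = 11, ...)
}

test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(frac_de_genes = 1.4), "proportions")
  expect_error(sim_config(n_chromosomes = 0), "positive")
  expect_error(sim_config(lfc_range = c(0.3, 1)), "log2")
  expect_silent(sim_config(frac_de_genes = 0, lfc_range = c(0.3, 1)))
  expect_error(sim_config(nonsense_field = 2), "unknown config")
  expect_error(sim_config(frac_te_fixed = 0.8, frac_te_ref_only = 0.5),
               "exceed")
})

test_that("simulated genomes satisfy their construction contracts", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  # genes non-overlapping
  expect_equal(length(GenomicRanges::reduce(sim$genes)), length(sim$genes))
  # every TE has a family and an order
  expect_true(all(sim$te_families$order %in% c("LTR", "LINE", "DNA")))
  expect_equal(nrow(sim$te_families), cfg$n_tes)
  # FASTA ids match annotation ids, lengths match widths
  expect_setequal(names(sim$te_seqs), sim$te_families$te_id)
  expect_equal(unname(Biostrings::width(sim$te_seqs[sim$tes$te_id])),
               width(sim$tes))
  # genome too small: explicit sizing error
  expect_error(simulate_genome(sim_config(genome_size = 5000, n_genes = 50,
                                          n_chromosomes = 1)),
               "too small")
})

test_that("zero genes yield an empty but valid annotation", {
  cfg <- sim_config(genome_size = 60000, n_chromosomes = 1, n_genes = 0,
                    n_tes = 5, frac_te_near_gene = 0, rng_seed = 2)
  sim <- simulate_genome(cfg)
  expect_length(sim$genes, 0)
  path <- tempfile(fileext = ".gff3")
  write_gff3(sim$genes, path)
  expect_equal(readLines(path), "##gff-version 3")
})

test_that("forced proximity places every TE within reach of a gene", {
  cfg <- sim_config(genome_size = 300000, n_chromosomes = 1, n_genes = 55,
                    n_tes = 50, frac_te_near_gene = 1, rng_seed = 3)
  sim <- simulate_genome(cfg)
  links <- link_tes_to_genes(sim$tes, sim$genes)
  expect_setequal(unique(links$te_id), sim$te_families$te_id)
})

test_that("the ground-truth manifest round-trips against the emitted annotation", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  # proximity truth is exactly what an independent link pass finds
  links <- link_tes_to_genes(sim$tes, sim$genes)
  truth <- sim$truth$te_gene_links
  key <- function(d) paste(d$te_id, d$gene_id, d$relation, d$distance)
  expect_setequal(key(links), key(truth))
  # genotype classes agree with the summary classification
  gs <- genotype_summary(sim$genotypes, cfg$ref_strain)
  expect_equal(unname(gs$class_by_te[names(sim$truth$genotype_class)]),
               unname(sim$truth$genotype_class))
  # motif counts equal planted copies
  counts <- count_bs_per_feature(sim$te_seqs, default_cnc_motif())
  expect_equal(unname(counts), unname(lengths(sim$truth$motif_positions[names(counts)])))
})

test_that("regeneration under one seed is byte-identical on disk", {
  cfg <- sim_config(genome_size = 80000, n_chromosomes = 1, n_genes = 12,
                    n_tes = 10, n_strains = 2, mortality_pct = c(0, 25),
                    frac_open_regions = 0.05, rng_seed = 21)
  render <- function(dir) {
    sim <- simulate_genome(cfg)
    cs <- simulate_counts(cfg, sim)
    cp <- simulate_te_copy_counts(cfg, sim, cs$sample_meta)
    at <- simulate_atac(cfg, sim)
    write_bundle(sim, cs, cp, at, dir)
  }
  d1 <- tempfile("bundleA"); d2 <- tempfile("bundleB")
  render(d1); render(d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("file", f))
  }
})

test_that("count simulation plants recoverable effects and null data stay null", {
  cfg <- sim_config(genome_size = 200000, n_chromosomes = 1, n_genes = 40,
                    n_tes = 20, rng_seed = 5, frac_de_genes = 0)
  sim <- simulate_genome(cfg)
  cs <- simulate_counts(cfg, sim)
  expect_true(all(cs$counts >= 0))
  expect_equal(dim(cs$counts), c(40, 4 * 2 * 3))
  res <- nb_test(cs$counts, cs$sample_meta, "strainA", sf_fallback = TRUE)
  expect_equal(sum(res$padj <= 0.05), 0)

  cfg2 <- sim_config(genome_size = 200000, n_chromosomes = 1, n_genes = 40,
                     n_tes = 20, rng_seed = 5, frac_de_genes = 0.3,
                     lfc_range = c(2, 2))
  sim2 <- simulate_genome(cfg2)
  cs2 <- simulate_counts(cfg2, sim2)
  res2 <- nb_test(cs2$counts, cs2$sample_meta, "strainB", sf_fallback = TRUE)
  planted <- cs2$de_truth$strainB$gene_id
  expect_gt(mean(res2$is_deg[match(planted, res2$feature_id)]), 0.8)
})

test_that("fragment insert sizes follow the two-mode mixture and open regions are disjoint", {
  cfg <- small_cfg(n_strains = 2, mortality_pct = c(0, 25))
  sim <- simulate_genome(cfg)
  at <- simulate_atac(cfg, sim)
  frags <- at$fragments$strainA$control[[1]]
  w <- width(frags)
  # sub-nucleosomal mode present: a known fraction is <= 100 bp
  expect_gt(mean(w <= 100), 0.4)
  expect_gt(mean(w > 100), 0.05)
  # per-condition open regions are non-overlapping
  for (cond in c("control", "stress")) {
    gr <- at$open_truth[[cond]]
    expect_equal(length(GenomicRanges::reduce(gr)), length(gr))
  }
})

test_that("PPI generation embeds scored cliques over an ER background", {
  cfg <- sim_config(planted_clique_sizes = c(4, 3), ppi_background_density = 0)
  genes <- sprintf("g%02d", 1:20)
  ppi <- simulate_ppi(genes, cfg, seed = 8)
  # background density 0: the graph is exactly the union of planted cliques
  expect_equal(nrow(ppi$edges), choose(4, 2) + choose(3, 2))
  expect_true(all(ppi$edges$combined_score > 0.5))
  g <- load_ppi(ppi$edges, score_cutoff = 1.0)
  expect_equal(igraph::ecount(g), 0)
  expect_error(simulate_ppi(genes[1:5], cfg, seed = 1), "exceed")
})
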