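# Synthetic-data generator: emits every input the pipeline consumes --
# annotation, TE genotypes, RNA-seq counts, per-copy TE counts, ATAC
# fragments, PPI edge lists, TE sequences -- together with a ground-truth
# manifest, so each downstream stage can be validated against planted
# structure. All randomness flows from one run seed through fixed per-stage
# offsets, so any stage can be regenerated independently and byte-identically.

TE_FAMILY_ORDERS <- c(
  roo = "LTR", `412` = "LTR", gypsy8 = "LTR", accord = "LTR", Idefix = "LTR",
  micropia = "LTR", flea = "LTR", Tirant = "LTR", diver2 = "LTR",
  `1360` = "DNA", Bari1 = "DNA", `S-element` = "DNA", `INE-1` = "DNA",
  `F-element` = "LINE", Rt1b = "LINE", G5 = "LINE", jockey = "LINE",
  Doc = "LINE")

#' Simulation configuration
#'
#' Defaults describe a small diploid-free caricature of the study system:
#' four strains (two tolerant, two sensitive, mortality 0/0/15/25%), three
#' replicates per condition, genes sparse enough that every TE placement
#' regime (inside, <1 kb flank, distal) is realizable, dispersion and
#' fold-change ranges under which planted effects are recoverable at the
#' standard cutoffs.
#'
#' @param genome_size bp per chromosome.
#' @param n_chromosomes number of chromosomes.
#' @param n_genes,n_tes feature counts (whole genome).
#' @param n_strains,n_replicates experimental design.
#' @param frac_de_genes proportion of genes with a treatment effect per strain.
#' @param lfc_range |log2 fold-change| interval for planted effects.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param frac_te_near_gene proportion of TEs placed inside or <1 kb from genes.
#' @param frac_open_regions proportion of the genome in open chromatin.
#' @param open_coverage_mean,closed_coverage_mean ATAC coverage depths
#'   (filtered fragments, replicates pooled).
#' @param motif_seed_rate mean planted motif copies per TE sequence (Poisson).
#' @param rng_seed integer master seed.
#' @param ... overrides for the remaining list elements (see the returned
#'   object for names: library-size range, genotype class fractions,
#'   selection fraction, mortality, insert-size mixture, open-region
#'   geometry, PPI background density and clique sizes, ...).
#' @return a validated `SimulationConfig` list.
#' @export
sim_config <- function(genome_size = 400000, n_chromosomes = 2,
                       n_genes = 160, n_tes = 120, n_strains = 4,
                       n_replicates = 3, frac_de_genes = 0.15,
                       lfc_range = c(1, 2), nb_dispersion = 0.05,
                       frac_te_near_gene = 0.4, frac_open_regions = 0.08,
                       open_coverage_mean = 20, closed_coverage_mean = 1,
                       motif_seed_rate = 0.3, rng_seed = 1, ...) {
  cfg <- list(
    genome_size = genome_size, n_chromosomes = n_chromosomes,
    n_genes = n_genes, n_tes = n_tes, n_strains = n_strains,
    n_replicates = n_replicates, frac_de_genes = frac_de_genes,
    lfc_range = lfc_range, nb_dispersion = nb_dispersion,
    frac_te_near_gene = frac_te_near_gene,
    frac_open_regions = frac_open_regions,
    open_coverage_mean = open_coverage_mean,
    closed_coverage_mean = closed_coverage_mean,
    motif_seed_rate = motif_seed_rate, rng_seed = rng_seed,
    # expression model
    baseline_meanlog = log(150), baseline_sdlog = 1,
    lib_size_range = c(0.7, 1.4), de_te_bias = 3,
    # genotype classes (reference-annotated TEs)
    frac_te_fixed = 0.786, frac_te_ref_only = 0.119,
    frac_te_selected = 0.12, failed_genotype_rate = 0,
    # phenotype
    mortality_pct = c(0, 0, 15, 25),
    # ATAC
    insert_frac_sub = 0.8, insert_meanlog_sub = log(60),
    insert_sdlog_sub = 0.25, insert_meanlog_mono = log(200),
    insert_sdlog_mono = 0.2, bg_insert_frac_sub = 0.5,
    open_width_range = c(300, 600), open_intensity_sdlog = 0.6,
    frac_open_shared = 0.74,
    frac_open_on_te = 0.25, frac_open_at_promoter = 0.2,
    frac_open_with_motif = 0.15,
    # PPI
    ppi_background_density = 0.02, planted_clique_sizes = c(6, 5, 4),
    # TE family expression
    copy_meanlog = log(30), copy_sdlog = 1,
    fam_lfc_range = c(2, 3), de_families_per_mortality = 0.4,
    de_families_base = 1)
  extra <- list(...)
  if (length(extra)) {
    bad <- setdiff(names(extra), names(cfg))
    if (length(bad)) stop_("unknown config fields: %s", paste(bad, collapse = ", "))
    cfg[names(extra)] <- extra
  }
  props <- c(cfg$frac_de_genes, cfg$frac_te_near_gene, cfg$frac_open_regions,
             cfg$frac_te_fixed, cfg$frac_te_ref_only, cfg$frac_te_selected,
             cfg$frac_open_shared, cfg$frac_open_on_te, cfg$insert_frac_sub)
  if (any(props < 0 | props > 1)) stop_("all proportions must lie in [0, 1]")
  if (cfg$frac_te_fixed + cfg$frac_te_ref_only > 1) {
    stop_("genotype class fractions exceed 1")
  }
  counts <- c(cfg$genome_size, cfg$n_chromosomes, cfg$n_strains, cfg$n_replicates)
  if (any(counts <= 0)) stop_("counts must be positive")
  if (cfg$n_genes < 0 || cfg$n_tes < 0) stop_("feature counts must be >= 0")
  if (cfg$frac_de_genes > 0 && cfg$lfc_range[1] < log2(1.5)) {
    stop_("lfc_range lower bound must be >= log2(1.5) when DE genes are planted")
  }
  cfg$strains <- paste0("strain", LETTERS[seq_len(cfg$n_strains)])
  cfg$ref_strain <- cfg$strains[cfg$n_strains]
  cfg$mortality_pct <- rep_len(cfg$mortality_pct, cfg$n_strains)
  names(cfg$mortality_pct) <- cfg$strains
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Plant `n_copies` motif consensus instances at non-overlapping offsets, then
# mutate away any spurious (unplanted) hits so the scan count equals the
# planted count exactly.
seed_motif_into <- function(seq_chr, n_copies, motif) {
  L <- motif$length
  n <- nchar(seq_chr)
  planted <- integer(0)
  if (n_copies > 0 && n >= L) {
    avail <- seq_len(n - L + 1)
    for (k in seq_len(n_copies)) {
      ok <- avail[vapply(avail, function(o) all(abs(o - planted) >= L), logical(1))]
      if (length(ok) == 0) break
      o <- if (length(ok) == 1) ok else sample(ok, 1)
      inst <- paste0("TGAC", random_dna(3), "GC")
      substr(seq_chr, o, o + L - 1) <- inst
      planted <- c(planted, o)
    }
  }
  for (iter in 1:30) {
    hits <- scan_sequence(seq_chr, motif)
    spurious <- hits[!(hits$offset %in% planted & hits$strand == "+"), , drop = FALSE]
    if (nrow(spurious) == 0) break
    for (i in seq_len(nrow(spurious))) {
      span <- spurious$offset[i]:(spurious$offset[i] + L - 1)
      in_planted <- vapply(span, function(p)
        any(p >= planted & p <= planted + L - 1), logical(1))
      pos <- span[!in_planted]
      if (length(pos) == 0) next  # identical to a planted copy
      p <- pos[1]
      cur <- substr(seq_chr, p, p)
      substr(seq_chr, p, p) <- sample(setdiff(BASES, cur), 1)
    }
  }
  list(seq = seq_chr, offsets = sort(planted))
}

#' Simulate the annotation bundle
#'
#' Places non-overlapping genes on a slotted genome, then TEs either inside
#' genes, within 1 kb of a gene, or at least 1 kb from every gene, in the
#' configured proportions; assigns families/orders, genotypes (fixed /
#' reference-only / polymorphic), selection flags, and motif-seeded TE
#' sequences plus a random genome sequence.
#'
#' @param config a [sim_config()] object.
#' @return list with `genes`, `tes` (`GRanges`), `te_families`,
#'   `genotypes`, `selection`, `te_seqs`, `genome_seq`, `seqlengths`,
#'   `truth` (ground-truth manifest), `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(derive_seed(config$rng_seed, 1), {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    seqlengths <- setNames(rep(config$genome_size, config$n_chromosomes), chroms)
    margin <- 1600

    # genes: one per slot, margins on both sides
    n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
    gene_rows <- list()
    gi <- 0
    for (ci in seq_along(chroms)) {
      k <- n_per[ci]
      if (k == 0) next
      w <- floor(config$genome_size / k)
      max_len <- w - 2 * margin - 10
      if (max_len < 500) {
        stop_("genome too small: %d genes on a %d bp chromosome leave %d bp per gene",
              k, config$genome_size, max_len)
      }
      for (s in seq_len(k)) {
        gi <- gi + 1
        len <- round(runif(1, 500, min(1700, max_len)))
        slot_start <- (s - 1) * w + 1
        start <- slot_start + margin + sample.int(max(w - 2 * margin - len, 1), 1) - 1
        gene_rows[[gi]] <- data.frame(
          chrom = chroms[ci], start = start, end = start + len - 1,
          strand = sample(c("+", "-"), 1),
          gene_id = sprintf("gene%04d", gi))
      }
    }
    genes_df <- if (gi > 0) do.call(rbind, gene_rows) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), gene_id = character(0))
    genes <- GRanges(genes_df$chrom, IRanges(genes_df$start, genes_df$end),
                     strand = genes_df$strand, gene_id = genes_df$gene_id,
                     seqlengths = seqlengths)

    # TEs
    n_near <- round(config$frac_te_near_gene * config$n_tes)
    n_far <- config$n_tes - n_near
    if (n_near > length(genes)) stop_("genome too small: more near-gene TEs than genes")
    te_rows <- list()
    near_genes <- if (n_near > 0) sample(seq_along(genes), n_near) else integer(0)
    links_truth <- list()
    for (i in seq_len(n_near)) {
      g <- genes_df[near_genes[i], ]
      glen <- g$end - g$start + 1
      if (runif(1) < 0.5 && glen >= 300) {      # inside the gene span
        len <- round(runif(1, 150, min(800, glen)))
        start <- g$start + sample.int(glen - len + 1, 1) - 1
        relation <- "inside_gene"; dist <- 0L
      } else {                                  # flanking, gap < 1 kb
        gap <- sample(0:999, 1)
        len <- round(runif(1, 100, max(100, min(600, margin - gap - 10))))
        left <- runif(1) < 0.5
        start <- if (left) g$start - gap - len else g$end + gap + 1
        upstream_plus <- !isFALSE(left)
        relation <- if (xor(left, g$strand == "-")) "five_prime" else "three_prime"
        dist <- as.integer(gap)
      }
      te_rows[[length(te_rows) + 1]] <- data.frame(
        chrom = g$chrom, start = start, end = start + len - 1)
      links_truth[[length(links_truth) + 1]] <- data.frame(
        te_idx = length(te_rows), gene_id = g$gene_id, relation = relation,
        distance = dist)
    }
    # distal TEs: >= 1 kb from every gene, inside inter-gene gaps
    if (n_far > 0) {
      gaps <- list()
      for (ci in seq_along(chroms)) {
        gsub_ <- genes_df[genes_df$chrom == chroms[ci], , drop = FALSE]
        gsub_ <- gsub_[order(gsub_$start), , drop = FALSE]
        if (nrow(gsub_) == 0) {
          starts <- 1; ends <- config$genome_size
        } else {
          starts <- c(1, gsub_$end + 1001)
          ends <- c(gsub_$start - 1001, config$genome_size)
        }
        for (k in seq_along(starts)) {
          if (ends[k] - starts[k] >= 800) {
            gaps[[length(gaps) + 1]] <- data.frame(
              chrom = chroms[ci], start = starts[k], end = ends[k])
          }
        }
      }
      if (length(gaps) == 0) stop_("genome too small to place distal TEs")
      gaps <- do.call(rbind, gaps)
      widths <- gaps$end - gaps$start + 1
      for (i in seq_len(n_far)) {
        len <- round(runif(1, 150, 600))
        feas <- which(widths >= len)
        if (length(feas) == 0) stop_("genome too small to place distal TEs")
        gpick <- if (length(feas) == 1) feas else
          sample(feas, 1, prob = widths[feas])
        start <- gaps$start[gpick] +
          sample.int(widths[gpick] - len + 1, 1) - 1
        te_rows[[length(te_rows) + 1]] <- data.frame(
          chrom = gaps$chrom[gpick], start = start, end = start + len - 1)
      }
    }
    tes_df <- if (length(te_rows)) do.call(rbind, te_rows) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
    te_ids <- sprintf("FBti%07d", 9000000 + seq_len(nrow(tes_df)))
    tes <- GRanges(tes_df$chrom, IRanges(tes_df$start, tes_df$end),
                   strand = "*", te_id = te_ids, seqlengths = seqlengths)
    fam <- if (nrow(tes_df)) sample(names(TE_FAMILY_ORDERS), nrow(tes_df),
                                    replace = TRUE) else character(0)
    mcols(tes)$family <- fam
    mcols(tes)$order <- unname(TE_FAMILY_ORDERS[fam])
    te_families <- data.frame(te_id = te_ids, family = fam,
                              order = unname(TE_FAMILY_ORDERS[fam]),
                              stringsAsFactors = FALSE)

    links <- if (length(links_truth)) {
      lt <- do.call(rbind, links_truth)
      data.frame(te_id = te_ids[lt$te_idx], gene_id = lt$gene_id,
                 relation = lt$relation, distance = lt$distance,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(te_id = character(0), gene_id = character(0),
                 relation = character(0), distance = integer(0))
    }

    # genotypes
    n_te <- length(te_ids)
    u <- runif(n_te)
    class <- ifelse(u < config$frac_te_fixed, "present_in_all",
             ifelse(u < config$frac_te_fixed + config$frac_te_ref_only,
                    "reference_only", "polymorphic"))
    nonref <- setdiff(config$strains, config$ref_strain)
    genotypes <- matrix(1L, n_te, config$n_strains,
                        dimnames = list(te_ids, config$strains))
    for (i in seq_len(n_te)) {
      if (class[i] == "reference_only") {
        genotypes[i, nonref] <- 0L
      } else if (class[i] == "polymorphic") {
        v <- rbinom(length(nonref), 1, 0.5)
        if (all(v == 1)) v[sample.int(length(v), 1)] <- 0L
        if (all(v == 0)) v[sample.int(length(v), 1)] <- 1L
        genotypes[i, nonref] <- v
      }
    }
    if (config$failed_genotype_rate > 0 && n_te > 0) {
      na_mask <- matrix(runif(n_te * length(nonref)) < config$failed_genotype_rate,
                        n_te, length(nonref))
      genotypes[, nonref][na_mask] <- NA_integer_
    }

    sel_n <- round(config$frac_te_selected * n_te)
    sel_ids <- if (sel_n > 0) sample(te_ids, sel_n) else character(0)
    selection <- data.frame(
      te_id = sel_ids,
      source = if (sel_n > 0)
        sample(c("TajimaD", "H12", "fTE", "young_and_long"), sel_n, replace = TRUE)
      else character(0),
      stringsAsFactors = FALSE)

    # sequences: TE FASTA (motif-seeded) and a random genome
    motif <- default_cnc_motif()
    motif_truth <- list()
    te_seq_chr <- character(n_te)
    for (i in seq_len(n_te)) {
      len <- GenomicRanges::width(tes)[i]
      n_cop <- rpois(1, config$motif_seed_rate)
      res <- seed_motif_into(random_dna(len), n_cop, motif)
      te_seq_chr[i] <- res$seq
      motif_truth[[te_ids[i]]] <- res$offsets
    }
    te_seqs <- DNAStringSet(setNames(te_seq_chr, te_ids))
    genome_seq <- DNAStringSet(setNames(
      vapply(chroms, function(c) random_dna(config$genome_size), character(1)),
      chroms))

    truth <- list(
      te_gene_links = links,
      genotype_class = setNames(class, te_ids),
      selection = selection,
      motif_positions = motif_truth,
      family_of_te = setNames(fam, te_ids))

    list(genes = genes, tes = tes, te_families = te_families,
         genotypes = genotypes, selection = selection, te_seqs = te_seqs,
         genome_seq = genome_seq, seqlengths = seqlengths, truth = truth,
         config = config)
  })
}

#' Simulate RNA-seq counts under the strain x treatment design
#'
#' Counts are negative binomial around a log-linear model with gene baseline,
#' a small strain effect, and planted strain-specific treatment effects
#' (signed log2 fold changes drawn from `lfc_range`); genes near TEs are
#' preferentially chosen as DE (weight `de_te_bias`), emulating TE-proximal
#' regulatory effects. Library sizes vary across samples within
#' `lib_size_range`.
#'
#' @param config a [sim_config()] object.
#' @param sim output of [simulate_genome()].
#' @return list with `counts` (matrix), `sample_meta`, and `de_truth`
#'   (per-strain data.frames of planted genes with sign and lfc).
#' @export
simulate_counts <- function(config, sim) {
  with_seed(derive_seed(config$rng_seed, 2), {
    gene_ids <- mcols(sim$genes)$gene_id
    n_g <- length(gene_ids)
    strains <- config$strains
    sample_meta <- expand.grid(replicate = seq_len(config$n_replicates),
                               treatment = c("control", "stress"),
                               strain = strains, stringsAsFactors = FALSE)
    sample_meta <- sample_meta[, c("strain", "treatment", "replicate")]
    sample_meta$sample_id <- sprintf("%s_%s_rep%d", sample_meta$strain,
                                     sample_meta$treatment, sample_meta$replicate)
    baseline <- rlnorm(n_g, config$baseline_meanlog, config$baseline_sdlog)
    strain_eff <- matrix(rnorm(n_g * length(strains), 0, 0.05), n_g,
                         dimnames = list(gene_ids, strains))
    near_te <- gene_ids %in% sim$truth$te_gene_links$gene_id
    w <- ifelse(near_te, config$de_te_bias, 1)
    n_de <- round(config$frac_de_genes * n_g)
    de_truth <- list()
    lfc_mat <- matrix(0, n_g, length(strains), dimnames = list(gene_ids, strains))
    for (s in strains) {
      ids <- if (n_de > 0) sample(gene_ids, n_de, prob = w) else character(0)
      sign <- sample(c(-1, 1), n_de, replace = TRUE)
      mag <- runif(n_de, config$lfc_range[1], config$lfc_range[2])
      lfc_mat[ids, s] <- sign * mag
      de_truth[[s]] <- data.frame(gene_id = ids, sign = sign,
                                  lfc = sign * mag, stringsAsFactors = FALSE)
    }
    lib <- runif(nrow(sample_meta), config$lib_size_range[1],
                 config$lib_size_range[2])
    counts <- matrix(0L, n_g, nrow(sample_meta),
                     dimnames = list(gene_ids, sample_meta$sample_id))
    for (j in seq_len(nrow(sample_meta))) {
      s <- sample_meta$strain[j]
      mu <- baseline * 2^strain_eff[, s]
      if (sample_meta$treatment[j] == "stress") mu <- mu * 2^lfc_mat[, s]
      counts[, j] <- rnbinom(n_g, mu = mu * lib[j], size = 1 / config$nb_dispersion)
    }
    list(counts = counts, sample_meta = sample_meta, de_truth = de_truth,
         lib_factors = setNames(lib, sample_meta$sample_id))
  })
}

#' Simulate per-copy TE read counts with planted DE families
#'
#' The number of DE families per strain scales with the strain's mortality
#' (`de_families_base + de_families_per_mortality * mortality`), so the
#' burden of deregulated families correlates with sensitivity; planted
#' family fold changes are drawn from `fam_lfc_range` (log2).
#'
#' @param config a [sim_config()] object.
#' @param sim output of [simulate_genome()].
#' @param sample_meta sample sheet from [simulate_counts()].
#' @return list with `copy_counts` (copies x samples), `family_map`,
#'   `de_family_truth` (per strain: family, sign, lfc).
#' @export
simulate_te_copy_counts <- function(config, sim, sample_meta) {
  with_seed(derive_seed(config$rng_seed, 4), {
    copy_ids <- mcols(sim$tes)$te_id
    fam <- sim$truth$family_of_te
    fams <- sort(unique(unname(fam)))
    baseline <- rlnorm(length(copy_ids), config$copy_meanlog, config$copy_sdlog)
    de_truth <- list()
    lfc_fam <- matrix(0, length(fams), config$n_strains,
                      dimnames = list(fams, config$strains))
    for (s in config$strains) {
      n_de <- min(length(fams), round(config$de_families_base +
        config$de_families_per_mortality * config$mortality_pct[[s]]))
      picks <- if (n_de > 0) sample(fams, n_de) else character(0)
      sign <- sample(c(-1, 1), n_de, replace = TRUE)
      mag <- runif(n_de, config$fam_lfc_range[1], config$fam_lfc_range[2])
      lfc_fam[picks, s] <- sign * mag
      de_truth[[s]] <- data.frame(family = picks, sign = sign, lfc = sign * mag,
                                  stringsAsFactors = FALSE)
    }
    counts <- matrix(0L, length(copy_ids), nrow(sample_meta),
                     dimnames = list(copy_ids, sample_meta$sample_id))
    for (j in seq_len(nrow(sample_meta))) {
      s <- sample_meta$strain[j]
      mu <- baseline
      if (sample_meta$treatment[j] == "stress") {
        mu <- mu * 2^lfc_fam[fam[copy_ids], s]
      }
      counts[, j] <- rnbinom(length(copy_ids), mu = mu,
                             size = 1 / config$nb_dispersion)
    }
    list(copy_counts = counts,
         family_map = data.frame(copy_id = copy_ids, family = unname(fam[copy_ids]),
                                 stringsAsFactors = FALSE),
         de_family_truth = de_truth)
  })
}

place_nonoverlapping <- function(n, width_range, seqlengths, occupied, anchors = NULL) {
  # anchors: optional GRanges to centre regions on (TE-anchored open regions)
  out <- GRanges(seqlengths = seqlengths)
  tries <- 0
  while (length(out) < n && tries < n * 200) {
    tries <- tries + 1
    w <- round(runif(1, width_range[1], width_range[2]))
    if (!is.null(anchors) && length(anchors) > 0) {
      a <- anchors[sample.int(length(anchors), 1)]
      centre <- round((GenomicRanges::start(a) + GenomicRanges::end(a)) / 2)
      chr <- as.character(seqnames(a))
      start <- max(1, centre - floor(w / 2))
    } else {
      chr <- sample(names(seqlengths), 1,
                    prob = as.numeric(seqlengths) / sum(as.numeric(seqlengths)))
      start <- sample.int(seqlengths[[chr]] - w + 1, 1)
    }
    end <- min(start + w - 1, seqlengths[[chr]])
    cand <- GRanges(chr, IRanges(start, end), seqlengths = seqlengths)
    if (!any(IRanges::overlapsAny(cand, occupied)) &&
        !any(IRanges::overlapsAny(cand, out))) {
      out <- c(out, cand)
      if (!is.null(anchors)) {
        hit <- which(IRanges::overlapsAny(anchors, cand))
        if (length(hit)) anchors <- anchors[-hit]
      }
    }
  }
  sort(out)
}

#' Simulate ATAC fragments and planted open chromatin
#'
#' Open regions are placed non-overlapping, a configured fraction centred on
#' TEs and another at gene promoters, and assigned to conditions (shared /
#' control-only / stress-only). Fragments have insert sizes from a
#' two-component log-normal mixture (sub-nucleosomal and mono-nucleosomal
#' modes), so the <= 100 bp filter retains a known fraction; filtered
#' fragment density reaches `open_coverage_mean` inside a condition's open
#' regions and `closed_coverage_mean` elsewhere.
#'
#' @param config a [sim_config()] object.
#' @param sim output of [simulate_genome()].
#' @return list with `fragments` (fragments\[\[strain\]\]\[\[condition\]\] =
#'   list of replicate `GRanges`) and `open_truth` (per-condition `GRanges`
#'   plus the planted condition class per region).
#' @export
simulate_atac <- function(config, sim) {
  with_seed(derive_seed(config$rng_seed, 3), {
    sl <- sim$seqlengths
    total <- sum(as.numeric(sl))
    mean_w <- mean(config$open_width_range)
    n_open <- round(config$frac_open_regions * total / mean_w)
    n_on_te <- round(config$frac_open_on_te * n_open)
    n_at_prom <- round(config$frac_open_at_promoter * n_open)

    occupied <- GRanges(seqlengths = sl)
    on_te <- place_nonoverlapping(n_on_te, config$open_width_range, sl,
                                  occupied, anchors = sim$tes)
    occupied <- c(occupied, on_te)
    proms <- suppressWarnings(GenomicRanges::trim(
      promoters(sim$genes, upstream = 400, downstream = 100)))
    at_prom <- place_nonoverlapping(n_at_prom, config$open_width_range, sl,
                                    occupied, anchors = proms)
    occupied <- c(occupied, at_prom)
    rest <- place_nonoverlapping(n_open - length(on_te) - length(at_prom),
                                 config$open_width_range, sl, occupied)
    open_all <- sort(c(granges(on_te), granges(at_prom), granges(rest)))
    n_open <- length(open_all)

    cls <- sample(c("both", "control_only", "stress_only"), n_open,
                  replace = TRUE,
                  prob = c(config$frac_open_shared,
                           (1 - config$frac_open_shared) / 2,
                           (1 - config$frac_open_shared) / 2))
    # per-region accessibility multiplier: peak intensities span a wide
    # dynamic range in real data (mean 1 on the natural scale)
    intensity <- rlnorm(n_open, -config$open_intensity_sdlog^2 / 2,
                        config$open_intensity_sdlog)
    open_control <- open_all[cls %in% c("both", "control_only")]
    open_stress <- open_all[cls %in% c("both", "stress_only")]
    int_control <- intensity[cls %in% c("both", "control_only")]
    int_stress <- intensity[cls %in% c("both", "stress_only")]

    # plant cnc motifs in the genome inside a fraction of open regions
    genome_chr <- as.character(sim$genome_seq)
    motif <- default_cnc_motif()
    with_motif <- which(runif(n_open) < config$frac_open_with_motif)
    motif_genome <- list()
    for (i in with_motif) {
      chr <- as.character(seqnames(open_all))[i]
      centre <- round((GenomicRanges::start(open_all)[i] +
                         GenomicRanges::end(open_all)[i]) / 2)
      inst <- paste0("TGAC", random_dna(3), "GC")
      substr(genome_chr[[chr]], centre, centre + 8) <- inst
      motif_genome[[length(motif_genome) + 1]] <-
        data.frame(chrom = chr, offset = centre)
    }
    genome_seq <- DNAStringSet(genome_chr)

    mean_sub <- exp(config$insert_meanlog_sub + config$insert_sdlog_sub^2 / 2)
    draw_frags <- function(region_gr, cov, frac_sub, intensity = 1) {
      n_fr <- rpois(length(region_gr),
                    intensity * GenomicRanges::width(region_gr) * cov /
                      (frac_sub * mean_sub))
      tot <- sum(n_fr)
      if (tot == 0) return(GRanges(seqlengths = sl))
      chr <- rep(as.character(seqnames(region_gr)), n_fr)
      rs <- rep(GenomicRanges::start(region_gr), n_fr)
      rw <- rep(GenomicRanges::width(region_gr), n_fr)
      pos <- rs + floor(runif(tot) * rw)
      sub <- runif(tot) < frac_sub
      ins <- ifelse(sub,
                    rlnorm(tot, config$insert_meanlog_sub, config$insert_sdlog_sub),
                    rlnorm(tot, config$insert_meanlog_mono, config$insert_sdlog_mono))
      ins <- pmax(20L, pmin(as.integer(round(ins)), 1000L))
      end <- pmin(pos + ins - 1, sl[chr])
      sort(GRanges(chr, IRanges(pos, end), seqlengths = sl))
    }

    whole <- GRanges(names(sl), IRanges(1, sl), seqlengths = sl)
    frags <- list()
    for (s in config$strains) {
      frags[[s]] <- list()
      for (cond in c("control", "stress")) {
        open_gr <- if (cond == "control") open_control else open_stress
        open_int <- if (cond == "control") int_control else int_stress
        reps <- list()
        for (r in seq_len(config$n_replicates)) {
          fg_open <- draw_frags(open_gr,
                                config$open_coverage_mean / config$n_replicates,
                                config$insert_frac_sub, intensity = open_int)
          fg_bg <- draw_frags(whole,
                              config$closed_coverage_mean / config$n_replicates,
                              config$bg_insert_frac_sub)
          reps[[r]] <- sort(c(fg_open, fg_bg))
        }
        frags[[s]][[cond]] <- reps
      }
    }
    list(fragments = frags,
         genome_seq = genome_seq,
         open_truth = list(all = open_all, class = cls,
                           control = open_control, stress = open_stress,
                           motif_genome = if (length(motif_genome))
                             do.call(rbind, motif_genome) else NULL))
  })
}

#' Simulate a scored PPI edge list with planted cliques
#'
#' Cliques of the configured sizes are planted among designated seed genes
#' (falling back to the first network genes) on top of an Erdos-Renyi
#' background; planted edges score in (0.7, 0.99), background edges span
#' (0, 1) so the confidence cutoff prunes part of them.
#'
#' @param gene_ids network node ids (e.g. the DEGs of one strain).
#' @param config a [sim_config()] object.
#' @param seed integer seed (use a strain-specific derived seed).
#' @param clique_seed_genes optional genes to preferentially place in cliques.
#' @return list with `edges` (gene_a, gene_b, combined_score) and
#'   `clique_truth` (list of planted clique memberships).
#' @export
simulate_ppi <- function(gene_ids, config, seed, clique_seed_genes = NULL) {
  sizes <- config$planted_clique_sizes
  if (sum(sizes) > length(gene_ids)) {
    stop_("planted clique sizes (%d genes) exceed the %d network genes",
          sum(sizes), length(gene_ids))
  }
  with_seed(seed, {
    pool <- unique(c(intersect(clique_seed_genes, gene_ids),
                     sample(gene_ids)))
    cliques <- list()
    used <- 0
    for (k in sizes) {
      cliques[[length(cliques) + 1]] <- pool[(used + 1):(used + k)]
      used <- used + k
    }
    edges <- list()
    for (cl in cliques) {
      pr <- t(combn(sort(cl), 2))
      edges[[length(edges) + 1]] <- data.frame(
        gene_a = pr[, 1], gene_b = pr[, 2],
        combined_score = round(runif(nrow(pr), 0.7, 0.99), 3),
        stringsAsFactors = FALSE)
    }
    n <- length(gene_ids)
    if (config$ppi_background_density > 0 && n >= 2) {
      all_pairs <- t(combn(sort(gene_ids), 2))
      pick <- runif(nrow(all_pairs)) < config$ppi_background_density
      if (any(pick)) {
        edges[[length(edges) + 1]] <- data.frame(
          gene_a = all_pairs[pick, 1], gene_b = all_pairs[pick, 2],
          combined_score = round(runif(sum(pick), 0, 1), 3),
          stringsAsFactors = FALSE)
      }
    }
    edges <- do.call(rbind, edges)
    edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b)), ]
    rownames(edges) <- NULL
    list(edges = edges, clique_truth = cliques)
  })
}

#' Write a simulated dataset to files
#'
#' Emits the fixed layout consumed by file-based runs: gene and TE GFF3,
#' family and genotype and selection TSVs, TE and genome FASTA, counts and
#' sample-sheet TSVs, per-copy TE counts, tagAlign fragments per
#' strain/condition/replicate, bedGraph coverage per strain/condition, and
#' the ground-truth manifest as JSON.
#'
#' @param sim output of [simulate_genome()].
#' @param counts_sim output of [simulate_counts()].
#' @param copy_sim output of [simulate_te_copy_counts()].
#' @param atac_sim output of [simulate_atac()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(sim, counts_sim, copy_sim, atac_sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fragments"), showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  write_gff3(sim$genes, file.path(dir, "genes.gff3"), type = "gene")
  write_gff3(sim$tes, file.path(dir, "tes.gff3"), type = "transposable_element")
  write_tsv(sim$te_families, file.path(dir, "te_families.tsv"))
  geno <- data.frame(te_id = rownames(sim$genotypes), sim$genotypes,
                     check.names = FALSE)
  write_tsv(geno, file.path(dir, "genotypes.tsv"))
  write_tsv(sim$selection, file.path(dir, "selection.tsv"))
  writeXStringSet(sim$te_seqs, file.path(dir, "te_sequences.fa"))
  writeXStringSet(atac_sim$genome_seq %||% sim$genome_seq,
                  file.path(dir, "genome.fa"))
  write_counts_tsv(counts_sim$counts, file.path(dir, "counts.tsv"),
                   id_name = "gene_id")
  write_tsv(counts_sim$sample_meta, file.path(dir, "samples.tsv"))
  write_counts_tsv(copy_sim$copy_counts, file.path(dir, "te_copy_counts.tsv"),
                   id_name = "copy_id")
  write_tsv(copy_sim$family_map, file.path(dir, "te_family_map.tsv"))
  for (s in names(atac_sim$fragments)) {
    for (cond in names(atac_sim$fragments[[s]])) {
      reps <- atac_sim$fragments[[s]][[cond]]
      for (r in seq_along(reps)) {
        write_tagalign(reps[[r]], file.path(
          dir, "fragments", sprintf("%s_%s_rep%d.tagAlign", s, cond, r)))
      }
      pooled <- filter_fragments(Reduce(c, reps))
      write_bedgraph(coverage_from_fragments(pooled, sim$seqlengths),
                     file.path(dir, "coverage", sprintf("%s_%s.bedGraph", s, cond)))
    }
  }
  manifest <- list(
    config = sim$config[setdiff(names(sim$config), character(0))],
    de_genes = counts_sim$de_truth,
    de_families = copy_sim$de_family_truth,
    te_gene_links = sim$truth$te_gene_links,
    genotype_class = as.list(sim$truth$genotype_class),
    selection = sim$truth$selection,
    motif_positions = sim$truth$motif_positions,
    open_regions = list(
      class = atac_sim$open_truth$class,
      intervals = data.frame(
        chrom = as.character(seqnames(atac_sim$open_truth$all)),
        start = GenomicRanges::start(atac_sim$open_truth$all),
        end = GenomicRanges::end(atac_sim$open_truth$all))),
    mortality_pct = as.list(sim$config$mortality_pct))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
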