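# Differential expression between stress and control within each strain.
#
# The samples follow a strain + treatment + strain:treatment design; the
# per-strain contrast of interest is the strain-specific treatment effect,
# which under the cell-means parametrization equals the stress-vs-control
# comparison restricted to that strain. Counts are modelled as negative
# binomial with per-gene dispersion estimated by method of moments on
# normalized counts, and the treatment effect is tested with a Wald statistic
# referred to a t distribution whose degrees of freedom equal the residual
# degrees of freedom used for the dispersion estimate.

#' Median-of-ratios size factors
#'
#' Library-size normalization: each sample's factor is the median across
#' features of the ratio between its count and the feature's geometric mean,
#' using only features with nonzero counts in every sample. Raw medians are
#' returned (no rescaling to unit geometric mean).
#'
#' @param counts integer matrix, features x samples.
#' @param fallback if no feature is expressed in every sample, setting this to
#'   `TRUE` switches to a pseudo-reference built from `log(count + 0.5)`
#'   averages; the result then carries `attr(, "fallback") = TRUE`.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, fallback = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_("counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (!fallback) {
      stop_(paste("no feature has nonzero counts in every sample;",
                  "call size_factors(..., fallback = TRUE) to use a",
                  "pseudo-reference"))
    }
    lp <- log(counts + 0.5)
    loggeo <- rowMeans(lp)
    sf <- apply(lp, 2, function(col) exp(median(col - loggeo)))
    attr(sf, "fallback") <- TRUE
    return(sf)
  }
  sub <- counts[all_pos, , drop = FALSE]
  loggeo <- rowMeans(log(sub))
  sf <- apply(log(sub), 2, function(col) exp(median(col - loggeo)))
  names(sf) <- colnames(counts)
  sf
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

check_sample_meta <- function(counts, sample_meta) {
  need <- c("sample_id", "strain", "treatment")
  if (!all(need %in% names(sample_meta))) {
    stop_("sample_meta must have columns %s", paste(need, collapse = ", "))
  }
  if (!setequal(colnames(counts), sample_meta$sample_id) ||
      anyDuplicated(sample_meta$sample_id)) {
    stop_("sample_meta$sample_id must match colnames(counts) exactly")
  }
  if (!all(sample_meta$treatment %in% c("control", "stress"))) {
    stop_("treatment must be 'control' or 'stress'")
  }
  sample_meta[match(colnames(counts), sample_meta$sample_id), , drop = FALSE]
}

#' Negative-binomial Wald test for the treatment effect of one strain
#'
#' Dispersions are estimated per gene by pooled within-cell method of moments
#' on normalized counts (floored at 1e-8); with `design = "full"` every
#' strain x treatment cell in the matrix contributes residual degrees of
#' freedom, with `design = "per_strain"` only the two cells of the tested
#' strain do.
#'
#' @param counts integer matrix, features x samples.
#' @param sample_meta data.frame with `sample_id`, `strain`, `treatment`
#'   (control/stress) and `replicate`.
#' @param strain strain whose stress-vs-control contrast is tested.
#' @param alpha adjusted-p cutoff for the DEG flag.
#' @param min_fold_change fold-change cutoff (applied as |FC| >= value).
#' @param design `"full"` (default) or `"per_strain"`; see Details.
#' @param sf optional precomputed size factors.
#' @param sf_fallback passed to [size_factors()].
#' @return data.frame with one row per feature: `feature_id`, `base_mean`,
#'   `log2_fold_change` (stress vs control), `p_value`, `padj`, `is_deg`,
#'   `direction`, `flagged` (all-zero or zero-group features).
#' @export
nb_test <- function(counts, sample_meta, strain, alpha = 0.05,
                    min_fold_change = 1.5, design = c("full", "per_strain"),
                    sf = NULL, sf_fallback = FALSE) {
  design <- match.arg(design)
  counts <- as.matrix(counts)
  sample_meta <- check_sample_meta(counts, sample_meta)
  if (!strain %in% sample_meta$strain) stop_("strain '%s' not in sample_meta", strain)
  in_strain <- sample_meta$strain == strain
  for (tr in c("control", "stress")) {
    if (sum(in_strain & sample_meta$treatment == tr) < 2) {
      stop_("need >= 2 replicates of %s/%s", strain, tr)
    }
  }
  if (design == "per_strain") {
    counts <- counts[, in_strain, drop = FALSE]
    sample_meta <- sample_meta[in_strain, , drop = FALSE]
    if (!is.null(sf)) sf <- sf[in_strain]
    in_strain <- rep(TRUE, ncol(counts))
  }
  if (is.null(sf)) sf <- size_factors(counts, fallback = sf_fallback)
  norm <- sweep(counts, 2, sf, "/")

  cell <- interaction(sample_meta$strain, sample_meta$treatment, drop = TRUE)
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts)); df_resid <- 0
  for (cl in levels(cell)) {
    j <- which(cell == cl)
    if (length(j) < 2) next
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- rowVars_(norm[, j, drop = FALSE])
    h <- mean(1 / sf[j])                     # shot-noise scale on the normalized axis
    w <- length(j) - 1
    num <- num + w * (v - m * h)
    den <- den + w * m^2
    df_resid <- df_resid + w
  }
  disp <- ifelse(den > 0, pmax(num / den, 1e-8), 1e-8)

  g0 <- which(in_strain & sample_meta$treatment == "control")
  g1 <- which(in_strain & sample_meta$treatment == "stress")
  m0 <- rowMeans(norm[, g0, drop = FALSE]); n0 <- length(g0)
  m1 <- rowMeans(norm[, g1, drop = FALSE]); n1 <- length(g1)
  h0 <- mean(1 / sf[g0]); h1 <- mean(1 / sf[g1])

  all_zero <- m0 == 0 & m1 == 0
  some_zero <- (m0 == 0 | m1 == 0) & !all_zero
  pseudo <- 0.5 * mean(1 / sf)
  m0a <- ifelse(some_zero, m0 + pseudo, m0)
  m1a <- ifelse(some_zero, m1 + pseudo, m1)

  lfc <- ifelse(all_zero, 0, log2(m1a / m0a))
  v_log <- h0 / (n0 * m0a) + disp / n0 + h1 / (n1 * m1a) + disp / n1
  wald <- ifelse(all_zero | v_log <= 0, 0, log(m1a / m0a) / sqrt(v_log))
  p <- 2 * pt(-abs(wald), df = max(df_resid, 1))
  p[all_zero] <- 1
  padj <- bh_adjust(p)
  is_deg <- padj <= alpha & abs(lfc) >= log2(min_fold_change)

  data.frame(
    feature_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = rowMeans(norm),
    log2_fold_change = lfc,
    dispersion = disp,
    p_value = p,
    padj = padj,
    is_deg = is_deg,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
    flagged = all_zero | some_zero,
    stringsAsFactors = FALSE
  )
}

#' Cross-strain DEG overlap table
#'
#' Shared-DEG counts for every strain pair, with percentages expressed
#' relative to the column strain's DEG total and rounded half-up to one
#' decimal.
#'
#' @param deg_sets named list of DEG id vectors, one per strain.
#' @return list with `counts` (shared counts, diagonal = set sizes), `pct`
#'   (percentage of the column strain's DEGs, `NA` on the diagonal and for
#'   empty column sets) and `sizes`.
#' @export
overlap_table <- function(deg_sets) {
  stopifnot(is.list(deg_sets), !is.null(names(deg_sets)))
  ns <- names(deg_sets)
  k <- length(ns)
  counts <- matrix(0L, k, k, dimnames = list(ns, ns))
  pct <- matrix(NA_real_, k, k, dimnames = list(ns, ns))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      shared <- length(intersect(deg_sets[[i]], deg_sets[[j]]))
      counts[i, j] <- shared
      if (i != j) {
        nc <- length(unique(deg_sets[[j]]))
        pct[i, j] <- if (nc == 0) NA_real_ else round_half_up(100 * shared / nc, 1)
      }
    }
  }
  diag(counts) <- vapply(deg_sets, function(s) length(unique(s)), integer(1))
  list(counts = counts, pct = pct,
       sizes = vapply(deg_sets, function(s) length(unique(s)), integer(1)))
}

#' Direction concordance between two DEG result sets
#'
#' @param res_a,res_b data.frames as returned by [nb_test()]; only rows with
#'   `is_deg` are considered.
#' @return list with `n_shared`, `n_same_direction`, `n_opposite`.
#' @export
direction_concordance <- function(res_a, res_b) {
  a <- res_a[res_a$is_deg, c("feature_id", "log2_fold_change")]
  b <- res_b[res_b$is_deg, c("feature_id", "log2_fold_change")]
  shared <- intersect(a$feature_id, b$feature_id)
  sa <- sign(a$log2_fold_change[match(shared, a$feature_id)])
  sb <- sign(b$log2_fold_change[match(shared, b$feature_id)])
  list(n_shared = length(shared),
       n_same_direction = sum(sa == sb),
       n_opposite = sum(sa != sb))
}
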