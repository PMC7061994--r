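# ATAC-seq post-processing: insert-size filter, pooled random split, a
# simple threshold peak caller, reciprocal-overlap reproducibility, IDR
# filter, summit rescaling, universal peak set, random-window background
# noise and open/closed calls, peak-to-gene assignment, TE-peak overlap
# classes, and quantile scaling of accessibility profiles.

#' Filter fragments by insert size
#'
#' Keeps fragments with insert size (fragment width) less than or equal to
#' `max_insert` -- the boundary is inclusive.
#'
#' @param frags `GRanges` of fragments.
#' @param max_insert maximum insert size in bp.
#' @return filtered `GRanges`.
#' @export
filter_fragments <- function(frags, max_insert = 100) {
  frags[GenomicRanges::width(frags) <= max_insert]
}

#' Pool replicate fragment sets and split them in two at random
#'
#' Fragments from all replicates are merged and partitioned uniformly at
#' random into two pseudo-replicates whose sizes differ by at most one.
#' Deterministic under `seed`.
#'
#' @param replicate_sets list of fragment `GRanges`.
#' @param seed integer seed.
#' @return list of two `GRanges` (`set1`, `set2`).
#' @export
pool_and_split <- function(replicate_sets, seed) {
  stopifnot(length(replicate_sets) >= 1)
  pooled <- Reduce(c, replicate_sets)
  n <- length(pooled)
  idx <- with_seed(seed, sample.int(n))
  k <- ceiling(n / 2)
  list(set1 = sort(pooled[idx[seq_len(k)]]),
       set2 = sort(pooled[idx[setdiff(seq_len(n), seq_len(k))]]))
}

#' Simple threshold peak caller
#'
#' Plumbing stand-in for a model-based caller: enriched runs are positions
#' where coverage is at least `min_enrichment` times the genome-wide mean;
#' runs separated by less than `merge_gap` bp are merged (brief dips inside
#' a peak do not split it), and merged runs at least `min_width` bp wide
#' become peaks. The summit is the leftmost position of maximum coverage and
#' the score is the summit coverage.
#'
#' @param cov named `RleList` coverage.
#' @param min_enrichment fold enrichment over the genome-wide mean coverage.
#' @param min_width minimum peak width in bp.
#' @param merge_gap maximum gap between enriched runs that is bridged.
#' @return `GRanges` with `summit` (absolute position) and `score` columns.
#' @export
call_peaks_simple <- function(cov, min_enrichment = 2, min_width = 100,
                              merge_gap = 100) {
  tot_len <- sum(as.numeric(lengths(cov)))
  if (tot_len == 0) return(GRanges(summit = integer(0), score = numeric(0)))
  gmean <- sum(vapply(cov, function(r) sum(as.numeric(r)), numeric(1))) / tot_len
  if (gmean == 0) {
    out <- GRanges(seqlengths = lengths(cov))
    mcols(out)$summit <- integer(0); mcols(out)$score <- numeric(0)
    return(out)
  }
  thr <- min_enrichment * gmean
  res <- list()
  for (chr in names(cov)) {
    runs <- methods::as(slice(cov[[chr]], lower = thr), "IRanges")
    runs <- IRanges::reduce(runs, min.gapwidth = merge_gap)
    runs <- runs[IRanges::width(runs) >= min_width]
    if (length(runs) == 0) next
    v <- Views(cov[[chr]], runs)
    summit <- vapply(seq_along(v), function(i) {
      x <- as.numeric(v[[i]])
      IRanges::start(runs)[i] + which.max(x) - 1L
    }, numeric(1))
    score <- vapply(seq_along(v), function(i) max(as.numeric(v[[i]])),
                    numeric(1))
    area <- vapply(seq_along(v), function(i) sum(as.numeric(v[[i]])),
                   numeric(1))
    res[[chr]] <- data.frame(chrom = chr, start = IRanges::start(runs),
                             end = IRanges::end(runs),
                             summit = as.integer(summit), score = score,
                             area = area)
  }
  si <- Seqinfo(names(cov), lengths(cov))
  if (length(res) == 0) {
    out <- GRanges(seqinfo = si)
    mcols(out)$summit <- integer(0); mcols(out)$score <- numeric(0)
    return(out)
  }
  df <- do.call(rbind, res)
  out <- GRanges(df$chrom, IRanges(df$start, df$end), seqinfo = si)
  mcols(out)$summit <- df$summit
  mcols(out)$score <- df$score
  mcols(out)$area <- df$area
  out
}

#' Reproducible peaks by reciprocal overlap
#'
#' A peak is retained iff a peak in the other set overlaps it by strictly
#' more than `min_overlap_frac` of its own width, reciprocally (both peaks of
#' a pair must satisfy the rule). With `reciprocal = FALSE` only the query
#' peak's own width is tested.
#'
#' @param peaks1,peaks2 `GRanges` with `summit` and `score` from the two
#'   split halves.
#' @param min_overlap_frac overlap fraction threshold (strict `>`).
#' @param reciprocal require the rule in both directions (default).
#' @param score_col metadata column used as the pair score for IDR;
#'   defaults to `"area"` (total coverage, whose rank is reproducible even
#'   when summit heights are uniform across peaks), falling back to
#'   `"score"` when absent.
#' @return list with `peaks1`, `peaks2` (retained peaks) and `pairs`, a
#'   data.frame of matched pairs (`idx1`, `idx2`, `score1`, `score2`), one
#'   best partner per retained peak of set 1.
#' @export
reproducible_peaks <- function(peaks1, peaks2, min_overlap_frac = 0.5,
                               reciprocal = TRUE, score_col = "area") {
  fo <- findOverlaps(peaks1, peaks2, ignore.strand = TRUE)
  q <- queryHits(fo); s <- subjectHits(fo)
  ovw <- GenomicRanges::width(pintersect(granges(peaks1)[q], granges(peaks2)[s]))
  ok1 <- ovw > min_overlap_frac * GenomicRanges::width(peaks1)[q]
  ok2 <- ovw > min_overlap_frac * GenomicRanges::width(peaks2)[s]
  ok <- if (reciprocal) ok1 & ok2 else ok1
  q <- q[ok]; s <- s[ok]; ovw <- ovw[ok]
  if (!score_col %in% names(mcols(peaks1))) score_col <- "score"
  pairs <- data.frame(idx1 = q, idx2 = s,
                      score1 = mcols(peaks1)[[score_col]][q],
                      score2 = mcols(peaks2)[[score_col]][s],
                      overlap = ovw)
  # one best partner per set-1 peak (largest overlap, then leftmost partner)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$idx1, -pairs$overlap, pairs$idx2), ]
    pairs <- pairs[!duplicated(pairs$idx1), ]
    rownames(pairs) <- NULL
  }
  list(peaks1 = peaks1[sort(unique(q))],
       peaks2 = peaks2[sort(unique(s))],
       pairs = pairs)
}

#' Rescale peaks to a fixed window around their summits
#'
#' @param peaks `GRanges` with a `summit` column.
#' @param flank bp added on each side of the summit (width `2 * flank + 1`).
#' @param seqlengths named chromosome lengths used for clipping.
#' @return `GRanges` of rescaled peaks with a `clipped` flag.
#' @export
rescale_peaks <- function(peaks, flank = 100, seqlengths = NULL) {
  if (length(peaks) == 0) return(peaks)
  summit <- mcols(peaks)$summit
  if (is.null(summit)) stop_("peaks must carry a summit column")
  sl <- seqlengths %||% seqlengths(peaks)
  len <- sl[as.character(seqnames(peaks))]
  if (any(is.na(len))) stop_("seqlengths required for every peak chromosome")
  if (any(summit < 1 | summit > len)) stop_("summit outside its chromosome")
  start <- pmax(1L, summit - as.integer(flank))
  end <- pmin(as.integer(len), summit + as.integer(flank))
  out <- GRanges(seqnames(peaks), IRanges(start, end))
  seqlengths(out) <- sl[seqlevels(out)]
  mcols(out) <- mcols(peaks)
  mcols(out)$clipped <- start != summit - as.integer(flank) |
    end != summit + as.integer(flank)
  out
}

#' Merge peak sets into a universal peak set
#'
#' Union of all intervals; overlapping or adjacent intervals are merged and
#' each merged peak keeps the list of contributing set labels.
#'
#' @param peak_sets named list of `GRanges`.
#' @return `GRanges` with a `sources` CharacterList column.
#' @export
merge_universal <- function(peak_sets) {
  stopifnot(is.list(peak_sets), !is.null(names(peak_sets)))
  nonempty <- peak_sets[vapply(peak_sets, length, integer(1)) > 0]
  if (length(nonempty) == 0) return(GRanges(sources = IRanges::CharacterList()))
  all <- Reduce(c, lapply(nonempty, granges))
  merged <- reduce(all, min.gapwidth = 1L)
  src <- vector("list", length(merged))
  for (nm in names(nonempty)) {
    hit <- unique(queryHits(findOverlaps(merged, nonempty[[nm]])))
    for (i in hit) src[[i]] <- c(src[[i]], nm)
  }
  mcols(merged)$sources <- IRanges::CharacterList(src)
  merged
}

#' Background-noise model from random genomic windows
#'
#' Draws `n_windows` uniform-random windows, takes the median coverage in
#' each, and summarizes the noise level as the median of those medians.
#' Deterministic under `seed`.
#'
#' @param cov named `RleList` coverage.
#' @param n_windows number of windows (>= 100).
#' @param window_size window width in bp.
#' @param seed integer seed.
#' @return list (`BackgroundModel`): `noise_level`, `window_medians`,
#'   `n_windows`, `window_size`, `seed`.
#' @export
background_noise <- function(cov, n_windows = 10000, window_size = 1000, seed = 1) {
  if (n_windows < 100) stop_("n_windows must be >= 100")
  lens <- lengths(cov)
  if (any(lens < window_size)) {
    stop_("window_size %d exceeds the smallest chromosome (%d bp)",
          window_size, min(lens))
  }
  draws <- with_seed(seed, {
    chr <- sample(names(cov), n_windows, replace = TRUE,
                  prob = as.numeric(lens) / sum(as.numeric(lens)))
    off <- vapply(chr, function(c) sample.int(lens[[c]] - window_size + 1L, 1L),
                  integer(1))
    data.frame(chr = chr, start = off)
  })
  med <- numeric(n_windows)
  for (chr in unique(draws$chr)) {
    i <- which(draws$chr == chr)
    dec <- as.numeric(cov[[chr]])
    med[i] <- vapply(draws$start[i], function(s)
      median(dec[s:(s + window_size - 1)]), numeric(1))
  }
  list(noise_level = median(med), window_medians = med,
       n_windows = n_windows, window_size = window_size, seed = seed)
}

#' Call peaks open or closed against a background model
#'
#' A peak is open iff its median coverage strictly exceeds the background
#' noise level.
#'
#' @param peaks `GRanges`.
#' @param cov named `RleList` coverage of the same condition.
#' @param background model from [background_noise()].
#' @return `peaks` with logical `is_open` (NA where no coverage track
#'   exists for the peak's chromosome).
#' @export
call_open <- function(peaks, cov, background) {
  is_open <- rep(NA, length(peaks))
  chrs <- as.character(seqnames(peaks))
  missing <- !chrs %in% names(cov)
  if (any(missing)) warn_("%d peaks on chromosomes without coverage", sum(missing))
  for (chr in unique(chrs[!missing])) {
    i <- which(chrs == chr)
    dec <- as.numeric(cov[[chr]])
    st <- GenomicRanges::start(peaks)[i]; en <- GenomicRanges::end(peaks)[i]
    med <- vapply(seq_along(i), function(k) median(dec[st[k]:en[k]]), numeric(1))
    is_open[i] <- med > background$noise_level
  }
  mcols(peaks)$is_open <- is_open
  peaks
}

#' Assign peaks to genomic classes
#'
#' `gene_body` if the peak overlaps a gene span (precedence), else
#' `promoter` if it overlaps the strand-aware window `promoter_bp` upstream
#' of a TSS, else `distal`.
#'
#' @param peaks `GRanges`.
#' @param genes stranded `GRanges` with `gene_id`.
#' @param promoter_bp promoter window size upstream of the TSS.
#' @return data.frame with `peak_idx`, `class`, `gene_id` (nearest assigned
#'   gene for gene_body/promoter, `NA` for distal).
#' @export
assign_peaks_to_genes <- function(peaks, genes, promoter_bp = 1000) {
  class <- rep("distal", length(peaks))
  gene_id <- rep(NA_character_, length(peaks))
  fo <- findOverlaps(peaks, genes, ignore.strand = TRUE)
  class[queryHits(fo)] <- "gene_body"
  gene_id[queryHits(fo)] <- mcols(genes)$gene_id[subjectHits(fo)]
  prom <- suppressWarnings(promoters(genes, upstream = promoter_bp, downstream = 0))
  prom <- GenomicRanges::trim(prom)
  fp <- findOverlaps(peaks, prom, ignore.strand = TRUE)
  sel <- class[queryHits(fp)] == "distal"
  class[queryHits(fp)[sel]] <- "promoter"
  gene_id[queryHits(fp)[sel]] <- mcols(genes)$gene_id[subjectHits(fp)[sel]]
  data.frame(peak_idx = seq_along(peaks), class = class, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' Condition-specificity classes of TE-peak overlap
#'
#' A TE overlaps a peak if the intervals intersect by at least one bp; the
#' class records in which conditions the TE sits under an open peak.
#'
#' @param tes `GRanges` with `te_id`.
#' @param open_peaks_control,open_peaks_stress `GRanges` of peaks called
#'   open in each condition.
#' @return data.frame with `te_id` and `class` in
#'   `both`/`control_only`/`stress_only`/`none`.
#' @export
te_peak_overlap <- function(tes, open_peaks_control, open_peaks_stress) {
  inc <- IRanges::overlapsAny(tes, open_peaks_control, ignore.strand = TRUE)
  ins <- IRanges::overlapsAny(tes, open_peaks_stress, ignore.strand = TRUE)
  class <- ifelse(inc & ins, "both",
           ifelse(inc, "control_only", ifelse(ins, "stress_only", "none")))
  data.frame(te_id = mcols(tes)$te_id, class = class, stringsAsFactors = FALSE)
}

#' Quantile scaling of per-gene accessibility values
#'
#' Values are binned into `n_quantiles` equal-count bins by rank; the linear
#' transform maps the median of the first bin to 0 and the median of the
#' last bin to 1.
#'
#' @param x numeric values (length >= `n_quantiles`).
#' @param n_quantiles number of bins.
#' @return numeric vector of scaled values (same order as `x`).
#' @export
quantile_scaled_profile <- function(x, n_quantiles = 20) {
  n <- length(x)
  if (n < n_quantiles) stop_("need at least %d values", n_quantiles)
  ord <- order(x)
  bin_sorted <- ceiling(seq_len(n) * n_quantiles / n)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  m1 <- median(x[bin == 1])
  mk <- median(x[bin == n_quantiles])
  if (mk == m1) stop_("degenerate input: first and last quantile medians equal")
  (x - m1) / (mk - m1)
}

#' Run the full ATAC post-processing chain for one coverage condition
#'
#' fragments -> insert-size filter -> pooled random split -> peak calls on
#' each half -> reciprocal-overlap reproducibility -> IDR filter -> summit
#' rescale. Peaks from the first half represent each reproducible pair.
#'
#' @param replicate_sets list of fragment `GRanges` (one per replicate).
#' @param seqlengths named chromosome lengths.
#' @param seed integer seed for the random split.
#' @param max_insert insert-size cutoff (bp, inclusive).
#' @param min_enrichment,min_width peak-caller parameters.
#' @param min_overlap_frac reciprocal-overlap threshold.
#' @param idr_threshold IDR cutoff (strict `<`).
#' @param flank summit flank for rescaling.
#' @param skip_idr skip the IDR filter (used when too few pairs exist).
#' @return list with `peaks` (rescaled reproducible peaks), `coverage`
#'   (pooled filtered-fragment coverage), `idr_fit`, and stage counts.
#' @export
atac_chain <- function(replicate_sets, seqlengths, seed,
                       max_insert = 100, min_enrichment = 4, min_width = 100,
                       min_overlap_frac = 0.5, idr_threshold = 0.05,
                       flank = 100, skip_idr = FALSE) {
  filtered <- lapply(replicate_sets, filter_fragments, max_insert = max_insert)
  halves <- pool_and_split(filtered, seed = seed)
  cov1 <- coverage_from_fragments(halves$set1, seqlengths)
  cov2 <- coverage_from_fragments(halves$set2, seqlengths)
  p1 <- call_peaks_simple(cov1, min_enrichment, min_width)
  p2 <- call_peaks_simple(cov2, min_enrichment, min_width)
  rep_ <- reproducible_peaks(p1, p2, min_overlap_frac)
  keep <- rep_$pairs
  idr_fit <- NULL
  if (!skip_idr && nrow(keep) >= 20) {
    idr_res <- idr_filter(keep, threshold = idr_threshold)
    keep <- idr_res$pairs[idr_res$pairs$keep, , drop = FALSE]
    idr_fit <- idr_res$fit
  }
  peaks <- p1[keep$idx1]
  pooled_cov <- coverage_from_fragments(Reduce(c, filtered), seqlengths)
  peaks <- rescale_peaks(peaks, flank = flank, seqlengths = seqlengths)
  list(peaks = peaks, coverage = pooled_cov, idr_fit = idr_fit,
       n_peaks_half1 = length(p1), n_peaks_half2 = length(p2),
       n_reproducible = nrow(rep_$pairs), n_after_idr = nrow(keep))
}
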