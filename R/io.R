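# File-format boundary. Internally everything is a GRanges (1-based,
# inclusive, the IRanges convention); 0-based half-open formats (tagAlign/BED,
# bedGraph, narrowPeak) are converted here and only here. GFF3 is 1-based
# inclusive and read through rtracklayer.

#' Write a feature set as GFF3
#'
#' @param gr `GRanges` with an id column (`gene_id` or `te_id`).
#' @param path output path.
#' @param type GFF3 feature type (e.g. `"gene"`, `"transposable_element"`).
#' @param source value for the source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gr, path, type = "gene", source = "xenoTE") {
  id_col <- intersect(c("gene_id", "te_id", "id"), names(mcols(gr)))[1]
  ids <- if (!is.na(id_col)) mcols(gr)[[id_col]] else paste0("feat", seq_along(gr))
  lines <- "##gff-version 3"
  if (length(gr)) {
    lines <- c(lines, sprintf(
      "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      as.character(seqnames(gr)), source, type,
      GenomicRanges::start(gr), GenomicRanges::end(gr),
      as.character(GenomicRanges::strand(gr)), ids, ids))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 feature file
#'
#' @param path GFF3 file.
#' @param id_col name to give the identifier column (from the ID attribute).
#' @return `GRanges` with the id in `mcols`.
#' @export
read_gff3 <- function(path, id_col = "gene_id") {
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- mcols(gr)$ID
  mcols(gr) <- NULL
  mcols(gr)[[id_col]] <- as.character(ids)
  gr
}

#' Write aligned fragments in tagAlign (6-column BED) format
#'
#' @param frags `GRanges` of fragments.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tagalign <- function(frags, path) {
  if (length(frags) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\tN\t1000\t.",
                   as.character(seqnames(frags)),
                   GenomicRanges::start(frags) - 1L,
                   GenomicRanges::end(frags))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tagAlign fragment file
#'
#' @param path tagAlign file (0-based half-open coordinates).
#' @param seqlengths optional named chromosome lengths.
#' @return `GRanges` of fragments; width equals the insert size.
#' @export
read_tagalign <- function(path, seqlengths = NULL) {
  if (file.size(path) == 0) {
    return(GRanges(seqlengths = seqlengths))
  }
  df <- tryCatch(
    read.table(path, sep = "\t", stringsAsFactors = FALSE,
               col.names = c("chrom", "start", "end", "name", "score", "strand")),
    error = function(e) stop_("malformed tagAlign record in %s: %s", path, conditionMessage(e)))
  if (any(df$end <= df$start)) {
    stop_("malformed tagAlign record at line %d of %s: end <= start",
          which(df$end <= df$start)[1], path)
  }
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  if (!is.null(seqlengths)) seqlengths(gr) <- seqlengths[seqlevels(gr)]
  gr
}

#' Write per-base coverage as bedGraph
#'
#' All runs are written, including zero runs, so that the track round-trips
#' exactly.
#'
#' @param cov named `RleList` of coverage (one element per chromosome).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path) {
  out <- character(0)
  for (chr in names(cov)) {
    r <- cov[[chr]]
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r)  # 0-based
    vals <- runValue(r)
    out <- c(out, sprintf("%s\t%d\t%d\t%s", chr, starts, ends,
                          format(vals, scientific = FALSE, trim = TRUE)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file.
#' @param seqlengths named chromosome lengths (needed to pad trailing zeros).
#' @return named `RleList` of numeric coverage.
#' @export
read_bedgraph <- function(path, seqlengths) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "value"))
  out <- lapply(names(seqlengths), function(chr) {
    sub <- df[df$chrom == chr, , drop = FALSE]
    r <- Rle(0, seqlengths[[chr]])
    if (nrow(sub)) {
      sub <- sub[order(sub$start), ]
      v <- rep(0, seqlengths[[chr]])
      for (i in seq_len(nrow(sub))) {
        v[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
      }
      r <- Rle(v)
    }
    r
  })
  names(out) <- names(seqlengths)
  methods::as(out, "SimpleRleList")
}

#' Write peaks in narrowPeak format
#'
#' @param peaks `GRanges` with `summit` (absolute 1-based position) and
#'   `score` metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  if (length(peaks) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\tpeak_%d\t%d\t.\t%s\t-1\t-1\t%d",
                   as.character(seqnames(peaks)),
                   GenomicRanges::start(peaks) - 1L,
                   GenomicRanges::end(peaks),
                   seq_along(peaks),
                   pmin(1000L, as.integer(round(mcols(peaks)$score))),
                   format(mcols(peaks)$score, scientific = FALSE, trim = TRUE),
                   as.integer(mcols(peaks)$summit - GenomicRanges::start(peaks)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a narrowPeak file
#'
#' Column 7 (signalValue) becomes `score` and column 10 (summit offset from
#' the 0-based start) is converted to an absolute 1-based `summit`.
#'
#' @param path narrowPeak file.
#' @return `GRanges` with `summit` and `score` columns.
#' @export
read_narrowpeak <- function(path) {
  if (file.size(path) == 0) return(GRanges(summit = integer(0), score = numeric(0)))
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
  mcols(gr)$score <- df[[7]]
  mcols(gr)$summit <- df[[2]] + df[[10]] + 1L
  gr
}

#' Write a counts matrix as TSV
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param path output path.
#' @param id_name header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path, id_name = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts matrix from TSV
#'
#' @param path TSV with the feature id in the first column.
#' @return integer matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

# plain write.table wrapper with fixed, deterministic settings
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute per-base coverage from fragments
#'
#' @param frags `GRanges` of fragments with seqlengths set.
#' @param seqlengths optional named chromosome lengths to impose.
#' @return named `RleList` of coverage.
#' @export
coverage_from_fragments <- function(frags, seqlengths = NULL) {
  if (!is.null(seqlengths)) {
    frags <- GRanges(seqnames(frags), IRanges::ranges(frags),
                     seqinfo = Seqinfo(names(seqlengths), seqlengths))
  }
  GenomicRanges::coverage(frags)
}
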