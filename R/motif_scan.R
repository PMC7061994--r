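# Position-weight-matrix scanning for cnc (CncC/Nrf2-class) binding sites.
#
# The motif model is a log-odds matrix over A/C/G/T versus a background
# composition, with a hit threshold expressed as an absolute score. The
# default model is an ARE-like consensus (TGACnnnGC), the motif class the
# cnc/Nrf2 factor binds; any JASPAR-style PFM can be supplied instead.

BASES <- c("A", "C", "G", "T")

#' Build a motif model from base probabilities
#'
#' @param prob 4 x L probability matrix with rownames A, C, G, T.
#' @param name motif name.
#' @param background base frequencies (must sum to 1).
#' @param threshold_frac hit threshold as a fraction of the maximum
#'   achievable log-odds score.
#' @return list (`MotifModel`): `name`, `matrix` (log2-odds), `threshold`,
#'   `background`, `length`.
#' @export
motif_model <- function(prob, name = "motif", background = rep(0.25, 4),
                        threshold_frac = 0.8) {
  stopifnot(nrow(prob) == 4, abs(sum(background) - 1) < 1e-6)
  rownames(prob) <- BASES
  names(background) <- BASES
  lo <- log2(prob / background)
  if (any(!is.finite(lo))) stop_("zero probabilities: add pseudocounts first")
  max_score <- sum(apply(lo, 2, max))
  thr <- threshold_frac * max_score
  list(name = name, matrix = lo, threshold = thr, background = background,
       length = ncol(prob), max_score = max_score)
}

#' Default cnc-binding-site motif
#'
#' ARE-like consensus TGACnnnGC compiled to log-odds against a uniform
#' background; consensus bases get probability 0.91 (0.03 elsewhere), the
#' spacer positions are uniform.
#'
#' @param threshold_frac hit threshold as a fraction of the maximum score.
#' @return a `MotifModel` list.
#' @export
default_cnc_motif <- function(threshold_frac = 0.8) {
  consensus <- strsplit("TGACNNNGC", "")[[1]]
  prob <- vapply(consensus, function(b) {
    if (b == "N") rep(0.25, 4)
    else ifelse(BASES == b, 0.91, 0.03)
  }, numeric(4))
  rownames(prob) <- BASES
  motif_model(prob, name = "cnc_ARE", threshold_frac = threshold_frac)
}

#' Read a JASPAR-style PFM
#'
#' Accepts the `>name` header followed by four lines of counts, with or
#' without the `A [ ... ]` bracket syntax.
#'
#' @param path PFM text file.
#' @param pseudocount added to every count before normalization.
#' @param threshold_frac hit threshold as a fraction of the maximum score.
#' @param background base frequencies.
#' @return a `MotifModel` list.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.5, threshold_frac = 0.8,
                            background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "pfm"
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4) stop_("PFM must have four base rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("\\[|\\]", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1) stop_("ragged PFM rows")
  counts <- do.call(rbind, rows)
  rownames(counts) <- BASES
  prob <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  motif_model(prob, name = name, background = background,
              threshold_frac = threshold_frac)
}

encode_seq <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  m <- match(chars, BASES)  # N and anything else -> NA
  m
}

scan_one_strand <- function(code, lo, threshold) {
  L <- ncol(lo)
  n <- length(code)
  if (n < L) return(data.frame(offset = integer(0), score = numeric(0)))
  np <- n - L + 1
  score <- rep(0, np)
  for (j in seq_len(L)) {
    idx <- code[j:(j + np - 1)]
    col <- lo[, j]
    contrib <- col[idx]
    contrib[is.na(idx)] <- -Inf   # N positions can never support a hit
    score <- score + contrib
  }
  hit <- which(score >= threshold)
  data.frame(offset = hit, score = score[hit])
}

#' Scan a sequence for motif hits on both strands
#'
#' Reverse-strand hits are scored on the reverse complement and reported at
#' their start position on the forward sequence. Positions containing N can
#' never reach the threshold.
#'
#' @param sequence character string or `DNAString` over A/C/G/T/N.
#' @param motif a `MotifModel`.
#' @return data.frame with `offset` (1-based forward start), `strand`,
#'   `score`, sorted by offset.
#' @export
scan_sequence <- function(sequence, motif) {
  seq_chr <- toupper(as.character(sequence))
  n <- nchar(seq_chr)
  L <- motif$length
  fwd <- scan_one_strand(encode_seq(seq_chr), motif$matrix, motif$threshold)
  rc <- as.character(reverseComplement(DNAString(seq_chr)))
  rev <- scan_one_strand(encode_seq(rc), motif$matrix, motif$threshold)
  hits <- rbind(
    if (nrow(fwd)) data.frame(offset = fwd$offset, strand = "+", score = fwd$score),
    if (nrow(rev)) data.frame(offset = n - (rev$offset + L - 1) + 1L,
                              strand = "-", score = rev$score))
  if (is.null(hits)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

#' Count motif hits per feature
#'
#' All hits are counted, including overlapping ones.
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @param motif a `MotifModel`.
#' @return named integer vector of hit counts.
#' @export
count_bs_per_feature <- function(sequences, motif) {
  seqs <- as.character(sequences)
  vapply(seqs, function(s) nrow(scan_sequence(s, motif)), integer(1),
         USE.NAMES = TRUE)
}

#' Fraction of peaks containing a motif hit
#'
#' @param peaks `GRanges` of peaks.
#' @param genome named `DNAStringSet` (one sequence per chromosome).
#' @param motif a `MotifModel`.
#' @return fraction of peaks with at least one hit.
#' @export
peaks_with_motif_fraction <- function(peaks, genome, motif) {
  if (length(peaks) == 0) return(NA_real_)
  has <- vapply(seq_along(peaks), function(i) {
    chr <- as.character(seqnames(peaks))[i]
    s <- subseq(genome[[chr]], GenomicRanges::start(peaks)[i],
                GenomicRanges::end(peaks)[i])
    nrow(scan_sequence(s, motif)) > 0
  }, logical(1))
  mean(has)
}
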