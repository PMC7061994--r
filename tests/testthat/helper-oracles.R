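# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles are deliberately naive (quadratic scans, exhaustive
# subset enumeration) and never call the code paths they check.

suppressMessages(library(GenomicRanges))

# explicit bindings: test environments do not always see search-path
# attachments from inside helper-defined closures
GRanges    <- GenomicRanges::GRanges
IRanges    <- IRanges::IRanges
granges    <- GenomicRanges::granges
start      <- GenomicRanges::start
end        <- GenomicRanges::end
width      <- GenomicRanges::width
strand     <- GenomicRanges::strand
seqnames   <- GenomicRanges::seqnames
mcols      <- S4Vectors::mcols
`mcols<-`  <- S4Vectors::`mcols<-`
seqlengths <- GenomeInfoDb::seqlengths
`seqlengths<-` <- GenomeInfoDb::`seqlengths<-`

mk_gr <- function(chrom, start, end, strand = "*", ...) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  extra <- list(...)
  for (nm in names(extra)) mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

mk_meta <- function(strains, n_rep = 3) {
  meta <- expand.grid(replicate = seq_len(n_rep),
                      treatment = c("control", "stress"),
                      strain = strains, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_%d", meta$strain, meta$treatment,
                            meta$replicate)
  meta
}

# NB counts for a design, with planted per-strain signed lfc (genes x strains)
mk_counts <- function(mu, meta, lfc_mat = NULL, dispersion = 0.05,
                      lib = rep(1, nrow(meta))) {
  n <- length(mu)
  cts <- matrix(0L, n, nrow(meta))
  for (j in seq_len(nrow(meta))) {
    m <- mu
    if (!is.null(lfc_mat) && meta$treatment[j] == "stress") {
      m <- m * 2^lfc_mat[, meta$strain[j]]
    }
    cts[, j] <- rnbinom(n, mu = m * lib[j], size = 1 / dispersion)
  }
  rownames(cts) <- sprintf("g%04d", seq_len(n))
  colnames(cts) <- meta$sample_id
  cts
}

# ---- MCC oracle: exhaustive subset enumeration with bitmasks ----

random_adj <- function(n, p) {
  a <- matrix(FALSE, n, n)
  a[upper.tri(a)] <- runif(n * (n - 1) / 2) < p
  a | t(a)
}

mcc_oracle <- function(adj) {
  n <- nrow(adj)
  bit <- bitwShiftL(1L, 0:(n - 1))
  nbr <- vapply(seq_len(n), function(v) sum(bit[which(adj[v, ])]), numeric(1))
  scores <- numeric(n)
  for (S in seq_len(2^n - 1)) {
    memb <- which(bitwAnd(S, bit) != 0)
    if (length(memb) < 2) next
    ok <- TRUE
    for (v in memb) {
      others <- S - bit[v]
      if (bitwAnd(nbr[v], others) != others) { ok <- FALSE; break }
    }
    if (!ok) next
    # maximality: no outside vertex adjacent to every member
    maximal <- TRUE
    for (u in setdiff(seq_len(n), memb)) {
      if (bitwAnd(nbr[u], S) == S) { maximal <- FALSE; break }
    }
    if (!maximal) next
    scores[memb] <- scores[memb] + factorial(length(memb) - 1)
  }
  scores
}

adj_to_edges <- function(adj) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  data.frame(gene_a = paste0("n", idx[, 1]), gene_b = paste0("n", idx[, 2]),
             combined_score = 1, stringsAsFactors = FALSE)
}

# ---- interval oracles: quadratic scans ----

links_oracle <- function(tes, genes, max_dist = 1000) {
  out <- list()
  for (i in seq_along(tes)) {
    for (j in seq_along(genes)) {
      if (as.character(seqnames(tes))[i] != as.character(seqnames(genes))[j]) next
      ts <- start(tes)[i]; te <- end(tes)[i]
      gs <- start(genes)[j]; ge <- end(genes)[j]
      if (ts <= ge && te >= gs) {
        out[[length(out) + 1]] <- data.frame(
          te_id = tes$te_id[i], gene_id = genes$gene_id[j],
          relation = "inside_gene", distance = 0L)
        next
      }
      gap <- if (te < gs) gs - te - 1L else ts - ge - 1L
      if (gap >= max_dist) next
      left <- te < gs
      plus <- as.character(strand(genes))[j] == "+"
      rel <- if (left == plus) "five_prime" else "three_prime"
      out[[length(out) + 1]] <- data.frame(
        te_id = tes$te_id[i], gene_id = genes$gene_id[j],
        relation = rel, distance = gap)
    }
  }
  if (length(out) == 0) {
    return(data.frame(te_id = character(0), gene_id = character(0),
                      relation = character(0), distance = integer(0)))
  }
  do.call(rbind, out)
}

reciprocal_oracle <- function(p1, p2, frac = 0.5) {
  keep1 <- logical(length(p1)); keep2 <- logical(length(p2))
  for (i in seq_along(p1)) {
    for (j in seq_along(p2)) {
      if (as.character(seqnames(p1))[i] != as.character(seqnames(p2))[j]) next
      ov <- min(end(p1)[i], end(p2)[j]) - max(start(p1)[i], start(p2)[j]) + 1
      if (ov <= 0) next
      if (ov > frac * width(p1)[i] && ov > frac * width(p2)[j]) {
        keep1[i] <- TRUE; keep2[j] <- TRUE
      }
    }
  }
  list(keep1 = keep1, keep2 = keep2)
}

merge_oracle <- function(gr_list) {
  df <- do.call(rbind, lapply(gr_list, function(g)
    data.frame(chrom = as.character(seqnames(g)), start = start(g),
               end = end(g))))
  out <- list()
  for (chr in sort(unique(df$chrom))) {
    sub <- df[df$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cs <- sub$start[1]; ce <- sub$end[1]
    for (k in seq_len(nrow(sub))[-1]) {
      if (sub$start[k] <= ce + 1) ce <- max(ce, sub$end[k])
      else { out[[length(out) + 1]] <- c(chr, cs, ce); cs <- sub$start[k]; ce <- sub$end[k] }
    }
    out[[length(out) + 1]] <- c(chr, cs, ce)
  }
  m <- do.call(rbind, out)
  data.frame(chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]))
}

assign_oracle <- function(peaks, genes, promoter_bp = 1000) {
  cls <- character(length(peaks))
  for (i in seq_along(peaks)) {
    cls[i] <- "distal"
    ps <- start(peaks)[i]; pe <- end(peaks)[i]
    chr <- as.character(seqnames(peaks))[i]
    for (j in seq_along(genes)) {
      if (chr != as.character(seqnames(genes))[j]) next
      if (ps <= end(genes)[j] && pe >= start(genes)[j]) { cls[i] <- "gene_body"; break }
    }
    if (cls[i] == "gene_body") next
    for (j in seq_along(genes)) {
      if (chr != as.character(seqnames(genes))[j]) next
      if (as.character(strand(genes))[j] == "+") {
        prs <- start(genes)[j] - promoter_bp; pre <- start(genes)[j] - 1
      } else {
        prs <- end(genes)[j] + 1; pre <- end(genes)[j] + promoter_bp
      }
      if (prs <= pre && ps <= pre && pe >= prs) { cls[i] <- "promoter"; break }
    }
  }
  cls
}

# naive per-position PWM rescoring (forward strand only)
scan_oracle_fwd <- function(seq_chr, lo, threshold) {
  chars <- strsplit(toupper(seq_chr), "")[[1]]
  L <- ncol(lo); n <- length(chars)
  hits <- integer(0); scores <- numeric(0)
  if (n >= L) {
    for (o in 1:(n - L + 1)) {
      sc <- 0
      for (j in 1:L) {
        b <- chars[o + j - 1]
        sc <- sc + if (b %in% rownames(lo)) lo[b, j] else -Inf
      }
      if (sc >= threshold) { hits <- c(hits, o); scores <- c(scores, sc) }
    }
  }
  data.frame(offset = hits, score = scores)
}

# bivariate copula mixture sampler for IDR recovery tests
mk_idr_mixture <- function(n, pi0, rho, mu = 2, sg = 1) {
  rep_ <- runif(n) < pi0
  z <- matrix(rnorm(2 * n), n)
  z[rep_, 2] <- rho * z[rep_, 1] + sqrt(1 - rho^2) * z[rep_, 2]
  z[rep_, ] <- mu + sg * z[rep_, ]
  list(score1 = z[, 1], score2 = z[, 2], reproducible = rep_)
}
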