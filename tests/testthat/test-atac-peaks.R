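test_that("fragment filter keeps the 100 bp boundary inclusively", {
  fr <- mk_gr("chr1", c(1, 1, 1), c(100, 101, 50))   # widths 100, 101, 50
  kept <- filter_fragments(fr, 100)
  expect_equal(width(kept), c(100, 50))
  expect_length(filter_fragments(GRanges()), 0)
  # synthetic mixture retains roughly the sub-100 fraction
  set.seed(1)
  w <- ifelse(runif(5000) < 0.6, round(rlnorm(5000, log(60), 0.25)),
              round(rlnorm(5000, log(200), 0.2)))
  fr2 <- mk_gr("chr1", 1:5000, 1:5000 + pmax(w, 20) - 1)
  f_true <- mean(pmax(w, 20) <= 100)
  expect_equal(length(filter_fragments(fr2)) / 5000, f_true, tolerance = 1e-12)
})

test_that("pool-and-split halves the pool evenly and is seed-deterministic", {
  fr <- lapply(1:3, function(i) mk_gr("chr1", (1:10) + i * 100, (1:10) + i * 100 + 49))
  sp <- pool_and_split(fr, seed = 5)
  expect_equal(length(sp$set1) + length(sp$set2), 30)
  expect_equal(abs(length(sp$set1) - length(sp$set2)), 0)
  odd <- pool_and_split(fr[1:2], seed = 5)                     # 20 -> 10/10
  sp11 <- pool_and_split(list(mk_gr("chr1", 1:11, 21:31)), seed = 2)
  expect_lte(abs(length(sp11$set1) - length(sp11$set2)), 1)
  sp2 <- pool_and_split(fr, seed = 5)
  expect_identical(as.data.frame(sp$set1), as.data.frame(sp2$set1))
  sp3 <- pool_and_split(fr, seed = 6)
  expect_false(identical(as.data.frame(sp$set1), as.data.frame(sp3$set1)))
})

test_that("the threshold caller finds rectangular peaks with leftmost summits", {
  sl <- c(chr1 = 10000)
  # flat coverage: no peaks
  flat <- coverage_from_fragments(mk_gr("chr1", seq(1, 9951, 50), seq(50, 10000, 50)), sl)
  expect_length(call_peaks_simple(flat), 0)
  # one 20x rectangle of 300 bp on 1x background
  bg <- mk_gr("chr1", seq(1, 9901, 10), seq(100, 10000, 10))
  pk <- mk_gr("chr1", rep(5001, 60), rep(5300, 60))
  cov <- coverage_from_fragments(c(bg, pk), sl)
  res <- call_peaks_simple(cov, min_enrichment = 2, min_width = 100)
  expect_equal(length(res), 1)
  expect_gte(start(res), 4900); expect_lte(end(res), 5400)
  v <- as.numeric(cov[["chr1"]])
  expect_equal(mcols(res)$summit,
               which(v == max(v))[1])          # leftmost maximum
  expect_equal(mcols(res)$score, max(v))
})

test_that("reciprocal overlap retention matches the all-pairs oracle", {
  # exact 50 percent overlap is dropped (strict >)
  p1 <- mk_gr("chr1", 1000, 1199, summit = 1100, score = 10, area = 100)
  p2 <- mk_gr("chr1", 1100, 1299, summit = 1200, score = 10, area = 100)
  rp <- reproducible_peaks(p1, p2)
  expect_length(rp$peaks1, 0)
  # identical sets: all retained
  rp2 <- reproducible_peaks(p1, p1)
  expect_length(rp2$peaks1, 1)

  set.seed(33)
  for (rep in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    g1 <- mk_gr("c1", s <- sample(1:5000, n1), s + sample(50:400, n1, replace = TRUE),
                summit = s, score = runif(n1, 1, 50), area = runif(n1, 10, 500))
    g2 <- mk_gr("c1", s2 <- sample(1:5000, n2), s2 + sample(50:400, n2, replace = TRUE),
                summit = s2, score = runif(n2, 1, 50), area = runif(n2, 10, 500))
    got <- reproducible_peaks(g1, g2)
    want <- reciprocal_oracle(g1, g2)
    expect_equal(start(got$peaks1), start(g1)[want$keep1])
    expect_equal(start(got$peaks2), start(g2)[want$keep2])
  }
})

test_that("summit rescaling yields 201 bp windows, clipping flagged at edges", {
  sl <- c(chr1 = 6000)
  pk <- mk_gr("chr1", c(4800, 10), c(5200, 120), summit = c(5000, 50),
              score = c(9, 9))
  rs <- rescale_peaks(pk, flank = 100, seqlengths = sl)
  expect_equal(start(rs)[1], 4900); expect_equal(end(rs)[1], 5100)
  expect_equal(width(rs)[1], 201)
  expect_false(mcols(rs)$clipped[1])
  expect_equal(start(rs)[2], 1)                 # clipped at the left edge
  expect_true(mcols(rs)$clipped[2])
  bad <- mk_gr("chr1", 1, 10, summit = 7000, score = 1)
  expect_error(rescale_peaks(bad, seqlengths = sl), "outside")
  # property: width always 201 when unclipped
  set.seed(2)
  s <- sample(200:5800, 50)
  pks <- mk_gr("chr1", s - 10, s + 10, summit = s, score = 1)
  expect_true(all(width(rescale_peaks(pks, seqlengths = sl)) == 201))
})

test_that("universal peak merging equals a sort-and-sweep oracle and keeps provenance", {
  a <- mk_gr("c1", c(100, 500), c(200, 600))
  b <- mk_gr("c1", c(150, 900), c(260, 950))
  uni <- merge_universal(list(A = a, B = b))
  oracle <- merge_oracle(list(a, b))
  expect_equal(start(uni), oracle$start)
  expect_equal(end(uni), oracle$end)
  src <- as.list(mcols(uni)$sources)
  expect_setequal(src[[1]], c("A", "B"))        # merged 100-260 from both
  expect_equal(src[[2]], "A")
  expect_equal(src[[3]], "B")
  # identical sets collapse to one copy; disjoint sets concatenate
  expect_length(merge_universal(list(x = a, y = a)), 2)
  set.seed(4)
  for (rep in 1:40) {
    sets <- lapply(1:3, function(i)
      mk_gr("c1", st <- sample(1:3000, 6), st + sample(20:300, 6, replace = TRUE)))
    names(sets) <- c("s1", "s2", "s3")
    got <- merge_universal(sets)
    want <- merge_oracle(sets)
    expect_equal(start(got), want$start)
    expect_equal(end(got), want$end)
  }
})

test_that("background noise is the median of window medians and reproducible", {
  sl <- c(chr1 = 50000)
  st <- seq(1, 49976, 25)
  const <- coverage_from_fragments(mk_gr("chr1", st, st + 24), sl)
  # constant coverage c -> noise level c
  cval <- as.numeric(const[["chr1"]][1])
  bg <- background_noise(const, n_windows = 200, window_size = 500, seed = 1)
  expect_equal(bg$noise_level, cval)
  bg2 <- background_noise(const, n_windows = 200, window_size = 500, seed = 1)
  expect_identical(bg$window_medians, bg2$window_medians)
  expect_error(background_noise(const, n_windows = 50), ">= 100")
  expect_error(background_noise(const, window_size = 60000), "exceeds")
  # sparse 20x islands on 1x background leave the noise level at ~1
  bg_frag <- mk_gr("chr1", seq(1, 49941, 60), seq(1, 49941, 60) + 59)
  isl <- mk_gr("chr1", rep(c(10001, 30001), each = 100), rep(c(10250, 30250), each = 100))
  cov <- coverage_from_fragments(c(bg_frag, isl), sl)
  bg3 <- background_noise(cov, n_windows = 500, window_size = 500, seed = 3)
  expect_equal(bg3$noise_level, 1)
})

test_that("open calls use a strict inequality against the noise level", {
  sl <- c(chr1 = 20000)
  frag <- mk_gr("chr1", seq(1, 19951, 50), seq(50, 20000, 50))  # exactly 1x
  cov <- coverage_from_fragments(frag, sl)
  bg <- background_noise(cov, n_windows = 100, window_size = 200, seed = 1)
  pk <- mk_gr("chr1", 5001, 5400, summit = 5200, score = 1)
  oc <- call_open(pk, cov, bg)
  expect_false(mcols(oc)$is_open)               # median == noise -> closed
  # peak on a chromosome without coverage: NA with a warning
  pk2 <- mk_gr("chrX", 100, 300, summit = 200, score = 1)
  expect_warning(oc2 <- call_open(pk2, cov, bg), "without coverage")
  expect_true(is.na(mcols(oc2)$is_open))
})

test_that("peak-to-gene assignment matches a brute-force classifier", {
  genes <- mk_gr("c1", c(5000, 20000), c(8000, 22000), c("+", "-"),
                 gene_id = c("gP", "gM"))
  peaks <- mk_gr("c1", c(6000, 4200, 22500, 1000), c(6100, 4300, 22800, 1100))
  cls <- assign_peaks_to_genes(peaks, genes, promoter_bp = 1000)
  expect_equal(cls$class, c("gene_body", "promoter", "promoter", "distal"))
  expect_equal(cls$gene_id[1:3], c("gP", "gP", "gM"))
  set.seed(21)
  for (rep in 1:60) {
    g <- mk_gr("c1", st <- sample(2000:30000, 4), st + sample(500:3000, 4, replace = TRUE),
               sample(c("+", "-"), 4, replace = TRUE), gene_id = paste0("g", 1:4))
    p <- mk_gr("c1", ps <- sample(1:35000, 8), ps + sample(50:400, 8, replace = TRUE))
    expect_equal(assign_peaks_to_genes(p, g)$class, assign_oracle(p, g))
  }
})

test_that("TE-peak overlap classes follow the per-condition flags", {
  tes <- mk_gr("c1", c(100, 1000, 2000, 3000), c(200, 1100, 2100, 3100),
               te_id = paste0("t", 1:4))
  openc <- mk_gr("c1", c(150, 1050), c(160, 1060))
  opens <- mk_gr("c1", c(150, 2050), c(160, 2060))
  cls <- te_peak_overlap(tes, openc, opens)
  expect_equal(cls$class, c("both", "control_only", "stress_only", "none"))
})

test_that("quantile scaling anchors the first and last bin medians at 0 and 1", {
  x <- 1:100
  sc <- quantile_scaled_profile(x)
  expect_equal(sc[3], 0)                       # median of first 5 values is 3
  expect_equal(sc[98], 1)
  # affine invariance
  expect_equal(quantile_scaled_profile(5 * x + 7), sc)
  # matches the two-point-anchor oracle on random input
  set.seed(6)
  y <- rnorm(200)
  scy <- quantile_scaled_profile(y)
  ord <- order(y)
  m1 <- median(y[ord][1:10]); m20 <- median(y[ord][191:200])
  expect_equal(scy, (y - m1) / (m20 - m1))
  expect_error(quantile_scaled_profile(rep(2, 50)), "degenerate")
  expect_error(quantile_scaled_profile(1:10), "at least")
})

test_that("tagAlign, bedGraph and narrowPeak round-trip through files", {
  sl <- c(chr1 = 4000, chr2 = 3000)
  fr <- mk_gr(c("chr1", "chr2", "chr1"), c(10, 50, 300), c(80, 120, 360))
  seqlengths(fr) <- sl
  ta <- tempfile(fileext = ".tagAlign")
  write_tagalign(fr, ta)
  back <- read_tagalign(ta, sl)
  expect_equal(as.data.frame(granges(sort(back)))[, 1:3],
               as.data.frame(granges(sort(fr)))[, 1:3])
  write_tagalign(GRanges(), ta)
  expect_length(read_tagalign(ta), 0)

  cov <- coverage_from_fragments(fr, sl)
  bgf <- tempfile(fileext = ".bedGraph")
  write_bedgraph(cov, bgf)
  cov2 <- read_bedgraph(bgf, sl)
  expect_equal(as.numeric(cov2[["chr1"]]), as.numeric(cov[["chr1"]]))
  expect_equal(as.numeric(cov2[["chr2"]]), as.numeric(cov[["chr2"]]))

  pk <- mk_gr("chr1", c(100, 900), c(400, 1300), summit = c(250, 1000),
              score = c(12.5, 3))
  np <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, np)
  pk2 <- read_narrowpeak(np)
  expect_equal(start(pk2), start(pk))
  expect_equal(mcols(pk2)$summit, mcols(pk)$summit)
  expect_equal(mcols(pk2)$score, mcols(pk)$score)
})
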