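test_that("size factors follow the median-of-ratios definition", {
  # hand computation: every gene's ratio vector is (1/sqrt(2), sqrt(2))
  m <- matrix(c(10, 20, 100, 200, 4, 8), nrow = 3, byrow = TRUE)
  sf <- size_factors(m)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(sf), c(sqrt(1 / 2), sqrt(2)), tolerance = 1e-12)

  # identical samples
  m2 <- matrix(c(5, 5, 9, 9), nrow = 2, byrow = TRUE)
  expect_equal(unname(size_factors(m2)), c(1, 1))

  # doubling a sample doubles its factor
  a <- matrix(rpois(40, 50) + 1, ncol = 1)
  m3 <- cbind(a, 2 * a)
  sf3 <- size_factors(m3)
  expect_equal(sf3[2] / sf3[1], 2, ignore_attr = TRUE)
})

test_that("size factors error without a common expressed feature unless the fallback is requested", {
  m <- matrix(c(0, 5, 7, 0), nrow = 2)
  expect_error(size_factors(m), "fallback")
  sf <- size_factors(m, fallback = TRUE)
  expect_true(all(sf > 0))
  expect_true(attr(sf, "fallback"))
})

test_that("BH adjustment matches the step-up rule and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # order-invariant: permuting the input permutes the output identically
  set.seed(1)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # monotone in the raw p ordering, capped at 1, never below p
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_true(all(q <= 1))
  expect_true(all(q >= p))
})

test_that("nb_test recovers planted effects and stays calibrated on nulls", {
  set.seed(42)
  meta <- mk_meta(c("A", "B"))
  mu <- rlnorm(800, log(150), 1)
  lfc <- matrix(0, 800, 2, dimnames = list(NULL, c("A", "B")))
  lfc[1:80, "A"] <- 2 * sample(c(-1, 1), 80, replace = TRUE)
  cts <- mk_counts(mu, meta, lfc)
  res <- nb_test(cts, meta, "A")
  expect_equal(nrow(res), 800)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # planted genes found with the right sign
  found <- res$is_deg[1:80]
  expect_gt(mean(found), 0.85)
  expect_equal(sign(res$log2_fold_change[1:80][found]),
               sign(lfc[1:80, "A"][found]))
  # strain B is null: few calls
  resB <- nb_test(cts, meta, "B")
  expect_lt(sum(resB$is_deg), 8)
  # is_deg re-derivable from padj and lfc alone
  expect_equal(res$is_deg,
               res$padj <= 0.05 & abs(res$log2_fold_change) >= log2(1.5))
})

test_that("nb_test handles degenerate features and refuses single replicates", {
  meta <- mk_meta("A", n_rep = 3)
  cts <- matrix(50L, 3, 6, dimnames = list(paste0("g", 1:3), meta$sample_id))
  cts[2, ] <- 0L                       # all-zero feature
  res <- nb_test(cts, meta, "A")
  expect_equal(res$log2_fold_change[2], 0)
  expect_equal(res$p_value[2], 1)
  expect_true(res$flagged[2])
  # identical counts, unit factors: lfc exactly 0
  expect_equal(res$log2_fold_change[1], 0)
  expect_equal(res$p_value[1], 1)

  meta1 <- mk_meta("A", n_rep = 1)
  cts1 <- matrix(5L, 2, 2, dimnames = list(c("a", "b"), meta1$sample_id))
  expect_error(nb_test(cts1, meta1, "A"), "2 replicates")
})

test_that("p-values are approximately uniform under label permutation", {
  set.seed(7)
  meta <- mk_meta("A")
  mu <- rlnorm(600, log(120), 0.8)
  lfc <- matrix(2, 600, 1, dimnames = list(NULL, "A"))
  cts <- mk_counts(mu, meta, lfc)
  # permute treatment labels within the strain: effect becomes exchangeable
  ks <- replicate(3, {
    m2 <- meta
    m2$treatment <- sample(m2$treatment)
    while (length(unique(table(m2$treatment))) != 1) m2$treatment <- sample(m2$treatment)
    r <- nb_test(cts, m2, "A")
    suppressWarnings(ks.test(r$p_value, "punif")$p.value)
  })
  expect_gt(max(ks), 0.01)
})

test_that("per-strain design flag reproduces the strain-only fit", {
  set.seed(3)
  meta <- mk_meta(c("A", "B"))
  mu <- rlnorm(200, log(100), 0.5)
  cts <- mk_counts(mu, meta)
  full <- nb_test(cts, meta, "A", design = "per_strain")
  only <- nb_test(cts[, meta$strain == "A"], meta[meta$strain == "A", ], "A")
  expect_equal(full$p_value, only$p_value)
  expect_equal(full$log2_fold_change, only$log2_fold_change)
})

test_that("log fold changes agree with an established NB fitter", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  meta <- mk_meta("A")
  mu <- rlnorm(300, log(200), 1)
  lfc <- matrix(runif(300, -2, 2), 300, 1, dimnames = list(NULL, "A"))
  cts <- mk_counts(mu, meta, lfc)
  ours <- nb_test(cts, meta, "A")
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cts, data.frame(condition = factor(meta$treatment,
                                       c("control", "stress"))), ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  theirs <- DESeq2::results(dds)
  expect_gt(cor(ours$log2_fold_change, theirs$log2FoldChange,
                use = "complete.obs"), 0.98)
})

test_that("overlap table counts are symmetric and percentages follow the column rule", {
  sets <- list(a = c("g1", "g2", "g3"), b = c("g2", "g3", "g4", "g5"),
               c = character(0))
  ot <- overlap_table(sets)
  expect_equal(ot$counts["a", "b"], ot$counts["b", "a"])
  expect_equal(ot$counts["a", "b"], 2L)
  expect_equal(ot$pct["a", "b"], 50)       # 2 of the 4 in column b
  expect_equal(ot$pct["b", "a"], 66.7)     # 2 of the 3 in column a, half-up
  expect_true(is.na(ot$pct["a", "c"]))     # empty column set
  expect_equal(diag(ot$counts), c(a = 3L, b = 4L, c = 0L))
  # identical sets give 100 percent everywhere off-diagonal
  ot2 <- overlap_table(list(x = c("p", "q"), y = c("p", "q")))
  expect_equal(ot2$pct["x", "y"], 100)
  expect_equal(ot2$pct["y", "x"], 100)
})

test_that("direction concordance partitions shared DEGs", {
  mk_res <- function(ids, lfc) data.frame(
    feature_id = ids, log2_fold_change = lfc, is_deg = TRUE)
  a <- mk_res(sprintf("g%03d", 1:100), c(rep(1, 60), rep(-1, 40)))
  b <- mk_res(sprintf("g%03d", 1:100), c(rep(1, 60), rep(1, 40)))
  cc <- direction_concordance(a, b)
  expect_equal(cc, list(n_shared = 100, n_same_direction = 60, n_opposite = 40))
  # flipped copy
  b2 <- a; b2$log2_fold_change <- -b2$log2_fold_change
  cc2 <- direction_concordance(a, b2)
  expect_equal(cc2$n_opposite, 100)
  # disjoint
  c3 <- mk_res("zz", 1)
  expect_equal(direction_concordance(a, c3)$n_shared, 0)
})
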