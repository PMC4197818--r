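test_that("ease_fisher matches full hypergeometric enumeration", {
  cases <- list(c(10, 10, 10, 100), c(0, 5, 8, 40), c(3, 12, 9, 60),
                c(25, 30, 40, 80))
  for (cc in cases) {
    r <- ease_fisher(cc[1], cc[2], cc[3], cc[4])
    o <- enum_hyper(cc[1], cc[2], cc[3], cc[4])
    expect_equal(r$fisher_p_two_tailed, o$two_tailed, tolerance = 1e-12)
    expect_equal(r$one_tailed_p, o$upper(cc[1]), tolerance = 1e-12)
    expect_equal(r$ease_p, o$upper(max(cc[1] - 1, 0)), tolerance = 1e-12)
  }
  # EASE at k=1 is exactly 1
  expect_equal(ease_fisher(1, 10, 10, 100)$ease_p, 1)
  # EASE is conservative: >= the plain one-tailed enrichment p
  set.seed(51)
  pick <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)
  for (i in 1:50) {
    N <- sample(20:200, 1); n1 <- pick(1, N); n2 <- pick(1, N)
    k <- pick(max(0, n1 + n2 - N), min(n1, n2))
    r <- ease_fisher(k, n1, n2, N)
    expect_gte(r$ease_p, r$one_tailed_p)
  }
  # k=0 is always "under"
  expect_equal(ease_fisher(0, 5, 5, 50)$direction, "under")
  # expected-overlap tables sit near p = 1
  r <- ease_fisher(1, 10, 10, 100)   # expected = 1
  expect_gt(r$fisher_p_two_tailed, 0.5)
  expect_error(ease_fisher(11, 10, 10, 100), "inconsistent")
})

test_that("disabling the EASE decrement reduces to plain Fisher", {
  set.seed(52)
  pick <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)
  for (i in 1:50) {
    N <- sample(20:300, 1); n1 <- pick(1, N); n2 <- pick(1, N)
    k <- pick(max(0, n1 + n2 - N), min(n1, n2))
    r <- ease_fisher(k, n1, n2, N, ease = FALSE)
    o <- enum_hyper(k, n1, n2, N)
    expect_equal(r$ease_p, o$upper(k), tolerance = 1e-12)
    # and the two-tailed p matches fisher.test's convention
    tab <- matrix(c(k, n1 - k, n2 - k, N - n1 - n2 + k), 2)
    expect_equal(r$fisher_p_two_tailed, fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("overlap p-values are valid under random-set permutations", {
  set.seed(53)
  universe <- sprintf("g%03d", 1:200)
  ps <- replicate(500, {
    a <- sample(universe, 30); b <- sample(universe, 40)
    ease_fisher(length(intersect(a, b)), 30, 40, 200)$ease_p
  })
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
  expect_lte(mean(ps < 0.01), 0.01 + 3 * sqrt(0.01 * 0.99 / 500))
})

test_that("set_overlap_test returns pairwise stats and Venn regions", {
  universe <- sprintf("g%03d", 1:100)
  s1 <- universe[1:30]; s2 <- universe[21:50]; s3 <- universe[c(1:10, 41:60)]
  res <- set_overlap_test(list(A = s1, B = s2, C = s3), universe)
  expect_equal(nrow(res$pairwise), 3L)
  ab <- res$pairwise[set_a == "A" & set_b == "B"]
  expect_equal(ab$k, 10L)
  # Venn region counts sum to the union size
  expect_equal(sum(res$venn$n), length(unique(c(s1, s2, s3))))
  # identical sets: overlap = size, minimal p over the support
  res2 <- set_overlap_test(list(X = s1, Y = s1), universe)
  expect_equal(res2$pairwise$k, 30L)
  expect_equal(res2$pairwise$direction, "over")
  # disjoint sets with large margins: under-representation
  res3 <- set_overlap_test(list(X = universe[1:45], Y = universe[46:90]), universe)
  expect_equal(res3$pairwise$direction, "under")
  expect_error(set_overlap_test(list(A = "nope", B = s1), universe), "universe")
})

test_that("expression tiers are exact tertiles with stable tie handling", {
  expr <- data.table(gene_id = sprintf("g%03d", 1:300),
                     base = sample(1:1000, 300), pert = 1)
  cls <- classify_expression(expr, "base")
  expect_equal(unname(table(cls$tier)[c("high", "low", "moderate")]),
               rep(100L, 3), ignore_attr = TRUE)
  # ranking respected
  expect_true(min(expr$base[cls$tier == "high"]) >
                max(expr$base[cls$tier == "moderate"]))
  # all-equal values: deterministic placement by input order
  expr2 <- data.table(gene_id = sprintf("g%02d", 1:9), base = 1)
  cls2 <- classify_expression(expr2, "base")
  expect_equal(cls2$tier, rep(c("low", "moderate", "high"), each = 3))
  # fold-change flags
  expr3 <- data.table(gene_id = c("a", "b", "c"), base = c(10, 10, 10),
                      pert = c(40, 10, 4))
  cls3 <- classify_expression(expr3, "base", "pert")
  expect_equal(cls3$up, c(TRUE, FALSE, FALSE))
  expect_equal(cls3$down, c(FALSE, FALSE, TRUE))
  expect_error(classify_expression(expr3, "missing"), "baseline")
})

test_that("enhancer linkage picks the nearest TSS within 20 kb", {
  ann <- structure(list(genes = data.table(
    gene_id = c("g1", "g2"), tx_id = c("g1", "g2"), chrom = "chr1",
    strand = c("+", "+"), tx_start = c(20000L, 30000L),
    tx_end = c(25000L, 36000L), cds_start = c(20000L, 30000L),
    cds_end = c(20000L, 30000L)),
    exons = NULL), class = "gene_annotation")
  enh <- data.table(chrom = "chr1", start = 5000L, end = 6000L,
                    enhancer_id = "e1")
  res <- enhancer_gene_linkage(enh, ann, repressed_genes = "g1")
  expect_equal(res$links$gene_id, "g1")
  expect_equal(res$links$distance, 14000)
  expect_equal(res$fraction_repression_explained, 1)
  # beyond the 20 kb limit: unlinked
  enh2 <- data.table(chrom = "chr1", start = 5000L, end = 6000L)
  ann2 <- ann; ann2$genes <- copy(ann$genes)[, `:=`(tx_start = tx_start + 21000L,
                                                    tx_end = tx_end + 21000L)]
  res2 <- enhancer_gene_linkage(enh2, ann2, repressed_genes = "g1")
  expect_equal(nrow(res2$links), 0L)
  # TSS inside the enhancer: distance 0
  enh3 <- data.table(chrom = "chr1", start = 19000L, end = 21000L)
  res3 <- enhancer_gene_linkage(enh3, ann, repressed_genes = character(0))
  expect_equal(res3$links$distance, 0)
})

test_that("linkage is invariant under coordinate translation", {
  set.seed(54)
  genes <- data.table(gene_id = sprintf("g%02d", 1:10), tx_id = sprintf("g%02d", 1:10),
                      chrom = "chr1", strand = "+",
                      tx_start = cumsum(sample(30000:60000, 10)))
  genes[, tx_end := tx_start + 5000L]
  genes[, `:=`(cds_start = tx_start, cds_end = tx_start)]
  ann <- structure(list(genes = genes, exons = NULL), class = "gene_annotation")
  enh <- data.table(chrom = "chr1", start = genes$tx_start[3] - 9000L,
                    end = genes$tx_start[3] - 7000L)
  shift <- 12345L
  ann_s <- ann
  ann_s$genes <- copy(genes)[, `:=`(tx_start = tx_start + shift,
                                    tx_end = tx_end + shift,
                                    cds_start = cds_start + shift,
                                    cds_end = cds_end + shift)]
  enh_s <- copy(enh)[, `:=`(start = start + shift, end = end + shift)]
  r1 <- enhancer_gene_linkage(enh, ann, "g03")
  r2 <- enhancer_gene_linkage(enh_s, ann_s, "g03")
  expect_equal(r1$links$gene_id, r2$links$gene_id)
  expect_equal(r1$links$distance, r2$links$distance)
})
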