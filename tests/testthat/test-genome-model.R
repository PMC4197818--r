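test_that("refFlat round-trips through write and read", {
  ann <- tiny_annotation()
  path <- withr::local_tempfile(fileext = ".refFlat")
  write_refflat(ann, path)
  back <- load_gene_annotation(path, "refFlat")
  expect_equal(back$genes[order(gene_id),
                          .(gene_id, chrom, strand, tx_start, tx_end,
                            cds_start, cds_end)],
               ann$genes[order(gene_id),
                         .(gene_id, chrom, strand, tx_start, tx_end,
                           cds_start, cds_end)])
  expect_equal(back$exons[order(gene_id, start), .(gene_id, start, end)],
               ann$exons[order(gene_id, start), .(gene_id, start, end)])
})

test_that("refFlat field mapping and validation errors", {
  path <- withr::local_tempfile(fileext = ".refFlat")
  writeLines("g1\tg1\tchr1\t+\t1000\t5000\t1500\t4500\t2\t1000,3000,\t2000,5000,",
             file.path(path))
  ann <- load_gene_annotation(path, "refFlat")
  expect_equal(ann$genes$tx_start, 1000L)
  regions <- derive_gene_regions(ann)
  expect_equal(nrow(regions$introns), 1L)
  expect_equal(regions$introns$start, 2000L)
  expect_equal(regions$introns$end, 3000L)
  # exon outside tx span
  writeLines("g1\tg1\tchr1\t+\t1000\t5000\t1500\t4500\t2\t500,3000,\t2000,5000,",
             path)
  expect_error(load_gene_annotation(path, "refFlat"), "exon")
})

test_that("GTF 1-based closed coordinates convert to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttoy\texon\t1001\t1500\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\texon\t2001\t2500\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\tCDS\t1101\t2400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    path)
  ann <- load_gene_annotation(path, "gtf")
  expect_equal(ann$exons$start, c(1000L, 2000L))
  expect_equal(ann$exons$end, c(1500L, 2500L))
  expect_equal(ann$genes$cds_start, 1100L)
  expect_equal(ann$genes$cds_end, 2400L)
})

test_that("representative transcript is the longest, ties by smaller start", {
  ann <- tiny_annotation()
  g2 <- copy(ann$genes)[gene_id == "gA"][, `:=`(tx_id = "gA.2", tx_start = 9000L)]
  e2 <- data.table(gene_id = "gA", start = 9000L, end = 20000L)
  ann2 <- structure(list(
    genes = rbind(ann$genes, g2, fill = TRUE),
    exons = rbind(ann$exons,
                  copy(e2)[, tx_id := "gA.2"], fill = TRUE)),
    class = "gene_annotation")
  ann2$exons[is.na(tx_id), tx_id := gene_id]
  picked <- dipdiff:::pick_representative(ann2)
  expect_equal(picked$genes[gene_id == "gA", tx_start], 9000L)
})

test_that("derived gene regions obey the promoter/TTS arithmetic", {
  ann <- tiny_annotation()
  r <- derive_gene_regions(ann)
  # plus strand gA tx=[10000,20000)
  expect_equal(r$promoters[gene_id == "gA", .(start, end)],
               data.table(start = 9000L, end = 11000L))
  expect_equal(r$tts_flanks[gene_id == "gA", .(start, end)],
               data.table(start = 20000L, end = 21000L))
  # minus strand gB tx=[50000,60000): promoter at the high end
  expect_equal(r$promoters[gene_id == "gB", .(start, end)],
               data.table(start = 59000L, end = 61000L))
  expect_equal(r$tts_flanks[gene_id == "gB", .(start, end)],
               data.table(start = 49000L, end = 50000L))
  # single-exon non-coding gC: no introns, no UTRs, no coding exons
  expect_equal(nrow(r$introns[gene_id == "gC"]), 0L)
  expect_equal(nrow(r$utr5[gene_id == "gC"]), 0L)
  expect_equal(nrow(r$coding_exons[gene_id == "gC"]), 0L)
})

test_that("exons and introns tile the transcript exactly", {
  ann <- tiny_annotation()
  r <- derive_gene_regions(ann)
  for (g in ann$genes$gene_id) {
    tx <- ann$genes[gene_id == g]
    pieces <- rbind(r$exons[gene_id == g, .(start, end)],
                    r$introns[gene_id == g, .(start, end)])
    setorder(pieces, start)
    expect_equal(pieces$start[1L], tx$tx_start)
    expect_equal(pieces$end[nrow(pieces)], tx$tx_end)
    if (nrow(pieces) > 1L)
      expect_equal(pieces$start[-1L], pieces$end[-nrow(pieces)])
  }
})

test_that("CGI shores are 2 kb flanks truncated at neighbours and edges", {
  cs <- c(chrA = 50000)
  isl <- data.table(chrom = "chrA", start = c(500L, 10000L, 11000L),
                    end = c(800L, 10500L, 11400L))
  ss <- compute_cgi_shores(isl, cs)
  sh <- ss$shores
  # chromosome-edge clip
  expect_equal(sh[island_id == "cgi_1" & side == "upstream", .(start, end)],
               data.table(start = 0L, end = 500L))
  # plain 2-kb flank
  expect_equal(sh[island_id == "cgi_2" & side == "upstream", .(start, end)],
               data.table(start = 8000L, end = 10000L))
  # truncation at the neighbouring island
  expect_equal(sh[island_id == "cgi_2" & side == "downstream", .(start, end)],
               data.table(start = 10500L, end = 11000L))
  # invariants: shores disjoint from islands, <= 2 per island, <= 2 kb
  expect_true(all(sh$end - sh$start <= 2000L))
  expect_true(all(table(sh$island_id) <= 2L))
  ov <- GenomicRanges::findOverlaps(dipdiff:::as_granges0(sh),
                                    dipdiff:::as_granges0(isl))
  expect_equal(length(ov), 0L)
  expect_error(compute_cgi_shores(data.table(chrom = "chrA", start = c(0L, 50L),
                                             end = c(100L, 150L)), cs),
               "overlap")
})

test_that("CGI location classes use promoter > gene_body > intergenic priority", {
  ann <- tiny_annotation()
  isl <- data.table(chrom = c("chr1", "chr1", "chr1"),
                    start = c(10500L, 14500L, 80000L),
                    end = c(10900L, 15000L, 80400L))
  cls <- classify_cgi_location(isl, ann)
  expect_equal(cls, c("promoter", "gene_body", "intergenic"))
  # partition: every island gets exactly one class
  expect_true(all(cls %in% c("promoter", "gene_body", "intergenic")))
})

test_that("promoter CpG classification matches closed-form constructions", {
  # pure CG repeat: GC=1, O/E = (250*500)/(250*250) = 2 -> HCP
  cg <- strrep("CG", 400)
  r <- classify_promoter_cpg_density(cg)
  expect_equal(r$class, "HCP")
  expect_equal(r$best_window_oe, 2, tolerance = 0.01)
  # poly-A: no CpG anywhere -> LCP
  expect_equal(classify_promoter_cpg_density(strrep("A", 900))$class, "LCP")
  # moderate CpG, low GC -> ICP (checked by brute force over all windows)
  set.seed(42)
  v <- sample(c("A", "C", "G", "T"), 900, replace = TRUE,
              prob = c(0.28, 0.22, 0.22, 0.28))
  icp <- paste(v, collapse = "")
  r2 <- classify_promoter_cpg_density(icp)
  # brute-force window scan
  win_stats <- sapply(seq(1, 401, by = 5), function(s) {
    w <- v[s:(s + 499)]
    nc <- sum(w == "C"); ng <- sum(w == "G")
    ncpg <- sum(w[-500] == "C" & w[-1] == "G")
    c(gc = (nc + ng) / 500, oe = ncpg * 500 / (nc * ng))
  })
  expect_false(any(win_stats["gc", ] >= 0.55 & win_stats["oe", ] >= 0.75))
  expect_true(any(win_stats["oe", ] >= 0.48))
  expect_equal(r2$class, "ICP")
  expect_equal(r2$best_window_oe, max(win_stats["oe", ]), tolerance = 1e-12)
})

test_that("CpG classification is reverse-complement invariant", {
  set.seed(7)
  for (i in 1:5) {
    v <- sample(c("A", "C", "G", "T", "N"), 900, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.28, 0.02))
    s <- paste(v, collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      gsub("N", "N", s))))
    expect_equal(classify_promoter_cpg_density(s)$class,
                 classify_promoter_cpg_density(rc)$class)
  }
})

test_that("short promoter sequence is classified whole with a warning", {
  expect_warning(r <- classify_promoter_cpg_density(strrep("CG", 50)),
                 "shorter")
  expect_equal(r$class, "HCP")
})
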