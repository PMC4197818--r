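# Mapping islands / differential regions onto gene regions, CGIs, shores
# and enhancers; per-gene-region change calls with 2x/4x magnitude strata.

#' Annotate regions with overlapping genomic features
#'
#' Any-overlap (>= 1 bp) assignment of each region to gene region classes
#' (promoter, 5' UTR, exon, coding exon, 3' UTR, intron, TTS flank) and,
#' when provided, CGIs, shores and enhancers. Regions touching nothing are
#' assigned `intergenic`.
#'
#' @param regions interval table (`chrom`, `start`, `end`); a `region_id`
#'   column is added if absent (row order).
#' @param gene_regions a `gene_regions` object (see
#'   [derive_gene_regions()]).
#' @param cgis,enhancers optional interval tables (id column: `cgi_id` /
#'   `enhancer_id`).
#' @param shores optional `shore_set`.
#' @return data.table: `region_id`, `feature_class`, `feature_id`,
#'   `overlap_bp`.
#' @export
annotate_regions <- function(regions, gene_regions, cgis = NULL, shores = NULL,
                             enhancers = NULL) {
  reg <- data.table::as.data.table(regions)
  validate_intervals(reg, "region")
  if (!"region_id" %in% names(reg)) reg[, region_id := sprintf("region_%d", .I)]
  feat <- region_class_table(gene_regions)
  feat <- feat[, .(chrom, start, end, feature_id = gene_id, feature_class = region_class)]
  add <- function(dt, id_col, cls) {
    if (is.null(dt)) return(NULL)
    d <- data.table::as.data.table(dt)
    d[, .(chrom, start, end, feature_id = get(id_col), feature_class = cls)]
  }
  feat <- rbind(feat,
                add(cgis, "cgi_id", "cgi"),
                if (!is.null(shores)) {
                  sh <- shores$shores
                  sh[, .(chrom, start, end,
                         feature_id = paste(island_id, side, sep = ":"),
                         feature_class = "shore")]
                },
                add(enhancers, "enhancer_id", "enhancer"))
  hits <- GenomicRanges::findOverlaps(as_granges0(reg), as_granges0(feat),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.table::data.table(
    region_id = reg$region_id[qi],
    feature_class = feat$feature_class[si],
    feature_id = feat$feature_id[si],
    overlap_bp = pmin(reg$end[qi], feat$end[si]) - pmax(reg$start[qi], feat$start[si]))
  orphan <- setdiff(reg$region_id, out$region_id)
  if (length(orphan)) {
    out <- rbind(out, data.table::data.table(region_id = orphan,
                                             feature_class = "intergenic",
                                             feature_id = NA_character_,
                                             overlap_bp = 0L))
  }
  out[order(match(region_id, reg$region_id), feature_class, feature_id)]
}

# shared call logic: best significant region per target interval
best_region_per_target <- function(diff_regions, targets, fdr) {
  dr <- data.table::as.data.table(diff_regions)
  sig <- dr[q_value <= fdr]
  if (nrow(sig) == 0L || nrow(targets) == 0L) return(NULL)
  hits <- GenomicRanges::findOverlaps(as_granges0(targets), as_granges0(sig),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0L) return(NULL)
  m <- data.table::data.table(
    target_idx = qi,
    log2_fc = sig$log2_fc[si],
    overlap_bp = pmin(targets$end[qi], sig$end[si]) - pmax(targets$start[qi], sig$start[si]),
    region_start = sig$start[si])
  # tie-break: max |log2FC|, then larger overlap, then smaller region start
  m[, abs_lfc := abs(log2_fc)]
  data.table::setorder(m, target_idx, -abs_lfc, -overlap_bp, region_start)
  m[!duplicated(target_idx)]
}

fold_stratum <- function(log2_fc) {
  a <- abs(log2_fc)
  data.table::fifelse(a >= 2, ">=4x", data.table::fifelse(a >= 1, "2-4x", "none"))
}

#' Per-gene, per-region-class change calls
#'
#' A (gene, region class) pair is called when a significant differential
#' region (q <= `fdr`) overlaps that region class by >= 1 bp and the
#' maximal-magnitude overlapping region changes at least two-fold.
#' Direction and stratum come from that region (ties: larger overlap,
#' then smaller start). Strata: `">=4x"` for |log2FC| >= 2, `"2-4x"` for
#' 1 <= |log2FC| < 2.
#'
#' @param diff_regions a `differential_regions` table.
#' @param gene_regions a `gene_regions` object.
#' @param mark label recorded in the output (e.g. `"5hmC"`).
#' @param fdr significance cutoff on `q_value`.
#' @return data.table: `gene_id`, `region_class`, `mark`, `direction`
#'   (hyper/hypo), `log2_fc`, `stratum`.
#' @export
gene_change_calls <- function(diff_regions, gene_regions, mark = "5hmC", fdr = 0.01) {
  targets <- region_class_table(gene_regions)
  best <- best_region_per_target(diff_regions, targets, fdr)
  empty <- data.table::data.table(gene_id = character(0), region_class = character(0),
                                  mark = character(0), direction = character(0),
                                  log2_fc = numeric(0), stratum = character(0))
  if (is.null(best)) return(empty)
  out <- data.table::data.table(
    gene_id = targets$gene_id[best$target_idx],
    region_class = targets$region_class[best$target_idx],
    mark = mark,
    direction = data.table::fifelse(best$log2_fc > 0, "hyper", "hypo"),
    log2_fc = best$log2_fc,
    stratum = fold_stratum(best$log2_fc))
  # multiple intervals of one class (e.g. exons) may hit: keep the best per pair
  out[, abs_lfc := abs(log2_fc)]
  data.table::setorder(out, gene_id, region_class, -abs_lfc)
  out[, abs_lfc := NULL]
  out <- out[!duplicated(paste(gene_id, region_class))]
  out <- out[stratum != "none"]
  out[order(gene_id, region_class)]
}

#' Count called genes per region class, direction and stratum
#' @param calls output of [gene_change_calls()].
#' @return data.table: `region_class`, `direction`, `stratum`, `n_genes`.
#' @export
summarize_gene_changes <- function(calls) {
  data.table::as.data.table(calls)[, .(n_genes = data.table::uniqueN(gene_id)),
                                   by = .(region_class, direction, stratum)]
}

#' Per-shore change calls and location-class summaries
#'
#' Shores (and their islands) are called hyper/hypo like gene regions.
#' The summary reports, per CGI location class, the fraction of shores
#' (and islands) called hyper, plus the fraction of promoter-CGI genes
#' with at least one hypermethylated shore.
#'
#' @param diff_regions a `differential_regions` table (typically 5mC).
#' @param shore_set a `shore_set` from [compute_cgi_shores()].
#' @param ann a `gene_annotation` (for location classes and the
#'   promoter-gene summary).
#' @param fdr significance cutoff.
#' @return list: `shore_calls`, `island_calls`, `class_summary`
#'   (per location class: shores/islands hyper fractions),
#'   `promoter_gene_summary` (`n_genes`, `n_hyper`, `fraction_hyper`).
#' @export
shore_change_calls <- function(diff_regions, shore_set, ann, fdr = 0.01) {
  stopifnot(inherits(shore_set, "shore_set"))
  isl <- data.table::copy(shore_set$islands)
  if (!"location" %in% names(isl))
    isl[, location := classify_cgi_location(isl, ann)]
  sh <- merge(shore_set$shores, isl[, .(island_id, location)], by = "island_id")
  call_tbl <- function(targets) {
    t2 <- data.table::copy(targets)
    best <- best_region_per_target(diff_regions, t2, fdr)
    t2[, `:=`(direction = "none", log2_fc = 0, stratum = "none")]
    if (!is.null(best)) {
      lfc <- best$log2_fc
      str <- fold_stratum(lfc)
      keep <- str != "none"
      t2$direction[best$target_idx[keep]] <-
        data.table::fifelse(lfc[keep] > 0, "hyper", "hypo")
      t2$log2_fc[best$target_idx[keep]] <- lfc[keep]
      t2$stratum[best$target_idx[keep]] <- str[keep]
    }
    t2
  }
  shore_calls <- call_tbl(sh)
  island_calls <- call_tbl(isl)
  class_summary <- merge(
    shore_calls[, .(n_shores = .N, shores_hyper = mean(direction == "hyper")),
                by = location],
    island_calls[, .(n_islands = .N, islands_hyper = mean(direction == "hyper")),
                 by = location],
    by = "location", all = TRUE)
  # promoter-gene summary: genes whose promoter overlaps a CGI
  prom <- derive_gene_regions(ann)$promoters
  hits <- GenomicRanges::findOverlaps(as_granges0(prom), as_granges0(isl),
                                      ignore.strand = TRUE)
  link <- data.table::data.table(gene_id = prom$gene_id[S4Vectors::queryHits(hits)],
                                 island_id = isl$island_id[S4Vectors::subjectHits(hits)])
  hyper_islands <- unique(shore_calls[direction == "hyper", island_id])
  gene_tbl <- link[, .(hyper = any(island_id %in% hyper_islands)), by = gene_id]
  promoter_gene_summary <- list(
    n_genes = nrow(gene_tbl),
    n_hyper = sum(gene_tbl$hyper),
    fraction_hyper = if (nrow(gene_tbl)) mean(gene_tbl$hyper) else 0)
  list(shore_calls = shore_calls, island_calls = island_calls,
       class_summary = class_summary,
       promoter_gene_summary = promoter_gene_summary)
}
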