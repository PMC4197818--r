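# fixtures built in code and independent brute-force oracles

library(data.table)

# --- tiny object builders -------------------------------------------------

tagset_from_midpoints <- function(mids_list, chrom_sizes, dedup_max = 1L,
                                  fragment_length = 300L) {
  mids <- lapply(names(chrom_sizes), function(ch) sort(mids_list[[ch]] %||% integer(0)))
  names(mids) <- names(chrom_sizes)
  structure(list(midpoints = mids,
                 library_size = sum(lengths(mids)),
                 chrom_sizes = chrom_sizes,
                 fragment_length = fragment_length,
                 dedup_max = dedup_max),
            class = "tag_set")
}
`%||%` <- function(x, y) if (is.null(x)) y else x

wc_from_counts <- function(counts_list, window_size, library_size, chrom_sizes) {
  structure(list(window_size = as.integer(window_size), counts = counts_list,
                 library_size = library_size, chrom_sizes = chrom_sizes),
            class = "window_counts")
}

reads_dt <- function(chrom, start, end, strand) {
  dipdiff:::as_aligned_reads(data.table(chrom = chrom, start = start,
                                        end = end, strand = strand))
}

# a small deterministic annotation: two genes on chr1 (one minus-strand),
# one on chr2
tiny_annotation <- function(chrom_sizes = c(chr1 = 100000, chr2 = 60000)) {
  genes <- data.table(
    gene_id = c("gA", "gB", "gC"),
    tx_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(10000L, 50000L, 20000L),
    tx_end = c(20000L, 60000L, 26000L),
    cds_start = c(11000L, 52000L, 20000L),
    cds_end = c(19000L, 58000L, 20000L))
  exons <- rbind(
    data.table(gene_id = "gA", start = c(10000L, 14000L, 18000L),
               end = c(12000L, 16000L, 20000L)),
    data.table(gene_id = "gB", start = c(50000L, 56000L), end = c(54000L, 60000L)),
    data.table(gene_id = "gC", start = 20000L, end = 26000L))
  structure(list(genes = genes, exons = exons, chrom_sizes = chrom_sizes),
            class = "gene_annotation")
}

# --- independent oracles --------------------------------------------------

# direct-scan island enumerator over one chromosome's window counts
brute_islands <- function(counts, lambda, window_size, gap_size,
                          eligibility_p = 0.2, threshold = 0) {
  p <- ppois(counts - 1L, lambda, lower.tail = FALSE)
  elig <- p < eligibility_p
  score <- ifelse(elig, -log(p), 0)
  out <- list(); cur <- NULL
  for (i in seq_along(counts)) {
    if (!elig[i]) next
    if (!is.null(cur) && (i - cur$last - 1L) * window_size <= gap_size) {
      cur$last <- i
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- list(first = i, last = i)
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  if (!length(out)) {
    return(data.table(start = integer(0), end = integer(0), score = numeric(0),
                      tag_count = integer(0), n_windows = integer(0)))
  }
  dt <- rbindlist(lapply(out, function(x) {
    span <- x$first:x$last
    data.table(start = (x$first - 1L) * window_size, end = x$last * window_size,
               score = sum(score[span][elig[span]]),
               tag_count = sum(counts[span]),
               n_windows = sum(elig[span]))
  }))
  dt[score >= threshold]
}

# full hypergeometric enumeration via log-binomials (independent of dhyper)
enum_hyper <- function(k, n1, n2, N) {
  supp <- max(0, n1 + n2 - N):min(n1, n2)
  logp <- lchoose(n1, supp) + lchoose(N - n1, n2 - supp) - lchoose(N, n2)
  p <- exp(logp)
  obs <- p[supp == k]
  list(two_tailed = min(1, sum(p[p <= obs * (1 + 1e-7)])),
       upper = function(kk) min(1, sum(p[supp >= kk])))
}

# all-pairs quadratic overlap check
brute_overlaps <- function(regions, features) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(features))) {
      if (regions$chrom[i] == features$chrom[j] &&
          regions$start[i] < features$end[j] &&
          features$start[j] < regions$end[i]) {
        out[[length(out) + 1L]] <- data.table(
          region_id = regions$region_id[i],
          feature_class = features$feature_class[j],
          feature_id = features$feature_id[j],
          overlap_bp = min(regions$end[i], features$end[j]) -
            max(regions$start[i], features$start[j]))
      }
    }
  }
  if (!length(out)) return(NULL)
  rbindlist(out)
}

# overlap between a call table and planted intervals (any overlap, same chrom)
overlaps_any_planted <- function(calls, planted) {
  vapply(seq_len(nrow(calls)), function(i) {
    any(planted$chrom == calls$chrom[i] & planted$start < calls$end[i] &
          planted$end > calls$start[i])
  }, logical(1))
}
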