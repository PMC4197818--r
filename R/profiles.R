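# FPKM-scaled composite tag-density profiles over absolute flanks and
# relative-length feature bodies.

#' Composite-profile specification
#'
#' @param flank_bp absolute flank width on each side (default 5000).
#' @param bins_flank bins per flank segment.
#' @param bins_body bins for the relative-length body segment.
#' @param body_range gene-body portion profiled, in percent of gene length
#'   (default 25 to 75).
#' @param dedup_max duplicate policy expected of the input tags
#'   (profiles use max 2 per position).
#' @return a `profile_spec` list.
#' @export
profile_spec <- function(flank_bp = 5000L, bins_flank = 100L, bins_body = 50L,
                         body_range = c(25, 75), dedup_max = 2L) {
  stopifnot(bins_flank >= 1L, bins_body >= 1L,
            length(body_range) == 2L, body_range[1L] < body_range[2L],
            body_range[1L] >= 0, body_range[2L] <= 100)
  structure(list(flank_bp = as.integer(flank_bp), bins_flank = as.integer(bins_flank),
                 bins_body = as.integer(bins_body), body_range = body_range,
                 dedup_max = as.integer(dedup_max)),
            class = "profile_spec")
}

# count tag midpoints of one chromosome between consecutive numeric edges
bin_counts <- function(mids, edges) {
  if (length(mids) == 0L) return(integer(length(edges) - 1L))
  diff(findInterval(edges - 1e-9, mids))
}

check_profile_dedup <- function(tags, spec) {
  dm <- tags$dedup_max
  if (!is.null(dm) && dm != spec$dedup_max)
    warning("tags deduplicated at max=", dm, " but profile spec expects max=",
            spec$dedup_max)
}

new_density_profile <- function(segments, sums, nfeat, totals, binlens, lib, skipped) {
  dt <- data.table::rbindlist(lapply(names(segments), function(sg) {
    n <- segments[[sg]]
    data.table::data.table(segment = sg, bin = seq_len(n),
                           mean_density = sums[[sg]] / pmax(nfeat[[sg]], 1L),
                           n_features = nfeat[[sg]])
  }))
  data.table::setattr(dt, "segment_totals",
                      data.table::data.table(segment = names(totals),
                                             total_count = unlist(totals)))
  data.table::setattr(dt, "library_size", lib)
  data.table::setattr(dt, "n_skipped", skipped)
  data.table::setattr(dt, "class", unique(c("density_profile", class(dt))))
  dt[]
}

#' Composite gene profile (TSS flank / relative body / TTS flank)
#'
#' Three segments per gene, flipped for minus-strand genes so bins run in
#' transcription direction: an absolute window of `2 * flank_bp` around
#' the TSS, the gene body from `body_range[1]`% to `body_range[2]`% of
#' gene length in relative bins, and an absolute window around the TTS.
#' Per-bin densities are FPKM-normalized (bin length, library size) and
#' averaged over genes. Genes whose profiled body is shorter than one bin
#' per bin are skipped and counted.
#'
#' @param tags a `tag_set` (dedup max 2 by convention).
#' @param ann a `gene_annotation`.
#' @param spec a `profile_spec`.
#' @return a `density_profile` data.table (`segment`, `bin`,
#'   `mean_density`, `n_features`) with attributes `segment_totals`
#'   (raw tag counts per segment, for conservation checks),
#'   `library_size` and `n_skipped`.
#' @export
composite_gene_profile <- function(tags, ann, spec = profile_spec()) {
  stopifnot(inherits(tags, "tag_set"), inherits(ann, "gene_annotation"))
  check_profile_dedup(tags, spec)
  if (tags$library_size <= 0) stop_dd("empty library")
  g <- ann$genes
  lib <- tags$library_size
  nb <- c(tss_flank = spec$bins_flank, body = spec$bins_body,
          tts_flank = spec$bins_flank)
  sums <- lapply(nb, numeric); nfeat <- lapply(nb, integer)
  totals <- lapply(nb, function(...) 0L)
  flank_binlen <- 2 * spec$flank_bp / spec$bins_flank
  skipped <- 0L
  for (i in seq_len(nrow(g))) {
    m <- tags$midpoints[[g$chrom[i]]]
    minus <- g$strand[i] == "-"
    tss <- if (minus) g$tx_end[i] else g$tx_start[i]
    tts <- if (minus) g$tx_start[i] else g$tx_end[i]
    L <- g$tx_end[i] - g$tx_start[i]
    lo <- g$tx_start[i] + L * spec$body_range[1L] / 100
    hi <- g$tx_start[i] + L * spec$body_range[2L] / 100
    body_ok <- (hi - lo) >= spec$bins_body
    if (!body_ok) skipped <- skipped + 1L
    seg_counts <- list(
      tss_flank = bin_counts(m, seq(tss - spec$flank_bp, tss + spec$flank_bp,
                                    length.out = spec$bins_flank + 1L)),
      body = if (body_ok) bin_counts(m, seq(lo, hi, length.out = spec$bins_body + 1L)),
      tts_flank = bin_counts(m, seq(tts - spec$flank_bp, tts + spec$flank_bp,
                                    length.out = spec$bins_flank + 1L)))
    binlen <- c(tss_flank = flank_binlen, body = (hi - lo) / spec$bins_body,
                tts_flank = flank_binlen)
    for (sg in names(nb)) {
      cnt <- seg_counts[[sg]]
      if (is.null(cnt)) next
      if (minus) cnt <- rev(cnt)
      sums[[sg]] <- sums[[sg]] + fpkm_density(cnt, binlen[[sg]], lib)
      nfeat[[sg]] <- nfeat[[sg]] + 1L
      totals[[sg]] <- totals[[sg]] + sum(cnt)
    }
  }
  new_density_profile(nb, sums, nfeat, totals, NULL, lib, skipped)
}

#' Scaled interval profile with absolute flanks
#'
#' Each interval (CGI, enhancer, exon, ...) is rescaled to `bins_body`
#' relative bins spanning 0-100% of its length, flanked on both sides by
#' absolute windows of `flank_bp` in `bins_flank` bins. Unstranded.
#'
#' @param tags a `tag_set`.
#' @param intervals interval table (`chrom`, `start`, `end`).
#' @param spec a `profile_spec` (`body_range` is ignored: scaled
#'   intervals use their full length).
#' @return a `density_profile` with segments `upstream`, `body`,
#'   `downstream`.
#' @export
scaled_interval_profile <- function(tags, intervals, spec = profile_spec()) {
  stopifnot(inherits(tags, "tag_set"))
  iv <- data.table::as.data.table(intervals)
  if (nrow(iv) == 0L) stop_dd("empty interval list")
  validate_intervals(iv, "profile interval")
  check_profile_dedup(tags, spec)
  if (tags$library_size <= 0) stop_dd("empty library")
  lib <- tags$library_size
  nb <- c(upstream = spec$bins_flank, body = spec$bins_body,
          downstream = spec$bins_flank)
  sums <- lapply(nb, numeric); nfeat <- lapply(nb, integer)
  totals <- lapply(nb, function(...) 0L)
  flank_binlen <- spec$flank_bp / spec$bins_flank
  skipped <- 0L
  for (i in seq_len(nrow(iv))) {
    m <- tags$midpoints[[iv$chrom[i]]]
    L <- iv$end[i] - iv$start[i]
    body_ok <- L >= spec$bins_body
    if (!body_ok) skipped <- skipped + 1L
    seg_counts <- list(
      upstream = bin_counts(m, seq(iv$start[i] - spec$flank_bp, iv$start[i],
                                   length.out = spec$bins_flank + 1L)),
      body = if (body_ok) bin_counts(m, seq(iv$start[i], iv$end[i],
                                            length.out = spec$bins_body + 1L)),
      downstream = bin_counts(m, seq(iv$end[i], iv$end[i] + spec$flank_bp,
                                     length.out = spec$bins_flank + 1L)))
    binlen <- c(upstream = flank_binlen, body = L / spec$bins_body,
                downstream = flank_binlen)
    for (sg in names(nb)) {
      cnt <- seg_counts[[sg]]
      if (is.null(cnt)) next
      sums[[sg]] <- sums[[sg]] + fpkm_density(cnt, binlen[[sg]], lib)
      nfeat[[sg]] <- nfeat[[sg]] + 1L
      totals[[sg]] <- totals[[sg]] + sum(cnt)
    }
  }
  new_density_profile(nb, sums, nfeat, totals, NULL, lib, skipped)
}

#' Log2 display transform of a density profile
#'
#' Stored profiles are linear; this applies `log2(density + eps)` for
#' plotting/presentation.
#'
#' @param profile a `density_profile`.
#' @param eps pseudo-density in FPKM (default 0.01).
#' @return the profile with a `log2_density` column added.
#' @export
profile_log2 <- function(profile, eps = 0.01) {
  dt <- data.table::copy(data.table::as.data.table(profile))
  dt[, log2_density := log2(mean_density + eps)]
  dt[]
}

#' Write a density profile as TSV
#' @param profile a `density_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  data.table::fwrite(data.table::as.data.table(profile), path, sep = "\t")
  invisible(path)
}
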