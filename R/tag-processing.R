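# Aligned reads -> deduplicated, 3'-extended fragment-midpoint tags;
# fixed-window counting; FPKM normalization.

#' Read aligned reads from a BED file
#'
#' @param path BED file of aligned reads (BED6 or more columns).
#' @return an `aligned_reads` data.table: `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_aligned_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  dt[strand == "*", strand := "+"]
  as_aligned_reads(dt)
}

#' Read aligned reads from SAM/BAM
#'
#' Unmapped records and reads at or below the mapping-quality threshold
#' are dropped, mirroring the removal of multiply mapped reads upstream.
#'
#' @param path SAM or BAM file.
#' @param min_mapq keep reads with MAPQ strictly greater than this
#'   (default 0).
#' @return an `aligned_reads` data.table.
#' @export
read_aligned_sam <- function(path, min_mapq = 0L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    what = c("rname", "pos", "qwidth", "strand", "mapq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(x$mapq) & x$mapq > min_mapq
  dt <- data.table::data.table(
    chrom = as.character(x$rname)[keep],
    start = x$pos[keep] - 1L,
    end = x$pos[keep] - 1L + x$qwidth[keep],
    strand = as.character(x$strand)[keep])
  as_aligned_reads(dt)
}

as_aligned_reads <- function(dt) {
  dt <- data.table::as.data.table(dt)
  validate_intervals(dt, "read")
  if (!all(dt$strand %in% c("+", "-"))) stop_dd("reads must be stranded (+/-)")
  data.table::setattr(dt, "class", c("aligned_reads", class(dt)))
  dt[]
}

#' Deduplicate aligned reads
#'
#' Retains at most `max_per_position` reads per duplicate key
#' (chromosome, 5' start, strand); retention is deterministic (first
#' occurrences in sorted order). The island caller uses
#' `max_per_position = 1` (redundancy 1); density profiles use
#' `max_per_position = 2` (discard beyond two reads per location).
#'
#' @param reads an `aligned_reads` table.
#' @param max_per_position 1 or 2.
#' @return deduplicated `aligned_reads` with attribute `dedup_max`.
#' @export
deduplicate_reads <- function(reads, max_per_position = 1L) {
  if (!is_count(max_per_position) || max_per_position < 1L)
    stop_dd("max_per_position must be a positive integer")
  dt <- data.table::as.data.table(reads)
  dt[, .pos5 := data.table::fifelse(strand == "-", end, start)]
  data.table::setorder(dt, chrom, .pos5, strand, start, end)
  dt[, .k := seq_len(.N), by = .(chrom, .pos5, strand)]
  out <- dt[.k <= max_per_position][, c(".pos5", ".k") := NULL]
  out <- as_aligned_reads(out)
  data.table::setattr(out, "dedup_max", as.integer(max_per_position))
  out[]
}

#' Convert reads to fragment-midpoint tags
#'
#' Each read is lengthened to `fragment_length` toward its 3' end (plus
#' read `[s,e)` becomes `[s, s+f)`; minus read becomes `[e-f, e)`), the
#' fragment is clipped to chromosome bounds, and the midpoint of the
#' clipped fragment becomes the tag position.
#'
#' @param reads deduplicated `aligned_reads`.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param fragment_length assumed fragment size (default 300 bp); must not
#'   be shorter than the longest read.
#' @return a `tag_set`: list with `midpoints` (per-chromosome sorted
#'   integer vectors), `library_size`, `chrom_sizes`, `fragment_length`,
#'   `dedup_max`.
#' @export
reads_to_tags <- function(reads, chrom_sizes, fragment_length = 300L) {
  if (inherits(reads, "tag_set"))
    stop_dd("reads_to_tags: input is already a tag_set")
  dt <- data.table::as.data.table(reads)
  validate_intervals(dt, "read")
  if (any(dt$end - dt$start > fragment_length))
    stop_dd("fragment_length shorter than read length")
  if (!all(dt$chrom %in% names(chrom_sizes)))
    stop_dd("reads on chromosomes absent from chrom_sizes")
  fs <- data.table::fifelse(dt$strand == "-", dt$end - fragment_length, dt$start)
  fe <- fs + fragment_length
  lim <- as.numeric(chrom_sizes[dt$chrom])
  cs <- pmax(fs, 0)
  ce <- pmin(fe, lim)
  mid <- as.integer((cs + ce) %/% 2)
  mids <- split(mid, dt$chrom)
  mids <- lapply(mids, sort)
  # keep empty chromosomes represented
  all_mids <- stats::setNames(vector("list", length(chrom_sizes)), names(chrom_sizes))
  for (ch in names(chrom_sizes)) all_mids[[ch]] <- mids[[ch]] %||% integer(0)
  structure(list(midpoints = all_mids,
                 library_size = length(mid),
                 chrom_sizes = chrom_sizes,
                 fragment_length = as.integer(fragment_length),
                 dedup_max = attr(reads, "dedup_max")),
            class = "tag_set")
}

#' Count tags in non-overlapping genome windows
#'
#' @param tags a `tag_set`.
#' @param window_size window width in bp (default 200).
#' @return a `window_counts`: list with `window_size`, `counts`
#'   (per-chromosome integer vectors of length `ceiling(len / window)`),
#'   `library_size`, `chrom_sizes`.
#' @export
count_window_tags <- function(tags, window_size = 200L) {
  stopifnot(inherits(tags, "tag_set"))
  if (!is_count(window_size) || window_size <= 0) stop_dd("window_size must be > 0")
  counts <- lapply(names(tags$chrom_sizes), function(ch) {
    nb <- as.integer(ceiling(tags$chrom_sizes[[ch]] / window_size))
    m <- tags$midpoints[[ch]]
    if (length(m) == 0L) integer(nb) else tabulate(m %/% window_size + 1L, nbins = nb)
  })
  names(counts) <- names(tags$chrom_sizes)
  structure(list(window_size = as.integer(window_size), counts = counts,
                 library_size = tags$library_size, chrom_sizes = tags$chrom_sizes),
            class = "window_counts")
}

#' FPKM density
#'
#' Fragments per kilobase of feature per million mapped fragments:
#' `count / (length/1000) / (library_size/1e6)`.
#'
#' @param count tag/fragment count (vectorized).
#' @param feature_length_bp feature length in bp (> 0).
#' @param library_size total mapped fragments (> 0).
#' @return numeric FPKM values.
#' @export
fpkm_density <- function(count, feature_length_bp, library_size) {
  if (any(feature_length_bp <= 0)) stop_dd("FPKM undefined for feature length <= 0")
  if (any(library_size <= 0)) stop_dd("FPKM undefined for empty library")
  count / (feature_length_bp / 1000) / (library_size / 1e6)
}

#' Pool two tag sets
#'
#' Concatenates the midpoints of both libraries (library size adds).
#' Used to form selection-unbiased candidate regions for differential
#' testing.
#'
#' @param a,b `tag_set`s over the same chromosomes.
#' @return a pooled `tag_set`.
#' @export
pool_tag_sets <- function(a, b) {
  stopifnot(inherits(a, "tag_set"), inherits(b, "tag_set"))
  if (!identical(names(a$chrom_sizes), names(b$chrom_sizes)))
    stop_dd("tag sets cover different chromosomes")
  mids <- lapply(names(a$chrom_sizes), function(ch)
    sort(c(a$midpoints[[ch]], b$midpoints[[ch]])))
  names(mids) <- names(a$chrom_sizes)
  structure(list(midpoints = mids,
                 library_size = a$library_size + b$library_size,
                 chrom_sizes = a$chrom_sizes,
                 fragment_length = a$fragment_length,
                 dedup_max = a$dedup_max),
            class = "tag_set")
}

# count tag midpoints falling in [start, end) on given chromosomes (vectorized)
count_in_intervals <- function(tags, chrom, start, end) {
  stopifnot(inherits(tags, "tag_set"))
  out <- integer(length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- tags$midpoints[[ch]]
    if (is.null(m) || length(m) == 0L) next
    out[idx] <- findInterval(end[idx] - 0.5, m) - findInterval(start[idx] - 0.5, m)
  }
  out
}

#' Export a tag set as bedGraph window coverage
#' @param tags a `tag_set`.
#' @param path output bedGraph path.
#' @param window_size aggregation window (bp).
#' @export
write_tag_bedgraph <- function(tags, path, window_size = 200L) {
  wc <- count_window_tags(tags, window_size)
  dt <- data.table::rbindlist(lapply(names(wc$counts), function(ch) {
    v <- wc$counts[[ch]]
    nz <- which(v > 0L)
    if (!length(nz)) return(NULL)
    data.table::data.table(chrom = ch, start = (nz - 1L) * wc$window_size,
                           end = pmin(nz * wc$window_size, as.integer(wc$chrom_sizes[[ch]])),
                           count = v[nz])
  }))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
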