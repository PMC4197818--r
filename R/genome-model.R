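# Gene annotation model: readers, region derivation, CGI shores,
# CGI location classes, and CpG-density promoter classification.

#' Load a gene annotation
#'
#' Reads transcript models from a refFlat (11-column, 0-based half-open)
#' or GTF (1-based closed, converted on read) file. When several
#' transcripts share a gene id, the longest transcript is kept as the
#' gene's representative (ties broken by smaller start).
#'
#' @param path annotation file.
#' @param format `"refFlat"` or `"gtf"`.
#' @param chrom_sizes optional named vector of chromosome lengths, used to
#'   clip derived regions.
#' @return a `gene_annotation` object: list with `genes` (one row per gene:
#'   `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`,
#'   `cds_end`) and `exons` (`gene_id`, `start`, `end`), both 0-based
#'   half-open.
#' @export
load_gene_annotation <- function(path, format = c("refFlat", "gtf"), chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_dd("annotation file not found: ", path)
  ann <- if (format == "refFlat") read_refflat(path) else read_gtf_genes(path)
  ann <- pick_representative(ann)
  validate_gene_annotation(ann)
  ann$chrom_sizes <- chrom_sizes
  ann
}

read_refflat <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = FALSE,
                      colClasses = list(character = c(1:4, 10, 11))),
    error = function(e) stop_dd("refFlat parse error in ", path, ": ", conditionMessage(e)))
  if (ncol(dt) != 11L) stop_dd("refFlat: expected 11 columns, got ", ncol(dt))
  data.table::setnames(dt, c("gene_id", "tx_id", "chrom", "strand", "tx_start",
                             "tx_end", "cds_start", "cds_end", "exon_count",
                             "exon_starts", "exon_ends"))
  for (i in seq_len(nrow(dt))) {
    if (!dt$strand[i] %in% c("+", "-"))
      stop_dd("refFlat line ", i, ": bad strand '", dt$strand[i], "'")
  }
  parse_csv_ints <- function(x, line) {
    v <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
    if (anyNA(v)) stop_dd("refFlat line ", line, ": malformed exon coordinate list")
    v
  }
  exons <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    es <- parse_csv_ints(dt$exon_starts[i], i)
    ee <- parse_csv_ints(dt$exon_ends[i], i)
    if (length(es) != dt$exon_count[i] || length(ee) != dt$exon_count[i])
      stop_dd("refFlat line ", i, ": exon count disagrees with exon lists")
    exons[[i]] <- data.table::data.table(gene_id = dt$gene_id[i], tx_id = dt$tx_id[i],
                                         start = es, end = ee)
  }
  genes <- dt[, .(gene_id, tx_id, chrom, strand,
                  tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
                  cds_start = as.integer(cds_start), cds_end = as.integer(cds_end))]
  structure(list(genes = genes, exons = data.table::rbindlist(exons)),
            class = "gene_annotation")
}

read_gtf_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop_dd("GTF parse error in ", path, ": ",
                                             conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id)) stop_dd("GTF: missing transcript_id attributes")
  gid <- if (!is.null(md$gene_id)) md$gene_id else md$transcript_id
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type), gene_id = gid, tx_id = md$transcript_id)
  ex <- dt[type == "exon"]
  if (nrow(ex) == 0L) stop_dd("GTF: no exon records")
  data.table::setorder(ex, tx_id, start)
  genes <- ex[, .(chrom = chrom[1L], strand = strand[1L],
                  tx_start = min(start), tx_end = max(end), gene_id = gene_id[1L]),
              by = tx_id]
  cds <- dt[type == "CDS", .(cds_start = min(start), cds_end = max(end)), by = tx_id]
  genes <- merge(genes, cds, by = "tx_id", all.x = TRUE)
  genes[is.na(cds_start), `:=`(cds_start = tx_start, cds_end = tx_start)]
  structure(list(genes = genes[, .(gene_id, tx_id, chrom, strand, tx_start, tx_end,
                                   cds_start, cds_end)],
                 exons = ex[, .(gene_id, tx_id, start, end)]),
            class = "gene_annotation")
}

# one representative transcript per gene id: longest tx, tie -> smallest start
pick_representative <- function(ann) {
  g <- data.table::copy(ann$genes)
  g[, len := tx_end - tx_start]
  data.table::setorder(g, gene_id, -len, tx_start)
  keep <- g[!duplicated(gene_id)]
  ex <- ann$exons[paste(gene_id, tx_id) %in% paste(keep$gene_id, keep$tx_id)]
  keep[, len := NULL]
  data.table::setorder(ex, gene_id, start)
  structure(list(genes = keep[order(chrom, tx_start)],
                 exons = ex[, .(gene_id, start, end)]),
            class = "gene_annotation")
}

validate_gene_annotation <- function(ann) {
  g <- ann$genes
  if (any(g$tx_start < 0) || any(g$tx_start >= g$tx_end))
    stop_dd("gene model: need 0 <= tx_start < tx_end")
  bad <- g[!(tx_start <= cds_start & cds_start <= cds_end & cds_end <= tx_end)]
  if (nrow(bad)) stop_dd("gene model: CDS outside transcript for ", bad$gene_id[1L])
  ex <- merge(ann$exons, g[, .(gene_id, tx_start, tx_end)], by = "gene_id")
  if (any(ex$start < ex$tx_start) || any(ex$end > ex$tx_end))
    stop_dd("gene model: exon outside transcript span")
  ov <- ex[, .(bad = any(start[-1L] < end[-.N]) || is.unsorted(start)), by = gene_id]
  if (any(ov$bad)) stop_dd("gene model: exons overlap or are unsorted for ",
                           ov[bad == TRUE]$gene_id[1L])
  span <- ex[, .(s = min(start), e = max(end), tx_start = tx_start[1L],
                 tx_end = tx_end[1L]), by = gene_id]
  if (any(span$s != span$tx_start) || any(span$e != span$tx_end))
    stop_dd("gene model: exons do not span the transcript")
  invisible(ann)
}

#' Write an annotation in refFlat format
#' @param ann a `gene_annotation`.
#' @param path output file.
#' @export
write_refflat <- function(ann, path) {
  exl <- ann$exons[, .(starts = paste0(paste(start, collapse = ","), ","),
                       ends = paste0(paste(end, collapse = ","), ","),
                       n = .N), by = gene_id]
  dt <- merge(ann$genes, exl, by = "gene_id")
  data.table::setorder(dt, chrom, tx_start)
  out <- dt[, .(gene_id, tx_id = if ("tx_id" %in% names(dt)) tx_id else gene_id,
                chrom, strand, tx_start, tx_end, cds_start, cds_end, n, starts, ends)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive the analysis region classes of every gene
#'
#' Regions follow the capture-seq annotation scheme: promoter = TSS +/- 1 kb
#' (strand-aware), gene-body subregions (5' UTR, exons, protein-coding
#' exons, 3' UTR, introns), and a 1-kb flank downstream of the TTS.
#' Intervals are clipped to chromosome bounds when sizes are known.
#'
#' @param ann a `gene_annotation`.
#' @param promoter_flank half-width of the promoter window (default 1000 bp).
#' @param tts_flank width of the downstream TTS flank (default 1000 bp).
#' @return a `gene_regions` object: list of data.tables (`promoters`,
#'   `tts_flanks`, `exons`, `coding_exons`, `introns`, `utr5`, `utr3`),
#'   each with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
derive_gene_regions <- function(ann, promoter_flank = 1000L, tts_flank = 1000L) {
  stopifnot(inherits(ann, "gene_annotation"))
  g <- data.table::copy(ann$genes)
  if (any(g$tx_end - g$tx_start < 1L)) stop_dd("gene shorter than 1 bp")
  minus <- g$strand == "-"
  tss <- ifelse(minus, g$tx_end, g$tx_start)
  tts <- ifelse(minus, g$tx_start, g$tx_end)
  prom <- data.table::data.table(gene_id = g$gene_id, chrom = g$chrom,
                                 start = tss - promoter_flank, end = tss + promoter_flank,
                                 strand = g$strand)
  ttsf <- data.table::data.table(gene_id = g$gene_id, chrom = g$chrom,
                                 start = ifelse(minus, tts - tts_flank, tts),
                                 end = ifelse(minus, tts, tts + tts_flank),
                                 strand = g$strand)
  clip <- function(dt) {
    dt[, start := pmax(start, 0L)]
    if (!is.null(ann$chrom_sizes)) {
      lim <- ann$chrom_sizes[dt$chrom]
      dt[, end := pmin(end, as.integer(lim))]
    }
    dt[end > start]
  }
  ex <- merge(ann$exons, g[, .(gene_id, chrom, strand, cds_start, cds_end)],
              by = "gene_id")
  introns <- ex[, if (.N > 1L) .(start = end[-.N], end = start[-1L],
                                 chrom = chrom[1L], strand = strand[1L]),
                by = gene_id]
  introns <- introns[end > start]
  coding <- ex[cds_end > cds_start]
  coding <- coding[, .(gene_id, chrom, strand,
                       start = pmax(start, cds_start), end = pmin(end, cds_end))]
  coding <- coding[end > start]
  # UTRs: exonic sequence outside the CDS; 5' vs 3' by strand
  utr_lo <- ex[cds_end > cds_start & start < cds_start,
               .(gene_id, chrom, strand, start, end = pmin(end, cds_start))]
  utr_hi <- ex[cds_end > cds_start & end > cds_end,
               .(gene_id, chrom, strand, start = pmax(start, cds_end), end)]
  utr5 <- rbind(utr_lo[strand == "+"], utr_hi[strand == "-"])
  utr3 <- rbind(utr_hi[strand == "+"], utr_lo[strand == "-"])
  cols <- c("gene_id", "chrom", "start", "end", "strand")
  structure(list(
    promoters = clip(prom)[, ..cols],
    tts_flanks = clip(ttsf)[, ..cols],
    exons = ex[, ..cols],
    coding_exons = coding[, ..cols],
    introns = introns[, ..cols],
    utr5 = utr5[, ..cols],
    utr3 = utr3[, ..cols]),
    class = "gene_regions")
}

#' Stack gene region classes into one interval table
#' @param regions a `gene_regions` object.
#' @return data.table with `chrom`, `start`, `end`, `gene_id`,
#'   `region_class` in {promoter, utr5, exon, coding_exon, utr3, intron,
#'   tts_flank}.
#' @export
region_class_table <- function(regions) {
  stopifnot(inherits(regions, "gene_regions"))
  map <- c(promoters = "promoter", utr5 = "utr5", exons = "exon",
           coding_exons = "coding_exon", utr3 = "utr3", introns = "intron",
           tts_flanks = "tts_flank")
  data.table::rbindlist(lapply(names(map), function(nm) {
    dt <- regions[[nm]]
    if (nrow(dt) == 0L) return(NULL)
    dt[, .(chrom, start, end, gene_id, region_class = map[[nm]])]
  }))
}

#' Compute CpG-island shores
#'
#' Each island receives up to two flanking shores of at most `shore_width`
#' bp (2 kb by default). Shores are truncated at chromosome ends and at
#' neighbouring islands, so shores and islands are disjoint genome-wide.
#'
#' @param islands data.frame/data.table with `chrom`, `start`, `end`
#'   (0-based half-open), sorted and non-overlapping per chromosome.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param shore_width maximum shore width in bp.
#' @return a `shore_set`: list with `islands` (input plus `island_id`) and
#'   `shores` (`island_id`, `side` in {upstream, downstream}, `chrom`,
#'   `start`, `end`).
#' @export
compute_cgi_shores <- function(islands, chrom_sizes, shore_width = 2000L) {
  isl <- data.table::as.data.table(islands)
  validate_intervals(isl, "CGI")
  data.table::setorder(isl, chrom, start)
  if (isl[, any(start[-1L] < end[-.N]), by = chrom][, any(V1)])
    stop_dd("overlapping CGIs are not allowed")
  isl[, island_id := paste0("cgi_", .I)]
  shores <- isl[, {
    lim <- as.numeric(chrom_sizes[[chrom[1L]]])
    up <- data.table::data.table(island_id = island_id, side = "upstream",
                                 start = pmax(start - shore_width, c(-Inf, end[-.N]), 0),
                                 end = as.numeric(start))
    dn <- data.table::data.table(island_id = island_id, side = "downstream",
                                 start = as.numeric(end),
                                 end = pmin(end + shore_width, c(start[-1L], Inf), lim))
    rbind(up, dn)
  }, by = chrom]
  shores <- shores[end > start]
  shores[, `:=`(start = as.integer(start), end = as.integer(end))]
  structure(list(islands = isl, shores = shores[, .(island_id, side, chrom, start, end)]),
            class = "shore_set")
}

#' Classify CpG islands by genomic location
#'
#' Priority classification: `promoter` if the island overlaps any
#' promoter window, else `gene_body` if it overlaps any transcript span,
#' else `intergenic`. Classes partition the island set.
#'
#' @param islands interval table (`chrom`, `start`, `end`).
#' @param ann a `gene_annotation`.
#' @param promoter_flank promoter half-width (bp).
#' @return character vector of classes, one per island row.
#' @export
classify_cgi_location <- function(islands, ann, promoter_flank = 1000L) {
  isl <- data.table::as.data.table(islands)
  validate_intervals(isl, "CGI")
  regions <- derive_gene_regions(ann, promoter_flank = promoter_flank)
  gi <- as_granges0(isl)
  in_prom <- IRanges::overlapsAny(gi, as_granges0(regions$promoters), ignore.strand = TRUE)
  tx <- ann$genes[, .(chrom, start = tx_start, end = tx_end)]
  in_body <- IRanges::overlapsAny(gi, as_granges0(tx), ignore.strand = TRUE)
  ifelse(in_prom, "promoter", ifelse(in_body, "gene_body", "intergenic"))
}

#' Classify a promoter sequence by CpG density
#'
#' Sliding 500-bp windows (5-bp step) are scored for GC fraction and the
#' CpG observed/expected ratio O/E = #CpG * L / (#C * #G), with ambiguous
#' bases excluded from counts and from the window length. The promoter is
#' `HCP` if any window has GC >= `gc_min` and O/E >= `oe_min`, `LCP` if no
#' window reaches O/E >= `oe_lcp`, and `ICP` otherwise.
#'
#' @param seq promoter-region sequence (character scalar or DNAString);
#'   conventionally TSS-700 to TSS+200.
#' @param window,step sliding window geometry (bp).
#' @param gc_min,oe_min HCP thresholds (GC fraction; CpG O/E).
#' @param oe_lcp O/E value below which all windows must fall for LCP.
#' @return a `promoter_cpg_class`: list with `class` ("HCP"/"ICP"/"LCP"),
#'   `best_window_gc`, `best_window_oe` (stats of the maximal-O/E window).
#' @export
classify_promoter_cpg_density <- function(seq, window = 500L, step = 5L,
                                          gc_min = 0.55, oe_min = 0.75,
                                          oe_lcp = 0.48) {
  s <- toupper(as.character(seq))
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(v)
  if (L < 2L) stop_dd("sequence too short to classify")
  if (L < window) {
    warning("sequence shorter than one window (", L, " < ", window,
            "); classifying on the full sequence")
    window <- L
  }
  isC <- v == "C"; isG <- v == "G"
  isN <- !(v %in% c("A", "C", "G", "T"))
  cpg <- isC & c(isG[-1L], FALSE)            # CpG starting at each position
  cum <- function(x) c(0, cumsum(x))
  cC <- cum(isC); cG <- cum(isG); cN <- cum(isN); cCpG <- cum(cpg)
  starts <- seq.int(1L, L - window + 1L, by = step)
  ends <- starts + window - 1L
  nC <- cC[ends + 1L] - cC[starts]
  nG <- cG[ends + 1L] - cG[starts]
  nN <- cN[ends + 1L] - cN[starts]
  # a CpG is inside the window only if both bases are: starts <= i <= end-1
  nCpG <- cCpG[ends] - cCpG[starts]
  len <- window - nN
  gc <- ifelse(len > 0, (nC + nG) / len, 0)
  oe <- ifelse(nC > 0 & nG > 0, nCpG * len / (nC * nG), 0)
  best <- order(-oe, -gc)[1L]
  cls <- if (any(gc >= gc_min & oe >= oe_min)) "HCP"
         else if (all(oe < oe_lcp)) "LCP"
         else "ICP"
  structure(list(class = cls, best_window_gc = gc[best], best_window_oe = oe[best]),
            class = "promoter_cpg_class")
}

#' Classify every promoter of an annotation by CpG density
#'
#' Extracts the classification region (TSS-700 to TSS+200 in transcription
#' direction by default) from genome sequence and applies
#' [classify_promoter_cpg_density()].
#'
#' @param ann a `gene_annotation`.
#' @param genome a `DNAStringSet` (named by chromosome) or FASTA path.
#' @param upstream,downstream classification region bounds relative to the
#'   TSS (bp).
#' @return data.table with `gene_id`, `class`, `best_window_gc`,
#'   `best_window_oe`.
#' @export
classify_promoters <- function(ann, genome, upstream = 700L, downstream = 200L) {
  stopifnot(inherits(ann, "gene_annotation"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  g <- ann$genes
  minus <- g$strand == "-"
  tss <- ifelse(minus, g$tx_end, g$tx_start)
  lo <- ifelse(minus, tss - downstream, tss - upstream)
  hi <- ifelse(minus, tss + upstream, tss + downstream)
  res <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    chr <- genome[[g$chrom[i]]]
    a <- max(lo[i], 0L) + 1L
    b <- min(hi[i], length(chr))
    cl <- classify_promoter_cpg_density(Biostrings::subseq(chr, a, b))
    res[[i]] <- data.table::data.table(gene_id = g$gene_id[i], class = cl$class,
                                       best_window_gc = cl$best_window_gc,
                                       best_window_oe = cl$best_window_oe)
  }
  data.table::rbindlist(res)
}
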