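# Synthetic worlds: toy genomes with annotation, CGIs and enhancers,
# capture libraries with planted fold-enrichment, and expression tables.
# Everything is seeded through named substreams so that adding one
# library never perturbs another.

#' Simulation configuration
#'
#' Geometry defaults mirror the assayed libraries: 50-bp reads from
#' ~300-bp fragments. The default toy genome (2 x 5 Mb, 300 genes,
#' 150 CGIs, 100 enhancers) is small enough for minutes-scale testing.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_genes,n_cgis,n_enhancers feature counts.
#' @param read_length,fragment_length read/fragment geometry (bp).
#' @param n_fragments fragments per simulated library (exact, before
#'   deduplication).
#' @param seed base seed; per-library streams are derived from it.
#' @param cgi_promoter_fraction,cgi_body_fraction fraction of CGIs placed
#'   over promoters / inside gene bodies (remainder intergenic).
#' @param promoter_class_probs named HCP/ICP/LCP mix of planted promoter
#'   classes.
#' @param n_linked_enhancers enhancers planted 2-8 kb upstream of a
#'   chosen gene's TSS (the truth for enhancer-gene linkage tests).
#' @param min_gene_gap minimum intergenic gap (bp).
#' @param write_fasta generate genome sequence (needed only for promoter
#'   CpG classification).
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
                       n_genes = 300L, n_cgis = 150L, n_enhancers = 100L,
                       read_length = 50L, fragment_length = 300L,
                       n_fragments = 5e5, seed = 1L,
                       cgi_promoter_fraction = 0.4, cgi_body_fraction = 0.3,
                       promoter_class_probs = c(HCP = 0.4, ICP = 0.3, LCP = 0.3),
                       n_linked_enhancers = 50L, min_gene_gap = 12000L,
                       write_fasta = TRUE) {
  stopifnot(length(chrom_sizes) >= 1L, all(chrom_sizes > 0),
            read_length <= fragment_length, is_count(seed))
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a toy genome with annotation, CGIs and enhancers
#'
#' Genes (2-10 exons) are laid out with randomized intergenic gaps; CGIs
#' are planted over promoters, in gene bodies and in intergenic space;
#' enhancers are intergenic, a subset placed 2-8 kb upstream of chosen
#' genes' TSSs. Promoter sequences are constructed to realize planted
#' HCP/ICP/LCP labels. All outputs are written as plain-text files
#' (FASTA, refFlat, BED6, chrom.sizes, JSON truth sidecar) and returned
#' in memory.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if needed).
#' @return a `toy_genome` list: `annotation` (gene_annotation), `cgis`,
#'   `enhancers` (data.tables), `chrom_sizes`, `truth` (planted labels and
#'   links), `paths` (written files).
#' @export
make_toy_genome <- function(config = sim_config(), dir = tempfile("toygenome")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(substream_seed(config$seed, "genome"), {
    world <- layout_toy_world(config)
    paths <- list(
      refflat = file.path(dir, "genes.refFlat"),
      cgi_bed = file.path(dir, "cgi.bed"),
      enhancer_bed = file.path(dir, "enhancers.bed"),
      chrom_sizes = file.path(dir, "chrom.sizes"),
      truth = file.path(dir, "truth.json"))
    write_refflat(world$annotation, paths$refflat)
    write_bed6 <- function(dt, id_col, path) {
      data.table::fwrite(dt[, .(chrom, start, end, name = get(id_col),
                                score = 0L, strand = ".")],
                         path, sep = "\t", col.names = FALSE, quote = FALSE)
    }
    write_bed6(world$cgis, "cgi_id", paths$cgi_bed)
    write_bed6(world$enhancers, "enhancer_id", paths$enhancer_bed)
    write_chrom_sizes(config$chrom_sizes, paths$chrom_sizes)
    jsonlite::write_json(world$truth, paths$truth, auto_unbox = TRUE, digits = NA)
    if (config$write_fasta) {
      paths$fasta <- file.path(dir, "genome.fa")
      write_toy_sequence(world, config, paths$fasta)
    }
    world$paths <- paths
    world$chrom_sizes <- config$chrom_sizes
    structure(world, class = "toy_genome")
  })
}

layout_toy_world <- function(config) {
  cs <- config$chrom_sizes
  n_per <- pmax(1L, round(config$n_genes * cs / sum(cs)))
  n_per[length(n_per)] <- config$n_genes - sum(n_per[-length(n_per)])
  genes <- list(); exons <- list(); gaps <- list()
  gid <- 0L
  for (ci in seq_along(cs)) {
    ch <- names(cs)[ci]; n_c <- n_per[ci]
    structs <- lapply(seq_len(n_c), function(i) {
      k <- sample(2:10, 1L)
      ew <- sample(150:600, k, replace = TRUE)
      iw <- if (k > 1L) sample(400:2500, k - 1L, replace = TRUE) else integer(0)
      list(ew = ew, iw = iw, len = sum(ew) + sum(iw))
    })
    lens <- vapply(structs, `[[`, numeric(1), "len")
    margin <- 20000
    extra <- cs[[ci]] - sum(lens) - (n_c + 1L) * config$min_gene_gap - 2 * margin
    if (extra < 0) stop_dd("requested features exceed genome capacity on ", ch)
    w <- stats::runif(n_c + 1L)
    gap <- config$min_gene_gap + floor(extra * w / sum(w))
    pos <- margin
    for (i in seq_len(n_c)) {
      gid <- gid + 1L
      pos <- pos + gap[i]
      st <- sample(c("+", "-"), 1L)
      tx_start <- as.integer(pos)
      es <- tx_start + cumsum(c(0L, head(structs[[i]]$ew, -1L) + structs[[i]]$iw))
      ee <- es + structs[[i]]$ew
      tx_end <- as.integer(ee[length(ee)])
      coding <- stats::runif(1) > 0.1
      if (coding) {
        cds_start <- es[1L] + structs[[i]]$ew[1L] %/% 2L
        cds_end <- es[length(es)] + structs[[i]]$ew[length(es)] %/% 2L
      } else cds_start <- cds_end <- tx_start
      id <- sprintf("gene_%03d", gid)
      genes[[gid]] <- data.table::data.table(
        gene_id = id, tx_id = id, chrom = ch, strand = st,
        tx_start = tx_start, tx_end = tx_end,
        cds_start = as.integer(cds_start), cds_end = as.integer(cds_end))
      exons[[gid]] <- data.table::data.table(gene_id = id, tx_id = id,
                                             start = as.integer(es),
                                             end = as.integer(ee))
      gaps[[gid]] <- data.table::data.table(
        gene_id = id, chrom = ch,
        gap_start = as.integer(pos - gap[i]), gap_end = tx_start)
      pos <- tx_end
    }
  }
  g <- data.table::rbindlist(genes)
  ex <- data.table::rbindlist(exons)
  gapdt <- data.table::rbindlist(gaps)

  # planted promoter CpG classes
  probs <- config$promoter_class_probs / sum(config$promoter_class_probs)
  classes <- sample(names(probs), nrow(g), replace = TRUE, prob = probs)

  # linked enhancers: force those genes and their predecessors to "+" strand
  n_link <- min(config$n_linked_enhancers, config$n_enhancers)
  link_idx <- integer(0)
  if (n_link > 0L) {
    elig <- which(seq_len(nrow(g)) > 1 & g$chrom == data.table::shift(g$chrom))
    link_idx <- sort(sample(elig, n_link))
    g$strand[link_idx] <- "+"
    g$strand[link_idx - 1L] <- "+"
  }

  minus <- g$strand == "-"
  tss <- ifelse(minus, g$tx_end, g$tx_start)

  # CGIs: promoter (over HCP-class genes), gene body, intergenic
  n_prom <- round(config$cgi_promoter_fraction * config$n_cgis)
  n_body <- round(config$cgi_body_fraction * config$n_cgis)
  n_inter <- config$n_cgis - n_prom - n_body
  hcp_pool <- setdiff(which(classes == "HCP"), c(link_idx, link_idx - 1L))
  if (length(hcp_pool) < n_prom) {
    warning("fewer HCP promoters than requested promoter CGIs; reducing")
    n_prom <- length(hcp_pool)
  }
  prom_cgi_genes <- sort(sample(hcp_pool, n_prom))
  cgi_prom <- data.table::data.table(
    chrom = g$chrom[prom_cgi_genes],
    start = as.integer(tss[prom_cgi_genes] - sample(200:500, n_prom, TRUE)),
    end = as.integer(tss[prom_cgi_genes] + sample(200:700, n_prom, TRUE)),
    location = "promoter", gene_id = g$gene_id[prom_cgi_genes])
  body_pool <- setdiff(which(g$tx_end - g$tx_start >= 7000L), prom_cgi_genes)
  body_genes <- sort(sample(body_pool, min(n_body, length(body_pool))))
  mid <- (g$tx_start[body_genes] + g$tx_end[body_genes]) %/% 2L
  cgi_body <- data.table::data.table(
    chrom = g$chrom[body_genes],
    start = as.integer(mid - sample(150:400, length(body_genes), TRUE)),
    end = as.integer(mid + sample(150:400, length(body_genes), TRUE)),
    location = "gene_body", gene_id = g$gene_id[body_genes])
  # intergenic CGIs and enhancers each take over a distinct gene-upstream gap
  free_gaps <- setdiff(seq_len(nrow(g)), c(link_idx, 1L))
  free_gaps <- free_gaps[gapdt$gap_end[free_gaps] - gapdt$gap_start[free_gaps] >=
                           config$min_gene_gap]
  picks <- sample(free_gaps, n_inter + (config$n_enhancers - n_link))
  inter_gaps <- picks[seq_len(n_inter)]
  enh_gaps <- picks[-seq_len(n_inter)]
  centre <- (gapdt$gap_start[inter_gaps] + gapdt$gap_end[inter_gaps]) %/% 2L
  cgi_inter <- data.table::data.table(
    chrom = gapdt$chrom[inter_gaps],
    start = as.integer(centre - sample(150:500, n_inter, TRUE)),
    end = as.integer(centre + sample(150:500, n_inter, TRUE)),
    location = "intergenic", gene_id = NA_character_)
  cgis <- rbind(cgi_prom, cgi_body, cgi_inter)
  data.table::setorder(cgis, chrom, start)
  cgis[, cgi_id := sprintf("cgi_%03d", .I)]

  # enhancers: linked (upstream of chosen TSS) + unlinked (in free gaps)
  enh_link <- if (n_link > 0L) {
    d <- sample(2000:8000, n_link, replace = TRUE)
    len <- sample(1000:2500, n_link, replace = TRUE)
    data.table::data.table(chrom = g$chrom[link_idx],
                           start = as.integer(tss[link_idx] - d - len),
                           end = as.integer(tss[link_idx] - d),
                           linked_gene = g$gene_id[link_idx])
  } else NULL
  enh_free <- if (length(enh_gaps) > 0L) {
    len <- sample(1000:2500, length(enh_gaps), replace = TRUE)
    st <- gapdt$gap_start[enh_gaps] + 2000L
    data.table::data.table(chrom = gapdt$chrom[enh_gaps],
                           start = as.integer(st), end = as.integer(st + len),
                           linked_gene = NA_character_)
  } else NULL
  enh <- rbind(enh_link, enh_free)
  if (is.null(enh)) enh <- data.table::data.table(chrom = character(0),
                                                  start = integer(0),
                                                  end = integer(0),
                                                  linked_gene = character(0))
  data.table::setorder(enh, chrom, start)
  enh[, enhancer_id := sprintf("enh_%03d", seq_len(.N))]

  ann <- structure(list(genes = g, exons = ex, chrom_sizes = config$chrom_sizes),
                   class = "gene_annotation")
  validate_gene_annotation(ann)
  truth <- list(
    promoter_classes = stats::setNames(as.list(classes), g$gene_id),
    cgi_locations = stats::setNames(as.list(cgis$location), cgis$cgi_id),
    promoter_cgi_genes = cgis[location == "promoter", gene_id],
    enhancer_links = stats::setNames(as.list(enh$linked_gene), enh$enhancer_id),
    seed = config$seed)
  list(annotation = ann,
       cgis = cgis[, .(cgi_id, chrom, start, end, location, gene_id)],
       enhancers = enh[, .(enhancer_id, chrom, start, end, linked_gene)],
       truth = truth)
}

# genome sequence with planted promoter-class and CGI composition
write_toy_sequence <- function(world, config, path) {
  bases <- c("A", "C", "G", "T")
  g <- world$annotation$genes
  minus <- g$strand == "-"
  tss <- ifelse(minus, g$tx_end, g$tx_start)
  prom_lo <- ifelse(minus, tss - 200L, tss - 700L)
  classes <- unlist(world$truth$promoter_classes)[g$gene_id]
  seqs <- lapply(names(config$chrom_sizes), function(ch) {
    n <- as.integer(config$chrom_sizes[[ch]])
    v <- sample(bases, n, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
    for (j in which(world$cgis$chrom == ch)) {
      a <- world$cgis$start[j] + 1L; b <- world$cgis$end[j]
      v[a:b] <- sample(bases, b - a + 1L, replace = TRUE,
                       prob = c(0.175, 0.325, 0.325, 0.175))
    }
    for (j in which(g$chrom == ch)) {
      a <- max(prom_lo[j], 0L) + 1L; b <- min(prom_lo[j] + 900L, n)
      if (b <= a) next
      p <- switch(classes[j],
                  HCP = c(0.175, 0.325, 0.325, 0.175),
                  ICP = c(0.28, 0.22, 0.22, 0.28),
                  LCP = c(0.28, 0.22, 0.22, 0.28))
      w <- sample(bases, b - a + 1L, replace = TRUE, prob = p)
      if (classes[j] == "LCP") {   # destroy CpG dinucleotides
        cg <- which(w == "C" & c(w[-1L], "") == "G")
        if (length(cg)) w[cg + 1L] <- "T"
      }
      v[a:b] <- w
    }
    paste(v, collapse = "")
  })
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- names(config$chrom_sizes)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Describe the enrichment truth of one library
#'
#' @param mark `"5mC"` or `"5hmC"`.
#' @param condition library condition label (e.g. `"siNTC"`, `"siTET1"`).
#' @param planted_regions data.table `chrom`, `start`, `end`, `fold`
#'   (enrichment multiplier >= 0; fold 0 excludes fragments). Regions must
#'   not overlap. Fold is 1 everywhere else.
#' @param background_rate expected fragments per bp outside planted
#'   regions; when `NULL` the library total is fixed at
#'   `config$n_fragments`.
#' @return an `enrichment_truth` list.
#' @export
enrichment_truth <- function(mark, condition,
                             planted_regions = data.table::data.table(
                               chrom = character(0), start = integer(0),
                               end = integer(0), fold = numeric(0)),
                             background_rate = NULL) {
  if (is.null(planted_regions))
    planted_regions <- data.table::data.table(chrom = character(0),
                                              start = integer(0),
                                              end = integer(0), fold = numeric(0))
  pr <- data.table::as.data.table(planted_regions)
  if (nrow(pr)) {
    validate_intervals(pr, "planted region")
    if (any(pr$fold < 0)) stop_dd("fold must be >= 0")
    data.table::setorder(pr, chrom, start)
    if (pr[, any(start[-1L] < end[-.N]), by = chrom][, any(V1)])
      stop_dd("planted regions must not overlap")
  }
  structure(list(mark = mark, condition = condition, planted_regions = pr,
                 background_rate = background_rate),
            class = "enrichment_truth")
}

#' Simulate one capture library
#'
#' Fragment midpoints are drawn from an inhomogeneous Poisson process with
#' rate `background_rate * fold(position)`; each ~`fragment_length`
#' fragment emits one `read_length` read from its 5' end, with strand
#' chosen uniformly. With `config$n_fragments` set the draw is conditioned
#' on the total, so the library holds exactly that many fragments. The
#' random stream is derived from `(seed, mark, condition)`.
#'
#' @param truth an `enrichment_truth`.
#' @param config a `sim_config`.
#' @param path optional output path for a sorted BED6 file of the reads.
#' @return an `aligned_reads` data.table (sorted).
#' @export
simulate_capture_library <- function(truth, config = sim_config(), path = NULL) {
  stopifnot(inherits(truth, "enrichment_truth"), inherits(config, "sim_config"))
  if (!is.null(truth$background_rate) && truth$background_rate <= 0)
    stop_dd("background_rate must be > 0")
  cs <- config$chrom_sizes
  pr <- truth$planted_regions
  if (nrow(pr) && !all(pr$chrom %in% names(cs)))
    stop_dd("planted regions on unknown chromosomes")
  if (nrow(pr)) {
    lim <- as.numeric(cs[pr$chrom])
    if (any(pr$end > lim)) stop_dd("planted regions outside genome")
  }
  segs <- data.table::rbindlist(lapply(names(cs), function(ch) {
    p <- pr[chrom == ch]
    brk <- sort(unique(c(0, p$start, p$end, as.numeric(cs[[ch]]))))
    s <- data.table::data.table(chrom = ch, start = head(brk, -1L), end = brk[-1L],
                                fold = 1)
    if (nrow(p)) {
      idx <- findInterval(s$start, p$start)
      hit <- idx >= 1L & s$start < p$end[pmax(idx, 1L)]
      s$fold[hit] <- p$fold[idx[hit]]
    }
    s
  }))
  segs <- segs[end > start]
  w <- (segs$end - segs$start) * segs$fold
  half <- config$fragment_length %/% 2L
  seed <- substream_seed(config$seed, paste(truth$mark, truth$condition, sep = "|"))
  reads <- with_seed(seed, {
    n_seg <- if (is.null(truth$background_rate)) {
      if (sum(w) <= 0) stop_dd("all fold values are zero")
      as.vector(stats::rmultinom(1L, config$n_fragments, prob = w))
    } else {
      stats::rpois(nrow(segs), truth$background_rate * w)
    }
    mid <- unlist(lapply(which(n_seg > 0L), function(i) {
      as.integer(floor(stats::runif(n_seg[i], segs$start[i], segs$end[i])))
    }))
    ch <- rep(segs$chrom, n_seg)
    lim <- as.numeric(cs[ch])
    mid <- pmin(pmax(mid, half), as.integer(lim) - half)  # keep fragments in-bounds
    st <- sample(c("+", "-"), length(mid), replace = TRUE)
    data.table::data.table(
      chrom = ch,
      start = data.table::fifelse(st == "+", mid - half,
                                  mid + half - config$read_length),
      end = data.table::fifelse(st == "+", mid - half + config$read_length,
                                mid + half),
      strand = st)
  })
  data.table::setorder(reads, chrom, start, end, strand)
  reads <- as_aligned_reads(reads)
  if (!is.null(path)) {
    data.table::fwrite(reads[, .(chrom, start, end, name = ".", score = 0L, strand)],
                       path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
  reads
}

#' Planted regions emulating enhancer 5hmC structure
#'
#' Interior fold above background with a dip ("gutter") in the outermost
#' `edge_width` bp on both sides of each enhancer.
#'
#' @param enhancers data.table `chrom`, `start`, `end`.
#' @param interior_fold,edge_fold fold multipliers.
#' @param edge_width gutter width (bp).
#' @return planted-region data.table for [enrichment_truth()].
#' @export
enhancer_truth_regions <- function(enhancers, interior_fold = 6, edge_fold = 0.3,
                                   edge_width = 200L) {
  e <- data.table::as.data.table(enhancers)
  validate_intervals(e, "enhancer")
  if (any(e$end - e$start <= 2L * edge_width))
    stop_dd("enhancers shorter than two edge widths")
  rbind(
    e[, .(chrom, start, end = start + edge_width, fold = edge_fold)],
    e[, .(chrom, start = start + edge_width, end = end - edge_width,
          fold = interior_fold)],
    e[, .(chrom, start = end - edge_width, end, fold = edge_fold)])[order(chrom, start)]
}

#' Planted fold spikes at CGI/shore borders
#'
#' A `width`-bp spike centred on each island/shore boundary, emulating the
#' sharp border peak of 5hmC between CGIs and their shores.
#'
#' @param islands data.table `chrom`, `start`, `end`.
#' @param spike_fold fold multiplier inside the spike.
#' @param width spike width (bp).
#' @return planted-region data.table.
#' @export
cgi_border_spike_regions <- function(islands, spike_fold = 8, width = 200L) {
  isl <- data.table::as.data.table(islands)
  validate_intervals(isl, "CGI")
  h <- width %/% 2L
  out <- rbind(
    isl[, .(chrom, start = start - h, end = start + h, fold = spike_fold)],
    isl[, .(chrom, start = end - h, end = end + h, fold = spike_fold)])
  out[start >= 0][order(chrom, start)]
}

#' Simulate a per-gene expression table
#'
#' Baseline expression is drawn within disjoint log-uniform ranges so the
#' high/moderate/low tiers are exact by construction; the perturbed
#' condition multiplies log-normal noise onto every gene and an
#' additional >= 2-fold repression onto linked genes.
#'
#' @param gene_ids character vector of gene ids (or a `gene_annotation`).
#' @param repressed_genes genes repressed in the perturbed condition.
#' @param conditions two condition labels (baseline first).
#' @param tier_probs named high/moderate/low proportions.
#' @param noise_sd log2-scale noise of unlinked genes.
#' @param repression_log2fc range of planted repression magnitude (log2).
#' @param seed random seed (substream `"expression"` of it).
#' @param path optional TSV output path.
#' @return data.table `gene_id`, `tier`, one expression column per
#'   condition, `log2_fc`, `repressed`.
#' @export
simulate_expression_table <- function(gene_ids, repressed_genes = character(0),
                                      conditions = c("siNTC", "siTET"),
                                      tier_probs = c(high = 1/3, moderate = 1/3,
                                                     low = 1/3),
                                      noise_sd = 0.15,
                                      repression_log2fc = c(1, 2.5),
                                      seed = 1L, path = NULL) {
  if (inherits(gene_ids, "gene_annotation")) gene_ids <- gene_ids$genes$gene_id
  if (!all(repressed_genes %in% gene_ids))
    stop_dd("repressed_genes contains unknown gene ids")
  stopifnot(length(conditions) == 2L)
  n <- length(gene_ids)
  probs <- tier_probs / sum(tier_probs)
  counts <- floor(n * probs)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  with_seed(substream_seed(seed, "expression"), {
    tier <- sample(rep(names(counts), counts))
    lo <- c(high = 9, moderate = 5, low = 1)[tier]
    base <- 2^stats::runif(n, lo, lo + 3)
    lfc <- stats::rnorm(n, 0, noise_sd)
    rep_flag <- gene_ids %in% repressed_genes
    # planted repression is guaranteed >= 2-fold after noise
    lfc[rep_flag] <- -pmax(
      stats::runif(sum(rep_flag), repression_log2fc[1L], repression_log2fc[2L]) -
        lfc[rep_flag],
      repression_log2fc[1L])
    out <- data.table::data.table(gene_id = gene_ids, tier = tier)
    data.table::set(out, j = conditions[1L], value = base)
    data.table::set(out, j = conditions[2L], value = base * 2^lfc)
    out[, log2_fc := lfc]
    out[, repressed := rep_flag]
    if (!is.null(path)) data.table::fwrite(out, path, sep = "\t")
    out[]
  })
}
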