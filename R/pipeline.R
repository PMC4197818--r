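# End-to-end orchestration: reads + annotation -> islands, differential
# regions, change tables, profiles, enrichment reports.

#' Assemble a pipeline configuration
#'
#' @param reads nested named list: `reads[[mark]][[condition]]` = BED path
#'   of aligned reads for that library.
#' @param annotation gene annotation path.
#' @param annotation_format `"refFlat"` or `"gtf"`.
#' @param chrom_sizes chrom.sizes path.
#' @param cgi_bed,enhancer_bed optional BED paths.
#' @param fasta optional genome FASTA (enables promoter CpG classes).
#' @param expression optional expression TSV (`gene_id` + one column per
#'   condition).
#' @param baseline_condition condition used as reference in differential
#'   calls and expression fold changes.
#' @param island island-caller settings (an `island_config` or list of
#'   overrides).
#' @param profile profile settings (a `profile_spec` or list of
#'   overrides).
#' @param output_dir where `run_pipeline()` writes artifacts.
#' @param seed pipeline seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(reads, annotation, annotation_format = "refFlat",
                            chrom_sizes = NULL, cgi_bed = NULL, enhancer_bed = NULL,
                            fasta = NULL, expression = NULL,
                            baseline_condition = "siNTC",
                            island = island_config(), profile = profile_spec(),
                            output_dir = "dipdiff_out", seed = 1L) {
  if (!inherits(island, "island_config")) island <- do.call(island_config, island)
  if (!inherits(profile, "profile_spec")) profile <- do.call(profile_spec, profile)
  structure(list(reads = reads, annotation = annotation,
                 annotation_format = annotation_format,
                 chrom_sizes = chrom_sizes, cgi_bed = cgi_bed,
                 enhancer_bed = enhancer_bed, fasta = fasta,
                 expression = expression,
                 baseline_condition = baseline_condition,
                 island = island, profile = profile,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$island <- unclass(x$island)
  x$profile <- unclass(x$profile)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$reads <- lapply(x$reads, as.list)
  do.call(pipeline_config, x)
}

validate_pipeline_config <- function(config) {
  if (is.null(config$chrom_sizes)) stop_dd("config requires a chrom_sizes path")
  need <- c(unlist(config$reads), config$annotation, config$chrom_sizes,
            config$cgi_bed, config$enhancer_bed, config$fasta, config$expression)
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop_dd("missing input file(s): ", paste(missing, collapse = ", "))
  invisible(config)
}

read_bed_intervals <- function(path, id_col) {
  gr <- rtracklayer::import(path, format = "BED")
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name
  data.table::set(dt, j = id_col,
                  value = if (!is.null(nm)) as.character(nm)
                          else sprintf("%s_%d", id_col, seq_len(nrow(dt))))
  data.table::setcolorder(dt, c(id_col, "chrom", "start", "end"))
  dt[]
}

#' Run the full analysis pipeline
#'
#' For every mark, reads are deduplicated (redundancy 1), islands are
#' called per condition, and each non-baseline condition is tested
#' against the baseline for differential regions. Significant regions are
#' annotated into per-gene change calls and shore calls; max-2
#' deduplicated tags feed composite gene, CGI and enhancer profiles; the
#' expression table (when given) yields tier classes and the
#' enhancer-to-gene repression linkage for enhancers losing 5hmC.
#' Outputs are plain TSV/BED files under `config$output_dir`.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "profiles"), showWarnings = FALSE)
  dir.create(file.path(out, "enrichment"), showWarnings = FALSE)
  log_path <- file.path(out, "run_log.txt")
  logf <- function(...) cat(format(Sys.time(), "[%H:%M:%S] "), ..., "\n",
                            sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("dipdiff ", as.character(utils::packageVersion("dipdiff")))
  logf("island config: ", paste(names(config$island), unlist(config$island),
                                sep = "=", collapse = " "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_dd("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  cs <- stage("chrom_sizes", read_chrom_sizes(config$chrom_sizes))
  ann <- stage("annotation", load_gene_annotation(config$annotation,
                                                  config$annotation_format,
                                                  chrom_sizes = cs))
  regions <- derive_gene_regions(ann)
  cgis <- if (!is.null(config$cgi_bed))
    stage("cgi", read_bed_intervals(config$cgi_bed, "cgi_id"))
  enh <- if (!is.null(config$enhancer_bed))
    stage("enhancers", read_bed_intervals(config$enhancer_bed, "enhancer_id"))
  shores <- if (!is.null(cgis)) compute_cgi_shores(cgis, cs)
  if (!is.null(config$fasta)) {
    pc <- stage("promoter_classes", classify_promoters(ann, config$fasta))
    data.table::fwrite(pc, file.path(out, "promoter_cpg_classes.tsv"), sep = "\t")
  }
  gene_changes <- list(); loss_enh <- character(0)
  for (mark in names(config$reads)) {
    conds <- names(config$reads[[mark]])
    tags1 <- tags2 <- list()
    for (cond in conds) {
      reads <- stage(paste0("reads:", mark, ":", cond),
                     read_aligned_bed(config$reads[[mark]][[cond]]))
      tags1[[cond]] <- reads_to_tags(deduplicate_reads(reads, 1L), cs,
                                     config$island$fragment_size)
      tags2[[cond]] <- reads_to_tags(deduplicate_reads(reads, 2L), cs,
                                     config$island$fragment_size)
      isl <- stage(paste0("islands:", mark, ":", cond),
                   call_islands(tags1[[cond]], config$island))
      write_regions_bed(isl, file.path(out, sprintf("islands_%s_%s.bed", mark, cond)))
      logf(mark, " ", cond, ": ", tags1[[cond]]$library_size, " tags, ",
           nrow(isl), " islands")
      prof <- composite_gene_profile(tags2[[cond]], ann, config$profile)
      write_profile_tsv(prof, file.path(out, "profiles",
                                        sprintf("genes_%s_%s.tsv", mark, cond)))
      if (!is.null(cgis)) {
        write_profile_tsv(scaled_interval_profile(tags2[[cond]], cgis, config$profile),
                          file.path(out, "profiles", sprintf("cgi_%s_%s.tsv", mark, cond)))
      }
      if (!is.null(enh)) {
        write_profile_tsv(scaled_interval_profile(tags2[[cond]], enh, config$profile),
                          file.path(out, "profiles", sprintf("enhancer_%s_%s.tsv", mark, cond)))
      }
    }
    base <- config$baseline_condition
    for (cond in setdiff(conds, base)) {
      diff <- stage(paste0("differential:", mark, ":", cond),
                    call_differential_regions(tags1[[cond]], tags1[[base]],
                                              config$island))
      write_regions_bed(diff, file.path(out, sprintf("differential_%s_%s.bed",
                                                     mark, cond)))
      logf(mark, " ", cond, " vs ", base, ": ", sum(diff$significant),
           " significant differential regions")
      calls <- gene_change_calls(diff, regions, mark = mark,
                                 fdr = config$island$fdr)
      calls[, condition := cond]
      gene_changes[[paste(mark, cond)]] <- calls
      if (!is.null(shores)) {
        sc <- shore_change_calls(diff, shores, ann, fdr = config$island$fdr)
        data.table::fwrite(sc$shore_calls,
                           file.path(out, sprintf("shore_calls_%s_%s.tsv", mark, cond)),
                           sep = "\t")
        data.table::fwrite(sc$class_summary,
                           file.path(out, sprintf("shore_summary_%s_%s.tsv", mark, cond)),
                           sep = "\t")
      }
      if (mark == "5hmC" && !is.null(enh)) {
        sig_loss <- diff[significant == TRUE & direction == "hypo"]
        if (nrow(sig_loss)) {
          hit <- IRanges::overlapsAny(as_granges0(enh), as_granges0(sig_loss),
                                      ignore.strand = TRUE)
          loss_enh <- union(loss_enh, enh$enhancer_id[hit])
        }
      }
    }
  }
  if (length(gene_changes)) {
    data.table::fwrite(data.table::rbindlist(gene_changes),
                       file.path(out, "gene_change_table.tsv"), sep = "\t")
  }
  if (!is.null(config$expression)) {
    expr <- data.table::fread(config$expression)
    conds <- setdiff(names(expr), c("gene_id", "tier", "log2_fc", "repressed"))
    base <- config$baseline_condition
    pert <- setdiff(conds, base)[1L]
    classes <- classify_expression(expr, base, pert)
    data.table::fwrite(classes, file.path(out, "enrichment", "expression_classes.tsv"),
                       sep = "\t")
    if (!is.null(enh) && length(loss_enh)) {
      repressed <- classes[down == TRUE, gene_id]
      lk <- enhancer_gene_linkage(enh[enhancer_id %in% loss_enh], ann, repressed)
      data.table::fwrite(lk$links, file.path(out, "enrichment", "enhancer_links.tsv"),
                         sep = "\t")
      ov <- lk$overlap
      data.table::fwrite(data.table::data.table(
        k = ov$k, n_linked = ov$n1, n_repressed = ov$n2, N = ov$N,
        fisher_p_two_tailed = ov$fisher_p_two_tailed, ease_p = ov$ease_p,
        odds_ratio = ov$odds_ratio, direction = ov$direction,
        fraction_repression_explained = lk$fraction_repression_explained),
        file.path(out, "enrichment", "enhancer_repression_overlap.tsv"), sep = "\t")
      logf("enhancer linkage: ", ov$k, "/", ov$n1, " linked genes repressed (EASE p=",
           signif(ov$ease_p, 3), ")")
    }
  }
  logf("done")
  invisible(out)
}

#' One-command synthetic demonstration
#'
#' Builds a toy genome, simulates two marks (5mC, 5hmC) in two conditions
#' (control and TET-depleted) with planted structure -- enhancer 5hmC
#' with boundary gutters that is lost at a subset of enhancers upon
#' depletion, CGI-border 5hmC spikes, promoter-CGI shore
#' hypermethylation, and expression repression of genes adjacent to
#' enhancers that lose 5hmC -- then runs the full pipeline on it.
#'
#' @param dir output directory.
#' @param seed simulation seed.
#' @param n_fragments fragments per library.
#' @return (invisibly) list with `genome`, `config` and the pipeline
#'   output directory.
#' @export
run_demo <- function(dir = tempfile("dipdiff_demo"), seed = 1L, n_fragments = 2e5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- sim_config(chrom_sizes = c(chr1 = 2.5e6, chr2 = 2.5e6),
                   n_genes = 120L, n_cgis = 60L, n_enhancers = 40L,
                   n_linked_enhancers = 20L, n_fragments = n_fragments,
                   seed = seed)
  genome <- make_toy_genome(sc, file.path(dir, "genome"))
  enh <- genome$enhancers
  linked <- enh[!is.na(linked_gene)]
  lost <- linked[seq_len(nrow(linked)) %% 2L == 1L]       # half lose 5hmC
  prom_cgis <- genome$cgis[location == "promoter"]
  hyper_cgis <- prom_cgis[seq_len(nrow(prom_cgis)) %% 3L == 1L]  # ~1/3 hyper shores
  sh <- compute_cgi_shores(hyper_cgis[, .(chrom, start, end)], sc$chrom_sizes)
  shore_regions <- sh$shores[, .(chrom, start, end, fold = 6)]
  truth_5hmc <- function(cond, enhancers_on) rbind(
    enhancer_truth_regions(enhancers_on),
    cgi_border_spike_regions(genome$cgis[, .(chrom, start, end)], spike_fold = 6))
  libs <- list(
    `5hmC` = list(
      siNTC = enrichment_truth("5hmC", "siNTC", truth_5hmc("siNTC", enh)),
      siTET = enrichment_truth("5hmC", "siTET",
                               truth_5hmc("siTET", enh[!enhancer_id %in% lost$enhancer_id]))),
    `5mC` = list(
      siNTC = enrichment_truth("5mC", "siNTC"),
      siTET = enrichment_truth("5mC", "siTET", shore_regions)))
  reads <- list()
  for (mark in names(libs)) {
    for (cond in names(libs[[mark]])) {
      p <- file.path(dir, sprintf("reads_%s_%s.bed", mark, cond))
      simulate_capture_library(libs[[mark]][[cond]], sc, path = p)
      reads[[mark]][[cond]] <- p
    }
  }
  expr_path <- file.path(dir, "expression.tsv")
  simulate_expression_table(genome$annotation,
                            repressed_genes = lost$linked_gene,
                            seed = seed, path = expr_path)
  cfg <- pipeline_config(
    reads = reads, annotation = genome$paths$refflat,
    chrom_sizes = genome$paths$chrom_sizes,
    cgi_bed = genome$paths$cgi_bed, enhancer_bed = genome$paths$enhancer_bed,
    fasta = genome$paths$fasta, expression = expr_path,
    baseline_condition = "siNTC",
    output_dir = file.path(dir, "out"), seed = seed)
  write_pipeline_config(cfg, file.path(dir, "config.json"))
  run_pipeline(cfg)
  invisible(list(genome = genome, config = cfg, output_dir = cfg$output_dir))
}
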