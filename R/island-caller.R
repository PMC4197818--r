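# Poisson-background enrichment-island calling and two-sample
# differential-region calling (window/gap/E-value parameterization).

#' Island-caller configuration
#'
#' Defaults follow the published capture-seq analysis settings:
#' redundancy 1, window 200 bp, fragment 300 bp, effective genome
#' fraction 0.854, gap 600 bp, E-value 1000, FDR 0.01. The window
#' eligibility threshold (0.2) is the upstream caller's default.
#'
#' @param window_size scoring window (bp).
#' @param gap_size maximum ineligible stretch bridged inside an island
#'   (bp); must be a multiple of `window_size`.
#' @param fragment_size assumed fragment length (bp).
#' @param effective_genome_fraction mappable fraction multiplying total
#'   genome length in the background rate.
#' @param evalue tolerated expected number of background islands
#'   genome-wide at the score threshold.
#' @param fdr false discovery rate for control-corrected island calls and
#'   differential regions (Benjamini-Hochberg).
#' @param redundancy duplicate reads retained per position for island
#'   calling.
#' @param eligibility_p windows with Poisson upper-tail probability below
#'   this are eligible island members.
#' @param threshold_seed fixed seed of the Monte-Carlo background used to
#'   derive the island score threshold.
#' @param threshold_reps genome replicates simulated for the threshold.
#' @param diff_candidates candidate differential regions: islands called
#'   on the pooled library (`"pooled"`, default -- keeps the conditional
#'   test exactly calibrated under the null), the merged union of both
#'   samples' islands (`"union"`), or sample A's islands only
#'   (`"sample_a"`).
#' @return an `island_config` list.
#' @export
island_config <- function(window_size = 200L, gap_size = 600L, fragment_size = 300L,
                          effective_genome_fraction = 0.854, evalue = 1000,
                          fdr = 0.01, redundancy = 1L, eligibility_p = 0.2,
                          threshold_seed = 20130715L, threshold_reps = 25L,
                          diff_candidates = c("pooled", "union", "sample_a")) {
  if (gap_size %% window_size != 0)
    stop_dd("gap_size must be a multiple of window_size")
  if (effective_genome_fraction <= 0 || effective_genome_fraction > 1)
    stop_dd("effective_genome_fraction must be in (0, 1]")
  structure(list(window_size = as.integer(window_size),
                 gap_size = as.integer(gap_size),
                 fragment_size = as.integer(fragment_size),
                 effective_genome_fraction = effective_genome_fraction,
                 evalue = evalue, fdr = fdr, redundancy = as.integer(redundancy),
                 eligibility_p = eligibility_p,
                 threshold_seed = as.integer(threshold_seed),
                 threshold_reps = as.integer(threshold_reps),
                 diff_candidates = match.arg(diff_candidates)),
            class = "island_config")
}

# background rate per window
window_lambda <- function(library_size, genome_length, config) {
  config$window_size * library_size /
    (config$effective_genome_fraction * genome_length)
}

#' Score genome windows against the Poisson background
#'
#' The background rate is `lambda = window_size * library_size /
#' (effective_genome_fraction * genome_length)`. Each window's p is the
#' Poisson upper tail `P(X >= count)`; windows with `p < eligibility_p`
#' are eligible and score `-ln p`, others score 0.
#'
#' @param wc a `window_counts`.
#' @param config an `island_config`.
#' @param lambda optional background-rate override (mainly for tests).
#' @return data.table: `chrom`, `start`, `end`, `count`, `p`, `eligible`,
#'   `score`, with the rate in attribute `lambda`.
#' @export
score_windows <- function(wc, config = island_config(), lambda = NULL) {
  stopifnot(inherits(wc, "window_counts"))
  if (wc$window_size != config$window_size)
    stop_dd("window_counts window_size disagrees with config")
  if (is.null(lambda)) {
    if (wc$library_size <= 0) stop_dd("empty library: cannot score windows")
    lambda <- window_lambda(wc$library_size, sum(wc$chrom_sizes), config)
  }
  dt <- data.table::rbindlist(lapply(names(wc$counts), function(ch) {
    v <- wc$counts[[ch]]
    data.table::data.table(chrom = ch,
                           start = (seq_along(v) - 1L) * wc$window_size,
                           end = seq_along(v) * wc$window_size,
                           count = v)
  }))
  dt[, p := stats::ppois(count - 1L, lambda, lower.tail = FALSE)]
  dt[, eligible := p < config$eligibility_p]
  dt[, score := data.table::fifelse(eligible, -log(p), 0)]
  data.table::setattr(dt, "lambda", lambda)
  dt[]
}

# core linking on one chromosome's window vectors
link_runs <- function(elig_idx, gap_windows) {
  if (length(elig_idx) == 0L) return(integer(0))
  cumsum(c(1L, diff(elig_idx) > gap_windows + 1L))
}

#' Merge eligible windows into islands
#'
#' Maximal runs of eligible windows in which consecutive members are
#' separated by at most `gap_size` bp of ineligible territory become one
#' island spanning first to last member window; the island score is the
#' sum of member window scores, and `tag_count` counts tags over the full
#' island span (internal gaps included).
#'
#' @param scored output of [score_windows()].
#' @param config an `island_config`.
#' @return data.table: `chrom`, `start`, `end`, `score`, `tag_count`,
#'   `n_windows` (eligible members).
#' @export
link_islands <- function(scored, config = island_config()) {
  gapw <- config$gap_size %/% config$window_size
  out <- scored[, {
    csum <- c(0, cumsum(count))
    e <- which(eligible)
    if (length(e) == 0L) {
      data.table::data.table(start = integer(0), end = integer(0),
                             score = numeric(0), tag_count = integer(0),
                             n_windows = integer(0))
    } else {
      grp <- link_runs(e, gapw)
      data.table::data.table(
        start = start[e][!duplicated(grp)],
        end = end[e][rev(!duplicated(rev(grp)))],
        score = as.numeric(tapply(score[e], grp, sum)),
        tag_count = as.integer(
          csum[end[e][rev(!duplicated(rev(grp)))] / config$window_size + 1L] -
          csum[start[e][!duplicated(grp)] / config$window_size + 1L]),
        n_windows = as.integer(tabulate(grp)))
    }
  }, by = chrom]
  out[]
}

#' Monte-Carlo island score threshold for a target E-value
#'
#' Simulates replicates of the effective genome as i.i.d. Poisson(lambda)
#' windows, forms background islands, and returns the smallest score `s`
#' such that the expected number of background islands with score >= `s`
#' genome-wide is at most `evalue`. The simulation uses a fixed private
#' seed so the threshold is deterministic for a given configuration.
#'
#' @param lambda background rate per window.
#' @param config an `island_config`.
#' @param genome_length total genome length (bp).
#' @param n_reps genome replicates (default from config).
#' @return score threshold (0 when the E-value is never exceeded).
#' @export
island_score_threshold <- function(lambda, config = island_config(), genome_length,
                                   n_reps = config$threshold_reps) {
  if (lambda <= 0) stop_dd("lambda must be > 0")
  n_windows <- max(1L, as.integer(round(
    config$effective_genome_fraction * genome_length / config$window_size)))
  if (n_reps < 2L) stop_dd("threshold simulation needs >= 2 replicates")
  gapw <- config$gap_size %/% config$window_size
  pool <- with_seed(config$threshold_seed, {
    unlist(lapply(seq_len(n_reps), function(r) {
      cnt <- stats::rpois(n_windows, lambda)
      p <- stats::ppois(cnt - 1L, lambda, lower.tail = FALSE)
      e <- which(p < config$eligibility_p)
      if (length(e) == 0L) return(numeric(0))
      sc <- -log(p[e])
      as.numeric(tapply(sc, link_runs(e, gapw), sum))
    }))
  })
  k_max <- floor(config$evalue * n_reps)
  if (length(pool) <= k_max) return(0)
  vals <- sort(unique(pool))
  mult <- tabulate(match(pool, vals), nbins = length(vals))
  n_ge <- rev(cumsum(rev(mult)))                 # count(pool >= v), tie-safe
  ok <- vals[n_ge <= k_max]
  if (length(ok)) min(ok) else max(pool) * (1 + 1e-9)
}

#' Call enrichment islands in one library
#'
#' Tags are counted in fixed windows, windows are scored against the
#' Poisson background, eligible windows are linked across gaps, and
#' islands below the E-value-derived score threshold are dropped. With a
#' control library, each island must additionally beat the (depth-scaled)
#' control count under a Poisson test at the configured FDR
#' (Benjamini-Hochberg).
#'
#' @param tags a `tag_set` deduplicated at redundancy 1.
#' @param config an `island_config`.
#' @param control_tags optional control/input `tag_set`.
#' @return data.table of islands: `chrom`, `start`, `end`, `score`,
#'   `tag_count`, `n_windows` (+ `control_count`, `p_vs_control`,
#'   `q_vs_control` when a control is given). Attribute `lambda` holds the
#'   background rate, `score_threshold` the E-value threshold.
#' @export
call_islands <- function(tags, config = island_config(), control_tags = NULL) {
  stopifnot(inherits(tags, "tag_set"))
  dm <- tags$dedup_max
  if (!is.null(dm) && dm != config$redundancy)
    warning("tag_set was deduplicated at max=", dm,
            " but config$redundancy is ", config$redundancy)
  wc <- count_window_tags(tags, config$window_size)
  scored <- score_windows(wc, config)
  lambda <- attr(scored, "lambda")
  isl <- link_islands(scored, config)
  thr <- island_score_threshold(lambda, config, sum(tags$chrom_sizes))
  isl <- isl[score >= thr]
  if (!is.null(control_tags) && nrow(isl) > 0L) {
    stopifnot(inherits(control_tags, "tag_set"))
    ctrl <- count_in_intervals(control_tags, isl$chrom, isl$start, isl$end)
    scale <- tags$library_size / control_tags$library_size
    lam_win <- lambda * (isl$end - isl$start) / config$window_size
    lam_ctrl <- pmax(ctrl * scale, lam_win)
    isl[, control_count := ctrl]
    isl[, p_vs_control := stats::ppois(tag_count - 1L, lam_ctrl, lower.tail = FALSE)]
    isl[, q_vs_control := stats::p.adjust(p_vs_control, "BH")]
    isl <- isl[q_vs_control < config$fdr]
  }
  data.table::setattr(isl, "lambda", lambda)
  data.table::setattr(isl, "score_threshold", thr)
  isl[]
}

#' Call differential regions between two libraries
#'
#' Candidate regions are, by default, islands called on the pooled
#' (A + B) library. Because island selection then depends only on the
#' pooled count, the conditional split of each candidate's tags between
#' the samples remains exactly binomial under the null, so the test is
#' calibrated; per-sample island unions (`config$diff_candidates =
#' "union"` or `"sample_a"`) are available but are anti-conservative,
#' since islands select high counts in the very sample being tested.
#' Each candidate is tested with an exact conditional binomial test of
#' `count_a` among `count_a + count_b` at success probability
#' `N_a / (N_a + N_b)`; p-values are Benjamini-Hochberg adjusted across
#' candidates. Normalized fold change uses pseudocount 1 on both counts
#' (reporting only, never in the test).
#'
#' @param tags_a,tags_b `tag_set`s (redundancy-1 deduplicated); direction
#'   `hyper` means enriched in `tags_a` relative to `tags_b`.
#' @param config an `island_config`.
#' @return a `differential_regions` data.table: `chrom`, `start`, `end`,
#'   `count_a`, `count_b`, `norm_fc`, `log2_fc`, `p_value`, `q_value`,
#'   `direction`, `significant` (q <= fdr).
#' @export
call_differential_regions <- function(tags_a, tags_b, config = island_config()) {
  stopifnot(inherits(tags_a, "tag_set"), inherits(tags_b, "tag_set"))
  if (tags_a$library_size == 0L || tags_b$library_size == 0L)
    stop_dd("cannot test differential enrichment with an empty library")
  cand <- switch(config$diff_candidates,
    pooled = call_islands(pool_tag_sets(tags_a, tags_b), config)[, .(chrom, start, end)],
    union = {
      isl_a <- call_islands(tags_a, config)
      isl_b <- call_islands(tags_b, config)
      rbind(isl_a[, .(chrom, start, end)], isl_b[, .(chrom, start, end)])
    },
    sample_a = call_islands(tags_a, config)[, .(chrom, start, end)])
  empty <- data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    count_a = integer(0), count_b = integer(0), norm_fc = numeric(0),
    log2_fc = numeric(0), p_value = numeric(0), q_value = numeric(0),
    direction = character(0), significant = logical(0))
  if (nrow(cand) == 0L) return(as_diff_regions(empty))
  merged <- GenomicRanges::reduce(as_granges0(cand))
  reg <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged))
  data.table::setorder(reg, chrom, start)
  na <- tags_a$library_size; nb <- tags_b$library_size
  reg[, count_a := count_in_intervals(tags_a, chrom, start, end)]
  reg[, count_b := count_in_intervals(tags_b, chrom, start, end)]
  pr <- na / (na + nb)
  reg[, p_value := vapply(seq_len(.N), function(i) {
    tot <- count_a[i] + count_b[i]
    if (tot == 0L) return(1)
    stats::binom.test(count_a[i], tot, pr)$p.value
  }, numeric(1))]
  reg[, norm_fc := ((count_a + 1) / na) / ((count_b + 1) / nb)]
  reg[, log2_fc := log2(norm_fc)]
  reg[, q_value := stats::p.adjust(p_value, "BH")]
  reg[, direction := data.table::fifelse(log2_fc > 0, "hyper", "hypo")]
  reg[, significant := q_value <= config$fdr]
  as_diff_regions(reg)
}

as_diff_regions <- function(dt) {
  data.table::setattr(dt, "class",
                      unique(c("differential_regions", class(dt))))
  dt[]
}

#' Write islands or differential regions as BED6+
#' @param x islands or `differential_regions` table.
#' @param path output path.
#' @export
write_regions_bed <- function(x, path) {
  dt <- data.table::as.data.table(x)
  base <- dt[, .(chrom, start, end,
                 name = sprintf("region_%d", .I),
                 score = if ("score" %in% names(dt)) round(score, 3) else 0,
                 strand = ".")]
  extra <- setdiff(names(dt), c("chrom", "start", "end", "score"))
  out <- cbind(base, dt[, ..extra])
  data.table::fwrite(out, path, sep = "\t", col.names = TRUE, quote = FALSE)
  invisible(path)
}
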