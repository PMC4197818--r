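# Gene-set overlap statistics: two-tailed Fisher with the conservative
# EASE modification, Venn tabulations, expression tiers, and
# enhancer-to-nearest-gene linkage.

#' Fisher exact overlap test with EASE modification
#'
#' For an overlap of `k` genes between sets of sizes `n1` and `n2` drawn
#' from a universe of `N`: the two-tailed Fisher p sums all hypergeometric
#' outcomes with probability at most that of the observed table; the EASE
#' p is the one-tailed enrichment p recomputed with the overlap cell
#' decremented by one (floored at zero), which is conservative by
#' construction. The odds ratio uses the Haldane 0.5 correction when any
#' cell is zero.
#'
#' @param k overlap count.
#' @param n1,n2 set sizes.
#' @param N universe size.
#' @param ease apply the EASE decrement (set `FALSE` for plain one-tailed
#'   Fisher in `ease_p`).
#' @return an `overlap_result` list: `k`, `n1`, `n2`, `N`,
#'   `fisher_p_two_tailed`, `one_tailed_p` (enrichment), `ease_p`,
#'   `odds_ratio`, `direction` ("over"/"under").
#' @export
ease_fisher <- function(k, n1, n2, N, ease = TRUE) {
  if (!all(vapply(list(k, n1, n2, N), is_count, logical(1))))
    stop_dd("k, n1, n2, N must be non-negative integers")
  if (k > min(n1, n2) || n1 > N || n2 > N || k < max(0, n1 + n2 - N))
    stop_dd("inconsistent contingency table: k=", k, " n1=", n1, " n2=", n2, " N=", N)
  support <- max(0, n1 + n2 - N):min(n1, n2)
  dens <- stats::dhyper(support, n1, N - n1, n2)
  obs <- dens[support == k]
  # two-tailed: sum of outcomes no more probable than the observed one
  fisher_p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  upper_tail <- function(kk) {
    if (kk <= support[1L]) return(1)   # whole support: exactly 1
    min(1, sum(dens[support >= kk]))
  }
  one_tailed <- upper_tail(k)
  ease_p <- if (ease) upper_tail(max(k - 1, 0)) else one_tailed
  a <- k; b <- n1 - k; c <- n2 - k; d <- N - n1 - n2 + k
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  expected <- n1 * n2 / N
  structure(list(k = k, n1 = n1, n2 = n2, N = N,
                 fisher_p_two_tailed = fisher_p,
                 one_tailed_p = one_tailed, ease_p = ease_p,
                 odds_ratio = (a * d) / (b * c),
                 direction = if (k > 0 && k >= expected) "over" else "under"),
            class = "overlap_result")
}

#' Pairwise overlap tests and Venn-region counts for named gene sets
#'
#' @param sets named list of character vectors, all subsets of `universe`.
#' @param universe character vector of all genes.
#' @param ease passed to [ease_fisher()].
#' @return list: `pairwise` (data.table of every pair with overlap and
#'   p-values) and `venn` (data.table of membership-pattern counts; for
#'   up to 3 sets these are the Venn regions).
#' @export
set_overlap_test <- function(sets, universe, ease = TRUE) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  for (nm in names(sets)) {
    if (!all(sets[[nm]] %in% universe))
      stop_dd("set '", nm, "' contains elements outside the universe")
  }
  N <- length(unique(universe))
  pairs <- utils::combn(names(sets), 2L, simplify = FALSE)
  pw <- data.table::rbindlist(lapply(pairs, function(p) {
    r <- ease_fisher(length(intersect(sets[[p[1L]]], sets[[p[2L]]])),
                     length(sets[[p[1L]]]), length(sets[[p[2L]]]), N, ease = ease)
    data.table::data.table(set_a = p[1L], set_b = p[2L], k = r$k,
                           n_a = r$n1, n_b = r$n2, N = N,
                           fisher_p_two_tailed = r$fisher_p_two_tailed,
                           ease_p = r$ease_p, odds_ratio = r$odds_ratio,
                           direction = r$direction)
  }))
  union_ids <- unique(unlist(sets))
  memb <- vapply(sets, function(s) union_ids %in% s, logical(length(union_ids)))
  if (length(union_ids) == 1L) memb <- matrix(memb, nrow = 1L,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  venn <- data.table::as.data.table(table(pattern))
  data.table::setnames(venn, c("pattern", "n"))
  list(pairwise = pw, venn = venn)
}

#' Classify genes into expression tiers
#'
#' Tiers are tertiles of the baseline-condition expression (high =
#' top third); ties are broken by stable input order, and when the gene
#' count is not divisible by three the lower tiers receive the extra
#' genes. Up/down flags use `|log2FC| >= lfc_threshold`.
#'
#' @param expr data.frame with `gene_id` and one column per condition.
#' @param baseline,perturbed condition column names (perturbed optional).
#' @param lfc_threshold differential-expression cutoff on |log2FC|
#'   (default 0.585, i.e. 1.5-fold).
#' @return data.table: `gene_id`, `tier`, and when `perturbed` is given
#'   `log2_fc`, `up`, `down`.
#' @export
classify_expression <- function(expr, baseline, perturbed = NULL,
                                lfc_threshold = 0.585) {
  dt <- data.table::as.data.table(expr)
  if (!baseline %in% names(dt)) stop_dd("missing baseline column '", baseline, "'")
  n <- nrow(dt)
  ord <- order(dt[[baseline]], seq_len(n))   # stable: ties keep input order
  n_low <- ceiling(n / 3); n_mod <- ceiling((n - n_low) / 2)
  tier <- character(n)
  tier[ord[seq_len(n_low)]] <- "low"
  tier[ord[n_low + seq_len(n_mod)]] <- "moderate"
  if (n_low + n_mod < n) tier[ord[(n_low + n_mod + 1):n]] <- "high"
  out <- data.table::data.table(gene_id = dt$gene_id, tier = tier)
  if (!is.null(perturbed)) {
    if (!perturbed %in% names(dt)) stop_dd("missing column '", perturbed, "'")
    out[, log2_fc := log2(dt[[perturbed]] / dt[[baseline]])]
    out[, up := log2_fc >= lfc_threshold]
    out[, down := log2_fc <= -lfc_threshold]
  }
  out[]
}

#' Link enhancers to their nearest gene and test repression overlap
#'
#' Each enhancer (e.g. one that loses 5hmC) is assigned to the gene whose
#' TSS is nearest (distance 0 if the TSS lies inside the enhancer; ties
#' go to the smaller transcript start) and discarded beyond
#' `max_distance`. The linked gene set is tested for over-representation
#' among `repressed_genes` with [ease_fisher()].
#'
#' @param enhancers interval table (`chrom`, `start`, `end`, optional
#'   `enhancer_id`).
#' @param ann a `gene_annotation`.
#' @param repressed_genes character vector of repressed gene ids.
#' @param universe gene universe for the overlap test (default: all
#'   annotated genes).
#' @param max_distance TSS distance limit in bp (default 20000).
#' @return list: `links` (`enhancer_id`, `gene_id`, `distance`,
#'   `repressed`), `overlap` (an `overlap_result`),
#'   `fraction_repression_explained`.
#' @export
enhancer_gene_linkage <- function(enhancers, ann, repressed_genes,
                                  universe = NULL, max_distance = 20000) {
  enh <- data.table::as.data.table(enhancers)
  validate_intervals(enh, "enhancer")
  if (!"enhancer_id" %in% names(enh)) enh[, enhancer_id := sprintf("enh_%d", .I)]
  g <- ann$genes
  universe <- universe %||% g$gene_id
  tss <- data.table::data.table(
    gene_id = g$gene_id, chrom = g$chrom,
    tss = ifelse(g$strand == "-", g$tx_end, g$tx_start),
    tx_start = g$tx_start)
  links <- enh[, {
    cand <- tss[chrom == .BY$chrom]
    if (nrow(cand) == 0L) NULL else {
      res <- lapply(seq_len(.N), function(i) {
        d <- pmax(0, pmax(start[i] - cand$tss, cand$tss - end[i] + 0L))
        d <- ifelse(cand$tss >= start[i] & cand$tss < end[i], 0, d)
        o <- order(d, cand$tx_start)[1L]
        data.table::data.table(enhancer_id = enhancer_id[i],
                               gene_id = cand$gene_id[o], distance = d[o])
      })
      data.table::rbindlist(res)
    }
  }, by = chrom][, chrom := NULL]
  links <- links[distance <= max_distance]
  links[, repressed := gene_id %in% repressed_genes]
  linked_genes <- unique(links$gene_id)
  k <- length(intersect(linked_genes, repressed_genes))
  overlap <- ease_fisher(k, length(linked_genes),
                         length(unique(repressed_genes)), length(unique(universe)))
  list(links = links[], overlap = overlap,
       fraction_repression_explained =
         if (length(repressed_genes)) k / length(unique(repressed_genes)) else 0)
}
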