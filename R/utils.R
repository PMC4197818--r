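# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_dd <- function(..., class = "dipdiff_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# Deterministic 32-bit sub-seed from a base seed and a string label.
# Used to give every simulated library its own reproducible stream so that
# adding a library never perturbs another one drawn from the same base seed.
substream_seed <- function(seed, label) {
  stopifnot(is_count(seed))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a private RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(df, strand = NULL) {
  s <- if (!is.null(strand)) strand else if ("strand" %in% names(df)) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else "*"
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end), strand = s)
}

validate_intervals <- function(df, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop_dd(what, " table must have chrom/start/end columns")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop_dd(what, " coordinates must satisfy 0 <= start < end")
  invisible(df)
}

# read a two-column chrom.sizes TSV into a named vector
#' Read a chrom.sizes file
#'
#' @param path two-column TSV of chromosome name and length.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, col.names = c("chrom", "size"))
  if (any(dt$size <= 0)) stop_dd("chrom.sizes: non-positive length")
  stats::setNames(as.numeric(dt$size), dt$chrom)
}

write_chrom_sizes <- function(chrom_sizes, path) {
  data.table::fwrite(data.table::data.table(chrom = names(chrom_sizes),
                                            size = as.integer(chrom_sizes)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
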