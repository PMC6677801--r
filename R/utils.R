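`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one base seed; each component draws
#' from its own substream so that adding a component never perturbs the draws
#' of earlier ones. The derived seed is kept below 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param component character label of the consuming component.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, component) {
  stopifnot(is.character(component), length(component) == 1L)
  v <- utf8ToInt(component)
  h <- sum(v * seq_along(v)) %% 65521L
  ((as.integer(seed) %% 1000003L) * 2011L + h) %% 2147483647L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Strict TSV reader: errors on missing required columns, warns on unknown ones.
# `prefix_ok` whitelists column-name prefixes (per-sample columns).
hv_read_tsv <- function(path, required, optional = character(),
                        prefix_ok = character(), what = "table") {
  if (!file.exists(path)) stop("cannot read ", what, ": file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " at ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  ok <- names(df) %in% c(required, optional)
  for (p in prefix_ok) ok <- ok | startsWith(names(df), p)
  if (any(!ok)) {
    warning(what, " at ", path, " has unknown column(s), ignored: ",
            paste(names(df)[!ok], collapse = ", "))
  }
  df
}

# Index (into the region table) of the region containing each 0-based point,
# NA when none. Regions are 0-based half-open and assumed non-overlapping.
hv_point_region <- function(chrom, pos, r_chrom, r_start, r_end) {
  out <- rep(NA_integer_, length(pos))
  if (!length(pos) || !length(r_start)) return(out)
  for (cc in unique(chrom)) {
    qi <- which(chrom == cc)
    si <- which(r_chrom == cc)
    if (!length(si)) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(as.integer(pos[qi]) + 1L, as.integer(pos[qi]) + 1L),
      IRanges::IRanges(as.integer(r_start[si]) + 1L, as.integer(r_end[si])),
      select = "first")
    out[qi] <- si[hit]
  }
  out
}

# TRUE per query interval when any subject interval on the same chromosome
# overlaps it. All coordinates 0-based half-open.
hv_overlaps_any <- function(chrom, start, end, s_chrom, s_start, s_end) {
  out <- logical(length(start))
  if (!length(start) || !length(s_start)) return(out)
  for (cc in unique(chrom)) {
    qi <- which(chrom == cc)
    si <- which(s_chrom == cc)
    if (!length(si)) next
    out[qi] <- IRanges::overlapsAny(
      IRanges::IRanges(as.integer(start[qi]) + 1L, as.integer(end[qi])),
      IRanges::IRanges(as.integer(s_start[si]) + 1L, as.integer(s_end[si])))
  }
  out
}

# Deterministic TSV writer shared by all module writers.
hv_write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
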