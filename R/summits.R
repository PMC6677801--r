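#' Read a MACS2-style summits BED file
#'
#' Five columns without header: chrom, start, end (start + 1), name, pileup.
#' Returns summit calls with the 0-based summit point and its pileup height.
#'
#' @param path BED path.
#' @param source_sample label recorded as the provenance of the calls.
#' @return data.frame with columns `chrom`, `summit_pos`, `pileup`,
#'   `source_sample`.
#' @export
read_summit_bed <- function(path, source_sample = basename(path)) {
  if (!file.exists(path)) stop("summit BED not found: ", path)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 5L) stop("summit BED needs >= 5 columns (chrom,start,end,name,pileup)")
  data.frame(chrom = df[[1]], summit_pos = as.integer(df[[2]]),
             pileup = as.numeric(df[[5]]), source_sample = source_sample,
             stringsAsFactors = FALSE)
}

#' Read a narrowPeak file
#'
#' Standard 10-column ENCODE narrowPeak; column 10 is the summit offset from
#' `start` (-1 when absent). Coordinates stay 0-based half-open.
#'
#' @param path narrowPeak path.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `signal`,
#'   `summit_pos` (NA when the offset is -1).
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("narrowPeak not found: ", path)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 10L) stop("narrowPeak needs 10 columns")
  out <- data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), name = df[[4]],
                    signal = as.numeric(df[[7]]),
                    summit_offset = as.integer(df[[10]]),
                    stringsAsFactors = FALSE)
  out$summit_pos <- ifelse(out$summit_offset < 0L, NA_integer_,
                           out$start + out$summit_offset)
  out
}

#' Merge summit calls into non-overlapping summit regions
#'
#' Each summit becomes a region `[summit - radius, summit + radius)` (clamped
#' at 0). Overlapping candidate regions are resolved greedily by descending
#' pileup height: the higher-pileup summit survives and any region overlapping
#' an accepted one is discarded, so the output is non-overlapping and
#' idempotent. Ties are broken by chromosome then position for determinism.
#'
#' @param summits data.frame of summit calls (`chrom`, `summit_pos`, `pileup`,
#'   optionally `source_sample`).
#' @param radius half-width of the summit region in bp (default 250, i.e.
#'   500 bp regions).
#' @return data.frame of regions: `chrom`, `start`, `end`, `summit_pos`,
#'   `pileup`, `source_sample`, sorted by chromosome and start.
#' @export
merge_summits <- function(summits, radius = 250L) {
  if (!nrow(summits)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      summit_pos = integer(), pileup = numeric(),
                      source_sample = character(), stringsAsFactors = FALSE))
  }
  if (any(summits$pileup < 0)) stop("negative pileup height in summit calls")
  if (any(summits$summit_pos < 0)) stop("negative summit position")
  if (is.null(summits$source_sample)) summits$source_sample <- NA_character_
  s <- summits[order(-summits$pileup, summits$chrom, summits$summit_pos), ]
  s$start <- pmax(0L, as.integer(s$summit_pos) - as.integer(radius))
  s$end <- as.integer(s$summit_pos) + as.integer(radius)
  keep <- logical(nrow(s))
  for (cc in unique(s$chrom)) {
    idx <- which(s$chrom == cc)
    acc_start <- integer()
    acc_end <- integer()
    for (i in idx) {
      if (!any(s$start[i] < acc_end & acc_start < s$end[i])) {
        keep[i] <- TRUE
        acc_start <- c(acc_start, s$start[i])
        acc_end <- c(acc_end, s$end[i])
      }
    }
  }
  out <- s[keep, c("chrom", "start", "end", "summit_pos", "pileup", "source_sample")]
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Keep summit regions whose summit lies inside a master peak
#'
#' @param regions summit regions from [merge_summits()].
#' @param master_peaks data.frame of intervals (`chrom`, `start`, `end`),
#'   0-based half-open.
#' @return the filtered regions.
#' @export
filter_in_master_peaks <- function(regions, master_peaks) {
  if (!nrow(regions)) return(regions)
  hit <- hv_point_region(regions$chrom, regions$summit_pos,
                         master_peaks$chrom, master_peaks$start, master_peaks$end)
  out <- regions[!is.na(hit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude summit regions overlapping blacklist intervals
#'
#' Optional guard against blacklisted or mitochondria-homologous regions,
#' supplied as a BED-like data.frame.
#'
#' @param regions summit regions.
#' @param exclude data.frame of intervals (`chrom`, `start`, `end`) or NULL.
#' @return the filtered regions.
#' @export
exclude_regions <- function(regions, exclude = NULL) {
  if (is.null(exclude) || !nrow(regions) || !nrow(exclude)) return(regions)
  hit <- hv_overlaps_any(regions$chrom, regions$start, regions$end,
                         exclude$chrom, exclude$start, exclude$end)
  out <- regions[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain master summits reproduced in at least `min_children` children
#'
#' A master summit is supported by a child when any of that child's peak
#' intervals overlaps the summit region. Supporting child ids are annotated.
#'
#' @param master master summit regions (non-overlapping).
#' @param per_child_peaks named list, child id -> data.frame of peak intervals
#'   (`chrom`, `start`, `end`).
#' @param min_children minimum number of distinct supporting children
#'   (default 3).
#' @return master regions with columns `n_support` and `supporters`
#'   (comma-separated child ids), filtered to `n_support >= min_children`.
#' @export
reproducibility_filter <- function(master, per_child_peaks, min_children = 3L) {
  if (min_children > length(per_child_peaks)) {
    stop("min_children (", min_children, ") exceeds the number of children (",
         length(per_child_peaks), ")")
  }
  if (!nrow(master)) return(cbind(master, n_support = integer(), supporters = character()))
  sup <- matrix(FALSE, nrow(master), length(per_child_peaks),
                dimnames = list(NULL, names(per_child_peaks)))
  for (ch in names(per_child_peaks)) {
    pk <- per_child_peaks[[ch]]
    if (is.null(pk) || !nrow(pk)) next
    sup[, ch] <- hv_overlaps_any(master$chrom, master$start, master$end,
                                 pk$chrom, pk$start, pk$end)
  }
  master$n_support <- rowSums(sup)
  master$supporters <- apply(sup, 1, function(v) paste(colnames(sup)[v], collapse = ","))
  out <- master[master$n_support >= min_children, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count shifted Read1 5' ends per summit region
#'
#' A read is assigned to a region when its (optionally Tn5-shifted) 5'
#' position lies in `[start, end)`. When `apply_shift` is TRUE the usual
#' transposase correction is applied first: +4 bp on the + strand, -5 bp on
#' the - strand. Reads on chromosomes absent from the master list are skipped
#' with one warning.
#'
#' @param fragments named list, child id -> data.frame of read 5' ends
#'   (`chrom`, `pos`, `strand`).
#' @param master master summit regions; row order defines the count rows.
#' @param apply_shift apply the +4/-5 Tn5 shift (default FALSE: positions are
#'   assumed already shifted).
#' @return object of class `hv_summit_counts`: list with integer `values`
#'   (summits x children, rownames `summit_id`), `regions`, `state = "raw"`.
#' @export
count_reads <- function(fragments, master, apply_shift = FALSE) {
  ids <- summit_ids(master)
  values <- matrix(0L, nrow(master), length(fragments),
                   dimnames = list(ids, names(fragments)))
  warned <- FALSE
  for (ch in names(fragments)) {
    rd <- fragments[[ch]]
    if (is.null(rd) || !nrow(rd)) next
    pos <- as.integer(rd$pos)
    if (apply_shift) {
      pos <- ifelse(rd$strand == "-", pos - 5L, pos + 4L)
    }
    unknown <- !(rd$chrom %in% master$chrom)
    if (any(unknown) && !warned) {
      warning("reads on chromosome(s) absent from the master summit list skipped: ",
              paste(unique(rd$chrom[unknown]), collapse = ", "))
      warned <- TRUE
    }
    hit <- hv_point_region(rd$chrom[!unknown], pos[!unknown],
                           master$chrom, master$start, master$end)
    tab <- table(factor(hit, levels = seq_len(nrow(master))))
    values[, ch] <- as.integer(tab)
  }
  structure(list(values = values, regions = master, state = "raw", gc = NULL),
            class = "hv_summit_counts")
}

summit_ids <- function(master) {
  if (!is.null(master$summit_id)) return(master$summit_id)
  paste0(master$chrom, ":", master$start, "-", master$end)
}

#' Normalize a summit count matrix
#'
#' Per-child depth scaling to counts-per-million within summits; when a
#' per-summit GC fraction is supplied, a per-child GC trend is additionally
#' removed from log2(CPM + 1) by subtracting a binned-median signal-vs-GC
#' curve and re-centering on the child's median. Without `gc` the returned
#' values are plain CPM.
#'
#' @param m `hv_summit_counts` with `state == "raw"`.
#' @param gc optional numeric vector of per-summit GC fractions (0-1).
#' @param n_bins number of equal-width GC bins for the median curve.
#' @return the object with normalized `values` and `state = "normalized"`.
#' @export
normalize_counts <- function(m, gc = NULL, n_bins = 10L) {
  stopifnot(inherits(m, "hv_summit_counts"))
  if (m$state != "raw") stop("counts are already normalized")
  tot <- colSums(m$values)
  if (any(tot == 0)) {
    stop("child with zero reads in summits: ",
         paste(colnames(m$values)[tot == 0], collapse = ", "))
  }
  cpm <- t(t(m$values) / tot) * 1e6
  if (is.null(gc)) {
    m$values <- cpm
  } else {
    stopifnot(length(gc) == nrow(m$values))
    y <- log2(cpm + 1)
    breaks <- seq(min(gc), max(gc), length.out = n_bins + 1L)
    bin <- cut(gc, breaks = breaks, include.lowest = TRUE)
    for (j in seq_len(ncol(y))) {
      med <- tapply(y[, j], bin, stats::median)
      trend <- med[as.integer(bin)]
      trend[is.na(trend)] <- stats::median(y[, j])
      y[, j] <- y[, j] - trend + stats::median(y[, j])
    }
    m$values <- y
    m$gc <- gc
  }
  m$state <- "normalized"
  m
}

#' Write a summit count matrix as TSV
#'
#' Columns: `summit_id`, `chrom`, `start`, `end`, then one column per child.
#'
#' @param m `hv_summit_counts`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summit_counts <- function(m, path) {
  df <- data.frame(summit_id = rownames(m$values),
                   chrom = m$regions$chrom, start = m$regions$start,
                   end = m$regions$end, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(m$values, check.names = FALSE))
  hv_write_tsv(df, path)
}
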