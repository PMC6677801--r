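#' Read a per-CpG methylation count table
#'
#' TSV with columns `chrom`, `pos` (0-based position of the cytosine),
#' `strand` (+/-), then `meth_<child>` and `unmeth_<child>` count columns,
#' one pair per child.
#'
#' @param path methylation TSV.
#' @return object of class `hv_meth`: list with `sites` (chrom, pos, strand),
#'   `meth` and `unmeth` integer matrices (CpGs x children), `mask` (NULL
#'   until [coverage_filter()] is applied).
#' @export
read_methylation <- function(path) {
  df <- hv_read_tsv(path, required = c("chrom", "pos", "strand"),
                    prefix_ok = c("meth_", "unmeth_"), what = "methylation table")
  mcols <- grep("^meth_", names(df), value = TRUE)
  ucols <- grep("^unmeth_", names(df), value = TRUE)
  kids <- sub("^meth_", "", mcols)
  if (!setequal(kids, sub("^unmeth_", "", ucols))) {
    stop("meth_/unmeth_ column pairs do not match")
  }
  meth <- as.matrix(df[, paste0("meth_", kids), drop = FALSE])
  unmeth <- as.matrix(df[, paste0("unmeth_", kids), drop = FALSE])
  colnames(meth) <- colnames(unmeth) <- kids
  if (any(meth < 0) || any(unmeth < 0)) stop("negative methylation counts")
  new_meth(df[, c("chrom", "pos", "strand")], meth, unmeth)
}

new_meth <- function(sites, meth, unmeth, mask = NULL) {
  structure(list(sites = sites, meth = meth, unmeth = unmeth, mask = mask),
            class = "hv_meth")
}

#' @export
print.hv_meth <- function(x, ...) {
  cat("hv_meth:", nrow(x$sites), "CpG records x", ncol(x$meth), "children",
      if (!is.null(x$mask)) "(coverage-filtered)" else "", "\n")
  invisible(x)
}

#' Merge plus- and minus-strand CpG records
#'
#' A CpG dinucleotide yields a + strand cytosine at `pos` and a - strand
#' cytosine at `pos + 1`; their counts are summed per child and reported at
#' the + strand position. A minus-strand record with no plus partner is kept
#' as its own CpG (at its plus-equivalent position) with a warning.
#'
#' @param meth an `hv_meth` with per-strand records.
#' @return an `hv_meth` with strand-merged records (strand set to `"*"`).
#' @export
merge_strands <- function(meth) {
  s <- meth$sites
  key_pos <- ifelse(s$strand == "-", s$pos - 1L, s$pos)
  key <- paste(s$chrom, key_pos)
  plus_keys <- key[s$strand != "-"]
  orphan <- s$strand == "-" & !(key %in% plus_keys)
  if (any(orphan)) {
    warning(sum(orphan), " minus-strand record(s) without a plus-strand partner",
            " kept as their own CpGs")
  }
  idx <- split(seq_len(nrow(s)), key)
  ord <- order(vapply(idx, function(i) s$chrom[i[1]], character(1)),
               vapply(idx, function(i) key_pos[i[1]], numeric(1)))
  idx <- idx[ord]
  m <- t(vapply(idx, function(i) colSums(meth$meth[i, , drop = FALSE]),
                numeric(ncol(meth$meth))))
  u <- t(vapply(idx, function(i) colSums(meth$unmeth[i, , drop = FALSE]),
                numeric(ncol(meth$unmeth))))
  colnames(m) <- colnames(meth$meth)
  colnames(u) <- colnames(meth$unmeth)
  sites <- data.frame(
    chrom = vapply(idx, function(i) s$chrom[i[1]], character(1)),
    pos = as.integer(vapply(idx, function(i) key_pos[i[1]], numeric(1))),
    strand = "*", stringsAsFactors = FALSE, row.names = NULL)
  new_meth(sites, m, u)
}

#' Apply the coverage filters to a CpG table
#'
#' Per child, a CpG is masked when its coverage (meth + unmeth) is below
#' `min_cov`, or lies at or above that child's `top_percentile` coverage
#' quantile (an inclusive upper cut guarding against PCR artifacts). The
#' percentile is computed on the raw coverage distribution of that child, so
#' the two rules commute.
#'
#' @param meth an `hv_meth`.
#' @param min_cov minimum reads defining methylation status (default 10).
#' @param top_percentile upper percentile cut (default 99.9).
#' @return the `hv_meth` with a logical `mask` matrix (TRUE = masked).
#' @export
coverage_filter <- function(meth, min_cov = 10L, top_percentile = 99.9) {
  cov <- meth$meth + meth$unmeth
  mask <- cov < min_cov
  for (j in seq_len(ncol(cov))) {
    cut <- stats::quantile(cov[, j], probs = top_percentile / 100, names = FALSE)
    mask[, j] <- mask[, j] | cov[, j] >= cut
  }
  meth$mask <- mask
  meth
}

#' Per-child methylation fractions (NA where masked or uncovered)
#'
#' @param meth an `hv_meth`.
#' @return numeric matrix of methylation fractions.
#' @export
meth_fractions <- function(meth) {
  cov <- meth$meth + meth$unmeth
  fr <- ifelse(cov > 0, meth$meth / cov, NA_real_)
  if (!is.null(meth$mask)) fr[meth$mask] <- NA_real_
  fr
}

#' CpGs with intermediate methylation in enough children
#'
#' Returns the CpGs at which at least `min_children` unmasked children have a
#' methylation fraction in the closed interval `[low, high]` — the signature
#' of one active and one silenced allele.
#'
#' @param meth a coverage-filtered `hv_meth`.
#' @param low,high fraction bounds (defaults 0.25 and 0.75, closed interval).
#' @param min_children minimum qualifying children (default 3).
#' @return data.frame `chrom`, `pos`, `n_intermediate` of qualifying CpGs.
#' @export
intermediate_cpgs <- function(meth, low = 0.25, high = 0.75, min_children = 3L) {
  if (low >= high) stop("low must be < high")
  fr <- meth_fractions(meth)
  inter <- !is.na(fr) & fr >= low & fr <= high
  n <- rowSums(inter)
  keep <- n >= min_children
  data.frame(chrom = meth$sites$chrom[keep], pos = meth$sites$pos[keep],
             n_intermediate = n[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Group-wise methylation means by genotype group
#'
#' Mean unmasked methylation fraction per CpG per genotype group (e.g.
#' ancestral/ancestral vs ancestral/human-specific vs
#' human-specific/human-specific carriers), plus each group's median
#' coverage; an empty or fully-masked group yields NA.
#'
#' @param meth an `hv_meth`.
#' @param genotype_groups named character vector, child id -> group label;
#'   the groups must partition the children.
#' @return data.frame with `chrom`, `pos`, then `mean_<group>` and
#'   `median_cov_<group>` columns.
#' @export
haplotype_group_means <- function(meth, genotype_groups) {
  kids <- colnames(meth$meth)
  if (!setequal(names(genotype_groups), kids)) {
    stop("genotype_groups must partition exactly the children in the table")
  }
  fr <- meth_fractions(meth)
  cov <- meth$meth + meth$unmeth
  if (!is.null(meth$mask)) cov[meth$mask] <- NA
  out <- meth$sites[, c("chrom", "pos")]
  for (g in unique(genotype_groups)) {
    members <- names(genotype_groups)[genotype_groups == g]
    out[[paste0("mean_", g)]] <-
      rowMeans(fr[, members, drop = FALSE], na.rm = TRUE)
    out[[paste0("median_cov_", g)]] <-
      apply(cov[, members, drop = FALSE], 1, stats::median, na.rm = TRUE)
  }
  for (j in seq_along(out)) out[[j]][is.nan(out[[j]])] <- NA
  out
}

#' Write methylation fractions as bedGraph (one file per child)
#'
#' @param meth an `hv_meth`.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_meth_bedgraph <- function(meth, dir) {
  fr <- meth_fractions(meth)
  paths <- character()
  for (ch in colnames(fr)) {
    ok <- !is.na(fr[, ch])
    df <- data.frame(meth$sites$chrom[ok], meth$sites$pos[ok],
                     meth$sites$pos[ok] + 1L, round(fr[ok, ch], 6))
    p <- file.path(dir, paste0("meth_", ch, ".bedGraph"))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
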