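#' Tally reads by allele at a heterozygous site
#'
#' Bases observed in a pileup at the site are filtered by base quality and
#' tallied into reference, alternate and other counts.
#'
#' @param read_bases data.frame with columns `base` and `qual` (numeric
#'   Phred), one row per read covering the site.
#' @param site list or one-row data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param min_baseq minimum base quality (default 20).
#' @param sample_id optional sample label carried through.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `n_ref`, `n_alt`,
#'   `n_other`, `sample_id`.
#' @export
count_alleles <- function(read_bases, site, min_baseq = 20, sample_id = NA_character_) {
  if (site$ref == site$alt) stop("site error: ref and alt alleles are identical")
  keep <- read_bases$qual >= min_baseq
  b <- toupper(read_bases$base[keep])
  data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
             n_ref = sum(b == toupper(site$ref)),
             n_alt = sum(b == toupper(site$alt)),
             n_other = sum(b != toupper(site$ref) & b != toupper(site$alt)),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Read a per-read base TSV for a site
#'
#' Plain-text alternative to a BAM pileup: TSV with columns `chrom`, `pos`,
#' `sample_id`, `base`, `qual`.
#'
#' @param path TSV path.
#' @return data.frame of per-read observations.
#' @export
read_site_bases <- function(path) {
  hv_read_tsv(path, required = c("chrom", "pos", "sample_id", "base", "qual"),
              what = "per-read base table")
}

#' Tally alleles from a coordinate-sorted BAM at a site
#'
#' Thin wrapper over Rsamtools::pileup; duplicate-flagged reads are honored
#' (excluded) when the flag is set upstream.
#'
#' @param bam path to an indexed, coordinate-sorted BAM.
#' @param site list with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param min_baseq minimum base quality (default 20).
#' @param sample_id optional sample label.
#' @return as [count_alleles()].
#' @export
count_alleles_bam <- function(bam, site, min_baseq = 20, sample_id = NA_character_) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required for BAM pileups; supply a per-read base TSV instead")
  }
  pos1 <- as.integer(site$pos) + 1L # pileup is 1-based
  wl <- IRanges::IRangesList(IRanges::IRanges(pos1, pos1))
  names(wl) <- site$chrom
  sp <- Rsamtools::ScanBamParam(
    which = wl, flag = Rsamtools::scanBamFlag(isDuplicate = FALSE))
  pp <- Rsamtools::PileupParam(min_base_quality = as.integer(min_baseq),
                               distinguish_strands = FALSE,
                               max_depth = 1e6L, min_nucleotide_depth = 0L)
  res <- Rsamtools::pileup(bam, scanBamParam = sp, pileupParam = pp)
  res <- res[res$pos == pos1, ]
  tally <- stats::setNames(res$count, as.character(res$nucleotide))
  n_of <- function(a) sum(tally[names(tally) == toupper(a)])
  data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
             n_ref = n_of(site$ref), n_alt = n_of(site$alt),
             n_other = sum(tally) - n_of(site$ref) - n_of(site$alt),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Exact binomial test of allelic imbalance
#'
#' Two-sided exact binomial test (minimum-likelihood method) of the
#' reference-allele read count against `expected_ratio`, the appropriate test
#' at the low read depths of a single heterozygous site.
#'
#' @param n_ref,n_alt informative read counts for the two alleles.
#' @param expected_ratio expected reference fraction under no imbalance
#'   (default 0.5).
#' @return the two-sided p-value, or NA (with a warning) when there are no
#'   informative reads.
#' @export
imbalance_test <- function(n_ref, n_alt, expected_ratio = 0.5) {
  n <- n_ref + n_alt
  if (n < 1) {
    warning("no informative reads at site; imbalance undefined")
    return(NA_real_)
  }
  stats::binom.test(n_ref, n, p = expected_ratio)$p.value
}

#' Allelic imbalance over a table of counted sites
#'
#' @param counts data.frame from [count_alleles()] rows.
#' @param expected_ratio expected reference fraction (default 0.5).
#' @return `counts` with an added `p_imbalance` column.
#' @export
imbalance_table <- function(counts, expected_ratio = 0.5) {
  counts$p_imbalance <- vapply(seq_len(nrow(counts)), function(i) {
    if (counts$n_ref[i] + counts$n_alt[i] < 1) return(NA_real_)
    imbalance_test(counts$n_ref[i], counts$n_alt[i], expected_ratio)
  }, numeric(1))
  counts
}
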