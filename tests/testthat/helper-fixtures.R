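# Shared fixtures and independent oracles for the test suite.

CHILDREN <- sprintf("CH%02d", 1:11)

# 17-member, 3-generation pedigree with an 11-child sibship
make_pedigree_file <- function(path = tempfile(fileext = ".tsv"), n_children = 11) {
  kids <- sprintf("CH%02d", seq_len(n_children))
  df <- data.frame(
    sample_id = c("GF1", "GM1", "GF2", "GM2", "FTH", "MTH", kids),
    father = c(".", ".", ".", ".", "GF1", "GF2", rep("FTH", n_children)),
    mother = c(".", ".", ".", ".", "GM1", "GM2", rep("MTH", n_children)),
    generation = c(1, 1, 1, 1, 2, 2, rep(3, n_children)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_pedigree <- function(n_children = 11) {
  load_pedigree(make_pedigree_file(n_children = n_children))
}

# transmission for one block with specified indicator vectors
make_tx <- function(p, m, block_id = "blk01", children = CHILDREN[seq_along(p)]) {
  data.frame(child_id = children, block_id = block_id,
             paternal_allele = as.integer(p), maternal_allele = as.integer(m),
             stringsAsFactors = FALSE)
}

# default informative transmission for 11 children
default_tx <- function(block_id = "blk01") {
  make_tx(p = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0),
          m = c(1, 1, 0, 0, 1, 1, 0, 0, 1, 1, 0), block_id = block_id)
}

make_cov <- function(children = CHILDREN) {
  # two extraction batches split front/back so the batch indicator is not
  # collinear with the alternating haplotype fixtures
  data.frame(child_id = children,
             batch = rep(c("b1", "b2"), c(ceiling(length(children) / 2),
                                          floor(length(children) / 2))),
             ebv_quartile = rep(c(2L, 4L, 1L, 3L, 3L, 1L, 4L, 2L, 1L, 3L, 2L),
                                length.out = length(children)),
             stringsAsFactors = FALSE)
}

default_blocks <- function() {
  data.frame(block_id = "blk01", chrom = "chr1", start = 0L, end = 1000000L,
             stringsAsFactors = FALSE)
}

# --- independent oracles ------------------------------------------------------

# greedy higher-pileup merge, written independently of merge_summits
oracle_merge <- function(summits, radius = 250) {
  s <- summits[order(-summits$pileup, summits$chrom, summits$summit_pos), ]
  out <- NULL
  for (i in seq_len(nrow(s))) {
    st <- max(0, s$summit_pos[i] - radius)
    en <- s$summit_pos[i] + radius
    clash <- FALSE
    if (!is.null(out)) {
      same <- out$chrom == s$chrom[i]
      clash <- any(same & st < out$end & out$start < en)
    }
    if (!clash) {
      out <- rbind(out, data.frame(chrom = s$chrom[i], start = st, end = en,
                                   summit_pos = s$summit_pos[i],
                                   pileup = s$pileup[i]))
    }
  }
  out[order(out$chrom, out$start), ]
}

# naive all-pairs membership count of positions in regions
oracle_count <- function(pos, chrom, regions) {
  vapply(seq_len(nrow(regions)), function(r) {
    sum(chrom == regions$chrom[r] & pos >= regions$start[r] & pos < regions$end[r])
  }, numeric(1))
}

# closed-form hypergeometric upper tail P(X >= k)
oracle_hyper_tail <- function(k, m, n, universe) {
  ks <- k:min(m, n)
  sum(choose(m, ks) * choose(universe - m, n - ks)) / choose(universe, n)
}

# minimal QTL-result stand-in for modules that consume scan output
fake_qtl <- function(ids, block, sig = TRUE) {
  structure(data.frame(trait_id = ids, block_id = block, is_significant = sig,
                       stringsAsFactors = FALSE),
            class = c("hv_qtl", "data.frame"))
}

# simple unshared-code variant record for cascade tests
make_variants <- function(sites, gt) {
  sites$variant_id <- paste0(sites$chrom, ":", sites$pos, ":", sites$ref, ":", sites$alt)
  gt <- matrix(gt, nrow = nrow(sites), byrow = TRUE,
               dimnames = list(sites$variant_id, c("FTH", "MTH", CHILDREN)))
  structure(list(sites = sites, gt = gt), class = "hv_variants")
}
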