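#' Truth configuration for the synthetic study generator
#'
#' Defines the conditions of the emulated study: an 11-child third generation
#' of a 17-member three-generation family, Mendelian block transmission,
#' negative-binomial count traits with planted haplotype effects, batch/EBV
#' covariate effects on expression traits, beta-binomial CpG methylation with
#' intermediate methylation at the planted monoallelically active summit, and
#' binomially sampled allelic reads at the planted heterozygous site.
#'
#' The negative binomial is parameterized by mean and dispersion `k` with
#' variance = mu + mu^2/k. Planted betas are on the natural-log scale of the
#' count mean.
#'
#' @param n_children number of third-generation children (default 11).
#' @param n_blocks number of haplotype blocks (default 4).
#' @param summits_per_block ATAC summits planted per block (default 6).
#' @param variants_per_block generic variants per block (default 12); the
#'   planted candidate and three stage-specific decoys are added on top in
#'   the planted block.
#' @param n_genes,n_mirna trait counts before filtering (each includes
#'   chromosome-filter / low-count / outside-block decoys).
#' @param planted named list of planted effects (`summit`, `gene`, `mirna`),
#'   each `list(block =, beta_paternal =, beta_maternal =)`; NULL gives the
#'   defaults (summit block 1 beta_p 2, gene block 1 beta_p 1.5, mirna block
#'   min(2, n_blocks) beta_p 1.5).
#' @param nb_mean named baseline count means per trait class.
#' @param nb_dispersion NB dispersion k (> 0).
#' @param batch_shift,ebv_slope covariate effects (natural-log scale) applied
#'   to gene and miRNA means.
#' @param meth_background,meth_low_background,meth_intermediate Beta(alpha,
#'   beta) parameters for highly methylated, lowly methylated, and
#'   intermediate CpGs.
#' @param meth_coverage mean per-child CpG coverage (Poisson).
#' @param allelic_depth,allele_bias read depth and active-allele fraction at
#'   the planted heterozygous site.
#' @param background_reads off-summit reads per child.
#' @param seed integer base seed recorded in every output.
#' @return a validated `hv_truth_config` list.
#' @export
truth_config <- function(n_children = 11L, n_blocks = 4L, summits_per_block = 6L,
                         variants_per_block = 12L, n_genes = 36L, n_mirna = 24L,
                         planted = NULL,
                         nb_mean = c(summit = 100, gene = 200, mirna = 100),
                         nb_dispersion = 20,
                         batch_shift = 0.2, ebv_slope = 0.05,
                         meth_background = c(45, 5),
                         meth_low_background = c(5, 45),
                         meth_intermediate = c(20, 20),
                         meth_coverage = 30, allelic_depth = 30,
                         allele_bias = 0.95, background_reads = 300L,
                         seed = 1463L) {
  if (is.null(planted)) {
    planted <- list(
      summit = list(block = 1L, beta_paternal = 2, beta_maternal = 0),
      gene = list(block = 1L, beta_paternal = 1.5, beta_maternal = 0),
      mirna = list(block = min(2L, n_blocks), beta_paternal = 1.5,
                   beta_maternal = 0))
  }
  cfg <- list(n_children = as.integer(n_children), n_blocks = as.integer(n_blocks),
              summits_per_block = as.integer(summits_per_block),
              variants_per_block = as.integer(variants_per_block),
              n_genes = as.integer(n_genes), n_mirna = as.integer(n_mirna),
              planted = planted, nb_mean = nb_mean,
              nb_dispersion = nb_dispersion, batch_shift = batch_shift,
              ebv_slope = ebv_slope, meth_background = meth_background,
              meth_low_background = meth_low_background,
              meth_intermediate = meth_intermediate,
              meth_coverage = meth_coverage, allelic_depth = allelic_depth,
              allele_bias = allele_bias,
              background_reads = as.integer(background_reads),
              seed = as.integer(seed))
  if (cfg$n_children < 3L) stop("truth config error: n_children must be >= 3")
  if (cfg$nb_dispersion <= 0) stop("truth config error: dispersion must be > 0")
  for (nm in names(cfg$planted)) {
    b <- cfg$planted[[nm]]$block
    if (!is.null(b) && (b < 1L || b > cfg$n_blocks)) {
      stop("truth config error: planted ", nm, " references nonexistent block ", b)
    }
  }
  structure(cfg, class = "hv_truth_config")
}

#' Draw one negative-binomial count trait under the inheritance model
#'
#' Counts are NB(mean, k) with log mean = log(base_mean) + beta_p * p +
#' beta_m * m + cov_offset; variance = mu + mu^2/k.
#'
#' @param p,m 0/1 paternal and maternal transmission indicators per child.
#' @param beta_paternal,beta_maternal planted effects (natural-log scale).
#' @param base_mean baseline count mean.
#' @param dispersion NB dispersion k.
#' @param cov_offset optional per-child covariate offset (natural-log scale).
#' @return integer count vector.
#' @export
simulate_nb_trait <- function(p, m, beta_paternal = 0, beta_maternal = 0,
                              base_mean = 100, dispersion = 20, cov_offset = 0) {
  mu <- exp(log(base_mean) + beta_paternal * p + beta_maternal * m + cov_offset)
  stats::rnbinom(length(p), size = dispersion, mu = mu)
}

#' Draw Gaussian null traits over a design (covariate effects, no haplotype
#' effect)
#'
#' Used for calibration studies of the joint F-test: each trait is the
#' design's covariate columns times `cov_beta` plus N(0, sigma) noise, with
#' no haplotype contribution.
#'
#' @param design an `hv_design`.
#' @param n_traits number of traits.
#' @param sigma residual standard deviation.
#' @param cov_beta coefficient applied to every covariate column.
#' @return numeric matrix, traits x children.
#' @export
simulate_null_traits <- function(design, n_traits, sigma = 1, cov_beta = 0.5) {
  X <- design$X
  base <- rep(0, nrow(X))
  for (term in design$cov_terms) base <- base + cov_beta * X[, term]
  out <- matrix(stats::rnorm(n_traits * nrow(X), sd = sigma), n_traits, nrow(X))
  out <- sweep(out, 2, base, "+")
  colnames(out) <- design$children
  rownames(out) <- sprintf("null%04d", seq_len(n_traits))
  out
}

# --- internal generator pieces ------------------------------------------------

hv_children_ids <- function(n) sprintf("CH%02d", seq_len(n))

hv_make_pedigree_df <- function(n_children) {
  data.frame(
    sample_id = c("GF1", "GM1", "GF2", "GM2", "FTH", "MTH",
                  hv_children_ids(n_children)),
    father = c(".", ".", ".", ".", "GF1", "GF2", rep("FTH", n_children)),
    mother = c(".", ".", ".", ".", "GM1", "GM2", rep("MTH", n_children)),
    generation = c(1L, 1L, 1L, 1L, 2L, 2L, rep(3L, n_children)),
    stringsAsFactors = FALSE)
}

hv_make_blocks <- function(n_blocks) {
  start <- (seq_len(n_blocks) - 1L) * 2000000L + 100000L
  data.frame(block_id = sprintf("blk%02d", seq_len(n_blocks)), chrom = "chr1",
             start = start, end = start + 900000L, stringsAsFactors = FALSE)
}

# transmission with guaranteed variation per (block, parent): an invariant
# column carries no information, so the first child's label is flipped when a
# draw comes out constant
hv_make_transmission <- function(children, blocks, seed) {
  with_seed(substream_seed(seed, "transmission"), {
    rows <- list()
    for (b in blocks$block_id) {
      p <- stats::rbinom(length(children), 1, 0.5)
      m <- stats::rbinom(length(children), 1, 0.5)
      if (length(unique(p)) == 1L) p[1] <- 1L - p[1]
      if (length(unique(m)) == 1L) m[1] <- 1L - m[1]
      rows[[b]] <- data.frame(child_id = children, block_id = b,
                              paternal_allele = p, maternal_allele = m,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

hv_make_covariates <- function(children, seed) {
  with_seed(substream_seed(seed, "covariates"), {
    data.frame(child_id = children,
               batch = rep(c("b1", "b2"), length.out = length(children)),
               ebv_quartile = sample(rep(1:4, length.out = length(children))),
               stringsAsFactors = FALSE)
  })
}

hv_cov_offset <- function(cov, children, batch_shift, ebv_slope) {
  cc <- cov[match(children, cov$child_id), ]
  batch_shift * (cc$batch == "b2") + ebv_slope * cc$ebv_quartile
}

hv_write_vcf <- function(sites, gt, path) {
  samples <- colnames(gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (i in seq_len(nrow(sites))) {
    writeLines(paste(c(sites$chrom[i], sites$pos[i] + 1L, sites$id[i],
                       sites$ref[i], sites$alt[i], ".", "PASS", ".", "GT",
                       gt[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Generate a complete synthetic study
#'
#' Writes, under `out_dir`, every input file the pipeline consumes —
#' pedigree, haplotype blocks, transmission, covariates, replicate summit
#' BEDs, master peaks, per-child peak narrowPeaks, per-child read-position
#' TSVs, gene/miRNA count and anchor TSVs, a strand-split methylation TSV, a
#' family VCF, a population MAF TSV and a per-read allelic base TSV — plus a
#' `truth.json` ground-truth ledger. Identical seeds give byte-identical
#' outputs.
#'
#' Besides the planted signals, the generator places stage-specific decoys:
#' an overlapping summit pair (merge rule), a summit outside the master
#' peaks, a summit reproduced in only two children, low-count and
#' sex-chromosome traits, and — inside the planted caSummit — a
#' haplotype-discordant variant, a wrong-parent-heterozygous variant and a
#' monomorphic variant, so that every cascade stage rejects something.
#'
#' @param cfg an `hv_truth_config`.
#' @param out_dir output directory (created).
#' @return invisibly, a list with `dir`, `files` (named paths) and `truth`
#'   (the ledger, also written as truth.json).
#' @export
simulate_study <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "hv_truth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  fp <- function(x) file.path(out_dir, x)
  files <- list()
  children <- hv_children_ids(cfg$n_children)

  ped_df <- hv_make_pedigree_df(cfg$n_children)
  files$pedigree <- hv_write_tsv(ped_df, fp("pedigree.tsv"))
  blocks <- hv_make_blocks(cfg$n_blocks)
  files$blocks <- hv_write_tsv(blocks, fp("blocks.tsv"))
  tx <- hv_make_transmission(children, blocks, seed)
  files$transmission <- hv_write_tsv(tx, fp("transmission.tsv"))
  cov <- hv_make_covariates(children, seed)
  files$covariates <- hv_write_tsv(cov, fp("covariates.tsv"))
  tx_of <- function(block_idx, col) {
    tb <- tx[tx$block_id == blocks$block_id[block_idx], ]
    tb[[col]][match(children, tb$child_id)]
  }

  # ---- summit layout ----
  real <- do.call(rbind, lapply(seq_len(cfg$n_blocks), function(b) {
    pos <- blocks$start[b] + 10000L + (seq_len(cfg$summits_per_block) - 1L) * 2000L
    data.frame(block = b, pos = pos, role = "real", stringsAsFactors = FALSE)
  }))
  d1w <- data.frame(block = 1L, pos = blocks$start[1] + 5000L, role = "merge_winner")
  d1l <- data.frame(block = 1L, pos = blocks$start[1] + 5100L, role = "merge_loser")
  d2 <- data.frame(block = min(3L, cfg$n_blocks),
                   pos = blocks$start[min(3L, cfg$n_blocks)] + 7000L,
                   role = "no_master_peak")
  d3 <- data.frame(block = min(2L, cfg$n_blocks),
                   pos = blocks$start[min(2L, cfg$n_blocks)] + 8200L,
                   role = "low_reproducibility")
  layout <- rbind(real, d1w, d1l, d2, d3)
  retained <- layout[layout$role %in% c("real", "merge_winner"), ]
  retained$summit_id <- paste0("chr1:", retained$pos - 250L, "-", retained$pos + 250L)
  planted_summit <- retained$summit_id[retained$block == cfg$planted$summit$block &
                                         retained$role == "real"][1]
  planted_pos <- retained$pos[retained$summit_id == planted_summit]

  with_seed(substream_seed(seed, "summit_pileups"), {
    base_pile <- stats::runif(nrow(layout), 40, 90)
    base_pile[layout$role == "merge_winner"] <- 10
    base_pile[layout$role == "merge_loser"] <- 5
    for (rep_i in 1:2) {
      pile <- round(base_pile + stats::runif(nrow(layout), 0, 5), 3)
      bed <- data.frame(chrom = "chr1", start = layout$pos,
                        end = layout$pos + 1L,
                        name = sprintf("summit_%03d", seq_len(nrow(layout))),
                        pileup = pile)
      f <- fp(sprintf("summits_rep%d.bed", rep_i))
      utils::write.table(bed, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      files[[paste0("summits_rep", rep_i)]] <- f
    }
  })

  # master peaks: everything except the no-master-peak decoy
  mp <- layout[layout$role != "no_master_peak", ]
  np <- data.frame(chrom = "chr1", start = mp$pos - 400L, end = mp$pos + 400L,
                   name = sprintf("peak_%03d", seq_len(nrow(mp))), score = 1000L,
                   strand = ".", signal = 50, p = -1, q = -1, summit = 400L)
  files$master_peaks <- fp("master_peaks.narrowPeak")
  utils::write.table(np, files$master_peaks, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # per-child peaks: all retained summits in every child; the
  # low-reproducibility decoy only in the first two children
  for (i in seq_along(children)) {
    keep <- layout$role %in% c("real", "merge_winner", "no_master_peak") |
      (layout$role == "low_reproducibility" & i <= 2L)
    pk <- layout[keep, ]
    df <- data.frame(chrom = "chr1", start = pk$pos - 300L, end = pk$pos + 300L,
                     name = sprintf("pk%03d", seq_len(nrow(pk))), score = 500L,
                     strand = ".", signal = 20, p = -1, q = -1, summit = 300L)
    f <- fp(sprintf("peaks_%s.narrowPeak", children[i]))
    utils::write.table(df, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files[[paste0("peaks_", children[i])]] <- f
  }

  # ---- summit counts and read positions ----
  p_sum <- tx_of(cfg$planted$summit$block, "paternal_allele")
  m_sum <- tx_of(cfg$planted$summit$block, "maternal_allele")
  counts <- with_seed(substream_seed(seed, "summit_counts"), {
    cm <- matrix(0L, nrow(retained), length(children),
                 dimnames = list(retained$summit_id, children))
    for (r in seq_len(nrow(retained))) {
      if (retained$summit_id[r] == planted_summit) {
        cm[r, ] <- simulate_nb_trait(p_sum, m_sum,
                                     cfg$planted$summit$beta_paternal,
                                     cfg$planted$summit$beta_maternal,
                                     cfg$nb_mean[["summit"]], cfg$nb_dispersion)
      } else {
        cm[r, ] <- simulate_nb_trait(rep(0, length(children)), rep(0, length(children)),
                                     0, 0, cfg$nb_mean[["summit"]], cfg$nb_dispersion)
      }
    }
    cm
  })
  with_seed(substream_seed(seed, "reads"), {
    for (j in seq_along(children)) {
      pos <- unlist(lapply(seq_len(nrow(retained)), function(r) {
        k <- counts[r, j]
        if (k == 0L) return(integer())
        as.integer(floor(stats::runif(k, retained$pos[r] - 250L, retained$pos[r] + 250L)))
      }))
      bg <- as.integer(floor(stats::runif(cfg$background_reads, 1500000, 1600000)))
      df <- data.frame(chrom = "chr1", pos = c(pos, bg),
                       strand = "+", stringsAsFactors = FALSE)
      f <- fp(sprintf("reads_%s.tsv", children[j]))
      hv_write_tsv(df, f)
      files[[paste0("reads_", children[j])]] <- f
    }
  })

  # ---- gene counts ----
  gene_ids <- sprintf("G%03d", seq_len(cfg$n_genes))
  n_special <- 6L # 2 chrX, 2 outside blocks, 2 low-count
  g_block <- rep(seq_len(cfg$n_blocks), length.out = cfg$n_genes)
  g_anchor <- data.frame(trait_id = gene_ids, chrom = "chr1",
                         start = blocks$start[g_block] + 30000L +
                           (seq_len(cfg$n_genes) - 1L) * 1500L,
                         stringsAsFactors = FALSE)
  g_anchor$end <- g_anchor$start + 1000L
  spec_idx <- seq(cfg$n_genes - n_special + 1L, cfg$n_genes)
  g_anchor$chrom[spec_idx[1:2]] <- "chrX"
  outside <- blocks$end[cfg$n_blocks] + 200000L
  g_anchor$start[spec_idx[3:4]] <- outside + c(0L, 5000L)
  g_anchor$end[spec_idx[3:4]] <- g_anchor$start[spec_idx[3:4]] + 1000L
  planted_gene <- gene_ids[g_block == cfg$planted$gene$block][1]
  cov_off <- hv_cov_offset(cov, children, cfg$batch_shift, cfg$ebv_slope)
  p_gene <- tx_of(cfg$planted$gene$block, "paternal_allele")
  m_gene <- tx_of(cfg$planted$gene$block, "maternal_allele")
  gcounts <- with_seed(substream_seed(seed, "gene_counts"), {
    cm <- matrix(0L, cfg$n_genes, length(children),
                 dimnames = list(gene_ids, children))
    bases <- exp(stats::rnorm(cfg$n_genes, 0, 0.3)) * cfg$nb_mean[["gene"]]
    bases[spec_idx[5:6]] <- 2 # low-count decoys
    for (g in seq_len(cfg$n_genes)) {
      bp <- if (gene_ids[g] == planted_gene) cfg$planted$gene$beta_paternal else 0
      bm <- if (gene_ids[g] == planted_gene) cfg$planted$gene$beta_maternal else 0
      cm[g, ] <- simulate_nb_trait(p_gene, m_gene, bp, bm, bases[g],
                                   cfg$nb_dispersion, cov_off)
    }
    cm
  })
  files$gene_counts <- hv_write_tsv(
    cbind(data.frame(trait_id = gene_ids), as.data.frame(gcounts)),
    fp("gene_counts.tsv"))
  files$gene_anchors <- hv_write_tsv(g_anchor, fp("gene_anchors.tsv"))

  # ---- miRNA counts ----
  mir_ids <- sprintf("M%03d", seq_len(cfg$n_mirna))
  mir_block <- rep(seq_len(cfg$n_blocks), length.out = cfg$n_mirna)
  mir_anchor <- data.frame(trait_id = mir_ids, chrom = "chr1",
                           start = blocks$start[mir_block] + 70000L +
                             (seq_len(cfg$n_mirna) - 1L) * 400L,
                           stringsAsFactors = FALSE)
  mir_anchor$end <- mir_anchor$start + 80L
  planted_mirna <- mir_ids[mir_block == cfg$planted$mirna$block][1]
  p_mir <- tx_of(cfg$planted$mirna$block, "paternal_allele")
  m_mir <- tx_of(cfg$planted$mirna$block, "maternal_allele")
  mcounts <- with_seed(substream_seed(seed, "mirna_counts"), {
    cm <- matrix(0L, cfg$n_mirna, length(children),
                 dimnames = list(mir_ids, children))
    bases <- exp(stats::rnorm(cfg$n_mirna, 0, 0.3)) * cfg$nb_mean[["mirna"]]
    bases[seq(cfg$n_mirna - 1L, cfg$n_mirna)] <- 0.5 # fail the 5-in-4 filter
    for (g in seq_len(cfg$n_mirna)) {
      bp <- if (mir_ids[g] == planted_mirna) cfg$planted$mirna$beta_paternal else 0
      bm <- if (mir_ids[g] == planted_mirna) cfg$planted$mirna$beta_maternal else 0
      cm[g, ] <- simulate_nb_trait(p_mir, m_mir, bp, bm, bases[g],
                                   cfg$nb_dispersion, cov_off)
    }
    cm
  })
  files$mirna_counts <- hv_write_tsv(
    cbind(data.frame(trait_id = mir_ids), as.data.frame(mcounts)),
    fp("mirna_counts.tsv"))
  files$mirna_anchors <- hv_write_tsv(mir_anchor, fp("mirna_anchors.tsv"))

  # ---- methylation (strand-split records) ----
  meth_rows <- with_seed(substream_seed(seed, "methylation"), {
    cpg_pos <- unlist(lapply(seq_len(nrow(retained)), function(r) {
      retained$pos[r] + c(-50L, 0L, 50L)
    }))
    cpg_summit <- rep(retained$summit_id, each = 3L)
    bg_pos <- blocks$start[1] + 50000L + (0:29) * 777L
    pos_all <- c(cpg_pos, bg_pos)
    owner <- c(cpg_summit, rep(NA_character_, length(bg_pos)))
    rows <- vector("list", 2L * length(pos_all))
    het <- p_sum == 1L # one active + one inactive allele at the planted summit
    for (i in seq_along(pos_all)) {
      covr <- stats::rpois(length(children), cfg$meth_coverage)
      if (!is.na(owner[i]) && owner[i] == planted_summit) {
        fr <- ifelse(het,
                     stats::rbeta(length(children), cfg$meth_intermediate[1],
                                  cfg$meth_intermediate[2]),
                     stats::rbeta(length(children), cfg$meth_background[1],
                                  cfg$meth_background[2]))
      } else if (i %% 7L == 0L) {
        fr <- stats::rbeta(length(children), cfg$meth_low_background[1],
                           cfg$meth_low_background[2])
      } else {
        fr <- stats::rbeta(length(children), cfg$meth_background[1],
                           cfg$meth_background[2])
      }
      meth <- stats::rbinom(length(children), covr, fr)
      unmeth <- covr - meth
      plus_m <- stats::rbinom(length(children), meth, 0.5)
      plus_u <- stats::rbinom(length(children), unmeth, 0.5)
      r1 <- c(chrom = "chr1", pos = pos_all[i], strand = "+",
              stats::setNames(plus_m, paste0("meth_", children)),
              stats::setNames(plus_u, paste0("unmeth_", children)))
      r2 <- c(chrom = "chr1", pos = pos_all[i] + 1L, strand = "-",
              stats::setNames(meth - plus_m, paste0("meth_", children)),
              stats::setNames(unmeth - plus_u, paste0("unmeth_", children)))
      rows[[2L * i - 1L]] <- r1
      rows[[2L * i]] <- r2
    }
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  })
  files$methylation <- hv_write_tsv(meth_rows, fp("methylation.tsv"))

  # ---- variants ----
  vrows <- with_seed(substream_seed(seed, "variants"), {
    sites <- list()
    gts <- list()
    samples <- c("FTH", "MTH", children)
    add_variant <- function(pos, ref, alt, f_hap, m_hap, child_gt, id) {
      sites[[length(sites) + 1L]] <<- data.frame(
        chrom = "chr1", pos = pos, ref = ref, alt = alt, id = id,
        stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <<- c(paste0(f_hap[1], "/", f_hap[2]),
                                    paste0(m_hap[1], "/", m_hap[2]), child_gt)
    }
    for (b in seq_len(cfg$n_blocks)) {
      p_b <- tx_of(b, "paternal_allele")
      m_b <- tx_of(b, "maternal_allele")
      for (j in seq_len(cfg$variants_per_block)) {
        pos <- blocks$start[b] + 40000L + (j - 1L) * 137L
        f_hap <- stats::rbinom(2, 1, 0.4)
        m_hap <- stats::rbinom(2, 1, 0.4)
        child_gt <- paste0(f_hap[p_b + 1L], "|", m_hap[m_b + 1L])
        add_variant(pos, "A", "G", f_hap, m_hap, child_gt,
                    sprintf("v_b%02d_%03d", b, j))
      }
    }
    # planted multifunctional variant: father het with the alternate allele on
    # his high-accessibility haplotype (hap 1), mother homozygous reference
    add_variant(planted_pos + 10L, "C", "T", c(0L, 1L), c(0L, 0L),
                paste0(p_sum, "|0"), "v_planted")
    # decoy: heterozygous in the father but discordant with his haplotypes
    disc <- stats::rbinom(length(children), 1, 0.5)
    if (all(disc == p_sum)) disc[1] <- 1L - disc[1]
    add_variant(planted_pos + 40L, "A", "G", c(0L, 1L), c(0L, 0L),
                paste0(disc, "|0"), "v_coseg_break")
    # decoy: heterozygous only in the mother (wrong parent)
    add_variant(planted_pos + 70L, "A", "G", c(0L, 0L), c(0L, 1L),
                paste0("0|", m_sum), "v_mother_het")
    # decoy: monomorphic among the children
    add_variant(planted_pos + 100L, "A", "G", c(0L, 0L), c(0L, 0L),
                rep("0|0", length(children)), "v_monomorphic")
    sites <- do.call(rbind, sites)
    gt <- do.call(rbind, gts)
    colnames(gt) <- samples
    ord <- order(sites$pos)
    list(sites = sites[ord, ], gt = gt[ord, , drop = FALSE])
  })
  files$vcf <- hv_write_vcf(vrows$sites, vrows$gt, fp("variants.vcf"))
  variant_keys <- paste0(vrows$sites$chrom, ":", vrows$sites$pos, ":",
                         vrows$sites$ref, ":", vrows$sites$alt)

  # ---- MAF table ----
  maf <- with_seed(substream_seed(seed, "maf"), {
    pops <- c("AFR", "AMR", "EAS", "EUR", "SAS")
    df <- data.frame(variant_id = variant_keys, stringsAsFactors = FALSE)
    for (p in pops) {
      v <- round(stats::runif(nrow(df), 0, 0.5), 4)
      v[vrows$sites$id == "v_planted"] <- round(stats::runif(1, 0.001, 0.04), 4)
      df[[paste0("maf_", p)]] <- v
    }
    df
  })
  files$maf <- hv_write_tsv(maf, fp("maf.tsv"))

  # ---- allelic reads at the planted heterozygous site ----
  het_child <- children[which(p_sum == 1L)[1]]
  allelic <- with_seed(substream_seed(seed, "allelic"), {
    from_active <- stats::rbinom(cfg$allelic_depth, 1, cfg$allele_bias)
    data.frame(chrom = "chr1", pos = planted_pos + 10L, sample_id = het_child,
               base = ifelse(from_active == 1L, "T", "C"),
               qual = sample(c(37L, 12L), cfg$allelic_depth, replace = TRUE,
                             prob = c(0.9, 0.1)),
               stringsAsFactors = FALSE)
  })
  files$allelic <- hv_write_tsv(allelic, fp("allelic_bases.tsv"))

  truth <- list(
    seed = seed,
    children = children,
    planted = list(
      summit = c(list(trait_id = planted_summit,
                      block_id = blocks$block_id[cfg$planted$summit$block]),
                 cfg$planted$summit),
      gene = c(list(trait_id = planted_gene,
                    block_id = blocks$block_id[cfg$planted$gene$block]),
               cfg$planted$gene),
      mirna = c(list(trait_id = planted_mirna,
                     block_id = blocks$block_id[cfg$planted$mirna$block]),
                cfg$planted$mirna)),
    planted_variant = list(
      variant_id = paste0("chr1:", planted_pos + 10L, ":C:T"),
      casummit_id = planted_summit,
      expected_flags = list(polymorphic_in_children = TRUE, in_casummit = TRUE,
                            het_in_associated_parent = TRUE, cosegregates = TRUE,
                            intermediate_methylation = TRUE, egene_overlap = TRUE),
      is_rare = TRUE),
    decoy_variants = list(
      v_coseg_break = "fails cosegregates",
      v_mother_het = "fails het_in_associated_parent",
      v_monomorphic = "fails polymorphic_in_children"),
    retained_summit_ids = retained$summit_id,
    n_master_expected = nrow(retained))
  files$truth <- fp("truth.json")
  jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(dir = out_dir, files = files, truth = truth, cfg = cfg))
}

#' Write the fixed worked-example study
#'
#' A tiny, fully deterministic dataset (1 haplotype block, 20 variants, 11
#' children, one planted multifunctional candidate) whose expected pipeline
#' outputs are hand-verifiable; `expected.json` records the planted candidate
#' and caSummit ids alongside the data.
#'
#' @param out_dir output directory.
#' @return invisibly, the [simulate_study()] result.
#' @export
worked_example <- function(out_dir) {
  cfg <- truth_config(n_blocks = 1L, summits_per_block = 4L,
                      variants_per_block = 16L, n_genes = 12L, n_mirna = 8L,
                      seed = 42L)
  res <- simulate_study(cfg, out_dir)
  expected <- list(n_candidates = 1L,
                   candidate_variant = res$truth$planted_variant$variant_id,
                   casummit_id = res$truth$planted_variant$casummit_id,
                   egene_id = res$truth$planted$gene$trait_id)
  jsonlite::write_json(expected, file.path(out_dir, "expected.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
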