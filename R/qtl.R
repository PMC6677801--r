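#' Construct a trait matrix
#'
#' Container shared by the gene, miRNA and summit scans: a traits-x-children
#' value matrix plus a genomic anchor per trait (TSS interval, miRNA locus or
#' summit region) used to assign each trait to the haplotype block it resides
#' in.
#'
#' @param values numeric matrix, traits x children, rownames = trait ids.
#' @param anchors data.frame with `trait_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param trait_class one of `"gene"`, `"mirna"`, `"summit"`.
#' @return object of class `hv_traits`.
#' @export
trait_matrix <- function(values, anchors, trait_class = c("gene", "mirna", "summit")) {
  trait_class <- match.arg(trait_class)
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  anchors <- anchors[match(rownames(values), anchors$trait_id), ]
  if (anyNA(anchors$trait_id)) stop("anchors missing for some traits")
  structure(list(values = values, anchors = anchors, trait_class = trait_class),
            class = "hv_traits")
}

#' @export
print.hv_traits <- function(x, ...) {
  cat("hv_traits (", x$trait_class, "): ", nrow(x$values), " traits x ",
      ncol(x$values), " children\n", sep = "")
  invisible(x)
}

#' Filter and transform a gene count matrix for the eGene scan
#'
#' Genes on the sex chromosomes and the EBV episome are removed, then genes
#' with a mean raw count below `min_mean` across the children; retained
#' counts become log2(CPM + 1), with the library size taken as the per-child
#' total over the chromosome-filtered genes.
#'
#' @param counts integer matrix, genes x children.
#' @param annotations data.frame `trait_id`, `chrom`, `start`, `end` covering
#'   all genes.
#' @param exclude_chroms chromosomes removed outright.
#' @param min_mean minimum mean raw count (default 10, inclusive).
#' @return `hv_traits` of class `"gene"`.
#' @export
filter_gene_counts <- function(counts, annotations,
                               exclude_chroms = c("chrX", "chrY", "chrEBV", "EBV"),
                               min_mean = 10) {
  anno <- annotations[match(rownames(counts), annotations$trait_id), ]
  if (anyNA(anno$trait_id)) stop("annotations must cover all genes")
  keep_chr <- !(anno$chrom %in% exclude_chroms)
  counts <- counts[keep_chr, , drop = FALSE]
  anno <- anno[keep_chr, , drop = FALSE]
  lib <- colSums(counts)
  keep <- rowMeans(counts) >= min_mean
  if (!any(keep)) {
    stop("no genes pass the mean-count filter; review min_mean (", min_mean, ")")
  }
  counts <- counts[keep, , drop = FALSE]
  vals <- log2(t(t(counts) / lib) * 1e6 + 1)
  trait_matrix(vals, anno[keep, , drop = FALSE], "gene")
}

#' Filter and TMM-normalize a miRNA count matrix for the e-miRNA scan
#'
#' miRNAs with at least `min_count` raw counts in at least `min_children`
#' children are retained, scaled by trimmed-mean-of-M-values (TMM) library
#' factors and returned as log2 CPM.
#'
#' @param counts integer matrix, miRNAs x children.
#' @param annotations data.frame `trait_id`, `chrom`, `start`, `end`.
#' @param min_count minimum count (default 5).
#' @param min_children minimum number of children reaching it (default 4).
#' @return `hv_traits` of class `"mirna"`; the TMM factors are attached as
#'   attribute `norm_factors`.
#' @export
filter_mirna_counts <- function(counts, annotations, min_count = 5L,
                                min_children = 4L) {
  if (ncol(counts) < 2L) stop("need at least 2 children for TMM normalization")
  keep <- rowSums(counts >= min_count) >= min_children
  counts <- counts[keep, , drop = FALSE]
  if (!nrow(counts)) stop("no miRNAs pass the count filter")
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  vals <- edgeR::cpm(dge, log = TRUE, prior.count = 0.5)
  tm <- trait_matrix(vals, annotations, "mirna")
  attr(tm, "norm_factors") <- dge$samples$norm.factors
  tm
}

#' Build a trait matrix from normalized summit counts
#'
#' @param m normalized `hv_summit_counts`.
#' @return `hv_traits` of class `"summit"`.
#' @export
summit_traits <- function(m) {
  stopifnot(inherits(m, "hv_summit_counts"))
  if (m$state == "raw") stop("normalize counts before the scan")
  anchors <- data.frame(trait_id = rownames(m$values), chrom = m$regions$chrom,
                        start = m$regions$start, end = m$regions$end,
                        stringsAsFactors = FALSE)
  # GC-corrected values are already on the log2 scale; plain CPM is logged here
  vals <- if (is.null(m$gc)) log2(m$values + 1) else m$values
  trait_matrix(vals, anchors, "summit")
}

#' Fit the haplotype-inheritance regression for one trait
#'
#' Ordinary least squares of the trait on the block design
#' (intercept + paternal indicator + maternal indicator + covariates). The
#' joint p-value is the F-test of all retained haplotype terms against the
#' nested covariate-only model; marginal p-values are the usual t-tests. A
#' perfectly constant trait is reported with zero haplotype effects and
#' `p_joint = 1` by convention.
#'
#' @param trait_values numeric vector, named by child id or aligned to
#'   `design$children`.
#' @param design an `hv_design` from [build_design()].
#' @return object of class `hv_qtlfit`: `mu`, `beta_paternal`,
#'   `beta_maternal`, `se_paternal`, `se_maternal`, `p_paternal`,
#'   `p_maternal`, `p_joint`, `n_used`, `dropped_terms`.
#' @export
fit_trait <- function(trait_values, design) {
  stopifnot(inherits(design, "hv_design"))
  X <- design$X
  if (!is.null(names(trait_values))) {
    trait_values <- trait_values[design$children]
  }
  y <- as.numeric(trait_values)
  if (anyNA(y)) stop("missing trait values for design children")
  n <- nrow(X)
  if (n < ncol(X) + 1L) stop("insufficient sample: n must exceed the number of terms")
  out <- list(mu = NA_real_,
              beta_paternal = NA_real_, beta_maternal = NA_real_,
              se_paternal = NA_real_, se_maternal = NA_real_,
              p_paternal = NA_real_, p_maternal = NA_real_,
              p_joint = NA_real_, n_used = n,
              dropped_terms = design$dropped_terms)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    out$flagged <- "rank_deficient"
    class(out) <- "hv_qtlfit"
    return(out)
  }
  rss1 <- sum(fit$residuals^2)
  df2 <- n - ncol(X)
  coefs <- fit$coefficients
  XtXinv <- chol2inv(qr.R(fit$qr))
  sigma2 <- rss1 / df2
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  names(se) <- colnames(X)
  tt <- coefs / se
  pmarg <- 2 * stats::pt(-abs(tt), df2)
  out$mu <- unname(coefs["mu"])
  for (term in c("paternal", "maternal")) {
    if (term %in% colnames(X)) {
      out[[paste0("beta_", term)]] <- unname(coefs[term])
      out[[paste0("se_", term)]] <- unname(se[term])
      out[[paste0("p_", term)]] <- unname(pmarg[term])
    }
  }
  if (!design$uninformative) {
    X0 <- X[, c("mu", design$cov_terms), drop = FALSE]
    rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
    q <- length(design$hap_terms)
    if (rss1 <= .Machine$double.eps * max(1, sum(y^2))) {
      # reduced model already fits perfectly (e.g. constant trait) -> no signal
      out$p_joint <- if (rss0 - rss1 <= .Machine$double.eps * max(1, sum(y^2))) 1 else 0
      if (out$p_joint == 1) {
        for (term in design$hap_terms) {
          out[[paste0("beta_", term)]] <- 0
          out[[paste0("p_", term)]] <- 1
        }
      }
    } else {
      f <- ((rss0 - rss1) / q) / (rss1 / df2)
      out$p_joint <- stats::pf(f, q, df2, lower.tail = FALSE)
    }
  }
  class(out) <- "hv_qtlfit"
  out
}

#' Scan all traits for haplotype-inheritance QTLs
#'
#' Each trait is tested only against the haplotype block its anchor midpoint
#' resides in; traits outside any block are skipped and counted. One joint-F
#' p-value per trait is corrected across the whole scan
#' (Benjamini-Hochberg by default) and called significant below the
#' class-appropriate FDR threshold (0.4 for eGenes/e-miRNAs, 0.5 for
#' caSummits in this study design). Among significant traits the associated
#' parent is the parent (or both) whose marginal t-test has p < 0.05.
#'
#' @param traits an `hv_traits`.
#' @param blocks haplotype block data.frame from [load_blocks()].
#' @param tx transmission data.frame.
#' @param cov optional covariate data.frame.
#' @param ped an `hv_pedigree`.
#' @param fdr_threshold scan-wide significance threshold on FDR; defaults to
#'   0.5 for summit traits and 0.4 otherwise.
#' @param fdr_method multiplicity correction passed to [stats::p.adjust()].
#' @param marginal_alpha marginal p cutoff for parent attribution.
#' @return data.frame of class `hv_qtl`, one row per anchored trait, with
#'   attributes `n_skipped` (traits outside any block) and `fdr_threshold`.
#' @export
qtl_scan <- function(traits, blocks, tx, cov = NULL, ped,
                     fdr_threshold = NULL, fdr_method = "BH",
                     marginal_alpha = 0.05) {
  stopifnot(inherits(traits, "hv_traits"))
  if (is.null(fdr_threshold)) {
    fdr_threshold <- if (traits$trait_class == "summit") 0.5 else 0.4
  }
  an <- traits$anchors
  mid <- floor((an$start + an$end) / 2)
  bi <- hv_point_region(an$chrom, mid, blocks$chrom, blocks$start, blocks$end)
  n_skipped <- sum(is.na(bi))
  testable <- which(!is.na(bi))
  if (!length(testable)) stop("no traits fall inside any haplotype block")
  designs <- list()
  rows <- vector("list", length(testable))
  for (k in seq_along(testable)) {
    i <- testable[k]
    bid <- blocks$block_id[bi[i]]
    if (is.null(designs[[bid]])) designs[[bid]] <- build_design(bid, tx, cov, ped)
    fit <- fit_trait(traits$values[i, ], designs[[bid]])
    rows[[k]] <- data.frame(
      trait_id = an$trait_id[i], block_id = bid,
      beta_paternal = fit$beta_paternal, se_paternal = fit$se_paternal,
      p_paternal = fit$p_paternal,
      beta_maternal = fit$beta_maternal, se_maternal = fit$se_maternal,
      p_maternal = fit$p_maternal,
      p_joint = fit$p_joint, n_used = fit$n_used,
      dropped_terms = paste(fit$dropped_terms, collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p_joint, method = fdr_method)
  res$is_significant <- !is.na(res$fdr) & res$fdr < fdr_threshold
  pat <- !is.na(res$p_paternal) & res$p_paternal < marginal_alpha
  mat <- !is.na(res$p_maternal) & res$p_maternal < marginal_alpha
  res$associated_parent <- "none"
  res$associated_parent[res$is_significant & pat & mat] <- "both"
  res$associated_parent[res$is_significant & pat & !mat] <- "paternal"
  res$associated_parent[res$is_significant & !pat & mat] <- "maternal"
  attr(res, "n_skipped") <- n_skipped
  attr(res, "fdr_threshold") <- fdr_threshold
  attr(res, "trait_class") <- traits$trait_class
  class(res) <- c("hv_qtl", "data.frame")
  res
}

#' Write QTL scan results as TSV
#'
#' @param res `hv_qtl` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_qtl_results <- function(res, path) {
  hv_write_tsv(as.data.frame(res), path)
}
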