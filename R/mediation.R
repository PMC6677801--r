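#' Test whether e-miRNAs account for eGene expression in the same block
#'
#' For every (eGene, e-miRNA) pair sharing a haplotype block, the eGene's
#' normalized expression is regressed on the miRNA's expression plus the
#' batch and EBV-quartile covariates; the miRNA coefficient's t-test p-value
#' is corrected by Benjamini-Hochberg over all pairs and a pair with
#' FDR < `fdr_threshold` is flagged as a potential miRNA-mediated haplotype
#' effect. Haplotype terms are excluded from the model by default
#' (`include_haplotype` adds them).
#'
#' @param egenes `hv_qtl` results for genes (significant rows are used).
#' @param egene_values numeric matrix genes x children (normalized).
#' @param emirnas `hv_qtl` results for miRNAs (significant rows are used).
#' @param emirna_values numeric matrix miRNAs x children (normalized).
#' @param cov optional covariate data.frame.
#' @param ped an `hv_pedigree`.
#' @param tx transmission table, required when `include_haplotype = TRUE`.
#' @param fdr_threshold FDR cutoff for the `mediates` flag (default 0.05).
#' @param include_haplotype also condition on the block haplotype indicators.
#' @return data.frame with `egene_id`, `mirna_id`, `block_id`, `beta_mirna`,
#'   `p_mirna`, `fdr`, `mediates`. Zero shared-block pairs give an empty
#'   data.frame (with a message), matching a study in which no mediation
#'   evidence exists.
#' @export
mediation_scan <- function(egenes, egene_values, emirnas, emirna_values,
                           cov = NULL, ped, tx = NULL, fdr_threshold = 0.05,
                           include_haplotype = FALSE) {
  eg <- egenes[egenes$is_significant, , drop = FALSE]
  em <- emirnas[emirnas$is_significant, , drop = FALSE]
  pairs <- merge(eg[, c("trait_id", "block_id")], em[, c("trait_id", "block_id")],
                 by = "block_id", suffixes = c("_gene", "_mirna"))
  empty <- data.frame(egene_id = character(), mirna_id = character(),
                      block_id = character(), beta_mirna = numeric(),
                      p_mirna = numeric(), fdr = numeric(),
                      mediates = logical(), stringsAsFactors = FALSE)
  if (!nrow(pairs)) {
    message("no (eGene, e-miRNA) pairs share a haplotype block; nothing to test")
    return(empty)
  }
  children <- ped$children
  children <- children[children %in% colnames(egene_values) &
                         children %in% colnames(emirna_values)]
  if (!is.null(cov)) children <- children[children %in% cov$child_id]
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    g <- egene_values[pairs$trait_id_gene[k], children]
    m <- emirna_values[pairs$trait_id_mirna[k], children]
    X <- cbind(mu = rep(1, length(children)), mirna = as.numeric(m))
    if (!is.null(cov)) {
      cc <- cov[match(children, cov$child_id), ]
      batch <- factor(cc$batch)
      if (nlevels(droplevels(batch)) > 1L) {
        mm <- stats::model.matrix(~batch)[, -1, drop = FALSE]
        X <- cbind(X, mm)
      }
      if (length(unique(cc$ebv_quartile)) > 1L) {
        X <- cbind(X, ebv = as.numeric(cc$ebv_quartile))
      }
    }
    if (include_haplotype) {
      if (is.null(tx)) stop("tx required when include_haplotype = TRUE")
      tb <- tx[tx$block_id == pairs$block_id[k], ]
      tb <- tb[match(children, tb$child_id), ]
      for (term in c("paternal_allele", "maternal_allele")) {
        v <- as.numeric(tb[[term]])
        if (length(unique(v)) > 1L) X <- cbind(X, v)
      }
    }
    fit <- stats::lm.fit(X, as.numeric(g))
    df2 <- length(children) - ncol(X)
    rss <- sum(fit$residuals^2)
    XtXinv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(pmax(diag(XtXinv), 0) * rss / df2)
    tval <- fit$coefficients[2] / se[2]
    rows[[k]] <- data.frame(
      egene_id = pairs$trait_id_gene[k], mirna_id = pairs$trait_id_mirna[k],
      block_id = pairs$block_id[k],
      beta_mirna = unname(fit$coefficients[2]),
      p_mirna = 2 * stats::pt(-abs(tval), df2), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p_mirna, method = "BH")
  res$mediates <- res$fdr < fdr_threshold
  res
}

#' Annotate mediation results with externally validated target pairs
#'
#' Optional hook: marks which tested (miRNA, gene) pairs appear in a supplied
#' validated-target table (TSV with columns `mirna_id`, `gene_id`).
#'
#' @param res mediation results from [mediation_scan()].
#' @param target_pairs data.frame with `mirna_id`, `gene_id`.
#' @return `res` with an added logical `validated_target` column.
#' @export
annotate_targets <- function(res, target_pairs) {
  key <- paste(res$mirna_id, res$egene_id)
  res$validated_target <- key %in% paste(target_pairs$mirna_id, target_pairs$gene_id)
  res
}
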