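#' Load a pedigree from a 4-column TSV
#'
#' The file is a PED-like dialect with header
#' `sample_id`, `father`, `mother`, `generation`; founders carry `.` (or an
#' empty field) for an absent parent. The analysis set ("children") is every
#' member of the maximum generation.
#'
#' @param path path to the pedigree TSV.
#' @return an object of class `hv_pedigree` with elements `members`
#'   (data.frame) and `children` (character vector).
#' @examples
#' ped <- load_pedigree(system.file("extdata", "pedigree.tsv", package = "hapvar"))
#' length(ped$children)
#' @export
load_pedigree <- function(path) {
  df <- hv_read_tsv(path, required = c("sample_id", "father", "mother", "generation"),
                    what = "pedigree")
  df$father[df$father %in% c(".", "", "NA")] <- NA
  df$mother[df$mother %in% c(".", "", "NA")] <- NA
  df$generation <- as.integer(df$generation)
  new_pedigree(df)
}

new_pedigree <- function(members) {
  if (anyDuplicated(members$sample_id)) {
    stop("pedigree structural error: duplicated sample_id(s): ",
         paste(unique(members$sample_id[duplicated(members$sample_id)]), collapse = ", "))
  }
  gen <- stats::setNames(members$generation, members$sample_id)
  for (side in c("father", "mother")) {
    ref <- members[[side]]
    bad <- !is.na(ref) & !(ref %in% members$sample_id)
    if (any(bad)) {
      stop("pedigree structural error: sample ", members$sample_id[which(bad)[1]],
           " references ", side, " ", ref[which(bad)[1]], " absent from members")
    }
    has <- !is.na(ref)
    # generation must strictly increase along parent -> child links; this also
    # excludes cycles in the parent graph
    if (any(has & gen[ref] >= members$generation)) {
      i <- which(has & gen[ref] >= members$generation)[1]
      stop("pedigree structural error: ", side, " of ", members$sample_id[i],
           " is not in an earlier generation (cycle or mislabeled generation)")
    }
  }
  children <- members$sample_id[members$generation == max(members$generation)]
  if (!length(children)) stop("pedigree structural error: no children")
  for (ch in children) {
    row <- members[members$sample_id == ch, ]
    if (is.na(row$father) || is.na(row$mother)) {
      stop("pedigree structural error: child ", ch, " lacks a recorded parent")
    }
  }
  structure(list(members = members, children = children), class = "hv_pedigree")
}

#' @export
print.hv_pedigree <- function(x, ...) {
  cat("hv_pedigree:", nrow(x$members), "members,",
      length(unique(x$members$generation)), "generations,",
      length(x$children), "children\n")
  invisible(x)
}

# Father and mother sample ids of the (single) analysis sibship.
hv_parents <- function(ped) {
  m <- ped$members
  kids <- m[m$sample_id %in% ped$children, ]
  fa <- unique(kids$father)
  mo <- unique(kids$mother)
  if (length(fa) != 1L || length(mo) != 1L) {
    stop("analysis children must form a single sibship (one father, one mother)")
  }
  c(father = fa, mother = mo)
}

#' Load a haplotype block table
#'
#' TSV with columns `block_id`, `chrom`, `start`, `end` (0-based half-open).
#' Blocks on one chromosome must be non-overlapping.
#'
#' @param path path to the block TSV.
#' @return data.frame of blocks.
#' @export
load_blocks <- function(path) {
  df <- hv_read_tsv(path, required = c("block_id", "chrom", "start", "end"),
                    what = "haplotype block table")
  validate_blocks(df)
}

validate_blocks <- function(df) {
  if (any(df$start >= df$end)) stop("haplotype block with start >= end")
  if (anyDuplicated(df$block_id)) stop("duplicated block_id")
  for (cc in unique(df$chrom)) {
    b <- df[df$chrom == cc, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("overlapping haplotype blocks on ", cc)
    }
  }
  df
}

#' Load a transmission table
#'
#' TSV with columns `child_id`, `block_id`, `paternal_allele`,
#' `maternal_allele`; the 0/1 allele label states which of that parent's two
#' block haplotypes the child inherited (labels are founder-arbitrary; the
#' model is invariant to swapping them).
#'
#' @param path path to the transmission TSV.
#' @return data.frame of per-(child, block) transmissions.
#' @export
load_transmission <- function(path) {
  df <- hv_read_tsv(path, required = c("child_id", "block_id",
                                       "paternal_allele", "maternal_allele"),
                    what = "transmission table")
  for (col in c("paternal_allele", "maternal_allele")) {
    if (!all(df[[col]] %in% c(0L, 1L))) stop(col, " must be 0/1")
  }
  if (anyDuplicated(df[, c("child_id", "block_id")])) {
    stop("duplicated (child_id, block_id) in transmission table")
  }
  df
}

#' Load the per-child covariate table
#'
#' TSV with columns `child_id`, `batch` (categorical label, e.g. extraction
#' date) and `ebv_quartile` (ordinal 1-4, precomputed from mean EBV
#' expression).
#'
#' @param path path to the covariate TSV.
#' @return data.frame of covariates, one row per child.
#' @export
load_covariates <- function(path) {
  df <- hv_read_tsv(path, required = c("child_id", "batch", "ebv_quartile"),
                    what = "covariate table")
  df$ebv_quartile <- as.integer(df$ebv_quartile)
  if (!all(df$ebv_quartile %in% 1:4)) stop("ebv_quartile must be in 1..4")
  if (anyDuplicated(df$child_id)) stop("duplicated child_id in covariate table")
  df
}

#' Build the haplotype-inheritance design matrix for one block
#'
#' Rows are the analysis children; columns are the intercept `mu`, a 0/1
#' paternal-allele indicator `paternal`, a 0/1 maternal-allele indicator
#' `maternal`, and (when covariates are supplied) batch one-hot columns minus
#' the reference level plus `ebv_quartile` as a single numeric column. A
#' haplotype indicator that does not vary across the usable children carries
#' no information and is dropped (recorded in `dropped_terms`); a constant
#' covariate column is silently omitted. Children lacking a transmission (or
#' covariate) record for the block are dropped and `n_used` reflects that.
#'
#' @param block_id block identifier to build the design for.
#' @param tx transmission data.frame from [load_transmission()].
#' @param cov optional covariate data.frame from [load_covariates()].
#' @param ped an `hv_pedigree`.
#' @return object of class `hv_design`: list with `X` (model matrix),
#'   `children`, `block_id`, `hap_terms`, `cov_terms`, `dropped_terms`,
#'   `uninformative`.
#' @export
build_design <- function(block_id, tx, cov = NULL, ped) {
  tb <- tx[tx$block_id == block_id, ]
  used <- ped$children[ped$children %in% tb$child_id]
  if (!is.null(cov)) used <- used[used %in% cov$child_id]
  if (length(used) < 3L) {
    stop("insufficient sample: fewer than 3 children with complete data for block ",
         block_id)
  }
  tb <- tb[match(used, tb$child_id), ]
  X <- cbind(mu = rep(1, length(used)),
             paternal = as.numeric(tb$paternal_allele),
             maternal = as.numeric(tb$maternal_allele))
  rownames(X) <- used
  dropped <- character()
  for (term in c("paternal", "maternal")) {
    if (length(unique(X[, term])) == 1L) dropped <- c(dropped, term)
  }
  if (length(dropped)) X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  hap_terms <- setdiff(c("paternal", "maternal"), dropped)
  cov_terms <- character()
  if (!is.null(cov)) {
    cc <- cov[match(used, cov$child_id), ]
    batch <- factor(cc$batch)
    if (nlevels(droplevels(batch)) > 1L) {
      mm <- stats::model.matrix(~batch)[, -1, drop = FALSE]
      colnames(mm) <- sub("^batch", "batch_", colnames(mm))
      keep <- apply(mm, 2, function(v) length(unique(v)) > 1L)
      mm <- mm[, keep, drop = FALSE]
      if (ncol(mm)) {
        rownames(mm) <- used
        X <- cbind(X, mm)
        cov_terms <- c(cov_terms, colnames(mm))
      }
    }
    ebv <- as.numeric(cc$ebv_quartile)
    if (length(unique(ebv)) > 1L) {
      X <- cbind(X, ebv = ebv)
      cov_terms <- c(cov_terms, "ebv")
    }
  }
  structure(list(X = X, children = used, block_id = block_id,
                 hap_terms = hap_terms, cov_terms = cov_terms,
                 dropped_terms = dropped,
                 uninformative = length(hap_terms) == 0L),
            class = "hv_design")
}

#' @export
print.hv_design <- function(x, ...) {
  cat("hv_design for block", x$block_id, "-", nrow(x$X), "children x",
      ncol(x$X), "terms (", paste(colnames(x$X), collapse = ", "), ")\n")
  if (length(x$dropped_terms)) {
    cat("  dropped (non-varying):", paste(x$dropped_terms, collapse = ", "), "\n")
  }
  invisible(x)
}
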