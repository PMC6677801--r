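#' Read family genotypes from a VCF
#'
#' Positions are converted to the package-wide 0-based convention on ingest.
#' Phased genotypes are respected; for children written by this package's
#' conventions a phased genotype is `paternal|maternal`. Multi-allelic
#' records are kept with their full allele set; each alternate allele is
#' handled separately downstream.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return object of class `hv_variants`: list with `sites` (data.frame
#'   `chrom`, `pos` (0-based), `ref`, `alt`), `gt` (character matrix variants
#'   x members, e.g. "0/1" or "0|1").
#' @export
read_vcf_family <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT", return.alleles = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]) - 1L, # VCF is 1-based
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  sites$variant_id <- paste0(sites$chrom, ":", sites$pos, ":",
                             sites$ref, ":", sites$alt)
  gt <- matrix(as.character(gt), nrow = nrow(sites),
               dimnames = list(sites$variant_id, colnames(gt)))
  structure(list(sites = sites, gt = gt), class = "hv_variants")
}

# Parse one GT string into list(alleles = int vector (NA for missing),
# phased = logical).
parse_gt <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) {
    return(list(alleles = c(NA_integer_, NA_integer_), phased = FALSE))
  }
  phased <- grepl("|", g, fixed = TRUE)
  parts <- strsplit(g, "[/|]")[[1]]
  al <- suppressWarnings(as.integer(parts))
  if (length(al) == 1L) al <- c(al, al) # haploid call treated as homozygous
  list(alleles = al, phased = phased)
}

gt_key <- function(g) {
  p <- parse_gt(g)
  if (anyNA(p$alleles)) return(NA_character_)
  paste(sort(p$alleles), collapse = "/")
}

#' Is a variant polymorphic among the children?
#'
#' TRUE when at least two distinct (unordered) genotypes occur among the
#' children; all-missing genotypes give FALSE with a warning.
#'
#' @param gt_children character vector of child GT strings.
#' @return logical.
#' @export
polymorphic_in_children <- function(gt_children) {
  keys <- vapply(gt_children, gt_key, character(1))
  keys <- keys[!is.na(keys)]
  if (!length(keys)) {
    warning("all child genotypes missing; treating variant as non-polymorphic")
    return(FALSE)
  }
  length(unique(keys)) >= 2L
}

#' Which caSummit region contains a variant?
#'
#' @param chrom,pos variant coordinates (0-based).
#' @param casummits data.frame of significant summit regions (`summit_id`,
#'   `chrom`, `start`, `end`), non-overlapping.
#' @return the containing `summit_id`, or NA when none ([start, end)
#'   half-open).
#' @export
in_casummit <- function(chrom, pos, casummits) {
  for (cc in unique(casummits$chrom)) {
    b <- casummits[casummits$chrom == cc, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1L && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("structural error: overlapping caSummit regions on ", cc)
    }
  }
  i <- hv_point_region(chrom, pos, casummits$chrom, casummits$start, casummits$end)
  ifelse(is.na(i), NA_character_, casummits$summit_id[i])
}

#' Is the variant heterozygous in the QTL-associated parent?
#'
#' When the association implicates both parents, heterozygosity in either
#' satisfies the filter (disjunction). A missing parent genotype gives FALSE
#' with a warning.
#'
#' @param gt named character vector of GT strings (all family members).
#' @param associated_parent `"paternal"`, `"maternal"` or `"both"`.
#' @param ped an `hv_pedigree`.
#' @return logical.
#' @export
het_in_associated_parent <- function(gt, associated_parent, ped) {
  par <- hv_parents(ped)
  ids <- switch(associated_parent,
                paternal = par["father"], maternal = par["mother"],
                both = par, stop("associated_parent must be paternal/maternal/both"))
  het <- vapply(ids, function(id) {
    g <- gt[[id]]
    if (is.null(g) || is.na(g)) {
      warning("missing genotype for parent ", id)
      return(FALSE)
    }
    p <- parse_gt(g)
    !anyNA(p$alleles) && p$alleles[1] != p$alleles[2]
  }, logical(1))
  any(het)
}

# Allele a child received from one parent ("father"/"mother"), resolved from
# a phased child GT (paternal|maternal) or by Mendelian deduction from the
# other parent's genotype; NA when unresolvable.
allele_from_parent <- function(child_gt, other_parent_gt, parent_alleles, side) {
  p <- parse_gt(child_gt)
  if (anyNA(p$alleles)) return(NA_integer_)
  if (p$phased) {
    return(if (side == "father") p$alleles[1] else p$alleles[2])
  }
  op <- parse_gt(other_parent_gt)
  cand <- unique(c(
    if (!anyNA(op$alleles) && p$alleles[2] %in% op$alleles &&
          p$alleles[1] %in% parent_alleles) p$alleles[1],
    if (!anyNA(op$alleles) && p$alleles[1] %in% op$alleles &&
          p$alleles[2] %in% parent_alleles) p$alleles[2]))
  if (length(cand) == 1L) cand else NA_integer_
}

#' Does the variant co-segregate with the informative haplotype?
#'
#' TRUE when, across the children, the allele received from the associated
#' parent is perfectly determined by which of that parent's two block
#' haplotypes was transmitted — i.e. the variant rides the informative
#' haplotype. Children whose allele-of-origin cannot be resolved (both
#' parents heterozygous, unphased child) are skipped and counted; when more
#' than `max_skip_frac` of children are skipped the call is indeterminate
#' (FALSE, flagged via attribute `indeterminate`). When the association
#' implicates both parents the test passes if segregation holds for at least
#' one heterozygous associated parent.
#'
#' @param gt named character vector of GT strings.
#' @param block_id the haplotype block of the caSummit.
#' @param associated_parent `"paternal"`, `"maternal"` or `"both"`.
#' @param tx transmission table.
#' @param ped an `hv_pedigree`.
#' @param max_skip_frac indeterminacy cap (default 0.5).
#' @return logical with attributes `n_skipped`, `indeterminate`.
#' @export
cosegregates <- function(gt, block_id, associated_parent, tx, ped,
                         max_skip_frac = 0.5) {
  par <- hv_parents(ped)
  sides <- switch(associated_parent,
                  paternal = "father", maternal = "mother",
                  both = c("father", "mother"))
  best <- structure(FALSE, n_skipped = NA_integer_, indeterminate = FALSE)
  for (side in sides) {
    pg <- parse_gt(gt[[par[side]]])
    if (anyNA(pg$alleles) || pg$alleles[1] == pg$alleles[2]) next # needs a het parent
    other <- gt[[par[if (side == "father") "mother" else "father"]]]
    tb <- tx[tx$block_id == block_id, ]
    hap_col <- if (side == "father") "paternal_allele" else "maternal_allele"
    got <- vapply(ped$children, function(ch) {
      allele_from_parent(gt[[ch]], other, pg$alleles, side)
    }, integer(1))
    hap <- tb[[hap_col]][match(ped$children, tb$child_id)]
    ok <- !is.na(got) & !is.na(hap)
    n_skipped <- sum(!ok)
    if (n_skipped > max_skip_frac * length(ped$children)) {
      res <- structure(FALSE, n_skipped = n_skipped, indeterminate = TRUE)
      if (!best) best <- res
      next
    }
    by_hap <- split(got[ok], hap[ok])
    consistent <- all(vapply(by_hap, function(v) length(unique(v)) == 1L, logical(1)))
    discriminates <- length(by_hap) == 2L &&
      by_hap[[1]][1] != by_hap[[2]][1]
    res <- structure(consistent && discriminates,
                     n_skipped = n_skipped, indeterminate = FALSE)
    if (res) return(res)
    if (is.na(attr(best, "n_skipped")) || !attr(res, "indeterminate")) best <- res
  }
  best
}

#' Does a caSummit region contain an intermediate-methylation CpG?
#'
#' @param region one-row data.frame (`chrom`, `start`, `end`).
#' @param intermediate_set data.frame from [intermediate_cpgs()].
#' @return logical.
#' @export
methylation_evidence <- function(region, intermediate_set) {
  if (!nrow(intermediate_set)) return(FALSE)
  any(intermediate_set$chrom == region$chrom &
        intermediate_set$pos >= region$start &
        intermediate_set$pos < region$end)
}

#' Does a haplotype block carry a significant eGene / a replicated eGene?
#'
#' @param block_id block identifier.
#' @param egenes `hv_qtl` results for genes.
#' @param replicated_set character vector of externally replicated eGene ids
#'   (may be empty).
#' @return logical vector `c(egene_overlap, replicated_egene)`.
#' @export
egene_overlap <- function(block_id, egenes, replicated_set = character()) {
  hits <- egenes$trait_id[egenes$is_significant & egenes$block_id == block_id]
  c(egene_overlap = length(hits) > 0L,
    replicated_egene = any(hits %in% replicated_set))
}

#' Load a population minor-allele-frequency table
#'
#' TSV with a `variant_id` key column (chrom:pos:ref:alt, 0-based pos) and
#' one numeric MAF column per population.
#'
#' @param path MAF TSV.
#' @return data.frame.
#' @export
load_maf_table <- function(path) {
  df <- hv_read_tsv(path, required = "variant_id",
                    prefix_ok = "maf_", what = "MAF table")
  pops <- grep("^maf_", names(df), value = TRUE)
  if (!length(pops)) stop("MAF table has no maf_<population> columns")
  for (p in pops) {
    if (!is.numeric(df[[p]])) stop("malformed MAF table: non-numeric ", p)
  }
  df
}

#' Is a variant rare in every listed population?
#'
#' @param variant_id key (chrom:pos:ref:alt).
#' @param maf_table data.frame from [load_maf_table()].
#' @param cutoff MAF cutoff (default 0.05, strict).
#' @return TRUE/FALSE, or NA when the variant is absent from the table.
#' @export
rare_annotation <- function(variant_id, maf_table, cutoff = 0.05) {
  i <- match(variant_id, maf_table$variant_id)
  if (is.na(i)) return(NA)
  pops <- grep("^maf_", names(maf_table), value = TRUE)
  all(unlist(maf_table[i, pops]) < cutoff)
}

#' Run the multifunctional-variant filtering cascade
#'
#' Applies, in order: polymorphic-among-children, located-in-caSummit,
#' heterozygous-in-associated-parent, co-segregation of SNP and informative
#' haplotype, intermediate-methylation evidence in the summit region,
#' eGene-bearing haplotype block, and (when configured) membership of that
#' eGene in an externally replicated set. Every variant's evidence ledger is
#' recorded (all flags evaluated when `audit = TRUE`, even past the first
#' failure) and a funnel report counts survivors per stage.
#'
#' @param variants an `hv_variants`.
#' @param casummits data.frame of significant summit regions (`summit_id`,
#'   `chrom`, `start`, `end`, `block_id`, `associated_parent`).
#' @param tx transmission table.
#' @param intermediate_set data.frame from [intermediate_cpgs()].
#' @param egenes `hv_qtl` gene scan results.
#' @param ped an `hv_pedigree`.
#' @param config list of toggles: `require_replicated` (default FALSE),
#'   `replicated_egenes` (character), `stages` (named logical to disable
#'   individual stages), `audit` (default TRUE), `maf_table`, `maf_cutoff`.
#' @return list with `candidates` (data.frame: variant fields, ids, evidence
#'   flags, `is_rare`, `survives`) and `funnel` (data.frame `stage`,
#'   `entering`, `surviving`).
#' @export
run_cascade <- function(variants, casummits, tx, intermediate_set, egenes, ped,
                        config = list()) {
  for (nm in c("variants", "casummits", "tx", "intermediate_set", "egenes")) {
    if (is.null(get(nm))) stop("cascade configuration error: missing upstream artifact ", nm)
  }
  audit <- config$audit %||% TRUE
  stages <- c(polymorphic_in_children = TRUE, in_casummit = TRUE,
              het_in_associated_parent = TRUE, cosegregates = TRUE,
              intermediate_methylation = TRUE, egene_overlap = TRUE)
  if (!is.null(config$stages)) stages[names(config$stages)] <- config$stages
  require_repl <- config$require_replicated %||% FALSE
  repl <- config$replicated_egenes %||% character()
  s <- variants$sites
  n <- nrow(s)
  if (n == 0L) {
    stage_names <- names(stages)[stages]
    if (require_repl) stage_names <- c(stage_names, "replicated_egene")
    return(list(candidates = cbind(s, survives = logical(0)),
                funnel = data.frame(stage = stage_names, entering = 0L,
                                    surviving = 0L, stringsAsFactors = FALSE)))
  }
  flags <- data.frame(polymorphic_in_children = rep(NA, n), in_casummit = NA,
                      het_in_associated_parent = NA, cosegregates = NA,
                      intermediate_methylation = NA, egene_overlap = NA,
                      replicated_egene = NA)
  casummit_id <- rep(NA_character_, n)
  block_id <- rep(NA_character_, n)
  is_rare <- rep(NA, n)
  children <- ped$children
  for (i in seq_len(n)) {
    gt <- variants$gt[i, ]
    alive <- TRUE
    flags$polymorphic_in_children[i] <-
      suppressWarnings(polymorphic_in_children(gt[children]))
    alive <- alive && isTRUE(flags$polymorphic_in_children[i])
    if (alive || audit) {
      casummit_id[i] <- in_casummit(s$chrom[i], s$pos[i], casummits)
      flags$in_casummit[i] <- !is.na(casummit_id[i])
    }
    alive <- alive && isTRUE(flags$in_casummit[i])
    if (!is.na(casummit_id[i])) {
      ci <- match(casummit_id[i], casummits$summit_id)
      block_id[i] <- casummits$block_id[ci]
      ap <- casummits$associated_parent[ci]
      if (ap %in% c("paternal", "maternal", "both")) {
        flags$het_in_associated_parent[i] <-
          suppressWarnings(het_in_associated_parent(gt, ap, ped))
        if (isTRUE(flags$het_in_associated_parent[i])) {
          flags$cosegregates[i] <-
            as.logical(cosegregates(gt, block_id[i], ap, tx, ped))
        }
      }
      region <- casummits[ci, c("chrom", "start", "end")]
      flags$intermediate_methylation[i] <-
        methylation_evidence(region, intermediate_set)
      ov <- egene_overlap(block_id[i], egenes, repl)
      flags$egene_overlap[i] <- ov[["egene_overlap"]]
      flags$replicated_egene[i] <- ov[["replicated_egene"]]
    }
    if (!is.null(config$maf_table)) {
      is_rare[i] <- rare_annotation(s$variant_id[i], config$maf_table,
                                    config$maf_cutoff %||% 0.05)
    }
  }
  stage_names <- names(stages)[stages]
  if (require_repl) stage_names <- c(stage_names, "replicated_egene")
  # survival: conjunction of the enabled stage flags (NA counts as failure)
  surv <- rep(TRUE, n)
  funnel <- data.frame(stage = stage_names,
                       entering = NA_integer_, surviving = NA_integer_,
                       stringsAsFactors = FALSE)
  for (k in seq_along(stage_names)) {
    st <- stage_names[k]
    funnel$entering[k] <- sum(surv)
    fl <- if (st == "intermediate_methylation") flags$intermediate_methylation
          else flags[[st]]
    surv <- surv & !is.na(fl) & fl
    funnel$surviving[k] <- sum(surv)
  }
  candidates <- cbind(s, casummit_id = casummit_id, block_id = block_id,
                      flags, is_rare = is_rare, survives = surv,
                      stringsAsFactors = FALSE)
  list(candidates = candidates, funnel = funnel)
}

#' Fisher exact test of overlap between two hit sets
#'
#' Hypergeometric upper-tail (Fisher exact, one-sided) p-value for the
#' observed overlap of two sets drawn from a common universe, plus the sample
#' odds ratio — the statistic used to compare eGene sets between studies.
#'
#' @param hits_a,hits_b character vectors of ids.
#' @param universe_size size of the common universe.
#' @return list with `overlap_n`, `odds_ratio`, `p_value`.
#' @export
set_overlap_test <- function(hits_a, hits_b, universe_size) {
  hits_a <- unique(hits_a)
  hits_b <- unique(hits_b)
  if (universe_size < length(union(hits_a, hits_b))) {
    stop("universe smaller than the union of the two hit sets")
  }
  k <- length(intersect(hits_a, hits_b))
  m <- length(hits_a)
  nn <- length(hits_b)
  p <- stats::phyper(k - 1, m, universe_size - m, nn, lower.tail = FALSE)
  n11 <- k
  n12 <- m - k
  n21 <- nn - k
  n22 <- universe_size - m - nn + k
  or <- (n11 * n22) / (n12 * n21)
  list(overlap_n = k, odds_ratio = or, p_value = p)
}

#' Write cascade outputs
#'
#' Candidates as TSV, the per-variant evidence ledger as JSON, and the funnel
#' report as TSV.
#'
#' @param cascade result of [run_cascade()].
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_cascade <- function(cascade, dir) {
  p1 <- hv_write_tsv(cascade$candidates, file.path(dir, "candidates.tsv"))
  p2 <- hv_write_tsv(cascade$funnel, file.path(dir, "funnel.tsv"))
  p3 <- file.path(dir, "evidence.json")
  jsonlite::write_json(cascade$candidates, p3, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(p1, p2, p3))
}
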