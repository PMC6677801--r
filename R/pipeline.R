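#' Build a run configuration
#'
#' Collects input paths, stage toggles, thresholds and the seed into a
#' validated configuration for [run_all()]. `study_dir` may point at a
#' directory written by [simulate_study()] (or any directory using the same
#' file names); individual paths can be overridden.
#'
#' @param study_dir directory holding the input files.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param fdr_casummit,fdr_egene,fdr_emirna,fdr_mediation scan thresholds.
#' @param meth_low,meth_high,meth_min_children intermediate-methylation
#'   parameters.
#' @param min_cov,top_percentile CpG coverage filters.
#' @param min_children_repro summit reproducibility threshold.
#' @param maf_cutoff rarity threshold.
#' @param do_mediation,do_allelic stage toggles.
#' @param require_replicated,replicated_egenes final cascade stage control.
#' @param paths named list of path overrides.
#' @return validated `hv_run_config` list.
#' @export
run_config <- function(study_dir, out_dir, seed = 1L,
                       fdr_casummit = 0.5, fdr_egene = 0.4, fdr_emirna = 0.4,
                       fdr_mediation = 0.05,
                       meth_low = 0.25, meth_high = 0.75, meth_min_children = 3L,
                       min_cov = 10L, top_percentile = 99.9,
                       min_children_repro = 3L, maf_cutoff = 0.05,
                       do_mediation = TRUE, do_allelic = TRUE,
                       require_replicated = FALSE,
                       replicated_egenes = character(),
                       paths = list()) {
  sd <- function(x) file.path(study_dir, x)
  ped <- load_pedigree(paths$pedigree %||% sd("pedigree.tsv"))
  children <- ped$children
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    pedigree = paths$pedigree %||% sd("pedigree.tsv"),
    blocks = paths$blocks %||% sd("blocks.tsv"),
    transmission = paths$transmission %||% sd("transmission.tsv"),
    covariates = paths$covariates %||% sd("covariates.tsv"),
    summit_beds = paths$summit_beds %||%
      sd(c("summits_rep1.bed", "summits_rep2.bed")),
    master_peaks = paths$master_peaks %||% sd("master_peaks.narrowPeak"),
    child_peaks = paths$child_peaks %||%
      stats::setNames(sd(sprintf("peaks_%s.narrowPeak", children)), children),
    reads = paths$reads %||%
      stats::setNames(sd(sprintf("reads_%s.tsv", children)), children),
    gene_counts = paths$gene_counts %||% sd("gene_counts.tsv"),
    gene_anchors = paths$gene_anchors %||% sd("gene_anchors.tsv"),
    mirna_counts = paths$mirna_counts %||% sd("mirna_counts.tsv"),
    mirna_anchors = paths$mirna_anchors %||% sd("mirna_anchors.tsv"),
    methylation = paths$methylation %||% sd("methylation.tsv"),
    vcf = paths$vcf %||% sd("variants.vcf"),
    maf = paths$maf %||% sd("maf.tsv"),
    allelic = paths$allelic %||% sd("allelic_bases.tsv"),
    fdr_casummit = fdr_casummit, fdr_egene = fdr_egene,
    fdr_emirna = fdr_emirna, fdr_mediation = fdr_mediation,
    meth_low = meth_low, meth_high = meth_high,
    meth_min_children = as.integer(meth_min_children),
    min_cov = as.integer(min_cov), top_percentile = top_percentile,
    min_children_repro = as.integer(min_children_repro),
    maf_cutoff = maf_cutoff,
    do_mediation = isTRUE(do_mediation), do_allelic = isTRUE(do_allelic),
    require_replicated = isTRUE(require_replicated),
    replicated_egenes = replicated_egenes)
  validate_run_config(cfg)
  structure(cfg, class = "hv_run_config")
}

validate_run_config <- function(cfg) {
  for (nm in c("fdr_casummit", "fdr_egene", "fdr_emirna", "fdr_mediation",
               "meth_low", "meth_high", "maf_cutoff")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("run config validation error: ", nm, " must lie in [0, 1], got ", v)
    }
  }
  if (cfg$meth_low >= cfg$meth_high) {
    stop("run config validation error: meth_low must be < meth_high")
  }
  required <- c(cfg$pedigree, cfg$blocks, cfg$transmission, cfg$covariates,
                cfg$summit_beds, cfg$master_peaks, cfg$child_peaks, cfg$reads,
                cfg$gene_counts, cfg$gene_anchors, cfg$mirna_counts,
                cfg$mirna_anchors, cfg$methylation, cfg$vcf, cfg$maf)
  missing <- required[!file.exists(required)]
  if (length(missing)) {
    stop("run config validation error: missing input file(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

hv_read_counts_tsv <- function(path, what) {
  df <- hv_read_tsv(path, required = "trait_id", prefix_ok = "", what = what)
  m <- as.matrix(df[, setdiff(names(df), "trait_id"), drop = FALSE])
  rownames(m) <- df$trait_id
  m
}

hv_config_hash <- function(cfg) {
  flat <- cfg[order(names(cfg))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full discovery pipeline
#'
#' Executes, in order: summit atlas construction (per-replicate merge,
#' cross-replicate merge, master-peak filter, reproducibility filter), summit
#' read counting and normalization, the three haplotype QTL scans (summits,
#' genes, miRNAs), miRNA mediation testing, the methylation filter, the
#' variant cascade and (optionally) allelic imbalance — writing every result
#' table plus a JSON manifest under `cfg$out_dir`. Given identical inputs the
#' result files are byte-identical between runs; only the manifest carries a
#' timestamp. A stage failure leaves a `RUN.partial` marker naming the failed
#' stage.
#'
#' @param cfg an `hv_run_config`.
#' @return invisibly, a list with `results` (in-memory stage outputs) and
#'   `manifest`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "hv_run_config"))
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_counts <- list()
  current_stage <- "setup"
  res <- list()
  tryCatch({
    ped <- load_pedigree(cfg$pedigree)
    blocks <- load_blocks(cfg$blocks)
    tx <- load_transmission(cfg$transmission)
    cov <- load_covariates(cfg$covariates)

    current_stage <- "summit_atlas"
    reps <- lapply(cfg$summit_beds, function(p) {
      merge_summits(read_summit_bed(p, source_sample = basename(p)))
    })
    combined <- merge_summits(do.call(rbind, reps))
    master_peaks <- read_narrowpeak(cfg$master_peaks)
    master <- filter_in_master_peaks(combined, master_peaks)
    child_peaks <- lapply(cfg$child_peaks, read_narrowpeak)
    master <- reproducibility_filter(master, child_peaks,
                                     min_children = cfg$min_children_repro)
    master$summit_id <- summit_ids(master)
    hv_write_tsv(master, file.path(cfg$out_dir, "master_summits.tsv"))
    stage_counts$master_summits <- nrow(master)

    current_stage <- "summit_counts"
    fragments <- lapply(cfg$reads, function(p) {
      hv_read_tsv(p, required = c("chrom", "pos", "strand"), what = "read table")
    })
    counts <- count_reads(fragments, master)
    write_summit_counts(counts, file.path(cfg$out_dir, "summit_counts.tsv"))
    norm <- normalize_counts(counts)

    current_stage <- "qtl_summits"
    qtl_sum <- qtl_scan(summit_traits(norm), blocks, tx, cov = NULL, ped,
                        fdr_threshold = cfg$fdr_casummit)
    write_qtl_results(qtl_sum, file.path(cfg$out_dir, "qtl_summits.tsv"))
    stage_counts$casummits <- sum(qtl_sum$is_significant)

    current_stage <- "qtl_genes"
    gtraits <- filter_gene_counts(hv_read_counts_tsv(cfg$gene_counts, "gene counts"),
                                  hv_read_tsv(cfg$gene_anchors,
                                              required = c("trait_id", "chrom",
                                                           "start", "end"),
                                              what = "gene anchors"))
    qtl_gene <- qtl_scan(gtraits, blocks, tx, cov = cov, ped,
                         fdr_threshold = cfg$fdr_egene)
    write_qtl_results(qtl_gene, file.path(cfg$out_dir, "qtl_genes.tsv"))
    stage_counts$egenes <- sum(qtl_gene$is_significant)

    current_stage <- "qtl_mirna"
    mtraits <- filter_mirna_counts(hv_read_counts_tsv(cfg$mirna_counts, "miRNA counts"),
                                   hv_read_tsv(cfg$mirna_anchors,
                                               required = c("trait_id", "chrom",
                                                            "start", "end"),
                                               what = "miRNA anchors"))
    qtl_mir <- qtl_scan(mtraits, blocks, tx, cov = cov, ped,
                        fdr_threshold = cfg$fdr_emirna)
    write_qtl_results(qtl_mir, file.path(cfg$out_dir, "qtl_mirna.tsv"))
    stage_counts$emirnas <- sum(qtl_mir$is_significant)

    current_stage <- "mediation"
    if (cfg$do_mediation) {
      med <- suppressMessages(
        mediation_scan(qtl_gene, gtraits$values, qtl_mir, mtraits$values,
                       cov = cov, ped = ped, fdr_threshold = cfg$fdr_mediation))
      hv_write_tsv(med, file.path(cfg$out_dir, "mediation.tsv"))
      stage_counts$mediation_pairs <- nrow(med)
    } else {
      stage_counts$mediation_pairs <- "skipped"
    }

    current_stage <- "methylation_filter"
    meth <- merge_strands(read_methylation(cfg$methylation))
    meth <- coverage_filter(meth, min_cov = cfg$min_cov,
                            top_percentile = cfg$top_percentile)
    inter <- intermediate_cpgs(meth, low = cfg$meth_low, high = cfg$meth_high,
                               min_children = cfg$meth_min_children)
    hv_write_tsv(inter, file.path(cfg$out_dir, "intermediate_cpgs.tsv"))
    stage_counts$intermediate_cpgs <- nrow(inter)

    current_stage <- "variant_cascade"
    sig <- qtl_sum[qtl_sum$is_significant, , drop = FALSE]
    mi <- match(sig$trait_id, master$summit_id)
    casummits <- data.frame(summit_id = sig$trait_id,
                            chrom = master$chrom[mi], start = master$start[mi],
                            end = master$end[mi], block_id = sig$block_id,
                            associated_parent = sig$associated_parent,
                            stringsAsFactors = FALSE)
    variants <- read_vcf_family(cfg$vcf)
    maf_table <- load_maf_table(cfg$maf)
    cascade <- run_cascade(variants, casummits, tx, inter, qtl_gene, ped,
                           config = list(require_replicated = cfg$require_replicated,
                                         replicated_egenes = cfg$replicated_egenes,
                                         maf_table = maf_table,
                                         maf_cutoff = cfg$maf_cutoff))
    write_cascade(cascade, cfg$out_dir)
    stage_counts$candidates <- sum(cascade$candidates$survives)

    current_stage <- "allelic_reads"
    if (cfg$do_allelic && file.exists(cfg$allelic)) {
      bases <- read_site_bases(cfg$allelic)
      sites <- variants$sites
      grp <- unique(bases[, c("chrom", "pos", "sample_id")])
      tallies <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
        sel <- bases$chrom == grp$chrom[i] & bases$pos == grp$pos[i] &
          bases$sample_id == grp$sample_id[i]
        si <- which(sites$chrom == grp$chrom[i] & sites$pos == grp$pos[i])[1]
        if (is.na(si)) return(NULL)
        count_alleles(bases[sel, ], as.list(sites[si, ]),
                      sample_id = grp$sample_id[i])
      }))
      tallies <- imbalance_table(tallies)
      hv_write_tsv(tallies, file.path(cfg$out_dir, "allelic.tsv"))
      stage_counts$allelic_sites <- nrow(tallies)
    } else {
      stage_counts$allelic_sites <- "skipped"
    }

    res <- list(master = master, counts = counts, qtl_summits = qtl_sum,
                qtl_genes = qtl_gene, qtl_mirna = qtl_mir,
                intermediate = inter, cascade = cascade)
  }, error = function(e) {
    writeLines(paste0("failed at stage: ", current_stage, "\n", conditionMessage(e)),
               file.path(cfg$out_dir, "RUN.partial"))
    stop("pipeline failed at stage ", current_stage, ": ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- list(package = "hapvar",
                   version = as.character(utils::packageVersion("hapvar")),
                   seed = cfg$seed, config_hash = hv_config_hash(unclass(cfg)),
                   stage_counts = stage_counts,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = res, manifest = manifest))
}
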