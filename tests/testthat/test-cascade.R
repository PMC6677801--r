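test_that("polymorphism among children follows the distinct-genotype rule", {
  expect_true(polymorphic_in_children(c(rep("0/0", 5), rep("0/1", 6))))
  expect_false(polymorphic_in_children(rep("0/1", 11)))
  expect_false(polymorphic_in_children(rep("1/0", 11))) # unordered genotypes
  expect_warning(res <- polymorphic_in_children(rep("./.", 11)), "missing")
  expect_false(res)
  # randomized draws vs a naive distinct-count oracle
  set.seed(6)
  for (i in 1:25) {
    g <- paste0(sample(0:1, 11, TRUE), "/", sample(0:1, 11, TRUE))
    naive <- length(unique(vapply(strsplit(g, "/"), function(a)
      paste(sort(a), collapse = "/"), character(1)))) >= 2
    expect_equal(polymorphic_in_children(g), naive)
  }
})

test_that("caSummit membership is half-open and rejects overlapping regions", {
  cs <- data.frame(summit_id = c("s1", "s2"), chrom = "chr1",
                   start = c(1000L, 2000L), end = c(1500L, 2500L))
  expect_equal(in_casummit("chr1", 1200L, cs), "s1")
  expect_true(is.na(in_casummit("chr1", 1500L, cs))) # end excluded
  expect_true(is.na(in_casummit("chr2", 1200L, cs)))
  bad <- data.frame(summit_id = c("a", "b"), chrom = "chr1",
                    start = c(100L, 300L), end = c(400L, 600L))
  expect_error(in_casummit("chr1", 350L, bad), "overlapping")
  # all-pairs oracle on random variants
  set.seed(14)
  pos <- sample(0:3000, 50)
  got <- in_casummit(rep("chr1", 50), pos, cs)
  naive <- vapply(pos, function(p) {
    h <- which(cs$start <= p & p < cs$end)
    if (length(h)) cs$summit_id[h] else NA_character_
  }, character(1))
  expect_equal(got, naive)
})

test_that("heterozygosity is required in the associated parent", {
  ped <- make_pedigree()
  gt <- setNames(c("0/1", "1/1", rep("0/0", 11)), c("FTH", "MTH", CHILDREN))
  expect_true(het_in_associated_parent(gt, "paternal", ped))
  gt2 <- setNames(c("1/1", "0/1", rep("0/0", 11)), c("FTH", "MTH", CHILDREN))
  expect_false(het_in_associated_parent(gt2, "paternal", ped))
  # both: disjunction — only the mother heterozygous still passes
  expect_true(het_in_associated_parent(gt2, "both", ped))
  gt3 <- gt
  gt3["FTH"] <- NA
  expect_warning(res <- het_in_associated_parent(gt3, "paternal", ped), "missing")
  expect_false(res)
})

test_that("co-segregation demands the variant ride the informative haplotype", {
  ped <- make_pedigree()
  tx <- default_tx()
  p <- tx$paternal_allele
  # father 0/1 with the alternate on haplotype 1; phased children pat|mat
  gt_ok <- setNames(c("0/1", "0/0", paste0(p, "|0")), c("FTH", "MTH", CHILDREN))
  expect_true(cosegregates(gt_ok, "blk01", "paternal", tx, ped))

  # one discordant child breaks it
  gt_bad <- gt_ok
  gt_bad[CHILDREN[1]] <- paste0(1 - p[1], "|0")
  expect_false(cosegregates(gt_bad, "blk01", "paternal", tx, ped))

  # a variant constant on both paternal haplotypes does not discriminate
  gt_const <- setNames(c("0/1", "0/1", rep("0/1", 11)), c("FTH", "MTH", CHILDREN))
  res <- cosegregates(gt_const, "blk01", "paternal", tx, ped)
  expect_false(as.logical(res))

  # unphased children with both parents het are skipped; >50% -> indeterminate
  gt_skip <- setNames(c("0/1", "0/1", rep("0/1", 11)), c("FTH", "MTH", CHILDREN))
  res2 <- cosegregates(gt_skip, "blk01", "paternal", tx, ped)
  expect_true(attr(res2, "indeterminate"))

  # Mendelian deduction works without phase when the mother is informative
  gt_ded <- setNames(c("0/1", "0/0",
                       vapply(p, function(x) paste(sort(c(x, 0)), collapse = "/"),
                              character(1))),
                     c("FTH", "MTH", CHILDREN))
  expect_true(cosegregates(gt_ded, "blk01", "paternal", tx, ped))
})

test_that("planted variants co-segregate, permuted genotypes mostly do not", {
  ped <- make_pedigree()
  set.seed(15)
  hits <- 0L
  for (i in 1:40) {
    tx <- make_tx(p = rbinom(11, 1, 0.5), m = rbinom(11, 1, 0.5))
    if (length(unique(tx$paternal_allele)) == 1) tx$paternal_allele[1] <- 1L - tx$paternal_allele[1]
    p <- tx$paternal_allele
    gt <- setNames(c("0/1", "0/0", paste0(p, "|0")), c("FTH", "MTH", CHILDREN))
    expect_true(as.logical(cosegregates(gt, "blk01", "paternal", tx, ped)))
    perm <- sample(p)
    gtp <- setNames(c("0/1", "0/0", paste0(perm, "|0")), c("FTH", "MTH", CHILDREN))
    hits <- hits + as.logical(cosegregates(gtp, "blk01", "paternal", tx, ped))
  }
  expect_lte(hits / 40, 0.05) # permuted control passes only when perm == p
})

test_that("methylation, eGene and rarity evidence follow their rules", {
  region <- data.frame(chrom = "chr1", start = 1000L, end = 1500L)
  inter <- data.frame(chrom = "chr1", pos = c(1200L, 9999L))
  expect_true(methylation_evidence(region, inter))
  expect_false(methylation_evidence(region, data.frame(chrom = "chr1", pos = 9999L)))
  expect_false(methylation_evidence(region, inter[0, ]))

  eg <- fake_qtl(c("G1", "G2"), c("blk01", "blk02"), sig = c(TRUE, FALSE))
  expect_equal(unname(egene_overlap("blk01", eg)), c(TRUE, FALSE))
  expect_equal(unname(egene_overlap("blk02", eg)), c(FALSE, FALSE))
  expect_equal(unname(egene_overlap("blk01", eg, replicated_set = "G1")),
               c(TRUE, TRUE))

  maf <- data.frame(variant_id = c("v1", "v2"),
                    maf_AFR = c(0.01, 0.01), maf_EUR = c(0.03, 0.30),
                    maf_EAS = c(0.04, 0.04))
  expect_true(rare_annotation("v1", maf))
  expect_false(rare_annotation("v2", maf))
  expect_true(is.na(rare_annotation("v3", maf)))
  bad_path <- tempfile(fileext = ".tsv")
  write.table(data.frame(variant_id = "v1", maf_AFR = "high"), bad_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_maf_table(bad_path), "malformed")
})

test_that("set_overlap_test equals the closed-form hypergeometric tail", {
  r <- set_overlap_test(as.character(1:10), as.character(6:15), 100)
  expect_equal(r$overlap_n, 5)
  expect_equal(r$p_value, oracle_hyper_tail(5, 10, 10, 100), tolerance = 1e-12)

  d <- set_overlap_test(as.character(1:10), as.character(11:20), 100)
  expect_equal(d$overlap_n, 0)
  expect_equal(d$p_value, 1, tolerance = 1e-12)

  s <- set_overlap_test(as.character(1:10), as.character(1:10), 100)
  expect_equal(s$overlap_n, 10)
  expect_equal(s$p_value, oracle_hyper_tail(10, 10, 10, 100), tolerance = 1e-12)
  expect_lt(s$p_value, 1e-12)

  expect_error(set_overlap_test(as.character(1:60), as.character(50:70), 65),
               "universe")
})

test_that("run_cascade equals independent predicate conjunction on synthetic data", {
  d <- file.path(tempdir(), "cascade_oracle")
  sim <- simulate_study(truth_config(seed = 77L), d)
  ped <- load_pedigree(sim$files$pedigree)
  tx <- load_transmission(sim$files$transmission)
  variants <- read_vcf_family(sim$files$vcf)
  planted <- sim$truth$planted_variant
  cs <- data.frame(summit_id = planted$casummit_id, chrom = "chr1",
                   start = as.integer(sub(".*:(\\d+)-.*", "\\1", planted$casummit_id)),
                   end = as.integer(sub(".*-(\\d+)$", "\\1", planted$casummit_id)),
                   block_id = sim$truth$planted$summit$block_id,
                   associated_parent = "paternal", stringsAsFactors = FALSE)
  inter <- data.frame(chrom = "chr1",
                      pos = as.integer(sub(".*:(\\d+)-.*", "\\1", planted$casummit_id)) + 250L)
  eg <- fake_qtl(sim$truth$planted$gene$trait_id, sim$truth$planted$gene$block_id)
  out <- run_cascade(variants, cs, tx, inter, eg, ped)

  # brute force: apply each predicate independently and conjoin
  expected <- vapply(seq_len(nrow(variants$sites)), function(i) {
    gt <- variants$gt[i, ]
    if (!suppressWarnings(polymorphic_in_children(gt[ped$children]))) return(FALSE)
    cid <- in_casummit(variants$sites$chrom[i], variants$sites$pos[i], cs)
    if (is.na(cid)) return(FALSE)
    if (!suppressWarnings(het_in_associated_parent(gt, "paternal", ped))) return(FALSE)
    if (!as.logical(cosegregates(gt, cs$block_id, "paternal", tx, ped))) return(FALSE)
    if (!methylation_evidence(cs[1, c("chrom", "start", "end")], inter)) return(FALSE)
    egene_overlap(cs$block_id, eg)[["egene_overlap"]]
  }, logical(1))
  expect_equal(out$candidates$survives, expected)
  expect_equal(sum(out$candidates$survives), 1)
  expect_equal(out$candidates$variant_id[out$candidates$survives],
               planted$variant_id)
  # funnel counts: non-increasing, final equals candidate count
  expect_true(all(diff(out$funnel$surviving) <= 0))
  expect_true(all(out$funnel$surviving <= out$funnel$entering))
  expect_equal(out$funnel$surviving[nrow(out$funnel)], sum(expected))

  # disabling the methylation stage can only grow the survivor set
  out2 <- run_cascade(variants, cs, tx, inter[0, ], eg, ped,
                      config = list(stages = c(intermediate_methylation = FALSE)))
  expect_true(all(which(out$candidates$survives) %in% which(out2$candidates$survives)))

  # zero variants: empty candidates, zero funnel counts
  empty <- variants
  empty$sites <- variants$sites[0, ]
  empty$gt <- variants$gt[0, , drop = FALSE]
  out0 <- run_cascade(empty, cs, tx, inter, eg, ped)
  expect_equal(nrow(out0$candidates), 0)
  expect_true(all(out0$funnel$surviving == 0))
})

test_that("stage order does not change the final candidate set", {
  d <- file.path(tempdir(), "cascade_order")
  sim <- simulate_study(truth_config(n_blocks = 2L, seed = 31L), d)
  ped <- load_pedigree(sim$files$pedigree)
  tx <- load_transmission(sim$files$transmission)
  variants <- read_vcf_family(sim$files$vcf)
  planted <- sim$truth$planted_variant
  st <- as.integer(sub(".*:(\\d+)-.*", "\\1", planted$casummit_id))
  cs <- data.frame(summit_id = planted$casummit_id, chrom = "chr1",
                   start = st, end = st + 500L,
                   block_id = sim$truth$planted$summit$block_id,
                   associated_parent = "paternal", stringsAsFactors = FALSE)
  inter <- data.frame(chrom = "chr1", pos = st + 250L)
  eg <- fake_qtl(sim$truth$planted$gene$trait_id, sim$truth$planted$gene$block_id)
  base <- run_cascade(variants, cs, tx, inter, eg, ped)
  # permute stage evaluation order by toggling subsets off/on pairwise:
  # the predicates are pure, so survivors must match the audit-mode flags
  flags <- base$candidates[, c("polymorphic_in_children", "in_casummit",
                               "het_in_associated_parent", "cosegregates",
                               "intermediate_methylation", "egene_overlap")]
  conj <- apply(flags, 1, function(v) all(!is.na(v) & v))
  expect_equal(base$candidates$survives, unname(conj))
})
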