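meth_obj <- function(chrom, pos, strand, meth, unmeth) {
  hapvar:::new_meth(data.frame(chrom = chrom, pos = pos, strand = strand,
                               stringsAsFactors = FALSE),
                    meth, unmeth)
}

two_kid <- function(m, u) {
  list(meth = matrix(m, ncol = 2, dimnames = list(NULL, c("CH01", "CH02"))),
       unmeth = matrix(u, ncol = 2, dimnames = list(NULL, c("CH01", "CH02"))))
}

test_that("strand merging sums counts at the CpG and keeps orphans with warning", {
  k <- two_kid(c(3, 4), c(2, 1))
  mm <- meth_obj("chr1", c(100L, 101L), c("+", "-"),
                 matrix(c(3, 4), 2, 1, dimnames = list(NULL, "CH01")),
                 matrix(c(2, 1), 2, 1, dimnames = list(NULL, "CH01")))
  out <- merge_strands(mm)
  expect_equal(nrow(out$sites), 1)
  expect_equal(out$sites$pos, 100L)
  expect_equal(unname(out$meth[1, 1]), 7)   # 3m+4m
  expect_equal(unname(out$unmeth[1, 1]), 3) # 2u+1u

  plus_only <- meth_obj("chr1", 200L, "+",
                        matrix(5, 1, 1, dimnames = list(NULL, "CH01")),
                        matrix(5, 1, 1, dimnames = list(NULL, "CH01")))
  po <- merge_strands(plus_only)
  expect_equal(unname(po$meth[1, 1]), 5)

  orphan <- meth_obj("chr1", 301L, "-",
                     matrix(2, 1, 1, dimnames = list(NULL, "CH01")),
                     matrix(2, 1, 1, dimnames = list(NULL, "CH01")))
  expect_warning(oo <- merge_strands(orphan), "orphan|partner|own")
  expect_equal(oo$sites$pos, 300L)
})

test_that("strand merging equals naive per-position summation on random input", {
  set.seed(12)
  n <- 100
  pos <- sort(sample(seq(1000, 5000, by = 2), n / 2))
  chrom <- rep("chr1", n)
  all_pos <- as.integer(c(pos, pos + 1L))
  strand <- rep(c("+", "-"), each = n / 2)
  meth <- matrix(rpois(n * 3, 10), n, 3,
                 dimnames = list(NULL, c("CH01", "CH02", "CH03")))
  unmeth <- matrix(rpois(n * 3, 10), n, 3,
                   dimnames = list(NULL, c("CH01", "CH02", "CH03")))
  out <- merge_strands(meth_obj(chrom, all_pos, strand, meth, unmeth))
  expect_equal(nrow(out$sites), n / 2)
  for (i in seq_along(pos)) {
    sel <- all_pos %in% c(pos[i], pos[i] + 1L)
    j <- which(out$sites$pos == pos[i])
    expect_equal(unname(out$meth[j, ]), unname(colSums(meth[sel, , drop = FALSE])))
    expect_equal(unname(out$unmeth[j, ]), unname(colSums(unmeth[sel, , drop = FALSE])))
  }
})

test_that("coverage filter masks low coverage and the inclusive top percentile", {
  # 10 CpGs, one child: coverages 9, 10, 11, ..., plus an extreme value
  cov <- c(9, 10, 15, 20, 25, 30, 30, 30, 30, 1000)
  meth <- matrix(as.integer(round(cov * 0.5)), 10, 1,
                 dimnames = list(NULL, "CH01"))
  unmeth <- matrix(as.integer(cov) - meth, 10, 1,
                   dimnames = list(NULL, "CH01"))
  mm <- meth_obj("chr1", seq(100L, by = 10L, length.out = 10), "*", meth, unmeth)
  out <- coverage_filter(mm, min_cov = 10, top_percentile = 99.9)
  # hand enumeration: cov 9 fails min_cov; the 99.9th percentile of these 10
  # values falls just below 1000, so only the 1000-coverage CpG is cut above
  expect_equal(unname(out$mask[, 1]),
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))

  # boundary: coverage exactly at the percentile cut is masked (inclusive)
  u <- matrix(30L, 100, 1, dimnames = list(NULL, "CH01"))
  uni <- meth_obj("chr1", seq(1L, by = 10L, length.out = 100), "*", u, u * 0L)
  ou <- coverage_filter(uni, min_cov = 10, top_percentile = 99.9)
  expect_true(all(ou$mask)) # all equal => all at the (degenerate) cut
})

test_that("intermediate CpG calls respect closed bounds and child threshold", {
  # target CpG plus 9 filler CpGs (fraction 0.9, staggered coverage) so the
  # per-child 99.9th-percentile cut lands above the target's coverage of 20
  fr_mat <- function(fr) {
    kids <- CHILDREN[seq_along(fr)]
    cov <- rbind(rep(20L, length(fr)),
                 matrix(rep(seq(30L, 70L, length.out = 9), length(fr)),
                        9, length(fr)))
    m <- rbind(as.integer(round(fr * 20L)),
               matrix(as.integer(round(cov[-1, ] * 0.9)), 9, length(fr)))
    dimnames(cov) <- dimnames(m) <- list(NULL, kids)
    meth_obj("chr1", seq(100L, by = 10L, length.out = 10), "*",
             m, cov - m)
  }
  m1 <- coverage_filter(fr_mat(c(0.5, 0.5, 0.5, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9)))
  expect_equal(nrow(intermediate_cpgs(m1)), 1) # exactly 3 children in range

  m0 <- coverage_filter(fr_mat(rep(0, 11)))
  expect_equal(nrow(intermediate_cpgs(m0)), 0)

  mb <- coverage_filter(fr_mat(rep(0.25, 11))) # closed interval boundary
  expect_equal(nrow(intermediate_cpgs(mb)), 1)

  expect_error(intermediate_cpgs(m1, low = 0.8, high = 0.2), "low")
})

test_that("intermediate_cpgs is monotone in its parameters", {
  set.seed(9)
  n <- 60
  cov <- matrix(rpois(n * 11, 30), n, 11, dimnames = list(NULL, CHILDREN))
  meth <- matrix(rbinom(n * 11, as.vector(cov), runif(n * 11)), n, 11,
                 dimnames = list(NULL, CHILDREN))
  mm <- coverage_filter(meth_obj("chr1", seq(100L, by = 2L, length.out = n), "*",
                                 meth, cov - meth))
  base <- nrow(intermediate_cpgs(mm, 0.25, 0.75, 3))
  expect_gte(nrow(intermediate_cpgs(mm, 0.20, 0.80, 3)), base) # wider interval
  expect_gte(nrow(intermediate_cpgs(mm, 0.25, 0.75, 2)), base) # fewer children
  expect_lte(nrow(intermediate_cpgs(mm, 0.25, 0.75, 5)), base)
})

test_that("group means match the naive per-group average", {
  m <- matrix(c(4L, 8L, 12L), 1, 3, dimnames = list(NULL, c("CH01", "CH02", "CH03")))
  u <- matrix(c(16L, 12L, 8L), 1, 3, dimnames = list(NULL, c("CH01", "CH02", "CH03")))
  mm <- meth_obj("chr1", 100L, "*", m, u)
  g <- c(CH01 = "A", CH02 = "B", CH03 = "B")
  out <- haplotype_group_means(mm, g)
  expect_equal(out$mean_A, 0.2)
  expect_equal(out$mean_B, 0.5) # (0.4 + 0.6) / 2
  one <- haplotype_group_means(mm, c(CH01 = "all", CH02 = "all", CH03 = "all"))
  expect_equal(one$mean_all, mean(c(0.2, 0.4, 0.6)))

  set.seed(77)
  n <- 20
  cov <- matrix(rpois(n * 11, 40) + 1L, n, 11, dimnames = list(NULL, CHILDREN))
  meth <- matrix(rbinom(n * 11, as.vector(cov), 0.5), n, 11,
                 dimnames = list(NULL, CHILDREN))
  mm2 <- meth_obj("chr1", seq(10L, by = 5L, length.out = n), "*", meth, cov - meth)
  grp <- setNames(rep(c("g1", "g2", "g3"), length.out = 11), CHILDREN)
  out2 <- haplotype_group_means(mm2, grp)
  fr <- meth / cov
  for (g2 in c("g1", "g2", "g3")) {
    expect_equal(out2[[paste0("mean_", g2)]],
                 rowMeans(fr[, names(grp)[grp == g2], drop = FALSE]))
  }
})

test_that("filter order is stable: percentile computed on raw coverage", {
  set.seed(13)
  cov <- matrix(c(rpois(99, 25), 500L), 100, 1, dimnames = list(NULL, "CH01"))
  meth <- matrix(rbinom(100, as.vector(cov), 0.5), 100, 1,
                 dimnames = list(NULL, "CH01"))
  mm <- meth_obj("chr1", seq(1L, by = 3L, length.out = 100), "*", meth, cov - meth)
  a <- coverage_filter(mm, min_cov = 10, top_percentile = 99)
  # direct computation: both rules on raw coverage, in either order
  cut <- quantile(cov[, 1], 0.99, names = FALSE)
  expect_equal(unname(a$mask[, 1]), unname(cov[, 1] < 10 | cov[, 1] >= cut))
})

test_that("methylation TSV reading and bedGraph export round-trip", {
  d <- file.path(tempdir(), "meth_io")
  sim <- simulate_study(truth_config(n_blocks = 1L, summits_per_block = 2L,
                                     seed = 21L), d)
  mm <- read_methylation(sim$files$methylation)
  expect_s3_class(mm, "hv_meth")
  expect_true(all(c("+", "-") %in% mm$sites$strand))
  merged <- merge_strands(mm)
  expect_equal(nrow(merged$sites), nrow(mm$sites) / 2)
  paths <- write_meth_bedgraph(coverage_filter(merged), tempdir())
  expect_true(all(file.exists(paths)))
})
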