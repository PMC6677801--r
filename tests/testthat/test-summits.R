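sc <- function(pos, pileup, chrom = "chr1") {
  data.frame(chrom = chrom, summit_pos = as.integer(pos), pileup = pileup,
             stringsAsFactors = FALSE)
}

test_that("merge_summits keeps distant summits and resolves overlaps by pileup", {
  r <- merge_summits(sc(c(1000, 1600), c(10, 5)))
  expect_equal(nrow(r), 2) # 600 bp apart: no overlap

  r2 <- merge_summits(sc(c(1000, 1100), c(10, 5)))
  expect_equal(nrow(r2), 1)
  expect_equal(r2$summit_pos, 1000) # higher pileup survives
  expect_equal(c(r2$start, r2$end), c(750, 1250))

  # chain of 5 summits 200 bp apart vs the brute-force greedy oracle
  chain <- sc(c(0, 200, 400, 600, 800) + 300, c(1, 9, 2, 8, 3))
  got <- merge_summits(chain)
  exp <- oracle_merge(chain)
  expect_equal(got$summit_pos, exp$summit_pos)
  expect_equal(got$pileup, exp$pileup)

  expect_error(merge_summits(sc(100, -1)), "negative pileup")
})

test_that("merge_summits output is non-overlapping, idempotent, equals oracle", {
  for (i in 1:20) {
    set.seed(100 + i)
    n <- sample(5:50, 1)
    s <- sc(sample(0:5000, n), runif(n, 0.1, 100),
            chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    r <- merge_summits(s)
    for (cc in unique(r$chrom)) {
      b <- r[r$chrom == cc, ]
      if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
    r2 <- merge_summits(data.frame(chrom = r$chrom, summit_pos = r$summit_pos,
                                   pileup = r$pileup))
    expect_equal(r2$summit_pos, r$summit_pos)
    o <- oracle_merge(s)
    expect_equal(r$summit_pos, o$summit_pos)
  }
})

test_that("filter_in_master_peaks keeps regions whose summit lies in a peak", {
  regions <- merge_summits(sc(1000, 10))
  keep <- filter_in_master_peaks(regions, data.frame(chrom = "chr1",
                                                     start = 900, end = 1400))
  expect_equal(nrow(keep), 1)
  drop <- filter_in_master_peaks(regions, data.frame(chrom = "chr1",
                                                     start = 2000, end = 2400))
  expect_equal(nrow(drop), 0)

  set.seed(7)
  rr <- merge_summits(sc(sample(0:20000, 10), runif(10, 1, 50)))
  pk <- data.frame(chrom = "chr1", start = c(0, 8000, 15000),
                   end = c(3000, 9000, 18000))
  got <- filter_in_master_peaks(rr, pk)
  naive <- rr[vapply(seq_len(nrow(rr)), function(i) {
    any(pk$start <= rr$summit_pos[i] & rr$summit_pos[i] < pk$end)
  }, logical(1)), ]
  expect_equal(got$summit_pos, naive$summit_pos)
})

test_that("reproducibility_filter applies the >= min_children rule monotonely", {
  master <- merge_summits(sc(c(1000, 5000), c(10, 8)))
  pk <- function(at) data.frame(chrom = "chr1", start = at - 100, end = at + 100)
  peaks <- c(lapply(1:3, function(i) pk(1000)), lapply(4:5, function(i) pk(5000)),
             lapply(6:11, function(i) pk(90000)))
  names(peaks) <- CHILDREN
  out <- reproducibility_filter(master, peaks, min_children = 3)
  expect_equal(out$summit_pos, 1000) # 3 supporters kept, 2 supporters removed
  expect_equal(out$supporters, "CH01,CH02,CH03")
  out1 <- reproducibility_filter(master, peaks, min_children = 1)
  expect_equal(nrow(out1), 2)
  # monotone in min_children
  sizes <- vapply(1:5, function(k) {
    nrow(reproducibility_filter(master, peaks, min_children = k))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(reproducibility_filter(master, peaks, min_children = 12),
               "exceeds")
})

test_that("count_reads uses half-open membership of shifted 5' positions", {
  master <- merge_summits(sc(1000, 10)) # [750, 1250)
  reads <- list(CH01 = data.frame(chrom = "chr1", pos = c(800, 900, 1249, 1250),
                                  strand = "+"))
  m <- count_reads(reads, master)
  expect_equal(unname(m$values[1, 1]), 3) # 1250 = end excluded

  # Tn5 shift applied: + strand +4, - strand -5
  reads2 <- list(CH01 = data.frame(chrom = "chr1", pos = c(746, 745, 1254, 1255),
                                   strand = c("+", "+", "-", "-")))
  m2 <- count_reads(reads2, master, apply_shift = TRUE)
  expect_equal(unname(m2$values[1, 1]), 2) # 750 and 1249 inside; 749, 1250 out

  expect_warning(count_reads(list(CH01 = data.frame(chrom = "chrUn", pos = 1,
                                                    strand = "+")), master),
                 "absent")
})

test_that("count_reads equals the naive membership oracle and conserves reads", {
  set.seed(42)
  master <- merge_summits(sc(seq(1000, 19000, by = 2000), runif(10, 1, 50)))
  pos <- sample(0:20000, 1000, replace = TRUE)
  reads <- list(CH01 = data.frame(chrom = "chr1", pos = pos, strand = "+"))
  m <- count_reads(reads, master)
  expect_equal(unname(m$values[, 1]), oracle_count(pos, "chr1", master))
  expect_lte(sum(m$values), 1000)
})

test_that("normalization removes depth and planted GC trends", {
  master <- merge_summits(sc(seq(1000, 39000, by = 2000), runif(20, 1, 50)))
  counts <- matrix(rep(c(10L, 40L, 90L, 20L, 50L), 4), ncol = 1)
  vals <- cbind(CH01 = counts[, 1], CH02 = 2L * counts[, 1])
  m <- structure(list(values = vals, regions = master, state = "raw", gc = NULL),
                 class = "hv_summit_counts")
  norm <- normalize_counts(m)
  expect_equal(norm$values[, "CH01"], norm$values[, "CH02"]) # depth removed
  expect_equal(norm$state, "normalized")
  expect_error(normalize_counts(norm), "already")

  zero <- m
  zero$values[, 2] <- 0L
  expect_error(normalize_counts(zero), "zero reads")

  # planted monotone log-linear GC bias is flattened to |slope| < 0.05
  set.seed(5)
  gc <- runif(20, 0.3, 0.7)
  base <- rpois(20, 200)
  biased <- round(base * 2^(3 * gc)) # slope 3 per unit GC on log2 scale
  m2 <- structure(list(values = cbind(CH01 = as.integer(biased),
                                      CH02 = as.integer(biased + 5L)),
                       regions = master, state = "raw", gc = NULL),
                  class = "hv_summit_counts")
  n2 <- normalize_counts(m2, gc = gc)
  slope_before <- coef(lm(log2(biased + 1) ~ gc))[2]
  slope_after <- coef(lm(n2$values[, 1] ~ gc))[2]
  expect_gt(abs(slope_before), 2)
  expect_lt(abs(slope_after), 0.05)
})

test_that("narrowPeak and summit BED readers round-trip generator output", {
  d <- file.path(tempdir(), "sum_io")
  sim <- simulate_study(truth_config(n_blocks = 1L, summits_per_block = 3L,
                                     seed = 9L), d)
  s <- read_summit_bed(sim$files$summits_rep1)
  expect_true(all(c("chrom", "summit_pos", "pileup") %in% names(s)))
  expect_true(all(s$pileup >= 0))
  np <- read_narrowpeak(sim$files$master_peaks)
  expect_true(all(np$end > np$start))
  expect_true(all(np$summit_pos >= np$start & np$summit_pos < np$end))
})
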