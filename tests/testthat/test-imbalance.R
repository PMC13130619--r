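test_that("exon splitting: breakpoint exon joins the retained side", {
  # 3' partner, 29 exons, breakpoint 18: groups 1-17 | 18-29
  v3 <- with_breakpoint(exon_count_vector("K", "tk", rep(5, 29)), 18, "three_prime")
  sp <- split_exons(v3)
  expect_identical(sp$group1, 1:17)
  expect_identical(sp$group2, 18:29)
  # 5' partner, breakpoint exon 2 of 7: {1,2} | {3..7}
  v5 <- with_breakpoint(exon_count_vector("C", "tc", rep(5, 7)), 2, "five_prime")
  sp5 <- split_exons(v5)
  expect_identical(sp5$group1, 1:2)
  expect_identical(sp5$group2, 3:7)
  # all-zero counts: both groups empty after exclusion
  vz <- with_breakpoint(exon_count_vector("Z", "tz", rep(0, 6)), 3, "five_prime")
  spz <- split_exons(vz)
  expect_length(spz$group1, 0)
  expect_length(spz$group2, 0)
  expect_identical(spz$zero_excluded, 1:6)
  # NA (unmeasured) exons excluded separately from zeros
  vm <- with_breakpoint(exon_count_vector("M", "tm", c(3, NA, 0, 8, 9)), 2, "five_prime")
  spm <- split_exons(vm)
  expect_identical(spm$missing_excluded, 2L)
  expect_identical(spm$zero_excluded, 3L)
})

test_that("rank-sum exact mode matches brute-force enumeration (ties included)", {
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5, 5), mode = "exact")$p_value, 1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 12, 14), mode = "exact")$p_value, 0.1)
  set.seed(3)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(c(0, 1, 2, 5, 50), n1, replace = TRUE)
    b <- sample(c(0, 1, 2, 5, 50), n2, replace = TRUE)
    for (alt in c("two_sided", "greater", "less")) {
      expect_equal(rank_sum_test(a, b, mode = "exact", alternative = alt)$p_value,
                   bf_ranksum_p(a, b, alt), tolerance = 1e-12,
                   info = paste(alt, paste(a, collapse = ","), "|", paste(b, collapse = ",")))
    }
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("two-sided p is invariant under swapping the groups", {
  set.seed(4)
  for (i in 1:25) {
    a <- rpois(sample(3:7, 1), 5); b <- rpois(sample(3:7, 1), 20)
    expect_equal(rank_sum_test(a, b, mode = "exact")$p_value,
                 rank_sum_test(b, a, mode = "exact")$p_value, tolerance = 1e-12)
  }
})

test_that("normal approximation is tie-corrected and close to exact", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    pe <- rank_sum_test(a, b, mode = "exact")$p_value
    pn <- rank_sum_test(a, b, mode = "normal_approx")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
  # auto switches on total size
  expect_identical(rank_sum_test(1:10, 2:11, mode = "auto")$method, "exact")
  expect_identical(rank_sum_test(1:11, 2:12, mode = "auto")$method, "normal_approx")
})

test_that("gene-level assessment enforces the minimum informative group size", {
  # drastic step at the breakpoint (scaled-down exon count keeps the
  # brute-force oracle enumerable): 9 low exons, 8 high exons
  v3 <- with_breakpoint(exon_count_vector("K", "tk", c(rep(10, 9), rep(1000, 8))),
                        10, "three_prime")
  r <- assess_gene(v3)
  expect_true(r$significant)
  expect_identical(r$direction, "group2_higher")
  expect_equal(r$p_value, bf_ranksum_p(rep(10, 9), rep(1000, 8)), tolerance = 1e-12)
  # 1 usable exon in a group: indeterminate, not "balanced"
  v1 <- with_breakpoint(exon_count_vector("G", "tg", c(7, 0, 5, 6, 8, 9)), 2, "five_prime")
  r1 <- assess_gene(v1)
  expect_identical(r1$status, "indeterminate")
  expect_false(r1$significant)
})

test_that("dual-gene rule: both partners must be significant", {
  flat <- function(n, b, side) with_breakpoint(exon_count_vector("G", "t", rep(20, n)), b, side)
  step5 <- with_breakpoint(exon_count_vector("G5", "t5", c(rep(800, 5), rep(10, 7))), 5, "five_prime")
  step3 <- with_breakpoint(exon_count_vector("G3", "t3", c(rep(10, 10), rep(900, 8))), 11, "three_prime")
  expect_true(assess_fusion(step5, step3)$overall_verdict)
  expect_false(assess_fusion(flat(12, 5, "five_prime"), flat(18, 11, "three_prime"))$overall_verdict)
  expect_false(assess_fusion(step5, flat(18, 11, "three_prime"))$overall_verdict)
  # indeterminate partner forces verdict FALSE with a reason
  tiny <- with_breakpoint(exon_count_vector("G5", "t5", c(5, 0, 6, 7)), 2, "five_prime")
  out <- assess_fusion(tiny, step3)
  expect_false(out$overall_verdict)
  expect_identical(out$status, "indeterminate")
})

test_that("direction requirement blocks significance in the unexpected direction", {
  # 3' partner with group1 higher: significant two-sided, but wrong direction
  v <- with_breakpoint(exon_count_vector("K", "tk", c(rep(900, 10), rep(10, 8))), 11, "three_prime")
  expect_true(assess_gene(v)$significant)
  expect_false(assess_gene(v, direction_required = TRUE)$significant)
})

test_that("count table reading pads missing exons and respects strand order", {
  cfg <- small_config(21, strand3 = "-")
  ref <- make_toy_reference(cfg)
  df <- simulate_exon_counts(ref)
  dir <- withr::local_tempdir()
  # drop one exon row of the 3' gene; rows are written in genomic order
  tx3 <- ref$meta$tx3_id
  drop_row <- which(df$transcript == tx3)[3]
  write.table(df[-drop_row, ], file.path(dir, "c.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cv <- read_exon_counts(file.path(dir, "c.tsv"), ref$models)
  v3 <- cv[[tx3]]
  expect_identical(sum(is.na(v3$counts)), 1L)  # padded as missing, not zero
  # counts are in transcript rank order: compare against interval lookup
  m3 <- ref$models[[tx3]]
  for (rk in c(1L, nrow(m3$exons))) {
    row <- df[df$transcript == tx3 & df$start == m3$exons$start[m3$exons$rank == rk] + 1L, ]
    expect_identical(v3$counts[rk], as.numeric(row$count))
  }
  expect_length(read_exon_counts({
    f <- file.path(dir, "empty.tsv")
    writeLines("gene\ttranscript\tcontig\tstart\tend\tstrand\tcount", f); f
  }, ref$models), 0)
})
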