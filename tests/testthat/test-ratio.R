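test_that("tissue totals and pairwise ratios match the direct computation", {
  tot <- tissue_totals(c(hemolymph = 66442, gut = 31312, ovary = 8759))
  expect_equal(format_ratio(tot$ratio["hemolymph", "gut"]), 2.1)
  expect_equal(format_ratio(tot$ratio["hemolymph", "ovary"], mode = "truncate"),
               7.5)
  expect_equal(format_ratio(tot$ratio["hemolymph", "ovary"]), 7.6)
  expect_equal(tot$ratio["gut", "gut"], 1)
  # reciprocal identity at full precision
  expect_lt(abs(tot$ratio["hemolymph", "gut"] * tot$ratio["gut", "hemolymph"] - 1),
            1e-9)
  expect_warning(z <- tissue_totals(c(a = 10, b = 0)), "zero total")
  expect_true(is.na(z$ratio["a", "b"]))

  sim <- make_fixture("tiny")
  tt <- tissue_totals(sim$counts, sim$samples)
  expect_equal(unname(tt$totals["gut"]),
               sum(sim$counts[, sim$samples$tissue == "gut"]))
})

test_that("housekeeping scaling is the ratio of summed housekeeping reads", {
  sheet <- sheet_for(c("hemolymph", "gut"), 1)
  m <- matrix(c(2900L, 1000L, 150L, 50L), 2, 2, byrow = TRUE,
              dimnames = list(c("hk1", "hk2"), sheet$sample_id))
  expect_equal(housekeeping_scaling(m, sheet, "hk1", "hemolymph", "gut")$factor, 2.9)
  expect_equal(housekeeping_scaling(m, sheet, "hk2", "hemolymph", "gut")$factor, 3.0)
  expect_equal(housekeeping_scaling(m, sheet, c("hk1", "hk2"),
                                    "hemolymph", "hemolymph")$factor, 1.0)
  z <- m; z[, 2] <- 0L
  expect_error(housekeeping_scaling(z, sheet, c("hk1", "hk2"), "hemolymph", "gut"),
               "impossible")
  expect_error(housekeeping_scaling(m, sheet, character(0), "hemolymph", "gut"),
               "empty")
})

test_that("scaling recovers the true titre multiplier on synthetic data", {
  cfg <- sim_config(n_genes = 600, n_housekeeping = 30,
                    tissues = data.frame(name = c("hemolymph", "gut"),
                                         titre = c(3, 1), depth = c(2e5, 2e5)),
                    seed = 9)
  sim <- simulate_counts(cfg)
  sc <- housekeeping_scaling(sim$counts, sim$samples, sim$truth$housekeeping,
                             "hemolymph", "gut")
  expect_lt(abs(sc$factor - 3) / 3, 0.10)
})

test_that("gene ratios apply scaling, the divisor-zero rule and the inclusive threshold", {
  sheet <- sheet_for(c("hemolymph", "gut"), 1)
  m <- matrix(c(29L, 5L,     # adjusted 10 vs 5 -> ratio exactly 2
                5L, 0L,      # zero divisor replaced by one
                29L, 10L,    # adjusted 10 vs 10 -> ratio 1
                0L, 0L), 4, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3", "g4"), sheet$sample_id))
  rt <- gene_ratios(m, sheet, "hemolymph", "gut", scaling = 2.9)
  expect_equal(rt$adjusted_sum_a[1], 10)
  expect_equal(rt$ratio_ab[1], 2)
  expect_equal(rt$call[1], "up_in_a")   # "2 or above 2" is inclusive
  expect_equal(rt$ratio_ab[2], (5 / 2.9) / 1)
  expect_equal(rt$ratio_ab[3], 1)
  expect_equal(rt$call[3], "not_up")
  expect_equal(rt$ratio_ab[4], 0)       # both sums zero
  expect_equal(rt$call[4], "not_up")
  expect_error(gene_ratios(m, sheet, "hemolymph", "gut", threshold = 0), "threshold")

  sc <- structure(list(numerator_tissue = "gut", denominator_tissue = "hemolymph",
                       factor = 2, housekeeping_genes_used = "g1"),
                  class = "scaling_factor")
  expect_error(gene_ratios(m, sheet, "hemolymph", "gut", scaling = sc), "numerator")
})

test_that("zero-rule asymmetry is confined to genes with a zero sum", {
  sim <- make_fixture("paper_like")
  rt <- gene_ratios(sim$counts, sim$samples, "hemolymph", "gut", scaling = 2.9)
  pos <- rt$sum_a > 0 & rt$sum_b > 0
  expect_gt(sum(pos), 1000)
  expect_lt(max(abs(rt$ratio_ab[pos] * rt$ratio_ba[pos] - 1)), 1e-9)
})

test_that("ranks are a strict total order with ties broken by gene id", {
  sheet <- sheet_for(c("a", "b"), 1)
  m <- matrix(c(4L, 2L, 8L, 4L, 2L, 1L, 1L, 5L), 4, 2,
              dimnames = list(c("gD", "gA", "gC", "gB"), sheet$sample_id))
  rt <- gene_ratios(m, sheet, "a", "b")
  expect_setequal(rt$rank_ab, 1:4)
  expect_setequal(rt$rank_ba, 1:4)
  # gD and gC tie at ratio 2: the alphabetically earlier id ranks first
  expect_lt(rt$rank_ab[rt$gene_id == "gC"], rt$rank_ab[rt$gene_id == "gD"])

  sim <- make_fixture("tiny")
  rs <- gene_ratios(sim$counts, sim$samples, "hemolymph", "gut", scaling = 2)
  expect_setequal(rs$rank_ab, seq_len(nrow(rs)))
})

test_that("equal-expression check flags reference genes away from ratio one", {
  sheet <- sheet_for(c("a", "b"), 1)
  m <- matrix(c(10L, 10L, 30L, 10L, 9L, 10L), 3, 2, byrow = TRUE,
              dimnames = list(c("r1", "r2", "r3"), sheet$sample_id))
  rt <- gene_ratios(m, sheet, "a", "b", scaling = 1)
  chk <- equal_expression_check(rt, c("r1", "r2", "r3"))
  expect_equal(chk$outliers$gene_id, "r2") # ratio 3 is outside (0.5, 2)
  expect_equal(chk$fraction_within, 2 / 3)
  expect_error(equal_expression_check(rt, "r9"), "missing")
})

test_that("housekeeping genes sit near ratio one under correct scaling", {
  sim <- make_fixture("paper_like")
  ra <- ratio_analysis(sim$counts, sim$samples, "hemolymph", "gut",
                       housekeeping = sim$truth$housekeeping)
  expect_gte(ra$reference_check$fraction_within, 0.95)
  expect_s3_class(ra, "ratio_analysis")
  expect_output(print(ra), "scaling factor")
  expect_output(summary(ra), "Top")
})
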