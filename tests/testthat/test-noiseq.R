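test_that("TMM factors are one for identical or purely rescaled samples", {
  m <- random_counts(50, 2, seed = 1)
  m[, 2] <- m[, 1]
  f <- tmm_factors(m)
  expect_equal(unname(f$factors), c(1, 1))

  m2 <- cbind(s1 = m[, 1], s2 = m[, 1] * 3L) # same composition, deeper library
  expect_equal(unname(tmm_factors(m2)$factors), c(1, 1))

  z <- m
  z[, 2] <- 0L
  expect_error(tmm_factors(z), "all-zero")
  expect_error(tmm_factors(m[, 1, drop = FALSE]), "two samples")
})

test_that("TMM equals the brute-force weighted trimmed-mean oracle", {
  for (s in 1:30) {
    set.seed(s)
    m <- random_counts(sample(8:20, 1), sample(2:4, 1), seed = s + 500)
    if (any(colSums(m) == 0)) next
    expect_equal(unname(tmm_factors(m)$factors), tmm_oracle(m),
                 tolerance = 1e-12)
  }
  # one composition-biased case: a gene dominating sample 2
  m <- random_counts(10, 2, seed = 42)
  m[1, 2] <- m[1, 2] + 5000L
  expect_equal(unname(tmm_factors(m)$factors), tmm_oracle(m), tolerance = 1e-12)
})

test_that("TMM agrees with an established independent implementation", {
  skip_if_not_installed("edgeR")
  for (s in 1:10) {
    m <- random_counts(60, 4, seed = s + 90)
    expect_equal(unname(tmm_factors(m)$factors),
                 unname(edgeR::calcNormFactors(m)), tolerance = 1e-10)
  }
})

test_that("the noise cloud has the documented size and invariances", {
  sheet <- sheet_for(c("a", "b"), 2)
  m <- random_counts(30, 4, seed = 3)
  colnames(m) <- sheet$sample_id
  f <- tmm_factors(m)
  noise <- noise_distribution(m, sheet, f, "a", "b")
  expect_equal(nrow(noise), 30 * 2) # one unordered pair per condition

  # identical replicates contribute only (0, 0) points
  m2 <- m
  m2[, 2] <- m2[, 1]
  m2[, 4] <- m2[, 3]
  f2 <- tmm_factors(m2)
  n2 <- noise_distribution(m2, sheet, f2, "a", "b")
  expect_true(all(n2$m == 0 & n2$d == 0))

  sheet1 <- sheet_for(c("a", "b"), 1)
  m1 <- m[, c(1, 3)]
  colnames(m1) <- sheet1$sample_id
  expect_error(noise_distribution(m1, sheet1, tmm_factors(m1), "a", "b"),
               ">= 2 replicates")

  # log ratios are invariant to a common scale factor on a pair
  x <- c(10, 40)
  expect_equal(log2((7 * x[1]) / (7 * x[2])), log2(x[1] / x[2]))
})

test_that("DE probability is exhaustive dominance counting", {
  noise <- data.frame(m = c(0.1, -0.2, 0.3, 1.0, 0.05),
                      d = c(1, 2, 3, 10, 0.5))
  # signal dominating exactly 3 of the 5 points (0.3 escapes on |m|)
  expect_equal(de_probability(0.25, 4, noise), 0.6)
  expect_equal(de_probability(0, 0, noise), 0)
  expect_equal(de_probability(5, 100, noise), 1)
  expect_error(de_probability(1, 1, noise[0, ]), "empty")

  for (s in 1:25) {
    set.seed(s)
    np <- sample(50:400, 1)
    noise <- data.frame(m = rnorm(np), d = rexp(np))
    M <- rnorm(20, sd = 2)
    D <- rexp(20, rate = 0.5)
    expect_equal(de_probability(M, D, noise),
                 de_prob_oracle(M, D, noise$m, noise$d))
  }
})

test_that("DE probability is monotone and label-swap invariant", {
  set.seed(8)
  noise <- data.frame(m = rnorm(500), d = rexp(500))
  M <- seq(0, 3, length.out = 30)
  p_m <- de_probability(M, rep(2, 30), noise)
  expect_true(all(diff(p_m) >= 0))
  p_d <- de_probability(rep(1, 30), seq(0, 8, length.out = 30), noise)
  expect_true(all(diff(p_d) >= 0))

  sim <- make_fixture("tiny")
  ab <- noise_de(sim$counts, sim$samples, "hemolymph", "gut")
  ba <- noise_de(sim$counts, sim$samples, "gut", "hemolymph")
  expect_equal(ab$table$prob, ba$table$prob)
  expect_equal(ab$table$M, -ba$table$M)
})

test_that("selection combines the probability cutoff with the fold-change filter", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    prob = c(0.96, 0.96, 0.90, 0.99),
                    log2fc = c(1.5, 0.5, 3.0, -2.0))
  out <- select_de(tab)
  expect_equal(out$call, c("up_in_a", "ns", "ns", "up_in_b"))
  s <- attr(out, "summary")
  expect_equal(s$total, s$up_in_a + s$up_in_b)
  expect_error(select_de(tab, prob_threshold = 1.2), "prob_threshold")
})

test_that("noise_de calls spiked genes and keeps the partition identity", {
  sim <- make_fixture("paper_like")
  de <- noise_de(sim$counts, sim$samples, "gut", "hemolymph")
  s <- de$summary
  expect_identical(s$total, s$up_in_a + s$up_in_b)
  expect_identical(s$total, sum(de$table$call != "ns"))
  # every call satisfies both thresholds
  called <- de$table[de$table$call != "ns", ]
  expect_true(all(called$prob >= 0.95 & abs(called$log2fc) > 1))
  # strongly spiked gut genes are found
  sp <- sim$truth$spikes
  gut_sp <- rownames(sim$counts)[sp$gene_index[sp$tissue == "gut"]]
  calls <- setNames(de$table$call, de$table$gene_id)
  expect_gt(mean(calls[gut_sp] == "up_in_a"), 0.8)
  expect_output(print(de), "up in gut")
})
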