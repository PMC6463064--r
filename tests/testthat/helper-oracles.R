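# Independent reference implementations used to check the package's
# numerical routines, written deliberately as plain loops over the method
# definitions rather than reusing any package internals.

# average rank by counting (matches the usual mid-rank convention for ties)
rank_by_counting <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- 0
    equal <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) below <- below + 1
      if (x[j] == x[i]) equal <- equal + 1
    }
    r[i] <- below + (equal + 1) / 2
  }
  r
}

# brute-force trimmed-mean-of-M-values factor for one sample against a
# reference: explicit M/A/weight computation, quantile trimming by mid-ranks,
# precision-weighted mean of the surviving M values
tmm_oracle_pair <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  m <- c(); a <- c(); w <- c()
  for (g in seq_along(obs)) {
    if (obs[g] > 0 && ref[g] > 0) {
      m <- c(m, log2((obs[g] / n_obs) / (ref[g] / n_ref)))
      a <- c(a, 0.5 * log2((obs[g] / n_obs) * (ref[g] / n_ref)))
      w <- c(w, (n_obs - obs[g]) / (n_obs * obs[g]) +
                (n_ref - ref[g]) / (n_ref * ref[g]))
    }
  }
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm <- rank_by_counting(m)
  ra <- rank_by_counting(a)
  num <- 0; den <- 0
  for (g in seq_len(n)) {
    if (rm[g] >= lo_m && rm[g] <= hi_m && ra[g] >= lo_a && ra[g] <= hi_a) {
      num <- num + m[g] / w[g]
      den <- den + 1 / w[g]
    }
  }
  2^(num / den)
}

# full oracle: drop empty genes, pick the reference by the upper-quartile
# rule, compute all pairwise factors, renormalize to geometric mean one
tmm_oracle <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  keep <- apply(counts, 1, function(r) any(r > 0))
  counts <- counts[keep, , drop = FALSE]
  lib <- colSums(counts)
  uq <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    uq[j] <- stats::quantile(counts[, j], 0.75) / lib[j]
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    f[j] <- tmm_oracle_pair(counts[, j], counts[, ref], trim_m, trim_a)
  f / exp(mean(log(f)))
}

# exhaustive dominance counting for the noise-distribution DE probability
de_prob_oracle <- function(M, D, noise_m, noise_d) {
  out <- numeric(length(M))
  for (g in seq_along(M)) {
    hits <- 0
    for (k in seq_along(noise_m)) {
      if (abs(noise_m[k]) < abs(M[g]) && noise_d[k] < D[g]) hits <- hits + 1
    }
    out[g] <- hits / length(noise_m)
  }
  out
}

# random count matrix with a realistic mix of abundances and zeros
random_counts <- function(n_genes, n_samples, seed, mean_scale = 50) {
  set.seed(seed)
  lam <- rlnorm(n_genes, log(mean_scale), 1.2)
  m <- matrix(rnbinom(n_genes * n_samples, size = 2,
                      mu = rep(lam, n_samples)),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

# minimal sample sheet for ad-hoc matrices
sheet_for <- function(tissues, reps) {
  data.frame(sample_id = paste0(rep(tissues, each = reps), "_", seq_len(reps)),
             tissue = rep(tissues, each = reps),
             replicate = rep(seq_len(reps), length(tissues)),
             stringsAsFactors = FALSE)
}
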