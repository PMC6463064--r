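#' Trimmed mean of M-values scaling factors
#'
#' Between-sample normalization factors by the trimmed mean of M-values
#' method: each sample is compared with a reference sample on per-gene
#' log-ratios (M) and log-abundances (A) of library-size-scaled counts; genes
#' in the extreme M and A quantiles, and genes with a zero in either sample,
#' are excluded; the factor is two to the power of the precision-weighted mean
#' of the surviving M values, and the factor vector is renormalized so its
#' geometric mean is one. Genes with zero counts in every sample are dropped
#' before anything else.
#'
#' @param counts Count matrix (>= 2 samples, each with a nonzero total).
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @param ref Reference sample id, or `"auto"` to pick the sample whose
#'   upper-quartile count/library-size is closest to the mean upper quartile.
#' @return List of class `tmm_factors`: `factors` (named, geometric mean 1),
#'   `reference_sample`, `trim_m`, `trim_a`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = "auto") {
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  counts <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  if (identical(ref, "auto")) {
    f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
    ref <- colnames(counts)[which.min(abs(f75 - mean(f75)))]
  }
  if (!ref %in% colnames(counts)) stop("unknown reference sample: ", ref)
  f <- vapply(colnames(counts), function(s) {
    .tmm_pair(counts[, s], counts[, ref], lib[s], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = f, reference_sample = ref,
                 trim_m = trim_m, trim_a = trim_a),
            class = "tmm_factors")
}

# one sample against the reference: weighted trimmed mean of M values
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  # delta-method precision weights for a log2 count ratio
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm <- rank(m); ra <- rank(a)
  keep <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
  2^(sum(m[keep] / w[keep], na.rm = TRUE) / sum(1 / w[keep], na.rm = TRUE))
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM scaling factors (reference:", x$reference_sample, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

# TMM-normalized expression on a common scale (reads per million of the
# effective library size)
.normalize_counts <- function(counts, factors) {
  lib <- colSums(counts)
  sweep(counts, 2, lib * factors$factors[colnames(counts)], "/") * 1e6
}

#' Within-condition replicate noise distribution
#'
#' Builds the noise cloud the signal is contrasted against: for every
#' unordered pair of replicates within each condition and every gene, the
#' absolute log2 ratio `|m|` and absolute difference `d` of TMM-normalized,
#' pseudocounted expression values. Pairs from both conditions are pooled.
#'
#' @param counts Count matrix.
#' @param sheet Sample sheet.
#' @param factors [tmm_factors()] for these samples.
#' @param condition_a,condition_b The two tissues/conditions compared.
#' @param pseudocount Added to normalized values before ratios and
#'   differences (default 0.5).
#' @return `data.frame` with columns `m` (absolute log2 ratio) and `d`
#'   (absolute difference); `n_genes x (choose(R_a,2) + choose(R_b,2))` rows.
#' @export
noise_distribution <- function(counts, sheet, factors, condition_a, condition_b,
                               pseudocount = 0.5) {
  x <- .normalize_counts(counts, factors) + pseudocount
  pairs_of <- function(cond) {
    s <- sheet$sample_id[sheet$tissue == cond]
    if (length(s) < 2) return(NULL)
    utils::combn(s, 2, simplify = FALSE)
  }
  pr <- c(pairs_of(condition_a), pairs_of(condition_b))
  if (!length(pr))
    stop("noise distribution needs >= 2 replicates in at least one condition")
  pieces <- lapply(pr, function(p) {
    data.frame(m = abs(log2(x[, p[1]] / x[, p[2]])),
               d = abs(x[, p[1]] - x[, p[2]]), row.names = NULL)
  })
  do.call(rbind, pieces)
}

#' Probability that a signal exceeds the replicate noise
#'
#' For each gene the probability is the fraction of noise points strictly
#' dominated by the gene's signal in both coordinates:
#' `prob_g = #\{(m, d) in noise : m < |M_g| and d < D_g\} / |noise|`.
#' Ties do not count as dominated, so a null signal at (0, 0) has
#' probability zero. The statistic is monotone non-decreasing in `|M|` and
#' in `D`.
#'
#' @param M Per-gene signed log2 fold change (signal).
#' @param D Per-gene absolute difference of normalized means (signal).
#' @param noise Noise cloud from [noise_distribution()].
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
de_probability <- function(M, D, noise) {
  if (!nrow(noise)) stop("empty noise distribution")
  am <- abs(noise$m)
  nd <- noise$d
  aM <- abs(M)
  n <- length(M)
  prob <- numeric(n)
  chunk <- 256L
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    hit <- outer(am, aM[idx], "<") & outer(nd, D[idx], "<")
    prob[idx] <- colMeans(hit)
  }
  prob
}

#' Apply significance and fold-change thresholds to a DE table
#'
#' A gene is called up in condition a when `prob >= prob_threshold` and
#' `log2fc > fc_threshold`, up in condition b when `prob >= prob_threshold`
#' and `log2fc < -fc_threshold`, and `ns` otherwise. With the defaults this is
#' a 0.95 probability cutoff (equivalently, a residual noise probability of at
#' most 0.05) and an absolute log2 fold change above 1, i.e. more than
#' two-fold.
#'
#' @param table `data.frame` with at least `prob` and `log2fc` columns.
#' @param prob_threshold Probability cutoff in (0, 1]; default 0.95.
#' @param fc_threshold Minimum absolute log2 fold change (exclusive);
#'   default 1.
#' @return The table with a `call` column, plus attribute `summary`: a list
#'   with `up_in_a`, `up_in_b`, `total`.
#' @export
select_de <- function(table, prob_threshold = 0.95, fc_threshold = 1) {
  if (!is.numeric(prob_threshold) || prob_threshold <= 0 || prob_threshold > 1)
    stop("prob_threshold must be in (0, 1]")
  if (fc_threshold < 0) stop("fc_threshold must be >= 0")
  sig <- table$prob >= prob_threshold
  table$call <- ifelse(sig & table$log2fc > fc_threshold, "up_in_a",
                ifelse(sig & table$log2fc < -fc_threshold, "up_in_b", "ns"))
  up_a <- sum(table$call == "up_in_a")
  up_b <- sum(table$call == "up_in_b")
  attr(table, "summary") <- list(up_in_a = up_a, up_in_b = up_b,
                                 total = up_a + up_b)
  table
}

#' Nonparametric noise-distribution differential expression
#'
#' The full between-tissue DE stage as one fit. Counts are TMM-normalized;
#' per-gene signal is the log2 ratio `M` and absolute difference `D` of the
#' two conditions' mean normalized expression (pseudocounted); the signal is
#' contrasted against the pooled within-condition replicate noise cloud, and
#' genes are called at a probability cutoff combined with a minimum absolute
#' log2 fold change.
#'
#' @param counts Count matrix (only the two conditions' samples are used).
#' @param sheet Sample sheet.
#' @param condition_a,condition_b Tissues compared; positive `M` means higher
#'   in `condition_a`.
#' @param prob_threshold,fc_threshold See [select_de()].
#' @param pseudocount Added to normalized values before logs (default 0.5).
#' @param trim_m,trim_a TMM trim fractions, see [tmm_factors()].
#' @return Object of class `noise_de`: `table` (gene_id, mean_a, mean_b, M, D,
#'   prob, log2fc, call), `summary`, `factors`, `noise`, `condition_a`,
#'   `condition_b`, thresholds.
#' @export
noise_de <- function(counts, sheet, condition_a, condition_b,
                     prob_threshold = 0.95, fc_threshold = 1,
                     pseudocount = 0.5, trim_m = 0.30, trim_a = 0.05) {
  keep <- sheet$tissue %in% c(condition_a, condition_b)
  sheet <- sheet[keep, , drop = FALSE]
  counts <- counts[, sheet$sample_id, drop = FALSE]
  if (!any(sheet$tissue == condition_a) || !any(sheet$tissue == condition_b))
    stop("both conditions must be present in the sample sheet")
  factors <- tmm_factors(counts, trim_m = trim_m, trim_a = trim_a)
  x <- .normalize_counts(counts, factors)
  sa <- sheet$sample_id[sheet$tissue == condition_a]
  sb <- sheet$sample_id[sheet$tissue == condition_b]
  mean_a <- rowMeans(x[, sa, drop = FALSE]) + pseudocount
  mean_b <- rowMeans(x[, sb, drop = FALSE]) + pseudocount
  M <- log2(mean_a / mean_b)
  D <- abs(mean_a - mean_b)
  noise <- noise_distribution(counts, sheet, factors, condition_a, condition_b,
                              pseudocount = pseudocount)
  prob <- de_probability(M, D, noise)
  table <- data.frame(gene_id = rownames(counts), mean_a = mean_a,
                      mean_b = mean_b, M = M, D = D, prob = prob,
                      log2fc = M, row.names = NULL, stringsAsFactors = FALSE)
  table <- select_de(table, prob_threshold, fc_threshold)
  structure(list(table = table, summary = attr(table, "summary"),
                 factors = factors, noise = noise,
                 condition_a = condition_a, condition_b = condition_b,
                 prob_threshold = prob_threshold, fc_threshold = fc_threshold,
                 pseudocount = pseudocount),
            class = "noise_de")
}

#' @export
print.noise_de <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Noise-distribution DE: %s vs %s\n", x$condition_a, x$condition_b))
  cat(sprintf("  %d genes, %d noise points\n", nrow(x$table), nrow(x$noise)))
  cat(sprintf("  called at prob >= %g, |log2FC| > %g: %d total (%d up in %s, %d up in %s)\n",
              x$prob_threshold, x$fc_threshold, s$total,
              s$up_in_a, x$condition_a, s$up_in_b, x$condition_b))
  invisible(x)
}

#' @export
#' @method summary noise_de
summary.noise_de <- function(object, n = 10, ...) {
  print(object)
  tab <- object$table[object$table$call != "ns", ]
  tab <- tab[order(-abs(tab$log2fc)), ]
  cat(sprintf("\nTop %d differentially expressed genes by |log2FC|:\n",
              min(n, nrow(tab))))
  print(utils::head(tab[, c("gene_id", "M", "D", "prob", "call")], n),
        row.names = FALSE)
  invisible(object)
}

#' @export
#' @method plot noise_de
plot.noise_de <- function(x, ...) {
  graphics::plot(abs(x$noise$m), x$noise$d, pch = 16, cex = 0.3,
                 col = "grey70", log = "y",
                 xlab = "|M| (log2 ratio)", ylab = "D (absolute difference)",
                 ...)
  tab <- x$table
  de <- tab$call != "ns"
  graphics::points(abs(tab$M)[!de], pmax(tab$D[!de], min(x$noise$d[x$noise$d > 0])),
                   pch = 16, cex = 0.4, col = "grey30")
  graphics::points(abs(tab$M)[de], tab$D[de], pch = 16, cex = 0.5, col = "firebrick")
  invisible(x)
}
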