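#' Per-tissue read totals and pairwise ratios
#'
#' Sums raw reads over genes and replicates within each tissue and forms all
#' ordered pairwise ratios at full precision. Display rounding is left to
#' [format_ratio()]; a tissue with zero total yields `NA` ratios with a
#' warning.
#'
#' @param x Either a count matrix (with `sheet`) or a named numeric vector /
#'   `data.frame(tissue, total)` of pre-summed per-tissue totals.
#' @param sheet Sample sheet, required when `x` is a count matrix.
#' @return List of class `tissue_totals` with `totals` (named vector) and
#'   `ratio` (matrix, `ratio[a, b] = total_a / total_b`).
#' @export
tissue_totals <- function(x, sheet = NULL) {
  if (is.matrix(x)) {
    if (is.null(sheet)) stop("a sample sheet is required with a count matrix")
    totals <- tapply(colSums(x)[sheet$sample_id], sheet$tissue, sum)
    totals <- totals[unique(sheet$tissue)]
  } else if (is.data.frame(x)) {
    if (!all(c("tissue", "total") %in% names(x)))
      stop("totals data.frame needs columns tissue, total")
    totals <- stats::setNames(as.numeric(x$total), x$tissue)
  } else if (is.numeric(x) && !is.null(names(x))) {
    totals <- x
  } else stop("x must be a count matrix, a totals data.frame, or a named vector")
  if (any(totals == 0))
    warning("tissue(s) with zero total reads; their ratios are undefined: ",
            paste(names(totals)[totals == 0], collapse = ", "))
  ratio <- outer(totals, totals, "/")
  ratio[!is.finite(ratio)] <- NA_real_
  structure(list(totals = totals, ratio = ratio), class = "tissue_totals")
}

#' Format a ratio for reporting
#'
#' One-decimal display of a full-precision ratio. `"round"` uses round-half-
#' even; `"truncate"` drops digits beyond the first decimal (some reported
#' ratios in the literature are truncated rather than rounded). Internal
#' comparisons always use full precision; this is display only.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @param mode `"round"` or `"truncate"`.
#' @return Numeric, formatted to `digits` decimals.
#' @export
format_ratio <- function(x, digits = 1, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  f <- 10^digits
  switch(mode,
         round = round(x, digits),
         truncate = trunc(x * f) / f)
}

#' @export
print.tissue_totals <- function(x, ...) {
  cat("Per-tissue read totals:\n")
  print(x$totals)
  cat("Pairwise ratios (rounded to one decimal):\n")
  print(format_ratio(x$ratio))
  invisible(x)
}

#' Housekeeping-based between-tissue scaling factor
#'
#' Uses summed housekeeping reads (ribosomal proteins, aminoacyl-tRNA ligases)
#' as a proxy for symbiont cell number: the factor is the ratio of the two
#' tissues' housekeeping read sums, at full precision. Dividing the numerator
#' tissue's per-gene read sums by this factor puts the two tissues on a common
#' per-cell scale.
#'
#' @param counts Count matrix.
#' @param sheet Sample sheet.
#' @param housekeeping Character vector of housekeeping gene ids.
#' @param tissue_a Numerator tissue (the one whose reads will be adjusted).
#' @param tissue_b Denominator tissue.
#' @return List of class `scaling_factor`: `numerator_tissue`,
#'   `denominator_tissue`, `factor`, `housekeeping_genes_used`.
#' @export
housekeeping_scaling <- function(counts, sheet, housekeeping, tissue_a, tissue_b) {
  if (!length(housekeeping)) stop("housekeeping gene list is empty")
  missing <- setdiff(housekeeping, rownames(counts))
  if (length(missing))
    stop("housekeeping genes missing from counts: ",
         paste(utils::head(missing, 5), collapse = ", "))
  hk_sum <- function(t) {
    s <- sheet$sample_id[sheet$tissue == t]
    if (!length(s)) stop("tissue not in sample sheet: ", t)
    sum(counts[housekeeping, s, drop = FALSE])
  }
  num <- hk_sum(tissue_a)
  den <- hk_sum(tissue_b)
  if (den == 0) stop("zero housekeeping reads in ", tissue_b, ": scaling impossible")
  if (num == 0) stop("zero housekeeping reads in ", tissue_a, ": scaling impossible")
  structure(list(numerator_tissue = tissue_a, denominator_tissue = tissue_b,
                 factor = num / den, housekeeping_genes_used = housekeeping),
            class = "scaling_factor")
}

#' @export
print.scaling_factor <- function(x, ...) {
  cat(sprintf("Housekeeping scaling %s / %s = %.4g (%d genes)\n",
              x$numerator_tissue, x$denominator_tissue, x$factor,
              length(x$housekeeping_genes_used)))
  invisible(x)
}

#' Housekeeping-adjusted per-gene read ratios between two tissues
#'
#' For each gene, pools replicate reads into `sum_a` and `sum_b`, divides the
#' numerator tissue's sum by the scaling factor (`adjusted_sum_a`), and forms
#' both directed ratios. A divisor of exactly zero is replaced by one (division
#' by zero is undefined; the replacement is applied to the divisor only, after
#' the scaling adjustment). Genes are ranked by descending ratio in each
#' direction, ties broken by ascending gene id, and called up-regulated at an
#' inclusive threshold (a ratio of exactly `threshold` is a call).
#'
#' @param counts Count matrix.
#' @param sheet Sample sheet.
#' @param tissue_a,tissue_b Tissues compared; `tissue_a` is adjusted.
#' @param scaling A [housekeeping_scaling()] result (its numerator tissue must
#'   be `tissue_a`) or a positive number.
#' @param threshold Up-regulation threshold on the ratio scale; default 2.
#' @return `data.frame` of class `ratio_table` with columns `gene_id`,
#'   `sum_a`, `sum_b`, `adjusted_sum_a`, `ratio_ab`, `ratio_ba`, `rank_ab`,
#'   `rank_ba`, `call` (`up_in_a` / `up_in_b` / `not_up`), and attributes
#'   `tissue_a`, `tissue_b`, `scaling_factor`, `threshold`.
#' @export
gene_ratios <- function(counts, sheet, tissue_a, tissue_b, scaling = 1,
                        threshold = 2) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  if (inherits(scaling, "scaling_factor")) {
    if (!identical(scaling$numerator_tissue, tissue_a))
      stop("scaling factor was computed with numerator ", scaling$numerator_tissue,
           ", not ", tissue_a)
    factor <- scaling$factor
  } else factor <- as.numeric(scaling)
  if (factor <= 0) stop("scaling factor must be > 0")
  sa <- sheet$sample_id[sheet$tissue == tissue_a]
  sb <- sheet$sample_id[sheet$tissue == tissue_b]
  if (!length(sa) || !length(sb)) stop("both tissues must be in the sample sheet")
  sum_a <- rowSums(counts[, sa, drop = FALSE])
  sum_b <- rowSums(counts[, sb, drop = FALSE])
  adj_a <- sum_a / factor
  ratio_ab <- adj_a / ifelse(sum_b == 0, 1, sum_b)
  ratio_ba <- sum_b / ifelse(adj_a == 0, 1, adj_a)
  gene_id <- rownames(counts)
  rank_ab <- integer(length(gene_id))
  rank_ab[order(-ratio_ab, gene_id)] <- seq_along(gene_id)
  rank_ba <- integer(length(gene_id))
  rank_ba[order(-ratio_ba, gene_id)] <- seq_along(gene_id)
  call <- ifelse(ratio_ab >= threshold, "up_in_a",
          ifelse(ratio_ba >= threshold, "up_in_b", "not_up"))
  out <- data.frame(gene_id = gene_id, sum_a = sum_a, sum_b = sum_b,
                    adjusted_sum_a = adj_a, ratio_ab = ratio_ab,
                    ratio_ba = ratio_ba, rank_ab = rank_ab, rank_ba = rank_ba,
                    call = call, row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("ratio_table", "data.frame"),
            tissue_a = tissue_a, tissue_b = tissue_b,
            scaling_factor = factor, threshold = threshold)
}

#' Check that reference genes sit near ratio one
#'
#' After correct titre scaling, constitutively expressed genes should attain
#' adjusted between-tissue ratios around one. This reports the reference genes
#' whose `ratio_ab` falls outside a tolerance band.
#'
#' @param ratios A [gene_ratios()] table.
#' @param reference_genes Gene ids expected to be equally expressed.
#' @param tolerance_band Ratio band counted as "around one"; a gene is within
#'   the band when `low <= ratio_ab < high` (the upper bound coincides with the
#'   default up-regulation threshold).
#' @return List with `outliers` (sub-table of flagged reference genes) and
#'   `fraction_within`.
#' @export
equal_expression_check <- function(ratios, reference_genes,
                                   tolerance_band = c(0.5, 2)) {
  missing <- setdiff(reference_genes, ratios$gene_id)
  if (length(missing))
    stop("reference genes missing from ratio table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ref <- ratios[ratios$gene_id %in% reference_genes, , drop = FALSE]
  within <- ref$ratio_ab >= tolerance_band[1] & ref$ratio_ab < tolerance_band[2]
  list(outliers = as.data.frame(ref[!within, , drop = FALSE]),
       fraction_within = mean(within))
}

#' Quantitative ratio analysis between two tissues
#'
#' The full housekeeping-scaled comparison as one fit: computes per-tissue
#' totals, the housekeeping scaling factor, the adjusted per-gene ratio table
#' with ranks and up-regulation calls, and the reference-gene sanity check.
#'
#' @inheritParams gene_ratios
#' @param housekeeping Housekeeping gene ids (used for scaling and as the
#'   default reference set).
#' @return Object of class `ratio_analysis`: `totals`, `scaling`, `table`,
#'   `reference_check`, `tissue_a`, `tissue_b`, `threshold`.
#' @export
ratio_analysis <- function(counts, sheet, tissue_a, tissue_b, housekeeping,
                           threshold = 2) {
  totals <- tissue_totals(counts, sheet)
  scaling <- housekeeping_scaling(counts, sheet, housekeeping, tissue_a, tissue_b)
  table <- gene_ratios(counts, sheet, tissue_a, tissue_b, scaling, threshold)
  check <- equal_expression_check(table, housekeeping)
  structure(list(totals = totals, scaling = scaling, table = table,
                 reference_check = check, tissue_a = tissue_a,
                 tissue_b = tissue_b, threshold = threshold),
            class = "ratio_analysis")
}

#' @export
print.ratio_analysis <- function(x, ...) {
  cat(sprintf("Quantitative ratio analysis: %s vs %s\n", x$tissue_a, x$tissue_b))
  cat(sprintf("  total-read ratio %s/%s: %.1f\n", x$tissue_a, x$tissue_b,
              format_ratio(x$totals$ratio[x$tissue_a, x$tissue_b])))
  cat(sprintf("  housekeeping scaling factor: %.3f\n", x$scaling$factor))
  tab <- table(x$table$call)
  cat(sprintf("  up in %s: %d; up in %s: %d (ratio >= %g)\n", x$tissue_a,
              sum(x$table$call == "up_in_a"), x$tissue_b,
              sum(x$table$call == "up_in_b"), x$threshold))
  cat(sprintf("  reference genes within band: %.1f%%\n",
              100 * x$reference_check$fraction_within))
  invisible(x)
}

#' @export
#' @method summary ratio_analysis
summary.ratio_analysis <- function(object, n = 10, ...) {
  print(object)
  tab <- object$table[order(object$table$rank_ab), ]
  cat(sprintf("\nTop %d genes by %s/%s ratio:\n", n, object$tissue_a, object$tissue_b))
  print(utils::head(tab[, c("gene_id", "sum_a", "sum_b", "adjusted_sum_a",
                            "ratio_ab", "rank_ab", "call")], n), row.names = FALSE)
  invisible(object)
}

#' @export
#' @method plot ratio_analysis
plot.ratio_analysis <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$rank_ab, log2(pmax(tab$ratio_ab, 2^-10)),
                 pch = 16, cex = 0.4,
                 col = ifelse(tab$call == "up_in_a", "firebrick",
                              ifelse(tab$call == "up_in_b", "steelblue", "grey40")),
                 xlab = sprintf("rank (%s/%s)", x$tissue_a, x$tissue_b),
                 ylab = "log2 adjusted ratio", ...)
  graphics::abline(h = log2(x$threshold), lty = 2)
  graphics::abline(h = -log2(x$threshold), lty = 2)
  invisible(x)
}
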