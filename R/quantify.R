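#' Transcripts per million from counts and gene lengths
#'
#' Length-normalizes raw counts to TPM: `rate_g = count_g / length_g`,
#' `tpm_g = 1e6 * rate_g / sum(rate)` within each sample, so every sample with
#' at least one nonzero count sums to exactly one million. The annotated length
#' is used as the effective length (no fragment-length correction).
#'
#' @param counts Integer matrix, genes x samples, rownames = gene ids.
#' @param genes Gene catalog `data.frame` with `gene_id` and `length`.
#' @return Numeric matrix of TPM values with the same dimnames as `counts`.
#' @export
compute_tpm <- function(counts, genes) {
  validate_counts(counts, genes)
  len <- genes$length[match(rownames(counts), genes$gene_id)]
  rate <- counts / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("samples with no mapped reads get all-zero TPM: ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Per-tissue average log2(TPM + pseudocount)
#'
#' @param tpm TPM matrix from [compute_tpm()].
#' @param sheet Sample sheet mapping samples to tissues.
#' @param pseudocount Added inside the log to keep zeros finite; must be > 0.
#' @return Numeric matrix, genes x tissues (tissue order as first seen in the
#'   sheet), of mean log2(TPM + pseudocount) over replicates.
#' @export
average_log2tpm <- function(tpm, sheet, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  tissues <- unique(sheet$tissue)
  out <- vapply(tissues, function(t) {
    s <- sheet$sample_id[sheet$tissue == t]
    rowMeans(log2(tpm[, s, drop = FALSE] + pseudocount))
  }, numeric(nrow(tpm)))
  dimnames(out) <- list(rownames(tpm), tissues)
  out
}

#' Replicate-supported presence calls
#'
#' A gene is called present in a tissue when it has a nonzero raw count in at
#' least `min_replicates` of that tissue's replicates (the 2-of-3 rule at the
#' defaults of a triplicated design). Presence uses raw counts, not TPM, so
#' the call is independent of library composition.
#'
#' @param counts Count matrix.
#' @param sheet Sample sheet.
#' @param min_replicates Minimum number of expressing replicates.
#' @return Logical matrix, genes x tissues, with attribute `n_expressed`
#'   giving the per-tissue number of present genes.
#' @export
call_presence <- function(counts, sheet, min_replicates = 2) {
  tissues <- unique(sheet$tissue)
  reps <- table(sheet$tissue)
  if (min_replicates > max(reps))
    stop("min_replicates exceeds the number of replicates of every tissue")
  present <- vapply(tissues, function(t) {
    s <- sheet$sample_id[sheet$tissue == t]
    rowSums(counts[, s, drop = FALSE] > 0) >= min_replicates
  }, logical(nrow(counts)))
  dimnames(present) <- list(rownames(counts), tissues)
  attr(present, "n_expressed") <- colSums(present)
  present
}

#' Core transcriptome across tissues
#'
#' Intersection of per-tissue presence sets: the genes expressed in every
#' tissue under comparison.
#'
#' @param presence Logical presence matrix from [call_presence()].
#' @param tissues Tissues to intersect over (default: all columns).
#' @return Character vector of gene ids.
#' @export
core_transcriptome <- function(presence, tissues = colnames(presence)) {
  unknown <- setdiff(tissues, colnames(presence))
  if (length(unknown))
    stop("unknown tissue(s): ", paste(unknown, collapse = ", "))
  rownames(presence)[rowSums(presence[, tissues, drop = FALSE]) == length(tissues)]
}

#' Quantify expression for a whole dataset
#'
#' Convenience wrapper running [compute_tpm()], [average_log2tpm()],
#' [call_presence()] and [core_transcriptome()] in one call.
#'
#' @param counts Count matrix.
#' @param genes Gene catalog.
#' @param sheet Sample sheet.
#' @param pseudocount Pseudocount for the log2 averaging.
#' @param min_replicates Presence rule.
#' @return List of class `expression_set` with elements `tpm`, `avg_log2tpm`,
#'   `presence`, `core`.
#' @export
quantify_expression <- function(counts, genes, sheet, pseudocount = 1,
                                min_replicates = 2) {
  tpm <- compute_tpm(counts, genes)
  avg <- average_log2tpm(tpm, sheet, pseudocount)
  pres <- call_presence(counts, sheet, min_replicates)
  structure(list(tpm = tpm, avg_log2tpm = avg, presence = pres,
                 core = core_transcriptome(pres)),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  ne <- attr(x$presence, "n_expressed")
  cat(sprintf("Expression set: %d genes, %d samples, %d tissues\n",
              nrow(x$tpm), ncol(x$tpm), ncol(x$presence)))
  cat("  expressed per tissue:",
      paste(sprintf("%s=%d", names(ne), ne), collapse = ", "), "\n")
  cat(sprintf("  core transcriptome: %d genes\n", length(x$core)))
  invisible(x)
}
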