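#' Per-tissue COG-category summary of expressed genes
#'
#' Counts present genes per COG functional letter class and tissue; genes
#' without an assigned category are counted under `"NA"`. Per-tissue column
#' sums equal the tissue's number of expressed genes.
#'
#' @param presence Presence matrix from [call_presence()].
#' @param genes Gene catalog with a `cog_category` column.
#' @return Integer matrix, COG categories (rows, `"NA"` last) x tissues.
#' @export
category_summary <- function(presence, genes) {
  cog <- genes$cog_category[match(rownames(presence), genes$gene_id)]
  cog[is.na(cog) | cog == ""] <- "NA"
  cats <- c(sort(setdiff(unique(cog), "NA")), "NA")
  out <- matrix(0L, length(cats), ncol(presence),
                dimnames = list(cats, colnames(presence)))
  for (t in colnames(presence)) {
    tab <- table(factor(cog[presence[, t]], levels = cats))
    out[, t] <- as.integer(tab)
  }
  out
}

#' Named pathway gene sets from a gene catalog
#'
#' Builds pathway gene sets from the catalog's `pathway_tags` column (each
#' gene may carry several `;`/`,`-separated tags). These are the functional
#' systems tracked in the tissue reports: flagellar assembly, chemotaxis,
#' secretion systems, type IV pili, nitrogen fixation, and CAZy
#' pectin/rhamnogalacturonan families.
#'
#' @param genes Gene catalog.
#' @return Named list of gene-id character vectors (tags with no member genes
#'   are absent).
#' @export
default_pathway_sets <- function(genes) {
  tags <- strsplit(genes$pathway_tags, "[;,] *")
  long <- data.frame(gene_id = rep(genes$gene_id, lengths(tags)),
                     tag = unlist(tags), stringsAsFactors = FALSE)
  long <- long[long$tag != "", , drop = FALSE]
  split(long$gene_id, long$tag)
}

#' Per-tissue pathway presence and completeness
#'
#' For each named gene set, reports which member genes are present in each
#' tissue and the per-tissue completeness fraction (present members / set
#' size), the table behind pathway presence/absence displays.
#'
#' @param presence Presence matrix from [call_presence()].
#' @param sets Named list of gene-id vectors (e.g. [default_pathway_sets()]).
#' @return List with `members` (`data.frame`: pathway, gene_id, one logical
#'   column per tissue) and `completeness` (matrix, pathway x tissue).
#' @export
pathway_presence <- function(presence, sets) {
  if (!length(sets)) stop("no pathway gene sets given")
  unknown <- setdiff(unlist(sets), rownames(presence))
  if (length(unknown))
    stop("pathway member gene(s) not in the gene catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  members <- do.call(rbind, lapply(names(sets), function(nm) {
    data.frame(pathway = nm, gene_id = sets[[nm]],
               presence[sets[[nm]], , drop = FALSE],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  completeness <- t(vapply(sets, function(g) {
    colMeans(presence[g, , drop = FALSE])
  }, numeric(ncol(presence))))
  list(members = members, completeness = completeness)
}

#' Cross-method functional-marker report
#'
#' Compares the up-regulation calls of the quantitative ratio analysis and the
#' noise-distribution DE analysis on the same tissue pair and, per direction,
#' partitions the called genes into those found by the ratio analysis only, by
#' the DE analysis only, and by both. The three sets are disjoint and their
#' union is the union of both methods' calls.
#'
#' @param ratio_calls A [gene_ratios()] / [ratio_analysis()] table.
#' @param de_calls A [noise_de()] fit or its table.
#' @return List of class `marker_report`: one element per direction
#'   (`up_in_a`, `up_in_b`), each with `both`, `ratio_only`, `de_only`.
#' @export
marker_report <- function(ratio_calls, de_calls) {
  if (inherits(ratio_calls, "ratio_analysis")) ratio_calls <- ratio_calls$table
  if (inherits(de_calls, "noise_de")) de_calls <- de_calls$table
  if (!setequal(ratio_calls$gene_id, de_calls$gene_id))
    stop("ratio and DE analyses were run on different gene catalogs")
  one <- function(dir) {
    r <- ratio_calls$gene_id[ratio_calls$call == dir]
    d <- de_calls$gene_id[de_calls$call == dir]
    list(both = sort(intersect(r, d)),
         ratio_only = sort(setdiff(r, d)),
         de_only = sort(setdiff(d, r)))
  }
  structure(list(up_in_a = one("up_in_a"), up_in_b = one("up_in_b")),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat("Proposed functional markers (by supporting analysis):\n")
  for (dir in names(x)) {
    s <- x[[dir]]
    cat(sprintf("  %s: both=%d, ratio only=%d, DE only=%d\n", dir,
                length(s$both), length(s$ratio_only), length(s$de_only)))
  }
  invisible(x)
}

#' Run the full tissue-comparison pipeline
#'
#' Drives every stage from a configuration list (or YAML path): load or
#' simulate inputs, quantify (TPM, average log2TPM, presence, core), run the
#' quantitative ratio analysis and the noise-distribution DE analysis on a
#' tissue pair, and write all result tables plus a run log. Outputs are
#' deterministic for a fixed config and seed.
#'
#' Config keys: either `inputs: {counts, genes, samples}` (file paths) or
#' `simulate: {fixture: tiny|paper_like}` (optionally `seed`); `comparison:
#' {tissue_a, tissue_b}`; optional `thresholds: {ratio, prob, log2fc}`,
#' `pseudocount`, `min_replicates`, `housekeeping` (path to a gene-id list,
#' default: catalog genes flagged `is_housekeeping`), and `outdir`.
#'
#' @param config Named list or YAML file path.
#' @param outdir Output directory (overrides `config$outdir`).
#' @return Invisibly, a list with every stage's result object.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  dat <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim <- make_fixture(config$simulate$fixture %||% "paper_like",
                          seed = config$simulate$seed)
      list(counts = sim$counts, genes = sim$genes, sheet = sim$samples)
    } else {
      genes <- read_gene_models(config$inputs$genes)
      sheet <- read_sample_sheet(config$inputs$samples)
      list(counts = read_counts(config$inputs$counts, sheet),
           genes = genes, sheet = sheet)
    }
  })
  hk <- stage("housekeeping", {
    if (!is.null(config$housekeeping)) readLines(config$housekeeping)
    else dat$genes$gene_id[dat$genes$is_housekeeping]
  })
  th <- config$thresholds %||% list()
  ratio_thr <- th$ratio %||% 2
  prob_thr <- th$prob %||% 0.95
  fc_thr <- th$log2fc %||% 1
  cmp <- config$comparison %||% list(tissue_a = "hemolymph", tissue_b = "gut")

  quant <- stage("quantify", quantify_expression(
    dat$counts, dat$genes, dat$sheet,
    pseudocount = config$pseudocount %||% 1,
    min_replicates = config$min_replicates %||% 2))
  ratio <- stage("ratio", ratio_analysis(
    dat$counts, dat$sheet, cmp$tissue_a, cmp$tissue_b, hk, threshold = ratio_thr))
  de <- stage("noise_de", noise_de(
    dat$counts, dat$sheet, cmp$tissue_a, cmp$tissue_b,
    prob_threshold = prob_thr, fc_threshold = fc_thr))
  markers <- stage("markers", marker_report(ratio, de))
  cats <- stage("report", category_summary(quant$presence, dat$genes))
  sets <- default_pathway_sets(dat$genes)
  paths <- if (length(sets)) stage("report", pathway_presence(quant$presence, sets))

  stage("write", {
    w <- function(d, f) write_table(d, file.path(outdir, f))
    w(data.frame(gene_id = rownames(quant$tpm), quant$tpm, check.names = FALSE), "tpm.tsv")
    w(data.frame(gene_id = rownames(quant$avg_log2tpm), quant$avg_log2tpm,
                 check.names = FALSE), "avg_log2tpm.tsv")
    w(data.frame(gene_id = rownames(quant$presence), quant$presence,
                 check.names = FALSE), "presence.tsv")
    writeLines(quant$core, file.path(outdir, "core.txt"))
    w(ratio$table, "ratio_table.tsv")
    jsonlite::write_json(list(numerator_tissue = ratio$scaling$numerator_tissue,
                              denominator_tissue = ratio$scaling$denominator_tissue,
                              factor = ratio$scaling$factor,
                              n_housekeeping = length(hk)),
                         file.path(outdir, "scaling.json"), auto_unbox = TRUE,
                         digits = NA)
    w(de$table, "de_table.tsv")
    jsonlite::write_json(de$summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    w(data.frame(category = rownames(cats), cats, check.names = FALSE),
      "cog_summary.tsv")
    if (!is.null(paths)) w(paths$members, "pathway_presence.tsv")
    mk <- do.call(rbind, lapply(names(markers), function(dir) {
      s <- markers[[dir]]
      data.frame(direction = dir,
                 gene_id = c(s$both, s$ratio_only, s$de_only),
                 support = rep(c("both", "ratio_only", "de_only"),
                               c(length(s$both), length(s$ratio_only), length(s$de_only))),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(mk, file.path(outdir, "markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("endosym %s on %s", as.character(utils::packageVersion("endosym")),
                         R.version.string),
                 sprintf("seed: %s", config$simulate$seed %||% "NA"),
                 sprintf("comparison: %s vs %s", cmp$tissue_a, cmp$tissue_b),
                 sprintf("thresholds: ratio>=%g, prob>=%g, |log2fc|>%g",
                         ratio_thr, prob_thr, fc_thr)),
               file.path(outdir, "run_log.txt"))
  })
  invisible(list(data = dat, quant = quant, ratio = ratio, de = de,
                 markers = markers, categories = cats, pathways = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
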