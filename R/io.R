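#' Read a gene catalog from GTF or TSV
#'
#' Builds the per-gene catalog (id, coding length, annotation) used by TPM
#' quantification and reporting. For GTF input the length of a gene is the sum
#' of its CDS segment lengths under 1-based inclusive coordinates, with
#' overlapping segments merged before summing; exon features are used for genes
#' without CDS rows, and bare gene/transcript rows as a last resort. Strand is
#' ignored (lengths are strand-invariant). Gene identifiers are taken from the
#' `gene_id` attribute, falling back to `locus_tag`.
#'
#' TSV input must carry the header
#' `gene_id, length, product, cog_category, pathway_tags, is_housekeeping`;
#' `pathway_tags` is a `;`- or `,`-separated list. Missing annotation fields
#' default to empty/`FALSE` so partially annotated draft-genome catalogs load.
#'
#' @param path Path to the catalog file.
#' @param format `"gtf"`, `"tsv"`, or `"auto"` (guessed from the extension).
#' @return A `data.frame` with columns `gene_id`, `length`, `product`,
#'   `cog_category`, `pathway_tags`, `is_housekeeping`, one row per gene.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene catalog file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff|gff3)$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  genes <- switch(format,
    gtf = .gene_models_from_gtf(path),
    tsv = .gene_models_from_tsv(path),
    stop("unknown gene catalog format: ", format)
  )
  validate_gene_models(genes)
  genes
}

.gene_models_from_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  need <- c("gene_id", "length")
  if (!all(need %in% names(d)))
    stop("gene catalog TSV must have at least columns: ", paste(need, collapse = ", "))
  opt <- function(col, default) if (col %in% names(d)) d[[col]] else rep(default, nrow(d))
  data.frame(
    gene_id = d$gene_id,
    length = as.integer(d$length),
    product = opt("product", ""),
    cog_category = .empty_to_na(opt("cog_category", NA_character_)),
    pathway_tags = opt("pathway_tags", ""),
    is_housekeeping = .parse_logical(opt("is_housekeeping", "false")),
    stringsAsFactors = FALSE
  )
}

.gene_models_from_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  id <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else rep(NA_character_, length(gr))
  if ("locus_tag" %in% names(mc)) {
    lt <- as.character(mc$locus_tag)
    id <- ifelse(is.na(id) | id == "", lt, id)
  }
  if (anyNA(id) || any(id == ""))
    stop("GTF records without a gene_id or locus_tag attribute")
  type <- as.character(mc$type)
  pick <- if (any(type == "CDS")) type == "CDS"
          else if (any(type == "exon")) type == "exon"
          else rep(TRUE, length(gr))
  gr <- gr[pick]
  id <- id[pick]
  # merge overlapping segments per gene, then sum widths (1-based inclusive)
  per_gene <- GenomicRanges::reduce(S4Vectors::split(GenomicRanges::granges(gr), id),
                                    ignore.strand = TRUE)
  len <- vapply(GenomicRanges::width(per_gene), sum, integer(1))
  prod <- rep("", length(len))
  mc_kept <- S4Vectors::mcols(gr)
  if ("product" %in% names(mc_kept)) {
    first <- !duplicated(id)
    prod_map <- as.character(mc_kept$product)[first]
    names(prod_map) <- id[first]
    prod <- ifelse(is.na(prod_map[names(len)]), "", prod_map[names(len)])
  }
  data.frame(
    gene_id = names(len),
    length = as.integer(len),
    product = unname(prod),
    cog_category = NA_character_,
    pathway_tags = "",
    is_housekeeping = FALSE,
    stringsAsFactors = FALSE
  )
}

.empty_to_na <- function(x) {
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

.parse_logical <- function(x) {
  tolower(trimws(x)) %in% c("true", "t", "1", "yes")
}

#' Validate a gene catalog
#'
#' @param genes A gene catalog `data.frame` as from [read_gene_models()].
#' @return The catalog, invisibly, after checking uniqueness of `gene_id` and
#'   positivity of `length`.
#' @export
validate_gene_models <- function(genes) {
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene catalog: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (any(is.na(genes$length)) || any(genes$length <= 0))
    stop("gene lengths must be positive integers")
  invisible(genes)
}

#' Read a sample sheet
#'
#' @param path TSV with header `sample_id, tissue, replicate`.
#' @return A validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "replicate")
  if (!all(need %in% names(d)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  d$replicate <- as.integer(d$replicate)
  validate_sample_sheet(d[need])
  d[need]
}

#' Validate a sample sheet
#'
#' Checks that sample ids and (tissue, replicate) pairs are unique and each
#' tissue has at least one replicate.
#'
#' @param sheet A sample sheet `data.frame`.
#' @return The sheet, invisibly.
#' @export
validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  key <- paste(sheet$tissue, sheet$replicate)
  if (anyDuplicated(key))
    stop("duplicate (tissue, replicate) pair in sample sheet")
  if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1))
    stop("replicate must be a positive integer")
  invisible(sheet)
}

#' Read a raw count matrix
#'
#' Reads a tab-separated gene-by-sample table of raw read counts and validates
#' it against a sample sheet. Columns are reordered to follow the sheet; file
#' columns absent from the sheet are dropped with a warning, sheet samples
#' absent from the file are an error.
#'
#' @param path TSV with a `gene_id` first column and one column per sample.
#' @param sheet Sample sheet `data.frame` (see [read_sample_sheet()]).
#' @return Integer matrix, rows = genes, columns = samples in sheet order.
#' @export
read_counts <- function(path, sheet) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "gene_id") names(d)[1] <- "gene_id"
  if (anyDuplicated(d$gene_id)) stop("duplicate gene_id in count table")
  missing <- setdiff(sheet$sample_id, names(d))
  if (length(missing))
    stop("samples in sheet missing from count table: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(d)[-1], sheet$sample_id)
  if (length(extra))
    warning("dropping count columns not in sample sheet: ", paste(extra, collapse = ", "))
  m <- as.matrix(d[, sheet$sample_id, drop = FALSE])
  rownames(m) <- d$gene_id
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Validate a count matrix
#'
#' @param counts Numeric matrix of raw counts.
#' @param genes Optional gene catalog; if given, every count row must be in it.
#' @return The matrix, invisibly.
#' @export
validate_counts <- function(counts, genes = NULL) {
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("count matrix has missing cells")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("non-integer counts are not allowed")
  if (!is.null(genes)) {
    unknown <- setdiff(rownames(counts), genes$gene_id)
    if (length(unknown))
      stop("genes in counts missing from catalog: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  invisible(counts)
}

#' Write a result table as TSV
#'
#' Tab-separated, header row, deterministic row order: ascending by the first
#' rank-like column if one exists (a column named `rank` or starting with
#' `rank`), otherwise ascending by `gene_id` when present. Numeric columns are
#' written with full precision so that a re-read reproduces every cell.
#'
#' @param table A `data.frame` (a classed result table is accepted).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(table, path) {
  table <- as.data.frame(table)
  rankcol <- grep("^rank", names(table), value = TRUE)
  if (length(rankcol)) {
    table <- table[order(table[[rankcol[1]]]), , drop = FALSE]
  } else if ("gene_id" %in% names(table)) {
    table <- table[order(table$gene_id), , drop = FALSE]
  }
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write table to ", path)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' @param path YAML file describing inputs or a `simulate` block, thresholds,
#'   gene sets and the seed (see [run_pipeline()]).
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Validate a full input set
#'
#' Cross-checks a gene catalog, sample sheet and count matrix and prints a
#' one-paragraph summary (genes, samples, tissues, read totals).
#'
#' @param counts Count matrix.
#' @param genes Gene catalog.
#' @param sheet Sample sheet.
#' @return Invisibly, a list with per-tissue totals.
#' @export
validate_inputs <- function(counts, genes, sheet) {
  validate_gene_models(genes)
  validate_sample_sheet(sheet)
  validate_counts(counts, genes)
  if (!setequal(colnames(counts), sheet$sample_id))
    stop("count columns and sample sheet disagree")
  tt <- tapply(colSums(counts)[sheet$sample_id], sheet$tissue, sum)
  message(sprintf("%d genes x %d samples; tissues: %s; reads per tissue: %s",
                  nrow(counts), ncol(counts),
                  paste(unique(sheet$tissue), collapse = ", "),
                  paste(sprintf("%s=%d", names(tt), tt), collapse = ", ")))
  invisible(list(tissue_totals = tt))
}
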