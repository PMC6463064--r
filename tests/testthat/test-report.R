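test_that("COG summaries partition the expressed genes per tissue", {
  sim <- make_fixture("tiny")
  p <- call_presence(sim$counts, sim$samples)
  cats <- category_summary(p, sim$genes)
  expect_equal(unname(colSums(cats)), unname(attr(p, "n_expressed")))
  expect_true("NA" %in% rownames(cats))

  genes <- sim$genes[1, , drop = FALSE]
  genes$cog_category <- "J"
  p1 <- matrix(TRUE, 1, 1, dimnames = list(genes$gene_id, "gut"))
  expect_equal(category_summary(p1, genes)["J", "gut"], 1L)
  genes$cog_category <- NA
  expect_equal(category_summary(p1, genes)["NA", "gut"], 1L)
})

test_that("pathway presence reports membership and completeness", {
  p <- matrix(c(TRUE, TRUE, FALSE,
                TRUE, FALSE, FALSE,
                TRUE, TRUE, TRUE), 3, 3, byrow = TRUE,
              dimnames = list(c("fliN", "fliG", "flhD"),
                              c("hemolymph", "gut", "ovary")))
  sets <- list(flagellum = c("fliN", "fliG", "flhD"))
  pp <- pathway_presence(p, sets)
  expect_equal(pp$completeness["flagellum", "hemolymph"], 1.0)
  expect_equal(pp$completeness["flagellum", "ovary"], 1 / 3)
  # only fliN-like survivors show up in the low-titre tissue
  ov <- pp$members[pp$members$ovary, "gene_id"]
  expect_equal(ov, "flhD")
  expect_error(pathway_presence(p, list(x = "nope")), "not in the gene catalog")
  expect_error(pathway_presence(p, list()), "no pathway")
})

test_that("synthetic catalogs carry usable default pathway sets", {
  sim <- make_fixture("paper_like")
  sets <- default_pathway_sets(sim$genes)
  expect_true(all(c("flagellum", "chemotaxis", "nitrogen_fixation") %in% names(sets)))
  p <- call_presence(sim$counts, sim$samples)
  pp <- pathway_presence(p, sets)
  expect_true(all(pp$completeness >= 0 & pp$completeness <= 1))
})

test_that("marker reports partition calls into both / ratio-only / DE-only", {
  rt <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   call = c("up_in_a", "up_in_a", "not_up", "up_in_b"))
  dt <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   call = c("up_in_a", "ns", "up_in_a", "ns"))
  mk <- marker_report(rt, dt)
  expect_equal(mk$up_in_a$both, "g1")
  expect_equal(mk$up_in_a$ratio_only, "g2")
  expect_equal(mk$up_in_a$de_only, "g3")
  expect_equal(mk$up_in_b$ratio_only, "g4")
  # disjointness and union identity
  for (dir in names(mk)) {
    s <- mk[[dir]]
    expect_length(intersect(s$both, s$ratio_only), 0)
    expect_length(intersect(s$both, s$de_only), 0)
    expect_setequal(c(s$both, s$ratio_only, s$de_only),
                    union(rt$gene_id[rt$call == dir], dt$gene_id[dt$call == dir]))
  }
  expect_error(marker_report(rt, dt[1:2, ]), "different gene catalogs")
})

test_that("the pipeline runs end to end, deterministically", {
  cfg <- list(simulate = list(fixture = "tiny", seed = 101),
              comparison = list(tissue_a = "hemolymph", tissue_b = "gut"))
  out1 <- file.path(tempdir(), "run1")
  out2 <- file.path(tempdir(), "run2")
  res <- run_pipeline(cfg, outdir = out1)
  run_pipeline(cfg, outdir = out2)
  files <- c("tpm.tsv", "avg_log2tpm.tsv", "presence.tsv", "core.txt",
             "ratio_table.tsv", "scaling.json", "de_table.tsv", "summary.json",
             "cog_summary.tsv", "markers.tsv", "run_log.txt")
  for (f in files) {
    expect_true(file.exists(file.path(out1, f)), label = f)
    expect_gt(file.size(file.path(out1, f)), 0)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  expect_s3_class(res$ratio, "ratio_analysis")
  expect_s3_class(res$de, "noise_de")
})

test_that("raising the ratio threshold can only shrink the up-regulated set", {
  sim <- make_fixture("tiny")
  r2 <- gene_ratios(sim$counts, sim$samples, "hemolymph", "gut",
                    scaling = 2, threshold = 2)
  r3 <- gene_ratios(sim$counts, sim$samples, "hemolymph", "gut",
                    scaling = 2, threshold = 3)
  up2 <- r2$gene_id[r2$call == "up_in_a"]
  up3 <- r3$gene_id[r3$call == "up_in_a"]
  expect_true(all(up3 %in% up2))
})

test_that("pipeline stage failures name the failing stage", {
  cfg <- list(simulate = list(fixture = "tiny"),
              comparison = list(tissue_a = "hemolymph", tissue_b = "brain"))
  expect_error(run_pipeline(cfg, outdir = tempfile()), "stage 'ratio'")
})
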