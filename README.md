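# endosym

Tissue-resolved metatranscriptomics of a low-titre bacterial endosymbiont.

Insect endosymbionts such as *Candidatus* Dactylopiibacterium carminicum in
the carmine cochineal live simultaneously in several host tissues —
hemolymph, gut, ovary — at very different cell densities, and contribute only
a small fraction of a bulk tissue metatranscriptome. Starting from a per-gene
raw read-count matrix (genes × tissue replicates), a gene catalog with CDS
lengths, and a sample sheet, `endosym` answers, per tissue and per tissue
pair: what is expressed, what is expressed everywhere, and what is
up-regulated *per symbiont cell* once differences in titre are removed.

## What it computes

* **TPM quantification** from counts and gene lengths:
  `tpm_g = 1e6 * (c_g/l_g) / Σ(c/l)`, plus per-tissue mean log2(TPM + 1).
* **Presence calls and core transcriptome**: a gene is present in a tissue
  when it has a nonzero count in ≥ 2 of 3 replicates; the core is the
  intersection across tissues.
* **Housekeeping-scaled ratio analysis**: summed ribosomal-protein /
  tRNA-ligase reads estimate relative titre between two tissues; per-gene
  pooled read sums are adjusted by that factor, directed ratios formed (a
  zero divisor is replaced by one), ranked, and called up-regulated at an
  inclusive ratio ≥ 2.
* **TMM-normalized noise-distribution DE**: per-gene signal (M = log2 ratio,
  D = absolute difference of normalized condition means) is compared against
  the cloud of the same statistics from within-condition replicate pairs;
  `prob` is the fraction of noise points strictly dominated, and genes are
  called at `prob ≥ 0.95` and `|log2FC| > 1`.
* **Reports**: per-tissue COG-category counts, named pathway
  presence/completeness (flagellum, chemotaxis, secretion systems, Tfp,
  nitrogen fixation, CAZy families), and cross-method marker lists
  (ratio-only / DE-only / both).
* **A seeded negative-binomial simulator** with tissue titre multipliers,
  titre-invariant housekeeping genes, spiked fold changes and ground truth,
  so the whole pipeline is testable without any sequencing data.

## Worked example

```r
library(endosym)

sim <- make_fixture("paper_like")   # 2,500 genes, 3 tissues x 3 replicates
sim
#> Synthetic endosymbiont dataset: 2500 genes x 9 samples
#>   reads per tissue: hemolymph=666462, gut=313258, ovary=87467
#>   housekeeping genes: 75; spiked genes: 227

housekeeping_scaling(sim$counts, sim$samples, sim$truth$housekeeping,
                     "hemolymph", "gut")
#> Housekeeping scaling hemolymph / gut = 2.964 (75 genes)

ra <- ratio_analysis(sim$counts, sim$samples, "gut", "hemolymph",
                     housekeeping = sim$truth$housekeeping)
ra
#> Quantitative ratio analysis: gut vs hemolymph
#>   total-read ratio gut/hemolymph: 0.5
#>   housekeeping scaling factor: 0.337
#>   up in gut: 142; up in hemolymph: 120 (ratio >= 2)
#>   reference genes within band: 100.0%

de <- noise_de(sim$counts, sim$samples, "gut", "hemolymph")
de
#> Noise-distribution DE: gut vs hemolymph
#>   2500 genes, 15000 noise points
#>   called at prob >= 0.95, |log2FC| > 1: 137 total (108 up in gut, 29 up in hemolymph)

marker_report(ra, de)
#> Proposed functional markers (by supporting analysis):
#>   up_in_a: both=108, ratio only=34, DE only=0
#>   up_in_b: both=29, ratio only=91, DE only=0
```

Reading the numbers: the hemolymph carries ~2.1× the gut's total symbiont
reads but ~2.9–3.0× its housekeeping reads, i.e. ~3× the bacterial titre —
so after scaling, a set of gut genes stands out as up-regulated per cell.
The simulated dataset contains 116 gut-spiked and 91 hemolymph-spiked genes;
the ratio analysis recovers essentially all of them (plus a few percent
false calls, which the stricter DE stage then filters), and every
housekeeping gene lands within the (0.5, 2) "equally expressed" band.

The same pipeline runs from files or a YAML config (see
`inst/extdata/example_config.yaml` and the thin CLI in
`inst/cli/endosym.R`):

```sh
Rscript inst/cli/endosym.R run --config inst/extdata/example_config.yaml --out out/
```

## Package layout

* `R/io.R` — gene catalogs (GTF/TSV), count matrices, sample sheets, result
  tables, YAML configs
* `R/simulate.R` — the synthetic-data generator and fixtures
* `R/quantify.R` — TPM, average log2TPM, presence, core transcriptome
* `R/ratio.R` — totals, housekeeping scaling, per-gene ratios,
  `ratio_analysis()`
* `R/noiseq.R` — TMM factors, noise cloud, dominance probability,
  `noise_de()`
* `R/report.R` — COG/pathway/marker reports and `run_pipeline()`
* `vignettes/endosymbiont-tissue-expression.Rmd` — the methods vignette
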