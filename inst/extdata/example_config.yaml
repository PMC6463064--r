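# Example pipeline configuration: simulate a study-like dataset and compare
# hemolymph against gut. Replace the `simulate` block with an `inputs` block
# (counts/genes/samples file paths) to analyze real count tables.
simulate:
  fixture: paper_like
  seed: 2019
comparison:
  tissue_a: hemolymph
  tissue_b: gut
thresholds:
  ratio: 2      # up-regulation call on the adjusted read ratio (inclusive)
  prob: 0.95    # noise-dominance probability cutoff
  log2fc: 1     # minimum |log2 fold change| for a DE call (exclusive)
min_replicates: 2
pseudocount: 1
outdir: endosym_out
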