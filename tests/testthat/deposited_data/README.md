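# Deposited-data integration fixtures (not included)

The final acceptance test reproduces published hit counts from the study's
deposited supplementary tables, which are too large to redistribute here.
To enable it, convert the processed per-protein ratio tables to TSV and
place them in this directory as:

- `fb_legs_ratios.tsv` — protein_id + one log2 BirA*/wt ratio column per
  comparison (fat body -> legs experiment)
- `fb_legs_design.yaml` — the comparison design (dataset_name, species,
  comparisons[] with comparison_id / numerator_label / denominator_label)
- `fb_legs_thresholds.yaml` — map comparison_id -> published log2
  threshold

The test is skipped while this directory contains no `.tsv` files.
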