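# Bundled reference tables

Published per-clone genotyping and selection summaries for the 15
registered Spanish stone-pine clones, used by the examples and the
acceptance script for reproducible summary arithmetic.

- `registered_clone_error_rates.tsv` — per registered clone: number of
  retained genotyped ramets, mean proportion of complete genotypes, mean
  mismatches against the clone consensus, per-sample genotyping error
  rate, provenance region.
- `ph_blup_summary.tsv` — clonal BLUP means (and SD) for total cone
  number (NC) and mean cone weight (MCW, g) at the PH clonal test, for
  all 99 clones, the 15 registered clones and the top decile.
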