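# Bundled fixtures

- `pcr_truth_synthetic.tsv` — a SYNTHETIC stand-in for a PCR validation
  table.  It is reconstructed from published aggregate counts only (tested
  SVs per category 135 / 118 / 102, confirmed 120 / 58 / 11); the individual
  rows are not real experimental records.  Used by the benchmark module's
  tests and examples.
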