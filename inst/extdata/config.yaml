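out_dir: reports
rpm_denominator: library_total
processing: {window: 4}
phasing: {cycle: 21, strand_mode: plus_only}
references: references.fa
precursor:
  ref_id: precursor
  kind: mir_foldback
  guide_start: 60
  guide_length: 21
target:
  ref_id: target
  site_start: 100
libraries:
  - {id: sim_amir, path: sim_amir.collapsed.fa, format: collapsed_fasta}
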