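# Bundled example data

Small plain-text fixtures emulating the result surfaces of a congenital
hemivertebrae WES cohort study (67 patients, 125 family controls), used by the
examples and the test suite.

- `candidate_calls.tsv` — CNV calls touching the candidate genes NOTCH2,
  DSCAM, SNTG1 and the TBX6-containing 16p11.2 region: 12 patient deletions,
  plus a **synthetic** row for CS050's father carrying the same DSCAM deletion
  (supporting the paternal-inheritance label).
- `recessive_calls.tsv` — homozygous deletion calls (observed/expected reads
  ratio < 0.1) in NBPF20, FAM138C and DHX40 for 8 patients. The four
  heterozygous DHX40 patient rows (CS010/CS020/CS030/CS040), the control
  heterozygous DHX40 carrier (CS071F) and the ZNF992 patient/control
  homozygous pair are **synthetic** reconstructions: only their existence and
  counts are documented, not their coordinates or carriers.
- `cohort.ped` — **synthetic** minimal pedigree consistent with the
  inheritance labels: trios/quartets where parents (and, for sibling-checked
  rows, one unaffected sibling) were assayed, singletons where the pattern is
  not determined.
- `candidate_popfreq.tsv`, `novel_popfreq.tsv` — DGV-like / gnomAD-SV-like
  heterozygous-loss frequency records per gene; cohort sizes are nominal
  (1000 / 10847), except the deliberately ineligible NAE1 record (n = 50).
- `novel_gene_counts.tsv` — gene-level recurrence counts for the 14 enriched
  genes plus three **synthetic** decoy genes (ZZZAA/ZZZBB/ZZZCC), each failing
  exactly one enrichment criterion.

Coordinates are hg19, 0-based half-open (size = end − start).
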