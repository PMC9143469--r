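{
 "table2.tsv": {
  "n_rows": 126,
  "sum_n_p450": 2643,
  "sum_n_fragments": 129
 },
 "table3.tsv": {
  "n_rows": 103,
  "n_families": 45,
  "sum_family_counts": 2643,
  "sum_subfamily_counts": 2643
 },
 "table4.tsv": {
  "n_rows": 151,
  "n_types": 18,
  "sum_p450_count": 1236
 }
}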