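Reference-cohort summary tables (121 subjects; 96 exposed to humidifier
disinfectants, 25 unexposed) used to re-derive published cohort statistics:

- cluster_exposure_counts.csv: exposed/unexposed subject counts per k-means
  subject cluster (C0..C5).
- cohort_group_summaries.csv: mean (SD) height and weight per exposure group.
- gender_by_exposure_counts.csv: 2x2 gender-by-exposure counts reconstructed
  from the published gender percentages (45.8/54.2% of 96; 16/84% of 25).

These are published aggregate tables, not patient-level data.
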