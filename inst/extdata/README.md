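# example_cohort.csv

A synthetic 3-patient fixture in the cohort CSV schema (see the package
README for column definitions). All values were invented for testing; no
real patient data.

Hand-computed score totals, band by band:

| patient | RAPS | REMS | MEWS | MEDS |
|---------|------|------|------|------|
| P1      | 0    | 3    | 2    | 0    |
| P2      | 2    | 8    | 7    | 9    |
| P3      | 13   | 23   | 11   | 19   |

Workings:

- **P1** — PR 106, MAP 94, RR 20, GCS 15: all RAPS zero bands (0). REMS
  adds age 60 (+3) and SpO2 98 (0) = 3. MEWS: SBP 121 (0), HR 106 (+1),
  RR 20 (+1), T 37.2 (0), Alert (0) = 2. MEDS: no criterion met (RR 20 is
  not > 20) = 0.
- **P2** — RAPS: PR 121 (+2), MAP 72.5 -> 73 (0), RR 22 (0), GCS 15 (0)
  = 2. REMS: + age 78 (+6), SpO2 95 (0) = 8. MEWS: SBP 99 (+1), HR 121
  (+2), RR 22 (+2), T 38.6 (+2), Alert (0) = 7. MEDS: age > 65 (+3),
  RR 22 > 20 tachypnea (+3), platelets 120 < 150 (+3) = 9.
- **P3** — RAPS: PR 150 (+3), MAP 38 (+4), RR 36 (+3), GCS 6 (+3) = 13.
  REMS: + age 81 (+6), SpO2 74 (+4) = 23. MEWS: SBP 65 (+3), HR 150 (+3),
  RR 36 (+3), T 35.1 (0), Pain (+2) = 11. MEDS: age (+3), tachypnea/
  hypoxia (+3), septic shock (+3), platelets 40 (+3), bands 11% (+3),
  lower respiratory infection (+2), altered mental status (+2) = 19.
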