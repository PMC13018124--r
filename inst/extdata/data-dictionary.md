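# Data dictionary

## Observation dataset (read_dataset / write_dataset, CSV)

| column | type | meaning |
|--------|------|---------|
| ID     | integer | subject identifier |
| TIME   | numeric | time since first dose (h), >= 0 |
| EVID   | integer | 1 = dosing record, 0 = observation |
| AMT    | numeric | dose amount (mg); > 0 on dosing records, empty otherwise |
| DVID   | integer | observation channel: 1 = plasma concentration (ug/mL), 2 = VAS pain score (0-10) |
| DV     | numeric | observed value; censored plasma records report the LLOQ |
| CENS   | integer | 1 = left-censored plasma record (true value in [0, LLOQ)); VAS records are never censored |
| LLOQ   | numeric | lower limit of quantification (ug/mL), 0.2 by default |
| EGFR   | numeric | recorded eGFR (mL/min/1.73 m2); empty when missing (median-imputed before fitting) |
| OCT2   | text | SLC22A2 c.808G>T genotype: GG / GT / TT |
| OCTN1  | text | SLC22A4 c.1507C>T genotype: CC / CT / TT |
| AGE    | numeric | years |
| WT     | numeric | body weight (kg) |
| SEX    | text | F / M |
| STUDY  | text | optional study label (generator adds study1/study2) |

## Trial-simulation metrics CSV (cli `simulate`, interval_metrics)

| column | meaning |
|--------|---------|
| subject_id | subject index within the cohort |
| auc_tau | steady-state AUC over the final dosing interval (mg.h/L), trapezoid |
| cmax | maximum plasma concentration over the interval (ug/mL) |
| auec_tau | area under the pain-attenuation curve (%.h), trapezoid |
| max_attenuation | maximum percent pain attenuation over the interval |
| category | minimal (< 30%), moderate (30-50%), substantial (>= 50%) by max attenuation |
| pta_flag | TRUE if attenuation >= 50% for >= 80% of the interval |

Cohort summary CSV: per-metric p10 / median / p90 (linear-interpolation
percentiles) and `pta_pct`, the percentage of subjects with pta_flag.

## Scenario configuration (flat key = value text)

Keys mirror the CLI flags: `stage` (1-4), `genotype` (GG/GT/TT), `dose`
(mg per administration), `n` (cohort size), `seed` (integer), `grid_dt`
(output resolution, h), `design` (study1/study2/pooled), `out` (path).
Flags given on the command line override config values.

Concentrations are serialized in ug/mL, attenuation in percent throughout.
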