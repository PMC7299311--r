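# Cohort file formats

## Cohort table (long-format CSV)

Header: `patient_id,timepoint,variable,value` — one row per observed cell.

- `patient_id`: free-form identifier, consistent across rows.
- `timepoint`: one of the labels declared in the metadata (e.g. `bl,y1,...`);
  the declared order defines the time axis and the first label is baseline.
- `variable`: a variable name declared in the metadata. Undeclared names are
  rejected.
- `value`: a number for continuous variables, `0`/`1` for binary variables
  (gender: 1 = male), or a genotype class label (e.g. `CT`) for genotype
  variables.

A (patient, timepoint, variable) combination may appear at most once;
missing combinations are treated as missing data (complete-case filtering
drops such patients). Static variables must carry the same value at every
timepoint where they appear.

## Variable metadata (JSON)

```json
{
  "timepoints": ["bl", "y1", "y2", "y3", "y4"],
  "variables": [
    {"name": "UPDRS1", "domain_group": "General PD Severity",
     "kind": "continuous", "direction": 1, "static": false},
    {"name": "MoCA", "domain_group": "Cognition",
     "kind": "continuous", "direction": -1, "static": false},
    {"name": "age", "domain_group": "Demographic",
     "kind": "continuous", "direction": 1, "static": true},
    {"name": "gender", "domain_group": "Demographic",
     "kind": "binary", "static": true},
    {"name": "G1", "domain_group": "Genetic", "kind": "genotype",
     "genotype_classes": ["CC", "CT", "TT"]}
  ]
}
```

- `direction` (`+1`/`-1`) is required for continuous variables only:
  `+1` when a higher raw value means greater disease severity, `-1` when a
  higher value means better health.
- `genotype_classes` is required for genotype variables (>= 2 labels);
  genotype variables are always static.
- `domain_group` `"Demographic"` marks the variables treated as
  demographics by the subtype-comparison statistics.
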