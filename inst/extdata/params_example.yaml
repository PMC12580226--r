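# Annotated example parameter file.
#
# Every block is optional: anything omitted is filled from the package
# defaults and flagged "synthetic" in the loaded set's meta block, so a
# minimal file (e.g. only `econ`) is valid. Unknown fields are rejected.
# All probabilities are per 1-year cycle; all costs are JPY.
schema_version: 1

# Disease-transition rows, keyed age band > sex > from-state. Each row
# maps successor states to probabilities; the stay probability may be
# omitted (remainder of the row) or written explicitly, in which case
# the row must sum to 1. Only the rows given here override the
# defaults; CRC death (DeadCRC) may appear only in clinical CRC rows —
# other-cause death always comes from the life table.
transition:
  60-64:
    female:
      Normal: {LowRiskPolyp_1_4mm: 0.018}
      HighRiskPolyp: {PreclinicalCRC_DukesA: 0.06}
    male:
      Normal: {LowRiskPolyp_1_4mm: 0.024}

# Test characteristics: sensitivity per lesion class (lr_small = low-risk
# polyp 1-4 mm, lr_medium = 5-9 mm, hr = high-risk polyp, crc_a..crc_d =
# preclinical CRC by Dukes stage), FIT specificity, and the colonoscopy
# perforation probability.
test_chars:
  fit_sensitivity: {lr_small: 0.05, lr_medium: 0.10, hr: 0.30,
                    crc_a: 0.70, crc_b: 0.80, crc_c: 0.85, crc_d: 0.90}
  fit_specificity: 0.96
  tcs_sensitivity: {lr_small: 0.75, lr_medium: 0.85, hr: 0.95,
                    crc_a: 0.95, crc_b: 0.97, crc_c: 0.98, crc_d: 0.98}
  tcs_perforation_prob: 0.0006

# Unit costs in JPY. crc_treatment is the annual treatment cost per
# Dukes stage while in the clinical state; dukes_d_multiplier supports
# the late-stage cost scenario (x10) without editing the base cost.
costs:
  fit: 1500
  tcs: 25000
  polypectomy: 70000
  perforation_management: 1000000
  crc_treatment: {a: 1500000, b: 2500000, c: 4000000, d: 6000000}
  dukes_d_multiplier: 1

# Annual utility weight per live health state (dead states accrue 0);
# perforation_disutility is a one-off QALY decrement in the cycle of a
# colonoscopy perforation.
utilities:
  states:
    Normal: 1.0
    LowRiskPolyp_1_4mm: 1.0
    LowRiskPolyp_5_9mm: 1.0
    HighRiskPolyp: 1.0
    PreclinicalCRC_DukesA: 1.0
    PreclinicalCRC_DukesB: 1.0
    PreclinicalCRC_DukesC: 1.0
    PreclinicalCRC_DukesD: 1.0
    ClinicalCRC_DukesA: 0.90
    ClinicalCRC_DukesB: 0.85
    ClinicalCRC_DukesC: 0.75
    ClinicalCRC_DukesD: 0.60
    PostPolypectomy: 1.0
  perforation_disutility: 0

# Economic constants: annual discount rate applied to costs and QALYs,
# willingness-to-pay threshold (JPY per QALY), exchange rate.
econ:
  discount_rate: 0.02
  wtp: 5000000
  jpy_per_usd: 145.52
  cycle_length: 1

# Initial population: ages 40-74 with sampling weights, sex split, and
# the seed used by sample_population().
population:
  n_individuals: 10000
  sex_weights: {female: 0.5, male: 0.5}
  seed: 1

# A full life table (ages 40..100, one annual death probability per sex)
# can be supplied as:
# life_table:
#   age: [40, 41, ..., 100]
#   female: [...]
#   male: [...]
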