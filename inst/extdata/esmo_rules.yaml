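# ESMO-MCBS v1.1 grading thresholds (editable; see ?esmo_rules).
# Gains are months of median survival; landmark gains are absolute
# survival fractions. Band edges are the minimal banding consistent with
# the scale's published grade assignments for checkpoint-inhibitor
# trials; replace with the full published scorecard to grade other
# cohorts.
version: "v1.1-default"

# a preliminary score above 1 requires the lower confidence limit of the
# hazard ratio at or below this ceiling
hr_ci_ceiling: 0.65

# absolute landmark-survival gain conferring the top preliminary score /
# long-term-benefit credit
landmark_gain_threshold: 0.10

form2a:                      # non-curative, overall survival
  low_median_cutoff_months: 12
  strata:
    low:                     # control median <= 12 months
      gain_bands: {score4: 3.0, score3: 2.0, score2: 1.5}
      landmark_months: 24    # 2-year survival gain confers score 4
      long_term_os_months: 60
    high:                    # control median > 12 months
      gain_bands: {score4: 5.0, score3: 3.0, score2: 2.0}
      landmark_months: 36    # 3-year survival gain confers score 4
      long_term_os_months: 84

form2b:                      # non-curative, progression-free survival
  preliminary_cap: 3         # top preliminary score on the PFS form
  final_cap: 4               # PFS-primary grades never reach 5
  gain_bands: {score3: 1.5}
  landmark_months: 12        # 1-year PFS gain: upgrade + long-term credit

form1:                       # curative (adjuvant); graded on the lower CI
  grade_a_ci: 0.65
  grade_b_ci: 0.80
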