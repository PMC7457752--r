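# Shared test fixtures, built in code.

make_record <- function(trial_id = "T-1", hr = 0.7, ci_lower = 0.55,
                        ci_upper = 0.9, ...) {
  trial_arm_record(trial_id = trial_id, hr = hr, ci_lower = ci_lower,
                   ci_upper = ci_upper, ...)
}

random_toxicity_table <- function(n = 5) {
  data.frame(ae = sprintf("AE%02d", seq_len(n)),
             inc_control = runif(n, 0, 0.6),
             inc_experimental = runif(n, 0, 0.6))
}

swap_arms <- function(tab) {
  data.frame(ae = tab$ae, inc_control = tab$inc_experimental,
             inc_experimental = tab$inc_control)
}

# a record fully specified for ESMO grading on raw inputs
make_esmo_record <- function(ci_lower, gain, landmark_gain, form,
                             median_control, qol = "not_reported",
                             toxicity_reduced = FALSE,
                             toxic_death_increased = FALSE) {
  endpoint <- if (form == "form2b_pfs") "PFS" else "OS"
  lm_time <- if (form == "form2b_pfs") 12
    else if (median_control <= 12) 24 else 36
  hr <- ci_lower + 0.05
  lm <- if (is.na(landmark_gain)) NULL else
    data.frame(time = lm_time, surv_control = 0.30,
               surv_experimental = 0.30 + landmark_gain)
  trial_arm_record(
    trial_id = "GRID", setting = "non_curative", endpoint = endpoint,
    hr = hr, ci_lower = ci_lower, ci_upper = hr + 0.3,
    median_control = median_control,
    median_experimental = median_control + gain,
    landmark_survival = lm,
    qol = qol, toxicity_reduced = toxicity_reduced,
    toxic_death_increased = toxic_death_increased)
}
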