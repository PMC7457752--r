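# Brute-force ESMO-MCBS rule evaluator, written directly from the packaged
# rule-table values as plain nested conditionals. Deliberately independent
# of the package's grading code so it can serve as an oracle.

oracle_esmo_final <- function(ci_lower, gain, landmark_gain, form,
                              median_control, qol = "not_reported",
                              toxicity_reduced = FALSE,
                              toxic_death_increased = FALSE) {
  top <- if (form == "form2a_os") 4 else 3
  fired <- c()
  if (!is.na(ci_lower) && !is.na(gain)) {
    s <- if (ci_lower > 0.65) 1 else if (form == "form2a_os") {
      if (median_control <= 12) {
        if (gain >= 3.0) 4 else if (gain >= 2.0) 3 else if (gain >= 1.5) 2 else 1
      } else {
        if (gain >= 5.0) 4 else if (gain >= 3.0) 3 else if (gain >= 2.0) 2 else 1
      }
    } else {
      if (gain >= 1.5) 3 else 2
    }
    fired <- c(fired, s)
  }
  if (!is.na(landmark_gain) && landmark_gain >= 0.10) fired <- c(fired, top)
  if (!length(fired)) return(NA_character_)
  prelim <- max(fired)
  plateau <- form == "form2b_pfs" && !is.na(landmark_gain) &&
    landmark_gain >= 0.10
  up <- qol == "improved" || toxicity_reduced || plateau
  g <- prelim + (if (up) 1 else 0) - (if (toxic_death_increased) 1 else 0)
  g <- max(1, min(5, g))
  if (form == "form2b_pfs") g <- min(g, 4)
  as.character(g)
}
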