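# ESMO-MCBS v1.1 grading: form selection, dual-rule preliminary score,
# QOL/toxicity/plateau adjustments, long-term-benefit criteria, and the
# meaningful-benefit predicate.

.esmo_forms <- c("form1_curative", "form2a_os", "form2b_pfs")
.rules_cache <- new.env(parent = emptyenv())

#' Load an ESMO-MCBS rule table
#'
#' The thresholds that drive grading are data, not code: the lower-CI-limit
#' ceiling, the median-gain band edges per preliminary score (stratified by
#' the control-arm median), the landmark-gain threshold and its
#' stratum-specific timepoints, and the curative-form grade boundaries all
#' come from a human-editable YAML file. The packaged default encodes the
#' minimal banding consistent with the scale's published grade assignments
#' for checkpoint-inhibitor trials (e.g. lower CI limit below 0.65 with a
#' 2.4-month OS gain in a short-survival stratum gives a preliminary score
#' of 3); users grading other cohorts can supply the full published
#' scorecard instead.
#'
#' @param path YAML file; `NULL` loads the packaged default.
#' @return An `esmo_rule_table` list.
#' @export
esmo_rules <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.rules_cache$default)) return(.rules_cache$default)
    path <- system.file("extdata", "esmo_rules.yaml", package = "oncovalue",
                        mustWork = TRUE)
  }
  rules <- yaml::read_yaml(path)
  .validate_esmo_rules(rules)
  rules <- structure(rules, class = "esmo_rule_table")
  if (path == system.file("extdata", "esmo_rules.yaml",
                          package = "oncovalue"))
    .rules_cache$default <- rules
  rules
}

.validate_esmo_rules <- function(r) {
  chk <- function(ok, msg) if (!ok) stop("rule table: ", msg, call. = FALSE)
  chk(is.numeric(r$hr_ci_ceiling) && r$hr_ci_ceiling > 0 &&
        r$hr_ci_ceiling <= 1, "hr_ci_ceiling must lie in (0, 1]")
  chk(is.numeric(r$landmark_gain_threshold) &&
        r$landmark_gain_threshold > 0 && r$landmark_gain_threshold <= 1,
      "landmark_gain_threshold must lie in (0, 1]")
  for (st in names(r$form2a$strata)) {
    b <- r$form2a$strata[[st]]$gain_bands
    chk(b$score4 > b$score3 && b$score3 > b$score2 && b$score2 > 0,
        sprintf("form2a '%s' gain-band edges must be strictly increasing", st))
  }
  chk(r$form2b$gain_bands$score3 > 0, "form2b score-3 gain floor must be > 0")
  chk(r$form1$grade_a_ci < r$form1$grade_b_ci,
      "form1 grade boundaries must be increasing (A < B)")
  invisible(r)
}

#' Select the ESMO-MCBS evaluation form
#'
#' Curative-setting (adjuvant) trials are graded A-C on form 1 regardless
#' of the survival endpoint used; non-curative trials use form 2a for OS
#' and form 2b for PFS. A non-curative RFS/DFS evaluation has no form and
#' errors.
#'
#' @param setting `"curative"` or `"non_curative"`.
#' @param endpoint `"OS"`, `"PFS"`, or `"RFS_DFS"`.
#' @return `"form1_curative"`, `"form2a_os"`, or `"form2b_pfs"`.
#' @export
select_form <- function(setting, endpoint) {
  if (identical(setting, "curative")) return("form1_curative")
  switch(endpoint,
         OS = "form2a_os",
         PFS = "form2b_pfs",
         stop("unsupported combination: non-curative setting with a ",
              "RFS/DFS endpoint", call. = FALSE))
}

.stratum <- function(record, rules) {
  if (is.na(record$median_control)) return(NA_character_)
  if (record$median_control <= rules$form2a$low_median_cutoff_months)
    "low" else "high"
}

# absolute survival gain (experimental - control) at a landmark timepoint,
# matched within +/-10%; NA when no usable entry exists
.landmark_gain_at <- function(record, timepoint) {
  lm <- record$landmark_survival
  if (is.null(lm) || nrow(lm) == 0 || is.na(timepoint)) return(NA_real_)
  off <- abs(lm$time - timepoint)
  cand <- which(off <= 0.1 * timepoint)
  if (!length(cand)) return(NA_real_)
  i <- cand[which.min(off[cand])]
  lm$surv_experimental[i] - lm$surv_control[i]
}

.preliminary_landmark_months <- function(form, stratum, rules) {
  if (form == "form2b_pfs") return(rules$form2b$landmark_months)
  if (is.na(stratum)) return(NA_real_)
  rules$form2a$strata[[stratum]]$landmark_months
}

#' ESMO-MCBS preliminary score (non-curative forms)
#'
#' Dual rule. Clause one: the lower confidence limit of the hazard ratio
#' must clear the rule-table ceiling (default 0.65) and the absolute gain
#' in median survival then selects the score from the stratum's gain bands
#' (a lower limit above the ceiling scores 1 regardless of gain). Clause
#' two: an absolute landmark-survival gain at or above the threshold
#' (default 10%) at the stratum's reference timepoint confers the form's
#' top preliminary score directly -- 4 on form 2a, 3 on form 2b (the PFS
#' form's preliminary cap). The clause may be satisfied either by raw
#' landmark data on the record or by a transcribed
#' `landmark_gain_qualifies` flag. The higher of the fired clauses wins;
#' a clause whose inputs are missing simply cannot fire, and if no clause
#' can fire the score is not computable and an error lists the missing
#' fields.
#'
#' @param record A non-curative [trial_arm_record].
#' @param rules An [esmo_rules()] table.
#' @return Integer preliminary score, 1-4.
#' @export
preliminary_score <- function(record, rules = esmo_rules()) {
  form <- select_form(record$setting, record$endpoint)
  if (form == "form1_curative")
    stop("curative-setting records are graded with curative_grade()",
         call. = FALSE)
  top <- if (form == "form2a_os") 4L else
    as.integer(rules$form2b$preliminary_cap)
  fired <- integer()
  missing <- character()

  st <- .stratum(record, rules)
  if (!is.na(record$ci_lower) && !is.na(record$gain_months) &&
      (form == "form2b_pfs" || !is.na(st))) {
    if (record$ci_lower <= rules$hr_ci_ceiling) {
      g <- record$gain_months
      s <- if (form == "form2a_os") {
        b <- rules$form2a$strata[[st]]$gain_bands
        if (g >= b$score4) 4L else if (g >= b$score3) 3L
        else if (g >= b$score2) 2L else 1L
      } else {
        if (g >= rules$form2b$gain_bands$score3) 3L else 2L
      }
    } else s <- 1L
    fired <- c(fired, s)
  } else {
    missing <- c(missing,
                 if (is.na(record$ci_lower)) "ci_lower",
                 if (is.na(record$gain_months)) "gain_months (arm medians)",
                 if (form == "form2a_os" && is.na(st))
                   "median_control (stratum)")
  }

  if (isTRUE(record$landmark_gain_qualifies)) {
    fired <- c(fired, top)
  } else {
    lg <- .landmark_gain_at(record,
                            .preliminary_landmark_months(form, st, rules))
    if (!is.na(lg)) {
      if (lg >= rules$landmark_gain_threshold) fired <- c(fired, top)
    } else if (!isFALSE(record$landmark_gain_qualifies)) {
      missing <- c(missing, "landmark_survival at the reference timepoint")
    }
  }

  if (!length(fired))
    stop(sprintf("record '%s': cannot compute the preliminary score; missing inputs: %s",
                 record$trial_id, paste(unique(missing), collapse = "; ")),
         call. = FALSE)
  max(fired)
}

#' Adjust an ESMO-MCBS preliminary score to the final grade
#'
#' Positive adjustments -- improved quality of life, reduced grade 3-4
#' toxicity, or a qualifying survival plateau (PFS form only) -- raise the
#' grade by at most one level in total, however many of them apply. An
#' excess of toxic deaths lowers it one level. The result is clamped to
#' \[1, 5\], and grades originating on the PFS form are additionally capped
#' (default 4): a PFS-primary evaluation cannot reach the top grade.
#'
#' @param preliminary Integer preliminary score from [preliminary_score()].
#' @param qol `"improved"`, `"not_improved"`, or `"not_reported"`.
#' @param toxicity_reduced Logical.
#' @param toxic_death_increased Logical.
#' @param plateau Logical: qualifying long-term plateau upgrade (callers
#'   should only pass `TRUE` for form 2b; on the OS form a plateau is an
#'   annotation, not an upgrade).
#' @param form The originating form.
#' @param form2b_cap Final-grade cap for form 2b grades.
#' @return Integer final grade, 1-5.
#' @export
#' @examples
#' adjust_grade(3, qol = "improved", toxicity_reduced = TRUE)  # 4 (one level)
adjust_grade <- function(preliminary, qol = "not_reported",
                         toxicity_reduced = FALSE,
                         toxic_death_increased = FALSE, plateau = FALSE,
                         form = "form2a_os", form2b_cap = 4L) {
  stopifnot(preliminary %in% 1:4)
  up <- identical(qol, "improved") || isTRUE(toxicity_reduced) ||
    isTRUE(plateau)
  g <- as.integer(preliminary) + as.integer(up) -
    as.integer(isTRUE(toxic_death_increased))
  g <- max(1L, min(5L, g))
  if (identical(form, "form2b_pfs")) g <- min(g, as.integer(form2b_cap))
  g
}

#' ESMO-MCBS curative-setting grade (form 1)
#'
#' Adjuvant trials are graded A-C from the hazard ratio's lower confidence
#' limit: A at or below the rule table's A-boundary (default 0.65), B at or
#' below the B-boundary (default 0.80), C otherwise. A and B denote
#' meaningful clinical benefit.
#'
#' @param record A curative-setting [trial_arm_record].
#' @param rules An [esmo_rules()] table.
#' @return `"A"`, `"B"`, or `"C"`.
#' @export
curative_grade <- function(record, rules = esmo_rules()) {
  if (is.null(record$ci_lower) || is.na(record$ci_lower))
    stop(sprintf("record '%s': curative grading requires the hazard-ratio confidence interval",
                 record$trial_id), call. = FALSE)
  if (record$ci_lower <= rules$form1$grade_a_ci) "A"
  else if (record$ci_lower <= rules$form1$grade_b_ci) "B"
  else "C"
}

#' ESMO-MCBS long-term-benefit criterion
#'
#' Credit for a durable effect in the true tail of the curve: an absolute
#' survival gain at or above the threshold (default 10%) at a
#' prognostically weighted timepoint. For PFS evaluations the timepoint is
#' 1 year (and the criterion doubles as the plateau upgrade); a transcribed
#' `landmark_gain_qualifies` flag satisfies it when raw proportions are
#' unavailable. For OS evaluations the advantage must persist far later --
#' 5 years when the control median is at most 12 months, 7 years otherwise
#' -- and only raw landmark data at that timepoint can satisfy it; with
#' immature follow-up the criterion is simply not met.
#'
#' @param record A [trial_arm_record].
#' @param rules An [esmo_rules()] table.
#' @return Logical.
#' @export
long_term_benefit <- function(record, rules = esmo_rules()) {
  form <- select_form(record$setting, record$endpoint)
  if (form == "form1_curative") return(FALSE)
  if (form == "form2b_pfs") {
    if (isTRUE(record$landmark_gain_qualifies)) return(TRUE)
    lg <- .landmark_gain_at(record, rules$form2b$landmark_months)
    return(!is.na(lg) && lg >= rules$landmark_gain_threshold)
  }
  st <- .stratum(record, rules)
  if (is.na(st)) return(FALSE)
  tp <- rules$form2a$strata[[st]]$long_term_os_months
  lg <- .landmark_gain_at(record, tp)
  !is.na(lg) && lg >= rules$landmark_gain_threshold
}

#' Grade one trial arm with the ESMO-MCBS v1.1
#'
#' Composes form selection, preliminary scoring (or curative grading), the
#' single-level adjustment, and the long-term-benefit criterion. On the OS
#' form a met long-term criterion is reported as a flag only (the scale
#' treats it as an additional curative-framework annotation, not a grade
#' change); on the PFS form it is the plateau upgrade.
#'
#' @param record A [trial_arm_record].
#' @param rules An [esmo_rules()] table.
#' @return An `esmo_assessment`: list with `form`, `preliminary`,
#'   `upgrade_applied`, `downgrade_applied`, `final_grade` (`"1"`-`"5"` or
#'   `"A"`-`"C"`), `meaningful_benefit` (grade 4, 5, A or B) and
#'   `long_term_benefit`.
#' @export
#' @examples
#' rec <- trial_arm_record("EXAMPLE-1", hr = 0.70, ci_lower = 0.52,
#'                         ci_upper = 0.92, median_control = 5,
#'                         median_experimental = 7.4, qol = "improved",
#'                         toxicity_reduced = TRUE)
#' score_esmo(rec)$final_grade  # preliminary 3 + one upgrade = "4"
score_esmo <- function(record, rules = esmo_rules()) {
  stopifnot(inherits(record, "trial_arm_record"))
  form <- select_form(record$setting, record$endpoint)
  if (form == "form1_curative") {
    g <- curative_grade(record, rules)
    return(structure(list(
      trial_id = record$trial_id, form = form, preliminary = NA_integer_,
      upgrade_applied = FALSE, downgrade_applied = FALSE, final_grade = g,
      meaningful_benefit = g %in% c("A", "B"), long_term_benefit = FALSE),
      class = "esmo_assessment"))
  }
  prelim <- preliminary_score(record, rules)
  ltb <- long_term_benefit(record, rules)
  plateau <- ltb && form == "form2b_pfs"
  up <- identical(record$qol, "improved") ||
    isTRUE(record$toxicity_reduced) || plateau
  final <- adjust_grade(prelim, record$qol, record$toxicity_reduced,
                        record$toxic_death_increased, plateau, form,
                        rules$form2b$final_cap)
  structure(list(
    trial_id = record$trial_id, form = form, preliminary = prelim,
    upgrade_applied = up, downgrade_applied = isTRUE(record$toxic_death_increased),
    final_grade = as.character(final), meaningful_benefit = final >= 4,
    long_term_benefit = ltb),
    class = "esmo_assessment")
}

#' @export
print.esmo_assessment <- function(x, ...) {
  cat(sprintf("<esmo_assessment> %s (%s)\n", x$trial_id, x$form))
  if (!is.na(x$preliminary))
    cat(sprintf("  preliminary %d%s%s -> ", x$preliminary,
                if (x$upgrade_applied) " +1" else "",
                if (x$downgrade_applied) " -1" else ""))
  else cat("  ")
  cat(sprintf("grade %s | meaningful benefit: %s | long-term benefit: %s\n",
              x$final_grade, x$meaningful_benefit, x$long_term_benefit))
  invisible(x)
}
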