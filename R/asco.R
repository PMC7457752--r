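# ASCO Value Framework (2016 update) net-health-benefit scoring.
#
# NHB = treatment-effect points + toxicity points + tail-of-the-curve bonus
#       + palliation bonus + QOL bonus + treatment-free-interval bonus.

#' ASCO-VF treatment-effect (clinical benefit) points
#'
#' The framework awards points proportional to the relative risk reduction:
#' `(1 - HR) * 100`, weighted by endpoint. Overall survival and, in the
#' adjuvant setting, recurrence/disease-free survival carry full weight;
#' progression-free survival is down-weighted to 0.8 (so a qualifying PFS
#' improvement is worth 80% of the equivalent OS improvement). A hazard
#' ratio of 1 scores 0 and ratios above 1 score negative; negative values
#' are deliberately not floored so that harmful or mis-entered effects
#' remain visible.
#'
#' @param hr Hazard ratio point estimate(s), > 0.
#' @param endpoint `"OS"`, `"PFS"`, or `"RFS_DFS"`.
#' @param setting `"curative"` or `"non_curative"` (informational; the
#'   endpoint determines the weight).
#' @return Unrounded points; report rounded to one decimal.
#' @export
#' @examples
#' treatment_effect_points(0.49, "OS")      # 51
#' treatment_effect_points(0.52, "PFS")     # 38.4
#' treatment_effect_points(0.65, "RFS_DFS") # 35
treatment_effect_points <- function(hr, endpoint = c("OS", "PFS", "RFS_DFS"),
                                    setting = "non_curative") {
  endpoint <- match.arg(endpoint)
  if (!is.numeric(hr) || any(is.na(hr)) || any(hr <= 0))
    stop("hazard ratio must be a positive number", call. = FALSE)
  w <- if (endpoint == "PFS") 0.8 else 1.0
  (1 - hr) * 100 * w
}

#' ASCO-VF toxicity points
#'
#' Compares the grade 3-4 adverse-event burden between arms. The burden of
#' an arm is the sum of its per-event incidences; the score is the relative
#' difference scaled to the framework's +/-20-point toxicity band:
#' `20 * (B_control - B_experimental) / max(B_control, B_experimental)`,
#' clamped to \[-20, 20\] (positive = the experimental arm is less toxic).
#' Two burden-free arms score 0. When a pre-computed score is supplied as
#' `override` (e.g. transcribed from a published assessment whose raw
#' adverse-event tables are unavailable) it is returned unchanged.
#'
#' @param toxicity_table `data.frame` with columns `ae`, `inc_control`,
#'   `inc_experimental` (grade 3-4 incidence fractions).
#' @param override Optional pre-computed score in \[-20, 20\].
#' @return Toxicity points in \[-20, 20\].
#' @export
#' @examples
#' tab <- data.frame(ae = c("fatigue", "anemia"),
#'                   inc_control = c(0.3, 0.3),
#'                   inc_experimental = c(0.2, 0.1))
#' toxicity_points(tab)  # 20 * (0.6 - 0.3) / 0.6 = 10
toxicity_points <- function(toxicity_table = NULL, override = NULL) {
  if (!is.null(override) && length(override) == 1 && !is.na(override)) {
    if (abs(override) > 20)
      stop("toxicity override must lie in [-20, 20]", call. = FALSE)
    return(as.numeric(override))
  }
  if (is.null(toxicity_table) || nrow(toxicity_table) == 0)
    stop(paste("no toxicity inputs: supply a grade 3-4 adverse-event",
               "incidence table or a toxicity score override"), call. = FALSE)
  b_c <- sum(toxicity_table$inc_control)
  b_e <- sum(toxicity_table$inc_experimental)
  if (b_c == 0 && b_e == 0) return(0)
  raw <- 20 * (b_c - b_e) / max(b_c, b_e)
  min(20, max(-20, raw))
}

#' ASCO-VF tail-of-the-curve bonus
#'
#' Rewards a durable survival plateau: at twice the control arm's median
#' survival, the experimental arm must show at least a 50% relative
#' improvement in the survival proportion, provided control-arm survival at
#' that timepoint is at least 20%. A qualifying OS or RFS/DFS tail earns 20
#' points; a qualifying PFS tail earns 16 (0.8 x 20). The landmark entry
#' whose timepoint lies within 10% of twice the control median is used;
#' when no such entry exists (typically limited follow-up) the bonus is not
#' assessable and 0 is returned, with the reason attached as the `"reason"`
#' attribute so that "not qualified" and "not available" stay
#' distinguishable.
#'
#' @param endpoint `"OS"`, `"PFS"`, or `"RFS_DFS"`.
#' @param median_control Control-arm median survival in months.
#' @param landmark_survival `data.frame` with columns `time`,
#'   `surv_control`, `surv_experimental`.
#' @return 0, 16 or 20, with attribute `"reason"`.
#' @export
#' @examples
#' lm <- data.frame(time = 24, surv_control = 0.25, surv_experimental = 0.40)
#' tail_of_curve_bonus("OS", 12, lm)   # 20: 0.40 >= 1.5 * 0.25, 0.25 >= 0.20
tail_of_curve_bonus <- function(endpoint, median_control, landmark_survival) {
  award <- if (identical(endpoint, "PFS")) 16 else 20
  not_assessable <- function(why)
    structure(0, reason = paste("not assessable:", why))
  if (is.null(median_control) || is.na(median_control))
    return(not_assessable("control-arm median unavailable"))
  if (is.null(landmark_survival) || nrow(landmark_survival) == 0)
    return(not_assessable("no landmark survival data"))
  target <- 2 * median_control
  off <- abs(landmark_survival$time - target)
  cand <- which(off <= 0.1 * target)
  if (!length(cand))
    return(not_assessable(sprintf(
      "no landmark within 10%% of 2 x control median (%.1f mo)", target)))
  i <- cand[which.min(off[cand])]
  sc <- landmark_survival$surv_control[i]
  se <- landmark_survival$surv_experimental[i]
  if (sc < 0.20)
    return(structure(0, reason = sprintf(
      "not qualified: control survival %.0f%% below the 20%% floor at %.1f mo",
      100 * sc, landmark_survival$time[i])))
  if (se < 1.5 * sc)
    return(structure(0, reason = sprintf(
      "not qualified: %.0f%% vs %.0f%% is below a 50%% relative improvement",
      100 * se, 100 * sc)))
  structure(award, reason = sprintf(
    "qualified at %.1f mo: %.0f%% vs %.0f%%", landmark_survival$time[i],
    100 * se, 100 * sc))
}

#' ASCO-VF flag bonus (palliation, QOL, treatment-free interval)
#'
#' A statistically significant improvement in cancer-related symptoms,
#' quality of life, or treatment-free interval each earns a flat 10 points.
#'
#' @param flag Logical.
#' @return 10 if `flag` is `TRUE`, else 0.
#' @export
flag_bonus <- function(flag) if (isTRUE(flag)) 10 else 0

#' Score one trial arm with the ASCO Value Framework
#'
#' Composes [treatment_effect_points()], [toxicity_points()],
#' [tail_of_curve_bonus()] and [flag_bonus()] into the net health benefit.
#' When the record carries transcribed overrides (toxicity score, tail
#' bonus) they take precedence over the raw-data path and the substitution
#' is logged in `notes` -- a value assessment should be auditable, so no
#' default is ever substituted silently.
#'
#' @param record A [trial_arm_record].
#' @param use_overrides Set `FALSE` to force the raw-data path (errors if
#'   raw inputs are absent).
#' @return An `asco_breakdown`: list with `treatment_effect_points`,
#'   `toxicity_points`, `tail_bonus`, `palliation_bonus`, `qol_bonus`,
#'   `tfi_bonus`, `nhb` (their exact sum, computed on unrounded components)
#'   and `notes`.
#' @export
#' @examples
#' rec <- trial_arm_record("EXAMPLE-1", hr = 0.73, ci_lower = 0.59,
#'                         ci_upper = 0.91, toxicity_points_override = 1.0,
#'                         tail_bonus_override = 20)
#' score_asco(rec)
score_asco <- function(record, use_overrides = TRUE) {
  stopifnot(inherits(record, "trial_arm_record"))
  notes <- character()
  te <- treatment_effect_points(record$hr, record$endpoint, record$setting)

  has_override <- use_overrides && !is.na(record$toxicity_points_override)
  tox <- toxicity_points(record$toxicity_table,
                         if (has_override) record$toxicity_points_override)
  if (has_override)
    notes <- c(notes, sprintf("toxicity: transcribed override %.2f used",
                              record$toxicity_points_override))

  if (use_overrides && !is.na(record$tail_bonus_override)) {
    tail <- record$tail_bonus_override
    notes <- c(notes, sprintf("tail: transcribed bonus %g used", tail))
    expected_award <- if (record$endpoint == "PFS") 16 else 20
    if (tail != 0 && tail != expected_award)
      notes <- c(notes, sprintf(
        "tail: transcribed bonus %g differs from the %g-point award level of a %s endpoint",
        tail, expected_award, record$endpoint))
  } else {
    tail <- tail_of_curve_bonus(record$endpoint, record$median_control,
                                record$landmark_survival)
    notes <- c(notes, paste("tail:", attr(tail, "reason")))
  }

  pall <- flag_bonus(record$palliation_improved)
  qolb <- flag_bonus(identical(record$qol, "improved"))
  tfib <- flag_bonus(record$tfi_improved)
  nhb <- te + tox + as.numeric(tail) + pall + qolb + tfib
  structure(list(trial_id = record$trial_id,
                 treatment_effect_points = te, toxicity_points = tox,
                 tail_bonus = as.numeric(tail), palliation_bonus = pall,
                 qol_bonus = qolb, tfi_bonus = tfib, nhb = nhb,
                 notes = notes),
            class = "asco_breakdown")
}

#' @export
print.asco_breakdown <- function(x, ...) {
  cat(sprintf("<asco_breakdown> %s\n", x$trial_id))
  cat(sprintf("  treatment effect %.1f | toxicity %.1f | tail %g | palliation %g | QOL %g | TFI %g\n",
              x$treatment_effect_points, x$toxicity_points, x$tail_bonus,
              x$palliation_bonus, x$qol_bonus, x$tfi_bonus))
  cat(sprintf("  NHB %.1f\n", x$nhb))
  invisible(x)
}
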