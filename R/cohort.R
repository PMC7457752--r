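# Cohort-level aggregation: per-arm score table, best-arm selection,
# medians/ranges/bonus counts, and the initial-vs-updated comparison.

#' Score a cohort of trial arms with both frameworks
#'
#' Applies [score_asco()] to every record and, when `grade_esmo = TRUE`,
#' [score_esmo()] as well. An arm whose ESMO-MCBS inputs are insufficient
#' (e.g. no published median gain or landmark data) gets `NA` grade columns
#' and the reason is recorded in the run log; the ASCO score must always be
#' computable. The run log -- one section per scored arm, listing which
#' bonus gates fired, every override substitution and every missing-input
#' fallback -- is attached as the `"run_log"` attribute.
#'
#' @param records List of [trial_arm_record] objects.
#' @param rules An [esmo_rules()] table.
#' @param grade_esmo Logical; set `FALSE` to skip ESMO-MCBS grading.
#' @return A `data.frame` with one row per arm: identifiers, the six ASCO
#'   score components and `nhb`, and the ESMO form, preliminary score,
#'   `esmo_grade`, `esmo_long_term` and `meaningful` columns.
#' @export
score_cohort <- function(records, rules = esmo_rules(), grade_esmo = TRUE) {
  if (!length(records)) stop("no records to score", call. = FALSE)
  rows <- vector("list", length(records))
  run_log <- vector("list", length(records))
  for (k in seq_along(records)) {
    rec <- records[[k]]
    a <- score_asco(rec)
    esmo_notes <- character()
    e <- NULL
    if (grade_esmo) {
      e <- tryCatch(score_esmo(rec, rules), error = function(err) {
        esmo_notes <<- conditionMessage(err)
        NULL
      })
    }
    rows[[k]] <- data.frame(
      trial_id = rec$trial_id, indication_id = rec$indication_id,
      setting = rec$setting, endpoint = rec$endpoint,
      treatment_effect = a$treatment_effect_points,
      toxicity = a$toxicity_points, tail = a$tail_bonus,
      palliation = a$palliation_bonus, qol_bonus = a$qol_bonus,
      tfi = a$tfi_bonus, nhb = a$nhb,
      esmo_form = if (is.null(e)) NA_character_ else e$form,
      esmo_preliminary = if (is.null(e)) NA_integer_ else e$preliminary,
      esmo_grade = if (is.null(e)) NA_character_ else e$final_grade,
      esmo_long_term = if (is.null(e)) NA else e$long_term_benefit,
      meaningful = if (is.null(e)) NA else e$meaningful_benefit,
      esmo_transcribed = FALSE,
      stringsAsFactors = FALSE)
    run_log[[k]] <- list(trial_id = rec$trial_id, asco = a$notes,
                         esmo = esmo_notes)
  }
  tab <- do.call(rbind, rows)
  names(run_log) <- tab$trial_id
  attr(tab, "run_log") <- run_log
  tab
}

# fill ESMO grades the engine could not derive from a transcription table
# (columns trial_id, exp_esmo_grade, exp_long_term); filled rows are flagged
.fill_transcribed_grades <- function(tab, expected) {
  m <- match(tab$trial_id, expected$trial_id)
  idx <- is.na(tab$esmo_grade) & !is.na(m)
  tab$esmo_grade[idx] <- as.character(expected$exp_esmo_grade[m[idx]])
  tab$esmo_transcribed[idx] <- TRUE
  if ("exp_long_term" %in% names(expected)) {
    jdx <- is.na(tab$esmo_long_term) & !is.na(m)
    tab$esmo_long_term[jdx] <- as.logical(expected$exp_long_term[m[jdx]])
  }
  tab$meaningful[idx] <- tab$esmo_grade[idx] %in% c("4", "5", "A", "B")
  tab
}

#' Pick the representative arm of a multi-arm indication
#'
#' When a trial reports significant results for more than one experimental
#' arm, each arm is scored separately but only the arm with the higher
#' score represents the indication. Ties go to the first arm in table
#' order.
#'
#' @param arm_table Rows of a [score_cohort()] table belonging to one
#'   indication.
#' @return The `trial_id` of the arm with maximal NHB.
#' @export
best_arm <- function(arm_table) {
  if (!nrow(arm_table)) stop("no arms supplied", call. = FALSE)
  arm_table$trial_id[which.max(arm_table$nhb)]
}

.best_rows <- function(arm_table) {
  grp <- factor(arm_table$indication_id,
                levels = unique(arm_table$indication_id))
  idx <- vapply(split(seq_len(nrow(arm_table)), grp),
                function(i) i[which.max(arm_table$nhb[i])], integer(1))
  arm_table[idx, , drop = FALSE]
}

# highest ESMO grade per indication across its arms (each indication's arms
# share a grading scale, so a within-scale order suffices)
.best_grades <- function(arm_table) {
  ord <- c("1", "2", "3", "4", "5", "C", "B", "A")
  grp <- factor(arm_table$indication_id,
                levels = unique(arm_table$indication_id))
  vapply(split(arm_table$esmo_grade, grp), function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_character_)
    g[which.max(match(g, ord))]
  }, character(1))
}

#' Summarize a scored cohort
#'
#' Medians (standard midpoint convention for even counts), range, and
#' indication-level bonus and grade counts. At `level = "arm"` the medians
#' and range run over every scored arm; at `level = "indication"` they run
#' over the best arm of each indication. Bonus counts, grade counts and the
#' meaningful-benefit count are always at indication level (best arm for
#' the ASCO bonuses, highest grade across arms for the ESMO counts).
#'
#' @param arm_table A [score_cohort()] table.
#' @param level `"arm"` or `"indication"`.
#' @return A `cohort_summary` list: `per_arm_table`, `per_indication_best`
#'   (named by indication), `median_nhb`, `nhb_min`, `nhb_max`,
#'   `median_treatment_effect`, `median_toxicity`, `n_tail_indications`,
#'   `n_tail_os`, `n_tail_pfs`, `n_palliation`, `n_qol`, `n_tfi`,
#'   `grade_counts`, `n_meaningful`, `n_arms`, `n_indications`, `level`.
#' @export
summarize_cohort <- function(arm_table, level = c("arm", "indication")) {
  level <- match.arg(level)
  if (!nrow(arm_table)) stop("empty score table", call. = FALSE)
  best <- .best_rows(arm_table)
  base <- if (level == "arm") arm_table else best
  grades <- .best_grades(arm_table)
  structure(list(
    level = level, per_arm_table = arm_table,
    per_indication_best = setNames(best$trial_id, best$indication_id),
    n_arms = nrow(arm_table), n_indications = nrow(best),
    median_nhb = stats::median(base$nhb),
    nhb_min = min(base$nhb), nhb_max = max(base$nhb),
    median_treatment_effect = stats::median(base$treatment_effect),
    median_toxicity = stats::median(base$toxicity),
    n_tail_indications = sum(best$tail > 0),
    n_tail_os = sum(best$tail == 20),
    n_tail_pfs = sum(best$tail == 16),
    n_palliation = sum(best$palliation > 0),
    n_qol = sum(best$qol_bonus > 0),
    n_tfi = sum(best$tfi > 0),
    grade_counts = table(grades[!is.na(grades)]),
    n_meaningful = sum(grades %in% c("4", "5", "A", "B"))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d arms, %d indications (%s level)\n",
              x$n_arms, x$n_indications, x$level))
  cat(sprintf("  NHB: median %.1f (range %.1f-%.1f)\n", x$median_nhb,
              x$nhb_min, x$nhb_max))
  cat(sprintf("  median treatment effect %.1f | median toxicity %.1f\n",
              x$median_treatment_effect, x$median_toxicity))
  cat(sprintf("  tail bonus: %d indications (%d x 20 pt, %d x 16 pt); palliation %d, QOL %d, TFI %d\n",
              x$n_tail_indications, x$n_tail_os, x$n_tail_pfs,
              x$n_palliation, x$n_qol, x$n_tfi))
  if (length(x$grade_counts)) {
    cat("  ESMO-MCBS grades:",
        paste(sprintf("%s x %d", names(x$grade_counts), x$grade_counts),
              collapse = ", "),
        sprintf("| meaningful benefit: %d\n", x$n_meaningful))
  }
  invisible(x)
}

#' Compare initial and updated cohort assessments
#'
#' Value scores change as long-term survival, toxicity and quality-of-life
#' reports mature. This computes per-indication best-arm NHB deltas
#' (updated minus initial) over the indications present in both phases,
#' splits them into improved (strictly positive), decreased and unchanged,
#' reports the median and range of the improvements, and lists ESMO-MCBS
#' grade changes. Indications present in only one phase are excluded and
#' listed in `excluded`.
#'
#' @param initial,updated `cohort_summary` objects for the two phases.
#' @return A `phase_comparison` list: `deltas` (data.frame), `improved`,
#'   `decreased`, `unchanged`, `median_improvement`, `improvement_range`,
#'   `grade_changes`, `excluded`.
#' @export
compare_phases <- function(initial, updated) {
  stopifnot(inherits(initial, "cohort_summary"),
            inherits(updated, "cohort_summary"))
  bi <- .best_rows(initial$per_arm_table)
  bu <- .best_rows(updated$per_arm_table)
  ni <- setNames(bi$nhb, bi$indication_id)
  nu <- setNames(bu$nhb, bu$indication_id)
  shared <- intersect(names(ni), names(nu))
  excluded <- setdiff(union(names(ni), names(nu)), shared)
  deltas <- data.frame(indication_id = shared,
                       initial_nhb = unname(ni[shared]),
                       updated_nhb = unname(nu[shared]),
                       delta = unname(nu[shared] - ni[shared]),
                       stringsAsFactors = FALSE)
  improved <- deltas[deltas$delta > 0, , drop = FALSE]
  decreased <- deltas[deltas$delta < 0, , drop = FALSE]
  unchanged <- deltas$indication_id[deltas$delta == 0]
  gi <- .best_grades(initial$per_arm_table)
  gu <- .best_grades(updated$per_arm_table)
  gshared <- shared[!is.na(gi[shared]) & !is.na(gu[shared])]
  gch <- data.frame(indication_id = gshared,
                    initial_grade = unname(gi[gshared]),
                    updated_grade = unname(gu[gshared]),
                    stringsAsFactors = FALSE)
  gch <- gch[gch$initial_grade != gch$updated_grade, , drop = FALSE]
  structure(list(
    deltas = deltas, improved = improved, decreased = decreased,
    unchanged = unchanged,
    median_improvement = if (nrow(improved)) stats::median(improved$delta)
      else NA_real_,
    improvement_range = if (nrow(improved)) range(improved$delta)
      else c(NA_real_, NA_real_),
    grade_changes = gch, excluded = excluded),
    class = "phase_comparison")
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf("<phase_comparison> %d shared indications\n", nrow(x$deltas)))
  cat(sprintf("  improved: %d (median +%.1f, range %.1f-%.1f) | decreased: %d | unchanged: %d\n",
              nrow(x$improved), x$median_improvement,
              x$improvement_range[1], x$improvement_range[2],
              nrow(x$decreased), length(x$unchanged)))
  if (nrow(x$decreased))
    cat("  decreases:", paste(sprintf("%s (%.1f -> %.1f)",
                                      x$decreased$indication_id,
                                      x$decreased$initial_nhb,
                                      x$decreased$updated_nhb),
                              collapse = ", "), "\n")
  if (nrow(x$grade_changes))
    cat("  grade changes:", paste(sprintf("%s (%s -> %s)",
                                          x$grade_changes$indication_id,
                                          x$grade_changes$initial_grade,
                                          x$grade_changes$updated_grade),
                                  collapse = ", "), "\n")
  if (length(x$excluded))
    cat("  excluded (single-phase):", paste(x$excluded, collapse = ", "),
        "\n")
  invisible(x)
}
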