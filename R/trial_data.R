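# Trial-arm data model: construction, validation, CSV/JSON serialization,
# and the packaged per-arm records for the FDA-approved checkpoint-inhibitor
# indications (initial and updated assessments).

.settings   <- c("curative", "non_curative")
.endpoints  <- c("OS", "PFS", "RFS_DFS")
.qol_levels <- c("improved", "not_improved", "not_reported")
.phases     <- c("initial", "updated")

# scalar fields in serialization order; list-valued fields are serialized as
# JSON within a CSV cell (see write_trial_table)
.scalar_cols <- c(
  "trial_id", "indication_id", "drug", "cancer_type", "year_approved",
  "setting", "endpoint", "hr", "ci_lower", "ci_upper", "ci_level",
  "median_control", "median_experimental", "gain_months",
  "toxicity_points_override", "tail_bonus_override", "landmark_gain_qualifies",
  "qol", "toxicity_reduced", "palliation_improved", "tfi_improved",
  "toxic_death_increased", "assessment_phase")
.list_cols <- c("landmark_survival", "toxicity_table")

#' Construct a validated trial-arm record
#'
#' One record describes a single experimental arm of a randomized trial
#' compared against its control arm: the treatment-effect estimate (hazard
#' ratio with confidence interval), median survival per arm, landmark
#' (fixed-timepoint) survival proportions, the grade 3-4 adverse-event
#' burden, and the quality-of-life / palliation / treatment-free-interval /
#' toxic-death flags that drive bonus points and grade adjustments.
#'
#' Where a source reports a scored quantity but not the raw inputs behind it
#' (common in published value assessments), the record can carry overrides:
#' `toxicity_points_override` stands in for a raw adverse-event table,
#' `tail_bonus_override` for the landmark survivals behind a published
#' tail-of-the-curve bonus, and `landmark_gain_qualifies` transcribes a
#' published "absolute survival gain of at least 10% at the reference
#' timepoint" qualification when the underlying proportions are unavailable.
#'
#' @param trial_id Arm identifier, e.g. `"KEYNOTE-010-1"`; multi-arm trials
#'   append `-1`/`-2` to the trial name.
#' @param indication_id Groups the arms of one approved indication; defaults
#'   to `trial_id`.
#' @param drug,cancer_type,year_approved Descriptive metadata.
#' @param setting `"curative"` (adjuvant) or `"non_curative"` (advanced).
#' @param endpoint Evaluated survival endpoint: `"OS"`, `"PFS"`, or
#'   `"RFS_DFS"` (recurrence/disease-free survival).
#' @param hr Hazard ratio point estimate (experimental vs control), > 0.
#' @param ci_lower,ci_upper Confidence limits bracketing `hr`.
#' @param ci_level Confidence level in percent, in (50, 100); 95 unless the
#'   trial reported an adjusted interval (e.g. 99.5 for a co-primary
#'   endpoint).
#' @param median_control,median_experimental Median survival in months,
#'   optional. When both are present `gain_months` is derived as their
#'   difference.
#' @param landmark_survival Optional `data.frame` with columns `time`
#'   (months, strictly positive and increasing), `surv_control`,
#'   `surv_experimental` (fractions in \[0, 1\]).
#' @param toxicity_table Optional `data.frame` of grade 3-4 adverse events
#'   with columns `ae`, `inc_control`, `inc_experimental` (incidence
#'   fractions in \[0, 1\]).
#' @param toxicity_points_override Optional pre-computed toxicity score in
#'   \[-20, 20\], used when no raw adverse-event table is available.
#' @param tail_bonus_override Optional pre-assessed tail-of-the-curve bonus
#'   (0, 16 or 20), used when the landmark survivals behind a published
#'   bonus are unavailable.
#' @param landmark_gain_qualifies Optional logical: a transcribed
#'   qualification that the absolute landmark-survival gain met the 10%
#'   threshold at the scale's reference timepoint (`NA` = unknown, assess
#'   from `landmark_survival`).
#' @param qol Quality-of-life outcome: `"improved"`, `"not_improved"`, or
#'   `"not_reported"`.
#' @param toxicity_reduced Logical: significantly less grade 3-4 toxicity in
#'   the experimental arm (an ESMO-MCBS upgrade trigger).
#' @param palliation_improved,tfi_improved Logicals: statistically
#'   significant improvement in cancer-related symptoms / treatment-free
#'   interval (ASCO-VF bonus triggers).
#' @param toxic_death_increased Logical: excess treatment-related deaths (an
#'   ESMO-MCBS downgrade trigger).
#' @param assessment_phase `"initial"` (pivotal report) or `"updated"`
#'   (re-assessment on later survival/QOL/toxicity reports).
#' @param metadata Named list of additional fields carried through
#'   serialization untouched.
#'
#' @return An object of class `trial_arm_record`.
#' @seealso [read_trial_table()], [score_asco()], [score_esmo()]
#' @export
#' @examples
#' rec <- trial_arm_record("EXAMPLE-1", hr = 0.70, ci_lower = 0.52,
#'                         ci_upper = 0.92, median_control = 5.1,
#'                         median_experimental = 7.5, qol = "improved",
#'                         toxicity_reduced = TRUE,
#'                         toxicity_points_override = 7.1)
#' rec$gain_months
trial_arm_record <- function(trial_id, indication_id = trial_id,
                             drug = NA_character_, cancer_type = NA_character_,
                             year_approved = NA_integer_,
                             setting = "non_curative", endpoint = "OS",
                             hr, ci_lower, ci_upper, ci_level = 95,
                             median_control = NA_real_,
                             median_experimental = NA_real_,
                             landmark_survival = NULL, toxicity_table = NULL,
                             toxicity_points_override = NA_real_,
                             tail_bonus_override = NA_real_,
                             landmark_gain_qualifies = NA,
                             qol = "not_reported", toxicity_reduced = FALSE,
                             palliation_improved = FALSE, tfi_improved = FALSE,
                             toxic_death_increased = FALSE,
                             assessment_phase = "initial", metadata = list()) {
  rec <- list(
    trial_id = as.character(trial_id),
    indication_id = as.character(indication_id),
    drug = as.character(drug), cancer_type = as.character(cancer_type),
    year_approved = suppressWarnings(as.integer(year_approved)),
    setting = as.character(setting), endpoint = as.character(endpoint),
    hr = as.numeric(hr), ci_lower = as.numeric(ci_lower),
    ci_upper = as.numeric(ci_upper), ci_level = as.numeric(ci_level),
    median_control = as.numeric(median_control),
    median_experimental = as.numeric(median_experimental),
    gain_months = NA_real_,
    landmark_survival = landmark_survival,
    toxicity_table = toxicity_table,
    toxicity_points_override = as.numeric(toxicity_points_override),
    tail_bonus_override = as.numeric(tail_bonus_override),
    landmark_gain_qualifies = as.logical(landmark_gain_qualifies),
    qol = as.character(qol),
    toxicity_reduced = isTRUE(as.logical(toxicity_reduced)),
    palliation_improved = isTRUE(as.logical(palliation_improved)),
    tfi_improved = isTRUE(as.logical(tfi_improved)),
    toxic_death_increased = isTRUE(as.logical(toxic_death_increased)),
    assessment_phase = as.character(assessment_phase),
    metadata = metadata)
  if (!is.na(rec$median_control) && !is.na(rec$median_experimental))
    rec$gain_months <- rec$median_experimental - rec$median_control
  class(rec) <- "trial_arm_record"
  validate_trial_arm_record(rec)
}

.field_error <- function(rec, field, msg) {
  id <- if (is.list(rec) && !is.null(rec$trial_id) && !is.na(rec$trial_id))
    rec$trial_id else "<unnamed>"
  stop(sprintf("record '%s', field '%s': %s", id, field, msg), call. = FALSE)
}

#' Validate a trial-arm record
#'
#' Enforces the record invariants: a positive hazard ratio bracketed by its
#' confidence limits, survival fractions in \[0, 1\] at strictly increasing
#' positive timepoints, adverse-event incidences in \[0, 1\], overrides
#' within their scales, controlled vocabularies for the categorical fields,
#' and consistency of the derived median gain. A curative-setting record
#' must not be evaluated on PFS.
#'
#' @param rec A `trial_arm_record` (or a bare list with the same fields).
#' @return The validated record, invisibly classed as `trial_arm_record`.
#' @export
validate_trial_arm_record <- function(rec) {
  if (is.null(rec$trial_id) || is.na(rec$trial_id) || !nzchar(rec$trial_id))
    .field_error(rec, "trial_id", "missing or empty")
  for (f in c("setting", "endpoint", "qol", "assessment_phase")) {
    vocab <- switch(f, setting = .settings, endpoint = .endpoints,
                    qol = .qol_levels, assessment_phase = .phases)
    if (is.null(rec[[f]]) || is.na(rec[[f]]) || !rec[[f]] %in% vocab)
      .field_error(rec, f, sprintf("must be one of: %s",
                                   paste(vocab, collapse = ", ")))
  }
  for (f in c("hr", "ci_lower", "ci_upper"))
    if (is.null(rec[[f]]) || is.na(rec[[f]]) || rec[[f]] <= 0)
      .field_error(rec, f, "must be a positive number")
  if (rec$ci_lower > rec$hr)
    .field_error(rec, "ci_lower", sprintf(
      "lower confidence limit %.3g exceeds the point estimate %.3g",
      rec$ci_lower, rec$hr))
  if (rec$ci_upper < rec$hr)
    .field_error(rec, "ci_upper", sprintf(
      "upper confidence limit %.3g is below the point estimate %.3g",
      rec$ci_upper, rec$hr))
  if (is.na(rec$ci_level) || rec$ci_level <= 50 || rec$ci_level >= 100)
    .field_error(rec, "ci_level", "must be a percentage in (50, 100)")
  for (f in c("median_control", "median_experimental"))
    if (!is.na(rec[[f]]) && rec[[f]] <= 0)
      .field_error(rec, f, "median survival must be positive (months)")
  if (!is.na(rec$median_control) && !is.na(rec$median_experimental)) {
    g <- rec$median_experimental - rec$median_control
    if (is.na(rec$gain_months)) rec$gain_months <- g
    else if (abs(rec$gain_months - g) > 1e-6)
      .field_error(rec, "gain_months",
                   "inconsistent with the difference of the arm medians")
  }
  lm <- rec$landmark_survival
  if (!is.null(lm) && nrow(lm) > 0) {
    need <- c("time", "surv_control", "surv_experimental")
    if (!all(need %in% names(lm)))
      .field_error(rec, "landmark_survival", sprintf(
        "must have columns: %s", paste(need, collapse = ", ")))
    if (any(lm$time <= 0) || any(diff(lm$time) <= 0))
      .field_error(rec, "landmark_survival",
                   "timepoints must be strictly positive and increasing")
    sv <- c(lm$surv_control, lm$surv_experimental)
    if (any(is.na(sv)) || any(sv < 0) || any(sv > 1))
      .field_error(rec, "landmark_survival",
                   "survival fractions must lie in [0, 1]")
  }
  tt <- rec$toxicity_table
  if (!is.null(tt) && nrow(tt) > 0) {
    need <- c("ae", "inc_control", "inc_experimental")
    if (!all(need %in% names(tt)))
      .field_error(rec, "toxicity_table", sprintf(
        "must have columns: %s", paste(need, collapse = ", ")))
    inc <- c(tt$inc_control, tt$inc_experimental)
    if (any(is.na(inc)) || any(inc < 0) || any(inc > 1))
      .field_error(rec, "toxicity_table",
                   "incidence fractions must lie in [0, 1]")
  }
  if (!is.na(rec$toxicity_points_override) &&
      abs(rec$toxicity_points_override) > 20)
    .field_error(rec, "toxicity_points_override", "must lie in [-20, 20]")
  if (!is.na(rec$tail_bonus_override) &&
      !rec$tail_bonus_override %in% c(0, 16, 20))
    .field_error(rec, "tail_bonus_override", "must be 0, 16 or 20")
  if (rec$setting == "curative" && rec$endpoint == "PFS")
    .field_error(rec, "endpoint",
                 "curative-setting records are graded on RFS/DFS (or OS), not PFS")
  invisible(structure(rec, class = "trial_arm_record"))
}

#' @export
print.trial_arm_record <- function(x, ...) {
  cat(sprintf("<trial_arm_record> %s (%s, %s, %s phase)\n", x$trial_id,
              x$endpoint, x$setting, x$assessment_phase))
  cat(sprintf("  HR %.2f (%g%% CI %.3g-%.3g)", x$hr, x$ci_level,
              x$ci_lower, x$ci_upper))
  if (!is.na(x$gain_months))
    cat(sprintf("; median gain %.1f mo", x$gain_months))
  cat("\n")
  invisible(x)
}

.record_to_row <- function(rec) {
  row <- lapply(.scalar_cols, function(f) rec[[f]])
  names(row) <- .scalar_cols
  for (f in .list_cols) {
    v <- rec[[f]]
    row[[f]] <- if (is.null(v) || !nrow(v)) "" else
      as.character(jsonlite::toJSON(v, dataframe = "rows", digits = NA))
  }
  for (m in names(rec$metadata)) row[[m]] <- rec$metadata[[m]]
  row
}

.parse_df_cell <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {                      # parsed JSON: list of row-objects
    if (!length(x)) return(NULL)
    return(do.call(rbind, lapply(x, function(r) as.data.frame(r))))
  }
  if (is.character(x) && !is.na(x) && nzchar(x))
    return(as.data.frame(jsonlite::fromJSON(x)))
  NULL
}

.record_from_row <- function(row) {
  row <- row[!vapply(row, is.null, logical(1))]
  mandatory <- c("trial_id", "setting", "endpoint", "hr", "ci_lower",
                 "ci_upper")
  for (f in mandatory)
    if (is.null(row[[f]]) || (length(row[[f]]) == 1 && is.na(row[[f]])))
      stop(sprintf("record '%s': mandatory field '%s' is missing",
                   if (is.null(row$trial_id)) "<unnamed>" else row$trial_id,
                   f), call. = FALSE)
  known <- c(.scalar_cols, .list_cols)
  extra <- row[setdiff(names(row), known)]
  args <- row[intersect(names(row), .scalar_cols)]
  args$gain_months <- NULL               # always re-derived
  args$landmark_survival <- .parse_df_cell(row$landmark_survival)
  args$toxicity_table <- .parse_df_cell(row$toxicity_table)
  args$metadata <- extra
  do.call(trial_arm_record, args)
}

#' Read trial-arm records from CSV or JSON
#'
#' CSV tables are UTF-8 with a header row; the list-valued fields
#' (`landmark_survival`, `toxicity_table`) are JSON arrays of row objects
#' inside the cell. JSON files hold a single document with a `records`
#' array. Unknown columns are preserved in each record's `metadata`. Every
#' record is validated on read; a violated invariant (e.g. a lower
#' confidence limit above the point estimate, or a survival fraction outside
#' \[0, 1\]) raises an error naming the record and field.
#'
#' @param path Input file path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return A list of [trial_arm_record] objects (empty for a header-only
#'   file).
#' @seealso [write_trial_table()]
#' @export
read_trial_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  if (format == "csv") {
    hdr <- names(utils::read.csv(path, nrows = 1, stringsAsFactors = FALSE))
    json_cols <- intersect(.list_cols, hdr)   # keep JSON cells as text
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = setNames(rep("character",
                                                    length(json_cols)),
                                                json_cols))
    if (nrow(df) == 0) return(list())
    lapply(seq_len(nrow(df)), function(i) .record_from_row(as.list(df[i, ])))
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(doc$records, .record_from_row)
  }
}

#' Write trial-arm records to CSV or JSON
#'
#' Inverse of [read_trial_table()]: `write` then `read` is the identity on
#' every field.
#'
#' @param records List of [trial_arm_record] objects.
#' @param path Output file path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  rows <- lapply(records, .record_to_row)
  if (format == "csv") {
    cols <- unique(unlist(lapply(rows, names)))
    df <- do.call(rbind, lapply(rows, function(r) {
      r[setdiff(cols, names(r))] <- NA
      as.data.frame(r[cols], stringsAsFactors = FALSE)
    }))
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    recs <- lapply(records, function(rec) {
      r <- rec[c(.scalar_cols, .list_cols)]
      r <- r[!vapply(r, function(v)
        is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
      c(r, rec$metadata)
    })
    jsonlite::write_json(list(records = recs), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Load the packaged checkpoint-inhibitor assessment data
#'
#' Returns the per-arm records for the 18 FDA-approved immune-checkpoint-
#' inhibitor indications supported by randomized trials, together with the
#' published per-arm score components and ESMO-MCBS grades they were
#' assessed at. The `initial` phase holds the 23 experimental arms scored
#' from the pivotal reports (five indications contributed two arms, each
#' scored separately); the `updated` phase holds the 18 arms re-assessed on
#' later survival, toxicity or quality-of-life reports.
#'
#' The published sources print score components but not, for most arms, the
#' underlying medians or landmark survival proportions; those records
#' therefore carry the printed toxicity scores and tail bonuses as overrides
#' and leave the unprinted inputs `NA`. The one fully worked example
#' (CHECKMATE-141) carries its arm medians.
#'
#' @param phase `"initial"` or `"updated"`.
#' @return A `fixture_set`: list with elements `phase`, `records` (list of
#'   [trial_arm_record]), and `expected` (data.frame of published score
#'   components and grades, columns prefixed `exp_`).
#' @export
#' @examples
#' fx <- load_fixtures("initial")
#' length(fx$records)
load_fixtures <- function(phase = c("initial", "updated")) {
  phase <- match.arg(phase)
  file <- system.file("extdata", paste0("fda_icis_", phase, ".csv"),
                      package = "oncovalue", mustWork = TRUE)
  records <- read_trial_table(file, "csv")
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  exp_cols <- grep("^exp_", names(raw), value = TRUE)
  expected <- raw[, c("trial_id", "indication_id", exp_cols)]
  structure(list(phase = phase, records = records, expected = expected),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("<fixture_set> %s phase: %d arms, %d indications\n", x$phase,
              length(x$records),
              length(unique(vapply(x$records, `[[`, "", "indication_id")))))
  invisible(x)
}
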