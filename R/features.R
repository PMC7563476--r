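#' Data-availability scenarios
#'
#' The four regimes under which classifiers are built, crossing laboratory
#' scope with the availability of coded sources:
#' * `S1`: index stay only, with ICD billing and discharge-summary flags;
#' * `S2`: index stay only, laboratory values and demographics alone;
#' * `S3`: full laboratory history, with ICD and discharge-summary flags;
#' * `S4`: full laboratory history, laboratory values alone.
#'
#' @param id One of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @return A list with `id`, `lab_scope` (`"index_only"` or
#'   `"full_history"`), `include_icd_flags`, `include_ds_flags`.
#' @export
scenario_spec <- function(id = c("S1", "S2", "S3", "S4")) {
  id <- match.arg(id)
  switch(id,
    S1 = list(id = "S1", lab_scope = "index_only", include_icd_flags = TRUE, include_ds_flags = TRUE),
    S2 = list(id = "S2", lab_scope = "index_only", include_icd_flags = FALSE, include_ds_flags = FALSE),
    S3 = list(id = "S3", lab_scope = "full_history", include_icd_flags = TRUE, include_ds_flags = TRUE),
    S4 = list(id = "S4", lab_scope = "full_history", include_icd_flags = FALSE, include_ds_flags = FALSE)
  )
}

#' Derived per-patient visit/measurement ratios
#'
#' Three ratios summarizing how eGFR measurements are distributed over
#' hospital visits (one visit = one hospital stay):
#' the ratio of visits with at least one eGFR measurement to total visits;
#' the ratio of total eGFR measurements to visits with eGFR measurements;
#' and the ratio of eGFR measurements below 60 mL/min/1.73 m² to visits with
#' eGFR measurements. When no visit carries an eGFR the two latter ratios
#' are undefined and reported as 0 with `ratio_defined = 0`.
#'
#' @param labs_egfr Laboratory table carrying an `egfr` column (see
#'   [add_egfr()]).
#' @param stays Stay table (`patient_id`, `stay_id`, `is_index`).
#' @param scope `"full_history"` (all stays) or `"index_only"`.
#' @return Tibble: `patient_id`, `ratio_visits_with_egfr`,
#'   `ratio_measurements_per_visit`, `ratio_low_egfr_per_visit`,
#'   `ratio_defined`.
#' @export
derive_ratios <- function(labs_egfr, stays, scope = c("full_history", "index_only")) {
  scope <- match.arg(scope)
  check_columns(labs_egfr, c("patient_id", "stay_id", "egfr"), "labs_egfr")
  check_columns(stays, c("patient_id", "stay_id", "is_index"), "stays")
  if (scope == "index_only") {
    stays <- dplyr::filter(stays, .data$is_index)
    labs_egfr <- dplyr::filter(labs_egfr, .data$stay_id %in% stays$stay_id)
  }
  if (nrow(stays) == 0) stop("zero hospital visits: ratios undefined", call. = FALSE)
  per_stay <- labs_egfr |>
    dplyr::group_by(.data$patient_id, .data$stay_id) |>
    dplyr::summarise(
      n_meas = dplyr::n(),
      n_low = sum(.data$egfr < EGFR_THRESHOLD),
      .groups = "drop"
    )
  stays |>
    dplyr::left_join(per_stay, by = c("patient_id", "stay_id")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_visits = dplyr::n(),
      n_with = sum(!is.na(.data$n_meas)),
      n_meas = sum(.data$n_meas, na.rm = TRUE),
      n_low = sum(.data$n_low, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      ratio_visits_with_egfr = .data$n_with / .data$n_visits,
      ratio_measurements_per_visit = ifelse(.data$n_with > 0, .data$n_meas / .data$n_with, 0),
      ratio_low_egfr_per_visit = ifelse(.data$n_with > 0, .data$n_low / .data$n_with, 0),
      ratio_defined = as.integer(.data$n_with > 0)
    )
}

#' Build the per-patient feature table for model training
#'
#' Assembles, per patient, the numeric, derived and categorical variables
#' used by the classification models: age; first/last eGFR of the index
#' stay; the time span between first and last index-stay measurement (an
#' indicator of length of stay); mean eGFR over the index stay and over the
#' in-scope history; the three derived ratios; sex; AKI and AKI-recovery
#' indicators over the index stay and over the in-scope history; and the
#' target-specific rule flags (`eGFR`, `eGFR_admission`, `eGFR_discharge`;
#' for NKD under full history the stricter `eGFR_history` flag supersedes
#' the all-index `eGFR` flag), plus `ICD` / `ICD_discharge_summary` flags in
#' scenarios that include coded sources. Under `lab_scope = "index_only"`
#' every history feature collapses to its index-stay counterpart.
#'
#' Patients without any index-stay creatinine are kept, with their
#' laboratory features zeroed and flagged by a `missing_index_lab` indicator
#' (added only when such patients occur). Ground-truth labels are never
#' read.
#'
#' @param cohort A `renal_cohort` or list with `patients`, `stays`, `labs`,
#'   `icd` tables.
#' @param scenario A [scenario_spec()] or scenario id string.
#' @param target `"CKD_GE3"` or `"NKD"`.
#' @param ckd_codeset,exclusion_codeset Code sets for the ICD flags.
#' @return Tibble keyed by `patient_id` with 17 or 19 feature columns.
#' @export
build_feature_table <- function(cohort, scenario = "S1", target = c("CKD_GE3", "NKD"),
                                ckd_codeset = codeset_charlson_renal(),
                                exclusion_codeset = codeset_cdc_exclusion()) {
  target <- match.arg(target)
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  patients <- cohort$patients
  stays <- cohort$stays
  labs <- cohort$labs
  index_scope <- scenario$lab_scope == "index_only"

  labs_e <- add_egfr(labs, patients) |> dplyr::arrange(.data$patient_id, .data$time)
  index_ids <- stays$stay_id[stays$is_index]
  labs_idx <- dplyr::filter(labs_e, .data$stay_id %in% index_ids)
  labs_hist <- if (index_scope) labs_idx else labs_e
  stays_scope <- if (index_scope) dplyr::filter(stays, .data$is_index) else stays

  idx_sum <- labs_idx |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      egfr_first_index = dplyr::first(.data$egfr),
      egfr_last_index = dplyr::last(.data$egfr),
      stay_span = max(.data$time) - min(.data$time),
      egfr_mean_index = mean(.data$egfr),
      .groups = "drop"
    )
  hist_sum <- labs_hist |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(egfr_mean_history = mean(.data$egfr), .groups = "drop")
  ratios <- derive_ratios(labs_hist, stays_scope, scope = "full_history")

  flags <- aki_flags(labs, stays, patients)
  if (index_scope) {
    flags$aki_history <- flags$aki_index
    flags$aki_recovery_history <- flags$aki_recovery_index
  }

  calls <- phenotype_rules(patients, stays, labs, cohort$icd,
    targets = target,
    ckd_codeset = ckd_codeset, exclusion_codeset = exclusion_codeset
  )
  rule_flags <- calls_to_flags(calls)
  rule_cols <- c(
    eGFR = "eGFR_index_stay", eGFR_admission = "eGFR_admission",
    eGFR_discharge = "eGFR_discharge"
  )
  if (target == "NKD" && !index_scope) {
    rule_cols <- c(
      eGFR_history = "eGFR_history", eGFR_admission = "eGFR_admission",
      eGFR_discharge = "eGFR_discharge"
    )
  }
  if (scenario$include_icd_flags) rule_cols <- c(rule_cols, ICD = "ICD_billing")
  if (scenario$include_ds_flags) {
    rule_cols <- c(rule_cols, ICD_discharge_summary = "ICD_discharge_summary")
  }
  rule_flags <- rule_flags |>
    dplyr::select("patient_id", dplyr::all_of(unname(rule_cols))) |>
    dplyr::rename(!!!rule_cols)

  out <- patients |>
    dplyr::transmute(
      patient_id = .data$patient_id, age = .data$age,
      sex = as.integer(.data$sex == "male")
    ) |>
    dplyr::left_join(idx_sum, by = "patient_id") |>
    dplyr::left_join(hist_sum, by = "patient_id") |>
    dplyr::left_join(ratios, by = "patient_id") |>
    dplyr::left_join(flags, by = "patient_id") |>
    dplyr::left_join(rule_flags, by = "patient_id")

  missing_idx <- is.na(out$egfr_mean_index)
  if (any(missing_idx)) {
    out$missing_index_lab <- as.integer(missing_idx)
  }
  num_cols <- setdiff(names(out), "patient_id")
  for (cl in num_cols) out[[cl]][is.na(out[[cl]])] <- 0
  n_features <- length(setdiff(names(out), c("patient_id", "ratio_defined", "missing_index_lab")))
  stopifnot(n_features >= 11, n_features <= 19)
  if (all(out$ratio_defined == 1)) out$ratio_defined <- NULL
  attr(out, "scenario") <- scenario$id
  attr(out, "target") <- target
  out
}

#' Write a feature table with a JSON schema sidecar
#'
#' @param features Output of [build_feature_table()].
#' @param path Path of the CSV file; a `.json` sidecar with the scenario,
#'   target and column set is written next to it.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  jsonlite::write_json(
    list(
      scenario = attr(features, "scenario"), target = attr(features, "target"),
      columns = names(features)
    ),
    sub("\\.csv$", ".json", path),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
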