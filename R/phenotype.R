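CALL_LEVELS <- c("POSITIVE", "NEGATIVE", "NOT_ASSIGNABLE")
EGFR_THRESHOLD <- 60 # mL/min/1.73 m2, CKD stage III boundary

#' Simple categorical rule classifiers for CKD and NKD
#'
#' Single-patient rules operating on eGFR values and AKI indicators. Each
#' returns one of `"POSITIVE"`, `"NEGATIVE"`, `"NOT_ASSIGNABLE"`.
#'
#' * `classify_ckd_egfr_index_stay()`: CKD positive iff *every* eGFR of the
#'   index stay is below 60 mL/min/1.73 m².
#' * `classify_nkd_egfr_index_stay()`: NKD positive iff every index-stay eGFR
#'   is at or above 60 *and* no AKI event occurred during the index stay.
#' * `classify_single_timepoint()`: one eGFR (admission = first, discharge =
#'   last measurement of the index stay); CKD positive iff value < 60, NKD
#'   positive iff value >= 60.
#' * `classify_nkd_full_history()`: NKD positive iff no eGFR below 60 anywhere
#'   in the laboratory history and neither AKI nor AKI recovery anywhere.
#'
#' The threshold convention makes the CKD (`< 60`) and NKD (`>= 60`) rules
#' partition the axis: an eGFR of exactly 60 is negative for CKD and counts
#' as "above 60" for NKD. With no eGFR available a rule abstains
#' (`NOT_ASSIGNABLE`); abstentions are scored as negative predictions
#' downstream.
#'
#' @param egfr Numeric vector of eGFR values (may be empty).
#' @param any_aki,any_recovery Logical; AKI / AKI-recovery present in the
#'   relevant scope.
#' @param value Single eGFR value (or `NA`/length zero when missing).
#' @param target `"CKD_GE3"` or `"NKD"`.
#' @param threshold eGFR cut point, default 60.
#' @return A call string.
#' @name rule_classifiers
NULL

#' @rdname rule_classifiers
#' @export
classify_ckd_egfr_index_stay <- function(egfr) {
  egfr <- egfr[!is.na(egfr)]
  if (!length(egfr)) {
    return("NOT_ASSIGNABLE")
  }
  if (all(egfr < EGFR_THRESHOLD)) "POSITIVE" else "NEGATIVE"
}

#' @rdname rule_classifiers
#' @export
classify_nkd_egfr_index_stay <- function(egfr, any_aki = FALSE) {
  egfr <- egfr[!is.na(egfr)]
  if (!length(egfr)) {
    return("NOT_ASSIGNABLE")
  }
  if (all(egfr >= EGFR_THRESHOLD) && !isTRUE(any_aki)) "POSITIVE" else "NEGATIVE"
}

#' @rdname rule_classifiers
#' @export
classify_single_timepoint <- function(value, target = c("CKD_GE3", "NKD"),
                                      threshold = EGFR_THRESHOLD) {
  target <- match.arg(target)
  value <- value[!is.na(value)]
  if (!length(value)) {
    return("NOT_ASSIGNABLE")
  }
  value <- value[[1]]
  pos <- if (target == "CKD_GE3") value < threshold else value >= threshold
  if (pos) "POSITIVE" else "NEGATIVE"
}

#' @rdname rule_classifiers
#' @export
classify_nkd_full_history <- function(egfr, any_aki = FALSE, any_recovery = FALSE) {
  egfr <- egfr[!is.na(egfr)]
  if (!length(egfr)) {
    return("NOT_ASSIGNABLE")
  }
  ok <- all(egfr >= EGFR_THRESHOLD) && !isTRUE(any_aki) && !isTRUE(any_recovery)
  if (ok) "POSITIVE" else "NEGATIVE"
}

#' Classify one patient by ICD-10 codes of one source
#'
#' CKD: positive iff any code prefix-matches the renal code set. NKD:
#' positive iff *no* code matches the union of the renal set and the
#' exclusion set. A patient without any code of the source is CKD-negative
#' and NKD-positive (absence of disease codes).
#'
#' @param codes Character vector of the patient's ICD-10 codes from one
#'   source (may be empty).
#' @param target `"CKD_GE3"` or `"NKD"`.
#' @param ckd_codeset Renal-disease `icd_codeset` (default: Charlson renal).
#' @param exclusion_codeset Additional kidney-code set used for NKD
#'   exclusion (default: bundled CDC-derived list).
#' @return A call string (`"POSITIVE"`/`"NEGATIVE"`).
#' @export
classify_by_icd <- function(codes, target = c("CKD_GE3", "NKD"),
                            ckd_codeset = codeset_charlson_renal(),
                            exclusion_codeset = codeset_cdc_exclusion()) {
  target <- match.arg(target)
  codes <- codes[!is.na(codes)]
  any_ckd <- length(codes) > 0 && any(icd_matches(codes, ckd_codeset))
  if (target == "CKD_GE3") {
    return(if (any_ckd) "POSITIVE" else "NEGATIVE")
  }
  any_excl <- length(codes) > 0 &&
    any(icd_matches(codes, ckd_codeset) | icd_matches(codes, exclusion_codeset))
  if (any_excl) "NEGATIVE" else "POSITIVE"
}

#' Apply every rule classifier to a cohort
#'
#' Computes, per patient and target, the calls of all single-source rules:
#' `eGFR_index_stay`, `eGFR_admission`, `eGFR_discharge`, `eGFR_history`
#' (NKD only), `ICD_billing` and `ICD_discharge_summary`. Admission and
#' discharge are the first and last eGFR of the index stay; ICD rules use
#' index-stay codes only.
#'
#' @param patients,stays,labs,icd Cohort tables as produced by
#'   [generate_cohort()] (or user-supplied tables with the same schemas).
#' @param targets Targets to classify, subset of `c("CKD_GE3", "NKD")`.
#' @param ckd_codeset,exclusion_codeset Code sets for the ICD rules.
#' @return Tibble with `patient_id`, `target`, `rule`, `call`.
#' @export
phenotype_rules <- function(patients, stays, labs, icd,
                            targets = c("CKD_GE3", "NKD"),
                            ckd_codeset = codeset_charlson_renal(),
                            exclusion_codeset = codeset_cdc_exclusion()) {
  targets <- match.arg(targets, several.ok = TRUE)
  check_columns(stays, c("patient_id", "stay_id", "is_index"), "stays")
  check_columns(icd, c("patient_id", "stay_id", "code", "source"), "icd")
  labs_e <- add_egfr(labs, patients) |>
    dplyr::arrange(.data$patient_id, .data$time)
  index_ids <- stays$stay_id[stays$is_index]
  labs_idx <- dplyr::filter(labs_e, .data$stay_id %in% index_ids)

  flags <- aki_flags(labs, stays, patients)

  idx_sum <- labs_idx |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      all_below = all(.data$egfr < EGFR_THRESHOLD),
      all_at_or_above = all(.data$egfr >= EGFR_THRESHOLD),
      first_egfr = dplyr::first(.data$egfr),
      last_egfr = dplyr::last(.data$egfr),
      .groups = "drop"
    )
  hist_sum <- labs_e |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(all_at_or_above_hist = all(.data$egfr >= EGFR_THRESHOLD), .groups = "drop")

  base <- tibble::tibble(patient_id = unique(patients$patient_id)) |>
    dplyr::left_join(idx_sum, by = "patient_id") |>
    dplyr::left_join(hist_sum, by = "patient_id") |>
    dplyr::left_join(flags, by = "patient_id")

  icd_idx <- dplyr::filter(icd, .data$stay_id %in% index_ids)
  icd_flag <- function(src, target) {
    hits <- icd_idx |> dplyr::filter(.data$source == src)
    pos_ids <- if (target == "CKD_GE3") {
      unique(hits$patient_id[icd_matches(hits$code, ckd_codeset)])
    } else {
      unique(hits$patient_id[
        icd_matches(hits$code, ckd_codeset) | icd_matches(hits$code, exclusion_codeset)
      ])
    }
    if (target == "CKD_GE3") {
      ifelse(base$patient_id %in% pos_ids, "POSITIVE", "NEGATIVE")
    } else {
      ifelse(base$patient_id %in% pos_ids, "NEGATIVE", "POSITIVE")
    }
  }

  tristate <- function(pos, na) {
    dplyr::case_when(na ~ "NOT_ASSIGNABLE", pos ~ "POSITIVE", TRUE ~ "NEGATIVE")
  }
  no_idx <- is.na(base$all_below)
  no_hist <- is.na(base$all_at_or_above_hist)

  out <- list()
  if ("CKD_GE3" %in% targets) {
    out$ckd <- tibble::tibble(
      patient_id = rep(base$patient_id, 5),
      target = "CKD_GE3",
      rule = rep(c(
        "eGFR_index_stay", "eGFR_admission", "eGFR_discharge",
        "ICD_billing", "ICD_discharge_summary"
      ), each = nrow(base)),
      call = c(
        tristate(base$all_below, no_idx),
        tristate(base$first_egfr < EGFR_THRESHOLD, no_idx),
        tristate(base$last_egfr < EGFR_THRESHOLD, no_idx),
        icd_flag("BILLING", "CKD_GE3"),
        icd_flag("DISCHARGE_SUMMARY", "CKD_GE3")
      )
    )
  }
  if ("NKD" %in% targets) {
    out$nkd <- tibble::tibble(
      patient_id = rep(base$patient_id, 6),
      target = "NKD",
      rule = rep(c(
        "eGFR_index_stay", "eGFR_admission", "eGFR_discharge",
        "eGFR_history", "ICD_billing", "ICD_discharge_summary"
      ), each = nrow(base)),
      call = c(
        tristate(base$all_at_or_above & base$aki_index == 0, no_idx),
        tristate(base$first_egfr >= EGFR_THRESHOLD, no_idx),
        tristate(base$last_egfr >= EGFR_THRESHOLD, no_idx),
        tristate(
          base$all_at_or_above_hist & base$aki_history == 0 &
            base$aki_recovery_history == 0,
          no_hist
        ),
        icd_flag("BILLING", "NKD"),
        icd_flag("DISCHARGE_SUMMARY", "NKD")
      )
    )
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$target, .data$rule, .data$patient_id)
}

#' Spread phenotype calls to per-patient binary flags
#'
#' Encodes `POSITIVE` as 1 and both `NEGATIVE` and `NOT_ASSIGNABLE` as 0 (a
#' patient the rule cannot claim is not a positive call), then pivots to one
#' column per rule.
#'
#' @param calls Output of [phenotype_rules()], already filtered to one target.
#' @return Wide tibble: `patient_id` plus one 0/1 column per rule.
#' @export
calls_to_flags <- function(calls) {
  stopifnot(length(unique(calls$target)) <= 1)
  calls |>
    dplyr::mutate(flag = as.integer(.data$call == "POSITIVE")) |>
    dplyr::select("patient_id", "rule", "flag") |>
    tidyr::pivot_wider(names_from = "rule", values_from = "flag")
}

#' Combine per-source flags with logistic regression
#'
#' Fits `truth ~ flags` by maximum-likelihood logistic regression on the
#' training split and scores the test split; this is the "simple categorical
#' classifier" built from a combination of EHR sources. Constant flags are
#' reported as non-identifiable (NA coefficient) with a warning.
#'
#' @param train_flags,test_flags Tibbles with `patient_id` and one 0/1 column
#'   per source flag.
#' @param train_truth Logical/0-1 vector aligned with `train_flags` rows.
#' @param sources Character vector of flag columns to combine (default: all
#'   non-id columns).
#' @return Object of class `source_combo`: the fitted model, the sources
#'   used, and `test_scores` (tibble `patient_id`, `score`).
#' @export
combine_calls_logistic <- function(train_flags, train_truth, test_flags,
                                   sources = NULL) {
  if (is.null(sources)) sources <- setdiff(names(train_flags), "patient_id")
  missing <- setdiff(sources, names(train_flags))
  if (length(missing)) stop("unknown source flag(s): ", paste(missing, collapse = ", "), call. = FALSE)
  x <- dplyr::select(train_flags, dplyr::all_of(sources))
  constant <- vapply(x, function(v) length(unique(v)) < 2, logical(1))
  if (any(constant)) {
    warning(
      "constant flag(s), coefficient non-identifiable: ",
      paste(sources[constant], collapse = ", ")
    )
  }
  df <- data.frame(.y = as.integer(train_truth), x, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = df)
  )
  newx <- data.frame(dplyr::select(test_flags, dplyr::all_of(sources)), check.names = FALSE)
  scores <- as.numeric(suppressWarnings(stats::predict(fit, newdata = newx, type = "response")))
  structure(
    list(
      model = fit, sources = sources,
      test_scores = tibble::tibble(patient_id = test_flags$patient_id, score = scores)
    ),
    class = "source_combo"
  )
}

#' @export
print.source_combo <- function(x, ...) {
  cat(
    "<source_combo> logistic combination of:", paste(x$sources, collapse = " + "),
    "\n scored", nrow(x$test_scores), "test patients\n"
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.source_combo <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' Overlap of positive calls across the three EHR sources
#'
#' Partitions patients into the seven regions of a three-set Venn diagram
#' (plus the none-of-the-three region) according to which sources called
#' them positive; optionally restricted to ground-truth positives.
#'
#' @param flags Wide tibble with `patient_id` and three 0/1 columns.
#' @param sources Character vector naming the three flag columns, in the
#'   order (laboratory, discharge summary, billing) or any other.
#' @param truth Optional logical vector aligned with `flags` rows; when
#'   given, counts are additionally reported within true positives.
#' @return Tibble with `region`, `count` and (when `truth` is given)
#'   `count_true_positive`.
#' @export
source_overlap_report <- function(flags, sources, truth = NULL) {
  stopifnot(length(sources) == 3)
  check_columns(flags, sources, "flags")
  a <- flags[[sources[1]]] > 0
  b <- flags[[sources[2]]] > 0
  c_ <- flags[[sources[3]]] > 0
  regions <- list(
    stats::setNames(list(a & !b & !c_), paste0(sources[1], "_only")),
    stats::setNames(list(!a & b & !c_), paste0(sources[2], "_only")),
    stats::setNames(list(!a & !b & c_), paste0(sources[3], "_only")),
    stats::setNames(list(a & b & !c_), paste(sources[1], sources[2], sep = "&")),
    stats::setNames(list(a & !b & c_), paste(sources[1], sources[3], sep = "&")),
    stats::setNames(list(!a & b & c_), paste(sources[2], sources[3], sep = "&")),
    stats::setNames(list(a & b & c_), "all_three"),
    stats::setNames(list(!a & !b & !c_), "none")
  )
  regions <- unlist(regions, recursive = FALSE)
  out <- tibble::tibble(
    region = names(regions),
    count = unname(vapply(regions, sum, integer(1)))
  )
  if (!is.null(truth)) {
    truth <- as.logical(truth)
    out$count_true_positive <- unname(vapply(regions, function(r) sum(r & truth), integer(1)))
  }
  out
}
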