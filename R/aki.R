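#' @keywords internal
MIN_PER_HOUR <- 60
MIN_PER_DAY <- 1440
AKI_ABS_WINDOW_MIN <- 48 * 60 # 48 h
AKI_REL_WINDOW_MIN <- 7 * 1440 # 7 days
AKI_ABS_THRESHOLD_UMOL <- 26.5 # KDIGO 0.3 mg/dL criterion
AKI_REL_THRESHOLD <- 1.5
AKI_RECOVERY_DECLINE <- 0.33

# All ordered measurement pairs (i before j) within `window` minutes, per
# patient. Window comparison is closed (dt <= window); pairs with dt == 0 are
# excluded (no direction). Returns one row per qualifying pair.
creatinine_pairs <- function(labs, window) {
  a <- dplyr::transmute(labs,
    patient_id = .data$patient_id,
    t_start = .data$time, from_value = .data$creatinine
  )
  b <- dplyr::transmute(labs,
    patient_id = .data$patient_id,
    t_end = .data$time, to_value = .data$creatinine
  )
  dplyr::inner_join(a, b, by = "patient_id", relationship = "many-to-many") |>
    dplyr::filter(.data$t_end > .data$t_start, .data$t_end - .data$t_start <= window)
}

validate_lab_series <- function(labs) {
  check_columns(labs, c("patient_id", "time", "creatinine"), "labs")
  if (nrow(labs) == 0) {
    stop("empty creatinine series: at least one measurement is required", call. = FALSE)
  }
  if (any(!is.finite(labs$creatinine) | labs$creatinine <= 0)) {
    stop("`creatinine` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(labs$time))) stop("`time` must be finite", call. = FALSE)
  tibble::as_tibble(labs)
}

restrict_scope <- function(labs, scope, stays) {
  if (scope == "index") {
    if (is.null(stays)) {
      if (!"stay_id" %in% names(labs)) {
        stop("index scope requires `stays` or a `stay_id` column flagged in `labs`", call. = FALSE)
      }
      stop("index scope requires the `stays` table to identify index stays", call. = FALSE)
    }
    check_columns(stays, c("stay_id", "is_index"), "stays")
    check_columns(labs, "stay_id", "labs")
    index_ids <- stays$stay_id[stays$is_index]
    labs <- dplyr::filter(labs, .data$stay_id %in% index_ids)
  }
  labs
}

#' Detect acute kidney injury events on irregular creatinine series
#'
#' Scans all ordered pairs of measurements per patient (not only adjacent
#' ones) and reports an event for every pair satisfying a KDIGO-style
#' criterion: a rise of more than 26.5 µmol/L within 48 h
#' (`AKI_ABSOLUTE_48H`) or a more than 1.5-fold rise within 7 days
#' (`AKI_RELATIVE_7D`). Windows are closed (\eqn{\Delta t \le} 48 h / 7 d),
#' thresholds strict. Within `scope = "history"` pairs may span hospital
#' stays; `scope = "index"` restricts measurements to the index stay first.
#'
#' @param labs Data frame with `patient_id`, `time` (minutes), `creatinine`
#'   (µmol/L); `stay_id` required for `scope = "index"`.
#' @param scope `"history"` (default, all measurements) or `"index"`.
#' @param stays Stay table with `stay_id` and `is_index`; required for
#'   `scope = "index"`.
#' @return Tibble of events: `patient_id`, `kind`, `t_start`, `t_end`,
#'   `from_value`, `to_value`. Zero rows when no pair qualifies.
#' @export
detect_aki <- function(labs, scope = c("history", "index"), stays = NULL) {
  scope <- match.arg(scope)
  labs <- validate_lab_series(labs)
  labs <- restrict_scope(labs, scope, stays)
  pairs <- creatinine_pairs(labs, AKI_REL_WINDOW_MIN)
  abs_ev <- pairs |>
    dplyr::filter(
      .data$t_end - .data$t_start <= AKI_ABS_WINDOW_MIN,
      .data$to_value - .data$from_value > AKI_ABS_THRESHOLD_UMOL
    ) |>
    dplyr::mutate(kind = "AKI_ABSOLUTE_48H")
  rel_ev <- pairs |>
    dplyr::filter(.data$to_value / .data$from_value > AKI_REL_THRESHOLD) |>
    dplyr::mutate(kind = "AKI_RELATIVE_7D")
  arrange_events(dplyr::bind_rows(abs_ev, rel_ev))
}

#' Detect recovery from acute kidney injury
#'
#' Reports an `AKI_RECOVERY_7D` event for every ordered measurement pair with
#' a creatinine decline of more than 33% within 7 days.
#'
#' @inheritParams detect_aki
#' @return Tibble of events with the same columns as [detect_aki()].
#' @export
detect_aki_recovery <- function(labs, scope = c("history", "index"), stays = NULL) {
  scope <- match.arg(scope)
  labs <- validate_lab_series(labs)
  labs <- restrict_scope(labs, scope, stays)
  ev <- creatinine_pairs(labs, AKI_REL_WINDOW_MIN) |>
    dplyr::filter((.data$from_value - .data$to_value) / .data$from_value > AKI_RECOVERY_DECLINE) |>
    dplyr::mutate(kind = "AKI_RECOVERY_7D")
  arrange_events(ev)
}

arrange_events <- function(ev) {
  ev |>
    dplyr::select("patient_id", "kind", "t_start", "t_end", "from_value", "to_value") |>
    dplyr::arrange(.data$patient_id, .data$t_start, .data$t_end, .data$kind)
}

#' Per-patient AKI and AKI-recovery indicator flags
#'
#' Reduces event lists to binary per-patient indicators, once over the full
#' laboratory history and once restricted to the index stay.
#'
#' @param labs Laboratory table (`patient_id`, `stay_id`, `time`,
#'   `creatinine`).
#' @param stays Stay table with `stay_id` and `is_index`.
#' @param patients Optional patient table; when given, every patient is
#'   represented in the output (zero flags when no event).
#' @return Tibble with `patient_id`, `aki_index`, `aki_recovery_index`,
#'   `aki_history`, `aki_recovery_history` (integers in \{0, 1\}).
#' @export
aki_flags <- function(labs, stays, patients = NULL) {
  ids <- if (is.null(patients)) unique(labs$patient_id) else unique(patients$patient_id)
  flag_tbl <- function(ev) unique(ev$patient_id)
  hist_aki <- flag_tbl(detect_aki(labs))
  hist_rec <- flag_tbl(detect_aki_recovery(labs))
  idx_aki <- flag_tbl(detect_aki(labs, scope = "index", stays = stays))
  idx_rec <- flag_tbl(detect_aki_recovery(labs, scope = "index", stays = stays))
  tibble::tibble(
    patient_id = ids,
    aki_index = as.integer(ids %in% idx_aki),
    aki_recovery_index = as.integer(ids %in% idx_rec),
    aki_history = as.integer(ids %in% hist_aki),
    aki_recovery_history = as.integer(ids %in% hist_rec)
  )
}
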