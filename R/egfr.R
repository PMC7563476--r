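#' Estimated glomerular filtration rate (CKD-EPI 2009)
#'
#' Computes eGFR from serum creatinine with the 2009 CKD-EPI creatinine
#' equation:
#' \deqn{eGFR = 141 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'   \max(Scr/\kappa, 1)^{-1.209} \cdot 0.993^{age} \cdot 1.018[female]
#'   \cdot 1.159[black]}
#' with creatinine \eqn{Scr} in mg/dL, \eqn{\kappa = 0.7} (female) or 0.9
#' (male) and \eqn{\alpha = -0.329} (female) or \eqn{-0.411} (male).
#' Creatinine is accepted in µmol/L and converted internally
#' (1 mg/dL = 88.4 µmol/L).
#'
#' @param creatinine Serum creatinine in µmol/L (positive).
#' @param age Age in years (positive). One value per patient; no
#'   per-measurement birthday arithmetic is attempted.
#' @param sex `"male"` or `"female"` (recycled against `creatinine`).
#' @param black Logical; apply the 1.159 ethnicity coefficient. Defaults to
#'   `FALSE`, appropriate for cohorts of European descent.
#' @return Numeric vector of eGFR values in mL/min/1.73 m².
#' @examples
#' compute_egfr(61.88, age = 50, sex = "female") # Scr at kappa: 141 * 0.993^50 * 1.018
#' @export
compute_egfr <- function(creatinine, age, sex, black = FALSE) {
  sex <- match_sex(sex)
  n <- max(length(creatinine), length(age), length(sex), length(black))
  creatinine <- rep_len(creatinine, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  black <- rep_len(black, n)
  if (any(!is.finite(creatinine) | creatinine <= 0)) {
    stop("`creatinine` must be positive and finite (umol/L)", call. = FALSE)
  }
  if (any(!is.finite(age) | age <= 0)) {
    stop("`age` must be positive and finite (years)", call. = FALSE)
  }
  scr <- umol_to_mgdl(creatinine)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- scr / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^-1.209 * 0.993^age *
    ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
}

#' Invert the CKD-EPI equation
#'
#' Returns the serum creatinine (µmol/L) that yields a given eGFR for a
#' patient of given age/sex/ethnicity. The CKD-EPI closed form is piecewise
#' in creatinine and strictly decreasing, so the inverse is unique. Used by
#' the cohort simulator to turn latent eGFR trajectories into creatinine
#' series.
#'
#' @inheritParams compute_egfr
#' @param egfr Target eGFR in mL/min/1.73 m² (positive).
#' @return Serum creatinine in µmol/L.
#' @export
invert_egfr <- function(egfr, age, sex, black = FALSE) {
  sex <- match_sex(sex)
  n <- max(length(egfr), length(age), length(sex), length(black))
  egfr <- rep_len(egfr, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  black <- rep_len(black, n)
  if (any(!is.finite(egfr) | egfr <= 0)) {
    stop("`egfr` must be positive and finite", call. = FALSE)
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  base <- 141 * 0.993^age * ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
  r <- egfr / base # = (Scr/kappa)^alpha if Scr <= kappa, (Scr/kappa)^-1.209 otherwise
  scr <- ifelse(r >= 1, kappa * r^(1 / alpha), kappa * r^(-1 / 1.209))
  mgdl_to_umol(scr)
}

#' Append eGFR values to a laboratory table
#'
#' Joins patient demographics onto a creatinine table and computes one eGFR
#' per measurement, preserving row order (one output value per input
#' measurement).
#'
#' @param labs Data frame with columns `patient_id`, `time`
#'   (minutes from the cohort epoch) and `creatinine` (µmol/L).
#' @param patients Data frame with columns `patient_id`, `age`, `sex` and
#'   optionally `black` (logical, defaults to `FALSE` when absent).
#' @return `labs` as a tibble with an added `egfr` column.
#' @export
add_egfr <- function(labs, patients) {
  check_columns(labs, c("patient_id", "time", "creatinine"), "labs")
  check_columns(patients, c("patient_id", "age", "sex"), "patients")
  if (!"black" %in% names(patients)) patients$black <- FALSE
  out <- dplyr::left_join(
    tibble::as_tibble(labs),
    dplyr::select(patients, "patient_id", "age", "sex", "black"),
    by = "patient_id"
  )
  if (anyNA(out$age)) {
    missing <- unique(out$patient_id[is.na(out$age)])
    stop("no demographics for patient(s): ", paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  out$egfr <- compute_egfr(out$creatinine, out$age, out$sex, out$black)
  dplyr::select(out, -"age", -"sex", -"black")
}

# unit conversions (1 mg/dL creatinine = 88.4 umol/L)
umol_to_mgdl <- function(x) x / 88.4
mgdl_to_umol <- function(x) x * 88.4

match_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  bad <- !sex %in% c("male", "female")
  if (any(bad)) {
    stop("`sex` must be \"male\" or \"female\"; got: ",
      paste(unique(sex[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  sex
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("`%s` is missing column(s): %s", what, paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  invisible(df)
}
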