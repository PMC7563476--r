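LABELS <- c("CKD_GE3", "NKD", "OTHER")
ICD_SOURCES <- c("BILLING", "DISCHARGE_SUMMARY")

# code pools used when the simulator emits a positive / exclusion / noise code
CHARLSON_EMIT_POOL <- c("N183", "N184", "N185", "N189", "I120", "N052", "Z992", "Z491")
EXCLUSION_EMIT_POOL <- c("N179", "N039", "N059", "N119", "N12", "N132", "Q611", "N26")
NOISE_EMIT_POOL <- c(
  "I10", "I500", "E119", "J449", "I251", "E785", "K219",
  "C189", "A099", "J189", "M545", "D649", "E039", "I480"
)

#' Configuration of the synthetic EHR cohort simulator
#'
#' Returns a validated configuration for [generate_cohort()]. Defaults are
#' calibrated to an elderly, multimorbid, hospitalized cohort: a CKD >= III
#' prevalence of 373/785 and an NKD prevalence of 129/785, label-specific age
#' and admission-eGFR distributions, a 33.6% AKI episode rate among CKD
#' patients, and per-source ICD coding operating points (sensitivity /
#' specificity for each of billing codes and discharge-summary codes, for
#' each target).
#'
#' @param n_patients Number of patients.
#' @param prevalence_ckd,prevalence_nkd Fractions of patients whose latent
#'   truth is CKD >= III and NKD; the remainder is a mixture of "hard
#'   negatives" (`OTHER`): mild CKD stages I-II with occasional eGFR dips,
#'   transient AKI on preserved baseline function, and borderline
#'   trajectories hovering just above 60 mL/min/1.73 m².
#' @param age_mean_sd Named list per label, each `c(mean, sd)` in years
#'   (truncated to 40-95).
#' @param male_fraction Fraction of male patients.
#' @param baseline_egfr Named list per label, each `c(meanlog, sdlog)` of a
#'   lognormal for the latent baseline eGFR; truncated per label so that the
#'   latent trajectory respects the label definition (CKD always < 60, NKD
#'   never < 60).
#' @param egfr_measurement_noise_cv Coefficient of variation of the
#'   multiplicative lognormal measurement noise applied to latent creatinine
#'   (combined analytical and biological variability). 0 switches noise off.
#' @param aki_rate Named vector: probability of at least one AKI episode for
#'   `CKD_GE3` and `NKD` patients (NKD must be 0 by definition); the AKI
#'   share of `OTHER` patients is governed by `other_mix`.
#' @param aki_magnitude `c(meanlog, sdlog, min, max)` of the truncated
#'   lognormal creatinine fold-increase at the episode peak (min must exceed
#'   1.5 so that episodes are detectable in the noise-free limit).
#' @param n_prev_stays `c(lambda, max)`: Poisson mean and cap for the number
#'   of previous hospital stays, placed in disjoint slots of a 1-5 year
#'   window before the index admission.
#' @param measurements_per_stay `c(index_mean, prev_mean)`: mean creatinine
#'   measurement counts (index stays draw `3 + Poisson`, previous stays
#'   `1 + Poisson`).
#' @param stay_length_days `c(index_min, index_mean, prev_min, prev_mean)`.
#' @param coding Data frame with columns `source` (`BILLING`,
#'   `DISCHARGE_SUMMARY`), `target` (`CKD_GE3`, `NKD`), `sens`, `spec`: the
#'   operating point each simulated code source should exhibit against
#'   ground truth. Defaults follow observed hospital operating points
#'   (billing codes for CKD 0.71/0.91, discharge summaries for CKD
#'   0.86/0.76, billing for NKD 0.99/0.53, discharge summaries for NKD
#'   0.98/0.68).
#' @param p_other_anomaly_index Probability that an `OTHER` patient's
#'   disqualifying anomaly (eGFR dip or AKI episode) is observable during
#'   the index stay; otherwise it occurs in a previous stay only, so the
#'   index-stay NKD rule cannot see it. 1 makes the observed index stay
#'   fully informative (the noise-free limit used for rule-recovery checks).
#' @param other_mix Mixture weights of the three `OTHER` sub-types
#'   `c(mild_ckd, transient_aki, borderline)`.
#' @param seed Integer seed; identical (config, seed) gives bit-identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 785,
                          prevalence_ckd = 373 / 785,
                          prevalence_nkd = 129 / 785,
                          age_mean_sd = list(
                            CKD_GE3 = c(77.9, 10),
                            NKD = c(68.4, 13.7),
                            OTHER = c(74.6, 12.2)
                          ),
                          male_fraction = 0.606,
                          baseline_egfr = list(
                            CKD_GE3 = c(meanlog = log(28.9), sdlog = 0.62),
                            NKD = c(meanlog = log(88.6), sdlog = 0.18),
                            OTHER = c(meanlog = log(72), sdlog = 0.20)
                          ),
                          egfr_measurement_noise_cv = 0.05,
                          aki_rate = c(CKD_GE3 = 0.336, NKD = 0),
                          aki_magnitude = c(meanlog = log(2.2), sdlog = 0.25, min = 1.7, max = 6),
                          n_prev_stays = c(lambda = 2, max = 8),
                          measurements_per_stay = c(index_mean = 5, prev_mean = 2.5),
                          stay_length_days = c(
                            index_min = 5, index_mean = 10,
                            prev_min = 1, prev_mean = 4
                          ),
                          coding = default_coding(),
                          p_other_anomaly_index = 0.6,
                          other_mix = c(mild_ckd = 1, transient_aki = 1, borderline = 1) / 3,
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, prevalence_ckd = prevalence_ckd,
    prevalence_nkd = prevalence_nkd, age_mean_sd = age_mean_sd,
    male_fraction = male_fraction, baseline_egfr = baseline_egfr,
    egfr_measurement_noise_cv = egfr_measurement_noise_cv,
    aki_rate = aki_rate, aki_magnitude = aki_magnitude,
    n_prev_stays = n_prev_stays, measurements_per_stay = measurements_per_stay,
    stay_length_days = stay_length_days, coding = tibble::as_tibble(coding),
    p_other_anomaly_index = p_other_anomaly_index,
    other_mix = other_mix / sum(other_mix), seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_coding <- function() {
  tibble::tibble(
    source = rep(ICD_SOURCES, each = 2),
    target = rep(c("CKD_GE3", "NKD"), 2),
    sens = c(0.71, 0.99, 0.86, 0.98),
    spec = c(0.91, 0.53, 0.76, 0.68)
  )
}

#' A noise-free, perfectly coded configuration
#'
#' Degenerate configuration in which the observed tables fully determine the
#' latent truth: no measurement noise, perfect ICD coding for both sources
#' and targets, and every `OTHER` patient's anomaly observable during the
#' index stay. In this limit every rule classifier recovers ground truth
#' exactly.
#'
#' @param n_patients Number of patients.
#' @param ... Further overrides passed to [cohort_config()].
#' @export
cohort_config_noisefree <- function(n_patients = 2000, ...) {
  perfect <- default_coding()
  perfect$sens <- 1
  perfect$spec <- 1
  cohort_config(
    n_patients = n_patients, egfr_measurement_noise_cv = 0,
    coding = perfect, p_other_anomaly_index = 1, ...
  )
}

fail_field <- function(field, msg) {
  stop(sprintf("invalid cohort config: `%s` %s", field, msg), call. = FALSE)
}

validate_cohort_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) fail_field(field, "must lie in [0, 1]")
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
    is.na(cfg$n_patients) || cfg$n_patients < 0 || cfg$n_patients %% 1 != 0) {
    fail_field("n_patients", "must be a nonnegative integer")
  }
  chk_prob(cfg$prevalence_ckd, "prevalence_ckd")
  chk_prob(cfg$prevalence_nkd, "prevalence_nkd")
  if (cfg$prevalence_ckd + cfg$prevalence_nkd > 1 + 1e-12) {
    fail_field("prevalence_ckd", "+ prevalence_nkd must not exceed 1")
  }
  chk_prob(cfg$male_fraction, "male_fraction")
  chk_prob(cfg$p_other_anomaly_index, "p_other_anomaly_index")
  if (!all(LABELS %in% names(cfg$age_mean_sd))) {
    fail_field("age_mean_sd", "must name all of CKD_GE3, NKD, OTHER")
  }
  if (!all(LABELS %in% names(cfg$baseline_egfr))) {
    fail_field("baseline_egfr", "must name all of CKD_GE3, NKD, OTHER")
  }
  if (!is.numeric(cfg$egfr_measurement_noise_cv) || cfg$egfr_measurement_noise_cv < 0) {
    fail_field("egfr_measurement_noise_cv", "must be >= 0")
  }
  chk_prob(cfg$aki_rate, "aki_rate")
  if (!all(c("CKD_GE3", "NKD") %in% names(cfg$aki_rate))) {
    fail_field("aki_rate", "must name CKD_GE3 and NKD")
  }
  if (cfg$aki_rate[["NKD"]] != 0) {
    fail_field("aki_rate", "must be 0 for NKD (no AKI by definition)")
  }
  if (cfg$aki_magnitude[["min"]] <= 1.5) {
    fail_field("aki_magnitude", "min fold-increase must exceed the 1.5 detection threshold")
  }
  if (cfg$n_prev_stays[["lambda"]] < 0 || cfg$n_prev_stays[["max"]] < 1) {
    fail_field("n_prev_stays", "lambda must be >= 0 and max >= 1")
  }
  need <- c("source", "target", "sens", "spec")
  if (!all(need %in% names(cfg$coding))) {
    fail_field("coding", paste("must have columns", paste(need, collapse = ", ")))
  }
  chk_prob(cfg$coding$sens, "coding$sens")
  chk_prob(cfg$coding$spec, "coding$spec")
  for (src in ICD_SOURCES) {
    for (tg in c("CKD_GE3", "NKD")) {
      if (sum(cfg$coding$source == src & cfg$coding$target == tg) != 1) {
        fail_field("coding", sprintf("needs exactly one row for (%s, %s)", src, tg))
      }
    }
  }
  if (length(cfg$other_mix) != 3 || any(cfg$other_mix < 0)) {
    fail_field("other_mix", "must be three nonnegative weights")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(
    "<cohort_config>", x$n_patients, "patients | prevalence CKD>=III",
    round(x$prevalence_ckd, 3), "NKD", round(x$prevalence_nkd, 3),
    "| noise CV", x$egfr_measurement_noise_cv, "| seed", x$seed, "\n"
  )
  invisible(x)
}

# truncated lognormal / normal draws via quantile inversion (vectorized)
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  if (n == 0) {
    return(numeric(0))
  }
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, p_lo, p_hi), meanlog, sdlog)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (n == 0) {
    return(numeric(0))
  }
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Per-source emission probabilities reproducing the configured coding
# operating points. A = "a Charlson renal code is present", B = "another
# kidney (exclusion-set) code is present". The CKD call is A; the NKD call is
# (!A & !B). Solves for P(A | label) and P(B | label) so that the empirical
# sensitivity/specificity of both calls match the configured values.
solve_coding_rates <- function(sens_ckd, spec_ckd, sens_nkd, spec_nkd, pi) {
  pi_c <- pi[["CKD_GE3"]]
  pi_n <- pi[["NKD"]]
  pi_o <- pi[["OTHER"]]
  a_c <- sens_ckd
  if (pi_n + pi_o == 0) { # all-CKD cohort: negative-class rates are moot
    return(list(
      a = c(CKD_GE3 = a_c, NKD = 0, OTHER = 0),
      b = c(CKD_GE3 = 0, NKD = 0, OTHER = 0)
    ))
  }
  if (pi_c + pi_o == 0) { # all-NKD cohort: only the NKD sensitivity binds
    return(list(
      a = c(CKD_GE3 = a_c, NKD = 1 - spec_ckd, OTHER = 0),
      b = c(CKD_GE3 = 0, NKD = max(1 - sens_nkd / spec_ckd, 0), OTHER = 0)
    ))
  }
  if (pi_o > 0) {
    a_n <- 0
    a_o <- (1 - spec_ckd) * (pi_n + pi_o) / pi_o
  } else {
    a_n <- 1 - spec_ckd
    a_o <- 0
  }
  if (a_o > 1 + 1e-9 || a_n > 1) {
    fail_field("coding", sprintf(
      "infeasible: CKD specificity %.2f cannot be concentrated on non-NKD patients", spec_ckd
    ))
  }
  a_o <- min(a_o, 1)
  if (a_n >= 1 && sens_nkd > 0) fail_field("coding", "infeasible NKD sensitivity")
  b_n <- 1 - sens_nkd / (1 - a_n)
  if (b_n < -1e-9) {
    fail_field("coding", sprintf("infeasible: NKD sensitivity %.2f unattainable", sens_nkd))
  }
  b_n <- max(b_n, 0)
  denom <- pi_c + pi_o
  c0 <- (pi_c * a_c + pi_o * a_o) / denom
  c1 <- (pi_c * (1 - a_c) + pi_o * (1 - a_o)) / denom
  if (c1 < 1e-12) {
    b <- 0
    if (abs(spec_nkd - c0) > 1e-6) {
      fail_field("coding", sprintf("infeasible NKD specificity %.2f (must be %.3f here)", spec_nkd, c0))
    }
  } else {
    b <- (spec_nkd - c0) / c1
  }
  if (b < -1e-9 || b > 1 + 1e-9) {
    fail_field("coding", sprintf(
      "infeasible: NKD specificity %.2f not reachable given the CKD operating point", spec_nkd
    ))
  }
  b <- min(max(b, 0), 1)
  list(
    a = c(CKD_GE3 = a_c, NKD = a_n, OTHER = a_o),
    b = c(CKD_GE3 = b, NKD = b_n, OTHER = b)
  )
}

empty_cohort <- function(config) {
  structure(list(
    patients = tibble::tibble(
      patient_id = character(), sex = character(),
      age = numeric(), black = logical()
    ),
    stays = tibble::tibble(
      patient_id = character(), stay_id = character(),
      admit_time = numeric(), discharge_time = numeric(), is_index = logical()
    ),
    labs = tibble::tibble(
      patient_id = character(), stay_id = character(),
      time = numeric(), creatinine = numeric()
    ),
    icd = tibble::tibble(
      patient_id = character(), stay_id = character(),
      code = character(), source = character()
    ),
    labels = tibble::tibble(patient_id = character(), label = character()),
    latent = tibble::tibble(
      patient_id = character(), stay_id = character(),
      time = numeric(), creatinine_latent = numeric(), egfr_latent = numeric()
    ),
    config = config
  ), class = "renal_cohort")
}

#' Generate a synthetic EHR cohort with known kidney status
#'
#' Simulates a hospitalized cohort as five linked tables (patients, hospital
#' stays, creatinine laboratory values, ICD-10 codes per source, and latent
#' ground-truth labels). The generator first draws a latent noiseless eGFR
#' trajectory per patient — constant label-specific baseline, plus transient
#' creatinine spikes for AKI episodes and isolated sub-60 dips for the
#' "hard-negative" mixture — inverts the CKD-EPI equation to latent
#' creatinine, and then applies multiplicative lognormal measurement noise.
#' ICD code rows are emitted per source by Bernoulli draws calibrated so
#' that each source's empirical sensitivity/specificity against ground truth
#' matches the configured operating point.
#'
#' Timestamps are integer minutes from a common cohort epoch. Previous stays
#' occupy disjoint slots of a 1-5-year window before the index admission, so
#' AKI detection windows never straddle two different stays.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return Object of class `renal_cohort`: a list of tibbles `patients`,
#'   `stays`, `labs`, `icd`, `labels`, plus `latent` (the noiseless series,
#'   for auditing only — downstream analysis must not read it) and the
#'   `config` used.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  if (is.null(seed)) seed <- config$seed
  n <- config$n_patients
  if (n == 0) {
    return(empty_cohort(config))
  }
  set.seed(as.integer(seed))

  id_width <- max(4, nchar(as.character(n)))
  pid <- sprintf(paste0("P%0", id_width, "d"), seq_len(n))
  label <- sample(LABELS, n,
    replace = TRUE,
    prob = c(
      config$prevalence_ckd, config$prevalence_nkd,
      1 - config$prevalence_ckd - config$prevalence_nkd
    )
  )
  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  age <- numeric(n)
  for (lb in LABELS) {
    m <- label == lb
    ms <- config$age_mean_sd[[lb]]
    age[m] <- round(rnorm_trunc(sum(m), ms[1], ms[2], 40, 95), 1)
  }

  # OTHER sub-types: 1 = mild CKD I-II (dips), 2 = transient AKI, 3 = borderline
  subtype <- rep(NA_character_, n)
  is_other <- label == "OTHER"
  subtype[is_other] <- sample(c("mild_ckd", "transient_aki", "borderline"),
    sum(is_other),
    replace = TRUE, prob = config$other_mix
  )

  baseline_egfr <- numeric(n)
  for (lb in LABELS) {
    m <- label == lb
    p <- config$baseline_egfr[[lb]]
    bounds <- switch(lb,
      CKD_GE3 = c(8, 58),
      NKD = c(65, 150),
      OTHER = c(62, 120)
    )
    baseline_egfr[m] <- rlnorm_trunc(sum(m), p[["meanlog"]], p[["sdlog"]], bounds[1], bounds[2])
  }
  # sub-type specific baseline ranges for the hard negatives
  st <- function(s) is_other & subtype == s
  baseline_egfr[st("mild_ckd")] <- pmin(pmax(baseline_egfr[st("mild_ckd")], 62), 85)
  baseline_egfr[st("borderline")] <- 62 + (baseline_egfr[st("borderline")] - 62) %% 6
  baseline_creat <- invert_egfr(baseline_egfr, age, sex)

  # anomaly bookkeeping: kind ("aki"/"dip"/none) and location (index/history)
  has_aki <- rep(FALSE, n)
  has_aki[label == "CKD_GE3"] <- stats::runif(sum(label == "CKD_GE3")) < config$aki_rate[["CKD_GE3"]]
  has_aki[st("transient_aki")] <- TRUE
  has_dip <- st("mild_ckd") | st("borderline")
  anomaly_kind <- ifelse(has_aki & is_other, "aki",
    ifelse(has_dip, "dip", ifelse(has_aki, "aki", "none"))
  )
  anomaly_in_index <- rep(TRUE, n)
  anomaly_in_index[is_other] <- stats::runif(sum(is_other)) < config$p_other_anomaly_index

  # hospital stays ---------------------------------------------------------
  lam <- config$n_prev_stays[["lambda"]]
  n_prev <- pmin(stats::rpois(n, lam), config$n_prev_stays[["max"]])
  needs_hist <- is_other & anomaly_kind != "none" & !anomaly_in_index
  n_prev[needs_hist] <- pmax(n_prev[needs_hist], 1L)

  sl <- config$stay_length_days
  index_admit <- floor(stats::runif(n, 5 * 365 * MIN_PER_DAY, 6 * 365 * MIN_PER_DAY))
  index_len <- (sl[["index_min"]] + stats::rgamma(n, shape = 2, scale = (sl[["index_mean"]] - sl[["index_min"]]) / 2)) * MIN_PER_DAY
  host_index_aki <- anomaly_kind == "aki" & anomaly_in_index
  host_index_dip <- anomaly_kind == "dip" & anomaly_in_index
  index_len[host_index_aki] <- pmax(index_len[host_index_aki], 11000)
  index_len[host_index_dip] <- pmax(index_len[host_index_dip], 9200)
  index_len <- floor(index_len)

  index_stays <- tibble::tibble(
    patient_id = pid, stay_id = paste0(pid, "-S0"),
    admit_time = index_admit, discharge_time = index_admit + index_len,
    is_index = TRUE,
    host = ifelse(host_index_aki, "aki", ifelse(host_index_dip, "dip", "none"))
  )

  prev_rows <- tibble::tibble(patient_id = pid, n_prev = n_prev, index_admit = index_admit) |>
    tidyr::uncount(.data$n_prev, .id = "k") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(n_k = dplyr::n()) |>
    dplyr::ungroup()
  if (nrow(prev_rows) > 0) {
    win_lo <- prev_rows$index_admit - 5 * 365 * MIN_PER_DAY
    slot_w <- (4 * 365 * MIN_PER_DAY) / prev_rows$n_k
    ord <- match(prev_rows$patient_id, pid)
    host_hist <- needs_hist[ord] & prev_rows$k == 1
    kindh <- anomaly_kind[ord]
    plen <- (sl[["prev_min"]] + stats::rgamma(nrow(prev_rows), shape = 2, scale = (sl[["prev_mean"]] - sl[["prev_min"]]) / 2)) * MIN_PER_DAY
    plen[host_hist & kindh == "aki"] <- pmax(plen[host_hist & kindh == "aki"], 11000)
    plen[host_hist & kindh == "dip"] <- pmax(plen[host_hist & kindh == "dip"], 9200)
    plen <- floor(pmin(plen, slot_w - 11 * MIN_PER_DAY))
    admit <- floor(win_lo + (prev_rows$k - 1) * slot_w +
      stats::runif(nrow(prev_rows)) * (slot_w - plen - 10 * MIN_PER_DAY))
    prev_stays <- tibble::tibble(
      patient_id = prev_rows$patient_id,
      stay_id = paste0(prev_rows$patient_id, "-S", prev_rows$k),
      admit_time = admit, discharge_time = admit + plen, is_index = FALSE,
      host = ifelse(host_hist & kindh == "aki", "aki",
        ifelse(host_hist & kindh == "dip", "dip", "none")
      )
    )
  } else {
    prev_stays <- index_stays[0, ]
  }
  stays_full <- dplyr::bind_rows(index_stays, prev_stays) |>
    dplyr::arrange(.data$patient_id, .data$admit_time)

  # measurement schedule ---------------------------------------------------
  plain <- dplyr::filter(stays_full, .data$host == "none")
  mps <- config$measurements_per_stay
  n_meas <- ifelse(plain$is_index,
    3 + stats::rpois(nrow(plain), max(mps[["index_mean"]] - 3, 0)),
    1 + stats::rpois(nrow(plain), max(mps[["prev_mean"]] - 1, 0))
  )
  plain_meas <- plain |>
    dplyr::mutate(n_meas = n_meas) |>
    tidyr::uncount(.data$n_meas) |>
    dplyr::mutate(
      time = .data$admit_time + 120 +
        floor(stats::runif(dplyr::n()) * (.data$discharge_time - .data$admit_time - 240)),
      fold = 1
    )

  # dip hosts: three measurements, dip in the middle, neighbours > 48 h away
  dips <- dplyr::filter(stays_full, .data$host == "dip")
  if (nrow(dips) > 0) {
    len <- dips$discharge_time - dips$admit_time
    dip_meas <- tibble::tibble(
      patient_id = rep(dips$patient_id, 3),
      stay_id = rep(dips$stay_id, 3),
      admit_time = rep(dips$admit_time, 3),
      discharge_time = rep(dips$discharge_time, 3),
      is_index = rep(dips$is_index, 3),
      host = "dip",
      time = c(
        dips$admit_time + 300,
        dips$admit_time + floor(len / 2),
        dips$discharge_time - 300
      ),
      fold = rep(c(1, NA, 1), each = nrow(dips)) # NA marks the dip point
    )
    # dip target below 60; the creatinine ratio is kept at <= 1.42 (below the
    # 1.5-fold AKI criterion) by raising the baseline where needed, so a dip
    # can never register as an AKI event itself
    ordd <- match(dips$patient_id, pid)
    target <- stats::runif(nrow(dips), 48, 57)
    creat_target <- invert_egfr(target, age[ordd], sex[ordd])
    baseline_creat[ordd] <- pmax(baseline_creat[ordd], creat_target / 1.42)
    baseline_egfr[ordd] <- compute_egfr(baseline_creat[ordd], age[ordd], sex[ordd])
    dip_fold <- creat_target / baseline_creat[ordd]
    dip_meas$fold[is.na(dip_meas$fold)] <- dip_fold
  } else {
    dip_meas <- plain_meas[0, ]
  }

  # AKI hosts: baseline, peak (onset + 2 d), mid-decline, near-baseline
  akis <- dplyr::filter(stays_full, .data$host == "aki")
  if (nrow(akis) > 0) {
    am <- config$aki_magnitude
    f <- rlnorm_trunc(nrow(akis), am[["meanlog"]], am[["sdlog"]], am[["min"]], am[["max"]])
    len <- akis$discharge_time - akis$admit_time
    t_on <- akis$admit_time + 720 +
      floor(stats::runif(nrow(akis)) * (len - 9560 - 920))
    aki_meas <- tibble::tibble(
      patient_id = rep(akis$patient_id, 4),
      stay_id = rep(akis$stay_id, 4),
      admit_time = rep(akis$admit_time, 4),
      discharge_time = rep(akis$discharge_time, 4),
      is_index = rep(akis$is_index, 4),
      host = "aki",
      time = c(t_on - 720, t_on + 2880, t_on + 5760, t_on + 8640),
      fold = c(rep(1, nrow(akis)), f, 1 + (f - 1) / 2, rep(1, nrow(akis)))
    )
  } else {
    aki_meas <- plain_meas[0, ]
  }

  meas <- dplyr::bind_rows(plain_meas, dip_meas, aki_meas) |>
    dplyr::arrange(.data$patient_id, .data$time)

  ordm <- match(meas$patient_id, pid)
  creat_latent <- baseline_creat[ordm] * meas$fold
  cv <- config$egfr_measurement_noise_cv
  if (cv > 0) {
    s <- sqrt(log(1 + cv^2))
    noise <- exp(stats::rnorm(nrow(meas), -s^2 / 2, s))
  } else {
    noise <- 1
  }
  creat_obs <- creat_latent * noise

  labs <- tibble::tibble(
    patient_id = meas$patient_id, stay_id = meas$stay_id,
    time = meas$time, creatinine = round(creat_obs, 2)
  )
  latent <- tibble::tibble(
    patient_id = meas$patient_id, stay_id = meas$stay_id,
    time = meas$time, creatinine_latent = creat_latent,
    egfr_latent = compute_egfr(creat_latent, age[ordm], sex[ordm])
  )

  # ICD codes --------------------------------------------------------------
  pi <- c(
    CKD_GE3 = config$prevalence_ckd, NKD = config$prevalence_nkd,
    OTHER = 1 - config$prevalence_ckd - config$prevalence_nkd
  )
  icd_out <- list()
  for (src in ICD_SOURCES) {
    row_c <- config$coding[config$coding$source == src & config$coding$target == "CKD_GE3", ]
    row_n <- config$coding[config$coding$source == src & config$coding$target == "NKD", ]
    rates <- solve_coding_rates(row_c$sens, row_c$spec, row_n$sens, row_n$spec, pi)
    emit_a <- stats::runif(n) < rates$a[label]
    emit_b <- stats::runif(n) < rates$b[label]
    n_noise <- stats::rpois(n, 3)
    code_rows <- list()
    if (any(emit_a)) {
      code_rows$a <- tibble::tibble(
        patient_id = pid[emit_a],
        code = sample(CHARLSON_EMIT_POOL, sum(emit_a), replace = TRUE)
      )
    }
    if (any(emit_b)) {
      code_rows$b <- tibble::tibble(
        patient_id = pid[emit_b],
        code = sample(EXCLUSION_EMIT_POOL, sum(emit_b), replace = TRUE)
      )
    }
    if (sum(n_noise) > 0) {
      code_rows$noise <- tibble::tibble(
        patient_id = rep(pid, n_noise),
        code = sample(NOISE_EMIT_POOL, sum(n_noise), replace = TRUE)
      )
    }
    icd_out[[src]] <- dplyr::bind_rows(code_rows) |>
      dplyr::mutate(stay_id = paste0(.data$patient_id, "-S0"), source = src)
  }
  icd <- dplyr::bind_rows(icd_out) |>
    dplyr::distinct(.data$patient_id, .data$stay_id, .data$code, .data$source) |>
    dplyr::arrange(.data$source, .data$patient_id, .data$code)

  structure(list(
    patients = tibble::tibble(patient_id = pid, sex = sex, age = age, black = FALSE),
    stays = dplyr::select(stays_full, -"host"),
    labs = labs,
    icd = icd,
    labels = tibble::tibble(patient_id = pid, label = label),
    latent = latent,
    config = config
  ), class = "renal_cohort")
}

#' @export
print.renal_cohort <- function(x, ...) {
  cat(
    "<renal_cohort>", nrow(x$patients), "patients,", nrow(x$stays), "stays,",
    nrow(x$labs), "creatinine measurements,", nrow(x$icd), "ICD rows\n"
  )
  if (nrow(x$labels)) print(table(x$labels$label))
  invisible(x)
}

#' Summarize an observed cohort by ground-truth label
#'
#' Computes descriptive statistics per latent label from the *observed*
#' tables only (the latent noiseless series is never read): group size, age
#' mean/SD (SD is `NA` for singleton groups), male fraction, median admission
#' eGFR (first eGFR of the index stay), and AKI incidence (fraction of
#' patients with at least one detected AKI event anywhere in the history).
#'
#' @param cohort A `renal_cohort` (or a list with elements `patients`,
#'   `stays`, `labs`, `labels`).
#' @return Tibble with one row per label.
#' @export
summarize_cohort <- function(cohort) {
  check_columns(cohort$patients, c("patient_id", "sex", "age"), "patients")
  check_columns(cohort$labels, c("patient_id", "label"), "labels")
  if (nrow(cohort$patients) == 0) {
    return(tibble::tibble(
      label = character(), n = integer(), age_mean = numeric(),
      age_sd = numeric(), male_fraction = numeric(),
      egfr_admission_median = numeric(), aki_incidence = numeric()
    ))
  }
  labs_e <- add_egfr(cohort$labs, cohort$patients)
  index_ids <- cohort$stays$stay_id[cohort$stays$is_index]
  adm <- labs_e |>
    dplyr::filter(.data$stay_id %in% index_ids) |>
    dplyr::arrange(.data$patient_id, .data$time) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(egfr_admission = dplyr::first(.data$egfr), .groups = "drop")
  aki_ids <- unique(detect_aki(cohort$labs)$patient_id)
  cohort$patients |>
    dplyr::left_join(cohort$labels, by = "patient_id") |>
    dplyr::left_join(adm, by = "patient_id") |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      age_mean = mean(.data$age),
      age_sd = ifelse(dplyr::n() > 1, stats::sd(.data$age), NA_real_),
      male_fraction = mean(.data$sex == "male"),
      egfr_admission_median = stats::median(.data$egfr_admission, na.rm = TRUE),
      aki_incidence = mean(.data$patient_id %in% aki_ids),
      .groups = "drop"
    )
}

#' Write / read a cohort as delimited text tables
#'
#' `write_cohort()` writes `patients.csv`, `stays.csv`, `labs.csv`,
#' `icd.csv` and `labels.csv` plus a `manifest.json` sidecar recording the
#' configuration and seed. `read_cohort()` loads them back, validating the
#' column schemas.
#'
#' @param cohort A `renal_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `renal_cohort` (without the latent table).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "stays", "labs", "icd", "labels")) {
    readr::write_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  cfg <- cohort$config
  cfg$coding <- as.data.frame(cfg$coding)
  jsonlite::write_json(
    list(config = unclass(cfg), seed = cohort$config$seed),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  schemas <- list(
    patients = c("patient_id", "sex", "age"),
    stays = c("patient_id", "stay_id", "admit_time", "discharge_time", "is_index"),
    labs = c("patient_id", "stay_id", "time", "creatinine"),
    icd = c("patient_id", "stay_id", "code", "source"),
    labels = c("patient_id", "label")
  )
  out <- list()
  for (nm in names(schemas)) {
    tbl <- readr::read_csv(file.path(dir, paste0(nm, ".csv")),
      show_col_types = FALSE, progress = FALSE
    )
    check_columns(tbl, schemas[[nm]], nm)
    out[[nm]] <- tbl
  }
  if (!"black" %in% names(out$patients)) out$patients$black <- FALSE
  structure(out, class = "renal_cohort")
}
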