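test_that("identical (config, seed) gives byte-identical serialized tables", {
  cfg <- cohort_config(n_patients = 150)
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  for (nm in c("patients", "stays", "labs", "icd", "labels")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7), readBin(file.path(d2, f), "raw", 1e7))
  }
  c2 <- generate_cohort(cfg, seed = 10)
  expect_false(identical(a$labs, c2$labs))
})

test_that("round trip through csv preserves the tables", {
  a <- small_cohort(n = 60, seed = 3)
  d <- file.path(tempdir(), "coh_rt")
  write_cohort(a, d)
  b <- read_cohort(d)
  expect_equal(as.data.frame(b$labs), as.data.frame(a$labs))
  expect_equal(as.data.frame(b$labels), as.data.frame(a$labels))
})

test_that("an empty cohort yields empty, schema-stable tables", {
  co <- generate_cohort(cohort_config(n_patients = 0))
  expect_equal(nrow(co$patients), 0)
  expect_equal(nrow(co$labs), 0)
  expect_named(co$labs, c("patient_id", "stay_id", "time", "creatinine"))
  expect_equal(nrow(summarize_cohort(co)), 0)
})

test_that("invalid configurations are rejected naming the violated field", {
  expect_error(cohort_config(n_patients = -1), "n_patients")
  expect_error(cohort_config(prevalence_ckd = 0.8, prevalence_nkd = 0.4), "prevalence")
  expect_error(cohort_config(male_fraction = 1.2), "male_fraction")
  expect_error(cohort_config(egfr_measurement_noise_cv = -0.1), "noise_cv")
  expect_error(cohort_config(aki_rate = c(CKD_GE3 = 0.3, NKD = 0.1)), "aki_rate")
  expect_error(
    cohort_config(aki_magnitude = c(meanlog = 0, sdlog = 0.1, min = 1.2, max = 3)),
    "aki_magnitude"
  )
  bad_coding <- default_coding()[1:3, ]
  expect_error(cohort_config(coding = bad_coding), "coding")
})

test_that("cohort structure matches the configuration", {
  co <- small_cohort(n = 500, seed = 21)
  expect_equal(nrow(co$patients), 500)
  # every patient has an index stay with at least one creatinine measurement
  idx <- co$stays$stay_id[co$stays$is_index]
  expect_setequal(unique(co$stays$patient_id[co$stays$is_index]), co$patients$patient_id)
  with_lab <- unique(co$labs$patient_id[co$labs$stay_id %in% idx])
  expect_setequal(with_lab, co$patients$patient_id)
  # one label per patient
  expect_equal(sort(co$labels$patient_id), sort(co$patients$patient_id))
  # label frequencies near configured prevalences
  frac <- table(co$labels$label) / 500
  expect_lt(abs(frac[["CKD_GE3"]] - 373 / 785), 0.08)
  expect_lt(abs(frac[["NKD"]] - 129 / 785), 0.06)
  # timestamps are integer minutes
  expect_true(all(co$labs$time %% 1 == 0))
  # index stays last at least five days
  len <- with(co$stays[co$stays$is_index, ], discharge_time - admit_time)
  expect_true(all(len >= 5 * 1440))
})

test_that("latent trajectories respect the label definitions for every patient", {
  co <- small_cohort(n = 800, seed = 5)
  lat <- dplyr::left_join(co$latent, co$labels, by = "patient_id")
  expect_true(all(lat$egfr_latent[lat$label == "CKD_GE3"] < 60))
  expect_true(all(lat$egfr_latent[lat$label == "NKD"] >= 60))
  # NKD latent series contain no AKI episode
  nkd <- co$labels$patient_id[co$labels$label == "NKD"]
  lat_labs <- dplyr::transmute(co$latent,
    patient_id = .data$patient_id, stay_id = .data$stay_id,
    time = .data$time, creatinine = .data$creatinine_latent
  )
  ev <- detect_aki(lat_labs)
  expect_length(intersect(nkd, unique(ev$patient_id)), 0)
  # every OTHER patient carries an anomaly: a sub-60 latent value or an AKI event
  oth <- co$labels$patient_id[co$labels$label == "OTHER"]
  low <- unique(lat$patient_id[lat$label == "OTHER" & lat$egfr_latent < 60])
  expect_setequal(setdiff(oth, union(low, unique(ev$patient_id))), character(0))
})

test_that("simulated coding recovers configured operating points (smoke scale)", {
  co <- generate_cohort(cohort_config(n_patients = 4000), seed = 31)
  calls <- phenotype_rules(co$patients, co$stays, co$labs, co$icd)
  coding <- default_coding()
  rule_of <- c(BILLING = "ICD_billing", DISCHARGE_SUMMARY = "ICD_discharge_summary")
  for (i in seq_len(nrow(coding))) {
    row <- coding[i, ]
    sub <- dplyr::filter(calls, .data$target == row$target, .data$rule == rule_of[[row$source]])
    truth <- truth_vector(co, row$target)
    flag <- sub$call[match(co$patients$patient_id, sub$patient_id)] == "POSITIVE"
    cm <- confusion_metrics(flag, truth)
    expect_lt(abs(cm$sensitivity - row$sens), 0.04)
    expect_lt(abs(cm$specificity - row$spec), 0.04)
  }
})

test_that("cohort summaries are computed from observed tables", {
  # degenerate NKD-only cohort with fixed baseline 90 and no noise
  cfg <- cohort_config_noisefree(
    n_patients = 40, prevalence_ckd = 0, prevalence_nkd = 1,
    baseline_egfr = list(
      CKD_GE3 = c(meanlog = log(28.9), sdlog = 0.62),
      NKD = c(meanlog = log(90), sdlog = 0),
      OTHER = c(meanlog = log(72), sdlog = 0.2)
    )
  )
  co <- generate_cohort(cfg, seed = 2)
  s <- summarize_cohort(co)
  expect_equal(s$label, "NKD")
  expect_equal(s$egfr_admission_median, 90, tolerance = 1e-3) # creatinine rounding only
  expect_equal(s$aki_incidence, 0)

  # default calibration: NKD group younger than CKD group on average
  s2 <- summarize_cohort(small_cohort(n = 600, seed = 42))
  expect_lt(
    s2$age_mean[s2$label == "NKD"],
    s2$age_mean[s2$label == "CKD_GE3"]
  )

  # single patient: SD undefined, flagged as absent
  one <- small_cohort(n = 1, seed = 8)
  s3 <- summarize_cohort(one)
  expect_equal(s3$n, 1)
  expect_true(is.na(s3$age_sd))
})

test_that("schema violations are reported with the column name", {
  co <- small_cohort(n = 20, seed = 1)
  broken <- co
  broken$labs <- dplyr::select(broken$labs, -"creatinine")
  expect_error(summarize_cohort(broken), "creatinine")
})
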