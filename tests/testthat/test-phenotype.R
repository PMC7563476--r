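test_that("index-stay eGFR rules implement the all-below / all-above conventions", {
  expect_equal(classify_ckd_egfr_index_stay(c(55, 48, 59)), "POSITIVE")
  expect_equal(classify_ckd_egfr_index_stay(c(55, 61)), "NEGATIVE")
  expect_equal(classify_ckd_egfr_index_stay(numeric(0)), "NOT_ASSIGNABLE")
  expect_equal(classify_nkd_egfr_index_stay(c(85, 92), any_aki = FALSE), "POSITIVE")
  expect_equal(classify_nkd_egfr_index_stay(c(85, 92), any_aki = TRUE), "NEGATIVE")
  expect_equal(classify_nkd_egfr_index_stay(c(59, 92)), "NEGATIVE")
  # the boundary value 60 partitions the axis: CKD-negative, NKD-positive
  expect_equal(classify_ckd_egfr_index_stay(60), "NEGATIVE")
  expect_equal(classify_nkd_egfr_index_stay(60), "POSITIVE")
})

test_that("single-timepoint rules use the threshold with the target's direction", {
  expect_equal(classify_single_timepoint(28.9, "CKD_GE3"), "POSITIVE")
  expect_equal(classify_single_timepoint(60, "CKD_GE3"), "NEGATIVE")
  expect_equal(classify_single_timepoint(60, "NKD"), "POSITIVE")
  expect_equal(classify_single_timepoint(NA_real_, "CKD_GE3"), "NOT_ASSIGNABLE")
})

test_that("full-history NKD rule is a conjunction over eGFR, AKI and recovery", {
  expect_equal(classify_nkd_full_history(c(75, 80, 90)), "POSITIVE")
  expect_equal(classify_nkd_full_history(c(75, 80), any_recovery = TRUE), "NEGATIVE")
  expect_equal(classify_nkd_full_history(c(75, 59)), "NEGATIVE")
  expect_equal(classify_nkd_full_history(75), "POSITIVE") # minimal satisfying history
})

test_that("ICD classification is prefix-based on normalized codes", {
  expect_equal(classify_by_icd("N184", "CKD_GE3"), "POSITIVE")
  expect_equal(classify_by_icd("N18.4", "CKD_GE3"), "POSITIVE") # dot removed
  expect_equal(classify_by_icd(c("I10", "E119"), "CKD_GE3"), "NEGATIVE")
  expect_equal(classify_by_icd(c("I10", "E119"), "NKD"), "POSITIVE")
  expect_equal(classify_by_icd("N179", "NKD"), "NEGATIVE") # exclusion set only
  expect_equal(classify_by_icd("N179", "CKD_GE3"), "NEGATIVE")
  expect_equal(classify_by_icd(character(0), "CKD_GE3"), "NEGATIVE")
  expect_equal(classify_by_icd(character(0), "NKD"), "POSITIVE")
  expect_error(normalize_icd("18N4"), "malformed")
})

test_that("code sets load from YAML and validate", {
  cs <- codeset_charlson_renal()
  expect_s3_class(cs, "icd_codeset")
  expect_true("N18" %in% cs$codes)
  expect_true(all(icd_matches(c("N180", "N185", "Z992"), cs)))
  expect_false(any(icd_matches(c("N179", "I10"), cs)))
  expect_error(codeset("x", character(0)), "at least one")
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "custom", codes = list("N18", "Q61")), tmp)
  expect_equal(read_codeset(tmp)$codes, c("N18", "Q61"))
})

test_that("CKD and NKD index rules are mutually exclusive without AKI", {
  co <- small_cohort(n = 300, seed = 13)
  calls <- phenotype_rules(co$patients, co$stays, co$labs, co$icd)
  wide <- calls |>
    dplyr::filter(.data$rule == "eGFR_index_stay") |>
    tidyr::pivot_wider(names_from = "target", values_from = "call")
  expect_false(any(wide$CKD_GE3 == "POSITIVE" & wide$NKD == "POSITIVE"))
})

test_that("batch phenotyping agrees with the single-patient rule functions", {
  co <- small_cohort(n = 120, seed = 17)
  calls <- phenotype_rules(co$patients, co$stays, co$labs, co$icd)
  labs_e <- add_egfr(co$labs, co$patients)
  labs_e <- labs_e[order(labs_e$patient_id, labs_e$time), ]
  idx <- co$stays$stay_id[co$stays$is_index]
  fl <- aki_flags(co$labs, co$stays, co$patients)
  for (p in sample(co$patients$patient_id, 25)) {
    e_idx <- labs_e$egfr[labs_e$patient_id == p & labs_e$stay_id %in% idx]
    e_all <- labs_e$egfr[labs_e$patient_id == p]
    f <- fl[fl$patient_id == p, ]
    got <- function(tg, rl) {
      calls$call[calls$patient_id == p & calls$target == tg & calls$rule == rl]
    }
    expect_equal(got("CKD_GE3", "eGFR_index_stay"), classify_ckd_egfr_index_stay(e_idx))
    expect_equal(
      got("NKD", "eGFR_index_stay"),
      classify_nkd_egfr_index_stay(e_idx, f$aki_index == 1)
    )
    expect_equal(got("CKD_GE3", "eGFR_admission"), classify_single_timepoint(e_idx[1], "CKD_GE3"))
    expect_equal(
      got("NKD", "eGFR_history"),
      classify_nkd_full_history(e_all, f$aki_history == 1, f$aki_recovery_history == 1)
    )
    codes_b <- co$icd$code[co$icd$patient_id == p & co$icd$source == "BILLING" &
      co$icd$stay_id %in% idx]
    expect_equal(got("CKD_GE3", "ICD_billing"), classify_by_icd(codes_b, "CKD_GE3"))
    expect_equal(got("NKD", "ICD_billing"), classify_by_icd(codes_b, "NKD"))
  }
})

test_that("source overlap report matches an independent set-algebra recount", {
  # hand-checkable corner cases
  f1 <- tibble::tibble(patient_id = as.character(1:10), a = 1, b = 1, c = 1)
  r1 <- source_overlap_report(f1, c("a", "b", "c"))
  expect_equal(r1$count[r1$region == "all_three"], 10)
  expect_equal(sum(r1$count), 10)
  f2 <- tibble::tibble(
    patient_id = as.character(1:12),
    a = rep(c(1, 0, 0, 0), c(3, 4, 5, 0)),
    b = rep(c(0, 1, 0, 0), c(3, 4, 5, 0)),
    c = rep(c(0, 0, 1, 0), c(3, 4, 5, 0))
  )
  r2 <- source_overlap_report(f2, c("a", "b", "c"))
  expect_equal(r2$count[r2$region %in% c("a_only", "b_only", "c_only")], c(3, 4, 5))
  expect_equal(r2$count[r2$region == "all_three"], 0)

  # simulated cohort versus brute-force set operations
  co <- small_cohort(n = 400, seed = 19)
  calls <- phenotype_rules(co$patients, co$stays, co$labs, co$icd, targets = "CKD_GE3")
  flags <- calls_to_flags(calls)
  truth <- truth_vector(co, "CKD_GE3")[match(flags$patient_id, co$patients$patient_id)]
  rep <- source_overlap_report(
    flags, c("eGFR_index_stay", "ICD_discharge_summary", "ICD_billing"), truth
  )
  A <- flags$patient_id[flags$eGFR_index_stay == 1]
  B <- flags$patient_id[flags$ICD_discharge_summary == 1]
  C <- flags$patient_id[flags$ICD_billing == 1]
  expect_equal(
    rep$count[rep$region == "all_three"],
    length(intersect(intersect(A, B), C))
  )
  expect_equal(
    rep$count[rep$region == "eGFR_index_stay_only"],
    length(setdiff(setdiff(A, B), C))
  )
  expect_equal(sum(rep$count), nrow(flags))
  expect_equal(sum(rep$count_true_positive), sum(truth))
})

test_that("logistic combination behaves under degenerate and single-flag designs", {
  set.seed(3)
  n <- 200
  truth <- rep(c(TRUE, FALSE), each = n / 2)
  flag <- as.integer(truth)
  flag[sample(n, 30)] <- 1 - flag[sample(n, 30)]
  flags <- tibble::tibble(patient_id = as.character(1:n), f = flag, const = 1L)
  # single flag: score ranking identical to the flag, same AUROC
  fit <- combine_calls_logistic(flags, truth, flags, sources = "f")
  expect_equal(
    auroc_with_ci(fit$test_scores$score, truth)$auc,
    auroc_with_ci(flag, truth)$auc
  )
  # constant flag warns and is reported non-identifiable
  expect_warning(
    fit2 <- combine_calls_logistic(flags, truth, flags, sources = c("f", "const")),
    "non-identifiable"
  )
  expect_true(any(is.na(stats::coef(fit2$model))))
  # identical flags for everyone: constant score, AUROC 0.5
  flags3 <- tibble::tibble(patient_id = as.character(1:n), f = 1L)
  expect_warning(fit3 <- combine_calls_logistic(flags3, truth, flags3, sources = "f"))
  expect_equal(auroc_with_ci(fit3$test_scores$score, truth)$auc, 0.5)
})
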