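#' Derive per-stage child seeds from one study seed
#'
#' One global seed fans out to fixed per-stage offsets (cohort generation
#' +1000, train/test split +2000, cross-validation +3000, bootstrap +4000),
#' so any stage can be rerun in isolation and reproduce its part of a full
#' run.
#'
#' @param seed Integer study seed.
#' @return Named list of integer seeds.
#' @export
study_seeds <- function(seed) {
  seed <- as.integer(seed)
  list(
    cohort = seed + 1000L, split = seed + 2000L,
    cv = seed + 3000L, boot = seed + 4000L
  )
}

rule_flag_sources <- c(
  eGFR = "eGFR_index_stay",
  DS = "ICD_discharge_summary",
  ICD = "ICD_billing"
)

#' Evaluate every single-source rule against ground truth
#'
#' Scores each rule classifier as a binary predictor (abstentions count as
#' negative): confusion metrics plus AUROC and AUCPR. A binary classifier
#' enters the ROC machinery as a two-point score set \{0, 1\}, so its AUROC
#' equals (sensitivity + specificity) / 2.
#'
#' @param calls Output of [phenotype_rules()].
#' @param labels Ground-truth label table (`patient_id`, `label`).
#' @param n_boot Bootstrap replicates for the AUCPR interval.
#' @param seed Seed for the bootstrap.
#' @return Tibble with one row per (target, rule).
#' @export
evaluate_rules <- function(calls, labels, n_boot = 2000, seed = 1L) {
  purrr::map_dfr(unique(calls$target), function(tg) {
    truth_tbl <- labels |>
      dplyr::mutate(truth = .data$label == tg)
    sub <- dplyr::filter(calls, .data$target == tg)
    purrr::map_dfr(unique(sub$rule), function(rl) {
      rc <- dplyr::filter(sub, .data$rule == rl) |>
        dplyr::left_join(truth_tbl, by = "patient_id")
      flag <- as.integer(rc$call == "POSITIVE")
      cm <- confusion_metrics(flag, rc$truth)
      roc <- auroc_with_ci(flag, rc$truth)
      pr <- aucpr_with_ci(flag, rc$truth, n_boot = n_boot, seed = seed)
      tibble::tibble(
        target = tg, rule = rl, cm,
        auroc = roc$auc, auroc_lo = roc$ci_low, auroc_hi = roc$ci_high,
        aucpr = pr$auc, aucpr_lo = pr$ci_low, aucpr_hi = pr$ci_high
      )
    })
  })
}

#' Evaluate all logistic combinations of the three EHR sources
#'
#' Builds, for one target, the seven non-empty combinations of the source
#' flags (laboratory eGFR rule, discharge-summary ICD rule, billing ICD
#' rule), each as a logistic regression trained on the training split and
#' scored on the test split, and compares each combination's AUROC with the
#' eGFR-only classifier by the DeLong test.
#'
#' @param flags Wide per-patient flag table from [calls_to_flags()] (one
#'   target).
#' @param truth Logical vector aligned with `flags` rows.
#' @param split Output of [split_cohort()] run on `flags` (or `NULL` to
#'   split here).
#' @param seed Seed for the split when `split` is `NULL`.
#' @return List: `results` tibble (combo, auroc, ci, aucpr, delong vs eGFR)
#'   and `scores` (named list of test-score vectors).
#' @export
evaluate_source_combos <- function(flags, truth, split = NULL, seed = 1L) {
  stopifnot(all(rule_flag_sources %in% names(flags)))
  flags <- dplyr::rename(flags, !!!stats::setNames(rule_flag_sources, names(rule_flag_sources)))
  if (is.null(split)) split <- split_cohort(flags, truth, seed = seed)
  combos <- unlist(lapply(1:3, function(k) {
    utils::combn(names(rule_flag_sources), k, simplify = FALSE)
  }), recursive = FALSE)
  scores <- list()
  rows <- purrr::map_dfr(combos, function(srcs) {
    nm <- paste(srcs, collapse = "+")
    fit <- suppressWarnings(combine_calls_logistic(
      split$train, split$train_truth, split$test,
      sources = srcs
    ))
    sc <- fit$test_scores$score
    scores[[nm]] <<- sc
    roc <- auroc_with_ci(sc, split$test_truth)
    pr <- aucpr_with_ci(sc, split$test_truth, n_boot = 1000, seed = seed)
    tibble::tibble(
      combo = nm, n_test = length(sc),
      auroc = roc$auc, auroc_lo = roc$ci_low, auroc_hi = roc$ci_high,
      aucpr = pr$auc, aucpr_lo = pr$ci_low, aucpr_hi = pr$ci_high
    )
  })
  delong <- purrr::map_dfr(setdiff(names(scores), "eGFR"), function(nm) {
    res <- delong_test(scores[[nm]], scores[["eGFR"]], split$test_truth)
    tibble::tibble(combo = nm, z_vs_egfr = res$z, p_vs_egfr = res$p_value)
  })
  rows <- dplyr::left_join(rows, delong, by = "combo")
  list(results = rows, scores = scores, split = split)
}

#' Run the full phenotyping study on one cohort
#'
#' End-to-end orchestration: simulate a cohort, apply every rule classifier,
#' report source overlaps (Venn partitions), evaluate the seven logistic
#' source combinations, and — for each target, scenario and model family —
#' train a grid-search cross-validated model on the training split and
#' compare its test AUROC with the scenario's simple categorical classifier
#' (the three-source logistic combination when coded sources are available,
#' the eGFR index-stay rule otherwise) by the DeLong test.
#'
#' One study seed governs every stage through [study_seeds()]; rerunning
#' with the same configuration and seed reproduces the report bundle
#' byte-identically.
#'
#' @param config A [cohort_config()].
#' @param seed Study seed (defaults to `config$seed`).
#' @param targets Targets to run.
#' @param scenarios Scenario ids to run.
#' @param families Model families to train.
#' @param n_boot Bootstrap replicates for AUCPR intervals.
#' @param out_dir Optional directory; when given the report bundle is
#'   written as CSV/JSON via [write_report_bundle()].
#' @return Object of class `study_report`: tibbles `cohort_summary`,
#'   `rule_metrics`, `source_overlap`, `combo_results`, `model_results`,
#'   plus the `manifest`.
#' @export
run_study <- function(config = cohort_config(), seed = NULL,
                      targets = c("CKD_GE3", "NKD"),
                      scenarios = c("S1", "S2", "S3", "S4"),
                      families = MODEL_FAMILIES,
                      n_boot = 2000,
                      out_dir = NULL) {
  if (is.null(seed)) seed <- config$seed
  seeds <- study_seeds(seed)
  stage <- function(...) message("[renalphen] ", ...)

  stage("simulating cohort (n=", config$n_patients, ")")
  cohort <- generate_cohort(config, seed = seeds$cohort)
  cohort_summary <- summarize_cohort(cohort)

  stage("applying rule classifiers")
  calls <- phenotype_rules(cohort$patients, cohort$stays, cohort$labs, cohort$icd,
    targets = targets
  )
  rule_metrics <- evaluate_rules(calls, cohort$labels, n_boot = n_boot, seed = seeds$boot)

  overlap <- list()
  combo_results <- list()
  model_results <- list()
  for (tg in targets) {
    truth_tbl <- dplyr::left_join(
      tibble::tibble(patient_id = cohort$patients$patient_id),
      cohort$labels,
      by = "patient_id"
    )
    truth <- truth_tbl$label == tg
    flags <- calls_to_flags(dplyr::filter(calls, .data$target == tg))
    flags <- flags[match(truth_tbl$patient_id, flags$patient_id), ]

    stage("source overlap: ", tg)
    fl3 <- dplyr::rename(flags, !!!stats::setNames(rule_flag_sources, names(rule_flag_sources)))
    overlap[[tg]] <- source_overlap_report(fl3, names(rule_flag_sources), truth) |>
      dplyr::mutate(target = tg, .before = 1)

    stage("source combinations: ", tg)
    cmb <- evaluate_source_combos(flags, truth, seed = seeds$split)
    combo_results[[tg]] <- dplyr::mutate(cmb$results, target = tg, .before = 1)
    split <- cmb$split

    for (sc_id in scenarios) {
      stage("features: ", tg, " ", sc_id)
      feats <- build_feature_table(cohort, sc_id, tg)
      feats <- feats[match(truth_tbl$patient_id, feats$patient_id), ]
      sc_scenario <- scenario_spec(sc_id)
      # scenario's simple categorical classifier on the same test split
      if (sc_scenario$include_icd_flags) {
        sc_scores <- cmb$scores[["eGFR+DS+ICD"]]
      } else {
        sc_scores <- split$test[["eGFR"]]
      }
      sc_roc <- auroc_with_ci(sc_scores, split$test_truth)
      for (fam in families) {
        stage("training: ", tg, " ", sc_id, " ", fam)
        fit <- suppressWarnings(fit_grid_cv(
          model_spec(fam),
          feats[split$train_idx, , drop = FALSE], split$train_truth,
          seed = seeds$cv
        ))
        pred <- predict(fit, feats[split$test_idx, , drop = FALSE])
        roc <- auroc_with_ci(pred$score, split$test_truth)
        pr <- aucpr_with_ci(pred$score, split$test_truth, n_boot = n_boot, seed = seeds$boot)
        dl <- delong_test(pred$score, sc_scores, split$test_truth)
        cm <- confusion_metrics(pred$call, split$test_truth)
        model_results[[paste(tg, sc_id, fam)]] <- tibble::tibble(
          target = tg, scenario = sc_id, family = fam,
          chosen = glance(fit)$chosen, mean_cv_f1 = fit$mean_f1,
          auroc = roc$auc, auroc_lo = roc$ci_low, auroc_hi = roc$ci_high,
          aucpr = pr$auc, aucpr_lo = pr$ci_low, aucpr_hi = pr$ci_high,
          test_f1 = cm$f1, test_sensitivity = cm$sensitivity,
          test_specificity = cm$specificity,
          sc_auroc = sc_roc$auc, delong_z_vs_sc = dl$z, delong_p_vs_sc = dl$p_value
        )
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("renalphen")),
    seed = seed, seeds = seeds,
    config_digest = rlang::hash(unclass(config)),
    targets = targets, scenarios = scenarios, families = families,
    n_patients = config$n_patients
  )
  report <- structure(list(
    cohort_summary = cohort_summary,
    rule_metrics = rule_metrics,
    source_overlap = dplyr::bind_rows(overlap),
    combo_results = dplyr::bind_rows(combo_results),
    model_results = dplyr::bind_rows(model_results),
    manifest = manifest
  ), class = "study_report")
  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(
    "<study_report> seed", x$manifest$seed, "|", x$manifest$n_patients,
    "patients |", nrow(x$model_results), "model cells\n"
  )
  print(x$cohort_summary)
  invisible(x)
}

#' Write a study report as a plain-text bundle
#'
#' Writes each report table as CSV plus `manifest.json`; rerunning the same
#' study into a fresh directory produces byte-identical files.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c(
    "cohort_summary", "rule_metrics", "source_overlap",
    "combo_results", "model_results"
  )) {
    readr::write_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Compare model and simple-classifier AUROCs across scenarios
#'
#' @param report A `study_report`.
#' @return A ggplot dot plot of test AUROCs by scenario, family and target.
#' @export
plot_scenario_auroc <- function(report) {
  df <- report$model_results
  sc <- df |>
    dplyr::distinct(.data$target, .data$scenario, .data$sc_auroc) |>
    dplyr::mutate(family = "SC", auroc = .data$sc_auroc)
  ggplot2::ggplot(
    dplyr::bind_rows(df, sc),
    ggplot2::aes(x = .data$scenario, y = .data$auroc, colour = .data$family)
  ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5), size = 2) +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(y = "Test AUROC", x = "Data-availability scenario") +
    ggplot2::theme_minimal()
}
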