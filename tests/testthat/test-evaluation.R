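test_that("confusion metrics follow the standard definitions", {
  # perfect classifier
  perfect <- confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(
    unlist(perfect[c("sensitivity", "specificity", "ppv", "npv", "f1", "accuracy")]),
    rep(1, 6),
    ignore_attr = TRUE
  )
  # count pattern with sens 0.71 / spec 0.91
  pred <- rep(c(TRUE, FALSE, TRUE, FALSE), c(71, 29, 9, 91))
  truth <- rep(c(TRUE, FALSE), c(100, 100))
  m <- confusion_metrics(pred, truth)
  expect_equal(m$sensitivity, 0.71)
  expect_equal(m$specificity, 0.91)
  expect_equal(m$ppv, 71 / 80)
  expect_equal(m$f1, 2 * (71 / 80) * 0.71 / (71 / 80 + 0.71))
  # all-negative classifier: PPV undefined, reported absent
  neg <- confusion_metrics(rep(FALSE, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(neg$sensitivity, 0)
  expect_equal(neg$specificity, 1)
  expect_true(is.na(neg$ppv))
  expect_error(confusion_metrics(logical(0), logical(0)), "non-empty")
})

test_that("AUROC equals brute-force pair counting to 1e-12, including ties", {
  set.seed(11)
  for (rep in 1:40) {
    n <- 200
    truth <- runif(n) < 0.4
    if (!any(truth) || all(truth)) next
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # heavy ties
    got <- auroc_with_ci(scores, truth)
    expect_equal(got$auc, oracle_auroc(scores, truth), tolerance = 1e-12)
    expect_true(got$ci_low <= got$auc && got$auc <= got$ci_high)
  }
})

test_that("AUROC degenerate cases and monotone-transform invariance", {
  truth <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(auroc_with_ci(as.numeric(truth), truth)$auc, 1)
  expect_equal(auroc_with_ci(rep(0.3, 20), truth)$auc, 0.5)
  set.seed(5)
  sc <- rnorm(20)
  expect_equal(
    auroc_with_ci(sc, truth)$auc,
    auroc_with_ci(exp(3 * sc) + 2, truth)$auc # strictly monotone transform
  )
  expect_error(auroc_with_ci(sc, rep(TRUE, 20)), "both classes")
})

test_that("AUROC and DeLong agree with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  truth <- runif(150) < 0.45
  a <- rnorm(150) + truth
  b <- rnorm(150) + 0.5 * truth
  got <- auroc_with_ci(a, truth)
  ref <- pROC::roc(truth, a, quiet = TRUE, direction = "<")
  expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci_ref <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(got$ci_low, got$ci_high), ci_ref[c(1, 3)], tolerance = 1e-9)
  dt <- delong_test(a, b, truth)
  ref2 <- pROC::roc.test(
    pROC::roc(truth, a, quiet = TRUE, direction = "<"),
    pROC::roc(truth, b, quiet = TRUE, direction = "<"),
    method = "delong", paired = TRUE
  )
  expect_equal(dt$p_value, ref2$p.value, tolerance = 1e-9)
})

test_that("DeLong variance matches the brute-force structural components", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 50
    truth <- c(rep(TRUE, 20), rep(FALSE, 30))
    a <- rnorm(n) + truth
    b <- rnorm(n) + 0.7 * truth
    ca <- oracle_delong(a, truth)
    cb <- oracle_delong(b, truth)
    v_oracle <- var(ca$v10 - cb$v10) / ca$m + var(ca$v01 - cb$v01) / ca$n
    dt <- delong_test(a, b, truth)
    z_oracle <- (ca$auc - cb$auc) / sqrt(v_oracle)
    expect_equal(dt$z, z_oracle, tolerance = 1e-9)
  }
})

test_that("DeLong test is antisymmetric and null on identical scores", {
  set.seed(19)
  truth <- runif(80) < 0.5
  a <- rnorm(80) + truth
  b <- rnorm(80) + 0.3 * truth
  same <- delong_test(a, a, truth)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  ab <- delong_test(a, b, truth)
  ba <- delong_test(b, a, truth)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(delong_test(a, b[-1], truth), "paired")
})

test_that("Holm adjustment is applied only when requested", {
  set.seed(23)
  truth <- runif(60) < 0.5
  sl <- list(x = rnorm(60) + truth, y = rnorm(60), ref = rnorm(60) + 0.5 * truth)
  plain <- delong_tests(sl, "ref", truth)
  expect_false("p_adjusted" %in% names(plain))
  adj <- delong_tests(sl, "ref", truth, adjust = "holm")
  expect_equal(adj$p_adjusted, p.adjust(adj$p_value, "holm"))
})

test_that("AUCPR equals a hand-computed step sum on a small fixture", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.5, 0.4, 0.3, 0.2, 0.1)
  truth <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  # thresholds descending; recall steps at each positive, precision = tp/(tp+fp)
  # steps: tp/rank at ranks of positives: 1/1, 2/3, 3/4, 4/7; each adds 1/4 recall
  manual <- (1 / 1 + 2 / 3 + 3 / 4 + 4 / 7) / 4
  got <- aucpr_with_ci(scores, truth, n_boot = 0)
  expect_equal(got$auc, manual, tolerance = 1e-12)
})

test_that("AUCPR limits: perfect ranker 1, constant ranker the prevalence", {
  truth <- rep(c(TRUE, FALSE), c(30, 70))
  expect_equal(aucpr_with_ci(as.numeric(truth), truth, n_boot = 0)$auc, 1)
  expect_equal(aucpr_with_ci(rep(0.5, 100), truth, n_boot = 0)$auc, 0.3)
  expect_error(aucpr_with_ci(rep(0.5, 10), rep(FALSE, 10)), "positive")
  # bootstrap interval brackets the estimate and is seed-reproducible
  set.seed(29)
  sc <- rnorm(100) + truth
  a <- aucpr_with_ci(sc, truth, n_boot = 200, seed = 4)
  b <- aucpr_with_ci(sc, truth, n_boot = 200, seed = 4)
  expect_equal(a$ci_low, b$ci_low)
  expect_true(a$ci_low <= a$auc && a$auc <= a$ci_high)
})

test_that("ROC points are monotone and curves plot", {
  set.seed(31)
  truth <- runif(60) < 0.5
  sc <- rnorm(60) + truth
  roc <- auroc_with_ci(sc, truth)
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_s3_class(ggplot2::autoplot(roc), "ggplot")
  pr <- aucpr_with_ci(sc, truth, n_boot = 0)
  expect_s3_class(ggplot2::autoplot(pr), "ggplot")
  expect_named(glance(roc), c("kind", "auc", "ci_low", "ci_high", "ci_method"))
})
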