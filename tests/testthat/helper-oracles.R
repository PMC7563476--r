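# Independent brute-force oracles. These deliberately share no code with the
# package implementation: plain loops and direct formula transcriptions.

# O(n^2) pairwise scan for AKI / recovery events on one patient's series
oracle_events <- function(time, creatinine, patient_id = "P1") {
  rows <- list()
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dt <- time[j] - time[i]
      if (dt <= 0) next
      if (dt <= 48 * 60 && creatinine[j] - creatinine[i] > 26.5) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = patient_id, kind = "AKI_ABSOLUTE_48H",
          t_start = time[i], t_end = time[j],
          from_value = creatinine[i], to_value = creatinine[j]
        )
      }
      if (dt <= 7 * 24 * 60 && creatinine[j] / creatinine[i] > 1.5) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = patient_id, kind = "AKI_RELATIVE_7D",
          t_start = time[i], t_end = time[j],
          from_value = creatinine[i], to_value = creatinine[j]
        )
      }
    }
  }
  do.call(rbind, rows)
}

oracle_recovery <- function(time, creatinine, patient_id = "P1") {
  rows <- list()
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dt <- time[j] - time[i]
      if (dt <= 0 || dt > 7 * 24 * 60) next
      if ((creatinine[i] - creatinine[j]) / creatinine[i] > 0.33) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = patient_id, kind = "AKI_RECOVERY_7D",
          t_start = time[i], t_end = time[j],
          from_value = creatinine[i], to_value = creatinine[j]
        )
      }
    }
  }
  do.call(rbind, rows)
}

sort_events <- function(ev) {
  if (is.null(ev) || nrow(ev) == 0) {
    return(data.frame())
  }
  ev <- ev[order(ev$patient_id, ev$t_start, ev$t_end, ev$kind), ]
  rownames(ev) <- NULL
  ev
}

# direct transcription of the 2009 CKD-EPI closed form, scalar, mg/dL input
oracle_ckdepi_mgdl <- function(scr, age, female, black = FALSE) {
  kappa <- if (female) 0.7 else 0.9
  alpha <- if (female) -0.329 else -0.411
  ratio <- scr / kappa
  v <- 141
  v <- v * (if (ratio < 1) ratio^alpha else 1)
  v <- v * (if (ratio > 1) ratio^(-1.209) else 1)
  v <- v * 0.993^age
  if (female) v <- v * 1.018
  if (black) v <- v * 1.159
  v
}

# AUROC by explicit concordant-pair counting with half credit for ties
oracle_auroc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# DeLong pseudo-value variance/covariance by direct pair enumeration
oracle_delong <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  m <- length(pos)
  n <- length(neg)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(vapply(neg, function(y) psi(x, y), numeric(1))), numeric(1))
  v01 <- vapply(neg, function(y) mean(vapply(pos, function(x) psi(x, y), numeric(1))), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

# logistic regression by hand-rolled iteratively-reweighted least squares
oracle_irls_logistic <- function(x, y, iter = 50) {
  x <- cbind(1, as.matrix(x))
  beta <- rep(0, ncol(x))
  for (it in seq_len(iter)) {
    eta <- as.numeric(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    beta <- solve(crossprod(x, w * x), crossprod(x, w * z))
  }
  as.numeric(beta)
}

# random irregular creatinine series (lengths 1-50, gaps 1 min - 30 d)
random_series <- function(id, len = NULL) {
  if (is.null(len)) len <- sample(1:50, 1)
  gaps <- sample(c(1, 30, 240, 1440, 2880, 7 * 1440, 30 * 1440), len, replace = TRUE)
  time <- cumsum(gaps)
  creat <- round(exp(rnorm(len, log(100), 0.4)), 1)
  data.frame(
    patient_id = id, stay_id = paste0(id, "-S0"),
    time = time, creatinine = creat
  )
}

# small cohort shortcut for tests
small_cohort <- function(n = 400, seed = 1, ...) {
  generate_cohort(cohort_config(n_patients = n, ...), seed = seed)
}

truth_vector <- function(cohort, target) {
  cohort$labels$label[match(cohort$patients$patient_id, cohort$labels$patient_id)] == target
}
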