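MODEL_FAMILIES <- c("LOGISTIC", "GLMNET", "RANDOM_FOREST", "ANN")

#' Stratified train/test split
#'
#' Splits a feature table into training and test partitions, stratified by
#' class: each class contributes `floor(n_class * (1 - train_fraction))`
#' patients to the test set, so per-class prevalence differs between the
#' partitions only by rounding. Deterministic under `seed`.
#'
#' @param features Feature table (one row per patient).
#' @param truth Logical/0-1 vector aligned with `features` rows.
#' @param train_fraction Fraction of patients used for training.
#' @param seed Integer seed.
#' @return List with `train`, `test` (tibbles), `train_truth`, `test_truth`,
#'   `train_idx`, `test_idx`.
#' @export
split_cohort <- function(features, truth, train_fraction = 0.8, seed = 1L) {
  truth <- as_binary_truth(truth)
  stopifnot(nrow(features) == length(truth))
  counts <- table(truth)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("each class needs at least 2 members for a stratified split", call. = FALSE)
  }
  set.seed(as.integer(seed))
  test_idx <- integer(0)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(truth == cls)
    n_test <- floor(length(idx) * (1 - train_fraction) + 1e-9)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(truth), test_idx)
  list(
    train = features[train_idx, , drop = FALSE],
    test = features[test_idx, , drop = FALSE],
    train_truth = truth[train_idx],
    test_truth = truth[test_idx],
    train_idx = train_idx, test_idx = test_idx
  )
}

#' Model specification with hyperparameter grid
#'
#' The four model families and their tuning grids: plain maximum-likelihood
#' logistic regression (no hyperparameters); elastic-net logistic regression
#' (`GLMNET`, mixing parameter alpha on \{0, 0.1, ..., 1\} with the
#' regularization strength lambda pre-selected on a 100-point path before
#' the alpha sweep); random forest (`RANDOM_FOREST`, 100 trees, `mtry` swept
#' over 1..p); and a single-hidden-layer feed-forward network (`ANN`,
#' logistic activations, sigmoid output, weight decay 1e-4, hidden size
#' swept over 1..10). All families are tuned by mean F1 (computed at the 0.5
#' probability threshold) over 3 independent repetitions of stratified
#' 10-fold cross-validation.
#'
#' @param family One of `"LOGISTIC"`, `"GLMNET"`, `"RANDOM_FOREST"`,
#'   `"ANN"`.
#' @param alpha,mtry,hidden_size Optional grid overrides.
#' @param ntree Number of random-forest trees.
#' @param cv_folds,cv_repeats Resampling protocol.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = MODEL_FAMILIES,
                       alpha = seq(0, 1, by = 0.1),
                       mtry = NULL,
                       hidden_size = 1:10,
                       ntree = 100,
                       cv_folds = 10, cv_repeats = 3) {
  family <- match.arg(family)
  structure(
    list(
      family = family, alpha = alpha, mtry = mtry, hidden_size = hidden_size,
      ntree = ntree, cv_folds = cv_folds, cv_repeats = cv_repeats,
      objective = "F1"
    ),
    class = "model_spec"
  )
}

# stratified fold assignment: per repetition, shuffle within class and deal
# fold ids round-robin; every fold keeps the class mix as even as possible
make_cv_folds <- function(truth, k, reps, seed) {
  set.seed(as.integer(seed))
  lapply(seq_len(reps), function(r) {
    fold <- integer(length(truth))
    for (cls in unique(truth)) {
      idx <- sample(which(truth == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

f1_binary <- function(pred, truth) {
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (tp + fp + fn == 0) {
    return(1)
  }
  if (tp == 0) {
    return(0)
  }
  2 * tp / (2 * tp + fp + fn)
}

scale_build <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}
scale_apply <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

child_seed <- function(seed, a, b = 0) {
  (as.integer(seed) + 7919L * as.integer(a) + 104729L * as.integer(b)) %% 2147483L
}

# fit one family at one grid point on (x, y); returns a predictor closure
fit_one <- function(family, x, y, pars, ntree, seed) {
  if (family == "LOGISTIC") {
    df <- data.frame(x)
    df$.y <- y
    fit <- suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = df))
    function(newx) {
      as.numeric(suppressWarnings(
        stats::predict(fit, newdata = data.frame(newx), type = "response")
      ))
    }
  } else if (family == "GLMNET") {
    fit <- glmnet::glmnet(x, y,
      family = "binomial", alpha = pars$alpha,
      lambda = pars$lambda_path
    )
    function(newx) {
      as.numeric(stats::predict(fit,
        newx = newx, s = pars$lambda,
        type = "response", exact = FALSE
      ))
    }
  } else if (family == "RANDOM_FOREST") {
    set.seed(seed)
    yf <- factor(ifelse(y > 0, "pos", "neg"), levels = c("neg", "pos"))
    fit <- randomForest::randomForest(x, yf, ntree = ntree, mtry = pars$mtry)
    function(newx) as.numeric(stats::predict(fit, newdata = newx, type = "prob")[, "pos"])
  } else { # ANN
    restarts <- if (isTRUE(pars$final)) 5 else 1
    best <- NULL
    for (r in seq_len(restarts)) {
      set.seed(child_seed(seed, r, 17))
      cand <- nnet::nnet(x, y,
        size = pars$size, decay = 1e-4, maxit = 200,
        entropy = TRUE, trace = FALSE
      )
      if (is.null(best) || cand$value < best$value) best <- cand
    }
    fit <- best
    function(newx) as.numeric(stats::predict(fit, newx))
  }
}

#' Grid-search training under repeated cross-validation
#'
#' Exhaustively evaluates the family's hyperparameter grid: every grid point
#' is scored by F1 on each of the 30 held-out folds (3 repetitions of
#' stratified 10-fold cross-validation, probability threshold 0.5), the
#' point with the best mean F1 is selected (ties: first grid point), and the
#' model is refitted on the full training set. For `GLMNET`, the
#' regularization strength lambda is first selected on a 100-point path at
#' alpha = 0.5 by the same resampling, then frozen for the alpha sweep.
#' Numeric features are standardized with training-split statistics for
#' `LOGISTIC`, `GLMNET` and `ANN`, and left raw for `RANDOM_FOREST`. Folds
#' that end up without positives are skipped with a warning.
#'
#' @param spec A [model_spec()].
#' @param features Training feature table (a `patient_id` column is kept
#'   aside; everything else must be numeric).
#' @param truth Logical/0-1 training labels aligned with `features`.
#' @param seed Integer seed governing folds, forest bootstraps and network
#'   initialization.
#' @return A `renal_fit`: chosen hyperparameters, the per-fold F1 values of
#'   the chosen point (`resample_f1`), `mean_f1`, the full grid table, the
#'   refitted model and the feature schema.
#' @export
fit_grid_cv <- function(spec, features, truth, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  truth <- as_binary_truth(truth)
  x_raw <- feature_matrix(features)
  y <- as.numeric(truth)
  if (min(table(truth)) < spec$cv_folds) {
    warning("fewer positives than folds; some folds will be skipped")
  }
  standardized <- spec$family %in% c("LOGISTIC", "GLMNET", "ANN")
  scaler <- if (standardized) scale_build(x_raw) else NULL
  x <- if (standardized) scale_apply(x_raw, scaler) else x_raw

  folds <- make_cv_folds(truth, spec$cv_folds, spec$cv_repeats, child_seed(seed, 1))

  grid <- switch(spec$family,
    LOGISTIC = tibble::tibble(.point = 1),
    GLMNET = tibble::tibble(alpha = spec$alpha),
    RANDOM_FOREST = tibble::tibble(
      mtry = if (is.null(spec$mtry)) seq_len(ncol(x)) else spec$mtry
    ),
    ANN = tibble::tibble(size = spec$hidden_size)
  )

  lambda_sel <- NULL
  lambda_path <- NULL
  if (spec$family == "GLMNET") {
    pre <- glmnet::glmnet(x, y, family = "binomial", alpha = 0.5, nlambda = 100)
    lambda_path <- pre$lambda
    lam_f1 <- matrix(NA_real_, nrow = length(lambda_path), ncol = 0)
    for (r in seq_along(folds)) {
      for (k in seq_len(spec$cv_folds)) {
        hold <- folds[[r]] == k
        if (sum(truth[hold]) == 0 || sum(truth[!hold]) == 0) next
        fit <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
          family = "binomial", alpha = 0.5, lambda = lambda_path
        )
        pr <- stats::predict(fit,
          newx = x[hold, , drop = FALSE],
          s = lambda_path, type = "response"
        )
        lam_f1 <- cbind(lam_f1, apply(pr > 0.5, 2, f1_binary, truth = truth[hold]))
      }
    }
    lambda_sel <- lambda_path[which.max(rowMeans(lam_f1))]
  }

  n_skipped <- 0L
  score_point <- function(gi) {
    pars <- as.list(grid[gi, , drop = FALSE])
    pars$lambda <- lambda_sel
    pars$lambda_path <- lambda_path
    f1s <- numeric(0)
    for (r in seq_along(folds)) {
      for (k in seq_len(spec$cv_folds)) {
        hold <- folds[[r]] == k
        if (sum(hold) == 0) next
        if (sum(truth[hold]) == 0 || sum(truth[!hold]) == 0) {
          n_skipped <<- n_skipped + 1L
          f1s <- c(f1s, NA_real_)
          next
        }
        predictor <- fit_one(
          spec$family, x[!hold, , drop = FALSE], y[!hold],
          pars, spec$ntree, child_seed(seed, gi, r * 100 + k)
        )
        pr <- predictor(x[hold, , drop = FALSE])
        f1s <- c(f1s, f1_binary(pr > 0.5, truth[hold]))
      }
    }
    f1s
  }

  f1_by_point <- lapply(seq_len(nrow(grid)), score_point)
  if (n_skipped > 0) {
    warning(sprintf("%d fold(s) without positives were skipped", n_skipped))
  }
  mean_f1s <- vapply(f1_by_point, function(v) mean(v, na.rm = TRUE), numeric(1))
  best <- which.max(mean_f1s)
  chosen <- as.list(grid[best, , drop = FALSE])
  chosen$.point <- NULL
  if (spec$family == "GLMNET") chosen$lambda <- lambda_sel

  pars <- as.list(grid[best, , drop = FALSE])
  pars$lambda <- lambda_sel
  pars$lambda_path <- lambda_path
  pars$final <- TRUE
  predictor <- fit_one(spec$family, x, y, pars, spec$ntree, child_seed(seed, best, 999))

  grid_tbl <- grid
  grid_tbl$.point <- NULL
  grid_tbl <- tibble::as_tibble(grid_tbl)
  grid_tbl$mean_f1 <- mean_f1s

  structure(
    list(
      spec = spec, chosen = chosen,
      resample_f1 = f1_by_point[[best]],
      mean_f1 = mean_f1s[best],
      grid = grid_tbl,
      predictor = predictor,
      scaler = scaler,
      feature_names = colnames(x_raw),
      n_train = nrow(x_raw),
      n_skipped_folds = n_skipped
    ),
    class = "renal_fit"
  )
}

feature_matrix <- function(features) {
  df <- dplyr::select(features, -dplyr::any_of("patient_id"))
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  as.matrix(df)
}

#' @export
print.renal_fit <- function(x, ...) {
  ch <- paste(names(x$chosen), unlist(x$chosen), sep = "=", collapse = ", ")
  cat(sprintf(
    "<renal_fit> %s (n=%d) chosen: %s | mean resample F1 %.3f\n",
    x$spec$family, x$n_train, if (nchar(ch)) ch else "none", x$mean_f1
  ))
  invisible(x)
}

#' Score new patients with a fitted model
#'
#' @param object A `renal_fit`.
#' @param newdata Feature table with the training columns.
#' @param threshold Probability threshold for the binary call.
#' @param ... Unused.
#' @return Tibble: `patient_id` (when present in `newdata`), `score` in
#'   \[0, 1\], `call` (logical, `score > threshold`).
#' @export
predict.renal_fit <- function(object, newdata, threshold = 0.5, ...) {
  x <- feature_matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(x))
  extra <- setdiff(colnames(x), object$feature_names)
  if (length(missing) || length(extra)) {
    stop(
      "feature schema mismatch; missing: ",
      paste(missing, collapse = ", "), "; unexpected: ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  x <- x[, object$feature_names, drop = FALSE]
  if (!is.null(object$scaler)) x <- scale_apply(x, object$scaler)
  score <- pmin(pmax(object$predictor(x), 0), 1)
  out <- tibble::tibble(score = score, call = score > threshold)
  if ("patient_id" %in% names(newdata)) {
    out <- tibble::tibble(patient_id = newdata$patient_id, out)
  }
  out
}

#' @importFrom generics tidy
#' @export
tidy.renal_fit <- function(x, ...) x$grid

#' @importFrom generics glance
#' @export
glance.renal_fit <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    chosen = paste(names(x$chosen), unlist(x$chosen), sep = "=", collapse = ", "),
    mean_f1 = x$mean_f1,
    n_resamples = sum(!is.na(x$resample_f1)),
    n_skipped_folds = x$n_skipped_folds,
    n_train = x$n_train
  )
}
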