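#' Classifier configuration
#'
#' @param algorithm `"RF"` (random forest, the default) or `"SVM"`
#'   (RBF-kernel C-SVM).
#' @param rf_trees Number of trees for the forest (default 3000, the value
#'   used for the reference results; tests use fewer).
#' @param rf_mtry Features tried per split; default `floor(sqrt(p))`.
#' @param svm_cost Soft-margin cost C (default 1, the common library
#'   default).
#' @param svm_gamma RBF width; default `1 / (p * var(X))` computed from the
#'   training matrix (the "scale" convention).
#' @param positive Positive class for scores and metrics (default `"DSB"`,
#'   the majority class of the reference dataset).
#' @return A `model_config` list.
#' @export
model_config <- function(algorithm = c("RF", "SVM"), rf_trees = 3000L,
                         rf_mtry = NULL, svm_cost = 1, svm_gamma = NULL,
                         positive = "DSB") {
  algorithm <- match.arg(algorithm)
  stopifnot(rf_trees >= 1L, svm_cost > 0, positive %in% .classes)
  structure(list(algorithm = algorithm, rf_trees = as.integer(rf_trees),
                 rf_mtry = rf_mtry, svm_cost = svm_cost,
                 svm_gamma = svm_gamma, positive = positive),
            class = "model_config")
}

# run `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Down-sample the majority class to balance a dataset
#'
#' Keeps every minority-class protein and a uniform random subset of the
#' majority class of equal size.  Applied to training data only; test data
#' is never down-sampled.
#'
#' @param dataset A `labeled_dataset`.
#' @param seed Integer seed; the selection is deterministic given it.
#' @return A balanced `labeled_dataset` (original row order preserved).
#' @export
downsample_majority <- function(dataset, seed) {
  tab <- table(dataset$label)
  if (any(tab == 0L)) stop("both classes must be present to down-sample")
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(.classes, minority)
  maj_idx <- which(dataset$label == majority)
  keep_maj <- .with_seed(seed, sample(maj_idx, min(tab)))
  keep <- sort(c(which(dataset$label == minority), keep_maj))
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(dataset)
  out
}

#' Stratified k-fold assignment
#'
#' Randomly partitions the dataset into `k` folds, stratified by class so
#' per-class fold sizes differ by at most one.  `k = nrow(dataset)` gives
#' leave-one-out folds (one protein per fold, stratification moot).
#'
#' @param dataset A `labeled_dataset`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`, named by protein id.
#' @export
make_folds <- function(dataset, k = 10L, seed) {
  n <- nrow(dataset)
  stopifnot(k == as.integer(k))
  if (k < 2L) stop("k must be >= 2")
  if (k == n) {  # leave-one-out
    folds <- .with_seed(seed, sample.int(n))
    names(folds) <- dataset$id
    return(folds)
  }
  tab <- table(dataset$label)
  if (any(tab < k)) stop("every class needs >= k members; counts: ",
                         paste(names(tab), tab, sep = "=", collapse = ", "))
  folds <- integer(n)
  .with_seed(seed, {
    for (cl in levels(dataset$label)) {
      idx <- which(dataset$label == cl)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  names(folds) <- dataset$id
  folds
}

#' Train a classifier on a feature matrix
#'
#' @param features Numeric matrix, rows = proteins (rownames = ids),
#'   columns = named features.
#' @param labels Factor/character of `DSB`/`SSB`, one per row.
#' @param config A [model_config()].
#' @param seed Integer seed (bootstrap draws for RF; kept for
#'   reproducibility bookkeeping for the deterministic SVM solver).
#' @return A `strand_model` handle usable with [predict_scores()].
#' @export
train_model <- function(features, labels, config = model_config(), seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- factor(as.character(labels), levels = .classes)
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("training set must contain both classes")
  pos <- labels == config$positive
  X <- unname(features)
  if (config$algorithm == "RF") {
    mtry <- if (is.null(config$rf_mtry)) max(1L, floor(sqrt(ncol(X))))
            else as.integer(config$rf_mtry)
    fit <- .rf_fit_cpp(X, as.integer(pos), config$rf_trees, mtry, 1L,
                       as.integer(seed %% .Machine$integer.max))
    names(fit$importance) <- colnames(features)
    model <- list(fit = fit)
  } else {
    y <- ifelse(pos, 1, -1)
    gamma <- config$svm_gamma
    if (is.null(gamma)) {
      v <- var(as.vector(X))
      gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
    }
    fit <- .svm_fit_cpp(X, y, config$svm_cost, gamma, 1e-3, 2000)
    platt <- .platt_fit(fit$decision, pos)
    model <- list(fit = fit, X = X, y = y, gamma = gamma, platt = platt)
  }
  structure(c(model, list(algorithm = config$algorithm,
                          feature_names = colnames(features),
                          positive = config$positive, seed = seed)),
            class = "strand_model")
}

#' Predict positive-class scores and hard labels
#'
#' Scores are in `[0, 1]` for both model types (RF: fraction of trees
#' voting positive; SVM: Platt-calibrated decision values).  Hard labels
#' use threshold 0.5 with ties going to the positive class.
#'
#' @param model A `strand_model` from [train_model()].
#' @param features Feature matrix with exactly the training columns.
#' @return data.frame with `id`, `score` and `label`.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "strand_model"), is.matrix(features))
  missing <- setdiff(model$feature_names, colnames(features))
  extra <- setdiff(colnames(features), model$feature_names)
  if (length(missing) || length(extra))
    stop("feature layout mismatch; missing: ",
         paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ...", "; extra: ",
         paste(head(extra, 5L), collapse = ", "),
         if (length(extra) > 5L) " ...")
  X <- unname(features[, model$feature_names, drop = FALSE])
  score <- if (model$algorithm == "RF") {
    .rf_predict_cpp(model$fit$trees, X)
  } else {
    d <- .svm_decision_cpp(model$X, model$y, model$fit$alpha, model$fit$b,
                           model$gamma, X)
    1 / (1 + exp(model$platt["A"] * d + model$platt["B"]))
  }
  negative <- setdiff(.classes, model$positive)
  data.frame(id = rownames(features) %||% seq_len(nrow(X)),
             score = as.numeric(score),
             label = ifelse(score >= 0.5, model$positive, negative),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Platt's sigmoid calibration (Newton iterations with backtracking),
# following the numerically stable published pseudo-code.
.platt_fit <- function(deci, pos) {
  prior1 <- sum(pos); prior0 <- sum(!pos)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(pos, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    fApB <- deci * A + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fv <- fval(A, B)
  for (it in 1:100) {
    fApB <- deci * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(deci * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(deci * deci * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(deci * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      nA <- A + step * dA; nB <- B + step * dB
      nf <- fval(nA, nB)
      if (nf < fv + 1e-4 * step * gd) { A <- nA; B <- nB; fv <- nf; break }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)  # P(pos | f) = 1/(1 + exp(A*f + B)); A is typically < 0
}

#' Majority-vote ensemble over per-family predictions
#'
#' The ensemble label is the strict majority of the per-family hard
#' labels; a tied vote (possible with an even number of families) is
#' broken by the mean positive-class score: positive iff it is >= 0.5.
#'
#' @param labels Character matrix (n proteins x n families) of hard labels.
#' @param scores Numeric matrix of matching shape with positive-class
#'   scores.
#' @param positive Positive class name.
#' @param expected Required number of family votes (default 6; pass the
#'   actual family count when running without the PSSM family).
#' @return data.frame with ensemble `score` (mean) and `label`.
#' @export
majority_vote <- function(labels, scores, positive = "DSB", expected = 6L) {
  stopifnot(is.matrix(labels), all(dim(labels) == dim(scores)))
  if (ncol(labels) != expected)
    stop("expected ", expected, " family votes, got ", ncol(labels))
  negative <- setdiff(.classes, positive)
  npos <- rowSums(labels == positive)
  mean_score <- rowMeans(scores)
  lab <- ifelse(npos * 2L > ncol(labels), positive,
         ifelse(npos * 2L < ncol(labels), negative,
                ifelse(mean_score >= 0.5, positive, negative)))
  data.frame(score = mean_score, label = lab, stringsAsFactors = FALSE)
}

#' AUC by the rank (Mann-Whitney) statistic
#'
#' Midranks handle tied scores, so the value equals the area under the
#' empirical ROC curve with trapezoidal interpolation across ties.
#'
#' @param scores Numeric vector of positive-class scores.
#' @param is_positive Logical vector, `TRUE` for positives.
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
auc_rank <- function(scores, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics for binary predictions
#'
#' Computes TP/FP/TN/FN and the full metric suite: accuracy (ACC),
#' sensitivity (SN = TP/(TP+FN)), specificity (SP = TN/(TN+FP)), AUC (rank
#' statistic over `scores`), Matthews correlation coefficient (MCC,
#' defined as 0 when any confusion-matrix marginal is 0) and F1
#' (2TP/(2TP+FP+FN)).
#'
#' @param predicted Character/factor vector of predicted labels.
#' @param truth Character/factor vector of true labels.
#' @param scores Optional positive-class scores for AUC.
#' @param positive Positive class (default `"DSB"`).
#' @return An `evaluation_report` list with `counts` (TP, FP, TN, FN) and
#'   `metrics` (ACC, SN, SP, AUC, MCC, F1).
#' @export
evaluate <- function(predicted, truth, scores = NULL, positive = "DSB") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth), length(truth) >= 1L)
  pos_t <- truth == positive; pos_p <- predicted == positive
  TP <- sum(pos_p & pos_t); FP <- sum(pos_p & !pos_t)
  TN <- sum(!pos_p & !pos_t); FN <- sum(!pos_p & pos_t)
  n <- TP + FP + TN + FN
  acc <- (TP + TN) / n
  sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  auc <- if (is.null(scores)) NA_real_ else auc_rank(scores, pos_t)
  structure(list(counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
                 metrics = c(ACC = acc, SN = sn, SP = sp, AUC = auc,
                             MCC = mcc, F1 = f1),
                 n = n, positive = positive),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation (positive =", x$positive, ", n =", x$n, ")\n")
  print(round(x$metrics, 4))
  invisible(x)
}

# per-fold training + test prediction shared by run_cv and the baseline
.fit_predict_families <- function(train_ds, test_ids, features, config,
                                  seeds, families) {
  scores <- labels <- matrix(NA_real_, length(test_ids), length(families),
                             dimnames = list(test_ids, families))
  labels <- matrix(NA_character_, length(test_ids), length(families),
                   dimnames = list(test_ids, families))
  importance <- vector("list", length(families)); names(importance) <- families
  for (j in seq_along(families)) {
    fam <- families[[j]]
    Xtr <- features[[fam]][train_ds$id, , drop = FALSE]
    model <- train_model(Xtr, train_ds$label, config, seed = seeds[[j]])
    pred <- predict_scores(model, features[[fam]][test_ids, , drop = FALSE])
    scores[, j] <- pred$score
    labels[, j] <- pred$label
    if (config$algorithm == "RF") importance[[fam]] <- model$fit$importance
  }
  list(scores = scores, labels = labels, importance = importance)
}

.check_features <- function(dataset, features) {
  stopifnot(is.list(features), length(features) >= 1L)
  for (fam in names(features)) {
    m <- features[[fam]]
    if (!all(dataset$id %in% rownames(m)))
      stop("feature matrix '", fam, "' is missing rows for some proteins")
  }
}

#' Cross-validated evaluation of all feature families and their ensemble
#'
#' Runs stratified k-fold cross-validation.  Within each fold the training
#' part only is balanced by majority-class down-sampling; one model per
#' feature family is trained and the untouched test part predicted.  Test
#' predictions are pooled over folds, so the pooled evaluation covers every
#' protein exactly once.  The "All features" row is the majority-voting
#' ensemble of the per-family models.
#'
#' @param dataset A `labeled_dataset`.
#' @param features A `feature_set` (named list of matrices) covering every
#'   protein; see [featurize()].
#' @param config A [model_config()].
#' @param k Number of folds (default 10; `nrow(dataset)` for
#'   leave-one-out).
#' @param seed Integer master seed; every random choice (folds,
#'   down-sampling, bootstrap) derives from it, making the run
#'   reproducible bit for bit.
#' @param downsample Balance training folds (default `TRUE`).
#' @param permute_labels Permute training labels within each fold (the
#'   chance baseline; default `FALSE`).
#' @return A `cv_result`: list with `reports` (one `evaluation_report` per
#'   family plus `"All features"`), `predictions` (pooled per-protein
#'   scores/labels), `folds`, `importance` (RF only: per-family matrix of
#'   per-fold Gini importances) and the configuration.
#' @export
run_cv <- function(dataset, features, config = model_config(), k = 10L,
                   seed = 1L, downsample = TRUE, permute_labels = FALSE) {
  .check_features(dataset, features)
  families <- names(features)
  folds <- make_folds(dataset, k, seed = seed)
  sub_seeds <- .with_seed(seed, matrix(sample.int(2^31 - 1,
                                                  k * (length(families) + 2L)),
                                       nrow = k))
  n <- nrow(dataset)
  scores <- matrix(NA_real_, n, length(families),
                   dimnames = list(dataset$id, families))
  hard <- matrix(NA_character_, n, length(families),
                 dimnames = list(dataset$id, families))
  importance <- lapply(features, function(m)
    matrix(NA_real_, k, ncol(m), dimnames = list(NULL, colnames(m))))
  for (f in seq_len(k)) {
    test_ids <- dataset$id[folds[dataset$id] == f]
    train_ds <- dataset[folds[dataset$id] != f, , drop = FALSE]
    class(train_ds) <- class(dataset)
    if (permute_labels) {
      perm <- .with_seed(sub_seeds[f, length(families) + 2L],
                         sample.int(nrow(train_ds)))
      train_ds$label <- train_ds$label[perm]
    }
    if (downsample)
      train_ds <- downsample_majority(train_ds,
                                      seed = sub_seeds[f, length(families) + 1L])
    fp <- .fit_predict_families(train_ds, test_ids, features, config,
                                sub_seeds[f, seq_along(families)], families)
    scores[test_ids, ] <- fp$scores
    hard[test_ids, ] <- fp$labels
    if (config$algorithm == "RF")
      for (fam in families) importance[[fam]][f, ] <- fp$importance[[fam]]
  }
  ens <- majority_vote(hard, scores, positive = config$positive,
                       expected = length(families))
  truth <- as.character(dataset$label)
  reports <- lapply(families, function(fam)
    evaluate(hard[, fam], truth, scores[, fam], positive = config$positive))
  names(reports) <- families
  reports[["All features"]] <- evaluate(ens$label, truth, ens$score,
                                        positive = config$positive)
  structure(list(reports = reports,
                 predictions = data.frame(id = dataset$id, truth = truth,
                                          scores, ensemble_score = ens$score,
                                          ensemble_label = ens$label,
                                          check.names = FALSE),
                 folds = folds,
                 importance = if (config$algorithm == "RF") importance,
                 config = config, k = k, seed = seed,
                 permuted = permute_labels),
            class = "cv_result")
}

#' Label-permutation chance baseline
#'
#' Identical protocol to [run_cv()] except that training labels are
#' uniformly permuted within each fold before (optional) down-sampling;
#' test labels are untouched.  A sound pipeline scores near chance
#' (AUC ~ 0.5) here regardless of how strong the true signal is.
#'
#' @inheritParams run_cv
#' @return A `cv_result` (see [run_cv()]).
#' @export
permutation_baseline <- function(dataset, features, config = model_config(),
                                 k = 10L, seed = 1L, downsample = TRUE) {
  run_cv(dataset, features, config, k = k, seed = seed,
         downsample = downsample, permute_labels = TRUE)
}

#' Independent-set evaluation
#'
#' Trains one model per feature family once on the (optionally
#' down-sampled) training set and evaluates on the full test set, plus the
#' voting ensemble.  Train and test id sets must be disjoint.
#'
#' @param train_ds,test_ds `labeled_dataset`s with disjoint ids.
#' @param train_features,test_features `feature_set`s with identical
#'   family layouts covering the respective datasets.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @param downsample Balance the training set (default `TRUE`).
#' @return List with `reports` (per family + `"All features"`) and
#'   `predictions`, class `independent_result`.
#' @export
independent_test <- function(train_ds, test_ds, train_features,
                             test_features, config = model_config(),
                             seed = 1L, downsample = TRUE) {
  if (nrow(test_ds) == 0L) stop("test set is empty")
  overlap <- intersect(train_ds$id, test_ds$id)
  if (length(overlap)) stop("train and test sets overlap: ",
                            paste(head(overlap, 5L), collapse = ", "))
  .check_features(train_ds, train_features)
  .check_features(test_ds, test_features)
  if (!identical(names(train_features), names(test_features)))
    stop("train and test feature families differ")
  families <- names(train_features)
  seeds <- .with_seed(seed, sample.int(2^31 - 1, length(families) + 1L))
  if (downsample)
    train_ds <- downsample_majority(train_ds, seed = seeds[length(families) + 1L])
  # train on train_features, predict rows drawn from test_features
  merged <- lapply(families, function(fam)
    rbind(train_features[[fam]][train_ds$id, , drop = FALSE],
          test_features[[fam]][test_ds$id, , drop = FALSE]))
  names(merged) <- families
  fp <- .fit_predict_families(train_ds, test_ds$id, merged, config,
                              seeds, families)
  scores <- fp$scores
  hard <- fp$labels
  ens <- majority_vote(hard, scores, positive = config$positive,
                       expected = length(families))
  truth <- as.character(test_ds$label)
  reports <- lapply(families, function(fam)
    evaluate(hard[, fam], truth, scores[, fam], positive = config$positive))
  names(reports) <- families
  reports[["All features"]] <- evaluate(ens$label, truth, ens$score,
                                        positive = config$positive)
  structure(list(reports = reports,
                 predictions = data.frame(id = test_ds$id, truth = truth,
                                          scores, ensemble_score = ens$score,
                                          ensemble_label = ens$label,
                                          check.names = FALSE)),
            class = "independent_result")
}

#' Metric table from a cross-validation or independent-test result
#'
#' One row per feature family plus `"All features"`, columns ACC, SN, SP,
#' AUC, MCC, F1.
#'
#' @param result A `cv_result` or `independent_result`.
#' @return data.frame of metrics.
#' @export
metrics_table <- function(result) {
  stopifnot(!is.null(result$reports))
  rows <- lapply(result$reports, function(r) as.data.frame(t(r$metrics)))
  out <- do.call(rbind, rows)
  data.frame(Features = names(result$reports), out, row.names = NULL,
             check.names = FALSE)
}
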