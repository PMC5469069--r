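test_that("downsample_majority balances classes deterministically", {
  ds <- tiny_dataset(10, 3, seed = 1)
  b <- downsample_majority(ds, seed = 4)
  expect_equal(unname(table(b$label)["DSB"]), 3L)
  expect_equal(unname(table(b$label)["SSB"]), 3L)
  expect_true(all(ds$id[ds$label == "SSB"] %in% b$id))
  expect_identical(b, downsample_majority(ds, seed = 4))
  b2 <- downsample_majority(ds, seed = 5)
  expect_false(identical(b$id, b2$id))
  # balanced input keeps membership
  even <- tiny_dataset(5, 5, seed = 2)
  expect_setequal(downsample_majority(even, seed = 1)$id, even$id)
})

test_that("make_folds stratifies and respects size constraints", {
  ds <- generate_dataset(n_dsb = 100, n_ssb = 100, delta = 0, len_min = 20,
                         len_max = 40, seed = 3)
  f <- make_folds(ds, 10, seed = 1)
  per <- table(f[ds$id], ds$label)
  expect_true(all(per == 10L))
  ds2 <- generate_dataset(n_dsb = 95, n_ssb = 95, delta = 0, len_min = 20,
                          len_max = 40, seed = 3)
  per2 <- table(make_folds(ds2, 10, seed = 1)[ds2$id], ds2$label)
  expect_true(all(per2 %in% c(9L, 10L)))
  expect_error(make_folds(ds, 1, seed = 1), "k")
  tiny <- tiny_dataset(12, 3, seed = 1)
  expect_error(make_folds(tiny, 10, seed = 1), "class")
})

test_that("train_model / predict_scores honour the basic contracts", {
  set.seed(11)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("x", 1:n),
                                                  paste0("f", 1:4)))
  y <- ifelse(X[, 1] > 0, "DSB", "SSB")
  for (alg in c("RF", "SVM")) {
    cfg <- model_config(alg, rf_trees = 100)
    m <- train_model(X, y, cfg, seed = 2)
    p <- predict_scores(m, X)
    expect_true(all(p$score >= 0 & p$score <= 1))
    expect_true(mean(p$label == y) > 0.9)  # separable case
    expect_equal(p$label, ifelse(p$score >= 0.5, "DSB", "SSB"))
    # determinism
    p2 <- predict_scores(train_model(X, y, cfg, seed = 2), X)
    expect_identical(p, p2)
    # layout mismatch
    Xbad <- X; colnames(Xbad)[2] <- "other"
    expect_error(predict_scores(m, Xbad), "missing.*f2|f2")
  }
  expect_error(train_model(X, rep("DSB", n), model_config()), "both classes")
})

test_that("constant features yield chance-level held-out AUC", {
  set.seed(12)
  X <- matrix(1, 80, 3, dimnames = list(paste0("x", 1:80), paste0("f", 1:3)))
  y <- rep(c("DSB", "SSB"), 40)
  m <- train_model(X[1:40, ], y[1:40], model_config("RF", rf_trees = 50),
                   seed = 1)
  p <- predict_scores(m, X[41:80, ])
  auc <- auc_rank(p$score, y[41:80] == "DSB")
  expect_true(is.na(auc) || abs(auc - 0.5) < 0.2)
})

test_that("majority_vote applies strict majority and the mean-score tie rule", {
  lab <- function(v) matrix(ifelse(v == 1, "DSB", "SSB"), nrow = 1)
  sc <- function(s) matrix(s, nrow = 1)
  expect_equal(majority_vote(lab(c(1, 1, 1, 1, 0, 0)), sc(rep(0.5, 6)))$label,
               "DSB")
  expect_equal(majority_vote(lab(c(0, 0, 0, 0, 1, 1)), sc(rep(0.5, 6)))$label,
               "SSB")
  # 3-3 tie broken by mean score
  expect_equal(majority_vote(lab(c(1, 1, 1, 0, 0, 0)), sc(rep(0.62, 6)))$label,
               "DSB")
  expect_equal(majority_vote(lab(c(1, 1, 1, 0, 0, 0)), sc(rep(0.38, 6)))$label,
               "SSB")
  expect_error(majority_vote(lab(c(1, 1, 0, 0)), sc(rep(0.5, 4))), "6")
  # five-family mode must be requested explicitly
  expect_equal(majority_vote(lab(c(1, 1, 1, 0, 0)), sc(rep(0.5, 5)),
                             expected = 5)$label, "DSB")
})

test_that("evaluate matches closed forms and the worked examples", {
  r <- evaluate(rep("DSB", 2), rep("DSB", 2), scores = c(0.9, 0.8))
  expect_equal(unname(r$counts), c(2, 0, 0, 0))
  r <- evaluate(c("DSB", "DSB", "SSB", "SSB"), c("DSB", "SSB", "DSB", "SSB"),
                scores = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(r$metrics["ACC"]), 0.5)
  expect_equal(unname(r$metrics["MCC"]), 0)
  # perfect classifier
  r <- evaluate(c("DSB", "DSB", "SSB", "SSB"), c("DSB", "DSB", "SSB", "SSB"),
                scores = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(r$metrics[c("ACC", "MCC", "F1", "AUC")]), rep(1, 4))
  # TP=50 FP=10 TN=40 FN=5 from the closed forms
  truth <- c(rep("DSB", 55), rep("SSB", 50))
  pred <- c(rep("DSB", 50), rep("SSB", 5), rep("DSB", 10), rep("SSB", 40))
  r <- evaluate(pred, truth)
  expect_equal(unname(r$counts), c(50, 10, 40, 5))
  expect_equal(unname(r$metrics["MCC"]),
               (50 * 40 - 10 * 5) / sqrt(60 * 55 * 50 * 45))
  expect_equal(unname(r$metrics["F1"]), 2 * 50 / (2 * 50 + 10 + 5))
})

test_that("evaluate agrees with the brute-force confusion oracle", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    truth <- sample(c("DSB", "SSB"), n, replace = TRUE)
    pred <- sample(c("DSB", "SSB"), n, replace = TRUE)
    o <- oracle_metrics(pred, truth)
    r <- evaluate(pred, truth)
    expect_equal(unname(r$counts), c(o$TP, o$FP, o$TN, o$FN))
    expect_equal(unname(r$metrics["ACC"]), o$ACC)
    if (!is.nan(o$SN)) expect_equal(unname(r$metrics["SN"]), o$SN)
    if (!is.nan(o$SP)) expect_equal(unname(r$metrics["SP"]), o$SP)
    expect_equal(unname(r$metrics["MCC"]), o$MCC)
    if (!is.nan(o$F1)) expect_equal(unname(r$metrics["F1"]), o$F1)
  }
})

test_that("MCC is symmetric under simultaneous class swap", {
  set.seed(14)
  swap <- function(x) ifelse(x == "DSB", "SSB", "DSB")
  for (rep in 1:50) {
    truth <- sample(c("DSB", "SSB"), 30, replace = TRUE)
    pred <- sample(c("DSB", "SSB"), 30, replace = TRUE)
    expect_equal(evaluate(pred, truth)$metrics[["MCC"]],
                 evaluate(swap(pred), swap(truth))$metrics[["MCC"]])
  }
})

test_that("rank AUC equals trapezoidal ROC integration, ties included", {
  set.seed(15)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    scores <- sample(round(runif(n), 2))  # rounding forces ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(auc_rank(scores, pos), oracle_auc_trapezoid(scores, pos),
                 tolerance = 1e-10)
  }
})

test_that("run_cv pools full test sets, never down-samples them", {
  ds <- tiny_dataset(40, 20, delta = 0.3, seed = 16)
  fs <- featurize(ds, families = c("OAAC", "DIPEP0"))
  cv <- run_cv(ds, fs, model_config("RF", rf_trees = 50), k = 5, seed = 2)
  expect_equal(nrow(cv$predictions), nrow(ds))
  expect_false(anyNA(cv$predictions$ensemble_score))
  expect_named(cv$reports, c("OAAC", "DIPEP0", "All features"))
  expect_equal(cv$reports[["All features"]]$n, nrow(ds))
})

test_that("run_cv is bit-reproducible for RF and SVM", {
  ds <- tiny_dataset(30, 15, delta = 0.3, seed = 17)
  fs <- featurize(ds, families = c("OAAC", "AAINDEX"),
                  aaindex = generate_aaindex_table(4, seed = 17))
  for (alg in c("RF", "SVM")) {
    cfg <- model_config(alg, rf_trees = 50)
    a <- run_cv(ds, fs, cfg, k = 5, seed = 9)
    b <- run_cv(ds, fs, cfg, k = 5, seed = 9)
    expect_identical(a$predictions, b$predictions)
    expect_identical(metrics_table(a), metrics_table(b))
  }
})

test_that("permutation baseline destroys signal that run_cv finds", {
  ds <- generate_dataset(n_dsb = 60, n_ssb = 30, delta = 0.4, len_min = 40,
                         len_max = 120, seed = 18)
  fs <- featurize(ds, families = c("OAAC", "DIPEP0"))
  cfg <- model_config("RF", rf_trees = 100)
  cv <- run_cv(ds, fs, cfg, k = 5, seed = 3)
  base <- permutation_baseline(ds, fs, cfg, k = 5, seed = 3)
  auc_true <- cv$reports[["All features"]]$metrics[["AUC"]]
  auc_base <- base$reports[["All features"]]$metrics[["AUC"]]
  expect_gt(auc_true, 0.9)
  expect_lt(auc_base, auc_true - 0.25)
  expect_gt(auc_base, 0.25)
  # seed-reproducible
  base2 <- permutation_baseline(ds, fs, cfg, k = 5, seed = 3)
  expect_identical(base$predictions, base2$predictions)
})

test_that("independent_test trains once and checks id disjointness", {
  tr <- generate_dataset(n_dsb = 50, n_ssb = 25, delta = 0.4, len_min = 40,
                         len_max = 120, seed = 19)
  te <- generate_dataset(n_dsb = 20, n_ssb = 10, delta = 0.4, len_min = 40,
                         len_max = 120, seed = 20)
  te$id <- sub("^", "T", te$id)
  fs_tr <- featurize(tr, families = c("OAAC", "DIPEP0"))
  fs_te <- featurize(te, families = c("OAAC", "DIPEP0"))
  res <- independent_test(tr, te, fs_tr, fs_te,
                          model_config("RF", rf_trees = 100), seed = 4)
  expect_equal(nrow(res$predictions), nrow(te))
  expect_gt(res$reports[["All features"]]$metrics[["AUC"]], 0.8)
  expect_error(independent_test(tr, tr, fs_tr, fs_tr), "overlap")
  expect_error(independent_test(tr, te[0, ], fs_tr, fs_te), "empty")
})

test_that("leave-one-out folds are supported as k = n", {
  ds <- tiny_dataset(8, 6, delta = 0.5, seed = 21)
  f <- make_folds(ds, nrow(ds), seed = 1)
  expect_setequal(f, seq_len(nrow(ds)))
})
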