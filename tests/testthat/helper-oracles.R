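# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the code paths they check.

# gapped dipeptide frequencies by explicit pair enumeration,
# first-residue-major layout to match compute_dipeptide()
oracle_dipeptide <- function(sequence, s) {
  aa <- aa_alphabet()
  ch <- strsplit(sequence, "")[[1L]]
  n <- length(ch)
  counts <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (t in seq_len(n - s - 1L))
    counts[ch[t], ch[t + s + 1L]] <- counts[ch[t], ch[t + s + 1L]] + 1
  as.vector(t(counts)) / (n - 1)
}

# confusion-matrix metrics computed element by element
oracle_metrics <- function(predicted, truth, positive = "DSB") {
  TP <- FP <- TN <- FN <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == positive) {
      if (predicted[i] == positive) TP <- TP + 1L else FN <- FN + 1L
    } else {
      if (predicted[i] == positive) FP <- FP + 1L else TN <- TN + 1L
    }
  }
  n <- TP + FP + TN + FN
  mcc_den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       ACC = (TP + TN) / n,
       SN = TP / (TP + FN), SP = TN / (TN + FP),
       MCC = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den,
       F1 = 2 * TP / (2 * TP + FP + FN))
}

# AUC by trapezoidal integration of the empirical ROC curve; ties are
# grouped into single ROC steps, equivalent to the midrank statistic
oracle_auc_trapezoid <- function(scores, is_positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & is_positive) / n1,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & !is_positive) / n0,
                     numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

random_sequence <- function(L) {
  paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
}

# small labeled dataset + matching features for classifier tests
tiny_dataset <- function(n_dsb = 40, n_ssb = 20, delta = 0.3, seed = 5) {
  generate_dataset(n_dsb = n_dsb, n_ssb = n_ssb, delta = delta,
                   len_min = 30, len_max = 120, seed = seed)
}
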