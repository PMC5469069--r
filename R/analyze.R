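#' Per-residue frequency contrast between the two classes
#'
#' For each of the 20 residues: the mean over proteins of its raw
#' occurrence frequency (n_i / L, no square-root transform), per class,
#' and the difference DSB - SSB.  On the reference data this contrast
#' shows the positively charged residues (Arg, Lys, His) enriched in
#' double-stranded binders and Asn/Gly/Phe/Tyr/Val in single-stranded
#' binders.
#'
#' @param dataset A `labeled_dataset` with both classes present.
#' @return data.frame with columns `item`, `mean_DSB`, `mean_SSB`,
#'   `difference`, one row per residue.
#' @export
residue_frequency_contrast <- function(dataset) {
  .check_both_classes(dataset)
  freq <- t(vapply(dataset$sequence,
                   function(s) compute_oaac(s, sqrt_transform = FALSE),
                   numeric(20)))
  m1 <- colMeans(freq[dataset$label == "DSB", , drop = FALSE])
  m2 <- colMeans(freq[dataset$label == "SSB", , drop = FALSE])
  data.frame(item = aa_alphabet(), mean_DSB = m1, mean_SSB = m2,
             difference = m1 - m2, row.names = NULL)
}

#' Dipeptide frequency contrast at a given interval
#'
#' Class means of the interval-`s` dipeptide frequencies and their
#' difference; only dipeptides whose absolute difference reaches
#' `report_threshold` are reported, sorted by decreasing absolute
#' difference.  The 0.003 default mirrors the reporting cut used for the
#' reference contrast figures.
#'
#' @param dataset A `labeled_dataset`; every sequence must have length at
#'   least `s + 2`.
#' @param s Interval in 0, 1, 2.
#' @param report_threshold Minimum |difference| to report (default 0.003;
#'   0 reports all 400).
#' @return data.frame with columns `item`, `mean_DSB`, `mean_SSB`,
#'   `difference`.
#' @export
dipeptide_frequency_contrast <- function(dataset, s,
                                         report_threshold = 0.003) {
  .check_both_classes(dataset)
  freq <- t(vapply(dataset$sequence, function(q) compute_dipeptide(q, s),
                   numeric(400)))
  m1 <- colMeans(freq[dataset$label == "DSB", , drop = FALSE])
  m2 <- colMeans(freq[dataset$label == "SSB", , drop = FALSE])
  d <- m1 - m2
  keep <- abs(d) >= report_threshold
  out <- data.frame(item = colnames(freq)[keep], mean_DSB = m1[keep],
                    mean_SSB = m2[keep], difference = d[keep],
                    row.names = NULL)
  out[order(-abs(out$difference)), , drop = FALSE]
}

#' Physicochemical difference rate per property and SAA part
#'
#' For every (property, SAA region) slot of the AAindex encoding the class
#' means K1 (DSB) and K2 (SSB) are compared by the relative difference
#' rate X = |K1 - K2| / max(K1, K2).  X is 0 when the means are equal and
#' lies in `[0, 1]` for non-negative means.  Signed property scales can
#' produce negative means, for which the ratio loses its interpretation;
#' in that case X is computed on the magnitudes |K1|, |K2| and a warning
#' is raised.  Slots where both means are 0 get X = 0.
#'
#' @param dataset A `labeled_dataset`, all sequence lengths >= 12.
#' @param table An `aaindex_table`.
#' @return data.frame with columns `property`, `part`, `mean_DSB`,
#'   `mean_SSB`, `difference_rate` (one row per property x region).
#' @export
property_difference_rate <- function(dataset, table) {
  .check_both_classes(dataset)
  enc <- t(vapply(dataset$sequence, function(q) encode_aaindex(q, table),
                  numeric(nrow(table) * 6L)))
  m1 <- colMeans(enc[dataset$label == "DSB", , drop = FALSE])
  m2 <- colMeans(enc[dataset$label == "SSB", , drop = FALSE])
  if (any(m1 < 0) || any(m2 < 0)) {
    warning("negative class means encountered; difference rate computed ",
            "on magnitudes |K1|, |K2|")
    m1x <- abs(m1); m2x <- abs(m2)
  } else {
    m1x <- m1; m2x <- m2
  }
  mx <- pmax(m1x, m2x)
  X <- ifelse(mx == 0, 0, abs(m1x - m2x) / mx)
  parts <- c("N1", "N2", "N3", "N4", "M", "C")
  data.frame(property = rep(rownames(table), each = 6L),
             part = rep(parts, times = nrow(table)),
             mean_DSB = m1, mean_SSB = m2, difference_rate = X,
             row.names = NULL)
}

#' Properties with the largest difference rates per SAA part
#'
#' Operationalises "significantly different" as a per-part upper quantile
#' of the difference rate (default: top 25% of properties within each
#' part).
#'
#' @param rates Output of [property_difference_rate()].
#' @param quantile Upper tail fraction to keep (default 0.25).
#' @return The filtered subset of `rates`, sorted within part by
#'   decreasing rate.
#' @export
top_difference_properties <- function(rates, quantile = 0.25) {
  stopifnot(quantile > 0, quantile <= 1)
  do.call(rbind, lapply(split(rates, rates$part), function(g) {
    cut <- stats::quantile(g$difference_rate, 1 - quantile, names = FALSE)
    g <- g[g$difference_rate >= cut, , drop = FALSE]
    g[order(-g$difference_rate), , drop = FALSE]
  }))
}

#' Mean Gini importance over cross-validation folds
#'
#' Averages the random-forest mean-decrease-Gini importance of every
#' feature over the folds of a [run_cv()] run, per feature family, sorted
#' descending.
#'
#' @param cv A `cv_result` from an RF run.
#' @return Named list (one element per family) of sorted named numeric
#'   vectors.
#' @export
gini_importance_summary <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  if (cv$config$algorithm != "RF" || is.null(cv$importance))
    stop("Gini importance requires a random-forest cross-validation run")
  lapply(cv$importance, function(m) sort(colMeans(m), decreasing = TRUE))
}

.check_both_classes <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  tab <- table(dataset$label)
  if (any(tab == 0L))
    stop("both classes must be non-empty; counts: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
}
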