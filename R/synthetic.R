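#' Synthetic labeled dataset with class-dependent composition bias
#'
#' Draws sequences residue by residue from class-specific multinomial
#' distributions.  Both classes start from the uniform 1/20 baseline; the
#' DSB class adds `delta / |S1|` to each residue of `dsb_enriched`
#' (default Arg, Lys, His — the positively charged residues enriched in
#' double-stranded binders) and the SSB class adds `delta / |S2|` to each
#' of `ssb_enriched` (default Asn, Gly, Phe, Tyr, Val); each distribution
#' is then renormalised.  `delta = 0` makes the classes distributionally
#' identical.  Defaults mirror the reference training data: a 873:183
#' class imbalance (scaled by `scale`) and lengths uniform on
#' `[len_min, len_max] = [60, 400]`, which exercises all three SAA
#' partition cases.
#'
#' @param n_dsb,n_ssb Class sizes (defaults `round(873 * scale)`,
#'   `round(183 * scale)`).
#' @param scale Scale factor applied to the default class sizes.
#' @param delta Total composition effect size (default 0.08).
#' @param len_min,len_max Uniform length bounds (defaults 60 and 400).
#' @param dsb_enriched,ssb_enriched Residue sets receiving the bias.
#' @param seed Integer seed; the dataset is deterministic given it.
#' @return A `labeled_dataset` with ids `DSB0001...`, `SSB0001...`.
#' @export
generate_dataset <- function(n_dsb = round(873 * scale),
                             n_ssb = round(183 * scale), scale = 1,
                             delta = 0.08, len_min = 60L, len_max = 400L,
                             dsb_enriched = c("R", "K", "H"),
                             ssb_enriched = c("N", "G", "F", "Y", "V"),
                             seed = 1L) {
  stopifnot(n_dsb >= 1L, n_ssb >= 1L, delta >= 0, len_min >= 1L,
            len_max >= len_min)
  aa <- aa_alphabet()
  stopifnot(all(dsb_enriched %in% aa), all(ssb_enriched %in% aa))
  probs_for <- function(enriched) {
    p <- rep(1 / 20, 20); names(p) <- aa
    p[enriched] <- p[enriched] + delta / length(enriched)
    if (any(p < 0)) stop("delta makes a residue probability negative")
    p / sum(p)
  }
  p_dsb <- probs_for(dsb_enriched)
  p_ssb <- probs_for(ssb_enriched)
  .with_seed(seed, {
    draw <- function(n, p, prefix) {
      lens <- sample(len_min:len_max, n, replace = TRUE)
      seqs <- vapply(lens, function(L)
        paste(sample(aa, L, replace = TRUE, prob = p), collapse = ""),
        character(1))
      protein_set(sprintf("%s%04d", prefix, seq_len(n)), seqs)
    }
    dsb <- draw(n_dsb, p_dsb, "DSB")
    ssb <- draw(n_ssb, p_ssb, "SSB")
  })
  labeled_dataset(protein_set(c(dsb$id, ssb$id), c(dsb$sequence, ssb$sequence)),
                  c(rep("DSB", n_dsb), rep("SSB", n_ssb)))
}

#' Synthetic PSSM profiles for a dataset
#'
#' For each protein, builds an L x 20 integer score matrix in which the
#' column matching the residue at each position carries a high score
#' (`match_score`) and all other columns a low score (`mismatch_score`),
#' plus rounded Gaussian noise of standard deviation `noise`.  With
#' `noise = 0` the matrix is exactly recoverable from the written file.
#'
#' @param dataset A `protein_set` or `labeled_dataset`.
#' @param noise Noise standard deviation (default 1).
#' @param match_score,mismatch_score Base scores (defaults 6 and -2,
#'   typical log-odds magnitudes).
#' @param seed Integer seed.
#' @return Named list of `pssm_profile` objects keyed by protein id.
#' @export
generate_pssm_profiles <- function(dataset, noise = 1, match_score = 6L,
                                   mismatch_score = -2L, seed = 1L) {
  aa <- aa_alphabet()
  .with_seed(seed, {
    out <- lapply(seq_len(nrow(dataset)), function(i) {
      s <- strsplit(dataset$sequence[[i]], "")[[1L]]
      L <- length(s)
      m <- matrix(mismatch_score, L, 20L, dimnames = list(NULL, aa))
      m[cbind(seq_len(L), match(s, aa))] <- match_score
      if (noise > 0) m <- m + round(matrix(rnorm(L * 20L, sd = noise), L, 20L))
      structure(list(id = dataset$id[[i]], scores = m), class = "pssm_profile")
    })
  })
  names(out) <- dataset$id
  out
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' Emits the header, the residue rows (position, residue, 20 log-odds
#' columns and 20 percentage columns) and trailing statistics lines in the
#' layout produced by `psiblast -out_ascii_pssm`, so [parse_pssm()] can
#' read the file back.  The percentage block is filled with a flat 5
#' (uninformative) since the generator models log-odds only.
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @param sequence The protein sequence the profile belongs to (used for
#'   the residue column); defaults to reconstructing from the peak column.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path, sequence = NULL) {
  scores <- profile$scores
  aa <- colnames(scores)
  if (is.null(sequence)) {
    res <- aa[max.col(scores, ties.method = "first")]
  } else {
    res <- strsplit(sequence, "")[[1L]]
    stopifnot(length(res) == nrow(scores))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("            ", paste(sprintf("%3s", aa), collapse = ""),
                      " ", paste(sprintf("%3s", aa), collapse = ""))), con)
  for (i in seq_len(nrow(scores))) {
    writeLines(paste0(sprintf("%5d %s  ", i, res[[i]]),
                      paste(sprintf("%3d", as.integer(round(scores[i, ]))),
                            collapse = ""),
                      " ",
                      paste(sprintf("%3d", rep(5L, 20L)), collapse = ""),
                      sprintf("  %4.2f %4.2f", 0.5, 0.8)), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1347     0.3179"), con)
  invisible(path)
}

#' Write synthetic PSSM files for a whole dataset
#'
#' @param dataset A `protein_set` or `labeled_dataset`.
#' @param dir Output directory (created if needed); one `<id>.pssm` per
#'   protein.
#' @param ... Passed to [generate_pssm_profiles()] (`noise`, `seed`, ...).
#' @return Named character vector of file paths, invisibly.
#' @export
generate_pssm_files <- function(dataset, dir, ...) {
  profiles <- generate_pssm_profiles(dataset, ...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(profiles), function(id) {
    p <- file.path(dir, paste0(id, ".pssm"))
    write_pssm(profiles[[id]], p,
               sequence = dataset$sequence[match(id, dataset$id)])
    p
  }, character(1))
  invisible(paths)
}

#' Synthetic AAindex-shaped property table
#'
#' Random finite property values (standard normal) with accession ids
#' `SYN0001`, `SYN0002`, ...; a drop-in shape replacement for the vendored
#' table in tests.
#'
#' @param n_properties Number of properties (default 28).
#' @param seed Integer seed.
#' @return An `aaindex_table` matrix (`n_properties` x 20).
#' @export
generate_aaindex_table <- function(n_properties = 28L, seed = 1L) {
  stopifnot(n_properties >= 1L)
  vals <- .with_seed(seed, matrix(rnorm(n_properties * 20L), n_properties, 20L))
  rownames(vals) <- sprintf("SYN%04d", seq_len(n_properties))
  colnames(vals) <- aa_alphabet()
  structure(vals, class = c("aaindex_table", class(vals)))
}

#' Write a labeled dataset's label table
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output path (TSV with header `id`, `label`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(dataset, path) {
  write.table(data.frame(id = dataset$id, label = as.character(dataset$label)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
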