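#' Square-root overall amino-acid composition (OAAC)
#'
#' Per-residue occurrence frequencies p_i = n_i / L over the 20 standard
#' amino acids, square-root transformed: f_i = sqrt(p_i).  The transform
#' makes the 20-vector lie on the unit sphere (the squared values sum to
#' one), which empirically improves composition-based classifiers.
#'
#' @param sequence Cleaned amino-acid sequence (character scalar) or a
#'   single-row `protein_set`.
#' @param sqrt_transform Apply the square-root transform (default `TRUE`);
#'   set `FALSE` to obtain raw frequencies p_i.
#' @return Named numeric vector of length 20 in canonical alphabet order.
#' @export
#' @examples
#' compute_oaac("ACDC")  # A 0.5, C ~0.7071, D 0.5
compute_oaac <- function(sequence, sqrt_transform = TRUE) {
  sequence <- .as_sequence(sequence)
  aa <- aa_alphabet()
  counts <- table(factor(strsplit(sequence, "")[[1L]], levels = aa))
  p <- as.numeric(counts) / nchar(sequence)
  out <- if (sqrt_transform) sqrt(p) else p
  names(out) <- aa
  out
}

#' Gapped dipeptide composition at interval s
#'
#' Frequencies of ordered residue pairs separated by `s` intervening
#' positions: interval 0 counts adjacent pairs, interval 1 pairs with one
#' residue between them, and so on.  Counts D_s(i,j) are divided by N - 1
#' for every interval (N = cleaned sequence length); for s > 0 only
#' N - 1 - s pairs exist, so the 400 cells sum to (N - 1 - s)/(N - 1)
#' rather than 1 — the denominator is deliberately shared across intervals
#' so the three blocks are on a common scale.
#'
#' @param sequence Cleaned sequence or single-row `protein_set`.
#' @param s Interval, one of 0, 1, 2 (larger values allowed).
#' @return Named numeric vector of length 400, ordered first residue major
#'   (names like `"AC_s1"`).
#' @export
#' @examples
#' compute_dipeptide("AGAG", 1)[c("AA_s1", "GG_s1")]  # 1/3, 1/3
compute_dipeptide <- function(sequence, s) {
  sequence <- .as_sequence(sequence)
  stopifnot(length(s) == 1L, s >= 0, s == as.integer(s))
  aa <- aa_alphabet()
  n <- nchar(sequence)
  if (n < s + 2) stop("sequence length ", n, " has no residue pairs at interval ",
                      s, " (need length >= ", s + 2, ")")
  idx <- match(strsplit(sequence, "")[[1L]], aa)
  first <- idx[seq_len(n - s - 1L)]
  second <- idx[seq_len(n - s - 1L) + s + 1L]
  counts <- tabulate((first - 1L) * 20L + second, nbins = 400L)
  out <- counts / (n - 1)
  names(out) <- paste0(rep(aa, each = 20L), rep(aa, times = 20L), "_s", s)
  out
}

#' Concatenated dipeptide composition at intervals 0, 1 and 2
#'
#' @param sequence Cleaned sequence or single-row `protein_set`.
#' @return Named numeric vector of length 1200: the interval-0, interval-1
#'   and interval-2 blocks in order.
#' @export
compute_dipeptide_all <- function(sequence) {
  sequence <- .as_sequence(sequence)
  c(compute_dipeptide(sequence, 0L),
    compute_dipeptide(sequence, 1L),
    compute_dipeptide(sequence, 2L))
}

#' Split-amino-acid (SAA) partition of a sequence
#'
#' Partitions positions 0..L-1 into six contiguous regions — four
#' N-terminal parts (N1-N4), a middle part (M) and a C-terminal part (C of
#' fixed length d_C = 10) — according to the sequence length:
#' \describe{
#'   \item{case A (L >= 130)}{N1..N4 of 25 residues each, C of 10, M the
#'     remaining L - 110.}
#'   \item{case B (90 <= L < 130)}{N1..N4 of 20 each, C of 10, M = L - 90.}
#'   \item{case C (12 <= L < 90)}{the N-terminal is not subdivided:
#'     N = floor((L - 10)/2), M the remainder, C of 10.  N1-N4 all alias
#'     the single undivided N range so every sequence still yields six
#'     region slots and feature dimensions stay constant.}
#' }
#'
#' @param L Cleaned sequence length (>= 12).
#' @return An `saa_partition`: list with `case` ("A"/"B"/"C") and
#'   `regions`, a named list of 6 half-open `[start, end)` 0-based ranges
#'   (`c(start, end)`) for N1, N2, N3, N4, M, C.
#' @export
#' @examples
#' saa_partition(130)$case  # "A"
#' vapply(saa_partition(50)$regions, diff, numeric(1))
saa_partition <- function(L) {
  stopifnot(length(L) == 1L, L == as.integer(L))
  if (L < 12) stop("SAA partition needs L >= 12, got ", L)
  d_c <- 10L
  if (L >= 130) {
    case <- "A"; d_n <- 25L
  } else if (L >= 90) {
    case <- "B"; d_n <- 20L
  } else {
    case <- "C"
  }
  if (case %in% c("A", "B")) {
    starts <- c(0L, d_n, 2L * d_n, 3L * d_n)
    regions <- list(
      N1 = c(starts[1L], starts[2L]),
      N2 = c(starts[2L], starts[3L]),
      N3 = c(starts[3L], starts[4L]),
      N4 = c(starts[4L], 4L * d_n),
      M  = c(4L * d_n, L - d_c),
      C  = c(L - d_c, L))
  } else {
    n_len <- (L - d_c) %/% 2L
    nr <- c(0L, n_len)
    regions <- list(N1 = nr, N2 = nr, N3 = nr, N4 = nr,
                    M = c(n_len, L - d_c), C = c(L - d_c, L))
  }
  structure(list(case = case, regions = regions), class = "saa_partition")
}

# mean of `values` over each SAA region; returns numeric(6) named by region.
# The middle region is empty only at L = 90 exactly (case-B lower boundary);
# its mean is defined as 0 so feature vectors never carry missing cells.
.region_means <- function(values, partition) {
  vapply(partition$regions, function(r) {
    if (r[2L] <= r[1L]) return(0)
    mean(values[(r[1L] + 1L):r[2L]])
  }, numeric(1))
}

#' SAA-partitioned AAindex physicochemical encoding
#'
#' For each physicochemical property and each of the six SAA regions, the
#' arithmetic mean of the per-residue property values over that region.
#' With the default 28-property table this yields 168 features.  Means (not
#' sums) are used so region length does not confound the encoding.
#'
#' @param sequence Cleaned sequence or single-row `protein_set` (length >= 12).
#' @param table An `aaindex_table` from [load_aaindex_table()] or
#'   [generate_aaindex_table()].
#' @param scale Optionally z-scale each property's 20 residue values before
#'   encoding (default `FALSE`: raw table values).
#' @return Named numeric vector of length `nrow(table) * 6`, property-major
#'   (names like `"KLEP840101_N1"`).
#' @export
encode_aaindex <- function(sequence, table, scale = FALSE) {
  sequence <- .as_sequence(sequence)
  stopifnot(is.matrix(table), ncol(table) == 20L)
  if (scale) table <- t(apply(table, 1L, function(r) (r - mean(r)) / sd(r)))
  part <- saa_partition(nchar(sequence))
  idx <- match(strsplit(sequence, "")[[1L]], aa_alphabet())
  out <- numeric(0)
  for (p in seq_len(nrow(table))) {
    per_res <- table[p, idx]
    out <- c(out, .region_means(per_res, part))
  }
  names(out) <- paste0(rep(rownames(table), each = 6L), "_",
                       rep(names(part$regions), times = nrow(table)))
  out
}

#' SAA-partitioned PSSM profile encoding
#'
#' For each of the 20 PSSM columns and each of the six SAA regions, the
#' arithmetic mean of that column's scores over the region's rows: 120
#' features summarising the local evolutionary profile.
#'
#' @param sequence Cleaned sequence or single-row `protein_set` (length >= 12).
#' @param profile A `pssm_profile` whose row count equals the sequence
#'   length.
#' @return Named numeric vector of length 120, PSSM-column-major (names
#'   like `"PSSM_A_N1"`).
#' @export
encode_pssm <- function(sequence, profile) {
  id <- if (inherits(sequence, "protein_set")) sequence$id[1L] else profile$id
  sequence <- .as_sequence(sequence)
  scores <- profile$scores
  stopifnot(is.matrix(scores), ncol(scores) == 20L)
  if (nrow(scores) != nchar(sequence))
    stop("PSSM profile for '", id, "' has ", nrow(scores),
         " rows but the sequence has ", nchar(sequence), " residues")
  part <- saa_partition(nchar(sequence))
  out <- numeric(0)
  for (cc in seq_len(20L))
    out <- c(out, .region_means(scores[, cc], part))
  names(out) <- paste0("PSSM_", rep(colnames(scores), each = 6L), "_",
                       rep(names(part$regions), times = 20L))
  out
}

#' Feature family names
#'
#' @param pssm Include the PSSM family (default `TRUE`).
#' @return Character vector of family identifiers.
#' @export
feature_families <- function(pssm = TRUE) {
  fams <- c("OAAC", "DIPEP0", "DIPEP1", "DIPEP2", "AAINDEX", "PSSM")
  if (pssm) fams else setdiff(fams, "PSSM")
}

#' Encode a dataset into per-family feature matrices
#'
#' Runs every requested encoder over every protein and assembles one
#' numeric matrix per feature family (rows = proteins, columns = named
#' features).  The PSSM family is included only when profiles are given;
#' the AAindex family only when a property table is given.
#'
#' @param records A `protein_set` or `labeled_dataset`.
#' @param aaindex An `aaindex_table`, or `NULL` to skip the family.
#' @param pssms Named list of `pssm_profile`s keyed by protein id, or
#'   `NULL` to skip the family.
#' @param families Families to compute (default: all available).
#' @return A named list of matrices, class `feature_set`.
#' @export
featurize <- function(records, aaindex = NULL, pssms = NULL,
                      families = NULL) {
  avail <- feature_families(pssm = !is.null(pssms))
  if (is.null(aaindex)) avail <- setdiff(avail, "AAINDEX")
  if (is.null(families)) families <- avail
  unknown <- setdiff(families, feature_families())
  if (length(unknown)) stop("unknown feature families: ",
                            paste(unknown, collapse = ", "))
  miss <- setdiff(families, avail)
  if (length(miss)) stop("families requested but inputs missing: ",
                         paste(miss, collapse = ", "))
  if (!is.null(pssms) && "PSSM" %in% families) {
    absent <- setdiff(records$id, names(pssms))
    if (length(absent)) stop("no PSSM profile for: ",
                             paste(absent, collapse = ", "))
  }
  enc_one <- function(fam, i) {
    seq_i <- records$sequence[[i]]
    switch(fam,
      OAAC    = compute_oaac(seq_i),
      DIPEP0  = compute_dipeptide(seq_i, 0L),
      DIPEP1  = compute_dipeptide(seq_i, 1L),
      DIPEP2  = compute_dipeptide(seq_i, 2L),
      AAINDEX = encode_aaindex(seq_i, aaindex),
      PSSM    = encode_pssm(seq_i, pssms[[records$id[[i]]]]))
  }
  out <- lapply(families, function(fam) {
    m <- t(vapply(seq_len(nrow(records)), function(i) enc_one(fam, i),
                  numeric(length(enc_one(fam, 1L)))))
    rownames(m) <- records$id
    m
  })
  names(out) <- families
  structure(out, class = "feature_set")
}

#' Write / read a feature matrix as delimited text
#'
#' Plain TSV with a header row of feature names and protein ids in the
#' first column, so matrices can be exchanged with other tools.
#'
#' @param m Numeric matrix with rownames (protein ids).
#' @param path Output/input path.
#' @return `path` invisibly / the matrix.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

.as_sequence <- function(x) {
  if (inherits(x, "protein_set")) {
    stopifnot(nrow(x) == 1L)
    x <- x$sequence[[1L]]
  }
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  x
}
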