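#' Clean a raw amino-acid sequence
#'
#' Uppercases the input and removes every character that is not one of the
#' 20 standard amino-acid letters.  Ambiguity codes (X, B, Z, J), the
#' non-standard residues U and O, stop characters (`*`) and gap characters
#' are all deleted rather than imputed: every downstream feature is defined
#' over the 20 standard residues only, and deletion keeps all composition
#' denominators well defined.  The cleaned length is the length used
#' everywhere else in the package.
#'
#' @param raw Character scalar, the raw sequence.
#' @return The cleaned sequence (character scalar) with attribute
#'   `removed` giving the number of characters deleted.
#' @export
#' @examples
#' clean_sequence("acdc")        # "ACDC"
#' clean_sequence("AXA")         # "AA", attr removed = 1
clean_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  up <- toupper(raw)
  kept <- gsub(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), "", up)
  removed <- nchar(up) - nchar(kept)
  if (nchar(kept) == 0L)
    stop("sequence empty after removing non-standard residues")
  structure(kept, removed = removed)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file, takes the first
#' whitespace-delimited token of each header as the record id, and cleans
#' each sequence with [clean_sequence()].  A warning names every record in
#' which non-standard characters were removed.
#'
#' @param path Path to a FASTA file.
#' @return A `protein_set`: a data.frame with columns `id`, `sequence` and
#'   `length` (cleaned length), one row per FASTA entry in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no sequences: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  raw <- as.character(set)
  cleaned <- character(length(raw))
  removed <- integer(length(raw))
  for (i in seq_along(raw)) {
    cl <- tryCatch(clean_sequence(raw[[i]]), error = function(e)
      stop("record '", ids[[i]], "': ", conditionMessage(e), call. = FALSE))
    cleaned[[i]] <- cl
    removed[[i]] <- attr(cl, "removed")
  }
  if (any(removed > 0L))
    warning("removed non-standard residues from: ",
            paste(sprintf("%s (%d)", ids[removed > 0L], removed[removed > 0L]),
                  collapse = ", "))
  protein_set(ids, cleaned)
}

#' Construct a protein set
#'
#' @param id Character vector of identifiers (must be unique).
#' @param sequence Character vector of cleaned sequences.
#' @return A `protein_set` data.frame with columns `id`, `sequence`, `length`.
#' @export
protein_set <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) stop("duplicate protein ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  sequence <- as.character(sequence)
  bad <- grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), sequence)
  if (any(bad)) stop("non-standard residues in sequences of: ",
                     paste(id[bad], collapse = ", "),
                     " (run clean_sequence first)")
  structure(
    data.frame(id = as.character(id), sequence = sequence,
               length = nchar(sequence), stringsAsFactors = FALSE),
    class = c("protein_set", "data.frame"))
}

#' Write a protein set to FASTA
#'
#' @param records A `protein_set`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read per-protein class labels
#'
#' Reads a two-column delimited text file (id, label; tab or comma
#' separated, optional header `id`/`label`) and pairs each record of
#' `records` with its class.  Labels are matched case-insensitively against
#' `DSB`/`SSB`.
#'
#' @param path Path to the label table.
#' @param records A `protein_set` as returned by [read_fasta()].
#' @return A `labeled_dataset`: the `protein_set` columns plus a `label`
#'   factor with levels `DSB`, `SSB`.
#' @export
read_labels <- function(path, records) {
  if (!file.exists(path)) stop("label file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else "\t"
  has_header <- grepl("^\\s*id[,\t]", first, ignore.case = TRUE)
  tab <- read.delim(path, sep = sep, header = has_header,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label file must have two columns (id, label)")
  ids <- as.character(tab[[1L]]); labs <- toupper(trimws(as.character(tab[[2L]])))
  bad <- setdiff(unique(labs), .classes)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "),
                        " (expected DSB or SSB)")
  extra <- setdiff(ids, records$id)
  missing <- setdiff(records$id, ids)
  if (length(extra)) stop("labels without a sequence record: ",
                          paste(extra, collapse = ", "))
  if (length(missing)) stop("records without a label: ",
                            paste(missing, collapse = ", "))
  labeled_dataset(records, labs[match(records$id, ids)])
}

#' Construct a labeled dataset
#'
#' @param records A `protein_set`.
#' @param labels Character or factor vector of `DSB`/`SSB`, one per record.
#' @return A `labeled_dataset` data.frame.
#' @export
labeled_dataset <- function(records, labels) {
  stopifnot(nrow(records) == length(labels))
  labels <- factor(toupper(as.character(labels)), levels = .classes)
  if (anyNA(labels)) stop("labels must be DSB or SSB")
  out <- records
  out$label <- labels
  class(out) <- c("labeled_dataset", "protein_set", "data.frame")
  out
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the position-specific scoring matrix written by PSI-BLAST's
#' `-out_ascii_pssm`: after the header, each residue row carries the
#' position, the query residue, 20 log-odds columns and 20 weighted
#' observed-percentage columns, followed by trailing statistics lines.  The
#' log-odds block (the "scoring matrix" proper) is returned by default,
#' reordered to the package's canonical alphabet regardless of the column
#' order declared in the file header.
#'
#' @param path Path to the PSSM file.
#' @param alphabet_order Target column ordering (default [aa_alphabet()]).
#' @param block Which 20-column block to keep: `"logodds"` (default) or
#'   `"percent"`.
#' @param id Identifier to attach; defaults to the file name without
#'   extension.
#' @return A `pssm_profile`: list with `id` and `scores`, an L x 20 numeric
#'   matrix with `colnames` equal to `alphabet_order`.
#' @export
parse_pssm <- function(path, alphabet_order = aa_alphabet(),
                       block = c("logodds", "percent"), id = NULL) {
  block <- match.arg(block)
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  # the column-header line names the 20 residues (twice in full files)
  hdr_idx <- which(grepl("^\\s*[A-Y](\\s+[A-Y]){19,39}\\s*$", lines))[1L]
  if (is.na(hdr_idx)) stop("not a PSI-BLAST ASCII PSSM (no residue header): ",
                           path)
  file_order <- strsplit(trimws(lines[hdr_idx]), "\\s+")[[1L]][1:20]
  if (!setequal(file_order, aa_alphabet()))
    stop("PSSM header does not list the 20 standard residues: ", path)

  rows <- list(); resi <- character(0)
  if (hdr_idx >= length(lines)) stop("no residue rows found in PSSM file: ",
                                     path)
  for (ln in seq(hdr_idx + 1L, length(lines))) {
    txt <- trimws(lines[[ln]])
    if (!grepl("^[0-9]+\\s+[A-Za-z]", txt)) {
      if (length(rows) > 0L) break else next
    }
    fields <- strsplit(txt, "\\s+")[[1L]]
    num <- suppressWarnings(as.numeric(fields[-(1:2)]))
    if (length(num) < 40L || anyNA(num[1:40]))
      stop("malformed PSSM matrix row at line ", ln, " of ", path,
           " (expected 40 numeric fields, found ", sum(!is.na(num)), ")")
    rows[[length(rows) + 1L]] <- num[1:40]
    resi <- c(resi, fields[[2L]])
  }
  if (length(rows) == 0L) stop("no residue rows found in PSSM file: ", path)
  mat <- do.call(rbind, rows)
  take <- if (block == "logodds") 1:20 else 21:40
  scores <- mat[, take, drop = FALSE]
  colnames(scores) <- file_order
  scores <- scores[, alphabet_order, drop = FALSE]
  rownames(scores) <- NULL
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(id = id, scores = scores), class = "pssm_profile")
}

#' Load an AAindex physicochemical property table
#'
#' Reads a delimited text table with one property per row: an accession id
#' followed by 20 per-residue values in canonical alphabet order (a header
#' line naming the residues is accepted and used to reorder).  By default
#' the loader enforces that exactly the package's vendored 28-accession set
#' is present.
#'
#' The vendored file shipped in `inst/extdata/aaindex28_synthetic.tsv`
#' carries the real 28 accession ids of the selected property set but
#' synthetic numeric values (see the package vignette): the upstream
#' AAindex database is not redistributed here.  Supply your own conforming
#' file extracted from AAindex1 for production use.
#'
#' @param path Path to the table; defaults to the vendored synthetic file.
#' @param strict If `TRUE` (default), require exactly the vendored
#'   28-accession set; if `FALSE`, accept any set of properties.
#' @return An `aaindex_table`: numeric matrix, properties x 20 residues,
#'   rownames = accessions, colnames = [aa_alphabet()].
#' @export
load_aaindex_table <- function(path = system.file("extdata",
                                                  "aaindex28_synthetic.tsv",
                                                  package = "strandbind"),
                               strict = TRUE) {
  if (!nzchar(path) || !file.exists(path))
    stop("AAindex table not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) != 21L)
    stop("AAindex table must have 21 columns (accession + 20 residues)")
  res_cols <- colnames(tab)[-1L]
  if (!setequal(res_cols, aa_alphabet()))
    stop("AAindex table header must name the 20 standard residues; missing: ",
         paste(setdiff(aa_alphabet(), res_cols), collapse = ", "))
  vals <- as.matrix(tab[, aa_alphabet()])
  rownames(vals) <- tab[[1L]]
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    bad <- rownames(vals)[apply(vals, 1L, function(r) any(!is.finite(r)))]
    stop("non-finite AAindex values for: ", paste(bad, collapse = ", "))
  }
  if (strict) {
    want <- aaindex28_accessions()
    miss <- setdiff(want, rownames(vals))
    if (length(miss)) stop("AAindex table is missing accessions: ",
                           paste(miss, collapse = ", "))
    vals <- vals[want, , drop = FALSE]
  }
  structure(vals, class = c("aaindex_table", class(vals)))
}

#' The 28 AAindex accessions used by the default physicochemical encoder
#'
#' The selected property set spans hydrophobicity/hydropathy, net charge,
#' polarity, side-chain partition energies, helix/sheet propensities and
#' inter-residue contact energies.
#'
#' @return Character vector of 28 AAindex accession ids.
#' @export
aaindex28_accessions <- function() {
  c("CHOP780202", "CIDH920103", "CIDH920105", "FAUJ880109", "FAUJ880111",
    "FINA910104", "GEIM800104", "GEIM800106", "KANM800102", "KLEP840101",
    "KRIW710101", "LIFS790101", "MEEJ800101", "OOBM770102", "PALJ810107",
    "QIAN880123", "RACS770103", "RADA880108", "ROSM880102", "SWER830101",
    "ZIMJ680102", "ZIMJ680104", "AURR980120", "MUNV940101", "NADH010104",
    "NADH010106", "GUYH850105", "MIYS990104")
}
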