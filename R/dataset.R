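## Dipeptide QSAR datasets are plain data.frames with columns
## sequence, activity, z11..z23, plus class "qsar_dataset" and a
## "provenance" attribute ("as-printed", "canonical", "user", "synthetic").

new_qsar_dataset <- function(df, provenance) {
  stopifnot(all(c("sequence", "activity", DESCRIPTOR_NAMES) %in% names(df)))
  rownames(df) <- NULL
  structure(df[, c("sequence", "activity", DESCRIPTOR_NAMES)],
            class = c("qsar_dataset", "data.frame"),
            provenance = provenance)
}

#' The 58-dipeptide ACE-inhibition training dataset
#'
#' The packaged set of 58 ACE-inhibitory dipeptides with activities expressed
#' as log(1/IC50) and six Z-scale descriptors per record. Two modes are
#' available because the published table is internally inconsistent in a few
#' rows (see [validate_dataset()]):
#'
#' * `"as-printed"` reproduces the published descriptor cells verbatim,
#'   including a duplicated `RP` entry (whose second descriptor row actually
#'   matches the dipeptide IP) and an `AY` row whose descriptors match VF.
#'   This is the default training input, mirroring what the original model
#'   most plausibly consumed.
#' * `"canonical"` keeps the sequences and activities but re-derives all
#'   descriptors from the Z-scale table via [encode_peptide()].
#'
#' @param mode `"as-printed"` (default) or `"canonical"`.
#' @param table Z-scale table used to re-derive descriptors in canonical mode.
#' @return A `qsar_dataset` data.frame with 58 rows and columns
#'   `sequence`, `activity`, `z11..z23`.
#' @export
ace_dipeptides <- function(mode = c("as-printed", "canonical"), table = zscales()) {
  mode <- match.arg(mode)
  df <- utils::read.csv(extdata_path("dipeptides58.csv"), stringsAsFactors = FALSE)
  if (nrow(df) != 58) {
    stop("packaged dipeptide dataset is corrupted: expected 58 records, found ",
         nrow(df), call. = FALSE)
  }
  if (mode == "canonical") {
    desc <- t(vapply(df$sequence, encode_peptide, numeric(6), table = table))
    df[, DESCRIPTOR_NAMES] <- desc
  }
  new_qsar_dataset(df, provenance = mode)
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("Dipeptide QSAR dataset: %d records (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "unknown"))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more records\n")
  invisible(x)
}

#' Audit a dataset's printed descriptors against the Z-scale table
#'
#' Compares every record's stored descriptors with the canonical encoding of
#' its sequence and reports rows that disagree beyond an absolute tolerance,
#' plus duplicated sequences. Applied to the as-printed packaged dataset this
#' surfaces its known internal inconsistencies instead of silently "fixing"
#' them.
#'
#' @param dataset A `qsar_dataset`.
#' @param table Z-scale table to encode against.
#' @param tol Absolute tolerance for declaring a descriptor cell inconsistent.
#' @return A list with elements `mismatches` (data.frame: `index`, `sequence`,
#'   printed `z11..z23`, canonical `canon_z11..canon_z23`, and `max_abs_diff`)
#'   and `duplicates` (data.frame: `sequence`, `indices` as a comma-joined
#'   string, `n`).
#' @export
validate_dataset <- function(dataset, table = zscales(), tol = 0.005) {
  stopifnot(inherits(dataset, "qsar_dataset") || is.data.frame(dataset))
  canon <- t(vapply(dataset$sequence, encode_peptide, numeric(6), table = table))
  printed <- as.matrix(dataset[, DESCRIPTOR_NAMES])
  diffs <- abs(printed - canon)
  bad <- which(apply(diffs, 1, max) > tol)
  mism <- data.frame(index = bad,
                     sequence = dataset$sequence[bad],
                     printed[bad, , drop = FALSE],
                     stringsAsFactors = FALSE)
  canon_bad <- canon[bad, , drop = FALSE]
  colnames(canon_bad) <- paste0("canon_", DESCRIPTOR_NAMES)
  mism <- cbind(mism, canon_bad,
                max_abs_diff = apply(diffs[bad, , drop = FALSE], 1, max))
  rownames(mism) <- NULL

  dup_seqs <- unique(dataset$sequence[duplicated(dataset$sequence)])
  dups <- data.frame(
    sequence = dup_seqs,
    indices = vapply(dup_seqs, function(s)
      paste(which(dataset$sequence == s), collapse = ","), character(1)),
    n = vapply(dup_seqs, function(s) sum(dataset$sequence == s), integer(1)),
    stringsAsFactors = FALSE)
  rownames(dups) <- NULL
  list(mismatches = mism, duplicates = dups)
}

#' Read a dipeptide QSAR dataset from CSV
#'
#' The file must contain `sequence` and `activity` columns. Descriptor
#' columns `z11..z23` are used when present and complete; otherwise they are
#' recomputed from the sequences via [encode_peptide()]. Only dipeptides are
#' accepted (the QSAR model is dipeptide-only). Unicode minus signs are
#' normalized to ASCII on input.
#'
#' @param path CSV path.
#' @param table Z-scale table for descriptor recomputation.
#' @return A `qsar_dataset` with provenance `"user"`.
#' @export
read_dataset_csv <- function(path, table = zscales()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("sequence", "activity") %in% names(df))) {
    stop("dataset CSV needs 'sequence' and 'activity' columns", call. = FALSE)
  }
  df$sequence <- toupper(trimws(df$sequence))
  bad <- which(nchar(df$sequence) != 2)
  if (length(bad) > 0) {
    stop("non-dipeptide sequences (model is dipeptide-only): ",
         paste(sprintf("row %d '%s'", bad, df$sequence[bad]), collapse = ", "),
         call. = FALSE)
  }
  ## tolerate Unicode minus in hand-edited files
  fix_minus <- function(x) {
    if (is.character(x)) as.numeric(gsub("−", "-", x)) else x
  }
  have_desc <- all(DESCRIPTOR_NAMES %in% names(df))
  if (have_desc) {
    df[DESCRIPTOR_NAMES] <- lapply(df[DESCRIPTOR_NAMES], fix_minus)
    have_desc <- !anyNA(df[, DESCRIPTOR_NAMES])
  }
  df$activity <- fix_minus(df$activity)
  if (anyNA(df$activity)) stop("non-numeric activity values", call. = FALSE)
  if (!have_desc) {
    desc <- t(vapply(df$sequence, encode_peptide, numeric(6), table = table))
    df[, DESCRIPTOR_NAMES] <- desc
  }
  new_qsar_dataset(df, provenance = "user")
}

#' Write a dipeptide QSAR dataset to CSV
#'
#' Writes the standard dialect (`sequence,activity,z11..z23`) that
#' [read_dataset_csv()] reads back; the round-trip is exact.
#'
#' @param dataset A `qsar_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
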