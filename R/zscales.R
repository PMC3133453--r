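#' Z-scale amino-acid descriptor table
#'
#' Returns the three principal-component-derived Z-scale descriptors for the
#' 20 standard amino acids: `z1` (hydrophilicity; hydrophobic residues score
#' negative), `z2` (side-chain size/shape) and `z3` (electronic properties).
#' These are the descriptors used throughout the package to encode peptides
#' for QSAR modeling.
#'
#' @param path Optional path to a CSV with columns `code,z1,z2,z3` to use an
#'   alternative descriptor table. Defaults to the packaged table.
#' @return A numeric matrix with one row per amino acid (rownames are
#'   1-letter codes) and columns `z1`, `z2`, `z3`.
#' @examples
#' zscales()["W", ]   # Trp: -4.75 3.65 0.85
#' @export
zscales <- function(path = NULL) {
  path <- path %||% extdata_path("zscales.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("code", "z1", "z2", "z3")
  if (!all(needed %in% names(tab))) {
    stop("Z-scale table must have columns code, z1, z2, z3", call. = FALSE)
  }
  if (anyDuplicated(tab$code)) {
    stop("Z-scale table has duplicated residue codes", call. = FALSE)
  }
  m <- as.matrix(tab[, c("z1", "z2", "z3")])
  if (any(!is.finite(m))) stop("Z-scale table contains non-numeric values", call. = FALSE)
  rownames(m) <- toupper(tab$code)
  m
}

#' Encode a peptide as a Z-scale descriptor vector
#'
#' Each residue contributes its (z1, z2, z3) triple, N-terminal residue
#' first, so a peptide of length L yields a 3L-vector. For dipeptides the
#' elements are named `z11, z12, z13, z21, z22, z23` (first index = residue
#' position, second = descriptor).
#'
#' @param sequence Peptide string in 1-letter codes (case-insensitive).
#' @param table Descriptor matrix as returned by [zscales()].
#' @return Named numeric vector of length `3 * nchar(sequence)`.
#' @examples
#' encode_peptide("IW")
#' @export
encode_peptide <- function(sequence, table = zscales()) {
  chars <- split_residues(sequence, valid = rownames(table))
  if (length(chars) < 1) stop("empty peptide sequence", call. = FALSE)
  v <- as.vector(t(table[chars, , drop = FALSE]))
  names(v) <- paste0("z", rep(seq_along(chars), each = 3), rep(1:3, length(chars)))
  v
}
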