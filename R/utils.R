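#' @keywords internal
"_PACKAGE"

## standard 20-letter amino-acid alphabet (1-letter codes)
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## average (not monoisotopic) residue masses in Da, i.e. amino-acid mass
## minus one water; used to convert residue counts to mass fractions
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

DESCRIPTOR_NAMES <- c("z11", "z12", "z13", "z21", "z22", "z23")

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "aceqsar", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged data file '", file, "' is missing or unreadable", call. = FALSE)
  }
  path
}

## Deterministic per-run seed derivation so whole sweeps/protocols are
## replayable from one master seed. Keeps results inside 32-bit range.
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  as.integer((abs(as.double(master)) * 48271 + as.double(index) * 7919) %% 2147483629)
}

## splits a peptide string into residue characters, validating the alphabet
split_residues <- function(sequence, valid = AA_CODES) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% valid)
  if (length(bad) > 0) {
    stop(sprintf("unknown residue code '%s' at position %d in '%s'",
                 chars[bad[1]], bad[1], sequence), call. = FALSE)
  }
  chars
}

`%||%` <- function(a, b) if (is.null(a)) b else a
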