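#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased; `*` stop characters are stripped with a
#' warning. Multi-record files return all records in file order.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names = record identifiers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0) stop("FASTA file '", path, "' contains no records",
                             call. = FALSE)
  seqs <- toupper(as.character(set))
  if (any(grepl("\\*", seqs))) {
    warning("stop characters '*' stripped from FASTA sequences")
    seqs <- gsub("\\*", "", seqs)
  }
  names(seqs) <- names(set)
  seqs
}

#' Amino-acid composition of wheat germ protein isolate
#'
#' The packaged composition (g residue per 100 g protein) of defatted wheat
#' germ protein isolate as determined by RP-HPLC amino-acid analysis.
#' Asp/Asn and Glu/Gln are reported as combined entries (acid hydrolysis
#' does not separate them), flagged by two-letter `codes`.
#'
#' @return A `protein_composition` data.frame with columns `label`, `codes`
#'   and `g_per_100g`.
#' @export
wheat_germ_composition <- function() {
  read_composition_csv(extdata_path("wheat_germ_composition.csv"))
}

#' Read a protein composition table from CSV
#'
#' Expected columns: `label`, `codes` (1-letter code, or several letters for
#' combined entries like Asx/Glx), `g_per_100g` (all non-negative).
#'
#' @param path CSV path.
#' @return A `protein_composition` data.frame.
#' @export
read_composition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "codes", "g_per_100g") %in% names(df))) {
    stop("composition CSV needs columns label, codes, g_per_100g", call. = FALSE)
  }
  df$codes <- toupper(df$codes)
  if (any(df$g_per_100g < 0)) stop("negative composition entries", call. = FALSE)
  structure(df, class = c("protein_composition", "data.frame"))
}

#' Built-in residue class sets
#'
#' The hydrophobic set `{A,V,L,I,P,F,M,W,Y}` reproduces the packaged wheat
#' germ composition's printed hydrophobic total to within rounding, and the
#' aromatic set is `{F,Y,W}`.
#'
#' @return Named list of character vectors of 1-letter codes.
#' @export
residue_classes <- function() {
  list(hydrophobic = c("A", "V", "L", "I", "P", "F", "M", "W", "Y"),
       aromatic = c("F", "Y", "W"))
}

#' Mass fraction of a residue class in a composition
#'
#' Sums the g/100 g contents of the composition entries whose residues all
#' belong to the class. Combined entries (e.g. Asx = Asp+Asn) that only
#' partially overlap the class are ambiguous: they are excluded with a
#' message.
#'
#' @param composition A `protein_composition`.
#' @param class_set Character vector of residue codes, or one of the names
#'   of [residue_classes()].
#' @return Class content in g per 100 g protein.
#' @export
class_fraction <- function(composition, class_set) {
  stopifnot(inherits(composition, "protein_composition"))
  if (is.character(class_set) && length(class_set) == 1 &&
      class_set %in% names(residue_classes())) {
    class_set <- residue_classes()[[class_set]]
  }
  class_set <- toupper(class_set)
  stopifnot(length(class_set) > 0)
  total <- 0
  for (i in seq_len(nrow(composition))) {
    codes <- strsplit(composition$codes[i], "")[[1]]
    inside <- codes %in% class_set
    if (all(inside)) {
      total <- total + composition$g_per_100g[i]
    } else if (any(inside)) {
      message("combined entry '", composition$label[i],
              "' overlaps the class only partially; excluded")
    }
  }
  total
}

#' Amino-acid composition from a protein sequence
#'
#' Converts residue counts into mass fractions (g residue per 100 g
#' protein) using average residue masses, normalized to sum to 100.
#'
#' @param sequence Protein string in 1-letter codes.
#' @return A `protein_composition` with one row per residue present.
#' @export
composition_from_sequence <- function(sequence) {
  chars <- split_residues(sequence)
  counts <- table(factor(chars, levels = AA_CODES))
  mass <- as.numeric(counts) * AA_RESIDUE_MASS[AA_CODES]
  keep <- mass > 0
  df <- data.frame(label = AA_CODES[keep], codes = AA_CODES[keep],
                   g_per_100g = 100 * mass[keep] / sum(mass),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("protein_composition", "data.frame"))
}

#' Built-in protease C-terminal specificity fixtures
#'
#' Four proteases with the residues they tend to leave at peptide
#' C-termini: Neutrase (Tyr/Trp/Phe), Alcalase (large uncharged side
#' chains: Ile, Leu, Val, Met, Phe, Tyr, Trp), Proteinase K and
#' Chymotrypsin C. User-defined specificities can be loaded with
#' [read_protease_csv()].
#'
#' @return Named list of `protease_spec` objects (fields `name`,
#'   `preference` as a character vector of codes, `note`).
#' @export
builtin_protease_specs <- function() {
  read_protease_csv(extdata_path("protease_specs.csv"))
}

#' Read protease specificities from CSV
#'
#' Expected columns: `name`, `preference` (string of 1-letter codes left at
#' C-termini), optional `note`.
#'
#' @param path CSV path.
#' @return Named list of `protease_spec` objects.
#' @export
read_protease_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "preference") %in% names(df))) {
    stop("protease CSV needs columns name, preference", call. = FALSE)
  }
  specs <- lapply(seq_len(nrow(df)), function(i) {
    pref <- unique(strsplit(toupper(df$preference[i]), "")[[1]])
    bad <- setdiff(pref, AA_CODES)
    if (length(pref) == 0 || length(bad) > 0) {
      stop("invalid preference set for ", df$name[i], call. = FALSE)
    }
    structure(list(name = df$name[i], preference = pref,
                   note = if ("note" %in% names(df)) df$note[i] else ""),
              class = "protease_spec")
  })
  stats::setNames(specs, df$name)
}

#' @export
print.protease_spec <- function(x, ...) {
  cat(sprintf("%s: C-terminal preference {%s}\n", x$name,
              paste(x$preference, collapse = ",")))
  invisible(x)
}

#' Candidate dipeptides exposed by a protease
#'
#' Enumerates all adjacent residue pairs of the protein whose second
#' (C-terminal) residue lies in the protease's preference set — the minimal
#' in-silico digestion model "the protease can expose this residue as a
#' C-terminus". Duplicates are retained with their positions; no cleavage
#' kinetics are modeled.
#'
#' @param sequence Protein string.
#' @param spec A `protease_spec`.
#' @return data.frame with columns `position` (of the first residue) and
#'   `dipeptide`; zero rows when nothing matches.
#' @export
candidate_dipeptides <- function(sequence, spec) {
  stopifnot(inherits(spec, "protease_spec"))
  chars <- split_residues(sequence)
  if (length(chars) < 2) stop("protein sequence must have >= 2 residues", call. = FALSE)
  first <- chars[-length(chars)]
  second <- chars[-1]
  keep <- second %in% spec$preference
  data.frame(position = which(keep),
             dipeptide = paste0(first[keep], second[keep]),
             stringsAsFactors = FALSE)
}

#' Predict dipeptide activity with a trained QSAR model
#'
#' Encodes peptides with the Z-scale table, normalizes the descriptors with
#' the model's scaler, runs the network forward, and (when the scaler
#' includes the target) returns predictions on the original log(1/IC50)
#' scale.
#'
#' @param net A trained `bp_network` (6 inputs).
#' @param scaler The `minmax_scaler` used in training.
#' @param peptides Character vector of dipeptide sequences.
#' @param table Z-scale table.
#' @return Named numeric vector of predicted activities.
#' @export
predict_activity <- function(net, scaler, peptides, table = zscales()) {
  stopifnot(inherits(net, "bp_network"), inherits(scaler, "minmax_scaler"))
  if (net$input_size != 6 || length(scaler$feature_min) != 6) {
    stop("model/normalizer mismatch: dipeptide QSAR needs 6 inputs", call. = FALSE)
  }
  bad <- nchar(peptides) != 2
  if (any(bad)) stop("only dipeptides can be scored: ",
                     paste(peptides[bad], collapse = ", "), call. = FALSE)
  x <- t(vapply(peptides, encode_peptide, numeric(6), table = table))
  xn <- suppressMessages(apply_normalizer(scaler, x))
  y <- nn_forward(net, xn)
  if (isTRUE(scaler$include_target)) y <- denormalize_activity(scaler, y)
  stats::setNames(y, peptides)
}

#' Rank proteases by the predicted activity of their candidate dipeptides
#'
#' For each protease, enumerates candidate dipeptides from the protein (see
#' [candidate_dipeptides()]), scores them with the QSAR model, and
#' summarizes per protease. Proteases with no candidates are excluded from
#' the ordering and reported separately.
#'
#' @param sequence Protein string.
#' @param specs List of `protease_spec`s (default [builtin_protease_specs()]).
#' @param net Trained `bp_network`.
#' @param scaler Its `minmax_scaler`.
#' @param order_by Summary used for ordering: `"mean"` (default), `"max"`
#'   or `"n"`.
#' @param table Z-scale table.
#' @return Object of class `digest_ranking`: `summary` (data.frame
#'   `protease`, `n`, `mean_activity`, `max_activity`, ordered by
#'   `order_by` descending), `details` (named list of per-candidate
#'   data.frames with predictions), and `excluded` (character).
#' @export
rank_proteases <- function(sequence, specs = builtin_protease_specs(),
                           net, scaler, order_by = c("mean", "max", "n"),
                           table = zscales()) {
  order_by <- match.arg(order_by)
  stopifnot(length(specs) >= 1)
  details <- list()
  rows <- list()
  excluded <- character()
  for (spec in specs) {
    cand <- candidate_dipeptides(sequence, spec)
    if (nrow(cand) == 0) {
      excluded <- c(excluded, spec$name)
      next
    }
    cand$predicted <- unname(predict_activity(net, scaler, cand$dipeptide,
                                              table = table))
    details[[spec$name]] <- cand
    rows[[spec$name]] <- data.frame(
      protease = spec$name, n = nrow(cand),
      mean_activity = mean(cand$predicted),
      max_activity = max(cand$predicted), stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  if (!is.null(summary)) {
    key <- switch(order_by, mean = summary$mean_activity,
                  max = summary$max_activity, n = summary$n)
    summary <- summary[order(-key, summary$protease), , drop = FALSE]
    rownames(summary) <- NULL
  }
  structure(list(summary = summary, details = details, excluded = excluded,
                 order_by = order_by),
            class = "digest_ranking")
}

#' @export
print.digest_ranking <- function(x, ...) {
  cat("Protease ranking by", x$order_by, "predicted dipeptide activity:\n")
  if (is.null(x$summary)) cat("  (no protease produced candidates)\n")
  else print(x$summary, row.names = FALSE)
  if (length(x$excluded) > 0) {
    cat("excluded (no candidate dipeptides):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
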