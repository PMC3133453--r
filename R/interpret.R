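#' The published trained 6-7-1 network weights
#'
#' Assembles a `bp_network` from the published hidden-to-output weight
#' vector LW(2,1) and input-to-hidden weight matrix LW(1,1) of the trained
#' dipeptide QSAR model. The biases were not published and are set to zero,
#' so this object supports the connection-weight interpretation procedures
#' ([select_hidden()], [backstep_importance()], [sign_analysis()]) but is
#' not a usable predictor.
#'
#' @return A `bp_network` with inputs `Z11..Z23`.
#' @export
published_network <- function() {
  doc <- jsonlite::read_json(extdata_path("trained_weights.json"),
                             simplifyVector = TRUE)
  as_bp_network(doc$iw, doc$b1, doc$lw, doc$b2, input_names = doc$input_names)
}

#' Most influential hidden neurons by output-weight magnitude
#'
#' First step of the back-stepping interpretation: hidden neurons whose
#' hidden-to-output weights `lw` have the largest absolute values influence
#' the predicted activity most. Ties break toward the lower index; indices
#' are 1-based.
#'
#' @param net A `bp_network`.
#' @param k_top How many hidden neurons to select (1..hidden_size).
#' @return data.frame with columns `index` and `weight` (signed), ordered by
#'   decreasing `|weight|`.
#' @export
select_hidden <- function(net, k_top) {
  stopifnot(inherits(net, "bp_network"))
  if (!(k_top >= 1 && k_top <= net$hidden_size)) {
    stop("k_top must be between 1 and hidden_size = ", net$hidden_size,
         call. = FALSE)
  }
  ord <- order(-abs(net$lw), seq_along(net$lw))[seq_len(k_top)]
  data.frame(index = ord, weight = net$lw[ord])
}

#' Back-stepping connection-weight importance of the inputs
#'
#' Second step of the back-stepping procedure: having selected the `k_top`
#' hidden neurons with the largest output weights, score each input by the
#' aggregate magnitude of its routes through those neurons,
#' `score_i = sum_j |lw_j * iw_{j,i}|`. This makes the qualitative
#' "observe the large weights" procedure quantitative while reproducing its
#' outcome; the raw weight matrix is carried in the report so the weights
#' can still be inspected directly.
#'
#' @param net A `bp_network`.
#' @param k_top Number of hidden neurons to trace back through (default 2).
#' @return Object of class `backstep_importance`: `selected_hidden`
#'   (data.frame from [select_hidden()]), `input_scores` (named, >= 0),
#'   `ranking` (input labels by decreasing score, ties toward the lower
#'   input index), `k_top`, and `weights` (the full `iw` matrix).
#' @export
backstep_importance <- function(net, k_top = 2) {
  sel <- select_hidden(net, k_top)
  w <- abs(net$lw[sel$index]) %*% abs(net$iw[sel$index, , drop = FALSE])
  scores <- drop(w)
  names(scores) <- net$input_names
  ord <- order(-scores, seq_along(scores))
  structure(list(selected_hidden = sel,
                 input_scores = scores,
                 ranking = net$input_names[ord],
                 k_top = k_top,
                 weights = net$iw),
            class = "backstep_importance")
}

#' @export
print.backstep_importance <- function(x, ...) {
  cat("Back-stepping connection-weight importance\n")
  cat(sprintf("hidden neurons examined (by |output weight|): %s\n",
              paste(sprintf("#%d (%.5g)", x$selected_hidden$index,
                            x$selected_hidden$weight), collapse = ", ")))
  cat("input scores:\n")
  print(round(x$input_scores, 5))
  cat("ranking:", paste(x$ranking, collapse = " > "), "\n")
  w <- x$weights
  marks <- ifelse(seq_len(nrow(w)) %in% x$selected_hidden$index, "*", " ")
  rownames(w) <- sprintf("(%d)%s", seq_len(nrow(w)), marks)
  cat("input-to-hidden weights (* = selected neurons):\n")
  print(round(w, 5))
  invisible(x)
}

#' Signed direction of an input's influence
#'
#' For one input, reports the sign of `lw_j * iw_{j,i}` through each
#' selected hidden neuron and the sum of the signed products. A positive
#' sum means increasing that (normalized) input increases the predicted
#' activity. Per-neuron signs are reported individually since routes may
#' disagree.
#'
#' @param net A `bp_network`.
#' @param input Input label (e.g. `"Z21"`) or 1-based index.
#' @param k_top Number of hidden neurons to trace (default 2).
#' @return List: `input`, `per_neuron` (data.frame `hidden`, `lw`, `iw`,
#'   `product`, `sign`), `signed_sum`, and `direction`
#'   (`"increasing"`, `"decreasing"` or `"none"`).
#' @export
sign_analysis <- function(net, input, k_top = 2) {
  stopifnot(inherits(net, "bp_network"))
  idx <- if (is.character(input)) match(toupper(input), toupper(net$input_names))
         else as.integer(input)
  if (is.na(idx) || idx < 1 || idx > net$input_size) {
    stop("unknown input: ", input, call. = FALSE)
  }
  sel <- select_hidden(net, k_top)
  products <- net$lw[sel$index] * net$iw[sel$index, idx]
  s <- sum(products)
  list(input = net$input_names[idx],
       per_neuron = data.frame(hidden = sel$index,
                               lw = net$lw[sel$index],
                               iw = net$iw[sel$index, idx],
                               product = products,
                               sign = sign(products)),
       signed_sum = s,
       direction = if (s > 0) "increasing" else if (s < 0) "decreasing" else "none")
}
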