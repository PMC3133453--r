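#' Training control parameters for the back-propagation network
#'
#' Defaults follow the documented defaults of the classical batch
#' gradient-descent-with-momentum trainer: learning rate 0.01, momentum 0.9,
#' at most 6000 epochs, and an early-stop goal of mean squared error 1e-2 on
#' the (normalized) target scale the trainer sees.
#'
#' @param learning_rate Positive step size.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param max_epochs Maximum number of full-batch epochs (>= 1).
#' @param mse_goal Early-stopping MSE threshold (> 0).
#' @param init_scale Half-range of the uniform weight initialization.
#' @return A list of class `bp_control`.
#' @export
bp_control <- function(learning_rate = 0.01, momentum = 0.9,
                       max_epochs = 6000, mse_goal = 1e-2, init_scale = 0.5) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            max_epochs >= 1, mse_goal > 0, init_scale > 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs), mse_goal = mse_goal,
                 init_scale = init_scale),
            class = "bp_control")
}

#' Initialize a three-layer feed-forward network
#'
#' Builds a 6-H-1 (generally P-H-1) network with a hyperbolic-tangent
#' sigmoid ("tansig") hidden layer and identity ("purelin") output. Weights
#' and biases are drawn uniformly from `[-init_scale, +init_scale]`,
#' reproducibly for a given seed.
#'
#' @param input_size Number of inputs P (6 for dipeptide Z descriptors).
#' @param hidden_size Number of hidden neurons H.
#' @param seed Optional RNG seed for reproducible initialization.
#' @param init_scale Half-range of the uniform initialization.
#' @param input_names Optional input labels; defaults to `Z11..Z23` when
#'   `input_size` is 6, else `x1..xP`.
#' @return An object of class `bp_network` with fields `iw` (H x P hidden
#'   weights), `b1` (H hidden biases), `lw` (H hidden-to-output weights) and
#'   `b2` (output bias).
#' @export
bp_network <- function(input_size, hidden_size, seed = NULL, init_scale = 0.5,
                       input_names = NULL) {
  stopifnot(input_size >= 1, hidden_size >= 1, init_scale > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(input_names)) {
    input_names <- if (input_size == 6) toupper(DESCRIPTOR_NAMES)
                   else paste0("x", seq_len(input_size))
  }
  stopifnot(length(input_names) == input_size)
  n_par <- hidden_size * input_size + hidden_size + hidden_size + 1
  w <- stats::runif(n_par, -init_scale, init_scale)
  structure(list(
    input_size = as.integer(input_size),
    hidden_size = as.integer(hidden_size),
    iw = matrix(w[seq_len(hidden_size * input_size)], nrow = hidden_size,
                dimnames = list(NULL, input_names)),
    b1 = w[hidden_size * input_size + seq_len(hidden_size)],
    lw = w[hidden_size * (input_size + 1) + seq_len(hidden_size)],
    b2 = w[n_par],
    input_names = input_names,
    hidden_transfer = "tansig",
    output_transfer = "purelin"
  ), class = "bp_network")
}

## Assemble a network from explicit weight components (fixtures, JSON).
as_bp_network <- function(iw, b1, lw, b2, input_names = NULL) {
  iw <- as.matrix(iw)
  h <- nrow(iw); p <- ncol(iw)
  stopifnot(length(b1) == h, length(lw) == h, length(b2) == 1)
  input_names <- input_names %||%
    (if (p == 6) toupper(DESCRIPTOR_NAMES) else paste0("x", seq_len(p)))
  colnames(iw) <- input_names
  structure(list(input_size = as.integer(p), hidden_size = as.integer(h),
                 iw = iw, b1 = as.numeric(b1), lw = as.numeric(lw),
                 b2 = as.numeric(b2), input_names = input_names,
                 hidden_transfer = "tansig", output_transfer = "purelin"),
            class = "bp_network")
}

#' @export
print.bp_network <- function(x, ...) {
  cat(sprintf("Feed-forward network %d-%d-1 (tansig hidden, linear output)\n",
              x$input_size, x$hidden_size))
  cat("inputs:", paste(x$input_names, collapse = ", "), "\n")
  invisible(x)
}

## x: n x P matrix (rows = samples). Returns list(a1 = n x H hidden
## activations, yhat = length-n predictions).
nn_forward_full <- function(net, x) {
  a1 <- tanh(x %*% t(net$iw) + matrix(net$b1, nrow(x), net$hidden_size, byrow = TRUE))
  yhat <- drop(a1 %*% net$lw) + net$b2
  list(a1 = a1, yhat = yhat)
}

as_input_matrix <- function(net, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != net$input_size) {
    stop("input dimension mismatch: network expects ", net$input_size,
         " inputs, got ", ncol(x), call. = FALSE)
  }
  x
}

#' Forward pass of a `bp_network`
#'
#' Computes `y = b2 + lw . tanh(iw x + b1)` for one descriptor vector or a
#' matrix of them (rows = samples).
#'
#' @param net A `bp_network`.
#' @param x Numeric vector of length `input_size`, or an n x `input_size`
#'   matrix.
#' @return Numeric vector of predictions (length 1 for a single vector).
#' @export
nn_forward <- function(net, x) {
  stopifnot(inherits(net, "bp_network"))
  nn_forward_full(net, as_input_matrix(net, x))$yhat
}

#' @rdname nn_forward
#' @param object A `bp_network`.
#' @param newdata Descriptor vector or matrix.
#' @param ... Ignored.
#' @export
predict.bp_network <- function(object, newdata, ...) {
  nn_forward(object, newdata)
}

## Analytic gradients of MSE = mean((yhat - y)^2) w.r.t. all parameters.
## Exposed (unexported) so tests can check them against finite differences.
bp_gradient <- function(net, x, y) {
  x <- as_input_matrix(net, x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  fw <- nn_forward_full(net, x)
  err <- fw$yhat - y
  loss <- mean(err^2)
  d_yhat <- 2 * err / n                       # n
  g_lw <- drop(crossprod(fw$a1, d_yhat))      # H
  g_b2 <- sum(d_yhat)
  d_z1 <- (d_yhat %o% net$lw) * (1 - fw$a1^2) # n x H
  g_iw <- crossprod(d_z1, x)                  # H x P
  g_b1 <- colSums(d_z1)
  list(loss = loss, iw = g_iw, b1 = g_b1, lw = g_lw, b2 = g_b2)
}

#' Train a network by full-batch gradient descent with momentum
#'
#' Minimizes the mean squared error over the training pairs with the
#' classical momentum update `delta_w(t) = momentum * delta_w(t-1) -
#' learning_rate * grad MSE`, stopping when the MSE reaches `mse_goal` or
#' after `max_epochs` epochs. Inputs and targets are expected on the
#' normalized `[0, 1]` scale (see [fit_normalizer()]).
#'
#' @param net Initial `bp_network` (see [bp_network()]).
#' @param x n x P matrix of normalized descriptors.
#' @param y Length-n vector of normalized activities.
#' @param control A [bp_control()] list.
#' @return An object of class `bp_training`: `network` (trained weights),
#'   `epochs_run`, `train_mse` (final MSE), `converged` (goal reached), and
#'   `loss_history` (per-epoch MSE before each update).
#' @export
bp_train <- function(net, x, y, control = bp_control()) {
  stopifnot(inherits(net, "bp_network"), inherits(control, "bp_control"))
  x <- as_input_matrix(net, x)
  n <- nrow(x)
  if (n < 1) stop("empty training set", call. = FALSE)
  stopifnot(length(y) == n)

  lr <- control$learning_rate
  mom <- control$momentum
  v_iw <- matrix(0, net$hidden_size, net$input_size)
  v_b1 <- numeric(net$hidden_size)
  v_lw <- numeric(net$hidden_size)
  v_b2 <- 0

  history <- numeric(control$max_epochs)
  converged <- FALSE
  epochs <- 0L
  for (epoch in seq_len(control$max_epochs)) {
    g <- bp_gradient(net, x, y)
    if (!is.finite(g$loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
    }
    history[epoch] <- g$loss
    epochs <- epoch
    if (g$loss <= control$mse_goal) {
      converged <- TRUE
      break
    }
    v_iw <- mom * v_iw - lr * g$iw
    v_b1 <- mom * v_b1 - lr * g$b1
    v_lw <- mom * v_lw - lr * g$lw
    v_b2 <- mom * v_b2 - lr * g$b2
    net$iw <- net$iw + v_iw
    net$b1 <- net$b1 + v_b1
    net$lw <- net$lw + v_lw
    net$b2 <- net$b2 + v_b2
  }
  final_mse <- mean((nn_forward(net, x) - y)^2)
  structure(list(network = net, epochs_run = epochs,
                 train_mse = final_mse,
                 converged = converged,
                 loss_history = history[seq_len(epochs)]),
            class = "bp_training")
}

#' @export
print.bp_training <- function(x, ...) {
  cat(sprintf("BP training: %d epochs, final MSE %.5g (%s)\n",
              x$epochs_run, x$train_mse,
              if (x$converged) "goal reached" else "epoch limit"))
  invisible(x)
}

#' Evaluate a network on labelled data
#'
#' Reports the Pearson correlation r of predicted versus actual activity and
#' the mean squared error. When a scaler is supplied, the paired predictions
#' are reported on the original log(1/IC50) scale (r is unchanged by the
#' affine map), while the MSE stays on the normalized scale so it is
#' comparable with the training goal.
#'
#' @param net A `bp_network`.
#' @param x n x P matrix of normalized descriptors.
#' @param y Length-n normalized activities.
#' @param scaler Optional `minmax_scaler` used to denormalize the paired
#'   predictions.
#' @return An object of class `bp_evaluation`: `r`, `mse`, `n`, and a
#'   `predictions` data.frame with columns `actual` and `predicted`.
#' @export
bp_evaluate <- function(net, x, y, scaler = NULL) {
  x <- as_input_matrix(net, x)
  stopifnot(nrow(x) >= 1, length(y) == nrow(x))
  yhat <- nn_forward(net, x)
  mse <- mean((yhat - y)^2)
  actual <- y; predicted <- yhat
  if (!is.null(scaler)) {
    actual <- denormalize_activity(scaler, y)
    predicted <- denormalize_activity(scaler, yhat)
  }
  r <- if (stats::sd(actual) == 0 || stats::sd(predicted) == 0) {
    message("Pearson r undefined (zero variance); reported as NA")
    NA_real_
  } else {
    stats::cor(actual, predicted)
  }
  structure(list(r = r, mse = mse, n = length(y),
                 predictions = data.frame(actual = actual, predicted = predicted)),
            class = "bp_evaluation")
}

#' @export
print.bp_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation on %d points: r = %.4f, MSE = %.5g\n", x$n, x$r, x$mse))
  invisible(x)
}

#' Random train/test partition of a QSAR dataset
#'
#' Uniform partition without replacement, reproducible for a given seed.
#' The default keeps 39 of the 58 packaged dipeptides for training and the
#' remaining 19 for testing.
#'
#' @param dataset A `qsar_dataset`.
#' @param n_train Number of training records (0 < n_train < nrow).
#' @param seed Optional RNG seed.
#' @return List with `train` and `test` datasets (provenance preserved) and
#'   the integer `train_idx`.
#' @export
split_dataset <- function(dataset, n_train = 39, seed = NULL) {
  n <- nrow(dataset)
  if (!(n_train > 0 && n_train < n)) {
    stop("n_train must be strictly between 0 and ", n, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(n, n_train))
  prov <- attr(dataset, "provenance")
  list(train = new_qsar_dataset(as.data.frame(dataset)[idx, , drop = FALSE], prov),
       test = new_qsar_dataset(as.data.frame(dataset)[-idx, , drop = FALSE], prov),
       train_idx = idx)
}

## dataset -> list(x = normalized descriptor matrix, y = normalized target)
dataset_xy <- function(dataset, scaler) {
  norm <- suppressMessages(apply_normalizer(scaler, as.data.frame(dataset)))
  list(x = as.matrix(norm[, DESCRIPTOR_NAMES]), y = norm$activity)
}

#' Save / load a network (with its normalizer) as JSON
#'
#' Persists shapes, weights, biases, transfer-function names and the
#' min-max normalization parameters; the round-trip is numerically exact.
#'
#' @param net A `bp_network`.
#' @param path JSON file path.
#' @param scaler Optional `minmax_scaler` stored alongside the weights.
#' @return `save_model`: `path` invisibly. `load_model`: a list with
#'   `network` and `scaler` (NULL when none was stored).
#' @export
save_model <- function(net, path, scaler = NULL) {
  stopifnot(inherits(net, "bp_network"))
  doc <- list(input_size = net$input_size, hidden_size = net$hidden_size,
              input_names = net$input_names,
              iw = unname(net$iw), b1 = net$b1, lw = net$lw, b2 = net$b2,
              hidden_transfer = net$hidden_transfer,
              output_transfer = net$output_transfer)
  if (!is.null(scaler)) {
    doc$scaler <- list(feature_min = unname(scaler$feature_min),
                       feature_max = unname(scaler$feature_max),
                       feature_names = names(scaler$feature_min),
                       include_target = scaler$include_target,
                       target_min = scaler$target_min,
                       target_max = scaler$target_max)
  }
  ## digits = I(17) guarantees an exact double round-trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- as_bp_network(doc$iw, doc$b1, doc$lw, doc$b2,
                       input_names = doc$input_names)
  scaler <- NULL
  if (!is.null(doc$scaler)) {
    s <- doc$scaler
    scaler <- structure(list(
      feature_min = stats::setNames(s$feature_min, s$feature_names),
      feature_max = stats::setNames(s$feature_max, s$feature_names),
      include_target = isTRUE(s$include_target),
      target_min = s$target_min, target_max = s$target_max),
      class = "minmax_scaler")
  }
  list(network = net, scaler = scaler)
}
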