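#' Fit a min-max normalizer to a QSAR dataset
#'
#' Computes per-feature minima and maxima so that each descriptor (and
#' optionally the activity target) can be mapped to `[0, 1]` by
#' `z' = (z - z_min) / (z_max - z_min)`. Normalizing the target as well keeps
#' the training mean-squared-error on the conventional 1e-2 goal scale; the
#' fitting population defaults to the full dataset so train and test records
#' share one scale.
#'
#' @param dataset A `qsar_dataset` (or data.frame with the same columns).
#' @param include_target Also store min/max of the `activity` column
#'   (default `TRUE`).
#' @return An object of class `minmax_scaler`.
#' @export
fit_normalizer <- function(dataset, include_target = TRUE) {
  stopifnot(nrow(dataset) > 0)
  x <- as.matrix(dataset[, DESCRIPTOR_NAMES])
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  flat <- names(mins)[maxs <= mins]
  if (length(flat) > 0) {
    stop("constant feature(s), cannot min-max normalize: ",
         paste(flat, collapse = ", "), call. = FALSE)
  }
  obj <- list(feature_min = mins, feature_max = maxs, include_target = include_target)
  if (include_target) {
    obj$target_min <- min(dataset$activity)
    obj$target_max <- max(dataset$activity)
    if (obj$target_max <= obj$target_min) {
      stop("constant feature(s), cannot min-max normalize: activity", call. = FALSE)
    }
  }
  structure(obj, class = "minmax_scaler")
}

#' @export
print.minmax_scaler <- function(x, ...) {
  cat("Min-max scaler over", length(x$feature_min), "features",
      if (x$include_target) "+ activity target" else "", "\n")
  print(rbind(min = x$feature_min, max = x$feature_max))
  invisible(x)
}

#' Apply a fitted min-max normalizer
#'
#' Maps descriptors (and, if the scaler was fitted with `include_target`,
#' the activity) onto the `[0, 1]` scale of the fitting set. Values from
#' outside the fitted range are passed through unclamped — a message flags
#' them, since extrapolation beyond the training descriptor space is then in
#' play.
#'
#' @param scaler A `minmax_scaler` from [fit_normalizer()].
#' @param data A `qsar_dataset`/data.frame with descriptor columns, or a
#'   numeric matrix/vector of descriptors in `z11..z23` order.
#' @return Object of the same shape with normalized values.
#' @export
apply_normalizer <- function(scaler, data) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  rng <- scaler$feature_max - scaler$feature_min
  scale_x <- function(x) {
    if (ncol(x) != length(scaler$feature_min)) {
      stop("feature-count mismatch: scaler has ", length(scaler$feature_min),
           " features, data has ", ncol(x), call. = FALSE)
    }
    out <- sweep(sweep(x, 2, scaler$feature_min, "-"), 2, rng, "/")
    if (any(out < -1e-12 | out > 1 + 1e-12)) {
      message("some descriptor values fall outside the fitted [min, max] range; ",
              "passed through unclamped")
    }
    out
  }
  if (is.data.frame(data)) {
    data[, DESCRIPTOR_NAMES] <- scale_x(as.matrix(data[, DESCRIPTOR_NAMES]))
    if (scaler$include_target && "activity" %in% names(data)) {
      data$activity <- (data$activity - scaler$target_min) /
        (scaler$target_max - scaler$target_min)
    }
    data
  } else if (is.matrix(data)) {
    scale_x(data)
  } else {
    drop(scale_x(matrix(data, nrow = 1)))
  }
}

#' Invert min-max normalization of the activity target
#'
#' @param scaler A `minmax_scaler` fitted with `include_target = TRUE`.
#' @param y Normalized activity values.
#' @return Activities on the original log(1/IC50) scale.
#' @export
denormalize_activity <- function(scaler, y) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  if (!isTRUE(scaler$include_target)) {
    stop("scaler was fitted without the activity target", call. = FALSE)
  }
  y * (scaler$target_max - scaler$target_min) + scaler$target_min
}

## inverse map for descriptor matrices (used by round-trip tests)
denormalize_features <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  rng <- scaler$feature_max - scaler$feature_min
  drop(sweep(sweep(x, 2, rng, "*"), 2, scaler$feature_min, "+"))
}
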