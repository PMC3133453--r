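## The trainer sees inputs and targets affinely mapped from the Eq-1 [0, 1]
## scale to [-1, 1] (the classical toolbox's native scale; the published
## error magnitudes live there). After training the map is absorbed back
## into the weights so the returned network consumes and emits [0, 1]
## directly. Hidden activations -- and hence the connection-weight
## importance products |lw_j * iw_ji| -- are invariant under the absorption.
to_symmetric <- function(v) 2 * v - 1

absorb_symmetric <- function(net) {
  net$b1 <- net$b1 - rowSums(net$iw)
  net$iw <- 2 * net$iw
  net$b2 <- (net$b2 + 1) / 2
  net$lw <- net$lw / 2
  net
}

## one split -> train -> evaluate cycle shared by the protocol and the sweep
run_cycle <- function(dataset, scaler, hidden_size, control, s_split, s_init,
                      n_train, trainer_scale) {
  parts <- split_dataset(dataset, n_train = n_train, seed = s_split)
  tr <- dataset_xy(parts$train, scaler)
  te <- dataset_xy(parts$test, scaler)
  al <- dataset_xy(dataset, scaler)
  net0 <- bp_network(ncol(tr$x), hidden_size, seed = s_init,
                     init_scale = control$init_scale,
                     input_names = toupper(DESCRIPTOR_NAMES))
  if (trainer_scale == "symmetric") {
    fit <- bp_train(net0, to_symmetric(tr$x), to_symmetric(tr$y), control = control)
    fit$network <- absorb_symmetric(fit$network)
    ## squared errors shrink by 4 under the [-1,1] -> [0,1] map
    fit$train_mse <- fit$train_mse / 4
    fit$loss_history <- fit$loss_history / 4
  } else {
    fit <- bp_train(net0, tr$x, tr$y, control = control)
  }
  list(fit = fit, split = parts,
       eval_train = bp_evaluate(fit$network, tr$x, tr$y, scaler = scaler),
       eval_test = bp_evaluate(fit$network, te$x, te$y, scaler = scaler),
       eval_all = bp_evaluate(fit$network, al$x, al$y, scaler = scaler))
}

#' Full training protocol with restarts
#'
#' Runs the complete modeling cycle — random 39/19 split, min-max
#' normalization of descriptors and target, momentum training of a
#' P-H-1 network, evaluation on train, test and all records — `restarts`
#' times with deterministically derived per-run seeds, and keeps the run
#' whose all-points Pearson r is highest. Repeated restarting operationalizes
#' "repeated modeling" on a problem this small, where individual runs vary
#' with the random split and initialization.
#'
#' @param dataset A `qsar_dataset` (default training input is the as-printed
#'   packaged dataset).
#' @param hidden_size Hidden neurons (default 7, the model-selection choice).
#' @param control A [bp_control()].
#' @param restarts Number of independent cycles (default 20).
#' @param seed Master seed; per-restart seeds derive from it.
#' @param n_train Training-set size (default 39 of 58).
#' @param include_target Normalize the activity target too (default TRUE).
#' @param scale_on Fit the normalizer on `"all"` records (default; train and
#'   test share one scale) or on `"train"` only.
#' @param trainer_scale `"symmetric"` (default): the optimizer works on
#'   data affinely mapped to `[-1, 1]`, the classical trainer's native
#'   scale, with `mse_goal` applied there; the map is absorbed back into
#'   the returned weights, so the network and all reported MSEs are on the
#'   Eq-1 `[0, 1]` scale regardless. `"unit"` trains on `[0, 1]` directly.
#' @return Object of class `train_protocol`: `result` (best run's
#'   `bp_training`), `eval_train`, `eval_test`, `eval_all`
#'   (`bp_evaluation`s, r on the original activity scale, MSE normalized),
#'   `scaler`, `split`, `best_restart`, and `runs` (per-restart summary
#'   data.frame).
#' @export
train_protocol <- function(dataset, hidden_size = 7, control = bp_control(),
                           restarts = 20, seed = NULL, n_train = 39,
                           include_target = TRUE,
                           scale_on = c("all", "train"),
                           trainer_scale = c("symmetric", "unit")) {
  scale_on <- match.arg(scale_on)
  trainer_scale <- match.arg(trainer_scale)
  stopifnot(restarts >= 1)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)

  best <- NULL
  runs <- data.frame(restart = integer(), seed = integer(), epochs = integer(),
                     converged = logical(), train_mse = numeric(),
                     r_train = numeric(), r_test = numeric(), r_all = numeric())
  scaler_all <- fit_normalizer(dataset, include_target = include_target)
  for (i in seq_len(restarts)) {
    s_split <- derive_seed(seed, 2L * i)
    s_init <- derive_seed(seed, 2L * i + 1L)
    scaler <- if (scale_on == "all") scaler_all else NULL
    if (is.null(scaler)) {
      parts_pre <- split_dataset(dataset, n_train = n_train, seed = s_split)
      scaler <- fit_normalizer(parts_pre$train, include_target = include_target)
    }
    cyc <- run_cycle(dataset, scaler, hidden_size, control, s_split, s_init,
                     n_train, trainer_scale)
    fit <- cyc$fit
    runs[i, ] <- list(i, s_split, fit$epochs_run, fit$converged, fit$train_mse,
                      cyc$eval_train$r, cyc$eval_test$r, cyc$eval_all$r)
    if (is.null(best) || (!is.na(cyc$eval_all$r) && cyc$eval_all$r > best$eval_all$r)) {
      best <- list(result = fit, eval_train = cyc$eval_train,
                   eval_test = cyc$eval_test, eval_all = cyc$eval_all,
                   scaler = scaler, split = cyc$split, best_restart = i)
    }
  }
  structure(c(best, list(runs = runs, hidden_size = hidden_size,
                         restarts = restarts, seed = seed)),
            class = "train_protocol")
}

#' @export
print.train_protocol <- function(x, ...) {
  cat(sprintf("QSAR training protocol: hidden size %d, best of %d restarts\n",
              x$hidden_size, x$restarts))
  cat(sprintf("  train: r = %.4f, MSE = %.4f (normalized), %d epochs%s\n",
              x$eval_train$r, x$result$train_mse, x$result$epochs_run,
              if (x$result$converged) ", goal reached" else ""))
  cat(sprintf("  test:  r = %.4f, MSE = %.4f (normalized)\n",
              x$eval_test$r, x$eval_test$mse))
  cat(sprintf("  all %d points: r = %.4f\n", x$eval_all$n, x$eval_all$r))
  invisible(x)
}

#' Hidden-layer-size model selection sweep
#'
#' For every candidate hidden-layer size, runs several independent
#' (split, initialize, train, evaluate-on-test) cycles and summarizes the
#' test-set Pearson r. The selected size maximizes the mean test r, with
#' ties broken toward the smaller network — fewer neurons are preferred when
#' convergence is comparable.
#'
#' @param dataset A `qsar_dataset`.
#' @param sizes Candidate hidden sizes (default `4:10`).
#' @param repeats Independent runs per size (default 5).
#' @param control A [bp_control()].
#' @param seed Master seed; per-run seeds derive from it.
#' @param n_train Training-set size per split (default 39).
#' @param include_target Normalize the target (default TRUE).
#' @param trainer_scale As in [train_protocol()].
#' @return Object of class `sweep_report`: `runs` (one row per surviving
#'   run: `hidden_size`, `rep`, `r_test`, `mse_test`, `converged`,
#'   `epochs`), `summary` (`hidden_size`, `n_runs`, `mean_r`), and
#'   `selected_size`.
#' @export
sweep_hidden <- function(dataset, sizes = 4:10, repeats = 5,
                         control = bp_control(), seed = NULL, n_train = 39,
                         include_target = TRUE,
                         trainer_scale = c("symmetric", "unit")) {
  trainer_scale <- match.arg(trainer_scale)
  stopifnot(length(sizes) >= 1, all(sizes >= 1), repeats >= 1)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  scaler <- fit_normalizer(dataset, include_target = include_target)

  rows <- list()
  counter <- 0L
  for (h in sizes) {
    for (rep_i in seq_len(repeats)) {
      counter <- counter + 1L
      s_split <- derive_seed(seed, 2L * counter)
      s_init <- derive_seed(seed, 2L * counter + 1L)
      row <- tryCatch({
        cyc <- run_cycle(dataset, scaler, h, control, s_split, s_init,
                         n_train, trainer_scale)
        data.frame(hidden_size = h, rep = rep_i, r_test = cyc$eval_test$r,
                   mse_test = cyc$eval_test$mse,
                   converged = cyc$fit$converged,
                   epochs = cyc$fit$epochs_run)
      }, error = function(e) {
        message(sprintf("sweep run (H=%d, rep %d) failed and was excluded: %s",
                        h, rep_i, conditionMessage(e)))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  runs <- do.call(rbind, rows)
  if (is.null(runs) || nrow(runs) == 0) stop("all sweep runs failed", call. = FALSE)
  summary <- do.call(rbind, lapply(split(runs, runs$hidden_size), function(d) {
    data.frame(hidden_size = d$hidden_size[1],
               n_runs = sum(!is.na(d$r_test)),
               mean_r = mean(d$r_test, na.rm = TRUE))
  }))
  rownames(summary) <- NULL
  summary <- summary[summary$n_runs > 0, , drop = FALSE]
  summary <- summary[order(summary$hidden_size), , drop = FALSE]
  ## argmax of mean r; ties toward the smaller network
  best <- summary$hidden_size[summary$mean_r >= max(summary$mean_r) - 1e-15]
  structure(list(runs = runs, summary = summary,
                 selected_size = min(best), seed = seed,
                 repeats = repeats),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("Hidden-layer size sweep (mean test-set r per size):\n")
  print(x$summary, row.names = FALSE)
  cat("selected size:", x$selected_size, "\n")
  invisible(x)
}

#' Plot a hidden-size sweep
#'
#' Mean test-set correlation against the number of hidden neurons, with the
#' selected size highlighted.
#'
#' @param x A `sweep_report`.
#' @param ... Passed to [plot()].
#' @export
plot.sweep_report <- function(x, ...) {
  plot(x$summary$hidden_size, x$summary$mean_r, type = "b", pch = 16,
       xlab = "hidden layer neurons", ylab = "mean test-set r", ...)
  graphics::abline(v = x$selected_size, lty = 2, col = "grey40")
  invisible(x)
}
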