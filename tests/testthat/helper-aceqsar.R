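## central finite-difference gradient of the training MSE, the independent
## oracle for the analytic back-propagation gradients
numeric_gradient <- function(net, x, y, eps = 1e-6) {
  f <- function(n) mean((nn_forward(n, x) - y)^2)
  g <- list(iw = net$iw * 0, b1 = net$b1 * 0, lw = net$lw * 0, b2 = 0)
  for (i in seq_along(net$iw)) {
    n1 <- net; n2 <- net
    n1$iw[i] <- n1$iw[i] + eps; n2$iw[i] <- n2$iw[i] - eps
    g$iw[i] <- (f(n1) - f(n2)) / (2 * eps)
  }
  for (i in seq_along(net$b1)) {
    n1 <- net; n2 <- net
    n1$b1[i] <- n1$b1[i] + eps; n2$b1[i] <- n2$b1[i] - eps
    g$b1[i] <- (f(n1) - f(n2)) / (2 * eps)
  }
  for (i in seq_along(net$lw)) {
    n1 <- net; n2 <- net
    n1$lw[i] <- n1$lw[i] + eps; n2$lw[i] <- n2$lw[i] - eps
    g$lw[i] <- (f(n1) - f(n2)) / (2 * eps)
  }
  n1 <- net; n2 <- net
  n1$b2 <- n1$b2 + eps; n2$b2 <- n2$b2 - eps
  g$b2 <- (f(n1) - f(n2)) / (2 * eps)
  g
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(b), floor))
}

## a modestly trained dipeptide QSAR model shared by application-layer
## tests; cached so the suite trains it once
quick_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- train_protocol(ace_dipeptides(), hidden_size = 7, restarts = 3,
                          seed = 1, control = bp_control(max_epochs = 1500))
      cache <<- list(network = p$result$network, scaler = p$scaler)
    }
    cache
  }
})

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}
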