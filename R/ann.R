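# Three-layer feed-forward network: tansig hidden layer, purelin (linear)
# output, trained full-batch by adaptive gradient descent with momentum
# under the least-mean-squares criterion. Matches the classic batch
# "adaptive gradient descent with momentum" scheme: after each epoch the
# step is kept or rejected by comparing the new error with the old one, and
# the learning rate is grown or shrunk accordingly.

#' Hyperbolic tangent sigmoid activation
#'
#' `tansig(n) = -1 + 2 / (1 + exp(-2 n))`, algebraically equal to `tanh(n)`;
#' the direct form is numerically stable for large |n| (it saturates to
#' exactly -1 / 1).
#'
#' @param n Numeric vector or matrix of net inputs.
#' @return Activations in (-1, 1).
#' @export
tansig <- function(n) -1 + 2 / (1 + exp(-2 * n))

#' Linear (identity) activation
#' @param n Numeric input.
#' @return `n` unchanged.
#' @export
purelin <- function(n) n

#' Training configuration for the network
#'
#' @param learning_rate Initial learning rate eta (default 0.01).
#' @param momentum Momentum mu in \[0, 1) (default 0.4).
#' @param max_epochs Epoch cap (default 5000).
#' @param lr_increase Factor applied to eta after an epoch that lowered the
#'   error (default 1.05).
#' @param lr_decrease Factor applied after a rejected epoch (default 0.7).
#' @param error_ratio_limit An epoch is rejected when its error exceeds this
#'   multiple of the previous error (default 1.04).
#' @param init_scale Half-width of the uniform weight initialization
#'   (default 0.5).
#' @param early_stop_tol Stop when the accepted-epoch error change falls
#'   below this (default 1e-10).
#' @param n_hidden Hidden-layer width (default 10).
#' @param seed Seed for weight initialization.
#' @return An `ann_config` list.
#' @export
ann_config <- function(learning_rate = 0.01, momentum = 0.4, max_epochs = 5000L,
                       lr_increase = 1.05, lr_decrease = 0.7,
                       error_ratio_limit = 1.04, init_scale = 0.5,
                       early_stop_tol = 1e-10, n_hidden = 10L, seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            lr_increase > 1 || lr_increase == 1, lr_decrease > 0, lr_decrease <= 1,
            n_hidden >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs), lr_increase = lr_increase,
                 lr_decrease = lr_decrease, error_ratio_limit = error_ratio_limit,
                 init_scale = init_scale, early_stop_tol = early_stop_tol,
                 n_hidden = as.integer(n_hidden), seed = as.integer(seed)),
            class = "ann_config")
}

#' Initialize a three-layer network
#'
#' Weights are drawn uniform(-init_scale, init_scale), biases start at 0.
#'
#' @param n_inputs,n_hidden Layer sizes (>= 1).
#' @param cfg An [ann_config()] (supplies `init_scale` and `seed`).
#' @return An `ann_model`: `w_hidden` (n_hidden x n_inputs), `b_hidden`,
#'   `w_out` (1 x n_hidden), `b_out`, `n_hidden`.
#' @export
init_ann <- function(n_inputs, n_hidden = cfg$n_hidden, cfg = ann_config()) {
  if (n_inputs < 1L || n_hidden < 1L) stop("layer sizes must be >= 1", call. = FALSE)
  with_seed(cfg$seed, {
    s <- cfg$init_scale
    structure(list(
      w_hidden = matrix(stats::runif(n_hidden * n_inputs, -s, s), n_hidden, n_inputs),
      b_hidden = numeric(n_hidden),
      w_out = matrix(stats::runif(n_hidden, -s, s), 1L, n_hidden),
      b_out = 0,
      n_hidden = as.integer(n_hidden)),
      class = "ann_model")
  })
}

#' Forward pass: continuous network scores
#'
#' `score = purelin(w_out . tansig(w_hidden x + b_hidden) + b_out)`.
#'
#' @param model An `ann_model`.
#' @param x Numeric matrix, samples x inputs.
#' @return Numeric score vector, one per row of `x`.
#' @export
ann_forward <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$w_hidden))
    stop("input has ", ncol(x), " columns; model expects ", ncol(model$w_hidden),
         call. = FALSE)
  h <- tansig(sweep(x %*% t(model$w_hidden), 2L, model$b_hidden, "+"))
  drop(h %*% t(model$w_out)) + model$b_out
}

ann_loss <- function(model, x, y) mean((ann_forward(model, x) - y)^2) / 2

# Loss L = mean((score - y)^2) / 2 and its analytic gradients.
ann_loss_grad <- function(model, x, y) {
  n <- nrow(x)
  z <- sweep(x %*% t(model$w_hidden), 2L, model$b_hidden, "+")
  h <- tansig(z)
  s <- drop(h %*% t(model$w_out)) + model$b_out
  e <- s - y
  loss <- mean(e^2) / 2
  ds <- e / n
  g_wout <- rbind(colSums(ds * h))           # 1 x n_hidden
  g_bout <- sum(ds)
  dh <- (ds %o% drop(model$w_out)) * (1 - h^2)
  g_whid <- crossprod(dh, x)                 # n_hidden x n_inputs
  g_bhid <- colSums(dh)
  list(loss = loss,
       grads = list(w_hidden = g_whid, b_hidden = g_bhid,
                    w_out = g_wout, b_out = g_bout))
}

#' Train the network by adaptive gradient descent with momentum
#'
#' Full-batch updates of the least-mean-squares loss
#' `L = mean((score - y)^2) / 2` with velocity
#' `delta_t = mu * delta_(t-1) - eta_t * grad L`. After each epoch the new
#' loss is compared with the previous one: if it exceeds
#' `error_ratio_limit` times the previous loss the step is undone, the
#' momentum buffer zeroed and eta shrunk by `lr_decrease`; otherwise the
#' step is kept and, when the loss decreased, eta grows by `lr_increase`.
#' Training stops at `max_epochs` or when the accepted loss change is below
#' `early_stop_tol`.
#'
#' @param model An `ann_model` (see [init_ann()]).
#' @param x Standardized feature matrix, samples x inputs.
#' @param y Numeric 0/1 target vector.
#' @param cfg An [ann_config()].
#' @return List with `model` (trained) and `trace` (per-epoch `mse`,
#'   `learning_rate`, and `epochs_run`).
#' @export
ann_train <- function(model, x, y, cfg = ann_config()) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  eta <- cfg$learning_rate
  mu <- cfg$momentum
  vel <- list(w_hidden = model$w_hidden * 0, b_hidden = model$b_hidden * 0,
              w_out = model$w_out * 0, b_out = 0)
  prev <- ann_loss(model, x, y)
  mse_trace <- lr_trace <- numeric(cfg$max_epochs)
  epochs <- 0L
  for (t in seq_len(cfg$max_epochs)) {
    lg <- ann_loss_grad(model, x, y)
    for (nm in names(vel)) {
      vel[[nm]] <- mu * vel[[nm]] - eta * lg$grads[[nm]]
      model[[nm]] <- model[[nm]] + vel[[nm]]
    }
    new_loss <- ann_loss(model, x, y)
    if (!is.finite(new_loss)) {
      epochs <- t
      mse_trace[t] <- new_loss; lr_trace[t] <- eta
      warning("non-finite loss; training aborted", call. = FALSE)
      break
    }
    if (new_loss > cfg$error_ratio_limit * prev) {
      for (nm in names(vel)) model[[nm]] <- model[[nm]] - vel[[nm]]
      vel <- lapply(vel, function(v) v * 0)
      eta <- eta * cfg$lr_decrease
      mse_trace[t] <- prev; lr_trace[t] <- eta
      epochs <- t
      next
    }
    if (new_loss < prev) eta <- eta * cfg$lr_increase
    delta <- abs(prev - new_loss)
    prev <- new_loss
    mse_trace[t] <- new_loss; lr_trace[t] <- eta
    epochs <- t
    if (delta < cfg$early_stop_tol) break
  }
  list(model = model,
       trace = list(mse = mse_trace[seq_len(epochs)],
                    learning_rate = lr_trace[seq_len(epochs)],
                    epochs_run = epochs))
}

#' Classify from network scores
#'
#' @param model A trained `ann_model`.
#' @param x Feature matrix.
#' @param threshold Score cutoff; class 1 when score >= threshold (default 0.5).
#' @return Integer 0/1 predictions.
#' @export
predict_class <- function(model, x, threshold = 0.5) {
  as.integer(ann_forward(model, x) >= threshold)
}

#' Misclassification rate
#'
#' @param pred,truth Equal-length 0/1 vectors.
#' @return Fraction of mismatches.
#' @export
error_rate <- function(pred, truth) {
  if (length(pred) == 0L || length(pred) != length(truth))
    stop("pred and truth must be nonempty and of equal length", call. = FALSE)
  mean(pred != truth)
}

#' Serialize / restore a trained network as JSON
#'
#' @param model An `ann_model`.
#' @param path File path.
#' @export
write_ann_json <- function(model, path) {
  jsonlite::write_json(list(w_hidden = model$w_hidden, b_hidden = model$b_hidden,
                            w_out = model$w_out, b_out = model$b_out,
                            n_hidden = model$n_hidden),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ann_json
#' @export
read_ann_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w_hidden = as.matrix(j$w_hidden), b_hidden = as.numeric(j$b_hidden),
                 w_out = matrix(j$w_out, nrow = 1L), b_out = as.numeric(j$b_out),
                 n_hidden = as.integer(j$n_hidden)),
            class = "ann_model")
}
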