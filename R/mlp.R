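# Minimal dense feedforward networks used as behavioral read-outs: ReLU
# hidden layers, sigmoid or softmax output, mean-absolute-error or
# categorical cross-entropy loss, RMSProp or Adam minibatch updates.
# Hyperparameter defaults follow common deep-learning-library settings
# (RMSProp rho 0.9; Adam beta 0.9/0.999; eps 1e-7; He initialization).

#' Network architecture and training parameters
#'
#' @param input_dim Number of input features.
#' @param hidden Integer vector of hidden-layer widths (ReLU units).
#' @param output_dim Number of output units.
#' @param activation_out `"sigmoid"` (with `"mae"` loss) or `"softmax"`
#'   (with `"categorical_crossentropy"`).
#' @param loss Loss function.
#' @param optimizer `"rmsprop"` or `"adam"`.
#' @param epochs,batch_size,learning_rate Training schedule.
#' @param standardize Standardize inputs with training-set mean/sd.
#' @param seed RNG seed for initialization and shuffling.
#' @return An object of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim, hidden, output_dim = 1L,
                     activation_out = c("sigmoid", "softmax"),
                     loss = c("mae", "categorical_crossentropy"),
                     optimizer = c("rmsprop", "adam"),
                     epochs = 100L, batch_size = 32L, learning_rate = 1e-3,
                     standardize = TRUE, seed = 1L) {
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim),
                 activation_out = match.arg(activation_out),
                 loss = match.arg(loss), optimizer = match.arg(optimizer),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, standardize = standardize,
                 seed = seed),
            class = "mlp_spec")
}

#' 2AFC discriminator network specification
#'
#' The fixed read-out used in the simulated behavioral experiments: 25
#' inputs, two hidden ReLU layers of 50 units, one sigmoid output trained
#' with mean-absolute-error loss under RMSProp.
#'
#' @param ... Overrides passed to [mlp_spec()] (e.g. `epochs`, `seed`).
#' @return An `mlp_spec`.
#' @export
discriminator_spec <- function(...) {
  args <- list(input_dim = 25L, hidden = c(50L, 50L), output_dim = 1L,
               activation_out = "sigmoid", loss = "mae",
               optimizer = "rmsprop")
  do.call(mlp_spec, utils::modifyList(args, list(...)))
}

#' Place-recognition network specification
#'
#' 25 inputs, hidden ReLU layers of 50, 100 and 50 units, and a softmax
#' output over the locations, trained with categorical cross-entropy under
#' Adam.
#'
#' @param n_classes Number of locations (output units).
#' @param ... Overrides passed to [mlp_spec()].
#' @return An `mlp_spec`.
#' @export
place_net_spec <- function(n_classes = 21L, ...) {
  args <- list(input_dim = 25L, hidden = c(50L, 100L, 50L),
               output_dim = as.integer(n_classes),
               activation_out = "softmax", loss = "categorical_crossentropy",
               optimizer = "adam")
  do.call(mlp_spec, utils::modifyList(args, list(...)))
}

#' @keywords internal
mlp_forward <- function(weights, X) {
  acts <- vector("list", length(weights))
  A <- X
  nl <- length(weights)
  for (l in seq_len(nl)) {
    Zl <- sweep(A %*% weights[[l]]$W, 2L, weights[[l]]$b, "+")
    if (l < nl) A <- pmax(Zl, 0)
    else A <- Zl
    acts[[l]] <- A
  }
  acts
}

#' @keywords internal
out_activation <- function(Z, kind) {
  if (kind == "sigmoid") return(1 / (1 + exp(-Z)))
  # softmax, rowwise, stabilized
  E <- exp(Z - apply(Z, 1L, max))
  E / rowSums(E)
}

#' Train a feedforward network
#'
#' @param x Numeric matrix of inputs (one row per observation).
#' @param y Targets: a 0/1 vector (sigmoid output) or a one-hot matrix /
#'   class factor (softmax output).
#' @param spec An [mlp_spec()].
#' @param verbose Print the loss every 10 epochs.
#' @return An object of class `mlp` with weights, the per-epoch training
#'   loss (`$history`) and the input standardization.
#' @export
mlp_train <- function(x, y, spec, verbose = FALSE) {
  if (!inherits(spec, "mlp_spec")) stop("`spec` must be an mlp_spec")
  x <- as.matrix(x)
  if (ncol(x) != spec$input_dim) stop("input width does not match `spec`")
  if (spec$activation_out == "softmax") {
    if (is.factor(y) || is.character(y) || is.null(dim(y))) {
      f <- factor(y)
      if (nlevels(f) < 2L) stop("training data contain a single class")
      Y <- diag(spec$output_dim)[as.integer(f), , drop = FALSE]
      levels_out <- levels(f)
    } else {
      Y <- as.matrix(y); levels_out <- colnames(Y)
    }
  } else {
    y <- as.numeric(y)
    if (length(unique(y)) < 2L) stop("training data contain a single class")
    Y <- matrix(y, ncol = 1L)
    levels_out <- NULL
  }
  if (nrow(Y) != nrow(x)) stop("`x` and `y` sizes differ")
  ctr <- if (spec$standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (spec$standardize) pmax(apply(x, 2L, stats::sd), 1e-12)
         else rep(1, ncol(x))
  X <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")

  sizes <- c(spec$input_dim, spec$hidden, spec$output_dim)
  nl <- length(sizes) - 1L
  eps <- 1e-7
  with_rng_seed(spec$seed, {
    weights <- lapply(seq_len(nl), function(l) {
      list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                   sd = sqrt(2 / sizes[l])),
                      sizes[l], sizes[l + 1L]),
           b = numeric(sizes[l + 1L]))
    })
    opt <- lapply(weights, function(w)
      list(vW = w$W * 0, vb = w$b * 0, mW = w$W * 0, mb = w$b * 0))
    step <- 0L
    history <- numeric(spec$epochs)
    n <- nrow(X)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        m <- length(idx)
        acts <- mlp_forward(weights, Xb)
        A_out <- out_activation(acts[[nl]], spec$activation_out)
        if (spec$loss == "mae") {
          ep_loss <- ep_loss + sum(abs(A_out - Yb))
          dZ <- sign(A_out - Yb) * A_out * (1 - A_out) / m
        } else {
          ep_loss <- ep_loss - sum(Yb * log(pmax(A_out, 1e-12)))
          dZ <- (A_out - Yb) / m
        }
        step <- step + 1L
        for (l in rev(seq_len(nl))) {
          A_prev <- if (l == 1L) Xb else acts[[l - 1L]]
          gW <- crossprod(A_prev, dZ)
          gb <- colSums(dZ)
          if (l > 1L) {
            dA <- tcrossprod(dZ, weights[[l]]$W)
            dZ <- dA * (acts[[l - 1L]] > 0)
          }
          o <- opt[[l]]
          if (spec$optimizer == "rmsprop") {
            o$vW <- 0.9 * o$vW + 0.1 * gW^2
            o$vb <- 0.9 * o$vb + 0.1 * gb^2
            weights[[l]]$W <- weights[[l]]$W -
              spec$learning_rate * gW / (sqrt(o$vW) + eps)
            weights[[l]]$b <- weights[[l]]$b -
              spec$learning_rate * gb / (sqrt(o$vb) + eps)
          } else {
            o$mW <- 0.9 * o$mW + 0.1 * gW
            o$mb <- 0.9 * o$mb + 0.1 * gb
            o$vW <- 0.999 * o$vW + 0.001 * gW^2
            o$vb <- 0.999 * o$vb + 0.001 * gb^2
            bc1 <- 1 - 0.9^step; bc2 <- 1 - 0.999^step
            weights[[l]]$W <- weights[[l]]$W -
              spec$learning_rate * (o$mW / bc1) / (sqrt(o$vW / bc2) + eps)
            weights[[l]]$b <- weights[[l]]$b -
              spec$learning_rate * (o$mb / bc1) / (sqrt(o$vb / bc2) + eps)
          }
          opt[[l]] <- o
        }
      }
      history[ep] <- ep_loss / n
      if (verbose && ep %% 10L == 0L)
        message(sprintf("epoch %d/%d loss %.4f", ep, spec$epochs, history[ep]))
    }
    structure(list(weights = weights, spec = spec, center = ctr, scale = scl,
                   history = history, levels = levels_out),
              class = "mlp")
  })
}

#' Network outputs for new inputs
#'
#' @param model A trained `mlp`.
#' @param x Numeric matrix of inputs (one row per observation).
#' @return Matrix of outputs: one column (sigmoid) or one per class
#'   (softmax probabilities).
#' @export
mlp_predict <- function(model, x) {
  if (!inherits(model, "mlp")) stop("`model` must be a trained mlp")
  X <- sweep(sweep(as.matrix(x), 2L, model$center), 2L, model$scale, "/")
  acts <- mlp_forward(model$weights, X)
  out_activation(acts[[length(acts)]], model$spec$activation_out)
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("<mlp> %s, final training loss %.4f\n",
              paste(c(x$spec$input_dim, x$spec$hidden, x$spec$output_dim),
                    collapse = "-"),
              utils::tail(x$history, 1L)))
  invisible(x)
}
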