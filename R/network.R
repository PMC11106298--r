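#' Three-layer network shape
#'
#' @param n_input Number of predictor variables.
#' @param n_hidden Hidden-layer size; 5 is the workflow default.
#' @param n_output Output size; 1 for a single suitability score.
#' @return An object of class `network_shape`.
#' @export
network_shape <- function(n_input, n_hidden = 5L, n_output = 1L) {
  n_input <- as.integer(n_input); n_hidden <- as.integer(n_hidden)
  n_output <- as.integer(n_output)
  if (any(is.na(c(n_input, n_hidden, n_output))) ||
      n_input < 1L || n_hidden < 1L || n_output < 1L)
    stop("all layer sizes must be positive integers")
  structure(list(n_input = n_input, n_hidden = n_hidden, n_output = n_output),
            class = "network_shape")
}

#' Length of the flat weight vector for a shape
#'
#' The search-space dimensionality when the whole network is encoded as one
#' position vector:
#' `n_input * n_hidden + n_hidden + n_hidden * n_output + n_output`
#' (input-to-hidden weights, hidden biases, hidden-to-output weights,
#' output biases — biases are the "thresholds" of the GWO-network
#' literature).
#'
#' @param shape A [network_shape()].
#' @export
#' @examples
#' network_dimension(network_shape(4, 5, 1))  # 31
network_dimension <- function(shape) {
  stopifnot(inherits(shape, "network_shape"))
  shape$n_input * shape$n_hidden + shape$n_hidden +
    shape$n_hidden * shape$n_output + shape$n_output
}

#' Build a network from explicit weight matrices
#'
#' @param W1 `n_input x n_hidden` input-to-hidden weights.
#' @param b1 Length-`n_hidden` hidden biases.
#' @param W2 `n_hidden x n_output` hidden-to-output weights.
#' @param b2 Length-`n_output` output biases.
#' @export
network <- function(W1, b1, W2, b2) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  if (ncol(W1) != length(b1) || nrow(W2) != length(b1) ||
      ncol(W2) != length(b2))
    stop("inconsistent layer dimensions")
  if (!all(is.finite(W1)) || !all(is.finite(b1)) ||
      !all(is.finite(W2)) || !all(is.finite(b2)))
    stop("network weights must be finite")
  structure(list(W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2)),
            class = "network")
}

#' Flatten a network into a weight vector
#'
#' Layout: `W1` row-major, then `b1`, then `W2` row-major, then `b2`.
#' [decode_weights()] is the exact inverse.
#'
#' @param net A [network()].
#' @export
encode_weights <- function(net) {
  stopifnot(inherits(net, "network"))
  c(as.vector(t(net$W1)), net$b1, as.vector(t(net$W2)), net$b2)
}

#' Rebuild a network from a flat weight vector
#'
#' @param v Numeric vector of length [network_dimension()] for `shape`.
#' @param shape A [network_shape()].
#' @export
decode_weights <- function(v, shape) {
  stopifnot(inherits(shape, "network_shape"))
  if (length(v) != network_dimension(shape))
    stop(sprintf("weight vector has length %d, expected %d",
                 length(v), network_dimension(shape)))
  ni <- shape$n_input; nh <- shape$n_hidden; no <- shape$n_output
  i <- 0L
  W1 <- matrix(v[i + seq_len(ni * nh)], nrow = ni, ncol = nh, byrow = TRUE)
  i <- i + ni * nh
  b1 <- v[i + seq_len(nh)]; i <- i + nh
  W2 <- matrix(v[i + seq_len(nh * no)], nrow = nh, ncol = no, byrow = TRUE)
  i <- i + nh * no
  b2 <- v[i + seq_len(no)]
  network(W1, b1, W2, b2)
}

# Logistic sigmoid with the pre-activation clamped to +/-35: the widest
# symmetric range whose double-precision result stays strictly inside
# (0, 1); indistinguishable from the exact value at ordinary scales.
sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -35), 35)))

#' Forward pass
#'
#' Sigmoid activations in both the hidden and the output layer:
#' `sigmoid(sigmoid(X W1 + b1) W2 + b2)`.  Outputs lie strictly in (0, 1).
#'
#' @param net A [network()].
#' @param X `n x n_input` matrix of (standardized) predictors.
#' @return `n x n_output` matrix of scores in (0, 1).
#' @export
nn_forward <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(net$W1))
    stop(sprintf("input has %d columns, network expects %d",
                 ncol(X), nrow(net$W1)))
  if (!all(is.finite(X))) stop("non-finite values in input matrix")
  cpp_forward(net$W1, net$b1, net$W2, net$b2, X)
}

#' Mean squared error
#'
#' The training loss and GWO fitness of the workflow: the mean of squared
#' residuals between predicted scores and 0/1 labels.
#'
#' @param pred Numeric predictions.
#' @param labels Numeric labels of the same length.
#' @export
nn_mse <- function(pred, labels) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(labels)) stop("length mismatch")
  mean((as.numeric(pred) - as.numeric(labels))^2)
}

#' Analytic gradient of the training loss
#'
#' Gradient of the mean squared error with respect to every weight and
#' bias, as used by [backprop_train()]; exposed so it can be checked
#' against a finite-difference oracle.
#'
#' @param net A [network()].
#' @param X,y Training predictors and labels.
#' @return List with fields `W1`, `b1`, `W2`, `b2` matching the network.
#' @export
nn_gradient <- function(net, X, y) {
  X <- as.matrix(X)
  Y <- matrix(as.numeric(y), nrow = nrow(X))
  g <- cpp_gradient(net$W1, net$b1, net$W2, net$b2, X, Y)
  g$b1 <- as.numeric(g$b1); g$b2 <- as.numeric(g$b2)
  g
}

#' Training settings for gradient descent
#'
#' Descent stops at the error goal, at the epoch cap, or at practical
#' convergence: when the best training mse has improved by less than
#' `conv_tol` (relatively) over the last `conv_window` epochs.  The goal
#' of 1e-5 is far below the Bayes error of overlapping presence /
#' pseudo-absence classes, so the convergence rule is what normally ends
#' training.
#'
#' @param learning_rate Step size of full-batch gradient descent.
#' @param momentum Classical momentum coefficient on the update velocity;
#'   the default `0` is plain gradient descent.
#' @param goal Target training mse; optimization stops once reached.
#' @param max_epochs Epoch cap.
#' @param conv_tol Relative improvement below which training is considered
#'   converged; `0` disables the stagnation stop.
#' @param conv_window Number of epochs over which `conv_tol` is assessed.
#' @export
train_settings <- function(learning_rate = 0.01, momentum = 0,
                           goal = 1e-5, max_epochs = 5000L,
                           conv_tol = 1e-4, conv_window = 100L) {
  if (learning_rate <= 0) stop("'learning_rate' must be positive")
  if (momentum < 0 || momentum >= 1) stop("'momentum' must be in [0, 1)")
  if (goal <= 0) stop("'goal' must be positive")
  if (conv_tol < 0) stop("'conv_tol' must be non-negative")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 goal = goal,
                 max_epochs = as.integer(max_epochs),
                 conv_tol = conv_tol, conv_window = as.integer(conv_window)),
            class = "train_settings")
}

#' Train a network by backpropagation
#'
#' Full-batch gradient descent on the mean squared error, stopping when the
#' training mse reaches `settings$goal` or after `settings$max_epochs`
#' epochs.  The best network seen over the run is returned, so the training
#' error of the result never exceeds that of the input network.
#'
#' @param net Starting [network()] (random for the BPNN baseline, or the
#'   GWO alpha position for fine-tuning).
#' @param X,y Training predictors (matrix) and 0/1 labels.
#' @param settings A [train_settings()].
#' @return The trained network with attributes `epochs` and `train_mse`.
#' @export
backprop_train <- function(net, X, y, settings = train_settings()) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty training data")
  shape <- network_shape(nrow(net$W1), ncol(net$W1), ncol(net$W2))
  res <- cpp_backprop(encode_weights(net), X, as.numeric(y),
                      shape$n_input, shape$n_hidden, shape$n_output,
                      settings$learning_rate, settings$momentum,
                      settings$goal, settings$max_epochs,
                      settings$conv_tol, settings$conv_window)
  out <- decode_weights(as.numeric(res$weights), shape)
  attr(out, "epochs") <- res$epochs
  attr(out, "train_mse") <- res$train_mse
  out
}
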