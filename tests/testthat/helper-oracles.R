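# Independent oracles and small fixture builders used across the suite.

# Brute-force Mann-Whitney AUC: average over all positive-negative pairs,
# ties counted as one half.
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Exhaustive threshold scan for the TSS maximum over a dense grid plus all
# observed scores; returns the best TSS value found.
tss_scan_best <- function(labels, scores, grid_n = 1001) {
  cand <- sort(unique(c(seq(0, 1, length.out = grid_n), scores)))
  best <- -Inf
  for (th in cand) {
    cc <- confusion_counts(labels, scores, th)
    best <- max(best, true_skill(cc))
  }
  best
}

# Central finite-difference gradient of the training mse with respect to
# the flat weight vector.
fd_gradient <- function(v, shape, X, y, h = 1e-6) {
  vapply(seq_along(v), function(i) {
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    (nn_mse(nn_forward(decode_weights(vp, shape), X), y) -
       nn_mse(nn_forward(decode_weights(vm, shape), X), y)) / (2 * h)
  }, numeric(1))
}

# Random small labelled problem on standardized predictors.
random_problem <- function(n = 40, p = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.integer(runif(n) < plogis(X[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}

# Tiny fully-valid env stack for raster tests.
tiny_env <- function(n = 10, p = 2, seed = 1, cellsize = 0.1) {
  make_env_stack(n_rows = n, n_cols = n, p = p, seed = seed,
                 cellsize = cellsize)
}

# Constant-score model for degenerate-metric checks.
constant_model <- function(value = 0.5) {
  structure(list(value = value), class = "constant_model")
}
registerS3method("predict", "constant_model",
                 function(object, newdata, ...)
                   rep(object$value, nrow(as.matrix(newdata))),
                 envir = asNamespace("stats"))
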