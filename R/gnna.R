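#' GNNA configuration
#'
#' Defaults follow the workflow's stated settings: a pack of 20 wolves for
#' 100 iterations searching weights bounded in `[-1, 1]`, a hidden layer of
#' 5 units, learning rate 0.01 and training goal 1e-5 for the
#' backpropagation stage.
#'
#' @param n_hidden Hidden-layer size.
#' @param pop_size,max_iter,lower_bound,upper_bound GWO settings, see
#'   [gwo_config()].
#' @param learning_rate,momentum,goal,max_epochs,conv_tol,conv_window
#'   Backpropagation settings, see [train_settings()].
#' @param fine_tune Refine the GWO optimum by backpropagation (default
#'   `TRUE`); `FALSE` gives the pure-GWO variant.
#' @param fine_tune_epochs Epoch budget of the fine-tuning polish.  The
#'   global search has already placed the weights well, so this is much
#'   smaller than `max_epochs`, the budget of a from-scratch BPNN fit.
#' @param mode GWO offspring rule (see [offspring_position()]).  The
#'   pipeline defaults to `"canonical"`, the classic mean-of-candidates
#'   update: the `"original"` rule's extra contraction collapses the pack
#'   toward the zero network and stalls the search, so it is kept only as
#'   an explicit option.
#' @export
gnna_config <- function(n_hidden = 5L, pop_size = 20L, max_iter = 100L,
                        lower_bound = -1, upper_bound = 1,
                        learning_rate = 0.01, momentum = 0, goal = 1e-5,
                        max_epochs = 5000L, conv_tol = 1e-4,
                        conv_window = 100L, fine_tune = TRUE,
                        fine_tune_epochs = 1000L,
                        mode = c("canonical", "original")) {
  structure(list(n_hidden = as.integer(n_hidden),
                 pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 train = train_settings(learning_rate, momentum, goal,
                                        max_epochs, conv_tol, conv_window),
                 fine_tune = isTRUE(fine_tune),
                 fine_tune_epochs = as.integer(fine_tune_epochs),
                 mode = match.arg(mode)),
            class = "gnna_config")
}

# z-score standardizer fitted on training data; constant columns keep sd 1
# so they pass through unchanged.
fit_standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2L, std$center, "-"), 2L, std$scale, "/")
}

check_labels <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop("training data must contain both presences and absences")
  y
}

new_gnna_model <- function(net, std, variables, algorithm, seed, trace,
                           train_mse, test_mse, threshold = NULL) {
  structure(list(network = net, center = std$center, scale = std$scale,
                 variables = variables, algorithm = algorithm, seed = seed,
                 trace = trace, train_mse = train_mse, test_mse = test_mse,
                 threshold = threshold),
            class = "gnna_model")
}

#' Fit the GNNA hybrid model
#'
#' The Grey Wolf Optimizer searches the flattened weight/bias space of a
#' three-layer sigmoid network, minimizing the mean squared training error
#' of the decoded network; optionally the alpha position then seeds a
#' backpropagation fine-tuning stage.  Predictors are z-scored internally
#' using training-set statistics.  With `split_frac < 1` the data are first
#' split (stratified by class) into a training portion used for the fitness
#' and a held-out portion scored as the test error; `split_frac = 1` trains
#' on everything (used inside [evaluate_repeated()], whose own 80/20 split
#' then plays that role).
#'
#' @param x Predictor matrix or data frame.
#' @param y 0/1 labels (1 = presence).
#' @param config A [gnna_config()].
#' @param seed Integer seed fixing every random draw; `NULL` uses the
#'   current RNG state.
#' @param split_frac Training fraction of the internal split (default 0.8,
#'   the 4:1 train:test design).
#' @return A `gnna_model` with the fitted [network()], the standardizer,
#'   the GWO convergence trace and the recorded training/test errors.
#' @export
fit_gnna <- function(x, y, config = gnna_config(), seed = NULL,
                     split_frac = 0.8) {
  x <- as.matrix(x)
  y <- check_labels(y)
  if (!is.null(seed)) set.seed(seed)
  if (split_frac < 1) {
    sp <- stratified_split(y, split_frac)
    x_tr <- x[sp$train, , drop = FALSE]; y_tr <- y[sp$train]
    x_te <- x[sp$test, , drop = FALSE]; y_te <- y[sp$test]
  } else {
    x_tr <- x; y_tr <- y; x_te <- NULL
  }
  std <- fit_standardizer(x_tr)
  z_tr <- apply_standardizer(std, x_tr)
  shape <- network_shape(ncol(x), config$n_hidden, 1L)
  y_num <- as.numeric(y_tr)
  fitness <- function(v) cpp_mse_fitness(v, z_tr, y_num, shape$n_input,
                                         shape$n_hidden, shape$n_output)
  fitness_batch <- function(V) cpp_mse_fitness_batch(V, z_tr, y_num,
                                                     shape$n_input,
                                                     shape$n_hidden,
                                                     shape$n_output)
  gcfg <- gwo_config(dim = network_dimension(shape),
                     pop_size = config$pop_size, max_iter = config$max_iter,
                     lower_bound = config$lower_bound,
                     upper_bound = config$upper_bound)
  res <- gwo_optimize(gcfg, fitness, mode = config$mode,
                      f_batch = fitness_batch)
  net <- decode_weights(res$best_position, shape)
  if (config$fine_tune) {
    polish <- config$train
    polish$max_epochs <- min(config$fine_tune_epochs, config$train$max_epochs)
    net <- backprop_train(net, z_tr, y_tr, polish)
  }
  train_mse <- nn_mse(nn_forward(net, z_tr), y_tr)
  test_mse <- if (is.null(x_te)) NA_real_ else
    nn_mse(nn_forward(net, apply_standardizer(std, x_te)), y_te)
  new_gnna_model(net, std, colnames(x), "GNNA", seed, res$trace,
                 train_mse, test_mse)
}

#' Fit the plain backpropagation baseline (BPNN)
#'
#' Same architecture, standardization and split protocol as [fit_gnna()],
#' but the weights start uniformly in `[-1, 1]` and are trained by
#' backpropagation alone — the baseline whose sensitivity to initial
#' weights the GWO search is designed to remove.
#'
#' @inheritParams fit_gnna
#' @export
fit_bpnn <- function(x, y, config = gnna_config(), seed = NULL,
                     split_frac = 0.8) {
  x <- as.matrix(x)
  y <- check_labels(y)
  if (!is.null(seed)) set.seed(seed)
  if (split_frac < 1) {
    sp <- stratified_split(y, split_frac)
    x_tr <- x[sp$train, , drop = FALSE]; y_tr <- y[sp$train]
    x_te <- x[sp$test, , drop = FALSE]; y_te <- y[sp$test]
  } else {
    x_tr <- x; y_tr <- y; x_te <- NULL
  }
  std <- fit_standardizer(x_tr)
  z_tr <- apply_standardizer(std, x_tr)
  shape <- network_shape(ncol(x), config$n_hidden, 1L)
  v0 <- stats::runif(network_dimension(shape), -1, 1)
  net <- backprop_train(decode_weights(v0, shape), z_tr, y_tr, config$train)
  train_mse <- nn_mse(nn_forward(net, z_tr), y_tr)
  test_mse <- if (is.null(x_te)) NA_real_ else
    nn_mse(nn_forward(net, apply_standardizer(std, x_te)), y_te)
  new_gnna_model(net, std, colnames(x), "BPNN", seed, numeric(0),
                 train_mse, test_mse)
}

#' Predict habitat suitability
#'
#' Applies the stored standardization and the forward pass; deterministic.
#'
#' @param object A `gnna_model`.
#' @param newdata Predictor matrix or data frame; when column names are
#'   present they must include every training variable (extra columns are
#'   ignored, order-free).
#' @param ... Unused.
#' @return Numeric vector of suitability scores in (0, 1).
#' @export
predict.gnna_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$variables) && !is.null(colnames(x))) {
    missing_vars <- setdiff(object$variables, colnames(x))
    if (length(missing_vars) > 0L)
      stop(sprintf("missing predictor variable(s): %s",
                   paste(missing_vars, collapse = ", ")))
    x <- x[, object$variables, drop = FALSE]
  }
  if (ncol(x) != length(object$center))
    stop(sprintf("newdata has %d columns, model expects %d",
                 ncol(x), length(object$center)))
  z <- apply_standardizer(list(center = object$center, scale = object$scale), x)
  as.numeric(nn_forward(object$network, z))
}

#' @export
print.gnna_model <- function(x, ...) {
  cat(sprintf("%s model: %d -> %d -> %d network\n", x$algorithm,
              nrow(x$network$W1), ncol(x$network$W1), ncol(x$network$W2)))
  cat(sprintf("training mse %.6g", x$train_mse))
  if (!is.na(x$test_mse)) cat(sprintf(", test mse %.6g", x$test_mse))
  cat("\n")
  invisible(x)
}

#' Save / load a fitted model as JSON
#'
#' The file stores the network shape, standardization constants, the flat
#' weight vector and the provenance block (algorithm, seed, trace, errors)
#' at full double precision, so a save/load round trip reproduces
#' predictions bit-exactly.
#'
#' @param model A `gnna_model`.
#' @param path JSON file path.
#' @export
save_model <- function(model, path) {
  shape <- list(n_input = nrow(model$network$W1),
                n_hidden = ncol(model$network$W1),
                n_output = ncol(model$network$W2))
  obj <- list(shape = shape,
              weights = encode_weights(model$network),
              center = as.list(model$center), scale = as.list(model$scale),
              variables = model$variables, algorithm = model$algorithm,
              seed = model$seed, trace = model$trace,
              train_mse = model$train_mse, test_mse = model$test_mse,
              threshold = model$threshold)
  # I(17) = 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @param path JSON file path.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- network_shape(obj$shape$n_input, obj$shape$n_hidden,
                         obj$shape$n_output)
  net <- decode_weights(as.numeric(obj$weights), shape)
  std <- list(center = unlist(obj$center), scale = unlist(obj$scale))
  new_gnna_model(net, std, obj$variables, obj$algorithm,
                 if (is.null(obj$seed)) NULL else as.integer(obj$seed),
                 as.numeric(obj$trace), obj$train_mse,
                 if (is.null(obj$test_mse)) NA_real_ else obj$test_mse,
                 obj$threshold)
}

#' Model factories for the repeated-split protocol
#'
#' Closures suitable as the `fit` argument of [evaluate_repeated()]: each
#' fits on the full training portion it receives (the protocol's 80/20
#' split is the only split) with a fresh model per call.
#'
#' @param config A [gnna_config()].
#' @return `function(x, y)` returning a `gnna_model`.
#' @export
gnna_factory <- function(config = gnna_config()) {
  function(x, y) fit_gnna(x, y, config = config, split_frac = 1)
}

#' @rdname gnna_factory
#' @export
bpnn_factory <- function(config = gnna_config()) {
  function(x, y) fit_bpnn(x, y, config = config, split_frac = 1)
}

#' Predict a suitability raster
#'
#' Runs the model over every valid cell of a stack and writes the result
#' as an ASCII grid; no-data cells are preserved.  When a classification
#' threshold is available a companion binary (0/1) map can be written.
#'
#' @param model A `gnna_model`; its variables must all be layers of `env`.
#' @param env An [env_stack()].
#' @param path Output `.asc` path for the continuous suitability map.
#' @param binary_path Optional `.asc` path for the thresholded 0/1 map.
#' @param threshold Cutoff for the binary map; defaults to the threshold
#'   stored in the model (e.g. the TSS-maximizing one).
#' @return Invisibly, the suitability matrix.
#' @export
write_prediction <- function(model, env, path, binary_path = NULL,
                             threshold = model$threshold) {
  stopifnot(inherits(env, "env_stack"))
  missing_layers <- setdiff(model$variables, names(env$layers))
  if (length(missing_layers) > 0L)
    stop(sprintf("missing layer(s): %s", paste(missing_layers, collapse = ", ")))
  suit <- predict_raster(model, env)
  write_ascii_grid(suit, path, xll = env$xll, yll = env$yll,
                   cellsize = env$cellsize)
  if (!is.null(binary_path)) {
    if (is.null(threshold))
      stop("no threshold available for the binary map")
    write_ascii_grid((suit >= threshold) * 1, binary_path, xll = env$xll,
                     yll = env$yll, cellsize = env$cellsize)
  }
  invisible(suit)
}

#' Suitability matrix over a stack (in memory)
#'
#' @inheritParams write_prediction
#' @return Matrix of suitability values with `NA` at no-data cells.
#' @export
predict_raster <- function(model, env) {
  vars <- if (is.null(model$variables)) names(env$layers) else model$variables
  mask <- env_valid_mask(env)
  X <- sapply(vars, function(v) env$layers[[v]][mask])
  X <- matrix(X, ncol = length(vars), dimnames = list(NULL, vars))
  out <- matrix(NA_real_, env$n_rows, env$n_cols)
  out[mask] <- predict(model, X)
  out
}
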