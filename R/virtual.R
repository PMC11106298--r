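#' Simulate a smooth environmental raster stack
#'
#' Each layer is a low-frequency random field built as a sum of Gaussian
#' bumps with random centres, widths and signed amplitudes, then
#' standardized to mean 0 and standard deviation 1 over the grid.  Layers
#' are smooth (strong neighbouring-cell correlation) like interpolated
#' bioclimatic surfaces, which is all the model-validation workflow needs;
#' they carry no realistic climate covariance.
#'
#' @param n_rows,n_cols Grid size.
#' @param p Number of layers; names `env1..envp`.
#' @param n_bumps Gaussian bumps per layer.
#' @param smoothness Bump width as a fraction of the grid extent; larger is
#'   smoother.
#' @param seed Optional integer seed.
#' @param xll,yll,cellsize Georeferencing of the grid, in degrees.
#' @return An [env_stack()] with no missing cells.
#' @export
make_env_stack <- function(n_rows = 100L, n_cols = 100L, p = 5L,
                           n_bumps = 30L, smoothness = 0.12, seed = NULL,
                           xll = 0, yll = 0, cellsize = 0.05) {
  if (n_rows < 1L || n_cols < 1L || p < 1L) stop("dimensions must be positive")
  if (!is.null(seed)) set.seed(seed)
  u <- (seq_len(n_cols) - 0.5) / n_cols   # unit-square coordinates
  v <- (seq_len(n_rows) - 0.5) / n_rows
  layers <- stats::setNames(vector("list", p), paste0("env", seq_len(p)))
  for (j in seq_len(p)) {
    m <- matrix(0, n_rows, n_cols)
    for (b in seq_len(n_bumps)) {
      cx <- stats::runif(1); cy <- stats::runif(1)
      amp <- stats::rnorm(1)
      w <- smoothness * stats::runif(1, 0.5, 1.5)
      m <- m + amp * outer(exp(-(v - cy)^2 / (2 * w^2)),
                           exp(-(u - cx)^2 / (2 * w^2)))
    }
    layers[[j]] <- (m - mean(m)) / stats::sd(m)
  }
  env_stack(layers, xll = xll, yll = yll, cellsize = cellsize)
}

#' Virtual species specification
#'
#' Defines the true niche as a logit-linear (optionally quadratic) function
#' of the standardized layers: suitability is
#' `sigmoid(b0 + sum(beta * z) + sum(gamma * z^2))` per cell.  The default
#' is the strong-signal species used for validation: coefficients
#' `(2, -2, 2, 0, 0)` on five layers with intercept -6 — a restricted-range
#' species suitable over roughly 5-10 percent of the landscape, the regime
#' real SDM studies operate in — 200 presences and three pseudo-absences
#' per presence.
#'
#' @param beta Linear coefficients, one per layer.
#' @param gamma Optional quadratic coefficients (default all zero).
#' @param b0 Intercept of the logit suitability.
#' @param n_presence Number of presence points to sample.
#' @param pa_ratio Pseudo-absences per presence.
#' @export
virtual_species_spec <- function(beta = c(2, -2, 2, 0, 0), gamma = NULL,
                                 b0 = -6, n_presence = 200L, pa_ratio = 3L) {
  if (all(beta == 0) && (is.null(gamma) || all(gamma == 0)))
    stop("at least one nonzero coefficient is required")
  structure(list(beta = as.numeric(beta),
                 gamma = if (is.null(gamma)) rep(0, length(beta))
                         else as.numeric(gamma),
                 b0 = b0, n_presence = as.integer(n_presence),
                 pa_ratio = as.integer(pa_ratio)),
            class = "virtual_species_spec")
}

#' True suitability raster of a virtual species
#'
#' @param env An [env_stack()].
#' @param spec A [virtual_species_spec()]; coefficient lengths must match
#'   the number of layers.
#' @return Matrix of suitabilities in (0, 1), `NA` on no-data cells.
#' @export
true_suitability <- function(env, spec) {
  stopifnot(inherits(env, "env_stack"), inherits(spec, "virtual_species_spec"))
  if (length(spec$beta) != length(env$layers))
    stop(sprintf("spec has %d coefficients but the stack has %d layers",
                 length(spec$beta), length(env$layers)))
  logit <- matrix(spec$b0, env$n_rows, env$n_cols)
  for (j in seq_along(env$layers)) {
    z <- env$layers[[j]]
    logit <- logit + spec$beta[j] * z + spec$gamma[j] * z^2
  }
  sigmoid(logit)
}

#' Sample presence points proportionally to suitability
#'
#' Cells are drawn without replacement with probability proportional to
#' their suitability (a probabilistic virtual species), and returned as
#' their cell-centre coordinates.  Zero-suitability and no-data cells are
#' never sampled.
#'
#' @param suit Suitability matrix (e.g. from [true_suitability()]).
#' @param env The [env_stack()] providing the georeferencing.
#' @param n Number of presences; must not exceed the positive-suitability
#'   cell count.
#' @param seed Optional integer seed.
#' @param species Species name for the output table.
#' @export
sample_presences <- function(suit, env, n, seed = NULL,
                             species = "virtual species") {
  if (!is.null(seed)) set.seed(seed)
  ok <- which(!is.na(suit) & suit > 0)
  if (n > length(ok))
    stop(sprintf("cannot sample %d presences from %d positive-suitability cells",
                 n, length(ok)))
  cells <- if (length(ok) == 1L) ok else sample(ok, n, prob = suit[ok])
  xy <- lonlat_from_cell(env, cells)
  occurrence_table(species, xy[, 1L], xy[, 2L])
}

#' Generate a labelled dataset with known ground truth
#'
#' End-to-end simulation of the presence / 3x pseudo-absence design:
#' presences are sampled from the true suitability, pseudo-absences
#' uniformly from the remaining valid cells, and each point is associated
#' with its cell's layer values.
#'
#' @param spec A [virtual_species_spec()].
#' @param env An [env_stack()].
#' @param seed Optional integer seed covering both sampling stages.
#' @return List with `x` (predictor matrix), `y` (0/1 labels), `truth`
#'   (suitability matrix), `presences` and `absences` (occurrence tables).
#' @export
make_dataset <- function(spec, env, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- true_suitability(env, spec)
  pres <- sample_presences(truth, env, spec$n_presence)
  abs_ <- sample_pseudo_absences(env, pres, ratio = spec$pa_ratio)
  pts <- rbind(pres, abs_)
  ex <- extract_env(env, pts)
  if (length(ex$kept) != nrow(pts))
    stop("internal error: simulated points fell outside the stack")
  y <- c(rep(1L, nrow(pres)), rep(0L, nrow(abs_)))
  list(x = as.matrix(ex$values), y = y, truth = truth,
       presences = pres, absences = abs_)
}

#' Write a labelled dataset as CSV
#'
#' One column per predictor plus a 0/1 `presence` column; the inverse of
#' [read_dataset()].
#'
#' @param ds List with `x` and `y` as produced by [make_dataset()].
#' @param path Output CSV path.
#' @export
write_dataset <- function(ds, path) {
  df <- as.data.frame(ds$x)
  df$presence <- as.integer(ds$y)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("dataset file not found: %s", path))
  df <- utils::read.csv(path)
  if (!"presence" %in% names(df))
    stop("dataset CSV must have a 'presence' column")
  y <- as.integer(df$presence)
  x <- as.matrix(df[, setdiff(names(df), "presence"), drop = FALSE])
  list(x = x, y = y)
}
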