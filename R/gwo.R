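#' Grey Wolf Optimizer configuration
#'
#' Bundles the search hyper-parameters of the Grey Wolf Optimizer (GWO):
#' pack size, iteration cap, box bounds and problem dimensionality.  The
#' defaults (20 wolves, 100 iterations, bounds \eqn{\pm 1}) are the settings
#' used throughout the GNNA species-distribution workflow.
#'
#' @param dim Positive integer, dimensionality of a wolf position vector.
#' @param pop_size Number of wolves; must be at least 4 so that the three
#'   leaders (alpha, beta, delta) leave at least one omega wolf.
#' @param max_iter Non-negative integer iteration cap.
#' @param lower_bound,upper_bound Per-component box constraints on positions.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return An object of class `gwo_config`.
#' @export
gwo_config <- function(dim, pop_size = 20L, max_iter = 100L,
                       lower_bound = -1, upper_bound = 1, seed = NULL) {
  dim <- as.integer(dim)
  pop_size <- as.integer(pop_size)
  max_iter <- as.integer(max_iter)
  if (is.na(dim) || dim < 1L) stop("'dim' must be a positive integer")
  if (is.na(pop_size) || pop_size < 4L)
    stop("'pop_size' must be at least 4 (alpha, beta, delta plus one omega wolf)")
  if (is.na(max_iter) || max_iter < 0L) stop("'max_iter' must be >= 0")
  if (!is.finite(lower_bound) || !is.finite(upper_bound) ||
      lower_bound >= upper_bound)
    stop("'lower_bound' must be strictly less than 'upper_bound'")
  structure(list(dim = dim, pop_size = pop_size, max_iter = max_iter,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "gwo_config")
}

#' Exploration coefficient schedule
#'
#' The scalar \eqn{a(t)} decays linearly from 2 at the first iteration to 0
#' at the last, shrinking the convergence vectors `A` and moving the pack
#' from exploration to exploitation.
#'
#' @param t Iteration index in `[0, max_iter]`.
#' @param max_iter Total iteration count, at least 1.
#' @return `2 * (1 - t / max_iter)`, exact at the endpoints.
#' @export
#' @examples
#' coefficient_a(0, 100)    # 2
#' coefficient_a(100, 100)  # 0
coefficient_a <- function(t, max_iter) {
  if (max_iter < 1) stop("'max_iter' must be >= 1")
  if (t < 0 || t > max_iter) stop("'t' must lie in [0, max_iter]")
  2 * (1 - t / max_iter)
}

#' Draw the stochastic GWO coefficient vectors
#'
#' Draws the attraction vector `C = 2 r1` (components in `[0, 2]`) and the
#' convergence vector `A = 2 a r2 - a` (components in `[-a, a]`), with fresh
#' uniform draws per call.
#'
#' @param dim Vector length.
#' @param a Current value of the decay schedule, from [coefficient_a()].
#' @return List with components `C`, `A` and `a`.
#' @export
random_coefficients <- function(dim, a) {
  list(C = 2 * stats::runif(dim),
       A = 2 * a * stats::runif(dim) - a,
       a = a)
}

#' Distance of a wolf from a leader
#'
#' Componentwise `|C * X_p - X|`: the perturbed distance between a wolf at
#' `X` and the leader (prey estimate) at `X_p`.
#'
#' @param C Attraction coefficient vector.
#' @param X_p Leader position.
#' @param X Wolf position.
#' @return Non-negative vector of the common length.
#' @export
leader_distance <- function(C, X_p, X) {
  if (length(C) != length(X_p) || length(X_p) != length(X))
    stop("'C', 'X_p' and 'X' must have equal length")
  abs(C * X_p - X)
}

#' Candidate position induced by one leader
#'
#' `X_p - A * D_p`: the wolf steps around the leader, repelled or attracted
#' according to the sign and magnitude of the convergence vector `A`.
#'
#' @param X_p Leader position.
#' @param A Convergence coefficient vector.
#' @param D_p Distance vector from [leader_distance()].
#' @export
candidate_position <- function(X_p, A, D_p) {
  if (length(X_p) != length(A) || length(A) != length(D_p))
    stop("'X_p', 'A' and 'D_p' must have equal length")
  X_p - A * D_p
}

#' Norm weights of the three leader candidates
#'
#' Each candidate position is weighted by its Euclidean norm relative to the
#' total: `w_i = ||X_i|| / sum_j ||X_j||`.  When all three candidates sit at
#' the origin the weights are undefined; equal weights of 1/3 are returned
#' with a message.
#'
#' @param X1,X2,X3 Candidate positions from the alpha, beta and delta leaders.
#' @return Numeric weight vector of length 3 summing to 1.
#' @export
omega_weights <- function(X1, X2, X3) {
  norms <- c(sqrt(sum(X1^2)), sqrt(sum(X2^2)), sqrt(sum(X3^2)))
  total <- sum(norms)
  if (total == 0) {
    message("all candidate norms are zero; falling back to equal weights")
    return(rep(1 / 3, 3))
  }
  norms / total
}

#' Offspring position of an omega wolf
#'
#' Combines the three leader-induced candidates.  In `"original"` mode the
#' update is the norm-weighted sum divided by 3,
#' `(w1 X1 + w2 X2 + w3 X3) / 3`; because the weights sum to one this
#' contracts offspring toward the origin by a factor of three.  In
#' `"canonical"` mode the weights are dropped and the update is the plain
#' mean `(X1 + X2 + X3) / 3` of classic GWO.
#'
#' @param X1,X2,X3 Candidate positions.
#' @param w Weight vector from [omega_weights()]; ignored in canonical mode.
#' @param mode `"original"` (default) or `"canonical"`.
#' @export
offspring_position <- function(X1, X2, X3, w = omega_weights(X1, X2, X3),
                               mode = c("original", "canonical")) {
  mode <- match.arg(mode)
  if (mode == "original") (w[1] * X1 + w[2] * X2 + w[3] * X3) / 3
  else (X1 + X2 + X3) / 3
}

# Evaluate a fitness function defensively: non-finite values become +Inf so
# a pathological wolf can never be selected as a leader.
eval_fitness <- function(f, x) {
  val <- f(x)
  if (!is.numeric(val) || length(val) != 1L) stop("fitness must return a single number")
  if (!is.finite(val)) {
    message("non-finite fitness treated as +Inf")
    val <- Inf
  }
  val
}

#' Initialize a GWO search state
#'
#' Positions are drawn uniformly inside the box; fitnesses are evaluated and
#' the three best wolves become the alpha, beta and delta leaders.
#'
#' @param config A [gwo_config()].
#' @param f Fitness function: numeric vector of length `dim` to scalar cost
#'   (lower is better).
#' @param f_batch Optional vectorized form of `f`: a function taking an
#'   `m x dim` matrix of positions and returning `m` costs in one call.
#'   Results must agree with `f`; used purely to cut call overhead.
#' @return A `gwo_state` list with `positions`, `fitnesses`, `leaders`
#'   (3 x dim matrix, best first), `leader_fitnesses`, `iteration` and
#'   `a_value`.
#' @export
gwo_init <- function(config, f, f_batch = NULL) {
  stopifnot(inherits(config, "gwo_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pos <- matrix(stats::runif(config$pop_size * config$dim,
                             config$lower_bound, config$upper_bound),
                nrow = config$pop_size, ncol = config$dim)
  fit <- eval_fitness_all(f, f_batch, pos)
  state <- list(positions = pos, fitnesses = fit,
                iteration = 0L, a_value = 2)
  refresh_leaders(state)
}

# Evaluate fitness for every row of a position matrix, through the batch
# evaluator when one is supplied; non-finite values become +Inf either way.
eval_fitness_all <- function(f, f_batch, pos) {
  if (is.null(f_batch))
    return(apply(pos, 1L, function(x) eval_fitness(f, x)))
  val <- f_batch(pos)
  bad <- !is.finite(val)
  if (any(bad)) {
    message("non-finite fitness treated as +Inf")
    val[bad] <- Inf
  }
  val
}

# Re-select alpha/beta/delta as the three best wolves; stable order by index
# breaks fitness ties deterministically.
refresh_leaders <- function(state) {
  ord <- order(state$fitnesses)[1:3]
  state$leaders <- state$positions[ord, , drop = FALSE]
  state$leader_fitnesses <- state$fitnesses[ord]
  state$leader_index <- ord
  class(state) <- "gwo_state"
  state
}

#' Advance a GWO state by one iteration
#'
#' Each non-leader (omega) wolf is replaced by its offspring: three
#' candidates are generated from the alpha, beta and delta leaders with
#' fresh `A` and `C` draws, combined by [offspring_position()], clipped to
#' the box, and re-evaluated.  Leaders are retained unchanged within the
#' iteration (elitism) and re-selected from the whole pack afterwards, so
#' the best fitness in the pack never increases.
#'
#' @inheritParams gwo_init
#' @param state A `gwo_state` from [gwo_init()] or a previous step.
#' @param mode Offspring rule, see [offspring_position()].
#' @export
gwo_step <- function(state, f, config, mode = c("original", "canonical"),
                     f_batch = NULL) {
  mode <- match.arg(mode)
  if (state$iteration >= config$max_iter)
    stop("iteration cap already reached")
  a <- coefficient_a(state$iteration, config$max_iter)
  state$a_value <- a
  omega_idx <- setdiff(seq_len(config$pop_size), state$leader_index)
  n_om <- length(omega_idx)
  Xo <- state$positions[omega_idx, , drop = FALSE]
  # Vectorized leader updates: one C/A draw per component, per omega wolf,
  # per leader (fresh independent draws), matching the scalar ops
  # leader_distance() / candidate_position() componentwise.
  cand <- vector("list", 3L)
  for (p in 1:3) {
    C <- matrix(2 * stats::runif(n_om * config$dim), n_om, config$dim)
    A <- matrix(2 * a * stats::runif(n_om * config$dim) - a, n_om, config$dim)
    Xp <- matrix(state$leaders[p, ], n_om, config$dim, byrow = TRUE)
    D <- abs(C * Xp - Xo)
    cand[[p]] <- Xp - A * D
  }
  if (mode == "original") {
    norms <- vapply(cand, function(m) sqrt(rowSums(m^2)), numeric(n_om))
    norms <- matrix(norms, nrow = n_om)
    tot <- rowSums(norms)
    w <- norms / ifelse(tot == 0, 1, tot)
    w[tot == 0, ] <- 1 / 3
    off <- (w[, 1L] * cand[[1L]] + w[, 2L] * cand[[2L]] +
              w[, 3L] * cand[[3L]]) / 3
  } else {
    off <- (cand[[1L]] + cand[[2L]] + cand[[3L]]) / 3
  }
  off <- pmin(pmax(off, config$lower_bound), config$upper_bound)
  state$positions[omega_idx, ] <- off
  state$fitnesses[omega_idx] <- eval_fitness_all(f, f_batch, off)
  state$iteration <- state$iteration + 1L
  refresh_leaders(state)
}

#' Run the Grey Wolf Optimizer
#'
#' Initializes a pack and iterates [gwo_step()] until the iteration cap,
#' tracking the best-so-far (alpha) fitness.  Fully reproducible when
#' `config$seed` is set.
#'
#' @inheritParams gwo_step
#' @param config A [gwo_config()].
#' @param f Fitness function (lower is better).
#' @return A `gwo_result` list: `best_position` (final alpha),
#'   `best_fitness`, and `trace`, the best-so-far fitness after each
#'   iteration (length `max_iter`; non-increasing).
#' @export
#' @examples
#' cfg <- gwo_config(dim = 2, pop_size = 10, max_iter = 25, seed = 1)
#' res <- gwo_optimize(cfg, function(x) sum(x^2))
#' res$best_fitness
gwo_optimize <- function(config, f, mode = c("original", "canonical"),
                         f_batch = NULL) {
  mode <- match.arg(mode)
  state <- gwo_init(config, f, f_batch = f_batch)
  trace <- numeric(config$max_iter)
  best <- state$leader_fitnesses[1]
  best_pos <- state$leaders[1, ]
  if (config$max_iter > 0L) {
    for (t in seq_len(config$max_iter)) {
      state <- gwo_step(state, f, config, mode = mode, f_batch = f_batch)
      if (state$leader_fitnesses[1] <= best) {
        best <- state$leader_fitnesses[1]
        best_pos <- state$leaders[1, ]
      }
      trace[t] <- best
    }
  }
  structure(list(best_position = best_pos, best_fitness = best,
                 trace = trace, mode = mode),
            class = "gwo_result")
}

#' Export a convergence trace as CSV
#'
#' @param result A `gwo_result`.
#' @param path Output CSV path with columns `iteration`, `best_fitness`.
#' @export
write_trace <- function(result, path) {
  utils::write.csv(data.frame(iteration = seq_along(result$trace),
                              best_fitness = result$trace),
                   path, row.names = FALSE)
  invisible(path)
}
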