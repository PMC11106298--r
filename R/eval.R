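#' Build an occurrence table
#'
#' @param species Character vector of species names (recycled if length 1).
#' @param longitude,latitude Coordinates in decimal degrees.
#' @return A `data.frame` with columns `species`, `longitude`, `latitude`.
#' @export
occurrence_table <- function(species, longitude, latitude) {
  longitude <- as.numeric(longitude); latitude <- as.numeric(latitude)
  if (any(!is.finite(longitude)) || any(!is.finite(latitude)))
    stop("non-finite coordinates")
  if (any(longitude < -180 | longitude > 180))
    stop("longitude outside [-180, 180]")
  if (any(latitude < -90 | latitude > 90))
    stop("latitude outside [-90, 90]")
  data.frame(species = as.character(species), longitude = longitude,
             latitude = latitude, stringsAsFactors = FALSE)
}

#' Spatially thin occurrence records
#'
#' Removes duplicate records within a radius: a single greedy pass in input
#' order keeps a record iff its great-circle (haversine) distance to every
#' previously kept record exceeds `radius_km`.  Any two kept records are
#' therefore more than `radius_km` apart, and thinning is idempotent.
#'
#' @param occ An occurrence `data.frame` with `longitude` and `latitude`
#'   columns in degrees.
#' @param radius_km Thinning radius in kilometres (default 5).
#' @return The kept subset of `occ`, original row order preserved.
#' @export
thin_occurrences <- function(occ, radius_km = 5) {
  n <- nrow(occ)
  if (n <= 1L) return(occ)
  pts <- as.matrix(occ[, c("longitude", "latitude")])
  keep <- logical(n)
  keep[1L] <- TRUE
  for (i in 2:n) {
    kept <- pts[keep, , drop = FALSE]
    d <- geosphere::distHaversine(pts[i, , drop = FALSE], kept)
    keep[i] <- all(d > radius_km * 1000)
  }
  occ[keep, , drop = FALSE]
}

#' Sample pseudo-absence points from a raster stack
#'
#' Draws cells uniformly without replacement from the valid (non-missing)
#' cells of the stack, excluding any cell containing a presence record, and
#' returns their cell-centre coordinates.  The number of pseudo-absences is
#' `ratio` times the number of presences — the 3x design used throughout
#' the workflow.
#'
#' @param env An [env_stack()].
#' @param presences Occurrence `data.frame` of presence records.
#' @param ratio Pseudo-absences per presence (default 3).
#' @param seed Optional integer seed for reproducibility.
#' @return An occurrence table of pseudo-absence points with species
#'   `"pseudo-absence"`.
#' @export
sample_pseudo_absences <- function(env, presences, ratio = 3L, seed = NULL) {
  stopifnot(inherits(env, "env_stack"))
  if (!is.null(seed)) set.seed(seed)
  n_abs <- as.integer(ratio) * nrow(presences)
  valid <- which(env_valid_mask(env))
  pres_cells <- cell_from_lonlat(env, presences$longitude, presences$latitude)
  eligible <- setdiff(valid, pres_cells[!is.na(pres_cells)])
  if (length(eligible) < n_abs)
    stop(sprintf("only %d eligible cells for %d pseudo-absences",
                 length(eligible), n_abs))
  cells <- sample(eligible, n_abs, replace = FALSE)
  xy <- lonlat_from_cell(env, cells)
  occurrence_table("pseudo-absence", xy[, 1L], xy[, 2L])
}

#' Screen predictors by pairwise Pearson correlation
#'
#' Greedy collinearity filter: while any pair of variables has
#' `|r| >= r_max`, the member of the most-correlated pair with the larger
#' mean absolute correlation to all remaining variables is dropped.  All
#' surviving pairs satisfy `|r| < r_max`.
#'
#' @param X Numeric predictor matrix or data frame.
#' @param names Variable names; defaults to column names of `X`.
#' @param r_max Correlation cutoff (default 0.7).
#' @return Character vector of kept variable names.
#' @export
select_variables <- function(X, names = colnames(X), r_max = 0.7) {
  X <- as.matrix(X)
  if (is.null(names)) names <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant column: %s",
                 paste(names[sds == 0], collapse = ", ")))
  keep <- seq_len(ncol(X))
  repeat {
    if (length(keep) < 2L) break
    r <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) < r_max) break
    worst <- which(r == max(r), arr.ind = TRUE)[1L, ]
    mean_r <- rowMeans(r)
    drop_local <- if (mean_r[worst[1L]] >= mean_r[worst[2L]])
      worst[1L] else worst[2L]
    keep <- keep[-drop_local]
  }
  names[keep]
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation via mid-ranks: the probability that a randomly
#' chosen presence scores above a randomly chosen absence, counting ties as
#' one half.  Identical to the trapezoidal ROC area.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Numeric scores of the same length.
#' @export
#' @examples
#' roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))  # 1
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a threshold
#'
#' A score greater than or equal to the threshold predicts presence (ties
#' inclusive).
#'
#' @inheritParams roc_auc
#' @param threshold Classification cutoff in `[0, 1]`.
#' @return List with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(labels, scores, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  list(tp = sum(pred == 1L & labels == 1L),
       fp = sum(pred == 1L & labels == 0L),
       tn = sum(pred == 0L & labels == 0L),
       fn = sum(pred == 0L & labels == 1L))
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with observed
#' agreement `p_o = (tp + tn) / n` and chance agreement
#' `p_e = ((tp+fp)(tp+fn) + (tn+fn)(tn+fp)) / n^2`.  Returns 0 when
#' `p_e = 1`.
#'
#' @param cc Confusion counts from [confusion_counts()].
#' @export
cohen_kappa <- function(cc) {
  n <- cc$tp + cc$fp + cc$tn + cc$fn
  if (n == 0L) stop("empty confusion table")
  po <- (cc$tp + cc$tn) / n
  pe <- ((cc$tp + cc$fp) * (cc$tp + cc$fn) +
           (cc$tn + cc$fn) * (cc$tn + cc$fp)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' True skill statistic from confusion counts
#'
#' Sensitivity + specificity - 1.
#'
#' @param cc Confusion counts from [confusion_counts()].
#' @export
true_skill <- function(cc) {
  if (cc$tp + cc$fn == 0L || cc$tn + cc$fp == 0L)
    stop("both observed classes required for TSS")
  cc$tp / (cc$tp + cc$fn) + cc$tn / (cc$tn + cc$fp) - 1
}

#' TSS-maximizing threshold and metric set
#'
#' Evaluates the true skill statistic at every distinct score (plus 0 and 1)
#' as a candidate threshold and returns the maximizer — the standard rule
#' for binarizing continuous suitability.  Ties go to the lowest candidate.
#'
#' @inheritParams roc_auc
#' @return List with `threshold` and `metrics`, the latter holding `auc`,
#'   `kappa`, `tss` and `threshold` for this labelled score set.
#' @export
tss_max_threshold <- function(labels, scores) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("both classes must be present")
  cand <- sort(unique(c(0, 1, scores)))
  tss_vals <- vapply(cand, function(th)
    true_skill(confusion_counts(labels, scores, th)), numeric(1))
  best <- cand[which.max(tss_vals)]  # which.max returns first (lowest) tie
  cc <- confusion_counts(labels, scores, best)
  list(threshold = best,
       metrics = list(auc = roc_auc(labels, scores),
                      kappa = cohen_kappa(cc),
                      tss = true_skill(cc),
                      threshold = best))
}

# Stratified train/test split of indices: samples train_frac within each
# class.  Returns list(train, test).
stratified_split <- function(y, train_frac) {
  idx1 <- which(y == 1L); idx0 <- which(y == 0L)
  tr <- c(sample(idx1, round(train_frac * length(idx1))),
          sample(idx0, round(train_frac * length(idx0))))
  list(train = sort(tr), test = sort(setdiff(seq_along(y), tr)))
}

#' Repeated split evaluation protocol
#'
#' Repeats an independent stratified 80/20 train/test split `n_repeats`
#' times (default 12), fits a model on each training portion, scores the
#' test portion, binarizes at the TSS-maximizing threshold and records AUC,
#' Cohen's kappa and TSS; medians over the repeats summarize performance.
#'
#' @param x Predictor matrix or data frame.
#' @param y 0/1 label vector.
#' @param fit Model factory: `function(x_train, y_train)` returning an
#'   object with a [predict()] method yielding scores in (0, 1).
#' @param n_repeats Number of repeated splits (default 12).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Optional integer seed.
#' @param threshold_on Compute the TSS-max threshold on `"test"` scores
#'   (default) or on the training scores of the same fitted model.
#' @return List of class `sdm_evaluation` with `repeats` (per-repeat
#'   data.frame of auc/kappa/tss/threshold) and `median` (named vector).
#' @export
evaluate_repeated <- function(x, y, fit, n_repeats = 12L, train_frac = 0.8,
                              seed = NULL,
                              threshold_on = c("test", "train")) {
  threshold_on <- match.arg(threshold_on)
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x); y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required")
  rows <- vector("list", n_repeats)
  for (k in seq_len(n_repeats)) {
    sp <- NULL
    for (attempt in seq_len(100L)) {
      sp <- stratified_split(y, train_frac)
      ok <- length(unique(y[sp$train])) == 2L &&
        length(unique(y[sp$test])) == 2L
      if (ok) break
      warning("degenerate split re-drawn")
      sp <- NULL
    }
    if (is.null(sp)) stop("could not draw a non-degenerate split")
    model <- fit(x[sp$train, , drop = FALSE], y[sp$train])
    sc_test <- as.numeric(stats::predict(model, x[sp$test, , drop = FALSE]))
    if (threshold_on == "test") {
      res <- tss_max_threshold(y[sp$test], sc_test)
    } else {
      sc_train <- as.numeric(stats::predict(model, x[sp$train, , drop = FALSE]))
      thr <- tss_max_threshold(y[sp$train], sc_train)$threshold
      cc <- confusion_counts(y[sp$test], sc_test, thr)
      res <- list(threshold = thr,
                  metrics = list(auc = roc_auc(y[sp$test], sc_test),
                                 kappa = cohen_kappa(cc),
                                 tss = true_skill(cc), threshold = thr))
    }
    rows[[k]] <- data.frame(repeat_id = k, auc = res$metrics$auc,
                            kappa = res$metrics$kappa, tss = res$metrics$tss,
                            threshold = res$threshold)
  }
  repeats <- do.call(rbind, rows)
  med <- vapply(repeats[, c("auc", "kappa", "tss", "threshold")],
                stats::median, numeric(1))
  structure(list(repeats = repeats, median = med,
                 n_repeats = n_repeats, train_frac = train_frac,
                 threshold_on = threshold_on),
            class = "sdm_evaluation")
}

#' Write an evaluation report
#'
#' Writes the per-repeat metric table plus a median row as CSV, and the
#' same content as JSON.
#'
#' @param ev An `sdm_evaluation` from [evaluate_repeated()].
#' @param csv_path,json_path Output paths; `NULL` skips that format.
#' @export
write_evaluation <- function(ev, csv_path = NULL, json_path = NULL) {
  tab <- ev$repeats
  med_row <- data.frame(repeat_id = NA_integer_, auc = ev$median[["auc"]],
                        kappa = ev$median[["kappa"]], tss = ev$median[["tss"]],
                        threshold = ev$median[["threshold"]])
  if (!is.null(csv_path))
    utils::write.csv(rbind(tab, med_row), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(repeats = tab, median = as.list(ev$median)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(ev)
}
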