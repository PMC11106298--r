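km_lat <- 1 / 111.3195  # degrees of latitude per km (haversine sphere)

test_that("spatial thinning keeps records farther apart than the radius", {
  # two records ~1 km apart -> one kept
  occ <- occurrence_table("sp", c(10, 10), c(0, km_lat))
  expect_equal(nrow(thin_occurrences(occ)), 1L)
  # two records ~10 km apart -> both kept
  occ <- occurrence_table("sp", c(10, 10), c(0, 10 * km_lat))
  expect_equal(nrow(thin_occurrences(occ)), 2L)
  # collinear at 0, 4, 8 km: greedy pass drops the middle record only
  occ <- occurrence_table("sp", c(0, 0, 0), c(0, 4 * km_lat, 8 * km_lat))
  kept <- thin_occurrences(occ)
  expect_equal(kept$latitude, c(0, 8 * km_lat))
})

test_that("thinning is idempotent and order-deterministic", {
  set.seed(31)
  occ <- occurrence_table("sp", runif(60, 0, 0.3), runif(60, 0, 0.3))
  once <- thin_occurrences(occ)
  expect_identical(thin_occurrences(once), once)
  # all pairwise distances above the radius
  pts <- as.matrix(once[, c("longitude", "latitude")])
  for (i in seq_len(nrow(pts) - 1)) {
    d <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                  pts[-seq_len(i), , drop = FALSE])
    expect_true(all(d > 5000))
  }
})

test_that("pseudo-absence sampling yields the 3x design off presence cells", {
  env <- tiny_env(n = 30, seed = 7)
  suit <- true_suitability(env, virtual_species_spec(beta = c(2, 0), b0 = 0))
  pres <- sample_presences(suit, env, 50, seed = 1)
  abs1 <- sample_pseudo_absences(env, pres, seed = 2)
  expect_equal(nrow(abs1), 150L)
  pres_cells <- gnna:::cell_from_lonlat(env, pres$longitude, pres$latitude)
  abs_cells <- gnna:::cell_from_lonlat(env, abs1$longitude, abs1$latitude)
  expect_length(intersect(pres_cells, abs_cells), 0L)
  expect_false(any(duplicated(abs_cells)))
  abs2 <- sample_pseudo_absences(env, pres, seed = 2)
  expect_identical(abs1, abs2)
  expect_error(sample_pseudo_absences(tiny_env(n = 5), pres), "eligible")
})

test_that("correlation screening drops the worst collinear variables", {
  set.seed(11)
  z <- rnorm(500)
  X <- cbind(v1 = z, v2 = z)
  expect_equal(select_variables(X), "v1")
  X <- matrix(rnorm(500 * 4), 500, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  expect_equal(select_variables(X), paste0("x", 1:4))
  # v2 correlates ~0.9 with v1 and ~0.8 with v3 while v1,v3 stay ~0.6:
  # the greedy rule drops v2 (largest mean |r|) and keeps the rest
  R <- matrix(c(1, 0.9, 0.6, 0.9, 1, 0.8, 0.6, 0.8, 1), 3, 3)
  Z <- matrix(rnorm(4000 * 3), 4000, 3) %*% chol(R)
  colnames(Z) <- c("v1", "v2", "v3")
  kept <- select_variables(Z)
  expect_equal(kept, c("v1", "v3"))
  expect_error(select_variables(cbind(a = z, b = rep(1, 500))), "b")
})

test_that("no surviving variable pair reaches the correlation cutoff", {
  set.seed(13)
  for (i in 1:10) {
    n <- 300
    base <- matrix(rnorm(n * 3), n, 3)
    mix <- matrix(runif(3 * 6, -1, 1), 3, 6)
    X <- base %*% mix + 0.3 * matrix(rnorm(n * 6), n, 6)
    colnames(X) <- paste0("v", 1:6)
    kept <- select_variables(X)
    expect_gte(length(kept), 1L)
    if (length(kept) > 1) {
      r <- abs(stats::cor(X[, kept])); diag(r) <- 0
      expect_lt(max(r), 0.7)
    }
  }
})

test_that("AUC matches its boundary cases and tie convention", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0)
  expect_equal(roc_auc(c(1, 0), c(0.4, 0.4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both")
})

test_that("confusion counts partition the data at the threshold", {
  cc <- confusion_counts(c(1, 0, 1, 0), c(0.9, 0.4, 0.6, 0.7), 0.5)
  expect_equal(cc, list(tp = 2L, fp = 1L, tn = 1L, fn = 0L))
  cc0 <- confusion_counts(c(1, 0), c(0.2, 0.8), 0)
  expect_equal(cc0$fn + cc0$tn, 0L)
  cc1 <- confusion_counts(c(1, 0), c(0.2, 0.8), 0.95)
  expect_equal(cc1$tp + cc1$fp, 0L)
})

test_that("kappa and TSS reproduce their closed forms", {
  expect_equal(cohen_kappa(list(tp = 5L, fp = 0L, tn = 5L, fn = 0L)), 1)
  expect_equal(cohen_kappa(list(tp = 5L, fp = 5L, tn = 0L, fn = 0L)), 0)
  expect_equal(cohen_kappa(list(tp = 40L, fp = 10L, tn = 30L, fn = 20L)), 0.4)
  expect_equal(true_skill(list(tp = 5L, fp = 0L, tn = 5L, fn = 0L)), 1)
  expect_equal(true_skill(list(tp = 3L, fn = 1L, tn = 2L, fp = 2L)), 0.25)
  expect_error(true_skill(list(tp = 0L, fn = 0L, tn = 2L, fp = 2L)), "class")
})

test_that("the TSS-max threshold matches exhaustive enumeration", {
  res <- tss_max_threshold(c(1, 0, 1, 0), c(0.9, 0.4, 0.6, 0.7))
  expect_equal(res$threshold, 0.6)
  expect_equal(res$metrics$tss, 0.5)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), 2)  # coarse scores force ties
    res <- tss_max_threshold(labels, scores)
    expect_equal(res$metrics$tss, tss_scan_best(labels, scores))
    cand <- sort(unique(c(0, 1, scores)))
    others <- vapply(cand, function(th)
      true_skill(confusion_counts(labels, scores, th)), numeric(1))
    expect_true(all(res$metrics$tss >= others - 1e-12))
    expect_equal(res$threshold, min(cand[others >= max(others) - 1e-12]))
  }
})

test_that("the repeated-split protocol defaults to 12 stratified 80/20 splits", {
  prob <- random_problem(n = 120, p = 3, seed = 23)
  ev <- evaluate_repeated(prob$X, prob$y, function(x, y) constant_model(),
                          seed = 1)
  expect_equal(nrow(ev$repeats), 12L)
  expect_equal(ev$train_frac, 0.8)
  expect_equal(ev$median[["tss"]], 0)
  expect_equal(ev$median[["kappa"]], 0)
  expect_equal(ev$median[["auc"]], 0.5)
})

test_that("repeated evaluation is reproducible and writes valid reports", {
  prob <- random_problem(n = 100, p = 2, seed = 29)
  glm_fit <- function(x, y) {
    d <- data.frame(x, y = y)
    structure(list(g = suppressWarnings(glm(y ~ ., d, family = binomial))),
              class = "glm_wrap")
  }
  assign("predict.glm_wrap",
         function(object, newdata, ...)
           as.numeric(predict(object$g, data.frame(newdata),
                              type = "response")),
         envir = globalenv())
  on.exit(rm("predict.glm_wrap", envir = globalenv()), add = TRUE)
  ev1 <- evaluate_repeated(prob$X, prob$y, glm_fit, seed = 4)
  ev2 <- evaluate_repeated(prob$X, prob$y, glm_fit, seed = 4)
  expect_identical(ev1$repeats, ev2$repeats)
  expect_true(all(ev1$repeats$auc >= 0 & ev1$repeats$auc <= 1))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_evaluation(ev1, csv_path = csv, json_path = js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 13L)  # 12 repeats + median row
  expect_equal(tab$auc[13], ev1$median[["auc"]])
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$median$auc, ev1$median[["auc"]])
})

test_that("train-threshold mode uses the training scores for the cutoff", {
  prob <- random_problem(n = 100, p = 2, seed = 31)
  fitc <- function(x, y) constant_model(0.7)
  ev <- evaluate_repeated(prob$X, prob$y, fitc, seed = 2,
                          threshold_on = "train")
  expect_equal(ev$threshold_on, "train")
  expect_equal(nrow(ev$repeats), 12L)
})

test_that("occurrence coordinates are validated", {
  expect_error(occurrence_table("s", 200, 0), "longitude")
  expect_error(occurrence_table("s", 0, -95), "latitude")
})
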