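sep3 <- function(n = 40, gap = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2, gap), n, 2),
             matrix(rnorm(n * 2, 0), n, 2),
             matrix(rnorm(n * 2, -gap), n, 2))
  colnames(x) <- c("F1", "F2")
  list(x = x, y = rep(c("bacterial", "noninfected", "viral"), each = n))
}

test_that("separable data trains to near-perfect one-vs-rest AUROCs", {
  d <- sep3()
  for (fam in c("mlp_ensemble", "svm_rbf")) {
    m <- train_classifier(d$x, d$y, classifier_spec(fam, ensemble_size = 3,
                                                    seed = 2))
    p <- predict(m, d$x)
    for (cl in c("bacterial", "viral", "noninfected"))
      expect_gte(auroc(p[, cl], d$y == cl), 0.99)
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
  }
})

test_that("classifier training is seed-deterministic and ensembles average", {
  d <- sep3(n = 20)
  spec <- classifier_spec("mlp_ensemble", ensemble_size = 3, seed = 5)
  p1 <- predict(train_classifier(d$x, d$y, spec), d$x)
  p2 <- predict(train_classifier(d$x, d$y, spec), d$x)
  expect_equal(p1, p2, tolerance = 1e-12)

  single <- classifier_spec("mlp_ensemble", ensemble_size = 1, seed = 5)
  m1 <- train_classifier(d$x, d$y, single)
  expect_length(m1$fits, 1)
  raw <- panelswap:::predict_mlp(m1$fits[[1]], d$x)
  expect_equal(unname(predict(m1, d$x)), unname(raw / rowSums(raw)),
               tolerance = 1e-12)

  expect_error(train_classifier(d$x[1:20, ], rep("bacterial", 20), spec),
               "degenerate|class")
})

test_that("band thresholds meet achievable targets found by grid search", {
  # overlapping scores: the maximal bands do not cross, so the fitted
  # thresholds must equal the grid-search extremes
  set.seed(6)
  scores <- c(rbeta(200, 3, 2), rbeta(200, 2, 3))
  labels <- rep(c(TRUE, FALSE), each = 200)
  cfg <- fit_band_thresholds(scores, labels, 98, 92)
  expect_true(cfg$t1 < cfg$t2 && cfg$t2 < cfg$t3)
  expect_gte(100 * mean(scores[labels] >= cfg$t1), 98)
  expect_gte(100 * mean(scores[!labels] < cfg$t3), 92)

  u <- sort(unique(scores))
  grid <- c(u[1] / 2, (u[-1] + u[-length(u)]) / 2, (u[length(u)] + 1) / 2)
  ok1 <- grid[vapply(grid, function(t) mean(scores[labels] >= t) >= 0.98,
                     logical(1))]
  ok3 <- grid[vapply(grid, function(t) mean(scores[!labels] < t) >= 0.92,
                     logical(1))]
  if (max(ok1) < min(ok3)) {
    expect_equal(cfg$t1, max(ok1))
    expect_equal(cfg$t3, min(ok3))
  }
})

test_that("well-separated scores keep both targets after overlap recentring", {
  set.seed(16)
  scores <- c(rbeta(200, 8, 2), rbeta(200, 2, 8))
  labels <- rep(c(TRUE, FALSE), each = 200)
  cfg <- fit_band_thresholds(scores, labels, 98, 92)
  expect_lt(cfg$t1, cfg$t3)
  expect_gte(100 * mean(scores[labels] >= cfg$t1), 98)
  expect_gte(100 * mean(scores[!labels] < cfg$t3), 92)
})

test_that("a 100% sensitivity target pushes t1 below the lowest positive", {
  set.seed(7)
  scores <- runif(60)
  labels <- runif(60) > 0.5
  cfg <- fit_band_thresholds(scores, labels, 100, 50)
  expect_lt(cfg$t1, min(scores[labels]))
  expect_equal(100 * mean(scores[labels] >= cfg$t1), 100)
})

test_that("raising the sensitivity target never raises t1", {
  set.seed(8)
  scores <- c(rbeta(100, 5, 2), rbeta(100, 2, 5))
  labels <- rep(c(TRUE, FALSE), each = 100)
  t1s <- vapply(c(80, 90, 95, 99, 100), function(tg)
    fit_band_thresholds(scores, labels, tg, 50)$t1, numeric(1))
  expect_true(all(diff(t1s) <= 0))
})

test_that("infeasible targets are flagged on the widest feasible bands", {
  set.seed(9)
  scores <- runif(100)
  labels <- runif(100) > 0.5
  cfg <- fit_band_thresholds(scores, labels, 100, 100)
  expect_lt(cfg$t1, cfg$t3)
  # 100%/100% is achievable here only by pushing t1/t3 to the extremes
  expect_equal(100 * mean(scores[labels] >= cfg$t1), 100)
  expect_equal(100 * mean(scores[!labels] < cfg$t3), 100)
})

test_that("band metrics match hand-counted contingencies", {
  # 10 positives (1 in band 1), 10 negatives (5 in band 1)
  cfg <- structure(list(t1 = 0.25, t2 = 0.5, t3 = 0.75,
                        feasible = c(t1 = TRUE, t3 = TRUE)),
                   class = "band_config")
  scores <- c(0.1, rep(0.6, 9),            # positives
              rep(0.1, 5), rep(0.6, 5))    # negatives
  labels <- rep(c(TRUE, FALSE), each = 10)
  bm <- compute_band_metrics(scores, labels, cfg)
  expect_equal(bm$band1_sensitivity, 90)
  expect_equal(bm$lr_minus, (1 / 10) / (5 / 10))
  expect_equal(bm$fraction1, 100 * 6 / 20)
  expect_equal(sum(bm$fractions), 100)
})

test_that("a perfect test yields LR- 0, LR+ Inf and full band-4 specificity", {
  cfg <- structure(list(t1 = 0.3, t2 = 0.5, t3 = 0.7,
                        feasible = c(t1 = TRUE, t3 = TRUE)),
                   class = "band_config")
  scores <- c(rep(0.9, 8), rep(0.1, 8))
  labels <- rep(c(TRUE, FALSE), each = 8)
  bm <- compute_band_metrics(scores, labels, cfg)
  expect_equal(bm$lr_minus, 0)
  expect_equal(bm$lr_plus, Inf)
  expect_equal(bm$band4_specificity, 100)
  expect_equal(bm$band1_sensitivity, 100)
})

test_that("band boundaries are half-open: scores at a threshold move up a band", {
  cfg <- structure(list(t1 = 0.2, t2 = 0.5, t3 = 0.8,
                        feasible = c(t1 = TRUE, t3 = TRUE)),
                   class = "band_config")
  b <- panelswap:::band_of(c(0, 0.19, 0.2, 0.49, 0.5, 0.79, 0.8, 1), cfg)
  expect_equal(b, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
})

test_that("band fractions obey the prevalence mixture identity", {
  set.seed(10)
  scores <- runif(300)
  labels <- runif(300) > 0.7
  cfg <- fit_band_thresholds(scores, labels, 90, 80)
  bm <- compute_band_metrics(scores, labels, cfg)
  pi <- bm$prevalence
  # identity from the LR decomposition, rule-in band
  expect_equal(bm$fraction4,
               band_fraction_identity(pi, bm$lr_plus, bm$band4_specificity),
               tolerance = 1e-9)
  # and rule-out band
  expect_equal(bm$fraction1,
               band_fraction_identity(pi, bm$lr_minus, bm$band1_sensitivity,
                                      band = "rule_out"),
               tolerance = 1e-9)
})

test_that("scores positively associated with the class give LR- <= 1 <= LR+", {
  d <- sep3(n = 60, gap = 2, seed = 11)
  m <- train_classifier(d$x, d$y, classifier_spec(ensemble_size = 2, seed = 3))
  p <- predict(m, d$x)
  for (cl in c("bacterial", "viral")) {
    cfg <- fit_band_thresholds(p[, cl], d$y == cl, 95, 90)
    bm <- compute_band_metrics(p[, cl], d$y == cl, cfg)
    expect_lte(bm$lr_minus, 1)
    expect_gte(bm$lr_plus, 1)
  }
})

test_that("panel evaluation freezes training thresholds for validation", {
  d <- planted_design(n_info = 3, n_noise = 2, n_per_class = 50, seed = 12,
                      n_cohorts = 3)
  ev <- evaluate_panel(d$informative, d$x_train, d$y_train, d$x_val, d$y_val,
                       classifier_spec(ensemble_size = 2, seed = 4),
                       cv_folds = 3)
  expect_setequal(unique(ev$metrics$dataset), c("train", "validation"))
  expect_setequal(unique(ev$metrics$class), c("bacterial", "viral"))
  # validation metrics recomputable from frozen thresholds and stored scores
  for (cl in c("bacterial", "viral")) {
    bm <- compute_band_metrics(ev$scores$validation[, cl],
                               d$y_val == cl, ev$bands[[cl]])
    got <- ev$metrics[ev$metrics$class == cl &
                      ev$metrics$dataset == "validation", ]
    expect_equal(got$value[got$metric == "auroc"], bm$auroc)
    expect_equal(got$value[got$metric == "fraction4"], bm$fraction4)
  }
})
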