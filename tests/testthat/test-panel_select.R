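test_that("a perfectly separating marker reaches cross-validated mAUROC 1", {
  set.seed(1)
  x <- matrix(c(rnorm(60, 10), rnorm(60, 0), rnorm(60, -10)), ncol = 1,
              dimnames = list(NULL, "M1"))
  y <- rep(c("bacterial", "noninfected", "viral"), each = 60)
  cv <- cross_validated_auc(x, y, model_spec("logistic", budget = 5,
                                             cv_folds = 3, seed = 1))
  expect_equal(cv$cv_mauroc, 1)
})

test_that("cross-validated mAUROC is calibrated at 0.5 under permuted labels", {
  set.seed(2)
  x <- matrix(rnorm(600 * 3), 600, 3, dimnames = list(NULL, paste0("M", 1:3)))
  y <- sample(rep(c("bacterial", "viral", "noninfected"), each = 200))
  cv <- cross_validated_auc(x, y, model_spec("logistic", budget = 5,
                                             cv_folds = 5, seed = 2))
  expect_lt(abs(cv$cv_mauroc - 0.5), 0.05)
})

test_that("the logistic CV path agrees with an independent per-fold oracle", {
  set.seed(3)
  d <- planted_design(n_info = 2, n_noise = 2, n_per_class = 30, seed = 3,
                      n_cohorts = 3)
  spec <- model_spec("logistic", budget = 3, cv_folds = 3, seed = 5)
  feats <- c(d$informative, d$noise)
  x <- d$x_train[, feats]
  y <- factor(d$y_train, levels = c("bacterial", "viral", "noninfected"))
  cv <- cross_validated_auc(x, y, spec)

  folds <- make_cv_folds(y, NULL, k = 3, seed = 5)
  lam <- cv$evaluations$lambda
  manual <- sapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- glmnet::glmnet(x[tr, ], y[tr], family = "multinomial", alpha = 0,
                          lambda = sort(lam, decreasing = TRUE))
    sapply(seq_along(lam), function(j) {
      p <- predict(fit, x[!tr, ], type = "response")[, , j]
      mean(sapply(colnames(p), function(cl)
        pair_count_auroc(p[, cl], y[!tr] == cl)))
    })
  })
  expect_equal(cv$evaluations$cv_mauroc, rowMeans(manual), tolerance = 1e-10)
})

test_that("cohort-grouped folds keep cohorts whole and classes covered", {
  d <- planted_design(n_info = 2, n_noise = 1, n_per_class = 60, seed = 4,
                      n_cohorts = 6)
  folds <- make_cv_folds(d$y_train, d$cohorts, k = 4, seed = 1)
  for (co in unique(d$cohorts))
    expect_length(unique(folds[d$cohorts == co]), 1)
  for (f in unique(folds))
    expect_setequal(unique(d$y_train[folds == f]),
                    c("bacterial", "viral", "noninfected"))
})

test_that("the only informative candidate dominates a step", {
  d <- planted_design(n_info = 1, n_noise = 8, n_per_class = 60, seed = 6,
                      n_cohorts = 3)
  st <- forward_select_step(character(0), c(d$informative, d$noise),
                            d$x_train, d$y_train, d$x_val, d$y_val,
                            model_spec("logistic", budget = 5, cv_folds = 3,
                                       seed = 2))
  expect_equal(st$chosen, d$informative)
  expect_true(st$table$chosen[st$table$candidate == d$informative])
})

test_that("ties between duplicated markers break lexicographically", {
  d <- planted_design(n_info = 1, n_noise = 2, n_per_class = 40, seed = 7,
                      n_cohorts = 3)
  dup <- function(x) {
    x <- cbind(x, x[, d$informative], x[, d$informative])
    colnames(x)[ncol(x) - 1:0] <- c("ZDUP", "ADUP")
    x
  }
  st <- forward_select_step(character(0), c("ADUP", "ZDUP"),
                            dup(d$x_train), d$y_train, dup(d$x_val), d$y_val,
                            model_spec("logistic", budget = 4, cv_folds = 3,
                                       seed = 2))
  expect_equal(st$chosen, "ADUP")
  expect_error(forward_select_step(character(0), character(0),
                                   d$x_train, d$y_train, d$x_val, d$y_val,
                                   model_spec("logistic")),
               "empty candidate")
})

test_that("the chosen marker always satisfies the trade-off argmax rule", {
  d <- planted_design(n_info = 3, n_noise = 5, n_per_class = 50, seed = 8,
                      n_cohorts = 3)
  eps <- 0.01
  sel <- run_two_phase_selection(
    d$x_train, d$y_train, d$x_val, d$y_val,
    pool = c(d$informative, d$noise),
    model_spec("logistic", budget = 4, cv_folds = 3, seed = 3),
    model_spec("mlp", budget = 3, cv_folds = 2, seed = 3,
               hyperparameters = list(size_max = 4, maxit = 50)),
    selection_config(phase1_size = 2, target_size = 4, epsilon = eps))
  for (s in unique(sel$trace$step)) {
    tr <- sel$trace[sel$trace$step == s, ]
    elig <- tr[tr$train_cv_auc >= max(tr$train_cv_auc) - eps, ]
    best <- elig[order(-elig$val_auc, elig$candidate), ][1, "candidate"]
    expect_equal(tr$candidate[tr$chosen], best)
  }
})

test_that("two-phase selection honors phase sizes, exhaustion and determinism", {
  d <- planted_design(n_info = 3, n_noise = 2, n_per_class = 40, seed = 9,
                      n_cohorts = 3)
  pool <- c(d$informative, d$noise)
  p1 <- model_spec("logistic", budget = 3, cv_folds = 3, seed = 4)
  p2 <- model_spec("mlp", budget = 3, cv_folds = 2, seed = 4,
                   hyperparameters = list(size_max = 4, maxit = 50))
  cfg <- selection_config(phase1_size = 3, target_size = 5)
  sel1 <- run_two_phase_selection(d$x_train, d$y_train, d$x_val, d$y_val,
                                  pool, p1, p2, cfg)
  sel2 <- run_two_phase_selection(d$x_train, d$y_train, d$x_val, d$y_val,
                                  pool, p1, p2, cfg)
  expect_identical(sel1$panel, sel2$panel)
  expect_identical(sel1$trace, sel2$trace)

  expect_setequal(sel1$panel, pool)  # target = pool size: exhaustion
  expect_equal(sum(sel1$trace$phase[sel1$trace$chosen] == 1), 3)
  expect_equal(sum(sel1$trace$phase[sel1$trace$chosen] == 2), 2)
  expect_error(run_two_phase_selection(d$x_train, d$y_train, d$x_val,
                                       d$y_val, pool[1:3], p1, p2, cfg),
               "smaller than target")
})

test_that("training CV AUROC of chosen additions is non-decreasing on separable data", {
  d <- planted_design(n_info = 5, n_noise = 3, n_per_class = 60, seed = 10,
                      n_cohorts = 3, residual_noise_sd = 0.5)
  panel <- character(0)
  prev <- -Inf
  for (s in 1:5) {
    st <- forward_select_step(panel, setdiff(c(d$informative, d$noise), panel),
                              d$x_train, d$y_train, d$x_val, d$y_val,
                              model_spec("logistic", budget = 4, cv_folds = 3,
                                         seed = 5))
    chosen_cv <- st$table$train_cv_auc[st$table$chosen]
    expect_gte(chosen_cv, prev - 0.02)
    prev <- chosen_cv
    panel <- c(panel, st$chosen)
  }
})

test_that("housekeeping markers are never selected while informative ones remain", {
  d <- planted_design(n_info = 3, n_noise = 2, n_per_class = 50, seed = 11,
                      n_cohorts = 3)
  pool <- c(d$informative, "HKG1", "HKG2")
  sel <- run_two_phase_selection(
    d$x_train, d$y_train, d$x_val, d$y_val, pool,
    model_spec("logistic", budget = 3, cv_folds = 3, seed = 6),
    model_spec("mlp", budget = 2, cv_folds = 2, seed = 6,
               hyperparameters = list(size_max = 3, maxit = 40)),
    selection_config(phase1_size = 2, target_size = 3))
  expect_true(all(d$informative %in% sel$panel))
  expect_false(any(c("HKG1", "HKG2") %in% sel$panel))
})

test_that("MLP search is deterministic and respects its budget", {
  d <- planted_design(n_info = 2, n_noise = 1, n_per_class = 30, seed = 12,
                      n_cohorts = 3)
  spec <- model_spec("mlp", budget = 5, cv_folds = 2, seed = 7,
                     hyperparameters = list(size_max = 5, maxit = 40))
  x <- d$x_train[, c(d$informative, d$noise)]
  cv1 <- cross_validated_auc(x, d$y_train, spec)
  cv2 <- cross_validated_auc(x, d$y_train, spec)
  expect_identical(cv1$evaluations, cv2$evaluations)
  expect_equal(nrow(cv1$evaluations), 5)
  expect_true(all(cv1$evaluations$size <= 5))

  rnd <- model_spec("mlp", budget = 4, cv_folds = 2, seed = 7,
                    search = "random",
                    hyperparameters = list(size_max = 5, maxit = 40))
  expect_equal(nrow(cross_validated_auc(x, d$y_train, rnd)$evaluations), 4)
})
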