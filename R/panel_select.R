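#' Model specification for panel selection
#'
#' Describes the classifier family, hyperparameter space, search strategy
#' and cross-validation layout used to score candidate marker additions.
#' Defaults mirror the two selection phases: a ridge-penalized multinomial
#' logistic model with random search over the penalty, and a single-hidden-
#' layer multi-layer perceptron with sequential model-based ("Bayesian")
#' search over width and weight decay.
#'
#' @param family `"logistic"` (ridge multinomial, via glmnet) or `"mlp"`
#'   (single-hidden-layer perceptron, via nnet).
#' @param hyperparameters named list of space bounds. Logistic:
#'   `lambda_min`, `lambda_max` (L2 penalty, log-uniform). MLP: `size_min`,
#'   `size_max` (hidden units), `decay_min`, `decay_max` (weight decay,
#'   log-uniform), `maxit`.
#' @param search `"random"` or `"bayes"` (sequential model-based; falls back
#'   to random proposals when the surrogate cannot be fit).
#' @param budget number of hyperparameter evaluations.
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed; all search randomness derives from it.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(family = c("logistic", "mlp"),
                       hyperparameters = NULL,
                       search = NULL,
                       budget = NULL,
                       cv_folds = 5,
                       seed = 1) {
  family <- match.arg(family)
  defaults <- switch(family,
    logistic = list(hp = list(lambda_min = 1e-4, lambda_max = 10),
                    search = "random", budget = 20),
    mlp = list(hp = list(size_min = 2, size_max = 16,
                         decay_min = 1e-4, decay_max = 1, maxit = 150),
               search = "bayes", budget = 30))
  hp <- utils::modifyList(defaults$hp, hyperparameters %||% list())
  search <- match.arg(search %||% defaults$search, c("random", "bayes"))
  budget <- budget %||% defaults$budget
  assert_scalar_number(budget, "budget", min = 1)
  assert_scalar_number(cv_folds, "cv_folds", min = 2)
  structure(list(family = family, hyperparameters = hp, search = search,
                 budget = as.integer(budget), cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Selection configuration for the two-phase forward search
#'
#' @param phase1_size panel size grown under the phase-1 model (default 19).
#' @param target_size final panel size (default 29).
#' @param epsilon train/validation trade-off band (AUC units): a candidate
#'   is eligible if its training CV AUC is within `epsilon` of the best
#'   training CV AUC at that step; among eligibles the one with highest
#'   validation AUC wins, ties broken by marker name.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(phase1_size = 19, target_size = 29,
                             epsilon = 0.01) {
  assert_scalar_number(phase1_size, "phase1_size", min = 1)
  assert_scalar_number(target_size, "target_size", min = 2)
  assert_scalar_number(epsilon, "epsilon", min = 0)
  if (phase1_size >= target_size)
    stop_ps("phase1_size (%d) must be < target_size (%d)",
            phase1_size, target_size)
  structure(list(phase1_size = as.integer(phase1_size),
                 target_size = as.integer(target_size),
                 epsilon = epsilon),
            class = "selection_config")
}

#' Cross-validation folds, stratified by class and grouped by cohort
#'
#' Whole cohorts are kept inside one fold (matching the multi-cohort
#' generalization goal of the design) when there are at least `k` cohorts
#' and the grouped assignment leaves every class represented in every fold;
#' otherwise folds are stratified by class at the sample level.
#'
#' @param labels class labels.
#' @param cohorts optional cohort ids (same length); `NULL` forces
#'   sample-level stratification.
#' @param k number of folds.
#' @param seed seed for the assignment.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_cv_folds <- function(labels, cohorts = NULL, k = 5, seed = 1) {
  n <- length(labels)
  y <- as_class_factor(labels)
  k <- as.integer(k)
  if (k < 2) stop_ps("need k >= 2 folds")
  if (!is.null(cohorts) && length(unique(cohorts)) >= k) {
    set.seed(seed)
    co <- sample(unique(cohorts))
    sizes <- table(cohorts)[co]
    fold_of <- setNames(integer(length(co)), co)
    load <- numeric(k)
    for (cc in co[order(-sizes)]) {
      f <- which.min(load)
      fold_of[cc] <- f
      load[f] <- load[f] + sizes[cc]
    }
    folds <- unname(fold_of[as.character(cohorts)])
    ok <- all(vapply(seq_len(k), function(f)
      all(TRIAGE_CLASSES %in% y[folds == f]), logical(1)))
    if (ok) return(folds)
  }
  # sample-level stratification by class
  set.seed(seed + 1L)
  folds <- integer(n)
  for (cl in TRIAGE_CLASSES) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# pad a single-column feature matrix (glmnet needs >= 2 columns)
pad_features <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `..pad` = 0)
}

# j-th lambda slice of a glmnet multinomial probability array, kept a matrix
slice_probs <- function(p, j) {
  out <- matrix(p[, , j], nrow = dim(p)[1],
                dimnames = list(NULL, dimnames(p)[[2]]))
  out[, TRIAGE_CLASSES, drop = FALSE]
}

# mean one-vs-rest AUROC at every lambda of a multinomial glmnet path,
# computed from the coefficients directly (one matrix product per class)
path_mauroc <- function(fit, x_new, y_new, n_lambda) {
  cls <- names(fit$beta)
  eta <- lapply(cls, function(cl)
    as.matrix(x_new %*% fit$beta[[cl]]) +
      matrix(fit$a0[cl, ], nrow(x_new), n_lambda, byrow = TRUE))
  names(eta) <- cls
  emax <- Reduce(pmax, eta)
  ex <- lapply(eta, function(e) exp(e - emax))
  denom <- Reduce(`+`, ex)
  per_class <- vapply(cls, function(cl) {
    pos <- y_new == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(rep(NA_real_, n_lambda))
    pr <- ex[[cl]] / denom
    r <- apply(pr, 2, rank)
    (colSums(r[pos, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(n_lambda))
  rowMeans(matrix(per_class, nrow = n_lambda), na.rm = TRUE)
}

# sample hyperparameter configurations from the spec's space (seeded)
draw_configs <- function(spec, n, seed) {
  hp <- spec$hyperparameters
  set.seed(seed)
  if (spec$family == "logistic") {
    lambda <- exp(stats::runif(n, log(hp$lambda_min), log(hp$lambda_max)))
    lapply(lambda, function(l) list(lambda = l))
  } else {
    size <- sample(seq(hp$size_min, hp$size_max), n, replace = TRUE)
    decay <- exp(stats::runif(n, log(hp$decay_min), log(hp$decay_max)))
    Map(function(s, d) list(size = s, decay = d, maxit = hp$maxit),
        size, decay)
  }
}

fit_mlp <- function(x, y, params, seed) {
  set.seed(seed)
  nnet::nnet(x, nnet::class.ind(y), size = params$size, decay = params$decay,
             maxit = params$maxit %||% 150, softmax = TRUE, trace = FALSE,
             MaxNWts = 10000)
}

predict_mlp <- function(fit, x) {
  p <- stats::predict(fit, x, type = "raw")
  colnames(p) <- fit$lev %||% colnames(p)
  p[, TRIAGE_CLASSES, drop = FALSE]
}

# CV mAUROC of an MLP configuration
cv_score_mlp <- function(x, y, folds, params, seed) {
  ks <- sort(unique(folds))
  mean(vapply(ks, function(f) {
    tr <- folds != f
    fit <- fit_mlp(x[tr, , drop = FALSE], y[tr], params, seed + f)
    p <- predict_mlp(fit, x[!tr, , drop = FALSE])
    as.numeric(mauroc(p, y[!tr], na_absent = TRUE))
  }, numeric(1)))
}

#' Cross-validated multi-class AUROC with hyperparameter search
#'
#' Scores a feature set by k-fold cross-validation on the training data:
#' for every hyperparameter configuration visited by the spec's search
#' strategy, the model is fit on each fold's training part and its held-out
#' mean one-vs-rest AUROC is averaged over folds; the best configuration's
#' score is returned. Deterministic given the spec's seed.
#'
#' @param x samples x features numeric matrix (normalized expression
#'   restricted to a marker set).
#' @param labels 3-class labels; every class must be present.
#' @param spec a [model_spec()].
#' @param folds optional precomputed fold ids (from [make_cv_folds()]);
#'   computed from `spec$cv_folds` and `spec$seed` when `NULL`.
#' @param cohorts optional cohort ids used when computing folds.
#' @return list with `cv_mauroc` (best mean CV AUROC), `best_params`,
#'   and `evaluations` (data.frame of every configuration and its score).
#' @export
cross_validated_auc <- function(x, labels, spec, folds = NULL,
                                cohorts = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  y <- as_class_factor(labels)
  if (any(table(y) == 0))
    stop_ps("all three classes must be present in training data")
  if (is.null(folds))
    folds <- make_cv_folds(y, cohorts, k = spec$cv_folds, seed = spec$seed)
  x <- as.matrix(x)

  if (spec$family == "logistic") {
    cfgs <- draw_configs(spec, spec$budget, spec$seed)
    lambdas <- sort(unique(vapply(cfgs, `[[`, numeric(1), "lambda")),
                    decreasing = TRUE)
    xp <- pad_features(x)
    ks <- sort(unique(folds))
    scores <- matrix(NA_real_, length(ks), length(lambdas))
    for (i in seq_along(ks)) {
      tr <- folds != ks[i]
      fit <- glmnet::glmnet(xp[tr, , drop = FALSE], y[tr],
                            family = "multinomial", alpha = 0,
                            lambda = lambdas)
      scores[i, ] <- path_mauroc(fit, xp[!tr, , drop = FALSE], y[!tr],
                                 length(lambdas))
    }
    mean_scores <- colMeans(scores)
    best <- which.max(mean_scores)
    evals <- data.frame(lambda = lambdas, cv_mauroc = mean_scores)
    return(list(cv_mauroc = mean_scores[best],
                best_params = list(lambda = lambdas[best]),
                evaluations = evals))
  }

  # MLP: sequential evaluations, random or surrogate-guided
  budget <- spec$budget
  n_init <- if (spec$search == "bayes") min(budget, max(4L, budget %/% 3L))
            else budget
  cfgs <- draw_configs(spec, n_init, spec$seed)
  scores <- vapply(seq_along(cfgs), function(i)
    cv_score_mlp(x, y, folds, cfgs[[i]], spec$seed + i * 131L), numeric(1))
  i <- length(cfgs)
  while (i < budget) {
    i <- i + 1L
    prop <- propose_config(spec, cfgs, scores, seed = spec$seed + i * 977L)
    cfgs[[i]] <- prop
    scores[i] <- cv_score_mlp(x, y, folds, prop, spec$seed + i * 131L)
  }
  best <- which.max(scores)
  evals <- data.frame(size = vapply(cfgs, `[[`, numeric(1), "size"),
                      decay = vapply(cfgs, `[[`, numeric(1), "decay"),
                      cv_mauroc = scores)
  list(cv_mauroc = scores[best], best_params = cfgs[[best]],
       evaluations = evals)
}

# sequential model-based proposal: quadratic surrogate over (size, log decay)
# ranked on a random candidate pool; falls back to a pure random draw
propose_config <- function(spec, cfgs, scores, seed, n_pool = 256) {
  cand <- draw_configs(spec, n_pool, seed)
  df <- data.frame(s = vapply(cfgs, `[[`, numeric(1), "size"),
                   d = log10(vapply(cfgs, `[[`, numeric(1), "decay")),
                   y = scores)
  pred <- tryCatch({
    fit <- stats::lm(y ~ s + I(s^2) + d + I(d^2) + s:d, data = df)
    newd <- data.frame(s = vapply(cand, `[[`, numeric(1), "size"),
                       d = log10(vapply(cand, `[[`, numeric(1), "decay")))
    suppressWarnings(stats::predict(fit, newd))  # rank-deficiency is fine here
  }, error = function(e) NULL)
  if (is.null(pred) || anyNA(pred)) {
    set.seed(seed + 1L)
    return(cand[[sample.int(length(cand), 1)]])
  }
  cand[[which.max(pred)]]
}

# refit the winning configuration on all training data and score validation
refit_and_score <- function(x_tr, y_tr, x_va, y_va, spec, params) {
  if (spec$family == "logistic") {
    xp <- pad_features(x_tr)
    lambdas <- sort(unique(c(params$lambda, params$lambda * 10)),
                    decreasing = TRUE)
    fit <- glmnet::glmnet(xp, y_tr, family = "multinomial", alpha = 0,
                          lambda = lambdas)
    p <- stats::predict(fit, pad_features(x_va), type = "response",
                        s = params$lambda)
    p <- slice_probs(p, 1)
  } else {
    fit <- fit_mlp(x_tr, y_tr, params, spec$seed)
    p <- predict_mlp(fit, x_va)
  }
  mauroc(p, y_va, na_absent = TRUE)
}

#' One greedy forward-selection step
#'
#' For every candidate marker, fits the spec's model with hyperparameter
#' search on the training data (cross-validation) over the current set plus
#' that candidate, refits the winning configuration on all training data,
#' and scores it on the held-out validation cohorts. The chosen candidate
#' maximizes validation AUC among candidates whose training CV AUC is
#' within `epsilon` of the best training CV AUC; ties break by marker name.
#'
#' @param current_set character vector of already-selected markers (may be
#'   empty).
#' @param candidates character vector of candidate markers, disjoint from
#'   `current_set`.
#' @param x_train,x_val normalized expression matrices (samples x markers).
#' @param y_train,y_val class labels.
#' @param spec a [model_spec()].
#' @param epsilon trade-off band in AUC units (see [selection_config()]).
#' @param folds optional precomputed training folds.
#' @param cohorts optional training cohort ids for fold construction.
#' @return list with `table` (candidate, train_cv_auc, val_auc, per-class
#'   validation AUROCs, chosen flag), `chosen`, `params` of the winning fit.
#' @export
forward_select_step <- function(current_set, candidates, x_train, y_train,
                                x_val, y_val, spec, epsilon = 0.01,
                                folds = NULL, cohorts = NULL) {
  if (length(candidates) == 0) stop_ps("empty candidate set")
  if (length(intersect(current_set, candidates)) > 0)
    stop_ps("candidates must be disjoint from the current set")
  candidates <- sort(candidates)
  y_tr <- as_class_factor(y_train)
  y_va <- as_class_factor(y_val)
  if (is.null(folds))
    folds <- make_cv_folds(y_tr, cohorts, k = spec$cv_folds, seed = spec$seed)

  res <- lapply(candidates, function(cand) {
    feats <- c(current_set, cand)
    cv <- cross_validated_auc(x_train[, feats, drop = FALSE], y_tr, spec,
                              folds = folds)
    val <- refit_and_score(x_train[, feats, drop = FALSE], y_tr,
                           x_val[, feats, drop = FALSE], y_va,
                           spec, cv$best_params)
    list(cv_auc = cv$cv_mauroc, val_auc = as.numeric(val),
         per_class = attr(val, "per_class"), params = cv$best_params)
  })
  cv_auc <- vapply(res, `[[`, numeric(1), "cv_auc")
  val_auc <- vapply(res, `[[`, numeric(1), "val_auc")
  per_class <- t(vapply(res, `[[`, numeric(3), "per_class"))

  eligible <- cv_auc >= max(cv_auc) - epsilon
  pick <- which(eligible)[which.max(val_auc[eligible])]  # lexicographic ties

  tab <- data.frame(candidate = candidates, train_cv_auc = cv_auc,
                    val_auc = val_auc,
                    val_auc_bacterial = per_class[, 1],
                    val_auc_viral = per_class[, 2],
                    val_auc_noninfected = per_class[, 3],
                    chosen = seq_along(candidates) == pick,
                    stringsAsFactors = FALSE)
  list(table = tab, chosen = candidates[pick], params = res[[pick]]$params)
}

#' Two-phase greedy forward panel selection
#'
#' Grows a marker panel from the candidate pool one marker per step,
#' scoring each candidate addition by training cross-validation AUC and
#' held-out validation AUC. The first `phase1_size` steps use the phase-1
#' model (default: ridge logistic regression with random hyperparameter
#' search); the remaining steps up to `target_size` use the phase-2 model
#' (default: MLP with sequential model-based hyperparameter search). The
#' full per-candidate audit trail is kept, sufficient to redraw the
#' train-vs-validation scatter of any step.
#'
#' @param x_train,x_val normalized expression matrices whose columns cover
#'   the pool.
#' @param y_train,y_val class labels.
#' @param pool ordered candidate pool (from [assemble_candidate_pool()]).
#' @param phase1_spec,phase2_spec [model_spec()]s for the two phases.
#' @param cfg a [selection_config()].
#' @param cohorts optional training cohort ids for fold construction.
#' @return object of class `panel_selection`: `panel` (ordered markers),
#'   `trace` (per-step, per-candidate AUC table), `params` (winning
#'   hyperparameters per step), `cfg`, `phase1_spec`, `phase2_spec`.
#' @export
run_two_phase_selection <- function(x_train, y_train, x_val, y_val, pool,
                                    phase1_spec = model_spec("logistic"),
                                    phase2_spec = model_spec("mlp"),
                                    cfg = selection_config(),
                                    cohorts = NULL) {
  stopifnot(inherits(cfg, "selection_config"))
  if (length(pool) < cfg$target_size)
    stop_ps("pool (%d markers) smaller than target panel size (%d)",
            length(pool), cfg$target_size)
  miss <- setdiff(pool, colnames(x_train))
  if (length(miss) > 0)
    stop_ps("pool marker(s) absent from training matrix: %s",
            paste(miss, collapse = ", "))
  y_tr <- as_class_factor(y_train)

  panel <- character(0)
  trace <- list()
  params <- list()
  for (step in seq_len(cfg$target_size)) {
    spec <- if (step <= cfg$phase1_size) phase1_spec else phase2_spec
    folds <- make_cv_folds(y_tr, cohorts, k = spec$cv_folds,
                           seed = spec$seed)
    candidates <- setdiff(pool, panel)
    st <- forward_select_step(panel, candidates, x_train, y_train,
                              x_val, y_val, spec, epsilon = cfg$epsilon,
                              folds = folds)
    st$table <- data.frame(step = step,
                           phase = if (step <= cfg$phase1_size) 1L else 2L,
                           st$table, stringsAsFactors = FALSE)
    trace[[step]] <- st$table
    params[[step]] <- st$params
    panel <- c(panel, st$chosen)
  }
  structure(list(panel = panel, trace = do.call(rbind, trace),
                 params = params, cfg = cfg,
                 phase1_spec = phase1_spec, phase2_spec = phase2_spec),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  p1 <- min(x$cfg$phase1_size, length(x$panel))
  cat(sprintf("Forward-selected panel of %d markers\n", length(x$panel)))
  cat(sprintf("  phase 1 (%s): %s\n", x$phase1_spec$family,
              paste(x$panel[seq_len(p1)], collapse = ", ")))
  if (length(x$panel) > p1)
    cat(sprintf("  phase 2 (%s): %s\n", x$phase2_spec$family,
                paste(x$panel[-seq_len(p1)], collapse = ", ")))
  invisible(x)
}

#' @export
summary.panel_selection <- function(object, ...) {
  tr <- object$trace[object$trace$chosen, ]
  out <- tr[, c("step", "phase", "candidate", "train_cv_auc", "val_auc")]
  names(out)[3] <- "marker"
  rownames(out) <- NULL
  out
}

#' Train-vs-validation AUC scatter for a selection step
#'
#' @param x a `panel_selection`.
#' @param step which step to plot (default: last).
#' @param ... passed to [graphics::plot()].
#' @export
plot.panel_selection <- function(x, step = max(x$trace$step), ...) {
  tr <- x$trace[x$trace$step == step, ]
  graphics::plot(tr$train_cv_auc, tr$val_auc,
                 xlab = "training cross-validation mAUROC",
                 ylab = "validation mAUROC",
                 main = sprintf("forward selection, step %d", step), ...)
  ch <- tr[tr$chosen, ]
  graphics::points(ch$train_cv_auc, ch$val_auc, pch = 19, col = "red")
  graphics::text(ch$train_cv_auc, ch$val_auc, ch$candidate, pos = 2,
                 col = "red", cex = 0.8)
  invisible(x)
}
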