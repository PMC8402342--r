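#' Classifier specification for the locked panel
#'
#' @param family `"mlp_ensemble"` (ensemble of single-hidden-layer
#'   perceptrons whose probability outputs are averaged and renormalized)
#'   or `"svm_rbf"` (support vector machine with radial kernel and Platt
#'   probability outputs, the baseline classifier family).
#' @param ensemble_size number of ensemble members (mlp_ensemble only);
#'   members differ only by derived sub-seeds.
#' @param hyperparameters mlp: `size`, `decay`, `maxit`; svm: `cost`,
#'   `gamma` (NULL = 1/n_features).
#' @param seed integer seed.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("mlp_ensemble", "svm_rbf"),
                            ensemble_size = 5,
                            hyperparameters = NULL,
                            seed = 1) {
  family <- match.arg(family)
  defaults <- switch(family,
    mlp_ensemble = list(size = 8, decay = 0.01, maxit = 150),
    svm_rbf = list(cost = 1, gamma = NULL))
  assert_scalar_number(ensemble_size, "ensemble_size", min = 1)
  structure(list(family = family, ensemble_size = as.integer(ensemble_size),
                 hyperparameters = utils::modifyList(defaults,
                                                     hyperparameters %||% list()),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train the final multi-class classifier on a locked panel
#'
#' Fits the spec's classifier on the panel features and returns a model
#' that emits per-sample probability triplets (bacterial, viral,
#' noninfected) summing to one. The MLP ensemble averages member
#' probabilities and renormalizes; members share data and hyperparameters
#' and differ only by sub-seeds derived from the spec seed, so training is
#' fully reproducible.
#'
#' @param x samples x panel-markers numeric matrix (normalized expression).
#' @param labels class labels; all three classes must be present.
#' @param spec a [classifier_spec()].
#' @return object of class `triage_classifier` with a [predict][stats::predict]
#'   method returning the samples x 3 probability matrix.
#' @export
train_classifier <- function(x, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- as_class_factor(labels)
  if (any(table(y) == 0))
    stop_ps("degenerate training data: all three classes must be present")

  hp <- spec$hyperparameters
  fits <- if (spec$family == "mlp_ensemble") {
    lapply(seq_len(spec$ensemble_size), function(i)
      fit_mlp(x, y, hp, spec$seed + i * 1000L))
  } else {
    set.seed(spec$seed)
    gamma <- hp$gamma %||% (1 / ncol(x))
    list(e1071::svm(x, y, kernel = "radial", cost = hp$cost, gamma = gamma,
                    probability = TRUE))
  }
  structure(list(fits = fits, spec = spec, markers = colnames(x),
                 classes = TRIAGE_CLASSES),
            class = "triage_classifier")
}

#' @export
#' @rdname train_classifier
#' @param object a `triage_classifier`.
#' @param newdata samples x markers matrix covering the panel markers.
#' @param ... unused.
predict.triage_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$markers, drop = FALSE]
  probs <- lapply(object$fits, function(fit) {
    if (object$spec$family == "mlp_ensemble") {
      predict_mlp(fit, x)
    } else {
      pr <- stats::predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, TRIAGE_CLASSES, drop = FALSE]
    }
  })
  p <- Reduce(`+`, probs) / length(probs)
  p <- p / rowSums(p)
  rownames(p) <- rownames(newdata)
  p
}

#' @export
print.triage_classifier <- function(x, ...) {
  cat(sprintf("%s classifier on %d markers", x$spec$family,
              length(x$markers)))
  if (x$spec$family == "mlp_ensemble")
    cat(sprintf(" (ensemble of %d)", length(x$fits)))
  cat("\n")
  invisible(x)
}

#' Fit four-band interpretation thresholds on training scores
#'
#' Partitions a one-vs-rest probability score into four interpretation
#' bands \[0,t1), \[t1,t2), \[t2,t3), \[t3,1\]: band 1 is the rule-out call,
#' band 4 the rule-in call, bands 2-3 intermediate. `t1` is the largest
#' threshold whose band-1 sensitivity (sensitivity of the not-band-1 call)
#' meets the target on training data; `t3` is the smallest threshold whose
#' band-4 specificity (specificity of the not-band-4 call) meets its
#' target; `t2` is their midpoint. Thresholds are snapped to midpoints
#' between adjacent observed scores. When a target is unachievable the
#' widest feasible band is used and flagged (`feasible = FALSE`); when the
#' two maximal bands overlap (scores well separated relative to the
#' targets) the thresholds are recentred at the overlap midpoint, which
#' preserves both targets.
#'
#' @param scores training scores in \[0,1\] for one class.
#' @param labels logical, `TRUE` = that class (positives).
#' @param band1_sensitivity_target percent, default 98.
#' @param band4_specificity_target percent, default 92.
#' @return list of class `band_config`: `t1`, `t2`, `t3`, targets, and
#'   per-threshold `feasible` flags.
#' @export
fit_band_thresholds <- function(scores, labels,
                                band1_sensitivity_target = 98,
                                band4_specificity_target = 92) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop_ps("both positives and negatives are required to fit thresholds")
  u <- sort(unique(scores))
  cand <- (u[-length(u)] + u[-1]) / 2
  cand <- unique(c(u[1] / 2, cand, (u[length(u)] + 1) / 2))
  cand <- cand[cand > 0 & cand < 1]
  if (length(cand) == 0) stop_ps("degenerate scores: no usable thresholds")

  sens <- vapply(cand, function(t) 100 * mean(scores[labels] >= t), numeric(1))
  spc <- vapply(cand, function(t) 100 * mean(scores[!labels] < t), numeric(1))

  ok1 <- sens >= band1_sensitivity_target
  feas1 <- any(ok1)
  t1 <- if (feas1) max(cand[ok1]) else min(cand)
  ok3 <- spc >= band4_specificity_target
  feas3 <- any(ok3)
  t3 <- if (feas3) min(cand[ok3]) else max(cand)
  if (t1 >= t3) {
    # the maximal rule-out and rule-in bands overlap (scores well separated
    # relative to the targets); recentre at the overlap midpoint, which keeps
    # both targets satisfied since sensitivity is monotone decreasing and
    # specificity monotone increasing in the threshold
    mid <- (t1 + t3) / 2
    lo <- cand[cand <= mid & ok1]
    hi <- cand[cand > mid & ok3]
    if (length(lo) == 0 || length(hi) == 0)
      stop_ps(paste0("band thresholds cross (t1 = %.4f >= t3 = %.4f) and no ",
                     "intermediate score separates them; bands cannot be fit"),
              t1, t3)
    t1 <- max(lo)
    t3 <- min(hi)
  }
  structure(list(t1 = t1, t2 = (t1 + t3) / 2, t3 = t3,
                 band1_sensitivity_target = band1_sensitivity_target,
                 band4_specificity_target = band4_specificity_target,
                 feasible = c(t1 = feas1, t3 = feas3)),
            class = "band_config")
}

band_of <- function(scores, cfg) {
  findInterval(scores, c(cfg$t1, cfg$t2, cfg$t3)) + 1L
}

#' Band-based clinical metrics for one class on one dataset
#'
#' Computes the per-class clinical metric block: one-vs-rest AUROC, the
#' band-1 (rule-out) likelihood ratio `LR- = P(band1|pos)/P(band1|neg)`,
#' the percent of all samples in band 1, band-1 sensitivity
#' (`100 * P(bands 2-4 | pos)`), the band-4 (rule-in) likelihood ratio
#' `LR+ = P(band4|pos)/P(band4|neg)` (infinite when no negative reaches
#' band 4), the percent of samples in band 4, and band-4 specificity
#' (`100 * P(bands 1-3 | neg)`). Band fractions over the four bands sum to
#' 100 and satisfy the prevalence identity
#' `fraction_b/100 = pi * P(b|pos) + (1 - pi) * P(b|neg)`.
#'
#' @param scores one-vs-rest scores in \[0,1\].
#' @param labels logical, `TRUE` = positive class.
#' @param cfg a `band_config` (typically fit on training scores and frozen
#'   for validation).
#' @return list of class `band_metrics`: `auroc`, `lr_minus`, `fraction1`,
#'   `band1_sensitivity`, `lr_plus`, `fraction4`, `band4_specificity`,
#'   `fractions` (all four bands, %), `prevalence`.
#' @export
compute_band_metrics <- function(scores, labels, cfg) {
  stopifnot(inherits(cfg, "band_config"))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop_ps("both positives and negatives are required")
  b <- band_of(scores, cfg)
  p_pos <- tabulate(b[labels], 4) / sum(labels)
  p_neg <- tabulate(b[!labels], 4) / sum(!labels)
  frac <- 100 * tabulate(b, 4) / length(b)

  structure(list(
    auroc = auroc(scores, labels),
    lr_minus = p_pos[1] / p_neg[1],
    fraction1 = frac[1],
    band1_sensitivity = 100 * (1 - p_pos[1]),
    lr_plus = p_pos[4] / p_neg[4],
    fraction4 = frac[4],
    band4_specificity = 100 * (1 - p_neg[4]),
    fractions = frac,
    prevalence = mean(labels)
  ), class = "band_metrics")
}

#' @export
print.band_metrics <- function(x, ...) {
  fmt <- function(v) ifelse(is.infinite(v), "Inf", sprintf("%.3f", v))
  cat(sprintf(
    "AUROC %.3f | LR- %s, band1 %.1f%% of samples, band1 sens %.1f%% | LR+ %s, band4 %.1f%% of samples, band4 spec %.1f%%\n",
    x$auroc, fmt(x$lr_minus), x$fraction1, x$band1_sensitivity,
    fmt(x$lr_plus), x$fraction4, x$band4_specificity))
  invisible(x)
}

#' Band fraction implied by prevalence, likelihood ratio and band rate
#'
#' The band fractions, likelihood ratios and sensitivities/specificities of
#' the four-band framework are linked by the mixture identity
#' `fraction_b/100 = pi * P(b|pos) + (1 - pi) * P(b|neg)`. For the rule-in
#' band, `P(4|neg) = 1 - specificity/100` and `P(4|pos) = LR+ * P(4|neg)`,
#' so `fraction4 = 100 * (1 - spec/100) * (pi * LR+ + 1 - pi)`. For the
#' rule-out band, `P(1|pos) = 1 - sensitivity/100` and
#' `P(1|neg) = P(1|pos)/LR-`. This reconstructs a band fraction from the
#' three published quantities without access to per-sample scores.
#'
#' @param prevalence positive-class prevalence `pi` in \[0,1\].
#' @param lr the band's likelihood ratio (LR+ for `"rule_in"`, LR- for
#'   `"rule_out"`).
#' @param rate_pct band-4 specificity (`"rule_in"`) or band-1 sensitivity
#'   (`"rule_out"`), in percent.
#' @param band `"rule_in"` (band 4) or `"rule_out"` (band 1).
#' @return the implied band fraction, percent of all samples.
#' @export
#' @examples
#' band_fraction_identity(1028 / 3159, 7.5, 95.0)  # 15.6
band_fraction_identity <- function(prevalence, lr, rate_pct,
                                   band = c("rule_in", "rule_out")) {
  band <- match.arg(band)
  if (prevalence < 0 || prevalence > 1) stop_ps("prevalence must be in [0,1]")
  q <- 1 - rate_pct / 100          # band rate in the reference group
  if (band == "rule_in") {
    100 * q * (prevalence * lr + 1 - prevalence)
  } else {
    100 * (prevalence * q + (1 - prevalence) * q / lr)
  }
}

#' Evaluate a locked panel with cross-validated training metrics
#'
#' Trains the spec's classifier on the training split restricted to the
#' panel and produces the clinical metric block for the bacterial and viral
#' classes on both splits. Training metrics are computed from out-of-fold
#' cross-validation scores (each sample scored by a model that never saw
#' it); band thresholds are fit on those training scores and frozen before
#' the validation split is scored by the final model trained on all
#' training data.
#'
#' @param panel character vector of marker names.
#' @param x_train,x_val normalized expression matrices.
#' @param y_train,y_val class labels.
#' @param spec a [classifier_spec()].
#' @param band1_sensitivity_target,band4_specificity_target threshold-fitting
#'   targets in percent.
#' @param cv_folds folds for the training-score cross-validation.
#' @param cohorts optional training cohort ids for fold construction.
#' @return object of class `panel_evaluation`: `metrics` (long data.frame:
#'   class, dataset, metric, value), `bands` (per-class `band_config`),
#'   `model` (the final `triage_classifier`), `scores` (per-sample
#'   probability triplets per split).
#' @export
evaluate_panel <- function(panel, x_train, y_train, x_val, y_val,
                           spec = classifier_spec(),
                           band1_sensitivity_target = 98,
                           band4_specificity_target = 92,
                           cv_folds = 5, cohorts = NULL) {
  y_tr <- as_class_factor(y_train)
  y_va <- as_class_factor(y_val)
  xt <- as.matrix(x_train)[, panel, drop = FALSE]
  xv <- as.matrix(x_val)[, panel, drop = FALSE]

  folds <- make_cv_folds(y_tr, cohorts, k = cv_folds, seed = spec$seed)
  oof <- matrix(NA_real_, nrow(xt), 3,
                dimnames = list(rownames(xt), TRIAGE_CLASSES))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    m <- train_classifier(xt[tr, , drop = FALSE], y_tr[tr], spec)
    oof[!tr, ] <- predict(m, xt[!tr, , drop = FALSE])
  }
  model <- train_classifier(xt, y_tr, spec)
  val_scores <- predict(model, xv)

  bands <- list()
  rows <- list()
  for (cl in c("bacterial", "viral")) {
    cfg <- fit_band_thresholds(oof[, cl], y_tr == cl,
                               band1_sensitivity_target,
                               band4_specificity_target)
    bands[[cl]] <- cfg
    for (ds in c("train", "validation")) {
      bm <- if (ds == "train")
        compute_band_metrics(oof[, cl], y_tr == cl, cfg)
      else
        compute_band_metrics(val_scores[, cl], y_va == cl, cfg)
      vals <- c(auroc = bm$auroc, lr_minus = bm$lr_minus,
                fraction1 = bm$fraction1,
                band1_sensitivity = bm$band1_sensitivity,
                lr_plus = bm$lr_plus, fraction4 = bm$fraction4,
                band4_specificity = bm$band4_specificity)
      rows[[paste(cl, ds)]] <- data.frame(
        class = cl, dataset = ds, metric = names(vals),
        value = unname(vals), stringsAsFactors = FALSE)
    }
  }
  structure(list(metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
                 bands = bands, model = model,
                 scores = list(train = oof, validation = val_scores),
                 panel = panel),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  w <- stats::reshape(x$metrics, direction = "wide",
                      idvar = c("class", "metric"), timevar = "dataset")
  names(w) <- sub("^value\\.", "", names(w))
  w$train <- round(w$train, 3)
  w$validation <- round(w$validation, 3)
  cat(sprintf("Panel evaluation (%d markers)\n", length(x$panel)))
  print(w, row.names = FALSE)
  invisible(x)
}
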