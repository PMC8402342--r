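#' Direction codes for the 29-mRNA host-response signature
#'
#' The 29 mRNAs of the InSep bacterial/viral/noninfected signature with their
#' expression direction in three class contrasts: bacterial infection vs.
#' uninfected control (`dir_bi_uc`), viral infection vs. uninfected control
#' (`dir_vi_uc`), and bacterial vs. viral infection (`dir_bi_vi`). Codes are
#' `up_strong`, `up`, `down`, `down_strong` (strength of the relative change
#' on the fold-change scale) or `none`.
#'
#' @return A data.frame with columns `marker`, `dir_bi_uc`, `dir_vi_uc`,
#'   `dir_bi_vi`.
#' @export
#' @examples
#' head(insep29_directions())
insep29_directions <- function() {
  raw <- c(
    "ARG1",    "up_strong",   "up",        "up",
    "BATF",    "up_strong",   "up",        "up",
    "C3AR1",   "up_strong",   "up",        "up",
    "CD163",   "up_strong",   "up",        "up",
    "CEACAM1", "up_strong",   "up",        "up",
    "CTSB",    "up_strong",   "up",        "up",
    "CTSL",    "up_strong",   "up",        "up",
    "DEFA4",   "up_strong",   "up",        "up",
    "FAM214A", "down_strong", "down",      "down",
    "FURIN",   "up_strong",   "up",        "up",
    "GADD45A", "up_strong",   "up",        "up",
    "GNA15",   "up_strong",   "up",        "up",
    "HK3",     "up_strong",   "up",        "up",
    "HLA-DMB", "down_strong", "down",      "down",
    "IFI27",   "up",          "up_strong", "down",
    "ISG15",   "down",        "up",        "down",
    "JUP",     "down",        "up",        "down",
    "KCNJ2",   "up_strong",   "up",        "up",
    "LY86",    "down",        "up",        "down",
    "NMRK1",   "up_strong",   "up",        "up",
    "OASL",    "up",          "up_strong", "down",
    "OLFM4",   "up_strong",   "up",        "up",
    "PDE4B",   "down_strong", "down",      "down",
    "PER1",    "up_strong",   "down",      "up",
    "PSMB9",   "down",        "up",        "down",
    "RAPGEF1", "down_strong", "down",      "down",
    "S100A12", "up_strong",   "up",        "up",
    "TGFBI",   "down_strong", "down",      "down",
    "ZDHHC19", "up_strong",   "up",        "up"
  )
  m <- matrix(raw, ncol = 4, byrow = TRUE)
  data.frame(marker = m[, 1], dir_bi_uc = m[, 2], dir_vi_uc = m[, 3],
             dir_bi_vi = m[, 4], stringsAsFactors = FALSE)
}

#' Default direction-to-log2-fold-change magnitude map
#'
#' Maps the qualitative direction codes to signed log2 fold changes. The
#' published contrasts give directions, not magnitudes; these defaults
#' (strong = 1.5, moderate = 0.75 log2 units, i.e. ~2.8x and ~1.7x) are
#' configuration, chosen so that abundance/dynamic-range filters and
#' classifiers are exercised at realistic effect sizes.
#'
#' @return Named numeric vector over the five direction codes.
#' @export
default_magnitude_map <- function() {
  c(up_strong = 1.5, up = 0.75, down = -0.75, down_strong = -1.5, none = 0)
}

#' Build a per-marker effect table from a manifest of direction codes
#'
#' Materializes signed log2-fold-change effects for the bacterial-vs-control
#' and viral-vs-control contrasts from qualitative direction codes. When the
#' manifest also codes the bacterial-vs-viral contrast, consistency of
#' `sign(bi_uc - vi_uc)` with that code is checked.
#'
#' @param manifest data.frame with columns `marker`, `dir_bi_uc`,
#'   `dir_vi_uc`, optionally `dir_bi_vi`. Arrow glyphs or code names accepted.
#' @param magnitude_map named numeric vector mapping every direction code to
#'   a signed log2 fold change; see [default_magnitude_map()].
#' @return data.frame of class `effect_table` with columns `marker`,
#'   `dir_bi_uc`, `dir_vi_uc`, `lfc_bi_uc`, `lfc_vi_uc`.
#' @export
#' @examples
#' eff <- build_effect_table(insep29_directions())
#' eff[eff$marker == "ARG1", ]
build_effect_table <- function(manifest,
                               magnitude_map = default_magnitude_map()) {
  need <- c("marker", "dir_bi_uc", "dir_vi_uc")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0)
    stop_ps("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$marker))
    stop_ps("duplicated marker(s) in manifest: %s",
            paste(unique(manifest$marker[duplicated(manifest$marker)]),
                  collapse = ", "))
  if (!all(DIRECTION_CODES %in% names(magnitude_map)))
    stop_ps("magnitude_map must cover all codes: %s",
            paste(DIRECTION_CODES, collapse = ", "))

  decode <- function(col) {
    code <- normalize_direction(manifest[[col]])
    bad <- which(is.na(code) | !(code %in% DIRECTION_CODES))
    if (length(bad) > 0)
      stop_ps("unknown direction code '%s' for marker '%s' in %s",
              as.character(manifest[[col]][bad[1]]),
              manifest$marker[bad[1]], col)
    code
  }
  d_bi <- decode("dir_bi_uc")
  d_vi <- decode("dir_vi_uc")

  out <- data.frame(
    marker    = as.character(manifest$marker),
    dir_bi_uc = d_bi,
    dir_vi_uc = d_vi,
    lfc_bi_uc = unname(magnitude_map[d_bi]),
    lfc_vi_uc = unname(magnitude_map[d_vi]),
    stringsAsFactors = FALSE
  )

  if ("dir_bi_vi" %in% names(manifest)) {
    d_bv <- normalize_direction(manifest$dir_bi_vi)
    known <- !is.na(d_bv) & d_bv %in% DIRECTION_CODES
    coded_sign <- ifelse(grepl("^up", d_bv), 1, ifelse(grepl("^down", d_bv), -1, 0))
    implied <- sign(out$lfc_bi_uc - out$lfc_vi_uc)
    bad <- which(known & coded_sign != implied)
    if (length(bad) > 0)
      stop_ps(paste0("bacterial-vs-viral direction inconsistent with the two ",
                     "control contrasts for marker '%s' (coded %s, implied sign %d)"),
              out$marker[bad[1]], d_bv[bad[1]], implied[bad[1]])
  }
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Simulation configuration for synthetic multi-cohort studies
#'
#' Describes a 3-class (bacterial / viral / noninfected), multi-cohort
#' expression study on the copy-number scale. Expression is generated as
#' `2^(baseline + class effect + cohort shift + residual noise)` and clamped
#' at a detection floor, emulating a heterogeneous multi-cohort compendium
#' with separate training and validation cohorts.
#'
#' @param n_cohorts number of cohorts.
#' @param samples_per_class_per_cohort samples per class within each cohort.
#' @param n_noise_markers uninformative markers added (named `NOISE###`).
#' @param baseline_log2_median center of per-marker baseline log2 abundance.
#' @param baseline_log2_sd spread of per-marker baselines (log2 units).
#' @param cohort_batch_sd sd of per-cohort, per-marker batch shifts (log2).
#' @param residual_noise_sd sd of per-sample residual noise (log2).
#' @param detection_floor minimum reportable copy number; values clamped.
#' @param housekeeping_markers names of stable reference markers (zero effect
#'   in every contrast).
#' @param seed integer master seed; per-cohort substreams are derived from it.
#' @param split_assignment character vector of `"train"`/`"validation"`,
#'   length `n_cohorts`, mapping each cohort to a split.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 6,
                       samples_per_class_per_cohort = 30,
                       n_noise_markers = 0,
                       baseline_log2_median = 10,
                       baseline_log2_sd = 1.5,
                       cohort_batch_sd = 0.5,
                       residual_noise_sd = 1,
                       detection_floor = 1,
                       housekeeping_markers = c("HKG1", "HKG2", "HKG3"),
                       seed = 1,
                       split_assignment = NULL) {
  assert_scalar_number(n_cohorts, "n_cohorts", min = 1)
  assert_scalar_number(samples_per_class_per_cohort,
                       "samples_per_class_per_cohort", min = 1)
  assert_scalar_number(n_noise_markers, "n_noise_markers", min = 0)
  assert_scalar_number(baseline_log2_sd, "baseline_log2_sd", min = 0)
  assert_scalar_number(cohort_batch_sd, "cohort_batch_sd", min = 0)
  assert_scalar_number(residual_noise_sd, "residual_noise_sd", min = 0)
  assert_scalar_number(detection_floor, "detection_floor", min = 0)
  assert_scalar_number(seed, "seed")

  if (is.null(split_assignment)) {
    n_val <- max(1L, round(n_cohorts / 3))
    split_assignment <- rep(c("train", "validation"),
                            c(n_cohorts - n_val, n_val))
  }
  if (length(split_assignment) != n_cohorts)
    stop_ps("split_assignment must have length n_cohorts (%d)", n_cohorts)
  if (!all(split_assignment %in% c("train", "validation")))
    stop_ps("split_assignment values must be 'train' or 'validation'")
  if (!any(split_assignment == "train"))
    stop_ps("no cohort assigned to the 'train' split")
  if (!any(split_assignment == "validation"))
    stop_ps("no cohort assigned to the 'validation' split")

  structure(list(
    n_cohorts = as.integer(n_cohorts),
    samples_per_class_per_cohort = as.integer(samples_per_class_per_cohort),
    n_noise_markers = as.integer(n_noise_markers),
    baseline_log2_median = baseline_log2_median,
    baseline_log2_sd = baseline_log2_sd,
    cohort_batch_sd = cohort_batch_sd,
    residual_noise_sd = residual_noise_sd,
    detection_floor = detection_floor,
    housekeeping_markers = as.character(housekeeping_markers),
    seed = as.integer(seed),
    split_assignment = split_assignment
  ), class = "sim_config")
}

#' Simulate a synthetic multi-cohort 3-class expression study
#'
#' Generates copy-number-scale expression for every marker in the effect
#' table, plus configured housekeeping and noise markers, across
#' `n_cohorts` cohorts with `samples_per_class_per_cohort` samples for each
#' of the bacterial, viral and noninfected classes. Log2 expression is
#' baseline + class effect + cohort batch shift + residual noise; copies are
#' `2^log2` clamped at `detection_floor`. Identical configurations and seeds
#' reproduce identical studies; each cohort draws from its own deterministic
#' substream, so relabeling cohorts does not change the pooled values.
#'
#' @param config a [sim_config()].
#' @param effects an `effect_table` from [build_effect_table()]. Markers
#'   absent from it (noise, housekeeping) get zero effect in every contrast.
#' @return list of class `sim_study` with elements `expression` (samples x
#'   markers numeric matrix, copies), `annotation` (data.frame: `sample_id`,
#'   `class`, `cohort_id`, `split`), `config`, `effects`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_cohorts = 2,
#'                                    samples_per_class_per_cohort = 5),
#'                         build_effect_table(insep29_directions()))
#' dim(study$expression)
simulate_study <- function(config, effects) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(effects, "effect_table"))
    stop_ps("'effects' must be an effect_table from build_effect_table()")

  hk <- config$housekeeping_markers
  hk_coded <- intersect(hk, effects$marker)
  if (length(hk_coded) > 0) {
    nz <- hk_coded[effects$lfc_bi_uc[match(hk_coded, effects$marker)] != 0 |
                   effects$lfc_vi_uc[match(hk_coded, effects$marker)] != 0]
    if (length(nz) > 0)
      stop_ps("housekeeping marker(s) with nonzero effect: %s",
              paste(nz, collapse = ", "))
  }

  noise <- if (config$n_noise_markers > 0)
    sprintf("NOISE%03d", seq_len(config$n_noise_markers)) else character(0)
  markers <- unique(c(effects$marker, hk, noise))
  M <- length(markers)

  lfc_bi <- lfc_vi <- setNames(numeric(M), markers)
  idx <- match(effects$marker, markers)
  lfc_bi[idx] <- effects$lfc_bi_uc
  lfc_vi[idx] <- effects$lfc_vi_uc
  class_effect <- cbind(bacterial = lfc_bi, viral = lfc_vi,
                        noninfected = 0)

  # marker baselines from the master seed, cohort draws from substreams
  set.seed(config$seed)
  baseline <- stats::rnorm(M, config$baseline_log2_median,
                           config$baseline_log2_sd)

  n <- config$samples_per_class_per_cohort
  rows_per_cohort <- n * 3L
  N <- config$n_cohorts * rows_per_cohort
  expr <- matrix(NA_real_, N, M, dimnames = list(NULL, markers))
  sample_id <- character(N)
  class_lab <- character(N)
  cohort_lab <- character(N)
  split_lab <- character(N)

  abbrev <- c(bacterial = "B", viral = "V", noninfected = "N")
  for (c_i in seq_len(config$n_cohorts)) {
    set.seed((config$seed * 1009L + 7919L * c_i) %% .Machine$integer.max)
    batch <- stats::rnorm(M, 0, config$cohort_batch_sd)
    row0 <- (c_i - 1L) * rows_per_cohort
    for (k in seq_along(TRIAGE_CLASSES)) {
      cl <- TRIAGE_CLASSES[k]
      eps <- matrix(stats::rnorm(n * M, 0, config$residual_noise_sd), n, M)
      log2val <- sweep(eps, 2, baseline + class_effect[, cl] + batch, "+")
      rows <- row0 + (k - 1L) * n + seq_len(n)
      expr[rows, ] <- pmax(2^log2val, config$detection_floor)
      sample_id[rows] <- sprintf("C%02d_%s%03d", c_i, abbrev[cl], seq_len(n))
      class_lab[rows] <- cl
      cohort_lab[rows] <- sprintf("cohort%02d", c_i)
      split_lab[rows] <- config$split_assignment[c_i]
    }
  }
  rownames(expr) <- sample_id

  annotation <- data.frame(sample_id = sample_id, class = class_lab,
                           cohort_id = cohort_lab, split = split_lab,
                           stringsAsFactors = FALSE)
  structure(list(expression = expr, annotation = annotation,
                 config = config, effects = effects),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  a <- x$annotation
  cat(sprintf("Synthetic expression study: %d samples x %d markers\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  cohorts: %d (%d train / %d validation)\n",
              length(unique(a$cohort_id)),
              length(unique(a$cohort_id[a$split == "train"])),
              length(unique(a$cohort_id[a$split == "validation"]))))
  print(table(class = a$class, split = a$split))
  invisible(x)
}
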