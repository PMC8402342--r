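#' Per-marker abundance percentile summary
#'
#' Computes, per marker and pooled over all samples, the median, 5th and
#' 95th percentiles of copy-number abundance and the dynamic range
#' p95/p5. Percentiles use the linear-interpolation definition
#' (`stats::quantile` type 7) so results are reproducible bit-for-bit.
#' A marker whose 5th percentile is zero gets an infinite dynamic range:
#' spanning zero to high copies is maximally dynamic (whether it is usable
#' is decided by the abundance rule, not here).
#'
#' @param mat samples x markers copy-number matrix (raw copies, not
#'   normalized: the abundance rule is stated in copy space).
#' @return data.frame of class `marker_stats`: `marker`, `p5`, `median`,
#'   `p95`, `dynamic_range`.
#' @export
#' @examples
#' m <- matrix(rep(1:100, 2), 100, 2, dimnames = list(NULL, c("a", "b")))
#' compute_marker_stats(m)
compute_marker_stats <- function(mat) {
  if (nrow(mat) < 20)
    stop_ps("need >= 20 samples for stable percentiles (got %d)", nrow(mat))
  q <- apply(mat, 2, stats::quantile, probs = c(0.05, 0.5, 0.95),
             type = 7, names = FALSE)
  out <- data.frame(marker = colnames(mat), p5 = q[1, ], median = q[2, ],
                    p95 = q[3, ], row.names = NULL, stringsAsFactors = FALSE)
  out$dynamic_range <- ifelse(out$p5 > 0, out$p95 / out$p5, Inf)
  class(out) <- c("marker_stats", "data.frame")
  out
}

#' Filter thresholds for the two-step marker exclusion
#'
#' The abundance rule excludes markers whose 95th percentile is below
#' `min_p95_copies` (default 400 copies = a 100-copy minimum times the
#' 4-fold resolution requirement); the dynamic-range rule then excludes
#' markers whose p95/p5 fold change is below `min_dynamic_fold` (default 4).
#' Survivors with dynamic range at or above `tier1_fold` (default 5) rank
#' Tier 1, the rest Tier 2.
#'
#' @param min_p95_copies abundance threshold (copies), exclusive below.
#' @param min_dynamic_fold dynamic-range threshold (fold), exclusive below.
#' @param tier1_fold Tier-1 dynamic-range cut (fold), inclusive at.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_p95_copies = 400, min_dynamic_fold = 4,
                          tier1_fold = 5) {
  assert_scalar_number(min_p95_copies, "min_p95_copies", min = 0)
  assert_scalar_number(min_dynamic_fold, "min_dynamic_fold", min = 0)
  assert_scalar_number(tier1_fold, "tier1_fold", min = min_dynamic_fold)
  if (min_p95_copies <= 0) stop_ps("min_p95_copies must be > 0")
  structure(list(min_p95_copies = min_p95_copies,
                 min_dynamic_fold = min_dynamic_fold,
                 tier1_fold = tier1_fold),
            class = "filter_config")
}

#' Two-step marker exclusion with tier ranking and gDNA screen
#'
#' Applies the exclusion rules in order: (1) abundance — a marker with 95th
#' percentile below `min_p95_copies` is excluded (`low_abundance`);
#' (2) dynamic range — a surviving marker with p95/p5 below
#' `min_dynamic_fold` is excluded (`low_dynamic_range`); (3) a surviving
#' marker that failed the wet-lab genomic-DNA screen is excluded
#' (`gdna_fail`). Survivors are ranked Tier 1 (dynamic range >=
#' `tier1_fold`) or Tier 2. Exactly one exclusion reason is recorded, the
#' first rule that fired.
#'
#' @param stats a `marker_stats` data.frame from [compute_marker_stats()].
#' @param cfg a [filter_config()].
#' @param gdna_pass named logical vector over exactly the same markers;
#'   `TRUE` means the marker amplifies mRNA only.
#' @return data.frame of class `filter_result`: the stats columns plus
#'   `passed_abundance`, `passed_dynamic`, `gdna_pass`, `tier` (`"1"`,
#'   `"2"`, `"excluded"`), `excluded_reason` (`low_abundance`,
#'   `low_dynamic_range`, `gdna_fail`, `none`).
#' @export
apply_two_step_exclusion <- function(stats, cfg = filter_config(),
                                     gdna_pass = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  if (is.null(gdna_pass))
    gdna_pass <- setNames(rep(TRUE, nrow(stats)), stats$marker)
  if (!setequal(names(gdna_pass), stats$marker))
    stop_ps("gdna_pass flags and stats cover different markers")
  g <- as.logical(gdna_pass[stats$marker])

  passed_abundance <- stats$p95 >= cfg$min_p95_copies
  passed_dynamic <- stats$dynamic_range >= cfg$min_dynamic_fold

  reason <- rep("none", nrow(stats))
  reason[!passed_abundance] <- "low_abundance"
  reason[passed_abundance & !passed_dynamic] <- "low_dynamic_range"
  reason[passed_abundance & passed_dynamic & !g] <- "gdna_fail"

  tier <- rep("excluded", nrow(stats))
  keep <- reason == "none"
  tier[keep & stats$dynamic_range >= cfg$tier1_fold] <- "1"
  tier[keep & stats$dynamic_range < cfg$tier1_fold] <- "2"

  out <- data.frame(stats, passed_abundance = passed_abundance,
                    passed_dynamic = passed_dynamic, gdna_pass = g,
                    tier = tier, excluded_reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("filter_result", "data.frame")
  out
}

#' Assemble the candidate pool from filter survivors
#'
#' Unions the surviving (tiered) markers of the original panel and of the
#' alternative candidates into one deterministic, ordered pool: Tier 1
#' before Tier 2, then descending dynamic range, then marker name.
#'
#' @param original_result `filter_result` for the original panel markers.
#' @param alternative_result optional `filter_result` for alternative
#'   candidates; marker sets must be disjoint from the original's.
#' @return character vector of marker ids (the ordered pool).
#' @export
assemble_candidate_pool <- function(original_result,
                                    alternative_result = NULL) {
  res <- original_result
  if (!is.null(alternative_result)) {
    overlap <- intersect(original_result$marker, alternative_result$marker)
    if (length(overlap) > 0)
      stop_ps("original and alternative marker sets overlap: %s",
              paste(overlap, collapse = ", "))
    res <- rbind(original_result, alternative_result)
  }
  surv <- res[res$tier %in% c("1", "2"), ]
  if (nrow(surv) == 0) stop_ps("no marker survived the filters; pool is empty")
  surv <- surv[order(surv$tier, -surv$dynamic_range, surv$marker), ]
  surv$marker
}
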