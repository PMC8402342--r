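# shared fixtures built in code

# small manifest: a few signature markers + housekeeping
toy_manifest <- function() {
  m <- insep29_directions()
  m <- m[m$marker %in% c("ARG1", "IFI27", "ISG15", "PER1", "DEFA4",
                         "LY86"), ]
  data.frame(marker = m$marker, role = "original", gdna_pass = TRUE,
             dir_bi_uc = m$dir_bi_uc, dir_vi_uc = m$dir_vi_uc,
             dir_bi_vi = m$dir_bi_vi, stringsAsFactors = FALSE)
}

toy_study <- function(n = 20, n_cohorts = 3, seed = 42, ...) {
  simulate_study(
    sim_config(n_cohorts = n_cohorts, samples_per_class_per_cohort = n,
               seed = seed, ...),
    build_effect_table(toy_manifest()))
}

# planted design: n_info strongly informative markers among noise markers,
# plus housekeeping; returns normalized train/val matrices and labels
planted_design <- function(n_info = 5, n_noise = 45, n_per_class = 300,
                           seed = 1, lfc = 1.5, n_cohorts = 6,
                           residual_noise_sd = 1) {
  # planted effects at +/- lfc in BOTH disease contrasts, with opposite
  # signs, so each informative marker separates all three classes
  info <- sprintf("INFO%02d", seq_len(n_info))
  manifest <- data.frame(marker = info,
                         dir_bi_uc = rep_len(c("up_strong", "down_strong"),
                                             n_info),
                         dir_vi_uc = rep_len(c("down_strong", "up_strong"),
                                             n_info),
                         stringsAsFactors = FALSE)
  eff <- build_effect_table(manifest,
                            magnitude_map = c(up_strong = lfc, up = lfc / 2,
                                              down = -lfc / 2,
                                              down_strong = -lfc, none = 0))
  n_val <- max(1L, round(n_cohorts / 3))
  cfg <- sim_config(
    n_cohorts = n_cohorts,
    samples_per_class_per_cohort = ceiling(n_per_class / (n_cohorts - n_val)),
    n_noise_markers = n_noise, seed = seed,
    residual_noise_sd = residual_noise_sd,
    split_assignment = rep(c("train", "validation"),
                           c(n_cohorts - n_val, n_val)))
  study <- simulate_study(cfg, eff)
  norm <- normalize_to_housekeepers(study$expression,
                                    cfg$housekeeping_markers)
  tr <- study$annotation$split == "train"
  list(informative = info,
       noise = grep("^NOISE", colnames(norm), value = TRUE),
       x_train = norm[tr, , drop = FALSE],
       y_train = study$annotation$class[tr],
       cohorts = study$annotation$cohort_id[tr],
       x_val = norm[!tr, , drop = FALSE],
       y_val = study$annotation$class[!tr])
}

# brute-force one-vs-rest AUROC by O(n^2) pair counting
pair_count_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}
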