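#' Demo marker manifest for the packaged pipeline
#'
#' The 29-marker signature (role `original`) together with `n_alternatives`
#' synthetic alternative candidates (random direction codes, seeded) and
#' the housekeeping references. All markers pass the gDNA screen except
#' those named in `gdna_fail`.
#'
#' @param n_alternatives number of synthetic alternative markers.
#' @param housekeeping_markers reference marker names.
#' @param gdna_fail markers flagged as failing the genomic-DNA screen.
#' @param seed seed for the alternatives' direction codes.
#' @return manifest data.frame (`marker`, `role`, `gdna_pass`, `dir_bi_uc`,
#'   `dir_vi_uc`).
#' @export
demo_manifest <- function(n_alternatives = 25,
                          housekeeping_markers = c("HKG1", "HKG2", "HKG3"),
                          gdna_fail = character(0), seed = 1) {
  orig <- insep29_directions()
  orig <- data.frame(marker = orig$marker, role = "original",
                     gdna_pass = TRUE, dir_bi_uc = orig$dir_bi_uc,
                     dir_vi_uc = orig$dir_vi_uc, stringsAsFactors = FALSE)
  set.seed(seed)
  alt <- data.frame(
    marker = sprintf("ALT%03d", seq_len(n_alternatives)),
    role = "alternative", gdna_pass = TRUE,
    dir_bi_uc = sample(c("up_strong", "up", "down", "down_strong"),
                       n_alternatives, replace = TRUE),
    dir_vi_uc = sample(c("up", "down", "none"), n_alternatives,
                       replace = TRUE),
    stringsAsFactors = FALSE)
  hk <- data.frame(marker = housekeeping_markers, role = "housekeeping",
                   gdna_pass = TRUE, dir_bi_uc = "none", dir_vi_uc = "none",
                   stringsAsFactors = FALSE)
  out <- rbind(orig, alt, hk)
  out$gdna_pass <- !(out$marker %in% gdna_fail)
  out
}

#' Assemble and validate a pipeline configuration
#'
#' Collects the stage configurations of the full pipeline (simulate ->
#' normalize -> qc -> select -> evaluate -> enrich) into one validated
#' object. Either a simulation block or paths to an expression matrix and
#' annotation must be supplied.
#'
#' @param output_dir directory for stage artifacts.
#' @param seed global seed; recorded in every output header and used to
#'   derive all stage seeds.
#' @param sim named list of [sim_config()] arguments, or `NULL` to start
#'   from files.
#' @param paths named list: `expression`, `annotation` (required when `sim`
#'   is NULL), optional `manifest`, `gmt`.
#' @param filter named list of [filter_config()] arguments.
#' @param pseudocount normalization pseudocount (copies).
#' @param selection named list of [selection_config()] arguments.
#' @param phase1,phase2 named lists of [model_spec()] arguments (family is
#'   fixed to logistic / mlp respectively).
#' @param classifier named list of [classifier_spec()] arguments.
#' @param band_targets list with `band1_sensitivity`, `band4_specificity`
#'   (percent).
#' @param n_alternatives alternatives in the generated demo manifest when
#'   no manifest path is given.
#' @return list of class `pipeline_config` with a `hash` attribute.
#' @export
pipeline_config <- function(output_dir = "panelswap_out", seed = 1,
                            sim = list(), paths = list(),
                            filter = list(), pseudocount = 1,
                            selection = list(phase1_size = 3,
                                             target_size = 5),
                            phase1 = list(), phase2 = list(),
                            classifier = list(),
                            band_targets = list(band1_sensitivity = 98,
                                                band4_specificity = 92),
                            n_alternatives = 25) {
  if (is.null(sim)) {
    for (p in c("expression", "annotation"))
      if (is.null(paths[[p]]))
        stop_ps("config error: paths$%s is required when sim is NULL", p)
  }
  for (p in intersect(names(paths), c("expression", "annotation",
                                      "manifest", "gmt")))
    if (!is.null(paths[[p]]) && !file.exists(paths[[p]]))
      stop_ps("config error: file not found: %s (paths$%s)", paths[[p]], p)
  cfg <- list(output_dir = output_dir, seed = as.integer(seed), sim = sim,
              paths = paths, filter = filter, pseudocount = pseudocount,
              selection = selection, phase1 = phase1, phase2 = phase2,
              classifier = classifier, band_targets = band_targets,
              n_alternatives = n_alternatives)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

# hash of the scientific configuration: where outputs land is irrelevant
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  object_md5(cfg[setdiff(names(cfg), "output_dir")])
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` configuration file whose top-level
#'   keys are [pipeline_config()] arguments.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_ps("config error: file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

stage_header <- function(config) {
  c(sprintf("config_hash: %s", attr(config, "hash")),
    sprintf("seed: %d", config$seed))
}

write_stage_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stage_header(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the panel-optimization pipeline end to end
#'
#' Executes, in order: `simulate` (when the config has a simulation block),
#' normalization, `qc` (two-step marker exclusion, tiering, pool assembly),
#' `select` (two-phase forward selection), `evaluate` (classifier training
#' and band metrics), and `enrich` (when a GMT path is configured). Every
#' artifact carries the config hash and seed in its header; a run manifest
#' with input/output md5 checksums makes reruns verifiable. Identical
#' config and seed produce identical artifacts.
#'
#' @param config a [pipeline_config()] (or path to a YAML/JSON config).
#' @param stages subset of stages to run (dependencies must already have
#'   their artifacts in `output_dir`).
#' @param seed optional override of the config seed.
#' @return invisibly, the artifact manifest (named list of paths) with the
#'   run-manifest path attached.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "qc", "select",
                                    "evaluate", "enrich"),
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    if (length(config$sim) > 0 || is.null(config$paths$expression))
      config$sim$seed <- config$seed
    attr(config, "hash") <- config_hash(config)
  }
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop_ps("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  path_of <- function(f) file.path(out, f)

  # manifest of markers (read or generated)
  manifest <- if (!is.null(config$paths$manifest))
    read_marker_manifest(config$paths$manifest)
  else demo_manifest(n_alternatives = config$n_alternatives,
                     seed = config$seed)
  hk <- manifest$marker[manifest$role == "housekeeping"]

  if ("simulate" %in% stages && !is.null(config$sim)) {
    run_stage("simulate", function() {
      sc_args <- utils::modifyList(list(seed = config$seed,
                                        housekeeping_markers = hk),
                                   config$sim)
      sc <- do.call(sim_config, sc_args)
      effects <- build_effect_table(manifest[manifest$role != "housekeeping", ])
      study <- simulate_study(sc, effects)
      write_expression_matrix(study$expression, path_of("expression.tsv"),
                              header_lines = stage_header(config))
      write_sample_annotation(study$annotation, path_of("annotation.tsv"),
                              header_lines = stage_header(config))
      art$expression <<- path_of("expression.tsv")
      art$annotation <<- path_of("annotation.tsv")
    })
  }

  expr_path <- art$expression %||% config$paths$expression %||%
    path_of("expression.tsv")
  anno_path <- art$annotation %||% config$paths$annotation %||%
    path_of("annotation.tsv")

  need_data <- any(c("qc", "select", "evaluate") %in% stages)
  if (need_data) {
    if (!file.exists(expr_path))
      stop_ps("stage input missing: expression matrix not found at %s",
              expr_path)
    if (!file.exists(anno_path))
      stop_ps("stage input missing: annotation not found at %s", anno_path)
    expr <- read_expression_matrix(expr_path)
    anno <- read_sample_annotation(anno_path)
    if (!setequal(anno$sample_id, rownames(expr)))
      stop_ps("annotation and expression matrix cover different samples")
    anno <- anno[match(rownames(expr), anno$sample_id), ]
    norm <- normalize_to_housekeepers(expr, intersect(hk, colnames(expr)),
                                      pseudocount = config$pseudocount)
    write_expression_matrix(norm, path_of("expression.norm.tsv"),
                            header_lines = stage_header(config))
    art$normalized <- path_of("expression.norm.tsv")
    is_tr <- anno$split == "train"
  }

  if ("qc" %in% stages) {
    run_stage("qc", function() {
      fc <- do.call(filter_config, config$filter)
      markers <- intersect(manifest$marker, colnames(expr))
      stats <- compute_marker_stats(expr[is_tr, markers, drop = FALSE])
      gd <- setNames(manifest$gdna_pass, manifest$marker)
      roles <- setNames(manifest$role, manifest$marker)
      res <- apply_two_step_exclusion(stats, fc, gd[markers])
      res_nohk <- res[roles[res$marker] != "housekeeping", ]
      orig <- res_nohk[roles[res_nohk$marker] == "original", ]
      altr <- res_nohk[roles[res_nohk$marker] == "alternative", ]
      pool <- assemble_candidate_pool(orig, if (nrow(altr) > 0) altr)
      write_stage_table(res, path_of("qc_result.tsv"), config)
      writeLines(c(paste0("# ", stage_header(config)), pool),
                 path_of("pool.txt"))
      art$qc <<- path_of("qc_result.tsv")
      art$pool <<- path_of("pool.txt")
    })
  }

  read_pool <- function() {
    l <- readLines(path_of("pool.txt"))
    l[!grepl("^#", l) & nzchar(l)]
  }
  read_panel <- function() {
    l <- readLines(path_of("panel.txt"))
    l[!grepl("^#", l) & nzchar(l)]
  }

  if ("select" %in% stages) {
    run_stage("select", function() {
      pool <- read_pool()
      sel_cfg <- do.call(selection_config, config$selection)
      p1 <- do.call(model_spec, utils::modifyList(
        list(family = "logistic", seed = config$seed), config$phase1))
      p2 <- do.call(model_spec, utils::modifyList(
        list(family = "mlp", seed = config$seed), config$phase2))
      sel <- run_two_phase_selection(
        norm[is_tr, , drop = FALSE], anno$class[is_tr],
        norm[!is_tr, , drop = FALSE], anno$class[!is_tr],
        pool, p1, p2, sel_cfg, cohorts = anno$cohort_id[is_tr])
      writeLines(c(paste0("# ", stage_header(config)), sel$panel),
                 path_of("panel.txt"))
      write_stage_table(sel$trace, path_of("trace.tsv"), config)
      art$panel <<- path_of("panel.txt")
      art$trace <<- path_of("trace.tsv")
    })
  }

  if ("evaluate" %in% stages) {
    run_stage("evaluate", function() {
      panel <- read_panel()
      cspec <- do.call(classifier_spec, utils::modifyList(
        list(seed = config$seed), config$classifier))
      ev <- evaluate_panel(panel,
                           norm[is_tr, , drop = FALSE], anno$class[is_tr],
                           norm[!is_tr, , drop = FALSE], anno$class[!is_tr],
                           cspec,
                           band1_sensitivity_target =
                             config$band_targets$band1_sensitivity,
                           band4_specificity_target =
                             config$band_targets$band4_specificity,
                           cohorts = anno$cohort_id[is_tr])
      write_stage_table(ev$metrics, path_of("evaluation.tsv"), config)
      js <- list(config_hash = attr(config, "hash"), seed = config$seed,
                 panel = panel,
                 thresholds = lapply(ev$bands, function(b)
                   b[c("t1", "t2", "t3")]),
                 scores = lapply(ev$scores, function(s)
                   data.frame(sample_id = rownames(s), s,
                              check.names = FALSE)))
      jsonlite::write_json(js, path_of("evaluation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      art$evaluation <<- path_of("evaluation.tsv")
      art$evaluation_json <<- path_of("evaluation.json")
    })
  }

  if ("enrich" %in% stages && !is.null(config$paths$gmt)) {
    run_stage("enrich", function() {
      coll <- read_gmt(config$paths$gmt)
      panel <- read_panel()
      res <- suppressWarnings(hypergeometric_enrichment(panel, coll))
      write_stage_table(res[, setdiff(names(res), "genes")],
                        path_of("enrichment.tsv"), config)
      art$enrichment <<- path_of("enrichment.tsv")
    })
  }

  inputs <- Filter(Negate(is.null),
                   config$paths[c("expression", "annotation", "manifest",
                                  "gmt")])
  manifest_json <- list(
    config_hash = attr(config, "hash"),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("panelswap")),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    artifacts = lapply(art, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest_json, path_of("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(art, "run_manifest") <- path_of("run_manifest.json")
  invisible(art)
}
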