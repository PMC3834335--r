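# Pipeline orchestration: config-driven wrappers around the package's
# fitting functions, writing TSV artifacts plus a JSON run manifest. These
# back the command-line interface in inst/scripts/fmcnet.

default_config <- function() list(
  seed = 1L,
  filter = list(min_reads_per_sample = 3000, drop_singletons = TRUE),
  sparcc = list(n_resamples = 20, exclusion_threshold = 0.1,
                max_exclusion_rounds = 10),
  network = list(beta = 4, min_module_size = 5, deep_split = 2,
                 transform = "log"),
  preservation = list(n_permutations = 100, correlation = "sparcc"),
  classifier = list(delta_grid = c(0, 0.25, 0.5, 0.75, 1.03, 1.25, 1.459, 2),
                    regions = c("descending", "rectum"), unit = "genus",
                    priors = "empirical"),
  simulate = list()
)

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, a YAML subset) key-value file; unspecified settings fall
#' back to the package defaults (beta 4, min module size 5, 100
#' preservation permutations, shrinkage presets 1.459 and 1.030 in the
#' classifier grid, LOOCV folds = number of subjects).
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return nested list of settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

write_manifest <- function(out_dir, stage, cfg, summaries) {
  cfg_file <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(stage = stage,
                   package_version = as.character(utils::packageVersion("fmcnet")),
                   seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = summaries)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.load_inputs <- function(cfg) {
  if (!is.null(cfg$input$counts)) {
    tab <- read_abundance_table(cfg$input$counts,
                                orientation = cfg$input$orientation %||% "genera_rows")
    md <- if (!is.null(cfg$input$metadata)) read_sample_metadata(cfg$input$metadata)
  } else {
    sim <- simulate_fmc(do.call(fmc_scenario, cfg$simulate %||% list()),
                        seed = cfg$seed)
    tab <- sim$table; md <- sim$metadata
  }
  list(table = tab, metadata = md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the module-discovery stage of the pipeline
#'
#' Loads (or simulates) a count table and metadata, fits the
#' co-occurrence network, and writes module assignments, eigengenus
#' scores, kME values, module-trait correlations and the per-genus
#' differential abundance report as TSV files plus a JSON run manifest.
#'
#' @param config a config list from [read_pipeline_config()] or a file
#'   path.
#' @param out_dir output directory (created if absent).
#' @return the fitted `fmc_network`, invisibly.
#' @export
run_discover <- function(config = NULL, out_dir = "fmcnet_out") {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else merge_config(default_config(), config %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- .load_inputs(cfg)
  fit <- fmc_network(inp$table, inp$metadata,
                     beta = cfg$network$beta,
                     min_module_size = cfg$network$min_module_size,
                     deep_split = cfg$network$deep_split,
                     transform = cfg$network$transform,
                     n_resamples = cfg$sparcc$n_resamples,
                     exclusion_threshold = cfg$sparcc$exclusion_threshold,
                     max_exclusion_rounds = cfg$sparcc$max_exclusion_rounds,
                     min_reads_per_sample = cfg$filter$min_reads_per_sample,
                     drop_singletons = cfg$filter$drop_singletons,
                     seed = cfg$seed)
  write_tsv(data.frame(genus_id = names(fit$modules$labels),
                       module = unname(fit$modules$labels)),
            file.path(out_dir, "modules.tsv"))
  write_tsv(data.frame(genus_id = rownames(fit$correlation$rho),
                       fit$correlation$rho, check.names = FALSE),
            file.path(out_dir, "sparcc_correlations.tsv"))
  if (!is.null(fit$eigengenus)) {
    write_tsv(data.frame(sample_id = rownames(fit$eigengenus$scores),
                         fit$eigengenus$scores, check.names = FALSE),
              file.path(out_dir, "eigengenus.tsv"))
    write_tsv(data.frame(genus_id = rownames(fit$kme), fit$kme,
                         check.names = FALSE),
              file.path(out_dir, "kme.tsv"))
  }
  if (!is.null(fit$traits)) {
    tr <- fit$traits
    write_tsv(data.frame(module = rownames(tr$correlation), tr$correlation,
                         check.names = FALSE),
              file.path(out_dir, "module_trait_correlation.tsv"))
    write_tsv(data.frame(module = rownames(tr$p_value), tr$p_value,
                         check.names = FALSE),
              file.path(out_dir, "module_trait_pvalue.tsv"))
  }
  if (!is.null(fit$differential))
    write_tsv(fit$differential, file.path(out_dir, "differential_abundance.tsv"))
  write_manifest(out_dir, "discover", cfg, list(
    genera = nrow(fit$table$counts), samples = ncol(fit$table$counts),
    modules = as.list(fit$modules$sizes)))
  invisible(fit)
}

#' Run the module-preservation stage of the pipeline
#'
#' Aligns a reference and a test count table on their shared genera,
#' computes the permutation Z-summary preservation report for the given
#' (or freshly discovered) reference modules, and writes the report and
#' verdicts.
#'
#' @param config config list or path; `config$input$counts` and
#'   `config$input$test_counts` name the two tables. With no inputs, a
#'   synthetic replicate pair from `config$simulate` is used.
#' @param out_dir output directory.
#' @return the `preservation_report`, invisibly.
#' @export
run_preserve <- function(config = NULL, out_dir = "fmcnet_out") {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else merge_config(default_config(), config %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$input$counts) && !is.null(cfg$input$test_counts)) {
    ref <- read_abundance_table(cfg$input$counts)
    test <- read_abundance_table(cfg$input$test_counts)
  } else {
    pair <- simulate_fmc_pair(do.call(fmc_scenario, cfg$simulate %||% list()),
                              perturbation = cfg$preservation$perturbation %||% "replicate",
                              seed = cfg$seed)
    ref <- pair$reference$table; test <- pair$test$table
  }
  al <- align_shared_genera(ref, test)
  fit <- fmc_network(al$a, beta = cfg$network$beta,
                     min_module_size = cfg$network$min_module_size,
                     deep_split = cfg$network$deep_split,
                     n_resamples = cfg$sparcc$n_resamples,
                     min_reads_per_sample = 0, drop_singletons = FALSE,
                     seed = cfg$seed)
  keep <- intersect(rownames(al$a$counts), rownames(al$b$counts))
  rep <- module_preservation(al$a, al$b, fit$modules,
                             n_permutations = cfg$preservation$n_permutations,
                             seed = cfg$seed + 1L,
                             beta = cfg$network$beta,
                             correlation = cfg$preservation$correlation)
  write_tsv(rep$summary, file.path(out_dir, "preservation_summary.tsv"))
  write_tsv(classify_preservation(rep), file.path(out_dir, "preservation_verdicts.tsv"))
  write_manifest(out_dir, "preserve", cfg, list(
    shared_genera = nrow(al$a$counts),
    retention = as.list(stats::setNames(al$report$percent_kept, al$report$dataset)),
    z_summary = as.list(stats::setNames(rep$summary$Z_summary, rep$summary$module))))
  invisible(rep)
}

#' Run the disease-classification stage of the pipeline
#'
#' Builds subject-level genus-region (or module-region) features, runs
#' leave-one-out cross-validated nearest shrunken centroids over the
#' configured shrinkage grid, and writes the cross-validation report.
#'
#' @param config config list or path.
#' @param out_dir output directory.
#' @param binary collapse UC/CD into a single IBD class (default TRUE).
#' @return the `nsc_cv` report, invisibly.
#' @export
run_classify <- function(config = NULL, out_dir = "fmcnet_out", binary = TRUE) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else merge_config(default_config(), config %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- .load_inputs(cfg)
  if (is.null(inp$metadata)) stop("classification requires sample metadata")
  rel <- to_relative(quality_filter(inp$table,
                                    cfg$filter$min_reads_per_sample,
                                    cfg$filter$drop_singletons))
  md <- inp$metadata[inp$metadata$sample_id %in% colnames(rel$fractions), ]
  eig <- NULL
  if (identical(cfg$classifier$unit, "module")) {
    fit <- fmc_network(inp$table, beta = cfg$network$beta,
                       min_module_size = cfg$network$min_module_size,
                       deep_split = cfg$network$deep_split,
                       n_resamples = cfg$sparcc$n_resamples,
                       min_reads_per_sample = cfg$filter$min_reads_per_sample,
                       drop_singletons = cfg$filter$drop_singletons,
                       seed = cfg$seed)
    eig <- fit$eigengenus
  }
  feats <- build_features(rel, md, regions = cfg$classifier$regions,
                          unit = cfg$classifier$unit, eigengenus = eig)
  y <- feats$diagnosis
  if (binary) y <- factor(ifelse(y == "control", "control", "IBD"),
                          levels = c("control", "IBD"))
  cv <- nsc_loocv(feats$x, y, delta_grid = cfg$classifier$delta_grid,
                  priors = cfg$classifier$priors)
  write_tsv(cv$errors, file.path(out_dir, "nsc_cv_errors.tsv"))
  write_tsv(data.frame(subject_id = rownames(cv$probabilities),
                       cv$probabilities, check.names = FALSE),
            file.path(out_dir, "nsc_cv_probabilities.tsv"))
  write_manifest(out_dir, "classify", cfg, list(
    subjects = cv$n, features = ncol(feats$x), chosen_delta = cv$delta,
    error_rate = cv$errors$error_rate[cv$errors$delta == cv$delta]))
  invisible(cv)
}

#' Run the simulation stage of the pipeline
#'
#' Draws a synthetic cohort from the configured scenario and writes the
#' count table, metadata and ground-truth module assignment.
#'
#' @param config config list or path (`config$simulate` holds
#'   [fmc_scenario()] arguments).
#' @param out_dir output directory.
#' @return the `fmc_simulation`, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir = "fmcnet_out") {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else merge_config(default_config(), config %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_fmc(do.call(fmc_scenario, cfg$simulate %||% list()),
                      seed = cfg$seed)
  write_abundance_table(sim$table, file.path(out_dir, "counts.tsv"))
  write_tsv(sim$metadata, file.path(out_dir, "metadata.tsv"))
  write_tsv(data.frame(genus_id = names(sim$truth$assignment),
                       module = unname(sim$truth$assignment)),
            file.path(out_dir, "true_modules.tsv"))
  write_manifest(out_dir, "simulate", cfg, list(
    genera = nrow(sim$table$counts), samples = ncol(sim$table$counts)))
  invisible(sim)
}
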