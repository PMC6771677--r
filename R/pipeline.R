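# Pipeline configuration, the end-to-end synthetic demonstration run, and
# the run manifest.

#' Pipeline configuration
#'
#' Collects the analysis constants of the whole pipeline with their standard
#' defaults (FDR 0.05, 10 sections, 1,000 estimators, elastic-net mixing
#' 0.5, 100 subsamples at 80%, 90th percentile, 20-bp motif window, k = 5)
#' plus the simulation configs used when a stage's inputs are generated
#' rather than read.
#'
#' @param sim A [sim_config()] for the count simulation.
#' @param paired A [paired_sim_config()] for the paired-dataset stages.
#' @param satmut A [satmut_sim_config()] for the variant stage.
#' @param fdr_threshold FDR level of the active call.
#' @param n_sections Cross-validation sections.
#' @param n_estimators Estimators per ensemble member.
#' @param elastic_net_mixing Elastic-net mixing ratio.
#' @param subsample_n,subsample_frac Subsample-robustness replicates and
#'   fraction.
#' @param percentile Score-table reference percentile.
#' @param motif_window Motif-density window (bp).
#' @param k k-mer length.
#' @param seed Master seed for all stage randomness.
#' @param stages Character vector of stages to run, in order, from
#'   `c("quantify", "rank", "train", "transfer", "hardness", "variant")`.
#'
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sim = sim_config(),
                            paired = paired_sim_config(),
                            satmut = satmut_sim_config(element_length = 150),
                            fdr_threshold = 0.05,
                            n_sections = 10,
                            n_estimators = 1000,
                            elastic_net_mixing = 0.5,
                            subsample_n = 100,
                            subsample_frac = 0.8,
                            percentile = 90,
                            motif_window = 20,
                            k = 5,
                            seed = 1L,
                            stages = c("quantify", "rank", "train",
                                       "transfer", "hardness", "variant")) {
  structure(list(
    sim = sim, paired = paired, satmut = satmut,
    fdr_threshold = assert_proportion(fdr_threshold, "fdr_threshold"),
    n_sections = assert_count(n_sections, "n_sections"),
    n_estimators = assert_count(n_estimators, "n_estimators"),
    elastic_net_mixing = assert_proportion(elastic_net_mixing,
                                           "elastic_net_mixing"),
    subsample_n = assert_count(subsample_n, "subsample_n"),
    subsample_frac = assert_proportion(subsample_frac, "subsample_frac",
                                       open = TRUE),
    percentile = assert_nonneg(percentile, "percentile"),
    motif_window = assert_count(motif_window, "motif_window"),
    k = assert_count(k, "k"),
    seed = assert_count(seed, "seed", min = -.Machine$integer.max),
    stages = stages
  ), class = "pipeline_config")
}

#' Write a pipeline configuration as YAML or JSON
#' @param config A [pipeline_config()].
#' @param path Output path; the extension picks the format (`.json` for
#'   JSON, YAML otherwise).
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a synthetic experiment from the configured simulators and runs
#' the enabled stages in order: quantification and active calling, feature
#' assessment and ranking, supervised training, cross-dataset transfer,
#' hardness analysis, and variant-effect prediction. All randomness flows
#' from the configured seeds; a manifest records the configuration hash and
#' per-stage record counts so that identical configs give identical
#' deterministic outputs.
#'
#' Stage dependencies are enforced: disabling a stage leaves its outputs
#' absent, and downstream stages that need them fail fast with the missing
#' stage named.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage output is also
#'   written as TSV.
#'
#' @return A list of stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- list()
  log <- list()
  emit <- function(name, obj, n) {
    log[[name]] <<- n
    if (!is.null(out_dir) && is.data.frame(obj)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv_table(obj, file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  need <- function(stage, what) {
    if (is.null(out[[what]])) {
      abort(sprintf("stage `%s` needs output `%s` of a disabled stage",
                    stage, what))
    }
  }

  if ("quantify" %in% config$stages) {
    sim <- simulate_counts(config$sim)
    out$counts <- sim$counts
    out$truth <- sim$truth
    act <- estimate_alpha(sim$counts) |>
      call_active(fdr_threshold = config$fdr_threshold)
    out$activity <- act
    emit("activity", act, nrow(act))
  }

  paired <- simulate_paired_datasets(config$paired)
  out$paired <- paired

  if ("rank" %in% config$stages) {
    suite_a <- test_suite(paired$features, y = paired$a$activity,
                          labels = paired$a$label)
    suite_b <- test_suite(paired$features, y = paired$b$activity,
                          labels = paired$b$label)
    ranks <- comprehensive_rank(list(a = within_dataset_rank(suite_a),
                                     b = within_dataset_rank(suite_b)))
    out$suite <- list(a = suite_a, b = suite_b)
    out$ranking <- ranks
    emit("ranking", ranks, nrow(ranks))
  }

  spec_reg <- model_spec("regression", n_estimators = config$n_estimators,
                         elastic_net_mixing = config$elastic_net_mixing,
                         seed = config$seed)
  spec_cls <- model_spec("classification", n_estimators = config$n_estimators,
                         seed = config$seed)
  plan <- make_splits(paired$features$region_id,
                      n_sections = config$n_sections)

  if ("train" %in% config$stages) {
    out$train_eval <- cross_validate(paired$features, paired$a,
                                     task = "regression", spec = spec_reg,
                                     split_plan = plan)
    emit("train_eval", out$train_eval$summary, nrow(out$train_eval$summary))
  }
  if ("transfer" %in% config$stages) {
    out$transfer_eval <- cross_dataset_evaluate(
      paired$features, paired$a, paired$features, paired$b,
      task = "classification", spec = spec_cls, split_plan = plan)
    emit("transfer_eval", out$transfer_eval$summary,
         nrow(out$transfer_eval$summary))
  }
  if ("hardness" %in% config$stages) {
    need("hardness", "transfer_eval")
    ev <- out$transfer_eval
    pred <- unlist(ev$folds$predictions[!duplicated(ev$folds$fold)])
    ids <- unlist(ev$folds$region_id[!duplicated(ev$folds$fold)])
    lab_b <- paired$b$label[match(ids, paired$b$region_id)]
    ht <- hardness(pmin(pmax(pred, 0), 1), lab_b, region_id = ids)
    cats <- categorize_regions(paired$a[c("region_id", "label")],
                               paired$b[c("region_id", "label")])
    ht$category <- cats$category[match(ht$region_id, cats$region_id)]
    out$hardness <- ht
    out$hardness_comparison <- compare_hardness(ht)
    emit("hardness", ht, nrow(ht))
  }
  if ("variant" %in% config$stages) {
    sat <- simulate_saturation(config$satmut)
    fv <- featurize_variant_table(sat$variants,
                                  setNames(sat$element_seq,
                                           sat$variants$element_id[1]),
                                  k = config$k)
    reg <- train_continuous(fv, scope = "per_element",
                            n_estimators = config$n_estimators,
                            seed = config$seed)
    test <- fv[fv$split == "test", ]
    pred <- predict(reg, test)
    out$variant_eval <- evaluate_variants(test, pred_cont = pred)
    emit("variant_eval", out$variant_eval, nrow(out$variant_eval))
  }

  out$manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    stages = config$stages,
    record_counts = log,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("mprascope"))
  )
  out
}
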