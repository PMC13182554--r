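# End-to-end orchestration: simulate -> curate -> featurize -> split ->
# train -> evaluate -> explain, from one declarative config, with a
# content-hashed artifact manifest.

#' Experiment configuration
#'
#' Declarative description of a full run. The defaults reproduce the
#' reference protocol constants: 80/20 grouped stratified holdout,
#' similarity threshold 0.8, 10-fold cross-validation with 10 repeats, and
#' a descriptor ensemble of random forest, MLP and gradient boosting.
#' `smoke = TRUE` shrinks the layout (3 folds, 2 repeats) for fast runs.
#'
#' @param generator a [generator_config()] describing the synthetic input
#'   (or `NULL` when `records` is given).
#' @param records optional raw record data.frame to curate instead of
#'   simulating.
#' @param encoder feature encoder id (see [fingerprint()]; `"descriptors"`
#'   for the descriptor vector).
#' @param test_fraction holdout fraction.
#' @param similarity_threshold Tanimoto grouping threshold.
#' @param n_folds,n_repeats cross-validation layout.
#' @param model_specs named list of [model_spec()]s forming the direct
#'   ensemble.
#' @param hierarchical logical: also train the two-step model.
#' @param explain logical: run attribution and feature grouping.
#' @param seed global seed; per-stage seeds are derived as
#'   `seed + stage offset`.
#' @param outdir output directory for artifacts (created when needed);
#'   `NULL` keeps everything in memory.
#' @param smoke shrink folds/repeats for a fast end-to-end run.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              records = NULL,
                              encoder = "descriptors",
                              test_fraction = 0.2,
                              similarity_threshold = 0.8,
                              n_folds = 10L, n_repeats = 10L,
                              model_specs = list(
                                random_forest = model_spec("random_forest"),
                                mlp = model_spec("mlp"),
                                xgb = model_spec("xgb")),
                              hierarchical = FALSE,
                              explain = TRUE,
                              seed = 1L,
                              outdir = NULL,
                              smoke = FALSE) {
  if (smoke) { n_folds <- 3L; n_repeats <- 2L }
  stopifnot(test_fraction > 0, test_fraction < 1,
            similarity_threshold > 0, similarity_threshold <= 1,
            n_folds >= 2, n_repeats >= 1, length(model_specs) >= 1)
  structure(list(generator = generator, records = records, encoder = encoder,
                 test_fraction = test_fraction,
                 similarity_threshold = similarity_threshold,
                 n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
                 model_specs = model_specs, hierarchical = hierarchical,
                 explain = explain, seed = as.integer(seed), outdir = outdir),
            class = "experiment_config")
}

.stage_seed <- function(config, stage) {
  offsets <- c(simulate = 0L, split = 100L, train = 200L, evaluate = 300L,
               explain = 400L)
  config$seed + offsets[[stage]]
}

#' Run an experiment end to end
#'
#' Executes simulate/ingest, curation, featurization, leakage-aware
#' splitting, ensemble (and optionally hierarchical) training, holdout
#' evaluation and attribution, collecting every result in one list. When
#' `config$outdir` is set, artifacts are also written to disk (CSV/JSON)
#' with a manifest of md5 content hashes, making the run reproducible and
#' auditable from its outputs.
#'
#' @param config an [experiment_config()].
#' @return list with elements `records`, `curation`, `features`, `split`,
#'   `models`, `evaluation` (an [evaluation_report()]), optional
#'   `hierarchical` + `evaluation_hierarchical`, optional `explanation`
#'   (attributions, grouping, group importance), and `manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  # --- simulate / ingest ---
  if (!is.null(config$records)) {
    records <- config$records
  } else {
    gen <- config$generator
    ds <- assign_labels(generate_molecules(gen), gen)
    records <- emit_two_source_dataset(ds, gen)
  }
  # --- curate ---
  cur <- curate(records)
  smiles <- cur$curated$smiles_canonical
  labels <- cur$curated$strength_code
  # --- featurize ---
  feats <- if (config$encoder == "descriptors") descriptors(smiles)
           else fingerprint(smiles, config$encoder)
  keep <- match(feats$row_keys, smiles)
  labels <- labels[keep]
  # --- split ---
  fp <- fingerprint(feats$row_keys, "morgan_bits")
  groups <- similarity_groups(feats$row_keys, config$similarity_threshold,
                              fp = fp)
  plan <- grouped_stratified_holdout(labels, groups, config$test_fraction,
                                     seed = .stage_seed(config, "split"))
  tr <- !plan$holdout; te <- plan$holdout
  Xtr <- fm_subset(feats, which(tr)); Xte <- fm_subset(feats, which(te))
  # --- train ---
  models <- lapply(config$model_specs, function(sp) {
    sp$seed <- .stage_seed(config, "train")
    train_direct(Xtr, labels[tr], sp)
  })
  pred <- if (length(models) >= 2) ensemble_predict(models, Xte)
          else predict_ordinal(models[[1]], Xte)
  # --- evaluate ---
  report <- evaluation_report(labels[te], pred$code, pred$prob)
  out <- list(records = records, curation = cur, features = feats,
              split = plan, groups = groups, models = models,
              prediction = pred, evaluation = report,
              train_index = which(tr), test_index = which(te),
              labels = labels)
  if (config$hierarchical) {
    hm <- train_hierarchical(Xtr, labels[tr],
                             config$model_specs[[1]],
                             config$model_specs[[1]])
    ph <- predict_hierarchical(hm, Xte)
    out$hierarchical <- hm
    out$evaluation_hierarchical <- evaluation_report(labels[te], ph$code)
  }
  if (config$explain) {
    att <- attribute(if (length(models) >= 2) models else models[[1]],
                     Xte, Xtr, seed = .stage_seed(config, "explain"))
    grouping <- correlation_grouping(feats)
    out$explanation <- list(attribution = att, grouping = grouping,
                            importance = group_importance(att, grouping,
                                                          y_true = labels[te]))
  }
  if (!is.null(config$outdir)) out$manifest <- .write_artifacts(out, config)
  out
}

.write_artifacts <- function(out, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$outdir, ...)
  utils::write.csv(out$records[, c("smiles", "source", "description", "strength")],
                   p("records.csv"), row.names = FALSE, na = "")
  utils::write.csv(out$curation$curated, p("curated.csv"), row.names = FALSE)
  jsonlite::write_json(out$curation$audit, p("audit.json"), auto_unbox = TRUE)
  ag <- out$curation$agreement
  jsonlite::write_json(list(kappa_quadratic = ag$kappa_quadratic,
                            krippendorff_alpha = ag$krippendorff_alpha,
                            n_overlap = ag$n_overlap),
                       p("agreement.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(smiles = out$features$row_keys,
                              group = out$groups,
                              holdout = out$split$holdout),
                   p("split_plan.csv"), row.names = FALSE)
  ev <- out$evaluation
  jsonlite::write_json(list(macro_mse = ev$macro_mse, micro_mse = ev$micro_mse,
                            f1_macro = ev$f1_macro, f1_micro = ev$f1_micro,
                            roc_auc = ev$roc_auc, n_test = ev$n_test),
                       p("evaluation.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(ev$confusion), p("confusion.csv"),
                   row.names = FALSE)
  if (!is.null(out$explanation)) {
    gi <- out$explanation$importance
    utils::write.csv(gi$groups, p("group_importance.csv"), row.names = FALSE)
    utils::write.csv(out$explanation$grouping$silhouette_curve,
                     p("silhouette_curve.csv"), row.names = FALSE)
  }
  files <- list.files(config$outdir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, p("manifest.csv"), row.names = FALSE)
  manifest
}
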