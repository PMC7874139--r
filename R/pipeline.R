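#' Pipeline configuration
#'
#' One serializable object driving [run_pipeline()] end-to-end. Defaults
#' mirror the final published protocol: all four feature blocks, lg = 28,
#' lambda = 17, four nuclei, SMOTE to parity applied once before
#' evaluation (`smote_mode = "outside"`), F-score ranking with IFS, RBF-SVM
#' with grid search, jackknife evaluation.
#'
#' @param positive_fasta,negative_fasta Class FASTA paths.
#' @param manifest Optional manifest TSV path (needed for the PSSM-AC and
#'   acACS blocks).
#' @param blocks Feature blocks, see [encode_combined()].
#' @param encoder An [encoder_config()].
#' @param acs_table_path Optional ACS table path (default: shipped table).
#' @param smote_mode `"outside"`, `"inside"` or `"none"`.
#' @param smote_k SMOTE neighbor count.
#' @param fscore_variant `"symmetric"` or `"printed"` (see [fscore_rank()]).
#' @param ifs_step IFS increment; `ifs_folds` the CV folds of its evaluator.
#' @param svm An [svm_config()]; `grid_folds` the grid-search CV folds.
#' @param protocol Final evaluation protocol, `"jackknife"` or `"kfold"`.
#' @param eval_folds Folds when `protocol = "kfold"`.
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(positive_fasta, negative_fasta, manifest = NULL,
                            blocks = c("AAC", "DC", "ACS", "PSSMAC"),
                            encoder = encoder_config(),
                            acs_table_path = NULL,
                            smote_mode = c("outside", "inside", "none"),
                            smote_k = 5L,
                            fscore_variant = "symmetric",
                            ifs_step = 1L, ifs_folds = 5L,
                            svm = svm_config(), grid_folds = 5L,
                            protocol = c("jackknife", "kfold"),
                            eval_folds = 5L, seed = 1L) {
  structure(list(
    positive_fasta = positive_fasta, negative_fasta = negative_fasta,
    manifest = manifest,
    blocks = match.arg(blocks, c("AAC", "DC", "ACS", "PSSMAC"),
                       several.ok = TRUE),
    encoder = encoder, acs_table_path = acs_table_path,
    smote_mode = match.arg(smote_mode), smote_k = as.integer(smote_k),
    fscore_variant = fscore_variant,
    ifs_step = as.integer(ifs_step), ifs_folds = as.integer(ifs_folds),
    svm = svm, grid_folds = as.integer(grid_folds),
    protocol = match.arg(protocol), eval_folds = as.integer(eval_folds),
    seed = as.integer(seed)), class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `path` invisibly (save); a `pipeline_config` (load).
#' @export
save_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$encoder <- unclass(obj$encoder)
  obj$svm <- unclass(obj$svm)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    positive_fasta = o$positive_fasta, negative_fasta = o$negative_fasta,
    manifest = o$manifest, blocks = o$blocks,
    encoder = encoder_config(o$encoder$lg, o$encoder$lambda,
                             o$encoder$nuclei, o$encoder$acacs_variant),
    acs_table_path = o$acs_table_path,
    smote_mode = o$smote_mode, smote_k = o$smote_k,
    fscore_variant = o$fscore_variant, ifs_step = o$ifs_step,
    ifs_folds = o$ifs_folds,
    svm = svm_config(o$svm$c, o$svm$gamma, o$svm$c_grid, o$svm$gamma_grid,
                     o$svm$scale),
    grid_folds = o$grid_folds, protocol = o$protocol,
    eval_folds = o$eval_folds, seed = o$seed)
}

#' Run the full prediction workflow
#'
#' Stages, in order: load and encode (`extract`), SMOTE balance
#' (`balance`), F-score ranking (`rank`), incremental feature selection
#' with a k-fold SVM evaluator (`ifs`), grid search and final training
#' (`train`), and protocol evaluation over the original samples
#' (`evaluate`). Every stage's artifact is written under `out_dir` along
#' with the archived configuration, so a run is reproducible from the
#' directory alone.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @param quiet Suppress stage log lines.
#' @return List with `features`, `balanced`, `ranking`, `ifs`, `svm_config`,
#'   `model`, `report`, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cwlrun"), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  say <- function(stage, ...) {
    msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  save_pipeline_config(config, file.path(out_dir, "config.json"))

  say("extract", "loading dataset and encoding blocks ",
      paste(config$blocks, collapse = "+"))
  fm <- stage("extract", {
    ds <- load_dataset(config$positive_fasta, config$negative_fasta,
                       manifest = config$manifest)
    tab <- if (is.null(config$acs_table_path)) NULL
           else read_acs_table(config$acs_table_path)
    extract_features(ds, config = config$encoder, blocks = config$blocks,
                     table = tab)
  })
  write_feature_csv(fm, file.path(out_dir, "features.csv"))

  say("balance", "smote_mode=", config$smote_mode,
      " imbalance=", sprintf("%.2f", imbalance_ratio(fm)))
  bal <- stage("balance", {
    if (config$smote_mode == "none") fm
    else smote_balance(fm, k = config$smote_k, seed = config$seed)
  })
  write_feature_csv(bal, file.path(out_dir, "balanced.csv"))

  say("rank", "F-score variant=", config$fscore_variant)
  ranking <- stage("rank", fscore_rank(bal, variant = config$fscore_variant))
  write.table(ranking, file.path(out_dir, "ranking.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)

  say("ifs", "step=", config$ifs_step, " evaluator=", config$ifs_folds,
      "-fold CV")
  ifs_eval <- function(sub_fm) {
    kfold(sub_fm, make_svm_trainer(config$svm), folds = config$ifs_folds,
          smote_mode = "none", seed = config$seed)$acc
  }
  curve <- stage("ifs", ifs_select(bal, ranking, ifs_eval,
                                   step = config$ifs_step))
  write.table(as.data.frame(curve), file.path(out_dir, "ifs_curve.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  sel <- attr(curve, "selected_features")
  say("ifs", "selected d=", attr(curve, "selected_d"),
      " acc=", sprintf("%.2f", attr(curve, "selected_acc")))

  say("train", "grid search ", length(config$svm$c_grid), "x",
      length(config$svm$gamma_grid), " over ", config$grid_folds, " folds")
  bal_sel <- fm_subset(bal, seq_len(nrow(bal$x)), cols = sel)
  best_cfg <- stage("train", svm_grid_search(bal_sel, config$svm,
                                             folds = config$grid_folds,
                                             seed = config$seed))
  say("train", "best C=", best_cfg$c, " gamma=", best_cfg$gamma)
  model <- stage("train", svm_train(bal_sel, best_cfg))
  save_model(model, file.path(out_dir, "model.json"))

  say("evaluate", config$protocol, " smote_mode=", config$smote_mode)
  fm_sel <- fm_subset(fm, seq_len(nrow(fm$x)), cols = sel)
  report <- stage("evaluate", {
    trainer <- make_svm_trainer(best_cfg)
    if (config$protocol == "jackknife")
      jackknife(fm_sel, trainer, smote_mode = config$smote_mode,
                seed = config$seed, k = config$smote_k)
    else
      kfold(fm_sel, trainer, folds = config$eval_folds,
            smote_mode = config$smote_mode, seed = config$seed,
            k = config$smote_k)
  })
  write_report(report, file.path(out_dir, "report.json"), "json")
  write_report(report, file.path(out_dir, "report.tsv"), "tsv")
  say("evaluate", sprintf("Sn %.2f Sp %.2f MCC %.4f Acc %.2f",
                          report$sn, report$sp, report$mcc, report$acc))

  invisible(list(features = fm, balanced = bal, ranking = ranking,
                 ifs = curve, svm_config = best_cfg, model = model,
                 report = report, out_dir = out_dir))
}

#' Sweep an encoder parameter and record accuracy
#'
#' Re-encodes the dataset and evaluates a cross-validated SVM for each
#' value of `lg`, `lambda`, or each nuclei combination (`values = "all"`
#' enumerates the 15 non-empty subsets of the four nuclei). A failing value
#' (e.g. a lag not satisfied by the shortest sequence) is recorded as NA
#' and the sweep continues.
#'
#' @param dataset A [labeled_dataset()] with the inputs the blocks need.
#' @param config A [pipeline_config()] (its encoder/svm settings are used).
#' @param parameter `"lg"`, `"lambda"` or `"nuclei"`.
#' @param values Numeric vector of lags, list of nuclei subsets, or
#'   `"all"`.
#' @return Data frame with columns `value` and `acc`.
#' @export
sweep_parameter <- function(dataset, config, parameter = c("lg", "lambda",
                                                           "nuclei"),
                            values) {
  parameter <- match.arg(parameter)
  if (parameter == "nuclei" && identical(values, "all")) {
    values <- unlist(lapply(seq_along(ACS_NUCLEI), function(k)
      combn(ACS_NUCLEI, k, simplify = FALSE)), recursive = FALSE)
  }
  if (!length(values)) stop("empty value list")
  blocks <- switch(parameter, lg = "PSSMAC", lambda = , nuclei = "ACS")
  tab <- if (is.null(config$acs_table_path)) NULL
         else read_acs_table(config$acs_table_path)
  rows <- lapply(values, function(v) {
    enc <- config$encoder
    if (parameter == "lg") enc$lg <- as.integer(v)
    if (parameter == "lambda") enc$lambda <- as.integer(v)
    if (parameter == "nuclei") enc$nuclei <- v
    acc <- tryCatch({
      fm <- extract_features(dataset, config = enc, blocks = blocks,
                             table = tab)
      bal <- if (config$smote_mode == "none") fm
             else smote_balance(fm, k = config$smote_k, seed = config$seed)
      kfold(bal, make_svm_trainer(config$svm), folds = config$ifs_folds,
            smote_mode = "none", seed = config$seed)$acc
    }, error = function(e) NA_real_)
    data.frame(value = paste(v, collapse = "+"), acc = acc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot an IFS curve to a PDF, accuracy against feature count
#'
#' @param curve An `ifs_curve` from [ifs_select()].
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
plot_ifs_curve <- function(curve, path = "ifs_curve.pdf") {
  grDevices::pdf(path, width = 6, height = 4)
  on.exit(grDevices::dev.off())
  graphics::plot(curve$d, curve$acc, type = "l",
       xlab = "number of top-ranked features",
       ylab = "accuracy (%)", main = "Incremental feature selection")
  best <- attr(curve, "selected_d")
  graphics::abline(v = best, lty = 2)
  graphics::points(best, attr(curve, "selected_acc"), pch = 19)
  invisible(path)
}
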