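#' Fully nested pipeline trainer for leakage-free evaluation
#'
#' Returns a trainer callback (for [jackknife()] / [kfold()] with
#' `smote_mode = "none"`) that performs the entire data-dependent part of
#' the workflow inside each training fold: SMOTE balancing (when the fold
#' is imbalanced), F-score ranking, incremental feature selection, and SVM
#' training on the selected columns. Because no held-out sample influences
#' balancing, ranking or selection, the resulting accuracy is an unbiased
#' estimate of the whole method's generalization — unlike the single-pass
#' protocol of [run_pipeline()], whose ranking/IFS on the full dataset is
#' optimistically biased (severely so when features outnumber samples).
#'
#' @param svm An [svm_config()]; its fixed `c` and `gamma` are used (no
#'   per-fold grid search).
#' @param smote Balance each training fold to parity.
#' @param smote_k SMOTE neighbor count (clamped to the fold minority size).
#' @param fscore_variant Passed to [fscore_rank()].
#' @param ifs_step,ifs_folds IFS increment and internal CV folds.
#' @param seed Seed for the fold-internal stochastic steps.
#' @return Function(feature_matrix) -> `cwl_pipeline_model`, predictable
#'   with `predict()`.
#' @export
make_pipeline_trainer <- function(svm = svm_config(), smote = TRUE,
                                  smote_k = 5L,
                                  fscore_variant = "symmetric",
                                  ifs_step = 1L, ifs_folds = 3L,
                                  seed = 1L) {
  force(svm); force(smote); force(smote_k); force(fscore_variant)
  force(ifs_step); force(ifs_folds); force(seed)
  function(fm) {
    cls <- table(fm$label)
    if (smote && length(cls) == 2L && cls[1L] != cls[2L]) {
      k_eff <- min(smote_k, min(cls) - 1L)
      fm <- smote_balance(fm, k = k_eff, seed = seed)
    }
    ranking <- fscore_rank(fm, variant = fscore_variant)
    evaluator <- function(sub)
      kfold(sub, make_svm_trainer(svm), folds = ifs_folds,
            smote_mode = "none", seed = seed)$acc
    curve <- ifs_select(fm, ranking, evaluator, step = ifs_step)
    sel <- attr(curve, "selected_features")
    model <- svm_train(fm_subset(fm, seq_len(nrow(fm$x)), cols = sel), svm)
    structure(list(model = model, features = sel, curve = curve),
              class = "cwl_pipeline_model")
  }
}

#' @export
predict.cwl_pipeline_model <- function(object, fm, ...) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  predict(object$model, x[, object$features, drop = FALSE], ...)
}
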