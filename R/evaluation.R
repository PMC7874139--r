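#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

# counts from predicted vs true labels
count_confusion <- function(pred, truth) {
  confusion_counts(tp = sum(pred == "positive" & truth == "positive"),
                   tn = sum(pred == "negative" & truth == "negative"),
                   fp = sum(pred == "positive" & truth == "negative"),
                   fn = sum(pred == "negative" & truth == "positive"))
}

#' Sensitivity, specificity, MCC and accuracy from confusion counts
#'
#' Sn = 100 TP/(TP+FN); Sp = 100 TN/(TN+FP); Acc = 100 (TP+TN)/total;
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP)), defined as 0
#' when any denominator factor vanishes. The `"printed"` specificity
#' variant computes TN/(TN+FN) instead, reproducing a transcription of the
#' formula seen in parts of this literature; the standard form is the
#' default. Undefined ratios (empty class) are reported as NA.
#'
#' @param counts A [confusion_counts()] with positive total.
#' @param sp_variant `"standard"` (TN/(TN+FP)) or `"printed"` (TN/(TN+FN)).
#' @return An `evaluation_report` list: `counts`, `sn`, `sp`, `acc`
#'   (percentages), `mcc`, `protocol` metadata.
#' @examples
#' compute_metrics(confusion_counts(45, 40, 10, 5))  # Sn 90, Sp 80, Acc 85
#' @export
compute_metrics <- function(counts, sp_variant = c("standard", "printed")) {
  sp_variant <- match.arg(sp_variant)
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table")
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  sn <- 100 * ratio(tp, tp + fn)
  sp <- if (sp_variant == "standard") 100 * ratio(tn, tn + fp)
        else 100 * ratio(tn, tn + fn)
  acc <- 100 * (tp + tn) / total
  den <- prod(sqrt(c(tp + fp, tn + fn, tp + fn, tn + fp)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  mcc <- max(-1, min(1, mcc))            # guard float overshoot at the corners
  structure(list(counts = counts, sn = sn, sp = sp, mcc = mcc, acc = acc,
                 protocol = list()), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))
  cat(sprintf("<evaluation_report> Sn %s%%  Sp %s%%  MCC %s  Acc %s%%\n",
              fmt(x$sn), fmt(x$sp), fmt(x$mcc), fmt(x$acc)))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d", x$counts$tp, x$counts$tn,
              x$counts$fp, x$counts$fn))
  if (length(x$protocol))
    cat("  [", paste(names(x$protocol), unlist(x$protocol), sep = "=",
                     collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Write an evaluation report as JSON or a Sn/Sp/MCC/Acc TSV line
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"` (one header + one data line in the
#'   column order Sn, Sp, MCC, Acc).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(counts = unclass(report$counts), sn = report$sn, sp = report$sp,
           mcc = report$mcc, acc = report$acc, protocol = report$protocol),
      path, digits = NA, auto_unbox = TRUE)
  } else {
    writeLines(c("Sn\tSp\tMCC\tAcc",
                 sprintf("%.2f\t%.2f\t%.4f\t%.2f", report$sn, report$sp,
                         report$mcc, report$acc)), path)
  }
  invisible(path)
}

#' Default trainer callback for the evaluation protocols
#'
#' @param config An [svm_config()].
#' @return Function(feature_matrix) -> model with a `predict` method.
#' @export
make_svm_trainer <- function(config = svm_config()) {
  force(config)
  function(fm) svm_train(fm, config)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each original sample is predicted by a model trained on all the others.
#' SMOTE placement is explicit protocol metadata:
#' \describe{
#'   \item{none}{no balancing.}
#'   \item{outside}{balance the full matrix once, before the loop; the
#'     training part of every round then contains synthetic points derived
#'     from the held-out sample — optimistically biased, but mirroring the
#'     balance-then-validate protocol common in this literature.}
#'   \item{inside}{re-balance each training fold after removing the
#'     held-out sample; statistically sound.}
#' }
#' Synthetic samples are never test points; with
#' `include_synthetic = TRUE` (mode `outside` only) they are also predicted
#' and counted, mimicking metrics computed over the balanced set.
#'
#' @param fm A [feature_matrix()] of original samples, >= 2 per class.
#' @param trainer Function(feature_matrix) -> model; see
#'   [make_svm_trainer()].
#' @param smote_mode `"none"`, `"outside"` or `"inside"`.
#' @param seed Integer seed driving SMOTE draws.
#' @param k SMOTE neighbor count.
#' @param include_synthetic Count held-out synthetic predictions too
#'   (mode `outside`).
#' @return An `evaluation_report` with protocol metadata.
#' @export
jackknife <- function(fm, trainer = make_svm_trainer(),
                      smote_mode = c("none", "outside", "inside"),
                      seed = 1L, k = 5L, include_synthetic = FALSE) {
  smote_mode <- match.arg(smote_mode)
  eval_loop(fm, trainer, fold_of = seq_len(nrow(fm$x)), smote_mode,
            seed, k, include_synthetic,
            protocol = list(protocol = "jackknife", smote = smote_mode))
}

#' Stratified k-fold cross-validation
#'
#' As [jackknife()] but over k stratified folds; the fast evaluator used
#' inside incremental feature selection. `k = n` with mode `"none"`
#' coincides with the jackknife.
#'
#' @inheritParams jackknife
#' @param folds Number of folds (2 <= folds <= smaller class size).
#' @return An `evaluation_report`.
#' @export
kfold <- function(fm, trainer = make_svm_trainer(), folds = 5L,
                  smote_mode = c("none", "outside", "inside"),
                  seed = 1L, k = 5L, include_synthetic = FALSE) {
  smote_mode <- match.arg(smote_mode)
  folds <- as.integer(folds)
  n_min <- min(table(fm$label))
  n <- nrow(fm$x)
  if (folds == n) {
    fold_of <- seq_len(n)                  # k = n is exactly the jackknife
  } else if (folds > n_min) {
    stop("folds = ", folds, " exceeds the smaller class size ", n_min)
  } else {
    fold_of <- stratified_folds(fm$label, folds, seed)
  }
  eval_loop(fm, trainer, fold_of, smote_mode, seed, k, include_synthetic,
            protocol = list(protocol = paste0(folds, "-fold"),
                            smote = smote_mode))
}

# shared train/predict loop over fold assignments of the ORIGINAL samples
eval_loop <- function(fm, trainer, fold_of, smote_mode, seed, k,
                      include_synthetic, protocol) {
  if (min(table(fm$label)) < 2L) stop("need >= 2 samples per class")
  if (smote_mode != "none" && any(fm$provenance != "original"))
    stop("evaluation with smote_mode='", smote_mode, "' expects a matrix ",
         "of original samples; balancing is performed by the protocol itself")
  n <- nrow(fm$x)
  pred <- character(0L); truth <- character(0L)

  if (smote_mode == "outside") {
    bal <- smote_balance(fm, k = k, seed = seed)
    for (f in unique(fold_of)) {
      test_orig <- which(fold_of == f)                  # indices into fm
      test_ids <- rownames(fm$x)[test_orig]
      train_rows <- which(!(rownames(bal$x) %in% test_ids))
      model <- trainer(fm_subset(bal, train_rows))
      test_fm <- fm_subset(fm, test_orig)
      pred <- c(pred, predict(model, test_fm))
      truth <- c(truth, test_fm$label)
    }
    if (include_synthetic) {
      # synthetic rows predicted leave-one-out over the balanced matrix
      syn_rows <- which(bal$provenance == "synthetic")
      for (s in syn_rows) {
        model <- trainer(fm_subset(bal, setdiff(seq_len(nrow(bal$x)), s)))
        pred <- c(pred, predict(model, fm_subset(bal, s)))
        truth <- c(truth, bal$label[s])
      }
    }
  } else {
    for (f in unique(fold_of)) {
      test_idx <- which(fold_of == f)
      train_fm <- fm_subset(fm, setdiff(seq_len(n), test_idx))
      if (smote_mode == "inside") {
        k_eff <- min(k, min(table(train_fm$label)) - 1L)  # small training folds
        train_fm <- smote_balance(train_fm, k = k_eff,
                                  seed = as.integer(seed) + as.integer(f))
      }
      model <- trainer(train_fm)
      test_fm <- fm_subset(fm, test_idx)
      pred <- c(pred, predict(model, test_fm))
      truth <- c(truth, test_fm$label)
    }
  }
  report <- compute_metrics(count_confusion(pred, truth))
  report$protocol <- c(protocol, list(seed = as.integer(seed),
                                      include_synthetic = include_synthetic))
  report
}
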