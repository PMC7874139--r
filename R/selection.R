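#' Rank features by F-score
#'
#' Per feature i, the F-score is the squared separation of the class means
#' from the pooled mean divided by the within-class spread:
#' \deqn{F_i = \frac{(\bar x_i^{(+)}-\bar x_i)^2 + (\bar x_i^{(-)}-\bar x_i)^2}
#'   {\frac{1}{n^+-1}\sum_k (x_{k,i}^{(+)}-\bar x_i^{(+)})^2 +
#'    \frac{1}{n^--1}\sum_k (x_{k,i}^{(-)}-\bar x_i^{(-)})^2}}
#' (the symmetric Chen--Lin form, default). The `"printed"` variant applies
#' the Bessel factor only to the negative-class sum, reproducing a common
#' asymmetric transcription of the formula. A zero denominator yields `Inf`
#' (perfect separator, ranked first) when the numerator is positive and 0
#' when it is also zero.
#'
#' @param fm A [feature_matrix()] with >= 2 samples in each class.
#' @param variant `"symmetric"` (default) or `"printed"`.
#' @return Data frame of class `feature_ranking` with columns `feature` and
#'   `score`, sorted by decreasing score, ties broken by feature name.
#' @export
fscore_rank <- function(fm, variant = c("symmetric", "printed")) {
  variant <- match.arg(variant)
  pos <- fm$x[fm$label == "positive", , drop = FALSE]
  neg <- fm$x[fm$label == "negative", , drop = FALSE]
  if (nrow(pos) < 2L || nrow(neg) < 2L)
    stop("F-score needs >= 2 samples per class (variance undefined)")
  mu <- colMeans(fm$x)
  mu_p <- colMeans(pos)
  mu_n <- colMeans(neg)
  ss_p <- colSums(sweep(pos, 2L, mu_p)^2)
  ss_n <- colSums(sweep(neg, 2L, mu_n)^2)
  num <- (mu_p - mu)^2 + (mu_n - mu)^2
  den <- if (variant == "symmetric") {
    ss_p / (nrow(pos) - 1L) + ss_n / (nrow(neg) - 1L)
  } else {
    ss_p + ss_n / (nrow(neg) - 1L)
  }
  score <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  out <- data.frame(feature = colnames(fm$x), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Incremental feature selection (IFS)
#'
#' Walks down a feature ranking evaluating nested top-d subsets
#' (d = 1, 1+step, 1+2*step, ...) with a user-supplied evaluator, and
#' selects the smallest d attaining the maximum accuracy. With step = 1 this
#' is the classic IFS curve; larger steps trade resolution for speed on big
#' feature spaces.
#'
#' @param fm A [feature_matrix()].
#' @param ranking A `feature_ranking` from [fscore_rank()].
#' @param evaluator Function(feature_matrix) -> accuracy in [0, 100],
#'   applied to the column subset.
#' @param step Positive integer increment of d.
#' @return An `ifs_curve` data frame with columns `d` and `acc`, plus
#'   attributes `selected_d` and `selected_acc`.
#' @export
ifs_select <- function(fm, ranking, evaluator, step = 1L) {
  stopifnot(inherits(ranking, "feature_ranking"))
  step <- as.integer(step)
  stopifnot(step >= 1L)
  feats <- ranking$feature
  if (!length(feats)) stop("empty ranking")
  if (!setequal(feats, colnames(fm$x)))
    stop("ranking features do not match matrix features")
  ds <- seq(1L, length(feats), by = step)
  accs <- vapply(ds, function(d) {
    evaluator(fm_subset(fm, seq_len(nrow(fm$x)), cols = feats[seq_len(d)]))
  }, numeric(1L))
  best <- ds[which.max(accs)]   # which.max takes the first (smallest d) tie
  out <- data.frame(d = ds, acc = accs)
  attr(out, "selected_d") <- best
  attr(out, "selected_acc") <- max(accs)
  attr(out, "selected_features") <- feats[seq_len(best)]
  class(out) <- c("ifs_curve", "data.frame")
  out
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf("<ifs_curve> %d points; peak Acc %.2f%% at d = %d\n",
              nrow(x), attr(x, "selected_acc"), attr(x, "selected_d")))
  invisible(x)
}
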