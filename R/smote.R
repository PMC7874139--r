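#' Majority/minority imbalance ratio
#'
#' @param fm A [feature_matrix()] containing both classes.
#' @return Majority count divided by minority count (e.g. 307 negatives vs
#'   68 positives gives 4.51..., "about 4.5 times").
#' @export
imbalance_ratio <- function(fm) {
  n_pos <- sum(fm$label == "positive")
  n_neg <- sum(fm$label == "negative")
  if (n_pos == 0L || n_neg == 0L)
    stop("imbalance ratio undefined: both classes must be present")
  max(n_pos, n_neg) / min(n_pos, n_neg)
}

#' SMOTE: oversample the minority class to parity
#'
#' Synthetic Minority Over-sampling TEchnique. Until the class counts are
#' equal, repeatedly: pick a minority sample x_i at random, pick one of its
#' k nearest minority neighbors x_nn (Euclidean distance within the minority
#' class), draw alpha uniformly in (0, 1), and add the interpolated sample
#' x_new = x_i + alpha * (x_nn - x_i). Original rows are preserved
#' unchanged; synthetic rows carry provenance `"synthetic"` and ids
#' `syn<j>.<base id>`.
#'
#' @param fm A [feature_matrix()] with both classes, minority size >= 2.
#' @param k Number of nearest neighbors considered (default 5, the
#'   technique's canonical value; must be <= minority size - 1).
#' @param seed Integer seed; mandatory for reproducibility of this
#'   stochastic stage.
#' @return A balanced [feature_matrix()]; original rows first, bit-identical.
#' @examples
#' fm <- gen_feature_matrix(synth_spec(n_pos = 5, n_neg = 12, seed = 1))
#' bal <- smote_balance(fm, k = 3, seed = 7)
#' table(bal$label)  # 12 / 12
#' @export
smote_balance <- function(fm, k = 5L, seed) {
  if (missing(seed)) stop("smote_balance: an explicit seed is required")
  k <- as.integer(k)
  n_pos <- sum(fm$label == "positive")
  n_neg <- sum(fm$label == "negative")
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  if (n_pos == n_neg) return(fm)
  minority <- if (n_pos < n_neg) "positive" else "negative"
  min_idx <- which(fm$label == minority)
  n_min <- length(min_idx)
  n_new <- max(n_pos, n_neg) - n_min
  if (n_min < 2L)
    stop("minority class has ", n_min, " sample(s); SMOTE needs >= 2")
  if (k > n_min - 1L)
    stop("k = ", k, " exceeds minority size - 1 = ", n_min - 1L)

  xm <- fm$x[min_idx, , drop = FALSE]
  d <- as.matrix(dist(xm))                 # minority-only Euclidean distances
  diag(d) <- Inf
  # k nearest minority neighbors of each minority point (ties by index)
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(d[i, ])[seq_len(k)]))

  syn <- withr::with_seed(as.integer(seed), {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- sample.int(k, n_new, replace = TRUE)
    alpha <- runif(n_new)
    xi <- xm[base, , drop = FALSE]
    xn <- xm[nn[cbind(base, pick)], , drop = FALSE]
    list(x = xi + alpha * (xn - xi), base = base)
  })
  rownames(syn$x) <- paste0("syn", seq_len(n_new), ".",
                            rownames(xm)[syn$base])
  fm_rbind(fm, feature_matrix(syn$x, rep(minority, n_new),
                              rep("synthetic", n_new)))
}
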