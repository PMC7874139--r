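#' SVM configuration
#'
#' Regularization constant C ("c" in the grid-search literature) and RBF
#' kernel width gamma, plus the candidate grids searched by
#' [svm_grid_search()] and the feature-scaling mode. The default grid is the
#' canonical libsvm recommendation: C in 2^(-5), 2^(-3), ..., 2^15 and
#' gamma in 2^(-15), 2^(-13), ..., 2^3.
#'
#' @param c Positive regularization parameter.
#' @param gamma Positive RBF width.
#' @param c_grid,gamma_grid Non-empty candidate vectors for grid search.
#' @param scale Logical; min-max scale each feature to [0, 1] using
#'   training-set statistics (default TRUE; RBF kernels on unscaled
#'   heterogeneous features are degenerate).
#' @return An `svm_config` list.
#' @export
svm_config <- function(c = 1, gamma = 0.05,
                       c_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       scale = TRUE) {
  stopifnot(c > 0, gamma > 0, length(c_grid) >= 1L, length(gamma_grid) >= 1L,
            all(c_grid > 0), all(gamma_grid > 0), is.logical(scale))
  structure(list(c = c, gamma = gamma, c_grid = sort(c_grid),
                 gamma_grid = sort(gamma_grid), scale = scale),
            class = "svm_config")
}

# fit / apply [0,1] min-max scaling; constant features map to 0
fit_scaling <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}

apply_scaling <- function(x, sc) {
  sweep(sweep(x, 2L, sc$lo), 2L, sc$rng, "/")
}

#' Train an RBF-kernel SVM
#'
#' Fits a binary C-SVC by sequential minimal optimization. Scaling
#' parameters are fitted on the given matrix only (never on data seen later
#' at prediction time), and the fit is fully deterministic.
#'
#' @param fm A [feature_matrix()] with both classes and finite values.
#' @param config An [svm_config()]; `config$c` and `config$gamma` are used.
#' @return A `cwl_svm` model usable with [predict.cwl_svm()].
#' @export
svm_train <- function(fm, config = svm_config()) {
  if (any(!is.finite(fm$x))) stop("feature matrix contains non-finite values")
  y <- ifelse(fm$label == "positive", 1, -1)
  if (length(unique(y)) < 2L) stop("training needs both classes")
  sc <- if (config$scale) fit_scaling(fm$x) else NULL
  xs <- if (is.null(sc)) fm$x else apply_scaling(fm$x, sc)
  fit <- .smo_fit(xs, y, C = config$c, gamma = config$gamma)
  structure(list(
    sv = xs[fit$sv_index, , drop = FALSE],
    coef = fit$coef, b = fit$b, gamma = config$gamma,
    config = config, scaling = sc, features = colnames(fm$x),
    iterations = fit$iter), class = "cwl_svm")
}

#' @export
print.cwl_svm <- function(x, ...) {
  cat(sprintf("<cwl_svm> RBF C-SVC: C = %g, gamma = %g, %d SVs, %d features\n",
              x$config$c, x$gamma, nrow(x$sv), length(x$features)))
  invisible(x)
}

#' Predict class labels with a trained SVM
#'
#' Applies the stored feature scaling, evaluates the RBF decision function
#' over the support vectors and thresholds at zero. Inputs must carry
#' exactly the feature names (and order) seen at training.
#'
#' @param object A `cwl_svm` model.
#' @param fm A [feature_matrix()] (or bare numeric matrix with colnames).
#' @param decision Return raw decision values instead of labels.
#' @param ... Unused.
#' @return Character vector of `"positive"` / `"negative"` (or numeric
#'   decision values), one per row; empty input gives an empty vector.
#' @export
predict.cwl_svm <- function(object, fm, decision = FALSE, ...) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (!identical(colnames(x), object$features))
    stop("feature names/order differ from the training matrix")
  if (nrow(x) == 0L) return(if (decision) numeric(0L) else character(0L))
  xs <- if (is.null(object$scaling)) x else apply_scaling(x, object$scaling)
  f <- .smo_decision(object$sv, object$coef, object$b, object$gamma, xs)
  if (decision) return(f)
  ifelse(f >= 0, "positive", "negative")
}

#' Grid search over (C, gamma) by stratified cross-validation
#'
#' Evaluates every pair of the configured grids by k-fold stratified
#' cross-validation (scaling refitted inside each training fold, so no
#' held-out statistic leaks into training) and returns the configuration
#' with the best mean accuracy. Ties are broken toward smaller C, then
#' smaller gamma.
#'
#' @param fm A [feature_matrix()].
#' @param config An [svm_config()] supplying `c_grid` and `gamma_grid`.
#' @param folds Number of CV folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return An [svm_config()] with `c` and `gamma` set to the winners; the
#'   searched accuracy table is attached as attribute `"grid"`.
#' @export
svm_grid_search <- function(fm, config = svm_config(), folds = 5L, seed = 1L) {
  folds <- as.integer(folds)
  stopifnot(folds >= 2L)
  assign_f <- stratified_folds(fm$label, folds, seed)
  grid <- expand.grid(c = config$c_grid, gamma = config$gamma_grid)
  grid <- grid[order(grid$c, grid$gamma), ]
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$c <- grid$c[g]; cfg$gamma <- grid$gamma[g]
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fm_subset(fm, which(assign_f != f))
      te <- fm_subset(fm, which(assign_f == f))
      model <- svm_train(tr, cfg)
      correct <- correct + sum(predict(model, te) == te$label)
    }
    100 * correct / nrow(fm$x)
  }, numeric(1L))
  best <- which.max(acc)   # grid sorted by (c, gamma): first max = tie rule
  out <- config
  out$c <- grid$c[best]
  out$gamma <- grid$gamma[best]
  attr(out, "grid") <- cbind(grid, acc = acc)
  out
}

# stratified fold assignment; every fold gets both classes when possible
stratified_folds <- function(label, k, seed) {
  out <- integer(length(label))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(label)) {
      idx <- which(label == cls)
      if (length(idx) < k && length(idx) < 2L)
        stop("class '", cls, "' has too few samples for ", k, " folds")
      out[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  out
}

#' Save / load a trained model archive
#'
#' The archive is a single JSON file holding the configuration, scaling
#' parameters, support vectors and coefficients, so a model round-trips
#' through plain text.
#'
#' @param model A `cwl_svm`.
#' @param path Archive path (JSON).
#' @return `path` invisibly (save); a `cwl_svm` (load).
#' @export
save_model <- function(model, path) {
  obj <- list(sv = model$sv, coef = model$coef, b = model$b,
              gamma = model$gamma,
              config = unclass(model$config), scaling = model$scaling,
              features = model$features)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- matrix(obj$sv, nrow = length(obj$coef), byrow = FALSE)
  # jsonlite returns row-major written matrices as proper matrices already
  if (is.matrix(obj$sv)) sv <- obj$sv
  colnames(sv) <- obj$features
  cfg <- obj$config
  model <- list(sv = sv, coef = obj$coef, b = obj$b, gamma = obj$gamma,
                config = svm_config(c = cfg$c, gamma = cfg$gamma,
                                    c_grid = cfg$c_grid,
                                    gamma_grid = cfg$gamma_grid,
                                    scale = cfg$scale),
                scaling = obj$scaling, features = obj$features,
                iterations = NA_integer_)
  if (!is.null(model$scaling)) {
    model$scaling$lo <- setNames(as.numeric(model$scaling$lo), obj$features)
    model$scaling$rng <- setNames(as.numeric(model$scaling$rng), obj$features)
  }
  class(model) <- "cwl_svm"
  model
}
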