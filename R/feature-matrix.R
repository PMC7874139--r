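#' Labeled feature matrix
#'
#' The common currency of balancing, selection and classification: a numeric
#' samples x features matrix with unique sample ids, a binary label per row
#' and a provenance flag distinguishing original samples from SMOTE-made
#' synthetic ones.
#'
#' @param x Numeric matrix with unique rownames (sample ids) and colnames
#'   (feature names).
#' @param label Character/factor vector of `"positive"` / `"negative"`, one
#'   per row.
#' @param provenance Character vector of `"original"` / `"synthetic"`, one
#'   per row; defaults to all original.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, label, provenance = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("s", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate sample ids")
  if (is.null(colnames(x))) stop("feature matrix needs feature names")
  if (anyDuplicated(colnames(x))) stop("duplicate feature names")
  label <- as.character(label)
  if (length(label) != nrow(x))
    stop("label vector length ", length(label), " != row count ", nrow(x))
  if (!all(label %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  if (is.null(provenance)) provenance <- rep("original", nrow(x))
  if (length(provenance) != nrow(x) ||
      !all(provenance %in% c("original", "synthetic")))
    stop("provenance must be 'original'/'synthetic', one per row")
  structure(list(x = x, label = label, provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d samples (%d positive / %d negative; %d synthetic) x %d features\n",
    nrow(x$x), sum(x$label == "positive"), sum(x$label == "negative"),
    sum(x$provenance == "synthetic"), ncol(x$x)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

# row subset preserving labels/provenance
fm_subset <- function(fm, rows, cols = NULL) {
  x <- fm$x[rows, , drop = FALSE]
  if (!is.null(cols)) x <- x[, cols, drop = FALSE]
  feature_matrix(x, fm$label[rows], fm$provenance[rows])
}

# rbind two feature matrices with identical feature names
fm_rbind <- function(a, b) {
  stopifnot(identical(colnames(a$x), colnames(b$x)))
  feature_matrix(rbind(a$x, b$x), c(a$label, b$label),
                 c(a$provenance, b$provenance))
}

#' Write / read a feature matrix as CSV
#'
#' Serialized with a header row of feature names plus `sample_id`, `label`
#' and `provenance` columns, so balanced matrices round-trip including the
#' synthetic flags.
#'
#' @param fm A [feature_matrix()].
#' @param path CSV file path.
#' @return `path` invisibly (writer); a [feature_matrix()] (reader).
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(sample_id = rownames(fm$x), label = fm$label,
                   provenance = fm$provenance, fm$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("sample_id", "label", "provenance")
  if (!all(meta %in% names(df)))
    stop("feature CSV '", path, "': needs columns ",
         paste(meta, collapse = ", "))
  x <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(x) <- df$sample_id
  feature_matrix(x, df$label, df$provenance)
}
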