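#' Encoder configuration
#'
#' Bundles the tunable parameters of the feature encoders. The defaults are
#' the values selected for the final model: PSSM auto-covariance maximum lag
#' `lg = 28`, acACS maximum lag `lambda = 17`, and all four backbone nuclei.
#'
#' @param lg Positive integer, maximum lag of the PSSM auto-covariance.
#' @param lambda Positive integer, maximum lag of the acACS encoder.
#' @param nuclei Non-empty subset of [ACS_NUCLEI].
#' @param acacs_variant `"difference"` (the printed formula: mean of signed
#'   lag differences) or `"covariance"` (mean-centered product form).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(lg = 28L, lambda = 17L, nuclei = ACS_NUCLEI,
                           acacs_variant = c("difference", "covariance")) {
  lg <- as.integer(lg); lambda <- as.integer(lambda)
  stopifnot(lg >= 1L, lambda >= 1L)
  nuclei <- match.arg(nuclei, ACS_NUCLEI, several.ok = TRUE)
  structure(list(lg = lg, lambda = lambda, nuclei = nuclei,
                 acacs_variant = match.arg(acacs_variant)),
            class = "encoder_config")
}

#' Amino acid composition (AAC)
#'
#' The 20-vector of per-residue occurrence frequencies: entry for residue a
#' is count(a) / L. Entries are named `AAC.<residue>` in alphabetical order
#' and sum to 1.
#'
#' @param record A [protein_record()].
#' @return Named numeric vector of length 20.
#' @examples
#' encode_aac(protein_record("p", "ACDE", "positive"))[1:4]  # 0.25 each
#' @export
encode_aac <- function(record) {
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  setNames(as.numeric(counts) / record$length,
           paste0("AAC.", AA_ALPHABET))
}

#' Dipeptide composition (DC)
#'
#' The 400-vector of adjacent ordered residue-pair frequencies: entry for
#' pair ab is (number of positions i with s[i]=a, s[i+1]=b) / (L - 1).
#' Pairs are named `DC.<ab>` in lexicographic order (AA, AC, ..., YY).
#'
#' @param record A [protein_record()] with L >= 2.
#' @return Named numeric vector of length 400 summing to 1.
#' @export
encode_dc <- function(record) {
  if (record$length < 2L)
    stop("record '", record$id, "': dipeptide composition needs L >= 2")
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  pairs <- paste0(chars[-length(chars)], chars[-1L])
  all_pairs <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  counts <- table(factor(pairs, levels = all_pairs))
  setNames(as.numeric(counts) / (record$length - 1L),
           paste0("DC.", all_pairs))
}

#' PSSM auto-covariance (PSSM-AC)
#'
#' For each of the 20 profile columns j and each lag l in 1..lg, the
#' auto-covariance of the mean-centered column:
#' \deqn{AC(j,l) = \frac{1}{L-l}\sum_{i=1}^{L-l}(R_{i,j}-\bar R_j)(R_{i+l,j}-\bar R_j)}
#' with \eqn{\bar R_j} the column mean over all L rows. Yields a 20 x lg
#' vector capturing along-sequence correlation of the evolutionary profile;
#' entries are named `PSSMAC.<residue>.lag<l>`, column-major (all lags of A,
#' then C, ...).
#'
#' @param profile A [pssm_profile()].
#' @param lg Maximum lag, 1 <= lg < L.
#' @return Named numeric vector of length 20 * lg.
#' @export
encode_pssm_ac <- function(profile, lg = 28L) {
  lg <- as.integer(lg)
  L <- nrow(profile$scores)
  if (lg < 1L || lg >= L)
    stop("profile '", profile$record_id, "': lg must satisfy 1 <= lg < L (L = ",
         L, ", lg = ", lg, ")")
  R <- profile$scores
  Rc <- sweep(R, 2L, colMeans(R))          # center each column by its mean
  out <- numeric(20L * lg)
  names(out) <- paste0("PSSMAC.", rep(AA_ALPHABET, each = lg),
                       ".lag", rep(seq_len(lg), times = 20L))
  idx <- 1L
  for (j in seq_len(20L)) {
    cj <- Rc[, j]
    for (l in seq_len(lg)) {
      out[idx] <- sum(cj[1:(L - l)] * cj[(1 + l):L]) / (L - l)
      idx <- idx + 1L
    }
  }
  out
}

#' Auto-covariance of the average chemical shift series (acACS)
#'
#' Substitutes each residue by its ACS value (conditioned on secondary
#' structure) for each selected nucleus, then summarizes each series A by a
#' lag profile for l = 0..lambda. The default `"difference"` variant is the
#' printed formula
#' \deqn{\phi_l = \frac{1}{L-l}\sum_{k=1}^{L-l}(A_k - A_{k+l})}
#' (mean signed lag difference; identically 0 at l = 0, kept for layout
#' fidelity). The `"covariance"` variant uses the conventional
#' mean-centered product \eqn{\frac{1}{L-l}\sum (A_k-\bar A)(A_{k+l}-\bar A)}.
#' Entries are named `ACS.<nucleus>.lag<l>`.
#'
#' @param record A [protein_record()].
#' @param track An [ss_track()] of the same length.
#' @param table An [acs_table()].
#' @param lambda Maximum lag, lambda < L.
#' @param nuclei Subset of [ACS_NUCLEI].
#' @param variant `"difference"` (default) or `"covariance"`.
#' @return Named numeric vector of length |nuclei| * (lambda + 1).
#' @export
encode_acacs <- function(record, track, table, lambda = 17L,
                         nuclei = ACS_NUCLEI,
                         variant = c("difference", "covariance")) {
  variant <- match.arg(variant)
  lambda <- as.integer(lambda)
  L <- record$length
  if (lambda < 1L || lambda >= L)
    stop("record '", record$id, "': lambda must satisfy 1 <= lambda < L (L = ",
         L, ", lambda = ", lambda, ")")
  nuclei <- match.arg(nuclei, ACS_NUCLEI, several.ok = TRUE)
  out <- numeric(0L)
  for (nu in nuclei) {
    A <- substitute_acs(record, track, table, nu)
    phis <- vapply(0:lambda, function(l) {
      if (variant == "difference") {
        if (l == 0L) 0 else sum(A[1:(L - l)] - A[(1 + l):L]) / (L - l)
      } else {
        Ac <- A - mean(A)
        sum(Ac[1:(L - l)] * Ac[(1 + l):L]) / (L - l)
      }
    }, numeric(1L))
    out <- c(out, setNames(phis, paste0("ACS.", nu, ".lag", 0:lambda)))
  }
  out
}

#' Combined feature vector
#'
#' Concatenates the selected feature blocks for one record in the given
#' order (default AAC, DC, acACS, PSSM-AC). Block prefixes keep the combined
#' namespace unique. With the default configuration (lg = 28, lambda = 17,
#' four nuclei) the combined vector has 20 + 400 + 72 + 560 = 1052 entries.
#'
#' @param record A [protein_record()].
#' @param profile A [pssm_profile()] (required iff `"PSSMAC"` is selected).
#' @param track An [ss_track()] (required iff `"ACS"` is selected).
#' @param table An [acs_table()] (required iff `"ACS"` is selected).
#' @param config An [encoder_config()].
#' @param blocks Ordered subset of `c("AAC", "DC", "ACS", "PSSMAC")`.
#' @return Named numeric vector.
#' @export
encode_combined <- function(record, profile = NULL, track = NULL,
                            table = NULL, config = encoder_config(),
                            blocks = c("AAC", "DC", "ACS", "PSSMAC")) {
  blocks <- match.arg(blocks, c("AAC", "DC", "ACS", "PSSMAC"),
                      several.ok = TRUE)
  out <- numeric(0L)
  for (b in blocks) {
    v <- switch(b,
      AAC = encode_aac(record),
      DC = encode_dc(record),
      ACS = {
        if (is.null(track) || is.null(table))
          stop("record '", record$id,
               "': acACS block requested but track/table missing")
        encode_acacs(record, track, table, lambda = config$lambda,
                     nuclei = config$nuclei, variant = config$acacs_variant)
      },
      PSSMAC = {
        if (is.null(profile))
          stop("record '", record$id,
               "': PSSM-AC block requested but profile missing")
        encode_pssm_ac(profile, lg = config$lg)
      })
    out <- c(out, v)
  }
  out
}

#' Encode every record of a dataset into a feature matrix
#'
#' Applies [encode_combined()] to each record and stacks the results into a
#' [feature_matrix()] carrying labels and provenance (`"original"`).
#'
#' @param dataset A [labeled_dataset()].
#' @param config An [encoder_config()].
#' @param blocks Feature blocks, as in [encode_combined()].
#' @param table An [acs_table()]; defaults to [default_acs_table()] when the
#'   ACS block is selected.
#' @return A [feature_matrix()] with one row per record.
#' @export
extract_features <- function(dataset, config = encoder_config(),
                             blocks = c("AAC", "DC", "ACS", "PSSMAC"),
                             table = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  blocks <- match.arg(blocks, c("AAC", "DC", "ACS", "PSSMAC"),
                      several.ok = TRUE)
  if ("ACS" %in% blocks && is.null(table)) table <- default_acs_table()
  rows <- lapply(dataset$records, function(r) {
    encode_combined(r,
                    profile = dataset$profiles[[r$id]],
                    track = dataset$tracks[[r$id]],
                    table = table, config = config, blocks = blocks)
  })
  nm <- names(rows[[1L]])
  for (v in rows) if (!identical(names(v), nm))
    stop("inconsistent feature names across records")
  x <- do.call(rbind, rows)
  rownames(x) <- names(dataset$records)
  feature_matrix(x, dataset_labels(dataset))
}
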