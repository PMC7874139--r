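#' Average chemical shift (ACS) lookup table
#'
#' Maps each (residue, secondary-structure state, nucleus) triple to an
#' average backbone chemical shift in ppm. A complete table covers
#' 20 residues x 3 states x 4 nuclei (15N, 13Ca, 1Ha, 1HN, coded `N15`,
#' `CA13`, `HA1`, `HN1`).
#'
#' @param df Data frame with columns `residue`, `state`, `nucleus`, `value`.
#' @return An object of class `acs_table` (environment-free lookup).
#' @export
acs_table <- function(df) {
  need <- c("residue", "state", "nucleus", "value")
  if (!all(need %in% names(df)))
    stop("ACS table needs columns ", paste(need, collapse = ", "))
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value))) stop("ACS table values must be finite")
  key <- paste(df$residue, df$state, df$nucleus, sep = ".")
  if (anyDuplicated(key)) stop("ACS table has duplicate (residue,state,nucleus) rows")
  full <- expand.grid(residue = AA_ALPHABET, state = SS_STATES,
                      nucleus = ACS_NUCLEI, stringsAsFactors = FALSE)
  full_key <- paste(full$residue, full$state, full$nucleus, sep = ".")
  missing <- setdiff(full_key, key)
  if (length(missing))
    stop("ACS table incomplete; missing e.g. ",
         paste(head(missing, 3L), collapse = ", "))
  structure(list(values = setNames(df$value, key)), class = "acs_table")
}

#' @export
print.acs_table <- function(x, ...) {
  cat("<acs_table> 20 residues x 3 states x 4 nuclei; range",
      sprintf("%.2f..%.2f ppm\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Read an ACS table from a whitespace-separated text file
#'
#' Expected columns: `residue state nucleus value`, one triple per line,
#' `#` comments allowed.
#'
#' @param path Path to the table file.
#' @return An [acs_table()].
#' @export
read_acs_table <- function(path) {
  if (!file.exists(path)) stop("ACS table file not found: ", path)
  df <- read.table(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  acs_table(df)
}

#' The package's default ACS table
#'
#' Loads the shipped synthetic reference table (`acs_shifts_synthetic.tsv`):
#' random-coil backbone shifts perturbed by fixed helix/sheet secondary-shift
#' offsets. It is a realistic stand-in, not measured data; supply your own
#' table via [read_acs_table()] for production use.
#'
#' @return An [acs_table()].
#' @export
default_acs_table <- function() {
  path <- system.file("extdata", "acs_shifts_synthetic.tsv",
                      package = "cwlytic", mustWork = TRUE)
  read_acs_table(path)
}

#' Substitute a sequence by per-residue average chemical shifts
#'
#' Replaces residue k by the table value for (residue_k, state_k, nucleus),
#' producing the real-valued series the acACS encoder summarizes.
#'
#' @param record A [protein_record()].
#' @param track An [ss_track()] of the same length.
#' @param table An [acs_table()].
#' @param nucleus One of `r paste(ACS_NUCLEI, collapse=", ")`.
#' @return Numeric vector of length L.
#' @examples
#' rec <- protein_record("p", "ACDE", "positive")
#' trk <- ss_track("p", "CHHC")
#' shifts <- substitute_acs(rec, trk, default_acs_table(), "CA13")
#' @export
substitute_acs <- function(record, track, table, nucleus) {
  stopifnot(inherits(table, "acs_table"))
  nucleus <- match.arg(nucleus, ACS_NUCLEI)
  if (nchar(track$states) != record$length)
    stop("record '", record$id, "': track length ", nchar(track$states),
         " != sequence length ", record$length)
  res <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  st <- strsplit(track$states, "", fixed = TRUE)[[1L]]
  key <- paste(res, st, nucleus, sep = ".")
  out <- unname(table$values[key])
  if (any(is.na(out))) {
    miss <- key[which(is.na(out))[1L]]
    stop("ACS table has no entry for (", gsub("\\.", ", ", miss), ")")
  }
  out
}
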