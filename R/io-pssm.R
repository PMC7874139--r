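#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` layout: header lines, a column-letter line,
#' then one row per residue holding the position index, the residue letter,
#' 20 substitution scores and (optionally) 20 weighted percentages plus
#' information columns, which are discarded. Whatever residue order the file
#' header declares, the returned matrix columns are permuted into the
#' package's canonical alphabetical order.
#'
#' @param path Path to the ASCII PSSM file.
#' @param record_id Identifier to attach; defaults to the file base name.
#' @return A [pssm_profile()] with an L x 20 score matrix.
#' @export
read_pssm_ascii <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(record_id))
    record_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)

  # locate the column-letter header: >= 20 single-letter tokens
  header_i <- NA_integer_
  col_order <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) >= 20L && all(grepl("^[A-Z]$", toks[1:20]))) {
      cand <- toks[1:20]
      if (setequal(cand, AA_ALPHABET)) {
        header_i <- i
        col_order <- cand
        break
      }
    }
  }
  if (is.na(header_i))
    stop("PSSM '", path, "': no residue column header line found")

  rows <- list()
  residues <- character()
  for (i in seq(header_i + 1L, length(lines))) {
    if (i > length(lines)) break
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break                       # blank line ends the matrix
    toks <- strsplit(ln, "\\s+")[[1L]]
    if (!grepl("^[0-9]+$", toks[1L])) break      # footer (Lambda/K block)
    if (length(toks) < 22L)
      stop("PSSM '", path, "' row ", toks[1L], ": expected >= 20 score ",
           "columns, found ", length(toks) - 2L)
    sc <- suppressWarnings(as.numeric(toks[3:22]))
    if (any(is.na(sc)))
      stop("PSSM '", path, "' row ", toks[1L], ": non-numeric score cell")
    rows[[length(rows) + 1L]] <- sc
    residues <- c(residues, toks[2L])
  }
  if (!length(rows))
    stop("PSSM '", path, "': no score rows found after header")
  m <- do.call(rbind, rows)
  colnames(m) <- col_order
  m <- m[, AA_ALPHABET, drop = FALSE]
  prof <- pssm_profile(record_id, m)
  prof$residues <- paste(residues, collapse = "")
  prof
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' Emits the classic `-out_ascii_pssm` text layout (default PSI-BLAST column
#' order) so generated fixtures exercise the same code path as real files.
#'
#' @param profile A [pssm_profile()].
#' @param sequence Residue letters for the second column (string of length L).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(profile, sequence, path) {
  m <- profile$scores[, PSIBLAST_ORDER, drop = FALSE]
  if (nchar(sequence) != nrow(m))
    stop("sequence length != profile rows")
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%4s", PSIBLAST_ORDER), collapse = ""))
  ), con)
  for (i in seq_len(nrow(m))) {
    writeLines(sprintf("%5d %s %s", i, res[i],
                       paste(sprintf("%4d", as.integer(round(m[i, ]))),
                             collapse = "")), con)
  }
  writeLines("", con)
  invisible(path)
}
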