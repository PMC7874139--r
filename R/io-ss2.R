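#' Read a PSIPRED VFORMAT (.ss2) secondary-structure file
#'
#' Layout: a comment line (starting with `#`), a blank line, then one row per
#' residue with columns `index residue state pC pH pE`. Only the state letter
#' column is kept; it must be one of H, E, C.
#'
#' @param path Path to the .ss2 file.
#' @param record_id Identifier to attach; defaults to the file base name.
#' @param sequence Optional paired sequence; when given, the residue column
#'   is cross-checked against it and a mismatch raises a validation error.
#' @return An [ss_track()].
#' @export
read_ss2 <- function(path, record_id = NULL, sequence = NULL) {
  if (!file.exists(path)) stop("ss2 file not found: ", path)
  if (is.null(record_id))
    record_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("ss2 '", path, "': no residue rows")
  states <- character(length(lines))
  residues <- character(length(lines))
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) < 3L)
      stop("ss2 '", path, "' row ", i, ": expected >= 3 columns")
    residues[i] <- toks[2L]
    st <- toks[3L]
    if (!st %in% SS_STATES)
      stop("ss2 '", path, "' row ", i, ": state letter '", st,
           "' outside {H,E,C}")
    states[i] <- st
  }
  if (!is.null(sequence)) {
    seq_chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
    if (length(seq_chars) != length(residues))
      stop("ss2 '", path, "': ", length(residues),
           " rows but paired sequence has ", length(seq_chars), " residues")
    mism <- which(residues != seq_chars)
    if (length(mism))
      stop("ss2 '", path, "': residue column disagrees with paired ",
           "sequence at position(s) ", paste(head(mism, 5L), collapse = ", "))
  }
  ss_track(record_id, paste(states, collapse = ""))
}

#' Write a secondary-structure track as a PSIPRED-style .ss2 file
#'
#' @param track An [ss_track()].
#' @param sequence Residue letters for the second column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ss2 <- function(track, sequence, path) {
  states <- strsplit(track$states, "", fixed = TRUE)[[1L]]
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (length(res) != length(states)) stop("sequence length != track length")
  # deterministic dummy probabilities: 1 on the called state
  pc <- ifelse(states == "C", 1, 0)
  ph <- ifelse(states == "H", 1, 0)
  pe <- ifelse(states == "E", 1, 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# PSIPRED VFORMAT (cwlytic synthetic)", ""), con)
  writeLines(sprintf("%4d %s %s  %5.3f %5.3f %5.3f",
                     seq_along(states), res, states, pc, ph, pe), con)
  invisible(path)
}
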