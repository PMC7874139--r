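#' Labeled protein sequence record
#'
#' Constructs a validated protein record. The sequence must be non-empty and
#' drawn from the 20-letter standard alphabet; the ambiguity letters
#' B, J, O, U, X, Z are rejected (sequences carrying them are excluded from
#' benchmark construction in this field). Lowercase input is upcased before
#' validation because FASTA dialects vary.
#'
#' @param id Character identifier, unique within a dataset.
#' @param sequence Amino-acid sequence string.
#' @param label Class label, `"positive"` (cell-wall lytic enzyme) or
#'   `"negative"`.
#' @return An object of class `protein_record` with fields `id`, `sequence`,
#'   `label` and `length`.
#' @examples
#' rec <- protein_record("p1", "ACDE", "positive")
#' rec$length  # 4
#' @export
protein_record <- function(id, sequence, label = c("positive", "negative")) {
  label <- match.arg(label)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string")
  sequence <- toupper(sequence)
  if (!nzchar(sequence))
    stop("record '", id, "': sequence is empty")
  letters_seen <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(letters_seen), AA_ALPHABET)
  if (length(bad)) {
    amb <- intersect(bad, AA_AMBIGUOUS)
    what <- if (length(amb)) "ambiguous letter" else "invalid character"
    stop("record '", id, "': ", what, " ",
         paste(sQuote(bad), collapse = ", "),
         " not in the 20-letter amino-acid alphabet")
  }
  structure(
    list(id = id, sequence = sequence, label = label,
         length = nchar(sequence)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s [%s] L=%d\n  %s%s\n", x$id, x$label,
              x$length, substr(x$sequence, 1L, 60L),
              if (x$length > 60L) "..." else ""))
  invisible(x)
}

#' Secondary-structure track
#'
#' A per-residue three-state (H/E/C) secondary-structure string aligned to a
#' protein record. Accepts a plain state string as a convenience constructor;
#' use [read_ss2()] for PSIPRED output files.
#'
#' @param record_id Identifier of the record the track belongs to.
#' @param states String over \{H, E, C\}, one state per residue.
#' @return An object of class `ss_track`.
#' @examples
#' ss_track("p1", "CCEEHH")
#' @export
ss_track <- function(record_id, states) {
  stopifnot(is.character(record_id), length(record_id) == 1L)
  states <- toupper(states)
  chars <- strsplit(states, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), SS_STATES)
  if (length(bad))
    stop("track '", record_id, "': state letter(s) ",
         paste(sQuote(bad), collapse = ", "), " outside {H,E,C}")
  structure(list(record_id = record_id, states = states),
            class = "ss_track")
}

#' Position-specific scoring matrix profile
#'
#' Wraps an L x 20 substitution-score matrix aligned to a sequence. Columns
#' are always in the canonical alphabetical residue order (see
#' [AA_ALPHABET]); [read_pssm_ascii()] permutes PSI-BLAST file order on read.
#'
#' @param record_id Identifier of the record the profile belongs to.
#' @param scores Numeric matrix, one row per residue, 20 columns.
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(record_id, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    stop("profile '", record_id, "': expected 20 score columns, got ",
         ncol(scores))
  if (!is.numeric(scores) || any(!is.finite(scores)))
    stop("profile '", record_id, "': scores must be finite numbers")
  if (is.null(colnames(scores))) {
    colnames(scores) <- AA_ALPHABET
  } else {
    if (!setequal(colnames(scores), AA_ALPHABET))
      stop("profile '", record_id, "': column names must be the 20 residues")
    scores <- scores[, AA_ALPHABET, drop = FALSE]
  }
  structure(list(record_id = record_id, scores = scores),
            class = "pssm_profile")
}

#' Labeled dataset of protein records with optional profiles and tracks
#'
#' The container moved through the pipeline: an ordered set of validated
#' records partitioned into positive and negative classes, with optional
#' per-record PSSM profiles and secondary-structure tracks. Attached
#' profiles/tracks are checked for id and length agreement.
#'
#' @param records List of [protein_record()] objects with unique ids.
#' @param profiles Optional named list of [pssm_profile()] (names = record ids).
#' @param tracks Optional named list of [ss_track()] (names = record ids).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(records, profiles = NULL, tracks = NULL) {
  stopifnot(is.list(records))
  ids <- vapply(records, function(r) r$id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(records) <- ids
  lens <- vapply(records, function(r) r$length, integer(1L))
  check_aligned <- function(objs, kind, len_of) {
    if (is.null(objs)) return(NULL)
    stopifnot(is.list(objs))
    for (o in objs) {
      rid <- o$record_id
      if (!rid %in% ids)
        stop(kind, " '", rid, "' has no matching record")
      if (len_of(o) != lens[[rid]])
        stop(kind, " '", rid, "' length ", len_of(o),
             " != sequence length ", lens[[rid]])
    }
    setNames(objs, vapply(objs, function(o) o$record_id, character(1L)))
  }
  profiles <- check_aligned(profiles, "profile", function(o) nrow(o$scores))
  tracks <- check_aligned(tracks, "track", function(o) nchar(o$states))
  structure(list(records = records, profiles = profiles, tracks = tracks),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  lab <- dataset_labels(x)
  cat(sprintf(
    "<labeled_dataset> %d records (%d positive, %d negative); %d PSSM, %d ss2\n",
    length(x$records), sum(lab == "positive"), sum(lab == "negative"),
    length(x$profiles), length(x$tracks)))
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$records)

# label vector in record order
dataset_labels <- function(dataset) {
  vapply(dataset$records, function(r) r$label, character(1L))
}
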