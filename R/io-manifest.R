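#' Read a dataset manifest linking record ids to PSSM and ss2 files
#'
#' Tab-separated, three columns with a header: `id`, `pssm`, `ss2`. Paths are
#' resolved relative to the manifest's own directory; empty cells mean the
#' corresponding input is absent for that record.
#'
#' @param path Path to the manifest TSV.
#' @return Data frame with columns `id`, `pssm`, `ss2` (absolute paths or NA).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character", quote = "", comment.char = "")
  need <- c("id", "pssm", "ss2")
  if (!all(need %in% names(df)))
    stop("manifest '", path, "': needs columns ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | !nzchar(p), NA_character_,
                            ifelse(grepl("^/", p), p, file.path(base, p)))
  df$pssm <- fix(df$pssm)
  df$ss2 <- fix(df$ss2)
  df[need]
}

#' Load a full labeled dataset from FASTA files and an optional manifest
#'
#' Reads one FASTA per class (positive first), then, if a manifest is given,
#' parses and attaches the per-record PSSM profiles and secondary-structure
#' tracks, validating id and length agreement.
#'
#' @param positive_fasta,negative_fasta Paths to the class FASTA files.
#' @param manifest Optional path to a manifest TSV (see [read_manifest()]).
#' @return A [labeled_dataset()].
#' @export
load_dataset <- function(positive_fasta, negative_fasta, manifest = NULL) {
  records <- c(read_fasta(positive_fasta, "positive"),
               read_fasta(negative_fasta, "negative"))
  profiles <- NULL
  tracks <- NULL
  if (!is.null(manifest)) {
    man <- read_manifest(manifest)
    seqs <- setNames(
      vapply(records, function(r) r$sequence, character(1L)),
      vapply(records, function(r) r$id, character(1L)))
    profiles <- list()
    tracks <- list()
    for (i in seq_len(nrow(man))) {
      id <- man$id[i]
      if (!id %in% names(seqs))
        stop("manifest row ", i, ": id '", id, "' not in the FASTA files")
      if (!is.na(man$pssm[i]))
        profiles[[id]] <- read_pssm_ascii(man$pssm[i], record_id = id)
      if (!is.na(man$ss2[i]))
        tracks[[id]] <- read_ss2(man$ss2[i], record_id = id,
                                 sequence = seqs[[id]])
    }
    if (!length(profiles)) profiles <- NULL
    if (!length(tracks)) tracks <- NULL
  }
  labeled_dataset(records, profiles = profiles, tracks = tracks)
}
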