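#' Specification for synthetic fixture generation
#'
#' The stated world of the package's closed-loop tests: class sizes, the
#' sequence-length range, a class-separation effect size and a mandatory
#' seed. Separation acts at the residue-composition level for sequences
#' (positives enriched, negatives depleted, in the first ten residues of
#' the alphabet), at the column-score level for PSSMs, and as a mean shift
#' for Gaussian feature matrices; `separation = 0` gives exchangeable
#' classes (the null world).
#'
#' @param n_pos,n_neg Class sizes (>= 0).
#' @param length_range Integer range of sequence lengths, min >= 2.
#' @param separation Non-negative effect size.
#' @param seed Integer seed (mandatory).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_pos, n_neg, length_range = c(60L, 100L),
                       separation = 1, seed) {
  if (missing(seed)) stop("synth_spec: seed is mandatory")
  stopifnot(n_pos >= 0, n_neg >= 0, length(length_range) == 2L,
            length_range[1] >= 2L, length_range[1] <= length_range[2],
            separation >= 0)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 separation = separation, seed = as.integer(seed)),
            class = "synth_spec")
}

# class-conditional residue composition: tilt the first 10 letters up for
# positives and down for negatives (softmax of +/- separation/2)
class_composition <- function(separation, positive) {
  s <- rep(c(1, -1), each = 10L)
  w <- exp((if (positive) 1 else -1) * (separation / 2) * s)
  w / sum(w)
}

#' Generate a synthetic labeled dataset on disk
#'
#' Writes `positive.fasta`, `negative.fasta`, one PSI-BLAST-layout PSSM and
#' one PSIPRED-layout ss2 file per record, and a `manifest.tsv`, all into
#' `dir`, then loads everything back through the package's own parsers.
#' Sequences are drawn from class-tilted residue compositions (so AAC/DC
#' separate the classes at large effect size), PSSM scores are class-biased
#' integers in [-10, 10], and secondary-structure states follow a sticky
#' three-state Markov chain. Deterministic given the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return The generated [labeled_dataset()], re-read from disk.
#' @export
gen_records <- function(spec, dir = tempfile("synthds")) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  dir.create(file.path(dir, "ss2"), showWarnings = FALSE)

  withr::with_seed(spec$seed, {
    make_class <- function(n, positive) {
      comp <- class_composition(spec$separation, positive)
      prefix <- if (positive) "pos" else "neg"
      lapply(seq_len(n), function(i) {
        L <- sample(seq(spec$length_range[1], spec$length_range[2]), 1L)
        seqs <- paste(sample(AA_ALPHABET, L, replace = TRUE, prob = comp),
                      collapse = "")
        rec <- protein_record(sprintf("%s%03d", prefix, i), seqs,
                              if (positive) "positive" else "negative")
        # class-biased PSSM scores: mean +/- separation on the tilted letters
        mu <- (if (positive) 1 else -1) * spec$separation *
          rep(c(1, -1), each = 10L)
        sc <- matrix(pmin(10, pmax(-10, round(
          rnorm(L * 20L, mean = rep(mu, each = L), sd = 3)))), nrow = L)
        colnames(sc) <- AA_ALPHABET
        # sticky H/E/C Markov chain (stay 0.8)
        st <- character(L)
        st[1L] <- sample(SS_STATES, 1L)
        for (p in seq_len(L - 1L)) {
          st[p + 1L] <- if (runif(1) < 0.8) st[p] else
            sample(setdiff(SS_STATES, st[p]), 1L)
        }
        list(record = rec, scores = sc, states = paste(st, collapse = ""))
      })
    }
    all <- c(make_class(spec$n_pos, TRUE), make_class(spec$n_neg, FALSE))

    man <- data.frame(id = character(0), pssm = character(0),
                      ss2 = character(0))
    for (e in all) {
      id <- e$record$id
      pssm_path <- file.path("pssm", paste0(id, ".pssm"))
      ss2_path <- file.path("ss2", paste0(id, ".ss2"))
      write_pssm_ascii(pssm_profile(id, e$scores), e$record$sequence,
                       file.path(dir, pssm_path))
      write_ss2(ss_track(id, e$states), e$record$sequence,
                file.path(dir, ss2_path))
      man <- rbind(man, data.frame(id = id, pssm = pssm_path, ss2 = ss2_path))
    }
    labels <- vapply(all, function(e) e$record$label, character(1L))
    write_fasta(lapply(all[labels == "positive"], `[[`, "record"),
                file.path(dir, "positive.fasta"))
    write_fasta(lapply(all[labels == "negative"], `[[`, "record"),
                file.path(dir, "negative.fasta"))
    write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  })
  load_dataset(file.path(dir, "positive.fasta"),
               file.path(dir, "negative.fasta"),
               manifest = file.path(dir, "manifest.tsv"))
}

#' Generate a two-class Gaussian feature matrix
#'
#' Unit-variance Gaussian features; the positive class mean is shifted by
#' `shift` (default: `spec$separation` on the first half of the features,
#' 0 on the rest). Used to test balancing, ranking, selection and
#' classification in isolation from the sequence encoders.
#'
#' @param spec A [synth_spec()] (class sizes, separation, seed).
#' @param n_features Number of features (default 20).
#' @param shift Optional explicit per-feature mean-shift vector.
#' @return A [feature_matrix()] with features `f1..fn`.
#' @export
gen_feature_matrix <- function(spec, n_features = 20L, shift = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  n_features <- as.integer(n_features)
  if (is.null(shift)) {
    shift <- rep(0, n_features)
    shift[seq_len(ceiling(n_features / 2))] <- spec$separation
  }
  stopifnot(length(shift) == n_features)
  n <- spec$n_pos + spec$n_neg
  withr::with_seed(spec$seed, {
    x <- matrix(rnorm(n * n_features), nrow = n)
    x[seq_len(spec$n_pos), ] <-
      sweep(x[seq_len(spec$n_pos), , drop = FALSE], 2L, shift, "+")
  })
  colnames(x) <- paste0("f", seq_len(n_features))
  rownames(x) <- c(sprintf("pos%03d", seq_len(spec$n_pos)),
                   sprintf("neg%03d", seq_len(spec$n_neg)))
  feature_matrix(x, rep(c("positive", "negative"),
                        c(spec$n_pos, spec$n_neg)))
}
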