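# Synthetic promoters with planted cis-element occurrences on a random
# background of controllable GC content.

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# one concrete realization of an IUPAC consensus
.realize_consensus <- function(consensus) {
  paste(map_chr(strsplit(toupper(consensus), "")[[1]], function(ch) {
    opts <- .iupac_sets[[ch]]
    if (is.null(opts)) abort(sprintf("invalid IUPAC letter '%s'", ch))
    if (length(opts) == 1) opts else sample(opts, 1)
  }), collapse = "")
}

#' Generate a promoter with planted motifs
#'
#' Builds a random background of the requested GC content and overwrites it
#' with concrete realizations of the planted consensi at the stated 1-based
#' positions (reverse-complemented for strand `-`). Planted occurrences must
#' fit inside the sequence and may not overlap each other. Scanning the
#' result with [scan_motifs()] finds every planted occurrence at its
#' recorded position and strand (the background may add further chance
#' hits).
#'
#' @param length Promoter length in nt.
#' @param planted Tibble with columns `motif`, `position`, `strand`
#'   (`"+"`/`"-"`); may have zero rows.
#' @param background_gc Background G+C fraction in `[0, 1]` (default 0.4).
#' @param motifs Motif-definition table mapping names to consensi
#'   (default [load_motifs()]).
#' @param seed Integer seed.
#' @return List: `sequence` (character), `truth` (the planted tibble with a
#'   `matched_sequence` column).
#' @export
generate_promoter <- function(length, planted = NULL, background_gc = 0.4,
                              motifs = load_motifs(), seed = 1) {
  stopifnot(length >= 1, background_gc >= 0, background_gc <= 1)
  planted <- planted %||% tibble(motif = character(0), position = integer(0),
                                 strand = character(0))
  if (nrow(planted) > 0) {
    cons <- motifs$consensus[match(planted$motif, motifs$name)]
    if (anyNA(cons)) abort("generate_promoter: unknown motif name in `planted`")
    w <- nchar(cons)
    if (any(planted$position < 1) || any(planted$position + w - 1 > length)) {
      abort("generate_promoter: planted motif does not fit within the sequence")
    }
    iv <- cbind(planted$position, planted$position + w - 1)
    if (nrow(iv) > 1) {
      o <- order(iv[, 1])
      iv <- iv[o, , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
        abort("generate_promoter: planted motifs overlap")
      }
    }
  }
  with_local_seed(seed, {
    p_gc <- background_gc
    bg <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                 prob = c((1 - p_gc) / 2, (1 - p_gc) / 2, p_gc / 2, p_gc / 2))
    truth_seq <- character(nrow(planted))
    if (nrow(planted) > 0) {
      cons <- motifs$consensus[match(planted$motif, motifs$name)]
      for (i in seq_len(nrow(planted))) {
        real <- .realize_consensus(cons[i])
        ins <- if (planted$strand[i] == "-") revcomp(real) else real
        idx <- planted$position[i] + seq_len(nchar(ins)) - 1
        bg[idx] <- strsplit(ins, "")[[1]]
        truth_seq[i] <- ins
      }
    }
    list(sequence = paste(bg, collapse = ""),
         truth = mutate(planted, matched_sequence = truth_seq))
  })
}
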