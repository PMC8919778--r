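#' Pairwise local-alignment identity
#'
#' Identity between two peptides as matches over the length of the shorter
#' sequence, computed on the best Smith–Waterman local alignment (the
#' greedy-incremental clustering convention).
#'
#' @param a,b peptide strings.
#' @return identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

#' Greedy incremental clustering at an identity threshold
#'
#' Sequences are sorted longest-first (ties by lexicographic id); each
#' sequence joins the first existing cluster whose representative it matches
#' at `>= threshold` identity, otherwise it founds a new cluster with itself
#' as representative. Representatives are therefore the longest member of
#' each cluster, and every member is at least `threshold` identical to its
#' representative.
#'
#' @param seqs named character vector of peptides (names are ids).
#' @param threshold identity threshold (default 0.85).
#' @return list of clusters, each `list(representative =, members =)`.
#' @export
greedy_cluster <- function(seqs, threshold = 0.85) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  clusters <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (seq_identity(seqs[[i]], seqs[[reps[k]]]) >= threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      clusters[[length(clusters) + 1L]] <-
        list(representative = id, members = id)
    }
  }
  clusters
}
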