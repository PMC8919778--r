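# Built-in local-alignment scanner: a desk-scale Smith-Waterman search so
# fixtures and small genomes can be processed without any external search
# binary.  Bit scores and e-values use a fixed Karlin-Altschul
# parameterisation; they are calibrated only against themselves and must
# never be compared with scores from external tools.

KA_PROTEIN <- list(lambda = 0.267, K = 0.041)   # gapped BLOSUM62-style
KA_NUCLEOTIDE <- list(lambda = 0.625, K = 0.41) # match/mismatch 2/-3-style

ka_bits <- function(raw, ka) (ka$lambda * raw - log(ka$K)) / log(2)
ka_evalue <- function(bits, m, n) m * as.numeric(n) * 2^(-bits)

# BLOSUM62 with the stop symbol scored like a strong mismatch (-12 instead
# of -4): a local alignment then only crosses a stop codon when the flanks
# on both sides genuinely match (an interrupted ORF), never as a marginal
# chance extension past the end of the real peptide.
blosum62_stop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      B <- blosum62()
      B["*", ] <- -12L; B[, "*"] <- -12L; B["*", "*"] <- 1L
      cache <<- B
    }
    cache
  }
})

# One best local alignment of one peptide query against one translated frame.
# Returns NULL or list(raw, q1, q2, s1, s2) with 1-based aa coordinates.
best_local_aa <- function(query_aa, subject_aa) {
  if (nchar(subject_aa) < 2L || nchar(query_aa) < 2L) return(NULL)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_aa), Biostrings::AAString(subject_aa),
    type = "local", substitutionMatrix = blosum62_stop(),
    gapOpening = 11, gapExtension = 1)
  if (Biostrings::score(al) <= 0) return(NULL)
  pr <- IRanges::ranges(Biostrings::pattern(al))
  sr <- IRanges::ranges(Biostrings::subject(al))
  list(raw = Biostrings::score(al),
       q1 = IRanges::start(pr), q2 = IRanges::end(pr),
       s1 = IRanges::start(sr), s2 = IRanges::end(sr))
}

# Translated (six-frame, genetic code 11) local search of peptide queries
# against a DNA string.  Returns a hit table in genome coordinates.
translated_search <- function(seq, queries, replicon_id = "region",
                              kind = "RT", score_min_bits = 0) {
  n <- nchar(seq)
  frames <- list()
  for (f in 0:2) {
    frames[[length(frames) + 1L]] <-
      list(aa = translate_frame(seq, f), frame = f, strand = "+")
  }
  rc <- revcomp(seq)
  for (f in 0:2) {
    frames[[length(frames) + 1L]] <-
      list(aa = translate_frame(rc, f), frame = f, strand = "-")
  }
  out <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi] %||% paste0("q", qi)
    q <- queries[[qi]]
    qlen <- nchar(q)
    for (fr in frames) {
      al <- best_local_aa(q, fr$aa)
      if (is.null(al)) next
      bits <- ka_bits(al$raw, KA_PROTEIN)
      if (bits < score_min_bits) next
      # aa positions -> nt on the translated strand (0-based half-open)
      nt_s <- fr$frame + 3L * (al$s1 - 1L)
      nt_e <- fr$frame + 3L * al$s2
      if (fr$strand == "-") { tmp <- nt_s; nt_s <- n - nt_e; nt_e <- n - tmp }
      out[[length(out) + 1L]] <- new_hits(
        replicon_id, kind, nt_s, nt_e, fr$strand, bits,
        ka_evalue(bits, qlen, n), qid, (al$q2 - al$q1 + 1L) / qlen,
        "alignment")
    }
  }
  do.call(rbind_hits, out)
}

# Nucleotide local search (both strands) of DNA queries against a DNA string.
nucleotide_search <- function(seq, queries, replicon_id = "region",
                              kind = "DV_VI", score_min_bits = 0) {
  n <- nchar(seq)
  subj <- Biostrings::DNAString(seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  out <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi] %||% paste0("q", qi)
    q <- queries[[qi]]
    qlen <- nchar(q)
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") q else revcomp(q)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(qs), subj, type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      raw <- Biostrings::score(al)
      if (raw <= 0) next
      bits <- ka_bits(raw, KA_NUCLEOTIDE)
      if (bits < score_min_bits) next
      sr <- IRanges::ranges(Biostrings::subject(al))
      pr <- IRanges::ranges(Biostrings::pattern(al))
      out[[length(out) + 1L]] <- new_hits(
        replicon_id, kind, IRanges::start(sr) - 1L, IRanges::end(sr), strand,
        bits, ka_evalue(bits, qlen, n), qid,
        IRanges::width(pr) / qlen, "alignment")
    }
  }
  do.call(rbind_hits, out)
}

#' Built-in local-alignment search
#'
#' Smith–Waterman local search of labelled queries against one genome:
#' `translated` mode aligns peptide queries against all six reading frames
#' (genetic code 11); `nucleotide` mode aligns DNA queries against both
#' strands. Scores are reported in bits with a score-derived pseudo-e-value
#' under fixed Karlin–Altschul parameters; these are internally consistent
#' but are fixture-scale stand-ins, never comparable with external search
#' tools. One best alignment per query, frame and strand is reported.
#'
#' @param genome a `GenomeRecord`.
#' @param queries named character vector of query sequences (peptides for
#'   `translated`, DNA for `nucleotide`).
#' @param mode `"translated"` or `"nucleotide"`.
#' @param score_min minimum bit score to report.
#' @param kind domain kind stamped on the hits.
#' @return a hit data.frame (0-based half-open genome coordinates).
#' @export
builtin_local_search <- function(genome, queries,
                                 mode = c("translated", "nucleotide"),
                                 score_min = 50, kind = "RT") {
  mode <- match.arg(mode)
  stopifnot(length(queries) > 0)
  qs <- as.character(queries)
  names(qs) <- names(queries)
  if (mode == "translated") {
    if (any(grepl("^[ACGTN]+$", qs) & nchar(qs) > 30))
      stop("translated mode expects peptide queries, got DNA-like sequences")
    translated_search(genome$sequence, qs, genome$replicon_id, kind, score_min)
  } else {
    if (any(grepl("[^ACGTN]", qs)))
      stop("nucleotide mode expects DNA queries (A/C/G/T/N)")
    nucleotide_search(genome$sequence, qs, genome$replicon_id, kind, score_min)
  }
}
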