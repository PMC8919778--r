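#' @importFrom stats fft lm runif setNames cor complete.cases
#' @importFrom utils read.delim write.table head tail data
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic package functions route
# through this so that library use never perturbs user RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Reverse complement of a DNA string
#'
#' @param x a single DNA character string (A/C/G/T/N).
#' @return the reverse complement, same alphabet.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# chartr-based upper-casing plus mapping of any non-ACGTN symbol to N.
# Returns list(seq=, n_mapped=).
sanitize_dna <- function(x) {
  x <- toupper(x)
  bad <- gsub("[ACGTN]", "", x)
  n_mapped <- nchar(bad)
  if (n_mapped > 0) x <- gsub("[^ACGTN]", "N", x)
  list(seq = x, n_mapped = n_mapped)
}

# Bacterial/plastid genetic code (transl_table 11); stops rendered "*".
genetic_code_11 <- function() Biostrings::getGeneticCode("11")

# Translate a DNA string in a given frame (0..2), trimming to whole codons.
# Ambiguous codons (any N) become "X".
translate_frame <- function(seq, frame = 0L) {
  n <- nchar(seq)
  if (n - frame < 3L) return("")
  len <- ((n - frame) %/% 3L) * 3L
  sub <- substr(seq, frame + 1L, frame + len)
  as.character(Biostrings::translate(
    Biostrings::DNAString(sub),
    genetic.code = genetic_code_11(),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

# Substitution matrix for peptide alignment: BLOSUM62 (shipped with
# Biostrings), which includes the '*' symbol so interrupted translations
# can still be aligned.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# 1-based inclusive <-> 0-based half-open coordinate conversion.
# Internal coordinates are 0-based half-open throughout the package;
# emitted files (GFF3/TSV) are 1-based inclusive.
to_1based <- function(start0, end0) list(start = start0 + 1L, end = end0)
to_0based <- function(start1, end1) list(start = start1 - 1L, end = end1)

`%||%` <- function(a, b) if (is.null(a)) b else a
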