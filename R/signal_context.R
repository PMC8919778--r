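# 5'-end localisation by per-IEP-type log-odds profiles, and terminator
# context: shape classification (L/I) and 5'-end-to-terminator distances.

# 5'-consensus profiles exist for nine lineages; CL1 serves CL1A/CL1B and
# CL2 serves CL2A/CL2B.  G (g1) has no published consensus and is excluded.
profile_key <- function(iep_type) {
  if (is.na(iep_type)) return(NA_character_)
  switch(iep_type,
         CL1A = , CL1B = "CL1",
         CL2A = , CL2B = "CL2",
         G_g1 = NA_character_,
         g6 = , U1 = , U2 = , U3 = , unclassified = NA_character_,
         iep_type)
}

#' Build a 5'-end log-odds profile from an alignment
#'
#' Position weight matrix over A/C/G/T from an aligned set of 5'-end
#' consensus sequences: per column, `log2((count + pseudocount) /
#' (n_nongap + 4 * pseudocount) / 0.25)` against a uniform background.
#' All-gap columns are dropped.
#'
#' @param alignment character vector of equal-length aligned sequences
#'   (`-` for gaps), or a path to an aligned FASTA file.
#' @param iep_type type label stored on the profile.
#' @param pseudocount additive smoothing (default 0.1).
#' @param min_bits acceptance score for a scan hit (default 10 bits).
#' @return object of class `FivePrimeProfile` (matrix 4 x width + metadata).
#' @export
build_profile <- function(alignment, iep_type = NA_character_,
                          pseudocount = 0.1, min_bits = 10) {
  if (length(alignment) == 1L && file.exists(alignment)) {
    ss <- Biostrings::readBStringSet(alignment)
    alignment <- as.character(ss)
  }
  stopifnot(length(alignment) >= 1)
  alignment <- toupper(alignment)
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop("alignment sequences must have equal length")
  mat <- do.call(rbind, strsplit(alignment, ""))
  cols <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) return(NULL)  # all-gap column dropped
    cnt <- table(factor(col, levels = c("A", "C", "G", "T")))
    p <- (as.numeric(cnt) + pseudocount) / (length(col) + 4 * pseudocount)
    log2(p / 0.25)
  })
  cols <- Filter(Negate(is.null), cols)
  if (length(cols) == 0L) stop("empty alignment (all columns gapped)")
  pwm <- do.call(cbind, cols)
  rownames(pwm) <- c("A", "C", "G", "T")
  if (ncol(pwm) < 8L) warning("profile shorter than 8 columns")
  structure(list(iep_type = iep_type, pwm = pwm, min_bits = min_bits),
            class = "FivePrimeProfile")
}

# Best-scoring window of a PWM over a DNA string.  Ns score 0.
# Returns list(pos = 0-based offset, bits) or NULL for empty sequence.
scan_pwm <- function(seq, pwm) {
  n <- nchar(seq); w <- ncol(pwm)
  if (n < w) return(NULL)
  ch <- strsplit(seq, "")[[1]]
  idx <- match(ch, c("A", "C", "G", "T"))
  score_at <- function(off) {
    ii <- idx[(off + 1):(off + w)]
    ok <- !is.na(ii)
    if (!any(ok)) return(-Inf)
    sum(pwm[cbind(ii[ok], which(ok))])
  }
  scores <- vapply(0:(n - w), score_at, 0)
  best <- which.max(scores)
  list(pos = best - 1L, bits = scores[best])
}

#' Locate the 5' end of an intron call
#'
#' Scans the per-type log-odds profile over the `window` nt immediately
#' upstream (intron orientation) of the IEP start and returns the genome
#' coordinate of the best-scoring site with score >= `profile$min_bits`
#' (highest bit score wins among multiple candidates). Calls whose type has
#' no published 5' consensus — including bacterial G (g1) — return `NA`.
#'
#' @param call one call-table row; the anchor is `call$rt_start` (plus
#'   strand) / `call$rt_end` (minus strand) unless `anchor` is given.
#' @param genome the `GenomeRecord`.
#' @param profile a `FivePrimeProfile` matching the call's IEP type.
#' @param window upstream search extent in nt (default 1,200).
#' @param anchor optional explicit IEP start genome coordinate.
#' @return 0-based genome coordinate of the 5' end, or `NA_integer_`.
#' @export
locate_5prime <- function(call, genome, profile, window = 1200L,
                          anchor = NULL) {
  if (is.null(profile)) return(NA_integer_)
  if (!is.na(call$iep_type) && call$iep_type == "G_g1") return(NA_integer_)
  if (call$strand == "+") {
    a <- anchor %||% call$rt_start
    s <- a - window
    if (genome$topology == "linear") s <- max(0L, s)
    if (a <= s) return(NA_integer_)
    seq <- extract_span(genome, s, a)
    hit <- scan_pwm(seq, profile$pwm)
    if (is.null(hit) || hit$bits < profile$min_bits) return(NA_integer_)
    as.integer(s + hit$pos)
  } else {
    a <- anchor %||% call$rt_end
    e <- a + window
    if (genome$topology == "linear") e <- min(genome$length, e)
    if (e <= a) return(NA_integer_)
    seq <- revcomp(extract_span(genome, a, e))
    hit <- scan_pwm(seq, profile$pwm)
    if (is.null(hit) || hit$bits < profile$min_bits) return(NA_integer_)
    # position on the reverse axis -> forward coordinate of the 5' base
    as.integer(e - hit$pos - 1L)
  }
}

#' Classify a rho-independent terminator as L- or I-shaped
#'
#' L-shaped terminators carry four or more U residues (T on the DNA sense
#' strand) in the tail immediately after the stem–loop; all others are
#' I-shaped. The tail window is the first `tail_len` nt downstream of the
#' stem (clipped at the replicon end).
#'
#' @param term one terminator row (see [load_terminators()]).
#' @param genome the `GenomeRecord`.
#' @param tail_len tail window (default 10 nt).
#' @param min_u U count for the L call (default 4).
#' @return `"L"` or `"I"`.
#' @export
classify_terminator_shape <- function(term, genome, tail_len = 10L,
                                      min_u = 4L) {
  if (term$strand == "+") {
    s <- term$stem_end
    e <- min(genome$length, s + tail_len)
    if (e <= s) return("I")
    tail <- extract_span(genome, s, e)
  } else {
    e <- term$stem_start
    s <- max(0L, e - tail_len)
    if (e <= s) return("I")
    tail <- revcomp(extract_span(genome, s, e))
  }
  nT <- sum(strsplit(tail, "")[[1]] == "T")
  if (nT >= min_u) "L" else "I"
}

#' Distance from an intron 5' end to the nearest upstream terminator
#'
#' Finds the nearest same-strand terminator whose 3' end lies at or upstream
#' of the intron 5' end (intron orientation) within `max_search` nt, and
#' returns the non-negative distance.
#'
#' @param five_prime 0-based genome coordinate of the intron 5' end.
#' @param strand call strand.
#' @param terms terminator table (see [load_terminators()]).
#' @param max_search search extent in nt (default 5,000).
#' @return list with `distance` and `term` (the matched row), or `NULL`.
#' @export
terminator_distance <- function(five_prime, strand, terms,
                                max_search = 5000L) {
  t <- terms[terms$strand == strand, , drop = FALSE]
  if (nrow(t) == 0) return(NULL)
  d <- if (strand == "+") five_prime - t$term_3prime
       else t$term_3prime - five_prime
  ok <- !is.na(d) & d >= 0 & d <= max_search
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(d[ok])]
  list(distance = as.integer(d[i]), term = t[i, , drop = FALSE])
}

#' Bin terminator distances at the reporting granularity
#'
#' Histogram bins of 100 nt from 0 to 1,000 plus an open `>1000` bin; the
#' bin totals conserve the number of distances.
#'
#' @param distances integer vector of distances (NA dropped).
#' @return named integer vector of bin counts.
#' @export
bin_terminator_distances <- function(distances) {
  d <- distances[!is.na(distances)]
  breaks <- c(seq(0, 1000, by = 100), Inf)
  labs <- c(paste(head(breaks, -2), breaks[-c(1, length(breaks))] - 1,
                  sep = "-"), ">1000")
  cnt <- table(cut(d, breaks = breaks, right = FALSE, labels = labs))
  stats::setNames(as.integer(cnt), names(cnt))
}
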