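# Intron-encoded protein (IEP) analysis: extract the region around each RT
# hit, recover the peptide, and classify it as canonical, interrupted
# (internal stop codons) or short ORF (>= 5 of the 15 conserved motifs
# missing).

START_CODONS <- c("ATG", "GTG", "TTG")

# Extract [s, e) from a replicon, clamping at the ends of linear replicons
# and wrapping around the origin of circular ones.
extract_span <- function(genome, s, e) {
  L <- genome$length
  if (genome$topology == "circular") {
    span <- e - s
    s <- ((s %% L) + L) %% L
    if (span <= 0 || span > L) stop("degenerate span on circular replicon")
    if (s + span <= L) return(substr(genome$sequence, s + 1L, s + span))
    paste0(substr(genome$sequence, s + 1L, L),
           substr(genome$sequence, 1L, span - (L - s)))
  } else {
    s <- max(0L, s); e <- min(L, e)
    if (e <= s) stop("degenerate empty region")
    substr(genome$sequence, s + 1L, e)
  }
}

#' Extract the IEP region around an intron call
#'
#' Returns the nucleotide sequence from `upstream` nt before the RT-domain
#' hit to `downstream` nt after the domain V/VI hit end, in intron
#' orientation (reverse-complemented for minus-strand calls). The region is
#' clamped at the ends of linear replicons and wraps on circular ones.
#' Attributes `g_start`/`g_end` (genome coordinates of the extracted window
#' on the forward axis), `strand` and `rt_span` (RT hit in region
#' coordinates) are attached for downstream ORF analysis.
#'
#' @param call one row of a call table (`category == "iep_containing"`).
#' @param genome the `GenomeRecord` the call lies on.
#' @param upstream,downstream window extents in nt (defaults 1,000 and 200).
#' @return a character scalar with coordinate attributes.
#' @export
extract_iep_region <- function(call, genome, upstream = 1000L,
                               downstream = 200L) {
  stopifnot(call$category == "iep_containing")
  if (call$strand == "+") {
    s <- call$rt_start - upstream; e <- call$dvvi_end + downstream
  } else {
    s <- call$dvvi_start - downstream; e <- call$rt_end + upstream
  }
  if (genome$topology == "linear") { s <- max(0L, s); e <- min(genome$length, e) }
  seq <- extract_span(genome, s, e)
  if (call$strand == "-") seq <- revcomp(seq)
  # RT hit in region coordinates (region is in intron orientation)
  rt_span <- if (call$strand == "+") {
    c(call$rt_start - s, call$rt_end - s)
  } else {
    c(e - call$rt_end, e - call$rt_start)
  }
  structure(seq, g_start = s, g_end = e, strand = call$strand,
            rt_span = as.integer(rt_span))
}

#' Locate the IEP peptide in a region by translated homology
#'
#' Aligns reference IEP peptides against the three forward reading frames of
#' the (already intron-oriented) region and returns the best-scoring local
#' alignment: the subject peptide (stops rendered `*`), its frame offset and
#' nt span in region coordinates, and the winning query. Deterministic; ties
#' broken by query order.
#'
#' @param region sequence from [extract_iep_region()].
#' @param references named character vector of reference IEP peptides.
#' @param min_bits score floor below which no location is reported.
#' @return list with `aa_seq`, `frame_offset`, `query_id`, `bits`, `span_nt`
#'   (region coordinates, 0-based half-open), or `NULL` if nothing scores
#'   above `min_bits`.
#' @export
locate_iep <- function(region, references, min_bits = 25) {
  region <- as.character(region)
  best <- NULL
  for (f in 0:2) {
    aa <- translate_frame(region, f)
    for (qi in seq_along(references)) {
      al <- best_local_aa(as.character(references[[qi]]), aa)
      if (is.null(al)) next
      bits <- ka_bits(al$raw, KA_PROTEIN)
      if (bits < min_bits) next
      if (is.null(best) || al$raw > best$raw) {
        best <- list(raw = al$raw, bits = bits, frame_offset = f,
                     query_id = names(references)[qi] %||% paste0("q", qi),
                     aa_seq = substr(aa, al$s1, al$s2),
                     span_aa = c(al$s1, al$s2),
                     span_nt = c(f + 3L * (al$s1 - 1L), f + 3L * al$s2))
      }
    }
  }
  best
}

#' Internal stop codons within a located subject peptide
#'
#' Reports stop codons (TAA/TAG/TGA, genetic code 11) strictly inside the
#' subject span; a stop at the final codon of the span is not internal.
#'
#' @param region region sequence (intron orientation).
#' @param span_nt subject nt span in region coordinates (0-based half-open,
#'   multiple of 3 from the frame).
#' @param frame_offset reading frame (0–2) of the subject.
#' @return integer vector of internal stop positions (1-based aa index
#'   within the subject span), possibly empty.
#' @export
detect_interrupted <- function(region, span_nt, frame_offset) {
  region <- as.character(region)
  sub <- substr(region, span_nt[1] + 1L, span_nt[2])
  stopifnot((span_nt[1] - frame_offset) %% 3L == 0L)
  aa <- translate_frame(sub, 0L)
  pos <- which(strsplit(aa, "")[[1]] == "*")
  pos[pos < nchar(aa)]
}

#' Find the IEP open reading frame around the RT hit
#'
#' Scans the three forward frames of the intron-oriented region for
#' stop-to-stop segments, takes the ORF from the first ATG/GTG/TTG start in
#' each segment to the closing stop, keeps those whose nt span overlaps the
#' RT hit interval, and returns the longest (the encoded peptide excludes
#' the stop).
#'
#' @param region region sequence (intron orientation).
#' @param rt_span RT hit in region coordinates, `c(start, end)` 0-based
#'   half-open (default taken from the region's `rt_span` attribute).
#' @return list with `start`, `end` (nt span incl. stop codon, 0-based
#'   half-open), `aa_seq`, `frame_offset`; or `NULL` when no ORF overlaps
#'   the RT hit.
#' @export
find_orf <- function(region, rt_span = attr(region, "rt_span")) {
  seq <- as.character(region)
  stopifnot(nchar(seq) >= 60L, !is.null(rt_span))
  best <- NULL
  for (f in 0:2) {
    aa <- translate_frame(seq, f)
    if (!nzchar(aa)) next
    ch <- strsplit(aa, "")[[1]]
    stops <- which(ch == "*")
    bounds <- c(0L, stops, length(ch) + 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      seg_s <- bounds[k] + 1L; seg_e <- bounds[k + 1L] - 1L
      if (seg_e - seg_s + 1L < 10L) next
      # first start codon in the segment
      starts_nt <- f + 3L * (seg_s:seg_e - 1L)
      codons <- substring(seq, starts_nt + 1L, starts_nt + 3L)
      si <- which(codons %in% START_CODONS)
      if (length(si) == 0L) next
      a_start <- seg_s + si[1L] - 1L
      nt_s <- f + 3L * (a_start - 1L)
      has_stop <- bounds[k + 1L] <= length(ch)
      nt_e <- f + 3L * (seg_e + if (has_stop) 1L else 0L)
      if (max(nt_s, rt_span[1]) >= min(nt_e, rt_span[2])) next
      pep <- paste(ch[a_start:seg_e], collapse = "")
      if (is.null(best) || nchar(pep) > nchar(best$aa_seq))
        best <- list(start = nt_s, end = nt_e, aa_seq = pep, frame_offset = f)
    }
  }
  best
}

#' Conserved-motif completeness of an IEP peptide
#'
#' Each of the 15 type-specific motifs (10–50 aa) is matched against the
#' peptide by the best ungapped local score under BLOSUM62; a motif is
#' present iff that score reaches `threshold` times the motif's self-score.
#'
#' @param aa_seq peptide.
#' @param motifs character vector of 15 motifs (a `MotifSet` entry).
#' @param threshold fraction of the motif self-score counted as present
#'   (default 0.6).
#' @return list with `presence` (logical, length 15) and `n_missing`.
#' @export
motif_completeness <- function(aa_seq, motifs, threshold = 0.6) {
  stopifnot(nchar(aa_seq) > 0, length(motifs) == 15L,
            all(nchar(motifs) >= 10L & nchar(motifs) <= 50L))
  B <- blosum62()
  pep <- strsplit(aa_seq, "")[[1]]
  pep[!pep %in% rownames(B)] <- "X"
  presence <- vapply(motifs, function(m) {
    mm <- strsplit(m, "")[[1]]
    self <- sum(B[cbind(mm, mm)])
    L <- length(mm); P <- length(pep)
    if (P < L) return(FALSE)
    scores <- vapply(0:(P - L), function(off) {
      sum(B[cbind(mm, pep[(off + 1):(off + L)])])
    }, 0)
    max(scores) >= threshold * self
  }, logical(1), USE.NAMES = FALSE)
  list(presence = presence, n_missing = sum(!presence))
}

#' Classify an IEP
#'
#' `interrupted` when the located subject contains internal stop codons
#' (takes precedence); otherwise `short_orf` when 5 or more of the 15
#' conserved motifs are missing; otherwise `canonical`.
#'
#' @param n_internal_stops count of internal stops in the subject.
#' @param n_missing count of missing motifs.
#' @param short_orf_min_missing missing-motif threshold (default 5).
#' @return one of `"interrupted"`, `"short_orf"`, `"canonical"`.
#' @export
classify_iep <- function(n_internal_stops, n_missing,
                         short_orf_min_missing = 5L) {
  if (n_internal_stops > 0) "interrupted"
  else if (n_missing >= short_orf_min_missing) "short_orf"
  else "canonical"
}

#' Remove stop symbols from a peptide
#'
#' Interrupted subjects carry `*` at internal stops; these are excluded
#' before clustering and tree building so the residue sequence is
#' contiguous.
#'
#' @param aa_seq peptide possibly containing `*`.
#' @return peptide without `*`.
#' @export
strip_stops <- function(aa_seq) gsub("\\*", "", aa_seq)

# A stop symbol inside a located subject marks a genuine interruption only
# when the subject shows independent homology to the winning reference on
# BOTH sides of the stop (the two-HSP signature of an interrupted gene).
# Stops without such support are boundary artifacts of local-alignment
# extension into flanking sequence and are discarded.
validate_stops <- function(loc, references, min_flank_raw = 60) {
  aa <- loc$aa_seq
  pos <- which(strsplit(aa, "")[[1]] == "*")
  pos <- pos[pos < nchar(aa)]
  ref <- as.character(references[[loc$query_id]])
  ok <- vapply(pos, function(p) {
    left <- substr(aa, 1L, p - 1L)
    right <- substr(aa, p + 1L, nchar(aa))
    if (nchar(left) < 10L || nchar(right) < 10L) return(FALSE)
    al <- best_local_aa(ref, left)
    ar <- best_local_aa(ref, right)
    !is.null(al) && !is.null(ar) &&
      al$raw >= min_flank_raw && ar$raw >= min_flank_raw
  }, logical(1))
  loc$supported_stops <- pos[ok]
  loc
}

#' Analyse the IEP of every IEP-containing call
#'
#' Runs the full IEP workflow per call: region extraction, translated
#' location of the subject peptide against `references`, internal-stop
#' detection, ORF recovery for uninterrupted subjects, motif completeness
#' against the call's IEP-type motif set, and status classification. The
#' call table's `iep_status` column is filled from the result.
#'
#' @param calls call table from [call_introns()].
#' @param genome the `GenomeRecord`.
#' @param references named character vector of reference IEP peptides.
#' @param motif_sets named list (by IEP type) of 15-motif character vectors.
#' @param motif_threshold per-motif match threshold (see
#'   [motif_completeness()]).
#' @return list with `ieps` (one row per analysed call: status, stop count,
#'   missing-motif count, peptide) and `calls` (input with `iep_status`
#'   filled).
#' @export
analyze_ieps <- function(calls, genome, references, motif_sets,
                         motif_threshold = 0.6) {
  rows <- list()
  for (k in seq_len(nrow(calls))) {
    call <- calls[k, ]
    if (call$category != "iep_containing") next
    region <- extract_iep_region(call, genome)
    loc <- locate_iep(region, references)
    if (!is.null(loc)) loc <- validate_stops(loc, references)
    if (is.null(loc)) {
      # no reference alignment: fall back to the ORF over the RT hit
      orf <- find_orf(region)
      if (is.null(orf)) {
        rows[[length(rows) + 1L]] <- data.frame(
          call_id = call$call_id, status = NA_character_,
          n_internal_stops = NA_integer_, n_missing_motifs = NA_integer_,
          aa_seq = NA_character_, stringsAsFactors = FALSE)
        next
      }
      stops <- integer(0)
      aa <- orf$aa_seq
    } else {
      stops <- loc$supported_stops
      aa <- loc$aa_seq
    }
    if (length(stops) > 0) {
      status <- "interrupted"; n_missing <- NA_integer_
    } else {
      orf <- find_orf(region)
      if (!is.null(orf)) aa <- orf$aa_seq
      ms <- motif_sets[[call$iep_type]] %||% motif_sets[[1L]]
      mc <- motif_completeness(aa, ms, motif_threshold)
      n_missing <- mc$n_missing
      status <- classify_iep(0L, n_missing)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      call_id = call$call_id, status = status,
      n_internal_stops = length(stops), n_missing_motifs = n_missing,
      aa_seq = aa, stringsAsFactors = FALSE)
  }
  ieps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(call_id = character(), status = character(),
               n_internal_stops = integer(), n_missing_motifs = integer(),
               aa_seq = character(), stringsAsFactors = FALSE)
  m <- match(calls$call_id, ieps$call_id)
  calls$iep_status <- ifelse(is.na(m), calls$iep_status, ieps$status[m])
  list(ieps = ieps, calls = calls)
}
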