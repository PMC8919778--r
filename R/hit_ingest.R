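#' IEP type vocabulary
#'
#' Closed vocabulary of intron-encoded-protein lineage classes: bacterial
#' A–E, G (g1), F (g2–g5), g6, mitochondrial-like (ML), chloroplast-like
#' (CL1A/CL1B/CL2A/CL2B), the U1–U3 clusters, and `unclassified`.
#'
#' @export
IEP_TYPES <- c("A", "B", "C", "D", "E", "G_g1", "F_g2_g5", "g6", "ML",
               "CL1A", "CL1B", "CL2A", "CL2B", "U1", "U2", "U3",
               "unclassified")

DOMAIN_KINDS <- c("RT", "DV_VI", "D1", "D2", "D3", "D4")

#' Default evidence filter thresholds
#'
#' Thresholds applied to external-search evidence before intron assembly:
#' RT (translated homology) hits need e-value <= `rt_evalue_max` and query
#' coverage strictly greater than `rt_qcov_min`; domain V/VI
#' covariance-model hits need bit score strictly greater than
#' `dvvi_bits_min`; domain I–IV hits need either (nucleotide-alignment
#' evidence) e-value <= `d1_4_blast_evalue_max` and coverage >
#' `d1_4_blast_qcov_min`, or (covariance-model evidence) e-value <=
#' `d1_4_cm_evalue_max`.
#'
#' @param rt_evalue_max,rt_qcov_min,dvvi_bits_min,d1_4_blast_evalue_max,d1_4_blast_qcov_min,d1_4_cm_evalue_max
#'   threshold overrides.
#' @return a list of class `FilterConfig`.
#' @export
filter_config <- function(rt_evalue_max = 1e-10, rt_qcov_min = 0.40,
                          dvvi_bits_min = 24, d1_4_blast_evalue_max = 1e-10,
                          d1_4_blast_qcov_min = 0.60, d1_4_cm_evalue_max = 1e-2) {
  stopifnot(rt_evalue_max > 0, rt_qcov_min > 0, dvvi_bits_min > 0,
            d1_4_blast_evalue_max > 0, d1_4_blast_qcov_min > 0,
            d1_4_cm_evalue_max > 0)
  structure(list(rt_evalue_max = rt_evalue_max, rt_qcov_min = rt_qcov_min,
                 dvvi_bits_min = dvvi_bits_min,
                 d1_4_blast_evalue_max = d1_4_blast_evalue_max,
                 d1_4_blast_qcov_min = d1_4_blast_qcov_min,
                 d1_4_cm_evalue_max = d1_4_cm_evalue_max),
            class = "FilterConfig")
}

# Canonical empty/constructed hit table. Coordinates 0-based half-open on the
# forward strand; `source` is "alignment" or "cm".
new_hits <- function(replicon_id = character(), kind = character(),
                     start = integer(), end = integer(), strand = character(),
                     bit_score = numeric(), evalue = numeric(),
                     query_id = character(), query_coverage = numeric(),
                     source = character(), iep_type = character()) {
  if (length(iep_type) == 0L && length(replicon_id) > 0L)
    iep_type <- rep(NA_character_, length(replicon_id))
  df <- data.frame(replicon_id = replicon_id, kind = kind,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, bit_score = bit_score, evalue = evalue,
                   query_id = query_id, query_coverage = query_coverage,
                   source = source, iep_type = iep_type,
                   stringsAsFactors = FALSE)
  stopifnot(all(df$start < df$end),
            all(df$query_coverage >= 0 & df$query_coverage <= 1, na.rm = TRUE),
            all(df$kind %in% DOMAIN_KINDS))
  df
}

rbind_hits <- function(...) {
  l <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(l) == 0) return(new_hits())
  do.call(rbind, l)
}

#' Parse an external hit table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`protein_tabular`}{the 12-column tabular format of translated /
#'     nucleotide homology searches (`qseqid sseqid pident length mismatch
#'     gapopen qstart qend sstart send evalue bitscore`); subject coordinates
#'     are 1-based inclusive, `sstart > send` denotes the minus strand.}
#'   \item{`cm_tblout`}{covariance-model search tabular output (tblout):
#'     whitespace-separated with target, query, model span, `seq from`,
#'     `seq to`, strand, score and E-value columns.}
#' }
#' Coordinates are normalised to 0-based half-open on the forward strand with
#' the strand recorded. Query coverage for `protein_tabular` is computed as
#' aligned query span / query length, so `query_lengths` (a named vector,
#' query id -> length) is required for that dialect. Malformed rows are
#' skipped with a warning naming the row number.
#'
#' @param path hit table file.
#' @param dialect `"protein_tabular"` or `"cm_tblout"`.
#' @param kind the domain kind these hits represent (`RT`, `DV_VI`, `D1`..`D4`).
#' @param query_lengths named integer vector of query lengths (sidecar;
#'   required for `protein_tabular`).
#' @param source evidence source recorded on the hits; defaults to
#'   `"alignment"` for `protein_tabular` and `"cm"` for `cm_tblout`.
#' @return a hit data.frame.
#' @export
parse_hit_table <- function(path, dialect = c("protein_tabular", "cm_tblout"),
                            kind, query_lengths = NULL, source = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(kind %in% DOMAIN_KINDS)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(new_hits())
  source <- source %||% if (dialect == "protein_tabular") "alignment" else "cm"
  rows <- strsplit(trimws(lines), "\\s+")
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    rec <- tryCatch({
      if (dialect == "protein_tabular") {
        if (length(f) < 12L) stop("too few columns")
        qid <- f[1L]; sid <- f[2L]
        qstart <- as.integer(f[7L]); qend <- as.integer(f[8L])
        sstart <- as.integer(f[9L]); send <- as.integer(f[10L])
        ev <- as.numeric(f[11L]); bits <- as.numeric(f[12L])
        if (anyNA(c(qstart, qend, sstart, send, ev, bits))) stop("non-numeric")
        strand <- if (sstart <= send) "+" else "-"
        s0 <- min(sstart, send) - 1L; e0 <- max(sstart, send)
        if (is.null(query_lengths) || is.na(query_lengths[qid]))
          stop("unknown query length for ", qid)
        cov <- (abs(qend - qstart) + 1L) / as.numeric(query_lengths[qid])
        new_hits(sid, kind, s0, e0, strand, bits, ev, qid, min(cov, 1), source)
      } else {
        if (length(f) < 16L) stop("too few columns")
        sid <- f[1L]; qid <- f[3L]
        sfrom <- as.integer(f[8L]); sto <- as.integer(f[9L])
        strand <- f[10L]
        bits <- as.numeric(f[15L]); ev <- as.numeric(f[16L])
        if (anyNA(c(sfrom, sto, bits, ev)) || !strand %in% c("+", "-"))
          stop("non-numeric")
        s0 <- min(sfrom, sto) - 1L; e0 <- max(sfrom, sto)
        new_hits(sid, kind, s0, e0, strand, bits, ev, qid, NA_real_, source)
      }
    }, error = function(e) {
      warning(sprintf("row %d skipped (%s)", i, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    out[[i]] <- rec
  }
  do.call(rbind_hits, out)
}

# Cluster same-replicon, same-strand hits that overlap by >= 1 nt.
# Returns an integer cluster id per row.
overlap_clusters <- function(hits) {
  cl <- integer(nrow(hits))
  nid <- 0L
  for (key in unique(paste(hits$replicon_id, hits$strand))) {
    idx <- which(paste(hits$replicon_id, hits$strand) == key)
    ord <- idx[order(hits$start[idx])]
    cur_end <- -1L
    for (i in ord) {
      if (hits$start[i] < cur_end) {
        cl[i] <- nid
      } else {
        nid <- nid + 1L
        cl[i] <- nid
      }
      cur_end <- max(cur_end, hits$end[i])
    }
  }
  cl
}

#' Filter and type RT-domain hits
#'
#' Keeps RT hits with e-value <= `rt_evalue_max` and query coverage strictly
#' greater than `rt_qcov_min`, then collapses overlapping surviving hits
#' (same replicon, same strand, intervals overlapping by at least 1 nt) to a
#' single hit — the one with the highest bit score — whose query determines
#' the locus IEP type.
#'
#' @param hits hit data.frame of kind `RT`.
#' @param cfg a [filter_config()].
#' @param query_types optional named character vector mapping query ids to
#'   IEP types; when supplied, the collapsed hit's `iep_type` is set from the
#'   best-scoring query.
#' @return filtered hit data.frame.
#' @export
filter_and_type_rt_hits <- function(hits, cfg = filter_config(),
                                    query_types = NULL) {
  if (nrow(hits) == 0) return(hits)
  stopifnot(all(hits$kind == "RT"))
  keep <- hits$evalue <= cfg$rt_evalue_max &
    !is.na(hits$query_coverage) & hits$query_coverage > cfg$rt_qcov_min
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  cl <- overlap_clusters(hits)
  best <- vapply(split(seq_len(nrow(hits)), cl), function(ii) {
    ii[which.max(hits$bit_score[ii])]
  }, 0L)
  hits <- hits[sort(best), , drop = FALSE]
  if (!is.null(query_types)) {
    typed <- query_types[hits$query_id]
    hits$iep_type <- ifelse(is.na(typed), hits$iep_type, unname(typed))
    if (anyNA(hits$iep_type))
      stop("RT query id(s) missing from query_types: ",
           paste(unique(hits$query_id[is.na(hits$iep_type)]), collapse = ", "))
  }
  rownames(hits) <- NULL
  hits
}

#' Filter structural RNA-domain hits
#'
#' Domain V/VI hits are kept iff bit score > `dvvi_bits_min` (strict).
#' Domain I–IV hits are kept iff the alignment-evidence rule (e-value <=
#' `d1_4_blast_evalue_max` and coverage > `d1_4_blast_qcov_min`) or the
#' covariance-model rule (e-value <= `d1_4_cm_evalue_max`) applies, according
#' to each hit's `source`.
#'
#' @param hits hit data.frame of kinds `DV_VI`, `D1`..`D4`.
#' @param cfg a [filter_config()].
#' @return filtered hit data.frame.
#' @export
filter_structural_hits <- function(hits, cfg = filter_config()) {
  if (nrow(hits) == 0) return(hits)
  stopifnot(all(hits$kind %in% c("DV_VI", "D1", "D2", "D3", "D4")))
  is_dvvi <- hits$kind == "DV_VI"
  keep <- logical(nrow(hits))
  keep[is_dvvi] <- hits$bit_score[is_dvvi] > cfg$dvvi_bits_min
  d <- !is_dvvi
  aln <- d & hits$source == "alignment"
  cm <- d & hits$source == "cm"
  keep[aln] <- hits$evalue[aln] <= cfg$d1_4_blast_evalue_max &
    !is.na(hits$query_coverage[aln]) &
    hits$query_coverage[aln] > cfg$d1_4_blast_qcov_min
  keep[cm] <- hits$evalue[cm] <= cfg$d1_4_cm_evalue_max
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
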