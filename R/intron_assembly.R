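#' Intron assembly configuration
#'
#' @param max_gap maximum nucleotide gap between the RT-domain hit and the
#'   domain V/VI hit (and between domain I–IV hits and domain V/VI) for them
#'   to be joined into one intron call. Default 1,300 nt.
#' @param allow_overlap may member hits overlap (gap clamped to 0)?
#' @param require_upstream_order require the RT / domain I–IV hit to lie
#'   upstream of domain V/VI in intron orientation (the RT ORF sits in RNA
#'   domain IV, 5' of domain V).
#' @param collapse_duplicated_dvvi drop ORF-less calls whose span overlaps an
#'   IEP-containing call on the same strand (tandem domain V/VI duplications
#'   flanking one IEP otherwise yield two calls).
#' @return a list of class `AssemblyConfig`.
#' @export
assembly_config <- function(max_gap = 1300L, allow_overlap = TRUE,
                            require_upstream_order = TRUE,
                            collapse_duplicated_dvvi = FALSE) {
  stopifnot(max_gap > 0)
  structure(list(max_gap = as.integer(max_gap), allow_overlap = allow_overlap,
                 require_upstream_order = require_upstream_order,
                 collapse_duplicated_dvvi = collapse_duplicated_dvvi),
            class = "AssemblyConfig")
}

#' Gap between two intervals along the strand orientation
#'
#' Distance in nucleotides from the end of the upstream interval `a` to the
#' start of the downstream interval `b`, measured along the strand (on the
#' minus strand "downstream" means decreasing genome coordinates).
#' Overlapping intervals have gap 0. On circular replicons the gap wraps the
#' origin; when upstream order is not enforced the smaller of the two arc
#' gaps is returned. `NA` when `require_upstream_order` is violated on a
#' linear replicon.
#'
#' @param a,b intervals `c(start, end)`, 0-based half-open.
#' @param strand `"+"` or `"-"` (orientation along which `a` precedes `b`).
#' @param topology `"linear"` or `"circular"`.
#' @param length replicon length (required for circular).
#' @param require_upstream_order see [assembly_config()].
#' @return gap in nt, or `NA_integer_`.
#' @export
gap_nt <- function(a, b, strand = "+", topology = "linear", length = NULL,
                   require_upstream_order = TRUE) {
  if (max(a[1], b[1]) < min(a[2], b[2])) return(0L)  # overlap clamps to 0
  gfwd <- if (strand == "+") b[1] - a[2] else a[1] - b[2]
  grev <- if (strand == "+") a[1] - b[2] else b[1] - a[2]
  if (topology == "circular") {
    stopifnot(!is.null(length))
    gfwd <- ((gfwd %% length) + length) %% length
    grev <- ((grev %% length) + length) %% length
    return(as.integer(if (require_upstream_order) gfwd else min(gfwd, grev)))
  }
  if (require_upstream_order) {
    if (gfwd >= 0) as.integer(gfwd) else NA_integer_
  } else {
    as.integer(max(gfwd, grev))
  }
}

empty_calls <- function() {
  df <- data.frame(call_id = character(), replicon_id = character(),
                   strand = character(), category = character(),
                   start = integer(), end = integer(),
                   rt_start = integer(), rt_end = integer(),
                   rt_bits = numeric(), rt_query = character(),
                   dvvi_start = integer(), dvvi_end = integer(),
                   dvvi_bits = numeric(), n_d1_4 = integer(),
                   iep_type = character(), five_prime = integer(),
                   iep_status = character(), stringsAsFactors = FALSE)
  df$d1_4 <- list()
  df
}

make_call <- function(replicon_id, strand, category, dvvi, rt = NULL,
                      d1_4 = NULL) {
  starts <- c(dvvi$start, rt$start, if (!is.null(d1_4)) d1_4$start)
  ends <- c(dvvi$end, rt$end, if (!is.null(d1_4)) d1_4$end)
  df <- data.frame(
    call_id = NA_character_, replicon_id = replicon_id, strand = strand,
    category = category, start = min(starts), end = max(ends),
    rt_start = if (is.null(rt)) NA_integer_ else rt$start,
    rt_end = if (is.null(rt)) NA_integer_ else rt$end,
    rt_bits = if (is.null(rt)) NA_real_ else rt$bit_score,
    rt_query = if (is.null(rt)) NA_character_ else rt$query_id,
    dvvi_start = dvvi$start, dvvi_end = dvvi$end, dvvi_bits = dvvi$bit_score,
    n_d1_4 = if (is.null(d1_4)) 0L else nrow(d1_4),
    iep_type = if (is.null(rt)) NA_character_ else rt$iep_type,
    five_prime = NA_integer_, iep_status = NA_character_,
    stringsAsFactors = FALSE)
  df$d1_4 <- list(d1_4)
  df
}

# replicon topology/length lookup used by the pairing routines
topo_of <- function(genome) {
  if (is.null(genome)) list(topology = "linear", length = NULL)
  else list(topology = genome$topology, length = genome$length)
}

#' Pair RT-domain hits with domain V/VI hits
#'
#' Each domain V/VI hit is paired with at most one RT hit on the same
#' replicon and strand, with the RT upstream in intron orientation and gap
#' <= `cfg$max_gap`. Pairing is greedy by smallest gap; ties go to the RT
#' hit with the highest bit score. The call inherits the RT hit's IEP type.
#'
#' @param rt_hits,dvvi_hits filtered hit data.frames.
#' @param cfg an [assembly_config()].
#' @param genome optional `GenomeRecord` (for circular wrap-around).
#' @return data.frame of `iep_containing` calls.
#' @export
pair_rt_with_dvvi <- function(rt_hits, dvvi_hits, cfg = assembly_config(),
                              genome = NULL) {
  if (nrow(rt_hits) == 0 || nrow(dvvi_hits) == 0) return(empty_calls())
  tp <- topo_of(genome)
  cand <- list()
  for (i in seq_len(nrow(rt_hits))) for (j in seq_len(nrow(dvvi_hits))) {
    if (rt_hits$replicon_id[i] != dvvi_hits$replicon_id[j]) next
    if (rt_hits$strand[i] != dvvi_hits$strand[j]) next
    g <- gap_nt(c(rt_hits$start[i], rt_hits$end[i]),
                c(dvvi_hits$start[j], dvvi_hits$end[j]),
                strand = rt_hits$strand[i], topology = tp$topology,
                length = tp$length,
                require_upstream_order = cfg$require_upstream_order)
    if (is.na(g) || g > cfg$max_gap) next
    if (!cfg$allow_overlap && g == 0L) next
    cand[[length(cand) + 1L]] <- c(i = i, j = j, gap = g,
                                   bits = rt_hits$bit_score[i])
  }
  if (length(cand) == 0) return(empty_calls())
  cand <- do.call(rbind, cand)
  ord <- order(cand[, "gap"], -cand[, "bits"],
               rt_hits$start[cand[, "i"]], dvvi_hits$start[cand[, "j"]])
  cand <- cand[ord, , drop = FALSE]
  used_rt <- logical(nrow(rt_hits)); used_dv <- logical(nrow(dvvi_hits))
  out <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, "i"]; j <- cand[k, "j"]
    if (used_rt[i] || used_dv[j]) next
    used_rt[i] <- TRUE; used_dv[j] <- TRUE
    out[[length(out) + 1L]] <- make_call(
      rt_hits$replicon_id[i], rt_hits$strand[i], "iep_containing",
      dvvi_hits[j, ], rt_hits[i, ])
  }
  do.call(rbind, out)
}

#' Build ORF-less calls from unconsumed domain V/VI hits
#'
#' A domain V/VI hit not paired with an RT hit becomes an ORF-less intron
#' call when at least one domain I–IV hit lies on the same replicon and
#' strand, upstream in intron orientation, within `cfg$max_gap`; all
#' qualifying domain I–IV hits are attached.
#'
#' @param unpaired_dvvi domain V/VI hits not consumed by [pair_rt_with_dvvi()].
#' @param d1_4_hits filtered domain I–IV hits.
#' @param cfg an [assembly_config()].
#' @param genome optional `GenomeRecord`.
#' @return data.frame of `orf_less` calls.
#' @export
attach_orfless <- function(unpaired_dvvi, d1_4_hits, cfg = assembly_config(),
                           genome = NULL) {
  if (nrow(unpaired_dvvi) == 0 || is.null(d1_4_hits) || nrow(d1_4_hits) == 0)
    return(empty_calls())
  tp <- topo_of(genome)
  out <- list()
  for (j in seq_len(nrow(unpaired_dvvi))) {
    dv <- unpaired_dvvi[j, ]
    sel <- logical(nrow(d1_4_hits))
    for (i in seq_len(nrow(d1_4_hits))) {
      if (d1_4_hits$replicon_id[i] != dv$replicon_id) next
      if (d1_4_hits$strand[i] != dv$strand) next
      g <- gap_nt(c(d1_4_hits$start[i], d1_4_hits$end[i]),
                  c(dv$start, dv$end), strand = dv$strand,
                  topology = tp$topology, length = tp$length,
                  require_upstream_order = cfg$require_upstream_order)
      if (!is.na(g) && g <= cfg$max_gap) sel[i] <- TRUE
    }
    if (any(sel))
      out[[length(out) + 1L]] <- make_call(dv$replicon_id, dv$strand,
                                           "orf_less", dv,
                                           d1_4 = d1_4_hits[sel, ])
  }
  if (length(out) == 0) empty_calls() else do.call(rbind, out)
}

# Merge overlapping domain V/VI hits (same replicon/strand, >=1 nt overlap),
# keeping the highest-scoring hit of each overlap cluster.
merge_dvvi <- function(dvvi_hits) {
  if (nrow(dvvi_hits) <= 1) return(dvvi_hits)
  cl <- overlap_clusters(dvvi_hits)
  best <- vapply(split(seq_len(nrow(dvvi_hits)), cl), function(ii) {
    ii[which.max(dvvi_hits$bit_score[ii])]
  }, 0L)
  out <- dvvi_hits[sort(best), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call group II introns on one genome
#'
#' Orchestrates assembly from already-filtered hits: overlapping domain V/VI
#' hits are merged (highest bit score wins), RT hits are paired with domain
#' V/VI under the gap rule, and leftover domain V/VI hits with nearby domain
#' I–IV evidence become ORF-less calls. Calls are sorted by span start and
#' given stable ids; each domain V/VI hit appears in at most one call.
#'
#' @param genome a `GenomeRecord`.
#' @param hits filtered hit data.frame (all kinds mixed).
#' @param cfg an [assembly_config()].
#' @return data.frame of intron calls.
#' @export
call_introns <- function(genome, hits, cfg = assembly_config()) {
  if (is.null(hits) || nrow(hits) == 0) return(empty_calls())
  hits <- hits[hits$replicon_id == genome$replicon_id, , drop = FALSE]
  rt <- hits[hits$kind == "RT", , drop = FALSE]
  dvvi <- merge_dvvi(hits[hits$kind == "DV_VI", , drop = FALSE])
  d14 <- hits[hits$kind %in% c("D1", "D2", "D3", "D4"), , drop = FALSE]
  iep <- pair_rt_with_dvvi(rt, dvvi, cfg, genome)
  if (is.null(iep)) iep <- empty_calls()
  consumed <- paste(iep$dvvi_start, iep$dvvi_end, iep$strand)
  unpaired <- dvvi[!paste(dvvi$start, dvvi$end, dvvi$strand) %in% consumed, ,
                   drop = FALSE]
  orfless <- attach_orfless(unpaired, d14, cfg, genome)
  calls <- rbind(iep, orfless)
  if (nrow(calls) == 0) return(empty_calls())
  if (cfg$collapse_duplicated_dvvi && any(calls$category == "orf_less")) {
    keep <- rep(TRUE, nrow(calls))
    for (k in which(calls$category == "orf_less")) {
      ov <- calls$category == "iep_containing" &
        calls$strand == calls$strand[k] &
        pmax(calls$start, calls$start[k]) < pmin(calls$end, calls$end[k])
      if (any(ov)) keep[k] <- FALSE
    }
    calls <- calls[keep, , drop = FALSE]
  }
  calls <- calls[order(calls$start, calls$end), , drop = FALSE]
  calls$call_id <- sprintf("%s_g2i_%03d", genome$replicon_id,
                           seq_len(nrow(calls)))
  rownames(calls) <- NULL
  calls
}
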