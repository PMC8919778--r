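#' Run the full intron-detection pipeline
#'
#' Orchestrates, per replicon: evidence filtering (RT typing + structural
#' thresholds), intron assembly under the gap rule, IEP extraction and
#' classification, 5'-end localisation, terminator-distance measurement,
#' leading/lagging classification with insertion-bias scoring, and GC
#' skew / GCSI. Stages requiring optional inputs (references, profiles,
#' terminators, *ori*) are skipped when those inputs are absent. A stage log
#' records hit counts in/out of every filter.
#'
#' @param genomes named list of `GenomeRecord`.
#' @param hits hit data.frame (all kinds, unfiltered), or `NULL`.
#' @param cfg an [assembly_config()].
#' @param fcfg a [filter_config()].
#' @param query_types named map query id -> IEP type for RT typing.
#' @param references named reference IEP peptides (IEP classification).
#' @param motif_sets named list of 15-motif sets by IEP type.
#' @param profiles named list of `FivePrimeProfile` by profile lineage.
#' @param terminators terminator table (see [load_terminators()]).
#' @param ori named vector of 0-based origin coordinates by replicon.
#' @param out_dir optional directory; when given, calls (GFF3 + TSV), IEP,
#'   context and skew tables are written there.
#' @return list with `calls`, `ieps`, `context`, `skew`, `ib`, `summary`,
#'   `log`.
#' @export
run_pipeline <- function(genomes, hits = NULL, cfg = assembly_config(),
                         fcfg = filter_config(), query_types = NULL,
                         references = NULL, motif_sets = NULL,
                         profiles = NULL, terminators = NULL, ori = NULL,
                         out_dir = NULL) {
  log <- list()
  all_calls <- list(); all_ieps <- list(); all_ctx <- list()
  skew_rows <- list(); ib_res <- list()
  if (!is.null(hits) && nrow(hits) > 0) {
    rt_raw <- hits[hits$kind == "RT", , drop = FALSE]
    st_raw <- hits[hits$kind != "RT", , drop = FALSE]
    rt <- filter_and_type_rt_hits(rt_raw, fcfg, query_types)
    st <- filter_structural_hits(st_raw, fcfg)
    log$rt_hits_in <- nrow(rt_raw); log$rt_hits_kept <- nrow(rt)
    log$structural_hits_in <- nrow(st_raw)
    log$structural_hits_kept <- nrow(st)
    fhits <- rbind(rt, st)
  } else fhits <- new_hits()
  for (rid in names(genomes)) {
    gnm <- genomes[[rid]]
    calls <- call_introns(gnm, fhits, cfg)
    if (!is.null(references) && !is.null(motif_sets) && nrow(calls) > 0) {
      res <- analyze_ieps(calls, gnm, references, motif_sets)
      calls <- res$calls
      all_ieps[[rid]] <- res$ieps
    }
    # 5' ends and terminator context
    if (nrow(calls) > 0) {
      fp <- rep(NA_integer_, nrow(calls))
      if (!is.null(profiles)) {
        for (i in seq_len(nrow(calls))) {
          if (calls$category[i] != "iep_containing") next
          pk <- profile_key(calls$iep_type[i])
          if (is.na(pk) || is.null(profiles[[pk]])) next
          fp[i] <- locate_5prime(calls[i, ], gnm, profiles[[pk]])
        }
      }
      calls$five_prime <- fp
      if (!is.null(terminators)) {
        trm <- terminators[terminators$replicon_id == rid, , drop = FALSE]
        ctx <- lapply(seq_len(nrow(calls)), function(i) {
          if (is.na(calls$five_prime[i])) return(NULL)
          td <- terminator_distance(calls$five_prime[i], calls$strand[i], trm)
          if (is.null(td)) return(NULL)
          shape <- td$term$shape
          if (identical(shape, "unknown"))
            shape <- classify_terminator_shape(td$term, gnm)
          data.frame(call_id = calls$call_id[i], iep_type = calls$iep_type[i],
                     distance = td$distance, term_shape = shape,
                     stringsAsFactors = FALSE)
        })
        ctx <- Filter(Negate(is.null), ctx)
        if (length(ctx)) all_ctx[[rid]] <- do.call(rbind, ctx)
      }
    }
    # replication geometry
    if (!is.null(ori) && !is.na(ori[rid] %||% NA) && nrow(calls) > 0) {
      model <- replication_model(rid, ori[[rid]], gnm$length)
      cls <- vapply(seq_len(nrow(calls)), function(i) {
        strand_class((calls$start[i] + calls$end[i]) %/% 2L,
                     calls$strand[i], model)
      }, "")
      ib_res[[rid]] <- ib_score(cls)
    }
    sp <- gc_skew_profile(gnm)
    gi <- if (gnm$length >= 4096) gcsi(gnm)$gcsi else NA_real_
    skew_rows[[rid]] <- data.frame(replicon_id = rid, length = gnm$length,
                                   mean_skew = mean(sp$skew), gcsi = gi,
                                   stringsAsFactors = FALSE)
    all_calls[[rid]] <- calls
  }
  calls <- do.call(rbind, all_calls) %||% empty_calls()
  rownames(calls) <- NULL
  ieps <- if (length(all_ieps)) do.call(rbind, all_ieps) else NULL
  context <- if (length(all_ctx)) do.call(rbind, all_ctx) else NULL
  skew <- do.call(rbind, skew_rows)
  rownames(skew) <- NULL
  summary <- summarize_calls(calls, genomes, ieps = ieps,
                             gcsi_values = stats::setNames(skew$gcsi,
                                                           skew$replicon_id))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_calls(calls, file.path(out_dir, "calls.gff3"), "gff3", genomes)
    export_calls(calls, file.path(out_dir, "calls.tsv"), "tsv", genomes)
    if (!is.null(ieps))
      write.table(ieps, file.path(out_dir, "ieps.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(context))
      write.table(context, file.path(out_dir, "context.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    write.table(skew, file.path(out_dir, "skew.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(calls = calls, ieps = ieps, context = context, skew = skew,
       ib = ib_res, summary = summary, log = log)
}

#' Per-replicon intron summary
#'
#' One row per replicon: total calls, count per IEP type, ORF-less count,
#' canonical / non-canonical counts, and GCSI when supplied. Per-type counts
#' plus the ORF-less count always sum to the total. The overall mean, SD and
#' median call count across replicons are attached as attribute
#' `"across_genomes"`.
#'
#' @param calls call table.
#' @param genomes named list of `GenomeRecord` (zero-call replicons are
#'   retained as all-zero rows).
#' @param ieps optional IEP table (for canonical / non-canonical counts).
#' @param gcsi_values optional named vector of GCSI by replicon.
#' @return data.frame summary.
#' @export
summarize_calls <- function(calls, genomes, ieps = NULL, gcsi_values = NULL) {
  rows <- lapply(names(genomes), function(rid) {
    cc <- calls[calls$replicon_id == rid, , drop = FALSE]
    type_counts <- table(factor(cc$iep_type[cc$category == "iep_containing"],
                                levels = IEP_TYPES))
    row <- data.frame(replicon_id = rid, length = genomes[[rid]]$length,
                      n_calls = nrow(cc),
                      n_orf_less = sum(cc$category == "orf_less"),
                      stringsAsFactors = FALSE)
    for (tp in IEP_TYPES) row[[paste0("n_", tp)]] <- as.integer(type_counts[tp])
    if (!is.null(ieps)) {
      st <- ieps$status[ieps$call_id %in% cc$call_id]
      row$n_canonical <- sum(st == "canonical", na.rm = TRUE)
      row$n_non_canonical <- sum(st %in% c("interrupted", "short_orf"))
    }
    row$gcsi <- if (!is.null(gcsi_values)) unname(gcsi_values[rid]) else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "across_genomes") <- c(mean = mean(out$n_calls),
                                   sd = stats::sd(out$n_calls),
                                   median = stats::median(out$n_calls))
  out
}

#' Regression of intron count on genome size
#'
#' Ordinary least-squares R-squared of the per-replicon call count against
#' replicon length.
#'
#' @param summary a [summarize_calls()] table (needs >= 3 rows).
#' @return R-squared (numeric scalar).
#' @export
regress_counts_vs_size <- function(summary) {
  stopifnot(nrow(summary) >= 3)
  if (stats::var(summary$length) == 0)
    stop("zero variance in genome size; regression undefined")
  if (stats::var(summary$n_calls) == 0) return(0)
  fit <- stats::lm(n_calls ~ length, data = summary)
  unname(stats::summary.lm(fit)$r.squared)
}
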