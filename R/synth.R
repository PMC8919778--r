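# Synthetic genome generator: backgrounds with tunable GC content and
# replichore GC-skew amplitude, plus an engine that plants intron elements,
# decoys and terminators and records ground truth.

#' Generate a synthetic replicon
#'
#' I.i.d. background with GC content `gc` and a per-replichore G/C imbalance
#' of `± skew_amplitude` switching at *ori* and *ter* (the two-replichore
#' signature of replication-driven skew). Deterministic per seed.
#'
#' @param length replicon length in nt.
#' @param gc GC fraction in (0, 1).
#' @param skew_amplitude replichore skew `(G − C)/(G + C)` magnitude, in
#'   `[-1, 1]`.
#' @param ori 0-based origin coordinate.
#' @param seed integer seed.
#' @param replicon_id,topology record metadata.
#' @return a `GenomeRecord`.
#' @export
generate_genome <- function(length, gc = 0.5, skew_amplitude = 0, ori = 0L,
                            seed = 1L, replicon_id = "synth1",
                            topology = "circular") {
  stopifnot(gc > 0, gc < 1, abs(skew_amplitude) <= 1, length >= 2)
  ter <- infer_ter(ori, length)
  with_seed(seed, {
    p_rep <- function(s) c(A = (1 - gc) / 2, C = gc / 2 * (1 - s),
                           G = gc / 2 * (1 + s), T = (1 - gc) / 2)
    n1 <- ((ter - ori) %% length)
    b1 <- sample(names(p_rep(0)), n1, replace = TRUE,
                 prob = p_rep(skew_amplitude))
    b2 <- sample(names(p_rep(0)), length - n1, replace = TRUE,
                 prob = p_rep(-skew_amplitude))
    seq <- character(length)
    idx1 <- (seq_len(n1) - 1L + ori) %% length + 1L
    seq[idx1] <- b1
    seq[-idx1] <- b2
    genome_record(replicon_id, paste(seq, collapse = ""), topology)
  })
}

#' Specification of one planted element
#'
#' @param kind `"iep_intron"`, `"orfless_intron"`, `"decoy_rt"`,
#'   `"decoy_dvvi_weak"`, `"decoy_d1_opposite"`, or `"terminator"`.
#' @param position 0-based genome coordinate where the element starts
#'   (intron 5' end for plus-strand introns).
#' @param strand `"+"` or `"-"`.
#' @param iep_type IEP type of the planted intron (must have parts).
#' @param interruptions number of internal stop codons written into the IEP.
#' @param deleted_motifs number of conserved motifs deleted (0–10; RT motifs
#'   are never deleted).
#' @param gap_rt_to_dvvi nt gap between the RT-domain (or domain I) hit and
#'   the domain V/VI hit.
#' @param terminator_offset distance (nt) from a planted terminator's 3' end
#'   to the intron 5' end, or `NA` for no terminator.
#' @param terminator_shape `"L"` or `"I"` tail for the planted terminator.
#' @return a one-row data.frame (`PlantSpec`).
#' @export
plant_spec <- function(kind, position, strand = "+", iep_type = "A",
                       interruptions = 0L, deleted_motifs = 0L,
                       gap_rt_to_dvvi = 300L, terminator_offset = NA_integer_,
                       terminator_shape = "L") {
  stopifnot(gap_rt_to_dvvi >= 0, deleted_motifs >= 0, deleted_motifs <= 15)
  data.frame(kind = kind, position = as.integer(position), strand = strand,
             iep_type = iep_type, interruptions = as.integer(interruptions),
             deleted_motifs = as.integer(deleted_motifs),
             gap_rt_to_dvvi = as.integer(gap_rt_to_dvvi),
             terminator_offset = as.integer(terminator_offset),
             terminator_shape = terminator_shape, stringsAsFactors = FALSE)
}

# overwrite genome sequence at 0-based offset (no length change)
splice_seq <- function(seq, pos, insert) {
  stopifnot(pos >= 0, pos + nchar(insert) <= nchar(seq))
  paste0(substr(seq, 1L, pos), insert,
         substr(seq, pos + nchar(insert) + 1L, nchar(seq)))
}

# Build the forward-orientation element for one spec.  Returns the element
# string plus relative (0-based half-open) component spans.
build_element <- function(spec, parts) {
  tp <- spec$iep_type
  pk <- profile_key(tp)
  c5 <- if (!is.na(pk) && spec$kind == "iep_intron")
    parts$five_prime_alignments[[pk]][1L] else ""
  spacer <- 150L
  comp <- list()
  if (spec$kind %in% c("iep_intron", "decoy_rt")) {
    if (spec$gap_rt_to_dvvi < 3L)
      stop("gap_rt_to_dvvi must be >= 3 (the ORF stop codon lies between ",
           "the RT hit and domain V)")
    bp <- build_iep_peptide(parts, tp, spec$deleted_motifs)
    orf_nt <- paste0(reverse_translate(bp$pep), "TAA")
    if (spec$interruptions > 0) {
      # internal stops written inside the RT domain, evenly spaced
      codon_idx <- round(seq(bp$rt_a1 + 3, bp$rt_a2 - 3,
                             length.out = spec$interruptions))
      for (ci in codon_idx) {
        orf_nt <- paste0(substr(orf_nt, 1L, 3L * (ci - 1L)), "TAA",
                         substr(orf_nt, 3L * ci + 1L, nchar(orf_nt)))
      }
    }
    orf_off <- nchar(c5) + spacer
    rt_rel <- c(orf_off + 3L * (bp$rt_a1 - 1L), orf_off + 3L * bp$rt_a2)
    el_len <- orf_off + nchar(orf_nt)
    comp$orf <- c(orf_off, el_len)
    comp$rt <- rt_rel
    if (spec$kind == "iep_intron" || spec$kind == "decoy_rt") {
      dvvi_rel <- c(rt_rel[2] + spec$gap_rt_to_dvvi,
                    rt_rel[2] + spec$gap_rt_to_dvvi + nchar(parts$dvvi_motif))
      comp$dvvi <- dvvi_rel
      el_len <- max(el_len, dvvi_rel[2])
    }
    list(orf_nt = orf_nt, c5 = c5, length = el_len, comp = comp)
  } else if (spec$kind == "orfless_intron") {
    d1_rel <- c(0L, nchar(parts$d1_motif))
    dvvi_rel <- c(d1_rel[2] + spec$gap_rt_to_dvvi,
                  d1_rel[2] + spec$gap_rt_to_dvvi + nchar(parts$dvvi_motif))
    list(orf_nt = NULL, c5 = "", length = dvvi_rel[2],
         comp = list(d1 = d1_rel, dvvi = dvvi_rel))
  } else if (spec$kind %in% c("decoy_dvvi_weak", "decoy_d1_opposite")) {
    dvvi_rel <- c(0L, nchar(parts$dvvi_motif))
    comp <- list(dvvi = dvvi_rel)
    len <- dvvi_rel[2]
    if (spec$kind == "decoy_d1_opposite") {
      d1_rel <- c(dvvi_rel[2] + 500L, dvvi_rel[2] + 500L + nchar(parts$d1_motif))
      comp$d1 <- d1_rel
      len <- d1_rel[2]
    }
    list(orf_nt = NULL, c5 = "", length = len, comp = comp)
  } else stop("unknown plant kind: ", spec$kind)
}

# map a relative span to genome coordinates given element placement
rel_to_genome <- function(rel, pos, el_len, strand) {
  if (strand == "+") c(pos + rel[1], pos + rel[2])
  else c(pos + el_len - rel[2], pos + el_len - rel[1])
}

#' Plant elements into a synthetic genome
#'
#' Writes intron elements, decoys and terminators into the genome sequence
#' (in place, preserving length), and emits: the edited `GenomeRecord`;
#' ready-made evidence hit tables (internal format, convertible to external
#' dialects with [write_hit_tables()]); planted terminator records; and a
#' truth table whose expected call outcomes are evaluated against the
#' supplied [assembly_config()] (so regenerating under a different
#' `max_gap` flips expectations for gaps between the two values).
#' Overlapping plant footprints are an error.
#'
#' @param genome a `GenomeRecord` from [generate_genome()].
#' @param specs data.frame of [plant_spec()] rows.
#' @param parts a [g2i_parts_library()].
#' @param cfg the [assembly_config()] against which truth is evaluated.
#' @return list with `genome`, `truth`, `hits`, `terminators`.
#' @export
plant <- function(genome, specs, parts, cfg = assembly_config()) {
  seq <- genome$sequence
  hits <- list(); truth <- list(); terms <- list()
  footprints <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(nrow(specs))) {
    spec <- specs[k, ]
    if (spec$kind == "decoy_rt" && spec$gap_rt_to_dvvi <= cfg$max_gap)
      stop("decoy_rt requires gap_rt_to_dvvi > max_gap (", cfg$max_gap, ")")
    el <- build_element(spec, parts)
    pos <- spec$position
    fp <- c(pos, pos + el$length)
    # terminator footprint (upstream of the intron 5' end)
    tfp <- NULL
    if (!is.na(spec$terminator_offset)) {
      stem_arm <- 10L; loop <- 5L; tail_len <- 7L
      tlen <- 2L * stem_arm + loop + tail_len
      stopifnot(spec$terminator_offset >= 1)
      # placed so that 5'end - term_3prime == terminator_offset exactly
      if (spec$strand == "+") tfp <- c(pos - spec$terminator_offset - tlen + 1L,
                                       pos - spec$terminator_offset + 1L)
      else tfp <- c(pos + el$length - 1L + spec$terminator_offset,
                    pos + el$length - 1L + spec$terminator_offset + tlen)
    }
    for (f in list(fp, tfp)) {
      if (is.null(f)) next
      if (f[1] < 0 || f[2] > genome$length)
        stop("plant ", k, " outside the replicon")
      if (nrow(footprints) &&
          any(pmax(footprints[, 1], f[1]) < pmin(footprints[, 2], f[2])))
        stop("overlapping plants at spec row ", k)
      footprints <- rbind(footprints, f)
    }
    # assemble the element sequence in forward element orientation over the
    # existing background (components overwrite, background fills gaps)
    elseq <- substr(seq, pos + 1L, pos + el$length)
    put <- function(s, rel, frag) splice_seq_rel(s, rel[1], frag)
    if (nzchar(el$c5)) elseq <- put(elseq, c(0L, nchar(el$c5)), el$c5)
    if (!is.null(el$orf_nt)) elseq <- put(elseq, el$comp$orf, el$orf_nt)
    if (!is.null(el$comp$dvvi)) elseq <- put(elseq, el$comp$dvvi, parts$dvvi_motif)
    if (!is.null(el$comp$d1)) elseq <- put(elseq, el$comp$d1, parts$d1_motif)
    if (spec$strand == "-") elseq <- revcomp(elseq)
    seq <- splice_seq(seq, pos, elseq)

    rid <- genome$replicon_id
    g <- function(rel) rel_to_genome(rel, pos, el$length, spec$strand)
    five_prime <- if (spec$strand == "+") pos else pos + el$length - 1L

    # evidence rows
    if (!is.null(el$comp$rt)) {
      rts <- g(el$comp$rt)
      hits[[length(hits) + 1L]] <- new_hits(
        rid, "RT", rts[1], rts[2], spec$strand, 150, 1e-60,
        sprintf("RT_%s_1", spec$iep_type), 1.0, "alignment")
    }
    if (!is.null(el$comp$dvvi)) {
      dvs <- g(el$comp$dvvi)
      dv_bits <- if (spec$kind == "decoy_dvvi_weak") 23.9 else 45
      hits[[length(hits) + 1L]] <- new_hits(
        rid, "DV_VI", dvs[1], dvs[2], spec$strand, dv_bits, 1e-8,
        "DVVI_model", NA_real_, "cm")
    }
    if (!is.null(el$comp$d1)) {
      d1_strand <- if (spec$kind == "decoy_d1_opposite") {
        if (spec$strand == "+") "-" else "+"
      } else spec$strand
      d1s <- g(el$comp$d1)
      hits[[length(hits) + 1L]] <- new_hits(
        rid, "D1", d1s[1], d1s[2], d1_strand, 80, 1e-4,
        "D1_model", NA_real_, "cm")
    }
    # terminator sequence + record
    term_3p <- NA_integer_
    if (!is.null(tfp)) {
      stem_arm <- 10L; loop <- 5L; tail_len <- 7L
      arm <- substr(parts$d1_motif, 1L, stem_arm)  # fixed arbitrary arm
      tail <- if (spec$terminator_shape == "L") strrep("T", tail_len)
              else "GAGCAGC"
      tseq <- paste0(arm, strrep("A", loop), revcomp(arm), tail)
      if (spec$strand == "-") tseq <- revcomp(tseq)
      seq <- splice_seq(seq, tfp[1], tseq)
      if (spec$strand == "+") {
        stem_start <- tfp[1]; stem_end <- tfp[1] + 2L * stem_arm + loop
        term_3p <- tfp[2] - 1L
      } else {
        stem_start <- tfp[1] + tail_len
        stem_end <- tfp[2]
        term_3p <- tfp[1]
      }
      terms[[length(terms) + 1L]] <- data.frame(
        replicon_id = rid, strand = spec$strand, stem_start = stem_start,
        stem_end = stem_end, term_3prime = term_3p,
        shape = spec$terminator_shape, stringsAsFactors = FALSE)
    }

    # truth: expected outcome under cfg
    expected_call <- switch(spec$kind,
      iep_intron = spec$gap_rt_to_dvvi <= cfg$max_gap,
      orfless_intron = spec$gap_rt_to_dvvi <= cfg$max_gap,
      FALSE)
    expected_category <- if (!expected_call) NA_character_
      else if (spec$kind == "iep_intron") "iep_containing" else "orf_less"
    expected_status <- if (!expected_call || spec$kind != "iep_intron")
      NA_character_
      else if (spec$interruptions > 0) "interrupted"
      else if (spec$deleted_motifs >= 5) "short_orf"
      else "canonical"
    span <- if (spec$kind == "iep_intron") {
      r <- range(c(g(el$comp$rt), g(el$comp$dvvi))); r
    } else if (spec$kind == "orfless_intron") {
      r <- range(c(g(el$comp$d1), g(el$comp$dvvi))); r
    } else c(NA_integer_, NA_integer_)
    truth[[length(truth) + 1L]] <- data.frame(
      element_id = sprintf("plant_%03d", k), kind = spec$kind,
      replicon_id = rid, strand = spec$strand, iep_type = spec$iep_type,
      expected_call = expected_call, expected_category = expected_category,
      expected_status = expected_status,
      span_start = span[1], span_end = span[2],
      five_prime = five_prime, term_3prime = term_3p,
      gap = spec$gap_rt_to_dvvi, stringsAsFactors = FALSE)
  }
  genome$sequence <- seq
  list(genome = genome,
       truth = do.call(rbind, truth) %||%
         data.frame(element_id = character(0)),
       hits = do.call(rbind_hits, hits),
       terminators = if (length(terms)) do.call(rbind, terms) else NULL)
}

# overwrite inside an element-local string
splice_seq_rel <- function(s, pos, frag) {
  stopifnot(pos + nchar(frag) <= nchar(s))
  paste0(substr(s, 1L, pos), frag, substr(s, pos + nchar(frag) + 1L, nchar(s)))
}

#' Write planted evidence as external-dialect hit tables
#'
#' Emits the planted hits in the two dialects [parse_hit_table()] reads:
#' RT and other alignment-source hits as 12-column `protein_tabular` rows
#' (plus a sidecar query-length table), covariance-model-source hits as
#' `cm_tblout`. Coordinates are converted to each dialect's 1-based
#' conventions (reversed subject coordinates on the minus strand for the
#' tabular dialect).
#'
#' @param hits internal hit data.frame (from [plant()]).
#' @param dir output directory.
#' @param query_lengths named vector of query lengths; defaults are derived
#'   from coverage-1 spans for alignment hits.
#' @return named list of file paths (`rt_tab`, `cm_tblout`, `query_lengths`).
#' @export
write_hit_tables <- function(hits, dir, query_lengths = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aln <- hits[hits$source == "alignment", , drop = FALSE]
  cm <- hits[hits$source == "cm", , drop = FALSE]
  if (is.null(query_lengths) && nrow(aln)) {
    # coverage-1 planted hits: aa length for translated kinds, nt otherwise
    ql <- ifelse(aln$kind == "RT", (aln$end - aln$start) %/% 3L,
                 aln$end - aln$start)
    query_lengths <- tapply(ql, aln$query_id, max)
  }
  rt_path <- file.path(dir, "rt_hits.tsv")
  lines <- character(0)
  for (i in seq_len(nrow(aln))) {
    h <- aln[i, ]
    qlen <- as.integer(query_lengths[h$query_id])
    qspan <- max(1L, round(h$query_coverage * qlen))
    sco <- if (h$strand == "+") c(h$start + 1L, h$end) else c(h$end, h$start + 1L)
    lines <- c(lines, sprintf(
      "%s\t%s\t100.00\t%d\t0\t0\t1\t%d\t%d\t%d\t%.2e\t%.1f",
      h$query_id, h$replicon_id, qspan, qspan, sco[1], sco[2],
      h$evalue, h$bit_score))
  }
  writeLines(lines, rt_path)
  ql_path <- file.path(dir, "query_lengths.tsv")
  if (length(query_lengths))
    write.table(data.frame(query_id = names(query_lengths),
                           length = as.integer(query_lengths)),
                ql_path, sep = "\t", quote = FALSE, row.names = FALSE)
  # covariance-model hits: one tblout per kind group so each file parses
  # with a single DomainHit kind
  tblout_lines <- function(h) {
    vapply(seq_len(nrow(h)), function(i) {
      sco <- if (h$strand[i] == "+") c(h$start[i] + 1L, h$end[i])
             else c(h$end[i], h$start[i] + 1L)
      sprintf("%s - %s - cm 1 90 %d %d %s no 1 0.50 0.0 %.1f %.2e ! -",
              h$replicon_id[i], h$query_id[i], sco[1], sco[2], h$strand[i],
              h$bit_score[i], h$evalue[i])
    }, "")
  }
  dvvi_path <- file.path(dir, "cm_dvvi.tblout")
  writeLines(c("#target name accession query ...",
               tblout_lines(cm[cm$kind == "DV_VI", , drop = FALSE])),
             dvvi_path)
  d14 <- cm[cm$kind %in% c("D1", "D2", "D3", "D4"), , drop = FALSE]
  d14_path <- file.path(dir, "cm_d1_4.tblout")
  writeLines(c("#target name accession query ...", tblout_lines(d14)),
             d14_path)
  list(rt_tab = rt_path, cm_dvvi = dvvi_path, cm_d1_4 = d14_path,
       query_lengths = ql_path)
}
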