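# Planted-truth evaluation scenarios.  Each function builds a synthetic
# study under fixed conditions, runs the relevant pipeline stages, and
# returns the measured quantities.  Tests and the reproduction script both
# call these, so the reported numbers are always recomputed from scratch.

#' End-to-end planted-recovery evaluation
#'
#' Generates `n_genomes` replicons of `genome_length` nt, each carrying 5
#' IEP-containing introns of assorted types, 2 ORF-less introns, and 3
#' decoys (an RT with its nearest domain V/VI 2,000 nt away, a domain V/VI
#' hit at 23.9 bits, and a domain I hit on the opposite strand of an
#' unpaired domain V/VI), then runs the full pipeline and scores recall and
#' false calls against the truth tables.
#'
#' @param n_genomes number of replicons (default 10).
#' @param genome_length replicon length (default 1e6).
#' @param seed integer seed.
#' @param parts a [g2i_parts_library()].
#' @return list: `recall` (fraction of expected calls recovered with exact
#'   span and category), `n_false` (calls matching no truth row),
#'   `n_expected`, `status_accuracy` (fraction of IEP statuses matching the
#'   planted label).
#' @export
bench_planted_recovery <- function(n_genomes = 10L, genome_length = 1e6,
                                   seed = 1L, parts = g2i_parts_library()) {
  types <- c("A", "B", "C", "D", "E", "F_g2_g5", "ML", "CL1A", "CL2A", "g6")
  n_hit <- 0L; n_exp <- 0L; n_false <- 0L
  st_ok <- 0L; st_tot <- 0L
  for (gi in seq_len(n_genomes)) {
    g <- generate_genome(genome_length, seed = seed * 1000L + gi,
                         replicon_id = sprintf("sim%02d", gi))
    base <- as.integer(seq(round(genome_length * 0.05),
                           by = round(genome_length * 0.09),
                           length.out = 10L))
    gaps <- c(3L, 150L, 500L, 1000L, 1300L)
    specs <- rbind(
      do.call(rbind, lapply(1:5, function(k) {
        plant_spec("iep_intron", base[k],
                   strand = if (k %% 2) "+" else "-",
                   iep_type = types[(gi + k) %% 10L + 1L],
                   gap_rt_to_dvvi = gaps[k],
                   interruptions = if (k == 2) 1L else 0L,
                   deleted_motifs = if (k == 4) 5L else 0L)
      })),
      plant_spec("orfless_intron", base[6], "+", gap_rt_to_dvvi = 700L),
      plant_spec("orfless_intron", base[7], "-", gap_rt_to_dvvi = 1300L),
      plant_spec("decoy_rt", base[8], "+", iep_type = types[gi %% 10L + 1L],
                 gap_rt_to_dvvi = 2000L),
      plant_spec("decoy_dvvi_weak", base[9], "+"),
      plant_spec("decoy_d1_opposite", base[10], "-"))
    pl <- plant(g, specs, parts)
    res <- run_pipeline(stats::setNames(list(pl$genome),
                                        pl$genome$replicon_id),
                        pl$hits, query_types = parts$query_types,
                        references = parts$references,
                        motif_sets = parts$motif_sets)
    truth <- pl$truth[pl$truth$expected_call, ]
    n_exp <- n_exp + nrow(truth)
    key <- function(s, e, cat) paste(s, e, cat)
    tk <- key(truth$span_start, truth$span_end, truth$expected_category)
    ck <- key(res$calls$start, res$calls$end, res$calls$category)
    n_hit <- n_hit + sum(tk %in% ck)
    n_false <- n_false + sum(!ck %in% tk)
    # status recovery for the recovered IEP-containing introns
    tr_iep <- truth[truth$kind == "iep_intron", ]
    m <- match(key(tr_iep$span_start, tr_iep$span_end, "iep_containing"), ck)
    ok <- !is.na(m)
    st_tot <- st_tot + sum(ok)
    st_ok <- st_ok + sum(res$calls$iep_status[m[ok]] ==
                           tr_iep$expected_status[ok], na.rm = TRUE)
  }
  list(recall = n_hit / n_exp, n_false = n_false, n_expected = n_exp,
       status_accuracy = st_ok / st_tot)
}

#' Threshold-boundary exactness check
#'
#' Evaluates the eight decision boundaries: assembly gap 1,300 vs 1,301 nt;
#' RT query coverage 0.40 vs 0.41; domain V/VI bit score 24.0 vs 24.1; and
#' 5'-profile score 9.9 vs 10.0 bits.
#'
#' @return list: `n_correct` (of 8), `detail` (named logical vector).
#' @export
bench_boundaries <- function() {
  dv <- new_hits("c", "DV_VI", 4500, 4590, "+", 40, 1e-8, "m", NA, "cm")
  rt_in <- new_hits("c", "RT", 2600, 3200, "+", 150, 1e-60, "q", 1, "alignment")
  rt_out <- new_hits("c", "RT", 2599, 3199, "+", 150, 1e-60, "q", 1, "alignment")
  cov <- function(x) new_hits("c", "RT", 100, 700, "+", 100, 1e-60, "q", x,
                              "alignment")
  bits <- function(b) new_hits("c", "DV_VI", 0, 90, "+", b, 1e-8, "m", NA, "cm")
  prof <- function(s) {
    m <- matrix(-5, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
    m["A", ] <- s / 10
    structure(list(iep_type = "A", pwm = m, min_bits = 10),
              class = "FivePrimeProfile")
  }
  g <- genome_record("r", paste0(strrep("C", 200), strrep("A", 10),
                                 strrep("C", 200)))
  call <- data.frame(strand = "+", rt_start = 300L, rt_end = 360L,
                     iep_type = "A")
  detail <- c(
    gap_1300_in = nrow(pair_rt_with_dvvi(rt_in, dv)) == 1L,
    gap_1301_out = nrow(pair_rt_with_dvvi(rt_out, dv)) == 0L,
    qcov_040_out = nrow(filter_and_type_rt_hits(cov(0.40))) == 0L,
    qcov_041_in = nrow(filter_and_type_rt_hits(cov(0.41))) == 1L,
    dvvi_240_out = nrow(filter_structural_hits(bits(24.0))) == 0L,
    dvvi_241_in = nrow(filter_structural_hits(bits(24.1))) == 1L,
    profile_99_out = is.na(locate_5prime(call, g, prof(9.9))),
    profile_100_in = identical(locate_5prime(call, g, prof(10.0)), 200L))
  list(n_correct = sum(detail), detail = detail)
}

#' IEP status recovery on planted proteins
#'
#' Plants `n_per_class` canonical, interrupted (internal stops) and
#' motif-deleted (short ORF) IEP introns, runs assembly plus IEP analysis,
#' and measures status accuracy.
#'
#' @param n_per_class introns per status class (default 20).
#' @param seed integer seed.
#' @param parts a [g2i_parts_library()].
#' @return list: `accuracy`, `n` (total IEPs), `confusion` (table).
#' @export
bench_iep_status <- function(n_per_class = 20L, seed = 1L,
                             parts = g2i_parts_library()) {
  types <- c("A", "B", "C", "D", "E", "F_g2_g5", "ML", "CL1A", "CL2A", "g6")
  n_total <- 3L * n_per_class
  per_genome <- 15L
  n_genomes <- ceiling(n_total / per_genome)
  labels <- rep(c("canonical", "interrupted", "short_orf"), n_per_class)
  got <- character(0); want <- character(0)
  idx <- 1L
  for (gi in seq_len(n_genomes)) {
    take <- labels[idx:min(idx + per_genome - 1L, n_total)]
    idx <- idx + length(take)
    g <- generate_genome(4000L * length(take) + 8000L,
                         seed = seed * 500L + gi,
                         replicon_id = sprintf("iep%02d", gi))
    specs <- do.call(rbind, lapply(seq_along(take), function(k) {
      plant_spec("iep_intron", 4000L * (k - 1L) + 2000L,
                 strand = if (k %% 2) "+" else "-",
                 iep_type = types[(k + gi) %% 10L + 1L],
                 interruptions = if (take[k] == "interrupted")
                   1L + k %% 2L else 0L,
                 deleted_motifs = if (take[k] == "short_orf")
                   5L + k %% 3L else 0L,
                 gap_rt_to_dvvi = 100L + 20L * k)
    }))
    pl <- plant(g, specs, parts)
    res <- run_pipeline(stats::setNames(list(pl$genome),
                                        pl$genome$replicon_id),
                        pl$hits, query_types = parts$query_types,
                        references = parts$references,
                        motif_sets = parts$motif_sets)
    truth <- pl$truth
    m <- match(truth$span_start, res$calls$start)
    got <- c(got, res$calls$iep_status[m])
    want <- c(want, truth$expected_status)
  }
  list(accuracy = mean(got == want, na.rm = FALSE), n = length(want),
       confusion = table(planted = want, called = got))
}

#' Greedy clustering versus an all-pairs oracle
#'
#' Generates `n_families` random peptide families (a base sequence plus
#' mutated members at several divergence levels), clusters each with
#' [greedy_cluster()], verifies the partition and identity invariants, and
#' compares against an order-independent all-pairs implementation of the
#' same greedy rule computed from the full identity matrix.
#'
#' @param n_families number of families (default 50).
#' @param seed integer seed.
#' @return list: `n_families`, `min_identity` (lowest member-representative
#'   identity observed), `partition_ok`, `oracle_agreement` (fraction of
#'   families with identical clusterings).
#' @export
bench_cluster_oracle <- function(n_families = 50L, seed = 1L) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  agree <- 0L; min_id <- 1; part_ok <- TRUE
  for (fs in seq_len(n_families)) {
    seqs <- with_seed(seed * 100L + fs, {
      len <- sample(120:200, 1)
      base <- paste(sample(aa, len, replace = TRUE), collapse = "")
      members <- vapply(1:5, function(i) {
        n_mut <- sample(c(3L, 10L, round(0.25 * len), round(0.5 * len)), 1)
        ch <- strsplit(base, "")[[1]]
        for (p in sample(len, n_mut)) ch[p] <- sample(setdiff(aa, ch[p]), 1)
        paste(ch, collapse = "")
      }, "")
      stats::setNames(c(base, members), paste0("m", 0:5))
    })
    cl <- greedy_cluster(seqs)
    members <- unlist(lapply(cl, `[[`, "members"))
    part_ok <- part_ok && setequal(members, names(seqs)) &&
      anyDuplicated(members) == 0L
    for (c1 in cl) for (m in c1$members)
      min_id <- min(min_id, seq_identity(seqs[[m]],
                                         seqs[[c1$representative]]))
    # oracle: same rule from a precomputed all-pairs identity matrix
    ids <- names(seqs)[order(-nchar(seqs), names(seqs))]
    idm <- outer(ids, ids, Vectorize(function(i, j)
      seq_identity(seqs[[i]], seqs[[j]])))
    dimnames(idm) <- list(ids, ids)
    reps <- character(0); oracle <- list()
    for (id in ids) {
      hit <- reps[which(idm[id, reps] >= 0.85)]
      if (length(hit)) oracle[[hit[1]]] <- c(oracle[[hit[1]]], id)
      else { reps <- c(reps, id); oracle[[id]] <- id }
    }
    got <- lapply(cl, `[[`, "members")
    names(got) <- vapply(cl, `[[`, "", "representative")
    if (identical(got[order(names(got))], oracle[order(names(oracle))]))
      agree <- agree + 1L
  }
  list(n_families = n_families, min_identity = min_id,
       partition_ok = part_ok, oracle_agreement = agree / n_families)
}

#' GC skew and GCSI property evaluation
#'
#' Checks the strand antisymmetry of the windowed skew, the `[0, 1]` range
#' of GCSI over random genomes, the monotone response of GCSI to planted
#' replichore amplitudes, and the near-zero GCSI of base-shuffled genomes.
#'
#' @param seed integer seed.
#' @param amplitudes planted skew amplitudes (defaults 0.02/0.05/0.1/0.2).
#' @param n_random random genomes for the range check (default 100).
#' @param n_shuffle shuffled genomes for the null check (default 20).
#' @return list: `skew_mirror_max_dev`, `range_ok`, `gcsi_values`,
#'   `spearman_rho`, `shuffled_below_005` (count), `n_shuffle`.
#' @export
bench_gcsi <- function(seed = 1L, amplitudes = c(0.02, 0.05, 0.1, 0.2),
                       n_random = 100L, n_shuffle = 20L) {
  g <- generate_genome(100000L, skew_amplitude = 0.1,
                       seed = seed * 7L, replicon_id = "m")
  g2 <- g; g2$sequence <- revcomp(g$sequence)
  dev <- max(abs(gc_skew_profile(g2)$skew + rev(gc_skew_profile(g)$skew)))
  range_ok <- TRUE
  for (i in seq_len(n_random)) {
    gr <- with_seed(seed * 11L + i, {
      generate_genome(20480L, gc = runif(1, 0.3, 0.7),
                      skew_amplitude = runif(1, 0, 0.3),
                      seed = seed * 11L + i, replicon_id = "r")
    })
    v <- gcsi(gr)$gcsi
    range_ok <- range_ok && v >= 0 && v <= 1
  }
  vals <- vapply(seq_along(amplitudes), function(k) {
    gk <- generate_genome(409600L, skew_amplitude = amplitudes[k],
                          seed = seed * 13L, replicon_id = "a")
    gcsi(gk)$gcsi
  }, 0)
  rho <- stats::cor(seq_along(amplitudes), vals, method = "spearman")
  below <- 0L
  for (i in seq_len(n_shuffle)) {
    gs <- generate_genome(102400L, skew_amplitude = 0.2,
                          seed = seed * 17L + i, replicon_id = "s")
    shuf <- with_seed(seed * 19L + i,
                      paste(sample(strsplit(gs$sequence, "")[[1]]),
                            collapse = ""))
    if (gcsi(genome_record("s", shuf))$gcsi < 0.05) below <- below + 1L
  }
  list(skew_mirror_max_dev = dev, range_ok = range_ok, gcsi_values = vals,
       spearman_rho = rho, shuffled_below_005 = below,
       n_shuffle = n_shuffle)
}

#' Terminator-context separation by IEP type
#'
#' Plants bacterial-C-type introns at most `near_max` nt downstream of
#' rho-independent terminators and CL-type introns at least `far_min` nt
#' away, then measures 5'-end-to-terminator distances through the pipeline
#' and the overlap between the per-type distance histograms.
#'
#' @param seed integer seed.
#' @param near_max,far_min planted offset bounds (defaults 50 / 2,000 nt).
#' @param n_per_type introns per type (default 6).
#' @param parts a [g2i_parts_library()].
#' @return list: `c_distances`, `cl_distances`, `overlap` (count of
#'   distances falling in the other type's range), `separated`.
#' @export
bench_terminator_context <- function(seed = 1L, near_max = 50L,
                                     far_min = 2000L, n_per_type = 6L,
                                     parts = g2i_parts_library()) {
  offs_c <- as.integer(round(seq(5L, near_max, length.out = n_per_type)))
  offs_cl <- as.integer(round(seq(far_min, far_min + 2500L,
                                  length.out = n_per_type)))
  spacing <- 12000L
  g <- generate_genome(spacing * 2L * n_per_type + 20000L,
                       seed = seed * 23L, replicon_id = "ctx")
  specs <- do.call(rbind, lapply(seq_len(2L * n_per_type), function(k) {
    is_c <- k <= n_per_type
    plant_spec("iep_intron", spacing * k,
               strand = "+",
               iep_type = if (is_c) "C" else "CL1A",
               gap_rt_to_dvvi = 200L,
               terminator_offset = if (is_c) offs_c[k]
                                   else offs_cl[k - n_per_type])
  }))
  pl <- plant(g, specs, parts)
  res <- run_pipeline(stats::setNames(list(pl$genome), "ctx"), pl$hits,
                      query_types = parts$query_types,
                      references = parts$references,
                      motif_sets = parts$motif_sets,
                      profiles = parts$profiles,
                      terminators = pl$terminators)
  ctx <- res$context
  dc <- ctx$distance[ctx$iep_type == "C"]
  dcl <- ctx$distance[ctx$iep_type == "CL1A"]
  overlap <- sum(dc >= min(dcl)) + sum(dcl <= max(dc))
  list(c_distances = sort(dc), cl_distances = sort(dcl), overlap = overlap,
       separated = length(dc) == n_per_type && length(dcl) == n_per_type &&
         max(dc) < min(dcl))
}
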