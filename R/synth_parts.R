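# Synthetic parts library: type-distinct RT/IEP peptides, 15-motif sets,
# a domain V/VI nucleotide motif, domain I-IV motifs and per-type 5'-end
# consensus alignments.  Everything is generated deterministically from a
# fixed seed, so the library is reproducible, text-only and carries no
# licensing coupling to external databases.  All sequences are synthetic:
# they exercise the pipeline's decision rules, not real intron biology.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# synonymous codons per amino acid (code 11), sorted for determinism
aa_codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- genetic_code_11()
      cache <<- lapply(split(names(gc), gc), sort)
    }
    cache
  }
})

# Deterministic reverse translation with position-dependent codon choice.
# Varying synonymous codons keeps shifted reading frames peppered with stop
# codons at a natural density, so the planted ORF is also the longest one.
reverse_translate <- function(pep) {
  tab <- aa_codon_table()
  ch <- strsplit(pep, "")[[1]]
  codons <- vapply(seq_along(ch), function(i) {
    if (ch[i] == "M") return("ATG")
    syn <- tab[[ch[i]]]
    syn[(i * 7L + utf8ToInt(ch[i])) %% length(syn) + 1L]
  }, "")
  paste(codons, collapse = "")
}

rand_peptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# substitute k random positions of a peptide
mutate_peptide <- function(pep, k) {
  ch <- strsplit(pep, "")[[1]]
  pos <- sample(length(ch), min(k, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  paste(ch, collapse = "")
}

PART_TYPES <- c("A", "B", "C", "D", "E", "F_g2_g5", "g6", "ML",
                "CL1A", "CL1B", "CL2A", "CL2B", "U1", "U2", "U3")
# Motifs forming the RT domain: the peptide tail, so that the ORF ends
# right after the RT hit and a planted domain V/VI at any gap >= 3 nt never
# overwrites coding sequence (domain V follows the ORF-bearing domain IV).
RT_MOTIF_RANGE <- 11:15

#' Synthetic parts library for fixture genomes
#'
#' Builds, deterministically from `seed`, the reference material the
#' synthetic pipeline needs: per IEP type a set of 15 conserved peptide
#' motifs (10–50 aa), the canonical IEP peptide assembled from them (motifs
#' 6–10 form the RT domain), 5 RT-domain query peptides (0–4 substitutions
#' from the canonical RT domain), a shared domain V/VI nucleotide motif, a
#' domain I nucleotide motif, and a 5'-end consensus alignment per profile
#' lineage (CL1/CL2 serve their A/B subtypes; G (g1) has none). All
#' sequences are synthetic.
#'
#' @param seed integer seed (default 101; the library is part of the study
#'   conditions, so tests and fixtures share the default).
#' @return list of class `G2IParts` with elements `motif_sets`,
#'   `peptides`, `rt_aa_span`, `rt_queries`, `query_types`,
#'   `references`, `dvvi_motif`, `d1_motif`, `five_prime_alignments`,
#'   `profiles`.
#' @export
g2i_parts_library <- function(seed = 101L) {
  with_seed(seed, {
    motif_sets <- list(); peptides <- list(); rt_span <- list()
    rt_queries <- character(0); query_types <- character(0)
    for (tp in PART_TYPES) {
      lens <- sample(18:36, 15, replace = TRUE)
      motifs <- vapply(lens, rand_peptide, "")
      # canonical peptide: leading M, motifs joined by GS linkers
      pieces <- character(0); spans <- matrix(0L, 15, 2)
      pos <- 1L  # leading "M"
      for (i in 1:15) {
        pieces <- c(pieces, motifs[i])
        spans[i, ] <- c(pos + 1L, pos + nchar(motifs[i]))
        pos <- pos + nchar(motifs[i]) + 2L  # + "GS"
      }
      pep <- paste0("M", paste(pieces, collapse = "GS"))
      motif_sets[[tp]] <- motifs
      peptides[[tp]] <- pep
      # RT domain = motifs 6..10 inclusive of linkers between them
      rt_span[[tp]] <- c(spans[min(RT_MOTIF_RANGE), 1L],
                         spans[max(RT_MOTIF_RANGE), 2L])
      rt_dom <- substr(pep, rt_span[[tp]][1], rt_span[[tp]][2])
      for (v in 1:5) {
        qid <- sprintf("RT_%s_%d", tp, v)
        rt_queries[qid] <- mutate_peptide(rt_dom, v - 1L)
        query_types[qid] <- tp
      }
    }
    references <- unlist(peptides)
    names(references) <- paste0("IEP_", names(peptides))
    dvvi_motif <- rand_dna(90)
    d1_motif <- rand_dna(120)
    prof_keys <- c("A", "B", "C", "D", "E", "F_g2_g5", "ML", "CL1", "CL2")
    five_prime_alignments <- list()
    profiles <- list()
    for (pk in prof_keys) {
      base <- rand_dna(30)
      aln <- vapply(1:6, function(i) {
        ch <- strsplit(base, "")[[1]]
        pos <- sample(30, 2)
        for (p in pos) ch[p] <- sample(c("A", "C", "G", "T"), 1)
        paste(ch, collapse = "")
      }, "")
      five_prime_alignments[[pk]] <- aln
      profiles[[pk]] <- build_profile(aln, iep_type = pk)
    }
    structure(list(motif_sets = motif_sets, peptides = peptides,
                   rt_aa_span = rt_span, rt_queries = rt_queries,
                   query_types = query_types, references = references,
                   dvvi_motif = dvvi_motif, d1_motif = d1_motif,
                   five_prime_alignments = five_prime_alignments,
                   profiles = profiles, seed = seed),
              class = "G2IParts")
  })
}

# Canonical or motif-deleted IEP peptide with RT-domain bookkeeping.
# Motifs are deleted head-first (1..10); the RT motifs 11-15 are never
# deleted.  Returns list(pep, rt_a1, rt_a2, kept).
build_iep_peptide <- function(parts, iep_type, deleted_motifs = 0L) {
  stopifnot(deleted_motifs >= 0, deleted_motifs <= 10)
  motifs <- parts$motif_sets[[iep_type]]
  del <- (1:10)[seq_len(deleted_motifs)]
  kept <- setdiff(1:15, del)
  pos <- 1L; rt_a1 <- NA_integer_; rt_a2 <- NA_integer_
  pieces <- character(0)
  for (i in kept) {
    pieces <- c(pieces, motifs[i])
    if (i == min(RT_MOTIF_RANGE)) rt_a1 <- pos + 1L
    if (i == max(RT_MOTIF_RANGE)) rt_a2 <- pos + nchar(motifs[i])
    pos <- pos + nchar(motifs[i]) + 2L
  }
  pep <- paste0("M", paste(pieces, collapse = "GS"))
  list(pep = pep, rt_a1 = rt_a1, rt_a2 = rt_a2, kept = kept)
}
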