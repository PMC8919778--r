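# Shared fixtures, built once per test run.  The parts library and the
# standard planted genome are deterministic, so every test file sees the
# same study conditions.

PARTS <- g2i_parts_library()

# a small planted genome exercising every element kind
standard_plant <- function(seed = 5L, length = 2e5) {
  g <- generate_genome(length, seed = seed, replicon_id = "chr1")
  specs <- rbind(
    plant_spec("iep_intron", 10000, "+", "A", gap_rt_to_dvvi = 300,
               terminator_offset = 40),
    plant_spec("iep_intron", 30000, "-", "C", interruptions = 1),
    plant_spec("iep_intron", 50000, "+", "ML", deleted_motifs = 5),
    plant_spec("orfless_intron", 70000, "+", "B", gap_rt_to_dvvi = 1300),
    plant_spec("decoy_rt", 90000, "+", "D", gap_rt_to_dvvi = 2000),
    plant_spec("decoy_dvvi_weak", 110000, "+"),
    plant_spec("decoy_d1_opposite", 130000, "-"))
  c(plant(g, specs, parts = PARTS), list(specs = specs))
}

# deterministic random peptide for oracle tests
rand_pep <- function(n, seed) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  g2iscan:::with_seed(seed, paste(sample(aa, n, replace = TRUE),
                                  collapse = ""))
}

# substitute k positions of a peptide at given (or random) sites
mutate_at <- function(pep, pos, seed = 1) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  g2iscan:::with_seed(seed, {
    ch <- strsplit(pep, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(aa, ch[p]), 1)
    paste(ch, collapse = "")
  })
}

# quick internal-format hit row
mk_hit <- function(kind, start, end, strand = "+", bits = 100,
                   evalue = 1e-20, qcov = 1, query = "q1", rid = "chr1",
                   source = "alignment", iep_type = NA_character_) {
  h <- g2iscan:::new_hits(rid, kind, start, end, strand, bits, evalue,
                          query, qcov, source)
  h$iep_type <- iep_type
  h
}
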