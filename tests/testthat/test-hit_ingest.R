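test_that("protein_tabular rows parse with strand-aware coordinate conversion", {
  f <- tempfile()
  writeLines(c(
    "q1\tchr1\t98.0\t200\t4\t0\t1\t200\t1001\t1600\t1e-50\t180.3",
    "q1\tchr1\t98.0\t200\t4\t0\t1\t200\t1600\t1001\t1e-50\t180.3"), f)
  h <- parse_hit_table(f, "protein_tabular", "RT", query_lengths = c(q1 = 200))
  expect_equal(h$start, c(1000L, 1000L))
  expect_equal(h$end, c(1600L, 1600L))
  expect_equal(h$strand, c("+", "-"))
  expect_equal(h$query_coverage, c(1, 1))
  expect_equal(h$bit_score, c(180.3, 180.3))
  unlink(f)
})

test_that("cm tblout rows parse scores and strand", {
  f <- tempfile()
  writeLines(c("# comment",
    "chr1 - Intron_gpII - cm 1 90 501 590 + no 1 0.5 0.0 30.2 1.2e-08 ! -",
    "chr1 - Intron_gpII - cm 1 90 700 611 - no 1 0.5 0.0 25.0 2.0e-05 ! -"), f)
  h <- parse_hit_table(f, "cm_tblout", "DV_VI")
  expect_equal(h$bit_score, c(30.2, 25.0))
  expect_equal(h$start, c(500L, 610L))
  expect_equal(h$end, c(590L, 700L))
  expect_equal(h$strand, c("+", "-"))
  expect_equal(h$source, c("cm", "cm"))
  unlink(f)
})

test_that("malformed rows are skipped with a warning naming the row", {
  f <- tempfile()
  writeLines(c("q1\tchr1\t98\t200\t4\t0\t1\t200\t1001\t1600\t1e-50\t180",
               "q1\tchr1\tbroken"), f)
  expect_warning(h <- parse_hit_table(f, "protein_tabular", "RT",
                                      query_lengths = c(q1 = 200)),
                 "row 2")
  expect_equal(nrow(h), 1)
  unlink(f)
})

test_that("RT filter honours e-value and strict coverage thresholds", {
  hits <- rbind(mk_hit("RT", 100, 700, evalue = 1e-9),       # too weak
                mk_hit("RT", 1000, 1600, qcov = 0.40),       # boundary: out
                mk_hit("RT", 2000, 2600, qcov = 0.41),       # boundary: in
                mk_hit("RT", 3000, 3600, evalue = 1e-10))    # boundary: in
  kept <- filter_and_type_rt_hits(hits)
  expect_equal(kept$start, c(2000L, 3000L))
})

test_that("co-located RT hits collapse to the top-scoring query's type", {
  hits <- rbind(mk_hit("RT", 100, 700, bits = 150, query = "qC"),
                mk_hit("RT", 150, 750, bits = 120, query = "qE"))
  kept <- filter_and_type_rt_hits(hits, query_types = c(qC = "C", qE = "E"))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$iep_type, "C")
  expect_equal(kept$bit_score, 150)
})

test_that("RT typing fails loudly on unknown query ids", {
  hits <- mk_hit("RT", 100, 700, query = "mystery")
  expect_error(filter_and_type_rt_hits(hits, query_types = c(qC = "C")),
               "mystery")
})

test_that("structural filter applies per-evidence-source rules", {
  hits <- rbind(
    mk_hit("DV_VI", 0, 90, bits = 24.0, source = "cm"),    # strict >: out
    mk_hit("DV_VI", 100, 190, bits = 24.1, source = "cm"), # in
    mk_hit("D1", 200, 400, evalue = 1e-11, qcov = 0.61),   # alignment: in
    mk_hit("D1", 500, 700, evalue = 1e-11, qcov = 0.60),   # boundary: out
    mk_hit("D2", 800, 900, evalue = 5e-3, source = "cm"),  # cm rule: in
    mk_hit("D2", 950, 1050, evalue = 2e-2, source = "cm")) # out
  kept <- filter_structural_hits(hits)
  expect_equal(kept$start, c(100L, 200L, 800L))
})

test_that("filtering is idempotent", {
  pl <- standard_plant()
  rt <- pl$hits[pl$hits$kind == "RT", ]
  st <- pl$hits[pl$hits$kind != "RT", ]
  f1 <- filter_and_type_rt_hits(rt)
  expect_equal(filter_and_type_rt_hits(f1), f1)
  s1 <- filter_structural_hits(st)
  expect_equal(filter_structural_hits(s1), s1)
})

test_that("built-in translated search recovers a planted peptide exactly", {
  pep <- rand_pep(200, seed = 11)
  g <- generate_genome(20000, seed = 12, replicon_id = "g1",
                       topology = "linear")
  ins <- g2iscan:::reverse_translate(pep)
  g$sequence <- g2iscan:::splice_seq(g$sequence, 5000, ins)
  hits <- builtin_local_search(g, c(myq = pep), "translated", score_min = 50)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 5000L)
  expect_equal(hits$end, 5000L + nchar(ins))
  expect_equal(hits$strand, "+")
  expect_equal(hits$query_coverage, 1)

  # strand symmetry: the reverse-complemented genome yields the mirrored hit
  g2 <- g; g2$sequence <- revcomp(g$sequence)
  h2 <- builtin_local_search(g2, c(myq = pep), "translated", score_min = 50)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, g$length - hits$end)
  expect_equal(h2$end, g$length - hits$start)
})

test_that("built-in nucleotide search is strand symmetric", {
  g <- generate_genome(10000, seed = 3, replicon_id = "g1")
  motif <- PARTS$dvvi_motif
  g$sequence <- g2iscan:::splice_seq(g$sequence, 4000, revcomp(motif))
  h <- builtin_local_search(g, c(dv = motif), "nucleotide", score_min = 50,
                            kind = "DV_VI")
  h <- h[which.max(h$bit_score), ]
  expect_equal(h$strand, "-")
  expect_equal(c(h$start, h$end), c(4000L, 4000L + nchar(motif)))
})

test_that("stringent built-in search of random genomes is quiet", {
  pep <- rand_pep(120, seed = 77)
  n_hit <- vapply(1:10, function(s) {
    g <- generate_genome(50000, seed = 1000 + s, replicon_id = "r")
    nrow(builtin_local_search(g, c(q = pep), "translated", score_min = 60))
  }, 0L)
  expect_gte(sum(n_hit == 0), 9)
})
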