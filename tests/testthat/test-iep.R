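test_that("IEP region spans 1000 nt upstream of RT to 200 nt past domain VI", {
  g <- generate_genome(20000, seed = 2, replicon_id = "chr1",
                       topology = "linear")
  call <- data.frame(category = "iep_containing", strand = "+",
                     rt_start = 5000L, rt_end = 5600L,
                     dvvi_start = 6900L, dvvi_end = 7000L)
  r <- extract_iep_region(call, g)
  expect_equal(attr(r, "g_start"), 4000L)
  expect_equal(attr(r, "g_end"), 7200L)
  expect_equal(nchar(r), 3200L)
  expect_equal(as.character(r), substr(g$sequence, 4001, 7200))
  expect_equal(attr(r, "rt_span"), c(1000L, 1600L))

  # clamped at the start of a linear replicon
  call2 <- transform(call, rt_start = 400L, rt_end = 1000L,
                     dvvi_start = 2300L, dvvi_end = 2400L)
  r2 <- extract_iep_region(call2, g)
  expect_equal(attr(r2, "g_start"), 0L)
  expect_equal(attr(r2, "rt_span"), c(400L, 1000L))

  # minus strand: RT upstream means higher coordinates; the region is
  # reverse-complemented into intron orientation
  call3 <- data.frame(category = "iep_containing", strand = "-",
                      rt_start = 6900L, rt_end = 7500L,
                      dvvi_start = 5000L, dvvi_end = 5100L)
  r3 <- extract_iep_region(call3, g)
  expect_equal(as.character(r3),
               revcomp(substr(g$sequence, 4801, 8500)))
  expect_equal(attr(r3, "rt_span"), c(1000L, 1600L))
})

test_that("IEP region wraps the origin of circular replicons", {
  g <- generate_genome(10000, seed = 3, replicon_id = "c", topology = "circular")
  call <- data.frame(category = "iep_containing", strand = "+",
                     rt_start = 500L, rt_end = 1100L,
                     dvvi_start = 2400L, dvvi_end = 2500L)
  r <- extract_iep_region(call, g)
  expect_equal(nchar(r), 3200L)
  expect_equal(substr(as.character(r), 1, 500),
               substr(g$sequence, 10000 - 500 + 1, 10000))
})

test_that("locate_iep picks the highest-scoring reference deterministically", {
  pep <- PARTS$peptides[["A"]]
  region <- paste0(strrep("T", 90), g2iscan:::reverse_translate(pep),
                   strrep("A", 90))
  loc <- locate_iep(region, PARTS$references)
  expect_equal(loc$query_id, "IEP_A")
  expect_equal(loc$aa_seq, pep)
  # a random region defers (no alignment above the floor)
  rand <- generate_genome(3000, seed = 9, replicon_id = "r")$sequence
  expect_null(locate_iep(rand, PARTS$references, min_bits = 60))
})

test_that("internal stops are reported, terminal stops are not", {
  pep <- PARTS$peptides[["B"]]
  nt <- paste0(g2iscan:::reverse_translate(pep), "TAA")
  mid <- 150L
  nt_int <- paste0(substr(nt, 1, 3 * (mid - 1)), "TAA",
                   substr(nt, 3 * mid + 1, nchar(nt)))
  region <- paste0(strrep("C", 30), nt_int, strrep("C", 30))
  span <- c(30L, 30L + nchar(nt_int))
  stops <- detect_interrupted(region, span, 0L)
  expect_equal(stops, mid)
  # the stop at the ORF end alone is not internal
  region0 <- paste0(strrep("C", 30), nt, strrep("C", 30))
  expect_length(detect_interrupted(region0, c(30L, 30L + nchar(nt)), 0L), 0)
})

test_that("find_orf returns the longest ORF overlapping the RT hit", {
  pep1 <- paste0("M", rand_pep(449, seed = 21))
  pep2 <- paste0("M", rand_pep(299, seed = 22))
  nt1 <- paste0(g2iscan:::reverse_translate(pep1), "TAA")
  nt2 <- paste0(g2iscan:::reverse_translate(pep2), "TAA")
  region <- paste0("TAA", nt1, nt2, "TAA")
  # RT interval straddling the junction between the two ORFs
  rt_span <- c(3L + nchar(nt1) - 60L, 3L + nchar(nt1) + 60L)
  orf <- find_orf(region, rt_span)
  expect_equal(orf$aa_seq, pep1)
  expect_equal((orf$end - orf$start) %% 3L, 0L)
  # ORF end includes the stop codon
  expect_equal(orf$end - orf$start, 3L * (nchar(pep1) + 1L))
})

test_that("motif completeness counts planted deletions exactly", {
  for (ndel in c(0L, 4L, 5L, 7L)) {
    bp <- g2iscan:::build_iep_peptide(PARTS, "ML", ndel)
    mc <- motif_completeness(bp$pep, PARTS$motif_sets[["ML"]])
    expect_equal(mc$n_missing, ndel)
    expect_equal(which(!mc$presence), setdiff(1:15, bp$kept))
  }
})

test_that("classification precedence: interrupted > short_orf > canonical", {
  expect_equal(classify_iep(2L, 6L), "interrupted")
  expect_equal(classify_iep(0L, 7L), "short_orf")
  expect_equal(classify_iep(0L, 5L), "short_orf")
  expect_equal(classify_iep(0L, 4L), "canonical")
  expect_equal(classify_iep(0L, 0L), "canonical")
})

test_that("stop exclusion shortens a peptide by the number of stops", {
  aa <- "MKL*VTT*AW"
  expect_equal(nchar(strip_stops(aa)), nchar(aa) - 2L)
  expect_false(grepl("\\*", strip_stops(aa)))
})
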