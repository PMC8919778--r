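test_that("FASTA genomes parse with case normalisation and alphabet policy", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">r1 some description", strrep("ACGT", 250),
               ">r2", paste0(strrep("acgt", 249), "acgR")), fa)
  expect_warning(gs <- load_genomes(fa), "mapped to N")
  expect_length(gs, 2)
  expect_equal(vapply(gs, `[[`, 0L, "length"), c(r1 = 1000L, r2 = 1000L))
  expect_equal(substr(gs$r2$sequence, 1, 4), "ACGT")
  expect_equal(substr(gs$r2$sequence, 1000, 1000), "N")
  unlink(fa)
})

test_that("minimal GenBank records are read (LOCUS + ORIGIN only)", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TESTREP1                 60 bp    DNA     circular BCT",
    "DEFINITION  synthetic test record.",
    "  ORGANISM  Examplea testii",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac",
    "       51 gtacgtacgt",
    "//"), gb)
  gs <- load_genomes(gb)
  expect_equal(gs$TESTREP1$length, 60L)
  expect_equal(gs$TESTREP1$topology, "circular")
  expect_equal(gs$TESTREP1$organism_label, "Examplea testii")
  expect_equal(substr(gs$TESTREP1$sequence, 1, 8), "ACGTACGT")
  unlink(gb)
})

test_that("empty or unreadable genome files are fatal", {
  empty <- tempfile(); file.create(empty)
  expect_error(load_genomes(empty), "empty")
  expect_error(load_genomes(tempfile()), "cannot read")
  unlink(empty)
})

test_that("terminator tables load with shape defaulting and row skipping", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("replicon_id\tstrand\tstem_start\tstem_end\tterm_3prime",
               "chr1\t+\t101\t130\t138",
               "chr1\t+\t300\t250\t320"), tsv)  # invalid stem order
  expect_warning(t <- load_terminators(tsv), "skipped")
  expect_equal(nrow(t), 1)
  expect_equal(t$shape, "unknown")
  expect_equal(t$stem_start, 100L)  # converted to 0-based
  expect_equal(t$term_3prime, 137L)
  unlink(tsv)
})

test_that("calls round-trip through GFF3 and TSV with exact coordinates", {
  pl <- standard_plant()
  hits <- rbind(
    filter_and_type_rt_hits(pl$hits[pl$hits$kind == "RT", ],
                            query_types = PARTS$query_types),
    filter_structural_hits(pl$hits[pl$hits$kind != "RT", ]))
  calls <- call_introns(pl$genome, hits)
  expect_gt(nrow(calls), 0)
  for (fmt in c("gff3", "tsv")) {
    f <- tempfile(fileext = paste0(".", fmt))
    export_calls(calls, f, fmt, genomes = list(chr1 = pl$genome))
    back <- import_calls(f, fmt)
    expect_equal(back$start, calls$start)
    expect_equal(back$end, calls$end)
    expect_equal(back$strand, calls$strand)
    expect_equal(back$category, calls$category)
    expect_equal(back$iep_type, calls$iep_type)
    unlink(f)
  }
})

test_that("emitted GFF3 uses 1-based inclusive coordinates", {
  calls <- g2iscan:::empty_calls()
  calls[1, c("call_id", "replicon_id", "strand", "category")] <-
    list("c1", "chr1", "+", "orf_less")
  calls$start <- 999L; calls$end <- 2999L
  calls$dvvi_start <- 999L; calls$dvvi_end <- 2999L; calls$dvvi_bits <- 30
  calls$n_d1_4 <- 1L
  f <- tempfile(fileext = ".gff3")
  export_calls(calls, f, "gff3")
  line <- grep("mobile_genetic_element", readLines(f), value = TRUE)[1]
  cols <- strsplit(line, "\t")[[1]]
  expect_equal(as.integer(cols[4:5]), c(1000L, 2999L))
  unlink(f)
})

test_that("empty call list exports a valid header-only GFF3", {
  f <- tempfile(fileext = ".gff3")
  export_calls(g2iscan:::empty_calls(), f, "gff3")
  expect_equal(readLines(f)[1], "##gff-version 3")
  unlink(f)
})

test_that("coordinate conversion between conventions is an involution", {
  x <- g2iscan:::to_1based(999L, 2999L)
  expect_equal(unlist(g2iscan:::to_0based(x$start, x$end)),
               c(start = 999L, end = 2999L))
})

test_that("calls naming unknown replicons are rejected at export", {
  pl <- standard_plant()
  calls <- g2iscan:::empty_calls()
  calls[1, c("call_id", "replicon_id", "strand", "category")] <-
    list("c1", "nope", "+", "orf_less")
  calls$start <- 1L; calls$end <- 10L
  expect_error(export_calls(calls, tempfile(), "tsv",
                            genomes = list(chr1 = pl$genome)),
               "unknown replicon")
})
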