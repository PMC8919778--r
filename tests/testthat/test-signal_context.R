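test_that("profile log-odds match the closed form", {
  # 50/50 A/C column with pseudocount 0.1:
  # p_A = (1 + 0.1) / (2 + 0.4); entry = log2(p_A / 0.25)
  aln <- c("AAAAAAAAAA", "CAAAAAAAAA")
  p <- build_profile(aln)
  expect_equal(unname(p$pwm["A", 1]), log2((1 + 0.1) / 2.4 / 0.25))
  expect_equal(unname(p$pwm["C", 1]), log2((1 + 0.1) / 2.4 / 0.25))
  expect_equal(unname(p$pwm["G", 1]), log2(0.1 / 2.4 / 0.25))
  # uniform consensus columns: every base identical
  expect_equal(unname(p$pwm["A", 2]), log2((2 + 0.1) / 2.4 / 0.25))
})

test_that("degenerate alignments score their own sequence maximally", {
  seqs <- rep("GTGCGATTACGG", 4)
  p <- build_profile(seqs)
  hit <- g2iscan:::scan_pwm(paste0("TTTT", seqs[1], "TTTT"), p$pwm)
  expect_equal(hit$pos, 4L)
  expect_equal(hit$bits, sum(apply(p$pwm, 2, max)))
})

test_that("all-gap columns are dropped", {
  p <- build_profile(c("AC-GTACGTA", "AC-GTACGTA"))
  expect_equal(ncol(p$pwm), 9L)
})

test_that("5' ends are found upstream within the 1200-nt window", {
  pl <- standard_plant()
  hits <- rbind(
    filter_and_type_rt_hits(pl$hits[pl$hits$kind == "RT", ],
                            query_types = PARTS$query_types),
    filter_structural_hits(pl$hits[pl$hits$kind != "RT", ]))
  calls <- call_introns(pl$genome, hits)
  iep <- calls[calls$category == "iep_containing", ]
  for (i in seq_len(nrow(iep))) {
    pk <- g2iscan:::profile_key(iep$iep_type[i])
    fp <- locate_5prime(iep[i, ], pl$genome, PARTS$profiles[[pk]])
    tr <- pl$truth[pl$truth$kind == "iep_intron" &
                     pl$truth$iep_type == iep$iep_type[i], ]
    expect_equal(fp, as.integer(tr$five_prime))
  }
})

test_that("the 10-bit acceptance threshold is exact", {
  pwm <- matrix(-5, nrow = 4, ncol = 10,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  mk_prof <- function(per_col) {
    m <- pwm; m["A", ] <- per_col
    structure(list(iep_type = "A", pwm = m, min_bits = 10),
              class = "FivePrimeProfile")
  }
  g <- genome_record("r", paste0(strrep("C", 200), strrep("A", 10),
                                 strrep("C", 200)))
  call <- data.frame(strand = "+", rt_start = 300L, rt_end = 360L,
                     iep_type = "A")
  expect_equal(locate_5prime(call, g, mk_prof(1.0)), 200L)   # 10.0 bits
  expect_true(is.na(locate_5prime(call, g, mk_prof(0.99)))) # 9.9 bits
})

test_that("the best-scoring of multiple candidate sites wins", {
  aln <- rep("GGGGGGGGGG", 3)
  p <- build_profile(aln)
  # two sites: a perfect match and one with two mismatches
  g <- genome_record("r", paste0(strrep("A", 100), "GGGGGGGGGG",
                                 strrep("A", 100), "GGGGTTGGGG",
                                 strrep("A", 100), strrep("C", 60)))
  call <- data.frame(strand = "+", rt_start = 370L, rt_end = 330L,
                     iep_type = "A")
  expect_equal(locate_5prime(call, g, p, window = 400L), 100L)
})

test_that("bacterial G (g1) calls are excluded from 5'-end search", {
  pl <- standard_plant()
  call <- data.frame(strand = "+", rt_start = 5000L, rt_end = 5600L,
                     iep_type = "G_g1")
  expect_true(is.na(locate_5prime(call, pl$genome, PARTS$profiles[["A"]])))
})

test_that("terminator tails classify as L with >= 4 U residues", {
  mk_term_genome <- function(tail) {
    genome_record("r", paste0(strrep("C", 100), tail, strrep("C", 100)))
  }
  term <- data.frame(replicon_id = "r", strand = "+", stem_start = 70L,
                     stem_end = 100L, term_3prime = 109L, shape = "unknown")
  expect_equal(classify_terminator_shape(term, mk_term_genome("TTTTAGGCAA")),
               "L")
  expect_equal(classify_terminator_shape(term, mk_term_genome("TTAGCCAGCA")),
               "I")
  expect_equal(classify_terminator_shape(term, mk_term_genome("TAGTCATGTA")),
               "L")  # exactly 4 scattered T
})

test_that("terminator distances are measured along the strand", {
  terms <- data.frame(replicon_id = "r", strand = c("+", "-"),
                      stem_start = c(960L, 2010L), stem_end = c(990L, 2040L),
                      term_3prime = c(1000L, 2000L), shape = "L")
  plus <- terminator_distance(1005L, "+", terms)
  expect_equal(plus$distance, 5L)
  minus <- terminator_distance(1990L, "-", terms)
  expect_equal(minus$distance, 10L)
  # out of range
  expect_null(terminator_distance(7000L, "+", terms, max_search = 5000L))
  # terminators downstream of the 5' end never match
  expect_null(terminator_distance(995L, "+", terms))
})

test_that("distance histogram bins conserve the call count", {
  d <- c(0L, 5L, 99L, 100L, 450L, 999L, 1000L, 1001L, 4000L, NA)
  b <- bin_terminator_distances(d)
  expect_equal(sum(b), 9L)
  expect_equal(unname(b["0-99"]), 3L)
  expect_equal(unname(b[">1000"]), 3L)  # 1000 falls in the 1000 bin edge
})
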