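test_that("gap arithmetic: separation, overlap clamp, circular wrap", {
  expect_equal(gap_nt(c(100, 200), c(300, 400)), 100L)
  expect_equal(gap_nt(c(100, 300), c(250, 400)), 0L)
  expect_equal(gap_nt(c(900, 950), c(10, 60), topology = "circular",
                      length = 1000), 60L)
  # minus strand: downstream means decreasing coordinates
  expect_equal(gap_nt(c(300, 400), c(100, 200), strand = "-"), 100L)
  # order violation on a linear replicon
  expect_true(is.na(gap_nt(c(300, 400), c(100, 200))))
  # without order requirement the smaller arc is returned
  expect_equal(gap_nt(c(10, 60), c(900, 950), topology = "circular",
                      length = 1000, require_upstream_order = FALSE), 60L)
})

test_that("RT/domain-V pairing honours the 1300-nt gap rule exactly", {
  dv <- mk_hit("DV_VI", 4500, 4590, source = "cm", bits = 40)
  paired <- pair_rt_with_dvvi(mk_hit("RT", 2600, 3200, iep_type = "A"), dv)
  expect_equal(nrow(paired), 1)   # gap 1300: in
  unpaired <- pair_rt_with_dvvi(
    mk_hit("RT", 2600, 3199, iep_type = "A"), dv)  # gap 1301
  expect_equal(nrow(unpaired), 0)
  # strand mismatch is never paired
  cross <- pair_rt_with_dvvi(mk_hit("RT", 2600, 3200, strand = "-"), dv)
  expect_equal(nrow(cross), 0)
})

test_that("pairing is greedy by gap with bit-score tie-break", {
  dv <- rbind(mk_hit("DV_VI", 5000, 5090, source = "cm", bits = 40),
              mk_hit("DV_VI", 9000, 9090, source = "cm", bits = 40))
  rt <- rbind(mk_hit("RT", 4000, 4600, bits = 100, query = "a", iep_type = "A"),
              mk_hit("RT", 8000, 8900, bits = 200, query = "b", iep_type = "B"))
  calls <- pair_rt_with_dvvi(rt, dv)
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$iep_type, c("A", "B"))
  # both RTs within range of dv2 only: the smaller gap wins
  dv1 <- mk_hit("DV_VI", 9000, 9090, source = "cm", bits = 40)
  calls <- pair_rt_with_dvvi(rt, dv1)
  expect_equal(calls$iep_type, "B")
})

test_that("ORF-less attachment requires unpaired domain V/VI plus I-IV", {
  dv <- mk_hit("DV_VI", 5000, 5090, source = "cm", bits = 40)
  d1_in <- mk_hit("D1", 3580, 3700, source = "cm", evalue = 1e-4)  # gap 1300
  out <- attach_orfless(dv, d1_in)
  expect_equal(nrow(out), 1)
  expect_equal(out$category, "orf_less")
  expect_equal(out$n_d1_4, 1L)
  d1_out <- mk_hit("D1", 3570, 3699, source = "cm", evalue = 1e-4) # gap 1301
  expect_equal(nrow(attach_orfless(dv, d1_out)), 0)
  expect_equal(nrow(attach_orfless(dv, d1_in[0, ])), 0)
})

test_that("overlapping domain V/VI hits merge keeping the best score", {
  dv <- rbind(mk_hit("DV_VI", 5000, 5090, source = "cm", bits = 40),
              mk_hit("DV_VI", 5010, 5100, source = "cm", bits = 30))
  rt <- mk_hit("RT", 4000, 4600, iep_type = "A")
  g <- generate_genome(10000, seed = 1, replicon_id = "chr1")
  calls <- call_introns(g, rbind(rt, dv))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$dvvi_bits, 40)
})

test_that("planted fixture yields exactly the expected calls, decoys absent", {
  pl <- standard_plant()
  hits <- rbind(
    filter_and_type_rt_hits(pl$hits[pl$hits$kind == "RT", ],
                            query_types = PARTS$query_types),
    filter_structural_hits(pl$hits[pl$hits$kind != "RT", ]))
  calls <- call_introns(pl$genome, hits)
  truth <- pl$truth[pl$truth$expected_call, ]
  expect_equal(nrow(calls), nrow(truth))
  expect_equal(calls$start, truth$span_start)
  expect_equal(calls$end, truth$span_end)
  expect_equal(calls$category, truth$expected_category)
  expect_equal(calls$iep_type[calls$category == "iep_containing"],
               truth$iep_type[truth$kind == "iep_intron"])
  expect_equal(nrow(call_introns(pl$genome, hits[0, ])), 0)
})

test_that("call count is monotone in max_gap", {
  pl <- standard_plant()
  hits <- rbind(
    filter_and_type_rt_hits(pl$hits[pl$hits$kind == "RT", ],
                            query_types = PARTS$query_types),
    filter_structural_hits(pl$hits[pl$hits$kind != "RT", ]))
  gaps <- c(100L, 500L, 1300L, 2500L)
  n <- vapply(gaps, function(mg) {
    nrow(call_introns(pl$genome, hits, assembly_config(max_gap = mg)))
  }, 0L)
  expect_true(all(diff(n) >= 0))
})

test_that("strand mirror: calls on the reverse complement are reflected", {
  pl <- standard_plant()
  hits <- rbind(
    filter_and_type_rt_hits(pl$hits[pl$hits$kind == "RT", ],
                            query_types = PARTS$query_types),
    filter_structural_hits(pl$hits[pl$hits$kind != "RT", ]))
  calls <- call_introns(pl$genome, hits)
  L <- pl$genome$length
  m <- hits
  m$strand <- ifelse(hits$strand == "+", "-", "+")
  m$start <- L - hits$end
  m$end <- L - hits$start
  g2 <- pl$genome; g2$sequence <- revcomp(pl$genome$sequence)
  mcalls <- call_introns(g2, m)
  expect_equal(nrow(mcalls), nrow(calls))
  expect_setequal(L - mcalls$end, calls$start)
  expect_setequal(mcalls$category, calls$category)
})

test_that("no hit is consumed by two calls (conservation)", {
  pl <- standard_plant()
  hits <- rbind(
    filter_and_type_rt_hits(pl$hits[pl$hits$kind == "RT", ],
                            query_types = PARTS$query_types),
    filter_structural_hits(pl$hits[pl$hits$kind != "RT", ]))
  calls <- call_introns(pl$genome, hits)
  iep <- calls[calls$category == "iep_containing", ]
  expect_false(anyDuplicated(paste(iep$rt_start, iep$rt_end)) > 0)
  expect_false(anyDuplicated(paste(calls$dvvi_start, calls$dvvi_end)) > 0)
})

test_that("greedy pairing matches the exhaustive min-total-gap oracle", {
  # brute force: enumerate all matchings, keep max cardinality, min total gap
  brute <- function(rt, dv, max_gap) {
    pairs <- list()
    for (i in seq_len(nrow(rt))) for (j in seq_len(nrow(dv))) {
      g <- gap_nt(c(rt$start[i], rt$end[i]), c(dv$start[j], dv$end[j]))
      if (!is.na(g) && g <= max_gap)
        pairs[[length(pairs) + 1L]] <- c(i, j, g)
    }
    best <- list(card = 0L, total = Inf)
    rec <- function(k, used_i, used_j, card, total) {
      if (k > length(pairs)) {
        if (card > best$card ||
            (card == best$card && total < best$total))
          best <<- list(card = card, total = total)
        return()
      }
      p <- pairs[[k]]
      rec(k + 1L, used_i, used_j, card, total)
      if (!(p[1] %in% used_i) && !(p[2] %in% used_j))
        rec(k + 1L, c(used_i, p[1]), c(used_j, p[2]),
            card + 1L, total + p[3])
    }
    rec(1L, integer(0), integer(0), 0L, 0)
    best
  }
  for (seed in 1:12) {
    hit_pos <- g2iscan:::with_seed(seed, {
      list(rt = sort(sample(seq(0, 30000, by = 1500), 4)),
           dv = sort(sample(seq(400, 30400, by = 1500), 4)))
    })
    rt <- do.call(rbind, lapply(hit_pos$rt, function(s)
      mk_hit("RT", s, s + 600, iep_type = "A")))
    dv <- do.call(rbind, lapply(hit_pos$dv, function(s)
      mk_hit("DV_VI", s, s + 90, source = "cm", bits = 40)))
    greedy <- pair_rt_with_dvvi(rt, dv)
    oracle <- brute(rt, dv, 1300L)
    if (nrow(greedy) == oracle$card) {
      ggap <- sum(vapply(seq_len(nrow(greedy)), function(k) {
        gap_nt(c(greedy$rt_start[k], greedy$rt_end[k]),
               c(greedy$dvvi_start[k], greedy$dvvi_end[k]))
      }, 0L))
      expect_equal(ggap, oracle$total)
    } else {
      expect_lte(nrow(greedy), oracle$card)
    }
  }
})
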