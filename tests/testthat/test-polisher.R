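test_that("candidate detection needs more than two disagreeing reads", {
  ref <- random_dna(300)
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 151, 151))[1]
  # 2 mismatching reads among 20: below threshold
  expect_equal(
    nrow(find_candidate_positions(make_site_pileup(ref, 150L, alt, 18, 2))),
    0L
  )
  # 3 mismatching reads: candidate
  cands <- find_candidate_positions(make_site_pileup(ref, 150L, alt, 17, 3))
  expect_equal(cands$pos, 150L)
  expect_equal(cands$n_reads, 3L)
})

test_that("insertions anchor after a position and deletions cover their span", {
  ref <- random_dna(200)
  ins_read <- paste0(substr(ref, 1, 100), "T", substr(ref, 101, 200))
  alns <- purrr::map_dfr(1:3, function(i) {
    make_aln(paste0("i", i), "c", 0L, "100=1I100=", ins_read)
  })
  cands <- find_candidate_positions(alns)
  expect_equal(cands$pos, 99L) # anchored immediately after 0-based 99
  del_read <- paste0(substr(ref, 1, 100), substr(ref, 104, 200))
  alns2 <- purrr::map_dfr(1:3, function(i) {
    make_aln(paste0("d", i), "c", 0L, "100=3D97=", del_read)
  })
  cands2 <- find_candidate_positions(alns2)
  expect_equal(cands2$pos, c(100L, 101L, 102L))
  # mixed evidence from distinct reads at one position counts together
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 101, 101))[1]
  mm_read <- ref
  substr(mm_read, 101, 101) <- alt
  mixed <- dplyr::bind_rows(
    make_aln("m1", "c", 0L, "100=1X99=", mm_read),
    make_aln("m2", "c", 0L, "100=1X99=", mm_read),
    make_aln("m3", "c", 0L, "100=1D99=", paste0(substr(ref, 1, 100), substr(ref, 102, 200)))
  )
  expect_equal(find_candidate_positions(mixed)$pos, 100L)
})

test_that("window grouping follows the gap and span rules", {
  w <- group_windows(c(10L, 40L, 200L))
  expect_equal(w$start, c(10, 200))
  expect_equal(w$end, c(41, 201))
  # span cap splits a chain of close positions
  w2 <- group_windows(c(0L, 30L, 60L, 90L, 120L))
  expect_equal(w2$start, c(0, 120))
  expect_equal(w2$end, c(91, 121))
  expect_equal(w2$n_candidates, c(4L, 1L))
  expect_equal(nrow(group_windows(integer())), 0L)
  # every position in exactly one window
  set.seed(2)
  pos <- sort(sample(0:5000, 120))
  w3 <- group_windows(pos)
  n_in <- vapply(pos, function(p) sum(w3$start <= p & w3$end > p), integer(1))
  expect_true(all(n_in == 1L))
  expect_true(all(w3$end - w3$start <= 100L))
})

test_that("featurization fills channels from the alignment", {
  ref <- c(c = random_dna(60))
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 31, 31))[1]
  perfect <- make_aln("p", "c", 0L, "60=", ref[["c"]], qual = strrep("I", 60))
  tens <- featurize_window(list(contig = "c", start = 20L, end = 40L), perfect, ref)
  expect_equal(nrow(tens$bases), 1L)
  expect_true(all(tens$match[1, ] == "match"))
  expect_equal(unname(tens$baseq[1, 1]), utf8ToInt("I") - 33L)
  expect_equal(paste(tens$bases[1, ], collapse = ""), substr(ref[["c"]], 21, 40))
  # deletion shows as gap with no match flag
  del_read <- paste0(substr(ref[["c"]], 1, 30), substr(ref[["c"]], 32, 60))
  tens2 <- featurize_window(
    list(contig = "c", start = 20L, end = 40L),
    make_aln("d", "c", 0L, "30=1D29=", del_read), ref
  )
  expect_equal(tens2$bases[1, 11], "-")
  expect_true(is.na(tens2$match[1, 11]))
  # mismatch flagged with the read base
  mm <- ref[["c"]]
  substr(mm, 31, 31) <- alt
  tens3 <- featurize_window(
    list(contig = "c", start = 20L, end = 40L),
    make_aln("m", "c", 0L, "30=1X29=", mm), ref
  )
  expect_equal(tens3$bases[1, 11], alt)
  expect_equal(tens3$match[1, 11], "mismatch")
})

test_that("depth capping is deterministic and stable across runs", {
  ref <- c(c = random_dna(120))
  alns <- purrr::map_dfr(1:40, function(i) {
    make_aln(paste0("r", sample(1000:9999, 1)), "c", 0L, "120=", ref[["c"]])
  })
  t1 <- featurize_window(list(contig = "c", start = 10L, end = 60L), alns, ref,
    depth_cap = 30L
  )
  t2 <- featurize_window(list(contig = "c", start = 10L, end = 60L),
    alns[sample(40), ], ref,
    depth_cap = 30L
  )
  expect_equal(nrow(t1$bases), 30L)
  expect_setequal(t1$reads, t2$reads)
})

test_that("consensus prediction weighs reads by base quality", {
  ref <- c(c = random_dna(40))
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 21, 21))[1]
  mm <- ref[["c"]]
  substr(mm, 21, 21) <- alt
  # 10 reads all showing alt: predicted sequence carries alt
  alns <- purrr::map_dfr(1:10, function(i) {
    make_aln(paste0("a", i), "c", 0L, "20=1X19=", mm)
  })
  tens <- featurize_window(list(contig = "c", start = 10L, end = 30L), alns, ref)
  pred <- predict_sequence(tens)
  expect_equal(substr(pred$seq, 11, 11), alt)
  # 5 ref reads at q30 outweigh 5 alt reads at q10
  alns2 <- dplyr::bind_rows(
    purrr::map_dfr(1:5, function(i) {
      make_aln(paste0("r", i), "c", 0L, "40=", ref[["c"]], qual = strrep("?", 40))
    }),
    purrr::map_dfr(1:5, function(i) {
      make_aln(paste0("a", i), "c", 0L, "20=1X19=", mm, qual = strrep("+", 40))
    })
  )
  tens2 <- featurize_window(list(contig = "c", start = 10L, end = 30L), alns2, ref)
  pred2 <- predict_sequence(tens2)
  expect_equal(pred2$seq, substr(ref[["c"]], 11, 30))
  # weight check: 5 * (1 - 1e-3) vs 5 * (1 - 1e-1)
  expect_equal(pred2$support[11], 5 * 0.999 / (5 * 0.999 + 5 * 0.9),
    tolerance = 1e-9
  )
})

test_that("insertions need a majority of covering weight to be emitted", {
  ref <- c(c = random_dna(40))
  with_ins <- paste0(substr(ref[["c"]], 1, 20), "T", substr(ref[["c"]], 21, 40))
  mk <- function(n, prefix, cig, seq) {
    purrr::map_dfr(seq_len(n), function(i) make_aln(paste0(prefix, i), "c", 0L, cig, seq))
  }
  # 2 of 10 reads with the insertion: not emitted
  alns <- dplyr::bind_rows(
    mk(8, "r", "40=", ref[["c"]]),
    mk(2, "i", "20=1I20=", with_ins)
  )
  tens <- featurize_window(list(contig = "c", start = 10L, end = 30L), alns, ref)
  expect_equal(predict_sequence(tens)$seq, substr(ref[["c"]], 11, 30))
  # 8 of 10 with the insertion: emitted
  alns2 <- dplyr::bind_rows(
    mk(2, "r", "40=", ref[["c"]]),
    mk(8, "i", "20=1I20=", with_ins)
  )
  tens2 <- featurize_window(list(contig = "c", start = 10L, end = 30L), alns2, ref)
  expect_equal(
    predict_sequence(tens2)$seq,
    paste0(substr(ref[["c"]], 11, 20), "T", substr(ref[["c"]], 21, 30))
  )
})

test_that("edits_from_diff emits normalized VCF records", {
  expect_equal(nrow(edits_from_diff("ACGT", "ACGT")), 0L)
  # deletion gets a left anchor
  ed <- edits_from_diff("ACGT", "ACT", support = rep(1, 3))
  expect_equal(ed$ref, "CG")
  expect_equal(ed$alt, "C")
  expect_equal(ed$pos, 2L)
  # two adjacent substitutions stay separate SNVs (no MNP merging)
  ed2 <- edits_from_diff("TTAATT", "TTGGTT")
  expect_equal(nrow(ed2), 2L)
  expect_true(all(nchar(ed2$ref) == 1L & nchar(ed2$alt) == 1L))
  # insertion in a homopolymer left-normalizes to the run start
  ed3 <- edits_from_diff("GAAAAC", "GAAAAAC")
  expect_equal(ed3$pos, 1L)
  expect_equal(ed3$ref, "G")
  expect_equal(ed3$alt, "GA")
  # window offset shifts coordinates
  ed4 <- edits_from_diff("ACGT", "ACT", window_start = 100L)
  expect_equal(ed4$pos, 102L)
})

test_that("applying diff edits reproduces the predicted sequence (round trip)", {
  set.seed(19)
  for (rep in 1:40) {
    a <- random_dna(sample(20:80, 1))
    b <- a
    # random mutations of the window
    for (k in seq_len(sample(0:4, 1))) {
      p <- sample(nchar(b), 1)
      op <- sample(3, 1)
      if (op == 1L) {
        substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
      } else if (op == 2L && nchar(b) > 5) {
        b <- paste0(substr(b, 1, p - 1), substr(b, p + 1, nchar(b)))
      } else {
        b <- paste0(substr(b, 1, p), sample(c("A", "C", "G", "T"), 1),
          substr(b, p + 1, nchar(b))
        )
      }
    }
    ed <- edits_from_diff(a, b, support = rep(1, nchar(b)))
    expect_identical(apply_edits(a, ed), b, label = paste(a, "->", b))
  }
})

test_that("GQ reflects the weakest supported position of a record", {
  ed2 <- edits_from_diff("TTAATT", "TTGGTT",
    support = c(1, 1, 0.99, 0.6, 1, 1)
  )
  expect_equal(ed2$gq[1], -10 * log10(1 - 0.99), tolerance = 1e-6)
  expect_equal(ed2$gq[2], -10 * log10(1 - 0.6), tolerance = 1e-6)
  # an insertion record takes the minimum over its inserted bases
  ed3 <- edits_from_diff("GATTC", "GATAAGTC", support = c(1, 1, 1, 0.9, 0.7, 1, 1, 1))
  ins <- ed3[nchar(ed3$alt) > nchar(ed3$ref), ]
  expect_equal(ins$gq, -10 * log10(1 - 0.7), tolerance = 1e-6)
})

test_that("no candidates means no windows and no edits", {
  ref <- c(c = random_dna(500))
  alns <- purrr::map_dfr(1:10, function(i) {
    make_aln(paste0("r", i), "c", 0L, "500=", ref[["c"]])
  })
  res <- polish_haplotype(ref, alns)
  expect_equal(res$n_candidates, 0L)
  expect_equal(nrow(res$windows), 0L)
  expect_equal(nrow(res$edits), 0L)
})

test_that("polishing corrects a known draft error end to end", {
  set.seed(23)
  truth <- c(c = random_dna(800))
  draft <- truth
  alt <- setdiff(c("A", "C", "G", "T"), substr(truth, 401, 401))[1]
  substr(draft[["c"]], 401, 401) <- alt # draft error at 1-based 401
  # reads carry the truth; vs the draft they all mismatch at 400 (0-based)
  alns <- purrr::map_dfr(1:20, function(i) {
    make_aln(paste0("r", i), "c", 0L, "400=1X399=", truth[["c"]])
  })
  res <- polish_haplotype(draft, alns)
  expect_equal(nrow(res$edits), 1L)
  expect_equal(res$edits$pos, 401L)
  expect_equal(res$edits$ref, alt)
  expect_equal(res$edits$alt, substr(truth[["c"]], 401, 401))
  expect_equal(res$edits$class, "OTHER")
  expect_gte(res$edits$gq, 20)
  polished <- apply_edits(draft[["c"]], res$edits)
  expect_identical(polished, truth[["c"]])
})
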