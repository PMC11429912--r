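test_that("QV report satisfies the errors-per-Mb identity", {
  r <- qv_report(252, 1e6, k = 31)
  expect_equal(r$errors_per_mb, 10^(-r$qv / 10) * 1e6, tolerance = 1e-9)
  # zero error k-mers: capped, not infinite
  r0 <- qv_report(0, 1e6)
  expect_true(r0$capped)
  expect_equal(r0$qv, 99)
  # identity holds across magnitudes
  for (b in c(1, 10, 1000, 1e5)) {
    r2 <- qv_report(b, 1e6)
    expect_equal(r2$errors_per_mb, 10^(-r2$qv / 10) * 1e6, tolerance = 1e-9)
  }
})

test_that("a single substituted base yields k error k-mers in one interval", {
  set.seed(41)
  truth <- random_dna(400)
  db <- kmer_set(truth, 31)
  mut <- truth
  p <- 200L
  substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), substr(truth, p, p))[1]
  ek <- error_kmers(c(x = mut), db, 31)
  expect_equal(ek$report$error_kmers, 31)
  expect_equal(nrow(ek$track), 1L)
  expect_equal(ek$track$end - ek$track$start, 2L * 31L - 1L)
  # assembly contained in reads: no error k-mers, capped QV
  ek0 <- error_kmers(c(x = truth), db, 31)
  expect_equal(ek0$report$error_kmers, 0)
  expect_true(ek0$report$capped)
  expect_error(error_kmers(c(x = "ACGT"), db, 31), "shorter than k")
})

test_that("k-mer scan is canonical: reverse-complemented reads still cover", {
  set.seed(43)
  truth <- random_dna(300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(truth)))
  db <- kmer_set(rc, 31)
  ek <- error_kmers(c(x = truth), db, 31)
  expect_equal(ek$report$error_kmers, 0)
})

test_that("delta QV follows the closed form and its paper identities", {
  expect_equal(delta_qv(100, 100), 0)
  expect_equal(delta_qv(100, 50), 3.0103, tolerance = 1e-4)
  expect_equal(delta_qv(100, 0), 99) # capped
  # additivity: dqv(b,a1) + dqv(a1,a2) = dqv(b,a2)
  expect_equal(
    delta_qv(1000, 400) + delta_qv(400, 70),
    delta_qv(1000, 70),
    tolerance = 1e-12
  )
  # a 3.4 improvement halves errors and then some: 54% reduction
  expect_equal(round(100 * error_reduction(3.4)), 54)
  expect_equal(round(100 * error_reduction(1.8)), 34)
  # 8.14 errors/Mb corresponds to QV 50.9
  expect_equal(round(qv_from_errors_per_mb(8.14), 1), 50.9)
})

test_that("error k-mer annotation classifies fixed/induced/unchanged", {
  idal <- make_aln("raw", "pol", 0L, "1000=", strrep("A", 10))
  raw <- intervals("raw", c(100, 300), c(140, 330))
  pol <- intervals("pol", c(300, 600), c(330, 640))
  tr <- annotate_error_kmers(raw, pol, idal)
  expect_equal(sort(unique(tr$status)), c("fixed", "induced", "unchanged"))
  expect_equal(tr$start[tr$status == "fixed"], 100L)
  expect_equal(tr$start[tr$status == "induced"], 600L)
  expect_equal(tr$start[tr$status == "unchanged"], 300L)
  # identical tracks through the identity alignment: all unchanged
  tr2 <- annotate_error_kmers(raw, intervals("pol", c(100, 300), c(140, 330)), idal)
  expect_true(all(tr2$status == "unchanged"))
  # raw-only interval with empty polished track: fixed
  tr3 <- annotate_error_kmers(raw, intervals(), idal)
  expect_true(all(tr3$status == "fixed"))
})

test_that("annotation interval lengths balance exactly", {
  set.seed(47)
  for (rep in 1:10) {
    idal <- make_aln("raw", "pol", 0L, "5000=", "A")
    mk <- function(n) {
      s <- sort(sample(0:4900, n))
      merge_intervals(intervals(rep("x", n), s, s + sample(10:60, n, TRUE)))
    }
    raw <- mk(12)
    raw$contig <- "raw"
    pol <- mk(9)
    pol$contig <- "pol"
    tr <- annotate_error_kmers(raw, pol, idal)
    len <- function(st) sum(tr$end[tr$status == st] - tr$start[tr$status == st])
    # |fixed| + |unchanged| = |raw|; |induced| + |unchanged| = |projected|
    expect_equal(len("fixed") + len("unchanged"), interval_span(raw))
    expect_equal(len("induced") + len("unchanged"), interval_span(pol))
  }
})

test_that("annotation agrees with a per-base mask oracle through an indel", {
  # raw has one extra base at 50 (insertion relative to polished); no
  # polished interval spans the insertion point, so interval projection and
  # the per-base mask agree exactly
  aln <- make_aln("raw", "pol", 0L, "50=1I949=", strrep("A", 1000))
  raw <- intervals("raw", c(30, 200), c(70, 240))
  pol <- intervals("pol", c(10, 500), c(40, 540))
  tr <- annotate_error_kmers(raw, pol, aln)
  # oracle: project polished mask base by base, then compare masks
  map <- per_base_map("50=1I949=", 0L)
  pol_mask <- rep(FALSE, 1001)
  for (i in seq_len(nrow(pol))) {
    for (p in pol$start[[i]]:(pol$end[[i]] - 1L)) {
      q <- map$t2q[map$t2q[, 1] == p, 2]
      if (length(q) == 1L && !is.na(q)) pol_mask[q + 1L] <- TRUE
    }
  }
  raw_mask <- rep(FALSE, 1001)
  for (i in seq_len(nrow(raw))) {
    raw_mask[(raw$start[[i]] + 1L):raw$end[[i]]] <- TRUE
  }
  status_at <- function(p) {
    hit <- tr[tr$start <= p & tr$end > p, ]
    if (nrow(hit) == 0L) NA_character_ else hit$status[[1]]
  }
  for (p in c(10:69, 200:239, 500:545)) {
    want <- if (raw_mask[p + 1L] && pol_mask[p + 1L]) {
      "unchanged"
    } else if (raw_mask[p + 1L]) {
      "fixed"
    } else if (pol_mask[p + 1L]) "induced" else NA_character_
    expect_identical(status_at(p), want, label = paste("pos", p))
  }
})

test_that("edit labelling intersects REF spans with precedence", {
  tr <- tibble::tibble(
    contig = "c", start = c(100L, 200L, 300L),
    end = c(140L, 240L, 340L),
    status = c("fixed", "induced", "unchanged"), unprojected = FALSE
  )
  ed <- tibble::tibble(
    contig = "c", pos = c(110L, 210L, 310L, 500L, 139L),
    ref = c("A", "A", "A", "A", strrep("A", 70)), alt = "G"
  )
  lab <- annotate_edits(ed, tr)
  expect_equal(lab$label, c("fixes", "induces", "no_change", "none", "induces"))
})

test_that("GQ sweep equals exhaustive enumeration on toy edit sets", {
  set.seed(53)
  mk_edits <- function(n) {
    tibble::tibble(
      class = sample(c("INS1", "DEL1", "OTHER"), n, TRUE),
      gq = sample(0:25, n, TRUE),
      label = sample(c("fixes", "induces", "none"), n, TRUE,
        prob = c(0.4, 0.3, 0.3)
      ),
      weight = sample(1:5, n, TRUE)
    )
  }
  # independent enumeration (plain loops, no shared code)
  enumerate <- function(ed, unchanged, grid) {
    best <- NULL
    best_after <- Inf
    for (r in seq_len(nrow(grid))) {
      after <- unchanged
      for (i in seq_len(nrow(ed))) {
        cut <- switch(ed$class[[i]],
          INS1 = grid$gq_ins1[[r]],
          DEL1 = grid$gq_del1[[r]],
          grid$gq_other[[r]]
        )
        kept <- ed$gq[[i]] >= cut
        if (kept && ed$label[[i]] == "induces") after <- after + ed$weight[[i]]
        if (!kept && ed$label[[i]] == "fixes") after <- after + ed$weight[[i]]
      }
      if (after < best_after) {
        best_after <- after
        best <- grid[r, ]
      }
    }
    list(best = best, after = best_after)
  }
  for (rep in 1:5) {
    ed <- mk_edits(20)
    sw <- sweep_gq(ed, "ins1_del1_rest", 0:25, unchanged = 10)
    grid <- sw$curve[, c("gq_ins1", "gq_del1", "gq_other")]
    oracle <- enumerate(ed, 10, grid)
    expect_equal(sw$optimum$errors_after, oracle$after)
    # the sweep's optimum achieves the oracle's minimum (cutoff vector may
    # tie; compare achieved error count, and tie-break is lowest cutoffs)
    ties <- sw$curve[sw$curve$errors_after == oracle$after, ]
    ord <- order(ties$gq_ins1, ties$gq_del1, ties$gq_other)
    expect_equal(
      unlist(sw$optimum[, c("gq_ins1", "gq_del1", "gq_other")]),
      unlist(ties[ord[1], c("gq_ins1", "gq_del1", "gq_other")])
    )
  }
})

test_that("GQ sweep degenerate and nesting properties hold", {
  # nothing induces: optimum keeps everything (cutoff 0)
  ed <- tibble::tibble(
    class = c("INS1", "DEL1", "OTHER"), gq = c(5, 10, 15),
    label = "fixes", weight = 1
  )
  for (sc in c("single", "ins1_rest", "ins1_del1_rest")) {
    sw <- sweep_gq(ed, sc, 0:25, unchanged = 5)
    expect_equal(unlist(sw$optimum[, c("gq_ins1", "gq_del1", "gq_other")]),
      c(gq_ins1 = 0, gq_del1 = 0, gq_other = 0)
    )
  }
  # all INS1 induce, others fix: scenario 2 pushes the INS1 cutoff above them
  ed2 <- dplyr::bind_rows(
    tibble::tibble(class = "INS1", gq = c(5, 12, 18), label = "induces", weight = 1),
    tibble::tibble(class = c("DEL1", "OTHER"), gq = c(8, 9), label = "fixes", weight = 1)
  )
  sw2 <- sweep_gq(ed2, "ins1_rest", 0:25, unchanged = 3)
  expect_gt(sw2$optimum$gq_ins1, 18)
  expect_equal(sw2$optimum$gq_other, 0)
  # scenario 3 never scores below scenario 1 at its own optimum
  set.seed(59)
  ed3 <- tibble::tibble(
    class = sample(c("INS1", "DEL1", "OTHER"), 30, TRUE),
    gq = sample(0:25, 30, TRUE),
    label = sample(c("fixes", "induces"), 30, TRUE), weight = 1
  )
  s1 <- sweep_gq(ed3, "single", 0:25, unchanged = 8)
  s3 <- sweep_gq(ed3, "ins1_del1_rest", 0:25, unchanged = 8)
  expect_lte(s3$optimum$errors_after, s1$optimum$errors_after)
  # no edits: degenerate zero cutoffs
  sw0 <- sweep_gq(ed3[0, ], "single")
  expect_equal(sw0$optimum$gq_ins1, 0)
})

test_that("error context stratification detects GC, homopolymers, low coverage", {
  hp_seq <- paste0(
    random_dna(58), "CC", strrep("A", 11), "CC", random_dna(58),
    strrep("GC", 20), random_dna(60)
  )
  seqs <- c(c = hp_seq)
  # homopolymer boundary: 11 bases counts ("greater than 10 bp")
  runs <- homopolymer_runs(seqs[["c"]], 11L, "c")
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$end - runs$start, 11L)
  expect_equal(nrow(homopolymer_runs(strrep("A", 10), 11L)), 0L)
  track <- intervals("c",
    c(60L, 131L, 10L),
    c(75L, 175L, 45L)
  ) # over the homopolymer run; over the GC tract; plain sequence
  depth <- tibble::tibble(
    contig = "c", start = c(0L, 100L),
    end = c(100L, nchar(hp_seq)), depth = c(30L, 3L)
  )
  res <- stratify_error_context(track, seqs, depth, k = 31L)
  expect_equal(res$n[res$category == "homopolymer_ge_11"], 1L)
  expect_gte(res$n[res$category == "gc_above_0.7"], 1L)
  expect_equal(res$n[res$category == "coverage_below_5"], 1L)
  # uniform high depth: no low-coverage overlap
  depth_hi <- tibble::tibble(
    contig = "c", start = 0L,
    end = nchar(hp_seq), depth = 30L
  )
  res2 <- stratify_error_context(track, seqs, depth_hi, k = 31L)
  expect_equal(res2$n[res2$category == "coverage_below_5"], 0L)
})

test_that("GC fraction boundary is computed per k-mer", {
  km <- paste0(strrep("G", 11), strrep("C", 11), strrep("A", 9)) # 22/31 GC
  expect_equal(stringr::str_count(km, "[GC]") / 31, 22 / 31)
  expect_gt(22 / 31, 0.70)
  track <- intervals("c", 0L, 31L)
  res <- stratify_error_context(track, c(c = km), NULL, k = 31L)
  expect_equal(res$n[res$category == "gc_above_0.7"], 1L)
})

test_that("coverage quantization produces the configured bands", {
  depth <- tibble::tibble(
    contig = "c", start = c(0L, 50L, 120L),
    end = c(50L, 120L, 200L), depth = c(2L, 7L, 40L)
  )
  q <- quantize_depth(depth, c(0, 5, 10, 150))
  expect_equal(q$band, c("[0,5)", "[5,10)", "[10,150)"))
})
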