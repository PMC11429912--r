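test_that("homozygous region finder decomposes identity runs correctly", {
  hvh <- make_aln("h2", "h1", 0L, "30000=", strrep("A", 10))
  r <- find_homozygous_regions(hvh, 20000L)
  expect_equal(nrow(r), 1L)
  expect_equal(r$length, 30000L)
  expect_equal(c(r$start_t, r$end_t), c(0L, 30000L))
  # runs of exactly the threshold or below are excluded
  r2 <- find_homozygous_regions(
    make_aln("h2", "h1", 0L, "15000=1X15000=", strrep("A", 10)), 20000L
  )
  expect_equal(nrow(r2), 0L)
  # both qualifying runs reported, on both coordinate systems
  r3 <- find_homozygous_regions(
    make_aln("h2", "h1", 0L, "25000=1X21000=", strrep("A", 10)), 20000L
  )
  expect_equal(r3$length, c(25000L, 21000L))
  expect_equal(r3$start_q, c(0L, 25001L))
  # boundary semantics: "greater than" is strict
  expect_equal(nrow(find_homozygous_regions(
    make_aln("h2", "h1", 0L, "20000=", "A"), 20000L
  )), 0L)
  expect_equal(nrow(find_homozygous_regions(
    make_aln("h2", "h1", 0L, "20001=", "A"), 20000L
  )), 1L)
  expect_error(
    find_homozygous_regions(make_aln("h2", "h1", 0L, "30000M", "A")),
    "M"
  )
})

test_that("site genotyper matches direct likelihood evaluation", {
  e <- 0.01
  direct <- function(nref, nalt) {
    ll <- c(
      nref * log10(1 - e) + nalt * log10(e),
      (nref + nalt) * log10(0.5),
      nref * log10(e) + nalt * log10(1 - e)
    )
    o <- order(ll, decreasing = TRUE)
    list(
      gt = c("ref", "het", "alt")[o[1]],
      gq = min(99, 10 * (ll[o[1]] - ll[o[2]]))
    )
  }
  for (case in list(c(20, 0), c(10, 10), c(3, 1), c(0, 15), c(7, 3), c(5, 5))) {
    got <- genotype_site(case[1], case[2], e)
    want <- direct(case[1], case[2])
    expect_equal(got$genotype, want$gt, info = paste(case, collapse = "/"))
    expect_equal(got$gq, want$gq, tolerance = 1e-10)
  }
  # balanced high coverage is a confident het; 3/1 falls below GQ 10
  expect_equal(genotype_site(10, 10, 0.01)$genotype, "het")
  expect_equal(genotype_site(10, 10, 0.01)$gq, 99)
  expect_lt(genotype_site(3, 1, 0.01)$gq, 10)
})

test_that("het candidate calling finds balanced sites and skips unanimous ones", {
  ref <- random_dna(400)
  # unanimous reference: no call
  alns <- make_site_pileup(ref, 200L, "A", 20, 0)
  expect_equal(nrow(call_het_candidates(alns, c(c1 = ref))), 0L)
  # 10/10 split at one site
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 201, 201))[1]
  alns2 <- make_site_pileup(ref, 200L, alt, 10, 10)
  calls <- call_het_candidates(alns2, c(c = ref))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 200L)
  expect_equal(calls$alt, alt)
  expect_gte(calls$gq, 10)
  # 3/1 site suppressed by the GQ filter
  alns3 <- make_site_pileup(ref, 200L, alt, 3, 1)
  expect_equal(nrow(call_het_candidates(alns3, c(c = ref), min_alt = 1L)), 0L)
})

test_that("phasing joins co-covered variants and matches brute force", {
  ref <- random_dna(3000)
  sites <- c(500L, 1500L, 2500L)
  alt <- vapply(sites, function(p) {
    setdiff(c("A", "C", "G", "T"), substr(ref, p + 1, p + 1))[1]
  }, character(1))
  cands <- tibble::tibble(
    contig = "c", pos = sites, ref = substring(ref, sites + 1, sites + 1),
    alt = alt, gq = 50, nref = 10L, nalt = 10L
  )
  hapA_seq <- ref # all-ref haplotype
  hapB_seq <- ref
  for (i in seq_along(sites)) {
    substr(hapB_seq, sites[i] + 1, sites[i] + 1) <- alt[i]
  }
  ul <- dplyr::bind_rows(
    purrr::map_dfr(1:5, function(i) {
      make_aln(paste0("ua", i), "c", 0L, "3000=", hapA_seq)
    }),
    purrr::map_dfr(1:5, function(i) {
      cig <- paste0(
        sites[1], "=1X", sites[2] - sites[1] - 1, "=1X",
        sites[3] - sites[2] - 1, "=1X", 3000 - sites[3] - 1, "="
      )
      make_aln(paste0("ub", i), "c", 0L, cig, hapB_seq)
    })
  )
  ph <- phase_hets(cands, ul, min_read_len = 1000L)
  expect_equal(length(unique(ph$block_id)), 1L)
  # all three alts lie on the same haplotype (cis)
  expect_true(all(ph$allele_hapB == "alt") || all(ph$allele_hapA == "alt"))
  # matches exhaustive enumeration of phasings
  amat <- rbind(
    matrix("ref", 5, 3), matrix("alt", 5, 3)
  )
  bf <- brute_force_phase(amat)
  phi_impl <- ifelse(ph$allele_hapA == "ref", 0L, 1L)
  expect_equal(phi_impl, bf$phi)
  # variants never co-covered become singleton blocks
  ul_gap <- make_aln("ug", "c", 0L, paste0(sites[1] + 100, "="),
    substr(hapA_seq, 1, sites[1] + 100)
  )
  ph2 <- phase_hets(cands, ul_gap, min_read_len = 100L)
  expect_equal(length(unique(ph2$block_id)), 3L)
})

test_that("randomized phasing agrees with the brute-force oracle", {
  set.seed(33)
  for (rep in 1:15) {
    n_var <- sample(3:6, 1)
    n_reads <- 12L
    sites <- sort(sample(seq(200L, 4800L, by = 200L), n_var))
    truth_phi <- c(0L, sample(0:1, n_var - 1L, replace = TRUE))
    hapA <- ifelse(truth_phi == 0L, "ref", "alt")
    hapB <- ifelse(truth_phi == 0L, "alt", "ref")
    ref <- random_dna(5000)
    alt <- vapply(sites, function(p) {
      setdiff(c("A", "C", "G", "T"), substr(ref, p + 1, p + 1))[1]
    }, character(1))
    cands <- tibble::tibble(
      contig = "c", pos = sites,
      ref = substring(ref, sites + 1, sites + 1), alt = alt, gq = 50
    )
    reads <- purrr::map_dfr(seq_len(n_reads), function(i) {
      pick <- if (i %% 2 == 0) hapA else hapB
      seqi <- ref
      for (k in seq_along(sites)) {
        if (pick[k] == "alt") substr(seqi, sites[k] + 1, sites[k] + 1) <- alt[k]
      }
      xs <- sites[pick == "alt"]
      cig <- if (length(xs) == 0L) "5000=" else {
        parts <- c()
        prev <- 0L
        for (x in xs) {
          parts <- c(parts, paste0(x - prev, "=1X"))
          prev <- x + 1L
        }
        paste0(paste(parts, collapse = ""), 5000 - prev, "=")
      }
      make_aln(paste0("r", i), "c", 0L, cig, seqi)
    })
    ph <- phase_hets(cands, reads, min_read_len = 1000L)
    expect_equal(length(unique(ph$block_id)), 1L)
    phi_impl <- ifelse(ph$allele_hapA == "ref", 0L, 1L)
    amat <- matrix(NA_character_, n_reads, n_var)
    for (i in seq_len(n_reads)) {
      pick <- if (i %% 2 == 0) hapA else hapB
      amat[i, ] <- pick
    }
    bf <- brute_force_phase(amat)
    # oracle score achieved (phase may be globally flipped, same concordance)
    score_impl <- sum(apply(amat, 1, function(obs) {
      max(
        sum(obs == ifelse(phi_impl == 0L, "ref", "alt")),
        sum(obs == ifelse(phi_impl == 0L, "alt", "ref"))
      )
    }))
    expect_equal(score_impl, bf$score)
  }
})

test_that("block haplotype selection retains alts on the assembly-like side", {
  ph <- tibble::tibble(
    contig = "c", pos = c(10L, 20L, 30L), ref = "A", alt = "G", gq = 50,
    block_id = 1L,
    allele_hapA = c("ref", "ref", "alt"),
    allele_hapB = c("alt", "alt", "ref")
  )
  sel <- select_block_haplotype(ph)
  expect_equal(sel$selection$selected, "A")
  expect_equal(sel$retained$pos, 30L)
  # all alts on one side: select the other, retain nothing
  ph2 <- dplyr::mutate(ph, allele_hapA = "alt", allele_hapB = "ref")
  sel2 <- select_block_haplotype(ph2)
  expect_equal(sel2$selection$selected, "B")
  expect_equal(nrow(sel2$retained), 0L)
  # tie in reference alleles goes to haplotype A
  ph3 <- ph[1:2, ]
  ph3$allele_hapA <- c("ref", "alt")
  ph3$allele_hapB <- c("alt", "ref")
  sel3 <- select_block_haplotype(ph3)
  expect_equal(sel3$selection$selected, "A")
  expect_equal(sel3$retained$pos, 20L)
})

test_that("variant blocks follow the centered width rule and merge", {
  b <- build_variant_blocks(
    tibble::tibble(contig = "c", pos = 1000L, ref = "A"), 100L
  )
  expect_equal(c(b$start, b$end), c(950L, 1050L))
  # a 60 bp deletion widens the window to 2x the span
  b2 <- build_variant_blocks(
    tibble::tibble(contig = "c", pos = 1000L, ref = strrep("A", 61)), 100L
  )
  expect_equal(b2$end - b2$start, 122L)
  # two nearby SNVs merge into one block
  b3 <- build_variant_blocks(
    tibble::tibble(contig = "c", pos = c(1000L, 1060L), ref = "A"), 100L
  )
  expect_equal(nrow(b3), 1L)
  expect_equal(c(b3$start, b3$end), c(950L, 1110L))
  # every variant lies inside exactly one merged block
  set.seed(4)
  vs <- tibble::tibble(
    contig = "c",
    pos = sort(sample(0:20000, 60)), ref = "A"
  )
  bl <- build_variant_blocks(vs, 100L, c(c = 20001L))
  hits <- vapply(vs$pos, function(p) {
    sum(bl$start <= p & bl$end > p)
  }, integer(1))
  expect_true(all(hits == 1L))
})

test_that("read scoring prefers the pseudo-polished matching haplotype", {
  set.seed(10)
  h1 <- random_dna(2000)
  h2 <- h1
  substr(h2, 1001, 1001) <- setdiff(c("A", "C", "G", "T"), substr(h1, 1001, 1001))[1]
  haps <- list(h1 = c(H1 = h1), h2 = c(H2 = h2))
  blocks <- list(
    h1 = intervals("H1", 950, 1050),
    h2 = intervals("H2", 950, 1050)
  )
  no_edits <- tibble::tibble(
    contig = character(), pos = integer(),
    ref = character(), alt = character()
  )
  read1 <- substr(h1, 501, 1500)
  alns <- list(
    h1 = aln_record("r", "H1", cigar = "1000=", target_start = 500L),
    h2 = aln_record("r", "H2", cigar = "1000=", target_start = 500L)
  )
  sc <- score_and_assign(read1, alns, blocks, haps,
    list(h1 = no_edits, h2 = no_edits),
    current_hap = 2L
  )
  expect_equal(sc$hap, 1L)
  expect_equal(sc$d1, 0)
  expect_equal(sc$d2, 1)
  # symmetric case
  read2 <- substr(h2, 501, 1500)
  sc2 <- score_and_assign(read2, alns, blocks, haps,
    list(h1 = no_edits, h2 = no_edits),
    current_hap = 1L
  )
  expect_equal(sc2$hap, 2L)
  # falsely homozygous assembly: both haps carry ref; the phased alt applied
  # to hap2 pulls alt-carrying reads to hap2
  haps_fh <- list(h1 = c(H1 = h1), h2 = c(H2 = h1))
  pe_h2 <- tibble::tibble(
    contig = "H2", pos = 1001L,
    ref = substr(h1, 1001, 1001),
    alt = substr(h2, 1001, 1001)
  )
  sc3 <- score_and_assign(read2, alns, blocks, haps_fh,
    list(h1 = no_edits, h2 = pe_h2),
    current_hap = 1L
  )
  expect_equal(sc3$hap, 2L)
  # tie (no discriminating site in blocks) keeps the current assignment
  sc4 <- score_and_assign(read1, alns, blocks, haps_fh,
    list(h1 = no_edits, h2 = no_edits),
    current_hap = 2L
  )
  expect_equal(sc4$hap, 2L)
  # a read overlapping no block passes through unchanged
  alns_far <- list(
    h1 = aln_record("r", "H1", cigar = "100=", target_start = 0L),
    h2 = aln_record("r", "H2", cigar = "100=", target_start = 0L)
  )
  sc5 <- score_and_assign(substr(h1, 1, 100), alns_far, blocks, haps,
    list(h1 = no_edits, h2 = no_edits),
    current_hap = 1L
  )
  expect_equal(sc5$n_blocks, 0L)
  expect_equal(sc5$hap, 1L)
})

test_that("constructed multi-block distances sum and pick the lower total", {
  # three blocks with known per-block distances (2,1),(0,0),(1,3):
  # totals (3,4) -> haplotype 1
  set.seed(11)
  base <- random_dna(3000)
  h1 <- base
  h2 <- base
  mut <- function(s, at, n) {
    # isolated substitutions 10 bp apart: edit distance equals their count
    for (p in at + 10L * (seq_len(n) - 1L)) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  }
  # block1 [500,600): read differs from h1 by 2, from h2 by 1
  # block2 [1500,1600): identical everywhere
  # block3 [2500,2600): read differs from h1 by 1, from h2 by 3
  read <- base
  h1 <- mut(h1, 520L, 2L)
  h2 <- mut(h2, 560L, 1L)
  h1 <- mut(h1, 2520L, 1L)
  h2 <- mut(h2, 2560L, 3L)
  haps <- list(h1 = c(H1 = h1), h2 = c(H2 = h2))
  blocks <- list(
    h1 = intervals("H1", c(500, 1500, 2500), c(600, 1600, 2600)),
    h2 = intervals("H2", c(500, 1500, 2500), c(600, 1600, 2600))
  )
  alns <- list(
    h1 = aln_record("r", "H1", cigar = "3000=", target_start = 0L),
    h2 = aln_record("r", "H2", cigar = "3000=", target_start = 0L)
  )
  no_edits <- tibble::tibble(
    contig = character(), pos = integer(),
    ref = character(), alt = character()
  )
  sc <- score_and_assign(read, alns, blocks, haps,
    list(h1 = no_edits, h2 = no_edits),
    current_hap = 2L
  )
  expect_equal(sc$d1, 3)
  expect_equal(sc$d2, 4)
  expect_equal(sc$hap, 1L)
  expect_equal(sc$n_blocks, 3L)
  # per-block distances equal the DP oracle
  expect_equal(
    dp_edit_distance(substr(read, 501, 600), substr(h1, 501, 600)), 2L
  )
  expect_equal(
    dp_edit_distance(substr(read, 2501, 2600), substr(h2, 2501, 2600)), 3L
  )
})
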