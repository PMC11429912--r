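# Phase-aware reassignment of HiFi reads in long homozygous assembly regions
# (the PHARAOH procedure with variant-mode edit-distance scoring).
#
# The driver is a common assembler failure: when a stretch where the two
# haplotypes are represented identically is longer than a HiFi read, the
# aligner cannot tell the haplotypes apart and assigns reads arbitrarily.
# Ultra-long reads, which span such stretches plus their flanking
# heterozygous sites, supply the phasing evidence to put each HiFi read back
# on its haplotype of origin before polishing.

#' Find long identical stretches between the two haplotypes
#'
#' Decomposes each haplotype-vs-haplotype alignment CIGAR into maximal runs
#' of `=` columns and reports every run strictly longer than `min_len` as a
#' homozygous region pair, on both haplotypes' coordinates.
#'
#' @param hap_vs_hap Alignment tibble (e.g. from [read_paf()]): query = one
#'   haplotype, target = the other, extended CIGARs required.
#' @param min_len Minimum identical run length in bases (default 20,000 --
#'   about the length of a HiFi read; runs of exactly `min_len` are excluded).
#' @return Tibble with one row per region pair: `contig_t`, `start_t`,
#'   `end_t` (target haplotype), `contig_q`, `start_q`, `end_q` (query
#'   haplotype, stored orientation), `length`.
#' @export
find_homozygous_regions <- function(hap_vs_hap, min_len = 20000L) {
  purrr::map_dfr(seq_len(nrow(hap_vs_hap)), function(i) {
    a <- hap_vs_hap[i, ]
    lay <- cigar_layout(a$cigar, a$target_start)
    if (any(lay$op %in% c("M", "N"))) {
      stop("CIGAR contains 'M'; identity is ambiguous (extended CIGAR required)")
    }
    runs <- lay[lay$op == "=" & lay$len > min_len, , drop = FALSE]
    if (nrow(runs) == 0L) return(NULL)
    tibble::tibble(
      contig_t = a$tname, start_t = runs$t0, end_t = runs$t1,
      contig_q = a$qname, start_q = runs$q0, end_q = runs$q1,
      length = runs$len
    )
  })
}

#' Genotype one biallelic site from ref/alt read counts
#'
#' Maximum-likelihood diploid genotype under a symmetric per-read error
#' model: a read reports the wrong allele with probability `error_rate`.
#' The genotype quality is the phred-scaled gap between the best and
#' second-best genotype log10-likelihoods, capped at 99.
#'
#' @param nref,nalt Read counts supporting the reference / alternate allele.
#' @param error_rate Per-read allele error probability.
#' @return List with `genotype` (`"ref"`, `"het"`, `"alt"`) and `gq`.
#' @export
genotype_site <- function(nref, nalt, error_rate = 0.01) {
  e <- error_rate
  ll <- c(
    ref = nref * log10(1 - e) + nalt * log10(e),
    het = (nref + nalt) * log10(0.5),
    alt = nref * log10(e) + nalt * log10(1 - e)
  )
  o <- order(ll, decreasing = TRUE)
  gq <- min(99, 10 * (ll[[o[[1]]]] - ll[[o[[2]]]]))
  list(genotype = names(ll)[[o[[1]]]], gq = gq)
}

# Per-record mismatch events: one row per X column with the read base.
.mismatch_events <- function(alns) {
  empty <- tibble::tibble(
    qname = character(), tname = character(),
    pos = integer(), base = character()
  )
  if (nrow(alns) == 0L) return(empty)
  out <- purrr::map_dfr(seq_len(nrow(alns)), function(i) {
    a <- alns[i, ]
    lay <- cigar_layout(a$cigar, a$target_start)
    xs <- lay[lay$op == "X", , drop = FALSE]
    if (nrow(xs) == 0L) return(NULL)
    pos <- unlist(purrr::map2(xs$t0, xs$t1 - 1L, seq))
    qoff <- unlist(purrr::map2(xs$q0, xs$q1 - 1L, seq))
    tibble::tibble(
      qname = a$qname, tname = a$tname, pos = as.integer(pos),
      base = substring(a$seq, qoff + 1L, qoff + 1L)
    )
  })
  if (nrow(out) == 0L) empty else out
}

# Aligned target span [t0, t1) of each record (vectorized over records).
.aln_spans <- function(alns) {
  m <- stringr::str_match_all(alns$cigar, "(\\d+)([MIDNSHP=X])")
  tlen <- vapply(m, function(x) {
    sum(as.integer(x[, 2])[x[, 3] %in% c("M", "=", "X", "D", "N")])
  }, numeric(1))
  tibble::tibble(
    qname = alns$qname, contig = alns$tname,
    start = alns$target_start,
    end = alns$target_start + as.integer(tlen)
  )
}

#' Call heterozygous SNV candidates from a pileup of alignments
#'
#' Collects per-column mismatch evidence from extended-CIGAR alignments,
#' genotypes every column with at least `min_alt` reads supporting one
#' alternate base ([genotype_site()]), and returns heterozygous calls with
#' GQ at or above `min_gq` (default 10, the phasing-stage filter). Reads
#' should already be filtered by gap-compressed mismatch ratio (<= 0.02).
#' Only SNVs are considered; indel heterozygosity is not called.
#'
#' @param alns Alignment tibble against one haplotype.
#' @param ref_seqs Named character vector of target sequences.
#' @param error_rate Per-read allele error probability.
#' @param min_gq Minimum genotype quality retained.
#' @param min_alt Minimum alternate-supporting reads to consider a column.
#' @return Tibble `contig`, `pos` (0-based), `ref`, `alt`, `gq`, `nref`,
#'   `nalt`.
#' @export
call_het_candidates <- function(alns, ref_seqs, error_rate = 0.01,
                                min_gq = 10, min_alt = 2L) {
  empty <- tibble::tibble(
    contig = character(), pos = integer(), ref = character(),
    alt = character(), gq = double(), nref = integer(), nalt = integer()
  )
  if (nrow(alns) == 0L) return(empty)
  ev <- .mismatch_events(alns)
  if (nrow(ev) == 0L) return(empty)
  ev <- dplyr::distinct(ev, .data$qname, .data$tname, .data$pos, .data$base)
  counts <- ev |>
    dplyr::count(.data$tname, .data$pos, .data$base, name = "n") |>
    dplyr::group_by(.data$tname, .data$pos) |>
    dplyr::summarise(
      alt = .data$base[which.max(.data$n)],
      nalt = max(.data$n), nmm = sum(.data$n), .groups = "drop"
    ) |>
    dplyr::filter(.data$nalt >= min_alt)
  if (nrow(counts) == 0L) return(empty)
  spans <- .aln_spans(alns)
  calls <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    ct <- counts$tname[[i]]
    p <- counts$pos[[i]]
    cov <- sum(spans$contig == ct & spans$start <= p & spans$end > p)
    nref <- max(0L, cov - counts$nmm[[i]])
    g <- genotype_site(nref, counts$nalt[[i]], error_rate)
    if (g$genotype != "het" || g$gq < min_gq) return(NULL)
    tibble::tibble(
      contig = ct, pos = p,
      ref = substr(ref_seqs[[ct]], p + 1L, p + 1L),
      alt = counts$alt[[i]], gq = g$gq,
      nref = as.integer(nref), nalt = counts$nalt[[i]]
    )
  })
  if (nrow(calls) == 0L) empty else dplyr::arrange(calls, .data$contig, .data$pos)
}

# Allele observed by each read at each candidate site ("ref"/"alt"/NA).
.read_alleles <- function(alns, sites) {
  ev <- .mismatch_events(alns)
  spans <- .aln_spans(alns)
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    cov <- spans[spans$contig == s$contig & spans$start <= s$pos &
      spans$end > s$pos, , drop = FALSE]
    if (nrow(cov) == 0L) return(NULL)
    mm <- ev[ev$tname == s$contig & ev$pos == s$pos, , drop = FALSE]
    allele <- ifelse(cov$qname %in% mm$qname[mm$base == s$alt], "alt",
      ifelse(cov$qname %in% mm$qname, NA, "ref")
    )
    tibble::tibble(
      read = cov$qname, site = i, allele = allele,
      contig = s$contig, pos = s$pos
    )
  })
}

#' Phase heterozygous candidates with ultra-long reads
#'
#' Joins variants co-covered by at least one qualifying ultra-long read into
#' phase blocks; the relative phase of each adjacent pair is decided by
#' majority vote of the co-covering reads (a read observing the same allele
#' class at both sites votes cis). Variants never co-covered become singleton
#' blocks. Within a block, haplotype A is anchored to the reference allele of
#' the block's first variant.
#'
#' @param candidates Het candidate tibble from [call_het_candidates()].
#' @param ul_alns Alignment tibble of ultra-long reads (same haplotype
#'   coordinates as `candidates`).
#' @param min_read_len Minimum ultra-long read length used as phasing
#'   evidence (default 100,000 bases).
#' @return `candidates` with `block_id`, `allele_hapA`, `allele_hapB` added.
#' @export
phase_hets <- function(candidates, ul_alns, min_read_len = 100000L) {
  out <- dplyr::arrange(candidates, .data$contig, .data$pos)
  n <- nrow(out)
  out$block_id <- integer(n)
  out$allele_hapA <- character(n)
  out$allele_hapB <- character(n)
  if (n == 0L) return(out)
  ul <- ul_alns[ul_alns$query_len >= min_read_len, , drop = FALSE]
  alleles <- if (nrow(ul)) .read_alleles(ul, out) else tibble::tibble(
    read = character(), site = integer(), allele = character()
  )
  block <- 0L
  phi <- 0L # 0: hapA carries ref at this site
  for (i in seq_len(n)) {
    new_block <- TRUE
    trans <- FALSE
    if (i > 1L && out$contig[[i]] == out$contig[[i - 1L]]) {
      ai <- alleles[alleles$site == i & !is.na(alleles$allele), , drop = FALSE]
      aj <- alleles[alleles$site == i - 1L & !is.na(alleles$allele), , drop = FALSE]
      j <- dplyr::inner_join(ai, aj, by = "read", suffix = c("_i", "_j"))
      if (nrow(j) > 0L) {
        cis <- sum(j$allele_i == j$allele_j)
        trans_votes <- nrow(j) - cis
        new_block <- FALSE
        trans <- trans_votes > cis
      }
    }
    if (new_block) {
      block <- block + 1L
      phi <- 0L
    } else if (trans) {
      phi <- 1L - phi
    }
    out$block_id[[i]] <- block
    out$allele_hapA[[i]] <- if (phi == 0L) "ref" else "alt"
    out$allele_hapB[[i]] <- if (phi == 0L) "alt" else "ref"
  }
  out
}

#' Select the assembly-like haplotype of each phase block
#'
#' For each block, picks the phase haplotype carrying more reference alleles
#' (i.e. the one more similar to the assembly sequence; ties go to haplotype
#' A) and retains the variants whose alternate allele lies on the selected
#' haplotype.
#'
#' @param phased Phased variant tibble from [phase_hets()].
#' @return List with `selection` (tibble `block_id`, `selected`) and
#'   `retained` (rows of `phased` whose alt allele is on the selected
#'   haplotype).
#' @export
select_block_haplotype <- function(phased) {
  stopifnot(nrow(phased) > 0L || is.data.frame(phased))
  selection <- phased |>
    dplyr::group_by(.data$block_id) |>
    dplyr::summarise(
      ref_a = sum(.data$allele_hapA == "ref"),
      ref_b = sum(.data$allele_hapB == "ref"),
      .groups = "drop"
    ) |>
    dplyr::mutate(selected = ifelse(.data$ref_b > .data$ref_a, "B", "A")) |>
    dplyr::select("block_id", "selected")
  retained <- phased |>
    dplyr::left_join(selection, by = "block_id") |>
    dplyr::filter(
      (.data$selected == "A" & .data$allele_hapA == "alt") |
        (.data$selected == "B" & .data$allele_hapB == "alt")
    )
  list(selection = selection, retained = retained)
}

#' Build merged variant blocks around selected variants
#'
#' Creates a window centered on each variant's reference span, of width
#' `max(min_block_size, 2 * span)`, clipped to the contig, then merges
#' overlapping windows -- so one block may encompass several variants.
#'
#' @param variants Tibble with `contig`, `pos` (0-based), `ref`.
#' @param min_block_size Minimum window width in bases (default 100).
#' @param contig_lengths Optional named lengths used for clipping.
#' @return Interval tibble of merged blocks.
#' @export
build_variant_blocks <- function(variants, min_block_size = 100L,
                                 contig_lengths = NULL) {
  if (nrow(variants) == 0L) return(intervals())
  span <- nchar(variants$ref)
  width <- pmax(min_block_size, 2L * span)
  start <- as.integer(floor(variants$pos + span / 2 - width / 2))
  end <- start + width
  start <- pmax(start, 0L)
  if (!is.null(contig_lengths)) {
    end <- pmin(end, contig_lengths[variants$contig])
  }
  merge_intervals(intervals(variants$contig, start, end))
}

#' Score a read against both pseudo-polished haplotypes and assign it
#'
#' Implements variant-block edit-distance scoring: the variant blocks of each
#' haplotype are projected onto the read through that haplotype's alignment;
#' the projected blocks are merged on read coordinates; each merged read
#' block is projected back to both haplotypes, whose sequences are
#' "pseudo-polished" by substituting the phased alleles assigned to that
#' haplotype; the Levenshtein edit distance between the read block and each
#' haplotype block is summed over all merged blocks, and the haplotype with
#' the lower total wins (ties keep the current assignment).
#'
#' @param read_seq Read sequence (stored orientation of its alignments).
#' @param alns List of two alignment records (`h1`, `h2`), the read's
#'   alignment to each haplotype.
#' @param blocks List of two interval tibbles (`h1`, `h2`), variant blocks on
#'   each haplotype's coordinates.
#' @param hap_seqs List of two named character vectors (`h1`, `h2`).
#' @param pseudo_edits List of two edit tibbles (`h1`, `h2`; columns
#'   `contig`, `pos` 1-based, `ref`, `alt`) applied to the respective
#'   haplotype within blocks; positions are trusted (no REF check) since the
#'   non-called haplotype may already carry the allele.
#' @param current_hap Current assignment (1 or 2), kept on ties.
#' @return List `hap`, `d1`, `d2`, `n_blocks`; `hap` equals `current_hap`
#'   with `n_blocks = 0` when the read overlaps no block.
#' @export
score_and_assign <- function(read_seq, alns, blocks, hap_seqs, pseudo_edits,
                             current_hap = 1L) {
  alns <- list(h1 = .as_aln(alns$h1), h2 = .as_aln(alns$h2))
  proj <- purrr::map2_dfr(alns, blocks, function(a, b) {
    bb <- b[b$contig == a$tname, , drop = FALSE]
    if (nrow(bb) == 0L) return(NULL)
    project_intervals(bb, a, "t2q")
  })
  if (nrow(proj) == 0L) {
    return(list(
      hap = current_hap, d1 = NA_real_, d2 = NA_real_,
      n_blocks = 0L
    ))
  }
  proj$contig <- "read"
  rb <- merge_intervals(proj)
  rb <- rb[rb$start < nchar(read_seq) & rb$end <= nchar(read_seq), , drop = FALSE]
  d <- c(0, 0)
  for (i in seq_len(nrow(rb))) {
    rseq <- substr(read_seq, rb$start[[i]] + 1L, rb$end[[i]])
    for (h in 1:2) {
      a <- alns[[h]]
      back <- project_intervals(
        intervals("read", rb$start[[i]], rb$end[[i]]), a, "q2t"
      )
      if (nrow(back) == 0L) {
        d[[h]] <- d[[h]] + nchar(rseq)
        next
      }
      hseq <- substr(
        hap_seqs[[h]][[a$tname]], back$start[[1]] + 1L,
        back$end[[1]]
      )
      pe <- pseudo_edits[[h]]
      pe <- pe[pe$contig == a$tname & pe$pos > back$start[[1]] &
        pe$pos + nchar(pe$ref) - 1L <= back$end[[1]], , drop = FALSE]
      if (nrow(pe) > 0L) {
        pe$pos <- pe$pos - back$start[[1]]
        hseq <- .apply_edit_table(hseq, pe, check_ref = FALSE)$seq
      }
      d[[h]] <- d[[h]] + utils::adist(rseq, hseq)[1, 1]
    }
  }
  hap <- if (d[[1]] < d[[2]]) 1L else if (d[[2]] < d[[1]]) 2L else as.integer(current_hap)
  list(hap = hap, d1 = d[[1]], d2 = d[[2]], n_blocks = nrow(rb))
}

#' Final strict alignment filter
#'
#' Removes alignment records with gap-compressed mismatch ratio above
#' `max_ratio` (default 0.002), the last step before polishing.
#'
#' @param alns Alignment tibble.
#' @param max_ratio Maximum allowed ratio.
#' @return Filtered tibble.
#' @export
final_alignment_filter <- function(alns, max_ratio = 0.002) {
  filter_by_mismatch_ratio(alns, max_ratio)
}

#' Reassign reads in long homozygous regions (PHARAOH)
#'
#' End-to-end phasing stage: find homozygous region pairs from the
#' haplotype-vs-haplotype alignment, take the HiFi reads overlapping them
#' (filtered at mismatch ratio `pre_ratio`), call het SNV candidates on the
#' target haplotype, phase them with ultra-long reads, build merged variant
#' blocks (projected to the other haplotype), pseudo-polish each haplotype
#' with its phased alleles, and re-score every region read against both
#' haplotypes by block edit distance.
#'
#' @param assembly `diploid_assembly` (hap1/hap2 named character vectors).
#' @param hifi_h1,hifi_h2 HiFi alignment tibbles to each haplotype.
#' @param ul_h1 Ultra-long alignment tibble to haplotype 1 (the calling
#'   haplotype).
#' @param hap_vs_hap Alignment tibble of haplotype 2 against haplotype 1.
#' @param assignments Tibble `read_id`, `hap` with each read's current
#'   haplotype assignment (e.g. from the diploid primary alignment).
#' @param min_homo_len Minimum identical-run length (default 20,000).
#' @param min_block Minimum variant block size (default 100).
#' @param het_gq Minimum het genotype quality (default 10).
#' @param pre_ratio Mismatch-ratio filter before variant calling (0.02).
#' @param error_rate Genotyping error model parameter.
#' @param ul_min_len Minimum ultra-long read length (100,000).
#' @return List of class `pharaoh_result`: `assignments` (with `hap_pharaoh`,
#'   `d1`, `d2`, `scored`), `regions`, `hets`, `blocks`.
#' @export
pharaoh <- function(assembly, hifi_h1, hifi_h2, ul_h1, hap_vs_hap,
                    assignments, min_homo_len = 20000L, min_block = 100L,
                    het_gq = 10, pre_ratio = 0.02, error_rate = 0.01,
                    ul_min_len = 100000L) {
  regions <- find_homozygous_regions(hap_vs_hap, min_homo_len)
  res <- assignments
  res$hap_pharaoh <- res$hap
  res$d1 <- NA_real_
  res$d2 <- NA_real_
  res$scored <- FALSE
  empty_out <- function() {
    structure(
      list(
        assignments = res, regions = regions,
        hets = tibble::tibble(), blocks = list(
          h1 = intervals(),
          h2 = intervals()
        )
      ),
      class = "pharaoh_result"
    )
  }
  if (nrow(regions) == 0L) return(empty_out())

  # reads overlapping a homozygous region on either haplotype
  reg_t <- intervals(regions$contig_t, regions$start_t, regions$end_t)
  reg_q <- intervals(regions$contig_q, regions$start_q, regions$end_q)
  sp1 <- .aln_spans(hifi_h1)
  sp2 <- .aln_spans(hifi_h2)
  ids <- union(
    sp1$qname[overlaps_any(sp1, reg_t)],
    sp2$qname[overlaps_any(sp2, reg_q)]
  )
  ids <- intersect(
    ids,
    intersect(hifi_h1$qname, hifi_h2$qname)
  )
  if (length(ids) == 0L) return(empty_out())
  a1 <- filter_by_mismatch_ratio(
    hifi_h1[hifi_h1$qname %in% ids, ], pre_ratio
  )
  a2 <- hifi_h2[hifi_h2$qname %in% ids, ]

  hets <- call_het_candidates(a1, assembly$hap1,
    error_rate = error_rate,
    min_gq = het_gq
  )
  phased <- phase_hets(hets, ul_h1, min_read_len = ul_min_len)
  if (nrow(phased) == 0L) {
    return(empty_out())
  }
  sel <- select_block_haplotype(phased)

  # pseudo-edits: selected haplotype's alts on hap1; complement on hap2
  sel_join <- dplyr::left_join(phased, sel$selection, by = "block_id")
  on_h1 <- sel_join[
    (sel_join$selected == "A" & sel_join$allele_hapA == "alt") |
      (sel_join$selected == "B" & sel_join$allele_hapB == "alt"), ,
    drop = FALSE
  ]
  on_h2 <- dplyr::anti_join(sel_join, on_h1, by = c("contig", "pos"))
  pe_h1 <- tibble::tibble(
    contig = on_h1$contig, pos = on_h1$pos + 1L,
    ref = on_h1$ref, alt = on_h1$alt
  )
  # project complement sites to hap2 coordinates (SNVs: width-1 images)
  pe_h2 <- purrr::map_dfr(seq_len(nrow(on_h2)), function(i) {
    hit <- NULL
    for (j in seq_len(nrow(hap_vs_hap))) {
      if (hap_vs_hap$tname[[j]] != on_h2$contig[[i]]) next
      p <- project_position(on_h2$pos[[i]], hap_vs_hap[j, ], "t2q")
      if (!is.na(p)) {
        hit <- tibble::tibble(
          contig = hap_vs_hap$qname[[j]], pos = p + 1L,
          ref = on_h2$ref[[i]], alt = on_h2$alt[[i]]
        )
        break
      }
    }
    hit
  })

  blocks_h1 <- build_variant_blocks(phased, min_block,
    contig_lengths = nchar(assembly$hap1)
  )
  blocks_h2 <- purrr::map_dfr(seq_len(nrow(hap_vs_hap)), function(j) {
    b <- blocks_h1[blocks_h1$contig == hap_vs_hap$tname[[j]], , drop = FALSE]
    if (nrow(b) == 0L) return(NULL)
    project_intervals(b, hap_vs_hap[j, ], "t2q")[, c("contig", "start", "end")]
  })
  if (nrow(blocks_h2)) blocks_h2 <- merge_intervals(blocks_h2)
  blocks <- list(h1 = blocks_h1, h2 = blocks_h2)
  pseudo <- list(h1 = pe_h1, h2 = pe_h2)
  hap_seqs <- list(h1 = assembly$hap1, h2 = assembly$hap2)

  scorable <- intersect(a1$qname, a2$qname)
  for (rid in scorable) {
    r1 <- a1[a1$qname == rid, ][1, ]
    r2 <- a2[a2$qname == rid, ][1, ]
    cur <- res$hap[match(rid, res$read_id)]
    if (is.na(cur)) cur <- 1L
    sc <- score_and_assign(
      r1$seq,
      alns = list(h1 = r1, h2 = r2),
      blocks = blocks, hap_seqs = hap_seqs, pseudo_edits = pseudo,
      current_hap = cur
    )
    k <- match(rid, res$read_id)
    if (!is.na(k) && sc$n_blocks > 0L) {
      res$hap_pharaoh[[k]] <- sc$hap
      res$d1[[k]] <- sc$d1
      res$d2[[k]] <- sc$d2
      res$scored[[k]] <- TRUE
    }
  }
  structure(
    list(
      assignments = res, regions = regions, hets = phased,
      blocks = blocks
    ),
    class = "pharaoh_result"
  )
}

#' @export
print.pharaoh_result <- function(x, ...) {
  cat("<pharaoh_result>\n")
  cat("  homozygous region pairs:", nrow(x$regions), "\n")
  cat("  phased het candidates:  ", nrow(x$hets), "\n")
  cat("  reads scored:           ", sum(x$assignments$scored), "\n")
  cat(
    "  reads reassigned:       ",
    sum(x$assignments$scored &
      x$assignments$hap != x$assignments$hap_pharaoh), "\n"
  )
  invisible(x)
}
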