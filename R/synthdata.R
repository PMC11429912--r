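# Seeded synthetic diploid genomes, corrupted drafts with truth edit sets,
# and simulated HiFi-like / ultra-long read sets with truth alignments.
# The generator emulates the statistical structure the polishing pipeline
# assumes: scattered heterozygosity, long runs with no het variants (loss of
# heterozygosity longer than a HiFi read), and homopolymer-biased indel
# sequencing error.

.BASES <- c("A", "C", "G", "T")

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(.BASES, x), 1L), character(1),
    USE.NAMES = FALSE
  )
}

#' Read-simulation profile
#'
#' Bundles the length distribution, per-base error rates and depth used by
#' [simulate_reads()]. [hifi_profile()] and [ul_profile()] provide the two
#' technology presets the pipeline is designed around: HiFi-like reads
#' (mean 18 kb, capped below 25 kb, low error) and ultra-long reads
#' (>= 100 kb, used only as phasing evidence).
#'
#' @param read_length_mean,read_length_sd,min_length,max_length Read length
#'   model in bases (normal, truncated to `[min_length, max_length]`).
#' @param substitution_rate,indel_rate Per-base error probabilities (each in
#'   `[0, 0.2]`).
#' @param homopolymer_indel_multiplier Multiplier (>= 1) applied to
#'   `indel_rate` inside homopolymer runs of length >= 5.
#' @param depth Fold coverage per haplotype.
#' @param baseq Constant phred base quality assigned to read bases.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list with class `sim_profile`.
#' @export
sim_profile <- function(read_length_mean, read_length_sd, min_length,
                        max_length = Inf, substitution_rate = 0,
                        indel_rate = 0, homopolymer_indel_multiplier = 1,
                        depth = 30, baseq = 30L, seed = 1L) {
  stopifnot(
    substitution_rate >= 0, substitution_rate <= 0.2,
    indel_rate >= 0, indel_rate <= 0.2,
    homopolymer_indel_multiplier >= 1,
    depth > 0, min_length > 0, read_length_mean >= min_length
  )
  structure(
    list(
      read_length_mean = read_length_mean, read_length_sd = read_length_sd,
      min_length = min_length, max_length = max_length,
      substitution_rate = substitution_rate, indel_rate = indel_rate,
      homopolymer_indel_multiplier = homopolymer_indel_multiplier,
      depth = depth, baseq = as.integer(baseq), seed = as.integer(seed)
    ),
    class = "sim_profile"
  )
}

#' @param ... Overrides passed to [sim_profile()].
#' @rdname sim_profile
#' @export
hifi_profile <- function(...) {
  args <- utils::modifyList(
    list(
      read_length_mean = 18000, read_length_sd = 2500, min_length = 1000,
      max_length = 24999, substitution_rate = 1e-3, indel_rate = 2e-4,
      homopolymer_indel_multiplier = 8, depth = 40, baseq = 30L, seed = 1L
    ),
    list(...)
  )
  do.call(sim_profile, args)
}

#' @rdname sim_profile
#' @export
ul_profile <- function(...) {
  args <- utils::modifyList(
    list(
      read_length_mean = 150000, read_length_sd = 40000, min_length = 100000,
      max_length = 400000, substitution_rate = 0.02, indel_rate = 0.005,
      homopolymer_indel_multiplier = 4, depth = 12, baseq = 12L, seed = 1L
    ),
    list(...)
  )
  do.call(sim_profile, args)
}

#' Generate a seeded synthetic diploid genome with a truth set
#'
#' Builds a shared base sequence per contig, scatters heterozygous SNVs and
#' small (1-3 bp) indels outside designated loss-of-heterozygosity (LOH)
#' intervals, and derives the two haplotype sequences by assigning each
#' variant's alternate allele to one haplotype at random. LOH intervals are
#' het-free by construction, so the two haplotypes are 100% identical across
#' them -- the falsely-homozygous-looking situation the phasing stage exists
#' for when such runs exceed the HiFi read length.
#'
#' @param seed Integer seed.
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bases.
#' @param het_snv_rate,het_indel_rate Per-base heterozygous variant rates.
#' @param loh_count Number of LOH intervals per contig.
#' @param loh_length Length of each LOH interval (>= 20 kb by default, i.e.
#'   longer than a HiFi read).
#' @param homopolymer_count Optional number of embedded homopolymer runs per
#'   contig (for error-context analyses).
#' @param homopolymer_length Length of each embedded run.
#' @return A list with class `synthetic_diploid`: `assembly` (a
#'   `diploid_assembly`: list of two named character vectors, haplotype 1 and
#'   2) and `truth` (het variant table with per-haplotype coordinates, LOH
#'   interval table, and the base genome).
#' @export
generate_diploid <- function(seed, n_contigs = 1L, contig_length = 1e5,
                             het_snv_rate = 1e-3, het_indel_rate = 1e-4,
                             loh_count = 0L, loh_length = 25000L,
                             homopolymer_count = 0L, homopolymer_length = 12L) {
  stopifnot(het_snv_rate >= 0, het_indel_rate >= 0, loh_count >= 0)
  contig_length <- as.integer(contig_length)
  loh_length <- as.integer(loh_length)
  margin <- 2000L
  if (loh_count > 0 &&
    contig_length < loh_count * (loh_length + 2L * margin)) {
    stop(
      "contig_length too small to place ", loh_count, " LOH intervals of ",
      loh_length, " bp"
    )
  }
  withr::with_seed(seed, {
    haps <- list(hap1 = character(), hap2 = character())
    hets <- list()
    lohs <- list()
    base_genome <- character()
    for (ci in seq_len(n_contigs)) {
      ct <- paste0("ctg", ci)
      base <- .rand_seq(contig_length)
      if (homopolymer_count > 0L) {
        hp_at <- sort(sample.int(
          contig_length - homopolymer_length - 2L,
          homopolymer_count
        ))
        hp_at <- hp_at[c(TRUE, diff(hp_at) > homopolymer_length + 10L)]
        for (p in hp_at) {
          run <- strrep(sample(.BASES, 1L), homopolymer_length)
          substr(base, p, p + homopolymer_length - 1L) <- run
        }
      }
      # one LOH interval per equal-sized segment: non-overlapping by design
      loh <- intervals()
      if (loh_count > 0L) {
        seg <- contig_length %/% loh_count
        starts <- vapply(seq_len(loh_count), function(i) {
          lo <- (i - 1L) * seg + margin
          hi <- i * seg - loh_length - margin
          as.integer(lo + floor(stats::runif(1) * (hi - lo + 1L)))
        }, integer(1))
        loh <- intervals(ct, starts, starts + loh_length)
      }
      in_loh <- rep(FALSE, contig_length)
      for (i in seq_len(nrow(loh))) {
        in_loh[(loh$start[[i]] + 1L):loh$end[[i]]] <- TRUE
      }
      # het variant sites (1-based, on base-genome coordinates)
      p_snv <- which(stats::runif(contig_length) < het_snv_rate & !in_loh)
      p_ind <- which(stats::runif(contig_length) < het_indel_rate & !in_loh)
      p_ind <- setdiff(p_ind, c(p_snv, p_snv + 1L, p_snv - 1L))
      sites <- sort(c(p_snv, p_ind))
      sites <- sites[sites > 1L & sites < contig_length - 4L]
      if (length(sites) > 1L) sites <- sites[c(TRUE, diff(sites) > 6L)]
      is_snv <- sites %in% p_snv
      vars <- purrr::map2_dfr(sites, is_snv, function(p, snv) {
        refb <- substr(base, p, p)
        if (snv) {
          tibble::tibble(pos = p, ref = refb, alt = .other_base(refb))
        } else if (stats::runif(1) < 0.5) { # insertion on the alt haplotype
          ins <- .rand_seq(sample(1:3, 1L))
          tibble::tibble(pos = p, ref = refb, alt = paste0(refb, ins))
        } else { # deletion on the alt haplotype
          dlen <- sample(1:3, 1L)
          tibble::tibble(
            pos = p, ref = substr(base, p, p + dlen),
            alt = refb
          )
        }
      })
      if (nrow(vars) == 0L) {
        vars <- tibble::tibble(
          pos = integer(), ref = character(),
          alt = character()
        )
      }
      vars$contig <- ct
      vars$alt_hap <- if (nrow(vars)) sample(1:2, nrow(vars), TRUE) else integer()
      a1 <- .apply_edit_table(base, vars[vars$alt_hap == 1L, , drop = FALSE])
      a2 <- .apply_edit_table(base, vars[vars$alt_hap == 2L, , drop = FALSE])
      # per-haplotype coordinates of every base-genome position we care about
      vars$pos_h1 <- .shift_positions(vars$pos, vars[vars$alt_hap == 1L, ])
      vars$pos_h2 <- .shift_positions(vars$pos, vars[vars$alt_hap == 2L, ])
      if (nrow(loh)) {
        loh$start_h1 <- .shift_positions(loh$start + 1L, vars[vars$alt_hap == 1L, ]) - 1L
        loh$end_h1 <- loh$start_h1 + loh_length
        loh$start_h2 <- .shift_positions(loh$start + 1L, vars[vars$alt_hap == 2L, ]) - 1L
        loh$end_h2 <- loh$start_h2 + loh_length
      }
      haps$hap1[paste0(ct, "_h1")] <- a1$seq
      haps$hap2[paste0(ct, "_h2")] <- a2$seq
      hets[[ci]] <- vars
      lohs[[ci]] <- loh
      base_genome[ct] <- base
    }
    assembly <- structure(haps, class = "diploid_assembly")
    truth <- list(
      het_variants = dplyr::bind_rows(hets)[, c(
        "contig", "pos", "ref", "alt", "alt_hap", "pos_h1", "pos_h2"
      )],
      loh_intervals = dplyr::bind_rows(lohs),
      base_genome = base_genome
    )
    structure(list(assembly = assembly, truth = truth),
      class = "synthetic_diploid"
    )
  })
}

# Apply a sorted, non-overlapping VCF-style edit table (1-based pos) to one
# sequence. Returns the edited sequence and the post-edit position of each
# input edit. Shared by haplotype construction, draft corruption and the
# public apply_edits().
.apply_edit_table <- function(seq, edits, check_ref = TRUE) {
  if (nrow(edits) == 0L) {
    return(list(seq = seq, new_pos = integer()))
  }
  o <- order(edits$pos)
  edits <- edits[o, , drop = FALSE]
  rl <- nchar(edits$ref)
  if (any(diff(edits$pos) < rl[-length(rl)])) {
    stop("overlapping edit REF spans; resolve overlaps first")
  }
  if (check_ref) {
    have <- substring(seq, edits$pos, edits$pos + rl - 1L)
    bad <- which(have != edits$ref)
    if (length(bad)) {
      stop(
        "edit REF disagrees with sequence at pos ", edits$pos[bad[[1]]],
        " (expected '", edits$ref[bad[[1]]], "', found '", have[bad[[1]]], "')"
      )
    }
  }
  n <- nrow(edits)
  gaps_start <- c(1L, edits$pos + rl)
  gaps_end <- c(edits$pos - 1L, nchar(seq))
  pieces <- character(2L * n + 1L)
  pieces[seq(1L, 2L * n + 1L, by = 2L)] <- substring(seq, gaps_start, gaps_end)
  pieces[seq(2L, 2L * n, by = 2L)] <- edits$alt
  offs <- cumsum(nchar(edits$alt) - rl)
  new_pos <- edits$pos + c(0L, offs[-n])
  new_pos_in_input_order <- integer(n)
  new_pos_in_input_order[o] <- new_pos
  list(
    seq = paste(pieces, collapse = ""),
    new_pos = new_pos_in_input_order
  )
}

# Map 1-based positions on the pre-edit sequence to post-edit coordinates,
# given the edit table that was applied.
.shift_positions <- function(pos, edits) {
  if (nrow(edits) == 0L || length(pos) == 0L) {
    return(as.integer(pos))
  }
  edits <- edits[order(edits$pos), , drop = FALSE]
  delta <- nchar(edits$alt) - nchar(edits$ref)
  shift <- c(0L, cumsum(delta))
  # an edit at pos p affects coordinates strictly after its REF span
  idx <- findInterval(pos, edits$pos + nchar(edits$ref) - 1L,
    left.open = TRUE
  ) + 1L
  as.integer(pos + shift[idx])
}

#' Corrupt a diploid genome into a draft assembly with a truth edit set
#'
#' Injects base-level errors (SNVs and 1 bp indels) independently into each
#' haplotype and records, for every injected error, the VCF-style edit that
#' repairs it. Applying all truth edits to the draft reproduces the input
#' genome exactly.
#'
#' @param genome A `diploid_assembly` (or `synthetic_diploid`).
#' @param error_snv_rate,error_indel_rate Per-base injection rates.
#' @param seed Integer seed.
#' @return List with `draft` (`diploid_assembly`) and `truth_edits`: tibble
#'   with `hap`, `contig` (haplotype contig name), `pos` (1-based draft
#'   coordinates), `ref`, `alt`, `class` (`INS1`/`DEL1`/`OTHER`), left
#'   normalized against the draft.
#' @export
corrupt_assembly <- function(genome, error_snv_rate = 2e-5,
                             error_indel_rate = 1e-5, seed = 1L) {
  stopifnot(error_snv_rate >= 0, error_indel_rate >= 0)
  if (inherits(genome, "synthetic_diploid")) genome <- genome$assembly
  withr::with_seed(seed, {
    draft <- genome
    all_edits <- list()
    for (h in 1:2) {
      hk <- paste0("hap", h)
      for (ct in names(genome[[hk]])) {
        seq <- genome[[hk]][[ct]]
        L <- nchar(seq)
        p_snv <- which(stats::runif(L) < error_snv_rate)
        p_ind <- which(stats::runif(L) < error_indel_rate)
        p_ind <- setdiff(p_ind, p_snv)
        sites <- sort(c(p_snv, p_ind))
        sites <- sites[sites > 20L & sites < L - 20L]
        if (length(sites) > 1L) sites <- sites[c(TRUE, diff(sites) > 20L)]
        if (length(sites) == 0L) next
        is_snv <- sites %in% p_snv
        corr <- purrr::map2_dfr(sites, is_snv, function(p, snv) {
          refb <- substr(seq, p, p)
          if (snv) {
            tibble::tibble(pos = p, ref = refb, alt = .other_base(refb))
          } else if (stats::runif(1) < 0.5) { # draft gains a base
            tibble::tibble(
              pos = p, ref = refb,
              alt = paste0(refb, sample(.BASES, 1L))
            )
          } else { # draft loses a base
            tibble::tibble(pos = p, ref = substr(seq, p, p + 1L), alt = refb)
          }
        })
        ap <- .apply_edit_table(seq, corr)
        draft[[hk]][[ct]] <- ap$seq
        repair <- tibble::tibble(
          hap = h, contig = ct, pos = ap$new_pos,
          ref = corr$alt, alt = corr$ref
        )
        repair <- .normalize_edit_table(ap$seq, repair)
        all_edits[[paste(hk, ct)]] <- repair
      }
    }
    truth_edits <- dplyr::bind_rows(all_edits)
    if (nrow(truth_edits) == 0L) {
      truth_edits <- tibble::tibble(
        hap = integer(), contig = character(), pos = integer(),
        ref = character(), alt = character()
      )
    }
    truth_edits <- dplyr::arrange(truth_edits, .data$hap, .data$contig, .data$pos)
    truth_edits$class <- classify_edit(truth_edits)
    list(draft = draft, truth_edits = truth_edits)
  })
}

# Left-normalize VCF-style records against `seq` (shift anchored indels left
# through repeat copies; trim shared trailing/leading bases).
.normalize_edit_table <- function(seq, edits) {
  if (nrow(edits) == 0L) return(edits)
  for (i in seq_len(nrow(edits))) {
    v <- normalize_edit(seq, edits$pos[[i]], edits$ref[[i]], edits$alt[[i]])
    edits$pos[[i]] <- v$pos
    edits$ref[[i]] <- v$ref
    edits$alt[[i]] <- v$alt
  }
  edits
}

#' Left-normalize a single VCF-style record
#'
#' Standard variant normalization against the reference sequence the record
#' applies to: shared trailing bases are trimmed (prepending the preceding
#' reference base when an allele would empty), then shared leading bases
#' beyond the anchor are trimmed. Indels in repeat tracts therefore shift to
#' their leftmost representation, which keeps simulator truth edits and
#' polisher output comparable record-by-record.
#'
#' @param seq Reference sequence (the sequence `ref` is read from).
#' @param pos 1-based position.
#' @param ref,alt Alleles.
#' @return List with normalized `pos`, `ref`, `alt`.
#' @export
normalize_edit <- function(seq, pos, ref, alt) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
      substr(ref, nr, nr) == substr(alt, na, na) &&
      !(nr == 1L && na == 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos <= 1L) { # cannot extend left; re-anchor on the right instead
          nxt <- substr(seq, pos + nchar(ref), pos + nchar(ref))
          ref <- paste0(ref, nxt); alt <- paste0(alt, nxt)
          break
        }
        pos <- pos - 1L
        b <- substr(seq, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
    substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Homopolymer runs of at least `min_len` bases
#'
#' @param seq A sequence string.
#' @param min_len Minimum run length.
#' @param contig Contig name for the output intervals.
#' @return Interval tibble (0-based half-open) with a `base` column.
#' @export
homopolymer_runs <- function(seq, min_len = 5L, contig = "seq") {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len
  tibble::tibble(
    contig = contig,
    start = as.integer(ends[keep] - r$lengths[keep]),
    end = as.integer(ends[keep]),
    base = r$values[keep]
  )
}

#' Simulate long reads with truth alignments
#'
#' Draws read start positions uniformly along each haplotype contig (reads
#' truncated at contig ends, no circularity), lengths from a truncated normal,
#' and injects substitution and 1 bp indel errors per base, with the indel
#' rate multiplied inside homopolymer runs of >= 5 bases. Each read's true
#' alignment to its haplotype of origin is emitted with an extended
#' `=`/`X`/`I`/`D` CIGAR describing exactly the simulated errors.
#'
#' @param genome A `diploid_assembly` (or `synthetic_diploid`).
#' @param profile A [sim_profile()].
#' @return List with `reads` (tibble `read_id`, `seq`, `qual`),
#'   `truth_alignments` (alignment tibble vs the haplotype of origin, MAPQ
#'   60), and `origins` (tibble `read_id`, `hap`, `contig`, `start` 0-based).
#' @export
simulate_reads <- function(genome, profile) {
  stopifnot(inherits(profile, "sim_profile"))
  if (inherits(genome, "synthetic_diploid")) genome <- genome$assembly
  withr::with_seed(profile$seed, {
    reads <- list()
    alns <- list()
    origins <- list()
    idx <- 0L
    for (h in 1:2) {
      hk <- paste0("hap", h)
      for (ct in names(genome[[hk]])) {
        seq <- genome[[hk]][[ct]]
        L <- nchar(seq)
        if (L < profile$min_length) {
          warning("contig ", ct, " shorter than min_length; no reads simulated")
          next
        }
        hp <- homopolymer_runs(seq, 5L, ct)
        hp_mask <- rep(FALSE, L)
        for (i in seq_len(nrow(hp))) {
          hp_mask[(hp$start[[i]] + 1L):hp$end[[i]]] <- TRUE
        }
        n_reads <- max(1L, round(profile$depth * L / profile$read_length_mean))
        starts <- floor(stats::runif(n_reads) * L)
        lens <- round(stats::rnorm(
          n_reads, profile$read_length_mean,
          profile$read_length_sd
        ))
        lens <- pmin(pmax(lens, profile$min_length), profile$max_length)
        lens <- pmin(lens, L - starts)
        for (i in seq_len(n_reads)) {
          if (lens[[i]] < min(profile$min_length, 200L)) next
          idx <- idx + 1L
          rid <- sprintf("r%06d", idx)
          sim <- .simulate_one_read(
            seq, starts[[i]], lens[[i]], profile, hp_mask
          )
          qual <- strrep(rawToChar(as.raw(profile$baseq + 33L)), nchar(sim$seq))
          reads[[idx]] <- tibble::tibble(
            read_id = rid, seq = sim$seq, qual = qual
          )
          alns[[idx]] <- tibble::tibble(
            qname = rid, flag = 0L, tname = ct,
            target_start = as.integer(starts[[i]]), mapq = 60L,
            cigar = sim$cigar, seq = sim$seq, qual = qual,
            strand = "+", hp = h, query_len = nchar(sim$seq)
          )
          origins[[idx]] <- tibble::tibble(
            read_id = rid, hap = h, contig = sub("_h[12]$", "", ct),
            start = as.integer(starts[[i]])
          )
        }
      }
    }
    out <- list(
      reads = dplyr::bind_rows(reads),
      truth_alignments = dplyr::bind_rows(alns),
      origins = dplyr::bind_rows(origins)
    )
    if (nrow(out$reads) == 0L) {
      out$reads <- tibble::tibble(
        read_id = character(), seq = character(), qual = character()
      )
      out$truth_alignments <- .empty_aln_tbl()
      out$origins <- tibble::tibble(
        read_id = character(), hap = integer(),
        contig = character(), start = integer()
      )
    }
    out
  })
}

# Simulate sequencing errors over one template span; returns read sequence
# and the extended CIGAR of the read against the template.
.simulate_one_read <- function(seq, start0, len, profile, hp_mask) {
  tmpl <- substr(seq, start0 + 1L, start0 + len)
  ind_rate <- profile$indel_rate *
    ifelse(hp_mask[(start0 + 1L):(start0 + len)],
      profile$homopolymer_indel_multiplier, 1
    )
  p_sub <- which(stats::runif(len) < profile$substitution_rate)
  p_ind <- which(stats::runif(len) < ind_rate)
  p_ind <- setdiff(p_ind, p_sub)
  pos <- c(p_sub, p_ind)
  type <- c(
    rep("S", length(p_sub)),
    ifelse(stats::runif(length(p_ind)) < 0.5, "I", "D")
  )
  if (length(pos) == 0L) {
    return(list(seq = tmpl, cigar = paste0(len, "=")))
  }
  o <- order(pos)
  pos <- pos[o]
  type <- type[o]
  n <- length(pos)
  # template piece before each event; insertions sit after template base pos
  gap_start <- c(1L, pos + 1L)[seq_len(n)]
  gap_end <- ifelse(type == "I", pos, pos - 1L)
  gaps <- substring(tmpl, gap_start, gap_end)
  ev_piece <- character(n)
  ev_piece[type == "S"] <- .other_base(substring(tmpl, pos, pos)[type == "S"])
  ev_piece[type == "I"] <- sample(.BASES, sum(type == "I"), replace = TRUE)
  tail_piece <- substring(tmpl, pos[n] + 1L, len)
  read_seq <- paste0(
    paste0(gaps, ev_piece, collapse = ""), tail_piece
  )
  op <- character(2L * n + 1L)
  oplen <- integer(2L * n + 1L)
  op[seq(1L, 2L * n, by = 2L)] <- "="
  oplen[seq(1L, 2L * n, by = 2L)] <- nchar(gaps)
  op[seq(2L, 2L * n, by = 2L)] <- c(S = "X", I = "I", D = "D")[type]
  oplen[seq(2L, 2L * n, by = 2L)] <- 1L
  op[2L * n + 1L] <- "="
  oplen[2L * n + 1L] <- nchar(tail_piece)
  list(
    seq = read_seq,
    cigar = cigar_string(tibble::tibble(op = op, len = oplen))
  )
}

#' @export
print.diploid_assembly <- function(x, ...) {
  cat("<diploid_assembly>\n")
  for (h in names(x)) {
    cat(
      " ", h, ":", length(x[[h]]), "contig(s),",
      sum(nchar(x[[h]])), "bp\n"
    )
  }
  invisible(x)
}

#' @export
print.synthetic_diploid <- function(x, ...) {
  print(x$assembly)
  cat(
    "  het variants:", nrow(x$truth$het_variants),
    "| LOH intervals:", nrow(x$truth$loh_intervals), "\n"
  )
  invisible(x)
}
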