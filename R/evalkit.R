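# K-mer based quality assessment: error k-mers and QV, quality-delta and
# errors-per-Mb conversions, fixed/induced/unchanged error accounting through
# assembly-to-assembly projection, GQ cutoff sweeps, and error-context
# stratification.

#' Build a canonical k-mer presence set from reads
#'
#' Canonical means the lexicographically smaller of a k-mer and its reverse
#' complement under 2-bit encoding; both the read database and assembly scan
#' use it, so strandedness never matters. Non-ACGT characters break k-mer
#' runs.
#'
#' @param seqs Character vector of read (or assembly) sequences.
#' @param k K-mer size (2..31; default 31).
#' @return An external pointer of class `kmer_set`.
#' @export
kmer_set <- function(seqs, k = 31L) {
  ptr <- .kmer_set_build(as.character(seqs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k)), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(
    "<kmer_set> k =", x$k, "|",
    format(.kmer_set_size(x$ptr), big.mark = ","), "distinct k-mers\n"
  )
  invisible(x)
}

#' QV and errors-per-Mb from error-k-mer counts
#'
#' Converts the number of assembly k-mers absent from the read set (`B`) out
#' of `T` total k-mers into a per-base error estimate
#' `E = 1 - (1 - B/T)^(1/k)`, a phred-scaled quality value
#' `QV = -10 log10(E)`, and the errors-per-megabase equivalent
#' `10^(-QV/10) * 10^6`. With zero error k-mers the QV is capped (flagged by
#' `capped = TRUE`) rather than infinite.
#'
#' @param error_kmers,total_kmers Counts `B` and `T`.
#' @param k K-mer size.
#' @param region_label Free-text label for the assessed region.
#' @param cap QV cap when `B = 0`.
#' @return One-row tibble of class `qv_report`.
#' @export
qv_report <- function(error_kmers, total_kmers, k = 31L,
                      region_label = "whole", cap = 99) {
  stopifnot(total_kmers > 0, error_kmers >= 0, error_kmers <= total_kmers)
  capped <- error_kmers == 0
  if (capped) {
    qv <- cap
  } else {
    err_rate <- 1 - (1 - error_kmers / total_kmers)^(1 / k)
    qv <- -10 * log10(err_rate)
  }
  out <- tibble::tibble(
    region_label = region_label,
    total_kmers = as.numeric(total_kmers),
    error_kmers = as.numeric(error_kmers),
    k = as.integer(k),
    qv = qv,
    errors_per_mb = errors_per_mb(qv),
    capped = capped
  )
  class(out) <- c("qv_report", class(out))
  out
}

#' Convert between QV and errors per megabase
#'
#' `errors_per_mb(qv) = 10^(-qv/10) * 10^6`; `qv_from_errors_per_mb()` is the
#' inverse.
#'
#' @param qv Quality value in decibels.
#' @return Errors per megabase.
#' @export
errors_per_mb <- function(qv) 10^(-qv / 10) * 1e6

#' @param epm Errors per megabase.
#' @rdname errors_per_mb
#' @export
qv_from_errors_per_mb <- function(epm) -10 * log10(epm / 1e6)

#' Find assembly error k-mers against a read k-mer set
#'
#' Scans every assembly k-mer and flags those absent from the read database;
#' overlapping flagged k-mers are merged into intervals (a single substituted
#' base yields k error k-mers spanning 2k-1 bases). Returns the merged
#' interval track and the QV report computed from the counts.
#'
#' @param assembly_seqs Named character vector of assembly sequences.
#' @param read_db A [kmer_set()] built from reads, or a character vector of
#'   read sequences (a set is then built).
#' @param k K-mer size (must match `read_db`).
#' @param region_label Label passed to [qv_report()].
#' @return List of class `error_kmer_result`: `track` (interval tibble with
#'   `n_kmers` per merged interval), `report` (a `qv_report`), `kmer_starts`
#'   (per-contig integer vectors, 0-based).
#' @export
error_kmers <- function(assembly_seqs, read_db, k = 31L,
                        region_label = "whole") {
  if (!inherits(read_db, "kmer_set")) read_db <- kmer_set(read_db, k)
  stopifnot(read_db$k == k)
  if (any(nchar(assembly_seqs) < k)) {
    stop("assembly sequence shorter than k")
  }
  tracks <- list()
  starts <- list()
  total <- 0
  bad <- 0
  for (ct in names(assembly_seqs)) {
    pos1 <- .kmer_missing_positions(read_db$ptr, assembly_seqs[[ct]], k)
    total <- total + nchar(assembly_seqs[[ct]]) - k + 1
    bad <- bad + length(pos1)
    starts[[ct]] <- pos1 - 1L
    if (length(pos1)) {
      iv <- merge_intervals(intervals(ct, pos1 - 1L, pos1 - 1L + k))
      nk <- vapply(seq_len(nrow(iv)), function(i) {
        sum(pos1 - 1L >= iv$start[[i]] & pos1 - 1L < iv$end[[i]])
      }, integer(1))
      iv$n_kmers <- nk
      tracks[[ct]] <- iv
    }
  }
  track <- dplyr::bind_rows(tracks)
  if (nrow(track) == 0L) {
    track <- tibble::tibble(
      contig = character(), start = integer(),
      end = integer(), n_kmers = integer()
    )
  }
  structure(
    list(
      track = track,
      report = qv_report(bad, total, k, region_label),
      kmer_starts = starts
    ),
    class = "error_kmer_result"
  )
}

#' @export
print.error_kmer_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<error_kmer_result> %s: %d error k-mers / %.0f total (k=%d) | QV %.2f | %.3f errors/Mb\n",
    r$region_label, as.integer(r$error_kmers), r$total_kmers, r$k, r$qv,
    r$errors_per_mb
  ))
  invisible(x)
}

#' Quality-value improvement from error-k-mer counts
#'
#' `delta_qv = -10 log10(errors_after / errors_before)`; positive when
#' polishing removed errors. A delta of 3.4 corresponds to a
#' `1 - 10^(-0.34) = 54%` reduction in errors.
#'
#' @param errors_before,errors_after Error-k-mer counts before/after.
#' @param cap Value returned when `errors_after = 0`.
#' @return Delta QV in decibels.
#' @export
delta_qv <- function(errors_before, errors_after, cap = 99) {
  stopifnot(errors_before > 0, errors_after >= 0)
  if (errors_after == 0) return(cap)
  -10 * log10(errors_after / errors_before)
}

#' Error reduction implied by a QV improvement
#'
#' @param dqv Delta QV in decibels.
#' @return Fractional error reduction `1 - 10^(-dqv/10)`.
#' @export
error_reduction <- function(dqv) 1 - 10^(-dqv / 10)

#' Annotate error k-mers as fixed, induced, or unchanged by polishing
#'
#' Projects the polished assembly's error intervals onto the unpolished
#' (raw) assembly through the raw-vs-polished alignment, then classifies by
#' interval arithmetic on raw coordinates: `fixed` = raw errors absent from
#' the projection, `induced` = projected errors absent from the raw track,
#' `unchanged` = the intersection. Polished error intervals with no
#' projection image are conservatively counted as induced (flagged
#' `unprojected`).
#'
#' @param raw_track Error interval tibble on raw assembly coordinates.
#' @param polished_track Error interval tibble on polished coordinates.
#' @param raw_vs_polished Alignment tibble: query = raw, target = polished
#'   (so the projection direction is target to query).
#' @return Tibble `contig`, `start`, `end`, `status`, `unprojected` -- of
#'   class `error_kmer_track`.
#' @export
annotate_error_kmers <- function(raw_track, polished_track, raw_vs_polished) {
  raw <- merge_intervals(raw_track)
  pol <- merge_intervals(polished_track)
  proj <- list()
  unproj <- list()
  for (i in seq_len(nrow(pol))) {
    hit <- NULL
    for (j in seq_len(nrow(raw_vs_polished))) {
      a <- raw_vs_polished[j, ]
      if (a$tname != pol$contig[[i]]) next
      p <- project_intervals(pol[i, ], a, "t2q")
      if (nrow(p)) {
        hit <- p[, c("contig", "start", "end")]
        break
      }
    }
    if (is.null(hit)) {
      unproj[[length(unproj) + 1L]] <- pol[i, c("contig", "start", "end")]
    } else {
      proj[[length(proj) + 1L]] <- hit
    }
  }
  proj <- if (length(proj)) merge_intervals(dplyr::bind_rows(proj)) else intervals()
  fixed <- setdiff_intervals(raw, proj)
  induced <- setdiff_intervals(proj, raw)
  unchanged <- intersect_intervals(raw, proj)
  status_tbl <- function(x, status, unprojected = FALSE) {
    if (nrow(x) == 0L) return(NULL)
    dplyr::mutate(x[, c("contig", "start", "end")],
      status = status, unprojected = unprojected
    )
  }
  out <- dplyr::bind_rows(
    status_tbl(fixed, "fixed"),
    status_tbl(induced, "induced"),
    status_tbl(unchanged, "unchanged"),
    status_tbl(dplyr::bind_rows(unproj), "induced", TRUE)
  )
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble::tibble(
      contig = character(), start = integer(), end = integer(),
      status = character(), unprojected = logical()
    )
  }
  out <- dplyr::arrange(out, .data$contig, .data$start)
  class(out) <- c("error_kmer_track", class(out))
  out
}

#' Label polishing edits by their effect on error k-mers
#'
#' Intersects each edit's REF span with the annotated error-k-mer track.
#' Precedence on multiple overlaps: `induces` > `fixes` > `no_change`; edits
#' overlapping nothing are labelled `none`.
#'
#' @param edits Edit tibble (`contig`, `pos` 1-based, `ref` on raw assembly
#'   coordinates).
#' @param track An [annotate_error_kmers()] result.
#' @return `edits` with a `label` column.
#' @export
annotate_edits <- function(edits, track) {
  lab <- function(status) c(
    fixed = "fixes", induced = "induces",
    unchanged = "no_change"
  )[[status]]
  edits$label <- vapply(seq_len(nrow(edits)), function(i) {
    s <- edits$pos[[i]] - 1L
    e <- s + nchar(edits$ref[[i]])
    hit <- track[track$contig == edits$contig[[i]] &
      track$start < e & track$end > s, , drop = FALSE]
    if (nrow(hit) == 0L) return("none")
    st <- unique(hit$status)
    if ("induced" %in% st) "induces" else if ("fixed" %in% st) "fixes" else "no_change"
  }, character(1))
  edits
}

#' Sweep class-specific GQ cutoffs and estimate the QV improvement
#'
#' For each cutoff vector in the scenario's grid, edits below their cutoff
#' are dropped; the estimated error count after polishing is
#' `unchanged + induced(kept) + fixes(dropped)` (an error an edit would have
#' fixed remains when the edit is filtered away), and the QV delta follows
#' [delta_qv()] against `before = unchanged + fixes(all)`. Scenarios:
#' `single` (one cutoff), `ins1_rest` (1 bp insertions vs the rest),
#' `ins1_del1_rest` (three cutoffs). Ties go to the lowest cutoffs.
#'
#' @param annotated_edits Edit tibble with `class`, `gq`, `label` and
#'   optionally `weight` (error k-mers affected; default 1 per edit).
#' @param scenario One of `"single"`, `"ins1_rest"`, `"ins1_del1_rest"`.
#' @param gq_range Cutoff grid (default 0:25).
#' @param unchanged Error count untouched by any edit.
#' @return List of class `gq_sweep`: `curve` (one row per cutoff vector with
#'   `errors_after`, `delta_qv`) and `optimum` (first row achieving the
#'   maximum delta in ascending cutoff order).
#' @export
sweep_gq <- function(annotated_edits, scenario = c(
                       "single", "ins1_rest",
                       "ins1_del1_rest"
                     ),
                     gq_range = 0:25, unchanged = 0) {
  scenario <- match.arg(scenario)
  ed <- annotated_edits
  if (nrow(ed) == 0L) {
    curve <- tibble::tibble(
      gq_ins1 = 0, gq_del1 = 0, gq_other = 0,
      errors_after = unchanged, delta_qv = 0
    )
    return(structure(list(curve = curve, optimum = curve, scenario = scenario),
      class = "gq_sweep"
    ))
  }
  if (!"weight" %in% names(ed)) ed$weight <- 1
  grid <- switch(scenario,
    single = tibble::tibble(
      gq_ins1 = gq_range, gq_del1 = gq_range,
      gq_other = gq_range
    ),
    ins1_rest = tidyr::crossing(gq_ins1 = gq_range, rest = gq_range) |>
      dplyr::mutate(gq_del1 = .data$rest, gq_other = .data$rest) |>
      dplyr::select("gq_ins1", "gq_del1", "gq_other"),
    ins1_del1_rest = tidyr::crossing(
      gq_ins1 = gq_range, gq_del1 = gq_range, gq_other = gq_range
    )
  )
  fixes_total <- sum(ed$weight[ed$label == "fixes"])
  before <- unchanged + fixes_total
  cuts <- function(cl, g) dplyr::case_when(
    cl == "INS1" ~ g$gq_ins1, cl == "DEL1" ~ g$gq_del1, TRUE ~ g$gq_other
  )
  res <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    kept <- ed$gq >= cuts(ed$class, g)
    unchanged +
      sum(ed$weight[kept & ed$label == "induces"]) +
      sum(ed$weight[!kept & ed$label == "fixes"])
  }, numeric(1))
  curve <- grid
  curve$errors_after <- res
  curve$delta_qv <- ifelse(
    res == 0, Inf, -10 * log10(res / max(before, 1e-12))
  )
  curve <- dplyr::arrange(curve, .data$gq_ins1, .data$gq_del1, .data$gq_other)
  best <- which.max(curve$delta_qv) # first max in ascending cutoff order
  structure(
    list(curve = curve, optimum = curve[best, ], scenario = scenario),
    class = "gq_sweep"
  )
}

#' @export
print.gq_sweep <- function(x, ...) {
  cat("<gq_sweep>", x$scenario, "scenario,", nrow(x$curve), "cutoff vectors\n")
  cat(sprintf(
    "  optimum: INS1 >= %g, DEL1 >= %g, OTHER >= %g (delta QV %.3f)\n",
    x$optimum$gq_ins1, x$optimum$gq_del1, x$optimum$gq_other,
    x$optimum$delta_qv
  ))
  invisible(x)
}

#' Stratify error intervals by sequence and coverage context
#'
#' Counts error intervals overlapping (a) at least one constituent k-mer
#' with GC content above `gc_threshold`, (b) homopolymer runs of at least
#' `homopolymer_min` bases (i.e. "greater than 10 bp" with the default 11),
#' and (c) regions below `low_cov` fold coverage, using quantized coverage
#' bands `[0,5) [5,10) [10,150)`. Categories are not exclusive.
#'
#' @param track Error interval tibble (`contig`, `start`, `end`).
#' @param assembly_seqs Named character vector.
#' @param depth Per-base coverage: tibble `contig`, `start`, `end`, `depth`
#'   (run-length encoded), e.g. from [coverage_track()].
#' @param k K-mer size for the GC computation.
#' @param gc_threshold GC fraction cutoff (default 0.70).
#' @param homopolymer_min Minimum homopolymer length (default 11).
#' @param low_cov Coverage cutoff (default 5).
#' @return Tibble `category`, `n`, `fraction` (of error intervals).
#' @export
stratify_error_context <- function(track, assembly_seqs, depth = NULL,
                                   k = 31L, gc_threshold = 0.70,
                                   homopolymer_min = 11L, low_cov = 5) {
  n_int <- nrow(track)
  if (n_int == 0L) {
    return(tibble::tibble(category = character(), n = integer(), fraction = double()))
  }
  gc_hit <- vapply(seq_len(n_int), function(i) {
    seq <- assembly_seqs[[track$contig[[i]]]]
    lo <- track$start[[i]]
    hi <- min(track$end[[i]], nchar(seq))
    ks <- seq(lo, max(lo, hi - k), by = 1L)
    any(vapply(ks, function(s) {
      km <- substr(seq, s + 1L, s + k)
      stringr::str_count(km, "[GCgc]") / nchar(km) > gc_threshold
    }, logical(1)))
  }, logical(1))
  hp <- purrr::map_dfr(names(assembly_seqs), function(ct) {
    homopolymer_runs(assembly_seqs[[ct]], homopolymer_min, ct)
  })
  hp_hit <- overlaps_any(track, hp)
  if (is.null(depth)) {
    low_hit <- rep(FALSE, n_int)
  } else {
    bands <- quantize_depth(depth, breaks = c(0, low_cov, 10, 150))
    low <- bands[bands$band == paste0("[0,", low_cov, ")"), , drop = FALSE]
    low_hit <- overlaps_any(track, low)
  }
  tibble::tibble(
    category = c(
      paste0("gc_above_", gc_threshold),
      paste0("homopolymer_ge_", homopolymer_min),
      paste0("coverage_below_", low_cov)
    ),
    n = c(sum(gc_hit), sum(hp_hit), sum(low_hit)),
    fraction = c(sum(gc_hit), sum(hp_hit), sum(low_hit)) / n_int
  )
}

#' Per-base coverage track from alignments
#'
#' Run-length encoded fold coverage of the target, counting `=`/`X`/`D`
#' columns of each record.
#'
#' @param alns Alignment tibble.
#' @param contig_lengths Named integer vector.
#' @return Tibble `contig`, `start`, `end`, `depth`.
#' @export
coverage_track <- function(alns, contig_lengths) {
  purrr::map_dfr(names(contig_lengths), function(ct) {
    a <- alns[alns$tname == ct, , drop = FALSE]
    L <- contig_lengths[[ct]]
    if (nrow(a) == 0L) {
      return(tibble::tibble(contig = ct, start = 0L, end = L, depth = 0L))
    }
    sp <- .aln_spans(a)
    cov <- IRanges::coverage(
      IRanges::IRanges(sp$start + 1L, sp$end),
      width = L
    )
    tibble::tibble(
      contig = ct,
      start = cumsum(c(0L, S4Vectors::runLength(cov)))[seq_along(S4Vectors::runLength(cov))],
      end = cumsum(S4Vectors::runLength(cov)),
      depth = S4Vectors::runValue(cov)
    )
  })
}

#' Quantize a coverage track into bands
#'
#' @param depth Coverage tibble from [coverage_track()].
#' @param breaks Ascending band boundaries, e.g. `c(0, 5, 10, 150)` giving
#'   bands `[0,5) [5,10) [10,150)` (values at or above the last boundary fall
#'   in the last band).
#' @return Tibble `contig`, `start`, `end`, `band`.
#' @export
quantize_depth <- function(depth, breaks = c(0, 5, 10, 150)) {
  labs <- paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
  band_of <- pmin(
    findInterval(depth$depth, breaks),
    length(labs)
  )
  band_of[band_of == 0L] <- 1L
  out <- depth
  out$band <- labs[band_of]
  out <- out |>
    dplyr::group_by(.data$contig) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(grp = cumsum(c(
      TRUE,
      .data$band[-1] != .data$band[-dplyr::n()]
    ))) |>
    dplyr::group_by(.data$contig, .data$grp, .data$band) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    ) |>
    dplyr::select("contig", "start", "end", "band") |>
    dplyr::arrange(.data$contig, .data$start)
  out
}
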