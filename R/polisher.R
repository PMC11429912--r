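# Candidate-window polishing: detect positions where reads disagree with the
# assembly, group them into small windows, featurize the window pileup into a
# tensor-like object, predict the window sequence with a pluggable predictor
# (default: base-quality-weighted pileup consensus), and emit the differences
# as VCF-style edits.

#' Find candidate error positions in a pileup
#'
#' A 0-based assembly position is a candidate if at least `min_support`
#' distinct reads disagree with the assembly there: a mismatched base at the
#' position, a deletion covering it, or an insertion anchored immediately
#' after it.
#'
#' @param alns Alignment tibble (extended CIGARs) against one haplotype.
#' @param contig Restrict to one contig (default: all).
#' @param interval Optional `c(start, end)` 0-based half-open scan interval.
#' @param min_support Minimum distinct disagreeing reads (default 3, i.e.
#'   "more than two").
#' @return Tibble `contig`, `pos` (sorted), `n_reads`.
#' @export
find_candidate_positions <- function(alns, contig = NULL, interval = NULL,
                                     min_support = 3L) {
  if (!is.null(contig)) alns <- alns[alns$tname == contig, , drop = FALSE]
  empty <- tibble::tibble(contig = character(), pos = integer(), n_reads = integer())
  if (nrow(alns) == 0L) return(empty)
  ev <- purrr::map_dfr(seq_len(nrow(alns)), function(i) {
    a <- alns[i, ]
    lay <- cigar_layout(a$cigar, a$target_start)
    bad <- lay[lay$op %in% c("X", "D", "I"), , drop = FALSE]
    if (nrow(bad) == 0L) return(NULL)
    pos <- unlist(purrr::pmap(
      list(bad$op, bad$t0, bad$t1),
      function(op, t0, t1) {
        if (op == "I") t0 - 1L else seq(t0, t1 - 1L)
      }
    ))
    tibble::tibble(qname = a$qname, contig = a$tname, pos = as.integer(pos))
  })
  if (nrow(ev) == 0L) return(empty)
  ev <- ev[ev$pos >= 0L, , drop = FALSE]
  if (!is.null(interval)) {
    ev <- ev[ev$pos >= interval[[1]] & ev$pos < interval[[2]], , drop = FALSE]
  }
  ev |>
    dplyr::distinct(.data$qname, .data$contig, .data$pos) |>
    dplyr::count(.data$contig, .data$pos, name = "n_reads") |>
    dplyr::filter(.data$n_reads >= min_support) |>
    dplyr::arrange(.data$contig, .data$pos)
}

#' Group candidate positions into bounded windows
#'
#' Greedy left-to-right chaining: the current window is extended while the
#' next position is within `max_gap` bases of the previous one AND the total
#' window span stays within `max_span`; otherwise a new window starts. Every
#' candidate position lands in exactly one window.
#'
#' @param positions Sorted, deduplicated integer positions (one contig).
#' @param max_gap Maximum gap between consecutive grouped positions (50).
#' @param max_span Maximum window span in bases (100).
#' @return Tibble `start`, `end` (0-based half-open, covering first..last
#'   candidate), `n_candidates`.
#' @export
group_windows <- function(positions, max_gap = 50L, max_span = 100L) {
  if (length(positions) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), n_candidates = integer()))
  }
  stopifnot(!is.unsorted(positions))
  win <- integer(length(positions))
  win[[1]] <- 1L
  start <- positions[[1]]
  w <- 1L
  for (i in seq_along(positions)[-1]) {
    if (positions[[i]] - positions[[i - 1L]] > max_gap ||
      positions[[i]] - start + 1L > max_span) {
      w <- w + 1L
      start <- positions[[i]]
    }
    win[[i]] <- w
  }
  tibble::tibble(pos = positions, win = win) |>
    dplyr::group_by(.data$win) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos) + 1L,
      n_candidates = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::select(-"win")
}

# Stable small string hash for deterministic read subsampling.
.name_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Featurize a candidate window into a pileup tensor
#'
#' One row per overlapping read (deterministically subsampled to `depth_cap`
#' by a fixed hash of the read name), one column per window reference
#' position plus one slot per distinct insertion locus. Channels: base (with
#' `-` for deletion gaps, `""` for pad), match flag, base quality, mapping
#' quality.
#'
#' @param window List or one-row tibble with `contig`, `start`, `end`
#'   (0-based half-open).
#' @param alns Alignment tibble.
#' @param ref_seqs Named character vector of assembly sequences.
#' @param depth_cap Maximum rows (default 30).
#' @return A list of class `feature_tensor` with matrices `bases`, `match`,
#'   `baseq`, `mapq`, the column table `columns` (`type`, `pos`), window
#'   coordinates and the assembly window sequence. Zero-coverage windows
#'   return `NULL` rows (`nrow = 0`).
#' @export
featurize_window <- function(window, alns, ref_seqs, depth_cap = 30L) {
  ct <- window$contig
  ws <- window$start
  we <- window$end
  alns <- alns[alns$tname == ct, , drop = FALSE]
  if (nrow(alns)) {
    sp <- .aln_spans(alns)
    keep <- sp$start < we & sp$end > ws
    alns <- alns[alns$qname %in% sp$qname[keep], , drop = FALSE]
  }
  ref_win <- substr(ref_seqs[[ct]], ws + 1L, we)
  if (nrow(alns) > depth_cap) {
    o <- order(.name_hash(alns$qname), alns$qname)
    alns <- alns[o[seq_len(depth_cap)], , drop = FALSE]
  }
  n <- nrow(alns)
  wlen <- we - ws
  bases <- matrix("", nrow = n, ncol = wlen)
  match_f <- matrix(NA_character_, nrow = n, ncol = wlen)
  baseq <- matrix(NA_integer_, nrow = n, ncol = wlen)
  mapq <- matrix(NA_integer_, nrow = n, ncol = wlen)
  ins <- list() # key: anchor pos -> tibble(row, seq, q)
  for (i in seq_len(n)) {
    a <- alns[i, ]
    lay <- cigar_layout(a$cigar, a$target_start)
    qphred <- utf8ToInt(a$qual) - 33L
    for (r in seq_len(nrow(lay))) {
      op <- lay$op[[r]]
      t0 <- lay$t0[[r]]
      t1 <- lay$t1[[r]]
      if (op %in% c("=", "X")) {
        lo <- max(t0, ws)
        hi <- min(t1, we)
        if (lo >= hi) next
        cols <- (lo - ws + 1L):(hi - ws)
        qidx <- lay$q0[[r]] + (lo - t0) + seq_len(hi - lo) - 1L
        bases[i, cols] <- substring(a$seq, qidx + 1L, qidx + 1L)
        match_f[i, cols] <- if (op == "=") "match" else "mismatch"
        baseq[i, cols] <- qphred[qidx + 1L]
        mapq[i, cols] <- a$mapq
      } else if (op == "D") {
        lo <- max(t0, ws)
        hi <- min(t1, we)
        if (lo >= hi) next
        cols <- (lo - ws + 1L):(hi - ws)
        bases[i, cols] <- "-"
        match_f[i, cols] <- NA_character_
        qi <- min(max(lay$q0[[r]], 1L), length(qphred))
        baseq[i, cols] <- qphred[qi]
        mapq[i, cols] <- a$mapq
      } else if (op == "I") {
        anchor <- t0 - 1L
        if (anchor < ws || anchor >= we) next
        key <- as.character(anchor)
        qidx <- lay$q0[[r]]:(lay$q1[[r]] - 1L)
        ins[[key]] <- dplyr::bind_rows(
          ins[[key]],
          tibble::tibble(
            row = i,
            seq = substr(a$seq, qidx[[1]] + 1L, qidx[[length(qidx)]] + 1L),
            q = min(qphred[qidx + 1L])
          )
        )
      }
    }
  }
  ins_pos <- sort(as.integer(names(ins)))
  columns <- dplyr::bind_rows(
    tibble::tibble(type = "ref", pos = seq(ws, length.out = wlen)),
    tibble::tibble(type = "ins", pos = ins_pos)
  ) |> dplyr::arrange(.data$pos, .data$type == "ins")
  structure(
    list(
      bases = bases, match = match_f, baseq = baseq, mapq = mapq,
      insertions = ins, columns = columns,
      contig = ct, start = ws, end = we, ref_seq = ref_win,
      reads = alns$qname
    ),
    class = "feature_tensor"
  )
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(
    "<feature_tensor>", nrow(x$bases), "reads x", nrow(x$columns),
    "columns |", x$contig, sprintf("[%d,%d)\n", x$start, x$end)
  )
  invisible(x)
}

#' Predict the window sequence from a feature tensor
#'
#' Default consensus core (the pluggable stand-in for a learned sequence
#' predictor): per column, each read votes for its allele (base, deletion
#' gap, or inserted string) with weight `1 - 10^(-baseq/10)`; the heaviest
#' allele wins. An insertion is emitted only when its summed weight exceeds
#' half the total weight of reads covering its anchor. All-pad columns keep
#' the assembly base.
#'
#' @param tensor A [featurize_window()] result.
#' @return List with `seq` (predicted window sequence), `support` (per
#'   emitted base: winning-allele weight fraction, `NA` where no read
#'   covered the column).
#' @export
predict_sequence <- function(tensor) {
  if (nrow(tensor$bases) == 0L) {
    stop("empty tensor: no reads cover the window")
  }
  wlen <- tensor$end - tensor$start
  out_chars <- character(0)
  out_supp <- double(0)
  w_of <- function(q) 1 - 10^(-q / 10)
  for (j in seq_len(wlen)) {
    cell <- tensor$bases[, j]
    live <- which(cell != "")
    if (length(live) == 0L) {
      out_chars <- c(out_chars, substr(tensor$ref_seq, j, j))
      out_supp <- c(out_supp, NA_real_)
    } else {
      w <- w_of(tensor$baseq[live, j])
      tot <- sum(w)
      agg <- tapply(w, cell[live], sum)
      ref_base <- substr(tensor$ref_seq, j, j)
      best <- max(agg)
      winners <- names(agg)[agg == best]
      win <- if (ref_base %in% winners) ref_base else sort(winners)[[1]]
      if (win != "-") {
        out_chars <- c(out_chars, win)
        out_supp <- c(out_supp, agg[[win]] / tot)
      }
      # a winning "-" contributes no base (deletion)
    }
    # insertion slot anchored after reference position j-1 (0-based ws+j-1)
    key <- as.character(tensor$start + j - 1L)
    if (!is.null(tensor$insertions[[key]])) {
      instab <- tensor$insertions[[key]]
      cover <- which(tensor$bases[, j] != "")
      tot <- sum(w_of(tensor$baseq[cover, j]))
      agg <- tapply(w_of(instab$q), instab$seq, sum)
      best <- max(agg)
      win <- sort(names(agg)[agg == best])[[1]]
      if (tot > 0 && best > 0.5 * tot) {
        out_chars <- c(out_chars, win)
        out_supp <- c(out_supp, rep(best / tot, nchar(win)))
      }
    }
  }
  list(seq = paste(out_chars, collapse = ""), support = out_supp)
}

#' Express differences between assembly and predicted sequence as VCF edits
#'
#' Aligns the two window sequences (Levenshtein edit script), emits adjacent
#' substitutions as separate SNV records (no MNPs), indels as left-normalized
#' anchored records, and assigns each record
#' `GQ = -10 log10(1 - support)` (capped at 99), minimized over the
#' predicted positions the record touches.
#'
#' @param assembly_seq Window sequence of the assembly.
#' @param predicted_seq Predicted window sequence.
#' @param support Per-base support fractions along `predicted_seq`.
#' @param contig Contig name for the records.
#' @param window_start 0-based assembly position of `assembly_seq`'s first
#'   base.
#' @return Edit tibble `contig`, `pos` (1-based), `ref`, `alt`, `gq`.
#' @export
edits_from_diff <- function(assembly_seq, predicted_seq, support = NULL,
                            contig = "ctg", window_start = 0L) {
  empty <- tibble::tibble(
    contig = character(), pos = integer(),
    ref = character(), alt = character(), gq = double()
  )
  if (assembly_seq == predicted_seq) return(empty)
  if (is.null(support)) support <- rep(1, nchar(predicted_seq))
  d <- utils::adist(assembly_seq, predicted_seq, counts = TRUE)
  tr <- strsplit(attr(d, "trafos")[1, 1], "")[[1]]
  gq_of <- function(su) {
    su <- su[!is.na(su)]
    if (length(su) == 0L) return(0)
    min(99, -10 * log10(pmax(1 - su, 1e-10)))
  }
  # group maximal runs of non-match ops: a pure-substitution run becomes one
  # SNV per column; any run containing an indel becomes a single anchored
  # record, so emitted REF spans can never overlap
  recs <- list()
  ai <- 1L # assembly cursor (1-based)
  pi <- 1L # predicted cursor
  i <- 1L
  n <- length(tr)
  while (i <= n) {
    if (tr[[i]] == "M") {
      ai <- ai + 1L
      pi <- pi + 1L
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && tr[[j]] != "M") j <- j + 1L
    run <- tr[i:(j - 1L)]
    n_s <- sum(run == "S")
    n_d <- sum(run == "D")
    n_i <- sum(run == "I")
    a_len <- n_s + n_d
    p_len <- n_s + n_i
    if (n_d == 0L && n_i == 0L) { # adjacent substitutions stay separate SNVs
      for (k in seq_len(n_s)) {
        recs[[length(recs) + 1L]] <- list(
          pos = ai + k - 1L,
          ref = substr(assembly_seq, ai + k - 1L, ai + k - 1L),
          alt = substr(predicted_seq, pi + k - 1L, pi + k - 1L),
          gq = gq_of(support[pi + k - 1L])
        )
      }
    } else {
      p_sup <- if (p_len > 0L) {
        support[pi:(pi + p_len - 1L)]
      } else {
        support[max(pi - 1L, 1L)]
      }
      a_seg <- if (a_len > 0L) substr(assembly_seq, ai, ai + a_len - 1L) else ""
      p_seg <- if (p_len > 0L) substr(predicted_seq, pi, pi + p_len - 1L) else ""
      if (ai > 1L) { # left anchor base
        recs[[length(recs) + 1L]] <- list(
          pos = ai - 1L,
          ref = paste0(substr(assembly_seq, ai - 1L, ai - 1L), a_seg),
          alt = paste0(substr(assembly_seq, ai - 1L, ai - 1L), p_seg),
          gq = gq_of(p_sup)
        )
      } else { # run at window start: anchor on the base to its right
        nxt <- substr(assembly_seq, a_len + 1L, a_len + 1L)
        recs[[length(recs) + 1L]] <- list(
          pos = 1L,
          ref = paste0(a_seg, nxt),
          alt = paste0(p_seg, nxt),
          gq = gq_of(p_sup)
        )
      }
    }
    ai <- ai + a_len
    pi <- pi + p_len
    i <- j
  }
  out <- purrr::map_dfr(recs, tibble::as_tibble)
  out$contig <- contig
  # left-normalize within the window, then convert to absolute coordinates
  out <- .normalize_edit_table(assembly_seq, out)
  out$pos <- out$pos + as.integer(window_start)
  out <- dplyr::arrange(out, .data$pos)
  out[, c("contig", "pos", "ref", "alt", "gq")]
}

#' Polish one haplotype: candidate detection through edit emission
#'
#' Scans the alignments of one haplotype for candidate error positions,
#' groups them into windows (gap 50 bp, span 100 bp), featurizes each window
#' with `flank` bases of context, predicts the window consensus, and emits
#' the differences as VCF-style edits, classified for downstream GQ
#' filtering. Windows with no read coverage are skipped.
#'
#' @param ref_seqs Named character vector (one haplotype's contigs).
#' @param alns Alignment tibble for that haplotype.
#' @param min_support Candidate threshold (default 3 disagreeing reads).
#' @param max_gap,max_span Window grouping parameters (50 / 100).
#' @param depth_cap Tensor row cap (default 30).
#' @param flank Context bases added around each window (default 15).
#' @param predictor Function `tensor -> list(seq, support)`; defaults to
#'   [predict_sequence()]. A learned model can be plugged in here.
#' @return List of class `polish_result`: `edits` (with `class` column),
#'   `windows`, `n_candidates`.
#' @export
polish_haplotype <- function(ref_seqs, alns, min_support = 3L, max_gap = 50L,
                             max_span = 100L, depth_cap = 30L, flank = 15L,
                             predictor = predict_sequence) {
  cands <- find_candidate_positions(alns, min_support = min_support)
  spans <- if (nrow(alns)) .aln_spans(alns) else NULL
  all_windows <- list()
  all_edits <- list()
  for (ct in unique(cands$contig)) {
    if (!ct %in% names(ref_seqs)) next
    pos <- cands$pos[cands$contig == ct]
    wins <- group_windows(pos, max_gap, max_span)
    wins$contig <- ct
    clen <- nchar(ref_seqs[[ct]])
    sp_ct <- spans[spans$contig == ct, , drop = FALSE]
    for (i in seq_len(nrow(wins))) {
      ws <- max(wins$start[[i]] - flank, 0L)
      we <- min(wins$end[[i]] + flank, clen)
      ids <- sp_ct$qname[sp_ct$start < we & sp_ct$end > ws]
      tens <- featurize_window(
        list(contig = ct, start = ws, end = we),
        alns[alns$qname %in% ids & alns$tname == ct, , drop = FALSE],
        ref_seqs, depth_cap
      )
      if (nrow(tens$bases) == 0L) next
      pred <- predictor(tens)
      ed <- edits_from_diff(
        tens$ref_seq, pred$seq, pred$support,
        contig = ct, window_start = ws
      )
      if (nrow(ed)) {
        # keep edits attributable to this window's candidates (flank edits
        # belong to the neighbouring window that owns them)
        core_lo <- wins$start[[i]] - 2L
        core_hi <- wins$end[[i]] + 2L
        span_end <- ed$pos - 1L + nchar(ed$ref)
        ed <- ed[span_end > core_lo & (ed$pos - 1L) < core_hi, , drop = FALSE]
      }
      if (nrow(ed)) all_edits[[length(all_edits) + 1L]] <- ed
    }
    all_windows[[ct]] <- wins
  }
  edits <- dplyr::bind_rows(all_edits)
  if (nrow(edits) == 0L) {
    edits <- tibble::tibble(
      contig = character(), pos = integer(),
      ref = character(), alt = character(), gq = double()
    )
  }
  edits <- dplyr::distinct(edits, .data$contig, .data$pos, .data$ref,
    .data$alt,
    .keep_all = TRUE
  )
  edits$class <- classify_edit(edits)
  structure(
    list(
      edits = dplyr::arrange(edits, .data$contig, .data$pos),
      windows = dplyr::bind_rows(all_windows),
      n_candidates = nrow(cands)
    ),
    class = "polish_result"
  )
}

#' @export
print.polish_result <- function(x, ...) {
  cat("<polish_result>\n")
  cat("  candidate positions:", x$n_candidates, "\n")
  cat("  windows:            ", nrow(x$windows), "\n")
  cat("  proposed edits:     ", nrow(x$edits), "\n")
  if (nrow(x$edits)) print(table(x$edits$class))
  invisible(x)
}
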