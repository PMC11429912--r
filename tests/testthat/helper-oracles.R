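# Independent oracles and small fixture builders used across the suite.

# Quadratic dynamic-programming Levenshtein distance (independent of the
# utils::adist-based implementation path).
dp_edit_distance <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(av) == 0L) return(length(bv))
  if (length(bv) == 0L) return(length(av))
  prev <- 0:length(bv)
  for (i in seq_along(av)) {
    cur <- integer(length(bv) + 1L)
    cur[1L] <- i
    sub_cost <- prev[1:length(bv)] + (av[[i]] != bv)
    del_cost <- prev[2:(length(bv) + 1L)] + 1L
    for (j in seq_along(bv)) {
      cur[j + 1L] <- min(sub_cost[[j]], del_cost[[j]], cur[[j]] + 1L)
    }
    prev <- cur
  }
  prev[[length(bv) + 1L]]
}

# Per-base coordinate map through a CIGAR: for every target position of the
# alignment, the query position it pairs with (NA across deletions), and the
# reverse. Walks the CIGAR one base at a time.
per_base_map <- function(cigar, target_start = 0L) {
  ops <- hapolish::parse_cigar(cigar)
  t2q <- list()
  q2t <- list()
  tp <- target_start
  qp <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[[i]]
    for (k in seq_len(ops$len[[i]])) {
      if (op %in% c("=", "X", "M")) {
        t2q[[length(t2q) + 1L]] <- c(tp, qp)
        q2t[[length(q2t) + 1L]] <- c(qp, tp)
        tp <- tp + 1L
        qp <- qp + 1L
      } else if (op == "D") {
        t2q[[length(t2q) + 1L]] <- c(tp, NA)
        tp <- tp + 1L
      } else if (op %in% c("I", "S")) {
        q2t[[length(q2t) + 1L]] <- c(qp, NA)
        qp <- qp + 1L
      } # H consumes nothing
    }
  }
  list(
    t2q = do.call(rbind, t2q),
    q2t = do.call(rbind, q2t)
  )
}

# Interval image under the per-base map: the span of paired destination
# positions for source positions in [s, e).
per_base_project <- function(map, s, e) {
  rows <- map[map[, 1] >= s & map[, 1] < e & !is.na(map[, 2]), , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  c(min(rows[, 2]), max(rows[, 2]) + 1L)
}

# Random extended CIGAR whose target span is roughly `len` bases.
random_cigar <- function(len, p_event = 0.05) {
  ops <- character(0)
  lens <- integer(0)
  remaining <- len
  while (remaining > 0L) {
    run <- min(remaining, 1L + stats::rgeom(1, p_event))
    ops <- c(ops, "=")
    lens <- c(lens, run)
    remaining <- remaining - run
    if (remaining > 0L) {
      ev <- sample(c("X", "I", "D"), 1L)
      el <- sample(1:3, 1L)
      ops <- c(ops, ev)
      lens <- c(lens, if (ev == "X") min(el, remaining) else el)
      if (ev %in% c("X", "D")) remaining <- remaining - min(el, remaining)
    }
  }
  paste0(lens, ops, collapse = "")
}

# Brute-force phasing oracle: enumerate both relative phases of every
# adjacent pair (equivalently all assignments with variant 1 fixed) and pick
# the one maximizing total read concordance.
brute_force_phase <- function(allele_mat) {
  n <- ncol(allele_mat)
  stopifnot(n <= 12)
  best <- NULL
  best_score <- -Inf
  grid <- expand.grid(rep(list(0:1), n - 1L))
  for (r in seq_len(nrow(grid))) {
    phi <- c(0L, as.integer(grid[r, ]))
    hapA <- ifelse(phi == 0L, "ref", "alt")
    hapB <- ifelse(phi == 0L, "alt", "ref")
    score <- sum(apply(allele_mat, 1L, function(obs) {
      max(
        sum(obs == hapA, na.rm = TRUE),
        sum(obs == hapB, na.rm = TRUE)
      )
    }))
    if (score > best_score) {
      best_score <- score
      best <- phi
    }
  }
  list(phi = best, score = best_score)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One-row alignment tibble in the package's SAM-derived layout.
make_aln <- function(qname, tname, target_start, cigar, seq,
                     qual = strrep("?", nchar(seq)), mapq = 60L, hp = NA_integer_) {
  tibble::tibble(
    qname = qname, flag = 0L, tname = tname,
    target_start = as.integer(target_start), mapq = mapq, cigar = cigar,
    seq = seq, qual = qual, strand = "+", hp = hp,
    query_len = nchar(seq)
  )
}

# Build a pileup of n_ref reads showing the reference and n_alt reads showing
# `alt` at 0-based position `pos` of `ref_seq`, all spanning the full contig.
make_site_pileup <- function(ref_seq, pos, alt, n_ref, n_alt, contig = "c") {
  L <- nchar(ref_seq)
  alt_seq <- ref_seq
  substr(alt_seq, pos + 1L, pos + 1L) <- alt
  cig_ref <- paste0(L, "=")
  cig_alt <- paste0(pos, "=1X", L - pos - 1L, "=")
  dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_ref), function(i) {
      make_aln(paste0("ref", i), contig, 0L, cig_ref, ref_seq)
    }),
    purrr::map_dfr(seq_len(n_alt), function(i) {
      make_aln(paste0("alt", i), contig, 0L, cig_alt, alt_seq)
    })
  )
}
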