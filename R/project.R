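# Coordinate projection through CIGAR alignments. This is the shared liftover
# primitive used by the phasing stage (variant blocks -> read coordinates) and
# the evaluation suite (error k-mers -> unpolished assembly coordinates).

#' Construct a minimal alignment record
#'
#' A lightweight list describing one pairwise alignment, the unit consumed by
#' [project_intervals()] and the phasing/scoring operations. `target_start` is
#' 0-based; `cigar` must use extended (`=`/`X`) operations for any operation
#' that inspects identity.
#'
#' @param qname,tname Query/target sequence names.
#' @param cigar CIGAR string.
#' @param target_start 0-based target start.
#' @param strand `"+"` or `"-"` (query orientation relative to target).
#' @param query_len Full query length (needed to normalize `-`-strand output).
#' @param mapq Mapping quality.
#' @return A list with class `aln_record`.
#' @export
aln_record <- function(qname = "q", tname = "t", cigar = "", target_start = 0L,
                       strand = "+", query_len = NA_integer_, mapq = 60L) {
  structure(
    list(
      qname = qname, tname = tname, cigar = cigar,
      target_start = as.integer(target_start), strand = strand,
      query_len = query_len, mapq = mapq
    ),
    class = "aln_record"
  )
}

.as_aln <- function(aln) {
  if (inherits(aln, "aln_record")) return(aln)
  if (is.data.frame(aln)) {
    stopifnot(nrow(aln) == 1L)
    aln <- as.list(aln)
  }
  if (is.null(aln$strand)) aln$strand <- "+"
  if (is.null(aln$query_len)) aln$query_len <- NA_integer_
  aln
}

# Generic source->dest op layout. Collapse ops (consume source, no dest) are
# interpolated flat; jump ops (dest only) advance dest at a fixed source
# boundary. Soft clips consume query only; hard clips consume nothing.
.proj_layout <- function(aln, direction) {
  lay <- cigar_layout(aln$cigar, aln$target_start)
  lay <- lay[lay$op != "H", , drop = FALSE]
  if (direction == "t2q") {
    s0 <- lay$t0; s1 <- lay$t1; d0 <- lay$q0; d1 <- lay$q1
  } else {
    s0 <- lay$q0; s1 <- lay$q1; d0 <- lay$t0; d1 <- lay$t1
  }
  both <- (s1 > s0) & (d1 > d0)
  list(
    s0 = s0, s1 = s1, d0 = d0, d1 = d1, both = both,
    s_min = min(s0), s_max = max(s1), d_min = min(d0), d_max = max(d1)
  )
}

# Map one source boundary. side = "L": position after any dest-only jump at b
# (used for interval starts); side = "R": before the jump (interval ends).
# Boundaries outside the alignment span are clamped to it.
.map_boundary <- function(b, L, side) {
  b <- min(max(b, L$s_min), L$s_max)
  cand <- if (side == "L") L$s1 <= b else (L$s1 <= b & L$s1 > L$s0)
  base <- if (any(cand)) max(L$d1[cand]) else L$d_min
  inside <- which(L$s0 < b & b < L$s1)
  if (length(inside)) {
    i <- inside[[1]]
    base <- max(base, L$d0[[i]] + if (L$both[[i]]) b - L$s0[[i]] else 0L)
  }
  base
}

#' Project intervals through an alignment
#'
#' Maps interval coordinates from one side of a pairwise alignment to the
#' other by walking the CIGAR. Portions falling in sequence that does not
#' exist on the destination side (deleted or inserted on the source side) are
#' clipped; intervals whose image is empty are dropped. Intervals outside the
#' alignment span are clipped to it.
#'
#' Insertions (destination-only sequence) strictly inside an interval are
#' included in its image; insertions at interval edges are excluded.
#'
#' @param ints Interval tibble (0-based half-open) on the source coordinate
#'   system: target coordinates for `direction = "t2q"`, query coordinates for
#'   `"q2t"`.
#' @param aln An [aln_record()] (or one-row tibble with the same fields).
#' @param direction `"t2q"` (target to query) or `"q2t"`.
#' @param normalize_strand If `TRUE` and the alignment is on the `-` strand,
#'   query-side output is flipped to forward-strand coordinates (requires
#'   `query_len`). With the default `FALSE`, query coordinates refer to the
#'   stored (aligned) orientation, which is what sequence extraction from SAM
#'   records expects.
#' @return Interval tibble on the destination coordinate system; a `src` column
#'   keeps the row index of the originating interval.
#' @export
project_intervals <- function(ints, aln, direction = c("t2q", "q2t"),
                              normalize_strand = FALSE) {
  direction <- match.arg(direction)
  aln <- .as_aln(aln)
  L <- .proj_layout(aln, direction)
  dest_contig <- if (direction == "t2q") aln$qname else aln$tname
  out <- purrr::map_dfr(seq_len(nrow(ints)), function(i) {
    a <- .map_boundary(ints$start[[i]], L, "L")
    b <- .map_boundary(ints$end[[i]], L, "R")
    if (b <= a) return(NULL)
    tibble::tibble(
      contig = dest_contig, start = as.integer(a),
      end = as.integer(b), src = i
    )
  })
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      contig = character(), start = integer(),
      end = integer(), src = integer()
    ))
  }
  if (normalize_strand && identical(aln$strand, "-") && direction == "t2q") {
    qlen <- aln$query_len
    stopifnot(!is.na(qlen))
    new_start <- qlen - out$end
    out$end <- qlen - out$start
    out$start <- new_start
    out <- out[order(out$start), , drop = FALSE]
  }
  out
}

#' Project a single position through an alignment
#'
#' Convenience wrapper around [project_intervals()] for a width-1 interval.
#' Returns `NA` when the base has no image (deleted on the other side).
#'
#' @param pos 0-based source position.
#' @inheritParams project_intervals
#' @return A single integer destination position, or `NA`.
#' @export
project_position <- function(pos, aln, direction = c("t2q", "q2t")) {
  direction <- match.arg(direction)
  res <- project_intervals(
    intervals("x", pos, pos + 1L), aln, direction
  )
  if (nrow(res) == 0L) NA_integer_ else res$start[[1]]
}
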