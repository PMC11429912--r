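# Interval tibbles: contig, start, end -- 0-based half-open throughout the
# package; conversion to 1-based happens only at VCF write time.

#' Construct an interval tibble
#'
#' @param contig Character vector of contig names.
#' @param start,end 0-based half-open bounds.
#' @return A tibble with columns `contig`, `start`, `end`.
#' @export
intervals <- function(contig = character(), start = integer(), end = integer()) {
  stopifnot(all(start <= end), all(start >= 0))
  tibble::tibble(
    contig = as.character(contig),
    start = as.integer(start), end = as.integer(end)
  )
}

.as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

.from_iranges <- function(ir, contig) {
  tibble::tibble(
    contig = contig,
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir)
  )
}

.per_contig_setop <- function(a, b, fun) {
  contigs <- union(unique(a$contig), unique(b$contig))
  purrr::map_dfr(contigs, function(ct) {
    ia <- .as_iranges(a[a$contig == ct, , drop = FALSE])
    ib <- .as_iranges(b[b$contig == ct, , drop = FALSE])
    .from_iranges(fun(IRanges::reduce(ia), IRanges::reduce(ib)), ct)
  })
}

#' Merge (union) overlapping or adjacent intervals per contig
#' @param x Interval tibble.
#' @return Interval tibble with disjoint, sorted intervals.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(intervals())
  purrr::map_dfr(split(x, x$contig), function(g) {
    .from_iranges(IRanges::reduce(.as_iranges(g)), g$contig[[1]])
  })
}

#' Interval set operations per contig
#'
#' Thin wrappers over IRanges set arithmetic, operating on 0-based half-open
#' interval tibbles.
#' @param a,b Interval tibbles.
#' @return Interval tibble.
#' @export
intersect_intervals <- function(a, b) .per_contig_setop(a, b, IRanges::intersect)

#' @rdname intersect_intervals
#' @export
setdiff_intervals <- function(a, b) .per_contig_setop(a, b, IRanges::setdiff)

#' Total length in bases of an interval tibble
#' @param x Interval tibble.
#' @return Integer total of `end - start`.
#' @export
interval_span <- function(x) sum(x$end - x$start)

#' Do intervals in `a` overlap any interval in `b`?
#' @param a,b Interval tibbles.
#' @return Logical vector along rows of `a`.
#' @export
overlaps_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical())
  vapply(seq_len(nrow(a)), function(i) {
    bb <- b[b$contig == a$contig[[i]], , drop = FALSE]
    any(bb$start < a$end[[i]] & bb$end > a$start[[i]])
  }, logical(1))
}
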