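#' Parse a CIGAR string into an operation table
#'
#' Splits an extended CIGAR (`=`/`X`/`I`/`D`/`S`/`H`, plus `M`/`N` which are
#' accepted but rejected by operations that require unambiguous identity) into
#' one row per run.
#'
#' @param cigar A single CIGAR string, e.g. `"50=1X49="`.
#' @return A tibble with columns `op` (character) and `len` (integer).
#' @examples
#' parse_cigar("10=2D5=")
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  if (cigar == "" || cigar == "*") {
    return(tibble::tibble(op = character(), len = integer()))
  }
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  if (nrow(m) == 0L || sum(nchar(m[, 1])) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  tibble::tibble(op = m[, 3], len = as.integer(m[, 2]))
}

#' Collapse an operation table back into a CIGAR string
#'
#' Adjacent runs of the same operation are merged; zero-length runs dropped.
#'
#' @param ops A tibble with columns `op` and `len`.
#' @return A CIGAR string.
#' @export
cigar_string <- function(ops) {
  ops <- ops[ops$len > 0L, , drop = FALSE]
  if (nrow(ops) == 0L) return("")
  grp <- cumsum(c(TRUE, ops$op[-1] != ops$op[-nrow(ops)]))
  len <- as.integer(tapply(ops$len, grp, sum))
  op <- ops$op[!duplicated(grp)]
  paste0(len, op, collapse = "")
}

# op classes per SAM: which side of the alignment each operation consumes
.q_ops <- c("M", "=", "X", "I", "S")
.t_ops <- c("M", "=", "X", "D", "N")

#' Per-operation coordinate layout of an alignment
#'
#' Annotates each CIGAR run with its half-open query span `[q0, q1)` (read
#' coordinates in the stored orientation, soft clips included) and target span
#' `[t0, t1)` (absolute, using `target_start`).
#'
#' @param cigar CIGAR string.
#' @param target_start 0-based target start of the alignment.
#' @return A tibble with columns `op`, `len`, `q0`, `q1`, `t0`, `t1`.
#' @export
cigar_layout <- function(cigar, target_start = 0L) {
  ops <- parse_cigar(cigar)
  dq <- ifelse(ops$op %in% .q_ops, ops$len, 0L)
  dt <- ifelse(ops$op %in% .t_ops, ops$len, 0L)
  ops$q1 <- cumsum(dq)
  ops$q0 <- ops$q1 - dq
  ops$t1 <- as.integer(target_start) + cumsum(dt)
  ops$t0 <- ops$t1 - dt
  ops
}

#' Gap-compressed mismatch ratio of an alignment
#'
#' Divergence measure where every mismatch column counts individually but each
#' insertion or deletion run counts once regardless of its length:
#' `(nX + I_events + D_events) / (n= + nX + I_events + D_events)`.
#' Used to drop reads too diverged from the assembly before variant calling
#' (cutoff 0.02) and again before polishing (cutoff 0.002).
#'
#' @param cigar Extended CIGAR string (`=`/`X` required; `M` is rejected as
#'   ambiguous).
#' @return The ratio as a single double in `[0, 1]`.
#' @examples
#' gap_compressed_mismatch_ratio("90=5I5=") # one gap event over 95 match cols
#' @export
gap_compressed_mismatch_ratio <- function(cigar) {
  ops <- parse_cigar(cigar)
  if (any(ops$op %in% c("M", "N"))) {
    stop("CIGAR contains 'M'/'N'; extended =/X CIGARs are required")
  }
  n_eq <- sum(ops$len[ops$op == "="])
  n_x <- sum(ops$len[ops$op == "X"])
  n_ins <- sum(ops$op == "I")
  n_del <- sum(ops$op == "D")
  denom <- n_eq + n_x + n_ins + n_del
  if (denom == 0L) stop("empty alignment: mismatch ratio undefined")
  (n_x + n_ins + n_del) / denom
}

#' Filter alignment records by gap-compressed mismatch ratio
#'
#' Keeps records whose ratio is less than or equal to `max_ratio`. This is the
#' strict pre-variant-calling filter (default 0.02) and, with
#' `max_ratio = 0.002`, the final filter applied before polishing.
#'
#' @param alns Alignment tibble with a `cigar` column.
#' @param max_ratio Maximum allowed gap-compressed mismatch ratio.
#' @return The filtered tibble, with a `mismatch_ratio` column added.
#' @export
filter_by_mismatch_ratio <- function(alns, max_ratio = 0.02) {
  if (nrow(alns) == 0L) {
    return(dplyr::mutate(alns, mismatch_ratio = double()))
  }
  alns$mismatch_ratio <- vapply(alns$cigar, gap_compressed_mismatch_ratio,
    numeric(1),
    USE.NAMES = FALSE
  )
  dplyr::filter(alns, .data$mismatch_ratio <= max_ratio)
}
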