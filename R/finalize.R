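# Class-specific GQ filtering of proposed edits and sequence-level
# application of the survivors.

#' Classify edits as 1 bp insertion, 1 bp deletion, or other
#'
#' `INS1`: alt is ref (the 1 bp anchor) plus one base; `DEL1`: ref is alt
#' plus one base; everything else (SNVs, longer indels, complex records) is
#' `OTHER`. These are the classes the GQ filter treats separately, because
#' 1 bp indel edits are the ones most prone to inducing new errors.
#'
#' @param edits Edit tibble with `ref`, `alt` columns.
#' @return Character vector along rows of `edits`.
#' @export
classify_edit <- function(edits) {
  if (nrow(edits) == 0L) return(character())
  nr <- nchar(edits$ref)
  na <- nchar(edits$alt)
  dplyr::case_when(
    na - nr == 1L & nr == 1L & substr(edits$alt, 1L, 1L) == edits$ref ~ "INS1",
    nr - na == 1L & na == 1L & substr(edits$ref, 1L, 1L) == edits$alt ~ "DEL1",
    TRUE ~ "OTHER"
  )
}

#' GQ filter policy per edit class
#'
#' Defaults are the optimized cutoffs: GQ 20 for 1 bp insertions, GQ 12 for
#' 1 bp deletions, GQ 5 for all other edits.
#'
#' @param ins1,del1,other Minimum GQ per class (kept if `GQ >= cutoff`).
#' @return List of class `filter_policy`.
#' @export
filter_policy <- function(ins1 = 20, del1 = 12, other = 5) {
  stopifnot(ins1 >= 0, del1 >= 0, other >= 0)
  structure(list(ins1 = ins1, del1 = del1, other = other),
    class = "filter_policy"
  )
}

#' Apply the class-specific GQ filter
#'
#' Keeps an edit iff its GQ is at or above its class cutoff. Idempotent.
#'
#' @param edits Edit tibble with `gq` and (optionally) `class` columns; the
#'   class is computed when absent.
#' @param policy A [filter_policy()].
#' @return The kept subset.
#' @export
apply_gq_filters <- function(edits, policy = filter_policy()) {
  if (nrow(edits) == 0L) return(edits)
  if (!"class" %in% names(edits)) edits$class <- classify_edit(edits)
  cut <- c(
    INS1 = policy$ins1, DEL1 = policy$del1,
    OTHER = policy$other
  )[edits$class]
  edits[edits$gq >= cut, , drop = FALSE]
}

# Resolve overlapping REF spans: keep the higher-GQ edit, ties to the
# leftmost record.
.resolve_overlaps <- function(edits) {
  if (nrow(edits) < 2L) return(edits)
  edits <- edits[order(-edits$gq, edits$pos), , drop = FALSE]
  keep <- logical(nrow(edits))
  covered_start <- integer(0)
  covered_end <- integer(0)
  for (i in seq_len(nrow(edits))) {
    s <- edits$pos[[i]]
    e <- s + nchar(edits$ref[[i]]) - 1L
    if (!any(covered_start <= e & covered_end >= s)) {
      keep[[i]] <- TRUE
      covered_start <- c(covered_start, s)
      covered_end <- c(covered_end, e)
    }
  }
  out <- edits[keep, , drop = FALSE]
  out[order(out$pos), , drop = FALSE]
}

#' Apply VCF-style edits to a sequence
#'
#' Substitutes each record's ALT for its REF span with cumulative coordinate
#' shifting; the output length is the input length plus the summed length
#' differences. Overlapping records are resolved first (higher GQ wins, ties
#' to the leftmost). A REF string that disagrees with the sequence at its
#' position is a hard error naming the locus -- the guard that catches
#' coordinate bookkeeping bugs.
#'
#' @param seq Sequence string.
#' @param edits Edit tibble (`pos` 1-based, `ref`, `alt`, optional `gq`).
#' @return The edited sequence.
#' @export
apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0L) return(seq)
  if (!"gq" %in% names(edits)) edits$gq <- 99
  edits <- .resolve_overlaps(edits)
  .apply_edit_table(seq, edits, check_ref = TRUE)$seq
}

#' Apply per-haplotype edits to a diploid assembly
#'
#' @param assembly A `diploid_assembly`.
#' @param edits Edit tibble with `hap` (1/2) and `contig` (haplotype contig
#'   name) columns.
#' @return The polished `diploid_assembly`.
#' @export
apply_edits_assembly <- function(assembly, edits) {
  for (h in 1:2) {
    hk <- paste0("hap", h)
    for (ct in names(assembly[[hk]])) {
      e <- edits[edits$hap == h & edits$contig == ct, , drop = FALSE]
      if (nrow(e)) {
        assembly[[hk]][[ct]] <- apply_edits(assembly[[hk]][[ct]], e)
      }
    }
  }
  assembly
}
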