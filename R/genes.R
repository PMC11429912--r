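# Gene-impact analysis on coding sequences: frameshifts from alignment gaps,
# premature stop codons, and nonsynonymous substitutions.

#' Detect frameshift-inducing gaps in a CDS alignment
#'
#' Scans a gapped pairwise alignment of an annotated CDS against its
#' reference CDS and reports every gap whose length is not a multiple of 3,
#' or longer than 30 bp (long in-frame gaps are treated as disruptive too).
#'
#' @param ref_aln,alt_aln Equal-length aligned sequences with `-` gaps
#'   (reference CDS and assembly CDS rows).
#' @param transcript_id Identifier attached to the output.
#' @return Tibble `transcript_id`, `cds_pos` (0-based position in the
#'   ungapped reference CDS at which the gap opens), `gap_len`, `gap_in`
#'   (`"ref"` = insertion in the assembly, `"alt"` = deletion), `frameshift`
#'   (always `TRUE` rows only).
#' @export
detect_frameshifts <- function(ref_aln, alt_aln, transcript_id = "tx") {
  stopifnot(nchar(ref_aln) == nchar(alt_aln))
  rows <- list(ref = ref_aln, alt = alt_aln)
  out <- purrr::map_dfr(names(rows), function(which_row) {
    chars <- strsplit(rows[[which_row]], "", fixed = TRUE)[[1]]
    r <- rle(chars == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gaps <- which(r$values)
    if (length(gaps) == 0L) return(NULL)
    ref_chars <- strsplit(ref_aln, "", fixed = TRUE)[[1]]
    ref_consumed <- cumsum(ref_chars != "-")
    purrr::map_dfr(gaps, function(g) {
      len <- r$lengths[[g]]
      tibble::tibble(
        transcript_id = transcript_id,
        cds_pos = if (starts[[g]] == 1L) 0L else ref_consumed[[starts[[g]] - 1L]],
        gap_len = len,
        gap_in = which_row
      )
    })
  })
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      transcript_id = character(), cds_pos = integer(),
      gap_len = integer(), gap_in = character(), frameshift = logical()
    ))
  }
  out$frameshift <- (out$gap_len %% 3L != 0L) | (out$gap_len > 30L)
  out[out$frameshift, , drop = FALSE]
}

.split_codons <- function(cds) {
  n <- nchar(cds)
  n3 <- n - n %% 3L
  if (n3 < n) {
    message("CDS length not divisible by 3; trailing ", n - n3, " base(s) ignored")
  }
  if (n3 == 0L) return(character())
  substring(cds, seq(1L, n3, by = 3L), seq(3L, n3, by = 3L))
}

#' Detect premature stop codons in a CDS
#'
#' Reports every in-frame stop codon (TAA/TAG/TGA) strictly before the final
#' codon of the sequence.
#'
#' @param cds_seq Coding sequence (a trailing partial codon is ignored with
#'   a message).
#' @return Integer vector of 1-based codon indices.
#' @export
detect_premature_stops <- function(cds_seq) {
  codons <- .split_codons(toupper(cds_seq))
  if (length(codons) < 2L) return(integer())
  idx <- which(codons %in% c("TAA", "TAG", "TGA"))
  idx[idx < length(codons)]
}

#' Detect nonsynonymous substitutions between two in-frame CDSs
#'
#' Compares codon by codon and reports codons that differ in nucleotide AND
#' in the amino acid they encode (synonymous changes are excluded). Lengths
#' must match; indels belong to the frameshift analysis.
#'
#' @param cds_ref,cds_alt Equal-length coding sequences, lengths divisible
#'   by 3.
#' @return Tibble `codon_index` (1-based), `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`.
#' @export
detect_nonsynonymous <- function(cds_ref, cds_alt) {
  if (nchar(cds_ref) != nchar(cds_alt)) {
    stop("CDS length mismatch: indels belong to the frameshift analysis")
  }
  stopifnot(nchar(cds_ref) %% 3L == 0L)
  rc <- .split_codons(toupper(cds_ref))
  ac <- .split_codons(toupper(cds_alt))
  diff <- which(rc != ac)
  gc <- Biostrings::GENETIC_CODE
  out <- tibble::tibble(
    codon_index = diff,
    ref_codon = rc[diff],
    alt_codon = ac[diff],
    ref_aa = unname(gc[rc[diff]]),
    alt_aa = unname(gc[ac[diff]])
  )
  out[!is.na(out$ref_aa) & !is.na(out$alt_aa) & out$ref_aa != out$alt_aa, ,
    drop = FALSE
  ]
}
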