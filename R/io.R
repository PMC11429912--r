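# Readers and writers for the plain-text formats the pipeline touches.
# FASTA/FASTQ go through Biostrings; SAM (text), PAF and VCF are simple
# tab-separated mappings onto tibbles.

#' Read / write FASTA as a named character vector
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual` (phred+33 string).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  if (nrow(reads) == 0L) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  # plain 4-line records: the fixed-width writer in Biostrings cannot handle
  # reads longer than its internal line buffer (~20 kb), which HiFi and
  # ultra-long reads routinely exceed
  lines <- character(4L * nrow(reads))
  lines[seq(1L, length(lines), by = 4L)] <- paste0("@", reads$read_id)
  lines[seq(2L, length(lines), by = 4L)] <- reads$seq
  lines[seq(3L, length(lines), by = 4L)] <- "+"
  lines[seq(4L, length(lines), by = 4L)] <- reads$qual
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read FASTQ into a reads tibble
#' @param path FASTQ path.
#' @return Tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path)
  stopifnot(length(lines) %% 4L == 0L)
  tibble::tibble(
    read_id = sub("\\s.*$", "", sub("^@", "", lines[seq(1L, length(lines), by = 4L)])),
    seq = lines[seq(2L, length(lines), by = 4L)],
    qual = lines[seq(4L, length(lines), by = 4L)]
  )
}

# ---- SAM ------------------------------------------------------------------

.empty_aln_tbl <- function() {
  tibble::tibble(
    qname = character(), flag = integer(), tname = character(),
    target_start = integer(), mapq = integer(), cigar = character(),
    seq = character(), qual = character(), strand = character(),
    hp = integer(), query_len = integer()
  )
}

#' Write alignment records as SAM text
#'
#' Emits a minimal SAM file (`@HD`/`@SQ` header plus 11 mandatory columns and
#' an `HP:i` tag when present). CIGARs are written as stored, i.e. with
#' extended `=`/`X` operations.
#'
#' @param alns Alignment tibble (columns `qname`, `flag`, `tname`,
#'   `target_start` 0-based, `mapq`, `cigar`, `seq`, `qual`, optional `hp`).
#' @param path Output path.
#' @param ref_lengths Named integer vector of reference lengths for `@SQ`.
#' @export
write_sam <- function(alns, path, ref_lengths) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths))
  )
  flag <- if ("flag" %in% names(alns)) alns$flag else rep(0L, nrow(alns))
  qual <- if ("qual" %in% names(alns)) alns$qual else rep("*", nrow(alns))
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
    alns$qname, flag, alns$tname, alns$target_start + 1L,
    alns$mapq, alns$cigar, alns$seq, qual
  )
  if ("hp" %in% names(alns)) {
    has_hp <- !is.na(alns$hp)
    body[has_hp] <- paste0(body[has_hp], sprintf("\tHP:i:%d", alns$hp[has_hp]))
  }
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM text into an alignment tibble
#'
#' Keeps primary aligned records by default (unmapped, secondary and
#' supplementary records dropped). Coordinates are converted to the package's
#' 0-based convention.
#'
#' @param path SAM file path.
#' @param primary_only Drop secondary/supplementary/unmapped records.
#' @return Alignment tibble; `strand` is derived from the flag, `query_len`
#'   from the stored sequence, and `hp` from an `HP:i` tag when present.
#' @export
read_sam <- function(path, primary_only = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(.empty_aln_tbl())
  f <- strsplit(lines, "\t", fixed = TRUE)
  hp <- vapply(f, function(x) {
    tag <- grep("^HP:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^HP:i:", "", tag[[1]])) else NA_integer_
  }, integer(1))
  out <- tibble::tibble(
    qname = vapply(f, `[[`, "", 1),
    flag = as.integer(vapply(f, `[[`, "", 2)),
    tname = vapply(f, `[[`, "", 3),
    target_start = as.integer(vapply(f, `[[`, "", 4)) - 1L,
    mapq = as.integer(vapply(f, `[[`, "", 5)),
    cigar = vapply(f, `[[`, "", 6),
    seq = vapply(f, `[[`, "", 10),
    qual = vapply(f, `[[`, "", 11),
    hp = hp
  )
  out$strand <- ifelse(bitwAnd(out$flag, 16L) > 0L, "-", "+")
  out$query_len <- nchar(out$seq)
  if (primary_only) {
    out <- dplyr::filter(
      out,
      bitwAnd(.data$flag, 0x904L) == 0L, .data$cigar != "*"
    )
  }
  out
}

# ---- PAF ------------------------------------------------------------------

#' Read a PAF file (with `cg:Z` CIGAR tags) into an alignment tibble
#'
#' The stored CIGAR is augmented with soft clips covering the unaligned query
#' ends, so query offsets computed from it are absolute coordinates in the
#' stored (alignment) orientation, matching SAM-derived records.
#'
#' @param path PAF file path.
#' @return Alignment tibble with PAF span columns retained
#'   (`query_start`, `query_end`, `target_end`).
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0L) {
    out <- .empty_aln_tbl()
    out$query_start <- integer()
    out$query_end <- integer()
    out$target_end <- integer()
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  cg <- vapply(f, function(x) {
    tag <- grep("^cg:Z:", x[-(1:12)], value = TRUE)
    if (length(tag)) sub("^cg:Z:", "", tag[[1]]) else NA_character_
  }, character(1))
  qlen <- as.integer(vapply(f, `[[`, "", 2))
  qs <- as.integer(vapply(f, `[[`, "", 3))
  qe <- as.integer(vapply(f, `[[`, "", 4))
  strand <- vapply(f, `[[`, "", 5)
  lead <- ifelse(strand == "+", qs, qlen - qe)
  trail <- ifelse(strand == "+", qlen - qe, qs)
  cigar <- paste0(
    ifelse(lead > 0L, paste0(lead, "S"), ""), cg,
    ifelse(trail > 0L, paste0(trail, "S"), "")
  )
  tibble::tibble(
    qname = vapply(f, `[[`, "", 1),
    flag = 0L,
    tname = vapply(f, `[[`, "", 6),
    target_start = as.integer(vapply(f, `[[`, "", 8)),
    mapq = as.integer(vapply(f, `[[`, "", 12)),
    cigar = cigar,
    seq = NA_character_, qual = NA_character_,
    strand = strand, hp = NA_integer_, query_len = qlen,
    query_start = qs, query_end = qe,
    target_end = as.integer(vapply(f, `[[`, "", 9))
  )
}

# ---- BED ------------------------------------------------------------------

#' Read / write BED3 interval files
#'
#' BED uses the same 0-based half-open convention as the package's interval
#' tibbles, so this is a direct column mapping.
#'
#' @param path File path.
#' @return `read_bed()` returns an interval tibble.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c("contig", "start", "end"),
    col_types = "cii", comment = "#"
  )
  tibble::as_tibble(x)
}

#' @param ints Interval tibble.
#' @rdname read_bed
#' @export
write_bed <- function(ints, path) {
  readr::write_tsv(ints[, c("contig", "start", "end")], path,
    col_names = FALSE
  )
  invisible(path)
}

# ---- VCF ------------------------------------------------------------------

#' Write polishing edits as VCF v4.2
#'
#' Emits `CHROM POS ID REF ALT QUAL FILTER INFO FORMAT sample` with genotype
#' `1/1` and the edit's GQ. `pos` is 1-based (records produced by the package
#' are already VCF-style).
#'
#' @param edits Edit tibble with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `gq`.
#' @param path Output path.
#' @param contig_lengths Optional named lengths for `##contig` header lines.
#' @param sample Sample column name.
#' @export
write_vcf <- function(edits, path, contig_lengths = NULL, sample = "polish") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf(
      "##contig=<ID=%s,length=%d>",
      names(contig_lengths), as.integer(contig_lengths)
    ))
  }
  hdr <- c(hdr, paste0(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample
  ))
  if (!"gq" %in% names(edits)) edits$gq <- 99
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:GQ\t1/1:%d",
    edits$contig, edits$pos, edits$ref, edits$alt,
    as.integer(round(edits$gq))
  )
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into an edit tibble
#'
#' Parses the 10-column single-sample layout written by [write_vcf()] (and by
#' common variant callers); multi-allelic records are split is not supported.
#'
#' @param path VCF file path.
#' @return Tibble with `contig`, `pos` (1-based), `ref`, `alt`, `gq`.
#' @export
read_vcf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      contig = character(), pos = integer(),
      ref = character(), alt = character(), gq = double()
    ))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  gq <- vapply(f, function(x) {
    if (length(x) < 10L) return(NA_real_)
    fmt <- strsplit(x[[9]], ":", fixed = TRUE)[[1]]
    val <- strsplit(x[[10]], ":", fixed = TRUE)[[1]]
    i <- match("GQ", fmt)
    if (is.na(i) || i > length(val)) NA_real_ else as.numeric(val[[i]])
  }, numeric(1))
  tibble::tibble(
    contig = vapply(f, `[[`, "", 1),
    pos = as.integer(vapply(f, `[[`, "", 2)),
    ref = vapply(f, `[[`, "", 4),
    alt = vapply(f, `[[`, "", 5),
    gq = gq
  )
}
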