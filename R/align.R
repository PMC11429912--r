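# Thin wrapper around minimap2 (run as-is, as an external tool) for the
# alignment steps of the end-to-end pipeline. All presets request extended
# =/X CIGARs, which every downstream operation relies on.

#' Is minimap2 available on the PATH?
#' @return Logical.
#' @export
minimap2_available <- function() nzchar(Sys.which("minimap2"))

.minimap2 <- function(args, out_path) {
  if (!minimap2_available()) {
    stop(
      "minimap2 not found on PATH; the end-to-end pipeline needs it ",
      "(individual components do not)"
    )
  }
  status <- system2("minimap2", args, stdout = out_path, stderr = FALSE)
  if (status != 0L) stop("minimap2 failed (exit ", status, ")")
  invisible(out_path)
}

#' Align reads to a reference with minimap2
#'
#' Runs minimap2 with extended-CIGAR output (`--eqx`) and a technology
#' preset, then parses the SAM into an alignment tibble (primary records
#' only).
#'
#' @param reads_fastq FASTQ path.
#' @param ref_fasta Reference FASTA path.
#' @param preset `"map-hifi"` or `"map-ont"`.
#' @param threads minimap2 thread count (1 keeps runs deterministic).
#' @return Alignment tibble (see [read_sam()]).
#' @export
minimap2_align <- function(reads_fastq, ref_fasta,
                           preset = c("map-hifi", "map-ont"), threads = 1L) {
  preset <- match.arg(preset)
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  .minimap2(c(
    "-a", "--eqx", "-L", "--secondary=no", "-t", threads,
    "-x", preset, shQuote(ref_fasta), shQuote(reads_fastq)
  ), sam)
  read_sam(sam)
}

#' Align one haplotype against the other with minimap2 (asm5 preset)
#'
#' Produces the haplotype-vs-haplotype PAF (with CIGAR) from which long
#' identical stretches are detected.
#'
#' @param query_fasta,target_fasta Haplotype FASTA paths.
#' @param threads minimap2 threads.
#' @return Alignment tibble (see [read_paf()]).
#' @export
minimap2_asm <- function(query_fasta, target_fasta, threads = 1L) {
  paf <- tempfile(fileext = ".paf")
  on.exit(unlink(paf))
  .minimap2(c(
    "-c", "--eqx", "-L", "--cs", "-t", threads, "-x", "asm5",
    shQuote(target_fasta), shQuote(query_fasta)
  ), paf)
  read_paf(paf)
}
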