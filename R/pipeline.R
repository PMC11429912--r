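# End-to-end orchestration: simulate -> align -> phase-aware reassignment ->
# polish -> filter/apply -> k-mer evaluation, with a machine-readable run
# manifest. Alignment runs through minimap2; everything else is in-package.

#' Pipeline configuration
#'
#' Bundles every stage parameter with its default: homozygous-region length
#' 20,000, het GQ 10, variant block minimum 100, mismatch-ratio filters
#' 0.02 / 0.002, ultra-long minimum 100,000, candidate support 3, window
#' grouping 50 / 100, GQ policy 20/12/5, k-mer size 31. Unknown keys are
#' rejected.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_contigs,contig_length,het_snv_rate,het_indel_rate,loh_count,loh_length
#'   Genome simulation parameters (see [generate_diploid()]).
#' @param error_snv_rate,error_indel_rate Draft corruption rates.
#' @param hifi_depth,ul_depth Read depths per haplotype.
#' @param min_homo_len,min_block,het_gq,pre_ratio,final_ratio,ul_min_len
#'   Phasing-stage parameters (see [pharaoh()]).
#' @param min_support,max_gap,max_window,depth_cap Polisher parameters.
#' @param gq_ins1,gq_del1,gq_other GQ filter policy.
#' @param k K-mer size for evaluation.
#' @param workdir Directory for intermediate files (default: tempdir).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_contigs = 1L, contig_length = 1e6,
                            het_snv_rate = 1e-3, het_indel_rate = 1e-4,
                            loh_count = 5L, loh_length = 25000L,
                            error_snv_rate = 1.5e-5, error_indel_rate = 5e-6,
                            hifi_depth = 40, ul_depth = 12,
                            min_homo_len = 20000L, min_block = 100L,
                            het_gq = 10, pre_ratio = 0.02,
                            final_ratio = 0.002, ul_min_len = 100000L,
                            min_support = 3L, max_gap = 50L,
                            max_window = 100L, depth_cap = 30L,
                            gq_ins1 = 20, gq_del1 = 12, gq_other = 5,
                            k = 31L, qv_margin = 1000L, workdir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' `read_config(write_config(cfg))` round-trips exactly; unknown keys in the
#' file are rejected.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$workdir <- if (is.null(x$workdir)) NULL else as.character(x$workdir)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

.stage_msg <- function(...) message("[hapolish] ", ...)

#' Run the full polishing pipeline on a simulated diploid
#'
#' Simulates a diploid genome with LOH intervals, corrupts it into a draft
#' with a recorded truth edit set, simulates HiFi-like and ultra-long reads
#' from the truth genome, aligns them to the draft with minimap2, reassigns
#' homozygous-region reads by ultra-long phasing evidence, polishes each
#' haplotype, applies the class-specific GQ filter, and evaluates the result
#' with k-mer QV plus truth-set comparisons.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`; see the manifest component for
#'   per-stage counts.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  wd <- config$workdir %||% file.path(tempdir(), paste0("hapolish_", config$seed))
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)

  # -- simulate -------------------------------------------------------------
  .stage_msg("simulating diploid genome (seed ", config$seed, ")")
  sim <- generate_diploid(
    seed = config$seed, n_contigs = config$n_contigs,
    contig_length = config$contig_length,
    het_snv_rate = config$het_snv_rate,
    het_indel_rate = config$het_indel_rate,
    loh_count = config$loh_count, loh_length = config$loh_length
  )
  corr <- corrupt_assembly(sim,
    error_snv_rate = config$error_snv_rate,
    error_indel_rate = config$error_indel_rate,
    seed = config$seed + 1000L
  )
  draft <- corr$draft
  truth_edits <- corr$truth_edits
  .stage_msg(
    nrow(sim$truth$het_variants), " het variants, ",
    nrow(truth_edits), " injected draft errors"
  )

  hifi <- simulate_reads(sim, hifi_profile(
    depth = config$hifi_depth,
    seed = config$seed + 2000L
  ))
  ul <- simulate_reads(sim, ul_profile(
    depth = config$ul_depth,
    seed = config$seed + 3000L
  ))
  .stage_msg(nrow(hifi$reads), " HiFi reads, ", nrow(ul$reads), " UL reads")

  f <- list(
    h1 = file.path(wd, "draft_h1.fa"), h2 = file.path(wd, "draft_h2.fa"),
    dip = file.path(wd, "draft_dip.fa"),
    hifi = file.path(wd, "hifi.fastq"), ul = file.path(wd, "ul.fastq"),
    edits = file.path(wd, "edits.vcf"), loh = file.path(wd, "loh.bed")
  )
  write_fasta(draft$hap1, f$h1)
  write_fasta(draft$hap2, f$h2)
  write_fasta(c(draft$hap1, draft$hap2), f$dip)
  write_fastq(hifi$reads, f$hifi)
  write_fastq(ul$reads, f$ul)
  write_bed(sim$truth$loh_intervals, f$loh)

  # -- align ----------------------------------------------------------------
  .stage_msg("aligning reads with minimap2")
  hifi_dip <- minimap2_align(f$hifi, f$dip, "map-hifi")
  hifi_h1 <- minimap2_align(f$hifi, f$h1, "map-hifi")
  hifi_h2 <- minimap2_align(f$hifi, f$h2, "map-hifi")
  ul_h1 <- minimap2_align(f$ul, f$h1, "map-ont")
  hvh <- minimap2_asm(f$h2, f$h1)

  assignments <- hifi_dip |>
    dplyr::distinct(.data$qname, .keep_all = TRUE) |>
    dplyr::transmute(
      read_id = .data$qname,
      hap = ifelse(grepl("_h1$", .data$tname), 1L, 2L)
    )

  # -- phase-aware reassignment --------------------------------------------
  .stage_msg("PHARAOH: reassigning homozygous-region reads")
  ph <- pharaoh(draft, hifi_h1, hifi_h2, ul_h1, hvh, assignments,
    min_homo_len = config$min_homo_len, min_block = config$min_block,
    het_gq = config$het_gq, pre_ratio = config$pre_ratio,
    ul_min_len = config$ul_min_len
  )
  asg <- ph$assignments

  # -- final alignment sets -------------------------------------------------
  hap_of <- stats::setNames(asg$hap_pharaoh, asg$read_id)
  pick <- function(alns, h) {
    ids <- names(hap_of)[hap_of == h]
    alns[alns$qname %in% ids, , drop = FALSE] |>
      dplyr::distinct(.data$qname, .keep_all = TRUE)
  }
  final_h1 <- final_alignment_filter(pick(hifi_h1, 1L), config$final_ratio)
  final_h2 <- final_alignment_filter(pick(hifi_h2, 2L), config$final_ratio)
  .stage_msg(
    "final alignments: ", nrow(final_h1), " on hap1, ",
    nrow(final_h2), " on hap2"
  )

  # -- polish ---------------------------------------------------------------
  .stage_msg("polishing haplotypes")
  pol <- list(
    h1 = polish_haplotype(draft$hap1, final_h1,
      min_support = config$min_support, max_gap = config$max_gap,
      max_span = config$max_window, depth_cap = config$depth_cap
    ),
    h2 = polish_haplotype(draft$hap2, final_h2,
      min_support = config$min_support, max_gap = config$max_gap,
      max_span = config$max_window, depth_cap = config$depth_cap
    )
  )
  edits <- dplyr::bind_rows(
    dplyr::mutate(pol$h1$edits, hap = 1L),
    dplyr::mutate(pol$h2$edits, hap = 2L)
  )
  policy <- filter_policy(config$gq_ins1, config$gq_del1, config$gq_other)
  kept <- apply_gq_filters(edits, policy)
  .stage_msg(nrow(edits), " proposed edits, ", nrow(kept), " pass GQ filter")
  polished <- apply_edits_assembly(draft, kept)
  if (nrow(kept)) {
    write_vcf(
      dplyr::mutate(kept, contig = .data$contig), f$edits,
      contig_lengths = c(nchar(draft$hap1), nchar(draft$hap2))
    )
  }

  # -- evaluate -------------------------------------------------------------
  .stage_msg("k-mer evaluation (k=", config$k, ")")
  db <- kmer_set(hifi$reads$seq, config$k)
  # QV is assessed on the contig interiors: the outermost qv_margin bases sit
  # under the read-coverage ramp at contig ends, where k-mers are absent from
  # the read set for depth reasons, not accuracy (the analogue of restricting
  # QV to well-covered confident regions)
  interior <- function(asm) {
    s <- c(asm$hap1, asm$hap2)
    m <- config$qv_margin
    vapply(s, function(x) substr(x, m + 1L, nchar(x) - m), character(1))
  }
  ek_draft <- error_kmers(interior(draft), db, config$k, "draft")
  ek_pol <- error_kmers(interior(polished), db, config$k, "polished")
  dq <- if (ek_draft$report$error_kmers > 0) {
    delta_qv(ek_draft$report$error_kmers, ek_pol$report$error_kmers)
  } else 0

  evalt <- .pipeline_truth_eval(sim, truth_edits, kept, ph, hifi$origins, config)

  manifest <- .build_manifest(
    config, sim, truth_edits, hifi, ul, ph, edits,
    kept, ek_draft, ek_pol, dq, evalt, f
  )
  structure(
    list(
      config = config, sim = sim, draft = draft, polished = polished,
      truth_edits = truth_edits, pharaoh = ph,
      polish = pol, edits = edits, kept_edits = kept,
      qv = list(draft = ek_draft$report, polished = ek_pol$report, delta = dq),
      truth_eval = evalt, manifest = manifest, files = f
    ),
    class = "pipeline_result"
  )
}

# Truth-set comparison: recovery of injected errors in unique sequence,
# unsupported-edit rate, and LOH read-assignment accuracy.
.pipeline_truth_eval <- function(sim, truth_edits, kept, ph, origins, config) {
  loh <- sim$truth$loh_intervals
  margin <- 100L
  in_loh <- function(hap, contig, pos) {
    vapply(seq_along(pos), function(i) {
      l <- loh[loh$contig == sub("_h[12]$", "", contig[[i]]), , drop = FALSE]
      if (nrow(l) == 0L) return(FALSE)
      s <- if (hap[[i]] == 1L) l$start_h1 else l$start_h2
      e <- if (hap[[i]] == 1L) l$end_h1 else l$end_h2
      any(pos[[i]] >= s - margin & pos[[i]] <= e + margin)
    }, logical(1))
  }
  te <- truth_edits
  te$in_loh <- if (nrow(te)) {
    in_loh(te$hap, te$contig, te$pos)
  } else logical()
  key <- function(x) paste(x$hap, x$contig, x$pos, x$ref, x$alt)
  te$corrected <- key(te) %in% key(kept)
  uniq <- te[!te$in_loh, , drop = FALSE]
  unsupported <- kept[!(key(kept) %in% key(te)), , drop = FALSE]
  genome_bp <- 2 * config$n_contigs * config$contig_length

  # LOH-origin reads whose alignment covers a phased flanking het
  asg <- ph$assignments
  loh_reads <- origins[in_loh(origins$hap, paste0(origins$contig, "_h1"),
    origins$start
  ), , drop = FALSE]
  acc <- NA_real_
  n_eval <- 0L
  if (nrow(loh_reads) && nrow(ph$hets)) {
    j <- dplyr::inner_join(loh_reads, asg, by = "read_id")
    j <- j[j$scored, , drop = FALSE]
    if (nrow(j)) {
      acc <- mean(j$hap.x == j$hap_pharaoh)
      n_eval <- nrow(j)
    }
  }
  list(
    truth_edits = te,
    recovery_unique = if (nrow(uniq)) mean(uniq$corrected) else NA_real_,
    n_unique = nrow(uniq),
    recovery_all = if (nrow(te)) mean(te$corrected) else NA_real_,
    unsupported_edits = nrow(unsupported),
    unsupported_per_500kb = nrow(unsupported) / (genome_bp / 5e5),
    loh_assignment_accuracy = acc,
    loh_reads_evaluated = n_eval
  )
}

.build_manifest <- function(config, sim, truth_edits, hifi, ul, ph, edits,
                            kept, ek_draft, ek_pol, dq, evalt, files) {
  counts <- tibble::tibble(
    stage = c(
      "simulate", "simulate", "simulate", "reads", "reads",
      "pharaoh", "pharaoh", "pharaoh", "polish", "polish",
      "eval", "eval", "eval", "eval", "eval", "eval"
    ),
    metric = c(
      "het_variants", "loh_intervals", "injected_errors",
      "hifi_reads", "ul_reads",
      "homozygous_regions", "phased_hets", "reads_scored",
      "proposed_edits", "kept_edits",
      "qv_draft", "qv_polished", "delta_qv",
      "recovery_unique", "unsupported_per_500kb", "loh_assignment_accuracy"
    ),
    value = c(
      nrow(sim$truth$het_variants), nrow(sim$truth$loh_intervals),
      nrow(truth_edits), nrow(hifi$reads), nrow(ul$reads),
      nrow(ph$regions), nrow(ph$hets), sum(ph$assignments$scored),
      nrow(edits), nrow(kept),
      ek_draft$report$qv, ek_pol$report$qv, dq,
      evalt$recovery_unique, evalt$unsupported_per_500kb,
      evalt$loh_assignment_accuracy
    )
  )
  existing <- unlist(files)[file.exists(unlist(files))]
  checksums <- tibble::tibble(
    file = basename(existing),
    md5 = unname(tools::md5sum(existing))
  )
  list(counts = counts, checksums = checksums)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(as.data.frame(x$manifest$counts), row.names = FALSE)
  invisible(x)
}

#' Write a pipeline manifest as TSV (counts plus a checksum block)
#'
#' @param result A `pipeline_result`.
#' @param path Output path.
#' @export
write_manifest <- function(result, path) {
  readr::write_tsv(result$manifest$counts, path)
  readr::write_tsv(result$manifest$checksums, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
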