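# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a phasing result into its per-read assignment table
#' @param x A `pharaoh_result`.
#' @param ... Unused.
#' @return Tibble with one row per read.
#' @method tidy pharaoh_result
#' @export
tidy.pharaoh_result <- function(x, ...) tibble::as_tibble(x$assignments)

#' @rdname tidy.pharaoh_result
#' @method glance pharaoh_result
#' @export
glance.pharaoh_result <- function(x, ...) {
  a <- x$assignments
  tibble::tibble(
    n_regions = nrow(x$regions),
    n_hets = nrow(x$hets),
    n_blocks = length(unique(x$hets$block_id)),
    n_scored = sum(a$scored),
    n_reassigned = sum(a$scored & a$hap != a$hap_pharaoh)
  )
}

#' Tidy a polishing result into its edit table
#' @param x A `polish_result`.
#' @param ... Unused.
#' @return Edit tibble.
#' @method tidy polish_result
#' @export
tidy.polish_result <- function(x, ...) tibble::as_tibble(x$edits)

#' @rdname tidy.polish_result
#' @method glance polish_result
#' @export
glance.polish_result <- function(x, ...) {
  tibble::tibble(
    n_candidates = x$n_candidates,
    n_windows = nrow(x$windows),
    n_edits = nrow(x$edits),
    n_ins1 = sum(x$edits$class == "INS1"),
    n_del1 = sum(x$edits$class == "DEL1"),
    n_other = sum(x$edits$class == "OTHER"),
    median_gq = stats::median(x$edits$gq)
  )
}

#' Tidy a GQ sweep into its cutoff curve
#' @param x A `gq_sweep`.
#' @param ... Unused.
#' @return The curve tibble.
#' @method tidy gq_sweep
#' @export
tidy.gq_sweep <- function(x, ...) tibble::as_tibble(x$curve)

#' @rdname tidy.gq_sweep
#' @method glance gq_sweep
#' @export
glance.gq_sweep <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$optimum), scenario = x$scenario)
}

#' Tidy a pipeline result into its manifest counts
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return Tibble `stage`, `metric`, `value`.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) x$manifest$counts

#' @rdname tidy.pipeline_result
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tidyr::pivot_wider(
    x$manifest$counts[, c("metric", "value")],
    names_from = "metric", values_from = "value"
  )
}
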