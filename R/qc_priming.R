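# QC for cDNA-synthesis batches with failed random priming, detected via
# sentinel genes that depend on random priming (non-polyadenylated RNAs such
# as 18S rRNA; optionally 5' regions of very long transcripts).

#' Screen cDNA batches for failed random priming
#'
#' A failed random-priming batch shifts the Cq of priming-dependent sentinel
#' genes (e.g. 18S rRNA, which has no poly-A tail) several cycles later while
#' leaving oligo-dT-primed genes untouched. For each batch this screen
#' computes, per gene, the batch median Cq minus the global median Cq; these
#' per-gene deviations are centred on the batch's median deviation across all
#' genes (so a batch-wide global shift — sample quality, loading — cancels
#' and cannot mask or mimic a priming defect). The sentinel deviation is the
#' median centred deviation over sentinel genes, the panel deviation the
#' median over all other genes; a batch is flagged when the sentinel
#' deviation reaches `sentinel_threshold` while the panel deviation stays
#' within `panel_threshold`.
#'
#' @param cq A Cq tibble (replicate-level or collapsed) with a `cdna_batch`
#'   column for every sample and at least two batches.
#' @param sentinels Sentinel gene names (default `"18S"`).
#' @param sentinel_threshold Minimum sentinel deviation, cycles (default 1.5).
#' @param panel_threshold Maximum panel deviation, cycles (default 0.5).
#' @return A `priming_qc` tibble with one row per batch: `cdna_batch`,
#'   `sentinel_deviation`, `panel_deviation`, `flagged`. With a single batch
#'   an empty report is returned with a warning.
#' @export
priming_qc <- function(cq, sentinels = "18S",
                       sentinel_threshold = 1.5, panel_threshold = 0.5) {
  if (!"cdna_batch" %in% names(cq)) stop_schema("missing required column: cdna_batch")
  if (any(is.na(cq$cdna_batch))) stop_schema("cdna_batch missing for one or more samples")
  absent <- setdiff(sentinels, unique(cq$gene))
  if (length(absent)) {
    stop_data(paste0("sentinel gene(s) absent from table: ", paste(absent, collapse = ", ")))
  }
  batches <- sort(unique(cq$cdna_batch))
  empty <- tibble::tibble(cdna_batch = character(), sentinel_deviation = numeric(),
                          panel_deviation = numeric(), flagged = logical())
  if (length(batches) < 2) {
    warn("only one cDNA batch present; priming QC needs a between-batch contrast")
    return(new_priming_qc(empty, sentinels, sentinel_threshold, panel_threshold))
  }

  global_med <- cq |>
    dplyr::filter(!is.na(.data$cq)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(global = median(.data$cq), .groups = "drop")

  out <- cq |>
    dplyr::filter(!is.na(.data$cq)) |>
    dplyr::group_by(.data$cdna_batch, .data$gene) |>
    dplyr::summarise(batch_med = median(.data$cq), .groups = "drop") |>
    dplyr::inner_join(global_med, by = "gene") |>
    dplyr::mutate(dev = .data$batch_med - .data$global) |>
    dplyr::group_by(.data$cdna_batch) |>
    dplyr::mutate(dev = .data$dev - median(.data$dev)) |>   # centre: batch-wide shifts cancel
    dplyr::summarise(
      sentinel_deviation = median(.data$dev[.data$gene %in% sentinels]),
      panel_deviation = median(.data$dev[!.data$gene %in% sentinels]),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$sentinel_deviation >= sentinel_threshold &
                    abs(.data$panel_deviation) <= panel_threshold)
  new_priming_qc(out, sentinels, sentinel_threshold, panel_threshold)
}

new_priming_qc <- function(x, sentinels, st, pt) {
  attr(x, "sentinels") <- sentinels
  attr(x, "sentinel_threshold") <- st
  attr(x, "panel_threshold") <- pt
  class(x) <- c("priming_qc", class(x))
  x
}

#' @export
print.priming_qc <- function(x, ...) {
  cat("Random-priming QC (sentinels: ", paste(attr(x, "sentinels"), collapse = ", "),
      "; thresholds ", attr(x, "sentinel_threshold"), " / ",
      attr(x, "panel_threshold"), " cycles)\n", sep = "")
  NextMethod()
  invisible(x)
}
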