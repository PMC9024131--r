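# Normalisation factors from chosen reference genes, GOI normalisation,
# summed per-timepoint coefficients of variation, and NF-vs-NF agreement.

#' Per-sample normalisation factor from reference genes
#'
#' The normalisation factor (NF) of a sample is the geometric mean of the
#' relative quantities of the chosen reference genes in that sample. Genes of
#' interest are normalised by dividing their RQ by the NF.
#'
#' @param rq An RQ tibble (see [linearise()]).
#' @param refs Character vector of reference gene names (non-empty, all
#'   present in the table with complete RQs).
#' @return A tibble with columns `sample_id`, `nf` plus sample metadata; the
#'   reference genes used are stored in the `"refs"` attribute.
#' @export
normalization_factor <- function(rq, refs) {
  if (length(refs) == 0) stop_data("refs must name at least one reference gene")
  absent <- setdiff(refs, unique(rq$gene))
  if (length(absent)) stop_data(paste0("reference gene(s) absent: ", paste(absent, collapse = ", ")))
  sub <- dplyr::filter(rq, .data$gene %in% refs)
  if (any(is.na(sub$rq))) {
    bad <- unique(sub$sample_id[is.na(sub$rq)])
    warn(paste0("RQ missing for reference gene(s) in sample(s): ",
                paste(bad, collapse = ", "), "; NF set to missing there"))
  }
  meta <- intersect(META_COLS, names(rq))
  out <- sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", meta)))) |>
    dplyr::summarise(nf = exp(mean(log(.data$rq))), .groups = "drop")
  attr(out, "refs") <- refs
  out
}

#' Normalise genes of interest by a normalisation factor
#'
#' Divides each gene's RQ by the per-sample NF. Samples without an NF are
#' dropped with a warning.
#'
#' @param rq An RQ tibble.
#' @param nf A [normalization_factor()] tibble.
#' @param genes Genes to normalise (default: every gene in `rq`).
#' @return A tibble `sample_id`, `gene`, `rq`, `nf`, `normalized` plus
#'   metadata.
#' @export
normalize_goi <- function(rq, nf, genes = NULL) {
  genes <- genes %||% unique(rq$gene)
  absent <- setdiff(genes, unique(rq$gene))
  if (length(absent)) stop_data(paste0("gene(s) absent: ", paste(absent, collapse = ", ")))
  sub <- dplyr::filter(rq, .data$gene %in% genes)
  missing_nf <- setdiff(unique(sub$sample_id), nf$sample_id[!is.na(nf$nf)])
  if (length(missing_nf)) {
    warn(paste0("dropping sample(s) without NF: ", paste(missing_nf, collapse = ", ")))
  }
  sub |>
    dplyr::inner_join(dplyr::select(nf, "sample_id", "nf"), by = "sample_id") |>
    dplyr::filter(!is.na(.data$nf)) |>
    dplyr::mutate(normalized = .data$rq / .data$nf)
}

#' Summed per-timepoint coefficient of variation
#'
#' Computes the coefficient of variation (sample SD / mean) of `values`
#' within each timepoint and sums the per-timepoint CoVs into a single total
#' — the study-design-aware spread measure used to judge whether
#' normalisation removed sample-quality variation rather than biological
#' trend.
#'
#' @param values Positive numeric vector (e.g. RQ or normalised RQ).
#' @param timepoints Timepoint label per value (e.g. gestational age).
#' @return The summed CoV (single number); per-timepoint CoVs are attached as
#'   the `"per_timepoint"` attribute.
#' @export
total_cov <- function(values, timepoints) {
  if (length(values) != length(timepoints)) stop_schema("values and timepoints differ in length")
  keep <- !is.na(values) & !is.na(timepoints)
  values <- values[keep]; timepoints <- timepoints[keep]
  sizes <- table(timepoints)
  if (any(sizes < 2)) {
    stop_data(paste0("timepoint(s) with fewer than 2 values: ",
                     paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  per <- tapply(values, timepoints, function(v) {
    m <- mean(v)
    if (m == 0) stop_data("timepoint mean of 0: CoV undefined")
    stats::sd(v) / m
  })
  per_tbl <- tibble::tibble(timepoint = names(per), cov = as.numeric(per))
  out <- sum(per_tbl$cov)
  attr(out, "per_timepoint") <- per_tbl
  out
}

#' Compare two normalisation factors
#'
#' Pearson correlation and ordinary-least-squares gradient of `nf_b`
#' regressed on `nf_a` (matched by sample), used to ask whether a reduced
#' reference set (e.g. two genes instead of three) yields an equivalent NF.
#'
#' @param nf_a,nf_b [normalization_factor()] tibbles over the same samples.
#' @param through_origin Fit the regression without an intercept (default
#'   `FALSE`: free intercept).
#' @return A one-row tibble: `r`, `gradient`, `intercept`, `n`.
#' @export
compare_nfs <- function(nf_a, nf_b, through_origin = FALSE) {
  merged <- dplyr::inner_join(dplyr::select(nf_a, "sample_id", a = "nf"),
                              dplyr::select(nf_b, "sample_id", b = "nf"),
                              by = "sample_id") |>
    dplyr::filter(!is.na(.data$a), !is.na(.data$b))
  if (nrow(merged) < 3) stop_data("compare_nfs() needs at least 3 shared samples")
  fit <- if (through_origin) lm(b ~ a + 0, data = merged) else lm(b ~ a, data = merged)
  tibble::tibble(
    r = stats::cor(merged$a, merged$b),
    gradient = unname(coef(fit)[["a"]]),
    intercept = if (through_origin) 0 else unname(coef(fit)[["(Intercept)"]]),
    n = nrow(merged)
  )
}

#' Validate reference genes by normalising target genes
#'
#' The end-to-end validation workflow: build an NF from the chosen reference
#' genes, normalise each target gene, and contrast the summed per-timepoint
#' CoV of its raw and normalised values within each tissue. Effective
#' references should reduce the total CoV (they remove shared sample-quality
#' variation) while leaving genuine developmental trends visible.
#'
#' @param rq An RQ tibble with `tissue` and `age_days` metadata.
#' @param refs Reference gene names for the NF.
#' @param targets Target (gene-of-interest) names; default: all non-reference
#'   genes.
#' @return An object of class `validation_report`: per (gene, tissue) raw and
#'   normalised total CoV with their difference, plus the per-sample
#'   trajectories used.
#' @export
validate_normalization <- function(rq, refs, targets = NULL) {
  for (col in c("tissue", "age_days")) {
    if (!col %in% names(rq)) stop_schema(paste0("missing required column: ", col))
  }
  targets <- targets %||% setdiff(unique(rq$gene), refs)
  nf <- normalization_factor(rq, refs)
  norm <- normalize_goi(rq, nf, genes = targets)

  cov_tbl <- norm |>
    dplyr::group_by(.data$gene, .data$tissue) |>
    dplyr::group_modify(~ tibble::tibble(
      cov_raw = as.numeric(total_cov(.x$rq, .x$age_days)),
      cov_normalized = as.numeric(total_cov(.x$normalized, .x$age_days))
    )) |>
    dplyr::ungroup() |>
    dplyr::mutate(cov_reduction = .data$cov_raw - .data$cov_normalized)

  structure(
    list(cov = cov_tbl, trajectories = norm, nf = nf,
         refs = refs, targets = targets),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Normalisation validation: refs {", paste(x$refs, collapse = ", "),
      "} -> targets {", paste(x$targets, collapse = ", "), "}\n", sep = "")
  print(x$cov, n = nrow(x$cov))
  invisible(x)
}
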