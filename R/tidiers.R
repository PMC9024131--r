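# broom-style tidy()/glance() methods for the fitted result objects.

#' Tidy a geNorm fit
#' @param x A [genorm_rank()] fit.
#' @param ... Unused.
#' @return Per-gene tibble: `gene`, `m_full`, `m_at_removal`, `rank`.
#' @method tidy genorm_fit
#' @export
tidy.genorm_fit <- function(x, ...) x$genes

#' One-row summary of a geNorm fit
#' @param x A [genorm_rank()] fit.
#' @param ... Unused.
#' @return Tibble: best pair, final M, panel size, samples, minimum V(n/n+1).
#' @method glance genorm_fit
#' @export
glance.genorm_fit <- function(x, ...) {
  tibble::tibble(
    best_pair = paste(x$best_pair, collapse = "+"),
    final_m = x$final_m,
    n_genes = nrow(x$genes),
    n_samples = x$n_samples,
    v_2_3 = if (!is.null(x$v_curve)) x$v_curve$v[x$v_curve$n == 2] else NA_real_
  )
}

#' Tidy a BestKeeper fit
#' @param x A [bestkeeper()] fit.
#' @param ... Unused.
#' @return Per-gene tibble: `gene`, `r`, `cq_sd`, `cq_cv`, `rank`.
#' @method tidy bestkeeper_fit
#' @export
tidy.bestkeeper_fit <- function(x, ...) x$genes

#' One-row summary of a BestKeeper fit
#' @param x A [bestkeeper()] fit.
#' @param ... Unused.
#' @return Tibble: index type, genes, samples used/dropped.
#' @method glance bestkeeper_fit
#' @export
glance.bestkeeper_fit <- function(x, ...) {
  tibble::tibble(
    index_type = x$index_type,
    n_genes = nrow(x$genes),
    n_samples = nrow(x$index),
    n_dropped_samples = length(x$dropped_samples)
  )
}

#' Tidy a NormFinder fit
#' @param x A [normfinder()] fit.
#' @param components Return the per-(gene, group) decomposition instead of
#'   the per-gene stabilities (grouped mode only).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy normfinder_fit
#' @export
tidy.normfinder_fit <- function(x, components = FALSE, ...) {
  if (components) {
    if (x$mode != "grouped") stop_data("components are only available for grouped fits")
    return(x$components)
  }
  x$genes
}

#' One-row summary of a NormFinder fit
#' @param x A [normfinder()] fit.
#' @param ... Unused.
#' @return Tibble: mode, panel size, samples, best pair (grouped mode).
#' @method glance normfinder_fit
#' @export
glance.normfinder_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_genes = nrow(x$genes),
    n_samples = x$n_samples,
    best_pair = if (x$mode == "grouped") paste(x$best_pair, collapse = "+") else NA_character_
  )
}

#' Tidy a validation report
#' @param x A [validate_normalization()] report.
#' @param ... Unused.
#' @return Per-(gene, tissue) tibble of raw and normalised total CoV.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$cov

#' One-row summary of a validation report
#' @param x A [validate_normalization()] report.
#' @param ... Unused.
#' @return Tibble: references, targets, share of (gene, tissue) cells whose
#'   total CoV decreased after normalisation.
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    refs = paste(x$refs, collapse = "+"),
    n_targets = length(x$targets),
    frac_cov_reduced = mean(x$cov$cov_reduction > 0)
  )
}
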