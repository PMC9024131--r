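# Integrated consensus ranking: per-gene geometric mean of the four method
# scores after putting all four on a "lower is better" scale.

#' Invert BestKeeper correlations to a stability-style score
#'
#' BestKeeper ranks by correlation coefficient r, where high r is good; the
#' other three methods rank by stability, where low is good. The integrated
#' ranking therefore uses 1 - r, with negative correlations first set to
#' zero (so any negatively correlated gene scores exactly 1, the worst
#' score).
#'
#' @param r Numeric vector of Pearson correlation coefficients in [-1, 1].
#' @return `1 - pmax(r, 0)`.
#' @export
invert_bestkeeper <- function(r) {
  if (any(r < -1 | r > 1, na.rm = TRUE)) stop_data("correlation coefficients must lie in [-1, 1]")
  1 - pmax(r, 0)
}

#' Integrated consensus ranking across the four methods
#'
#' Combines geNorm, deltaCt, BestKeeper and (ungrouped) NormFinder results
#' for one sample subset into a per-gene geometric mean and rank. The geNorm
#' contribution is the M value at removal, with both best-pair genes assigned
#' the shared final M; the BestKeeper contribution is the inverted
#' correlation (see [invert_bestkeeper()]). Scores are floored at `epsilon`
#' before the geometric mean so that a single perfect (zero) method score
#' cannot collapse the consensus to exactly zero.
#'
#' @param genorm A [genorm_rank()] fit.
#' @param deltact A [deltact_scores()] result.
#' @param bestkeeper A [bestkeeper()] fit.
#' @param normfinder A [normfinder()] fit in ungrouped mode.
#' @param genorm_m Which geNorm M to use: `"at_removal"` (default) or
#'   `"full_panel"`.
#' @param epsilon Floor applied to each method score (default 1e-6).
#' @param context Optional label for the sample subset (e.g. `"embryo"`).
#' @return A `consensus_ranking` tibble: per gene, the four component scores,
#'   their geometric mean `consensus`, and `rank` (1 = most stable).
#' @export
consensus_rank <- function(genorm, deltact, bestkeeper, normfinder,
                           genorm_m = c("at_removal", "full_panel"),
                           epsilon = 1e-6, context = NULL) {
  genorm_m <- match.arg(genorm_m)
  if (!identical(normfinder$mode, "ungrouped")) {
    stop_data("consensus_rank() requires an ungrouped NormFinder fit")
  }
  panels <- list(genorm = sort(genorm$genes$gene),
                 deltact = sort(deltact$gene),
                 bestkeeper = sort(bestkeeper$genes$gene),
                 normfinder = sort(normfinder$genes$gene))
  if (length(unique(panels)) != 1) {
    all_genes <- sort(unique(unlist(panels)))
    diffs <- vapply(panels, function(p) paste(setdiff(all_genes, p), collapse = ","),
                    character(1))
    stop_data(paste0("gene panels differ across methods; missing per method: ",
                     paste(names(diffs), diffs, sep = "=", collapse = "; ")))
  }

  gn_col <- if (genorm_m == "at_removal") "m_at_removal" else "m_full"
  scores <- tibble::tibble(gene = panels$genorm) |>
    dplyr::left_join(dplyr::select(genorm$genes, "gene", genorm = dplyr::all_of(gn_col)),
                     by = "gene") |>
    dplyr::left_join(dplyr::select(deltact, "gene", deltact = "score"), by = "gene") |>
    dplyr::left_join(
      dplyr::mutate(dplyr::select(bestkeeper$genes, "gene", "r"),
                    bestkeeper = invert_bestkeeper(.data$r), r = NULL),
      by = "gene") |>
    dplyr::left_join(dplyr::select(normfinder$genes, "gene", normfinder = "stability"),
                     by = "gene")

  out <- scores |>
    dplyr::mutate(
      consensus = exp(rowMeans(log(pmax(cbind(.data$genorm, .data$deltact,
                                              .data$bestkeeper, .data$normfinder),
                                        epsilon))))
    ) |>
    dplyr::arrange(.data$consensus, .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "context") <- context
  attr(out, "epsilon") <- epsilon
  attr(out, "genorm_m") <- genorm_m
  class(out) <- c("consensus_ranking", class(out))
  out
}

#' @export
print.consensus_ranking <- function(x, ...) {
  ctx <- attr(x, "context")
  cat("Consensus ranking (geometric mean of geNorm, deltaCt, BestKeeper, NormFinder)",
      if (!is.null(ctx)) paste0(" - context: ", ctx), "\n", sep = "")
  NextMethod()
  invisible(x)
}
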