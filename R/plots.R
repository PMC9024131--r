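# ggplot2 visualisations of the result objects.

#' Plot geNorm results
#'
#' Bar chart of per-gene M values (most stable on the right, mirroring the
#' usual geNorm presentation) with the best pair highlighted, and the
#' V(n/n+1) curve with the conventional 0.2 guide line when available.
#'
#' @param object A [genorm_rank()] fit.
#' @param which `"m"` (default) or `"v"` for the V(n/n+1) curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genorm_fit
#' @export
autoplot.genorm_fit <- function(object, which = c("m", "v"), ...) {
  which <- match.arg(which)
  if (which == "v") {
    if (is.null(object$v_curve)) stop_data("fit has no V curve; rerun with v_curve = TRUE")
    return(
      ggplot2::ggplot(object$v_curve, ggplot2::aes(x = .data$comparison, y = .data$v, group = 1)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::geom_hline(yintercept = 0.2, linetype = "dashed") +
        ggplot2::labs(x = "genes in normalisation factor", y = "pairwise variation V",
                      title = "geNorm V(n/n+1)") +
        ggplot2::theme_minimal()
    )
  }
  df <- dplyr::mutate(object$genes,
                      gene = factor(.data$gene, levels = rev(.data$gene[order(.data$rank, .data$gene)])),
                      best_pair = .data$gene %in% object$best_pair)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$m_at_removal,
                                   fill = .data$best_pair)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "steelblue")) +
    ggplot2::labs(x = NULL, y = "geNorm M (least stable → most stable)",
                  title = "geNorm gene stability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot BestKeeper correlations
#'
#' Per-gene Pearson correlation with the BestKeeper index, ranked.
#'
#' @param object A [bestkeeper()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bestkeeper_fit
#' @export
autoplot.bestkeeper_fit <- function(object, ...) {
  df <- dplyr::mutate(object$genes,
                      gene = factor(.data$gene, levels = .data$gene[order(.data$r)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$r)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Pearson r vs BestKeeper index",
                  title = "BestKeeper correlation ranking") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot NormFinder stability values
#'
#' @param object A [normfinder()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot normfinder_fit
#' @export
autoplot.normfinder_fit <- function(object, ...) {
  df <- dplyr::mutate(object$genes,
                      gene = factor(.data$gene, levels = .data$gene[order(-.data$stability)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$stability)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::labs(x = NULL, y = "NormFinder stability value",
                  title = paste0("NormFinder stability (", object$mode, ")")) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot the consensus ranking
#'
#' Per-gene consensus score (geometric mean of the four method scores) with
#' the conventional 0.5 guide separating strong from weak candidates.
#'
#' @param object A [consensus_rank()] ranking.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_ranking
#' @export
autoplot.consensus_ranking <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      gene = factor(.data$gene, levels = .data$gene[order(-.data$rank)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$consensus)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "consensus score (geometric mean)",
                  title = paste0("Integrated stability ranking",
                                 if (!is.null(attr(object, "context")))
                                   paste0(" - ", attr(object, "context")))) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot raw vs normalised trajectories from a validation report
#'
#' Gene-of-interest expression by gestational age, raw and after division by
#' the normalisation factor, faceted by gene and tissue.
#'
#' @param object A [validate_normalization()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- object$trajectories |>
    tidyr::pivot_longer(c("rq", "normalized"), names_to = "state", values_to = "value") |>
    dplyr::mutate(state = factor(.data$state, levels = c("rq", "normalized"),
                                 labels = c("raw RQ", "normalised")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_days, y = .data$value,
                                   colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::facet_grid(gene ~ tissue, scales = "free_y") +
    ggplot2::labs(x = "gestational age (days)", y = "relative quantity",
                  colour = NULL, title = "Normalisation validation") +
    ggplot2::theme_minimal()
}
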