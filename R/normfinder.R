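# NormFinder: model-based stability on log2 relative quantities, with
# closed-form variance estimators (no numerical optimisation).
#
# Model: y_gs = alpha_g + beta_s + eps_gs with gene-specific error variance
# sigma_g^2; grouped mode adds a gene-by-group interaction (the intergroup
# deviation d) shrunk towards zero.

# Ungrouped per-gene variance estimates for a log2 RQ matrix y (genes x
# samples). Returns the bias-corrected sigma^2-hat (floored at 0) and the raw
# residual variances s^2.
nf_variances <- function(y) {
  k <- nrow(y); n <- ncol(y)
  r <- y - rowMeans(y) - rep(colMeans(y), each = k) + mean(y)
  s2 <- rowSums(r^2) / (n - 1)
  sigma2 <- pmax(0, (k / (k - 2)) * (s2 - mean(s2) / (k - 1)))
  list(s2 = s2, sigma2 = sigma2)
}

#' NormFinder stability values
#'
#' Estimates per-gene stability from log2 relative quantities under a two-way
#' (gene + sample) model with gene-specific error variance.
#'
#' Ungrouped mode (`groups = NULL`): the stability value of gene g is the
#' square root of its bias-corrected error-variance estimate
#' \eqn{\hat\sigma^2_g = \frac{k}{k-2}\left(s^2_g - \bar{s^2}/(k-1)\right)}
#' (floored at zero), where \eqn{s^2_g} is the residual variance of gene g
#' after removing gene and sample means and \eqn{\bar{s^2}} their mean over
#' the k genes.
#'
#' Grouped mode: within each group the ungrouped estimator gives
#' \eqn{\hat\sigma^2_{g,grp}}; the intergroup deviation \eqn{d_{g,grp}}
#' (sample-centred group mean minus grand mean; deviations sum to zero over
#' genes within a group) is shrunk towards zero by
#' \eqn{\tilde d = d\,\hat\gamma^2 / (\hat\gamma^2 + \hat\sigma^2/n_{grp})}
#' with \eqn{\hat\gamma^2} the across-gene variance of d in the group. The
#' stability value is the mean over groups of
#' \eqn{|\tilde d| + \sqrt{\hat\sigma^2/n_{grp}}}, and the best pair is the
#' two-gene set minimising the analogous combined criterion
#' \eqn{\mathrm{mean}_{grp}\left(|(\tilde d_1+\tilde d_2)/2| +
#' \sqrt{(\hat\sigma^2_1+\hat\sigma^2_2)/(4 n_{grp})}\right)} — two genes
#' that vary between groups in opposite directions can pair well even when
#' neither is individually best.
#'
#' @param rq An RQ tibble (see [linearise()]) with at least 3 genes.
#' @param groups `NULL` for ungrouped mode, or either the name of a metadata
#'   column in `rq` (e.g. `"tissue"`) or a vector of group labels named by
#'   sample id.
#' @return An object of class `normfinder_fit`: per-gene tibble (`gene`,
#'   `stability`, `rank`), `mode`, and in grouped mode the per-(gene, group)
#'   components (`d`, `d_shrunk`, `sigma2`, `n`) and the `best_pair` with its
#'   combined stability.
#' @export
normfinder <- function(rq, groups = NULL) {
  y <- log2_rq_matrix(rq)
  k <- nrow(y); n <- ncol(y)
  if (k < 3) stop_data("normfinder() needs at least 3 genes (bias correction undefined)")
  if (n < 3) stop_data("normfinder() needs at least 3 complete samples")

  if (is.null(groups)) {
    est <- nf_variances(y)
    genes <- tibble::tibble(gene = rownames(y), stability = sqrt(est$sigma2),
                            s2 = est$s2) |>
      dplyr::arrange(.data$stability) |>
      dplyr::mutate(rank = dplyr::row_number())
    return(structure(list(mode = "ungrouped", genes = genes, n_samples = n),
                     class = "normfinder_fit"))
  }

  grp <- resolve_groups(rq, groups, colnames(y))
  sizes <- table(grp)
  if (any(sizes < 2)) {
    stop_data(paste0("group(s) with fewer than 2 samples: ",
                     paste(names(sizes)[sizes < 2], collapse = ", ")))
  }

  z <- y - rep(colMeans(y), each = k)          # sample-centred
  grand <- rowMeans(z)
  comp <- purrr::map_dfr(sort(unique(grp)), function(g) {
    cols <- which(grp == g)
    ng <- length(cols)
    sigma2 <- nf_variances(y[, cols, drop = FALSE])$sigma2
    d <- rowMeans(z[, cols, drop = FALSE]) - grand
    gamma2 <- stats::var(d)
    d_shrunk <- d * gamma2 / (gamma2 + sigma2 / ng)
    tibble::tibble(gene = rownames(y), group = g, n = ng,
                   d = unname(d), d_shrunk = unname(d_shrunk),
                   sigma2 = unname(sigma2))
  })

  genes <- comp |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(stability = mean(abs(.data$d_shrunk) + sqrt(.data$sigma2 / .data$n)),
                     .groups = "drop") |>
    dplyr::arrange(.data$stability) |>
    dplyr::mutate(rank = dplyr::row_number())

  pairs <- utils::combn(rownames(y), 2, simplify = FALSE)
  pair_scores <- vapply(pairs, function(p) {
    comp |>
      dplyr::filter(.data$gene %in% p) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(term = abs(sum(.data$d_shrunk) / 2) +
                         sqrt(sum(.data$sigma2) / (4 * .data$n[1])),
                       .groups = "drop") |>
      dplyr::pull(.data$term) |>
      mean()
  }, numeric(1))
  best <- pairs[[which.min(pair_scores)]]

  structure(
    list(mode = "grouped", genes = genes, components = comp,
         best_pair = sort(best), best_pair_stability = min(pair_scores),
         n_samples = n, group_sizes = as.list(sizes)),
    class = "normfinder_fit"
  )
}

# Group labels aligned to the matrix columns (sample ids).
resolve_groups <- function(rq, groups, sample_ids) {
  if (is.character(groups) && length(groups) == 1 && groups %in% names(rq)) {
    map <- rq |>
      dplyr::distinct(.data$sample_id, g = .data[[groups]])
    grp <- setNames(as.character(map$g), map$sample_id)[sample_ids]
  } else {
    if (is.null(names(groups))) stop_schema("groups vector must be named by sample_id")
    grp <- as.character(groups)[match(sample_ids, names(groups))]
  }
  if (any(is.na(grp))) stop_schema("group label missing for one or more samples")
  grp
}

#' @export
print.normfinder_fit <- function(x, ...) {
  cat("NormFinder stability (", x$mode, " mode, ", x$n_samples, " samples)\n", sep = "")
  print(x$genes, n = nrow(x$genes))
  if (x$mode == "grouped") {
    cat("Best pair:", paste(x$best_pair, collapse = " + "),
        sprintf("(combined stability %.4f)\n", x$best_pair_stability))
  }
  invisible(x)
}
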