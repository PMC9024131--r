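# The comparative deltaCt score and the BestKeeper consensus-index
# correlation, both computed on collapsed mean Cq values.

#' Comparative deltaCt stability scores
#'
#' For each gene, the mean over all partner genes of the sample standard
#' deviation of the per-sample Cq difference. Lower scores indicate more
#' stable candidates. With perfect amplification efficiency (E = 2) this is
#' numerically identical to the geNorm M value on the full panel.
#'
#' @param cq A collapsed Cq tibble with at least 3 genes and 3 complete
#'   samples.
#' @return An object of class `deltact_result`: a tibble with columns `gene`,
#'   `score` (cycles) and `rank`.
#' @export
deltact_scores <- function(cq) {
  if (!is_collapsed(cq)) stop_data("deltact_scores() requires a collapsed table")
  m <- complete_case_matrix(value_matrix(cq, "cq"))
  if (nrow(m) < 3) stop_data("deltact_scores() needs at least 3 genes")
  if (ncol(m) < 3) stop_data("deltact_scores() needs at least 3 complete samples")
  v <- pairwise_v_matrix(m)   # sd of Cq differences, pair by pair
  score <- rowSums(v) / (nrow(m) - 1)
  out <- tibble::tibble(gene = names(score), score = unname(score)) |>
    dplyr::arrange(.data$score) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("deltact_result", class(out))
  out
}

#' BestKeeper index and per-gene correlation
#'
#' Builds the BestKeeper index — the per-sample geometric mean of the Cq
#' values of all candidate genes — and ranks genes by their Pearson
#' correlation coefficient r with this consensus profile. Per-gene Cq
#' standard deviation and coefficient of variation are reported as
#' descriptors. Samples with any missing Cq are dropped (complete-case)
#' before the index is computed.
#'
#' @param cq A collapsed Cq tibble.
#' @param index `"geometric"` (default; the method's original consensus) or
#'   `"arithmetic"` mean of Cq values.
#' @return An object of class `bestkeeper_fit` with a per-gene tibble
#'   (`gene`, `r`, `cq_sd`, `cq_cv`, `rank`), the per-sample `index`, and
#'   the ids of any dropped samples. A gene with zero Cq variance has an
#'   undefined correlation; it is assigned r = 0 with a warning.
#' @export
bestkeeper <- function(cq, index = c("geometric", "arithmetic")) {
  index <- match.arg(index)
  if (!is_collapsed(cq)) stop_data("bestkeeper() requires a collapsed table")
  m <- complete_case_matrix(value_matrix(cq, "cq"))
  if (nrow(m) < 2) stop_data("bestkeeper() needs at least 2 genes")
  if (ncol(m) < 3) stop_data("bestkeeper() needs at least 3 complete samples")
  idx <- if (index == "geometric") exp(colMeans(log(m))) else colMeans(m)

  zero_var <- apply(m, 1, stats::sd) == 0
  if (any(zero_var)) {
    warn(paste0("zero Cq variance, r set to 0 for: ",
                paste(rownames(m)[zero_var], collapse = ", ")))
  }
  r <- vapply(seq_len(nrow(m)), function(j) {
    if (zero_var[j] || stats::sd(idx) == 0) 0 else stats::cor(m[j, ], idx)
  }, numeric(1))

  genes <- tibble::tibble(
    gene = rownames(m),
    r = r,
    cq_sd = unname(apply(m, 1, stats::sd)),
    cq_cv = unname(apply(m, 1, stats::sd) / rowMeans(m))
  ) |>
    dplyr::arrange(dplyr::desc(.data$r)) |>
    dplyr::mutate(rank = dplyr::row_number())

  structure(
    list(genes = genes,
         index = tibble::tibble(sample_id = colnames(m), index = unname(idx)),
         index_type = index,
         zero_variance_genes = rownames(m)[zero_var],
         dropped_genes = attr(m, "dropped_genes"),
         dropped_samples = attr(m, "dropped_samples")),
    class = "bestkeeper_fit"
  )
}

#' @export
print.deltact_result <- function(x, ...) {
  cat("deltaCt stability scores (mean pairwise Cq-difference SD, cycles)\n")
  NextMethod()
  invisible(x)
}

#' @export
print.bestkeeper_fit <- function(x, ...) {
  cat("BestKeeper analysis (", x$index_type, "-mean index, ",
      nrow(x$index), " samples)\n", sep = "")
  print(x$genes, n = nrow(x$genes))
  if (length(x$dropped_samples)) {
    cat("Dropped (incomplete) samples:", paste(x$dropped_samples, collapse = ", "), "\n")
  }
  invisible(x)
}
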