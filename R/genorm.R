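# geNorm: pairwise variation V, gene-stability measure M, iterative
# exclusion to a best pair, and the V(n/n+1) curve.

# log2 RQ matrix (genes x samples), complete-case.
log2_rq_matrix <- function(rq) {
  m <- complete_case_matrix(value_matrix(rq, "rq"))
  if (any(m <= 0, na.rm = TRUE)) stop_data("RQ values must be positive")
  log2(m)
}

# Pairwise-variation matrix: V[j, k] = sd over samples of (y_j - y_k),
# y = log2 RQ. Symmetric, zero diagonal.
pairwise_v_matrix <- function(y) {
  k <- nrow(y)
  v <- matrix(0, k, k, dimnames = list(rownames(y), rownames(y)))
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      v[j, l] <- v[l, j] <- stats::sd(y[j, ] - y[l, ])
    }
  }
  v
}

#' geNorm pairwise variation between two genes
#'
#' The sample standard deviation (n-1 denominator), across samples, of the
#' log2 expression ratio of two genes. Two perfectly proportional genes have
#' V = 0; larger V means the pair co-varies less.
#'
#' @param rq An RQ tibble (see [linearise()]).
#' @param j,k Gene names; must differ.
#' @return A single non-negative number (log2 units).
#' @export
pairwise_v <- function(rq, j, k) {
  if (identical(j, k)) stop_data("pairwise_v() requires two distinct genes")
  y <- log2_rq_matrix(dplyr::filter(rq, .data$gene %in% c(j, k)))
  for (g in c(j, k)) if (!g %in% rownames(y)) stop_data(paste0("gene not in table: ", g))
  if (ncol(y) < 3) stop_data("pairwise_v() needs at least 3 complete samples")
  stats::sd(y[j, ] - y[k, ])
}

#' geNorm gene-stability measure M (full panel)
#'
#' M_j is the mean pairwise variation of gene j with every other gene on the
#' panel. Low M indicates stable expression; M < 0.5 is the conventional
#' acceptability heuristic.
#'
#' @param rq An RQ tibble with at least 3 genes.
#' @return A tibble with columns `gene` and `m`, sorted by `m`.
#' @export
genorm_m <- function(rq) {
  y <- log2_rq_matrix(rq)
  if (nrow(y) < 3) stop_data("genorm_m() needs at least 3 genes")
  if (ncol(y) < 3) stop_data("genorm_m() needs at least 3 complete samples")
  v <- pairwise_v_matrix(y)
  m <- rowSums(v) / (nrow(y) - 1)
  dplyr::arrange(tibble::tibble(gene = names(m), m = unname(m)), .data$m)
}

#' geNorm iterative ranking and best pair
#'
#' Repeatedly removes the gene with the highest M (recomputing M among the
#' remaining genes each round) until two genes remain: the best pair, which
#' shares the final M (their mutual pairwise variation). Ties in the maximum
#' M are broken by removing the reverse-alphabetically first (i.e. the
#' alphabetically last) gene name; any tie is recorded.
#'
#' @param rq An RQ tibble with at least 3 genes.
#' @param v_curve Also compute the V(n/n+1) curve (default `TRUE`).
#' @return An object of class `genorm_fit` with components
#'   \describe{
#'     \item{genes}{per-gene tibble: full-panel `m_full`, `m_at_removal`
#'       (best pair shares the final M), `rank` (1 = most stable).}
#'     \item{best_pair}{character vector of the final two genes.}
#'     \item{removal_order}{genes in order of exclusion with M at removal.}
#'     \item{v_curve}{tibble of V(n/n+1) values (if requested).}
#'   }
#' @export
genorm_rank <- function(rq, v_curve = TRUE) {
  y_all <- log2_rq_matrix(rq)
  if (nrow(y_all) < 3) stop_data("genorm_rank() needs at least 3 genes")
  if (ncol(y_all) < 3) stop_data("genorm_rank() needs at least 3 complete samples")

  v_full <- pairwise_v_matrix(y_all)
  m_full <- rowSums(v_full) / (nrow(y_all) - 1)

  y <- y_all
  removal <- tibble::tibble(gene = character(), m_at_removal = numeric())
  ties <- character()
  while (nrow(y) > 2) {
    v <- pairwise_v_matrix(y)
    m <- rowSums(v) / (nrow(y) - 1)
    worst <- max(m)
    cand <- names(m)[m >= worst - 1e-12]
    if (length(cand) > 1) ties <- c(ties, paste(sort(cand), collapse = "|"))
    drop <- sort(cand, decreasing = TRUE)[1]
    removal <- dplyr::bind_rows(removal,
                                tibble::tibble(gene = drop, m_at_removal = unname(m[drop])))
    y <- y[setdiff(rownames(y), drop), , drop = FALSE]
  }
  best_pair <- sort(rownames(y))
  final_m <- stats::sd(y[1, ] - y[2, ])

  genes <- tibble::tibble(
    gene = c(best_pair, rev(removal$gene)),
    m_at_removal = c(final_m, final_m, rev(removal$m_at_removal)),
    rank = c(1L, 1L, seq(3L, length.out = nrow(removal)))
  ) |>
    dplyr::mutate(m_full = unname(m_full[.data$gene]), .after = "gene")

  fit <- structure(
    list(genes = genes, best_pair = best_pair, final_m = final_m,
         removal_order = removal, ties = ties,
         n_samples = ncol(y_all),
         dropped_genes = attr(y_all, "dropped_genes"),
         dropped_samples = attr(y_all, "dropped_samples")),
    class = "genorm_fit"
  )
  if (v_curve) fit$v_curve <- genorm_v_curve(rq, fit)
  fit
}

#' geNorm V(n/n+1) curve
#'
#' For n = 2..k-1, builds normalisation factors NF_n (per-sample geometric
#' mean of the RQs of the n highest-ranked genes) and reports
#' V(n/n+1) = sd over samples of log2(NF_n / NF_(n+1)). Values below 0.2 are
#' conventionally taken to mean the extra gene adds little.
#'
#' @param rq The RQ tibble the ranking was fitted on.
#' @param fit A [genorm_rank()] result.
#' @return A tibble with columns `n`, `comparison`, `v`.
#' @export
genorm_v_curve <- function(rq, fit) {
  y <- log2_rq_matrix(rq)
  ranked <- fit$genes$gene[order(fit$genes$rank, fit$genes$gene)]
  ranked <- ranked[ranked %in% rownames(y)]
  k <- length(ranked)
  if (k < 3) stop_data("V curve needs at least 3 genes")
  # log2 NF_n per sample = column mean of the top-n rows of y.
  purrr::map_dfr(2:(k - 1), function(n) {
    nf_n  <- colMeans(y[ranked[1:n], , drop = FALSE])
    nf_n1 <- colMeans(y[ranked[1:(n + 1)], , drop = FALSE])
    tibble::tibble(n = n, comparison = paste0("V", n, "/", n + 1),
                   v = stats::sd(nf_n - nf_n1))
  })
}

#' @export
print.genorm_fit <- function(x, ...) {
  cat("geNorm stability ranking (", nrow(x$genes), " genes, ",
      x$n_samples, " samples)\n", sep = "")
  cat("Best pair:", paste(x$best_pair, collapse = " + "),
      sprintf("(M = %.4f)\n", x$final_m))
  print(x$genes, n = nrow(x$genes))
  if (!is.null(x$v_curve)) {
    cat("\nPairwise variation V(n/n+1):\n")
    print(x$v_curve)
  }
  invisible(x)
}
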