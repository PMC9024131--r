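# Shared fixtures and independent oracles, built in code.

# 3-gene x 4-sample collapsed Cq fixture:
#   A rises one cycle per sample, B = A + 5 (perfectly proportional),
#   C constant. Hand-derived (E = 2): log2 RQ_A = {0,-1,-2,-3}, ratios
#   A/C have sample SD sqrt(5/3) = 1.29099.
fixture_abc <- function() {
  tibble::tibble(
    sample_id = rep(paste0("s", 1:4), times = 3),
    gene = rep(c("A", "B", "C"), each = 4),
    cq = c(20, 21, 22, 23, 25, 26, 27, 28, 20, 20, 20, 20)
  )
}

SD_53 <- sqrt(5 / 3)  # 1.290994...

# Random collapsed Cq table (no missing values).
random_cq <- function(k = 6, n = 10, seed = 1) {
  set.seed(seed)
  tidyr::crossing(gene = paste0("g", seq_len(k)),
                  sample_id = sprintf("s%02d", seq_len(n))) |>
    dplyr::mutate(cq = stats::rnorm(dplyr::n(), mean = 24, sd = 1.5))
}

# Independent oracle for geNorm M / deltaCt: explicit double loop over gene
# pairs on the Cq matrix, sd of per-sample Cq differences.
oracle_mean_pairwise_sd <- function(cq_tbl) {
  genes <- sort(unique(cq_tbl$gene))
  wide <- tidyr::pivot_wider(cq_tbl, names_from = "sample_id", values_from = "cq")
  m <- as.matrix(wide[, -1]); rownames(m) <- wide$gene
  out <- numeric(length(genes)); names(out) <- genes
  for (j in genes) {
    acc <- 0
    for (l in setdiff(genes, j)) acc <- acc + stats::sd(m[j, ] - m[l, ])
    out[j] <- acc / (length(genes) - 1)
  }
  out
}

# Independent naive NormFinder ungrouped estimator: elementwise loops.
oracle_normfinder <- function(y) {
  k <- nrow(y); n <- ncol(y)
  r <- matrix(0, k, n)
  for (g in seq_len(k)) for (s in seq_len(n)) {
    r[g, s] <- y[g, s] - mean(y[g, ]) - mean(y[, s]) + mean(y)
  }
  s2 <- numeric(k)
  for (g in seq_len(k)) s2[g] <- sum(r[g, ]^2) / (n - 1)
  sigma2 <- numeric(k)
  for (g in seq_len(k)) {
    sigma2[g] <- max(0, (k / (k - 2)) * (s2[g] - mean(s2) / (k - 1)))
  }
  stats::setNames(sqrt(sigma2), rownames(y))
}

# Archetype panel for the geNorm correlated-pair capture regime: four
# moderately noisy stable genes plus a tightly co-trending pair whose shared
# loading is comparable to (not dominating) the stable noise.
pathology_archetypes <- function() {
  tibble::tribble(
    ~gene, ~archetype, ~baseline_cq, ~slope_embryo, ~slope_head, ~slope_forelimb, ~latent_loading, ~sigma_g, ~priming_sensitive,
    "S1", "stable",      20, 0, 0, 0, 0,    0.25, FALSE,
    "S2", "stable",      22, 0, 0, 0, 0,    0.25, FALSE,
    "S3", "stable",      24, 0, 0, 0, 0,    0.25, FALSE,
    "S4", "stable",      26, 0, 0, 0, 0,    0.25, FALSE,
    "C1", "co_trending", 23, 0, 0, 0, 0.25, 0.10, FALSE,
    "C2", "co_trending", 25, 0, 0, 0, 0.25, 0.10, FALSE
  )
}

stable_genes <- function(arch = default_archetypes()) {
  arch$gene[arch$archetype == "stable"]
}

trending_genes <- function(arch = default_archetypes()) {
  arch$gene[arch$archetype %in% c("up_trending", "co_trending", "tissue_conditional")]
}

# Default simulated dataset, calibrated and collapsed.
sim_collapsed <- function(seed = 1, params = sim_params(), archetypes = default_archetypes()) {
  sim <- simulate_cq(archetypes = archetypes, params = params, seed = seed)
  collapse_replicates(plate_calibrate(sim$cq))
}
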