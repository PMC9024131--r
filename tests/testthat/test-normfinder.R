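test_that("ungrouped NormFinder reproduces the hand-worked fixture algebra", {
  fit <- normfinder(linearise(fixture_abc()))
  st <- setNames(fit$genes$stability, fit$genes$gene)
  # full hand algebra: s2_A = s2_B = 5/27, s2_C = 20/27; k = 3 correction
  # zeroes A and B exactly and gives C sigma^2 = 5/3
  expect_equal(setNames(fit$genes$s2, fit$genes$gene)[c("A", "B", "C")],
               c(A = 5 / 27, B = 5 / 27, C = 20 / 27), tolerance = 1e-12)
  expect_equal(st[["A"]], 0, tolerance = 1e-9)
  expect_equal(st[["B"]], 0, tolerance = 1e-9)
  expect_equal(st[["C"]], SD_53, tolerance = 1e-9)
  # identical genes: all stabilities zero
  ident <- tibble::tibble(sample_id = rep(paste0("s", 1:4), 3),
                          gene = rep(c("X", "Y", "Z"), each = 4),
                          cq = rep(c(20, 21, 23, 22), 3))
  expect_equal(normfinder(linearise(ident))$genes$stability, rep(0, 3))
  expect_error(normfinder(linearise(fixture_abc()[1:8, ])), "3 genes",
               class = "refstab_data_error")
})

test_that("ungrouped estimates match the naive elementwise oracle on random data", {
  for (seed in 1:5) {
    cq <- random_cq(6, 10, seed = 100 + seed)
    rq <- linearise(cq)
    fit <- normfinder(rq)
    y <- log2(refstab:::complete_case_matrix(refstab:::value_matrix(rq, "rq")))
    oracle <- oracle_normfinder(y)
    expect_equal(setNames(fit$genes$stability, fit$genes$gene)[names(oracle)],
                 oracle, tolerance = 1e-9)
  }
})

test_that("stability values are invariant to gene rescaling and sample effects", {
  rq <- linearise(random_cq(6, 12, seed = 31))
  s0 <- dplyr::arrange(normfinder(rq)$genes, gene)$stability
  rq_g <- rq |>
    dplyr::group_by(gene) |>
    dplyr::mutate(rq = rq * stats::runif(1, 0.1, 4)) |>
    dplyr::ungroup()
  expect_equal(dplyr::arrange(normfinder(rq_g)$genes, gene)$stability, s0,
               tolerance = 1e-9)
  rq_s <- rq |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(rq = rq * stats::runif(1, 0.1, 4)) |>
    dplyr::ungroup()
  expect_equal(dplyr::arrange(normfinder(rq_s)$genes, gene)$stability, s0,
               tolerance = 1e-9)
})

test_that("the variance estimator is calibrated on the two-way model (k=8, n=20)", {
  set.seed(814)
  k <- 8; n <- 20
  sigma <- seq(0.3, 1.0, length.out = k)
  est <- replicate(400, {
    y <- outer(rnorm(k, 20, 2), rep(1, n)) +
      rep(rnorm(n), each = k) + matrix(rnorm(k * n), k, n) * sigma
    refstab:::nf_variances(y)$sigma2
  })
  # mean-unbiasedness of the closed-form estimator
  expect_equal(rowMeans(est) / sigma^2, rep(1, k), tolerance = 0.08)
})

test_that("grouped mode decomposes intergroup deviation and finds opposite-bias pairs", {
  # two groups; gene P1 deviates +delta in G1 / -delta in G2, P2 mirrored,
  # N1 and N2 have no group effect. Best pair must be {P1, P2}.
  set.seed(5)
  n_per <- 6
  samples <- sprintf("s%02d", 1:(2 * n_per))
  grp <- rep(c("G1", "G2"), each = n_per)
  delta <- 1.0
  make_gene <- function(name, dev) {
    tibble::tibble(sample_id = samples, gene = name,
                   cq = 24 + dev * ifelse(grp == "G1", 1, -1) + rnorm(2 * n_per, 0, 0.15))
  }
  cq <- dplyr::bind_rows(make_gene("P1", delta), make_gene("P2", -delta),
                         make_gene("N1", 0), make_gene("N2", 0))
  rq <- linearise(cq)
  fit <- normfinder(rq, groups = setNames(grp, samples))
  expect_equal(fit$mode, "grouped")
  # deviations sum to zero over genes within each group
  sums <- fit$components |>
    dplyr::group_by(group) |>
    dplyr::summarise(s = sum(d))
  expect_equal(sums$s, c(0, 0), tolerance = 1e-9)
  # the mirrored pair cancels intergroup deviation and wins the pair search
  expect_setequal(fit$best_pair, c("P1", "P2"))
  # oracle: exhaustive pair criterion recomputed from the components table
  pair_score <- function(p) {
    fit$components |>
      dplyr::filter(gene %in% p) |>
      dplyr::group_by(group) |>
      dplyr::summarise(term = abs(sum(d_shrunk) / 2) + sqrt(sum(sigma2) / (4 * n[1])),
                       .groups = "drop") |>
      dplyr::summarise(m = mean(term)) |>
      dplyr::pull(m)
  }
  pairs <- combn(c("P1", "P2", "N1", "N2"), 2, simplify = FALSE)
  scores <- vapply(pairs, pair_score, numeric(1))
  expect_equal(sort(fit$best_pair),
               sort(pairs[[which.min(scores)]]))
  expect_equal(fit$best_pair_stability, min(scores), tolerance = 1e-12)
  # group of size 1 is refused by name
  bad <- setNames(c("G1", rep("G2", 2 * n_per - 1)), samples)
  expect_error(normfinder(rq, groups = bad), "G1", class = "refstab_data_error")
})

test_that("with statistically identical groups, grouped stabilities track ungrouped", {
  set.seed(99)
  k <- 8; n <- 24
  sigma <- seq(0.15, 1.2, length.out = k)   # distinct true stabilities
  samples <- sprintf("s%02d", seq_len(n))
  cq <- tidyr::crossing(gene = paste0("g", seq_len(k)), sample_id = samples) |>
    dplyr::mutate(cq = 24 + rnorm(dplyr::n()) * sigma[as.integer(factor(gene))])
  rq <- linearise(cq)
  grp <- setNames(rep(c("G1", "G2"), each = n / 2), samples)
  g <- normfinder(rq, groups = grp)
  u <- normfinder(rq)
  merged <- dplyr::inner_join(g$genes, u$genes, by = "gene")
  # no true group effect: same ordering up to Monte-Carlo noise
  expect_gt(cor(merged$stability.x, merged$stability.y, method = "spearman"), 0.7)
})

test_that("a larger true intergroup deviation strictly increases grouped stability", {
  set.seed(12)
  n_per <- 8
  samples <- sprintf("s%02d", 1:(2 * n_per))
  grp <- rep(c("G1", "G2"), each = n_per)
  noise <- matrix(rnorm(5 * 2 * n_per, 0, 0.2), nrow = 5)
  stab_at <- function(delta) {
    cq <- purrr::map_dfr(1:5, function(g) {
      dev <- if (g == 1) delta else 0
      tibble::tibble(sample_id = samples, gene = paste0("g", g),
                     cq = 24 + dev * ifelse(grp == "G1", 1, -1) + noise[g, ])
    })
    fit <- normfinder(linearise(cq), groups = setNames(grp, samples))
    fit$genes$stability[fit$genes$gene == "g1"]
  }
  vals <- vapply(c(0.2, 0.6, 1.2, 2.0), stab_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})
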