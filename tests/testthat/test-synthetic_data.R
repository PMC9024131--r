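test_that("the default design reproduces the 44-sample study layout", {
  d <- default_design()
  expect_equal(nrow(d), 44)
  counts <- table(d$tissue)
  expect_equal(unname(counts[c("embryo", "head", "forelimb")]), c(24L, 11L, 9L),
               ignore_attr = TRUE)
  embryo_n <- d |>
    dplyr::filter(tissue == "embryo") |>
    dplyr::count(age_days)
  expect_equal(embryo_n$age_days, c(11.5, 12.5, 13.5, 14.5, 15.5, 16.5, 18.5))
  expect_equal(embryo_n$n, c(3L, 3L, 4L, 3L, 3L, 3L, 5L))
  head_n <- d |> dplyr::filter(tissue == "head") |> dplyr::count(age_days)
  expect_equal(head_n$n, c(3L, 3L, 5L))
  # schema completeness and calibrators
  expect_false(any(is.na(d)))
  expect_equal(sum(d$is_calibrator), 3)
  expect_gt(dplyr::n_distinct(d$cdna_batch), 1)
  expect_gt(dplyr::n_distinct(d$plate), 1)
})

test_that("simulation is deterministic in the seed and validates parameters", {
  a <- simulate_cq(seed = 42)
  b <- simulate_cq(seed = 42)
  expect_identical(a$cq, b$cq)
  c <- simulate_cq(seed = 43)
  expect_false(identical(a$cq$cq, c$cq$cq))
  expect_error(sim_params(sigma_quality = -1), class = "refstab_schema_error")
  expect_equal(dplyr::n_distinct(a$cq$gene), 15)
  expect_equal(dplyr::n_distinct(a$cq$sample_id), 44)
  # two replicate wells per (gene, sample) on the sample's own plate
  own <- a$cq |> dplyr::count(gene, sample_id, plate)
  expect_true(all(own$n == 2))
  # calibrators appear on every plate
  cal_plates <- a$cq |>
    dplyr::filter(is_calibrator) |>
    dplyr::distinct(sample_id, plate) |>
    dplyr::count(sample_id)
  expect_true(all(cal_plates$n == dplyr::n_distinct(a$cq$plate)))
})

test_that("the noise-free limit collapses to exact archetype expectations", {
  arch <- default_archetypes() |>
    dplyr::mutate(slope_embryo = 0, slope_head = 0, slope_forelimb = 0,
                  latent_loading = 0, sigma_g = 0)
  p <- sim_params(sigma_quality = 0, sigma_tech = 0, sigma_plate = 0,
                  priming_batch = NULL)
  sim <- simulate_cq(archetypes = arch, params = p, seed = 1)
  per_gene <- sim$cq |> dplyr::group_by(gene) |> dplyr::summarise(s = sd(cq), m = mean(cq))
  expect_equal(per_gene$s, rep(0, 15))
  expect_equal(setNames(per_gene$m, per_gene$gene)[arch$gene], arch$baseline_cq,
               ignore_attr = TRUE)
  # every stability statistic is zero/degenerate-stable in this limit
  cqc <- collapse_replicates(sim$cq)
  expect_equal(genorm_m(linearise(cqc))$m, rep(0, 15), tolerance = 1e-12)
  expect_equal(deltact_scores(cqc)$score, rep(0, 15), tolerance = 1e-12)
})

test_that("the per-sample quality effect cancels exactly in ratio-based statistics", {
  p_big <- sim_params(sigma_quality = 2)
  p_off <- sim_params(sigma_quality = 0)
  a <- simulate_cq(params = p_big, seed = 7)
  b <- simulate_cq(params = p_off, seed = 7)
  # identical noise realisations, only q differs
  expect_equal(a$truth$sample_effects$u, b$truth$sample_effects$u)
  cqa <- collapse_replicates(a$cq); cqb <- collapse_replicates(b$cq)
  expect_equal(genorm_m(linearise(cqa))$m, genorm_m(linearise(cqb))$m,
               tolerance = 1e-9)
  expect_equal(deltact_scores(cqa)$score, deltact_scores(cqb)$score, tolerance = 1e-9)
  expect_equal(normfinder(linearise(cqa))$genes$stability,
               normfinder(linearise(cqb))$genes$stability, tolerance = 1e-9)
})

test_that("the ground truth reconstructs the simulated signal", {
  sim <- simulate_cq(seed = 9)
  merged <- sim$cq |>
    dplyr::inner_join(sim$truth$expected, by = c("gene", "sample_id", "plate"))
  # well Cq sits within technical noise of the recorded expectation
  expect_lt(max(abs(merged$cq - merged$expected_cq)),
            6 * sim$truth$params$sigma_tech)
  expect_equal(nrow(sim$truth$plate_offsets), 3)
  expect_equal(sum(sim$truth$batch_offsets$priming_offset > 0), 1)
})

test_that("co-trending genes correlate tightly at defaults while scoring worse
           than stable genes under deltaCt and NormFinder", {
  ok <- vapply(1:10, function(s) {
    cqc <- sim_collapsed(seed = 600 + s)
    rq <- linearise(cqc)
    stab <- stable_genes()
    # residual correlation after removing per-sample effects: the pair shares
    # a latent trajectory, stable genes share nothing
    y <- log2(refstab:::complete_case_matrix(refstab:::value_matrix(rq, "rq")))
    resid <- y - rep(colMeans(y), each = nrow(y))
    pair_cor <- cor(resid["CDC40", ], resid["HTATSF1", ])
    stable_cors <- combn(stab, 2, function(p) cor(resid[p[1], ], resid[p[2], ]))
    dct <- deltact_scores(cqc)
    nf <- normfinder(rq)$genes
    pair_cor > 0.5 && all(pair_cor > stable_cors) &&
      min(dct$score[dct$gene %in% c("CDC40", "HTATSF1")]) >
        max(dct$score[dct$gene %in% stab]) &&
      min(nf$stability[nf$gene %in% c("CDC40", "HTATSF1")]) >
        max(nf$stability[nf$gene %in% stab])
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("a moderately loaded co-trending pair captures the geNorm best pair
           among noisier stable genes", {
  p <- sim_params(priming_batch = NULL)
  wins <- vapply(1:10, function(s) {
    sim <- simulate_cq(archetypes = pathology_archetypes(), params = p, seed = 700 + s)
    fit <- genorm_rank(linearise(collapse_replicates(plate_calibrate(sim$cq))))
    setequal(fit$best_pair, c("C1", "C2"))
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
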