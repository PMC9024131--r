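test_that("read_cq parses long tables, tracks missing cells and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,gene,cq,well",
    "s1,ACTB,20.1,w1",
    "s1,ACTB,20.3,w2",
    "s1,ACTB,20.2,w3",
    "s2,ACTB,NA,w1",
    "s2,GAPDH,notanumber,w1",
    "s3,GAPDH,99,w1",
    "s3,ACTB,21.0,w1"
  ), path)
  expect_warning(cq <- read_cq(path), "rejected")
  # 3 replicate wells for (s1, ACTB)
  expect_equal(sum(cq$sample_id == "s1" & cq$gene == "ACTB"), 3)
  # "NA" kept as an explicitly missing cell
  expect_equal(sum(is.na(cq$cq)), 1)
  # non-numeric and out-of-range rows dropped and reported
  expect_equal(nrow(attr(cq, "rejected")), 2)
  expect_false(any(cq$cq > 45, na.rm = TRUE))
})

test_that("read_cq reads wide matrices and joins sample metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  meta_path <- withr::local_tempfile(fileext = ".csv")
  genes <- paste0("g", 1:15)
  samples <- paste0("s", 1:44)
  set.seed(3)
  mat <- matrix(round(rnorm(15 * 44, 25, 2), 2), 15, 44)
  readr::write_csv(tibble::as_tibble(cbind(data.frame(gene = genes),
                                           setNames(as.data.frame(mat), samples))), path)
  readr::write_csv(tibble::tibble(sample_id = samples,
                                  tissue = rep(c("embryo", "head"), c(24, 20)),
                                  age_days = 13.5), meta_path)
  cq <- read_cq(path, dialect = "wide", meta = meta_path)
  expect_equal(nrow(cq), 15 * 44)
  expect_true(refstab:::is_collapsed(cq))
  expect_equal(unique(cq$tissue[cq$sample_id == "s1"]), "embryo")
})

test_that("read_cq raises schema errors for missing columns and duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,cq", "s1,20"), path)
  expect_error(read_cq(path), "gene", class = "refstab_schema_error")
  writeLines(c("sample_id,gene,cq,well", "s1,A,20,w1", "s1,A,21,w1"), path)
  expect_error(read_cq(path), "duplicate", class = "refstab_schema_error")
  writeLines(c("sample_id,gene,cq,tissue", "s1,A,20,liver"), path)
  expect_error(read_cq(path), "tissue", class = "refstab_schema_error")
})

test_that("collapse_replicates averages wells, records SD and flags dispersion", {
  cq <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    gene = "A",
    cq = c(20, 20, 20, 20, 21, 22.3)
  )
  out <- collapse_replicates(cq)
  s1 <- out[out$sample_id == "s1", ]
  expect_equal(s1$cq, 20); expect_equal(s1$cq_sd, 0); expect_false(s1$high_sd)
  s2 <- out[out$sample_id == "s2", ]
  expect_equal(s2$cq, 20.5)
  expect_equal(s2$cq_sd, sd(c(20, 21)), tolerance = 1e-12)  # ~0.7071
  expect_true(s2$high_sd)                                   # exceeds 0.5 default
  s3 <- out[out$sample_id == "s3", ]
  expect_equal(s3$cq, 22.3); expect_equal(s3$cq_sd, 0); expect_equal(s3$n_wells, 1)
})

test_that("plate_calibrate estimates and removes additive plate offsets", {
  base <- tidyr::crossing(gene = c("A", "B"), sample_id = c("cal1", "cal2", "x1")) |>
    dplyr::mutate(cq = 20 + as.numeric(factor(gene)) + as.numeric(factor(sample_id)),
                  is_calibrator = sample_id != "x1")
  pa <- dplyr::mutate(base, plate = "A", well = "w1")
  # plate B repeats the calibrators, shifted
  pb <- base |>
    dplyr::filter(is_calibrator) |>
    dplyr::mutate(cq = cq + rep(c(0.4, 0.8), each = 2), plate = "B", well = "w2")
  pb_extra <- dplyr::mutate(base[base$sample_id == "x1", ], cq = cq + 0.6,
                            plate = "B", well = "w2", sample_id = "x2")
  cq <- dplyr::bind_rows(pa, pb, pb_extra)
  out <- plate_calibrate(cq)
  off <- plate_offsets(out)
  expect_equal(off$offset[off$plate == "B"], 0.6, tolerance = 1e-12)  # mean(0.4, 0.8)
  expect_equal(off$offset[off$plate == "A"], 0)
  # plate-B sample corrected by the pooled offset
  expect_equal(out$cq[out$sample_id == "x2"], base$cq[base$sample_id == "x1"],
               tolerance = 1e-12)
  # idempotence: second application finds zero offsets
  out2 <- plate_calibrate(out)
  expect_equal(max(abs(plate_offsets(out2)$offset)), 0, tolerance = 1e-12)
  # a plate without shared calibrators is an error naming the plate
  bad <- dplyr::bind_rows(pa, dplyr::mutate(pb_extra, plate = "C"))
  expect_error(plate_calibrate(bad), "plate 'C'", class = "refstab_data_error")
})

test_that("linearise maps Cq to RQ with per-gene calibration to minimum Cq", {
  cq <- tibble::tibble(sample_id = rep(paste0("s", 1:3), 2),
                       gene = rep(c("A", "B"), each = 3),
                       cq = c(20, 21, 24, 30, 32, 31))
  rq <- linearise(cq)
  a <- rq$rq[rq$gene == "A"]
  expect_equal(a, c(1, 0.5, 2^-4))            # min-Cq sample gets RQ 1
  expect_equal(max(rq$rq[rq$gene == "B"]), 1)
  rq195 <- linearise(cq, efficiency = 1.95)
  expect_equal(rq195$rq[rq195$gene == "A"][2], 1.95^-1, tolerance = 1e-12)
  expect_equal(rq195$rq[rq195$gene == "A"][3], 1.95^-4, tolerance = 1e-12)
  # E = 1.95, two cycles above minimum -> 1.95^-2 ~ 0.2630
  cq2 <- tibble::tibble(sample_id = c("s1", "s2"), gene = "A", cq = c(20, 22))
  expect_equal(linearise(cq2, efficiency = 1.95)$rq[2], 1.95^-2, tolerance = 1e-12)
  expect_error(linearise(cq, efficiency = 2.5), class = "refstab_schema_error")
  # missing Cq propagates
  cq$cq[2] <- NA
  expect_true(is.na(linearise(cq)$rq[2]))
})

test_that("linearise is shift-invariant per gene and commutes with replicate collapse", {
  cq <- random_cq(4, 6, seed = 11)
  shifted <- dplyr::mutate(cq, cq = cq + ifelse(gene == "g1", 3.7, 0))
  expect_equal(linearise(cq)$rq, linearise(shifted)$rq, tolerance = 1e-12)

  wells <- dplyr::bind_rows(dplyr::mutate(cq, well = "w1", cq = cq + 0.2),
                            dplyr::mutate(cq, well = "w2", cq = cq - 0.2))
  via_collapse <- linearise(collapse_replicates(wells)) |>
    dplyr::arrange(gene, sample_id)
  direct <- linearise(cq) |> dplyr::arrange(gene, sample_id)
  expect_equal(via_collapse$rq, direct$rq, tolerance = 1e-12)
})
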