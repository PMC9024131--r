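# Synthetic Cq-data generator emulating a developmental RT-qPCR reference
# gene study: whole embryos, heads and forelimbs across gestational ages,
# technical replicate wells, plate offsets with shared calibrators, a global
# per-sample quality effect, gene archetypes, and a batch-restricted
# random-priming failure hitting only priming-dependent genes.

AGE_MIDPOINT <- 14.5  # design midpoint: baselines are mid-gestation Cq

#' Default study design: 44 samples across three tissues
#'
#' Whole embryos at seven gestational ages (E11.5-E18.5, n = 3/3/4/3/3/3/5,
#' 24 samples), heads at E13.5/E16.5/E18.5 (n = 3/3/5, 11 samples), and
#' forelimbs at the same three ages (n = 3 each, 9 samples). Samples carry a
#' litter label (shared within tissue/age), a cDNA synthesis batch (four
#' batches covering early embryos, late embryos, heads and forelimbs), a
#' plate assignment (three plates), and a calibrator flag: three embryo
#' samples act as shared between-plate calibration samples and are run on
#' every plate.
#'
#' @return A tibble with one row per sample: `sample_id`, `tissue`,
#'   `age_days`, `litter`, `cdna_batch`, `plate`, `is_calibrator`.
#' @export
default_design <- function() {
  blocks <- tibble::tribble(
    ~tissue,    ~age_days, ~n,
    "embryo",   11.5, 3L,
    "embryo",   12.5, 3L,
    "embryo",   13.5, 4L,
    "embryo",   14.5, 3L,
    "embryo",   15.5, 3L,
    "embryo",   16.5, 3L,
    "embryo",   18.5, 5L,
    "head",     13.5, 3L,
    "head",     16.5, 3L,
    "head",     18.5, 5L,
    "forelimb", 13.5, 3L,
    "forelimb", 16.5, 3L,
    "forelimb", 18.5, 3L
  )
  design <- blocks |>
    dplyr::rowwise() |>
    dplyr::reframe(tissue = .data$tissue, age_days = .data$age_days,
                   replicate = seq_len(.data$n)) |>
    dplyr::mutate(
      sample_id = paste0(substr(.data$tissue, 1, 3), "_E", .data$age_days,
                         "_", .data$replicate),
      litter = paste0("L", .data$age_days),
      cdna_batch = dplyr::case_when(
        .data$tissue == "embryo" & .data$age_days <= 13.5 ~ "B1",
        .data$tissue == "embryo" ~ "B2",
        .data$tissue == "head" ~ "B3",
        TRUE ~ "B4"
      ),
      plate = paste0("P", ((dplyr::row_number() - 1) %/% 15) + 1),
      is_calibrator = .data$sample_id %in% c("emb_E11.5_1", "emb_E14.5_1", "emb_E18.5_1")
    ) |>
    dplyr::select("sample_id", "tissue", "age_days", "litter", "cdna_batch",
                  "plate", "is_calibrator")
  stopifnot(nrow(design) == 44, !anyDuplicated(design$sample_id))
  design
}

#' Default 15-gene archetype panel
#'
#' Gene archetypes emulating the behaviours the analysis must distinguish:
#' \describe{
#'   \item{stable}{eight genes with no age trend and low gene-specific noise
#'     (the true reference candidates).}
#'   \item{up_trending}{two genes upregulated with gestational age in every
#'     tissue (Cq falls as age rises), HPRT1/B2M-like.}
#'   \item{co_trending}{a correlated pair sharing a strong per-sample latent
#'     trajectory plus a modest down-trend, CDC40/HTATSF1-like: they track
#'     each other closely while both varying across samples.}
#'   \item{tissue_conditional}{two genes stable in whole embryos but
#'     downregulated with age in heads and forelimbs, CYC1/EIF4A-like.}
#'   \item{priming_sensitive}{an 18S-like non-polyadenylated gene whose Cq
#'     depends on random priming and shifts in a failed cDNA batch.}
#' }
#'
#' @return A tibble with columns `gene`, `archetype`, `baseline_cq`,
#'   `slope_embryo`, `slope_head`, `slope_forelimb` (log2 expression per
#'   day; the Cq contribution is minus slope times age offset),
#'   `latent_loading` (cycles per latent-unit), `sigma_g` (biological noise
#'   SD, cycles), `priming_sensitive`.
#' @export
default_archetypes <- function() {
  tibble::tribble(
    ~gene,      ~archetype,           ~baseline_cq, ~slope_embryo, ~slope_head, ~slope_forelimb, ~latent_loading, ~sigma_g, ~priming_sensitive,
    "ACTB",     "stable",             19.5,  0,     0,     0,     0,   0.10, FALSE,
    "SDHA",     "stable",             24.5,  0,     0,     0,     0,   0.12, FALSE,
    "GAPDH",    "stable",             20.0,  0,     0,     0,     0,   0.15, FALSE,
    "RPL13A",   "stable",             21.0,  0,     0,     0,     0,   0.10, FALSE,
    "CSNK2A2",  "stable",             26.0,  0,     0,     0,     0,   0.12, FALSE,
    "AP3D1",    "stable",             25.5,  0,     0,     0,     0,   0.10, FALSE,
    "PAK1IP1",  "stable",             27.0,  0,     0,     0,     0,   0.12, FALSE,
    "UBC",      "stable",             22.5,  0,     0,     0,     0,   0.10, FALSE,
    "HPRT1",    "up_trending",        24.0,  0.30,  0.30,  0.30,  0,   0.20, FALSE,
    "B2M",      "up_trending",        21.5,  0.35,  0.35,  0.35,  0,   0.20, FALSE,
    "CDC40",    "co_trending",        26.5, -0.10, -0.10, -0.10,  0.8, 0.10, FALSE,
    "HTATSF1",  "co_trending",        25.0, -0.10, -0.10, -0.10,  0.8, 0.10, FALSE,
    "CYC1",     "tissue_conditional", 23.0,  0,    -0.25, -0.25,  0,   0.15, FALSE,
    "EIF4A",    "tissue_conditional", 21.0,  0,    -0.25, -0.25,  0,   0.15, FALSE,
    "18S",      "priming_sensitive",   9.5,  0,     0,     0,     0,   0.15, TRUE
  )
}

#' Simulation noise and artifact parameters
#'
#' @param sigma_quality SD of the global per-sample quality effect (cycles,
#'   shared by all genes of a sample; default 0.5). This is the effect a
#'   normalisation factor exists to remove.
#' @param sigma_tech SD of per-well technical noise (cycles, default 0.15).
#' @param sigma_plate SD of the per-plate offset (cycles, default 0.3).
#' @param latent_sd SD of the per-sample latent trajectory loaded by
#'   co-trending genes (default 1).
#' @param priming_offset Cq shift applied to priming-sensitive genes in the
#'   failed batch (cycles, default 3.0, the magnitude seen when random
#'   priming fails for an rRNA target).
#' @param priming_batch cDNA batch affected by the priming failure (default
#'   `"B2"`; set `NULL` for no failure).
#' @param n_replicates Technical replicate wells per (sample, gene), default 2.
#' @return A named list of validated parameters.
#' @export
sim_params <- function(sigma_quality = 0.5, sigma_tech = 0.15, sigma_plate = 0.3,
                       latent_sd = 1, priming_offset = 3.0, priming_batch = "B2",
                       n_replicates = 2) {
  sig <- c(sigma_quality = sigma_quality, sigma_tech = sigma_tech,
           sigma_plate = sigma_plate, latent_sd = latent_sd)
  if (any(sig < 0)) stop_schema("variance parameters must be >= 0")
  if (n_replicates < 1) stop_schema("n_replicates must be >= 1")
  list(sigma_quality = sigma_quality, sigma_tech = sigma_tech,
       sigma_plate = sigma_plate, latent_sd = latent_sd,
       priming_offset = priming_offset, priming_batch = priming_batch,
       n_replicates = as.integer(n_replicates))
}

#' Simulate a replicate-level Cq dataset with ground truth
#'
#' Generates well-level Cq values
#' \deqn{Cq_{g,s,w} = b_g - s_{g,tissue(s)}(age_s - 14.5) + c_g u_s + q_s +
#'   \delta_{plate} + \delta_{batch}[g\ priming] + \epsilon_{g,s} +
#'   \eta_{g,s,w}}
#' where b is the gene baseline, s the tissue-specific log2-per-day trend,
#' u the per-sample latent trajectory (loading c), q the per-sample quality
#' effect, and the two noise terms are per-(gene, sample) biological and
#' per-well technical noise. Calibrator samples are run on every plate. The
#' same seed reproduces the dataset exactly.
#'
#' @param design A study design tibble (see [default_design()]).
#' @param archetypes A gene archetype tibble (see [default_archetypes()]).
#' @param params Simulation parameters from [sim_params()].
#' @param seed Integer seed for all randomness.
#' @return A list of class `refstab_sim` with `cq` (replicate-level Cq
#'   tibble in the long dialect) and `truth` (realised per-sample effects,
#'   plate and batch offsets, gene parameters, and the noise-free expected
#'   Cq per gene/sample/plate).
#' @export
simulate_cq <- function(design = default_design(), archetypes = default_archetypes(),
                        params = sim_params(), seed = 1) {
  if (any(archetypes$baseline_cq <= 5 | archetypes$baseline_cq >= 40)) {
    stop_schema("baseline_cq must lie in (5, 40)")
  }
  if (any(archetypes$sigma_g < 0)) stop_schema("sigma_g must be >= 0")
  set.seed(seed)
  n_s <- nrow(design); n_g <- nrow(archetypes)
  plates <- sort(unique(design$plate))

  # Standard normals scaled outside rnorm() so the random stream is identical
  # across parameter settings (a sigma of 0 must not shift later draws).
  q <- params$sigma_quality * rnorm(n_s)
  u <- params$latent_sd * rnorm(n_s)
  plate_off <- setNames(params$sigma_plate * rnorm(length(plates)), plates)
  bio <- matrix(rnorm(n_g * n_s), n_g, n_s) * archetypes$sigma_g
  dimnames(bio) <- list(archetypes$gene, design$sample_id)

  sample_effects <- tibble::tibble(sample_id = design$sample_id, q = q, u = u)
  batch_offsets <- tibble::tibble(
    cdna_batch = sort(unique(design$cdna_batch))
  ) |>
    dplyr::mutate(priming_offset = ifelse(
      .data$cdna_batch %in% (params$priming_batch %||% character(0)),
      params$priming_offset, 0))

  # One row per (gene, sample, plate): samples sit on their own plate;
  # calibrators additionally on every other plate.
  cells <- tidyr::crossing(gene = archetypes$gene, sample_id = design$sample_id) |>
    dplyr::left_join(design, by = "sample_id") |>
    dplyr::left_join(sample_effects, by = "sample_id") |>
    dplyr::left_join(batch_offsets, by = "cdna_batch") |>
    dplyr::left_join(archetypes, by = "gene")
  cal_extra <- cells |>
    dplyr::filter(.data$is_calibrator) |>
    dplyr::select(-"plate") |>
    tidyr::crossing(plate = plates) |>
    dplyr::anti_join(dplyr::distinct(cells, .data$gene, .data$sample_id, .data$plate),
                     by = c("gene", "sample_id", "plate"))
  cells <- dplyr::bind_rows(cells, cal_extra) |>
    dplyr::arrange(.data$gene, .data$sample_id, .data$plate) |>
    dplyr::mutate(
      slope = dplyr::case_when(
        .data$tissue == "embryo" ~ .data$slope_embryo,
        .data$tissue == "head" ~ .data$slope_head,
        TRUE ~ .data$slope_forelimb
      ),
      expected_cq = .data$baseline_cq -
        .data$slope * (.data$age_days - AGE_MIDPOINT) +
        .data$latent_loading * .data$u + .data$q +
        plate_off[.data$plate] +
        .data$priming_offset * .data$priming_sensitive +
        bio[cbind(.data$gene, .data$sample_id)]
    )

  wells <- cells |>
    tidyr::crossing(rep_idx = seq_len(params$n_replicates)) |>
    dplyr::mutate(
      well = paste0(.data$plate, "_r", .data$rep_idx),
      cq = .data$expected_cq + params$sigma_tech * rnorm(dplyr::n())
    ) |>
    dplyr::select("sample_id", "gene", "cq", "well", "plate", "tissue",
                  "age_days", "litter", "cdna_batch", "is_calibrator")

  truth <- list(
    seed = seed,
    params = params,
    sample_effects = sample_effects,
    plate_offsets = tibble::tibble(plate = plates, offset = unname(plate_off)),
    batch_offsets = batch_offsets,
    gene_params = archetypes,
    expected = dplyr::select(cells, "gene", "sample_id", "plate", "expected_cq")
  )
  structure(list(cq = wells, truth = truth), class = "refstab_sim")
}

#' @export
print.refstab_sim <- function(x, ...) {
  cat("Synthetic RT-qPCR dataset: ", dplyr::n_distinct(x$cq$gene), " genes x ",
      dplyr::n_distinct(x$cq$sample_id), " samples (", nrow(x$cq),
      " wells), seed ", x$truth$seed, "\n", sep = "")
  invisible(x)
}
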