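# Run orchestration: sample subsets, the one-call stability pipeline, and
# file-writing entry points (simulate / rank / validate) with run manifests.
# A thin command-line wrapper over these functions lives in inst/cli/refstab.

#' Restrict a Cq or RQ table to one analysis subset
#'
#' Subsets are defined purely by tissue: `"all"` keeps every sample,
#' otherwise only samples of the named tissue are retained.
#'
#' @param x A Cq or RQ tibble with a `tissue` column (not needed for
#'   `"all"`).
#' @param subset One of `"all"`, `"embryo"`, `"head"`, `"forelimb"`.
#' @return The filtered tibble.
#' @export
subset_cq <- function(x, subset = c("all", "embryo", "head", "forelimb")) {
  subset <- match.arg(subset)
  if (subset == "all") return(x)
  if (!"tissue" %in% names(x)) stop_schema("missing required column: tissue")
  out <- dplyr::filter(x, .data$tissue == subset)
  if (nrow(out) == 0) stop_data(paste0("subset '", subset, "' contains no samples"))
  out
}

#' Run the full stability analysis on one sample subset
#'
#' Convenience pipeline: collapse replicates if needed, restrict to the
#' subset, linearise, run the requested stability methods, and (when all
#' four are present) integrate them into the consensus ranking.
#'
#' @param cq A Cq tibble (replicate-level or collapsed; already
#'   plate-calibrated if calibration is needed).
#' @param subset Sample subset (see [subset_cq()]).
#' @param methods Which of `"genorm"`, `"deltact"`, `"bestkeeper"`,
#'   `"normfinder"` to run (default all four).
#' @param efficiency Amplification efficiency for [linearise()].
#' @param groups Optional grouping (column name or named vector) for an
#'   additional grouped NormFinder run.
#' @param max_sd Replicate-SD flag threshold for [collapse_replicates()].
#' @return A list of class `stability_analysis` holding the per-method fits,
#'   the `consensus` ranking (if all methods ran), any grouped NormFinder
#'   fit, and the subset used.
#' @export
stability_analysis <- function(cq, subset = "all",
                               methods = c("genorm", "deltact", "bestkeeper", "normfinder"),
                               efficiency = 2.0, groups = NULL, max_sd = 0.5) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is_collapsed(cq)) cq <- collapse_replicates(cq, max_sd = max_sd)
  cq <- subset_cq(cq, subset)
  rq <- linearise(cq, efficiency = efficiency)

  out <- list(subset = subset, n_samples = dplyr::n_distinct(cq$sample_id))
  if ("genorm" %in% methods) out$genorm <- genorm_rank(rq)
  if ("deltact" %in% methods) out$deltact <- deltact_scores(cq)
  if ("bestkeeper" %in% methods) out$bestkeeper <- bestkeeper(cq)
  if ("normfinder" %in% methods) out$normfinder <- normfinder(rq)
  if (!is.null(groups) && "normfinder" %in% methods) {
    out$normfinder_grouped <- normfinder(rq, groups = groups)
  }
  if (all(c("genorm", "deltact", "bestkeeper", "normfinder") %in% methods)) {
    out$consensus <- consensus_rank(out$genorm, out$deltact, out$bestkeeper,
                                    out$normfinder, context = subset)
  }
  structure(out, class = "stability_analysis")
}

#' @export
print.stability_analysis <- function(x, ...) {
  cat("Stability analysis, subset '", x$subset, "' (", x$n_samples, " samples)\n",
      sep = "")
  if (!is.null(x$consensus)) print(x$consensus) else
    cat("Methods run:", paste(intersect(names(x), c("genorm", "deltact", "bestkeeper",
                                                    "normfinder")), collapse = ", "), "\n")
  invisible(x)
}

write_manifest <- function(out_dir, command, inputs = list(), options = list(),
                           warnings = character()) {
  manifest <- list(
    command = command,
    package = "refstab",
    version = as.character(utils::packageVersion("refstab")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    options = options,
    config_hash = rlang::hash(list(command = command, inputs = inputs, options = options)),
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

ensure_dir <- function(path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE)) {
    stop_io(paste0("cannot create output directory: ", path))
  }
  invisible(path)
}

write_tsv_out <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, name))
}

#' Simulate a dataset and write it to disk
#'
#' Writes the simulated replicate-level Cq table as a long-dialect CSV, the
#' ground truth as JSON, and a run manifest.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed.
#' @param design,archetypes,params Passed to [simulate_cq()].
#' @return Invisibly, the [simulate_cq()] result.
#' @export
run_simulate <- function(out_dir, seed = 1, design = default_design(),
                         archetypes = default_archetypes(), params = sim_params()) {
  ensure_dir(out_dir)
  sim <- simulate_cq(design, archetypes, params, seed = seed)
  readr::write_csv(sim$cq, file.path(out_dir, "cq.csv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "simulate",
                 inputs = list(),
                 options = list(seed = seed, params = params,
                                n_samples = nrow(design), n_genes = nrow(archetypes)))
  invisible(sim)
}

#' Run stability methods and write ranked outputs
#'
#' Runs the requested methods plus the consensus ranking on one subset and
#' writes the per-gene tables as TSV files with a run manifest.
#'
#' @param cq A Cq tibble or a path to a long-dialect CSV/TSV.
#' @param out_dir Output directory.
#' @param subset,methods,efficiency,groups Passed to [stability_analysis()].
#' @return Invisibly, the [stability_analysis()] result.
#' @export
run_rank <- function(cq, out_dir, subset = "all",
                     methods = c("genorm", "deltact", "bestkeeper", "normfinder"),
                     efficiency = 2.0, groups = NULL) {
  ensure_dir(out_dir)
  input_path <- if (is.character(cq)) cq else NA_character_
  if (is.character(cq)) cq <- read_cq(cq, dialect = "long")
  res <- stability_analysis(cq, subset = subset, methods = methods,
                            efficiency = efficiency, groups = groups)
  if (!is.null(res$genorm)) {
    write_tsv_out(res$genorm$genes, out_dir, "genorm_m.tsv")
    write_tsv_out(res$genorm$removal_order, out_dir, "genorm_removal.tsv")
    write_tsv_out(res$genorm$v_curve, out_dir, "genorm_vcurve.tsv")
  }
  if (!is.null(res$deltact)) write_tsv_out(res$deltact, out_dir, "deltact.tsv")
  if (!is.null(res$bestkeeper)) {
    write_tsv_out(res$bestkeeper$genes, out_dir, "bestkeeper_genes.tsv")
    write_tsv_out(res$bestkeeper$index, out_dir, "bestkeeper_index.tsv")
  }
  if (!is.null(res$normfinder)) write_tsv_out(res$normfinder$genes, out_dir, "normfinder.tsv")
  if (!is.null(res$normfinder_grouped)) {
    write_tsv_out(res$normfinder_grouped$genes, out_dir, "normfinder_grouped.tsv")
    write_tsv_out(res$normfinder_grouped$components, out_dir, "normfinder_components.tsv")
  }
  if (!is.null(res$consensus)) write_tsv_out(res$consensus, out_dir, "consensus.tsv")
  write_manifest(out_dir, "rank",
                 inputs = list(cq = input_path),
                 options = list(subset = subset, methods = methods,
                                efficiency = efficiency))
  invisible(res)
}

#' Run priming QC and write the report
#'
#' @param cq A Cq tibble or path to a long-dialect CSV/TSV.
#' @param out_dir Output directory.
#' @param ... Passed to [priming_qc()].
#' @return Invisibly, the [priming_qc()] report.
#' @export
run_qc <- function(cq, out_dir, ...) {
  ensure_dir(out_dir)
  input_path <- if (is.character(cq)) cq else NA_character_
  if (is.character(cq)) cq <- read_cq(cq, dialect = "long")
  rep <- priming_qc(cq, ...)
  write_tsv_out(rep, out_dir, "priming_qc.tsv")
  write_manifest(out_dir, "qc", inputs = list(cq = input_path),
                 options = list(sentinels = attr(rep, "sentinels"),
                                sentinel_threshold = attr(rep, "sentinel_threshold"),
                                panel_threshold = attr(rep, "panel_threshold")))
  invisible(rep)
}

#' Run normalisation validation and write the report
#'
#' @param cq A Cq tibble or path to a long-dialect CSV/TSV.
#' @param refs Reference genes for the normalisation factor.
#' @param targets Target genes to validate against (default: all others).
#' @param out_dir Output directory.
#' @param efficiency Amplification efficiency for [linearise()].
#' @return Invisibly, the [validate_normalization()] report.
#' @export
run_validate <- function(cq, refs, out_dir, targets = NULL, efficiency = 2.0) {
  ensure_dir(out_dir)
  input_path <- if (is.character(cq)) cq else NA_character_
  if (is.character(cq)) cq <- read_cq(cq, dialect = "long")
  if (!is_collapsed(cq)) cq <- collapse_replicates(cq)
  rq <- linearise(cq, efficiency = efficiency)
  rep <- validate_normalization(rq, refs = refs, targets = targets)
  write_tsv_out(rep$cov, out_dir, "validation_cov.tsv")
  write_tsv_out(rep$trajectories, out_dir, "validation_trajectories.tsv")
  write_tsv_out(rep$nf, out_dir, "normalization_factor.tsv")
  write_manifest(out_dir, "validate", inputs = list(cq = input_path),
                 options = list(refs = refs, targets = rep$targets,
                                efficiency = efficiency))
  invisible(rep)
}
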