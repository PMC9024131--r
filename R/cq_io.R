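# Reading, validating, calibrating and collapsing raw Cq data, and
# linearisation to relative quantities (RQ).

# Sample-level metadata columns recognised throughout the package.
META_COLS <- c("tissue", "age_days", "litter", "cdna_batch", "is_calibrator")
TISSUES <- c("embryo", "head", "forelimb")

#' Read a Cq table from CSV/TSV
#'
#' Reads raw quantification-cycle (Cq) data in either of two dialects:
#' \describe{
#'   \item{long}{one row per well, columns `sample_id`, `gene`, `cq`, plus
#'     optional `well`, `plate` and the sample metadata columns `tissue`,
#'     `age_days`, `litter`, `cdna_batch`, `is_calibrator`.}
#'   \item{wide}{a gene-by-sample matrix whose first column is `gene` and
#'     remaining columns are sample ids; per-sample metadata may be supplied
#'     as a separate CSV via `meta` (keyed by `sample_id`).}
#' }
#' Cells that cannot be parsed as a number, or fall outside the plausible
#' Cq range (0, 45), are rejected row-by-row with a warning; missing values
#' (`NA`, empty) are kept and tracked as missing.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from extension).
#' @param dialect `"long"` (default, replicate-level wells) or `"wide"`.
#' @param meta Optional path to a sample metadata CSV (wide dialect only).
#' @return A tibble of Cq values (one row per well for the long dialect, one
#'   row per gene/sample cell for wide). Rejected rows are recorded in the
#'   `"rejected"` attribute.
#' @export
read_cq <- function(path, dialect = c("long", "wide"), meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (dialect == "long") {
    cq <- as_cq(raw)
  } else {
    if (!identical(names(raw)[1], "gene")) {
      stop_schema("wide dialect requires the first column to be named 'gene'")
    }
    long <- tidyr::pivot_longer(raw, -"gene", names_to = "sample_id", values_to = "cq")
    if (!is.null(meta)) {
      md <- readr::read_csv(meta, show_col_types = FALSE, progress = FALSE)
      if (!"sample_id" %in% names(md)) stop_schema("metadata file lacks required column: sample_id")
      long <- dplyr::left_join(long, md, by = "sample_id")
    }
    cq <- as_cq(long, require_well_unique = FALSE)
  }
  cq
}

#' Validate a data frame as a Cq table
#'
#' Coerces and validates the columns of an in-memory Cq table: `cq` parsed to
#' numeric, out-of-range values rejected with row indices, metadata types
#' checked (`tissue` from \{embryo, head, forelimb\}, `age_days` positive).
#'
#' @param x A data frame with at least `sample_id`, `gene`, `cq`.
#' @param require_well_unique Enforce uniqueness of (sample, gene, well).
#' @return A validated tibble; rows rejected for unparseable or out-of-range
#'   Cq are dropped and listed in the `"rejected"` attribute.
#' @export
as_cq <- function(x, require_well_unique = TRUE) {
  x <- tibble::as_tibble(x)
  required <- c("sample_id", "gene", "cq")
  for (col in required) {
    if (!col %in% names(x)) stop_schema(paste0("missing required column: ", col))
  }
  cq_chr <- as.character(x$cq)
  missing_mask <- is.na(cq_chr) | cq_chr %in% c("", "NA", "na", "NaN")
  cq_num <- suppressWarnings(as.numeric(cq_chr))
  bad_parse <- !missing_mask & is.na(cq_num)
  bad_range <- !missing_mask & !is.na(cq_num) & (cq_num <= 0 | cq_num >= 45 | !is.finite(cq_num))
  rejected <- which(bad_parse | bad_range)
  if (length(rejected)) {
    warn(paste0(length(rejected), " row(s) rejected (non-numeric or Cq outside (0,45)): rows ",
                paste(head(rejected, 10), collapse = ", "),
                if (length(rejected) > 10) ", ..." else ""))
  }
  x$cq <- cq_num
  x$cq[missing_mask] <- NA_real_
  keep <- !(bad_parse | bad_range)
  rejected_rows <- x[!keep, , drop = FALSE]
  x <- x[keep, , drop = FALSE]

  if ("age_days" %in% names(x)) {
    x$age_days <- as.numeric(x$age_days)
    if (any(!is.na(x$age_days) & x$age_days <= 0)) stop_schema("age_days must be > 0")
  }
  if ("tissue" %in% names(x)) {
    bad <- setdiff(unique(stats::na.omit(x$tissue)), TISSUES)
    if (length(bad)) stop_schema(paste0("unknown tissue value(s): ", paste(bad, collapse = ", ")))
  }
  if ("is_calibrator" %in% names(x)) {
    x$is_calibrator <- as.logical(x$is_calibrator)
  }
  if (require_well_unique && "well" %in% names(x)) {
    dup <- duplicated(x[, c("sample_id", "gene", "well")])
    if (any(dup)) {
      stop_schema(paste0("duplicate (sample, gene, well) record(s), e.g. row ", which(dup)[1]))
    }
  }
  # Metadata must be constant within a sample.
  for (col in intersect(META_COLS, names(x))) {
    n_per <- tapply(x[[col]], x$sample_id, function(v) length(unique(v[!is.na(v)])))
    if (any(n_per > 1, na.rm = TRUE)) {
      stop_schema(paste0("metadata column '", col, "' is not constant within sample_id"))
    }
  }
  attr(x, "rejected") <- rejected_rows
  x
}

# TRUE when the table has exactly one row per (gene, sample): i.e. replicate
# wells have been collapsed (or the input was a wide matrix).
is_collapsed <- function(cq) {
  !any(duplicated(cq[, c("sample_id", "gene")]))
}

#' Collapse replicate wells to per-(gene, sample) mean Cq
#'
#' Averages technical replicate wells for each gene/sample cell, recording the
#' replicate standard deviation and the number of wells. Cells whose replicate
#' SD exceeds `max_sd` are flagged (`high_sd`), never dropped. A single-well
#' cell gets SD 0.
#'
#' @param cq A replicate-level Cq tibble (see [read_cq()]).
#' @param max_sd Replicate-SD flag threshold in cycles (default 0.5).
#' @return A collapsed tibble with columns `sample_id`, `gene`, `cq`, `cq_sd`,
#'   `n_wells`, `high_sd` plus any sample metadata.
#' @export
collapse_replicates <- function(cq, max_sd = 0.5) {
  meta <- intersect(META_COLS, names(cq))
  out <- cq |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", "gene", meta)))) |>
    dplyr::summarise(
      cq_sd = if (sum(!is.na(.data$cq)) > 1) stats::sd(.data$cq, na.rm = TRUE) else 0,
      n_wells = sum(!is.na(.data$cq)),
      cq = if (all(is.na(.data$cq))) NA_real_ else mean(.data$cq, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(high_sd = .data$cq_sd > max_sd) |>
    dplyr::relocate("cq", .after = "gene")
  if (any(is.na(out$cq))) {
    warn(paste0(sum(is.na(out$cq)), " (gene, sample) cell(s) have no usable wells and remain missing"))
  }
  out
}

#' Between-plate calibration via shared calibrator samples
#'
#' Estimates a per-plate additive offset on the Cq scale from calibrator
#' samples shared between each plate and a reference plate, and subtracts it.
#' The offset for plate p is the mean, over shared (calibrator sample, gene)
#' pairs, of the difference between the plate-p mean Cq and the
#' reference-plate mean Cq. Applying the correction twice yields zero offsets.
#'
#' @param cq A Cq tibble with `plate` and `is_calibrator` columns.
#' @param reference_plate Plate id used as baseline; defaults to the
#'   lexicographically first plate.
#' @param per_gene Estimate one offset per (plate, gene) instead of pooling
#'   across genes (default `FALSE`, pooled).
#' @return The calibrated tibble; offsets are stored in the `"plate_offsets"`
#'   attribute (see [plate_offsets()]).
#' @export
plate_calibrate <- function(cq, reference_plate = NULL, per_gene = FALSE) {
  if (!"plate" %in% names(cq)) stop_schema("missing required column: plate")
  if (!"is_calibrator" %in% names(cq)) stop_schema("missing required column: is_calibrator")
  plates <- sort(unique(cq$plate))
  reference_plate <- reference_plate %||% plates[1]
  if (!reference_plate %in% plates) stop_data(paste0("reference plate not present: ", reference_plate))

  # Per (plate, gene, calibrator sample) mean Cq, so duplicate/triplicate
  # wells do not weight the offset.
  cal <- cq |>
    dplyr::filter(.data$is_calibrator, !is.na(.data$cq)) |>
    dplyr::group_by(.data$plate, .data$gene, .data$sample_id) |>
    dplyr::summarise(cq = mean(.data$cq), .groups = "drop")
  ref <- cal |>
    dplyr::filter(.data$plate == reference_plate) |>
    dplyr::select("gene", "sample_id", ref_cq = "cq")

  offsets <- lapply(setdiff(plates, reference_plate), function(p) {
    shared <- cal |>
      dplyr::filter(.data$plate == p) |>
      dplyr::inner_join(ref, by = c("gene", "sample_id"))
    if (nrow(shared) == 0) {
      stop_data(paste0("plate '", p, "' shares no calibrator sample with reference plate '",
                       reference_plate, "'"))
    }
    if (per_gene) {
      shared |>
        dplyr::group_by(.data$gene) |>
        dplyr::summarise(offset = mean(.data$cq - .data$ref_cq), .groups = "drop") |>
        dplyr::mutate(plate = p, n_shared = nrow(shared))
    } else {
      tibble::tibble(plate = p, gene = NA_character_,
                     offset = mean(shared$cq - shared$ref_cq), n_shared = nrow(shared))
    }
  })
  offsets <- dplyr::bind_rows(
    tibble::tibble(plate = reference_plate, gene = NA_character_, offset = 0,
                   n_shared = NA_integer_),
    dplyr::bind_rows(offsets)
  )

  if (per_gene) {
    out <- cq |>
      dplyr::left_join(dplyr::select(offsets, "plate", "gene", "offset"),
                       by = c("plate", "gene")) |>
      dplyr::mutate(cq = .data$cq - dplyr::coalesce(.data$offset, 0)) |>
      dplyr::select(-"offset")
  } else {
    off_vec <- setNames(offsets$offset, offsets$plate)
    out <- dplyr::mutate(cq, cq = .data$cq - unname(off_vec[as.character(.data$plate)]))
  }
  attr(out, "plate_offsets") <- offsets
  attr(out, "reference_plate") <- reference_plate
  out
}

#' Plate offsets estimated by the last calibration
#' @param cq A tibble returned by [plate_calibrate()].
#' @return Tibble of per-plate (or per plate/gene) additive offsets in cycles.
#' @export
plate_offsets <- function(cq) attr(cq, "plate_offsets")

#' Linearise Cq values to relative quantities (RQ)
#'
#' Converts collapsed Cq values to linear relative quantities,
#' RQ = E^(Cq_min - Cq), calibrated per gene to its minimum observed Cq in
#' the table, so every gene's maximum RQ is exactly 1 and all RQs lie in
#' (0, 1]. Missing Cq propagates to missing RQ.
#'
#' @param cq A collapsed Cq tibble (see [collapse_replicates()]).
#' @param efficiency Per-cycle amplification factor E, either a single value
#'   for all genes or a named vector keyed by gene. Must lie in [1.6, 2.1];
#'   default 2.0 (perfect doubling).
#' @return A tibble with columns `sample_id`, `gene`, `rq`, `efficiency` plus
#'   sample metadata.
#' @export
linearise <- function(cq, efficiency = 2.0) {
  if (!is_collapsed(cq)) {
    stop_data("linearise() requires a collapsed table; run collapse_replicates() first")
  }
  genes <- unique(cq$gene)
  if (is.null(names(efficiency))) {
    if (length(efficiency) != 1) stop_schema("unnamed efficiency must be a single value")
    eff <- setNames(rep(efficiency, length(genes)), genes)
  } else {
    missing_g <- setdiff(genes, names(efficiency))
    eff <- c(efficiency, setNames(rep(2.0, length(missing_g)), missing_g))[genes]
  }
  if (any(eff < 1.6 | eff > 2.1)) stop_schema("efficiency values must lie in [1.6, 2.1]")

  meta <- intersect(META_COLS, names(cq))
  cq |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(
      efficiency = unname(eff[.data$gene[1]]),
      rq = .data$efficiency^(min(.data$cq, na.rm = TRUE) - .data$cq)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("sample_id", "gene", "rq", "efficiency", meta)))
}

# gene x sample matrix from a collapsed Cq or RQ tibble.
value_matrix <- function(tbl, value) {
  wide <- tbl |>
    dplyr::select("sample_id", "gene", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  m
}

# Complete-case gene x sample submatrix: genes missing in more than
# `max_gene_missing` of samples are excluded (warning), then only samples
# complete for all remaining genes are kept.
complete_case_matrix <- function(m, max_gene_missing = 0.2) {
  frac_missing <- rowMeans(is.na(m))
  drop_genes <- rownames(m)[frac_missing > max_gene_missing]
  if (length(drop_genes)) {
    warn(paste0("excluding gene(s) missing in >", round(100 * max_gene_missing),
                "% of samples: ", paste(drop_genes, collapse = ", ")))
    m <- m[setdiff(rownames(m), drop_genes), , drop = FALSE]
  }
  keep_samples <- colSums(is.na(m)) == 0
  m <- m[, keep_samples, drop = FALSE]
  attr(m, "dropped_genes") <- drop_genes
  attr(m, "dropped_samples") <- names(keep_samples)[!keep_samples]
  m
}
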