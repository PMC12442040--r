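#' Pipeline configuration
#'
#' A single auditable container for every stage parameter. Defaults follow
#' the standard workflow values: picking threshold 200,000 counts,
#' prominence 0, distance 5 points; alignment at 3 ppm; CH2 Kendrick base
#' with ceiling rounding; analysis window KMD 0.10-0.50, m/z 200-1400;
#' series chaining and adduct collapsing at 2 ppm. The external lock-mass
#' recalibration parameters (`st`, `tl`, `lm`) are recorded for provenance
#' but not interpreted; the package's own recalibration is the linear ppm
#' model of [recalibrate_peaks()].
#'
#' @param picking A [picking_params()].
#' @param align_tol_ppm Centroid alignment tolerance (ppm).
#' @param kendrick A [kendrick_params()].
#' @param window A [kmd_window()].
#' @param chain_tol_ppm CH2 / vertical chaining tolerance (ppm).
#' @param k_max Maximum CH2 multiple per chaining edge.
#' @param kmd_tol KMD-class grouping tolerance.
#' @param collapse_tol_ppm Adduct/isotope collapse tolerance (ppm).
#' @param n_isotopes Isotopologues considered per adduct.
#' @param matrix_tol_ppm Matrix-ion flagging tolerance (ppm).
#' @param image_ppm Ion-image extraction half window (ppm).
#' @param policy A [ranking_policy()].
#' @param recal_provenance Named list of external recalibration parameters
#'   kept for the record.
#' @param seed Integer seed for simulation stages.
#' @return List of class `"kmd_config"`.
#' @export
kmd_config <- function(picking = picking_params(), align_tol_ppm = 3,
                       kendrick = kendrick_params(), window = kmd_window(),
                       chain_tol_ppm = 2, k_max = 10, kmd_tol = 0.0025,
                       collapse_tol_ppm = 2, n_isotopes = 2,
                       matrix_tol_ppm = 2, image_ppm = 3,
                       policy = ranking_policy(),
                       recal_provenance = list(st = 0.0003, tl = 0.02,
                                               lm = 0.002),
                       seed = 1L) {
  structure(list(picking = picking, align_tol_ppm = align_tol_ppm,
                 kendrick = kendrick, window = window,
                 chain_tol_ppm = chain_tol_ppm, k_max = k_max,
                 kmd_tol = kmd_tol, collapse_tol_ppm = collapse_tol_ppm,
                 n_isotopes = n_isotopes, matrix_tol_ppm = matrix_tol_ppm,
                 image_ppm = image_ppm, policy = policy,
                 recal_provenance = recal_provenance, seed = as.integer(seed)),
            class = "kmd_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips all defaults unchanged.
#'
#' @param config A [kmd_config()].
#' @param path YAML file path.
#' @return `write_kmd_config` invisibly returns `path`; `read_kmd_config`
#'   returns the reconstructed `kmd_config`.
#' @export
write_kmd_config <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_kmd_config
#' @export
read_kmd_config <- function(path) {
  plain <- yaml::read_yaml(path)
  kmd_config(
    picking = do.call(picking_params, plain$picking),
    align_tol_ppm = plain$align_tol_ppm,
    kendrick = do.call(kendrick_params, plain$kendrick[c("base", "nominal_mass",
                                                         "exact_mass", "rounding")]),
    window = do.call(kmd_window, plain$window),
    chain_tol_ppm = plain$chain_tol_ppm, k_max = plain$k_max,
    kmd_tol = plain$kmd_tol, collapse_tol_ppm = plain$collapse_tol_ppm,
    n_isotopes = plain$n_isotopes, matrix_tol_ppm = plain$matrix_tol_ppm,
    image_ppm = plain$image_ppm,
    policy = do.call(ranking_policy, plain$policy),
    recal_provenance = plain$recal_provenance,
    seed = plain$seed
  )
}

#' Run the full KMD analysis pipeline
#'
#' Stages, in order: peak picking, optional lock-mass recalibration,
#' cross-pixel centroid alignment, Kendrick projection, matrix-ion
#' flagging, KMD window filtering, KMD-class grouping, adduct/isotopologue
#' collapsing, CH2 horizontal chaining and H2 vertical chaining on the
#' canonical points, and exact-mass annotation of the canonical protonated
#' species.
#'
#' @param dataset An `msi_dataset` (profile spectra), or a path to an
#'   imzML file.
#' @param config A [kmd_config()].
#' @param lipid_table Reference table for annotation
#'   ([load_lipid_table()]).
#' @param matrix_mz Known matrix-ion m/z values to flag
#'   (default [matrix_ion_set()]).
#' @param reference_mz Optional lock-mass list; when given, peaks are
#'   recalibrated before alignment.
#' @return List of class `"kmd_pipeline"`: `peaks`, `aligned`, `points`
#'   (all Kendrick points with flags), `filtered` (window-passing,
#'   unflagged, with `kmd_class`, `group_id`, `canonical_mz`), `canonical`
#'   (collapsed points with `series_id` and `vertical_id`), `annotations`,
#'   `summary` (per-stage counts), `config`.
#' @export
run_kmd_pipeline <- function(dataset, config = kmd_config(),
                             lipid_table = load_lipid_table(),
                             matrix_mz = matrix_ion_set()$mz,
                             reference_mz = NULL) {
  if (is.character(dataset)) dataset <- read_imzml(dataset)

  peaks <- pick_peaks(dataset, config$picking)
  if (!is.null(reference_mz) && nrow(peaks)) {
    peaks <- recalibrate_peaks(peaks, reference_mz)
  }
  if (!nrow(peaks)) {
    empty <- tibble::tibble()
    return(structure(list(peaks = peaks, aligned = NULL,
                          points = empty, filtered = empty,
                          canonical = empty, annotations = empty,
                          summary = tibble::tibble(stage = "peaks", n = 0L),
                          config = config),
                     class = "kmd_pipeline"))
  }
  aligned <- align_peaks(peaks, config$align_tol_ppm)
  points <- kendrick_points(aligned, config$kendrick)
  points <- flag_matrix_ions(points, matrix_mz, config$matrix_tol_ppm)
  filtered <- filter_kmd_window(points, config$window)
  filtered <- filtered[!filtered$matrix_flag, , drop = FALSE]
  filtered <- group_kmd_classes(filtered, config$kmd_tol)
  filtered <- collapse_adducts(filtered, config$collapse_tol_ppm,
                               config$n_isotopes)
  canonical <- canonical_points(filtered, config$kendrick)
  canonical <- chain_ch2_series(canonical, config$chain_tol_ppm, config$k_max)
  canonical <- chain_vertical(canonical, "H2", config$chain_tol_ppm)
  # canonical points are protonated-monoisotopic where the adduct pattern
  # identified the cation; single-adduct families stay adduct-ambiguous, so
  # all three adduct hypotheses are offered to the annotator
  annotations <- annotate_mz(canonical$mz, lipid_table, policy = config$policy)

  summary <- tibble::tibble(
    stage = c("peaks", "bins", "points", "matrix_flagged", "window_filtered",
              "canonical", "ch2_series", "annotated"),
    n = c(nrow(peaks), nrow(aligned$bins), nrow(points),
          sum(points$matrix_flag), nrow(filtered), nrow(canonical),
          dplyr::n_distinct(canonical$series_id, na.rm = TRUE),
          dplyr::n_distinct(annotations$query_mz))
  )
  structure(list(peaks = peaks, aligned = aligned, points = points,
                 filtered = filtered, canonical = canonical,
                 annotations = annotations, summary = summary,
                 config = config),
            class = "kmd_pipeline")
}

#' @export
print.kmd_pipeline <- function(x, ...) {
  cat("KMD pipeline result\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.kmd_pipeline <- function(x, ...) {
  s <- stats::setNames(as.list(x$summary$n), x$summary$stage)
  tibble::as_tibble(s)
}

#' Recompute the bundled reference ion assignments
#'
#' Regression check over the bundled table of published ion assignments
#' (experimental m/z, elemental composition, adduct, theoretical m/z, ppm
#' error): recomputes every theoretical m/z from the composition and the
#' mass error from the experimental m/z, and reports agreement to 4 decimal
#' places and 0.2 ppm. Rows whose printed values carry known documented
#' quirks (first-isotope rounding, composition typos) are marked in the
#' `note` column and flagged `known_exception`.
#'
#' @param path Assignments CSV; defaults to the bundled table. Schema:
#'   `table_no`, `cloud`, `series`, `mz_exp`, `intensity`, `best_match`,
#'   `composition_printed`, `ion`, `mz_the`, `delta_ppm_printed`,
#'   `neutral_formula`, `note`.
#' @return Tibble with recomputed `mz_calc`, `delta_ppm_calc`, agreement
#'   flags `mz_agree_4dp`, `ppm_agree_0p2`, and `known_exception`.
#' @export
check_reference_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "published_ion_assignments.csv",
                        package = "kendrickmsi", mustWork = TRUE)
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  n <- nrow(tbl)
  mz_calc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- tbl$neutral_formula[i]
    if (is.na(f) || !nzchar(f)) next
    mz_calc[i] <- ion_mz(f, tbl$ion[i])
  }
  tbl$mz_calc <- round(mz_calc, 4)
  tbl$delta_ppm_calc <- ifelse(is.na(mz_calc), NA_real_,
                               round(abs(ppm_error(tbl$mz_exp, mz_calc)), 1))
  tbl$known_exception <- !is.na(tbl$note) & nzchar(tbl$note)
  tbl$mz_agree_4dp <- !is.na(tbl$mz_calc) & !is.na(tbl$mz_the) &
    abs(tbl$mz_calc - tbl$mz_the) < 5e-5
  tbl$ppm_agree_0p2 <- !is.na(tbl$delta_ppm_calc) &
    !is.na(tbl$delta_ppm_printed) &
    abs(tbl$delta_ppm_calc - tbl$delta_ppm_printed) <= 0.2 + 1e-9
  tbl
}
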