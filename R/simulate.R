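#' FT-ICR-like instrument model
#'
#' Forward-model parameters for the synthetic acquisition. Resolving power
#' follows the FT-ICR scaling `R(m) = R0 * ref_mz / m`, so peak FWHM grows
#' quadratically with m/z: `FWHM(m) = m / R(m) = m^2 / (R0 * ref_mz)`.
#' Mass-accuracy jitter is Gaussian in ppm with `sigma_ppm = 1` by default,
#' keeping 99.7% of centroid errors within 3 ppm. The default m/z range is
#' opened slightly below the 200-1400 analysis window so that the full CHCA
#' matrix cluster set (whose protonated monomer sits at m/z 190) is present
#' in the raw data; the KMD analysis window still starts at 200.
#'
#' @param mz_min,mz_max Simulated m/z range in Th (default 185-1400).
#' @param resolving_power FWHM resolving power at `ref_mz` (default 300,000).
#' @param ref_mz Reference m/z for the resolving power anchor (default 400).
#' @param sigma_ppm Standard deviation of the per-peak mass jitter in ppm.
#' @param points_per_fwhm Profile sampling density (default 6).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise (0 = noiseless).
#' @param baseline Additive baseline level in counts.
#' @return List of class `"instrument_model"`.
#' @export
instrument_model <- function(mz_min = 185, mz_max = 1400,
                             resolving_power = 3e5, ref_mz = 400,
                             sigma_ppm = 1, points_per_fwhm = 6,
                             noise_cv = 0.2, baseline = 0) {
  stopifnot(mz_min < mz_max, resolving_power > 0, points_per_fwhm >= 2)
  structure(list(mz_min = mz_min, mz_max = mz_max,
                 resolving_power = resolving_power, ref_mz = ref_mz,
                 sigma_ppm = sigma_ppm, points_per_fwhm = points_per_fwhm,
                 noise_cv = noise_cv, baseline = baseline),
            class = "instrument_model")
}

#' Peak full width at half maximum under the FT-ICR scaling
#' @param mz m/z values.
#' @param instrument An [instrument_model()].
#' @return FWHM in Th.
#' @export
peak_fwhm <- function(mz, instrument = instrument_model()) {
  mz^2 / (instrument$resolving_power * instrument$ref_mz)
}

#' Expand species assignments into per-region ion lists
#'
#' Each (species, adduct with positive weight, isotopologue) triple becomes
#' one ion with its theoretical m/z and expected peak height
#' `base_intensity * adduct_weight * isotopologue_abundance`.
#'
#' @param assignments Tibble as returned by [default_assignments()].
#' @param n_isotopes Number of carbon isotopologues per ion (default 2:
#'   monoisotopic + first isotope).
#' @return Tibble with one row per planted ion per (region, sub_region).
#' @export
expand_assignments <- function(assignments = default_assignments(),
                               n_isotopes = 2) {
  rows <- purrr::pmap(assignments, function(region, sub_region, species,
                                            formula, w_h, w_na, w_k,
                                            base_intensity) {
    w <- c("[M+H]+" = w_h, "[M+Na]+" = w_na, "[M+K]+" = w_k)
    w <- w[w > 0]
    if (!length(w)) stop("species ", species, " has no positive adduct weight",
                         call. = FALSE)
    iso <- isotope_pattern(formula, n = n_isotopes)
    grid <- tidyr::expand_grid(adduct = names(w), k = iso$k)
    grid$weight <- w[grid$adduct]
    grid$abundance <- iso$abundance[match(grid$k, iso$k)]
    grid$mz <- ion_mz(formula, grid$adduct) +
      iso$mz_offset[match(grid$k, iso$k)]
    tibble::tibble(region = region, sub_region = sub_region,
                   species = species, formula = formula,
                   adduct = grid$adduct, k = grid$k, mz = grid$mz,
                   height = base_intensity * grid$weight * grid$abundance)
  })
  dplyr::bind_rows(rows)
}

# evaluate gaussian peaks (center, height, fwhm) on a locally sampled union
# axis; returns list(mz, intensity)
.render_profile <- function(center, height, fwhm, points_per_fwhm, baseline) {
  if (!length(center)) return(list(mz = numeric(0), intensity = numeric(0)))
  segs <- lapply(seq_along(center), function(i) {
    step <- fwhm[i] / points_per_fwhm
    seq(center[i] - 4 * fwhm[i], center[i] + 4 * fwhm[i], by = step)
  })
  axis <- sort(unique(unlist(segs)))
  y <- rep(baseline, length(axis))
  for (i in seq_along(center)) {
    lo <- findInterval(center[i] - 4.5 * fwhm[i], axis) + 1L
    hi <- findInterval(center[i] + 4.5 * fwhm[i], axis)
    if (hi < lo) next
    idx <- lo:hi
    y[idx] <- y[idx] +
      height[i] * exp(-4 * log(2) * ((axis[idx] - center[i]) / fwhm[i])^2)
  }
  list(mz = axis, intensity = y)
}

#' Simulate one pixel's profile spectrum
#'
#' Every planted ion contributes a Gaussian peak centered at its theoretical
#' m/z perturbed by Gaussian ppm jitter, with FT-ICR FWHM and log-normal
#' intensity noise; the six CHCA matrix ions are added to every pixel. Ions
#' outside the instrument range are skipped with a warning.
#'
#' @param ions Tibble with columns `species`, `adduct`, `k`, `mz`, `height`
#'   (may have zero rows for a matrix-only pixel).
#' @param instrument An [instrument_model()].
#' @param matrix_ions Tibble from [matrix_ion_set()] with an added `height`
#'   column, or NULL to omit matrix background.
#' @return List with `mz`, `intensity` (profile arrays) and `truth` (tibble
#'   of realized peaks: `species`, `adduct`, `k`, `mz_true`, `mz_obs`,
#'   `intensity`).
#' @export
simulate_pixel_spectrum <- function(ions, instrument = instrument_model(),
                                    matrix_ions = NULL) {
  if (!is.null(matrix_ions)) {
    ions <- dplyr::bind_rows(
      ions[, c("species", "adduct", "k", "mz", "height")],
      tibble::tibble(species = matrix_ions$species,
                     adduct = matrix_ions$adduct, k = 0L,
                     mz = matrix_ions$mz, height = matrix_ions$height)
    )
  }
  out_of_range <- ions$mz < instrument$mz_min | ions$mz > instrument$mz_max
  if (any(out_of_range)) {
    warning(sum(out_of_range), " ion(s) outside the instrument m/z range skipped",
            call. = FALSE)
    ions <- ions[!out_of_range, , drop = FALSE]
  }
  n <- nrow(ions)
  eps <- if (instrument$sigma_ppm > 0) {
    stats::rnorm(n, 0, instrument$sigma_ppm) * 1e-6
  } else {
    rep(0, n)
  }
  noise <- if (instrument$noise_cv > 0) {
    sdlog <- sqrt(log(1 + instrument$noise_cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    rep(1, n)
  }
  center <- ions$mz * (1 + eps)
  height <- ions$height * noise
  prof <- .render_profile(center, height, peak_fwhm(center, instrument),
                          instrument$points_per_fwhm, instrument$baseline)
  truth <- tibble::tibble(species = ions$species, adduct = ions$adduct,
                          k = ions$k, mz_true = ions$mz, mz_obs = center,
                          intensity = height)
  list(mz = prof$mz, intensity = prof$intensity, truth = truth)
}

#' Simulate a full phantom MSI dataset with ground truth
#'
#' One profile spectrum per pixel: organ pixels carry their region's planted
#' species (with sub-region-dependent adduct weights for the ovary shell vs
#' core), and every pixel carries the CHCA matrix cluster ions. Reproducible
#' for a given seed.
#'
#' @param phantom A [build_phantom()] result (or a [phantom_spec()], which
#'   is built first).
#' @param assignments Species placement tibble ([default_assignments()]).
#' @param instrument An [instrument_model()].
#' @param seed Integer seed; defaults to the phantom spec's seed.
#' @param matrix_intensity Peak height of each matrix ion (present in all
#'   pixels; default 2e9, dominating the mean spectrum as MALDI matrix
#'   clusters do).
#' @param n_isotopes Carbon isotopologues per planted ion (default 2).
#' @return List of class `"msi_simulation"`: `dataset` (tibble of class
#'   `"msi_dataset"` with columns `x`, `y`, `region`, `mz`, `intensity`),
#'   `truth` (per-pixel realized peaks), `ions` (expanded planted ion
#'   table), `matrix_ions`, `phantom`.
#' @export
simulate_msi <- function(phantom = phantom_spec(),
                         assignments = default_assignments(),
                         instrument = instrument_model(),
                         seed = NULL,
                         matrix_intensity = 2e9,
                         n_isotopes = 2) {
  if (inherits(phantom, "phantom_spec")) phantom <- build_phantom(phantom)
  if (is.null(seed)) seed <- phantom$spec$seed
  set.seed(seed)

  ions <- expand_assignments(assignments, n_isotopes = n_isotopes)
  matrix_ions <- matrix_ion_set()
  matrix_ions$height <- matrix_intensity

  reg <- phantom$regions
  # resolve sub-region membership per pixel for sub-region-scoped species
  sub_of_pixel <- function(x, y) {
    for (nm in names(phantom$sub)) {
      if (phantom$sub[[nm]][y + 1L, x + 1L]) return(nm)
    }
    NA_character_
  }

  pixels <- vector("list", nrow(reg))
  truths <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    r <- reg$region[i]
    px_ions <- ions[ions$region == r, , drop = FALSE]
    if (nrow(px_ions) && any(!is.na(px_ions$sub_region))) {
      sub <- sub_of_pixel(reg$x[i], reg$y[i])
      keep <- is.na(px_ions$sub_region) |
        (!is.na(sub) & px_ions$sub_region == sub)
      px_ions <- px_ions[keep, , drop = FALSE]
    }
    sim <- simulate_pixel_spectrum(px_ions, instrument, matrix_ions)
    pixels[[i]] <- sim[c("mz", "intensity")]
    truths[[i]] <- sim$truth
  }

  dataset <- tibble::tibble(
    x = reg$x, y = reg$y, region = reg$region,
    mz = lapply(pixels, `[[`, "mz"),
    intensity = lapply(pixels, `[[`, "intensity")
  )
  attr(dataset, "pitch_um") <- phantom$spec$pitch_um
  attr(dataset, "dims") <- c(height = phantom$spec$height,
                             width = phantom$spec$width)
  attr(dataset, "seed") <- seed
  attr(dataset, "mode") <- "processed"
  class(dataset) <- c("msi_dataset", class(dataset))

  truth <- dplyr::bind_rows(
    purrr::map2(truths, seq_len(nrow(reg)),
                ~ dplyr::mutate(.x, x = reg$x[.y], y = reg$y[.y],
                                region = reg$region[.y], .before = 1))
  )

  structure(list(dataset = dataset, truth = truth, ions = ions,
                 matrix_ions = matrix_ions, phantom = phantom,
                 instrument = instrument, seed = seed),
            class = "msi_simulation")
}
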