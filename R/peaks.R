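#' Peak-picking parameters
#'
#' Defaults follow routine MALDI-FT-ICR MSI processing of profile data: an
#' intensity threshold of 200,000 counts, zero prominence, and a minimum
#' peak distance of 5 data points.
#'
#' @param threshold Minimum apex intensity in counts.
#' @param prominence Minimum peak prominence (0 disables the check).
#' @param min_distance Minimum index separation between retained peaks, in
#'   data points (>= 1); of two close peaks the taller wins.
#' @return List of class `"picking_params"`.
#' @export
picking_params <- function(threshold = 200000, prominence = 0,
                           min_distance = 5) {
  stopifnot(threshold >= 0, prominence >= 0, min_distance >= 1)
  structure(list(threshold = threshold, prominence = prominence,
                 min_distance = as.integer(min_distance)),
            class = "picking_params")
}

# quadratic vertex through three (x, y) points; NA when degenerate
.parabola_vertex <- function(x1, x2, x3, y1, y2, y3) {
  d1 <- (y2 - y1) / (x2 - x1)
  a <- ((y3 - y2) / (x3 - x2) - d1) / (x3 - x1)
  if (!is.finite(a) || a >= 0) return(NA_real_)
  b <- d1 - a * (x1 + x2)
  -b / (2 * a)
}

# prominence of peak at index i: height above the higher of the two valley
# minima found walking out to the nearest taller sample (or the edge)
.prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]; j <- i - 1L
  while (j >= 1L && y[j] <= y[i]) { left_min <- min(left_min, y[j]); j <- j - 1L }
  if (j < 1L) left_min <- min(y[1:i])
  right_min <- y[i]; j <- i + 1L
  while (j <= n && y[j] <= y[i]) { right_min <- min(right_min, y[j]); j <- j + 1L }
  if (j > n) right_min <- min(y[i:n])
  y[i] - max(left_min, right_min)
}

#' Pick centroid peaks from one profile spectrum
#'
#' Local maxima with apex intensity at or above the threshold, prominence at
#' or above the configured minimum, and pairwise index separation at least
#' `min_distance` (ties resolved by keeping the higher peak). Each retained
#' apex is refined to a centroid m/z by parabolic interpolation through the
#' apex and its two neighbors on log intensity, which is exact for Gaussian
#' peak shapes; the raw-intensity parabola is used when a neighbor is
#' non-positive.
#'
#' @param mz Strictly increasing numeric m/z axis.
#' @param intensity Non-negative intensities, same length.
#' @param params A [picking_params()].
#' @return Tibble with columns `mz` (centroid), `intensity` (apex), `index`.
#' @export
find_spectrum_peaks <- function(mz, intensity, params = picking_params()) {
  n <- length(mz)
  empty <- tibble::tibble(mz = numeric(0), intensity = numeric(0),
                          index = integer(0))
  if (n < 3) return(empty)
  y <- intensity
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_max & y >= params$threshold)
  if (params$prominence > 0 && length(cand)) {
    prom <- vapply(cand, function(i) .prominence(y, i), numeric(1))
    cand <- cand[prom >= params$prominence]
  }
  if (!length(cand)) return(empty)
  # enforce minimum distance, taller peaks first
  cand <- cand[order(y[cand], decreasing = TRUE)]
  keep <- logical(0); kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= params$min_distance)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  centroid <- vapply(kept, function(i) {
    xs <- mz[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
    v <- if (all(ys > 0)) {
      .parabola_vertex(xs[1], xs[2], xs[3], log(ys[1]), log(ys[2]), log(ys[3]))
    } else {
      .parabola_vertex(xs[1], xs[2], xs[3], ys[1], ys[2], ys[3])
    }
    if (is.na(v) || v < xs[1] || v > xs[3]) xs[2] else v
  }, numeric(1))
  tibble::tibble(mz = centroid, intensity = y[kept], index = kept)
}

#' Pick peaks across all pixels of an MSI dataset
#'
#' @param dataset An `msi_dataset` tibble (profile spectra).
#' @param params A [picking_params()].
#' @return Tibble of class `"centroid_peaks"` with columns `x`, `y`, `mz`,
#'   `intensity`; grid dimensions carried as an attribute.
#' @export
pick_peaks <- function(dataset, params = picking_params()) {
  stopifnot(nrow(dataset) > 0)
  per_pixel <- purrr::map(seq_len(nrow(dataset)), function(i) {
    pk <- find_spectrum_peaks(dataset$mz[[i]], dataset$intensity[[i]], params)
    if (!nrow(pk)) return(NULL)
    tibble::tibble(x = dataset$x[i], y = dataset$y[i],
                   mz = pk$mz, intensity = pk$intensity)
  })
  peaks <- dplyr::bind_rows(per_pixel)
  if (!nrow(peaks)) {
    peaks <- tibble::tibble(x = integer(0), y = integer(0),
                            mz = numeric(0), intensity = numeric(0))
  }
  attr(peaks, "dims") <- attr(dataset, "dims")
  class(peaks) <- c("centroid_peaks", class(peaks))
  peaks
}

#' Lock-mass style linear recalibration of centroid peaks
#'
#' Matches observed peaks to a reference m/z list (nearest observed peak
#' within `tol_ppm`), fits the linear ppm-drift model
#' `ppm(m) = a + b * m` by least squares on the matched pairs, and applies
#' the inverse correction to all peak m/z values. Intensities are never
#' changed. With fewer than two matched references the peaks are returned
#' unchanged and the model is flagged.
#'
#' @param peaks A `centroid_peaks` tibble (or any tibble with `mz`).
#' @param reference_mz Numeric vector of reference (theoretical) m/z values.
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @return The peaks tibble with corrected `mz`; the fitted model (class
#'   `"recal_model"`) is attached as attribute `"recal"` and is accessible
#'   via [generics::tidy()] / [generics::glance()].
#' @export
recalibrate_peaks <- function(peaks, reference_mz, tol_ppm = 5) {
  matches <- purrr::map_dfr(reference_mz, function(ref) {
    d_ppm <- ppm_error(peaks$mz, ref)
    i <- which.min(abs(d_ppm))
    if (!length(i) || abs(d_ppm[i]) > tol_ppm) return(NULL)
    tibble::tibble(observed = peaks$mz[i], reference = ref, ppm = d_ppm[i])
  })
  if (nrow(matches) < 2) {
    model <- structure(list(a = 0, b = 0, rms_ppm = NA_real_,
                            n_matched = nrow(matches), status = "no-op"),
                       class = "recal_model")
    warning("fewer than 2 reference matches; recalibration skipped",
            call. = FALSE)
  } else {
    fit <- stats::lm(ppm ~ observed, data = matches)
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
    corrected <- matches$observed / (1 + (a + b * matches$observed) * 1e-6)
    model <- structure(list(a = a, b = b,
                            rms_ppm = sqrt(mean(ppm_error(corrected,
                                                          matches$reference)^2)),
                            n_matched = nrow(matches), status = "ok"),
                       class = "recal_model")
    peaks$mz <- peaks$mz / (1 + (model$a + model$b * peaks$mz) * 1e-6)
  }
  attr(peaks, "recal") <- model
  peaks
}

#' @exportS3Method generics::tidy
tidy.recal_model <- function(x, ...) {
  tibble::tibble(term = c("intercept_ppm", "slope_ppm_per_mz"),
                 estimate = c(x$a, x$b))
}

#' @exportS3Method generics::glance
glance.recal_model <- function(x, ...) {
  tibble::tibble(n_matched = x$n_matched, rms_ppm = x$rms_ppm,
                 status = x$status)
}

#' Align centroid peaks across pixels into consensus m/z bins
#'
#' Single-linkage gap clustering on the pooled, sorted centroid list: a new
#' bin starts whenever the gap to the previous centroid exceeds `tol_ppm`
#' (relative to the current centroid). Deterministic and invariant to pixel
#' order. The bin representative is the intensity-weighted mean m/z; when a
#' pixel contributes several centroids to one bin their intensities are
#' summed, so total ion current is conserved.
#'
#' @param peaks A `centroid_peaks` tibble.
#' @param tol_ppm Gap tolerance in ppm (default 3, the instrument's targeted
#'   mass accuracy).
#' @return List of class `"aligned_peaks"`: `bins` (tibble `bin`, `mz`,
#'   `n_pixels`, `total_intensity`), `intensities` (long tibble `bin`, `x`,
#'   `y`, `intensity`), `tol_ppm`, `dims`.
#' @export
align_peaks <- function(peaks, tol_ppm = 3) {
  stopifnot(nrow(peaks) >= 1)
  ord <- order(peaks$mz)
  p <- peaks[ord, ]
  gap <- c(Inf, diff(p$mz))
  new_bin <- gap > tol_ppm * 1e-6 * p$mz
  p$bin <- cumsum(new_bin)

  bins <- p |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
                     n_pixels = dplyr::n_distinct(.data$x * 1e6 + .data$y),
                     total_intensity = sum(.data$intensity),
                     .groups = "drop")
  intensities <- p |>
    dplyr::group_by(.data$bin, .data$x, .data$y) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")

  structure(list(bins = bins, intensities = intensities, tol_ppm = tol_ppm,
                 dims = attr(peaks, "dims")),
            class = "aligned_peaks")
}

#' @export
print.aligned_peaks <- function(x, ...) {
  cat("Aligned peak matrix:", nrow(x$bins), "consensus bins,",
      dplyr::n_distinct(x$intensities$x * 1e6 + x$intensities$y),
      "occupied pixels, tolerance", x$tol_ppm, "ppm\n")
  invisible(x)
}

#' Per-pixel total ion current
#'
#' @param x An `msi_dataset` (profile TIC) or `aligned_peaks` (binned TIC).
#' @return Tibble with columns `x`, `y`, `tic`.
#' @export
pixel_tic <- function(x) {
  if (inherits(x, "msi_dataset")) {
    xs <- x$x; ys <- x$y
    tics <- vapply(x$intensity, sum, numeric(1))
    tibble::tibble(x = xs, y = ys, tic = tics)
  } else if (inherits(x, "aligned_peaks")) {
    x$intensities |>
      dplyr::group_by(.data$x, .data$y) |>
      dplyr::summarise(tic = sum(.data$intensity), .groups = "drop")
  } else {
    stop("unsupported input for pixel_tic()", call. = FALSE)
  }
}

#' Mean spectrum over all pixels of an aligned peak matrix
#'
#' @param aligned An `aligned_peaks` object.
#' @param n_pixels Total pixel count to average over; defaults to the grid
#'   area when known, else the number of occupied pixels.
#' @return Tibble `bin`, `mz`, `mean_intensity`.
#' @export
mean_spectrum <- function(aligned, n_pixels = NULL) {
  if (is.null(n_pixels)) {
    dims <- aligned$dims
    n_pixels <- if (!is.null(dims)) prod(dims) else
      dplyr::n_distinct(aligned$intensities$x * 1e6 + aligned$intensities$y)
  }
  dplyr::mutate(aligned$bins,
                mean_intensity = .data$total_intensity / n_pixels) |>
    dplyr::select("bin", "mz", "mean_intensity")
}
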