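.new_ion_image <- function(grid, pitch_um = NA_real_, provenance = list()) {
  structure(grid, class = c("ion_image", "matrix", "array"),
            pitch_um = pitch_um, provenance = provenance)
}

.image_dims <- function(aligned) {
  dims <- aligned$dims
  if (is.null(dims)) {
    dims <- c(height = max(aligned$intensities$y) + 1L,
              width = max(aligned$intensities$x) + 1L)
  }
  dims
}

# accumulate a long (bin, x, y, intensity) table onto a grid; origin
# top-left, x = column, y = row, 0-based
.accumulate <- function(rows, dims) {
  grid <- matrix(0, nrow = dims[["height"]], ncol = dims[["width"]])
  if (nrow(rows)) {
    lin <- (rows$x) * dims[["height"]] + rows$y + 1L # column-major linear index
    sums <- rowsum(rows$intensity, group = lin)
    grid[as.integer(rownames(sums))] <- sums[, 1]
  }
  grid
}

#' Reconstruct a single-ion image
#'
#' Per pixel, the summed intensity of all consensus bins within a ppm window
#' of the target m/z; pixels with no matching bin are 0.
#'
#' @param aligned An `aligned_peaks` object.
#' @param target_mz Target m/z.
#' @param ppm Half-window in ppm (default 3; 0 selects exactly equal bins).
#' @param mz_range Valid instrument m/z range; targets outside error.
#' @return An `"ion_image"` matrix (height x width, origin top-left).
#' @export
ion_image <- function(aligned, target_mz, ppm = 3, mz_range = c(185, 1400)) {
  if (ppm < 0) stop("ppm window must be >= 0", call. = FALSE)
  if (target_mz < mz_range[1] || target_mz > mz_range[2]) {
    stop("target m/z ", target_mz, " outside instrument range [",
         mz_range[1], ", ", mz_range[2], "]", call. = FALSE)
  }
  sel <- abs(ppm_error(aligned$bins$mz, target_mz)) <= ppm
  bins <- aligned$bins$bin[sel]
  rows <- aligned$intensities[aligned$intensities$bin %in% bins, , drop = FALSE]
  .new_ion_image(.accumulate(rows, .image_dims(aligned)),
                 provenance = list(target_mz = target_mz, ppm = ppm))
}

#' Summed (TIC) image of a set of consensus bins
#'
#' Pixel-wise sum of the member bins' intensities. Members are deduplicated
#' by bin identity, so the result is exactly additive over disjoint member
#' sets and equals the sum of the members' individual ion images.
#'
#' @param aligned An `aligned_peaks` object.
#' @param bins Integer vector of member bin ids (non-empty).
#' @return An `"ion_image"` matrix.
#' @export
cloud_tic_image <- function(aligned, bins) {
  if (!length(bins)) stop("empty member list", call. = FALSE)
  bins <- unique(bins)
  rows <- aligned$intensities[aligned$intensities$bin %in% bins, , drop = FALSE]
  .new_ion_image(.accumulate(rows, .image_dims(aligned)),
                 provenance = list(bins = bins))
}

#' Total ion current image over all bins
#' @param aligned An `aligned_peaks` object.
#' @return An `"ion_image"` matrix.
#' @export
tic_image <- function(aligned) {
  cloud_tic_image(aligned, aligned$bins$bin)
}

#' Normalize an ion image
#'
#' @param image An `"ion_image"`.
#' @param mode `"none"` (identity) or `"per-pixel-TIC"` (divide by the
#'   pixel TIC; zero-TIC pixels yield 0).
#' @param tic TIC image, required for TIC mode.
#' @return Normalized `"ion_image"`.
#' @export
normalize_image <- function(image, mode = c("none", "per-pixel-TIC"),
                            tic = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(image)
  if (is.null(tic)) stop("TIC image required for per-pixel-TIC mode", call. = FALSE)
  stopifnot(all(dim(image) == dim(tic)))
  out <- unclass(image) / ifelse(unclass(tic) > 0, unclass(tic), Inf)
  .new_ion_image(out, pitch_um = attr(image, "pitch_um"),
                 provenance = c(attr(image, "provenance"),
                                list(normalization = mode)))
}

#' Fraction of image intensity inside a region mask
#'
#' @param image An `"ion_image"` (or plain matrix).
#' @param mask Logical matrix of the same shape.
#' @return Fraction in \[0, 1\]; 0 when the image is empty.
#' @export
region_enrichment <- function(image, mask) {
  stopifnot(all(dim(image) == dim(mask)))
  total <- sum(image)
  if (total <= 0) return(0)
  sum(image[mask]) / total
}

#' @export
print.ion_image <- function(x, ...) {
  cat("Ion image", nrow(x), "x", ncol(x), "- total intensity",
      format(sum(x), digits = 4), "\n")
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ion_image <- function(object, clip_quantile = 0.99, ...) {
  df <- tibble::tibble(
    x = rep(0:(ncol(object) - 1), each = nrow(object)),
    y = rep(0:(nrow(object) - 1), times = ncol(object)),
    intensity = as.vector(unclass(object))
  )
  cap <- stats::quantile(df$intensity[df$intensity > 0], clip_quantile,
                         na.rm = TRUE)
  if (!is.finite(cap) || cap <= 0) cap <- 1
  df$display <- pmin(df$intensity, cap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$display)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
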