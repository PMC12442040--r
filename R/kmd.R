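#' KMD analysis window
#'
#' The lipid-focused selection window in (m/z, KMD) space: ceiling-mode KMD
#' between 0.10 and 0.50 and m/z between 200 and 1400.
#'
#' @param kmd_min,kmd_max KMD bounds.
#' @param mz_min,mz_max m/z bounds in Th.
#' @return List of class `"kmd_window"`.
#' @export
kmd_window <- function(kmd_min = 0.10, kmd_max = 0.50,
                       mz_min = 200, mz_max = 1400) {
  stopifnot(kmd_min < kmd_max, mz_min < mz_max)
  structure(list(kmd_min = kmd_min, kmd_max = kmd_max,
                 mz_min = mz_min, mz_max = mz_max),
            class = "kmd_window")
}

#' Kendrick points of an aligned peak matrix
#'
#' One point per consensus bin, carrying its Kendrick mass and mass defect.
#'
#' @param aligned An `aligned_peaks` object (or a tibble with `mz` and
#'   optionally `total_intensity`).
#' @param params A [kendrick_params()].
#' @return Tibble with columns `bin`, `mz`, `km`, `kmd`, `intensity`.
#' @export
kendrick_points <- function(aligned, params = kendrick_params()) {
  bins <- if (inherits(aligned, "aligned_peaks")) aligned$bins else aligned
  stopifnot(nrow(bins) > 0)
  kt <- kendrick_transform(bins$mz, params)
  tibble::tibble(
    bin = if ("bin" %in% names(bins)) bins$bin else seq_len(nrow(bins)),
    mz = bins$mz, km = kt$km, kmd = kt$kmd,
    intensity = if ("total_intensity" %in% names(bins)) bins$total_intensity
                else if ("intensity" %in% names(bins)) bins$intensity
                else NA_real_
  )
}

#' Filter Kendrick points to the analysis window
#'
#' Keeps points with `kmd_min <= KMD <= kmd_max` and
#' `mz_min <= m/z <= mz_max` (boundary inclusive); order preserved;
#' idempotent.
#'
#' @param points Tibble with `mz` and `kmd` columns.
#' @param window A [kmd_window()].
#' @return Filtered tibble.
#' @export
filter_kmd_window <- function(points, window = kmd_window()) {
  dplyr::filter(points,
                .data$kmd >= window$kmd_min, .data$kmd <= window$kmd_max,
                .data$mz >= window$mz_min, .data$mz <= window$mz_max)
}

#' Flag points matching known matrix cluster ions
#'
#' @param points Tibble with an `mz` column.
#' @param matrix_mz Numeric vector of matrix ion m/z values (e.g.
#'   `matrix_ion_set()$mz`); may be empty.
#' @param tol_ppm Match tolerance in ppm (default 2).
#' @return `points` with an added logical `matrix_flag` column.
#' @export
flag_matrix_ions <- function(points, matrix_mz, tol_ppm = 2) {
  flag <- rep(FALSE, nrow(points))
  for (m in matrix_mz) {
    flag <- flag | abs(ppm_error(points$mz, m)) <= tol_ppm
  }
  points$matrix_flag <- flag
  points
}

# --- union-find ------------------------------------------------------------

.uf_new <- function(n) seq_len(n)

.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

.uf_union <- function(parent, i, j) {
  ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

# generic step-mass chaining: edge between i < j when the mass difference is
# an integer multiple (1..k_max) of step_mass within tol_ppm of the heavier
# member; returns integer component ids (NA for singletons)
.chain_by_step <- function(mz, step_mass, tol_ppm, k_max, span_limit = Inf) {
  n <- length(mz)
  if (n == 0) return(integer(0))
  ord <- order(mz)
  m <- mz[ord]
  parent <- .uf_new(n)
  for (k in seq_len(k_max)) {
    target <- m + k * step_mass
    if (min(target) - max(m) > 0) break
    tol <- tol_ppm * 1e-6 * target
    lo <- findInterval(target - tol, m) + 1L
    hi <- findInterval(target + tol, m)
    for (i in which(hi >= lo)) {
      for (j in lo[i]:hi[i]) {
        if (j == i) next
        parent <- .uf_union(parent, ord[i], ord[j])
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  if (is.finite(span_limit)) {
    # split components exceeding the total m/z span limit by walking members
    # in m/z order and starting a new sub-component when the running span
    # from the segment start would be exceeded
    next_id <- max(roots) + 1L
    for (r in unique(roots)) {
      members <- which(roots == r)
      if (length(members) < 2) next
      members <- members[order(mz[members])]
      mm <- mz[members]
      if (max(mm) - min(mm) <= span_limit) next
      start <- mm[1]
      seg <- integer(length(mm))
      cur <- 0L
      for (i in seq_along(mm)) {
        if (mm[i] - start > span_limit) { cur <- cur + 1L; start <- mm[i] }
        seg[i] <- cur
      }
      for (s in unique(seg)) {
        roots[members[seg == s]] <- next_id
        next_id <- next_id + 1L
      }
    }
  }
  sizes <- table(roots)
  keep <- as.integer(names(sizes)[sizes >= 2])
  match(roots, keep)
}

#' Chain CH2 homologous series (horizontal alignments)
#'
#' Groups points whose mass differences are integer multiples of the CH2
#' exact mass (14.01565 Da) within a relative tolerance. Series are the
#' connected components with at least two members of the graph whose edges
#' link points at `k` CH2 steps, `k` in `1..k_max`; the ppm tolerance is
#' measured against the heavier member of each pair. Points flagged as
#' matrix ions (column `matrix_flag`) are never chained.
#'
#' @param points Tibble with `mz` (and optionally `matrix_flag`).
#' @param tol_ppm Relative tolerance in ppm (default 2).
#' @param k_max Largest CH2 multiple considered per edge (default 10).
#' @param step_mass Step exact mass (default CH2, 14.01565).
#' @return `points` with an added integer `series_id` column (NA for
#'   singletons and matrix-flagged points).
#' @export
chain_ch2_series <- function(points, tol_ppm = 2, k_max = 10,
                             step_mass = round(monoisotopic_mass("CH2"), 5)) {
  eligible <- if ("matrix_flag" %in% names(points)) !points$matrix_flag
              else rep(TRUE, nrow(points))
  ids <- rep(NA_integer_, nrow(points))
  ids[eligible] <- .chain_by_step(points$mz[eligible], step_mass, tol_ppm, k_max)
  points$series_id <- ids
  points
}

.vertical_steps <- function() {
  c(H2 = round(monoisotopic_mass("H2"), 5),
    O  = round(monoisotopic_mass("O"), 5))
}

#' Chain vertical series (unsaturation / oxidation groups)
#'
#' Same chaining as [chain_ch2_series()] but with the H2 (2.01565 Da) or O
#' (15.99491 Da) step, linking nearly isobaric species differing in degrees
#' of unsaturation or oxidation. Components are restricted to a total m/z
#' span of `span_steps` step masses.
#'
#' @param points Tibble with `mz` (and optionally `matrix_flag`).
#' @param step `"H2"` or `"O"`.
#' @param tol_ppm Relative tolerance in ppm (default 2).
#' @param span_steps Maximum component span in step units (default 3).
#' @return `points` with an added `vertical_id` column.
#' @export
chain_vertical <- function(points, step = c("H2", "O"), tol_ppm = 2,
                           span_steps = 3) {
  step <- match.arg(step)
  step_mass <- .vertical_steps()[[step]]
  eligible <- if ("matrix_flag" %in% names(points)) !points$matrix_flag
              else rep(TRUE, nrow(points))
  ids <- rep(NA_integer_, nrow(points))
  ids[eligible] <- .chain_by_step(points$mz[eligible], step_mass, tol_ppm,
                                  k_max = span_steps,
                                  span_limit = span_steps * step_mass * 1.001)
  points$vertical_id <- ids
  points
}

#' Group points into KMD classes
#'
#' Single-linkage clustering of points along the KMD axis with an absolute
#' KMD tolerance; ions differing only by CH2 units share a KMD value and
#' fall into one class.
#'
#' @param points Tibble with a `kmd` column.
#' @param tol KMD gap tolerance (default 0.0025, about 2 mDa at the CH2
#'   scale, consistent with 2 ppm chaining at m/z 800).
#' @return `points` with an added `kmd_class` column.
#' @export
group_kmd_classes <- function(points, tol = 0.0025) {
  ord <- order(points$kmd)
  gap <- c(Inf, diff(points$kmd[ord]))
  cls <- cumsum(gap > tol)
  points$kmd_class <- integer(nrow(points))
  points$kmd_class[ord] <- cls
  points
}

# states of the adduct x isotopologue grid, as mass offsets relative to the
# protonated monoisotopic ion
.collapse_states <- function(n_isotopes) {
  shifts <- adduct_mass_shifts()
  adducts <- c("[M+H]+" = 0, "[M+Na]+" = shifts[["Na-H"]],
               "[M+K]+" = shifts[["K-H"]])
  grid <- expand.grid(adduct = names(adducts), k = 0:(n_isotopes - 1),
                      stringsAsFactors = FALSE)
  grid$offset <- adducts[grid$adduct] + grid$k * shifts[["13C"]]
  grid[order(grid$offset), ]
}

#' Collapse adduct and isotopologue series onto protonated monoisotopic points
#'
#' Transforms signal series coming from different carbon-13 isotopologues or
#' Na/K cation adducts of one species into a single protonated monoisotopic
#' point. For every point and every pairwise difference of
#' (adduct, isotopologue) states, the best partner (smallest absolute ppm)
#' within tolerance is linked; union-find merges the chains. The canonical
#' m/z of a group is the protonated monoisotopic interpretation of its
#' lowest member: the lowest-offset state assignment that explains all group
#' members is chosen, so when no `[M+H]+` ion is observed the canonical m/z
#' is imputed by shift subtraction. Group intensity is the sum over members.
#'
#' @param points Tibble with `mz` and `intensity` (and optionally
#'   `matrix_flag`; flagged points are left ungrouped).
#' @param tol_ppm Tolerance in ppm against the heavier member (default 2).
#' @param n_isotopes Isotopologues per adduct considered (default 2).
#' @return `points` with added columns `group_id` (integer) and
#'   `canonical_mz` (imputed protonated monoisotopic m/z of the group).
#' @export
collapse_adducts <- function(points, tol_ppm = 2, n_isotopes = 2) {
  n <- nrow(points)
  eligible <- if ("matrix_flag" %in% names(points)) !points$matrix_flag
              else rep(TRUE, n)
  idx <- which(eligible)
  mz <- points$mz[idx]
  m <- length(mz)
  states <- .collapse_states(n_isotopes)
  offs <- states$offset
  # positive pairwise state differences (deduplicated at 1e-6 Da)
  deltas <- sort(unique(round(as.vector(outer(offs, offs, "-")), 6)))
  deltas <- deltas[deltas > 1e-6]

  parent <- .uf_new(m)
  ord <- order(mz)
  ms <- mz[ord]
  for (d in deltas) {
    target <- ms + d
    tol <- tol_ppm * 1e-6 * target
    lo <- findInterval(target - tol, ms) + 1L
    hi <- findInterval(target + tol, ms)
    for (i in which(hi >= lo)) {
      js <- lo[i]:hi[i]
      js <- js[js != i]
      if (!length(js)) next
      best <- js[which.min(abs(ms[js] - target[i]))]
      parent <- .uf_union(parent, ord[i], ord[best])
    }
  }
  roots <- vapply(seq_len(m), function(i) .uf_find(parent, i), integer(1))
  group <- match(roots, unique(roots))

  canonical <- numeric(m)
  for (g in unique(group)) {
    members <- which(group == g)
    mm <- mz[members]
    base <- min(mm)
    rel <- mm - base
    chosen <- NA_real_
    for (s in seq_len(nrow(states))) {
      cand_off <- offs[s]
      ok <- vapply(seq_along(rel), function(i) {
        d <- rel[i] + cand_off
        any(abs(d - offs) <= tol_ppm * 1e-6 * mm[i])
      }, logical(1))
      if (all(ok)) { chosen <- cand_off; break }
    }
    if (is.na(chosen)) chosen <- 0
    canonical[members] <- base - chosen
  }

  points$group_id <- NA_integer_
  points$canonical_mz <- NA_real_
  points$group_id[idx] <- group
  points$canonical_mz[idx] <- canonical
  points
}

#' Canonical (collapsed) points of an adduct/isotope grouping
#'
#' @param points Output of [collapse_adducts()].
#' @param params Kendrick parameters used to recompute KM/KMD of the
#'   canonical m/z.
#' @return Tibble with one row per group: `group_id`, `mz` (canonical
#'   protonated monoisotopic), `km`, `kmd`, `intensity` (sum over members),
#'   `n_members`.
#' @export
canonical_points <- function(points, params = kendrick_params()) {
  grouped <- dplyr::filter(points, !is.na(.data$group_id))
  out <- grouped |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(mz = .data$canonical_mz[1],
                     intensity = sum(.data$intensity),
                     n_members = dplyr::n(), .groups = "drop")
  kt <- kendrick_transform(out$mz, params)
  out$km <- kt$km
  out$kmd <- kt$kmd
  out[, c("group_id", "mz", "km", "kmd", "intensity", "n_members")]
}

#' Select a cloud of points in (m/z, KMD) space
#'
#' Membership by boundary-inclusive point-in-geometry test. The geometry is
#' either an axis-aligned rectangle (`mz_range` + `kmd_range`) or a polygon
#' given as a two-column matrix of (m/z, KMD) vertices.
#'
#' @param points Tibble with `mz` and `kmd`.
#' @param mz_range,kmd_range Numeric length-2 ranges (rectangle selection).
#' @param polygon Optional two-column matrix of vertices; overrides the
#'   rectangle.
#' @param name Cloud name stored as attribute.
#' @return Subset tibble of members (attribute `"cloud"` carries name and
#'   geometry).
#' @export
select_cloud <- function(points, mz_range = NULL, kmd_range = NULL,
                         polygon = NULL, name = "cloud") {
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3 || nrow(unique(polygon)) < 3) {
      stop("degenerate polygon geometry", call. = FALSE)
    }
    inside <- .point_in_polygon(points$mz, points$kmd, polygon)
  } else {
    if (is.null(mz_range) || is.null(kmd_range)) {
      stop("provide either a polygon or both mz_range and kmd_range",
           call. = FALSE)
    }
    if (diff(range(mz_range)) <= 0 || diff(range(kmd_range)) <= 0) {
      stop("degenerate rectangle geometry", call. = FALSE)
    }
    inside <- points$mz >= min(mz_range) & points$mz <= max(mz_range) &
      points$kmd >= min(kmd_range) & points$kmd <= max(kmd_range)
  }
  out <- points[inside, , drop = FALSE]
  attr(out, "cloud") <- list(name = name, mz_range = mz_range,
                             kmd_range = kmd_range, polygon = polygon)
  out
}

# even-odd ray casting, with on-edge points counted inside
.point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    j <- nv
    for (k in seq_len(nv)) {
      xi <- xs[k]; yi <- ys[k]; xj <- xs[j]; yj <- ys[j]
      # on-edge test
      cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
      if (abs(cross) < 1e-12 &&
          x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
          y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12) {
        return(TRUE)
      }
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) {
        inside <- !inside
      }
      j <- k
    }
    inside
  }, logical(1))
}

#' KMD scatter plot
#'
#' @param points Tibble with `mz`, `kmd` and optionally `matrix_flag` /
#'   `series_id`.
#' @param color One of `"matrix_flag"`, `"series"`, `"none"`.
#' @return A ggplot object.
#' @export
plot_kmd <- function(points, color = c("matrix_flag", "series", "none")) {
  color <- match.arg(color)
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$mz, y = .data$kmd))
  if (color == "matrix_flag" && "matrix_flag" %in% names(points)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$matrix_flag),
                                 size = 0.8)
  } else if (color == "series" && "series_id" %in% names(points)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(color = factor(.data$series_id)), size = 0.8) +
      ggplot2::guides(color = "none")
  } else {
    p <- p + ggplot2::geom_point(size = 0.8)
  }
  p + ggplot2::labs(x = "m/z", y = "Kendrick mass defect (CH2, ceiling)")
}
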