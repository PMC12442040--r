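#' Phantom organism specification
#'
#' Defines the raster grid and schematic anatomy of the synthetic
#' whole-body MSI phantom: a spider-like body with an abdominal cuticle
#' ring, paired ovary blobs (with a distinct shell and core), brain, silk
#' glands, heart, digestive tubules and a chelicerae tip, embedded in a
#' gelatin background. Regions are simple geometry — only region-conditional
#' statistics matter downstream, not anatomical realism.
#'
#' @param width,height Grid size in pixels (default 64 x 64, minimum 16).
#' @param pitch_um Pixel pitch in micrometers (default 50).
#' @param seed Integer seed carried by the object (region geometry itself is
#'   deterministic; the seed feeds the downstream signal simulation).
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(width = 64, height = 64, pitch_um = 50, seed = 1L) {
  if (width < 16 || height < 16) stop("grid must be at least 16 x 16", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pitch_um = pitch_um, seed = as.integer(seed)),
            class = "phantom_spec")
}

# ellipse membership helper on the pixel grid (x = column, y = row, 0-based)
.in_ellipse <- function(px, py, cx, cy, rx, ry) {
  ((px - cx) / rx)^2 + ((py - cy) / ry)^2 <= 1
}

#' Build the phantom region label image
#'
#' Regions are painted in a fixed priority order onto unclaimed pixels, so
#' they are disjoint by construction. Every region is guaranteed non-empty
#' (its center pixel is claimed first); an impossible geometry errors.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `"phantom"` with elements `labels` (height x
#'   width character matrix of region names, `"background"` elsewhere),
#'   `regions` (tibble of `region`, `x`, `y`, 0-based), `sub` (logical masks
#'   `ovary_shell`, `ovary_core`), and `spec`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  w <- spec$width; h <- spec$height
  px <- matrix(rep(0:(w - 1), each = h), nrow = h)  # x = column index
  py <- matrix(rep(0:(h - 1), times = w), nrow = h) # y = row index

  # geometry in grid fractions; abdomen right, cephalothorax left
  geo <- list(
    abdomen  = c(cx = 0.62, cy = 0.50, rx = 0.30, ry = 0.34),
    ovary    = c(cx = 0.62, cy = 0.62, rx = 0.13, ry = 0.12),
    heart    = c(cx = 0.62, cy = 0.22, rx = 0.15, ry = 0.05),
    digest   = c(cx = 0.52, cy = 0.40, rx = 0.10, ry = 0.10),
    silk1    = c(cx = 0.88, cy = 0.55, rx = 0.05, ry = 0.05),
    silk2    = c(cx = 0.88, cy = 0.44, rx = 0.05, ry = 0.05),
    cephalo  = c(cx = 0.24, cy = 0.50, rx = 0.15, ry = 0.20),
    brain    = c(cx = 0.24, cy = 0.44, rx = 0.08, ry = 0.09),
    chelicer = c(cx = 0.06, cy = 0.50, rx = 0.05, ry = 0.07)
  )
  ell <- function(g, scale = 1) {
    .in_ellipse(px, py, g[["cx"]] * (w - 1), g[["cy"]] * (h - 1),
                pmax(g[["rx"]] * w * scale, 0.6), pmax(g[["ry"]] * h * scale, 0.6))
  }

  abdomen <- ell(geo$abdomen)
  cuticle_band <- abdomen & !ell(geo$abdomen, scale = 0.82)
  ovary <- ell(geo$ovary)
  ovary_core <- ell(geo$ovary, scale = 0.65)
  masks <- list(
    chelicerae        = ell(geo$chelicer),
    brain             = ell(geo$brain),
    heart             = ell(geo$heart) & abdomen,
    silk_glands       = (ell(geo$silk1) | ell(geo$silk2)) & abdomen,
    ovary             = ovary & abdomen,
    digestive_tubules = ell(geo$digest) & abdomen,
    cuticle           = cuticle_band
  )

  labels <- matrix("background", nrow = h, ncol = w)
  for (nm in names(masks)) {
    claim <- masks[[nm]] & labels == "background"
    if (!any(claim)) stop("region '", nm, "' does not fit the grid", call. = FALSE)
    labels[claim] <- nm
  }

  regions <- tibble::tibble(
    region = as.vector(labels),
    x = as.vector(px),
    y = as.vector(py)
  )
  structure(
    list(labels = labels,
         regions = regions,
         sub = list(ovary_shell = (ovary & !ovary_core) & labels == "ovary",
                    ovary_core  = ovary_core & labels == "ovary"),
         spec = spec),
    class = "phantom"
  )
}

#' Logical mask for one phantom region
#' @param phantom A [build_phantom()] result.
#' @param region Region name (a label or one of the `sub` masks).
#' @return Logical height x width matrix.
#' @export
region_mask <- function(phantom, region) {
  if (region %in% names(phantom$sub)) return(phantom$sub[[region]])
  phantom$labels == region
}

#' CHCA matrix cluster ion set
#'
#' The six recurring matrix-derived background ions injected into every
#' phantom pixel: protonated, sodiated and potassiated monomer plus
#' `[2M+H]+`, `[2M+Na]+` and `[3M+H]+` clusters of alpha-cyano-4-
#' hydroxycinnamic acid. None of these differ by a CH2 multiple, so they do
#' not align horizontally in a CH2-based KMD plot — which is exactly what
#' makes them recognizable and removable.
#'
#' @param matrix_formula Neutral matrix composition (default CHCA,
#'   `"C10H7NO3"`).
#' @return Tibble with columns `species`, `adduct`, `n_matrix`, `mz`.
#' @export
matrix_ion_set <- function(matrix_formula = "C10H7NO3") {
  comp <- parse_composition(matrix_formula)
  spec <- tibble::tribble(
    ~n_matrix, ~adduct,
    1L, "[M+H]+",
    1L, "[M+Na]+",
    1L, "[M+K]+",
    2L, "[M+H]+",
    2L, "[M+Na]+",
    3L, "[M+H]+"
  )
  spec$species <- paste0(ifelse(spec$n_matrix == 1L, "",
                                paste0(spec$n_matrix, "x")), "CHCA")
  spec$mz <- vapply(seq_len(nrow(spec)), function(i) {
    ion_mz(comp * spec$n_matrix[i], spec$adduct[i])
  }, numeric(1))
  spec[, c("species", "adduct", "n_matrix", "mz")]
}

#' Default phantom species assignments
#'
#' The bundled placement of lipid species into phantom organs, mirroring the
#' organ-specific distributions the workflow is meant to recover:
#' triacylglycerol (TG) CH2/unsaturation series in the cuticle under Na/K
#' adducts, phosphatidic acids (PA) in the ovary with potassium-weighted
#' adducts on the ovary shell and sodium-weighted in the core,
#' lysophosphatidylcholines (LPC) in the ovary, PC/PE-class phospholipids in
#' brain, digestive tubules and heart, sterols in the chelicerae, and a
#' medium-chain acylcarnitine in the silk glands. Base intensities sit in
#' the 1e9 range typical of summed FT-ICR MSI table intensities.
#'
#' @return Tibble with columns `region`, `sub_region` (NA or a finer mask
#'   name), `species`, `formula` (neutral composition), `w_h`, `w_na`,
#'   `w_k` (relative adduct weights), `base_intensity`.
#' @export
default_assignments <- function() {
  tibble::tribble(
    ~region,            ~sub_region,   ~species,      ~formula,      ~w_h, ~w_na, ~w_k, ~base_intensity,
    "cuticle",           NA,           "TG 50:1",     "C53H100O6",   0,    0.7,   0.3,  3e9,
    "cuticle",           NA,           "TG 50:2",     "C53H98O6",    0,    0.7,   0.3,  4e9,
    "cuticle",           NA,           "TG 50:3",     "C53H96O6",    0,    0.7,   0.3,  5e9,
    "cuticle",           NA,           "TG 52:3",     "C55H100O6",   0,    0.7,   0.3,  5e9,
    "cuticle",           NA,           "TG 54:3",     "C57H104O6",   0,    0.7,   0.3,  2.5e9,
    "ovary",             "ovary_shell","PA 36:2",     "C39H73O8P",   0,    0.1,   0.9,  3e9,
    "ovary",             "ovary_shell","PA 36:3",     "C39H71O8P",   0,    0.1,   0.9,  2e9,
    "ovary",             "ovary_core", "PA 36:2",     "C39H73O8P",   0,    0.9,   0.1,  2e9,
    "ovary",             "ovary_core", "PA 36:3",     "C39H71O8P",   0,    0.9,   0.1,  1.5e9,
    "ovary",             NA,           "LPC O-16:0",  "C24H52NO6P",  0.2,  0.8,   0,    8e9,
    "ovary",             NA,           "LPC O-16:1",  "C24H50NO6P",  0.2,  0.8,   0,    3e9,
    "brain",             NA,           "PC 34:1",     "C42H82NO8P",  0.3,  0.4,   0.3,  4e9,
    "brain",             NA,           "PC 36:2",     "C44H84NO8P",  0.3,  0.4,   0.3,  2e9,
    "digestive_tubules", NA,           "PC 34:2",     "C42H80NO8P",  0.3,  0.4,   0.3,  3e9,
    "heart",             NA,           "PC 34:3",     "C42H78NO8P",  0.3,  0.4,   0.3,  2e9,
    "chelicerae",        NA,           "ST 26:2;O4",  "C26H42O4",    0,    1,     0,    8e8,
    "chelicerae",        NA,           "ST 28:2;O4",  "C28H46O4",    0,    1,     0,    1e9,
    "silk_glands",       NA,           "CAR 6:0",     "C13H25NO4",   1,    0,     0,    1e9
  )
}
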