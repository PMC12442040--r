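#' Monoisotopic atomic masses
#'
#' Returns the table of monoisotopic atomic masses (in Da) used throughout the
#' package, together with the electron and proton particle masses. The set
#' covers CHNOP plus the MALDI cations Na and K and the heavy carbon isotope
#' `13C`; that is all positive-mode lipid MSI needs here.
#'
#' @return A named numeric vector of masses in Da. Particle masses are stored
#'   under `"e-"` (electron) and `"p+"` (proton).
#' @examples
#' atomic_masses()[["C"]]
#' @export
atomic_masses <- function() {
  c(
    "C"   = 12.000000,
    "H"   = 1.00782503,
    "N"   = 14.00307401,
    "O"   = 15.99491462,
    "Na"  = 22.98976928,
    "P"   = 30.97376163,
    "K"   = 38.96370649,
    "13C" = 13.00335484,
    "e-"  = 0.00054858,
    "p+"  = 1.00727646
  )
}

#' Parse an elemental composition string
#'
#' Accepts both compact formulas (`"C53H96O6"`) and the space-separated table
#' notation (`"C53 H96 O6 Na"`, `"12C38 13C H73 O8 P K"`). A leading mass
#' number marks an explicit isotope (`12C` is folded into ordinary `C`; `13C`
#' is kept as its own symbol).
#'
#' @param x A single composition string, or an already-parsed named integer
#'   vector (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @examples
#' parse_composition("C53 H96 O6")
#' parse_composition("12C38 13C H73 O8 P K")
#' @export
parse_composition <- function(x) {
  if (is.numeric(x)) {
    counts <- x
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("numeric compositions must be named by element symbol", call. = FALSE)
    }
  } else {
    stopifnot(is.character(x), length(x) == 1)
    s <- trimws(x)
    if (!nzchar(s)) {
      counts <- integer(0)
    } else if (grepl("\\s", s)) {
      # space-separated table notation; the only form where isotope-prefixed
      # tokens ("12C38", "13C") are unambiguous
      toks <- strsplit(s, "\\s+")[[1]]
      m <- regmatches(toks, regexec("^(1[23])?([A-Z][a-z]?)([0-9]*)$", toks))
      if (any(lengths(m) == 0)) {
        stop("cannot parse composition string: ", x, call. = FALSE)
      }
      sym <- vapply(m, function(p) paste0(p[2], p[3]), character(1))
      cnt <- vapply(m, function(p) if (p[4] == "") 1L else as.integer(p[4]),
                    integer(1))
      sym[sym == "12C"] <- "C"
      counts <- tapply(cnt, sym, sum)
      counts <- stats::setNames(as.integer(counts), names(counts))
    } else {
      g <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
      toks <- regmatches(s, list(g))[[1]]
      if (sum(attr(g, "match.length")) != nchar(s)) {
        stop("cannot parse composition string: ", x, call. = FALSE)
      }
      sym <- sub("[0-9]*$", "", toks)
      cnt <- sub("^[A-Za-z]+", "", toks)
      cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
      counts <- tapply(as.integer(cnt), sym, sum)
      counts <- stats::setNames(as.integer(counts), names(counts))
    }
  }
  if (any(counts < 0)) stop("element counts must be non-negative", call. = FALSE)
  known <- names(atomic_masses())
  bad <- setdiff(names(counts), known)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts[counts > 0]
}

#' Format a composition as a compact string
#' @param comp Composition (string or named counts).
#' @return Single string such as `"C53H96O6"`.
#' @export
format_composition <- function(comp) {
  comp <- parse_composition(comp)
  ord <- c("C", "13C", "H", "N", "O", "Na", "P", "K")
  comp <- comp[order(match(names(comp), ord))]
  sep <- if ("13C" %in% names(comp)) " " else ""
  paste0(names(comp), ifelse(comp == 1, "", comp), collapse = sep)
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp Composition string or named integer vector (see
#'   [parse_composition()]).
#' @return Mass in Da. The empty composition has mass 0.
#' @examples
#' monoisotopic_mass("CH2") # 14.01565
#' @export
monoisotopic_mass <- function(comp) {
  comp <- parse_composition(comp)
  if (!length(comp)) return(0)
  masses <- atomic_masses()
  sum(masses[names(comp)] * comp)
}

supported_adducts <- c("[M+H]+", "[M+Na]+", "[M+K]+")

adduct_cation <- c("[M+H]+" = "H", "[M+Na]+" = "Na", "[M+K]+" = "K")

normalize_adduct <- function(adduct) {
  a <- gsub("\\s+", "", adduct)
  a <- sub("\\^\\+\\^?$", "+", a)
  bad <- setdiff(unique(a), supported_adducts)
  if (length(bad)) {
    stop("unsupported adduct(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(supported_adducts, collapse = ", "),
         call. = FALSE)
  }
  a
}

#' Theoretical m/z of a singly charged adduct ion
#'
#' Computes the ion m/z for the positive-mode adducts seen in MALDI lipid
#' imaging. Protonation adds one proton mass; metal cationization adds the
#' neutral atom mass and removes one electron. All ions are singly charged,
#' so m/z equals the ion mass.
#'
#' @param comp Neutral composition (string or named counts), or a character
#'   vector of compositions (recycled against `adduct`).
#' @param adduct One of `"[M+H]+"`, `"[M+Na]+"`, `"[M+K]+"` (vectorized).
#' @return Numeric m/z vector.
#' @examples
#' ion_mz("C53H96O6", "[M+Na]+") # TG 50:3, 851.7099
#' @export
ion_mz <- function(comp, adduct) {
  adduct <- normalize_adduct(adduct)
  if (is.character(comp) && length(comp) > 1) {
    n <- max(length(comp), length(adduct))
    comp <- rep_len(comp, n)
    adduct <- rep_len(adduct, n)
    return(vapply(seq_len(n), function(i) ion_mz(comp[i], adduct[i]), numeric(1)))
  }
  m <- monoisotopic_mass(comp)
  if (m <= 0) stop("neutral composition must have positive mass", call. = FALSE)
  masses <- atomic_masses()
  vapply(adduct, function(a) {
    if (a == "[M+H]+") {
      m + masses[["p+"]]
    } else {
      m + masses[[adduct_cation[[a]]]] - masses[["e-"]]
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z (vectorized).
#' @param theoretical Theoretical m/z (> 0, vectorized).
#' @return Signed ppm error `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0, na.rm = TRUE)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  (observed - theoretical) / theoretical * 1e6
}

#' Kendrick transform parameters
#'
#' Defaults follow the CH2 base unit standard for lipids: Kendrick mass
#' `KM = mz * 14.00000 / 14.01565`, with the mass defect taken as
#' `round(KM) - KM` under a configurable rounding convention. Rounding "up"
#' (ceiling) is the default because it places lipid KMD values near the
#' middle of the 0 to 1 band.
#'
#' @param base Base-unit composition string (default `"CH2"`).
#' @param nominal_mass Integer-valued nominal mass of the base (default 14).
#' @param exact_mass Exact mass of the base; defaults to the monoisotopic
#'   mass of `base` rounded to 5 decimals (14.01565 for CH2).
#' @param rounding One of `"up"`, `"down"`, `"nearest"`.
#' @return A list of class `"kendrick_params"`.
#' @export
kendrick_params <- function(base = "CH2", nominal_mass = 14.00000,
                            exact_mass = NULL,
                            rounding = c("up", "down", "nearest")) {
  rounding <- match.arg(rounding)
  if (is.null(exact_mass)) exact_mass <- round(monoisotopic_mass(base), 5)
  stopifnot(exact_mass > 0, nominal_mass == round(nominal_mass))
  structure(
    list(base = base, nominal_mass = nominal_mass, exact_mass = exact_mass,
         rounding = rounding),
    class = "kendrick_params"
  )
}

#' Kendrick mass
#' @param mz Observed m/z (vectorized, > 0).
#' @param params A [kendrick_params()] object.
#' @return Kendrick mass `mz * nominal / exact`.
#' @export
kendrick_mass <- function(mz, params = kendrick_params()) {
  if (any(mz <= 0)) stop("m/z must be positive", call. = FALSE)
  mz * params$nominal_mass / params$exact_mass
}

#' Kendrick mass defect
#'
#' `round(KM) - KM` under the chosen rounding convention: `"down"` (floor,
#' KMD in (-1, 0]), `"up"` (ceiling, KMD in [0, 1)), or `"nearest"` (KMD in
#' [-0.5, 0.5]).
#'
#' @param km Kendrick mass (vectorized).
#' @param rounding Rounding convention.
#' @return KMD values.
#' @export
kendrick_mass_defect <- function(km, rounding = c("up", "down", "nearest")) {
  rounding <- match.arg(rounding)
  # snap floating-point near-integers so that exact CH2 multiples give 0
  near <- abs(km - round(km)) < 1e-9
  km[near] <- round(km[near])
  switch(rounding,
    up      = ceiling(km) - km,
    down    = floor(km) - km,
    nearest = round(km) - km
  )
}

#' Kendrick transform of a set of m/z values
#'
#' Convenience wrapper returning a tibble of m/z, KM and KMD.
#'
#' @param mz Numeric m/z vector.
#' @param params A [kendrick_params()] object (its `rounding` is used).
#' @return Tibble with columns `mz`, `km`, `kmd`.
#' @export
kendrick_transform <- function(mz, params = kendrick_params()) {
  km <- kendrick_mass(mz, params)
  tibble::tibble(mz = mz, km = km,
                 kmd = kendrick_mass_defect(km, params$rounding))
}

#' Carbon isotopologue pattern (binomial approximation)
#'
#' Approximates the isotope pattern of a composition by the carbon-13
#' binomial model: isotopologue k sits `k * (13.00335484 - 12)` Da above the
#' monoisotopic peak with relative abundance `dbinom(k, nC, p)` normalized to
#' the monoisotopic peak. Adequate for CHNOP(+Na/K) lipids where carbon
#' dominates the A+1 envelope.
#'
#' @param comp Composition containing carbon.
#' @param n Number of isotopologues to return (>= 1), counting the
#'   monoisotopic peak.
#' @param p Natural 13C abundance (default 0.0107).
#' @return Tibble with columns `k`, `mz_offset`, `abundance` (monoisotopic
#'   abundance = 1).
#' @export
isotope_pattern <- function(comp, n = 3, p = 0.0107) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  comp <- parse_composition(comp)
  n_c <- sum(comp[names(comp) %in% c("C", "13C")])
  if (n_c < 1) stop("composition must contain carbon", call. = FALSE)
  k <- seq_len(n) - 1L
  ab <- stats::dbinom(k, n_c, p)
  masses <- atomic_masses()
  tibble::tibble(
    k = k,
    mz_offset = k * (masses[["13C"]] - masses[["C"]]),
    abundance = ab / ab[1]
  )
}

#' Mass shifts used for adduct and isotopologue collapsing
#'
#' @return Named vector: `"Na-H"`, `"K-H"`, `"K-Na"` cation-exchange shifts
#'   and the `"13C"` isotopologue spacing, all in Da, derived from
#'   [atomic_masses()].
#' @export
adduct_mass_shifts <- function() {
  m <- atomic_masses()
  c("Na-H" = m[["Na"]] - m[["H"]],
    "K-H"  = m[["K"]] - m[["H"]],
    "K-Na" = m[["K"]] - m[["Na"]],
    "13C"  = m[["13C"]] - m[["C"]])
}
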