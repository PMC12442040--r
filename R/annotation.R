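#' Parse a lipid shorthand name
#'
#' Understands the class + carbons:double-bonds shorthand with an optional
#' ether prefix and extra-oxygen suffix, e.g. `"TG 50:3"`, `"LPC O-16:0"`,
#' `"SM 36:2;O2"`, `"ST 28:2;O4"`, and the parenthesized table variant
#' `"PC (34:1)"`.
#'
#' @param name Single shorthand string.
#' @return List with `class`, `ether` (logical), `carbons`, `double_bonds`,
#'   `extra_ox` (0 when absent).
#' @export
parse_lipid_name <- function(name) {
  m <- regmatches(name,
    regexec("^\\s*([A-Za-z]+)\\s*\\(?\\s*(O-)?(\\d+):(\\d+)\\s*\\)?\\s*(?:;\\s*O(\\d+))?\\s*$",
            name))[[1]]
  if (!length(m)) stop("cannot parse lipid shorthand: ", name, call. = FALSE)
  list(class = m[2], ether = m[3] == "O-",
       carbons = as.integer(m[4]), double_bonds = as.integer(m[5]),
       extra_ox = ifelse(m[6] == "", 0L, as.integer(m[6])))
}

#' Shift a lipid shorthand by k CH2 units
#'
#' Adds `k` carbons to the shorthand (e.g. `"TG 50:3"` with `k = 2` becomes
#' `"TG 52:3"`); double bonds and oxygens are unchanged. Joined isomer names
#' (`"PC 34:1 or PE 37:1"`) are shifted component-wise.
#'
#' @param name Shorthand string.
#' @param k Integer CH2 steps (may be negative).
#' @return Shifted shorthand string.
#' @export
shift_lipid_name <- function(name, k) {
  parts <- strsplit(name, "\\s+or\\s+")[[1]]
  shifted <- vapply(parts, function(p) {
    info <- parse_lipid_name(p)
    paste0(info$class, " ", if (info$ether) "O-" else "",
           info$carbons + k, ":", info$double_bonds,
           if (info$extra_ox > 0) paste0(";O", info$extra_ox) else "")
  }, character(1))
  paste(shifted, collapse = " or ")
}

#' Load the bundled lipid reference table
#'
#' An offline reference of neutral lipid and metabolite species with
#' LIPID MAPS shorthand names and elemental compositions, replacing live
#' database queries for reproducibility. Isobaric PC/PE isomer pairs that
#' positive-mode MSI cannot distinguish are stored as one joined record
#' (`"PC 34:1 or PE 37:1"`).
#'
#' @param path CSV path; defaults to the table shipped with the package.
#'   Schema: `name`, `class`, `formula`, `double_bonds`, `oxygens`, `notes`.
#' @return Tibble of validated records.
#' @export
load_lipid_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lipid_reference.csv",
                        package = "kendrickmsi", mustWork = TRUE)
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           name = readr::col_character(),
                           class = readr::col_character(),
                           formula = readr::col_character(),
                           double_bonds = readr::col_integer(),
                           oxygens = readr::col_integer(),
                           notes = readr::col_character()
                         ))
  required <- c("name", "class", "formula", "double_bonds", "oxygens")
  if (!all(required %in% names(tbl))) {
    stop("lipid table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tbl$name)) {
    dup <- tbl$name[duplicated(tbl$name)][1]
    stop("duplicate lipid name at line ",
         which(tbl$name == dup)[2] + 1L, ": ", dup, call. = FALSE)
  }
  for (i in seq_len(nrow(tbl))) {
    comp <- tryCatch(parse_composition(tbl$formula[i]), error = function(e) {
      stop("invalid composition at line ", i + 1L, ": ",
           conditionMessage(e), call. = FALSE)
    })
    n_ox <- if ("O" %in% names(comp)) comp[["O"]] else 0L
    if (n_ox != tbl$oxygens[i]) {
      stop("oxygen count mismatch at line ", i + 1L, " (", tbl$name[i], ")",
           call. = FALSE)
    }
  }
  tbl$neutral_mass <- vapply(tbl$formula, monoisotopic_mass, numeric(1),
                             USE.NAMES = FALSE)
  tbl
}

#' Candidate ranking policy for exact-mass annotation
#'
#' Encodes the three positive-mode annotation criteria: lowest absolute
#' mass error first; on near-ties, classes that ionize well in positive
#' mode are prioritized; highly oxidized or polyunsaturated compositions
#' are excluded outright.
#'
#' @param max_ppm Matches up to this |ppm| are full-confidence (default 5).
#' @param low_conf_ppm Matches in `(max_ppm, low_conf_ppm]` are kept but
#'   flagged `"low-confidence"` (default 6; set equal to `max_ppm` to make
#'   the cut hard).
#' @param tie_ppm Near-tie window for invoking class priority (default 0.3).
#' @param class_priority Character vector, most ionizable first.
#' @param max_double_bonds,max_oxygens Oxidation caps beyond which
#'   candidates are excluded.
#' @return List of class `"ranking_policy"`.
#' @export
ranking_policy <- function(max_ppm = 5, low_conf_ppm = 6, tie_ppm = 0.3,
                           class_priority = c("PC", "SM", "LPC", "DG", "TG",
                                              "MG", "PE", "LPE", "PA", "ST",
                                              "CAR"),
                           max_double_bonds = 10, max_oxygens = 10) {
  stopifnot(max_ppm > 0, low_conf_ppm >= max_ppm)
  structure(list(max_ppm = max_ppm, low_conf_ppm = low_conf_ppm,
                 tie_ppm = tie_ppm, class_priority = class_priority,
                 max_double_bonds = max_double_bonds,
                 max_oxygens = max_oxygens),
            class = "ranking_policy")
}

.class_rank <- function(class, priority) {
  # joined classes ("PC/PE") rank by their best component
  vapply(strsplit(class, "/"), function(parts) {
    r <- match(parts, priority)
    if (all(is.na(r))) length(priority) + 1L else min(r, na.rm = TRUE)
  }, integer(1))
}

#' Rank annotation candidates under a policy
#'
#' Oxidation-cap violators are removed; remaining candidates are ordered by
#' ascending |ppm|, with clusters of candidates within the near-tie window
#' reordered by class priority, ties broken deterministically by name.
#'
#' @param candidates Tibble with columns `name`, `class`, `double_bonds`,
#'   `oxygens`, `ppm` (signed).
#' @param policy A [ranking_policy()].
#' @return Ordered tibble with added `rank` and `rationale` columns.
#' @export
rank_candidates <- function(candidates, policy = ranking_policy()) {
  keep <- candidates$double_bonds <= policy$max_double_bonds &
    candidates$oxygens <= policy$max_oxygens
  out <- candidates[keep, , drop = FALSE]
  if (!nrow(out)) {
    out$rank <- integer(0); out$rationale <- character(0)
    return(out)
  }
  out <- out[order(abs(out$ppm), out$name), , drop = FALSE]
  # near-tie clusters along sorted |ppm|
  apm <- abs(out$ppm)
  cluster <- cumsum(c(TRUE, diff(apm) > policy$tie_ppm))
  prio <- .class_rank(out$class, policy$class_priority)
  out <- out[order(cluster, prio, apm, out$name), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$rationale <- ifelse(abs(out$ppm) > policy$max_ppm,
                          "low-confidence",
                          ifelse(out$rank == 1L, "best-match", "mass-error"))
  out
}

#' Annotate observed m/z values against the lipid reference table
#'
#' Generates all (record, adduct) candidates whose theoretical ion m/z lies
#' within the policy's ppm window of the query and ranks them.
#'
#' @param mz Numeric vector of query m/z values.
#' @param table Lipid reference tibble ([load_lipid_table()]).
#' @param adducts Adducts to consider (default H, Na, K).
#' @param policy A [ranking_policy()].
#' @return Tibble with one row per candidate: `query_mz`, `name`, `class`,
#'   `formula`, `adduct`, `mz_theoretical`, `ppm`, `rank`, `rationale`.
#'   Queries with no candidates contribute no rows.
#' @export
annotate_mz <- function(mz, table = load_lipid_table(),
                        adducts = c("[M+H]+", "[M+Na]+", "[M+K]+"),
                        policy = ranking_policy()) {
  stopifnot(nrow(table) > 0)
  masses <- atomic_masses()
  ion_grid <- tidyr::expand_grid(idx = seq_len(nrow(table)), adduct = adducts)
  add_mass <- c("[M+H]+" = masses[["p+"]],
                "[M+Na]+" = masses[["Na"]] - masses[["e-"]],
                "[M+K]+" = masses[["K"]] - masses[["e-"]])
  ion_grid$mz_theoretical <- table$neutral_mass[ion_grid$idx] +
    unname(add_mass[ion_grid$adduct])

  purrr::map_dfr(mz, function(q) {
    ppm <- ppm_error(q, ion_grid$mz_theoretical)
    hit <- abs(ppm) <= policy$low_conf_ppm
    if (!any(hit)) return(NULL)
    cand <- tibble::tibble(
      query_mz = q,
      name = table$name[ion_grid$idx[hit]],
      class = table$class[ion_grid$idx[hit]],
      formula = table$formula[ion_grid$idx[hit]],
      double_bonds = table$double_bonds[ion_grid$idx[hit]],
      oxygens = table$oxygens[ion_grid$idx[hit]],
      adduct = ion_grid$adduct[hit],
      mz_theoretical = ion_grid$mz_theoretical[hit],
      ppm = ppm[hit]
    )
    rank_candidates(cand, policy)
  })
}

#' Propagate an anchor annotation along a CH2 homologous series
#'
#' Once one member of a horizontal series is identified, every other member
#' at an integer number of CH2 steps from the anchor inherits the anchor's
#' class with the carbon count adjusted; such annotations are flagged
#' `"propagated"` rather than `"matched"`. Members at a non-integer CH2
#' offset are left unannotated with a warning.
#'
#' @param series_points Tibble of the series members with an `mz` column
#'   (must contain the anchor).
#' @param anchor_mz The anchor member's m/z.
#' @param anchor_name Anchor shorthand name (e.g. `"TG 50:3"`).
#' @param anchor_formula Anchor neutral composition string.
#' @param tol_ppm Tolerance for the integer-CH2-offset check (default 2).
#' @return `series_points` with added `annotation`, `formula`, `status`
#'   columns.
#' @export
propagate_series_annotation <- function(series_points, anchor_mz, anchor_name,
                                        anchor_formula = NULL, tol_ppm = 2) {
  ch2 <- round(monoisotopic_mass("CH2"), 5)
  i_anchor <- which(abs(ppm_error(series_points$mz, anchor_mz)) <= tol_ppm)
  if (!length(i_anchor)) {
    stop("anchor m/z is not a member of the series", call. = FALSE)
  }
  delta <- series_points$mz - anchor_mz
  k <- round(delta / ch2)
  resid_ppm <- abs((delta - k * ch2) / series_points$mz * 1e6)
  ok <- resid_ppm <= tol_ppm
  if (any(!ok)) {
    warning(sum(!ok), " member(s) at non-integer CH2 offset left unannotated",
            call. = FALSE)
  }
  ann <- rep(NA_character_, nrow(series_points))
  frm <- rep(NA_character_, nrow(series_points))
  ann[ok] <- vapply(k[ok], function(kk) shift_lipid_name(anchor_name, kk),
                    character(1))
  if (!is.null(anchor_formula)) {
    comp0 <- parse_composition(anchor_formula)
    frm[ok] <- vapply(k[ok], function(kk) {
      comp <- comp0
      comp["C"] <- comp["C"] + kk
      comp["H"] <- comp["H"] + 2L * kk
      format_composition(comp)
    }, character(1))
  }
  series_points$annotation <- ann
  series_points$formula <- frm
  series_points$status <- ifelse(!ok, NA_character_,
                                 ifelse(k == 0L, "matched", "propagated"))
  series_points
}

#' Validate a candidate composition against an observed isotope pattern
#'
#' Cosine similarity between the theoretical carbon-13 isotopologue pattern
#' (first `n` isotopologues, binomial model) and the observed relative
#' intensities matched within `tol_ppm` per isotopologue; a missing
#' observed isotopologue contributes 0.
#'
#' @param comp Candidate neutral composition (carbon-containing).
#' @param mono_mz Observed monoisotopic ion m/z anchoring the pattern.
#' @param observed Tibble with `mz`, `intensity` of peaks near the query.
#' @param tol_ppm Per-isotopologue match tolerance (default 2).
#' @param n Isotopologues compared (default 3).
#' @return Agreement score in \[0, 1\].
#' @export
validate_isotope_pattern <- function(comp, mono_mz, observed, tol_ppm = 2,
                                     n = 3) {
  theo <- isotope_pattern(comp, n = n)
  obs <- vapply(theo$mz_offset, function(off) {
    d <- abs(ppm_error(observed$mz, mono_mz + off))
    i <- which.min(d)
    if (length(i) && d[i] <= tol_ppm) observed$intensity[i] else 0
  }, numeric(1))
  if (all(obs == 0)) return(0)
  sum(theo$abundance * obs) /
    (sqrt(sum(theo$abundance^2)) * sqrt(sum(obs^2)))
}
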