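test_that("lipid shorthand parses and shifts by CH2 units", {
  info <- parse_lipid_name("TG 50:3")
  expect_equal(info$class, "TG")
  expect_equal(info$carbons, 50L)
  expect_equal(info$double_bonds, 3L)
  expect_false(info$ether)
  lpc <- parse_lipid_name("LPC O-16:0")
  expect_true(lpc$ether)
  st <- parse_lipid_name("ST 28:2;O4")
  expect_equal(st$extra_ox, 4L)
  expect_equal(parse_lipid_name("PC (34:1)")$carbons, 34L)
  expect_error(parse_lipid_name("notalipid"), "parse")

  expect_equal(shift_lipid_name("TG 50:3", 2), "TG 52:3")
  expect_equal(shift_lipid_name("LPC O-16:0", -1), "LPC O-15:0")
  expect_equal(shift_lipid_name("PC 34:1 or PE 37:1", 2),
               "PC 36:1 or PE 39:1")
})

test_that("the bundled lipid table loads and validates", {
  tbl <- load_lipid_table()
  expect_true(all(c("TG 50:3", "LPC O-16:0", "SM 36:2;O2", "CAR 6:0",
                    "cyclo(Leu-Phe)") %in% tbl$name))
  expect_equal(tbl$formula[tbl$name == "TG 50:3"], "C53H96O6")
  expect_false(anyDuplicated(tbl$name) > 0)
  # duplicate names are rejected
  tmp <- withr::local_tempfile(fileext = ".csv")
  dup <- tbl[c(1, 1, 2), c("name", "class", "formula", "double_bonds",
                           "oxygens", "notes")]
  readr::write_csv(dup, tmp)
  expect_error(load_lipid_table(tmp), "duplicate")
  # composition mismatch against declared oxygens is rejected
  bad <- tbl[1:2, c("name", "class", "formula", "double_bonds", "oxygens",
                    "notes")]
  bad$oxygens[1] <- bad$oxygens[1] + 1L
  readr::write_csv(bad, tmp)
  expect_error(load_lipid_table(tmp), "mismatch")
})

test_that("candidate ranking follows mass error, class priority and caps", {
  pol <- ranking_policy()
  cand <- tibble::tibble(
    name = c("far", "near", "oxid"),
    class = c("PA", "PC", "PC"),
    double_bonds = c(2L, 1L, 12L),
    oxygens = c(8L, 8L, 8L),
    ppm = c(3.0, 0.5, 0.1)
  )
  ranked <- rank_candidates(cand, pol)
  # the oxidation-cap violator is gone; lowest |ppm| wins
  expect_false("oxid" %in% ranked$name)
  expect_equal(ranked$name[1], "near")
  # near-tie: class priority decides
  tie <- tibble::tibble(
    name = c("pa", "pc"), class = c("PA", "PC"),
    double_bonds = 1L, oxygens = 8L, ppm = c(0.4, 0.6)
  )
  expect_equal(rank_candidates(tie, pol)$name[1], "pc")
  # outside the tie window, |ppm| wins despite priority
  apart <- tie; apart$ppm <- c(0.4, 1.0)
  expect_equal(rank_candidates(apart, pol)$name[1], "pa")
  # single candidate passes through
  one <- cand[2, ]
  expect_equal(rank_candidates(one, pol)$name, "near")
})

test_that("published experimental m/z re-annotate to the printed best match", {
  path <- system.file("extdata", "published_ion_assignments.csv",
                      package = "kendrickmsi")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata",
                                       "published_ion_assignments.csv")
  rows <- readr::read_csv(path, show_col_types = FALSE)
  rows <- rows[!is.na(rows$neutral_formula) &
                 (is.na(rows$note) | !nzchar(rows$note)) &
                 !grepl("isotope", rows$best_match), ]
  tbl <- load_lipid_table()
  for (i in seq_len(nrow(rows))) {
    res <- annotate_mz(rows$mz_exp[i], tbl)
    expect_gt(nrow(res), 0)
    top <- res[res$rank == 1, ]
    expect_equal(top$name[1], rows$best_match[i],
                 label = paste("query", rows$mz_exp[i]))
    expect_equal(top$adduct[1], rows$ion[i])
    # recomputed |ppm| within 0.2 of the printed value
    expect_lt(abs(abs(top$ppm[1]) - rows$delta_ppm_printed[i]), 0.2 + 1e-9)
  }
})

test_that("annotation handles metabolites, misses and unidentified ions", {
  tbl <- load_lipid_table()
  # hexanoylcarnitine by exact mass
  res <- annotate_mz(260.1854, tbl)
  expect_equal(res$name[res$rank == 1], "CAR 6:0")
  expect_equal(res$adduct[res$rank == 1], "[M+H]+")
  # far-off query returns nothing
  expect_equal(nrow(annotate_mz(9999.0, tbl)), 0)
  # the unidentified ions from the published list (> 10 ppm off everything)
  # stay unannotated or at best low-confidence
  for (q in c(666.4834, 682.4575, 692.4991)) {
    res <- annotate_mz(q, tbl)
    expect_true(nrow(res) == 0 || all(res$rationale == "low-confidence"))
  }
  # the 5.5 ppm MG match is kept but flagged low-confidence
  res55 <- annotate_mz(549.4883, tbl)
  expect_equal(res55$name[res55$rank == 1], "MG 30:0 or DG O-30:0")
  expect_equal(res55$rationale[res55$rank == 1], "low-confidence")
})

test_that("series annotation propagates by CH2 steps and is involutive", {
  series <- tibble::tibble(mz = c(851.7099, 879.7412, 907.7725),
                           intensity = 1)
  out <- propagate_series_annotation(series, 851.7099, "TG 50:3", "C53H96O6")
  expect_equal(out$annotation, c("TG 50:3", "TG 52:3", "TG 54:3"))
  expect_equal(out$status, c("matched", "propagated", "propagated"))
  expect_equal(out$formula[2], "C55H100O6")
  # involution: propagating back from the middle member recovers the anchor
  back <- propagate_series_annotation(series, 879.7412, "TG 52:3", "C55H100O6")
  expect_equal(back$annotation[1], "TG 50:3")
  expect_equal(back$formula[1], "C53H96O6")
  # series of one: only the anchor
  one <- propagate_series_annotation(series[1, ], 851.7099, "TG 50:3")
  expect_equal(one$status, "matched")
  # corrupted member at a non-integer offset is left unannotated
  bad <- tibble::tibble(mz = c(851.7099, 860.0), intensity = 1)
  expect_warning(outb <- propagate_series_annotation(bad, 851.7099, "TG 50:3"),
                 "non-integer")
  expect_true(is.na(outb$annotation[2]))
  expect_error(propagate_series_annotation(series, 555.5, "TG 50:3"),
               "anchor")
})

test_that("isotope-pattern validation scores simulated spectra correctly", {
  comp <- "C39H73O8P" # PA 36:2
  mono <- ion_mz(comp, "[M+K]+")
  theo <- isotope_pattern(comp, n = 3)
  # perfect pattern scores 1
  obs <- tibble::tibble(mz = mono + theo$mz_offset, intensity = theo$abundance)
  expect_equal(validate_isotope_pattern(comp, mono, obs), 1, tolerance = 1e-12)
  # mono-only observation: cosine against the truncated vector, direct formula
  obs1 <- obs[1, ]
  expected <- theo$abundance[1] / sqrt(sum(theo$abundance^2))
  expect_equal(validate_isotope_pattern(comp, mono, obs1), expected,
               tolerance = 1e-12)
  # a simulated pixel spectrum of the same composition scores > 0.95
  instr <- instrument_model(sigma_ppm = 0.5, noise_cv = 0.05)
  set.seed(99)
  ions <- tibble::tibble(species = "PA 36:2", adduct = "[M+K]+",
                         k = theo$k, mz = mono + theo$mz_offset,
                         height = 1e9 * theo$abundance)
  sp <- simulate_pixel_spectrum(ions, instr, NULL)
  pk <- find_spectrum_peaks(sp$mz, sp$intensity, picking_params())
  expect_gt(validate_isotope_pattern(comp, mono, pk, tol_ppm = 3), 0.95)
})
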