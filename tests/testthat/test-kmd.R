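published_mz <- function() {
  path <- system.file("extdata", "published_ion_assignments.csv",
                      package = "kendrickmsi")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata",
                                       "published_ion_assignments.csv")
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  tbl$mz_exp
}

test_that("Kendrick points carry the window-passing KMD of published ions", {
  bins <- tibble::tibble(bin = 1:2, mz = c(14.01565, 851.7103),
                         total_intensity = c(1, 2))
  pts <- kendrick_points(bins)
  expect_equal(nrow(pts), 2)
  expect_equal(pts$kmd[1], 0, tolerance = 1e-9)
  # all published experimental m/z sit inside the ceiling-mode lipid window
  kt <- kendrick_transform(published_mz())
  expect_true(all(kt$kmd >= 0.10 & kt$kmd <= 0.50))
})

test_that("window filtering is boundary-inclusive and idempotent", {
  pts <- tibble::tibble(mz = c(150, 400, 400, 200, 1400, 700),
                        kmd = c(0.3, 0.05, 0.10, 0.50, 0.30, 0.55))
  f1 <- filter_kmd_window(pts)
  expect_equal(nrow(f1), 3) # the m/z 150 and kmd 0.05 / 0.55 points drop
  expect_true(all(f1$mz >= 200 & f1$kmd >= 0.10 & f1$kmd <= 0.50))
  expect_equal(filter_kmd_window(f1), f1)
})

test_that("CH2 chaining matches the published TG series and the ppm rule", {
  # TG 50:3 / 52:3 / 54:3 sodiated homologs chain into one series
  pts <- tibble::tibble(mz = c(851.7099, 879.7412, 907.7725, 500.0),
                        intensity = 1)
  out <- chain_ch2_series(pts)
  expect_equal(length(unique(out$series_id[1:3])), 1)
  expect_false(is.na(out$series_id[1]))
  expect_true(is.na(out$series_id[4]))
  # a 14.0300 Da gap is ~1000 ppm off a CH2 step: not chained
  pair <- tibble::tibble(mz = c(700, 714.03), intensity = 1)
  expect_true(all(is.na(chain_ch2_series(pair)$series_id)))
  # multi-step links (k = 2) connect across a missing member
  gap2 <- tibble::tibble(mz = c(700, 700 + 2 * 14.01565), intensity = 1)
  expect_equal(length(unique(chain_ch2_series(gap2)$series_id)), 1)
})

test_that("chaining equals the brute-force all-pairs oracle on random sets", {
  set.seed(31)
  ch2 <- 14.01565
  for (rep in 1:5) {
    # seed masses plus planted homologs and decoys
    base <- runif(6, 300, 900)
    mz <- c(base,
            base[1] + ch2 * (1:3),
            base[2] + ch2 * 2,
            base[3] + ch2 * 1.5,       # half-step decoy
            runif(8, 300, 1000))
    mz <- sort(mz * (1 + runif(length(mz), -5e-7, 5e-7)))
    pts <- tibble::tibble(mz = mz, intensity = 1)
    got <- chain_ch2_series(pts, tol_ppm = 2, k_max = 10)$series_id
    want <- oracle_chain_components(mz, ch2, tol_ppm = 2, k_max = 10)
    expect_identical(partition_of(got), partition_of(want))
  }
})

test_that("vertical H2/O chaining groups unsaturation and oxidation series", {
  h2 <- 2.01565
  tg <- tibble::tibble(mz = 855.7412 - h2 * (0:2), intensity = 1) # TG 50:1..3
  out <- chain_vertical(tg, "H2")
  expect_equal(length(unique(out$vertical_id)), 1)
  # 2.0300 Da apart is not an H2 step
  off <- tibble::tibble(mz = c(700, 702.03), intensity = 1)
  expect_true(all(is.na(chain_vertical(off, "H2")$vertical_id)))
  # O steps
  ox <- tibble::tibble(mz = c(600, 600 + 15.99491), intensity = 1)
  expect_equal(length(unique(chain_vertical(ox, "O")$vertical_id)), 1)
  expect_error(chain_vertical(ox, "CO2"))
  # empty input
  none <- tibble::tibble(mz = numeric(0), intensity = numeric(0))
  expect_equal(nrow(chain_vertical(none, "H2")), 0)
})

test_that("KMD-class grouping clusters series sharing a mass defect", {
  kt <- kendrick_transform(c(851.7099, 879.7412, 907.7725, 760.5851))
  kt$intensity <- 1
  out <- group_kmd_classes(kt, tol = 0.0025)
  expect_equal(length(unique(out$kmd_class[1:3])), 1)
  expect_false(out$kmd_class[4] == out$kmd_class[1])
})

test_that("adduct/isotope collapse merges published adduct triplets", {
  # PC 34:1 as H / Na / K from the published tables
  pts <- tibble::tibble(mz = c(760.5851, 782.5670, 798.5410), intensity = c(3, 2, 1))
  out <- collapse_adducts(pts)
  expect_equal(length(unique(out$group_id)), 1)
  expect_equal(unique(out$canonical_mz), 760.5851, tolerance = 1e-4)
  cp <- canonical_points(out)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$intensity, 6)

  # monoisotopic + first isotope pair
  iso <- tibble::tibble(mz = c(739.4675, 740.4709), intensity = c(10, 4))
  out2 <- collapse_adducts(iso)
  expect_equal(length(unique(out2$group_id)), 1)

  # a lone protonated ion maps to itself
  solo <- tibble::tibble(mz = 760.5851, intensity = 1)
  out3 <- collapse_adducts(solo)
  expect_equal(out3$canonical_mz, 760.5851)

  # Na and K adducts merge even when the protonated form is absent,
  # imputing the canonical protonated m/z by shift subtraction
  nak <- tibble::tibble(mz = c(723.4935, 739.4675), intensity = c(1, 1))
  out4 <- collapse_adducts(nak)
  expect_equal(length(unique(out4$group_id)), 1)
  expect_equal(unique(out4$canonical_mz), 701.5116, tolerance = 2e-4)
})

test_that("collapse conserves total intensity", {
  set.seed(7)
  shifts <- adduct_mass_shifts()
  base <- runif(10, 400, 900)
  mz <- c(base, base[1:5] + shifts[["Na-H"]], base[1:3] + shifts[["K-H"]],
          base[1:4] + shifts[["13C"]])
  pts <- tibble::tibble(mz = mz, intensity = rexp(length(mz)) * 1e6)
  out <- collapse_adducts(pts)
  expect_equal(sum(canonical_points(out)$intensity), sum(pts$intensity),
               tolerance = 1e-9)
})

test_that("cloud selection is geometric, boundary-inclusive, deterministic", {
  kt <- kendrick_transform(published_mz())
  kt$intensity <- 1
  all_in <- select_cloud(kt, mz_range = c(0, 2000), kmd_range = c(0, 1))
  expect_equal(nrow(all_in), nrow(kt))
  none <- select_cloud(kt, mz_range = c(10, 20), kmd_range = c(0.9, 0.95))
  expect_equal(nrow(none), 0)
  # rectangle over the TG/DG region of the published list: membership agrees
  # with direct KMD arithmetic
  rect <- select_cloud(kt, mz_range = c(840, 910), kmd_range = c(0.23, 0.25))
  manual <- kt[kt$mz >= 840 & kt$mz <= 910 &
                 kt$kmd >= 0.23 & kt$kmd <= 0.25, ]
  expect_equal(rect$mz, manual$mz)
  expect_gt(nrow(rect), 0)
  # polygon path agrees with the rectangle for a rectangular polygon
  poly <- select_cloud(kt, polygon = cbind(c(840, 910, 910, 840),
                                           c(0.23, 0.23, 0.25, 0.25)))
  expect_equal(sort(poly$mz), sort(rect$mz))
  expect_error(select_cloud(kt, mz_range = c(500, 500),
                            kmd_range = c(0.2, 0.3)), "degenerate")
  expect_error(select_cloud(kt, polygon = cbind(c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("matrix flagging marks only matrix-matching points", {
  ions <- matrix_ion_set()
  pts <- tibble::tibble(mz = c(ions$mz, 760.5851, 851.7099), intensity = 1)
  out <- flag_matrix_ions(pts, ions$mz, tol_ppm = 2)
  expect_equal(sum(out$matrix_flag), 6)
  expect_false(any(out$matrix_flag[7:8]))
  # empty matrix list: no flags; zero tolerance: only exact matches
  expect_false(any(flag_matrix_ions(pts, numeric(0))$matrix_flag))
  out0 <- flag_matrix_ions(pts, ions$mz + 1e-4, tol_ppm = 0)
  expect_false(any(out0$matrix_flag))
  # flagged points are excluded from chaining
  chained <- chain_ch2_series(out)
  expect_true(all(is.na(chained$series_id[chained$matrix_flag])))
})
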