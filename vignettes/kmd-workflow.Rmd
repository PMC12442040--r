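---
title: "Kendrick mass defect analysis of whole-body MSI data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kendrick mass defect analysis of whole-body MSI data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kendrickmsi)
```

# The problem and the model

Whole-body MALDI-FT-ICR imaging of a small organism produces one
high-resolution mass spectrum per ~50 µm pixel, with thousands of features
per spectrum. Three structural facts make the data tractable:

1. **Homology.** Lipid families grow by CH2 units. Rescaling every m/z by
   the ratio of the nominal to the exact CH2 mass (`KM = mz × 14.00000 /
   14.01565`) makes homologs differ by exactly 14, so their mass defect
   `KMD = round(KM) − KM` is invariant along the family. In a KMD vs m/z
   scatter, families are horizontal lines; unsaturation (H2, 2.01565 Da)
   and oxidation (O, 15.99491 Da) variants stack almost vertically.
2. **Redundancy.** One species appears as [M+H]+, [M+Na]+, [M+K]+ and as
   ¹³C isotopologues. These are deterministic mass shifts (Na−H 21.98194,
   K−H 37.95588, ¹³C 1.00336 Da), so the redundant points can be collapsed
   onto one canonical protonated monoisotopic point per species.
3. **Matrix background.** CHCA matrix cluster ions appear in every pixel,
   including bare embedding medium, but contain no repeating CH2 unit —
   they form recognizable recurring clusters off the lipid lines and can be
   flagged and excluded.

The package implements this workflow end to end, with each stage a plain
function over tibbles so intermediate results stay inspectable.

## KMD conventions

`kendrick_mass_defect()` supports the three roundings: floor (KMD in
(−1, 0]), ceiling (KMD in [0, 1)) and nearest (±0.5). The package default
is **ceiling**, which places common lipid classes near the middle of the
unit band and keeps the standard lipid selection window KMD 0.10–0.50,
m/z 200–1400 (`kmd_window()`) meaningful. Kendrick masses that are integers
up to a 1e-9 float tolerance are snapped before rounding, so an exact CH2
multiple always has KMD 0 in every mode.

## Mass arithmetic

Monoisotopic atomic masses are fixed 8-significant-digit constants
(`atomic_masses()`), sufficient to reproduce published 4-decimal
theoretical ion masses. Metal adduct ions subtract one electron mass;
protonated ions add the proton mass (equivalently M + H − e). All ions are
singly charged — multiply charged species are out of scope. Isotope
patterns use the carbon-only binomial model at natural ¹³C abundance
0.0107; for CHNOP(+Na/K) lipids carbon dominates the A+1 envelope, and
heavier fine structure is irrelevant at the 2 ppm tolerances used here.
Compositions parse from both compact (`"C53H96O6"`) and space-separated
table notation; isotope-substituted tokens (`"12C38 13C H73 O8 P"`)
require the spaced form, because `13C` after a count digit is ambiguous in
compact strings.

# The synthetic phantom

`simulate_msi()` generates a ground-truthed whole-body dataset so that
every downstream guarantee can be tested quantitatively:

* **Anatomy** (`build_phantom()`): schematic geometry on a pixel grid —
  cuticle ring, ovary (with distinct shell and core sub-masks), brain,
  heart, digestive tubules, silk glands, chelicerae, gelatin background.
  Regions are painted in fixed priority order, hence disjoint by
  construction. This is deliberately not an anatomical atlas: only
  region-conditional statistics matter for validating the pipeline.
* **Species placement** (`default_assignments()`): TG homolog/unsaturation
  series in the cuticle under Na/K adducts; PA species in the ovary with
  potassium-weighted adducts on the shell and sodium-weighted in the core
  (mirroring follicle-vs-surroundings cation partitioning); LPCs in the
  ovary; PC/PE-class species in brain, heart and digestive tubules;
  sterols in the chelicerae; a medium-chain acylcarnitine in the silk
  glands. Base intensities sit in the 1e8–1e10 range typical of summed
  FT-ICR MSI intensities; they are order-of-magnitude realistic, not
  per-pixel calibrated.
* **Instrument** (`instrument_model()`): Gaussian peaks with FT-ICR
  resolving-power scaling R(m) = R₀ · 400 / m anchored at R₀ = 300,000
  FWHM at m/z 400, sampled at 6 points per FWHM over ±4 FWHM windows;
  Gaussian mass jitter with σ = 1 ppm so 99.7% of centroids fall within
  3 ppm of truth; multiplicative log-normal intensity noise (CV 0.2,
  unit mean). The true FT-ICR apodized line shape is not modeled — a
  Gaussian is sufficient to exercise centroiding.
* **Matrix background** (`matrix_ion_set()`): six CHCA cluster ions
  ([M+H]+, [M+Na]+, [M+K]+, [2M+H]+, [2M+Na]+, [3M+H]+) injected into
  every pixel. Six species are enough to exercise matrix recognition
  without modeling full CHCA cluster chemistry.

One deliberate choice: the simulated m/z range defaults to **185–1400**
although the analysis window starts at 200. The protonated CHCA monomer
sits at m/z 190.05; opening the acquisition floor slightly keeps the full
six-ion matrix cluster set present in the raw data (as it is in real
acquisitions with different matrices or ranges), while the KMD window
still removes everything below m/z 200 from analysis.

What the phantom does **not** emulate: MALDI ionization physics and matrix
suppression, detector saturation, chemical noise continua, 3D sectioning
artifacts, or realistic organ textures. Passing tests on the phantom
therefore demonstrate the correctness of the *data treatment* — peak
recovery, alignment, grouping, collapse, annotation, localization — not
robustness to every instrumental pathology of real data.

# Numerical choices, stage by stage

**Peak picking** (`picking_params()`): threshold 200,000 counts,
prominence 0, minimum distance 5 data points — the routine profile-mode
settings for this kind of data. Distance is defined in data points and so
couples to profile sampling density; it applies to profile input only
(centroided input should skip picking). Apexes are refined by a parabola
through the apex and both neighbors **on log intensity**, which is exact
for Gaussian peaks on any locally uniform grid; the raw-intensity parabola
is the fallback when a neighbor is non-positive, and the apex sample is
kept when the fit degenerates. Close maxima are resolved greedily from the
tallest down.

**Recalibration** (`recalibrate_peaks()`): a linear ppm-drift model
`ppm(m) = a + b·m` fit by least squares to matched reference peaks and
inverted. This is a deliberately simple lock-mass scheme; the parameters
of the external recalibration tool used upstream of such workflows are
recorded in `kmd_config()$recal_provenance` for provenance but not
interpreted. Fewer than two reference matches gives a flagged no-op, never
an error. Intensities are never modified.

**Alignment** (`align_peaks()`): pooled sorted centroids, new bin when the
gap to the previous centroid exceeds the tolerance — single-linkage gap
clustering, deterministic and pixel-order invariant. Default tolerance
3 ppm, the instrument's targeted mass accuracy. The bin representative is
the intensity-weighted mean m/z; multiple same-pixel members of one bin
are summed so total ion current is conserved exactly.

**KMD-class grouping** (`group_kmd_classes()`): absolute KMD tolerance
0.0025 — about 2 mDa at the CH2 scale, consistent with 2 ppm chaining at
m/z ~800.

**Series chaining** (`chain_ch2_series()`, `chain_vertical()`): an edge
links two points when their mass difference is within 2 ppm (measured
against the heavier member — a fixed convention so results are
reproducible) of k × step for k ≤ k_max; series are connected components
with ≥ 2 members. k_max defaults to 10, comfortably above the span of
published lipid series while bounding the graph. Multi-step links are
allowed by default so a missing middle homolog does not split a series.
Vertical (H2/O) components are additionally limited to a 3-step total m/z
span, since long unsaturation ladders are not chemically expected.
Matrix-flagged points never chain.

**Adduct/isotope collapse** (`collapse_adducts()`): the states of a
species are the (adduct, isotopologue) grid; two observed points link when
their mass difference matches any pairwise difference of state offsets
within tolerance. Using state *differences* — not just the raw Na−H, K−H,
¹³C shifts — means a potassium and a sodium adduct link directly (K−Na =
15.97394 Da) even when the protonated form was never detected, which is
exactly the situation for ovary phosphatidic acids observed only as Na/K
adducts. Among multiple in-tolerance partners the smallest |ppm| wins,
deterministically; union-find merges chains. The canonical m/z is the
lowest-offset state assignment that explains every member, so a family
observed as {Na, Na+¹³C, K, K+¹³C} imputes its protonated monoisotopic
mass by shift subtraction. A family observed under a *single* adduct is
intrinsically ambiguous — {X, X+1.00336} is explained equally well by any
adduct — and the convention resolves it as protonated, i.e. the lowest
member is kept as-is. Downstream annotation therefore offers all three
adduct hypotheses for canonical points. Collapse conserves summed
intensity exactly.

**Cloud selection** (`select_cloud()`): explicit analyst geometry
(rectangle or polygon, boundary-inclusive) — clouds in a KMD plot are an
interpretive device, and automatic density clustering is intentionally not
the default.

**Annotation** (`annotate_mz()`, `ranking_policy()`): candidates are all
(record, adduct) pairs within the ppm window of the bundled offline
reference table (no live database queries — reproducibility). Ranking
follows three criteria in order: ascending |ΔM|; on near-ties within
0.3 ppm, positive-mode class priority; and outright exclusion of
implausibly oxidized compositions (defaults: > 10 double bonds or > 10
oxygens). The 0.3 ppm tie window is the package's own calibration of
"similar mass error" at FT-ICR accuracy. The default class order places
DG ahead of TG: sodiated-DG and potassiated-TG readings of one peak can
tie within 0.3 ppm (e.g. at m/z 867.68, DG +Na vs TG +K differ by
0.28 mDa), and in reference assignments such ties resolve toward the
sodiated DG. Matches between 5 and 6 ppm are kept but flagged
`low-confidence` rather than discarded, since genuine assignments at up to
~5.5 ppm occur in practice. Isobaric PC/PE pairs that positive-mode exact
mass cannot distinguish are stored and reported as one joined record
("PC 34:1 or PE 37:1"); resolving them needs MS/MS or LC and is out of
scope. Remaining ties break deterministically by name, so ranking is a
total order.

**Series propagation** (`propagate_series_annotation()`): one identified
anchor annotates every member of its horizontal series at integer CH2
offsets (carbons shifted in the shorthand, C and 2H per step in the
composition), flagged `propagated` rather than `matched`; non-integer
offsets are left unannotated with a warning. Propagation is involutive.

**Isotope validation** (`validate_isotope_pattern()`): cosine similarity
between the binomial pattern (first 3 isotopologues) and observed
intensities matched at 2 ppm, missing isotopologues counted as zero.

**Imaging** (`ion_image()`, `cloud_tic_image()`): pixel convention is
0-based, x = column, y = row, origin top-left, matching common imzML
readers; images are plain matrices. Cloud images deduplicate members by
bin identity, making them exactly additive over disjoint sets and summing
to the TIC image over all bins. Display clipping (99th percentile in
`autoplot()`) happens only at rendering; stored intensities are never
clipped. Per-pixel TIC normalization guards zero-TIC pixels to 0.

**imzML I/O**: both the continuous (shared m/z axis) and processed
(per-pixel axis) dialects are supported; arrays are written as
uncompressed little-endian 64-bit floats and read back at either 32- or
64-bit width, including files produced by other writers. Compressed
arrays are rejected with a clear error.

# Degenerate inputs

Empty spectra pick no peaks; an all-zero dataset flows through the
pipeline into empty reports rather than errors. Empty matrix lists flag
nothing. Degenerate cloud geometry (zero-area rectangle, < 3 distinct
polygon vertices) errors. Unknown element symbols, unsupported adducts and
malformed reference tables error with the offending symbol, adduct or line
number named.

# Problem sizes

The bundled validation runs use a 64 × 64 pixel phantom (4,096 spectra,
~18 planted species × adducts × isotopologues plus 6 matrix ions per
pixel) for the end-to-end guarantees, and 24 × 24 phantoms for unit-level
checks; these sizes exercise every code path with comfortable statistics
while keeping a full test run around a minute and a half.

# Known limitations

* Adduct identity of single-adduct families is unrecoverable from m/z
  differences alone; their canonical points keep the observed mass and
  annotation considers all adduct hypotheses.
* The carbon-binomial isotope model ignores ¹⁵N/¹⁸O/²H contributions;
  at the 1% abundance scale this is negligible for the validation
  tolerances used, but the model should not be used for fine isotope
  structure work.
* The linear recalibration model cannot remove non-linear mass drift.
* Matrix recognition is list-based (known cluster m/z); it does not
  discover unknown background families, though the KMD plot makes them
  visually conspicuous.
* Published printed values carry printing artifacts the package
  documents rather than reproduces blindly: two first-isotope rows and
  one rounding-boundary row differ by 1e-4 from composition-derived
  values, and two rows print compositions inconsistent with their own
  printed theoretical masses (`check_reference_tables()` marks all of
  these as known exceptions).
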