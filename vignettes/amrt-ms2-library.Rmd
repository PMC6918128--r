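---
title: "Building and applying AMRT+MS2 spectral libraries from AIF data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and applying AMRT+MS2 spectral libraries from AIF data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiflib)
```

## The problem

Confident metabolite annotation in untargeted LC–MS needs more than an
accurate mass. Isomers share the elemental formula exactly — every
positional isomer of C7H7NO2 produces a protonated ion at 138.055 Th — and
low-mass metabolites with different structures can even produce similar
fragment spectra. Annotation therefore rests on three orthogonal
properties: accurate mass (AM), retention time (RT), and the MS2 fragment
spectrum. `aiflib` implements the workflow that turns dilution series of
chemical standards, acquired in all-ion-fragmentation (AIF) mode, into a
curated AMRT+MS2 library, and then applies that library to query data.

AIF acquisition cycles through collision-energy channels — a full scan,
then 10 eV and 30 eV here — fragmenting *all* coeluting precursors
together. Each high-energy scan is thus a superposition of the fragment
spectra of everything eluting at that moment, plus chemical background.
The computational core of the package is the attribution of those mixed
fragments to their precursors ("deconvolution"), done two independent
ways:

* **Within-run least squares** (`ms2dec()`). Each fragment m/z bin's
  chromatogram inside the precursor's elution window is fitted as a
  non-negative combination of the precursor's own full-scan elution
  profile, Gaussian profiles at the apexes of any interfering peaks
  detected in that bin, and a constant baseline. The coefficient on the
  precursor profile is the deconvoluted fragment intensity. Interferents
  are modeled as Gaussians with the precursor's fitted chromatographic
  width rather than with the bin's own (mixed) trace — using the mixed
  trace would let the interferent component absorb the precursor's share
  of an overlapped bin. A bin is only attributed to the precursor when the
  precursor component explains at least `min_share` (default 5%) of the
  bin's signal.
* **Cross-sample correlation** (`corrdec()`). Across a dilution series the
  precursor's apex height spans orders of magnitude; a fragment that
  belongs to it must co-vary. Bins whose apex heights correlate with the
  precursor's (Pearson r ≥ 0.90 over the runs where the precursor exceeds
  the noise level) are kept, with intensity taken from the through-origin
  regression slope. The method declines entirely unless at least 4 runs
  are above the noise level — with fewer points a correlation is not
  trustworthy. A fragment present at *constant* intensity in every run —
  the signature of chemical background such as the ubiquitous phthalate
  ion at 149.0233 Th — has (near-)zero variance and can never pass, which
  is exactly the desired behavior.

Agreement between two methods that use disjoint information (intensity
over time vs. intensity across samples) is strong evidence that a
deconvoluted spectrum is real; the package's tests require ≥ 90% dot
product agreement on interference-free synthetic series.

## Retention-time correction

RTs on HILIC columns drift between injections. Every injection carries
technical internal standards (tIS) spanning the gradient; `build_rt_map()`
matches their observed apexes (found within ±1.5 min of the reference RT)
to reference RTs from an authentic representative analysis and
`correct_rt()` applies a piecewise-linear map: exact at the anchors,
linear interpolation between them. Beyond the anchor span the nearest
anchor's *offset* is held constant rather than extrapolating the segment
slope — at gradient extremes slope extrapolation amplifies noise in the
outermost anchor pair. A tIS lost to ion suppression (which the generator
can emulate) is dropped with a warning; at least two anchors must remain.
`rt_deviation_stats()` summarizes cross-run repeatability (mean, maximum
absolute deviation, CV% with the sample standard deviation, appropriate
for the handful of injections involved).

## Annotation and curation

Because the standards are known compounds, every deconvoluted peak can be
tested against chemistry: `annotate_fragments()` enumerates all
subformulas of the ionized precursor's atom multiset, keeps those with
ring-plus-double-bond equivalents ≥ 0 and H ≤ 2C + N + 2, and also tests
adduct, water-loss and carbon-13 isotope ions of the intact molecule
(sodium and potassium adducts travel with the standard itself). The
lowest-|mass-error| candidate within ±0.01 Th wins; identities of the
intact molecule (precursor/isotope/adduct) outrank a coincidental
subformula at the same error; even-electron ions are preferred on ties,
then fewer atoms — making annotation deterministic. Peaks with no
candidate are removed (`strip_unannotated()`): in AIF data they are
usually noise or another compound's ions.

Curation (`curate_library()`, `group_records()`) then groups records by
InChIKey first block (the 14-character skeleton hash), flags groups whose
records disagree on formula or spread more than 1 min in RT, replaces the
experimental precursor m/z with the theoretical value — the compound's
identity is known, so the library should carry the exact mass — while
retaining the measurement in `experimental_mz` (serialized into the MSP
COMMENT field) because it documents the record's mass accuracy.
Consensus spectra, product-ion frequencies and library comparison support
maintenance of growing collections.

## Identification policy

`identify_run()` finds candidates within ±0.01 Th and ±0.7 min, scores
each by the spectral dot product (squared cosine of greedily matched
intensity vectors, in percent) per shared collision energy, and accepts at
≥ 70%. The RT window is deliberately wide for HILIC, so same-formula
isomers regularly produce multiple AMRT candidates; MS2 is what separates
them. Accepted matches earn "level-1" only when the standards were run in
the same analytical batch; otherwise "level-2 (AMRT+MS2)", and AMRT-only
candidates are reported, not discarded, as "level-2 (AMRT)". The 70%
threshold is a configuration default (`default_config()`), not a law; the
policy table of `assign_level()` is overridable.

## The synthetic-data generator

Real AIF data from the instrument cannot ship with a package, so
`simulate_run()` / `simulate_characterization_campaign()` generate
ground-truthed data under the study's acquisition design: a 15-min
gradient sampled at 6 scans/s across three alternating channels (full
scan, 10, 30 eV), m/z 40–1200, Gaussian elution peaks (σ = 3 s), a
linear-with-hard-ceiling detector response (ceiling 5×10⁶ AU, so the top
dilution levels clip realistically), adducts with M+1 isotope partners
(1.1% per carbon), per-centroid m/z jitter ≤ 2 mDa, 3% multiplicative
intensity noise, uniform chemical noise, a constant contaminant ion at
149.0233 Th in every scan, and a smooth monotone per-run RT drift (offset
plus half-sine, up to ~0.45 min). The dilution design is seven 4-fold
steps from 4.0 µM (8000 fmol at 2 µL) down to ~0.001 µM, plus a blank,
with tIS at constant amount everywhere. The manifest and the scan data
are written from the same source, so the manifest is exact ground truth.

Two of the five example compounds are positional isomers of the first
(same formula C7H7NO2, distinct RTs and fragmentation) — reproducing the
isobaric ambiguity that motivates MS2 matching — and the query scenario
plants two decoy features at the same nominal m/z as the true compound
with disjoint fragment sets.

What the generator does *not* emulate: electrospray matrix effects beyond
a simple coelution-suppression flag, peak fronting/tailing, isotope fine
structure, centroiding artifacts from profile data, and real biological
matrix complexity. Passing the recovery tests therefore demonstrates the
correctness of the algorithms under their stated model, not instrument
performance.

## Numerical choices and degenerate inputs

* Atomic monoisotopic masses are fixed in code (¹²C exact; H 1.0078250319;
  electron mass 0.00054858 subtracted per positive charge); all
  theoretical m/z derive from this one table, and display rounds to 4
  decimals while full precision is kept internally.
* Fragment binning clusters centroids separated by gaps > 0.01 Th;
  bin centers are intensity-weighted means.
* Peak detection smooths with a 3-point moving average, requires ≥ 3
  scans width, and refines apexes by parabolic interpolation — one scan
  (0.5 s) would otherwise bound RT accuracy.
* Non-negative least squares uses an active-set solver with an
  iterative-clamping fallback for the rare ill-conditioned windows.
* A saturated (clipped) precursor profile is replaced by a Gaussian
  fitted to the peak's width before being used as a model profile; the
  representative run for library spectra is the most intense
  *nonsaturated* one.
* Pearson correlation with zero variance on either side fails the bin
  (never a division by zero); an empty spectrum scores 0 with a warning
  in the dot product.
* MSP/MGF writers emit fixed field orders and 8-decimal m/z so output is
  byte-stable and round-trips losslessly.

## Problem sizes

The shipped tests and the acceptance script run the full design: 5
compounds × (7 dilutions + blank) × 5 tIS at 1800 cycles per run for
library construction, a decoy query run, and a 7-point sweep of the
above-noise sample count for the correlation method's decline criterion.
The whole suite completes in a few minutes on one core; the generator and
deconvolution are vectorized per ion and per bin respectively.

## Worked example

```{r example, eval = FALSE}
# simulate a campaign, build the library, identify a query run
camp <- simulate_characterization_campaign(example_compounds(),
                                           example_tis(), seed = 1)
built <- characterize_campaign(camp, example_compounds(), example_tis())
write_msp(built$library, "library.msp")

q <- simulate_query_dataset(example_compounds()[1, ], example_decoys(),
                            tis = example_tis(), seed = 2)
tis_ref <- tibble::tibble(name = example_tis()$name,
                          formula = example_tis()$formula,
                          adduct = "[M+H]+", rt = example_tis()$rt)
res <- identify_run(q$run, built$library, tis_ref = tis_ref)
dplyr::filter(tidy(res$matches), accepted)
```

## Known limitations

Only singly charged positive-mode ions are generated and annotated by
default; profile-mode data must be centroided upstream; the identification
step is targeted (library m/z values drive feature detection) rather than
a full untargeted feature finder; and the deconvolution model assumes
roughly Gaussian elution within a window — strongly tailing peaks would
degrade the least-squares attribution before they degrade the
correlation method.
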