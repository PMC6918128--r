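# aiflib

Construction and application of **AMRT+MS2 spectral libraries** —
accurate mass + retention time + tandem mass spectra — from
**all-ion-fragmentation (AIF)** LC–MS data, for metabolomics groups that
characterize chemical standards in-house and want their annotations to
rest on more than an accurate mass.

In AIF acquisition every scan cycle alternates collision energies (full
scan, 10 eV, 30 eV) and fragments *all* coeluting precursors together, so
each high-energy spectrum is a mixture. `aiflib` implements the full
chain that turns dilution series of standards into a curated library and
applies it to query data:

* **Exact-mass chemistry** — elemental formulas, adducts
  (`[M+H]+`, `[M+Na]+`, `[M+H-2H2O]+`, …), carbon-13 isotopes, InChIKey
  handling. E.g. C7H7NO2 → 137.0477 Da, `[M+H]+` at 138.0550 Th.
* **Spectral deconvolution**, two independent ways:
  * `ms2dec()` — within one run, each fragment bin's chromatogram is fit
    as a non-negative combination of the precursor's elution profile,
    interferent profiles and a baseline (the coefficient on the precursor
    profile is the fragment's intensity);
  * `corrdec()` — across a dilution series, fragments whose apex heights
    correlate with the precursor's (Pearson r ≥ 0.90 over above-noise
    runs, at least 4 of them required) are kept, with through-origin
    regression slopes as intensities. Constant background ions (e.g. the
    phthalate contaminant at 149.0233 Th) can never pass.
* **tIS-anchored RT correction** — piecewise-linear mapping between
  observed and reference retention times of spiked technical internal
  standards, constant-offset extrapolation beyond the anchor span.
* **Annotation** — bounded subformula search (RDBE ≥ 0, H ≤ 2C+N+2)
  plus adduct/water-loss/isotope candidates within ±0.01 Th; unannotated
  peaks are stripped.
* **Curation** (`curate_library()`) — InChIKey-first-block grouping,
  formula/RT consistency flags, theoretical-precursor replacement (the
  measured m/z is retained as `experimental_mz`), consensus spectra,
  product-ion frequencies, library comparison.
* **Identification** (`identify_run()`) — AMRT candidate search
  (±0.01 Th, ±0.7 min), dot-product MS2 scoring
  (100·(Σxy)²/(Σx²·Σy²)), and MSI-style confidence levels ("level-1"
  only when the standards ran in the same batch).
* **I/O** — NIST-style MSP (read/write, annotation-preserving), MGF
  (read/write), MassBank records (read), mzML (read, via `mzR`), and a
  plain-text tabular AIF scan format.
* **Ground-truthed synthetic data** (`simulate_run()`,
  `simulate_characterization_campaign()`, `simulate_query_dataset()`) —
  7-level 4-fold dilution series (8000 → ~2 fmol), Gaussian peaks,
  saturation, adducts and isotopes, contaminants, noise, RT drift, decoy
  features; the manifest is exact truth for validation.

All user-facing functions take and return tibbles (spectra are peak
tibbles with metadata attributes; a library is a tibble with a spectrum
list-column), so pipelines compose with dplyr, and `tidy()`/`glance()`/
`autoplot()` methods cover the result types.

## Worked example

Characterize one compound from a simulated 7-level dilution series with
two tIS, on a short 3-min gradient:

```r
library(aiflib)
cmp <- example_compounds()[1, ]; cmp$rt <- 1.5
tis <- example_tis()[1:2, ];     tis$rt <- c(0.6, 2.4)
runs <- lapply(1:7, function(i)
  simulate_run(dplyr::bind_rows(cmp, tis), c(4000/4^(i-1), 200, 200),
               drift = make_drift(0.05, 0.03, 3), seed = 100 + i,
               gradient_min = 3)$run)
tis_ref <- tibble::tibble(name = tis$name, formula = tis$formula,
                          adduct = "[M+H]+", rt = tis$rt)
res <- characterize_series(runs, cmp, tis_ref)
res$library[, c("name", "adduct", "collision_energy", "precursor_mz", "rt")]
#> # A tibble: 6 × 5
#>   name              adduct  collision_energy precursor_mz    rt
#>   <chr>             <chr>              <dbl>        <dbl> <dbl>
#> 1 trigonelline-like [M+H]+                10         138.  1.51
#> 2 trigonelline-like [M+H]+                30         138.  1.51
#> 3 trigonelline-like [M+Na]+               10         160.  1.51
#> 4 trigonelline-like [M+Na]+               30         160.  1.51
#> 5 trigonelline-like [M+K]+                10         176.  1.51
#> 6 trigonelline-like [M+K]+                30         176.  1.51
```

One record per detected adduct × collision energy. The 30 eV spectrum of
the protonated molecule, deconvoluted (correlation method preferred, the
least-squares result as fallback), 1%-filtered, annotated and stripped:

```r
res$library$spectrum[[2]]
#> # A tibble: 6 × 3
#>      mz intensity annotation
#>   <dbl>     <dbl> <chr>
#> 1  78.0     12.3  C5H4N+; fragment
#> 2  92.0     20.1  C6H6N+; fragment
#> 3  94.1    100    C6H8N+; fragment
#> 4 138.      25.4  C7H8NO2+; precursor
#> 5 160.       2.54 [M+Na]+; adduct
#> 6 176.       1.26 [M+K]+; adduct
```

The generator's truth for this channel was C6H8N⁺ 100, C7H8NO2⁺ 25,
C6H6N⁺ 20, C5H4N⁺ 12 — every fragment is recovered within a few relative
percent, the RT (true 1.5 min, drifted ~1.55) comes back as 1.51 after
tIS correction, and the precursor m/z is the exact theoretical value.
`write_msp(res$library, "library.msp")` exports the records;
`identify_run()` applies them to query runs.

A thin command-line wrapper over the same functions ships in
`inst/cli/aif.R` (subcommands `simulate`, `characterize`, `curate`,
`compare`, `identify`), with defaults in
`inst/extdata/default_config.yaml`.

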