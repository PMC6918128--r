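# aiflib pipeline configuration (defaults shown; any key may be omitted).
# Units: Th for m/z tolerances, minutes for RT, AU for intensities, eV for
# collision energies, percent where noted.

mz_tol: 0.01              # accurate-mass window for EICs and AMRT matching
rt_tol: 0.7               # RT window for AMRT matching
bin_tol: 0.01             # peak-matching tolerance in spectral dot products
frag_tol: 0.01            # fragment m/z binning during deconvolution
tis_search_window: 1.5    # tIS anchor search half-window around reference RT
intensity_threshold_pct: 1.0   # remove peaks below this % of the base peak
noise_level: 1000         # precursor height for a run to count as above-noise
min_samples: 4            # minimum above-noise runs required by the
                          # correlation deconvolution; below this it declines
r_threshold: 0.90         # minimum Pearson r fragment-vs-precursor
ms2_threshold: 70         # % dot product to accept an identification
rt_group_window: 1.0      # RT spread that flags a compound group
sat_ceiling: 5.0e6        # detector saturation ceiling
min_peak_height: 500      # chromatographic peak detection floor
annotation_tol: 0.01      # fragment/adduct/isotope annotation tolerance
seed: 1
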