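# Curation engine: dot product, grouping, consistency, precursor
# replacement, consensus, ion frequency, library comparison.

test_that("dot product on identical, disjoint and hand-computed spectra", {
  a <- ms_spectrum(c(100, 110), c(100, 50))
  expect_equal(dot_product(a, a), 100)
  b <- ms_spectrum(c(200, 210), c(100, 50))
  expect_equal(dot_product(a, b), 0)
  # hand cosine^2: (100*50 + 50*100)^2 / ((100^2+50^2)(50^2+100^2)) = 0.64
  cr <- ms_spectrum(c(100, 110), c(50, 100))
  expect_equal(dot_product(a, cr), 64.0)
  expect_warning(z <- dot_product(a, ms_spectrum()), "empty")
  expect_equal(z, 0)
})

test_that("dot product is symmetric and bounded on random spectra", {
  withr::with_seed(12, {
    for (i in 1:30) {
      a <- random_spectrum()
      b <- random_spectrum()
      sab <- dot_product(a, b)
      expect_equal(sab, dot_product(b, a))
      expect_gte(sab, 0)
      expect_lte(sab, 100)
      expect_equal(dot_product(a, a), 100)
    }
  })
})

test_that("grouping partitions any library by InChIKey first block", {
  lib <- toy_library()
  # same skeleton, different protonation-layer block -> one group
  lib$inchikey[2] <- paste0(substr(lib$inchikey[1], 1, 14), "-ZZZZZZZZZZ-M")
  g <- group_records(lib)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_records, 2)

  lib2 <- toy_library()  # distinct first blocks -> separate groups
  g2 <- group_records(lib2)
  expect_equal(nrow(g2), 2)

  # partition property on random key assignments
  withr::with_seed(13, {
    keys <- vapply(sample(letters, 12, TRUE), synthetic_inchikey, "")
    lib3 <- ms_library(name = paste0("r", 1:12), formula = "C7H7NO2",
                       adduct = "[M+H]+", inchikey = keys,
                       precursor_mz = 138.055, rt = 5, collision_energy = 30,
                       spectrum = replicate(12, random_spectrum(),
                                            simplify = FALSE))
    g3 <- group_records(lib3)
    expect_equal(sum(g3$n_records), 12)
    all_rows <- dplyr::bind_rows(lapply(g3$records, tibble::as_tibble))
    expect_setequal(all_rows$name, lib3$name)
  })

  # missing key -> flagged singleton
  lib4 <- toy_library()
  lib4$inchikey[1] <- NA
  g4 <- group_records(lib4)
  expect_true(any(g4$missing_key & g4$n_records == 1))
})

test_that("group consistency flags formula mismatch and RT spread", {
  lib <- toy_library()
  lib$rt <- c(7.41, 7.46)
  expect_false(check_group_consistency(lib)$rt_spread_exceeded)
  lib$rt <- c(6.0, 7.5)
  expect_true(check_group_consistency(lib)$rt_spread_exceeded)
  lib$formula <- c("C7H7NO2", "C7H7NO2")
  expect_false(check_group_consistency(lib)$formula_mismatch)
  lib$formula <- c("C7H7NO2", "C5H11NO2")
  expect_true(check_group_consistency(lib)$formula_mismatch)
})

test_that("precursor replacement stores the measurement and is idempotent", {
  lib <- toy_library()
  lib$precursor_mz[1] <- 138.0561
  lib$experimental_mz[1] <- NA
  cur <- replace_precursor_mz(lib)
  expect_equal(round(cur$precursor_mz[1], 4), 138.0550)
  expect_equal(cur$experimental_mz[1], 138.0561)
  again <- replace_precursor_mz(cur)
  expect_equal(again$precursor_mz, cur$precursor_mz)
  expect_equal(again$experimental_mz, cur$experimental_mz)

  lib$formula[1] <- NA
  expect_error(replace_precursor_mz(lib), "formula")
})

test_that("consensus spectrum: identity, idempotence and the presence rule", {
  s <- ms_spectrum(c(94.0651, 138.055), c(999, 250), collision_energy = 30)
  one <- consensus_spectrum(list(s))
  expect_equal(one$mz, s$mz)
  expect_equal(one$intensity, 100 * s$intensity / max(s$intensity))

  three <- consensus_spectrum(list(s, s, s))
  expect_equal(three$mz, one$mz)
  expect_equal(three$intensity, one$intensity)

  # a peak in 1 of 3 spectra is dropped at min_fraction 0.5
  s_extra <- ms_spectrum(c(94.0651, 120.05, 138.055), c(999, 400, 250),
                         collision_energy = 30)
  cons <- consensus_spectrum(list(s, s, s_extra))
  expect_false(any(abs(cons$mz - 120.05) < 0.01))

  s10 <- ms_spectrum(100, 10, collision_energy = 10)
  expect_error(consensus_spectrum(list(s, s10)), "collision energy")
})

test_that("product-ion frequency counts each record once per bin", {
  lib <- toy_library()
  freq <- product_ion_frequency(lib)
  expect_equal(sum(freq$n_records), 4)  # 2 + 2 peaks, no shared ions
  expect_true(all(freq$n_records == 1))

  shared <- toy_library()
  shared$spectrum[[2]] <- ms_spectrum(c(94.0651, 118.0863), c(10, 1000),
                                      collision_energy = 10)
  freq2 <- product_ion_frequency(shared)
  expect_equal(freq2$n_records[abs(freq2$mz - 94.0651) < 0.01], 2)

  empty <- ms_library()
  expect_equal(nrow(product_ion_frequency(empty)), 0)
})

test_that("library comparison: self gives 100, disjoint gives nothing", {
  lib <- toy_library()
  self <- compare_libraries(lib, lib)
  expect_equal(nrow(self), 2)
  expect_true(all(self$similarity == 100))
  expect_true(all(self$rt_diff == 0))

  other <- toy_library()
  other$inchikey <- vapply(c("x1", "x2"), synthetic_inchikey, "")
  expect_equal(nrow(compare_libraries(lib, other)), 0)
})

test_that("perturbed library copy scores below 100 but above the floor", {
  withr::with_seed(14, {
    lib <- toy_library()
    pert <- lib
    pert$spectrum <- lapply(pert$spectrum, function(s) {
      ms_spectrum(s$mz, s$intensity * runif(nrow(s), 0.9, 1.1),
                  precursor_mz = precursor_mz(s),
                  collision_energy = collision_energy(s),
                  rt = spectrum_rt(s))
    })
    cmpd <- compare_libraries(lib, pert)
    expect_true(all(cmpd$similarity < 100))
    expect_true(all(cmpd$similarity > 95))  # 10% intensity perturbation
  })
})

test_that("curation pipeline applied twice equals applied once", {
  sim <- small_run(seed = 33)
  run <- sim$run
  mz <- adduct_mz("C7H7NO2", "[M+H]+")
  pk <- detect_peaks(extract_eic(run, 0, mz), min_height = 500)
  dec <- ms2dec(run, pk[which.max(pk$height), ], channel = 30,
                precursor_mz = mz)
  lib <- ms_library(name = "t", formula = "C7H7NO2", adduct = "[M+H]+",
                    inchikey = synthetic_inchikey("t"),
                    precursor_mz = 138.0561, rt = 1.5, collision_energy = 30,
                    spectrum = list(dec))
  c1 <- curate_library(lib)$library
  c2 <- curate_library(c1)$library
  expect_equal(c2$precursor_mz, c1$precursor_mz)
  expect_equal(c2$experimental_mz, c1$experimental_mz)
  expect_equal(c2$spectrum[[1]]$mz, c1$spectrum[[1]]$mz)
  expect_equal(c2$spectrum[[1]]$intensity, c1$spectrum[[1]]$intensity)
})
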