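# MSP / MGF / MassBank / AIF tabular format I/O.

test_that("MSP write/read round-trips field-for-field and peak-for-peak", {
  lib <- toy_library()
  lines <- write_msp(lib)
  back <- read_msp(lines)
  expect_equal(nrow(back), 2)
  for (col in c("name", "formula", "adduct", "inchikey", "precursor_mz",
                "experimental_mz", "rt", "ion_mode", "collision_energy")) {
    expect_equal(back[[col]], lib[[col]], info = col)
  }
  for (i in 1:2) {
    expect_equal(back$spectrum[[i]]$mz, lib$spectrum[[i]]$mz)
    expect_equal(back$spectrum[[i]]$intensity, lib$spectrum[[i]]$intensity)
    expect_equal(back$spectrum[[i]]$annotation, lib$spectrum[[i]]$annotation)
  }
  # unknown header keys survive verbatim
  expect_identical(back$provenance[[1]][["INSTRUMENT"]], "synthetic Q-TOF")
})

test_that("MSP writer output is byte-stable across runs", {
  lib <- toy_library()
  expect_identical(write_msp(lib), write_msp(lib))
  expect_identical(write_msp(read_msp(write_msp(lib))), write_msp(lib))
})

test_that("MSP round-trips a generated record corpus", {
  withr::with_seed(42, {
    specs <- lapply(1:8, function(i) {
      n <- sample(1:10, 1)
      ms_spectrum(round(sort(runif(n, 50, 900)) + seq_len(n), 4),
                  round(runif(n, 1, 1e5)),
                  precursor_mz = round(runif(1, 100, 900), 4),
                  collision_energy = sample(c(10, 30), 1),
                  rt = round(runif(1, 0.5, 14), 3))
    })
    lib <- ms_library(name = paste0("cmpd-", 1:8),
                      formula = "C7H7NO2", adduct = "[M+H]+",
                      inchikey = vapply(paste0("cmpd-", 1:8),
                                        synthetic_inchikey, ""),
                      precursor_mz = vapply(specs, precursor_mz, 0),
                      rt = vapply(specs, spectrum_rt, 0),
                      collision_energy = vapply(specs, collision_energy, 0),
                      spectrum = specs)
    back <- read_msp(write_msp(lib))
    expect_equal(back$precursor_mz, lib$precursor_mz)
    expect_equal(back$rt, lib$rt)
    for (i in seq_len(nrow(lib))) {
      expect_equal(back$spectrum[[i]]$mz, lib$spectrum[[i]]$mz)
      expect_equal(back$spectrum[[i]]$intensity, lib$spectrum[[i]]$intensity)
    }
  })
})

test_that("MSP peak-count mismatch and bad peak lines are errors", {
  bad <- c("NAME: x", "PRECURSORMZ: 100.1", "Num Peaks: 3",
           "50.1\t100", "60.2\t200")
  expect_error(read_msp(bad), "Num Peaks")
  bad2 <- c("NAME: x", "Num Peaks: 1", "not-a-peak-line???")
  expect_error(read_msp(bad2), "peak")
})

test_that("MSP annotated peak lines carry the annotation", {
  lines <- c("NAME: t", "PRECURSORMZ: 138.055", "Num Peaks: 1",
             "94.0651\t999\t\"C6H8N+; fragment\"")
  rec <- read_msp(lines)
  expect_identical(rec$spectrum[[1]]$annotation, "C6H8N+; fragment")
})

test_that("curated experimental m/z lands in COMMENT and returns intact", {
  lib <- toy_library()
  lines <- write_msp(lib)
  expect_true(any(grepl("experimental_mz=138.0561", lines, fixed = TRUE)))
  back <- read_msp(lines)
  expect_equal(back$experimental_mz[1], 138.0561)
})

test_that("MGF round-trips with RT converted at the seconds boundary", {
  lib <- toy_library()
  lines <- write_mgf(lib)
  expect_true(any(grepl("RTINSECONDS=447.6", lines, fixed = TRUE)))
  back <- read_mgf(lines)
  expect_equal(back$rt, lib$rt)
  expect_equal(back$precursor_mz, lib$precursor_mz)
  expect_equal(back$name, lib$name)
  for (i in 1:2) {
    expect_equal(back$spectrum[[i]]$mz, lib$spectrum[[i]]$mz)
    expect_equal(back$spectrum[[i]]$intensity, lib$spectrum[[i]]$intensity)
  }
})

test_that("MGF edge cases: seconds conversion, empty stream, unterminated", {
  rec <- read_mgf(c("BEGIN IONS", "TITLE=x", "PEPMASS=138.055",
                    "RTINSECONDS=447.6", "94.07 100", "END IONS"))
  expect_equal(rec$rt, 7.46)
  expect_equal(nrow(read_mgf(character())), 0)
  expect_error(read_mgf(c("BEGIN IONS", "TITLE=x")), "unterminated")
})

test_that("MassBank records are read with peaks and metadata", {
  block <- c(
    "ACCESSION: SYNTH00001",
    "CH$NAME: trigonelline-like",
    "CH$FORMULA: C7H7NO2",
    "CH$LINK: INCHIKEY AAAAAAAAAAAAAA-UHFFFAOYSA-N",
    "AC$MASS_SPECTROMETRY: ION_MODE POSITIVE",
    "AC$MASS_SPECTROMETRY: COLLISION_ENERGY 30 eV",
    "AC$CHROMATOGRAPHY: RETENTION_TIME 7.46 min",
    "MS$FOCUSED_ION: PRECURSOR_M/Z 138.055",
    "MS$FOCUSED_ION: PRECURSOR_TYPE [M+H]+",
    "PK$NUM_PEAK: 2",
    "PK$PEAK: m/z int. rel.int.",
    "  94.0651 999 999",
    "  138.055 250 250",
    "//")
  rec <- read_massbank(block)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$formula, "C7H7NO2")
  expect_equal(rec$rt, 7.46)
  expect_equal(rec$precursor_mz, 138.055)
  expect_equal(nrow(rec$spectrum[[1]]), 2)
})

test_that("AIF runs round-trip through the internal tabular format", {
  sim <- small_run()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_aif_run(sim$run, path)
  back <- read_aif_run(path)
  expect_equal(back$channel_energies, sim$run$channel_energies)
  expect_equal(back$mass_range, sim$run$mass_range)
  expect_equal(nrow(back$points), nrow(sim$run$points))
  expect_equal(sort(back$points$mz), sort(sim$run$points$mz))
  expect_equal(dplyr::arrange(back$cycles, .data$time_min)$time_min,
               dplyr::arrange(sim$run$cycles, .data$time_min)$time_min)
})

test_that("three channels at 6 scans per second give 2 cycles per second", {
  sim <- simulate_run(example_compounds()[0, ], numeric(0), seed = 1,
                      gradient_min = 1)
  cyc <- sim$run$cycles
  expect_equal(length(unique(cyc$cycle)), 120)  # 60 s x 2 cycles/s
  one_sec <- cyc[cyc$time_min < 1 / 60 - 1e-9, ]
  expect_equal(length(unique(one_sec$cycle)), 2)
})

test_that("a cycle missing a channel is rejected", {
  sim <- small_run()
  pts <- sim$run$points
  cyc <- sim$run$cycles
  cyc <- cyc[!(cyc$cycle == 5 & cyc$channel == 30), ]
  expect_error(aif_run(pts, cycles = cyc), "all channels")
})

test_that("non-monotone scan times are rejected", {
  sim <- small_run()
  cyc <- sim$run$cycles
  cyc$time_min[2] <- cyc$time_min[1]
  expect_error(aif_run(sim$run$points, cycles = cyc), "strictly increasing")
})
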