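# Synthetic AIF data generator: dilution design, determinism, manifest
# fidelity, campaign structure, query scenario, spec-file round trip.

test_that("dilution series reproduces the published design arithmetic", {
  d <- make_dilution_series()
  expect_equal(nrow(d), 7)
  expect_equal(d$concentration_um[1], 4.0)
  expect_equal(signif(d$concentration_um[7], 1), 0.001)
  expect_equal(d$amount_fmol[1], 8000)  # 2 uL at 4.0 uM
  d1 <- make_dilution_series(volume_ul = 1)
  expect_equal(round(d1$amount_fmol[7]), 1)  # ~1 fmol at the bottom
  expect_error(make_dilution_series(level_count = 1), "level_count")
})

test_that("the same seed reproduces a run exactly", {
  cmp <- example_compounds()[1:2, ]
  cmp$rt <- c(1.4, 2.1)
  a <- simulate_run(cmp, c(100, 50), seed = 77, gradient_min = 3)
  b <- simulate_run(cmp, c(100, 50), seed = 77, gradient_min = 3)
  expect_identical(a$run$points, b$run$points)
  expect_identical(a$manifest, b$manifest)
  c2 <- simulate_run(cmp, c(100, 50), seed = 78, gradient_min = 3)
  expect_false(identical(a$run$points, c2$run$points))
})

test_that("zero compounds still yields noise plus the contaminant", {
  sim <- simulate_run(example_compounds()[0, ], numeric(0), seed = 5,
                      gradient_min = 2)
  expect_equal(nrow(sim$manifest), 0)
  expect_gt(nrow(sim$run$points), 0)
  cont <- sim$run$points[abs(sim$run$points$mz - 149.0233) < 0.01, ]
  expect_gt(nrow(cont), 0.9 * nrow(sim$run$cycles))  # in essentially every scan
})

test_that("manifest matches the emitted scan data", {
  sim <- small_run(amount = 200, seed = 88)
  man <- sim$manifest
  run <- sim$run
  for (i in seq_len(nrow(man))) {
    eic <- extract_eic(run, man$channel[i], man$mz[i], tol = 0.011)
    apex_i <- which.max(eic$intensity)
    expect_lt(abs(eic$time_min[apex_i] - man$rt[i]), 0.03)
    expect_lt(abs(max(eic$intensity) - man$apex_height[i]) / man$apex_height[i],
              0.15)
  }
})

test_that("drifted retention times outside the gradient are an error", {
  cmp <- example_compounds()[1, ]  # rt 7.46
  expect_error(simulate_run(cmp, 100, seed = 1, gradient_min = 3),
               "outside the gradient")
})

test_that("campaign structure: 7 dilutions + blank, tIS everywhere", {
  cmp <- example_compounds()[2, ]
  tis <- example_tis()
  camp <- simulate_characterization_campaign(cmp, tis, seed = 3)
  ser <- camp$series[[cmp$name]]
  expect_length(ser$runs, 8)
  expect_equal(ser$amounts[1:7], make_dilution_series()$amount_fmol)
  expect_equal(ser$amounts[8], 0)
  for (ri in c(1, 5, 8)) {
    man <- ser$manifests[[ri]]
    expect_setequal(intersect(man$compound, tis$name), tis$name)
  }
  # blank has no analyte
  expect_false(cmp$name %in% ser$manifests[[8]]$compound)
})

test_that("coelution suppression halves the affected tIS height", {
  cmp <- example_compounds()[1, ]   # rt 7.46
  tis <- example_tis()              # tis-C at 7.50 coelutes
  camp_on <- simulate_characterization_campaign(
    cmp, tis, seed = 4, suppression = TRUE, suppression_window = 0.3,
    dilution = make_dilution_series(level_count = 2))
  camp_off <- simulate_characterization_campaign(
    cmp, tis, seed = 4, suppression = FALSE,
    dilution = make_dilution_series(level_count = 2))
  h <- function(camp, run_i, who) {
    man <- camp$series[[cmp$name]]$manifests[[run_i]]
    max(man$apex_height[man$compound == who & man$channel == 0])
  }
  expect_equal(h(camp_on, 1, "tis-C") / h(camp_off, 1, "tis-C"), 0.5,
               tolerance = 1e-6)
  # non-coeluting tIS untouched; blank (no analyte) untouched
  expect_equal(h(camp_on, 1, "tis-A"), h(camp_off, 1, "tis-A"))
  expect_equal(h(camp_on, 3, "tis-C"), h(camp_off, 3, "tis-C"))
})

test_that("query scenario: three same-m/z features, disjoint decoy fragments", {
  q <- simulate_query_dataset(example_compounds()[1, ], example_decoys(),
                              tis = example_tis(), seed = 6)
  expect_equal(nrow(q$truth), 3)
  expect_equal(length(unique(round(q$truth$mz, 3))), 1)
  expect_equal(sum(q$truth$is_true), 1)
  # decoy fragment m/z sets are disjoint from the true compound's
  man <- q$manifest
  true_frags <- man$mz[man$compound == "trigonelline-like" &
                         man$kind == "fragment"]
  for (d in c("decoy-early", "decoy-late")) {
    decoy_frags <- man$mz[man$compound == d & man$kind == "fragment"]
    expect_equal(length(intersect(round(true_frags, 2), round(decoy_frags, 2))),
                 0)
  }
  q2 <- simulate_query_dataset(example_compounds()[1, ], example_decoys(),
                               tis = example_tis(), seed = 6)
  expect_identical(q$run$points, q2$run$points)
})

test_that("compound spec files round-trip through YAML", {
  cmps <- dplyr::bind_rows(example_compounds(), example_decoys())
  path <- withr::local_tempfile(fileext = ".yaml")
  write_compound_specs(cmps, path)
  back <- read_compound_specs(path)
  expect_equal(back$name, cmps$name)
  expect_equal(back$formula, cmps$formula)
  expect_equal(back$rt, cmps$rt)
  expect_equal(back$ion_mz, cmps$ion_mz)
  expect_equal(back$adducts, cmps$adducts)
  for (i in seq_len(nrow(cmps))) {
    expect_equal(names(back$fragments[[i]]), names(cmps$fragments[[i]]))
    for (ch in names(cmps$fragments[[i]])) {
      expect_equal(back$fragments[[i]][[ch]]$rel_intensity,
                   cmps$fragments[[i]][[ch]]$rel_intensity)
    }
  }
})

test_that("fragment intensities outside (0, 100] are rejected", {
  expect_error(synthetic_compound(
    "bad", "C5H5N5", rt = 1,
    fragments = list("30" = data.frame(formula = NA, mz = 50,
                                       rel_intensity = 120))),
    "relative intensities")
})
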