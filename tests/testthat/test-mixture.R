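test_that("the mixture model is a pure weighted sum of pure spectra", {
  lib <- singlet_library(test_axis(1024), n = 3, biofluid = "urine")
  spec <- mixture_spec(mode = "1d", noise_sd = 0)

  one <- simulate_mixture_1d(lib, c(sing01 = 1), spec)
  expect_identical(one$grid$intensity,
                   lib$records[["sing01"]]$spectrum_1d$intensity)

  two <- simulate_mixture_1d(lib, c(sing01 = 2), spec)
  expect_equal(two$grid$intensity, 2 * one$grid$intensity,
               tolerance = 1e-15)

  a <- simulate_mixture_1d(lib, c(sing01 = 3, sing02 = 0), spec)
  b <- simulate_mixture_1d(lib, c(sing01 = 0, sing02 = 5), spec)
  ab <- simulate_mixture_1d(lib, c(sing01 = 3, sing02 = 5), spec)
  expect_equal(ab$grid$intensity, a$grid$intensity + b$grid$intensity,
               tolerance = 1e-12)

  expect_error(simulate_mixture_1d(lib, c(ghost = 1), spec),
               "not in library")
  expect_error(simulate_mixture_1d(lib, c(sing01 = -1), spec), ">= 0")
})

test_that("scaling all concentrations scales the clean spectrum", {
  lib <- singlet_library(test_axis(1024), n = 3, biofluid = "urine")
  spec <- mixture_spec(mode = "1d")
  conc <- c(sing01 = 10, sing02 = 20, sing03 = 5)
  base <- simulate_mixture_1d(lib, conc, spec)
  scaled <- simulate_mixture_1d(lib, 3 * conc, spec)
  expect_equal(scaled$grid$intensity, 3 * base$grid$intensity,
               tolerance = 1e-12)
})

test_that("protein background adds pointwise with its own scale", {
  lib <- singlet_library(test_axis(1024), n = 2)  # blood library
  bg <- lib$protein_background
  g <- simulate_mixture_1d(lib, c(sing01 = 1),
                           mixture_spec(biofluid = "urine"))$grid
  expect_identical(add_protein_background(g, bg, 0)$intensity, g$intensity)
  zero <- spectrum_grid_1d(g$ppm, numeric(length(g$ppm)))
  expect_identical(add_protein_background(zero, bg, 1)$intensity,
                   bg$intensity)
  out <- add_protein_background(g, bg, 2.5)
  expect_equal(trapz_integral(out),
               trapz_integral(g) + 2.5 * trapz_integral(bg),
               tolerance = 1e-9)
  other <- spectrum_grid_1d(seq(5, 1, length.out = 64), numeric(64))
  expect_error(add_protein_background(other, bg, 1), "match")
})

test_that("additive noise hits its target SD and skips empty grids", {
  axis <- seq(10, 0, length.out = 2e5)
  flat <- spectrum_grid_1d(axis, rep(2, length(axis)))
  noisy <- add_noise(flat, 0.01, seed = 55)
  expect_equal(sd(noisy$intensity - 2), 0.01 * 2, tolerance = 0.01)
  expect_identical(add_noise(flat, 0, seed = 55)$intensity,
                   flat$intensity)
  zero <- spectrum_grid_1d(axis, numeric(length(axis)))
  expect_identical(add_noise(zero, 0.01, seed = 55)$intensity,
                   zero$intensity)
  expect_identical(add_noise(flat, 0.01, seed = 9)$intensity,
                   add_noise(flat, 0.01, seed = 9)$intensity)
})

test_that("2D mixtures are additive and keep COSY symmetry", {
  lib <- make_toy_library(3, seed = 21, axis = test_axis(512),
                          with_2d = TRUE, f2_points = 128, f1_points = 24)
  ids <- library_ids(lib)
  spec <- mixture_spec(mode = "jres")

  single <- stats::setNames(c(1, 0, 0), ids)
  s1 <- simulate_mixture_2d(lib, single, spec)
  rec <- lib$records[[ids[1]]]
  expect_equal(sum(s1$grid$intensity) /
                 sum(rec$spectrum_jres$intensity), 1, tolerance = 1e-9)

  both <- stats::setNames(c(2, 3, 0), ids)
  sa <- simulate_mixture_2d(lib, stats::setNames(c(2, 0, 0), ids), spec)
  sb <- simulate_mixture_2d(lib, stats::setNames(c(0, 3, 0), ids), spec)
  sab <- simulate_mixture_2d(lib, both, spec)
  expect_equal(sab$grid$intensity, sa$grid$intensity + sb$grid$intensity,
               tolerance = 1e-12)

  cosy <- mixture_spec(mode = "cosy")
  sc <- simulate_mixture_2d(lib, both, cosy)
  expect_lt(max(abs(sc$grid$intensity - t(sc$grid$intensity))), 1e-9)

  lib$records[[ids[2]]]$spectrum_jres <- NULL
  expect_error(simulate_mixture_2d(lib, both, spec), "lacking jres")
})

test_that("cohorts are deterministic with faithful labels", {
  lib <- singlet_library(test_axis(1024), n = 4)
  st <- list(normal = lapply(lib$records[1:4], function(r)
    record_stats(r, "normal", "blood")))
  names(st$normal) <- library_ids(lib)[1:4]
  design <- discrete_design(c(normal = 4, abnormal = 4), st,
                            fold_change = list(abnormal = list(sing02 = 2)),
                            seed = 77)
  spec <- mixture_spec(biofluid = "blood", mode = "1d", noise_sd = 0.005)

  c1 <- simulate_cohort(lib, design, spec)
  c2 <- simulate_cohort(lib, design, spec)
  expect_identical(cohort_matrix(c1), cohort_matrix(c2))
  expect_identical(c1$table$concentrations, c2$table$concentrations)

  for (i in seq_along(c1$spectra))
    expect_identical(c1$spectra[[i]]$provenance$concentrations,
                     stats::setNames(c1$table$concentrations[i, ],
                                     colnames(c1$table$concentrations)))
})

test_that("blood baseline grows monotonically with protein scale", {
  lib <- singlet_library(test_axis(1024), n = 3)
  conc <- c(sing01 = 100, sing02 = 100, sing03 = 100)
  ints <- vapply(c(0, 0.5, 1, 2), function(sc) {
    g <- simulate_mixture_1d(lib, conc,
                             mixture_spec(biofluid = "blood",
                                          protein_scale = sc))$grid
    trapz_integral(g, window = c(0.5, 3))
  }, 0)
  expect_true(all(diff(ints) > 0))
})

test_that("per-replicate pH draws shift peaks in cohort simulation", {
  axis <- test_axis(2048)
  spec1 <- toy_metabolite_spec(
    "shifty",
    multiplets = list(multiplet_spec(3.0, "s", linewidth_hz = 6,
                                     protons_weight = 1)),
    protons = 1, pka = 7.0, shift_limits = list(c(3.2, 2.8)),
    stats = list(condition_stats(100, 0, "normal", "urine")))
  lib <- build_library_from_specs(list(spec1), axis = axis)
  st <- list(normal = list(shifty = condition_stats(100, 0)))
  design <- discrete_design(c(normal = 6), st, seed = 5)
  spec <- mixture_spec(mode = "1d", shift_enabled = TRUE,
                       ph_mean = 6.0, ph_sd = 0.3)
  cohort <- simulate_cohort(lib, design, spec)
  apexes <- vapply(cohort$spectra, function(s)
    s$grid$ppm[which.max(s$grid$intensity)], 0)
  phs <- vapply(cohort$spectra, function(s) s$provenance$ph, 0)
  expect_identical(length(unique(phs)), 6L)
  # at pH 6 (below pKa 7) peaks sit toward the acid limit: above 3.0 ppm
  expect_true(all(apexes > 3.0))
  # lower pH -> larger shift toward delta_L
  expect_gt(cor(apexes, -phs), 0.9)
})
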