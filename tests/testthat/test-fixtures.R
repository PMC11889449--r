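test_that("multiplets carry the stated area and line geometry", {
  axis <- seq(4.0, 2.0, length.out = 20001)  # 1e-4 ppm spacing

  s <- make_multiplet(multiplet_spec(3.0, "s", protons_weight = 3), axis)
  expect_equal(trapz_integral(s), 3, tolerance = 1e-3)
  expect_equal(axis[which.max(s$intensity)], 3.0, tolerance = 2e-4)

  # doublet apexes J/field apart
  d <- make_multiplet(multiplet_spec(3.0, "d", j_hz = 7), axis,
                      field_mhz = 600)
  pk <- detect_peaks_1d(d, 0.5, 0.1)
  apex_ppm <- axis[unlist(pk$apexes)]
  expect_length(apex_ppm, 2)
  expect_lt(abs(abs(diff(apex_ppm)) - 7 / 600), 2e-4)  # grid quantization

  # triplet: central line area ~ 2x an outer line (lines well separated)
  tr <- make_multiplet(multiplet_spec(3.0, "t", j_hz = 18,
                                      linewidth_hz = 1, protons_weight = 4),
                       axis, field_mhz = 600)
  half_gap <- 18 / 600 / 2
  centre <- trapz_integral(tr, window = 3.0 + c(-half_gap, half_gap))
  outer <- trapz_integral(tr, window = 3.0 + 18 / 600 + c(-half_gap, half_gap))
  expect_equal(centre / outer, 2, tolerance = 0.05)
})

test_that("multiplets beyond the axis warn and truncate", {
  axis <- seq(4, 3, length.out = 501)
  expect_warning(make_multiplet(multiplet_spec(5.0, "s"), axis),
                 "beyond the axis")
})

test_that("J-Res fixtures place multiplet lines on F1 at the J offsets", {
  f2 <- seq(9.9, 0.1, length.out = 512)
  f1 <- seq(30, -30, length.out = 121)  # 0.5 Hz spacing
  spec <- toy_metabolite_spec(
    "m", multiplets = list(multiplet_spec(3.0, "s", protons_weight = 2)),
    protons = 2)
  g <- make_pure_jres(spec, f2, f1)
  ij <- which(g$intensity == max(g$intensity), arr.ind = TRUE)
  expect_equal(f1[ij[1]], 0, tolerance = 0.5)
  expect_equal(f2[ij[2]], 3.0, tolerance = 0.02)

  dbl <- toy_metabolite_spec(
    "d", multiplets = list(multiplet_spec(6.0, "d", j_hz = 7,
                                          protons_weight = 1)),
    protons = 1)
  gd <- make_pure_jres(dbl, f2, f1)
  col <- which.min(abs(f2 - 6.0))
  prof <- gd$intensity[, col]
  top2 <- sort(f1[order(prof, decreasing = TRUE)[1:2]])
  expect_equal(top2, c(-3.5, 3.5), tolerance = 0.5)

  # skyline projection collapses the multiplet to its center
  sky <- skyline_projection(gd)
  expect_equal(sky$ppm[which.max(sky$intensity)], 6.0, tolerance = 0.02)
  expect_error(make_pure_jres(dbl, f2, seq(10, -10, length.out = 41)),
               "25 Hz")
})

test_that("COSY fixtures are symmetric with diagonal and cross peaks", {
  axis <- seq(9.9, 0.1, length.out = 256)
  spec <- toy_metabolite_spec(
    "m", multiplets = list(
      multiplet_spec(2.0, "d", 7, protons_weight = 1),
      multiplet_spec(7.0, "d", 7, protons_weight = 1)),
    protons = 2)
  g <- make_pure_cosy(spec, axis, coupled_pairs = list(c(1, 2)))
  expect_lt(max(abs(g$intensity - t(g$intensity))), 1e-9)
  i2 <- which.min(abs(axis - 2)); i7 <- which.min(abs(axis - 7))
  expect_gt(g$intensity[i2, i2], 0.5 * max(g$intensity))
  expect_gt(g$intensity[i7, i7], 0.5 * max(g$intensity))
  expect_gt(g$intensity[i2, i7], 0.1 * max(g$intensity))  # cross peak

  solo <- toy_metabolite_spec(
    "s", multiplets = list(multiplet_spec(5.5, "s", protons_weight = 1)),
    protons = 1)
  gs <- make_pure_cosy(solo, axis)
  d <- diagonal_projection(gs)
  expect_equal(d$ppm[which.max(d$intensity)], 5.5, tolerance = 0.05)
  expect_error(make_pure_cosy(spec, axis, list(c(1, 3))),
               "missing multiplet")
})

test_that("protein background is a broad envelope with the stated area", {
  axis <- test_axis(4096)
  bg <- make_protein_background(axis, total_area = 100)
  expect_equal(trapz_integral(bg), 100, tolerance = 1e-3)
  expect_true(all(bg$intensity >= 0))
  # FWHM of the envelope around the 1.3 ppm component is >= 0.3 ppm
  i0 <- which.min(abs(axis - 1.3))
  half <- bg$intensity[i0] / 2
  above <- axis[bg$intensity >= half & abs(axis - 1.3) < 1.5]
  expect_gte(max(above) - min(above), 0.3)
  expect_error(make_protein_background(axis, total_area = 0), "> 0")
})

test_that("toy libraries are deterministic, seed-sensitive and valid", {
  axis <- test_axis(1024)
  a <- make_toy_library(5, seed = 42, axis = axis)
  b <- make_toy_library(5, seed = 42, axis = axis)
  expect_identical(
    lapply(a$records, function(r) r$spectrum_1d$intensity),
    lapply(b$records, function(r) r$spectrum_1d$intensity))

  c2 <- make_toy_library(5, seed = 2, axis = axis)
  expect_false(isTRUE(all.equal(
    a$records[["met01"]]$spectrum_1d$intensity,
    c2$records[["met01"]]$spectrum_1d$intensity)))

  one <- make_toy_library(1, seed = 9, axis = axis)
  expect_s3_class(one, "nmr_library")

  for (r in a$records) {
    expect_equal(trapz_integral(r$spectrum_1d), r$protons,
                 tolerance = 1e-3)
    expect_true(all(r$spectrum_1d$intensity >= 0))
    expect_length(record_stats(r, "heart transplant", "urine")$mean, 1)
  }
  # at least half the records exercise the pH-shift path
  n_shift <- sum(vapply(a$records, function(r)
    is.finite(r$pka) && !is.null(r$shift_limits), TRUE))
  expect_gte(n_shift, length(a$records) / 2)

  blood <- make_toy_library(3, seed = 1, axis = axis, biofluid = "blood")
  expect_s3_class(blood$protein_background, "grid1d")
})

test_that("J-Res fixtures keep the 1D intensity budget", {
  lib <- make_toy_library(4, seed = 11, axis = test_axis(1024),
                          with_2d = TRUE, f2_points = 256, f1_points = 48)
  for (r in lib$records) {
    prof <- spectrum_grid_1d(r$spectrum_jres$f2,
                             colSums(r$spectrum_jres$intensity))
    expect_equal(trapz_integral(prof), trapz_integral(r$spectrum_1d),
                 tolerance = 0.02)
  }
})
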