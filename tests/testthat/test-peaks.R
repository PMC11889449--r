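toy_grid <- function(v) spectrum_grid_1d(seq(length(v), 1), v)

test_that("two-threshold run detection matches the hand-worked case", {
  v <- c(0, 1, 5, 1, 0, 0, 2, 2, 0)
  pk <- detect_peaks_1d(toy_grid(v), main_threshold_frac = 0.6,
                        cluster_threshold_frac = 0.15)
  # one kept cluster spanning indices 2..4 with the apex on the 5;
  # the 2,2 run has no point >= 3 and is filtered out
  expect_identical(nrow(pk$clusters), 1L)
  expect_identical(c(pk$clusters$start, pk$clusters$end), c(2L, 4L))
  expect_identical(pk$apexes[[1]], 3L)
})

test_that("a lone Lorentzian yields one cluster with the apex at center", {
  axis <- seq(4, 2, length.out = 2001)
  g <- make_multiplet(multiplet_spec(3.0, "s", protons_weight = 1), axis)
  pk <- detect_peaks_1d(g, 0.5, 0.01)
  expect_identical(nrow(pk$clusters), 1L)
  expect_equal(axis[pk$apexes[[1]]], 3.0, tolerance = 2e-3)

  none <- detect_peaks_1d(toy_grid(rep(0, 16)), 0.5, 0.1)
  expect_identical(nrow(none$clusters), 0L)
})

test_that("detection agrees with a brute-force oracle on random vectors", {
  set.seed(606)
  for (i in 1:200) {
    len <- sample(5:200, 1)
    v <- round(runif(len, 0, 10))
    cfrac <- runif(1, 0.05, 0.3)
    mfrac <- runif(1, cfrac, 1)
    got <- detect_peaks_1d(toy_grid(v), mfrac, cfrac)
    want <- oracle_detect(v, mfrac, cfrac)
    expect_identical(got$clusters$start, want$starts)
    expect_identical(got$clusters$end, want$ends)
    expect_identical(got$apexes, want$apexes)
  }
})

test_that("projections match their brute-force definitions", {
  m <- matrix(c(1, 0, 0, 2), 2, byrow = TRUE)
  g <- spectrum_grid_2d(c(2, 1), c(2, 1), m, mode = "jres")
  expect_equal(skyline_projection(g)$intensity, c(1, 2))

  set.seed(88)
  M <- matrix(runif(30 * 40), 30)
  gj <- spectrum_grid_2d(seq(30, 1), seq(40, 1), M, mode = "jres")
  expect_equal(skyline_projection(gj)$intensity,
               vapply(1:40, function(j) max(M[, j]), 0))

  S <- matrix(runif(25^2), 25); S <- (S + t(S)) / 2
  gc <- spectrum_grid_2d(seq(25, 1), seq(25, 1), S, mode = "cosy")
  expect_equal(diagonal_projection(gc)$intensity,
               vapply(1:25, function(j) S[j, j], 0))
  diag(S) <- 0
  gz <- spectrum_grid_2d(seq(25, 1), seq(25, 1), S, mode = "cosy")
  expect_equal(diagonal_projection(gz)$intensity, rep(0, 25))

  expect_error(diagonal_projection(gj), "COSY")
  expect_error(skyline_projection(gc), "J-Res")
  rect <- spectrum_grid_2d(c(2, 1), c(3, 2, 1), matrix(0, 2, 3), "cosy")
  expect_error(diagonal_projection(rect), "square")
})

test_that("the pH shift formula matches direct evaluation and its limits", {
  expect_identical(compute_delta_shift(3.0, 2.8, 7.0, ph1 = 7.4), 0)
  expect_equal(compute_delta_shift(3.00, 2.80, 7.0, ph1 = 6.5, ph0 = 7.4),
               naive_delta_shift(3.00, 2.80, 7.0, 6.5), tolerance = 1e-12)
  expect_equal(compute_delta_shift(3.00, 2.80, 7.0, ph1 = 6.5, ph0 = 7.4),
               0.0950, tolerance = 1e-4)
  # full acid -> base traversal approaches -(delta_L - delta_HL)
  expect_equal(compute_delta_shift(0.2, 0, 7, ph1 = 12, ph0 = 2), -0.2,
               tolerance = 1e-4)
  # overflow-safe at extreme pH - pKa
  expect_true(is.finite(compute_delta_shift(1, 0, 0, ph1 = 400,
                                            ph0 = -400)))
})

test_that("the pH shift is bounded, antisymmetric and monotone", {
  set.seed(99)
  for (i in 1:200) {
    dl <- runif(1, 0, 5); dhl <- runif(1, 0, 5)
    pka <- runif(1, 0, 14)
    ph0 <- runif(1, 0, 14); ph1 <- runif(1, 0, 14)
    dd <- compute_delta_shift(dl, dhl, pka, ph1 = ph1, ph0 = ph0)
    expect_lte(abs(dd), abs(dl - dhl) + 1e-12)
    expect_equal(dd, -compute_delta_shift(dl, dhl, pka, ph1 = ph0,
                                          ph0 = ph1), tolerance = 1e-12)
  }
  ph_grid <- seq(2, 12, by = 0.25)
  dd <- compute_delta_shift(3.0, 2.8, 6.5, ph1 = ph_grid, ph0 = 7.4)
  expect_true(all(diff(dd) < 0))  # strictly decreasing when delta_L > delta_HL
})

test_that("pKa imputation is clamped, seeded and calibrated", {
  expect_equal(sample_pka(6.8, 0), 6.8)
  expect_equal(sample_pka(15, 0), 14)  # clamped to the physical range
  draws <- sample_pka(7, 1, 1e4, seed = 12)
  expect_equal(mean(draws), 7, tolerance = 0.05 / 7)
  expect_identical(sample_pka(7, 1, 5, seed = 3), sample_pka(7, 1, 5, seed = 3))
  expect_error(sample_pka(NA, 1), "configured")
})

test_that("1D cluster shifting moves segments and conserves area", {
  axis <- seq(10, 0.01, length.out = 1000)
  sp <- axis_spacing(axis)
  g <- make_multiplet(multiplet_spec(5, "s", linewidth_hz = 30,
                                     protons_weight = 1), axis)
  pk <- detect_peaks_1d(g, 0.5, 0.01)
  expect_identical(nrow(pk$clusters), 1L)

  same <- apply_shift_1d(g, pk, 0)
  expect_identical(same$intensity, g$intensity)

  shifted <- apply_shift_1d(g, pk, 10 * sp)
  expect_identical(which.max(shifted$intensity),
                   which.max(g$intensity) - 10L)
  expect_equal(trapz_integral(shifted), trapz_integral(g),
               tolerance = 1e-9)

  expect_error(apply_shift_1d(g, pk, 20), "off the grid")
  expect_error(apply_shift_1d(g, pk, c(0, 0)), "one shift per cluster")
})

test_that("colliding shifted clusters error unless superposition is asked", {
  v <- c(0, 4, 0, 0, 0, 4, 0, 0, 0, 0)
  g <- toy_grid(v)
  pk <- detect_peaks_1d(g, 0.5, 0.1)
  expect_identical(nrow(pk$clusters), 2L)
  sp <- axis_spacing(g$ppm)
  # move the second peak onto the first
  expect_error(apply_shift_1d(g, pk, c(0, 4 * sp)), "collides")
  summed <- apply_shift_1d(g, pk, c(0, 4 * sp), collision = "sum")
  expect_equal(summed$intensity[2], 8)
  expect_equal(sum(summed$intensity), sum(v))
})

test_that("J-Res shifting commutes with the skyline projection", {
  f2 <- seq(9.9, 0.1, length.out = 512)
  f1 <- seq(30, -30, length.out = 41)
  spec <- toy_metabolite_spec(
    "m", multiplets = list(multiplet_spec(6.0, "d", j_hz = 7,
                                          protons_weight = 2)),
    protons = 2)
  g <- make_pure_jres(spec, f2, f1)
  proj <- skyline_projection(g)
  pk <- detect_peaks_1d(proj, 0.5, 0.01)
  shift <- 5 * axis_spacing(f2)

  g2 <- apply_shift_2d(g, pk, shift)
  expect_identical(skyline_projection(g2)$intensity,
                   apply_shift_1d(proj, pk, shift)$intensity)

  # F1 (J) structure untouched: row profile through the apex column
  col_old <- which.max(proj$intensity)
  expect_identical(g2$intensity[, col_old - 5L], g$intensity[, col_old])
  expect_equal(trapz_integral(skyline_projection(g2)),
               trapz_integral(proj), tolerance = 1e-9)
})

test_that("COSY diagonal shifting preserves symmetry", {
  axis <- seq(9.9, 0.1, length.out = 256)
  spec <- toy_metabolite_spec(
    "m", multiplets = list(
      multiplet_spec(2.0, "s", protons_weight = 1),
      multiplet_spec(7.0, "s", protons_weight = 1)),
    protons = 2)
  g <- make_pure_cosy(spec, axis, coupled_pairs = list(c(1, 2)))
  proj <- diagonal_projection(g)
  pk <- detect_peaks_1d(proj, 0.5, 0.05)
  expect_gte(nrow(pk$clusters), 2L)
  shifts <- rep(3 * axis_spacing(axis), nrow(pk$clusters))
  g2 <- apply_shift_2d(g, pk, shifts)
  expect_lt(max(abs(g2$intensity - t(g2$intensity))), 1e-9)
  expect_equal(sum(g2$intensity), sum(g$intensity), tolerance = 1e-9)

  same <- apply_shift_2d(g, pk, rep(0, nrow(pk$clusters)))
  expect_identical(same$intensity, g$intensity)
})
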