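# Synthetic pure-compound fixtures: Lorentzian multiplets (Pascal-ratio
# line intensities), separable 2D J-Res / COSY peaks, an albumin-like
# protein envelope, and a deterministic toy library generator. These
# stand in for experimental pure-compound spectra so the whole pipeline
# is buildable and testable with no external data.

PATTERNS <- list(
  s = list(offsets = 0,                    weights = 1),
  d = list(offsets = c(-0.5, 0.5),         weights = c(1, 1)),
  t = list(offsets = c(-1, 0, 1),          weights = c(1, 2, 1)),
  q = list(offsets = c(-1.5, -0.5, 0.5, 1.5), weights = c(1, 3, 3, 1)))

# Unit-area Lorentzian; hwhm = half width at half maximum.
lorentzian <- function(x, x0, hwhm) {
  (hwhm / pi) / (hwhm^2 + (x - x0)^2)
}

#' Multiplet specification
#'
#' @param center chemical shift of the multiplet center (ppm)
#' @param pattern `"s"`, `"d"`, `"t"` or `"q"` (singlet/doublet/triplet/
#'   quartet; line intensities follow Pascal ratios)
#' @param j_hz scalar coupling constant in Hz (0 for a singlet)
#' @param linewidth_hz full width at half maximum in Hz
#' @param protons_weight area of the whole multiplet in proton units
#' @return object of class `multiplet_spec`
#' @export
multiplet_spec <- function(center, pattern = "s", j_hz = 0,
                           linewidth_hz = 1.5, protons_weight = 1) {
  pattern <- match.arg(pattern, names(PATTERNS))
  stopifnot(is.finite(center), j_hz >= 0, linewidth_hz > 0,
            protons_weight > 0)
  structure(list(center = center, pattern = pattern, j_hz = j_hz,
                 linewidth_hz = linewidth_hz,
                 protons_weight = protons_weight),
            class = "multiplet_spec")
}

#' Render one multiplet as a 1D spectrum
#'
#' Sum of Lorentzian lines at `center` plus the pattern's offsets
#' (d: +/- J/2; t: -J, 0, +J; q: -3J/2 ... +3J/2, converted from Hz to
#' ppm at `field_mhz`), with Pascal-ratio amplitudes and a total area of
#' `protons_weight`. Lines are rendered no narrower than one grid step so
#' coarse working grids keep the area budget.
#'
#' @param spec a [multiplet_spec()]
#' @param axis uniform ppm axis
#' @param field_mhz spectrometer 1H frequency (1 Hz = 1/field ppm)
#' @return `grid1d`
#' @export
make_multiplet <- function(spec, axis, field_mhz = 600) {
  stopifnot(field_mhz > 0)
  pat <- PATTERNS[[spec$pattern]]
  centers <- spec$center + pat$offsets * spec$j_hz / field_mhz
  hwhm <- max(spec$linewidth_hz / 2 / field_mhz, axis_spacing(axis))
  if (any(centers < min(axis)) || any(centers > max(axis)))
    warning("multiplet at ", spec$center,
            " ppm extends beyond the axis; lines truncated")
  areas <- spec$protons_weight * pat$weights / sum(pat$weights)
  y <- numeric(length(axis))
  for (i in seq_along(centers))
    y <- y + areas[i] * lorentzian(axis, centers[i], hwhm)
  spectrum_grid_1d(axis, y)
}

#' Toy metabolite specification
#'
#' @param id,name identifier and display name
#' @param multiplets list of [multiplet_spec()]; their `protons_weight`
#'   values must sum to `protons`
#' @param protons observable proton count
#' @param pka optional acid dissociation constant
#' @param shift_limits optional per-multiplet `c(delta_L, delta_HL)` pairs
#' @param stats list of [condition_stats()]
#' @return object of class `toy_metabolite_spec`
#' @export
toy_metabolite_spec <- function(id, name = id, multiplets, protons,
                                pka = NA_real_, shift_limits = NULL,
                                stats = list()) {
  if (length(multiplets) == 0) stop("at least one multiplet required")
  w <- sum(vapply(multiplets, `[[`, 0, "protons_weight"))
  if (abs(w - protons) > 1e-9)
    stop("multiplet protons_weight sum (", w, ") != protons (", protons, ")")
  structure(list(id = id, name = name, multiplets = multiplets,
                 protons = protons, pka = pka, shift_limits = shift_limits,
                 stats = stats),
            class = "toy_metabolite_spec")
}

make_pure_1d <- function(spec, axis, field_mhz = 600) {
  y <- numeric(length(axis))
  for (m in spec$multiplets)
    y <- y + make_multiplet(m, axis, field_mhz)$intensity
  spectrum_grid_1d(axis, y)
}

# Total intensity budget of a 2D grid, measured as the trapezoidal F2
# integral of the F1 column sums. Used to keep 2D fixtures on the same
# proton-area scale as the 1D records.
grid2d_total <- function(g2) {
  trapz_integral(spectrum_grid_1d(g2$f2, colSums(g2$intensity)))
}

# Separable Lorentzian x Lorentzian bump added in place.
add_peak_2d <- function(mat, f1, f2, p1, p2, hw1, hw2, area) {
  mat + area * outer(lorentzian(f1, p1, hw1), lorentzian(f2, p2, hw2))
}

#' Synthetic 2D J-resolved grid for one metabolite
#'
#' Each multiplet line becomes a separable 2D Lorentzian at
#' (F1 = line offset in Hz, F2 = multiplet center in ppm), following the
#' tilted J-Res convention: multiplet structure lives on F1, chemical
#' shift on F2, so a skyline projection along F2 collapses each multiplet
#' to a single peak at its center. The grid is scaled so its total
#' intensity budget equals the proton count, matching the normalized 1D
#' record.
#'
#' @param spec a [toy_metabolite_spec()]
#' @param f2_axis ppm axis; should span the multiplet centers
#' @param f1_axis_hz Hz axis; must span at least +/- 25 Hz
#' @param field_mhz spectrometer frequency
#' @return `grid2d` with `mode = "jres"`
#' @export
make_pure_jres <- function(spec, f2_axis, f1_axis_hz, field_mhz = 600) {
  if (max(f1_axis_hz) < 25 || min(f1_axis_hz) > -25)
    stop("J-Res F1 axis must span at least +/- 25 Hz")
  hw1 <- numeric(0)
  mat <- matrix(0, length(f1_axis_hz), length(f2_axis))
  for (m in spec$multiplets) {
    pat <- PATTERNS[[m$pattern]]
    hw_f1 <- max(m$linewidth_hz / 2, axis_spacing(f1_axis_hz))
    hw_f2 <- max(m$linewidth_hz / 2 / field_mhz, axis_spacing(f2_axis))
    areas <- m$protons_weight * pat$weights / sum(pat$weights)
    for (i in seq_along(pat$offsets)) {
      mat <- add_peak_2d(mat, f1_axis_hz, f2_axis,
                         pat$offsets[i] * m$j_hz, m$center,
                         hw_f1, hw_f2, areas[i])
    }
  }
  g <- spectrum_grid_2d(f1_axis_hz, f2_axis, mat, mode = "jres")
  tot <- grid2d_total(g)
  if (tot > 0) g$intensity <- g$intensity * (spec$protons / tot)
  g
}

#' Synthetic COSY grid for one metabolite
#'
#' Diagonal peaks at (c_i, c_i) for every multiplet center, plus
#' symmetric cross peaks at (c_i, c_j) and (c_j, c_i) for each coupled
#' multiplet pair. The matrix is exactly symmetric by construction, and
#' scaled to the proton-area budget like the J-Res fixture. Cross peaks
#' carry half the geometric-mean weight of their diagonal partners.
#'
#' @param spec a [toy_metabolite_spec()]
#' @param axis shared F1 = F2 ppm axis
#' @param coupled_pairs list of `c(i, j)` multiplet index pairs
#' @param field_mhz spectrometer frequency
#' @return `grid2d` with `mode = "cosy"`
#' @export
make_pure_cosy <- function(spec, axis, coupled_pairs = list(),
                           field_mhz = 600) {
  k <- length(spec$multiplets)
  for (p in coupled_pairs)
    if (length(p) != 2 || any(p < 1) || any(p > k))
      stop("coupled pair (", paste(p, collapse = ","),
           ") references a missing multiplet")
  mat <- matrix(0, length(axis), length(axis))
  hw <- vapply(spec$multiplets, function(m)
    max(m$linewidth_hz / 2 / field_mhz, axis_spacing(axis)), 0)
  ctr <- vapply(spec$multiplets, `[[`, 0, "center")
  w <- vapply(spec$multiplets, `[[`, 0, "protons_weight")
  for (i in seq_len(k))
    mat <- add_peak_2d(mat, axis, axis, ctr[i], ctr[i], hw[i], hw[i], w[i])
  for (p in coupled_pairs) {
    i <- p[1]; j <- p[2]
    xw <- 0.5 * sqrt(w[i] * w[j])
    mat <- add_peak_2d(mat, axis, axis, ctr[i], ctr[j], hw[i], hw[j], xw)
    mat <- add_peak_2d(mat, axis, axis, ctr[j], ctr[i], hw[j], hw[i], xw)
  }
  mat <- (mat + t(mat)) / 2  # guard against floating-point asymmetry
  g <- spectrum_grid_2d(axis, axis, mat, mode = "cosy")
  tot <- grid2d_total(g)
  if (tot > 0) g$intensity <- g$intensity * (spec$protons / tot)
  g
}

#' Albumin-like protein background envelope
#'
#' Smooth non-negative mixture of broad Gaussians emulating the
#' unresolved protein (chiefly albumin) signal underlying blood 1H NMR
#' spectra. Component widths are far broader than metabolite linewidths,
#' so the envelope adds baseline without sharp features.
#'
#' @param axis ppm axis
#' @param total_area integral of the envelope (area units), > 0
#' @param centers,sigmas,weights Gaussian component centers (ppm), SDs
#'   (ppm, each >= 0.1) and relative weights
#' @return `grid1d` with trapezoidal integral `total_area`
#' @export
make_protein_background <- function(axis, total_area = 1,
                                    centers = c(0.9, 1.3, 2.0, 3.0, 7.3),
                                    sigmas = c(0.2, 0.25, 0.3, 0.5, 0.35),
                                    weights = c(1.5, 2, 1.5, 1, 0.6)) {
  if (!is.finite(total_area) || total_area <= 0)
    stop("total_area must be > 0")
  stopifnot(length(centers) == length(sigmas),
            length(centers) == length(weights), all(sigmas >= 0.1))
  y <- numeric(length(axis))
  for (i in seq_along(centers))
    y <- y + weights[i] * stats::dnorm(axis, centers[i], sigmas[i])
  g <- spectrum_grid_1d(axis, y)
  g$intensity <- g$intensity * (total_area / trapz_integral(g))
  g
}

#' Build a library from explicit toy metabolite specifications
#'
#' Renders each spec's 1D spectrum on the common grid, normalizes it to
#' the proton count, optionally attaches J-Res/COSY grids, and (for
#' blood) a protein background envelope.
#'
#' @param specs list of [toy_metabolite_spec()]
#' @param axis common 1D ppm grid
#' @param biofluid biofluid label; `"blood"` adds the protein background
#' @param with_2d attach 2D fixture grids?
#' @param f2_points,f1_points 2D grid sizes (F2 ppm points; F1 Hz points
#'   for J-Res)
#' @param field_mhz spectrometer frequency for Hz to ppm conversion
#' @param background_area integral of the blood protein envelope at
#'   `protein_scale = 1`, in the same area units as the metabolite
#'   signal (1 unit per proton per uM)
#' @return an `nmr_library`
#' @export
build_library_from_specs <- function(specs, axis = default_ppm_axis(),
                                     biofluid = "urine", with_2d = FALSE,
                                     f2_points = 512, f1_points = 64,
                                     field_mhz = 600,
                                     background_area = 5000) {
  f2_axis <- seq(max(axis), min(axis), length.out = f2_points)
  f1_axis <- seq(30, -30, length.out = f1_points)
  records <- lapply(specs, function(sp) {
    raw <- make_pure_1d(sp, axis, field_mhz)
    spec1d <- normalize_pure_spectrum(raw, sp$protons)
    jres <- cosy <- NULL
    if (with_2d) {
      jres <- make_pure_jres(sp, f2_axis, f1_axis, field_mhz)
      nm <- length(sp$multiplets)
      pairs <- if (nm >= 2) lapply(seq_len(nm - 1), function(i) c(i, i + 1))
               else list()
      cosy <- make_pure_cosy(sp, f2_axis, pairs, field_mhz)
    }
    pure_compound_record(sp$id, sp$name, sp$protons, spec1d,
                         pka = sp$pka, shift_limits = sp$shift_limits,
                         spectrum_jres = jres, spectrum_cosy = cosy,
                         stats = sp$stats)
  })
  bg <- if (identical(biofluid, "blood"))
    make_protein_background(axis, total_area = background_area)
  nmr_library(records, protein_background = bg)
}

#' Generate a deterministic toy reference library
#'
#' Draws `n_metabolites` synthetic metabolites: 1-3 multiplets each with
#' centers uniform on 0.8-9.0 ppm avoiding the water window, random
#' s/d/t/q patterns, J in 4-12 Hz, linewidths 1.5-3 Hz. Odd-numbered
#' records (at least half) carry a pKa and per-multiplet shift limits so
#' the pH-shift path is exercised. Every record gets "normal" stats
#' (mean 100-800 uM, SD 10-30% of the mean, so zero-truncation is
#' negligible) plus a "heart transplant" condition derived by a random
#' fold change (0.5-2.5) and SD ratio (0.8-1.5). Blood libraries include
#' the protein background. Fully deterministic given `seed`.
#'
#' @param n_metabolites number of records, >= 1
#' @param seed RNG seed
#' @inheritParams build_library_from_specs
#' @return an `nmr_library`
#' @export
make_toy_library <- function(n_metabolites, seed = 1, biofluid = "urine",
                             axis = default_ppm_axis(), with_2d = FALSE,
                             f2_points = 512, f1_points = 64,
                             field_mhz = 600) {
  stopifnot(n_metabolites >= 1)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  draw_center <- function() {
    repeat {
      c0 <- stats::runif(1, 0.8, 9.0)
      if (c0 < 4.4 || c0 > 5.1) return(c0)  # keep clear of the water window
    }
  }
  specs <- lapply(seq_len(n_metabolites), function(i) {
    id <- sprintf("met%02d", i)
    n_mult <- sample(1:3, 1)
    mults <- list(); weights <- integer(0); centers <- numeric(0)
    for (j in seq_len(n_mult)) {
      w <- sample(1:3, 1)
      centers <- c(centers, draw_center())
      weights <- c(weights, w)
      mults[[j]] <- multiplet_spec(
        center = centers[j],
        pattern = sample(c("s", "d", "t", "q"), 1),
        j_hz = stats::runif(1, 4, 12),
        linewidth_hz = stats::runif(1, 1.5, 3),
        protons_weight = w)
    }
    has_pka <- (i %% 2) == 1
    pka <- if (has_pka) stats::runif(1, 4, 9.5) else NA_real_
    sl <- NULL
    if (has_pka) {
      sl <- lapply(centers, function(c0) {
        d <- stats::runif(1, 0.02, 0.08)
        c(c0 + d, c0 - d)          # acid limit above, basic limit below
      })
    }
    m0 <- stats::runif(1, 100, 800)
    s0 <- m0 * stats::runif(1, 0.1, 0.3)
    fc <- stats::runif(1, 0.5, 2.5)
    sr <- stats::runif(1, 0.8, 1.5)
    toy_metabolite_spec(
      id, name = paste("toy metabolite", i), multiplets = mults,
      protons = sum(weights), pka = pka, shift_limits = sl,
      stats = list(
        condition_stats(m0, s0, "normal", biofluid),
        condition_stats(m0 * fc, s0 * sr, "heart transplant", biofluid)))
  })
  build_library_from_specs(specs, axis = axis, biofluid = biofluid,
                           with_2d = with_2d, f2_points = f2_points,
                           f1_points = f1_points, field_mhz = field_mhz)
}
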