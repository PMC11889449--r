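# Mixture synthesis: the weighted-sum mixture model (concentration x
# proton-normalized pure spectrum, summed over metabolites), optional
# pH-dependent peak shifting, protein background for blood, additive
# noise, and cohort-level orchestration for 1D / J-Res / COSY.

#' Mixture simulation settings
#'
#' @param biofluid `"urine"`, `"blood"` or `"csf"`; blood adds the
#'   library's protein background
#' @param mode `"1d"`, `"jres"` or `"cosy"`
#' @param shift_enabled apply pH-dependent peak shifts?
#' @param ph_mean,ph_sd per-replicate sample pH distribution
#' @param ph0 pH of the standard (reference) spectra, default 7.4
#' @param noise_sd additive Gaussian noise SD as a fraction of the clean
#'   maximum intensity (0 disables)
#' @param protein_scale multiplier on the protein background (blood)
#' @param main_threshold_frac,cluster_threshold_frac peak-detection
#'   thresholds used when shifting (see [detect_peaks_1d()])
#' @param pka_fallback_mean,pka_fallback_sd imputation distribution for
#'   records lacking a pKa (see [sample_pka()])
#' @param collision cluster collision policy for shifting
#' @param seed seed used when a mixture is simulated outside a cohort
#' @return object of class `mixture_spec`
#' @export
mixture_spec <- function(biofluid = "urine", mode = c("1d", "jres", "cosy"),
                         shift_enabled = FALSE, ph_mean = 7.4, ph_sd = 0.1,
                         ph0 = 7.4, noise_sd = 0, protein_scale = 1,
                         main_threshold_frac = 0.2,
                         cluster_threshold_frac = 0.02,
                         pka_fallback_mean = 6.8, pka_fallback_sd = 1.5,
                         collision = "sum", seed = 1) {
  mode <- match.arg(mode)
  biofluid <- match.arg(biofluid, BIOFLUIDS)
  stopifnot(noise_sd >= 0, protein_scale >= 0, ph_sd >= 0)
  structure(list(biofluid = biofluid, mode = mode,
                 shift_enabled = shift_enabled, ph_mean = ph_mean,
                 ph_sd = ph_sd, ph0 = ph0, noise_sd = noise_sd,
                 protein_scale = protein_scale,
                 main_threshold_frac = main_threshold_frac,
                 cluster_threshold_frac = cluster_threshold_frac,
                 pka_fallback_mean = pka_fallback_mean,
                 pka_fallback_sd = pka_fallback_sd,
                 collision = collision, seed = seed),
            class = "mixture_spec")
}

#' Add the protein background to a 1D spectrum
#'
#' `output = input + protein_scale x background`, pointwise on the
#' common grid.
#'
#' @param spec,background `grid1d` objects on the same axis
#' @param protein_scale non-negative multiplier
#' @return `grid1d`
#' @export
add_protein_background <- function(spec, background, protein_scale = 1) {
  stopifnot(protein_scale >= 0)
  if (!grids_equal(spec$ppm, background$ppm))
    stop("background grid does not match the spectrum grid")
  spectrum_grid_1d(spec$ppm, spec$intensity +
                     protein_scale * background$intensity)
}

#' Add white Gaussian noise to a spectrum
#'
#' Noise SD is `noise_sd_frac` times the maximum clean intensity, so the
#' level scales with the signal; an all-zero grid stays noise-free.
#' Works on `grid1d` and `grid2d`.
#'
#' @param grid a `grid1d` or `grid2d`
#' @param noise_sd_frac noise SD as a fraction of max intensity, >= 0
#' @param seed optional seed
#' @return same class as `grid`, with attribute `"noise_sd"` (absolute)
#' @export
add_noise <- function(grid, noise_sd_frac, seed = NULL) {
  stopifnot(noise_sd_frac >= 0)
  if (noise_sd_frac == 0) return(grid)
  M <- max(grid$intensity)
  if (M <= 0) return(grid)
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  sd_abs <- noise_sd_frac * M
  grid$intensity <- grid$intensity +
    stats::rnorm(length(grid$intensity), 0, sd_abs)
  attr(grid, "noise_sd") <- sd_abs
  grid
}

# Resolve the pKa used for one record: curated value when present,
# otherwise a deterministic imputation from the fallback distribution.
resolve_pka <- function(record, spec, seed) {
  if (is.finite(record$pka)) return(record$pka)
  sample_pka(spec$pka_fallback_mean, spec$pka_fallback_sd, 1, seed = seed)
}

# Order shift-limit pairs along the descending ppm axis (highest
# midpoint first) so the k-th pair maps to the k-th detected cluster in
# grid order. Clusters beyond the list stay unshifted.
ordered_limits <- function(shift_limits) {
  mids <- vapply(shift_limits, function(p) mean(p), 0)
  shift_limits[order(-mids)]
}

cluster_shifts <- function(record, clusters, spec, ph1, pka) {
  ncl <- nrow(clusters$clusters)
  shifts <- numeric(ncl)
  if (is.null(record$shift_limits) || ncl == 0) return(shifts)
  lims <- ordered_limits(record$shift_limits)
  for (k in seq_len(min(ncl, length(lims))))
    shifts[k] <- compute_delta_shift(lims[[k]][1], lims[[k]][2], pka,
                                     ph1 = ph1, ph0 = spec$ph0)
  shifts
}

shifted_record_1d <- function(record, spec, ph1, pka) {
  if (is.null(record$shift_limits)) return(record$spectrum_1d)
  clusters <- detect_peaks_1d(record$spectrum_1d,
                              spec$main_threshold_frac,
                              spec$cluster_threshold_frac)
  shifts <- cluster_shifts(record, clusters, spec, ph1, pka)
  apply_shift_1d(record$spectrum_1d, clusters, shifts,
                 collision = spec$collision)
}

validate_concentrations <- function(lib, concentrations) {
  ids <- names(concentrations)
  if (is.null(ids) || !all(nzchar(ids)))
    stop("concentrations must be a named vector of metabolite ids")
  missing <- setdiff(ids, library_ids(lib))
  if (length(missing))
    stop("metabolite(s) not in library: ", paste(missing, collapse = ", "))
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  ids
}

#' Simulate one 1D mixture spectrum
#'
#' The clean signal is the concentration-weighted sum of the normalized
#' pure spectra (proton counts are folded into the normalization, so the
#' sum is a pure weighted combination). With shifting enabled, each
#' metabolite's clusters are relocated by its own pH shift - one
#' realized sample pH shared by all metabolites - before summation.
#' Blood then receives the protein background, and noise is added last.
#'
#' @param lib an `nmr_library`
#' @param concentrations named vector of concentrations c_k (uM)
#' @param spec a [mixture_spec()] with `mode = "1d"`
#' @param ph1 realized sample pH; `NULL` draws one from the spec's pH
#'   distribution
#' @param noise_seed,ph_seed,pka_seed substream seeds; default derived
#'   from `spec$seed`
#' @return object of class `simulated_spectrum`: `grid` plus a
#'   `provenance` list (concentrations, pH, per-metabolite shifts
#'   applied, noise seed, clean intensities when noise was added)
#' @export
simulate_mixture_1d <- function(lib, concentrations, spec = mixture_spec(),
                                ph1 = NULL, noise_seed = NULL,
                                ph_seed = NULL, pka_seed = NULL) {
  ids <- validate_concentrations(lib, concentrations)
  if (is.null(noise_seed)) noise_seed <- substream_seed(spec$seed, "noise")
  shifted <- spec$shift_enabled
  if (shifted && is.null(ph1)) {
    if (is.null(ph_seed)) ph_seed <- substream_seed(spec$seed, "ph")
    restore <- .Random.seed_guard(ph_seed)
    ph1 <- stats::rnorm(1, spec$ph_mean, spec$ph_sd)
    restore()
  }
  if (is.null(pka_seed)) pka_seed <- substream_seed(spec$seed, "pka")
  axis <- lib$common_grid
  y <- numeric(length(axis))
  pkas <- list()
  for (i in seq_along(ids)) {
    rec <- lib$records[[ids[i]]]
    if (shifted && !is.null(rec$shift_limits)) {
      pka <- resolve_pka(rec, spec, substream_seed(pka_seed, "pka", i))
      pkas[[ids[i]]] <- pka
      g <- shifted_record_1d(rec, spec, ph1, pka)
    } else {
      g <- rec$spectrum_1d
    }
    y <- y + concentrations[[i]] * g$intensity
  }
  clean <- spectrum_grid_1d(axis, y)
  if (spec$biofluid == "blood" && spec$protein_scale > 0 &&
      !is.null(lib$protein_background))
    clean <- add_protein_background(clean, lib$protein_background,
                                    spec$protein_scale)
  out <- add_noise(clean, spec$noise_sd, seed = noise_seed)
  structure(list(
    grid = out,
    provenance = list(
      concentrations = concentrations, ph = ph1, ph0 = spec$ph0,
      pka = pkas, mode = "1d", biofluid = spec$biofluid,
      protein_scale = spec$protein_scale, noise_sd = spec$noise_sd,
      noise_seed = noise_seed,
      clean = if (spec$noise_sd > 0) clean$intensity)),
    class = "simulated_spectrum")
}

#' @export
print.simulated_spectrum <- function(x, ...) {
  cat(sprintf("<simulated_spectrum:%s> %d metabolites, %s\n",
              x$provenance$mode, length(x$provenance$concentrations),
              if (is.null(x$provenance$ph)) "no pH shift"
              else sprintf("pH %.2f", x$provenance$ph)))
  invisible(x)
}

# Fetch a record's 2D grid in the requested mode, rescaled so its total
# intensity budget matches the (proton-normalized) 1D integral.
record_grid_2d <- function(record, mode) {
  g <- if (mode == "jres") record$spectrum_jres else record$spectrum_cosy
  if (is.null(g)) return(NULL)
  target <- trapz_integral(record$spectrum_1d)
  tot <- grid2d_total(g)
  if (tot > 0) g$intensity <- g$intensity * (target / tot)
  g
}

#' Simulate one 2D (J-Res or COSY) mixture spectrum
#'
#' Concentration-weighted sum of the per-metabolite 2D grids, each
#' pre-scaled so its total intensity budget matches the metabolite's 1D
#' integral (proton count), keeping 1D and 2D on one scale. Shifting
#' detects clusters on the projected profile (skyline / diagonal) and
#' relocates column blocks (J-Res) or diagonal blocks (COSY).
#'
#' @inheritParams simulate_mixture_1d
#' @param spec a [mixture_spec()] with `mode = "jres"` or `"cosy"`
#' @return `simulated_spectrum` holding a `grid2d`
#' @export
simulate_mixture_2d <- function(lib, concentrations, spec, ph1 = NULL,
                                noise_seed = NULL, ph_seed = NULL,
                                pka_seed = NULL) {
  if (!spec$mode %in% c("jres", "cosy"))
    stop("spec$mode must be 'jres' or 'cosy'")
  ids <- validate_concentrations(lib, concentrations)
  lack <- ids[vapply(ids, function(id)
    is.null(if (spec$mode == "jres") lib$records[[id]]$spectrum_jres
            else lib$records[[id]]$spectrum_cosy), TRUE)]
  if (length(lack))
    stop("metabolite(s) lacking ", spec$mode, " data: ",
         paste(lack, collapse = ", "))
  if (is.null(noise_seed)) noise_seed <- substream_seed(spec$seed, "noise")
  shifted <- spec$shift_enabled
  if (shifted && is.null(ph1)) {
    if (is.null(ph_seed)) ph_seed <- substream_seed(spec$seed, "ph")
    restore <- .Random.seed_guard(ph_seed)
    ph1 <- stats::rnorm(1, spec$ph_mean, spec$ph_sd)
    restore()
  }
  if (is.null(pka_seed)) pka_seed <- substream_seed(spec$seed, "pka")
  acc <- NULL
  pkas <- list()
  for (i in seq_along(ids)) {
    rec <- lib$records[[ids[i]]]
    g <- record_grid_2d(rec, spec$mode)
    if (shifted && !is.null(rec$shift_limits)) {
      proj <- if (spec$mode == "jres") skyline_projection(g)
              else diagonal_projection(g)
      clusters <- detect_peaks_1d(proj, spec$main_threshold_frac,
                                  spec$cluster_threshold_frac)
      pka <- resolve_pka(rec, spec, substream_seed(pka_seed, "pka", i))
      pkas[[ids[i]]] <- pka
      shifts <- cluster_shifts(rec, clusters, spec, ph1, pka)
      g <- apply_shift_2d(g, clusters, shifts, collision = spec$collision)
    }
    acc <- if (is.null(acc)) {
      g$intensity <- g$intensity * concentrations[[i]]
      g
    } else {
      if (!grids_equal(acc$f2, g$f2) || !grids_equal(acc$f1, g$f1))
        stop("record '", ids[i], "' 2D grid does not match the others")
      acc$intensity <- acc$intensity + concentrations[[i]] * g$intensity
      acc
    }
  }
  out <- add_noise(acc, spec$noise_sd, seed = noise_seed)
  structure(list(
    grid = out,
    provenance = list(
      concentrations = concentrations, ph = ph1, ph0 = spec$ph0,
      pka = pkas, mode = spec$mode, biofluid = spec$biofluid,
      protein_scale = spec$protein_scale, noise_sd = spec$noise_sd,
      noise_seed = noise_seed,
      clean = if (spec$noise_sd > 0) acc$intensity)),
    class = "simulated_spectrum")
}

#' Simulate a full cohort of spectra
#'
#' Runs the three-step pipeline: sample concentrations from the study
#' design, draw a per-replicate sample pH (when shifting), and simulate
#' one spectrum per replicate with its own noise substream. The master
#' seed comes from the design; everything downstream is derived from it,
#' so results are fully deterministic.
#'
#' @param lib an `nmr_library`
#' @param design a [discrete_design()] or [continuous_design()]
#' @param spec a [mixture_spec()]
#' @return object of class `cohort_result`: list `spectra` of
#'   `simulated_spectrum` (aligned with the rows of `table`), the
#'   `concentration_table`, the design echo and the master seed
#' @export
simulate_cohort <- function(lib, design, spec = mixture_spec()) {
  tab <- if (inherits(design, "discrete_design")) sample_discrete(design)
         else if (inherits(design, "continuous_design"))
           sample_continuous(design)
         else stop("design must be a discrete_design or continuous_design")
  ids <- colnames(tab$concentrations)
  missing <- setdiff(ids, library_ids(lib))
  if (length(missing))
    stop("design metabolite(s) not in library: ",
         paste(missing, collapse = ", "))
  n <- nrow(tab$concentrations)
  master <- design$seed
  ph_seed <- substream_seed(master, "ph")
  noise_seed <- substream_seed(master, "noise")
  pka_seed <- substream_seed(master, "pka")
  ph1 <- NULL
  if (spec$shift_enabled) {
    restore <- .Random.seed_guard(ph_seed)
    ph1 <- stats::rnorm(n, spec$ph_mean, spec$ph_sd)
    restore()
  }
  sim_one <- function(i) {
    conc <- tab$concentrations[i, ]
    names(conc) <- ids
    if (spec$mode == "1d")
      simulate_mixture_1d(lib, conc, spec, ph1 = ph1[i],
                          noise_seed = substream_seed(noise_seed, "noise", i),
                          pka_seed = pka_seed)
    else
      simulate_mixture_2d(lib, conc, spec, ph1 = ph1[i],
                          noise_seed = substream_seed(noise_seed, "noise", i),
                          pka_seed = pka_seed)
  }
  spectra <- lapply(seq_len(n), function(i) {
    tryCatch(sim_one(i), error = function(e)
      stop("replicate ", i, ": ", conditionMessage(e), call. = FALSE))
  })
  structure(list(spectra = spectra, table = tab, design = design,
                 spec = spec, seed = master),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d spectra (%s, %s design, seed %s)\n",
              length(x$spectra), x$spec$mode, x$table$design_type,
              format(x$seed)))
  invisible(x)
}

#' Stack a 1D cohort into a replicate x grid-point matrix
#'
#' @param cohort a `cohort_result` in 1D mode
#' @return numeric matrix, one row per replicate
#' @export
cohort_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_result"))
  if (cohort$spec$mode != "1d")
    stop("cohort_matrix applies to 1D cohorts")
  do.call(rbind, lapply(cohort$spectra, function(s) s$grid$intensity))
}
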