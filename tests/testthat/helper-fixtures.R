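# Shared fixtures, built in code at test time.

# Coarse working axis: 4096 points over the standard 1H window. Coarser
# than the package default but plenty for area-based checks, since
# normalization pins every record's integral to its proton count.
test_axis <- function(n = 4096) default_ppm_axis(n)

# Ten well-separated singlets (2 protons each) on a blood background.
# Centers avoid the water window and sit >= 0.8 ppm apart, so each
# metabolite owns an exclusive spectral region: center +/- 0.3 ppm.
singlet_centers <- c(1.0, 1.8, 2.6, 3.4, 4.2, 5.4, 6.2, 7.0, 7.8, 8.6)

singlet_library <- function(axis = test_axis(), n = 10,
                            biofluid = "blood") {
  centers <- singlet_centers[seq_len(n)]
  specs <- lapply(seq_len(n), function(i) {
    toy_metabolite_spec(
      sprintf("sing%02d", i),
      multiplets = list(multiplet_spec(centers[i], "s", 0,
                                       linewidth_hz = 3,
                                       protons_weight = 2)),
      protons = 2,
      stats = list(condition_stats(300, 60, "normal", biofluid)))
  })
  build_library_from_specs(specs, axis = axis, biofluid = biofluid)
}

region_integral <- function(grid, center, half = 0.3) {
  trapz_integral(grid, window = c(center - half, center + half))
}

# Independent brute-force peak detector: explicit index scan, no rle.
oracle_detect <- function(v, main_frac, cluster_frac) {
  M <- max(v)
  res <- list(starts = integer(0), ends = integer(0), apexes = list())
  if (M <= 0) return(res)
  thr_c <- cluster_frac * M
  thr_m <- main_frac * M
  i <- 1L
  while (i <= length(v)) {
    if (v[i] >= thr_c) {
      s <- i
      while (i <= length(v) && v[i] >= thr_c) i <- i + 1L
      e <- i - 1L
      ap <- integer(0)
      for (j in s:e) {
        if (v[j] < thr_m) next
        lo <- if (j == s) TRUE else v[j] > v[j - 1]
        hi <- if (j == e) TRUE else v[j] >= v[j + 1]
        if (lo && hi) ap <- c(ap, j)
      }
      if (length(ap)) {
        res$starts <- c(res$starts, s)
        res$ends <- c(res$ends, e)
        res$apexes[[length(res$apexes) + 1L]] <- ap
      }
    } else i <- i + 1L
  }
  res
}

# Direct transcription of the pH-shift formula, kept naive on purpose
# (no logistic rewrite) as an independent oracle.
naive_delta_shift <- function(dl, dhl, pka, ph1, ph0 = 7.4) {
  (dl - dhl) * (10^(ph0 - pka) - 10^(ph1 - pka)) /
    ((1 + 10^(ph0 - pka)) * (1 + 10^(ph1 - pka)))
}
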