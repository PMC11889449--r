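# Peak-cluster detection on 1D and projected 2D spectra, the
# Henderson-Hasselbalch pH shift model, pKa imputation, and cluster
# relocation on 1D/2D grids.
#
# Cluster convention: 1-based inclusive index intervals [start, end] on
# the source axis, disjoint and sorted in grid order (descending ppm).

#' Detect peak clusters in a 1D spectrum
#'
#' Two-threshold run scan: clusters are maximal runs of consecutive grid
#' points with intensity >= `cluster_threshold_frac` x global max;
#' within each run, apexes are local maxima (leftmost point of a
#' plateau) with intensity >= `main_threshold_frac` x global max. Runs
#' without an apex are discarded.
#'
#' @param spec a `grid1d`
#' @param main_threshold_frac,cluster_threshold_frac thresholds as
#'   fractions of the global maximum;
#'   `0 < cluster_threshold_frac <= main_threshold_frac <= 1`
#' @return object of class `peak_clusters`: data frame `clusters`
#'   (columns start, end - 1-based inclusive) plus list `apexes` of apex
#'   index vectors and the `source_axis`
#' @export
detect_peaks_1d <- function(spec, main_threshold_frac = 0.2,
                            cluster_threshold_frac = 0.02) {
  if (!(cluster_threshold_frac > 0 &&
        cluster_threshold_frac <= main_threshold_frac &&
        main_threshold_frac <= 1))
    stop("need 0 < cluster_threshold_frac <= main_threshold_frac <= 1")
  v <- spec$intensity
  M <- max(v)
  empty <- structure(list(clusters = data.frame(start = integer(0),
                                                end = integer(0)),
                          apexes = list(), source_axis = spec$ppm),
                     class = "peak_clusters")
  if (M <= 0) return(empty)
  above <- v >= cluster_threshold_frac * M
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_runs <- which(r$values)
  cl_start <- integer(0); cl_end <- integer(0); apexes <- list()
  main_thr <- main_threshold_frac * M
  for (ri in keep_runs) {
    s <- starts[ri]; e <- ends[ri]
    ap <- integer(0)
    for (i in s:e) {
      if (v[i] < main_thr) next
      left_ok <- i == s || v[i] > v[i - 1]
      right_ok <- i == e || v[i] >= v[i + 1]
      if (left_ok && right_ok) ap <- c(ap, i)
    }
    if (length(ap)) {
      cl_start <- c(cl_start, s); cl_end <- c(cl_end, e)
      apexes[[length(apexes) + 1L]] <- ap
    }
  }
  structure(list(clusters = data.frame(start = cl_start, end = cl_end),
                 apexes = apexes, source_axis = spec$ppm),
            class = "peak_clusters")
}

#' @export
print.peak_clusters <- function(x, ...) {
  cat(sprintf("<peak_clusters> %d clusters on %d-point axis\n",
              nrow(x$clusters), length(x$source_axis)))
  invisible(x)
}

#' Skyline projection of a J-Res spectrum
#'
#' Collapses the indirect dimension by taking, for every F2 column, the
#' maximum over all F1 rows.
#'
#' @param spec a `grid2d` with `mode = "jres"`
#' @return `grid1d` on the F2 axis
#' @export
skyline_projection <- function(spec) {
  if (spec$mode != "jres") stop("skyline projection applies to J-Res grids")
  spectrum_grid_1d(spec$f2, apply(spec$intensity, 2, max))
}

#' Diagonal projection of a COSY spectrum
#'
#' The diagonal trace intensity[j, j]; requires a square grid with
#' identical F1/F2 axes.
#'
#' @param spec a `grid2d` with `mode = "cosy"`
#' @return `grid1d` on the F2 axis
#' @export
diagonal_projection <- function(spec) {
  if (spec$mode != "cosy") stop("diagonal projection applies to COSY grids")
  if (length(spec$f1) != length(spec$f2) ||
      !grids_equal(spec$f1, spec$f2))
    stop("COSY grid must be square with F1 = F2 axes")
  spectrum_grid_1d(spec$f2, diag(spec$intensity))
}

# base-10 logistic, overflow-safe for any finite x
logistic10 <- function(x) 1 / (1 + 10^(-x))

#' pH-dependent peak shift (Henderson-Hasselbalch transform)
#'
#' The displacement (ppm) of a peak cluster when the sample pH moves
#' from the standard `ph0` to `ph1`:
#'
#' Delta = (delta_L - delta_HL) *
#'   (10^(ph0-pKa) - 10^(ph1-pKa)) /
#'   ((1 + 10^(ph0-pKa)) * (1 + 10^(ph1-pKa)))
#'
#' evaluated in the algebraically identical logistic form
#' `(delta_L - delta_HL) * (f(ph0-pKa) - f(ph1-pKa))` with
#' `f(x) = 1/(1+10^-x)`, which cannot overflow at extreme pH - pKa.
#' Vectorized over all arguments.
#'
#' @param delta_l,delta_hl peak position at the acid / basic limit (ppm)
#' @param pka acid dissociation constant
#' @param ph0 pH of the standard spectrum (default 7.4)
#' @param ph1 sample pH
#' @return shift in ppm; bounded by `|delta_l - delta_hl|` and zero when
#'   `ph1 == ph0`
#' @export
compute_delta_shift <- function(delta_l, delta_hl, pka, ph1, ph0 = 7.4) {
  stopifnot(all(is.finite(delta_l)), all(is.finite(delta_hl)),
            all(is.finite(pka)), all(is.finite(ph1)), all(is.finite(ph0)))
  (delta_l - delta_hl) * (logistic10(ph0 - pka) - logistic10(ph1 - pka))
}

#' Impute a pKa (or limit-difference) value from a fallback distribution
#'
#' Metabolites lacking curated pKa data get one sampled from a normal
#' fallback distribution and clamped to the physical range [0, 14]. The
#' same mechanism imputes acid/basic limit differences when shift limits
#' are unknown (no clamping makes sense there; use `clamp = NULL`).
#'
#' @param mean,sd fallback distribution parameters
#' @param n number of draws
#' @param seed optional seed
#' @param clamp `c(lo, hi)` clamp range, or `NULL`
#' @return numeric vector
#' @export
sample_pka <- function(mean, sd, n = 1, seed = NULL, clamp = c(0, 14)) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0)
    stop("fallback mean/sd must be configured (finite, sd >= 0)")
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  x <- stats::rnorm(n, mean, sd)
  if (!is.null(clamp)) x <- pmin(pmax(x, clamp[1]), clamp[2])
  x
}

# Convert per-cluster ppm shifts to signed grid-point moves on a
# descending axis: +delta ppm (toward higher ppm) = lower index.
shift_to_points <- function(axis, shifts_ppm) {
  as.integer(round(shifts_ppm / axis_spacing(axis)))
}

# Core 1D relocation on an intensity vector. Sources are zeroed first,
# then each segment is added at its target, so the integral is conserved
# whenever nothing falls off the grid edge.
shift_vector <- function(v, clusters, n_pts, collision = "error") {
  P <- length(v)
  out <- v
  segs <- vector("list", nrow(clusters))
  for (k in seq_len(nrow(clusters))) {
    idx <- clusters$start[k]:clusters$end[k]
    segs[[k]] <- v[idx]
    out[idx] <- 0
  }
  claimed <- integer(0)
  for (k in seq_len(nrow(clusters))) {
    idx <- clusters$start[k]:clusters$end[k]
    tgt <- idx - n_pts[k]
    keep <- tgt >= 1 & tgt <= P
    if (!any(keep))
      stop("cluster ", k, " [", clusters$start[k], ",", clusters$end[k],
           "] shifted fully off the grid")
    if (n_pts[k] != 0 && collision == "error" &&
        any(tgt[keep] %in% claimed))
      stop("shifted cluster ", k, " collides with another shifted cluster",
           " (use collision = \"sum\" to superpose)")
    out[tgt[keep]] <- out[tgt[keep]] + segs[[k]][keep]
    claimed <- c(claimed, tgt[keep])
  }
  out
}

#' Relocate peak clusters of a 1D spectrum by per-cluster pH shifts
#'
#' Each cluster's intensity segment moves by `round(shift / spacing)`
#' whole grid points (quantized - at the default ~0.0003 ppm grid the
#' quantization error is far below a linewidth); vacated points are
#' zeroed, and the segment is added at its destination, so the total
#' integral is conserved unless a segment is truncated at a grid edge.
#'
#' @param spec a `grid1d`
#' @param clusters a `peak_clusters` on the same axis
#' @param shifts_ppm one shift per cluster (ppm, positive = toward
#'   higher ppm)
#' @param collision `"error"` (default) to fail when two shifted
#'   clusters land on the same points, `"sum"` to superpose them
#' @return shifted `grid1d`
#' @export
apply_shift_1d <- function(spec, clusters, shifts_ppm,
                           collision = c("error", "sum")) {
  collision <- match.arg(collision)
  cl <- clusters$clusters
  if (length(shifts_ppm) != nrow(cl))
    stop("need one shift per cluster (", nrow(cl), "), got ",
         length(shifts_ppm))
  if (nrow(cl) == 0) return(spec)
  if (!grids_equal(clusters$source_axis, spec$ppm))
    stop("clusters were detected on a different axis")
  n_pts <- shift_to_points(spec$ppm, shifts_ppm)
  spectrum_grid_1d(spec$ppm, shift_vector(spec$intensity, cl, n_pts,
                                          collision))
}

shift_columns <- function(mat, clusters, n_pts, collision) {
  P <- ncol(mat)
  out <- mat
  segs <- vector("list", nrow(clusters))
  for (k in seq_len(nrow(clusters))) {
    idx <- clusters$start[k]:clusters$end[k]
    segs[[k]] <- mat[, idx, drop = FALSE]
    out[, idx] <- 0
  }
  claimed <- integer(0)
  for (k in seq_len(nrow(clusters))) {
    idx <- clusters$start[k]:clusters$end[k]
    tgt <- idx - n_pts[k]
    keep <- tgt >= 1 & tgt <= P
    if (!any(keep))
      stop("cluster ", k, " shifted fully off the F2 grid")
    if (n_pts[k] != 0 && collision == "error" &&
        any(tgt[keep] %in% claimed))
      stop("shifted cluster ", k, " collides with another shifted cluster")
    out[, tgt[keep]] <- out[, tgt[keep]] + segs[[k]][, keep, drop = FALSE]
    claimed <- c(claimed, tgt[keep])
  }
  out
}

#' Relocate peak clusters of a 2D spectrum
#'
#' Clusters are detected on the projected 1D profile (skyline for J-Res,
#' diagonal for COSY) and refer to the F2 axis. J-Res mode moves each
#' cluster's F2 column block as a whole - all F1 rows together, so
#' multiplet (J) structure along F1 is untouched. COSY mode moves the
#' cluster's column band and row band by the same amount (a diagonal
#' move), which keeps a symmetric matrix symmetric; cross peaks move
#' with their diagonal blocks.
#'
#' @param spec a `grid2d`
#' @param clusters `peak_clusters` on the projected profile (F2 axis)
#' @param shifts_ppm one shift per cluster (ppm)
#' @param collision see [apply_shift_1d()]
#' @return shifted `grid2d`
#' @export
apply_shift_2d <- function(spec, clusters, shifts_ppm,
                           collision = c("error", "sum")) {
  collision <- match.arg(collision)
  cl <- clusters$clusters
  if (length(shifts_ppm) != nrow(cl))
    stop("need one shift per cluster (", nrow(cl), ")")
  if (nrow(cl) == 0) return(spec)
  if (!grids_equal(clusters$source_axis, spec$f2))
    stop("clusters were detected on a different axis than F2")
  n_pts <- shift_to_points(spec$f2, shifts_ppm)
  out <- spec
  out$intensity <- shift_columns(spec$intensity, cl, n_pts, collision)
  if (spec$mode == "cosy")
    out$intensity <- t(shift_columns(t(out$intensity), cl, n_pts,
                                     collision))
  out
}
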