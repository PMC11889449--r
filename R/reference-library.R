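# Pure-compound reference library: per-metabolite normalized 1D spectra
# (optionally 2D J-Res/COSY grids), chemical metadata (observable proton
# count, pKa, acid/basic-limit peak positions) and HMDB-style per-biofluid
# concentration statistics, plus on-disk I/O.

BIOFLUIDS <- c("urine", "blood", "csf")

#' Concentration statistics for one metabolite under one condition
#'
#' @param mean mean concentration (uM), non-negative
#' @param sd concentration SD (uM), non-negative
#' @param condition condition label, e.g. `"normal"` or `"heart transplant"`
#' @param biofluid one of urine, blood, csf
#' @return object of class `condition_stats`
#' @export
condition_stats <- function(mean, sd, condition = "normal",
                            biofluid = c("urine", "blood", "csf")) {
  biofluid <- match.arg(biofluid)
  if (!is.finite(mean) || mean < 0) stop("mean concentration must be >= 0")
  if (!is.finite(sd) || sd < 0) stop("concentration sd must be >= 0")
  structure(list(mean = mean, sd = sd, condition = condition,
                 biofluid = biofluid), class = "condition_stats")
}

#' Convert a concentration range to (mean, SD)
#'
#' HMDB frequently reports biofluid concentrations as a min-max range.
#' The range is taken as a 99.7% (3-sigma) interval of a normal
#' distribution, so `mean = (min + max) / 2` and `sd = (max - min) / 6`.
#'
#' @param min_conc,max_conc range bounds in uM, `0 <= min <= max`
#' @inheritParams condition_stats
#' @return `condition_stats`
#' @export
range_to_stats <- function(min_conc, max_conc, condition = "normal",
                           biofluid = "urine") {
  if (!is.finite(min_conc) || !is.finite(max_conc) || min_conc < 0)
    stop("concentration bounds must be finite and non-negative")
  if (max_conc < min_conc)
    stop("max_conc (", max_conc, ") must be >= min_conc (", min_conc, ")")
  condition_stats((min_conc + max_conc) / 2, (max_conc - min_conc) / 6,
                  condition = condition, biofluid = biofluid)
}

#' Aggregate multiple concentration entries for one metabolite/condition
#'
#' Database entries from different sources are pooled by unweighted
#' arithmetic averaging of their means and of their SDs. Entries given as
#' ranges (`list(min =, max =)`) are first converted by [range_to_stats()].
#'
#' @param entries list; each element a `condition_stats` or a
#'   `list(min =, max =)` range
#' @inheritParams condition_stats
#' @return pooled `condition_stats`
#' @export
aggregate_entries <- function(entries, condition = "normal",
                              biofluid = "urine") {
  if (length(entries) == 0) stop("at least one concentration entry required")
  as_stats <- lapply(entries, function(e) {
    if (inherits(e, "condition_stats")) return(e)
    if (is.list(e) && all(c("min", "max") %in% names(e)))
      return(range_to_stats(e$min, e$max, condition, biofluid))
    if (is.list(e) && all(c("mean", "sd") %in% names(e)))
      return(condition_stats(e$mean, e$sd, condition, biofluid))
    stop("entry must be condition_stats, (mean, sd) or (min, max)")
  })
  condition_stats(mean(vapply(as_stats, `[[`, 0, "mean")),
                  mean(vapply(as_stats, `[[`, 0, "sd")),
                  condition = condition, biofluid = biofluid)
}

#' Normalize a pure-compound spectrum to its proton count
#'
#' Scales the spectrum so its trapezoidal integral equals
#' `protons x 1` area unit: one area unit per observable proton at unit
#' concentration. The mixture model then reduces to a pure weighted sum -
#' multiplying the normalized spectrum by a concentration c_k reproduces
#' the c_k * p_k scaling with p_k baked in.
#'
#' An optional exclusion window (default: the 4.5-5.0 ppm residual-water
#' region) is zeroed *before* normalization.
#'
#' @param raw `grid1d` with at least one strictly positive intensity
#' @param protons observable proton count, positive integer
#' @param exclude_window optional `c(lo, hi)` ppm window zeroed first;
#'   `NULL` to keep all points
#' @return normalized `grid1d`
#' @export
normalize_pure_spectrum <- function(raw, protons, exclude_window = NULL) {
  if (!is.finite(protons) || protons < 1 || protons != round(protons))
    stop("protons must be a positive integer")
  y <- raw$intensity
  if (any(y < 0)) stop("pure spectrum intensities must be non-negative")
  if (!is.null(exclude_window)) {
    y[raw$ppm >= min(exclude_window) & raw$ppm <= max(exclude_window)] <- 0
  }
  s <- spectrum_grid_1d(raw$ppm, y)
  area <- trapz_integral(s)
  if (area <= 0)
    stop("cannot normalize: spectrum has zero integral")
  spectrum_grid_1d(raw$ppm, y * (protons / area))
}

#' One metabolite's record in the reference library
#'
#' @param id stable identifier (unique within a library)
#' @param name display name
#' @param protons observable proton count p_k (positive integer)
#' @param spectrum_1d normalized `grid1d` (see [normalize_pure_spectrum()])
#' @param pka acid dissociation constant, or `NA` when unknown
#' @param shift_limits list of per-cluster `c(delta_L, delta_HL)` pairs
#'   (acid- and basic-limit peak positions in ppm), or `NULL` for a
#'   pH-invariant metabolite
#' @param spectrum_jres,spectrum_cosy optional `grid2d` objects
#' @param stats list of `condition_stats`
#' @return object of class `compound_record`
#' @export
pure_compound_record <- function(id, name, protons, spectrum_1d,
                                 pka = NA_real_, shift_limits = NULL,
                                 spectrum_jres = NULL, spectrum_cosy = NULL,
                                 stats = list()) {
  if (!nzchar(id)) stop("record id must be non-empty")
  if (!is.finite(protons) || protons < 1 || protons != round(protons))
    stop("record '", id, "': protons must be a positive integer")
  stopifnot(inherits(spectrum_1d, "grid1d"))
  if (any(spectrum_1d$intensity < 0))
    stop("record '", id, "': negative intensities in pure spectrum")
  area <- trapz_integral(spectrum_1d)
  if (abs(area - protons) > 1e-6 * protons)
    stop("record '", id, "': spectrum integral ", signif(area, 8),
         " != protons (", protons, "); normalize first")
  if (!is.null(shift_limits)) {
    ok <- vapply(shift_limits, function(p) length(p) == 2 &&
                   all(is.finite(p)), TRUE)
    if (!all(ok)) stop("record '", id, "': malformed shift_limits")
  }
  structure(list(id = id, name = name, protons = as.integer(protons),
                 pka = as.numeric(pka), shift_limits = shift_limits,
                 spectrum_1d = spectrum_1d, spectrum_jres = spectrum_jres,
                 spectrum_cosy = spectrum_cosy, stats = stats),
            class = "compound_record")
}

#' Pure-compound reference library
#'
#' A set of [pure_compound_record()]s sharing one common 1D grid, with an
#' optional albumin-like protein background envelope (unit scale) used
#' when simulating blood.
#'
#' @param records list of `compound_record`, unique ids
#' @param protein_background optional `grid1d` on the common grid
#' @return object of class `nmr_library`
#' @export
nmr_library <- function(records, protein_background = NULL) {
  if (length(records) == 0) stop("library needs at least one record")
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate record id '", dup, "'")
  }
  records <- records[order(ids)]
  ids <- sort(ids)
  axis <- records[[1]]$spectrum_1d$ppm
  for (r in records) {
    if (!grids_equal(r$spectrum_1d$ppm, axis))
      stop("record '", r$id, "' is not on the common grid")
  }
  if (!is.null(protein_background) &&
      !grids_equal(protein_background$ppm, axis))
    stop("protein background is not on the common grid")
  names(records) <- ids
  structure(list(records = records, common_grid = axis,
                 protein_background = protein_background),
            class = "nmr_library")
}

#' @export
print.nmr_library <- function(x, ...) {
  cat(sprintf("<nmr_library> %d records on %d-point grid (%s protein background)\n",
              length(x$records), length(x$common_grid),
              if (is.null(x$protein_background)) "no" else "with"))
  invisible(x)
}

#' @rdname nmr_library
#' @param lib an `nmr_library`
#' @export
library_ids <- function(lib) names(lib$records)

# ---- on-disk format -------------------------------------------------------
# Directory layout:
#   library.tsv              metadata, one row per (id, biofluid, condition)
#   <id>.tsv                 2-column ppm \t intensity
#   <id>_jres.tsv, <id>_cosy.tsv   dense matrices; first row = f2 axis,
#                            first column = f1 axis (cell [1,1] = mode tag)
#   protein_background.tsv   optional, 2-column

format_shift_limits <- function(sl) {
  if (is.null(sl)) return("")
  paste(vapply(sl, function(p) sprintf("%.15g:%.15g", p[1], p[2]), ""),
        collapse = ";")
}

parse_shift_limits <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  lapply(strsplit(txt, ";", fixed = TRUE)[[1]], function(pair) {
    v <- as.numeric(strsplit(pair, ":", fixed = TRUE)[[1]])
    if (length(v) != 2 || any(!is.finite(v)))
      stop("malformed shift_limits entry '", pair, "'")
    v
  })
}

write_matrix_tsv <- function(g2, path) {
  m <- rbind(c(NA, g2$f2), cbind(g2$f1, g2$intensity))
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, na = if (g2$mode == "jres") "jres" else "cosy")
}

read_matrix_tsv <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character")
  mode <- m[1, 1]
  f2 <- as.numeric(m[1, -1])
  f1 <- as.numeric(m[-1, 1])
  intensity <- matrix(as.numeric(as.matrix(m[-1, -1])), nrow = length(f1))
  spectrum_grid_2d(f1, f2, intensity, mode = mode)
}

#' Write a library to a directory
#'
#' Inverse of [load_library()]: writes `library.tsv` metadata plus one
#' 2-column TSV per record (and dense TSV matrices for 2D grids).
#'
#' @param lib an `nmr_library`
#' @param path directory to create/write into
#' @return `path`, invisibly
#' @export
write_library <- function(lib, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (r in lib$records) {
    utils::write.table(
      data.frame(ppm = r$spectrum_1d$ppm, intensity = r$spectrum_1d$intensity),
      file.path(path, paste0(r$id, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(r$spectrum_jres))
      write_matrix_tsv(r$spectrum_jres, file.path(path, paste0(r$id, "_jres.tsv")))
    if (!is.null(r$spectrum_cosy))
      write_matrix_tsv(r$spectrum_cosy, file.path(path, paste0(r$id, "_cosy.tsv")))
    sts <- if (length(r$stats)) r$stats else
      list(condition_stats(0, 0, "normal", "urine"))
    for (s in sts) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = r$id, name = r$name, protons = r$protons,
        pka = r$pka, biofluid = s$biofluid, condition = s$condition,
        conc_mean_uM = s$mean, conc_sd_uM = s$sd,
        shift_limits = format_shift_limits(r$shift_limits),
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), file.path(path, "library.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(lib$protein_background)) {
    utils::write.table(
      data.frame(ppm = lib$protein_background$ppm,
                 intensity = lib$protein_background$intensity),
      file.path(path, "protein_background.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Load a reference library from a directory
#'
#' Reads `library.tsv` plus per-record spectra, resamples every record
#' onto one common grid, normalizes each spectrum to its proton count
#' (zeroing the water exclusion window first) and attaches concentration
#' metadata. Records are ordered by id, so loading is deterministic.
#'
#' Metadata rows may carry either `conc_mean_uM` + `conc_sd_uM` or
#' `conc_min_uM` + `conc_max_uM` (converted via the 3-sigma rule).
#'
#' @param path library directory
#' @param common_grid target ppm axis; default: the axis of the first
#'   record (by id)
#' @param exclude_window water window zeroed before normalization;
#'   `NULL` disables
#' @return an `nmr_library`
#' @export
load_library <- function(path, common_grid = NULL,
                         exclude_window = c(4.5, 5.0)) {
  meta_path <- file.path(path, "library.tsv")
  if (!file.exists(meta_path)) stop("no library.tsv under '", path, "'")
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            colClasses = c(id = "character"))
  ids <- sort(unique(meta$id))
  per_id <- split(meta, meta$id)
  # metadata consistency per id
  for (id in ids) {
    m <- per_id[[id]]
    if (length(unique(m$protons)) != 1 || length(unique(m$name)) != 1)
      stop("inconsistent metadata rows for record '", id, "'")
    if (anyDuplicated(paste(m$biofluid, m$condition)))
      stop("duplicate id '", id, "' for the same biofluid/condition")
  }
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    m <- per_id[[id]]
    spath <- file.path(path, paste0(id, ".tsv"))
    if (!file.exists(spath))
      stop("missing spectrum file for record '", id, "'")
    tab <- utils::read.delim(spath)
    raw <- spectrum_grid_1d(tab$ppm, tab$intensity)
    if (is.null(common_grid)) common_grid <- raw$ppm
    res <- resample_to_grid(raw, common_grid)
    spec <- normalize_pure_spectrum(res, m$protons[1],
                                    exclude_window = exclude_window)
    stats <- lapply(seq_len(nrow(m)), function(j) {
      row <- m[j, ]
      if (!is.null(row$conc_mean_uM) && is.finite(row$conc_mean_uM))
        condition_stats(row$conc_mean_uM, row$conc_sd_uM,
                        row$condition, row$biofluid)
      else
        range_to_stats(row$conc_min_uM, row$conc_max_uM,
                       row$condition, row$biofluid)
    })
    jres_path <- file.path(path, paste0(id, "_jres.tsv"))
    cosy_path <- file.path(path, paste0(id, "_cosy.tsv"))
    records[[i]] <- pure_compound_record(
      id = id, name = m$name[1], protons = m$protons[1],
      spectrum_1d = spec,
      pka = if (is.finite(m$pka[1])) m$pka[1] else NA_real_,
      shift_limits = parse_shift_limits(m$shift_limits[1]),
      spectrum_jres = if (file.exists(jres_path)) read_matrix_tsv(jres_path),
      spectrum_cosy = if (file.exists(cosy_path)) read_matrix_tsv(cosy_path),
      stats = stats)
  }
  bg_path <- file.path(path, "protein_background.tsv")
  bg <- NULL
  if (file.exists(bg_path)) {
    tab <- utils::read.delim(bg_path)
    bg <- resample_to_grid(spectrum_grid_1d(tab$ppm, tab$intensity),
                           common_grid)
  }
  nmr_library(records, protein_background = bg)
}

#' Look up the concentration stats of one record
#'
#' @param record a `compound_record`
#' @param condition,biofluid labels to match
#' @return `condition_stats`, or error when absent
#' @export
record_stats <- function(record, condition = "normal", biofluid = "urine") {
  for (s in record$stats)
    if (s$condition == condition && s$biofluid == biofluid) return(s)
  stop("record '", record$id, "' has no stats for ", biofluid, "/", condition)
}
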