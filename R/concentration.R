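# Concentration simulation for synthetic cohorts: truncated-normal
# marginals, Gaussian-copula inter-metabolite correlation, discrete
# (case-control, fold change / SD ratio) and continuous
# (response-correlated) designs.

#' Sample from a normal distribution truncated below
#'
#' Inverse-CDF sampling of normal(mean, sd) conditioned on being
#' `>= lower` (default 0, so concentrations stay physical). With
#' `sd = 0` all values equal `mean` (an error when `mean < lower`:
#' empty support).
#'
#' @param mean,sd normal parameters; `sd >= 0`
#' @param n number of draws
#' @param seed optional seed; `NULL` uses the current RNG stream
#' @param lower truncation bound
#' @return numeric vector of `n` values `>= lower`
#' @export
sample_truncated_normal <- function(mean, sd, n, seed = NULL, lower = 0) {
  stopifnot(sd >= 0, n >= 1)
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  if (sd == 0) {
    if (mean < lower)
      stop("empty support: mean ", mean, " < lower bound ", lower,
           " with sd = 0")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  if (plo >= 1)
    stop("empty support: essentially no mass above ", lower)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(u, mean, sd)
}

#' Mean of a below-truncated normal (closed form)
#'
#' `mean + sd * phi(alpha) / (1 - Phi(alpha))` with
#' `alpha = (lower - mean) / sd`. Used as an independent check on the
#' sampler.
#'
#' @inheritParams sample_truncated_normal
#' @return scalar expected value
#' @export
truncated_normal_mean <- function(mean, sd, lower = 0) {
  if (sd == 0) return(mean)
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

#' Inter-metabolite correlation specification
#'
#' @param ids metabolite identifiers (column order of `R`)
#' @param R target Pearson correlation matrix: symmetric, unit diagonal,
#'   entries in `[-1, 1]`
#' @return object of class `correlation_spec`
#' @export
correlation_spec <- function(ids, R) {
  R <- as.matrix(R)
  k <- length(ids)
  if (!all(dim(R) == k)) stop("R must be ", k, " x ", k)
  if (max(abs(R - t(R))) > 1e-9) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-9) stop("R must have unit diagonal")
  if (any(abs(R) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  dimnames(R) <- list(ids, ids)
  structure(list(ids = ids, R = R), class = "correlation_spec")
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' PSD inputs (smallest eigenvalue >= -1e-10) are returned unchanged.
#' Otherwise negative eigenvalues are clipped at 1e-8, the matrix is
#' reassembled and rescaled back to unit diagonal, and a message records
#' the repair.
#'
#' @param R symmetric unit-diagonal matrix
#' @return PSD correlation matrix
#' @export
repair_correlation <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -1e-10) return(R)
  message("correlation matrix not PSD (min eigenvalue ",
          signif(min(e$values), 3), "); repaired by eigenvalue clipping")
  v <- pmax(e$values, 1e-8)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- 1 / sqrt(diag(R2))
  R2 <- R2 * tcrossprod(d)
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  R2
}

#' Sample correlated metabolite concentrations (Gaussian copula)
#'
#' Draws multivariate normal scores with correlation `R`, maps them to
#' the stated per-metabolite (mean, SD) marginals, and clamps at zero.
#' Marginals match the stats and the empirical correlation matches `R`
#' up to Monte-Carlo error; zero-clamping distorts both negligibly when
#' `mean/sd >= 3`.
#'
#' @param stats named list of [condition_stats()] (names = metabolite ids)
#' @param R a [correlation_spec()] over the same ids
#' @param n number of replicates
#' @param seed optional seed
#' @return `n x K` concentration matrix with metabolite ids as colnames
#' @export
sample_correlated <- function(stats, R, n, seed = NULL) {
  ids <- names(stats)
  if (!setequal(ids, R$ids) || length(ids) != length(R$ids))
    stop("stats and correlation spec cover different metabolites")
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  Rm <- repair_correlation(R$R[ids, ids, drop = FALSE])
  e <- eigen(Rm, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(ids))
  Z <- matrix(stats::rnorm(n * length(ids)), n) %*% t(A)
  X <- sapply(seq_along(ids), function(k)
    pmax(0, stats[[k]]$mean + stats[[k]]$sd * Z[, k]))
  X <- matrix(X, nrow = n, dimnames = list(NULL, ids))
  X
}

#' Derive an abnormal condition from normal stats
#'
#' `mean' = mean x fold_change`, `sd' = sd x sd_ratio`.
#'
#' @param normal `condition_stats` of the normal group
#' @param fold_change multiplicative change in the mean, > 0
#' @param sd_ratio multiplicative change in the SD, >= 0
#' @param condition label for the derived stats
#' @return `condition_stats`
#' @export
apply_condition <- function(normal, fold_change, sd_ratio = 1,
                            condition = "abnormal") {
  if (!is.finite(fold_change) || fold_change <= 0)
    stop("fold_change must be > 0")
  if (!is.finite(sd_ratio) || sd_ratio < 0)
    stop("sd_ratio must be >= 0")
  condition_stats(normal$mean * fold_change, normal$sd * sd_ratio,
                  condition = condition, biofluid = normal$biofluid)
}

new_concentration_table <- function(concentrations, labels, seed,
                                    design_type) {
  stopifnot(nrow(concentrations) == length(labels),
            all(concentrations >= 0))
  structure(list(concentrations = concentrations, labels = labels,
                 seed = seed, design_type = design_type),
            class = "concentration_table")
}

#' @export
print.concentration_table <- function(x, ...) {
  cat(sprintf("<concentration_table:%s> %d replicates x %d metabolites (seed %s)\n",
              x$design_type, nrow(x$concentrations),
              ncol(x$concentrations), format(x$seed)))
  invisible(x)
}

#' Discrete (case-control) study design
#'
#' Each group draws per-metabolite concentrations from truncated normals
#' (optionally correlated via a Gaussian copula). Group stats come
#' either from `stats[[group]][[id]]` directly or, for non-reference
#' groups, from the reference group's stats via `fold_change` /
#' `sd_ratio` tables.
#'
#' @param n_per_group named vector of replicate counts per group
#' @param stats nested list: `stats[[group]][[metabolite_id]]` of
#'   [condition_stats()]; at minimum the reference group must be complete
#' @param reference name of the reference ("normal") group
#' @param fold_change,sd_ratio named lists per non-reference group:
#'   `fold_change[[group]][[id]]` (defaults: 1)
#' @param correlation optional [correlation_spec()] shared by all groups
#' @param seed RNG seed
#' @return object of class `discrete_design`
#' @export
discrete_design <- function(n_per_group, stats, reference = names(stats)[1],
                            fold_change = list(), sd_ratio = list(),
                            correlation = NULL, seed = 1) {
  stopifnot(all(n_per_group >= 1), !is.null(names(n_per_group)))
  if (!reference %in% names(stats))
    stop("reference group '", reference, "' has no stats")
  for (g in names(fold_change))
    if (!g %in% names(n_per_group))
      stop("fold_change refers to unknown group '", g, "'")
  for (g in names(sd_ratio))
    if (!g %in% names(n_per_group))
      stop("sd_ratio refers to unknown group '", g, "'")
  structure(list(n_per_group = n_per_group, stats = stats,
                 reference = reference, fold_change = fold_change,
                 sd_ratio = sd_ratio, correlation = correlation,
                 seed = seed),
            class = "discrete_design")
}

resolve_group_stats <- function(design, group, ids) {
  out <- list()
  for (id in ids) {
    s <- design$stats[[group]][[id]]
    if (is.null(s)) {
      base <- design$stats[[design$reference]][[id]]
      if (is.null(base))
        stop("no stats for metabolite '", id, "' in reference group")
      fc <- design$fold_change[[group]][[id]]
      sr <- design$sd_ratio[[group]][[id]]
      s <- apply_condition(base, if (is.null(fc)) 1 else fc,
                           if (is.null(sr)) 1 else sr, condition = group)
    }
    out[[id]] <- s
  }
  out
}

#' Simulate concentrations for a discrete design
#'
#' @param design a [discrete_design()]
#' @return `concentration_table` with group labels
#' @export
sample_discrete <- function(design) {
  stopifnot(inherits(design, "discrete_design"))
  ids <- names(design$stats[[design$reference]])
  restore <- .Random.seed_guard(design$seed)
  on.exit(restore(), add = TRUE)
  blocks <- list(); labels <- character(0)
  for (g in names(design$n_per_group)) {
    n <- design$n_per_group[[g]]
    st <- resolve_group_stats(design, g, ids)
    if (!is.null(design$correlation)) {
      X <- sample_correlated(st, design$correlation, n)
    } else {
      X <- sapply(ids, function(id)
        sample_truncated_normal(st[[id]]$mean, st[[id]]$sd, n))
      X <- matrix(X, nrow = n, dimnames = list(NULL, ids))
    }
    blocks[[g]] <- X
    labels <- c(labels, rep(g, n))
  }
  new_concentration_table(do.call(rbind, blocks), labels, design$seed,
                          "discrete")
}

#' Continuous-outcome study design
#'
#' Concentrations correlate with a continuous biological response y
#' (e.g. age or BMI) through a standardized linear model: with
#' z_y the response standardized by its *sample* mean and SD,
#' `z_x = a * z_y + eps`, `eps ~ normal(0, eps_sd)`, and
#' `x = x_mean + x_sd * z_x` clamped at zero. When
#' `eps_sd = sqrt(1 - a^2)` the population correlation of x and y is
#' exactly `a`; for other `eps_sd` the realized correlation is
#' `a / sqrt(a^2 + eps_sd^2)` and is reported via a message.
#'
#' @param n replicate count (>= 3: standardization uses the sample SD)
#' @param response_mean,response_sd distribution of the response y
#'   (`response_sd > 0`)
#' @param metabolites named list; each element a list with `x_mean`,
#'   `x_sd`, and optionally `a` (target Pearson correlation, default 0)
#'   and `eps_sd` (default `sqrt(1 - a^2)` when `a != 0`, else 0)
#' @param seed RNG seed
#' @return object of class `continuous_design`
#' @export
continuous_design <- function(n, response_mean, response_sd, metabolites,
                              seed = 1) {
  if (n < 3) stop("n must be >= 3 (sample-SD standardization)")
  if (!is.finite(response_sd) || response_sd <= 0)
    stop("response_sd must be > 0")
  mets <- lapply(metabolites, function(m) {
    a <- if (is.null(m$a)) 0 else m$a
    if (abs(a) > 1) stop("|a| must be <= 1")
    eps <- if (is.null(m$eps_sd)) {
      if (a != 0) sqrt(1 - a^2) else 0
    } else m$eps_sd
    if (eps < 0) stop("eps_sd must be >= 0")
    if (m$x_sd < 0) stop("x_sd must be >= 0")
    list(x_mean = m$x_mean, x_sd = m$x_sd, a = a, eps_sd = eps)
  })
  structure(list(n = n, response_mean = response_mean,
                 response_sd = response_sd, metabolites = mets,
                 seed = seed),
            class = "continuous_design")
}

#' Simulate concentrations for a continuous design
#'
#' @param design a [continuous_design()]
#' @return `concentration_table` whose labels are the response values y
#' @export
sample_continuous <- function(design) {
  stopifnot(inherits(design, "continuous_design"))
  restore <- .Random.seed_guard(design$seed)
  on.exit(restore(), add = TRUE)
  n <- design$n
  y <- stats::rnorm(n, design$response_mean, design$response_sd)
  zy <- (y - mean(y)) / stats::sd(y)
  ids <- names(design$metabolites)
  X <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  for (k in seq_along(ids)) {
    m <- design$metabolites[[k]]
    eps <- stats::rnorm(n, 0, m$eps_sd)
    zx <- m$a * zy + eps
    X[, k] <- pmax(0, m$x_mean + m$x_sd * zx)
  }
  new_concentration_table(X, y, design$seed, "continuous")
}
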