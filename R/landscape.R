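#' Configuration for the synthetic landscape generator
#'
#' Bundles the generative parameters for [generate_landscape()] and
#' [generate_species()].  The defaults emulate an atlas-style study area: a
#' grid of roughly 3,000 10x10 km cells, a dozen spatially autocorrelated
#' continuous predictors (climate/topography analogues), and a species whose
#' occurrence follows a known logistic model at a set prevalence.
#'
#' @param seed integer; every draw made under this configuration is
#'   deterministic given `seed`.
#' @param n_rows,n_cols grid dimensions (cells).
#' @param n_predictors number of autocorrelated continuous predictor layers
#'   (two pure spatial-trend layers, `spat_row` and `spat_col`, are always
#'   added on top).
#' @param autocorr_scale Gaussian smoothing length, in cells, applied to the
#'   white-noise fields; 0 disables smoothing.
#' @param true_coefficients logistic slopes of the generating model, on the
#'   standardized predictor scale.  Either a full vector (one per predictor
#'   layer, in layer order) or a named vector; unnamed layers get 0.  `NULL`
#'   means all zero.
#' @param target_prevalence desired mean occurrence probability, strictly
#'   inside (0, 1).  The generating intercept is solved so the mean of the
#'   true probabilities equals this value.
#' @param cell_size nominal cell side length (abstract units; 10 for a
#'   10 km UTM-style grid).
#' @param mask `"none"` for an all-valid grid, or `"coast"` to punch
#'   irregular NODATA regions (roughly 15% of cells) so masked-grid code
#'   paths are exercised.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_rows = 55L, n_cols = 55L,
                             n_predictors = 12L, autocorr_scale = 5,
                             true_coefficients = NULL,
                             target_prevalence = 0.3,
                             cell_size = 10,
                             mask = c("none", "coast")) {
  mask <- match.arg(mask)
  if (!is_count(n_rows) || !is_count(n_cols))
    stop("invalid config: grid dimensions must be positive integers")
  if (!is_count(n_predictors, min = 0))
    stop("invalid config: n_predictors must be a non-negative integer")
  if (!is.numeric(autocorr_scale) || length(autocorr_scale) != 1 ||
      !is.finite(autocorr_scale) || autocorr_scale < 0)
    stop("invalid config: autocorr_scale must be >= 0")
  if (!is.numeric(target_prevalence) || length(target_prevalence) != 1 ||
      !is.finite(target_prevalence) ||
      target_prevalence <= 0 || target_prevalence >= 1)
    stop("invalid config: target_prevalence must be strictly inside (0, 1)")
  structure(
    list(seed = as.integer(seed), n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), n_predictors = as.integer(n_predictors),
         autocorr_scale = autocorr_scale,
         true_coefficients = true_coefficients,
         target_prevalence = target_prevalence,
         cell_size = cell_size, mask = mask),
    class = "generator_config")
}

# row-stochastic Gaussian smoothing operator along one axis
smoothing_matrix <- function(n, scale) {
  if (scale <= 0 || n == 1) return(diag(n))
  w <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = scale)
  w / rowSums(w)
}

# standardize over valid cells; degenerate layers (single cell, zero
# variance) are centered and left at 0 so every value stays finite
standardize_layer <- function(m, valid) {
  v <- m[valid]
  mu <- mean(v)
  sd <- stats::sd(v)
  if (!is.finite(sd) || sd == 0) {
    m[] <- 0
    m[!valid] <- NA_real_
    return(m)
  }
  m <- (m - mu) / sd
  m[!valid] <- NA_real_
  m
}

#' Generate a synthetic gridded landscape
#'
#' Draws `n_predictors` spatially autocorrelated continuous predictor layers
#' (Gaussian white noise smoothed at `autocorr_scale` cells, then
#' standardized to mean 0, sd 1 over valid cells) plus two pure
#' spatial-trend layers (`spat_row`, `spat_col`: standardized row and column
#' index).  With `mask = "coast"` an irregular NODATA region is removed
#' first, emulating a coastline.
#'
#' @param config a [generator_config()].
#' @return a `grid_landscape`: list with `n_rows`, `n_cols`, `cell_size`,
#'   logical matrix `valid`, and `predictors`, a named list of matrices
#'   (`NA` outside the study area).
#' @export
#' @examples
#' land <- generate_landscape(generator_config(seed = 7, n_rows = 20,
#'                                             n_cols = 25))
#' names(land$predictors)
generate_landscape <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  nr <- config$n_rows; nc <- config$n_cols
  with_seed(config$seed, {
    Sr <- smoothing_matrix(nr, config$autocorr_scale)
    Sc <- smoothing_matrix(nc, config$autocorr_scale)
    valid <- matrix(TRUE, nr, nc)
    if (config$mask == "coast" && nr * nc >= 16) {
      # smooth field thresholded at its 15% quantile -> irregular NODATA
      f <- Sr %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% t(Sc)
      valid <- f >= stats::quantile(f, 0.15)
      if (!any(valid)) valid[which.max(f)] <- TRUE
    }
    preds <- vector("list", config$n_predictors)
    for (i in seq_len(config$n_predictors)) {
      z <- matrix(stats::rnorm(nr * nc), nr, nc)
      preds[[i]] <- standardize_layer(Sr %*% z %*% t(Sc), valid)
    }
    names(preds) <- sprintf("env%02d", seq_len(config$n_predictors))
    preds$spat_row <- standardize_layer(matrix(seq_len(nr), nr, nc), valid)
    preds$spat_col <- standardize_layer(
      matrix(seq_len(nc), nr, nc, byrow = TRUE), valid)
    structure(list(n_rows = nr, n_cols = nc, cell_size = config$cell_size,
                   valid = valid, predictors = preds),
              class = "grid_landscape")
  })
}

#' @export
print.grid_landscape <- function(x, ...) {
  cat(sprintf("grid_landscape: %d x %d cells (%d valid), %d predictor layers\n",
              x$n_rows, x$n_cols, sum(x$valid), length(x$predictors)))
  cat("  layers:", paste(names(x$predictors), collapse = ", "), "\n")
  invisible(x)
}

#' Valid-cell data frame of a landscape
#'
#' One row per valid cell, in the column-major order used throughout the
#' package, with `cell_id` (linear index into the full grid), `row`, `col`
#' and one column per predictor layer.
#'
#' @param x a `grid_landscape`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a data.frame.
#' @export
as.data.frame.grid_landscape <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  idx <- which(x$valid)
  df <- data.frame(
    cell_id = idx,
    row = ((idx - 1L) %% x$n_rows) + 1L,
    col = ((idx - 1L) %/% x$n_rows) + 1L)
  for (nm in names(x$predictors)) df[[nm]] <- x$predictors[[nm]][idx]
  df
}

#' Construct a species occurrence record
#'
#' @param presence 0/1 vector, one entry per valid cell of `landscape`
#'   (column-major order of `which(landscape$valid)`).
#' @param landscape the `grid_landscape` the cells refer to.
#' @param species_id label.
#' @return a `species_occurrence`: `species_id`, integer `presence`,
#'   `cell_id` (linear grid indices), and the class counts `n1` (presences)
#'   and `n0` (absences).
#' @export
species_occurrence <- function(presence, landscape, species_id = "sp1") {
  stopifnot(inherits(landscape, "grid_landscape"))
  presence <- as.integer(presence)
  if (length(presence) != sum(landscape$valid))
    stop("`presence` must have one entry per valid cell")
  if (!all(presence %in% c(0L, 1L)))
    stop("`presence` must be 0/1")
  structure(list(species_id = species_id, presence = presence,
                 cell_id = which(landscape$valid),
                 n1 = sum(presence), n0 = sum(presence == 0L)),
            class = "species_occurrence")
}

#' @export
print.species_occurrence <- function(x, ...) {
  cat(sprintf("species_occurrence '%s': %d presences, %d absences (prevalence %.3f)\n",
              x$species_id, x$n1, x$n0, x$n1 / (x$n1 + x$n0)))
  invisible(x)
}

resolve_coefficients <- function(coefs, predictor_names) {
  full <- stats::setNames(numeric(length(predictor_names)), predictor_names)
  if (is.null(coefs)) return(full)
  if (!is.null(names(coefs)) && all(nzchar(names(coefs)))) {
    unknown <- setdiff(names(coefs), predictor_names)
    if (length(unknown))
      stop("unknown predictor(s) in true_coefficients: ",
           paste(unknown, collapse = ", "))
    full[names(coefs)] <- coefs
  } else {
    if (length(coefs) != length(predictor_names))
      stop("true_coefficients must be named or have one entry per predictor (",
           length(predictor_names), ")")
    full[] <- coefs
  }
  full
}

# solve mean(plogis(a + eta)) = target by bisection; monotone in a
solve_intercept <- function(eta, target, tol = 1e-12) {
  if (any(!is.finite(eta)))
    stop("degenerate predictors: non-finite linear predictor")
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -40 - max(eta); hi <- 40 - min(eta)
  if (f(lo) > 0 || f(hi) < 0)
    stop("target prevalence unreachable for these predictors")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Simulate a species from a known logistic model
#'
#' The true per-cell occurrence probability is
#' `plogis(intercept + sum(coef * predictor))`, with the intercept solved by
#' bisection so the mean probability equals `config$target_prevalence`;
#' presence is then drawn independently per cell.  Deterministic given
#' `seed`.
#'
#' @param landscape a `grid_landscape`.
#' @param config a [generator_config()]; `true_coefficients` are matched to
#'   `landscape$predictors` by name (or positionally if unnamed and
#'   full-length).
#' @param species_id label for the simulated species.
#' @param seed RNG seed for the presence draw; defaults to `config$seed`.
#' @return a [species_occurrence] with an extra element `truth`:
#'   `intercept`, `coefficients`, and the per-valid-cell `probability`.
#' @export
generate_species <- function(landscape, config, species_id = "sp1",
                             seed = config$seed) {
  stopifnot(inherits(landscape, "grid_landscape"),
            inherits(config, "generator_config"))
  pnames <- names(landscape$predictors)
  beta <- resolve_coefficients(config$true_coefficients, pnames)
  idx <- which(landscape$valid)
  X <- vapply(landscape$predictors, function(m) m[idx],
              numeric(length(idx)))
  eta <- as.vector(X %*% beta)
  a <- solve_intercept(eta, config$target_prevalence)
  p <- stats::plogis(a + eta)
  presence <- with_seed(seed, stats::rbinom(length(p), 1L, p))
  occ <- species_occurrence(presence, landscape, species_id)
  occ$truth <- list(intercept = a, coefficients = beta, probability = p)
  occ
}

#' Landscape + species fixture with a known multi-patch favorable area
#'
#' Adds to a generated landscape one predictor (`blob`) built as a union of
#' `n_blobs` Gaussian bumps placed along the grid's middle row, separated by
#' low-value corridors, and simulates a species with a strong positive
#' weight on it.  The TRUE probability surface, passed through the
#' favorability transform and thresholded at 0.8, then has `n_blobs`
#' connected components (asserted on the truth, before any fitting) —
#' the canonical fragmented, metapopulation-style scenario.
#'
#' @param config a [generator_config()]; the scenario default uses a 55 x 55
#'   grid, 6 nuisance predictors and target prevalence 0.15.
#' @param n_blobs number of high-favorability nuclei.
#' @param blob_radius Gaussian radius of each bump, in cells.
#' @param separation corridor width between consecutive bump edges, in
#'   cells; 0 merges the bumps into a single component.
#' @param blob_coefficient logistic slope on the standardized blob layer.
#' @return a list of class `fragmented_scenario` with `landscape`,
#'   `occurrence`, and `truth` (`probability`, `favorability`, both as full
#'   grid matrices, plus `n_true_patches` under queen adjacency and the bump
#'   `centers`).
#' @export
make_fragmented_scenario <- function(config = NULL, n_blobs = 2L,
                                     blob_radius = 5, separation = 14,
                                     blob_coefficient = 4) {
  if (is.null(config))
    config <- generator_config(seed = 1L, n_rows = 55L, n_cols = 55L,
                               n_predictors = 6L, autocorr_scale = 4,
                               target_prevalence = 0.15)
  stopifnot(inherits(config, "generator_config"), is_count(n_blobs),
            blob_radius > 0, separation >= 0)
  land <- generate_landscape(config)
  nr <- land$n_rows; nc <- land$n_cols
  spacing <- 2 * blob_radius + separation
  span <- (n_blobs - 1L) * spacing
  c0 <- (nc - span) / 2
  if (c0 < 1 || c0 + span > nc)
    stop("blobs do not fit on the grid; reduce n_blobs, radius or separation")
  centers <- cbind(row = rep(ceiling(nr / 2), n_blobs),
                   col = c0 + (seq_len(n_blobs) - 1L) * spacing)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  blob <- matrix(0, nr, nc)
  for (b in seq_len(n_blobs)) {
    d2 <- (rr - centers[b, "row"])^2 + (cc - centers[b, "col"])^2
    blob <- pmax(blob, exp(-d2 / (2 * blob_radius^2)))
  }
  land$predictors$blob <- standardize_layer(blob, land$valid)
  sp_config <- config
  sp_config$true_coefficients <- c(blob = blob_coefficient)
  occ <- generate_species(land, sp_config, species_id = "fragmented")
  p_true <- occ$truth$probability
  f_true <- favorability(p_true, occ$n1, occ$n0)
  f_mat <- surface_matrix(land, f_true)
  comps <- label_components(!is.na(f_mat) & f_mat >= 0.8, "queen")
  structure(list(landscape = land, occurrence = occ,
                 truth = list(probability = surface_matrix(land, p_true),
                              favorability = f_mat,
                              n_true_patches = comps$n,
                              centers = centers)),
            class = "fragmented_scenario")
}
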