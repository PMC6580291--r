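# Climatic-niche overlap between species: occurrences are projected onto
# the two leading principal axes of the pooled climate space, smoothed
# onto a shared grid, and compared with Schoener's D.

#' Project occurrences onto the pooled climate principal axes
#'
#' Standardizes the climate variables over the pooled occurrences of all
#' species and projects every occurrence onto the two leading principal
#' components.
#'
#' @param occ Data frame with a `species` column and one numeric column
#'   per climate variable (no missing values).
#' @return An `env_space` object: `scores` (tibble with `species`,
#'   `axis1`, `axis2`), `loadings`, `sdev` and `var_explained` of the
#'   two retained axes.
#' @export
env_axes <- function(occ) {
  if (length(unique(occ$species)) < 2)
    abort("pooled ordination needs at least 2 species")
  vars <- names(occ)[vapply(occ, is.numeric, TRUE)]
  if (length(vars) < 2) abort("need at least two numeric climate variables")
  X <- as.matrix(occ[, vars])
  if (anyNA(X)) abort("climate values must not be missing")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    abort(sprintf("constant climate variable: %s",
                  paste(vars[sds == 0], collapse = ", ")))
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  structure(list(
    scores = tibble(species = occ$species,
                    axis1 = pc$x[, 1], axis2 = pc$x[, 2]),
    loadings = pc$rotation[, 1:2],
    sdev = pc$sdev,
    var_explained = sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  ), class = "env_space")
}

#' @export
#' @method print env_space
print.env_space <- function(x, ...) {
  cat(sprintf("<env_space> %d occurrences, %d species, axes hold %.1f%% of variance\n",
              nrow(x$scores), length(unique(x$scores$species)),
              100 * x$var_explained))
  invisible(x)
}

#' Tidy environmental-space scores
#'
#' @param x An `env_space`.
#' @param ... Unused.
#' @return The scores tibble.
#' @export
tidy.env_space <- function(x, ...) x$scores

#' Kernel-smoothed occupancy densities on a shared environment grid
#'
#' Smooths each species' scores with a Gaussian kernel
#' ([MASS::kde2d()]) on one grid spanning the pooled extent and
#' normalizes each density to sum to 1.  The default bandwidth is
#' Scott's rule per axis (`sd * n^(-1/6)`).
#'
#' @param env An `env_space` from [env_axes()], or a data frame with
#'   `species`, `axis1`, `axis2`.
#' @param R Grid resolution per axis (default 100).
#' @param bandwidth Optional numeric bandwidth (kernel standard
#'   deviation), length 1 or 2.
#' @param expand Fractional extension of the pooled range (default
#'   0.1) so densities are not clipped at the margin.
#' @return An `env_grid`: grid coordinates `x`, `y` and a named list `z`
#'   of per-species densities, each summing to 1.
#' @export
density_grid <- function(env, R = 100, bandwidth = NULL, expand = 0.1) {
  scores <- if (inherits(env, "env_space")) env$scores else as_tibble(env)
  rng_x <- range(scores$axis1); rng_y <- range(scores$axis2)
  pad <- c(-1, 1) * expand * max(diff(rng_x), diff(rng_y), 1e-8)
  lims <- c(rng_x + pad, rng_y + pad)
  z <- lapply(split(scores, scores$species), function(sp) {
    n <- nrow(sp)
    if (n < 5) abort("need at least 5 occurrences per species")
    bw <- bandwidth %||% c(sd(sp$axis1), sd(sp$axis2)) * n^(-1 / 6)
    if (length(bw) == 1) bw <- rep(bw, 2)
    if (any(bw <= 0)) abort("bandwidth must be positive (constant coordinates?)")
    # kde2d's h is 4x the kernel standard deviation
    k <- MASS::kde2d(sp$axis1, sp$axis2, h = 4 * bw, n = R, lims = lims)
    k$z / sum(k$z)
  })
  structure(list(x = seq(lims[1], lims[2], length.out = R),
                 y = seq(lims[3], lims[4], length.out = R),
                 z = z), class = "env_grid")
}

#' Schoener's niche-overlap statistic D
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over the shared grid: 0 for disjoint
#' occupancy, 1 for identical occupancy.
#'
#' @param z1,z2 Density matrices on the same grid, or (first form) an
#'   `env_grid` plus two species names.
#' @return A value in \[0, 1\].
#' @export
schoener_d <- function(z1, z2) {
  if (inherits(z1, "env_grid")) {
    grid <- z1
    if (!all(z2 %in% names(grid$z)))
      abort("species not found in the density grid")
    z1 <- grid$z[[z2[1]]]; z2 <- grid$z[[z2[2]]]
  }
  if (!identical(dim(z1), dim(z2))) abort("densities are on different grids")
  1 - 0.5 * sum(abs(z1 / sum(z1) - z2 / sum(z2)))
}

#' Pairwise niche overlap from an occurrence table
#'
#' Convenience wrapper: ordination ([env_axes()]), shared-grid densities
#' ([density_grid()]), then [schoener_d()] for every species pair.
#'
#' @inheritParams env_axes
#' @inheritParams density_grid
#' @return A tibble with `species_a`, `species_b`, `schoener_d`.
#' @export
niche_overlap <- function(occ, R = 100, bandwidth = NULL) {
  grid <- density_grid(env_axes(occ), R = R, bandwidth = bandwidth)
  sps <- names(grid$z)
  pairs <- utils::combn(sps, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i)
    tibble(species_a = pairs[1, i], species_b = pairs[2, i],
           schoener_d = schoener_d(grid, c(pairs[1, i], pairs[2, i]))))
}
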