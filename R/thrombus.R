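#' Thrombus-occurrence likelihood at a point
#'
#' The likelihood field is the exact reciprocal of an independent trivariate
#' normal density centred on the oxygenator (mu = 0, sigma = (0.045, 0.045,
#' 0.025) m, half the box dimensions): blood flow is fastest in the centre
#' and stagnates near walls and corners, so the thrombus likelihood is lowest
#' in the centre and highest in the corners,
#' `L = sx sy sz (2 pi)^{3/2} exp(sum_d (d - mu_d)^2 / (2 sigma_d^2))`.
#'
#' @param x,y,z Coordinates in m (vectorized).
#' @param sigma Length-3 standard deviations in m.
#' @param mu Length-3 means in m.
#' @return Likelihood values (m^3 scale; only ratios and ranks matter).
#' @examples
#' likelihood(0, 0, 0)                      # ~7.97e-4, the central minimum
#' likelihood(0.045, 0.045, 0.025) / likelihood(0, 0, 0)  # exp(1.5)
#' @export
likelihood <- function(x, y, z, sigma = c(0.045, 0.045, 0.025), mu = c(0, 0, 0)) {
  prod(sigma) * (2 * pi)^(3 / 2) *
    exp((x - mu[1])^2 / (2 * sigma[1]^2) +
        (y - mu[2])^2 / (2 * sigma[2]^2) +
        (z - mu[3])^2 / (2 * sigma[3]^2))
}

#' Voxelized thrombus-likelihood field with CDF
#'
#' Evaluates [likelihood()] on a regular voxel grid over the box interior,
#' normalizes it to a probability field, and prepares the sorted cumulative
#' distribution used for percentile-based placement sampling.
#'
#' @param geom An [oxy_geometry()].
#' @param voxel Voxel edge length in m (default 0.002).
#' @param sigma,mu Passed to [likelihood()].
#' @return Object of class `likelihood_field`: list with voxel `centers`
#'   (n x 3), `L`, probabilities `p` (summing to 1), and the increasing
#'   ordering `ord` of `L`.
#' @export
likelihood_field <- function(geom = oxy_geometry(), voxel = 0.002,
                             sigma = c(0.045, 0.045, 0.025), mu = c(0, 0, 0)) {
  stopifnot(voxel > 0)
  ax <- function(size) {
    n <- max(1L, round(size / voxel))
    seq(-size / 2 + size / n / 2, size / 2 - size / n / 2, length.out = n)
  }
  xs <- ax(geom$size_x); ys <- ax(geom$size_y); zs <- ax(geom$size_z)
  centers <- cbind(x = rep(xs, times = length(ys) * length(zs)),
                   y = rep(rep(ys, each = length(xs)), times = length(zs)),
                   z = rep(zs, each = length(xs) * length(ys)))
  L <- likelihood(centers[, 1], centers[, 2], centers[, 3], sigma = sigma, mu = mu)
  structure(list(centers = centers, L = L, p = L / sum(L),
                 ord = order(L), voxel = voxel, geom = geom,
                 sigma = sigma, mu = mu),
            class = "likelihood_field")
}

#' @export
print.likelihood_field <- function(x, ...) {
  cat(sprintf("thrombus likelihood field: %d voxels of %.3g m, L in [%.3e, %.3e]\n",
              length(x$L), x$voxel, min(x$L), max(x$L)))
  invisible(x)
}

#' Sample thrombus centres at a likelihood percentile
#'
#' The percentile is taken over the voxel-likelihood CDF (the fraction of
#' voxels with lower likelihood). Because the field has ellipsoidal isolines,
#' many voxels share (nearly) the likelihood value at a given percentile; the
#' returned centre is drawn uniformly among all voxels within a relative
#' tolerance band of that value, scattering repeated draws over the isoline.
#'
#' @param field A [likelihood_field()].
#' @param percentile Value in \[0, 100\].
#' @param seed Optional integer seed.
#' @param n Number of centres to draw (default 1).
#' @param band Relative half-width of the likelihood band (default 0.005);
#'   if the band is empty it is widened once by a factor of 10, then an
#'   error is raised.
#' @return An `n` x 3 matrix of voxel centres (m).
#' @export
sample_by_percentile <- function(field, percentile, seed = NULL, n = 1,
                                 band = 0.005) {
  stopifnot(inherits(field, "likelihood_field"),
            percentile >= 0, percentile <= 100)
  Ls <- field$L[field$ord]
  nv <- length(Ls)
  idx <- min(nv, max(1L, 1L + round(percentile / 100 * (nv - 1L))))
  v <- Ls[idx]
  for (b in c(band, band * 10)) {
    hits <- which(abs(field$L - v) <= b * v)
    if (length(hits) > 0) break
  }
  if (length(hits) == 0)
    stop("empty likelihood band at percentile ", percentile)
  pick <- function() hits[sample.int(length(hits), n, replace = n > length(hits))]
  sel <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  field$centers[sel, , drop = FALSE]
}

# unconstrained draw from the normalized voxel probability field
sample_voxels <- function(field, n, seed = NULL) {
  pick <- function() sample.int(length(field$p), n, replace = TRUE, prob = field$p)
  sel <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  field$centers[sel, , drop = FALSE]
}

#' Thrombus scenarios for electrode-array optimization
#'
#' Generates `n_sets` scenarios of `targets_per_set` spherical targets each.
#' All sets share the same percentile schedule (equidistant from 5 to 98 by
#' default, covering all oxygenator areas from near-centre to corner); the
#' voxel choice on each percentile isoline is seeded per set.
#'
#' @param field A [likelihood_field()].
#' @param n_sets,targets_per_set Scenario counts (defaults 12 and 6).
#' @param percentiles Percentile schedule; default equidistant over
#'   \[5, 98\] with `targets_per_set` points.
#' @param diameter Target diameter in m (default 0.01).
#' @param sigma_t Target conductivity in S/m (default clot).
#' @param seed Optional integer seed.
#' @return List of `thrombus_scenario` objects, each a data frame with
#'   columns `x`, `y`, `z`, `diameter`, `sigma`, `percentile`.
#' @export
make_training_sets <- function(field, n_sets = 12, targets_per_set = 6,
                               percentiles = seq(5, 98, length.out = targets_per_set),
                               diameter = 0.01,
                               sigma_t = oxy_conductivities()[["clot"]],
                               seed = NULL) {
  stopifnot(n_sets >= 1, targets_per_set >= 1,
            length(percentiles) == targets_per_set)
  base_seed <- seed %||% sample.int(2^31 - 1, 1)
  lapply(seq_len(n_sets), function(s) {
    centers <- do.call(rbind, lapply(seq_along(percentiles), function(k)
      sample_by_percentile(field, percentiles[k],
                           seed = (base_seed + 1000L * s + k) %% (2^31 - 1))))
    structure(data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                         diameter = diameter, sigma = sigma_t,
                         percentile = percentiles),
              class = c("thrombus_scenario", "data.frame"),
              seed = base_seed, set = s)
  })
}

#' Regular single-target grid for detector training
#'
#' A rectangular lattice of sphere centres such that every sphere of the
#' given diameter lies entirely inside the box; one single-target scenario
#' per centre. With the defaults (1 cm spheres, 4 mm lattice pitch in-plane
#' and 5 mm vertically) the grid has 3,969 targets.
#'
#' @param geom An [oxy_geometry()].
#' @param diameter Sphere diameter in m (default 0.01).
#' @param spacing Length-3 lattice pitch in m (default
#'   `c(0.004, 0.004, 0.005)`); a scalar is recycled.
#' @param sigma_t Target conductivity in S/m.
#' @return A data frame of class `target_grid` with one row per target
#'   (`x`, `y`, `z`, `diameter`, `sigma`).
#' @export
make_target_grid <- function(geom = oxy_geometry(), diameter = 0.01,
                             spacing = c(0.004, 0.004, 0.005),
                             sigma_t = oxy_conductivities()[["clot"]]) {
  stopifnot(all(spacing > 0), diameter > 0)
  spacing <- rep(spacing, length.out = 3)
  r <- diameter / 2
  ax <- function(size, sp) {
    half <- size / 2 - r
    if (half < 0) return(numeric(0))
    k <- floor(half / sp)
    sp * (-k:k)
  }
  xs <- ax(geom$size_x, spacing[1]); ys <- ax(geom$size_y, spacing[2])
  zs <- ax(geom$size_z, spacing[3])
  centers <- expand.grid(x = xs, y = ys, z = zs)
  structure(data.frame(x = centers$x, y = centers$y, z = centers$z,
                       diameter = diameter, sigma = sigma_t),
            class = c("target_grid", "data.frame"))
}

# apply every target of a scenario (data frame rows) to a conductivity field
apply_scenario <- function(field, mesh, scenario) {
  for (i in seq_len(nrow(scenario)))
    field <- insert_spherical_target(field, mesh,
                                     center = c(scenario$x[i], scenario$y[i],
                                                scenario$z[i]),
                                     diameter = scenario$diameter[i],
                                     sigma_t = scenario$sigma[i])
  field
}
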