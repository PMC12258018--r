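#' Reference conductivities of the model components
#'
#' Blood at 0.662 S/m (IT'IS tissue database value used for whole blood at
#' low frequency), clot at one tenth of blood (0.0662 S/m), and the
#' essentially non-conductive polycarbonate separation grid at 1e-6 S/m.
#'
#' @return Named numeric vector with elements `blood`, `clot`, `grid` (S/m).
#' @export
oxy_conductivities <- function() {
  c(blood = 0.662, clot = 0.0662, grid = 1e-6)
}

#' Per-element conductivity field
#'
#' @param mesh An [build_mesh()] mesh.
#' @param sigma_blood,sigma_grid Background (BG) and separation-grid (SG)
#'   conductivities in S/m.
#' @return Object of class `conductivity_field`: list with `sigma` (S/m per
#'   element) and the constants used.
#' @export
conductivity_field <- function(mesh, sigma_blood = oxy_conductivities()[["blood"]],
                               sigma_grid = oxy_conductivities()[["grid"]]) {
  stopifnot(inherits(mesh, "oxy_mesh"), sigma_blood > 0, sigma_grid > 0)
  sigma <- ifelse(mesh$region == "SG", sigma_grid, sigma_blood)
  structure(list(sigma = sigma, sigma_blood = sigma_blood,
                 sigma_grid = sigma_grid),
            class = "conductivity_field")
}

#' Insert a spherical conductivity target (thrombus) into a field
#'
#' Every element whose centroid lies within `diameter / 2` of `center` is set
#' to `sigma_t`; all other elements are unchanged. A sphere that captures no
#' element centroid is below the mesh resolution and raises an error.
#'
#' @param field A [conductivity_field()].
#' @param mesh The mesh the field lives on.
#' @param center Numeric length-3 sphere centre (m), inside the box.
#' @param diameter Sphere diameter in m.
#' @param sigma_t Target conductivity in S/m
#'   (default [oxy_conductivities()]`["clot"]`).
#' @return The modified `conductivity_field`.
#' @export
insert_spherical_target <- function(field, mesh, center, diameter,
                                    sigma_t = oxy_conductivities()[["clot"]]) {
  stopifnot(inherits(field, "conductivity_field"), inherits(mesh, "oxy_mesh"),
            length(center) == 3, diameter > 0, sigma_t > 0)
  g <- mesh$geom
  if (abs(center[1]) > g$size_x / 2 || abs(center[2]) > g$size_y / 2 ||
      abs(center[3]) > g$size_z / 2)
    stop("target center lies outside the oxygenator box")
  d2 <- (mesh$centroid[, 1] - center[1])^2 +
        (mesh$centroid[, 2] - center[2])^2 +
        (mesh$centroid[, 3] - center[3])^2
  hit <- d2 <= (diameter / 2)^2
  if (!any(hit))
    stop(sprintf("target (diameter %.3g m) intersects no element centroid: below mesh resolution (max_h = %.3g m)",
                 diameter, mesh$max_h))
  field$sigma[hit] <- sigma_t
  field
}
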