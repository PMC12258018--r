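#' Parametric oxygenator geometry
#'
#' Describes the simplified oxygenator interior: a rectangular box (origin at
#' the box centre, z vertical) with a separation grid of orthogonal cylindrical
#' rods spanning a horizontal plane at mid-height. All lengths are in meters.
#'
#' The separation grid emulates the polycarbonate compartment divider of a
#' real hollow-fiber oxygenator; it is electrically almost non-conductive and
#' is modelled as an orthogonal lattice of rods (the manufacturer's exact rod
#' count is not public, so the lattice is configurable).
#'
#' @param size_x,size_y,size_z Interior box dimensions in m
#'   (default 0.09 x 0.09 x 0.05).
#' @param rod_diameter Separation-grid rod diameter in m (default 0.004).
#'   Use 0 for no grid.
#' @param n_rods Number of rods per in-plane direction (default 5; the grid
#'   is `n_rods` rods parallel to x plus `n_rods` parallel to y).
#' @param rod_spacing Centre-to-centre rod spacing in m (default 0.018).
#' @param grid_plane_z Height of the grid plane in m (default 0, mid-height).
#' @return An object of class `oxy_geometry`.
#' @examples
#' geom <- oxy_geometry()
#' geom
#' @export
oxy_geometry <- function(size_x = 0.09, size_y = 0.09, size_z = 0.05,
                         rod_diameter = 0.004, n_rods = 5,
                         rod_spacing = 0.018, grid_plane_z = 0) {
  stopifnot(size_x > 0, size_y > 0, size_z > 0,
            rod_diameter >= 0, n_rods >= 0, rod_spacing > 0)
  if (rod_diameter >= min(size_x, size_y, size_z))
    stop("rod_diameter must be smaller than the smallest box dimension")
  r <- rod_diameter / 2
  offs <- rod_offsets(n_rods, rod_spacing)
  if (rod_diameter > 0 && n_rods > 0) {
    if (any(abs(offs) + r >= size_y / 2) || any(abs(offs) + r >= size_x / 2))
      stop("separation-grid rods extend outside the box; reduce n_rods or rod_spacing")
    if (abs(grid_plane_z) + r >= size_z / 2)
      stop("grid plane too close to the top/bottom boundary")
  }
  structure(list(size_x = size_x, size_y = size_y, size_z = size_z,
                 rod_diameter = rod_diameter, n_rods = n_rods,
                 rod_spacing = rod_spacing, grid_plane_z = grid_plane_z),
            class = "oxy_geometry")
}

rod_offsets <- function(n_rods, rod_spacing) {
  if (n_rods == 0) return(numeric(0))
  rod_spacing * (seq_len(n_rods) - (n_rods + 1) / 2)
}

#' @export
print.oxy_geometry <- function(x, ...) {
  cat(sprintf("oxygenator geometry: %.3g x %.3g x %.3g m box\n",
              x$size_x, x$size_y, x$size_z))
  cat(sprintf("  separation grid: %d + %d rods, diameter %.3g m, plane z = %.3g m\n",
              x$n_rods, x$n_rods, x$rod_diameter, x$grid_plane_z))
  invisible(x)
}

# Spoke angles (radians) of the 8 radial electrode slots per plane.
spoke_angles <- function() (0:7) * pi / 4

#' Maximal radial distance of an electrode slot
#'
#' Electrode centres lie on 8 radial spokes (45 degrees apart) on the top and
#' bottom plane. The spoke of angle theta leaves the square plane at
#' `min(half_x / |cos|, half_y / |sin|)`; for the default square cross-section
#' this is `0.045 / max(|cos|, |sin|)`.
#'
#' @param spoke Spoke index 0..7 (angle `spoke * 45` degrees), vectorized.
#' @param geom An [oxy_geometry()].
#' @return Maximal admissible radial distance in m for each spoke.
#' @export
slot_r_max <- function(spoke, geom = oxy_geometry()) {
  th <- spoke_angles()[spoke + 1L]
  pmin(ifelse(abs(cos(th)) < 1e-12, Inf, (geom$size_x / 2) / abs(cos(th))),
       ifelse(abs(sin(th)) < 1e-12, Inf, (geom$size_y / 2) / abs(sin(th))))
}

#' Construct an electrode array on the radial slot system
#'
#' Exactly 16 electrodes: one per spoke (0..7) on each of the top and bottom
#' planes. Electrodes are modelled with the complete electrode model: each has
#' a circular contact patch and a contact impedance.
#'
#' @param radial Numeric vector of 16 radial distances in m, ordered top
#'   spokes 0..7 then bottom spokes 0..7.
#' @param geom An [oxy_geometry()].
#' @param patch_radius Contact patch radius in m (default 0.004).
#' @param contact_impedance Contact impedance in Ohm m^2 (default 1e-4).
#' @return An object of class `electrode_array`: a data frame with one row per
#'   electrode (columns `plane`, `spoke`, `radial`, `x`, `y`, `z`).
#' @examples
#' arr <- electrode_array(rep(0.03, 16))
#' arr
#' @export
electrode_array <- function(radial, geom = oxy_geometry(),
                            patch_radius = 0.004, contact_impedance = 1e-4) {
  stopifnot(length(radial) == 16, all(is.finite(radial)))
  plane <- rep(c("top", "bottom"), each = 8L)
  spoke <- rep(0:7, times = 2L)
  rmax <- slot_r_max(spoke, geom)
  if (any(radial < 0) || any(radial > rmax + 1e-12))
    stop("electrode radial distance outside the plane for spokes: ",
         paste(spoke[radial < 0 | radial > rmax + 1e-12], collapse = ", "))
  th <- spoke_angles()[spoke + 1L]
  z <- ifelse(plane == "top", geom$size_z / 2, -geom$size_z / 2)
  out <- data.frame(plane = plane, spoke = spoke, radial = radial,
                    x = radial * cos(th), y = radial * sin(th), z = z)
  structure(out, class = c("electrode_array", "data.frame"),
            geom = geom, patch_radius = patch_radius,
            contact_impedance = contact_impedance)
}

#' Uniform and edge-placed reference arrays
#'
#' `uniform_array()` places every electrode at the same radial distance.
#' `edge_array()` places each electrode at a fixed fraction of its spoke's
#' maximal radial distance, i.e. along the edges/corners of the planes; this
#' symmetric corner-reaching layout is the reference array on which the
#' injection-measurement pattern is designed.
#'
#' @param radial Common radial distance in m.
#' @param frac Fraction of the per-spoke maximal radial distance (default 0.9).
#' @param geom An [oxy_geometry()].
#' @param ... Passed to [electrode_array()].
#' @return An `electrode_array`.
#' @export
uniform_array <- function(radial = 0.03, geom = oxy_geometry(), ...) {
  electrode_array(rep(radial, 16), geom = geom, ...)
}

#' @rdname uniform_array
#' @export
edge_array <- function(frac = 0.9, geom = oxy_geometry(), ...) {
  rmax <- slot_r_max(rep(0:7, 2), geom)
  electrode_array(frac * rmax, geom = geom, ...)
}

#' Draw a random electrode array
#'
#' Radial distances are drawn independently per slot from N(mu, sigma^2) and
#' rejected (re-sampled) while outside `[0, r_max(spoke)]`, preserving the
#' truncated-normal shape near the plane edges. Draw order is fixed (top
#' spokes 0..7, then bottom), so a seed reproduces the array exactly.
#'
#' @param mu_elpos,sigma_elpos Mean and standard deviation of the radial draw
#'   in m (defaults 0.030 and 0.012).
#' @param geom An [oxy_geometry()].
#' @param seed Optional integer seed.
#' @param max_attempts Rejection-sampling cap per electrode (default 1e4).
#' @param ... Passed to [electrode_array()].
#' @return An `electrode_array`.
#' @export
generate_random_array <- function(mu_elpos = 0.030, sigma_elpos = 0.012,
                                  geom = oxy_geometry(), seed = NULL,
                                  max_attempts = 1e4, ...) {
  stopifnot(mu_elpos >= 0, sigma_elpos >= 0)
  draw <- function() {
    spoke <- rep(0:7, 2)
    rmax <- slot_r_max(spoke, geom)
    radial <- numeric(16)
    for (i in 1:16) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        r <- stats::rnorm(1, mu_elpos, sigma_elpos)
        if (r >= 0 && r <= rmax[i]) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf("no admissible radial draw for spoke %d after %d attempts (mu=%g, sigma=%g)",
                     spoke[i], max_attempts, mu_elpos, sigma_elpos))
      radial[i] <- r
    }
    radial
  }
  radial <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  electrode_array(radial, geom = geom, ...)
}

#' Snap free 3D electrode coordinates to the radial slot system
#'
#' Maps 16 arbitrary coordinate triples to valid slots: each point goes to the
#' (plane, spoke) slot minimizing the Euclidean distance to the nearest point
#' of the spoke segment (radial distance clamped to `[0, r_max]`). If several
#' points contend for one slot the closest one wins and the others move to
#' their next-nearest free slot; ties break on the lower electrode index.
#'
#' @param coords A 16 x 3 numeric matrix (x, y, z in m) or length-48 vector
#'   (row-major per electrode).
#' @param geom An [oxy_geometry()].
#' @param ... Passed to [electrode_array()].
#' @return An `electrode_array`; snapping is idempotent.
#' @export
snap_to_slots <- function(coords, geom = oxy_geometry(), ...) {
  if (is.numeric(coords) && is.null(dim(coords))) {
    stopifnot(length(coords) == 48)
    coords <- matrix(coords, nrow = 16, byrow = TRUE)
  }
  stopifnot(is.matrix(coords), nrow(coords) == 16, ncol(coords) == 3)
  slots <- data.frame(plane = rep(c("top", "bottom"), each = 8),
                      spoke = rep(0:7, 2))
  rmax <- slot_r_max(slots$spoke, geom)
  th <- spoke_angles()[slots$spoke + 1L]
  zs <- ifelse(slots$plane == "top", geom$size_z / 2, -geom$size_z / 2)
  # distance of each point to each slot, with the clamped radial projection
  D <- matrix(NA_real_, 16, 16)
  Tproj <- matrix(NA_real_, 16, 16)
  for (s in 1:16) {
    t_raw <- coords[, 1] * cos(th[s]) + coords[, 2] * sin(th[s])
    t_cl <- pmin(pmax(t_raw, 0), rmax[s])
    dx <- coords[, 1] - t_cl * cos(th[s])
    dy <- coords[, 2] - t_cl * sin(th[s])
    dz <- coords[, 3] - zs[s]
    D[, s] <- sqrt(dx^2 + dy^2 + dz^2)
    Tproj[, s] <- t_cl
  }
  assigned <- rep(NA_integer_, 16)
  free <- rep(TRUE, 16)
  while (anyNA(assigned)) {
    pend <- which(is.na(assigned))
    want <- vapply(pend, function(e) {
      fs <- which(free)
      fs[which.min(D[e, fs])]
    }, integer(1))
    for (s in unique(want)) {
      cand <- pend[want == s]
      win <- cand[which.min(D[cand, s])]   # which.min is first-min: low index wins ties
      assigned[win] <- s
      free[s] <- FALSE
    }
  }
  radial <- numeric(16)
  radial[assigned] <- Tproj[cbind(seq_len(16), assigned)]
  electrode_array(radial, geom = geom, ...)
}

#' Symmetrize an electrode array
#'
#' Replaces, per plane, all 8 radial distances by their common mean (clamped
#' to the smallest per-spoke maximum so all spokes stay valid and equal).
#' This is the deterministic counterpart of manually regularizing a proposed
#' array to match the device's rotational symmetry; it is never applied
#' implicitly.
#'
#' @param array An `electrode_array`.
#' @return An `electrode_array` with one radial distance per plane.
#' @export
symmetrize_array <- function(array) {
  stopifnot(inherits(array, "electrode_array"))
  geom <- attr(array, "geom")
  rcap <- min(slot_r_max(0:7, geom))
  radial <- array$radial
  for (pl in c("top", "bottom")) {
    i <- array$plane == pl
    radial[i] <- min(mean(radial[i]), rcap)
  }
  electrode_array(radial, geom = geom,
                  patch_radius = attr(array, "patch_radius"),
                  contact_impedance = attr(array, "contact_impedance"))
}
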