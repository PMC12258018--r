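#' Build a tetrahedral mesh of the oxygenator interior
#'
#' Deterministic structured mesher: the box is divided into a regular grid of
#' hexahedral cells no larger than `max_h` per axis, and each cell is split
#' into 6 tetrahedra by the Kuhn (Freudenthal) subdivision along the cell
#' diagonal. The subdivision contains one tetrahedron per axis permutation,
#' so the mesh conforms across cells and is exactly invariant under the
#' x <-> y transposition for a square cross-section. Elements are labelled
#' `BG` (blood background) or `SG` (separation grid) by whether their
#' centroid lies within a rod radius of a grid rod axis; rods are interior
#' subregions, so the summed element volume equals the box volume exactly.
#'
#' @param geom An [oxy_geometry()].
#' @param max_h Target maximal element edge length in m (default 0.002).
#' @return An object of class `oxy_mesh`: list with `nodes` (n x 3),
#'   `elems` (ne x 4 node indices, positively oriented), `region` (character,
#'   `"BG"`/`"SG"`), `vol` (element volumes, m^3), `centroid` (ne x 3),
#'   `max_h`, `geom` and the grid resolution `n_cells`.
#' @examples
#' m <- build_mesh(oxy_geometry(), max_h = 0.01)
#' m
#' @export
build_mesh <- function(geom, max_h = 0.002) {
  stopifnot(inherits(geom, "oxy_geometry"), max_h > 0)
  nx <- max(1L, ceiling(geom$size_x / max_h))
  ny <- max(1L, ceiling(geom$size_y / max_h))
  nz <- max(1L, ceiling(geom$size_z / max_h))
  hx <- geom$size_x / nx; hy <- geom$size_y / ny; hz <- geom$size_z / nz
  xs <- seq(-geom$size_x / 2, geom$size_x / 2, length.out = nx + 1L)
  ys <- seq(-geom$size_y / 2, geom$size_y / 2, length.out = ny + 1L)
  zs <- seq(-geom$size_z / 2, geom$size_z / 2, length.out = nz + 1L)
  nodes <- cbind(x = rep(xs, times = (ny + 1L) * (nz + 1L)),
                 y = rep(rep(ys, each = nx + 1L), times = nz + 1L),
                 z = rep(zs, each = (nx + 1L) * (ny + 1L)))
  nid <- function(ix, iy, iz) 1L + ix + (nx + 1L) * (iy + (ny + 1L) * iz)

  # Kuhn subdivision: one tet per permutation of the axes; vertices are the
  # lattice path 0 -> e_p1 -> e_p1+e_p2 -> (1,1,1) within each cell.
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  offs <- array(0L, dim = c(6L, 4L, 3L))
  for (p in 1:6) {
    e <- diag(3L)
    offs[p, 2L, ] <- e[perms[p, 1], ]
    offs[p, 3L, ] <- e[perms[p, 1], ] + e[perms[p, 2], ]
    offs[p, 4L, ] <- c(1L, 1L, 1L)
  }
  cix <- rep(0:(nx - 1L), times = ny * nz)
  ciy <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  ciz <- rep(0:(nz - 1L), each = nx * ny)
  ncell <- nx * ny * nz
  elems <- matrix(0L, nrow = 6L * ncell, ncol = 4L)
  for (p in 1:6) {
    rows <- seq.int(p, by = 6L, length.out = ncell)
    for (v in 1:4) {
      elems[rows, v] <- nid(cix + offs[p, v, 1L], ciy + offs[p, v, 2L],
                            ciz + offs[p, v, 3L])
    }
  }

  storage.mode(elems) <- "integer"
  vol <- tet_signed_volume(nodes, elems)
  neg <- vol < 0
  if (any(neg)) {   # enforce positive orientation
    tmp <- elems[neg, 3L]
    elems[neg, 3L] <- elems[neg, 4L]
    elems[neg, 4L] <- tmp
    vol[neg] <- -vol[neg]
  }
  if (any(vol <= 0))
    stop("degenerate mesh element produced; geometry: ",
         paste(deparse(unclass(geom)), collapse = " "))

  centroid <- (nodes[elems[, 1L], ] + nodes[elems[, 2L], ] +
               nodes[elems[, 3L], ] + nodes[elems[, 4L], ]) / 4
  region <- rep("BG", nrow(elems))
  if (geom$rod_diameter > 0 && geom$n_rods > 0) {
    r2 <- (geom$rod_diameter / 2)^2
    offsr <- rod_offsets(geom$n_rods, geom$rod_spacing)
    dz2 <- (centroid[, 3L] - geom$grid_plane_z)^2
    in_grid <- rep(FALSE, nrow(elems))
    for (o in offsr) {
      in_grid <- in_grid | (centroid[, 2L] - o)^2 + dz2 <= r2  # rod along x
      in_grid <- in_grid | (centroid[, 1L] - o)^2 + dz2 <= r2  # rod along y
    }
    region[in_grid] <- "SG"
  }

  structure(list(nodes = nodes, elems = elems, region = region, vol = vol,
                 centroid = centroid, max_h = max_h, geom = geom,
                 n_cells = c(nx = nx, ny = ny, nz = nz),
                 h = c(hx = hx, hy = hy, hz = hz)),
            class = "oxy_mesh")
}

tet_signed_volume <- function(nodes, elems) {
  a <- nodes[elems[, 2L], , drop = FALSE] - nodes[elems[, 1L], , drop = FALSE]
  b <- nodes[elems[, 3L], , drop = FALSE] - nodes[elems[, 1L], , drop = FALSE]
  d <- nodes[elems[, 4L], , drop = FALSE] - nodes[elems[, 1L], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' @export
print.oxy_mesh <- function(x, ...) {
  cat(sprintf("oxygenator mesh: %d nodes, %d tetrahedra (max_h = %.3g m)\n",
              nrow(x$nodes), nrow(x$elems), x$max_h))
  cat(sprintf("  regions: BG %d, SG %d; total volume %.6g m^3\n",
              sum(x$region == "BG"), sum(x$region == "SG"), sum(x$vol)))
  invisible(x)
}

# Boundary triangles lying on the top (+z) or bottom (-z) plane, as a matrix
# of node triples. Each tet face whose three nodes all sit on the plane is one
# boundary triangle; the structured mesh yields two triangles per surface quad.
plane_faces <- function(mesh, plane = c("top", "bottom")) {
  plane <- match.arg(plane)
  zb <- if (plane == "top") mesh$geom$size_z / 2 else -mesh$geom$size_z / 2
  tol <- 1e-9
  on_plane <- abs(mesh$nodes[, 3L] - zb) < tol
  cnt <- on_plane[mesh$elems[, 1L]] + on_plane[mesh$elems[, 2L]] +
         on_plane[mesh$elems[, 3L]] + on_plane[mesh$elems[, 4L]]
  cand <- which(cnt == 3L)
  faces <- matrix(0L, length(cand), 3L)
  for (k in seq_along(cand)) {
    vs <- mesh$elems[cand[k], ]
    faces[k, ] <- vs[on_plane[vs]]
  }
  unique_faces <- unique(t(apply(faces, 1, sort)))
  unique_faces
}

tri_area <- function(nodes, faces) {
  a <- nodes[faces[, 2L], , drop = FALSE] - nodes[faces[, 1L], , drop = FALSE]
  b <- nodes[faces[, 3L], , drop = FALSE] - nodes[faces[, 1L], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}
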