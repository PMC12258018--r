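#' Four-point injection-measurement pattern
#'
#' A frame of four-point (tetrapolar) measurements: for each entry a current
#' is driven through the inject pair `(inj_a, inj_b)` and the voltage is read
#' across the disjoint measure pair `(meas_c, meas_d)`. Electrode indices are
#' 1..16 (top spokes 0..7 are electrodes 1..8, bottom spokes are 9..16).
#' Patterns must be reciprocity-unique: an entry with inject and measure
#' pairs swapped carries the same transfer impedance and is rejected.
#'
#' @param df Data frame (or matrix) with columns `inj_a`, `inj_b`, `meas_c`,
#'   `meas_d`.
#' @param amplitude Injected current in A (default 1; relative voltage
#'   differences are amplitude-invariant).
#' @return Object of class `im_pattern`.
#' @export
im_pattern <- function(df, amplitude = 1) {
  df <- as.data.frame(df)
  need <- c("inj_a", "inj_b", "meas_c", "meas_d")
  if (!all(need %in% names(df))) {
    stopifnot(ncol(df) == 4)
    names(df) <- need
  }
  df <- df[need]
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  stopifnot(all(m >= 1L), all(m <= 16L))
  if (any(m[, 1] == m[, 2]) || any(m[, 3] == m[, 4]))
    stop("inject/measure pair with identical electrodes")
  share <- (m[, 1] == m[, 3]) | (m[, 1] == m[, 4]) |
           (m[, 2] == m[, 3]) | (m[, 2] == m[, 4])
  if (any(share))
    stop("measurement(s) not four-point: inject and measure pairs share an electrode: rows ",
         paste(which(share), collapse = ", "))
  key <- measurement_keys(m)
  swapped <- measurement_keys(m[, c(3, 4, 1, 2), drop = FALSE])
  comb <- paste(pmin(key, swapped), pmax(key, swapped))
  if (any(duplicated(comb)))
    stop("pattern contains reciprocity-duplicate measurements: rows ",
         paste(which(duplicated(comb)), collapse = ", "))
  meas <- as.data.frame(m)
  rownames(meas) <- NULL
  structure(list(meas = meas, amplitude = amplitude), class = "im_pattern")
}

# canonical string key of (inject pair | measure pair), pair order normalized
measurement_keys <- function(m) {
  paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), "|",
        pmin(m[, 3], m[, 4]), pmax(m[, 3], m[, 4]))
}

#' @export
print.im_pattern <- function(x, ...) {
  cat(sprintf("injection-measurement pattern: %d four-point measurements, %d unique inject pairs, amplitude %g A\n",
              nrow(x$meas), nrow(unique(t(apply(x$meas[, 1:2], 1, sort)))),
              x$amplitude))
  invisible(x)
}

#' @export
length.im_pattern <- function(x) nrow(x$meas)

# ---------------------------------------------------------------------------
# mesh-level FEM precomputation (array-independent, reusable across arrays)

mesh_fem <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  ne <- nrow(el); nn <- nrow(nd)
  d1 <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  d2 <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  d3 <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cr(d2, d3); c31 <- cr(d3, d1); c12 <- cr(d1, d2)
  det <- rowSums(d1 * c23)            # = 6 * signed volume (> 0 here)
  g2 <- c23 / det; g3 <- c31 / det; g4 <- c12 / det
  g1 <- -(g2 + g3 + g4)
  G <- array(0, dim = c(ne, 4L, 3L))
  G[, 1, ] <- g1; G[, 2, ] <- g2; G[, 3, ] <- g3; G[, 4, ] <- g4

  # geometric element stiffness triplets (value scales linearly with sigma_e)
  li <- c(1, 2, 3, 4, 1, 1, 1, 2, 2, 3)
  lj <- c(1, 2, 3, 4, 2, 3, 4, 3, 4, 4)
  npair <- length(li)
  ti <- integer(ne * npair); tj <- integer(ne * npair); tw <- numeric(ne * npair)
  eid <- integer(ne * npair)
  for (p in seq_len(npair)) {
    idx <- seq.int((p - 1L) * ne + 1L, p * ne)
    gi <- el[, li[p]]; gj <- el[, lj[p]]
    ti[idx] <- pmax(gi, gj); tj[idx] <- pmin(gi, gj)
    tw[idx] <- mesh$vol * rowSums(G[, li[p], ] * G[, lj[p], ])
    eid[idx] <- seq_len(ne)
  }

  # sparse per-element gradient operators: (Gx %*% u)[e] = d(u)/dx on element e
  rows <- rep(seq_len(ne), 4L)
  cols <- as.vector(el)
  Gx <- Matrix::sparseMatrix(i = rows, j = cols, x = as.vector(G[, , 1L]),
                             dims = c(ne, nn))
  Gy <- Matrix::sparseMatrix(i = rows, j = cols, x = as.vector(G[, , 2L]),
                             dims = c(ne, nn))
  Gz <- Matrix::sparseMatrix(i = rows, j = cols, x = as.vector(G[, , 3L]),
                             dims = c(ne, nn))
  list(ti = ti, tj = tj, tw = tw, eid = eid, Gx = Gx, Gy = Gy, Gz = Gz)
}

# ---------------------------------------------------------------------------

#' Build a complete-electrode-model forward solver
#'
#' Precomputes everything that does not depend on the conductivity field:
#' element stiffness geometry, electrode contact patches (boundary triangles
#' on the electrode's plane whose centroid lies within the patch radius; if
#' the mesh is too coarse for any triangle to qualify, the nearest triangle
#' is used), the contact-impedance boundary terms of the complete electrode
#' model, and the symbolic sparse Cholesky factorization. The constant-
#' potential gauge freedom is removed by grounding one mesh node; measured
#' voltages are electrode-pair differences and do not depend on the gauge.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param array An [electrode_array()]; its `patch_radius` and
#'   `contact_impedance` attributes define the contact model.
#' @param fem Optional precomputed result of the internal mesh FEM setup, to
#'   share across many arrays on the same mesh.
#' @return Object of class `forward_solver`.
#' @export
forward_solver <- function(mesh, array, fem = NULL) {
  stopifnot(inherits(mesh, "oxy_mesh"), inherits(array, "electrode_array"))
  if (is.null(fem)) fem <- mesh_fem(mesh)
  nn <- nrow(mesh$nodes)
  zc <- attr(array, "contact_impedance")
  pr <- attr(array, "patch_radius")
  stopifnot(zc > 0, pr > 0)

  faces <- list(top = plane_faces(mesh, "top"), bottom = plane_faces(mesh, "bottom"))
  fcent <- lapply(faces, function(f)
    (mesh$nodes[f[, 1], , drop = FALSE] + mesh$nodes[f[, 2], , drop = FALSE] +
     mesh$nodes[f[, 3], , drop = FALSE]) / 3)
  farea <- lapply(faces, function(f) tri_area(mesh$nodes, f))

  bi <- integer(0); bj <- integer(0); bw <- numeric(0)
  bvec <- vector("list", 16L)   # node-load vectors b_l for current bookkeeping
  dl <- numeric(16L)
  patch_faces <- vector("list", 16L)
  for (l in 1:16) {
    pl <- array$plane[l]
    f <- faces[[pl]]; cen <- fcent[[pl]]; ar <- farea[[pl]]
    d2 <- (cen[, 1] - array$x[l])^2 + (cen[, 2] - array$y[l])^2
    # all faces inside the patch; on meshes too coarse to resolve the patch,
    # all faces tied at the minimal distance (keeps symmetric configurations
    # symmetric instead of breaking ties arbitrarily)
    sel <- which(d2 <= max(pr^2, min(d2) * (1 + 1e-9)))
    patch_faces[[l]] <- f[sel, , drop = FALSE]
    A <- ar[sel]
    eldof <- nn + l
    nsel <- length(sel)
    fsel <- f[sel, , drop = FALSE]
    # triangle mass matrix / z: diag A/6, off-diag A/12
    mi <- c(fsel[, 1], fsel[, 2], fsel[, 3])
    mw_diag <- rep(A / (6 * zc), 3L)
    oi <- c(fsel[, 1], fsel[, 1], fsel[, 2])
    oj <- c(fsel[, 2], fsel[, 3], fsel[, 3])
    ow <- rep(A / (12 * zc), 3L)
    # node-electrode coupling -A/(3 z) and electrode diagonal |patch|/z
    ci <- rep(eldof, 3L * nsel)
    cj <- mi
    cw <- rep(-A / (3 * zc), 3L)
    bi <- c(bi, mi, pmax(oi, oj), ci, eldof)
    bj <- c(bj, mi, pmin(oi, oj), cj, eldof)
    bw <- c(bw, mw_diag, ow, cw, sum(A) / zc)
    bl <- numeric(nn)
    agg <- rowsum(rep(A / (3 * zc), 3L), mi)
    bl[as.integer(rownames(agg))] <- agg[, 1]
    bvec[[l]] <- bl
    dl[l] <- sum(A) / zc
  }

  ground <- 1L
  ndof <- nn + 16L
  map <- integer(ndof); keep <- setdiff(seq_len(ndof), ground)
  map[keep] <- seq_along(keep); map[ground] <- NA_integer_
  efilter <- !(fem$ti == ground | fem$tj == ground)
  bfilter <- !(bi == ground | bj == ground)

  solver <- structure(list(
    mesh = mesh, array = array, fem = fem, nn = nn, ndof = ndof,
    m = ndof - 1L, ground = ground, map = map,
    ei = map[fem$ti[efilter]], ej = map[fem$tj[efilter]],
    ew = fem$tw[efilter], eid = fem$eid[efilter],
    fi = map[bi[bfilter]], fj = map[bj[bfilter]], fw = bw[bfilter],
    eldof = map[nn + 1:16], bvec = bvec, dl = dl,
    patch_faces = patch_faces,
    contact_impedance = zc, patch_radius = pr), class = "forward_solver")
  A0 <- assemble_system(solver, conductivity_field(mesh)$sigma)
  solver$chol0 <- tryCatch(
    Matrix::Cholesky(A0, LDL = FALSE),
    error = function(e) stop("forward system factorization failed (disconnected electrode?): ",
                             conditionMessage(e)))
  solver
}

#' @export
print.forward_solver <- function(x, ...) {
  cat(sprintf("complete-electrode-model forward solver: %d nodes + 16 electrodes, %d elements\n",
              x$nn, nrow(x$mesh$elems)))
  cat(sprintf("  contact impedance %g Ohm m^2, patch radius %g m, %d reduced dof\n",
              x$contact_impedance, x$patch_radius, x$m))
  invisible(x)
}

assemble_system <- function(solver, sigma) {
  Matrix::sparseMatrix(
    i = c(solver$ei, solver$fi), j = c(solver$ej, solver$fj),
    x = c(solver$ew * sigma[solver$eid], solver$fw),
    dims = c(solver$m, solver$m), symmetric = TRUE)
}

factorize_field <- function(solver, sigma, fresh = FALSE) {
  A <- assemble_system(solver, sigma)
  ch <- if (fresh) Matrix::Cholesky(A, LDL = FALSE)
        else Matrix::update(solver$chol0, A)
  list(chol = ch)
}

# Solve for a set of injection pairs (k x 2 matrix, electrode indices).
# Returns electrode potentials (16 x k) and, optionally, full nodal
# potentials (nn x k, ground node at zero).
solve_pairs <- function(solver, fct, pairs, amplitude = 1, want_nodal = FALSE) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  k <- nrow(pairs)
  B <- matrix(0, solver$m, k)
  B[cbind(solver$eldof[pairs[, 1]], seq_len(k))] <- amplitude
  B[cbind(solver$eldof[pairs[, 2]], seq_len(k))] <- -amplitude
  X <- as.matrix(Matrix::solve(fct$chol, B, system = "A"))
  Uel <- X[solver$eldof, , drop = FALSE]
  out <- list(Uel = Uel)
  if (want_nodal) {
    Unod <- matrix(0, solver$nn, k)
    nodal_keep <- setdiff(seq_len(solver$nn), solver$ground)
    Unod[nodal_keep, ] <- X[solver$map[nodal_keep], , drop = FALSE]
    out$Unod <- Unod
  }
  out
}

# net current through each electrode for one solved injection column
electrode_currents <- function(solver, Uel, Unod) {
  vapply(1:16, function(l)
    solver$dl[l] * Uel[l] - sum(solver$bvec[[l]] * Unod), numeric(1))
}

#' Solve the bioimpedance forward problem for one frame
#'
#' For every unique injection pair of the pattern the complete-electrode-model
#' system is solved once (a single sparse Cholesky factorization of the
#' conductivity-dependent system is shared by all injections); each
#' measurement voltage is the difference of the two measure-electrode
#' potentials.
#'
#' @param solver A [forward_solver()].
#' @param field A [conductivity_field()].
#' @param pattern An [im_pattern()].
#' @param reuse If `FALSE`, solve each injection with its own fresh
#'   factorization (reference path; numerically identical to the shared
#'   factorization up to solver round-off).
#' @return Object of class `measurement_frame` with the voltage vector `v`
#'   (V), the pattern and the amplitude.
#' @export
solve_forward <- function(solver, field, pattern, reuse = TRUE) {
  stopifnot(inherits(solver, "forward_solver"),
            inherits(field, "conductivity_field"),
            inherits(pattern, "im_pattern"))
  m <- as.matrix(pattern$meas)
  if (reuse) {
    up <- unique_pairs(m[, 1:2, drop = FALSE])
    fct <- factorize_field(solver, field$sigma)
    sol <- solve_pairs(solver, fct, up$pairs, amplitude = pattern$amplitude)
    Uel <- sol$Uel[, up$index, drop = FALSE]
    Uel <- sweep(Uel, 2L, up$sign, `*`)
  } else {
    Uel <- matrix(0, 16L, nrow(m))
    for (i in seq_len(nrow(m))) {
      fct <- factorize_field(solver, field$sigma, fresh = TRUE)
      Uel[, i] <- solve_pairs(solver, fct, m[i, 1:2, drop = FALSE],
                              amplitude = pattern$amplitude)$Uel
    }
  }
  v <- Uel[cbind(m[, 3], seq_len(nrow(m)))] - Uel[cbind(m[, 4], seq_len(nrow(m)))]
  structure(list(v = v, pattern = pattern, amplitude = pattern$amplitude),
            class = "measurement_frame")
}

# normalize pairs to (min,max); return unique pairs, index into them for each
# input row, and the sign flip incurred by normalization
unique_pairs <- function(p) {
  p <- matrix(as.integer(p), ncol = 2L)
  sgn <- ifelse(p[, 1] <= p[, 2], 1, -1)
  pn <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  key <- paste(pn[, 1], pn[, 2])
  uk <- unique(key)
  list(pairs = pn[match(uk, key), , drop = FALSE],
       index = match(key, uk), sign = sgn)
}

#' @export
print.measurement_frame <- function(x, ...) {
  cat(sprintf("measurement frame: %d voltages, range [%.3e, %.3e] V\n",
              length(x$v), min(x$v), max(x$v)))
  invisible(x)
}

#' Relative voltage differences between two frames
#'
#' `dVr[i] = (v_inh[i] - v_hom[i]) / v_hom[i]`, the dimensionless relative
#' change of each measurement against the stored clean homogeneous reference.
#'
#' @param v_inh,v_hom `measurement_frame`s (or bare numeric vectors) on the
#'   same pattern and array.
#' @param floor Smallest admissible `|v_hom|` in V; a reference voltage below
#'   this is a degenerate measurement and raises an error (default 1e-12).
#' @return Numeric vector of relative voltage differences.
#' @export
delta_vr <- function(v_inh, v_hom, floor = 1e-12) {
  vi <- if (inherits(v_inh, "measurement_frame")) v_inh$v else as.numeric(v_inh)
  vh <- if (inherits(v_hom, "measurement_frame")) v_hom$v else as.numeric(v_hom)
  stopifnot(length(vi) == length(vh))
  bad <- abs(vh) < floor
  if (any(bad))
    stop("degenerate measurement(s): |reference voltage| below ", floor,
         " V at rows ", paste(which(bad), collapse = ", "))
  (vi - vh) / vh
}

#' Adjoint Jacobian sensitivity matrix
#'
#' Computes `J[i, j] = d v_i / d sigma_j` for every measurement i of the
#' pattern and every mesh element j, by the adjoint method:
#' `J[i, j] = -vol_j * grad(u_inj) . grad(u_meas)` on element j, where
#' `u_meas` solves the same system with unit current driven through the
#' measure pair. One linear solve per unique electrode pair (inject or
#' measure) is needed; all share one factorization. Values are per unit
#' injected current (V per S/m).
#'
#' @param solver A [forward_solver()].
#' @param field A [conductivity_field()].
#' @param pattern An [im_pattern()].
#' @return Dense matrix, one row per measurement, one column per element.
#' @export
compute_jacobian <- function(solver, field, pattern) {
  stopifnot(inherits(solver, "forward_solver"),
            inherits(field, "conductivity_field"),
            inherits(pattern, "im_pattern"))
  m <- as.matrix(pattern$meas)
  allp <- rbind(m[, 1:2, drop = FALSE], m[, 3:4, drop = FALSE])
  up <- unique_pairs(allp)
  nmeas <- nrow(m)
  fct <- factorize_field(solver, field$sigma)
  sol <- solve_pairs(solver, fct, up$pairs, amplitude = 1, want_nodal = TRUE)
  GX <- as.matrix(solver$fem$Gx %*% sol$Unod)
  GY <- as.matrix(solver$fem$Gy %*% sol$Unod)
  GZ <- as.matrix(solver$fem$Gz %*% sol$Unod)
  vol <- solver$mesh$vol
  J <- matrix(0, nmeas, nrow(solver$mesh$elems))
  for (i in seq_len(nmeas)) {
    ii <- up$index[i]; im <- up$index[nmeas + i]
    s <- up$sign[i] * up$sign[nmeas + i]
    J[i, ] <- -s * vol * (GX[, ii] * GX[, im] + GY[, ii] * GY[, im] +
                          GZ[, ii] * GZ[, im])
  }
  J
}
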