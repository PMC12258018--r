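test_that("pattern construction rejects malformed measurements", {
  expect_error(im_pattern(data.frame(inj_a = 1, inj_b = 1, meas_c = 3,
                                     meas_d = 4)), "identical electrodes")
  expect_error(im_pattern(data.frame(inj_a = 1, inj_b = 2, meas_c = 2,
                                     meas_d = 4)), "share an electrode")
  expect_error(im_pattern(data.frame(inj_a = c(1, 3), inj_b = c(2, 4),
                                     meas_c = c(3, 1), meas_d = c(4, 2))),
               "reciprocity")
})

test_that("swapping inject and measure pairs reproduces the voltage", {
  cb <- coarse_bundle()
  v1 <- solve_forward(cb$solver, cb$field, cb$pattern)
  swapped <- im_pattern(cb$pattern$meas[, c(3, 4, 1, 2)])
  v2 <- solve_forward(cb$solver, cb$field, swapped)
  expect_lt(max(abs(v1$v - v2$v) / abs(v1$v)), 1e-8)
})

test_that("mirror-symmetric measurements agree on the homogeneous field", {
  # the structured mesh is exactly invariant under the x <-> y transposition;
  # electrodes map spoke 0<->2, 1 fixed, 3<->7 etc. (angle th -> pi/2 - th)
  cb <- coarse_bundle()
  swap <- c(3L, 2L, 1L, 8L, 7L, 6L, 5L, 4L)
  swap <- c(swap, swap + 8L)
  pat <- im_pattern(data.frame(inj_a = 1, inj_b = 5, meas_c = 2, meas_d = 6))
  mir <- im_pattern(data.frame(inj_a = swap[1], inj_b = swap[5],
                               meas_c = swap[2], meas_d = swap[6]))
  v <- solve_forward(cb$solver, cb$field, pat)$v
  vm <- solve_forward(cb$solver, cb$field, mir)$v
  expect_lt(abs(v - vm) / abs(v), 1e-6)
})

test_that("voltages scale inversely with a uniform conductance scaling", {
  cb <- coarse_bundle()
  v1 <- solve_forward(cb$solver, cb$field, cb$pattern)
  arr2 <- electrode_array(cb$array$radial, geom = cb$geom,
                          patch_radius = attr(cb$array, "patch_radius"),
                          contact_impedance = attr(cb$array, "contact_impedance") / 2)
  s2 <- forward_solver(cb$mesh, arr2)
  f2 <- cb$field; f2$sigma <- 2 * f2$sigma
  v2 <- solve_forward(s2, f2, cb$pattern)
  expect_equal(v2$v, v1$v / 2, tolerance = 1e-12)
  # bulk-only scaling is approximate: contact terms do not scale
  v3 <- solve_forward(cb$solver, f2, cb$pattern)
  expect_equal(v3$v, v1$v / 2, tolerance = 0.05)
})

test_that("injected currents are conserved", {
  cb <- coarse_bundle()
  fct <- oxeit:::factorize_field(cb$solver, cb$field$sigma)
  for (pair in list(c(1L, 2L), c(3L, 11L), c(6L, 16L))) {
    sol <- oxeit:::solve_pairs(cb$solver, fct, matrix(pair, 1),
                               want_nodal = TRUE)
    I <- oxeit:::electrode_currents(cb$solver, sol$Uel[, 1], sol$Unod[, 1])
    expect_equal(I[pair[1]], 1, tolerance = 1e-10)
    expect_equal(I[pair[2]], -1, tolerance = 1e-10)
    expect_lt(max(abs(sum(I))), 1e-10)
  }
})

test_that("shared-factorization and per-injection solve paths agree", {
  cb <- coarse_bundle()
  v_fast <- solve_forward(cb$solver, cb$field, cb$pattern, reuse = TRUE)
  v_slow <- solve_forward(cb$solver, cb$field, cb$pattern, reuse = FALSE)
  expect_equal(v_fast$v, v_slow$v, tolerance = 1e-12)
})

test_that("relative voltage differences behave as defined", {
  cb <- coarse_bundle()
  v <- solve_forward(cb$solver, cb$field, cb$pattern)
  expect_identical(delta_vr(v, v), rep(0, length(v$v)))
  expect_error(delta_vr(v$v, rep(0, length(v$v))), "degenerate")

  # a clot near a measuring pair moves its measurement more than the same
  # clot in the centre moves any measurement
  near_el <- c(cb$array$x[5], cb$array$y[5], cb$array$z[5] - 0.006)
  # far clot: centred on the most central element centroid (guaranteed to
  # intersect the mesh at this coarse resolution)
  far <- cb$mesh$centroid[which.min(rowSums(cb$mesh$centroid^2)), ]
  f_near <- insert_spherical_target(cb$field, cb$mesh, near_el, 0.015)
  f_far <- insert_spherical_target(cb$field, cb$mesh, far, 0.015)
  d_near <- delta_vr(solve_forward(cb$solver, f_near, cb$pattern), v)
  d_far <- delta_vr(solve_forward(cb$solver, f_far, cb$pattern), v)
  expect_gt(max(abs(d_near)), max(abs(d_far)))
})

test_that("first-order response matches the Jacobian prediction", {
  cb <- coarse_bundle()
  J <- compute_jacobian(cb$solver, cb$field, cb$pattern)
  v0 <- solve_forward(cb$solver, cb$field, cb$pattern)
  set.seed(11)
  dsig <- rnorm(length(cb$field$sigma), 0, 1e-3 * 0.662)
  f1 <- cb$field; f1$sigma <- f1$sigma + dsig
  v1 <- solve_forward(cb$solver, f1, cb$pattern)
  lin <- drop(J %*% dsig)
  expect_lt(max(abs((v1$v - v0$v) - lin)) / max(abs(lin)), 0.1)

  # the clot-induced sign agrees with the Jacobian's first-order prediction
  near_el <- c(cb$array$x[5], cb$array$y[5], cb$array$z[5] - 0.006)
  f_cl <- insert_spherical_target(cb$field, cb$mesh, near_el, 0.015)
  dv <- solve_forward(cb$solver, f_cl, cb$pattern)$v - v0$v
  pred <- drop(J %*% (f_cl$sigma - cb$field$sigma))
  i <- which.max(abs(pred))
  expect_identical(sign(dv[i]), sign(pred[i]))
})

test_that("Jacobian rows of reciprocal descriptions are identical", {
  cb <- coarse_bundle()
  J1 <- compute_jacobian(cb$solver, cb$field, cb$pattern)
  swapped <- im_pattern(cb$pattern$meas[, c(3, 4, 1, 2)])
  J2 <- compute_jacobian(cb$solver, cb$field, swapped)
  expect_equal(J1, J2, tolerance = 1e-12)
})

test_that("sensitivity is largest next to the active electrodes", {
  cb <- coarse_bundle()
  pat <- im_pattern(data.frame(inj_a = 1, inj_b = 3, meas_c = 2, meas_d = 4))
  J <- compute_jacobian(cb$solver, cb$field, pat)
  els <- c(1L, 2L, 3L, 4L)
  d_act <- sapply(seq_len(nrow(cb$mesh$elems)), function(e) min(
    sqrt((cb$mesh$centroid[e, 1] - cb$array$x[els])^2 +
         (cb$mesh$centroid[e, 2] - cb$array$y[els])^2 +
         (cb$mesh$centroid[e, 3] - cb$array$z[els])^2)))
  near <- which.min(d_act)
  central <- which.min(rowSums(cb$mesh$centroid^2))
  expect_gt(abs(J[1, near]), abs(J[1, central]))
})
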