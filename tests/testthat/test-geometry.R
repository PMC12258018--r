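test_that("mesh conserves the box volume across resolutions", {
  geom <- oxy_geometry()
  box <- geom$size_x * geom$size_y * geom$size_z
  for (h in c(0.005, 0.01, 0.015)) {
    m <- build_mesh(geom, max_h = h)
    expect_lt(abs(sum(m$vol) - box) / box, 0.01)
    expect_true(all(m$vol > 0))
    expect_true(all(m$elems >= 1 & m$elems <= nrow(m$nodes)))
  }
})

test_that("2 mm mesh has on the order of 1e5 elements", {
  m <- build_mesh(oxy_geometry(), max_h = 0.002)
  expect_gt(nrow(m$elems), 1e5)
  expect_lt(nrow(m$elems), 1e6)
})

test_that("separation-grid labels sit on the rod lattice", {
  geom <- oxy_geometry()
  m <- build_mesh(geom, max_h = 0.005)
  sg <- m$centroid[m$region == "SG", , drop = FALSE]
  expect_gt(nrow(sg), 0)
  offs <- oxeit:::rod_offsets(geom$n_rods, geom$rod_spacing)
  r <- geom$rod_diameter / 2
  dz2 <- (sg[, 3] - geom$grid_plane_z)^2
  ok <- rep(FALSE, nrow(sg))
  for (o in offs) {
    ok <- ok | (sg[, 2] - o)^2 + dz2 <= r^2 | (sg[, 1] - o)^2 + dz2 <= r^2
  }
  expect_true(all(ok))
})

test_that("zero rod diameter yields a grid-free mesh", {
  m <- build_mesh(oxy_geometry(rod_diameter = 0), max_h = 0.01)
  expect_identical(sum(m$region == "SG"), 0L)
})

test_that("random arrays honor the truncated-normal draw model", {
  # zero variance pins every electrode at the mean
  arr0 <- generate_random_array(0.03, 0, seed = 1)
  expect_equal(arr0$radial, rep(0.03, 16))
  # determinism under a fixed seed
  a1 <- generate_random_array(0.03, 0.01, seed = 7)
  a2 <- generate_random_array(0.03, 0.01, seed = 7)
  expect_identical(a1$radial, a2$radial)
  # an infeasible mean exhausts the rejection cap
  expect_error(generate_random_array(0.2, 0.001, max_attempts = 50),
               "no admissible radial draw")
})

test_that("rejection sampling matches the truncated-normal mean", {
  mu <- 0.03; sd <- 0.012
  n <- 625   # 625 arrays * 16 electrodes = 1e4 draws
  draws <- unlist(lapply(seq_len(n), function(s)
    generate_random_array(mu, sd, seed = s)$radial))
  # spokes alternate between axis-aligned (r_max = 0.045) and diagonal caps
  rmax <- slot_r_max(rep(0:7, 2))
  for (cap in unique(rmax)) {
    idx <- rep(abs(rmax - cap) < 1e-9, n)
    x <- draws[idx]
    a <- (0 - mu) / sd; b <- (cap - mu) / sd
    tmean <- mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
    tvar <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / (pnorm(b) - pnorm(a)) -
                      ((dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a)))^2)
    se <- sqrt(tvar / length(x))
    expect_lt(abs(mean(x) - tmean), 3 * se)
  }
})

test_that("snapping free coordinates to slots matches brute force and is idempotent", {
  geom <- oxy_geometry()
  # coordinates already on slots: identity
  arr <- generate_random_array(0.02, 0.008, seed = 3)
  snapped <- snap_to_slots(cbind(arr$x, arr$y, arr$z), geom)
  expect_equal(snapped$radial, arr$radial, tolerance = 1e-12)
  # z sign decides the plane
  eps_pts <- cbind(arr$x, arr$y, ifelse(arr$plane == "top", 1, -1) * 0.001)
  snapped_eps <- snap_to_slots(eps_pts, geom)
  expect_identical(snapped_eps$plane, arr$plane)

  # random clouds: replicate the stated rule naively (nearest free slot,
  # closest contender wins, losers take their next-nearest free slot)
  slot_dist <- function(p, s) {
    th <- oxeit:::spoke_angles()[(s - 1) %% 8 + 1]
    rmx <- slot_r_max((s - 1) %% 8, geom)
    zs <- if (s <= 8) geom$size_z / 2 else -geom$size_z / 2
    t_cl <- min(max(p[1] * cos(th) + p[2] * sin(th), 0), rmx)
    sqrt((p[1] - t_cl * cos(th))^2 + (p[2] - t_cl * sin(th))^2 + (p[3] - zs)^2)
  }
  for (seed in 1:3) {
    set.seed(seed)
    pts <- cbind(runif(16, -0.05, 0.05), runif(16, -0.05, 0.05),
                 runif(16, -0.03, 0.03))
    D <- outer(seq_len(16), seq_len(16),
               Vectorize(function(e, s) slot_dist(pts[e, ], s)))
    assigned <- rep(NA_integer_, 16); free <- rep(TRUE, 16)
    while (anyNA(assigned)) {
      pend <- which(is.na(assigned))
      want <- sapply(pend, function(e) which(free)[which.min(D[e, free])])
      for (s in unique(want)) {
        cand <- pend[want == s]
        win <- cand[which.min(D[cand, s])]
        assigned[win] <- s; free[s] <- FALSE
      }
    }
    # expected radial distance per canonical slot from the naive assignment
    slot_radial <- function(p, s) {
      th <- oxeit:::spoke_angles()[(s - 1) %% 8 + 1]
      rmx <- slot_r_max((s - 1) %% 8, geom)
      min(max(p[1] * cos(th) + p[2] * sin(th), 0), rmx)
    }
    expected <- numeric(16)
    expected[assigned] <- sapply(seq_len(16), function(e)
      slot_radial(pts[e, ], assigned[e]))
    got <- snap_to_slots(pts, geom)
    expect_equal(got$radial, expected, tolerance = 1e-12)
    # idempotence
    again <- snap_to_slots(cbind(got$x, got$y, got$z), geom)
    expect_equal(again$radial, got$radial, tolerance = 1e-12)
    expect_identical(again$spoke, got$spoke)
  }
})

test_that("spherical target insertion matches a brute-force centroid scan", {
  fx <- tiny_fixture()
  f0 <- conductivity_field(fx$mesh)
  center <- c(0.03, 0.03, 0.015)
  f1 <- insert_spherical_target(f0, fx$mesh, center, diameter = 0.012,
                                sigma_t = 0.0662)
  d <- sqrt((fx$mesh$centroid[, 1] - center[1])^2 +
            (fx$mesh$centroid[, 2] - center[2])^2 +
            (fx$mesh$centroid[, 3] - center[3])^2)
  expect_identical(sum(f1$sigma != f0$sigma), sum(d <= 0.006))
  expect_gt(sum(f1$sigma != f0$sigma), 0)
  # a target at background conductivity changes nothing numerically
  f2 <- insert_spherical_target(f0, fx$mesh, center, diameter = 0.012,
                                sigma_t = f0$sigma_blood)
  expect_identical(f2$sigma, f0$sigma)
  # sub-resolution target errors
  expect_error(insert_spherical_target(f0, fx$mesh, center, diameter = 1e-6),
               "below mesh resolution")
  expect_error(insert_spherical_target(f0, fx$mesh, c(0.2, 0, 0), 0.01),
               "outside")
})

test_that("electrode array invariants are enforced", {
  expect_error(electrode_array(rep(0.2, 16)), "outside the plane")
  arr <- edge_array()
  expect_identical(nrow(arr), 16L)
  expect_identical(unname(table(arr$plane)["top"]), 8L)
  expect_false(any(duplicated(arr[, c("plane", "spoke")])))
  # symmetrization: one radial per plane
  r <- symmetrize_array(generate_random_array(seed = 9))
  expect_length(unique(round(r$radial[r$plane == "top"], 12)), 1L)
  expect_length(unique(round(r$radial[r$plane == "bottom"], 12)), 1L)
})
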