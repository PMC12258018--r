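# Shared fixtures, built once per test run and cached. Everything is
# generated in code (no stored data) and deterministic for fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# tiny end-to-end bundle: 1 cm mesh, 8-measurement pattern, 20-sample dataset
tiny_fixture <- function() {
  cached("tiny", function() make_fixture("tiny", with_dataset = TRUE))
}

# coarse mesh + solver for derivative checks (864 elements)
coarse_bundle <- function() {
  cached("coarse", function() {
    geom <- oxy_geometry()
    mesh <- build_mesh(geom, max_h = 0.015)
    array <- edge_array(geom = geom)
    solver <- forward_solver(mesh, array)
    field <- conductivity_field(mesh)
    pattern <- im_pattern(data.frame(inj_a = c(1, 3, 1, 2, 5),
                                     inj_b = c(2, 7, 9, 10, 14),
                                     meas_c = c(5, 9, 5, 13, 1),
                                     meas_d = c(6, 12, 13, 16, 8)))
    list(geom = geom, mesh = mesh, array = array, solver = solver,
         field = field, pattern = pattern)
  })
}

# surrogate study shared by the training-sanity and correlation tests:
# 50 random arrays on the tiny mesh with the tiny fixture's fixed pattern
surrogate_study <- function() {
  cached("surrogate", function() {
    fx <- tiny_fixture()
    build_surrogate_dataset(fx$mesh, fx$pattern, fx$target_sets,
                            n_random = 50, seed = 4242)
  })
}

# scaled-down detection study: 0.005 m mesh, 208-measurement pattern,
# 800 + 800 samples with the reference noise models, trained detector
detection_study <- function() {
  cached("detection", function() {
    fx <- make_fixture("small", with_dataset = TRUE)
    net <- train_detector(fx$dataset, seed = fx$config$seeds$detector)
    report <- evaluate_detector(net, dataset = fx$dataset)
    list(fixture = fx, net = net, report = report)
  })
}
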