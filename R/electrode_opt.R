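#' Figures of merit of an electrode array
#'
#' Computes the three homogeneity figures of merit used as surrogate inputs,
#' plus the wider catalogue screened by [correlation_screen()]:
#' \describe{
#'   \item{f1 (J homogeneity)}{`median / min` of the Jacobian row L1 norms;}
#'   \item{f2 (J condition number)}{`max(s_k) / min(s_k)` over the singular
#'     values of J;}
#'   \item{f3 (measurement homogeneity)}{`median / min` over the absolute
#'     relative voltage differences pooled across all target sets.}
#' }
#' All three are scale-free ratios with ideal value 1 (perfectly homogeneous
#' sensitivity), invariant to global rescaling of J and to the injection
#' amplitude.
#'
#' @param solver A [forward_solver()] for the array under evaluation.
#' @param pattern The fixed [im_pattern()] applied to every array.
#' @param target_sets List of thrombus scenarios (see
#'   [make_training_sets()]); relative voltage differences are pooled over
#'   all of them.
#' @param field_hom Optional homogeneous [conductivity_field()] (built from
#'   the solver's mesh if missing).
#' @return List with `f` (named length-3 vector `c(f1, f2, f3)`) and
#'   `extras` (named vector of all screened figures of merit).
#' @export
array_features <- function(solver, pattern, target_sets, field_hom = NULL) {
  mesh <- solver$mesh
  if (is.null(field_hom)) field_hom <- conductivity_field(mesh)
  J <- compute_jacobian(solver, field_hom, pattern)
  rn <- score_l1(J)
  if (min(rn) <= 0) stop("degenerate array: a Jacobian row has zero L1 norm")
  sv <- svd(J, nu = 0, nv = 0)$d
  v_hom <- solve_forward(solver, field_hom, pattern)
  dvr <- unlist(lapply(target_sets, function(sc) {
    f_inh <- apply_scenario(field_hom, mesh, sc)
    abs(delta_vr(solve_forward(solver, f_inh, pattern), v_hom))
  }))
  f <- c(f1 = stats::median(rn) / min(rn),
         f2 = max(sv) / max(min(sv), 1e-300),
         f3 = stats::median(dvr) / max(min(dvr), 1e-300))
  extras <- c(mean_J = mean(rn), median_J = stats::median(rn),
              max_J = max(rn), min_J = min(rn),
              rank_J = sum(sv > max(sv) * 1e-10),
              J_homog = f[["f1"]], cond_J = f[["f2"]],
              mean_dV = mean(dvr), median_dV = stats::median(dvr),
              max_dV = max(dvr), min_dV = min(dvr),
              dV_homog = f[["f3"]])
  list(f = f, extras = extras)
}

#' Build the surrogate training dataset
#'
#' Draws random electrode arrays, keeps only unique ones (an array is a
#' duplicate if it differs from a kept array in fewer than 2 electrode
#' positions), and computes for each the three figures of merit (inputs) and
#' the flattened 48-vector of electrode coordinates (labels). Arrays whose
#' Jacobian has a zero row are dropped with a message.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param pattern The fixed [im_pattern()].
#' @param target_sets List of thrombus scenarios for the voltage-difference
#'   features.
#' @param n_random Number of random arrays to draw (default 8000; use far
#'   fewer for coarse-mesh studies).
#' @param mu_elpos,sigma_elpos Radial draw parameters (see
#'   [generate_random_array()]).
#' @param seed Optional integer seed.
#' @param position_tol Positional tolerance (m) under which two electrodes
#'   count as identical for the uniqueness rule (default 1e-9).
#' @param geom Geometry (taken from the mesh).
#' @return Object of class `surrogate_dataset`: list with `features`
#'   (n x 3), `coords` (n x 48), `extras` (n x 12 screened figures of
#'   merit), `arrays`, and bookkeeping (`seed`, counts).
#' @export
build_surrogate_dataset <- function(mesh, pattern, target_sets,
                                    n_random = 8000, mu_elpos = 0.030,
                                    sigma_elpos = 0.012, seed = NULL,
                                    position_tol = 1e-9,
                                    geom = mesh$geom) {
  base_seed <- seed %||% sample.int(2^31 - 1, 1)
  fem <- mesh_fem(mesh)
  field_hom <- conductivity_field(mesh)
  kept_radial <- NULL
  features <- NULL; coords <- NULL; extras <- NULL; arrays <- list()
  n_dup <- 0L; n_degenerate <- 0L
  for (k in seq_len(n_random)) {
    arr <- generate_random_array(mu_elpos, sigma_elpos, geom = geom,
                                 seed = (base_seed + k) %% (2^31 - 1))
    if (!is.null(kept_radial)) {
      ndiff <- rowSums(abs(kept_radial - matrix(arr$radial, nrow(kept_radial),
                                                16, byrow = TRUE)) > position_tol)
      if (any(ndiff < 2)) { n_dup <- n_dup + 1L; next }
    }
    ft <- tryCatch({
      solver <- forward_solver(mesh, arr, fem = fem)
      array_features(solver, pattern, target_sets, field_hom = field_hom)
    }, error = function(e) e)
    if (inherits(ft, "error")) {
      n_degenerate <- n_degenerate + 1L
      message("dropping degenerate array ", k, ": ", conditionMessage(ft))
      next
    }
    kept_radial <- rbind(kept_radial, arr$radial)
    features <- rbind(features, ft$f)
    extras <- rbind(extras, ft$extras)
    coords <- rbind(coords, as.vector(t(cbind(arr$x, arr$y, arr$z))))
    arrays[[length(arrays) + 1L]] <- arr
  }
  structure(list(features = features, coords = coords, extras = extras,
                 arrays = arrays, seed = base_seed,
                 n_requested = n_random, n_unique = nrow(features),
                 n_duplicate = n_dup, n_degenerate = n_degenerate),
            class = "surrogate_dataset")
}

#' @export
print.surrogate_dataset <- function(x, ...) {
  cat(sprintf("surrogate dataset: %d unique arrays (of %d drawn; %d duplicates, %d degenerate)\n",
              x$n_unique, x$n_requested, x$n_duplicate, x$n_degenerate))
  invisible(x)
}

#' Pearson correlation screen over candidate figures of merit
#'
#' Reporting tool: correlates all screened figures of merit across the arrays
#' of a surrogate dataset to expose redundant and informative features. The
#' surrogate input set itself is fixed to the three homogeneity ratios.
#' Zero-variance features yield `NA` (undefined correlation) with a warning
#' suppressed.
#'
#' @param dataset A [build_surrogate_dataset()] result, or a plain numeric
#'   matrix of features (columns = figures of merit).
#' @return Correlation matrix.
#' @export
correlation_screen <- function(dataset) {
  X <- if (inherits(dataset, "surrogate_dataset")) dataset$extras else as.matrix(dataset)
  if (nrow(X) < 3) stop("need at least 3 arrays for a correlation screen")
  suppressWarnings(stats::cor(X))
}

#' Train the electrode-position surrogate network
#'
#' Regression MLP mapping the three figures of merit to the 48 flattened
#' electrode coordinates (two hidden layers of 254 and 203 units with leaky
#' rectifier activations). Trained with momentum SGD, step-decayed learning
#' rate and L2 regularization on a seeded 80/10/10 split.
#'
#' @param dataset A [build_surrogate_dataset()] result.
#' @param widths Hidden-layer widths (default `c(254, 203)`).
#' @param epochs,lr,l2,momentum,lr_decay,decay_every,batch_size Training
#'   hyper-parameters (defaults 200, 1e-3, 1e-6, 0.9, 0.95, 10, 32).
#' @param leak Leaky-rectifier slope (default 0.01).
#' @param patience Validation early-stop patience (default `Inf`).
#' @param split Fractions for train/validation/test (default
#'   `c(0.8, 0.1, 0.1)`).
#' @param seed Optional integer seed (initialization, split, shuffling).
#' @return The trained [mlp_new()] network, with attributes `split`
#'   (index list) and `test_mse`.
#' @export
train_surrogate <- function(dataset, widths = c(254, 203), epochs = 200,
                            lr = 1e-3, l2 = 1e-6, momentum = 0.9,
                            lr_decay = 0.95, decay_every = 10,
                            batch_size = 32, leak = 0.01, patience = Inf,
                            split = c(0.8, 0.1, 0.1), seed = NULL) {
  stopifnot(inherits(dataset, "surrogate_dataset"))
  X <- dataset$features; Y <- dataset$coords
  base_seed <- seed %||% sample.int(2^31 - 1, 1)
  idx <- split_indices(nrow(X), split, seed = base_seed)
  net <- mlp_new(c(ncol(X), widths, ncol(Y)), activation = "lrelu",
                 leak = leak, output = "linear", seed = base_seed + 1L)
  net <- mlp_train(net, X[idx$train, , drop = FALSE], Y[idx$train, , drop = FALSE],
                   X_val = X[idx$val, , drop = FALSE],
                   y_val = Y[idx$val, , drop = FALSE],
                   epochs = epochs, batch_size = batch_size, lr = lr,
                   momentum = momentum, l2 = l2, lr_decay = lr_decay,
                   decay_every = decay_every, patience = patience,
                   seed = base_seed + 2L)
  pred <- mlp_predict(net, X[idx$test, , drop = FALSE])
  attr(net, "split") <- idx
  attr(net, "test_mse") <- mean((pred - Y[idx$test, , drop = FALSE])^2)
  net
}

# seeded disjoint train/val/test index split; with strata, each stratum is
# partitioned separately so every split keeps every class
split_indices <- function(n, fractions = c(0.8, 0.1, 0.1), seed = NULL,
                          strata = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, n >= 3)
  split_one <- function(idx) {
    k <- length(idx)
    perm <- idx[sample.int(k)]
    n_tr <- max(1L, round(fractions[1] * k))
    n_va <- max(1L, round(fractions[2] * k))
    n_tr <- min(n_tr, k - 2L)
    n_va <- min(n_va, k - n_tr - 1L)
    list(train = perm[seq_len(n_tr)],
         val = perm[n_tr + seq_len(n_va)],
         test = perm[(n_tr + n_va + 1L):k])
  }
  run <- function() {
    if (is.null(strata)) return(split_one(seq_len(n)))
    parts <- lapply(split(seq_len(n), strata), split_one)
    list(train = unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
         val = unlist(lapply(parts, `[[`, "val"), use.names = FALSE),
         test = unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  lapply(out, sort)
}

#' Propose an optimized electrode array from ideal feature values
#'
#' Forward pass of the trained surrogate on the ideal (maximally homogeneous)
#' feature vector `[1, 1, 1]`; the predicted 48 coordinates are snapped to the
#' nearest plausible radial slots. Optionally the result is symmetrized to
#' one radial distance per plane (never applied silently).
#'
#' @param net A [train_surrogate()] network.
#' @param ideal_features Feature vector fed to the network (default
#'   `c(1, 1, 1)`).
#' @param geom An [oxy_geometry()].
#' @param symmetrize Apply [symmetrize_array()] to the snapped proposal
#'   (default `FALSE`).
#' @param ... Passed to [snap_to_slots()] (contact model parameters).
#' @return An `electrode_array`.
#' @export
propose_array <- function(net, ideal_features = c(1, 1, 1),
                          geom = oxy_geometry(), symmetrize = FALSE, ...) {
  stopifnot(inherits(net, "mlp"), length(ideal_features) == net$sizes[1])
  coords <- matrix(drop(mlp_predict(net, ideal_features)), 16, 3, byrow = TRUE)
  arr <- snap_to_slots(coords, geom = geom, ...)
  if (symmetrize) arr <- symmetrize_array(arr)
  arr
}
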