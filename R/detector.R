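#' Noise specification for detector training data
#'
#' Three stochastic perturbations emulate realistic variability:
#' \describe{
#'   \item{target jitter}{the clot conductivity of each positive sample is
#'     drawn from `N(sigma_target, (sigma_target / 10)^2)`, truncated away
#'     from zero;}
#'   \item{background jitter}{each negative sample perturbs every background
#'     element by `N(0, (sigma_back / 100)^2)`;}
#'   \item{measurement noise}{additive white Gaussian noise on the relative
#'     voltage frame, scaled to a fixed power signal-to-noise ratio
#'     (default 15 dB, i.e. signal power about 31.6 times noise power).}
#' }
#'
#' @param target_jitter_sd SD of the clot-conductivity draw in S/m
#'   (default `0.0662 / 10`).
#' @param background_jitter_sd Per-element SD of the background perturbation
#'   in S/m (default `0.662 / 100`).
#' @param snr_db Frame signal-to-noise ratio in dB (default 15).
#' @param sigma_floor Truncation floor for drawn conductivities in S/m
#'   (default 1e-4).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(target_jitter_sd = oxy_conductivities()[["clot"]] / 10,
                       background_jitter_sd = oxy_conductivities()[["blood"]] / 100,
                       snr_db = 15, sigma_floor = 1e-4) {
  stopifnot(target_jitter_sd >= 0, background_jitter_sd >= 0,
            !is.na(snr_db), sigma_floor > 0)   # snr_db = Inf: noise-free
  structure(list(target_jitter_sd = target_jitter_sd,
                 background_jitter_sd = background_jitter_sd,
                 snr_db = snr_db, sigma_floor = sigma_floor),
            class = "noise_spec")
}

# additive white Gaussian noise at a fixed power SNR on one frame;
# a zero frame stays zero (no signal to scale against)
add_snr_noise <- function(v, snr_db) {
  ps <- sum(v^2)
  if (ps == 0 || !is.finite(snr_db)) return(v)
  sd_n <- sqrt(ps / (10^(snr_db / 10) * length(v)))
  v + stats::rnorm(length(v), sd = sd_n)
}

# truncated-normal conductivity redraw (truncation at spec floor)
draw_sigma <- function(mean, sd, floor) {
  repeat {
    s <- stats::rnorm(1, mean, sd)
    if (s >= floor) return(s)
  }
}

#' Generate one thrombus-present training sample
#'
#' Inserts a single spherical clot (conductivity drawn around the clot value)
#' into the clean background, solves the forward problem, forms the relative
#' voltage difference against the clean homogeneous reference frame, and adds
#' frame noise at the specified SNR.
#'
#' @param solver A [forward_solver()] for the fixed (optimized) array.
#' @param pattern The fixed [im_pattern()].
#' @param v_hom Clean homogeneous reference `measurement_frame`.
#' @param target One-row data frame (or list) with `x`, `y`, `z`,
#'   `diameter` of the clot.
#' @param noise A [noise_spec()].
#' @param field_hom Clean homogeneous [conductivity_field()].
#' @param seed Optional integer seed.
#' @return Numeric relative-voltage-difference vector with attribute
#'   `label = "present"`.
#' @export
generate_positive <- function(solver, pattern, v_hom, target, noise,
                              field_hom = NULL, seed = NULL) {
  run <- function() {
    mesh <- solver$mesh
    fh <- field_hom %||% conductivity_field(mesh)
    sig_t <- draw_sigma(oxy_conductivities()[["clot"]], noise$target_jitter_sd,
                        noise$sigma_floor)
    f <- insert_spherical_target(fh, mesh,
                                 center = c(target$x, target$y, target$z),
                                 diameter = target$diameter, sigma_t = sig_t)
    dvr <- delta_vr(solve_forward(solver, f, pattern), v_hom)
    structure(add_snr_noise(dvr, noise$snr_db), label = "present")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate one thrombus-free (noise-only) training sample
#'
#' Perturbs every background element of the clean field by the background
#' jitter, solves the forward problem, forms the relative voltage difference
#' against the clean homogeneous reference, and adds frame noise at the
#' specified SNR.
#'
#' @inheritParams generate_positive
#' @return Numeric relative-voltage-difference vector with attribute
#'   `label = "absent"`.
#' @export
generate_negative <- function(solver, pattern, v_hom, noise,
                              field_hom = NULL, seed = NULL) {
  run <- function() {
    mesh <- solver$mesh
    f <- field_hom %||% conductivity_field(mesh)
    bg <- mesh$region == "BG"
    if (noise$background_jitter_sd > 0) {
      pert <- stats::rnorm(sum(bg), 0, noise$background_jitter_sd)
      f$sigma[bg] <- pmax(f$sigma[bg] + pert, noise$sigma_floor)
    }
    dvr <- delta_vr(solve_forward(solver, f, pattern), v_hom)
    structure(add_snr_noise(dvr, noise$snr_db), label = "absent")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a labelled detection dataset
#'
#' Balanced dataset of single-clot positives (clot centres drawn without
#' replacement from the target grid when possible) and noise-only negatives,
#' all measured with the same fixed array and pattern against one clean
#' homogeneous reference frame.
#'
#' @param solver A [forward_solver()].
#' @param pattern The fixed [im_pattern()].
#' @param grid A [make_target_grid()] data frame of candidate clot positions.
#' @param n_pos,n_neg Class sizes (equal by default use).
#' @param noise A [noise_spec()].
#' @param seed Optional integer seed.
#' @param progress Print a progress message every this many samples
#'   (default 0: silent).
#' @return Object of class `detection_dataset`: list with `X` (n x n_V
#'   matrix of relative voltage differences), `y` (factor
#'   `absent`/`present`), `targets` (grid rows used for positives, NA rows
#'   for negatives) and `seed`.
#' @export
build_detection_dataset <- function(solver, pattern, grid, n_pos, n_neg,
                                    noise = noise_spec(), seed = NULL,
                                    progress = 0) {
  base_seed <- seed %||% sample.int(2^31 - 1, 1)
  field_hom <- conductivity_field(solver$mesh)
  v_hom <- solve_forward(solver, field_hom, pattern)
  pick <- function() sample.int(nrow(grid), n_pos, replace = n_pos > nrow(grid))
  rows <- withr::with_seed(base_seed, pick())
  n <- n_pos + n_neg
  X <- matrix(NA_real_, n, length(pattern))
  lab <- character(n)
  tgt <- grid[rep(NA_integer_, n), , drop = FALSE]
  for (i in seq_len(n_pos)) {
    X[i, ] <- generate_positive(solver, pattern, v_hom, grid[rows[i], ], noise,
                                field_hom = field_hom,
                                seed = (base_seed + 7L * i) %% (2^31 - 1))
    lab[i] <- "present"
    tgt[i, ] <- grid[rows[i], ]
    if (progress > 0 && i %% progress == 0)
      message("positives: ", i, "/", n_pos)
  }
  for (i in seq_len(n_neg)) {
    X[n_pos + i, ] <- generate_negative(solver, pattern, v_hom, noise,
                                        field_hom = field_hom,
                                        seed = (base_seed + 7L * (n_pos + i) + 3L) %% (2^31 - 1))
    lab[n_pos + i] <- "absent"
    if (progress > 0 && i %% progress == 0)
      message("negatives: ", i, "/", n_neg)
  }
  structure(list(X = X, y = factor(lab, levels = c("absent", "present")),
                 targets = tgt, seed = base_seed, noise = noise),
            class = "detection_dataset")
}

#' @export
print.detection_dataset <- function(x, ...) {
  cat(sprintf("detection dataset: %d samples (%d present / %d absent), %d measurements each\n",
              nrow(x$X), sum(x$y == "present"), sum(x$y == "absent"), ncol(x$X)))
  invisible(x)
}

#' Train the thrombus-presence classifier
#'
#' Classification MLP (hidden layers 200 and 100, rectifier activations,
#' two-class softmax head) on relative voltage difference frames, trained
#' with momentum SGD on a seeded 80/10/10 split. Both classes must be
#' present in every split.
#'
#' @param dataset A [build_detection_dataset()] result.
#' @param widths Hidden-layer widths (default `c(200, 100)`).
#' @param epochs,lr,l2,momentum,lr_decay,decay_every,batch_size,patience
#'   Training hyper-parameters (defaults 200, 1e-3, 1e-6, 0.9, 0.95, 10,
#'   32, Inf).
#' @param split Train/validation/test fractions (default `c(0.8, 0.1, 0.1)`).
#' @param seed Optional integer seed.
#' @return The trained [mlp_new()] network with attribute `split`; levels
#'   are `absent` (class 1) and `present` (class 2).
#' @export
train_detector <- function(dataset, widths = c(200, 100), epochs = 200,
                           lr = 1e-3, l2 = 1e-6, momentum = 0.9,
                           lr_decay = 0.95, decay_every = 10,
                           batch_size = 32, patience = Inf,
                           split = c(0.8, 0.1, 0.1), seed = NULL) {
  stopifnot(inherits(dataset, "detection_dataset"))
  base_seed <- seed %||% sample.int(2^31 - 1, 1)
  idx <- split_indices(nrow(dataset$X), split, seed = base_seed,
                       strata = dataset$y)
  for (part in idx)
    if (length(unique(dataset$y[part])) < 2)
      stop("a data split contains a single class; enlarge the dataset or reseed")
  net <- mlp_new(c(ncol(dataset$X), widths, 2L), activation = "relu",
                 output = "softmax", seed = base_seed + 1L)
  net <- mlp_train(net, dataset$X[idx$train, , drop = FALSE],
                   dataset$y[idx$train],
                   X_val = dataset$X[idx$val, , drop = FALSE],
                   y_val = dataset$y[idx$val],
                   epochs = epochs, batch_size = batch_size, lr = lr,
                   momentum = momentum, l2 = l2, lr_decay = lr_decay,
                   decay_every = decay_every, patience = patience,
                   seed = base_seed + 2L)
  attr(net, "split") <- idx
  net
}

#' Evaluate the classifier on a held-out test split
#'
#' Computes the 2 x 2 confusion matrix and the derived metrics with
#' `present` as the positive class: sensitivity `TP / (TP + FN)`, precision
#' `TP / (TP + FP)`, F1 `2 p s / (p + s)`, accuracy, and the false-positive
#' fraction `FP / (total test cases)`.
#'
#' @param net A [train_detector()] network.
#' @param X_test,y_test Test inputs and labels (factor with levels `absent`,
#'   `present`). Defaults: the test split stored on the network applied to
#'   `dataset`.
#' @param dataset Optional [build_detection_dataset()] from which to take the
#'   stored test split.
#' @return Object of class `eval_report`: list with `confusion` (2 x 2
#'   matrix, rows = truth, cols = prediction), `sensitivity`, `precision`,
#'   `f1`, `accuracy`, `fp_fraction` and `n_test`.
#' @export
evaluate_detector <- function(net, X_test = NULL, y_test = NULL, dataset = NULL) {
  if (is.null(X_test)) {
    stopifnot(!is.null(dataset))
    idx <- attr(net, "split")$test
    X_test <- dataset$X[idx, , drop = FALSE]
    y_test <- dataset$y[idx]
  }
  y_test <- factor(y_test, levels = c("absent", "present"))
  if (any(table(y_test) == 0)) stop("test split misses a class")
  pred <- attr(mlp_predict(net, X_test), "class_pred")
  pred <- factor(c("absent", "present")[pred], levels = c("absent", "present"))
  cm <- table(truth = y_test, prediction = pred)
  tp <- cm["present", "present"]; fn <- cm["present", "absent"]
  fp <- cm["absent", "present"]; tn <- cm["absent", "absent"]
  sens <- tp / (tp + fn)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  structure(list(confusion = cm, sensitivity = sens, precision = prec,
                 f1 = f1, accuracy = (tp + tn) / sum(cm),
                 fp_fraction = fp / sum(cm), n_test = sum(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("thrombus detection report\n")
  print(x$confusion)
  cat(sprintf("  sensitivity %.1f%%  precision %.1f%%  F1 %.1f%%  accuracy %.1f%%\n",
              100 * x$sensitivity, 100 * x$precision, 100 * x$f1,
              100 * x$accuracy))
  cat(sprintf("  false positives: %.2f%% of %d test cases\n",
              100 * x$fp_fraction, x$n_test))
  invisible(x)
}
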