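#' Construct a shallow multi-layer perceptron
#'
#' Fully-connected feed-forward network with rectifier (or leaky rectifier)
#' activations on the hidden layers and either a linear regression head or a
#' two-class (or K-class) softmax head. Weights use He-scaled normal
#' initialization; a seed makes the initialization reproducible.
#'
#' @param layer_sizes Integer vector of layer widths, input first, output
#'   last (e.g. `c(3, 254, 203, 48)`).
#' @param activation `"relu"` or `"lrelu"` (leaky).
#' @param leak Leak slope for `"lrelu"` (default 0.01).
#' @param output `"linear"` (regression, mean-squared-error loss) or
#'   `"softmax"` (classification, cross-entropy loss).
#' @param seed Optional integer seed for the initialization.
#' @return Object of class `mlp`.
#' @export
mlp_new <- function(layer_sizes, activation = c("relu", "lrelu"), leak = 0.01,
                    output = c("linear", "softmax"), seed = NULL) {
  activation <- match.arg(activation)
  output <- match.arg(output)
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  init <- function() {
    L <- length(layer_sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      W[[l]] <- matrix(stats::rnorm(fan_in * layer_sizes[l + 1L],
                                    sd = sqrt(2 / fan_in)),
                       fan_in, layer_sizes[l + 1L])
      b[[l]] <- numeric(layer_sizes[l + 1L])
    }
    list(W = W, b = b)
  }
  wb <- if (is.null(seed)) init() else withr::with_seed(seed, init())
  structure(list(sizes = layer_sizes, W = wb$W, b = wb$b,
                 activation = activation, leak = leak, output = output,
                 x_center = NULL, x_scale = NULL,
                 y_center = NULL, y_scale = NULL,
                 history = NULL),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("mlp: %s, %s hidden activation, %s output\n",
              paste(x$sizes, collapse = "-"), x$activation, x$output))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, final train loss %.4g, val loss %.4g\n",
                nrow(x$history), utils::tail(x$history$train_loss, 1),
                utils::tail(x$history$val_loss, 1)))
  invisible(x)
}

mlp_act <- function(z, net) {
  if (net$activation == "relu") pmax(z, 0) else pmax(z, 0) + net$leak * pmin(z, 0)
}
mlp_act_grad <- function(z, net) {
  if (net$activation == "relu") (z > 0) + 0 else ifelse(z > 0, 1, net$leak)
}

mlp_forward_raw <- function(net, X) {
  L <- length(net$W)
  zs <- vector("list", L); as <- vector("list", L + 1L)
  as[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(as[[l]] %*% net$W[[l]], 2L, net$b[[l]], `+`)
    zs[[l]] <- z
    as[[l + 1]] <- if (l < L) mlp_act(z, net) else z
  }
  list(zs = zs, as = as)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Predict with an MLP
#'
#' Applies the network's stored input standardization (if fitted with one),
#' runs the forward pass and, for a regression head, undoes any stored
#' output scaling. For a softmax head the class probabilities are returned
#' (attribute `class` holds the argmax labels).
#'
#' @param net A trained [mlp_new()] network.
#' @param X Input matrix (one row per sample) or a single input vector.
#' @return Prediction matrix; for `softmax`, probabilities with attribute
#'   `class`.
#' @export
mlp_predict <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (!is.null(net$x_center))
    X <- sweep(sweep(X, 2L, net$x_center), 2L, net$x_scale, `/`)
  out <- mlp_forward_raw(net, X)$as[[length(net$W) + 1L]]
  if (net$output == "softmax") {
    p <- softmax_rows(out)
    attr(p, "class_pred") <- max.col(p, ties.method = "first")
    return(p)
  }
  if (!is.null(net$y_center))
    out <- sweep(sweep(out, 2L, net$y_scale, `*`), 2L, net$y_center, `+`)
  out
}

#' Train an MLP by stochastic gradient descent with momentum
#'
#' Mini-batch SGD with classical momentum, step-decayed learning rate and L2
#' weight regularization. Inputs (and, for regression, outputs) are z-scored
#' with training-set statistics stored in the network. Validation loss is
#' checked every epoch; if it fails to improve for `patience` consecutive
#' epochs, training stops and the best-validation weights are restored.
#'
#' @param net An [mlp_new()] network.
#' @param X,y Training inputs (rows = samples) and targets: a numeric matrix
#'   for a linear head, an integer/factor class vector for softmax.
#' @param X_val,y_val Optional validation split (same formats).
#' @param epochs Training epochs (default 200).
#' @param batch_size Mini-batch size (default 32).
#' @param lr Initial learning rate (default 1e-3).
#' @param momentum Momentum coefficient (default 0.9).
#' @param l2 L2 regularization factor (default 1e-6).
#' @param lr_decay Multiplicative learning-rate decay factor (default 0.95),
#'   applied every `decay_every` epochs.
#' @param decay_every Epoch period of the learning-rate decay (default 10).
#' @param patience Early-stop patience in epochs (default `Inf`: never stop
#'   early, still restore best-validation weights at the end).
#' @param standardize Standardize inputs (and regression outputs) with
#'   training statistics (default TRUE).
#' @param seed Optional integer seed for shuffling (and any redraws).
#' @return The trained `mlp`, with a `history` data frame (epoch, learning
#'   rate, training/validation loss and, for softmax, accuracy).
#' @export
mlp_train <- function(net, X, y, X_val = NULL, y_val = NULL, epochs = 200,
                      batch_size = 32, lr = 1e-3, momentum = 0.9, l2 = 1e-6,
                      lr_decay = 0.95, decay_every = 10, patience = Inf,
                      standardize = TRUE, seed = NULL) {
  run <- function() mlp_train_impl(net, X, y, X_val, y_val, epochs, batch_size,
                                   lr, momentum, l2, lr_decay, decay_every,
                                   patience, standardize)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

mlp_train_impl <- function(net, X, y, X_val, y_val, epochs, batch_size, lr0,
                           momentum, l2, lr_decay, decay_every, patience,
                           standardize) {
  X <- as.matrix(X)
  n <- nrow(X)
  cls <- net$output == "softmax"
  if (cls) {
    y <- as.integer(as.factor(y))
    K <- net$sizes[length(net$sizes)]
    stopifnot(max(y) <= K)
    Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  } else {
    Y <- as.matrix(y)
    stopifnot(ncol(Y) == net$sizes[length(net$sizes)])
  }
  if (standardize) {
    net$x_center <- colMeans(X)
    net$x_scale <- pmax(apply(X, 2, stats::sd), 1e-12)
    X <- sweep(sweep(X, 2L, net$x_center), 2L, net$x_scale, `/`)
    if (!cls) {
      net$y_center <- colMeans(Y)
      net$y_scale <- pmax(apply(Y, 2, stats::sd), 1e-12)
      Y <- sweep(sweep(Y, 2L, net$y_center), 2L, net$y_scale, `/`)
    }
  }
  has_val <- !is.null(X_val)
  if (has_val) {
    Xv <- as.matrix(X_val)
    if (!is.null(net$x_center))
      Xv <- sweep(sweep(Xv, 2L, net$x_center), 2L, net$x_scale, `/`)
    if (cls) {
      yv <- as.integer(as.factor(y_val))
      Yv <- matrix(0, nrow(Xv), ncol(Y)); Yv[cbind(seq_len(nrow(Xv)), yv)] <- 1
    } else {
      Yv <- as.matrix(y_val)
      if (!is.null(net$y_center))
        Yv <- sweep(sweep(Yv, 2L, net$y_center), 2L, net$y_scale, `/`)
    }
  }
  loss_of <- function(Xm, Ym) {
    out <- mlp_forward_raw(net, Xm)$as[[length(net$W) + 1L]]
    if (cls) {
      p <- softmax_rows(out)
      list(loss = -mean(log(pmax(p[Ym > 0], 1e-300))),
           acc = mean(max.col(p, ties.method = "first") == max.col(Ym)))
    } else {
      list(loss = mean((out - Ym)^2), acc = NA_real_)
    }
  }
  L <- length(net$W)
  vW <- lapply(net$W, function(w) w * 0)
  vb <- lapply(net$b, function(b) b * 0)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), val_loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0))
  best_val <- Inf; best_W <- net$W; best_b <- net$b; stall <- 0L
  for (ep in seq_len(epochs)) {
    lr <- lr0 * lr_decay^((ep - 1) %/% decay_every)
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      fp <- mlp_forward_raw(net, Xb)
      out <- fp$as[[L + 1L]]
      nb <- nrow(Xb)
      delta <- if (cls) (softmax_rows(out) - Yb) / nb
               else 2 * (out - Yb) / (nb * ncol(Yb))
      for (l in L:1) {
        gW <- crossprod(fp$as[[l]], delta) + l2 * net$W[[l]]
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(net$W[[l]])) * mlp_act_grad(fp$zs[[l - 1L]], net)
        vW[[l]] <- momentum * vW[[l]] - lr * gW
        vb[[l]] <- momentum * vb[[l]] - lr * gb
        net$W[[l]] <- net$W[[l]] + vW[[l]]
        net$b[[l]] <- net$b[[l]] + vb[[l]]
      }
    }
    tr <- loss_of(X, Y)
    if (!is.finite(tr$loss))
      stop("training diverged (non-finite loss) at epoch ", ep,
           sprintf(" [lr0=%g, momentum=%g, l2=%g, batch=%d]",
                   lr0, momentum, l2, batch_size))
    vl <- if (has_val) loss_of(Xv, Yv) else list(loss = NA_real_, acc = NA_real_)
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, train_loss = tr$loss,
                                   val_loss = vl$loss, train_acc = tr$acc,
                                   val_acc = vl$acc))
    if (has_val) {
      if (vl$loss < best_val - 1e-12) {
        best_val <- vl$loss; best_W <- net$W; best_b <- net$b; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  }
  if (has_val && is.finite(best_val)) { net$W <- best_W; net$b <- best_b }
  net$history <- hist
  net
}

#' Serialize / restore an MLP as JSON
#'
#' Portable checkpoint: architecture, activation, scalers, weights and the
#' training history in one JSON file.
#'
#' @param net An [mlp_new()] network.
#' @param path JSON file path.
#' @return Write: `path` invisibly; read: an `mlp`.
#' @export
write_mlp_json <- function(net, path) {
  stopifnot(inherits(net, "mlp"))
  out <- unclass(net)
  out$W <- lapply(out$W, function(w) list(dim = dim(w), x = as.vector(w)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  net <- mlp_new(unlist(raw$sizes), activation = raw$activation,
                 leak = raw$leak, output = raw$output)
  net$W <- lapply(raw$W, function(w)
    matrix(unlist(w$x), unlist(w$dim)[1], unlist(w$dim)[2]))
  net$b <- lapply(raw$b, unlist)
  for (f in c("x_center", "x_scale", "y_center", "y_scale"))
    if (!is.null(raw[[f]]) && length(raw[[f]]) > 0) net[[f]] <- unlist(raw[[f]])
  if (!is.null(raw$history) && length(raw$history) > 0)
    net$history <- as.data.frame(lapply(as.data.frame(
      do.call(rbind, lapply(raw$history, function(r)
        lapply(r, function(v) if (is.null(v)) NA else v)))), unlist))
  net
}
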