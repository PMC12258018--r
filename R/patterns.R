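#' Enumerate candidate four-point measurements for an electrode array
#'
#' Builds the electrode-pair set and all reciprocity-unique four-point
#' (inject pair, measure pair) combinations with disjoint electrodes. Each
#' pair serves as both injector and measurer. Two rulesets are provided:
#' \describe{
#'   \item{`"default"`}{all intra-plane pairs within each plane plus the
#'     inter-plane pairs between spoke-aligned and spoke-adjacent electrodes,
#'     reproducing the intra-/inter-plane structure of the designed pattern;}
#'   \item{`"all"`}{all 120 electrode pairs.}
#' }
#'
#' @param array An [electrode_array()] (or any object with `plane` and
#'   `spoke` columns for 16 electrodes).
#' @param rules List with element `pair_mode` (`"default"` or `"all"`).
#' @param n_electrodes Number of electrodes when `array` is `NULL` and
#'   `pair_mode = "all"` (small toy cases).
#' @return Object of class `candidate_set`: data frame with columns `inj_a`,
#'   `inj_b`, `meas_c`, `meas_d`, `inj_class`, `meas_class` (class is
#'   `"intra"` or `"inter"` plane).
#' @export
enumerate_candidates <- function(array = NULL, rules = list(pair_mode = "default"),
                                 n_electrodes = 16L) {
  mode <- match.arg(rules$pair_mode %||% "default", c("default", "all"))
  if (!is.null(array)) {
    stopifnot(nrow(array) == 16)
    plane <- array$plane; spoke <- array$spoke
    n_electrodes <- 16L
  } else {
    stopifnot(mode == "all")
    plane <- rep("top", n_electrodes); spoke <- seq_len(n_electrodes) - 1L
  }
  cmb <- utils::combn(n_electrodes, 2L)
  a <- cmb[1, ]; b <- cmb[2, ]
  cls <- ifelse(plane[a] == plane[b], "intra", "inter")
  if (mode == "default" && !is.null(array)) {
    dspoke <- (spoke[a] - spoke[b]) %% 8L
    keep <- cls == "intra" | (cls == "inter" & dspoke %in% c(0L, 1L, 7L))
    a <- a[keep]; b <- b[keep]; cls <- cls[keep]
  }
  np <- length(a)
  pc <- utils::combn(np, 2L)
  p <- pc[1, ]; q <- pc[2, ]
  disjoint <- a[p] != a[q] & a[p] != b[q] & b[p] != a[q] & b[p] != b[q]
  p <- p[disjoint]; q <- q[disjoint]
  out <- data.frame(inj_a = a[p], inj_b = b[p], meas_c = a[q], meas_d = b[q],
                    inj_class = cls[p], meas_class = cls[q],
                    stringsAsFactors = FALSE)
  structure(out, class = c("candidate_set", "data.frame"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Sensitivity-row selection scores
#'
#' `score_l1()` is the L1 norm (sum of absolute sensitivities) of a
#' measurement's Jacobian row; `score_l2()` is its Euclidean norm. Rows of
#' large norm mirror conductivity changes into voltage changes more strongly
#' and are more robust to noise.
#'
#' @param J Jacobian sensitivity matrix (rows = measurements).
#' @param meas Row index; if missing, scores for all rows are returned.
#' @return Numeric scalar (or vector over rows).
#' @export
score_l1 <- function(J, meas = NULL) {
  if (is.null(meas)) rowSums(abs(J)) else sum(abs(J[meas, ]))
}

#' @rdname score_l1
#' @export
score_l2 <- function(J, meas = NULL) {
  if (is.null(meas)) sqrt(rowSums(J^2)) else sqrt(sum(J[meas, ]^2))
}

#' Gram (parallelotope) volume of a sensitivity-row subset
#'
#' `det(J_sub %*% t(J_sub))`: the squared volume of the parallelotope spanned
#' by the selected sensitivity vectors. It is large when rows are long and
#' mutually orthogonal, zero when any row is a linear combination of the
#' others; ranking by it is equivalent to ranking by the volume itself.
#'
#' @param J_subset Matrix whose rows are the selected sensitivity vectors
#'   (at most as many rows as columns).
#' @return Non-negative scalar.
#' @export
gram_volume <- function(J_subset) {
  J_subset <- as.matrix(J_subset)
  stopifnot(nrow(J_subset) <= ncol(J_subset))
  G <- tcrossprod(J_subset)
  max(det(G), 0)
}

#' Select the final injection-measurement pattern
#'
#' Three-stage selection mirroring the designed measurement budget: first a
#' greedy Gram-volume maximization picks `counts["volume"]` rows (each step
#' adds the candidate whose orthogonal residual against the selected span is
#' largest, which maximizes the updated Gram determinant); then the
#' `counts["l1"]` largest remaining rows by L1 norm; then the `counts["l2"]`
#' largest remaining rows by L2 norm. Already-selected rows are skipped at
#' every stage so the final pattern has exactly `sum(counts)` distinct
#' measurements. Ties break on the lowest candidate index.
#'
#' @param J Candidate Jacobian matrix, one row per candidate measurement.
#' @param candidates A [enumerate_candidates()] data frame aligned with the
#'   rows of `J`.
#' @param counts Named integer vector with any of `volume`, `l1`, `l2`
#'   (default `c(volume = 144, l1 = 32, l2 = 32)`).
#' @param amplitude Current amplitude stored in the resulting pattern.
#' @param v_ref Optional homogeneous reference voltages, one per candidate.
#'   Candidates with `|v_ref| < ref_floor` are excluded before selection:
#'   relative voltage monitoring divides by the reference, so a measurement
#'   whose homogeneous voltage vanishes (e.g. by mirror symmetry of the
#'   configuration) is unusable however sensitive its Jacobian row is.
#' @param ref_floor Reference-voltage floor in V at unit current
#'   (default 1e-9).
#' @return An [im_pattern()] with attribute `selection` (a data frame with
#'   the candidate index, stage and selection order of every chosen row).
#' @export
select_pattern <- function(J, candidates,
                           counts = c(volume = 144, l1 = 32, l2 = 32),
                           amplitude = 1, v_ref = NULL, ref_floor = 1e-9) {
  J <- as.matrix(J)
  stopifnot(nrow(J) == nrow(candidates))
  keep_map <- seq_len(nrow(J))
  if (!is.null(v_ref)) {
    v_ref <- if (inherits(v_ref, "measurement_frame")) v_ref$v else as.numeric(v_ref)
    stopifnot(length(v_ref) == nrow(J))
    keep_map <- which(abs(v_ref) >= ref_floor)
    J <- J[keep_map, , drop = FALSE]
    candidates <- candidates[keep_map, , drop = FALSE]
  }
  counts <- counts[counts > 0]
  if (sum(counts) > nrow(J))
    stop(sprintf("requested %d measurements but only %d candidates available",
                 sum(counts), nrow(J)))
  nsel_v <- as.integer(counts["volume"] %||% 0); nsel_v <- max(nsel_v, 0L, na.rm = TRUE)
  if (is.na(nsel_v)) nsel_v <- 0L
  chosen <- integer(0); stage <- character(0)

  if (!is.na(counts["volume"]) && counts["volume"] > 0) {
    k <- as.integer(counts["volume"])
    n <- nrow(J)
    rn2 <- rowSums(J^2)          # residual squared norms against selected span
    proj2 <- numeric(n)
    Q <- matrix(0, 0, ncol(J))   # orthonormal basis of the selected rows
    gains <- numeric(0)
    for (s in seq_len(k)) {
      res <- rn2 - proj2
      res[chosen] <- -Inf
      best <- which.max(res)     # first max: lowest index on ties
      gains <- c(gains, max(res[best], 0))
      r <- J[best, ]
      if (nrow(Q) > 0) r <- r - drop(crossprod(Q, Q %*% r))
      nr <- sqrt(sum(r^2))
      if (nr > 1e-300) {
        q <- r / nr
        Q <- rbind(Q, q)
        proj2 <- proj2 + drop(J %*% q)^2
      }
      chosen <- c(chosen, best)
      stage <- c(stage, "volume")
    }
    attr(chosen, "gains") <- gains
  }
  for (nm in c("l1", "l2")) {
    kk <- counts[nm]
    if (is.na(kk) || kk == 0) next
    sc <- if (nm == "l1") score_l1(J) else score_l2(J)
    ord <- order(-sc, seq_along(sc))
    ord <- ord[!(ord %in% chosen)]
    take <- ord[seq_len(kk)]
    gains <- attr(chosen, "gains")
    chosen <- c(chosen, take); attr(chosen, "gains") <- gains
    stage <- c(stage, rep(nm, kk))
  }
  sel <- data.frame(candidate = keep_map[as.integer(chosen)], stage = stage,
                    order = seq_along(chosen))
  pat <- im_pattern(candidates[as.integer(chosen),
                               c("inj_a", "inj_b", "meas_c", "meas_d")],
                    amplitude = amplitude)
  attr(pat, "selection") <- sel
  attr(pat, "volume_gains") <- attr(chosen, "gains")
  pat
}
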