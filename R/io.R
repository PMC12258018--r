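#' Write a mesh to legacy VTK (unstructured grid, ASCII)
#'
#' Region labels are written as an integer cell data array (`region`, BG = 0,
#' SG = 1) alongside the element volumes.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param path Output file path (`.vtk`).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  stopifnot(inherits(mesh, "oxy_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "oxygenator tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(format(mesh$nodes, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, 5L * ne), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(10L, ne)), con)
  writeLines(c(sprintf("CELL_DATA %d", ne),
               "SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(ifelse(mesh$region == "SG", 1L, 0L)), con)
  writeLines(c("SCALARS volume double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(mesh$vol, digits = 17, scientific = TRUE, trim = TRUE), con)
  invisible(path)
}

#' Write / read a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Elements are written as 4-node tetrahedra (type 4) with the region label
#' encoded in the physical tag (BG = 1, SG = 2). `read_mesh_msh()` restores
#' nodes, elements and region labels and recomputes the derived quantities;
#' it reads only files produced by [write_mesh_msh()] (tet-only, 2.2 ASCII).
#'
#' @param mesh An [build_mesh()] mesh.
#' @param path File path (`.msh`).
#' @param geom Geometry to attach on read (default box inferred from node
#'   bounds).
#' @return `write_mesh_msh()`: `path` invisibly; `read_mesh_msh()`: an
#'   `oxy_mesh`.
#' @export
write_mesh_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "oxy_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", as.character(nn)), con)
  utils::write.table(cbind(seq_len(nn),
                           format(mesh$nodes, digits = 17,
                                  scientific = TRUE, trim = TRUE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("$EndNodes", "$Elements", as.character(ne)), con)
  phys <- ifelse(mesh$region == "SG", 2L, 1L)
  utils::write.table(cbind(seq_len(ne), 4L, 2L, phys, phys, mesh$elems),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$EndElements", con)
  invisible(path)
}

#' @rdname write_mesh_msh
#' @export
read_mesh_msh <- function(path, geom = NULL) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- which(lines == paste0("$", name)) + 1L
    i1 <- which(lines == paste0("$End", name)) - 1L
    lines[i0:i1]
  }
  nd <- sect("Nodes")
  nn <- as.integer(nd[1])
  ntab <- utils::read.table(text = nd[-1])
  nodes <- as.matrix(ntab[order(ntab[[1]]), 2:4])
  dimnames(nodes) <- list(NULL, c("x", "y", "z"))
  el <- sect("Elements")
  etab <- utils::read.table(text = el[-1])
  stopifnot(all(etab[[2]] == 4L))
  elems <- as.matrix(etab[, 6:9])
  storage.mode(elems) <- "integer"
  dimnames(elems) <- NULL
  region <- ifelse(etab[[4]] == 2L, "SG", "BG")
  if (is.null(geom)) {
    span <- apply(nodes, 2, function(v) diff(range(v)))
    geom <- oxy_geometry(size_x = span[1], size_y = span[2], size_z = span[3],
                         rod_diameter = 0)
  }
  vol <- tet_signed_volume(nodes, elems)
  stopifnot(nrow(nodes) == nn, all(vol > 0))
  centroid <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
               nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
  structure(list(nodes = nodes, elems = elems, region = region, vol = vol,
                 centroid = centroid, max_h = NA_real_, geom = geom,
                 n_cells = NULL, h = NULL),
            class = "oxy_mesh")
}

#' Write / read an injection-measurement pattern as CSV
#'
#' Columns `inj_a`, `inj_b`, `meas_c`, `meas_d` (electrode indices 1..16).
#'
#' @param pattern An [im_pattern()].
#' @param path CSV file path.
#' @return Write: `path` invisibly; read: an `im_pattern`.
#' @export
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "im_pattern"))
  utils::write.csv(pattern$meas, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path) {
  im_pattern(utils::read.csv(path))
}

#' Write / read thrombus scenarios as CSV
#'
#' Columns `x`, `y`, `z`, `diameter`, `sigma` (plus any extra columns such
#' as `percentile` or `set`); one row per spherical target.
#'
#' @param scenarios A data frame of targets, or a list of scenario data
#'   frames (a `set` column is added).
#' @param path CSV file path.
#' @return Write: `path` invisibly; read: a data frame.
#' @export
write_scenarios_csv <- function(scenarios, path) {
  if (is.data.frame(scenarios)) {
    df <- as.data.frame(scenarios)
  } else {
    df <- do.call(rbind, lapply(seq_along(scenarios), function(i)
      cbind(as.data.frame(scenarios[[i]]), set = i)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenarios_csv
#' @export
read_scenarios_csv <- function(path) {
  utils::read.csv(path)
}

#' Default run configuration
#'
#' One structured configuration drives the whole pipeline. Defaults follow
#' the reference study conditions: 0.662 / 0.0662 / 1e-6 S/m conductivities,
#' 2 mm mesh, a 144 + 32 + 32 = 208 measurement budget, 12 sets of 6
#' optimization targets, 80/10/10 splits, 200 epochs at learning rate 1e-3
#' with regularization 1e-6, and 15 dB frame SNR. Every stochastic stage has
#' an explicit seed.
#'
#' @return Nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(size_x = 0.09, size_y = 0.09, size_z = 0.05,
                    rod_diameter = 0.004, n_rods = 5, rod_spacing = 0.018,
                    grid_plane_z = 0),
    mesh = list(max_h = 0.002),
    electrodes = list(patch_radius = 0.004, contact_impedance = 1e-4,
                      mu_elpos = 0.030, sigma_elpos = 0.012,
                      reference_frac = 0.9),
    pattern = list(pair_mode = "default",
                   counts = list(volume = 144, l1 = 32, l2 = 32)),
    sampler = list(voxel = 0.002, sigma = c(0.045, 0.045, 0.025),
                   n_sets = 12, targets_per_set = 6,
                   percentile_range = c(5, 98), diameter = 0.01,
                   grid_spacing = c(0.004, 0.004, 0.005)),
    surrogate = list(n_random = 8000, widths = c(254, 203), epochs = 200,
                     lr = 1e-3, l2 = 1e-6, momentum = 0.9, leak = 0.01),
    detector = list(n_pos = 3971, n_neg = 3971, widths = c(200, 100),
                    epochs = 200, lr = 1e-3, l2 = 1e-6, momentum = 0.9),
    noise = list(snr_db = 15, target_jitter_frac = 0.1,
                 background_jitter_frac = 0.01),
    split = c(0.8, 0.1, 0.1),
    seeds = list(arrays = 101, sampler = 202, dataset = 303,
                 surrogate = 404, detector = 505),
    output_dir = "oxeit-output"), class = c("run_config", "list"))
}

#' Read, write and validate run configurations (YAML)
#'
#' @param config A `run_config` (any nested list with the required blocks).
#' @param path YAML file path.
#' @return `write_config()`: `path` invisibly; `read_config()`: a validated
#'   `run_config`; `validate_config()`: the config invisibly, or an error
#'   naming the missing key.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname write_config
#' @export
validate_config <- function(config) {
  required <- c("geometry", "mesh", "electrodes", "pattern", "sampler",
                "surrogate", "detector", "noise", "split", "seeds",
                "output_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    stop("configuration is missing required key(s): ",
         paste(missing, collapse = ", "))
  for (s in c("arrays", "sampler", "dataset", "surrogate", "detector"))
    if (is.null(config$seeds[[s]]))
      stop("configuration is missing required key: seeds$", s)
  invisible(config)
}

#' Write / read an evaluation report as JSON
#'
#' @param report An [evaluate_detector()] `eval_report` (or any list of
#'   scalars/matrices).
#' @param path JSON file path.
#' @return Write: `path` invisibly; read: a list.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  if (!is.null(out$confusion)) out$confusion <- as.matrix(unclass(out$confusion))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# append an ISO-timestamped line to a run log (and echo when verbose)
log_line <- function(path, ..., verbose = FALSE) {
  msg <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 paste0(...))
  cat(msg, "\n", file = path, append = TRUE, sep = "")
  if (verbose) message(msg)
  invisible(msg)
}

# md5 of the serialized config, for run provenance
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

#' Write / read an electrode array as CSV
#'
#' Columns `plane`, `spoke`, `radial`, `x`, `y`, `z`; the contact model
#' parameters are stored in a comment-free extra row-wise pair of columns
#' (`patch_radius`, `contact_impedance`) so the file round-trips losslessly.
#'
#' @param array An [electrode_array()].
#' @param path CSV file path.
#' @param geom Geometry used on read (default [oxy_geometry()]).
#' @return Write: `path` invisibly; read: an `electrode_array`.
#' @export
write_array_csv <- function(array, path) {
  stopifnot(inherits(array, "electrode_array"))
  df <- as.data.frame(array)
  df$patch_radius <- attr(array, "patch_radius")
  df$contact_impedance <- attr(array, "contact_impedance")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_array_csv
#' @export
read_array_csv <- function(path, geom = oxy_geometry()) {
  df <- utils::read.csv(path)
  ord <- order(match(df$plane, c("top", "bottom")), df$spoke)
  df <- df[ord, ]
  electrode_array(df$radial, geom = geom,
                  patch_radius = df$patch_radius[1],
                  contact_impedance = df$contact_impedance[1])
}

#' Write / read a detection dataset as CSV
#'
#' One row per sample: `label`, the clot position columns (`NA` for
#' negatives) and the relative voltage differences `m1..mK`.
#'
#' @param dataset A [build_detection_dataset()] result.
#' @param path CSV file path.
#' @return Write: `path` invisibly; read: a `detection_dataset`.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "detection_dataset"))
  M <- as.data.frame(dataset$X)
  names(M) <- paste0("m", seq_len(ncol(M)))
  df <- cbind(data.frame(label = as.character(dataset$y),
                         seed = dataset$seed),
              dataset$targets, M)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path)
  mc <- grep("^m[0-9]+$", names(df))
  tgt_cols <- setdiff(names(df), c("label", "seed", names(df)[mc]))
  structure(list(X = as.matrix(df[, mc]),
                 y = factor(df$label, levels = c("absent", "present")),
                 targets = df[, tgt_cols, drop = FALSE],
                 seed = df$seed[1], noise = NULL),
            class = "detection_dataset")
}
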