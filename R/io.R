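#' Load a design problem from a config file
#'
#' Reads a JSON (or YAML, when the yaml package is installed) problem
#' specification and validates it into a [design_problem()]. Recognized
#' keys: `schema`, `n_genes`, `signal_mask`, `y_lower`, `y_upper`,
#' `x_lower`, `x_upper`, `boxes` (list of `{s_interval, omega_box}`),
#' `n_folds`, `target_label`, `curvature_signs`, `objectives`, `tying`,
#' `s_range`, `s_points`, `n_runs`, `seed`. Unknown keys are rejected
#' with an error naming the offending key.
#'
#' @param path config file path (`.json`, `.yaml`, `.yml`).
#' @return A [design_problem()].
#' @export
load_problem <- function(path) {
  cfg <- read_config(path)
  known <- c("schema", "n_genes", "signal_mask", "y_lower", "y_upper",
             "x_lower", "x_upper", "boxes", "n_folds", "target_label",
             "curvature_signs", "objectives", "tying", "s_range",
             "s_points", "n_runs", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (!is.null(cfg$schema) && cfg$schema != "bifdesign-problem/1")
    stop("unrecognized schema '", cfg$schema, "'")
  args <- list()
  if (!is.null(cfg$n_genes)) args$n_genes <- cfg$n_genes
  if (!is.null(cfg$signal_mask)) args$signal_mask <- cfg$signal_mask
  for (k in c("y_lower", "y_upper"))
    if (!is.null(cfg[[k]]))
      args[[k]] <- matrix(as.integer(unlist(cfg[[k]])),
                          nrow = cfg$n_genes, byrow = TRUE)
  for (k in c("x_lower", "x_upper"))
    if (!is.null(cfg[[k]])) args[[k]] <- unlist(cfg[[k]])
  if (!is.null(cfg$boxes))
    args$boxes <- lapply(cfg$boxes, function(b)
      target_box(unlist(b$s_interval),
                 matrix(unlist(b$omega_box), ncol = 2, byrow = TRUE)))
  for (k in c("n_folds", "target_label", "curvature_signs", "objectives",
              "s_range", "s_points", "n_runs", "seed"))
    if (!is.null(cfg[[k]])) args[[k]] <- unlist(cfg[[k]])
  if (!is.null(cfg$tying)) args$tying <- cfg$tying
  do.call(design_problem, args)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

#' Save a design problem to a JSON config
#' @param problem a [design_problem()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_problem <- function(problem, path) {
  stopifnot(inherits(problem, "design_problem"))
  cfg <- list(schema = "bifdesign-problem/1",
              n_genes = problem$n_genes,
              signal_mask = problem$signal_mask,
              y_lower = apply(problem$y_lower, 1, as.list),
              y_upper = apply(problem$y_upper, 1, as.list),
              x_lower = as.list(problem$x_lower),
              x_upper = as.list(problem$x_upper),
              boxes = lapply(problem$boxes, function(b)
                list(s_interval = b$s_interval,
                     omega_box = apply(b$omega_box, 1, as.list))),
              n_folds = problem$n_folds,
              target_label = problem$target_label,
              objectives = problem$objectives,
              s_range = problem$s_range,
              s_points = problem$s_points,
              n_runs = problem$n_runs,
              seed = problem$seed)
  if (!is.null(problem$curvature_signs))
    cfg$curvature_signs <- problem$curvature_signs
  if (length(problem$tying)) cfg$tying <- problem$tying
  # I(17) significant digits: numeric bounds survive the round trip
  # bit-exactly, so runs replayed from a saved problem are identical
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Export a bifurcation diagram as CSV tables
#'
#' Writes a branch table (`branch_id`, `S`, one column per state
#' coordinate, `stability`) and a fold table (`fold`, `S`, state
#' coordinates, `J`).
#'
#' @param diagram a [bifurcation_diagram()].
#' @param branches_path,folds_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_diagram_csv <- function(diagram, branches_path, folds_path) {
  stopifnot(inherits(diagram, "bifurcation_diagram"))
  pts <- diagram$points
  out <- data.frame(branch_id = pts$branch, S = pts$S,
                    pts[diagram$gene_cols],
                    stability = ifelse(pts$stable, "stable", "unstable"))
  utils::write.csv(out, branches_path, row.names = FALSE)
  utils::write.csv(diagram$saddle_nodes, folds_path, row.names = FALSE)
  invisible(c(branches_path, folds_path))
}

#' Export a phase map as a long-format CSV
#' @param map matrix from [phase_map()].
#' @param path output CSV path.
#' @param axis_names names of the two swept parameters.
#' @return `path`, invisibly.
#' @export
write_phase_map_csv <- function(map, path, axis_names = c("axis1", "axis2")) {
  long <- expand.grid(a1 = rownames(map), a2 = colnames(map),
                      stringsAsFactors = FALSE)
  long$label <- as.vector(map)
  names(long)[1:2] <- axis_names
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write a full run report with replay manifest
#'
#' Serializes a result object to CSV/JSON files plus a `manifest.json`
#' recording the seed, the full configuration and package/R versions --
#' enough to replay the run exactly.
#'
#' @param result a `"design_result"`, `"bifurcation_diagram"`, phase-map
#'   matrix, or `"robustness_report"`.
#' @param dir output directory (created if missing).
#' @param seed the master seed used for the run.
#' @param config optional configuration object stored verbatim in the
#'   manifest (e.g. the [design_problem()]).
#' @return Character vector of written paths, invisibly.
#' @export
run_report <- function(result, dir, seed = NULL, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (inherits(result, "design_result")) {
    sol_rows <- lapply(result$solutions, function(s) {
      data.frame(run = s$run %||% NA_integer_,
                 topology = paste(as_topology_vector(s$topology),
                                  collapse = ","),
                 t(s$x), psi = s$psi, label = s$verified_label,
                 folds_S = paste(signif(s$folds$S, 8), collapse = ";"),
                 check.names = FALSE)
    })
    sol_path <- file.path(dir, "solutions.csv")
    freq_path <- file.path(dir, "topology_frequency.csv")
    utils::write.csv(if (length(sol_rows)) do.call(rbind, sol_rows)
                     else data.frame(), sol_path, row.names = FALSE)
    utils::write.csv(result$frequency, freq_path, row.names = FALSE)
    paths <- c(sol_path, freq_path)
    if (is.null(seed)) seed <- result$seed
  } else if (inherits(result, "bifurcation_diagram")) {
    paths <- file.path(dir, c("branches.csv", "folds.csv"))
    write_diagram_csv(result, paths[1], paths[2])
  } else if (is.matrix(result) && is.character(result)) {
    paths <- file.path(dir, "phase_map.csv")
    write_phase_map_csv(result, paths)
  } else if (inherits(result, "robustness_report")) {
    paths <- file.path(dir, "robustness.json")
    jsonlite::write_json(unclass(result), paths, auto_unbox = TRUE,
                         digits = NA)
    if (is.null(seed)) seed <- result$seed
  } else stop("unsupported result type")
  manifest <- list(seed = seed,
                   config = serialize_config(config),
                   package = "bifdesign",
                   package_version = as.character(
                     utils::packageVersion("bifdesign")),
                   r_version = R.version.string,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(c(paths, man_path))
}

serialize_config <- function(config) {
  if (is.null(config)) return(NULL)
  if (inherits(config, "design_problem")) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    save_problem(config, tmp)
    jsonlite::read_json(tmp)
  } else config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
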