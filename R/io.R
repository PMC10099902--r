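## known configuration blocks and their constructors
.CONFIG_BLOCKS <- c("anatomy", "kinetics", "transport", "optics", "light",
                    "solver", "ga", "seed", "output_dir", "voxel_size",
                    "n_rays", "n_replicates", "units")

#' Load a run configuration from YAML
#'
#' A configuration file holds named blocks (`anatomy`, `kinetics`,
#' `transport`, `optics`, `light`, `solver`, `ga`) plus scalar settings
#' (`seed`, `voxel_size`, `n_rays`, `n_replicates`, `output_dir`).  Every
#' block is validated through its parameter constructor with defaults
#' filled in; unknown top-level keys or unknown fields inside a block are
#' errors.  The file's MD5 hash is recorded for provenance.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list with validated parameter objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_eleaf("config", "no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .CONFIG_BLOCKS)
  if (length(unknown)) {
    stop_eleaf("config", "unknown configuration keys: ",
               paste(unknown, collapse = ", "))
  }
  build <- function(block, ctor) {
    args <- raw[[block]] %||% list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad)) {
      stop_eleaf("config", "unknown fields in `", block, "`: ",
                 paste(bad, collapse = ", "))
    }
    do.call(ctor, args)
  }
  cfg <- list(anatomy = build("anatomy", anatomy_params),
              kinetics = build("kinetics", kinetic_params),
              transport = build("transport", transport_params),
              optics = build("optics", optical_props),
              light = build("light", light_source),
              ga = build("ga", ga_config),
              solver = raw$solver %||% list(),
              seed = as.integer(raw$seed %||% 1L),
              voxel_size = raw$voxel_size %||% 2,
              n_rays = as.integer(raw$n_rays %||% 20000L),
              n_replicates = as.integer(raw$n_replicates %||% 5L),
              output_dir = raw$output_dir %||% ".",
              provenance = list(file = normalizePath(path),
                                md5 = unname(tools::md5sum(path))))
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration to YAML
#'
#' Round-trips with [load_config()].
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(anatomy = unclass(cfg$anatomy),
              kinetics = unclass(cfg$kinetics),
              transport = unclass(cfg$transport),
              optics = unclass(cfg$optics),
              light = as.list(unclass(cfg$light)),
              solver = cfg$solver,
              seed = cfg$seed, voxel_size = cfg$voxel_size,
              n_rays = cfg$n_rays, n_replicates = cfg$n_replicates,
              output_dir = cfg$output_dir)
  out$light$direction <- as.numeric(out$light$direction)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a 3D field or labelled volume as legacy-VTK text
#'
#' ASCII `STRUCTURED_POINTS` legacy VTK, readable by ParaView and VisIt.
#'
#' @param x A `labelled_volume`, an `absorbed_light_field`, or a numeric
#'   3D array.
#' @param path Output file (conventionally `.vtk`).
#' @param name Dataset name for the scalar field.
#' @param voxel_size Voxel edge (um); taken from `x` when available.
#' @export
write_vtk <- function(x, path, name = "field", voxel_size = NULL) {
  if (inherits(x, "labelled_volume")) {
    arr <- x$label; voxel_size <- x$voxel_size; name <- "label"
    type <- "int"
  } else if (inherits(x, "absorbed_light_field")) {
    arr <- x$absorbed; voxel_size <- x$voxel_size
    type <- "float"
  } else {
    arr <- x
    if (is.null(voxel_size)) voxel_size <- 1
    type <- "float"
  }
  d <- dim(arr)
  if (length(d) != 3L) stop_eleaf("io", "need a 3D array")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("eleaf", name),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               paste("SPACING", voxel_size, voxel_size, voxel_size),
               paste("POINT_DATA", prod(d)),
               paste("SCALARS", name, type, "1"),
               "LOOKUP_TABLE default"), con)
  vals <- as.vector(arr)
  vals[!is.finite(vals)] <- 0
  writeLines(paste(formatC(vals, format = if (type == "int") "d" else "g",
                           digits = 7), collapse = " "), con)
  invisible(path)
}

#' Read back the header of a legacy-VTK file
#'
#' Convenience check for files produced by [write_vtk()].
#'
#' @param path VTK file path.
#' @return List with `dims`, `spacing` and `name`.
#' @export
read_vtk_header <- function(path) {
  ln <- readLines(path, n = 10L)
  dims <- as.integer(strsplit(grep("^DIMENSIONS", ln, value = TRUE),
                              " ")[[1]][-1])
  sp <- as.numeric(strsplit(grep("^SPACING", ln, value = TRUE), " ")[[1]][-1])
  nm <- strsplit(grep("^SCALARS", ln, value = TRUE), " ")[[1]][2]
  list(dims = dims, spacing = sp, name = nm)
}

#' Run the full pipeline for one configuration
#'
#' Geometry -> light -> coupled solve (or a response surface / fit /
#' substitution / sweep), writing CSV results, optional VTK snapshots and
#' a JSON manifest with versions, seeds, hashes and runtimes.
#'
#' @param cfg A `run_config` from [load_config()].
#' @param command One of `"solve"`, `"surface"`, `"substitute"`,
#'   `"sweep"`, `"fit"`, `"build-geometry"`, `"trace"`.
#' @param out_dir Output directory (defaults to `cfg$output_dir`).
#' @param ... Command-specific options: `ci_grid`, `q_grid` (surface),
#'   `alt_condition`, `group` (substitute), `field`, `values` (sweep),
#'   `data` (fit: path to a gas-exchange CSV).
#' @return Invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(cfg, command = "solve", out_dir = NULL, ...) {
  stopifnot(inherits(cfg, "run_config"))
  opts <- list(...)
  out_dir <- out_dir %||% cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  artifacts <- character()
  emit <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    artifacts <<- c(artifacts, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_eleaf(paste0("pipeline:", name), conditionMessage(e))
    })
  }

  if (command == "build-geometry") {
    vols <- stage("geometry",
                  generate_replicates(cfg$anatomy, cfg$n_replicates,
                                      cfg$seed, cfg$voxel_size))
    for (i in seq_along(vols)) {
      p <- file.path(out_dir, sprintf("volume_%02d.vtk", i))
      write_vtk(vols[[i]], p)
      artifacts <- c(artifacts, p)
    }
    stats <- do.call(rbind, lapply(vols, function(v) {
      as.data.frame(measure_anatomy(v))
    }))
    emit(stats, "anatomy_stats.csv")
  } else if (command == "trace") {
    vol <- stage("geometry",
                 pack_mesophyll(cfg$anatomy, cfg$seed, cfg$voxel_size))
    fld <- stage("optics",
                 trace_light(vol, cfg$optics, cfg$light, cfg$n_rays,
                             cfg$seed + 1000L))
    p <- file.path(out_dir, "absorbed_light.vtk")
    write_vtk(fld, p, name = "absorbed")
    artifacts <- c(artifacts, p)
    emit(absorbed_per_chloroplast(fld, vol), "absorbed_per_cell.csv")
  } else if (command == "solve") {
    vol <- stage("geometry",
                 pack_mesophyll(cfg$anatomy, cfg$seed, cfg$voxel_size))
    fld <- stage("optics",
                 trace_light(vol, cfg$optics, cfg$light, cfg$n_rays,
                             cfg$seed + 1000L))
    st <- stage("transport",
                solve_coupled(vol, cfg$transport, fld, cfg$kinetics,
                              cfg$solver))
    emit(data.frame(ci = cfg$transport$ci_boundary,
                    q = cfg$light$incident_ppfd,
                    a_n = st$a_net_leaf, phi_psii = st$phi_psii_leaf,
                    iterations = st$iterations,
                    mass_balance_error = st$mass_balance_error),
         "steady_state.csv")
  } else if (command == "surface") {
    ci_grid <- opts$ci_grid %||% c(100, 280, 700, 1200, 1500)
    q_grid <- opts$q_grid %||% c(100, 500, 1000, 1500, 2000)
    sf <- stage("experiments",
                response_surface(cfg$anatomy, cfg$kinetics, ci_grid, q_grid,
                                 cfg$n_replicates, cfg$seed,
                                 voxel_size = cfg$voxel_size,
                                 n_rays = cfg$n_rays, optics = cfg$optics,
                                 tp = cfg$transport,
                                 solver_cfg = cfg$solver))
    emit(as.data.frame(sf), "surface.csv")
    emit(attr(sf, "summary"), "surface_summary.csv")
  } else if (command == "substitute") {
    alt <- opts$alt_condition %||% "eCO2"
    grp <- opts$group %||% "F9"
    conditions <- opts$conditions %||% data.frame(ci = c(280, 1000),
                                                  q = 2000)
    fs <- stage("experiments",
                factor_substitution(cfg$anatomy, anatomy_preset(alt),
                                    cfg$kinetics, kinetics_preset(alt),
                                    grp, conditions, cfg$n_replicates,
                                    cfg$seed, voxel_size = cfg$voxel_size,
                                    n_rays = cfg$n_rays,
                                    optics = cfg$optics,
                                    tp = cfg$transport,
                                    solver_cfg = cfg$solver))
    emit(as.data.frame(fs), "substitution.csv")
  } else if (command == "sweep") {
    field <- opts$field %||% "porosity"
    values <- opts$values %||% (cfg$anatomy[[field]] * c(0.8, 0.9, 1, 1.1))
    conditions <- opts$conditions %||% data.frame(ci = c(280, 1000), q = 2000)
    sw <- stage("experiments",
                sweep_anatomy(cfg$anatomy, cfg$kinetics, field, values,
                              conditions, cfg$n_replicates, cfg$seed,
                              voxel_size = cfg$voxel_size,
                              n_rays = cfg$n_rays, optics = cfg$optics,
                              tp = cfg$transport, solver_cfg = cfg$solver))
    emit(as.data.frame(sw), "sweep.csv")
  } else if (command == "fit") {
    ds <- if (!is.null(opts$data)) {
      stage("io", read_gas_exchange(opts$data))
    } else {
      stage("fitting", synth_dataset(cfg$kinetics, seed = cfg$seed))
    }
    gacfg <- cfg$ga
    gacfg$seed <- cfg$seed
    fit <- stage("fitting", fit_parameters(ds, gacfg, cfg$kinetics))
    p <- file.path(out_dir, "fit_report.json")
    jsonlite::write_json(list(estimates = as.list(fit$estimates),
                              objective = fit$objective,
                              warnings = fit$warnings),
                         p, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, p)
  } else {
    stop_eleaf("pipeline", "unknown command: ", command)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("eleaf")),
    command = command,
    config_md5 = cfg$provenance$md5 %||% NA,
    seed = cfg$seed,
    replicate_seeds = cfg$seed + seq_len(cfg$n_replicates) - 1L,
    voxel_size = cfg$voxel_size,
    n_rays = cfg$n_rays,
    artifacts = basename(artifacts),
    runtime_s = as.numeric(Sys.time() - t_start, units = "secs"))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(artifacts, mp))
}
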