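#' Read a valve/pipeline configuration file
#'
#' Configurations are YAML or JSON with sections mirroring the package's
#' objects: `fixture` (name/seed) *or* `leaflets` (three blocks of
#' [leaflet_params()] fields, angles in degrees), `mesh`, `gamma`, `flow`,
#' `geometry`, and `output`. Missing sections fall back to documented
#' defaults, and the fully resolved configuration is echoed into the output
#' directory for provenance.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list (the raw configuration).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# resolved defaults for every pipeline stage
default_pipeline_config <- function() {
  list(
    fixture = list(name = "severe", seed = 42),
    geometry = list(nu = 25, nv = 25),
    mesh = list(h_fine = 1.5, h_coarse = 2.25),
    gamma = list(C = 1e8, h_phys = 0),
    flow = list(Re_max = 1200, T = 0.4, T_end = 0.2, dt = 0.01,
                rho = 1060, mu = 3.5e-3, backflow_coeff = 0.5),
    output = "riisvalve-out")
}

# deep-merge user config over defaults
merge_config <- function(user) {
  cfg <- default_pipeline_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], user[[nm]])
    else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

# leaflet parameter sets from a config (fixture or explicit blocks)
config_leaflets <- function(cfg) {
  if (!is.null(cfg$leaflets)) {
    if (length(cfg$leaflets) != 3L)
      stop("config: 'leaflets' must contain exactly three blocks")
    lapply(cfg$leaflets, leaflet_params_from_degrees)
  } else {
    fx <- cfg$fixture
    generate_fixture(fx$name, seed = fx$seed,
                     jitter = if (!is.null(fx$jitter)) fx$jitter
                     else if (is.null(fx$seed)) 0 else 0.05)
  }
}

# content hash of a config subsection (base tools::md5sum on canonical JSON)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

# stage caching: returns TRUE if the stage may be skipped
stage_cached <- function(dir, stage, hash, outputs) {
  hf <- file.path(dir, paste0(stage, ".hash"))
  file.exists(hf) && identical(readLines(hf, warn = FALSE), hash) &&
    all(file.exists(file.path(dir, outputs)))
}

stage_done <- function(dir, stage, hash) {
  writeLines(hash, file.path(dir, paste0(stage, ".hash")))
}

#' Run the full geometry-to-hemodynamics pipeline
#'
#' Executes the stages geometry (valve assembly + surface export), mesh
#' (graded cylinder tetrahedralization), gamma (resistive field), simulate
#' (penalized transient flow) and postprocess (peak velocity, transvalvular
#' drop, Bernoulli ratio) into an artifact directory. Each stage writes a
#' content hash of the configuration it consumed; reruns with unchanged
#' upstream configuration are skipped. Any stage error aborts with the stage
#' name and an echo of the resolved configuration.
#'
#' @param config A file path or configuration list
#'   (see [read_pipeline_config()]).
#' @param dry_run If `TRUE`, validate and echo the resolved configuration
#'   without computing anything.
#' @param verbose Log stage progress.
#' @return Invisibly, a list with the resolved config, the artifact paths,
#'   and (unless `dry_run`) the summary statistics.
#' @export
run_pipeline <- function(config, dry_run = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_config(config)
  leaflets <- config_leaflets(cfg)  # validates parameters
  say <- function(...) if (verbose) message(sprintf(...))

  if (dry_run) {
    say("dry run: configuration valid (output -> %s)", cfg$output)
    return(invisible(list(config = cfg)))
  }
  dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
  echo_path <- file.path(cfg$output, "config-resolved.json")
  jsonlite::write_json(cfg, echo_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  run_stage <- function(stage, hash, outputs, fn) {
    if (stage_cached(cfg$output, stage, hash, outputs)) {
      say("[%s] cached, skipping", stage)
      return(FALSE)
    }
    say("[%s] running ...", stage)
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s\nresolved config: %s",
                   stage, conditionMessage(e), echo_path), call. = FALSE)
    })
    stage_done(cfg$output, stage, hash)
    TRUE
  }

  h_geo <- config_hash(list(cfg$fixture, cfg$leaflets, cfg$geometry))
  valve <- assemble_valve(leaflets)
  run_stage("geometry", h_geo, c("valve.stl", "valve.vtk", "leaflets.json"),
            function() {
    sample_and_export(valve, cfg$geometry$nu, cfg$geometry$nv,
                      file.path(cfg$output, "valve.stl"), "stl")
    sample_and_export(valve, cfg$geometry$nu, cfg$geometry$nv,
                      file.path(cfg$output, "valve.vtk"), "vtk")
    jsonlite::write_json(
      lapply(leaflets, function(p) unclass(p)),
      file.path(cfg$output, "leaflets.json"), auto_unbox = TRUE, digits = NA)
  })

  h_mesh <- config_hash(list(h_geo, cfg$mesh))
  spec <- cylinder_spec_for_valve(valve, cfg$mesh$h_fine, cfg$mesh$h_coarse)
  mesh_path <- file.path(cfg$output, "mesh.vtk")
  mesh <- NULL
  run_stage("mesh", h_mesh, "mesh.vtk", function() {
    mesh <<- generate_cylinder_mesh(spec)
    write_vtk_mesh(mesh, mesh_path)
  })
  if (is.null(mesh)) mesh <- generate_cylinder_mesh(spec)

  h_gamma <- config_hash(list(h_mesh, cfg$gamma))
  gamma_path <- file.path(cfg$output, "gamma.vtk")
  gam <- NULL
  run_stage("gamma", h_gamma, "gamma.vtk", function() {
    gam <<- build_gamma(mesh, valve,
                        resistive_config(C = cfg$gamma$C,
                                         h_phys = cfg$gamma$h_phys))
    export_gamma(gam, mesh, gamma_path)
  })
  if (is.null(gam)) {
    vals <- read_vtk_mesh(gamma_path)$point_data$gamma
    gam <- structure(list(values = vals,
                          epsilon_used = compute_epsilon(mesh$h_max,
                                                         cfg$gamma$h_phys),
                          support_count = sum(vals > 0), C = cfg$gamma$C),
                     class = "gamma_field")
  }

  h_sim <- config_hash(list(h_gamma, cfg$flow))
  series_path <- file.path(cfg$output, "diagnostics.csv")
  fields_path <- file.path(cfg$output, "solution.vtk")
  state <- NULL
  run_stage("simulate", h_sim, c("diagnostics.csv", "solution.vtk"),
            function() {
    inflow <- inflow_spec(T = cfg$flow$T, T_end = cfg$flow$T_end,
                          Re_max = cfg$flow$Re_max)
    props <- fluid_properties(rho = cfg$flow$rho, mu = cfg$flow$mu)
    sc <- solver_config(dt = cfg$flow$dt,
                        backflow_coeff = cfg$flow$backflow_coeff)
    state <<- run_simulation(mesh, gam, inflow, sc, props,
                             z_up = -valve$max_l_h,
                             z_down = 3 * valve$max_l_h,
                             verbose = verbose)
    write.csv(state$series, series_path, row.names = FALSE)
    write_vtk_mesh(mesh, fields_path,
                   point_data = list(pressure = state$p,
                                     velocity = state$u))
  })
  series <- read.csv(series_path)

  h_post <- config_hash(list(h_sim, "postprocess"))
  summary_path <- file.path(cfg$output, "summary.json")
  run_stage("postprocess", h_post, "summary.json", function() {
    pk_v <- max(series$v_max)
    pk_dp <- max(series$dP)
    summ <- list(
      peak_v_max_ms = pk_v,
      peak_dP_mmHg = pk_dp,
      bernoulli_ratio = pk_dp / pk_v^2,
      bernoulli_flag = (pk_dp / pk_v^2) >= 4,
      support_count = gam$support_count,
      epsilon_mm = gam$epsilon_used,
      orifice_area_mm2 = orifice_area(leaflets),
      n_nodes = nrow(mesh$nodes), n_cells = nrow(mesh$cells))
    jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  say("pipeline complete -> %s", cfg$output)
  invisible(list(config = cfg, output = cfg$output,
                 summary = jsonlite::fromJSON(summary_path)))
}
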