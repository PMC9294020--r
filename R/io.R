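# Configuration files, result serialisation and run provenance.
#
# Scenario configs are YAML or JSON.  Either a single key `case_id: 1..9`
# naming a reference case, or an explicit description:
#   geometry: {length_mm, min_clearance_mm}
#   permeability_m2: 1e-10
#   side_holes: true | false | <count>
#   occlusion: {present, start_mm, length_mm}
#   pressures_pa: {inlet, outlet}
#   fluid: {density, viscosity}
# Lengths in config files are millimetres; everything internal is SI.

config_keys <- list(
  top = c("case_id", "geometry", "permeability_m2", "side_holes",
          "occlusion", "pressures_pa", "fluid"),
  geometry = c("length_mm", "min_clearance_mm"),
  occlusion = c("present", "start_mm", "length_mm"),
  pressures_pa = c("inlet", "outlet"),
  fluid = c("density", "viscosity")
)

check_keys <- function(x, allowed, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown config key(s): ",
         paste(paste0(path, bad), collapse = ", "))
  }
}

num1 <- function(x, path) {
  if (is.null(x)) return(NULL)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("config key ", path, " must be a single finite number")
  }
  as.numeric(x)
}

#' Build a scenario from a configuration list
#'
#' @param cfg A named list as parsed from a YAML/JSON scenario file.
#' @return A validated `scenario`.
#' @seealso [read_scenario()]
#' @export
scenario_from_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping (named list)")
  check_keys(cfg, config_keys$top, "")
  if (!is.null(cfg$case_id)) {
    others <- setdiff(names(cfg), "case_id")
    if (length(others)) {
      stop("config conflict: case_id fixes all model choices; remove key(s) ",
           paste(others, collapse = ", "))
    }
    return(make_scenario(cfg$case_id))
  }
  geom <- cfg$geometry %||% list()
  check_keys(geom, config_keys$geometry, "geometry/")
  L <- (num1(geom$length_mm, "geometry/length_mm") %||% 240) * 1e-3
  clear <- (num1(geom$min_clearance_mm, "geometry/min_clearance_mm") %||%
              0.1) * 1e-3
  alpha <- num1(cfg$permeability_m2, "permeability_m2") %||% 0
  if (alpha < 0) stop("config key permeability_m2 must be >= 0")
  sh <- cfg$side_holes %||% TRUE
  if (is.logical(sh)) {
    n_holes <- if (isTRUE(sh)) 42L else 0L
  } else {
    n_holes <- as.integer(num1(sh, "side_holes"))
    if (!n_holes %in% c(0L, 42L)) {
      stop("config key side_holes must be true, false, 0 or 42")
    }
  }
  st <- default_stent_spec(permeability = alpha, shaft_length = L)
  if (n_holes == 0L) {
    st$n_side_holes <- 0L
    st$holes_per_coil <- 0L
  }
  profile <- default_ureter_profile(L)
  occ_cfg <- cfg$occlusion %||% list(present = FALSE)
  check_keys(occ_cfg, config_keys$occlusion, "occlusion/")
  occ <- if (isTRUE(occ_cfg$present)) {
    if (is.null(occ_cfg$start_mm) && is.null(occ_cfg$length_mm)) {
      default_occlusion(profile, default_stent_spec(shaft_length = L))
    } else {
      occlusion_spec(TRUE,
                     start = num1(occ_cfg$start_mm,
                                  "occlusion/start_mm") * 1e-3,
                     length = num1(occ_cfg$length_mm,
                                   "occlusion/length_mm") * 1e-3)
    }
  } else {
    occlusion_spec(FALSE)
  }
  pp <- cfg$pressures_pa %||% list()
  check_keys(pp, config_keys$pressures_pa, "pressures_pa/")
  fl_cfg <- cfg$fluid %||% list()
  check_keys(fl_cfg, config_keys$fluid, "fluid/")
  scenario(profile = profile, stent = st, occlusion = occ,
           fluid = fluid_props(
             density = num1(fl_cfg$density, "fluid/density") %||% 997.044,
             viscosity = num1(fl_cfg$viscosity,
                              "fluid/viscosity") %||% 0.001),
           inlet_pressure = num1(pp$inlet, "pressures_pa/inlet") %||% 97.8,
           outlet_pressure = num1(pp$outlet, "pressures_pa/outlet") %||% 0,
           side_holes_enabled = n_holes > 0L,
           min_clearance = clear)
}

#' Canonical configuration list of a scenario
#'
#' Inverse of [scenario_from_config()] up to normalisation:
#' `scenario_from_config(scenario_to_config(sc))` reproduces `sc`.
#'
#' @param sc A `scenario`.
#' @return A named list suitable for YAML/JSON serialisation.
#' @export
scenario_to_config <- function(sc) {
  validate_scenario(sc)
  if (!is.na(sc$case_id)) return(list(case_id = sc$case_id))
  list(
    geometry = list(length_mm = sc$profile$total_length * 1e3,
                    min_clearance_mm = sc$min_clearance * 1e3),
    permeability_m2 = sc$stent$permeability,
    side_holes = sc$side_holes_enabled && sc$stent$n_side_holes > 0L,
    occlusion = if (sc$occlusion$present) {
      list(present = TRUE, start_mm = sc$occlusion$start * 1e3,
           length_mm = sc$occlusion$length * 1e3)
    } else {
      list(present = FALSE)
    },
    pressures_pa = list(inlet = sc$inlet_pressure,
                        outlet = sc$outlet_pressure),
    fluid = list(density = sc$fluid$density,
                 viscosity = sc$fluid$viscosity)
  )
}

#' Read a scenario configuration file
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A validated `scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("unsupported config extension '.", ext,
                     "' (use .yaml or .json)"))
  scenario_from_config(cfg)
}

# 32-bit FNV-1a over the canonical config serialisation; provenance only.
config_hash <- function(sc) {
  s <- jsonlite::toJSON(scenario_to_config(sc), auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))  # fold to 31 bits
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

run_record <- function(sc, seed = NA_integer_) {
  list(package = "stentflow",
       version = as.character(utils::packageVersion("stentflow")),
       solver = "direct sparse Cholesky on the nodal conductance system",
       seed = seed,
       config_hash = config_hash(sc),
       config = scenario_to_config(sc))
}

write_units_csv <- function(df, units, path) {
  con <- file(path, open = "wb")  # binary mode: byte-identical across runs
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(paste(units, collapse = ","), con)
  for (i in seq_len(nrow(df))) {
    cells <- vapply(df[i, ], function(v) {
      if (is.numeric(v)) sprintf("%.6g", v) else as.character(v)
    }, character(1))
    writeLines(paste(cells, collapse = ","), con)
  }
  invisible(path)
}

#' Write a flow solution to disk
#'
#' Writes `profile.csv` (per-segment decomposition), `holes.csv`
#' (per-side-hole flows) and `summary.json` (totals, activity, Reynolds
#' check, and the run record with package version, seed and config hash).
#' CSV files carry a units row under the header; identical scenario and
#' seed give byte-identical files.
#'
#' @param sol A `stent_flow` solution.
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the run record.
#' @return The output directory, invisibly.
#' @export
write_solution <- function(sol, dir, seed = NA_integer_) {
  stopifnot(inherits(sol, "stent_flow"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg <- sol$segments
  write_units_csv(
    seg[, c("segment", "hole_left", "hole_right", "x", "m_intra", "m_extra",
            "m_wall", "m_total", "wall_exchange")],
    c("index", "index", "index", "m", "kg/s", "kg/s", "kg/s", "kg/s",
      "kg/s"),
    file.path(dir, "profile.csv"))
  write_units_csv(sol$holes, c("index", "m", "kg/s"),
                  file.path(dir, "holes.csv"))
  rr <- reynolds_report(sol)
  s <- summary(sol)
  out <- list(run_record = run_record(sol$network$scenario, seed),
              m_total = sol$m_total,
              avg_total_flow = mean(seg$m_total),
              max_residual = sol$max_residual,
              max_reynolds = max(rr$Re),
              all_laminar = all(rr$laminar),
              active_holes = s$active_holes)
  jsonlite::write_json(out, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
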