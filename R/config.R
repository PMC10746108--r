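# Configuration, provenance and file IO.
#
# Configs are YAML; results are CSV tables plus a JSON metadata sidecar
# carrying the resolved config, its hash, seeds and package version, which is
# sufficient for bit-identical replay of the deterministic stages.

#' Load a reaction scheme from a config source
#'
#' With `config_source = NULL` the packaged default scheme is returned.
#' Otherwise `config_source` is a YAML file path or an equivalent nested list
#' with optional blocks `solution` (concentrations), `species` (extra species
#' entries) and `reactions` (extra or replacement reactions). Extra reactions
#' are appended to the default scheme unless `replace: true`.
#'
#' @param config_source `NULL`, a YAML path, or a list.
#' @return A validated [reaction_network()].
#' @examples
#' net <- load_scheme()
#' @export
load_scheme <- function(config_source = NULL) {
  if (is.null(config_source)) return(default_scheme())
  cfg <- if (is.character(config_source)) {
    if (!file.exists(config_source)) stop("config file not found: ", config_source)
    yaml::read_yaml(config_source)
  } else if (is.list(config_source)) config_source
  else stop("config_source must be NULL, a path, or a list")

  sol <- cfg$solution %||% list()
  net <- default_scheme(
    cystamine_conc = sol$cystamine %||% 0,
    fe2_conc = sol$fe2 %||% 1e-3,
    o2_conc = sol$o2 %||% 2.5e-4,
    hplus_conc = sol$hplus %||% 0.4
  )
  if (!is.null(cfg$species)) {
    extra <- purrr::map_dfr(cfg$species, function(s) {
      req <- c("name", "charge", "diffusion_coefficient")
      if (!all(req %in% names(s)))
        stop("species entry needs fields: ", paste(req, collapse = ", "))
      tibble::tibble(
        name = s$name, charge = as.integer(s$charge),
        diffusion_coefficient = s$diffusion_coefficient,
        is_bulk = isTRUE(s$is_bulk), conc = s$conc %||% 0,
        nH = as.integer(s$nH %||% 0), nO = as.integer(s$nO %||% 0),
        nS = as.integer(s$nS %||% 0), nN = as.integer(s$nN %||% 0),
        nC = as.integer(s$nC %||% 0), nFe = as.integer(s$nFe %||% 0)
      )
    })
    net$species <- dplyr::bind_rows(net$species, extra)
  }
  if (!is.null(cfg$reactions)) {
    extra <- purrr::map_dfr(cfg$reactions, function(r) {
      req <- c("id", "reactants", "products", "k25")
      if (!all(req %in% names(r)))
        stop("reaction entry needs fields: ", paste(req, collapse = ", "))
      new_reaction_row(
        as.character(r$id), as.character(unlist(r$reactants)),
        as.character(unlist(r$products)),
        as.numeric(r$k25),  # YAML floats like "1.1e9" may arrive as strings
        kinetic_class = r$kinetic_class %||% "fully-diffusion-controlled",
        no_ionic = isTRUE(r$no_ionic),
        bulk_stage = r$bulk_stage %||% TRUE,
        note = r$note %||% ""
      )
    })
    net$reactions <- if (isTRUE(cfg$replace)) extra
      else dplyr::bind_rows(net$reactions, extra)
  }
  validate_network(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a reaction network to JSON (provenance dump)
#'
#' @param network A [reaction_network()].
#' @param path Output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
network_to_json <- function(network, path = NULL) {
  x <- list(
    species = network$species,
    reactions = dplyr::mutate(
      network$reactions,
      reactants = purrr::map_chr(.data$reactants, paste, collapse = " + "),
      products = purrr::map_chr(.data$products, paste, collapse = " + ")
    )
  )
  js <- jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

default_run_config <- function() {
  list(
    beam = list(ion = "12C6+", energy_per_nucleon = NULL, let = NULL,
                segment_um = NULL),
    solution = list(cystamine = 0, fe2 = 1e-3, o2 = 2.5e-4, hplus = 0.4),
    track = as.list(default_track_params()),
    engine = list(t_handoff_s = 1e-6, cutoff_nm = 120),
    experiment = list(replicates = 10, t_end_s = 200),
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Merges a YAML file (or list) over the package defaults and validates the
#' result: exactly one of `beam.energy_per_nucleon` / `beam.let`,
#' non-negative concentrations, known species in any scavenger overrides.
#' Schema violations are reported with their field paths.
#'
#' @param source YAML file path, a list, or `NULL` for pure defaults.
#' @return A list of class `run_config` with a `hash` attribute.
#' @export
load_run_config <- function(source = NULL) {
  user <- if (is.null(source)) list()
    else if (is.character(source)) yaml::read_yaml(source)
    else if (is.list(source)) source
    else stop("source must be NULL, a path, or a list")
  cfg <- utils::modifyList(default_run_config(), user)
  for (f in c("cystamine", "fe2", "o2", "hplus")) {
    v <- cfg$solution[[f]]
    if (!is.numeric(v) || v < 0) stop("solution.", f, ": must be numeric >= 0")
  }
  if (!is.null(cfg$beam$energy_per_nucleon) && !is.null(cfg$beam$let))
    stop("beam: give exactly one of energy_per_nucleon or let")
  if (is.null(cfg$beam$energy_per_nucleon) && is.null(cfg$beam$let))
    stop("beam: give one of energy_per_nucleon or let")
  if (!is.null(cfg$experiment$scavengers)) {
    known <- default_species()$name
    bad <- setdiff(names(cfg$experiment$scavengers), known)
    if (length(bad) > 0)
      stop("experiment.scavengers: unknown species ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(cfg$seed)) stop("seed: must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  attr(cfg, "hash") <- rlang::hash(cfg)
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Write run outputs with provenance metadata
#'
#' Writes each tabular component of a result object as CSV and a JSON
#' metadata sidecar (config hash, seeds, package version) to `dir`.
#'
#' @param result A result object (e.g. from [run_kinetics_experiment()] or
#'   [run_concentration_scan()]) or a named list of data frames.
#' @param dir Output directory, created if missing.
#' @param name Stem for the output files.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, dir, name = "run") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- if (is.data.frame(result)) list(table = result)
    else Filter(is.data.frame, unclass(result))
  meta <- attr(result, "meta") %||%
    (if (is.list(result) && !is.null(result$meta)) result$meta else list())
  if (inherits(result, "track_segment")) {
    meta <- list(ion = result$beam$ion %||% NA,
                 energy_per_nucleon = result$beam$energy_per_nucleon,
                 let = result$let, length_nm = result$length_nm,
                 deposited_eV = result$deposited_eV,
                 n_events = result$n_events, seed = result$seed,
                 params = utils::modifyList(
                   unclass(result$params),
                   list(yields_1ps = as.list(result$params$yields_1ps))))
  }
  meta$package_version <- as.character(utils::packageVersion("frickeirt"))
  meta$written <- format(Sys.time(), tz = "UTC")
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(name, "_", nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  pm <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, pm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, pm))
}

#' Reload a serialized track segment for replay
#'
#' Reads the particle CSV and JSON metadata written by [write_results()] for
#' a [generate_track()] segment and rebuilds a `track_segment` that can be
#' fed to [run_track_stage()].
#'
#' @param csv Particle table path (`species`, `x`, `y`, `z`, ...).
#' @param json Metadata sidecar path.
#' @return A `track_segment`.
#' @export
read_track_segment <- function(csv, json) {
  p <- tibble::as_tibble(utils::read.csv(csv))
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  pl <- meta$params
  pl$yields_1ps <- unlist(pl$yields_1ps)
  if (is.null(names(pl$yields_1ps)))
    names(pl$yields_1ps) <- c("ion", "exc_radical", "exc_molecular")
  params <- do.call(track_params, pl)
  structure(list(
    particles = p, event_x = NULL, let = as.numeric(meta$let),
    length_nm = as.numeric(meta$length_nm),
    deposited_eV = as.numeric(meta$deposited_eV),
    n_events = as.integer(meta$n_events),
    beam = beam_spec(let = meta$let, segment_um = meta$length_nm / 1000,
                     ion = meta$ion %||% "12C6+"),
    params = params, seed = meta$seed
  ), class = "track_segment")
}
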