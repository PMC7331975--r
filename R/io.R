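#' Save a kinetic model to a JSON text file
#'
#' Stores class energies, barrier energies keyed by canonical transition
#' label, the decoy offset, kinetics constants, and optionally the
#' environment, at full double precision (round-trips bit-exactly through
#' [load_model()]).
#'
#' @param model An [energy_model()].
#' @param path Output file.
#' @param env Optional [transport_env()] to embed.
#' @param cfg Optional [kinetics_config()] to embed.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path, env = NULL, cfg = NULL) {
  obj <- list(state_energy = as.list(model$E),
              barrier_energy = as.list(model$B),
              ddG = model$ddG)
  if (!is.null(cfg)) { obj$k0 <- cfg$k0; obj$split <- cfg$split }
  if (!is.null(env)) obj$dmu <- as.list(unclass(env))
  ## 17 significant digits: lossless text representation of IEEE doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a kinetic model saved by [save_model()]
#'
#' @param path JSON file.
#' @param space The `state_space` the model belongs to (labels must match).
#' @return A list with `model` (an `energy_model`), and `env`/`cfg` when the
#'   file embeds them (else `NULL`).
#' @export
load_model <- function(path, space) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- energy_model(space, unlist(obj$state_energy),
                        unlist(obj$barrier_energy),
                        ddG = as.numeric(obj$ddG %||% 0))
  env <- if (!is.null(obj$dmu)) do.call(transport_env, as.list(obj$dmu))
  cfg <- if (!is.null(obj$k0))
    kinetics_config(k0 = obj$k0, split = obj$split %||% 0.5)
  list(model = model, env = env, cfg = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## strict-key helper: error on unknown fields, naming them
.check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop("configuration error in '", where, "': unknown key(s) ",
         paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' Load and validate a run configuration (YAML)
#'
#' A run configuration describes the machine (conformations, species,
#' exclusions), the environment (`dmu` per species), the kinetics
#' (`k0`, `split`, `ddG`), the fitness goal, the Monte Carlo settings, an
#' optional analysis block (sweep grid), and a seed. Unknown keys anywhere
#' are rejected with an error naming them.
#'
#' @param path YAML file.
#' @return A list of constructed objects: `spec` ([machine_spec()]), `space`
#'   (a `state_space`), `env`, `kinetics`, `ddG`, `fitness`, `mc`
#'   ([mc_config()]), `analysis` (list), `seed`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, c("machine", "environment", "kinetics", "fitness", "mc",
                     "analysis", "seed"), "config")
  if (is.null(cfg$machine)) stop("configuration error: missing machine block")
  .check_keys(cfg$machine, c("conformations", "species", "exclusions"),
              "machine")
  confs <- unlist(cfg$machine$conformations)
  species <- lapply(cfg$machine$species, function(s) {
    .check_keys(s, c("name", "code", "exclusive_group", "decoy_of"),
                "machine/species")
    if (!is.null(s$code) && !is.character(s$code))
      stop("configuration error: species code must be a quoted letter ",
           "(YAML reads a bare N or Y as a boolean)")
    species_spec(s$name, s$code %||% toupper(substr(s$name, 1, 1)),
                 exclusive_group = s$exclusive_group, decoy_of = s$decoy_of)
  })
  spec <- machine_spec(confs, species,
                       exclusions = unlist(cfg$machine$exclusions) %||%
                         character())
  space <- state_space(spec)
  sp_names <- vapply(species, `[[`, character(1), "name")

  envb <- cfg$environment %||% list()
  .check_keys(envb, c("dmu"), "environment")
  dmu <- unlist(envb$dmu) %||% stats::setNames(numeric(0), character(0))
  unknown_sp <- setdiff(names(dmu), sp_names)
  if (length(unknown_sp))
    stop("configuration error: environment names unknown species ",
         paste(unknown_sp, collapse = ", "))
  env <- do.call(transport_env, as.list(dmu))

  kb <- cfg$kinetics %||% list()
  .check_keys(kb, c("k0", "split", "ddG"), "kinetics")
  kin <- kinetics_config(k0 = kb$k0 %||% 1e-3, split = kb$split %||% 0.5)
  ddG <- kb$ddG %||% 0

  fb <- cfg$fitness %||% list(kind = "symport")
  .check_keys(fb, c("kind", "substrate", "decoy", "epsilon"), "fitness")
  for (s in c(fb$substrate, fb$decoy))
    if (!is.null(s) && !(s %in% sp_names))
      stop("configuration error: fitness names unknown species ", s)
  fitness <- fitness_spec(fb$kind %||% "symport",
                          substrate = fb$substrate %||% "substrate",
                          decoy = fb$decoy,
                          epsilon = fb$epsilon %||% 1e-15)

  mb <- cfg$mc %||% list()
  .check_keys(mb, c("n_steps", "thin", "beta_schedule", "step_size",
                    "state_bounds", "barrier_bounds"), "mc")
  sched <- if (is.null(mb$beta_schedule)) NULL
           else lapply(mb$beta_schedule, unlist)
  mc_args <- list(n_steps = mb$n_steps %||% 1e6, thin = mb$thin %||% 500,
                  step_size = mb$step_size %||% 1.0,
                  seed = cfg$seed %||% 1)
  if (!is.null(sched)) mc_args$beta_schedule <- sched
  if (!is.null(mb$state_bounds)) mc_args$state_bounds <- unlist(mb$state_bounds)
  if (!is.null(mb$barrier_bounds))
    mc_args$barrier_bounds <- unlist(mb$barrier_bounds)
  mc <- do.call(mc_config, mc_args)

  ab <- cfg$analysis %||% list()
  .check_keys(ab, c("sweep_species", "sweep_from", "sweep_to", "sweep_step"),
              "analysis")

  list(spec = spec, space = space, env = env, kinetics = kin, ddG = ddG,
       fitness = fitness, mc = mc, analysis = ab, seed = cfg$seed %||% 1)
}

#' Write a trajectory index as CSV
#'
#' One row per recorded model: step, fitness score, and fluxes.
#'
#' @param traj A `model_trajectory`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
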