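## Hand-built reference models. Barrier conventions: pathway edges carry low
## barriers (LOW, ~3 kBT), all other edges high barriers (HIGH, 15 kBT) that
## suppress off-pathway flow by a factor ~e^-12. The discriminator constants
## were tuned numerically by direct steady-state solves (see the package
## vignette); they are frozen here, not computed at load time.
.FX_LOW <- 3
.FX_HIGH <- 15

.fx_ion_substrate_spec <- function() {
  machine_spec(species = list(species_spec("ion", "N"),
                              species_spec("substrate", "S")))
}

.fx_decoy_spec <- function() {
  machine_spec(species = list(
    species_spec("ion", "N"),
    species_spec("substrate", "S", exclusive_group = "sub"),
    species_spec("decoy", "W", exclusive_group = "sub",
                 decoy_of = "substrate")))
}

## numerically tuned discriminator (cluster-B-like topology: substrate-first
## binding outside, leak through the ion-only conformational edge, both
## unbinding orders inside). State energies in kBT; decoy entries derived.
.FX_HOPFIELD_E <- c(
  "OF" = -0.14, "OF-Sb" = -2.41, "OF-Nb" = 0.33, "OF-Nb-Sb" = 1.76,
  "IF" = 1.50, "IF-Sb" = 1.47, "IF-Nb" = 0.25, "IF-Nb-Sb" = 1.14)
.FX_HOPFIELD_B <- c(
  "OF <-> OF-Sb" = 3.24, "OF <-> IF" = 4.60,
  "OF-Sb <-> OF-Nb-Sb" = 4.16, "OF-Nb <-> OF-Nb-Sb" = 5.35,
  "OF-Nb <-> IF-Nb" = 3.90, "OF-Nb-Sb <-> IF-Nb-Sb" = 5.49,
  "IF <-> IF-Sb" = 4.39, "IF <-> IF-Nb" = 4.73,
  "IF-Sb <-> IF-Nb-Sb" = 4.26, "IF-Nb <-> IF-Nb-Sb" = 4.54)

#' Reference models (fixtures)
#'
#' Hand-built kinetic models with documented qualitative behavior, used for
#' validation and as analysis examples:
#' \describe{
#'   \item{`ideal_symporter`}{One minimal symport pathway on the 8-class
#'     ion+substrate space (bind ion then substrate outside, transport,
#'     release inside): 1:1 ion:substrate influx, no leaks.}
#'   \item{`mixed_symporter`}{All four minimal symport pathways open (every
#'     binding edge plus the empty and fully-bound conformational edges);
#'     still 1:1 overall.}
#'   \item{`ideal_antiporter`}{Ion in, substrate out, 1:1, via the ion-only
#'     and substrate-only conformational edges.}
#'   \item{`hopfield_discriminator`}{12-class space with a decoy (`ddG = 1`):
#'     an ion leak through the ion-only conformational edge drives substrate
#'     and decoy unbinding in the outward-facing conformation; at the
#'     optimization condition (`dmu_ion = -4`, `dmu_substrate = dmu_decoy =
#'     +2`) the decoy flux vanishes (selectivity far above the equilibrium
#'     factor `e^ddG`) while raising the leak barrier by 100 kBT collapses
#'     selectivity to about `e^ddG`.}
#' }
#' Each fixture's environment is its documented operating condition.
#'
#' @param name One of `"ideal_symporter"`, `"mixed_symporter"`,
#'   `"ideal_antiporter"`, `"hopfield_discriminator"`.
#' @return A list with `space` (a `state_space`), `model` (an
#'   [energy_model()]), and `env` (a [transport_env()]).
#' @export
#' @examples
#' fx <- build_fixture("ideal_symporter")
#' sol <- solve_steady_state(fx$space, fx$model, fx$env)
#' sol$flux  # 1:1 ion and substrate influx
build_fixture <- function(name = c("ideal_symporter", "mixed_symporter",
                                   "ideal_antiporter",
                                   "hopfield_discriminator")) {
  name <- match.arg(name)
  if (name == "hopfield_discriminator") {
    space <- state_space(.fx_decoy_spec())
    B <- stats::setNames(rep(.FX_HIGH, nrow(space$transitions)),
                         space$transitions$label)
    B[names(.FX_HOPFIELD_B)] <- .FX_HOPFIELD_B
    E <- stats::setNames(rep(0, nrow(space$classes)), space$classes$label)
    E[names(.FX_HOPFIELD_E)] <- .FX_HOPFIELD_E
    model <- energy_model(space, E, B, ddG = 1)
    env <- transport_env(ion = -4, substrate = 2, decoy = 2)
    return(list(space = space, model = model, env = env))
  }
  space <- state_space(.fx_ion_substrate_spec())
  open <- switch(name,
    ideal_symporter = c("OF <-> OF-Nb", "OF-Nb <-> OF-Nb-Sb",
                        "OF-Nb-Sb <-> IF-Nb-Sb", "IF-Nb <-> IF-Nb-Sb",
                        "IF <-> IF-Nb", "OF <-> IF"),
    mixed_symporter = c(space$transitions$label[
                          space$transitions$kind == "binding"],
                        "OF <-> IF", "OF-Nb-Sb <-> IF-Nb-Sb"),
    ideal_antiporter = c("OF <-> OF-Nb", "OF-Nb <-> IF-Nb", "IF <-> IF-Nb",
                         "IF <-> IF-Sb", "OF-Sb <-> IF-Sb", "OF <-> OF-Sb"))
  B <- stats::setNames(rep(.FX_HIGH, nrow(space$transitions)),
                       space$transitions$label)
  B[open] <- .FX_LOW
  model <- energy_model(space, rep(0, nrow(space$classes)), B)
  env <- if (name == "ideal_antiporter")
    transport_env(ion = -4, substrate = -2)
  else transport_env(ion = -4, substrate = 2)
  list(space = space, model = model, env = env)
}
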