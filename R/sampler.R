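#' Fitness (Monte Carlo energy) specification
#'
#' By convention lower scores are fitter. The built-in kinds are
#' `symport` (`-J_substrate`: reward substrate influx), `antiport`
#' (`+J_substrate`: reward substrate efflux), and `competitive`
#' (`-J_substrate * (|J_substrate| + epsilon) / (|J_decoy| + epsilon)`:
#' reward substrate influx weighted by substrate-over-decoy selectivity).
#' `custom` takes a function of the named flux vector.
#'
#' @param kind `"symport"`, `"antiport"`, `"competitive"`, or `"custom"`.
#' @param substrate Species whose flux is optimized.
#' @param decoy Decoy species (required for `competitive`).
#' @param epsilon Numerical stabilizer in the competitive score (default
#'   `1e-15`).
#' @param fn For `kind = "custom"`: `function(flux)` returning a scalar.
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(kind = c("symport", "antiport", "competitive",
                                  "custom"),
                         substrate = "substrate", decoy = NULL,
                         epsilon = 1e-15, fn = NULL) {
  kind <- match.arg(kind)
  stopifnot(epsilon > 0)
  if (kind == "competitive" && is.null(decoy))
    stop("configuration error: competitive fitness requires a decoy species")
  if (kind == "custom" && !is.function(fn))
    stop("configuration error: custom fitness requires 'fn'")
  structure(list(kind = kind, substrate = substrate, decoy = decoy,
                 epsilon = epsilon, fn = fn), class = "fitness_spec")
}

#' Evaluate a model's fitness score
#'
#' @param solution A `steady_state` from [solve_steady_state()], or a named
#'   flux vector.
#' @param spec A [fitness_spec()].
#' @return The scalar Monte Carlo energy `E_MC` (lower = fitter).
#' @export
#' @examples
#' evaluate_fitness(c(substrate = 1e-3, decoy = 1e-6),
#'                  fitness_spec("competitive", decoy = "decoy"))
evaluate_fitness <- function(solution, spec) {
  flux <- if (inherits(solution, "steady_state")) solution$flux else solution
  if (!(spec$substrate %in% names(flux)))
    stop("configuration error: no flux for species '", spec$substrate, "'")
  js <- flux[[spec$substrate]]
  switch(spec$kind,
    symport = -js,
    antiport = js,
    competitive = {
      if (!(spec$decoy %in% names(flux)))
        stop("configuration error: no flux for species '", spec$decoy, "'")
      jd <- flux[[spec$decoy]]
      -js * (abs(js) + spec$epsilon) / (abs(jd) + spec$epsilon)
    },
    custom = spec$fn(flux))
}

#' Monte Carlo sampling configuration
#'
#' @param n_steps Number of Monte Carlo steps (default `1e6`).
#' @param thin Record the current model every `thin` steps (default 500).
#' @param beta_schedule Tempering schedule: list of `c(phase_length, beta)`
#'   pairs, cycled for the whole run. `beta` is the inverse sampling
#'   temperature in units where the reference flux `fitness_scale` is 1. The
#'   default `(4e4 steps at beta = 1e5, 1e4 steps at beta = 2)` alternates a
#'   near-greedy optimization phase (the competitive fitness spans many
#'   orders of magnitude, so selection must bite even at small fluxes) with
#'   a hot phase that escapes local fitness basins.
#' @param step_size Maximum energy perturbation per trial move (kBT).
#' @param state_bounds Allowed range for class energies (kBT).
#' @param barrier_bounds Allowed range for barrier energies (kBT).
#' @param seed Integer RNG seed; the whole trajectory is reproducible from
#'   it.
#' @param fitness_scale Reference flux used to non-dimensionalize `E_MC`
#'   before applying `beta` (default `1e-3 * exp(-5)`, the rate across a
#'   typical 5 kBT barrier at the default prefactor, so fluxes are O(1) in
#'   these units).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_steps = 1e6, thin = 500,
                      beta_schedule = list(c(4e4, 1e5), c(1e4, 2)),
                      step_size = 1.0, state_bounds = c(-10, 15),
                      barrier_bounds = c(-5, 20), seed = 1,
                      fitness_scale = 1e-3 * exp(-5)) {
  stopifnot(n_steps >= 1, thin >= 1, step_size >= 0, fitness_scale > 0,
            length(state_bounds) == 2L, length(barrier_bounds) == 2L)
  if (!is.list(beta_schedule) ||
      !all(vapply(beta_schedule, length, integer(1)) == 2L) ||
      !all(vapply(beta_schedule, function(p) p[1] >= 1 && p[2] > 0,
                  logical(1))))
    stop("beta_schedule must be a list of c(phase_length, beta>0) pairs")
  structure(list(n_steps = as.integer(n_steps), thin = as.integer(thin),
                 beta_schedule = beta_schedule, step_size = step_size,
                 state_bounds = state_bounds, barrier_bounds = barrier_bounds,
                 seed = as.integer(seed), fitness_scale = fitness_scale),
            class = "mc_config")
}

## expand the cyclic schedule into a per-step beta vector
.beta_vector <- function(schedule, n_steps) {
  lens <- vapply(schedule, `[`, numeric(1), 1)
  betas <- vapply(schedule, `[`, numeric(1), 2)
  reps <- rep(betas, times = lens)
  rep_len(reps, n_steps)
}

## free (non-derived) parameters of a model on a space
.free_params <- function(space) {
  free_E <- if (is.null(space$class_counterpart))
    seq_len(nrow(space$classes)) else which(is.na(space$class_counterpart))
  free_B <- if (is.null(space$edge_counterpart))
    seq_len(nrow(space$transitions)) else which(is.na(space$edge_counterpart))
  list(E = free_E, B = free_B)
}

#' Propose a tied trial move
#'
#' Picks one free parameter (a class energy or a barrier energy, uniformly
#' among all free parameters) and perturbs it by `uniform(-step_size,
#' +step_size)` kBT. Decoy-linked energies and barriers are re-derived from
#' the tie constraints, so physically equivalent quantities always move
#' together. A proposal that violates an energy bound or the
#' barrier-above-states constraint is returned as a null move
#' (`attr(, "valid") = FALSE`); the sampler counts it as a rejected step.
#'
#' @param model Current [energy_model()].
#' @param space The `state_space`.
#' @param step_size Maximum perturbation (kBT).
#' @param state_bounds,barrier_bounds Allowed ranges (kBT).
#' @return The trial `energy_model` (equal to `model` if the proposal was
#'   invalid), with attribute `valid`.
#' @export
propose_move <- function(model, space, step_size = 1.0,
                         state_bounds = c(-10, 15),
                         barrier_bounds = c(-5, 20)) {
  fp <- .free_params(space)
  nE <- length(fp$E); nB <- length(fp$B)
  j <- sample.int(nE + nB, 1L)
  delta <- stats::runif(1, -step_size, step_size)
  trial <- model
  if (j <= nE) {
    idx <- fp$E[j]
    trial$E[idx] <- trial$E[idx] + delta
    ok <- trial$E[idx] >= state_bounds[1] && trial$E[idx] <= state_bounds[2]
  } else {
    idx <- fp$B[j - nE]
    trial$B[idx] <- trial$B[idx] + delta
    ok <- trial$B[idx] >= barrier_bounds[1] && trial$B[idx] <= barrier_bounds[2]
  }
  if (ok) {
    trial <- .apply_ties(trial, space)
    tr <- space$transitions
    ok <- all(trial$B >= pmax(trial$E[tr$from], trial$E[tr$to]) - 1e-12)
  }
  if (!ok) {
    attr(model, "valid") <- FALSE
    return(model)
  }
  attr(trial, "valid") <- TRUE
  trial
}

#' Metropolis acceptance decision
#'
#' Accepts with probability `min(1, exp(-beta * dE))`. Draws one uniform
#' variate from the current RNG stream.
#'
#' @param dE Fitness difference `E_MC(trial) - E_MC(current)` (already
#'   non-dimensionalized).
#' @param beta Inverse sampling temperature.
#' @return Logical: accept the trial?
#' @export
metropolis_accept <- function(dE, beta) {
  if (is.nan(dE)) return(FALSE)
  if (dE <= 0) return(TRUE)
  if (!is.finite(dE)) return(FALSE)
  stats::runif(1) < exp(-beta * dE)
}

#' Explore model space by Metropolis Monte Carlo with tempering
#'
#' The central sampling routine: starting from `init` (by default all class
#' energies 0 and barriers uniform in [2, 8] kBT), it repeatedly proposes
#' tied single-parameter moves, scores each trial model by its steady-state
#' fitness in `env`, and accepts with the Metropolis criterion
#' `min(1, exp(-beta * dE_MC))` under the cyclic tempering schedule. Every
#' model along the chain is a fully specified, thermodynamically consistent
#' kinetic model; the thinned chain is returned as a trajectory in model
#' space. The run is deterministic given `control$seed` (which is set via
#' [set.seed()] at entry).
#'
#' @param space A `state_space` with transitions.
#' @param env A [transport_env()]; fitness is evaluated at this single
#'   environment (sweeps over conditions are post-hoc analysis).
#' @param fitness A [fitness_spec()].
#' @param control An [mc_config()].
#' @param init Optional initial [energy_model()].
#' @param kinetics A [kinetics_config()].
#' @param ddG Decoy destabilization (kBT) used when `init` is drawn
#'   internally.
#' @param verbose Print phase progress lines.
#' @return An object of class `model_trajectory`: a list with `records`
#'   (each: `step`, `E`, `B`, `E_MC`, `flux`), `best` (index of the fittest
#'   record), `acceptance` (accepted / rejected / invalid counts),
#'   `init_E_MC`, and the configuration objects. `floor(n_steps / thin)`
#'   records are kept.
#' @seealso [best_model()], [plot.model_trajectory()]
#' @export
#' @examples
#' ss <- state_space(machine_spec(species = list(
#'   species_spec("ion", "N"), species_spec("substrate", "S"))))
#' traj <- explore_models(ss, transport_env(ion = -4, substrate = 2),
#'                        fitness_spec("symport"),
#'                        mc_config(n_steps = 2000, thin = 100, seed = 7))
#' best_model(traj)
explore_models <- function(space, env, fitness, control = mc_config(),
                           init = NULL, kinetics = kinetics_config(),
                           ddG = 0, verbose = FALSE) {
  stopifnot(inherits(space, "state_space"), inherits(fitness, "fitness_spec"),
            inherits(control, "mc_config"))
  set.seed(control$seed)
  n <- nrow(space$classes)
  if (is.null(init)) {
    E0 <- rep(0, n)
    tr <- space$transitions
    B0 <- stats::runif(nrow(tr), 2, 8)
    init <- energy_model(space, E0, B0, ddG = ddG)
  }
  eng <- .make_engine(space, env, kinetics)
  fp <- .free_params(space)
  nE <- length(fp$E); nB <- length(fp$B)
  sb <- control$state_bounds; bb <- control$barrier_bounds
  tr_from <- space$transitions$from; tr_to <- space$transitions$to
  cc <- space$class_counterpart; ec <- space$edge_counterpart
  eco <- space$edge_counterpart_offset
  has_ties <- !is.null(cc) && any(!is.na(cc))
  tie_E <- if (has_ties) which(!is.na(cc)) else integer()
  tie_B <- if (has_ties) which(!is.na(ec)) else integer()

  score <- function(E, B) {
    rt <- .rates(eng, E, B)
    P <- .steady_P(.Kmat(eng, rt))
    netflow <- P[eng$ef] * rt$a_f - P[eng$et] * rt$a_r
    flux <- vapply(eng$flux_edges, function(ix) -sum(netflow[ix]), numeric(1))
    list(E_MC = evaluate_fitness(flux, fitness), flux = flux)
  }

  E <- init$E; B <- init$B
  cur <- score(E, B)
  if (!is.finite(cur$E_MC)) stop("non-finite fitness at initialization")
  init_E_MC <- cur$E_MC
  beta <- .beta_vector(control$beta_schedule, control$n_steps)
  scale <- control$fitness_scale
  n_rec <- control$n_steps %/% control$thin
  records <- vector("list", n_rec)
  acc <- 0L; rej <- 0L; inv <- 0L
  best_E_MC <- Inf; best_i <- NA_integer_
  r <- 0L
  for (step in seq_len(control$n_steps)) {
    j <- sample.int(nE + nB, 1L)
    delta <- stats::runif(1, -control$step_size, control$step_size)
    E2 <- E; B2 <- B
    if (j <= nE) {
      idx <- fp$E[j]
      v <- E2[idx] + delta
      ok <- v >= sb[1] && v <= sb[2]
      E2[idx] <- v
    } else {
      idx <- fp$B[j - nE]
      v <- B2[idx] + delta
      ok <- v >= bb[1] && v <= bb[2]
      B2[idx] <- v
    }
    if (ok) {
      if (has_ties) {
        E2[tie_E] <- E2[cc[tie_E]] + init$ddG
        B2[tie_B] <- B2[ec[tie_B]] + init$ddG * eco[tie_B]
      }
      ok <- all(B2 >= pmax(E2[tr_from], E2[tr_to]) - 1e-12)
    }
    if (!ok) {
      inv <- inv + 1L
    } else {
      trial <- score(E2, B2)
      if (is.nan(trial$E_MC))
        stop("non-finite fitness at step ", step)
      dE <- (trial$E_MC - cur$E_MC) / scale
      if (metropolis_accept(dE, beta[step])) {
        E <- E2; B <- B2; cur <- trial
        acc <- acc + 1L
      } else rej <- rej + 1L
    }
    if (step %% control$thin == 0L && r < n_rec) {
      r <- r + 1L
      records[[r]] <- list(step = step, E = E, B = B,
                           E_MC = cur$E_MC, flux = cur$flux)
      if (cur$E_MC < best_E_MC) { best_E_MC <- cur$E_MC; best_i <- r }
      if (verbose && r %% 50L == 0L)
        cat(sprintf("step %d  beta %.3g  E_MC %.4g  acc %.2f\n", step,
                    beta[step], cur$E_MC, acc / step))
    }
  }
  structure(list(records = records, best = best_i, init_E_MC = init_E_MC,
                 acceptance = c(accepted = acc, rejected = rej,
                                invalid = inv),
                 space = space, env = env, fitness = fitness,
                 control = control, kinetics = kinetics, ddG = init$ddG),
            class = "model_trajectory")
}

#' Extract the fittest recorded model from a trajectory
#'
#' @param traj A `model_trajectory` from [explore_models()].
#' @param which Record index; defaults to the fittest record.
#' @return An [energy_model()].
#' @export
best_model <- function(traj, which = traj$best) {
  stopifnot(inherits(traj, "model_trajectory"))
  rec <- traj$records[[which]]
  energy_model(traj$space, rec$E, rec$B, ddG = traj$ddG)
}

#' @export
print.model_trajectory <- function(x, ...) {
  ns <- x$control$n_steps
  cat("model_trajectory:", length(x$records), "records over", ns,
      "MC steps\n")
  a <- x$acceptance
  cat(sprintf("acceptance: %.1f%% accepted, %.1f%% rejected, %.1f%% invalid\n",
              100 * a[1] / ns, 100 * a[2] / ns, 100 * a[3] / ns))
  cat(sprintf("E_MC: init %.4g, best %.4g (record %d)\n", x$init_E_MC,
              x$records[[x$best]]$E_MC, x$best))
  invisible(x)
}

#' @export
summary.model_trajectory <- function(object, ...) {
  print(object)
  em <- vapply(object$records, `[[`, numeric(1), "E_MC")
  cat("\nE_MC quantiles:\n")
  print(stats::quantile(em))
  fl <- do.call(rbind, lapply(object$records, `[[`, "flux"))
  cat("\nfluxes of the fittest model (1/s):\n")
  print(signif(object$records[[object$best]]$flux, 4))
  invisible(object)
}

#' Plot a model-space trajectory
#'
#' Fitness score of the recorded models against Monte Carlo step; local
#' minima are fit models, excursions upward are tempering escapes.
#'
#' @param x A `model_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.model_trajectory <- function(x, ...) {
  steps <- vapply(x$records, `[[`, numeric(1), "step")
  em <- vapply(x$records, `[[`, numeric(1), "E_MC")
  graphics::plot(steps, em, type = "l", xlab = "MC step",
                 ylab = expression(E[MC]), ...)
  graphics::points(steps[x$best], em[x$best], pch = 19, col = 2)
  invisible(x)
}

#' Trajectory records as a data frame
#'
#' @param x A `model_trajectory`.
#' @param ... Unused.
#' @return Data frame with `step`, `E_MC` and one flux column per species.
#' @export
as.data.frame.model_trajectory <- function(x, ...) {
  fl <- do.call(rbind, lapply(x$records, `[[`, "flux"))
  colnames(fl) <- paste0("J_", colnames(fl))
  data.frame(step = vapply(x$records, `[[`, numeric(1), "step"),
             E_MC = vapply(x$records, `[[`, numeric(1), "E_MC"), fl)
}
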