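#' Sweep a species' chemical-potential difference
#'
#' Re-solves the steady state over a grid of chemical-potential differences
#' for one species (all other driving forces fixed) and records every
#' species' flux at each grid point — the stoichiometry analysis behind
#' flux-versus-driving plots.
#'
#' @param space A `state_space` with transitions.
#' @param model An [energy_model()].
#' @param env Base [transport_env()]; the swept species' entry is replaced by
#'   each grid value.
#' @param species Species to sweep (default `"ion"`).
#' @param grid Strictly monotone numeric grid of chemical-potential
#'   differences (kBT). Default `seq(-8, 0, 0.25)`.
#' @param cfg A [kinetics_config()].
#' @param normalize If `TRUE`, add columns with fluxes divided by the largest
#'   absolute flux of the swept species over the grid (display scaling only;
#'   raw fluxes are always kept).
#' @return An object of class `dmu_sweep`: a data frame with column `dmu`
#'   and one flux column per species (`J_<species>`), plus normalized
#'   columns if requested. Grid points where the solver fails are recorded
#'   as `NA` with a warning.
#' @export
#' @examples
#' fx <- build_fixture("ideal_symporter")
#' sw <- sweep_dmu(fx$space, fx$model, fx$env, "ion", seq(-8, 0, 0.5))
#' range(sw$J_substrate / sw$J_ion)  # 1:1 stoichiometry at every point
sweep_dmu <- function(space, model, env, species = "ion",
                      grid = seq(-8, 0, 0.25), cfg = kinetics_config(),
                      normalize = FALSE) {
  stopifnot(length(grid) >= 1, all(diff(grid) > 0) || all(diff(grid) < 0))
  nms <- colnames(space$bound)
  if (!(species %in% nms)) stop("unknown species: ", species)
  out <- matrix(NA_real_, length(grid), length(nms),
                dimnames = list(NULL, paste0("J_", nms)))
  base <- stats::setNames(numeric(length(nms)), nms)
  known <- intersect(names(env), nms)
  base[known] <- unclass(env)[known]
  for (i in seq_along(grid)) {
    e <- base; e[species] <- grid[i]
    sol <- tryCatch(
      solve_steady_state(space, model, do.call(transport_env, as.list(e)),
                         cfg),
      error = function(err) {
        warning("solver failed at dmu = ", grid[i], ": ",
                conditionMessage(err))
        NULL
      })
    if (!is.null(sol)) out[i, ] <- sol$flux[nms]
  }
  df <- data.frame(dmu = grid, out)
  if (normalize) {
    scale <- max(abs(out[, paste0("J_", species)]), na.rm = TRUE)
    norm <- out / scale
    colnames(norm) <- paste0(colnames(out), "_scaled")
    df <- cbind(df, norm)
  }
  attr(df, "species") <- species
  class(df) <- c("dmu_sweep", "data.frame")
  df
}

#' Plot a chemical-potential sweep
#'
#' @param x A `dmu_sweep`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dmu_sweep <- function(x, ...) {
  jc <- grep("^J_", names(x), value = TRUE)
  jc <- jc[!grepl("_scaled$", jc)]
  graphics::matplot(x$dmu, as.matrix(x[jc]), type = "l", lty = 1,
                    xlab = bquote(Delta * mu[.(attr(x, "species"))] ~ (k[B] * T)),
                    ylab = "flux (1/s)", ...)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topleft", legend = sub("^J_", "", jc), lty = 1,
                   col = seq_along(jc), bty = "n")
  invisible(x)
}

#' Transport cost and selectivity of a steady state
#'
#' Cost is the ion-to-substrate flux ratio (ions spent per substrate
#' transported); selectivity is the substrate-to-decoy flux ratio. A zero
#' denominator gives a signed infinity marker (`Inf`/`-Inf` by the
#' numerator's sign; `NaN` for 0/0).
#'
#' @param solution A `steady_state`.
#' @param ion,substrate,decoy Species names; `decoy = NULL` skips
#'   selectivity.
#' @return A list with `cost` and `selectivity` (or `NA` if no decoy).
#' @export
stoichiometry <- function(solution, ion = "ion", substrate = "substrate",
                          decoy = if ("decoy" %in% names(solution$flux))
                            "decoy" else NULL) {
  flux <- solution$flux
  miss <- setdiff(c(ion, substrate, decoy), names(flux))
  if (length(miss))
    stop("configuration error: no flux for species ",
         paste(miss, collapse = ", "))
  list(cost = flux[[ion]] / flux[[substrate]],
       selectivity = if (is.null(decoy)) NA_real_
                     else flux[[substrate]] / flux[[decoy]])
}

#' Select the ion-only conformational transition
#'
#' The conformational transition whose endpoints have only the given ion
#' bound: the central "ion leak" edge whose closure shuts off futile ion
#' cycles in the discriminative models.
#'
#' @param space A `state_space`.
#' @param ion Ion species name.
#' @return Integer vector of transition ids.
#' @export
ion_only_edge <- function(space, ion = "ion") {
  tr <- space$transitions
  b <- space$bound
  only_ion <- b[, ion] & rowSums(b) == 1
  which(tr$kind == "conformational" & only_ion[tr$from] & only_ion[tr$to])
}

#' Perturb transition barriers
#'
#' Returns a copy of the model with the selected barriers shifted by `dE`
#' kBT; tied (decoy-linked) barriers move together because the underlying
#' free parameter is perturbed and the ties re-derived. Used for targeted
#' interventions such as shutting off an ion leak with `dE = 100`.
#'
#' @param model An [energy_model()].
#' @param space The `state_space`.
#' @param edges Transition selector: integer ids, transition labels, or a
#'   predicate `function(transitions)` returning a logical vector.
#' @param dE Barrier shift in kBT.
#' @param check Validate the barrier-above-states constraint on the result.
#' @return A new `energy_model`; the input is untouched.
#' @export
#' @examples
#' fx <- build_fixture("hopfield_discriminator")
#' leak_free <- perturb_barrier(fx$model, fx$space,
#'                              ion_only_edge(fx$space), 100)
perturb_barrier <- function(model, space, edges, dE, check = TRUE) {
  tr <- space$transitions
  idx <- if (is.function(edges)) which(edges(tr))
         else if (is.character(edges)) match(edges, tr$label)
         else as.integer(edges)
  if (length(idx) == 0L || anyNA(idx) || any(idx < 1L | idx > nrow(tr)))
    stop("empty or invalid transition selector")
  ## perturb the free representative so ties stay consistent
  ec <- space$edge_counterpart
  if (!is.null(ec)) idx <- ifelse(is.na(ec[idx]), idx, ec[idx])
  out <- model
  out$B[unique(idx)] <- out$B[unique(idx)] + dE
  out <- .apply_ties(out, space)
  if (check) .check_barriers(out, space)
  out
}

#' Kinetic pathway diagram from steady-state flows
#'
#' Directed graph of the net probability flows, scaled by the largest edge
#' flow; edges below `threshold` times the maximum are omitted (negligible
#' flows are not drawn).
#'
#' @param solution A `steady_state`.
#' @param space The `state_space`.
#' @param threshold Relative display threshold (default `1e-3`).
#' @return An object of class `pathway_diagram`: data frame of directed
#'   edges (`from`, `to` labels, `weight` in (0, 1], `flow` raw) plus the
#'   node set, in deterministic order.
#' @export
pathway_diagram <- function(solution, space, threshold = 1e-3) {
  fl <- solution$flows
  mx <- max(abs(fl$flow))
  if (mx == 0) {
    warning("all net flows are zero: empty diagram")
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), flow = numeric())
  } else {
    keep <- abs(fl$flow) > threshold * mx
    f <- fl[keep, , drop = FALSE]
    lab <- space$classes$label
    fwd <- f$flow >= 0
    edges <- data.frame(
      from = lab[ifelse(fwd, f$from, f$to)],
      to = lab[ifelse(fwd, f$to, f$from)],
      weight = abs(f$flow) / mx, flow = abs(f$flow),
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, nodes = space$classes$label,
                 threshold = threshold),
            class = "pathway_diagram")
}

#' @export
print.pathway_diagram <- function(x, ...) {
  cat("pathway_diagram:", nrow(x$edges), "edges over", length(x$nodes),
      "states (threshold", x$threshold, "x max flow)\n")
  if (nrow(x$edges))
    print(transform(x$edges, weight = round(weight, 3),
                    flow = signif(flow, 3)), row.names = FALSE)
  invisible(x)
}

#' Write a pathway diagram as a DOT graph file
#'
#' @param diagram A [pathway_diagram()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dot <- function(diagram, path) {
  q <- function(s) paste0('"', s, '"')
  lines <- c("digraph pathways {",
             paste0("  ", q(diagram$nodes), ";"),
             sprintf('  %s -> %s [weight=%g, label="%.3f"];',
                     q(diagram$edges$from), q(diagram$edges$to),
                     diagram$edges$weight, diagram$edges$weight),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a sweep as CSV
#'
#' Columns: the swept chemical potential, one flux column per species, and
#' cost/selectivity where defined.
#'
#' @param sweep A `dmu_sweep`.
#' @param path Output file.
#' @param ion,substrate,decoy Species roles for the ratio columns.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(sweep, path, ion = "ion",
                            substrate = "substrate",
                            decoy = if ("J_decoy" %in% names(sweep))
                              "decoy" else NULL) {
  df <- as.data.frame(sweep)
  if (all(paste0("J_", c(ion, substrate)) %in% names(df)))
    df$cost <- df[[paste0("J_", ion)]] / df[[paste0("J_", substrate)]]
  if (!is.null(decoy))
    df$selectivity <- df[[paste0("J_", substrate)]] / df[[paste0("J_", decoy)]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
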