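#' Kinetics configuration
#'
#' @param k0 Overall rate prefactor in 1/s. All rates scale linearly with
#'   `k0`; it sets the absolute time scale but changes no flow ratios or
#'   mechanisms. Default `1e-3`.
#' @param split Chemical-potential splitting factor in (0, 1]. The driving
#'   chemical-potential difference of a species is split across its two
#'   binding events; `1/2` is the symmetrical split. The value has little
#'   effect on the mechanisms discovered.
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(k0 = 1e-3, split = 0.5) {
  stopifnot(is.numeric(k0), length(k0) == 1L, k0 > 0,
            is.numeric(split), length(split) == 1L, split > 0, split <= 1)
  structure(list(k0 = k0, split = split), class = "kinetics_config")
}

#' Environment: chemical-potential differences
#'
#' For species x, `dmu_x = ln([x_in]/[x_out])` in kBT units. Negative values
#' (outside concentration higher) drive net inward flow. Values for species
#' the machine does not bind are ignored.
#'
#' @param ... Named values, e.g. `transport_env(ion = -4, substrate = 2)`,
#'   or a single named numeric vector.
#' @return An object of class `transport_env` (named numeric vector).
#' @export
transport_env <- function(...) {
  v <- c(...)
  if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
    stop("all chemical-potential differences must be named by species")
  if (!all(is.finite(v))) stop("chemical-potential differences must be finite")
  v <- stats::setNames(as.numeric(v), names(v))
  structure(v, class = "transport_env")
}

#' Free-energy parameterization of a kinetic model
#'
#' A model assigns every state class a free energy `E_i` and every reversible
#' transition an absolute transition-state energy `E_ij_bar` (shared by both
#' directions), all in kBT. Decoy-bound classes are constrained to their
#' substrate counterparts so that selectivity can arise only from the
#' binding-affinity offset (Hopfield-type discrimination, no "internal
#' proofreading"): `E(decoy class) = E(counterpart) + ddG`; the decoy's own
#' binding/unbinding transitions carry the counterpart's absolute barrier
#' (equal binding rates, unbinding faster by `exp(ddG)`); and transitions
#' between two decoy-bound classes carry the counterpart's barrier plus
#' `ddG` (equal barrier height: the transition state retains the bound,
#' destabilized decoy, so conformational and ion-binding kinetics of the
#' decoy branch match the substrate branch). These derived entries are
#' overwritten here from the counterparts; supply them freely or not at all.
#'
#' @param space A `state_space` with transitions.
#' @param state_energy Numeric vector of class energies, either unnamed in
#'   class order or named by class label.
#' @param barrier_energy Numeric vector of barrier energies, unnamed in
#'   transition order or named by transition label (`"A <-> B"`).
#' @param ddG Decoy destabilization in kBT (>= 0). Ignored if the machine has
#'   no decoy species.
#' @param check If `TRUE`, enforce `E_ij_bar >= max(E_i, E_j)` on every
#'   transition.
#' @return An object of class `energy_model` with named vectors `E`, `B` and
#'   scalar `ddG`.
#' @export
energy_model <- function(space, state_energy, barrier_energy, ddG = 0,
                         check = TRUE) {
  stopifnot(inherits(space, "state_space"), !is.null(space$transitions),
            is.numeric(ddG), length(ddG) == 1L, ddG >= 0)
  n <- nrow(space$classes); m <- nrow(space$transitions)
  E <- .match_named(state_energy, space$classes$label, "state_energy")
  B <- .match_named(barrier_energy, space$transitions$label, "barrier_energy")
  mod <- structure(list(E = E, B = B, ddG = as.numeric(ddG)),
                   class = "energy_model")
  mod <- .apply_ties(mod, space)
  if (check) .check_barriers(mod, space)
  mod
}

.match_named <- function(x, labels, what) {
  if (is.null(names(x))) {
    if (length(x) != length(labels))
      stop(what, " must have length ", length(labels))
    return(stats::setNames(as.numeric(x), labels))
  }
  if (!setequal(names(x), labels))
    stop(what, " names must match: missing ",
         paste(setdiff(labels, names(x)), collapse = ", "))
  stats::setNames(as.numeric(x[labels]), labels)
}

## re-derive decoy-tied entries from their substrate counterparts
.apply_ties <- function(mod, space) {
  cc <- space$class_counterpart
  if (!is.null(cc) && any(!is.na(cc))) {
    idx <- which(!is.na(cc))
    mod$E[idx] <- mod$E[cc[idx]] + mod$ddG
    ec <- space$edge_counterpart
    jdx <- which(!is.na(ec))
    mod$B[jdx] <- mod$B[ec[jdx]] + mod$ddG * space$edge_counterpart_offset[jdx]
  }
  mod
}

.check_barriers <- function(mod, space) {
  tr <- space$transitions
  lo <- pmax(mod$E[tr$from], mod$E[tr$to])
  bad <- which(mod$B < lo - 1e-12)
  if (length(bad))
    stop("constraint violation: barrier below state energy on ",
         paste(tr$label[bad], collapse = "; "))
  invisible(TRUE)
}

#' Draw a random thermodynamically valid energy model
#'
#' Class energies are uniform in `state_range`; each barrier is the larger
#' endpoint energy plus a uniform draw from `margin`. Decoy ties are applied
#' afterwards, so decoy-bound entries are derived, not drawn.
#'
#' @param space A `state_space` with transitions.
#' @param state_range Range for class energies (kBT).
#' @param margin Range for barrier heights above the larger endpoint (kBT);
#'   the lower end must be `>= ddG` so derived decoy barriers stay valid.
#' @param ddG Decoy destabilization (kBT).
#' @return An `energy_model`.
#' @export
random_energy_model <- function(space, state_range = c(-2, 2),
                                margin = c(1, 6), ddG = 0) {
  n <- nrow(space$classes); m <- nrow(space$transitions)
  E <- stats::runif(n, state_range[1], state_range[2])
  tr <- space$transitions
  B <- pmax(E[tr$from], E[tr$to]) + ddG +
    stats::runif(m, margin[1], margin[2])
  energy_model(space, E, B, ddG = ddG)
}

## -------------------------------------------------------------------------
## Rate engine. Precomputes index arrays for a space so that rates, the
## generator matrix and fluxes can be recomputed cheaply for many energy
## models (the Monte Carlo inner loop).

.make_engine <- function(space, env, cfg) {
  tr <- space$transitions
  n <- nrow(space$classes)
  m <- nrow(tr)
  nms <- colnames(space$bound)
  dmu <- stats::setNames(numeric(length(nms)), nms)
  known <- intersect(names(env), nms)
  dmu[known] <- unclass(env)[known]
  ## chemical-potential exponent per direction (side-sign convention):
  ## binding from outside: -split*dmu ; binding from inside: +split*dmu ;
  ## unbinding: none. Edge orientation from -> to is the binding direction.
  g_f <- numeric(m); g_r <- numeric(m)
  is_bind <- tr$kind == "binding"
  if (any(is_bind)) {
    sgn <- ifelse(tr$side[is_bind] == "outside", -1, +1)
    g_f[is_bind] <- sgn * cfg$split * dmu[tr$species[is_bind]]
  }
  ## flux accounting: J_x sums net unbinding flow on x's inside-side edges.
  ## Unbinding direction is to -> from, so its net flow is -(net flow f->t).
  flux_edges <- lapply(nms, function(x)
    which(is_bind & tr$species == x & tr$side == "inside"))
  names(flux_edges) <- nms
  list(n = n, m = m, ef = tr$from, et = tr$to, g_f = g_f, g_r = g_r,
       dmu = dmu, k0 = cfg$k0, flux_edges = flux_edges)
}

## directed rates for both orientations of every reversible pair
.rates <- function(eng, E, B) {
  a_f <- eng$k0 * exp(-(B - E[eng$ef]) + eng$g_f)
  a_r <- eng$k0 * exp(-(B - E[eng$et]) + eng$g_r)
  list(a_f = a_f, a_r = a_r)
}

## rate matrix K with K_ij = -alpha_ji (i != j), K_ii = sum_j alpha_ij,
## so that dP/dt = -K P.
.Kmat <- function(eng, rt) {
  n <- eng$n
  K <- matrix(0, n, n)
  K[cbind(eng$et, eng$ef)] <- K[cbind(eng$et, eng$ef)] - rt$a_f
  K[cbind(eng$ef, eng$et)] <- K[cbind(eng$ef, eng$et)] - rt$a_r
  out <- numeric(n)
  ft <- c(eng$ef, eng$et)
  af <- c(rt$a_f, rt$a_r)
  for (k in seq_along(ft)) out[ft[k]] <- out[ft[k]] + af[k]
  diag(K) <- out
  K
}

.steady_P <- function(K, tol = 1e-10) {
  n <- nrow(K)
  A <- K
  A[n, ] <- 1
  b <- c(numeric(n - 1L), 1)
  P <- tryCatch(solve(A, b), error = function(e)
    stop("numerical error solving steady state: ", conditionMessage(e)))
  res <- max(abs(K %*% P)) / max(abs(diag(K)))
  if (res > tol)
    stop(sprintf("numerical error: steady-state residual %.3g > %.1g", res, tol))
  P[P < 1e-14] <- 0
  P / sum(P)
}

#' Build the rate matrix of a model in an environment
#'
#' Directed rates follow the Arrhenius-like form
#' `alpha_ij = k0 * exp(-(E_ij_bar - E_i))`, multiplied for binding events by
#' `exp(dmu_ij)` where `dmu_ij = -split*dmu_x` for binding from outside and
#' `+split*dmu_x` for binding from inside; unbinding carries no
#' chemical-potential factor. With `split = 1/2` each transported particle
#' contributes exactly one `dmu_x` of driving per cycle.
#'
#' @param space A `state_space` with transitions.
#' @param model An [energy_model()].
#' @param env A [transport_env()].
#' @param cfg A [kinetics_config()].
#' @return A list with `alpha` (data frame of directed rates per reversible
#'   pair: `forward` is the binding / from->to direction) and `K`, the square
#'   generator-form matrix with `K_ij = -alpha_ji` and
#'   `K_ii = sum_j alpha_ij`, so the master equation reads `dP/dt = -K P`.
#' @export
build_rate_matrix <- function(space, model, env = transport_env(),
                              cfg = kinetics_config()) {
  eng <- .make_engine(space, env, cfg)
  rt <- .rates(eng, model$E, model$B)
  alpha <- cbind(space$transitions[, c("id", "from", "to", "kind", "species",
                                       "side", "label")],
                 forward = rt$a_f, reverse = rt$a_r)
  list(alpha = alpha, K = .Kmat(eng, rt))
}

#' Directed rate constant of one transition
#'
#' Convenience scalar form of the rate law used by [build_rate_matrix()].
#'
#' @param E_from Free energy of the origin state (kBT).
#' @param E_bar Absolute transition-state energy (kBT); must be >= `E_from`.
#' @param kind `"conformational"`, `"binding"` or `"unbinding"`.
#' @param side `"outside"` or `"inside"` for (un)binding events.
#' @param dmu Chemical-potential difference of the species involved (kBT).
#' @param cfg A [kinetics_config()].
#' @return Rate in 1/s.
#' @export
#' @examples
#' rate_constant(0, 5)                         # 1e-3 * exp(-5)
#' rate_constant(0, 5, "binding", "outside", dmu = -4)  # times exp(+2)
rate_constant <- function(E_from, E_bar, kind = "conformational",
                          side = c("outside", "inside"), dmu = 0,
                          cfg = kinetics_config()) {
  if (E_bar < E_from - 1e-12)
    stop("constraint violation: barrier below origin state energy")
  base <- cfg$k0 * exp(-(E_bar - E_from))
  kind <- match.arg(kind, c("conformational", "binding", "unbinding"))
  if (kind == "conformational" || kind == "unbinding") return(base)
  side <- match.arg(side)
  sgn <- if (side == "outside") -1 else +1
  base * exp(sgn * cfg$split * dmu)
}

#' Solve the steady-state master equation
#'
#' Solves `K P = 0` with the normalization `sum(P) = 1` by replacing one
#' balance row of the dense system, then computes per-edge net flows
#' `j_ij - j_ji` (with `j_ij = P_i alpha_ij`) and per-species fluxes. The
#' flux `J_x` is the net unbinding flow summed over the species' inside-side
#' transitions; positive means net transport into the cell.
#'
#' @inheritParams build_rate_matrix
#' @param tol Residual tolerance for the linear solve (relative to the
#'   largest total exit rate).
#' @return An object of class `steady_state`: `P` (named probabilities),
#'   `flows` (data frame of transitions with net flow in the from->to
#'   direction, 1/s), `flux` (named per-species fluxes, 1/s), `env`,
#'   `residual`.
#' @export
solve_steady_state <- function(space, model, env = transport_env(),
                               cfg = kinetics_config(), tol = 1e-10) {
  stopifnot(inherits(space, "state_space"), inherits(model, "energy_model"))
  tr <- space$transitions
  if (nrow(tr)) {
    g <- igraph::graph_from_edgelist(cbind(tr$from, tr$to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(space$classes) -
                                       igraph::vcount(g)))
    if (igraph::components(g)$no > 1L)
      stop("ambiguity error: transition graph is disconnected; ",
           "the stationary distribution is not unique")
  } else if (nrow(space$classes) > 1L) {
    stop("ambiguity error: transition graph is disconnected")
  }
  eng <- .make_engine(space, env, cfg)
  rt <- .rates(eng, model$E, model$B)
  if (eng$n == 1L) {
    P <- stats::setNames(1, space$classes$label)
    flows <- cbind(tr[, c("id", "label", "kind", "species", "side")],
                   flow = numeric(0))
    return(structure(list(P = P, flows = flows,
                          flux = stats::setNames(numeric(ncol(space$bound)),
                                                 colnames(space$bound)),
                          env = env, residual = 0),
                     class = "steady_state"))
  }
  K <- .Kmat(eng, rt)
  P <- .steady_P(K, tol)
  names(P) <- space$classes$label
  netflow <- P[eng$ef] * rt$a_f - P[eng$et] * rt$a_r
  flux <- vapply(eng$flux_edges, function(ix) -sum(netflow[ix]), numeric(1))
  flows <- cbind(tr[, c("id", "from", "to", "label", "kind", "species", "side")],
                 flow = unname(netflow))
  structure(list(P = P, flows = flows, flux = flux, env = env,
                 residual = max(abs(K %*% P)) / max(abs(diag(K)))),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, digits = 4, ...) {
  cat("steady_state:\n probabilities:\n")
  print(round(x$P, digits))
  cat(" fluxes (1/s, positive = into cell):\n")
  print(signif(x$flux, digits))
  invisible(x)
}

#' Verify thermodynamic consistency of all cycles
#'
#' For every simple cycle, the log ratio of the forward to reverse rate
#' products (the cycle affinity) must equal minus the net transported free
#' energy, `-sum_x n_x dmu_x`, where `n_x` is the species' net transport per
#' forward traversal. A violation indicates an inconsistent rate
#' parameterization.
#'
#' @inheritParams build_rate_matrix
#' @param cycles Optional precomputed cycle list from [enumerate_cycles()].
#' @param tol Allowed absolute deviation (kBT).
#' @param error If `TRUE` (default), a violation raises an error naming the
#'   cycle.
#' @return Invisibly, a data frame with one row per cycle: `length`,
#'   `affinity`, `expected`, and the per-species net transport.
#' @export
cycle_affinity_check <- function(space, model, env = transport_env(),
                                 cfg = kinetics_config(), cycles = NULL,
                                 tol = 1e-10, error = TRUE) {
  if (is.null(cycles)) cycles <- enumerate_cycles(space)
  eng <- .make_engine(space, env, cfg)
  rt <- .rates(eng, model$E, model$B)
  lf <- log(rt$a_f); lr <- log(rt$a_r)
  res <- lapply(cycles, function(cy) {
    aff <- sum(ifelse(cy$direction > 0, lf[cy$transitions] - lr[cy$transitions],
                      lr[cy$transitions] - lf[cy$transitions]))
    expd <- -sum(cy$net_transport * eng$dmu[names(cy$net_transport)])
    c(length = cy$length, affinity = aff, expected = expd, cy$net_transport)
  })
  df <- as.data.frame(do.call(rbind, res))
  bad <- which(abs(df$affinity - df$expected) > tol)
  if (length(bad) && error) {
    cy <- cycles[[bad[1]]]
    stop("thermodynamic-consistency error on cycle ",
         paste(space$classes$label[cy$classes], collapse = " -> "),
         sprintf(": affinity %.6g, expected %.6g",
                 df$affinity[bad[1]], df$expected[bad[1]]))
  }
  invisible(df)
}
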