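#' Declare a transported species
#'
#' A species (driving ion, substrate, or decoy substrate) occupies one of
#' three base substates at any time: free outside the cell, bound to the
#' machine, or free inside the cell. Substate codes are built from a single
#' code letter, e.g. `"N"` gives `No`/`Nb`/`Ni`.
#'
#' @param name Species name (unique within a machine), e.g. `"ion"`.
#' @param code Single-letter code used in state strings; defaults to the
#'   capitalized first letter of `name`.
#' @param exclusive_group Optional group label. Species sharing a group are
#'   mutually exclusive binders: no generated state has more than one of
#'   them bound (used for substrate/decoy pairs).
#' @param decoy_of Optional name of the species this one is a weaker-binding
#'   copy of. Decoy-bound state energies are constrained to the counterpart
#'   substrate-bound energies plus a fixed offset (the `ddG` parameter of
#'   [energy_model()]), with equal absolute barrier energies.
#' @return An object of class `species_spec`.
#' @seealso [machine_spec()]
#' @export
#' @examples
#' species_spec("ion", "N")
#' species_spec("decoy", "W", exclusive_group = "sub", decoy_of = "substrate")
species_spec <- function(name, code = toupper(substr(name, 1, 1)),
                         exclusive_group = NULL, decoy_of = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  structure(list(name = name, code = code,
                 exclusive_group = exclusive_group, decoy_of = decoy_of),
            class = "species_spec")
}

#' Describe an alternating-access machine
#'
#' The machine is specified by an ordered set of conformations, each exposing
#' its binding sites to one side of the membrane (alternating access), plus
#' the species it can bind and optional exclusion patterns.
#'
#' @param conformations Named character vector mapping conformation label to
#'   the accessible side, e.g. `c(OF = "outside", IF = "inside")`. Binding
#'   and unbinding in a conformation exchange particles only with its side.
#' @param species List of [species_spec()] objects (unique names and codes).
#' @param exclusions Character vector of regular expressions; raw states whose
#'   label matches any pattern are dropped (e.g. forbidden co-binding, or
#'   whole conformations).
#' @return An object of class `machine_spec`.
#' @export
#' @examples
#' machine_spec(species = list(species_spec("ion", "N"),
#'                             species_spec("substrate", "S")))
machine_spec <- function(conformations = c(OF = "outside", IF = "inside"),
                         species = list(), exclusions = character()) {
  if (is.null(names(conformations)) || any(!nzchar(names(conformations))))
    stop("'conformations' must be a named vector (label -> side)")
  if (length(conformations) < 1L) stop("need at least one conformation")
  if (!all(conformations %in% c("outside", "inside")))
    stop("conformation sides must be 'outside' or 'inside'")
  if (!all(vapply(species, inherits, logical(1), "species_spec")))
    stop("'species' must be a list of species_spec objects")
  nm <- vapply(species, `[[`, character(1), "name")
  cd <- vapply(species, `[[`, character(1), "code")
  if (anyDuplicated(nm)) stop("species names must be unique")
  if (anyDuplicated(cd)) stop("species codes must be unique")
  for (sp in species) {
    if (!is.null(sp$decoy_of) && !(sp$decoy_of %in% nm))
      stop("decoy_of refers to unknown species: ", sp$decoy_of)
  }
  structure(list(conformations = conformations, species = species,
                 exclusions = as.character(exclusions)),
            class = "machine_spec")
}

## substate code for species sp at location loc in {"o","b","i"}
.substate_code <- function(code, loc) paste0(code, loc)

#' Enumerate the state classes of a machine
#'
#' Builds all raw states as hyphen-joined strings
#' `<CONF>-<code1><o|b|i>-<code2><o|b|i>-...` in declared species order
#' (e.g. `"OF-Nb-Si"`), drops states matching the exclusion patterns and any
#' state co-binding members of one exclusive group, and collapses the
#' survivors into physically equivalent classes. Two raw states are
#' equivalent when they share the conformation and the bound/unbound pattern:
#' with fixed bath concentrations on both sides, the location of an unbound
#' particle does not affect the kinetics, so such states carry identical free
#' energies and are updated together ("tied") during sampling.
#'
#' @param spec A [machine_spec()].
#' @return An object of class `state_space` with elements
#'   `classes` (data frame: `id`, `conf`, `label`, `n_raw`),
#'   `bound` (logical matrix, classes x species),
#'   `raw` (data frame mapping every raw state label to its class id), and
#'   `spec`. Transitions are added by [build_transitions()]; use
#'   [state_space()] to do both.
#' @export
enumerate_states <- function(spec) {
  stopifnot(inherits(spec, "machine_spec"))
  confs <- names(spec$conformations)
  nsp <- length(spec$species)
  codes <- vapply(spec$species, `[[`, character(1), "code")
  nms <- if (nsp) vapply(spec$species, `[[`, character(1), "name") else character()

  ## raw enumeration: conformation x {o,b,i}^nsp
  locs <- c("o", "b", "i")
  grid <- expand.grid(c(list(conf = confs),
                        stats::setNames(rep(list(locs), nsp), nms)),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  labels <- grid$conf
  if (nsp) {
    for (k in seq_len(nsp))
      labels <- paste(labels, .substate_code(codes[k], grid[[k + 1L]]), sep = "-")
  }

  keep <- rep(TRUE, nrow(grid))
  ## exclusive groups: never co-bound
  groups <- vapply(spec$species, function(s)
    if (is.null(s$exclusive_group)) NA_character_ else s$exclusive_group,
    character(1))
  for (g in unique(groups[!is.na(groups)])) {
    idx <- which(!is.na(groups) & groups == g)
    if (length(idx) >= 2L) {
      nb <- rowSums(vapply(idx, function(k) grid[[k + 1L]] == "b",
                           logical(nrow(grid))))
      keep <- keep & nb <= 1L
    }
  }
  ## user exclusions (regex on the raw label)
  for (pat in spec$exclusions) keep <- keep & !grepl(pat, labels)
  if (!any(keep)) stop("configuration error: exclusions removed all states")

  grid <- grid[keep, , drop = FALSE]
  labels <- labels[keep]

  ## collapse: (conformation, bound pattern)
  bound <- if (nsp) {
    vapply(seq_len(nsp), function(k) grid[[k + 1L]] == "b", logical(nrow(grid)))
  } else matrix(logical(0), nrow(grid), 0L)
  if (is.null(dim(bound))) bound <- matrix(bound, ncol = nsp)
  colnames(bound) <- nms

  class_label <- grid$conf
  if (nsp) {
    for (i in seq_len(nrow(grid))) {
      b <- which(bound[i, ])
      if (length(b))
        class_label[i] <- paste(c(grid$conf[i],
                                  .substate_code(codes[b], "b")), collapse = "-")
    }
  }
  ## deterministic class order: conformation order, then bound pattern
  pat <- if (nsp) apply(bound, 1L, function(b) paste(as.integer(b), collapse = ""))
         else rep("", nrow(grid))
  key <- sprintf("%03d-%s", match(grid$conf, confs), pat)
  ukey <- sort(unique(key))
  cid <- match(key, ukey)

  first <- which(!duplicated(cid))
  first <- first[order(cid[first])]
  cls <- data.frame(id = cid[first], conf = grid$conf[first],
                    label = class_label[first], stringsAsFactors = FALSE)
  rownames(cls) <- NULL
  cbound <- bound[first, , drop = FALSE]
  dimnames(cbound) <- list(cls$label, nms)
  cls$n_raw <- as.integer(tabulate(cid, nbins = nrow(cls)))

  structure(list(classes = cls, bound = cbound,
                 raw = data.frame(label = labels, class_id = cid,
                                  stringsAsFactors = FALSE),
                 spec = spec),
            class = "state_space")
}

#' Build the allowed elementary transitions between state classes
#'
#' Only elementary transitions are allowed: a single conformational change
#' (same bound pattern, different conformation) or a single binding/unbinding
#' event (same conformation, one species' bound flag flipped). The side of a
#' binding event is set by the conformation's accessible side (alternating
#' access). Every transition is reversible; each row describes one
#' reversible pair, oriented so that `from -> to` is the binding direction
#' for binding edges and lower-id to higher-id for conformational edges.
#'
#' @param space A `state_space` from [enumerate_states()].
#' @return The `state_space` with a `transitions` data frame added
#'   (`id`, `from`, `to`, `kind`, `species`, `side`, `label`), ordered
#'   lexicographically by `(from, to)` (the canonical edge ordering used for
#'   flow vectors).
#' @export
build_transitions <- function(space) {
  stopifnot(inherits(space, "state_space"))
  cls <- space$classes
  bound <- space$bound
  n <- nrow(cls)
  nsp <- ncol(bound)
  sides <- space$spec$conformations
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (n < 2L) break
    same_conf <- cls$conf[i] == cls$conf[j]
    diffb <- if (nsp) which(bound[i, ] != bound[j, ]) else integer()
    if (!same_conf && length(diffb) == 0L) {
      rows[[length(rows) + 1L]] <- list(from = i, to = j, kind = "conformational",
                                        species = NA_character_, side = "none")
    } else if (same_conf && length(diffb) == 1L) {
      k <- diffb
      ## orient from = unbound endpoint, to = bound endpoint
      if (bound[j, k]) { u <- i; b <- j } else { u <- j; b <- i }
      rows[[length(rows) + 1L]] <- list(from = u, to = b, kind = "binding",
                                        species = colnames(bound)[k],
                                        side = unname(sides[cls$conf[i]]))
    }
  }
  tr <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
  } else {
    data.frame(from = integer(), to = integer(), kind = character(),
               species = character(), side = character(),
               stringsAsFactors = FALSE)
  }
  tr <- tr[order(tr$from, tr$to), , drop = FALSE]
  tr <- cbind(id = seq_len(nrow(tr)), tr)
  tr$label <- paste(cls$label[tr$from], cls$label[tr$to], sep = " <-> ")
  rownames(tr) <- NULL
  space$transitions <- tr
  space <- .add_decoy_maps(space)
  space
}

## Precompute decoy tie maps: for each class/edge involving a decoy-bound
## species, the counterpart obtained by replacing the decoy with its parent
## substrate. These drive the ddG offset and equal-barrier constraints.
.add_decoy_maps <- function(space) {
  cls <- space$classes
  bound <- space$bound
  tr <- space$transitions
  nms <- colnames(bound)
  decoys <- Filter(function(s) !is.null(s$decoy_of), space$spec$species)
  class_ctr <- rep(NA_integer_, nrow(cls))
  if (length(decoys)) {
    for (d in decoys) {
      di <- match(d$name, nms); pi <- match(d$decoy_of, nms)
      for (i in which(bound[, di])) {
        target <- bound[i, ]; target[di] <- FALSE; target[pi] <- TRUE
        j <- which(cls$conf == cls$conf[i] &
                     apply(bound, 1L, function(b) all(b == target)))
        if (length(j) == 1L) class_ctr[i] <- j
      }
    }
  }
  edge_ctr <- rep(NA_integer_, nrow(tr))
  edge_off <- rep(0L, nrow(tr))
  if (any(!is.na(class_ctr)) && nrow(tr)) {
    map1 <- ifelse(is.na(class_ctr), seq_len(nrow(cls)), class_ctr)
    for (e in seq_len(nrow(tr))) {
      f2 <- map1[tr$from[e]]; t2 <- map1[tr$to[e]]
      if (f2 != tr$from[e] || t2 != tr$to[e]) {
        j <- which((tr$from == f2 & tr$to == t2) | (tr$from == t2 & tr$to == f2))
        if (length(j) == 1L) {
          edge_ctr[e] <- j
          ## both endpoints decoy-bound: the transition state carries the
          ## destabilized decoy, so its tied barrier is offset by +ddG
          ## (equal barrier HEIGHT). Edges where the decoy itself (un)binds
          ## keep the counterpart's absolute barrier (equal on-rates,
          ## off-rates faster by e^ddG: Hopfield-type discrimination).
          if (f2 != tr$from[e] && t2 != tr$to[e]) edge_off[e] <- 1L
        }
      }
    }
  }
  space$class_counterpart <- class_ctr
  space$edge_counterpart <- edge_ctr
  space$edge_counterpart_offset <- edge_off
  space
}

#' Construct a state space (classes plus transitions)
#'
#' Convenience wrapper: [enumerate_states()] followed by
#' [build_transitions()].
#'
#' @inheritParams enumerate_states
#' @return A `state_space` with classes, raw-state map and transitions.
#' @export
#' @examples
#' sp <- machine_spec(species = list(species_spec("ion", "N"),
#'                                   species_spec("substrate", "S")))
#' ss <- state_space(sp)
#' nrow(ss$classes)      # 8
#' nrow(ss$transitions)  # 12 reversible pairs
state_space <- function(spec) build_transitions(enumerate_states(spec))

#' @export
print.state_space <- function(x, ...) {
  cat("state_space:", nrow(x$classes), "classes,",
      nrow(x$raw), "raw states,",
      if (is.null(x$transitions)) 0L else nrow(x$transitions),
      "reversible transitions\n")
  cat("classes:", paste(x$classes$label, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.state_space <- function(object, ...) {
  print(object)
  if (!is.null(object$transitions)) {
    cat("\ntransitions:\n")
    print(object$transitions[, c("id", "label", "kind", "species", "side")],
          row.names = FALSE)
  }
  invisible(object)
}

#' Enumerate simple cycles with net-transport accounting
#'
#' Brute-force depth-first enumeration of simple directed cycles (length
#' >= 3; a reversible pair traversed back and forth is not a cycle) in the
#' transition graph. For each cycle the net transport of every species is the
#' signed count of particles moved outside-to-inside per forward traversal,
#' computed as (bindings from outside) minus (unbindings to outside). A cycle
#' and its reversal are distinct directed cycles with opposite transport.
#'
#' @param space A `state_space` with transitions.
#' @param target Optional named numeric vector of per-species net transport;
#'   only cycles matching it exactly (unnamed species implicitly 0) are
#'   returned.
#' @param minimal_only If `TRUE`, keep only cycles of minimum length among
#'   the matches.
#' @param max_cycles Safety cap on the number of enumerated cycles.
#' @return A list of cycles, each a list with `classes` (closed walk of class
#'   ids, first == last), `transitions` (edge ids), `direction` (+1 if the
#'   edge is traversed from->to), `length`, and `net_transport` (named
#'   vector). Empty list if nothing matches.
#' @export
#' @examples
#' ss <- state_space(machine_spec(species = list(
#'   species_spec("ion", "N"), species_spec("substrate", "S"))))
#' cyc <- enumerate_cycles(ss, target = c(ion = 1, substrate = 1),
#'                         minimal_only = TRUE)
#' length(cyc)  # 4 ideal symport pathways
enumerate_cycles <- function(space, target = NULL, minimal_only = FALSE,
                             max_cycles = 1e6) {
  stopifnot(inherits(space, "state_space"), !is.null(space$transitions))
  tr <- space$transitions
  n <- nrow(space$classes)
  if (!nrow(tr)) return(list())
  ## adjacency: list of (neighbor, edge id, direction)
  adj <- vector("list", n)
  for (e in seq_len(nrow(tr))) {
    f <- tr$from[e]; t <- tr$to[e]
    adj[[f]] <- rbind(adj[[f]], c(t, e, 1L))
    adj[[t]] <- rbind(adj[[t]], c(f, e, -1L))
  }
  out <- list()
  count <- 0L
  path_nodes <- integer(n + 1L); path_edges <- integer(n)
  path_dirs <- integer(n)
  for (anchor in seq_len(n)) {
    in_path <- rep(FALSE, n)
    dfs <- function(v, depth) {
      nb <- adj[[v]]
      if (is.null(nb)) return(invisible())
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1L]
        if (w == anchor && depth >= 3L) {
          count <<- count + 1L
          if (count > max_cycles) stop("cycle cap exceeded (max_cycles)")
          eids <- c(path_edges[seq_len(depth - 1L)], nb[r, 2L])
          dirs <- c(path_dirs[seq_len(depth - 1L)], nb[r, 3L])
          out[[length(out) + 1L]] <<- list(
            classes = c(path_nodes[seq_len(depth)], anchor),
            transitions = eids, direction = dirs, length = depth)
        } else if (w > anchor && !in_path[w]) {
          in_path[w] <<- TRUE
          path_nodes[depth + 1L] <<- w
          path_edges[depth] <<- nb[r, 2L]
          path_dirs[depth] <<- nb[r, 3L]
          dfs(w, depth + 1L)
          in_path[w] <<- FALSE
        }
      }
    }
    in_path[anchor] <- TRUE
    path_nodes[1L] <- anchor
    dfs(anchor, 1L)
    in_path[anchor] <- FALSE
  }
  ## net transport per cycle
  nms <- colnames(space$bound)
  out <- lapply(out, function(cy) {
    nt <- stats::setNames(numeric(length(nms)), nms)
    for (k in seq_along(cy$transitions)) {
      e <- cy$transitions[k]
      if (tr$kind[e] == "binding" && tr$side[e] == "outside") {
        ## direction +1 is the binding direction
        nt[tr$species[e]] <- nt[tr$species[e]] + cy$direction[k]
      }
    }
    cy$net_transport <- nt
    cy
  })
  if (!is.null(target)) {
    want <- stats::setNames(numeric(length(nms)), nms)
    if (is.null(names(target)) || !all(names(target) %in% nms))
      stop("'target' must be named by species")
    want[names(target)] <- target
    out <- Filter(function(cy) all(cy$net_transport == want), out)
  }
  if (minimal_only && length(out)) {
    lmin <- min(vapply(out, `[[`, integer(1), "length"))
    out <- Filter(function(cy) cy$length == lmin, out)
  }
  out
}

#' Export a state space as CSV tables
#'
#' Writes `<prefix>_classes.csv` (class id, conformation, label, raw member
#' count, member labels) and `<prefix>_transitions.csv`.
#'
#' @param space A `state_space` with transitions.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_state_space <- function(space, prefix) {
  cls <- space$classes
  members <- vapply(cls$id, function(i)
    paste(space$raw$label[space$raw$class_id == i], collapse = ";"),
    character(1))
  f1 <- paste0(prefix, "_classes.csv")
  f2 <- paste0(prefix, "_transitions.csv")
  utils::write.csv(cbind(cls, members = members), f1, row.names = FALSE)
  utils::write.csv(space$transitions, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
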