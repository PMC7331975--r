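test_that("rate constants follow the Arrhenius form with driving factors", {
  expect_equal(rate_constant(0, 5), 1e-3 * exp(-5), tolerance = 1e-12)
  # zero driving: binding identical to the conformational formula
  expect_equal(rate_constant(0, 5, "binding", "outside", dmu = 0),
               rate_constant(0, 5))
  # binding from outside against dmu = -4 at split 1/2: factor e^{+2}
  expect_equal(rate_constant(0, 5, "binding", "outside", dmu = -4),
               rate_constant(0, 5) * exp(2), tolerance = 1e-12)
  # binding from inside carries the opposite sign
  expect_equal(rate_constant(0, 5, "binding", "inside", dmu = -4),
               rate_constant(0, 5) * exp(-2), tolerance = 1e-12)
  # unbinding carries no chemical-potential factor
  expect_equal(rate_constant(1, 5, "unbinding", dmu = -4),
               1e-3 * exp(-4))
  expect_error(rate_constant(6, 5), "constraint violation")
})

test_that("the generator matrix conserves probability", {
  ss8 <- make_space8()
  set.seed(11)
  m <- random_energy_model(ss8)
  rm_ <- build_rate_matrix(ss8, m, transport_env(ion = -4, substrate = 2))
  K <- rm_$K
  expect_equal(dim(K), c(8L, 8L))
  expect_equal(sum(K[row(K) != col(K)] != 0), 24L)  # 12 reversible pairs
  expect_lt(max(abs(colSums(K))), 1e-14 * max(abs(K)))
  # raising one barrier shrinks both directed rates by e^{-100}
  m2 <- m; m2$B[3] <- m2$B[3] + 100
  rm2 <- build_rate_matrix(ss8, m2, transport_env(ion = -4, substrate = 2))
  expect_equal(rm2$alpha$forward[3] / rm_$alpha$forward[3], exp(-100))
  expect_equal(rm2$alpha$reverse[3] / rm_$alpha$reverse[3], exp(-100))
})

test_that("two-state steady state matches the closed form", {
  sp <- machine_spec(conformations = c(OF = "outside", IF = "inside"))
  ss <- state_space(sp)
  m <- energy_model(ss, c(0.3, -0.7), 4.1)
  sol <- solve_steady_state(ss, m)
  a12 <- rate_constant(0.3, 4.1)
  a21 <- rate_constant(-0.7, 4.1)
  expect_equal(unname(sol$P[1]), a21 / (a12 + a21), tolerance = 1e-12)
})

test_that("equilibrium gives Boltzmann occupancies and zero flows", {
  set.seed(2)
  for (make in list(make_space8, make_space12)) {
    ss <- make()
    ddG <- if (is.null(ss$class_counterpart) ||
               all(is.na(ss$class_counterpart))) 0 else 1
    for (r in 1:20) {
      m <- random_energy_model(ss, ddG = ddG)
      env <- do.call(transport_env, as.list(
        stats::setNames(rep(0, ncol(ss$bound)), colnames(ss$bound))))
      sol <- solve_steady_state(ss, m, env)
      pb <- exp(-m$E) / sum(exp(-m$E))
      expect_equal(unname(sol$P), unname(pb), tolerance = 1e-10)
      rm_ <- build_rate_matrix(ss, m, env)
      expect_lt(max(abs(sol$flows$flow)),
                1e-12 * sum(rm_$alpha$forward + rm_$alpha$reverse))
    }
  }
})

test_that("steady state matches long-time ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(5)
  cfg <- kinetics_config(k0 = 1)  # time rescaling only (scale property below)
  for (r in 1:10) {
    ss <- if (r %% 2) make_space8() else make_space12()
    ddG <- if (all(is.na(ss$class_counterpart))) 0 else 1
    m <- random_energy_model(ss, state_range = c(-1.5, 1.5),
                             margin = c(1, 4), ddG = ddG)
    env <- transport_env(ion = stats::runif(1, -5, 0),
                         substrate = stats::runif(1, -2, 2),
                         decoy = stats::runif(1, -2, 2))
    sol <- solve_steady_state(ss, m, env, cfg)
    K <- build_rate_matrix(ss, m, env, cfg)$K
    expect_lt(max(abs(oracle_ode_steady(K) - sol$P)), 1e-8)
  }
})

test_that("steady flows balance at nodes and across the membrane", {
  set.seed(8)
  ss <- make_space12()
  env <- transport_env(ion = -4, substrate = 2, decoy = 2)
  for (r in 1:10) {
    m <- random_energy_model(ss, ddG = 1)
    sol <- solve_steady_state(ss, m, env)
    expect_lt(node_balance(sol, ss), 1e-10)
    # per-species: net uptake on outside edges equals net release inside
    tr <- ss$transitions
    for (x in colnames(ss$bound)) {
      up <- sum(sol$flows$flow[tr$kind == "binding" & tr$species == x &
                                 tr$side == "outside"])
      expect_lt(abs(up - sol$flux[[x]]), 1e-10 * max(abs(sol$flux)))
    }
  }
})

test_that("cycle affinities equal minus the transported free energy", {
  set.seed(13)
  ss <- make_space8()
  m <- random_energy_model(ss)
  env <- transport_env(ion = -4, substrate = 2)
  df <- cycle_affinity_check(ss, m, env)
  expect_lt(max(abs(df$affinity - df$expected)), 1e-10)
  # ideal symport cycle: -(+2*1 + (-4)*1) = +2
  sym <- enumerate_cycles(ss, target = c(ion = 1, substrate = 1),
                          minimal_only = TRUE)
  df2 <- cycle_affinity_check(ss, m, env, cycles = sym)
  expect_equal(df2$affinity, rep(2, 4), tolerance = 1e-10)
  # pure ion leak: -(-4) = +4
  leak <- enumerate_cycles(ss, target = c(ion = 1, substrate = 0))
  df3 <- cycle_affinity_check(ss, m, env, cycles = leak)
  expect_equal(df3$affinity, rep(4, length(leak)), tolerance = 1e-10)
  # all zero at equilibrium
  df0 <- cycle_affinity_check(ss, m, transport_env(ion = 0, substrate = 0))
  expect_lt(max(abs(df0$affinity)), 1e-10)
  # a broken (untied) rate set is flagged as inconsistent
  expect_error(
    cycle_affinity_check(ss, m, env, cycles = local({
      cy <- sym[[1]]; cy$net_transport["ion"] <- 5; list(cy)
    })),
    "thermodynamic-consistency")
})

test_that("the prefactor k0 rescales flows without changing ratios", {
  set.seed(21)
  ss <- make_space8()
  m <- random_energy_model(ss)
  env <- transport_env(ion = -4, substrate = 2)
  s1 <- solve_steady_state(ss, m, env, kinetics_config(k0 = 1e-3))
  s2 <- solve_steady_state(ss, m, env, kinetics_config(k0 = 0.37))
  expect_equal(unname(s2$P), unname(s1$P), tolerance = 1e-12)
  expect_equal(s2$flows$flow, s1$flows$flow * 370, tolerance = 1e-10)
  expect_equal(unname(s2$flux / s1$flux), c(370, 370), tolerance = 1e-10)
})

test_that("degenerate inputs are rejected with informative errors", {
  # disconnected graph: exclusions leave two classes with no linking edge
  sp <- machine_spec(species = list(species_spec("ion", "N")),
                     exclusions = c("^OF-Nb$", "^IF-N[oi]"))
  ss <- state_space(sp)
  expect_equal(nrow(ss$classes), 2L)
  expect_equal(nrow(ss$transitions), 0L)
  m <- energy_model(ss, c(0, 0), numeric(0))
  expect_error(solve_steady_state(ss, m, transport_env(ion = 0)),
               "disconnected")
  # barrier below a state energy
  ss8 <- make_space8()
  expect_error(energy_model(ss8, rep(1, 8), rep(0.5, 12)),
               "constraint violation")
})

test_that("decoy ties hold: offset energies, Hopfield barrier rule", {
  ss <- make_space12()
  set.seed(31)
  m <- random_energy_model(ss, ddG = 1.3)
  cc <- ss$class_counterpart
  dec <- which(!is.na(cc))
  expect_equal(unname(m$E[dec]), unname(m$E[cc[dec]] + 1.3))
  ec <- ss$edge_counterpart
  je <- which(!is.na(ec))
  expect_equal(unname(m$B[je]),
               unname(m$B[ec[je]] + 1.3 * ss$edge_counterpart_offset[je]))
  # consequence: decoy binding rates equal the substrate's, decoy unbinding
  # and within-branch rates faster/equal as documented
  env <- transport_env(ion = -4, substrate = 2, decoy = 2)
  al <- build_rate_matrix(ss, m, env)$alpha
  for (e in je) {
    e0 <- ec[e]
    if (al$kind[e] == "binding" && al$species[e] == "decoy") {
      expect_equal(al$forward[e], al$forward[e0], tolerance = 1e-12)
      expect_equal(al$reverse[e], al$reverse[e0] * exp(1.3),
                   tolerance = 1e-12)
    } else {
      # decoy-carrying transition: both rates equal the counterpart's
      expect_equal(al$forward[e], al$forward[e0], tolerance = 1e-12)
      expect_equal(al$reverse[e], al$reverse[e0], tolerance = 1e-12)
    }
  }
})
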