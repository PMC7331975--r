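test_that("fitness scores follow the three functional goals", {
  expect_equal(evaluate_fitness(c(substrate = 0), fitness_spec("symport")), 0)
  expect_equal(evaluate_fitness(c(substrate = 2e-6), fitness_spec("symport")),
               -2e-6)
  expect_equal(evaluate_fitness(c(substrate = -3e-6),
                                fitness_spec("antiport")), -3e-6)
  fc <- fitness_spec("competitive", decoy = "decoy")
  expect_equal(
    evaluate_fitness(c(substrate = 1e-3, decoy = 1e-6), fc),
    -1e-3 * (1e-3 + 1e-15) / (1e-6 + 1e-15))
  # vanishing decoy flux: score approaches -J^2 / epsilon
  expect_equal(evaluate_fitness(c(substrate = 1e-3, decoy = 0), fc),
               -1e-6 / 1e-15, tolerance = 1e-9)
  expect_error(evaluate_fitness(c(ion = 1), fitness_spec("symport")),
               "configuration error")
  expect_error(fitness_spec("competitive"), "requires a decoy")
})

test_that("trial moves perturb one free parameter and preserve ties", {
  ss <- make_space12()
  set.seed(4)
  m <- random_energy_model(ss, ddG = 1)
  # zero step size: trial identical to current
  t0 <- propose_move(m, ss, step_size = 0)
  expect_equal(t0$E, m$E)
  expect_equal(t0$B, m$B)
  cc <- ss$class_counterpart
  ec <- ss$edge_counterpart
  seen_E <- rep(FALSE, nrow(ss$classes))
  seen_B <- rep(FALSE, nrow(ss$transitions))
  for (i in 1:3000) {
    tr <- propose_move(m, ss, step_size = 0.5)
    if (!attr(tr, "valid")) next
    dE <- which(tr$E != m$E); dB <- which(tr$B != m$B)
    seen_E[dE] <- TRUE; seen_B[dB] <- TRUE
    free_dE <- dE[is.na(cc[dE])]
    free_dB <- dB[is.na(ec[dB])]
    # exactly one free parameter moved
    expect_equal(length(free_dE) + length(free_dB), 1L)
    # tied decoy entries moved by exactly the same amount
    expect_equal(unname(tr$E[!is.na(cc)]),
                 unname(tr$E[cc[!is.na(cc)]] + m$ddG))
    expect_equal(unname(tr$B[!is.na(ec)]),
                 unname(tr$B[ec[!is.na(ec)]] +
                          m$ddG * ss$edge_counterpart_offset[!is.na(ec)]))
    # constraints hold on every returned trial
    trn <- ss$transitions
    expect_true(all(tr$B >= pmax(tr$E[trn$from], tr$E[trn$to]) - 1e-12))
  }
  # uniform selection reaches every free parameter (coupon collector)
  expect_true(all(seen_E[is.na(cc)]))
  expect_true(all(seen_B[is.na(ec)]))
})

test_that("the Metropolis rule accepts at the theoretical rate", {
  expect_true(metropolis_accept(-1, 20))
  expect_true(metropolis_accept(0, 20))
  expect_false(metropolis_accept(Inf, 1))
  set.seed(99)
  n <- 1e5
  acc <- sum(vapply(seq_len(n), function(i) metropolis_accept(1, 1),
                    logical(1)))
  p <- exp(-1)
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("sampling is reproducible and records the thinned chain", {
  ss <- make_space8()
  env <- transport_env(ion = -4, substrate = 2)
  cfg <- mc_config(n_steps = 2000, thin = 250, seed = 42)
  t1 <- explore_models(ss, env, fitness_spec("symport"), cfg)
  t2 <- explore_models(ss, env, fitness_spec("symport"), cfg)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$acceptance, t2$acceptance)
  expect_length(t1$records, 8L)
  # single-step single-record edge case
  t3 <- explore_models(ss, env, fitness_spec("symport"),
                       mc_config(n_steps = 1, thin = 1, seed = 1))
  expect_length(t3$records, 1L)
})

test_that("a flat fitness accepts every valid move", {
  ss <- make_space8()
  cfg <- mc_config(n_steps = 2000, thin = 500, seed = 7)
  traj <- explore_models(ss, transport_env(ion = -4, substrate = 2),
                         fitness_spec("custom", fn = function(flux) 1), cfg)
  a <- traj$acceptance
  expect_equal(unname(a["rejected"]), 0L)
  expect_equal(unname(a["accepted"] + a["invalid"]), 2000L)
})

test_that("recorded models always satisfy the energy-model invariants", {
  ss <- make_space12()
  env <- transport_env(ion = -4, substrate = 2, decoy = 2)
  traj <- explore_models(ss, env,
                         fitness_spec("competitive", decoy = "decoy"),
                         mc_config(n_steps = 5000, thin = 250, seed = 3),
                         ddG = 1)
  cc <- ss$class_counterpart; ec <- ss$edge_counterpart
  trn <- ss$transitions
  for (r in traj$records) {
    expect_true(all(r$B >= pmax(r$E[trn$from], r$E[trn$to]) - 1e-12))
    expect_equal(unname(r$E[!is.na(cc)]), unname(r$E[cc[!is.na(cc)]] + 1))
    expect_equal(unname(r$B[!is.na(ec)]),
                 unname(r$B[ec[!is.na(ec)]] +
                          ss$edge_counterpart_offset[!is.na(ec)]))
    # recorded fitness is recomputable from the snapshot
    m <- energy_model(ss, r$E, r$B, ddG = 1)
    sol <- solve_steady_state(ss, m, env, traj$kinetics)
    emc <- evaluate_fitness(sol, traj$fitness)
    expect_lt(abs(emc - r$E_MC), 1e-10 * max(abs(r$E_MC), 1e-300))
  }
})

test_that("cold chains descend; tempering allows escapes", {
  ss <- make_space8()
  env <- transport_env(ion = -4, substrate = 2)
  # single very cold phase: recorded fitness is non-increasing (greedy)
  cold <- explore_models(ss, env, fitness_spec("symport"),
                         mc_config(n_steps = 10000, thin = 200, seed = 12,
                                   beta_schedule = list(c(1e6, 1e9))))
  em <- vapply(cold$records, `[[`, numeric(1), "E_MC")
  # non-increasing up to acceptance of sub-resolution (beta*dE << 1) noise
  expect_true(all(diff(em) <= 1e-6 * max(abs(em))))
  # alternating schedule: fitness also rises somewhere (escapes happen)
  temp <- explore_models(ss, env, fitness_spec("symport"),
                         mc_config(n_steps = 20000, thin = 200, seed = 12,
                                   beta_schedule = list(c(4e3, 1e5),
                                                        c(1e3, 2))))
  emt <- vapply(temp$records, `[[`, numeric(1), "E_MC")
  expect_true(any(diff(emt) > 0))
  # and both runs improve on the initial model
  expect_lt(min(em), cold$init_E_MC)
  expect_lt(min(emt), temp$init_E_MC)
})

test_that("sampling improves fitness under all three functional goals", {
  ss8 <- make_space8()
  ss12 <- make_space12()
  runs <- list(
    list(ss8, transport_env(ion = -4, substrate = 2),
         fitness_spec("symport"), 0),
    list(ss8, transport_env(ion = -4, substrate = -2),
         fitness_spec("antiport"), 0),
    list(ss12, transport_env(ion = -4, substrate = 2, decoy = 2),
         fitness_spec("competitive", decoy = "decoy"), 1))
  for (r in runs) {
    traj <- explore_models(r[[1]], r[[2]], r[[3]],
                           mc_config(n_steps = 10000, thin = 500, seed = 5),
                           ddG = r[[4]])
    expect_lt(traj$records[[traj$best]]$E_MC, traj$init_E_MC)
  }
})
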