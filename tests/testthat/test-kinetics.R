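# Mass-action kinetics: rate laws, derivative fields, simulation, and the
# dynamic verification of emulation and steady-state transfer.

test_that("mass action is the multiplicity-weighted product", {
  expect_equal(mass_action(reaction("2A + B", "C"), c(A = 2, B = 3)), 12)
  expect_equal(mass_action(reaction("0", "A", 2), c(A = 5)), 1)
  expect_equal(mass_action(reaction("A + B", "C"), c(A = 0, B = 3)), 0)
  # a species with zero multiplicity contributes 1 even at concentration 0
  expect_equal(mass_action(reaction("A", "B"), c(A = 2, B = 0)), 2)
  expect_error(mass_action(reaction("A", "B"), c(A = -1)), "negative")
})

test_that("derivatives sum phi against mass action", {
  am <- am_net()
  dv <- derivatives(am, c(x_0 = 1, x_1 = 0, x_2 = 1))
  expect_equal(dv, c(x_0 = -1, x_1 = 2, x_2 = -1))
  # brute-force oracle: per-reaction accumulation at random states
  for (k in 1:20) {
    net <- random_crn(500 + k, n_species = 4, n_reactions = 6)
    v <- random_state(600 + k, net, zero_prob = if (k %% 4 == 0) 0.5 else 0)
    oracle <- setNames(numeric(n_species(net)), net$species)
    for (r in net$reactions) {
      ma <- mass_action(r, v)
      for (s in union(names(r$reactants), names(r$products))) {
        rho_s <- if (s %in% names(r$reactants)) unclass(r$reactants)[[s]] else 0
        pi_s <- if (s %in% names(r$products)) unclass(r$products)[[s]] else 0
        oracle[s] <- oracle[s] + r$rate * (pi_s - rho_s) * ma
      }
    }
    expect_equal(derivatives(net, v), oracle, tolerance = 1e-12)
  }
})

test_that("multiplicity-conserving networks have zero total derivative", {
  net <- mi_net()   # every reaction preserves total multiplicity
  for (k in 1:10) {
    v <- random_state(700 + k, net)
    expect_equal(sum(derivatives(net, v)), 0, tolerance = 1e-12)
  }
})

test_that("simulation matches closed forms and fixed points", {
  # first-order decay A -> 0
  k <- 0.8
  net <- crn(list(reaction("A", "0", k)))
  traj <- simulate_crn(net, c(A = 1), t_end = 5, grid = 51)
  expect_equal(unname(traj$conc[, "A"]), exp(-k * traj$times),
               tolerance = 1e-7)
  # the zero state is a fixed point when nothing flows in
  am <- am_net()
  tz <- simulate_crn(am, c(x_0 = 0, x_1 = 0, x_2 = 0), t_end = 10,
                     grid = 11)
  expect_true(all(tz$conc == 0))
  # majority wins: AM from 2:0:1 converges to all mass in x_0
  tm <- simulate_crn(am, c(x_0 = 2, x_1 = 0, x_2 = 1), t_end = 100,
                     grid = 41)
  final <- tm$conc[nrow(tm$conc), ]
  expect_equal(unname(final["x_0"]), 3, tolerance = 1e-3)
  expect_lt(max(abs(derivatives(am, pmax(final, 0)))), 1e-6)
  expect_true(tm$meta$success)
  expect_gte(min(tm$conc), -10 * tm$meta$atol)
})

test_that("trajectory CSV export has the documented layout", {
  net <- crn(list(reaction("A", "B", 1)))
  traj <- simulate_crn(net, c(A = 1), t_end = 1, grid = 5)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("time", "A", "B"))
  expect_equal(nrow(df), 5L)
  expect_equal(df$A + df$B, rep(1, 5), tolerance = 1e-8)
})

test_that("pullback copies (never sums) target concentrations", {
  m <- mi_to_am()
  v <- pullback_state(m$species_map, c(x_0 = 0.3, x_1 = 0.5, x_2 = 0.9))
  expect_equal(v, c(y_0 = 0.3, y_1 = 0.5, y_2 = 0.9,
                    z_0 = 0.9, z_1 = 0.5, z_2 = 0.3))
  expect_equal(pullback_state(c(a = "t", b = "t"), c(t = 2)),
               c(a = 2, b = 2))
  expect_error(pullback_state(c(a = "t"), c(u = 1)), "cover")
})

test_that("mass action lemma: reactant morphisms preserve rate laws", {
  m <- mi_to_am()
  states <- sample_states(m$target, 100)
  for (v_hat in states) {
    v <- pullback_state(m$species_map, v_hat)
    for (j in seq_len(n_reactions(m$source))) {
      lhs <- mass_action(m$source$reactions[[j]], v)
      rhs <- mass_action(m$target$reactions[[m$reaction_map[j]]], v_hat)
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("emulation theorem: static conditions imply derivative identity", {
  for (nm in c("mi_to_am_morphism", "fig6a", "fig6f")) {
    m <- builtin_fixture(nm)$network
    expect_true(is_reactant_morphism(m)$holds)
    expect_true(is_stoichiomorphism(m)$holds)
    res <- check_emulation_derivative(m, sample_states(m$target, 50))
    expect_lt(as.numeric(res), 1e-12)
  }
  # contrapositive: the failing stoichiomorphisms miss the identity at the
  # all-ones state by exactly the witness gap
  for (nm in c("fig6b", "fig6d")) {
    m <- builtin_fixture(nm)$network
    ones <- setNames(rep(1, n_species(m$target)), m$target$species)
    expect_equal(as.numeric(check_emulation_derivative(m, ones)), 1)
  }
})

test_that("derivative identity holds for composed emulations", {
  comp <- compose_morphisms(double_mi(), mi_to_am())
  res <- check_emulation_derivative(comp, sample_states(comp$target, 20))
  expect_lt(as.numeric(res), 1e-12)
})

test_that("paired trajectories coincide for the MI -> AM emulation", {
  m <- mi_to_am()
  rep <- check_emulation_trajectory(m, random_state(42, m$target),
                                    t_end = 50)
  expect_true(rep$verdict)
  expect_lt(rep$trajectory_deviation, 1e-6)
  expect_lt(rep$derivative_residual, 1e-9)
  # identity morphism: zero deviation up to solver noise
  am <- am_net()
  idm <- crn_morphism(am, am, species = setNames(am$species, am$species),
                      reactions = 1:4)
  rep_id <- check_emulation_trajectory(idm, random_state(43, am))
  expect_lt(rep_id$trajectory_deviation, 1e-12)
})

test_that("broken stoichiomorphisms diverge within unit time", {
  m <- builtin_fixture("fig6b")$network
  ones <- setNames(rep(1, n_species(m$target)), m$target$species)
  rep <- check_emulation_trajectory(m, ones, t_end = 1, grid = 51)
  expect_false(rep$verdict)
  expect_gt(rep$trajectory_deviation, 1e-2)
})

test_that("reported deviations are stable under tolerance refinement", {
  m <- mi_to_am()
  v0 <- random_state(99, m$target)
  d1 <- check_emulation_trajectory(m, v0, rtol = 1e-9,
                                   atol = 1e-9)$trajectory_deviation
  d2 <- check_emulation_trajectory(m, v0, rtol = 5e-10,
                                   atol = 5e-10)$trajectory_deviation
  expect_lt(max(d1, d2), 1e-6)
  ratio <- max(d1, d2) / max(min(d1, d2), .Machine$double.eps)
  expect_lt(ratio, 10)
})

test_that("steady states transfer from target to source", {
  m <- mi_to_am()
  # boundary steady state: all mass in the active species
  chk <- steady_state_transfer(m, c(x_0 = 2.5, x_1 = 0, x_2 = 0),
                               tol = 1e-12)
  expect_true(chk$holds)
  expect_lt(chk$max_residual, 1e-12)
  # symmetric interior fixed point of AM
  chk2 <- steady_state_transfer(m, c(x_0 = 1, x_1 = 1, x_2 = 1) / 3)
  expect_true(chk2$holds)
  # non-steady states are rejected as a precondition
  expect_error(steady_state_transfer(m, c(x_0 = 1, x_1 = 1, x_2 = 0)),
               "not a steady state")
  # identity morphism transfers trivially
  am <- am_net()
  idm <- crn_morphism(am, am, species = setNames(am$species, am$species),
                      reactions = 1:4)
  expect_true(steady_state_transfer(idm, c(x_0 = 1, x_1 = 0,
                                           x_2 = 0))$holds)
})
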