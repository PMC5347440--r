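test_that("time step selection follows the transit-time quantile", {
  net3 <- make_chain(c("C", "C", "C"), lengths = c(100, 200, 300))
  # velocities chosen so L/v = 0.1, 0.2, 0.3 s
  v <- c(100, 200, 300) / c(0.1, 0.2, 0.3) / 1e3 # mm/s
  expect_equal(select_timestep(net3, v, coverage = 1.0), 0.1)

  # 1000 vessels, coverage 0.998: the 2nd-smallest ratio
  set.seed(1)
  L <- runif(1000, 40, 150)
  net1000 <- make_chain(rep("C", 1000), lengths = L)
  vel <- runif(1000, 0.2, 5)
  ratios <- sort(L / (vel * 1e3))
  expect_equal(select_timestep(net1000, vel, coverage = 0.998), ratios[2])

  # identical vessels: the common transit time regardless of coverage
  net_id <- make_chain(rep("C", 5), lengths = 80)
  expect_equal(select_timestep(net_id, rep(2, 5), coverage = 0.95),
               80 / 2000)
  expect_error(select_timestep(make_chain("C"), 0), "no flowing vessel")
})

test_that("divergent branch choice: velocity rule vs flow-rate rule", {
  ch <- branch_choice_divergent(c(11, 12), velocities = c(2, 1),
                                flows = c(2, 1))
  expect_equal(ch$velocity_rule, 11)
  expect_true(ch$agree)

  # exact tie: lowest edge id, and both rules agree
  tie <- branch_choice_divergent(c(21, 20), velocities = c(1, 1),
                                 flows = c(1, 1))
  expect_equal(tie$velocity_rule, 20)
  expect_equal(tie$flow_rule, 20)
  expect_true(tie$agree)

  # v = (2, 1.5) mm/s but d = (3, 4) um: q ~ v d^2 disagrees
  q <- c(2, 1.5) * pi * c(3, 4)^2 / 4
  dis <- branch_choice_divergent(c(1, 2), velocities = c(2, 1.5), flows = q)
  expect_equal(dis$velocity_rule, 1)
  expect_equal(dis$flow_rule, 2)
  expect_false(dis$agree)

  stall <- branch_choice_divergent(c(1, 2), c(0, 0), c(0, 0))
  expect_true(stall$stalled)
})

test_that("phase separation law: symmetry, thresholds, monotonicity", {
  # identical daughters at equal flow: equal split
  expect_equal(phase_separation_split(0.5, 10, 5, 5, 0.3), 0.5)

  # below the low-flow threshold no RBC enters the daughter
  x0 <- 0.964 * (1 - 0.3) / 10
  expect_equal(phase_separation_split(x0 * 0.9, 10, 5, 5, 0.3), 0)
  expect_equal(phase_separation_split(1 - x0 * 0.9, 10, 5, 5, 0.3), 1)

  # monotone sweep and exact complementarity for identical daughters
  x <- seq(0, 1, length.out = 201)
  f <- phase_separation_split(x, 10, 5, 5, 0.3)
  expect_true(all(diff(f) >= -1e-12))
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(f + rev(f), rep(1, 201), tolerance = 1e-10)

  # complementarity also holds for unequal daughters
  f1 <- phase_separation_split(x, 10, 4, 7, 0.3)
  f2 <- phase_separation_split(1 - x, 10, 7, 4, 0.3)
  expect_equal(f1 + f2, rep(1, 201), tolerance = 1e-10)

  expect_error(phase_separation_split(0.5, -1, 5, 5, 0.3), "domain error")
})

test_that("RBC advance: kinematics, Fahraeus factor and hematocrit", {
  net <- make_chain(c("C", "C"), diameters = 4, lengths = 50)
  bcs <- boundary_conditions(c(1, 3), c(50, 10), ht = 0)
  st <- sim_state(net, bcs, simulation_config(rbc_volume_fl = 49))

  # hematocrit bookkeeping: 3 cells in a 4 um x 50 um vessel
  st3 <- add_rbcs(st, c(1, 1, 1), c(10, 20, 30))
  ht <- mvnflow:::.edge_ht(st3)
  expect_equal(ht[1], 3 * 49e-18 / (pi * (2e-6)^2 * 50e-6),
               tolerance = 1e-12)

  # pure kinematics at ht = 0: the cell moves v * dt
  sol <- solve_pressure_flow(net, rep(1e15, 2), bcs)
  v_um <- sol$velocity[1] * 1e3
  dt <- 10 / v_um # time to travel 10 um
  st1 <- add_rbcs(st, 1, 0)
  st1 <- advance_rbcs(st1, sol, dt, ht = c(0, 0))
  expect_equal(st1$rbc_pos, 10, tolerance = 1e-9)

  # with hematocrit the cell is faster than the bulk by hd/ht >= 1
  st2 <- add_rbcs(st, 1, 0)
  ht_e <- mvnflow:::.edge_ht(st2)
  st2 <- advance_rbcs(st2, sol, dt, ht = ht_e)
  hd_e <- discharge_hematocrit(ht_e[1], 4, rheology_params(warn_small_d = FALSE))
  expect_equal(st2$rbc_pos, 10 * hd_e / ht_e[1], tolerance = 1e-9)
  expect_gte(st2$rbc_pos, 10)
})

test_that("no-overlap rule enforces the effective cell length", {
  # d = 3.533 um gives a ~5 um effective length for a 49 fL cell
  d <- sqrt(4 * 49e-18 / (5e-6 * pi)) * 1e6
  net <- make_chain("C", diameters = d, lengths = 100)
  bcs <- boundary_conditions(c(1, 2), c(50, 10), ht = 0)
  st <- sim_state(net, bcs)
  eff <- st$eff_len[1]
  expect_equal(eff, 5, tolerance = 1e-6)

  # leader at 51 um (stalled: zero flow), trailer 1 um behind
  sol0 <- solve_pressure_flow(net, 1e15, boundary_conditions(c(1, 2), c(10, 10)))
  st <- add_rbcs(st, c(1, 1), c(51, 50))
  st <- advance_rbcs(st, sol0, 0.01, ht = 0.2)
  gap <- abs(diff(sort(st$rbc_pos)))
  expect_gte(gap + 1e-9, eff)
})

test_that("RBC count is conserved exactly through a coupled run", {
  net <- make_y(parent_type = "DA", branch_types = c("C", "C"),
                parent_d = 10, branch_d = c(5, 6),
                branch_L = c(120, 80))
  bcs <- boundary_conditions(c(1, 3, 4), c(60, 12, 10), ht = 0.3)
  sim <- run_simulation(net, bcs,
                        simulation_config(warmup_turnovers = 2,
                                          record_turnovers = 2,
                                          drain_turnovers = 2, seed = 5))
  expect_true(sim$conservation_ok)
  expect_identical(sim$audit[["injected"]],
                   sim$audit[["exited"]] + sim$audit[["resident"]])
  expect_gt(sim$audit[["injected"]], 0)
  # with zero RBCs the coupled solve equals the pure plasma solve: the
  # first step's hematocrit is all-zero by construction
  ht0 <- mvnflow:::.edge_ht(sim_state(net, bcs, simulation_config()))
  expect_identical(ht0, rep(0, 3))
})

test_that("symmetric bifurcation splits RBC flux evenly", {
  # symmetric Y: identical daughters under identical outlet pressures
  net <- make_y(parent_type = "DA", branch_types = c("C", "C"),
                parent_d = 8, branch_d = c(5, 5), branch_L = c(100, 100))
  bcs <- boundary_conditions(c(1, 3, 4), c(80, 10, 10), ht = 0.3)
  sim <- run_simulation(net, bcs,
                        simulation_config(warmup_turnovers = 1,
                                          record_turnovers = 40,
                                          drain_turnovers = 3, seed = 11))
  ev <- sim$trajectories$events
  n1 <- sum(ev$edge == 2)
  n2 <- sum(ev$edge == 3)
  n <- n1 + n2
  expect_gte(n, 2000)
  # 99 % binomial interval around an even split
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(n1, ci[1])
  expect_lte(n1, ci[2])
})

test_that("time-step criterion holds for at least 99.8% of vessels", {
  net <- make_random_network(n = 60, extra = 30, seed = 2)
  res <- effective_resistance(net$vessels$diameter, net$vessels$length, 0,
                              rheology_params(warn_small_d = FALSE))
  bcs <- boundary_conditions(c(1, 25, 60), c(70, 40, 10))
  sol <- solve_pressure_flow(net, res, bcs)
  dt <- select_timestep(net, sol$velocity, 0.998)
  ratio <- net$vessels$length / (abs(sol$velocity) * 1e3)
  expect_gte(mean(dt <= ratio[is.finite(ratio)]), 0.998)
})
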