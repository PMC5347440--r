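test_that("pial pressure model: cubic arterioles, uniform venules", {
  model <- pial_pressure_model()
  expect_equal(pial_pressure(30, model, "venule"), 10)
  expect_equal(pial_pressure(c(15, 60), model, "venule"), c(10, 10))

  # degenerate model: constant polynomial
  flat <- structure(list(coef = c(42, 0, 0, 0), range = c(5, 100),
                         venular_pressure = 10),
                    class = "pial_pressure_model")
  expect_equal(pial_pressure(c(10, 50, 90), flat), c(42, 42, 42))

  # bundled fit against an independent Horner evaluation
  cf <- model$coef
  horner <- function(d) ((cf[4] * d + cf[3]) * d + cf[2]) * d + cf[1]
  for (d in c(15, 35, 70)) {
    expect_equal(pial_pressure(d, model), horner(d), tolerance = 1e-10)
  }
  # arteriolar pressures exceed the venular level over the fitted range
  expect_true(all(pial_pressure(seq(10, 80, 5), model) > 10))
  expect_warning(pial_pressure(200, model), "clamped")
})

# a small compound fixture shared by the remaining tests
local({
  bed <- generate_capillary_bed(700, 700, 500, hex_edge = 80, seed = 31)
  da <- generate_penetrating_tree("DA", template_depth = 700,
                                  ct_scale = 0.66, seed = 32)
  av <- generate_penetrating_tree("AV", template_depth = 700,
                                  ct_scale = 0.66, root_diameter = 18,
                                  seed = 33)
  host <- assemble_artificial_mvn(
    list(da, av), bed, positions = data.frame(x = c(220, 480),
                                              y = c(220, 480)))
  impl_bed <- generate_capillary_bed(420, 420, 460, hex_edge = 70,
                                     seed = 34)
  impl_da <- generate_penetrating_tree("DA", template_depth = 650,
                                       ct_scale = 0.66, seed = 35)
  impl_av <- generate_penetrating_tree("AV", template_depth = 650,
                                       root_diameter = 18,
                                       ct_scale = 0.66, seed = 36)
  implant_full <- assemble_artificial_mvn(
    list(impl_da, impl_av), impl_bed,
    positions = data.frame(x = c(140, 280), y = c(140, 280)))
  implant <- suppressMessages(trim_network(implant_full, 0.1, 0.4))

  test_that("build_compound stitches every deep boundary node once", {
    n_deep <- sum(implant$nodes$boundary == "deep_boundary")
    expect_gt(n_deep, 0)
    comp <- build_compound(implant, host)
    expect_equal(nrow(comp$stitch_map), n_deep)
    expect_equal(sum(comp$provenance == "stitch"), n_deep)
    expect_equal(sum(comp$provenance == "realistic"),
                 nrow(implant$vessels))
    expect_equal(igraph::components(as_igraph(comp$net))$no, 1L)

    # hole cutting removed exactly the host vessels with both endpoints
    # inside the implant bounding box (point-in-box oracle, accounting
    # for the centring translation)
    kept_host <- comp$net$vessels[comp$provenance == "artificial", ]
    hx <- range(host$nodes$x); hy <- range(host$nodes$y)
    ix <- range(implant$nodes$x); iy <- range(implant$nodes$y)
    sx <- mean(hx) - mean(ix); sy <- mean(hy) - mean(iy)
    bb <- list(x = ix + sx, y = iy + sy, z = range(implant$nodes$z))
    inside <- function(n) {
      n$x > bb$x[1] - 1 & n$x < bb$x[2] + 1 &
        n$y > bb$y[1] - 1 & n$y < bb$y[2] + 1 & n$z < bb$z[2] + 1
    }
    hn <- host$nodes
    hin <- setNames(inside(hn), as.character(hn$id))
    expected_removed <- sum(hin[as.character(host$vessels$from)] &
                              hin[as.character(host$vessels$to)])
    expect_equal(nrow(host$vessels) - nrow(kept_host), expected_removed)

    # an implant without deep boundary nodes cannot be stitched
    expect_error(build_compound(implant_full, host), "no deep_boundary")
  })

  test_that("hierarchical pressures: constant solution and bounds", {
    comp <- build_compound(implant, host)

    # uniform pial pressures propagate unchanged to the deep boundaries
    flat <- structure(list(coef = c(25, 0, 0, 0), range = c(2, 100),
                           venular_pressure = 25),
                      class = "pial_pressure_model")
    hp_flat <- hierarchical_pressures(comp, model = flat)
    deep <- hp_flat$implant_bcs[
      hp_flat$implant_bcs$node_id %in% comp$stitch_map$implant_original, ]
    expect_equal(deep$pressure, rep(25, nrow(deep)), tolerance = 1e-8)

    # with the bundled model: maximum principle on the deep pressures
    model <- pial_pressure_model()
    hp <- hierarchical_pressures(comp, model = model)
    deep <- hp$implant_bcs[
      hp$implant_bcs$node_id %in% comp$stitch_map$implant_original, ]
    p_max <- max(hp$compound_bcs$pressure)
    expect_true(all(deep$pressure >= 10 - 1e-9))
    expect_true(all(deep$pressure <= p_max + 1e-9))

    # compound solve against the dense oracle
    res <- effective_resistance(comp$net$vessels$diameter,
                                comp$net$vessels$length, 0.3,
                                rheology_params(warn_small_d = FALSE))
    oracle <- dense_solve_oracle(comp$net, res, hp$compound_bcs)
    got <- hp$compound_solution$node_pressure
    expect_lt(max(abs(got - oracle[names(got)])) / max(abs(oracle)), 1e-10)
  })

  test_that("two-level scheme is consistent at constant hematocrit", {
    comp <- build_compound(implant, host)
    hp <- hierarchical_pressures(comp)

    # flows through the stitch vessels in the compound solve
    sm <- comp$stitch_map
    vrow <- match(sm$vessel_id, comp$net$vessels$id)
    q_comp <- hp$compound_solution$flow[vrow]
    # sign: positive flow leaves the implant (stitch from = implant node)
    # solve the implant alone with the transferred pressures
    res_impl <- effective_resistance(implant$vessels$diameter,
                                     implant$vessels$length, 0.3,
                                     rheology_params(warn_small_d = FALSE))
    sol_impl <- solve_pressure_flow(implant, res_impl, hp$implant_bcs)
    v <- implant$vessels
    q_bnd <- vapply(sm$implant_original, function(nd) {
      sum(sol_impl$flow[v$from == nd]) - sum(sol_impl$flow[v$to == nd])
    }, numeric(1))
    # the implant's net outflow through its own vessels at a stitched
    # node balances the flow entering the stitch vessel there (the
    # compound node balance), so q_bnd = -q_comp
    expect_lt(max(abs(q_bnd + q_comp)) / max(abs(q_comp)), 1e-8)
  })
})
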