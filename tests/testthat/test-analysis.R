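test_that("trajectory classifier applies the two-edge deviation tolerance", {
  expect_equal(classify_trajectory(c("PA", "DA", "C", "C", "AV", "PV"))$class,
               "full_valid")
  # two deviating edges, then resumption at the same stage: accepted
  expect_true(classify_trajectory(
    c("PA", "DA", "C", "DA", "DA", "C", "AV", "PV"))$full_valid)
  # three deviating edges: rejected
  cl3 <- classify_trajectory(
    c("PA", "DA", "C", "DA", "DA", "DA", "C", "AV", "PV"))
  expect_false(cl3$full_valid)
  expect_false(cl3$capillary_valid)
  expect_equal(cl3$class, "invalid")

  # capillary-valid: no PA/PV needed
  cl <- classify_trajectory(c("DA", "C", "C", "AV"))
  expect_equal(cl$class, "capillary_valid")
  expect_false(cl$full_valid)

  # exit classes for invalid paths
  expect_equal(classify_trajectory(c("PA", "DA", "A"))$exit_class,
               "arteriole_outlet")
  expect_equal(classify_trajectory(c("PA", "DA", "C"))$exit_class,
               "capillary_outlet")
  expect_equal(classify_trajectory(c("V", "AV"))$exit_class, "other")
  expect_equal(classify_trajectory(character(0))$class, "invalid")
})

test_that("analysis layers use half-open depth bins", {
  expect_equal(layer_of(150), 1L)
  expect_equal(layer_of(200), 2L) # boundary belongs to the deeper layer
  expect_equal(layer_of(999.9), 5L)
  expect_true(is.na(layer_of(1050)))
  expect_true(is.na(layer_of(1000)))
  expect_error(analysis_layers(300, 1000), "divide")
})

test_that("Eq-style normalization divides by the per-start maximum", {
  expect_equal(normalize_by_group_max(c(2, 4, 8), rep(1, 3)),
               c(0.25, 0.5, 1.0))
  # normalization is per start point
  x <- c(2, 4, 8, 1, 3)
  g <- c(1, 1, 1, 2, 2)
  expect_equal(normalize_by_group_max(x, g), c(0.25, 0.5, 1, 1 / 3, 1))
})

test_that("endpoint preference flags and frequency normalization", {
  # one start node (100), three end nodes with frequencies 0.6/0.25/0.15
  counts <- c(12, 5, 3)
  ends <- c(201, 202, 203)
  paths <- list(); nodes <- list()
  k <- 0
  for (i in seq_along(counts)) {
    for (j in seq_len(counts[i])) {
      k <- k + 1
      paths[[k]] <- simple_path(
        c("DA", "C", "AV"), c(50, 40, 20),
        edge_ids = c(1, 10 * i, 100 + i),
        times = c(1, 2, 3))
      nodes[[k]] <- c(99, 100, 200 + i, 300 + i)
    }
  }
  traj <- make_traj(paths, node_seqs = nodes)
  ep <- endpoint_preference_and_correlation(traj)
  expect_equal(sum(ep$endpoints$f_ep), 1, tolerance = 1e-12)
  expect_equal(sort(ep$endpoints$f_ep), c(0.15, 0.25, 0.6))
  expect_true(ep$start_points$preferred_endpoint)

  # 0.55 / 0.35 / 0.10: runner-up too frequent, not preferred
  counts2 <- c(11, 7, 2)
  paths2 <- list(); nodes2 <- list(); k <- 0
  for (i in seq_along(counts2)) {
    for (j in seq_len(counts2[i])) {
      k <- k + 1
      paths2[[k]] <- simple_path(c("DA", "C", "AV"), c(50, 40, 20),
                                 edge_ids = c(1, 10 * i, 100 + i),
                                 times = c(1, 2, 3))
      nodes2[[k]] <- c(99, 100, 200 + i, 300 + i)
    }
  }
  ep2 <- endpoint_preference_and_correlation(make_traj(paths2, nodes2))
  expect_false(ep2$start_points$preferred_endpoint)
})

test_that("averaged curves: idempotent mean, endpoint values, mean ramps", {
  p1 <- simple_path(c("PA", "DA", "C", "AV", "PV"),
                    c(80, 70, 50, 20, 12), lengths = 100)
  traj_same <- make_traj(list(p1, p1), exit_pressures = c(10, 10))
  cv <- averaged_curves(traj_same, "pressure",
                        analysis_layers(200, 1000))
  expect_length(cv, 1)
  single <- averaged_curves(make_traj(list(p1), exit_pressures = 10),
                            "pressure", analysis_layers(200, 1000))
  expect_equal(cv[[1]]$curve$value, single[[1]]$curve$value,
               tolerance = 1e-12)
  # endpoints equal the inlet and outlet values
  expect_equal(cv[[1]]$curve$value[1], 80)
  expect_equal(cv[[1]]$curve$value[100], 10)

  # two linear ramps with distinct slopes average to the analytic mean
  pa <- simple_path(c("PA", "DA", "C", "AV", "PV"),
                    seq(100, 20, length.out = 5), lengths = 50)
  pb <- simple_path(c("PA", "DA", "C", "AV", "PV"),
                    seq(60, 20, length.out = 5), lengths = 50)
  tr <- make_traj(list(pa, pb), exit_pressures = c(0, 10))
  cv2 <- averaged_curves(tr, "pressure", analysis_layers(200, 1000),
                         grid_size = 51)
  ramp <- function(p0, p1) approx(c(0, 1), c(p0, p1),
                                  seq(0, 1, length.out = 51))$y
  expect_equal(cv2[[1]]$curve$value,
               (ramp(100, 0) + ramp(60, 10)) / 2, tolerance = 1e-9)
})

test_that("pressure drop decomposition reproduces hand arithmetic", {
  # inlet pressures 80 / 60 / 30 / 15 / 10 at the five type transitions
  p <- simple_path(c("PA", "DA", "C", "C", "AV", "PV"),
                   c(80, 60, 30, 25, 15, 10), lengths = 100)
  traj <- make_traj(list(p), exit_pressures = 8)
  drops <- pressure_drop_by_type(traj, analysis_layers(200, 1000))
  expect_equal(drops$type, c("PA", "DA+A", "C", "V+AV", "PV"))
  expect_equal(drops$inlet_pressure, c(80, 60, 30, 15, 10))
  expect_equal(drops$drop_fraction[1:4],
               c(2 / 7, 3 / 7, 1.5 / 7, 0.5 / 7), tolerance = 1e-12)

  # first_C_as_DA+A: the first capillary edge's drop moves to the DA+A
  d2 <- pressure_drop_by_type(traj, analysis_layers(200, 1000),
                              labeling_variant = "first_C_as_DA+A")
  expect_equal(d2$inlet_pressure[d2$type == "C"], 25)
  expect_gt(d2$drop[d2$type == "DA+A"],
            drops$drop[drops$type == "DA+A"])
  expect_lt(d2$drop[d2$type == "C"], drops$drop[drops$type == "C"])

  # ensemble against a per-trajectory brute-force average
  set.seed(8)
  paths <- lapply(1:100, function(i) {
    ps <- sort(runif(5, 10, 90), decreasing = TRUE)
    simple_path(c("PA", "DA", "C", "AV", "PV"), ps, lengths = 100)
  })
  trj <- make_traj(paths, exit_pressures = rep(5, 100))
  dd <- pressure_drop_by_type(trj, analysis_layers(200, 1000))
  inlet_means <- rowMeans(vapply(paths, function(p) p$pressure,
                                 numeric(5)))
  expect_equal(dd$inlet_pressure, unname(inlet_means), tolerance = 1e-9)
  expect_equal(sum(dd$drop_fraction[1:4]), 1, tolerance = 1e-12)
})

test_that("transit, feeding and in-plane statistics", {
  # tt_C and v_RBC arithmetic: capillary from t=1.0 to 1.5 s over 0.3 mm
  p <- data.frame(edge = 1:4, type = c("DA", "C", "C", "AV"),
                  length = c(100, 150, 150, 100),
                  time = c(0.5, 1.0, 1.25, 1.5),
                  pressure = c(50, 40, 30, 20))
  traj <- make_traj(list(p), exit_times = 2, exit_pressures = 10)
  st <- transit_and_feeding_stats(traj, analysis_layers(200, 1000))
  expect_equal(st$layer_summary$tt_c_mean, 0.5)
  expect_equal(st$layer_summary$ts_c_mean, 0.3)
  expect_equal(st$layer_summary$v_rbc_c_mean, 0.6)

  # feeding: AV receiving 7/2/1 RBCs from three DAs
  counts <- c(7, 2, 1)
  paths <- list(); k <- 0
  for (i in seq_along(counts)) {
    for (j in seq_len(counts[i])) {
      k <- k + 1
      paths[[k]] <- simple_path(c("DA", "C", "AV"), c(50, 30, 15),
                                edge_ids = c(i, 50, 99),
                                times = c(1, 2, 3))
    }
  }
  st2 <- transit_and_feeding_stats(make_traj(paths),
                                   analysis_layers(200, 1000))
  expect_equal(st2$feeding$primary_da, 1L)
  expect_equal(st2$feeding$primary_fraction, 0.7)
  expect_equal(st2$feeding$n_feeding_da, 3L)

  # in-plane regression recovery: end depth = start depth + small noise
  set.seed(99)
  depths <- runif(60, 100, 900)
  noise <- rnorm(60, 0, 5)
  paths3 <- list(); nodes3 <- list(); zs <- c()
  for (i in seq_len(60)) {
    paths3[[i]] <- simple_path(c("DA", "C", "AV"),
                               c(50, 30, 15), times = c(1, 1.5, 2))
    ns <- (i - 1) * 4 + 1:4
    nodes3[[i]] <- ns
    zs[as.character(ns[2])] <- depths[i]
    zs[as.character(ns[3])] <- depths[i] + noise[i]
  }
  tr3 <- make_traj(paths3, node_seqs = nodes3, node_z = zs)
  st3 <- transit_and_feeding_stats(tr3, analysis_layers(200, 1000))
  expect_equal(st3$inplane_fit$slope, 1, tolerance = 0.05)
  expect_equal(st3$inplane_fit$intercept, 0, tolerance = 0.02) # mm
  expect_gt(st3$inplane_fit$r, 0.99)
})

test_that("simple-path counts match an igraph enumeration oracle", {
  net <- make_random_network(n = 12, extra = 6, seed = 13)
  g <- as_igraph(net)
  for (pair in list(c(1, 12), c(2, 11))) {
    mine <- count_simple_paths(net, pair[1], pair[2])
    oracle <- length(igraph::all_simple_paths(
      g, from = as.character(pair[1]), to = as.character(pair[2])))
    expect_equal(mine, oracle)
  }
  # type restriction: only capillary edges may be traversed
  nety <- make_y(parent_type = "DA")
  expect_equal(count_simple_paths(nety, 2, c(3, 4), via_types = "C"), 2)
  expect_equal(count_simple_paths(nety, 1, c(3, 4), via_types = "C"), 0)
})
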