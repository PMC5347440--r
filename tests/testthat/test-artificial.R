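test_that("capillary bed: degree-3 interior topology and determinism", {
  bed <- generate_capillary_bed(500, 500, 500, hex_edge = 60, seed = 21)
  g <- as_igraph(bed)
  deg <- igraph::degree(g)
  nd <- bed$nodes
  interior <- nd$x > 60 & nd$x < max(nd$x) - 60 &
    nd$y > 60 & nd$y < max(nd$y) - 60 &
    nd$z > min(nd$z) & nd$z < max(nd$z)
  expect_true(all(deg[as.character(nd$id[interior])] == 3))
  expect_equal(igraph::components(g)$no, 1L)

  expect_true(network_identical(
    bed, generate_capillary_bed(500, 500, 500, hex_edge = 60, seed = 21)))
  d2 <- generate_capillary_bed(500, 500, 500, hex_edge = 60, seed = 22)
  expect_false(isTRUE(all.equal(bed$vessels$diameter, d2$vessels$diameter)))

  expect_true(all(bed$vessels$diameter >= 2.5 &
                    bed$vessels$diameter <= 9.0))
  expect_error(generate_capillary_bed(50, 50, 100, hex_edge = 60),
               "config error")
})

test_that("capillary bed vessel count matches the lattice construction", {
  # independent re-count: enumerate hexagon corners and unique edges,
  # then apply the stacking bookkeeping (one orientation class replaced
  # by verticals on each side of every layer interface)
  a <- 60; ex <- 400; ey <- 400; depth <- 400
  cx <- c(); cy <- c()
  for (row in 0:(ceiling(ey / (1.5 * a)) + 1)) {
    for (col in 0:(ceiling(ex / (sqrt(3) * a)) + 1)) {
      cx <- c(cx, sqrt(3) * a * (col + 0.5 * (row %% 2)))
      cy <- c(cy, 1.5 * a * row)
    }
  }
  ang <- (30 + 60 * 0:5) * pi / 180
  ekeys <- character(0); ecls <- integer(0)
  for (h in seq_along(cx)) {
    px <- cx[h] + a * cos(ang); py <- cy[h] + a * sin(ang)
    for (k in 1:6) {
      k2 <- if (k == 6) 1 else k + 1
      if (min(px[c(k, k2)]) < -1e-6 || max(px[c(k, k2)]) > ex + 1e-6 ||
          min(py[c(k, k2)]) < -1e-6 || max(py[c(k, k2)]) > ey + 1e-6) next
      key <- paste(sort(c(paste(round(px[k], 3), round(py[k], 3)),
                          paste(round(px[k2], 3), round(py[k2], 3)))),
                   collapse = "|")
      th <- (atan2(py[k2] - py[k], px[k2] - px[k]) * 180 / pi) %% 180
      ekeys <- c(ekeys, key); ecls <- c(ecls, round((th - 30) / 60) %% 3 + 1)
    }
  }
  keep <- !duplicated(ekeys)
  cls_count <- table(ecls[keep])
  e_layer <- sum(keep)
  nodes_layer <- length(unique(unlist(strsplit(ekeys[keep], "|",
                                               fixed = TRUE))))
  n_z <- floor(depth / a) + 1
  drop_per_layer <- vapply(seq_len(n_z), function(k) {
    dc <- integer(0)
    if (k > 1) dc <- c(dc, (k - 2) %% 3 + 1)
    if (k < n_z) dc <- c(dc, (k - 1) %% 3 + 1)
    sum(cls_count[as.character(dc)])
  }, numeric(1))
  expected <- n_z * e_layer - sum(drop_per_layer) +
    (n_z - 1) * nodes_layer
  bed <- generate_capillary_bed(ex, ey, depth, hex_edge = a, seed = 1)
  expect_equal(nrow(bed$vessels), expected)
})

test_that("penetrating trees: depth scaling, taper and labels", {
  tr <- generate_penetrating_tree("DA", template_depth = 1500,
                                  ct_scale = 1.0, branch_segments = 2,
                                  seed = 2)
  # trunk reaches the template depth; side branches dip slightly deeper
  expect_equal(max(tr$nodes$z), 1500 + 2 * 150 * 0.25, tolerance = 1e-9)
  tr66 <- generate_penetrating_tree("DA", template_depth = 1500,
                                    ct_scale = 0.66, branch_segments = 0,
                                    seed = 2)
  expect_equal(max(tr66$nodes$z), 0.66 * 1500, tolerance = 1e-9)

  # area-halving taper: each side-branch segment divides d by sqrt(2)
  tr3 <- generate_penetrating_tree("DA", root_diameter = 15,
                                   template_depth = 600,
                                   segment_length = 200,
                                   branch_segments = 3, trunk_tip_frac = 0.9,
                                   seed = 3)
  v <- tr3$vessels
  trunk_rows <- which(v$type %in% c("PA", "DA"))
  first_branch <- which(v$type == "A")[1:3]
  parent_d <- v$diameter[trunk_rows[1]]
  # the branch hangs off the node after the first trunk segment
  expect_equal(v$diameter[first_branch],
               v$diameter[1] / sqrt(2)^(1:3), tolerance = 1e-9)

  av <- generate_penetrating_tree("AV", seed = 4)
  expect_true(all(av$vessels$type %in% c("PV", "AV", "V")))
  expect_equal(av$nodes$boundary[1], "pial_outflow")
  expect_equal(tr$nodes$boundary[1], "pial_inflow")
  expect_warning(
    generate_penetrating_tree("DA", root_diameter = 5, seed = 1),
    "2.5 um floor")
})

test_that("rhombic lattice positions match the generator formula", {
  lat <- penetrating_lattice(2, 2, spacing = 350)
  expect_equal(lat$x, c(0, 350, 175, 525))
  expect_equal(lat$y, c(0, 0, 350 * sqrt(3) / 2, 350 * sqrt(3) / 2))
  expect_equal(lat$kind, c("DA", "AV", "AV", "DA"))
})

test_that("assembly joins every tree leaf to the nearest capillary node", {
  bed <- generate_capillary_bed(500, 500, 900, hex_edge = 70, seed = 5)
  da <- generate_penetrating_tree("DA", seed = 6)
  av <- generate_penetrating_tree("AV", root_diameter = 18, seed = 7)
  mvn <- assemble_artificial_mvn(list(da, av), bed,
                                 positions = data.frame(x = c(150, 350),
                                                        y = c(150, 350)))
  g <- as_igraph(mvn)
  expect_equal(igraph::components(g)$no, 1L)
  expect_equal(sum(mvn$nodes$boundary == "pial_inflow"), 1L)
  expect_equal(sum(mvn$nodes$boundary == "pial_outflow"), 1L)
  # every DA-side capillary path can reach the venular side
  dists <- igraph::distances(
    g, v = as.character(mvn$nodes$id[mvn$nodes$boundary == "pial_inflow"]),
    to = as.character(mvn$nodes$id[mvn$nodes$boundary == "pial_outflow"]))
  expect_true(all(is.finite(dists)))

  # a leaf exactly equidistant from two capillary nodes picks the lower id
  mini_bed <- vasc_network(
    data.frame(id = 1:3, x = c(-50, 50, 0), y = 0, z = c(100, 100, 200),
               boundary = "interior"),
    data.frame(id = 1:2, from = c(1, 2), to = 3, diameter = 5,
               length = c(112, 112), type = "C"))
  stub <- vasc_network(
    data.frame(id = 1:2, x = 0, y = 0, z = c(0, 50),
               boundary = c("pial_inflow", "interior")),
    data.frame(id = 1, from = 1, to = 2, diameter = 10, length = 50,
               type = "DA"))
  attr(stub, "kind") <- "DA"
  asm <- assemble_artificial_mvn(list(stub), mini_bed, positions = NULL,
                                 connect_radius = 200)
  stitch <- asm$vessels[asm$vessels$from == 2 & asm$vessels$type == "C", ]
  # node ids were renumbered: bed node 1 (x = -50) comes before node 2
  expect_equal(nrow(stitch), 1L)
  bed_node <- asm$nodes[asm$nodes$id == stitch$to, ]
  expect_equal(bed_node$x, -50)
})
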