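#' Pial pressure model
#'
#' Pressure boundary values at the pial surface: a cubic polynomial in the
#' vessel diameter on the arteriolar side, and a uniform pressure on the
#' venular side (default 10 mmHg). The cubic is fitted at build time by
#' least squares to a bundled table of literature-shaped pial arteriole
#' pressure points. The bundled table is a synthetic stand-in shaped after
#' published micropipette measurements (see the file
#' `extdata/pial_pressure_points_synthetic.csv`); supply your own `points`
#' to override it.
#'
#' @param points data.frame with columns `diameter_um`, `pressure_mmhg`
#'   (default: the bundled synthetic table).
#' @param venular_pressure uniform pial venule pressure in mmHg (default 10).
#' @return object of class `pial_pressure_model` with the fitted cubic
#'   `coef` (intercept first) and the supported diameter `range`.
#' @export
pial_pressure_model <- function(points = NULL, venular_pressure = 10) {
  if (is.null(points)) {
    path <- system.file("extdata", "pial_pressure_points_synthetic.csv",
                        package = "mvnflow")
    if (path == "") { # running from a source tree
      path <- file.path("inst", "extdata",
                        "pial_pressure_points_synthetic.csv")
    }
    points <- utils::read.csv(path)
  }
  fit <- stats::lm(pressure_mmhg ~ poly(diameter_um, 3, raw = TRUE),
                   data = points)
  structure(list(coef = unname(stats::coef(fit)),
                 range = range(points$diameter_um),
                 venular_pressure = venular_pressure),
            class = "pial_pressure_model")
}

#' Evaluate the pial pressure model
#'
#' @param d vessel diameter(s) in um. Diameters outside the fitted range
#'   are clamped with a warning.
#' @param model a [pial_pressure_model()].
#' @param kind `"arteriole"` (cubic in diameter) or `"venule"` (uniform).
#' @return pressure(s) in mmHg.
#' @export
pial_pressure <- function(d, model = pial_pressure_model(),
                          kind = c("arteriole", "venule")) {
  kind <- match.arg(kind)
  if (kind == "venule") return(rep(model$venular_pressure, length(d)))
  if (any(d < model$range[1] | d > model$range[2])) {
    warning("diameter outside the fitted pial pressure range [",
            model$range[1], ", ", model$range[2], "] um; clamped")
    d <- pmin(pmax(d, model$range[1]), model$range[2])
  }
  cf <- model$coef
  cf[1] + cf[2] * d + cf[3] * d^2 + cf[4] * d^3
}

#' Assign pial pressure boundary conditions to a network
#'
#' Every `pial_inflow` node receives the arteriolar cubic evaluated at the
#' diameter of its adjacent vessel; every `pial_outflow` node receives the
#' uniform venular pressure. The inflow tube hematocrit is attached to all
#' entries.
#'
#' @param net a [vasc_network()].
#' @param model a [pial_pressure_model()].
#' @param inflow_ht tube hematocrit at inflows (default 0.3).
#' @return a [boundary_conditions()] table.
#' @export
pial_boundary_conditions <- function(net, model = pial_pressure_model(),
                                     inflow_ht = 0.3) {
  adj <- .adjacency_index(net)
  root_d <- function(id) net$vessels$diameter[adj[[as.character(id)]][1]]
  ain <- net$nodes$id[net$nodes$boundary == "pial_inflow"]
  vout <- net$nodes$id[net$nodes$boundary == "pial_outflow"]
  if (!length(ain) || !length(vout)) {
    stop("integrity error: network needs pial inflow and outflow nodes")
  }
  p_in <- pial_pressure(vapply(ain, root_d, numeric(1)), model, "arteriole")
  p_out <- pial_pressure(vapply(vout, root_d, numeric(1)), model, "venule")
  boundary_conditions(c(ain, vout), c(p_in, p_out), inflow_ht)
}

#' Implant a network into an artificial host (compound network)
#'
#' Cuts a hole of the implant's bounding box out of the artificial host
#' (all host vessels with both endpoints inside the box are removed, along
#' with host nodes left isolated), positions the implant in the cut-out,
#' and joins every `deep_boundary` node of the implant to the nearest
#' remaining host capillary vertex by a stitch vessel.
#'
#' @param realistic the implant [vasc_network()]; must carry at least one
#'   `deep_boundary` node.
#' @param artificial the host [vasc_network()]; its footprint must strictly
#'   contain the implant's bounding box.
#' @param margin box margin in um added around the implant bounding box
#'   when cutting the hole (default 1).
#' @return an object of class `compound_network`: list with the merged
#'   `net`, the `stitch_map` (data.frame implant node id in the compound,
#'   original implant node id, host node id, stitch vessel id), a vessel
#'   `provenance` factor (realistic/artificial/stitch) and `implant_nodes`
#'   mapping original implant node ids to compound node ids.
#' @export
build_compound <- function(realistic, artificial, margin = 1) {
  deep <- realistic$nodes$id[realistic$nodes$boundary == "deep_boundary"]
  if (!length(deep)) {
    stop("assembly error: implant has no deep_boundary node to stitch")
  }
  hx <- range(artificial$nodes$x); hy <- range(artificial$nodes$y)
  # position the implant in the centre of the host footprint (the two
  # networks keep their own node ids; only coordinates move)
  ix <- range(realistic$nodes$x); iy <- range(realistic$nodes$y)
  realistic <- .translate_network(realistic,
                                  mean(hx) - mean(ix), mean(hy) - mean(iy))
  bb <- list(x = range(realistic$nodes$x), y = range(realistic$nodes$y),
             z = range(realistic$nodes$z))
  if (bb$x[1] <= hx[1] || bb$x[2] >= hx[2] ||
      bb$y[1] <= hy[1] || bb$y[2] >= hy[2]) {
    stop("assembly error: artificial footprint must strictly contain the ",
         "implant bounding box")
  }
  inside <- function(x, y, z) {
    x > bb$x[1] - margin & x < bb$x[2] + margin &
      y > bb$y[1] - margin & y < bb$y[2] + margin &
      z < bb$z[2] + margin # the hole is open toward the pial surface
  }
  an <- artificial$nodes
  node_in <- inside(an$x, an$y, an$z)
  names(node_in) <- as.character(an$id)
  av <- artificial$vessels
  v_in <- node_in[as.character(av$from)] & node_in[as.character(av$to)]
  host_v <- av[!v_in, , drop = FALSE]
  keep_node <- an$id %in% c(host_v$from, host_v$to) | !node_in
  host <- vasc_network(an[keep_node, , drop = FALSE], host_v)

  merged <- .merge_networks(list(realistic, host))
  net <- merged$net
  n_impl_nodes <- nrow(realistic$nodes)
  implant_nodes <- data.frame(
    original = realistic$nodes$id,
    compound = merged$node_offsets[1] + seq_len(n_impl_nodes))
  n_impl_v <- nrow(realistic$vessels)
  provenance <- rep(c("realistic", "artificial"),
                    c(n_impl_v, nrow(host$vessels)))

  # host capillary vertices available for stitching
  host_first <- merged$node_offsets[2] + 1L
  cap_v <- net$vessels[net$vessels$type == "C" &
                         net$vessels$from >= host_first, , drop = FALSE]
  cap_nodes <- sort(unique(c(cap_v$from, cap_v$to)))
  cap_nodes <- cap_nodes[cap_nodes >= host_first]
  if (!length(cap_nodes)) stop("assembly error: host has no capillary vertex")
  ci <- match(cap_nodes, net$nodes$id)

  deep_compound <- implant_nodes$compound[match(deep, implant_nodes$original)]
  stitch <- vector("list", length(deep))
  vid <- max(net$vessels$id)
  for (k in seq_along(deep)) {
    i <- match(deep_compound[k], net$nodes$id)
    d2 <- (net$nodes$x[ci] - net$nodes$x[i])^2 +
      (net$nodes$y[ci] - net$nodes$y[i])^2 +
      (net$nodes$z[ci] - net$nodes$z[i])^2
    j <- which(d2 == min(d2))
    j <- j[which.min(cap_nodes[j])]
    # stitch caliber follows the implant vessel at the deep node
    dd <- net$vessels$diameter[net$vessels$from == deep_compound[k] |
                                 net$vessels$to == deep_compound[k]][1]
    vid <- vid + 1L
    stitch[[k]] <- data.frame(
      implant_compound = deep_compound[k], implant_original = deep[k],
      host_node = cap_nodes[j], vessel_id = vid,
      stringsAsFactors = FALSE)
    net$vessels <- rbind(net$vessels, data.frame(
      id = vid, from = deep_compound[k], to = cap_nodes[j],
      diameter = min(max(dd, 2.5), 9), length = max(sqrt(d2[j]), 1),
      type = "C"))
    provenance <- c(provenance, "stitch")
  }
  validate_network(net)
  g <- as_igraph(net)
  if (igraph::components(g)$no != 1L) {
    stop("assembly error: compound network is not connected")
  }
  structure(list(net = net, stitch_map = do.call(rbind, stitch),
                 provenance = provenance, implant_nodes = implant_nodes),
            class = "compound_network")
}

#' Deep boundary pressures from the compound steady solve
#'
#' Solves the steady pressure/flow problem on the compound network with
#' every vessel's resistance evaluated at a constant tube hematocrit (no
#' RBC tracking), pial boundary conditions from the pial pressure model,
#' and returns the solved pressures at the implant's deep boundary nodes
#' as a boundary-condition table for the implant alone.
#'
#' @param compound a [build_compound()] result.
#' @param constant_ht constant tube hematocrit of the steady solve
#'   (default 0.3, mirroring the inflow hematocrit).
#' @param model a [pial_pressure_model()].
#' @param inflow_ht hematocrit attached to the returned BC entries.
#' @return list with `implant_bcs` (a [boundary_conditions()] table in the
#'   implant's original node ids, covering its deep boundary and pial
#'   nodes), `compound_solution` (the [solve_pressure_flow()] result) and
#'   `compound_bcs`.
#' @export
hierarchical_pressures <- function(compound, constant_ht = 0.3,
                                   model = pial_pressure_model(),
                                   inflow_ht = 0.3) {
  net <- compound$net
  bcs <- pial_boundary_conditions(net, model, inflow_ht)
  res <- effective_resistance(net$vessels$diameter, net$vessels$length,
                              constant_ht)
  sol <- solve_pressure_flow(net, res, bcs)
  deep <- compound$stitch_map
  p_deep <- sol$node_pressure[as.character(deep$implant_compound)]
  deep_bcs <- boundary_conditions(deep$implant_original, p_deep, inflow_ht)
  # pial nodes of the implant keep their model pressures
  impl_pial <- compound$implant_nodes[
    compound$implant_nodes$compound %in%
      bcs$node_id[bcs$node_id %in% compound$implant_nodes$compound], ]
  if (nrow(impl_pial)) {
    pb <- bcs[match(impl_pial$compound, bcs$node_id), ]
    pial_bcs <- boundary_conditions(impl_pial$original, pb$pressure, pb$ht)
    implant_bcs <- rbind(pial_bcs, deep_bcs)
  } else {
    implant_bcs <- deep_bcs
  }
  list(implant_bcs = implant_bcs, compound_solution = sol,
       compound_bcs = bcs)
}
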