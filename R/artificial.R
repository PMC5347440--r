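# run expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# honeycomb patch covering [0, extent_x] x [0, extent_y]: returns nodes
# (x, y) and edges (from, to, class) with class in 1:3 by edge orientation
.honeycomb_layer <- function(extent_x, extent_y, a) {
  if (extent_x < sqrt(3) * a || extent_y < 1.5 * a) {
    stop("config error: lateral extent too small for one hexagon of edge ",
         a, " um")
  }
  ncol_ <- ceiling(extent_x / (sqrt(3) * a)) + 1L
  nrow_ <- ceiling(extent_y / (1.5 * a)) + 1L
  centers <- expand.grid(col = 0:(ncol_ - 1L), row = 0:(nrow_ - 1L))
  cx <- sqrt(3) * a * (centers$col + 0.5 * (centers$row %% 2))
  cy <- 1.5 * a * centers$row
  ang <- (30 + 60 * 0:5) * pi / 180
  corner_x <- outer(cx, a * cos(ang), "+")
  corner_y <- outer(cy, a * sin(ang), "+")
  key <- paste(round(corner_x, 3), round(corner_y, 3))
  uniq <- !duplicated(as.vector(key))
  ux <- as.vector(corner_x)[uniq]
  uy <- as.vector(corner_y)[uniq]
  node_of <- stats::setNames(seq_along(ux), as.vector(key)[uniq])
  nh <- nrow(centers)
  e_from <- e_to <- integer(0)
  for (k in 1:6) {
    k2 <- if (k == 6) 1L else k + 1L
    e_from <- c(e_from, node_of[key[(k - 1) * nh + seq_len(nh)]])
    e_to <- c(e_to, node_of[key[(k2 - 1) * nh + seq_len(nh)]])
  }
  lo <- pmin(e_from, e_to); hi <- pmax(e_from, e_to)
  keep <- !duplicated(paste(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  # clip to the requested footprint: drop edges with a node outside
  in_box <- ux >= -1e-6 & ux <= extent_x + 1e-6 &
    uy >= -1e-6 & uy <= extent_y + 1e-6
  keep <- in_box[lo] & in_box[hi]
  lo <- lo[keep]; hi <- hi[keep]
  # orientation class from the edge angle modulo 180 degrees
  th <- atan2(uy[hi] - uy[lo], ux[hi] - ux[lo]) * 180 / pi
  th <- th %% 180
  cls <- round((th - 30) / 60) %% 3 + 1L
  used <- sort(unique(c(lo, hi)))
  remap <- integer(length(ux)); remap[used] <- seq_along(used)
  list(x = ux[used], y = uy[used],
       edges = data.frame(from = remap[lo], to = remap[hi], class = cls))
}

#' Generate a stacked hexagonal capillary bed
#'
#' Builds planar honeycomb lattices stacked in z. Between each pair of
#' adjacent layers one of the three in-plane edge-orientation classes
#' (cycling with depth) is removed from both layers and replaced by
#' vertical connecting vessels at every node, so that every interior
#' bifurcation keeps exactly three adjacent edges. All vessels are labeled
#' `C` with diameters drawn from the goal beta distribution, truncated to
#' its support.
#'
#' @param extent_x,extent_y lateral footprint in um.
#' @param depth vertical extent in um (z from 0 or `z_offset` downward).
#' @param hex_edge hexagon edge length in um (default 60).
#' @param layer_spacing vertical spacing between lattice planes, um
#'   (default `hex_edge`).
#' @param z_offset depth of the topmost lattice plane, um (default 60; a
#'   capillary bed does not reach the pial surface).
#' @param diameter_config an [upscale_config()] describing the capillary
#'   diameter distribution.
#' @param seed RNG seed for the diameter draw (the topology is
#'   deterministic).
#' @return a [vasc_network()] of capillaries.
#' @export
generate_capillary_bed <- function(extent_x, extent_y, depth,
                                   hex_edge = 60, layer_spacing = hex_edge,
                                   z_offset = 60,
                                   diameter_config = upscale_config(),
                                   seed = 1L) {
  layer <- .honeycomb_layer(extent_x, extent_y, hex_edge)
  n_layer <- length(layer$x)
  n_z <- max(1L, floor(depth / layer_spacing) + 1L)
  zs <- z_offset + (0:(n_z - 1L)) * layer_spacing

  nodes <- data.frame(
    id = seq_len(n_layer * n_z),
    x = rep(layer$x, n_z),
    y = rep(layer$y, n_z),
    z = rep(zs, each = n_layer),
    boundary = "interior")

  edges_list <- vector("list", 2L * n_z)
  for (k in seq_len(n_z)) {
    drop_cls <- integer(0)
    if (k > 1L) drop_cls <- c(drop_cls, (k - 2L) %% 3L + 1L)
    if (k < n_z) drop_cls <- c(drop_cls, (k - 1L) %% 3L + 1L)
    e <- layer$edges[!(layer$edges$class %in% drop_cls), , drop = FALSE]
    off <- (k - 1L) * n_layer
    edges_list[[2L * k - 1L]] <- data.frame(from = e$from + off,
                                            to = e$to + off)
    if (k < n_z) {
      edges_list[[2L * k]] <- data.frame(from = off + seq_len(n_layer),
                                         to = off + n_layer + seq_len(n_layer))
    }
  }
  ed <- do.call(rbind, edges_list)
  dx <- nodes$x[ed$to] - nodes$x[ed$from]
  dy <- nodes$y[ed$to] - nodes$y[ed$from]
  dz <- nodes$z[ed$to] - nodes$z[ed$from]
  len <- sqrt(dx^2 + dy^2 + dz^2)
  diam <- .with_seed(seed, {
    d <- sample_goal_diameters(nrow(ed), diameter_config)
    pmin(pmax(d, diameter_config$d_min), diameter_config$d_max)
  })
  vessels <- data.frame(id = seq_len(nrow(ed)), from = ed$from, to = ed$to,
                        diameter = diam, length = len, type = "C")
  vasc_network(nodes, vessels)
}

#' Generate a penetrating arteriole or venule tree
#'
#' A rooted tree descending from the pial surface (z = 0) to a target
#' template depth, with lateral side branches at every trunk node. Template
#' depths are scaled by the ratio of cortical thicknesses `ct_scale`
#' (default 0.66, mouse/rat) before the network is returned. Trunk
#' diameters taper linearly from the root diameter to `trunk_tip_frac`
#' times the root; each side-branch level halves the lumen area relative
#' to its parent (diameter divided by sqrt(2)). Branch segments whose taper
#' would fall below 2.5 um are truncated with a warning.
#'
#' @param kind `"DA"` (descending arteriole, labeled DA with side branches
#'   A, root flagged `pial_inflow`) or `"AV"` (ascending venule, labeled AV
#'   with side branches V, root flagged `pial_outflow`).
#' @param template_depth unscaled tree depth in um (rat template; default
#'   1500).
#' @param ct_scale cortical-thickness scale factor applied to all depths
#'   (default 0.66).
#' @param root_diameter trunk diameter at the pial surface, um.
#' @param segment_length trunk segment length in um (template scale).
#' @param branches_per_level side branches at every trunk node (default 1).
#' @param branch_segments segments per side branch (default 2).
#' @param trunk_tip_frac trunk tip diameter as a fraction of the root
#'   diameter (default 0.4).
#' @param root_xy root position `(x, y)` in um.
#' @param pial_root label the first trunk segment as a pial vessel (PA for
#'   DA trees, PV for AV trees), so that paths through an assembled
#'   artificial network traverse all five vessel classes (default TRUE).
#' @param seed RNG seed for branch azimuths.
#' @return a [vasc_network()] whose leaves (degree-1 nodes other than the
#'   root) are the connection points to a capillary bed.
#' @export
generate_penetrating_tree <- function(kind = c("DA", "AV"),
                                      template_depth = 1500,
                                      ct_scale = 0.66,
                                      root_diameter = 15,
                                      segment_length = 150,
                                      branches_per_level = 1L,
                                      branch_segments = 2L,
                                      trunk_tip_frac = 0.4,
                                      root_xy = c(0, 0),
                                      pial_root = TRUE,
                                      seed = 1L) {
  kind <- match.arg(kind)
  trunk_lab <- kind
  side_lab <- if (kind == "DA") "A" else "V"
  n_seg <- max(2L, round(template_depth / segment_length))
  zs <- seq(0, template_depth, length.out = n_seg + 1L)
  trunk_d <- seq(root_diameter, root_diameter * trunk_tip_frac,
                 length.out = n_seg)

  nodes <- data.frame(id = seq_len(n_seg + 1L), x = root_xy[1],
                      y = root_xy[2], z = zs, boundary = "interior")
  nodes$boundary[1] <- if (kind == "DA") "pial_inflow" else "pial_outflow"
  vessels <- data.frame(id = seq_len(n_seg), from = seq_len(n_seg),
                        to = seq_len(n_seg) + 1L, diameter = trunk_d,
                        length = diff(zs), type = trunk_lab)
  if (pial_root) {
    vessels$type[1] <- if (kind == "DA") "PA" else "PV"
  }

  truncated <- FALSE
  .with_seed(seed, {
    nid <- n_seg + 1L
    vid <- n_seg
    for (lev in 2:(n_seg + 1L)) { # no side branch at the pial root
      for (b in seq_len(branches_per_level)) {
        parent_d <- trunk_d[lev - 1L]
        d <- parent_d / sqrt(2)
        az <- stats::runif(1, 0, 2 * pi)
        px <- nodes$x[lev]; py <- nodes$y[lev]; pz <- nodes$z[lev]
        prev <- lev
        for (s in seq_len(branch_segments)) {
          if (d < 2.5) { truncated <- TRUE; break }
          px <- px + cos(az) * segment_length * 0.6
          py <- py + sin(az) * segment_length * 0.6
          pz <- pz + segment_length * 0.25
          nid <- nid + 1L; vid <- vid + 1L
          nodes[nid, ] <- list(nid, px, py, pz, "interior")
          seg_len <- sqrt((segment_length * 0.6)^2 +
                            (segment_length * 0.25)^2)
          vessels[vid, ] <- list(vid, prev, nid, d, seg_len, side_lab)
          prev <- nid
          d <- d / sqrt(2)
        }
      }
    }
  })
  if (truncated) {
    warning("taper reached the 2.5 um floor; branch growth truncated")
  }
  nodes$z <- nodes$z * ct_scale
  vessels$length <- vessels$length * ct_scale
  net <- vasc_network(nodes, vessels)
  attr(net, "kind") <- kind
  net
}

#' Root positions of penetrating trees on a rhombic lattice
#'
#' @param nx,ny lattice counts.
#' @param spacing lattice constant in um (default 350).
#' @param origin lattice origin `(x, y)`.
#' @return data.frame with `x`, `y` and alternating `kind` (DA/AV).
#' @export
penetrating_lattice <- function(nx, ny, spacing = 350, origin = c(0, 0)) {
  g <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L))
  data.frame(
    x = origin[1] + g$i * spacing + (g$j %% 2) * spacing / 2,
    y = origin[2] + g$j * spacing * sqrt(3) / 2,
    kind = ifelse((g$i + g$j) %% 2 == 0, "DA", "AV"))
}

# shift all node coordinates of a network
.translate_network <- function(net, dx = 0, dy = 0, dz = 0) {
  net$nodes$x <- net$nodes$x + dx
  net$nodes$y <- net$nodes$y + dy
  net$nodes$z <- net$nodes$z + dz
  net
}

# merge networks, renumbering node and vessel ids; returns the merged
# network plus the id offsets used
.merge_networks <- function(parts) {
  n_off <- 0L; v_off <- 0L
  nodes <- list(); vessels <- list(); offsets <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    offsets[i] <- n_off
    nd <- p$nodes; vs <- p$vessels
    remap <- stats::setNames(n_off + seq_len(nrow(nd)), as.character(nd$id))
    nd$id <- n_off + seq_len(nrow(nd))
    vs$from <- remap[as.character(vs$from)]
    vs$to <- remap[as.character(vs$to)]
    vs$id <- v_off + seq_len(nrow(vs))
    n_off <- n_off + nrow(nd); v_off <- v_off + nrow(vs)
    nodes[[i]] <- nd; vessels[[i]] <- vs
  }
  list(net = vasc_network(do.call(rbind, nodes), do.call(rbind, vessels)),
       node_offsets = offsets)
}

#' Assemble an artificial microvascular network
#'
#' Places penetrating trees at the given lattice positions above a
#' capillary bed and joins every tree leaf to its nearest capillary node
#' by a new connecting capillary vessel (ties broken toward the lowest
#' node id). Roots are flagged pial inflow/outflow by tree kind.
#'
#' @param trees list of [generate_penetrating_tree()] networks.
#' @param bed a [generate_capillary_bed()] network.
#' @param positions data.frame with `x`, `y` per tree (e.g. from
#'   [penetrating_lattice()]); defaults to the trees' own root positions.
#' @param connect_radius maximum leaf-to-capillary distance in um
#'   (default 250); a leaf without a capillary node within it is an error.
#' @return a connected [vasc_network()].
#' @export
assemble_artificial_mvn <- function(trees, bed, positions = NULL,
                                    connect_radius = 250) {
  if (!is.null(positions)) {
    stopifnot(nrow(positions) == length(trees))
    for (i in seq_along(trees)) {
      r <- trees[[i]]$nodes[1, ]
      trees[[i]] <- .translate_network(trees[[i]],
                                       positions$x[i] - r$x,
                                       positions$y[i] - r$y)
    }
  }
  merged <- .merge_networks(c(trees, list(bed)))
  net <- merged$net
  bed_off <- merged$node_offsets[length(trees) + 1L]
  bed_ids <- net$nodes$id[net$nodes$id > bed_off]

  # leaves: degree-1 non-pial nodes of the tree parts
  deg <- table(factor(c(net$vessels$from, net$vessels$to),
                      levels = net$nodes$id))
  leaf <- net$nodes$id[deg[as.character(net$nodes$id)] == 1L &
                         net$nodes$boundary == "interior" &
                         net$nodes$id <= bed_off]
  bx <- net$nodes$x[match(bed_ids, net$nodes$id)]
  by <- net$nodes$y[match(bed_ids, net$nodes$id)]
  bz <- net$nodes$z[match(bed_ids, net$nodes$id)]
  new_v <- list()
  vid <- max(net$vessels$id)
  for (lf in leaf) {
    i <- match(lf, net$nodes$id)
    d2 <- (bx - net$nodes$x[i])^2 + (by - net$nodes$y[i])^2 +
      (bz - net$nodes$z[i])^2
    j <- which(d2 == min(d2))
    j <- j[which.min(bed_ids[j])] # tie: lowest node id
    if (sqrt(d2[j]) > connect_radius) {
      stop("assembly error: leaf node ", lf, " has no capillary node within ",
           connect_radius, " um")
    }
    # connecting vessel enters the bed: capillary caliber
    leaf_d <- net$vessels$diameter[net$vessels$from == lf |
                                     net$vessels$to == lf][1]
    vid <- vid + 1L
    new_v[[length(new_v) + 1L]] <-
      data.frame(id = vid, from = lf, to = bed_ids[j],
                 diameter = min(max(leaf_d / sqrt(2), 2.5), 9.0),
                 length = max(sqrt(d2[j]), 1), type = "C")
  }
  if (length(new_v)) net$vessels <- rbind(net$vessels, do.call(rbind, new_v))
  validate_network(net)
  g <- as_igraph(net)
  if (igraph::components(g)$no != 1L) {
    stop("assembly error: assembled network is not connected")
  }
  net
}
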