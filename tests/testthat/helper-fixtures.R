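# Fixture builders shared across the suite. All geometry in um.

# linear chain along +x: one node per joint, first node pial inflow,
# last node pial outflow
make_chain <- function(types, diameters = 8, lengths = 100,
                       depths = 0) {
  n <- length(types)
  diameters <- rep_len(diameters, n)
  lengths <- rep_len(lengths, n)
  depths <- rep_len(depths, n + 1)
  nodes <- data.frame(id = seq_len(n + 1),
                      x = c(0, cumsum(lengths)), y = 0, z = depths,
                      boundary = c("pial_inflow",
                                   rep("interior", n - 1), "pial_outflow"))
  vessels <- data.frame(id = seq_len(n), from = seq_len(n),
                        to = seq_len(n) + 1, diameter = diameters,
                        length = lengths, type = types)
  vasc_network(nodes, vessels)
}

# Y-split: inflow pipe from node 1 to node 2, two branches to outflow
# nodes 3 and 4
make_y <- function(parent_type = "DA", branch_types = c("C", "C"),
                   parent_d = 10, branch_d = c(6, 6),
                   parent_L = 100, branch_L = c(100, 100)) {
  nodes <- data.frame(id = 1:4,
                      x = c(0, 100, 200, 200), y = c(0, 0, 50, -50), z = 0,
                      boundary = c("pial_inflow", "interior",
                                   "pial_outflow", "pial_outflow"))
  vessels <- data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
                        diameter = c(parent_d, branch_d),
                        length = c(parent_L, branch_L),
                        type = c(parent_type, branch_types))
  vasc_network(nodes, vessels)
}

# connected random network on n nodes with extra cross links
make_random_network <- function(n = 50, extra = 25, seed = 1) {
  set.seed(seed)
  nodes <- data.frame(id = seq_len(n), x = runif(n, 0, 500),
                      y = runif(n, 0, 500), z = runif(n, 0, 500),
                      boundary = "interior")
  nodes$boundary[1] <- "pial_inflow"
  nodes$boundary[n] <- "pial_outflow"
  from <- 2:n
  to <- vapply(2:n, function(i) sample(i - 1, 1), integer(1)) # spanning tree
  from <- c(from, sample(n, extra, replace = TRUE))
  to <- c(to, sample(n, extra, replace = TRUE))
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  dup <- duplicated(paste(pmin(from, to), pmax(from, to)))
  from <- from[!dup]; to <- to[!dup]
  vessels <- data.frame(id = seq_along(from), from = from, to = to,
                        diameter = runif(length(from), 3, 12),
                        length = runif(length(from), 40, 150),
                        type = "C")
  vasc_network(nodes, vessels)
}

# dense reference solve of the same linear system (independent oracle)
dense_solve_oracle <- function(net, resistances, bcs) {
  nn <- nrow(net$nodes)
  idx <- setNames(seq_len(nn), as.character(net$nodes$id))
  A <- matrix(0, nn, nn)
  # conductances rescaled to order 1: a uniform factor leaves the
  # pressures unchanged but keeps the dense system well conditioned
  scale_w <- mean(1 / resistances)
  for (k in seq_len(nrow(net$vessels))) {
    i <- idx[[as.character(net$vessels$from[k])]]
    j <- idx[[as.character(net$vessels$to[k])]]
    w <- 1 / resistances[k] / scale_w
    A[i, i] <- A[i, i] + w; A[j, j] <- A[j, j] + w
    A[i, j] <- A[i, j] - w; A[j, i] <- A[j, i] - w
  }
  b <- numeric(nn)
  for (r in seq_len(nrow(bcs))) {
    i <- idx[[as.character(bcs$node_id[r])]]
    A[i, ] <- 0; A[i, i] <- 1
    b[i] <- bcs$pressure[r] * mvnflow::MMHG_TO_PA
  }
  setNames(solve(A, b) / mvnflow::MMHG_TO_PA, as.character(net$nodes$id))
}

# Build an rbc_trajectories object from hand-written paths.
#
# paths: list of data.frames with columns edge, type, length, time,
#   pressure (one row per traversed edge, in order).
# node_seqs: optional list of integer vectors (length nrow + 1) giving the
#   entry nodes of each edge plus the exit node; shared node ids across
#   paths produce shared capillary start/end points. Auto-generated
#   disjoint ids when NULL.
# node_z: optional named vector of node depths (um), default 0.
make_traj <- function(paths, node_seqs = NULL, node_z = NULL,
                      exit_times = NULL, exit_pressures = NULL) {
  if (is.null(node_seqs)) {
    nid <- 0L
    node_seqs <- lapply(paths, function(p) {
      s <- nid + seq_len(nrow(p) + 1L)
      nid <<- nid + nrow(p) + 1L
      s
    })
  }
  all_nodes <- sort(unique(unlist(node_seqs)))
  zval <- setNames(rep(0, length(all_nodes)), all_nodes)
  if (!is.null(node_z)) zval[names(node_z)] <- node_z
  nodes <- data.frame(id = all_nodes,
                      x = seq_along(all_nodes) * 10, y = 0,
                      z = unname(zval), boundary = "interior")
  evs <- list(); vessels <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    n <- nrow(p)
    ns <- node_seqs[[i]]
    vessels[[i]] <- data.frame(
      id = p$edge, from = ns[-(n + 1)], to = ns[-1],
      diameter = if ("diameter" %in% names(p)) p$diameter else 5,
      length = p$length, type = p$type)
    exit_t <- if (is.null(exit_times)) max(p$time) + 1 else exit_times[i]
    exit_p <- if (is.null(exit_pressures)) min(p$pressure) - 1 else
      exit_pressures[i]
    nrowz <- zval[as.character(ns)]
    evs[[i]] <- data.frame(
      rbc = i, edge = c(p$edge, 0L), node = ns,
      time = c(p$time, exit_t), pressure = c(p$pressure, exit_p),
      vessel_id = c(p$edge, NA), type = c(p$type, NA),
      diameter = c(if ("diameter" %in% names(p)) p$diameter else
        rep(5, n), NA),
      length = c(p$length, NA),
      z = unname(nrowz),
      x = nodes$x[match(ns, nodes$id)],
      y = 0)
  }
  vs <- do.call(rbind, vessels)
  vs <- vs[!duplicated(vs$id), ]
  net <- vasc_network(nodes, vs, validate = FALSE)
  structure(list(events = do.call(rbind, evs),
                 rbcs = data.frame(rbc = seq_along(paths), complete = TRUE),
                 network = net),
            class = "rbc_trajectories")
}

# shorthand: path data.frame from a type sequence
simple_path <- function(types, pressures, lengths = 100, times = NULL,
                        edge_ids = NULL) {
  n <- length(types)
  data.frame(
    edge = if (is.null(edge_ids)) seq_len(n) else edge_ids,
    type = types,
    length = rep_len(lengths, n),
    time = if (is.null(times)) seq_len(n) else times,
    pressure = pressures)
}
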