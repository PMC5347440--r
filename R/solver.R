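#' Boundary condition table
#'
#' @param node_id node ids carrying a pressure boundary condition.
#' @param pressure pressures in mmHg (recycled).
#' @param ht inflow tube hematocrit at the boundary (default 0.3, recycled).
#' @return data.frame with columns `node_id`, `pressure`, `ht`.
#' @export
boundary_conditions <- function(node_id, pressure, ht = 0.3) {
  data.frame(node_id = as.integer(node_id),
             pressure = rep_len(pressure, length(node_id)),
             ht = rep_len(ht, length(node_id)))
}

#' Solve the steady pressure and flow field on a network
#'
#' Poiseuille flow `q_ij = (p_i - p_j) / R_ij` with mass conservation at
#' every interior node yields a sparse symmetric positive-definite linear
#' system in the unknown node pressures, solved by a sparse Cholesky
#' factorization. Pressure boundary conditions are given in mmHg; flows are
#' returned in m^3/s with the convention that `q > 0` means flow from the
#' vessel's `from` node to its `to` node.
#'
#' @param net a [vasc_network()].
#' @param resistances per-vessel effective resistance in Pa s m^-3 (in the
#'   order of `net$vessels`); by default computed from the vessel geometry
#'   at zero hematocrit.
#' @param bcs a [boundary_conditions()] table; every connected component
#'   needs at least one entry.
#' @param chol_cache optional cached Cholesky factor from a previous solve
#'   on the same network and boundary set (see Details).
#' @details When solving repeatedly on a fixed topology (e.g. in the coupled
#'   RBC loop) pass `chol_cache = attr(prev, "chol")` from the previous
#'   solution so only a numeric factorization update is performed.
#' @return an object of class `pressure_solution`: list with `node_pressure`
#'   (mmHg, named by node id), `flow` (m^3/s per vessel), `velocity` (bulk
#'   velocity, mm/s per vessel) and the `resistances` used.
#' @export
solve_pressure_flow <- function(net, resistances = NULL, bcs,
                                chol_cache = NULL) {
  nodes <- net$nodes
  vessels <- net$vessels
  nv <- nrow(vessels)
  nn <- nrow(nodes)
  if (is.null(resistances)) {
    resistances <- effective_resistance(vessels$diameter, vessels$length, 0)
  }
  if (length(resistances) != nv || any(resistances <= 0)) {
    stop("solver error: need one positive resistance per vessel")
  }
  node_index <- stats::setNames(seq_len(nn), as.character(nodes$id))
  bi <- node_index[as.character(bcs$node_id)]
  if (anyNA(bi)) stop("solver error: boundary condition on unknown node")
  is_bc <- rep(FALSE, nn)
  is_bc[bi] <- TRUE
  p_bc <- numeric(nn)
  p_bc[bi] <- bcs$pressure * MMHG_TO_PA

  ia <- node_index[as.character(vessels$from)]
  ib <- node_index[as.character(vessels$to)]
  w <- 1 / resistances

  # check every component holds a BC (otherwise the reduced system is
  # singular); report the offending component. Skipped on cached solves:
  # the topology was validated when the factorization was built.
  if (is.null(chol_cache)) {
    g <- as_igraph(net)
    comp <- igraph::components(g)$membership[as.character(nodes$id)]
    bad <- setdiff(unique(comp), unique(comp[is_bc]))
    if (length(bad)) {
      ex <- nodes$id[comp == bad[1]][1]
      stop("solver error: connected component containing node ", ex,
           " has no pressure boundary condition")
    }
  }

  free <- which(!is_bc)
  free_index <- integer(nn)
  free_index[free] <- seq_along(free)

  # weighted graph Laplacian restricted to free nodes
  keep_ff <- !is_bc[ia] & !is_bc[ib]
  L <- Matrix::sparseMatrix(
    i = c(free_index[ia[keep_ff]], free_index[ib[keep_ff]], seq_along(free)),
    j = c(free_index[ib[keep_ff]], free_index[ia[keep_ff]], seq_along(free)),
    x = c(-w[keep_ff], -w[keep_ff], rep(0, length(free))),
    dims = c(length(free), length(free)), symmetric = FALSE)
  deg <- numeric(length(free))
  add_deg <- function(idx) {
    f <- free_index[idx[!is_bc[idx]]]
    tab <- rowsum(w[!is_bc[idx]], f)
    deg[as.integer(rownames(tab))] <<- deg[as.integer(rownames(tab))] + tab[, 1]
  }
  add_deg(ia); add_deg(ib)
  Matrix::diag(L) <- deg

  rhs <- numeric(length(free))
  # edges with one BC endpoint contribute w * p_bc to the free endpoint
  one_bc_a <- is_bc[ia] & !is_bc[ib]
  one_bc_b <- is_bc[ib] & !is_bc[ia]
  if (any(one_bc_a)) {
    tab <- rowsum(w[one_bc_a] * p_bc[ia[one_bc_a]], free_index[ib[one_bc_a]])
    rhs[as.integer(rownames(tab))] <- rhs[as.integer(rownames(tab))] + tab[, 1]
  }
  if (any(one_bc_b)) {
    tab <- rowsum(w[one_bc_b] * p_bc[ib[one_bc_b]], free_index[ia[one_bc_b]])
    rhs[as.integer(rownames(tab))] <- rhs[as.integer(rownames(tab))] + tab[, 1]
  }

  p <- p_bc
  if (length(free)) {
    Lc <- Matrix::forceSymmetric(L)
    if (!is.null(chol_cache)) {
      ch <- Matrix::update(chol_cache, Lc)
    } else {
      ch <- Matrix::Cholesky(Lc, LDL = FALSE, perm = TRUE)
    }
    p[free] <- as.numeric(Matrix::solve(ch, rhs))
  } else {
    ch <- NULL
  }

  q <- (p[ia] - p[ib]) * w
  area <- .lumen_area(vessels$diameter)
  sol <- structure(
    list(node_pressure = stats::setNames(p / MMHG_TO_PA,
                                         as.character(nodes$id)),
         flow = q,
         velocity = q / area * 1e3, # m/s -> mm/s
         resistances = resistances),
    class = "pressure_solution")
  attr(sol, "chol") <- ch
  sol
}

#' Mass-conservation residual of a solution
#'
#' @param net a [vasc_network()].
#' @param sol a [solve_pressure_flow()] result.
#' @return maximum node-balance residual over interior
#'   (non-boundary-condition) nodes, relative to the largest flow
#'   magnitude in the network (so dead-end stubs carrying only roundoff
#'   flow do not register as imbalances).
#' @export
conservation_residual <- function(net, sol, bcs) {
  v <- net$vessels
  infl <- rowsum(c(sol$flow, -sol$flow),
                 c(as.character(v$to), as.character(v$from)))
  net_in <- stats::setNames(infl[, 1], rownames(infl))
  interior <- setdiff(rownames(infl), as.character(bcs$node_id))
  if (!length(interior)) return(0)
  scale <- max(abs(sol$flow), .Machine$double.xmin)
  max(abs(net_in[interior])) / scale
}

#' Impact of RBCs on the flow field: per-vessel flow ratio
#'
#' Compares the flow field of an RBC-laden solve with a pure-plasma solve
#' on the same network and boundary conditions. The flow ratio of a vessel
#' is `gamma = q_plasma / q_blood` (variant `"unit"`: plasma solve at unit
#' relative viscosity) or `q_plasma / (mu_vitro q_blood)` with the plasma
#' solve at a fixed-hematocrit viscosity (variant `"fixed_ht"`). A ratio of
#' 1 everywhere would mean RBCs raise resistance uniformly without
#' redistributing flow.
#'
#' @param net a [vasc_network()].
#' @param bcs a [boundary_conditions()] table.
#' @param blood_sol a converged [solve_pressure_flow()] result with
#'   hematocrit-dependent resistances.
#' @param variant `"unit"` (default) or `"fixed_ht"`.
#' @param fixed_ht hematocrit of the reference solve for `"fixed_ht"`.
#' @return list with per-vessel `gamma`, logical `capillary`, and a
#'   `summary` data.frame per vessel group (fraction of vessels with
#'   `|gamma - 1| < 0.05`, median relative difference, number of
#'   zero-blood-flow vessels reported as missing).
#' @export
flow_ratio <- function(net, bcs, blood_sol, variant = c("unit", "fixed_ht"),
                       fixed_ht = 0.3) {
  variant <- match.arg(variant)
  v <- net$vessels
  if (variant == "unit") {
    r_ref <- effective_resistance(v$diameter, v$length, 0)
    plasma <- solve_pressure_flow(net, r_ref, bcs)
    gamma <- plasma$flow / blood_sol$flow
  } else {
    r_ref <- effective_resistance(v$diameter, v$length, fixed_ht)
    plasma <- solve_pressure_flow(net, r_ref, bcs)
    mu <- blood_sol$resistances / effective_resistance(v$diameter, v$length, 0)
    gamma <- plasma$flow / (mu * blood_sol$flow)
  }
  zero <- blood_sol$flow == 0
  gamma[zero] <- NA_real_
  cap <- v$type == "C"
  grp_summary <- function(sel) {
    g <- gamma[sel]
    data.frame(n = sum(sel),
               n_missing = sum(is.na(g)),
               frac_within_5pct = mean(abs(g - 1) < 0.05, na.rm = TRUE),
               median_rel_diff = stats::median(abs(g - 1), na.rm = TRUE))
  }
  summary <- rbind(capillary = grp_summary(cap),
                   non_capillary = grp_summary(!cap))
  list(gamma = gamma, capillary = cap, summary = summary)
}
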