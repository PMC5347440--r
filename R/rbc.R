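#' Simulation configuration for discrete RBC tracking
#'
#' @param dt_coverage quantile coverage of the time-step criterion: the
#'   fixed time step is chosen so that `dt <= L/v` holds for at least this
#'   fraction of vessels (default 0.998).
#' @param warmup_turnovers turn-over times simulated before RBC paths are
#'   recorded (default 15).
#' @param record_turnovers length of the recording window in turn-over
#'   times (default 1).
#' @param drain_turnovers extra turn-over times allowed for recorded RBCs
#'   to finish their paths after the recording window closes (default 5).
#' @param rbc_volume_fl RBC volume in femtolitres (default 49, mouse).
#' @param seed RNG seed for bifurcation sampling and injection phases.
#' @param max_steps hard cap on the number of time steps (default Inf).
#' @param phase_sep_coef coefficients `(a, b, x0)` of the empirical
#'   phase-separation law at arteriolar bifurcations (defaults
#'   `c(-13.29, 6.98, 0.964)` from the classical in-vitro parameterization).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(dt_coverage = 0.998, warmup_turnovers = 15,
                              record_turnovers = 1, drain_turnovers = 5,
                              rbc_volume_fl = 49, seed = 1L,
                              max_steps = Inf,
                              phase_sep_coef = c(a = -13.29, b = 6.98,
                                                 x0 = 0.964)) {
  stopifnot(dt_coverage > 0.9, dt_coverage <= 1, warmup_turnovers >= 0,
            record_turnovers > 0, rbc_volume_fl > 0)
  structure(list(dt_coverage = dt_coverage,
                 warmup_turnovers = warmup_turnovers,
                 record_turnovers = record_turnovers,
                 drain_turnovers = drain_turnovers,
                 rbc_volume_fl = rbc_volume_fl, seed = seed,
                 max_steps = max_steps, phase_sep_coef = phase_sep_coef),
            class = "simulation_config")
}

#' Fixed time step from the vessel transit-time criterion
#'
#' The constant time step is the `(1 - coverage)` empirical quantile of the
#' vessel transit times `L_ij / |v_ij|`, so that `dt <= L/v` for at least
#' `coverage` of all vessels (all of them for `coverage = 1`).
#'
#' @param net a [vasc_network()].
#' @param velocities signed bulk velocities in mm/s (e.g. from an initial
#'   pure-plasma [solve_pressure_flow()]).
#' @param coverage required fraction of vessels satisfying the criterion.
#' @return time step in seconds.
#' @export
select_timestep <- function(net, velocities, coverage = 0.998) {
  L <- net$vessels$length
  if (any(L <= 0)) stop("config error: zero-length vessel")
  ratio <- L / (abs(velocities) * 1e3) # um / (um/s)
  ratio <- ratio[is.finite(ratio)]
  if (!length(ratio)) stop("config error: no flowing vessel")
  k <- max(1L, floor(length(ratio) * (1 - coverage)))
  sort(ratio)[k]
}

#' Divergent-bifurcation branch choice for a capillary RBC
#'
#' At capillary divergent bifurcations the RBC follows the path of the
#' largest pressure force, equivalent to the outgoing branch with the
#' largest bulk flow velocity. The commonly used alternative picks the
#' branch with the largest flow rate; both are evaluated and an agreement
#' indicator returned. Ties break toward the lowest edge id.
#'
#' @param edge_ids outgoing edge ids (length >= 2).
#' @param velocities outgoing bulk velocity magnitudes (mm/s).
#' @param flows outgoing flow-rate magnitudes (m^3/s).
#' @return list with `velocity_rule` (chosen edge id), `flow_rule`, and
#'   logical `agree`.
#' @export
branch_choice_divergent <- function(edge_ids, velocities, flows) {
  stopifnot(length(edge_ids) >= 2)
  if (all(velocities == 0)) {
    return(list(velocity_rule = NA_integer_, flow_rule = NA_integer_,
                agree = NA, stalled = TRUE))
  }
  ord_v <- order(-velocities, edge_ids)
  ord_q <- order(-flows, edge_ids)
  list(velocity_rule = edge_ids[ord_v[1]], flow_rule = edge_ids[ord_q[1]],
       agree = edge_ids[ord_v[1]] == edge_ids[ord_q[1]], stalled = FALSE)
}

#' Phase-separation law at arteriolar divergent bifurcations
#'
#' Empirical logit law for the RBC flux fraction entering a daughter
#' branch as a function of its blood flow fraction. With
#' `x0 = 0.964 (1 - hd) / dp` the RBC fraction is 0 below the flow
#' fraction `x0`, 1 above `1 - x0`, and in between
#' `logit(f) = A + B logit((x - x0)/(1 - 2 x0))` with
#' `B = 1 + 6.98 (1 - hd)/dp` and an asymmetry term
#' `A = -13.29 ((d1^2/d2^2 - 1)/(d1^2/d2^2 + 1)) (1 - hd)/dp` from the
#' daughter diameter ratio. For two daughters the fractions are exactly
#' complementary.
#'
#' @param flow_fraction blood flow fraction of the daughter under
#'   consideration, in `[0, 1]`. Vectorized.
#' @param parent_d,daughter_d,other_d diameters (um) of the parent, this
#'   daughter and the other daughter.
#' @param parent_hd discharge hematocrit of the parent vessel.
#' @param coef coefficients `(a, b, x0)`; see [simulation_config()].
#' @return RBC flux fraction(s) in `[0, 1]`.
#' @export
phase_separation_split <- function(flow_fraction, parent_d, daughter_d,
                                   other_d, parent_hd,
                                   coef = c(a = -13.29, b = 6.98,
                                            x0 = 0.964)) {
  if (any(parent_d <= 0)) stop("domain error: nonpositive parent diameter")
  if (any(flow_fraction < -1e-12 | flow_fraction > 1 + 1e-12)) {
    stop("domain error: flow fraction outside [0, 1]")
  }
  x <- pmin(pmax(flow_fraction, 0), 1)
  scale <- (1 - parent_hd) / parent_d
  x0 <- coef[["x0"]] * scale
  rat <- (daughter_d / other_d)^2
  A <- coef[["a"]] * ((rat - 1) / (rat + 1)) * scale
  B <- 1 + coef[["b"]] * scale
  inner <- (x - x0) / (1 - 2 * x0)
  inner <- pmin(pmax(inner, 1e-15), 1 - 1e-15)
  lg <- A + B * log(inner / (1 - inner))
  f <- 1 / (1 + exp(-lg))
  f[x <= x0] <- 0
  f[x >= 1 - x0] <- 1
  unname(f)
}

# ---- internal simulation state ---------------------------------------

# Build the static part of the simulation state.
.sim_init <- function(net, bcs, config) {
  v <- net$vessels
  nn <- nrow(net$nodes)
  node_index <- stats::setNames(seq_len(nn), as.character(net$nodes$id))
  area <- .lumen_area(v$diameter) # m^2
  rbc_vol <- config$rbc_volume_fl * 1e-18 # fL -> m^3
  eff_len <- pmin(rbc_vol / area * 1e6, v$length) # um
  v_from <- unname(node_index[as.character(v$from)])
  v_to <- unname(node_index[as.character(v$to)])
  bc_node <- unname(node_index[as.character(bcs$node_id)])
  bc_adj <- lapply(bc_node, function(nd) {
    which(v_from == nd | v_to == nd)
  })
  params0 <- rheology_params(warn_small_d = FALSE)
  bc_hd <- lapply(seq_along(bc_node), function(b) {
    if (bcs$ht[b] <= 0) return(rep(0, length(bc_adj[[b]])))
    discharge_hematocrit(bcs$ht[b], v$diameter[bc_adj[[b]]], params0)
  })
  list(net = net, bcs = bcs, config = config,
       nv = nrow(v), nn = nn,
       bc_node = bc_node, bc_adj = bc_adj, bc_hd = bc_hd,
       v_from = v_from,
       v_to = v_to,
       v_d = v$diameter, v_L = v$length, v_type = v$type,
       v_area = area, v_vol = area * v$length * UM_TO_M,
       eff_len = eff_len, rbc_vol = rbc_vol,
       node_id = net$nodes$id,
       node_is_bc = seq_len(nn) %in% bc_node,
       arteriolar_edge = v$type %in% c("PA", "DA", "A"),
       # dynamic fields
       rbc_edge = integer(0), rbc_pos = numeric(0), rbc_id = integer(0),
       rbc_tracked = logical(0),
       next_rbc_id = 1L, clock = 0,
       n_injected = 0L, n_exited = 0L,
       inj_acc = rep(NA_real_, nrow(v)), log = list(), stalls = 0L,
       rule_agree = c(agree = 0L, total = 0L))
}

.edge_ht <- function(st) {
  cnt <- tabulate(st$rbc_edge, nbins = st$nv)
  pmin(cnt * st$rbc_vol / st$v_vol, 0.99)
}

# per-node outgoing-edge summary for the current flow field; returns a
# list of vectors indexed by node
.node_outgoing <- function(st, flow, vel) {
  out_node <- st$v_from
  neg <- flow < 0
  out_node[neg] <- st$v_to[neg]
  keep <- flow != 0
  e <- which(keep)
  n <- out_node[keep]
  absq <- abs(flow[keep]); absv <- abs(vel[keep])
  n_out <- tabulate(n, nbins = st$nn)
  ord <- order(n, -absv, e)
  first <- !duplicated(n[ord])
  out1v <- integer(st$nn); out1v[n[ord][first]] <- e[ord][first]
  ordq <- order(n, -absq, e)
  firstq <- !duplicated(n[ordq])
  out1q <- integer(st$nn); out1q[n[ordq][firstq]] <- e[ordq][firstq]
  nq <- n[ordq]; eq <- e[ordq]
  # second-largest flow daughter per node
  out2q <- integer(st$nn)
  m <- length(nq)
  if (m) {
    new_grp <- c(TRUE, nq[-1] != nq[-m])
    idx <- seq_len(m)
    rank0 <- idx - cummax(idx * new_grp)
    sec <- rank0 == 1L
    out2q[nq[sec]] <- eq[sec]
  }
  list(n_out = n_out, out1v = out1v, out1q = out1q, out2q = out2q)
}

# entry coordinate (um) and direction for an RBC entering each edge under
# the current flow field: +1 means entry at 0 moving toward L
.edge_dir <- function(st, flow) ifelse(flow >= 0, 1, -1)

# minimum admission gap at the entry of every edge: distance from the
# entry point to the nearest resident RBC (Inf when empty)
.entry_gap <- function(st, dir, alive = NULL) {
  gap <- rep(Inf, st$nv)
  edge <- st$rbc_edge; pos <- st$rbc_pos
  if (!is.null(alive)) { edge <- edge[alive]; pos <- pos[alive] }
  if (!length(edge)) return(gap)
  s <- pos
  neg <- dir[edge] < 0
  if (any(neg)) s[neg] <- st$v_L[edge[neg]] - pos[neg]
  o <- order(edge, s)
  f <- !duplicated(edge[o])
  gap[edge[o][f]] <- s[o][f]
  gap
}

# enforce the no-overlap spacing within every edge, preserving order in
# the direction of travel (leading cells push back trailing ones)
.enforce_spacing <- function(st, dir) {
  if (length(st$rbc_edge) < 2L) return(st)
  e <- st$rbc_edge
  # work in entry-anchored coordinates: larger s = further along the edge
  s <- st$rbc_pos
  neg <- dir[e] < 0
  if (any(neg)) s[neg] <- st$v_L[e[neg]] - st$rbc_pos[neg]
  ord <- order(e, -s)
  ee <- e[ord]; ss <- s[ord]
  n <- length(ee)
  new_grp <- c(TRUE, ee[-1] != ee[-n])
  idx <- seq_len(n)
  k <- idx - cummax(idx * new_grp) # 0-based rank within each edge group
  elen <- st$eff_len[ee]
  t0 <- ss + k * elen
  # grouped cummin via a per-group offset large enough to dominate t0
  base <- cumsum(new_grp) * 1e5
  tmin <- cummin(t0 - base) + base
  s_new <- tmin - k * elen
  changed <- s_new < ss
  if (any(changed)) {
    s[ord] <- s_new
    pos <- s
    if (any(neg)) pos[neg] <- st$v_L[e[neg]] - s[neg]
    st$rbc_pos <- pos
  }
  st
}

#' Create an RBC simulation state
#'
#' Builds the mutable state of a discrete RBC simulation: the static
#' vessel arrays, the RBC coordinate vectors (initially empty), the clock
#' and the conservation counters. Mostly useful for testing the stepping
#' kernel in isolation; [run_simulation()] drives the full coupled loop.
#'
#' @param net a labeled [vasc_network()].
#' @param bcs a [boundary_conditions()] table.
#' @param config a [simulation_config()].
#' @return an object of class `sim_state`.
#' @export
sim_state <- function(net, bcs, config = simulation_config()) {
  st <- .sim_init(net, bcs, config)
  class(st) <- "sim_state"
  st
}

#' Place RBCs on the network by hand
#'
#' @param st a [sim_state()].
#' @param edges vessel row indices (1-based, in `net$vessels` order).
#' @param pos linear coordinates along each edge, um from the `from` node.
#' @param tracked log the paths of these RBCs (default TRUE).
#' @return the updated state.
#' @export
add_rbcs <- function(st, edges, pos, tracked = TRUE) {
  n <- length(edges)
  stopifnot(length(pos) == n, all(edges >= 1), all(edges <= st$nv))
  if (any(pos < 0) || any(pos > st$v_L[edges])) {
    stop("RBC coordinate outside [0, L]")
  }
  ids <- st$next_rbc_id - 1L + seq_len(n)
  st$rbc_edge <- c(st$rbc_edge, as.integer(edges))
  st$rbc_pos <- c(st$rbc_pos, pos)
  st$rbc_id <- c(st$rbc_id, ids)
  st$rbc_tracked <- c(st$rbc_tracked, rep(isTRUE(tracked), n))
  st$next_rbc_id <- st$next_rbc_id + n
  st$n_injected <- st$n_injected + n
  st
}

# log entry events (already filtered to tracked RBCs)
.log_events <- function(st, id, edge, node, time, pressure) {
  if (!length(id)) return(st)
  st$log[[length(st$log) + 1L]] <-
    cbind(id = id, edge = edge, node = node, time = time,
          pressure = pressure)
  st
}

#' Advance all RBCs over one time step
#'
#' Each RBC advances by `v_RBC * dt`, where `v_RBC = v_bulk * hd/ht` of its
#' edge (floored at the bulk velocity; Fahraeus). RBCs reaching a node
#' within the step cross it -- possibly several nodes per step -- applying
#' the bifurcation rules: largest bulk velocity at capillary divergent
#' bifurcations, the phase-separation law (sampled) at arteriolar ones.
#' An RBC cannot overlap the RBC ahead (minimum centre spacing = RBC
#' volume / lumen cross-section, capped at the vessel length); at
#' convergent nodes an RBC is held at the node while the downstream vessel
#' lacks space and proceeds as soon as it fits. RBCs reaching a boundary
#' node with no outgoing vessel exit and are recorded.
#'
#' @param st a [sim_state()].
#' @param sol the current [solve_pressure_flow()] solution.
#' @param dt time step in seconds.
#' @param ht per-edge tube hematocrit (defaults to the state occupancy).
#' @param max_pass maximum node-crossing sweeps per step.
#' @return the updated state (clock advanced by `dt`).
#' @export
advance_rbcs <- function(st, sol, dt, ht = NULL, max_pass = 12L) {
  if (is.null(ht)) ht <- .edge_ht(st)
  flow <- sol$flow
  vel <- sol$velocity # mm/s signed
  hd <- discharge_hematocrit(ht, st$v_d,
                             rheology_params(warn_small_d = FALSE))
  fac <- ifelse(ht > 0, pmax(hd / ht, 1), 1)
  v_um <- vel * 1e3 * fac # um/s signed (from -> to positive)
  dir <- .edge_dir(st, flow)
  nodes_p <- sol$node_pressure # mmHg, named by node id

  n <- length(st$rbc_edge)
  gap <- NULL
  if (n) {
    trem <- rep(dt, n)
    alive <- rep(TRUE, n)
    pass <- 0L
    out <- .node_outgoing(st, flow, vel)
    while (pass < max_pass && any(trem > 0 & alive)) {
      pass <- pass + 1L
      act <- which(trem > 0 & alive)
      e <- st$rbc_edge[act]
      st$rbc_pos[act] <- st$rbc_pos[act] + v_um[e] * trem[act]
      spd <- abs(v_um[e])
      over_hi <- st$rbc_pos[act] > st$v_L[e] & v_um[e] > 0
      over_lo <- st$rbc_pos[act] < 0 & v_um[e] < 0
      new_trem <- numeric(length(act))
      new_trem[over_hi] <- (st$rbc_pos[act][over_hi] -
                              st$v_L[e][over_hi]) / spd[over_hi]
      new_trem[over_lo] <- -st$rbc_pos[act][over_lo] / spd[over_lo]
      st$rbc_pos[act][over_hi] <- st$v_L[e][over_hi]
      st$rbc_pos[act][over_lo] <- 0
      trem[act] <- pmin(new_trem, dt)
      cross <- act[over_hi | over_lo]
      if (!length(cross)) break
      ce <- st$rbc_edge[cross]
      cnode <- ifelse(v_um[ce] > 0, st$v_to[ce], st$v_from[ce])
      n_out <- out$n_out[cnode]

      # exits (boundary-condition nodes) and stalls (dead ends)
      done <- n_out == 0L
      if (any(done)) {
        is_exit <- st$node_is_bc[cnode[done]]
        exit_idx <- cross[done][is_exit]
        if (length(exit_idx)) {
          tr <- st$rbc_tracked[exit_idx]
          st <- .log_events(st, st$rbc_id[exit_idx][tr], 0L,
                            st$node_id[cnode[done][is_exit]][tr],
                            st$clock + dt - trem[exit_idx][tr],
                            nodes_p[cnode[done][is_exit]][tr])
          st$n_exited <- st$n_exited + length(exit_idx)
          alive[exit_idx] <- FALSE
        }
        st$stalls <- st$stalls + sum(!is_exit)
        trem[cross[done]] <- 0
        keep <- !done
        cross <- cross[keep]; ce <- ce[keep]; cnode <- cnode[keep]
        n_out <- n_out[keep]
        if (!length(cross)) next
      }

      # branch choice: largest-velocity rule by default, phase separation
      # at arteriolar divergent bifurcations
      target <- out$out1v[cnode]
      multi <- n_out >= 2L
      if (any(multi)) {
        capm <- multi & !st$arteriolar_edge[ce]
        if (any(capm)) {
          agree <- out$out1v[cnode[capm]] == out$out1q[cnode[capm]]
          st$rule_agree <- st$rule_agree +
            c(agree = sum(agree), total = sum(capm))
        }
        artm <- which(multi & st$arteriolar_edge[ce] & n_out == 2L)
        if (length(artm)) {
          nd <- cnode[artm]
          e1 <- out$out1q[nd]; e2 <- out$out2q[nd]
          q1 <- abs(flow[e1]); q2 <- abs(flow[e2])
          f1 <- phase_separation_split(
            q1 / (q1 + q2), st$v_d[ce[artm]], st$v_d[e1], st$v_d[e2],
            hd[ce[artm]], st$config$phase_sep_coef)
          pick1 <- stats::runif(length(artm)) < f1
          target[artm] <- ifelse(pick1, e1, e2)
        }
      }

      # admission: all of a step's entrants into an edge are placed at
      # once, earliest arrival furthest along, each at its projected
      # position v * t_remaining, clamped by the no-overlap spacing
      # behind the nearest resident cell (the gap vector, computed once
      # per step and tightened on every admission; cells leaving an edge
      # only widen the true gap, so the stale value is conservative).
      # Entrants that do not fit wait at the node for the next step.
      if (is.null(gap)) gap <- .entry_gap(st, dir, alive)
      ordc <- order(target, -trem[cross])
      tgt_o <- target[ordc]
      cand <- cross[ordc]
      m <- length(cand)
      grp_new <- c(TRUE, tgt_o[-1] != tgt_o[-m])
      idx <- seq_len(m)
      rank0 <- idx - cummax(idx * grp_new) # 0-based within each target
      spd_t <- abs(v_um[tgt_o])
      eff_t <- st$eff_len[tgt_o]
      s_allow <- pmin(spd_t * trem[cand],
                      gap[tgt_o] - (rank0 + 1) * eff_t,
                      st$v_L[tgt_o])
      ok <- s_allow >= 0
      adm <- cand[ok]
      if (length(adm)) {
        tgt <- tgt_o[ok]
        s_adm <- s_allow[ok]
        st$rbc_edge[adm] <- tgt
        pos_adm <- s_adm
        tneg <- dir[tgt] < 0
        pos_adm[tneg] <- st$v_L[tgt[tneg]] - s_adm[tneg]
        st$rbc_pos[adm] <- pos_adm
        # tighten the gap to the least-advanced entrant per edge
        mins <- tapply(s_adm, tgt, min)
        gap[as.integer(names(mins))] <- pmin(gap[as.integer(names(mins))],
                                             unname(mins))
        tr <- st$rbc_tracked[adm]
        entry_node <- ifelse(dir[tgt] > 0, st$v_from[tgt], st$v_to[tgt])
        st <- .log_events(st, st$rbc_id[adm][tr], tgt[tr],
                          st$node_id[entry_node][tr],
                          st$clock + dt - trem[adm][tr],
                          nodes_p[entry_node][tr])
        # cells that traverse the whole target vessel within the step
        # keep their leftover time and cross again on the next sweep
        full_len <- s_adm >= st$v_L[tgt] - 1e-12
        spd_adm <- spd_t[ok]
        trem[adm] <- ifelse(full_len & spd_adm > 0,
                            pmax(trem[adm] - st$v_L[tgt] / spd_adm, 0), 0)
      }
      # entrants that did not fit wait at the node until the next step
      trem[cand[!ok]] <- 0
    }
    if (any(!alive)) {
      st$rbc_edge <- st$rbc_edge[alive]
      st$rbc_pos <- st$rbc_pos[alive]
      st$rbc_id <- st$rbc_id[alive]
      st$rbc_tracked <- st$rbc_tracked[alive]
    }
    st <- .enforce_spacing(st, dir)
  }

  st <- .inject_rbcs(st, sol, dt, v_um, dir, nodes_p, gap)
  st$clock <- st$clock + dt
  st
}

# injection at inflow edges: maintains the boundary tube hematocrit in
# expectation by scheduling hd * q / V_rbc cells per second; the fractional
# accumulator per edge is phase-seeded uniformly on first activation
.inject_rbcs <- function(st, sol, dt, v_um, dir, nodes_p, gap = NULL) {
  track_now <- !is.null(st$track_window) &&
    st$clock >= st$track_window[1] && st$clock < st$track_window[2]
  if (is.null(gap)) gap <- .entry_gap(st, dir)
  add_edge <- integer(0); add_pos <- numeric(0)
  add_id <- integer(0); add_node <- integer(0); add_t <- numeric(0)
  add_p <- numeric(0)
  for (b in seq_along(st$bc_node)) {
    eds <- st$bc_adj[[b]]
    if (!length(eds)) next
    nd <- st$bc_node[b]
    hds <- st$bc_hd[[b]]
    for (k in seq_along(eds)) {
      ed <- eds[k]
      q <- sol$flow[ed]
      outgoing <- (st$v_from[ed] == nd && q > 0) ||
        (st$v_to[ed] == nd && q < 0)
      if (!outgoing || hds[k] <= 0) next
      rate <- hds[k] * abs(q) / st$rbc_vol
      if (is.na(st$inj_acc[ed])) st$inj_acc[ed] <- stats::runif(1)
      acc <- st$inj_acc[ed] + rate * dt
      kk <- floor(acc)
      st$inj_acc[ed] <- acc - kk
      if (kk < 1) next
      spd <- abs(v_um[ed])
      g <- gap[ed]
      placed <- 0L
      for (j in seq_len(kk)) {
        s <- spd * dt * (kk - j + 0.5) / kk
        s <- min(s, g - st$eff_len[ed])
        if (s < 0) break # no space: defer to the next step
        id <- st$next_rbc_id
        st$next_rbc_id <- st$next_rbc_id + 1L
        add_edge <- c(add_edge, ed)
        add_pos <- c(add_pos, if (dir[ed] > 0) s else st$v_L[ed] - s)
        add_id <- c(add_id, id)
        add_node <- c(add_node, nd)
        add_t <- c(add_t, st$clock + dt - s / max(spd, 1e-12))
        add_p <- c(add_p, nodes_p[nd])
        g <- s
        placed <- placed + 1L
      }
      gap[ed] <- g
      if (placed < kk) st$inj_acc[ed] <- st$inj_acc[ed] + (kk - placed)
    }
  }
  if (length(add_edge)) {
    st$rbc_edge <- c(st$rbc_edge, add_edge)
    st$rbc_pos <- c(st$rbc_pos, add_pos)
    st$rbc_id <- c(st$rbc_id, add_id)
    st$rbc_tracked <- c(st$rbc_tracked, rep(track_now, length(add_edge)))
    st$n_injected <- st$n_injected + length(add_edge)
    if (track_now) {
      st <- .log_events(st, add_id, add_edge, st$node_id[add_node],
                        add_t, add_p)
    }
  }
  st
}

#' Run a coupled RBC-tracking blood flow simulation
#'
#' Alternates the steady pressure/flow solve (with per-edge resistances at
#' the instantaneous tube hematocrit) and the RBC propagation step. The
#' time step is fixed from the initial pure-plasma solve via
#' [select_timestep()]. The turn-over time is the total vascular volume
#' over the total boundary inflow; RBC paths are recorded for RBCs
#' injected after `warmup_turnovers` turn-over times during a window of
#' `record_turnovers`, and the run continues up to `drain_turnovers`
#' longer so recorded RBCs can finish their paths.
#'
#' @param net a labeled [vasc_network()].
#' @param bcs a [boundary_conditions()] table with inflow hematocrits.
#' @param config a [simulation_config()].
#' @param progress print a progress line every `progress` steps (0 = off).
#' @return an object of class `rbc_simulation`: list with `trajectories`
#'   (an `rbc_trajectories` object, see [build_trajectories()]), `dt`,
#'   `turnover_time` (s), `audit` (exact RBC conservation counters),
#'   `rule_agreement` (capillary bifurcation-rule agreement fraction),
#'   `timestep_coverage`, the final `solution` and `state`.
#' @export
run_simulation <- function(net, bcs, config = simulation_config(),
                           progress = 0) {
  params0 <- rheology_params(warn_small_d = FALSE)
  v <- net$vessels
  res0 <- effective_resistance(v$diameter, v$length, 0, params0)
  sol0 <- solve_pressure_flow(net, res0, bcs)
  dt <- select_timestep(net, sol0$velocity, config$dt_coverage)
  ratio <- v$length / pmax(abs(sol0$velocity) * 1e3, 1e-12)
  coverage <- mean(dt <= ratio)

  # total boundary inflow of the plasma solve
  node_index <- stats::setNames(seq_len(nrow(net$nodes)),
                                as.character(net$nodes$id))
  bcn <- unname(node_index[as.character(bcs$node_id)])
  vf <- unname(node_index[as.character(v$from)])
  vt <- unname(node_index[as.character(v$to)])
  net_out <- vapply(bcn, function(nd) {
    sum(sol0$flow[vf == nd]) - sum(sol0$flow[vt == nd])
  }, numeric(1))
  total_in <- sum(net_out[net_out > 0])
  if (total_in <= 0) stop("solver error: no net inflow under these BCs")
  turnover <- network_volume(net) / total_in

  st <- sim_state(net, bcs, config)
  t_warm <- config$warmup_turnovers * turnover
  t_rec <- t_warm + config$record_turnovers * turnover
  t_max <- t_rec + config$drain_turnovers * turnover
  st$track_window <- c(t_warm, t_rec)

  ch <- NULL
  step <- 0L
  .with_seed(config$seed, {
    repeat {
      ht <- .edge_ht(st)
      res <- effective_resistance(st$v_d, st$v_L, ht, params0)
      sol <- solve_pressure_flow(net, res, bcs, chol_cache = ch)
      ch <- attr(sol, "chol")
      st <- advance_rbcs(st, sol, dt, ht)
      step <- step + 1L
      if (progress > 0 && step %% progress == 0L) {
        message(sprintf("step %d  t=%.3fs  rbc=%d  tracked=%d",
                        step, st$clock, length(st$rbc_id),
                        sum(st$rbc_tracked)))
      }
      if (step >= config$max_steps) break
      if (st$clock >= t_max) break
      if (st$clock >= t_rec && !any(st$rbc_tracked)) break
    }
  })
  audit <- c(injected = st$n_injected, exited = st$n_exited,
             resident = length(st$rbc_id))
  traj <- build_trajectories(st, net)
  structure(list(trajectories = traj, dt = dt, turnover_time = turnover,
                 steps = step, audit = audit,
                 conservation_ok =
                   audit[["injected"]] ==
                   audit[["exited"]] + audit[["resident"]],
                 rule_agreement = if (st$rule_agree[["total"]] > 0) {
                   st$rule_agree[["agree"]] / st$rule_agree[["total"]]
                 } else NA_real_,
                 timestep_coverage = coverage,
                 solution = sol0, state = st),
            class = "rbc_simulation")
}

#' Assemble recorded RBC paths into trajectories
#'
#' @param st a [sim_state()] after stepping.
#' @param net the simulated [vasc_network()].
#' @return an object of class `rbc_trajectories`: list with `events` (one
#'   row per edge entry: `rbc`, `edge` (vessel id, 0 for the final exit),
#'   `node` (entry node id), `time` (s), `pressure` (mmHg at the entry
#'   node), plus joined vessel `type`, `diameter`, `length` and entry-node
#'   depth `z`), `rbcs` (per-RBC summary with `complete` flag) and the
#'   `network`.
#' @export
build_trajectories <- function(st, net) {
  if (!length(st$log)) {
    ev <- data.frame(rbc = integer(), edge = integer(), node = integer(),
                     time = numeric(), pressure = numeric())
  } else {
    ev <- as.data.frame(do.call(rbind, st$log))
    names(ev) <- c("rbc", "edge", "node", "time", "pressure")
  }
  ev <- ev[order(ev$rbc, ev$time), , drop = FALSE]
  vrow <- match(ev$edge, seq_len(nrow(net$vessels)))
  ev$vessel_id <- net$vessels$id[vrow]
  ev$type <- net$vessels$type[vrow]
  ev$diameter <- net$vessels$diameter[vrow]
  ev$length <- net$vessels$length[vrow]
  nrow_ <- match(ev$node, net$nodes$id)
  ev$z <- net$nodes$z[nrow_]
  ev$x <- net$nodes$x[nrow_]
  ev$y <- net$nodes$y[nrow_]
  ids <- unique(ev$rbc)
  complete <- vapply(split(ev$edge, ev$rbc),
                     function(e) any(e == 0L), logical(1))
  rbcs <- data.frame(rbc = as.integer(names(complete)),
                     complete = unname(complete))
  structure(list(events = ev, rbcs = rbcs, network = net),
            class = "rbc_trajectories")
}
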