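#' Analysis layer configuration
#'
#' Cortical depth is divided into equally thick analysis layers (ALs);
#' the default five 200-um slices cover the upper 1000 um. Depth bins are
#' half-open `[lower, upper)`, so a capillary start point at exactly
#' 200 um belongs to AL 2.
#'
#' @param thickness layer thickness in um (default 200).
#' @param max_depth maximum analyzed depth in um (default 1000); must be a
#'   multiple of `thickness`.
#' @return an object of class `analysis_layers`.
#' @export
analysis_layers <- function(thickness = 200, max_depth = 1000) {
  if (max_depth %% thickness != 0) {
    stop("layer thickness must divide the maximum depth")
  }
  structure(list(thickness = thickness, max_depth = max_depth,
                 n = max_depth %/% thickness),
            class = "analysis_layers")
}

#' @rdname analysis_layers
#' @param depth depth(s) in um.
#' @param layers an `analysis_layers` object.
#' @return [layer_of()]: integer AL index (1-based), NA beyond `max_depth`.
#' @export
layer_of <- function(depth, layers = analysis_layers()) {
  al <- floor(depth / layers$thickness) + 1L
  al[depth < 0 | depth >= layers$max_depth] <- NA_integer_
  as.integer(al)
}

.stage_of <- function(type) {
  c(PA = 1L, DA = 2L, A = 2L, C = 3L, V = 4L, AV = 4L, PV = 5L)[type]
}

#' Classify an RBC trajectory by its vessel-type sequence
#'
#' A correct full trajectory passes the vessel types in the order
#' PA -> DA+A -> C -> V+AV -> PV. To be robust against labeling errors the
#' path may deviate from this order for at most two consecutive edges,
#' provided it then resumes at a stage at least as far along as before the
#' excursion (the tolerance resets after every accepted edge). A
#' capillary-valid trajectory only needs (PA or DA+A) -> C -> (V+AV or PV)
#' under the same tolerance. Anything else is invalid, with an exit class
#' derived from the last traversed edge.
#'
#' @param types character vector of vessel types along the path.
#' @return list with `class` (`"full_valid"`, `"capillary_valid"` or
#'   `"invalid"`; a full-valid path is also capillary-valid), logical
#'   `full_valid`, `capillary_valid`, and `exit_class` (`"arteriole_outlet"`,
#'   `"capillary_outlet"` or `"other"`).
#' @export
classify_trajectory <- function(types) {
  if (!length(types)) {
    return(list(class = "invalid", full_valid = FALSE,
                capillary_valid = FALSE, exit_class = "other"))
  }
  st <- .stage_of(types)
  if (anyNA(st)) stop("unknown vessel type in trajectory")
  cur <- 0L
  dev <- 0L
  seen <- logical(5)
  ok <- TRUE
  for (s in st) {
    if (s >= cur) {
      cur <- s
      dev <- 0L
      seen[s] <- TRUE
    } else {
      dev <- dev + 1L
      if (dev > 2L) { ok <- FALSE; break }
    }
  }
  full <- ok && all(seen)
  cap <- ok && (seen[1] || seen[2]) && seen[3] && (seen[4] || seen[5])
  last <- types[length(types)]
  exit_class <- if (last %in% c("PA", "DA", "A")) "arteriole_outlet"
    else if (last == "C") "capillary_outlet" else "other"
  list(class = if (full) "full_valid" else if (cap) "capillary_valid"
       else "invalid",
       full_valid = full, capillary_valid = cap, exit_class = exit_class)
}

# apply a labeling sensitivity variant to one path's type sequence
.apply_labeling_variant <- function(types, variant) {
  if (variant == "standard") return(types)
  st <- .stage_of(types)
  first_c <- which(st == 3L)[1]
  if (is.na(first_c)) return(types)
  if (variant == "first_C_as_DA+A") {
    types[first_c] <- "A"
  } else if (variant == "last_DA+A_as_C") {
    before <- which(st == 2L & seq_along(st) < first_c)
    if (length(before)) types[max(before)] <- "C"
  } else stop("unknown labeling variant")
  types
}

#' Per-trajectory records: classification, capillary start/end, layers
#'
#' Derives, for every recorded RBC, the path classification, the capillary
#' start point (first node where the type transitions from the arteriolar
#' group into C), the capillary end point (first later node where C
#' transitions into the venular group), the analysis layer of the start
#' depth, the capillary transit time and transit path length, and the
#' total path length.
#'
#' @param traj an `rbc_trajectories` object (see [build_trajectories()]).
#' @param layers an [analysis_layers()] configuration.
#' @param labeling_variant `"standard"`, `"first_C_as_DA+A"` or
#'   `"last_DA+A_as_C"` (labeling sensitivity variants).
#' @param complete_only drop RBCs that never exited (default TRUE).
#' @return data.frame with one row per RBC.
#' @export
trajectory_records <- function(traj, layers = analysis_layers(),
                               labeling_variant = "standard",
                               complete_only = TRUE) {
  ev <- traj$events
  if (!nrow(ev)) {
    return(data.frame(rbc = integer(), class = character(),
                      full_valid = logical(), capillary_valid = logical()))
  }
  by_rbc <- split(seq_len(nrow(ev)), ev$rbc)
  recs <- lapply(by_rbc, function(ix) {
    e <- ev[ix, , drop = FALSE]
    has_exit <- any(e$edge == 0L)
    path <- e[e$edge != 0L, , drop = FALSE]
    if (!nrow(path)) return(NULL)
    types <- .apply_labeling_variant(path$type, labeling_variant)
    cl <- classify_trajectory(types)
    s_cum <- c(0, cumsum(path$length)) # path length at each entry + exit
    s_tot <- s_cum[length(s_cum)]
    stg <- .stage_of(types)
    # capillary start: first arteriolar -> C transition
    start_i <- end_i <- NA_integer_
    trans <- which(stg[-1] == 3L & stg[-length(stg)] <= 2L) + 1L
    if (length(stg) && stg[1] == 3L) trans <- c(1L, trans)
    if (length(trans)) {
      start_i <- trans[1]
      after <- which(stg >= 4L & seq_along(stg) > start_i)
      if (length(after)) end_i <- after[1]
    }
    start_node <- if (!is.na(start_i)) path$node[start_i] else NA_integer_
    end_node <- if (!is.na(end_i)) path$node[end_i] else NA_integer_
    exit_time <- if (has_exit) e$time[e$edge == 0L][1] else NA_real_
    data.frame(
      rbc = path$rbc[1],
      complete = has_exit,
      class = cl$class, full_valid = cl$full_valid,
      capillary_valid = cl$capillary_valid, exit_class = cl$exit_class,
      n_edges = nrow(path), s_tot = s_tot,
      start_node = start_node, end_node = end_node,
      start_depth = if (!is.na(start_i)) path$z[start_i] else NA_real_,
      end_depth = if (!is.na(end_i)) path$z[end_i] else NA_real_,
      start_x = if (!is.na(start_i)) path$x[start_i] else NA_real_,
      start_y = if (!is.na(start_i)) path$y[start_i] else NA_real_,
      end_x = if (!is.na(end_i)) path$x[end_i] else NA_real_,
      end_y = if (!is.na(end_i)) path$y[end_i] else NA_real_,
      cap_start_s = if (!is.na(start_i)) s_cum[start_i] else NA_real_,
      cap_end_s = if (!is.na(end_i)) s_cum[end_i] else NA_real_,
      cap_start_time = if (!is.na(start_i)) path$time[start_i] else NA_real_,
      cap_end_time = if (!is.na(end_i)) path$time[end_i] else NA_real_,
      da_edge = {
        i <- which(types %in% c("DA", "A"))
        if (length(i)) path$vessel_id[i[1]] else NA_integer_
      },
      av_edge = {
        i <- which(types %in% c("AV", "V"))
        if (length(i)) path$vessel_id[i[length(i)]] else NA_integer_
      },
      feed_edge = if (!is.na(start_i)) path$vessel_id[start_i]
                  else NA_integer_,
      path_key = paste(path$vessel_id, collapse = "-"),
      cap_path_key = if (!is.na(start_i) && !is.na(end_i)) {
        paste(path$vessel_id[start_i:end_i], collapse = "-")
      } else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out$tt_c <- out$cap_end_time - out$cap_start_time
  out$ts_c <- out$cap_end_s - out$cap_start_s
  out$al <- layer_of(out$start_depth, layers)
  if (complete_only) out <- out[out$complete, , drop = FALSE]
  out
}

#' Normalize trajectory characteristics per capillary start point
#'
#' Each characteristic is divided by the maximum value it attains over all
#' end points of the same start point, i.e. `tc_norm = tc / max(TC)`.
#'
#' @param x numeric characteristic values.
#' @param group grouping vector (one group per start point).
#' @return normalized values in `(0, 1]` with the per-group maximum at 1.
#' @export
normalize_by_group_max <- function(x, group) {
  mx <- stats::ave(x, group, FUN = function(v) max(v, na.rm = TRUE))
  x / mx
}

#' End-point preferences and their correlation with path characteristics
#'
#' For every capillary start point the relative end-point frequency `f_ep`
#' is the number of RBCs reaching an end point over the number of RBCs
#' passing the start point. A start point has a preferred end point if the
#' largest frequency exceeds 0.5 while the second largest stays below 0.3;
#' preferred paths are defined analogously on per-path frequencies. Five
#' per-(start, end) characteristics -- euclidean distance, mean path
#' length, mean summed tube resistance, mean flow rate and mean RBC
#' velocity along the capillary paths -- are normalized per start point by
#' their maximum and correlated (Pearson) with `f_ep`.
#'
#' @param traj an `rbc_trajectories` object.
#' @param records optional precomputed [trajectory_records()].
#' @param min_rbc start points with fewer trajectories are excluded from
#'   the correlation (default 2) and flagged.
#' @return list with `endpoints` (per start/end pair: `n`, `f_ep`,
#'   characteristics and their normalized versions), `start_points` (per
#'   start point: `n_ep`, preference flags), `correlations` (named vector
#'   of 5 Pearson coefficients), `n_excluded_start_points`.
#' @export
endpoint_preference_and_correlation <- function(traj, records = NULL,
                                                min_rbc = 2L) {
  if (is.null(records)) records <- trajectory_records(traj)
  r <- records[records$capillary_valid & !is.na(records$start_node) &
                 !is.na(records$end_node), , drop = FALSE]
  if (!nrow(r)) stop("no capillary-valid trajectories")
  ev <- traj$events
  net <- traj$network

  # per-trajectory capillary-path characteristics
  vres <- effective_resistance(net$vessels$diameter, net$vessels$length, 0)
  names(vres) <- as.character(net$vessels$id)
  per_traj <- lapply(seq_len(nrow(r)), function(i) {
    ids <- strsplit(r$cap_path_key[i], "-", fixed = TRUE)[[1]]
    ids <- ids[-length(ids)] # edges strictly between start and end node
    vrow <- match(as.integer(ids), net$vessels$id)
    L <- net$vessels$length[vrow]
    d <- net$vessels$diameter[vrow]
    # cell speed per edge from entry timestamps
    e <- ev[ev$rbc == r$rbc[i] & ev$edge != 0L, , drop = FALSE]
    tt <- r$tt_c[i]
    v_mean <- r$ts_c[i] / tt / 1e3 # um/s -> mm/s
    q_mean <- mean(v_mean * 1e-3 * .lumen_area(d)) # ~ bulk flow, m^3/s
    c(path_length = sum(L), resistance = sum(vres[ids]),
      v_rbc = v_mean, flow = q_mean)
  })
  ch <- do.call(rbind, per_traj)
  key <- paste(r$start_node, r$end_node, sep = ">")
  agg <- function(x) tapply(x, key, mean)
  pair <- data.frame(
    key = names(agg(ch[, 1])),
    start_node = as.integer(tapply(r$start_node, key, `[`, 1)),
    end_node = as.integer(tapply(r$end_node, key, `[`, 1)),
    n = as.integer(table(key)[names(agg(ch[, 1]))]),
    distance = c(tapply(sqrt((r$end_x - r$start_x)^2 +
                               (r$end_y - r$start_y)^2 +
                               (r$end_depth - r$start_depth)^2), key, mean)),
    path_length = c(agg(ch[, "path_length"])),
    resistance = c(agg(ch[, "resistance"])),
    flow = c(agg(ch[, "flow"])),
    v_rbc = c(agg(ch[, "v_rbc"])))
  n_start <- table(r$start_node)
  pair$n_start <- as.integer(n_start[as.character(pair$start_node)])
  pair$f_ep <- pair$n / pair$n_start

  # preference flags per start point
  sp <- lapply(split(pair, pair$start_node), function(p) {
    f <- sort(p$f_ep, decreasing = TRUE)
    second <- if (length(f) > 1) f[2] else 0
    data.frame(start_node = p$start_node[1], n_ep = nrow(p),
               n_rbc = p$n_start[1],
               preferred_endpoint = f[1] > 0.5 && second < 0.3)
  })
  start_points <- do.call(rbind, sp)
  # preferred path: frequencies over distinct capillary paths
  pk <- paste(r$start_node, r$cap_path_key)
  path_n <- table(pk)
  pp <- vapply(split(as.integer(path_n),
                     vapply(strsplit(names(path_n), " "), `[`, "", 1)),
               function(cnt) {
                 f <- sort(cnt / sum(cnt), decreasing = TRUE)
                 second <- if (length(f) > 1) f[2] else 0
                 f[1] > 0.5 && second < 0.3
               }, logical(1))
  start_points$preferred_path <-
    unname(pp[as.character(start_points$start_node)])

  keep <- pair$n_start >= min_rbc
  excl <- length(unique(pair$start_node[!keep]))
  pk2 <- pair[keep, , drop = FALSE]
  cors <- c(distance = NA, path_length = NA, resistance = NA, flow = NA,
            v_rbc = NA)
  if (nrow(pk2) > 2) {
    for (nm in names(cors)) {
      norm <- normalize_by_group_max(pk2[[nm]], pk2$start_node)
      if (stats::sd(norm) > 0 && stats::sd(pk2$f_ep) > 0) {
        cors[nm] <- stats::cor(pk2$f_ep, norm)
      }
    }
  }
  list(endpoints = pair, start_points = start_points,
       correlations = cors, n_excluded_start_points = excl)
}

#' Averaged pressure or diameter curves over the normalized path length
#'
#' Every full-valid trajectory is resampled by interpolation onto a
#' uniform grid of the normalized path length `s_norm = s / s_tot`
#' (pressure: linear between node samples; diameter: piecewise constant
#' per edge), then averaged pointwise within each analysis layer. The
#' abscissa is rescaled by the layer's mean total path length, and the
#' mean capillary start/end positions are reported.
#'
#' @param traj an `rbc_trajectories` object.
#' @param quantity `"pressure"` or `"diameter"`.
#' @param layers an [analysis_layers()].
#' @param grid_size number of `s_norm` samples (default 100).
#' @param records optional precomputed [trajectory_records()].
#' @return list per AL: `curve` (data.frame `s_norm`, `s_um`, `value`),
#'   `n`, `mean_s_tot`, `cap_start_snorm`, `cap_end_snorm`.
#' @export
averaged_curves <- function(traj, quantity = c("pressure", "diameter"),
                            layers = analysis_layers(), grid_size = 100L,
                            records = NULL) {
  quantity <- match.arg(quantity)
  if (is.null(records)) records <- trajectory_records(traj, layers)
  r <- records[records$full_valid & !is.na(records$al) &
                 records$s_tot > 0, , drop = FALSE]
  ev <- traj$events
  grid <- seq(0, 1, length.out = grid_size)
  out <- list()
  for (al in sort(unique(r$al))) {
    ra <- r[r$al == al, , drop = FALSE]
    mat <- matrix(NA_real_, nrow(ra), grid_size)
    for (i in seq_len(nrow(ra))) {
      e <- ev[ev$rbc == ra$rbc[i], , drop = FALSE]
      path <- e[e$edge != 0L, , drop = FALSE]
      s <- c(0, cumsum(path$length))
      if (quantity == "pressure") {
        p_exit <- e$pressure[e$edge == 0L][1]
        y <- c(path$pressure, p_exit)
        mat[i, ] <- stats::approx(s / ra$s_tot[i], y, grid,
                                  rule = 2)$y
      } else {
        y <- c(path$diameter, path$diameter[nrow(path)])
        mat[i, ] <- stats::approx(s / ra$s_tot[i], y, grid,
                                  method = "constant", rule = 2)$y
      }
    }
    mean_s <- mean(ra$s_tot)
    out[[paste0("AL", al)]] <- list(
      curve = data.frame(s_norm = grid, s_um = grid * mean_s,
                         value = colMeans(mat)),
      n = nrow(ra), mean_s_tot = mean_s,
      cap_start_snorm = mean(ra$cap_start_s / ra$s_tot),
      cap_end_snorm = mean(ra$cap_end_s / ra$s_tot))
  }
  out
}

#' Layer-specific pressure drop decomposition by vessel type
#'
#' For every full-valid trajectory the pressure at the first node of each
#' vessel-type group (PA, DA+A, C, V+AV, PV, in path order) and the
#' cumulative path length at that transition are extracted, averaged per
#' analysis layer, and converted into per-type fractions of the total
#' pressure drop (from the PA inlet to the final exit).
#'
#' @param traj an `rbc_trajectories` object.
#' @param layers an [analysis_layers()].
#' @param labeling_variant `"standard"`, `"first_C_as_DA+A"` or
#'   `"last_DA+A_as_C"` (sensitivity re-runs with shifted type
#'   boundaries).
#' @return data.frame per (AL, type group): mean inlet pressure (mmHg),
#'   mean cumulative path length (um), drop to the next group (mmHg) and
#'   its fraction of the AL's total drop, plus the number of trajectories.
#' @export
pressure_drop_by_type <- function(traj, layers = analysis_layers(),
                                  labeling_variant = "standard") {
  records <- trajectory_records(traj, layers, labeling_variant)
  r <- records[records$full_valid & !is.na(records$al), , drop = FALSE]
  if (!nrow(r)) stop("no full-valid trajectories in any analysis layer")
  ev <- traj$events
  groups <- c("PA", "DA+A", "C", "V+AV", "PV")
  grp_of <- c(PA = 1L, DA = 2L, A = 2L, C = 3L, V = 4L, AV = 4L, PV = 5L)
  rows <- list()
  for (i in seq_len(nrow(r))) {
    e <- ev[ev$rbc == r$rbc[i], , drop = FALSE]
    path <- e[e$edge != 0L, , drop = FALSE]
    types <- .apply_labeling_variant(path$type, labeling_variant)
    g <- grp_of[types]
    s <- c(0, cumsum(path$length))
    # first index at or beyond each group, scanning monotonically
    inlet_p <- inlet_s <- rep(NA_real_, 5)
    cur <- 0L
    for (k in seq_along(g)) {
      if (g[k] > cur) {
        for (gg in (cur + 1L):g[k]) {
          if (gg == g[k]) { inlet_p[gg] <- path$pressure[k]
                            inlet_s[gg] <- s[k] }
        }
        cur <- g[k]
      }
    }
    p_exit <- e$pressure[e$edge == 0L][1]
    rows[[i]] <- data.frame(al = r$al[i], group = groups,
                            inlet_p = inlet_p, inlet_s = inlet_s,
                            p_exit = p_exit)
  }
  long <- do.call(rbind, rows)
  res <- list()
  for (al in sort(unique(long$al))) {
    la <- long[long$al == al, , drop = FALSE]
    mp <- tapply(la$inlet_p, la$group, mean, na.rm = TRUE)[groups]
    ms <- tapply(la$inlet_s, la$group, mean, na.rm = TRUE)[groups]
    p_exit <- mean(la$p_exit[la$group == "PA"])
    nxt <- c(mp[-1], p_exit)
    # the total drop is taken from the PA inlet to the PV inlet; the PV
    # segment's own drop (to the exit) is reported but lies outside it
    total <- mp[1] - mp[5]
    res[[length(res) + 1L]] <- data.frame(
      al = al, type = groups, inlet_pressure = unname(mp),
      inlet_path_length = unname(ms),
      drop = unname(mp - nxt), drop_fraction = unname((mp - nxt) / total),
      n = sum(la$group == "PA"))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Transit, feeding and in-plane statistics per analysis layer
#'
#' Per AL: capillary transit time `tt_C` (its standard deviation is the
#' capillary transit time heterogeneity, CTH), transit path length `ts_C`,
#' capillary RBC velocity `v_RBC,C = ts_C / tt_C`, the number of distinct
#' observed capillary paths (DA+A to V+AV), the number of feeding branches
#' (distinct arteriole-to-capillary transition vessels with start point in
#' the AL) and, when a flow solution is supplied, the summed blood flow
#' through them. The feeding matrix counts, per draining AV, the RBCs
#' received from each DA; the in-plane fit regresses the capillary end
#' depth on the start depth (reported in mm).
#'
#' @param traj an `rbc_trajectories` object.
#' @param layers an [analysis_layers()].
#' @param solution optional [solve_pressure_flow()] result used to sum the
#'   blood flow through feeding branches.
#' @param records optional precomputed [trajectory_records()].
#' @param recording_window duration of the trajectory recording window in
#'   seconds (to convert RBC counts into fluxes), or NULL.
#' @return list with `layer_summary` (data.frame per AL), `feeding`
#'   (data.frame per AV: primary DA, its fraction, number of feeding DAs),
#'   `inplane_fit` (slope, intercept in mm, Pearson r, n).
#' @export
transit_and_feeding_stats <- function(traj, layers = analysis_layers(),
                                      solution = NULL, records = NULL,
                                      recording_window = NULL) {
  if (is.null(records)) records <- trajectory_records(traj, layers)
  r <- records[records$capillary_valid & !is.na(records$al) &
                 !is.na(records$tt_c) & records$tt_c > 0, , drop = FALSE]
  if (!nrow(r)) stop("no capillary-valid trajectories with timestamps")
  net <- traj$network
  flows <- NULL
  if (!is.null(solution)) {
    flows <- stats::setNames(abs(solution$flow),
                             as.character(net$vessels$id))
  }
  summ <- list()
  for (al in sort(unique(r$al))) {
    ra <- r[r$al == al, , drop = FALSE]
    v_c <- ra$ts_c / ra$tt_c / 1e3 # mm/s
    feed_edges <- unique(ra$feed_edge)
    summ[[length(summ) + 1L]] <- data.frame(
      al = al, n = nrow(ra),
      tt_c_mean = mean(ra$tt_c), tt_c_sd = stats::sd(ra$tt_c),
      cth = stats::sd(ra$tt_c),
      ts_c_mean = mean(ra$ts_c) / 1e3, # mm
      ts_c_sd = stats::sd(ra$ts_c) / 1e3,
      v_rbc_c_mean = mean(v_c), v_rbc_c_sd = stats::sd(v_c),
      unique_paths = length(unique(ra$cap_path_key)),
      feeding_branches = length(feed_edges),
      feeding_blood_flow = if (!is.null(flows)) {
        sum(flows[as.character(feed_edges)], na.rm = TRUE)
      } else NA_real_,
      feeding_rbc_flow = if (!is.null(recording_window)) {
        nrow(ra) / recording_window
      } else NA_real_)
  }
  layer_summary <- do.call(rbind, summ)

  fr <- r[!is.na(r$da_edge) & !is.na(r$av_edge), , drop = FALSE]
  feeding <- NULL
  if (nrow(fr)) {
    tab <- table(fr$av_edge, fr$da_edge)
    feeding <- data.frame(
      av_edge = as.integer(rownames(tab)),
      n_rbc = as.integer(rowSums(tab)),
      n_feeding_da = as.integer(rowSums(tab > 0)),
      primary_da = as.integer(colnames(tab)[max.col(tab)]),
      primary_fraction = apply(tab, 1, max) / rowSums(tab))
    rownames(feeding) <- NULL
  }

  fit <- NULL
  if (nrow(r) >= 3) {
    x <- r$start_depth / 1e3; y <- r$end_depth / 1e3 # mm
    lmfit <- stats::lm(y ~ x)
    fit <- list(slope = unname(stats::coef(lmfit)[2]),
                intercept = unname(stats::coef(lmfit)[1]),
                r = if (stats::sd(x) > 0 && stats::sd(y) > 0) {
                  stats::cor(x, y)
                } else NA_real_,
                n = nrow(r))
  }
  list(layer_summary = layer_summary, feeding = feeding, inplane_fit = fit)
}

#' Enumerate simple paths between two node sets
#'
#' Depth-first enumeration of simple (node-disjoint) paths, optionally
#' restricted to edges of given vessel types. Intended for small graphs
#' (the count grows combinatorially); enumeration aborts beyond
#' `max_paths`.
#'
#' @param net a [vasc_network()].
#' @param from_nodes,to_nodes node id vectors.
#' @param via_types restrict intermediate edges to these vessel types
#'   (default NULL = all).
#' @param max_paths abort threshold (default 1e5).
#' @return number of distinct simple paths.
#' @export
count_simple_paths <- function(net, from_nodes, to_nodes, via_types = NULL,
                               max_paths = 1e5) {
  v <- net$vessels
  if (!is.null(via_types)) v <- v[v$type %in% via_types, , drop = FALSE]
  adj <- list()
  for (i in seq_len(nrow(v))) {
    a <- as.character(v$from[i]); b <- as.character(v$to[i])
    adj[[a]] <- c(adj[[a]], v$to[i])
    adj[[b]] <- c(adj[[b]], v$from[i])
  }
  target <- as.character(to_nodes)
  count <- 0L
  visit <- function(node, seen) {
    if (count >= max_paths) stop("path enumeration exceeded max_paths")
    for (nb in adj[[as.character(node)]]) {
      if (as.character(nb) %in% target) {
        count <<- count + 1L
      } else if (!nb %in% seen) {
        visit(nb, c(seen, nb))
      }
    }
  }
  for (s in from_nodes) visit(s, s)
  count
}
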