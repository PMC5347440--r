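#' Trim a network laterally and in depth
#'
#' Cuts away a fraction of the lateral extent on all four sides and
#' everything below a cut depth, to expose deep in- and outflow vertices.
#' Vessels crossing a cut plane are severed at the plane: a new node is
#' created at the intersection and flagged `deep_boundary`, and the
#' retained stump keeps a proportional share of the tortuous length.
#' Components that lose their connection to any pial node are removed and
#' reported. Re-applying the same trim is a no-op: the lateral planes are
#' computed from the extent of the network as it was before the first trim
#' (stored in the `trim_extent` attribute).
#'
#' @param net a [vasc_network()].
#' @param side_fraction fraction of the total width cut on each side, in
#'   `[0, 0.5)` (default 0.125).
#' @param depth_cut cut depth in mm (default 1.2).
#' @return the trimmed [vasc_network()].
#' @export
trim_network <- function(net, side_fraction = 0.125, depth_cut = 1.2) {
  stopifnot(side_fraction >= 0, side_fraction < 0.5, depth_cut > 0)
  nodes <- net$nodes
  vessels <- net$vessels
  ext <- attr(net, "trim_extent")
  if (is.null(ext)) {
    ext <- c(xmin = min(nodes$x), xmax = max(nodes$x),
             ymin = min(nodes$y), ymax = max(nodes$y))
  }
  z_cut <- depth_cut * 1000 # mm -> um
  x_lo <- ext["xmin"] + side_fraction * (ext["xmax"] - ext["xmin"])
  x_hi <- ext["xmax"] - side_fraction * (ext["xmax"] - ext["xmin"])
  y_lo <- ext["ymin"] + side_fraction * (ext["ymax"] - ext["ymin"])
  y_hi <- ext["ymax"] - side_fraction * (ext["ymax"] - ext["ymin"])

  inside <- nodes$x >= x_lo & nodes$x <= x_hi &
    nodes$y >= y_lo & nodes$y <= y_hi & nodes$z <= z_cut
  node_in <- stats::setNames(inside, as.character(nodes$id))

  keep_v <- logical(nrow(vessels))
  new_nodes <- list()
  next_node_id <- max(nodes$id) + 1L
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(pos) <- as.character(nodes$id)

  for (vi in seq_len(nrow(vessels))) {
    a <- as.character(vessels$from[vi]); b <- as.character(vessels$to[vi])
    ina <- node_in[[a]]; inb <- node_in[[b]]
    if (ina && inb) {
      keep_v[vi] <- TRUE
    } else if (ina || inb) {
      # sever at the closest violated plane along the straight chord
      p_in <- pos[if (ina) a else b, ]
      p_out <- pos[if (ina) b else a, ]
      tt <- 1
      cut_k <- NA_integer_; cut_lim <- NA_real_
      bounds <- list(c(1, x_lo, -1), c(1, x_hi, 1), c(2, y_lo, -1),
                     c(2, y_hi, 1), c(3, z_cut, 1))
      for (bd in bounds) {
        k <- bd[1]; lim <- bd[2]; sgn <- bd[3]
        out_of <- if (sgn > 0) p_out[k] > lim else p_out[k] < lim
        if (out_of && abs(p_out[k] - p_in[k]) > 0) {
          tk <- (lim - p_in[k]) / (p_out[k] - p_in[k])
          if (tk >= 0 && tk < tt) { tt <- tk; cut_k <- k; cut_lim <- lim }
        }
      }
      if (tt == 0) {
        # the retained endpoint already sits on the cut plane: the
        # vessel is removed and that node becomes the exposed boundary
        keep_id <- if (ina) a else b
        nodes$boundary[nodes$id == as.integer(keep_id)] <- "deep_boundary"
        keep_v[vi] <- FALSE
      } else {
        p_cut <- p_in + tt * (p_out - p_in)
        # snap exactly onto the cut plane so re-trimming is a no-op
        if (!is.na(cut_k)) p_cut[cut_k] <- cut_lim
        nid <- next_node_id; next_node_id <- next_node_id + 1L
        new_nodes[[length(new_nodes) + 1L]] <-
          data.frame(id = nid, x = p_cut[1], y = p_cut[2], z = p_cut[3],
                     boundary = "deep_boundary")
        if (ina) vessels$to[vi] <- nid else vessels$from[vi] <- nid
        vessels$length[vi] <- max(vessels$length[vi] * tt, 1e-6)
        keep_v[vi] <- TRUE
      }
    }
  }

  vessels <- vessels[keep_v, , drop = FALSE]
  nodes <- nodes[inside, , drop = FALSE]
  if (length(new_nodes)) nodes <- rbind(nodes, do.call(rbind, new_nodes))
  out <- vasc_network(nodes, vessels, validate = FALSE)

  # drop components with no pial node
  if (nrow(out$vessels)) {
    g <- as_igraph(out)
    comp <- igraph::components(g)
    pial <- out$nodes$id[out$nodes$boundary %in%
                           c("pial_inflow", "pial_outflow")]
    memb <- comp$membership[as.character(out$nodes$id)]
    good_comp <- unique(memb[as.character(pial)])
    if (!length(good_comp) || all(is.na(good_comp))) {
      stop("empty-network error: trim removed all pial in-/outflow nodes")
    }
    drop_nodes <- out$nodes$id[!(memb %in% good_comp)]
    if (length(drop_nodes)) {
      message("trim: removing ", length(drop_nodes),
              " node(s) in components disconnected from the pial surface")
      out$vessels <- out$vessels[!(out$vessels$from %in% drop_nodes |
                                     out$vessels$to %in% drop_nodes), ,
                                 drop = FALSE]
      out$nodes <- out$nodes[!(out$nodes$id %in% drop_nodes), , drop = FALSE]
    }
  } else {
    stop("empty-network error: trim removed every vessel")
  }
  validate_network(out)
  attr(out, "trim_extent") <- ext
  out
}
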