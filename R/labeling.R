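#' Apply diameter- and angle-based corrections to vessel-type labels
#'
#' Takes a network with provisional labels (PA / DA+A / C / V+AV / PV) and
#' applies three corrections, walking outward from every penetrating-tree
#' root (pial inflow nodes on the arteriolar side, pial outflow nodes on
#' the venular side):
#'
#' 1. the capillary bed starts only after two consecutive vessels with
#'    diameter below `consec_thresh`; provisional capillaries encountered
#'    earlier are pushed back into the arteriolar (or venular) class, and
#'    the vessel at which the bed starts becomes a capillary;
#' 2. no capillary keeps a diameter above `max_cap_diam` and no
#'    arteriole/venule keeps a diameter below `min_av_diam` (violators are
#'    relabeled, capillary-bound violators toward the majority class of
#'    their graph neighbours);
#' 3. within an arteriolar tree, once the angle between two subsequent
#'    branches falls below `da_a_angle` degrees all downstream vessels are
#'    relabeled A (trunk stays DA); the mirrored split of V vs AV is
#'    controlled by `split_venular`.
#'
#' Angles are measured between the chord vectors of consecutive centreline
#' segments at a node, so a straight continuation measures 180 degrees; a
#' tie at exactly `da_a_angle` does not trigger the relabeling.
#'
#' @param net a [vasc_network()] with provisional labels.
#' @param min_av_diam minimum arteriole/venule diameter in um (default 6.0;
#'   4.8 is appropriate for small-caliber networks).
#' @param max_cap_diam maximum capillary diameter in um (default 9.0).
#' @param consec_thresh diameter below which a vessel counts toward the
#'   two-consecutive-thin-vessels rule, um (default 7.0).
#' @param da_a_angle branching angle in degrees below which downstream
#'   vessels become A (default 125).
#' @param split_venular also split V/AV by the angle rule (default TRUE).
#' @return the relabeled [vasc_network()].
#' @export
label_vessels <- function(net, min_av_diam = 6.0, max_cap_diam = 9.0,
                          consec_thresh = 7.0, da_a_angle = 125,
                          split_venular = TRUE) {
  nodes <- net$nodes
  vessels <- net$vessels
  roots_a <- nodes$id[nodes$boundary == "pial_inflow"]
  roots_v <- nodes$id[nodes$boundary == "pial_outflow"]
  if (length(roots_a) == 0L && length(roots_v) == 0L) {
    stop("labeling error: network has no penetrating-tree root ",
         "(no pial inflow or outflow node)")
  }
  type <- vessels$type
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(pos) <- as.character(nodes$id)
  adj <- .adjacency_index(net)

  walk_side <- function(type, roots, trunk_lab, side_lab, pial_lab,
                        use_angle) {
    visited <- rep(FALSE, nrow(vessels))
    # queue entries: vessel row, node it was entered from, consec count so
    # far, in-bed flag, side-branch flag
    queue <- list()
    for (r in roots) {
      for (vi in adj[[as.character(r)]]) {
        if (type[vi] %in% c(pial_lab, trunk_lab, side_lab, "C")) {
          queue[[length(queue) + 1L]] <-
            list(vi = vi, from = r, consec = 0L, bed = FALSE, side = FALSE)
        }
      }
    }
    head_i <- 1L
    while (head_i <= length(queue)) {
      st <- queue[[head_i]]; head_i <- head_i + 1L
      vi <- st$vi
      if (visited[vi]) next
      visited[vi] <- TRUE
      v_from <- vessels$from[vi]; v_to <- vessels$to[vi]
      other <- if (v_from == st$from) v_to else v_from
      consec <- st$consec; bed <- st$bed; side <- st$side
      if (type[vi] == pial_lab) {
        consec <- 0L
      } else if (!bed) {
        thin <- vessels$diameter[vi] < consec_thresh
        consec <- if (thin) consec + 1L else 0L
        if (consec >= 2L) {
          bed <- TRUE
          type[vi] <- "C"
        } else {
          type[vi] <- if (side) side_lab else trunk_lab
        }
      } else {
        # inside the capillary bed: keep/force C, but do not march into
        # another penetrating tree (thick provisional trunk vessels)
        if (type[vi] %in% c(trunk_lab, side_lab) &&
            vessels$diameter[vi] >= consec_thresh) next
        type[vi] <- "C"
      }
      # extend the walk
      for (wi in adj[[as.character(other)]]) {
        if (visited[wi]) next
        lab <- type[wi]
        admissible <- if (bed) {
          lab == "C" || (lab %in% c(trunk_lab, side_lab))
        } else {
          lab %in% c(trunk_lab, side_lab, "C")
        }
        if (!admissible) next
        nxt_side <- side
        if (use_angle && !bed && type[vi] != pial_lab && !side) {
          u <- pos[as.character(st$from), ] - pos[as.character(other), ]
          o2 <- if (vessels$from[wi] == other) vessels$to[wi] else
            vessels$from[wi]
          w <- pos[as.character(o2), ] - pos[as.character(other), ]
          nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
          if (nu > 0 && nw > 0) {
            ang <- acos(max(-1, min(1, sum(u * w) / (nu * nw)))) * 180 / pi
            if (ang < da_a_angle) nxt_side <- TRUE
          }
        }
        queue[[length(queue) + 1L]] <-
          list(vi = wi, from = other, consec = consec, bed = bed,
               side = nxt_side)
      }
    }
    type
  }

  if (length(roots_a)) {
    type <- walk_side(type, roots_a, "DA", "A", "PA", use_angle = TRUE)
  }
  if (length(roots_v)) {
    type <- walk_side(type, roots_v, "AV", "V", "PV",
                      use_angle = split_venular)
  }

  # diameter bound corrections
  too_thin <- which(type %in% c(ARTERIOLAR_TYPES, VENULAR_TYPES) &
                      vessels$diameter < min_av_diam)
  if (length(too_thin)) {
    type[too_thin] <- "C"
    message(length(too_thin), " arteriole/venule vessel(s) below ",
            min_av_diam, " um relabeled C")
  }
  too_thick <- which(type == "C" & vessels$diameter > max_cap_diam)
  if (length(too_thick)) {
    for (vi in too_thick) {
      nb <- unique(c(adj[[as.character(vessels$from[vi])]],
                     adj[[as.character(vessels$to[vi])]]))
      nb_lab <- type[setdiff(nb, vi)]
      nb_lab <- nb_lab[nb_lab != "C"]
      type[vi] <- if (length(nb_lab)) {
        names(sort(table(nb_lab), decreasing = TRUE))[1]
      } else "DA"
    }
    message(length(too_thick), " capillary vessel(s) above ", max_cap_diam,
            " um relabeled toward neighbour-majority class")
  }
  net$vessels$type <- type
  net
}
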