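#' Vessel type labels
#'
#' The seven vessel classes used throughout: pial arteriole (PA), descending
#' arteriole (DA), arteriole (A), capillary (C), venule (V), ascending
#' venule (AV) and pial venule (PV). Analyses frequently use the grouped
#' views DA+A (arteriolar tree) and V+AV (venular tree); those are unions
#' computed on the fly, never stored.
#'
#' @export
VESSEL_TYPES <- c("PA", "DA", "A", "C", "V", "AV", "PV")

#' @rdname VESSEL_TYPES
#' @export
ARTERIOLAR_TYPES <- c("DA", "A")

#' @rdname VESSEL_TYPES
#' @export
VENULAR_TYPES <- c("V", "AV")

BOUNDARY_KINDS <- c("interior", "pial_inflow", "pial_outflow", "deep_boundary")

#' Construct a vascular network
#'
#' A vascular network is a graph whose nodes are bifurcations (or endpoints)
#' with 3-D positions, and whose edges are vessels approximated by straight
#' pipes carrying a diameter, a tortuous length and a vessel-type label.
#' The z coordinate is cortical depth in um, 0 at the pial surface and
#' increasing downward.
#'
#' @param nodes data.frame with columns `id` (integer, unique), `x`, `y`, `z`
#'   (um) and optionally `boundary` (one of interior, pial_inflow,
#'   pial_outflow, deep_boundary; default interior).
#' @param vessels data.frame with columns `id` (integer, unique), `from`,
#'   `to` (node ids, distinct), `diameter` (um, > 0), `length` (um, > 0) and
#'   `type` (one of `VESSEL_TYPES`).
#' @param validate run integrity checks (default TRUE).
#' @return an object of class `vasc_network`.
#' @export
vasc_network <- function(nodes, vessels, validate = TRUE) {
  nodes <- as.data.frame(nodes)
  vessels <- as.data.frame(vessels)
  if (!"boundary" %in% names(nodes)) nodes$boundary <- "interior"
  nodes <- nodes[, c("id", "x", "y", "z", "boundary")]
  if (nrow(vessels)) {
    vessels <- vessels[, c("id", "from", "to", "diameter", "length", "type")]
  } else {
    vessels <- data.frame(id = integer(), from = integer(), to = integer(),
                          diameter = numeric(), length = numeric(),
                          type = character())
  }
  nodes$id <- as.integer(nodes$id)
  vessels$id <- as.integer(vessels$id)
  vessels$from <- as.integer(vessels$from)
  vessels$to <- as.integer(vessels$to)
  vessels$type <- as.character(vessels$type)
  net <- structure(list(nodes = nodes, vessels = vessels),
                   class = "vasc_network")
  if (validate) validate_network(net)
  net
}

#' Validate network integrity
#'
#' Checks id uniqueness, endpoint existence, positive geometry and known
#' vessel-type strings. Errors describe the first offending element.
#'
#' @param net a [vasc_network()].
#' @param require_pial also require at least one pial inflow and one pial
#'   outflow node (default FALSE; enforced where a flow problem is posed).
#' @return `net`, invisibly.
#' @export
validate_network <- function(net, require_pial = FALSE) {
  nodes <- net$nodes
  vessels <- net$vessels
  if (anyDuplicated(nodes$id)) stop("integrity error: duplicate node ids")
  if (anyDuplicated(vessels$id)) stop("integrity error: duplicate vessel ids")
  if (nrow(vessels)) {
    missing <- setdiff(c(vessels$from, vessels$to), nodes$id)
    if (length(missing)) {
      stop("integrity error: vessel endpoint references absent node ",
           missing[1])
    }
    if (any(vessels$from == vessels$to)) {
      stop("integrity error: vessel with identical endpoints")
    }
    if (any(vessels$diameter <= 0)) stop("integrity error: nonpositive diameter")
    if (any(vessels$length <= 0)) stop("integrity error: nonpositive length")
    unknown <- setdiff(unique(vessels$type), VESSEL_TYPES)
    if (length(unknown)) {
      stop("format error: unknown vessel type '", unknown[1], "'")
    }
  }
  if (!all(nodes$boundary %in% BOUNDARY_KINDS)) {
    stop("format error: unknown boundary kind")
  }
  if (require_pial) {
    if (!any(nodes$boundary == "pial_inflow") ||
        !any(nodes$boundary == "pial_outflow")) {
      stop("integrity error: network needs at least one pial inflow and one ",
           "pial outflow node")
    }
  }
  invisible(net)
}

#' @export
print.vasc_network <- function(x, ...) {
  cat("<vasc_network> ", nrow(x$nodes), " nodes, ", nrow(x$vessels),
      " vessels\n", sep = "")
  if (nrow(x$vessels)) {
    tb <- table(factor(x$vessels$type, levels = VESSEL_TYPES))
    cat("  types:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  if (nrow(x$nodes)) {
    cat(sprintf("  depth range: %.1f - %.1f um\n",
                min(x$nodes$z), max(x$nodes$z)))
    bt <- table(x$nodes$boundary)
    cat("  boundary:", paste(names(bt), bt, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Read / write a vascular network as node and edge CSV tables
#'
#' The node table needs columns `id, x, y, z` (optional `boundary`); the
#' edge table `id, n1, n2, diameter, length, type`. A write followed by a
#' read reproduces the network exactly.
#'
#' @param nodes_path,edges_path CSV file paths.
#' @return [read_network()] returns a [vasc_network()]; [write_network()]
#'   returns the paths invisibly.
#' @export
read_network <- function(nodes_path, edges_path) {
  nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  need_n <- c("id", "x", "y", "z")
  need_e <- c("id", "n1", "n2", "diameter", "length", "type")
  if (!all(need_n %in% names(nodes))) {
    stop("format error: node table must have columns ",
         paste(need_n, collapse = ", "))
  }
  if (!all(need_e %in% names(edges))) {
    stop("format error: edge table must have columns ",
         paste(need_e, collapse = ", "))
  }
  names(edges)[names(edges) == "n1"] <- "from"
  names(edges)[names(edges) == "n2"] <- "to"
  vasc_network(nodes, edges)
}

#' @rdname read_network
#' @param net a [vasc_network()].
#' @export
write_network <- function(net, nodes_path, edges_path) {
  nodes <- net$nodes
  edges <- net$vessels
  names(edges)[names(edges) == "from"] <- "n1"
  names(edges)[names(edges) == "to"] <- "n2"
  # 17 significant digits keep doubles exact through the round trip
  fmt <- function(df) {
    for (nm in names(df)) {
      if (is.double(df[[nm]])) {
        df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
      }
    }
    df
  }
  utils::write.csv(fmt(nodes), nodes_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(edges), edges_path, row.names = FALSE, quote = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' Convert to an igraph object
#'
#' @param net a [vasc_network()].
#' @param directed build a directed graph from -> to (default FALSE).
#' @return an igraph graph whose vertex name is the node id and edge
#'   attributes carry vessel id, diameter, length and type.
#' @export
as_igraph <- function(net, directed = FALSE) {
  vdf <- data.frame(name = as.character(net$nodes$id),
                    x = net$nodes$x, y = net$nodes$y, z = net$nodes$z,
                    boundary = net$nodes$boundary)
  edf <- data.frame(from = as.character(net$vessels$from),
                    to = as.character(net$vessels$to),
                    vessel_id = net$vessels$id,
                    diameter = net$vessels$diameter,
                    length = net$vessels$length,
                    type = net$vessels$type)
  igraph::graph_from_data_frame(edf, directed = directed, vertices = vdf)
}

# adjacency list: for each node id, the vessel row indices touching it
.adjacency_index <- function(net) {
  v <- net$vessels
  idx <- c(seq_len(nrow(v)), seq_len(nrow(v)))
  nid <- c(v$from, v$to)
  split(idx, factor(nid, levels = net$nodes$id))
}

#' Structural equality of two networks
#'
#' Compares nodes and vessels field-by-field after sorting by id, with an
#' optional tolerance on coordinates and geometry.
#'
#' @param a,b two [vasc_network()] objects.
#' @param tol numeric tolerance (default 0 = exact).
#' @return TRUE/FALSE.
#' @export
network_identical <- function(a, b, tol = 0) {
  na <- a$nodes[order(a$nodes$id), ]; nb <- b$nodes[order(b$nodes$id), ]
  va <- a$vessels[order(a$vessels$id), ]; vb <- b$vessels[order(b$vessels$id), ]
  if (nrow(na) != nrow(nb) || nrow(va) != nrow(vb)) return(FALSE)
  num_ok <- function(x, y) all(abs(x - y) <= tol)
  all(na$id == nb$id) && num_ok(na$x, nb$x) && num_ok(na$y, nb$y) &&
    num_ok(na$z, nb$z) && all(na$boundary == nb$boundary) &&
    all(va$id == vb$id) && all(va$from == vb$from) && all(va$to == vb$to) &&
    num_ok(va$diameter, vb$diameter) && num_ok(va$length, vb$length) &&
    all(va$type == vb$type)
}

#' Total vascular volume of a network
#'
#' @param net a [vasc_network()].
#' @return volume in m^3 (sum of cylindrical vessel volumes).
#' @export
network_volume <- function(net) {
  sum(.vessel_volume(net$vessels$diameter, net$vessels$length))
}
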