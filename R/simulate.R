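# Electrical-equivalent steady-flow analysis. Channels become resistors
# (pressure drop per volumetric flow), components become junction nodes,
# and the network is solved by nodal analysis: Kirchhoff's current law
# with conductances G = 1/R, pressure boundaries eliminated, flow
# boundaries injected on the right-hand side.

#' Hydraulic resistance of a rectangular channel
#'
#' Low-aspect rectangular-duct approximation
#' \deqn{R = 12 \mu L / (w h^3 (1 - 0.63 h/w))}
#' valid for aspect ratios h/w <= 1; when height exceeds width the two are
#' swapped first, so R is symmetric in (w, h).
#'
#' @param length,width,height Channel dimensions in metres.
#' @param viscosity Dynamic viscosity in Pa s (water ~ 1e-3).
#' @return Resistance in Pa s / m^3.
#' @export
channel_resistance <- function(length, width, height, viscosity = 1e-3) {
  if (any(c(length, width, height) <= 0)) {
    stop("channel dimensions must be positive", call. = FALSE)
  }
  if (viscosity <= 0) stop("viscosity must be positive", call. = FALSE)
  if (height > width) { tmp <- width; width <- height; height <- tmp }
  12 * viscosity * length / (width * height^3 * (1 - 0.63 * height / width))
}

UM <- 1e-6  # metres per micrometre

new_network <- function() {
  structure(list(
    nodes = data.frame(id = character(0), x = numeric(0), y = numeric(0),
                       stringsAsFactors = FALSE),
    edges = data.frame(id = character(0), from = character(0), to = character(0),
                       resistance = numeric(0), origin = character(0),
                       stringsAsFactors = FALSE),
    bc = list()
  ), class = "mf_network")
}

net_add_node <- function(net, id, x = NA_real_, y = NA_real_) {
  if (!id %in% net$nodes$id) {
    net$nodes <- rbind(net$nodes, data.frame(id = id, x = x, y = y,
                                             stringsAsFactors = FALSE))
  }
  net
}

#' Add a resistor edge to a hydraulic network
#' @param net An `mf_network`.
#' @param from,to Node ids (created if absent).
#' @param resistance Pa s / m^3, must be > 0.
#' @param id Optional edge id.
#' @param origin Free-text provenance tag.
#' @return The modified network.
#' @export
net_add_edge <- function(net, from, to, resistance, id = NULL, origin = "") {
  if (resistance <= 0) stop("edge resistance must be > 0", call. = FALSE)
  net <- net_add_node(net, from)
  net <- net_add_node(net, to)
  if (is.null(id)) id <- sprintf("e%d", nrow(net$edges) + 1L)
  net$edges <- rbind(net$edges, data.frame(
    id = id, from = from, to = to, resistance = resistance, origin = origin,
    stringsAsFactors = FALSE))
  net
}

#' Set a boundary condition on a network node
#'
#' @param net An `mf_network`.
#' @param node Node id; for device-built networks, component nodes are
#'   named after the component id (PORT components are the intended
#'   attachment points).
#' @param pressure Pa, or `NULL`.
#' @param flow Injected volumetric flow in m^3/s (positive into the node),
#'   or `NULL`. Exactly one of `pressure`/`flow` must be given.
#' @return The modified network.
#' @export
set_boundary <- function(net, node, pressure = NULL, flow = NULL) {
  if (is.null(pressure) == is.null(flow)) {
    stop("give exactly one of pressure or flow", call. = FALSE)
  }
  if (!node %in% net$nodes$id) stop(sprintf("no node '%s' in network", node), call. = FALSE)
  net$bc[[node]] <- if (!is.null(pressure)) list(type = "pressure", value = pressure)
                    else list(type = "flow", value = flow)
  net
}

# Interior resistance model of a placed component, or NULL for an ideal
# junction (all its ports merge into one node).
component_interior <- function(comp, viscosity) {
  if (comp$entity == "MIXER") {
    p <- validate_params("MIXER", comp$params)
    L <- mixer_centerline_length(p) * UM
    list(ports = c("in", "out"),
         resistance = channel_resistance(L, p$channelWidth * UM, p$height * UM, viscosity))
  } else {
    NULL
  }
}

#' Build the electrical-equivalent network of a device's flow layers
#'
#' One node per component (ideal-junction interior model) or per component
#' port (entities with an interior resistance model, e.g. MIXER uses its
#' unrolled serpentine centreline length); one node per interior path
#' vertex; one resistor edge per channel element. Control layers are
#' excluded; open valves contribute no resistance, and a valve listed as
#' closed removes its mapped connection's edges.
#'
#' @param device A valid, placed `mf_device`.
#' @param viscosity Fluid dynamic viscosity, Pa s.
#' @param closed_valves Character vector of valve component ids whose
#'   mapped channels are blocked.
#' @return An `mf_network`.
#' @export
build_network <- function(device, viscosity = 1e-3, closed_valves = character(0)) {
  rep <- validate_device(device)
  if (has_errors(rep)) {
    stop(paste0("device fails validation:\n",
                paste(rep$message[rep$severity == "error"], collapse = "\n")),
         call. = FALSE)
  }
  flow_layers <- vapply(Filter(function(l) l$kind == "FLOW", device$layers),
                        `[[`, character(1), "id")
  net <- new_network()
  interiors <- list()
  for (comp in device$components) {
    if (!any(comp$layer_ids %in% flow_layers)) next
    interiors[[comp$id]] <- component_interior(comp, viscosity)
  }
  node_of_terminal <- function(t) {
    int <- interiors[[t$component]]
    if (is.null(int) || !t$port %in% int$ports) t$component
    else paste0(t$component, ":", t$port)
  }
  for (comp in device$components) {
    if (!any(comp$layer_ids %in% flow_layers)) next
    pos <- comp$position %||% c(NA_real_, NA_real_)
    int <- interiors[[comp$id]]
    if (is.null(int)) {
      net <- net_add_node(net, comp$id, pos[1], pos[2])
    } else {
      for (p in int$ports) net <- net_add_node(net, paste0(comp$id, ":", p), pos[1], pos[2])
      net <- net_add_edge(net, paste0(comp$id, ":", int$ports[1]),
                          paste0(comp$id, ":", int$ports[2]), int$resistance,
                          id = paste0(comp$id, ":interior"), origin = comp$id)
    }
  }
  blocked <- unlist(device$valve_map[intersect(closed_valves, names(device$valve_map))],
                    use.names = FALSE)
  for (conn in device$connections) {
    if (!conn$layer_id %in% flow_layers) next
    if (conn$id %in% blocked) next
    if (is.null(conn$path)) stop(sprintf("connection '%s' has no path; place the device first",
                                         conn$id), call. = FALSE)
    if (is.null(conn$channel_width) || is.null(conn$height)) {
      stop(sprintf("connection '%s' lacks width/height", conn$id), call. = FALSE)
    }
    n <- nrow(conn$path)
    node_ids <- character(n)
    node_ids[1] <- node_of_terminal(conn$source)
    node_ids[n] <- node_of_terminal(conn$sinks[[1]])
    if (n > 2) {
      for (i in 2:(n - 1)) {
        node_ids[i] <- sprintf("%s:v%d", conn$id, i)
        net <- net_add_node(net, node_ids[i], conn$path[i, 1], conn$path[i, 2])
      }
    }
    for (i in seq_len(n - 1)) {
      L <- sqrt(sum((conn$path[i + 1, ] - conn$path[i, ])^2)) * UM
      if (L <= 0) next  # degenerate zero-length element (coincident ports)
      R <- channel_resistance(L, conn$channel_width * UM, conn$height * UM, viscosity)
      net <- net_add_edge(net, node_ids[i], node_ids[i + 1], R,
                          id = sprintf("%s:s%d", conn$id, i), origin = conn$id)
    }
    # extra sinks attach at the path end node
    if (length(conn$sinks) > 1) {
      for (k in 2:length(conn$sinks)) {
        extra <- node_of_terminal(conn$sinks[[k]])
        ep <- resolve_terminal(device, conn$sinks[[k]])$position
        L <- sqrt(sum((conn$path[n, ] - ep)^2)) * UM
        if (L <= 0) next
        R <- channel_resistance(L, conn$channel_width * UM, conn$height * UM, viscosity)
        net <- net_add_edge(net, node_ids[n], extra, R,
                            id = sprintf("%s:x%d", conn$id, k), origin = conn$id)
      }
    }
  }
  net
}

#' Solve a hydraulic network for node pressures and edge flows
#'
#' Nodal analysis on the conductance Laplacian: pressures at pressure
#' boundaries are fixed, injected flows enter the right-hand side, and the
#' remaining pressures come from a sparse direct solve. Edge flow is
#' signed along the edge orientation, Q = (P_from - P_to) / R.
#'
#' @param net An `mf_network` with at least one pressure boundary.
#' @return An `mf_flow_solution`: `pressures` (named, Pa), `flows` (data
#'   frame with `id`, `from`, `to`, `flow` in m^3/s) and `residual` (worst
#'   Kirchhoff imbalance over unconstrained nodes, m^3/s).
#' @export
solve_network <- function(net) {
  nodes <- net$nodes$id
  if (length(nodes) == 0) stop("empty network", call. = FALSE)
  if (any(net$edges$resistance <= 0)) stop("resistances must be > 0", call. = FALSE)
  bc_types <- vapply(net$bc, `[[`, character(1), "type")
  p_nodes <- names(net$bc)[bc_types == "pressure"]
  if (length(p_nodes) == 0) stop("need at least one pressure boundary", call. = FALSE)

  # connectivity: every node must reach a pressure boundary through edges
  adj <- split(c(net$edges$to, net$edges$from), c(net$edges$from, net$edges$to))
  seen <- new.env(parent = emptyenv())
  queue <- p_nodes
  for (q in queue) assign(q, TRUE, envir = seen)
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (nb in adj[[cur]] %||% character(0)) {
      if (!exists(nb, envir = seen)) { assign(nb, TRUE, envir = seen); queue <- c(queue, nb) }
    }
  }
  floating <- nodes[!vapply(nodes, exists, logical(1), envir = seen)]
  if (length(floating) > 0) {
    stop(sprintf("floating subnetwork not tied to any pressure boundary: %s",
                 paste(floating, collapse = ", ")), call. = FALSE)
  }

  idx <- stats::setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  G <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n, n))
  for (r in seq_len(nrow(net$edges))) {
    g <- 1 / net$edges$resistance[r]
    i <- idx[[net$edges$from[r]]]; j <- idx[[net$edges$to[r]]]
    G[i, i] <- G[i, i] + g; G[j, j] <- G[j, j] + g
    G[i, j] <- G[i, j] - g; G[j, i] <- G[j, i] - g
  }
  b <- numeric(n)
  for (nm in names(net$bc)) {
    if (net$bc[[nm]]$type == "flow") b[idx[[nm]]] <- b[idx[[nm]]] + net$bc[[nm]]$value
  }
  fixed <- idx[p_nodes]
  pfix <- vapply(p_nodes, function(nm) net$bc[[nm]]$value, numeric(1))
  free <- setdiff(seq_len(n), fixed)
  P <- numeric(n)
  P[fixed] <- pfix
  if (length(free) > 0) {
    rhs <- b[free] - as.numeric(G[free, fixed, drop = FALSE] %*% pfix)
    P[free] <- as.numeric(Matrix::solve(G[free, free, drop = FALSE], rhs))
  }
  names(P) <- nodes
  Q <- (P[net$edges$from] - P[net$edges$to]) / net$edges$resistance
  flows <- data.frame(id = net$edges$id, from = net$edges$from, to = net$edges$to,
                      flow = as.numeric(Q), stringsAsFactors = FALSE)
  imbalance <- as.numeric(G %*% P - b)
  residual <- if (length(free) > 0) max(abs(imbalance[free])) else 0
  structure(list(pressures = P, flows = flows, residual = residual),
            class = "mf_flow_solution")
}

#' @export
print.mf_flow_solution <- function(x, ...) {
  cat(sprintf("<mf_flow_solution> %d node(s), %d edge(s), KCL residual %.3e m^3/s\n",
              length(x$pressures), nrow(x$flows), x$residual))
  invisible(x)
}
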