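# Core component-connection model: a device is a netlist of placed
# parametric components joined by explicit channel connections, organised
# into paired FLOW/CONTROL functional layers, with a key-value map tying
# membrane valves to the flow channels they pinch.

MF_SCHEMA_VERSION <- "mfda-1"
SNAP_TOL <- 1e-6  # um; path endpoint / port coincidence tolerance

#' Create an empty device
#'
#' @param name Device name (non-empty).
#' @return An `mf_device` with no layers, components or connections.
#' @export
create_device <- function(name) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("device name must be a non-empty string", call. = FALSE)
  }
  structure(list(
    name = name,
    version = MF_SCHEMA_VERSION,
    layers = list(),
    components = list(),
    connections = list(),
    valve_map = list(),
    counters = list()
  ), class = "mf_device")
}

#' @export
print.mf_device <- function(x, ...) {
  st <- device_stats(x)
  cat(sprintf("<mf_device '%s'> %d layer(s), %d component(s), %d channel element(s), %d valve mapping(s)\n",
              x$name, length(x$layers), st[["n_components"]],
              st[["n_channel_elements"]], length(x$valve_map)))
  invisible(x)
}

#' Add a flow/control layer pair
#'
#' Every level of a device carries exactly one FLOW layer (the channels
#' holding the working fluid) and one CONTROL layer (the pressurised
#' channels actuating membrane valves); the pair is always created
#' together. Layer ids are deterministic in the level index.
#'
#' @param device An `mf_device`.
#' @param z_offset Base z of the level in micrometres (default stacks
#'   levels 1000 um apart).
#' @return The modified device, with attribute `"layer_ids"` giving
#'   `c(flow, control)` ids of the new pair.
#' @export
add_level <- function(device, z_offset = NULL) {
  lvl <- length(device$layers) / 2L
  if (is.null(z_offset)) z_offset <- lvl * 1000
  flow <- list(id = sprintf("flow_%d", lvl), kind = "FLOW", level = lvl, z_offset = z_offset)
  control <- list(id = sprintf("control_%d", lvl), kind = "CONTROL", level = lvl, z_offset = z_offset)
  device$layers <- c(device$layers, list(flow), list(control))
  attr(device, "layer_ids") <- c(flow$id, control$id)
  device
}

layer_by_id <- function(device, id) {
  for (l in device$layers) if (l$id == id) return(l)
  NULL
}

#' Id of the layer pairing a given layer at its level
#' @keywords internal
paired_layer_id <- function(device, layer_id) {
  l <- layer_by_id(device, layer_id)
  if (is.null(l)) return(NULL)
  want <- if (l$kind == "FLOW") "CONTROL" else "FLOW"
  for (x in device$layers) if (x$level == l$level && x$kind == want) return(x$id)
  NULL
}

next_id <- function(device, entity) {
  k <- (device$counters[[entity]] %||% 0L) + 1L
  list(id = sprintf("%s_%d", tolower(entity), k), k = k)
}

#' A terminal: a (component, port) reference
#'
#' @param component Component id.
#' @param port Port label on that component.
#' @return A terminal list usable as a connection source or sink.
#' @export
term <- function(component, port) list(component = component, port = port)

#' Place a component on a layer
#'
#' @param device An `mf_device`.
#' @param entity Registered entity key.
#' @param params Named parameter overrides; the rest take registry defaults.
#' @param position Length-2 numeric, micrometres, geometric centre.
#' @param rotation Degrees counter-clockwise about the centre.
#' @param layer_id Id of the host layer. A VALVE3D spans a level: given
#'   either layer of a level it is attached to both the FLOW and CONTROL
#'   layer of that level.
#' @param id Optional explicit id; by default `<entity>_<k>` with a
#'   per-entity counter.
#' @return The modified device, with attribute `"id"` holding the new
#'   component id.
#' @export
place_component <- function(device, entity, params = list(), position = c(0, 0),
                            rotation = 0, layer_id, id = NULL) {
  def <- definition_of(entity)
  p <- validate_params(entity, params)
  if (is.null(layer_by_id(device, layer_id))) {
    stop(sprintf("no layer '%s' in device", layer_id), call. = FALSE)
  }
  layer_ids <- layer_id
  if (entity == "VALVE3D") {
    other <- paired_layer_id(device, layer_id)
    if (is.null(other)) stop("VALVE3D requires a paired flow/control level", call. = FALSE)
    l <- layer_by_id(device, layer_id)
    layer_ids <- if (l$kind == "FLOW") c(layer_id, other) else c(other, layer_id)
  }
  if (is.null(id)) {
    nx <- next_id(device, entity)
    id <- nx$id
    device$counters[[entity]] <- nx$k
  }
  if (id %in% c(names(device$components), names(device$connections))) {
    stop(sprintf("id '%s' already used in device", id), call. = FALSE)
  }
  comp <- list(
    id = id, name = id, entity = entity, layer_ids = layer_ids,
    position = if (is.null(position)) NULL else as.numeric(position),
    rotation = as.numeric(rotation), params = p,
    height = as.numeric(p$height %||% 100)
  )
  device$components[[id]] <- comp
  attr(device, "id") <- id
  device
}

#' Resolved port positions of a placed component
#'
#' @return Data frame `label`, `x`, `y` (device coordinates), `role`.
#' @export
component_ports <- function(device, component_id) {
  comp <- device$components[[component_id]]
  if (is.null(comp)) stop(sprintf("no component '%s'", component_id), call. = FALSE)
  ps <- ports_of(comp$entity, comp$params)
  if (is.null(comp$position)) return(ps)
  xy <- transform_points(as.matrix(ps[, c("x", "y")]), comp$position, comp$rotation)
  ps$x <- xy[, 1]; ps$y <- xy[, 2]
  ps
}

resolve_terminal <- function(device, terminal, where = "terminal") {
  comp <- device$components[[terminal$component]]
  if (is.null(comp)) {
    stop(sprintf("%s references missing component '%s'", where, terminal$component),
         call. = FALSE)
  }
  ps <- component_ports(device, terminal$component)
  i <- match(terminal$port, ps$label)
  if (is.na(i)) {
    stop(sprintf("%s references missing port '%s' on component '%s'",
                 where, terminal$port, terminal$component), call. = FALSE)
  }
  list(component = comp, position = c(ps$x[i], ps$y[i]))
}

#' Two-segment Manhattan path between two points (horizontal then vertical)
#' @keywords internal
manhattan_path <- function(a, b) {
  p <- if (isTRUE(all.equal(a[1], b[1])) || isTRUE(all.equal(a[2], b[2]))) {
    rbind(a, b)
  } else {
    rbind(a, c(b[1], a[2]), b)
  }
  dimnames(p) <- NULL
  p
}

#' Add a channel connection between terminals
#'
#' @param device An `mf_device`.
#' @param layer_id Host layer of the channel.
#' @param source,sinks Source terminal and list of sink terminals (see
#'   [term()]); at least one sink.
#' @param waypoints Optional n x 2 matrix of path waypoints; when omitted a
#'   two-segment Manhattan path (horizontal then vertical) is generated from
#'   the source port to the first sink port. Endpoints are snapped to the
#'   exact port positions.
#' @param channel_width,height Channel cross-section, micrometres.
#' @param id Optional explicit id.
#' @return The modified device with attribute `"id"` = connection id.
#' @export
add_connection <- function(device, layer_id, source, sinks, waypoints = NULL,
                           channel_width = 400, height = 100, id = NULL) {
  if (!is.null(sinks$component)) sinks <- list(sinks)  # single terminal given bare
  if (length(sinks) < 1) stop("connection needs at least one sink", call. = FALSE)
  if (is.null(layer_by_id(device, layer_id))) {
    stop(sprintf("no layer '%s' in device", layer_id), call. = FALSE)
  }
  src <- resolve_terminal(device, source, "connection source")
  snk <- lapply(sinks, resolve_terminal, device = device, where = "connection sink")
  for (s in sinks) {
    if (identical(s$component, source$component) && identical(s$port, source$port)) {
      stop("connection source and sink are the same terminal", call. = FALSE)
    }
  }
  for (t in c(list(src), snk)) {
    if (!layer_id %in% t$component$layer_ids) {
      stop(sprintf("terminal component '%s' is not on layer '%s'",
                   t$component$id, layer_id), call. = FALSE)
    }
  }
  placed <- !is.null(src$component$position)
  if (placed) {
    path <- if (is.null(waypoints)) {
      manhattan_path(src$position, snk[[1]]$position)
    } else {
      w <- as.matrix(waypoints)
      w[1, ] <- src$position
      w[nrow(w), ] <- snk[[1]]$position
      dimnames(w) <- NULL
      w
    }
  } else {
    path <- NULL
  }
  if (channel_width <= 0) stop("channel_width must be > 0", call. = FALSE)
  if (height <= 0) stop("connection height must be > 0", call. = FALSE)
  if (is.null(id)) {
    nx <- next_id(device, "channel")
    id <- nx$id
    device$counters[["channel"]] <- nx$k
  }
  if (id %in% c(names(device$components), names(device$connections))) {
    stop(sprintf("id '%s' already used in device", id), call. = FALSE)
  }
  device$connections[[id]] <- list(
    id = id, layer_id = layer_id,
    source = source, sinks = sinks,
    path = path,
    channel_width = as.numeric(channel_width), height = as.numeric(height)
  )
  attr(device, "id") <- id
  device
}

#' Replicate a component along an arithmetic offset
#'
#' Creates `n_copies` new components with the same entity, parameters and
#' rotation, at positions offset by `(k*dx, k*dy)` for `k = 1..n_copies`.
#'
#' @return The modified device with attribute `"ids"` listing the new ids.
#' @export
generate_array <- function(device, component_id, n_copies, dx, dy) {
  comp <- device$components[[component_id]]
  if (is.null(comp)) stop(sprintf("no component '%s'", component_id), call. = FALSE)
  if (n_copies < 1) stop("n_copies must be >= 1", call. = FALSE)
  ids <- character(n_copies)
  for (k in seq_len(n_copies)) {
    device <- place_component(device, comp$entity, comp$params,
                              position = comp$position + c(k * dx, k * dy),
                              rotation = comp$rotation,
                              layer_id = comp$layer_ids[[1]])
    ids[k] <- attr(device, "id")
  }
  attr(device, "ids") <- ids
  device
}

#' Remove a component, detaching its valve mapping and connections' validity
#'
#' The component is dropped from the netlist and from the valve map.
#' Connections that referenced it are left in place and will be reported
#' by [validate_device()].
#'
#' @export
remove_component <- function(device, component_id) {
  if (is.null(device$components[[component_id]])) {
    stop(sprintf("no component '%s'", component_id), call. = FALSE)
  }
  device$components[[component_id]] <- NULL
  device$valve_map[[component_id]] <- NULL
  device
}

is_valve_entity <- function(entity) entity %in% c("VALVE", "VALVE3D")

#' Map a membrane valve onto a flow channel
#'
#' Moves the valve to the nearest point of the connection's polyline, sets
#' its rotation perpendicular to the local channel direction, and records
#' the valve-to-channel relation in the device's valve map. For a VALVE3D
#' (which spans the flow/control level) the mapped connection is split into
#' two channels meeting at the valve seat.
#'
#' @param device An `mf_device`.
#' @param valve_id Id of a VALVE or VALVE3D component.
#' @param connection_id Id of a connection on the flow layer paired with
#'   the valve's control layer.
#' @return The modified device with attribute `"alignment_point"`.
#' @export
map_valve <- function(device, valve_id, connection_id) {
  comp <- device$components[[valve_id]]
  if (is.null(comp)) stop(sprintf("no component '%s'", valve_id), call. = FALSE)
  if (!is_valve_entity(comp$entity)) {
    stop(sprintf("component '%s' is a %s, not a valve", valve_id, comp$entity), call. = FALSE)
  }
  conn <- device$connections[[connection_id]]
  if (is.null(conn)) stop(sprintf("no connection '%s'", connection_id), call. = FALSE)
  ctrl <- Filter(function(l) !is.null(layer_by_id(device, l)) &&
                   layer_by_id(device, l)$kind == "CONTROL", comp$layer_ids)
  if (length(ctrl) > 0) {
    flow_of_level <- paired_layer_id(device, ctrl[[1]])
    if (!identical(conn$layer_id, flow_of_level)) {
      stop(sprintf("connection '%s' is not on the flow layer paired with valve '%s'",
                   connection_id, valve_id), call. = FALSE)
    }
  }
  pr <- project_on_polyline(conn$path, comp$position)
  seg <- conn$path[pr$segment + 1L, ] - conn$path[pr$segment, ]
  angle <- atan2(seg[2], seg[1]) * 180 / pi
  device$components[[valve_id]]$position <- pr$point
  device$components[[valve_id]]$rotation <- (angle + 90) %% 360
  device$valve_map[[valve_id]] <- connection_id

  if (comp$entity == "VALVE3D") {
    path <- conn$path
    d_start <- sqrt(sum((pr$point - path[1, ])^2))
    d_end <- sqrt(sum((pr$point - path[nrow(path), ])^2))
    if (d_start > SNAP_TOL && d_end > SNAP_TOL) {
      if (length(conn$sinks) != 1) {
        stop("VALVE3D can only split a single-sink connection", call. = FALSE)
      }
      i <- pr$segment
      at_vertex <- sqrt(sum((pr$point - path[i + 1L, ])^2)) <= SNAP_TOL
      path_a <- rbind(path[seq_len(i), , drop = FALSE], pr$point)
      path_b <- rbind(pr$point,
                      path[seq(if (at_vertex) i + 2L else i + 1L, nrow(path)), , drop = FALSE])
      device$connections[[connection_id]] <- NULL
      device <- add_connection(device, conn$layer_id, conn$source,
                               list(term(valve_id, "fin")), waypoints = path_a,
                               channel_width = conn$channel_width, height = conn$height,
                               id = paste0(connection_id, "_a"))
      device <- add_connection(device, conn$layer_id, term(valve_id, "fout"),
                               conn$sinks, waypoints = path_b,
                               channel_width = conn$channel_width, height = conn$height,
                               id = paste0(connection_id, "_b"))
      device$valve_map[[valve_id]] <- paste0(connection_id, "_a")
    }
  }
  attr(device, "alignment_point") <- pr$point
  device
}

#' Component and channel-element counts
#'
#' A channel element is one straight segment of a connection path: a path
#' of k waypoints contributes k - 1 elements.
#'
#' @return Named integer vector `c(n_components, n_channel_elements)`.
#' @export
device_stats <- function(device) {
  n_el <- sum(vapply(device$connections, function(c) {
    if (is.null(c$path)) 0L else nrow(c$path) - 1L
  }, integer(1)))
  c(n_components = length(device$components), n_channel_elements = as.integer(n_el))
}

violation <- function(code, severity, id, message) {
  data.frame(code = code, severity = severity, id = id, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a device against the model invariants
#'
#' Checks referential closure (layers, terminals, valve map), parameter
#' validity, path/port coincidence within the snap tolerance, and
#' layer-kind consistency (flow-functional entities on CONTROL layers and
#' vice versa yield warnings, not errors).
#'
#' @param device An `mf_device`.
#' @return A data frame of violations (`code`, `severity`, `id`,
#'   `message`); zero rows when every invariant holds.
#' @export
validate_device <- function(device) {
  v <- list()
  push <- function(...) v[[length(v) + 1L]] <<- violation(...)
  layer_ids <- vapply(device$layers, `[[`, character(1), "id")
  if (anyDuplicated(layer_ids)) push("dup_layer", "error", "", "duplicate layer ids")
  # level pairing
  for (lvl in unique(vapply(device$layers, `[[`, numeric(1), "level"))) {
    kinds <- vapply(Filter(function(l) l$level == lvl, device$layers), `[[`, character(1), "kind")
    if (!identical(sort(kinds), c("CONTROL", "FLOW"))) {
      push("level_pairing", "error", as.character(lvl),
           sprintf("level %s lacks a FLOW/CONTROL pair", lvl))
    }
  }
  all_ids <- c(names(device$components), names(device$connections))
  if (anyDuplicated(all_ids)) {
    push("dup_id", "error", all_ids[duplicated(all_ids)][1], "duplicate component/connection id")
  }
  for (comp in device$components) {
    for (lid in comp$layer_ids) {
      if (!lid %in% layer_ids) {
        push("missing_layer", "error", comp$id,
             sprintf("component '%s' references missing layer '%s'", comp$id, lid))
      }
    }
    ok <- tryCatch({ validate_params(comp$entity, comp$params); TRUE },
                   error = function(e) { push("bad_params", "error", comp$id, conditionMessage(e)); FALSE })
    if (!ok) next
    if (comp$height <= 0) push("bad_height", "error", comp$id, "component height must be > 0")
    role <- definition_of(comp$entity)$functional_role
    if (role %in% c("FLOW", "CONTROL")) {
      for (lid in comp$layer_ids) {
        l <- layer_by_id(device, lid)
        if (!is.null(l) && l$kind != role) {
          push("layer_kind", "warning", comp$id,
               sprintf("%s-functional component '%s' placed on %s layer '%s'",
                       role, comp$id, l$kind, lid))
        }
      }
    }
  }
  for (conn in device$connections) {
    if (!conn$layer_id %in% layer_ids) {
      push("missing_layer", "error", conn$id,
           sprintf("connection '%s' references missing layer '%s'", conn$id, conn$layer_id))
      next
    }
    if (conn$channel_width <= 0) push("bad_width", "error", conn$id, "channel_width must be > 0")
    terms <- c(list(conn$source), conn$sinks)
    ends <- vector("list", length(terms))
    bad <- FALSE
    for (i in seq_along(terms)) {
      res <- tryCatch(resolve_terminal(device, terms[[i]], sprintf("connection '%s'", conn$id)),
                      error = function(e) { push("bad_terminal", "error", conn$id, conditionMessage(e)); NULL })
      if (is.null(res)) { bad <- TRUE; next }
      ends[[i]] <- res$position
      if (!conn$layer_id %in% res$component$layer_ids) {
        push("terminal_layer", "error", conn$id,
             sprintf("terminal component '%s' of connection '%s' not on layer '%s'",
                     res$component$id, conn$id, conn$layer_id))
      }
    }
    if (bad || is.null(conn$path)) next
    if (nrow(conn$path) < 2) {
      push("short_path", "error", conn$id, "connection path needs >= 2 points")
      next
    }
    if (!is.null(ends[[1]]) &&
        sqrt(sum((conn$path[1, ] - ends[[1]])^2)) > SNAP_TOL) {
      push("endpoint_mismatch", "error", conn$id,
           sprintf("connection '%s' path start is off its source port", conn$id))
    }
    if (!is.null(ends[[2]]) &&
        sqrt(sum((conn$path[nrow(conn$path), ] - ends[[2]])^2)) > SNAP_TOL) {
      push("endpoint_mismatch", "error", conn$id,
           sprintf("connection '%s' path end is off its first sink port", conn$id))
    }
  }
  for (vid in names(device$valve_map)) {
    comp <- device$components[[vid]]
    if (is.null(comp)) {
      push("valve_ref", "error", vid, sprintf("valve map key '%s' is not a component", vid))
      next
    }
    if (!is_valve_entity(comp$entity)) {
      push("valve_kind", "error", vid, sprintf("valve map key '%s' is not a valve", vid))
    }
    cid <- device$valve_map[[vid]]
    conn <- device$connections[[cid]]
    if (is.null(conn)) {
      push("valve_conn", "error", vid,
           sprintf("valve '%s' maps to missing connection '%s'", vid, cid))
      next
    }
    ctrl <- Filter(function(l) { ly <- layer_by_id(device, l); !is.null(ly) && ly$kind == "CONTROL" },
                   comp$layer_ids)
    if (length(ctrl) > 0) {
      flow_of_level <- paired_layer_id(device, ctrl[[1]])
      if (!identical(conn$layer_id, flow_of_level)) {
        push("valve_layer", "error", vid,
             sprintf("valve '%s' maps to connection '%s' off its paired flow layer", vid, cid))
      }
    }
  }
  if (length(v) == 0) {
    violation(character(0), character(0), character(0), character(0))[0, ]
  } else {
    do.call(rbind, v)
  }
}

#' Are there validation errors (severity "error")?
#' @keywords internal
has_errors <- function(report) any(report$severity == "error")

#' Canonical form of a device
#'
#' Components, connections, the valve map and the id counters are maps
#' keyed by id, so their storage order is not meaningful; the canonical
#' form sorts each by id and drops transient operation attributes. Two
#' devices are the same design iff their canonical forms are deeply
#' equal, and serialization writes the canonical order.
#'
#' @param device An `mf_device`.
#' @return The device with id-sorted maps.
#' @export
canonicalize_device <- function(device) {
  sort_by_name <- function(x) if (length(x) == 0) x else x[order(names(x))]
  device$components <- sort_by_name(device$components)
  device$connections <- sort_by_name(device$connections)
  device$valve_map <- sort_by_name(device$valve_map)
  device$counters <- sort_by_name(device$counters)
  strip_op_attrs(device)
}
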