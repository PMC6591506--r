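# Parametric component library: procedural geometry and port layouts for
# the built-in entities (PORT, MIXER, MUX, VALVE, VALVE3D, PUMP, CHAMBER)
# plus registration of custom entities imported from CAD geometry.

.mf <- new.env(parent = emptyenv())

registry_path <- function() {
  system.file("extdata", "entity_registry.json", package = "mfda", mustWork = TRUE)
}

#' Load (or reload) the entity registry
#'
#' The registry holds, for every entity, its parameter definitions
#' (name, units, kind, default, min, max), its design-for-manufacturing
#' class, its procedural difficulty class, and its functional role
#' (FLOW, CONTROL, BOTH or ANY). The shipped registry is loaded on first
#' use; calling this with a path replaces it, dropping any custom
#' entities registered in the meantime.
#'
#' @param path JSON registry file; `NULL` reloads the shipped defaults.
#' @return Invisibly, the vector of registered entity keys.
#' @export
load_entity_registry <- function(path = NULL) {
  if (is.null(path)) path <- registry_path()
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ents <- list()
  for (key in names(cfg$entities)) {
    e <- cfg$entities[[key]]
    pd <- do.call(rbind, lapply(e$params, function(p) {
      data.frame(name = p$name, units = p$units, kind = p$kind,
                 default = as.numeric(p$default), min = as.numeric(p$min),
                 max = as.numeric(p$max), stringsAsFactors = FALSE)
    }))
    ents[[key]] <- structure(list(
      entity = key,
      param_defs = pd,
      dfm_class = e$dfm_class,
      procedural_order = e$procedural_order,
      functional_role = e$functional_role,
      size_param = e$size_param %||% NA_character_,
      custom = FALSE
    ), class = "mf_component_definition")
  }
  .mf$registry <- ents
  .mf$circle_resolution <- as.integer(cfg$circle_resolution %||% 32L)
  invisible(names(ents))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

registry <- function() {
  if (is.null(.mf$registry)) load_entity_registry()
  .mf$registry
}

#' List the registered entity keys
#' @return Character vector of entity keys.
#' @export
list_entities <- function() names(registry())

#' Look up a component definition
#'
#' @param entity Entity key, e.g. `"MIXER"`.
#' @return An `mf_component_definition`: parameter definitions, DFM class,
#'   procedural difficulty class and functional role.
#' @export
definition_of <- function(entity) {
  reg <- registry()
  if (!entity %in% names(reg)) {
    stop(sprintf("unknown entity '%s'; registered: %s", entity,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  reg[[entity]]
}

#' @export
print.mf_component_definition <- function(x, ...) {
  cat(sprintf("<%s> dfm=%s procedural=%s role=%s\n",
              x$entity, x$dfm_class, x$procedural_order, x$functional_role))
  print(x$param_defs, row.names = FALSE)
  invisible(x)
}

#' Validate parameters against an entity's definitions, filling defaults
#'
#' @param entity Entity key.
#' @param params Named list of parameter values; unspecified parameters
#'   take their registry defaults.
#' @return Named list of resolved parameters, in definition order.
#' @export
validate_params <- function(entity, params = list()) {
  def <- definition_of(entity)
  pd <- def$param_defs
  unknown <- setdiff(names(params), pd$name)
  if (length(unknown) > 0) {
    stop(sprintf("unknown parameter(s) for %s: %s", entity,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(pd))) {
    nm <- pd$name[i]
    v <- if (nm %in% names(params)) as.numeric(params[[nm]]) else pd$default[i]
    if (!is.finite(v)) stop(sprintf("parameter '%s' of %s is not finite", nm, entity), call. = FALSE)
    if (v < pd$min[i] || v > pd$max[i]) {
      stop(sprintf("parameter '%s' of %s out of range: %g not in [%g, %g]",
                   nm, entity, v, pd$min[i], pd$max[i]), call. = FALSE)
    }
    if (pd$kind[i] == "count" && v != round(v)) {
      stop(sprintf("parameter '%s' of %s must be an integer, got %g", nm, entity, v),
           call. = FALSE)
    }
    out[[nm]] <- v
  }
  out
}

# ---- geometry builders (local frame, centred at the origin) --------------

mf_face <- function(poly, height, role, circle = NULL) {
  list(poly = poly, height = height, role = role, circle = circle)
}

geom_port <- function(p) {
  r <- p$portRadius
  list(mf_face(make_poly(circle_ring(0, 0, r, .mf$circle_resolution)),
               p$height, "ANY", circle = list(center = c(0, 0), r = r)))
}

# Serpentine: (2X+1) horizontal bars of bendLength x channelWidth stacked
# with vertical gaps of bendSpacing, bridged by 2X vertical bars of
# channelWidth x bendSpacing at alternating ends. Bars meet flush, so the
# union area is exactly (2X+1)*l*w + 2X*s*w.
geom_mixer <- function(p) {
  X <- p$numberOfBends; l <- p$bendLength; w <- p$channelWidth; s <- p$bendSpacing
  pitch <- w + s
  y0 <- -X * pitch                     # centres bars 0..2X about y = 0
  faces <- list()
  for (i in 0:(2 * X)) {
    faces <- c(faces, list(mf_face(make_poly(rect_ring(0, y0 + i * pitch, l, w)),
                                   p$height, "FLOW")))
  }
  for (j in 0:(2 * X - 1)) {
    xc <- if (j %% 2 == 0) l / 2 - w / 2 else -l / 2 + w / 2
    yc <- y0 + j * pitch + w / 2 + s / 2
    faces <- c(faces, list(mf_face(make_poly(rect_ring(xc, yc, w, s)),
                                   p$height, "FLOW")))
  }
  faces
}

mixer_port_offsets <- function(p) {
  X <- p$numberOfBends; l <- p$bendLength; w <- p$channelWidth; s <- p$bendSpacing
  ytop <- X * (w + s)
  data.frame(label = c("in", "out"),
             x = c(-l / 2, l / 2), y = c(-ytop, ytop),
             role = "FLOW", stringsAsFactors = FALSE)
}

#' Serpentine centreline length of a mixer
#'
#' Sum of the horizontal bar lengths plus the vertical runs between bar
#' centrelines; used as the equivalent channel length in the hydraulic
#' interior model.
#' @param params Resolved MIXER parameters.
#' @return Length in micrometres.
#' @export
mixer_centerline_length <- function(params) {
  X <- params$numberOfBends
  (2 * X + 1) * params$bendLength + 2 * X * (params$bendSpacing + params$channelWidth)
}

# Full binary distribution tree, root inlet at the top, 2^k leaf outlets
# along the bottom. Axis-aligned channel rectangles of channelWidth.
mux_levels <- function(p) {
  n <- p$outputs
  k <- log2(n)
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("MUX outputs must be a power of two, got %g", n), call. = FALSE)
  }
  k <- as.integer(round(k))
  leaves_x <- (seq_len(n) - 1 - (n - 1) / 2) * p$spacing
  levels <- list(leaves_x)                     # level k (bottom) first
  x <- leaves_x
  while (length(x) > 1) {
    x <- (x[seq(1, length(x), 2)] + x[seq(2, length(x), 2)]) / 2
    levels <- c(levels, list(x))
  }
  list(k = k, levels = rev(levels))            # levels[[1]] = root
}

geom_mux <- function(p) {
  lv <- mux_levels(p)
  k <- lv$k; w <- p$channelWidth; sh <- p$stageHeight
  H <- k * sh
  cy <- H / 2                                  # shift so geometry is centred
  faces <- list()
  add_rect <- function(x0, x1, y0, y1) {
    faces[[length(faces) + 1L]] <<- mf_face(
      make_poly(rect_ring((x0 + x1) / 2, (y0 + y1) / 2, x1 - x0, y1 - y0)),
      p$height, "FLOW")
  }
  for (d in seq_len(k)) {
    parents <- lv$levels[[d]]
    children <- lv$levels[[d + 1L]]
    yp <- H - (d - 1) * sh - cy
    yc <- H - d * sh - cy
    ym <- (yp + yc) / 2
    for (i in seq_along(parents)) {
      px <- parents[i]
      c1 <- children[2 * i - 1]; c2 <- children[2 * i]
      add_rect(px - w / 2, px + w / 2, ym - w / 2, yp)        # stem down from parent
      add_rect(c1 - w / 2, c2 + w / 2, ym - w / 2, ym + w / 2) # distribution bar
      add_rect(c1 - w / 2, c1 + w / 2, yc, ym + w / 2)         # drops to children
      add_rect(c2 - w / 2, c2 + w / 2, yc, ym + w / 2)
    }
  }
  faces
}

mux_port_offsets <- function(p) {
  lv <- mux_levels(p)
  H <- lv$k * p$stageHeight
  leaves <- lv$levels[[lv$k + 1L]]
  rbind(
    data.frame(label = "in", x = 0, y = H / 2, role = "FLOW", stringsAsFactors = FALSE),
    data.frame(label = paste0("out", seq_along(leaves)),
               x = leaves, y = -H / 2, role = "FLOW", stringsAsFactors = FALSE)
  )
}

geom_valve <- function(p) {
  list(mf_face(make_poly(rect_ring(0, 0, p$width, p$length)), p$height, "CONTROL"))
}

geom_valve3d <- function(p) {
  r <- p$valveRadius; w <- p$channelWidth; g <- p$gap
  xoff <- g / 2 + r / 2
  list(
    mf_face(make_poly(circle_ring(0, 0, r, .mf$circle_resolution)),
            p$height, "CONTROL", circle = list(center = c(0, 0), r = r)),
    mf_face(make_poly(rect_ring(-xoff, 0, r, w)), p$height, "FLOW"),
    mf_face(make_poly(rect_ring(xoff, 0, r, w)), p$height, "FLOW")
  )
}

geom_pump <- function(p) {
  dx <- p$width + p$spacing
  lapply(c(-dx, 0, dx), function(x) {
    mf_face(make_poly(rect_ring(x, 0, p$width, p$length)), p$height, "CONTROL")
  })
}

geom_chamber <- function(p) {
  list(mf_face(make_poly(rect_ring(0, 0, p$width, p$length)), p$height, "FLOW"))
}

ports_builtin <- function(entity, p) {
  switch(entity,
    PORT = data.frame(label = "p", x = 0, y = 0, role = "ANY", stringsAsFactors = FALSE),
    MIXER = mixer_port_offsets(p),
    MUX = mux_port_offsets(p),
    CHAMBER = data.frame(label = c("in", "out"), x = c(-p$width / 2, p$width / 2),
                         y = c(0, 0), role = "FLOW", stringsAsFactors = FALSE),
    VALVE = data.frame(label = "c", x = 0, y = 0, role = "CONTROL", stringsAsFactors = FALSE),
    VALVE3D = data.frame(label = c("c", "fin", "fout"), x = c(0, 0, 0), y = c(0, 0, 0),
                         role = c("CONTROL", "FLOW", "FLOW"), stringsAsFactors = FALSE),
    PUMP = {
      dx <- p$width + p$spacing
      data.frame(label = c("c1", "c2", "c3"), x = c(-dx, 0, dx), y = c(0, 0, 0),
                 role = "CONTROL", stringsAsFactors = FALSE)
    },
    stop(sprintf("no port layout for entity '%s'", entity), call. = FALSE)
  )
}

geom_builtin <- function(entity, p) {
  switch(entity,
    PORT = geom_port(p), MIXER = geom_mixer(p), MUX = geom_mux(p),
    VALVE = geom_valve(p), VALVE3D = geom_valve3d(p), PUMP = geom_pump(p),
    CHAMBER = geom_chamber(p),
    stop(sprintf("no geometry builder for entity '%s'", entity), call. = FALSE)
  )
}

#' Port layout of an entity
#'
#' @param entity Entity key.
#' @param params Parameter values (defaults filled in).
#' @return A data frame with columns `label`, `x`, `y` (offsets from the
#'   component centre, micrometres, before rotation) and `role`
#'   (FLOW/CONTROL/ANY).
#' @export
ports_of <- function(entity, params = list()) {
  def <- definition_of(entity)
  p <- validate_params(entity, params)
  if (isTRUE(def$custom)) def$port_builder(p) else ports_builtin(entity, p)
}

#' Render a component's geometry in device coordinates
#'
#' Generates the entity's procedural geometry at the component's resolved
#' parameters, then applies the component rotation (CCW, degrees, about
#' the component centre) and translation to its position.
#'
#' @param component A component record from a device, or any list with
#'   `entity`, `params`, `position`, `rotation`.
#' @return An `mf_geometry`: list of faces, each holding a polygon (outer
#'   ring + holes), a height (um), a functional-layer role and, where the
#'   face is an exact disc, its circle parameters; plus the DFM class.
#' @export
render_component <- function(component) {
  def <- definition_of(component$entity)
  p <- validate_params(component$entity, component$params %||% list())
  faces <- if (isTRUE(def$custom)) def$geom_builder(p) else geom_builtin(component$entity, p)
  pos <- component$position %||% c(0, 0)
  rot <- component$rotation %||% 0
  faces <- lapply(faces, function(f) {
    f$poly$outer <- transform_points(f$poly$outer, pos, rot)
    f$poly$holes <- lapply(f$poly$holes, transform_points, position = pos, rotation = rot)
    if (!is.null(f$circle)) {
      f$circle$center <- drop(transform_points(matrix(f$circle$center, 1), pos, rot))
    }
    f
  })
  structure(list(entity = component$entity, faces = faces, dfm_class = def$dfm_class),
            class = "mf_geometry")
}

#' Total face area of a rendered geometry
#' @param geom An `mf_geometry`.
#' @param union If `TRUE` (default) overlapping faces are unioned first.
#' @return Area in um^2.
#' @export
geometry_area <- function(geom, union = TRUE) {
  polys <- lapply(geom$faces, `[[`, "poly")
  if (union) polys <- union_polys(polys)
  sum(vapply(polys, poly_area, numeric(1)))
}

#' Register a custom entity from explicit polygon geometry
#'
#' Custom components carry no parametric metadata, so their only
#' parameters are `height` and a uniform `scale` factor applied about the
#' geometry centroid.
#'
#' @param key New entity key (must be unused).
#' @param polygons List of polygons, each either an n x 2 ring matrix or a
#'   list with `outer` and `holes`. Rings must be simple and closed.
#' @param port_spec Optional data frame (`label`, `x`, `y`, `role`) of port
#'   offsets at scale 1; default: two FLOW ports at the bounding-box
#'   midpoints of the x extremes.
#' @param dfm_class Design-for-manufacturing class, default `"XY"`.
#' @return The new `mf_component_definition`, invisibly.
#' @export
register_custom_entity <- function(key, polygons, port_spec = NULL, dfm_class = "XY") {
  reg <- registry()
  if (key %in% names(reg)) stop(sprintf("entity key '%s' already registered", key), call. = FALSE)
  polys <- lapply(polygons, function(p) {
    if (is.matrix(p)) make_poly(p) else make_poly(p$outer, p$holes %||% list())
  })
  for (p in polys) {
    for (r in c(list(p$outer), p$holes)) {
      if (!ring_is_simple(r)) stop("custom geometry ring is not simple/closed", call. = FALSE)
    }
  }
  bb <- rings_bbox(lapply(polys, `[[`, "outer"))
  ctr <- c((bb[1] + bb[3]) / 2, (bb[2] + bb[4]) / 2)
  polys <- lapply(polys, function(p) {
    p$outer <- sweep(p$outer, 2, ctr)
    p$holes <- lapply(p$holes, function(h) sweep(h, 2, ctr))
    p
  })
  if (is.null(port_spec)) {
    hw <- (bb[3] - bb[1]) / 2
    port_spec <- data.frame(label = c("in", "out"), x = c(-hw, hw), y = c(0, 0),
                            role = "FLOW", stringsAsFactors = FALSE)
  }
  pd <- data.frame(
    name = c("height", "scale"), units = c("um", "ratio"), kind = "length",
    default = c(100, 1), min = c(1, 0.01), max = c(2000, 100),
    stringsAsFactors = FALSE)
  def <- structure(list(
    entity = key, param_defs = pd, dfm_class = dfm_class,
    procedural_order = "constant", functional_role = "ANY",
    size_param = NA_character_, custom = TRUE,
    base_polygons = polys, base_ports = port_spec,
    geom_builder = function(p) {
      lapply(polys, function(pl) {
        mf_face(make_poly(pl$outer * p$scale, lapply(pl$holes, `*`, p$scale)),
                p$height, "FLOW")
      })
    },
    port_builder = function(p) {
      ps <- port_spec
      ps$x <- ps$x * p$scale; ps$y <- ps$y * p$scale
      ps
    }
  ), class = "mf_component_definition")
  .mf$registry[[key]] <- def
  invisible(def)
}
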