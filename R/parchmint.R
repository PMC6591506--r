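# ParchMINT-superset JSON serialization. The document mirrors the open
# ParchMINT interchange structure (name / layers / components /
# connections) and adds the extensions this model needs to round-trip
# losslessly: the valve map, per-element heights, and the id counters
# that keep auto-generated ids deterministic. Output is canonical: fixed
# key order, entries sorted by id, floats at 6 decimal places.

PM_DIGITS <- 6

pm_num <- function(x) round(as.numeric(x), PM_DIGITS)

pm_point <- function(p) I(pm_num(p))

#' Serialize a device to ParchMINT-superset JSON
#'
#' Refuses devices with validation errors, attaching the report. The
#' output is deterministic: components/connections sorted by id, fixed
#' key order, 6-decimal micrometre floats.
#'
#' @param device A valid `mf_device`.
#' @return A single JSON string.
#' @export
write_parchmint <- function(device) {
  rep <- validate_device(device)
  if (has_errors(rep)) {
    stop(paste0("refusing to serialize an invalid device:\n",
                paste(rep$message[rep$severity == "error"], collapse = "\n")),
         call. = FALSE)
  }
  comp_json <- function(comp) {
    placed <- !is.null(comp$position)
    span <- c(NA_real_, NA_real_)
    ports <- ports_of(comp$entity, comp$params)
    geom <- render_component(c(comp[c("entity", "params")], list(position = c(0, 0), rotation = 0)))
    bb <- rings_bbox(lapply(geom$faces, function(f) f$poly$outer))
    span <- c(bb[3] - bb[1], bb[4] - bb[2])
    list(
      id = comp$id, name = comp$name, entity = comp$entity,
      layers = as.list(comp$layer_ids),
      params = lapply(comp$params, pm_num),
      position = if (placed) pm_point(comp$position) else NULL,
      rotation = pm_num(comp$rotation),
      height = pm_num(comp$height),
      `x-span` = pm_num(span[1]), `y-span` = pm_num(span[2]),
      ports = lapply(seq_len(nrow(ports)), function(i) {
        list(label = ports$label[i], x = pm_num(ports$x[i]), y = pm_num(ports$y[i]),
             layer = ports$role[i])
      })
    )
  }
  conn_json <- function(conn) {
    list(
      id = conn$id, layer = conn$layer_id,
      source = list(component = conn$source$component, port = conn$source$port),
      sinks = lapply(conn$sinks, function(s) list(component = s$component, port = s$port)),
      paths = if (is.null(conn$path)) list() else
        list(lapply(seq_len(nrow(conn$path)), function(i) pm_point(conn$path[i, ]))),
      params = list(channelWidth = pm_num(conn$channel_width), height = pm_num(conn$height))
    )
  }
  device <- canonicalize_device(device)
  doc <- list(
    name = device$name,
    version = device$version,
    layers = lapply(device$layers, function(l) {
      list(id = l$id, kind = l$kind, level = l$level, z_offset = pm_num(l$z_offset))
    }),
    components = lapply(device$components, comp_json),
    connections = lapply(device$connections, conn_json),
    valve_map = if (length(device$valve_map) == 0) structure(list(), names = character(0))
                else device$valve_map,
    counters = if (length(device$counters) == 0) structure(list(), names = character(0))
               else device$counters
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = PM_DIGITS,
                                pretty = TRUE, null = "null"))
}

pm_require <- function(doc, key, path) {
  if (is.null(doc[[key]])) {
    stop(sprintf("ParchMINT parse error at $.%s: missing key '%s'",
                 if (nzchar(path)) paste0(path, ".", key) else key, key), call. = FALSE)
  }
  doc[[key]]
}

#' Read a ParchMINT-superset JSON document into a device
#'
#' @param text JSON string, or a file path to one.
#' @return An `mf_device` that passes [validate_device()] with no errors.
#' @export
read_parchmint <- function(text) {
  if (length(text) == 1 && !grepl("[{]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop(sprintf("not valid JSON: %s", conditionMessage(e)),
                                           call. = FALSE))
  name <- pm_require(doc, "name", "")
  layers <- pm_require(doc, "layers", "")
  components <- pm_require(doc, "components", "")
  connections <- pm_require(doc, "connections", "")
  dev <- create_device(name)
  if (!is.null(doc$version)) dev$version <- doc$version
  for (l in layers) {
    dev$layers[[length(dev$layers) + 1L]] <- list(
      id = pm_require(l, "id", "layers"), kind = pm_require(l, "kind", "layers"),
      level = as.numeric(pm_require(l, "level", "layers")),
      z_offset = as.numeric(l$z_offset %||% 0))
  }
  for (i in seq_along(components)) {
    c0 <- components[[i]]
    path <- sprintf("components[%d]", i - 1L)
    entity <- pm_require(c0, "entity", path)
    definition_of(entity)  # unknown entity -> lookup error
    pos <- if (is.null(c0$position)) NULL else as.numeric(unlist(c0$position))
    lids <- as.character(unlist(pm_require(c0, "layers", path)))
    dev <- place_component(dev, entity,
                           params = lapply(c0$params %||% list(), as.numeric),
                           position = pos, rotation = as.numeric(c0$rotation %||% 0),
                           layer_id = lids[[1]], id = pm_require(c0, "id", path))
    if (!is.null(c0$name)) dev$components[[c0$id]]$name <- c0$name
  }
  for (i in seq_along(connections)) {
    cn <- connections[[i]]
    path <- sprintf("connections[%d]", i - 1L)
    src <- pm_require(cn, "source", path)
    sinks <- lapply(pm_require(cn, "sinks", path), function(s) term(s$component, s$port))
    wp <- NULL
    if (length(cn$paths %||% list()) > 0) {
      wp <- do.call(rbind, lapply(cn$paths[[1]], function(p) as.numeric(unlist(p))))
    }
    dev <- add_connection(dev, pm_require(cn, "layer", path),
                          term(src$component, src$port), sinks, waypoints = wp,
                          channel_width = as.numeric(cn$params$channelWidth %||% 400),
                          height = as.numeric(cn$params$height %||% 100),
                          id = pm_require(cn, "id", path))
  }
  for (v in names(doc$valve_map %||% list())) {
    dev$valve_map[[v]] <- doc$valve_map[[v]]
  }
  if (length(doc$counters %||% list()) > 0) {
    dev$counters <- lapply(doc$counters, as.integer)
  }
  rep <- validate_device(dev)
  if (has_errors(rep)) {
    stop(paste0("document decodes to an invalid device:\n",
                paste(rep$message[rep$severity == "error"], collapse = "\n")),
         call. = FALSE)
  }
  strip_op_attrs(dev)
}

# drop the transient "last operation" attributes (id, ids, layer_ids,
# alignment_point) that builder functions attach for convenience
strip_op_attrs <- function(device) {
  attributes(device) <- attributes(device)[c("names", "class")]
  device
}
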