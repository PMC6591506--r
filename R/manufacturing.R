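# Design-for-manufacturing classification and 2.5D manufacturing-layer
# generation. Every rendered feature carries a DFM class describing its
# fabrication complexity: XY (in-plane feature milled to one depth), Z
# (through-hole / drill), XYZ (feature spanning levels) and EDGE (device
# outline cut). Same-class XY features of one functional layer are grouped
# by height into one machining pass each.

#' DFM class of a placed component
#'
#' The class comes from the entity's registry definition: PORT is Z
#' (through-hole), VALVE3D is XYZ (spans the flow/control level), the
#' device outline is EDGE, and everything else defaults to XY.
#'
#' @param component A component record (or anything with `$entity`).
#' @return One of `"XY"`, `"XYZ"`, `"Z"`, `"EDGE"`.
#' @export
dfm_class_of <- function(component) {
  definition_of(component$entity)$dfm_class
}

# Rectangle polygon of one channel element (segment widened to the
# channel width), including square end caps so consecutive elements of a
# Manhattan path union cleanly at the corners.
segment_polygon <- function(a, b, width) {
  d <- b - a
  L <- sqrt(sum(d^2))
  if (L == 0) return(NULL)
  u <- d / L
  nvec <- c(-u[2], u[1]) * width / 2
  a2 <- a - u * width / 2
  b2 <- b + u * width / 2
  make_poly(rbind(a2 + nvec, b2 + nvec, b2 - nvec, a2 - nvec))
}

# All renderable features of a device: one record per polygon, with the
# concrete functional layer id, height, DFM class and owning id.
device_features <- function(device) {
  feats <- list()
  add <- function(poly, layer_id, height, dfm, owner, circle = NULL) {
    feats[[length(feats) + 1L]] <<- list(poly = poly, layer_id = layer_id,
                                         height = height, dfm = dfm,
                                         owner = owner, circle = circle)
  }
  for (comp in device$components) {
    if (is.null(comp$position)) {
      stop(sprintf("component '%s' is unplaced; run auto_place first", comp$id), call. = FALSE)
    }
    geom <- render_component(comp)
    for (f in geom$faces) {
      lid <- comp$layer_ids[[1]]
      if (length(comp$layer_ids) > 1) {
        # role-tagged faces of a level-spanning entity land on the
        # matching layer of its level
        for (l in comp$layer_ids) {
          ly <- layer_by_id(device, l)
          if (!is.null(ly) && ly$kind == f$role) lid <- l
        }
      }
      add(f$poly, lid, f$height, geom$dfm_class, comp$id, f$circle)
    }
  }
  for (conn in device$connections) {
    if (is.null(conn$path)) {
      stop(sprintf("connection '%s' is unrouted; run auto_place first", conn$id), call. = FALSE)
    }
    for (i in seq_len(nrow(conn$path) - 1L)) {
      sp <- segment_polygon(conn$path[i, ], conn$path[i + 1L, ], conn$channel_width)
      if (!is.null(sp)) add(sp, conn$layer_id, conn$height, "XY", conn$id)
    }
  }
  feats
}

#' Generate the 2.5D manufacturing layers of a device
#'
#' XY features are partitioned by (functional layer, height) — heights
#' compared after rounding to 0.1 um — one manufacturing layer per
#' non-empty group, with member polygons unioned. XYZ features join the
#' XY group matching each face's layer and height. All Z features of a
#' functional layer form one drill layer. An EDGE outline layer is the
#' device bounding box plus a margin when no explicit outline exists.
#'
#' @param device A valid, placed `mf_device`.
#' @param edge_margin Outline margin around the bounding box, um.
#' @return List of `mf_manufacturing_layer` objects: `functional_layer_id`,
#'   `dfm_class`, `height` (NA for Z/EDGE), `polygons`, `member_ids`,
#'   and `circles` for drill layers.
#' @export
generate_manufacturing_layers <- function(device, edge_margin = 2000) {
  rep <- validate_device(device)
  if (has_errors(rep)) {
    stop(paste0("device fails validation:\n",
                paste(rep$message[rep$severity == "error"], collapse = "\n")),
         call. = FALSE)
  }
  feats <- device_features(device)
  out <- list()
  mk <- function(layer_id, dfm, height, members) {
    structure(list(
      functional_layer_id = layer_id, dfm_class = dfm, height = height,
      polygons = union_polys(lapply(members, `[[`, "poly")),
      member_ids = sort(unique(vapply(members, `[[`, character(1), "owner"))),
      circles = Filter(Negate(is.null), lapply(members, `[[`, "circle"))
    ), class = "mf_manufacturing_layer")
  }
  plane <- Filter(function(f) f$dfm %in% c("XY", "XYZ"), feats)
  if (length(plane) > 0) {
    keys <- vapply(plane, function(f) sprintf("%s|%.1f", f$layer_id, round(f$height, 1)),
                   character(1))
    for (k in sort(unique(keys))) {
      members <- plane[keys == k]
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      out[[length(out) + 1L]] <- mk(parts[1], "XY", as.numeric(parts[2]), members)
    }
  }
  drills <- Filter(function(f) f$dfm == "Z", feats)
  if (length(drills) > 0) {
    lids <- vapply(drills, `[[`, character(1), "layer_id")
    for (l in sort(unique(lids))) {
      out[[length(out) + 1L]] <- mk(l, "Z", NA_real_, drills[lids == l])
    }
  }
  edges <- Filter(function(f) f$dfm == "EDGE", feats)
  if (length(edges) > 0) {
    out[[length(out) + 1L]] <- mk(edges[[1]]$layer_id, "EDGE", NA_real_, edges)
  } else if (length(feats) > 0) {
    bb <- rings_bbox(lapply(feats, function(f) f$poly$outer))
    ring <- rect_ring((bb[1] + bb[3]) / 2, (bb[2] + bb[4]) / 2,
                      bb[3] - bb[1] + 2 * edge_margin, bb[4] - bb[2] + 2 * edge_margin)
    out[[length(out) + 1L]] <- structure(list(
      functional_layer_id = device$layers[[1]]$id, dfm_class = "EDGE",
      height = NA_real_, polygons = list(make_poly(ring)),
      member_ids = character(0), circles = list()
    ), class = "mf_manufacturing_layer")
  }
  out
}

#' @export
print.mf_manufacturing_layer <- function(x, ...) {
  cat(sprintf("<mf_manufacturing_layer> %s %s%s: %d polygon(s), %d member(s)\n",
              x$functional_layer_id, x$dfm_class,
              if (is.na(x$height)) "" else sprintf(" h=%gum", x$height),
              length(x$polygons), length(x$member_ids)))
  invisible(x)
}

#' One-line-per-layer grouping report
#' @param layers Output of [generate_manufacturing_layers()].
#' @return A data frame summarising the grouping.
#' @export
manufacturing_report <- function(layers) {
  do.call(rbind, lapply(layers, function(l) {
    data.frame(functional_layer = l$functional_layer_id, dfm_class = l$dfm_class,
               height_um = l$height, n_polygons = length(l$polygons),
               n_members = length(l$member_ids),
               area_um2 = sum(vapply(l$polygons, poly_area, numeric(1))),
               stringsAsFactors = FALSE)
  }))
}
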