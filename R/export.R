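# Visual and manufacturing export: SVG (one group per functional layer,
# 1 user unit = 1 um, y flipped for screen display) and per-manufacturing-
# layer DXF in millimetres for CNC micro-milling.

svg_margin <- 500  # um of white space around the device bounding box

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a device drawing as SVG text
#'
#' One `<g>` group per functional layer (all of them, or the subset in
#' `layers`), FLOW and CONTROL distinguished by class. Faces without
#' holes become `<polygon>` elements; holed faces become even-odd
#' `<path>` elements. 1 SVG user unit = 1 um; the y axis is flipped so
#' the device's y-up frame displays upright.
#'
#' @param device A placed, valid `mf_device`.
#' @param layers Optional character vector of layer ids to include.
#' @return SVG document as a single string.
#' @export
export_svg <- function(device, layers = NULL) {
  for (comp in device$components) {
    if (is.null(comp$position)) {
      stop(sprintf("cannot export an unplaced device (component '%s'); run auto_place",
                   comp$id), call. = FALSE)
    }
  }
  feats <- device_features(device)
  keep <- vapply(device$layers, function(l) is.null(layers) || l$id %in% layers, logical(1))
  bb <- if (length(feats) > 0) rings_bbox(lapply(feats, function(f) f$poly$outer))
        else c(0, 0, 1000, 1000)
  x0 <- bb[1] - svg_margin; y1 <- bb[4] + svg_margin
  w <- bb[3] - bb[1] + 2 * svg_margin
  h <- bb[4] - bb[2] + 2 * svg_margin
  fy <- function(y) y1 - y                         # flip to screen coordinates
  pts_attr <- function(ring) {
    paste(sprintf("%.3f,%.3f", ring[, 1] - x0, fy(ring[, 2])), collapse = " ")
  }
  path_d <- function(poly) {
    ring_d <- function(r) {
      paste0("M ", paste(sprintf("%.3f %.3f", r[, 1] - x0, fy(r[, 2])), collapse = " L "), " Z")
    }
    paste(vapply(c(list(poly$outer), poly$holes), ring_d, character(1)), collapse = " ")
  }
  body <- character(0)
  for (i in seq_along(device$layers)) {
    if (!keep[i]) next
    l <- device$layers[[i]]
    cls <- tolower(l$kind)
    elems <- character(0)
    for (f in feats) {
      if (!identical(f$layer_id, l$id)) next
      elems <- c(elems, if (length(f$poly$holes) == 0) {
        sprintf('      <polygon points="%s"/>', pts_attr(f$poly$outer))
      } else {
        sprintf('      <path fill-rule="evenodd" d="%s"/>', path_d(f$poly))
      })
    }
    body <- c(body,
              sprintf('    <g id="%s" class="%s">', xml_escape(l$id), cls),
              elems, "    </g>")
  }
  paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.3f %.3f">',
            w, h, w, h),
    sprintf('  <title>%s</title>', xml_escape(device$name)),
    '  <style>.flow{fill:#3b6fb6;stroke:none}.control{fill:#c0392b;fill-opacity:0.75;stroke:none}</style>',
    body,
    '</svg>'), collapse = "\n")
}

#' Export manufacturing layers as DXF documents
#'
#' One DXF per manufacturing layer, coordinates in millimetres
#' (um / 1000), polygons as closed LWPOLYLINEs. Drill (Z-class) layers
#' export their port features as CIRCLE entities. Empty layers are
#' skipped with a warning.
#'
#' @param layers Output of [generate_manufacturing_layers()].
#' @param device_name Name used in the file-name pattern
#'   `<device>_<layer>_<class>[_<height>um].dxf`.
#' @param dir Optional directory: when given, files are written there and
#'   their paths returned; otherwise a named character vector of DXF
#'   texts is returned.
#' @return Named character vector (file name -> DXF text, or paths).
#' @export
export_dxf_layers <- function(layers, device_name = "device", dir = NULL) {
  out <- character(0)
  for (l in layers) {
    use_circles <- l$dfm_class == "Z" && length(l$circles) > 0
    if (length(l$polygons) == 0 && !use_circles) {
      warning(sprintf("manufacturing layer %s/%s is empty; skipped",
                      l$functional_layer_id, l$dfm_class))
      next
    }
    ents <- character(0)
    if (use_circles) {
      for (c0 in l$circles) {
        ents <- c(ents, dxf_circle(c0$center / 1000, c0$r / 1000))
      }
    } else {
      for (p in l$polygons) {
        for (r in c(list(p$outer), p$holes)) {
          ents <- c(ents, dxf_lwpolyline(r / 1000))
        }
      }
    }
    fname <- if (is.na(l$height)) {
      sprintf("%s_%s_%s.dxf", device_name, l$functional_layer_id, l$dfm_class)
    } else {
      sprintf("%s_%s_%s_%gum.dxf", device_name, l$functional_layer_id, l$dfm_class, l$height)
    }
    out[[fname]] <- dxf_document(ents)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(0)
    for (fname in names(out)) {
      p <- file.path(dir, fname)
      writeLines(out[[fname]], p)
      paths[[fname]] <- p
    }
    return(paths)
  }
  out
}
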