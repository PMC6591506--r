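# Minimal ASCII DXF (R12+) reader/writer covering the primitives needed
# for custom-component exchange with CAD tools: LINE, LWPOLYLINE,
# POLYLINE/VERTEX, ARC, CIRCLE and SPLINE (flattened through its fit or
# control points). Unsupported entity types are skipped with a warning
# report, never an error.

#' Parse the ENTITIES section of an ASCII DXF file
#'
#' @param path DXF file path.
#' @return A `DxfEntitySet`: list with `entities` (parsed primitive
#'   records, coordinates in drawing units) and `ignored` (types seen but
#'   not supported).
#' @export
read_dxf_entities <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) %% 2 == 1) lines <- lines[-length(lines)]
  codes <- suppressWarnings(as.integer(trimws(lines[seq(1, length(lines), 2)])))
  vals <- trimws(lines[seq(2, length(lines), 2)])
  if (anyNA(codes)) stop(sprintf("cannot parse '%s' as ASCII DXF (bad group code)", path),
                         call. = FALSE)
  # locate ENTITIES section
  in_entities <- FALSE
  recs <- list()          # list of list(type, codes, values)
  cur <- NULL
  for (k in seq_along(codes)) {
    c0 <- codes[k]; v <- vals[k]
    if (c0 == 0L && v == "SECTION") { cur <- NULL; next }
    if (c0 == 2L && v == "ENTITIES") { in_entities <- TRUE; next }
    if (c0 == 0L && v == "ENDSEC") { in_entities <- FALSE; cur <- NULL; next }
    if (!in_entities) next
    if (c0 == 0L) {
      cur <- list(type = v, codes = integer(0), values = character(0))
      recs[[length(recs) + 1L]] <- cur
    } else if (!is.null(cur)) {
      i <- length(recs)
      recs[[i]]$codes <- c(recs[[i]]$codes, c0)
      recs[[i]]$values <- c(recs[[i]]$values, v)
    }
  }
  nums <- function(rec, code) as.numeric(rec$values[rec$codes == code])
  entities <- list()
  ignored <- character(0)
  i <- 1L
  while (i <= length(recs)) {
    rec <- recs[[i]]
    ent <- switch(rec$type,
      LINE = list(type = "LINE",
                  start = c(nums(rec, 10)[1], nums(rec, 20)[1]),
                  end = c(nums(rec, 11)[1], nums(rec, 21)[1])),
      CIRCLE = list(type = "CIRCLE", center = c(nums(rec, 10)[1], nums(rec, 20)[1]),
                    r = nums(rec, 40)[1]),
      ARC = list(type = "ARC", center = c(nums(rec, 10)[1], nums(rec, 20)[1]),
                 r = nums(rec, 40)[1], a0 = nums(rec, 50)[1], a1 = nums(rec, 51)[1]),
      LWPOLYLINE = list(type = "POLYLINE",
                        points = cbind(nums(rec, 10), nums(rec, 20)),
                        closed = bitwAnd(as.integer(c(nums(rec, 70), 0)[1]), 1L) == 1L),
      POLYLINE = {
        flags <- as.integer(c(nums(rec, 70), 0)[1])
        pts <- NULL
        j <- i + 1L
        while (j <= length(recs) && recs[[j]]$type == "VERTEX") {
          pts <- rbind(pts, c(nums(recs[[j]], 10)[1], nums(recs[[j]], 20)[1]))
          j <- j + 1L
        }
        if (j <= length(recs) && recs[[j]]$type == "SEQEND") j <- j + 1L
        i <- j - 1L
        list(type = "POLYLINE", points = pts, closed = bitwAnd(flags, 1L) == 1L)
      },
      SPLINE = {
        fx <- nums(rec, 11); fy <- nums(rec, 21)
        pts <- if (length(fx) >= 2) cbind(fx, fy) else cbind(nums(rec, 10), nums(rec, 20))
        flags <- as.integer(c(nums(rec, 70), 0)[1])
        list(type = "POLYLINE", points = pts, closed = bitwAnd(flags, 1L) == 1L)
      },
      { ignored <- c(ignored, rec$type); NULL }
    )
    if (!is.null(ent)) {
      if (!all(is.finite(unlist(ent[names(ent) != "type"])))) {
        stop(sprintf("non-finite coordinates in DXF entity %s", rec$type), call. = FALSE)
      }
      entities[[length(entities) + 1L]] <- ent
    }
    i <- i + 1L
  }
  structure(list(entities = entities, ignored = unique(ignored)), class = "mf_dxf_entities")
}

arc_points <- function(center, r, a0, a1, res_deg = 5) {
  span <- (a1 - a0) %% 360
  if (span == 0) span <- 360
  n <- max(2L, ceiling(span / res_deg))
  th <- (a0 + seq(0, span, length.out = n + 1L)) * pi / 180
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

#' Infer closed polygons from loose DXF primitives
#'
#' Chains endpoint-adjacent segments (endpoints within `snap_tol` merge)
#' into closed rings; arcs are discretized; rings nested inside another
#' ring become its holes (even-odd parity). Open chains are reported, not
#' returned as polygons.
#'
#' @param dxf A `DxfEntitySet` from [read_dxf_entities()], or a bare list
#'   of entity records.
#' @param snap_tol Endpoint merge tolerance in drawing units; default
#'   1e-6 of the drawing bounding-box diagonal.
#' @param arc_res Arc discretization, degrees per segment.
#' @return List with `polygons` (list of outer-ring + holes), `open_chains`
#'   (point matrices that failed to close) and `ignored` entity types.
#' @export
infer_closed_shapes <- function(dxf, snap_tol = NULL, arc_res = 5) {
  entities <- if (inherits(dxf, "mf_dxf_entities")) dxf$entities else dxf
  ignored <- if (inherits(dxf, "mf_dxf_entities")) dxf$ignored else character(0)
  rings <- list()
  chains <- list()
  for (e in entities) {
    if (e$type == "LINE") {
      chains <- c(chains, list(rbind(e$start, e$end)))
    } else if (e$type == "CIRCLE") {
      rings <- c(rings, list(circle_ring(e$center[1], e$center[2], e$r,
                                         max(8L, as.integer(360 / arc_res)))))
    } else if (e$type == "ARC") {
      chains <- c(chains, list(arc_points(e$center, e$r, e$a0, e$a1, arc_res)))
    } else if (e$type == "POLYLINE") {
      if (is.null(e$points) || nrow(e$points) < 2) next
      if (isTRUE(e$closed) && nrow(e$points) >= 3) {
        rings <- c(rings, list(e$points))
      } else {
        chains <- c(chains, list(e$points))
      }
    }
  }
  if (is.null(snap_tol)) {
    all_pts <- do.call(rbind, c(chains, rings))
    snap_tol <- if (is.null(all_pts) || nrow(all_pts) == 0) 1e-6 else {
      bb <- rings_bbox(list(all_pts))
      max(1e-12, 1e-6 * sqrt((bb[3] - bb[1])^2 + (bb[4] - bb[2])^2))
    }
  }
  if (snap_tol <= 0) stop("snap_tol must be > 0", call. = FALSE)

  near <- function(a, b) sqrt(sum((a - b)^2)) <= snap_tol
  # iteratively merge chains sharing an endpoint; close when ends meet
  repeat {
    merged <- FALSE
    # first close any chain whose own endpoints coincide
    k <- 1L
    while (k <= length(chains)) {
      ch <- chains[[k]]
      if (nrow(ch) >= 4 && near(ch[1, ], ch[nrow(ch), ])) {
        rings <- c(rings, list(ch[-nrow(ch), , drop = FALSE]))
        chains[[k]] <- NULL
        merged <- TRUE
      } else k <- k + 1L
    }
    if (length(chains) >= 2) {
      done <- FALSE
      for (a in seq_along(chains)) {
        if (done) break
        for (b in seq_along(chains)) {
          if (a == b) next
          A <- chains[[a]]; B <- chains[[b]]
          joined <- NULL
          if (near(A[nrow(A), ], B[1, ])) joined <- rbind(A, B[-1, , drop = FALSE])
          else if (near(A[nrow(A), ], B[nrow(B), ]))
            joined <- rbind(A, B[rev(seq_len(nrow(B) - 1L)), , drop = FALSE])
          else if (near(A[1, ], B[nrow(B), ])) joined <- rbind(B, A[-1, , drop = FALSE])
          else if (near(A[1, ], B[1, ]))
            joined <- rbind(B[rev(seq_len(nrow(B))), , drop = FALSE], A[-1, , drop = FALSE])
          if (!is.null(joined)) {
            chains[[a]] <- joined
            chains[[b]] <- NULL
            merged <- TRUE; done <- TRUE
            break
          }
        }
      }
    }
    if (!merged) break
  }
  polys <- rings_to_polys(rings)
  list(polygons = polys, open_chains = chains, ignored = ignored)
}

#' Import a DXF drawing as a custom component entity
#'
#' Reads the drawing, infers its closed shapes, scales drawing units to
#' micrometres and registers the result as a placeable entity.
#'
#' @param path DXF file.
#' @param key New entity key.
#' @param dfm_class Design-for-manufacturing class of the imported
#'   geometry, default `"XY"`.
#' @param unit_scale Micrometres per drawing unit; default 1000
#'   (1 drawing unit = 1 mm).
#' @param port_spec Optional port layout (see [register_custom_entity()]),
#'   in drawing units.
#' @return The registered `mf_component_definition`, invisibly.
#' @export
import_dxf_component <- function(path, key, dfm_class = "XY", unit_scale = 1000,
                                 port_spec = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read DXF file '%s'", path), call. = FALSE)
  shapes <- infer_closed_shapes(read_dxf_entities(path))
  if (length(shapes$polygons) == 0) {
    stop(sprintf("no closed shapes inferred from '%s'", path), call. = FALSE)
  }
  polys <- lapply(shapes$polygons, function(p) {
    list(outer = p$outer * unit_scale, holes = lapply(p$holes, `*`, unit_scale))
  })
  if (!is.null(port_spec)) {
    port_spec$x <- port_spec$x * unit_scale
    port_spec$y <- port_spec$y * unit_scale
  }
  register_custom_entity(key, polys, port_spec = port_spec, dfm_class = dfm_class)
}

# ---- writing -------------------------------------------------------------

fmt_num <- function(x) {
  s <- formatC(x, format = "f", digits = 6)
  s
}

dxf_lwpolyline <- function(ring, layer = "0") {
  c("0", "LWPOLYLINE", "8", layer, "90", as.character(nrow(ring)), "70", "1",
    unlist(lapply(seq_len(nrow(ring)), function(i) {
      c("10", fmt_num(ring[i, 1]), "20", fmt_num(ring[i, 2]))
    })))
}

dxf_circle <- function(center, r, layer = "0") {
  c("0", "CIRCLE", "8", layer, "10", fmt_num(center[1]), "20", fmt_num(center[2]),
    "40", fmt_num(r))
}

#' Assemble a DXF document from pre-built entity chunks
#' @keywords internal
dxf_document <- function(entity_lines) {
  paste(c("0", "SECTION", "2", "ENTITIES", entity_lines, "0", "ENDSEC", "0", "EOF"),
        collapse = "\n")
}
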