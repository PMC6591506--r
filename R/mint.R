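# Minimal MINT-style netlist import. The accepted language is a
# documented subset of the MINT microfluidic hardware-description
# language, sufficient for component/channel/valve netlists:
#
#   program    := "DEVICE" name { layerblock }
#   layerblock := "LAYER" ("FLOW" | "CONTROL") { statement } "END" "LAYER"
#   statement  := entity id { param "=" number } ";"
#               | "CHANNEL" id "from" id port "to" id port { param "=" number } ";"
#               | "VALVE" id "on" channel-id { param "=" number } ";"
#
# Channel parameter `w` is the channel width in micrometres (`h` its
# height). Imported devices are unplaced: run auto_place() before any
# geometry, export or simulation operation.

mint_error <- function(line_no, col, msg) {
  stop(sprintf("MINT syntax error at line %d, column %d: %s", line_no, col, msg),
       call. = FALSE)
}

mint_tokens <- function(line) {
  strsplit(trimws(line), "[[:space:]]+")[[1]]
}

#' Parse a MINT-subset netlist into an unplaced device
#'
#' Components get null positions, channels empty paths, and valve
#' statements populate the valve map; call [auto_place()] before geometry
#' operations.
#'
#' @param text The program, as a single string or character vector of
#'   lines; a path to a `.mint` file also works.
#' @return An unplaced `mf_device`.
#' @export
parse_mint <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  dev <- NULL
  cur_layer <- NULL
  valve_stmts <- list()
  semantic <- function(line_no, msg) {
    stop(sprintf("MINT semantic error at line %d: %s", line_no, msg), call. = FALSE)
  }
  parse_params <- function(toks, line_no) {
    out <- list()
    for (t in toks) {
      m <- regmatches(t, regexec("^([A-Za-z][A-Za-z0-9]*)=(-?[0-9.]+)$", t))[[1]]
      if (length(m) == 0) mint_error(line_no, 1L, sprintf("expected name=value, got '%s'", t))
      out[[m[2]]] <- as.numeric(m[3])
    }
    out
  }
  for (ln in seq_along(lines)) {
    toks <- mint_tokens(lines[ln])
    if (length(toks) == 0 || (length(toks) == 1 && !nzchar(toks[1]))) next
    kw <- toupper(toks[1])
    if (kw == "DEVICE") {
      if (length(toks) < 2) mint_error(ln, 8L, "DEVICE needs a name")
      if (!is.null(dev)) mint_error(ln, 1L, "duplicate DEVICE declaration")
      dev <- create_device(toks[2])
      next
    }
    if (is.null(dev)) mint_error(ln, 1L, "program must start with DEVICE <name>")
    if (kw == "LAYER") {
      if (length(toks) < 2 || !toupper(toks[2]) %in% c("FLOW", "CONTROL")) {
        mint_error(ln, 7L, "LAYER must be FLOW or CONTROL")
      }
      kind <- toupper(toks[2])
      if (kind == "FLOW" || length(dev$layers) == 0) {
        if (kind == "FLOW" || length(dev$layers) == 0) {
          # a FLOW block opens a new level; a CONTROL block with no level
          # yet opens level 0
          if (kind == "FLOW" || length(dev$layers) == 0) dev <- add_level(dev)
        }
      }
      lvl <- max(vapply(dev$layers, `[[`, numeric(1), "level"))
      cur_layer <- Filter(function(l) l$level == lvl && l$kind == kind, dev$layers)[[1]]$id
      next
    }
    if (kw == "END") {
      cur_layer <- NULL
      next
    }
    if (is.null(cur_layer)) mint_error(ln, 1L, "statement outside a LAYER block")
    if (length(toks) < 2) mint_error(ln, 1L, "statement needs an id")
    if (toks[length(toks)] != ";") mint_error(ln, nchar(lines[ln]), "statement must end with ';'")
    toks <- toks[-length(toks)]
    id <- toks[2]
    if (kw == "CHANNEL") {
      if (length(toks) < 8 || tolower(toks[3]) != "from" || tolower(toks[6]) != "to") {
        mint_error(ln, 1L, "CHANNEL syntax: CHANNEL id from <comp> <port> to <comp> <port> w=<um> ;")
      }
      p <- parse_params(toks[-(1:8)], ln)
      for (cid in c(toks[4], toks[7])) {
        if (is.null(dev$components[[cid]])) {
          semantic(ln, sprintf("channel '%s' references undeclared component '%s'", id, cid))
        }
      }
      dev <- tryCatch(
        add_connection(dev, cur_layer, term(toks[4], toks[5]),
                       list(term(toks[7], toks[8])),
                       channel_width = p$w %||% 400, height = p$h %||% 100, id = id),
        error = function(e) semantic(ln, conditionMessage(e)))
    } else if (kw == "VALVE" && length(toks) >= 3 && tolower(toks[3]) == "on") {
      if (length(toks) < 4) mint_error(ln, 1L, "VALVE syntax: VALVE id on <channel> ;")
      if (is.null(dev$connections[[toks[4]]])) {
        semantic(ln, sprintf("valve '%s' references undeclared channel '%s'", id, toks[4]))
      }
      p <- parse_params(toks[-(1:4)], ln)
      dev <- tryCatch(
        place_component(dev, "VALVE", params = p, position = NULL,
                        layer_id = cur_layer, id = id),
        error = function(e) semantic(ln, conditionMessage(e)))
      dev$valve_map[[id]] <- toks[4]
    } else {
      entity <- kw
      ok <- tryCatch({ definition_of(entity); TRUE },
                     error = function(e) semantic(ln, conditionMessage(e)))
      p <- parse_params(toks[-(1:2)], ln)
      dev <- tryCatch(
        place_component(dev, entity, params = p, position = NULL,
                        layer_id = cur_layer, id = id),
        error = function(e) semantic(ln, conditionMessage(e)))
    }
  }
  if (is.null(dev)) mint_error(1L, 1L, "empty program")
  strip_op_attrs(dev)
}

component_extent <- function(comp) {
  geom <- render_component(c(comp[c("entity", "params")],
                             list(position = c(0, 0), rotation = comp$rotation %||% 0)))
  bb <- rings_bbox(lapply(geom$faces, function(f) f$poly$outer))
  max(bb[3] - bb[1], bb[4] - bb[2])
}

#' Grid-place the unplaced components of a device
#'
#' Components without positions are assigned row-major grid positions
#' with the given pitch, in declaration order; already-placed components
#' are untouched. Unrouted connections then get two-segment Manhattan
#' paths, and mapped valves are re-aligned onto their channels.
#'
#' @param device An `mf_device`, possibly from [parse_mint()].
#' @param pitch Grid pitch in micrometres; must be at least the largest
#'   unplaced component's bounding-box extent.
#' @param ncol Components per grid row; default puts everything in one row.
#' @return A placed device passing validation.
#' @export
auto_place <- function(device, pitch = 10000, ncol = Inf) {
  unplaced <- Filter(function(c) is.null(c$position), device$components)
  if (length(unplaced) > 0) {
    ext <- vapply(unplaced, component_extent, numeric(1))
    if (pitch < max(ext)) {
      stop(sprintf("pitch %g um is smaller than the largest component extent (%g um, '%s')",
                   pitch, max(ext), names(unplaced)[which.max(ext)]), call. = FALSE)
    }
    k <- 0L
    for (id in names(unplaced)) {
      col <- k %% min(ncol, length(unplaced))
      row <- k %/% min(ncol, length(unplaced))
      device$components[[id]]$position <- c(col * pitch, row * pitch)
      k <- k + 1L
    }
  }
  for (cid in names(device$connections)) {
    conn <- device$connections[[cid]]
    if (!is.null(conn$path)) next
    src <- resolve_terminal(device, conn$source)
    snk <- resolve_terminal(device, conn$sinks[[1]])
    device$connections[[cid]]$path <- manhattan_path(src$position, snk$position)
  }
  for (vid in names(device$valve_map)) {
    device <- map_valve(device, vid, device$valve_map[[vid]])
  }
  strip_op_attrs(device)
}
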