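# Quantitative design-effort model. Effort is a heuristic count of the
# user actions needed to draw (E_Design) and parameterize
# (E_Parameterization) a design element in a given environment:
#
#   E_Design           = C_Base * f_Procedural(X)
#   E_Parameterization = C_Identification + N_Params * (C_Constraint + C_Value)
#   E_Primitive        = E_Design + E_Parameterization
#   E_Total            = sum of E_Primitive over the device
#
# f_Procedural captures how drawing difficulty scales with the size
# parameter X of a procedurally generated geometry: constant (f = 1),
# linear (f = coef * X, e.g. a serpentine mixer in its bend count) or
# polynomial (f = coef * X^degree, e.g. a multiplexer tree in its output
# count). CAD mode models manual drafting; TOOL mode models placement in
# a parametric design environment (one action plus one per parameter the
# user actually edits).

#' Load design-effort constants
#'
#' @param path JSON constants file; `NULL` loads the shipped registry,
#'   which carries the published MIXER calibration (C_Base = 6,
#'   C_Identification = 20, C_Value = 4, identity f at X = numberOfBends)
#'   and documented library choices for the other entities.
#' @return An `mf_effort_constants` object.
#' @export
effort_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "effort_constants.json", package = "mfda", mustWork = TRUE)
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(list(modes = cfg$modes,
                 include_connections = isTRUE(cfg$include_connections)),
            class = "mf_effort_constants")
}

resolve_entry <- function(constants, entity, mode) {
  m <- constants$modes[[mode]]
  if (is.null(m)) stop(sprintf("no effort constants for mode '%s'", mode), call. = FALSE)
  e <- m[[entity]] %||% m[["default"]]
  if (is.null(e) && entity %in% list_entities() && isTRUE(definition_of(entity)$custom)) {
    e <- m[["CUSTOM"]]
  }
  if (is.null(e)) {
    stop(sprintf("no effort constants for entity '%s' in mode '%s'", entity, mode),
         call. = FALSE)
  }
  e
}

f_procedural <- function(f, X) {
  switch(f$class,
    constant = 1,
    linear = (f$coef %||% 1) * X,
    polynomial = (f$coef %||% 1) * X^(f$degree %||% 2),
    stop(sprintf("unknown f_Procedural class '%s'", f$class), call. = FALSE)
  )
}

#' Drawing effort of an entity: E_Design = C_Base * f_Procedural(X)
#'
#' @param entity Entity key (or `"CHANNEL"` for connections).
#' @param X Size parameter of the procedural geometry (bend count, output
#'   count, element count); ignored for constant-difficulty entities.
#' @param constants An [effort_constants()] object.
#' @param mode `"CAD"` or `"TOOL"`.
#' @return Effort in actions.
#' @export
effort_design <- function(entity, X = 0, constants = effort_constants(), mode = "CAD") {
  if (X < 0) stop("size parameter X must be >= 0", call. = FALSE)
  e <- resolve_entry(constants, entity, mode)
  as.numeric(e$c_base) * as.numeric(f_procedural(e$f, X))
}

#' Parameterization effort: C_Identification + N_Params (C_Constraint + C_Value)
#'
#' @inheritParams effort_design
#' @param n_params Override of N_Params; default is the entity's entry in
#'   the constants registry.
#' @return Effort in actions.
#' @export
effort_parameterization <- function(entity, constants = effort_constants(),
                                    mode = "CAD", n_params = NULL) {
  e <- resolve_entry(constants, entity, mode)
  n <- n_params %||% e$n_params %||% 0
  as.numeric(e$c_identification) + as.numeric(n) *
    (as.numeric(e$c_constraint) + as.numeric(e$c_value))
}

n_changed_params <- function(component) {
  def <- definition_of(component$entity)
  pd <- def$param_defs
  sum(vapply(seq_len(nrow(pd)), function(i) {
    v <- component$params[[pd$name[i]]]
    !is.null(v) && v != pd$default[i]
  }, logical(1)))
}

#' Effort to create one placed component
#'
#' In CAD mode N_Params comes from the constants registry; in TOOL mode it
#' is the number of parameters the user actually edited away from the
#' library defaults.
#'
#' @param component A component record from a device.
#' @inheritParams effort_design
#' @return One-row data frame: `id`, `entity`, `e_design`,
#'   `e_parameterization`, `e_primitive` (actions).
#' @export
effort_component <- function(component, constants = effort_constants(), mode = "CAD") {
  e <- resolve_entry(constants, component$entity, mode)
  X <- 0
  if (!is.null(e$size_param)) X <- component$params[[e$size_param]] %||% 0
  n_params <- if (mode == "TOOL") n_changed_params(component) else NULL
  ed <- effort_design(component$entity, X, constants, mode)
  ep <- effort_parameterization(component$entity, constants, mode, n_params = n_params)
  data.frame(id = component$id %||% "", entity = component$entity,
             e_design = ed, e_parameterization = ep, e_primitive = ed + ep,
             stringsAsFactors = FALSE)
}

effort_connection <- function(conn, constants, mode) {
  n_el <- if (is.null(conn$path)) length(conn$sinks) else nrow(conn$path) - 1L
  if (mode == "TOOL") {
    ed <- effort_design("CHANNEL", n_el, constants, mode)
    ep <- effort_parameterization("CHANNEL", constants, mode, n_params = 1)
  } else {
    ed <- effort_design("CHANNEL", n_el, constants, mode)
    ep <- effort_parameterization("CHANNEL", constants, mode)
  }
  data.frame(id = conn$id, entity = "CHANNEL",
             e_design = ed, e_parameterization = ep, e_primitive = ed + ep,
             stringsAsFactors = FALSE)
}

#' Effort to create a whole device: E_Total = sum of E_Primitive
#'
#' Sums the per-component efforts; connections contribute through a
#' CHANNEL pseudo-entity whose drawing effort is linear in the channel
#' element count (toggleable via `include_connections`).
#'
#' @param device An `mf_device`.
#' @inheritParams effort_design
#' @param include_connections Count connection effort; defaults to the
#'   registry setting.
#' @return An `mf_effort_report`: `rows` (per-element breakdown) and
#'   `e_total` (actions).
#' @export
effort_device <- function(device, constants = effort_constants(), mode = "CAD",
                          include_connections = NULL) {
  inc <- include_connections %||% constants$include_connections
  rows <- lapply(device$components, effort_component, constants = constants, mode = mode)
  if (inc) {
    rows <- c(rows, lapply(device$connections, effort_connection,
                           constants = constants, mode = mode))
  }
  rows <- if (length(rows) == 0) {
    data.frame(id = character(0), entity = character(0), e_design = numeric(0),
               e_parameterization = numeric(0), e_primitive = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  structure(list(rows = rows, e_total = sum(rows$e_primitive), mode = mode),
            class = "mf_effort_report")
}

#' @export
print.mf_effort_report <- function(x, ...) {
  cat(sprintf("Design effort (%s mode), in actions:\n", x$mode))
  print(x$rows, row.names = FALSE)
  cat(sprintf("E_Total = %g actions\n", x$e_total))
  invisible(x)
}
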