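# Deterministic synthetic device generation, for tests, demos and the
# CLI `fixture` command. random_device() draws a seeded netlist on one
# flow/control level; build_daridon_style_fixture() scripts a workflow in
# the style of a published single-cell-trap device: port arrays, a custom
# trap imported from DXF, chambers, a mixer, flow plumbing, and a control
# layer with mapped membrane valves.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

random_params <- function(entity) {
  switch(entity,
    PORT = list(portRadius = 100 * sample(5:9, 1)),
    MIXER = list(numberOfBends = sample(1:4, 1),
                 bendLength = 100 * sample(10:30, 1),
                 bendSpacing = 100 * sample(2:6, 1),
                 channelWidth = 50 * sample(2:6, 1)),
    CHAMBER = list(width = 100 * sample(10:30, 1), length = 100 * sample(10:30, 1)),
    MUX = list(outputs = sample1(c(2, 4)), spacing = 1000, stageHeight = 1000,
               channelWidth = 200),
    VALVE = list(length = 100 * sample(8:14, 1), width = 100 * sample(3:6, 1)),
    list()
  )
}

flow_ports_of <- function(device, id) {
  ps <- component_ports(device, id)
  ps$label[ps$role %in% c("FLOW", "ANY")]
}

#' Generate a seeded random device
#'
#' Draws `n_components` entities from the weight mix, grid-places flow
#' entities on the flow layer and valves on the control layer, wires the
#' flow components with a random spanning tree plus `density` extra
#' Manhattan channels per flow component, and maps each valve onto a
#' random flow channel. The seed fully determines the output; the result
#' always passes [validate_device()] with no errors.
#'
#' @param n_components Total components to draw (>= 1).
#' @param weights Named entity mix weights; valves come from the VALVE
#'   weight, everything else is placed on the flow layer.
#' @param density Extra channels per flow component beyond the spanning
#'   tree.
#' @param seed Integer seed.
#' @return A placed `mf_device`.
#' @export
random_device <- function(n_components = 20,
                          weights = c(PORT = 0.35, MIXER = 0.2, CHAMBER = 0.2,
                                      MUX = 0.1, VALVE = 0.15),
                          density = 0.3, seed = 1) {
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  with_seed(seed, {
    dev <- create_device(sprintf("random_%d", seed))
    dev <- add_level(dev)
    entities <- sample(names(weights), n_components, replace = TRUE, prob = weights)
    flow_ids <- character(0)
    valve_ids <- character(0)
    pitch <- 10000
    k_flow <- 0L; k_ctrl <- 0L
    ncols <- max(1L, ceiling(sqrt(n_components)))
    for (e in entities) {
      p <- random_params(e)
      if (e == "VALVE") {
        pos <- c((k_ctrl %% ncols) * pitch + pitch / 2, (k_ctrl %/% ncols) * pitch + pitch / 2)
        dev <- place_component(dev, e, p, pos, 0, "control_0")
        valve_ids <- c(valve_ids, attr(dev, "id"))
        k_ctrl <- k_ctrl + 1L
      } else {
        pos <- c((k_flow %% ncols) * pitch, (k_flow %/% ncols) * pitch)
        dev <- place_component(dev, e, p, pos, 0, "flow_0")
        flow_ids <- c(flow_ids, attr(dev, "id"))
        k_flow <- k_flow + 1L
      }
    }
    n_flow <- length(flow_ids)
    n_extra <- floor(density * n_flow)
    max_edges <- n_flow * (n_flow - 1) / 2
    if (n_flow >= 2 && (n_flow - 1 + n_extra) > max_edges) {
      stop(sprintf("infeasible connection density %g for %d flow components",
                   density, n_flow), call. = FALSE)
    }
    conn_ids <- character(0)
    if (n_flow >= 2) {
      for (i in 2:n_flow) {
        j <- if (i == 2) 1L else sample.int(i - 1L, 1L)
        sp <- sample1(flow_ports_of(dev, flow_ids[j]))
        tp <- sample1(flow_ports_of(dev, flow_ids[i]))
        dev <- add_connection(dev, "flow_0", term(flow_ids[j], sp),
                              list(term(flow_ids[i], tp)),
                              channel_width = 100 * sample(2:4, 1))
        conn_ids <- c(conn_ids, attr(dev, "id"))
      }
      for (k in seq_len(n_extra)) {
        ij <- sample.int(n_flow, 2L)
        sp <- sample1(flow_ports_of(dev, flow_ids[ij[1]]))
        tp <- sample1(flow_ports_of(dev, flow_ids[ij[2]]))
        dev <- add_connection(dev, "flow_0", term(flow_ids[ij[1]], sp),
                              list(term(flow_ids[ij[2]], tp)),
                              channel_width = 100 * sample(2:4, 1))
        conn_ids <- c(conn_ids, attr(dev, "id"))
      }
    }
    if (length(conn_ids) > 0) {
      for (v in valve_ids) {
        dev <- map_valve(dev, v, sample1(conn_ids))
      }
    }
    strip_op_attrs(dev)
  })
}

ensure_trap_entity <- function() {
  if (!"CELL_TRAP" %in% list_entities()) {
    import_dxf_component(
      system.file("extdata", "cell_trap_synthetic.dxf", package = "mfda", mustWork = TRUE),
      key = "CELL_TRAP", dfm_class = "XY", unit_scale = 1000)
  }
  invisible("CELL_TRAP")
}

#' Scripted single-cell-trap style device
#'
#' A compact reconstruction of a trap-chip workflow: a uniformly spaced
#' PORT array, a custom cell-trap entity imported from a bundled
#' synthetic DXF drawing, a reaction chamber and serpentine mixer on the
#' flow layer, and a control layer carrying ports, a pump, a membrane
#' valve aligned onto a flow channel and a level-spanning valve that
#' splits its channel at the seat. It exercises every core modelling
#' operation and passes validation with no errors.
#'
#' @return A placed `mf_device`.
#' @export
build_daridon_style_fixture <- function() {
  ensure_trap_entity()
  dev <- create_device("daridon_style")
  dev <- add_level(dev)
  # inlet port array along the bottom of the flow layer
  dev <- place_component(dev, "PORT", list(portRadius = 500), c(0, 0), 0, "flow_0",
                         id = "in_1")
  dev <- generate_array(dev, "in_1", 3, 4000, 0)
  ins <- c("in_1", attr(dev, "ids"))
  dev <- place_component(dev, "CELL_TRAP", list(), c(4000, 8000), 0, "flow_0",
                         id = "trap_1")
  dev <- place_component(dev, "CHAMBER", list(width = 2000, length = 3000),
                         c(12000, 8000), 0, "flow_0", id = "chamber_1")
  dev <- place_component(dev, "MIXER",
                         list(numberOfBends = 3, bendLength = 3000,
                              bendSpacing = 400, channelWidth = 200),
                         c(20000, 8000), 0, "flow_0", id = "mixer_1")
  dev <- place_component(dev, "PORT", list(portRadius = 500), c(28000, 8000), 0,
                         "flow_0", id = "out_1")
  dev <- add_connection(dev, "flow_0", term(ins[1], "p"), term("trap_1", "in"),
                        channel_width = 200, id = "c_in_trap")
  dev <- add_connection(dev, "flow_0", term("trap_1", "out"), term("chamber_1", "in"),
                        channel_width = 200, id = "c_trap_chamber")
  dev <- add_connection(dev, "flow_0", term("chamber_1", "out"), term("mixer_1", "in"),
                        channel_width = 200, id = "c_chamber_mixer")
  dev <- add_connection(dev, "flow_0", term("mixer_1", "out"), term("out_1", "p"),
                        channel_width = 200, id = "c_mixer_out")
  dev <- add_connection(dev, "flow_0", term(ins[2], "p"), term("chamber_1", "in"),
                        channel_width = 200, id = "c_in2_chamber")
  # control layer: supply ports, a pump, and two valves on flow channels
  dev <- place_component(dev, "PORT", list(portRadius = 500), c(0, -6000), 0,
                         "control_0", id = "cport_1")
  dev <- place_component(dev, "PORT", list(portRadius = 500), c(8000, -6000), 0,
                         "control_0", id = "cport_2")
  dev <- place_component(dev, "PUMP", list(), c(16000, -6000), 0, "control_0",
                         id = "pump_1")
  dev <- place_component(dev, "VALVE", list(), c(6000, 7000), 0, "control_0",
                         id = "valve_1")
  dev <- map_valve(dev, "valve_1", "c_trap_chamber")
  dev <- place_component(dev, "VALVE3D", list(valveRadius = 500), c(24000, 7000), 0,
                         "control_0", id = "valve3d_1")
  dev <- map_valve(dev, "valve3d_1", "c_mixer_out")
  dev <- add_connection(dev, "control_0", term("cport_1", "p"), term("valve_1", "c"),
                        channel_width = 200, id = "cc_1")
  dev <- add_connection(dev, "control_0", term("cport_2", "p"), term("valve3d_1", "c"),
                        channel_width = 200, id = "cc_2")
  dev <- add_connection(dev, "control_0", term("cport_2", "p"), term("pump_1", "c2"),
                        channel_width = 200, id = "cc_3")
  strip_op_attrs(dev)
}
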