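# Shared device fixtures, all built in code.

two_port_channel <- function(gap_um = 1000, width = 100, height = 100) {
  d <- create_device("two_port")
  d <- add_level(d)
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0", id = "p1")
  d <- place_component(d, "PORT", list(), c(gap_um, 0), 0, "flow_0", id = "p2")
  d <- add_connection(d, "flow_0", term("p1", "p"), term("p2", "p"),
                      channel_width = width, height = height, id = "ch")
  d
}

# the documented MINT-subset example (also shown in the vignette)
mint_example_program <- function() {
  c("DEVICE mint_demo",
    "LAYER FLOW",
    "  MIXER m1 numberOfBends=4 bendLength=2000 ;",
    "  PORT p1 ;",
    "  PORT p2 ;",
    "  CHANNEL c1 from p1 p to m1 in w=400 ;",
    "  CHANNEL c2 from m1 out to p2 p w=400 ;",
    "END LAYER",
    "LAYER CONTROL",
    "  VALVE v1 on c1 ;",
    "END LAYER")
}

# flow layer carrying two feature heights (channels at 100 um, a chamber
# at 400 um) plus two through-hole ports
mixed_height_device <- function() {
  d <- create_device("heights")
  d <- add_level(d)
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0", id = "p1")
  d <- place_component(d, "PORT", list(), c(20000, 0), 0, "flow_0", id = "p2")
  d <- place_component(d, "CHAMBER", list(width = 2000, length = 2000, height = 400),
                       c(10000, 0), 0, "flow_0", id = "chamber_1")
  d <- add_connection(d, "flow_0", term("p1", "p"), term("chamber_1", "in"),
                      channel_width = 200, height = 100, id = "c1")
  d <- add_connection(d, "flow_0", term("chamber_1", "out"), term("p2", "p"),
                      channel_width = 200, height = 100, id = "c2")
  d
}

# 4 LINE entities forming the unit square, in drawing units
unit_square_entities <- function() {
  list(
    list(type = "LINE", start = c(0, 0), end = c(1, 0)),
    list(type = "LINE", start = c(1, 0), end = c(1, 1)),
    list(type = "LINE", start = c(1, 1), end = c(0, 1)),
    list(type = "LINE", start = c(0, 1), end = c(0, 0))
  )
}

# 10x10 square containing a 4x4 square (a hole): net area 84
nested_square_entities <- function() {
  c(unit_square_scaled(10, 0), unit_square_scaled(4, 3))
}

unit_square_scaled <- function(s, off) {
  list(
    list(type = "LINE", start = c(off, off), end = c(off + s, off)),
    list(type = "LINE", start = c(off + s, off), end = c(off + s, off + s)),
    list(type = "LINE", start = c(off + s, off + s), end = c(off, off + s)),
    list(type = "LINE", start = c(off, off + s), end = c(off, off))
  )
}

# fresh registry for tests that register custom entities
reset_registry <- function() load_entity_registry()
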