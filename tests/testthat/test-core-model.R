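# Device container, layers, placement, connections, valve mapping,
# validation and statistics.

test_that("device construction and layer pairing", {
  d <- create_device("demo")
  expect_s3_class(d, "mf_device")
  expect_identical(unname(device_stats(d)), c(0L, 0L))
  expect_error(create_device(""), "non-empty")

  d <- add_level(d)
  kinds <- vapply(d$layers, `[[`, character(1), "kind")
  levels <- vapply(d$layers, `[[`, numeric(1), "level")
  expect_identical(kinds, c("FLOW", "CONTROL"))
  expect_identical(levels, c(0, 0))

  d <- add_level(d)
  expect_length(d$layers, 4L)
  expect_setequal(vapply(d$layers, `[[`, numeric(1), "level"), c(0, 1))

  for (i in 1:3) d <- add_level(d)
  expect_identical(nrow(validate_device(d)), 0L)  # pairing invariant by construction
})

test_that("place_component resolves ports, validates params and layer kinds", {
  d <- add_level(create_device("demo"))
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0")
  id <- attr(d, "id")
  ps <- component_ports(d, id)
  expect_identical(nrow(ps), 1L)
  expect_equal(c(ps$x, ps$y), c(0, 0))

  expect_error(place_component(d, "MIXER", list(numberOfBends = 0), c(0, 0), 0, "flow_0"),
               "numberOfBends")
  expect_error(place_component(d, "NOPE", list(), c(0, 0), 0, "flow_0"), "unknown entity")
  expect_error(place_component(d, "PORT", list(), c(0, 0), 0, "flow_9"), "no layer")

  # control-functional entity on a FLOW layer: accepted, flagged as warning
  d <- place_component(d, "VALVE", list(), c(500, 500), 0, "flow_0")
  rep <- validate_device(d)
  expect_false(has_errors <- any(rep$severity == "error"))
  expect_true(any(rep$code == "layer_kind" & rep$severity == "warning"))
})

test_that("generate_array replicates along an arithmetic progression", {
  d <- add_level(create_device("demo"))
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0", id = "p0")
  d <- generate_array(d, "p0", 7, 1000, 0)
  ids <- attr(d, "ids")
  expect_length(ids, 7L)
  xs <- vapply(ids, function(i) d$components[[i]]$position[1], numeric(1))
  expect_equal(unname(xs), seq(1000, 7000, by = 1000))
  expect_identical(unname(device_stats(d)[["n_components"]]), 8L)

  d <- place_component(d, "MIXER", list(numberOfBends = 2), c(0, 20000), 0, "flow_0", id = "m")
  d <- generate_array(d, "m", 1, 0, 5000)
  copy <- d$components[[attr(d, "ids")[1]]]
  expect_identical(copy$params, d$components[["m"]]$params)
  expect_error(generate_array(d, "m", 0, 0, 1000), "n_copies")
})

test_that("add_connection builds Manhattan paths and checks terminals", {
  d <- add_level(create_device("demo"))
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0", id = "a")
  d <- place_component(d, "PORT", list(), c(1000, 1000), 0, "flow_0", id = "b")
  d <- add_connection(d, "flow_0", term("a", "p"), term("b", "p"), id = "c")
  expect_equal(d$connections[["c"]]$path,
               rbind(c(0, 0), c(1000, 0), c(1000, 1000)))

  # sink on a different layer is a reference error
  d2 <- place_component(d, "PORT", list(), c(2000, 0), 0, "control_0", id = "cport")
  expect_error(add_connection(d2, "flow_0", term("a", "p"), term("cport", "p")),
               "not on layer")
  expect_error(add_connection(d, "flow_0", term("a", "p"), term("a", "p")),
               "same terminal")
  expect_error(add_connection(d, "flow_0", term("a", "p"), term("ghost", "p")),
               "missing component")

  # explicit 4-point path is stored verbatim: 3 channel elements
  wp <- rbind(c(0, 0), c(500, 0), c(500, 1000), c(1000, 1000))
  d <- add_connection(d, "flow_0", term("a", "p"), term("b", "p"), waypoints = wp, id = "c4")
  expect_equal(d$connections[["c4"]]$path, wp)
  expect_identical(unname(device_stats(d)[["n_channel_elements"]]), 2L + 3L)
})

test_that("map_valve aligns by perpendicular projection and clamps at ends", {
  d <- add_level(create_device("demo"))
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0", id = "a")
  d <- place_component(d, "PORT", list(), c(1000, 0), 0, "flow_0", id = "b")
  d <- add_connection(d, "flow_0", term("a", "p"), term("b", "p"), id = "ch")
  d <- place_component(d, "VALVE", list(), c(500, 100), 0, "control_0", id = "v")
  d <- map_valve(d, "v", "ch")
  expect_equal(attr(d, "alignment_point"), c(500, 0))
  expect_equal(d$components[["v"]]$rotation, 90)  # perpendicular to a horizontal channel
  expect_identical(d$valve_map[["v"]], "ch")

  # beyond the segment end: clamped to the nearest path vertex
  d <- place_component(d, "VALVE", list(), c(2500, 300), 0, "control_0", id = "v2")
  d <- map_valve(d, "v2", "ch")
  expect_equal(attr(d, "alignment_point"), c(1000, 0))

  # idempotence: re-mapping changes nothing
  d2 <- map_valve(d, "v", "ch")
  expect_equal(canonicalize_device(d2), canonicalize_device(d))

  expect_error(map_valve(d, "a", "ch"), "not a valve")
  expect_error(map_valve(d, "v", "nope"), "no connection")
})

test_that("VALVE3D mapping splits the channel at the seat", {
  d <- add_level(create_device("demo"))
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0", id = "a")
  d <- place_component(d, "PORT", list(), c(10000, 0), 0, "flow_0", id = "b")
  d <- add_connection(d, "flow_0", term("a", "p"), term("b", "p"),
                      channel_width = 200, id = "ch")
  d <- place_component(d, "VALVE3D", list(), c(4000, 2000), 0, "control_0", id = "v3")
  expect_identical(d$components[["v3"]]$layer_ids, c("flow_0", "control_0"))
  d <- map_valve(d, "v3", "ch")
  expect_null(d$connections[["ch"]])
  a <- d$connections[["ch_a"]]; b <- d$connections[["ch_b"]]
  expect_false(is.null(a) || is.null(b))
  seat <- attr(d, "alignment_point")
  expect_equal(seat, c(4000, 0))
  expect_equal(a$path[nrow(a$path), ], seat)
  expect_equal(b$path[1, ], seat)        # path continuity through the seat
  expect_identical(d$valve_map[["v3"]], "ch_a")
  expect_identical(nrow(validate_device(d)), 0L)

  # idempotent: second mapping does not split again
  d2 <- map_valve(d, "v3", "ch_a")
  expect_equal(canonicalize_device(d2), canonicalize_device(d))
})

test_that("validate_device reports referential and geometric violations", {
  d <- build_daridon_style_fixture()
  expect_identical(nrow(validate_device(d)), 0L)

  # valve map pointing at a deleted connection
  d1 <- d
  d1$connections[[d1$valve_map[["valve_1"]]]] <- NULL
  rep <- validate_device(d1)
  expect_true(any(rep$code == "valve_conn" & rep$severity == "error"))

  # path endpoint shifted 5 um off its port
  d2 <- d
  d2$connections[["c_in_trap"]]$path[1, ] <- d2$connections[["c_in_trap"]]$path[1, ] + c(5, 0)
  rep2 <- validate_device(d2)
  expect_true(any(rep2$code == "endpoint_mismatch"))

  # deleting a component invalidates its connections and valve map entry
  d3 <- remove_component(d, "valve_1")
  expect_false("valve_1" %in% names(d3$valve_map))
  d4 <- remove_component(d, "trap_1")
  rep4 <- validate_device(d4)
  expect_true(any(rep4$code == "bad_terminal" & rep4$severity == "error"))
})

test_that("device_stats counts components and straight channel elements", {
  d <- add_level(create_device("demo"))
  expect_identical(unname(device_stats(d)), c(0L, 0L))
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0", id = "a")
  d <- place_component(d, "PORT", list(), c(1000, 1000), 0, "flow_0", id = "b")
  d <- add_connection(d, "flow_0", term("a", "p"), term("b", "p"))
  expect_identical(unname(device_stats(d)), c(2L, 2L))

  s1 <- device_stats(random_device(20, seed = 1))
  s2 <- device_stats(random_device(20, seed = 1))
  expect_identical(s1, s2)
})
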