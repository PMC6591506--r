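# Electrical-equivalent hydraulic analysis.

test_that("rectangular-duct resistance matches the closed form", {
  R <- channel_resistance(1e-3, 1e-4, 1e-4, 1e-3)
  expect_equal(R, 12e-6 / (1e-16 * 0.37), tolerance = 1e-4)   # 3.2432e11
  expect_equal(channel_resistance(2e-3, 1e-4, 1e-4), 2 * channel_resistance(1e-3, 1e-4, 1e-4))
  expect_equal(channel_resistance(1e-3, 2e-4, 5e-5), channel_resistance(1e-3, 5e-5, 2e-4))
  expect_error(channel_resistance(0, 1e-4, 1e-4), "positive")
  expect_error(channel_resistance(1e-3, 1e-4, 1e-4, 0), "viscosity")
})

test_that("device networks mirror the channel topology", {
  net <- build_network(two_port_channel())
  expect_identical(nrow(net$nodes), 2L)
  expect_identical(nrow(net$edges), 1L)

  # a 3-point (L-shaped) path becomes two series elements and one interior node
  d <- add_level(create_device("elbow"))
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0", id = "p1")
  d <- place_component(d, "PORT", list(), c(1000, 1000), 0, "flow_0", id = "p2")
  d <- add_connection(d, "flow_0", term("p1", "p"), term("p2", "p"), id = "ch")
  net2 <- build_network(d)
  expect_identical(nrow(net2$nodes), 3L)
  expect_identical(nrow(net2$edges), 2L)

  # control-layer plumbing stays out of the flow network
  f <- build_daridon_style_fixture()
  netf <- build_network(f)
  expect_false(any(grepl("^cc_", netf$edges$origin)))
})

test_that("mixer interiors carry their unrolled serpentine resistance", {
  d <- add_level(create_device("mix"))
  p <- list(numberOfBends = 8, bendLength = 2000, bendSpacing = 400, channelWidth = 200,
            height = 100)
  d <- place_component(d, "MIXER", p, c(0, 0), 0, "flow_0", id = "m")
  d <- place_component(d, "PORT", list(), c(-5000, -4800), 0, "flow_0", id = "p1")
  d <- place_component(d, "PORT", list(), c(5000, 4800), 0, "flow_0", id = "p2")
  d <- add_connection(d, "flow_0", term("p1", "p"), term("m", "in"))
  d <- add_connection(d, "flow_0", term("m", "out"), term("p2", "p"))
  net <- build_network(d)
  edge <- net$edges[net$edges$id == "m:interior", ]
  expect_identical(nrow(edge), 1L)
  # centreline oracle: bars plus the vertical runs between bar centrelines
  L_um <- (2 * 8 + 1) * 2000 + 2 * 8 * (400 + 200)
  expect_equal(edge$resistance,
               channel_resistance(L_um * 1e-6, 200e-6, 100e-6))
})

test_that("solutions obey the Ohm analogy on canonical topologies", {
  d <- two_port_channel()
  net <- build_network(d)
  net <- set_boundary(net, "p1", pressure = 1000)
  net <- set_boundary(net, "p2", pressure = 0)
  sol <- solve_network(net)
  R <- channel_resistance(1e-3, 100e-6, 100e-6)
  expect_equal(sol$flows$flow, 1000 / R, tolerance = 1e-12)

  # two equal resistors in series: midpoint at half the drive
  net2 <- mfda:::new_network()
  net2 <- net_add_edge(net2, "a", "m", 1e12)
  net2 <- net_add_edge(net2, "m", "b", 1e12)
  net2 <- set_boundary(net2, "a", pressure = 1000)
  net2 <- set_boundary(net2, "b", pressure = 0)
  sol2 <- solve_network(net2)
  expect_equal(unname(sol2$pressures[["m"]]), 500)

  # two equal parallel channels split the flow evenly
  net3 <- mfda:::new_network()
  net3 <- net_add_edge(net3, "a", "b", 2e12)
  net3 <- net_add_edge(net3, "a", "b", 2e12)
  net3 <- set_boundary(net3, "a", pressure = 1000)
  net3 <- set_boundary(net3, "b", pressure = 0)
  sol3 <- solve_network(net3)
  expect_equal(sol3$flows$flow[1], sol3$flows$flow[2])
  expect_equal(sum(sol3$flows$flow), 1000 / 1e12)

  expect_error(net_add_edge(net3, "a", "b", 0), "resistance")
  net4 <- net_add_edge(net3, "x", "y", 1e12)   # island with no boundary
  expect_error(solve_network(net4), "floating")
})

test_that("random networks conserve flow and match a dense oracle", {
  for (seed in 1:20) {
    net <- random_network(seed)
    sol <- solve_network(net)
    inflow <- boundary_inflow(net, sol)
    expect_lte(kcl_imbalance(net, sol), 1e-9 * max(inflow, 1e-30))
    P_oracle <- dense_network_solve(net)
    expect_equal(sol$pressures, P_oracle[names(sol$pressures)], tolerance = 1e-9)
  }
})

test_that("flows scale inversely with a global resistance factor", {
  base <- random_ladder(11, 5)
  net <- set_boundary(base$net, base$inlet, pressure = 2000)
  net <- set_boundary(net, base$outlet, pressure = 0)
  sol <- solve_network(net)
  scaled <- net
  scaled$edges$resistance <- scaled$edges$resistance * 7
  sol7 <- solve_network(scaled)
  expect_equal(sol7$flows$flow, sol$flows$flow / 7, tolerance = 1e-12)
})

test_that("closing a valve reroutes the flow through the open branch", {
  d <- add_level(create_device("bypass"))
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0", id = "in")
  d <- place_component(d, "PORT", list(), c(10000, 0), 0, "flow_0", id = "out")
  d <- place_component(d, "CHAMBER", list(width = 1000, length = 1000), c(5000, 4000),
                       0, "flow_0", id = "top")
  d <- add_connection(d, "flow_0", term("in", "p"), term("out", "p"), id = "direct")
  d <- add_connection(d, "flow_0", term("in", "p"), term("top", "in"), id = "up")
  d <- add_connection(d, "flow_0", term("top", "out"), term("out", "p"), id = "down")
  d <- place_component(d, "VALVE", list(), c(5000, 300), 0, "control_0", id = "v")
  d <- map_valve(d, "v", "direct")

  solve_bc <- function(net) {
    net <- set_boundary(net, "in", pressure = 1000)
    net <- set_boundary(net, "out", pressure = 0)
    solve_network(net)
  }
  open_sol <- solve_bc(build_network(d))
  expect_true(any(open_sol$flows$flow[grepl("^direct", open_sol$flows$id)] != 0))
  closed_sol <- solve_bc(build_network(d, closed_valves = "v"))
  expect_false(any(grepl("^direct", closed_sol$flows$id)))
  expect_gt(abs(sum(closed_sol$flows$flow[grepl("^up", closed_sol$flows$id)])), 0)
})
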