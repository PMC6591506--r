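# Procedural geometry of the parametric component library.

test_that("definitions expose procedural difficulty classes", {
  expect_identical(definition_of("MIXER")$procedural_order, "linear")
  expect_identical(definition_of("MUX")$procedural_order, "polynomial")
  expect_error(definition_of("FOO"), "unknown entity")
  expect_true(all(c("PORT", "MIXER", "MUX", "VALVE", "VALVE3D", "PUMP", "CHAMBER")
                  %in% list_entities()))
})

test_that("mixer serpentine has the closed-form flush-joint area", {
  for (X in c(1, 2, 5, 12)) {
    p <- list(numberOfBends = X, bendLength = 1000, channelWidth = 100, bendSpacing = 300)
    g <- render_component(list(entity = "MIXER", params = p, position = c(0, 0), rotation = 0))
    expect_length(g$faces, (2 * X + 1) + 2 * X)
    closed_form <- (2 * X + 1) * 1000 * 100 + 2 * X * 300 * 100
    # independent oracle: plane-sweep union over the bar rectangles
    sweep_area <- rect_union_area(lapply(g$faces, face_rect))
    expect_equal(sweep_area, closed_form)
    expect_equal(geometry_area(g), closed_form)
  }
})

test_that("port renders as a near-exact disc and mux as a power-of-two tree", {
  g <- render_component(list(entity = "PORT", params = list(portRadius = 700),
                             position = c(0, 0), rotation = 0))
  expect_identical(nrow(g$faces[[1]]$poly$outer), 32L)
  expect_lt(abs(geometry_area(g) - pi * 700^2) / (pi * 700^2), 0.005)

  expect_error(render_component(list(entity = "MUX", params = list(outputs = 3),
                                     position = c(0, 0), rotation = 0)),
               "power of two")
  for (n in c(2, 4, 8, 16)) {
    ps <- ports_of("MUX", list(outputs = n))
    expect_identical(nrow(ps), as.integer(1 + n))
    expect_identical(sum(grepl("^out", ps$label)), as.integer(n))
  }
})

test_that("port layouts sit on the geometry they serve", {
  p <- list(numberOfBends = 3, bendLength = 2000, channelWidth = 200, bendSpacing = 400)
  ps <- ports_of("MIXER", p)
  ytop <- 3 * (200 + 400)
  expect_equal(ps$y, c(-ytop, ytop))      # first/last horizontal bar midlines
  expect_equal(ps$x, c(-1000, 1000))

  cp <- ports_of("CHAMBER", list(width = 2000, length = 4000))
  expect_equal(cp$x + rev(cp$x), c(0, 0)) # symmetric about the centre
  expect_equal(cp$y, c(0, 0))

  expect_identical(nrow(ports_of("PUMP", list())), 3L)
})

test_that("rendering is equivariant under translation and rotation", {
  cases <- list(
    list(entity = "MIXER", params = list(numberOfBends = 2)),
    list(entity = "PORT", params = list()),
    list(entity = "CHAMBER", params = list()),
    list(entity = "VALVE3D", params = list())
  )
  for (cs in cases) {
    for (rot in c(0, 37, 90, 180)) {
      pos <- c(1234, -567)
      placed <- render_component(c(cs, list(position = pos, rotation = rot)))
      origin <- render_component(c(cs, list(position = c(0, 0), rotation = 0)))
      for (i in seq_along(placed$faces)) {
        expect_equal(placed$faces[[i]]$poly$outer,
                     mfda:::transform_points(origin$faces[[i]]$poly$outer, pos, rot),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("rendered rings are simple and closed across random parameter draws", {
  set.seed(42)
  entities <- list_entities()
  entities <- entities[entities %in% c("PORT", "MIXER", "MUX", "VALVE", "VALVE3D",
                                       "PUMP", "CHAMBER")]
  for (k in seq_len(200)) {
    e <- sample(entities, 1)
    pd <- definition_of(e)$param_defs
    params <- list()
    for (i in seq_len(nrow(pd))) {
      v <- stats::runif(1, pd$min[i], pd$max[i])
      if (pd$kind[i] == "count") v <- round(v)
      params[[pd$name[i]]] <- v
    }
    if (e == "MUX") params$outputs <- sample(c(2, 4, 8, 16), 1)
    if (e == "MIXER") {
      # keep the serpentine legs physically wide enough to stay simple
      params$channelWidth <- min(params$channelWidth, params$bendLength / 3)
    }
    g <- render_component(list(entity = e, params = params,
                               position = c(0, 0), rotation = stats::runif(1, 0, 360)))
    for (f in g$faces) {
      expect_true(mfda:::ring_is_simple(f$poly$outer),
                  info = sprintf("%s draw %d", e, k))
    }
  }
})

test_that("custom entities register, scale and reject bad input", {
  reset_registry()
  tri <- rbind(c(0, 0), c(200, 0), c(100, 300))
  register_custom_entity("TRAP_T", list(tri), dfm_class = "XY")
  expect_true("TRAP_T" %in% list_entities())
  expect_error(register_custom_entity("TRAP_T", list(tri)), "already registered")

  g1 <- render_component(list(entity = "TRAP_T", params = list(scale = 1),
                              position = c(0, 0), rotation = 0))
  g2 <- render_component(list(entity = "TRAP_T", params = list(scale = 2),
                              position = c(0, 0), rotation = 0))
  bb1 <- mfda:::rings_bbox(list(g1$faces[[1]]$poly$outer))
  bb2 <- mfda:::rings_bbox(list(g2$faces[[1]]$poly$outer))
  expect_equal(bb2[3] - bb2[1], 2 * (bb1[3] - bb1[1]))
  expect_equal(bb2[4] - bb2[2], 2 * (bb1[4] - bb1[2]))

  bowtie <- rbind(c(0, 0), c(100, 100), c(100, 0), c(0, 100))
  expect_error(register_custom_entity("BOWTIE", list(bowtie)), "not simple")
  reset_registry()
})
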