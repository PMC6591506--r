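# ParchMINT-superset serialization, MINT-subset import, grid placement,
# SVG and DXF export.

test_that("ParchMINT writing is canonical and reading inverts it", {
  d <- two_port_channel()
  doc <- write_parchmint(d)
  expect_identical(write_parchmint(read_parchmint(doc)), doc)  # byte-stable

  empty <- add_level(create_device("empty"))
  doc0 <- write_parchmint(empty)
  back <- read_parchmint(doc0)
  expect_equal(canonicalize_device(empty), back)
  parsed <- jsonlite::fromJSON(doc0, simplifyVector = FALSE)
  expect_length(parsed$components, 0L)
  expect_length(parsed$connections, 0L)

  # VALVE3D documents carry both layer references
  d3 <- add_level(create_device("v3"))
  d3 <- place_component(d3, "VALVE3D", list(), c(0, 0), 0, "control_0", id = "v")
  parsed3 <- jsonlite::fromJSON(write_parchmint(d3), simplifyVector = FALSE)
  expect_setequal(unlist(parsed3$components[[1]]$layers), c("flow_0", "control_0"))
})

test_that("serialization round trip is lossless over seeded random devices", {
  for (seed in 1:15) {
    d <- random_device(5 + seed, seed = seed)
    d2 <- read_parchmint(write_parchmint(d))
    expect_equal(canonicalize_device(d), d2, info = sprintf("seed %d", seed))
  }
})

test_that("malformed documents fail with located errors", {
  d <- two_port_channel()
  doc <- jsonlite::fromJSON(write_parchmint(d), simplifyVector = FALSE)
  doc$connections <- NULL
  expect_error(read_parchmint(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "\\$\\.connections")
  doc2 <- jsonlite::fromJSON(write_parchmint(d), simplifyVector = FALSE)
  doc2$components[[1]]$layers <- list("flow_9")
  expect_error(read_parchmint(jsonlite::toJSON(doc2, auto_unbox = TRUE)), "layer")
  expect_error(read_parchmint("{nonsense"), "JSON")
})

test_that("MINT-subset programs parse to the declared netlist", {
  d <- parse_mint(mint_example_program())
  expect_identical(length(d$components), 4L)   # mixer, 2 ports, valve
  expect_identical(length(d$connections), 2L)
  expect_identical(d$valve_map[["v1"]], "c1")
  expect_null(d$components[["m1"]]$position)

  bad <- c("DEVICE d", "LAYER FLOW", "  VALVE v1 on c9 ;", "END LAYER")
  expect_error(parse_mint(bad), "undeclared channel 'c9'")
  dup <- c("DEVICE d", "LAYER FLOW", "  PORT p1 ;", "  PORT p1 ;", "END LAYER")
  expect_error(parse_mint(dup), "already used")
  expect_error(parse_mint(c("DEVICE d", "PORT p1 ;")), "outside a LAYER")
  expect_error(parse_mint(c("DEVICE d", "LAYER FLOW", "  PORT p1", "END LAYER")),
               "';'")
})

test_that("auto_place grids unplaced components and routes channels", {
  prog <- c("DEVICE grid", "LAYER FLOW",
            "  PORT a ;", "  PORT b ;", "  PORT c ;", "  PORT d ;", "END LAYER")
  d <- auto_place(parse_mint(prog), pitch = 5000)
  pos <- lapply(c("a", "b", "c", "d"), function(i) d$components[[i]]$position)
  expect_equal(pos, list(c(0, 0), c(5000, 0), c(10000, 0), c(15000, 0)))
  expect_identical(nrow(validate_device(d)), 0L)

  # already-placed components untouched
  d2 <- parse_mint(prog)
  d2$components[["a"]]$position <- c(77, 88)
  d2 <- auto_place(d2, pitch = 5000)
  expect_equal(d2$components[["a"]]$position, c(77, 88))

  mix <- parse_mint(c("DEVICE m", "LAYER FLOW", "  MIXER m1 bendLength=4000 ;", "END LAYER"))
  expect_error(auto_place(mix, pitch = 10), "pitch")

  full <- auto_place(parse_mint(mint_example_program()), pitch = 12000)
  expect_identical(nrow(validate_device(full)), 0L)
  expect_true(all(vapply(full$connections, function(cn) !is.null(cn$path), logical(1))))
})

test_that("SVG export mirrors the layer structure", {
  empty <- add_level(create_device("empty"))
  svg0 <- export_svg(empty)
  expect_false(grepl("<polygon", svg0))

  d <- add_level(create_device("one_port"))
  d <- place_component(d, "PORT", list(), c(0, 0), 0, "flow_0")
  svg <- export_svg(d)
  poly <- regmatches(svg, regexpr('<polygon points="[^"]*"', svg))
  expect_length(poly, 1L)
  expect_identical(lengths(regmatches(poly, gregexpr(",", poly))), 32L)  # 32 vertices
  expect_identical(lengths(regmatches(svg, gregexpr("<g ", svg))),
                   length(d$layers))

  skip_if_not_installed("xml2")
  expect_silent(xml2::read_xml(export_svg(build_daridon_style_fixture())))
  expect_silent(xml2::read_xml(svg0))
})

test_that("manufacturing DXF export groups by height and routes ports to drills", {
  d <- mixed_height_device()
  ml <- generate_manufacturing_layers(d)
  dx <- export_dxf_layers(ml, device_name = "heights")
  xy_files <- grep("_XY_", names(dx), value = TRUE)
  expect_length(grep("flow_0", xy_files), 2L)        # two heights, two XY files
  z_file <- grep("_Z\\.dxf$", names(dx), value = TRUE)
  expect_length(z_file, 1L)
  expect_true(grepl("CIRCLE", dx[[z_file]]))         # ports exported as drill circles

  # re-import of an exported XY layer recovers polygon areas
  for (l in ml) {
    if (l$dfm_class != "XY") next
    f <- sprintf("heights_%s_XY_%gum.dxf", l$functional_layer_id, l$height)
    expect_true(f %in% names(dx))
    tf <- tempfile(fileext = ".dxf")
    writeLines(dx[[f]], tf)
    shapes <- infer_closed_shapes(read_dxf_entities(tf))
    got <- sum(vapply(shapes$polygons, mfda:::poly_area, numeric(1))) * 1000^2
    want <- sum(vapply(l$polygons, mfda:::poly_area, numeric(1)))
    expect_equal(got, want, tolerance = 1e-6)
  }
})
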