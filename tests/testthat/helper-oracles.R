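# Independent oracles used by the tests. These deliberately avoid the
# package's own geometry/solver code paths: the union-area oracle is a
# plane sweep over axis-aligned rectangles, and the network oracle
# assembles Kirchhoff's equations densely and solves them with base R.

# Union area of axis-aligned rectangles, each c(x0, y0, x1, y1):
# sweep over x breakpoints, merging y intervals per vertical strip.
rect_union_area <- function(rects) {
  if (length(rects) == 0) return(0)
  xs <- sort(unique(unlist(lapply(rects, function(r) r[c(1, 3)]))))
  total <- 0
  for (i in seq_len(length(xs) - 1L)) {
    x0 <- xs[i]; x1 <- xs[i + 1L]
    xm <- (x0 + x1) / 2
    ys <- do.call(rbind, Filter(Negate(is.null), lapply(rects, function(r) {
      if (r[1] <= xm && xm <= r[3]) c(r[2], r[4]) else NULL
    })))
    if (is.null(ys)) next
    ys <- ys[order(ys[, 1]), , drop = FALSE]
    cov <- 0; lo <- ys[1, 1]; hi <- ys[1, 2]
    if (nrow(ys) > 1) {
      for (j in 2:nrow(ys)) {
        if (ys[j, 1] > hi) { cov <- cov + hi - lo; lo <- ys[j, 1]; hi <- ys[j, 2] }
        else hi <- max(hi, ys[j, 2])
      }
    }
    cov <- cov + hi - lo
    total <- total + cov * (x1 - x0)
  }
  total
}

# axis-aligned bounding box of a face's outer ring
face_rect <- function(face) {
  r <- face$poly$outer
  c(min(r[, 1]), min(r[, 2]), max(r[, 1]), max(r[, 2]))
}

# normalise a ring for set comparison: CCW orientation, start at the
# lexicographically smallest vertex, values rounded
normalize_ring <- function(ring, digits = 6) {
  ring <- round(ring, digits)
  if (mfda:::ring_signed_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  i <- order(ring[, 1], ring[, 2])[1]
  if (i > 1) ring <- rbind(ring[i:nrow(ring), , drop = FALSE], ring[1:(i - 1), , drop = FALSE])
  ring
}

ring_set_signature <- function(rings) {
  sigs <- vapply(rings, function(r) paste(t(normalize_ring(r)), collapse = ","), character(1))
  sort(sigs)
}

# Brute-force nodal solution of a resistor network: write one current
# balance per non-fixed node and solve densely with base R.
dense_network_solve <- function(net) {
  nodes <- net$nodes$id
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  bc_types <- vapply(net$bc, `[[`, character(1), "type")
  fixed <- names(net$bc)[bc_types == "pressure"]
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (r in seq_len(nrow(net$edges))) {
    g <- 1 / net$edges$resistance[r]
    i <- idx[[net$edges$from[r]]]; j <- idx[[net$edges$to[r]]]
    A[i, i] <- A[i, i] + g; A[j, j] <- A[j, j] + g
    A[i, j] <- A[i, j] - g; A[j, i] <- A[j, i] - g
  }
  for (nm in names(net$bc)) {
    if (net$bc[[nm]]$type == "flow") b[idx[[nm]]] <- b[idx[[nm]]] + net$bc[[nm]]$value
  }
  for (nm in fixed) {
    i <- idx[[nm]]
    A[i, ] <- 0; A[i, i] <- 1; b[i] <- net$bc[[nm]]$value
  }
  P <- solve(A, b)
  stats::setNames(P, nodes)
}

# Random resistor network built through the public network API: a
# spanning tree plus extra edges, log-uniform resistances, two pressure
# boundaries (and sometimes a flow injection).
random_network <- function(seed, max_edges = 40) {
  set.seed(seed)
  n <- sample(4:12, 1)
  net <- mfda:::new_network()
  ids <- sprintf("n%d", seq_len(n))
  for (i in 2:n) {
    j <- sample.int(i - 1L, 1L)
    net <- net_add_edge(net, ids[j], ids[i], 10^stats::runif(1, 9, 13))
  }
  extra <- sample(0:(max_edges - (n - 1)), 1)
  extra <- min(extra, n * (n - 1) / 2 - (n - 1))
  for (k in seq_len(extra)) {
    ij <- sample.int(n, 2)
    net <- net_add_edge(net, ids[ij[1]], ids[ij[2]], 10^stats::runif(1, 9, 13))
  }
  net <- set_boundary(net, ids[1], pressure = stats::runif(1, 500, 5000))
  net <- set_boundary(net, ids[n], pressure = 0)
  if (stats::runif(1) < 0.4 && n > 3) {
    net <- set_boundary(net, ids[2], flow = stats::runif(1, 1e-10, 1e-8))
  }
  net
}

# Ladder of n sections, each a parallel resistor pair, in series.
# Returns the network plus the closed-form equivalent resistance.
random_ladder <- function(seed, n_sections = NULL) {
  set.seed(seed)
  if (is.null(n_sections)) n_sections <- sample(2:9, 1)
  net <- mfda:::new_network()
  r_eq <- 0
  for (i in seq_len(n_sections)) {
    ra <- 10^stats::runif(1, 9, 13); rb <- 10^stats::runif(1, 9, 13)
    a <- sprintf("n%d", i - 1L); b <- sprintf("n%d", i)
    net <- net_add_edge(net, a, b, ra)
    net <- net_add_edge(net, a, b, rb)
    r_eq <- r_eq + 1 / (1 / ra + 1 / rb)
  }
  list(net = net, r_eq = r_eq, inlet = "n0", outlet = sprintf("n%d", n_sections))
}

# worst KCL imbalance of a solution, computed from the flows alone
kcl_imbalance <- function(net, sol) {
  free <- setdiff(net$nodes$id, names(net$bc))
  flow_bc <- names(net$bc)[vapply(net$bc, `[[`, character(1), "type") == "flow"]
  imb <- numeric(0)
  for (nd in c(free, flow_bc)) {
    inj <- if (nd %in% flow_bc) net$bc[[nd]]$value else 0
    s <- inj +
      sum(sol$flows$flow[sol$flows$to == nd]) -
      sum(sol$flows$flow[sol$flows$from == nd])
    imb <- c(imb, abs(s))
  }
  if (length(imb) == 0) 0 else max(imb)
}

# total volumetric inflow at the pressure boundaries of a solved network
boundary_inflow <- function(net, sol) {
  p_nodes <- names(net$bc)[vapply(net$bc, `[[`, character(1), "type") == "pressure"]
  total <- 0
  for (nd in p_nodes) {
    s <- sum(sol$flows$flow[sol$flows$from == nd]) -
         sum(sol$flows$flow[sol$flows$to == nd])
    total <- total + max(s, 0)
  }
  flow_bc <- names(net$bc)[vapply(net$bc, `[[`, character(1), "type") == "flow"]
  total + sum(vapply(flow_bc, function(nd) max(net$bc[[nd]]$value, 0), numeric(1)))
}
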