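test_that("generated networks are valid drainage trees with conserved area", {
  for (style in c("lattice_random_tree", "scheidegger")) {
    for (seed in 1:3) {
      net <- generate_network(60, cell_size = 100, seed = seed, style = style)
      nd <- net$nodes
      expect_equal(sum(is.na(nd$downstream_id)), 1)
      expect_true(all(nd$reach_length_m > 0))
      expect_true(all(nd$slope > 0))
      expect_true(all(nd$width_m > 0))
      # additivity: own cell plus immediate upstream areas (exact with unit cells)
      cell_area <- 100^2
      upstream_sum <- vapply(nd$node_id, function(i) {
        sum(nd$area_m2[which(nd$downstream_id == i)])
      }, numeric(1))
      expect_equal(nd$area_m2, cell_area + upstream_sum)
      expect_equal(nd$area_m2[net$outlet + 1], 60 * cell_area)
      # area non-decreasing downstream
      down <- nd$downstream_id
      ok <- is.na(down) | nd$area_m2 < nd$area_m2[down + 1]
      expect_true(all(ok))
    }
  }
})

test_that("two-node request yields one headwater draining into the outlet", {
  net <- generate_network(2, cell_size = 50, seed = 1)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(net$nodes$area_m2[net$outlet + 1], 2 * 50^2)
  leaf <- setdiff(net$nodes$node_id, net$outlet)
  expect_equal(net$nodes$downstream_id[leaf + 1], net$outlet)
})

test_that("network generation is reproducible per seed", {
  a <- generate_network(80, cell_size = 100, seed = 42)
  b <- generate_network(80, cell_size = 100, seed = 42)
  expect_identical(a$nodes, b$nodes)
  c <- generate_network(80, cell_size = 100, seed = 43)
  expect_false(identical(a$nodes$downstream_id, c$nodes$downstream_id))
})

test_that("nodes with bare cell area are exactly the leaves", {
  net <- generate_network(200, cell_size = 100, seed = 1)
  nd <- net$nodes
  leaves <- setdiff(nd$node_id, nd$downstream_id[!is.na(nd$downstream_id)])
  expect_equal(sum(nd$area_m2 == 100^2), length(leaves))
  expect_setequal(nd$node_id[nd$area_m2 == 100^2], leaves)
})

test_that("contributing area on a chain is a running sum and is idempotent", {
  net <- make_chain_net(3, cell = 1)
  expect_equal(net$nodes$area_m2, c(1, 2, 3))
  again <- compute_contributing_area(net)
  expect_equal(again$nodes$area_m2, net$nodes$area_m2)
})

test_that("cyclic or malformed downstream maps are rejected", {
  nodes <- tibble::tibble(
    node_id = 0:2, downstream_id = c(1L, 2L, NA), x = 1:3, y = 0,
    reach_length_m = 1
  )
  expect_no_error(stream_network(nodes, cell_size = 1))
  nodes$downstream_id <- c(1L, 0L, NA)  # 0 <-> 1 cycle, 2 unreachable-from
  expect_error(stream_network(nodes, cell_size = 1), "tree")
  nodes$downstream_id <- c(1L, NA, NA)  # two outlets
  expect_error(stream_network(nodes, cell_size = 1), "outlet")
  expect_error(generate_network(1), "n_nodes")
  expect_error(generate_network(10, cell_size = 0), "cell_size")
})

test_that("TWI follows the log identity and preserves area order at uniform slope", {
  net <- make_chain_net(5, cell = 100, slope = 0.1)
  twi1 <- net$nodes$twi
  net2 <- net
  net2$nodes$area_m2 <- net$nodes$area_m2 * 2
  net2 <- compute_twi(net2)
  expect_equal(net2$nodes$twi - twi1, rep(log(2), 5))
  # uniform slope: TWI ordering equals area ordering
  expect_equal(order(net$nodes$twi), order(net$nodes$area_m2))
  # hand value: A = 1e4 m2, w_c = 100 m, tan(beta) = 0.1 -> ln(1000)
  expect_equal(twi1[1], log((1e4 / 100) / 0.1), tolerance = 1e-12)
  expect_equal(twi1[1], 6.9078, tolerance = 1e-4)
  net3 <- net
  net3$nodes$slope[1] <- 0
  expect_error(compute_twi(net3), "positive")
})

test_that("slope model degenerates to a power law and keeps TWI tied to area", {
  net <- generate_network(150, cell_size = 100, seed = 7)
  flat <- assign_slopes(net, seed = 1, exponent = -0.5, noise_sd = 0)
  a_rel <- flat$nodes$area_m2 / flat$nodes$area_m2[flat$outlet + 1]
  expect_equal(flat$nodes$slope, 0.05 * a_rel^(-0.5))
  unif <- assign_slopes(net, seed = 1, exponent = 0, noise_sd = 0)
  expect_equal(unif$nodes$slope, rep(0.05, 150))
  expect_error(assign_slopes(net, seed = 1, noise_sd = -1), "noise_sd")
  # with default noise the TWI and area rankings agree on most adjacent pairs
  net <- compute_twi(net)
  nd <- net$nodes
  pair <- !is.na(nd$downstream_id)
  d_twi <- nd$twi[pair] - nd$twi[nd$downstream_id[pair] + 1]
  d_area <- nd$area_m2[pair] - nd$area_m2[nd$downstream_id[pair] + 1]
  concord <- mean(sign(d_twi) == sign(d_area))
  expect_gt(concord, 0.6)
  expect_gt(cor(nd$twi, nd$area_m2, method = "spearman"), 0)
})

test_that("width law scales with the square root of area and hits its calibration", {
  net <- make_chain_net(4, cell = 100)
  flat <- compute_width(net, k_w = 3, b_w = 0)
  expect_equal(flat$nodes$width_m, rep(3, 4))
  w1 <- compute_width(net, b_w = 0.5)$nodes$width_m
  net4 <- net
  net4$nodes$area_m2 <- net$nodes$area_m2 * 4
  w4 <- compute_width(net4, b_w = 0.5)$nodes$width_m
  expect_equal(w4, 2 * w1)
  # default calibration: 10 km^2 drains through a 15 m wide outlet
  net10 <- net
  net10$nodes$area_m2[4] <- 1e7
  expect_equal(compute_width(net10)$nodes$width_m[4], 15, tolerance = 1e-12)
  expect_equal(0.00474 * sqrt(1e7), 14.99, tolerance = 1e-3)
  expect_error(compute_width(net, k_w = -1), "k_w")
})

test_that("proxy rankings order nodes as their scenario dictates", {
  net <- make_chain_net(6)
  r_area <- proxy_ranking(net, "area")
  expect_equal(r_area$node_id[6], net$outlet)       # outlet most persistent
  expect_setequal(r_area$node_id, net$nodes$node_id)
  r_twi <- proxy_ranking(net, "twi")                # uniform slopes here
  expect_equal(r_twi$node_id, r_area$node_id)
  r1 <- proxy_ranking(net, "random", seed = 1)
  r2 <- proxy_ranking(net, "random", seed = 2)
  expect_false(identical(r1$node_id, r2$node_id))
  expect_identical(r1$node_id, proxy_ranking(net, "random", seed = 1)$node_id)
  expect_error(proxy_ranking(net, "upstream"))
})

test_that("area-ranked top-k sets are connected subtrees containing the outlet", {
  net <- generate_network(120, cell_size = 100, seed = 3)
  rk <- proxy_ranking(net, "area")
  ids_desc <- rev(rk$node_id)  # most persistent first
  for (k in seq_len(120)) {
    active <- net$nodes$node_id %in% ids_desc[seq_len(k)]
    comp <- riverspom:::active_components(net, active)
    expect_equal(length(unique(comp[active])), 1)
    expect_true(active[net$outlet + 1])
  }
})

test_that("nearest-neighbour distance is the mean adjacent separation", {
  net <- make_chain_net(5, cell = 80)
  expect_equal(net$nnd, 80)
  sch <- generate_network(60, cell_size = 100, seed = 2, style = "scheidegger")
  nd <- sch$nodes
  sep <- nd$reach_length_m[!is.na(nd$downstream_id)]
  expect_equal(sch$nnd, mean(sep))
  expect_true(any(abs(sep - 100 * sqrt(2)) < 1e-9))  # diagonal steps present
})

test_that("CSV round trip is lossless", {
  net <- generate_network(50, cell_size = 100, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream_network(net, path)
  back <- read_stream_network(path, cell_size = 100)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$outlet, net$outlet)
  expect_equal(back$nnd, net$nnd)
})
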