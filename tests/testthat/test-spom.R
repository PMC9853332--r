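test_that("species traits validate and the focal species follows the NND", {
  tr <- species_traits(0.015, 20, 400)
  expect_equal(tr$c, 0.015)
  expect_error(species_traits(-1, 20, 400), "positive")
  expect_warning(species_traits(1e3, 20, 400), "colonization")
  expect_warning(species_traits(0.015, 1e4, 400), "extinction")
  net <- make_chain_net(5, cell = 120)
  fs <- focal_species(net)
  expect_equal(fs$delta, 4 * 120)
  expect_equal(fs$e, 20)
})

test_that("active-path distances are blocked by dry intermediate nodes", {
  net <- make_chain_net(3)  # a(0) - b(1) - c(2), 100 m links
  d_all <- active_path_distances(net, active_set = 0:2, sources = c(0L, 2L))
  expect_equal(d_all$distance_m[d_all$source == 0 & d_all$node_id == 0], 0)
  expect_equal(d_all$distance_m[d_all$source == 0 & d_all$node_id == 2], 200)
  expect_equal(d_all$distance_m[d_all$source == 2 & d_all$node_id == 0], 200)
  d_blocked <- active_path_distances(net, active_set = c(0L, 2L), sources = 0L)
  expect_false(2 %in% d_blocked$node_id)  # middle node dry: path infinite
  expect_error(active_path_distances(net, active_set = c(0L, 2L), sources = 1L),
               "active")
  # cutoff omits distant pairs
  d_cut <- active_path_distances(net, 0:2, sources = 0L, cutoff = 150)
  expect_setequal(d_cut$node_id, c(0L, 1L))
})

test_that("colonization rates follow the exponential kernel sum", {
  net <- make_chain_net(2, cell = 100, width = 5)  # S = 500 m^2 per node
  tr <- species_traits(0.015, 20, 400)
  S <- c(500, 500)
  cr <- colonization_rates(net, S, w_prev = c(1L, 0L), tr)
  expect_equal(cr$c_rate[2], 0.015 * exp(-0.25) * 500, tolerance = 1e-9)
  expect_equal(cr$c_rate[2], 5.841, tolerance = 1e-3)
  # no occupied sources -> zero everywhere
  cr0 <- colonization_rates(net, S, w_prev = c(0L, 0L), tr)
  expect_equal(cr0$c_rate, c(0, 0))
  # dry target receives nothing
  crd <- colonization_rates(net, c(500, 0), w_prev = c(1L, 0L), tr)
  expect_equal(crd$c_rate[2], 0)
  # delta -> infinity: kernel flattens to the plain suitability sum
  net5 <- make_chain_net(5, cell = 100, width = 2)
  S5 <- rep(200, 5)
  w5 <- c(1L, 0L, 1L, 1L, 0L)
  cr_inf <- colonization_rates(net5, S5, w5, species_traits(0.01, 20, 1e12))
  expect_equal(cr_inf$c_rate[2], 0.01 * sum(S5 * w5), tolerance = 1e-6)
})

test_that("kernel truncation at 23 dispersal distances is numerically immaterial", {
  net <- make_chain_net(40, cell = 100, width = 5)
  tr <- species_traits(0.015, 20, 100)   # delta = 100 m, cutoff 2300 m < span
  S <- rep(500, 40)
  w <- rep(1L, 40); w[1] <- 0L
  K_cut <- dispersal_kernel(net, tr$delta)
  K_full <- dispersal_kernel(net, tr$delta, cutoff = Inf)
  expect_true(any(K_cut == 0 & K_full > 0))
  C_cut <- as.numeric((K_cut %*% (S * w)))[1] * tr$c
  C_full <- as.numeric((K_full %*% (S * w)))[1] * tr$c
  expect_lt(abs(C_cut - C_full) / C_full, 1e-9)
})

test_that("extinction rates invert suitability and dry nodes are lost surely", {
  tr <- species_traits(0.015, 20, 400)
  er <- extinction_rates(c(500, 0, 1e12), tr)
  expect_equal(er$e_rate[1], 0.04)
  expect_equal(er$phi_e[1], 1 - exp(-0.04))
  expect_equal(er$phi_e[1], 0.0392, tolerance = 1e-3)
  expect_equal(er$phi_e[2], 1)       # dry rule
  expect_equal(er$e_rate[2], Inf)
  expect_lt(er$phi_e[3], 1e-10)      # unbounded habitat: no extinction
})

test_that("the synchronous step behaves deterministically at probability bounds", {
  w <- c(1L, 1L, 0L, 0L)
  set.seed(1)
  expect_equal(spom_step(w, phi_c = rep(0, 4), phi_e = rep(1, 4)),
               rep(0L, 4))
  set.seed(1)
  expect_equal(spom_step(w, phi_c = rep(1, 4), phi_e = rep(0, 4)),
               rep(1L, 4))
  # whole-network extinction is absorbing: no sources, no colonization
  net <- make_chain_net(4)
  S <- net$nodes$reach_length_m * net$nodes$width_m
  cr <- colonization_rates(net, S, w_prev = rep(0L, 4),
                           species_traits(0.015, 20, 400))
  expect_equal(cr$phi_c, rep(0, 4))
})

test_that("trajectories are seed-reproducible and the two engines agree exactly", {
  net <- generate_network(30, cell_size = 100, seed = 2)
  ref <- climate_preset("intermediate")
  fld <- calibrate_thresholds(net, proxy_ranking(net, "twi"), ref)
  acts <- activate(net, simulate_climate_discharge(ref, 80, seed = 5), fld)
  tr <- focal_species(net)
  t1 <- simulate_spom(net, acts, tr, seed = 11)
  t2 <- simulate_spom(net, acts, tr, seed = 11)
  t3 <- simulate_spom(net, acts, tr, seed = 12)
  expect_identical(t1$W, t2$W)
  expect_false(identical(t1$W, t3$W))
  tR <- simulate_spom(net, acts, tr, seed = 11, engine = "r")
  expect_identical(t1$W, tR$W)
  # occupied nodes are never dry after the update that observes the dry state
  W <- t1$W[-1, , drop = FALSE]
  expect_true(all(W <= acts$X))
  expect_error(simulate_spom(net, acts, tr, w0 = 1L - acts$X[1, ], seed = 1),
               "dry")
})

test_that("a species that cannot go extinct keeps a full static network full", {
  net <- make_chain_net(6)
  fld <- calibrate_thresholds(net, proxy_ranking(net, "area"),
                              climate_preset("intermediate"))
  acts <- static_equivalent(net, fld, sum(net$nodes$reach_length_m),
                            n_days = 50)
  tr <- suppressWarnings(species_traits(0.015, 1e-9, 400))
  traj <- simulate_spom(net, acts, tr, seed = 3)
  expect_true(all(traj$W == 1L))
  om <- occupancy_fraction(traj)
  expect_equal(om$omega, rep(1, 51))
})

test_that("exact enumeration matches the single-node geometric survival law", {
  net1 <- make_chain_net(2, width = 5)
  # isolate one occupied node: the other never activates
  X <- cbind(rep(1L, 30), rep(0L, 30))
  acts <- make_acts(net1, X)
  tr <- species_traits(0.015, 20, 400)  # phi_e = 1 - exp(-20/500)
  oracle <- exact_occupancy_distribution(net1, acts, tr, w0 = c(1L, 0L))
  p <- 1 - exp(-20 / 500)
  expect_equal(oracle$marginals[, 1], (1 - p)^(0:30), tolerance = 1e-12)
  expect_equal(oracle$marginals[, 2], rep(0, 31))
  expect_equal(sum(oracle$state_prob), 1, tolerance = 1e-12)
  # Monte-Carlo agreement at day 20
  freq <- spom_ensemble(net1, acts, tr, w0 = c(1L, 0L), n_rep = 1e5, seed = 4)
  se <- sqrt((1 - p)^20 * (1 - (1 - p)^20) / 1e5)
  expect_lt(abs(freq[21, 1] - (1 - p)^20), 3 * se)
  expect_error(exact_occupancy_distribution(
    generate_network(16, seed = 1), make_acts(generate_network(16, seed = 1),
    matrix(1L, 2, 16)), tr), "12")
})

test_that("Monte-Carlo marginals track the exact oracle on a pulsing 3-node chain", {
  net <- make_chain_net(3, width = 2)   # S = 200 m^2 when wet
  tr <- species_traits(0.01, 5, 300)
  set.seed(7)
  X <- matrix(rbinom(20 * 3, 1, 0.8), 20, 3)
  storage.mode(X) <- "integer"
  X[1, ] <- 1L
  acts <- make_acts(net, X)
  oracle <- exact_occupancy_distribution(net, acts, tr, w0 = c(1L, 0L, 1L))
  n_rep <- 2e4
  freq <- spom_ensemble(net, acts, tr, w0 = c(1L, 0L, 1L), n_rep = n_rep,
                        seed = 9)
  for (d in c(1, 5, 20)) {
    p <- oracle$marginals[d + 1, ]
    se <- sqrt(pmax(p * (1 - p), 1e-12) / n_rep)
    expect_true(all(abs(freq[d + 1, ] - p) <= 4 * se + 1e-12))
  }
  expect_equal(sum(oracle$state_prob), 1, tolerance = 1e-12)
})

test_that("occupancy responds monotonically to the colonization and extinction rates", {
  net <- generate_network(24, cell_size = 100, seed = 13)
  ref <- climate_preset("intermediate")
  fld <- calibrate_thresholds(net, proxy_ranking(net, "area"), ref)
  acts <- activate(net, simulate_climate_discharge(ref, 120, seed = 17), fld)
  mean_omega <- function(cc, ee, seed) {
    tr <- species_traits(cc, ee, 400)
    mean(occupancy_fraction(simulate_spom(net, acts, tr, seed = seed))$omega[-1])
  }
  seeds <- 1:8
  lo_c <- mean(vapply(seeds, function(s) mean_omega(0.002, 20, s), numeric(1)))
  hi_c <- mean(vapply(seeds, function(s) mean_omega(0.2, 20, s), numeric(1)))
  expect_gte(hi_c, lo_c)
  lo_e <- mean(vapply(seeds, function(s) mean_omega(0.015, 2, s), numeric(1)))
  hi_e <- mean(vapply(seeds, function(s) mean_omega(0.015, 200, s), numeric(1)))
  expect_gte(lo_e, hi_e)
})
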