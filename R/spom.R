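#' Species traits for the patch occupancy model
#'
#' @param c Colonization rate (m^-2 d^-1).
#' @param e Extinction rate (m^2 d^-1).
#' @param delta Dispersal distance (m); typically a small multiple of the
#'   network's nearest-neighbour distance.
#' @return An object of class `species_traits`.
#' @export
species_traits <- function(c, e, delta) {
  if (any(c(c, e, delta) <= 0)) abort("c, e and delta must be positive")
  if (c < 1e-5 || c > 1e2) warn("colonization rate c outside the usual sweep range [1e-5, 1e2]")
  if (e < 1e-3 || e > 1e3) warn("extinction rate e outside the usual sweep range [1e-3, 1e3]")
  structure(list(c = c, e = e, delta = delta), class = "species_traits")
}

#' @export
print.species_traits <- function(x, ...) {
  cat("<species_traits> c=", x$c, " /m^2/d, e=", x$e, " m^2/d, delta=",
      x$delta, " m\n", sep = "")
  invisible(x)
}

#' The focal species used in the occupancy experiments
#'
#' `c = 0.015 m^-2 d^-1`, `e = 20 m^2 d^-1`, dispersal distance 4 times the
#' network's nearest-neighbour distance.
#'
#' @param net A [stream_network] (supplies the NND), or a numeric NND in m.
#' @param delta_nnd Dispersal distance as a multiple of NND.
#' @return A [species_traits] object.
#' @export
focal_species <- function(net, delta_nnd = 4) {
  nnd <- if (inherits(net, "stream_network")) net$nnd else as.numeric(net)
  species_traits(c = 0.015, e = 20, delta = delta_nnd * nnd)
}

#' All pairwise along-channel distances on the drainage tree
#'
#' @param net A [stream_network].
#' @return An N x N numeric matrix (node-id order) of along-channel
#'   distances between node centres.
#' @export
network_distances <- function(net) {
  tree_distances_cpp(parent0(net), net$nodes$reach_length_m)
}

#' Dispersal kernel matrix
#'
#' `K_ij = exp(-d_ij / delta)` with entries beyond the distance cutoff set to
#' zero and a zero diagonal. With the default cutoff `23 * delta` the
#' relative truncation error of any colonization rate is below `exp(-23)`,
#' i.e. < 1e-9.
#'
#' @param net A [stream_network].
#' @param delta Dispersal distance (m).
#' @param distances Optional precomputed [network_distances()] matrix.
#' @param cutoff Distance beyond which the kernel is truncated to zero (m).
#' @return An N x N numeric matrix.
#' @export
dispersal_kernel <- function(net, delta, distances = NULL,
                             cutoff = 23 * delta) {
  D <- distances %||% network_distances(net)
  K <- exp(-D / delta)
  K[D > cutoff] <- 0
  diag(K) <- 0
  K
}

# component labels (integers) of the active subgraph of the tree;
# inactive nodes get NA
active_components <- function(net, active) {
  n <- nrow(net$nodes)
  p <- parent0(net)
  up <- seq_len(n)
  find <- function(i) {
    while (up[i] != i) {
      up[i] <<- up[up[i]]
      i <- up[i]
    }
    i
  }
  for (i in seq_len(n)) {
    pi <- p[i] + 1L
    if (pi > 0L && active[i] && active[pi]) {
      a <- find(i); b <- find(pi)
      if (a != b) up[a] <- b
    }
  }
  labs <- vapply(seq_len(n), find, integer(1))
  ifelse(active, labs, NA_integer_)
}

#' Along-channel distances restricted to the active network
#'
#' Distances between node pairs are finite only when every node on the
#' unique tree path between them (endpoints included) is active; pairs
#' farther apart than the cutoff are omitted.
#'
#' @param net A [stream_network].
#' @param active_set Integer node ids forming the active network.
#' @param sources Integer node ids (must be active) to measure from.
#' @param cutoff Largest distance returned (m).
#' @return A tibble with columns `source`, `node_id`, `distance_m`, one row
#'   per reachable pair (self-pairs included at distance 0).
#' @export
active_path_distances <- function(net, active_set, sources, cutoff = Inf) {
  if (!all(sources %in% active_set)) abort("all sources must be in the active set")
  n <- nrow(net$nodes)
  active <- net$nodes$node_id %in% active_set
  p <- parent0(net)
  adj <- vector("list", n)
  len <- net$nodes$reach_length_m
  for (i in seq_len(n)) {
    pi <- p[i] + 1L
    if (pi > 0L && active[i] && active[pi]) {
      adj[[i]] <- c(adj[[i]], pi)
      adj[[pi]] <- c(adj[[pi]], i)
    }
  }
  res <- purrr::map(sources, function(s) {
    dist <- rep(Inf, n)
    si <- s + 1L
    dist[si] <- 0
    queue <- si
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in adj[[u]]) {
        # edge length between u and v is the reach length of the upstream one
        el <- if (p[v] + 1L == u) len[v] else len[u]
        d <- dist[u] + el
        if (d < dist[v] && d <= cutoff) {
          dist[v] <- d
          queue <- c(queue, v)
        }
      }
    }
    keep <- is.finite(dist)
    tibble(source = s, node_id = which(keep) - 1L, distance_m = dist[keep])
  })
  bind_rows(res)
}

#' Per-node colonization rates
#'
#' `C_i = c * sum_j exp(-d_ij / delta) * S_j * w_j`, summed over occupied
#' source nodes `j` whose whole path to `i` is active; dry nodes receive
#' `C_i = 0` (their own dry endpoint blocks every path).
#'
#' @param net A [stream_network].
#' @param S Per-node suitability (m^2), zero at dry nodes.
#' @param w_prev Previous-step occupancy (0/1 per node).
#' @param traits A [species_traits].
#' @param distances Optional precomputed distance matrix.
#' @param dt Time step (d).
#' @return A tibble with columns `node_id`, `c_rate` (d^-1) and `phi_c`.
#' @export
colonization_rates <- function(net, S, w_prev, traits, distances = NULL,
                               dt = 1) {
  active <- S > 0
  K <- dispersal_kernel(net, traits$delta, distances = distances)
  comp <- active_components(net, active)
  same <- outer(comp, comp, "==")
  same[is.na(same)] <- FALSE
  C <- traits$c * as.numeric((K * same) %*% (S * w_prev))
  C[!active] <- 0
  tibble(node_id = net$nodes$node_id, c_rate = C,
         phi_c = 1 - exp(-C * dt))
}

#' Per-node extinction rates
#'
#' Active nodes: `E_i = e / S_i` and `phi_e = 1 - exp(-E_i * dt)` (extinction
#' risk inversely proportional to wetted habitat area). Dry nodes:
#' `phi_e = 1` exactly — a population caught on a drying reach is lost.
#'
#' @param S Per-node suitability (m^2), zero at dry nodes.
#' @param traits A [species_traits].
#' @param dt Time step (d).
#' @return A tibble with columns `e_rate` (d^-1, `Inf` at dry nodes) and
#'   `phi_e`.
#' @export
extinction_rates <- function(S, traits, dt = 1) {
  active <- S > 0
  E <- ifelse(active, traits$e / S, Inf)
  tibble(e_rate = E, phi_e = ifelse(active, 1 - exp(-E * dt), 1))
}

#' One synchronous update of the occupancy chain
#'
#' Each node draws one uniform variate (in node order): an empty node becomes
#' occupied with probability `phi_c`, an occupied node goes extinct with
#' probability `phi_e`. All probabilities are evaluated from the previous
#' step's occupancy only.
#'
#' @param w_prev Integer 0/1 occupancy vector.
#' @param phi_c,phi_e Per-node colonization/extinction probabilities.
#' @return Integer 0/1 occupancy vector.
#' @export
spom_step <- function(w_prev, phi_c, phi_e) {
  u <- runif(length(w_prev))
  ifelse(w_prev == 1L, as.integer(u >= phi_e), as.integer(u < phi_c))
}

#' Simulate the dynamic stochastic patch occupancy model
#'
#' Daily loop over the activation series: suitability `S_i(t) =
#' dl_i * W_i * X_i(t)`, connectivity restricted to the active network,
#' colonization rates from the previous day's occupancy, then one
#' synchronous Bernoulli update per node. Works identically on a
#' time-constant activation series (the static model).
#'
#' @param net A [stream_network].
#' @param acts An [activate()] or [static_equivalent()] result.
#' @param traits A [species_traits].
#' @param w0 Initial occupancy: integer 0/1 vector, or `NULL` for the
#'   default "all initially active nodes occupied". Occupying an initially
#'   dry node is an error.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param dt Time step (d); the model is calibrated for `dt = 1`.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); both consume one uniform draw per node per day in node
#'   order and give identical trajectories for the same seed.
#' @return An object of class `occupancy_trajectory` holding the (T+1) x N
#'   occupancy matrix `W` (row 1 is day 0 = `w0`), day index `0..T`, node
#'   ids, and the reach lengths needed for occupancy summaries.
#' @export
simulate_spom <- function(net, acts, traits, w0 = NULL, seed = NULL, dt = 1,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  X <- acts$X
  n <- ncol(X)
  w0 <- w0 %||% as.integer(X[1, ])
  w0 <- as.integer(w0)
  if (length(w0) != n) abort("w0 must have one entry per node")
  if (any(w0 == 1L & X[1, ] == 0L)) {
    abort("w0 occupies a node that is dry on the first day")
  }
  area <- net$nodes$reach_length_m * net$nodes$width_m
  if (anyNA(area)) abort("network widths must be assigned before running the SPOM")
  K <- dispersal_kernel(net, traits$delta)
  W <- with_seed(seed, {
    if (engine == "cpp") {
      spom_core(X, parent0(net), K, area, traits$c, traits$e, w0, dt)
    } else {
      spom_engine_r(X, net, K, area, traits, w0, dt)
    }
  })
  structure(
    list(W = W, day = 0:nrow(X), node_id = net$nodes$node_id,
         traits = traits, seed = seed,
         reach_length_m = acts$reach_length_m,
         total_length_m = acts$total_length_m,
         static = acts$static),
    class = "occupancy_trajectory"
  )
}

# pure-R reference engine: same draw discipline as the compiled core
spom_engine_r <- function(X, net, K, area, traits, w0, dt) {
  T_ <- nrow(X)
  n <- ncol(X)
  W <- matrix(0L, T_ + 1L, n)
  W[1, ] <- w0
  w <- w0
  for (t in seq_len(T_)) {
    active <- X[t, ] == 1L
    S <- ifelse(active, area, 0)
    comp <- active_components(net, active)
    same <- outer(comp, comp, "==")
    same[is.na(same)] <- FALSE
    C <- traits$c * as.numeric((K * same) %*% (S * w))
    phi_c <- ifelse(active, 1 - exp(-C * dt), 0)
    phi_e <- ifelse(active, 1 - exp(-traits$e / S * dt), 1)
    w <- spom_step(w, phi_c, phi_e)
    W[t + 1L, ] <- w
  }
  W
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  om <- occupancy_fraction(x)
  cat("<occupancy_trajectory> ", nrow(x$W) - 1L, " days x ", ncol(x$W),
      " nodes; final occupancy fraction ", format(om$omega[nrow(om)]),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.occupancy_trajectory <- function(x, ...) {
  tibble(day = rep(x$day, times = ncol(x$W)),
         node_id = rep(x$node_id, each = nrow(x$W)),
         occupied = as.integer(x$W))
}

#' Monte-Carlo ensemble of SPOM trajectories on one activation schedule
#'
#' Runs `n_rep` independent trajectories with identical inputs and returns
#' the marginal occupancy probability of every node on every day — the
#' Monte-Carlo counterpart of [exact_occupancy_distribution()].
#'
#' @inheritParams simulate_spom
#' @param n_rep Number of replicates.
#' @return A (T+1) x N matrix of occupancy frequencies.
#' @export
spom_ensemble <- function(net, acts, traits, w0 = NULL, n_rep = 1000,
                          seed = NULL, dt = 1) {
  X <- acts$X
  w0 <- as.integer(w0 %||% X[1, ])
  area <- net$nodes$reach_length_m * net$nodes$width_m
  K <- dispersal_kernel(net, traits$delta)
  counts <- with_seed(seed, {
    spom_core_ensemble(X, parent0(net), K, area, traits$c, traits$e, w0, dt,
                       as.integer(n_rep))
  })
  counts / n_rep
}

#' Exact occupancy distribution for small networks
#'
#' Brute-force enumeration oracle for the colonization/extinction Markov
#' chain: propagates the full `2^N` distribution over occupancy states
#' through the exact per-step transition probabilities (products of
#' independent per-node Bernoulli terms). Feasible for `N <= 12`.
#'
#' @inheritParams simulate_spom
#' @return A list with `marginals` ((T+1) x N matrix of per-node occupancy
#'   probabilities, row 1 = day 0), `extinct` (per-day probability that no
#'   node is occupied) and `state_prob` (final-day distribution over the
#'   `2^N` states).
#' @export
exact_occupancy_distribution <- function(net, acts, traits, w0 = NULL,
                                         dt = 1) {
  X <- acts$X
  n <- ncol(X)
  if (n > 12) abort("exact enumeration is limited to networks of at most 12 nodes")
  T_ <- nrow(X)
  w0 <- as.integer(w0 %||% X[1, ])
  area <- net$nodes$reach_length_m * net$nodes$width_m
  K <- dispersal_kernel(net, traits$delta)
  n_states <- 2L^n
  bits <- t(vapply(0:(n_states - 1L),
                   function(s) as.integer(intToBits(s))[seq_len(n)],
                   integer(n)))                     # states x nodes
  p <- numeric(n_states)
  p[sum(w0 * 2L^(seq_len(n) - 1L)) + 1L] <- 1
  marginals <- matrix(0, T_ + 1L, n)
  extinct <- numeric(T_ + 1L)
  marginals[1, ] <- as.numeric(p %*% bits)
  extinct[1] <- p[1]
  for (t in seq_len(T_)) {
    active <- X[t, ] == 1L
    S <- ifelse(active, area, 0)
    comp <- active_components(net, active)
    same <- outer(comp, comp, "==")
    same[is.na(same)] <- FALSE
    A <- t(K * same) * S                       # A[j, i] = K[i, j] * S[j]
    Cmat <- traits$c * (bits %*% A)            # states x nodes
    phiC <- 1 - exp(-Cmat * dt)
    phiC[, !active] <- 0
    phiE <- ifelse(active, 1 - exp(-traits$e / S * dt), 1)
    p_new <- numeric(n_states)
    for (s in which(p > 0)) {
      # q_i = P(node i occupied next | state s)
      q <- ifelse(bits[s, ] == 1L, 1 - phiE, phiC[s, ])
      # tensor doubling: after appending node i, bit i toggles blocks of
      # 2^(i-1), matching the intToBits state encoding (node 1 = LSB)
      v <- 1
      for (i in seq_len(n)) v <- c(v * (1 - q[i]), v * q[i])
      p_new <- p_new + p[s] * v
    }
    p <- p_new
    marginals[t + 1L, ] <- as.numeric(p %*% bits)
    extinct[t + 1L] <- p[1]
  }
  list(marginals = marginals, extinct = extinct, state_prob = p)
}
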