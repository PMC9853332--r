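#' Stream network objects
#'
#' A `stream_network` is a rooted drainage tree: every node stands for one
#' uniform stream reach and drains to exactly one downstream neighbour, except
#' the single outlet. Node attributes live in a tibble with columns `node_id`
#' (integer, `0..N-1`), `downstream_id` (`NA` at the outlet), planar
#' coordinates `x`, `y` (m), `reach_length_m`, contributing `area_m2`, local
#' `slope` (tan of the bed angle), topographic wetness index `twi` and channel
#' `width_m`.
#'
#' @param nodes Tibble of node attributes (see Details).
#' @param cell_size Side length of one lattice cell (m); also the contour
#'   width used in the TWI and the cell area `cell_size^2` per node.
#' @return An object of class `stream_network`: a list with elements `nodes`
#'   (tibble), `outlet` (node id), `cell_size` and `nnd` (mean along-channel
#'   distance between adjacent nodes, m).
#' @export
stream_network <- function(nodes, cell_size) {
  nodes <- as_tibble(nodes)
  req <- c("node_id", "downstream_id", "x", "y", "reach_length_m")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols) > 0) {
    abort(paste0("nodes is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  nodes <- arrange(nodes, .data$node_id)
  if (!identical(as.integer(nodes$node_id), seq_len(nrow(nodes)) - 1L)) {
    abort("node_id must be the integers 0..N-1")
  }
  outlet <- nodes$node_id[is.na(nodes$downstream_id)]
  if (length(outlet) != 1) abort("exactly one node (the outlet) may lack a downstream neighbour")
  if (any(nodes$reach_length_m <= 0)) abort("reach lengths must be positive")
  for (col in c("area_m2", "slope", "width_m")) {
    if (col %in% names(nodes) && any(!is.na(nodes[[col]]) & nodes[[col]] <= 0)) {
      abort(paste0(col, " must be positive"))
    }
  }
  net <- structure(
    list(nodes = nodes, outlet = as.integer(outlet),
         cell_size = cell_size, nnd = NA_real_),
    class = "stream_network"
  )
  assert_tree(net)
  net$nnd <- mean(nodes$reach_length_m[!is.na(nodes$downstream_id)])
  net
}

# 0-based downstream pointer vector (-1 at the outlet), in node_id order
parent0 <- function(net) {
  p <- net$nodes$downstream_id
  ifelse(is.na(p), -1L, as.integer(p))
}

# BFS order from the outlet over the child relation; errors on cycles or
# disconnected parts (every node must be reachable walking upstream)
upstream_order <- function(net) {
  p <- parent0(net)
  n <- length(p)
  children <- split(seq_len(n) - 1L, factor(p, levels = -1:(n - 1)))
  ord <- integer(n)
  ord[1] <- net$outlet
  head_i <- 1L
  tail_i <- 1L
  while (head_i <= tail_i) {
    u <- ord[head_i]
    kids <- children[[as.character(u)]]
    kids <- kids[kids != u]
    if (length(kids) > 0) {
      ord[(tail_i + 1L):(tail_i + length(kids))] <- kids
      tail_i <- tail_i + length(kids)
    }
    head_i <- head_i + 1L
    if (head_i > n) break
  }
  if (tail_i != n) abort("downstream map is not a tree rooted at the outlet (cycle or disconnected node)")
  ord
}

assert_tree <- function(net) invisible(upstream_order(net))

#' Generate a synthetic dendritic stream network
#'
#' Builds a random drainage tree on a rectangular lattice of square cells and
#' assigns the geomorphic attributes the coupled model needs: contributing
#' area (cell-area accumulation down the tree), local slope (power law of
#' relative area with lognormal noise, see [assign_slopes()]), topographic
#' wetness index and channel width (power law of area, see
#' [compute_width()]).
#'
#' `style = "lattice_random_tree"` draws a uniform spanning tree of the
#' 4-neighbour lattice (Wilson's algorithm) rooted at the outlet in the middle
#' of the bottom edge; all reaches have length `cell_size`.
#' `style = "scheidegger"` routes every cell to one of its two diagonally
#' downslope neighbours at random (reach length `cell_size * sqrt(2)`), with
#' the bottom row draining along the edge to the outlet.
#'
#' @param n_nodes Number of nodes/cells (>= 2). The lattice is the most
#'   nearly square factorisation of `n_nodes`.
#' @param cell_size Cell side (m).
#' @param seed Integer seed; the same seed always yields the same network.
#' @param style Tree construction style.
#' @param slope_exponent,slope_noise_sd,slope_s0 Passed to [assign_slopes()].
#' @param k_w,b_w Width-law coefficients, passed to [compute_width()].
#' @return A [stream_network] with all attribute columns filled.
#' @examples
#' net <- generate_network(60, cell_size = 100, seed = 1)
#' net
#' @export
generate_network <- function(n_nodes, cell_size = 100, seed = 1,
                             style = c("lattice_random_tree", "scheidegger"),
                             slope_exponent = -0.5, slope_noise_sd = 0.5,
                             slope_s0 = 0.05, k_w = NULL, b_w = 0.5) {
  style <- match.arg(style)
  if (!is.numeric(n_nodes) || n_nodes < 2) abort("n_nodes must be at least 2")
  if (!is.numeric(cell_size) || cell_size <= 0) abort("cell_size must be positive")
  n_nodes <- as.integer(n_nodes)

  ny <- max(1L, floor(sqrt(n_nodes)))
  while (n_nodes %% ny != 0L) ny <- ny - 1L
  nx <- n_nodes %/% ny

  cell <- function(ix, iy) (iy - 1L) * nx + ix  # 1-based cell index
  ox <- (nx + 1L) %/% 2L                        # outlet column, bottom row
  outlet <- cell(ox, 1L)

  parent <- with_seed(seed, {
    if (style == "lattice_random_tree") wilson_tree(nx, ny, outlet)
    else scheidegger_tree(nx, ny, ox)
  })

  ix <- (seq_len(n_nodes) - 1L) %% nx + 1L
  iy <- (seq_len(n_nodes) - 1L) %/% nx + 1L
  x <- (ix - 0.5) * cell_size
  y <- (iy - 0.5) * cell_size
  reach_len <- rep(cell_size, n_nodes)
  has_down <- parent > 0L
  reach_len[has_down] <- sqrt((x[has_down] - x[parent[has_down]])^2 +
                              (y[has_down] - y[parent[has_down]])^2)
  reach_len[!has_down] <- cell_size

  nodes <- tibble(
    node_id = seq_len(n_nodes) - 1L,
    downstream_id = ifelse(parent > 0L, parent - 1L, NA_integer_),
    x = x, y = y,
    reach_length_m = reach_len,
    area_m2 = NA_real_, slope = NA_real_, twi = NA_real_, width_m = NA_real_
  )
  net <- stream_network(nodes, cell_size = cell_size)
  net <- compute_contributing_area(net)
  net <- assign_slopes(net, seed = seed + 1L, exponent = slope_exponent,
                       noise_sd = slope_noise_sd, s0 = slope_s0)
  net <- compute_twi(net)
  net <- compute_width(net, k_w = k_w, b_w = b_w)
  net
}

# uniform spanning tree via Wilson's loop-erased random walks,
# 4-neighbour lattice, rooted at `root`; returns 1-based parent (0 = root)
wilson_tree <- function(nx, ny, root) {
  n <- nx * ny
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    ix <- (i - 1L) %% nx + 1L
    iy <- (i - 1L) %/% nx + 1L
    nb <- integer(0)
    if (ix > 1L) nb <- c(nb, i - 1L)
    if (ix < nx) nb <- c(nb, i + 1L)
    if (iy > 1L) nb <- c(nb, i - nx)
    if (iy < ny) nb <- c(nb, i + nx)
    nbrs[[i]] <- nb
  }
  parent <- integer(n)
  in_tree <- logical(n)
  in_tree[root] <- TRUE
  nxt <- integer(n)
  for (start in seq_len(n)) {
    if (in_tree[start]) next
    u <- start
    while (!in_tree[u]) {
      nb <- nbrs[[u]]
      nxt[u] <- nb[sample.int(length(nb), 1L)]
      u <- nxt[u]
    }
    u <- start
    while (!in_tree[u]) {
      parent[u] <- nxt[u]
      in_tree[u] <- TRUE
      u <- nxt[u]
    }
  }
  parent
}

# directed-random-walk drainage: each cell above the bottom row drains to a
# diagonal neighbour one row down; the bottom row drains towards the outlet
scheidegger_tree <- function(nx, ny, ox) {
  n <- nx * ny
  parent <- integer(n)
  for (i in seq_len(n)) {
    ix <- (i - 1L) %% nx + 1L
    iy <- (i - 1L) %/% nx + 1L
    if (iy > 1L) {
      step <- if (ix == 1L) 1L else if (ix == nx) -1L else sample(c(-1L, 1L), 1L)
      parent[i] <- (iy - 2L) * nx + (ix + step)
    } else if (ix != ox) {
      parent[i] <- i + sign(ox - ix)
    } else {
      parent[i] <- 0L
    }
  }
  parent
}

#' Accumulate contributing area down the drainage tree
#'
#' Each node contributes one cell area (`cell_size^2`); the contributing area
#' of a node is its own cell plus the areas of all immediately upstream
#' nodes, so area is non-decreasing downstream and the outlet carries the
#' total basin area. Idempotent.
#'
#' @param net A [stream_network].
#' @return `net` with the `area_m2` column (re)computed.
#' @export
compute_contributing_area <- function(net) {
  ord <- upstream_order(net)  # errors on cycles
  idx <- ord + 1L
  p <- parent0(net)
  area <- rep(net$cell_size^2, nrow(net$nodes))
  for (i in rev(idx)) {
    if (p[i] >= 0L) area[p[i] + 1L] <- area[p[i] + 1L] + area[i]
  }
  net$nodes$area_m2 <- area
  net
}

#' Assign local channel slopes
#'
#' Slopes follow a power law of relative contributing area with lognormal
#' scatter: `tan(beta)_i = s0 * (A_i / A_outlet)^exponent * exp(eps_i)` with
#' `eps_i ~ Normal(0, noise_sd^2)`. The negative default exponent makes
#' headwaters steeper than the main stem; the noise decorrelates the wetness
#' index from contributing area, which is what lets TWI-ranked and
#' area-ranked persistency fields differ.
#'
#' @param net A [stream_network] with areas assigned.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param exponent Power-law exponent on relative area.
#' @param noise_sd Standard deviation of the log-noise (>= 0).
#' @param s0 Slope scale at the outlet.
#' @return `net` with the `slope` column filled.
#' @export
assign_slopes <- function(net, seed = NULL, exponent = -0.5, noise_sd = 0.5,
                          s0 = 0.05) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (anyNA(net$nodes$area_m2)) net <- compute_contributing_area(net)
  a_rel <- net$nodes$area_m2 / net$nodes$area_m2[net$outlet + 1L]
  eps <- with_seed(seed, stats::rnorm(nrow(net$nodes), 0, noise_sd))
  net$nodes$slope <- s0 * a_rel^exponent * exp(eps)
  net
}

#' Topographic wetness index
#'
#' `TWI_i = ln((A_i / w_c) / tan(beta)_i)` with contour width `w_c` equal to
#' the cell size. Strictly increasing in contributing area at fixed slope and
#' strictly decreasing in slope at fixed area.
#'
#' @param net A [stream_network] with areas and slopes assigned.
#' @return `net` with the `twi` column filled.
#' @export
compute_twi <- function(net) {
  a <- net$nodes$area_m2
  s <- net$nodes$slope
  if (anyNA(a) || anyNA(s)) abort("areas and slopes must be assigned before the TWI")
  if (any(a <= 0) || any(s <= 0)) abort("areas and slopes must be positive")
  net$nodes$twi <- log((a / net$cell_size) / s)
  net
}

#' Channel width from contributing area
#'
#' Hydraulic-geometry power law `W_i = k_w * A_i^b_w`. The default `k_w` is
#' calibrated so that the outlet of a 10 km^2 basin is 15 m wide under the
#' default square-root exponent.
#'
#' @param net A [stream_network] with areas assigned.
#' @param k_w Width coefficient (m^(1-2*b_w)); default `15 / (1e7)^b_w`.
#' @param b_w Width exponent.
#' @return `net` with the `width_m` column filled.
#' @export
compute_width <- function(net, k_w = NULL, b_w = 0.5) {
  k_w <- k_w %||% (15 / 1e7^b_w)
  if (k_w <= 0) abort("k_w must be positive")
  if (anyNA(net$nodes$area_m2)) abort("areas must be assigned before widths")
  net$nodes$width_m <- k_w * net$nodes$area_m2^b_w
  net
}

#' Rank nodes by a persistency proxy
#'
#' Orders nodes from least to most persistent according to one of three
#' spatial configurations of local persistency: spatially random, proportional
#' to the topographic wetness index, or proportional to contributing area.
#' Ties are broken by node id.
#'
#' @param net A [stream_network] with the needed attributes.
#' @param scenario One of `"random"`, `"twi"`, `"area"`.
#' @param seed Seed for the `"random"` scenario.
#' @return A tibble of class `proxy_ranking` with columns `node_id` and
#'   `rank` (0-based, ascending persistency), ordered least persistent first;
#'   attribute `scenario` records the configuration.
#' @export
proxy_ranking <- function(net, scenario = c("random", "twi", "area"),
                          seed = NULL) {
  scenario <- match.arg(scenario)
  n <- nrow(net$nodes)
  proxy <- switch(scenario,
    random = with_seed(seed, runif(n)),
    twi = {
      if (anyNA(net$nodes$twi)) abort("twi must be assigned for scenario 'twi'")
      net$nodes$twi
    },
    area = {
      if (anyNA(net$nodes$area_m2)) abort("areas must be assigned for scenario 'area'")
      net$nodes$area_m2
    }
  )
  ord <- order(proxy, net$nodes$node_id)
  out <- tibble(node_id = net$nodes$node_id[ord], rank = seq_len(n) - 1L)
  structure(out, class = c("proxy_ranking", class(out)),
            scenario = scenario, seed = seed)
}

#' @export
as_tibble.stream_network <- function(x, ...) x$nodes

#' @export
print.stream_network <- function(x, ...) {
  cat("<stream_network> ", nrow(x$nodes), " nodes, outlet ", x$outlet,
      ", total length ", format(sum(x$nodes$reach_length_m)), " m, NND ",
      format(x$nnd), " m\n", sep = "")
  print(x$nodes, n = 5)
  invisible(x)
}

#' Read and write stream networks as CSV node tables
#'
#' The on-disk format is one row per node with columns `node_id`,
#' `downstream_id` (empty at the outlet), `x`, `y`, `reach_length_m`,
#' `area_m2`, `slope`, `twi`, `width_m`. Doubles are written in shortest
#' round-trip representation, so write followed by read restores values
#' exactly.
#'
#' @param net A [stream_network].
#' @param path File path.
#' @param cell_size Cell size of the lattice; when `NULL` the reader uses the
#'   smallest reach length (the orthogonal lattice step).
#' @return `write_stream_network()` returns `net` invisibly;
#'   `read_stream_network()` returns a [stream_network].
#' @export
write_stream_network <- function(net, path) {
  readr::write_csv(net$nodes, path, na = "")
  invisible(net)
}

#' @rdname write_stream_network
#' @export
read_stream_network <- function(path, cell_size = NULL) {
  nodes <- readr::read_csv(
    path,
    col_types = readr::cols(
      node_id = readr::col_integer(),
      downstream_id = readr::col_integer(),
      .default = readr::col_double()
    ),
    na = ""
  )
  stream_network(nodes, cell_size = cell_size %||% min(nodes$reach_length_m))
}
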