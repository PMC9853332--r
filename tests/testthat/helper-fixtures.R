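# Hand-built chain network a -> b -> ... -> outlet (node n-1 is the outlet),
# unit-square cells of side `cell`, all reaches `cell` long, constant width.
make_chain_net <- function(n, cell = 100, width = 5, slope = 0.1) {
  nodes <- tibble::tibble(
    node_id = 0:(n - 1),
    downstream_id = c(1:(n - 1), NA),
    x = (0:(n - 1)) * cell + cell / 2,
    y = cell / 2,
    reach_length_m = cell,
    area_m2 = NA_real_,
    slope = slope,
    twi = NA_real_,
    width_m = width
  )
  net <- stream_network(nodes, cell_size = cell)
  net <- compute_contributing_area(net)
  compute_twi(net)
}

# Persistency field with prescribed thresholds, bypassing calibration
# (useful for forcing exact wet/dry schedules).
make_field <- function(net, q_star) {
  n <- nrow(net$nodes)
  out <- tibble::tibble(
    node_id = net$nodes$node_id,
    rank = order(order(-q_star, net$nodes$node_id)) - 1L,
    q_star = q_star,
    p_ref = NA_real_
  )
  structure(out, class = c("persistency_field", class(out)))
}

# Activation series with a fully prescribed wet/dry matrix.
make_acts <- function(net, X) {
  dl <- net$nodes$reach_length_m
  structure(
    list(X = X, day = seq_len(nrow(X)), node_id = net$nodes$node_id,
         q_mm = NULL, L = as.numeric(X %*% dl), reach_length_m = dl,
         total_length_m = sum(dl), parent = riverspom:::parent0(net),
         static = FALSE),
    class = "activation_series"
  )
}
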