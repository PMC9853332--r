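#' Calibrate node activation thresholds from a persistency ranking
#'
#' Under hierarchical activation every node carries a discharge threshold
#' `Q*_i` and is wet whenever catchment discharge equals or exceeds it, so
#' nodes always activate from the most to the least persistent. Thresholds
#' are set by assigning the node of ascending-persistency rank `r` (0-based)
#' the uniform quantile `u_r = (r + rank_offset) / N` and inverting the
#' stationary flow distribution of a reference climate:
#' `Q*_i = F_ref^{-1}(1 - u_r)`. The node's persistency under the reference
#' climate is then exactly `u_r`, and the network-mean persistency is 0.5
#' with the default half-offset. Keeping the thresholds fixed while the
#' climate changes makes persistency a function of climate through the flow
#' distribution alone.
#'
#' @param net A [stream_network].
#' @param ranking A [proxy_ranking()] covering all nodes.
#' @param reference_climate A [climate_params] defining the calibration flow
#'   regime.
#' @param rank_offset Offset in (0, 1) of the quantile ranks.
#' @return A tibble of class `persistency_field` in node-id order with
#'   columns `node_id`, `rank` (ascending persistency), `q_star` (mm d^-1)
#'   and `p_ref` (persistency under the reference climate).
#' @export
calibrate_thresholds <- function(net, ranking, reference_climate,
                                 rank_offset = 0.5) {
  n <- nrow(net$nodes)
  if (!setequal(ranking$node_id, net$nodes$node_id) ||
      anyDuplicated(ranking$rank) > 0) {
    abort("ranking must assign one distinct rank to every node")
  }
  if (rank_offset <= 0 || rank_offset >= 1) abort("rank_offset must be in (0, 1)")
  dist <- stationary_flow_distribution(reference_climate)
  out <- tibble(node_id = ranking$node_id, rank = ranking$rank) |>
    mutate(p_ref = (.data$rank + rank_offset) / n,
           q_star = dist$quantile(1 - .data$p_ref)) |>
    arrange(.data$node_id) |>
    select("node_id", "rank", "q_star", "p_ref")
  structure(out, class = c("persistency_field", class(out)),
            scenario = attr(ranking, "scenario"),
            reference = reference_climate$label,
            rank_offset = rank_offset)
}

#' Evaluate node persistency under a (possibly different) climate
#'
#' `P_i = 1 - F_Q(Q*_i)`, the exceedance probability of the node's threshold
#' under the stationary flow distribution of the given climate.
#'
#' @param field A [calibrate_thresholds()] result.
#' @param climate A [climate_params].
#' @return A tibble with columns `node_id` and `persistency`.
#' @export
persistency_under <- function(field, climate) {
  dist <- stationary_flow_distribution(climate)
  tibble(node_id = field$node_id,
         persistency = 1 - dist$cdf(field$q_star))
}

new_activation_series <- function(X, day, net, q_mm = NULL, static = FALSE) {
  dl <- net$nodes$reach_length_m
  structure(
    list(X = X, day = day, node_id = net$nodes$node_id,
         q_mm = q_mm, L = as.numeric(X %*% dl),
         reach_length_m = dl, total_length_m = sum(dl),
         parent = parent0(net), static = static),
    class = "activation_series"
  )
}

#' Wet/dry state of every node through time
#'
#' Applies the threshold rule `X_i(t) = 1` iff `Q(t) >= Q*_i`. Because all
#' nodes respond to the same discharge signal, active networks are nested:
#' any day with lower flow has an active set contained in that of any day
#' with higher flow.
#'
#' @param net A [stream_network].
#' @param q A `discharge_series` (or numeric vector of daily discharge,
#'   mm d^-1).
#' @param field A `persistency_field` for `net`.
#' @return An object of class `activation_series`: binary matrix `X` (days x
#'   nodes, node-id order), day index, active length `L` (m) per day and the
#'   network geometry needed by downstream computations.
#' @export
activate <- function(net, q, field) {
  q_mm <- if (is.data.frame(q)) q$q_mm else as.numeric(q)
  X <- outer(q_mm, field$q_star, ">=")
  storage.mode(X) <- "integer"
  new_activation_series(X, seq_along(q_mm), net, q_mm = q_mm)
}

#' @export
print.activation_series <- function(x, ...) {
  cat("<activation_series> ", nrow(x$X), " days x ", ncol(x$X), " nodes",
      if (x$static) " (static)", "; mean active length ",
      format(mean(x$L)), " of ", format(x$total_length_m), " m\n", sep = "")
  invisible(x)
}

#' @export
tidy.activation_series <- function(x, ...) {
  tibble(day = rep(x$day, times = ncol(x$X)),
         node_id = rep(x$node_id, each = nrow(x$X)),
         active = as.integer(x$X))
}

#' Empirical (time-mean) persistency of each node
#'
#' @param acts An [activate()] result.
#' @return A tibble with columns `node_id` and `persistency`, the time
#'   fraction each node was active.
#' @export
empirical_persistency <- function(acts) {
  tibble(node_id = acts$node_id, persistency = colMeans(acts$X))
}

#' Largest connected portion (LCP) of the active network
#'
#' Per day, the active nodes induce a subgraph of the drainage tree (an edge
#' is present iff both endpoints are active); the LCP is the largest
#' component's summed reach length, zero when nothing is active.
#'
#' @param net A [stream_network].
#' @param acts An `activation_series` on `net`.
#' @return A tibble with columns `day`, `lcp_m` and `active_m` (total active
#'   length that day).
#' @export
lcp_series <- function(net, acts) {
  lcp <- lcp_lengths_cpp(acts$X, parent0(net), net$nodes$reach_length_m)
  tibble(day = acts$day, lcp_m = lcp, active_m = acts$L)
}

#' Duration curve (exceedance curve) of a daily length series
#'
#' Sorts the series in descending order; the j-th point is equalled or
#' exceeded a fraction `j / T` of the time.
#'
#' @param x Numeric vector (e.g. daily LCP or active length), or a
#'   `lcp_series()` tibble (its `lcp_m` column is used).
#' @return A tibble of class `duration_curve` with columns `exceedance` and
#'   `value`, non-increasing in `value`.
#' @export
duration_curve <- function(x) {
  if (is.data.frame(x)) x <- x$lcp_m
  if (length(x) < 1) abort("need at least one observation")
  v <- sort(as.numeric(x), decreasing = TRUE)
  out <- tibble(exceedance = seq_along(v) / length(v), value = v)
  structure(out, class = c("duration_curve", class(out)))
}

#' Static-equivalent fixed active network
#'
#' The time-invariant network used to benchmark dynamic runs: the smallest
#' prefix of nodes in descending persistency whose cumulative reach length
#' reaches a target (typically the time-mean active length of the dynamic
#' simulations), held constant through time.
#'
#' @param net A [stream_network].
#' @param field A `persistency_field`.
#' @param target_length Target flowing length (m), in `(0, total length]`.
#' @param n_days Number of (identical) days the series should span.
#' @return A time-constant `activation_series`.
#' @export
static_equivalent <- function(net, field, target_length, n_days = 1L) {
  total <- sum(net$nodes$reach_length_m)
  if (target_length <= 0 || target_length > total) {
    abort("target_length must be positive and no larger than the total network length")
  }
  ord <- order(-field$p_ref, field$node_id)    # most persistent first
  cum <- cumsum(net$nodes$reach_length_m[ord])
  m <- which(cum >= target_length - 1e-9)[1]
  active <- logical(nrow(net$nodes))
  active[ord[seq_len(m)]] <- TRUE
  X <- matrix(rep(as.integer(active), each = n_days), nrow = n_days)
  new_activation_series(X, seq_len(n_days), net, static = TRUE)
}
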