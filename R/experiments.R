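#' Length-weighted fraction of the network occupied
#'
#' `Omega(t) = sum_i dl_i * w_i(t) / sum_i dl_i`, normalised by the total
#' geomorphic network length, so `Omega = 1` means every node is occupied
#' and `Omega = 0` means the species is extinct network-wide.
#'
#' @param traj An [simulate_spom()] trajectory.
#' @return A tibble with columns `day` (0..T) and `omega`.
#' @export
occupancy_fraction <- function(traj) {
  tibble(day = traj$day,
         omega = as.numeric(traj$W %*% traj$reach_length_m) /
           traj$total_length_m)
}

#' Fraction of replicates whose metapopulation survived
#'
#' A replicate survives when its occupancy fraction on the final simulated
#' day is positive.
#'
#' @param omega A tibble with columns `replicate`, `day`, `omega` (and
#'   optionally `model`), e.g. `tidy(run_scenario(...))`.
#' @return A tibble with columns (`model`,) `survival`, `n`.
#' @export
survival_probability <- function(omega) {
  grp <- intersect("model", names(omega))
  omega |>
    group_by(across(all_of(c(grp, "replicate")))) |>
    summarise(alive = .data$omega[which.max(.data$day)] > 0,
              .groups = "drop_last") |>
    summarise(survival = mean(.data$alive), n = dplyr::n(), .groups = "drop")
}

# population standard deviation (divide by n, not n-1): makes the two-point
# identity CV = |a-b|/(a+b) exact and is negligible at T = 365
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Mean temporal coefficient of variation of occupancy
#'
#' Per replicate, the CV of `Omega(t)` over days `1..T` (the initial
#' condition at day 0 is excluded); replicates with zero mean occupancy are
#' excluded from the average, and the inclusion count is reported.
#'
#' @inheritParams survival_probability
#' @return A tibble with columns (`model`,) `mean_cv`, `n_included`,
#'   `n_total`. `mean_cv` is `NA` when every replicate was excluded.
#' @export
temporal_cv <- function(omega) {
  grp <- intersect("model", names(omega))
  omega |>
    filter(.data$day > 0) |>
    group_by(across(all_of(c(grp, "replicate")))) |>
    summarise(m = mean(.data$omega), s = pop_sd(.data$omega),
              .groups = "drop_last") |>
    summarise(mean_cv = if (any(.data$m > 0)) mean(.data$s[.data$m > 0] / .data$m[.data$m > 0]) else NA_real_,
              n_included = sum(.data$m > 0), n_total = dplyr::n(),
              .groups = "drop")
}

#' Time fraction each node is occupied
#'
#' @param trajs An [simulate_spom()] trajectory or a list of them (the
#'   ensemble average is returned); days `1..T` are used.
#' @return A tibble with columns `node_id` and `occupancy`.
#' @export
local_occupancy <- function(trajs) {
  if (inherits(trajs, "occupancy_trajectory")) trajs <- list(trajs)
  per_rep <- purrr::map(trajs, function(tr) colMeans(tr$W[-1, , drop = FALSE]))
  tibble(node_id = trajs[[1]]$node_id,
         occupancy = Reduce(`+`, per_rep) / length(per_rep))
}

#' Scenario configuration
#'
#' Bundles everything one climate x persistency experiment needs: the
#' network, the climate, the persistency scenario, the species, the
#' Monte-Carlo design and the seed. Thresholds are calibrated on a reference
#' climate (default: the intermediate preset with the same recession rate),
#' shared across climates so that climate changes move persistency through
#' the flow distribution alone.
#'
#' @param climate A [climate_params] (or preset name).
#' @param scenario Persistency configuration: `"random"`, `"twi"`, `"area"`.
#' @param net A [stream_network].
#' @param n_days Simulation horizon (d).
#' @param n_mc Number of Monte-Carlo replicates.
#' @param traits A [species_traits]; default the focal species of `net`.
#' @param base_seed Integer master seed; every replicate seed derives from it.
#' @param reference_climate Climate whose flow distribution calibrates the
#'   thresholds.
#' @param rank_offset Quantile-rank offset, see [calibrate_thresholds()].
#' @param run_static Also run the static-equivalent counterpart.
#' @param dt Time step; only the daily resolution the model is calibrated
#'   for (`dt = 1`) is accepted.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(climate, scenario = c("random", "twi", "area"),
                            net, n_days = 365, n_mc = 50, traits = NULL,
                            base_seed = 1,
                            reference_climate = NULL, rank_offset = 0.5,
                            run_static = TRUE, dt = 1) {
  if (is.character(climate)) climate <- climate_preset(climate)
  scenario <- match.arg(scenario)
  if (!identical(as.numeric(dt), 1)) abort("only the daily time step dt = 1 is supported")
  if (n_days < 1 || n_mc < 1) abort("n_days and n_mc must be at least 1")
  reference_climate <- reference_climate %||% climate_preset("intermediate", k = climate$k)
  structure(
    list(climate = climate, scenario = scenario, net = net,
         n_days = as.integer(n_days), n_mc = as.integer(n_mc),
         traits = traits %||% focal_species(net),
         base_seed = as.integer(base_seed),
         reference_climate = reference_climate,
         rank_offset = rank_offset, run_static = isTRUE(run_static), dt = 1),
    class = "scenario_config"
  )
}

# replicate-level sub-seeds, all derived reproducibly from the master seed
draw_seeds <- function(base_seed, n, k) {
  with_seed(base_seed,
            matrix(sample.int(.Machine$integer.max, n * k), nrow = n))
}

#' Run one climate x persistency scenario
#'
#' Two-pass Monte-Carlo design. Pass 1 simulates `n_mc` independent
#' discharge realisations and their activation series; the ensemble mean of
#' the time-mean active length defines the target length of the scenario's
#' static-equivalent network. Pass 2 runs, for every replicate, the dynamic
#' SPOM on its pulsing network and (optionally) a static SPOM on the shared
#' static-equivalent network. Fully reproducible from `base_seed`.
#'
#' @param cfg A [scenario_config()].
#' @return An object of class `scenario_result`; see [tidy()] and
#'   [glance()] methods, and fields `omega` (long tibble), `local_occupancy`,
#'   `lcp` (pooled per-day LCP lengths), `field`, `target_length_m`, `seeds`.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  net <- cfg$net
  T_ <- cfg$n_days
  seeds <- draw_seeds(cfg$base_seed, cfg$n_mc, 4)
  ranking <- proxy_ranking(net, cfg$scenario, seed = cfg$base_seed)
  field <- calibrate_thresholds(net, ranking, cfg$reference_climate,
                                cfg$rank_offset)

  acts <- purrr::map(seq_len(cfg$n_mc), function(r) {
    q <- simulate_climate_discharge(cfg$climate, T_, seed = seeds[r, 1])
    activate(net, q, field)
  })
  target_len <- mean(purrr::map_dbl(acts, function(a) mean(a$L)))
  static_acts <- if (cfg$run_static) {
    static_equivalent(net, field, target_len, n_days = T_)
  }

  runs <- purrr::map(seq_len(cfg$n_mc), function(r) {
    dyn <- simulate_spom(net, acts[[r]], cfg$traits, seed = seeds[r, 2])
    out <- list(dynamic = dyn)
    if (cfg$run_static) {
      out$static <- simulate_spom(net, static_acts, cfg$traits,
                                  seed = seeds[r, 3])
    }
    out
  })

  omega <- purrr::imap(runs, function(run, r) {
    bind_rows(purrr::imap(run, function(tr, model) {
      occupancy_fraction(tr) |> mutate(model = model, replicate = r)
    }))
  }) |>
    bind_rows() |>
    select("replicate", "model", "day", "omega")

  lcp <- purrr::imap(acts, function(a, r) {
    lcp_series(net, a) |> mutate(replicate = r)
  }) |> bind_rows()

  res <- list(
    config = cfg,
    seeds = seeds,
    field = field,
    target_length_m = target_len,
    omega = omega,
    lcp = lcp,
    local_occupancy = local_occupancy(purrr::map(runs, "dynamic")),
    mean_persistency = mean(persistency_under(field, cfg$climate)$persistency),
    mean_active_m = mean(purrr::map_dbl(acts, function(a) mean(a$L))),
    mean_lcp_m = mean(lcp$lcp_m),
    total_length_m = sum(net$nodes$reach_length_m)
  )
  structure(res, class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  g <- glance(x)
  cat("<scenario_result> climate=", g$climate, ", persistency=", g$scenario,
      ", n_mc=", g$n_mc, "\n  survival: dynamic ", format(g$survival_dynamic),
      if (!is.na(g$survival_static)) paste0(", static ", format(g$survival_static)),
      "\n  mean occupancy: dynamic ", format(signif(g$mean_omega_dynamic, 3)),
      if (!is.na(g$mean_omega_static)) paste0(", static ", format(signif(g$mean_omega_static, 3))),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.scenario_result <- function(x, ...) x$omega

#' @export
glance.scenario_result <- function(x, ...) {
  surv <- survival_probability(x$omega)
  cv <- temporal_cv(x$omega)
  om <- x$omega |>
    filter(.data$day > 0) |>
    group_by(.data$model) |>
    summarise(mean_omega = mean(.data$omega))
  pick <- function(tb, col, model) {
    v <- tb[[col]][tb$model == model]
    if (length(v) == 1) v else NA_real_
  }
  tibble(
    climate = x$config$climate$label,
    scenario = x$config$scenario,
    n_mc = x$config$n_mc,
    survival_dynamic = pick(surv, "survival", "dynamic"),
    survival_static = pick(surv, "survival", "static"),
    cv_dynamic = pick(cv, "mean_cv", "dynamic"),
    cv_static = pick(cv, "mean_cv", "static"),
    cv_n_dynamic = pick(cv, "n_included", "dynamic"),
    mean_omega_dynamic = pick(om, "mean_omega", "dynamic"),
    mean_omega_static = pick(om, "mean_omega", "static"),
    mean_persistency = x$mean_persistency,
    mean_active_m = x$mean_active_m,
    mean_lcp_m = x$mean_lcp_m,
    target_length_m = x$target_length_m
  )
}

#' Survival sensitivity map over colonization/extinction trait grids
#'
#' For every `(c, e)` cell of a log-spaced grid, runs `n_mc` Monte-Carlo
#' replicates of the dynamic model (and of the static-equivalent model) with
#' the dispersal distance of `cfg$traits`, and records the survival
#' probability at the end of the horizon. Discharge and activation
#' realisations are shared across cells, so the grid isolates the species
#' traits.
#'
#' @param cfg A [scenario_config()].
#' @param c_grid,e_grid Trait grids (m^-2 d^-1 and m^2 d^-1).
#' @param n_mc Replicates per cell (default `cfg$n_mc`).
#' @return A tibble with columns `c`, `e`, `survival_dynamic`,
#'   `survival_static`, `n_mc`.
#' @export
sensitivity_analysis <- function(cfg,
                                 c_grid = 10^seq(-5, 2, length.out = 8),
                                 e_grid = 10^seq(-3, 3, length.out = 7),
                                 n_mc = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (length(c_grid) < 1 || length(e_grid) < 1) abort("grids must be non-empty")
  n_mc <- n_mc %||% cfg$n_mc
  net <- cfg$net
  T_ <- cfg$n_days
  seeds <- draw_seeds(cfg$base_seed, n_mc, 2 + 2 * length(c_grid) * length(e_grid))
  ranking <- proxy_ranking(net, cfg$scenario, seed = cfg$base_seed)
  field <- calibrate_thresholds(net, ranking, cfg$reference_climate,
                                cfg$rank_offset)
  acts <- purrr::map(seq_len(n_mc), function(r) {
    q <- simulate_climate_discharge(cfg$climate, T_, seed = seeds[r, 1])
    activate(net, q, field)
  })
  target_len <- mean(purrr::map_dbl(acts, function(a) mean(a$L)))
  static_acts <- static_equivalent(net, field, target_len, n_days = T_)

  area <- net$nodes$reach_length_m * net$nodes$width_m
  K <- dispersal_kernel(net, cfg$traits$delta)
  par0 <- parent0(net)
  survived <- function(W) any(W[nrow(W), ] == 1L)

  grid <- tidyr::expand_grid(e = e_grid, c = c_grid)
  out <- purrr::pmap(list(grid$c, grid$e, seq_len(nrow(grid))),
                     function(cc, ee, cell) {
    alive_d <- alive_s <- logical(n_mc)
    for (r in seq_len(n_mc)) {
      Wd <- with_seed(seeds[r, 2 * cell + 1], {
        spom_core(acts[[r]]$X, par0, K, area, cc, ee,
                  as.integer(acts[[r]]$X[1, ]), 1)
      })
      alive_d[r] <- survived(Wd)
      Ws <- with_seed(seeds[r, 2 * cell + 2], {
        spom_core(static_acts$X, par0, K, area, cc, ee,
                  as.integer(static_acts$X[1, ]), 1)
      })
      alive_s[r] <- survived(Ws)
    }
    tibble(c = cc, e = ee, survival_dynamic = mean(alive_d),
           survival_static = mean(alive_s), n_mc = n_mc)
  }) |> bind_rows()
  out
}

#' Draw a pool of virtual species
#'
#' Dispersal distance uniform on 1-10 nearest-neighbour distances,
#' colonization rate log-uniform on `[1e-5, 1e2]` m^-2 d^-1 and extinction
#' rate log-uniform on `[1e-3, 1e3]` m^2 d^-1.
#'
#' @param n Number of species.
#' @param net A [stream_network] (supplies the NND).
#' @param seed Integer seed.
#' @return A tibble with columns `species`, `c`, `e`, `delta_nnd`,
#'   `delta_m`.
#' @export
species_pool <- function(n, net, seed = NULL) {
  if (n < 1) abort("n must be at least 1")
  with_seed(seed, {
    tibble(
      species = seq_len(n),
      c = 10^runif(n, -5, 2),
      e = 10^runif(n, -3, 3),
      delta_nnd = runif(n, 1, 10)
    ) |> mutate(delta_m = .data$delta_nnd * net$nnd)
  })
}

#' Export a scenario result to plain-text files
#'
#' Writes `omega_timeseries.csv` (replicate, day, omega by model),
#' `local_occupancy.csv` and `summary.json` (the [glance()] row plus seeds
#' and configuration scalars) under `dir`.
#'
#' @param res A [run_scenario()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario_summary <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- res$omega |>
    tidyr::pivot_wider(names_from = "model", values_from = "omega",
                       names_prefix = "omega_")
  readr::write_csv(wide, file.path(dir, "omega_timeseries.csv"))
  readr::write_csv(res$local_occupancy, file.path(dir, "local_occupancy.csv"))
  g <- glance(res)
  summary <- c(as.list(g),
               list(base_seed = res$config$base_seed,
                    n_days = res$config$n_days,
                    traits = unclass(res$config$traits),
                    rank_offset = res$config$rank_offset,
                    reference_climate = res$config$reference_climate$label))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
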