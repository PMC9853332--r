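#' Climate parameter sets for the stochastic streamflow model
#'
#' Daily effective rainfall is a marked Poisson process (frequency `lambda`
#' d^-1, exponentially distributed depths with mean `alpha` mm) feeding a
#' linear reservoir with recession rate `k` d^-1. `lambda_p` is the frequency
#' of all rainfall events and `e_p` the potential evapotranspiration; the
#' derived mean total precipitation is `p_t = alpha * lambda_p` and the
#' actual evapotranspiration `e_a = p_t - alpha * lambda`. The effective
#' frequency `lambda` is a configured input (its soil-moisture derivation
#' needs a storage parameter outside this model's scope).
#'
#' @param alpha Mean effective rainfall depth per event (mm).
#' @param lambda_p Total rainfall frequency (d^-1).
#' @param e_p Potential evapotranspiration (mm d^-1).
#' @param lambda Effective rainfall frequency (d^-1), `<= lambda_p`.
#' @param k Recession rate (d^-1).
#' @param label Scenario label.
#' @return An object of class `climate_params`.
#' @examples
#' climate_preset("intermediate")$e_a  # 2.16 mm/d
#' @export
climate_params <- function(alpha, lambda_p, e_p, lambda, k = 0.35,
                           label = "custom") {
  vals <- c(alpha = alpha, lambda_p = lambda_p, e_p = e_p, lambda = lambda, k = k)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("alpha, lambda_p, e_p, lambda and k must all be positive")
  }
  if (lambda > lambda_p) abort("lambda cannot exceed lambda_p")
  if (lambda == lambda_p) {
    warn("lambda equals lambda_p: actual evapotranspiration is zero (boundary case)")
  }
  structure(
    list(alpha = alpha, lambda_p = lambda_p, e_p = e_p, lambda = lambda,
         k = k, p_t = alpha * lambda_p, e_a = alpha * lambda_p - alpha * lambda,
         label = label),
    class = "climate_params"
  )
}

#' @rdname climate_params
#' @param name Preset name: `"dry"`, `"intermediate"` (or `"int"`), `"wet"`.
#' @export
climate_preset <- function(name = c("dry", "intermediate", "wet", "int"),
                           k = 0.35) {
  name <- match.arg(name)
  if (name == "int") name <- "intermediate"
  p <- switch(name,
    dry          = list(alpha = 15.0, lambda_p = 0.25, e_p = 3.0, lambda = 0.10),
    intermediate = list(alpha = 12.0, lambda_p = 0.40, e_p = 2.5, lambda = 0.22),
    wet          = list(alpha = 10.0, lambda_p = 0.55, e_p = 2.0, lambda = 0.37)
  )
  climate_params(p$alpha, p$lambda_p, p$e_p, p$lambda, k = k, label = name)
}

#' @export
print.climate_params <- function(x, ...) {
  cat("<climate_params> ", x$label,
      ": alpha=", x$alpha, " mm, lambda_p=", x$lambda_p,
      " /d, E_p=", x$e_p, " mm/d, lambda=", x$lambda,
      " /d, k=", x$k, " /d, P_t=", format(x$p_t),
      " mm/d, E_a=", format(x$e_a), " mm/d\n", sep = "")
  invisible(x)
}

#' Simulate daily effective rainfall
#'
#' Event counts per day are Poisson(`lambda`) and event depths exponential
#' with mean `alpha`; the returned series is the per-day total. Event-level
#' detail (arrival time within the day, depth) is kept in the `events`
#' attribute so the discharge simulator can sample the continuous reservoir
#' process exactly.
#'
#' @param climate A [climate_params].
#' @param n_days Series length (days, >= 1).
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A tibble with columns `day` (1..n_days) and `rain_mm`, carrying
#'   attributes `events` (tibble `day`, `tau`, `depth_mm`) and `climate`.
#' @export
effective_rainfall <- function(climate, n_days, seed = NULL) {
  stopifnot(inherits(climate, "climate_params"))
  if (n_days < 1) abort("n_days must be at least 1")
  n_days <- as.integer(n_days)
  ev <- with_seed(seed, {
    counts <- rpois(n_days, climate$lambda)
    m <- sum(counts)
    tibble(
      day = rep.int(seq_len(n_days), counts),
      tau = runif(m),                     # event time as fraction of the day
      depth_mm = rexp(m, rate = 1 / climate$alpha)
    )
  })
  rain <- numeric(n_days)
  if (nrow(ev) > 0) {
    agg <- rowsum(ev$depth_mm, ev$day)
    rain[as.integer(rownames(agg))] <- agg[, 1]
  }
  out <- tibble(day = seq_len(n_days), rain_mm = rain)
  attr(out, "events") <- ev
  attr(out, "climate") <- climate
  attr(out, "seed") <- seed
  out
}

#' Simulate daily discharge from a rainfall series
#'
#' Linear storage-discharge: between rainfall pulses, specific discharge
#' decays exponentially at rate `k`; each effective-rainfall pulse of depth
#' `h` raises discharge by `k * h`. With `sampling = "continuous"` (default)
#' pulses occur at their within-day arrival times and the series is the
#' continuous process sampled at the end of each day, so the stationary
#' marginal is exactly Gamma(shape `lambda/k`, scale `alpha*k`). With
#' `sampling = "day_boundary"` the whole daily total is applied as one pulse
#' at the end of the day (`Q_t = Q_{t-1} e^{-k} + k h_t`), a simpler scheme
#' whose stationary mean is biased upward by `k / (1 - e^{-k})`.
#'
#' @param rain Output of [effective_rainfall()], or a numeric vector of daily
#'   depths (mm).
#' @param k Recession rate (d^-1); defaults to the rain series' climate.
#' @param q0 Initial discharge (mm d^-1) or `"stationary"` to draw it from
#'   the stationary gamma law (requires a climate).
#' @param seed Seed for the initial condition (and pulse times when the rain
#'   series carries no event detail).
#' @param sampling Pulse-timing scheme, see Details.
#' @param climate Optional [climate_params] when `rain` is a bare vector.
#' @return A tibble of class `discharge_series` with columns `day`,
#'   `rain_mm`, `q_mm`.
#' @export
simulate_discharge <- function(rain, k = NULL, q0 = "stationary", seed = NULL,
                               sampling = c("continuous", "day_boundary"),
                               climate = NULL) {
  sampling <- match.arg(sampling)
  climate <- climate %||% attr(rain, "climate")
  events <- attr(rain, "events")
  if (is.data.frame(rain)) {
    depths <- rain$rain_mm
  } else {
    depths <- as.numeric(rain)
  }
  if (any(depths < 0)) abort("rainfall depths cannot be negative")
  k <- k %||% climate$k
  if (is.null(k) || k <= 0) abort("k must be positive")
  n_days <- length(depths)

  with_seed(seed, {
    if (identical(q0, "stationary")) {
      if (is.null(climate)) {
        abort("q0 = \"stationary\" needs a climate (attach one or pass climate=)")
      }
      q0 <- rgamma(1, shape = climate$lambda / k, scale = climate$alpha * k)
    }
    if (sampling == "continuous") {
      if (is.null(events)) {
        # one pulse per rainy day at a uniform time: unbiased in the mean
        tau <- runif(n_days)
        jumps <- k * depths * exp(-k * (1 - tau))
      } else {
        wt <- k * events$depth_mm * exp(-k * (1 - events$tau))
        jumps <- numeric(n_days)
        if (nrow(events) > 0) {
          agg <- rowsum(wt, events$day)
          jumps[as.integer(rownames(agg))] <- agg[, 1]
        }
      }
    } else {
      jumps <- k * depths
    }
    q <- as.numeric(stats::filter(jumps, exp(-k), method = "recursive",
                                  init = q0))
    out <- tibble(day = seq_len(n_days), rain_mm = depths, q_mm = q)
    structure(out, class = c("discharge_series", class(out)),
              k = k, q0 = q0, climate = climate, seed = seed,
              sampling = sampling)
  })
}

#' One-call climate-to-discharge simulation
#'
#' @inheritParams effective_rainfall
#' @inheritParams simulate_discharge
#' @return A `discharge_series` tibble (see [simulate_discharge()]).
#' @export
simulate_climate_discharge <- function(climate, n_days, seed = NULL,
                                       q0 = "stationary",
                                       sampling = "continuous") {
  with_seed(seed, {
    rain <- effective_rainfall(climate, n_days, seed = NULL)
    simulate_discharge(rain, k = climate$k, q0 = q0, seed = NULL,
                       sampling = sampling)
  })
}

#' Stationary distribution of daily discharge
#'
#' Under the Poisson-rainfall linear-reservoir model the stationary specific
#' discharge is Gamma distributed with shape `lambda / k` and scale
#' `alpha * k`, hence mean `alpha * lambda` and squared coefficient of
#' variation `k / lambda`.
#'
#' @param climate A [climate_params].
#' @return A list of class `flow_distribution` with fields `shape`, `scale`,
#'   `mean`, `cv2` and functions `pdf`, `cdf`, `quantile`.
#' @export
stationary_flow_distribution <- function(climate) {
  stopifnot(inherits(climate, "climate_params"))
  shape <- climate$lambda / climate$k
  scale <- climate$alpha * climate$k
  structure(
    list(
      shape = shape, scale = scale,
      mean = shape * scale, cv2 = climate$k / climate$lambda,
      pdf = function(x) dgamma(x, shape = shape, scale = scale),
      cdf = function(x) pgamma(x, shape = shape, scale = scale),
      quantile = function(p) qgamma(p, shape = shape, scale = scale),
      climate = climate
    ),
    class = "flow_distribution"
  )
}

#' @export
print.flow_distribution <- function(x, ...) {
  cat("<flow_distribution> Gamma(shape=", format(x$shape), ", scale=",
      format(x$scale), ") mm/d; mean=", format(x$mean), ", CV^2=",
      format(x$cv2), "\n", sep = "")
  invisible(x)
}
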