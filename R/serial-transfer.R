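#' Daily serial-transfer protocol
#'
#' Describes the 24-well daily passaging protocol: each day the selected
#' culture is diluted into eight wells at factors 10^1..10^8, grown for
#' `incubation_h`, and the single well found in early exponential phase
#' (OD600 inside `od_window`) is carried forward.
#'
#' The default regrowth is deterministic exponential growth capped at the
#' carrying capacity, with `mu_ref` calibrated so that an unsaturated well
#' regrows 2^8 = 256-fold in 24 h; a selected (in-window, unsaturated) well
#' then accumulates exactly 8 generations per day, i.e. 400 generations over
#' the 50-day protocol. Optional multiplicative OD noise (`od_noise_sd`, on
#' the log scale) makes the overnight densities stochastic.
#'
#' @param n_days Number of daily transfers (default 50).
#' @param dilution_ratios Strictly increasing dilution factors (default
#'   `10^(1:8)`).
#' @param od_window Closed OD600 selection interval (default 0.001..0.05).
#' @param incubation_h Incubation time between transfers, hours.
#' @param tie_break Rule when several wells land in the window; only
#'   `"geometric_midpoint"` (nearest to sqrt(lower*upper) in log-OD) is
#'   implemented.
#' @param od_init OD600 of the founding culture at day 0.
#' @param carrying_capacity Saturating OD600 of the growth model.
#' @param od_noise_sd Log-scale sd of multiplicative OD noise (0 = exact).
#' @return A list of class `transfer_protocol`.
#' @export
transfer_protocol <- function(n_days = 50, dilution_ratios = 10^(1:8),
                              od_window = c(0.001, 0.05), incubation_h = 24,
                              tie_break = "geometric_midpoint",
                              od_init = 0.01, carrying_capacity = 0.5,
                              od_noise_sd = 0) {
  stopifnot(n_days >= 0, all(diff(dilution_ratios) > 0),
            length(od_window) == 2, od_window[1] < od_window[2],
            incubation_h > 0, od_init > 0, carrying_capacity > od_window[2],
            od_noise_sd >= 0)
  tie_break <- match.arg(tie_break, "geometric_midpoint")
  structure(list(n_days = as.integer(n_days),
                 dilution_ratios = dilution_ratios, od_window = od_window,
                 incubation_h = incubation_h, tie_break = tie_break,
                 od_init = od_init, carrying_capacity = carrying_capacity,
                 od_noise_sd = od_noise_sd),
            class = "transfer_protocol")
}

#' Growth-rate adaptation model for serial transfer
#'
#' Minimal monotone (hyperbolically saturating) adaptation of the growth rate
#' with cumulative generations `g`:
#' `mu(g) = mu_start + (mu_max - mu_start) * g / (g + half_saturation)`,
#' with the mutation rate tied to the growth rate through the growth-rate
#' scaling law `log10(M) = log10_M0 + alpha * mu` at every point of the
#' trajectory. Setting `mu_max = mu_start` disables adaptation.
#'
#' The default rates are the 24-h / 8-generation calibration of
#' [transfer_protocol()] (`mu_start = 8 * log(2) / 24` per hour); the default
#' coupling coefficients are the M63 values of the growth-rate scaling law.
#'
#' @param mu_start Growth rate at generation 0 (1/h).
#' @param mu_max Asymptotic growth rate (>= `mu_start`); equal to `mu_start`
#'   disables adaptation.
#' @param half_saturation_generations Generations at which half of the
#'   adaptive gain is realised.
#' @param alpha,log10_M0 Coefficients coupling the mutation rate to `mu`.
#' @return A list of class `adaptation_model`.
#' @export
adaptation_model <- function(mu_start = 8 * log(2) / 24, mu_max = mu_start,
                             half_saturation_generations = 150,
                             alpha = -4.9, log10_M0 = -6.1) {
  stopifnot(mu_start > 0, mu_max >= mu_start,
            half_saturation_generations > 0)
  structure(list(mu_start = mu_start, mu_max = mu_max,
                 half_saturation_generations = half_saturation_generations,
                 alpha = alpha, log10_M0 = log10_M0),
            class = "adaptation_model")
}

adapted_mu <- function(model, generations) {
  model$mu_start + (model$mu_max - model$mu_start) * generations /
    (generations + model$half_saturation_generations)
}

coupled_M <- function(model, mu) 10^(model$log10_M0 + model$alpha * mu)

#' Select the transfer well from overnight optical densities
#'
#' Returns the index of the unique well whose OD lies in the closed selection
#' window. When several wells qualify, the tie is broken in favour of the
#' well nearest (in log OD) to the geometric midpoint
#' `sqrt(lower * upper)` of the window; no well in the window is a protocol
#' failure (washout or saturation).
#'
#' @param od_values Overnight OD600 of the wells, ordered by dilution.
#' @param od_window Closed selection interval.
#' @return Integer index into `od_values`.
#' @examples
#' select_transfer_well(c(0.5, 0.2, 0.05, 0.02, 0.005, 8e-4))  # 5
#' @export
select_transfer_well <- function(od_values, od_window = c(0.001, 0.05)) {
  ok <- which(od_values >= od_window[1] & od_values <= od_window[2])
  if (length(ok) == 0) {
    stop("protocol failure (washout or saturation): no well in OD window [",
         od_window[1], ", ", od_window[2], "]", call. = FALSE)
  }
  if (length(ok) == 1) return(ok)
  mid <- sqrt(od_window[1] * od_window[2])
  ok[which.min(abs(log(od_values[ok]) - log(mid)))]
}

default_regrowth <- function(od_start, mu, protocol) {
  pmin(od_start * exp(mu * protocol$incubation_h),
       protocol$carrying_capacity)
}

#' Simulate one serial-transfer day
#'
#' Dilutes the previous day's selected culture into the protocol's wells,
#' grows each well for the incubation time under the growth model, selects
#' the well in the early-exponential window, and accounts generations as
#' `log2(od_selected * dilution / od_previous)`.
#'
#' @param state List with at least `day`, `od_at_selection` (previous day's
#'   selected OD) and `cumulative_generations`; see [run_serial_transfer()].
#' @param protocol A [transfer_protocol()].
#' @param mu Growth rate used for today's regrowth (1/h).
#' @param regrowth Growth model `function(od_start, mu, protocol)` returning
#'   the OD after incubation; defaults to capped exponential regrowth.
#' @param noise Optional multiplicative noise factors, one per well
#'   (internal; drawn by [run_serial_transfer()] when `od_noise_sd > 0`).
#' @return The updated state: `day`, `od_at_selection`, `selected_dilution`,
#'   `generations_today`, `cumulative_generations`.
#' @export
simulate_transfer_day <- function(state, protocol, mu,
                                  regrowth = default_regrowth,
                                  noise = NULL) {
  od_prev <- state$od_at_selection
  stopifnot(od_prev > 0)
  wells <- regrowth(od_prev / protocol$dilution_ratios, mu, protocol)
  if (!is.null(noise)) {
    wells <- pmin(wells * noise, protocol$carrying_capacity)
  }
  sel <- select_transfer_well(wells, protocol$od_window)
  gen <- log2(wells[sel] * protocol$dilution_ratios[sel] / od_prev)
  list(day = state$day + 1L,
       od_at_selection = wells[sel],
       selected_dilution = protocol$dilution_ratios[sel],
       generations_today = gen,
       cumulative_generations = state$cumulative_generations + gen)
}

#' Run the serial-transfer evolution simulation
#'
#' Iterates [simulate_transfer_day()] for the protocol's `n_days`. Each day's
#' growth rate follows the adaptation model as a function of the generations
#' accumulated so far, and the mutation rate follows the growth rate through
#' the coupled scaling law, so every trajectory point satisfies
#' `log10(M) = log10_M0 + alpha * mu` exactly.
#'
#' @param protocol A [transfer_protocol()].
#' @param adaptation An [adaptation_model()].
#' @param seed RNG seed, used only when the protocol has `od_noise_sd > 0`.
#' @return A tibble of class `transfer_trajectory` with one row per day:
#'   `day`, `selected_dilution`, `od`, `generations_today`,
#'   `cumulative_generations`, `mu`, `M`. Attributes `mu_fold_change` and
#'   `log10_M_change` summarise the endpoint against day 0.
#' @examples
#' tr <- run_serial_transfer()
#' tail(tr$cumulative_generations, 1)  # 400 under the default calibration
#' @export
run_serial_transfer <- function(protocol = transfer_protocol(),
                                adaptation = adaptation_model(),
                                seed = 1) {
  stopifnot(inherits(protocol, "transfer_protocol"),
            inherits(adaptation, "adaptation_model"))
  noise_mat <- NULL
  if (protocol$od_noise_sd > 0 && protocol$n_days > 0) {
    noise_mat <- withr::with_seed(seed, matrix(
      exp(rnorm(protocol$n_days * length(protocol$dilution_ratios),
                0, protocol$od_noise_sd)),
      nrow = protocol$n_days))
  }
  state <- list(day = 0L, od_at_selection = protocol$od_init,
                cumulative_generations = 0)
  rows <- vector("list", protocol$n_days)
  for (d in seq_len(protocol$n_days)) {
    mu <- adapted_mu(adaptation, state$cumulative_generations)
    state <- tryCatch(
      simulate_transfer_day(state, protocol, mu,
                            noise = if (is.null(noise_mat)) NULL else
                              noise_mat[d, ]),
      error = function(e) {
        stop("day ", d, ": ", conditionMessage(e), call. = FALSE)
      })
    rows[[d]] <- tibble::tibble(
      day = state$day, selected_dilution = state$selected_dilution,
      od = state$od_at_selection,
      generations_today = state$generations_today,
      cumulative_generations = state$cumulative_generations,
      mu = mu, M = coupled_M(adaptation, mu))
  }
  traj <- if (protocol$n_days == 0) {
    tibble::tibble(day = integer(), selected_dilution = numeric(),
                   od = numeric(), generations_today = numeric(),
                   cumulative_generations = numeric(), mu = numeric(),
                   M = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  mu0 <- adaptation$mu_start
  attr(traj, "mu_fold_change") <- if (nrow(traj)) tail(traj$mu, 1) / mu0
    else 1
  attr(traj, "log10_M_change") <- if (nrow(traj)) {
    log10(tail(traj$M, 1)) - log10(coupled_M(adaptation, mu0))
  } else 0
  class(traj) <- c("transfer_trajectory", class(traj))
  traj
}
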