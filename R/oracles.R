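#' Dominating severity process (linear-rate oracle)
#'
#' Simulates the integer-valued severity process in which node `i`'s state
#' `Y_i` rises by one at rate `beta * f'(0) * sum_j W[i, j] * Y_j` and
#' falls by one at rate `delta * Y_i`. For concave `f`, started from the
#' same initial state, the total severity stochastically dominates the
#' number of infected nodes in the exact SIS model; its mean solves the
#' linear ODE with matrix `beta * f'(0) * W - delta * I`. Used as a test
#' oracle for the stochastic-domination and exponential-extinction bounds.
#'
#' The process is unbounded; simulation stops (with a warning and
#' `capped = TRUE` on the result) if the total severity reaches
#' `severity_cap`, so that supercritical runs cannot loop forever.
#'
#' @inheritParams simulate_discrete
#' @param rf a *concave* `rate_function` (only `f'(0)` enters the rates).
#' @param severity_cap upper guard on the total severity.
#' @return an `sis_trajectory` (type `"severity"`) whose `infected_count`
#'   holds the total severity `sum_i Y_i`.
#' @export
simulate_severity_chain <- function(H, params, rf, T, seed = NULL,
                                    init = NULL, severity_cap = 1e6) {
  stopifnot(T > 0)
  if (!isTRUE(rf$concave))
    stop("severity-chain domination requires a concave rate function")
  run <- function() {
    W <- as.matrix(comembership(H))
    coef <- params$beta * rf$deriv0
    y <- if (is.null(init)) draw_initial_state(H$n, params$i0)
         else as.numeric(init)
    t <- 0
    times <- 0
    totals <- sum(y)
    capped <- FALSE
    while (sum(y) > 0) {
      up <- coef * as.vector(W %*% y)
      down <- params$delta * y
      total <- sum(up) + sum(down)
      t <- t + stats::rexp(1, rate = total)
      if (t > T) break
      i <- sample.int(H$n, 1L, prob = up + down)
      if (stats::runif(1) < up[i] / (up[i] + down[i])) y[i] <- y[i] + 1
      else y[i] <- y[i] - 1
      times <- c(times, t)
      totals <- c(totals, sum(y))
      if (sum(y) >= severity_cap) {
        warning("severity cap ", severity_cap, " reached at t = ",
                format(t, digits = 4), "; trajectory truncated")
        capped <- TRUE
        break
      }
    }
    ext <- if (length(totals) && totals[length(totals)] == 0)
      times[length(times)] else NA_real_
    make_trajectory(times, totals, H$n, "severity", ext, capped = capped)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Bounding birth-death chain (lower oracle)
#'
#' Simulates the birth-death chain on `{0, ..., m_cap}` with upward rate
#' `k * up_rate_coeff` (suppressed at the cap) and downward rate
#' `k * delta` from state `k`. In the non-extinction analysis the exact
#' infected-count process stochastically dominates this chain with
#' `up_rate_coeff = beta * (f(e_max - 1)/(e_max - 1)) * eta(H, m)`, so its
#' survival time lower-bounds the epidemic's extinction time.
#'
#' @param m_cap chain ceiling (the analysis uses `floor(n/2)`).
#' @param up_rate_coeff per-unit upward rate coefficient.
#' @param delta per-unit downward rate.
#' @param z0 initial state in `0..m_cap`.
#' @param T time horizon.
#' @param seed optional integer seed.
#' @return an `sis_trajectory` (type `"birth_death"`) whose
#'   `infected_count` holds the chain state.
#' @export
simulate_bounding_birth_death <- function(m_cap, up_rate_coeff, delta,
                                          z0, T, seed = NULL) {
  stopifnot(m_cap >= 1, z0 >= 0, z0 <= m_cap, T > 0, delta > 0,
            up_rate_coeff >= 0)
  run <- function() {
    k <- as.integer(z0)
    t <- 0
    times <- 0
    states <- k
    while (k > 0) {
      up <- if (k < m_cap) k * up_rate_coeff else 0
      down <- k * delta
      t <- t + stats::rexp(1, rate = up + down)
      if (t > T) break
      k <- if (stats::runif(1) < up / (up + down)) k + 1L else k - 1L
      times <- c(times, t)
      states <- c(states, k)
    }
    ext <- if (length(states) && states[length(states)] == 0L)
      times[length(times)] else NA_real_
    make_trajectory(times, states, m_cap, "birth_death", ext)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
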