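#' SIS model parameters
#'
#' @param beta infection strength (per unit time), `> 0` (0 allowed for
#'   degenerate pure-recovery runs).
#' @param delta recovery rate (per unit time), `> 0`.
#' @param i0 independent initial infection probability per node, in
#'   `[0, 1]`.
#' @return an object of class `sis_params`.
#' @export
sis_params <- function(beta, delta = 1, i0 = 0.5) {
  stopifnot(beta >= 0, delta > 0, i0 >= 0, i0 <= 1)
  structure(list(beta = beta, delta = delta, i0 = i0),
            class = "sis_params")
}

# Per-category incidence matrices paired with rate functions; computed once
# per simulation / integration.
sim_structure <- function(H, rf) {
  rfs <- as_rate_list(rf, H)
  K <- length(rfs)
  Is <- lapply(seq_len(K), function(k) {
    if (is_partitioned(H)) incidence(H, category = k) else incidence(H)
  })
  list(Is = Is, rfs = rfs, K = K, n = H$n)
}

rates_from_structure <- function(ss, x, beta) {
  r <- numeric(ss$n)
  for (k in seq_len(ss$K)) {
    counts <- as.vector(Matrix::crossprod(ss$Is[[k]], x))
    r <- r + as.vector(ss$Is[[k]] %*% ss$rfs[[k]]$fn(counts))
  }
  beta * r
}

#' Per-node infection rates of the exact model
#'
#' For the current binary state `X`, node `i`'s infection rate is
#' `beta * sum_h I[i, h] * f(sum_j X[j] * I[j, h])`, summed over categories
#' in the partitioned case. The value is returned for every node; it is
#' only meaningful (as a transition rate) for susceptible nodes, which the
#' caller masks. The inner count includes node `i` itself, but a
#' susceptible node has `X[i] = 0` so no self-infection arises.
#'
#' @param H a `hypergraph`.
#' @param state binary 0/1 vector of length `n`.
#' @param rf a `rate_function`, `rate_family`, or list of rate functions
#'   (one per category).
#' @param beta infection strength.
#' @return numeric vector of length `n`.
#' @export
infection_rates <- function(H, state, rf, beta) {
  if (length(state) != H$n)
    stop("state has length ", length(state), ", expected ", H$n)
  rates_from_structure(sim_structure(H, rf), as.numeric(state), beta)
}

#' One synchronous discrete-time update
#'
#' Advances the exact model by one step of length `dt`: a single uniform
#' draw `r_i` per node decides its flip. A susceptible node becomes
#' infected when `r_i < 1 - exp(-rate_i * dt)`; an infected node recovers
#' when `r_i < 1 - exp(-delta * dt)`. All transitions are computed from the
#' pre-step state (synchronous update). Uses the current RNG stream.
#'
#' @inheritParams infection_rates
#' @param params an `sis_params`.
#' @param dt time step, `> 0`.
#' @return the new 0/1 state vector.
#' @export
step_discrete <- function(H, state, rf, params, dt) {
  stopifnot(dt > 0)
  ss <- sim_structure(H, rf)
  step_discrete_ss(ss, as.numeric(state), params, dt)
}

step_discrete_ss <- function(ss, x, params, dt) {
  r <- stats::runif(ss$n)
  rates <- rates_from_structure(ss, x, params$beta)
  p_inf <- -expm1(-rates * dt)
  p_rec <- -expm1(-params$delta * dt)
  new_x <- x
  new_x[x == 0 & r < p_inf] <- 1
  new_x[x == 1 & r < p_rec] <- 0
  new_x
}

draw_initial_state <- function(n, i0) as.numeric(stats::runif(n) < i0)

make_trajectory <- function(times, counts, n, type, extinction_time,
                            states = NULL, capped = FALSE) {
  structure(list(times = times, infected_count = counts, n = n,
                 type = type, extinction_time = extinction_time,
                 states = states, capped = capped),
            class = "sis_trajectory")
}

#' @export
print.sis_trajectory <- function(x, ...) {
  cat("SIS trajectory (", x$type, "): n = ", x$n, ", ",
      length(x$times), " records, final count ",
      x$infected_count[length(x$infected_count)], sep = "")
  if (!is.na(x$extinction_time))
    cat(", extinct at t = ", format(x$extinction_time, digits = 5), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.sis_trajectory <- function(x, ...) {
  data.frame(time = x$times, infected_count = x$infected_count)
}

#' Discrete-time simulation of the exact model
#'
#' Draws the initial state i.i.d. Bernoulli(`i0`) (unless `init` is given)
#' and iterates [step_discrete()] with step `dt` up to time `T`. The
#' all-susceptible state is absorbing; by default the run stops at the
#' first step with zero infections and `extinction_time` records it.
#'
#' @inheritParams infection_rates
#' @param params an `sis_params`.
#' @param T time horizon, `> 0`.
#' @param dt time step, `> 0`.
#' @param seed optional integer seed (caller's RNG untouched when given).
#' @param init optional 0/1 initial state overriding the Bernoulli draw.
#' @param full_history keep the full `n x (steps+1)` state history.
#' @param stop_at_extinction stop early once no node is infected.
#' @return an `sis_trajectory`.
#' @export
simulate_discrete <- function(H, params, rf, T, dt, seed = NULL,
                              init = NULL, full_history = FALSE,
                              stop_at_extinction = TRUE) {
  stopifnot(T > 0, dt > 0)
  run <- function() {
    ss <- sim_structure(H, rf)
    x <- if (is.null(init)) draw_initial_state(H$n, params$i0)
         else as.numeric(init)
    n_steps <- ceiling(T / dt)
    times <- (0:n_steps) * dt
    counts <- integer(n_steps + 1L)
    counts[1L] <- sum(x)
    states <- if (full_history) matrix(NA_real_, H$n, n_steps + 1L)
    if (full_history) states[, 1L] <- x
    ext <- if (counts[1L] == 0L) 0 else NA_real_
    last <- n_steps + 1L
    for (s in seq_len(n_steps)) {
      if (!is.na(ext)) {
        if (stop_at_extinction) { last <- s; break }
        counts[s + 1L] <- 0L
        if (full_history) states[, s + 1L] <- 0
        next
      }
      x <- step_discrete_ss(ss, x, params, dt)
      counts[s + 1L] <- sum(x)
      if (full_history) states[, s + 1L] <- x
      if (counts[s + 1L] == 0L && is.na(ext)) ext <- times[s + 1L]
    }
    keep <- seq_len(min(last, n_steps + 1L))
    make_trajectory(times[keep], counts[keep], H$n, "discrete", ext,
                    states = if (full_history) states[, keep, drop = FALSE])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Event-driven (statistically exact) simulation
#'
#' Simulates the continuous-time Markov chain directly: the waiting time to
#' the next event is exponential with the current total rate (sum of
#' susceptible nodes' infection rates plus `delta` times the number of
#' infected nodes) and the event is chosen proportionally to the individual
#' rates. The resulting trajectory has exactly the law of the model, with
#' no time-discretization error.
#'
#' @inheritParams simulate_discrete
#' @return an `sis_trajectory` with one record per event.
#' @export
simulate_exact <- function(H, params, rf, T, seed = NULL, init = NULL) {
  stopifnot(T > 0)
  run <- function() {
    ss <- sim_structure(H, rf)
    x <- if (is.null(init)) draw_initial_state(H$n, params$i0)
         else as.numeric(init)
    times <- 0
    counts <- sum(x)
    t <- 0
    ext <- if (counts == 0L) 0 else NA_real_
    while (is.na(ext)) {
      inf_rates <- rates_from_structure(ss, x, params$beta)
      inf_rates[x == 1] <- 0
      rec_rates <- params$delta * x
      total <- sum(inf_rates) + sum(rec_rates)
      if (total <= 0) break  # no infected left and no pressure
      t <- t + stats::rexp(1, rate = total)
      if (t > T) break
      i <- sample.int(ss$n, 1L, prob = inf_rates + rec_rates)
      x[i] <- 1 - x[i]
      times <- c(times, t)
      counts <- c(counts, sum(x))
      if (sum(x) == 0) ext <- t
    }
    make_trajectory(times, counts, H$n, "exact", ext)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Right-continuous step-function evaluation of an event trajectory on a
# time grid.
eval_on_grid <- function(traj, grid) {
  idx <- findInterval(grid, traj$times)
  idx[idx < 1L] <- 1L
  counts <- traj$infected_count[idx]
  # after extinction (or after the last record of an extinct run) stay 0
  if (!is.na(traj$extinction_time))
    counts[grid >= traj$extinction_time] <- 0L
  counts
}

#' Ensemble of stochastic runs on a fixed hypergraph
#'
#' Runs `n_runs` independent trajectories on the *same* hypergraph, with
#' per-run seeds derived deterministically as `base_seed + run`. By default
#' the initial state is drawn once (from `base_seed`) and shared across
#' runs, matching the protocol of averaging repeated runs with identical
#' connectivity and initial condition; `share_init = FALSE` redraws it per
#' run.
#'
#' @inheritParams simulate_discrete
#' @param n_runs number of runs, `>= 1`.
#' @param base_seed integer seed from which per-run seeds are derived.
#' @param dt time step for the discrete scheme, or `NULL` to use the
#'   event-driven exact simulator.
#' @param record_dt spacing of the common recording grid (defaults to `dt`,
#'   or `T/200` for exact runs).
#' @param share_init share one initial state across runs.
#' @param init optional 0/1 state shared by every run, overriding the
#'   Bernoulli draw (implies `share_init`).
#' @return an object of class `sis_ensemble` with fields `times`,
#'   `mean_fraction` (mean infected fraction across runs),
#'   `survival_prob` (fraction of runs with at least one infected node),
#'   `counts` (runs-by-time matrix), `n_runs`, `seeds`, `n`.
#' @export
run_ensemble <- function(H, params, rf, T, n_runs, base_seed,
                         dt = NULL, record_dt = NULL, share_init = TRUE,
                         init = NULL) {
  stopifnot(n_runs >= 1)
  if (is.null(record_dt)) record_dt <- if (is.null(dt)) T / 200 else dt
  grid <- seq(0, T, by = record_dt)
  if (is.null(init) && share_init)
    init <- with_seed(base_seed, draw_initial_state(H$n, params$i0))
  seeds <- base_seed + seq_len(n_runs)
  counts <- matrix(0L, n_runs, length(grid))
  for (r in seq_len(n_runs)) {
    traj <- if (is.null(dt))
      simulate_exact(H, params, rf, T, seed = seeds[r], init = init)
    else
      simulate_discrete(H, params, rf, T, dt, seed = seeds[r], init = init)
    counts[r, ] <- eval_on_grid(traj, grid)
  }
  structure(list(times = grid,
                 mean_fraction = colMeans(counts) / H$n,
                 survival_prob = colMeans(counts > 0),
                 counts = counts, n_runs = n_runs, seeds = seeds,
                 n = H$n, share_init = share_init),
            class = "sis_ensemble")
}

#' @export
print.sis_ensemble <- function(x, ...) {
  cat("SIS ensemble: ", x$n_runs, " runs, n = ", x$n,
      ", final mean fraction ",
      format(x$mean_fraction[length(x$mean_fraction)], digits = 4),
      ", final survival ",
      format(x$survival_prob[length(x$survival_prob)], digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sis_ensemble <- function(x, ...) {
  data.frame(time = x$times, mean_fraction = x$mean_fraction,
             survival_probability = x$survival_prob)
}
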