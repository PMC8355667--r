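#' Mean-field vector field
#'
#' Evaluates the right-hand side of the mean-field ODE for the node
#' infection probabilities `p`:
#' `g_i(p) = beta * sum_h I[i,h] * f(sum_j p_j I[j,h]) * (1 - p_i)
#'           - delta * p_i`,
#' with the category-summed form on a partitioned hypergraph. The inner
#' probability mass includes the node's own `p_i` (self-term), exactly as
#' in the model's derivation; no correction is applied — the discrepancy
#' with the exact process is part of the mean-field approximation.
#'
#' @param p probability vector of length `n`, or an `n x B` matrix whose
#'   columns are independent states.
#' @param H a `hypergraph`.
#' @param params an `sis_params`.
#' @param rf a `rate_function`, `rate_family` or list (one per category).
#' @return vector (or matrix) of the same shape as `p`.
#' @export
meanfield_rhs <- function(p, H, params, rf) {
  ss <- sim_structure(H, rf)
  meanfield_rhs_ss(p, ss, params)
}

meanfield_rhs_ss <- function(p, ss, params) {
  if (NROW(p) != ss$n)
    stop("state has ", NROW(p), " rows, expected ", ss$n)
  pressure <- 0
  for (k in seq_len(ss$K)) {
    counts <- Matrix::crossprod(ss$Is[[k]], p)
    pressure <- pressure +
      as.matrix(ss$Is[[k]] %*% ss$rfs[[k]]$fn(as.matrix(counts)))
  }
  out <- params$beta * pressure * (1 - p) - params$delta * p
  if (is.matrix(p)) out else as.vector(out)
}

make_mf_trajectory <- function(times, norms, mean_fraction, final,
                               clamp_events, states = NULL,
                               max_excursion = 0, integrator = "euler") {
  structure(list(times = times, norm = norms,
                 mean_fraction = mean_fraction, final = final,
                 clamp_events = clamp_events, states = states,
                 max_excursion = max_excursion, integrator = integrator),
            class = "meanfield_trajectory")
}

#' @export
print.meanfield_trajectory <- function(x, ...) {
  nrm <- if (is.matrix(x$norm)) x$norm[nrow(x$norm), 1] else
    x$norm[length(x$norm)]
  cat("mean-field trajectory (", x$integrator, "): ",
      length(x$times), " records, final ||P|| = ",
      format(nrm, digits = 5), ", clamp events: ", x$clamp_events,
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.meanfield_trajectory <- function(x, ...) {
  if (is.matrix(x$norm))
    stop("as.data.frame is only available for single-start trajectories")
  data.frame(time = x$times, norm = x$norm,
             mean_fraction = x$mean_fraction)
}

#' Explicit Euler integration of the mean-field ODE
#'
#' Advances `p <- p + dt * g(p)` and projects each step onto `[0,1]^n`;
#' large steps can overshoot the probability box and every projected entry
#' is counted in `clamp_events` rather than silently accepted. `p0` may be
#' a matrix to integrate several initial conditions simultaneously.
#'
#' @inheritParams meanfield_rhs
#' @param p0 initial probabilities (vector, or `n x B` matrix).
#' @param dt step size, `> 0`.
#' @param T time horizon.
#' @param record_states keep the full state history (vector `p0` only).
#' @return a `meanfield_trajectory` with the Euclidean norm and mean
#'   infected fraction per recorded time (columns per start when `p0` is a
#'   matrix), the final state(s) and the clamp count.
#' @export
integrate_euler <- function(p0, H, params, rf, dt, T,
                            record_states = FALSE) {
  stopifnot(dt > 0, T > 0)
  ss <- sim_structure(H, rf)
  p <- if (is.matrix(p0)) p0 else as.numeric(p0)
  n_steps <- ceiling(T / dt)
  times <- (0:n_steps) * dt
  B <- if (is.matrix(p)) ncol(p) else 1L
  norms <- matrix(0, n_steps + 1L, B)
  fracs <- matrix(0, n_steps + 1L, B)
  states <- if (record_states && !is.matrix(p0))
    matrix(0, ss$n, n_steps + 1L)
  clamp <- 0L
  col_norm <- function(q) if (is.matrix(q)) sqrt(colSums(q^2)) else
    sqrt(sum(q^2))
  col_mean <- function(q) if (is.matrix(q)) colMeans(q) else mean(q)
  norms[1L, ] <- col_norm(p)
  fracs[1L, ] <- col_mean(p)
  if (!is.null(states)) states[, 1L] <- p
  for (s in seq_len(n_steps)) {
    p <- p + dt * meanfield_rhs_ss(p, ss, params)
    out <- sum(p < 0 | p > 1)
    if (out > 0) {
      clamp <- clamp + out
      p[p < 0] <- 0
      p[p > 1] <- 1
    }
    norms[s + 1L, ] <- col_norm(p)
    fracs[s + 1L, ] <- col_mean(p)
    if (!is.null(states)) states[, s + 1L] <- p
  }
  if (!is.matrix(p0)) {
    norms <- as.vector(norms)
    fracs <- as.vector(fracs)
  }
  make_mf_trajectory(times, norms, fracs, p, clamp, states,
                     integrator = "euler")
}

# Cash-Karp embedded Runge-Kutta 4(5) tableau.
ck_a <- list(c(1/5),
             c(3/40, 9/40),
             c(3/10, -9/10, 6/5),
             c(-11/54, 5/2, -70/27, 35/27),
             c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
ck_c5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
ck_c4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)

#' Adaptive (embedded RK45) integration of the mean-field ODE
#'
#' Error-controlled Cash-Karp Runge-Kutta 4(5) integration of the same
#' vector field as [integrate_euler()]; serves as the reference integrator
#' for quantifying Euler's discretization error. States are projected onto
#' `[0,1]^n` only after each accepted step; the worst pre-projection
#' excursion outside the box is reported in `max_excursion`.
#'
#' @inheritParams integrate_euler
#' @param p0 initial probability vector.
#' @param tol mixed absolute/relative local error tolerance, `> 0`.
#' @param max_steps guard on the number of accepted steps.
#' @return a `meanfield_trajectory` (integrator `"rk45"`).
#' @export
integrate_adaptive <- function(p0, H, params, rf, T, tol = 1e-8,
                               max_steps = 1e6) {
  stopifnot(tol > 0, T > 0)
  ss <- sim_structure(H, rf)
  p <- as.numeric(p0)
  t <- 0
  h <- min(T / 100, 0.1)
  times <- 0
  norms <- sqrt(sum(p^2))
  fracs <- mean(p)
  clamp <- 0L
  excur <- 0
  steps <- 0L
  f <- function(q) meanfield_rhs_ss(q, ss, params)
  while (t < T) {
    if (steps >= max_steps)
      stop("adaptive integrator exceeded ", max_steps, " steps")
    h <- min(h, T - t)
    k <- vector("list", 6)
    k[[1]] <- f(p)
    for (j in 2:6) {
      incr <- Reduce(`+`, Map(`*`, ck_a[[j - 1]], k[seq_len(j - 1)]))
      k[[j]] <- f(p + h * incr)
    }
    p5 <- p + h * Reduce(`+`, Map(`*`, ck_c5, k))
    p4 <- p + h * Reduce(`+`, Map(`*`, ck_c4, k))
    err <- max(abs(p5 - p4) / (tol + tol * abs(p5)))
    if (err <= 1) {
      t <- t + h
      excur <- max(excur, max(0, max(p5) - 1), max(0, -min(p5)))
      out <- sum(p5 < 0 | p5 > 1)
      if (out > 0) {
        clamp <- clamp + out
        p5[p5 < 0] <- 0
        p5[p5 > 1] <- 1
      }
      p <- p5
      times <- c(times, t)
      norms <- c(norms, sqrt(sum(p^2)))
      fracs <- c(fracs, mean(p))
      steps <- steps + 1L
    }
    h <- h * max(0.2, min(5, 0.9 * err^(-0.2)))
    if (h < 1e-14 * max(T, 1))
      stop("adaptive integrator step size underflow at t = ", t)
  }
  make_mf_trajectory(times, norms, fracs, p, clamp,
                     max_excursion = excur, integrator = "rk45")
}

#' Analytic Jacobian of the mean-field vector field
#'
#' Returns the `n x n` matrix with entries
#' `J[i, j] = beta * sum_h I[i,h] I[j,h] f'(sum_l p_l I[l,h]) * (1 - p_i)`
#' for `j != i`, and additionally
#' `- beta * sum_h I[i,h] f(sum_l p_l I[l,h]) - delta` on the diagonal
#' (category-summed in the partitioned case). At `p = 0` this reduces to
#' `beta * f'(0) * W - delta * I`. Where `f` has a kink (e.g.
#' `capped_linear` at `c`), the one-sided derivative from below is used and
#' the result carries attribute `nondifferentiable = TRUE`.
#'
#' @inheritParams meanfield_rhs
#' @param p probability vector of length `n`.
#' @return a dense `n x n` matrix.
#' @export
jacobian <- function(p, H, params, rf) {
  ss <- sim_structure(H, rf)
  p <- as.numeric(p)
  if (length(p) != ss$n) stop("state has wrong length")
  J <- matrix(0, ss$n, ss$n)
  diag_extra <- numeric(ss$n)
  kink <- FALSE
  for (k in seq_len(ss$K)) {
    rfk <- ss$rfs[[k]]
    counts <- as.vector(Matrix::crossprod(ss$Is[[k]], p))
    kp <- switch(rfk$name,
                 capped_linear = rfk$params$c,
                 hinge = rfk$params$c,
                 step = rfk$params$c1,
                 NULL)
    if (!is.null(kp) && any(abs(counts - kp) < 1e-9)) kink <- TRUE
    Dk <- Matrix::Diagonal(x = rfk$deriv(counts))
    J <- J + as.matrix(ss$Is[[k]] %*% Dk %*% Matrix::t(ss$Is[[k]]))
    diag_extra <- diag_extra +
      as.vector(ss$Is[[k]] %*% rfk$fn(counts))
  }
  J <- params$beta * (1 - p) * J  # row scaling by (1 - p_i)
  diag(J) <- diag(J) - params$beta * diag_extra - params$delta
  attr(J, "nondifferentiable") <- kink
  J
}

#' Detect eventual norm decay of a mean-field trajectory
#'
#' Reports whether the Euclidean norm of the state is genuinely decaying
#' towards zero: the trailing half of the records must be monotone
#' non-increasing *and* keep shrinking (a monotone approach to a non-zero
#' endemic plateau does not count as decay). Over the positive part of the
#' tail, `log ||P(t)|| ~ a + rate * t` is fitted to estimate the
#' exponential decay rate.
#'
#' @param traj a single-start `meanfield_trajectory` (at least 3 records).
#' @return a list `decay` (logical), `rate` (slope of the log-norm fit, or
#'   `NA` for an identically-zero trajectory).
#' @export
equilibrium_norm_decay <- function(traj) {
  nrm <- traj$norm
  if (is.matrix(nrm)) stop("single-start trajectory required")
  if (length(nrm) < 3) stop("trajectory too short")
  if (all(nrm == 0)) return(list(decay = TRUE, rate = NA_real_))
  tail_ix <- seq(floor(length(nrm) / 2) + 1L, length(nrm))
  tail_n <- nrm[tail_ix]
  monotone <- all(diff(tail_n) <= 1e-12)
  shrinking <- tail_n[length(tail_n)] < 1e-10 ||
    tail_n[length(tail_n)] <= 0.99 * tail_n[1]
  pos <- tail_n > 0
  rate <- if (sum(pos) >= 2) {
    stats::coef(stats::lm(log(tail_n[pos]) ~ traj$times[tail_ix][pos]))[[2]]
  } else -Inf
  list(decay = monotone && shrinking, rate = rate)
}
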