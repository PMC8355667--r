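#' Symmetric part of a square matrix
#'
#' @param M a square matrix.
#' @return `(M + t(M)) / 2`.
#' @export
symmetric_part <- function(M) {
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  (M + Matrix::t(M)) / 2
}

# Largest eigenvalue of a symmetric positive-semidefinite matrix: dense
# solver below n = 2000, power iteration (rel. tol 1e-9) above.
lambda_max_sym <- function(M, tol = 1e-9) {
  n <- nrow(M)
  if (n == 0L) return(0)
  if (n <= 2000L)
    return(max(eigen(as.matrix(M), symmetric = TRUE,
                     only.values = TRUE)$values, 0))
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (it in seq_len(10000L)) {
    w <- as.vector(M %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    lam_new <- as.vector(crossprod(v, as.vector(M %*% v)))
    if (abs(lam_new - lam) <= tol * max(abs(lam_new), 1)) return(lam_new)
    lam <- lam_new
  }
  warning("power iteration did not reach tolerance ", tol)
  lam
}

# Per-category largest hyperedge size (falls back to the global e_max for
# an empty category).
category_emax <- function(H) {
  sizes <- vapply(H$edges, length, integer(1))
  global <- if (length(sizes)) max(sizes) else 2L
  K <- if (is_partitioned(H)) H$K else 1L
  vapply(seq_len(K), function(k) {
    s <- if (is_partitioned(H)) sizes[H$category == k] else sizes
    if (length(s)) max(s) else global
  }, integer(1))
}

category_slopes <- function(H, rfs, mode) {
  emax <- category_emax(H)
  vapply(seq_along(rfs), function(k) {
    if (mode == "derivative_at_zero") rfs[[k]]$deriv0
    else concave_majorant_slope(rfs[[k]], max(emax[k], 2L))
  }, numeric(1))
}

#' Slope-weighted effective matrix
#'
#' Builds `sum_k s_k * W^(k)` where `s_k` is either the derivative at zero
#' of the category's rate function (`mode = "derivative_at_zero"`, the
#' quantity entering the local/global stability conditions for concave
#' responses) or its concave-majorant slope on the attainable range
#' (`mode = "majorant"`, the constant entering the collective-contagion
#' extinction bounds). An unpartitioned hypergraph is treated as one
#' category.
#'
#' @param H a `hypergraph`.
#' @param rf `rate_function`, `rate_family` or list (one per category).
#' @param mode `"derivative_at_zero"` or `"majorant"`.
#' @return a symmetric `n x n` sparse `Matrix`.
#' @export
effective_matrix <- function(H, rf,
                             mode = c("derivative_at_zero", "majorant")) {
  mode <- match.arg(mode)
  rfs <- as_rate_list(rf, H)
  s <- category_slopes(H, rfs, mode)
  Ws <- partition_comembership(H)
  Reduce(`+`, Map(`*`, s, Ws))
}

#' Spectral extinction threshold
#'
#' Computes the largest eigenvalue of the slope-weighted co-membership
#' matrix and the critical infection strength
#' `beta_c = delta / (c_f * lambda_max)`. Below `beta_c` the zero-infection
#' state of the mean-field ODE is asymptotically stable — locally for any
#' response, globally when every response is concave — and the exact
#' stochastic model goes extinct exponentially fast (via the majorant slope
#' for non-concave responses).
#'
#' For a single (unpartitioned) rate function the report keeps the
#' three-factor decomposition explicit: `lambda_max` is the eigenvalue of
#' the bare co-membership matrix `W` and `c_f` the slope constant. With
#' heterogeneous per-category slopes the slopes are folded into the matrix
#' and `c_f = 1`.
#'
#' @inheritParams effective_matrix
#' @param params an `sis_params` (`beta` is checked against the threshold).
#' @return an object of class `spectral_report` with fields `lambda_max`,
#'   `c_f`, `beta_c`, `condition_met`, `theorem_basis`,
#'   `concavity_certified`, `mode`, `beta`, `delta`, `note`.
#' @examples
#' H <- hypergraph(list(c(1, 2, 3), c(1, 2)))
#' spectral_threshold(H, rate_function("identity"), sis_params(0.1))
#' @export
spectral_threshold <- function(H, rf, params,
                               mode = c("derivative_at_zero",
                                        "majorant")) {
  mode <- match.arg(mode)
  rfs <- as_rate_list(rf, H)
  emax <- category_emax(H)
  certified <- all(vapply(seq_along(rfs), function(k)
    check_concavity(rfs[[k]], max(emax[k], 2L)), logical(1)))
  note <- NULL
  if (mode == "derivative_at_zero" && !certified) {
    vac <- vapply(rfs, function(f) f$deriv0 == 0, logical(1))
    note <- paste("concavity not certified: derivative-at-zero threshold",
                  "is local-only; use mode = 'majorant' for global and",
                  "stochastic statements")
    if (any(vac))
      note <- paste(note, "(some responses have f'(0) = 0, giving a",
                    "vacuous local condition)")
  }
  fallback <- mode == "majorant" &&
    any(vapply(rfs, function(f)
      !f$concave && !(f$name %in% c("step", "hinge")), logical(1)))
  if (fallback)
    note <- paste(c(note, "majorant slope for a non-analysed family uses",
                    "the generic max f(x)/x fallback"), collapse = " ")
  single <- length(rfs) == 1L
  if (single) {
    lam <- lambda_max_sym(comembership(H))
    c_f <- category_slopes(H, rfs, mode)
  } else {
    lam <- lambda_max_sym(effective_matrix(H, rf, mode))
    c_f <- 1
  }
  beta_c <- if (c_f * lam > 0) params$delta / (c_f * lam) else Inf
  basis <- if (mode == "majorant")
    "stochastic-exponential (majorant slope)"
  else if (certified) "global (concave) + stochastic-exponential"
  else "local-only (linearization)"
  structure(list(lambda_max = lam, c_f = c_f, beta_c = beta_c,
                 condition_met = params$beta * c_f * lam < params$delta,
                 theorem_basis = basis, concavity_certified = certified,
                 mode = mode, beta = params$beta, delta = params$delta,
                 note = note),
            class = "spectral_report")
}

#' @export
print.spectral_report <- function(x, ...) {
  cat("Spectral threshold report\n",
      "  decomposition: beta = ", format(x$beta, digits = 6),
      " | lambda = ", format(x$lambda_max, digits = 6),
      " | c_f = ", format(x$c_f, digits = 6), "\n",
      "  beta_c = ", format(x$beta_c, digits = 6),
      "   condition beta * c_f * lambda / delta < 1: ",
      x$condition_met, "\n",
      "  basis: ", x$theorem_basis,
      " (concavity certified: ", x$concavity_certified, ")\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Extinction-probability and expected-extinction-time bounds
#'
#' From a spectral report with growth exponent
#' `rho = beta * c_f * lambda_max - delta`, returns the survival bound
#' `P(any node infected at t) <= min(1, n * i0 * exp(rho * t))` and, when
#' `rho < 0`, the expected extinction time bound
#' `E[tau] <= (log(n) + 1) / (-rho)`; both require either certified
#' concavity (with the derivative-at-zero slope) or the majorant slope.
#'
#' @param report a `spectral_report`.
#' @param n node count.
#' @param i0 initial infection probability per node.
#' @param params an `sis_params` (supplies `beta` and `delta`; these must
#'   match the report).
#' @return an object of class `extinction_bounds`: `prob_bound` (a
#'   function of `t`), `expected_tau_bound`, `growth_rate`.
#' @export
extinction_bounds <- function(report, n, i0, params) {
  if (report$mode == "derivative_at_zero" && !report$concavity_certified)
    stop("stochastic extinction bounds require concave responses when ",
         "using the derivative-at-zero slope; recompute the report with ",
         "mode = 'majorant'")
  if (abs(report$beta - params$beta) > 1e-12 ||
      abs(report$delta - params$delta) > 1e-12)
    stop("params do not match those used in the spectral report")
  rho <- params$beta * report$c_f * report$lambda_max - params$delta
  structure(list(
    prob_bound = function(t) pmin(1, n * i0 * exp(rho * t)),
    expected_tau_bound = if (rho < 0) (log(n) + 1) / (-rho) else Inf,
    growth_rate = rho, n = n, i0 = i0),
    class = "extinction_bounds")
}

#' @export
print.extinction_bounds <- function(x, ...) {
  cat("Extinction bounds: growth rate ", format(x$growth_rate, digits = 6),
      ", E[tau] <= ", format(x$expected_tau_bound, digits = 6), "\n",
      sep = "")
  invisible(x)
}

# Fast E(S, f) given hyperedges and a logical membership vector for S.
pressure_value <- function(H, rfs, in_S) {
  val <- 0
  for (h in seq_along(H$edges)) {
    e <- H$edges[[h]]
    k <- if (is_partitioned(H)) H$category[h] else 1L
    n_S <- sum(in_S[e])
    if (n_S == 0L) next
    val <- val + n_S * rfs[[k]]$fn(length(e) - n_S)
  }
  val
}

#' Boundary infection pressure on a node subset
#'
#' Evaluates `E(S, f) = sum_{i in S} sum_h I[i,h] * f(|h \ S|)`, the total
#' rate (up to the factor `beta`) at which nodes inside `S` are infected
#' by nodes outside it. When `S` is the current susceptible set this is
#' exactly the upward transition rate of the infected-count process.
#'
#' @param H a `hypergraph`.
#' @param S non-empty vector of node indices.
#' @param rf `rate_function`, `rate_family` or list (one per category).
#' @return a list of class `subset_pressure` with fields `subset`, `value`.
#' @export
subset_pressure <- function(H, S, rf) {
  S <- as.integer(S)
  if (length(S) < 1L) stop("S must be non-empty")
  if (any(S < 1L) || any(S > H$n)) stop("node index outside 1..", H$n)
  rfs <- as_rate_list(rf, H)
  in_S <- rep(FALSE, H$n)
  in_S[S] <- TRUE
  structure(list(subset = sort(unique(S)),
                 value = pressure_value(H, rfs, in_S)),
            class = "subset_pressure")
}

#' @export
print.subset_pressure <- function(x, ...) {
  cat("E(S, f) = ", format(x$value, digits = 6), " for |S| = ",
      length(x$subset), "\n", sep = "")
  invisible(x)
}

#' Minimum average boundary pressure (Cheeger-like constant)
#'
#' Computes `eta(H, m, f) = min over non-empty S with |S| <= m of
#' E(S, f) / |S|`. With `f` the identity and `m = floor(n/2)` this is the
#' Cheeger (isoperimetric) constant of the weighted graph induced by the
#' off-diagonal co-membership. `method = "brute"` enumerates every subset
#' up to size `m_limit` (refusing when the subset count exceeds `budget`);
#' `method = "greedy"` runs an add/drop/swap local search and returns an
#' *upper bound* on `eta`, flagged as heuristic.
#'
#' @param H a `hypergraph`.
#' @param m_limit largest subset size, between 1 and `floor(n/2)`.
#' @param rf rate function(s); defaults to the identity.
#' @param method `"auto"` (brute when affordable), `"brute"` or
#'   `"greedy"`.
#' @param budget maximum number of subsets brute enumeration may visit.
#' @return a list of class `eta_report`: `value`, `minimizer` (node set),
#'   `method`, `is_upper_bound` (`TRUE` for greedy).
#' @export
eta <- function(H, m_limit, rf = rate_function("identity"),
                method = c("auto", "brute", "greedy"), budget = 5e5) {
  method <- match.arg(method)
  m_limit <- as.integer(m_limit)
  if (m_limit < 1L || m_limit > floor(H$n / 2))
    stop("m_limit must be between 1 and floor(n/2) = ", floor(H$n / 2))
  rfs <- as_rate_list(rf, H)
  n_subsets <- sum(choose(H$n, seq_len(m_limit)))
  if (method == "auto")
    method <- if (n_subsets <= budget) "brute" else "greedy"
  if (method == "brute" && n_subsets > budget)
    stop("brute enumeration of ", format(n_subsets, digits = 3),
         " subsets exceeds the budget ", budget,
         "; use method = 'greedy'")
  score <- function(S) {
    in_S <- rep(FALSE, H$n)
    in_S[S] <- TRUE
    pressure_value(H, rfs, in_S) / length(S)
  }
  if (method == "brute") {
    best <- Inf
    best_S <- integer(0)
    for (s in seq_len(m_limit)) {
      combs <- utils::combn(H$n, s)
      for (j in seq_len(ncol(combs))) {
        v <- score(combs[, j])
        if (v < best) { best <- v; best_S <- combs[, j] }
      }
    }
  } else {
    singles <- vapply(seq_len(H$n), function(i) score(i), numeric(1))
    best_S <- which.min(singles)
    best <- singles[best_S]
    repeat {
      improved <- FALSE
      outside <- setdiff(seq_len(H$n), best_S)
      if (length(best_S) < m_limit) {
        for (i in outside) {
          v <- score(c(best_S, i))
          if (v < best - 1e-12) {
            best <- v; best_S <- sort(c(best_S, i)); improved <- TRUE
            break
          }
        }
      }
      if (!improved && length(best_S) > 1L) {
        for (i in best_S) {
          v <- score(setdiff(best_S, i))
          if (v < best - 1e-12) {
            best <- v; best_S <- setdiff(best_S, i); improved <- TRUE
            break
          }
        }
      }
      if (!improved) {
        for (i in best_S) {
          hit <- FALSE
          for (j in setdiff(seq_len(H$n), best_S)) {
            v <- score(sort(c(setdiff(best_S, i), j)))
            if (v < best - 1e-12) {
              best <- v; best_S <- sort(c(setdiff(best_S, i), j))
              improved <- TRUE; hit <- TRUE
              break
            }
          }
          if (hit) break
        }
      }
      if (!improved) break
    }
  }
  structure(list(value = best, minimizer = best_S, method = method,
                 is_upper_bound = method == "greedy"),
            class = "eta_report")
}

#' @export
print.eta_report <- function(x, ...) {
  cat("eta = ", format(x$value, digits = 6), " (", x$method,
      if (x$is_upper_bound) ", upper bound" else ", exact",
      "), minimizer size ", length(x$minimizer), "\n", sep = "")
  invisible(x)
}

#' Non-extinction certificate
#'
#' Checks the persistence condition
#' `lambda_c(L) > 2 * ((e_max - 1)/f(e_max - 1)) * (delta / beta)` (where
#' `lambda_c(L)` is the smallest non-zero Laplacian eigenvalue) and, when
#' it holds, computes `r = (e_max - 1) * delta /
#' (f(e_max - 1) * beta * eta(H, m))` with `m = floor(n/2)`. For `r < 1`
#' the infected count dominates a supercritical birth-death chain and the
#' extinction time exceeds `floor(r^(-m+1)) / (2m)` with probability at
#' least `1 - r*e` up to an unquantified `O(r^m)` correction, which is
#' surfaced as an explicit caveat and never folded into a pass/fail
#' decision.
#'
#' The chain of inequalities behind the certificate uses the identity-`f`
#' isoperimetric constant together with the concavity prefactor
#' `f(e_max - 1)/(e_max - 1)`; `f` must be concave and non-decreasing.
#' When `eta` is computed greedily it is an upper bound, so the reported
#' `r` is a *lower* bound and the certificate may overstate persistence;
#' the report labels this direction explicitly.
#'
#' @param H a `hypergraph` with `n >= 2`.
#' @param rf a concave, non-decreasing `rate_function`.
#' @param params an `sis_params`.
#' @param eta_method passed to [eta()].
#' @param m_limit subset-size limit for `eta` (default `floor(n/2)`).
#' @return an object of class `nonextinction_report`.
#' @export
nonextinction_certificate <- function(H, rf, params,
                                      eta_method = c("auto", "brute",
                                                     "greedy"),
                                      m_limit = NULL) {
  eta_method <- match.arg(eta_method)
  if (H$n < 2L) stop("need at least 2 nodes")
  if (!isTRUE(rf$concave) || !isTRUE(rf$nondecreasing))
    stop("the non-extinction certificate requires a concave, ",
         "non-decreasing rate function")
  e_max <- max_hyperedge_size(H)
  pref <- (e_max - 1) / rf$fn(e_max - 1)
  lap <- laplacian(H)
  cond <- !is.na(lap$lambda_c) &&
    lap$lambda_c > 2 * pref * params$delta / params$beta
  m <- if (is.null(m_limit)) floor(H$n / 2) else as.integer(m_limit)
  et <- eta(H, m, rate_function("identity"), method = eta_method)
  r <- if (et$value > 0)
    pref * params$delta / (params$beta * et$value) else Inf
  horizon <- if (r < 1) floor(r^(-m + 1)) / (2 * m) else NA_real_
  lb <- if (r < 1) 1 - r * exp(1) else NA_real_
  structure(list(
    e_max = e_max, eta_value = et$value, eta_method = et$method,
    eta_is_upper_bound = et$is_upper_bound, m = m,
    lambda_c = lap$lambda_c, condition_met = cond && r < 1, r = r,
    time_horizon = horizon, prob_lower_bound = lb,
    caveat = paste("the survival probability bound 1 - r*e omits an",
                   "unquantified O(r^m) correction; with a greedy eta",
                   "(an upper bound on eta) the reported r is a lower",
                   "bound, so persistence may be overstated")),
    class = "nonextinction_report")
}

#' @export
print.nonextinction_report <- function(x, ...) {
  cat("Non-extinction certificate\n",
      "  e_max = ", x$e_max, ", lambda_c = ",
      format(x$lambda_c, digits = 6),
      ", eta(H, ", x$m, ") = ", format(x$eta_value, digits = 6),
      " (", x$eta_method, ")\n",
      "  r = ", format(x$r, digits = 6),
      ", condition met: ", x$condition_met, "\n", sep = "")
  if (x$condition_met)
    cat("  P(tau > ", format(x$time_horizon, digits = 6), ") >= ",
        format(x$prob_lower_bound, digits = 6), " (nominal)\n", sep = "")
  cat("  caveat: ", x$caveat, "\n", sep = "")
  invisible(x)
}
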