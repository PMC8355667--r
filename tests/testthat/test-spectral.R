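test_that("effective matrix folds per-category slopes into W", {
  idf <- rate_function("identity")
  expect_equal(as.matrix(effective_matrix(H3, idf, "derivative_at_zero")),
               as.matrix(comembership(H3)), ignore_attr = TRUE)
  expect_equal(as.matrix(effective_matrix(H3, idf, "majorant")),
               as.matrix(comembership(H3)), ignore_attr = TRUE)
  # partitioned: f1 identity, f2 = 2 log(1+x) gives W1 + 2 W2
  fam <- rate_family("identity", "log1p:a=2")
  Ws <- lapply(partition_comembership(PH3), as.matrix)
  expect_equal(as.matrix(effective_matrix(PH3, fam)),
               Ws[[1]] + 2 * Ws[[2]], ignore_attr = TRUE)
  # step majorant scales W by c2/c1
  stp <- rate_function("step", c1 = 2, c2 = 1)
  expect_equal(as.matrix(effective_matrix(H3, stp, "majorant")),
               0.5 * as.matrix(comembership(H3)), ignore_attr = TRUE)
})

test_that("spectral threshold reproduces hand-computed eigenvalues", {
  idf <- rate_function("identity")
  rep3 <- spectral_threshold(H3, idf, sis_params(0.1))
  expect_equal(rep3$lambda_max, lambda_H3, tolerance = 1e-12)
  expect_equal(rep3$beta_c, 1 / lambda_H3, tolerance = 1e-12)
  expect_true(rep3$condition_met)
  expect_true(rep3$concavity_certified)
  # single edge: lambda = 2, beta_c = 1/2
  r1 <- spectral_threshold(hypergraph(list(c(1, 2))), idf,
                           sis_params(0.6))
  expect_equal(r1$lambda_max, 2)
  expect_equal(r1$beta_c, 0.5)
  expect_false(r1$condition_met)
  # no hyperedges: vacuous threshold, every beta is safe
  r0 <- spectral_threshold(hypergraph(list(), n = 4), idf,
                           sis_params(10))
  expect_equal(r0$beta_c, Inf)
  expect_true(r0$condition_met)
  # invariant: beta_c * c_f * lambda = delta; scale equivariance in delta
  for (s in c(0.5, 2, 7)) {
    rs <- spectral_threshold(H3, idf, sis_params(0.1, delta = s))
    expect_equal(rs$beta_c * rs$c_f * rs$lambda_max, s)
    expect_equal(rs$beta_c, s * rep3$beta_c)
  }
  # non-concave response with f'(0) = 0: local-only basis with a warning
  # note; majorant mode gives the collective-contagion threshold
  stp <- rate_function("step", c1 = 2, c2 = 1)
  rl <- spectral_threshold(H3, stp, sis_params(0.1))
  expect_match(rl$theorem_basis, "local")
  expect_false(is.null(rl$note))
  rm_ <- spectral_threshold(H3, stp, sis_params(0.1), mode = "majorant")
  expect_equal(rm_$c_f, 0.5)
  expect_equal(rm_$beta_c, 1 / (0.5 * lambda_H3))
})

test_that("graph reduction: W-threshold is conservative against adjacency", {
  # for all-size-2 hypergraphs the co-membership diagonal adds degree
  # mass, so lambda(W) >= lambda(A)
  for (seed in 1:5) {
    H <- random_hypergraph(15, c(`2` = 25), seed = seed)
    W <- as.matrix(comembership(H))
    A <- W
    diag(A) <- 0
    expect_gte(max(eigen(W, symmetric = TRUE, only.values = TRUE)$values),
               max(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  }
})

test_that("extinction bounds evaluate the closed-form expressions", {
  idf <- rate_function("identity")
  pars <- sis_params(0.1, 1, 0.5)
  rep3 <- spectral_threshold(H3, idf, pars)
  b <- extinction_bounds(rep3, n = 3, i0 = 0.5, pars)
  # t = 0: min(1, n i0)
  expect_equal(b$prob_bound(0), 1)
  expect_equal(extinction_bounds(rep3, 3, 0.1, pars)$prob_bound(0), 0.3)
  # plug-in of the expected-extinction-time formula on H3
  expect_equal(b$expected_tau_bound,
               (log(3) + 1) / (1 - 0.1 * lambda_H3), tolerance = 1e-12)
  expect_equal(b$expected_tau_bound, 3.858845, tolerance = 1e-6)
  # boundary case beta c_f lambda = delta (exact on a single edge, where
  # lambda = 2): constant bound, infinite tau
  He <- hypergraph(list(c(1, 2)))
  pb <- sis_params(0.5, 1, 0.1)
  bb <- extinction_bounds(spectral_threshold(He, idf, pb), 2, 0.1, pb)
  expect_equal(bb$expected_tau_bound, Inf)
  expect_equal(bb$prob_bound(c(1, 5)), c(0.2, 0.2))
  # refusal: derivative-at-zero bounds with uncertified concavity
  stp <- rate_function("step", c1 = 2, c2 = 1)
  rl <- spectral_threshold(H3, stp, pars)
  expect_error(extinction_bounds(rl, 3, 0.5, pars), "majorant")
  expect_error(extinction_bounds(rep3, 3, 0.5, sis_params(0.2, 1, 0.5)),
               "match")
})

test_that("subset pressure matches the definitional double sum", {
  idf <- rate_function("identity")
  expect_equal(subset_pressure(H3, 3, idf)$value, 2)     # f(2) via triangle
  expect_equal(subset_pressure(H3, 1, idf)$value, 3)     # f(2) + f(1)
  expect_equal(subset_pressure(H3, 1:3, idf)$value, 0)   # empty complement
  expect_error(subset_pressure(H3, integer(0), idf), "non-empty")
  hypersis:::with_seed(13, {
    for (H in small_instances(4)) {
      S <- sample.int(H$n, sample(1:(H$n - 1), 1))
      for (rf in list(idf, rate_function("log1p", a = 1),
                      rate_function("step", c1 = 2, c2 = 1)))
        expect_equal(subset_pressure(H, S, rf)$value,
                     oracle_pressure(H, S, rf$fn))
    }
  })
})

test_that("eta brute force is exact and greedy upper-bounds it", {
  idf <- rate_function("identity")
  # H3, m = 1: singleton pressures are 3, 3, 2
  e3 <- eta(H3, 1, idf, method = "brute")
  expect_equal(e3$value, 2)
  expect_equal(e3$minimizer, 3L)
  # isolated component inside the size limit gives eta = 0
  Hd <- hypergraph(list(c(1, 2), c(3, 4), c(3, 4, 5), c(4, 5), c(1, 5)),
                   n = 10)
  expect_equal(eta(Hd, 3, idf, method = "brute")$value, 0)
  # brute vs the independent enumeration oracle; greedy >= brute always
  for (H in small_instances(6)) {
    m <- max(1, floor(H$n / 2) - 1)
    for (rf in list(idf, rate_function("log1p", a = 1))) {
      eb <- eta(H, m, rf, method = "brute")
      expect_equal(eb$value, oracle_eta(H, m, rf$fn))
      eg <- eta(H, m, rf, method = "greedy")
      expect_true(eg$is_upper_bound)
      expect_gte(eg$value + 1e-12, eb$value)
      # equality when the brute minimizer is a singleton
      if (length(eb$minimizer) == 1L)
        expect_equal(eg$value, eb$value)
    }
  }
  expect_error(eta(H3, 1, idf, method = "brute", budget = 1), "budget")
  expect_error(eta(H3, 3, idf), "floor")
})

test_that("Cheeger consistency: 2 eta >= lambda_c on connected instances", {
  idf <- rate_function("identity")
  for (H in small_instances(8, seed = 123)) {
    lap <- laplacian(H)
    if (lap$n_zero != 1L) next  # Cheeger relates eta to the Fiedler value
    e <- eta(H, floor(H$n / 2), idf, method = "brute")
    expect_gte(2 * e$value + 1e-9, lap$lambda_c)
  }
})

test_that("Cheeger-type chord bound links eta under f to identity eta", {
  # for concave non-decreasing f:
  # (f(e_max - 1)/(e_max - 1)) eta(H, m) <= eta(H, m, f)
  for (H in small_instances(6, seed = 7)) {
    e_max <- max_hyperedge_size(H)
    m <- floor(H$n / 2)
    e_id <- eta(H, m, rate_function("identity"), method = "brute")$value
    for (rf in list(rate_function("log1p", a = 1.3),
                    rate_function("arctan"),
                    rate_function("capped_linear", c = 2))) {
      e_f <- eta(H, m, rf, method = "brute")$value
      chord <- rf$fn(e_max - 1) / (e_max - 1)
      expect_gte(e_f + 1e-12, chord * e_id)
    }
  }
})

test_that("eigenvalue monotonicity under diagonal subtraction", {
  # The quadratic-form argument gives monotonicity of the symmetric
  # part's largest eigenvalue for arbitrary B, and of the largest
  # eigenvalue itself when B is symmetric (the max-real-part analogue is
  # FALSE for general non-symmetric B, so it is not asserted).
  lam_sym <- function(M) max(eigen((M + t(M)) / 2, symmetric = TRUE,
                                   only.values = TRUE)$values)
  hypersis:::with_seed(5150, {
    for (trial in 1:200) {
      n <- sample(2:8, 1)
      B <- matrix(rnorm(n * n), n, n)
      L <- diag(runif(n, 0, 2), n)
      expect_lte(lam_sym(B - L), lam_sym(B) + 1e-10)
      Bs <- (B + t(B)) / 2
      expect_lte(max(eigen(Bs - L, symmetric = TRUE,
                           only.values = TRUE)$values),
                 max(eigen(Bs, symmetric = TRUE,
                           only.values = TRUE)$values) + 1e-10)
    }
  })
})

test_that("symmetric part is the forced average", {
  expect_equal(as.matrix(symmetric_part(matrix(c(0, 0, 2, 0), 2, 2))),
               matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)
  M <- as.matrix(comembership(H3))
  expect_equal(as.matrix(symmetric_part(M)), M, ignore_attr = TRUE)
  expect_error(symmetric_part(matrix(0, 2, 3)), "square")
  # along a subcritical trajectory the symmetrized Jacobian stays stable
  idf <- rate_function("identity")
  bc <- 1 / lambda_H3
  pars <- sis_params(0.8 * bc, 1, 0)
  tr <- integrate_euler(rep(0.5, 3), H3, pars, idf, dt = 0.05, T = 10,
                        record_states = TRUE)
  for (j in seq(1, ncol(tr$states), by = 20)) {
    Js <- symmetric_part(jacobian(tr$states[, j], H3, pars, idf))
    expect_lt(max(eigen(as.matrix(Js), symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("non-extinction certificate assembles r and the horizon", {
  idf <- rate_function("identity")
  # dense hypergraph, strong infection: persistence certified
  H <- random_hypergraph(10, c(`2` = 20, `3` = 10), seed = 3)
  pars <- sis_params(5, 0.1, 0.5)
  cert <- nonextinction_certificate(H, idf, pars, eta_method = "brute")
  # identity response: prefactor cancels, r = delta / (beta eta)
  e <- eta(H, 5, idf, method = "brute")
  expect_equal(cert$r, 0.1 / (5 * e$value))
  expect_true(cert$condition_met)
  m <- 5
  expect_equal(cert$time_horizon, floor(cert$r^(-m + 1)) / (2 * m))
  expect_equal(cert$prob_lower_bound, 1 - cert$r * exp(1))
  expect_match(cert$caveat, "O\\(r\\^m\\)")
  # r >= 1: certificate withheld
  weak <- nonextinction_certificate(H, idf, sis_params(1e-4, 1, 0.5),
                                    eta_method = "brute")
  expect_false(weak$condition_met)
  expect_true(is.na(weak$prob_lower_bound))
  # hypotheses are enforced
  expect_error(nonextinction_certificate(H, rate_function("step", c1 = 2,
                                                          c2 = 1), pars),
               "concave")
})
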