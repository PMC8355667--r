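# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive loops over the definitions so they share no code path with the
# package implementation they check.

H3 <- hypergraph(list(c(1, 2, 3), c(1, 2)))
# H3 partitioned: the triangle is category 2, the edge category 1
PH3 <- hypergraph(list(c(1, 2, 3), c(1, 2)), category = c(2, 1), K = 2)

lambda_H3 <- (5 + sqrt(17)) / 2  # largest eigenvalue of W(H3), by hand

small_instances <- function(n_instances = 8, n_max = 12, seed = 99) {
  with_seed <- hypersis:::with_seed
  with_seed(seed, lapply(seq_len(n_instances), function(i) {
    n <- sample(4:n_max, 1)
    m <- sample(3:(2 * n), 1)
    edges <- lapply(seq_len(m), function(h)
      sample.int(n, sample(2:min(5, n), 1)))
    hypergraph(edges, n = n)
  }))
}

# W by definition: count hyperedges containing both i and j.
oracle_comembership <- function(H) {
  W <- matrix(0, H$n, H$n)
  for (i in seq_len(H$n)) for (j in seq_len(H$n))
    for (e in H$edges)
      if (i %in% e && j %in% e) W[i, j] <- W[i, j] + 1
  W
}

# Infection rates by direct transcription of the per-hyperedge sum.
oracle_infection_rates <- function(H, x, f, beta, category_f = NULL) {
  r <- numeric(H$n)
  for (i in seq_len(H$n)) {
    for (h in seq_along(H$edges)) {
      e <- H$edges[[h]]
      if (!(i %in% e)) next
      fk <- if (is.null(category_f)) f else category_f[[H$category[h]]]
      r[i] <- r[i] + fk(sum(x[e]))
    }
  }
  beta * r
}

# E(S, f) by definition.
oracle_pressure <- function(H, S, f) {
  Sc <- setdiff(seq_len(H$n), S)
  val <- 0
  for (i in S) for (h in seq_along(H$edges)) {
    e <- H$edges[[h]]
    if (i %in% e) val <- val + f(length(intersect(e, Sc)))
  }
  val
}

# eta by exhaustive enumeration using oracle_pressure only.
oracle_eta <- function(H, m, f) {
  best <- Inf
  for (s in seq_len(m)) {
    cs <- utils::combn(H$n, s)
    for (j in seq_len(ncol(cs)))
      best <- min(best, oracle_pressure(H, cs[, j], f) / s)
  }
  best
}

# Step-function evaluation of an event trajectory on a grid (independent
# re-implementation used when checking simulator output).
oracle_on_grid <- function(traj, grid) {
  vapply(grid, function(t) {
    i <- max(which(traj$times <= t))
    traj$infected_count[i]
  }, numeric(1))
}
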