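#' Construct a hypergraph
#'
#' A hypergraph is a set of `n` labelled nodes together with an ordered list
#' of hyperedges, each a non-empty subset of the nodes. Hyperedges may
#' optionally be partitioned into `K` categories (e.g. by venue type or by
#' hyperedge size), in which case each category can later be given its own
#' infection-response function.
#'
#' Duplicate hyperedges are permitted and add co-membership weight; a
#' hyperedge may not contain the same node twice.
#'
#' @param edges list of integer vectors, each a set of node indices in
#'   `1..n`; may be empty.
#' @param n node count. Defaults to the largest index appearing in `edges`.
#' @param category optional integer vector, one entry per hyperedge, giving
#'   the category `k` in `1..K` of each hyperedge.
#' @param K number of categories; defaults to `max(category)`. Categories
#'   with no hyperedges are allowed when `K` is given explicitly.
#' @param labels optional character vector of external node labels
#'   (length `n`).
#' @return an object of class `hypergraph` with fields `n`, `edges`,
#'   `category` (or `NULL`), `K`, `labels` (or `NULL`).
#' @examples
#' H <- hypergraph(list(c(1, 2, 3), c(1, 2)))
#' comembership(H)
#' @export
hypergraph <- function(edges, n = NULL, category = NULL, K = NULL,
                       labels = NULL) {
  if (!is.list(edges)) stop("`edges` must be a list of integer vectors")
  edges <- lapply(edges, function(e) as.integer(sort(e)))
  if (is.null(n)) {
    n <- if (length(edges)) max(vapply(edges, max, integer(1))) else 0L
  }
  n <- as.integer(n)
  for (h in seq_along(edges)) {
    e <- edges[[h]]
    if (length(e) == 0L)
      stop("hyperedge ", h, " is empty")
    if (anyDuplicated(e))
      stop("hyperedge ", h, " contains duplicate nodes")
    if (any(e < 1L) || any(e > n))
      stop("hyperedge ", h, " has node index outside 1..", n)
  }
  if (!is.null(category)) {
    category <- as.integer(category)
    if (length(category) != length(edges))
      stop("`category` must have one entry per hyperedge")
    if (is.null(K)) K <- if (length(category)) max(category) else 1L
    K <- as.integer(K)
    if (length(category) && (any(category < 1L) || any(category > K)))
      stop("hyperedge category outside 1..", K)
  } else {
    K <- 1L
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("`labels` must have length n")
    if (anyDuplicated(labels)) stop("node labels must be unique")
  }
  structure(list(n = n, edges = edges, category = category,
                 K = K, labels = labels),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("hypergraph: ", x$n, " nodes, ", length(x$edges), " hyperedges",
      sep = "")
  if (!is.null(x$category)) cat(", ", x$K, " categories", sep = "")
  if (length(x$edges)) {
    sz <- table(vapply(x$edges, length, integer(1)))
    cat("\n  sizes: ", paste0(names(sz), ":", sz, collapse = " "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
n_nodes <- function(H) H$n

#' @export
n_hyperedges <- function(H) length(H$edges)

#' Whether a hypergraph carries a hyperedge partition
#' @param H a `hypergraph`.
#' @export
is_partitioned <- function(H) !is.null(H$category)

#' Size of the largest hyperedge
#'
#' @param H a `hypergraph` with at least one hyperedge.
#' @return the integer `e_max = max_h |h|`.
#' @export
max_hyperedge_size <- function(H) {
  if (length(H$edges) == 0L)
    stop("hypergraph has no hyperedges: e_max undefined")
  max(vapply(H$edges, length, integer(1)))
}

#' Node-by-hyperedge incidence matrix
#'
#' Returns the sparse binary matrix `I` with `I[i, h] = 1` iff node `i`
#' belongs to hyperedge `h`. Column sums are hyperedge sizes, row sums are
#' node degrees (number of incident hyperedges).
#'
#' @param H a `hypergraph`.
#' @param category if non-`NULL`, restrict to hyperedges of this category:
#'   columns for other hyperedges are kept but zeroed, so that the category
#'   incidence matrices sum to the full one.
#' @return an `n x m` sparse `Matrix`.
#' @export
incidence <- function(H, category = NULL) {
  m <- length(H$edges)
  keep <- if (is.null(category)) seq_len(m) else which(H$category == category)
  i <- unlist(H$edges[keep], use.names = FALSE)
  j <- rep.int(keep, vapply(H$edges[keep], length, integer(1)))
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(H$n, m))
}

#' Co-membership matrix W = I I^T
#'
#' `W[i, j]` counts the hyperedges containing both `i` and `j`; the diagonal
#' `W[i, i]` is the degree of node `i`. For a plain graph (all hyperedges of
#' size 2) the off-diagonal part is the adjacency matrix and the diagonal
#' holds the degrees, so `W = A + D`.
#'
#' @param H a `hypergraph`.
#' @param diagonal keep the degree diagonal (default). `FALSE` zeroes it,
#'   giving the weighted-adjacency part used for comparison with the classic
#'   graph SIS threshold.
#' @return a symmetric `n x n` sparse `Matrix`.
#' @export
comembership <- function(H, diagonal = TRUE) {
  W <- Matrix::tcrossprod(incidence(H))
  if (!diagonal) Matrix::diag(W) <- 0
  methods::as(Matrix::forceSymmetric(W), "generalMatrix")
}

#' Per-category co-membership matrices
#'
#' For a partitioned hypergraph returns the list `W^(1), ..., W^(K)` with
#' `W^(k) = I^(k) (I^(k))^T`; the elementwise sum over categories equals
#' [comembership()] of the full hypergraph. An unpartitioned hypergraph is
#' treated as having a single category.
#'
#' @param H a `hypergraph`.
#' @return a list of `K` symmetric sparse matrices.
#' @export
partition_comembership <- function(H) {
  K <- if (is_partitioned(H)) H$K else 1L
  lapply(seq_len(K), function(k) {
    Ik <- if (is_partitioned(H)) incidence(H, category = k) else incidence(H)
    methods::as(Matrix::forceSymmetric(Matrix::tcrossprod(Ik)),
                "generalMatrix")
  })
}

#' Weighted-graph Laplacian of the co-membership structure
#'
#' Builds the Laplacian `L = D - W_off` of the weighted graph induced by the
#' off-diagonal part of `W = I I^T` (self-loops do not affect cut sizes),
#' with `D[i, i] = sum_{j != i} W[i, j]`. Reports the smallest eigenvalue
#' exceeding the zero tolerance (the algebraic connectivity when connected)
#' and the number of numerically-zero eigenvalues, which equals the number
#' of connected components.
#'
#' @param H a `hypergraph` with `n >= 1`.
#' @param zero_tol relative tolerance for declaring an eigenvalue zero,
#'   as a fraction of the largest eigenvalue.
#' @return a list with class `hg_laplacian`: `matrix` (dense symmetric),
#'   `eigenvalues` (ascending), `lambda_c` (smallest non-zero eigenvalue, or
#'   `NA` if all are zero), `n_zero` (component count), `zero_tol`.
#' @export
laplacian <- function(H, zero_tol = 1e-8) {
  if (H$n == 0L) stop("empty hypergraph: Laplacian undefined")
  W <- as.matrix(comembership(H, diagonal = FALSE))
  L <- diag(rowSums(W), nrow = H$n) - W
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  thresh <- zero_tol * max(abs(ev), 1e-300)
  nz <- sum(ev <= thresh)
  structure(list(matrix = L, eigenvalues = ev,
                 lambda_c = if (nz < length(ev)) ev[nz + 1L] else NA_real_,
                 n_zero = nz, zero_tol = zero_tol),
            class = "hg_laplacian")
}

#' @export
print.hg_laplacian <- function(x, ...) {
  cat("Laplacian of co-membership graph: n =", nrow(x$matrix),
      "| components =", x$n_zero,
      "| lambda_c =", format(x$lambda_c, digits = 6), "\n")
  invisible(x)
}

#' Random hypergraph with a prescribed size composition
#'
#' For each entry `size -> count` of `counts_by_size`, draws `count`
#' hyperedges, each a uniformly random subset of `size` distinct nodes.
#' Hyperedges are mutually independent (duplicates across hyperedges are
#' possible). With `partition_by_size = TRUE` each size-`s` hyperedge is
#' assigned category `s - 1`, the convention used when each group size gets
#' its own infection response.
#'
#' @param n node count.
#' @param counts_by_size named vector or list, names are hyperedge sizes
#'   (each between 2 and `n`), values the number of hyperedges to draw.
#' @param seed optional integer seed; when given, generation is
#'   reproducible and the caller's RNG state is left untouched.
#' @param partition_by_size assign category `s - 1` to size-`s` hyperedges.
#' @return a `hypergraph`.
#' @examples
#' H <- random_hypergraph(400, c(`2` = 300, `3` = 200, `4` = 100, `5` = 50),
#'                        seed = 1)
#' n_hyperedges(H)  # 650
#' @export
random_hypergraph <- function(n, counts_by_size, seed = NULL,
                              partition_by_size = FALSE) {
  n <- as.integer(n)
  sizes <- as.integer(names(counts_by_size))
  counts <- as.integer(unlist(counts_by_size, use.names = FALSE))
  if (any(is.na(sizes))) stop("`counts_by_size` must be named by size")
  if (any(sizes < 2L)) stop("hyperedge sizes must be at least 2")
  if (any(sizes > n)) stop("hyperedge size exceeds node count n = ", n)
  if (any(counts < 0L)) stop("hyperedge counts must be non-negative")
  draw <- function() {
    edges <- vector("list", sum(counts))
    cat_of <- integer(sum(counts))
    h <- 0L
    for (s_idx in seq_along(sizes)) {
      s <- sizes[s_idx]
      for (rep in seq_len(counts[s_idx])) {
        h <- h + 1L
        edges[[h]] <- sample.int(n, s)
        cat_of[h] <- s - 1L
      }
    }
    list(edges = edges, cat_of = cat_of)
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  hypergraph(d$edges, n = n,
             category = if (partition_by_size) d$cat_of else NULL,
             K = if (partition_by_size && length(sizes)) max(sizes) - 1L
                 else NULL)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Export a matrix as coordinate-format sparse text
#'
#' Writes lines `row col value` with 0-based row/column indices, one
#' non-zero per line, preceded by a header line `n_rows n_cols nnz`.
#'
#' @param M a matrix or `Matrix`.
#' @param path output file path.
#' @export
write_sparse_coords <- function(M, path) {
  M <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(M), ncol(M), length(M@x)), con)
  if (length(M@x))
    writeLines(paste(M@i, M@j, M@x), con)
  invisible(path)
}
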