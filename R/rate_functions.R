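#' Infection-response functions
#'
#' A rate function `f` maps the number of infectious co-members of a
#' hyperedge (a non-negative real in the mean-field setting) to that
#' hyperedge's contribution to a susceptible node's infection rate. All
#' implemented families satisfy `f(0) = 0`. Concave families model
#' *collective suppression* (diminishing marginal risk); the step and hinge
#' families model *collective contagion*, where spread within a hyperedge
#' requires a threshold number of infectious members.
#'
#' Available families (`name`, parameters):
#' * `identity` — `f(x) = x`; the classic linear graph model.
#' * `capped_linear` (`c > 0`) — `f(x) = min(x, c)`.
#' * `log1p` (`a > 0`) — `f(x) = a * log(1 + x)`.
#' * `arctan` — `f(x) = atan(x)`.
#' * `step` (`c1, c2 > 0`) — `f(x) = c2 * 1(x >= c1)`; not concave,
#'   `f'(0) = 0`.
#' * `hinge` (`c > 0`) — `f(x) = max(0, x - c)`; not concave, `f'(0) = 0`.
#'
#' The derivative at zero is stored analytically per family (thresholds must
#' be exact, so it is never obtained by numerical differentiation). The
#' stored pointwise derivative uses the one-sided derivative from below at
#' kink points (`capped_linear` at `c`, `hinge` at `c`, `step` at `c1`).
#'
#' @param name family name, one of the identifiers above.
#' @param ... family parameters (`c`, `a`, `c1`, `c2`).
#' @return an object of class `rate_function` with fields `name`, `params`,
#'   `fn` (vectorized evaluation), `deriv` (pointwise derivative),
#'   `deriv0` (`f'(0)`), `concave`, `nondecreasing`, `label`.
#' @examples
#' f <- rate_function("capped_linear", c = 3)
#' f$fn(c(2, 5))      # 2 3
#' f$deriv0           # 1
#' @export
rate_function <- function(name, ...) {
  params <- list(...)
  pos <- function(p) {
    v <- params[[p]]
    if (is.null(v) || !is.numeric(v) || v <= 0)
      stop("rate function '", name, "' needs positive parameter '", p, "'")
    as.numeric(v)
  }
  rf <- switch(
    name,
    identity = list(fn = function(x) x,
                    deriv = function(x) rep_len(1, length(x)),
                    deriv0 = 1, concave = TRUE, nondecreasing = TRUE),
    capped_linear = {
      c0 <- pos("c")
      list(fn = function(x) pmin(x, c0),
           deriv = function(x) as.numeric(x <= c0),
           deriv0 = 1, concave = TRUE, nondecreasing = TRUE)
    },
    log1p = {
      a <- pos("a")
      list(fn = function(x) a * log1p(x),
           deriv = function(x) a / (1 + x),
           deriv0 = a, concave = TRUE, nondecreasing = TRUE)
    },
    arctan = list(fn = function(x) atan(x),
                  deriv = function(x) 1 / (1 + x^2),
                  deriv0 = 1, concave = TRUE, nondecreasing = TRUE),
    step = {
      c1 <- pos("c1"); c2 <- pos("c2")
      list(fn = function(x) c2 * as.numeric(x >= c1),
           deriv = function(x) rep_len(0, length(x)),
           deriv0 = 0, concave = FALSE, nondecreasing = TRUE)
    },
    hinge = {
      c0 <- pos("c")
      list(fn = function(x) pmax(0, x - c0),
           deriv = function(x) as.numeric(x > c0),
           deriv0 = 0, concave = FALSE, nondecreasing = TRUE)
    },
    stop("unknown rate function '", name, "'")
  )
  rf$name <- name
  rf$params <- lapply(params, as.numeric)
  rf$label <- if (length(params))
    paste0(name, ":", paste0(names(params), "=", unlist(params),
                             collapse = ",")) else name
  structure(rf, class = "rate_function")
}

#' @export
print.rate_function <- function(x, ...) {
  cat("rate function ", x$label, " | f'(0) = ", x$deriv0,
      " | concave: ", x$concave, "\n", sep = "")
  invisible(x)
}

#' Parse a rate-function spec string
#'
#' Accepts the identifiers of [rate_function()] with inline parameters,
#' e.g. `"step:c1=2,c2=1"`, `"log1p:a=2"`, `"identity"`.
#'
#' @param spec a character scalar.
#' @return a `rate_function`.
#' @export
parse_rate_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  name <- parts[1]
  args <- list()
  if (length(parts) > 1 && nzchar(parts[2])) {
    kv <- strsplit(strsplit(parts[2], ",", fixed = TRUE)[[1]], "=",
                   fixed = TRUE)
    bad <- vapply(kv, length, integer(1)) != 2L
    if (any(bad)) stop("malformed rate spec '", spec, "'")
    args <- stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                            vapply(kv, `[`, character(1), 1))
  }
  do.call(rate_function, c(list(name = name), args))
}

#' A family of rate functions for a partitioned hypergraph
#'
#' @param ... `rate_function` objects (or spec strings), one per hyperedge
#'   category `k = 1..K` in order.
#' @return an object of class `rate_family` (a list of `rate_function`s).
#' @export
rate_family <- function(...) {
  fs <- lapply(list(...), function(f) {
    if (is.character(f)) parse_rate_spec(f) else f
  })
  stopifnot(all(vapply(fs, inherits, logical(1), "rate_function")))
  structure(fs, class = "rate_family")
}

# Normalize a rate_function / rate_family / list against a hypergraph:
# returns a plain list of K rate_functions.
as_rate_list <- function(rf, H) {
  K <- if (is_partitioned(H)) H$K else 1L
  if (inherits(rf, "rate_function")) rf <- rep(list(rf), K)
  if (inherits(rf, "rate_family")) rf <- unclass(rf)
  if (length(rf) != K)
    stop("rate family has length ", length(rf),
         " but the hypergraph has ", K, " categories")
  rf
}

#' Slope of the smallest implemented linear majorant
#'
#' Returns the constant `c_f` such that `c_f * x >= f(x)` for integer
#' `x` in `[0, e_max - 1]` (the attainable co-member counts when the
#' largest hyperedge has `e_max` nodes). This is the slope constant entering
#' the stochastic extinction bounds: `f'(0)` for concave `f`, `c2/c1` for
#' the step family, `(e_max - 1 - c)/(e_max - 1)` for the hinge family, and
#' a generic `max f(x)/x` fallback over the integer grid otherwise (the
#' fallback is an extension beyond the analysed families and is flagged as
#' such in threshold reports).
#'
#' @param rf a `rate_function`.
#' @param e_max size of the largest hyperedge (at least 2).
#' @return a non-negative scalar.
#' @export
concave_majorant_slope <- function(rf, e_max) {
  e_max <- as.integer(e_max)
  if (e_max < 2L) stop("e_max must be at least 2")
  if (isTRUE(rf$concave)) return(rf$deriv0)
  if (rf$name == "step") return(rf$params$c2 / rf$params$c1)
  if (rf$name == "hinge") {
    c0 <- rf$params$c
    return(max(0, (e_max - 1 - c0) / (e_max - 1)))
  }
  x <- seq_len(e_max - 1L)
  max(rf$fn(x) / x, 0)
}

#' Numerically verify concavity on the attainable range
#'
#' Checks midpoint concavity of `f` on a grid over `[0, e_max - 1]`:
#' `f((x + y)/2) >= (f(x) + f(y))/2` within a small tolerance for all grid
#' pairs. Used to gate theorems whose hypotheses require concave `f`.
#'
#' @param rf a `rate_function`.
#' @param e_max size of the largest hyperedge (at least 2).
#' @param grid_n number of grid points.
#' @return `TRUE` if no violation was found.
#' @export
check_concavity <- function(rf, e_max, grid_n = 101L) {
  if (e_max < 2L) stop("e_max must be at least 2")
  x <- seq(0, e_max - 1, length.out = grid_n)
  fx <- rf$fn(x)
  for (i in seq_along(x)) {
    mid <- (x[i] + x) / 2
    if (any(rf$fn(mid) < (fx[i] + fx) / 2 - 1e-12)) return(FALSE)
  }
  TRUE
}
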