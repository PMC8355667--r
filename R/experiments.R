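#' Build an experiment configuration
#'
#' Assembles and validates the configuration driving
#' [run_figure_protocol()]. The hypergraph source is either a file path or
#' a generator spec; rate functions are given as spec strings (see
#' [parse_rate_spec()]), one per hyperedge category.
#'
#' @param hypergraph either `list(file = path)` or
#'   `list(n =, counts_by_size =, partition_by_size =)` for the internal
#'   generator.
#' @param rates character vector of rate specs (length 1, or one per
#'   category).
#' @param beta scalar or grid of infection strengths.
#' @param delta recovery rate.
#' @param i0 initial infection probability.
#' @param T time horizon (terminal sampling time).
#' @param dt time step for both the discrete simulator and Euler.
#' @param n_runs stochastic runs per grid point.
#' @param mode `"both"`, `"stochastic"` or `"meanfield"`.
#' @param thresholds compute the spectral threshold report.
#' @param seed master seed; the hypergraph seed and all per-run seeds
#'   derive from it.
#' @param keep_trajectories store mean-fraction time series per beta.
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(hypergraph, rates, beta, delta = 1,
                              i0 = 0.5, T = 150, dt = 0.05, n_runs = 5,
                              mode = c("both", "stochastic", "meanfield"),
                              thresholds = TRUE, seed = 1,
                              keep_trajectories = FALSE) {
  mode <- match.arg(mode)
  problems <- character(0)
  if (!is.list(hypergraph) ||
      (is.null(hypergraph$file) && is.null(hypergraph$n)))
    problems <- c(problems,
                  "hypergraph: need $file or generator fields $n, $counts_by_size")
  if (!is.null(hypergraph$n) && is.null(hypergraph$counts_by_size))
    problems <- c(problems, "hypergraph: generator needs $counts_by_size")
  if (length(beta) < 1) problems <- c(problems, "beta: empty grid")
  rfs <- tryCatch(lapply(rates, parse_rate_spec), error = function(e) e)
  if (inherits(rfs, "error"))
    problems <- c(problems, paste("rates:", conditionMessage(rfs)))
  if (length(problems))
    stop("invalid experiment config:\n  ",
         paste(problems, collapse = "\n  "))
  structure(list(hypergraph = hypergraph, rates = rates, beta = beta,
                 delta = delta, i0 = i0, T = T, dt = dt, n_runs = n_runs,
                 mode = mode, thresholds = thresholds, seed = seed,
                 keep_trajectories = keep_trajectories),
            class = "experiment_config")
}

config_hypergraph <- function(config) {
  hg <- config$hypergraph
  if (!is.null(hg$file)) return(read_hypergraph(hg$file))
  random_hypergraph(hg$n, hg$counts_by_size,
                    seed = hg$seed %||% config$seed,
                    partition_by_size = isTRUE(hg$partition_by_size))
}

#' Run a terminal-fraction-versus-beta experiment
#'
#' Reproduces the standard protocol for probing the spectral threshold: on
#' one fixed hypergraph, for every `beta` on the grid, integrate the
#' mean-field ODE (Euler, step `dt`) and/or average `n_runs` discrete-time
#' stochastic runs sharing one initial state, and record the infected
#' fraction at the terminal time `T`. The experiment layer only composes
#' the module operations — it computes no model mathematics itself.
#'
#' @param config an `experiment_config` (or plain list accepted by
#'   [experiment_config()]).
#' @return an object of class `experiment_result`: `table` (one row per
#'   beta: `beta`, `meanfield_terminal`, `stochastic_terminal`),
#'   `threshold` (a `spectral_report` at the first grid beta, or `NULL`),
#'   `beta_c`, `trajectories` (optional), `provenance`.
#' @export
run_figure_protocol <- function(config) {
  if (!inherits(config, "experiment_config"))
    config <- do.call(experiment_config, config)
  H <- config_hypergraph(config)
  rfs <- do.call(rate_family, as.list(config$rates))
  if (length(rfs) == 1L) rfs <- rfs[[1L]]
  betas <- as.numeric(config$beta)
  mf_term <- st_term <- rep(NA_real_, length(betas))
  trajs <- if (config$keep_trajectories) vector("list", length(betas))
  init <- with_seed(config$seed,
                    draw_initial_state(H$n, config$i0))
  for (b in seq_along(betas)) {
    pars <- sis_params(betas[b], config$delta, config$i0)
    entry <- list()
    if (config$mode %in% c("both", "meanfield")) {
      # start the ODE from the same realized initial state the stochastic
      # runs share, so the two models are compared from matched conditions
      mf <- integrate_euler(init, H, pars, rfs,
                            dt = config$dt, T = config$T)
      mf_term[b] <- mf$mean_fraction[length(mf$mean_fraction)]
      entry$meanfield <- data.frame(time = mf$times,
                                    mean_fraction = mf$mean_fraction)
    }
    if (config$mode %in% c("both", "stochastic")) {
      ens <- run_ensemble(H, pars, rfs, T = config$T,
                          n_runs = config$n_runs,
                          base_seed = config$seed + 1000L * b,
                          dt = config$dt, init = init)
      st_term[b] <- ens$mean_fraction[length(ens$mean_fraction)]
      entry$stochastic <- as.data.frame(ens)
      entry$mc_se <- apply(ens$counts / H$n, 2, stats::sd) /
        sqrt(config$n_runs)
    }
    if (config$keep_trajectories) trajs[[b]] <- entry
  }
  thr <- if (config$thresholds)
    spectral_threshold(H, rfs, sis_params(betas[1], config$delta,
                                          config$i0))
  concave <- all(vapply(as_rate_list(rfs, H), function(f)
    isTRUE(f$concave), logical(1)))
  structure(list(
    table = data.frame(beta = betas, meanfield_terminal = mf_term,
                       stochastic_terminal = st_term),
    threshold = thr,
    beta_c = if (!is.null(thr)) thr$beta_c else NA_real_,
    concave_family = concave,
    trajectories = trajs,
    hypergraph = H,
    provenance = list(seed = config$seed, n_runs = config$n_runs,
                      dt = config$dt, T = config$T, i0 = config$i0,
                      delta = config$delta, rates = config$rates,
                      version = as.character(
                        utils::packageVersion("hypersis")))),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment result over ", nrow(x$table), " beta value(s)",
      if (!is.na(x$beta_c)) paste0(", beta_c = ",
                                   format(x$beta_c, digits = 5)),
      "\n", sep = "")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Compare mean-field and stochastic outputs of an experiment
#'
#' Tabulates the per-beta difference (mean field minus stochastic mean) of
#' the terminal infected fraction, and — when trajectories were kept —
#' the largest per-time violation of the concave ordering (stochastic mean
#' exceeding mean field by more than `tol_se` Monte-Carlo standard
#' errors). For concave families the mean field over-estimates the exact
#' expectations, so flagged violations should be empty; for non-concave
#' (e.g. collective contagion) families no ordering is asserted and the
#' flag is suppressed.
#'
#' @param result an `experiment_result` run with `mode = "both"`.
#' @param tol_se Monte-Carlo tolerance in standard errors.
#' @return a data.frame with columns `beta`, `difference`,
#'   `ordering_violation` (`NA` when not asserted).
#' @export
compare_models <- function(result, tol_se = 3) {
  tab <- result$table
  if (all(is.na(tab$meanfield_terminal)) ||
      all(is.na(tab$stochastic_terminal)))
    stop("compare_models needs an experiment run with mode = 'both'")
  viol <- rep(NA, nrow(tab))
  if (result$concave_family) {
    viol <- rep(FALSE, nrow(tab))
    if (!is.null(result$trajectories)) {
      for (b in seq_len(nrow(tab))) {
        e <- result$trajectories[[b]]
        if (is.null(e$meanfield) || is.null(e$stochastic)) next
        mf <- stats::approx(e$meanfield$time, e$meanfield$mean_fraction,
                            xout = e$stochastic$time, rule = 2)$y
        viol[b] <- any(e$stochastic$mean_fraction >
                         mf + tol_se * e$mc_se)
      }
    }
  }
  data.frame(beta = tab$beta,
             difference = tab$meanfield_terminal -
               tab$stochastic_terminal,
             ordering_violation = viol)
}

#' Write experiment outputs to disk
#'
#' Emits `table.csv` (per-beta terminal fractions), `result.json` (table,
#' threshold report and provenance), and per-beta trajectory CSVs when
#' they were kept.
#'
#' @param result an `experiment_result`.
#' @param dir output directory (created if needed).
#' @param format `"csv"`, `"json"` or `"both"`.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir, format = c("both", "csv",
                                                     "json")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format %in% c("both", "csv")) {
    utils::write.csv(result$table, file.path(dir, "table.csv"),
                     row.names = FALSE)
    if (!is.null(result$trajectories)) {
      for (b in seq_along(result$trajectories)) {
        e <- result$trajectories[[b]]
        if (!is.null(e$meanfield))
          utils::write.csv(e$meanfield,
                           file.path(dir, sprintf("meanfield_beta%02d.csv",
                                                  b)),
                           row.names = FALSE)
        if (!is.null(e$stochastic))
          utils::write.csv(e$stochastic,
                           file.path(dir, sprintf("stochastic_beta%02d.csv",
                                                  b)),
                           row.names = FALSE)
      }
    }
  }
  if (format %in% c("both", "json")) {
    thr <- result$threshold
    jsonlite::write_json(
      list(table = result$table,
           threshold = if (!is.null(thr)) unclass(thr),
           beta_c = result$beta_c,
           provenance = result$provenance),
      file.path(dir, "result.json"),
      auto_unbox = TRUE, null = "null", digits = NA, force = TRUE)
  }
  invisible(dir)
}
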