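# Experiment simulation: equilibrate the model without inputs, apply the
# experiment's initial-value overrides, then integrate the stimulated
# system on the requested output grid ("default" or "detailed"
# resolution) and map states to outputs. Integration uses deSolve's
# stiff-capable lsoda solver.

sim_defaults <- function() {
  list(rtol = 1e-6, atol = 1e-9,
       step_default = 0.05, step_detailed = 0.01,
       equil_max_time = 10000, equil_steady_tol = 1e-8)
}

# deSolve wrapper around a compiled model's rhs.
desolve_func <- function(model, theta, channels, totals) {
  inputs <- model$network$inputs
  function(t, y, parms) {
    u <- if (length(inputs)) {
      vapply(inputs, function(id) {
        f <- channels[[id]]
        if (is.null(f)) model$network$input_defaults[[id]] else f(t)
      }, numeric(1))
    } else numeric(0)
    list(model$rhs(t, y, theta, u, totals))
  }
}

resting_channels <- function(network) {
  ch <- list()
  for (id in network$inputs) {
    v <- network$input_defaults[[id]] %||% 0
    ch[[id]] <- local({ vv <- v; function(t) rep(vv, length(t)) })
  }
  ch
}

#' Equilibrate a compiled model
#'
#' Integrates the model with all inputs held at their resting values
#' (Input-table defaults, typically 0) until the scaled right-hand-side
#' norm `||rhs||_inf / max(||x||_inf, 1)` drops below `steady_tol`, or
#' until `max_time` is reached (then a warning flag is set).
#'
#' @param model a `compiled_model`.
#' @param theta named parameter vector; defaults to the Parameter table.
#' @param x0 initial full state; defaults to Compound-table initial values.
#' @param settings list overriding `equil_max_time`, `equil_steady_tol`,
#'   `rtol`, `atol`.
#' @return named steady-state vector over the full species set, with
#'   attributes `converged` (logical) and `residual`.
#' @export
equilibrate <- function(model, theta = NULL, x0 = NULL, settings = list()) {
  stopifnot(inherits(model, "compiled_model"))
  cfg <- utils::modifyList(sim_defaults(), settings)
  net <- model$network
  if (is.null(theta)) theta <- default_theta(net)
  if (is.null(x0)) x0 <- stats::setNames(net$species$initial, net$species$id)
  totals <- model$totals_of(x0)
  y <- x0[model$state_idx]
  channels <- resting_channels(net)
  fn <- desolve_func(model, theta, channels, totals)
  resid_of <- function(y) {
    dx <- model$rhs(0, y, theta,
                    vapply(net$inputs, function(id) net$input_defaults[[id]] %||% 0,
                           numeric(1)), totals)
    max(abs(dx)) / max(max(abs(y)), 1)
  }
  t_now <- 0; horizon <- min(10, cfg$equil_max_time)
  converged <- resid_of(y) <= cfg$equil_steady_tol
  while (!converged && t_now < cfg$equil_max_time) {
    t_end <- min(t_now + horizon, cfg$equil_max_time)
    sol <- deSolve::lsoda(y, c(t_now, t_end), fn, parms = NULL,
                          rtol = cfg$rtol, atol = cfg$atol)
    if (attr(sol, "istate")[1] < 0) {
      abort_sbtab("equilibration solver failure", "sbtab_simulation_error")
    }
    y <- sol[nrow(sol), -1]
    t_now <- t_end
    horizon <- horizon * 2
    converged <- resid_of(y) <= cfg$equil_steady_tol
  }
  if (!converged) {
    warning("equilibration did not reach steady_tol before max_time; returning final state")
  }
  x_full <- model$reconstruct(y, totals)
  names(x_full) <- net$species$id
  attr(x_full, "converged") <- converged
  attr(x_full, "residual") <- resid_of(y)
  x_full
}

# Parse one Experiments-table row into override lists.
experiment_spec <- function(doc, network, row) {
  exps <- doc$tables[["Experiments"]]
  overrides_in <- list(); overrides_init <- list()
  for (cn in grep("^>", names(exps), value = TRUE)) {
    ref <- sub("^>", "", cn)
    val <- exps[[cn]][row]
    if (is.character(val)) {
      if (is.na(val) || !nzchar(val)) next
      num <- suppressWarnings(as.numeric(val))
      val <- if (is.na(num)) val else num
    } else if (is.na(val)) next
    base <- sub(":.*$", "", ref)
    if (base %in% network$inputs) overrides_in[[ref]] <- val
    else if (base %in% network$species$id) overrides_init[[ref]] <- val
  }
  list(id = as.character(exps[["!ID"]][row]),
       input_overrides = overrides_in,
       initial_overrides = overrides_init)
}

#' Simulate one experiment
#'
#' Runs the full protocol: equilibration without inputs, application of
#' the experiment's initial-value overrides, then integration with the
#' experiment's stimulus channels on the resolution grid, and mapping of
#' states to the Output-table outputs.
#'
#' @param model a `compiled_model`.
#' @param doc the `sbtab_document` holding the Experiments and Input
#'   tables.
#' @param experiment_id an `!ID` from the Experiments table.
#' @param theta named parameter vector (defaults to the Parameter table).
#' @param window simulation window `c(t0, t1)` in seconds. Default
#'   `c(0, 20)`.
#' @param resolution `"default"` (0.05 s step) or `"detailed"` (0.01 s);
#'   overridable through `settings$step_default` / `settings$step_detailed`.
#' @param settings solver settings (see [equilibrate()]).
#' @param equilibrated optionally a precomputed equilibrium state (full
#'   species vector) to skip re-equilibration.
#' @param times optional explicit output grid overriding the resolution
#'   step.
#' @return a `simulation_result`: list with `times`, `states` (grid x
#'   species, nM), `outputs` (grid x outputs), `experiment_id`,
#'   `equilibrium`.
#' @export
run_experiment <- function(model, doc, experiment_id, theta = NULL,
                           window = c(0, 20),
                           resolution = c("default", "detailed"),
                           settings = list(), equilibrated = NULL,
                           times = NULL) {
  stopifnot(inherits(model, "compiled_model"))
  resolution <- match.arg(resolution)
  cfg <- utils::modifyList(sim_defaults(), settings)
  net <- model$network
  if (is.null(theta)) theta <- default_theta(net)

  exps <- doc$tables[["Experiments"]]
  if (is.null(exps) || !experiment_id %in% as.character(exps[["!ID"]])) {
    abort_sbtab(sprintf("unknown experiment id '%s'", experiment_id),
                "sbtab_validation_error")
  }
  row <- match(experiment_id, as.character(exps[["!ID"]]))
  spec <- experiment_spec(doc, net, row)

  x_eq <- if (is.null(equilibrated)) {
    equilibrate(model, theta, settings = cfg)
  } else equilibrated
  x0 <- x_eq
  for (sp in names(spec$initial_overrides)) {
    x0[[sp]] <- spec$initial_overrides[[sp]]
  }
  totals <- model$totals_of(x0)
  channels <- build_protocol(net, doc, spec$input_overrides)

  if (is.null(times)) {
    step <- if (resolution == "default") cfg$step_default else cfg$step_detailed
    times <- seq(window[1], window[2], by = step)
  }
  fn <- desolve_func(model, theta, channels, totals)
  sol <- deSolve::lsoda(x0[model$state_idx], times, fn, parms = NULL,
                        rtol = cfg$rtol, atol = cfg$atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    abort_sbtab(sprintf("solver failure in experiment '%s'", experiment_id),
                "sbtab_simulation_error")
  }
  states <- matrix(NA_real_, length(times), nrow(net$species),
                   dimnames = list(NULL, net$species$id))
  outputs <- matrix(NA_real_, length(times), length(model$output_ids),
                    dimnames = list(NULL, model$output_ids))
  for (i in seq_along(times)) {
    y <- sol[i, -1]
    states[i, ] <- model$reconstruct(y, totals)
    u <- vapply(net$inputs, function(id) channels[[id]](times[i]), numeric(1))
    if (length(model$output_ids)) {
      outputs[i, ] <- model$output_map(times[i], y, theta, u, totals)
    }
  }
  structure(list(times = times, states = states, outputs = outputs,
                 experiment_id = experiment_id, equilibrium = x_eq,
                 channels = channels),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result '%s': %d timepoints, %d species, %d output(s)\n",
              x$experiment_id, length(x$times), ncol(x$states), ncol(x$outputs)))
  invisible(x)
}

#' Simulate every experiment of a document
#'
#' Applies [run_experiment()] across the Experiments table in row order,
#' equilibrating once and reusing the equilibrium for all experiments
#' (the protocol's initial conditions are shared). Per-experiment
#' failures are recorded, not propagated, so a batch never aborts.
#'
#' @inheritParams run_experiment
#' @return named list (experiment id -> `simulation_result`); failed
#'   experiments hold a `simulation_failure` record instead, and the
#'   `failures` attribute names them.
#' @export
run_all_experiments <- function(model, doc, theta = NULL, window = c(0, 20),
                                resolution = "default", settings = list(),
                                times = NULL) {
  exps <- doc$tables[["Experiments"]]
  if (is.null(exps) || !nrow(exps)) return(structure(list(), failures = character()))
  ids <- as.character(exps[["!ID"]])
  x_eq <- equilibrate(model, theta, settings = settings)
  out <- list(); failures <- character()
  for (id in ids) {
    res <- tryCatch(
      run_experiment(model, doc, id, theta, window, resolution, settings,
                     equilibrated = x_eq, times = times),
      error = function(e) structure(list(experiment_id = id,
                                         message = conditionMessage(e)),
                                    class = "simulation_failure"))
    if (inherits(res, "simulation_failure")) failures <- c(failures, id)
    out[[id]] <- res
  }
  structure(out, failures = failures)
}

#' Export a simulation result as an SBtab data table
#'
#' Formats a `simulation_result` in the same dialect as an experiment
#' data sheet: `!TimePoint`, `!Time`, one `>Y` column per output and an
#' `SD_Y` column (filled with `sd_value`).
#'
#' @param result a `simulation_result`.
#' @param sd_value value for the SD columns. Default 1.
#' @return data frame in SBtab data-table layout.
#' @export
result_as_data_table <- function(result, sd_value = 1) {
  stopifnot(inherits(result, "simulation_result"))
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   `!TimePoint` = paste0(result$experiment_id, "T",
                                         seq_along(result$times) - 1L),
                   `!Time` = result$times)
  for (k in seq_len(ncol(result$outputs))) {
    df[[paste0(">", colnames(result$outputs)[k])]] <- result$outputs[, k]
    df[[paste0("SD_", colnames(result$outputs)[k])]] <- sd_value
  }
  df
}
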