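# Parameter estimation: a standard-deviation-weighted least-squares
# objective over all experiments and outputs,
#   F(theta) = sum_k sum_j (1/n) sum_i ((Y_ijk - y_ijk(theta)) / tau_ijk)^2,
# minimized in log10 parameter space (all rates positive) by a pluggable
# optimizer registry.

#' Build the estimation objective from a document
#'
#' Constructs `F(theta)` over every experiment that has a data table:
#' the squared residuals between data `Y` and simulated outputs `y`,
#' weighted by the per-point allowed mismatch `tau` (the `SD_` columns),
#' averaged over the `n` points of each output, then summed over outputs
#' and experiments. Simulated trajectories are cubic-spline interpolated
#' onto the data time grid. A failed simulation yields a large finite
#' penalty (`penalty + number of completed experiments`) so population
#' optimizers can proceed.
#'
#' The variant `score_kind = "max_normalized"` replaces `tau` by each
#' output's data maximum (an extension, not part of the reference
#' scheme).
#'
#' @param model a `compiled_model`.
#' @param doc the `sbtab_document` with Experiments and data tables.
#' @param free named list or vector giving the free parameter ids (values
#'   ignored); other parameters stay at their Parameter-table values.
#' @param window,resolution,settings,times as in [run_experiment()].
#' @param score_kind `"mean_sq"` (reference) or `"max_normalized"`.
#' @param penalty base penalty for failed simulations. Default `1e10`.
#' @param per_experiment if `TRUE` the returned function yields the named
#'   vector of per-experiment scores instead of their sum.
#' @return function mapping a (named or positional) free-parameter vector
#'   in linear units to the scalar objective `F` (or the per-experiment
#'   vector).
#' @export
make_objective <- function(model, doc, free = NULL, window = c(0, 20),
                           resolution = "default", settings = list(),
                           times = NULL,
                           score_kind = c("mean_sq", "max_normalized"),
                           penalty = 1e10, per_experiment = FALSE) {
  stopifnot(inherits(model, "compiled_model"))
  score_kind <- match.arg(score_kind)
  net <- model$network
  theta0 <- default_theta(net)
  free_ids <- if (is.null(free)) names(theta0) else
    if (is.character(free)) free else names(free)
  stopifnot(all(free_ids %in% names(theta0)))

  exps <- doc$tables[["Experiments"]]
  eids <- if (is.null(exps)) character() else as.character(exps[["!ID"]])
  eids <- eids[eids %in% names(doc$tables)]
  if (!length(eids)) abort_sbtab("no experiment data tables found",
                                 "sbtab_validation_error")
  datasets <- lapply(eids, function(id) sbtab_data_table(doc, id))
  names(datasets) <- eids
  for (d in datasets) {
    unknown <- setdiff(d$output_ids, model$output_ids)
    if (length(unknown)) {
      abort_sbtab(sprintf("data output(s) with no model output: %s",
                          paste(unknown, collapse = ", ")),
                  "sbtab_validation_error")
    }
  }

  function(theta_free) {
    theta <- theta0
    if (length(free_ids)) {
      if (!is.null(names(theta_free))) theta[names(theta_free)] <- theta_free
      else theta[free_ids] <- theta_free
    }
    scores <- stats::setNames(rep(NA_real_, length(eids)), eids)
    x_eq <- tryCatch(equilibrate(model, theta, settings = settings),
                     error = function(e) NULL)
    completed <- 0L
    for (id in eids) {
      d <- datasets[[id]]
      res <- if (is.null(x_eq)) NULL else tryCatch(
        run_experiment(model, doc, id, theta, window, resolution, settings,
                       equilibrated = x_eq, times = times),
        error = function(e) NULL)
      if (is.null(res)) next
      score <- 0
      for (j in seq_along(d$output_ids)) {
        oid <- d$output_ids[j]
        yfun <- stats::splinefun(res$times, res$outputs[, oid], method = "natural")
        yj <- yfun(d$times)
        denom <- if (score_kind == "mean_sq") d$tau[, j] else
          rep(max(abs(d$Y[, j])), length(yj))
        score <- score + mean(((d$Y[, j] - yj) / denom)^2)
      }
      if (is.finite(score)) {
        scores[id] <- score
        completed <- completed + 1L
      }
    }
    if (anyNA(scores)) {
      warning(sprintf("simulation failure for experiment(s): %s",
                      paste(eids[is.na(scores)], collapse = ", ")))
      scores[is.na(scores)] <- penalty + completed
    }
    if (per_experiment) scores else sum(scores)
  }
}

#' Direct evaluation of the weighted least-squares score
#'
#' The elementary score for one set of matrices: mean over points of the
#' squared tau-weighted residual, summed over output columns. Exposed for
#' testing arithmetic against hand-computed cases.
#'
#' @param Y,y,tau matrices (timepoints x outputs) of data, simulation and
#'   allowed mismatch.
#' @return scalar score.
#' @export
wls_score <- function(Y, y, tau) {
  Y <- as.matrix(Y); y <- as.matrix(y); tau <- as.matrix(tau)
  stopifnot(all(dim(Y) == dim(y)), all(dim(Y) == dim(tau)))
  sum(colMeans(((Y - y) / tau)^2))
}

# ---- optimizer registry -----------------------------------------------

optimizer_registry <- new.env(parent = emptyenv())

#' Register or list optimizers
#'
#' Optimizers operate on `z = log10(theta)` with box bounds and must
#' return `list(z, value, n_evaluations, trace)`. Built-in names:
#' `"lbfgsb"` (local gradient-based), `"neldermead"`, `"anneal"`
#' (simulated annealing), `"de"` (differential evolution), `"pso"`
#' (particle swarm).
#'
#' @param name optimizer name; @param fun optimizer function.
#' @return `register_optimizer` invisibly returns `fun`;
#'   `list_optimizers` the registered names.
#' @export
register_optimizer <- function(name, fun) {
  assign(name, fun, envir = optimizer_registry)
  invisible(fun)
}

#' @rdname register_optimizer
#' @export
list_optimizers <- function() sort(ls(optimizer_registry))

wrap_counted <- function(f) {
  n <- 0L
  trace <- numeric()
  best <- Inf
  g <- function(z) {
    n <<- n + 1L
    v <- f(z)
    if (is.na(v) || !is.finite(v)) v <- .Machine$double.xmax
    if (v < best) best <<- v
    trace[n] <<- best
    v
  }
  list(fn = g, count = function() n, trace = function() trace)
}

opt_lbfgsb <- function(f, z0, lower, upper, options = list()) {
  w <- wrap_counted(f)
  res <- stats::optim(z0, w$fn, method = "L-BFGS-B", lower = lower, upper = upper,
                      control = utils::modifyList(list(maxit = 200,
                                                       factr = 1e7),
                                                  options))
  list(z = res$par, value = res$value, n_evaluations = w$count(),
       trace = w$trace())
}

opt_neldermead <- function(f, z0, lower, upper, options = list()) {
  w <- wrap_counted(f)
  fb <- function(z) w$fn(pmin(pmax(z, lower), upper))
  res <- stats::optim(z0, fb, method = "Nelder-Mead",
                      control = utils::modifyList(list(maxit = 500), options))
  z <- pmin(pmax(res$par, lower), upper)
  list(z = z, value = f(z), n_evaluations = w$count(), trace = w$trace())
}

# Final local polish shared by the stochastic optimizers: a short
# bounded Nelder-Mead descent from the best point found.
polish_local <- function(fn, z, lower, upper, maxit = 200) {
  if (length(z) == 1) {
    res <- stats::optimize(function(s) fn(pmin(pmax(s, lower), upper)),
                           lower = lower, upper = upper)
    return(pmin(pmax(res$minimum, lower), upper))
  }
  res <- stats::optim(z, function(p) fn(pmin(pmax(p, lower), upper)),
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
  pmin(pmax(res$par, lower), upper)
}

opt_anneal <- function(f, z0, lower, upper, options = list()) {
  opts <- utils::modifyList(list(n_iter = 400, temp0 = 1, cooling = 0.99,
                                 step = 0.1), options)
  w <- wrap_counted(f)
  z <- z0; v <- w$fn(z)
  zb <- z; vb <- v
  temp <- opts$temp0
  for (i in seq_len(opts$n_iter)) {
    cand <- pmin(pmax(z + stats::rnorm(length(z), 0, opts$step * (upper - lower)),
                      lower), upper)
    vc <- w$fn(cand)
    if (vc < v || stats::runif(1) < exp((v - vc) / max(temp, 1e-12))) {
      z <- cand; v <- vc
      if (v < vb) { zb <- z; vb <- v }
    }
    temp <- temp * opts$cooling
  }
  zb <- polish_local(w$fn, zb, lower, upper)
  vb <- w$fn(zb)
  list(z = zb, value = vb, n_evaluations = w$count(), trace = w$trace())
}

opt_de <- function(f, z0, lower, upper, options = list()) {
  opts <- utils::modifyList(list(pop = max(10 * length(z0), 20), n_gen = 60,
                                 F = 0.8, CR = 0.9), options)
  w <- wrap_counted(f)
  k <- length(z0)
  P <- sweep(sweep(matrix(stats::runif(opts$pop * k), opts$pop, k), 2,
                   upper - lower, `*`), 2, lower, `+`)
  P[1, ] <- z0
  vals <- apply(P, 1, w$fn)
  for (g in seq_len(opts$n_gen)) {
    for (i in seq_len(opts$pop)) {
      idx <- sample(setdiff(seq_len(opts$pop), i), 3)
      mutant <- P[idx[1], ] + opts$F * (P[idx[2], ] - P[idx[3], ])
      cross <- stats::runif(k) < opts$CR
      cross[sample.int(k, 1)] <- TRUE
      trial <- ifelse(cross, mutant, P[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      vt <- w$fn(trial)
      if (vt <= vals[i]) { P[i, ] <- trial; vals[i] <- vt }
    }
  }
  b <- which.min(vals)
  list(z = P[b, ], value = vals[b], n_evaluations = w$count(), trace = w$trace())
}

opt_pso <- function(f, z0, lower, upper, options = list()) {
  opts <- utils::modifyList(list(swarm = max(10, 5 * length(z0)), n_iter = 80,
                                 inertia = 0.7, c1 = 1.5, c2 = 1.5), options)
  w <- wrap_counted(f)
  k <- length(z0)
  X <- sweep(sweep(matrix(stats::runif(opts$swarm * k), opts$swarm, k), 2,
                   upper - lower, `*`), 2, lower, `+`)
  X[1, ] <- z0
  V <- matrix(0, opts$swarm, k)
  vals <- apply(X, 1, w$fn)
  Pb <- X; Pv <- vals
  gb <- X[which.min(vals), ]; gv <- min(vals)
  for (it in seq_len(opts$n_iter)) {
    r1 <- matrix(stats::runif(opts$swarm * k), opts$swarm, k)
    r2 <- matrix(stats::runif(opts$swarm * k), opts$swarm, k)
    V <- opts$inertia * V + opts$c1 * r1 * (Pb - X) +
      opts$c2 * r2 * sweep(-X, 2, -gb, `+`)
    X <- pmin(pmax(X + V, matrix(lower, opts$swarm, k, byrow = TRUE)),
              matrix(upper, opts$swarm, k, byrow = TRUE))
    vals <- apply(X, 1, w$fn)
    imp <- vals < Pv
    Pb[imp, ] <- X[imp, ]; Pv[imp] <- vals[imp]
    if (min(Pv) < gv) { gv <- min(Pv); gb <- Pb[which.min(Pv), ] }
  }
  gb <- polish_local(w$fn, gb, lower, upper)
  gv <- w$fn(gb)
  list(z = gb, value = gv, n_evaluations = w$count(), trace = w$trace())
}

local({
  register_optimizer("lbfgsb", opt_lbfgsb)
  register_optimizer("neldermead", opt_neldermead)
  register_optimizer("anneal", opt_anneal)
  register_optimizer("de", opt_de)
  register_optimizer("pso", opt_pso)
})

#' Minimize an objective in log10 parameter space
#'
#' The search runs over `z = log10(theta)` with box bounds
#' `log10(lower)`/`log10(upper)` (all bounds must be positive). Multiple
#' restarts perturb the start point deterministically from `seed`; the
#' best restart is returned. Results are fully reproducible given the
#' seed.
#'
#' @param objective function of a named parameter vector in linear units
#'   (e.g. from [make_objective()]).
#' @param start named start vector (linear units).
#' @param lower,upper named bound vectors, `0 < lower < upper`.
#' @param optimizer registered optimizer name. Default `"lbfgsb"`.
#' @param n_restarts number of restarts. Default 1.
#' @param seed RNG seed. Default 1.
#' @param options passed to the optimizer.
#' @return a `fit_result`: `theta_hat` (linear units), `score`,
#'   `optimizer_name`, `n_evaluations`, `trace`, `seed`.
#' @export
fit_parameters <- function(objective, start, lower, upper,
                           optimizer = "lbfgsb", n_restarts = 1, seed = 1,
                           options = list()) {
  if (!optimizer %in% list_optimizers()) {
    abort_sbtab(sprintf("unknown optimizer '%s' (registered: %s)", optimizer,
                        paste(list_optimizers(), collapse = ", ")),
                "sbtab_config_error")
  }
  ids <- names(start)
  stopifnot(!is.null(ids), all(ids %in% names(lower)), all(ids %in% names(upper)))
  lo <- lower[ids]; hi <- upper[ids]
  if (any(lo <= 0) || any(lo >= hi)) {
    abort_sbtab("bounds must satisfy 0 < lower < upper (log10 search space)",
                "sbtab_config_error")
  }
  if (!length(ids)) {
    val <- objective(stats::setNames(numeric(), character()))
    return(structure(list(theta_hat = start, score = val,
                          optimizer_name = optimizer, n_evaluations = 1L,
                          trace = val, seed = seed),
                     class = "fit_result"))
  }
  zl <- log10(lo); zu <- log10(hi)
  z0 <- pmin(pmax(log10(start), zl), zu)
  f_z <- function(z) objective(stats::setNames(10^z, ids))
  opt_fun <- get(optimizer, envir = optimizer_registry)
  best <- NULL
  total_evals <- 0L
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    zs <- if (r == 1) z0 else
      pmin(pmax(z0 + stats::rnorm(length(z0), 0, 0.2 * (zu - zl)), zl), zu)
    res <- opt_fun(f_z, zs, zl, zu, options)
    total_evals <- total_evals + res$n_evaluations
    if (is.null(best) || res$value < best$value) best <- res
  }
  theta_hat <- stats::setNames(10^best$z, ids)
  structure(list(theta_hat = theta_hat, score = objective(theta_hat),
                 optimizer_name = optimizer, n_evaluations = total_evals,
                 trace = best$trace, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): F = %.6g after %d evaluation(s)\n",
              x$optimizer_name, x$score, x$n_evaluations))
  print(x$theta_hat)
  invisible(x)
}

#' Parameter-recovery experiment on synthetic data
#'
#' Generates data from `theta_true`, fits starting from a perturbed point
#' and reports the relative error per parameter — the package's
#' self-consistency strategy for validating the estimation machinery.
#'
#' @param model,doc model and document (document must already carry data
#'   tables generated at `theta_true`, e.g. via [fixture_data()]).
#' @param theta_true named true values of the free parameters.
#' @param lower,upper bounds; default `theta_true/100` and
#'   `theta_true*100`.
#' @param start start point; default `theta_true * 10^0.3` (factor-2
#'   perturbation).
#' @param optimizer,seed,options,window,times,settings passed through.
#' @return list with `fit` (a `fit_result`), `relative_error` (named) and
#'   `score`.
#' @export
recover_parameters <- function(model, doc, theta_true,
                               lower = theta_true / 100,
                               upper = theta_true * 100,
                               start = theta_true * 10^0.3,
                               optimizer = "lbfgsb", seed = 1,
                               options = list(), window = c(0, 20),
                               times = NULL, settings = list()) {
  obj <- make_objective(model, doc, free = names(theta_true), window = window,
                        times = times, settings = settings)
  fit <- fit_parameters(obj, start, lower, upper, optimizer = optimizer,
                        seed = seed, options = options)
  rel <- abs(fit$theta_hat - theta_true) / abs(theta_true)
  list(fit = fit, relative_error = rel, score = fit$score)
}
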