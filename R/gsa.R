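# Variance-based global sensitivity analysis. Parameters are sampled from
# a lognormal distribution (log10(theta) ~ N(mu, sigma), mu = log10 of the
# optimum, sigma = 0.1 by default) on a Saltelli design: two base matrices
# A and B plus k column-substituted matrices AB_i, costing N*(k+2) model
# evaluations. First-order indices use the Saltelli/Sobol' estimator
#   S_i  = mean(Y_B * (Y_ABi - Y_A)) / V[Y],
# total-order indices the Jansen estimator
#   S_Ti = mean((Y_A - Y_ABi)^2) / (2 V[Y]).

# Digit-scrambled radical-inverse Halton sequence in the first `dim`
# prime bases. Unscrambled Halton dimensions are strongly correlated
# pairwise (the classic striping pathology), which biases the Saltelli
# pairing of A and B rows; a seeded random permutation of the nonzero
# digits per dimension removes it while keeping the low-discrepancy
# structure.
halton_matrix <- function(n, dim, seed = 1L, skip = 20L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113)
  if (dim > length(primes)) {
    abort_sbtab(sprintf("Halton sequence limited to %d dimensions", length(primes)),
                "sbtab_config_error")
  }
  set.seed(seed)
  idx <- seq_len(n) + skip
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    # digit permutation fixing 0 (so trailing zeros stay zero)
    perm <- c(0L, sample.int(b - 1L))
    i <- idx
    f <- 1
    r <- numeric(n)
    repeat {
      f <- f / b
      r <- r + f * perm[(i %% b) + 1L]
      i <- i %/% b
      if (all(i == 0)) break
    }
    out[, d] <- r
  }
  out
}

#' Build a Saltelli sampling plan
#'
#' Draws the base matrices `A` and `B` (`N x k`) from independent uniform
#' coordinates (low-discrepancy Halton sequence by default, pseudo-random
#' with `sampler = "random"`), maps them through per-parameter quantile
#' transforms, and forms `AB_i` by substituting column `i` of `B` into
#' `A`. Total evaluation rows: `N * (k + 2)`.
#'
#' The default transform is the lognormal prior
#' `log10(theta_i) ~ N(log10(theta_star_i), sigma)`; pass `transform` for
#' other distributions (a function `(u, j) -> value` applied to uniform
#' coordinates of parameter `j`).
#'
#' @param parameter_ids character vector (length k >= 1).
#' @param theta_star named positive vector of distribution centres
#'   (ignored when `transform` is given).
#' @param sigma log10 standard deviation, scalar or per-parameter.
#'   Default 0.1.
#' @param N base sample size (>= 2).
#' @param seed RNG seed (pseudo-random sampler; the Halton sequence is
#'   deterministic by construction).
#' @param sampler `"halton"` or `"random"`.
#' @param transform optional quantile transform `(u, j) -> value`.
#' @return a `gsa_plan` with matrices `A`, `B`, list `AB` and the design
#'   metadata.
#' @export
build_gsa_plan <- function(parameter_ids, theta_star = NULL, sigma = 0.1,
                           N = 1000, seed = 1,
                           sampler = c("halton", "random"),
                           transform = NULL) {
  sampler <- match.arg(sampler)
  N <- as.integer(N)
  k <- length(parameter_ids)
  if (k < 1) abort_sbtab("need at least one parameter", "sbtab_config_error")
  if (N < 2) abort_sbtab("need N >= 2", "sbtab_config_error")
  if (is.null(transform)) {
    if (is.null(theta_star)) abort_sbtab("theta_star required for the lognormal prior",
                                         "sbtab_config_error")
    theta_star <- if (is.null(names(theta_star))) {
      stats::setNames(rep_len(theta_star, k), parameter_ids)
    } else theta_star[parameter_ids]
    if (any(!is.finite(theta_star)) || any(theta_star <= 0)) {
      abort_sbtab("theta_star must be positive (log10 undefined otherwise)",
                  "sbtab_config_error")
    }
    sig <- rep(sigma, length.out = k)
    mu <- log10(theta_star)
    transform <- function(u, j) 10^stats::qnorm(u, mean = mu[j], sd = sig[j])
  }
  U <- if (sampler == "halton") {
    halton_matrix(N, 2 * k, seed = seed)
  } else {
    set.seed(seed)
    matrix(stats::runif(N * 2 * k), N, 2 * k)
  }
  # keep quantile transforms finite
  U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
  A <- matrix(0, N, k); B <- matrix(0, N, k)
  for (j in seq_len(k)) {
    A[, j] <- transform(U[, j], j)
    B[, j] <- transform(U[, k + j], j)
  }
  colnames(A) <- colnames(B) <- parameter_ids
  AB <- lapply(seq_len(k), function(i) { M <- A; M[, i] <- B[, i]; M })
  names(AB) <- parameter_ids
  structure(list(parameter_ids = parameter_ids, N = N, k = k, seed = seed,
                 sampler = sampler, A = A, B = B, AB = AB,
                 n_rows = N * (k + 2L)),
            class = "gsa_plan")
}

#' @export
print.gsa_plan <- function(x, ...) {
  cat(sprintf("gsa_plan: k = %d parameter(s), N = %d, %d evaluation rows (%s sampling)\n",
              x$k, x$N, x$n_rows, x$sampler))
  invisible(x)
}

#' Evaluate the model outputs over a Saltelli plan
#'
#' Applies `output_fn` (one parameter vector -> numeric vector of scalar
#' outputs, e.g. the per-experiment estimation scores) to every row of
#' `A`, `B` and each `AB_i`, in that deterministic order. Failed
#' evaluations are recorded as missing; more than `max_failure_rate`
#' failures abort with a report.
#'
#' @param plan a `gsa_plan`.
#' @param output_fn function of a named parameter vector.
#' @param max_failure_rate abort threshold. Default 0.01.
#' @return list with matrices `Y_A`, `Y_B` (N x outputs) and list `Y_AB`.
#' @export
evaluate_gsa <- function(plan, output_fn, max_failure_rate = 0.01) {
  stopifnot(inherits(plan, "gsa_plan"))
  eval_matrix <- function(M) {
    rows <- lapply(seq_len(nrow(M)), function(i) {
      theta <- stats::setNames(M[i, ], plan$parameter_ids)
      tryCatch({
        r <- output_fn(theta)
        stopifnot(is.numeric(r))
        r + 0  # force double, keep names
      }, error = function(e) NA_real_)
    })
    lens <- vapply(rows, length, integer(1))
    len <- max(lens)
    nm <- names(rows[[which.max(lens)]])
    out <- matrix(NA_real_, length(rows), len)
    for (i in seq_along(rows)) {
      r <- rows[[i]]; length(r) <- len
      out[i, ] <- r
    }
    colnames(out) <- nm
    out
  }
  Y_A <- eval_matrix(plan$A)
  Y_B <- eval_matrix(plan$B)
  Y_AB <- lapply(plan$AB, eval_matrix)
  n_fail <- sum(is.na(Y_A)) + sum(is.na(Y_B)) + sum(vapply(Y_AB, function(m) sum(is.na(m)), numeric(1)))
  n_tot <- length(Y_A) + length(Y_B) + sum(vapply(Y_AB, length, numeric(1)))
  if (n_fail / n_tot > max_failure_rate) {
    abort_sbtab(sprintf("GSA aborted: %d of %d evaluations failed (> %.1f%%)",
                        n_fail, n_tot, 100 * max_failure_rate),
                "sbtab_simulation_error")
  }
  list(Y_A = Y_A, Y_B = Y_B, Y_AB = Y_AB)
}

#' Sobol first-order and total-order indices from Saltelli evaluations
#'
#' First-order indices `S_i` (fraction of output variance explained by
#' parameter i alone) use the Saltelli estimator
#' `mean(Y_B (Y_ABi - Y_A)) / V`; total-order indices `S_Ti` (fraction
#' involving i in any combination) use the Jansen estimator
#' `mean((Y_A - Y_ABi)^2) / (2V)`. `V` is the variance of the pooled
#' `A` and `B` evaluations. Small negative estimates are reported raw —
#' the Monte-Carlo half-widths `eps` (bootstrap over rows, 200 resamples,
#' 95%) give the context; nothing is clamped. Zero-variance outputs are
#' flagged as undefined rather than silently NaN.
#'
#' @param evals output of [evaluate_gsa()] (or a compatible list).
#' @param n_boot bootstrap resamples for the Monte-Carlo tolerance.
#'   Default 200. Set 0 to skip.
#' @param seed bootstrap RNG seed. Default 1.
#' @return a `gsa_result`: matrices `S_i`, `S_Ti` (parameters x outputs),
#'   `eps_S_i`, `eps_S_Ti`, vector `V`, logical `defined`,
#'   `n_evaluations`.
#' @export
sobol_indices <- function(evals, n_boot = 200, seed = 1) {
  Y_A <- as.matrix(evals$Y_A); Y_B <- as.matrix(evals$Y_B)
  Y_AB <- lapply(evals$Y_AB, as.matrix)
  k <- length(Y_AB); m <- ncol(Y_A); N <- nrow(Y_A)
  pnames <- names(Y_AB) %||% paste0("p", seq_len(k))
  onames <- colnames(Y_A) %||% paste0("y", seq_len(m))

  index_once <- function(rows) {
    V <- numeric(m); S <- matrix(NA_real_, k, m); ST <- matrix(NA_real_, k, m)
    for (j in seq_len(m)) {
      ya <- Y_A[rows, j]; yb <- Y_B[rows, j]
      V[j] <- stats::var(c(ya, yb))
      if (!is.finite(V[j]) || V[j] <= 0) next
      for (i in seq_len(k)) {
        yab <- Y_AB[[i]][rows, j]
        S[i, j] <- mean(yb * (yab - ya), na.rm = TRUE) / V[j]
        ST[i, j] <- mean((ya - yab)^2, na.rm = TRUE) / (2 * V[j])
      }
    }
    list(V = V, S = S, ST = ST)
  }

  full <- index_once(seq_len(N))
  defined <- is.finite(full$V) & full$V > 0
  eps_S <- matrix(NA_real_, k, m); eps_ST <- matrix(NA_real_, k, m)
  if (n_boot > 0) {
    set.seed(seed)
    bs_S <- array(NA_real_, c(k, m, n_boot))
    bs_ST <- array(NA_real_, c(k, m, n_boot))
    for (b in seq_len(n_boot)) {
      rows <- sample.int(N, N, replace = TRUE)
      r <- index_once(rows)
      bs_S[, , b] <- r$S; bs_ST[, , b] <- r$ST
    }
    for (i in seq_len(k)) for (j in seq_len(m)) {
      qs <- stats::quantile(bs_S[i, j, ], c(0.025, 0.975), na.rm = TRUE)
      eps_S[i, j] <- diff(qs) / 2
      qs <- stats::quantile(bs_ST[i, j, ], c(0.025, 0.975), na.rm = TRUE)
      eps_ST[i, j] <- diff(qs) / 2
    }
  }
  dn <- list(pnames, onames)
  structure(list(S_i = structure(full$S, dimnames = dn),
                 S_Ti = structure(full$ST, dimnames = dn),
                 eps_S_i = structure(eps_S, dimnames = dn),
                 eps_S_Ti = structure(eps_ST, dimnames = dn),
                 V = stats::setNames(full$V, onames),
                 defined = stats::setNames(defined, onames),
                 n_evaluations = N * (k + 2L), seed = seed),
            class = "gsa_result")
}

#' @export
print.gsa_result <- function(x, ...) {
  cat(sprintf("gsa_result: %d parameter(s) x %d output(s), %d evaluations\n",
              nrow(x$S_i), ncol(x$S_i), x$n_evaluations))
  if (any(!x$defined)) {
    cat("  zero-variance output(s):", paste(names(x$defined)[!x$defined],
                                            collapse = ", "), "\n")
  }
  cat("first-order S_i:\n"); print(round(x$S_i, 4))
  cat("total-order S_Ti:\n"); print(round(x$S_Ti, 4))
  invisible(x)
}

#' Stacked-bar report of sensitivity indices
#'
#' One panel per index kind (first-order and total-order), one stacked
#' bar per output (e.g. per experiment score), segments per parameter —
#' plus a long-format table of all indices.
#'
#' @param result a `gsa_result`.
#' @param tsv_path optional path: writes the table as TSV.
#' @return list with `plot` (a ggplot object) and `table` (data frame).
#' @export
gsa_report <- function(result, tsv_path = NULL) {
  stopifnot(inherits(result, "gsa_result"))
  if (!nrow(result$S_i) || !ncol(result$S_i)) {
    abort_sbtab("nothing to plot: empty GSA result", "sbtab_config_error")
  }
  long <- do.call(rbind, lapply(c("S_i", "S_Ti"), function(kind) {
    M <- result[[kind]]
    data.frame(kind = kind,
               parameter = rep(rownames(M), times = ncol(M)),
               output = rep(colnames(M), each = nrow(M)),
               index = as.vector(M),
               eps = as.vector(result[[paste0("eps_", kind)]]),
               stringsAsFactors = FALSE)
  }))
  long$output <- factor(long$output, levels = colnames(result$S_i))
  long$parameter <- factor(long$parameter, levels = rownames(result$S_i))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$output, y = .data$index,
                                          fill = .data$parameter)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~kind, nrow = 1) +
    ggplot2::labs(x = NULL, y = "sensitivity index", fill = "parameter") +
    ggplot2::theme_minimal()
  if (!is.null(tsv_path)) {
    utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(plot = p, table = long)
}
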