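# Model pre-processing from the stoichiometric matrix: conserved moieties
# (integer left null vectors of S) and Wegscheider thermodynamic
# constraints (integer right null vectors of S restricted to reversible
# reactions). All computations use exact rational elimination with
# cleared denominators, never floating SVD, so the emitted constraints are
# exact combinatorial objects with a deterministic normal form
# (gcd-reduced, first nonzero coefficient positive, lexicographic order).

# Exact rational reduced row-echelon form. Entries are kept as num/den
# pairs of doubles holding exact (small) integers.
rational_rref <- function(M) {
  n <- nrow(M); m <- ncol(M)
  num <- matrix(as.numeric(M), n, m)
  den <- matrix(1, n, m)
  normalize <- function(i, j) {
    g <- gcd2(num[i, j], den[i, j])
    if (g > 1) { num[i, j] <<- num[i, j] / g; den[i, j] <<- den[i, j] / g }
    if (den[i, j] < 0) { num[i, j] <<- -num[i, j]; den[i, j] <<- -den[i, j] }
  }
  pivots <- integer()
  row <- 1L
  for (col in seq_len(m)) {
    if (row > n) break
    pr <- which(num[row:n, col] != 0)
    if (!length(pr)) next
    pr <- pr[1] + row - 1L
    if (pr != row) {
      tmp <- num[row, ]; num[row, ] <- num[pr, ]; num[pr, ] <- tmp
      tmp <- den[row, ]; den[row, ] <- den[pr, ]; den[pr, ] <- tmp
    }
    # scale pivot row to 1 at (row, col)
    pn <- num[row, col]; pd <- den[row, col]
    for (j in seq_len(m)) {
      num[row, j] <- num[row, j] * pd
      den[row, j] <- den[row, j] * pn
      normalize(row, j)
    }
    # clear the column everywhere else
    for (i in seq_len(n)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      for (j in seq_len(m)) {
        # a_ij <- a_ij - f * row_j
        an <- num[i, j] * fd * den[row, j] - fn * num[row, j] * den[i, j]
        ad <- den[i, j] * fd * den[row, j]
        num[i, j] <- an; den[i, j] <- ad
        normalize(i, j)
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots)
}

#' Integer basis of the null space of an integer matrix
#'
#' Computes `{x : M x = 0}` by exact rational row reduction, clears
#' denominators and normalizes each basis vector (gcd of nonzero entries
#' 1, first nonzero entry positive). The basis is deterministic: one
#' vector per free column, in column order.
#'
#' @param M integer-valued matrix.
#' @return matrix with one basis vector per column (ncol = nullity);
#'   a zero-column matrix when the null space is trivial.
#' @export
integer_nullspace <- function(M) {
  M <- as.matrix(M)
  m <- ncol(M)
  if (!nrow(M) || !m) return(matrix(numeric(), max(m, 0), 0))
  r <- rational_rref(M)
  pivots <- r$pivots
  free <- setdiff(seq_len(m), pivots)
  out <- matrix(0, m, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    x_num <- numeric(m); x_den <- rep(1, m)
    x_num[f] <- 1
    for (i in seq_along(pivots)) {
      # pivot row i: x[pivots[i]] = -R[i, f] * x[f]
      x_num[pivots[i]] <- -r$num[i, f]
      x_den[pivots[i]] <- r$den[i, f]
    }
    lcm_den <- 1
    for (d in x_den) lcm_den <- lcm_den * d / gcd2(lcm_den, d)
    v <- x_num * (lcm_den / x_den)
    g <- gcd_vec(v)
    if (g > 1) v <- v / g
    fz <- which(v != 0)[1]
    if (!is.na(fz) && v[fz] < 0) v <- -v
    out[, k] <- v
  }
  rownames(out) <- colnames(M)
  out
}

law_expression <- function(coef, ids) {
  nz <- which(coef != 0)
  terms <- vapply(nz, function(i) {
    c_i <- coef[i]
    if (c_i == 1) ids[i]
    else if (c_i == -1) paste0("-", ids[i])
    else paste0(c_i, "*", ids[i])
  }, character(1))
  paste(paste(terms, collapse = " + "), "= const")
}

#' Conserved moieties of a stoichiometric matrix
#'
#' Returns an integer basis of the left null space of `S` (vectors `c`
#' with `c' S = 0`), each one a conserved moiety: the weighted total
#' concentration it defines is constant along every trajectory. The count
#' equals `n_species - rank(S)`.
#'
#' @param S integer stoichiometric matrix (species x reactions), rownames
#'   used as species ids when present.
#' @return list of conservation laws; each has `coefficients` (integer
#'   vector over species) and `total_expression` (human-readable).
#' @export
conservation_laws <- function(S) {
  S <- as.matrix(S)
  ids <- rownames(S) %||% paste0("x", seq_len(nrow(S)))
  B <- integer_nullspace(t(S))
  lapply(seq_len(ncol(B)), function(k) {
    coef <- B[, k]
    names(coef) <- ids
    list(coefficients = coef, total_expression = law_expression(coef, ids))
  })
}

kf_kr_names <- function(network, j) {
  rid <- network$reactions[[j]]$id
  cand_f <- paste0("kf_", rid); cand_r <- paste0("kr_", rid)
  par_ids <- network$parameters$id
  syms <- all.vars(network$reactions[[j]]$flux)
  kf <- if (cand_f %in% par_ids) cand_f else {
    hits <- grep("^kf", intersect(syms, par_ids), value = TRUE)
    if (length(hits)) hits[1] else cand_f
  }
  kr <- if (cand_r %in% par_ids) cand_r else {
    hits <- grep("^kr", intersect(syms, par_ids), value = TRUE)
    if (length(hits)) hits[1] else cand_r
  }
  c(kf = kf, kr = kr)
}

#' Wegscheider thermodynamic constraints of a reaction network
#'
#' Each reversible cycle of the network (integer right null vector of `S`
#' restricted to the columns of reversible reactions) imposes, at
#' thermodynamic equilibrium, a multiplicative condition on the forward
#' and backward rate constants: `prod_j (kf_j/kr_j)^{c_j} = 1`.
#' Irreversible reactions never enter a cycle. These constraints should be
#' re-examined after every structural model change.
#'
#' @param network a `reaction_network`.
#' @return list of constraints; each has `cycle_coefficients` (named
#'   integer vector over reversible reaction ids), `kf`/`kr` parameter
#'   name vectors, and `constraint_expression`.
#' @export
thermodynamic_constraints <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  rev_idx <- which(vapply(network$reactions, `[[`, logical(1), "reversible"))
  if (!length(rev_idx)) return(list())
  S_rev <- network$S[, rev_idx, drop = FALSE]
  B <- integer_nullspace(S_rev)
  rids <- vapply(network$reactions[rev_idx], `[[`, character(1), "id")
  lapply(seq_len(ncol(B)), function(k) {
    coef <- B[, k]
    names(coef) <- rids
    nz <- which(coef != 0)
    pairs <- t(vapply(rev_idx[nz], function(j) kf_kr_names(network, j),
                      character(2)))
    expr_terms <- vapply(seq_along(nz), function(i) {
      base <- sprintf("(%s/%s)", pairs[i, 1], pairs[i, 2])
      if (coef[nz[i]] == 1) base else sprintf("%s^%d", base, as.integer(coef[nz[i]]))
    }, character(1))
    list(cycle_coefficients = coef,
         kf = stats::setNames(pairs[, 1], rids[nz]),
         kr = stats::setNames(pairs[, 2], rids[nz]),
         constraint_expression = paste(paste(expr_terms, collapse = " * "), "= 1"))
  })
}

#' Check rate constants against thermodynamic constraints
#'
#' For each Wegscheider constraint evaluates the log residual
#' `sum_j c_j (log kf_j - log kr_j)`; a constraint passes when the
#' absolute residual is at most `tol`.
#'
#' @param constraints output of [thermodynamic_constraints()].
#' @param parameter_values named numeric vector holding every `kf`/`kr`
#'   named in the constraints (all values must be positive).
#' @param tol residual tolerance on the log scale. Default `1e-9`.
#' @return data frame with one row per constraint: `constraint`,
#'   `residual` (log scale) and `pass`.
#' @export
check_parameter_consistency <- function(constraints, parameter_values, tol = 1e-9) {
  if (!length(constraints)) {
    return(data.frame(constraint = character(), residual = numeric(),
                      pass = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(constraints, function(con) {
    need <- c(con$kf, con$kr)
    missing <- setdiff(need, names(parameter_values))
    if (length(missing)) {
      abort_sbtab(sprintf("missing rate constant value(s): %s",
                          paste(missing, collapse = ", ")),
                  "sbtab_validation_error")
    }
    vals <- parameter_values[need]
    if (any(vals <= 0)) {
      abort_sbtab(sprintf("non-positive rate constant value(s): %s",
                          paste(need[vals <= 0], collapse = ", ")),
                  "sbtab_validation_error")
    }
    coef <- con$cycle_coefficients
    nz <- which(coef != 0)
    resid <- sum(coef[nz] * (log(parameter_values[con$kf]) -
                               log(parameter_values[con$kr])))
    data.frame(constraint = con$constraint_expression, residual = resid,
               pass = abs(resid) <= tol, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
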