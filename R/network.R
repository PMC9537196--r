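# Reaction-network compilation: reaction-scheme and rate-law parsing,
# stoichiometric matrix assembly, and ODE right-hand-side construction
# x'(t) = S v(x, theta, u(t)).

#' Parse a reaction-scheme string
#'
#' Parses schemes such as `"CaM + Ca <=> CaM_Ca2"` or `"2 A => B"` into
#' reactant and product multisets with integer stoichiometries. Spaced
#' arrow variants (`"< = >"`) as they appear in spreadsheet exports are
#' tolerated. The arrow suggests reversibility but the authoritative flag
#' in a Reaction table is the `!IsReversible` column.
#'
#' @param scheme reaction-scheme string with exactly one arrow token
#'   (`<=>` or `=>`).
#' @return list with `reactants` and `products` (named integer vectors,
#'   side order preserved) and `reversible` (from the arrow).
#' @export
parse_reaction_formula <- function(scheme) {
  raw <- as.character(scheme)
  s <- gsub("<\\s*=\\s*>", "<=>", raw)
  s <- gsub("(^|[^<=])=\\s*>", "\\1=>", s)
  rev_arrow <- grepl("<=>", s, fixed = TRUE)
  arrow <- if (rev_arrow) "<=>" else "=>"
  parts <- strsplit(s, arrow, fixed = TRUE)[[1]]
  if (length(parts) != 2 || grepl(arrow, parts[2], fixed = TRUE)) {
    abort_sbtab(sprintf("malformed reaction scheme '%s': expected exactly one arrow", raw),
                "sbtab_parse_error")
  }
  parse_side <- function(txt, side) {
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    if (!length(terms) || any(!nzchar(terms))) {
      abort_sbtab(sprintf("malformed reaction scheme '%s': empty %s side at position %d",
                          raw, side, regexpr(arrow, s, fixed = TRUE)[1]),
                  "sbtab_parse_error")
    }
    out <- integer()
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9]+)\\s*\\*?\\s*([A-Za-z_][A-Za-z0-9_]*)$", tm))[[1]]
      if (length(m)) {
        coef <- as.integer(m[2]); sp <- m[3]
      } else if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", tm)) {
        coef <- 1L; sp <- tm
      } else {
        abort_sbtab(sprintf("malformed term '%s' in reaction scheme '%s'", tm, raw),
                    "sbtab_parse_error")
      }
      if (coef < 1L) {
        abort_sbtab(sprintf("stoichiometric coefficient must be >= 1 in '%s'", tm),
                    "sbtab_parse_error")
      }
      out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + coef
    }
    out
  }
  list(reactants = parse_side(parts[1], "reactant"),
       products = parse_side(parts[2], "product"),
       reversible = rev_arrow)
}

allowed_call_fns <- c("+", "-", "*", "/", "^", "(", "exp", "log", "pow")

# Recursively verify an expression tree uses only the permitted grammar.
check_expr_tree <- function(e, symbols, context = "expression") {
  if (is.numeric(e) || is.integer(e)) return(invisible(TRUE))
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!nm %in% symbols) {
      abort_sbtab(sprintf("%s references undeclared symbol '%s'", context, nm),
                  "sbtab_validation_error")
    }
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% allowed_call_fns) {
      abort_sbtab(sprintf("%s uses unsupported function '%s'", context, fn),
                  "sbtab_validation_error")
    }
    for (i in seq_along(e)[-1]) check_expr_tree(e[[i]], symbols, context)
    return(invisible(TRUE))
  }
  abort_sbtab(sprintf("%s contains an unsupported element", context),
              "sbtab_validation_error")
}

#' Parse a kinetic-law or assignment expression
#'
#' Parses an arithmetic expression over declared identifiers (parameters,
#' compounds, compartments, inputs, assignment targets) and the time symbol
#' (`t` or `time`), with operators `+ - * / ^`, parentheses and the
#' functions `exp`, `log` and `pow` (rewritten to `^`). Evaluation of the
#' returned expression is deterministic.
#'
#' @param expr expression string, e.g. `"kf_R5*CaM*Ca-kr_R5*CaM_Ca2"`.
#' @param symbols character vector of resolvable symbol names.
#' @return an R language object (expression tree).
#' @export
parse_rate_expression <- function(expr, symbols) {
  txt <- as.character(expr)
  if (!nzchar(trimws(txt))) abort_sbtab("empty expression", "sbtab_parse_error")
  lang <- tryCatch(str2lang(txt), error = function(e) {
    abort_sbtab(sprintf("cannot parse expression '%s': %s", txt, conditionMessage(e)),
                "sbtab_parse_error")
  })
  lang <- rewrite_pow(lang)
  check_expr_tree(lang, symbols, context = sprintf("expression '%s'", txt))
  lang
}

rewrite_pow <- function(e) {
  if (is.call(e)) {
    if (identical(as.character(e[[1]]), "pow") && length(e) == 3) {
      e <- call("^", rewrite_pow(e[[2]]), rewrite_pow(e[[3]]))
    } else {
      for (i in seq_along(e)[-1]) e[[i]] <- rewrite_pow(e[[i]])
    }
  }
  e
}

as_logical_cell <- function(x) {
  v <- toupper(trimws(as.character(x)))
  out <- v %in% c("TRUE", "T", "1", "YES")
  out
}

first_col <- function(df, candidates, default = NULL) {
  for (cn in candidates) if (cn %in% names(df)) return(df[[cn]])
  if (is.null(default)) return(NULL)
  rep(default, nrow(df))
}

# Topological sort of assignment expressions; errors on cycles.
order_assignments <- function(targets, exprs) {
  n <- length(targets)
  if (!n) return(integer())
  deps <- lapply(exprs, function(e) intersect(all.vars(e), targets))
  order <- integer(); placed <- rep(FALSE, n); names(placed) <- targets
  repeat {
    progress <- FALSE
    for (i in seq_len(n)) {
      if (placed[i]) next
      if (all(placed[deps[[i]]])) {
        order <- c(order, i); placed[i] <- TRUE; progress <- TRUE
      }
    }
    if (all(placed)) break
    if (!progress) {
      abort_sbtab(sprintf("cyclic assignment dependency among: %s",
                          paste(targets[!placed], collapse = ", ")),
                  "sbtab_validation_error")
    }
  }
  order
}

#' Build a reaction network from an SBtab document
#'
#' Assembles the stoichiometric matrix `S` (one row per compound, one
#' column per reaction; entries are product minus reactant counts), parses
#' every kinetic law and assignment expression, and collects species,
#' parameters, inputs and outputs in document order.
#'
#' @param doc a validated `sbtab_document`.
#' @return an object of class `reaction_network`.
#' @export
build_network <- function(doc) {
  stopifnot(inherits(doc, "sbtab_document"))
  cptab <- doc$tables[["Compartment"]]
  if (is.null(cptab) || !nrow(cptab)) {
    compartments <- data.frame(id = "cell", size = 1, stringsAsFactors = FALSE)
  } else {
    compartments <- data.frame(
      id = as.character(cptab[["!ID"]]),
      size = sbtab_numeric(first_col(cptab, c("!Size", "!Volume"), 1)),
      stringsAsFactors = FALSE)
    compartments$size[is.na(compartments$size)] <- 1
  }

  cmp <- doc$tables[["Compound"]]
  if (is.null(cmp) || !nrow(cmp)) abort_sbtab("document has no Compound table rows",
                                              "sbtab_validation_error")
  species <- data.frame(
    id = as.character(cmp[["!ID"]]),
    compartment = {
      loc <- first_col(cmp, "!Location")
      if (is.null(loc)) rep(compartments$id[1], nrow(cmp)) else {
        loc <- as.character(loc); loc[!nzchar(loc) | is.na(loc)] <- compartments$id[1]; loc
      }
    },
    initial = {
      iv <- sbtab_numeric(first_col(cmp, c("!InitialValue", "!InitialConcentration"), 0))
      iv[is.na(iv)] <- 0; iv
    },
    stringsAsFactors = FALSE)

  prm <- doc$tables[["Parameter"]]
  parameters <- if (is.null(prm) || !nrow(prm)) {
    data.frame(id = character(), value = numeric(), unit = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      id = as.character(prm[["!ID"]]),
      value = {
        v <- sbtab_numeric(first_col(prm, c("!DefaultValue", "!Value"), NA))
        v[is.na(v)] <- 1; v
      },
      unit = as.character(first_col(prm, "!Unit", "")),
      stringsAsFactors = FALSE)
  }

  intab <- doc$tables[["Input"]]
  inputs <- if (is.null(intab) || !nrow(intab)) character() else as.character(intab[["!ID"]])
  input_defaults <- if (length(inputs)) {
    dv <- sbtab_numeric(first_col(intab, "!DefaultValue", 0))
    dv[is.na(dv)] <- 0
    stats::setNames(dv, inputs)
  } else stats::setNames(numeric(), character())

  extab <- doc$tables[["Expression"]]
  assign_targets <- if (is.null(extab) || !nrow(extab)) character() else
    as.character(extab[["!ID"]])

  known <- c(species$id, parameters$id, compartments$id, inputs, assign_targets,
             "t", "time")

  assignments <- list()
  if (length(assign_targets)) {
    exprs <- lapply(seq_along(assign_targets), function(i) {
      parse_rate_expression(as.character(extab[["!Formula"]][i]), known)
    })
    ord <- order_assignments(assign_targets, exprs)
    assignments <- lapply(ord, function(i) list(target = assign_targets[i],
                                                expr = exprs[[i]]))
  }

  rxtab <- doc$tables[["Reaction"]]
  if (is.null(rxtab) || !nrow(rxtab)) abort_sbtab("document has no Reaction table rows",
                                                  "sbtab_validation_error")
  nr <- nrow(rxtab)
  rid <- as.character(rxtab[["!ID"]])
  S <- matrix(0L, nrow = nrow(species), ncol = nr,
              dimnames = list(species$id, rid))
  reactions <- vector("list", nr)
  for (j in seq_len(nr)) {
    scheme <- parse_reaction_formula(as.character(rxtab[["!ReactionFormula"]][j]))
    for (sp in names(scheme$reactants)) {
      if (!sp %in% species$id)
        abort_sbtab(sprintf("reaction '%s': undeclared species '%s'", rid[j], sp),
                    "sbtab_validation_error")
      S[sp, j] <- S[sp, j] - scheme$reactants[[sp]]
    }
    for (sp in names(scheme$products)) {
      if (!sp %in% species$id)
        abort_sbtab(sprintf("reaction '%s': undeclared species '%s'", rid[j], sp),
                    "sbtab_validation_error")
      S[sp, j] <- S[sp, j] + scheme$products[[sp]]
    }
    revcol <- first_col(rxtab, "!IsReversible")
    reversible <- if (is.null(revcol)) scheme$reversible else as_logical_cell(revcol[j])
    loc <- as.character(first_col(rxtab, "!Location", compartments$id[1])[j])
    if (!nzchar(loc) || is.na(loc)) loc <- compartments$id[1]
    flux <- parse_rate_expression(as.character(rxtab[["!KineticLaw"]][j]), known)
    reactions[[j]] <- list(id = rid[j], reversible = reversible,
                           location = loc, flux = flux,
                           reactants = scheme$reactants, products = scheme$products)
  }

  outtab <- doc$tables[["Output"]]
  outputs <- list()
  if (!is.null(outtab) && nrow(outtab)) {
    for (i in seq_len(nrow(outtab))) {
      outputs[[i]] <- list(id = as.character(outtab[["!ID"]][i]),
                           expr = parse_rate_expression(
                             as.character(outtab[["!Formula"]][i]), known))
    }
  }

  ids_all <- c(species$id, rid, parameters$id)
  if (anyDuplicated(ids_all)) {
    abort_sbtab(sprintf("species, reaction and parameter ids must be disjoint; duplicated: %s",
                        paste(unique(ids_all[duplicated(ids_all)]), collapse = ", ")),
                "sbtab_validation_error")
  }

  structure(list(species = species, reactions = reactions, S = S,
                 assignments = assignments, inputs = inputs,
                 input_defaults = input_defaults,
                 parameters = parameters, compartments = compartments,
                 outputs = outputs),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("reaction_network: %d species, %d reactions, %d parameters, %d input(s)\n",
              nrow(x$species), length(x$reactions), nrow(x$parameters),
              length(x$inputs)))
  invisible(x)
}

# Environment holding constants shared by every rhs evaluation.
base_eval_env <- function(network) {
  env <- new.env(parent = baseenv())
  for (i in seq_len(nrow(network$compartments))) {
    assign(network$compartments$id[i], network$compartments$size[i], envir = env)
  }
  env
}

#' Compile a reaction network into an evaluable ODE model
#'
#' Produces the right-hand side `rhs(t, x, theta, u)` = `S v(x, theta,
#' u(t))` where `v` stacks the reaction flux expressions, plus the
#' output map from the Output table. With `reduce_conservation = TRUE`
#' one state per independent conserved moiety is removed from the ODE
#' state and reconstructed algebraically from the conserved total; the
#' eliminated species is the one with the largest index within each
#' moiety, so output ordering is reproducible.
#'
#' Cross-compartment reactions are interpreted in concentration units of
#' the reaction's Location compartment; species residing in another
#' compartment receive the flux scaled by the volume ratio
#' V(reaction)/V(species).
#'
#' @param network a `reaction_network`.
#' @param reduce_conservation replace conserved states by algebraic
#'   expressions. Default `FALSE`.
#' @return an object of class `compiled_model` with elements `rhs`,
#'   `output_map`, `state_ids`, `output_ids` and reduction metadata.
#' @export
compile_model <- function(network, reduce_conservation = FALSE) {
  stopifnot(inherits(network, "reaction_network"))
  S <- network$S
  n_sp <- nrow(S); n_rx <- ncol(S)
  sp_ids <- network$species$id

  # volume-ratio scaling of fluxes into species rows
  vol <- stats::setNames(network$compartments$size, network$compartments$id)
  sp_vol <- vol[network$species$compartment]
  rx_vol <- vapply(network$reactions, function(r) vol[[r$location]], numeric(1))
  Ssc <- S * outer(1 / sp_vol, rx_vol)

  flux_exprs <- lapply(network$reactions, `[[`, "flux")
  assignments <- network$assignments
  out_ids <- vapply(network$outputs, `[[`, character(1), "id")
  out_exprs <- lapply(network$outputs, `[[`, "expr")
  par_ids <- network$parameters$id
  inputs <- network$inputs
  const_env <- base_eval_env(network)

  # One generated evaluator for fluxes and outputs: binding every symbol
  # through generated code is far cheaper than per-call environment
  # assignment, and keeps evaluation deterministic.
  deparse1l <- function(e) paste(deparse(e), collapse = " ")
  bind_lines <- c(
    "time <- t",
    sprintf("%s <- x_full[[%d]]", sp_ids, seq_len(n_sp)),
    if (length(par_ids)) sprintf("%s <- theta[[%d]]", par_ids, seq_along(par_ids)),
    if (length(inputs)) sprintf("%s <- u_vals[[%d]]", inputs, seq_along(inputs)),
    vapply(assignments, function(a) {
      sprintf("%s <- %s", a$target, deparse1l(a$expr))
    }, character(1)))
  flux_body <- if (length(flux_exprs)) {
    sprintf("c(%s)", paste(vapply(flux_exprs, deparse1l, character(1)),
                           collapse = ", "))
  } else "numeric(0)"
  out_body <- if (length(out_exprs)) {
    sprintf("c(%s)", paste(vapply(out_exprs, deparse1l, character(1)),
                           collapse = ", "))
  } else "numeric(0)"
  eval_all <- eval(parse(text = paste(
    c("function(t, x_full, theta, u_vals) {", bind_lines,
      sprintf("list(v = %s, y = %s)", flux_body, out_body), "}"),
    collapse = "\n"))[[1]], envir = const_env)

  reduction <- NULL
  if (reduce_conservation) {
    laws <- conservation_laws(S)
    if (length(laws)) {
      C <- do.call(rbind, lapply(laws, `[[`, "coefficients"))
      elim <- integer(0)
      keep_rows <- logical(nrow(C))
      for (r in seq_len(nrow(C))) {
        cand <- which(C[r, ] != 0)
        cand <- setdiff(cand, elim)
        if (!length(cand)) next  # dependent with already-eliminated set
        elim <- c(elim, max(cand))
        keep_rows[r] <- TRUE
      }
      if (length(elim)) {
        Ck <- C[keep_rows, , drop = FALSE] * 1.0
        # make each row reference only its own eliminated species, so the
        # algebraic reconstruction is explicit (no triangular solve needed)
        for (r in seq_along(elim)) {
          piv <- Ck[r, elim[r]]
          for (r2 in seq_along(elim)) {
            if (r2 != r && Ck[r2, elim[r]] != 0) {
              Ck[r2, ] <- Ck[r2, ] - Ck[r2, elim[r]] / piv * Ck[r, ]
            }
          }
        }
        reduction <- list(C = Ck, elim = elim)
      }
    }
  }

  state_idx <- if (is.null(reduction)) seq_len(n_sp) else
    setdiff(seq_len(n_sp), reduction$elim)
  state_ids <- sp_ids[state_idx]

  reconstruct <- function(x_state, totals) {
    x_full <- numeric(n_sp)
    x_full[state_idx] <- x_state
    if (!is.null(reduction)) {
      for (r in seq_along(reduction$elim)) {
        i <- reduction$elim[r]
        cr <- reduction$C[r, ]
        x_full[i] <- (totals[r] - sum(cr[-i] * x_full[-i])) / cr[i]
      }
    }
    x_full
  }

  totals_of <- function(x_full0) {
    if (is.null(reduction)) numeric(0) else
      as.numeric(reduction$C %*% x_full0)
  }

  rhs <- function(t, x_state, theta, u_vals = NULL, totals = NULL) {
    x_full <- reconstruct(x_state, totals)
    v <- eval_all(t, x_full, theta, u_vals)$v
    dx <- as.numeric(Ssc %*% v)
    dx[state_idx]
  }

  fluxes <- function(t, x_full, theta, u_vals = NULL) {
    eval_all(t, x_full, theta, u_vals)$v
  }

  output_map <- function(t, x_state, theta, u_vals = NULL, totals = NULL) {
    x_full <- reconstruct(x_state, totals)
    eval_all(t, x_full, theta, u_vals)$y
  }

  structure(list(rhs = rhs, output_map = output_map, fluxes = fluxes,
                 reconstruct = reconstruct, totals_of = totals_of,
                 state_ids = state_ids, state_idx = state_idx,
                 output_ids = out_ids, network = network,
                 reduction = reduction),
            class = "compiled_model")
}

#' @export
print.compiled_model <- function(x, ...) {
  cat(sprintf("compiled_model: %d ODE state(s)%s, %d output(s)\n",
              length(x$state_ids),
              if (!is.null(x$reduction))
                sprintf(" (%d conserved state(s) eliminated)", length(x$reduction$elim))
              else "",
              length(x$output_ids)))
  invisible(x)
}

# Default parameter vector (document order) of a network.
default_theta <- function(network) {
  stats::setNames(network$parameters$value, network$parameters$id)
}
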