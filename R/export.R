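# Model exporters: SBML Level 2 Version 4, NEURON NMODL (MOD) and VFGEN
# vector-field XML. All writers are byte-stable for identical inputs.

# ---- expression rendering ---------------------------------------------

# R language object -> plain infix string (for MOD / VFGEN).
expr_to_infix <- function(e) {
  if (is.numeric(e)) return(format(e, digits = 15, scientific = FALSE, trim = TRUE))
  if (is.symbol(e)) return(as.character(e))
  fn <- as.character(e[[1]])
  if (fn == "(") return(paste0("(", expr_to_infix(e[[2]]), ")"))
  if (fn %in% c("+", "-", "*", "/", "^")) {
    if (length(e) == 2) return(paste0("-", maybe_paren(e[[2]], fn, TRUE)))
    return(paste0(maybe_paren(e[[2]], fn, FALSE), fn, maybe_paren(e[[3]], fn, TRUE)))
  }
  paste0(fn, "(", paste(vapply(as.list(e)[-1], expr_to_infix, character(1)),
                        collapse = ","), ")")
}

op_prec <- c("+" = 1, "-" = 1, "*" = 2, "/" = 2, "^" = 3)

maybe_paren <- function(e, parent_op, rhs) {
  s <- expr_to_infix(e)
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (fn %in% names(op_prec)) {
      pp <- op_prec[[parent_op]]; cp <- op_prec[[fn]]
      need <- cp < pp || (cp == pp && rhs && parent_op %in% c("-", "/", "^"))
      if (length(e) == 2 && fn == "-") need <- TRUE
      if (need) return(paste0("(", s, ")"))
    }
  }
  s
}

# R language object -> MathML node inside `parent` (for SBML kinetic laws).
mathml_time_url <- "http://www.sbml.org/sbml/symbols/time"

expr_to_mathml <- function(e, parent) {
  if (is.numeric(e)) {
    xml2::xml_add_child(parent, "cn",
                        format(e, digits = 15, scientific = FALSE, trim = TRUE))
    return(invisible())
  }
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm %in% c("t", "time")) {
      node <- xml2::xml_add_child(parent, "csymbol", "time",
                                  encoding = "text",
                                  definitionURL = mathml_time_url)
    } else {
      xml2::xml_add_child(parent, "ci", nm)
    }
    return(invisible())
  }
  fn <- as.character(e[[1]])
  if (fn == "(") return(expr_to_mathml(e[[2]], parent))
  apply_node <- xml2::xml_add_child(parent, "apply")
  opname <- switch(fn, "+" = "plus", "-" = "minus", "*" = "times",
                   "/" = "divide", "^" = "power", "exp" = "exp",
                   "log" = "ln", "pow" = "power",
                   abort_sbtab(sprintf("cannot render function '%s' as MathML", fn),
                               "sbtab_export_error"))
  xml2::xml_add_child(apply_node, opname)
  for (arg in as.list(e)[-1]) expr_to_mathml(arg, apply_node)
  invisible()
}

sanitize_network_ids <- function(network) {
  ids <- c(network$species$id, vapply(network$reactions, `[[`, character(1), "id"),
           network$parameters$id, network$compartments$id)
  clean <- sanitize_ids(ids)
  renamed <- ids[clean != ids]
  if (length(renamed)) {
    abort_sbtab(sprintf("identifier(s) not exportable without renaming: %s",
                        paste(renamed, collapse = ", ")),
                "sbtab_export_error")
  }
  invisible(TRUE)
}

# ---- SBML --------------------------------------------------------------

#' Export a reaction network as SBML Level 2 Version 4
#'
#' Species, reaction, parameter and compartment ids equal the (sanitized)
#' SBtab `!ID`s — never opaque hashes. Kinetic laws are embedded as
#' MathML of the parsed expressions; reversibility flags come from the
#' `!IsReversible` column; assignment expressions become assignment
#' rules; inputs are emitted as non-constant parameters. Model-wide
#' default units are declared: substance nanomole, time second.
#'
#' @param network a `reaction_network`.
#' @param model_id model id attribute. Default `"model"`.
#' @return SBML document as a single character string.
#' @export
to_sbml <- function(network, model_id = "model") {
  stopifnot(inherits(network, "reaction_network"))
  sanitize_network_ids(network)
  doc <- xml2::xml_new_root("sbml",
                            xmlns = "http://www.sbml.org/sbml/level2/version4",
                            level = "2", version = "4")
  model <- xml2::xml_add_child(doc, "model", id = model_id, name = model_id)

  uds <- xml2::xml_add_child(model, "listOfUnitDefinitions")
  ud <- xml2::xml_add_child(uds, "unitDefinition", id = "substance")
  ul <- xml2::xml_add_child(ud, "listOfUnits")
  xml2::xml_add_child(ul, "unit", kind = "mole", scale = "-9", exponent = "1")
  ud <- xml2::xml_add_child(uds, "unitDefinition", id = "time")
  ul <- xml2::xml_add_child(ud, "listOfUnits")
  xml2::xml_add_child(ul, "unit", kind = "second", exponent = "1")

  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (i in seq_len(nrow(network$compartments))) {
    xml2::xml_add_child(lc, "compartment",
                        id = network$compartments$id[i],
                        size = format(network$compartments$size[i], digits = 15,
                                      scientific = FALSE, trim = TRUE))
  }

  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$species))) {
    xml2::xml_add_child(ls, "species",
                        id = network$species$id[i],
                        name = network$species$id[i],
                        compartment = network$species$compartment[i],
                        initialConcentration = format(network$species$initial[i],
                                                      digits = 15,
                                                      scientific = FALSE,
                                                      trim = TRUE))
  }

  if (nrow(network$parameters) || length(network$inputs) ||
      length(network$assignments)) {
    lp <- xml2::xml_add_child(model, "listOfParameters")
    for (i in seq_len(nrow(network$parameters))) {
      xml2::xml_add_child(lp, "parameter",
                          id = network$parameters$id[i],
                          value = format(network$parameters$value[i], digits = 15,
                                         scientific = FALSE, trim = TRUE),
                          constant = "true")
    }
    for (id in network$inputs) {
      xml2::xml_add_child(lp, "parameter", id = id,
                          value = format(network$input_defaults[[id]] %||% 0,
                                         digits = 15, scientific = FALSE,
                                         trim = TRUE),
                          constant = "false")
    }
    for (a in network$assignments) {
      xml2::xml_add_child(lp, "parameter", id = a$target, constant = "false")
    }
  }

  if (length(network$assignments)) {
    lr <- xml2::xml_add_child(model, "listOfRules")
    for (a in network$assignments) {
      rule <- xml2::xml_add_child(lr, "assignmentRule", variable = a$target)
      math <- xml2::xml_add_child(rule, "math",
                                  xmlns = "http://www.w3.org/1998/Math/MathML")
      expr_to_mathml(a$expr, math)
    }
  }

  lrx <- xml2::xml_add_child(model, "listOfReactions")
  for (r in network$reactions) {
    rx <- xml2::xml_add_child(lrx, "reaction", id = r$id,
                              reversible = tolower(as.character(r$reversible)))
    if (length(r$reactants)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (sp in names(r$reactants)) {
        xml2::xml_add_child(lre, "speciesReference", species = sp,
                            stoichiometry = as.character(r$reactants[[sp]]))
      }
    }
    if (length(r$products)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (sp in names(r$products)) {
        xml2::xml_add_child(lpr, "speciesReference", species = sp,
                            stoichiometry = as.character(r$products[[sp]]))
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    expr_to_mathml(r$flux, math)
  }
  as.character(doc)
}

# ---- NMODL (MOD) -------------------------------------------------------

nmodl_keywords <- c("STATE", "PARAMETER", "ASSIGNED", "DERIVATIVE", "INITIAL",
                    "BREAKPOINT", "NEURON", "UNITS", "SOLVE", "METHOD", "LOCAL",
                    "t", "dt", "v", "celsius")

# Exponent of the second in a parameter unit string such as "1/s",
# "1/(nM*s)", "nM/s", "s^-1", "nM". NA when no time factor is present.
unit_time_exponent <- function(unit) {
  u <- trimws(as.character(unit))
  # whitespace between unit factors means multiplication ("nM s")
  u <- gsub("(?<=[A-Za-z0-9])\\s+(?=[A-Za-z])", "*", u, perl = TRUE)
  u <- gsub("\\s+", "", u)
  if (!nzchar(u)) return(NA_integer_)
  u <- gsub("[()]", "", u)
  parts <- strsplit(u, "/", fixed = TRUE)[[1]]
  expo <- 0L
  count_s <- function(txt) {
    total <- 0L
    for (f in strsplit(txt, "*", fixed = TRUE)[[1]]) {
      m <- regmatches(f, regexec("^s(\\^(-?[0-9]+))?$", f))[[1]]
      if (length(m)) {
        total <- total + if (nzchar(m[3])) as.integer(m[3]) else 1L
      }
    }
    total
  }
  if (length(parts) >= 1) expo <- expo + count_s(parts[1])
  if (length(parts) >= 2) for (p in parts[-1]) expo <- expo - count_s(p)
  if (expo == 0L) NA_integer_ else expo
}

# Rescale one parameter value from seconds to milliseconds according to
# the time exponent of its unit; unitless parameters are assumed
# first-order in time (exponent -1) with a warning.
rescale_to_ms <- function(value, unit, id = "") {
  expo <- unit_time_exponent(unit)
  if (is.na(expo)) {
    u <- gsub("\\s+", "", as.character(unit))
    if (nzchar(u) && !grepl("(^|[*/(])s([*/)^]|$)", u)) {
      # unit declared and carries no time factor: leave untouched
      return(list(value = value, unit = unit, warned = FALSE))
    }
    warning(sprintf("parameter '%s' has no declared unit; assuming first order in time (1/s)",
                    id))
    expo <- -1L
  }
  list(value = value * 1000^expo,
       unit = gsub("(^|[*/(])s(?=[*/)^]|$)", "\\1ms", paste0(unit), perl = TRUE),
       warned = FALSE)
}

#' Export a reaction network as an NMODL MOD file
#'
#' Emits a NEURON mechanism with a STATE block (one state per
#' non-eliminated species), a PARAMETER block whose rate constants are
#' rescaled from seconds to milliseconds (NEURON's time unit; a
#' first-order /s rate becomes x 1e-3 /ms, composite units rescale by
#' their time exponent), assignment expressions emitted before use, a
#' DERIVATIVE block with the ODEs and an INITIAL block from the initial
#' concentrations. Concentration units (nM) are never changed. With
#' `reduce_conservation = TRUE`, conservation-eliminated species become
#' algebraic assignments of the conserved totals. Coupling the mechanism
#' into a cell model (wiring inputs/outputs) remains a manual user step;
#' input channels are emitted as ASSIGNED quantities flagged in a
#' comment.
#'
#' @param network a `reaction_network`.
#' @param suffix NEURON mechanism name. Default `"sbtabflow"`.
#' @param reduce_conservation substitute conserved states by algebraic
#'   equations. Default `FALSE`.
#' @return MOD file text as a single character string.
#' @export
to_mod <- function(network, suffix = "sbtabflow", reduce_conservation = FALSE) {
  stopifnot(inherits(network, "reaction_network"))
  sanitize_network_ids(network)
  clash <- intersect(c(network$species$id, network$parameters$id),
                     nmodl_keywords)
  rename <- stats::setNames(character(), character())
  if (length(clash)) {
    warning(sprintf("identifier(s) clash with NMODL keywords, renamed with suffix: %s",
                    paste(clash, collapse = ", ")))
    rename <- stats::setNames(paste0(clash, "_1"), clash)
  }
  nm <- function(id) if (id %in% names(rename)) rename[[id]] else id

  model <- compile_model(network, reduce_conservation = reduce_conservation)
  sp_ids <- network$species$id
  state_ids <- model$state_ids
  elim_ids <- setdiff(sp_ids, state_ids)

  params <- network$parameters
  plines <- character(); notes <- character()
  for (i in seq_len(nrow(params))) {
    r <- withCallingHandlers(
      rescale_to_ms(params$value[i], params$unit[i], params$id[i]),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    plines <- c(plines, sprintf("    %s = %s %s", nm(params$id[i]),
                                format(r$value, digits = 15, scientific = FALSE,
                                       trim = TRUE),
                                if (nzchar(r$unit)) paste0("(", r$unit, ")") else ""))
  }

  sub_ids <- function(txt) {
    for (old in names(rename)) {
      txt <- gsub(paste0("\\b", old, "\\b"), rename[[old]], txt)
    }
    txt
  }

  flux_lines <- vapply(network$reactions, function(r) {
    sprintf("    %s = %s", paste0("flux_", r$id), sub_ids(expr_to_infix(r$flux)))
  }, character(1))
  assign_lines <- vapply(network$assignments, function(a) {
    sprintf("    %s = %s", nm(a$target), sub_ids(expr_to_infix(a$expr)))
  }, character(1))

  # dX/dt = sum_j Ssc[X, j] * flux_j, written over flux variables
  vol <- stats::setNames(network$compartments$size, network$compartments$id)
  deriv_lines <- character()
  elim_lines <- character()
  if (length(elim_ids)) {
    red <- model$reduction
    for (r in seq_along(red$elim)) {
      i <- red$elim[r]
      cr <- red$C[r, ]
      others <- setdiff(which(cr != 0), i)
      rhs_terms <- vapply(others, function(jj) {
        sprintf("%s*%s", format(cr[jj], digits = 15, trim = TRUE), nm(sp_ids[jj]))
      }, character(1))
      total_name <- paste0("total_", nm(sp_ids[i]))
      expr <- if (length(rhs_terms))
        sprintf("(%s - (%s))/%s", total_name, paste(rhs_terms, collapse = " + "),
                format(cr[i], digits = 15, trim = TRUE))
      else sprintf("%s/%s", total_name, format(cr[i], digits = 15, trim = TRUE))
      elim_lines <- c(elim_lines, sprintf("    %s = %s", nm(sp_ids[i]), expr))
    }
  }
  for (i in seq_along(sp_ids)) {
    if (sp_ids[i] %in% elim_ids) next
    terms <- character()
    for (j in seq_along(network$reactions)) {
      s_ij <- network$S[i, j]
      if (s_ij == 0) next
      scale <- vol[[network$reactions[[j]]$location]] /
        vol[[network$species$compartment[i]]]
      coef <- s_ij * scale
      term <- if (coef == 1) paste0("flux_", network$reactions[[j]]$id)
      else sprintf("%s*flux_%s", format(coef, digits = 15, trim = TRUE),
                   network$reactions[[j]]$id)
      terms <- c(terms, if (coef > 0 && length(terms)) paste0("+", term)
                 else if (coef > 0) term else paste0("-", sub("^-", "", term)))
    }
    rhs_txt <- if (length(terms)) paste(gsub("^\\+", "", terms[1]),
                                        paste(terms[-1], collapse = " "))
    else "0"
    deriv_lines <- c(deriv_lines, sprintf("    %s' = %s", nm(sp_ids[i]),
                                          trimws(rhs_txt)))
  }

  init_lines <- vapply(seq_along(sp_ids), function(i) {
    sprintf("    %s = %s", nm(sp_ids[i]),
            format(network$species$initial[i], digits = 15, scientific = FALSE,
                   trim = TRUE))
  }, character(1))
  total_lines <- character()
  if (length(elim_ids)) {
    red <- model$reduction
    for (r in seq_along(red$elim)) {
      i <- red$elim[r]
      cr <- red$C[r, ]
      nz <- which(cr != 0)
      expr <- paste(vapply(nz, function(jj) {
        sprintf("%s*%s", format(cr[jj], digits = 15, trim = TRUE),
                format(network$species$initial[jj], digits = 15,
                       scientific = FALSE, trim = TRUE))
      }, character(1)), collapse = " + ")
      total_lines <- c(total_lines,
                       sprintf("    total_%s = %s", nm(sp_ids[i]), expr))
    }
  }

  lines <- c(
    sprintf("NEURON {"),
    sprintf("    SUFFIX %s", suffix),
    if (length(network$inputs))
      sprintf("    RANGE %s", paste(vapply(network$inputs, nm, character(1)),
                                    collapse = ", ")),
    "}",
    "",
    "UNITS {",
    "    (nM) = (nanomole/liter)",
    "}",
    "",
    "PARAMETER {",
    plines,
    "}",
    "",
    "ASSIGNED {",
    if (length(network$inputs)) paste0("    ", vapply(network$inputs, nm,
                                                      character(1)), " (nM)"),
    if (length(network$assignments)) paste0("    ",
                                            vapply(network$assignments,
                                                   function(a) nm(a$target),
                                                   character(1))),
    if (length(elim_ids)) paste0("    ", vapply(elim_ids, nm, character(1)), " (nM)"),
    if (length(elim_ids)) paste0("    total_", vapply(elim_ids, nm, character(1)),
                                 " (nM)"),
    paste0("    ", vapply(network$reactions, function(r) paste0("flux_", r$id),
                          character(1))),
    "}",
    "",
    if (length(network$inputs)) c(
      ": input channel(s) below must be assigned by the user when coupling",
      ": this mechanism into a cell model (e.g. from a calcium source);",
      ": time-dependent stimulus expressions are not emitted automatically.",
      ""),
    "STATE {",
    paste0("    ", vapply(state_ids, nm, character(1)), " (nM)"),
    "}",
    "",
    "INITIAL {",
    init_lines,
    total_lines,
    "}",
    "",
    "BREAKPOINT {",
    "    SOLVE kinetics METHOD sparse",
    "}",
    "",
    "DERIVATIVE kinetics {",
    elim_lines,
    assign_lines,
    flux_lines,
    deriv_lines,
    "}")
  if (length(notes)) {
    lines <- c(paste0(": note: ", notes), "", lines)
  }
  paste(unlist(lines), collapse = "\n")
}

# ---- VFGEN -------------------------------------------------------------

#' Export a reaction network as a VFGEN vector-field file
#'
#' Produces VFGEN XML: one `Parameter` element per rate constant, one
#' `Expression` per assignment (inputs appear as Expressions of time,
#' defaulting to their resting values), and one `StateVariable` per
#' species whose `Formula` is the full ODE right-hand side.
#'
#' @param network a `reaction_network`.
#' @param name vector-field name. Default `"model"`.
#' @return VFGEN document as a single character string.
#' @export
to_vf <- function(network, name = "model") {
  stopifnot(inherits(network, "reaction_network"))
  sanitize_network_ids(network)
  doc <- xml2::xml_new_root("VectorField", Name = name,
                            IndependentVariable = "t")
  for (i in seq_len(nrow(network$compartments))) {
    xml2::xml_add_child(doc, "Constant", Name = network$compartments$id[i],
                        Value = format(network$compartments$size[i], digits = 15,
                                       scientific = FALSE, trim = TRUE))
  }
  for (i in seq_len(nrow(network$parameters))) {
    xml2::xml_add_child(doc, "Parameter", Name = network$parameters$id[i],
                        DefaultValue = format(network$parameters$value[i],
                                              digits = 15, scientific = FALSE,
                                              trim = TRUE))
  }
  for (id in network$inputs) {
    xml2::xml_add_child(doc, "Expression", Name = id,
                        Formula = format(network$input_defaults[[id]] %||% 0,
                                         digits = 15, scientific = FALSE,
                                         trim = TRUE))
  }
  for (a in network$assignments) {
    xml2::xml_add_child(doc, "Expression", Name = a$target,
                        Formula = expr_to_infix(a$expr))
  }
  for (r in network$reactions) {
    xml2::xml_add_child(doc, "Expression", Name = paste0("flux_", r$id),
                        Formula = expr_to_infix(r$flux))
  }
  vol <- stats::setNames(network$compartments$size, network$compartments$id)
  for (i in seq_len(nrow(network$species))) {
    terms <- character()
    for (j in seq_along(network$reactions)) {
      s_ij <- network$S[i, j]
      if (s_ij == 0) next
      coef <- s_ij * vol[[network$reactions[[j]]$location]] /
        vol[[network$species$compartment[i]]]
      base <- paste0("flux_", network$reactions[[j]]$id)
      term <- if (abs(coef) == 1) base
      else paste0(format(abs(coef), digits = 15, trim = TRUE), "*", base)
      terms <- c(terms, paste0(if (coef < 0) "-" else if (length(terms)) "+" else "",
                               term))
    }
    xml2::xml_add_child(doc, "StateVariable", Name = network$species$id[i],
                        Formula = if (length(terms)) paste(terms, collapse = "")
                        else "0",
                        InitialCondition = format(network$species$initial[i],
                                                  digits = 15, scientific = FALSE,
                                                  trim = TRUE))
  }
  as.character(doc)
}
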