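# Independent oracles and fixture builders shared by the test files.
# These deliberately use different algorithms/code paths than the package
# (floating-point QR null spaces, a separate MathML reader, a separate
# NMODL reader) so that agreement is evidence, not tautology.

# ---- floating-point null space oracle (QR-based, via svd) -------------

# Orthonormal basis of {x : M x = 0} by singular value decomposition.
float_nullspace <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  if (!nrow(M)) return(diag(ncol(M)))
  s <- svd(M, nu = 0, nv = ncol(M))
  null_idx <- which(c(s$d, rep(0, ncol(M) - length(s$d))) < tol)
  s$v[, null_idx, drop = FALSE]
}

# Do the columns of A and B span the same subspace?
same_span <- function(A, B, tol = 1e-8) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) return(FALSE)
  if (!ncol(A)) return(TRUE)
  ra <- qr(A, tol = tol)$rank
  rb <- qr(B, tol = tol)$rank
  rab <- qr(cbind(A, B), tol = tol)$rank
  ra == rb && rab == ra
}

# Is vector v inside the span of the columns of A?
in_span <- function(v, A, tol = 1e-8) {
  if (!ncol(A)) return(all(abs(v) < tol))
  qr(cbind(A, v), tol = tol)$rank == qr(A, tol = tol)$rank
}

# ---- random network generator -----------------------------------------

# Random small reaction network document with mass-action kinetics.
# Reactions are uni- or bimolecular on each side; a configurable fraction
# is reversible.
random_network_doc <- function(n_species = NULL, n_reactions = NULL,
                               p_reversible = 0.7) {
  if (is.null(n_species)) n_species <- sample(2:8, 1)
  if (is.null(n_reactions)) n_reactions <- sample(1:10, 1)
  sp <- paste0("X", seq_len(n_species))
  schemes <- character(n_reactions)
  laws <- character(n_reactions)
  revs <- character(n_reactions)
  pids <- character(); pvals <- numeric()
  for (j in seq_len(n_reactions)) {
    ns_l <- sample(seq_len(min(2, n_species - 1)), 1)
    ns_r <- sample(seq_len(min(2, n_species - ns_l)), 1)
    lhs <- sample(sp, ns_l); rhs <- sample(setdiff(sp, lhs), ns_r)
    rev <- runif(1) < p_reversible
    kf <- paste0("kf_R", j); kr <- paste0("kr_R", j)
    fwd <- paste(c(kf, lhs), collapse = "*")
    schemes[j] <- paste(paste(lhs, collapse = " + "),
                        if (rev) "<=>" else "=>",
                        paste(rhs, collapse = " + "))
    if (rev) {
      laws[j] <- paste0(fwd, "-", paste(c(kr, rhs), collapse = "*"))
      pids <- c(pids, kf, kr); pvals <- c(pvals, runif(2, 0.1, 2))
    } else {
      laws[j] <- fwd
      pids <- c(pids, kf); pvals <- c(pvals, runif(1, 0.1, 2))
    }
    revs[j] <- if (rev) "TRUE" else "FALSE"
  }
  doc <- sbtabflow:::new_sbtab_document(source = "test:random")
  doc <- sbtabflow:::sbtab_table(doc, "Compartment",
    data.frame(`!ID` = "cell", `!Size` = 1, check.names = FALSE), "Compartment")
  doc <- sbtabflow:::sbtab_table(doc, "Compound",
    data.frame(`!ID` = sp, `!Location` = "cell",
               `!InitialValue` = runif(n_species, 0.5, 5),
               check.names = FALSE), "Compound")
  doc <- sbtabflow:::sbtab_table(doc, "Reaction",
    data.frame(`!ID` = paste0("R", seq_len(n_reactions)),
               `!KineticLaw` = laws, `!IsReversible` = revs,
               `!Location` = "cell", `!ReactionFormula` = schemes,
               check.names = FALSE), "Reaction")
  doc <- sbtabflow:::sbtab_table(doc, "Parameter",
    data.frame(`!ID` = pids, `!DefaultValue` = pvals, `!Unit` = "1/s",
               check.names = FALSE), "Quantity")
  doc
}

# Assign reversible rate pairs from species chemical potentials so that
# kf/kr = exp(mu_reactants - mu_products); such rates satisfy detailed
# balance, hence every Wegscheider constraint, by construction.
detailed_balance_theta <- function(network, mu = NULL) {
  sp <- network$species$id
  if (is.null(mu)) mu <- stats::setNames(rnorm(length(sp)), sp)
  theta <- sbtabflow:::default_theta(network)
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    if (!r$reversible) next
    dmu <- sum(mu[names(r$reactants)] * r$reactants) -
      sum(mu[names(r$products)] * r$products)
    kf <- runif(1, 0.5, 2)
    theta[paste0("kf_", r$id)] <- kf
    theta[paste0("kr_", r$id)] <- kf / exp(dmu)
  }
  theta
}

# ---- Table-3-style receptor/G-protein document ------------------------

# The printed seven-reaction receptor activation set (D1 receptor, Golf,
# adenylyl cyclase, calmodulin) used as a realistic parsing/stoichiometry
# fixture.
receptor_cascade_doc <- function() {
  sp <- c("GaolfGTP", "GaolfGDP", "D1R_Golf_DA", "Gbgolf", "D1R_DA",
          "D1R_Golf", "DA", "D1R", "AC5", "AC5_GaolfGTP", "CaM", "Ca",
          "CaM_Ca2", "PP2B", "PP2B_CaM")
  rx <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    `!ID` = paste0("R", 0:6),
    `!Name` = paste0("ReactionFlux", 0:6),
    `!KineticLaw` = c("kf_R0*GaolfGTP",
                      "kf_R1*D1R_Golf_DA",
                      "kf_R2*D1R_Golf*DA-kr_R2*D1R_Golf_DA",
                      "kf_R3*D1R*DA-kr_R3*D1R_DA",
                      "kf_R4*AC5*GaolfGTP-kr_R4*AC5_GaolfGTP",
                      "kf_R5*CaM*Ca-kr_R5*CaM_Ca2",
                      "kf_R6*PP2B*CaM-kr_R6*PP2B_CaM"),
    `!IsReversible` = c("FALSE", "FALSE", "TRUE", "TRUE", "TRUE", "TRUE",
                        "TRUE"),
    `!Location` = "Spine",
    `!ReactionFormula` = c("GaolfGTP < = > GaolfGDP",
                           "D1R_Golf_DA < = > Gbgolf + D1R_DA + GaolfGTP",
                           "D1R_Golf + DA < = > D1R_Golf_DA",
                           "D1R + DA < = > D1R_DA",
                           "AC5 + GaolfGTP < = > AC5_GaolfGTP",
                           "CaM + Ca < = > CaM_Ca2",
                           "PP2B + CaM < = > PP2B_CaM"))
  pid <- c("kf_R0", "kf_R1", "kf_R2", "kr_R2", "kf_R3", "kr_R3",
           "kf_R4", "kr_R4", "kf_R5", "kr_R5", "kf_R6", "kr_R6")
  doc <- sbtabflow:::new_sbtab_document(source = "test:receptor")
  doc <- sbtabflow:::sbtab_table(doc, "Compartment",
    data.frame(`!ID` = "Spine", `!Size` = 1, check.names = FALSE),
    "Compartment")
  doc <- sbtabflow:::sbtab_table(doc, "Compound",
    data.frame(`!ID` = sp, `!Location` = "Spine", `!InitialValue` = 1,
               check.names = FALSE), "Compound")
  doc <- sbtabflow:::sbtab_table(doc, "Reaction", rx, "Reaction")
  doc <- sbtabflow:::sbtab_table(doc, "Parameter",
    data.frame(`!ID` = pid, `!DefaultValue` = 1, `!Unit` = "1/s",
               check.names = FALSE), "Quantity")
  doc
}

# ---- independent MathML reader ----------------------------------------

# MathML -> R expression, written against the MathML spec rather than the
# package's writer.
mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    return(mathml_to_expr(kids[[1]]))
  }
  if (name == "cn") return(as.numeric(xml2::xml_text(node)))
  if (name == "ci") return(as.symbol(trimws(xml2::xml_text(node))))
  if (name == "csymbol") return(as.symbol("t"))
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr)
    fold <- function(fn) Reduce(function(a, b) call(fn, a, b), args)
    return(switch(op,
      plus = if (length(args) == 1) args[[1]] else fold("+"),
      minus = if (length(args) == 1) call("-", args[[1]]) else fold("-"),
      times = fold("*"),
      divide = fold("/"),
      power = fold("^"),
      exp = call("exp", args[[1]]),
      ln = call("log", args[[1]]),
      stop("unhandled MathML operator: ", op)))
  }
  stop("unhandled MathML node: ", name)
}

# Independent SBML reader: stoichiometric matrix and kinetic-law
# expressions straight from the XML structure.
read_sbml_semantics <- function(sbml_text) {
  doc <- xml2::read_xml(sbml_text)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfSpecies/species"),
                            "id")
  reactions <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rids <- xml2::xml_attr(reactions, "id")
  S <- matrix(0, length(species), length(rids),
              dimnames = list(species, rids))
  laws <- list()
  for (j in seq_along(rids)) {
    rx <- reactions[[j]]
    for (ref in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      st <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
      S[sp, j] <- S[sp, j] - st
    }
    for (ref in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      st <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
      S[sp, j] <- S[sp, j] + st
    }
    math <- xml2::xml_find_first(rx, "./kineticLaw/math")
    laws[[j]] <- mathml_to_expr(xml2::xml_child(math))
  }
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  list(species = species, S = S, laws = laws, parameters = pvals)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

# ---- independent NMODL reader -----------------------------------------

# Extracts PARAMETER values, STATE ids, INITIAL values and the DERIVATIVE
# block program (assignments + derivative equations) from MOD text, and
# builds a deSolve-ready RHS in milliseconds.
read_mod_semantics <- function(mod_text) {
  lines <- strsplit(mod_text, "\n", fixed = TRUE)[[1]]
  block <- function(name) {
    i0 <- grep(paste0("^", name, "\\b"), lines)[1]
    depth <- 0; out <- character()
    for (i in i0:length(lines)) {
      depth <- depth + lengths(regmatches(lines[i], gregexpr("\\{", lines[i]))) -
        lengths(regmatches(lines[i], gregexpr("\\}", lines[i])))
      out <- c(out, lines[i])
      if (i > i0 && depth <= 0) break
    }
    out
  }
  parse_assign <- function(txt) {
    m <- regmatches(txt, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*?)\\s*$", txt))[[1]]
    if (!length(m)) return(NULL)
    list(target = m[2], expr = str2lang(m[3]))
  }
  params <- list()
  for (l in block("PARAMETER")) {
    m <- regmatches(l, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([-+0-9.eE]+)", l))[[1]]
    if (length(m)) params[[m[2]]] <- as.numeric(m[3])
  }
  states <- character()
  for (l in block("STATE")) {
    m <- regmatches(l, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*(\\(.*\\))?\\s*$", l))[[1]]
    if (length(m) && !m[2] %in% c("STATE", "")) states <- c(states, m[2])
  }
  inits <- list()
  for (l in block("INITIAL")) {
    a <- parse_assign(l)
    if (!is.null(a)) inits[[a$target]] <- eval(a$expr)
  }
  program <- list()
  derivs <- list()
  for (l in block("DERIVATIVE")) {
    if (grepl("'", l, fixed = TRUE)) {
      m <- regmatches(l, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)'\\s*=\\s*(.*)$", l))[[1]]
      derivs[[m[2]]] <- str2lang(m[3])
    } else {
      a <- parse_assign(l)
      if (!is.null(a) && !grepl("DERIVATIVE", l)) program[[length(program) + 1]] <- a
    }
  }
  rhs <- function(t, y, parms) {
    e <- list2env(c(params, inits[startsWith(names(inits), "total_")],
                    as.list(y)))
    assign("t", t, envir = e)
    for (a in program) assign(a$target, eval(a$expr, e), envir = e)
    list(vapply(states, function(s) eval(derivs[[s]], e), numeric(1)))
  }
  y0 <- vapply(states, function(s) inits[[s]], numeric(1))
  list(params = params, states = states, inits = inits, rhs = rhs, y0 = y0)
}

# ---- closed-form Ishigami decomposition -------------------------------

# Variance decomposition of f(x) = sin x1 + a sin^2 x2 + b x3^4 sin x1
# with x_i ~ U(-pi, pi).
ishigami_indices <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  V <- V1 + V2 + V13
  list(S1 = V1 / V, S2 = V2 / V, S3 = 0,
       ST1 = (V1 + V13) / V, ST2 = V2 / V, ST3 = V13 / V, V = V)
}

ishigami_fn <- function(x, a = 7, b = 0.1) {
  sin(x[1]) + a * sin(x[2])^2 + b * x[3]^4 * sin(x[1])
}
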