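# Reaction-scheme parsing, rate expressions, stoichiometric assembly and
# ODE compilation.

test_that("reaction schemes parse to integer multisets with side order kept", {
  f <- parse_reaction_formula("CaM + Ca <=> CaM_Ca2")
  expect_equal(f$reactants, c(CaM = 1L, Ca = 1L))
  expect_equal(f$products, c(CaM_Ca2 = 1L))
  expect_true(f$reversible)

  f <- parse_reaction_formula("2 A => B")
  expect_equal(f$reactants, c(A = 2L))
  expect_equal(f$products, c(B = 1L))
  expect_false(f$reversible)

  # spaced arrows as printed in spreadsheet exports
  f <- parse_reaction_formula("GaolfGTP < = > GaolfGDP")
  expect_true(f$reversible)

  expect_error(parse_reaction_formula("A <=> "), "malformed")
  expect_error(parse_reaction_formula("A + => B"), "malformed")
})

test_that("the reversibility flag comes from the IsReversible column, not the arrow", {
  net <- build_network(receptor_cascade_doc())
  # R0 is printed with a reversible arrow but flagged FALSE
  expect_false(net$reactions[[1]]$reversible)
  expect_true(net$reactions[[3]]$reversible)
})

test_that("rate expressions evaluate deterministically and reject unknown symbols", {
  syms <- c("kf_R5", "CaM", "Ca", "kr_R5", "CaM_Ca2")
  e <- parse_rate_expression("kf_R5*CaM*Ca-kr_R5*CaM_Ca2", syms)
  env <- list2env(list(kf_R5 = 2, CaM = 3, Ca = 4, kr_R5 = 1, CaM_Ca2 = 5))
  expect_identical(eval(e, env), 19)

  e <- parse_rate_expression("kf_R0*GaolfGTP", c("kf_R0", "GaolfGTP"))
  expect_identical(eval(e, list2env(list(kf_R0 = 3, GaolfGTP = 0))), 0)

  expect_error(parse_rate_expression("kf_X*A", "A"), "kf_X")
  expect_error(parse_rate_expression("system('ls')", "A"), "unsupported function")
  # pow() and ^ are interchangeable
  e1 <- parse_rate_expression("pow(A,2)", "A")
  e2 <- parse_rate_expression("A^2", "A")
  expect_identical(eval(e1, list2env(list(A = 3))), eval(e2, list2env(list(A = 3))))
})

test_that("inputs resolve as time-dependent channels in kinetic laws", {
  doc <- fixture_experiments(fixture_model("usecase_like"))
  net <- build_network(doc)
  expect_true("Ca" %in% net$inputs)
  m <- compile_model(net)
  th <- sbtabflow:::default_theta(net)
  x0 <- net$species$initial
  # calcium on vs off changes only the kinase-activation flux
  v_on <- m$fluxes(0, x0, th, c(Ca = 1000, DA = 0))
  v_off <- m$fluxes(0, x0, th, c(Ca = 0, DA = 0))
  expect_gt(v_on[1], v_off[1])
  expect_equal(v_on[-1], v_off[-1])
})

test_that("the stoichiometric matrix follows the printed reaction set", {
  net <- build_network(receptor_cascade_doc())
  S <- net$S
  expect_equal(dim(S), c(15L, 7L))
  # R1: D1R_Golf_DA -> Gbgolf + D1R_DA + GaolfGTP
  expect_equal(S["D1R_Golf_DA", "R1"], -1L)
  expect_equal(S["Gbgolf", "R1"], 1L)
  expect_equal(S["D1R_DA", "R1"], 1L)
  expect_equal(S["GaolfGTP", "R1"], 1L)
  expect_equal(sum(S[, "R1"] != 0), 4)

  net2 <- build_network(fixture_model("two_state"))
  expect_equal(unname(net2$S), matrix(c(-1L, 1L), 2, 1))
})

test_that("rhs equals S times the flux vector (unit-flux consistency)", {
  for (seed in 1:5) {
    set.seed(seed)
    doc <- random_network_doc()
    # force every kinetic law to the constant 1
    doc$tables$Reaction[["!KineticLaw"]] <- "1"
    doc$tables$Parameter <- doc$tables$Parameter[0, ]
    net <- build_network(doc)
    m <- compile_model(net)
    dx <- m$rhs(0, net$species$initial, numeric(0), NULL, numeric(0))
    expect_equal(dx, unname(rowSums(net$S)))
  }
})

test_that("cyclic assignment dependencies are rejected with the cycle listed", {
  doc <- fixture_model("two_state")
  doc <- sbtabflow:::sbtab_table(doc, "Expression",
    data.frame(`!ID` = c("u", "w"), `!Formula` = c("w + 1", "u + 1"),
               check.names = FALSE), "Quantity")
  expect_error(build_network(doc), "cyclic assignment.*u.*w")
})

test_that("conservation reduction preserves trajectories", {
  # closed form two-state check plus random mass-action networks
  doc <- fixture_model("two_state")
  net <- build_network(doc)
  full <- compile_model(net)
  red <- compile_model(net, reduce_conservation = TRUE)
  expect_length(red$state_ids, 1)
  times <- seq(0, 3, by = 0.1)
  doc_e <- sbtabflow:::sbtab_table(doc, "Experiments",
    data.frame(`!ID` = "E0", `!Name` = "free relaxation", check.names = FALSE),
    "Quantity")
  r_full <- run_experiment(full, doc_e, "E0", times = times,
                           equilibrated = c(A = 2, B = 0))
  r_red <- run_experiment(red, doc_e, "E0", times = times,
                          equilibrated = c(A = 2, B = 0))
  expect_lt(max(abs(r_full$states - r_red$states)), 1e-5)
  # B reconstructed as total - A
  expect_equal(r_red$states[, "A"] + r_red$states[, "B"], rep(2, length(times)),
               tolerance = 1e-8)

  for (seed in 1:5) {
    set.seed(100 + seed)
    docr <- random_network_doc(n_species = 5, n_reactions = 4)
    netr <- build_network(docr)
    mr_full <- compile_model(netr)
    mr_red <- compile_model(netr, reduce_conservation = TRUE)
    x0 <- stats::setNames(netr$species$initial, netr$species$id)
    th <- sbtabflow:::default_theta(netr)
    tt <- seq(0, 2, by = 0.2)
    fn_full <- sbtabflow:::desolve_func(mr_full, th, list(), mr_full$totals_of(x0))
    fn_red <- sbtabflow:::desolve_func(mr_red, th, list(), mr_red$totals_of(x0))
    s_full <- deSolve::lsoda(x0[mr_full$state_idx], tt, fn_full, NULL,
                             rtol = 1e-8, atol = 1e-10)
    s_red <- deSolve::lsoda(x0[mr_red$state_idx], tt, fn_red, NULL,
                            rtol = 1e-8, atol = 1e-10)
    totals <- mr_red$totals_of(x0)
    full_states <- s_full[, -1, drop = FALSE]
    rec <- t(apply(s_red[, -1, drop = FALSE], 1, mr_red$reconstruct, totals))
    expect_lt(max(abs(rec[, mr_full$state_idx] - full_states)), 1e-5)
  }
})

test_that("reduction is a no-op when nothing is conserved", {
  doc <- fixture_model("two_state")
  # the autocatalytic branch breaks the A+B moiety: S is full rank
  doc$tables$Reaction <- rbind(doc$tables$Reaction,
    data.frame(`!ID` = "R2", `!Name` = "autocatalysis",
               `!KineticLaw` = "kr_R1*B", `!IsReversible` = "FALSE",
               `!Location` = "cell", `!ReactionFormula` = "B => 2 A",
               check.names = FALSE))
  net <- build_network(doc)
  expect_length(conservation_laws(net$S), 0)
  m_red <- compile_model(net, reduce_conservation = TRUE)
  m_full <- compile_model(net)
  expect_identical(m_red$state_ids, m_full$state_ids)
  expect_null(m_red$reduction)
})

test_that("mass-action trajectories stay nonnegative at solver tolerance", {
  for (seed in 1:8) {
    set.seed(200 + seed)
    doc <- random_network_doc(n_species = 4, n_reactions = 5)
    net <- build_network(doc)
    m <- compile_model(net)
    x0 <- stats::setNames(net$species$initial, net$species$id)
    fn <- sbtabflow:::desolve_func(m, sbtabflow:::default_theta(net), list(),
                                   numeric(0))
    sol <- deSolve::lsoda(x0, seq(0, 5, by = 0.5), fn, NULL,
                          rtol = 1e-6, atol = 1e-9)
    expect_gt(min(sol[, -1]), -1e-6)
  }
})
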