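# SBML, NMODL and VFGEN export.

test_that("the receptor-binding reaction exports as a reversible SBML reaction", {
  net <- build_network(receptor_cascade_doc())
  sem <- read_sbml_semantics(to_sbml(net))
  doc <- xml2::read_xml(to_sbml(net))
  xml2::xml_ns_strip(doc)
  sbml <- xml2::xml_find_first(doc, "/sbml")
  expect_identical(xml2::xml_attr(sbml, "level"), "2")
  expect_identical(xml2::xml_attr(sbml, "version"), "4")
  r2 <- xml2::xml_find_first(doc, "//reaction[@id='R2']")
  expect_identical(xml2::xml_attr(r2, "reversible"), "true")
  expect_length(xml2::xml_find_all(r2, "./listOfReactants/speciesReference"), 2)
  expect_length(xml2::xml_find_all(r2, "./listOfProducts/speciesReference"), 1)
  # the re-read kinetic law is algebraically the printed law
  j <- match("R2", colnames(sem$S))
  env <- list2env(list(kf_R2 = 2, D1R_Golf = 3, DA = 5, kr_R2 = 7,
                       D1R_Golf_DA = 11))
  expect_identical(eval(sem$laws[[j]], env), 2 * 3 * 5 - 7 * 11)
  # ids are the SBtab ids, never hash-like
  expect_true(all(c("D1R_Golf", "CaM_Ca2") %in% sem$species))
})

test_that("an empty network still yields a valid document skeleton", {
  doc <- fixture_model("two_state")
  net <- build_network(doc)
  net$reactions <- list()
  net$S <- net$S[, 0, drop = FALSE]
  txt <- to_sbml(net)
  parsed <- xml2::read_xml(txt)
  expect_identical(xml2::xml_name(parsed), "sbml")
})

test_that("SBML round trip preserves stoichiometry and fluxes", {
  set.seed(31)
  for (kind in c("two_state", "enzyme_cycle", "thermo_triangle",
                 "usecase_like")) {
    net <- build_network(fixture_model(kind))
    sem <- read_sbml_semantics(to_sbml(net))
    expect_identical(sem$S[rownames(net$S), colnames(net$S), drop = FALSE],
                     net$S * 1.0, label = paste(kind, "stoichiometry"))
    theta <- sbtabflow:::default_theta(net)
    for (rep in 1:10) {
      x <- stats::setNames(runif(nrow(net$S), 0, 10), net$species$id)
      u <- stats::setNames(runif(length(net$inputs), 0, 10), net$inputs)
      v_native <- net_fluxes <- compile_model(net)$fluxes(0.5, x, theta, u)
      env <- list2env(as.list(c(x, theta, u,
                                stats::setNames(net$compartments$size,
                                                net$compartments$id))))
      assign("t", 0.5, envir = env)
      # assignment rules first, as an SBML interpreter would
      for (a in net$assignments) assign(a$target, eval(a$expr, env), envir = env)
      v_sbml <- vapply(sem$laws, function(e) eval(e, env), numeric(1))
      expect_equal(v_sbml, unname(v_native), tolerance = 1e-12,
                   label = paste(kind, "fluxes at random state"))
    }
  }
})

test_that("MOD export rescales rate constants from seconds to milliseconds", {
  net <- build_network(fixture_model("enzyme_cycle"))
  sem <- read_mod_semantics(to_mod(net))
  # kf_R1 = 0.01 /(nM s) -> 1e-5 /(nM ms); kr_R1 = 1 /s -> 1e-3 /ms
  expect_equal(sem$params$kf_R1, 1e-5)
  expect_equal(sem$params$kr_R1, 1e-3)
  expect_equal(sem$params$kcat_R2, 5e-4)
  txt <- to_mod(net)
  expect_match(txt, "kr_R1 = 0.001 (1/ms)", fixed = TRUE)
  expect_match(txt, "(nM) = (nanomole/liter)", fixed = TRUE)
})

test_that("unit strings map to the right time exponent", {
  ute <- sbtabflow:::unit_time_exponent
  expect_identical(ute("1/s"), -1L)
  expect_identical(ute("s^-1"), -1L)
  expect_identical(ute("1/(nM*s)"), -1L)
  expect_identical(ute("1/(nM s)"), -1L)
  expect_identical(ute("nM/s"), -1L)
  expect_true(is.na(ute("nM")))
  # concentration units are never touched
  r <- sbtabflow:::rescale_to_ms(5, "nM", "conc")
  expect_identical(r$value, 5)
  expect_warning(sbtabflow:::rescale_to_ms(2, "", "k_unitless"),
                 "first order")
})

test_that("conservation reduction turns the eliminated state into algebra", {
  net <- build_network(fixture_model("two_state"))
  txt <- to_mod(net, reduce_conservation = TRUE)
  sem <- read_mod_semantics(txt)
  expect_identical(sem$states, "A")
  expect_match(txt, "B = (total_B - (1*A))/1", fixed = TRUE)
})

test_that("the emitted MOD ODEs match the native engine after time rescaling", {
  for (reduce in c(FALSE, TRUE)) {
    net <- build_network(fixture_model("two_state"))
    sem <- read_mod_semantics(to_mod(net, reduce_conservation = reduce))
    t_s <- seq(0, 3, by = 0.1)
    sol_mod <- deSolve::lsoda(sem$y0, t_s * 1000, sem$rhs, NULL,
                              rtol = 1e-10, atol = 1e-12)
    m <- compile_model(net)
    fn <- sbtabflow:::desolve_func(m, sbtabflow:::default_theta(net), list(),
                                   numeric(0))
    sol_nat <- deSolve::lsoda(c(A = 2, B = 0)[m$state_idx], t_s, fn, NULL,
                              rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(sol_mod[, "A"]), unname(sol_nat[, "A"]),
                 tolerance = 1e-6,
                 label = sprintf("ms/s agreement (reduce=%s)", reduce))
  }
})

test_that("NMODL keyword clashes are renamed with a warning", {
  doc <- fixture_model("two_state")
  doc$tables$Compound[["!ID"]] <- c("A", "v")  # v is reserved in NMODL
  doc$tables$Reaction[["!KineticLaw"]][1] <- "kf_R1*A-kr_R1*v"
  doc$tables$Reaction[["!ReactionFormula"]][1] <- "A <=> v"
  doc$tables$Output[["!Formula"]] <- "v"
  net <- build_network(doc)
  expect_warning(txt <- to_mod(net), "clash")
  expect_match(txt, "v_1", fixed = TRUE)
})

test_that("VFGEN output carries every species, parameter and expression", {
  for (kind in c("two_state", "usecase_like")) {
    net <- build_network(fixture_model(kind))
    vf <- xml2::read_xml(to_vf(net))
    expect_identical(xml2::xml_name(vf), "VectorField")
    sv <- xml2::xml_find_all(vf, "./StateVariable")
    expect_length(sv, nrow(net$species))
    expect_length(xml2::xml_find_all(vf, "./Parameter"),
                  nrow(net$parameters))
  }
  net <- build_network(fixture_model("two_state"))
  vf <- xml2::read_xml(to_vf(net))
  sv <- xml2::xml_find_all(vf, "./StateVariable")
  f <- stats::setNames(xml2::xml_attr(sv, "Formula"), xml2::xml_attr(sv, "Name"))
  expect_identical(unname(f["A"]), "-flux_R1")
  expect_identical(unname(f["B"]), "flux_R1")
  # one Expression element per assignment, referenced by the formulas
  net_u <- build_network(fixture_model("usecase_like"))
  vf_u <- xml2::read_xml(to_vf(net_u))
  ex <- xml2::xml_attr(xml2::xml_find_all(vf_u, "./Expression"), "Name")
  expect_true("phospho_frac" %in% ex)
  expect_true(all(c("Ca", "DA") %in% ex))
})

test_that("export is byte-stable across repeated calls", {
  net <- build_network(fixture_model("usecase_like"))
  expect_identical(to_sbml(net), to_sbml(net))
  expect_identical(to_mod(net), to_mod(net))
  expect_identical(to_vf(net), to_vf(net))
})
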