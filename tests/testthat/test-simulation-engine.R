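# Stimulus generation, equilibration and experiment simulation.

test_that("a double-exponential transient peaks exactly at its amplitude", {
  tr <- 0.05; td <- 0.5; t0 <- 2
  f <- make_stimulus("double_exponential", amplitude = 1500, onset = t0,
                     tau_rise = tr, tau_decay = td)
  s_star <- tr * td / (td - tr) * log(td / tr)
  expect_equal(f(t0 + s_star), 1500, tolerance = 1e-9)
  expect_lte(max(f(seq(0, 20, by = 1e-3))), 1500 + 1e-6)
  expect_identical(f(t0 - 0.001), 0)
  expect_identical(f(0), 0)
})

test_that("a 10-spike 10 Hz burst starting at 4 s has onsets 4.0 ... 4.9", {
  expect_equal(spike_onsets(4, 10, 10), seq(4, 4.9, by = 0.1))
  f <- make_stimulus("spike_train", amplitude = 5000, onset = 4, count = 10,
                     frequency = 10)
  expect_identical(f(3.999), 0)
  expect_gt(f(4.02), 0)
  # after the last spike decays the train returns to (near) zero
  expect_lt(f(8), 5000 * 1e-6)
})

test_that("degenerate stimulus parameters are rejected or give zero", {
  expect_error(make_stimulus("double_exponential", amplitude = 1,
                             tau_rise = 0.5, tau_decay = 0.1),
               "tau_rise < tau_decay")
  expect_error(make_stimulus("double_exponential", amplitude = -1),
               ">= 0")
  f0 <- make_stimulus("double_exponential", amplitude = 0)
  expect_identical(f0(seq(0, 5)), rep(0, 6))
  ft <- make_stimulus("tabulated", times = c(0, 1, 2), values = c(0, 2, 0))
  expect_equal(ft(0.5), 1)
  expect_equal(ft(5), 0)  # held at edge value
})

test_that("equilibration reaches the analytic steady state", {
  net <- build_network(fixture_model("two_state"))
  m <- compile_model(net)
  x_eq <- equilibrate(m)
  expect_equal(unname(x_eq[c("A", "B")]), c(1, 1), tolerance = 1e-6)
  expect_true(attr(x_eq, "converged"))

  # idempotence: equilibrating from the steady state returns it unchanged
  x_eq2 <- equilibrate(m, x0 = x_eq)
  expect_equal(unname(x_eq2), unname(x_eq), tolerance = 1e-8)
})

test_that("a linear three-species chain equilibrates to the closed form", {
  doc <- fixture_model("thermo_triangle")
  doc$tables$Reaction <- doc$tables$Reaction[1:2, ]  # A <=> B <=> C chain
  doc$tables$Parameter <- doc$tables$Parameter[1:4, ]
  doc$tables$Parameter[["!DefaultValue"]] <- c(2, 1, 3, 1)  # kf1 kr1 kf2 kr2
  net <- build_network(doc)
  m <- compile_model(net)
  x_eq <- equilibrate(m, settings = list(equil_steady_tol = 1e-10))
  # detailed balance: B = (kf1/kr1) A, C = (kf2/kr2) B; total = 3
  A <- 3 / (1 + 2 + 2 * 3)
  expect_equal(unname(x_eq[c("A", "B", "C")]), c(A, 2 * A, 6 * A),
               tolerance = 1e-6)
})

test_that("constant-input relaxation reproduces the analytic exponential", {
  doc <- fixture_model("two_state")
  doc <- sbtabflow:::sbtab_table(doc, "Input",
    data.frame(`!ID` = "drive", `!Kind` = "constant", `!Amplitude` = 0,
               `!DefaultValue` = 0, check.names = FALSE), "Quantity")
  doc$tables$Reaction[["!KineticLaw"]][1] <- "kf_R1*A-kr_R1*B+drive"
  doc <- sbtabflow:::sbtab_table(doc, "Experiments",
    data.frame(`!ID` = "E0", `!Name` = "relaxation", `>drive` = 0,
               check.names = FALSE), "Quantity")
  net <- build_network(doc)
  m <- compile_model(net)
  times <- seq(0, 2, by = 0.01)
  res <- run_experiment(m, doc, "E0", times = times,
                        equilibrated = c(A = 2, B = 0))
  # A(t) = 1 + e^{-2t} for kf = kr = 1, A0 = 2
  expect_equal(res$states[, "A"], 1 + exp(-2 * times), tolerance = 1e-6)
})

test_that("a 20 s window at 0.01 s steps gives 2001 grid points", {
  doc <- fixture_experiments(fixture_model("usecase_like"), dt_list = 0,
                             include_no_dopamine = FALSE)
  net <- build_network(doc); m <- compile_model(net)
  res <- run_experiment(m, doc, "E0", window = c(0, 20),
                        resolution = "detailed")
  expect_length(res$times, 2001)
  res_d <- run_experiment(m, doc, "E0", window = c(0, 20),
                          resolution = "default",
                          equilibrated = res$equilibrium)
  expect_length(res_d$times, 401)
})

test_that("the calcium-only experiment has a silent dopamine channel", {
  doc <- fixture_experiments(fixture_model("usecase_like"))
  net <- build_network(doc); m <- compile_model(net)
  eq <- equilibrate(m)
  res <- run_experiment(m, doc, "E9", times = seq(0, 20, by = 0.5),
                        equilibrated = eq)
  expect_identical(res$channels$DA(seq(0, 20, by = 0.01)),
                   rep(0, length(seq(0, 20, by = 0.01))))
  expect_equal(max(res$states[, "Rc_DA"]), 0, tolerance = 1e-9)
})

test_that("run_all returns one result per experiment and isolates failures", {
  doc <- fixture_experiments(fixture_model("usecase_like"))
  net <- build_network(doc); m <- compile_model(net)
  all <- run_all_experiments(m, doc, times = seq(0, 12, by = 0.5))
  expect_identical(names(all), paste0("E", 0:9))
  expect_length(attr(all, "failures"), 0)

  # empty Experiments table -> empty map
  doc0 <- fixture_experiments(fixture_model("usecase_like"),
                              dt_list = integer(),
                              include_no_dopamine = FALSE)
  expect_length(run_all_experiments(compile_model(build_network(doc0)), doc0), 0)

  # a broken experiment among ten: nine results, one recorded failure
  doc$tables$Experiments[[">DA:TauRise"]] <- c(NA, NA, 5, rep(NA, 7))
  all2 <- run_all_experiments(m, doc, times = seq(0, 12, by = 0.5))
  expect_length(all2, 10)
  expect_identical(attr(all2, "failures"), "E2")
  expect_s3_class(all2$E2, "simulation_failure")
  expect_identical(sum(vapply(all2, inherits, logical(1), "simulation_result")), 9L)
})

test_that("halving the output step leaves shared-grid outputs unchanged", {
  doc <- fixture_experiments(fixture_model("usecase_like"), dt_list = 0,
                             include_no_dopamine = FALSE)
  net <- build_network(doc); m <- compile_model(net)
  eq <- equilibrate(m)
  coarse <- run_experiment(m, doc, "E0", times = seq(0, 10, by = 0.1),
                           equilibrated = eq)
  fine <- run_experiment(m, doc, "E0", times = seq(0, 10, by = 0.05),
                         equilibrated = eq)
  shared <- seq(1, 201, by = 2)
  scale <- max(abs(coarse$states))
  expect_lt(max(abs(fine$states[shared, ] - coarse$states)) / scale, 1e-5)
})

test_that("simulation results export in the data-table dialect", {
  doc <- fixture_experiments(fixture_model("usecase_like"), dt_list = 0,
                             include_no_dopamine = FALSE)
  net <- build_network(doc); m <- compile_model(net)
  res <- run_experiment(m, doc, "E0", times = seq(0, 2, by = 1))
  df <- result_as_data_table(res)
  expect_identical(names(df)[1:2], c("!TimePoint", "!Time"))
  expect_true(all(c(">Y0", "SD_Y0", ">Y3", "SD_Y3") %in% names(df)))
  expect_identical(nrow(df), 3L)
})
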