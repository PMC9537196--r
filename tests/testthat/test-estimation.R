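# The weighted least-squares objective and the optimizer registry.

test_that("the score arithmetic matches hand-computed cases", {
  # one experiment, one output, two points
  expect_identical(wls_score(Y = matrix(c(1, 3)), y = matrix(c(2, 5)),
                             tau = matrix(c(1, 1))), 2.5)
  # perfect fit
  Y <- matrix(runif(10), 5, 2)
  expect_identical(wls_score(Y, Y, tau = Y * 0 + 1), 0)
  # doubling tau divides the score by four, exactly
  y <- Y + 0.3
  tau <- matrix(runif(10, 0.5, 2), 5, 2)
  expect_equal(wls_score(Y, y, 2 * tau), wls_score(Y, y, tau) / 4)
})

usecase_fit_doc <- function(dt_list = c(0), include_no_dopamine = TRUE,
                            step = 0.25, window = 12) {
  doc <- fixture_experiments(fixture_model("usecase_like"), dt_list = dt_list,
                             include_no_dopamine = include_no_dopamine)
  fixture_data(doc, window = window, step = step)
}

test_that("the objective is zero at the generating parameters and positive away", {
  doc <- usecase_fit_doc()
  model <- compile_model(build_network(doc))
  obj <- make_objective(model, doc, free = c("kf_R3", "kr_R3"),
                        window = c(0, 12), times = seq(0, 12, by = 0.25))
  th0 <- sbtabflow:::default_theta(model$network)[c("kf_R3", "kr_R3")]
  expect_equal(obj(th0), 0, tolerance = 1e-10)
  expect_gt(obj(th0 * 2), 1e-4)
})

test_that("the objective is invariant under experiment and output reordering", {
  doc <- usecase_fit_doc(dt_list = c(-1, 1), include_no_dopamine = FALSE)
  model <- compile_model(build_network(doc))
  mk <- function(d) make_objective(model, d, free = "kf_R3",
                                   window = c(0, 12),
                                   times = seq(0, 12, by = 0.25))
  f1 <- mk(doc)(c(kf_R3 = 3e-4))
  doc2 <- doc
  doc2$tables$Experiments <- doc2$tables$Experiments[2:1, ]
  f2 <- mk(doc2)(c(kf_R3 = 3e-4))
  expect_equal(f2, f1, tolerance = 1e-12)
  # permute the output columns of one data table
  doc3 <- doc
  dt <- doc3$tables$E0
  perm <- c("!TimePoint", "!Time", ">Y3", "SD_Y3", ">Y1", "SD_Y1",
            ">Y0", "SD_Y0", ">Y2", "SD_Y2")
  doc3$tables$E0 <- dt[perm]
  f3 <- mk(doc3)(c(kf_R3 = 3e-4))
  expect_equal(f3, f1, tolerance = 1e-12)
})

test_that("objective in linear space equals objective of 10^z exactly", {
  doc <- usecase_fit_doc(dt_list = integer(), include_no_dopamine = TRUE)
  model <- compile_model(build_network(doc))
  obj <- make_objective(model, doc, free = "kf_R3", window = c(0, 12),
                        times = seq(0, 12, by = 0.25))
  th <- c(kf_R3 = 7e-4)
  # same bits in, same bits out: the objective applies no transform itself
  expect_identical(obj(th), obj(th + 0))
  # and the log10 round trip agrees to floating precision
  expect_equal(obj(stats::setNames(10^log10(th), names(th))), obj(th),
               tolerance = 1e-9)
})

test_that("tau-scaled noise puts the score near its chi-square expectation", {
  # noise sd = tau => each (Y - y)/tau is standard normal, the mean of n
  # squares has expectation 1, so F ~ n_outputs * n_experiments
  doc <- fixture_experiments(fixture_model("usecase_like"), dt_list = c(0),
                             include_no_dopamine = TRUE)
  doc <- fixture_data(doc, window = 12, step = 0.05, noise_sd = 1, tau = 1,
                      seed = 11)
  model <- compile_model(build_network(doc))
  obj <- make_objective(model, doc, free = character(), window = c(0, 12),
                        times = seq(0, 12, by = 0.05))
  F_true <- obj(stats::setNames(numeric(), character()))
  m_out <- 4; l_exp <- 2; n <- 241
  expect_equal(F_true, m_out * l_exp,
               tolerance = 4 * sqrt(2 / n * m_out * l_exp) / (m_out * l_exp))
})

quadratic_objective <- function(theta) {
  (theta[["a"]] - 3)^2 + 10 * (theta[["b"]] - 0.2)^2
}
quad_bounds <- list(start = c(a = 1, b = 1), lower = c(a = 0.01, b = 0.001),
                    upper = c(a = 100, b = 10))

test_that("the local optimizer recovers a known analytic minimum", {
  fit <- fit_parameters(quadratic_objective, quad_bounds$start,
                        quad_bounds$lower, quad_bounds$upper,
                        optimizer = "lbfgsb", seed = 1)
  expect_equal(unname(fit$theta_hat), c(3, 0.2), tolerance = 1e-4)
  expect_lt(fit$score, 1e-8)
  expect_identical(fit$score, quadratic_objective(fit$theta_hat))
})

test_that("population optimizers reach the local optimizer's score", {
  ref <- fit_parameters(quadratic_objective, quad_bounds$start,
                        quad_bounds$lower, quad_bounds$upper,
                        optimizer = "lbfgsb", seed = 1)
  for (opt in c("pso", "de", "anneal", "neldermead")) {
    for (seed in 1:3) {
      fit <- fit_parameters(quadratic_objective, quad_bounds$start,
                            quad_bounds$lower, quad_bounds$upper,
                            optimizer = opt, seed = seed,
                            options = if (opt == "anneal") list(n_iter = 1500)
                            else list())
      expect_lt(fit$score, ref$score + 1e-6,
                label = sprintf("%s seed %d reaches the reference minimum", opt, seed))
    }
  }
})

test_that("fits are bitwise reproducible given a seed", {
  f1 <- fit_parameters(quadratic_objective, quad_bounds$start,
                       quad_bounds$lower, quad_bounds$upper,
                       optimizer = "pso", seed = 7)
  f2 <- fit_parameters(quadratic_objective, quad_bounds$start,
                       quad_bounds$lower, quad_bounds$upper,
                       optimizer = "pso", seed = 7)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_identical(f1$score, f2$score)
  expect_identical(f1$trace, f2$trace)
})

test_that("unknown optimizers and bad bounds are configuration errors", {
  expect_error(fit_parameters(quadratic_objective, quad_bounds$start,
                              quad_bounds$lower, quad_bounds$upper,
                              optimizer = "gradient_descent_deluxe"),
               "unknown optimizer")
  expect_error(fit_parameters(quadratic_objective, c(a = 1, b = 1),
                              c(a = -1, b = 0.1), c(a = 10, b = 10)),
               "log10")
})

test_that("zero free parameters returns the fixed point immediately", {
  obj <- function(theta) 42
  fit <- fit_parameters(obj, stats::setNames(numeric(), character()),
                        numeric(), numeric())
  expect_identical(fit$score, 42)
  expect_identical(fit$n_evaluations, 1L)
})

test_that("a failing simulation yields the penalty, not an abort", {
  doc <- usecase_fit_doc(dt_list = integer(), include_no_dopamine = TRUE)
  model <- compile_model(build_network(doc))
  obj <- make_objective(model, doc, free = "kf_R3", window = c(0, 12),
                        times = seq(0, 12, by = 0.25), penalty = 1e10)
  # an absurd rate makes the system explode stiffly enough to fail
  v <- suppressWarnings(obj(c(kf_R3 = 1e280)))
  expect_true(is.finite(v))
  expect_gte(v, 1e10)
})

test_that("reversible-binding rates are recovered from noiseless data", {
  doc <- usecase_fit_doc(dt_list = c(-2, 1), include_no_dopamine = TRUE,
                         step = 0.25, window = 12)
  model <- compile_model(build_network(doc))
  theta_true <- sbtabflow:::default_theta(model$network)[c("kf_R3", "kr_R3")]
  rec <- recover_parameters(model, doc, theta_true,
                            window = c(0, 12),
                            times = seq(0, 12, by = 0.25), seed = 3)
  expect_lt(max(rec$relative_error), 0.01)
})
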