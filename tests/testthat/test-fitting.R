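make_sh_spectrum <- function(freqs = test_frequencies(),
                             truth = c(Re = 10000, Ri = 2000, Cm = 5e-8)) {
  evaluate_circuit(builtin_model("simplified_hayden"), truth, freqs)
}

test_that("residual vectors interleave real/imag parts with the chosen weighting", {
  m <- parse_circuit("R1")
  s <- evaluate_circuit(m, c(R1 = 500), c(100, 1000))
  expect_equal(residual_vector(m, c(R1 = 500), s, "unit"), c(0, 0, 0, 0))

  s1 <- impedance_spectrum(1000, 100, 0)
  expect_equal(residual_vector(m, c(R1 = 110), s1, "modulus"), c(0.1, 0))

  s2 <- impedance_spectrum(c(100, 1000), c(499, 499), c(0, 0))
  expect_equal(residual_vector(m, c(R1 = 500), s2, "unit"), c(1, 0, 1, 0))

  s0 <- impedance_spectrum(1000, 0, 0)
  expect_error(residual_vector(m, c(R1 = 1), s0, "modulus"), "\\|Z\\| = 0")
})

test_that("goodness-of-fit metrics match the hand-computed toy example", {
  meas <- impedance_spectrum(c(100, 1000), c(100, 200), c(-50, -60))
  fit <- impedance_spectrum(c(100, 1000), c(110, 190), c(-50, -60))
  m <- goodness_of_fit(fit, meas)
  expect_equal(m$mae_real_pct, 7.5)
  expect_equal(m$rmse_real_pct, 7.9057, tolerance = 1e-5)
  expect_equal(m$mae_imag_pct, 0)
  expect_equal(m$rmse_imag_pct, 0)

  # zero iff identical
  m0 <- goodness_of_fit(meas, meas)
  expect_equal(unlist(unclass(m0)), c(mae_real_pct = 0, mae_imag_pct = 0,
                                      rmse_real_pct = 0, rmse_imag_pct = 0))

  # invariant under a common rescaling of both spectra
  scale_spec <- function(s, k) impedance_spectrum(s$frequency_hz, s$re_ohm * k, s$im_ohm * k)
  m1000 <- goodness_of_fit(scale_spec(fit, 1000), scale_spec(meas, 1000))
  expect_equal(unclass(m1000), unclass(m))

  expect_error(goodness_of_fit(impedance_spectrum(c(100, 900), c(1, 1), c(-1, -1)), meas),
               "grids")
  expect_error(goodness_of_fit(fit, impedance_spectrum(c(100, 1000), c(1, 1), c(0, -1))),
               "zero")
})

test_that("a one-parameter resistor fit converges quickly and exactly", {
  m <- parse_circuit("R1")
  s <- evaluate_circuit(m, c(R1 = 500), test_frequencies())
  f <- fit_model(m, s, fit_options(n_restarts = 0))
  expect_equal(unname(f$parameters[["R1"]]), 500, tolerance = 1e-8)
  expect_lte(f$n_iterations, 200)
  expect_true(f$converged)
})

test_that("noiseless simplified-Hayden spectra are recovered from a biased start", {
  truth <- c(Re = 10000, Ri = 2000, Cm = 5e-8)
  s <- make_sh_spectrum(truth = truth)
  f <- fit_model(builtin_model("simplified_hayden"), s,
                 fit_options(weighting = "modulus", n_restarts = 0),
                 init = truth * c(1.5, 0.7, 2.0))
  expect_lt(max(abs(f$parameters[names(truth)] / truth - 1)), 1e-4)
  expect_lt(f$objective, 1e-12)
})

test_that("restarts rescue an initial point at the bound edge", {
  truth <- c(Re = 10000, Ri = 2000, Cm = 5e-8)
  s <- make_sh_spectrum(truth = truth)
  ref <- fit_model(builtin_model("simplified_hayden"), s,
                   fit_options(n_restarts = 0), init = truth * c(1.5, 0.7, 2.0))
  edge <- fit_model(builtin_model("simplified_hayden"), s,
                    fit_options(n_restarts = 4, seed = 3),
                    init = c(Re = 1e-3, Ri = 1e-3, Cm = 1e-3))
  expect_equal(unname(edge$parameters), unname(ref$parameters), tolerance = 1e-6)
})

test_that("fits are deterministic given the seed", {
  s <- make_sh_spectrum()
  f1 <- fit_model("simplified_hayden", s, fit_options(seed = 9))
  f2 <- fit_model("simplified_hayden", s, fit_options(seed = 9))
  expect_identical(f1$parameters, f2$parameters)
  expect_identical(f1$objective, f2$objective)
})

test_that("the running-best objective never increases and ends below the start", {
  s <- make_sh_spectrum()
  f <- fit_model("simplified_hayden", s, fit_options(seed = 2))
  expect_true(all(diff(f$trace) <= 0))
  expect_lte(f$objective, f$trace[1])
})

test_that("the CPE-modified model nests the simplified Hayden model", {
  # noisy spectrum generated from simplified_hayden truth: the CPE model can
  # always do at least as well because n = 1 reproduces the capacitor
  truth <- c(Re = 10000, Ri = 2000, Cm = 5e-8)
  s0 <- make_sh_spectrum(truth = truth)
  set.seed(5)
  s <- impedance_spectrum(s0$frequency_hz,
                          s0$re_ohm * (1 + rnorm(nrow(s0), 0, 0.005)),
                          s0$im_ohm * (1 + rnorm(nrow(s0), 0, 0.005)))
  opts <- fit_options(seed = 11, n_restarts = 6)
  f_sh <- fit_model("simplified_hayden", s, opts)
  f_cpe <- fit_model("cpe_modified", s, opts)
  expect_lte(f_cpe$objective, f_sh$objective * (1 + 1e-6))
})

test_that("reported metrics are recomputable from the returned parameters", {
  s <- make_sh_spectrum()
  f <- fit_model("simplified_hayden", s, fit_options(seed = 4))
  refit <- evaluate_circuit(builtin_model("simplified_hayden"), f$parameters,
                            s$frequency_hz)
  m <- goodness_of_fit(refit, s)
  expect_equal(unclass(f$metrics), unclass(m))
})

test_that("an underdetermined fit is refused", {
  s <- make_sh_spectrum()[1, ]
  class(s) <- c("impedance_spectrum", "data.frame")
  expect_error(fit_model("proposed", s, fit_options()), "free parameters")
})

test_that("model comparison tabulates all requested models, worst fit last", {
  truth_model <- builtin_model("cpe_modified")
  s <- evaluate_circuit(truth_model, frequencies = test_frequencies())
  cmp <- compare_models(s, c("simplified_hayden", "cpe_modified", "hayden"),
                        fit_options(seed = 8, n_restarts = 1))
  expect_s3_class(cmp, "data.frame")
  expect_equal(nrow(cmp), 3)
  expect_true(all(c("mae_real_pct", "mae_imag_pct", "rmse_real_pct",
                    "rmse_imag_pct") %in% names(cmp)))
  expect_false(is.unsorted(cmp$mae_real_pct))
  expect_equal(cmp$model[1], "cpe_modified")
})

test_that("a failing model yields an error row, not an aborted comparison", {
  s <- make_sh_spectrum()[1:2, ]
  class(s) <- c("impedance_spectrum", "data.frame")
  cmp <- compare_models(s, c("R1", "proposed"), fit_options(n_restarts = 0))
  expect_equal(nrow(cmp), 2)
  bad <- cmp[cmp$model == "proposed", ]
  expect_true(is.na(bad$mae_real_pct))
  expect_match(bad$error, "free parameters")
})
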