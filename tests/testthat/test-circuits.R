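test_that("element impedances match closed forms", {
  z <- element_impedance("capacitor", list(C = 1e-6), 1e6)
  expect_equal(z, complex(real = 0, imaginary = -1), tolerance = 1e-12)
  # CPE with n = 1 degenerates to the capacitor
  z <- element_impedance("cpe", list(P = 1e-6, n = 1), 1e6)
  expect_equal(z, complex(real = 0, imaginary = -1), tolerance = 1e-12)
  # independent complex-exponentiation value 1/(1e-3 * (j 1e4)^0.5)
  z <- element_impedance("cpe", list(P = 1e-3, n = 0.5), 1e4)
  expect_equal(Re(z), 7.0711, tolerance = 1e-4)
  expect_equal(Im(z), -7.0711, tolerance = 1e-4)

  expect_error(element_impedance("capacitor", list(C = 1e-6), 0), "omega")
  expect_error(element_impedance("cpe", list(P = 1e-6, n = 1.2), 1), "\\(0, 1\\]")
  expect_error(element_impedance("cpe", list(P = 1e-6, n = 0), 1), "\\(0, 1\\]")
})

test_that("CPE degeneracies: n = 1 is a capacitor, n -> 0 is a resistor", {
  omega <- 10^seq(1, 7, length.out = 40)
  z_cpe <- element_impedance("cpe", list(P = 3e-7, n = 1), omega)
  z_cap <- element_impedance("capacitor", list(C = 3e-7), omega)
  expect_lt(max(Mod(z_cpe - z_cap) / Mod(z_cap)), 1e-12)
  z <- element_impedance("cpe", list(P = 2e-3, n = 1e-9), omega)
  expect_equal(z, rep(complex(real = 500, imaginary = 0), length(omega)),
               tolerance = 1e-6)
})

test_that("circuit expressions parse with | binding tighter than -", {
  m <- parse_circuit("R1-R2")
  expect_equal(names(circuit_parameters(m)), c("R1", "R2"))
  m <- parse_circuit("Re|(Ri-Cm)")
  expect_equal(sort(names(circuit_parameters(m))), c("Cm", "Re", "Ri"))
  # precedence: Ra|Rb-Rc == (Ra|Rb)-Rc
  freqs <- 1000
  za <- evaluate_circuit(parse_circuit("Ra|Rb-Rc"),
                         c(Ra = 100, Rb = 100, Rc = 7), freqs)
  zb <- evaluate_circuit(parse_circuit("(Ra|Rb)-Rc"),
                         c(Ra = 100, Rb = 100, Rc = 7), freqs)
  expect_equal(za$re_ohm, zb$re_ohm)
  expect_equal(za$re_ohm, 57)
})

test_that("parse errors carry positions and name duplicates", {
  expect_error(parse_circuit("R1-(R2|C1"), "position 10")
  expect_error(parse_circuit("R1--R2"), "position")
  expect_error(parse_circuit("R1-R1"), "duplicate element name")
  expect_error(parse_circuit("R1-X2"), "unexpected character")
  expect_error(parse_circuit("R1)R2"), "position 3")
})

test_that("series and parallel evaluation follows circuit algebra", {
  f <- c(10, 1000)
  z <- evaluate_circuit(parse_circuit("R1-R2"), c(R1 = 300, R2 = 700), f)
  expect_equal(z$re_ohm, c(1000, 1000))
  expect_equal(z$im_ohm, c(0, 0))
  z <- evaluate_circuit(parse_circuit("R1|R2"), c(R1 = 1000, R2 = 1000), f)
  expect_equal(z$re_ohm, c(500, 500))
  # hand-worked 1000 || (1000 - j1000) at omega = 1000 rad/s
  z <- evaluate_circuit(parse_circuit("Re|(Ri-Cm)"),
                        c(Re = 1000, Ri = 1000, Cm = 1e-6), 1000 / (2 * pi))
  expect_equal(z$re_ohm, 600, tolerance = 1e-12)
  expect_equal(z$im_ohm, -200, tolerance = 1e-12)
  expect_error(evaluate_circuit(parse_circuit("R1-R2"), c(R1 = 1), f), "R2")
})

test_that("built-in models expose the expected parameter sets", {
  expect_length(circuit_parameters(builtin_model("simplified_hayden")), 3)
  expect_length(circuit_parameters(builtin_model("hayden")), 4)
  expect_length(circuit_parameters(builtin_model("cpe_modified")), 4)
  expect_length(circuit_parameters(builtin_model("double_shell")), 5)
  expect_length(circuit_parameters(builtin_model("proposed")), 6)
  expect_error(builtin_model("nope"), "hayden.*double_shell|valid names")
})

test_that("hayden frequency limits reduce to resistor networks", {
  m <- builtin_model("hayden")
  p <- circuit_parameters(m)
  z0 <- evaluate_circuit(m, p, 1e-6)$re_ohm
  expect_equal(z0, p[["Re"]] * (p[["Rm"]] + p[["Ri"]]) /
                     (p[["Re"]] + p[["Rm"]] + p[["Ri"]]), tolerance = 1e-6)
  zinf <- spectrum_modulus(evaluate_circuit(m, p, 1e9))
  expect_equal(zinf, p[["Re"]] * p[["Ri"]] / (p[["Re"]] + p[["Ri"]]),
               tolerance = 1e-3)
})

test_that("single-dispersion built-ins drop from |Z|(0) to Re||Ri", {
  for (nm in c("hayden", "simplified_hayden", "cpe_modified")) {
    m <- builtin_model(nm)
    p <- circuit_parameters(m)
    zlo <- spectrum_modulus(evaluate_circuit(m, p, 500))
    zhi <- spectrum_modulus(evaluate_circuit(m, p, 10000))
    expect_gt(zlo, zhi)
    zinf <- spectrum_modulus(evaluate_circuit(m, p, 1e9))
    expect_equal(zinf, p[["Re"]] * p[["Ri"]] / (p[["Re"]] + p[["Ri"]]),
                 tolerance = 1e-3, label = nm)
  }
})

test_that("built-ins are passive with monotone |Z| over a dense grid", {
  grid <- 10^seq(log10(500), log10(10000), length.out = 200)
  for (nm in builtin_model_names()) {
    m <- builtin_model(nm)
    s <- evaluate_circuit(m, frequencies = grid)
    expect_true(all(s$re_ohm > 0), label = paste(nm, "Re > 0"))
    expect_true(all(s$im_ohm <= 1e-12), label = paste(nm, "Im <= 0"))
    ph <- spectrum_phase(s)
    expect_true(all(ph >= -90 - 1e-9 & ph <= 1e-9), label = paste(nm, "phase"))
    expect_true(all(diff(spectrum_modulus(s)) <= 1e-9),
                label = paste(nm, "|Z| non-increasing"))
  }
})

test_that("parser+evaluator agree with the brute-force oracle on random trees", {
  set.seed(20)
  freqs <- test_frequencies()
  omega <- 2 * pi * freqs
  for (rep in 1:60) {
    rc <- random_circuit(8)
    model <- parse_circuit(rc$expr)
    got <- evaluate_circuit(model, rc$params, freqs)
    want <- oracle_impedance(rc$node, omega)
    scale <- abs(want)
    expect_lt(max(abs(complex(real = got$re_ohm, imaginary = got$im_ohm) - want) / scale),
              1e-12)
  }
})
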