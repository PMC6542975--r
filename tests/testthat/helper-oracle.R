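# Independent brute-force circuit evaluator used as the oracle for the
# parser/evaluator pipeline.  Works on a plain nested list (not the package's
# topology objects) with direct complex arithmetic; the CPE uses literal
# complex exponentiation (1i * omega)^n rather than the magnitude/phase form
# the package evaluates.

oracle_impedance <- function(node, omega) {
  if (!is.null(node$kind)) {
    return(switch(node$kind,
      resistor = rep(complex(real = node$R, imaginary = 0), length(omega)),
      capacitor = 1 / (1i * omega * node$C),
      cpe = 1 / (node$P * (1i * omega)^node$n)
    ))
  }
  zs <- lapply(node$children, oracle_impedance, omega = omega)
  if (node$op == "series") Reduce(`+`, zs) else 1 / Reduce(`+`, lapply(zs, function(z) 1 / z))
}

# Random series/parallel tree over <= max_elements elements with random
# positive parameters.  Returns the plain tree, the equivalent fully
# parenthesised expression string, and the named parameter vector.
random_circuit <- function(max_elements = 8) {
  counter <- new.env()
  counter$i <- 0L
  make_leaf <- function() {
    counter$i <- counter$i + 1L
    kind <- sample(c("resistor", "capacitor", "cpe"), 1)
    if (kind == "resistor") {
      R <- 10^runif(1, 0, 5)
      list(node = list(kind = "resistor", R = R),
           expr = sprintf("Rx%d", counter$i),
           params = stats::setNames(R, sprintf("Rx%d", counter$i)))
    } else if (kind == "capacitor") {
      C <- 10^runif(1, -9, -5)
      list(node = list(kind = "capacitor", C = C),
           expr = sprintf("Cx%d", counter$i),
           params = stats::setNames(C, sprintf("Cx%d", counter$i)))
    } else {
      P <- 10^runif(1, -8, -4)
      n <- runif(1, 0.3, 1)
      list(node = list(kind = "cpe", P = P, n = n),
           expr = sprintf("CPEx%d", counter$i),
           params = stats::setNames(c(P, n), paste0(sprintf("CPEx%d", counter$i), c(".P", ".n"))))
    }
  }
  build <- function(k) {
    if (k == 1) return(make_leaf())
    k_left <- sample(k - 1, 1)
    left <- build(k_left)
    right <- build(k - k_left)
    op <- sample(c("series", "parallel"), 1)
    sym <- if (op == "series") "-" else "|"
    list(node = list(op = op, children = list(left$node, right$node)),
         expr = sprintf("(%s%s%s)", left$expr, sym, right$expr),
         params = c(left$params, right$params))
  }
  build(sample(2:max_elements, 1))
}

test_frequencies <- function(n = 27) {
  sort(c(10^seq(log10(500), log10(10000), length.out = n - 2), 1100, 5000))
}
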