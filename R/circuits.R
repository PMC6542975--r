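#' Circuit element impedance
#'
#' Impedance of a single element at angular frequency `omega` (rad/s):
#' resistor `R`; capacitor `1/(j omega C)`; constant phase element (CPE)
#' `1/(P (j omega)^n)` on the principal branch, i.e. modulus
#' `1/(P omega^n)` at constant phase `-n * 90` degrees.  The CPE reduces to a
#' capacitor `C = P` at `n = 1` and to a resistor `1/P` as `n -> 0`.
#'
#' @param kind one of `"resistor"`, `"capacitor"`, `"cpe"`.
#' @param params named list/vector: resistor needs `R` (ohm), capacitor `C`
#'   (farad), cpe `P` (pre-exponential factor, S s^n) and `n` (exponent in
#'   (0, 1]).
#' @param omega angular frequency in rad/s, strictly positive (vectorised).
#' @return complex impedance in ohm.
#' @examples
#' element_impedance("cpe", list(P = 1e-3, n = 0.5), 1e4)
#' @export
element_impedance <- function(kind, params, omega) {
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    stop("omega must be finite and > 0", call. = FALSE)
  }
  params <- as.list(params)
  switch(kind,
    resistor = {
      R <- params$R
      if (is.null(R) || R <= 0) stop("resistor requires R > 0", call. = FALSE)
      complex(real = rep(R, length(omega)), imaginary = 0)
    },
    capacitor = {
      C <- params$C
      if (is.null(C) || C <= 0) stop("capacitor requires C > 0", call. = FALSE)
      1 / (1i * omega * C)
    },
    cpe = {
      P <- params$P
      n <- params$n
      if (is.null(P) || P <= 0) stop("cpe requires P > 0", call. = FALSE)
      if (is.null(n) || n <= 0 || n > 1) {
        stop("cpe exponent n must lie in (0, 1]", call. = FALSE)
      }
      (1 / (P * omega^n)) * exp(complex(real = 0, imaginary = -n * pi / 2))
    },
    stop(sprintf("unknown element kind '%s'", kind), call. = FALSE)
  )
}

element_defaults <- list(
  resistor  = list(params = c(R = 1000),          lower = c(R = 1e-3),  upper = c(R = 1e9)),
  capacitor = list(params = c(C = 1e-6),          lower = c(C = 1e-15), upper = c(C = 1)),
  cpe       = list(params = c(P = 1e-6, n = 0.8), lower = c(P = 1e-15, n = 1e-9),
                   upper = c(P = 1, n = 1))
)

## --- circuit expression parser -------------------------------------------
## Grammar: expr := term ('-' term)* ; term := atom ('|' atom)* ;
## atom := element | '(' expr ')' ; element := ('CPE'|'R'|'C') [A-Za-z0-9_]*
## '|' (parallel) binds tighter than '-' (series).

tokenize_circuit <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", "-", "|")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, text = ch, pos = i)
      i <- i + 1L
      next
    }
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^(CPE|R|C)[A-Za-z0-9_]*", rest))
    if (length(m) == 1 && nzchar(m)) {
      kind <- if (startsWith(m, "CPE")) "cpe" else if (startsWith(m, "R")) "resistor" else "capacitor"
      tokens[[length(tokens) + 1L]] <- list(type = "element", text = m, kind = kind, pos = i)
      i <- i + nchar(m)
      next
    }
    stop(sprintf("parse error at position %d: unexpected character '%s' (elements start with R, C or CPE)",
                 i, ch), call. = FALSE)
  }
  tokens
}

parser_state <- function(tokens, text) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env$text <- text
  env
}

peek_tok <- function(st) if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
next_tok <- function(st) { tok <- peek_tok(st); st$i <- st$i + 1L; tok }

parse_expr_node <- function(st) {
  terms <- list(parse_term_node(st))
  while (!is.null(tok <- peek_tok(st)) && tok$type == "-") {
    next_tok(st)
    terms[[length(terms) + 1L]] <- parse_term_node(st)
  }
  if (length(terms) == 1) terms[[1]] else list(op = "series", children = terms)
}

parse_term_node <- function(st) {
  atoms <- list(parse_atom_node(st))
  while (!is.null(tok <- peek_tok(st)) && tok$type == "|") {
    next_tok(st)
    atoms[[length(atoms) + 1L]] <- parse_atom_node(st)
  }
  if (length(atoms) == 1) atoms[[1]] else list(op = "parallel", children = atoms)
}

parse_atom_node <- function(st) {
  tok <- peek_tok(st)
  if (is.null(tok)) {
    stop(sprintf("parse error at position %d: unexpected end of expression",
                 nchar(st$text) + 1L), call. = FALSE)
  }
  if (tok$type == "(") {
    open <- next_tok(st)
    node <- parse_expr_node(st)
    closing <- peek_tok(st)
    if (is.null(closing) || closing$type != ")") {
      stop(sprintf("parse error at position %d: missing ')' for '(' at position %d",
                   if (is.null(closing)) nchar(st$text) + 1L else closing$pos,
                   open$pos), call. = FALSE)
    }
    next_tok(st)
    return(node)
  }
  if (tok$type == "element") {
    next_tok(st)
    return(list(op = "element", kind = tok$kind, name = tok$text, pos = tok$pos))
  }
  stop(sprintf("parse error at position %d: unexpected '%s'", tok$pos, tok$text),
       call. = FALSE)
}

collect_elements <- function(node) {
  if (node$op == "element") return(list(node))
  do.call(c, lapply(node$children, collect_elements))
}

element_param_names <- function(el) {
  if (el$kind == "cpe") paste0(el$name, c(".P", ".n")) else el$name
}

#' Parse a circuit expression
#'
#' Builds a [circuit_model] from a textual series/parallel expression.
#' Elements are written `R<name>` (resistor), `C<name>` (capacitor) or
#' `CPE<name>` (constant phase element); `-` is the series operator, `|` the
#' parallel operator, and `|` binds tighter than `-` so the common
#' `Re|(Ri-Cm)` forms need no extra nesting.  Parentheses group as usual.
#' Resistor/capacitor elements contribute one parameter named after the
#' element; a CPE named `CPEx` contributes `CPEx.P` and `CPEx.n`.
#'
#' @param expression circuit expression string, e.g. `"Re|(Ri-Cm)"`.
#' @param name optional model name attached to the result.
#' @return an object of class `circuit_model` with default parameter values
#'   and bounds; see [circuit_parameters()].
#' @examples
#' parse_circuit("Re|(Ri-Cm)")
#' @export
parse_circuit <- function(expression, name = NULL) {
  st <- parser_state(tokenize_circuit(expression), expression)
  tree <- parse_expr_node(st)
  trailing <- peek_tok(st)
  if (!is.null(trailing)) {
    stop(sprintf("parse error at position %d: unexpected '%s' after complete expression",
                 trailing$pos, trailing$text), call. = FALSE)
  }
  elements <- collect_elements(tree)
  el_names <- vapply(elements, `[[`, "", "name")
  dup <- duplicated(el_names)
  if (any(dup)) {
    stop(sprintf("parse error: duplicate element name(s): %s",
                 paste(unique(el_names[dup]), collapse = ", ")), call. = FALSE)
  }
  params <- numeric(0)
  lower <- numeric(0)
  upper <- numeric(0)
  for (el in elements) {
    def <- element_defaults[[el$kind]]
    pn <- element_param_names(el)
    p <- def$params; names(p) <- pn
    lo <- def$lower; names(lo) <- pn
    up <- def$upper; names(up) <- pn
    params <- c(params, p)
    lower <- c(lower, lo)
    upper <- c(upper, up)
  }
  structure(list(
    name = if (is.null(name)) expression else name,
    expression = expression,
    topology = tree,
    parameters = params,
    lower = lower,
    upper = upper
  ), class = "circuit_model")
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf("circuit model '%s': %s\n", x$name, x$expression))
  cat(sprintf("  %d parameter(s):\n", length(x$parameters)))
  for (pn in names(x$parameters)) {
    cat(sprintf("    %-10s = %-12.6g in [%.3g, %.3g]\n",
                pn, x$parameters[[pn]], x$lower[[pn]], x$upper[[pn]]))
  }
  invisible(x)
}

#' Circuit parameters
#'
#' `circuit_parameters()` returns the named parameter vector of a model;
#' `set_circuit_parameters()` returns a copy with some or all values replaced
#' (values must respect the model's bounds).
#'
#' @param circuit a [circuit_model].
#' @param values named numeric vector of parameter values.
#' @export
circuit_parameters <- function(circuit) circuit$parameters

#' @rdname circuit_parameters
#' @export
set_circuit_parameters <- function(circuit, values) {
  unknown <- setdiff(names(values), names(circuit$parameters))
  if (length(unknown) > 0) {
    stop(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  circuit$parameters[names(values)] <- values
  bad <- names(circuit$parameters)[circuit$parameters < circuit$lower |
                                   circuit$parameters > circuit$upper]
  if (length(bad) > 0) {
    stop(sprintf("parameter(s) outside bounds: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  circuit
}

eval_node <- function(node, params, omega) {
  if (node$op == "element") {
    pn <- element_param_names(node)
    vals <- params[pn]
    if (any(is.na(vals))) {
      stop(sprintf("missing parameter(s): %s",
                   paste(pn[is.na(vals)], collapse = ", ")), call. = FALSE)
    }
    p <- switch(node$kind,
                resistor = list(R = vals[[1]]),
                capacitor = list(C = vals[[1]]),
                cpe = list(P = vals[[1]], n = vals[[2]]))
    return(element_impedance(node$kind, p, omega))
  }
  zs <- lapply(node$children, eval_node, params = params, omega = omega)
  if (node$op == "series") {
    Reduce(`+`, zs)
  } else {
    1 / Reduce(`+`, lapply(zs, function(z) 1 / z))
  }
}

#' Evaluate a circuit over a frequency grid
#'
#' Combines element impedances recursively — series nodes sum impedances,
#' parallel nodes sum admittances — and returns the model spectrum.
#'
#' @param circuit a [circuit_model].
#' @param params named parameter vector; defaults to the model's stored
#'   parameters.  All parameters of the topology must be present and positive.
#' @param frequencies frequency grid in Hz, strictly positive.
#' @param label label for the returned spectrum.
#' @return an [impedance_spectrum()].
#' @examples
#' m <- parse_circuit("Re|(Ri-Cm)")
#' evaluate_circuit(m, c(Re = 1000, Ri = 1000, Cm = 1e-6),
#'                  frequencies = 1000 / (2 * pi))
#' @export
evaluate_circuit <- function(circuit, params = NULL, frequencies,
                             label = circuit$name) {
  if (is.null(params)) params <- circuit$parameters
  params <- unlist(params)
  missing_p <- setdiff(names(circuit$parameters), names(params))
  if (length(missing_p) > 0) {
    stop(sprintf("missing parameter(s): %s", paste(missing_p, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("frequencies must be finite and > 0", call. = FALSE)
  }
  omega <- 2 * pi * frequencies
  z <- eval_node(circuit$topology, params, omega)
  impedance_spectrum(frequencies, Re(z), Im(z), label = label)
}

builtin_circuit_table <- list(
  hayden = list(
    expression = "Re|((Rm|Cm)-Ri)",
    defaults = c(Re = 10000, Rm = 1000, Cm = 1e-7, Ri = 2000)
  ),
  simplified_hayden = list(
    expression = "Re|(Ri-Cm)",
    defaults = c(Re = 10000, Ri = 2000, Cm = 5e-8)
  ),
  cpe_modified = list(
    expression = "Re|(Ri-CPEm)",
    defaults = c(Re = 10000, Ri = 2000, CPEm.P = 1e-6, CPEm.n = 0.8)
  ),
  ## defaults place both relaxations inside the 0.5-10 kHz measuring band
  ## (about a decade apart) so that all five parameters are observable
  double_shell = list(
    expression = "R1|(C1-(R2|(C2-R3)))",
    defaults = c(R1 = 10000, C1 = 2e-8, R2 = 2000, C2 = 6e-8, R3 = 3000)
  ),
  proposed = list(
    expression = "R1-(R2|CPE1)-(R3|C1)",
    defaults = c(R1 = 500, R2 = 5000, CPE1.P = 1e-6, CPE1.n = 0.8,
                 R3 = 2000, C1 = 1e-7)
  )
)

#' Built-in equivalent-circuit models for plant tissue
#'
#' The classical plant-tissue circuits plus a two-relaxation series model:
#' \describe{
#'   \item{`hayden`}{`Re|((Rm|Cm)-Ri)` — extracellular resistance Re in
#'     parallel with the membrane branch (membrane resistance Rm parallel to
#'     membrane capacitance Cm, in series with intracellular resistance Ri).}
#'   \item{`simplified_hayden`}{`Re|(Ri-Cm)` — Hayden with the membrane
#'     resistance dropped.}
#'   \item{`cpe_modified`}{`Re|(Ri-CPEm)` — the membrane capacitance replaced
#'     by a constant phase element, giving a depressed (semi-elliptical)
#'     Nyquist arc.}
#'   \item{`double_shell`}{`R1|(C1-(R2|(C2-R3)))` — cell wall resistance R1,
#'     plasma membrane capacitance C1, cytoplasm resistance R2, tonoplast
#'     capacitance C2, vacuole resistance R3.}
#'   \item{`proposed`}{`R1-(R2|CPE1)-(R3|C1)` — a series resistance with two
#'     relaxation blocks (one CPE-dispersive, one ideal-capacitive), the
#'     default dehydration-tracking topology of this package.  The element
#'     arrangement is configurable: any expression over R/C/CPE elements may
#'     be supplied to [parse_circuit()] instead.}
#' }
#' All built-ins are passive: with positive parameters, `Re(Z) > 0` and
#' `Im(Z) <= 0` at every frequency, and `|Z|` decreases from a low-frequency
#' plateau to a high-frequency plateau (beta-dispersion shape).
#'
#' @param name one of `builtin_model_names()`.
#' @return a [circuit_model] with physically plausible default parameters.
#' @examples
#' builtin_model("simplified_hayden")
#' @export
builtin_model <- function(name) {
  if (!name %in% names(builtin_circuit_table)) {
    stop(sprintf("unknown model '%s'; valid names: %s",
                 name, paste(names(builtin_circuit_table), collapse = ", ")),
         call. = FALSE)
  }
  entry <- builtin_circuit_table[[name]]
  model <- parse_circuit(entry$expression, name = name)
  model$parameters[names(entry$defaults)] <- entry$defaults
  model
}

#' @rdname builtin_model
#' @export
builtin_model_names <- function() names(builtin_circuit_table)

#' Resolve a model specification
#'
#' Accepts a `circuit_model`, a built-in model name, or a circuit expression
#' string, and returns a `circuit_model`.
#'
#' @param model a [circuit_model], built-in name, or expression string.
#' @export
as_circuit_model <- function(model) {
  if (inherits(model, "circuit_model")) return(model)
  if (is.character(model) && length(model) == 1) {
    if (model %in% names(builtin_circuit_table)) return(builtin_model(model))
    return(parse_circuit(model))
  }
  stop("model must be a circuit_model, a built-in name, or an expression string",
       call. = FALSE)
}
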