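#' Transition rate specifications
#'
#' Each transition of a simulated net carries a rate specification.  Four
#' kinds exist:
#' \describe{
#'   \item{`rate_stochastic(c)`}{a stochastic rate constant `c`, used
#'     directly as the per-combination event rate (SSA/tau) or as the
#'     exponential firing rate lambda (stochastic mode).}
#'   \item{`rate_mass_action(k)`}{a deterministic mass-action constant `k`
#'     in M^-(x-1) s^-1, converted once to `c` via
#'     [mass_action_to_stochastic()] when the simulation is set up.}
#'   \item{`rate_expression(text, units)`}{a mathematical expression over
#'     `Time` and non-constant place names, re-evaluated after every
#'     simulation step.}
#'   \item{`rate_conditional(text, units)`}{a conditional expression
#'     (see [parse_conditional()]), re-evaluated after every step.}
#' }
#' For expression-valued rates, `units = "mass_action"` means each evaluated
#' value is interpreted in deterministic units and multiplied by the same
#' `prod(f!) / (V N_A)^(x-1)` factor as a fixed mass-action constant;
#' `units = "stochastic"` uses the value as `c` directly.
#'
#' @param c,k a single non-negative number.
#' @param text expression text (parsed immediately; syntax errors are
#'   reported at construction).
#' @param units `"mass_action"` or `"stochastic"`.
#' @return An object of class `rate_spec`.
#' @name rate_spec
NULL

#' @rdname rate_spec
#' @export
rate_stochastic <- function(c) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c), c >= 0)
  structure(list(kind = "stochastic", value = c), class = "rate_spec")
}

#' @rdname rate_spec
#' @export
rate_mass_action <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k >= 0)
  structure(list(kind = "mass_action", value = k), class = "rate_spec")
}

#' @rdname rate_spec
#' @export
rate_expression <- function(text, units = c("mass_action", "stochastic")) {
  units <- match.arg(units)
  expr <- parse_expression(text)
  structure(list(kind = "expression", text = text, units = units,
                 expr = expr),
            class = "rate_spec")
}

#' @rdname rate_spec
#' @export
rate_conditional <- function(text, units = c("mass_action", "stochastic")) {
  units <- match.arg(units)
  expr <- parse_conditional(text)
  structure(list(kind = "conditional", text = text, units = units,
                 expr = expr),
            class = "rate_spec")
}

#' @export
print.rate_spec <- function(x, ...) {
  if (x$kind %in% c("stochastic", "mass_action")) {
    cat("rate (", x$kind, "): ", x$value, "\n", sep = "")
  } else {
    cat("rate (", x$kind, ", ", x$units, " units): ", x$text, "\n", sep = "")
  }
  invisible(x)
}

# normalise a rates argument: a named list of rate_spec or bare numbers
# (interpreted as stochastic constants), covering every transition
.normalise_rates <- function(rates, net) {
  if (is.numeric(rates)) rates <- as.list(rates)
  if (!is.list(rates) || is.null(names(rates))) {
    stop("rates must be a named list (one entry per transition)")
  }
  unknown <- setdiff(names(rates), net$transitions)
  if (length(unknown)) {
    stop("rates given for unknown transition(s): ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(net$transitions, names(rates))
  if (length(missing)) {
    stop("no rate specified for transition(s): ",
         paste(missing, collapse = ", "))
  }
  out <- lapply(rates[net$transitions], function(r) {
    if (inherits(r, "rate_spec")) r else rate_stochastic(as.numeric(r))
  })
  names(out) <- net$transitions
  out
}
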