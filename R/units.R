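#' Conversion context: reaction volume and Avogadro constant
#'
#' Stochastic simulation operates on molecule counts, while biological
#' parameters are usually given as molar concentrations and mass-action rate
#' constants.  The conversion needs the reaction volume `V` (liters) and the
#' Avogadro constant `N_A`.  The default `N_A = 6e23` is the rounded value
#' conventionally used with such models; pass `avogadro = 6.02214076e23` for
#' the exact constant.
#'
#' @param volume reaction volume in liters, positive.
#' @param avogadro Avogadro constant in mol^-1, positive.
#' @return An object of class `conversion_context`.
#' @export
conversion_context <- function(volume, avogadro = 6e23) {
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("volume must be a single positive number (liters)")
  }
  if (!is.numeric(avogadro) || length(avogadro) != 1L ||
      !is.finite(avogadro) || avogadro <= 0) {
    stop("avogadro must be a single positive number")
  }
  structure(list(volume = volume, avogadro = avogadro),
            class = "conversion_context")
}

#' Convert a molar concentration to a molecule count
#'
#' Applies `n = N_A * conc * V` and rounds to the nearest integer (ties to
#' even).
#'
#' @param conc concentration in mol/l, non-negative (vectorised).
#' @param ctx a [conversion_context()].
#' @return Non-negative integral count(s), as numeric to allow counts beyond
#'   the integer range.
#' @examples
#' ctx <- conversion_context(volume = 1e-9)
#' concentration_to_molecules(9e-13, ctx)  # 540
#' @export
concentration_to_molecules <- function(conc, ctx) {
  stopifnot(inherits(ctx, "conversion_context"))
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentration must be non-negative and finite")
  }
  round(ctx$avogadro * conc * ctx$volume)
}

#' Convert a molecule count back to a molar concentration
#'
#' Inverse of [concentration_to_molecules()] up to rounding:
#' `conc = n / (N_A * V)`.
#'
#' @param n molecule count(s), non-negative.
#' @param ctx a [conversion_context()].
#' @return Concentration(s) in mol/l.
#' @export
molecules_to_concentration <- function(n, ctx) {
  stopifnot(inherits(ctx, "conversion_context"))
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("molecule count must be non-negative and finite")
  }
  n / (ctx$avogadro * ctx$volume)
}

#' Order of the reaction modelled by a transition
#'
#' The reaction order is the total number of reactant molecules consumed per
#' firing: the sum of the pre-arc weights.  Source transitions (no
#' pre-places) have order 0; a mass-action constant of an order-`x` reaction
#' carries units of M^-(x-1) s^-1.
#'
#' @param net a [petri_net()].
#' @param t transition identifier.
#' @return Integer order `x >= 0`.
#' @export
reaction_order <- function(net, t) {
  .check_transition(net, t)
  as.integer(sum(net$pre[, t]))
}

#' Convert a mass-action rate constant to a stochastic rate constant
#'
#' For a transition of order `x` with pre-arc weights `f(P_j, t)`, the
#' stochastic rate constant is
#' \deqn{c = k \prod_j f(P_j, t)! / (V N_A)^{x-1}.}
#' The familiar specialisations follow: `c = k V N_A` for order 0, `c = k`
#' for order 1, `c = k/(V N_A)` for `A + B -> C`, and `c = 2k/(V N_A)` for
#' `2A -> B`.
#'
#' @param k mass-action rate constant in M^-(x-1) s^-1; a single
#'   non-negative number.
#' @param net a [petri_net()].
#' @param t transition identifier.
#' @param ctx a [conversion_context()].
#' @return The stochastic rate constant `c`.
#' @export
mass_action_to_stochastic <- function(k, net, t, ctx) {
  stopifnot(inherits(ctx, "conversion_context"))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("k must be a single non-negative mass-action rate constant; ",
         "expression-valued rates are converted at evaluation time")
  }
  .check_transition(net, t)
  k * .stochastic_factor(net, t, ctx)
}

# prod(f!) / (V N_A)^(x-1): multiplies an evaluated mass-action value to
# give the stochastic constant; shared with expression-valued rates
.stochastic_factor <- function(net, t, ctx) {
  w <- net$pre[, t]
  w <- w[w > 0]
  x <- sum(w)
  prod(factorial(w)) / (ctx$volume * ctx$avogadro)^(x - 1)
}
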