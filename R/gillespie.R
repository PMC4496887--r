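## Exact SSA (Gillespie direct method with a dependency graph) and the
## approximate SSA (tau-leaping with critical reactions).

#' Propensity (reaction rate) of a transition
#'
#' The propensity is the stochastic rate constant times the number of
#' distinct reactant combinations:
#' \deqn{r = c \prod_{p \in pre(t)} \binom{m(p)}{f(p,t)}}
#' with the empty product equal to 1 for source transitions.  Constant
#' places contribute their current token counts but are not consumed on
#' firing.  A transition is enabled iff its propensity is positive
#' (given `c > 0`); insufficient tokens give 0.
#'
#' @param net a [petri_net()].
#' @param m named marking vector.
#' @param t transition identifier.
#' @param c stochastic rate constant, non-negative.
#' @return The propensity, a non-negative number.
#' @examples
#' net <- petri_net(c("A", "B", "C"), "bind",
#'   arcs = data.frame(from = c("A", "B", "bind"), to = c("bind", "bind", "C")))
#' propensity(net, c(A = 10, B = 5, C = 0), "bind", 0.1)  # 5
#' @export
propensity <- function(net, m, t, c) {
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0)
  .check_transition(net, t)
  m <- .check_marking(net, m)
  w <- net$pre[, t]
  ip <- which(w > 0)
  if (!length(ip)) return(c)
  c * prod(choose(m[ip], w[ip]))
}

#' Waiting time of the direct method
#'
#' Inverts a uniform draw into the exponential waiting time
#' `dt = -ln(1 - u1) / a0` where `a0` is the sum of all propensities.
#'
#' @param a0 total propensity, strictly positive.
#' @param u1 a uniform(0,1) variate, in `[0, 1)`.
#' @return The waiting time `dt >= 0`.
#' @export
draw_waiting_time <- function(a0, u1) {
  if (!is.finite(a0) || a0 <= 0) {
    stop("total propensity a0 must be positive (detect dead markings first)")
  }
  if (u1 < 0 || u1 >= 1) stop("u1 must lie in [0, 1)")
  -log1p(-u1) / a0
}

#' Reaction selection of the direct method
#'
#' Returns the unique index `i` with
#' `sum(r[1:(i-1)]) < u2 * sum(r) <= sum(r[1:i])`, in the fixed transition
#' ordering of the net definition.
#'
#' @param rates numeric vector of propensities.
#' @param u2 a uniform(0,1) variate.
#' @return The selected index.
#' @export
select_reaction <- function(rates, u2) {
  a0 <- sum(rates)
  if (a0 <= 0) stop("all propensities are zero; no reaction can be selected")
  .select_idx(rates, u2, a0)
}

.select_idx <- function(rates, u2, a0) {
  target <- u2 * a0
  acc <- 0
  for (i in seq_along(rates)) {
    acc <- acc + rates[i]
    if (target <= acc && rates[i] > 0) return(i)
  }
  # numerical edge: return last positive entry
  max(which(rates > 0))
}

#' Dependency graph of a net
#'
#' For each transition `t`, the set of transitions whose propensity may
#' change when `t` fires: all transitions with a pre-place whose token count
#' changes (plus `t` itself).  A conservative over-approximation is
#' permitted; an under-approximation is not.  Transitions with a constant
#' pre-place are additionally flagged for recomputation on every step (the
#' constant place may be expression-driven), returned as the
#' `"constant_post"` attribute.
#'
#' @param net a [petri_net()].
#' @return Named list mapping each transition to a character vector of
#'   dependent transitions, with attribute `constant_post`.
#' @export
build_dependency_graph <- function(net) {
  nt <- length(net$transitions)
  delta <- net$post - net$pre
  delta[net$constant, ] <- 0
  dep <- vector("list", nt)
  names(dep) <- net$transitions
  for (j in seq_len(nt)) {
    ch <- which(delta[, j] != 0)
    hit <- if (length(ch)) {
      which(colSums(net$pre[ch, , drop = FALSE] > 0) > 0)
    } else integer()
    dep[[j]] <- net$transitions[sort(unique(c(j, hit)))]
  }
  cp <- which(colSums(net$pre[net$constant, , drop = FALSE] > 0) > 0)
  attr(dep, "constant_post") <- net$transitions[cp]
  dep
}

#' Exact SSA step (direct method)
#'
#' Computes the total propensity, draws the waiting time and the reaction
#' by inversion of two uniforms, executes the reaction (constant places are
#' untouched), advances the clock, re-evaluates expression-valued
#' quantities (constant places and expression rates) and recomputes only
#' the propensities of the fired transition's dependency-graph neighbours
#' (plus the always-recompute set).  A zero total propensity terminates the
#' run with status `"dead marking"`.
#'
#' @param state a [sim_state()] in `"ssa"` or `"tau"` mode.
#' @param t_end stop time: if the next event falls beyond it, the clock
#'   moves to `t_end` and nothing fires (status `"t_end"`).
#' @return The state, invisibly.
#' @export
step_exact <- function(state, t_end = Inf) {
  stopifnot(inherits(state, "sim_state"))
  if (state$status != "running") return(invisible(state))
  a0 <- sum(state$a)
  if (a0 <= 0) {
    state$status <- "dead marking"
    return(invisible(state))
  }
  dt <- .rexp_inv(a0)
  if (state$clock + dt > t_end) {
    state$clock <- t_end
    state$status <- "t_end"
    .post_step_expressions(state)
    .update_propensities(state, seq_along(state$a))
    .record(state, NA_character_)
    return(invisible(state))
  }
  u2 <- stats::runif(1)
  i <- .select_idx(state$a, u2, a0)
  state$clock <- state$clock + dt
  state$m <- state$m + state$delta[, i]
  state$firing_counts[i] <- state$firing_counts[i] + 1L
  state$step_count <- state$step_count + 1L
  .post_step_expressions(state)
  idx <- if (state$use_dep) state$dep_union[[i]] else seq_along(state$a)
  .update_propensities(state, idx)
  .record(state, state$t_names[i])
  invisible(state)
}

#' Is a reaction critical?
#'
#' A reaction is critical when its reactants do not allow it to fire at
#' least `critical_threshold` (default 20) consecutive times: the maximum
#' number of firings is `min(floor(m(p) / f(p,t)))` over its pre-places
#' (infinite for source transitions).  Critical reactions are simulated
#' exactly within the tau-leaping algorithm to avoid negative populations.
#'
#' @param net a [petri_net()].
#' @param m named marking.
#' @param t transition identifier.
#' @param cfg a [leap_config()].
#' @return `TRUE` if critical.
#' @export
classify_critical <- function(net, m, t, cfg = leap_config()) {
  .check_transition(net, t)
  m <- .check_marking(net, m)
  w <- net$pre[, t]
  ip <- which(w > 0)
  if (!length(ip)) return(FALSE)
  max_firings <- min(floor(m[ip] / w[ip]))
  max_firings < cfg$critical_threshold
}

.critical_vec <- function(st, cfg) {
  vapply(seq_along(st$t_names), function(j) {
    ip <- st$pre_idx[[j]]
    if (!length(ip)) return(FALSE)
    min(floor(st$m[ip] / st$pre_w[[j]])) < cfg$critical_threshold
  }, logical(1))
}

#' Leap length for the non-critical reactions
#'
#' Selects the largest tau such that no propensity is expected to change by
#' more than a fraction `epsilon` during the leap, using the mean/variance
#' bound on the state change: for each reactant species `i`,
#' `tau <= min(max(eps*x_i/g_i, 1)/|mu_i|, max(eps*x_i/g_i, 1)^2/sigma2_i)`
#' with `mu_i` and `sigma2_i` the first two moments of the net change of
#' species `i` per unit time over the non-critical reactions and `g_i` the
#' highest order of reaction in which `i` appears as a reactant.  Returns
#' `Inf` when no non-critical reaction has positive propensity.
#'
#' @param state a [sim_state()] in `"tau"` mode.
#' @param cfg a [leap_config()].
#' @return The leap candidate `tau1 > 0` (possibly `Inf`).
#' @export
select_tau_noncritical <- function(state, cfg = state$leap) {
  stopifnot(inherits(state, "sim_state"))
  crit <- .critical_vec(state, cfg)
  .tau1(state, cfg, crit)
}

.tau1 <- function(st, cfg, crit) {
  nc <- which(!crit & st$a > 0)
  if (!length(nc)) return(Inf)
  eps <- cfg$epsilon
  # reactant species of any reaction, non-constant
  species <- which(!st$const & rowSums(st$pre) > 0)
  if (!length(species)) return(Inf)
  tau <- Inf
  for (i in species) {
    di <- st$delta[i, nc]
    ai <- st$a[nc]
    mu <- sum(di * ai)
    sig2 <- sum(di * di * ai)
    if (mu == 0 && sig2 == 0) next
    # highest order of reaction where species i is a reactant
    g <- 1
    for (j in which(st$pre[i, ] > 0)) {
      x <- sum(st$pre[, j])
      gj <- x
      if (x == 2 && st$pre[i, j] == 2) {
        gj <- if (st$m[i] > 1) 2 + 1 / (st$m[i] - 1) else Inf
      } else if (x == 3 && st$pre[i, j] >= 2) {
        gj <- if (st$m[i] > 1) 3 + 1 / (st$m[i] - 1) else Inf
      }
      g <- max(g, gj)
    }
    bound <- max(eps * st$m[i] / g, 1)
    if (mu != 0) tau <- min(tau, bound / abs(mu))
    if (sig2 > 0) tau <- min(tau, bound * bound / sig2)
  }
  tau
}

#' Tau-leaping step (approximate SSA with critical reactions)
#'
#' Classifies every reaction as critical or non-critical, selects the leap
#' candidate `tau1` for the non-critical set
#' ([select_tau_noncritical()]) and draws `tau2 ~ Exp(sum of critical
#' propensities)` (infinite when no critical reaction can fire).  If
#' `tau1 < tau2` no critical reaction occurs and each non-critical reaction
#' fires `Poisson(r * tau1)` times; otherwise one critical reaction chosen
#' by the direct method fires once and each non-critical reaction fires
#' `Poisson(r * tau2)` times.  A leap that would drive any token count
#' negative is rejected: `tau1` is halved and the step retried (at most 10
#' halvings, then one exact step is taken instead).  Nets in which every
#' reaction is critical are therefore simulated exactly, with the same RNG
#' discipline as [step_exact()].
#'
#' @param state a [sim_state()] in `"tau"` mode.
#' @param cfg a [leap_config()].
#' @param t_end stop time (leaps are truncated at the horizon).
#' @return The state, invisibly.
#' @export
step_tau_leap <- function(state, cfg = state$leap, t_end = Inf) {
  stopifnot(inherits(state, "sim_state"))
  if (state$status != "running") return(invisible(state))
  a0 <- sum(state$a)
  if (a0 <= 0) {
    state$status <- "dead marking"
    return(invisible(state))
  }
  crit <- .critical_vec(state, cfg)
  tau1 <- .tau1(state, cfg, crit)
  crit_idx <- which(crit & state$a > 0)
  a0c <- sum(state$a[crit_idx])
  tau2 <- if (a0c > 0) .rexp_inv(a0c) else Inf
  nc_idx <- which(!crit & state$a > 0)
  if (is.infinite(tau1) && is.infinite(tau2)) {
    # no reactant species constrains the leap (pure source reactions):
    # bounded only by the simulation horizon
    if (!is.finite(t_end)) {
      stop("unbounded leap: no critical reaction and no reactant species; ",
           "a finite t_end is required")
    }
    tau1 <- max(t_end - state$clock, 0)
  }

  halvings <- 0L
  repeat {
    if (tau1 < tau2) {
      tau <- tau1
      fire_crit <- NA_integer_
    } else {
      tau <- tau2
      # one uniform is always consumed, mirroring the exact direct method
      u2 <- stats::runif(1)
      fire_crit <- crit_idx[.select_idx(state$a[crit_idx], u2, a0c)]
    }
    truncated <- FALSE
    if (state$clock + tau >= t_end) {
      tau <- t_end - state$clock
      fire_crit <- NA_integer_   # the critical event lies beyond the horizon
      truncated <- TRUE
    }
    k <- integer(length(nc_idx))
    if (length(nc_idx) && tau > 0) {
      k <- stats::rpois(length(nc_idx), state$a[nc_idx] * tau)
    }
    dm <- numeric(length(state$m))
    if (length(nc_idx)) {
      dm <- as.numeric(state$delta[, nc_idx, drop = FALSE] %*% k)
    }
    if (!is.na(fire_crit)) dm <- dm + state$delta[, fire_crit]
    newm <- state$m + dm
    if (all(newm >= 0)) {
      state$m <- newm
      state$clock <- state$clock + tau
      state$step_count <- state$step_count + 1L
      if (length(nc_idx)) {
        state$firing_counts[nc_idx] <- state$firing_counts[nc_idx] + k
      }
      fired <- character(0)
      if (!is.na(fire_crit)) {
        state$firing_counts[fire_crit] <- state$firing_counts[fire_crit] + 1L
        fired <- state$t_names[fire_crit]
      }
      if (truncated) state$status <- "t_end"
      .post_step_expressions(state)
      .update_propensities(state, seq_along(state$a))
      .record(state, paste(fired, collapse = ","))
      return(invisible(state))
    }
    halvings <- halvings + 1L
    if (halvings > 10L) {
      return(step_exact(state, t_end = t_end))
    }
    tau1 <- tau / 2
  }
}
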