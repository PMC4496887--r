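## Token-game and constant-rate stochastic engines.

#' Asynchronous simulation step
#'
#' Fires exactly one enabled transition, chosen uniformly at random among
#' all enabled transitions.  No time is consumed; the step counter
#' increases by one.  If no transition is enabled the state is marked as a
#' dead marking and left unchanged.
#'
#' @param state a [sim_state()] in `"async"` mode.
#' @return The state, invisibly (mutated in place).
#' @export
step_async <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  if (state$status != "running") return(invisible(state))
  en <- .enabled_idx(state)
  if (!length(en)) {
    state$status <- "dead marking"
    return(invisible(state))
  }
  i <- if (length(en) == 1L) en else sample(en, 1L)
  state$m <- state$m + state$delta[, i]
  state$firing_counts[i] <- state$firing_counts[i] + 1L
  state$step_count <- state$step_count + 1L
  .post_step_expressions(state)
  .record(state, state$t_names[i])
  invisible(state)
}

#' Synchronous simulation step
#'
#' Selects a uniformly random subset of `ceiling(fraction * |A|)` of the
#' enabled transitions `A` and attempts to fire them in a uniformly random
#' order.  Each selected transition is re-checked against the evolving
#' marking and skipped if an earlier firing within the same step disabled
#' it -- this realises the competition of concurrent transitions for shared
#' tokens.  With `fraction = 1` the simulator tries to fire all enabled
#' transitions at once.
#'
#' @param state a [sim_state()] in `"sync"` mode.
#' @param fraction fraction of enabled transitions to select, in (0, 1].
#' @return The state, invisibly.
#' @export
step_sync <- function(state, fraction = state$fraction) {
  stopifnot(inherits(state, "sim_state"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (state$status != "running") return(invisible(state))
  en <- .enabled_idx(state)
  if (!length(en)) {
    state$status <- "dead marking"
    return(invisible(state))
  }
  k <- ceiling(fraction * length(en))
  sel <- if (length(en) == 1L) en else sample(en, k)
  fired <- character(0)
  for (i in sel) {
    if (all(state$pre[, i] <= state$m)) {
      state$m <- state$m + state$delta[, i]
      state$firing_counts[i] <- state$firing_counts[i] + 1L
      fired <- c(fired, state$t_names[i])
    }
  }
  state$step_count <- state$step_count + 1L
  .post_step_expressions(state)
  .record(state, paste(fired, collapse = ","))
  invisible(state)
}

#' Schedule a waiting time for a transition (stochastic mode)
#'
#' Draws an exponentially distributed waiting time `Exp(rate)` and stores
#' the absolute scheduled firing time `clock + dt` for the transition.
#'
#' @param state a [sim_state()] in `"stochastic"` mode.
#' @param t transition identifier.
#' @param rate the firing rate lambda, strictly positive.
#' @return The state, invisibly.
#' @export
schedule_stochastic <- function(state, t, rate) {
  stopifnot(inherits(state, "sim_state"))
  .check_transition(state$net, t)
  if (!is.finite(rate) || rate <= 0) stop("rate lambda must be positive")
  j <- match(t, state$t_names)
  state$pending[j] <- state$clock + .rexp_inv(rate)
  invisible(state)
}

#' Constant-rate stochastic simulation step
#'
#' Every enabled transition holds a pending firing time drawn as
#' `clock + Exp(lambda)`.  The transition with the smallest pending time
#' fires (ties broken uniformly at random) and the clock advances to that
#' time.  Pending times are kept for transitions whose pre-place token
#' counts did not change (valid by the memorylessness of the exponential)
#' and redrawn for the fired transition, for transitions whose pre-place
#' counts changed, for newly enabled transitions and for all
#' post-transitions of constant places.
#'
#' @param state a [sim_state()] in `"stochastic"` mode.
#' @param t_end stop time: if the earliest pending time exceeds it, the
#'   clock moves to `t_end` and no transition fires.
#' @return The state, invisibly.
#' @export
step_stochastic <- function(state, t_end = Inf) {
  stopifnot(inherits(state, "sim_state"))
  if (state$status != "running") return(invisible(state))
  cand <- which(!is.na(state$pending))
  if (!length(cand)) {
    state$status <- "dead marking"
    return(invisible(state))
  }
  tmin <- min(state$pending[cand])
  if (tmin > t_end) {
    state$clock <- t_end
    state$status <- "t_end"
    .post_step_expressions(state)
    .record(state, NA_character_)
    return(invisible(state))
  }
  tied <- cand[state$pending[cand] == tmin]
  i <- if (length(tied) == 1L) tied else sample(tied, 1L)
  state$clock <- tmin
  changed <- which(state$delta[, i] != 0)
  state$m <- state$m + state$delta[, i]
  state$firing_counts[i] <- state$firing_counts[i] + 1L
  state$step_count <- state$step_count + 1L
  const_before <- state$m[state$const_expr_idx]
  .post_step_expressions(state)
  if (length(state$const_expr_idx)) {
    moved <- state$const_expr_idx[state$m[state$const_expr_idx] !=
                                    const_before]
    changed <- union(changed, moved)
  }
  # refresh pending times
  recompute <- state$always_idx
  if (length(changed)) {
    hit <- which(colSums(
      state$pre[changed, , drop = FALSE] > 0) > 0)
    recompute <- union(recompute, hit)
  }
  recompute <- union(recompute, i)
  en <- .enabled_idx(state)
  enabled <- logical(length(state$t_names))
  enabled[en] <- TRUE
  for (j in seq_along(state$t_names)) {
    if (!enabled[j]) {
      state$pending[j] <- NA_real_
    } else if (is.na(state$pending[j]) || j %in% recompute) {
      state$pending[j] <- state$clock + .rexp_inv(state$c_eff[j])
    }
  }
  .record(state, state$t_names[i])
  invisible(state)
}
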