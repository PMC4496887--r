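## Simulation state and step-level engines.
##
## A `sim_state` is an environment (reference semantics: step functions
## mutate it in place and return it invisibly) holding the net, the current
## marking, the clock, propensities / pending firing times, the RNG is R's
## global stream (seed it with set.seed before constructing the state for
## reproducible runs).

#' Tau-leaping configuration
#'
#' @param critical_threshold reactions whose reactants allow fewer than this
#'   many consecutive firings are *critical* and simulated exactly;
#'   default 20.
#' @param epsilon bound on the relative change of any propensity during one
#'   leap, used by the tau-selection procedure; default 0.03.
#' @return An object of class `leap_config`.
#' @export
leap_config <- function(critical_threshold = 20, epsilon = 0.03) {
  stopifnot(critical_threshold >= 1, epsilon > 0, epsilon < 1)
  structure(list(critical_threshold = critical_threshold, epsilon = epsilon),
            class = "leap_config")
}

# exponential draw by inversion of a single uniform; used by every engine so
# that modes sharing the same mathematical step consume identical RNG draws
.rexp_inv <- function(rate) -log1p(-stats::runif(1)) / rate

#' Create a simulation state
#'
#' Builds the mutable state all step functions ([step_async()],
#' [step_sync()], [step_stochastic()], [step_exact()], [step_tau_leap()])
#' operate on.  Seed the RNG with `set.seed()` immediately before calling
#' this for reproducible runs (the constructor itself draws waiting times in
#' `"stochastic"` mode).
#'
#' @param net a [petri_net()].
#' @param marking named vector of initial token counts (non-constant places;
#'   constant places with expressions are initialised from the expression at
#'   `Time = 0`).
#' @param rates named list of [rate_spec] objects (or bare numbers, taken as
#'   stochastic constants), one per transition.  Ignored by the async and
#'   sync modes.
#' @param mode one of `"ssa"`, `"tau"`, `"stochastic"`, `"async"`, `"sync"`.
#' @param ctx a [conversion_context()]; required when any rate is in
#'   mass-action units.
#' @param constant_expressions named list (by constant place) of expression
#'   texts, [parse_expression()] or [parse_conditional()] objects driving
#'   constant-place token counts; re-evaluated after every step.
#' @param fraction sync mode: fraction of the enabled transitions selected
#'   to fire per step, in (0, 1].
#' @param leap a [leap_config()].
#' @param use_dependency_graph recompute only the propensities that the
#'   fired transition can have changed (`TRUE`, default) or all of them;
#'   the two settings produce bitwise-identical trajectories.
#' @return An environment of class `sim_state`.  Fields of interest:
#'   `clock`, `step_count`, `status` (`"running"`, `"dead marking"`,
#'   `"t_end"`), `firing_counts`; read the marking with [sim_marking()].
#' @export
sim_state <- function(net, marking, rates = NULL,
                      mode = c("ssa", "tau", "stochastic", "async", "sync"),
                      ctx = NULL, constant_expressions = list(),
                      fraction = 1, leap = leap_config(),
                      use_dependency_graph = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "petri_net"))
  if (mode == "sync" && (fraction <= 0 || fraction > 1)) {
    stop("fraction must be in (0, 1]")
  }
  np <- length(net$places); nt <- length(net$transitions)
  st <- new.env(parent = emptyenv())
  class(st) <- "sim_state"
  st$net <- net
  st$mode <- mode
  st$fraction <- fraction
  st$leap <- leap
  st$use_dep <- isTRUE(use_dependency_graph)
  st$p_names <- net$places
  st$t_names <- net$transitions
  st$const <- unname(net$constant)
  st$nonconst_idx <- which(!st$const)
  st$pre <- unname(net$pre)
  st$post <- unname(net$post)
  delta <- st$post - st$pre
  delta[st$const, ] <- 0
  st$delta <- delta
  st$pre_idx <- lapply(seq_len(nt), function(j) which(st$pre[, j] > 0))
  st$pre_w <- lapply(seq_len(nt), function(j) st$pre[st$pre_idx[[j]], j])

  m <- .check_marking(net, marking)
  st$m <- unname(as.numeric(m))

  # constant-place expressions (a plain expression is the degenerate
  # unconditional case of a conditional expression)
  ce <- constant_expressions
  if (length(ce)) {
    bad <- setdiff(names(ce), net$places[net$constant])
    if (length(bad)) {
      stop("constant_expressions given for non-constant or unknown place(s): ",
           paste(bad, collapse = ", "))
    }
  }
  st$const_expr_idx <- match(names(ce), net$places)
  st$const_exprs <- lapply(ce, function(x) {
    if (is.character(x)) x <- parse_conditional(x)
    if (inherits(x, "pn_expression")) {
      x <- parse_conditional(x$text)
    }
    stopifnot(inherits(x, "pn_conditional"))
    legal <- c(net$places[!net$constant], "Time")
    bad <- setdiff(x$vars, legal)
    if (length(bad)) {
      stop("constant-place expression uses illegal variable(s): ",
           paste(bad, collapse = ", "),
           " (only Time and non-constant place names are allowed)")
    }
    x
  })

  # rates
  if (mode %in% c("ssa", "tau", "stochastic")) {
    if (is.null(rates)) stop("mode ", mode, " requires transition rates")
    rates <- .normalise_rates(rates, net)
    c_eff <- numeric(nt)
    dyn <- list()
    for (j in seq_len(nt)) {
      r <- rates[[j]]
      if (r$kind == "stochastic") {
        c_eff[j] <- r$value
      } else if (r$kind == "mass_action") {
        if (is.null(ctx)) {
          stop("mass-action rates require a conversion_context (ctx)")
        }
        c_eff[j] <- r$value * .stochastic_factor(net, net$transitions[j], ctx)
      } else {
        if (mode == "stochastic") {
          stop("the constant-rate stochastic mode takes a fixed rate ",
               "lambda per transition; expression-valued rates belong to ",
               "the SSA modes")
        }
        factor <- 1
        if (r$units == "mass_action") {
          if (is.null(ctx)) {
            stop("mass-action-unit expression rates require a ",
                 "conversion_context (ctx)")
          }
          factor <- .stochastic_factor(net, net$transitions[j], ctx)
        }
        ex <- r$expr
        if (inherits(ex, "pn_expression")) ex <- parse_conditional(ex$text)
        legal <- c(net$places[!net$constant], "Time")
        bad <- setdiff(ex$vars, legal)
        if (length(bad)) {
          stop("rate expression for ", net$transitions[j],
               " uses illegal variable(s): ", paste(bad, collapse = ", "))
        }
        dyn[[length(dyn) + 1L]] <- list(j = j, expr = ex, factor = factor)
      }
    }
    st$c_eff <- c_eff
    st$dyn_rates <- dyn
    st$rates <- rates
  } else {
    st$c_eff <- numeric(nt)
    st$dyn_rates <- list()
    st$rates <- NULL
  }
  st$has_dynamic <- length(st$dyn_rates) > 0 || length(st$const_exprs) > 0

  # dependency bookkeeping: after firing j, recompute propensities of
  # dep_idx[[j]]; always_idx are recomputed every step (expression-valued
  # rates and post-transitions of constant places)
  changed <- lapply(seq_len(nt), function(j) {
    which(delta[, j] != 0)
  })
  st$dep_idx <- lapply(seq_len(nt), function(j) {
    ch <- changed[[j]]
    if (!length(ch)) return(j)
    hit <- which(colSums(st$pre[ch, , drop = FALSE] > 0) > 0)
    sort(unique(c(j, hit)))
  })
  const_pre <- which(colSums(st$pre[st$const, , drop = FALSE] > 0) > 0)
  st$always_idx <- sort(unique(c(
    const_pre,
    vapply(st$dyn_rates, function(d) d$j, 1L))))
  # per-transition union with the always-recompute set (hot path)
  st$dep_union <- lapply(st$dep_idx, function(d) {
    sort(unique(c(d, st$always_idx)))
  })
  # non-constant places actually referenced by any expression
  used <- unique(c(
    unlist(lapply(st$const_exprs, `[[`, "vars")),
    unlist(lapply(st$dyn_rates, function(d) d$expr$vars))))
  st$bind_places <- intersect(match(used, net$places),
                              st$nonconst_idx)

  st$clock <- 0
  st$step_count <- 0L
  st$status <- "running"
  st$firing_counts <- stats::setNames(integer(nt), st$t_names)
  st$warned_clamp <- FALSE

  # binding environment for expressions
  st$bind_env <- new.env(parent = .expr_base_env)

  # initial expression evaluation (Time = 0) sets constant-place values
  .post_step_expressions(st)

  if (mode %in% c("ssa", "tau")) {
    st$a <- numeric(nt)
    .update_propensities(st, seq_len(nt))
  } else if (mode == "stochastic") {
    if (any(st$c_eff <= 0)) {
      stop("stochastic mode requires a positive rate lambda for every ",
           "transition")
    }
    st$pending <- rep(NA_real_, nt)
    en <- .enabled_idx(st)
    for (j in en) st$pending[j] <- st$clock + .rexp_inv(st$c_eff[j])
  }

  # trajectory recording buffers: fixed-size chunks, flushed to a list, so
  # that per-event assignment never copies the full history
  st$chunk_size <- 512L
  st$ch_t <- numeric(st$chunk_size)
  st$ch_f <- character(st$chunk_size)
  st$ch_m <- matrix(0, st$chunk_size, np)
  st$ch_n <- 0L
  st$done_chunks <- list()
  st$rec_n <- 0L
  .record(st, NA_character_)
  st
}

#' Current marking of a simulation state
#'
#' @param state a [sim_state()].
#' @return Named vector of token counts.
#' @export
sim_marking <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  stats::setNames(state$m, state$p_names)
}

#' @export
print.sim_state <- function(x, ...) {
  cat("sim_state (", x$mode, "): clock ", x$clock, ", ",
      x$step_count, " steps, status ", x$status, "\n", sep = "")
  invisible(x)
}

.enabled_idx <- function(st) {
  which(colSums(st$pre > st$m) == 0)
}

# evaluate constant-place and rate expressions after a step; the Time
# variable is the clock for timed modes and the step count for the token
# game modes
.post_step_expressions <- function(st) {
  if (!st$has_dynamic) return(invisible())
  tvar <- if (st$mode == "async" || st$mode == "sync") st$step_count
          else st$clock
  env <- st$bind_env
  assign("Time", tvar, envir = env)
  for (i in st$bind_places) assign(st$p_names[i], st$m[i], envir = env)
  if (length(st$const_exprs)) {
    for (k in seq_along(st$const_exprs)) {
      v <- .eval_conditional_env(st$const_exprs[[k]], env)
      v <- round(v)
      if (v < 0) {
        if (!st$warned_clamp) {
          warning("constant-place expression produced a negative value; ",
                  "clamped to 0 (warning issued once per run)")
          st$warned_clamp <- TRUE
        }
        v <- 0
      }
      st$m[st$const_expr_idx[k]] <- v
    }
  }
  if (length(st$dyn_rates)) {
    for (d in st$dyn_rates) {
      v <- .eval_conditional_env(d$expr, env)
      st$c_eff[d$j] <- max(0, v * d$factor)
    }
  }
  invisible()
}

# conditional evaluation against a prepared environment (hot path)
.eval_conditional_env <- function(cexpr, env) {
  for (cs in cexpr$cases) {
    ok <- TRUE
    for (cd in cs$conditions) {
      if (!isTRUE(eval(cd$lang, env))) { ok <- FALSE; break }
    }
    if (ok) return(as.numeric(eval(cs$value_lang, env)))
  }
  0
}

.update_propensities <- function(st, idx) {
  m <- st$m
  for (j in idx) {
    ip <- st$pre_idx[[j]]
    if (length(ip)) {
      st$a[j] <- st$c_eff[j] * prod(choose(m[ip], st$pre_w[[j]]))
    } else {
      st$a[j] <- st$c_eff[j]
    }
  }
  invisible()
}

.record <- function(st, fired) {
  n <- st$ch_n + 1L
  st$ch_t[n] <- if (st$mode == "async" || st$mode == "sync") st$step_count
                else st$clock
  st$ch_f[n] <- fired
  st$ch_m[n, ] <- st$m
  st$ch_n <- n
  st$rec_n <- st$rec_n + 1L
  if (n == st$chunk_size) .flush_chunk(st)
  invisible()
}

.flush_chunk <- function(st) {
  n <- st$ch_n
  if (!n) return(invisible())
  keep <- seq_len(n)
  st$done_chunks[[length(st$done_chunks) + 1L]] <-
    list(t = st$ch_t[keep], f = st$ch_f[keep],
         m = st$ch_m[keep, , drop = FALSE])
  st$ch_t <- numeric(st$chunk_size)
  st$ch_f <- character(st$chunk_size)
  st$ch_m <- matrix(0, st$chunk_size, ncol(st$ch_m))
  st$ch_n <- 0L
  invisible()
}

# full record history: list(t =, f =, m =)
.collect_records <- function(st) {
  .flush_chunk(st)
  chunks <- st$done_chunks
  list(t = unlist(lapply(chunks, `[[`, "t")),
       f = unlist(lapply(chunks, `[[`, "f")),
       m = do.call(rbind, lapply(chunks, `[[`, "m")))
}
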