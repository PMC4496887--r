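#' Define a simulation setup
#'
#' Bundles everything needed to (re)run a simulation: mode, end condition,
#' master seed, initial values (token counts and/or concentrations plus
#' volume), constant-place expressions, per-transition rate specifications,
#' tau-leaping configuration and the replicate count.  A setup serialises
#' losslessly to and from XML via [save_setup()]/[load_setup()].
#'
#' Exactly one of `steps` (number of firing events / token-game steps) and
#' `t_end` (simulated seconds; timed modes only) must be given.
#'
#' @param mode one of `"ssa"`, `"tau"`, `"stochastic"`, `"async"`, `"sync"`.
#' @param steps,t_end the end condition (give exactly one).
#' @param seed integer master seed for the pseudo random number generator;
#'   runs with the same setup and seed are bitwise identical.
#' @param marking named vector of initial token counts.
#' @param concentrations named vector of initial molar concentrations,
#'   converted with `volume`/`avogadro` at run time (requires `volume`).
#' @param volume reaction volume in liters (required when concentrations or
#'   mass-action rates are used).
#' @param avogadro Avogadro constant; defaults to 6e23.
#' @param rates named list of [rate_spec] objects (or bare stochastic
#'   constants), one per transition; not used by async/sync modes.
#' @param constant_expressions named list of expression texts (or parsed
#'   expressions) for constant places.
#' @param fraction sync mode firing fraction in (0, 1].
#' @param leap a [leap_config()].
#' @param replicates default replicate count for [run_replicates()].
#' @param use_dependency_graph see [sim_state()].
#' @return An object of class `simulation_setup`.
#' @export
simulation_setup <- function(mode = c("ssa", "tau", "stochastic", "async",
                                      "sync"),
                             steps = NULL, t_end = NULL, seed = 1L,
                             marking = NULL, concentrations = NULL,
                             volume = NULL, avogadro = 6e23,
                             rates = NULL, constant_expressions = list(),
                             fraction = 1, leap = leap_config(),
                             replicates = 1L,
                             use_dependency_graph = TRUE) {
  mode <- match.arg(mode)
  if (is.null(steps) == is.null(t_end)) {
    stop("give exactly one of `steps` and `t_end`")
  }
  if (!is.null(t_end) && mode %in% c("async", "sync")) {
    stop("the async and sync modes do not consume time; use `steps`")
  }
  if (!is.null(steps) && (steps < 1 || steps != round(steps))) {
    stop("steps must be a positive integer")
  }
  if (!is.null(t_end) && t_end <= 0) stop("t_end must be positive")
  if (replicates < 1) stop("replicate count must be >= 1")
  if (!is.null(concentrations) && is.null(volume)) {
    stop("initial concentrations require `volume`")
  }
  structure(
    list(mode = mode, steps = steps, t_end = t_end, seed = as.integer(seed),
         marking = marking, concentrations = concentrations,
         volume = volume, avogadro = avogadro, rates = rates,
         constant_expressions = constant_expressions, fraction = fraction,
         leap = leap, replicates = as.integer(replicates),
         use_dependency_graph = use_dependency_graph),
    class = "simulation_setup")
}

#' @export
print.simulation_setup <- function(x, ...) {
  end <- if (is.null(x$steps)) paste0("t_end = ", x$t_end, " s")
         else paste0(x$steps, " steps")
  cat("simulation setup: mode", x$mode, "|", end, "| seed", x$seed, "\n")
  invisible(x)
}

# resolve the initial marking of a setup against a net
.initial_marking <- function(net, setup) {
  m <- stats::setNames(rep(NA_real_, length(net$places)), net$places)
  if (!is.null(setup$marking)) {
    unknown <- setdiff(names(setup$marking), net$places)
    if (length(unknown)) {
      stop("marking refers to unknown place(s): ",
           paste(unknown, collapse = ", "))
    }
    m[names(setup$marking)] <- as.numeric(setup$marking)
  }
  if (!is.null(setup$concentrations)) {
    unknown <- setdiff(names(setup$concentrations), net$places)
    if (length(unknown)) {
      stop("concentrations refer to unknown place(s): ",
           paste(unknown, collapse = ", "))
    }
    ctx <- conversion_context(setup$volume, setup$avogadro)
    m[names(setup$concentrations)] <-
      concentration_to_molecules(as.numeric(setup$concentrations), ctx)
  }
  # expression-driven constant places are initialised by the expression
  m[names(setup$constant_expressions)] <- 0
  if (anyNA(m)) {
    stop("no initial value for place(s): ",
         paste(names(m)[is.na(m)], collapse = ", "))
  }
  if (any(m < 0)) stop("initial token counts must be non-negative")
  m
}

#' Run a simulation
#'
#' Executes the setup against the net and returns the trajectory together
#' with bookkeeping statistics (total fired steps, per-transition firing
#' counts, termination status).  Runs are deterministic given the setup
#' seed.
#'
#' @param net a [petri_net()].
#' @param setup a [simulation_setup()].
#' @return An object of class `pn_trajectory` with components
#'   \describe{
#'     \item{records}{data frame: `time` (seconds; or `step` for the token
#'       game modes) followed by one column per place; the first row is the
#'       initial marking.}
#'     \item{fired}{character vector, the transition(s) fired at each
#'       record (`NA` for the initial record).}
#'     \item{firing_counts}{named integer vector.}
#'     \item{steps}{total number of executed steps.}
#'     \item{status}{`"completed"`, `"dead marking"`.}
#'   }
#' @export
run <- function(net, setup) {
  stopifnot(inherits(net, "petri_net"), inherits(setup, "simulation_setup"))
  issues <- validate_net(net)
  if (length(issues)) {
    stop("net fails validation: ", paste(issues, collapse = "; "))
  }
  m0 <- .initial_marking(net, setup)
  ctx <- if (!is.null(setup$volume)) {
    conversion_context(setup$volume, setup$avogadro)
  }
  set.seed(setup$seed)
  state <- sim_state(net, m0, rates = setup$rates, mode = setup$mode,
                     ctx = ctx,
                     constant_expressions = setup$constant_expressions,
                     fraction = setup$fraction, leap = setup$leap,
                     use_dependency_graph = setup$use_dependency_graph)
  t_end <- if (is.null(setup$t_end)) Inf else setup$t_end
  max_steps <- if (is.null(setup$steps)) Inf else setup$steps
  stepper <- switch(setup$mode,
    async = function(s) step_async(s),
    sync = function(s) step_sync(s),
    stochastic = function(s) step_stochastic(s, t_end = t_end),
    ssa = function(s) step_exact(s, t_end = t_end),
    tau = function(s) step_tau_leap(s, t_end = t_end))
  while (state$status == "running" && state$step_count < max_steps) {
    stepper(state)
  }
  as_trajectory(state)
}

#' Convert a simulation state into a trajectory object
#'
#' @param state a [sim_state()].
#' @return A `pn_trajectory`; see [run()].
#' @export
as_trajectory <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  rec <- .collect_records(state)
  timecol <- if (state$mode %in% c("async", "sync")) "step" else "time"
  records <- data.frame(rec$t)
  names(records) <- timecol
  mm <- rec$m
  colnames(mm) <- state$p_names
  records <- cbind(records, as.data.frame(mm))
  status <- if (state$status == "dead marking") "dead marking" else "completed"
  structure(
    list(records = records, fired = rec$f,
         firing_counts = state$firing_counts,
         steps = state$step_count, status = status, mode = state$mode,
         time_column = timecol),
    class = "pn_trajectory")
}

#' @export
print.pn_trajectory <- function(x, ...) {
  cat("trajectory (", x$mode, "): ", x$steps, " steps, status ", x$status,
      "\n", sep = "")
  cat("final state:\n")
  print(utils::tail(x$records, 1))
  invisible(x)
}

#' Run seeded replicate simulations
#'
#' Runs `n` independent replicates of one setup.  Each replicate's seed is
#' derived deterministically from the master seed and the replicate index
#' (pairwise distinct), so results are a pure function of
#' `(setup, master_seed, index)` and independent of any execution order.
#' Up to hundreds of replicates of a small model complete in seconds.
#'
#' @param net a [petri_net()].
#' @param setup a [simulation_setup()].
#' @param n number of replicates (>= 1); defaults to `setup$replicates`.
#' @param master_seed integer master seed; defaults to `setup$seed`.
#' @return An object of class `pn_replicates`: list with `trajectories`
#'   (length `n`), `seeds`, `master_seed`.  Summaries over a common time
#'   grid are computed by [replicate_summary()].
#' @export
run_replicates <- function(net, setup, n = setup$replicates,
                           master_seed = setup$seed) {
  if (n < 1) stop("replicate count must be >= 1")
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  trajectories <- lapply(seq_len(n), function(i) {
    s <- setup
    s$seed <- seeds[i]
    run(net, s)
  })
  structure(list(trajectories = trajectories, seeds = seeds,
                 master_seed = as.integer(master_seed)),
            class = "pn_replicates")
}

#' @export
print.pn_replicates <- function(x, ...) {
  cat("replicate set:", length(x$trajectories), "trajectories, master seed",
      x$master_seed, "\n")
  invisible(x)
}

#' Per-place summary statistics of a replicate set
#'
#' Evaluates every trajectory on a common grid (piecewise-constant
#' interpolation: the state at grid point `g` is the last recorded state
#' with time <= `g`) and returns the per-place mean and standard deviation
#' across replicates at each grid point.
#'
#' @param reps a [run_replicates()] result.
#' @param at numeric grid (times or steps).  Default: 101 equally spaced
#'   points spanning the shortest replicate.
#' @return A data frame with columns `time` (or `step`), then `mean.<place>`
#'   and `sd.<place>` per place.
#' @export
replicate_summary <- function(reps, at = NULL) {
  stopifnot(inherits(reps, "pn_replicates"))
  trajs <- reps$trajectories
  tc <- trajs[[1]]$time_column
  if (is.null(at)) {
    tmax <- min(vapply(trajs, function(tr) max(tr$records[[tc]]), 0))
    at <- seq(0, tmax, length.out = 101)
  }
  places <- setdiff(names(trajs[[1]]$records), tc)
  per_rep <- lapply(trajs, function(tr) {
    idx <- findInterval(at, tr$records[[tc]])
    idx[idx < 1] <- 1
    as.matrix(tr$records[idx, places, drop = FALSE])
  })
  arr <- simplify2array(per_rep)           # grid x place x replicate
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  out <- data.frame(at)
  names(out) <- tc
  for (p in places) {
    out[[paste0("mean.", p)]] <- mu[, p]
    out[[paste0("sd.", p)]] <- sdv[, p]
  }
  out
}
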