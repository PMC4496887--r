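## Packaged models: the insulin-receptor (IR) recycling case study and a
## birth-death net with closed-form stationary behaviour for testing.

#' Parameters of the daily insulin profile
#'
#' A healthy person's plasma insulin follows a basal level with
#' postprandial peaks: meal intake triggers a rapid rise that decays back
#' to the basal level as a negative exponential.  The defaults are a basal
#' concentration of 6e-11 M, a peak of 3.6e-10 M, meals at 09:00, 13:00 and
#' 18:00 and a return to (within `tolerance` of) basal within 3 hours.
#'
#' @param basal basal concentration (M), positive.
#' @param peak peak postprandial concentration (M), greater than basal.
#' @param meal_times_h meal times as hours of the day, each in `[0, 24)`.
#' @param return_h duration of the decay back to basal, hours.
#' @param tolerance fraction of basal by which the profile may still exceed
#'   the basal level at the end of the decay window (sets the exponential
#'   time constant); default 0.05.
#' @return An object of class `insulin_profile_params`.
#' @export
insulin_profile_params <- function(basal = 6e-11, peak = 3.6e-10,
                                   meal_times_h = c(9, 13, 18),
                                   return_h = 3, tolerance = 0.05) {
  stopifnot(basal > 0, peak > basal, return_h > 0,
            tolerance > 0, tolerance < 1)
  if (any(meal_times_h < 0 | meal_times_h >= 24)) {
    stop("meal times must lie within the 24 h day")
  }
  structure(list(basal = basal, peak = peak,
                 meal_times_h = sort(meal_times_h),
                 return_h = return_h, tolerance = tolerance),
            class = "insulin_profile_params")
}

#' Conditional-expression text for the daily insulin profile
#'
#' Builds a conditional expression (see [parse_conditional()]) with one
#' time-gated case per meal and a final condition-free case for the basal
#' level -- four cases with the default three meals.  The expression
#' evaluates to molecule counts (the volume/Avogadro conversion is applied
#' to the concentrations) as a function of `Time` in seconds; `Time % 86400`
#' makes the profile repeat every 24 hours.  Within a meal window the value
#' decays as `basal + (peak - basal) * exp(-(t - t_meal)/tau)` with `tau`
#' chosen so the value is within `tolerance` of basal at the end of the
#' window.
#'
#' @param params an [insulin_profile_params()].
#' @param ctx a [conversion_context()]; default volume 1e-9 l.
#' @return A single character string.
#' @export
insulin_profile_expression <- function(params = insulin_profile_params(),
                                       ctx = conversion_context(1e-9)) {
  stopifnot(inherits(params, "insulin_profile_params"),
            inherits(ctx, "conversion_context"))
  meal_s <- params$meal_times_h * 3600
  dur <- params$return_h * 3600
  ends <- meal_s + dur
  if (any(ends[-length(ends)] > meal_s[-1]) || any(ends > 86400)) {
    stop("meal decay windows overlap (or run past midnight)")
  }
  n_basal <- concentration_to_molecules(params$basal, ctx)
  n_peak <- concentration_to_molecules(params$peak, ctx)
  amp <- n_peak - n_basal
  # tau such that amp * exp(-dur/tau) = tolerance * basal
  tau <- dur / log(amp / (params$tolerance * n_basal))
  num <- .fmt_num
  cases <- vapply(meal_s, function(ms) {
    sprintf("Time %% 86400 >= %s , Time %% 86400 < %s : %s + %s * exp(-(Time %% 86400 - %s) / %s)",
            num(ms), num(ms + dur), num(n_basal), num(amp), num(ms),
            num(tau))
  }, "")
  paste(c(cases, num(n_basal)), collapse = " ; ")
}

#' The insulin-receptor recycling model
#'
#' Builds the packaged case-study net: 6 places (the constant external
#' `Insulin` level, the free membrane receptor `IR`, the receptor-insulin
#' complex `IR_I`, its phosphorylated form `IR_I_P`, the internalised
#' phosphorylated complex `IR_I_P_Int` and the internal receptor pool
#' `IR_Int`) and 11 transitions covering insulin binding/dissociation,
#' receptor (de)phosphorylation, internalisation and recycling, receptor
#' degradation and synthesis.  All arc weights are 1.  The reaction volume
#' is 1e-9 l; initial concentrations and mass-action rate constants follow
#' the published parameter set, with the synthesis rate given as a
#' conditional expression: 2.78e-19 M/s while the internal pool
#' `IR_Int + IR_I_P_Int` is at or above its steady-state concentration of
#' 1e-13 M, and an increased 1.67e-18 M/s below it.  The `Insulin` place is
#' driven by the daily profile of [insulin_profile_expression()].
#'
#' @param profile an [insulin_profile_params()].
#' @param t_end simulated seconds for the setup's end condition (default
#'   two days).
#' @param seed setup seed.
#' @return A list with components `net` (a [petri_net()]), `setup` (a
#'   [simulation_setup()] for the exact SSA) and `ctx` (the
#'   [conversion_context()]).
#' @export
build_ir_model <- function(profile = insulin_profile_params(),
                           t_end = 48 * 3600, seed = 1L) {
  ctx <- conversion_context(volume = 1e-9, avogadro = 6e23)
  places <- c("Insulin", "IR", "IR_I", "IR_I_P", "IR_I_P_Int", "IR_Int")
  transitions <- c("Bind_Insulin", "Diss_Insulin", "Inter_IR", "Phos_IR_I",
                   "Dephos_IR_I_P", "Inter_IR_I_P", "Deinter_IR_I_P",
                   "Dephos_IR_I_P_Int", "Deinter_IR", "Degradation",
                   "Synthesis")
  arcs <- data.frame(
    from = c("Insulin", "IR",           # Bind_Insulin: Insulin + IR -> IR_I
             "Bind_Insulin",
             "IR_I", "Diss_Insulin",    # Diss_Insulin: IR_I -> IR
             "IR", "Inter_IR",          # Inter_IR: IR -> IR_Int
             "IR_I", "Phos_IR_I",       # Phos_IR_I: IR_I -> IR_I_P
             "IR_I_P", "Dephos_IR_I_P", # Dephos_IR_I_P: IR_I_P -> IR_I
             "IR_I_P", "Inter_IR_I_P",  # Inter_IR_I_P: IR_I_P -> IR_I_P_Int
             "IR_I_P_Int", "Deinter_IR_I_P",
             "IR_I_P_Int", "Dephos_IR_I_P_Int",
             "IR_Int", "Deinter_IR",    # Deinter_IR: IR_Int -> IR
             "IR_Int",                  # Degradation: IR_Int -> (sink)
             "Synthesis"),              # Synthesis: (source) -> IR_Int
    to = c("Bind_Insulin", "Bind_Insulin", "IR_I",
           "Diss_Insulin", "IR",
           "Inter_IR", "IR_Int",
           "Phos_IR_I", "IR_I_P",
           "Dephos_IR_I_P", "IR_I",
           "Inter_IR_I_P", "IR_I_P_Int",
           "Deinter_IR_I_P", "IR_I_P",
           "Dephos_IR_I_P_Int", "IR_Int",
           "Deinter_IR", "IR",
           "Degradation",
           "IR_Int"))
  net <- petri_net(places, transitions, arcs, constant = "Insulin")

  pool_threshold <- concentration_to_molecules(1e-13, ctx)  # 60 molecules
  num <- .fmt_num
  synthesis <- sprintf(
    "IR_Int + IR_I_P_Int >= %s : 2.78e-19 ; IR_Int + IR_I_P_Int < %s : 1.67e-18",
    num(pool_threshold), num(pool_threshold))

  rates <- list(
    Bind_Insulin = rate_mass_action(1e6),       # M^-1 s^-1, second order
    Diss_Insulin = rate_mass_action(3.33e-3),   # s^-1
    Inter_IR = rate_mass_action(5.56e-6),
    Phos_IR_I = rate_mass_action(41.66),
    Dephos_IR_I_P = rate_mass_action(3.33e-3),
    Inter_IR_I_P = rate_mass_action(3.5e-5),
    Deinter_IR_I_P = rate_mass_action(3.5e-6),
    Dephos_IR_I_P_Int = rate_mass_action(7.68e-3),  # s^-1 (unimolecular)
    Deinter_IR = rate_mass_action(5e-5),
    Degradation = rate_mass_action(2.783e-6),       # s^-1 (unimolecular)
    Synthesis = rate_conditional(synthesis, units = "mass_action"))

  setup <- simulation_setup(
    mode = "ssa", t_end = t_end, seed = seed,
    concentrations = c(IR = 9e-13, IR_I = 0, IR_I_P = 0,
                       IR_I_P_Int = 0, IR_Int = 1e-13),
    volume = ctx$volume, avogadro = ctx$avogadro,
    rates = rates,
    constant_expressions = list(
      Insulin = insulin_profile_expression(profile, ctx)))
  list(net = net, setup = setup, ctx = ctx)
}

#' Run the insulin-receptor case study
#'
#' Simulates the IR model with the exact SSA for the requested number of
#' hours under the repeating daily insulin profile.
#'
#' @param hours simulated hours, positive (48 reproduces the two-day
#'   experiment).
#' @param seed RNG seed.
#' @param profile an [insulin_profile_params()].
#' @return A `pn_trajectory` (see [run()]).
#' @export
run_ir_simulation <- function(hours = 48, seed = 1L,
                              profile = insulin_profile_params()) {
  stopifnot(hours > 0)
  model <- build_ir_model(profile = profile, t_end = hours * 3600,
                          seed = seed)
  run(model$net, model$setup)
}

#' A one-place birth-death net
#'
#' The immigration-death process: a source transition `birth` produces
#' tokens on place `A` at stochastic rate `c_birth` and a death transition
#' consumes them at per-molecule rate `c_death`.  Under the exact SSA the
#' stationary occupancy of `A` is Poisson with mean `c_birth / c_death`.
#'
#' @param c_birth zero-order birth rate, non-negative.
#' @param c_death first-order death rate, positive.
#' @param m0 initial token count on `A`.
#' @param steps end condition for the setup.
#' @param seed setup seed.
#' @return A list with components `net` and `setup` (exact SSA).
#' @export
build_birth_death <- function(c_birth = 1, c_death = 0.1, m0 = 0,
                              steps = 1000, seed = 1L) {
  stopifnot(c_birth >= 0, c_death > 0)
  net <- petri_net(
    places = "A", transitions = c("birth", "death"),
    arcs = data.frame(from = c("birth", "A"), to = c("A", "death")))
  setup <- simulation_setup(
    mode = "ssa", steps = steps, seed = seed,
    marking = c(A = m0),
    rates = list(birth = rate_stochastic(c_birth),
                 death = rate_stochastic(c_death)))
  list(net = net, setup = setup)
}
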