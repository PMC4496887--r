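# two source transitions feeding B: always enabled, never conflicting
two_source_net <- function() {
  petri_net("B", c("T1", "T2"),
            arcs = data.frame(from = c("T1", "T2"), to = c("B", "B")))
}

# T1, T2 compete for a single token on shared pre-place A
conflict_net <- function() {
  petri_net(c("A", "B", "C"), c("T1", "T2"),
            arcs = data.frame(from = c("A", "T1", "A", "T2"),
                              to = c("T1", "B", "T2", "C")))
}

test_that("async mode fires one uniformly chosen enabled transition", {
  net <- two_source_net()
  set.seed(1)
  st <- sim_state(net, c(B = 0), mode = "async")
  step_async(st)
  expect_identical(st$step_count, 1L)
  expect_identical(st$clock, 0)          # no time consumption
  expect_identical(sum(st$firing_counts), 1L)

  # single enabled transition fires with probability 1
  single <- chain_net()
  set.seed(2)
  st1 <- sim_state(single, c(A = 1, B = 0), mode = "async")
  step_async(st1)
  expect_identical(unname(st1$firing_counts["T1"]), 1L)

  # uniformity: two always-enabled transitions, 1e4 steps
  set.seed(3)
  st2 <- sim_state(net, c(B = 0), mode = "async")
  for (i in 1:10000) step_async(st2)
  p1 <- st2$firing_counts[["T1"]] / 10000
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("async deadlock is a termination status, not an error", {
  net <- chain_net()
  set.seed(1)
  st <- sim_state(net, c(A = 0, B = 0), mode = "async")
  step_async(st)
  expect_identical(st$status, "dead marking")
})

test_that("sync mode fires all non-conflicting enabled transitions at once", {
  net <- two_source_net()
  set.seed(1)
  st <- sim_state(net, c(B = 0), mode = "sync")
  step_sync(st)
  expect_identical(unname(st$firing_counts), c(1L, 1L))
  expect_identical(st$step_count, 1L)
})

test_that("sync conflicts resolve uniformly: one of two fires per step", {
  net <- conflict_net()
  set.seed(5)
  wins <- c(T1 = 0, T2 = 0)
  total <- 0L
  for (i in 1:10000) {
    st <- sim_state(net, c(A = 1, B = 0, C = 0), mode = "sync")
    step_sync(st)
    total <- total + sum(st$firing_counts)
    wins <- wins + st$firing_counts
  }
  expect_identical(total, 10000L)   # exactly one of the two fires per step
  expect_lt(abs(wins[["T1"]] / 10000 - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("sync fraction selects ceiling(fraction * enabled) transitions", {
  net <- petri_net("B", paste0("T", 1:4),
                   arcs = data.frame(from = paste0("T", 1:4),
                                     to = rep("B", 4)))
  set.seed(9)
  st <- sim_state(net, c(B = 0), mode = "sync", fraction = 0.5)
  step_sync(st)
  expect_identical(sum(st$firing_counts), 2L)
  expect_error(step_sync(st, fraction = 0), "fraction")
  expect_error(step_sync(st, fraction = 1.5), "fraction")
})

test_that("scheduled waiting times are Exp(lambda) draws", {
  net <- two_source_net()
  set.seed(31)
  st <- sim_state(net, c(B = 0), mode = "stochastic",
                  rates = list(T1 = 2, T2 = 2))
  draws <- replicate(100000, {
    schedule_stochastic(st, "T1", 2)
    st$pending[1] - st$clock
  })
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.5 / sqrt(100000))
  expect_error(schedule_stochastic(st, "T1", 0), "positive")
  expect_error(schedule_stochastic(st, "nope", 1), "nope")
})

test_that("stochastic mode fires by the minimal waiting time: race rates", {
  # two always-enabled transitions, lambda 1 and 3: firing fraction of the
  # faster one tends to 3/4 (min-of-exponentials)
  net <- two_source_net()
  set.seed(11)
  st <- sim_state(net, c(B = 0), mode = "stochastic",
                  rates = list(T1 = 1, T2 = 3))
  for (i in 1:10000) step_stochastic(st)
  frac2 <- st$firing_counts[["T2"]] / 10000
  expect_lt(abs(frac2 - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  # the clock equals the realised event times and is non-decreasing
  expect_gt(st$clock, 0)
})

test_that("single-transition inter-firing times are Exp(lambda)", {
  net <- petri_net("B", "T",
                   arcs = data.frame(from = "T", to = "B"))
  set.seed(13)
  st <- sim_state(net, c(B = 0), mode = "stochastic", rates = list(T = 1))
  times <- numeric(10000)
  for (i in 1:10000) { step_stochastic(st); times[i] <- st$clock }
  gaps <- diff(c(0, times))
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("disabling a transition clears its pending time", {
  net <- conflict_net()
  set.seed(17)
  st <- sim_state(net, c(A = 1, B = 0, C = 0), mode = "stochastic",
                  rates = list(T1 = 1, T2 = 1))
  expect_false(anyNA(st$pending))
  step_stochastic(st)
  expect_identical(st$status, "running")
  expect_true(all(is.na(st$pending)))    # token consumed; both disabled
  step_stochastic(st)
  expect_identical(st$status, "dead marking")
})

test_that("lazy waiting-time caching matches full per-step resampling", {
  # memorylessness: keeping unexpired exponential clocks is distributionally
  # equivalent to redrawing all of them each step.  Compare firing fractions
  # and inter-event gaps on a 3-transition net.
  net <- petri_net(c("A", "B"), c("make", "use", "tick"),
                   arcs = data.frame(
                     from = c("make", "A", "use", "tick"),
                     to = c("A", "use", "B", "B")))
  rates <- list(make = 2, use = 1, tick = 0.5)
  run_mode <- function(seed, lazy) {
    set.seed(seed)
    st <- sim_state(net, c(A = 0, B = 0), mode = "stochastic",
                    rates = rates)
    gaps <- numeric(5000)
    last <- 0
    for (i in 1:5000) {
      if (!lazy) {   # force full resampling by clearing the cache
        en <- which(colSums(st$pre > st$m) == 0)
        st$pending[] <- NA_real_
        for (j in en) st$pending[j] <- st$clock + -log1p(-runif(1)) /
            c(2, 1, 0.5)[j]
      }
      step_stochastic(st)
      gaps[i] <- st$clock - last
      last <- st$clock
    }
    list(gaps = gaps, counts = st$firing_counts)
  }
  lazy <- run_mode(101, TRUE)
  full <- run_mode(202, FALSE)
  ks <- suppressWarnings(stats::ks.test(lazy$gaps, full$gaps))
  expect_gt(ks$p.value, 0.01)
  # firing fractions agree within 3 sigma (binomial, n = 5000)
  f1 <- lazy$counts / sum(lazy$counts)
  f2 <- full$counts / sum(full$counts)
  expect_true(all(abs(f1 - f2) < 3 * sqrt(0.5 * 0.5 / 5000) * 2))
})

test_that("token-game modes never advance the clock; stochastic clock sums gaps", {
  net <- two_source_net()
  set.seed(23)
  st <- sim_state(net, c(B = 0), mode = "sync")
  for (i in 1:20) step_sync(st)
  expect_identical(st$clock, 0)

  set.seed(23)
  st2 <- sim_state(net, c(B = 0), mode = "stochastic",
                   rates = list(T1 = 1, T2 = 1))
  gaps <- numeric(50)
  last <- 0
  for (i in 1:50) {
    step_stochastic(st2)
    gaps[i] <- st2$clock - last
    last <- st2$clock
  }
  expect_true(all(gaps > 0))
  expect_equal(sum(gaps), st2$clock)
})

test_that("fixed seeds reproduce stochastic-mode trajectories bitwise", {
  net <- conflict_net()
  su <- simulation_setup("stochastic", steps = 200, seed = 77,
                         marking = c(A = 50, B = 0, C = 0),
                         rates = list(T1 = 1.5, T2 = 0.5))
  tr1 <- run(net, su)
  tr2 <- run(net, su)
  expect_identical(tr1$records, tr2$records)
  expect_identical(tr1$fired, tr2$fired)
})
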