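# fixtures built in code

# A --w--> T --v--> B
chain_net <- function(w = 1, v = 1) {
  petri_net(c("A", "B"), "T1",
            arcs = data.frame(from = c("A", "T1"), to = c("T1", "B"),
                              weight = c(w, v)))
}

# random small net: up to `max_nodes` places/transitions, random arcs with
# weights 1..3; returns list(net, marking)
random_net <- function(max_nodes = 10, max_tokens = 8) {
  np <- sample(1:max_nodes, 1)
  nt <- sample(1:max_nodes, 1)
  places <- paste0("p", seq_len(np))
  transitions <- paste0("t", seq_len(nt))
  n_arcs <- sample(1:(2 * (np + nt)), 1)
  from_place <- sample(c(TRUE, FALSE), n_arcs, replace = TRUE)
  arcs <- data.frame(
    from = ifelse(from_place, sample(places, n_arcs, replace = TRUE),
                  sample(transitions, n_arcs, replace = TRUE)),
    to = ifelse(from_place, sample(transitions, n_arcs, replace = TRUE),
                sample(places, n_arcs, replace = TRUE)),
    weight = sample(1:3, n_arcs, replace = TRUE))
  const <- if (np > 1 && runif(1) < 0.3) sample(places, 1) else character()
  net <- petri_net(places, transitions, arcs, constant = const)
  marking <- stats::setNames(sample(0:max_tokens, np, replace = TRUE),
                             places)
  list(net = net, marking = marking)
}

# brute-force enablement: iterate the arc list
enabled_brute <- function(net, m, t) {
  a <- net$arcs
  pre <- a[a$to == t, ]
  for (i in seq_len(nrow(pre))) {
    if (m[[pre$from[i]]] < pre$weight[i]) return(FALSE)
  }
  TRUE
}

# random expression corpus for parser round-trip tests
random_expression_text <- function(depth = 3) {
  if (depth == 0 || runif(1) < 0.3) {
    return(sample(c(
      as.character(round(runif(1, 0, 100), 3)),
      "Time", "x", "3e-2", "1.5e3"), 1))
  }
  op <- sample(c("+", "-", "*", "/", "^", "%", "fun"), 1,
               prob = c(.2, .2, .2, .15, .05, .1, .1))
  if (op == "fun") {
    f <- sample(c("abs", "cos", "sin", "exp", "sqrt", "tanh", "floor"), 1)
    return(paste0(f, "(", random_expression_text(depth - 1), ")"))
  }
  if (op == "^") {
    return(paste0("(", random_expression_text(0), ")^(",
                  sample(1:3, 1), ")"))
  }
  paste0("(", random_expression_text(depth - 1), op,
         random_expression_text(depth - 1), ")")
}

# time-weighted mean of a place over [from, max(time)]: states are held
# constant between events, so the continuous-time average weights each
# recorded state by its holding time (event-count averages are biased
# towards high-propensity states)
time_mean <- function(tr, place, from = 0) {
  t <- tr$records[[tr$time_column]]
  x <- tr$records[[place]]
  keep <- t >= from
  t <- t[keep]; x <- x[keep]
  dt <- diff(t)
  sum(x[-length(x)] * dt) / sum(dt)
}

insulin_cases_text <-
  "Time < 5*60 : 1000 ; Time < 10*60 : 100 ; Time >= 10*60 : 0"
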