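#' Construct a place/transition Petri net
#'
#' A Petri net is a directed bipartite graph of places (species, states) and
#' transitions (reactions) connected by weighted arcs.  Tokens on places
#' represent molecule counts; transitions move tokens according to the arc
#' weights.  Places flagged as *constant* contribute to transition enablement
#' and propensities but are never changed by firing -- their token count is
#' typically driven by a mathematical expression (see
#' [parse_conditional()]) and models a boundary condition such as an
#' externally regulated hormone level.
#'
#' Place and transition identifiers are case-sensitive strings and the two
#' sets must be disjoint.  Duplicate arcs between the same ordered pair are
#' merged by summing their weights.
#'
#' @param places character vector of place identifiers.
#' @param transitions character vector of transition identifiers.
#' @param arcs data frame with columns `from`, `to` and optionally `weight`
#'   (positive integers, default 1).  Each row is a directed arc; `from`/`to`
#'   must be one place and one transition.
#' @param constant character vector of place identifiers whose token counts
#'   are not affected by firing.
#' @return An object of class `petri_net` with components `places`,
#'   `transitions`, `constant` (logical per place), `pre` and `post`
#'   (place-by-transition weight matrices) and the normalised `arcs` table.
#' @examples
#' net <- petri_net(
#'   places = c("A", "B"), transitions = "T1",
#'   arcs = data.frame(from = c("A", "T1"), to = c("T1", "B"))
#' )
#' pre_places(net, "T1")
#' @export
petri_net <- function(places, transitions, arcs = NULL, constant = character()) {
  places <- as.character(places)
  transitions <- as.character(transitions)
  if (anyDuplicated(places)) {
    stop("duplicate place identifiers: ",
         paste(unique(places[duplicated(places)]), collapse = ", "))
  }
  if (anyDuplicated(transitions)) {
    stop("duplicate transition identifiers: ",
         paste(unique(transitions[duplicated(transitions)]), collapse = ", "))
  }
  clash <- intersect(places, transitions)
  if (length(clash)) {
    stop("place and transition sets must be disjoint; shared names: ",
         paste(clash, collapse = ", "))
  }
  bad_const <- setdiff(constant, places)
  if (length(bad_const)) {
    stop("constant flags refer to unknown places: ",
         paste(bad_const, collapse = ", "))
  }

  np <- length(places)
  nt <- length(transitions)
  pre <- matrix(0, np, nt, dimnames = list(places, transitions))
  post <- matrix(0, np, nt, dimnames = list(places, transitions))

  if (is.null(arcs)) {
    arcs <- data.frame(from = character(), to = character(),
                       weight = integer())
  }
  if (!all(c("from", "to") %in% names(arcs))) {
    stop("`arcs` must have columns `from` and `to`")
  }
  if (is.null(arcs$weight)) arcs$weight <- 1L
  arcs$from <- as.character(arcs$from)
  arcs$to <- as.character(arcs$to)
  w <- arcs$weight
  if (any(!is.finite(w)) || any(w < 1) || any(w != round(w))) {
    stop("arc weights must be positive integers")
  }
  arcs$weight <- as.integer(round(w))

  for (i in seq_len(nrow(arcs))) {
    from <- arcs$from[i]; to <- arcs$to[i]; wi <- arcs$weight[i]
    if (from %in% places && to %in% transitions) {
      pre[from, to] <- pre[from, to] + wi
    } else if (from %in% transitions && to %in% places) {
      post[to, from] <- post[to, from] + wi
    } else {
      stop("arc ", from, " -> ", to,
           " does not connect a place with a transition")
    }
  }

  # re-derive the normalised (merged) arc table from the matrices
  arcs <- .arcs_from_matrices(pre, post)

  structure(
    list(places = places,
         transitions = transitions,
         constant = stats::setNames(places %in% constant, places),
         pre = pre, post = post, arcs = arcs),
    class = "petri_net")
}

.arcs_from_matrices <- function(pre, post) {
  places <- rownames(pre); transitions <- colnames(pre)
  out <- list()
  for (t in transitions) {
    ip <- which(pre[, t] > 0)
    for (p in ip) {
      out[[length(out) + 1L]] <- data.frame(
        from = places[p], to = t, weight = as.integer(pre[p, t]))
    }
    ip <- which(post[, t] > 0)
    for (p in ip) {
      out[[length(out) + 1L]] <- data.frame(
        from = t, to = places[p], weight = as.integer(post[p, t]))
    }
  }
  if (!length(out)) {
    return(data.frame(from = character(), to = character(),
                      weight = integer()))
  }
  do.call(rbind, out)
}

#' @export
print.petri_net <- function(x, ...) {
  cat("Petri net:", length(x$places), "places,",
      length(x$transitions), "transitions,", nrow(x$arcs), "arcs\n")
  if (any(x$constant)) {
    cat("constant places:", paste(names(x$constant)[x$constant],
                                  collapse = ", "), "\n")
  }
  invisible(x)
}

.check_transition <- function(net, t) {
  if (length(t) != 1L || !t %in% net$transitions) {
    stop("unknown transition: ", t)
  }
}

.check_marking <- function(net, m) {
  if (is.null(names(m)) || !all(net$places %in% names(m))) {
    stop("marking must be a named vector covering all places")
  }
  m <- m[net$places]
  if (any(m < 0) || any(m != round(m))) {
    stop("marking must assign a non-negative integer token count to each place")
  }
  m
}

#' Pre- and post-places of a transition
#'
#' The pre-places of a transition are the places with an arc into it (its
#' reactants); the post-places are the places it feeds (its products).
#'
#' @param net a [petri_net()].
#' @param t a transition identifier.
#' @return Character vector of place identifiers (possibly empty).
#' @export
pre_places <- function(net, t) {
  .check_transition(net, t)
  net$places[net$pre[, t] > 0]
}

#' @rdname pre_places
#' @export
post_places <- function(net, t) {
  .check_transition(net, t)
  net$places[net$post[, t] > 0]
}

#' Is a transition enabled under a marking?
#'
#' A transition is enabled (active) iff every pre-place -- constant or not --
#' holds at least as many tokens as the weight of the connecting arc.  A
#' transition with no pre-places is always enabled.
#'
#' @param net a [petri_net()].
#' @param m named vector: token count per place.
#' @param t transition identifier.
#' @return `TRUE` or `FALSE`.
#' @export
is_enabled <- function(net, m, t) {
  .check_transition(net, t)
  m <- .check_marking(net, m)
  all(net$pre[, t] <= m)
}

#' Fire a transition
#'
#' Consumes tokens from the pre-places and adds tokens to the post-places
#' according to the arc weights.  Constant places are left untouched even
#' when they are pre- or post-places.  Firing a disabled transition is a
#' contract violation and raises an error; token counts can never go
#' negative.
#'
#' @inheritParams is_enabled
#' @return The new marking (named vector).
#' @export
fire <- function(net, m, t) {
  .check_transition(net, t)
  m <- .check_marking(net, m)
  if (!all(net$pre[, t] <= m)) {
    stop("transition ", t, " is not enabled under the given marking")
  }
  delta <- net$post[, t] - net$pre[, t]
  delta[net$constant] <- 0
  m + delta
}

#' Diagnose structural problems of a Petri net
#'
#' Returns human-readable diagnostics rather than raising errors, so that a
#' model under construction can be inspected.  A well-formed net yields an
#' empty character vector.  Checked: place/transition name collisions,
#' dangling arc endpoints, and non-positive arc weights.
#'
#' @param net a `petri_net` object (possibly hand-modified).
#' @return Character vector of diagnostic messages; empty if the net is
#'   well-formed.
#' @export
validate_net <- function(net) {
  out <- character()
  clash <- intersect(net$places, net$transitions)
  if (length(clash)) {
    out <- c(out, paste0("name used for both a place and a transition: ",
                         paste(clash, collapse = ", ")))
  }
  a <- net$arcs
  for (i in seq_len(nrow(a))) {
    nodes <- c(net$places, net$transitions)
    if (!a$from[i] %in% nodes) {
      out <- c(out, paste0("arc ", i, " starts at unknown node ", a$from[i]))
    }
    if (!a$to[i] %in% nodes) {
      out <- c(out, paste0("arc ", i, " ends at unknown node ", a$to[i]))
    }
    if (!is.finite(a$weight[i]) || a$weight[i] < 1) {
      out <- c(out, paste0("arc ", a$from[i], " -> ", a$to[i],
                           " has non-positive weight ", a$weight[i]))
    }
  }
  if (any(net$pre < 0) || any(net$post < 0)) {
    out <- c(out, "negative entry in an arc weight matrix")
  }
  out
}

# enabled status of every transition as a logical vector (internal, fast)
.enabled_all <- function(net, m) {
  if (!length(net$transitions)) return(logical())
  colSums(net$pre > m) == 0
}
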