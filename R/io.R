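## Persistence: tab-separated trajectories, XML setups, PNML nets.

# shortest decimal representation that parses back to the same double;
# keeps persisted artifacts byte-stable and exact
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      return(sprintf("%.0f", v))
    }
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g", width = 1)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, "")
}

#' Export a trajectory as a tab-separated file
#'
#' Writes a header row (`time` or `step` followed by the place names) and
#' one tab-separated row per recorded point, with locale-independent
#' decimal points.  Integer counts round-trip exactly through
#' [utils::read.delim()].
#'
#' @param trajectory a [run()] result.
#' @param destination file path.
#' @return The destination, invisibly.
#' @export
export_tsv <- function(trajectory, destination) {
  stopifnot(inherits(trajectory, "pn_trajectory"))
  if (!nrow(trajectory$records)) stop("trajectory has no records")
  df <- trajectory$records
  # format numerics explicitly so the output is independent of OutDec
  for (j in seq_along(df)) df[[j]] <- .fmt_num(df[[j]])
  con <- file(destination, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(destination)
}

# ---------------------------------------------------------------------------
# simulation setup XML
#
# Schema (all numeric attributes in C locale):
#   <simulationSetup mode=".." seed=".." replicates=".." fraction="..">
#     <end steps=".."/> | <end time=".."/>
#     <context volume=".." avogadro=".."/>          (optional)
#     <leap criticalThreshold=".." epsilon=".."/>   (optional)
#     <places>
#       <place id=".." tokens=".."/>
#       <place id=".." concentration=".."/>
#       <place id=".." constant="true"><expression>text</expression></place>
#     </places>
#     <rates>
#       <rate transition=".." kind="stochastic|mass_action" value=".."/>
#       <rate transition=".." kind="expression|conditional"
#             units="mass_action|stochastic"><text>..</text></rate>
#     </rates>
#   </simulationSetup>

#' Save / load a simulation setup as XML
#'
#' The XML schema carries the marking (counts and/or concentrations plus
#' volume), constant-place expressions, rate specifications, end condition,
#' seed, replicate count and tau-leaping parameters; `load_setup(save_setup(x))`
#' reproduces all fields including expression texts.  Unknown XML elements
#' are an error, never silently ignored.
#'
#' @param setup a [simulation_setup()].
#' @param destination,source file paths.
#' @return `load_setup` returns a `simulation_setup`; `save_setup` its
#'   destination, invisibly.
#' @export
save_setup <- function(setup, destination) {
  stopifnot(inherits(setup, "simulation_setup"))
  num <- .fmt_num
  doc <- xml2::xml_new_root("simulationSetup",
    mode = setup$mode, seed = as.character(setup$seed),
    replicates = as.character(setup$replicates),
    fraction = num(setup$fraction))
  if (!is.null(setup$steps)) {
    xml2::xml_add_child(doc, "end", steps = as.character(setup$steps))
  } else {
    xml2::xml_add_child(doc, "end", time = num(setup$t_end))
  }
  if (!is.null(setup$volume)) {
    xml2::xml_add_child(doc, "context", volume = num(setup$volume),
                        avogadro = num(setup$avogadro))
  }
  xml2::xml_add_child(doc, "leap",
    criticalThreshold = as.character(setup$leap$critical_threshold),
    epsilon = num(setup$leap$epsilon))
  places <- xml2::xml_add_child(doc, "places")
  for (p in names(setup$marking)) {
    xml2::xml_add_child(places, "place", id = p,
                        tokens = num(setup$marking[[p]]))
  }
  for (p in names(setup$concentrations)) {
    xml2::xml_add_child(places, "place", id = p,
                        concentration = num(setup$concentrations[[p]]))
  }
  for (p in names(setup$constant_expressions)) {
    e <- setup$constant_expressions[[p]]
    txt <- if (is.character(e)) e else e$text
    node <- xml2::xml_add_child(places, "place", id = p, constant = "true")
    xml2::xml_add_child(node, "expression", txt)
  }
  if (!is.null(setup$rates)) {
    rates <- xml2::xml_add_child(doc, "rates")
    for (t in names(setup$rates)) {
      r <- setup$rates[[t]]
      if (!inherits(r, "rate_spec")) r <- rate_stochastic(as.numeric(r))
      if (r$kind %in% c("stochastic", "mass_action")) {
        xml2::xml_add_child(rates, "rate", transition = t, kind = r$kind,
                            value = num(r$value))
      } else {
        node <- xml2::xml_add_child(rates, "rate", transition = t,
                                    kind = r$kind, units = r$units)
        xml2::xml_add_child(node, "text", r$text)
      }
    }
  }
  xml2::write_xml(doc, destination)
  invisible(destination)
}

.req_attr <- function(node, name, where) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) stop("missing attribute `", name, "` on <", where, ">")
  v
}

#' @rdname save_setup
#' @export
load_setup <- function(source) {
  doc <- xml2::read_xml(source)
  if (xml2::xml_name(doc) != "simulationSetup") {
    stop("not a simulation setup file: root element <",
         xml2::xml_name(doc), ">")
  }
  mode <- .req_attr(doc, "mode", "simulationSetup")
  seed <- as.integer(.req_attr(doc, "seed", "simulationSetup"))
  replicates <- as.integer(xml2::xml_attr(doc, "replicates", default = "1"))
  fraction <- as.numeric(xml2::xml_attr(doc, "fraction", default = "1"))

  steps <- NULL; t_end <- NULL
  volume <- NULL; avogadro <- 6e23
  leap <- leap_config()
  marking <- NULL; concentrations <- NULL
  const_exprs <- list(); rates <- NULL

  for (node in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(node)
    if (nm == "end") {
      s <- xml2::xml_attr(node, "steps"); tt <- xml2::xml_attr(node, "time")
      if (!is.na(s)) steps <- as.numeric(s)
      if (!is.na(tt)) t_end <- as.numeric(tt)
      if (is.null(steps) && is.null(t_end)) {
        stop("element <end> needs a `steps` or `time` attribute")
      }
    } else if (nm == "context") {
      volume <- as.numeric(.req_attr(node, "volume", "context"))
      av <- xml2::xml_attr(node, "avogadro")
      if (!is.na(av)) avogadro <- as.numeric(av)
    } else if (nm == "leap") {
      leap <- leap_config(
        critical_threshold =
          as.numeric(.req_attr(node, "criticalThreshold", "leap")),
        epsilon = as.numeric(.req_attr(node, "epsilon", "leap")))
    } else if (nm == "places") {
      for (pl in xml2::xml_children(node)) {
        if (xml2::xml_name(pl) != "place") {
          stop("unknown element <", xml2::xml_name(pl), "> inside <places>")
        }
        id <- .req_attr(pl, "id", "place")
        tok <- xml2::xml_attr(pl, "tokens")
        conc <- xml2::xml_attr(pl, "concentration")
        isconst <- identical(xml2::xml_attr(pl, "constant"), "true")
        kids <- xml2::xml_children(pl)
        if (isconst && length(kids)) {
          if (xml2::xml_name(kids[[1]]) != "expression") {
            stop("unknown element <", xml2::xml_name(kids[[1]]),
                 "> inside <place>")
          }
          const_exprs[[id]] <- xml2::xml_text(kids[[1]])
        }
        if (!is.na(tok)) {
          marking <- c(marking, stats::setNames(as.numeric(tok), id))
        }
        if (!is.na(conc)) {
          concentrations <- c(concentrations,
                              stats::setNames(as.numeric(conc), id))
        }
      }
    } else if (nm == "rates") {
      rates <- list()
      for (rt in xml2::xml_children(node)) {
        if (xml2::xml_name(rt) != "rate") {
          stop("unknown element <", xml2::xml_name(rt), "> inside <rates>")
        }
        tr <- .req_attr(rt, "transition", "rate")
        kind <- .req_attr(rt, "kind", "rate")
        if (kind == "stochastic") {
          rates[[tr]] <- rate_stochastic(
            as.numeric(.req_attr(rt, "value", "rate")))
        } else if (kind == "mass_action") {
          rates[[tr]] <- rate_mass_action(
            as.numeric(.req_attr(rt, "value", "rate")))
        } else if (kind %in% c("expression", "conditional")) {
          units <- .req_attr(rt, "units", "rate")
          txt <- xml2::xml_text(xml2::xml_find_first(rt, "./text"))
          if (is.na(txt)) stop("<rate kind=\"", kind, "\"> needs a <text>")
          rates[[tr]] <- if (kind == "expression") {
            rate_expression(txt, units = units)
          } else {
            rate_conditional(txt, units = units)
          }
        } else {
          stop("unknown rate kind: ", kind)
        }
      }
    } else {
      stop("unknown element <", nm, "> in simulation setup")
    }
  }
  if (!is.null(concentrations) && is.null(volume)) {
    stop("setup gives concentrations but no <context volume=..>")
  }
  simulation_setup(mode = mode, steps = steps, t_end = t_end, seed = seed,
                   marking = marking, concentrations = concentrations,
                   volume = volume, avogadro = avogadro, rates = rates,
                   constant_expressions = const_exprs, fraction = fraction,
                   leap = leap, replicates = replicates)
}

# ---------------------------------------------------------------------------
# PNML (ISO/IEC 15909-2 place/transition subset)

.PNML_NS <- "http://www.pnml.org/version-2009/grammar/pnml"
.PNML_PT <- "http://www.pnml.org/version-2009/grammar/ptnet"

#' Write / read a net in PNML (place/transition subset)
#'
#' Supports the standard P/T-net PNML elements (`place`, `transition`,
#' `arc` with `inscription` weights, `initialMarking`).  Constant-place
#' flags and their driving expressions are stored in a `toolspecific`
#' annotation (`tool="stochpn"`); third-party tools ignore it, and nets
#' written by other tools read back without it.  An arc without an
#' inscription has weight 1.  Net types other than the P/T net are rejected
#' with an explicit error.
#'
#' @param net a [petri_net()].
#' @param marking named vector of initial token counts.
#' @param destination,source file paths.
#' @param constant_expressions named list of expression texts for constant
#'   places, persisted in the toolspecific annotation.
#' @return `read_pnml` returns a list with components `net`, `marking` and
#'   `constant_expressions`; `write_pnml` its destination, invisibly.
#' @export
write_pnml <- function(net, marking, destination,
                       constant_expressions = list()) {
  stopifnot(inherits(net, "petri_net"))
  marking <- .check_marking(net, marking)
  doc <- xml2::xml_new_root("pnml", xmlns = .PNML_NS)
  netn <- xml2::xml_add_child(doc, "net", id = "net1", type = .PNML_PT)
  page <- xml2::xml_add_child(netn, "page", id = "page1")
  for (p in net$places) {
    pl <- xml2::xml_add_child(page, "place", id = p)
    nmn <- xml2::xml_add_child(pl, "name")
    xml2::xml_add_child(nmn, "text", p)
    mk <- xml2::xml_add_child(pl, "initialMarking")
    xml2::xml_add_child(mk, "text", format(marking[[p]], scientific = FALSE))
    if (net$constant[[p]]) {
      ts <- xml2::xml_add_child(pl, "toolspecific", tool = "stochpn",
                                version = "1")
      xml2::xml_add_child(ts, "constant", "true")
      if (!is.null(constant_expressions[[p]])) {
        e <- constant_expressions[[p]]
        txt <- if (is.character(e)) e else e$text
        xml2::xml_add_child(ts, "expression", txt)
      }
    }
  }
  for (t in net$transitions) {
    tr <- xml2::xml_add_child(page, "transition", id = t)
    nmn <- xml2::xml_add_child(tr, "name")
    xml2::xml_add_child(nmn, "text", t)
  }
  a <- net$arcs
  for (i in seq_len(nrow(a))) {
    arc <- xml2::xml_add_child(page, "arc", id = paste0("a", i),
                               source = a$from[i], target = a$to[i])
    if (a$weight[i] != 1L) {
      ins <- xml2::xml_add_child(arc, "inscription")
      xml2::xml_add_child(ins, "text", as.character(a$weight[i]))
    }
  }
  xml2::write_xml(doc, destination)
  invisible(destination)
}

#' @rdname write_pnml
#' @export
read_pnml <- function(source) {
  doc <- xml2::read_xml(source)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "pnml") {
    stop("not a PNML file: root element <", xml2::xml_name(doc), ">")
  }
  netn <- xml2::xml_find_first(doc, "./net")
  if (inherits(netn, "xml_missing")) stop("PNML file contains no <net>")
  type <- xml2::xml_attr(netn, "type")
  if (!is.na(type) && !grepl("ptnet", type, fixed = TRUE)) {
    stop("unsupported PNML net type: ", type,
         " (only place/transition nets are supported)")
  }
  # elements may sit directly under <net> or inside <page> elements
  scope <- xml2::xml_find_all(netn, ".//place | .//transition | .//arc")
  places <- character(); transitions <- character()
  marking <- numeric(); const <- character(); const_exprs <- list()
  arcs <- list()
  for (node in scope) {
    nm <- xml2::xml_name(node)
    if (nm == "place") {
      id <- .req_attr(node, "id", "place")
      places <- c(places, id)
      mk <- xml2::xml_find_first(node, "./initialMarking/text")
      marking[id] <- if (inherits(mk, "xml_missing")) 0
                     else as.numeric(xml2::xml_text(mk))
      ts <- xml2::xml_find_first(node,
        "./toolspecific[@tool=\"stochpn\"]")
      if (!inherits(ts, "xml_missing")) {
        cflag <- xml2::xml_find_first(ts, "./constant")
        if (!inherits(cflag, "xml_missing") &&
            identical(xml2::xml_text(cflag), "true")) {
          const <- c(const, id)
        }
        ex <- xml2::xml_find_first(ts, "./expression")
        if (!inherits(ex, "xml_missing")) {
          const_exprs[[id]] <- xml2::xml_text(ex)
        }
      }
    } else if (nm == "transition") {
      transitions <- c(transitions, .req_attr(node, "id", "transition"))
    } else if (nm == "arc") {
      w <- xml2::xml_find_first(node, "./inscription/text")
      arcs[[length(arcs) + 1L]] <- data.frame(
        from = .req_attr(node, "source", "arc"),
        to = .req_attr(node, "target", "arc"),
        weight = if (inherits(w, "xml_missing")) 1L
                 else as.integer(xml2::xml_text(w)))
    }
  }
  arcs <- if (length(arcs)) do.call(rbind, arcs) else NULL
  net <- petri_net(places, transitions, arcs, constant = const)
  list(net = net, marking = marking[net$places],
       constant_expressions = const_exprs)
}
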