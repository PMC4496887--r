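## Mathematical and conditional expression engine.
##
## Rate constants and the token counts of constant places can be given as
## textual mathematical expressions over numeric literals (standard and
## scientific notation), the constant `pi`, the simulated time variable
## `Time` (seconds) and the names of non-constant places (which bind to the
## current token counts).  Supported operators: + - * / ^ % (remainder) and
## unary sign; supported functions: abs, acos, asin, atan, cbrt, ceil, cos,
## cosh, exp, floor, log (natural), sin, sinh, sqrt, tan, tanh and the
## two-argument div(x, y) (integer division towards the nearest lower
## integer, so div(28, 24) = 1).  Implicit multiplication by juxtaposition
## is not accepted; write `2*pi`, not `2 pi`.
##
## Conditional expressions are ordered lists of cases separated by `;`:
##
##     [cond , cond , ... :] value ; [cond , ... :] value ; ...
##
## where each `cond` is `expr OP expr` with OP one of  =  <  >  <=  >=
## (`=` compares with absolute tolerance 1e-9).  Conditions within one case
## are conjunctive.  Evaluation returns the value of the FIRST case whose
## conditions all hold; a case without conditions always holds; if no case
## holds, 0 is returned.

.EXPR_FUNS1 <- c("abs", "acos", "asin", "atan", "cbrt", "ceil", "cos",
                 "cosh", "exp", "floor", "log", "sin", "sinh", "sqrt",
                 "tan", "tanh")
.EXPR_FUNS2 <- c("div")
.EXPR_EQ_TOL <- 1e-9

# ---------------------------------------------------------------------------
# tokenizer

.tokenize <- function(text, conditional = FALSE) {
  toks <- list()
  n <- nchar(text)
  i <- 1L
  push <- function(type, value, pos) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[ \t\r\n]", ch)) { i <- i + 1L; next }
    if (grepl("[0-9.]", ch)) {
      rest <- substr(text, i, n)
      mm <- regmatches(rest,
        regexpr("^([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?", rest))
      if (!length(mm) || mm == "" || mm == ".") {
        stop("invalid number at position ", i, " in \"", text, "\"")
      }
      push("num", as.numeric(mm), i)
      i <- i + nchar(mm)
      next
    }
    if (grepl("[A-Za-z_]", ch)) {
      rest <- substr(text, i, n)
      mm <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      push("ident", mm, i)
      i <- i + nchar(mm)
      next
    }
    two <- substr(text, i, min(i + 1L, n))
    if (conditional && two %in% c("<=", ">=")) {
      push("cmp", two, i); i <- i + 2L; next
    }
    if (conditional && ch %in% c("<", ">", "=")) {
      push("cmp", ch, i); i <- i + 1L; next
    }
    if (ch %in% c("+", "-", "*", "/", "^", "%")) {
      push("op", ch, i); i <- i + 1L; next
    }
    if (ch == "(") { push("lparen", ch, i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ch, i); i <- i + 1L; next }
    if (ch == ",") { push("comma", ch, i); i <- i + 1L; next }
    if (conditional && ch == ";") { push("semi", ch, i); i <- i + 1L; next }
    if (conditional && ch == ":") { push("colon", ch, i); i <- i + 1L; next }
    stop("unexpected character \"", ch, "\" at position ", i,
         " in \"", text, "\"")
  }
  push("eof", "", n + 1L)
  toks
}

# ---------------------------------------------------------------------------
# recursive-descent parser -> AST
# node kinds: num(value), var(name), call(fun, args), unary(op, arg),
#             binary(op, lhs, rhs)

.parser_new <- function(toks, text) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks; env$i <- 1L; env$text <- text
  env
}
.peek <- function(ps) ps$toks[[ps$i]]
.advance <- function(ps) { tk <- ps$toks[[ps$i]]; ps$i <- ps$i + 1L; tk }
.expect <- function(ps, type, what) {
  tk <- .peek(ps)
  if (tk$type != type) {
    stop("expected ", what, " at position ", tk$pos, " in \"", ps$text, "\"")
  }
  .advance(ps)
}

.parse_expr <- function(ps) {
  node <- .parse_term(ps)
  repeat {
    tk <- .peek(ps)
    if (tk$type == "op" && tk$value %in% c("+", "-")) {
      .advance(ps)
      node <- list(kind = "binary", op = tk$value, lhs = node,
                   rhs = .parse_term(ps))
    } else break
  }
  node
}

.parse_term <- function(ps) {
  node <- .parse_unary(ps)
  repeat {
    tk <- .peek(ps)
    if (tk$type == "op" && tk$value %in% c("*", "/", "%")) {
      .advance(ps)
      node <- list(kind = "binary", op = tk$value, lhs = node,
                   rhs = .parse_unary(ps))
    } else break
  }
  node
}

.parse_unary <- function(ps) {
  tk <- .peek(ps)
  if (tk$type == "op" && tk$value %in% c("+", "-")) {
    .advance(ps)
    return(list(kind = "unary", op = tk$value, arg = .parse_unary(ps)))
  }
  .parse_power(ps)
}

# exponentiation is right-associative and binds tighter than unary minus on
# the left (-2^2 == -(2^2)); the exponent may carry its own sign (2^-3)
.parse_power <- function(ps) {
  base <- .parse_atom(ps)
  tk <- .peek(ps)
  if (tk$type == "op" && tk$value == "^") {
    .advance(ps)
    return(list(kind = "binary", op = "^", lhs = base,
                rhs = .parse_unary(ps)))
  }
  base
}

.parse_atom <- function(ps) {
  tk <- .peek(ps)
  if (tk$type == "num") {
    .advance(ps)
    return(list(kind = "num", value = tk$value))
  }
  if (tk$type == "ident") {
    .advance(ps)
    if (.peek(ps)$type == "lparen") {
      .advance(ps)
      args <- list(.parse_expr(ps))
      while (.peek(ps)$type == "comma") {
        .advance(ps)
        args[[length(args) + 1L]] <- .parse_expr(ps)
      }
      .expect(ps, "rparen", "\")\"")
      fun <- tk$value
      if (fun %in% .EXPR_FUNS1) {
        if (length(args) != 1L) {
          stop("function ", fun, " takes one argument (position ", tk$pos,
               " in \"", ps$text, "\")")
        }
      } else if (fun %in% .EXPR_FUNS2) {
        if (length(args) != 2L) {
          stop("function ", fun, " takes two arguments (position ", tk$pos,
               " in \"", ps$text, "\")")
        }
      } else {
        stop("unknown function: ", fun, " (position ", tk$pos,
             " in \"", ps$text, "\")")
      }
      return(list(kind = "call", fun = fun, args = args))
    }
    if (tk$value == "pi") return(list(kind = "num", value = pi))
    return(list(kind = "var", name = tk$value))
  }
  if (tk$type == "lparen") {
    .advance(ps)
    node <- .parse_expr(ps)
    .expect(ps, "rparen", "\")\"")
    return(node)
  }
  stop("expected a number, variable, function or \"(\" at position ",
       tk$pos, " in \"", ps$text, "\"")
}

.ast_vars <- function(node) {
  switch(node$kind,
    num = character(),
    var = node$name,
    unary = .ast_vars(node$arg),
    binary = c(.ast_vars(node$lhs), .ast_vars(node$rhs)),
    call = unlist(lapply(node$args, .ast_vars)))
}

# ---------------------------------------------------------------------------
# compilation of the AST to an R language object evaluated in a sealed
# environment that exposes only the Table-of-operators semantics

.s_div <- function(x, y) {
  if (y == 0) stop("division by zero")
  x / y
}
.s_mod <- function(x, y) {        # remainder with the sign of the dividend
  if (y == 0) stop("modulo by zero")
  x - trunc(x / y) * y
}
.s_intdiv <- function(x, y) {     # div(x, y): nearest lower integer of x/y
  if (y == 0) stop("division by zero in div()")
  floor(x / y)
}
.s_cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

.expr_base_env <- local({
  e <- new.env(parent = baseenv())
  e$`+` <- `+`; e$`-` <- `-`; e$`*` <- `*`; e$`^` <- `^`
  e$.div <- .s_div; e$.mod <- .s_mod; e$.intdiv <- .s_intdiv
  e$abs <- abs; e$acos <- acos; e$asin <- asin; e$atan <- atan
  e$cbrt <- .s_cbrt; e$ceil <- ceiling; e$cos <- cos; e$cosh <- cosh
  e$exp <- exp; e$floor <- floor; e$log <- log; e$sin <- sin
  e$sinh <- sinh; e$sqrt <- sqrt; e$tan <- tan; e$tanh <- tanh
  e
})

.compile_ast <- function(node) {
  switch(node$kind,
    num = node$value,
    var = as.name(node$name),
    unary = if (node$op == "-") call("-", .compile_ast(node$arg))
            else .compile_ast(node$arg),
    binary = {
      lhs <- .compile_ast(node$lhs); rhs <- .compile_ast(node$rhs)
      switch(node$op,
        "+" = call("+", lhs, rhs),
        "-" = call("-", lhs, rhs),
        "*" = call("*", lhs, rhs),
        "/" = call(".div", lhs, rhs),
        "%" = call(".mod", lhs, rhs),
        "^" = call("^", lhs, rhs))
    },
    call = {
      fun <- switch(node$fun, ceil = "ceiling", div = ".intdiv",
                    cbrt = "cbrt", node$fun)
      as.call(c(as.name(fun), lapply(node$args, .compile_ast)))
    })
}

# ---------------------------------------------------------------------------
# public API

#' Parse a mathematical expression
#'
#' Parses the textual expression language used for rate constants and
#' constant-place token counts into an evaluable object.  See the package
#' vignette for the full grammar.  Variables may be `Time` (simulated
#' seconds) and names of non-constant places; `pi` is a predefined constant.
#'
#' @param text a single non-empty character string.
#' @return An object of class `pn_expression`.
#' @examples
#' e <- parse_expression("1400*cos(Time/300*2*pi)+1600")
#' eval_expression(e, c(Time = 0))   # 3000
#' eval_expression(parse_expression("div(28,24)"))  # 1
#' @export
parse_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("expression text must be a single non-empty string")
  }
  ps <- .parser_new(.tokenize(text), text)
  ast <- .parse_expr(ps)
  tk <- .peek(ps)
  if (tk$type != "eof") {
    stop("unexpected input at position ", tk$pos, " in \"", text, "\"")
  }
  structure(
    list(ast = ast, lang = .compile_ast(ast),
         vars = unique(.ast_vars(ast)), text = text),
    class = "pn_expression")
}

#' Evaluate a parsed expression
#'
#' @param e a [parse_expression()] result.
#' @param bindings named numeric vector (or list) binding every variable
#'   occurring in the expression, e.g. `c(Time = 30, IR = 540)`.
#' @return A single numeric value.  Division by zero raises an error, as
#'   does an unbound variable.
#' @export
eval_expression <- function(e, bindings = numeric()) {
  stopifnot(inherits(e, "pn_expression"))
  missing <- setdiff(e$vars, names(bindings))
  if (length(missing)) {
    stop("unbound variable(s): ", paste(missing, collapse = ", "))
  }
  env <- list2env(as.list(bindings), parent = .expr_base_env)
  as.numeric(eval(e$lang, env))
}

#' @export
print.pn_expression <- function(x, ...) {
  cat("expression:", render_expression(x), "\n")
  invisible(x)
}

#' Render an expression back to text
#'
#' Produces a fully parenthesised textual form that parses back to an
#' expression with identical evaluation semantics.
#'
#' @param e a `pn_expression`.
#' @return A character string.
#' @export
render_expression <- function(e) {
  stopifnot(inherits(e, "pn_expression"))
  .render_ast(e$ast)
}

.render_ast <- function(node) {
  switch(node$kind,
    num = format(node$value, digits = 17, scientific = NA),
    var = node$name,
    unary = paste0("(", node$op, .render_ast(node$arg), ")"),
    binary = paste0("(", .render_ast(node$lhs), node$op,
                    .render_ast(node$rhs), ")"),
    call = paste0(node$fun, "(",
                  paste(vapply(node$args, .render_ast, ""), collapse = ","),
                  ")"))
}

# ---------------------------------------------------------------------------
# conditional expressions

#' Parse a conditional expression
#'
#' A conditional expression is an ordered list of cases separated by
#' semicolons.  Each case is either a bare value expression (always
#' satisfied) or `cond, cond, ... : value` where every condition has the
#' form `expr OP expr` with OP one of `=`, `<`, `>`, `<=`, `>=` and all
#' conditions of a case must hold (conjunction).  Evaluation returns the
#' value of the first satisfied case, or 0 when no case is satisfied.
#'
#' @param text a single non-empty string, e.g.
#'   `"Time < 300 : 1000 ; Time < 600 : 100 ; Time >= 600 : 0"`.
#' @return An object of class `pn_conditional` whose `cases` component is a
#'   list of `(conditions, value)` pairs.
#' @examples
#' insulin <- parse_conditional(
#'   "Time < 5*60 : 1000 ; Time < 10*60 : 100 ; Time >= 10*60 : 0")
#' eval_conditional(insulin, c(Time = 100))  # 1000
#' eval_conditional(insulin, c(Time = 400))  # 100
#' eval_conditional(insulin, c(Time = 700))  # 0
#' @export
parse_conditional <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("conditional expression text must be a single non-empty string")
  }
  ps <- .parser_new(.tokenize(text, conditional = TRUE), text)
  cases <- list()
  repeat {
    cases[[length(cases) + 1L]] <- .parse_case(ps)
    tk <- .peek(ps)
    if (tk$type == "semi") {
      .advance(ps)
      if (.peek(ps)$type == "eof") {
        stop("dangling \";\" at position ", tk$pos, " in \"", text, "\"")
      }
      next
    }
    if (tk$type == "eof") break
    stop("expected \";\" or end of input at position ", tk$pos,
         " in \"", text, "\"")
  }
  vars <- unique(unlist(lapply(cases, function(cs) {
    c(unlist(lapply(cs$conditions, function(cd) {
        c(.ast_vars(cd$lhs), .ast_vars(cd$rhs))
      })),
      .ast_vars(cs$value))
  })))
  if (is.null(vars)) vars <- character()
  structure(list(cases = cases, vars = vars, text = text),
            class = "pn_conditional")
}

# case := expr (cmp expr (, expr cmp expr)* : expr)?
.parse_case <- function(ps) {
  conditions <- list()
  first <- .parse_expr(ps)
  tk <- .peek(ps)
  if (tk$type %in% c("semi", "eof")) {
    # unconditional case: bare value
    return(list(conditions = list(),
                value = first, value_lang = .compile_ast(first)))
  }
  if (tk$type == "colon") {
    stop("condition without comparison operator before \":\" at position ",
         tk$pos, " in \"", ps$text, "\"")
  }
  repeat {
    tk <- .peek(ps)
    if (tk$type != "cmp") {
      stop("expected comparison operator at position ", tk$pos,
           " in \"", ps$text, "\"")
    }
    .advance(ps)
    rhs <- .parse_expr(ps)
    conditions[[length(conditions) + 1L]] <-
      list(op = tk$value, lhs = first, rhs = rhs,
           lang = .compile_cond(tk$value, first, rhs))
    tk <- .peek(ps)
    if (tk$type == "comma") {
      .advance(ps)
      first <- .parse_expr(ps)
      next
    }
    if (tk$type == "colon") {
      .advance(ps)
      value <- .parse_expr(ps)
      return(list(conditions = conditions, value = value,
                  value_lang = .compile_ast(value)))
    }
    stop("expected \",\" or \":\" at position ", tk$pos,
         " in \"", ps$text, "\"")
  }
}

.compile_cond <- function(op, lhs, rhs) {
  l <- .compile_ast(lhs); r <- .compile_ast(rhs)
  switch(op,
    "=" = call("<=", call("abs", call("-", l, r)), .EXPR_EQ_TOL),
    "<" = call("<", l, r),
    ">" = call(">", l, r),
    "<=" = call("<=", l, r),
    ">=" = call(">=", l, r))
}

#' Evaluate a conditional expression
#'
#' @param cexpr a [parse_conditional()] result.
#' @param bindings named numeric vector binding all variables.
#' @return The value of the first case whose conditions are all satisfied,
#'   or 0 when none is.
#' @export
eval_conditional <- function(cexpr, bindings = numeric()) {
  stopifnot(inherits(cexpr, "pn_conditional"))
  missing <- setdiff(cexpr$vars, names(bindings))
  if (length(missing)) {
    stop("unbound variable(s): ", paste(missing, collapse = ", "))
  }
  env <- list2env(as.list(bindings), parent = .expr_base_env)
  for (cs in cexpr$cases) {
    ok <- TRUE
    for (cd in cs$conditions) {
      if (!isTRUE(eval(cd$lang, env))) { ok <- FALSE; break }
    }
    if (ok) return(as.numeric(eval(cs$value_lang, env)))
  }
  0
}

#' @export
print.pn_conditional <- function(x, ...) {
  cat("conditional expression with", length(x$cases), "case(s)\n")
  invisible(x)
}
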