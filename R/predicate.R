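# Minimal infix predicate grammar over descriptor values.
#
#   expr  := or
#   or    := and (OR and)*
#   and   := not (AND not)*
#   not   := NOT not | prim
#   prim  := '(' expr ')' | ABSENT '(' ident ')' | TRUE | FALSE | cmp
#   cmp   := ident op number        op in  = != <> < <= > >=
#
# Comparisons against an absent cell are FALSE; ABSENT(d) is the only way to
# test for absence. Parse errors carry the 1-based character position.

tokenize_predicate <- function(src) {
  pats <- c(
    ws     = "^\\s+",
    lparen = "^\\(",
    rparen = "^\\)",
    op     = "^(<=|>=|!=|<>|=|<|>|≠|≤|≥)",
    number = "^[0-9]+(\\.[0-9]+)?",
    ident  = "^[A-Za-z_][A-Za-z0-9_]*"
  )
  tokens <- list()
  pos <- 1L
  rest <- src
  while (nchar(rest) > 0) {
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[ty]], rest, perl = TRUE))
      if (length(m) == 1) {
        if (ty != "ws") {
          txt <- m
          if (ty == "ident") {
            up <- toupper(txt)
            if (up %in% c("AND", "OR", "NOT", "TRUE", "FALSE", "ABSENT")) ty <- tolower(up)
          }
          if (ty == "op") {
            alias <- c("≠" = "!=", "<>" = "!=", "≤" = "<=", "≥" = ">=")
            if (txt %in% names(alias)) txt <- unname(alias[[txt]])
          }
          tokens[[length(tokens) + 1L]] <- list(type = ty, text = txt, pos = pos)
        }
        pos <- pos + nchar(m)
        rest <- substring(rest, nchar(m) + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      abort(sprintf("predicate parse error at position %d: unexpected character '%s'",
                    pos, substring(rest, 1, 1)),
            class = "gmx_parse_error")
    }
  }
  tokens
}

#' Parse a row-selection predicate
#'
#' @param src Predicate string (see [select_rows()] for the grammar).
#' @return An AST (nested lists) consumed by [select_rows()].
#' @keywords internal
#' @export
parse_predicate <- function(src) {
  if (!is.character(src) || length(src) != 1 || is.na(src)) {
    abort("predicate must be a single string", class = "gmx_parse_error")
  }
  tokens <- tokenize_predicate(src)
  i <- 1L
  peek <- function() if (i <= length(tokens)) tokens[[i]] else NULL
  take <- function(type = NULL) {
    tk <- peek()
    if (is.null(tk)) {
      abort(sprintf("predicate parse error at position %d: unexpected end of input",
                    nchar(src) + 1L), class = "gmx_parse_error")
    }
    if (!is.null(type) && tk$type != type) {
      abort(sprintf("predicate parse error at position %d: expected %s, found '%s'",
                    tk$pos, type, tk$text), class = "gmx_parse_error")
    }
    i <<- i + 1L
    tk
  }

  p_expr <- function() {
    node <- p_and()
    while (!is.null(peek()) && peek()$type == "or") {
      take("or")
      node <- list(op = "or", lhs = node, rhs = p_and())
    }
    node
  }
  p_and <- function() {
    node <- p_not()
    while (!is.null(peek()) && peek()$type == "and") {
      take("and")
      node <- list(op = "and", lhs = node, rhs = p_not())
    }
    node
  }
  p_not <- function() {
    if (!is.null(peek()) && peek()$type == "not") {
      take("not")
      return(list(op = "not", arg = p_not()))
    }
    p_prim()
  }
  p_prim <- function() {
    tk <- peek()
    if (is.null(tk)) take()  # raises end-of-input error
    if (tk$type == "lparen") {
      take("lparen"); node <- p_expr(); take("rparen"); return(node)
    }
    if (tk$type == "absent") {
      take("absent"); take("lparen")
      d <- take("ident"); take("rparen")
      return(list(op = "absent", descriptor = d$text))
    }
    if (tk$type == "true")  { take("true");  return(list(op = "const", value = TRUE)) }
    if (tk$type == "false") { take("false"); return(list(op = "const", value = FALSE)) }
    if (tk$type == "ident") {
      d <- take("ident")
      o <- take("op")
      v <- take("number")
      return(list(op = "cmp", descriptor = d$text, cmp = o$text,
                  value = as.numeric(v$text)))
    }
    abort(sprintf("predicate parse error at position %d: unexpected '%s'",
                  tk$pos, tk$text), class = "gmx_parse_error")
  }

  ast <- p_expr()
  tk <- peek()
  if (!is.null(tk)) {
    abort(sprintf("predicate parse error at position %d: trailing input '%s'",
                  tk$pos, tk$text), class = "gmx_parse_error")
  }
  ast
}

predicate_descriptors <- function(ast) {
  switch(ast$op,
    const = character(),
    cmp = ast$descriptor,
    absent = ast$descriptor,
    not = predicate_descriptors(ast$arg),
    unique(c(predicate_descriptors(ast$lhs), predicate_descriptors(ast$rhs)))
  )
}

# env: named list descriptor -> scalar value (NA = absent cell)
eval_predicate <- function(ast, env) {
  switch(ast$op,
    const = ast$value,
    absent = is.na(env[[ast$descriptor]]),
    cmp = {
      v <- env[[ast$descriptor]]
      if (is.na(v)) return(FALSE)
      switch(ast$cmp,
        "="  = v == ast$value,
        "!=" = v != ast$value,
        "<"  = v <  ast$value,
        "<=" = v <= ast$value,
        ">"  = v >  ast$value,
        ">=" = v >= ast$value
      )
    },
    not = !eval_predicate(ast$arg, env),
    and = eval_predicate(ast$lhs, env) && eval_predicate(ast$rhs, env),
    or  = eval_predicate(ast$lhs, env) || eval_predicate(ast$rhs, env)
  )
}
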