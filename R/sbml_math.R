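# MathML <-> R expression conversion for the SBML translator.
# Supported operators: +, -, *, /, power, exp, ln/log, root, min, max,
# piecewise, plus user function definitions (inlined at parse time).

.mathml_to_expr <- function(node, fundefs = list()) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop("malformed MathML: expected one root child")
    return(.mathml_to_expr(kids[[1]], fundefs))
  }
  if (name == "ci") {
    return(as.name(trimws(xml2::xml_text(node))))
  }
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    txt <- xml2::xml_text(node)
    if (!is.na(type) && type %in% c("e-notation", "rational")) {
      parts <- xml2::xml_contents(node)
      nums <- trimws(vapply(parts, function(p) xml2::xml_text(p), ""))
      nums <- as.numeric(nums[nzchar(nums)])
      val <- if (type == "e-notation") nums[1] * 10^nums[2]
      else nums[1] / nums[2]
      return(val)
    }
    return(as.numeric(trimws(txt)))
  }
  if (name == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    stop("unsupported SBML construct: csymbol (", url, ")")
  }
  if (name == "pi") return(pi)
  if (name == "exponentiale") return(exp(1))
  if (name == "true") return(TRUE)
  if (name == "false") return(FALSE)
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], .mathml_to_expr, fundefs = fundefs)
    return(.apply_to_call(op, kids[[1]], args, fundefs))
  }
  if (name == "piecewise") {
    return(.piecewise_to_expr(node, fundefs))
  }
  stop("unsupported MathML element: ", name)
}

.nary <- function(fun, args) {
  Reduce(function(a, b) call(fun, a, b), args)
}

.apply_to_call <- function(op, opnode, args, fundefs) {
  switch(
    op,
    plus = if (length(args) == 0) 0 else .nary("+", args),
    times = if (length(args) == 0) 1 else .nary("*", args),
    minus = if (length(args) == 1) call("-", args[[1]])
    else .nary("-", args),
    divide = .nary("/", args),
    power = call("^", args[[1]], args[[2]]),
    exp = call("exp", args[[1]]),
    ln = call("log", args[[1]]),
    log = if (length(args) == 1) call("log", args[[1]], 10)
    else stop("unsupported MathML log with explicit base"),
    root = call("sqrt", args[[1]]),
    min = .nary("min", args),
    max = .nary("max", args),
    abs = call("abs", args[[1]]),
    floor = call("floor", args[[1]]),
    ceiling = call("ceiling", args[[1]]),
    eq = call("==", args[[1]], args[[2]]),
    neq = call("!=", args[[1]], args[[2]]),
    lt = call("<", args[[1]], args[[2]]),
    leq = call("<=", args[[1]], args[[2]]),
    gt = call(">", args[[1]], args[[2]]),
    geq = call(">=", args[[1]], args[[2]]),
    and = .nary("&", args),
    or = .nary("|", args),
    not = call("!", args[[1]]),
    ci = , # function call through a defined function id
    {
      if (op == "ci") {
        fname <- trimws(xml2::xml_text(opnode))
        def <- fundefs[[fname]]
        if (is.null(def)) stop("call to undefined function: ", fname)
        return(.substitute_all(def$body,
                               setNames(args, def$args)))
      }
      stop("unsupported MathML operator: ", op)
    }
  )
}

.piecewise_to_expr <- function(node, fundefs) {
  kids <- xml2::xml_children(node)
  pieces <- kids[xml2::xml_name(kids) == "piece"]
  other <- kids[xml2::xml_name(kids) == "otherwise"]
  expr <- if (length(other) == 1) {
    .mathml_to_expr(xml2::xml_child(other[[1]]), fundefs)
  } else {
    NA_real_
  }
  for (p in rev(pieces)) {
    pk <- xml2::xml_children(p)
    val <- .mathml_to_expr(pk[[1]], fundefs)
    cond <- .mathml_to_expr(pk[[2]], fundefs)
    expr <- call("ifelse", cond, val, expr)
  }
  expr
}

# substitute named values/expressions into an expression
.substitute_all <- function(expr, env_list) {
  eval(call("substitute", expr, env_list))
}

# all symbols used in an expression
.expr_symbols <- function(expr) {
  if (is.name(expr)) return(as.character(expr))
  if (is.call(expr)) {
    return(unique(unlist(lapply(as.list(expr)[-1], .expr_symbols))))
  }
  character(0)
}

.supported_funs <- c("+", "-", "*", "/", "^", "exp", "log", "sqrt", "min",
                     "max", "abs", "floor", "ceiling", "ifelse", "==", "!=",
                     "<", "<=", ">", ">=", "&", "|", "!", "(")

.expr_functions <- function(expr) {
  if (is.call(expr)) {
    fn <- as.character(expr[[1]])
    return(unique(c(fn, unlist(lapply(as.list(expr)[-1], .expr_functions)))))
  }
  character(0)
}

# R expression -> MathML string
.expr_to_mathml <- function(expr) {
  if (is.numeric(expr) || is.integer(expr)) {
    return(sprintf("<cn> %.17g </cn>", as.numeric(expr)))
  }
  if (is.name(expr)) {
    return(sprintf("<ci> %s </ci>", as.character(expr)))
  }
  if (is.call(expr)) {
    fn <- as.character(expr[[1]])
    args <- as.list(expr)[-1]
    if (fn == "(") return(.expr_to_mathml(args[[1]]))
    inner <- paste(vapply(args, .expr_to_mathml, ""), collapse = "")
    op <- switch(fn,
                 "+" = "plus", "-" = "minus", "*" = "times", "/" = "divide",
                 "^" = "power", exp = "exp", log = "ln", sqrt = "root",
                 min = "min", max = "max", abs = "abs",
                 stop("cannot export function to MathML: ", fn))
    return(sprintf("<apply><%s/>%s</apply>", op, inner))
  }
  stop("cannot export object of class ", class(expr)[1], " to MathML")
}
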