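# Rate-law expression handling: a deliberately small arithmetic grammar
# (+, -, *, /, ^, parentheses, symbols, numbers) so every formula in a
# Ratelaws file stays auditable and maps 1:1 onto SBML MathML.

.allowed_ops <- c("+", "-", "*", "/", "^", "(")

#' Parse a rate-law formula string into an R expression
#'
#' Accepts only arithmetic (`+`, `-`, `*`, `/`, `^`), parentheses, numeric
#' literals and symbols.  Anything else (function calls, conditionals,
#' assignment) is rejected.
#'
#' @param text formula string, e.g. `"kc*S/(kM + S)"`.
#' @param where label used in error messages (reaction name).
#' @return an unevaluated R expression.
#' @keywords internal
parse_ratelaw <- function(text, where = "ratelaw") {
  ex <- tryCatch(str2lang(text),
                 error = function(e) stop("cannot parse formula in ", where,
                                          ": ", conditionMessage(e), call. = FALSE))
  check_expr_grammar(ex, where)
  ex
}

check_expr_grammar <- function(ex, where) {
  if (is.numeric(ex) || is.symbol(ex)) return(invisible(TRUE))
  if (is.call(ex)) {
    op <- as.character(ex[[1L]])
    if (!op %in% .allowed_ops)
      stop("operator '", op, "' not allowed in rate law (", where, ")",
           call. = FALSE)
    for (i in seq_along(ex)[-1L]) check_expr_grammar(ex[[i]], where)
    return(invisible(TRUE))
  }
  stop("unsupported token in rate law (", where, ")", call. = FALSE)
}

#' Symbols used in an expression, in order of first appearance
#' @keywords internal
expr_symbols <- function(ex) {
  out <- character()
  walk <- function(e) {
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (!nm %in% out) out <<- c(out, nm)
    } else if (is.call(e)) {
      for (i in seq_along(e)[-1L]) walk(e[[i]])
    }
  }
  walk(ex)
  out
}

#' Substitute symbols in an expression
#'
#' @param ex expression.
#' @param map named list: symbol name -> replacement (language object or
#'   numeric).
#' @keywords internal
substitute_symbols <- function(ex, map) {
  if (is.symbol(ex)) {
    nm <- as.character(ex)
    if (nm %in% names(map)) return(map[[nm]])
    return(ex)
  }
  if (is.call(ex)) {
    for (i in seq_along(ex)[-1L]) ex[[i]] <- substitute_symbols(ex[[i]], map)
    return(ex)
  }
  ex
}

#' Render an expression back to text (single line)
#' @keywords internal
deparse_one <- function(ex) paste(deparse(ex, width.cutoff = 500L), collapse = "")

# Full-precision numeric formatting: %.17g round-trips every double exactly.
fmt_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- ""
  ok <- !is.na(x)
  out[ok] <- vapply(x[ok], function(v) {
    if (v == floor(v) && abs(v) < 1e15) sprintf("%.17g", v) else sprintf("%.17g", v)
  }, character(1L))
  # trim trailing precision noise: keep shortest of %.17g and shorter forms
  out[ok] <- vapply(x[ok], shortest_roundtrip, character(1L))
  out
}

shortest_roundtrip <- function(v) {
  for (d in 1:17) {
    s <- sprintf(paste0("%.", d, "g"), v)
    if (as.numeric(s) == v) return(s)
  }
  sprintf("%.17g", v)
}
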