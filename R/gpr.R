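# Gene-protein-reaction (GPR) boolean expressions.
#
# Grammar (case-insensitive keywords, `and` binds tighter than `or`):
#   expr   := term ("or" term)*
#   term   := factor ("and" factor)*
#   factor := "(" expr ")" | gene-id
# The empty string is the empty expression: a reaction without gene
# evidence, which is always active.

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(tibble::tibble(token = character(0), pos = integer(0)))
  tibble::tibble(
    token = regmatches(text, gregexpr(pat, text))[[1]],
    pos = as.integer(m)
  )
}

#' Parse a GPR string
#'
#' Parses a gene-protein-reaction rule such as `"g1 and (g2 or g3)"` into a
#' boolean expression tree. `and`/`or` are case-insensitive and `and` binds
#' tighter than `or`. The empty string parses to the empty expression, which
#' is always active.
#'
#' @param text A single GPR string.
#' @return An object of class `gpr`: either the empty expression, a gene
#'   leaf, or a list node with fields `op` (`"and"`/`"or"`) and `args`.
#' @examples
#' parse_gpr("g1 and (g2 or g3)")
#' parse_gpr("")
#' @export
parse_gpr <- function(text) {
  if (length(text) != 1L || is.na(text)) stop("`text` must be a single string")
  toks <- gpr_tokenize(text)
  if (nrow(toks) == 0L) {
    return(structure(list(kind = "empty"), class = "gpr"))
  }
  i <- 1L
  n <- nrow(toks)
  peek <- function() if (i <= n) toks$token[i] else NA_character_
  pos <- function() if (i <= n) toks$pos[i] else nchar(text) + 1L
  advance <- function() i <<- i + 1L
  is_kw <- function(tok, kw) !is.na(tok) && tolower(tok) == kw

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), "or")) {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else
      structure(list(kind = "op", op = "or", args = args), class = "gpr")
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else
      structure(list(kind = "op", op = "and", args = args), class = "gpr")
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok)) {
      stop("GPR parse error at position ", pos(),
           ": expected gene id or '(', found end of input")
    }
    if (tok == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) {
        stop("GPR parse error at position ", pos(),
             ": unbalanced parentheses (expected ')')")
      }
      advance()
      return(e)
    }
    if (tok == ")" || is_kw(tok, "and") || is_kw(tok, "or")) {
      stop("GPR parse error at position ", pos(),
           ": empty operand (found '", tok, "')")
    }
    advance()
    structure(list(kind = "gene", gene = tok), class = "gpr")
  }

  out <- parse_expr()
  if (i <= n) {
    stop("GPR parse error at position ", pos(),
         ": unexpected token '", peek(), "'")
  }
  out
}

#' Serialize a GPR expression to its canonical string
#'
#' The canonical form uses lower-case `and`/`or` and parenthesizes `or`
#' groups nested under `and`, so that `parse_gpr(deparse_gpr(x))` yields an
#' equivalent tree.
#'
#' @param expr A `gpr` object.
#' @return A single string (empty for the empty expression).
#' @export
deparse_gpr <- function(expr) {
  stopifnot(inherits(expr, "gpr"))
  rec <- function(e, parent_op) {
    switch(e$kind,
      empty = "",
      gene = e$gene,
      op = {
        parts <- vapply(e$args, rec, character(1), parent_op = e$op)
        s <- paste(parts, collapse = paste0(" ", e$op, " "))
        if (e$op == "or" && identical(parent_op, "and")) paste0("(", s, ")") else s
      }
    )
  }
  rec(expr, NA_character_)
}

#' @export
print.gpr <- function(x, ...) {
  s <- deparse_gpr(x)
  cat("<gpr> ", if (nzchar(s)) s else "(empty: always active)", "\n", sep = "")
  invisible(x)
}

#' Evaluate a GPR expression under gene knockouts
#'
#' Genes in `knocked_out` are set to FALSE, all other genes to TRUE; the
#' empty expression evaluates to TRUE (a reaction without gene evidence is
#' never disabled by a deletion).
#'
#' @param expr A `gpr` object or a GPR string.
#' @param knocked_out Character vector of knocked-out gene ids.
#' @return A single logical.
#' @examples
#' evaluate_gpr("g1 and g2", "g1")  # FALSE
#' evaluate_gpr("g1 or g2", "g1")   # TRUE
#' @export
evaluate_gpr <- function(expr, knocked_out = character()) {
  if (is.character(expr)) expr <- parse_gpr(expr)
  stopifnot(inherits(expr, "gpr"))
  rec <- function(e) {
    switch(e$kind,
      empty = TRUE,
      gene = !(e$gene %in% knocked_out),
      op = {
        vals <- vapply(e$args, rec, logical(1))
        if (e$op == "and") all(vals) else any(vals)
      }
    )
  }
  rec(expr)
}

#' Genes referenced by a GPR expression
#'
#' @param expr A `gpr` object or GPR string.
#' @return Character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(expr) {
  if (is.character(expr)) expr <- parse_gpr(expr)
  rec <- function(e) {
    switch(e$kind,
      empty = character(0),
      gene = e$gene,
      op = unlist(lapply(e$args, rec))
    )
  }
  unique(rec(expr))
}

# Rewrite every gene leaf through `map`, a named list mapping old gene id ->
# character vector of replacement ids (OR-ed together). Leaves absent from
# `map` are dropped (treated as absent genes) when drop_missing, otherwise
# kept. Used when translating reference-organism GPRs into target gene ids.
gpr_translate <- function(expr, map) {
  if (is.character(expr)) expr <- parse_gpr(expr)
  rec <- function(e) {
    switch(e$kind,
      empty = e,
      gene = {
        repl <- map[[e$gene]]
        if (is.null(repl) || length(repl) == 0L) {
          NULL
        } else if (length(repl) == 1L) {
          structure(list(kind = "gene", gene = repl), class = "gpr")
        } else {
          structure(list(kind = "op", op = "or",
                         args = lapply(repl, function(g)
                           structure(list(kind = "gene", gene = g), class = "gpr"))),
                    class = "gpr")
        }
      },
      op = {
        args <- Filter(Negate(is.null), lapply(e$args, rec))
        if (length(args) == 0L) return(NULL)
        if (e$op == "and" && length(args) < length(e$args)) return(NULL)
        if (length(args) == 1L) args[[1]] else
          structure(list(kind = "op", op = e$op, args = args), class = "gpr")
      }
    )
  }
  out <- rec(expr)
  if (is.null(out)) structure(list(kind = "empty"), class = "gpr") else out
}
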