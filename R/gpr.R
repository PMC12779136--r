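#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers in which `and`
#' joins subunits of an enzyme complex and `or` joins isozymes. The grammar
#' accepted here is the one used by COBRA-style model files: identifiers,
#' parentheses, and the connectives `and` / `or` (case-insensitive).
#' Operator precedence is parentheses > `and` > `or`, so
#' `"A and B or C"` parses as `(A and B) or C`.
#'
#' @param text A single character string, e.g. `"(A and B) or C"`. An empty
#'   or all-whitespace string yields `NULL` (no gene association).
#' @return A GPR expression tree of class `gpr`: nested lists with nodes
#'   `list(op = "and"/"or", args = list(...))` and leaves
#'   `list(gene = "<id>")`, or `NULL` for an empty rule.
#' @examples
#' parse_gpr("FABP1 or SLC27A1")
#' parse_gpr("(HK1 and GAPDH) or HK2")
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(NULL)
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks$type)) {
    gpr_error(st, sprintf("unexpected token '%s'", st$toks$text[st$pos]))
  }
  structure(tree, class = "gpr")
}

# Tokenizer: identifiers are runs of non-space, non-parenthesis characters.
gpr_tokenize <- function(text) {
  n <- nchar(text)
  type <- character(0)
  tok <- character(0)
  off <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "(" || ch == ")") {
      type <- c(type, ch)
      tok <- c(tok, ch)
      off <- c(off, i)
      i <- i + 1L
    } else {
      j <- i
      while (j <= n) {
        cj <- substr(text, j, j)
        if (grepl("^\\s$", cj) || cj == "(" || cj == ")") break
        j <- j + 1L
      }
      word <- substr(text, i, j - 1L)
      lw <- tolower(word)
      type <- c(type, if (lw %in% c("and", "or")) lw else "id")
      tok <- c(tok, word)
      off <- c(off, i)
      i <- j
    }
  }
  list(type = type, text = tok, offset = off, src = text)
}

gpr_error <- function(st, msg) {
  pos <- if (st$pos <= length(st$toks$offset)) {
    st$toks$offset[st$pos]
  } else {
    nchar(st$toks$src) + 1L
  }
  stop(sprintf("GPR parse error at character %d: %s in \"%s\"",
               pos, msg, st$toks$src), call. = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks$type)) NA_character_ else st$toks$type[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (identical(gpr_peek(st), "or")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (identical(gpr_peek(st), "and")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  t <- gpr_peek(st)
  if (is.na(t)) gpr_error(st, "dangling connective or empty expression")
  if (t == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) gpr_error(st, "unbalanced parentheses")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (t == "id") {
    g <- st$toks$text[st$pos]
    st$pos <- st$pos + 1L
    return(list(gene = g))
  }
  gpr_error(st, sprintf("expected gene id or '(', got '%s'", st$toks$text[st$pos]))
}

#' Serialize a GPR tree back to rule text
#'
#' The output round-trips: `parse_gpr(deparse_gpr(x))` is equal to `x`
#' (up to the `gpr` class attribute on subtrees).
#'
#' @param x A GPR tree from [parse_gpr()], or `NULL`.
#' @return A character string; `""` for `NULL`.
#' @export
deparse_gpr <- function(x) {
  if (is.null(x)) return("")
  rec <- function(node, parent_op) {
    if (!is.null(node$gene)) return(node$gene)
    parts <- vapply(node$args, rec, character(1), parent_op = node$op)
    s <- paste(parts, collapse = paste0(" ", node$op, " "))
    # parenthesize an OR nested under an AND
    if (identical(parent_op, "and") && identical(node$op, "or")) {
      s <- paste0("(", s, ")")
    }
    s
  }
  rec(unclass(x), parent_op = NA_character_)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", deparse_gpr(x), "\n", sep = "")
  invisible(x)
}

#' List the gene identifiers in a GPR tree
#'
#' @param x A GPR tree or `NULL`.
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(x) {
  if (is.null(x)) return(character(0))
  out <- character(0)
  rec <- function(node) {
    if (!is.null(node$gene)) {
      out[[length(out) + 1L]] <<- node$gene
    } else {
      for (a in node$args) rec(a)
    }
  }
  rec(unclass(x))
  unique(out)
}

#' Evaluate a GPR tree against per-gene values
#'
#' Two evaluation modes share one traversal. With numeric `values`, the
#' standard COBRA gene-to-reaction mapping is applied: `and` takes the
#' minimum of its operands (complex limited by its scarcest subunit) and
#' `or` the maximum (isozymes add alternatives). Genes missing from
#' `values` are treated as absent rather than zero: an `and` node takes
#' the minimum over its *present* operands only, and a node whose
#' operands are all absent is itself absent. A rule in which every gene
#' is absent evaluates to `NA` (unmapped reaction).
#'
#' With logical `values`, plain boolean evaluation is performed (used by
#' the truth-table tests); missing genes are treated as `FALSE`.
#'
#' @param x A GPR tree or `NULL`.
#' @param values Named numeric (expression levels) or named logical
#'   (gene on/off) vector.
#' @return A single numeric (or `NA_real_` when unmapped), or a logical.
#' @export
eval_gpr <- function(x, values) {
  if (is.null(x)) {
    return(if (is.logical(values)) FALSE else NA_real_)
  }
  if (is.logical(values)) {
    rec_b <- function(node) {
      if (!is.null(node$gene)) {
        v <- values[node$gene]
        return(!is.na(v) && isTRUE(unname(v)))
      }
      vals <- vapply(node$args, rec_b, logical(1))
      if (node$op == "and") all(vals) else any(vals)
    }
    return(rec_b(unclass(x)))
  }
  rec_n <- function(node) {
    if (!is.null(node$gene)) {
      v <- values[node$gene]
      if (is.null(v) || length(v) == 0L || is.na(v)) return(NA_real_)
      return(unname(v))
    }
    vals <- vapply(node$args, rec_n, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    if (node$op == "and") min(vals) else max(vals)
  }
  rec_n(unclass(x))
}
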