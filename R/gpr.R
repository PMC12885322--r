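# Gene-protein-reaction (GPR) Boolean rules.
#
# A rule is an abstract syntax tree: a gene leaf, or an AND / OR node with
# two or more children. AND expresses an enzyme complex (all subunits
# required, activity = min of subunit expression); OR expresses isozymes
# (any one suffices, activity = max).

#' Construct GPR rule nodes
#'
#' `gpr_gene()` builds a leaf, `gpr_and()` / `gpr_or()` build internal nodes
#' with at least two children. Consecutive same-operator children are kept as
#' given; [parse_gpr()] flattens them.
#'
#' @param gene_id Gene identifier (leaf).
#' @param ... Child nodes (`gpr_rule` objects).
#' @return A `gpr_rule` object.
#' @export
gpr_gene <- function(gene_id) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  structure(list(kind = "gene", gene = gene_id), class = "gpr_rule")
}

#' @rdname gpr_gene
#' @export
gpr_and <- function(...) gpr_node("and", list(...))

#' @rdname gpr_gene
#' @export
gpr_or <- function(...) gpr_node("or", list(...))

gpr_node <- function(kind, children) {
  stopifnot(length(children) >= 2L,
            all(vapply(children, inherits, logical(1), "gpr_rule")))
  structure(list(kind = kind, children = children), class = "gpr_rule")
}

#' Parse a GPR rule string into an AST
#'
#' Accepts Boolean expressions over gene identifiers with `and` / `or`
#' (case-insensitive; `&` and `|` also accepted) and parentheses. `and` binds
#' tighter than `or`, the community convention for GPR strings. Runs of the
#' same operator are flattened into a single node with two or more children.
#'
#' @param rule_text The rule string, e.g. `"(g1 and g2) or g3"`.
#' @return A `gpr_rule` AST, or `NULL` for an empty/blank string.
#' @examples
#' parse_gpr("(b0001 and b0002) or b0003")
#' @export
parse_gpr <- function(rule_text) {
  stopifnot(is.character(rule_text), length(rule_text) == 1L)
  tokens <- gpr_tokenize(rule_text)
  if (nrow(tokens) == 0L) return(NULL)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  ast <- gpr_parse_or(state)
  if (state$pos <= nrow(state$tokens)) {
    tok <- state$tokens[state$pos, ]
    stop("GPR parse error at position ", tok$at, ": unexpected '", tok$text,
         "'", call. = FALSE)
  }
  ast
}

gpr_tokenize <- function(text) {
  out <- list()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      out[[length(out) + 1L]] <- data.frame(type = ch, text = ch, at = i)
      i <- i + 1L
      next
    }
    if (ch %in% c("&", "|")) {
      # tolerate &&/||
      len <- if (substr(text, i + 1L, i + 1L) == ch) 2L else 1L
      out[[length(out) + 1L]] <- data.frame(
        type = if (ch == "&") "and" else "or",
        text = substr(text, i, i + len - 1L), at = i)
      i <- i + len
      next
    }
    m <- regmatches(substr(text, i, n), regexpr("^[^()&|[:space:]]+", substr(text, i, n)))
    if (length(m) == 0L) {
      stop("GPR parse error at position ", i, ": unexpected '", ch, "'",
           call. = FALSE)
    }
    word <- m[[1]]
    type <- switch(tolower(word), "and" = "and", "or" = "or", "gene")
    out[[length(out) + 1L]] <- data.frame(type = type, text = word, at = i)
    i <- i + nchar(word)
  }
  if (length(out) == 0L) {
    data.frame(type = character(), text = character(), at = integer())
  } else {
    do.call(rbind, out)
  }
}

gpr_peek <- function(state) {
  if (state$pos > nrow(state$tokens)) NULL else state$tokens[state$pos, ]
}

gpr_parse_or <- function(state) {
  children <- list(gpr_parse_and(state))
  repeat {
    tok <- gpr_peek(state)
    if (is.null(tok) || tok$type != "or") break
    state$pos <- state$pos + 1L
    nxt <- gpr_parse_and(state)
    # flatten nested or-nodes produced by parenthesised sub-expressions only
    children[[length(children) + 1L]] <- nxt
  }
  if (length(children) == 1L) children[[1]] else gpr_flatten("or", children)
}

gpr_parse_and <- function(state) {
  children <- list(gpr_parse_atom(state))
  repeat {
    tok <- gpr_peek(state)
    if (is.null(tok) || tok$type != "and") break
    state$pos <- state$pos + 1L
    children[[length(children) + 1L]] <- gpr_parse_atom(state)
  }
  if (length(children) == 1L) children[[1]] else gpr_flatten("and", children)
}

gpr_parse_atom <- function(state) {
  tok <- gpr_peek(state)
  if (is.null(tok)) {
    stop("GPR parse error: dangling operator at end of rule", call. = FALSE)
  }
  if (tok$type == "(") {
    state$pos <- state$pos + 1L
    inner <- gpr_parse_or(state)
    closing <- gpr_peek(state)
    if (is.null(closing) || closing$type != ")") {
      stop("GPR parse error at position ", tok$at, ": unbalanced '('",
           call. = FALSE)
    }
    state$pos <- state$pos + 1L
    return(inner)
  }
  if (tok$type == "gene") {
    state$pos <- state$pos + 1L
    return(gpr_gene(tok$text))
  }
  stop("GPR parse error at position ", tok$at, ": unexpected '", tok$text,
       "'", call. = FALSE)
}

# Merge children that are themselves unparenthesised runs of the same op.
gpr_flatten <- function(kind, children) {
  flat <- list()
  for (ch in children) {
    if (!is.null(ch$kind) && ch$kind == kind && !isTRUE(attr(ch, "grouped"))) {
      flat <- c(flat, ch$children)
    } else {
      flat[[length(flat) + 1L]] <- ch
    }
  }
  gpr_node(kind, flat)
}

#' Serialize a GPR AST back to a rule string
#'
#' Inverse of [parse_gpr()] up to whitespace: `parse_gpr(gpr_serialize(x))`
#' reproduces `x`.
#'
#' @param rule A `gpr_rule` or `NULL`.
#' @return A character string (empty for `NULL`).
#' @export
gpr_serialize <- function(rule) {
  if (is.null(rule)) return("")
  if (rule$kind == "gene") return(rule$gene)
  parts <- vapply(rule$children, function(ch) {
    s <- gpr_serialize(ch)
    if (ch$kind != "gene" && ch$kind != rule$kind) paste0("(", s, ")") else s
  }, character(1))
  sep <- if (rule$kind == "and") " and " else " or "
  paste(parts, collapse = sep)
}

#' Evaluate a GPR rule on continuous gene activities
#'
#' The direct (non-MILP) semantics: AND nodes take the minimum of their
#' children, OR nodes the maximum (or, optionally, the sum). This is the
#' reference oracle against which the mixed-integer encoding is tested.
#'
#' @param rule A `gpr_rule` AST.
#' @param gene_values Named numeric vector of activities in \[0, 1\].
#' @param or_mode `"max"` (default) or `"sum"` for OR aggregation.
#' @return A single numeric activity.
#' @export
evaluate_rule <- function(rule, gene_values, or_mode = c("max", "sum")) {
  or_mode <- match.arg(or_mode)
  stopifnot(inherits(rule, "gpr_rule"))
  if (rule$kind == "gene") {
    if (!rule$gene %in% names(gene_values)) {
      stop("no value supplied for gene '", rule$gene, "'", call. = FALSE)
    }
    return(unname(gene_values[[rule$gene]]))
  }
  vals <- vapply(rule$children, evaluate_rule, numeric(1),
                 gene_values = gene_values, or_mode = or_mode)
  if (rule$kind == "and") min(vals)
  else if (or_mode == "max") max(vals) else sum(vals)
}

#' List the genes appearing in a rule
#'
#' @param rule A `gpr_rule` or `NULL`.
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
rule_genes <- function(rule) {
  if (is.null(rule)) return(character())
  if (rule$kind == "gene") return(rule$gene)
  unique(unlist(lapply(rule$children, rule_genes)))
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> ", gpr_serialize(x), "\n", sep = "")
  invisible(x)
}
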