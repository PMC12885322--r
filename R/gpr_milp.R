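# Mixed-integer encoding of min/max over gene-activity variables.
#
# A k-child min (AND) or max (OR) node contributes 2k+1 linear rows and k
# binary selectors summing to k-1; exactly one selector is zero and picks the
# extreme child. Because all gene activities and auxiliaries live in [0, 1],
# big-M = 1 is both valid and the tightest possible choice. Nested rules are
# encoded recursively, one auxiliary variable per internal AST node; the root
# auxiliary is the reaction-level activity that enters the flux-matching
# constraint.

#' Encode min/max of bounded variables as mixed-integer constraints
#'
#' `encode_min(out)` forces `out = min(children)` at any feasible integer
#' assignment; `encode_max` the maximum. All participating variables must be
#' bounded in \[0, 1\] (big-M = 1). A single child short-circuits to an
#' equality with no binaries.
#'
#' @param lp An internal `lp_builder`.
#' @param child_idx Variable indices of the children (length >= 1).
#' @param out_idx Variable index of the output.
#' @param prefix Name prefix for the selector binaries.
#' @param M Big-M constant (default 1).
#' @return Number of binaries added, invisibly.
#' @keywords internal
encode_min <- function(lp, child_idx, out_idx, prefix = "y", M = 1) {
  encode_extreme(lp, child_idx, out_idx, prefix, M, sense = "min")
}

#' @rdname encode_min
#' @keywords internal
encode_max <- function(lp, child_idx, out_idx, prefix = "y", M = 1) {
  encode_extreme(lp, child_idx, out_idx, prefix, M, sense = "max")
}

encode_extreme <- function(lp, child_idx, out_idx, prefix, M, sense) {
  if (any(!is.finite(lp$lb[c(child_idx, out_idx)])) ||
      any(!is.finite(lp$ub[c(child_idx, out_idx)]))) {
    stop("min/max encoding requires bounded variables", call. = FALSE)
  }
  k <- length(child_idx)
  if (k == 1L) {
    lp_add_constr(lp, c(out_idx, child_idx), c(1, -1), "=", 0)
    return(invisible(0L))
  }
  y_idx <- lp_add_vars(lp, paste0(prefix, "_", seq_len(k)),
                       lb = 0, ub = 1, integer = TRUE)
  for (i in seq_len(k)) {
    if (sense == "min") {
      lp_add_constr(lp, c(out_idx, child_idx[i]), c(1, -1), "<=", 0)
      lp_add_constr(lp, c(out_idx, child_idx[i], y_idx[i]), c(1, -1, M), ">=", 0)
    } else {
      lp_add_constr(lp, c(out_idx, child_idx[i]), c(1, -1), ">=", 0)
      lp_add_constr(lp, c(out_idx, child_idx[i], y_idx[i]), c(1, -1, -M), "<=", 0)
    }
  }
  lp_add_constr(lp, y_idx, rep(1, k), "=", k - 1)
  invisible(k)
}

#' Recursively encode a GPR rule into MILP constraints
#'
#' Each internal AST node gets an auxiliary activity variable in \[0, 1\]
#' constrained to the min (AND) or max (OR) of its children; gene leaves map
#' to the supplied gene variables. The returned index is the root auxiliary —
#' the reaction-level expression activity. With `or_mode = "sum"` OR nodes
#' are encoded as plain sums (no binaries), clipped to the \[0, 1\] box by the
#' auxiliary's bounds.
#'
#' @param lp An internal `lp_builder`.
#' @param rule A [gpr_rule][parse_gpr] AST.
#' @param gene_idx Named integer vector: gene id -> variable index.
#' @param prefix Unique name prefix for auxiliaries/binaries of this rule.
#' @param M Big-M constant (default 1).
#' @param or_mode `"max"` (default) or `"sum"`.
#' @return Index of the variable holding the rule's value.
#' @keywords internal
encode_rule <- function(lp, rule, gene_idx, prefix = "r", M = 1,
                        or_mode = c("max", "sum")) {
  or_mode <- match.arg(or_mode)
  stopifnot(inherits(rule, "gpr_rule"))
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  rec <- function(node) {
    if (node$kind == "gene") {
      if (!node$gene %in% names(gene_idx)) {
        stop("no variable for gene '", node$gene, "'", call. = FALSE)
      }
      return(gene_idx[[node$gene]])
    }
    child_idx <- vapply(node$children, rec, integer(1))
    counter$i <- counter$i + 1L
    aux <- lp_add_var(lp, paste0(prefix, "_aux", counter$i), lb = 0, ub = 1)
    if (node$kind == "and") {
      encode_min(lp, child_idx, aux, prefix = paste0(prefix, "_n", counter$i), M = M)
    } else if (or_mode == "max") {
      encode_max(lp, child_idx, aux, prefix = paste0(prefix, "_n", counter$i), M = M)
    } else {
      lp_add_constr(lp, c(aux, child_idx), c(1, rep(-1, length(child_idx))), "=", 0)
    }
    aux
  }
  root <- rec(rule)
  if (rule$kind == "gene") {
    # single-gene rule: introduce an alias so the reaction activity is its own
    # variable (keeps the flux-matching row uniform)
    aux <- lp_add_var(lp, paste0(prefix, "_aux_root"), lb = 0, ub = 1)
    lp_add_constr(lp, c(aux, root), c(1, -1), "=", 0)
    root <- aux
  }
  as.integer(root)
}

#' Solve a GPR rule's MILP encoding at fixed gene activities
#'
#' Builds a fresh MILP holding the gene variables at the given values,
#' encodes the rule, solves, and returns the root activity. Used as the
#' round-trip check that the mixed-integer encoding reproduces the direct
#' min/max semantics of [evaluate_rule()].
#'
#' @param rule A [gpr_rule][parse_gpr] AST.
#' @param gene_values Named numeric vector of activities in \[0, 1\].
#' @param M Big-M constant.
#' @param or_mode OR aggregation, `"max"` or `"sum"`.
#' @return The root activity at a feasible integer assignment.
#' @export
solve_rule_milp <- function(rule, gene_values, M = 1, or_mode = "max") {
  lp <- new_lp()
  gidx <- vapply(names(gene_values), function(g) {
    lp_add_var(lp, paste0("g_", g), lb = gene_values[[g]], ub = gene_values[[g]])
  }, integer(1))
  names(gidx) <- names(gene_values)
  root <- encode_rule(lp, rule, gidx, prefix = "r", M = M, or_mode = or_mode)
  res <- lp_solve(lp)
  if (res$status != 0L) stop("rule MILP did not solve: ", res$status_name,
                             call. = FALSE)
  unname(res$x[root])
}
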