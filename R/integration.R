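# The expression-integration MILP.
#
# Per condition, minimize  -c~ * v_biomass + sum(delta) + sum(eps)  subject to
#   mass balance                     S v = 0
#   switchable bounds                0 <= v_j <= U_j * b_j
#   measured exchange fluxes         per exp_mode
#   direction exclusivity            b_f + b_b = 1 per split pair
#   flux/expression matching         (v_j - env_min) / (env_max - env_min)
#                                      = ghat_j + eps1_j - eps2_j
#   GPR activities                   ghat_j = f({g_i}) (mixed-integer min/max)
#   expression anchoring             g_i - gtilde_i = delta1_i - delta2_i
# with g, ghat in [0, 1] and all deviations non-negative. The flux-matching
# row is emitted only for rule-bearing reactions whose cross-condition
# envelope is non-degenerate; the anchoring row only for measured genes.

#' Configuration for the expression-integration MILP
#'
#' @param ctilde Biomass objective coefficient: a number, or one of
#'   `"B"`, `"2B"`, `"B/10"`, `"B/100"`, `"B/1000"`, `"1"` resolved against
#'   the balance constant `B = (2k + 2n) / v_biomass_max` (see [compute_B()]).
#' @param transform Expression scheme passed to [relative_expression()].
#' @param p FVA objective-retention fraction.
#' @param U_default Upper bound replacing non-finite bounds (flux units;
#'   default 1000).
#' @param exp_mode How measured fluxes constrain their reactions:
#'   `"equality"` (band `v_exp * (1 +/- exp_band)`, default), `"upper"`, or
#'   `"lower"`.
#' @param exp_band Relative half-width of the equality band (default 0.01).
#' @param mip_gap Relative MIP optimality gap (default 1e-9).
#' @param retention_tol Relative tolerance on the step-1 optimum in the
#'   two-step L1/L2 variants (default 1e-6).
#' @param omega Denominator guard for expression transforms.
#' @param omega_flux Degeneracy threshold for the flux envelope.
#' @param mean_low Lower-branch form of the mean-reference transform.
#' @param or_mode OR-rule aggregation, `"max"` (default) or `"sum"`.
#' @param variant `"base"`, `"l1"`, or `"l2"` (used by
#'   [run_multi_condition()]).
#' @return An `integration_config` list.
#' @export
integration_config <- function(ctilde = "B",
                       transform = "mean_reference",
                       p = 1.0,
                       U_default = 1000,
                       exp_mode = "equality",
                       exp_band = 0.01,
                       mip_gap = 1e-9,
                       retention_tol = 1e-6,
                       omega = 0.001,
                       omega_flux = 0.001,
                       mean_low = "monotone",
                       or_mode = "max",
                       variant = "base") {
  cfg <- list(ctilde = ctilde, transform = transform, p = p,
              U_default = U_default, exp_mode = exp_mode, exp_band = exp_band,
              mip_gap = mip_gap, retention_tol = retention_tol,
              omega = omega, omega_flux = omega_flux, mean_low = mean_low,
              or_mode = or_mode, variant = variant)
  stopifnot(cfg$U_default > 0, cfg$p >= 0, cfg$p <= 1)
  class(cfg) <- "integration_config"
  cfg
}

#' Compute the biomass-balancing constant B
#'
#' `B = (2k + 2n) / v_biomass_max`, where `k` is the number of model genes,
#' `n` the number of irreversible reactions, and `v_biomass_max` the FBA
#' optimum for the condition. `2k + 2n` is the maximum possible total of the
#' non-negative deviation variables, so a biomass coefficient of `B` puts the
#' biomass term on the same scale as the deviation terms.
#'
#' @param net An [to_irreversible()] network.
#' @param cond Optional [condition_spec()].
#' @param cfg An [integration_config()] (for exchange-constraint mode).
#' @return The constant `B` (> 0).
#' @export
compute_B <- function(net, cond = NULL, cfg = integration_config()) {
  fba <- solve_fba(net, cond, cfg$exp_mode, cfg$exp_band)
  if (fba$objective <= 1e-12) {
    stop("FBA biomass optimum is zero; B is undefined", call. = FALSE)
  }
  k <- length(net$gene_ids); n <- length(net$reaction_ids)
  (2 * k + 2 * n) / fba$objective
}

resolve_ctilde <- function(ctilde, B) {
  if (is.numeric(ctilde)) return(ctilde)
  switch(as.character(ctilde),
         "1" = 1, "B" = B, "2B" = 2 * B,
         "B/10" = B / 10, "B/100" = B / 100, "B/1000" = B / 1000,
         {
           v <- suppressWarnings(as.numeric(ctilde))
           if (is.na(v)) stop("unrecognized ctilde: ", ctilde, call. = FALSE)
           v
         })
}

#' Assemble the expression-integration MILP for one condition
#'
#' @param net An [to_irreversible()] network with a biomass objective.
#' @param envelope A [build_envelope()] result over all conditions.
#' @param gtilde Relative expression for this condition: named vector over
#'   model genes (NA = unmeasured), e.g. one column of [align_to_model()].
#' @param cond A [condition_spec()].
#' @param cfg An [integration_config()].
#' @param ctilde Resolved numeric biomass coefficient.
#' @return An `integration_problem`: the constraint system plus variable index maps.
#' @export
build_integration <- function(net, envelope, gtilde, cond, cfg = integration_config(),
                      ctilde) {
  stopifnot(inherits(net, "irreversible_network"),
            inherits(envelope, "flux_envelope"))
  n <- length(net$reaction_ids)
  k <- length(net$gene_ids)
  if (!identical(names(envelope$min), net$reaction_ids)) {
    stop("envelope does not match the network's reactions", call. = FALSE)
  }
  if (!identical(names(gtilde), net$gene_ids)) {
    stop("expression vector must be aligned to the model gene list (see ",
         "align_to_model)", call. = FALSE)
  }
  biomass_j <- which(net$obj_coef != 0)
  if (length(biomass_j) != 1L) {
    stop("the integration MILP needs exactly one biomass reaction ",
         "(one non-zero objective coefficient)", call. = FALSE)
  }
  bounds <- condition_bounds(net, cond, cfg$exp_mode, cfg$exp_band)
  ub <- ifelse(is.finite(bounds$ub), bounds$ub, cfg$U_default)

  lp <- new_lp()
  v_idx <- lp_add_vars(lp, paste0("v_", net$reaction_ids),
                       lb = bounds$lb, ub = ub)
  # mass balance
  for (i in seq_along(net$metabolite_ids)) {
    nz <- which(net$S[i, ] != 0)
    if (length(nz)) lp_add_constr(lp, v_idx[nz], net$S[i, nz], "=", 0)
  }
  # direction binaries: only split pairs get a free binary; all other
  # reactions behave as b = 1 (their plain upper bound)
  b_idx <- rep(NA_integer_, n)
  if (!is.null(net$re_pairs) && nrow(net$re_pairs)) {
    for (r in seq_len(nrow(net$re_pairs))) {
      f <- net$re_pairs[r, "forward"]; b <- net$re_pairs[r, "backward"]
      b_idx[f] <- lp_add_var(lp, paste0("b_", net$reaction_ids[f]),
                             lb = 0, ub = 1, integer = TRUE)
      b_idx[b] <- lp_add_var(lp, paste0("b_", net$reaction_ids[b]),
                             lb = 0, ub = 1, integer = TRUE)
      lp_add_constr(lp, c(v_idx[f], b_idx[f]), c(1, -ub[f]), "<=", 0)
      lp_add_constr(lp, c(v_idx[b], b_idx[b]), c(1, -ub[b]), "<=", 0)
      lp_add_constr(lp, c(b_idx[f], b_idx[b]), c(1, 1), "=", 1)
    }
  }
  # gene activity variables and anchoring to measured relative expression
  g_idx <- lp_add_vars(lp, paste0("g_", net$gene_ids), lb = 0, ub = 1)
  names(g_idx) <- net$gene_ids
  delta_idx <- matrix(NA_integer_, k, 2)
  measured <- !is.na(gtilde)
  for (i in which(measured)) {
    d1 <- lp_add_var(lp, paste0("delta1_", net$gene_ids[i]), obj = 1)
    d2 <- lp_add_var(lp, paste0("delta2_", net$gene_ids[i]), obj = 1)
    delta_idx[i, ] <- c(d1, d2)
    lp_add_constr(lp, c(g_idx[i], d1, d2), c(1, -1, 1), "=", gtilde[[i]])
  }
  # GPR activities and flux matching
  has_rule <- !vapply(net$rules, is.null, logical(1))
  ghat_idx <- rep(NA_integer_, n)
  eps_idx <- matrix(NA_integer_, n, 2)
  for (j in which(has_rule)) {
    ghat_idx[j] <- encode_rule(lp, net$rules[[j]], g_idx,
                               prefix = paste0("gpr_", j), M = 1,
                               or_mode = cfg$or_mode)
    if (envelope$degenerate[j]) next
    rng <- envelope$max[j] - envelope$min[j]
    e1 <- lp_add_var(lp, paste0("eps1_", net$reaction_ids[j]), obj = 1)
    e2 <- lp_add_var(lp, paste0("eps2_", net$reaction_ids[j]), obj = 1)
    eps_idx[j, ] <- c(e1, e2)
    # (v - min)/rng = ghat + e1 - e2   ->   v/rng - ghat - e1 + e2 = min/rng
    lp_add_constr(lp, c(v_idx[j], ghat_idx[j], e1, e2),
                  c(1 / rng, -1, -1, 1), "=", envelope$min[j] / rng)
  }
  lp$obj[v_idx[biomass_j]] <- -ctilde * net$obj_coef[biomass_j]
  structure(list(lp = lp, net = net, envelope = envelope, cond = cond,
                 cfg = cfg, ctilde = ctilde, gtilde = gtilde,
                 v_idx = v_idx, b_idx = b_idx, g_idx = g_idx,
                 ghat_idx = ghat_idx, delta_idx = delta_idx,
                 eps_idx = eps_idx, biomass_j = biomass_j),
            class = "integration_problem")
}

integration_solution_from_x <- function(problem, x, z_star, status, gap,
                                extra = list()) {
  net <- problem$net
  flux <- stats::setNames(x[problem$v_idx], net$reaction_ids)
  g <- stats::setNames(x[problem$g_idx], net$gene_ids)
  ghat <- stats::setNames(rep(NA_real_, length(net$reaction_ids)),
                          net$reaction_ids)
  ok <- !is.na(problem$ghat_idx)
  ghat[ok] <- x[problem$ghat_idx[ok]]
  dsum <- sum(x[stats::na.omit(as.integer(problem$delta_idx))])
  esum <- sum(x[stats::na.omit(as.integer(problem$eps_idx))])
  out <- c(list(
    condition_id = problem$cond$condition_id,
    flux = flux,
    flux_net = collapse_fluxes(net, flux),
    biomass = unname(flux[problem$biomass_j]),
    g = g, ghat = ghat,
    deviation_gene = dsum, deviation_flux = esum,
    z_star = z_star, status = status, gap = gap,
    ctilde = problem$ctilde), extra)
  class(out) <- "integration_solution"
  attr(out, "x_full") <- x
  out
}

#' @export
print.integration_solution <- function(x, ...) {
  cat("<integration_solution> condition ", x$condition_id,
      ": z* = ", format(x$z_star, digits = 6),
      ", biomass = ", format(x$biomass, digits = 6),
      ", deviations (gene ", format(x$deviation_gene, digits = 4),
      ", flux ", format(x$deviation_flux, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Solve the expression-integration MILP
#'
#' @param problem An [build_integration()] problem.
#' @param cfg An [integration_config()] (for the MIP gap).
#' @return An `integration_solution` with fluxes (split and collapsed), gene and
#'   reaction activities, deviation totals, and the optimum `z_star`.
#' @export
solve_integration <- function(problem, cfg = problem$cfg) {
  res <- lp_solve(problem$lp, maximize = FALSE, mip_gap = cfg$mip_gap)
  if (res$status == 2L) stop("integration MILP is infeasible", call. = FALSE)
  if (res$status != 0L && is.null(res$x)) {
    stop("integration MILP failed: ", res$status_name, call. = FALSE)
  }
  integration_solution_from_x(problem, res$x, res$objective, res$status_name, res$gap)
}

# Retention row: -ctilde * v_biomass + sum(delta) + sum(eps) pinned to z*.
add_retention <- function(lp, problem, z_star, tol) {
  idx <- c(problem$v_idx[problem$biomass_j],
           stats::na.omit(as.integer(problem$delta_idx)),
           stats::na.omit(as.integer(problem$eps_idx)))
  coef <- c(-problem$ctilde * problem$net$obj_coef[problem$biomass_j],
            rep(1, length(idx) - 1L))
  lp_add_constr(lp, idx, coef, ">=", z_star - tol)
  lp_add_constr(lp, idx, coef, "<=", z_star + tol)
  invisible(lp)
}

#' Two-step L1 variant: minimal total flux at the retained optimum
#'
#' Step 1 solves the base MILP; step 2 minimizes the total flux
#' `sum(v)` subject to all original constraints plus retention of the step-1
#' optimum within `cfg$retention_tol` (relative). Shrinks alternate optima
#' and removes futile cycles.
#'
#' @inheritParams solve_integration
#' @param base Optional pre-computed step-1 `integration_solution`.
#' @return An `integration_solution`; `z_star` is the retained step-1 optimum and
#'   `total_flux` the minimized flux sum.
#' @export
solve_integration_l1 <- function(problem, cfg = problem$cfg, base = NULL) {
  if (is.null(base)) base <- solve_integration(problem, cfg)
  tol <- cfg$retention_tol * max(1, abs(base$z_star))
  lp <- problem$lp
  nrow0 <- length(lp$rows)
  add_retention(lp, problem, base$z_star, tol)
  obj <- numeric(lp$n_var); obj[problem$v_idx] <- 1
  res <- lp_solve(lp, maximize = FALSE, obj = obj, mip_gap = cfg$mip_gap)
  lp$rows <- lp$rows[seq_len(nrow0)]   # restore the problem
  if (res$status != 0L) {
    stop("L1 step-2 failed: ", res$status_name, call. = FALSE)
  }
  integration_solution_from_x(problem, res$x, base$z_star, res$status_name, res$gap,
                      extra = list(total_flux = res$objective, variant = "l1"))
}

#' Two-step L2 variant: smooth fluxes at the retained optimum
#'
#' Step 2 minimizes `sum(v^2)` under the same constraints and retention row.
#' The backend has no mixed-integer quadratic solver, so the binaries are
#' fixed at their step-1 values and the remaining continuous quadratic
#' program is solved with a tiny ridge on the non-flux variables to keep it
#' strictly convex.
#'
#' @inheritParams solve_integration_l1
#' @return An `integration_solution` with `sum_sq_flux`.
#' @export
solve_integration_l2 <- function(problem, cfg = problem$cfg, base = NULL) {
  if (is.null(base)) base <- solve_integration(problem, cfg)
  step1 <- attr(base, "x_full")
  if (is.null(step1)) {
    res1 <- lp_solve(problem$lp, maximize = FALSE, mip_gap = cfg$mip_gap)
    step1 <- res1$x
  }
  lp <- problem$lp
  nrow0 <- length(lp$rows)
  # retention as a single equality pinned at the step-1 value of the
  # retention expression (exactly feasible; a tight two-sided band is
  # numerically fragile for the active-set QP solver)
  ridx <- c(problem$v_idx[problem$biomass_j],
            stats::na.omit(as.integer(problem$delta_idx)),
            stats::na.omit(as.integer(problem$eps_idx)))
  rcoef <- c(-problem$ctilde * problem$net$obj_coef[problem$biomass_j],
             rep(1, length(ridx) - 1L))
  lp_add_constr(lp, ridx, rcoef, "=", sum(rcoef * step1[ridx]))
  m <- lp_matrices(lp)
  lp$rows <- lp$rows[seq_len(nrow0)]
  # fix binaries at their step-1 values
  int <- which(m$integer)
  if (length(int)) m$lb[int] <- m$ub[int] <- round(step1[int])
  ridge <- rep(1e-6, lp$n_var)
  ridge[problem$v_idx] <- 1
  sol <- solve_qp_rows(2 * ridge, m$A, m$cl, m$cu, m$lb, m$ub, x0 = step1)
  x <- sol$x
  integration_solution_from_x(problem, x, base$z_star, "optimal", NA_real_,
                      extra = list(sum_sq_flux = sum(x[problem$v_idx]^2),
                                   variant = "l2"))
}

#' Run the full pipeline over multiple conditions
#'
#' Per condition: FBA and FVA (retention fraction `cfg$p`); then the shared
#' cross-condition envelope; then the expression transform of the full table;
#' then one integration MILP per condition using that condition's expression
#' column and measured-flux constraints. The balance constant `B` is resolved
#' per condition from its own FBA optimum.
#'
#' @param net A [metabolic_network()] (converted to irreversible form
#'   internally if needed).
#' @param expr Raw gene x condition expression matrix (gene rownames,
#'   condition colnames matching the condition ids).
#' @param conditions List of [condition_spec()] objects.
#' @param cfg An [integration_config()]; `cfg$variant` selects base/l1/l2.
#' @return list with `solutions` (named by condition), `envelope`, `fva`,
#'   `fba`, `rel` (aligned relative expression), and `B` per condition.
#' @export
run_multi_condition <- function(net, expr, conditions, cfg = integration_config()) {
  net <- to_irreversible(net)
  stopifnot(length(conditions) >= 1L,
            all(vapply(conditions, inherits, logical(1), "condition_spec")))
  ids <- vapply(conditions, `[[`, character(1), "condition_id")
  names(conditions) <- ids
  missing_cols <- setdiff(ids, colnames(expr))
  if (length(missing_cols)) {
    stop("expression table lacks condition column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rel <- relative_expression(expr, scheme = cfg$transform, omega = cfg$omega,
                             mean_low = cfg$mean_low)
  rel <- align_to_model(rel, net)
  fba <- lapply(conditions, function(cd)
    solve_fba(net, cd, cfg$exp_mode, cfg$exp_band))
  fva <- lapply(conditions, function(cd)
    run_fva(net, cd, p = cfg$p, exp_mode = cfg$exp_mode,
            exp_band = cfg$exp_band))
  envelope <- build_envelope(fva, omega_flux = cfg$omega_flux)
  k <- length(net$gene_ids); n <- length(net$reaction_ids)
  B <- vapply(fba, function(f) (2 * k + 2 * n) / f$objective, numeric(1))
  solutions <- list(); errors <- list()
  for (id in ids) {
    sol <- tryCatch({
      ct <- resolve_ctilde(cfg$ctilde, B[[id]])
      problem <- build_integration(net, envelope, rel[, id], conditions[[id]], cfg, ct)
      switch(cfg$variant,
             base = solve_integration(problem, cfg),
             l1 = solve_integration_l1(problem, cfg),
             l2 = solve_integration_l2(problem, cfg),
             stop("unknown variant: ", cfg$variant, call. = FALSE))
    }, error = function(e) e)
    if (inherits(sol, "error")) errors[[id]] <- conditionMessage(sol)
    else solutions[[id]] <- sol
  }
  if (length(errors)) {
    warning("condition(s) failed: ",
            paste(names(errors), unlist(errors), sep = ": ", collapse = "; "))
  }
  list(solutions = solutions, envelope = envelope, fva = fva, fba = fba,
       rel = rel, B = B, errors = errors, net = net)
}
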