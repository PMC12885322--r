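# Flux balance analysis, flux variability analysis, and the cross-condition
# flux envelope that places each reaction flux on a [0, 1] scale.

#' Define an experimental condition
#'
#' A condition carries the measured exchange/uptake fluxes (the EXP set) and
#' optional per-reaction bound overrides. Measured values refer to original
#' reaction ids and must be non-negative in the direction the irreversible
#' model carries them.
#'
#' @param condition_id Condition label.
#' @param uptake Named numeric vector: reaction id -> measured flux
#'   (mmol/gDW/h).
#' @param bounds Optional named list: reaction id -> c(lb, ub) override.
#' @return A `condition_spec` object.
#' @export
condition_spec <- function(condition_id, uptake = numeric(), bounds = list()) {
  stopifnot(is.character(condition_id), length(condition_id) == 1L)
  if (length(uptake) && is.null(names(uptake))) {
    stop("uptake must be a named vector of reaction fluxes", call. = FALSE)
  }
  if (any(uptake < 0)) {
    stop("measured fluxes must be non-negative on the irreversible model",
         call. = FALSE)
  }
  structure(list(condition_id = condition_id, uptake = uptake, bounds = bounds),
            class = "condition_spec")
}

# Map an original reaction id to its irreversible column carrying positive
# measured flux (forward column of a split pair, the flipped column of a
# backward-only reaction, or the reaction itself).
exp_column <- function(net, rxn_id) {
  prov <- net$provenance
  hits <- which(prov$orig_id == rxn_id)
  if (!length(hits)) {
    stop("condition references unknown reaction: ", rxn_id, call. = FALSE)
  }
  hits[which.max(prov$sign[hits])]  # forward direction if split
}

# Condition-adjusted bounds for the irreversible network. exp_mode controls
# how measured fluxes constrain their reaction: an equality band v_exp*(1 +/-
# band), a pure upper bound, or a pure lower bound.
#' @keywords internal
condition_bounds <- function(net, cond = NULL,
                             exp_mode = c("equality", "upper", "lower"),
                             exp_band = 0.01) {
  exp_mode <- match.arg(exp_mode)
  lb <- net$lb; ub <- net$ub
  if (is.null(cond)) return(list(lb = lb, ub = ub))
  stopifnot(inherits(cond, "condition_spec"))
  for (rid in names(cond$uptake)) {
    j <- exp_column(net, rid)
    v <- cond$uptake[[rid]]
    if (exp_mode == "equality") {
      lb[j] <- v * (1 - exp_band); ub[j] <- v * (1 + exp_band)
    } else if (exp_mode == "upper") {
      ub[j] <- v
    } else {
      lb[j] <- v
    }
  }
  for (rid in names(cond$bounds)) {
    j <- match(rid, net$reaction_ids)
    if (is.na(j)) stop("bound override references unknown reaction: ", rid,
                       call. = FALSE)
    lb[j] <- cond$bounds[[rid]][1]; ub[j] <- cond$bounds[[rid]][2]
  }
  if (any(lb > ub)) stop("condition bounds are inconsistent (lb > ub)",
                         call. = FALSE)
  list(lb = lb, ub = ub)
}

# Assemble the FBA LP: variables v with mass balance Sv = 0.
fba_lp <- function(net, bounds) {
  lp <- new_lp()
  lp_add_vars(lp, net$reaction_ids, lb = bounds$lb, ub = bounds$ub,
              obj = net$obj_coef)
  n <- length(net$reaction_ids)
  for (i in seq_along(net$metabolite_ids)) {
    nz <- which(net$S[i, ] != 0)
    if (length(nz)) lp_add_constr(lp, nz, net$S[i, nz], "=", 0)
  }
  lp
}

#' Solve flux balance analysis
#'
#' Maximizes the model objective (biomass unless stated otherwise) subject to
#' steady-state mass balance and condition bounds, on the irreversible
#' network.
#'
#' @param net An [to_irreversible()] network.
#' @param cond Optional [condition_spec()].
#' @param exp_mode,exp_band How measured fluxes constrain their reactions;
#'   see [integration_config()].
#' @return list with `flux` (named vector), `objective` (f*), and `status`.
#' @export
solve_fba <- function(net, cond = NULL, exp_mode = "equality", exp_band = 0.01) {
  stopifnot(inherits(net, "irreversible_network"))
  bounds <- condition_bounds(net, cond, exp_mode, exp_band)
  lp <- fba_lp(net, bounds)
  res <- lp_solve(lp, maximize = TRUE)
  if (res$status == 2L) stop("FBA is infeasible under the given condition",
                             call. = FALSE)
  if (res$status == 3L) stop("FBA is unbounded; check exchange bounds",
                             call. = FALSE)
  list(flux = res$x, objective = res$objective, status = res$status_name)
}

#' Run flux variability analysis for one condition
#'
#' Computes per-reaction minimum (`alpha`) and maximum (`beta`) fluxes subject
#' to mass balance, condition bounds, and retention of the FBA optimum:
#' objective fixed at `p * f` (equality by default, `>=` with
#' `retention = "ge"`).
#'
#' @inheritParams solve_fba
#' @param p Retained fraction of the FBA optimum, in \[0, 1\] (default 1).
#' @param retention `"eq"` (objective pinned to `p * f`) or `"ge"`.
#' @param reactions Optional subset of reaction ids to scan.
#' @return An `fva_result`: list(condition_id, alpha, beta, f_star, p).
#' @export
run_fva <- function(net, cond = NULL, p = 1, retention = c("eq", "ge"),
                    exp_mode = "equality", exp_band = 0.01, reactions = NULL) {
  stopifnot(inherits(net, "irreversible_network"), p >= 0, p <= 1)
  retention <- match.arg(retention)
  fba <- solve_fba(net, cond, exp_mode, exp_band)
  bounds <- condition_bounds(net, cond, exp_mode, exp_band)
  lp <- fba_lp(net, bounds)
  nz <- which(net$obj_coef != 0)
  if (length(nz)) {
    lp_add_constr(lp, nz, net$obj_coef[nz],
                  if (retention == "eq") "=" else ">=", p * fba$objective)
  }
  if (is.null(reactions)) reactions <- net$reaction_ids
  jset <- match(reactions, net$reaction_ids)
  if (anyNA(jset)) stop("unknown reaction id in FVA request", call. = FALSE)
  n <- length(net$reaction_ids)
  alpha <- beta <- stats::setNames(rep(NA_real_, length(jset)), reactions)
  for (k in seq_along(jset)) {
    ej <- numeric(n); ej[jset[k]] <- 1
    lo <- lp_solve(lp, maximize = FALSE, obj = ej)
    hi <- lp_solve(lp, maximize = TRUE, obj = ej)
    if (lo$status != 0L || hi$status != 0L) {
      stop("FVA subproblem failed for reaction ", reactions[k], call. = FALSE)
    }
    alpha[k] <- lo$objective; beta[k] <- hi$objective
  }
  # suppress solver sign noise near zero and enforce alpha <= beta
  alpha[abs(alpha) < 1e-9] <- 0
  beta[abs(beta) < 1e-9] <- 0
  alpha <- pmin(alpha, beta)
  structure(list(condition_id = if (is.null(cond)) "default" else cond$condition_id,
                 alpha = alpha, beta = beta, f_star = fba$objective, p = p),
            class = "fva_result")
}

#' Build the cross-condition flux envelope
#'
#' Element-wise minimum of FVA minima and maximum of FVA maxima over all
#' conditions. Reactions whose envelope range does not exceed `omega_flux`
#' are flagged degenerate and are skipped by the flux-scaling constraint of
#' the integration MILP.
#'
#' @param results List of `fva_result` objects on the same reaction set.
#' @param omega_flux Degeneracy threshold on the envelope range (default
#'   0.001, mirroring the expression guard).
#' @return A `flux_envelope`: list(min, max, degenerate) over reactions.
#' @export
build_envelope <- function(results, omega_flux = 0.001) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "fva_result")))
  ids <- names(results[[1]]$alpha)
  for (r in results) {
    if (!identical(names(r$alpha), ids)) {
      stop("FVA results cover different reaction sets", call. = FALSE)
    }
  }
  amin <- do.call(pmin, lapply(results, `[[`, "alpha"))
  bmax <- do.call(pmax, lapply(results, `[[`, "beta"))
  structure(list(min = amin, max = bmax,
                 degenerate = (bmax - amin) <= omega_flux,
                 omega_flux = omega_flux),
            class = "flux_envelope")
}
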