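# Accuracy against measured fluxes and flexibility of predicted fluxes.
#
# Measured fluxes (e.g. from 13C metabolic flux analysis) rarely map
# one-to-one onto model reactions: a measured step spanning sequential
# reactions takes the minimum of their predicted fluxes, parallel routes take
# the sum. Mapping expressions use a mini-language: min(...), +, parentheses
# and reaction ids, arbitrarily nested.

#' Parse a measured-flux mapping expression
#'
#' Grammar: `expr := term ('+' term)*`;
#' `term := 'min' '(' expr (',' expr)* ')' | '(' expr ')' | reaction_id`.
#'
#' @param text Mapping expression, e.g. `"min(R1, R2 + R3)"`.
#' @return A parsed expression tree (internal representation).
#' @export
parse_flux_map <- function(text) {
  tokens <- regmatches(text, gregexpr("min|[()+,]|[^()+,[:space:]]+", text))[[1]]
  st <- new.env(parent = emptyenv()); st$t <- tokens; st$pos <- 1L
  peek <- function() if (st$pos > length(st$t)) NULL else st$t[st$pos]
  eat <- function(expected = NULL) {
    tok <- peek()
    if (is.null(tok)) stop("flux-map parse error: unexpected end of '", text,
                           "'", call. = FALSE)
    if (!is.null(expected) && tok != expected) {
      stop("flux-map parse error in '", text, "': expected '", expected,
           "', got '", tok, "'", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    tok
  }
  parse_expr <- function() {
    terms <- list(parse_term())
    while (identical(peek(), "+")) {
      eat("+")
      terms[[length(terms) + 1L]] <- parse_term()
    }
    if (length(terms) == 1L) terms[[1]] else list(op = "sum", args = terms)
  }
  parse_term <- function() {
    tok <- peek()
    if (identical(tok, "min")) {
      eat("min"); eat("(")
      args <- list(parse_expr())
      while (identical(peek(), ",")) { eat(","); args[[length(args) + 1L]] <- parse_expr() }
      eat(")")
      return(list(op = "min", args = args))
    }
    if (identical(tok, "(")) {
      eat("(")
      inner <- parse_expr()
      eat(")")
      return(inner)
    }
    if (is.null(tok) || tok %in% c(")", ",", "+")) {
      stop("flux-map parse error in '", text, "'", call. = FALSE)
    }
    list(op = "rxn", id = eat())
  }
  out <- parse_expr()
  if (st$pos <= length(st$t)) {
    stop("flux-map parse error in '", text, "': trailing '", peek(), "'",
         call. = FALSE)
  }
  out
}

eval_flux_map <- function(node, flux) {
  if (node$op == "rxn") {
    if (!node$id %in% names(flux)) {
      stop("flux map references unknown reaction: ", node$id, call. = FALSE)
    }
    return(unname(flux[[node$id]]))
  }
  vals <- vapply(node$args, eval_flux_map, numeric(1), flux = flux)
  if (node$op == "min") min(vals) else sum(vals)
}

#' Evaluate mapping expressions on a predicted flux vector
#'
#' @param map Named character vector or list: measured id -> mapping
#'   expression (see [parse_flux_map()]).
#' @param flux Named numeric vector of predicted fluxes on original reaction
#'   ids (typically collapsed net fluxes).
#' @param absolute Evaluate on `|flux|` (default), matching magnitude-based
#'   measured fluxes; set `FALSE` for signed fluxes.
#' @return Named numeric vector of predicted values aligned to measured ids.
#' @export
map_predicted <- function(map, flux, absolute = TRUE) {
  if (absolute) flux <- abs(flux)
  vapply(map, function(expr) {
    node <- if (is.character(expr)) parse_flux_map(expr) else expr
    eval_flux_map(node, flux)
  }, numeric(1))
}

#' Uncentered Pearson correlation
#'
#' Cosine similarity of the raw (non-mean-centered) vectors:
#' `R = sum(p * m) / sqrt(sum(p^2) * sum(m^2))`, in \[-1, 1\].
#'
#' @param v_p,v_m Predicted and measured flux vectors (equal length >= 2).
#' @return The correlation R.
#' @examples
#' uncentered_pearson(c(1, 2), c(2, 1))  # 0.8
#' @export
uncentered_pearson <- function(v_p, v_m) {
  stopifnot(length(v_p) == length(v_m), length(v_p) >= 2)
  np <- sqrt(sum(v_p^2)); nm <- sqrt(sum(v_m^2))
  if (np == 0 || nm == 0) {
    stop("uncentered correlation undefined for a zero vector", call. = FALSE)
  }
  sum(v_p * v_m) / (np * nm)
}

#' Root mean square error between predicted and measured fluxes
#'
#' The standard RMSE `sqrt(mean((p - m)^2))`. `as_printed = TRUE` returns the
#' raw sum of squared deviations instead (no root, no 1/t), for comparison
#' with summaries that report it that way.
#'
#' @param v_p,v_m Equal-length numeric vectors.
#' @param as_printed Return the plain sum of squares.
#' @return A non-negative scalar.
#' @export
flux_rmse <- function(v_p, v_m, as_printed = FALSE) {
  stopifnot(length(v_p) == length(v_m), length(v_p) >= 1)
  ss <- sum((v_p - v_m)^2)
  if (as_printed) ss else sqrt(ss / length(v_p))
}

#' Normalize RMSE values across a batch
#'
#' `NRMSE = (rmse - min) / (max - min)` with the min/max taken over the batch
#' of runs (methods and/or conditions) the caller chooses to normalize
#' together. A batch with zero spread gets 0 for all members, with a warning.
#'
#' @param rmse Numeric vector of RMSE values (length >= 2).
#' @return Numeric vector of NRMSE values in \[0, 1\].
#' @export
nrmse <- function(rmse) {
  stopifnot(length(rmse) >= 2)
  rng <- max(rmse) - min(rmse)
  if (rng == 0) {
    warning("all RMSE values equal; NRMSE set to 0")
    return(rep(0, length(rmse)))
  }
  (rmse - min(rmse)) / rng
}

#' Accuracy report for one condition
#'
#' Maps predicted fluxes onto measured ids and computes the uncentered
#' Pearson correlation and RMSE.
#'
#' @param map Measured id -> mapping expression (see [map_predicted()]).
#' @param flux Predicted net flux vector on original reaction ids.
#' @param measured Named numeric vector of measured fluxes (same ids as
#'   `map`).
#' @param absolute Evaluate mappings on absolute fluxes.
#' @return list(pairs data.frame, R, rmse, n).
#' @export
accuracy_report <- function(map, flux, measured, absolute = TRUE) {
  v_p <- map_predicted(map[names(measured)], flux, absolute = absolute)
  v_m <- as.numeric(measured)
  list(pairs = data.frame(measured_id = names(measured),
                          predicted = unname(v_p), measured = v_m),
       R = uncentered_pearson(v_p, v_m),
       rmse = flux_rmse(v_p, v_m),
       n = length(v_m))
}

#' Flexibility of reaction fluxes under a fixed stage-1 optimum
#'
#' Two-stage analysis: the stage-1 objective (either the FBA biomass optimum
#' or the integration MILP optimum) is fixed within a relative tolerance,
#' then each original reaction's net flux is independently minimized and
#' maximized. Flexibility is `FR = |v_max - v_min|` per reaction; subsystem
#' means aggregate it pathway-wise.
#'
#' @param source Either a list returned by [solve_fba()] together with
#'   `net`/`cond`, or an `integration_problem` + its solved `integration_solution`.
#' @param net An [to_irreversible()] network (FBA mode).
#' @param cond Optional [condition_spec()] (FBA mode).
#' @param problem,solution Integration-MILP mode: the [build_integration()] problem
#'   and its [solve_integration()] solution.
#' @param tol Relative tolerance on the fixed stage-1 objective (default
#'   1e-6).
#' @param exp_mode,exp_band Exchange-constraint mode (FBA mode).
#' @return A `flexibility_report`: data.frame(reaction, subsystem, v_min,
#'   v_max, fr) plus a `subsystem_mean` attribute.
#' @export
flexibility <- function(net = NULL, cond = NULL, problem = NULL,
                        solution = NULL, tol = 1e-6,
                        exp_mode = "equality", exp_band = 0.01) {
  if (!is.null(problem)) {
    stopifnot(inherits(problem, "integration_problem"))
    if (is.null(solution)) solution <- solve_integration(problem)
    net <- problem$net
    lp <- problem$lp
    nrow0 <- length(lp$rows)
    add_retention(lp, problem, solution$z_star,
                  tol * max(1, abs(solution$z_star)))
    on.exit(lp$rows <- lp$rows[seq_len(nrow0)], add = TRUE)
    v_idx <- problem$v_idx
    solve_dir <- function(obj, maximize) lp_solve(lp, maximize = maximize, obj = obj)
  } else {
    stopifnot(inherits(net, "irreversible_network"))
    fba <- solve_fba(net, cond, exp_mode, exp_band)
    bounds <- condition_bounds(net, cond, exp_mode, exp_band)
    lp <- fba_lp(net, bounds)
    nz <- which(net$obj_coef != 0)
    band <- tol * max(1, abs(fba$objective))
    lp_add_constr(lp, nz, net$obj_coef[nz], ">=", fba$objective - band)
    lp_add_constr(lp, nz, net$obj_coef[nz], "<=", fba$objective + band)
    v_idx <- seq_along(net$reaction_ids)
    solve_dir <- function(obj, maximize) lp_solve(lp, maximize = maximize, obj = obj)
  }
  orig <- net$original_reaction_ids
  prov <- net$provenance
  n_var <- lp$n_var
  v_min <- v_max <- stats::setNames(numeric(length(orig)), orig)
  for (rid in orig) {
    rows <- which(prov$orig_id == rid)
    obj <- numeric(n_var)
    obj[v_idx[rows]] <- prov$sign[rows]
    lo <- solve_dir(obj, FALSE); hi <- solve_dir(obj, TRUE)
    if (lo$status != 0L || hi$status != 0L) {
      stop("flexibility subproblem failed for ", rid, call. = FALSE)
    }
    v_min[rid] <- lo$objective; v_max[rid] <- hi$objective
  }
  fr <- abs(v_max - v_min)
  fr[fr < 1e-9] <- 0
  sub <- stats::setNames(net$subsystem[match(
    vapply(orig, function(r) which(prov$orig_id == r)[1], integer(1)),
    seq_len(nrow(prov)))], orig)
  df <- data.frame(reaction = orig, subsystem = unname(sub),
                   v_min = unname(v_min), v_max = unname(v_max),
                   fr = unname(fr), stringsAsFactors = FALSE)
  means <- tapply(df$fr, df$subsystem, mean)
  structure(df, class = c("flexibility_report", "data.frame"),
            subsystem_mean = means)
}

#' Subsystem flexibility ratio between two flexibility reports
#'
#' Mean flexibility per subsystem of `numer` divided by that of `denom`
#' (e.g. expression-integrated vs. plain FBA). Subsystems with zero
#' denominator and zero numerator give 1; zero denominator with positive
#' numerator gives Inf.
#'
#' @param numer,denom Two [flexibility()] reports on the same network.
#' @return Named numeric vector of ratios per subsystem.
#' @export
flexibility_ratio <- function(numer, denom) {
  a <- attr(numer, "subsystem_mean"); b <- attr(denom, "subsystem_mean")
  stopifnot(identical(names(a), names(b)))
  ratio <- ifelse(b > 0, a / b, ifelse(a > 0, Inf, 1))
  stats::setNames(as.numeric(ratio), names(a))
}
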