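# Incremental builder for (mixed-integer) linear programs.
#
# Variables and constraint rows are accumulated in an environment so that
# encoders (GPR blocks, deviation rows, ...) can compose freely; the finished
# problem is materialised as dense matrices and handed to the solver backend.

#' Create an empty linear-program builder
#'
#' An internal mutable container for variables (name, bounds, objective
#' coefficient, integrality) and linear constraint rows. Used by the FBA/FVA
#' and expression-integration model assemblers and by the GPR constraint
#' encoders.
#'
#' @return An object of class `lp_builder`.
#' @keywords internal
new_lp <- function() {
  lp <- new.env(parent = emptyenv())
  lp$n_var <- 0L
  lp$var_name <- character()
  lp$lb <- numeric()
  lp$ub <- numeric()
  lp$obj <- numeric()
  lp$integer <- logical()
  lp$rows <- list()     # each: list(idx, coef, sense, rhs, name)
  class(lp) <- "lp_builder"
  lp
}

#' @keywords internal
lp_add_var <- function(lp, name, lb = 0, ub = Inf, obj = 0, integer = FALSE) {
  if (name %in% lp$var_name) {
    stop("duplicate variable name: ", name, call. = FALSE)
  }
  lp$n_var <- lp$n_var + 1L
  lp$var_name <- c(lp$var_name, name)
  lp$lb <- c(lp$lb, lb)
  lp$ub <- c(lp$ub, ub)
  lp$obj <- c(lp$obj, obj)
  lp$integer <- c(lp$integer, integer)
  lp$n_var
}

#' @keywords internal
lp_add_vars <- function(lp, names, lb = 0, ub = Inf, obj = 0, integer = FALSE) {
  k <- length(names)
  if (any(names %in% lp$var_name)) {
    stop("duplicate variable name(s)", call. = FALSE)
  }
  idx <- lp$n_var + seq_len(k)
  lp$n_var <- lp$n_var + k
  lp$var_name <- c(lp$var_name, names)
  lp$lb <- c(lp$lb, rep_len(lb, k))
  lp$ub <- c(lp$ub, rep_len(ub, k))
  lp$obj <- c(lp$obj, rep_len(obj, k))
  lp$integer <- c(lp$integer, rep_len(integer, k))
  idx
}

#' @keywords internal
lp_add_constr <- function(lp, idx, coef, sense = c("=", "<=", ">="), rhs,
                          name = NULL) {
  sense <- match.arg(sense)
  stopifnot(length(idx) == length(coef))
  lp$rows[[length(lp$rows) + 1L]] <-
    list(idx = as.integer(idx), coef = as.numeric(coef),
         sense = sense, rhs = as.numeric(rhs), name = name)
  invisible(lp)
}

#' @keywords internal
lp_set_bounds <- function(lp, idx, lb = NULL, ub = NULL) {
  if (!is.null(lb)) lp$lb[idx] <- lb
  if (!is.null(ub)) lp$ub[idx] <- ub
  invisible(lp)
}

#' @keywords internal
lp_set_objective <- function(lp, obj) {
  stopifnot(length(obj) == lp$n_var)
  lp$obj <- as.numeric(obj)
  invisible(lp)
}

# Materialise the builder as dense matrices: A x within [cl, cu].
#' @keywords internal
lp_matrices <- function(lp) {
  n_row <- length(lp$rows)
  A <- matrix(0, nrow = n_row, ncol = lp$n_var)
  cl <- numeric(n_row)
  cu <- numeric(n_row)
  for (r in seq_len(n_row)) {
    row <- lp$rows[[r]]
    A[r, row$idx] <- row$coef
    cl[r] <- switch(row$sense, "=" = row$rhs, ">=" = row$rhs, "<=" = -Inf)
    cu[r] <- switch(row$sense, "=" = row$rhs, "<=" = row$rhs, ">=" = Inf)
  }
  list(A = A, cl = cl, cu = cu, lb = lp$lb, ub = lp$ub,
       obj = lp$obj, integer = lp$integer, var_name = lp$var_name)
}

#' Solve a built (MI)LP with the HiGHS backend
#'
#' @param lp An `lp_builder`.
#' @param maximize Maximize instead of minimize.
#' @param obj Optional objective vector overriding the one stored on the
#'   variables (used by variability sweeps that re-solve with many objectives).
#' @param relax_integrality Treat binaries as continuous (LP relaxation).
#' @param mip_gap Relative MIP optimality gap passed to the solver.
#' @return list(status, status_code, objective, x (named), gap).
#' @keywords internal
lp_solve <- function(lp, maximize = FALSE, obj = NULL,
                     relax_integrality = FALSE, mip_gap = 1e-9) {
  m <- lp_matrices(lp)
  if (!is.null(obj)) {
    stopifnot(length(obj) == lp$n_var)
    m$obj <- as.numeric(obj)
  }
  integrality <- if (relax_integrality) rep(0L, lp$n_var) else as.integer(m$integer)
  res <- solve_highs(m$obj, m$A, m$cl, m$cu, m$lb, m$ub, integrality,
                     maximize = maximize, mip_gap = mip_gap)
  if (res$status == 0L && !is.null(res$x)) names(res$x) <- m$var_name
  res
}

# Thin wrapper around scipy.optimize.milp (HiGHS). Handles both pure LPs and
# MILPs; equality rows are encoded as cl == cu.
#' @keywords internal
solve_highs <- function(obj, A, cl, cu, lb, ub, integrality,
                        maximize = FALSE, mip_gap = 1e-9) {
  sp <- scipy_optimize()
  np <- reticulate::import("numpy", delay_load = FALSE)
  sign <- if (maximize) -1 else 1
  n <- length(obj)
  constraints <- NULL
  if (nrow(A) > 0L) {
    constraints <- sp$LinearConstraint(A, as.numeric(cl), as.numeric(cu))
  }
  bounds <- sp$Bounds(as.numeric(lb), as.numeric(ub))
  res <- sp$milp(sign * as.numeric(obj),
                 constraints = constraints,
                 integrality = np$array(as.integer(integrality)),
                 bounds = bounds,
                 options = list(mip_rel_gap = mip_gap, presolve = TRUE))
  status_code <- as.integer(res$status)
  status <- c("optimal", "limit", "infeasible", "unbounded", "error")[status_code + 1L]
  x <- if (!is.null(res$x)) as.numeric(res$x) else NULL
  objective <- if (!is.null(res$fun)) sign * as.numeric(res$fun) else NA_real_
  gap <- tryCatch(as.numeric(res$mip_gap), error = function(e) NA_real_)
  list(status = status_code, status_name = status, objective = objective,
       x = x, gap = gap, message = as.character(res$message))
}

# Continuous quadratic program min 0.5 x'D x s.t. rows/bounds, via quadprog.
# D must be positive definite; callers add a small ridge on variables without
# a quadratic cost. Rows with cl == cu become equalities. Variables with
# lb == ub are substituted out and linearly dependent equality rows removed
# (quadprog requires an independent equality system).
#' @keywords internal
solve_qp_rows <- function(Ddiag, A, cl, cu, lb, ub, x0 = NULL) {
  out <- tryCatch(solve_qp_quadprog(Ddiag, A, cl, cu, lb, ub),
                  error = function(e) e)
  if (!inherits(out, "error")) return(out)
  if (is.null(x0)) stop(out)
  solve_qp_trust_constr(Ddiag, A, cl, cu, lb, ub, x0)
}

# Interior/trust-region fallback via scipy, warm-started from a feasible
# point (the step-1 MILP solution); used when the active-set solver reports
# numerical inconsistency on degenerate constraint systems.
solve_qp_trust_constr <- function(Ddiag, A, cl, cu, lb, ub, x0) {
  sp <- scipy_optimize()
  np <- reticulate::import("numpy", delay_load = FALSE)
  n <- length(Ddiag)
  fun <- function(x) 0.5 * sum(Ddiag * x^2)
  jac <- function(x) Ddiag * x
  hess <- function(x) diag(Ddiag, n)
  res <- sp$minimize(
    fun, np$array(as.numeric(x0)), jac = jac, hess = hess,
    method = "trust-constr",
    constraints = list(sp$LinearConstraint(A, as.numeric(cl), as.numeric(cu))),
    bounds = sp$Bounds(as.numeric(lb), as.numeric(ub)),
    options = list(gtol = 1e-10, xtol = 1e-12, maxiter = 3000L))
  x <- as.numeric(res$x)
  list(x = x, objective = sum(Ddiag * x^2) / 2)
}

solve_qp_quadprog <- function(Ddiag, A, cl, cu, lb, ub) {
  n <- length(Ddiag)
  # presolve: repeatedly substitute pinned variables into the rows and fold
  # single-variable rows into bounds; the active-set solver is fragile when
  # a variable is pinned by opposing inequalities instead of its bounds
  x <- rep(NA_real_, n)
  repeat {
    changed <- FALSE
    pin <- is.na(x) & is.finite(lb) & is.finite(ub) & (ub - lb) < 1e-10
    if (any(pin)) {
      x[pin] <- (lb[pin] + ub[pin]) / 2
      shift <- as.numeric(A[, pin, drop = FALSE] %*% x[pin])
      cl <- cl - shift; cu <- cu - shift
      A[, pin] <- 0
      lb[pin] <- 0; ub[pin] <- 0   # excluded below
      changed <- TRUE
    }
    nzc <- rowSums(A != 0)
    single <- which(nzc == 1L)
    for (r in single) {
      j <- which(A[r, ] != 0)
      a <- A[r, j]
      lo <- min(cl[r] / a, cu[r] / a); hi <- max(cl[r] / a, cu[r] / a)
      if (lo > lb[j] + 1e-12) { lb[j] <- lo; changed <- TRUE }
      if (hi < ub[j] - 1e-12) { ub[j] <- hi; changed <- TRUE }
      A[r, j] <- 0; cl[r] <- -Inf; cu[r] <- Inf
      if (lb[j] > ub[j] + 1e-9) {
        stop("quadratic step infeasible after fixing integer variables",
             call. = FALSE)
      }
    }
    if (!changed) break
  }
  fixed <- !is.na(x)
  free <- which(!fixed)
  nz_row <- rowSums(abs(A)) > 1e-12
  if (any(!nz_row & (cl > 1e-9 | cu < -1e-9))) {
    stop("quadratic step infeasible after fixing integer variables",
         call. = FALSE)
  }
  A <- A[nz_row, , drop = FALSE]; cl <- cl[nz_row]; cu <- cu[nz_row]
  A <- A[, free, drop = FALSE]
  lb <- lb[free]; ub <- ub[free]; Ddiag <- Ddiag[free]
  nf <- length(free)
  # merge rows that are scalar multiples of each other (fixed selector
  # binaries leave opposing inequality pairs — implicit equalities that the
  # active-set solver cannot cope with)
  if (nrow(A) > 1L) {
    canon_cl <- cl; canon_cu <- cu
    for (r in seq_len(nrow(A))) {
      j1 <- which(abs(A[r, ]) > 1e-12)[1]
      s <- A[r, j1]
      A[r, ] <- A[r, ] / s
      bnds <- sort(c(canon_cl[r] / s, canon_cu[r] / s))
      canon_cl[r] <- bnds[1]; canon_cu[r] <- bnds[2]
    }
    key <- apply(round(A, 9), 1, paste, collapse = ",")
    grp <- match(key, key)
    cl <- tapply(canon_cl, grp, max)[as.character(sort(unique(grp)))]
    cu <- tapply(canon_cu, grp, min)[as.character(sort(unique(grp)))]
    A <- A[sort(unique(grp)), , drop = FALSE]
    cl <- as.numeric(cl); cu <- as.numeric(cu)
    if (any(cl > cu + 1e-7)) {
      stop("quadratic step infeasible after fixing integer variables",
           call. = FALSE)
    }
    near <- cu - cl < 1e-7 & cu > cl
    mid <- (cl + cu) / 2
    cl[near] <- mid[near]; cu[near] <- mid[near]
  }
  eq <- is.finite(cl) & is.finite(cu) & (cu - cl) < 1e-12
  Ae <- A[eq, , drop = FALSE]; be <- (cl[eq] + cu[eq]) / 2
  if (nrow(Ae) > 1L) {
    qre <- qr(t(Ae))
    keep <- qre$pivot[seq_len(qre$rank)]
    Ae <- Ae[keep, , drop = FALSE]; be <- be[keep]
  }
  # inequality rows G z >= h (constraint rows both ways, finite bounds)
  rows <- list(); rhs <- numeric()
  add <- function(a, b) { rows[[length(rows) + 1L]] <<- a; rhs[length(rhs) + 1L] <<- b }
  for (r in which(!eq)) {
    if (is.finite(cl[r])) add(A[r, ], cl[r])
    if (is.finite(cu[r])) add(-A[r, ], -cu[r])
  }
  for (j in seq_len(nf)) {
    ej <- numeric(nf)
    if (is.finite(lb[j])) { ej[j] <- 1; add(ej, lb[j]) }
    if (is.finite(ub[j])) { ej <- numeric(nf); ej[j] <- -1; add(ej, -ub[j]) }
  }
  G <- do.call(rbind, rows); h <- rhs
  # eliminate the equalities through the null space of Ae, leaving an
  # inequality-only QP (the active-set solver is far more robust there),
  # escalating the ridge if it still reports numerical inconsistency
  me <- nrow(Ae)
  if (me > 0L) {
    x0 <- as.numeric(t(Ae) %*% solve(Ae %*% t(Ae), be))
    Qfull <- qr.Q(qr(t(Ae)), complete = TRUE)
    N <- Qfull[, (me + 1L):nf, drop = FALSE]
  } else {
    x0 <- numeric(nf)
    N <- diag(nf)
  }
  Gy <- G %*% N
  hy <- h - as.numeric(G %*% x0)
  sol <- NULL
  for (floor_ratio in c(0, 1e-4, 1e-2, 1)) {
    dd <- pmax(Ddiag, max(Ddiag) * floor_ratio)
    Dy <- crossprod(N, dd * N)
    Dy <- (Dy + t(Dy)) / 2 + diag(1e-10, ncol(N))
    dvec <- -as.numeric(crossprod(N, dd * x0))
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = Dy, dvec = dvec, Amat = t(Gy), bvec = hy),
      error = function(e) e)
    if (!inherits(sol, "error")) break
  }
  if (inherits(sol, "error")) {
    stop("quadratic step failed: ", conditionMessage(sol), call. = FALSE)
  }
  z <- x0 + as.numeric(N %*% sol$solution)
  x[free] <- z
  list(x = x, objective = sum(Ddiag * z^2) / 2)
}
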