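# Fixtures and independent oracles shared across the suite.

# Small bespoke network: uptake -> A <-> B -> C -> D -> biomass with one
# reversible (rule-less) pair and two rule-bearing reactions over 3 genes.
census_network <- function(uptake = 10) {
  mets <- c("A", "B", "C", "D")
  rxns <- c("EX_A", "TRANS", "R1", "R2", "BIOMASS")
  S <- matrix(0, 4, 5, dimnames = list(mets, rxns))
  S["A", "EX_A"] <- 1
  S["A", "TRANS"] <- -1; S["B", "TRANS"] <- 1
  S["B", "R1"] <- -1; S["C", "R1"] <- 1
  S["C", "R2"] <- -1; S["D", "R2"] <- 1
  S["D", "BIOMASS"] <- -1
  metabolic_network(
    mets, rxns, S,
    lb = c(0, -1000, 0, 0, 0),
    ub = c(uptake, 1000, 1000, 1000, 1000),
    obj_coef = c(0, 0, 0, 0, 1),
    rules = list(NULL, NULL, parse_gpr("g1 and g2"), parse_gpr("g3"), NULL),
    subsystem = c("Exchange", "Core", "Core", "Core", "Biomass"))
}

# Random GPR AST with bounded depth and leaf count (for oracle equivalence).
random_ast <- function(genes, max_depth = 3) {
  build <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.35) {
      return(gpr_gene(sample(genes, 1)))
    }
    k <- sample(2:3, 1)
    children <- lapply(seq_len(k), function(i) build(depth + 1))
    if (stats::runif(1) < 0.5) do.call(gpr_and, children)
    else do.call(gpr_or, children)
  }
  build(0)
}

# Exhaustive-enumeration oracle for a small MILP: fix every assignment of the
# binary variables via bounds, solve the LP relaxation, and return the best
# objective over feasible assignments. Independent of branch-and-bound.
enumerate_milp_optimum <- function(lp, maximize = FALSE) {
  int <- which(lp$integer)
  stopifnot(length(int) <= 12)
  lb0 <- lp$lb; ub0 <- lp$ub
  on.exit({ lp$lb <- lb0; lp$ub <- ub0 }, add = TRUE)
  best <- if (maximize) -Inf else Inf
  for (mask in 0:(2^length(int) - 1)) {
    bits <- as.numeric(bitwAnd(mask, bitwShiftL(1, seq_along(int) - 1)) > 0)
    lp$lb[int] <- bits; lp$ub[int] <- bits
    res <- lp_solve_relaxed(lp, maximize = maximize)
    if (res$status == 0L) {
      best <- if (maximize) max(best, res$objective) else min(best, res$objective)
    }
  }
  best
}

# Access to internal builder helpers for oracle construction.
lp_solve_relaxed <- function(lp, maximize = FALSE) {
  fluxweaver:::lp_solve(lp, maximize = maximize, relax_integrality = TRUE)
}

# Build a solved multi-condition run on a branch fixture (memoised per
# parameter set to keep the suite fast).
.run_cache <- new.env(parent = emptyenv())
branch_run <- function(D = 3, noise_sd = 0, seed = 1, variant = "base",
                       transform = "max_reference", ctilde = "B") {
  key <- paste(D, noise_sd, seed, variant, transform, ctilde, sep = "|")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  net0 <- make_network("parallel_branches")
  cs <- make_condition_set(net0, D)
  expr <- make_expression(net0, cs$designed, noise_sd, seed = seed)
  cfg <- integration_config(transform = transform, variant = variant, ctilde = ctilde)
  run <- run_multi_condition(net0, expr, cs$conditions, cfg)
  out <- list(net0 = net0, cs = cs, expr = expr, cfg = cfg, run = run)
  .run_cache[[key]] <- out
  out
}
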